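#' Write / read a 2D array as 32-bit float TIFF with a sidecar header
#'
#' TIFF storage is normalized to \[0, 1\]; the affine scale is recorded in
#' a plain-text sidecar (`<path>.txt`) together with any caller-supplied
#' metadata, and undone on read. `NA` values are stored as the minimum and
#' flagged in the sidecar by an `na_value` line.
#'
#' @param x Numeric matrix.
#' @param path Output TIFF path.
#' @param metadata Named list written as `key: value` lines to the
#'   sidecar.
#' @return `write_map_tiff()`: the path, invisibly.
#' @export
write_map_tiff <- function(x, path, metadata = list()) {
  stopifnot(is.matrix(x))
  nas <- is.na(x)
  finite <- x[!nas]
  lo <- if (length(finite)) min(finite) else 0
  hi <- if (length(finite)) max(finite) else 1
  span <- if (hi > lo) hi - lo else 1
  y <- (x - lo) / span
  y[nas] <- 0
  tiff::writeTIFF(y, path, bits.per.sample = 32L)
  meta <- c(list(offset = lo, scale = span,
                 has_na = any(nas)), metadata)
  side <- paste0(path, ".txt")
  writeLines(c("# npfate map sidecar",
               sprintf("%s: %s", names(meta),
                       vapply(meta, function(v) paste(format(v, digits = 17),
                                                      collapse = " "),
                              character(1)))),
             side)
  if (any(nas)) {
    # NA pixel list (row col), 1-based
    idx <- which(nas, arr.ind = TRUE)
    utils::write.table(idx, paste0(path, ".na.txt"), row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

.read_sidecar <- function(path) {
  side <- paste0(path, ".txt")
  if (!file.exists(side)) return(list())
  ln <- grep("^[^#]", readLines(side), value = TRUE)
  keys <- sub(":.*$", "", ln)
  vals <- sub("^[^:]*: *", "", ln)
  stats::setNames(as.list(vals), keys)
}

#' @rdname write_map_tiff
#' @return `read_map_tiff()`: the matrix with the sidecar metadata in
#'   attribute `metadata`.
#' @export
read_map_tiff <- function(path) {
  y <- tiff::readTIFF(path)
  meta <- .read_sidecar(path)
  lo <- as.numeric(meta$offset %||% 0)
  span <- as.numeric(meta$scale %||% 1)
  x <- y * span + lo
  nafile <- paste0(path, ".na.txt")
  if (identical(meta$has_na, "TRUE") && file.exists(nafile)) {
    idx <- as.matrix(utils::read.table(nafile))
    x[idx] <- NA_real_
  }
  attr(x, "metadata") <- meta
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a mesh scan as a directory container
#'
#' The canonical interchange layout: one directory holding a `scan.yaml`
#' manifest (mesh shape, motor step, beam geometry, point validity) and one
#' float TIFF per scan point, `frame_rRRR_cCCC.tif`, each with its sidecar.
#'
#' @param scan A [mesh_scan()].
#' @param dir Directory to create.
#' @return `write_scan_container()`: `dir`, invisibly.
#' @export
write_scan_container <- function(scan, dir) {
  stopifnot(inherits(scan, "mesh_scan"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    kind = "npfate_mesh_scan",
    shape = as.integer(scan$shape),
    step_mm = as.numeric(scan$step),
    valid = as.logical(scan$valid),
    beam = list(energy_kev = scan$beam$energy_kev,
                distance_mm = scan$beam$distance_mm,
                pixel_um = scan$beam$pixel_um,
                center = as.numeric(scan$beam$center)))
  yaml::write_yaml(manifest, file.path(dir, "scan.yaml"))
  k <- 0L
  for (r in seq_len(scan$shape[1])) for (cc in seq_len(scan$shape[2])) {
    k <- k + 1L
    if (!scan$valid[k]) next
    fr <- scan$frames[[k]]
    write_map_tiff(fr$counts,
                   file.path(dir, sprintf("frame_r%03d_c%03d.tif", r, cc)),
                   metadata = list(row = r, col = cc,
                                   motor_y_mm = (r - 1) * scan$step[1],
                                   motor_x_mm = (cc - 1) * scan$step[2],
                                   exposure_time_s = fr$exposure_time))
  }
  invisible(dir)
}

#' @rdname write_scan_container
#' @return `read_scan_container()`: a [mesh_scan()].
#' @export
read_scan_container <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "scan.yaml"))
  if (!identical(manifest$kind, "npfate_mesh_scan"))
    stop("not a mesh-scan container: ", dir)
  shape <- as.integer(manifest$shape)
  beam <- beam_geometry(manifest$beam$energy_kev, manifest$beam$distance_mm,
                        manifest$beam$pixel_um, manifest$beam$center)
  valid <- as.logical(manifest$valid)
  frames <- vector("list", prod(shape))
  k <- 0L
  for (r in seq_len(shape[1])) for (cc in seq_len(shape[2])) {
    k <- k + 1L
    if (!valid[k]) next
    p <- file.path(dir, sprintf("frame_r%03d_c%03d.tif", r, cc))
    x <- read_map_tiff(p)
    expo <- as.numeric(attr(x, "metadata")$exposure_time_s %||% 1)
    attr(x, "metadata") <- NULL
    frames[[k]] <- detector_frame(x, exposure_time = expo)
  }
  mesh_scan(frames, shape, beam, step = as.numeric(manifest$step_mm),
            valid = valid)
}

#' Write / read a CT volume as a TIFF slice stack
#'
#' One float TIFF per z-slice (`slice_ZZZZ.tif`) plus a `volume.yaml`
#' manifest with dimensions and voxel size.
#'
#' @param vol A [volume3d()].
#' @param dir Directory to create.
#' @export
write_volume_stack <- function(vol, dir) {
  stopifnot(inherits(vol, "volume3d"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(vol$gray)
  yaml::write_yaml(list(kind = "npfate_volume", dim = as.integer(d),
                        voxel_size_um = vol$voxel_size,
                        description = vol$description),
                   file.path(dir, "volume.yaml"))
  for (z in seq_len(d[3]))
    write_map_tiff(vol$gray[, , z],
                   file.path(dir, sprintf("slice_%04d.tif", z)))
  invisible(dir)
}

#' @rdname write_volume_stack
#' @export
read_volume_stack <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "volume.yaml"))
  if (!identical(manifest$kind, "npfate_volume"))
    stop("not a volume container: ", dir)
  d <- as.integer(manifest$dim)
  gray <- array(NA_real_, d)
  for (z in seq_len(d[3])) {
    x <- read_map_tiff(file.path(dir, sprintf("slice_%04d.tif", z)))
    attr(x, "metadata") <- NULL
    gray[, , z] <- x
  }
  volume3d(gray, voxel_size = as.numeric(manifest$voxel_size_um),
           description = manifest$description %||% "")
}

#' Export a feature map as float TIFF with a descriptive sidecar
#'
#' Missing points are stored as `NA` (recorded in the sidecar), never as
#' zeros. A fixed color-scale range can be recorded for comparable
#' time-series rendering.
#'
#' @param map A [feature_map()].
#' @param path Output TIFF path.
#' @param color_range Optional `c(lo, hi)` recorded in the sidecar so a
#'   series of maps can be displayed on one scale.
#' @export
write_feature_map <- function(map, path, color_range = NULL) {
  stopifnot(inherits(map, "feature_map"))
  meta <- list(statistic = map$statistic,
               q_lo = map$q_window[1], q_hi = map$q_window[2],
               step_mm = paste(map$step, collapse = " "))
  if (!is.null(color_range))
    meta$color_range <- paste(color_range, collapse = " ")
  write_map_tiff(map$values, path, metadata = meta)
}

# ---------------------------------------------------------------------------
# run configuration

#' Read and validate a run configuration
#'
#' A single declarative YAML file drives the command-line pipeline. The
#' recognized keys (all optional unless a stage needs them) are `beam`
#' (energy_kev, distance_mm, pixel_um, center, photon_flux, exposure_time,
#' spot_area_um2, mass_attenuation_cm2g), `q_window` (lo, hi),
#' `stability_band`, `guinier_limit`, `seed`, `output_dir`.
#'
#' @param path YAML file path.
#' @return A validated `run_config` list with defaults filled in and a
#'   `config_hash` field (FNV-1a of the canonical YAML) echoed into output
#'   headers.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("beam", "q_window", "stability_band", "guinier_limit", "seed",
             "output_dir")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("malformed config: unknown key(s) ", paste(bad, collapse = ", "))
  cfg$q_window <- cfg$q_window %||% list(lo = 0.004, hi = 0.022)
  if (!is.numeric(cfg$q_window$lo) || !is.numeric(cfg$q_window$hi) ||
      cfg$q_window$lo >= cfg$q_window$hi)
    stop("malformed config: q_window needs numeric lo < hi")
  cfg$stability_band <- cfg$stability_band %||% 0.10
  cfg$guinier_limit <- cfg$guinier_limit %||% 1.3
  cfg$seed <- as.integer(cfg$seed %||% 1)
  cfg$output_dir <- cfg$output_dir %||% "."
  if (!is.null(cfg$beam)) {
    need <- c("energy_kev", "distance_mm", "pixel_um", "center")
    miss <- setdiff(need, names(cfg$beam))
    if (length(miss))
      stop("malformed config: beam block missing ", paste(miss, collapse = ", "))
  }
  cfg$config_hash <- config_hash(cfg[setdiff(names(cfg), "config_hash")])
  class(cfg) <- "run_config"
  cfg
}

#' @rdname read_run_config
#' @param cfg A config list.
#' @return `config_hash()`: an 8-hex-digit 32-bit rolling polynomial hash
#'   of the canonical YAML serialization.
#' @export
config_hash <- function(cfg) {
  bytes <- utf8ToInt(yaml::as.yaml(cfg))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Beam geometry from a run config
#' @param cfg A `run_config` with a `beam` block.
#' @return A [beam_geometry()].
#' @export
config_beam <- function(cfg) {
  b <- cfg$beam
  if (is.null(b)) stop("config has no beam block")
  beam_geometry(b$energy_kev, b$distance_mm, b$pixel_um,
                as.numeric(b$center),
                photon_flux = b$photon_flux %||% 1e13,
                exposure_time = b$exposure_time %||% 0.05,
                spot_area_um2 = b$spot_area_um2 %||% 2500,
                mass_attenuation_cm2g = b$mass_attenuation_cm2g %||% 0.56)
}
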