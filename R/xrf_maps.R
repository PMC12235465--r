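#' A fitted X-ray fluorescence element map
#'
#' @param element Element symbol (e.g. `"P"`, `"Ca"`, `"K"`, `"Ce"`,
#'   `"Eu"`).
#' @param intensity Non-negative numeric matrix of fitted line intensities.
#' @param pixel_size Pixel size in um.
#' @return An object of class `element_map`.
#' @export
element_map <- function(element, intensity, pixel_size = 20) {
  stopifnot(is.character(element), length(element) == 1,
            is.matrix(intensity), all(intensity >= 0, na.rm = TRUE),
            pixel_size > 0)
  structure(list(element = element, intensity = intensity,
                 pixel_size = pixel_size), class = "element_map")
}

#' @export
print.element_map <- function(x, ...) {
  cat(sprintf("element_map [%s]: %d x %d px @ %.3g um, max %.4g\n",
              x$element, nrow(x$intensity), ncol(x$intensity),
              x$pixel_size, max(x$intensity)))
  invisible(x)
}

# integer-shift normalized cross-correlation of two binary masks
.ncc_shift <- function(a, b, max_shift) {
  best <- c(0L, 0L); best_cc <- -Inf
  am <- a - mean(a)
  for (dy in -max_shift:max_shift) for (dx in -max_shift:max_shift) {
    r1 <- max(1, 1 + dy):min(nrow(a), nrow(a) + dy)
    c1 <- max(1, 1 + dx):min(ncol(a), ncol(a) + dx)
    r2 <- r1 - dy; c2 <- c1 - dx
    if (length(r1) < 2 || length(c1) < 2) next
    x <- a[r1, c1]; y <- b[r2, c2]
    sx <- stats::sd(x); sy <- stats::sd(y)
    if (sx == 0 || sy == 0) next
    cc <- mean((x - mean(x)) * (y - mean(y))) / (sx * sy)
    if (cc > best_cc) { best_cc <- cc; best <- c(dy, dx) }
  }
  list(offset = best, cc = best_cc)
}

#' Co-register two maps by integer translation and crop to the overlap
#'
#' When no offset is given, the translation of `map_b` relative to `map_a`
#' is estimated by normalized cross-correlation of the Otsu-binarized maps
#' (translation only -- rotation and scale are out of scope and must be
#' handled upstream). Both maps are then cropped to the common region.
#'
#' @param map_a,map_b [element_map()] objects (or any objects with an
#'   `intensity` matrix) of equal size.
#' @param offset Optional known `c(dy, dx)` offset of `map_b` relative to
#'   `map_a` (positive = b's content sits dy rows / dx cols later in a).
#' @param max_shift Search radius in pixels for the automatic estimate
#'   (default a quarter of the smaller map dimension).
#' @param min_correlation Below this correlation the automatic alignment is
#'   rejected (default 0.2).
#' @return List with cropped `a`, `b` (intensity matrices), the `offset`
#'   used and the `correlation` (NA when the offset was supplied).
#' @export
coregister_crop <- function(map_a, map_b, offset = NULL,
                            max_shift = NULL, min_correlation = 0.2) {
  ia <- if (is.list(map_a)) map_a$intensity else map_a
  ib <- if (is.list(map_b)) map_b$intensity else map_b
  stopifnot(is.matrix(ia), is.matrix(ib), all(dim(ia) == dim(ib)))
  cc <- NA_real_
  if (is.null(offset)) {
    if (is.null(max_shift)) max_shift <- floor(min(dim(ia)) / 4)
    ba <- ia > otsu_threshold(as.vector(ia))
    bb <- ib > otsu_threshold(as.vector(ib))
    est <- .ncc_shift(ba * 1, bb * 1, max_shift)
    if (est$cc < min_correlation)
      stop(sprintf("alignment failed: best correlation %.3f < %.2f; supply a manual offset",
                   est$cc, min_correlation))
    offset <- est$offset; cc <- est$cc
  }
  dy <- offset[1]; dx <- offset[2]
  r1 <- max(1, 1 + dy):min(nrow(ia), nrow(ia) + dy)
  c1 <- max(1, 1 + dx):min(ncol(ia), ncol(ia) + dx)
  if (length(r1) < 1 || length(c1) < 1) stop("offset leaves no overlap")
  list(a = ia[r1, c1, drop = FALSE],
       b = ib[r1 - dy, c1 - dx, drop = FALSE],
       offset = as.integer(offset), correlation = cc)
}

#' Time-series element histograms against a control-group reference
#'
#' Builds common-bin histograms of a time series of element maps and marks
#' the maximum intensity of the control map: pixels above that marker are
#' attributable to the dosed nanoparticles rather than to the native
#' tissue. For each map the fraction of pixels above the control maximum is
#' reported, a scalar that decays as the element leaves the mapped region.
#'
#' @param maps List of [element_map()] objects (same element), in time
#'   order.
#' @param control The control-group [element_map()] (same element).
#' @param breaks Number of common bins (default 64).
#' @return A list with `histograms` (one `histogram` per map on common
#'   edges), `control_max`, `fraction_above_control` and `peak_bin` (index
#'   of the modal bin per map).
#' @export
histogram_vs_control <- function(maps, control, breaks = 64) {
  stopifnot(length(maps) >= 1, inherits(control, "element_map"))
  el <- vapply(maps, function(m) m$element, character(1))
  if (!all(el == control$element))
    stop("element mismatch: maps are ", paste(unique(el), collapse = "/"),
         " but control is ", control$element)
  all_vals <- c(unlist(lapply(maps, function(m) as.vector(m$intensity))),
                as.vector(control$intensity))
  edges <- seq(min(all_vals), max(all_vals), length.out = breaks + 1)
  control_max <- max(control$intensity)
  hs <- lapply(maps, function(m)
    graphics::hist(as.vector(m$intensity), breaks = edges, plot = FALSE,
                   include.lowest = TRUE))
  frac <- vapply(maps, function(m) mean(m$intensity > control_max), numeric(1))
  list(histograms = hs, control_max = control_max,
       fraction_above_control = frac,
       peak_bin = vapply(hs, function(h) which.max(h$counts), integer(1)))
}

#' Write / read an element map as delimited text
#'
#' @param map An [element_map()].
#' @param path File path; a `#`-prefixed header records element and pixel
#'   size.
#' @export
write_element_map <- function(map, path) {
  stopifnot(inherits(map, "element_map"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# element: %s", map$element), con)
  writeLines(sprintf("# pixel_size_um: %g", map$pixel_size), con)
  utils::write.table(map$intensity, con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_element_map
#' @export
read_element_map <- function(path) {
  hdr <- readLines(path, n = 2)
  element <- sub("^# element: *", "", hdr[1])
  px <- as.numeric(sub("^# pixel_size_um: *", "", hdr[2]))
  m <- as.matrix(utils::read.table(path, comment.char = "#", header = FALSE))
  dimnames(m) <- NULL
  element_map(element, m, px)
}
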