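#' A SAXS mesh scan
#'
#' A raster of detector frames, one per scan point, plus the shared beam
#' geometry. Frames are stored in row-major order (row 1 col 1, row 1
#' col 2, ...). Points may be marked invalid (failed exposures); invalid
#' points propagate as missing values in feature maps.
#'
#' @param frames List of [detector_frame()] objects, length `prod(shape)`.
#' @param shape `c(rows, cols)` of the scan grid.
#' @param beam The shared [beam_geometry()].
#' @param step `c(dy, dx)` motor step in mm (metadata), default `c(1, 1)`.
#' @param valid Logical vector per point, default all `TRUE`.
#' @return An object of class `mesh_scan`.
#' @export
mesh_scan <- function(frames, shape, beam, step = c(1, 1), valid = NULL) {
  stopifnot(length(frames) == prod(shape), inherits(beam, "beam_geometry"))
  if (is.null(valid)) valid <- rep(TRUE, length(frames))
  stopifnot(length(valid) == length(frames))
  ok <- vapply(frames[valid], inherits, logical(1), "detector_frame")
  if (!all(ok)) stop("every valid mesh point must carry a detector_frame")
  structure(list(frames = frames, shape = as.integer(shape), beam = beam,
                 step = step, valid = valid), class = "mesh_scan")
}

#' @export
print.mesh_scan <- function(x, ...) {
  cat(sprintf("mesh_scan: %d x %d points (%d valid), frame %s px\n",
              x$shape[1], x$shape[2], sum(x$valid),
              paste(dim(x$frames[[which(x$valid)[1]]]$counts), collapse = " x ")))
  invisible(x)
}

.scan_frame <- function(scan, row, col) {
  scan$frames[[(row - 1L) * scan$shape[2] + col]]
}

#' A per-mesh-point feature map
#'
#' @param values Numeric matrix over the mesh (missing points are `NA`).
#' @param statistic One of `"total_scattering"`, `"anisotropy_m1"`,
#'   `"anisotropy_m1_normalized"`.
#' @param q_window `c(q_lo, q_hi)` used, 1/Angstrom.
#' @param step Mesh step `c(dy, dx)` in mm.
#' @return An object of class `feature_map`.
#' @export
feature_map <- function(values, statistic, q_window, step = c(1, 1)) {
  statistic <- match.arg(statistic, c("total_scattering", "anisotropy_m1",
                                      "anisotropy_m1_normalized"))
  stopifnot(is.matrix(values))
  structure(list(values = values, statistic = statistic,
                 q_window = q_window, step = step), class = "feature_map")
}

#' @export
print.feature_map <- function(x, ...) {
  cat(sprintf("feature_map (%s): %d x %d, q-window [%.4g, %.4g] 1/A, %d missing\n",
              x$statistic, nrow(x$values), ncol(x$values),
              x$q_window[1], x$q_window[2], sum(is.na(x$values))))
  invisible(x)
}

# regroup one mesh point, memoizing bin geometry across points
.regroup_point <- function(scan, row, col, n_q, n_theta, q_edges) {
  azimuthal_regroup(.scan_frame(scan, row, col), scan$beam,
                    n_q = n_q, n_theta = n_theta, q_edges = q_edges)
}

#' Total scattering map of a mesh scan
#'
#' For every scan point, the summed counts attributable to the q-window:
#' the sum over cake cells in the window of (mean intensity x contributing
#' pixels). Linear in the frame intensity. Points with no valid cell in the
#' window, and invalid scan points, are `NA`.
#'
#' @param scan A [mesh_scan()].
#' @param q_lo,q_hi Analysis q-window in 1/Angstrom (default the effective
#'   window 0.004-0.022 used throughout the package).
#' @param n_q,n_theta Regrouping bin counts.
#' @return A [feature_map()] with statistic `"total_scattering"`.
#' @export
total_scattering_map <- function(scan, q_lo = 0.004, q_hi = 0.022,
                                 n_q = 40, n_theta = 36) {
  stopifnot(inherits(scan, "mesh_scan"), q_lo < q_hi)
  vals <- matrix(NA_real_, scan$shape[1], scan$shape[2])
  for (r in seq_len(scan$shape[1])) for (cc in seq_len(scan$shape[2])) {
    if (!scan$valid[(r - 1L) * scan$shape[2] + cc]) next
    ck <- .regroup_point(scan, r, cc, n_q, n_theta, NULL)
    qc <- cake_centers(ck)$q
    sel <- qc >= q_lo & qc <= q_hi
    cells <- ck$intensity[sel, , drop = FALSE]
    w <- ck$pixel_counts[sel, , drop = FALSE]
    if (!any(w > 0 & !is.na(cells))) next
    vals[r, cc] <- sum(cells * w, na.rm = TRUE)
  }
  feature_map(vals, "total_scattering", c(q_lo, q_hi), scan$step)
}

#' First moment of an azimuthal profile
#'
#' A scalar anisotropy statistic: the trapezoidal integral of
#' theta * I(theta) over the profile. On a theta grid centered on zero an
#' isotropic profile gives exactly 0, while intensity concentrated at a
#' preferred orientation pulls the moment toward that angle. The normalized
#' variant divides by the integral of I(theta), yielding an
#' intensity-independent orientation statistic (approximately the
#' circular-mean angle for a concentrated profile); the raw variant is the
#' literal moment, which scales with intensity and is origin-dependent on
#' a non-centered grid.
#'
#' @param profile An [azimuthal_profile()]; `NA` intensities are dropped.
#' @param normalized If `TRUE` (default), divide by the integrated
#'   intensity.
#' @return The first moment (radians when normalized; a.u. x radians^2
#'   otherwise).
#' @export
first_moment <- function(profile, normalized = TRUE) {
  stopifnot(inherits(profile, "azimuthal_profile"))
  keep <- !is.na(profile$intensity)
  th <- profile$theta[keep]; ii <- profile$intensity[keep]
  if (length(th) < 2) stop("first_moment needs at least 2 valid profile points")
  centered <- abs(mean(range(th))) < 1e-8
  if (!centered && !normalized)
    warning("theta grid is not centered on 0: the raw first moment is origin-dependent")
  m1 <- pracma::trapz(th, th * ii)
  if (!normalized) return(m1)
  denom <- pracma::trapz(th, ii)
  if (denom == 0) return(0)
  m1 / denom
}

#' Scattering-anisotropy map of a mesh scan
#'
#' For every scan point: azimuthal integration over the q-window, then the
#' first moment of the resulting profile. Distinguishes oriented cellulose
#' (large |moment| where the preferred orientation is off-axis) from
#' isotropic nanoparticle scattering (moment near 0).
#'
#' @inheritParams total_scattering_map
#' @param normalized Use the normalized first moment (default `TRUE`).
#' @return A [feature_map()] with statistic `"anisotropy_m1_normalized"`
#'   or `"anisotropy_m1"`.
#' @export
anisotropy_map <- function(scan, q_lo = 0.004, q_hi = 0.022,
                           normalized = TRUE, n_q = 40, n_theta = 36) {
  stopifnot(inherits(scan, "mesh_scan"), q_lo < q_hi)
  vals <- matrix(NA_real_, scan$shape[1], scan$shape[2])
  for (r in seq_len(scan$shape[1])) for (cc in seq_len(scan$shape[2])) {
    if (!scan$valid[(r - 1L) * scan$shape[2] + cc]) next
    ck <- .regroup_point(scan, r, cc, n_q, n_theta, NULL)
    prof <- azimuthal_integrate(ck, q_lo, q_hi)
    vals[r, cc] <- tryCatch(first_moment(prof, normalized = normalized),
                            error = function(e) NA_real_)
  }
  feature_map(vals,
              if (normalized) "anisotropy_m1_normalized" else "anisotropy_m1",
              c(q_lo, q_hi), scan$step)
}
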