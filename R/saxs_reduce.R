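#' A single 2D detector frame
#'
#' @param counts Numeric matrix of detector counts (finite, usually
#'   non-negative).
#' @param mask Logical matrix of the same shape, `TRUE` = exclude pixel
#'   (beamstop, gaps, hot pixels). Default: nothing masked.
#' @param exposure_time Exposure in seconds (metadata).
#' @return An object of class `detector_frame`.
#' @export
detector_frame <- function(counts, mask = NULL, exposure_time = 1) {
  stopifnot(is.matrix(counts), all(is.finite(counts)))
  if (is.null(mask)) mask <- matrix(FALSE, nrow(counts), ncol(counts))
  stopifnot(is.logical(mask), all(dim(mask) == dim(counts)))
  structure(list(counts = counts, mask = mask,
                 exposure_time = exposure_time),
            class = "detector_frame")
}

#' @export
print.detector_frame <- function(x, ...) {
  cat(sprintf("detector_frame: %d x %d px, %d masked, exposure %.3g s\n",
              nrow(x$counts), ncol(x$counts), sum(x$mask), x$exposure_time))
  invisible(x)
}

#' Map a detector pixel to scattering vector and azimuth
#'
#' q = (4 pi / lambda) sin(atan(r / Dsd) / 2) with lambda = 12.398 / E[keV];
#' the azimuth theta is measured counterclockwise from the detector +x axis
#' (increasing column), in \[-pi, pi), with +y along increasing row. The
#' beam-center pixel has q = 0 and no defined azimuth: its `theta` is `NA`
#' and `undefined_azimuth` is `TRUE`.
#'
#' @param beam A [beam_geometry()].
#' @param pixel `c(row, col)`, 1-based; fractional values allowed.
#' @return List with `q` (1/Angstrom), `theta` (radians) and
#'   `undefined_azimuth` (logical).
#' @examples
#' b <- beam_geometry(20.129, 2250, 172, c(33, 33))
#' pixel_q_theta(b, c(33, 60))   # on the +x axis: theta = 0
#' @export
pixel_q_theta <- function(beam, pixel) {
  stopifnot(inherits(beam, "beam_geometry"), length(pixel) == 2)
  dx <- (pixel[2] - beam$center[2]) * beam$pixel_um * 1e-3  # mm
  dy <- (pixel[1] - beam$center[1]) * beam$pixel_um * 1e-3
  r <- sqrt(dx^2 + dy^2)
  lambda <- wavelength_angstrom(beam)
  q <- 4 * pi / lambda * sin(atan2(r, beam$distance_mm) / 2)
  undef <- r == 0
  theta <- if (undef) NA_real_ else atan2(dy, dx)
  if (!undef && theta >= pi) theta <- theta - 2 * pi
  list(q = q, theta = theta, undefined_azimuth = undef)
}

# vectorized q/theta maps for a full frame; theta NA at the exact center
.qtheta_map <- function(beam, dim) {
  rows <- matrix(seq_len(dim[1]), dim[1], dim[2])
  cols <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  dx <- (cols - beam$center[2]) * beam$pixel_um * 1e-3
  dy <- (rows - beam$center[1]) * beam$pixel_um * 1e-3
  r <- sqrt(dx^2 + dy^2)
  lambda <- wavelength_angstrom(beam)
  q <- 4 * pi / lambda * sin(atan2(r, beam$distance_mm) / 2)
  theta <- atan2(dy, dx)
  theta[theta >= pi] <- theta[theta >= pi] - 2 * pi
  theta[r == 0] <- NA_real_
  list(q = q, theta = theta)
}

#' Azimuthal regrouping (caking) of a detector frame
#'
#' Rebins the frame onto a polar (q, theta) grid about the beam center. Each
#' cell holds the *mean* of the unmasked pixel counts falling in it, with
#' the number of contributing pixels recorded in `pixel_counts`, so that
#' `sum(intensity * pixel_counts)` over valid cells equals the summed
#' unmasked pixel counts exactly. Cells that receive no pixel are `NA`, not
#' zero. The beam-center pixel (undefined azimuth) is treated as masked.
#'
#' @param frame A [detector_frame()].
#' @param beam A [beam_geometry()].
#' @param n_q,n_theta Number of q and theta bins (each >= 2).
#' @param q_edges Optional explicit q bin edges (strictly increasing,
#'   length `n_q + 1`); default spans \[0, max q on the frame\].
#' @return An object of class `cake` with fields `intensity`
#'   (n_q x n_theta), `pixel_counts`, `q_edges`, `theta_edges`.
#' @export
azimuthal_regroup <- function(frame, beam, n_q = 50, n_theta = 36,
                              q_edges = NULL) {
  stopifnot(inherits(frame, "detector_frame"), inherits(beam, "beam_geometry"),
            n_q >= 2, n_theta >= 2)
  qt <- .qtheta_map(beam, dim(frame$counts))
  use <- !frame$mask & !is.na(qt$theta)
  if (!any(use)) stop("empty cake: all pixels masked")
  qv <- qt$q[use]; tv <- qt$theta[use]; cv <- frame$counts[use]
  if (is.null(q_edges)) {
    q_edges <- seq(0, max(qv), length.out = n_q + 1)
  } else {
    stopifnot(length(q_edges) == n_q + 1, all(diff(q_edges) > 0))
  }
  theta_edges <- seq(-pi, pi, length.out = n_theta + 1)
  qi <- findInterval(qv, q_edges, rightmost.closed = TRUE)
  ti <- findInterval(tv, theta_edges, rightmost.closed = TRUE)
  inb <- qi >= 1 & qi <= n_q & ti >= 1 & ti <= n_theta
  qi <- qi[inb]; ti <- ti[inb]; cvb <- cv[inb]
  cell <- (ti - 1L) * n_q + qi
  ncell <- n_q * n_theta
  counts <- tabulate(cell, nbins = ncell)
  rs <- rowsum(cvb, cell)
  tot <- numeric(ncell)
  tot[as.integer(rownames(rs))] <- rs[, 1]
  intensity <- matrix(NA_real_, n_q, n_theta)
  pc <- matrix(as.numeric(counts), n_q, n_theta)
  valid <- counts > 0
  intensity[valid] <- tot[valid] / counts[valid]
  # pixel-weighted mean q per q-bin: the faithful abscissa for radial curves
  qrow_counts <- tabulate(qi, nbins = n_q)
  qs <- rowsum(qv[inb], qi)
  qrow_sum <- numeric(n_q)
  qrow_sum[as.integer(rownames(qs))] <- qs[, 1]
  q_mean <- ifelse(qrow_counts > 0, qrow_sum / qrow_counts, NA_real_)
  structure(list(intensity = intensity, pixel_counts = pc,
                 q_edges = q_edges, theta_edges = theta_edges,
                 q_mean = q_mean,
                 n_excluded = sum(!inb) + sum(!use)),
            class = "cake")
}

#' @export
print.cake <- function(x, ...) {
  cat(sprintf("cake: %d q-bins x %d theta-bins, q in [%.4g, %.4g] 1/A, %d valid cells\n",
              nrow(x$intensity), ncol(x$intensity),
              min(x$q_edges), max(x$q_edges), sum(x$pixel_counts > 0)))
  invisible(x)
}

#' Bin centers of a cake
#' @param cake A `cake`.
#' @return List with `q` and `theta` center vectors.
#' @export
cake_centers <- function(cake) {
  list(q = (head(cake$q_edges, -1) + tail(cake$q_edges, -1)) / 2,
       theta = (head(cake$theta_edges, -1) + tail(cake$theta_edges, -1)) / 2)
}

#' A 1D scattering curve I(q) with counting uncertainties
#'
#' @param q Scattering vector, 1/Angstrom.
#' @param intensity Intensity, a.u.
#' @param sigma Standard uncertainty (>= 0), a.u.; default 0.
#' @return An object of class `curve1d`.
#' @export
curve1d <- function(q, intensity, sigma = NULL) {
  if (is.null(sigma)) sigma <- numeric(length(q)) * 0
  stopifnot(length(q) == length(intensity), length(sigma) == length(q),
            all(sigma >= 0 | is.na(sigma)))
  structure(list(q = as.numeric(q), intensity = as.numeric(intensity),
                 sigma = as.numeric(sigma)), class = "curve1d")
}

#' @export
print.curve1d <- function(x, ...) {
  cat(sprintf("curve1d: %d points, q in [%.4g, %.4g] 1/A\n",
              length(x$q), min(x$q), max(x$q)))
  invisible(x)
}

#' Radial integration of a cake to I(q)
#'
#' Pixel-count-weighted mean over the azimuthal dimension; invalid (empty)
#' cells are excluded. The reported q is the pixel-weighted mean q of each
#' bin (falling back to the bin center for empty bins), which avoids the
#' bin-center bias where the curve is steep. Sigma assumes Poisson pixel
#' counts: for a q-bin with N contributing pixels and mean intensity I,
#' sigma = sqrt(max(I, 0) / N).
#'
#' @param cake A `cake` from [azimuthal_regroup()].
#' @return A [curve1d()]; q-bins with no valid cell carry `NA` intensity.
#' @export
radial_integrate <- function(cake) {
  stopifnot(inherits(cake, "cake"))
  w <- cake$pixel_counts
  num <- rowSums(cake$intensity * w, na.rm = TRUE)
  den <- rowSums(w * !is.na(cake$intensity))
  intensity <- ifelse(den > 0, num / den, NA_real_)
  sigma <- ifelse(den > 0, sqrt(pmax(intensity, 0) / den), NA_real_)
  qc <- cake_centers(cake)$q
  if (!is.null(cake$q_mean)) qc <- ifelse(is.na(cake$q_mean), qc, cake$q_mean)
  curve1d(qc, intensity, sigma)
}

#' An azimuthal intensity profile I(theta)
#'
#' @param theta Azimuth in radians, within \[-pi, pi).
#' @param intensity Intensity, a.u.
#' @return An object of class `azimuthal_profile`.
#' @export
azimuthal_profile <- function(theta, intensity) {
  stopifnot(length(theta) == length(intensity),
            all(theta >= -pi & theta < pi))
  structure(list(theta = as.numeric(theta), intensity = as.numeric(intensity)),
            class = "azimuthal_profile")
}

#' Azimuthal integration of a cake to I(theta)
#'
#' Pixel-count-weighted mean over the q-bins whose centers fall in
#' `[q_lo, q_hi]`.
#'
#' @param cake A `cake`.
#' @param q_lo,q_hi The q-window in 1/Angstrom; must overlap the cake's
#'   q-range.
#' @return An [azimuthal_profile()] on the cake's theta bin centers; theta
#'   bins with no valid cell carry `NA`.
#' @export
azimuthal_integrate <- function(cake, q_lo, q_hi) {
  stopifnot(inherits(cake, "cake"), q_lo < q_hi)
  qc <- cake_centers(cake)$q
  sel <- qc >= q_lo & qc <= q_hi
  if (!any(sel)) stop("empty q-window: no cake q-bins in [q_lo, q_hi]")
  w <- cake$pixel_counts[sel, , drop = FALSE]
  ii <- cake$intensity[sel, , drop = FALSE]
  num <- colSums(ii * w, na.rm = TRUE)
  den <- colSums(w * !is.na(ii))
  azimuthal_profile(cake_centers(cake)$theta,
                    ifelse(den > 0, num / den, NA_real_))
}

#' Subtract a (scaled) background curve from a sample curve
#'
#' If the q-grids differ, the background is re-binned onto the sample grid
#' by linear interpolation; the grids must overlap the full sample range.
#' Uncertainties add in quadrature. Negative results are retained (they are
#' informative about over-subtraction) and counted in a warning.
#'
#' @param sample,background [curve1d()] objects.
#' @param scale Multiplier applied to the background (e.g. a transmission
#'   ratio), default 1.
#' @return A [curve1d()] on the sample q-grid with attribute
#'   `n_negative`.
#' @export
subtract_background <- function(sample, background, scale = 1) {
  stopifnot(inherits(sample, "curve1d"), inherits(background, "curve1d"))
  if (max(background$q) < min(sample$q) || min(background$q) > max(sample$q))
    stop("disjoint q-grids: background does not overlap the sample")
  if (isTRUE(all.equal(sample$q, background$q))) {
    bi <- background$intensity
    bs <- background$sigma
  } else {
    if (min(background$q) > min(sample$q) || max(background$q) < max(sample$q))
      stop("background q-grid does not cover the sample q-range")
    bi <- stats::approx(background$q, background$intensity, xout = sample$q)$y
    bs <- stats::approx(background$q, background$sigma, xout = sample$q)$y
  }
  out <- sample$intensity - scale * bi
  sig <- sqrt(sample$sigma^2 + (scale * bs)^2)
  nneg <- sum(out < 0, na.rm = TRUE)
  if (nneg > 0)
    warning(nneg, " point(s) negative after background subtraction")
  res <- curve1d(sample$q, out, sig)
  attr(res, "n_negative") <- nneg
  res
}
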