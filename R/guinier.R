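#' Guinier fit of a solution scattering curve
#'
#' Fits the low-q Guinier law I(q) = I0 exp(-q^2 Rg^2 / 3) by weighted
#' linear least squares of ln I against q^2 (weights (I/sigma)^2, the
#' delta-method variance of ln I; unweighted when no uncertainties are
#' available). Points with I <= 0 are dropped and counted.
#'
#' When no explicit window is given, the fit window is selected
#' automatically: starting from all points, the fit and the restriction
#' q <= qmax_rg_limit / Rg are iterated until the window is stable
#' (the standard Guinier validity criterion q_max x Rg <= 1.3 for globular
#' scatterers).
#'
#' @param curve A [curve1d()].
#' @param q_window Optional `c(q_min, q_max)`; when supplied it is used
#'   as-is (no validity iteration).
#' @param qmax_rg_limit Guinier validity limit on q_max x Rg for the
#'   automatic window (default 1.3).
#' @param max_iter Maximum window iterations (default 50).
#' @return An object of class `guinier_result` with fields `rg`, `rg_err`,
#'   `i_zero`, `i_zero_err`, `q_window`, `q_max_rg`, `n_points`,
#'   `n_dropped`, `degenerate`.
#' @examples
#' q <- seq(0.0015, 0.0044, length.out = 30)
#' cv <- curve1d(q, 7845 * exp(-q^2 * 297^2 / 3))
#' guinier_fit(cv, q_window = c(0.0015, 0.0044))
#' @export
guinier_fit <- function(curve, q_window = NULL, qmax_rg_limit = 1.3,
                        max_iter = 50) {
  stopifnot(inherits(curve, "curve1d"))
  ok <- is.finite(curve$q) & is.finite(curve$intensity)
  pos <- ok & curve$intensity > 0
  n_dropped <- sum(ok) - sum(pos)
  if (sum(pos) < 5)
    stop("Guinier fit impossible: fewer than 5 points with positive intensity")
  q <- curve$q[pos]; ii <- curve$intensity[pos]; sg <- curve$sigma[pos]

  fit_window <- function(sel) {
    if (sum(sel) < 5) return(NULL)
    x <- q[sel]^2
    y <- log(ii[sel])
    w <- if (all(sg[sel] > 0)) (ii[sel] / sg[sel])^2 else rep(1, sum(sel))
    fm <- stats::lm(y ~ x, weights = w)
    cf <- stats::coef(fm)
    slope <- cf[[2]]
    se <- tryCatch(suppressWarnings(sqrt(diag(stats::vcov(fm)))),
                   error = function(e) c(NA, NA))
    rg_try <- if (is.finite(slope) && slope < 0) sqrt(-3 * slope) else 0
    # a fit is degenerate when the curve carries no size information over
    # its window: non-negative slope, or q_max * Rg far below the Guinier
    # regime (the intensity decays by < 0.01% across the window)
    degenerate <- !is.finite(slope) || slope >= 0 ||
      rg_try * max(q[sel]) < 0.01
    rg <- if (degenerate) 0 else rg_try
    rg_err <- if (degenerate || !is.finite(se[2]) || rg == 0) NA_real_
              else 3 * se[[2]] / (2 * rg)
    i0 <- exp(cf[[1]])
    list(rg = rg, rg_err = rg_err, i_zero = i0,
         i_zero_err = i0 * se[[1]], degenerate = degenerate,
         n = sum(sel), q_min = min(q[sel]), q_max = max(q[sel]))
  }

  if (!is.null(q_window)) {
    sel <- q >= q_window[1] & q <= q_window[2]
    f <- fit_window(sel)
    if (is.null(f)) stop("fewer than 5 positive points in the requested q-window")
  } else {
    sel <- rep(TRUE, length(q))
    f <- fit_window(sel)
    for (iter in seq_len(max_iter)) {
      if (f$degenerate) break
      new_sel <- q <= qmax_rg_limit / f$rg
      if (identical(new_sel, sel)) break
      nf <- fit_window(new_sel)
      if (is.null(nf)) break  # window shrank below 5 points; keep last fit
      sel <- new_sel; f <- nf
      if (iter == max_iter)
        stop("Guinier window iteration did not converge in ", max_iter, " iterations")
    }
  }
  structure(list(rg = f$rg, rg_err = f$rg_err,
                 i_zero = f$i_zero, i_zero_err = f$i_zero_err,
                 q_window = c(f$q_min, f$q_max),
                 q_max_rg = f$q_max * f$rg, n_points = f$n,
                 n_dropped = n_dropped, degenerate = f$degenerate),
            class = "guinier_result")
}

#' @export
print.guinier_result <- function(x, ...) {
  cat(sprintf("guinier_result: Rg = %.4g +/- %.3g A, I0 = %.5g +/- %.3g (n = %d, qmax*Rg = %.3g%s)\n",
              x$rg, x$rg_err, x$i_zero, x$i_zero_err, x$n_points, x$q_max_rg,
              if (x$degenerate) ", DEGENERATE" else ""))
  invisible(x)
}

#' A dilution series of Guinier fits
#'
#' @param labels Character labels (e.g. `"baseline"`, `"5-fold"`).
#' @param dilution_factors Numeric factors (>= 1); the baseline is 1.
#' @param fits List of [guinier_fit()] results, one per entry.
#' @param baseline_label Label of the undiluted entry (default the entry
#'   with dilution factor 1, else the first).
#' @return An object of class `dilution_series`.
#' @export
dilution_series <- function(labels, dilution_factors, fits,
                            baseline_label = NULL) {
  stopifnot(length(labels) == length(dilution_factors),
            length(fits) == length(labels),
            all(dilution_factors >= 1))
  if (is.null(baseline_label)) {
    i <- which(dilution_factors == 1)
    baseline_label <- if (length(i)) labels[i[1]] else labels[1]
  }
  if (!baseline_label %in% labels) stop("baseline entry not present")
  structure(list(labels = labels, dilution_factors = dilution_factors,
                 fits = fits, baseline_label = baseline_label),
            class = "dilution_series")
}

#' Forward-intensity reduction ratios of a dilution series
#'
#' ratio = I0(baseline) / I0(entry). Tracks the dilution factor when the
#' particles neither aggregate nor interact. Reported at full precision;
#' use `round(x, 2)` to reproduce the conventional 2-decimal table.
#'
#' @param series A [dilution_series()].
#' @return A data frame with columns `label`, `dilution_factor`, `i_zero`,
#'   `ratio`.
#' @export
reduction_ratios <- function(series) {
  stopifnot(inherits(series, "dilution_series"))
  i0 <- vapply(series$fits, function(f) f$i_zero, numeric(1))
  base <- i0[match(series$baseline_label, series$labels)]
  if (!is.finite(base) || base <= 0) stop("baseline I0 must be positive")
  if (any(i0 <= 0)) stop("diluted I0 must be positive to form a ratio")
  data.frame(label = series$labels,
             dilution_factor = series$dilution_factors,
             i_zero = i0, ratio = base / i0,
             stringsAsFactors = FALSE)
}

#' Particle-size stability across a dilution series
#'
#' The gyration radius should not change on dilution unless particles
#' aggregate or dissolve; this reports the maximum relative deviation of
#' the fitted Rg values from their median.
#'
#' @param series A [dilution_series()] with >= 2 entries.
#' @param tolerance Stability tolerance on the relative spread
#'   (default 0.05).
#' @return A list with `rg`, `max_relative_spread` and `stable`.
#' @export
rg_stability <- function(series, tolerance = 0.05) {
  stopifnot(inherits(series, "dilution_series"),
            length(series$fits) >= 2)
  rg <- vapply(series$fits, function(f) f$rg, numeric(1))
  med <- stats::median(rg)
  spread <- max(abs(rg - med)) / med
  list(rg = rg, max_relative_spread = spread, stable = spread <= tolerance)
}

#' Read / write 2-3 column delimited scattering curves
#'
#' Whitespace- or comma-delimited text with columns q, I and optionally
#' sigma; lines starting with `#` are comments.
#'
#' @param path File path.
#' @return `read_curve()`: a [curve1d()].
#' @export
read_curve <- function(path) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          sep = "", fill = TRUE)
  if (ncol(df) < 2) stop("curve file needs at least 2 columns (q, I)")
  curve1d(df[[1]], df[[2]], if (ncol(df) >= 3) df[[3]] else NULL)
}

#' @rdname read_curve
#' @param curve A [curve1d()].
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "curve1d"))
  df <- data.frame(q = curve$q, intensity = curve$intensity,
                   sigma = curve$sigma)
  utils::write.table(df, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Export a dilution-series results table
#'
#' Mirrors the columns of a solution-characterization table: label,
#' dilution factor, Rg with uncertainty, I0 with uncertainty, and the
#' reduction ratio (2 decimals).
#'
#' @param series A [dilution_series()].
#' @param path Optional file to write a tab-delimited table to.
#' @return The table as a data frame (invisibly when writing).
#' @export
dilution_table <- function(series, path = NULL) {
  rr <- reduction_ratios(series)
  tab <- data.frame(
    label = rr$label,
    dilution_factor = rr$dilution_factor,
    rg = vapply(series$fits, function(f) f$rg, numeric(1)),
    rg_err = vapply(series$fits, function(f) f$rg_err, numeric(1)),
    i_zero = rr$i_zero,
    i_zero_err = vapply(series$fits, function(f) f$i_zero_err, numeric(1)),
    reduction_ratio = round(rr$ratio, 2),
    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(tab))
  }
  tab
}
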