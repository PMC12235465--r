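# independent oracles used across the suite

# brute-force per-pixel regrouping: double loop over pixels via
# pixel_q_theta, accumulate sums and counts per (q, theta) cell
oracle_regroup <- function(frame, beam, q_edges, n_theta) {
  n_q <- length(q_edges) - 1
  theta_edges <- seq(-pi, pi, length.out = n_theta + 1)
  sums <- matrix(0, n_q, n_theta)
  counts <- matrix(0, n_q, n_theta)
  for (r in seq_len(nrow(frame$counts))) for (cc in seq_len(ncol(frame$counts))) {
    if (frame$mask[r, cc]) next
    qt <- pixel_q_theta(beam, c(r, cc))
    if (qt$undefined_azimuth) next
    qi <- findInterval(qt$q, q_edges, rightmost.closed = TRUE)
    ti <- findInterval(qt$theta, theta_edges, rightmost.closed = TRUE)
    if (qi < 1 || qi > n_q || ti < 1 || ti > n_theta) next
    sums[qi, ti] <- sums[qi, ti] + frame$counts[r, cc]
    counts[qi, ti] <- counts[qi, ti] + 1
  }
  intensity <- ifelse(counts > 0, sums / counts, NA_real_)
  list(intensity = intensity, pixel_counts = counts)
}

# high-accuracy normalized first moment of a continuous profile function
# over the support [lo, hi] (pass the profile grid's range so the adaptive
# quadrature and the trapezoidal statistic integrate the same domain)
oracle_first_moment <- function(fun, normalized = TRUE, lo = -pi, hi = pi) {
  num <- stats::integrate(function(th) th * fun(th), lo, hi,
                          rel.tol = 1e-12, subdivisions = 2000L)$value
  if (!normalized) return(num)
  den <- stats::integrate(fun, lo, hi, rel.tol = 1e-12,
                          subdivisions = 2000L)$value
  num / den
}

# centered azimuthal grid of n bin centers
centered_theta_grid <- function(n) {
  edges <- seq(-pi, pi, length.out = n + 1)
  (head(edges, -1) + tail(edges, -1)) / 2
}

# a minimal guinier_result carrying given values, for table arithmetic
fixed_fit <- function(rg, i_zero, rg_err = 0, i_zero_err = 0) {
  structure(list(rg = rg, rg_err = rg_err, i_zero = i_zero,
                 i_zero_err = i_zero_err, q_window = c(NA, NA),
                 q_max_rg = NA, n_points = 5L, n_dropped = 0L,
                 degenerate = FALSE),
            class = "guinier_result")
}

# leaf-slab volume with a block of bright voxels at a known fraction
known_fraction_volume <- function(dim3 = 40, fraction = 0.05, seed = 1) {
  set.seed(seed)
  d <- dim3
  gray <- array(rnorm(d^3, 0.08, 0.015), c(d, d, d))
  leaf <- array(FALSE, c(d, d, d))
  m <- 4
  leaf[(m + 1):(d - m), (m + 1):(d - m), (m + 1):(d - m)] <- TRUE
  gray[leaf] <- rnorm(sum(leaf), 0.35, 0.02)
  n_np <- round(fraction * sum(leaf))
  idx <- which(leaf)[seq_len(n_np)]
  gray[idx] <- rnorm(n_np, 0.9, 0.02)
  list(vol = volume3d(gray), leaf = leaf, n_np = n_np,
       true_fraction = n_np / sum(leaf))
}
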