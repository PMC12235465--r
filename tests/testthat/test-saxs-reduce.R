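test_that("pixel-to-(q, theta) mapping follows the stated conventions", {
  b <- beam_geometry(20.129, 2250, 172, c(33, 33))
  expect_equal(wavelength_angstrom(b), 12.398 / 20.129)

  center <- pixel_q_theta(b, c(33, 33))
  expect_equal(center$q, 0)
  expect_true(center$undefined_azimuth)
  expect_true(is.na(center$theta))

  on_x <- pixel_q_theta(b, c(33, 50))   # +x axis (increasing column)
  expect_equal(on_x$theta, 0)
  on_y <- pixel_q_theta(b, c(50, 33))   # +y axis (increasing row)
  expect_equal(on_y$theta, pi / 2)

  # q from the closed form at a known radius
  px <- pixel_q_theta(b, c(33, 43))
  r_mm <- 10 * 172e-3
  expect_equal(px$q, 4 * pi / (12.398 / 20.129) * sin(atan(r_mm / 2250) / 2))
})

test_that("azimuthal regrouping equals the brute-force per-pixel oracle", {
  set.seed(42)
  for (rep in 1:4) {
    n <- 48
    counts <- matrix(rpois(n * n, 20 + rep * 5), n, n)
    mask <- matrix(runif(n * n) < 0.07, n, n)
    center <- c(runif(1, n / 3, 2 * n / 3), runif(1, n / 3, 2 * n / 3))
    b <- beam_geometry(runif(1, 10, 25), runif(1, 1500, 4000), 172, center)
    fr <- detector_frame(counts, mask)
    n_q <- sample(8:20, 1); n_theta <- sample(8:24, 1)
    ck <- azimuthal_regroup(fr, b, n_q = n_q, n_theta = n_theta)
    or <- oracle_regroup(fr, b, ck$q_edges, n_theta)
    expect_equal(ck$intensity, or$intensity, tolerance = 1e-12)
    expect_equal(ck$pixel_counts, or$pixel_counts)
  }
})

test_that("regrouping conserves total unmasked counts and handles uniform frames", {
  b <- phantom_beam(64)
  fr <- detector_frame(matrix(1, 64, 64))
  ck <- azimuthal_regroup(fr, b, n_q = 20, n_theta = 16)
  expect_true(all(ck$intensity[ck$pixel_counts > 0] == 1))
  expect_equal(sum(ck$intensity * ck$pixel_counts, na.rm = TRUE), 64 * 64)

  set.seed(1)
  counts <- matrix(rpois(64 * 64, 30), 64, 64)
  mask <- matrix(runif(64 * 64) < 0.1, 64, 64)
  fr2 <- detector_frame(counts, mask)
  ck2 <- azimuthal_regroup(fr2, b, n_q = 25, n_theta = 18)
  expect_equal(sum(ck2$intensity * ck2$pixel_counts, na.rm = TRUE),
               sum(counts[!mask]))
  expect_error(azimuthal_regroup(detector_frame(counts,
                                                matrix(TRUE, 64, 64)), b),
               "all pixels masked")
})

test_that("isotropic frames regroup to azimuthally flat cakes and flat profiles", {
  spec <- phantom_spec(mesh_shape = c(1, 1),
                       background = cellulose_background(amplitude = 0),
                       noise = "none", frame_dim = 64, seed = 1)
  fr <- render_frame(spec, c(1, 1))
  ck <- azimuthal_regroup(fr, spec$beam, n_q = 20, n_theta = 16)
  # each q-row constant across theta (noiseless isotropic particle signal,
  # up to in-bin q variation)
  for (i in 5:15) {
    row <- ck$intensity[i, ]
    row <- row[!is.na(row)]
    expect_lt(stats::sd(row) / mean(row), 0.05)
  }
  prof <- azimuthal_integrate(ck, 0.004, 0.022)
  v <- prof$intensity[!is.na(prof$intensity)]
  expect_lt(stats::sd(v) / mean(v), 0.05)
})

test_that("radial integration of a guinier-model frame matches the forward model", {
  rg <- 150
  spec <- phantom_spec(mesh_shape = c(1, 1),
                       particle = particle_model("guinier", rg = rg,
                                                 concentration = 1000),
                       background = cellulose_background(amplitude = 0),
                       noise = "none", frame_dim = 64, seed = 1)
  fr <- render_frame(spec, c(1, 1))
  ck <- azimuthal_regroup(fr, spec$beam, n_q = 80, n_theta = 24)
  cv <- radial_integrate(ck)
  qc <- cv$q
  counts_per_bin <- rowSums(ck$pixel_counts)
  sel <- counts_per_bin > 50 & !is.na(cv$intensity) & qc > 0
  model <- 1000 * exp(-qc^2 * rg^2 / 3)
  rel <- abs(cv$intensity[sel] - model[sel]) / model[sel]
  expect_lt(max(rel), 0.01)
})

test_that("rotating a frame about the beam center shifts the azimuthal profile", {
  spec <- phantom_spec(mesh_shape = c(1, 1),
                       background = cellulose_background(amplitude = 30,
                                                         anisotropy_fraction = 0.8,
                                                         preferred_orientation = 0.6),
                       noise = "none", frame_dim = 64, seed = 1)
  fr <- render_frame(spec, c(1, 1))
  # 90-degree rotation about the (fractional) center is an exact pixel map
  rot <- detector_frame(t(fr$counts)[, rev(seq_len(64))])
  n_theta <- 24
  p0 <- azimuthal_integrate(azimuthal_regroup(fr, spec$beam, 30, n_theta),
                            0.004, 0.022)
  p1 <- azimuthal_integrate(azimuthal_regroup(rot, spec$beam, 30, n_theta),
                            0.004, 0.022)
  shift_bins <- n_theta / 4
  shifted <- p0$intensity[((seq_len(n_theta) - 1 - shift_bins) %% n_theta) + 1]
  keep <- !is.na(p1$intensity) & !is.na(shifted)
  expect_equal(p1$intensity[keep], shifted[keep], tolerance = 0.02)
})

test_that("background subtraction propagates errors and flags negatives", {
  q <- seq(0.002, 0.02, length.out = 30)
  s <- curve1d(q, 100 * exp(-q * 50), sigma = rep(1, 30))
  expect_equal(subtract_background(s, s, scale = 1)$intensity, rep(0, 30))
  expect_equal(subtract_background(s, s, scale = 0)$intensity, s$intensity)

  b <- curve1d(q, rep(10, 30), sigma = rep(2, 30))
  out <- subtract_background(s, b, scale = 1)
  expect_equal(out$sigma, rep(sqrt(1 + 4), 30))

  # over-subtraction keeps negatives and warns
  expect_warning(res <- subtract_background(b, s, scale = 1), "negative")
  expect_true(any(res$intensity < 0))
  expect_gt(attr(res, "n_negative"), 0)

  # disjoint grids are an error
  b2 <- curve1d(q + 1, rep(10, 30))
  expect_error(subtract_background(s, b2), "disjoint")
})

test_that("particle + solvent minus solvent recovers the particle curve", {
  rg <- 150
  base <- list(mesh_shape = c(1, 1), noise = "none", frame_dim = 64, seed = 1)
  bg <- cellulose_background(amplitude = 20, anisotropy_fraction = 0)
  sp_both <- phantom_spec(mesh_shape = c(1, 1),
                          particle = particle_model("guinier", rg = rg,
                                                    concentration = 500),
                          background = bg, noise = "none", frame_dim = 64)
  sp_solv <- phantom_spec(mesh_shape = c(1, 1),
                          particle = particle_model("guinier", rg = rg,
                                                    concentration = 0),
                          background = bg, noise = "none", frame_dim = 64)
  cv_both <- radial_integrate(azimuthal_regroup(render_frame(sp_both, c(1, 1)),
                                                sp_both$beam, 40, 24))
  cv_solv <- radial_integrate(azimuthal_regroup(render_frame(sp_solv, c(1, 1)),
                                                sp_solv$beam, 40, 24))
  diff <- subtract_background(cv_both, cv_solv, scale = 1)
  sel <- diff$q > 0.003 & diff$q < 0.02 & !is.na(diff$intensity)
  model <- 500 * exp(-diff$q^2 * rg^2 / 3)
  expect_lt(max(abs(diff$intensity[sel] - model[sel]) / model[sel]), 0.02)
})
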