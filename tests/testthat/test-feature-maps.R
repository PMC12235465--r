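test_that("first moment is zero for isotropic profiles and matches quadrature", {
  th <- centered_theta_grid(36)
  expect_lt(abs(first_moment(azimuthal_profile(th, rep(7, 36)), FALSE)), 1e-10)
  expect_lt(abs(first_moment(azimuthal_profile(th, rep(7, 36)), TRUE)), 1e-10)

  # concentrated unit-area peak at theta0 = +1: normalized moment ~ theta0
  fine <- centered_theta_grid(20001)
  peak <- exp(-(fine - 1.0)^2 / (2 * 0.02^2))
  expect_equal(first_moment(azimuthal_profile(fine, peak), TRUE), 1.0,
               tolerance = 1e-3)

  # smooth anisotropic profiles vs independent quadrature, both modes
  for (th0 in c(0.3, 1.2, -0.7)) {
    fun <- function(x) 1 + cos(x - th0)^2
    prof <- azimuthal_profile(fine, fun(fine))
    expect_equal(first_moment(prof, TRUE),
                 oracle_first_moment(fun, TRUE, min(fine), max(fine)),
                 tolerance = 1e-6)
    expect_equal(first_moment(prof, FALSE),
                 oracle_first_moment(fun, FALSE, min(fine), max(fine)),
                 tolerance = 1e-6)
  }
})

test_that("raw first moment warns on a non-centered grid", {
  th <- seq(0, pi - 0.1, length.out = 30)
  expect_warning(first_moment(azimuthal_profile(th, rep(1, 30)), FALSE),
                 "origin-dependent")
})

test_that("total scattering map is linear, localizes clusters, and flags missing points", {
  conc <- matrix(0.2, 6, 6)
  conc[4, 5] <- 3
  spec <- phantom_spec(mesh_shape = c(6, 6), concentration_field = conc,
                       background = cellulose_background(amplitude = 2),
                       noise = "none", frame_dim = 32, seed = 1)
  scan <- render_mesh_scan(spec)
  map <- total_scattering_map(scan, 0.004, 0.022)
  expect_equal(dim(map$values), c(6, 6))
  expect_equal(which(map$values == max(map$values), arr.ind = TRUE)[1, ],
               c(row = 4, col = 5))

  # doubling every frame doubles the map exactly (noiseless)
  scan2 <- scan
  scan2$frames <- lapply(scan$frames, function(f)
    detector_frame(2 * f$counts, f$mask, f$exposure_time))
  map2 <- total_scattering_map(scan2, 0.004, 0.022)
  expect_equal(map2$values, 2 * map$values, tolerance = 1e-12)

  # invalid points become NA, not 0
  scan3 <- scan
  scan3$valid[8] <- FALSE
  map3 <- total_scattering_map(scan3, 0.004, 0.022)
  expect_true(is.na(map3$values[2, 2]))
  expect_equal(sum(is.na(map3$values)), 1)
})

test_that("anisotropy map separates oriented stripes from an isotropic cluster", {
  mesh <- c(6, 6)
  aniso <- matrix(0, 6, 6)
  aniso[c(2, 5), ] <- 0.8            # cellulose stripes
  orient <- matrix(1.2, 6, 6)
  conc <- matrix(0, 6, 6)
  conc[3:4, 3:4] <- 1                # isotropic particle cluster
  spec <- phantom_spec(mesh_shape = mesh, concentration_field = conc,
                       background = cellulose_background(amplitude = 30),
                       anisotropy_field = aniso, orientation_field = orient,
                       noise = "none", frame_dim = 32, seed = 1)
  scan <- render_mesh_scan(spec)
  map <- anisotropy_map(scan, 0.004, 0.022)
  stripe_vals <- abs(map$values[c(2, 5), ])
  cluster_vals <- abs(map$values[3:4, 3:4])
  expect_gt(min(stripe_vals), max(cluster_vals))

  # fully isotropic phantom: map ~ 0 everywhere
  spec0 <- phantom_spec(mesh_shape = c(3, 3),
                        background = cellulose_background(amplitude = 10,
                                                          anisotropy_fraction = 0),
                        noise = "none", frame_dim = 32, seed = 1)
  map0 <- anisotropy_map(render_mesh_scan(spec0), 0.004, 0.022)
  expect_lt(max(abs(map0$values)), 0.02)
})

test_that("day-0 dissolution maps dominate day-3 maps over the infiltrated region", {
  ts <- render_timeseries_phantoms(c(0, 3), mode = "dissolution", seed = 5)
  region <- attr(ts, "region_mask")
  m0 <- total_scattering_map(ts[[1]]$scan, 0.004, 0.022)$values
  m3 <- total_scattering_map(ts[[2]]$scan, 0.004, 0.022)$values
  expect_true(all(m0[region] > m3[region]))
  # histogram mass moves to lower intensities
  expect_gt(mean(m0[region]), mean(m3[region]))
  expect_gt(sum(m0 > stats::median(m0)), sum(m3 > stats::median(m0)) - 1)
})
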