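test_that("noiseless Guinier data are recovered to machine precision", {
  q <- seq(0.0015, 0.0044, length.out = 30)
  cv <- curve1d(q, 7845 * exp(-q^2 * 297^2 / 3))
  fit <- guinier_fit(cv, q_window = range(q))
  expect_equal(fit$rg, 297, tolerance = 1e-10)
  expect_equal(fit$i_zero, 7845, tolerance = 1e-8)
})

test_that("automatic window selection respects the q_max * Rg limit", {
  rg <- 297
  q <- seq(0.0008, 0.008, length.out = 60)   # extends well past the limit
  cv <- curve1d(q, 5000 * exp(-q^2 * rg^2 / 3))
  fit <- guinier_fit(cv)
  expect_lte(fit$q_max_rg, 1.3 + 1e-6)
  expect_equal(fit$rg, rg, tolerance = 1e-6)
})

test_that("degenerate and impossible curves are handled explicitly", {
  q <- seq(0.001, 0.005, length.out = 20)
  flat <- guinier_fit(curve1d(q, rep(100, 20)))
  expect_true(flat$degenerate)
  expect_equal(flat$rg, 0)
  expect_error(guinier_fit(curve1d(q, rep(-1, 20))), "fit impossible|positive")
})

test_that("scaling a curve scales I0 and leaves Rg unchanged", {
  q <- seq(0.001, 0.004, length.out = 25)
  cv <- curve1d(q, 1234 * exp(-q^2 * 200^2 / 3))
  f1 <- guinier_fit(cv, q_window = range(q))
  f2 <- guinier_fit(curve1d(q, 7 * cv$intensity), q_window = range(q))
  expect_equal(f2$rg, f1$rg, tolerance = 1e-10)
  expect_equal(f2$i_zero, 7 * f1$i_zero, tolerance = 1e-8)
})

test_that("stochastic replicates recover the generating parameters", {
  rg_true <- 297; i0_true <- 7845
  fits <- lapply(1:200, function(i) {
    cv <- simulate_guinier_curve(rg_true, i0_true, noise = 0.01, seed = i)
    guinier_fit(cv, q_window = c(0.0015, 0.0044))
  })
  rg <- vapply(fits, `[[`, numeric(1), "rg")
  i0 <- vapply(fits, `[[`, numeric(1), "i_zero")
  expect_lt(abs(stats::median(rg) - rg_true) / rg_true, 0.02)
  expect_lt(abs(stats::median(i0) - i0_true) / i0_true, 0.03)
})

test_that("reduction ratios reproduce the printed solution table arithmetic", {
  series <- dilution_series(
    labels = c("baseline", "5-fold", "9-fold"),
    dilution_factors = c(1, 5, 9),
    fits = list(fixed_fit(297, 7845), fixed_fit(298, 1437),
                fixed_fit(296, 830)))
  rr <- reduction_ratios(series)
  expect_equal(rr$ratio[1], 1)
  expect_equal(round(rr$ratio[2], 2), 5.46)
  expect_equal(round(rr$ratio[3], 2), 9.45)

  st <- rg_stability(series)
  expect_true(st$stable)
  expect_equal(st$max_relative_spread, 1 / 297, tolerance = 1e-10)
})

test_that("rg stability flags a drifting series as unstable", {
  series <- dilution_series(c("baseline", "2-fold"), c(1, 2),
                            list(fixed_fit(100, 10), fixed_fit(200, 5)))
  st <- rg_stability(series)
  expect_false(st$stable)
  expect_equal(st$max_relative_spread, 50 / 150)
  same <- dilution_series(c("baseline", "2-fold"), c(1, 2),
                          list(fixed_fit(100, 10), fixed_fit(100, 5)))
  expect_equal(rg_stability(same)$max_relative_spread, 0)
})

test_that("phantom dilution series tracks the dilution factor within 10%", {
  particle <- particle_model("cylinder", length = 280, radius = 80,
                             concentration = 2000)
  series <- simulate_dilution_series(particle, dilution_factors = c(5, 9),
                                     noise = 0.01, seed = 11)
  rr <- reduction_ratios(series)
  for (i in seq_len(nrow(rr)))
    expect_lt(abs(rr$ratio[i] - rr$dilution_factor[i]) / rr$dilution_factor[i],
              0.10)
  expect_true(rg_stability(series)$stable)
})

test_that("curves round-trip through delimited text", {
  q <- seq(0.001, 0.01, length.out = 15)
  cv <- curve1d(q, 100 * exp(-q * 30), sigma = sqrt(q))
  path <- tempfile(fileext = ".dat")
  write_curve(cv, path)
  back <- read_curve(path)
  expect_equal(back$q, cv$q, tolerance = 1e-12)
  expect_equal(back$intensity, cv$intensity, tolerance = 1e-12)
  expect_equal(back$sigma, cv$sigma, tolerance = 1e-12)
})
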