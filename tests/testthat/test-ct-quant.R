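test_that("leaf segmentation recovers a slab phantom and rejects empty volumes", {
  kf <- known_fraction_volume(dim3 = 36, fraction = 0.05, seed = 2)
  mask <- segment_leaf(kf$vol)
  disagree <- mean(xor(mask, kf$leaf))
  expect_lt(disagree, 0.01)
  # one connected component by construction
  labels <- npfate:::.label_components_3d(as.vector(mask), dim(mask))
  expect_equal(max(labels), 1L)

  air <- volume3d(array(rnorm(20^3, 0.05, 1e-4), c(20, 20, 20)))
  expect_error(segment_leaf(air), "empty foreground|Otsu|threshold")
})

test_that("np segmentation recovers a known volume fraction and obeys containment", {
  kf <- known_fraction_volume(dim3 = 36, fraction = 0.05, seed = 3)
  leaf <- segment_leaf(kf$vol)
  seg <- segment_np(kf$vol, leaf)
  expect_gte(seg$volume_fraction, 0.045)
  expect_lte(seg$volume_fraction, 0.055)
  expect_true(all(leaf[seg$np_mask]))           # np_mask subset of leaf
  expect_true(seg$volume_fraction >= 0 && seg$volume_fraction <= 1)
  expect_identical(seg$method, "otsu_seeded")

  # manual override: a threshold below every gray value labels all of the leaf
  seg_all <- segment_np(kf$vol, leaf, threshold = -Inf)
  expect_equal(seg_all$volume_fraction, 1)
  expect_identical(seg_all$method, "manual")
  # a threshold above the maximum yields an empty mask, fraction 0 (valid)
  seg_none <- segment_np(kf$vol, leaf, threshold = max(kf$vol$gray) + 1)
  expect_equal(seg_none$volume_fraction, 0)
})

test_that("volume fraction is monotone in the threshold", {
  kf <- known_fraction_volume(dim3 = 30, fraction = 0.08, seed = 4)
  leaf <- segment_leaf(kf$vol)
  ths <- seq(0.3, 1.0, length.out = 8)
  fr <- vapply(ths, function(t) segment_np(kf$vol, leaf, t)$volume_fraction,
               numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("otsu segmentation is invariant under a gray-level shift", {
  kf <- known_fraction_volume(dim3 = 30, fraction = 0.05, seed = 5)
  leaf <- segment_leaf(kf$vol)
  seg1 <- segment_np(kf$vol, leaf)
  shifted <- volume3d(kf$vol$gray + 0.37, kf$vol$voxel_size)
  seg2 <- segment_np(shifted, leaf)
  expect_equal(seg2$threshold - seg1$threshold, 0.37, tolerance = 1e-3)
  expect_identical(seg2$np_mask, seg1$np_mask)
})

test_that("np-region histograms conserve counts and shift left under dispersion", {
  ts <- render_timeseries_phantoms(c(0, 1, 3), mode = "dispersion", seed = 7)
  vols <- lapply(ts, `[[`, "volume")
  gray_all <- unlist(lapply(vols, function(v) as.vector(v$gray)))
  edges <- seq(min(gray_all), max(gray_all), length.out = 65)
  means <- numeric(3)
  for (i in 1:3) {
    leaf <- segment_leaf(vols[[i]])
    seg <- segment_np(vols[[i]], leaf)
    h <- np_region_histogram(vols[[i]], seg, breaks = edges)
    expect_equal(sum(h$counts), sum(seg$np_mask))
    means[i] <- sum(h$mids * h$counts) / sum(h$counts)
  }
  expect_true(all(diff(means) < 0))
})

test_that("time-series report reproduces the dispersion threshold/fraction trends", {
  ts <- render_timeseries_phantoms(c(0, 1, 3), mode = "dispersion", seed = 8)
  rep <- ct_timeseries_report(lapply(ts, `[[`, "volume"), c(0, 1, 3))
  expect_true(all(diff(rep$threshold) < 0))
  expect_true(all(diff(rep$volume_fraction) > 0))

  # identical volumes give identical rows
  v <- ts[[1]]$volume
  rep2 <- ct_timeseries_report(list(v, v))
  expect_equal(rep2$threshold[1], rep2$threshold[2])
  expect_equal(rep2$volume_fraction[1], rep2$volume_fraction[2])

  # replicate pair with perturbed noise seeds: fractions within a band
  ts_b <- render_timeseries_phantoms(c(0, 1, 3), mode = "dispersion", seed = 9)
  rep_b <- ct_timeseries_report(lapply(ts_b, `[[`, "volume"), c(0, 1, 3))
  expect_lt(max(abs(rep_b$volume_fraction - rep$volume_fraction) /
                rep$volume_fraction), 0.25)
})

test_that("np-region mean gray rises under aggregation, stays put under dissolution", {
  agg <- ct_timeseries_report(lapply(
    render_timeseries_phantoms(c(0, 3), mode = "aggregation", seed = 10),
    `[[`, "volume"))
  expect_gt(agg$np_mean_gray[2] / agg$np_mean_gray[1], 1.10)
  dis <- ct_timeseries_report(lapply(
    render_timeseries_phantoms(c(0, 3), mode = "dissolution", seed = 10),
    `[[`, "volume"))
  expect_lt(abs(dis$np_mean_gray[2] / dis$np_mean_gray[1] - 1), 0.10)
})
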