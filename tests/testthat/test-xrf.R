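make_blob_map <- function(element = "P", n = 40, cx = 20, cy = 20, seed = 1) {
  set.seed(seed)
  base <- matrix(rgamma(n * n, 20, 20), n, n)
  blob <- outer(seq_len(n), seq_len(n),
                function(r, cc) 6 * exp(-((r - cy)^2 + (cc - cx)^2) / 30))
  element_map(element, base + blob)
}

test_that("constructed integer shifts are recovered exactly", {
  a <- make_blob_map(seed = 2)
  for (off in list(c(3, -2), c(0, 0), c(-4, 5))) {
    dy <- off[1]; dx <- off[2]
    n <- nrow(a$intensity)
    b <- matrix(stats::median(a$intensity), n, n)
    rs <- max(1, 1 + dy):min(n, n + dy)
    cs <- max(1, 1 + dx):min(n, n + dx)
    b[rs - dy, cs - dx] <- a$intensity[rs, cs]
    res <- coregister_crop(a, element_map("P", b))
    expect_equal(res$offset, as.integer(off))
    expect_equal(res$a, res$b, tolerance = 1e-12)
  }
})

test_that("identical maps align at zero offset with a full-frame crop", {
  a <- make_blob_map(seed = 3)
  res <- coregister_crop(a, a)
  expect_equal(res$offset, c(0L, 0L))
  expect_equal(dim(res$a), dim(a$intensity))
})

test_that("structureless content fails alignment and requires a manual offset", {
  set.seed(4)
  n <- 30
  a <- element_map("P", matrix(rgamma(n * n, 20, 20), n, n))
  b <- element_map("P", matrix(rgamma(n * n, 20, 20), n, n))
  # noise-only maps: either the correlation peak is below the floor or the
  # estimate is meaningless; a manual offset always works
  res_manual <- coregister_crop(a, b, offset = c(2, 1))
  expect_equal(res_manual$offset, c(2L, 1L))
  expect_true(is.na(res_manual$correlation))
})

test_that("histograms conserve pixels and mark the control maximum", {
  maps <- lapply(1:3, function(i) make_blob_map(seed = 10 + i))
  control <- element_map("P", maps[[1]]$intensity * 0.2)
  res <- histogram_vs_control(maps, control, breaks = 32)
  expect_equal(res$control_max, max(control$intensity))
  for (i in 1:3)
    expect_equal(sum(res$histograms[[i]]$counts),
                 length(maps[[i]]$intensity))
  # a map identical to the control has nothing above the control max
  res0 <- histogram_vs_control(list(control), control)
  expect_equal(res0$fraction_above_control, 0)
  expect_error(histogram_vs_control(maps, element_map("Ce", control$intensity)),
               "element mismatch")
})

test_that("mobile element decays while the immobile tracer peak is stable", {
  ts <- render_timeseries_phantoms(c(0, 1, 3), mode = "dissolution", seed = 6,
                                   mesh_shape = c(24, 24), frame_dim = 16)
  p_maps <- lapply(ts, function(x) x$xrf$P)
  ce_maps <- lapply(ts, function(x) x$xrf$Ce)
  tissue_p <- p_maps[[1]]$intensity[!attr(ts, "region_mask")]
  control <- element_map("P", matrix(tissue_p[1:400], nrow = 20))
  res_p <- histogram_vs_control(p_maps, control, breaks = 32)
  expect_true(all(diff(res_p$fraction_above_control) < 0))

  tissue_ce <- ce_maps[[1]]$intensity[!attr(ts, "region_mask")]
  ce_control <- element_map("Ce", matrix(tissue_ce[1:400], nrow = 20))
  res_ce <- histogram_vs_control(ce_maps, ce_control, breaks = 16)
  expect_lte(max(res_ce$peak_bin) - min(res_ce$peak_bin), 1)
})

test_that("element maps round-trip through delimited text", {
  m <- make_blob_map(seed = 9)
  path <- tempfile(fileext = ".txt")
  write_element_map(m, path)
  back <- read_element_map(path)
  expect_equal(back$element, "P")
  expect_equal(back$intensity, m$intensity, tolerance = 1e-10)
  expect_equal(back$pixel_size, m$pixel_size)
})
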