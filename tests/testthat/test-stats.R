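test_that("region summaries report means, SDs and counts", {
  d <- c(3, 1, 1)
  lab <- vol3d(array(c(1L, 1L, 1L), d))
  maps <- list(APD = vol3d(array(c(10, 12, 14), d)))
  rois <- roi_set(lab, c(region_a = 1L))
  s <- roi_summary(maps, rois, parameters = "APD")
  expect_equal(s$mean, 12)
  expect_equal(s$sd, 2)
  expect_equal(s$n_voxels, 3L)
  const <- list(APD = vol3d(array(7, d)))
  expect_equal(roi_summary(const, rois, parameters = "APD")$sd, 0)
  # all-NA region errors with its name
  maps$APD$data[] <- NA
  expect_error(roi_summary(maps, rois, parameters = "APD"), "region_a")
})

test_that("coefficient of variation follows the SD/mean definition", {
  expect_equal(cov_percent(c(40, 42, 44)), 4.76, tolerance = 1e-2)
  expect_equal(cov_percent(c(5, 5, 5)), 0)
  x <- c(3.2, 4.8, 4.1, 3.9)
  expect_equal(cov_percent(x * 1000), cov_percent(x)) # scale invariant
  expect_error(cov_percent(7), "two")
  expect_error(cov_percent(c(-3, 1)), "positive|mean")
})

test_that("odd/even robustness is the two-value CoV", {
  expect_equal(robustness_percent(1.40, 1.50), 4.88, tolerance = 1e-2)
  expect_equal(robustness_percent(2, 2), 0)
  expect_equal(robustness_percent(1.4, 1.5), robustness_percent(140, 150))
  expect_error(robustness_percent(1, -1), "positive")
})

test_that("paired t-test reproduces the hand-computed statistic", {
  b <- c(10, 20, 30)
  a <- b + c(1, 0, 2)
  r <- paired_ttest(a, b)
  expect_equal(r$t, 1.732, tolerance = 1e-3)
  expect_equal(r$df, 2)
  expect_equal(r$p, 0.2254, tolerance = 1e-3)
  # null case: equal up to tiny symmetric jitter -> t = 0, p = 1
  jit <- rep(c(1e-9, -1e-9), 5)
  r0 <- paired_ttest(1:10 + jit, 1:10)
  expect_equal(r0$p, 1, tolerance = 1e-6)
  expect_error(paired_ttest(1:3, 1:3 + 5), "zero-variance")
  expect_error(paired_ttest(1:3, 1:4), "equal length")
})

test_that("intra-class correlation spans its reference cases", {
  # identical pairs, subjects differ: perfect agreement
  p <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(icc(p)$icc, 1)
  expect_equal(icc(p, "two_way")$icc, 1)
  # independent measurements: ICC near 0
  set.seed(6)
  q <- cbind(rnorm(200), rnorm(200))
  expect_lt(abs(icc(q)$icc), 0.1)
  # variance-component recovery: ICC ~ sb^2 / (sb^2 + sw^2)
  sb <- 2; sw <- 1
  subj <- rnorm(400, 0, sb)
  q2 <- cbind(subj + rnorm(400, 0, sw), subj + rnorm(400, 0, sw))
  expect_equal(icc(q2)$icc, sb^2 / (sb^2 + sw^2), tolerance = 0.08)
  expect_warning(got <- icc(cbind(rep(1, 5), rep(1, 5))), "degenerate")
  expect_true(is.na(got$icc))
  expect_error(icc(cbind(1:2, 1:2)), "n >= 3")
})

test_that("roi_set erosion keeps regions disjoint and smaller", {
  lab <- default_subject()$labels
  plain <- roi_set(lab)
  eroded <- roi_set(lab, erode = 1)
  for (code in plain$names) {
    n0 <- sum(plain$labels$data == code)
    n1 <- sum(eroded$labels$data == code)
    expect_lt(n1, n0)
    expect_gt(n1, 0)
  }
  # eroded voxels are excluded (-1), never relabelled into another region
  moved <- eroded$labels$data != lab$data
  expect_true(all(eroded$labels$data[moved] == -1L))
})
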