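test_that("log-linear R2* fit is exact on clean decays", {
  te <- c(3.00, 6.11, 9.22, 12.33, 15.44, 18.55)
  d <- c(2, 2, 2)
  arr <- array(0, c(d, 6))
  for (e in 1:6) arr[, , , e] <- 100 * exp(-0.0226 * te[e])
  es <- echo_series(arr, acq_params("PDw", 24.05, 6, te))
  fit <- fit_r2star(es)
  expect_equal(fit$R2star$data[1], 22.6, tolerance = 1e-9)
  expect_equal(fit$S0$data[1], 100, tolerance = 1e-9)
  # flat signal: no decay
  flat <- es; flat$data[] <- 50
  expect_equal(fit_r2star(flat)$R2star$data[1], 0, tolerance = 1e-12)
  # two echoes reduce to the closed form ln(S1/S2)/(TE2-TE1)
  two <- echo_series(arr[, , , 1:2, drop = FALSE],
                     acq_params("PDw", 24.05, 6, te[1:2]))
  expect_equal(fit_r2star(two)$R2star$data[1],
               1000 * log(arr[1, 1, 1, 1] / arr[1, 1, 1, 2]) / (te[2] - te[1]),
               tolerance = 1e-9)
  # scale invariance
  scaled <- es; scaled$data <- scaled$data * 17
  expect_equal(fit_r2star(scaled)$R2star$data, fit$R2star$data,
               tolerance = 1e-12)
  # non-positive signals mask the voxel rather than erroring
  neg <- es; neg$data[1, 1, 1, 3] <- -1
  expect_true(is.na(fit_r2star(neg)$R2star$data[1, 1, 1]))
  expect_false(anyNA(fit_r2star(neg)$R2star$data[2, , ]))
})

test_that("T1/APD inversion reproduces the worked dual-angle fixture", {
  acq <- default_acquisition()
  sp <- flash_signal(1000, 1800, 0, 6, 24.05, "approx")
  s1 <- flash_signal(1000, 1800, 0, 20, 22, "approx")
  expect_equal(sp, 74.25, tolerance = 1e-3)
  expect_equal(s1, 58.33, tolerance = 1e-3)
  fit <- estimate_t1_apd(const_vol(sp), const_vol(s1), acq$pd, acq$t1)
  expect_equal(fit$T1$data[1], 1800, tolerance = 1e-3)
  expect_equal(fit$A$data[1], 1000, tolerance = 1e-3)
  expect_equal(fit$R1$data[1], 1000 / 1800, tolerance = 1e-6)
  # degenerate voxels are masked
  z <- estimate_t1_apd(const_vol(0), const_vol(0), acq$pd, acq$t1)
  expect_true(all(is.na(z$T1$data)))
  expect_error(estimate_t1_apd(const_vol(1), const_vol(1, c(3, 3, 3)),
                               acq$pd, acq$t1), "grid")
})

test_that("rational approximation bias on exact signals matches the numerical oracle", {
  acq <- default_acquisition()
  # independent oracle: brute-force least-squares inversion of the exact
  # Ernst steady state
  exact_invert <- function(sp, s1) {
    obj <- function(p) {
      (flash_signal(p[1], p[2], 0, 6, 24.05, "exact") - sp)^2 +
      (flash_signal(p[1], p[2], 0, 20, 22, "exact") - s1)^2
    }
    stats::optim(c(800, 1000), obj, control = list(reltol = 1e-14))$par
  }
  sp <- flash_signal(1000, 1800, 0, 6, 24.05, "exact")
  s1 <- flash_signal(1000, 1800, 0, 20, 22, "exact")
  oracle <- exact_invert(sp, s1)
  expect_equal(oracle[2], 1800, tolerance = 1e-3) # oracle sanity
  fit <- estimate_t1_apd(const_vol(sp), const_vol(s1), acq$pd, acq$t1)
  expect_equal(fit$T1$data[1], 1824, tolerance = 1e-3) # ~ +1.3% bias
  for (t1_true in seq(800, 2500, by = 170)) {
    spx <- flash_signal(1000, t1_true, 0, 6, 24.05, "exact")
    s1x <- flash_signal(1000, t1_true, 0, 20, 22, "exact")
    fx <- estimate_t1_apd(const_vol(spx), const_vol(s1x), acq$pd, acq$t1)
    expect_lt(abs(fx$T1$data[1] - t1_true) / t1_true, 0.03)
  }
})

test_that("MT saturation inverts the MT-FLASH signal equation", {
  acq <- default_acquisition()
  smt <- flash_signal(1000, 1800, 0.0140, 6, 24.05, "approx")
  mts <- compute_mtsat(const_vol(smt), const_vol(1000),
                       const_vol(1000 / 1800), acq$mt)
  expect_equal(mts$data[1], 1.40, tolerance = 1e-3)
  # no MT effect: signal equal to the plain FLASH signal gives delta = 0
  s0 <- flash_signal(1000, 1800, 0, 6, 24.05, "approx")
  mts0 <- compute_mtsat(const_vol(s0), const_vol(1000),
                        const_vol(1000 / 1800), acq$mt)
  expect_equal(mts0$data[1], 0, tolerance = 1e-9)
  # monotone: larger delta -> smaller signal -> larger MTsat and MTR
  deltas <- c(0.005, 0.01, 0.02, 0.04)
  smts <- flash_signal(1000, 1800, deltas, 6, 24.05, "approx")
  est <- sapply(smts, function(s)
    compute_mtsat(const_vol(s), const_vol(1000), const_vol(1000 / 1800),
                  acq$mt)$data[1])
  expect_true(all(diff(est) > 0))
  mtrs <- sapply(smts, function(s)
    compute_mtr(const_vol(s0), const_vol(s))$data[1])
  expect_true(all(diff(mtrs) > 0))
  # masking
  expect_true(is.na(compute_mtsat(const_vol(0), const_vol(1000),
                                  const_vol(0.5), acq$mt)$data[1]))
})

test_that("MTR is the fractional signal drop in percent units", {
  expect_equal(compute_mtr(const_vol(74.25), const_vol(42.60))$data[1],
               42.63, tolerance = 1e-3)
  expect_equal(compute_mtr(const_vol(50), const_vol(50))$data[1], 0)
  expect_equal(compute_mtr(const_vol(50), const_vol(0))$data[1], 100)
  expect_true(is.na(compute_mtr(const_vol(0), const_vol(1))$data[1]))
})

test_that("estimate_all recovers uniform truth to machine precision", {
  data <- uniform_dataset()
  maps <- estimate_all(data)
  truthv <- c(APD = 1000, T1 = 1800, MTsat = 1.40, R2star = 22.6)
  for (p in names(truthv))
    expect_lt(max(abs(maps[[p]]$data - truthv[p])) / truthv[p], 1e-6)
  sref <- flash_signal(1000, 1800, 0, 6, 24.05)
  smt <- flash_signal(1000, 1800, 0.0140, 6, 24.05)
  expect_lt(max(abs(maps$MTR$data - 100 * (sref - smt) / sref)), 1e-6)
})

test_that("estimate_all masks background and matches truth inside tissue", {
  sub <- default_subject()
  maps <- estimate_all(sub[c("pd", "t1", "mt")])
  bg <- sub$labels$data == 0L
  interior <- bg & array(rep((1:64 %in% 5:10), 64 * 30), dim(bg)) # far corner
  for (p in c("APD", "T1", "MTsat", "R2star"))
    expect_true(all(is.na(maps[[p]]$data[interior])))
  rois <- roi_set(sub$labels, erode = 1)
  s <- roi_summary(maps, rois)
  truth <- default_tissues(); rownames(truth) <- truth$label
  for (rg in c("GM", "dorsal_WM", "left_lateral_WM", "right_lateral_WM")) {
    expect_lt(abs(s$mean[s$region == rg & s$parameter == "T1"] -
                  truth[rg, "T1"]) / truth[rg, "T1"], 0.01)
    expect_lt(abs(s$mean[s$region == rg & s$parameter == "MTsat"] -
                  100 * truth[rg, "delta"]) / (100 * truth[rg, "delta"]), 0.01)
  }
})

test_that("odd and even subsets agree on noiseless data", {
  sub <- default_subject()
  rois <- roi_set(sub$labels, erode = 1)
  so <- roi_summary(estimate_all(sub[c("pd", "t1", "mt")], echo_subset = "odd"),
                    rois)
  se <- roi_summary(estimate_all(sub[c("pd", "t1", "mt")], echo_subset = "even"),
                    rois)
  expect_lt(max(robustness_percent(so$mean, se$mean)), 0.5)
})

test_that("MTsat tolerates transmit-field errors better than MTR", {
  acq <- default_acquisition()
  base <- uniform_dataset()
  maps0 <- estimate_all(base)
  mts0 <- maps0$MTsat$data[1]; mtr0 <- maps0$MTR$data[1]
  dev_mts <- dev_mtr <- numeric(0)
  for (f in c(80, 90, 110, 120)) {
    b1 <- const_vol(f, c(6, 6, 4)); b1$affine <- centred_affine(c(6, 6, 4), c(1, 1, 3))
    data <- uniform_dataset(b1 = b1)     # simulated at actual angles
    maps <- estimate_all(data, b1 = NULL) # estimated with nominal angles
    dev_mts <- c(dev_mts, abs(maps$MTsat$data[1] - mts0) / mts0)
    dev_mtr <- c(dev_mtr, abs(maps$MTR$data[1] - mtr0) / mtr0)
  }
  expect_lt(max(dev_mts), max(dev_mtr))
  expect_lt(max(abs(dev_mts * mts0)), 0.02) # < 0.02 p.u. absolute
})

test_that("B1 correction restores T1 under a transmit-field error", {
  d <- c(6, 6, 4)
  b1 <- vol3d(array(110, d), centred_affine(d, c(1, 1, 3)))
  data <- uniform_dataset(b1 = b1)
  biased <- estimate_all(data, b1 = NULL)
  corrected <- estimate_all(data, b1 = b1)
  expect_gt(abs(biased$T1$data[1] - 1800), 100)       # ~ 1/f^2 bias
  expect_lt(abs(corrected$T1$data[1] - 1800), 1e-3)
  expect_lt(abs(corrected$APD$data[1] - 1000), 1e-3)
})
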