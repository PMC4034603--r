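test_that("geometry builds the six-tissue cord cross-section", {
  spec <- phantom_spec()
  lab <- make_geometry(spec)
  expect_identical(dim(lab$data), c(64L, 64L, 30L))
  expect_setequal(unique(as.vector(lab$data)), 0:5)
  # everything inside the CSF boundary carries a non-background label
  d <- dim(lab$data)
  aff <- lab$affine
  x <- (0:(d[1] - 1)) + aff[1, 4]
  y <- (0:(d[2] - 1)) + aff[2, 4]
  X <- matrix(x, d[1], d[2]); Y <- matrix(y, d[1], d[2], byrow = TRUE)
  inside <- (X / 6)^2 + (Y / 3.5)^2 <= 1 # safely interior to the cord
  expect_true(all(lab$data[, , 15][inside] > 0))
})

test_that("left and right lateral columns are mirror images", {
  lab <- make_geometry(phantom_spec())
  expect_identical(sum(lab$data == 4L), sum(lab$data == 5L))
  # mirror symmetry of the full label field about the midline
  expect_identical(sum(lab$data == 2L), sum(lab$data[64:1, , ] == 2L))
})

test_that("degenerate geometry is rejected", {
  expect_error(phantom_spec(cord_radius = 0), "geometry")
  expect_error(phantom_spec(csf_radius = 5, cord_radius = 6), "geometry")
  expect_error(phantom_spec(noise = list(model = "rician", snr = -1)), "SNR")
})

test_that("ground-truth maps take the tissue-table values", {
  lab <- make_geometry(phantom_spec())
  truth <- assign_ground_truth(lab)
  expect_equal(unique(truth$T1$data[lab$data == 3L]), 1735)   # dorsal WM
  expect_equal(unique(truth$delta$data[lab$data == 3L]), 0.0143)
  expect_equal(unique(truth$T1$data[lab$data == 2L]), 1815)   # GM
  expect_equal(unique(truth$R2star$data[lab$data == 2L]), 18.9)
  for (p in c("A", "T1", "delta", "R2star"))
    expect_true(all(truth[[p]]$data[lab$data == 0L] == 0))
  bad <- lab; bad$data[1] <- 99L
  expect_error(assign_ground_truth(bad), "99")
})

test_that("flash_signal matches the closed forms", {
  expect_equal(flash_signal(1000, 1800, 0, 6, 24.05, "approx"), 74.25,
               tolerance = 1e-4)
  expect_equal(flash_signal(1000, 1800, 0, 6, 24.05, "exact"), 74.28,
               tolerance = 1e-4)
  expect_equal(flash_signal(1000, 1800, 0.0140, 6, 24.05, "approx"), 42.60,
               tolerance = 1e-4)
  expect_error(flash_signal(1000, -5, 0, 6, 24.05), "T1")
})

test_that("approximation tracks the exact steady state in the small-angle regime", {
  t1 <- seq(800, 4500, by = 100)
  rel6 <- abs(flash_signal(1, t1, 0, 6, 24.05, "approx") /
              flash_signal(1, t1, 0, 6, 24.05, "exact") - 1)
  rel20 <- abs(flash_signal(1, t1, 0, 20, 22, "approx") /
               flash_signal(1, t1, 0, 20, 22, "exact") - 1)
  expect_lt(max(rel6), 0.001)
  expect_lt(max(rel20), 0.01)
})

test_that("MT-mode signal reduces to the PD-mode signal at delta = 0", {
  for (mode in c("approx", "exact"))
    expect_equal(flash_signal(500, 1500, 0, 6, 24.05, mode),
                 flash_signal(500, 1500, delta = 0, 6, 24.05, mode))
  # and decreases monotonically in delta
  s <- flash_signal(500, 1500, c(0, 0.01, 0.02, 0.04), 6, 24.05)
  expect_true(all(diff(s) < 0))
})

test_that("simulated echoes decay at the configured R2*", {
  acq <- default_acquisition()
  expect_equal(diff(acq$pd$echo_times)[1], 3.11, tolerance = 1e-12)
  truth <- uniform_truth()
  es <- simulate_echoes(truth, acq$pd)
  expect_identical(dim(es$data)[4], 6L)
  ratio <- es$data[1, 1, 1, 2] / es$data[1, 1, 1, 1]
  expect_equal(ratio, exp(-0.0226 * 3.11), tolerance = 1e-12) # ~0.9321
  # monotone decreasing in TE, increasing in A
  expect_true(all(diff(es$data[1, 1, 1, ]) < 0))
  truth2 <- uniform_truth(A = 2000)
  es2 <- simulate_echoes(truth2, acq$pd)
  expect_true(all(es2$data > es$data))
  # grid mismatch rejected
  b1_bad <- vol3d(array(100, c(3, 3, 3)))
  expect_error(simulate_echoes(truth, acq$pd, b1_bad), "grid")
})

test_that("AFI ratio follows the ideal two-TR model", {
  d <- c(4, 4, 2)
  mk <- function(pct) vol3d(array(pct, d), centred_affine(d, c(1, 1, 1)))
  afi <- simulate_afi(mk(100), amplitude = 1000)
  expect_equal(afi$S2$data[1] / afi$S1$data[1], 0.71429, tolerance = 1e-5)
  afi30 <- simulate_afi(mk(50), amplitude = 1000) # 50% of 60 deg = 30 deg
  expect_equal(afi30$S2$data[1] / afi30$S1$data[1], 0.93069, tolerance = 1e-5)
  afi0 <- simulate_afi(mk(1e-9), amplitude = 1000)
  expect_equal(afi0$S2$data[1] / afi0$S1$data[1], 1, tolerance = 1e-9)
  expect_error(simulate_afi(mk(100), 1000, TR1_ms = 150, TR2_ms = 50), "TR2")
})

test_that("noise injection is reproducible and Rician on background", {
  truth <- uniform_truth(d = c(10, 10, 10))
  es <- simulate_echoes(truth, default_acquisition()$pd)
  expect_identical(add_noise(es, snr = 10, model = "none"), es)
  n1 <- add_noise(es, model = "rician", seed = 11, sigma = 5)
  n2 <- add_noise(es, model = "rician", seed = 11, sigma = 5)
  expect_identical(n1$data, n2$data)
  expect_error(add_noise(es, 10, model = "weird"), "arg")
  # zero-signal voxels acquire the Rician floor sigma * sqrt(pi/2)
  z <- es; z$data[] <- 0
  zn <- add_noise(z, model = "rician", seed = 3, sigma = 5)
  expect_equal(mean(zn$data), 5 * sqrt(pi / 2), tolerance = 0.02)
})

test_that("cohort draws respect the configured inter-subject variation", {
  spec <- phantom_spec(dim = c(16, 16, 4), cord_radius = 4, csf_radius = 6,
                       cohort_cv = c(A = 0, T1 = 0, delta = 0, R2star = 0),
                       noise = list(model = "none"), seed = 5L)
  coh <- generate_cohort(spec, 3)
  expect_identical(nrow(coh$manifest), 3L * nrow(default_tissues()))
  # zero CoV: all subjects share the default truth
  expect_true(all(coh$manifest$T1_ms[coh$manifest$tissue == "GM"] == 1815))
  spec2 <- phantom_spec(dim = c(16, 16, 4), cord_radius = 4, csf_radius = 6,
                        cohort_cv = c(A = 0, T1 = 0, delta = 0.15 / 1.43,
                                      R2star = 0),
                        noise = list(model = "none"), seed = 9L)
  coh2 <- generate_cohort(spec2, 13)
  drawn <- coh2$manifest$MTsat_pu[coh2$manifest$tissue == "dorsal_WM"]
  expect_lt(abs(mean(drawn) - 1.43), 3 * 0.15 / sqrt(13))
})
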