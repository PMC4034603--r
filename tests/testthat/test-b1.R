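test_that("AFI flip-angle inversion matches the closed form", {
  d <- c(3, 3, 2)
  s1 <- const_vol(1000, d)
  mk <- function(r) vol3d(array(1000 * r, d), s1$affine)
  expect_equal(afi_flip_angle(s1, mk(0.71429))$data[1], 60, tolerance = 1e-3)
  expect_equal(afi_flip_angle(s1, mk(1))$data[1], 0, tolerance = 1e-6)
  expect_equal(afi_flip_angle(s1, mk(0.93069))$data[1], 30, tolerance = 1e-3)
  expect_error(afi_flip_angle(s1, mk(1), TR1_ms = 150, TR2_ms = 50), "TR2")
  # out-of-range ratios are clipped and counted
  wild <- afi_flip_angle(s1, mk(1.5))
  expect_gt(attr(wild, "clipped"), 0)
  # noise threshold masks low-signal voxels
  weak <- s1; weak$data[1, 1, 1] <- 1
  masked <- afi_flip_angle(weak, mk(0.9), noise_sigma = 10)
  expect_true(is.na(masked$data[1, 1, 1]))
})

test_that("percent-of-nominal conversion is a plain ratio", {
  fm <- const_vol(54)
  expect_equal(to_percent_nominal(fm, 60)$data[1], 90)
  expect_equal(to_percent_nominal(const_vol(60), 60)$data[1], 100)
  expect_error(to_percent_nominal(fm, 0), "positive")
})

test_that("simulated AFI round-trips the injected transmit-field ramp", {
  spec <- phantom_spec(b1 = list(mean = 100, gradient = 10 / 31.5,
                                 bounds = c(70, 130)))
  b1 <- make_b1_field(spec)
  expect_equal(range(b1$data), c(90, 110), tolerance = 0.5)
  sub <- simulate_subject(spec)
  est <- compute_b1_map(sub$afi1, sub$afi2)
  cord <- sub$labels$data > 0
  expect_lt(max(abs(est$data[cord] - b1$data[cord])), 0.5)
  # depends only on the ratio: rescaling both volumes changes nothing
  s1 <- sub$afi1; s1$data <- s1$data * 7.3
  s2 <- sub$afi2; s2$data <- s2$data * 7.3
  est2 <- compute_b1_map(s1, s2)
  expect_equal(est2$data, est$data, tolerance = 1e-12)
})

test_that("B1 preparation preserves constants and smooth ramps", {
  spec <- phantom_spec(b1 = list(mean = 100, gradient = 10 / 31.5,
                                 bounds = c(70, 130)))
  ramp <- make_b1_field(spec)
  ref <- average_echoes(default_subject()$t1, "all")
  # identity transform, zero smoothing: unchanged
  expect_equal(prepare_b1_for_correction(ramp, ref, smoothing_fwhm_mm = 0)$data,
               ramp$data, tolerance = 1e-9)
  # uniform map invariant under smoothing
  u <- const_vol(100, dim(ref$data)); u$affine <- ref$affine
  expect_equal(prepare_b1_for_correction(u, ref, smoothing_fwhm_mm = 8)$data,
               u$data, tolerance = 1e-9)
  # linear ramp survives an 8-mm Gaussian away from the volume edges
  sm <- prepare_b1_for_correction(ramp, ref, smoothing_fwhm_mm = 8)
  interior <- 13:52
  expect_lt(max(abs(sm$data[interior, , ] - ramp$data[interior, , ])), 1)
  # masked voxels are filled from neighbours before smoothing
  holey <- ramp; holey$data[30:34, 30:34, 10] <- NA
  filled <- prepare_b1_for_correction(holey, ref, smoothing_fwhm_mm = 0)
  expect_false(anyNA(filled$data))
  all_na <- ramp; all_na$data[] <- NA
  expect_error(prepare_b1_for_correction(all_na, ref, smoothing_fwhm_mm = 0),
               "empty")
})
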