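test_that("echo averaging selects the requested subsets", {
  acq <- acq_params("PDw", 24.05, 6, c(3, 6.11, 9.22, 12.33, 15.44, 18.55))
  d <- c(2, 2, 2)
  arr <- array(0, c(d, 6))
  vals <- c(10, 8, 6, 4, 2, 0)
  for (e in 1:6) arr[, , , e] <- vals[e]
  es <- echo_series(arr, acq)
  expect_equal(average_echoes(es, "all")$data[1], 5)
  expect_equal(average_echoes(es, "odd")$data[1], 6)   # echoes 1, 3, 5
  expect_equal(average_echoes(es, "even")$data[1], 4)  # echoes 2, 4, 6
  expect_equal(average_echoes(es, "first_k", k = 2)$data[1], 9)
  one <- echo_series(arr[, , , 1, drop = FALSE], acq_params("PDw", 24.05, 6, 3))
  expect_error(average_echoes(one, "even"), "empty")
  # matches a direct mean on simulated data
  sub <- default_subject()
  m <- average_echoes(sub$pd, "all")
  expect_equal(m$data[32, 32, 15], mean(sub$pd$data[32, 32, 15, ]))
})

test_that("contrast inversion makes CSF brighter than cord", {
  v <- vol3d(array(c(0, 100), c(2, 1, 1)))
  inv <- invert_contrast(v)
  expect_equal(as.vector(inv$data), c(100, 0), tolerance = 0.2)
  # involution on the non-clipped range
  v2 <- average_echoes(default_subject()$t1, "all")
  twice <- invert_contrast(invert_contrast(v2))
  big <- v2$data > 0.05 * max(v2$data)
  expect_equal(twice$data[big], v2$data[big], tolerance = 0.01)
  # rank order of CSF vs WM flips on the averaged T1w volume
  lab <- default_subject()$labels$data
  csf <- lab == 1L; wm <- lab == 3L
  expect_gt(mean(v2$data[wm]), mean(v2$data[csf]))      # T1w: cord bright
  inv2 <- invert_contrast(v2)
  expect_gt(mean(inv2$data[csf]), mean(inv2$data[wm]))  # inverted: CSF bright
  expect_warning(invert_contrast(const_vol(7)), "constant")
})

test_that("normalised mutual information behaves as an information measure", {
  v <- average_echoes(default_subject()$pd, "all")
  expect_equal(nmi(v, v), 2, tolerance = 1e-12)
  set.seed(2)
  d <- c(48, 48, 24)
  a <- vol3d(array(runif(prod(d)), d))
  b <- vol3d(array(runif(prod(d)), d))
  expect_lt(abs(nmi(a, b) - 1), 0.05)
  expect_equal(nmi(a, b), nmi(b, a)) # shared binning rule => symmetric
  shifted <- resample(v, rigid_transform(tx = 2), "nearest")
  expect_lt(nmi(v, shifted), nmi(v, v))
  expect_warning(got <- nmi(const_vol(3), const_vol(5)), "constant")
  expect_equal(got, 1)
})

test_that("rigid registration recovers an injected motion", {
  # thinner slab keeps the unit test quick; the acceptance suite exercises
  # the full-size phantom
  spec <- phantom_spec(dim = c(64, 64, 16))
  sub <- simulate_subject(spec)
  v <- average_echoes(sub$pd, "all")
  inj <- rigid_transform(2, -1, 0, 0, 0, 3)
  mv <- resample(v, inj, "sinc")
  est <- register_rigid(mv, v)
  truth <- rigid_invert(inj, volume_centre(v))
  err <- est$params - truth$params
  expect_lt(max(abs(err[1:3])), 0.5)
  expect_lt(max(abs(err[4:6])), 0.5)
  # self-registration is the identity
  self <- register_rigid(v, v, init = rigid_transform())
  expect_lt(max(abs(self$params[1:3])), 0.1)
  expect_lt(max(abs(self$params[4:6])), 0.1)
})

test_that("registration target is a normalised average of the three contrasts", {
  v <- average_echoes(default_subject()$pd, "all")
  t3 <- build_target(v, v, v)
  expect_equal(t3$data, v$data / cordmpm:::robust_box_mean(v))
  a <- v; a$data <- a$data * 10
  b <- v; b$data <- b$data * 20
  ct <- build_target(a, b, v)
  expect_equal(ct$data / max(ct$data), v$data / max(v$data), tolerance = 1e-12)
  zero <- v; zero$data[] <- 0
  expect_error(build_target(zero, v, v), "threshold|mean")
  # GM/WM contrast sign of the target follows MTw (GM brighter than WM there)
  sub <- default_subject()
  lab <- sub$labels$data
  mt <- average_echoes(sub$mt, "all")
  tgt <- build_target(average_echoes(sub$pd, "all"),
                      invert_contrast(average_echoes(sub$t1, "all")), mt)
  sgn <- function(x) sign(mean(x$data[lab == 2L]) - mean(x$data[lab == 3L]))
  expect_equal(sgn(tgt), sgn(mt))
})
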