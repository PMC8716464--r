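fake_map <- function(mat) {
  structure(mat, class = c("field_map", "matrix", "array"))
}

test_that("the envelope is twice the smaller field magnitude", {
  m1 <- fake_map(matrix(c(0.05, 0, 0,
                          0.03, 0.04, 0), 2, 3, byrow = TRUE))
  m2 <- fake_map(matrix(c(0.05, 0, 0,
                          0, 0, 0.10), 2, 3, byrow = TRUE))
  env <- if_envelope(m1, m2)
  expect_equal(as.numeric(env), c(0.10, 0.10))
  # silent second source: no interference anywhere
  z <- fake_map(matrix(0, 2, 3))
  expect_equal(as.numeric(if_envelope(m1, z)), c(0, 0))
  # symmetric in argument order
  expect_equal(as.numeric(if_envelope(m2, m1)), as.numeric(env))
  # envelope cap: never above twice either field magnitude
  set.seed(3)
  a <- fake_map(matrix(rnorm(30), 10, 3))
  b <- fake_map(matrix(rnorm(30), 10, 3))
  env_ab <- as.numeric(if_envelope(a, b))
  expect_true(all(env_ab <= 2 * magnitude_map(a) + 1e-12))
  expect_true(all(env_ab <= 2 * magnitude_map(b) + 1e-12))
  expect_error(if_envelope(a, fake_map(matrix(0, 4, 3))), "voxel")
})

test_that("the direction-resolved envelope projects before the minimum", {
  m1 <- fake_map(matrix(c(0.05, 0, 0), 1, 3))
  m2 <- fake_map(matrix(c(0.03, 0.04, 0), 1, 3))
  env_x <- if_envelope(m1, m2, direction = c(1, 0, 0))
  expect_equal(as.numeric(env_x), 2 * 0.03)
  env_mag <- if_envelope(m1, m2)
  expect_equal(as.numeric(env_mag), 2 * 0.05)
})

test_that("scaling both sources scales the envelope and preserves focality", {
  set.seed(9)
  a <- matrix(rnorm(60), 20, 3)
  b <- matrix(rnorm(60), 20, 3)
  env1 <- if_envelope(fake_map(a), fake_map(b))
  env2 <- if_envelope(fake_map(3 * a), fake_map(3 * b))
  expect_equal(as.numeric(env2), 3 * as.numeric(env1), tolerance = 1e-12)
  f1 <- focality_half_value(as.numeric(env1), 1, 64)
  f2 <- focality_half_value(as.numeric(env2), 1, 64)
  expect_equal(f1$F_cm, f2$F_cm)
})

test_that("half-value focality counts strictly supra-threshold volume", {
  # hand-countable 3-voxel map at 1 cm3 per voxel
  rep3 <- focality_half_value(c(1.0, 0.6, 0.4), 1, 1000)
  expect_equal(rep3$threshold, 0.5)
  expect_identical(rep3$n_supra, 2L)
  expect_equal(rep3$volume_cm3, 2)
  expect_equal(rep3$F_cm, 2^(1 / 3))
  # single nonzero voxel of 8 mm3: F = 0.2 cm
  rep1 <- focality_half_value(c(0.3, 0, 0), 1, 8)
  expect_equal(rep1$F_cm, 0.2)
  # uniform map: every voxel exceeds half the target value
  repu <- focality_half_value(rep(2, 125), 5, 1000)
  expect_equal(repu$F_cm, 125^(1 / 3) * 1)
  # ties at exactly half are excluded
  rept <- focality_half_value(c(1, 0.5, 0.5), 1, 1000)
  expect_identical(rept$n_supra, 1L)
  # zero target: undefined, reported as such
  expect_warning(rep0 <- focality_half_value(c(0, 1), 1, 8), "undefined")
  expect_true(is.na(rep0$F_cm))
})

test_that("focality counts are integer voxel multiples of the voxel volume", {
  set.seed(31)
  vals <- runif(200)
  rep <- focality_half_value(vals, which.max(vals), 64)
  expect_equal(rep$volume_cm3, rep$n_supra * 64 / 1000)
  expect_equal(rep$F_cm, rep$volume_cm3^(1 / 3))
})

test_that("nonif magnitude aliases the field magnitude map", {
  set.seed(5)
  f <- fake_map(matrix(rnorm(30), 10, 3))
  expect_identical(nonif_magnitude(f), magnitude_map(f))
})

test_that("interference shifts the field maximum toward the deep target", {
  # the phenomenon that motivates interferential stimulation: at the
  # grand-optimal solution, the envelope is relatively stronger at depth
  # than either single high-frequency field
  sw <- phantom_sweep("stn_left", "skull")
  go <- attr(sw, "grand_optimal")
  res <- attr(sw, "results")[[go]]
  ph <- phantom_4mm()
  lf <- ph$lf$skull
  tgt <- attr(sw, "target")$target_row
  # cortical shell: brain voxels in the outer 12 mm of the GM radius
  vi <- lf$voxel_index
  r <- sqrt(rowSums(sweep(vi, 2, lf$center)^2)) * lf$voxel_size
  cortical <- r >= 64
  nv1 <- magnitude_map(total_field(lf, res$s1))
  nv2 <- magnitude_map(total_field(lf, res$s2))
  env <- 2 * pmin(nv1, nv2)
  contrast_env <- env[tgt] / max(env[cortical])
  expect_gt(contrast_env, nv1[tgt] / max(nv1[cortical]))
  expect_gt(contrast_env, nv2[tgt] / max(nv2[cortical]))
})
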