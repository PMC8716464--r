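test_that("zero injected current gives an identically zero field", {
  g <- small_homog_grid()
  ctr <- linear_index(g, matrix(g$center, 1))
  far <- linear_index(g, matrix(g$center + c(5L, 0L, 0L), 1))
  sol <- solve_current_sources(g, c(ctr, far), c(0, 0))
  expect_true(all(abs(sol$E) == 0))
  phi <- sol$phi[!is.na(sol$phi)]
  expect_true(all(abs(phi) < 1e-14))
})

test_that("the solution is linear in the injected current", {
  g <- small_homog_grid()
  ctr <- linear_index(g, matrix(g$center, 1))
  far <- linear_index(g, matrix(g$center + c(0L, 0L, 7L), 1))
  cfg <- solver_config(tol = 1e-11)
  s1 <- solve_current_sources(g, c(ctr, far), c(1, -1), config = cfg)
  s3 <- solve_current_sources(g, c(ctr, far), c(3, -3), config = cfg,
                              system = s1$system)
  scale <- max(abs(s1$E), na.rm = TRUE)
  expect_lt(max(abs(s3$E - 3 * s1$E), na.rm = TRUE), 1e-6 * scale)
})

test_that("discrete charge is conserved away from the electrodes", {
  g <- small_homog_grid()
  ctr <- linear_index(g, matrix(g$center + c(-6L, 0L, 0L), 1))
  far <- linear_index(g, matrix(g$center + c(6L, 0L, 0L), 1))
  cfg <- solver_config(tol = 1e-10)
  sol <- solve_current_sources(g, c(ctr, far), c(1, -1), config = cfg)
  sys <- sol$system
  # net discrete flux out of a source-free region = sum of residuals there
  phi_u <- sol$phi[sys$cond]
  resid <- as.numeric(sys$L %*% phi_u)  # b is zero off the electrodes
  region <- which(sys$map > 0 & !seq_along(sys$map) %in% c(ctr, far))
  # per-voxel and aggregate imbalance, in units of the injected current (mA)
  imbalance <- sum(resid[sys$map[region]]) / 1e-3
  expect_lt(abs(imbalance), 1e-6)
})

test_that("solver reproduces the infinite-medium point-source field", {
  ps <- point_source_fixture()
  rel <- ps$rel_err
  expect_lt(stats::median(rel), 0.03)
  expect_lte(stats::quantile(rel, 0.9), 0.05)
})

test_that("layered radial flow matches the series-resistance closed form", {
  g <- radial_grid()
  sol <- cache_get("radial_sol", function() {
    solve_radial_harness(g, config = solver_config(tol = 1e-10))
  })
  # mid-shell radii, away from the interfaces and >= 5 voxels from the
  # central injection voxel (closer shells see the source discretization)
  for (r0 in c(20, 45, 75)) {
    pred <- analytic_radial_profile(g$shells, 1, r0)
    obs <- band_median_E(g, sol, r0)
    expect_lt(abs(obs / pred - 1), 0.03)
  }
})

test_that("field concentrates in the resistive shell", {
  g <- radial_grid()
  sol <- cache_get("radial_sol", function() {
    solve_radial_harness(g, config = solver_config(tol = 1e-10))
  })
  # resistive (skull-like) shell vs the conductive shell outside it
  expect_gt(band_median_E(g, sol, 45), band_median_E(g, sol, 75))
})

test_that("non-convergence and disconnected domains raise errors", {
  g <- small_homog_grid()
  ctr <- linear_index(g, matrix(g$center, 1))
  far <- linear_index(g, matrix(g$center + c(6L, 0L, 0L), 1))
  expect_error(
    solve_current_sources(g, c(ctr, far), c(1, -1),
                          config = solver_config(max_iter = 2, method = "pcg")),
    "did not converge")
  # split the sphere into two disconnected conductive blobs
  g2 <- g
  mid <- g$center[1]
  g2$sigma[mid + (-1:1), , ] <- 0
  expect_error(solve_current_sources(g2, c(ctr, far), c(1, -1)),
               "[Dd]isconnected|outside the conductive")
})

test_that("direct and iterative solvers agree", {
  g <- small_homog_grid()
  ctr <- linear_index(g, matrix(g$center, 1))
  far <- linear_index(g, matrix(g$center + c(0L, 6L, 0L), 1))
  sd <- solve_current_sources(g, c(ctr, far), c(1, -1),
                              config = solver_config(method = "direct"))
  sp <- solve_current_sources(g, c(ctr, far), c(1, -1),
                              config = solver_config(method = "pcg", tol = 1e-10))
  expect_lt(max(abs(sd$phi - sp$phi), na.rm = TRUE),
            1e-6 * max(abs(sd$phi), na.rm = TRUE))
})
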