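test_that("a two-electrode problem saturates the current budget", {
  tp <- toy_problem(2, 3, seed = 5)
  # huge budget: L1 constraint is the only active one
  opt <- optimize_single_source(tp$A, e = tp$e, gamma = tp$gamma,
                                config = optimizer_config(p_max = 1e6))
  s <- as.numeric(opt$s)
  expect_equal(sort(s), c(-0.5, 0.5), tolerance = 1e-9)
  expect_gt(opt$objective, 0)
})

test_that("a vanishing power budget collapses current and objective", {
  tp <- toy_problem(3, 4, seed = 15)
  p0 <- default_pmax(tp$A, tp$e, tp$gamma)
  big <- optimize_single_source(tp$A, e = tp$e, gamma = tp$gamma,
                                config = optimizer_config(p_max = p0))
  small <- optimize_single_source(tp$A, e = tp$e, gamma = tp$gamma,
                                  config = optimizer_config(p_max = p0 * 1e-8))
  expect_lt(small$objective, 0.01 * big$objective)
  expect_lt(small$sum_abs_s, 0.05)
  expect_lte(small$power, p0 * 1e-8 * (1 + 1e-6))
})

test_that("single-source solutions match the brute-force oracle", {
  tp <- toy_problem(3, 5, seed = 42)
  p0 <- default_pmax(tp$A, tp$e, tp$gamma)
  for (frac in c(0.03, 0.3, 3)) {
    P <- p0 * frac
    opt <- optimize_single_source(tp$A, e = tp$e, gamma = tp$gamma,
                                  config = optimizer_config(p_max = P))
    bf <- brute_single(tp, P)
    # the grid oracle is a lower bound; agreement within 1%
    expect_gt(opt$objective, bf * 0.99)
    expect_lt(opt$objective, bf * 1.01)
    expect_lte(opt$power, P * (1 + 1e-6))
    expect_lt(abs(sum(as.numeric(opt$s))), 1e-9)
    expect_lte(sum(abs(as.numeric(opt$s))), 1 + 1e-9)
  }
})

test_that("negating the target direction mirrors the solution", {
  tp <- toy_problem(3, 5, seed = 42)
  p0 <- default_pmax(tp$A, tp$e, tp$gamma)
  a <- optimize_single_source(tp$A, e = tp$e, gamma = tp$gamma,
                              config = optimizer_config(p_max = p0))
  b <- optimize_single_source(tp$A, e = -tp$e, gamma = tp$gamma,
                              config = optimizer_config(p_max = p0))
  expect_equal(b$objective, a$objective, tolerance = 1e-6)
  expect_equal(as.numeric(b$s), -as.numeric(a$s), tolerance = 1e-5)
})

test_that("interferential solutions respect every constraint", {
  tp <- toy_problem(4, 5, seed = 7)
  p0 <- default_pmax(tp$A, tp$e, tp$gamma)
  for (frac in c(0.03, 0.3)) {
    opt <- optimize_interferential(tp$A, e = tp$e, gamma = tp$gamma,
                                   config = optimizer_config(p_max = p0 * frac))
    for (s in list(as.numeric(opt$s1), as.numeric(opt$s2))) {
      expect_lt(abs(sum(s)), 1e-9)
      expect_lte(sum(abs(s)), 1 + 1e-9)
    }
    expect_lte(opt$envelope_power, p0 * frac * (1 + 1e-6))
    # stored objective equals the recomputed value
    expect_equal(opt$objective,
                 2 * min(sum(tp$c_vec * as.numeric(opt$s1)),
                         sum(tp$c_vec * as.numeric(opt$s2))),
                 tolerance = 1e-8)
  }
})

test_that("interferential solutions match the brute-force pair oracle", {
  tp <- toy_problem(4, 5, seed = 7)
  p0 <- default_pmax(tp$A, tp$e, tp$gamma)
  for (frac in c(0.03, 0.3)) {
    P <- p0 * frac
    opt <- optimize_interferential(tp$A, e = tp$e, gamma = tp$gamma,
                                   config = optimizer_config(p_max = P))
    bf <- brute_if(tp, P)
    expect_gt(opt$objective, bf$objective * 0.98)
    expect_lt(opt$objective, bf$objective * 1.05)
  }
})

test_that("with no penalty each source solves the pure current-budget problem", {
  tp <- toy_problem(4, 5, seed = 23)
  gam0 <- rep(0, nrow(tp$A))
  opt <- optimize_interferential(tp$A, e = tp$e, gamma = gam0,
                                 config = optimizer_config(p_max = 1))
  lp_obj <- sum(tp$c_vec * interfield:::l1_lp(tp$c_vec, 1))
  expect_equal(opt$objective, 2 * lp_obj, tolerance = 1e-6)
})

test_that("two identical decoupled pairs give a symmetric optimum", {
  # electrodes 1,2 act only on voxel 1; electrodes 3,4 only on voxel 2;
  # both with identical geometry, target on the shared x direction
  A <- matrix(0, 6, 4)
  A[1, 1] <- 1; A[1, 2] <- -1   # voxel 1, x row
  A[4, 3] <- 1; A[4, 4] <- -1   # voxel 2, x row
  e <- numeric(6); e[1] <- 1; e[4] <- 1
  gam <- rep(0, 6)
  opt <- optimize_interferential(A, e = e, gamma = gam,
                                 config = optimizer_config(p_max = 10))
  o1 <- abs(sum(as.numeric(crossprod(A, e)) * as.numeric(opt$s1)))
  o2 <- abs(sum(as.numeric(crossprod(A, e)) * as.numeric(opt$s2)))
  expect_equal(o1, o2, tolerance = 1e-6)
  # objective equals twice the single-pair value (each pair spans 1 mA)
  expect_equal(opt$objective, 2 * 1, tolerance = 1e-6)
})

test_that("grand-optimal selection picks the first saturated point", {
  sw <- tibble::tibble(
    exponent = -1:2, p_max = 10^(-1:2),
    objective = c(1, 2, 3, 3), envelope_target = c(1, 2, 3, 3) / 10,
    focality_cm = 1:4, sum_abs_s1 = c(0.2, 0.7, 1.0, 1.0),
    sum_abs_s2 = c(0.2, 0.7, 1.0, 1.0),
    envelope_power = 1:4, valid = TRUE)
  class(sw) <- c("sweep_result", class(sw))
  expect_identical(select_grand_optimal(sw, optimizer_config()), 3L)
  sw$sum_abs_s1 <- rep(1, 4); sw$sum_abs_s2 <- rep(1, 4)
  expect_identical(select_grand_optimal(sw, optimizer_config()), 1L)
  sw$sum_abs_s1 <- rep(0.5, 4); sw$sum_abs_s2 <- rep(0.5, 4)
  expect_warning(last <- select_grand_optimal(sw, optimizer_config()),
                 "saturat")
  expect_identical(last, 4L)
  sw$valid <- FALSE
  expect_error(select_grand_optimal(sw, optimizer_config()), "empty")
})

test_that("sweeps on a small head are monotone and deterministic", {
  mh <- mini_leadfield()
  ts <- target_spec(mh$lf, c(0, 0, -6), name = "deep")
  cfg <- optimizer_config(sweep_exponents = -2:2)
  sw1 <- sweep_pmax(mh$lf, ts, cfg)
  expect_identical(nrow(sw1), 5L)
  expect_true(all(sw1$valid))
  obj <- sw1$objective
  expect_true(all(diff(obj) >= -1e-9 * max(obj)))
  cur <- pmin(sw1$sum_abs_s1, sw1$sum_abs_s2)
  expect_true(all(diff(cur) >= -1e-6))
  # repeat run: identical results (deterministic pipeline)
  sw2 <- sweep_pmax(mh$lf, ts, cfg)
  expect_identical(sw1$objective, sw2$objective)
  expect_identical(attr(sw1, "grand_optimal"), attr(sw2, "grand_optimal"))
})

test_that("the compiled polytope QP agrees with an interior-point solver", {
  # independent route: kernlab's interior-point QP on the split
  # formulation s = u - v, u, v >= 0
  set.seed(64)
  m <- 4
  lam <- 3
  M <- crossprod(matrix(rnorm(12 * m), 12, m))
  cv <- rnorm(m)
  H <- 2 * lam * M
  r <- interfield:::.polytope_qp(H, cv, 1, numeric(m), 20000, 1e-12)
  s_admm <- interfield:::clean_pattern(r$s, 1)
  obj_admm <- 0.5 * sum(s_admm * (H %*% s_admm)) - sum(cv * s_admm)
  H2 <- rbind(cbind(H, -H), cbind(-H, H)) + diag(1e-8 * sum(diag(H)), 2 * m)
  A2 <- rbind(c(rep(1, m), rep(-1, m)),  # zero net current
              rep(1, 2 * m))             # total absolute current
  ip <- kernlab::ipop(c = c(-cv, cv), H = H2, A = A2, b = c(0, 0),
                      l = rep(0, 2 * m), u = rep(1, 2 * m), r = c(0, 1),
                      sigf = 9)
  x <- kernlab::primal(ip)
  s_ip <- interfield:::clean_pattern(x[1:m] - x[(m + 1):(2 * m)], 1)
  obj_ip <- 0.5 * sum(s_ip * (H %*% s_ip)) - sum(cv * s_ip)
  scale <- max(abs(obj_admm), abs(obj_ip), 1e-12)
  expect_lt(abs(obj_admm - obj_ip) / scale, 1e-3)
  expect_lte(obj_admm, obj_ip + 1e-3 * scale)  # ADMM at least as good
})
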