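#' Optimizer configuration
#'
#' Tunables of the montage optimizations. `I_max` is the per-source
#' total-current budget in mA (zero-to-peak). `p_max` caps the
#' Gamma-weighted non-target field power ((V/m)^2 units); when `NULL` it is
#' taken from the target's closed-form default. `sweep_exponents` are the
#' decadic multipliers of the default power budget used by [sweep_pmax()].
#'
#' @param I_max Total absolute current per source, mA. Must be > 0.
#' @param p_max Non-target power cap; `NULL` = use `p_max0` of the target.
#' @param sweep_exponents Strictly increasing integer exponents; the sweep
#'   evaluates `p_max0 * 10^exponents`.
#' @param qp_tol,qp_max_iter Inner ADMM stopping tolerance and cap.
#' @param bisect_tol Relative tolerance on the power constraint when
#'   bisecting the quadratic-penalty multiplier.
#' @param max_rounds Alternating-majorization rounds for the two-source
#'   problem.
#' @param round_tol Relative objective improvement below which alternation
#'   stops.
#' @param polish_steps Bisection steps of the target-level polish stage of
#'   the two-source solver (0 disables it).
#' @param polish_rounds Joint minimum-power majorization rounds per polish
#'   step.
#' @param saturation_tol Fraction of `I_max` within which a source counts
#'   as current-saturated for grand-optimal selection.
#' @return An `optimizer_config` list.
#' @export
optimizer_config <- function(I_max = 1, p_max = NULL,
                             sweep_exponents = -3:5,
                             qp_tol = 1e-12, qp_max_iter = 3000,
                             bisect_tol = 1e-5,
                             max_rounds = 8, round_tol = 1e-4,
                             polish_steps = 8, polish_rounds = 3,
                             saturation_tol = 0.01) {
  if (!is.numeric(I_max) || I_max <= 0) {
    stop("I_max must be > 0 mA", call. = FALSE)
  }
  if (any(diff(sweep_exponents) <= 0)) {
    stop("sweep_exponents must be strictly increasing", call. = FALSE)
  }
  structure(list(I_max = I_max, p_max = p_max,
                 sweep_exponents = sweep_exponents,
                 qp_tol = qp_tol, qp_max_iter = qp_max_iter,
                 bisect_tol = bisect_tol, max_rounds = max_rounds,
                 round_tol = round_tol, polish_steps = polish_steps,
                 polish_rounds = polish_rounds,
                 saturation_tol = saturation_tol),
            class = "optimizer_config")
}

# exact maximizer of c's over {sum(s)=0, ||s||_1 <= I}: put +I/2 on the
# largest coefficient(s) and -I/2 on the smallest, splitting ties equally
l1_lp <- function(c_vec, I_max) {
  s <- numeric(length(c_vec))
  hi <- which(c_vec >= max(c_vec) - 1e-15 * max(1, abs(max(c_vec))))
  lo <- which(c_vec <= min(c_vec) + 1e-15 * max(1, abs(min(c_vec))))
  if (length(intersect(hi, lo)) > 0L) return(s)  # constant c: 0 is optimal
  s[hi] <- (I_max / 2) / length(hi)
  s[lo] <- -(I_max / 2) / length(lo)
  s
}

# exact cleanup: zero-sum then radial shrink onto the L1 ball
clean_pattern <- function(s, I_max) {
  s <- s - mean(s)
  a <- sum(abs(s))
  if (a > I_max && a > 0) s <- s * (I_max / a)
  s
}

# Single-source subproblem (small convex SOCP in s, dimension m):
#   maximize c's  s.t.  sum(s) = 0, ||s||_1 <= I, s' M s <= budget
# Solved by bisection on the multiplier of the quadratic: for each lambda
# the penalized problem max c's - lambda s'Ms over the polytope is a QP
# handled by the compiled ADMM; s'Ms is non-increasing in lambda, so the
# multiplier satisfying complementary slackness is found by bisection.
solve_l1qcqp <- function(M, c_vec, I_max, budget, cfg, warm = NULL,
                         lam0 = NULL) {
  m <- length(c_vec)
  zero <- list(s = numeric(m), objective = 0, quad = 0, lambda = Inf,
               iterations = 0L)
  qscale <- max(diag(M), 0)
  if (budget <= 1e-14 * max(qscale * I_max^2, 1e-30)) return(zero)

  s_lp <- l1_lp(c_vec, I_max)
  q_lp <- as.numeric(crossprod(s_lp, M %*% s_lp))
  if (q_lp <= budget * (1 + 1e-12)) {
    return(list(s = s_lp, objective = sum(c_vec * s_lp), quad = q_lp,
                lambda = 0, iterations = 0L))
  }

  warm0 <- if (is.null(warm)) numeric(m) else warm
  uw <- NULL  # dual warm start carried across the bisection
  qp <- function(lambda, w) {
    lambda <- min(lambda, 1e100)
    res <- .polytope_qp(2 * lambda * M + diag(1e-300, m), c_vec, I_max, w,
                        cfg$qp_max_iter, cfg$qp_tol, uw)
    uw <<- res$u
    s <- clean_pattern(res$s, I_max)
    if (!all(is.finite(s))) s <- numeric(m)
    list(s = s, quad = as.numeric(crossprod(s, M %*% s)),
         obj = sum(c_vec * s), iterations = res$iterations)
  }

  nM <- norm(M, "F")
  lam <- if (!is.null(lam0) && is.finite(lam0) && lam0 > 0) {
    min(lam0, 1e90)
  } else {
    min(max(sqrt(sum(c_vec^2)) / (2 * nM * I_max + 1e-300), 1e-12), 1e90)
  }
  r <- qp(lam, warm0)
  n_dbl <- 0L
  q_prev <- Inf
  while (r$quad > budget && n_dbl < 80L) {
    if (r$quad > q_prev * (1 - 1e-9)) break  # numerical plateau
    q_prev <- r$quad
    lam <- min(lam * 4, 1e100)
    r <- qp(lam, r$s)
    n_dbl <- n_dbl + 1L
    if (lam >= 1e100) break
  }
  if (r$quad > budget) {
    return(zero)  # quadratic cannot be met except at s = 0
  }
  lam_hi <- lam
  best <- r
  lam_lo <- lam_hi / 4
  # ensure lam_lo is infeasible (bracket) unless it already satisfies budget
  r_lo <- qp(lam_lo, best$s)
  while (r_lo$quad <= budget && lam_lo > 1e-14) {
    best <- if (r_lo$obj > best$obj) r_lo else best
    lam_hi <- lam_lo
    lam_lo <- lam_lo / 4
    r_lo <- qp(lam_lo, best$s)
  }
  for (i in seq_len(48L)) {
    lam_mid <- exp(0.5 * (log(lam_lo) + log(lam_hi)))
    r_mid <- qp(lam_mid, best$s)
    if (r_mid$quad <= budget) {
      lam_hi <- lam_mid
      if (r_mid$obj > best$obj) best <- r_mid
      if (r_mid$quad >= budget * (1 - cfg$bisect_tol)) break
    } else {
      lam_lo <- lam_mid
    }
    if (lam_hi / lam_lo < 1 + 1e-7) break
  }
  # feasible ascent polish: scale toward whichever constraint binds first
  s <- best$s
  if (best$obj > 0) {
    alpha <- min(I_max / max(sum(abs(s)), 1e-300),
                 sqrt(budget / max(best$quad, 1e-300)))
    if (is.finite(alpha) && alpha > 1) s <- s * alpha
  }
  s <- clean_pattern(s, I_max)
  quad <- as.numeric(crossprod(s, M %*% s))
  if (quad > budget) {
    s <- s * sqrt(budget / quad)
    quad <- as.numeric(crossprod(s, M %*% s))
  }
  list(s = s, objective = sum(c_vec * s), quad = quad,
       lambda = exp(0.5 * (log(lam_lo) + log(lam_hi))), iterations = best$iterations)
}

# Frontier companion of solve_l1qcqp: minimize s' M s subject to
# c's >= tau over the polytope, by walking the same lambda-parametrized
# Pareto frontier (s(lambda) maximizes c's - lambda s'Ms) until the
# objective meets tau, then shrinking radially onto c's = tau.
solve_min_power <- function(M, c_vec, I_max, tau, cfg, warm = NULL,
                            lam0 = NULL) {
  m <- length(c_vec)
  if (tau <= 0) {
    return(list(s = numeric(m), objective = 0, quad = 0, lambda = NA_real_))
  }
  s_lp <- l1_lp(c_vec, I_max)
  o_lp <- sum(c_vec * s_lp)
  if (o_lp < tau) return(NULL)  # tau unreachable
  uw <- NULL  # dual warm start carried across the bisection
  qp <- function(lambda, w) {
    lambda <- min(lambda, 1e100)
    res <- .polytope_qp(2 * lambda * M + diag(1e-300, m), c_vec, I_max, w,
                        cfg$qp_max_iter, cfg$qp_tol, uw)
    uw <<- res$u
    s <- clean_pattern(res$s, I_max)
    if (!all(is.finite(s))) s <- numeric(m)
    list(s = s, obj = sum(c_vec * s),
         quad = as.numeric(crossprod(s, M %*% s)))
  }
  warm0 <- if (is.null(warm)) s_lp else warm
  nM <- norm(M, "F")
  lam_lo <- if (!is.null(lam0) && is.finite(lam0) && lam0 > 0) {
    min(lam0, 1e90)
  } else {
    min(max(sqrt(sum(c_vec^2)) / (2 * nM * I_max + 1e-300), 1e-12) * 1e-3,
        1e90)
  }
  r_lo <- qp(lam_lo, warm0)
  while (r_lo$obj < tau && lam_lo > 1e-18) {
    lam_lo <- lam_lo / 16
    r_lo <- qp(lam_lo, r_lo$s)
  }
  if (r_lo$obj < tau) return(NULL)
  lam_hi <- lam_lo
  r_hi <- r_lo
  n_dbl <- 0L
  o_prev <- Inf
  while (r_hi$obj >= tau && n_dbl < 80L) {
    if (r_hi$obj > o_prev * (1 - 1e-9) && lam_hi >= 1e100) break
    o_prev <- r_hi$obj
    lam_hi <- min(lam_hi * 4, 1e100)
    r_hi <- qp(lam_hi, r_hi$s)
    n_dbl <- n_dbl + 1L
    if (lam_hi >= 1e100) break
  }
  best <- r_lo  # feasible side: obj >= tau
  for (i in seq_len(40L)) {
    lam_mid <- exp(0.5 * (log(lam_lo) + log(lam_hi)))
    r_mid <- qp(lam_mid, best$s)
    if (r_mid$obj >= tau) {
      lam_lo <- lam_mid
      if (r_mid$quad < best$quad) best <- r_mid
      if (r_mid$obj <= tau * (1 + 1e-5)) break
    } else {
      lam_hi <- lam_mid
    }
    if (lam_hi / lam_lo < 1 + 1e-7) break
  }
  s <- best$s * (tau / best$obj)  # exact objective, quadratically less power
  list(s = s, objective = sum(c_vec * s),
       quad = as.numeric(crossprod(s, M %*% s)),
       lambda = exp(0.5 * (log(lam_lo) + log(lam_hi))))
}

# shared pre-processing of (lead field, target) into optimizer ingredients.
# Bg holds the gamma^2-weighted per-voxel quadratic-form blocks: row v is
# the upper triangle of gv2_v * t(A_v) A_v (A_v = 3 x m block of voxel v),
# so any per-voxel reweighted matrix t(A) diag(w) A is a single
# matrix-vector product over Bg instead of a full crossprod over A.
opt_ingredients <- function(lf, target, e = NULL, gamma = NULL) {
  A <- if (inherits(lf, "lead_field")) lf$A else lf
  if (!is.null(target)) {
    stopifnot(inherits(target, "target_spec"))
    e <- target$e; gamma <- target$gamma
  }
  stopifnot(length(e) == nrow(A), length(gamma) == nrow(A))
  m <- ncol(A)
  n <- nrow(A) / 3L
  gv2 <- gamma[seq(1L, length(gamma), by = 3L)]^2
  rx <- seq(1L, 3L * n, by = 3L)
  Ax <- A[rx, , drop = FALSE]
  Ay <- A[rx + 1L, , drop = FALSE]
  Az <- A[rx + 2L, , drop = FALSE]
  ut <- which(upper.tri(diag(m), diag = TRUE), arr.ind = TRUE)
  u1 <- ut[, 1L]; u2 <- ut[, 2L]
  Bg <- (Ax[, u1, drop = FALSE] * Ax[, u2, drop = FALSE] +
         Ay[, u1, drop = FALSE] * Ay[, u2, drop = FALSE] +
         Az[, u1, drop = FALSE] * Az[, u2, drop = FALSE]) * gv2
  M_of <- function(t_v) {
    v <- as.numeric(crossprod(Bg, t_v))
    M <- matrix(0, m, m)
    M[cbind(ut[, 1L], ut[, 2L])] <- v
    M[cbind(ut[, 2L], ut[, 1L])] <- v
    M
  }
  list(A = A,
       c_vec = as.numeric(crossprod(A, e)),
       M = M_of(rep(1, n)),
       M_of = M_of,
       gv2 = gv2,
       e = e, gamma = gamma)
}

#' Optimize a single-source montage
#'
#' Maximizes the direction-projected field at the target,
#' `t(e) %*% A %*% s`, over electrode current patterns `s` that conserve
#' current (`sum(s) = 0`), respect the total-current budget
#' (`sum(|s|) <= I_max`), and cap the Gamma-weighted non-target field power
#' (`||Gamma A s||^2 <= P_max`). This is a small convex program (linear
#' objective, L1 polytope, one convex quadratic constraint); the returned
#' point satisfies its KKT conditions to solver tolerance.
#'
#' @param lf A `lead_field` (or plain N x m matrix).
#' @param target A [target_spec()], or supply `e` and `gamma` directly.
#' @param e,gamma Optional explicit weight/penalty vectors (length N).
#' @param config An [optimizer_config()]. `config$p_max` of `NULL` uses the
#'   target's `p_max0`.
#' @return An `if_opt` object: `s` ([current_pattern()]), `objective`
#'   (V/m), `power` (achieved `||Gamma A s||^2`), `p_max`, `sum_abs_s`,
#'   `feasible`, `diagnostics`.
#' @export
optimize_single_source <- function(lf, target = NULL, e = NULL, gamma = NULL,
                                   config = optimizer_config()) {
  ing <- opt_ingredients(lf, target, e, gamma)
  p_max <- config$p_max
  if (is.null(p_max)) {
    if (is.null(target)) stop("p_max not set and no target_spec supplied",
                              call. = FALSE)
    p_max <- target$p_max0
  }
  if (p_max <= 0) stop("P_max must be > 0", call. = FALSE)
  res <- solve_l1qcqp(ing$M, ing$c_vec, config$I_max, p_max, config)
  ids <- if (inherits(lf, "lead_field")) lf$electrode_ids else NULL
  s <- current_pattern(res$s, ids = ids, I_max = config$I_max, source = "single")
  structure(list(
    s = s, objective = res$objective, power = res$quad, p_max = p_max,
    sum_abs_s = sum(abs(res$s)),
    feasible = res$quad <= p_max * (1 + 1e-6),
    diagnostics = list(lambda = res$lambda, admm_iterations = res$iterations)
  ), class = "if_opt")
}

# per-voxel field norms for a pattern (no validation; internal)
voxel_norms <- function(A, s, n) {
  v <- as.numeric(A %*% s)
  dim(v) <- c(3L, n)
  sqrt(colSums(v^2))
}

# Gamma-weighted power of the interference envelope 2*min(||E1||,||E2||)
envelope_power_of <- function(nv1, nv2, gv2) {
  sum(gv2 * (2 * pmin(nv1, nv2))^2)
}

#' Optimize an interferential two-source montage
#'
#' Maximizes the interference envelope at the target,
#' `2 * min(t(e) A s1, t(e) A s2)`, over two electrode current patterns,
#' each zero-sum and L1-bounded by `I_max`, subject to the Gamma-weighted
#' envelope-power cap
#' `sum_v gamma_v^2 (2 min(||E1(v)||, ||E2(v)||))^2 <= P_max`.
#'
#' The envelope-power constraint is nonconvex (a voxelwise minimum of the
#' two field magnitudes). The solver uses a monotone alternating
#' majorization: since `min(a,b)^2 <= t a^2 + (1-t) b^2` for any
#' `t` in `[0,1]`, fixing per-voxel weights `t_v` yields a convex
#' single-source subproblem for each source that conservatively bounds the
#' true constraint; `t_v` is refreshed between rounds to charge each voxel
#' to whichever source currently has the smaller magnitude there. Every
#' iterate is feasible for the true constraint and the objective is
#' non-decreasing. Deterministic starting points (the symmetric
#' equal-budget solution, an asymmetric full-budget/zero split, and an
#' optional warm start) are run and the best result kept.
#'
#' @inheritParams optimize_single_source
#' @param init Optional warm start: list with elements `s1`, `s2`.
#' @param ing Precomputed ingredients from an earlier call on the same
#'   lead field and target (internal reuse across a sweep).
#' @param starts_mode `"full"` runs every deterministic starting point;
#'   `"lite"` runs only the warm/symmetric/asymmetric starts (used for
#'   warm-started sweep points).
#' @return An `if_opt` object with `s1`, `s2` ([current_pattern()]s),
#'   `objective` (V/m), `envelope_power`, `p_max`, `sum_abs_s1`,
#'   `sum_abs_s2`, `feasible`, `diagnostics`.
#' @export
optimize_interferential <- function(lf, target = NULL, e = NULL, gamma = NULL,
                                    config = optimizer_config(), init = NULL,
                                    ing = NULL,
                                    starts_mode = c("full", "lite")) {
  starts_mode <- match.arg(starts_mode)
  if (is.null(ing)) ing <- opt_ingredients(lf, target, e, gamma)
  p_max <- config$p_max
  if (is.null(p_max)) {
    if (is.null(target)) stop("p_max not set and no target_spec supplied",
                              call. = FALSE)
    p_max <- target$p_max0
  }
  if (p_max <= 0) stop("P_max must be > 0", call. = FALSE)
  A <- ing$A; c_vec <- ing$c_vec; M <- ing$M; gv2 <- ing$gv2
  M_of <- ing$M_of
  n <- nrow(A) / 3L
  I_max <- config$I_max

  # one convex subproblem: re-optimize source k with per-voxel weights t_v
  # charging each voxel's envelope contribution to this source (t_v = 1) or
  # bounding it by the other source's current magnitude (t_v = 0).
  # lam_cache carries each source's frontier multiplier between calls as a
  # warm bracket for the inner bisection.
  lam_cache <- new.env(parent = emptyenv())
  update_source <- function(sk, other_nv, t_v, key = "s") {
    Mk <- 4 * M_of(t_v)
    R <- sum(4 * gv2 * (1 - t_v) * other_nv^2)
    budget <- max(p_max - R, 0)
    res <- solve_l1qcqp(Mk, c_vec, I_max, budget, config, warm = sk,
                        lam0 = lam_cache[[key]])
    if (is.finite(res$lambda) && res$lambda > 0) lam_cache[[key]] <- res$lambda
    res$s
  }

  refine <- function(s1, s2, soft = FALSE, rounds = config$max_rounds) {
    obj <- 2 * min(sum(c_vec * s1), sum(c_vec * s2))
    best <- list(s1 = s1, s2 = s2, objective = obj)
    obj_prev <- obj
    stall <- 0L
    for (round in seq_len(rounds)) {
      # update the currently weaker (binding) source first
      ord <- if (sum(c_vec * s1) <= sum(c_vec * s2)) 1:2 else 2:1
      for (k in ord) {
        nv1 <- voxel_norms(A, s1, n)
        nv2 <- voxel_norms(A, s2, n)
        mine <- if (k == 1L) nv1 else nv2
        other <- if (k == 1L) nv2 else nv1
        t_v <- if (soft) {
          # softened weights: a valid (conservative) convex combination that
          # loosens the binding voxels and helps escape coordinate optima
          other^2 / (mine^2 + other^2 + 1e-300)
        } else {
          ifelse(mine < other, 1, ifelse(mine > other, 0, 0.5))
        }
        sk <- update_source(if (k == 1L) s1 else s2, other, t_v,
                            key = paste0("s", k))
        # keep the update only if it does not lose objective to solver noise
        if (sum(c_vec * sk) >= sum(c_vec * (if (k == 1L) s1 else s2)) - 1e-12) {
          if (k == 1L) s1 <- sk else s2 <- sk
        }
      }
      # balance pass: the stronger source retreats along its Pareto
      # frontier to the weaker one's objective, freeing envelope budget
      # that the weaker source then reclaims
      o1 <- sum(c_vec * s1); o2 <- sum(c_vec * s2)
      if (round %% 2L == 0L &&
          abs(o1 - o2) > 1e-3 * max(abs(o1), abs(o2), 1e-12)) {
        ks <- if (o1 > o2) 1L else 2L
        tau <- min(o1, o2)
        nv1 <- voxel_norms(A, s1, n)
        nv2 <- voxel_norms(A, s2, n)
        mine <- if (ks == 1L) nv1 else nv2
        other <- if (ks == 1L) nv2 else nv1
        t_v <- ifelse(mine < other, 1, ifelse(mine > other, 0, 0.5))
        Mk <- 4 * M_of(t_v)
        mp <- solve_min_power(Mk, c_vec, I_max, tau, config,
                              warm = if (ks == 1L) s1 else s2,
                              lam0 = lam_cache[[paste0("mp", ks)]])
        if (!is.null(mp) && isTRUE(is.finite(mp$lambda)) && isTRUE(mp$lambda > 0)) {
          lam_cache[[paste0("mp", ks)]] <- mp$lambda
        }
        if (!is.null(mp) && mp$quad <= as.numeric(
              crossprod(if (ks == 1L) s1 else s2,
                        Mk %*% (if (ks == 1L) s1 else s2))) + 1e-15) {
          if (ks == 1L) s1 <- mp$s else s2 <- mp$s
          # regrow the weaker source with the freed budget
          kw <- 3L - ks
          nv1 <- voxel_norms(A, s1, n)
          nv2 <- voxel_norms(A, s2, n)
          mine <- if (kw == 1L) nv1 else nv2
          other <- if (kw == 1L) nv2 else nv1
          t_w <- ifelse(mine < other, 1, ifelse(mine > other, 0, 0.5))
          sw <- update_source(if (kw == 1L) s1 else s2, other, t_w,
                              key = paste0("s", kw))
          if (sum(c_vec * sw) >= sum(c_vec * (if (kw == 1L) s1 else s2)) - 1e-12) {
            if (kw == 1L) s1 <- sw else s2 <- sw
          }
        }
      }
      obj_new <- 2 * min(sum(c_vec * s1), sum(c_vec * s2))
      if (obj_new > best$objective) {
        best <- list(s1 = s1, s2 = s2, objective = obj_new)
      }
      if (obj_new - obj_prev <= config$round_tol * max(abs(obj_prev), 1e-12)) {
        stall <- stall + 1L
        if (stall >= 2L) break
      } else stall <- 0L
      obj_prev <- obj_new
    }
    best
  }

  run_start <- function(s1, s2, rounds = config$max_rounds) {
    # scale a possibly infeasible seed pair onto the true constraint
    ep <- envelope_power_of(voxel_norms(A, s1, n), voxel_norms(A, s2, n), gv2)
    if (ep > p_max) {
      al <- sqrt(p_max / ep)
      s1 <- s1 * al; s2 <- s2 * al
    }
    refine(s1, s2, rounds = rounds)
  }
  continue_soft <- function(r1) {
    r1b <- refine(r1$s1, r1$s2)              # full-depth tightening
    if (r1b$objective > r1$objective) r1 <- r1b
    r2 <- refine(r1$s1, r1$s2, soft = TRUE)  # escape pass
    r3 <- refine(r2$s1, r2$s2)               # tighten again
    rs <- list(r1, r2, r3)
    rs[[which.max(vapply(rs, function(x) x$objective, numeric(1)))]]
  }

  m_el <- length(c_vec)
  starts <- list()
  # symmetric start: the equal-budget surrogate (t = 1/2 everywhere), i.e.
  # 4 ||Gamma A s||^2 <= P per source, which satisfies the true constraint
  sym <- solve_l1qcqp(M, c_vec, I_max, p_max / 4, config)
  starts$symmetric <- list(sym$s, sym$s)
  # asymmetric start: one full-budget source against a silent partner
  asy <- solve_l1qcqp(M, c_vec, I_max, p_max, config)
  starts$asymmetric <- list(asy$s, numeric(m_el))
  # disjoint-support start: best L1 vertex pair on complementary electrodes
  lp1 <- l1_lp(c_vec, I_max)
  used <- which(lp1 != 0)
  if (length(used) < m_el - 1L) {
    c_rest <- c_vec
    c_rest[used] <- NA
    free <- which(!is.na(c_rest))
    lp2 <- numeric(m_el)
    lp2_free <- l1_lp(c_vec[free], I_max)
    lp2[free] <- lp2_free
    if (any(lp2 != 0)) starts$disjoint <- list(lp1, lp2)
  }
  # spatial-partition starts: charge the envelope budget to complementary
  # halves of the penalty region (split along each axis through the target
  # and by voxel parity) and give each source half the power budget
  vi <- if (inherits(lf, "lead_field")) lf$voxel_index else NULL
  part_seed <- function(t_v) {
    sa <- solve_l1qcqp(4 * M_of(t_v), c_vec, I_max, p_max / 2, config)$s
    sb <- solve_l1qcqp(4 * M_of(1 - t_v), c_vec, I_max, p_max / 2, config)$s
    if (any(sa != 0) && any(sb != 0)) list(sa, sb) else NULL
  }
  if (!is.null(vi)) {
    tgt_idx <- if (!is.null(target)) vi[target$target_row, ] else
      round(colMeans(vi))
    for (ax in 1:3) {
      nm <- paste0("split_", c("x", "y", "z")[ax])
      starts[[nm]] <- part_seed(as.numeric(vi[, ax] >= tgt_idx[ax]))
    }
  }
  starts$split_parity <- part_seed(as.numeric(seq_len(n) %% 2L == 0L))
  # vertex-pair starts: the strongest bipolar patterns paired up
  vert_obj <- outer(c_vec, c_vec, `-`)  # objective of vertex (i+, j-)
  diag(vert_obj) <- -Inf
  topk <- order(vert_obj, decreasing = TRUE)[seq_len(min(3L, m_el * (m_el - 1L)))]
  verts <- lapply(topk, function(ij) {
    i <- (ij - 1L) %% m_el + 1L; j <- (ij - 1L) %/% m_el + 1L
    v <- numeric(m_el); v[i] <- I_max / 2; v[j] <- -I_max / 2; v
  })
  if (length(verts) >= 2L) {
    for (a in 1:(length(verts) - 1L)) {
      for (b in (a + 1L):length(verts)) {
        starts[[paste0("vertices_", a, b)]] <- list(verts[[a]], verts[[b]])
      }
    }
  }
  if (!is.null(init)) starts$warm <- list(as.numeric(init$s1), as.numeric(init$s2))
  if (identical(starts_mode, "lite")) {
    keep <- intersect(c("warm", "symmetric", "asymmetric"), names(starts))
    if (length(keep)) starts <- starts[keep]
  }
  starts <- purrr::compact(starts)
  # triage: a shallow pass over every start, full refinement and the
  # soft-escape continuation only for the most promising candidates
  cand <- purrr::map(starts, function(st) run_start(st[[1L]], st[[2L]],
                                                    rounds = 2L))
  sc <- vapply(cand, function(x) x$objective, numeric(1))
  for (i in order(sc, decreasing = TRUE)[seq_len(min(2L, length(cand)))]) {
    cand[[i]] <- continue_soft(cand[[i]])
  }
  best <- cand[[which.max(vapply(cand, function(x) x$objective, numeric(1)))]]

  # polish stage: bisection on the achievable target level tau. For fixed
  # tau, alternately minimize each source's charged envelope power subject
  # to c's >= tau (joint minimum-power majorization); tau is raised while
  # the minimized true envelope power stays within P_max.
  polish_lam <- new.env(parent = emptyenv())
  min_power_pair <- function(tau, s1, s2, rounds) {
    for (r in seq_len(rounds)) {
      nv1 <- voxel_norms(A, s1, n)
      nv2 <- voxel_norms(A, s2, n)
      t_v <- ifelse(nv1 < nv2, 1, ifelse(nv1 > nv2, 0, 0.5))
      for (k in 1:2) {
        tk <- if (k == 1L) t_v else 1 - t_v
        Mk <- 4 * M_of(tk)
        key <- paste0("p", k)
        mp <- solve_min_power(Mk, c_vec, I_max, tau, config,
                              warm = if (k == 1L) s1 else s2,
                              lam0 = polish_lam[[key]])
        if (is.null(mp)) return(NULL)
        if (isTRUE(is.finite(mp$lambda)) && isTRUE(mp$lambda > 0)) {
          polish_lam[[key]] <- mp$lambda
        }
        if (k == 1L) s1 <- mp$s else s2 <- mp$s
        nv1 <- voxel_norms(A, s1, n)
        nv2 <- voxel_norms(A, s2, n)
        t_v <- ifelse(nv1 < nv2, 1, ifelse(nv1 > nv2, 0, 0.5))
      }
    }
    list(s1 = s1, s2 = s2,
         power = envelope_power_of(voxel_norms(A, s1, n),
                                   voxel_norms(A, s2, n), gv2))
  }
  if (config$polish_steps > 0L) {
    tau_lo <- best$objective / 2
    tau_hi <- sum(c_vec * l1_lp(c_vec, I_max))
    if (tau_hi > tau_lo * (1 + 1e-9)) {
      cur <- best
      for (i in seq_len(config$polish_steps)) {
        tau <- 0.5 * (tau_lo + tau_hi)
        r <- min_power_pair(tau, cur$s1, cur$s2, config$polish_rounds)
        if (!is.null(r) && r$power <= p_max * (1 + 1e-9)) {
          tau_lo <- tau
          cur <- list(s1 = r$s1, s2 = r$s2,
                      objective = 2 * min(sum(c_vec * r$s1), sum(c_vec * r$s2)))
        } else {
          tau_hi <- tau
        }
      }
      if (cur$objective > best$objective) best <- cur
    }
  }

  nv1 <- voxel_norms(A, best$s1, n)
  nv2 <- voxel_norms(A, best$s2, n)
  env_pow <- envelope_power_of(nv1, nv2, gv2)
  ids <- if (inherits(lf, "lead_field")) lf$electrode_ids else NULL
  structure(list(
    s1 = current_pattern(best$s1, ids = ids, I_max = I_max, source = "s1"),
    s2 = current_pattern(best$s2, ids = ids, I_max = I_max, source = "s2"),
    objective = best$objective,
    envelope_power = env_pow, p_max = p_max,
    sum_abs_s1 = sum(abs(best$s1)), sum_abs_s2 = sum(abs(best$s2)),
    feasible = env_pow <= p_max * (1 + 1e-6),
    diagnostics = list(n_candidates = length(cand))
  ), class = "if_opt")
}

#' @export
print.if_opt <- function(x, ...) {
  if (!is.null(x$s1)) {
    cat(sprintf(
      "<if_opt: interferential> objective = %.4g V/m, envelope power = %.4g / P_max %.4g, sum|s1| = %.4g, sum|s2| = %.4g mA\n",
      x$objective, x$envelope_power, x$p_max, x$sum_abs_s1, x$sum_abs_s2))
  } else {
    cat(sprintf(
      "<if_opt: single source> objective = %.4g V/m, power = %.4g / P_max %.4g, sum|s| = %.4g mA\n",
      x$objective, x$power, x$p_max, x$sum_abs_s))
  }
  invisible(x)
}

#' Sweep the non-target power budget
#'
#' Runs the interferential optimization for `p_max0 * 10^k` over the
#' configured exponents (default -3..5, nine points), recording the
#' objective, the envelope value and the half-value-volume focality at the
#' target, and the per-source total currents. Each point is warm-started
#' from the previous one, which makes the recorded objective non-decreasing
#' along the sweep. Failures at individual points are caught, marked
#' invalid, and the sweep continues.
#'
#' @inheritParams optimize_interferential
#' @param target A [target_spec()] (required: supplies `p_max0` and the
#'   target voxel for focality).
#' @return A `sweep_result`: tibble with columns `exponent`, `p_max`,
#'   `objective`, `envelope_target`, `focality_cm`, `sum_abs_s1`,
#'   `sum_abs_s2`, `envelope_power`, `valid`; attributes `results` (list of
#'   `if_opt`), `target`, `config`, `grand_optimal` (index, filled by
#'   [select_grand_optimal()]).
#' @export
sweep_pmax <- function(lf, target, config = optimizer_config()) {
  stopifnot(inherits(target, "target_spec"))
  p0 <- target$p_max0
  exps <- config$sweep_exponents
  rows <- vector("list", length(exps))
  results <- vector("list", length(exps))
  ing <- opt_ingredients(lf, target)
  A <- if (inherits(lf, "lead_field")) lf$A else lf
  n <- nrow(A) / 3L
  vol <- if (inherits(lf, "lead_field")) lf$voxel_volume_mm3 else NULL
  na_row <- function(i) tibble::tibble(
    exponent = exps[i], p_max = p0 * 10^exps[i], objective = NA_real_,
    envelope_target = NA_real_, focality_cm = NA_real_,
    sum_abs_s1 = NA_real_, sum_abs_s2 = NA_real_,
    envelope_power = NA_real_, valid = FALSE)
  run_point <- function(i, init, mode) {
    cfg_i <- config
    cfg_i$p_max <- p0 * 10^exps[i]
    if (!identical(mode, "full")) {
      # warm-chained points refine an already good solution: cap the effort
      cfg_i$polish_steps <- min(cfg_i$polish_steps, 4L)
      cfg_i$max_rounds <- min(cfg_i$max_rounds, 5L)
    }
    tryCatch(
      optimize_interferential(lf, target, config = cfg_i, init = init,
                              ing = ing, starts_mode = mode),
      error = function(err) err)
  }
  record <- function(i, res) {
    if (inherits(res, "error")) {
      rows[[i]] <<- na_row(i)
      return(NULL)
    }
    nv1 <- voxel_norms(A, as.numeric(res$s1), n)
    nv2 <- voxel_norms(A, as.numeric(res$s2), n)
    env <- 2 * pmin(nv1, nv2)
    foc <- if (!is.null(vol)) {
      focality_half_value(env, target$target_row, vol)$F_cm
    } else NA_real_
    rows[[i]] <<- tibble::tibble(
      exponent = exps[i], p_max = p0 * 10^exps[i], objective = res$objective,
      envelope_target = env[target$target_row], focality_cm = foc,
      sum_abs_s1 = res$sum_abs_s1, sum_abs_s2 = res$sum_abs_s2,
      envelope_power = res$envelope_power, valid = TRUE)
    results[[i]] <<- res
    list(s1 = as.numeric(res$s1), s2 = as.numeric(res$s2))
  }
  # anchor the sweep at the central budget, then move outward. Downward,
  # the optimum approaches a fixed shape scaled to the shrinking budget, so
  # warm-chained lite solves suffice (and the full-start search is at its
  # most expensive there). Upward, the optimum changes quickly as the power
  # constraint loosens, and the full deterministic start set is cheap in
  # that regime, so every point from the anchor up runs the full search
  # (with the previous point's solution among its warm starts).
  i0 <- which.min(abs(exps))
  anchor <- record(i0, run_point(i0, NULL, "full"))
  prev <- anchor
  if (i0 > 1L) for (i in seq(i0 - 1L, 1L)) {
    prev <- record(i, run_point(i, prev, "lite"))
    if (is.null(prev) && i < length(exps)) prev <- anchor
  }
  prev <- anchor
  if (i0 < length(exps)) for (i in seq(i0 + 1L, length(exps))) {
    prev <- record(i, run_point(i, prev, "full"))
    if (is.null(prev)) prev <- anchor
  }
  # monotonicity repair: a feasible point at a smaller budget is feasible at
  # a larger one, so re-run any point that fell below its predecessor,
  # seeded with the predecessor's solution
  for (i in seq_along(exps)[-1L]) {
    if (is.null(results[[i]]) || is.null(results[[i - 1L]])) next
    if (rows[[i]]$objective < rows[[i - 1L]]$objective * (1 - 1e-9)) {
      init <- list(s1 = as.numeric(results[[i - 1L]]$s1),
                   s2 = as.numeric(results[[i - 1L]]$s2))
      res2 <- run_point(i, init, "full")
      if (!inherits(res2, "error") &&
          res2$objective > rows[[i]]$objective) {
        record(i, res2)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- structure(out, results = results, target = target, config = config,
                   class = c("sweep_result", class(out)))
  attr(out, "grand_optimal") <- tryCatch(select_grand_optimal(out, config),
                                         error = function(err) NA_integer_)
  out
}

#' Select the grand-optimal sweep point
#'
#' The grand-optimal configuration is the solution at the lowest power
#' budget for which the total absolute current of both sources has reached
#' the budget `I_max` (within `saturation_tol`). If no sweep point
#' saturates, the last valid point is returned with a warning.
#'
#' @param sweep A `sweep_result` from [sweep_pmax()].
#' @param config The [optimizer_config()] (for `I_max` and
#'   `saturation_tol`); defaults to the sweep's own config.
#' @return Integer index into the sweep rows.
#' @export
select_grand_optimal <- function(sweep, config = NULL) {
  if (is.null(config)) config <- attr(sweep, "config")
  if (is.null(config)) config <- optimizer_config()
  valid <- which(sweep$valid)
  if (length(valid) == 0L) stop("empty sweep: no valid points", call. = FALSE)
  thr <- (1 - config$saturation_tol) * config$I_max
  is_sat <- sweep$sum_abs_s1[valid] >= thr & sweep$sum_abs_s2[valid] >= thr
  # the budget at which the currents have *reached* their maximum: the
  # earliest point from which every later valid point is also saturated
  # (an isolated early saturation is solver noise, not the knee)
  persistent <- rev(cumprod(rev(is_sat))) > 0
  if (any(persistent)) return(valid[which(persistent)[1L]])
  warning("no sweep point saturates the current budget; returning the last valid point",
          call. = FALSE)
  valid[length(valid)]
}
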