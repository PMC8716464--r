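# Independent brute-force oracles and toy problem builders for the
# optimizer tests. The oracles enumerate discretized zero-sum L1 balls and
# never call the package's solvers.

# toy targeting problem: m electrodes, n brain voxels, synthetic lead field
toy_problem <- function(m, n, seed, sd = 0.1) {
  set.seed(seed)
  A <- matrix(rnorm(3 * n * m, sd = sd), 3 * n, m)
  e <- numeric(3 * n)
  e[1] <- 1  # target = voxel 1, x direction
  gam <- rep(c(0, rep(1, n - 1)), each = 3)  # no penalty at the target voxel
  list(A = A, e = e, gamma = gam,
       gv2 = gam[seq(1, length(gam), 3)]^2,
       c_vec = as.numeric(crossprod(A, e)),
       n = n, m = m)
}

# grid of zero-sum patterns with sum|s| <= I_max for m electrodes
# (the last electrode carries minus the sum of the free ones)
zero_sum_grid <- function(m, I_max, npts, lim = I_max / 2) {
  gr <- seq(-lim, lim, length.out = npts)
  free <- do.call(expand.grid, rep(list(gr), m - 1L))
  S <- cbind(as.matrix(free), -rowSums(free))
  dimnames(S) <- NULL
  S[rowSums(abs(S)) <= I_max + 1e-12, , drop = FALSE]
}

# single-source oracle: max c's s.t. zero-sum, L1 <= I, s'Ms <= P
brute_single <- function(tp, P, I_max = 1, npts = 201) {
  S <- zero_sum_grid(tp$m, I_max, npts)
  M <- crossprod(tp$A * tp$gamma)
  quad <- rowSums((S %*% M) * S)
  obj <- as.numeric(S %*% tp$c_vec)
  feas <- quad <= P * (1 + 1e-9)
  max(obj[feas])
}

# per-candidate voxel field norms (n x K)
cand_norms <- function(tp, S) {
  F <- tp$A %*% t(S)
  matrix(sqrt(colSums(matrix(F^2, nrow = 3))), tp$n, ncol(F))
}

# two-source interferential oracle with objective-ordered pruning:
# maximize 2*min(c's1, c's2) under the true envelope-power constraint
brute_if_grid <- function(tp, P, S, I_max = 1) {
  obj <- as.numeric(S %*% tp$c_vec)
  NV <- cand_norms(tp, S)
  ord <- order(obj, decreasing = TRUE)
  best <- -Inf; bi <- NA; bj <- NA
  for (oi in seq_along(ord)) {
    i <- ord[oi]
    if (2 * obj[i] <= best) break
    mn <- pmin(NV, NV[, i])
    lhs <- 4 * colSums(tp$gv2 * mn^2)
    feas <- which(lhs <= P * (1 + 1e-9))
    if (!length(feas)) next
    j <- feas[which.max(obj[feas])]
    val <- 2 * min(obj[i], obj[j])
    if (val > best) { best <- val; bi <- i; bj <- j }
  }
  list(objective = best, s1 = S[bi, ], s2 = S[bj, ])
}

# two-stage interferential oracle: coarse global grid, then a fine local
# grid around the coarse argmax (each source independently)
brute_if <- function(tp, P, I_max = 1, npts = 41, refine_pts = 9,
                     refine_span = 2) {
  S <- zero_sum_grid(tp$m, I_max, npts)
  coarse <- brute_if_grid(tp, P, S, I_max)
  h <- I_max / (npts - 1)  # coarse step
  local_grid <- function(s0) {
    delta <- seq(-refine_span * h, refine_span * h, length.out = refine_pts)
    free <- do.call(expand.grid, rep(list(delta), tp$m - 1L))
    Sl <- cbind(as.matrix(free), -rowSums(free))
    Sl <- sweep(Sl, 2L, s0, `+`)
    dimnames(Sl) <- NULL
    Sl[rowSums(abs(Sl)) <= I_max + 1e-12, , drop = FALSE]
  }
  S2 <- unique(rbind(local_grid(coarse$s1), local_grid(coarse$s2)))
  fine <- brute_if_grid(tp, P, S2, I_max)
  if (fine$objective >= coarse$objective) fine else coarse
}
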