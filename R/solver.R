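#' Solver configuration for the quasi-static forward problem
#'
#' @param tol Relative residual tolerance for the iterative solver.
#' @param max_iter Iteration cap for conjugate gradients.
#' @param method `"auto"` (sparse Cholesky for systems up to
#'   `direct_limit` unknowns, conjugate gradients above), `"direct"`, or
#'   `"pcg"` (Jacobi-preconditioned conjugate gradients; deterministic,
#'   zero initialization).
#' @param direct_limit Unknown-count threshold for `"auto"`.
#' @return A `solver_config` list.
#' @export
solver_config <- function(tol = 1e-8, max_iter = 10000,
                          method = c("auto", "direct", "pcg"),
                          direct_limit = 150000) {
  method <- match.arg(method)
  stopifnot(tol > 0, max_iter >= 1)
  structure(list(tol = tol, max_iter = max_iter, method = method,
                 direct_limit = direct_limit), class = "solver_config")
}

# Conservative 7-point finite-volume discretization of div(sigma grad phi) = 0.
# Face conductivities are harmonic means of the adjacent voxel conductivities,
# which keeps fluxes exact across sharp conductivity jumps. Units: sigma S/m,
# voxel edge h in mm -> face conductance g = sigma_face * h * 1e-3 siemens.
build_forward_system <- function(grid, sigma = NULL) {
  if (is.null(sigma)) sigma <- grid$sigma
  d <- grid$dim
  cond <- sigma > 0
  n_c <- sum(cond)
  if (n_c == 0L) stop("no conductive voxels", call. = FALSE)
  map <- array(0L, d)
  map[cond] <- seq_len(n_c)

  h_m <- grid$voxel_size * 1e-3
  ii <- integer(0); jj <- integer(0); gg <- numeric(0)
  for (axis in 1:3) {
    n <- d[axis]
    sl_a <- lapply(d, seq_len); sl_b <- sl_a
    sl_a[[axis]] <- seq_len(n - 1L)
    sl_b[[axis]] <- 2:n
    s1 <- sigma[sl_a[[1]], sl_a[[2]], sl_a[[3]]]
    s2 <- sigma[sl_b[[1]], sl_b[[2]], sl_b[[3]]]
    m1 <- map[sl_a[[1]], sl_a[[2]], sl_a[[3]]]
    m2 <- map[sl_b[[1]], sl_b[[2]], sl_b[[3]]]
    ok <- s1 > 0 & s2 > 0
    if (!any(ok)) next
    g <- 2 * s1[ok] * s2[ok] / (s1[ok] + s2[ok]) * h_m
    ii <- c(ii, m1[ok]); jj <- c(jj, m2[ok]); gg <- c(gg, g)
  }
  L <- Matrix::sparseMatrix(
    i = c(ii, jj), j = c(jj, ii), x = c(-gg, -gg),
    dims = c(n_c, n_c)
  )
  diag_val <- as.numeric(Matrix::rowSums(-L))
  L <- L + Matrix::Diagonal(n_c, diag_val)
  conn <- connected_to(map, d, which.max(cond))
  list(L = L, map = map, cond = cond, n = n_c, dims = d,
       h_m = h_m, diag = diag_val, conn = conn, cache = new.env(parent = emptyenv()))
}

# BFS connectivity from a seed voxel over the conductive 6-neighbour graph,
# used to detect a disconnected conductive domain before solving.
connected_to <- function(map, d, seed_lin) {
  n_c <- max(map)
  # neighbour offsets in linear indexing
  offs <- c(1L, -1L, d[1L], -d[1L], d[1L] * d[2L], -d[1L] * d[2L])
  cond_lin <- which(map > 0L)
  pos <- array(FALSE, d); pos[cond_lin] <- TRUE
  visited <- array(FALSE, d)
  frontier <- seed_lin
  visited[seed_lin] <- TRUE
  total <- length(cond_lin)
  nvis <- 1L
  di <- d[1L]; dij <- d[1L] * d[2L]
  while (length(frontier) > 0L && nvis < total) {
    nxt <- integer(0)
    for (o in offs) {
      cand <- frontier + o
      cand <- cand[cand >= 1L & cand <= prod(d)]
      # guard against wrap-around across rows/planes
      if (o == 1L)  cand <- cand[((cand - 1L) %% di) != 0L]
      if (o == -1L) cand <- cand[(cand %% di) != 0L]
      if (abs(o) == di) {
        keep <- ((cand - 1L) %/% di) %% d[2L]
        ref  <- ((cand - o - 1L) %/% di) %% d[2L]
        cand <- cand[abs(keep - ref) == 1L]
      }
      cand <- cand[pos[cand] & !visited[cand]]
      if (length(cand)) {
        visited[cand] <- TRUE
        nvis <- nvis + length(cand)
        nxt <- c(nxt, cand)
      }
    }
    frontier <- unique(nxt)
  }
  nvis == total
}

# Jacobi-preconditioned conjugate gradients; deterministic (x0 = 0).
pcg_solve <- function(L, b, diag_L, tol, max_iter) {
  n <- length(b)
  x <- numeric(n)
  r <- b
  Minv <- 1 / diag_L
  z <- Minv * r
  p <- z
  rz <- sum(r * z)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(list(x = x, iter = 0L, rel_residual = 0))
  for (it in seq_len(max_iter)) {
    Ap <- as.numeric(L %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    res <- sqrt(sum(r^2)) / bnorm
    if (res <= tol) {
      return(list(x = x, iter = it, rel_residual = res))
    }
    z <- Minv * r
    rz_new <- sum(r * z)
    beta <- rz_new / rz
    rz <- rz_new
    p <- z + beta * p
  }
  stop(sprintf(
    "forward solver did not converge: relative residual %.3e after %d iterations",
    res, max_iter), call. = FALSE)
}

#' Solve the quasi-static potential for arbitrary current sources
#'
#' Low-level entry point: injects the given currents (mA) at the given
#' voxels of the conductive domain and solves the conservative
#' finite-volume discretization of the Laplace problem
#' `div(sigma grad phi) = 0` with pure Neumann (insulating) outer
#' boundaries. Currents must sum to zero. The gauge is fixed so that the
#' potential averages to zero over `gauge_voxels` (if given), else over the
#' injection voxels.
#'
#' @param grid A `labeled_grid`.
#' @param voxels Linear voxel indices of the sources.
#' @param currents_mA Currents in mA at those voxels (must sum to 0 within
#'   1e-9).
#' @param sigma Optional conductivity array overriding `grid$sigma`
#'   (used for epicranial insulation).
#' @param gauge_voxels Optional linear voxel indices over which the mean
#'   potential is set to zero.
#' @param config A [solver_config()].
#' @param system Optional precomputed system from an earlier call (field
#'   `system` of a previous result), reused to avoid reassembly.
#' @return A `potential_field` list: `phi` (array, volts, `NA` outside the
#'   conductive domain), `E` (4-d array, V/m, components x,y,z; field is
#'   `-grad(phi)`), `iterations`, `rel_residual`, `system`.
#' @export
solve_current_sources <- function(grid, voxels, currents_mA, sigma = NULL,
                                  gauge_voxels = NULL,
                                  config = solver_config(), system = NULL) {
  stopifnot(inherits(grid, "labeled_grid"), length(voxels) == length(currents_mA))
  if (abs(sum(currents_mA)) > 1e-9) {
    stop("source currents must sum to zero (charge conservation)", call. = FALSE)
  }
  if (is.null(system)) system <- build_forward_system(grid, sigma)
  if (!system$conn) {
    stop("disconnected conductive domain: the forward problem is ill-posed",
         call. = FALSE)
  }
  uidx <- system$map[voxels]
  if (any(uidx == 0L)) stop("a source voxel lies outside the conductive domain",
                            call. = FALSE)
  b <- numeric(system$n)
  b[uidx] <- b[uidx] + currents_mA * 1e-3
  b <- b - sum(b) / system$n  # exact discrete compatibility
  if (all(b == 0)) {
    phi <- array(NA_real_, system$dims)
    phi[system$cond] <- 0
    E <- array(0, c(system$dims, 3L))
    return(structure(list(phi = phi, E = E, iterations = 0L,
                          rel_residual = 0, system = system),
                     class = "potential_field"))
  }

  n <- system$n
  use_direct <- switch(config$method,
                       direct = TRUE, pcg = FALSE,
                       auto = n <= config$direct_limit)
  # pin one unknown: L + e_k e_k^T is SPD and, because sum(b) = 0, its
  # solution solves the original singular system exactly with phi_k = 0.
  # The pin is a fixed node so the factorization is shared across solves.
  k <- 1L
  scale <- mean(system$diag)
  if (use_direct) {
    ch <- system$cache$chol
    if (is.null(ch)) {
      Lp <- system$L
      Lp[k, k] <- Lp[k, k] + scale
      ch <- Matrix::Cholesky(Matrix::forceSymmetric(Lp), LDL = FALSE,
                             super = TRUE)
      system$cache$chol <- ch
    }
    x <- as.numeric(Matrix::solve(ch, b))
    res <- sqrt(sum((as.numeric(system$L %*% x) - b)^2)) / sqrt(sum(b^2))
    if (res > 1e-6) {
      stop(sprintf("direct solve residual %.3e unexpectedly large", res),
           call. = FALSE)
    }
    sol <- list(x = x, iter = 0L, rel_residual = res)
  } else {
    Lp <- system$L
    Lp[k, k] <- Lp[k, k] + scale
    dg <- system$diag
    dg[k] <- dg[k] + scale
    sol <- pcg_solve(Lp, b, dg, config$tol, config$max_iter)
  }

  gv <- if (is.null(gauge_voxels)) voxels else gauge_voxels
  gidx <- system$map[gv]; gidx <- gidx[gidx > 0L]
  phi_u <- sol$x - mean(sol$x[gidx])

  phi <- array(NA_real_, system$dims)
  phi[system$cond] <- phi_u
  E <- field_from_potential(phi, system$cond, grid$voxel_size)
  structure(list(phi = phi, E = E, iterations = sol$iter,
                 rel_residual = sol$rel_residual, system = system),
            class = "potential_field")
}

# E = -grad(phi) by central differences inside the conductive domain,
# one-sided at its boundary; V/m (phi volts, spacing mm).
field_from_potential <- function(phi, cond, voxel_size) {
  d <- dim(phi)
  h_m <- voxel_size * 1e-3
  E <- array(0, c(d, 3L))
  for (axis in 1:3) {
    n <- d[axis]
    up <- lapply(d, seq_len); dn <- up
    up[[axis]] <- c(2:n, n)        # clamped shift: neighbour above
    dn[[axis]] <- c(1L, 1:(n - 1L))  # neighbour below
    phi_up <- phi[up[[1]], up[[2]], up[[3]]]
    phi_dn <- phi[dn[[1]], dn[[2]], dn[[3]]]
    ok_up <- !is.na(phi_up); ok_dn <- !is.na(phi_dn)
    ctr_ok <- !is.na(phi)
    grad <- array(0, d)
    both <- ctr_ok & ok_up & ok_dn
    grad[both] <- (phi_up[both] - phi_dn[both]) / (2 * h_m)
    only_up <- ctr_ok & ok_up & !ok_dn
    grad[only_up] <- (phi_up[only_up] - phi[only_up]) / h_m
    only_dn <- ctr_ok & !ok_up & ok_dn
    grad[only_dn] <- (phi[only_dn] - phi_dn[only_dn]) / h_m
    # clamped shifts double-count at the array edge; treat as one-sided zero
    E[, , , axis] <- -grad
  }
  E
}

#' Solve the forward problem for one montage electrode
#'
#' Injects `I` mA uniformly over the electrode patch and extracts it over
#' the inferior reference patch, then solves for the potential and electric
#' field. For epicranial (skull-layer) montages the insulating electrode
#' backs are applied by removing the covered skin voxels from the
#' conductive domain. The gauge is zero mean potential on the reference
#' patch.
#'
#' @param grid A `labeled_grid`.
#' @param montage A `montage` from [place_1020_montage()].
#' @param electrode_id Electrode name, e.g. `"Cz"`.
#' @param I Injected current, mA (zero-to-peak). Must be non-zero for a
#'   meaningful solve; `I = 0` returns a zero field.
#' @param config A [solver_config()].
#' @param system Optional precomputed forward system (reuse across the 19
#'   electrodes of one montage).
#' @return A `potential_field` (see [solve_current_sources()]) with an
#'   additional element `brain_field`: an n x 3 matrix of field vectors at
#'   the brain (GM+WM) voxels, ordered as `which(grid$brain_mask)`.
#' @export
solve_forward <- function(grid, montage, electrode_id, I = 1,
                          config = solver_config(), system = NULL) {
  stopifnot(inherits(montage, "montage"))
  if (attr(montage, "grid_signature") != grid_signature(grid)) {
    stop("montage was placed on a different grid", call. = FALSE)
  }
  patches <- attr(montage, "patches")
  if (!electrode_id %in% names(patches)) {
    stop(sprintf("electrode '%s' is not in the montage", electrode_id), call. = FALSE)
  }
  sigma <- montage_sigma(grid, montage)
  patch <- patches[[electrode_id]]
  ref <- attr(montage, "reference")
  voxels <- c(patch, ref)
  currents <- c(rep(I / length(patch), length(patch)),
                rep(-I / length(ref), length(ref)))
  sol <- solve_current_sources(grid, voxels, currents, sigma = sigma,
                               gauge_voxels = ref, config = config,
                               system = system)
  sol$brain_field <- extract_brain_field(sol$E, grid)
  sol$electrode_id <- electrode_id
  sol$current_mA <- I
  sol
}

# effective conductivity for a montage (epicranial insulating backs)
montage_sigma <- function(grid, montage) {
  sigma <- grid$sigma
  ins <- attr(montage, "insulation")
  if (length(ins)) sigma[ins] <- 0
  sigma
}

# n x 3 field matrix over brain voxels, ordered as which(grid$brain_mask)
extract_brain_field <- function(E, grid) {
  lin <- which(grid$brain_mask)
  nvox <- prod(grid$dim)
  cbind(E[lin], E[lin + nvox], E[lin + 2 * nvox])
}

#' Exact radial-flow field magnitude in concentric shells
#'
#' For spherically symmetric current flow (total current `I` crossing every
#' concentric sphere), the field magnitude at radius `r` is
#' `I / (4 pi sigma(r) r^2)` with `sigma(r)` the conductivity of the shell
#' containing `r`. This closed form is the validation oracle for the
#' finite-volume solver on the radial test harness.
#'
#' @param shells Shell tibble (see [shell_spec()]).
#' @param I Total radial current, mA.
#' @param r Radii in mm (vectorized). Must lie inside the head and not
#'   exactly on a shell interface.
#' @return Field magnitudes in V/m.
#' @export
analytic_radial_profile <- function(shells, I, r) {
  stopifnot(is.data.frame(shells), all(r > 0))
  R <- shells$outer_radius
  if (any(r > R[1L])) stop("r outside the head", call. = FALSE)
  if (any(abs(outer(r, R, `-`)) < 1e-12)) {
    stop("r lies exactly on a shell interface", call. = FALSE)
  }
  # innermost shell whose outer radius >= r
  k <- vapply(r, function(ri) max(which(R >= ri)), integer(1))
  sig <- shells$conductivity[k]
  (I * 1e-3) / (4 * pi * sig * (r * 1e-3)^2)
}
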