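#' Gaussian target weight vector e
#'
#' Builds the length-`N` desired-field vector for one target point and
#' desired direction. The weight magnitude is 1 at the target voxel and
#' decays as a Gaussian of distance, `exp(-d^2 / (2 sigma_e^2))`; the three
#' rows of each voxel carry that magnitude times the desired-direction
#' components, so `t(e) %*% (A %*% s)` is the direction-projected,
#' distance-weighted field.
#'
#' @param lf A `lead_field` (supplies the brain voxel positions).
#' @param target_mm Target point, physical mm coordinates (length 3). Must
#'   fall inside the brain mask.
#' @param direction Desired field direction, unit 3-vector (default +x).
#' @param sigma_e Gaussian width, mm.
#' @return Numeric vector of length `3n` with attribute `target_row`
#'   (index of the target voxel in brain-voxel ordering).
#' @export
build_target_weights <- function(lf, target_mm, direction = c(1, 0, 0),
                                 sigma_e = 10) {
  stopifnot(inherits(lf, "lead_field"), sigma_e > 0, length(direction) == 3L)
  nd <- sqrt(sum(direction^2))
  if (abs(nd - 1) > 1e-8) direction <- direction / nd
  tgt <- target_voxel_row(lf, target_mm)
  d <- voxel_distances_mm(lf, tgt)
  w <- exp(-d^2 / (2 * sigma_e^2))
  e <- as.numeric(t(outer(w, direction)))
  attr(e, "target_row") <- tgt
  e
}

#' Gaussian non-target penalty diagonal
#'
#' Diagonal of the penalty matrix used in the non-target field-power
#' constraint: zero at the target and rising with distance as
#' `1 - exp(-d^2 / (2 sigma_gamma^2))`, replicated across the three
#' component rows of each voxel. All three field components are penalized
#' equally (the constraint caps total non-target power, not a projection).
#'
#' @inheritParams build_target_weights
#' @param sigma_gamma Gaussian width, mm.
#' @param per_voxel If `TRUE` return the length-n per-voxel values instead
#'   of the length-3n diagonal.
#' @return Numeric vector (length `3n`, or `n` if `per_voxel`).
#' @export
build_penalty_weights <- function(lf, target_mm, sigma_gamma = 10,
                                  per_voxel = FALSE) {
  stopifnot(inherits(lf, "lead_field"), sigma_gamma > 0)
  tgt <- target_voxel_row(lf, target_mm)
  d <- voxel_distances_mm(lf, tgt)
  g <- 1 - exp(-d^2 / (2 * sigma_gamma^2))
  if (per_voxel) return(g)
  rep(g, each = 3L)
}

# row index (brain-voxel ordering) of the voxel containing a mm point
target_voxel_row <- function(lf, target_mm) {
  vi <- lf$voxel_index
  ctr <- if (!is.null(lf$center)) lf$center else rep((max(vi) + min(vi)) / 2, 3L)
  pos <- sweep(vi, 2L, ctr) * lf$voxel_size
  d2 <- rowSums((pos - matrix(target_mm, nrow(pos), 3, byrow = TRUE))^2)
  row <- which.min(d2)
  if (sqrt(d2[row]) > lf$voxel_size * sqrt(3)) {
    stop("target point lies outside the brain mask", call. = FALSE)
  }
  row
}

# distances (mm) from every brain voxel to a given brain-voxel row
voxel_distances_mm <- function(lf, row) {
  vi <- lf$voxel_index
  dd <- sweep(vi, 2L, vi[row, ])
  sqrt(rowSums(dd^2)) * lf$voxel_size
}

#' Target specification
#'
#' Convenience bundle of the target weight vector, the penalty diagonal and
#' the default power budget for one named target.
#'
#' @inheritParams build_target_weights
#' @inheritParams build_penalty_weights
#' @param name Target label used in reports.
#' @return A `target_spec` list: `name`, `target_mm`, `direction`,
#'   `sigma_e`, `sigma_gamma`, `e`, `gamma` (length-3n diagonal),
#'   `gamma_voxel` (length n), `target_row`, `p_max0`.
#' @export
target_spec <- function(lf, target_mm, direction = c(1, 0, 0),
                        sigma_e = 10, sigma_gamma = 10, name = "target") {
  e <- build_target_weights(lf, target_mm, direction, sigma_e)
  g <- build_penalty_weights(lf, target_mm, sigma_gamma)
  structure(list(
    name = name, target_mm = target_mm, direction = direction,
    sigma_e = sigma_e, sigma_gamma = sigma_gamma,
    e = as.numeric(e), gamma = g,
    gamma_voxel = g[seq(1L, length(g), by = 3L)],
    target_row = attr(e, "target_row"),
    p_max0 = default_pmax(lf$A, e, g)
  ), class = "target_spec")
}

#' Default non-target power budget
#'
#' Closed-form default for the non-target field-power cap:
#' `P_max0 = t(e) A (t(A) Gamma^2 A)^(-1) t(A) e`, the power reached by the
#' Gamma-weighted least-squares pattern that best realizes the desired
#' field. Used as the centre of the power-budget sweep.
#'
#' @param A Lead-field matrix (N x m) or a `lead_field`.
#' @param e Target weight vector, length N.
#' @param gamma Penalty diagonal, length N.
#' @param regularize If `TRUE`, add Tikhonov damping
#'   `lambda = 1e-10 * mean(diag(M))` to a rank-deficient
#'   `M = t(A) Gamma^2 A` instead of failing.
#' @return Scalar `P_max0` (squared-field power units, (V/m)^2).
#' @export
default_pmax <- function(A, e, gamma, regularize = FALSE) {
  if (inherits(A, "lead_field")) A <- A$A
  stopifnot(is.matrix(A), length(e) == nrow(A), length(gamma) == nrow(A))
  M <- crossprod(A * gamma)
  c_vec <- as.numeric(crossprod(A, e))
  if (regularize) {
    M <- M + diag(1e-10 * mean(diag(M)), nrow(M))
  }
  sol <- tryCatch(solve(M, c_vec), error = function(err) {
    stop(sprintf(
      "t(A) Gamma^2 A is rank deficient (%s); rerun with regularize = TRUE",
      conditionMessage(err)), call. = FALSE)
  })
  as.numeric(crossprod(c_vec, sol))
}

#' Named deep targets for the spherical phantom
#'
#' Four generic deep target points standing in for clinically motivated
#' subcortical structures (subthalamic nucleus, ventral intermediate
#' nucleus, hippocampus, insula). Anatomical coordinates do not transfer to
#' a sphere, so the phantom uses four fixed points 12-30 mm from the head
#' center in distinct octants, all inside white/grey matter.
#'
#' @return A tibble with columns `name`, `x`, `y`, `z` (mm).
#' @export
default_deep_targets <- function() {
  tibble::tribble(
    ~name,          ~x,  ~y,  ~z,
    "stn_left",    -12,  -2,  -6,
    "vim_right",    14,  -6,   2,
    "hippocampus", -22, -16,  -8,
    "insula_left", -28,   6,   4
  )
}
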