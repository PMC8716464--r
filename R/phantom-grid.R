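#' Shell specification for the layered head phantom
#'
#' A shell is one concentric tissue layer of the spherical head phantom:
#' its name, its outer radius, and its (isotropic) conductivity. Shells are
#' listed from the outermost (skin) inward, with strictly decreasing radii.
#'
#' @param name Tissue name. One of `"skin"`, `"skull"`, `"csf"`, `"gm"`,
#'   `"wm"` for the standard five-tissue head; arbitrary names are allowed
#'   for test phantoms.
#' @param outer_radius Outer radius of the shell in mm.
#' @param conductivity Electrical conductivity in S/m. Must be positive.
#' @return A one-row tibble with columns `name`, `outer_radius`,
#'   `conductivity`.
#' @seealso [default_shells()], [build_shell_phantom()]
#' @export
shell_spec <- function(name, outer_radius, conductivity) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(outer_radius) || outer_radius <= 0) {
    stop("shell outer_radius must be a positive length in mm", call. = FALSE)
  }
  if (!is.numeric(conductivity) || conductivity <= 0) {
    stop("shell conductivity must be > 0 S/m", call. = FALSE)
  }
  tibble::tibble(
    name = name,
    outer_radius = as.numeric(outer_radius),
    conductivity = as.numeric(conductivity)
  )
}

#' Default five-tissue head shells
#'
#' Skin, skull, CSF, grey matter and white matter as concentric shells.
#' Conductivities are the standard literature values used throughout the
#' package (S/m): skin 0.465, skull 0.01, CSF 1.65, GM 0.27, WM 0.126.
#' The radii are standard four-shell EEG head-model radii (92/85/78 mm)
#' extended with a GM/WM division at 76/50 mm; the phantom geometry is a
#' simplification, the conductivities are the physical quantities of
#' interest.
#'
#' @param radii Outer radii in mm, outermost first. Length 5.
#' @param conductivities Conductivities in S/m, same order.
#' @return A five-row shell tibble (see [shell_spec()]).
#' @export
default_shells <- function(radii = c(92, 85, 78, 76, 50),
                           conductivities = c(0.465, 0.01, 1.65, 0.27, 0.126)) {
  stopifnot(length(radii) == 5L, length(conductivities) == 5L)
  dplyr::bind_rows(purrr::pmap(
    list(c("skin", "skull", "csf", "gm", "wm"), radii, conductivities),
    shell_spec
  ))
}

#' Build a voxelized concentric-shell head phantom
#'
#' Discretizes a set of concentric spherical shells onto a regular voxel
#' grid. Each voxel center is labeled by the innermost shell whose outer
#' radius is at least the center's distance from the origin; voxels outside
#' the outermost shell are unlabeled. The brain mask is the union of the
#' shells named `"gm"` and `"wm"`.
#'
#' Physical coordinates are in mm with the origin at the sphere center;
#' +x is the subject's right, +y anterior, +z the vertex.
#'
#' @param shells Shell tibble, outermost first, radii strictly decreasing
#'   (see [shell_spec()], [default_shells()]).
#' @param voxel_size Isotropic voxel edge length in mm. 2 mm is the default
#'   analysis resolution; 4 mm is used for fast runs.
#' @return A `labeled_grid` object: list with `voxel_size`, `dim`,
#'   `center` (index of the origin voxel), `shells`, `label` (integer array,
#'   0 = outside, `k` = k-th shell, outermost first), `sigma` (conductivity
#'   array, S/m, 0 outside), `brain_mask` (logical array).
#' @export
build_shell_phantom <- function(shells = default_shells(), voxel_size = 2) {
  stopifnot(is.data.frame(shells), nrow(shells) >= 1L)
  if (!is.numeric(voxel_size) || voxel_size <= 0) {
    stop("voxel_size must be > 0 mm", call. = FALSE)
  }
  r <- shells$outer_radius
  if (any(diff(r) >= 0)) {
    stop("shell radii must be strictly decreasing from the outermost shell inward",
         call. = FALSE)
  }
  if (any(shells$conductivity <= 0)) {
    stop("shell conductivities must be > 0 S/m", call. = FALSE)
  }
  thickness <- c(-diff(r), r[length(r)])
  thin <- thickness < voxel_size
  if (any(thin)) {
    warning(sprintf(
      "shell(s) %s thinner than voxel_size (%g mm); the layer will be ragged at this resolution",
      paste(shells$name[thin], collapse = ", "), voxel_size
    ), call. = FALSE)
  }

  R <- r[1L]
  half <- ceiling(R / voxel_size) + 1L
  d <- 2L * half + 1L
  center <- half + 1L
  ax <- (seq_len(d) - center) * voxel_size
  dist2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  dist <- sqrt(dist2)

  # innermost shell whose outer radius >= distance
  label <- array(0L, dim = c(d, d, d))
  for (k in seq_along(r)) {
    label[dist <= r[k]] <- k
  }
  counts <- tabulate(label, nbins = length(r))
  if (any(counts == 0L)) {
    stop(sprintf("unresolvable shell: %s captures no voxels at voxel_size %g mm",
                 paste(shells$name[counts == 0L], collapse = ", "), voxel_size),
         call. = FALSE)
  }

  sigma <- array(0, dim = dim(label))
  sigma[label > 0L] <- shells$conductivity[label[label > 0L]]
  brain <- label %in% which(shells$name %in% c("gm", "wm"))
  brain_mask <- array(brain, dim = dim(label))

  structure(
    list(
      voxel_size = voxel_size,
      dim = dim(label),
      center = rep(center, 3L),
      shells = shells,
      label = label,
      sigma = sigma,
      brain_mask = brain_mask
    ),
    class = "labeled_grid"
  )
}

#' @export
print.labeled_grid <- function(x, ...) {
  cat(sprintf(
    "<labeled_grid> %d x %d x %d voxels @ %g mm, %d shell(s), %d labeled, %d brain voxels\n",
    x$dim[1], x$dim[2], x$dim[3], x$voxel_size,
    nrow(x$shells), sum(x$label > 0L), sum(x$brain_mask)
  ))
  print(x$shells)
  invisible(x)
}

#' Grid coordinate helpers
#'
#' Conversions between the three addressings of a phantom grid: integer
#' grid indices (i, j, k), linear indices into the flattened arrays, and
#' physical mm coordinates (origin at the sphere center; +x right,
#' +y anterior, +z vertex).
#'
#' @param grid A `labeled_grid`.
#' @param idx Integer index matrix (n x 3), or a length-3 vector.
#' @param mask Logical array on the grid.
#' @param point_mm Physical point, mm (length 3).
#' @return `grid_coords_mm()`: n x 3 mm coordinates. `which_idx()`: n x 3
#'   integer indices of the `TRUE` cells. `nearest_voxel()`: length-3
#'   integer index of the closest voxel (clamped to the grid).
#'   `linear_index()`: integer vector of linear indices.
#' @name grid-helpers
NULL

#' @rdname grid-helpers
#' @export
grid_coords_mm <- function(grid, idx) {
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 3L)
  (idx - matrix(grid$center, nrow(idx), 3L, byrow = TRUE)) * grid$voxel_size
}

#' @rdname grid-helpers
#' @export
which_idx <- function(mask) {
  which(mask, arr.ind = TRUE)
}

#' @rdname grid-helpers
#' @export
nearest_voxel <- function(grid, point_mm) {
  idx <- round(point_mm / grid$voxel_size) + grid$center
  idx <- pmin(pmax(as.integer(idx), 1L), grid$dim)
  idx
}

#' @rdname grid-helpers
#' @export
linear_index <- function(grid, idx) {
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 3L)
  (idx[, 3L] - 1L) * grid$dim[1L] * grid$dim[2L] +
    (idx[, 2L] - 1L) * grid$dim[1L] + idx[, 1L]
}

# signature used to check that two objects came from the same grid
grid_signature <- function(grid) {
  paste(c(grid$dim, grid$voxel_size, nrow(grid$shells),
          signif(grid$shells$outer_radius, 10),
          signif(grid$shells$conductivity, 10)), collapse = "/")
}

#' Outer-surface voxels of a tissue shell
#'
#' Voxels of the named shell that have at least one 6-neighbour lying
#' outside it (outside the head, or in a more superficial shell) — the
#' surface on which electrode patches are placed.
#'
#' @param grid A `labeled_grid`.
#' @param tissue Shell name, e.g. `"skin"` or `"skull"`.
#' @return Logical array on the grid.
#' @export
surface_mask <- function(grid, tissue) {
  k <- match(tissue, grid$shells$name)
  if (is.na(k)) stop(sprintf("grid has no '%s' shell", tissue), call. = FALSE)
  lab <- grid$label
  outerish <- lab < k  # 0 (outside) or any shell outside this one
  d <- dim(lab)
  res <- array(FALSE, d)
  tgt <- lab == k
  shift_has <- function(arr, axis, by) {
    out <- array(TRUE, d)  # out-of-bounds counts as outside
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[axis]
    if (by == 1L) {
      idx_dst[[axis]] <- seq_len(n - 1L); idx_src[[axis]] <- 2:n
    } else {
      idx_dst[[axis]] <- 2:n; idx_src[[axis]] <- seq_len(n - 1L)
    }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      arr[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  nb_outside <- array(FALSE, d)
  for (axis in 1:3) {
    for (by in c(1L, -1L)) {
      nb_outside <- nb_outside | shift_has(outerish, axis, by)
    }
  }
  res[tgt & nb_outside] <- TRUE
  res
}
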