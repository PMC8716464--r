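#' Assemble a lead-field matrix from per-electrode unit solves
#'
#' Stacks the per-electrode unit-current (1 mA) brain field maps into the
#' lead-field matrix `A` of size `N x m`, `N = 3n`, where `n` is the number
#' of brain (GM+WM) voxels and `m` the number of electrodes. Row blocks are
#' voxel-major with component order x, y, z: rows `3(v-1)+1 .. 3v` hold the
#' field at voxel `v`. Column `j` is the field produced by 1 mA through
#' electrode `j` against the common inferior reference.
#'
#' @param solutions Named list of forward solutions from [solve_forward()]
#'   (one per electrode, all on the same grid and reference, all at 1 mA),
#'   or a named list of n x 3 brain-field matrices.
#' @param grid The `labeled_grid` the solves were run on.
#' @param montage The `montage` used (stored for provenance).
#' @return A `lead_field` object: list with `A` (N x m), `electrode_ids`,
#'   `voxel_index` (n x 3 integer grid coordinates), `voxel_size` (mm),
#'   `voxel_volume_mm3`, `n`, `m`, `layer`, `grid_signature`.
#' @export
assemble_leadfield <- function(solutions, grid, montage = NULL) {
  stopifnot(length(solutions) >= 1L)
  ids <- names(solutions)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("solutions must be a named list (electrode ids)", call. = FALSE)
  }
  fields <- purrr::map(solutions, function(s) {
    if (inherits(s, "potential_field")) s$brain_field else s
  })
  n <- nrow(fields[[1L]])
  bad <- vapply(fields, function(f) !is.matrix(f) || nrow(f) != n || ncol(f) != 3L,
                logical(1))
  if (any(bad)) stop("per-electrode fields disagree in voxel count: mismatched grids",
                     call. = FALSE)
  if (n != sum(grid$brain_mask)) {
    stop("fields do not match the grid's brain mask", call. = FALSE)
  }
  A <- vapply(fields, function(f) as.numeric(t(f)), numeric(3L * n))
  dimnames(A) <- NULL
  if (!all(is.finite(A))) stop("non-finite lead-field entries", call. = FALSE)
  voxel_index <- which_idx(grid$brain_mask)
  dimnames(voxel_index) <- NULL
  structure(
    list(A = A, electrode_ids = ids, voxel_index = voxel_index,
         voxel_size = grid$voxel_size,
         voxel_volume_mm3 = grid$voxel_size^3,
         center = grid$center,
         n = n, m = length(ids),
         layer = if (!is.null(montage)) attr(montage, "layer") else NA_character_,
         grid_signature = grid_signature(grid)),
    class = "lead_field"
  )
}

#' Compute the full lead field of a montage
#'
#' Runs one unit-current (1 mA) forward solve per montage electrode,
#' sharing the assembled finite-volume system across solves, and stacks the
#' results with [assemble_leadfield()].
#'
#' @inheritParams solve_forward
#' @param verbose Print one line per electrode solve.
#' @return A `lead_field`.
#' @export
compute_leadfield <- function(grid, montage, config = solver_config(),
                              verbose = FALSE) {
  sigma <- montage_sigma(grid, montage)
  system <- build_forward_system(grid, sigma)
  sols <- list()
  for (id in montage$id) {
    sol <- solve_forward(grid, montage, id, I = 1, config = config,
                         system = system)
    if (verbose) {
      message(sprintf("  electrode %-4s iters=%4d rel_res=%.2e",
                      id, sol$iterations, sol$rel_residual))
    }
    sol$system <- NULL
    sols[[id]] <- sol
  }
  assemble_leadfield(sols, grid, montage)
}

#' @export
print.lead_field <- function(x, ...) {
  cat(sprintf("<lead_field> N = 3 x %d brain voxels, m = %d electrodes (%s), %g mm voxels\n",
              x$n, x$m, x$layer, x$voxel_size))
  invisible(x)
}

#' Electrode current pattern
#'
#' A vector of per-electrode currents (mA, zero-to-peak) for one source.
#' Valid patterns conserve current (entries sum to zero) and respect the
#' total-current budget `sum(|s|) <= I_max`. Both constraints are checked
#' with 1e-9 mA tolerance.
#'
#' @param s Numeric currents, mA.
#' @param ids Electrode ids (optional; taken from `names(s)` if present).
#' @param I_max Total absolute current budget, mA.
#' @param source Tag: `"single"`, `"s1"` or `"s2"`.
#' @return A `current_pattern` numeric vector with attributes `ids`,
#'   `I_max`, `source`.
#' @export
current_pattern <- function(s, ids = names(s), I_max = 1,
                            source = c("single", "s1", "s2")) {
  source <- match.arg(source)
  s <- as.numeric(s)
  if (abs(sum(s)) > 1e-9) {
    stop("current conservation violated: electrode currents must sum to zero",
         call. = FALSE)
  }
  if (sum(abs(s)) > I_max + 1e-9) {
    stop(sprintf("total-current budget violated: sum(|s|) = %.6g mA exceeds I_max = %g mA",
                 sum(abs(s)), I_max), call. = FALSE)
  }
  structure(s, ids = ids, I_max = I_max, source = source,
            class = "current_pattern")
}

#' Total brain field for a current pattern
#'
#' Evaluates `E = A s` by superposition of the unit-current solves and
#' reshapes the result to one 3-vector per brain voxel.
#'
#' @param lf A `lead_field`.
#' @param s A [current_pattern()] (validated) or a plain numeric vector
#'   (validated here with `I_max`).
#' @param I_max Budget used when `s` is a plain vector.
#' @return A `field_map`: n x 3 matrix (V/m) with attributes `voxel_index`,
#'   `voxel_size`, `voxel_volume_mm3`, `grid_signature`, `s`.
#' @export
total_field <- function(lf, s, I_max = 1) {
  stopifnot(inherits(lf, "lead_field"))
  if (!inherits(s, "current_pattern")) {
    s <- current_pattern(s, ids = lf$electrode_ids, I_max = I_max)
  }
  if (length(s) != lf$m) {
    stop(sprintf("pattern length %d does not match m = %d electrodes",
                 length(s), lf$m), call. = FALSE)
  }
  v <- as.numeric(lf$A %*% as.numeric(s))
  field_map(matrix(v, nrow = lf$n, ncol = 3L, byrow = TRUE), lf, s = as.numeric(s))
}

field_map <- function(mat, lf, s = NULL) {
  structure(mat,
            voxel_index = lf$voxel_index,
            voxel_size = lf$voxel_size,
            voxel_volume_mm3 = lf$voxel_volume_mm3,
            grid_signature = lf$grid_signature,
            s = s,
            class = c("field_map", "matrix", "array"))
}

#' Per-voxel field magnitude
#'
#' Euclidean norm of the per-voxel 3-vector field.
#'
#' @param f A `field_map` (n x 3) or plain n x 3 matrix.
#' @return Numeric vector of length n, V/m.
#' @export
magnitude_map <- function(f) {
  stopifnot(is.matrix(f), ncol(f) == 3L)
  sqrt(rowSums(unclass(f)^2))
}

#' Write / read a lead field as a plain-text container
#'
#' Lossless round-trip of the lead-field matrix and its metadata through a
#' directory container of plain-text files: `A.csv` (header row of
#' electrode ids, one row per matrix row, full double precision),
#' `voxel_index.csv` (n rows, grid coordinates i,j,k) and `meta.json`
#' (n, m, voxel_size, voxel_volume_mm3, layer, grid signature). The layout
#' is self-describing and readable by external tools; externally produced
#' containers load as long as shapes and metadata agree.
#'
#' @param lf A `lead_field`.
#' @param path Directory to create/write.
#' @return `path` (write) or a `lead_field` (read).
#' @export
write_leadfield <- function(lf, path) {
  stopifnot(inherits(lf, "lead_field"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  A <- as.data.frame(lf$A)
  names(A) <- lf$electrode_ids
  utils::write.csv(format(A, digits = 17, scientific = TRUE, trim = TRUE),
                   file.path(path, "A.csv"), row.names = FALSE, quote = FALSE)
  vi <- as.data.frame(lf$voxel_index)
  names(vi) <- c("i", "j", "k")
  utils::write.csv(vi, file.path(path, "voxel_index.csv"), row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(
    list(n = lf$n, m = lf$m, voxel_size = lf$voxel_size,
         voxel_volume_mm3 = lf$voxel_volume_mm3, layer = lf$layer,
         center = lf$center, grid_signature = lf$grid_signature),
    file.path(path, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_leadfield
#' @export
read_leadfield <- function(path) {
  meta_file <- file.path(path, "meta.json")
  a_file <- file.path(path, "A.csv")
  vi_file <- file.path(path, "voxel_index.csv")
  if (!all(file.exists(meta_file, a_file, vi_file))) {
    stop("lead-field container is missing A.csv, voxel_index.csv or meta.json",
         call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  need <- c("n", "m", "voxel_size", "voxel_volume_mm3")
  if (!all(need %in% names(meta))) {
    stop("lead-field metadata is missing required fields", call. = FALSE)
  }
  meta$n <- as.integer(meta$n)
  meta$m <- as.integer(meta$m)
  A_df <- utils::read.csv(a_file, check.names = FALSE,
                          colClasses = "numeric")
  A <- as.matrix(A_df)
  vi <- as.matrix(utils::read.csv(vi_file, colClasses = "integer"))
  if (nrow(A) != 3L * meta$n || ncol(A) != meta$m || nrow(vi) != meta$n) {
    stop("lead-field container shape metadata does not match its contents",
         call. = FALSE)
  }
  if (!all(is.finite(A))) stop("non-finite lead-field entries", call. = FALSE)
  dimnames(A) <- NULL
  dimnames(vi) <- NULL
  structure(
    list(A = A, electrode_ids = names(A_df), voxel_index = vi,
         voxel_size = meta$voxel_size,
         voxel_volume_mm3 = meta$voxel_volume_mm3,
         center = if (is.null(meta$center)) NULL else as.numeric(meta$center),
         n = meta$n, m = meta$m,
         layer = if (is.null(meta$layer)) NA_character_ else meta$layer,
         grid_signature = if (is.null(meta$grid_signature)) NA_character_
                          else meta$grid_signature),
    class = "lead_field"
  )
}
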