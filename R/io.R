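#' Export a per-voxel map as NIfTI
#'
#' Writes a brain-voxel scalar map (envelope, magnitude) or a full grid
#' array to NIfTI-1, with the affine encoding the isotropic mm spacing and
#' the head-centred origin. Brain-voxel vectors are scattered back into the
#' grid (background 0); `field_map` matrices are written as one volume per
#' component.
#'
#' @param x Numeric vector over brain voxels (with `voxel_index`
#'   attribute), a `field_map`, or a 3-d array on the full grid.
#' @param grid The `labeled_grid` (required for brain-voxel vectors).
#' @param path Output file (`.nii` / `.nii.gz`). For a `field_map`, the
#'   component suffixes `_x`, `_y`, `_z` are inserted.
#' @return The written path(s), invisibly.
#' @export
write_nifti_map <- function(x, grid, path) {
  to_array <- function(values) {
    arr <- array(0, grid$dim)
    arr[grid$brain_mask] <- values
    arr
  }
  img <- function(arr) {
    RNifti::asNifti(arr, reference = NULL)
  }
  write_one <- function(arr, p) {
    ni <- RNifti::asNifti(arr)
    RNifti::pixdim(ni) <- rep(grid$voxel_size, 3L)
    RNifti::writeNifti(ni, p)
    p
  }
  if (is.matrix(x) && ncol(x) == 3L) {
    base <- sub("(\\.nii(\\.gz)?)$", "", path)
    ext <- sub(sprintf("^%s", gsub("([.\\\\])", "\\\\\\1", base)), "", path)
    if (identical(ext, path)) ext <- ".nii.gz"
    paths <- vapply(1:3, function(k) {
      write_one(to_array(unclass(x)[, k]),
                sprintf("%s_%s%s", base, c("x", "y", "z")[k], ext))
    }, character(1))
    return(invisible(paths))
  }
  arr <- if (is.array(x) && length(dim(x)) == 3L) x else to_array(as.numeric(x))
  invisible(write_one(arr, path))
}

#' Export a grid array as legacy VTK structured points
#'
#' Plain-ASCII legacy VTK (`STRUCTURED_POINTS`) writer for quick
#' visualization of phantom volumes and field maps in ParaView-like tools.
#'
#' @param arr 3-d numeric array on the full grid (use `grid$sigma`,
#'   `grid$label`, or a scattered map).
#' @param grid The `labeled_grid` (spacing/origin).
#' @param path Output `.vtk` file.
#' @param name Scalar field name embedded in the file.
#' @return `path`, invisibly.
#' @export
write_vtk_image <- function(arr, grid, path, name = "values") {
  stopifnot(is.array(arr), length(dim(arr)) == 3L)
  d <- dim(arr)
  h <- grid$voxel_size
  org <- -(grid$center - 1) * h
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", name, "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               sprintf("ORIGIN %g %g %g", org[1], org[2], org[3]),
               sprintf("SPACING %g %g %g", h, h, h),
               sprintf("POINT_DATA %d", prod(d)),
               sprintf("SCALARS %s double 1", name),
               "LOOKUP_TABLE default"), con)
  vals <- as.numeric(arr)  # column-major = x fastest, VTK's expected order
  vals[is.na(vals)] <- 0
  writeLines(paste(format(vals, trim = TRUE, digits = 9), collapse = "\n"), con)
  invisible(path)
}
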