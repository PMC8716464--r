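#' Unit direction vectors of the 19-electrode 10-20 montage
#'
#' Idealized 10-20 positions on the unit sphere. The vertex Cz is +z.
#' Midline and central electrodes sit at multiples of 18 degrees of polar
#' angle (10% of the nasion-inion arc); the circumferential 10% chain
#' (Fp1/Fp2, F7/F8, T3/T4, T5/T6, O1/O2) lies on the 72-degree circle at
#' 36-degree azimuthal steps with Fp1/Fp2 18 degrees off the front midline.
#' F3/F4 and P3/P4 are spherical (slerp) midpoints of their neighbouring
#' standard positions, the usual idealization on a sphere.
#'
#' Axes: +x right, +y anterior, +z vertex.
#'
#' @return A tibble with columns `id`, `x`, `y`, `z` (unit vectors),
#'   19 rows.
#' @export
electrode_positions_1020 <- function() {
  deg <- pi / 180
  sph <- function(theta_deg, az_deg) {
    th <- theta_deg * deg; az <- az_deg * deg
    c(sin(th) * cos(az), sin(th) * sin(az), cos(th))
  }
  slerp_mid <- function(a, b) {
    v <- a + b
    v / sqrt(sum(v^2))
  }
  # azimuth measured from +x (right), counter-clockwise; front midline = 90
  pos <- list(
    Cz  = c(0, 0, 1),
    Fz  = sph(36,  90),
    Pz  = sph(36, -90),
    C3  = sph(36, 180),
    C4  = sph(36,   0),
    Fp1 = sph(72, 108),
    Fp2 = sph(72,  72),
    F7  = sph(72, 144),
    F8  = sph(72,  36),
    T3  = sph(72, 180),
    T4  = sph(72,   0),
    T5  = sph(72, -144),
    T6  = sph(72,  -36),
    O1  = sph(72, -108),
    O2  = sph(72,  -72)
  )
  pos$F3 <- slerp_mid(pos$Fz, pos$F7)
  pos$F4 <- slerp_mid(pos$Fz, pos$F8)
  pos$P3 <- slerp_mid(pos$Pz, pos$T5)
  pos$P4 <- slerp_mid(pos$Pz, pos$T6)
  ord <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
           "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
  m <- do.call(rbind, pos[ord])
  tibble::tibble(id = ord, x = m[, 1], y = m[, 2], z = m[, 3])
}

#' Place a 10-20 disk-electrode montage on a phantom surface
#'
#' Maps the 19 standard 10-20 directions radially onto the requested
#' surface of the phantom and realizes each electrode as the set of surface
#' voxels within `diameter/2` of its center. For `layer = "scalp"`
#' (transcranial, TES) patches lie on the outer skin surface. For
#' `layer = "skull"` (epicranial, ECS) patches lie on the outer skull
#' surface and each electrode carries an insulating back: the skin voxels
#' in the cylinder above the patch are excluded from the conductive domain
#' when the forward problem is solved, so no current leaks into the scalp
#' directly over an epicranial electrode.
#'
#' A far-reference patch is always placed at the inferior pole: the skin
#' surface voxels within a 30-degree polar cap around -z, approximating a
#' distant body reference electrode.
#'
#' @param grid A `labeled_grid` from [build_shell_phantom()].
#' @param layer `"scalp"` or `"skull"`.
#' @param diameter Electrode disk diameter in mm (default 15).
#' @param positions Electrode direction tibble; defaults to
#'   [electrode_positions_1020()].
#' @param reference_half_angle Half-angle of the inferior reference cap,
#'   degrees.
#' @return A `montage` object: a tibble (`id`, `layer`, `diameter_mm`,
#'   `x`, `y`, `z`, `n_voxels`) with attributes `patches` (named list of
#'   linear voxel indices), `reference` (linear voxel indices),
#'   `insulation` (linear indices of skin voxels disabled for ECS),
#'   `layer`, `grid_signature`.
#' @export
place_1020_montage <- function(grid, layer = c("scalp", "skull"),
                               diameter = 15,
                               positions = electrode_positions_1020(),
                               reference_half_angle = 30) {
  layer <- match.arg(layer)
  stopifnot(inherits(grid, "labeled_grid"), diameter > 0)
  tissue <- if (layer == "scalp") "skin" else "skull"
  if (!tissue %in% grid$shells$name) {
    stop(sprintf("grid lacks the '%s' shell required for layer '%s'",
                 tissue, layer), call. = FALSE)
  }
  surf <- surface_mask(grid, tissue)
  surf_idx <- which_idx(surf)
  surf_lin <- linear_index(grid, surf_idx)
  surf_mm <- grid_coords_mm(grid, surf_idx)
  r_surf <- grid$shells$outer_radius[match(tissue, grid$shells$name)]

  dirs <- as.matrix(positions[, c("x", "y", "z")])
  nrm <- sqrt(rowSums(dirs^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("electrode directions must be unit vectors",
                                     call. = FALSE)

  patches <- vector("list", nrow(positions))
  names(patches) <- positions$id
  insulation <- integer(0)
  for (j in seq_len(nrow(positions))) {
    ctr <- r_surf * dirs[j, ]
    d2 <- rowSums((surf_mm - matrix(ctr, nrow(surf_mm), 3, byrow = TRUE))^2)
    sel <- d2 <= (diameter / 2)^2
    if (!any(sel)) {
      stop(sprintf("electrode %s captures no surface voxels at voxel_size %g",
                   positions$id[j], grid$voxel_size), call. = FALSE)
    }
    patches[[j]] <- surf_lin[sel]
    if (layer == "skull") {
      # insulating back: skin voxels within the patch cylinder above it
      skin_k <- match("skin", grid$shells$name)
      if (!is.na(skin_k)) {
        skin_idx <- which_idx(grid$label == skin_k)
        skin_mm <- grid_coords_mm(grid, skin_idx)
        along <- skin_mm %*% dirs[j, ]
        perp2 <- rowSums(skin_mm^2) - as.vector(along)^2
        cover <- as.vector(along) > 0 & perp2 <= (diameter / 2)^2
        insulation <- c(insulation, linear_index(grid, skin_idx[cover, , drop = FALSE]))
      }
    }
  }
  # pairwise overlap check
  all_lin <- unlist(patches, use.names = FALSE)
  if (anyDuplicated(all_lin)) {
    stop("montage overlap: electrode patches share voxels at this voxel_size",
         call. = FALSE)
  }

  skin_surf <- surface_mask(grid, if ("skin" %in% grid$shells$name) "skin" else tissue)
  ref_idx <- which_idx(skin_surf)
  ref_mm <- grid_coords_mm(grid, ref_idx)
  rr <- sqrt(rowSums(ref_mm^2))
  cosang <- -ref_mm[, 3] / pmax(rr, .Machine$double.eps)
  ref_sel <- cosang >= cos(reference_half_angle * pi / 180)
  reference <- linear_index(grid, ref_idx[ref_sel, , drop = FALSE])
  if (length(reference) == 0L) stop("reference patch captured no voxels", call. = FALSE)
  if (length(intersect(reference, all_lin)) > 0L) {
    stop("montage overlap: reference patch intersects an electrode", call. = FALSE)
  }

  out <- tibble::tibble(
    id = positions$id,
    layer = layer,
    diameter_mm = diameter,
    x = dirs[, 1], y = dirs[, 2], z = dirs[, 3],
    n_voxels = vapply(patches, length, integer(1))
  )
  structure(out,
            patches = patches,
            reference = sort(unique(reference)),
            insulation = sort(unique(insulation)),
            layer = layer,
            grid_signature = grid_signature(grid),
            class = c("montage", class(out)))
}

#' Serialize a montage to JSON
#'
#' Writes the electrode list as JSON: one record per electrode with
#' `id`, `direction`, `diameter_mm`, `layer`.
#'
#' @param montage A `montage`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_montage_json <- function(montage, path) {
  stopifnot(inherits(montage, "montage"))
  recs <- purrr::pmap(
    list(montage$id, montage$x, montage$y, montage$z,
         montage$diameter_mm, montage$layer),
    function(id, x, y, z, d, layer) {
      list(id = id, direction = c(x, y, z), diameter_mm = d, layer = layer)
    }
  )
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
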