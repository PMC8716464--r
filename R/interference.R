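#' Interference-envelope map
#'
#' Amplitude of the low-frequency modulation produced by two sinusoidal
#' sources at slightly different high frequencies (for example 5000 and
#' 5010 Hz): at each brain voxel the envelope is
#' `2 * min(||E1||, ||E2||)`, the magnitude-based formula. A
#' direction-resolved variant (modulation along a fixed unit vector,
#' `2 * min(|E1.u|, |E2.u|)`) is available through `direction` for
#' comparison; the default is the magnitude form.
#'
#' @param map1,map2 `field_map` objects (n x 3) from [total_field()], on
#'   the same grid and voxel ordering.
#' @param direction Optional unit 3-vector for the direction-resolved
#'   envelope; `NULL` (default) uses field magnitudes.
#' @param f1,f2 Source frequencies in Hz, stored as metadata.
#' @return An `envelope_map`: numeric vector of length n (V/m) with
#'   attributes `f1`, `f2`, `voxel_index`, `voxel_volume_mm3`.
#' @export
if_envelope <- function(map1, map2, direction = NULL,
                        f1 = 5000, f2 = 5010) {
  stopifnot(is.matrix(map1), is.matrix(map2), ncol(map1) == 3L)
  if (nrow(map1) != nrow(map2)) {
    stop("field maps disagree in voxel count", call. = FALSE)
  }
  sig1 <- attr(map1, "grid_signature"); sig2 <- attr(map2, "grid_signature")
  if (!is.null(sig1) && !is.null(sig2) && !identical(sig1, sig2)) {
    stop("field maps come from different grids", call. = FALSE)
  }
  if (is.null(direction)) {
    a <- magnitude_map(map1)
    b <- magnitude_map(map2)
  } else {
    u <- direction / sqrt(sum(direction^2))
    a <- abs(as.numeric(unclass(map1) %*% u))
    b <- abs(as.numeric(unclass(map2) %*% u))
  }
  structure(2 * pmin(a, b),
            f1 = f1, f2 = f2,
            voxel_index = attr(map1, "voxel_index"),
            voxel_volume_mm3 = attr(map1, "voxel_volume_mm3"),
            class = "envelope_map")
}

#' Non-interferential field-magnitude map
#'
#' The per-voxel magnitude of a single high-frequency source's field — the
#' quantity plotted alongside the interference envelope when illustrating
#' that a single source peaks under its electrodes while the envelope peaks
#' at depth. Alias of [magnitude_map()] kept for report symmetry.
#'
#' @param map A `field_map`.
#' @return Numeric vector of length n (V/m).
#' @export
nonif_magnitude <- function(map) {
  magnitude_map(map)
}

#' Half-value-volume focality
#'
#' Focality metric `F`: the cube root of the brain volume whose field (or
#' envelope) magnitude is strictly higher than half of the value at the
#' target voxel. Smaller `F` means a more focal stimulation. Ties exactly
#' at the half-value threshold are excluded.
#'
#' @param values Non-negative per-brain-voxel scalar map (field magnitude
#'   or envelope), length n.
#' @param target_row Index of the target voxel in the same ordering.
#' @param voxel_volume_mm3 Volume of one voxel, mm^3. Taken from the map
#'   attribute if absent.
#' @return A `focality_report` list: `target_value` (V/m), `threshold`
#'   (V/m), `n_supra`, `volume_cm3`, `F_cm` (`NA` with a warning when the
#'   target value is zero, where the metric is undefined).
#' @export
focality_half_value <- function(values, target_row, voxel_volume_mm3 = NULL) {
  if (is.null(voxel_volume_mm3)) {
    voxel_volume_mm3 <- attr(values, "voxel_volume_mm3")
  }
  stopifnot(is.numeric(values), !is.null(voxel_volume_mm3))
  if (any(values < 0)) stop("scalar map must be non-negative", call. = FALSE)
  stopifnot(target_row >= 1L, target_row <= length(values))
  tv <- as.numeric(values[target_row])
  if (tv == 0) {
    warning("target value is zero: half-value focality is undefined",
            call. = FALSE)
    return(structure(list(target_value = 0, threshold = 0, n_supra = NA_integer_,
                          volume_cm3 = NA_real_, F_cm = NA_real_),
                     class = "focality_report"))
  }
  thr <- tv / 2
  n_supra <- sum(values > thr)
  vol_cm3 <- n_supra * voxel_volume_mm3 / 1000
  structure(list(target_value = tv, threshold = thr, n_supra = n_supra,
                 volume_cm3 = vol_cm3, F_cm = vol_cm3^(1 / 3)),
            class = "focality_report")
}

#' @export
print.focality_report <- function(x, ...) {
  cat(sprintf(
    "<focality> target %.4g V/m, threshold %.4g V/m, %s voxels, %.4g cm^3, F = %.3g cm\n",
    x$target_value, x$threshold, format(x$n_supra), x$volume_cm3, x$F_cm))
  invisible(x)
}
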