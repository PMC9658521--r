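#' Volume represented by one voxel, in microlitres
#'
#' `spacing^3 * 1e-9` (um3 to uL; 1 uL = 1e9 um3). At the 5 um working
#' resolution one voxel is 5 x 5 x 5 = 125 um3 = 1.25e-7 uL.
#'
#' @param spacing_um voxel edge length, micrometres (> 0).
#' @return Microlitres per voxel.
#' @export
voxel_volume_ul <- function(spacing_um) {
  if (!is.numeric(spacing_um) || spacing_um <= 0)
    stop("spacing_um must be positive")
  spacing_um^3 * 1e-9
}

#' Select the air-filled regions (the darker voxels)
#'
#' Inverse-sense counterpart of [threshold_tissue()]: true where intensity
#' is strictly below the threshold. By default the same Otsu threshold as
#' the tissue mask is used, so the tissue and air partitions are exactly
#' complementary.
#'
#' @param grid a [voxel_grid()].
#' @param threshold numeric grey level; `NULL` for Otsu.
#' @return A [binary_mask()] labelled `"air"` with field `threshold`.
#' @export
air_mask <- function(grid, threshold = NULL) {
  tis <- if (is.null(threshold)) threshold_tissue(grid, "otsu")
         else threshold_tissue(grid, "fixed", threshold)
  m <- binary_mask(!tis$data, grid$spacing_um, "air",
                   z_offset = grid$z_offset)
  m$threshold <- tis$threshold
  m
}

#' Reconstruct the nectar level from a measured nectar volume
#'
#' Starting at the flower base and scanning upward, air voxels are
#' accumulated in deterministic (z ascending, then y, then x) order until
#' the accumulated volume reaches the measured nectar volume. By default
#' only air voxels 6-connected to the air component touching slice
#' `base_seed_z` are eligible — nectar pools in the basal chamber, not in
#' disconnected pockets; `restrict_to_base_component = FALSE` gives the
#' literal all-air-voxels scan. Accumulation stops at the first voxel at
#' which the achieved volume reaches or exceeds the target, so the result
#' is never under-filled and overshoots by less than one voxel volume.
#'
#' @param air an `"air"` [binary_mask()].
#' @param target_ul measured nectar volume, microlitres (>= 0).
#' @param spacing_um spacing override, micrometres.
#' @param restrict_to_base_component restrict to the basal air component?
#' @param base_seed_z slice (1-based) seeding the basal component.
#' @return An object of class `fill_result`: list with `nectar_mask`
#'   ([binary_mask()]), `target_ul`, `achieved_ul`, `voxels_used`,
#'   `top_z` (highest filled slice, `NA` if none) and `truncated` (target
#'   exceeded the eligible air).
#' @export
fill_to_volume <- function(air, target_ul, spacing_um = NULL,
                           restrict_to_base_component = TRUE,
                           base_seed_z = 1L) {
  if (target_ul < 0) stop("target_ul must be >= 0")
  if (is.null(spacing_um)) spacing_um <- air$spacing_um
  vvox <- voxel_volume_ul(spacing_um)
  eligible <- air$data
  if (restrict_to_base_component) {
    seeds <- array(FALSE, dim = dim(eligible))
    seeds[base_seed_z, , ] <- eligible[base_seed_z, , ]
    eligible <- flood6(eligible, seeds)
  }
  need <- ceiling(target_ul / vvox * (1 - 1e-12))
  idx <- which(eligible, arr.ind = TRUE)
  truncated <- FALSE
  if (need >= nrow(idx)) {
    take <- idx
    truncated <- need > nrow(idx)
  } else if (need <= 0) {
    take <- idx[integer(0), , drop = FALSE]
  } else {
    ord <- order(idx[, 1], idx[, 2], idx[, 3])
    take <- idx[ord[seq_len(need)], , drop = FALSE]
  }
  mask <- array(FALSE, dim = dim(eligible))
  mask[take] <- TRUE
  structure(list(
    nectar_mask = binary_mask(mask, spacing_um, "nectar",
                              z_offset = air$z_offset),
    target_ul = target_ul,
    achieved_ul = nrow(take) * vvox,
    voxels_used = nrow(take),
    top_z = if (nrow(take)) max(take[, 1]) else NA_integer_,
    truncated = truncated),
    class = "fill_result")
}

#' @export
print.fill_result <- function(x, ...) {
  cat(sprintf(paste0("<fill_result> target %.4g uL, achieved %.6g uL ",
                     "(%d voxels), top slice %s%s\n"),
              x$target_ul, x$achieved_ul, x$voxels_used,
              ifelse(is.na(x$top_z), "none", x$top_z),
              if (x$truncated) " [TRUNCATED: air exhausted]" else ""))
  invisible(x)
}

#' Export a nectar overlay on the greyscale stack
#'
#' Writes the nectar mask as a stack (via [write_stack()]) and a per-slice
#' composite PNG in which nectar voxels tint the greyscale slice.
#'
#' @param grid the source [voxel_grid()].
#' @param nectar_mask a matching [binary_mask()].
#' @param out_path output directory.
#' @param tint RGB weights of the tint colour.
#' @return `out_path`, invisibly.
#' @export
overlay_export <- function(grid, nectar_mask, out_path,
                           tint = c(0.1, 0.4, 1)) {
  if (!identical(dim(grid$data), dim(nectar_mask$data)))
    stop("grid and mask shapes differ")
  dir.create(out_path, recursive = TRUE, showWarnings = FALSE)
  write_stack(nectar_mask, file.path(out_path, "nectar_mask"))
  d <- dim(grid$data)
  for (z in seq_len(d[1])) {
    g <- grid$data[z, , ] / 65535
    m <- nectar_mask$data[z, , ]
    rgb <- array(0, dim = c(d[2], d[3], 3))
    for (ch in 1:3) {
      plane <- g
      plane[m] <- 0.5 * g[m] + 0.5 * tint[ch]
      rgb[, , ch] <- plane
    }
    png::writePNG(rgb, file.path(out_path, sprintf("overlay_%04d.png", z)))
  }
  invisible(out_path)
}
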