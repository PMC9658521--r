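#' Nectary cross-sectional area from two perpendicular central sections
#'
#' Reproduces the virtual-sectioning measurement: two perpendicular
#' longitudinal sections of one-voxel thickness are taken through the
#' centre of the flower — operationalised as the lateral centroid of the
#' gland mask, so off-centre crops are handled — and the gland area in
#' each plane (all lobes included: an annular gland shows two lobes per
#' section) is averaged. For axially symmetric glands the two sections are
#' equal.
#'
#' @param nectary_mask a nonempty [binary_mask()].
#' @param spacing_um spacing override, micrometres.
#' @return Mean section area in mm2, with attribute `center` = c(y, x).
#' @export
cross_section_area <- function(nectary_mask, spacing_um = NULL) {
  m <- nectary_mask$data
  if (!any(m)) stop("empty mask")
  if (is.null(spacing_um)) spacing_um <- nectary_mask$spacing_um
  idx <- which(m, arr.ind = TRUE)
  cy <- round(mean(idx[, 2]))
  cx <- round(mean(idx[, 3]))
  ctr_img <- round((dim(m)[2:3] + 1) / 2)
  if (max(abs(c(cy, cx) - ctr_img)) > 5)
    message("gland centroid (", cy, ",", cx, ") is > 5 voxels from the ",
            "image centre (", ctr_img[1], ",", ctr_img[2], ")")
  a1 <- sum(m[, , cx])   # plane x = cx, counted over (z, y)
  a2 <- sum(m[, cy, ])   # plane y = cy
  structure(mean(c(a1, a2)) * spacing_um^2 * 1e-6, center = c(cy, cx))
}

#' Flower width from the tissue mask
#'
#' `max_extent` (default): the maximum per-axis lateral extent of the
#' tissue footprint projected over all slices. `at_z`: the same evaluated
#' on a single slice (e.g. at the corolla rim). The anatomical level of a
#' width measurement is a reporting choice; both modes are provided and
#' recorded.
#'
#' @param tissue_mask a nonempty [binary_mask()].
#' @param spacing_um spacing override, micrometres.
#' @param mode `"max_extent"` or `"at_z"`.
#' @param z slice index for `mode = "at_z"`.
#' @return Width in mm.
#' @export
flower_width <- function(tissue_mask, spacing_um = NULL,
                         mode = c("max_extent", "at_z"), z = NULL) {
  mode <- match.arg(mode)
  if (is.null(spacing_um)) spacing_um <- tissue_mask$spacing_um
  m <- tissue_mask$data
  foot <- if (mode == "max_extent") apply(m, c(2, 3), any) else {
    if (is.null(z) || z < 1 || z > dim(m)[1]) stop("need a valid z slice")
    m[z, , ]
  }
  if (!any(foot)) stop("empty tissue footprint")
  yext <- diff(range(which(apply(foot, 1, any)))) + 1L
  xext <- diff(range(which(apply(foot, 2, any)))) + 1L
  max(yext, xext) * spacing_um * 1e-3
}

#' Measure one flower: full per-flower phenotype record
#'
#' Composes the segmentation pipeline with the morphometric measures into
#' a single measurement record: tissue thresholding, gland segmentation,
#' gland volume (mm3) and air-contact surface (mm2), flower width (mm),
#' central cross-section area (mm2), plus the externally measured nectar
#' volume (uL) when supplied. Full provenance (thresholds, parameters,
#' estimator tags) is attached as the `"provenance"` attribute.
#'
#' @param grid a [voxel_grid()] of the flower stack.
#' @param sex `"male"` or `"female"`.
#' @param z_first,z_last gland volume-of-interest slice bounds.
#' @param nectar_ul capillary-measured nectar volume, microlitres
#'   (`NA` if not measured).
#' @param flower_id identifier string.
#' @param width_mode,width_z see [flower_width()].
#' @param ... further arguments passed to [segment_nectary()]
#'   (`threshold`, `h_min`, `strategy`, `ids`, `estimator`,
#'   `lateral_box`).
#' @return A one-row data.frame with columns `flower_id`, `sex`,
#'   `flower_width_mm`, `cross_section_area_mm2`, `nectary_surface_mm2`,
#'   `nectary_volume_mm3`, `nectar_volume_ul`.
#' @export
measure_flower <- function(grid, sex, z_first, z_last, nectar_ul = NA_real_,
                           flower_id = "flower", width_mode = "max_extent",
                           width_z = NULL, ...) {
  model <- segment_nectary(grid, z_first, z_last, ...)
  tissue_full <- if (is.numeric(model$threshold_used))
    threshold_tissue(grid, "fixed", model$threshold_used)
  else threshold_tissue(grid, "otsu")
  rec <- data.frame(
    flower_id = flower_id,
    sex = sex,
    flower_width_mm = flower_width(tissue_full, mode = width_mode,
                                   z = width_z),
    cross_section_area_mm2 = as.numeric(cross_section_area(model$mask)),
    nectary_surface_mm2 = model$surface_mm2,
    nectary_volume_mm3 = model$volume_mm3,
    nectar_volume_ul = nectar_ul,
    stringsAsFactors = FALSE)
  attr(rec, "provenance") <- c(model$params,
                               list(threshold_used = model$threshold_used,
                                    compartment_id = model$compartment_id,
                                    width_mode = width_mode))
  rec
}
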