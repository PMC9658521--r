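#' Select the volume of interest (slice range) containing the nectary
#'
#' Restricts the stack to the contiguous slice range in which the gland is
#' observed, from the first to the last slice inclusive. The returned grid
#' records the slice offset so that all heights reported downstream remain
#' in the coordinates of the original stack.
#'
#' @param grid a [voxel_grid()].
#' @param z_first,z_last 1-based inclusive slice bounds,
#'   `1 <= z_first <= z_last <= nz`.
#' @return A [voxel_grid()] of `z_last - z_first + 1` slices.
#' @export
select_voi <- function(grid, z_first, z_last) {
  nz <- dim(grid$data)[1]
  if (z_first < 1 || z_last > nz || z_first > z_last)
    stop("need 1 <= z_first <= z_last <= ", nz)
  crop(grid, crop_box(c(z_first, z_last), c(1, dim(grid$data)[2]),
                      c(1, dim(grid$data)[3])))
}

#' Separate tissue from air by a grey-level threshold
#'
#' Tissue is brighter than air in reconstructed micro-CT, so the mask is
#' true where intensity >= threshold. The default threshold is Otsu's on
#' the 16-bit histogram of the volume of interest; a fixed value can be
#' supplied instead. The threshold actually used is recorded in the
#' returned mask (`$threshold`) for reproducibility.
#'
#' @param grid a [voxel_grid()].
#' @param method `"otsu"` or `"fixed"`.
#' @param value fixed threshold (required for `method = "fixed"`).
#' @return A [binary_mask()] labelled `"tissue"` with field `threshold`.
#' @export
threshold_tissue <- function(grid, method = c("otsu", "fixed"), value = NULL) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(value) || value < 0 || value > 65536)
      stop("fixed method requires a threshold value in the intensity range")
    thr <- value
  } else {
    rng <- range(grid$data)
    if (rng[1] == rng[2])
      stop("constant-intensity volume: Otsu is undefined, use a fixed ",
           "threshold")
    # flatten to one frame: otsu() thresholds each frame of a 3D image
    # separately, but the pipeline uses one global threshold per VOI
    v <- EBImage::Image(matrix(grid$data / 65535, ncol = 1L))
    thr <- EBImage::otsu(v, range = c(0, 1), levels = 65536L) * 65535
  }
  m <- binary_mask(grid$data >= thr, grid$spacing_um, "tissue",
                   z_offset = grid$z_offset)
  m$threshold <- thr
  m
}

#' Topographic height projection of a tissue mask
#'
#' Collapses the 3D tissue mask into a 2D map over (y, x) holding, for
#' each lateral position, the z index of the topmost tissue voxel measured
#' from the flower base upward — the "grey level corroborating with the
#' height". Columns with no tissue get the sentinel `NA`. Heights are
#' reported in original-stack coordinates (the mask's `z_offset` is added).
#'
#' @param tissue a [binary_mask()].
#' @return An object of class `height_map`: list with `data` (integer
#'   matrix over (y, x), `NA` = empty column), `spacing_um`, `z_offset`.
#' @export
height_zproject <- function(tissue) {
  d <- dim(tissue$data)
  hm <- matrix(NA_integer_, d[2], d[3])
  for (z in seq_len(d[1])) {
    s <- tissue$data[z, , ]
    hm[s] <- z + tissue$z_offset
  }
  structure(list(data = hm, spacing_um = tissue$spacing_um,
                 z_offset = tissue$z_offset),
            class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("<height_map> %d x %d, %d empty columns, z range [%s, %s]\n",
              nrow(x$data), ncol(x$data), sum(is.na(x$data)),
              min(x$data, na.rm = TRUE), max(x$data, na.rm = TRUE)))
  invisible(x)
}

#' Watershed compartmentalization of a height map
#'
#' Partitions the height map into compartments by topographic watershed:
#' each compartment grows from a regional maximum of the height map, and
#' maxima shallower than `h_min` (the h-maxima suppression depth) are
#' merged into their dominant neighbour, so minor surface texture does not
#' oversegment the gland. Flooding is performed by
#' \code{\link[EBImage]{watershed}}, which is deterministic for fixed
#' input. Sentinel (empty) columns are background (label 0).
#'
#' @param hmap a `height_map` from [height_zproject()].
#' @param h_min minimal compartment prominence in z voxels (default 2).
#' @return An object of class `label_map`: integer matrix over (y, x) with
#'   0 = background and k >= 1 per compartment.
#' @export
watershed_compartments <- function(hmap, h_min = 2) {
  if (h_min < 0) stop("h_min must be >= 0")
  hm <- hmap$data
  if (all(is.na(hm))) {
    lab <- matrix(0L, nrow(hm), ncol(hm))
  } else {
    lo <- min(hm, na.rm = TRUE)
    v <- hm - lo + 1L       # valid columns >= 1
    v[is.na(v)] <- 0L
    ws <- EBImage::watershed(EBImage::Image(v), tolerance = h_min, ext = 1)
    lab <- matrix(as.integer(EBImage::imageData(ws)), nrow(hm), ncol(hm))
  }
  structure(list(data = lab, spacing_um = hmap$spacing_um),
            class = "label_map")
}

#' Select the nectary compartment and its external contour
#'
#' Picks the watershed compartment corresponding to the gland. Strategies:
#' `"centermost"` (compartment whose footprint centroid is nearest the
#' lateral image centre — the nectary sits at the base of the corolla in
#' the centre of the flower), `"largest"` (largest footprint; useful for
#' concentric female anatomy where several centroids coincide with the
#' centre), or `"manual"` with explicit label id(s) in `ids` (several ids
#' are merged, covering a gland split into two apparent lobes).
#'
#' The external contour is the set of footprint pixels 4-adjacent to the
#' outside background component connected to the image border; interior
#' hole boundaries (e.g. around the style) are not part of it.
#'
#' @param labels a `label_map` from [watershed_compartments()].
#' @param hmap the matching `height_map`.
#' @param strategy `"centermost"`, `"largest"` or `"manual"`.
#' @param ids integer label id(s) for `strategy = "manual"`.
#' @return List with `id` (selected label(s)), `footprint` (logical
#'   matrix) and `contour` (logical matrix, subset of footprint).
#' @export
select_nectary_compartment <- function(labels, hmap,
                                       strategy = c("centermost", "largest",
                                                    "manual"),
                                       ids = NULL) {
  strategy <- match.arg(strategy)
  lab <- labels$data
  present <- sort(setdiff(unique(as.vector(lab)), 0L))
  if (length(present) == 0) stop("empty labeling: no compartments")
  if (strategy == "manual") {
    if (is.null(ids) || !all(ids %in% present))
      stop("manual strategy: ids absent from the labeling")
    sel <- as.integer(ids)
  } else if (strategy == "largest") {
    sizes <- vapply(present, function(k) sum(lab == k), numeric(1))
    sel <- present[which.max(sizes)]
  } else {
    ctr <- (dim(lab) + 1) / 2
    dist2 <- vapply(present, function(k) {
      ij <- which(lab == k, arr.ind = TRUE)
      (mean(ij[, 1]) - ctr[1])^2 + (mean(ij[, 2]) - ctr[2])^2
    }, numeric(1))
    sel <- present[which.min(dist2)]
  }
  footprint <- matrix(lab %in% sel, nrow(lab), ncol(lab))
  outside <- border_connected_2d(!footprint)
  d <- dim(footprint)
  pad <- function(m, di, dj) {
    out <- matrix(TRUE, d[1], d[2])  # off-image counts as outside
    si <- seq_len(d[1]) - di; sj <- seq_len(d[2]) - dj
    ki <- si >= 1 & si <= d[1]; kj <- sj >= 1 & sj <= d[2]
    out[ki, kj] <- m[si[ki], sj[kj], drop = FALSE]
    out
  }
  near_out <- pad(outside, 1, 0) | pad(outside, -1, 0) |
    pad(outside, 0, 1) | pad(outside, 0, -1)
  contour <- footprint & near_out
  list(id = sel, footprint = footprint, contour = contour)
}

#' Interpolate the hidden lower surface of the gland
#'
#' The gland's upper surface is observable in the height projection, but
#' its base rests on (or merges into) other tissue and cannot be obtained
#' by thresholding. It is reconstructed from the external contour: at each
#' contour pixel the boundary value is the z of the lowest tissue voxel of
#' that column, and interior values are filled by discrete harmonic
#' (Laplace) interpolation — deterministic, parameter-free and exact for
#' planar bases — then rounded to integer z and clamped to not exceed the
#' upper surface.
#'
#' @param contour logical matrix (from [select_nectary_compartment()]).
#' @param tissue the [binary_mask()] of tissue over the volume of
#'   interest.
#' @param hmap upper `height_map` (clamping bound).
#' @param footprint logical matrix of the gland footprint.
#' @return A `height_map` of lower-surface z values (original-stack
#'   coordinates), `NA` outside the footprint.
#' @export
interpolate_lower_surface <- function(contour, tissue, hmap, footprint) {
  d <- dim(tissue$data)
  stopifnot(identical(dim(contour), dim(hmap$data)),
            identical(dim(footprint), dim(hmap$data)))
  # lowest tissue z per column (original coordinates)
  lowz <- matrix(NA_integer_, d[2], d[3])
  for (z in rev(seq_len(d[1]))) {
    s <- tissue$data[z, , ]
    lowz[s] <- z + tissue$z_offset
  }
  if (any(contour & is.na(lowz)))
    stop("contour has columns with no tissue beneath; cannot anchor the ",
         "lower surface")
  lower <- matrix(NA_real_, nrow(contour), ncol(contour))
  lower[contour] <- lowz[contour]
  interior <- footprint & !contour
  if (any(interior)) {
    idx <- which(interior)
    nr <- nrow(contour)
    id_of <- rep(NA_integer_, length(interior))
    id_of[idx] <- seq_along(idx)
    nb_off <- c(-1L, 1L, -nr, nr)
    ii <- integer(0); jj <- integer(0); vv <- numeric(0)
    rhs <- numeric(length(idx))
    deg <- numeric(length(idx))
    ri <- ((idx - 1L) %% nr) + 1L
    for (o in nb_off) {
      nidx <- idx + o
      ok <- nidx >= 1 & nidx <= length(interior)
      # forbid row wrap-around for vertical offsets
      if (o == -1L) ok <- ok & ri > 1L
      if (o == 1L) ok <- ok & ri < nr
      ok[ok] <- footprint[nidx[ok]]
      wi <- which(ok)
      deg[wi] <- deg[wi] + 1
      nb <- nidx[wi]
      is_int <- interior[nb]
      ii <- c(ii, wi[is_int]); jj <- c(jj, id_of[nb[is_int]])
      vv <- c(vv, rep(-1, sum(is_int)))
      bc <- wi[!is_int]
      if (length(bc)) rhs[bc] <- rhs[bc] + lower[nb[!is_int]]
    }
    A <- Matrix::sparseMatrix(i = c(seq_along(idx), ii),
                              j = c(seq_along(idx), jj),
                              x = c(deg, vv),
                              dims = c(length(idx), length(idx)))
    sol <- as.numeric(Matrix::solve(A, rhs))
    lower[idx] <- sol
  }
  lower <- round(lower)
  up <- hmap$data
  clampable <- footprint & !is.na(up)
  lower[clampable] <- pmin(lower[clampable], up[clampable])
  structure(list(data = lower, spacing_um = hmap$spacing_um,
                 z_offset = hmap$z_offset),
            class = "height_map")
}

#' Build the 3D nectary mask between the two surfaces
#'
#' Voxel `(z, y, x)` belongs to the gland iff `(y, x)` lies in the
#' footprint and `lower(y, x) <= z <= upper(y, x)` (z in original-stack
#' coordinates).
#'
#' @param upper,lower `height_map` objects (original coordinates).
#' @param footprint logical matrix.
#' @param tissue a [binary_mask()] supplying the target grid shape,
#'   spacing and z offset.
#' @return A [binary_mask()] labelled `"nectary"`.
#' @export
build_nectary_mask <- function(upper, lower, footprint, tissue) {
  d <- dim(tissue$data)
  lo <- lower$data; up <- upper$data
  on <- footprint & !is.na(lo) & !is.na(up)
  if (any(lo[on] > up[on]))
    stop("lower surface exceeds upper surface inside the footprint")
  mask <- array(FALSE, dim = d)
  for (z in seq_len(d[1])) {
    zg <- z + tissue$z_offset
    mask[z, , ] <- on & !is.na(lo) & lo <= zg & zg <= up
  }
  binary_mask(mask, tissue$spacing_um, "nectary", z_offset = tissue$z_offset)
}

#' Voxel-count volume of a binary mask
#'
#' `volume = count * spacing^3 * 1e-9` mm3; numerically equal to
#' microlitres (1 mm3 = 1 uL).
#'
#' @param mask a [binary_mask()] (or logical array with `spacing_um`).
#' @param spacing_um spacing override, micrometres.
#' @return Volume in mm3.
#' @export
mask_volume <- function(mask, spacing_um = NULL) {
  if (inherits(mask, "binary_mask")) {
    if (is.null(spacing_um)) spacing_um <- mask$spacing_um
    mask <- mask$data
  }
  if (is.null(spacing_um) || spacing_um <= 0)
    stop("spacing_um must be positive")
  sum(mask) * spacing_um^3 * 1e-9
}

#' Air-contact surface area of a gland mask
#'
#' Air is the complement of the full tissue mask (not merely of the gland),
#' so gland surface pressed against other organs — the style, the
#' receptacle — is not counted: only surface in contact with air is.
#' Positions outside the grid (beyond the field of view) are unknown and
#' contribute no faces.
#'
#' Two estimators: `"exposed_faces"` (default) counts 6-neighbour faces
#' between a gland voxel and an air voxel, times `spacing^2`; it is
#' additive over disjoint masks and has an exact brute-force oracle.
#' `"surface_voxels"` counts gland voxels having at least one air
#' 6-neighbour, times `spacing^2` — the literal "pixels kept" reading.
#' The voxelised (Manhattan) surface systematically overestimates a smooth
#' continuum area; absolute values are estimator-dependent.
#'
#' @param mask gland [binary_mask()].
#' @param tissue full-tissue [binary_mask()] defining air as its
#'   complement; defaults to the gland mask itself.
#' @param estimator `"exposed_faces"` or `"surface_voxels"`.
#' @return Surface in mm2, with attribute `estimator`.
#' @export
mask_surface_area <- function(mask, tissue = NULL,
                              estimator = c("exposed_faces",
                                            "surface_voxels")) {
  estimator <- match.arg(estimator)
  m <- mask$data
  air <- if (is.null(tissue)) !m else !tissue$data
  stopifnot(identical(dim(air), dim(m)))
  if (estimator == "exposed_faces") {
    cnt <- .face_count(m, air, oob_air = FALSE)
  } else {
    touch <- array(FALSE, dim = dim(m))
    for (k in seq_len(nrow(.offsets6)))
      touch <- touch | shift3(air, .offsets6[k, 1], .offsets6[k, 2],
                              .offsets6[k, 3], fill = FALSE)
    cnt <- sum(m & touch)
  }
  structure(cnt * mask$spacing_um^2 * 1e-6, estimator = estimator)
}

#' Run the full nectary segmentation pipeline on a stack
#'
#' Chains [select_voi()], [threshold_tissue()], [height_zproject()],
#' [watershed_compartments()], [select_nectary_compartment()],
#' [interpolate_lower_surface()], [build_nectary_mask()], [mask_volume()]
#' and [mask_surface_area()] into one call.
#'
#' @param grid a [voxel_grid()] of the flower.
#' @param z_first,z_last volume-of-interest slice bounds (gland extent).
#' @param threshold `"otsu"` or a fixed numeric value.
#' @param h_min watershed prominence, voxels.
#' @param strategy,ids compartment selection
#'   (see [select_nectary_compartment()]).
#' @param estimator surface estimator (see [mask_surface_area()]).
#' @param lateral_box optional [crop_box()]-style list with `y` and `x`
#'   intervals applied before segmentation (e.g. to exclude the corolla
#'   wall for concentric female anatomy).
#' @return An object of class `nectary_model`: list with `mask`
#'   ([binary_mask()] on the VOI grid), `upper_surface`, `lower_surface`
#'   (`height_map`s), `footprint`, `volume_mm3`, `surface_mm2`,
#'   `threshold_used`, `compartment_id` and `params`.
#' @export
segment_nectary <- function(grid, z_first, z_last, threshold = "otsu",
                            h_min = 2, strategy = "centermost", ids = NULL,
                            estimator = "exposed_faces",
                            lateral_box = NULL) {
  if (!is.null(lateral_box))
    grid <- crop(grid, crop_box(c(1, dim(grid$data)[1]),
                                lateral_box$y, lateral_box$x))
  voi <- select_voi(grid, z_first, z_last)
  tissue <- if (is.numeric(threshold))
    threshold_tissue(voi, "fixed", threshold)
  else threshold_tissue(voi, "otsu")
  hmap <- height_zproject(tissue)
  labels <- watershed_compartments(hmap, h_min)
  comp <- select_nectary_compartment(labels, hmap, strategy, ids)
  lower <- interpolate_lower_surface(comp$contour, tissue, hmap,
                                     comp$footprint)
  mask <- build_nectary_mask(hmap, lower, comp$footprint, tissue)
  structure(list(
    mask = mask,
    upper_surface = hmap,
    lower_surface = lower,
    footprint = comp$footprint,
    volume_mm3 = mask_volume(mask),
    surface_mm2 = as.numeric(mask_surface_area(mask, tissue, estimator)),
    threshold_used = tissue$threshold,
    compartment_id = comp$id,
    params = list(z_first = z_first, z_last = z_last, h_min = h_min,
                  strategy = strategy, estimator = estimator)),
    class = "nectary_model")
}

#' @export
print.nectary_model <- function(x, ...) {
  cat(sprintf(paste0("<nectary_model> volume %.4g mm3, surface %.4g mm2 ",
                     "(%s), threshold %.1f, compartment %s\n"),
              x$volume_mm3, x$surface_mm2, x$params$estimator,
              x$threshold_used, paste(x$compartment_id, collapse = "+")))
  invisible(x)
}
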