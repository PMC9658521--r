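#' Specification of a synthetic flower phantom
#'
#' Describes an idealised melon-flower anatomy used to validate the
#' pipeline in the absence of deposited scans: a solid receptacle slab at
#' the base, a hollow corolla tube above it, and a nectary gland on the
#' floor of the tube. Male flowers carry a dome-shaped nectary at the
#' centre; female flowers carry an annular nectary completely surrounding
#' a central style, separated from it by a narrow air groove. The geometry
#' is axially symmetric, so the two perpendicular central longitudinal
#' sections are equal by construction.
#'
#' The degradation model emulating a reconstructed micro-CT scan is:
#' Gaussian blur (a partial-volume surrogate), then additive Gaussian
#' noise, then 16-bit quantisation. Ground truth is always defined on the
#' ideal pre-degradation geometry.
#'
#' @param sex `"male"` or `"female"`.
#' @param corolla_outer_radius_vox,corolla_wall_vox,corolla_depth_vox
#'   corolla tube outer radius, wall thickness and depth, voxels.
#' @param dome_radius_vox male nectary dome radius (voxels).
#' @param annulus_inner_vox,annulus_outer_vox,annulus_height_vox female
#'   nectary annulus radii and height (voxels).
#' @param style_radius_vox female style radius (voxels); must be smaller
#'   than `annulus_inner_vox` (the nectar groove between them).
#' @param base_height_vox thickness of the solid base slab (voxels).
#' @param margin_vox air margin around the corolla (voxels).
#' @param tissue_intensity,air_intensity 16-bit grey levels; tissue must be
#'   brighter than air.
#' @param blur_sigma_vox,noise_sd degradation parameters (voxels / grey
#'   levels).
#' @param seed integer RNG seed making the phantom deterministic.
#' @return An object of class `flower_phantom_spec`.
#' @export
flower_phantom_spec <- function(sex = c("male", "female"),
                                corolla_outer_radius_vox = 40,
                                corolla_wall_vox = 4,
                                corolla_depth_vox = 70,
                                dome_radius_vox = 20,
                                annulus_inner_vox = 12,
                                annulus_outer_vox = 26,
                                annulus_height_vox = 14,
                                style_radius_vox = 8,
                                base_height_vox = 6,
                                margin_vox = 4,
                                tissue_intensity = 30000,
                                air_intensity = 5000,
                                blur_sigma_vox = 0,
                                noise_sd = 0,
                                seed = 1L) {
  sex <- match.arg(sex)
  if (tissue_intensity <= air_intensity)
    stop("tissue_intensity must exceed air_intensity")
  inner <- corolla_outer_radius_vox - corolla_wall_vox
  if (sex == "male") {
    if (dome_radius_vox >= inner)
      stop("dome radius must fit inside the corolla tube")
  } else {
    if (!(style_radius_vox < annulus_inner_vox &&
          annulus_inner_vox < annulus_outer_vox &&
          annulus_outer_vox < inner))
      stop("radii must nest: style < annulus inner < annulus outer < ",
           "corolla inner")
  }
  structure(as.list(environment()), class = "flower_phantom_spec")
}

.restore_seed <- function() {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  function() {
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  }
}

# exposed 6-neighbour faces between `mask` and `air`; `oob_air` controls
# whether positions beyond the grid count as air
.face_count <- function(mask, air, oob_air = FALSE) {
  total <- 0
  for (k in seq_len(nrow(.offsets6))) {
    nb <- shift3(air, .offsets6[k, 1], .offsets6[k, 2], .offsets6[k, 3],
                 fill = oob_air)
    total <- total + sum(mask & nb)
  }
  total
}

#' Generate a synthetic flower volume with analytic ground truth
#'
#' @param spec a [flower_phantom_spec()].
#' @return A list with elements `grid` (the degraded [voxel_grid()]) and
#'   `truth`, a list holding the ideal tissue / nectary / air-cavity masks
#'   and the derived scalars: `nectary_volume_mm3` (exact voxel count),
#'   `nectary_volume_mm3_analytic` (continuum solid), `nectary_surface_mm2`
#'   (air-exposed face count on the ideal geometry), `flower_width_mm`,
#'   `cross_section_area_mm2` and `air_cavity_volume_ul`. Also records
#'   `nectary_z` (slice range of the gland) for volume-of-interest
#'   selection.
#' @param spacing_um voxel spacing in micrometres.
#' @export
make_flower_phantom <- function(spec, spacing_um = 5) {
  stopifnot(inherits(spec, "flower_phantom_spec"))
  R <- spec$corolla_outer_radius_vox
  w <- spec$corolla_wall_vox
  b <- spec$base_height_vox
  D <- spec$corolla_depth_vox
  nz <- b + D
  half <- R + spec$margin_vox
  ny <- nx <- 2L * half + 1L
  cc <- half + 1L
  r2 <- outer((seq_len(ny) - cc)^2, (seq_len(nx) - cc)^2, "+")
  zi <- seq_len(nz)

  sl <- function(cond2d, zsel) {
    a <- array(FALSE, dim = c(nz, ny, nx))
    for (z in zsel) a[z, , ] <- cond2d
    a
  }
  base <- sl(r2 <= R^2, seq_len(b))
  wall <- sl(r2 > (R - w)^2 & r2 <= R^2, (b + 1L):nz)

  if (spec$sex == "male") {
    a0 <- spec$dome_radius_vox
    nect <- array(FALSE, dim = c(nz, ny, nx))
    zmax <- min(nz, b + ceiling(a0))
    # dome base plane at z = b + 0.5 (voxel-boundary), midpoint sampling
    for (z in (b + 1L):zmax) nect[z, , ] <- r2 <= a0^2 - (z - b - 0.5)^2
    style <- array(FALSE, dim = c(nz, ny, nx))
    vol_analytic_vox <- 2 / 3 * pi * a0^3
    nect_z <- c(b + 1L, zmax)
  } else {
    ri <- spec$annulus_inner_vox; ro <- spec$annulus_outer_vox
    h <- spec$annulus_height_vox; rs <- spec$style_radius_vox
    nect <- sl(r2 >= ri^2 & r2 <= ro^2, (b + 1L):(b + h))
    style <- sl(r2 <= rs^2, (b + 1L):nz)
    vol_analytic_vox <- pi * (ro^2 - ri^2) * h
    nect_z <- c(b + 1L, b + h)
  }
  tissue <- base | wall | nect | style
  air <- !tissue
  cavity <- air & sl(r2 <= (R - w)^2, (b + 1L):nz)

  vox_mm3 <- (spacing_um^3) * 1e-9
  foot <- apply(tissue, c(2, 3), any)
  yext <- diff(range(which(apply(foot, 1, any)))) + 1L
  xext <- diff(range(which(apply(foot, 2, any)))) + 1L
  cs_x <- sum(nect[, , cc])   # plane x = centre
  cs_y <- sum(nect[, cc, ])   # plane y = centre

  truth <- list(
    tissue_mask = binary_mask(tissue, spacing_um, "tissue"),
    nectary_mask = binary_mask(nect, spacing_um, "nectary"),
    air_cavity_mask = binary_mask(cavity, spacing_um, "air"),
    nectary_volume_mm3 = sum(nect) * vox_mm3,
    nectary_volume_mm3_analytic = vol_analytic_vox * vox_mm3,
    nectary_surface_mm2 = .face_count(nect, air) * spacing_um^2 * 1e-6,
    flower_width_mm = max(yext, xext) * spacing_um * 1e-3,
    cross_section_area_mm2 = mean(c(cs_x, cs_y)) * spacing_um^2 * 1e-6,
    air_cavity_volume_ul = sum(cavity) * vox_mm3,
    nectary_z = nect_z,
    center_yx = c(cc, cc))

  img <- spec$air_intensity +
    (spec$tissue_intensity - spec$air_intensity) * tissue
  if (spec$blur_sigma_vox > 0) img <- blur3(img, spec$blur_sigma_vox)
  if (spec$noise_sd > 0) {
    restore <- .restore_seed(); on.exit(restore())
    set.seed(spec$seed)
    img <- img + stats::rnorm(length(img), sd = spec$noise_sd)
  }
  img <- array(pmin(pmax(round(img), 0), 65535), dim = dim(img))
  list(grid = voxel_grid(img, spacing_um), truth = truth)
}

#' Calibration solids with exact and analytic volumes
#'
#' Binary-valued test volumes (sphere, cube, axis-aligned cylinder) used to
#' calibrate the voxel-count volume and face-count surface estimators.
#'
#' @param shape `"sphere"`, `"cube"` or `"cylinder"`.
#' @param size_vox radius (sphere, cylinder) or edge (cube), in voxels; for
#'   a cylinder a length-2 vector `c(radius, height)` is accepted
#'   (default height `2 * radius`).
#' @param spacing_um voxel spacing, micrometres.
#' @param tissue_intensity,air_intensity grey levels of the two phases.
#' @return A list with `grid` ([voxel_grid()]), `mask` ([binary_mask()])
#'   and `truth` (voxel count, exact voxel volume, analytic continuum
#'   volume in mm3, and for the cylinder the central longitudinal section
#'   area in voxel units).
#' @export
make_calibration_solid <- function(shape = c("sphere", "cube", "cylinder"),
                                   size_vox, spacing_um = 5,
                                   tissue_intensity = 30000,
                                   air_intensity = 1000) {
  shape <- match.arg(shape)
  if (size_vox[1] < 3) stop("size must be >= 3 voxels")
  m <- 2L
  vox_mm3 <- spacing_um^3 * 1e-9
  if (shape == "cube") {
    n <- as.integer(size_vox[1])
    d <- n + 2L * m
    mask <- array(FALSE, dim = c(d, d, d))
    mask[m + seq_len(n), m + seq_len(n), m + seq_len(n)] <- TRUE
    analytic <- n^3 * vox_mm3
    section <- n^2
  } else if (shape == "sphere") {
    r <- size_vox[1]
    d <- 2L * ceiling(r) + 1L + 2L * m
    cc <- ceiling(r) + 1L + m
    ax <- (seq_len(d) - cc)^2
    r2 <- outer(ax, ax, "+")
    mask <- array(FALSE, dim = c(d, d, d))
    for (z in seq_len(d)) mask[z, , ] <- r2 <= r^2 - ax[z]
    analytic <- 4 / 3 * pi * r^3 * vox_mm3
    section <- pi * r^2
  } else {
    r <- size_vox[1]
    h <- if (length(size_vox) > 1) as.integer(size_vox[2]) else 2L * as.integer(r)
    dl <- 2L * ceiling(r) + 1L + 2L * m
    dz <- h + 2L * m
    cc <- ceiling(r) + 1L + m
    ax <- (seq_len(dl) - cc)^2
    r2 <- outer(ax, ax, "+")
    mask <- array(FALSE, dim = c(dz, dl, dl))
    disc <- r2 <= r^2
    for (z in m + seq_len(h)) mask[z, , ] <- disc
    analytic <- pi * r^2 * h * vox_mm3
    section <- 2 * r * h
  }
  img <- array(air_intensity + (tissue_intensity - air_intensity) * mask,
               dim = dim(mask))
  img <- array(as.integer(img), dim = dim(mask))
  list(grid = voxel_grid(img, spacing_um),
       mask = binary_mask(mask, spacing_um, "tissue"),
       truth = list(voxel_count = sum(mask),
                    volume_mm3_voxel = sum(mask) * vox_mm3,
                    volume_mm3_analytic = analytic,
                    central_section_area_vox = section))
}

#' Simplified honey-bee head solid
#'
#' An ellipsoid head (axial semi-axis 0.8 of the lateral one) with a
#' cylindrical proboscis extending downward along -z. The result is a
#' single 6-connected component whose maximal lateral extent equals
#' `head_width_vox`.
#'
#' @param head_width_vox odd integer, lateral head width in voxels.
#' @param proboscis_length_vox cylinder length (0 = head only).
#' @param proboscis_radius_vox cylinder radius.
#' @param spacing_um voxel spacing, micrometres.
#' @return A [binary_mask()] labelled `"bee"`.
#' @export
make_bee_head_phantom <- function(head_width_vox, proboscis_length_vox = 0,
                                  proboscis_radius_vox = 2, spacing_um = 5) {
  if (head_width_vox < 3 || head_width_vox %% 2 == 0)
    stop("head_width_vox must be an odd integer >= 3")
  if (proboscis_length_vox < 0 || proboscis_radius_vox <= 0)
    stop("dimensions must be positive")
  a <- (head_width_vox - 1) / 2
  caz <- max(1, round(0.8 * a))
  L <- as.integer(proboscis_length_vox)
  nz <- 2L * caz + 1L + L
  ny <- nx <- as.integer(head_width_vox)
  cc <- a + 1
  cz <- L + caz + 1
  ax <- (seq_len(ny) - cc)^2
  r2 <- outer(ax, ax, "+")
  mask <- array(FALSE, dim = c(nz, ny, nx))
  for (z in seq_len(nz)) {
    e <- 1 - (z - cz)^2 / caz^2
    if (e >= 0) mask[z, , ] <- r2 <= e * a^2
  }
  if (L > 0) {
    disc <- r2 <= proboscis_radius_vox^2
    for (z in seq_len(L + 1L)) mask[z, , ] <- mask[z, , ] | disc
  }
  binary_mask(mask, spacing_um, "bee")
}

#' Synthetic per-flower measurement cohort
#'
#' Emulates the statistical structure of a nectar-secretion study: gland
#' volume drawn uniformly on `x_range`, nectar volume generated as
#' `slope * gland_volume + intercept + N(0, noise_sd)` and clipped at zero
#' (flagged when clipping occurs). Companion morphometric fields follow
#' dimensional scalings of the gland volume (surface and cross-section
#' proportional to volume^(2/3), width to volume^(1/3)) with mild
#' multiplicative noise. Defaults give a population Pearson correlation of
#' about 0.85 between gland volume and nectar volume.
#'
#' @param n number of flowers (sexes alternate).
#' @param slope,intercept linear relation, microlitres per mm3 and
#'   microlitres.
#' @param noise_sd additive Gaussian noise on nectar volume, microlitres.
#' @param x_range range of gland volumes, mm3.
#' @param seed integer RNG seed.
#' @return A data.frame with columns `flower_id`, `sex`,
#'   `nectar_volume_ul`, `gland_volume_mm3`, `gland_surface_mm2`,
#'   `cross_section_mm2`, `flower_width_mm`, `clipped`.
#' @export
make_synthetic_cohort <- function(n = 20, slope = 3, intercept = 0.5,
                                  noise_sd = 1.34, x_range = c(0.5, 3),
                                  seed = 1L) {
  stopifnot(n >= 0, noise_sd >= 0)
  cols <- c("flower_id", "sex", "nectar_volume_ul", "gland_volume_mm3",
            "gland_surface_mm2", "cross_section_mm2", "flower_width_mm",
            "clipped")
  if (n == 0) {
    df <- as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols))
    return(df)
  }
  restore <- .restore_seed(); on.exit(restore())
  set.seed(seed)
  x <- stats::runif(n, x_range[1], x_range[2])
  y <- slope * x + intercept + stats::rnorm(n, sd = noise_sd)
  clipped <- y < 0
  y[clipped] <- 0
  data.frame(
    flower_id = sprintf("F%03d", seq_len(n)),
    sex = rep(c("male", "female"), length.out = n),
    nectar_volume_ul = y,
    gland_volume_mm3 = x,
    gland_surface_mm2 = 4.5 * x^(2 / 3) * (1 + stats::rnorm(n, sd = 0.05)),
    cross_section_mm2 = 1.6 * x^(2 / 3) * (1 + stats::rnorm(n, sd = 0.05)),
    flower_width_mm = 4 * x^(1 / 3) * (1 + stats::rnorm(n, sd = 0.03)),
    clipped = clipped,
    stringsAsFactors = FALSE)
}
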