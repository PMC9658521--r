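#' Rigid placement of a bee mask on the flower grid
#'
#' Integer voxel translation plus optional axis-aligned flips; rotational
#' search is deliberately omitted (the centred-descent accessibility proxy
#' does not need it, and interpolating rotations would resample the mask).
#'
#' @param dz,dy,dx integer voxel translation applied to the bee mask
#'   (bee voxel at index i appears at i + offset on the flower grid).
#' @param flips logical length-3: flip the bee mask along (z, y, x) first.
#' @return An object of class `rigid_placement`.
#' @export
rigid_placement <- function(dz = 0L, dy = 0L, dx = 0L,
                            flips = c(FALSE, FALSE, FALSE)) {
  structure(list(dz = as.integer(dz), dy = as.integer(dy),
                 dx = as.integer(dx), flips = flips),
            class = "rigid_placement")
}

# bee mask voxels placed on a grid of dim `d`; returns logical array
.place_bee <- function(bee, d, placement) {
  m <- bee$data
  if (any(placement$flips)) {
    db <- dim(m)
    idx <- lapply(1:3, function(i)
      if (placement$flips[i]) db[i]:1L else seq_len(db[i]))
    m <- m[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  }
  out <- array(FALSE, dim = d)
  ijk <- which(m, arr.ind = TRUE)
  if (nrow(ijk)) {
    ijk[, 1] <- ijk[, 1] + placement$dz
    ijk[, 2] <- ijk[, 2] + placement$dy
    ijk[, 3] <- ijk[, 3] + placement$dx
    keep <- ijk[, 1] >= 1 & ijk[, 1] <= d[1] &
      ijk[, 2] >= 1 & ijk[, 2] <= d[2] &
      ijk[, 3] >= 1 & ijk[, 3] <= d[3]
    out[ijk[keep, , drop = FALSE]] <- TRUE
  }
  out
}

#' Superimpose flower, nectar and bee into a composite label volume
#'
#' Per-voxel labels: 0 background, 1 flower tissue, 2 nectar, 3 bee,
#' 4 overlap (bee colliding with tissue). A bee voxel inside nectar is
#' labelled bee (drinking is not a collision); only bee-tissue contact is
#' an overlap.
#'
#' @param flower_tissue,nectar [binary_mask()]s on the same grid.
#' @param bee a `"bee"` [binary_mask()] (own grid).
#' @param placement a [rigid_placement()] of the bee.
#' @return Integer 3D array of labels with attribute `overlap_voxels`.
#' @export
superimpose <- function(flower_tissue, nectar, bee, placement) {
  if (flower_tissue$spacing_um != bee$spacing_um ||
      flower_tissue$spacing_um != nectar$spacing_um)
    stop("masks must share voxel spacing")
  d <- dim(flower_tissue$data)
  if (!identical(d, dim(nectar$data)))
    stop("flower and nectar must share a grid")
  beep <- .place_bee(bee, d, placement)
  lab <- array(0L, dim = d)
  lab[nectar$data] <- 2L
  lab[flower_tissue$data] <- 1L
  lab[beep] <- 3L
  ov <- beep & flower_tissue$data
  lab[ov] <- 4L
  structure(lab, overlap_voxels = sum(ov))
}

# topmost slice whose tissue footprint encloses air (annular opening)
detect_rim_z <- function(flower_tissue) {
  d <- dim(flower_tissue$data)
  for (z in d[1]:1) {
    s <- flower_tissue$data[z, , ]
    if (!any(s)) next
    air2 <- !s
    enclosed <- air2 & !border_connected_2d(air2)
    if (any(enclosed)) return(list(z = z, enclosed = enclosed))
  }
  stop("no slice with an enclosed opening found; supply rim_z")
}

#' Maximum collision-free insertion depth of the bee head
#'
#' Deterministic accessibility proxy for a flower-visitation event: the
#' bee head is laterally centred on the corolla-opening centroid and slid
#' down the flower axis from the rim in one-voxel steps; the deepest
#' position with zero bee-tissue overlap is reported. Insertion depth `s`
#' means the head's lowest voxel sits `s` slices below the rim (bottom at
#' `rim_z - s + 1`); depth 0 means the head cannot enter at all.
#'
#' @param flower_tissue tissue [binary_mask()].
#' @param bee bee [binary_mask()], same spacing.
#' @param rim_z corolla rim slice; default: topmost slice whose tissue
#'   footprint encloses air.
#' @param step descent step in voxels.
#' @return An object of class `visitation_report`: `max_depth_mm`,
#'   `depth_vox`, `overlap_voxels` (0 at the reported placement),
#'   `head_bottom_z` (`NA` when depth is 0), `rim_z`, `center_yx`,
#'   `placement` (the winning [rigid_placement()], or `NULL`).
#' @export
max_insertion_depth <- function(flower_tissue, bee, rim_z = NULL,
                                step = 1L) {
  if (!any(bee$data)) stop("bee mask is empty")
  d <- dim(flower_tissue$data)
  db <- dim(bee$data)
  if (db[2] > d[2] || db[3] > d[3])
    stop("bee mask is laterally wider than the flower grid")
  if (is.null(rim_z)) {
    rim <- detect_rim_z(flower_tissue)
    rim_z <- rim$z
    ij <- which(rim$enclosed, arr.ind = TRUE)
    ctr <- c(mean(ij[, 1]), mean(ij[, 2]))
  } else {
    if (rim_z < 1 || rim_z > d[1]) stop("rim_z out of bounds")
    s <- flower_tissue$data[rim_z, , ]
    opening <- !s & !border_connected_2d(!s)
    ij <- which(if (any(opening)) opening else !s, arr.ind = TRUE)
    ctr <- c(mean(ij[, 1]), mean(ij[, 2]))
  }
  bidx <- which(bee$data, arr.ind = TRUE)
  bee_bottom <- min(bidx[, 1])
  bee_cy <- mean(range(bidx[, 2]))
  bee_cx <- mean(range(bidx[, 3]))
  dy <- as.integer(round(ctr[1] - bee_cy))
  dx <- as.integer(round(ctr[2] - bee_cx))
  best <- 0L; best_placement <- NULL
  s <- step
  while (TRUE) {
    bottom_target <- rim_z - s + 1L
    if (bottom_target < 1L) break
    dz <- bottom_target - bee_bottom
    pl <- rigid_placement(dz, dy, dx)
    beep <- .place_bee(bee, d, pl)
    if (any(beep & flower_tissue$data)) break
    best <- s; best_placement <- pl
    s <- s + step
  }
  structure(list(max_depth_mm = best * flower_tissue$spacing_um * 1e-3,
                 depth_vox = best,
                 overlap_voxels = 0L,
                 head_bottom_z = if (best > 0L) rim_z - best + 1L
                                 else NA_integer_,
                 rim_z = rim_z,
                 center_yx = ctr,
                 placement = best_placement),
            class = "visitation_report")
}

#' @export
print.visitation_report <- function(x, ...) {
  cat(sprintf("<visitation> depth %.3f mm (%d voxels) below rim z=%d\n",
              x$max_depth_mm, x$depth_vox, x$rim_z))
  invisible(x)
}

#' Can the proboscis reach the nectar from the deepest head position?
#'
#' True iff the top surface of the nectar lies within the proboscis
#' length below the head's lowest voxel at its deepest collision-free
#' placement. An empty nectar mask yields `FALSE` with a warning.
#'
#' @param report a `visitation_report` from [max_insertion_depth()].
#' @param nectar nectar [binary_mask()] on the flower grid.
#' @param proboscis_length_mm proboscis (tongue) length, millimetres.
#' @return Logical flag with attribute `gap_mm` (head bottom to nectar
#'   top; negative when the head is below the nectar surface).
#' @export
nectar_reachability <- function(report, nectar, proboscis_length_mm) {
  if (!any(nectar$data)) {
    warning("empty nectar mask: nothing to reach")
    return(structure(FALSE, gap_mm = NA_real_))
  }
  nectar_top <- max(which(apply(nectar$data, 1, any)))
  head_bottom <- report$head_bottom_z
  if (is.na(head_bottom)) head_bottom <- report$rim_z + 1L
  gap_mm <- (head_bottom - nectar_top) * nectar$spacing_um * 1e-3
  structure(gap_mm <= proboscis_length_mm, gap_mm = gap_mm)
}
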