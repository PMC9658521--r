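#' Volumetric image containers
#'
#' A `voxel_grid` holds a 3D greyscale micro-CT volume as an integer array
#' indexed `[z, y, x]` with isotropic voxel spacing in micrometres. The
#' z axis is the flower axis and `z = 1` is the flower base (peduncle end);
#' all "upward" scans in the pipeline rely on this convention. Stacks
#' scanned tip-first should be flipped with [reorient()].
#'
#' Indexing is 1-based with inclusive ranges throughout the package.
#' `z_offset` records how many slices were removed below the grid by
#' [select_voi()] or [crop()], so that height values can always be reported
#' in the coordinates of the original stack (global z = local z + z_offset).
#'
#' @param data 3D numeric/integer array, dim `(nz, ny, nx)`, intensities in
#'   `[0, 65535]`.
#' @param spacing_um voxel edge length in micrometres (> 0, isotropic).
#' @param z_offset integer, number of original slices below slice 1.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(data, spacing_um, z_offset = 0L) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (!is.numeric(spacing_um) || length(spacing_um) != 1L || spacing_um <= 0)
    stop("spacing_um must be a single positive number")
  if (any(dim(data) < 1L)) stop("all three dimensions must be >= 1")
  rng <- range(data)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 65535)
    stop("intensities must lie in [0, 65535] with no NA")
  storage.mode(data) <- "integer"
  structure(list(data = data, spacing_um = as.numeric(spacing_um),
                 z_offset = as.integer(z_offset)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_grid> %d x %d x %d (z,y,x), spacing %.3g um, z_offset %d\n",
              d[1], d[2], d[3], x$spacing_um, x$z_offset))
  cat(sprintf("  intensity range [%d, %d]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Binary voxel mask on the grid of its source volume
#'
#' @param data 3D logical array, dim `(nz, ny, nx)`.
#' @param spacing_um voxel spacing in micrometres, matching the source grid.
#' @param label semantic tag: one of `"tissue"`, `"air"`, `"nectary"`,
#'   `"nectar"`, `"bee"`.
#' @param z_offset slices removed below the mask (see [voxel_grid()]).
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, spacing_um,
                        label = c("tissue", "air", "nectary", "nectar", "bee"),
                        z_offset = 0L) {
  label <- match.arg(label)
  stopifnot(is.array(data), length(dim(data)) == 3L, is.logical(data))
  if (spacing_um <= 0) stop("spacing_um must be positive")
  structure(list(data = data, spacing_um = as.numeric(spacing_um),
                 label = label, z_offset = as.integer(z_offset)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<binary_mask:%s> %d x %d x %d, spacing %.3g um, %d voxels set\n",
              x$label, d[1], d[2], d[3], x$spacing_um, sum(x$data)))
  invisible(x)
}

#' Axis-aligned crop box
#'
#' Per-axis 1-based inclusive index intervals.
#'
#' @param z,y,x integer vectors `c(lo, hi)` with `1 <= lo <= hi`.
#' @return An object of class `crop_box`.
#' @export
crop_box <- function(z, y, x) {
  chk <- function(v, nm) {
    if (length(v) != 2L || v[1] < 1L || v[1] > v[2])
      stop("invalid ", nm, " interval: need 1 <= lo <= hi")
    as.integer(v)
  }
  structure(list(z = chk(z, "z"), y = chk(y, "y"), x = chk(x, "x")),
            class = "crop_box")
}

#' Crop a volume to a box
#'
#' Spacing is unchanged; `z_offset` is advanced by the number of slices
#' dropped below the box so that global z coordinates are preserved.
#'
#' @param grid a [voxel_grid()] or [binary_mask()].
#' @param box a [crop_box()] within the grid bounds.
#' @return Object of the same class as `grid`.
#' @export
crop <- function(grid, box) {
  stopifnot(inherits(box, "crop_box"))
  d <- dim(grid$data)
  if (box$z[2] > d[1] || box$y[2] > d[2] || box$x[2] > d[3])
    stop("crop box exceeds grid bounds")
  sub <- grid$data[box$z[1]:box$z[2], box$y[1]:box$y[2], box$x[1]:box$x[2],
                   drop = FALSE]
  if (inherits(grid, "binary_mask"))
    binary_mask(sub, grid$spacing_um, grid$label,
                z_offset = grid$z_offset + box$z[1] - 1L)
  else
    voxel_grid(sub, grid$spacing_um,
               z_offset = grid$z_offset + box$z[1] - 1L)
}

#' Axis-aligned reorientation (flips and axis permutation)
#'
#' Only axis-aligned operations are supported: interpolating rotations
#' would resample intensities and bias the voxel-count volumes that are the
#' primary measurand. The voxel multiset is preserved exactly, so the
#' intensity histogram is invariant.
#'
#' @param grid a [voxel_grid()] or [binary_mask()].
#' @param flips logical length-3 vector: flip along (z, y, x)?
#' @param axis_permutation integer length-3 permutation of `1:3`
#'   (positions refer to the current (z, y, x) axes); the default keeps
#'   axes in place.
#' @return Object of the same class as `grid`.
#' @export
reorient <- function(grid, flips = c(FALSE, FALSE, FALSE),
                     axis_permutation = 1:3) {
  stopifnot(length(flips) == 3L, is.logical(flips))
  if (!identical(sort(as.integer(axis_permutation)), 1:3))
    stop("axis_permutation must be a permutation of 1:3")
  a <- grid$data
  d <- dim(a)
  idx <- lapply(1:3, function(i) if (flips[i]) d[i]:1L else seq_len(d[i]))
  a <- a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  a <- aperm(a, as.integer(axis_permutation))
  if (inherits(grid, "binary_mask"))
    binary_mask(a, grid$spacing_um, grid$label)
  else
    voxel_grid(a, grid$spacing_um)
}
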