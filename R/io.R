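#' Read a micro-CT slice stack into a voxel grid
#'
#' Accepts either a multi-page TIFF file or a directory of single-slice
#' TIFFs whose lexicographic filename order is the slice order (slice 1 =
#' first file = flower base). Reconstructed micro-CT exports are 16-bit
#' greyscale; 8-bit mask stacks are accepted too. A JSON sidecar written by
#' [write_stack()] is honoured for the voxel spacing when `spacing_um` is
#' not given.
#'
#' @param path multi-page TIFF file or directory of slice TIFFs.
#' @param spacing_um isotropic voxel spacing in micrometres; may be omitted
#'   when a sidecar is present.
#' @return A [voxel_grid()].
#' @export
read_stack <- function(path, spacing_um = NULL) {
  if (!file.exists(path)) stop("no such path: ", path)
  sidecar <- if (dir.exists(path)) file.path(path, "stack.json")
             else paste0(path, ".json")
  if (is.null(spacing_um)) {
    if (!file.exists(sidecar))
      stop("spacing_um not given and no sidecar found at ", sidecar)
    spacing_um <- jsonlite::read_json(sidecar)$spacing_um
  }
  slices <- if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE))
    if (length(files) == 0L) stop("no TIFF slices in directory: ", path)
    nums <- regmatches(basename(files), regexpr("[0-9]+", basename(files)))
    if (length(nums) == length(files) &&
        length(unique(nchar(nums))) > 1L)
      warning("slice numerals are not zero-padded; lexicographic order ",
              "may not be numeric order")
    lapply(files, function(f) {
      x <- tiff::readTIFF(f, as.is = TRUE)
      attr(x, "file") <- f
      x
    })
  } else {
    tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  }
  shp <- dim(slices[[1]])
  for (i in seq_along(slices)) {
    s <- slices[[i]]
    nm <- attr(s, "file")
    if (is.null(nm)) nm <- sprintf("%s page %d", path, i)
    if (!is.matrix(s))
      stop("format error: non-greyscale sample in ", nm)
    if (!identical(dim(s), shp))
      stop("format error: inconsistent slice shape in ", nm)
    if (is.double(s) && any(s != round(s)))
      stop("format error: non-integer (float) samples in ", nm,
           "; only 8/16-bit greyscale is supported")
  }
  arr <- array(0L, dim = c(length(slices), shp[1], shp[2]))
  for (i in seq_along(slices)) arr[i, , ] <- as.integer(slices[[i]])
  voxel_grid(arr, spacing_um)
}

#' Write a voxel grid or mask as a TIFF stack with a JSON sidecar
#'
#' Grids are written as 16-bit greyscale, masks as 8-bit 0/255. `path`
#' ending in `.tif`/`.tiff` produces a multi-page file; otherwise a
#' directory of zero-padded slice files `slice_0001.tif`, ... is created.
#' A sidecar (`<path>.json` or `<dir>/stack.json`) records `spacing_um`,
#' the `(z, y, x)` axis convention and that `z = 1` is the flower base.
#'
#' @param x a [voxel_grid()] or [binary_mask()].
#' @param path output file or directory.
#' @return `path`, invisibly.
#' @export
write_stack <- function(x, path) {
  is_mask <- inherits(x, "binary_mask")
  if (!is_mask && !inherits(x, "voxel_grid"))
    stop("x must be a voxel_grid or binary_mask")
  d <- dim(x$data)
  to_page <- function(z) {
    if (is_mask) matrix(ifelse(x$data[z, , ], 255, 0) / 255, d[2], d[3])
    else matrix(x$data[z, , ] / 65535, d[2], d[3])
  }
  bits <- if (is_mask) 8L else 16L
  multipage <- grepl("\\.tiff?$", path, ignore.case = TRUE)
  if (multipage) {
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    tiff::writeTIFF(lapply(seq_len(d[1]), to_page), path,
                    bits.per.sample = bits)
    sidecar <- paste0(path, ".json")
  } else {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    for (z in seq_len(d[1]))
      tiff::writeTIFF(to_page(z),
                      file.path(path, sprintf("slice_%04d.tif", z)),
                      bits.per.sample = bits)
    sidecar <- file.path(path, "stack.json")
  }
  meta <- list(spacing_um = x$spacing_um,
               axis_order = c("z", "y", "x"),
               z_base = "z = 1 is the flower base (peduncle end)",
               kind = if (is_mask) "mask" else "grid")
  if (is_mask) meta$label <- x$label
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a mask stack written by [write_stack()]
#'
#' @param path stack path (file or directory).
#' @param label semantic tag for the mask; defaults to the sidecar's.
#' @param spacing_um spacing override; defaults to the sidecar's.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path, label = NULL, spacing_um = NULL) {
  sidecar <- if (dir.exists(path)) file.path(path, "stack.json")
             else paste0(path, ".json")
  if (is.null(label)) {
    label <- if (file.exists(sidecar)) jsonlite::read_json(sidecar)$label
    if (is.null(label)) label <- "tissue"
  }
  g <- read_stack(path, spacing_um)
  binary_mask(g$data > 0L, g$spacing_um, label)
}
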