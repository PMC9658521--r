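# Internal array helpers shared across the pipeline.
# 6-connectivity (face neighbours) is the package-wide convention for
# surfaces, connected components and fills.

# result[z,y,x] = a[z-dz, y-dy, x-dx]; out-of-bounds positions get `fill`.
shift3 <- function(a, dz = 0L, dy = 0L, dx = 0L, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, dim = d)
  src <- list(z = seq_len(d[1]) - dz, y = seq_len(d[2]) - dy,
              x = seq_len(d[3]) - dx)
  keep <- lapply(seq_along(src), function(i) src[[i]] >= 1L & src[[i]] <= d[i])
  out[keep[[1]], keep[[2]], keep[[3]]] <-
    a[src$z[keep[[1]]], src$y[keep[[2]]], src$x[keep[[3]]], drop = FALSE]
  out
}

.offsets6 <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))

# Voxels of `mask` reachable from `seeds` (logical array) through
# face-adjacent steps; vectorised frontier dilation.
flood6 <- function(mask, seeds) {
  reached <- seeds & mask
  frontier <- reached
  while (any(frontier)) {
    grown <- array(FALSE, dim = dim(mask))
    for (k in seq_len(nrow(.offsets6)))
      grown <- grown | shift3(frontier, .offsets6[k, 1], .offsets6[k, 2],
                              .offsets6[k, 3])
    frontier <- grown & mask & !reached
    reached <- reached | frontier
  }
  reached
}

# Separable 3D Gaussian blur with replicated edges. No installed package
# offers 3D Gaussian filtering, so this is done by shift-and-add along
# each axis in turn (kernel truncated at 4 sigma).
blur3 <- function(a, sigma) {
  if (sigma <= 0) return(a)
  k <- max(1L, ceiling(4 * sigma))
  w <- stats::dnorm(-k:k, sd = sigma)
  w <- w / sum(w)
  d <- dim(a)
  for (axis in 1:3) {
    out <- array(0, dim = d)
    n <- d[axis]
    for (j in seq_along(w)) {
      off <- j - k - 1L
      idx <- pmin(pmax(seq_len(n) - off, 1L), n)
      out <- out + w[j] * switch(axis,
        a[idx, , , drop = FALSE],
        a[, idx, , drop = FALSE],
        a[, , idx, drop = FALSE])
    }
    a <- out
  }
  a
}

# Dice overlap 2|A.B| / (|A| + |B|) between two logical arrays.
#' Dice similarity coefficient between two binary masks
#'
#' @param a,b [binary_mask()] objects or logical arrays of equal shape.
#' @return Numeric in `[0, 1]`; 1 for two empty masks by convention.
#' @export
dice <- function(a, b) {
  if (inherits(a, "binary_mask")) a <- a$data
  if (inherits(b, "binary_mask")) b <- b$data
  stopifnot(identical(dim(a), dim(b)))
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}

# 2D 4-neighbour flood used for contour/rim logic.
flood4_2d <- function(mask, seeds) {
  reached <- seeds & mask
  frontier <- reached
  d <- dim(mask)
  sh <- function(m, di, dj) {
    out <- matrix(FALSE, d[1], d[2])
    si <- seq_len(d[1]) - di; sj <- seq_len(d[2]) - dj
    ki <- si >= 1 & si <= d[1]; kj <- sj >= 1 & sj <= d[2]
    out[ki, kj] <- m[si[ki], sj[kj], drop = FALSE]
    out
  }
  while (any(frontier)) {
    grown <- sh(frontier, 1, 0) | sh(frontier, -1, 0) |
      sh(frontier, 0, 1) | sh(frontier, 0, -1)
    frontier <- grown & mask & !reached
    reached <- reached | frontier
  }
  reached
}

# Border-connected region of a 2D logical mask (4-connectivity).
border_connected_2d <- function(mask) {
  seeds <- matrix(FALSE, nrow(mask), ncol(mask))
  seeds[1, ] <- TRUE; seeds[nrow(mask), ] <- TRUE
  seeds[, 1] <- TRUE; seeds[, ncol(mask)] <- TRUE
  flood4_2d(mask, seeds & mask)
}
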