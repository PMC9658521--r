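# Shared fixtures and independent oracles. All fixtures are generated in
# code; nothing is read from disk.

# lateral crop window strictly inside the corolla tube (excludes the wall)
inner_box <- function(spec, truth) {
  r <- spec$corolla_outer_radius_vox - spec$corolla_wall_vox - 1
  cc <- truth$center_yx
  list(y = c(cc[1] - r, cc[1] + r), x = c(cc[2] - r, cc[2] + r))
}

# crop a full-grid mask to the VOI + lateral box used by segment_nectary
crop_like_voi <- function(mask, z_first, z_last, lb = NULL) {
  d <- dim(mask$data)
  y <- if (is.null(lb)) c(1, d[2]) else lb$y
  x <- if (is.null(lb)) c(1, d[3]) else lb$x
  crop(mask, crop_box(c(z_first, z_last), y, x))
}

# brute-force O(N) face enumeration between mask and air (triple loop);
# out-of-grid contributes nothing
brute_face_count <- function(m, air) {
  d <- dim(m)
  off <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  cnt <- 0L
  idx <- which(m, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    for (k in 1:6) {
      p <- idx[r, ] + off[k, ]
      if (all(p >= 1) && all(p <= d) && air[p[1], p[2], p[3]])
        cnt <- cnt + 1L
    }
  }
  cnt
}

# independent marker-based flooding oracle: starting from the given seed
# pixels, repeatedly label the highest unlabelled pixel that is 4-adjacent
# to an already-labelled one, inheriting the label of its highest labelled
# neighbour (ties broken by scan order)
ws_flood_oracle <- function(hm, seeds) {
  d <- dim(hm)
  lab <- matrix(0L, d[1], d[2])
  for (k in seq_along(seeds)) lab[seeds[[k]][1], seeds[[k]][2]] <- k
  nbs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  repeat {
    besti <- 0L; bestj <- 0L; besth <- -Inf; bestlab <- 0L
    for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
      if (lab[i, j] > 0L || is.na(hm[i, j])) next
      nlab <- 0L; nh <- -Inf
      for (o in nbs) {
        ii <- i + o[1]; jj <- j + o[2]
        if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2]) next
        if (lab[ii, jj] > 0L && hm[ii, jj] > nh) {
          nlab <- lab[ii, jj]; nh <- hm[ii, jj]
        }
      }
      if (nlab > 0L && hm[i, j] > besth) {
        besth <- hm[i, j]; besti <- i; bestj <- j; bestlab <- nlab
      }
    }
    if (besti == 0L) break
    lab[besti, bestj] <- bestlab
  }
  lab
}

# exhaustive-placement insertion-depth oracle: tries every depth step
# directly and reports the deepest collision-free streak from the rim
exhaustive_depth <- function(tissue, bee, rim_z, dy, dx) {
  d <- dim(tissue$data)
  bidx <- which(bee$data, arr.ind = TRUE)
  bee_bottom <- min(bidx[, 1])
  best <- 0L
  for (s in seq_len(rim_z)) {
    dz <- (rim_z - s + 1L) - bee_bottom
    ijk <- bidx
    ijk[, 1] <- ijk[, 1] + dz; ijk[, 2] <- ijk[, 2] + dy
    ijk[, 3] <- ijk[, 3] + dx
    keep <- ijk[, 1] >= 1 & ijk[, 1] <= d[1] &
      ijk[, 2] >= 1 & ijk[, 2] <= d[2] & ijk[, 3] >= 1 & ijk[, 3] <= d[3]
    hit <- any(tissue$data[ijk[keep, , drop = FALSE]])
    if (hit) break
    best <- s
  }
  best
}

# male/female phantom pair constructed so the analytic nectary volume
# ratio female/male is exactly `ratio`, with matched central sections
fold_change_pair <- function(ratio = 2.7, seed = 41) {
  ri <- 15; ro <- 31; h <- 20
  a <- (3 * (ro^2 - ri^2) * h / (2 * ratio))^(1 / 3)
  male <- flower_phantom_spec("male", dome_radius_vox = a, seed = seed)
  female <- flower_phantom_spec("female", annulus_inner_vox = ri,
                                annulus_outer_vox = ro,
                                annulus_height_vox = h, seed = seed + 1)
  list(male = make_flower_phantom(male), female = make_flower_phantom(female),
       male_spec = male, female_spec = female)
}

# run the full pipeline on a phantom, returning the nectary model and the
# ground-truth mask cropped onto the model's grid
run_pipeline <- function(ph, spec, pad_top = 2, strategy = "centermost") {
  zr <- ph$truth$nectary_z
  lb <- inner_box(spec, ph$truth)
  mod <- segment_nectary(ph$grid, zr[1], min(zr[2] + pad_top,
                                             dim(ph$grid$data)[1]),
                         strategy = strategy, lateral_box = lb)
  gt <- crop_like_voi(ph$truth$nectary_mask, zr[1],
                      min(zr[2] + pad_top, dim(ph$grid$data)[1]), lb)
  list(model = mod, gt = gt)
}

# simple open corolla tube: solid base slab, hollow wall above it
tube_fixture <- function(inner = 12, nz = 40, base = 4, half = 16) {
  n <- 2L * half + 1L
  r2 <- outer((seq_len(n) - half - 1)^2, (seq_len(n) - half - 1)^2, "+")
  m <- array(FALSE, c(nz, n, n))
  for (z in seq_len(base)) m[z, , ] <- r2 <= (inner + 2)^2
  for (z in (base + 1):nz) m[z, , ] <- r2 > inner^2 & r2 <= (inner + 2)^2
  binary_mask(m, 5, "tissue")
}

new_height_map <- function(data, spacing_um = 5, z_offset = 0L) {
  structure(list(data = data, spacing_um = spacing_um,
                 z_offset = as.integer(z_offset)),
            class = "height_map")
}
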