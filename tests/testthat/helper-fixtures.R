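# Shared fixtures: all synthetic, built in code at test time.

# Reduced problem size used across the suite: same geometry proportions and
# noise model as the full-scale defaults, smaller frames so tests stay fast.
small_params <- function(...) {
  synthetic_params(image_size = 96L, z_planes = 9L,
                   radius_range_px = c(20, 34), ...)
}

medium_params <- function(...) {
  synthetic_params(image_size = 128L, z_planes = 9L,
                   radius_range_px = c(30, 45), ...)
}

# 90-degree rotation of a stack (pure pixel permutation).
rotate_stack90 <- function(st) {
  v <- st$voxels
  d <- dim(v)
  vr <- aperm(v, c(2, 1, 3, 4))[d[2]:1, , , , drop = FALSE]
  spheroid_stack(vr, st$channel_map, st$pixel_size_um, st$z_step_um,
                 st$spheroid_id)
}

# Rescale single channels by exact powers of two (exact in IEEE arithmetic).
scale_channels_pow2 <- function(st, factors = c(1, 4, 0.5, 2)) {
  for (ci in seq_along(factors)) st$voxels[, , , ci] <- st$voxels[, , , ci] * factors[ci]
  st
}

# Filled disc mask / image helpers.
disc_mask <- function(size, cx, cy, r) {
  x <- matrix(rep(0:(size - 1L), each = size), size, size)
  y <- matrix(rep(0:(size - 1L), times = size), size, size)
  sqrt((x - cx)^2 + (y - cy)^2) <= r
}

gaussian_blob_img <- function(size, cx, cy, sigma, amp) {
  x <- matrix(rep(0:(size - 1L), each = size), size, size)
  y <- matrix(rep(0:(size - 1L), times = size), size, size)
  amp * exp(-((x - cx)^2 + (y - cy)^2) / (2 * sigma^2))
}

# Hand-built equatorial image (for direct nuclei/actin fixtures).
make_eq <- function(projections, mask, com, r_max, pixel_size_um = 0.1) {
  structure(list(projections = projections, mask = mask, com = com,
                 r_max = r_max, z_index = 1L, pixel_size_um = pixel_size_um,
                 spheroid_id = "fixture"),
            class = "equatorial_image")
}

# Brute-force Cohen's kappa from expanded rating lists (independent of the
# table-based implementation): po as a direct match rate, pe from label
# frequencies.
kappa_bruteforce <- function(a, b) {
  po <- mean(a == b)
  labs <- unique(c(a, b))
  pe <- sum(vapply(labs, function(l) mean(a == l) * mean(b == l), numeric(1)))
  (po - pe) / (1 - pe)
}

# Expand a count table into the two raters' rating lists.
expand_table <- function(tab) {
  labs <- rownames(tab)
  a <- character(0); b <- character(0)
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    k <- tab[i, j]
    if (k > 0) { a <- c(a, rep(labs[i], k)); b <- c(b, rep(labs[j], k)) }
  }
  list(a = a, b = b)
}

# RGB test images: random but integer-valued.
random_rgb <- function(size = 16L, seed = 1L, label = NA_character_) {
  withr::with_seed(seed, {
    px <- array(sample(0:255, size * size * 3, TRUE), c(size, size, 3L))
  })
  structure(px, label = label, apical_source = "apical", class = "rgb_image")
}
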