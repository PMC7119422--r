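# Internal numeric helpers shared across modules.
#
# Determinism note: feature extraction is designed so that 90-degree image
# rotations (pure pixel permutations) and exact positive rescalings of a
# channel reproduce bit-identical features. That requires order-independent
# reductions: order-statistic quantiles, integer chain-code step counts, and
# canonically ordered floating-point sums.

# Round half away from zero (the convention used for the polar radius and
# for reported percentages); base round() is banker's rounding.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Lower empirical order statistic (quantile type 1): returns an observed
# value, so integer-valued images keep integer thresholds.
quantile_lower <- function(x, prob) {
  x <- sort(x)
  n <- length(x)
  if (n == 0L) stop("quantile of empty vector")
  x[max(1L, ceiling(prob * n))]
}

# Otsu threshold on non-negative data (matrix, array or vector), histogram
# over [0, max]; the data is flattened so stacks get one global threshold.
otsu_threshold <- function(x) {
  mx <- max(x)
  if (mx <= 0) stop("no signal: image is constant zero")
  EBImage::otsu(EBImage::Image(matrix(as.vector(x) / mx, nrow = 1L)),
                range = c(0, 1), levels = 256L) * mx
}

# Largest connected component of a logical matrix (8-connected).
largest_component <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n == 0) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0], nbins = n)
  lab == which.max(sizes)
}

# Chain-code (Freeman) perimeter of a single connected region: number of
# axial steps + sqrt(2) * number of diagonal steps along the object contour.
# Computed from integer step counts, hence exactly invariant under
# 90-degree rotations of the mask.
chain_perimeter <- function(mask) {
  if (!any(mask)) return(0)
  lab <- EBImage::bwlabel(mask)
  total_even <- 0L
  total_odd <- 0L
  for (oc in EBImage::ocontour(lab)) {
    if (nrow(oc) == 1L) { total_even <- total_even + 1L; next }
    d <- rbind(diff(oc), oc[1L, ] - oc[nrow(oc), ])
    diag_step <- (d[, 1] != 0) & (d[, 2] != 0)
    total_even <- total_even + sum(!diag_step)
    total_odd <- total_odd + sum(diag_step)
  }
  total_even + sqrt(2) * total_odd
}

# 4*pi*A / P^2 clipped to [0, 1]; P from the chain-code estimator.
mask_circularity <- function(mask) {
  a <- sum(mask)
  if (a == 0L) stop("circularity of empty region")
  p <- chain_perimeter(mask)
  if (p <= 0) return(1)
  min(1, max(0, 4 * pi * a / p^2))
}

# Circularity of the convex hull of a pixel set given as (x, y) coordinates.
# Shoelace area (exact on integer coordinates) and perimeter summed over
# sorted segment lengths so the reduction order is canonical.
hull_circularity <- function(xy) {
  if (nrow(xy) < 3L) return(1)
  h <- grDevices::chull(xy)
  pts <- xy[h, , drop = FALSE]
  k <- nrow(pts)
  if (k < 3L) return(1)
  nxt <- c(2:k, 1L)
  area <- abs(sum(pts[, 1] * pts[nxt, 2] - pts[nxt, 1] * pts[, 2])) / 2
  seglen <- sqrt((pts[nxt, 1] - pts[, 1])^2 + (pts[nxt, 2] - pts[, 2])^2)
  per <- sum(sort(seglen))
  if (per <= 0 || area <= 0) return(1)
  min(1, max(0, 4 * pi * area / per^2))
}

# Seed derivation: stable small-integer streams below 2^31.
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
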