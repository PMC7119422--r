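# Equatorial-plane extraction and spheroid shape parameters.
#
# Spheroid polarity is radially symmetric at the equatorial plane, so the
# whole downstream analysis works on a projection of the central z-slices.
# Coordinates are 0-based pixel indices throughout: matrix element [i, j]
# is the pixel at (x, y) = (j - 1, i - 1); centres of mass are sub-pixel.

#' Spheroid mask, centre of mass and maximum radius
#'
#' Each channel is background-subtracted (its 5th-percentile order
#' statistic, floored at zero) and thresholded on its own (Otsu over a
#' 256-bin histogram); the spheroid support is the union of the per-channel
#' masks, hole-filled (a bright marker ring around a darker interior or an
#' empty lumen fills to its full disc) with the largest connected component
#' kept. Thresholding each channel independently makes the support — and
#' everything derived from it — invariant to per-channel detector gain. The
#' centre of mass is the area centroid of the support; the maximum radius
#' is the largest rounded polar radius (see [polar_radius()]) over mask
#' pixels.
#'
#' @param projections numeric array `[Y, X, C]` (any number of channels >= 1)
#'   or a single matrix.
#' @param background_quantile per-channel background percentile (default 0.05).
#' @return list with `mask` (logical matrix), `com` (`c(x, y)`, 0-based,
#'   sub-pixel) and `r_max` (integer, px).
#' @export
spheroid_mask <- function(projections, background_quantile = 0.05) {
  if (is.matrix(projections))
    projections <- array(projections, c(dim(projections), 1L))
  d <- dim(projections)
  mask0 <- matrix(FALSE, d[1], d[2])
  any_signal <- FALSE
  for (ci in seq_len(d[3])) {
    ch <- projections[, , ci]
    bg <- quantile_lower(ch, background_quantile)
    ch <- pmax(ch - bg, 0)
    if (max(ch) <= 0) next
    any_signal <- TRUE
    mask0 <- mask0 | (ch > otsu_threshold(ch))
  }
  if (!any_signal) stop("no spheroid detected: image has no signal")
  if (!any(mask0)) stop("no spheroid detected: empty mask after thresholding")
  mask <- largest_component(EBImage::fillHull(mask0) > 0)
  xs <- matrix(rep(0:(d[2] - 1L), each = d[1]), d[1], d[2])
  ys <- matrix(rep(0:(d[1] - 1L), times = d[2]), d[1], d[2])
  idx <- which(mask)
  com <- c(sum(xs[idx]), sum(ys[idx])) / length(idx)
  r_max <- max(polar_radius(xs[idx], ys[idx], com))
  list(mask = mask, com = com, r_max = r_max)
}

#' Extract the equatorial plane of a spheroid stack
#'
#' The central plane is the z-slice with the largest spheroid cross-section
#' (area above a global Otsu threshold of the summed-channel stack); the
#' projection is a per-channel maximum-intensity projection over `n_slices`
#' planes centred there (window clamped to the stack bounds).
#'
#' @param stack a [spheroid_stack()].
#' @param n_slices odd number of central planes to project (default 5,
#'   about 1.2 um at a 0.24 um z-step).
#' @return an `equatorial_image`: list with `projections` (`[Y, X, 4]`,
#'   dimnames on channel = roles), `mask`, `com`, `r_max`, `z_index`,
#'   `pixel_size_um`, `spheroid_id`.
#' @export
equatorial_projection <- function(stack, n_slices = 5L) {
  d <- dim(stack$voxels)
  z <- d[3]
  n_slices <- as.integer(n_slices)
  if (n_slices < 1L || n_slices > z)
    stop("n_slices must be between 1 and Z = ", z)
  if (n_slices %% 2L == 0L) stop("n_slices must be odd")
  # per-channel background and Otsu threshold over the whole stack; the
  # cross-section at z is the union of above-threshold voxels of any channel
  occupied <- array(FALSE, d[1:3])
  any_signal <- FALSE
  for (ci in 1:4) {
    ch <- stack$voxels[, , , ci, drop = TRUE]
    dim(ch) <- d[1:3]
    bg <- quantile_lower(as.vector(ch), 0.05)
    ch <- pmax(ch - bg, 0)
    if (max(ch) <= 0) next
    any_signal <- TRUE
    occupied <- occupied | (ch > otsu_threshold(ch))
  }
  if (!any_signal) stop("no spheroid detected: stack has no signal")
  areas <- apply(occupied, 3, sum)
  z_star <- which.max(areas)
  half <- (n_slices - 1L) %/% 2L
  lo <- z_star - half; hi <- z_star + half
  if (lo < 1L) { hi <- hi + (1L - lo); lo <- 1L }
  if (hi > z) { lo <- lo - (hi - z); hi <- z }
  lo <- max(lo, 1L)
  proj <- array(0, c(d[1], d[2], 4L))
  roles <- names(stack$channel_map)[order(stack$channel_map)]
  for (ci in 1:4) {
    sl <- stack$voxels[, , lo:hi, ci, drop = FALSE]
    proj[, , ci] <- apply(sl, c(1, 2), max)
  }
  # reorder channel planes into canonical role order
  proj <- proj[, , stack$channel_map[CHANNEL_ROLES], drop = FALSE]
  dimnames(proj) <- list(NULL, NULL, CHANNEL_ROLES)
  msk <- spheroid_mask(proj)
  structure(list(projections = proj, mask = msk$mask, com = msk$com,
                 r_max = msk$r_max, z_index = z_star,
                 pixel_size_um = stack$pixel_size_um,
                 spheroid_id = stack$spheroid_id),
            class = "equatorial_image")
}

#' @export
print.equatorial_image <- function(x, ...) {
  cat(sprintf("<equatorial_image '%s'> %dx%d px, z* = %d, com = (%.2f, %.2f), r_max = %d px\n",
              x$spheroid_id, dim(x$projections)[1], dim(x$projections)[2],
              x$z_index, x$com[1], x$com[2], x$r_max))
  invisible(x)
}

#' Circularity of a binary region
#'
#' `4 * pi * Area / Perimeter^2`, clipped to `[0, 1]`. The perimeter is the
#' Freeman chain-code estimate on the region contour (axial steps count 1,
#' diagonal steps `sqrt(2)`), which is exactly invariant under 90-degree
#' rotations of the mask.
#'
#' @param mask non-empty logical matrix.
#' @return circularity in `[0, 1]` (1 for an ideal circle).
#' @export
shape_circularity <- function(mask) {
  mask_circularity(mask)
}

#' Actin-belt shape parameters
#'
#' The belt comprises the most intense actin signals — pixels inside the
#' spheroid mask whose intensity exceeds the 90th-percentile order statistic
#' of the masked actin channel. Particles are 8-connected components of at
#' least `min_particle_px` pixels.
#'
#' @param eq an [equatorial_projection()] result.
#' @param belt_quantile intensity quantile defining "most intense" (0.90).
#' @param min_particle_px minimum particle area in px (10).
#' @return list with `actin_rel_area` (belt area / spheroid area),
#'   `actin_particle_count`, `actin_circularity` (largest particle; 0 when
#'   no particle) and `belt_mask`.
#' @export
actin_belt <- function(eq, belt_quantile = 0.90, min_particle_px = 10L) {
  actin <- eq$projections[, , "actin"]
  inside <- actin[eq$mask]
  q <- quantile_lower(inside, belt_quantile)
  belt <- eq$mask & (actin > q)
  rel_area <- sum(belt) / sum(eq$mask)
  if (!any(belt)) {
    warning("empty actin belt")
    return(list(actin_rel_area = 0, actin_particle_count = 0L,
                actin_circularity = 0, belt_mask = belt))
  }
  lab <- EBImage::bwlabel(belt)
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(sizes >= min_particle_px)
  count <- length(keep)
  circ <- 0
  if (count > 0) {
    biggest <- keep[which.max(sizes[keep])]
    circ <- mask_circularity(lab == biggest)
  }
  list(actin_rel_area = rel_area, actin_particle_count = count,
       actin_circularity = circ, belt_mask = belt)
}

#' Nuclear positions, count and circularity
#'
#' Nuclei are segmented in the nuclei projection restricted to the spheroid
#' mask (Otsu threshold on the background-subtracted channel), touching
#' nuclei are split by a distance-map watershed, and objects of at least
#' `min_nucleus_px` pixels are accepted. The centre of mass is the
#' intensity-weighted centroid of the segmented union; the circularity is
#' that of the union's convex hull (how circularly the nuclei are arranged).
#'
#' @param eq an [equatorial_projection()] result.
#' @param min_nucleus_px minimum accepted object area (default 9 px).
#' @return list with `nuclei_count`, `nuclei_circularity`, `com_nuclei`
#'   (`c(x, y)`, 0-based) and `nuclei_mask`.
#' @export
nuclei_analysis <- function(eq, min_nucleus_px = 9L) {
  nuc <- eq$projections[, , "nuclei"]
  bg <- quantile_lower(nuc, 0.05)
  nucs <- pmax(nuc - bg, 0)
  if (max(nucs[eq$mask]) <= 0) stop("no nuclei detected")
  th <- otsu_threshold(nucs)
  nmask <- eq$mask & (nucs > th)
  if (!any(nmask)) stop("no nuclei detected")
  dm <- EBImage::distmap(nmask)
  ws <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  sizes <- tabulate(ws[ws > 0], nbins = max(ws))
  count <- sum(sizes >= min_nucleus_px)
  if (count == 0L) stop("no nuclei detected")
  w <- nucs * nmask
  d <- dim(nucs)
  xs <- matrix(rep(0:(d[2] - 1L), each = d[1]), d[1], d[2])
  ys <- matrix(rep(0:(d[1] - 1L), times = d[2]), d[1], d[2])
  com_nuclei <- c(sum(xs * w), sum(ys * w)) / sum(w)
  idx <- which(nmask)
  circ <- hull_circularity(cbind(xs[idx], ys[idx]))
  list(nuclei_count = count, nuclei_circularity = circ,
       com_nuclei = com_nuclei, nuclei_mask = nmask)
}

#' All descriptive shape parameters of one equatorial image
#'
#' Bundles the spheroid-, actin- and nuclei-derived shape descriptors used
#' by the 15-feature vector.
#'
#' @param eq an [equatorial_projection()] result.
#' @return list of class `shape_params`: `spheroid_area_px2`,
#'   `spheroid_circularity`, `nuclei_circularity`, `nuclei_count`,
#'   `com_nuclei`, `com_distance_rel`, `actin_rel_area`,
#'   `actin_particle_count`, `actin_circularity`.
#' @export
shape_params <- function(eq) {
  ab <- actin_belt(eq)
  na <- nuclei_analysis(eq)
  structure(list(
    spheroid_area_px2 = sum(eq$mask),
    spheroid_circularity = shape_circularity(eq$mask),
    nuclei_circularity = na$nuclei_circularity,
    nuclei_count = na$nuclei_count,
    com_nuclei = na$com_nuclei,
    com_distance_rel = sqrt(sum((na$com_nuclei - eq$com)^2)) / eq$r_max,
    actin_rel_area = ab$actin_rel_area,
    actin_particle_count = ab$actin_particle_count,
    actin_circularity = ab$actin_circularity), class = "shape_params")
}
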