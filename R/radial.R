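# Polar transformation and radial intensity-profile features.
#
# Every pixel is assigned an integer radius bin — its rounded Euclidean
# distance from the spheroid centre of mass — making the intensity profile
# angle-independent. Per radius, intensities are integrated and divided by
# the pixel count at that radius (so a thin ring and a full annulus with the
# same per-pixel brightness contribute equally), then normalised by the
# channel total; the running sum over radii is the cumulative intensity
# curve. The radius at 60% of total intensity summarises a marker's radial
# position; the chord slope of the nuclear curve at 30% of the spheroid
# radius reports nuclei inside the expected luminal area.

#' Integer polar radius of pixels
#'
#' `round(sqrt((x - X_com)^2 + (y - Y_com)^2))` with half-away-from-zero
#' rounding (banker's rounding would change bin membership).
#'
#' @param x,y pixel coordinates (0-based, vectors of equal length).
#' @param com centre of mass `c(x, y)`.
#' @return integer radius bins.
#' @export
#' @examples
#' polar_radius(3, 4, c(0, 0)) # 5
polar_radius <- function(x, y, com) {
  as.integer(floor(sqrt((x - com[1])^2 + (y - com[2])^2) + 0.5))
}

#' Radial intensity profile of one channel
#'
#' @param projection non-negative intensity matrix (one channel of an
#'   equatorial image).
#' @param com centre of mass `c(x, y)` (0-based, sub-pixel).
#' @param r_max maximum radius in px; pixels with a larger radius bin are
#'   excluded.
#' @return a `radial_profile`: list with `mean_intensity` (per-radius mean,
#'   index 1 = radius 0; empty bins are 0), `cumulative` (normalised
#'   non-decreasing curve ending at 1), `rel_radius` (radius / r_max),
#'   `r_max`, and `zero_signal` flag (all-zero channel: cumulative is all 0
#'   with a warning).
#' @export
radial_profile <- function(projection, com, r_max) {
  stopifnot(r_max >= 1)
  d <- dim(projection)
  xs <- matrix(rep(0:(d[2] - 1L), each = d[1]), d[1], d[2])
  ys <- matrix(rep(0:(d[1] - 1L), times = d[2]), d[1], d[2])
  r <- polar_radius(as.vector(xs), as.vector(ys), com)
  keep <- r <= r_max
  r <- r[keep]
  v <- as.vector(projection)[keep]
  nb <- r_max + 1L
  sums <- numeric(nb)
  cnts <- numeric(nb)
  agg <- rowsum(cbind(v, 1), r)
  bins <- as.integer(rownames(agg)) + 1L
  sums[bins] <- agg[, 1]
  cnts[bins] <- agg[, 2]
  means <- ifelse(cnts > 0, sums / ifelse(cnts > 0, cnts, 1), 0)
  total <- sum(means)
  zero <- total <= 0
  if (zero) {
    warning("all-zero channel: flat cumulative profile")
    cum <- numeric(nb)
  } else {
    cum <- cumsum(means) / total
  }
  structure(list(mean_intensity = means, cumulative = cum,
                 rel_radius = (0:r_max) / r_max, r_max = r_max,
                 zero_signal = zero), class = "radial_profile")
}

# Interpolated cumulative value at an arbitrary relative radius.
profile_cumulative_at <- function(profile, rel) {
  stats::approx(x = profile$rel_radius, y = profile$cumulative,
                xout = min(max(rel, 0), 1), rule = 2)$y
}

#' Relative radius at a fraction of total intensity
#'
#' Smallest relative radius where the cumulative curve reaches `fraction`,
#' refined by linear interpolation between the bracketing radius bins (the
#' curve's 60% point approximates the centre of its linear rise).
#'
#' @param profile a [radial_profile()].
#' @param fraction target fraction of total intensity in (0, 1); 0.60 is the
#'   positional feature used throughout.
#' @return relative radius in `[0, 1]`.
#' @export
radius_at_fraction <- function(profile, fraction = 0.60) {
  stopifnot(fraction > 0, fraction < 1)
  if (profile$zero_signal) stop("no signal: flat cumulative profile")
  cum <- profile$cumulative
  i <- which(cum >= fraction)[1]
  if (is.na(i)) stop("cumulative curve never reaches the requested fraction")
  if (i == 1L) return(0)
  x0 <- profile$rel_radius[i - 1L]; x1 <- profile$rel_radius[i]
  y0 <- cum[i - 1L]; y1 <- cum[i]
  x0 + (fraction - y0) / (y1 - y0) * (x1 - x0)
}

#' Initial chord slope of the nuclear cumulative curve
#'
#' Cumulative nuclear intensity at `cutoff` of the spheroid radius divided
#' by `cutoff`: the slope of the chord from the origin, in units of "per
#' relative radius". A value near 0 means an empty lumen; values above 1
#' mean nuclei are over-represented inside the cutoff (no lumen).
#'
#' @param profile a [radial_profile()] of the nuclei channel.
#' @param cutoff fraction of the spheroid radius in (0, 1); default 0.30.
#' @return slope (>= 0).
#' @export
nuclear_initial_slope <- function(profile, cutoff = 0.30) {
  stopifnot(cutoff > 0, cutoff < 1)
  if (profile$zero_signal) return(0)
  profile_cumulative_at(profile, cutoff) / cutoff
}

#' Polarity-marker position differences
#'
#' `f1 = relpos60(basolateral) - relpos60(apical)`: positive for regular
#' apicobasal polarity (basolateral marker outside), negative for inverse
#' polarity. `f2 = relpos60(actin) - relpos60(apical)` verifies consistency:
#' distinct polarity gives values near 0 (actin belt colocalises with the
#' apical surface), large differences indicate undefined polarity.
#'
#' @param relpos60 named numeric vector with elements `basolateral`,
#'   `apical`, `actin` (and optionally `nuclei`), each in `[0, 1]`.
#' @return named vector `c(f1_delta_gp58_gp135, f2_delta_actin_gp135)`.
#' @export
marker_deltas <- function(relpos60) {
  stopifnot(all(c("basolateral", "apical", "actin") %in% names(relpos60)))
  c(f1_delta_gp58_gp135 = unname(relpos60["basolateral"] - relpos60["apical"]),
    f2_delta_actin_gp135 = unname(relpos60["actin"] - relpos60["apical"]))
}

#' Names of the 15 spheroid features
#'
#' @return character vector of the feature-vector column names, in order.
#' @export
feature_names <- function() {
  c("f1_delta_gp58_gp135", "f2_delta_actin_gp135",
    "f3_relpos60_gp58", "f4_relpos60_gp135", "f5_relpos60_actin",
    "f6_relpos60_nuclei", "f7_spheroid_circularity",
    "f8_nuclei_circularity", "f9_nuclear_initial_slope",
    "f10_actin_rel_area", "f11_actin_particle_count",
    "f12_actin_circularity", "f13_nuclei_count", "f14_com_distance_rel",
    "f15_r_max_um")
}

#' Radial feature configuration
#'
#' @param position_fraction fraction of total intensity defining the
#'   positional features (0.60).
#' @param slope_cutoff_fraction radius fraction for the nuclear initial
#'   slope (0.30).
#' @return list of class `radial_config`.
#' @export
radial_config <- function(position_fraction = 0.60,
                          slope_cutoff_fraction = 0.30) {
  stopifnot(position_fraction > 0, position_fraction < 1,
            slope_cutoff_fraction > 0, slope_cutoff_fraction < 1)
  structure(list(position_fraction = position_fraction,
                 slope_cutoff_fraction = slope_cutoff_fraction),
            class = "radial_config")
}

#' Radial profiles of all four channels
#'
#' Profiles are computed on background-subtracted projections (per-channel
#' 5th-percentile order statistic, floored at 0) so that the constant camera
#' background does not flatten the cumulative curves.
#'
#' @param eq an [equatorial_projection()] result.
#' @param background_quantile per-channel background percentile.
#' @return named list of [radial_profile()], one per channel role.
#' @export
radial_profiles <- function(eq, background_quantile = 0.05) {
  setNames(lapply(CHANNEL_ROLES, function(role) {
    ch <- eq$projections[, , role]
    bg <- quantile_lower(ch, background_quantile)
    radial_profile(pmax(ch - bg, 0), eq$com, eq$r_max)
  }), CHANNEL_ROLES)
}

#' Assemble the 15-feature vector of one spheroid
#'
#' Features: (1) basolateral-apical 60%-position difference, (2)
#' actin-apical difference, (3-6) per-channel 60% positions, (7) spheroid
#' circularity, (8) nuclei circularity, (9) nuclear initial slope, (10)
#' relative actin area, (11) actin particle count, (12) actin circularity,
#' (13) nuclei count, (14) relative distance of nuclear to spheroid centre
#' of mass, (15) maximum radius in micrometres. By construction
#' `f1 = f3 - f4` and `f2 = f5 - f4` exactly.
#'
#' @param eq an [equatorial_projection()] result.
#' @param shapes optional precomputed [shape_params()]; computed if `NULL`.
#' @param profiles optional precomputed [radial_profiles()].
#' @param cfg a [radial_config()].
#' @return named numeric vector of length 15 (see [feature_names()]); never
#'   contains `NA`/`NaN`.
#' @export
feature_vector <- function(eq, shapes = NULL, profiles = NULL,
                           cfg = radial_config()) {
  if (is.null(shapes)) shapes <- shape_params(eq)
  if (is.null(profiles)) profiles <- radial_profiles(eq)
  relpos <- vapply(profiles, radius_at_fraction,
                   numeric(1), fraction = cfg$position_fraction)
  deltas <- marker_deltas(relpos)
  f <- c(deltas["f1_delta_gp58_gp135"], deltas["f2_delta_actin_gp135"],
         f3_relpos60_gp58 = unname(relpos["basolateral"]),
         f4_relpos60_gp135 = unname(relpos["apical"]),
         f5_relpos60_actin = unname(relpos["actin"]),
         f6_relpos60_nuclei = unname(relpos["nuclei"]),
         f7_spheroid_circularity = shapes$spheroid_circularity,
         f8_nuclei_circularity = shapes$nuclei_circularity,
         f9_nuclear_initial_slope = nuclear_initial_slope(
           profiles$nuclei, cfg$slope_cutoff_fraction),
         f10_actin_rel_area = shapes$actin_rel_area,
         f11_actin_particle_count = as.numeric(shapes$actin_particle_count),
         f12_actin_circularity = shapes$actin_circularity,
         f13_nuclei_count = as.numeric(shapes$nuclei_count),
         f14_com_distance_rel = shapes$com_distance_rel,
         f15_r_max_um = eq$r_max * eq$pixel_size_um)
  names(f) <- feature_names()
  if (any(!is.finite(f))) stop("non-finite feature computed")
  f
}

#' Extract the feature table of a dataset
#'
#' Runs the full engineered pipeline (equatorial projection, shape
#' parameters, radial profiles, feature assembly) over a list of stacks or a
#' [generate_dataset()] result.
#'
#' @param x a `labelled_dataset`, or a list of [spheroid_stack()].
#' @param n_slices passed to [equatorial_projection()].
#' @param cfg a [radial_config()].
#' @return data.frame with `spheroid_id`, columns `f1..f15` (named as in
#'   [feature_names()]) and, when labels are known, `fine_label` and
#'   `coarse_label`.
#' @export
extract_features <- function(x, n_slices = 5L, cfg = radial_config()) {
  if (inherits(x, "labelled_dataset")) {
    stacks <- lapply(x$spheroids, `[[`, "stack")
    fine <- vapply(x$spheroids, `[[`, character(1), "fine_label")
  } else {
    stacks <- x
    fine <- NULL
  }
  rows <- lapply(stacks, function(st) {
    eq <- equatorial_projection(st, n_slices)
    fv <- feature_vector(eq, cfg = cfg)
    cbind(data.frame(spheroid_id = st$spheroid_id, stringsAsFactors = FALSE),
          as.data.frame(as.list(fv)))
  })
  out <- do.call(rbind, rows)
  if (!is.null(fine)) {
    out$fine_label <- fine
    out$coarse_label <- coarse_label(fine)
  }
  out
}

#' Write / read a feature table CSV
#'
#' One row per spheroid, `spheroid_id` then `f1..f15` in the deterministic
#' order of [feature_names()]; round-trips losslessly (full precision).
#'
#' @param features data.frame from [extract_features()].
#' @param path CSV path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(format(features, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (fn in intersect(feature_names(), names(df))) df[[fn]] <- as.numeric(df[[fn]])
  df
}
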