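# Synthetic four-channel spheroid z-stacks for all polarity groups.
#
# The generator emulates the equatorial geometry that defines the polarity
# phenotypes: group 1 (regular apicobasal polarity) has a single central
# lumen lined by the apical marker with a pronounced apical actin belt and
# the basolateral marker on the outside; group 2 (inverse) has the apical
# marker and actin ring at the periphery and basolateral signal filling the
# matrix-filled interior; group 3a is an aggregate without lumen (nuclei
# occupy the centre, markers incoherent); group 3b carries several small
# apical/actin-lined lumina. The z-extent is modulated by a spherical-cap
# intensity profile; imaging is emulated by an in-plane Gaussian PSF,
# constant background, Poisson shot noise and additive Gaussian read noise.
# All intensities are integer photon-count-like values (16-bit range).

#' Parameters of the synthetic spheroid generator
#'
#' Defaults mirror the imaging conditions the package targets: 256 x 256 px
#' regions of interest with 50 z-planes, spheroids of 12-24 cells (nuclei),
#' and a z-step of 0.24 um.
#'
#' @param image_size square frame side in px.
#' @param z_planes number of z-slices.
#' @param radius_range_px min/max spheroid radius in px (drawn uniformly).
#' @param lumen_frac_range group-1 lumen radius as a fraction of the
#'   spheroid radius.
#' @param n_nuclei_range min/max number of nuclei (cells).
#' @param n_lumina_range number of lumina for group 3b.
#' @param ring_width_px width of marker rings in px.
#' @param nucleus_sigma_px Gaussian sigma of a nucleus blob in px.
#' @param amplitude peak marker intensity (photon counts).
#' @param psf_sigma_px in-plane Gaussian PSF sigma.
#' @param background constant background level (counts).
#' @param gaussian_noise_sigma additive read-noise sigma (counts); 0 disables.
#' @param poisson_gain photon gain for shot noise; 0 disables shot noise.
#' @param pixel_size_um,z_step_um calibration passed to the stacks.
#' @param noise set `FALSE` to zero out background, shot and read noise
#'   (convenience for noise-free geometry checks).
#' @return list of class `synthetic_params`.
#' @export
synthetic_params <- function(image_size = 256L, z_planes = 50L,
                             radius_range_px = c(40, 80),
                             lumen_frac_range = c(0.3, 0.5),
                             n_nuclei_range = c(12L, 24L),
                             n_lumina_range = c(2L, 4L),
                             ring_width_px = 4,
                             nucleus_sigma_px = NULL,
                             amplitude = 1000,
                             psf_sigma_px = 2,
                             background = 20,
                             gaussian_noise_sigma = 4,
                             poisson_gain = 1,
                             pixel_size_um = 0.103,
                             z_step_um = 0.24,
                             noise = TRUE) {
  if (!noise) {
    background <- 0; gaussian_noise_sigma <- 0; poisson_gain <- 0
  }
  if (max(radius_range_px) >= image_size / 2)
    stop("spheroid radius must fit inside the frame")
  if (max(lumen_frac_range) >= 1)
    stop("lumen radius must be smaller than the spheroid radius")
  if (is.null(nucleus_sigma_px))
    nucleus_sigma_px <- max(2, min(radius_range_px) / 14)
  structure(list(
    image_size = as.integer(image_size), z_planes = as.integer(z_planes),
    radius_range_px = radius_range_px, lumen_frac_range = lumen_frac_range,
    n_nuclei_range = as.integer(n_nuclei_range),
    n_lumina_range = as.integer(n_lumina_range),
    ring_width_px = ring_width_px, nucleus_sigma_px = nucleus_sigma_px,
    amplitude = amplitude, psf_sigma_px = psf_sigma_px,
    background = background, gaussian_noise_sigma = gaussian_noise_sigma,
    poisson_gain = poisson_gain, pixel_size_um = pixel_size_um,
    z_step_um = z_step_um), class = "synthetic_params")
}

# Distance-from-centre matrix for a size x size frame, centre (cx, cy)
# in 0-based pixel coordinates.
dist_matrix <- function(size, cx, cy) {
  x <- matrix(rep(0:(size - 1L), each = size), size, size)
  y <- matrix(rep(0:(size - 1L), times = size), size, size)
  sqrt((x - cx)^2 + (y - cy)^2)
}

ring_template <- function(dist, r0, width, amp) {
  amp * (abs(dist - r0) <= width / 2)
}

disc_template <- function(dist, r0, amp) {
  amp * (dist <= r0)
}

gaussian_blob <- function(size, cx, cy, sigma, amp) {
  x <- matrix(rep(0:(size - 1L), each = size), size, size)
  y <- matrix(rep(0:(size - 1L), times = size), size, size)
  amp * exp(-((x - cx)^2 + (y - cy)^2) / (2 * sigma^2))
}

# Place n nuclei on a ring of radius r_ring (evenly spaced angles with
# jitter) or scattered over a disc of radius r_disc (Poisson-disc style
# rejection with a minimum spacing). Disc placement draws the radius as
# r_disc * u^centre_weight; exponents above 0.5 oversample the core
# relative to a uniform-by-area draw. Aggregates without a lumen pack
# cells into the core, which is what the nuclear initial-slope feature
# detects downstream.
nuclei_centres <- function(n, cx, cy, r_ring = NULL, r_disc = NULL,
                           min_sep = 6, centre_weight = 0.8) {
  if (!is.null(r_ring)) {
    ang <- (seq_len(n) - 1) * 2 * pi / n + runif(1, 0, 2 * pi) +
      runif(n, -0.25, 0.25) * 2 * pi / n
    return(cbind(cx + r_ring * cos(ang), cy + r_ring * sin(ang)))
  }
  pts <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(pts) < n && tries < 4000L) {
    tries <- tries + 1L
    rr <- r_disc * runif(1)^centre_weight; aa <- runif(1, 0, 2 * pi)
    cand <- c(cx + rr * cos(aa), cy + rr * sin(aa))
    if (nrow(pts) == 0L ||
        min(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)) >= min_sep)
      pts <- rbind(pts, cand)
  }
  pts
}

# Noise-free equatorial template [Y, X, 4] (role order: basolateral,
# apical, actin, nuclei) plus per-spheroid geometry draws.
spheroid_template <- function(group, p) {
  size <- p$image_size
  jit <- size * 0.02
  cx <- (size - 1) / 2 + runif(1, -jit, jit)
  cy <- (size - 1) / 2 + runif(1, -jit, jit)
  R <- runif(1, p$radius_range_px[1], p$radius_range_px[2])
  dist <- dist_matrix(size, cx, cy)
  w <- p$ring_width_px
  A <- p$amplitude
  baso <- apical <- actin <- nuc <- matrix(0, size, size)
  geom <- list(cx = cx, cy = cy, radius = R, lumen_frac = NA, n_lumina = NA)

  n_nuc <- sample(seq(p$n_nuclei_range[1], p$n_nuclei_range[2]), 1)
  geom$n_nuclei <- n_nuc

  if (group == "1_regular") {
    lf <- runif(1, p$lumen_frac_range[1], p$lumen_frac_range[2])
    geom$lumen_frac <- lf
    r_lumen <- lf * R
    apical <- ring_template(dist, r_lumen, w, A)
    actin <- ring_template(dist, r_lumen + w / 2, w, A)
    baso <- ring_template(dist, R, w, A) +
      0.2 * A * (dist > r_lumen + w & dist < R - w / 2)
    ctr <- nuclei_centres(n_nuc, cx, cy, r_ring = (r_lumen + R) / 2)
  } else if (group == "2_inverse") {
    apical <- ring_template(dist, R, w, A)
    actin <- ring_template(dist, R - w / 2, w, A)
    baso <- disc_template(dist, 0.75 * R, A)
    ctr <- nuclei_centres(n_nuc, cx, cy, r_ring = 0.6 * R)
  } else if (group == "3a_aggregate") {
    # incoherent low-contrast markers: shared diffuse disc plus random blobs
    diffuse <- disc_template(dist, R, 0.25 * A)
    blobs <- function() {
      m <- matrix(0, size, size)
      for (i in 1:6) {
        rr <- R * sqrt(runif(1)); aa <- runif(1, 0, 2 * pi)
        m <- m + gaussian_blob(size, cx + rr * cos(aa), cy + rr * sin(aa),
                               R / 5, 0.35 * A)
      }
      m * (dist <= R)
    }
    baso <- diffuse + blobs()
    apical <- diffuse + blobs()
    actin <- diffuse + blobs()
    ctr <- nuclei_centres(n_nuc, cx, cy, r_disc = 0.85 * R,
                          min_sep = 4 * p$nucleus_sigma_px * 0.8)
  } else if (group == "3b_multilumen") {
    nl <- sample(seq(p$n_lumina_range[1], p$n_lumina_range[2]), 1)
    geom$n_lumina <- nl
    baso <- ring_template(dist, R, w, A) +
      0.15 * A * (dist < R - w / 2)
    r_lum <- runif(nl, 0.12, 0.18) * R
    # lumen centres on an inner ring at evenly spaced angles (with jitter):
    # guarantees the requested number of well-separated apical/actin rings
    lang <- (seq_len(nl) - 1) * 2 * pi / nl + runif(1, 0, 2 * pi) +
      runif(nl, -0.15, 0.15) * 2 * pi / nl
    lrad <- runif(nl, 0.4, 0.5) * R
    lcent <- cbind(cx + lrad * cos(lang), cy + lrad * sin(lang))
    for (i in seq_len(nrow(lcent))) {
      dl <- dist_matrix(size, lcent[i, 1], lcent[i, 2])
      apical <- apical + ring_template(dl, r_lum[i], w, A)
      actin <- actin + ring_template(dl, r_lum[i] + w / 2, w, A)
    }
    ctr <- nuclei_centres(n_nuc, cx, cy, r_disc = 0.85 * R,
                          min_sep = 4 * p$nucleus_sigma_px * 0.8)
  } else {
    stop("unknown group: ", group)
  }

  for (i in seq_len(nrow(ctr)))
    nuc <- nuc + gaussian_blob(size, ctr[i, 1], ctr[i, 2],
                               p$nucleus_sigma_px, 0.8 * A)
  tmpl <- array(0, c(size, size, 4L))
  tmpl[, , 1] <- baso; tmpl[, , 2] <- apical
  tmpl[, , 3] <- actin; tmpl[, , 4] <- nuc
  list(template = tmpl, geom = geom)
}

#' Generate one synthetic spheroid stack
#'
#' @param group fine polarity label: `"1_regular"`, `"2_inverse"`,
#'   `"3a_aggregate"` or `"3b_multilumen"`.
#' @param params a [synthetic_params()] object.
#' @param seed integer seed; identical seeds give bit-identical stacks.
#' @param spheroid_id identifier for the stack.
#' @return list with `stack` (a [spheroid_stack()]), `fine_label`,
#'   `coarse_label` and `geometry` (the per-spheroid parameter draws).
#' @export
generate_spheroid <- function(group, params = synthetic_params(), seed = 1L,
                              spheroid_id = NULL) {
  group <- match.arg(group, FINE_LABELS)
  p <- params
  withr::with_seed(as.integer(seed), {
    sp <- spheroid_template(group, p)
    tmpl <- sp$template
    if (p$psf_sigma_px > 0)
      for (ci in 1:4)
        tmpl[, , ci] <- EBImage::gblur(tmpl[, , ci], sigma = p$psf_sigma_px)
    z <- p$z_planes
    zc <- (z + 1) / 2
    half <- max(zc - 1, 1)
    wz <- sqrt(pmax(0, 1 - ((seq_len(z) - zc) / (half + 0.5))^2))
    vox <- array(0, c(p$image_size, p$image_size, z, 4L))
    for (zi in seq_len(z)) for (ci in 1:4) {
      plane <- tmpl[, , ci] * wz[zi] + p$background
      if (p$poisson_gain > 0) {
        plane <- rpois(length(plane), lambda = pmax(plane * p$poisson_gain, 0)) /
          p$poisson_gain
      }
      if (p$gaussian_noise_sigma > 0)
        plane <- plane + rnorm(length(plane), 0, p$gaussian_noise_sigma)
      vox[, , zi, ci] <- matrix(pmin(pmax(round(plane), 0), 65535),
                                p$image_size, p$image_size)
    }
    if (is.null(spheroid_id)) spheroid_id <- sprintf("%s_seed%d", group, seed)
    stk <- spheroid_stack(vox, c(basolateral = 1L, apical = 2L, actin = 3L,
                                 nuclei = 4L),
                          p$pixel_size_um, p$z_step_um, spheroid_id)
    list(stack = stk, fine_label = group, coarse_label = coarse_label(group),
         geometry = sp$geom)
  })
}

#' Generate a labelled synthetic dataset
#'
#' @param class_counts named integer vector of fine labels to counts, e.g.
#'   `c("1_regular" = 40, "2_inverse" = 40, "3a_aggregate" = 30,
#'   "3b_multilumen" = 10)`.
#' @param params a [synthetic_params()].
#' @param seed master seed; per-spheroid seeds are derived from it, so the
#'   whole dataset is reproducible from `(class_counts, params, seed)`.
#' @return list of class `labelled_dataset` with `spheroids` (list of
#'   [generate_spheroid()] results) and `manifest` (one row per stack:
#'   id, labels, seed and geometry draws).
#' @export
generate_dataset <- function(class_counts, params = synthetic_params(),
                             seed = 1L) {
  stopifnot(all(names(class_counts) %in% FINE_LABELS), all(class_counts >= 0))
  groups <- rep(names(class_counts), times = as.integer(class_counts))
  n <- length(groups)
  seeds <- derive_seeds(seed, n)
  spheroids <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("syn_%04d_%s", i, groups[i])
    spheroids[[i]] <- generate_spheroid(groups[i], params, seeds[i], id)
    g <- spheroids[[i]]$geometry
    rows[[i]] <- data.frame(
      spheroid_id = id, fine_label = groups[i],
      coarse_label = coarse_label(groups[i]), seed = seeds[i],
      radius_px = g$radius, lumen_frac = g$lumen_frac,
      n_nuclei = g$n_nuclei, n_lumina = g$n_lumina,
      stringsAsFactors = FALSE)
  }
  structure(list(spheroids = spheroids, manifest = do.call(rbind, rows)),
            class = "labelled_dataset")
}

#' Write a labelled dataset to disk
#'
#' Writes one multi-page TIFF per spheroid plus `manifest.csv` and
#' `labels.csv` (`spheroid_id,fine_label`) consumable by the other tools.
#'
#' @param dataset a [generate_dataset()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in dataset$spheroids)
    write_stack(sp$stack, file.path(dir, paste0(sp$stack$spheroid_id, ".tif")))
  write.csv(dataset$manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  labels <- dataset$manifest[c("spheroid_id", "fine_label")]
  write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}
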