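# Reading/writing spheroid image data and rating tables.
#
# A spheroid stack is stored as a numeric array [Y, X, Z, C] of non-negative
# intensities with a channel-role map {basolateral, apical, actin, nuclei}.
# Multi-page TIFFs carry the planes; the page order is explicit (never
# guessed from file names): with the default `dimension_order = "CZYX"` the
# channel index varies fastest across pages (c1z1, c2z1, ..., c4z1, c1z2, ...),
# with "ZCYX" the z index varies fastest.

#' Construct a spheroid z-stack object
#'
#' @param voxels numeric array `[Y, X, Z, C]` with four channels; all values
#'   finite and non-negative; square frames (Y = X).
#' @param channel_map named integer vector mapping the roles
#'   `basolateral`, `apical`, `actin`, `nuclei` to distinct channel indices.
#' @param pixel_size_um lateral pixel size in micrometres.
#' @param z_step_um z-plane spacing in micrometres (wide-field imaging of the
#'   spheroids this package targets uses 0.24 um).
#' @param spheroid_id identifier string.
#' @return an object of class `spheroid_stack`.
#' @export
spheroid_stack <- function(voxels, channel_map, pixel_size_um = 0.103,
                           z_step_um = 0.24, spheroid_id = "spheroid") {
  stopifnot(is.array(voxels), length(dim(voxels)) == 4L)
  d <- dim(voxels)
  if (d[4] != 4L)
    stop("expected exactly 4 channels, got ", d[4])
  if (d[1] != d[2])
    stop("non-square frames: Y = ", d[1], ", X = ", d[2])
  if (d[3] < 1L) stop("Z must be >= 1")
  if (!all(is.finite(voxels)) || min(voxels) < 0)
    stop("intensities must be finite and non-negative")
  channel_map <- validate_channel_map(channel_map)
  structure(
    list(voxels = voxels, channel_map = channel_map,
         pixel_size_um = pixel_size_um, z_step_um = z_step_um,
         spheroid_id = spheroid_id),
    class = "spheroid_stack")
}

validate_channel_map <- function(channel_map) {
  cm <- as.integer(channel_map[CHANNEL_ROLES])
  names(cm) <- CHANNEL_ROLES
  if (anyNA(cm))
    stop("channel_map must name all four roles: ",
         paste(CHANNEL_ROLES, collapse = ", "))
  if (anyDuplicated(cm) || any(cm < 1L) || any(cm > 4L))
    stop("channel_map must map the four roles to the four distinct indices 1..4")
  cm
}

#' @export
print.spheroid_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<spheroid_stack '%s'> %dx%d px, %d z-planes, 4 channels (%.3f um/px, %.2f um z-step)\n",
              x$spheroid_id, d[1], d[2], d[3], x$pixel_size_um, x$z_step_um))
  invisible(x)
}

#' Extract one channel of a stack by role
#'
#' @param stack a [spheroid_stack()].
#' @param role one of `"basolateral"`, `"apical"`, `"actin"`, `"nuclei"`.
#' @return numeric array `[Y, X, Z]`.
#' @export
stack_channel <- function(stack, role) {
  role <- match.arg(role, CHANNEL_ROLES)
  stack$voxels[, , , stack$channel_map[[role]], drop = TRUE]
}

#' Read a spheroid stack from a multi-page TIFF
#'
#' Intensities are stored as 16-bit samples; the round trip through
#' [write_stack()] is bit-exact for integer intensities in 0..65535.
#'
#' @param path TIFF file path.
#' @param channel_map named role-to-index map (see [spheroid_stack()]).
#' @param pixel_size_um,z_step_um,spheroid_id calibration and identifier
#'   (TIFF metadata is not relied on).
#' @param dimension_order `"CZYX"` (channel varies fastest across pages,
#'   default) or `"ZCYX"`.
#' @return a [spheroid_stack()].
#' @export
read_stack <- function(path, channel_map, pixel_size_um = 0.103,
                       z_step_um = 0.24, spheroid_id = NULL,
                       dimension_order = c("CZYX", "ZCYX")) {
  dimension_order <- match.arg(dimension_order)
  if (!file.exists(path)) stop("file not found: ", path)
  channel_map <- validate_channel_map(channel_map)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  n <- length(pages)
  if (n %% 4L != 0L)
    stop("page count not divisible by 4 channels: ", n, " pages")
  z <- n %/% 4L
  d <- dim(pages[[1]])
  if (d[1] != d[2])
    stop("non-square frames: Y = ", d[1], ", X = ", d[2])
  vox <- array(0, dim = c(d[1], d[2], z, 4L))
  for (i in seq_len(n)) {
    if (!identical(dim(pages[[i]]), d))
      stop("page ", i, " has inconsistent dimensions")
    if (dimension_order == "CZYX") {
      ci <- (i - 1L) %% 4L + 1L
      zi <- (i - 1L) %/% 4L + 1L
    } else {
      zi <- (i - 1L) %% z + 1L
      ci <- (i - 1L) %/% z + 1L
    }
    vox[, , zi, ci] <- round(pages[[i]] * 65535)
  }
  if (is.null(spheroid_id))
    spheroid_id <- sub("\\.tiff?$", "", basename(path), ignore.case = TRUE)
  spheroid_stack(vox, channel_map, pixel_size_um, z_step_um, spheroid_id)
}

#' Write a spheroid stack to a multi-page TIFF
#'
#' @param stack a [spheroid_stack()]; intensities are clipped to 0..65535 and
#'   written as 16-bit samples.
#' @param path output file path.
#' @param dimension_order page order, as in [read_stack()].
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, dimension_order = c("CZYX", "ZCYX")) {
  dimension_order <- match.arg(dimension_order)
  d <- dim(stack$voxels)
  z <- d[3]
  pages <- vector("list", 4L * z)
  for (ci in 1:4) for (zi in seq_len(z)) {
    idx <- if (dimension_order == "CZYX") (zi - 1L) * 4L + ci else (ci - 1L) * z + zi
    pages[[idx]] <- pmin(pmax(stack$voxels[, , zi, ci], 0), 65535) / 65535
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Crop square regions of interest out of a multi-spheroid stack
#'
#' Boxes are axis-aligned squares given in 1-based pixel coordinates; crops
#' are verbatim across all channels and z-planes.
#'
#' @param multi_stack a [spheroid_stack()] possibly holding several spheroids.
#' @param boxes list of boxes, each a list/vector with `x`, `y` (top-left
#'   corner) and `size` (side length in px).
#' @return list of [spheroid_stack()], one per box.
#' @export
split_rois <- function(multi_stack, boxes) {
  d <- dim(multi_stack$voxels)
  lapply(seq_along(boxes), function(i) {
    b <- as.list(boxes[[i]])
    x0 <- as.integer(b$x); y0 <- as.integer(b$y); s <- as.integer(b$size)
    if (s < 1L) stop("box ", i, ": size must be positive")
    if (x0 < 1L || y0 < 1L || x0 + s - 1L > d[2] || y0 + s - 1L > d[1])
      stop("box ", i, " extends past the image bounds")
    spheroid_stack(
      multi_stack$voxels[y0:(y0 + s - 1L), x0:(x0 + s - 1L), , , drop = FALSE],
      multi_stack$channel_map, multi_stack$pixel_size_um, multi_stack$z_step_um,
      paste0(multi_stack$spheroid_id, "_roi", i))
  })
}

#' Convert an equatorial projection to an 8-bit RGB image
#'
#' Channel routing follows the reduction used for the convolutional branch:
#' basolateral marker to green, nuclei to blue, and either the apical marker
#' or actin to red. Each channel is independently min-max rescaled to 0..255
#' (floor rounding); a constant channel maps to zeros with a warning.
#'
#' @param eq an [equatorial_projection()] result.
#' @param apical_source `"apical"` (default) or `"actin"`: the red channel.
#' @param label optional polarity label attached to the image.
#' @return an `rgb_image`: integer array `[H, W, 3]` in 0..255 with
#'   attributes `label` (fine label or `NA`) and `apical_source`.
#' @export
to_rgb <- function(eq, apical_source = c("apical", "actin"), label = NA_character_) {
  apical_source <- match.arg(apical_source)
  chans <- list(red = eq$projections[, , apical_source],
                green = eq$projections[, , "basolateral"],
                blue = eq$projections[, , "nuclei"])
  d <- dim(chans$red)
  out <- array(0L, dim = c(d[1], d[2], 3L))
  for (k in 1:3) {
    ch <- chans[[k]]
    rng <- range(ch)
    if (rng[2] > rng[1]) {
      out[, , k] <- pmin(255L, as.integer(floor((ch - rng[1]) / (rng[2] - rng[1]) * 256)))
    } else {
      warning("constant ", names(chans)[k], " channel mapped to zeros")
    }
  }
  structure(out, label = label, apical_source = apical_source, class = "rgb_image")
}

#' Write an RGB image as 8-bit PNG
#'
#' @param img an `rgb_image` from [to_rgb()] (or any `[H, W, 3]` array in
#'   0..255).
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_rgb_png <- function(img, path) {
  png::writePNG(unclass(img) / 255, path)
  invisible(path)
}

#' Read an 8-bit RGB PNG back into an `rgb_image`
#'
#' @param path PNG path.
#' @param label optional fine polarity label to attach.
#' @return an `rgb_image` (integer array `[H, W, 3]`, 0..255).
#' @export
read_rgb_png <- function(path, label = NA_character_) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  structure(array(as.integer(round(px[, , 1:3] * 255)), dim = c(dim(px)[1:2], 3L)),
            label = label, apical_source = NA_character_, class = "rgb_image")
}

#' Read a channel-role configuration file
#'
#' The mapping of staining roles to channel indices is declared explicitly in
#' a YAML or JSON file (keys `basolateral`, `apical`, `actin`, `nuclei`;
#' optional `dimension_order`, `pixel_size_um`, `z_step_um`), never inferred
#' from file names.
#'
#' @param path configuration file (`.yaml`/`.yml` or `.json`).
#' @return list with `channel_map` (named integer vector) and any calibration
#'   keys present.
#' @export
read_channel_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cm <- validate_channel_map(unlist(cfg[CHANNEL_ROLES]))
  out <- list(channel_map = cm)
  for (k in c("dimension_order", "pixel_size_um", "z_step_um"))
    if (!is.null(cfg[[k]])) out[[k]] <- cfg[[k]]
  out
}

#' Read a long-form rating table
#'
#' @param path CSV with header `spheroid_id,rater,label`.
#' @return data.frame with character columns `spheroid_id`, `rater`, `label`.
#' @export
read_ratings_csv <- function(path) {
  df <- read.csv(path, colClasses = "character")
  need <- c("spheroid_id", "rater", "label")
  if (!all(need %in% names(df)))
    stop("ratings CSV must have columns: ", paste(need, collapse = ", "))
  df[need]
}

#' Read a sidecar label table
#'
#' @param path CSV with header `spheroid_id,fine_label`.
#' @return data.frame with columns `spheroid_id`, `fine_label`, `coarse_label`.
#' @export
read_labels_csv <- function(path) {
  df <- read.csv(path, colClasses = "character")
  if (!all(c("spheroid_id", "fine_label") %in% names(df)))
    stop("labels CSV must have columns: spheroid_id, fine_label")
  df$coarse_label <- coarse_label(df$fine_label)
  df[c("spheroid_id", "fine_label", "coarse_label")]
}
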