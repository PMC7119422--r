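# Convolutional branch: classification of 8-bit RGB equatorial projections.
#
# Transfer-learning structure at desk scale: a small, *frozen* convolutional
# backbone provides the feature representation and only the replaced dense
# classification head is (re)trained, with stochastic gradient descent with
# momentum at the configured schedule. The backbone is a fixed
# random-feature convolutional network (He-initialised filters from a fixed
# seed): two conv/ReLU/max-pool stages whose flattened activations feed the
# head. Random convolutional features are a standard lightweight feature
# map; freezing them mirrors the usual transfer-learning recipe of
# retraining only the final layers. Everything is plain R matrix algebra,
# so results are deterministic given the seeds.

#' CNN training configuration
#'
#' Defaults are the training schedule used throughout: 15 epochs, batch
#' size 80, learning rate 3e-3, stochastic gradient descent with momentum
#' 0.9. The batch size is auto-reduced when the training set is smaller
#' than one batch.
#'
#' @param epochs full passes over the training data (>= 1).
#' @param batch_size spheroids per gradient step.
#' @param learning_rate SGDM learning rate.
#' @param momentum SGDM momentum coefficient.
#' @param input_size `c(H, W)` the backbone input; images are resized to it
#'   bilinearly.
#' @param label_set class labels (default the four fine labels).
#' @param seed seed for the head initialisation, shuffling and holdout split.
#' @return list of class `cnn_training_config`.
#' @export
cnn_training_config <- function(epochs = 15L, batch_size = 80L,
                                learning_rate = 3e-3, momentum = 0.9,
                                input_size = c(32L, 32L),
                                label_set = FINE_LABELS, seed = 1L) {
  stopifnot(epochs >= 1L, batch_size >= 1L, learning_rate > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 input_size = as.integer(input_size),
                 label_set = label_set, seed = as.integer(seed)),
            class = "cnn_training_config")
}

#' Augmentation configuration
#'
#' Random rotation between 45 and 315 degrees and scaling between 0.4 and
#' 1.2, boosting every label class to `target_per_label` images (the class
#' balance the training schedule assumes).
#'
#' @param rotation_range_deg `c(min, max)` rotation in degrees.
#' @param scale_range `c(min, max)` isotropic scale factors.
#' @param target_per_label images per label after augmentation (>= 1).
#' @param seed seed for the sampled transforms.
#' @return list of class `augmentation_config`.
#' @export
augmentation_config <- function(rotation_range_deg = c(45, 315),
                                scale_range = c(0.4, 1.2),
                                target_per_label = 600L, seed = 1L) {
  stopifnot(rotation_range_deg[1] <= rotation_range_deg[2],
            scale_range[1] <= scale_range[2], scale_range[1] > 0,
            target_per_label >= 1L)
  structure(list(rotation_range_deg = rotation_range_deg,
                 scale_range = scale_range,
                 target_per_label = as.integer(target_per_label),
                 seed = as.integer(seed)),
            class = "augmentation_config")
}

# Rotate + scale one [H, W, 3] image about its centre, returning the same
# size (cropped/padded with black).
transform_rgb <- function(px, angle_deg, scale) {
  d <- dim(px)
  img <- EBImage::Image(aperm(unclass(px), c(2, 1, 3)) / 255, colormode = "Color")
  if (scale != 1) {
    img <- EBImage::resize(img, w = max(1L, round(d[2] * scale)),
                           h = max(1L, round(d[1] * scale)))
    dw <- dim(img)[1]; dh <- dim(img)[2]
    canvas <- EBImage::Image(array(0, c(d[2], d[1], 3L)), colormode = "Color")
    ox <- (d[2] - dw) %/% 2L; oy <- (d[1] - dh) %/% 2L
    sx <- max(1L, 1L - ox); sy <- max(1L, 1L - oy)
    ex <- min(dw, d[2] - ox); ey <- min(dh, d[1] - oy)
    canvas[(ox + sx):(ox + ex), (oy + sy):(oy + ey), ] <-
      img[sx:ex, sy:ey, , drop = FALSE]
    img <- canvas
  }
  if (angle_deg != 0)
    img <- EBImage::rotate(img, angle_deg, output.dim = c(d[2], d[1]),
                           bg.col = "black")
  out <- aperm(img@.Data, c(2, 1, 3))
  structure(array(as.integer(pmin(pmax(round(out * 255), 0), 255)),
                  dim = d),
            label = attr(px, "label"), apical_source = attr(px, "apical_source"),
            class = "rgb_image")
}

#' Augment a labelled RGB image set to exact class balance
#'
#' Originals are retained; each label class is topped up to
#' `target_per_label` by applying seeded random rotations and scalings to
#' randomly chosen originals of that class. With a degenerate configuration
#' (target equal to the class size, rotation range (0,0), scale (1,1)) the
#' output equals the input.
#'
#' @param images list of `rgb_image` objects.
#' @param labels character vector of labels, one per image.
#' @param cfg an [augmentation_config()].
#' @return list with `images` (list of `rgb_image`) and `labels`; every
#'   label occurs exactly `cfg$target_per_label` times.
#' @export
augment <- function(images, labels, cfg = augmentation_config()) {
  stopifnot(length(images) == length(labels))
  classes <- unique(labels)
  out_imgs <- list(); out_labs <- character(0)
  withr::with_seed(cfg$seed, {
    for (cl in classes) {
      idx <- which(labels == cl)
      if (!length(idx)) stop("empty label class: ", cl)
      if (length(idx) > cfg$target_per_label)
        stop("class ", cl, " already exceeds target_per_label")
      keep <- images[idx]
      n_new <- cfg$target_per_label - length(idx)
      if (n_new > 0) {
        src <- sample(idx, n_new, replace = TRUE)
        ang <- runif(n_new, cfg$rotation_range_deg[1], cfg$rotation_range_deg[2])
        sc <- runif(n_new, cfg$scale_range[1], cfg$scale_range[2])
        aug <- lapply(seq_len(n_new), function(i)
          transform_rgb(images[[src[i]]], ang[i], sc[i]))
        keep <- c(keep, aug)
      }
      out_imgs <- c(out_imgs, keep)
      out_labs <- c(out_labs, rep(cl, length(keep)))
    }
  })
  list(images = out_imgs, labels = out_labs)
}

# ---- backbone ------------------------------------------------------------

he_init <- function(nr, nc, fan_in) {
  matrix(rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

im2col_index <- function(h, w, c, kh, kw) {
  oh <- h - kh + 1L; ow <- w - kw + 1L
  # linear indices into an [h, w, c] array for each patch (column-major)
  patch <- integer(kh * kw * c)
  p <- 1L
  for (ci in seq_len(c)) for (wi in seq_len(kw)) for (hi in seq_len(kh)) {
    patch[p] <- hi + (wi - 1L) * h + (ci - 1L) * h * w
    p <- p + 1L
  }
  base <- integer(oh * ow)
  p <- 1L
  for (wi in seq_len(ow)) for (hi in seq_len(oh)) {
    base[p] <- hi + (wi - 1L) * h
    p <- p + 1L
  }
  list(idx = outer(patch - 1L, base, `+`), oh = oh, ow = ow)
}

conv_forward <- function(x, filt, idx_info) {
  # x: [h, w, c] array (vectorised); filt: [kh*kw*c, n_filters]
  patches <- matrix(x[idx_info$idx], nrow = nrow(idx_info$idx))
  out <- crossprod(patches, filt) # [oh*ow, n_filters]
  array(out, c(idx_info$oh, idx_info$ow, ncol(filt)))
}

maxpool2 <- function(x) {
  d <- dim(x)
  oh <- d[1] %/% 2L; ow <- d[2] %/% 2L
  a <- x[seq_len(2L * oh), seq_len(2L * ow), , drop = FALSE]
  pmax(a[seq(1, 2 * oh, 2), seq(1, 2 * ow, 2), , drop = FALSE],
       a[seq(2, 2 * oh, 2), seq(1, 2 * ow, 2), , drop = FALSE],
       a[seq(1, 2 * oh, 2), seq(2, 2 * ow, 2), , drop = FALSE],
       a[seq(2, 2 * oh, 2), seq(2, 2 * ow, 2), , drop = FALSE])
}

#' Build the frozen convolutional backbone
#'
#' Two convolution/ReLU/max-pool stages with He-initialised filters drawn
#' from `backbone_seed`; the weights are fixed (never updated) and act as
#' the transferred representation whose final layers [retrain()] replaces.
#'
#' @param input_size `c(H, W)` image size the backbone accepts.
#' @param n_filters1,n_filters2 filters in the two stages.
#' @param kernel1,kernel2 square kernel sides.
#' @param backbone_seed seed fixing the filter bank.
#' @return list of class `cnn_backbone` (filters, geometry, feature
#'   dimension).
#' @export
cnn_backbone <- function(input_size = c(32L, 32L), n_filters1 = 12L,
                         n_filters2 = 24L, kernel1 = 5L, kernel2 = 3L,
                         backbone_seed = 20200327L) {
  h <- input_size[1]; w <- input_size[2]
  withr::with_seed(backbone_seed, {
    f1 <- he_init(kernel1 * kernel1 * 3L, n_filters1, kernel1 * kernel1 * 3L)
    f2 <- he_init(kernel2 * kernel2 * n_filters1, n_filters2,
                  kernel2 * kernel2 * n_filters1)
  })
  i1 <- im2col_index(h, w, 3L, kernel1, kernel1)
  h1 <- i1$oh %/% 2L; w1 <- i1$ow %/% 2L
  i2 <- im2col_index(h1, w1, n_filters1, kernel2, kernel2)
  h2 <- i2$oh %/% 2L; w2 <- i2$ow %/% 2L
  structure(list(input_size = as.integer(c(h, w)), f1 = f1, f2 = f2,
                 i1 = i1, i2 = i2,
                 n_features = h2 * w2 * n_filters2,
                 backbone_seed = as.integer(backbone_seed)),
            class = "cnn_backbone")
}

# Resize an rgb_image to the backbone input (bilinear) and scale to [0, 1].
prep_image <- function(px, input_size) {
  d <- dim(px)
  x <- aperm(unclass(px), c(2, 1, 3)) / 255
  if (d[1] != input_size[1] || d[2] != input_size[2]) {
    x <- EBImage::resize(EBImage::Image(x, colormode = "Color"),
                         w = input_size[2], h = input_size[1])@.Data
  }
  aperm(x, c(2, 1, 3))
}

backbone_features_one <- function(backbone, x) {
  a1 <- conv_forward(x, backbone$f1, backbone$i1)
  a1 <- maxpool2(pmax(a1, 0))
  a2 <- conv_forward(a1, backbone$f2, backbone$i2)
  a2 <- maxpool2(pmax(a2, 0))
  as.vector(a2)
}

#' Backbone feature matrix of an image set
#'
#' @param backbone a [cnn_backbone()].
#' @param images list of `rgb_image` objects (any size; resized bilinearly).
#' @return numeric matrix `[n_images, n_features]`.
#' @export
backbone_features <- function(backbone, images) {
  t(vapply(images, function(px)
    backbone_features_one(backbone, prep_image(px, backbone$input_size)),
    numeric(backbone$n_features)))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Retrain the classification head on labelled images
#'
#' The backbone stays frozen; the replaced head (one hidden dense layer
#' with ReLU plus a softmax output over the label set) is trained with
#' stochastic gradient descent with momentum on standardised backbone
#' features. A stratified 20% holdout provides the internal validation
#' curve; the history records per-epoch training loss and holdout accuracy.
#'
#' @param backbone a [cnn_backbone()].
#' @param images list of `rgb_image`.
#' @param labels character labels, one per image; every class in
#'   `cfg$label_set` that occurs must have at least one image.
#' @param cfg a [cnn_training_config()].
#' @param holdout_fraction internal-validation fraction (default 0.2).
#' @param hidden_units width of the retrained hidden layer.
#' @return object of class `spheroid_cnn`: backbone, head weights, feature
#'   standardisation, label set, config and `history` (data.frame with
#'   `epoch`, `train_loss`, `holdout_accuracy`).
#' @export
retrain <- function(backbone, images, labels, cfg = cnn_training_config(),
                    holdout_fraction = 0.2, hidden_units = 96L) {
  stopifnot(length(images) == length(labels))
  label_set <- cfg$label_set
  if (!all(labels %in% label_set)) stop("labels outside cfg$label_set")
  present <- intersect(label_set, unique(labels))
  if (length(present) < 2L) stop("need at least two classes with images")
  absent <- setdiff(label_set, labels)
  if (length(absent))
    stop("class with zero training images: ", paste(absent, collapse = ", "))
  y <- match(labels, label_set)
  n <- length(images)
  X <- backbone_features(backbone, images)

  withr::with_seed(cfg$seed, {
    # stratified holdout
    hold <- integer(0)
    for (k in seq_along(label_set)) {
      idx <- which(y == k)
      nh <- floor(length(idx) * holdout_fraction)
      if (nh > 0) hold <- c(hold, sample(idx, nh))
    }
    tr <- setdiff(seq_len(n), hold)
    mu <- colMeans(X[tr, , drop = FALSE])
    sg <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    sg[sg < 1e-8] <- 1
    Xs <- sweep(sweep(X, 2, mu), 2, sg, "/")
    K <- length(label_set)
    D <- ncol(X)
    H <- as.integer(hidden_units)
    W1 <- he_init(D, H, D); b1 <- numeric(H)
    W2 <- he_init(H, K, H); b2 <- numeric(K)
    vW1 <- matrix(0, D, H); vb1 <- numeric(H)
    vW2 <- matrix(0, H, K); vb2 <- numeric(K)
    bs <- min(cfg$batch_size, length(tr))
    lr <- cfg$learning_rate; mom <- cfg$momentum
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          holdout_accuracy = numeric(0))
    onehot <- matrix(0, n, K); onehot[cbind(seq_len(n), y)] <- 1
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(tr)
      losses <- numeric(0)
      for (start in seq(1, length(ord), by = bs)) {
        bidx <- ord[start:min(start + bs - 1L, length(ord))]
        xb <- Xs[bidx, , drop = FALSE]
        yb <- onehot[bidx, , drop = FALSE]
        h1 <- xb %*% W1
        h1 <- sweep(h1, 2, b1, "+")
        a1 <- pmax(h1, 0)
        z2 <- sweep(a1 %*% W2, 2, b2, "+")
        p <- softmax_rows(z2)
        losses <- c(losses, -mean(log(pmax(rowSums(p * yb), 1e-12))))
        m <- nrow(xb)
        dz2 <- (p - yb) / m
        gW2 <- crossprod(a1, dz2); gb2 <- colSums(dz2)
        da1 <- dz2 %*% t(W2)
        dz1 <- da1 * (h1 > 0)
        gW1 <- crossprod(xb, dz1); gb1 <- colSums(dz1)
        vW2 <- mom * vW2 - lr * gW2; W2 <- W2 + vW2
        vb2 <- mom * vb2 - lr * gb2; b2 <- b2 + vb2
        vW1 <- mom * vW1 - lr * gW1; W1 <- W1 + vW1
        vb1 <- mom * vb1 - lr * gb1; b1 <- b1 + vb1
      }
      acc <- NA_real_
      if (length(hold)) {
        ph <- pmax(Xs[hold, , drop = FALSE] %*% W1 +
                     matrix(b1, length(hold), H, byrow = TRUE), 0) %*% W2
        pred <- label_set[max.col(ph, ties.method = "first")]
        acc <- mean(pred == labels[hold])
      }
      history <- rbind(history, data.frame(epoch = ep,
                                           train_loss = mean(losses),
                                           holdout_accuracy = acc))
    }
  })
  structure(list(backbone = backbone, W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                 feature_mean = mu, feature_sd = sg, label_set = label_set,
                 config = cfg, history = history,
                 holdout_index = sort(hold)),
            class = "spheroid_cnn")
}

#' @export
print.spheroid_cnn <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf("<spheroid_cnn> %d classes, %d epochs, final holdout accuracy %.3f\n",
              length(x$label_set), nrow(x$history), last$holdout_accuracy))
  invisible(x)
}

#' Predict polarity labels with the convolutional branch
#'
#' @param model a [retrain()]ed `spheroid_cnn`.
#' @param images list of `rgb_image` (resized to the model input).
#' @return data.frame with `fine_label`, `coarse_label` (3a/3b collapsed)
#'   and one probability column per class (`prob_<label>`; rows sum to 1).
#' @export
predict_cnn <- function(model, images) {
  X <- backbone_features(model$backbone, images)
  Xs <- sweep(sweep(X, 2, model$feature_mean), 2, model$feature_sd, "/")
  H <- length(model$b1)
  a1 <- pmax(Xs %*% model$W1 + matrix(model$b1, nrow(Xs), H, byrow = TRUE), 0)
  z2 <- a1 %*% model$W2 + matrix(model$b2, nrow(Xs), length(model$b2), byrow = TRUE)
  p <- softmax_rows(z2)
  colnames(p) <- model$label_set
  fine <- model$label_set[max.col(p, ties.method = "first")]
  out <- data.frame(fine_label = fine,
                    coarse_label = if (all(fine %in% FINE_LABELS))
                      coarse_label(fine) else fine,
                    stringsAsFactors = FALSE)
  probs <- as.data.frame(p)
  names(probs) <- paste0("prob_", model$label_set)
  cbind(out, probs)
}
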