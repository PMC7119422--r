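# Decision-tree training, prediction, two-step reclassification and a
# bagged-tree ensemble on the 15-feature table.
#
# Trees are grown CART-style (Gini impurity, minimum leaf size 3, no depth
# cap beyond CART's own limit — a deliberately "complex" tree) with rpart,
# then exported into a plain nested-node structure (split feature,
# threshold, children, leaf class distribution) that the package descends
# deterministically and serialises to JSON. Cross-validated accuracy uses
# stratified, seeded folds. Ensemble votes break ties toward the lower
# group number (documented, configurable).

DEFAULT_TREE_SUBSET <- function() feature_names()[c(1, 2, 6:15)]
DEFAULT_SECONDARY_SUBSET <- function() {
  c("f8_nuclei_circularity", "f9_nuclear_initial_slope",
    "f13_nuclei_count", "f14_com_distance_rel")
}

tree_control <- function(min_leaf = 3L) {
  rpart::rpart.control(minsplit = 2L * min_leaf, minbucket = min_leaf,
                       cp = 0, xval = 0L, maxcompete = 0L, maxsurrogate = 0L,
                       usesurrogate = 0L)
}

fit_rpart <- function(df, subset, min_leaf = 3L) {
  form <- stats::as.formula(paste("label ~", paste(subset, collapse = " + ")))
  rpart::rpart(form, data = df, method = "class",
               parms = list(split = "gini"), control = tree_control(min_leaf))
}

# Export a fitted rpart tree into the package's own node structure.
# With maxcompete = maxsurrogate = 0 each internal frame row corresponds to
# exactly one row of fit$splits, in frame order. ncat = -1 sends x < threshold
# left; ncat = +1 sends x >= threshold left.
rpart_to_nodes <- function(fit) {
  frame <- fit$frame
  classes <- attr(fit, "ylevels")
  nodes <- as.integer(rownames(frame))
  is_leaf <- frame$var == "<leaf>"
  split_rows <- which(!is_leaf)
  splits <- fit$splits
  K <- length(classes)
  probs <- frame$yval2[, (1L + K + 1L):(1L + 2L * K), drop = FALSE]
  build <- function(node_id) {
    i <- match(node_id, nodes)
    dist <- as.numeric(probs[i, ])
    names(dist) <- classes
    if (is_leaf[i]) {
      return(list(leaf = TRUE, class_distribution = as.list(dist)))
    }
    k <- match(i, split_rows)
    list(leaf = FALSE,
         feature = as.character(frame$var[i]),
         threshold = unname(splits[k, "index"]),
         left_if_less = unname(splits[k, "ncat"]) < 0,
         class_distribution = as.list(dist),
         left = build(2L * node_id),
         right = build(2L * node_id + 1L))
  }
  list(root = build(1L), classes = classes)
}

descend_node <- function(node, feats, classes) {
  while (!isTRUE(node$leaf)) {
    x <- feats[[node$feature]]
    if (is.null(x) || is.na(x)) stop("missing feature: ", node$feature)
    go_left <- if (node$left_if_less) x < node$threshold else x >= node$threshold
    node <- if (go_left) node$left else node$right
  }
  p <- unlist(node$class_distribution)[classes]
  p
}

node_features <- function(node) {
  if (isTRUE(node$leaf)) return(character(0))
  c(node$feature, node_features(node$left), node_features(node$right))
}

make_folds <- function(labels, folds, seed) {
  n <- length(labels)
  if (folds < 2L || folds > n) stop("folds must be in 2..n")
  fold_id <- integer(n)
  withr::with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  fold_id
}

#' Train a complex decision tree with cross-validated accuracy
#'
#' Grows an unpruned CART tree (Gini impurity, minimum leaf size 3) on the
#' given feature subset and reports the pooled held-out accuracy over
#' stratified k-fold cross validation (default 20 folds, guarding against
#' overfitting). The default subset is features 1, 2 and 6-15 of the
#' 15-feature vector.
#'
#' @param features data.frame containing the subset columns (e.g. from
#'   [extract_features()]).
#' @param labels coarse labels (`"1"`, `"2"`, `"3"`), one per row; at least
#'   two classes.
#' @param subset feature names used for splitting.
#' @param folds number of cross-validation folds (default 20).
#' @param seed integer seed for fold assignment.
#' @param min_leaf minimum leaf size (default 3).
#' @return object of class `polarity_tree`: nested `tree` (splits,
#'   thresholds, leaf class distributions), `feature_subset`, `cv_folds`,
#'   `cv_accuracy`, `training_seed`, `classes`.
#' @export
train_tree <- function(features, labels, subset = DEFAULT_TREE_SUBSET(),
                       folds = 20L, seed = 1L, min_leaf = 3L) {
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels))
  if (length(unique(labels)) < 2L)
    stop("need at least two classes to train")
  missing_cols <- setdiff(subset, names(features))
  if (length(missing_cols))
    stop("features table lacks columns: ", paste(missing_cols, collapse = ", "))
  df <- features[subset]
  df$label <- factor(labels)
  fold_id <- make_folds(labels, folds, seed)
  correct <- 0L
  for (k in seq_len(folds)) {
    tr <- df[fold_id != k, , drop = FALSE]
    te <- df[fold_id == k, , drop = FALSE]
    if (nrow(te) == 0L) next
    if (length(unique(tr$label)) < 2L) next
    fit_k <- fit_rpart(tr, subset, min_leaf)
    pred <- predict(fit_k, te, type = "class")
    correct <- correct + sum(as.character(pred) == as.character(te$label))
  }
  fit <- fit_rpart(df, subset, min_leaf)
  exported <- rpart_to_nodes(fit)
  structure(list(tree = exported$root, classes = exported$classes,
                 feature_subset = subset, cv_folds = as.integer(folds),
                 cv_accuracy = correct / nrow(df),
                 training_seed = as.integer(seed), min_leaf = min_leaf),
            class = "polarity_tree")
}

#' @export
print.polarity_tree <- function(x, ...) {
  cat(sprintf("<polarity_tree> %d features, %d-fold CV accuracy %.3f\n",
              length(x$feature_subset), x$cv_folds, x$cv_accuracy))
  invisible(x)
}

#' Train the secondary group-1-vs-3 tree
#'
#' The second reclassification stage uses only group-1 and group-3 samples
#' and the lumen/nuclei descriptors (nuclei circularity, nuclear initial
#' slope, nuclei count, nuclear-to-spheroid centre distance) that best
#' discriminate a real lumen from an aggregate.
#'
#' @inheritParams train_tree
#' @param subset secondary feature subset.
#' @return a `polarity_tree` trained on labels `"1"` and `"3"` only.
#' @export
train_secondary_tree <- function(features, labels,
                                 subset = DEFAULT_SECONDARY_SUBSET(),
                                 folds = 10L, seed = 1L, min_leaf = 3L) {
  labels <- as.character(labels)
  keep <- labels %in% c("1", "3")
  if (!any(labels[keep] == "1") || !any(labels[keep] == "3"))
    stop("secondary tree needs both group-1 and group-3 samples")
  train_tree(features[keep, , drop = FALSE], labels[keep], subset,
             folds = min(folds, sum(keep)), seed = seed, min_leaf = min_leaf)
}

predict_tree_one <- function(model, feats) {
  p <- descend_node(model$tree, feats, model$classes)
  # ties break toward the lower group number (classes sorted "1" < "2" < "3")
  ord <- order(model$classes)
  cls <- model$classes[ord][which.max(p[ord])]
  list(class = cls, probs = p)
}

#' Classify spheroids with a tree or ensemble
#'
#' Deterministic tree descent; for an ensemble, a majority vote over trees
#' with ties broken toward the lower group number.
#'
#' @param model a `polarity_tree` or `polarity_ensemble`.
#' @param features data.frame with all subset feature columns (and
#'   optionally `spheroid_id`).
#' @return data.frame of classification records: `spheroid_id`, `predicted`,
#'   `reclassified` (all `FALSE` until [reclassify()]), `final`, plus the
#'   feature columns.
#' @export
classify_spheroids <- function(model, features) {
  ids <- if ("spheroid_id" %in% names(features)) features$spheroid_id
         else sprintf("s%04d", seq_len(nrow(features)))
  preds <- character(nrow(features))
  for (i in seq_len(nrow(features))) {
    feats <- as.list(features[i, , drop = FALSE])
    preds[i] <- if (inherits(model, "polarity_ensemble")) {
      predict_ensemble_one(model, feats)
    } else {
      predict_tree_one(model, feats)$class
    }
  }
  out <- data.frame(spheroid_id = ids, predicted = preds,
                    reclassified = FALSE, final = preds,
                    stringsAsFactors = FALSE)
  cbind(out, features[setdiff(names(features), names(out))])
}

#' Second-stage reclassification of groups 1 and 3
#'
#' Records predicted as group 1 or 3 are re-evaluated by the secondary
#' tree; group-2 records pass through untouched. The `reclassified` flag is
#' set wherever the final label differs from the first-stage prediction.
#'
#' @param records data.frame from [classify_spheroids()].
#' @param features feature table aligned with `records` (matched by
#'   `spheroid_id` when present, else by row order).
#' @param secondary a [train_secondary_tree()] model (classes `"1"`, `"3"`).
#' @return `records` with updated `final` and `reclassified` columns.
#' @export
reclassify <- function(records, features, secondary) {
  if (!setequal(secondary$classes, c("1", "3")))
    stop("secondary model must be trained on groups 1 and 3 only")
  if ("spheroid_id" %in% names(features)) {
    ord <- match(records$spheroid_id, features$spheroid_id)
    if (anyNA(ord)) stop("records and features do not match by spheroid_id")
    features <- features[ord, , drop = FALSE]
  }
  for (i in seq_len(nrow(records))) {
    if (!records$predicted[i] %in% c("1", "3")) next
    new <- predict_tree_one(secondary, as.list(features[i, , drop = FALSE]))$class
    records$final[i] <- new
    records$reclassified[i] <- new != records$predicted[i]
  }
  records
}

predict_ensemble_one <- function(model, feats) {
  votes <- vapply(model$trees, function(tr) predict_tree_one(tr, feats)$class,
                  character(1))
  tab <- table(factor(votes, levels = sort(model$classes)))
  names(tab)[which.max(tab)] # which.max takes the first max: lower group wins ties
}

#' Train a bagged ensemble of decision trees
#'
#' `n_trees` CART trees on seeded bootstrap resamples, aggregated by
#' majority vote (ties toward the lower group). Out-of-bag accuracy is
#' estimated from the samples each tree did not see.
#'
#' @inheritParams train_tree
#' @param n_trees number of bootstrap trees (default 30).
#' @return object of class `polarity_ensemble`: `trees`, `n_trees`,
#'   `oob_accuracy`, `feature_subset`, `classes`, `training_seed`.
#' @export
train_bagged <- function(features, labels, subset = DEFAULT_TREE_SUBSET(),
                         n_trees = 30L, seed = 1L, min_leaf = 3L) {
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels), n_trees >= 1L)
  if (length(unique(labels)) < 2L) stop("need at least two classes to train")
  df <- features[subset]
  df$label <- factor(labels)
  n <- nrow(df)
  boot_seeds <- derive_seeds(seed, n_trees)
  trees <- vector("list", n_trees)
  inbag <- matrix(FALSE, n, n_trees)
  classes <- levels(df$label)
  for (b in seq_len(n_trees)) {
    idx <- withr::with_seed(boot_seeds[b], sample.int(n, n, replace = TRUE))
    inbag[unique(idx), b] <- TRUE
    fit <- fit_rpart(df[idx, , drop = FALSE], subset, min_leaf)
    exported <- rpart_to_nodes(fit)
    trees[[b]] <- structure(list(tree = exported$root,
                                 classes = exported$classes,
                                 feature_subset = subset),
                            class = "polarity_tree")
  }
  # out-of-bag vote per sample
  oob_ok <- logical(n); oob_seen <- logical(n)
  for (i in seq_len(n)) {
    oob_trees <- which(!inbag[i, ])
    if (!length(oob_trees)) next
    feats <- as.list(df[i, , drop = FALSE])
    votes <- vapply(trees[oob_trees],
                    function(tr) predict_tree_one(tr, feats)$class, character(1))
    tab <- table(factor(votes, levels = classes))
    oob_seen[i] <- TRUE
    oob_ok[i] <- names(tab)[which.max(tab)] == as.character(df$label[i])
  }
  structure(list(trees = trees, n_trees = as.integer(n_trees),
                 oob_accuracy = if (any(oob_seen)) mean(oob_ok[oob_seen]) else NA_real_,
                 feature_subset = subset, classes = classes,
                 training_seed = as.integer(seed)),
            class = "polarity_ensemble")
}

#' @export
print.polarity_ensemble <- function(x, ...) {
  cat(sprintf("<polarity_ensemble> %d bagged trees, OOB accuracy %.3f\n",
              x$n_trees, x$oob_accuracy))
  invisible(x)
}

#' Impurity-decrease feature importance
#'
#' Sums the Gini impurity decrease attributable to each feature over a
#' bagged ensemble and normalises the scores to sum 1. Used to choose the
#' optimal predictor subset.
#'
#' @inheritParams train_bagged
#' @return data.frame with `feature` and `importance`, sorted by descending
#'   importance (ties alphabetical); importances sum to 1.
#' @export
feature_importance <- function(features, labels, subset = feature_names(),
                               n_trees = 30L, seed = 1L, min_leaf = 3L) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) stop("need at least two classes")
  df <- features[subset]
  df$label <- factor(labels)
  n <- nrow(df)
  boot_seeds <- derive_seeds(seed, n_trees)
  scores <- setNames(numeric(length(subset)), subset)
  for (b in seq_len(n_trees)) {
    idx <- withr::with_seed(boot_seeds[b], sample.int(n, n, replace = TRUE))
    fit <- fit_rpart(df[idx, , drop = FALSE], subset, min_leaf)
    vi <- fit$variable.importance
    if (!is.null(vi)) {
      common <- intersect(names(vi), subset)
      scores[common] <- scores[common] + vi[common]
    }
  }
  if (sum(scores) > 0) scores <- scores / sum(scores)
  out <- data.frame(feature = names(scores), importance = unname(scores),
                    stringsAsFactors = FALSE)
  out[order(-out$importance, out$feature), , drop = FALSE]
}

#' Serialize / restore tree models as self-describing JSON
#'
#' The document records every split feature, threshold and leaf class
#' distribution, the feature subset, fold count, seed and CV accuracy, so a
#' model file is interpretable without the package.
#'
#' @param model a `polarity_tree` or `polarity_ensemble`.
#' @param path JSON file path.
#' @return `path` (write); the restored model (read).
#' @export
write_model_json <- function(model, path) {
  obj <- unclass(model)
  obj$model_type <- if (inherits(model, "polarity_ensemble")) "ensemble" else "tree"
  if (obj$model_type == "ensemble") obj$trees <- lapply(obj$trees, unclass)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  restore_scalar <- function(x) {
    x$classes <- as.character(unlist(x$classes))
    x$feature_subset <- as.character(unlist(x$feature_subset))
    for (k in c("cv_accuracy", "oob_accuracy")) if (!is.null(x[[k]])) x[[k]] <- as.numeric(x[[k]])
    x
  }
  type <- obj$model_type
  obj$model_type <- NULL
  if (identical(type, "ensemble")) {
    obj <- restore_scalar(obj)
    obj$trees <- lapply(obj$trees, function(tr)
      structure(restore_scalar(tr), class = "polarity_tree"))
    structure(obj, class = "polarity_ensemble")
  } else {
    structure(restore_scalar(obj), class = "polarity_tree")
  }
}

#' Write a classification results table
#'
#' One row per spheroid: id, first-stage prediction, reclassification flag,
#' final label, and every feature used — the comprehensive results table of
#' the engineered pipeline.
#'
#' @param records data.frame from [classify_spheroids()] /
#'   [reclassify()].
#' @param path CSV path.
#' @export
write_records_csv <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}
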