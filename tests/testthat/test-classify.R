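# Feature tables for classifier tests are drawn directly in feature space
# (fast, and the decision geometry is fully controlled); image-derived
# features are exercised in the acceptance suite.

sim_features <- function(n_per_class, seed = 1L, noise_sd = 0.05,
                         f1_centres = c("1" = 0.4, "2" = -0.4, "3" = 0)) {
  withr::with_seed(seed, {
    labels <- rep(names(f1_centres), times = n_per_class)
    n <- length(labels)
    df <- as.data.frame(setNames(
      lapply(feature_names(), function(fn) rnorm(n, 0.5, 0.2)),
      feature_names()))
    df$f1_delta_gp58_gp135 <- f1_centres[labels] + rnorm(n, 0, noise_sd)
    # lumen descriptors separate 1 vs 3
    df$f9_nuclear_initial_slope <- ifelse(labels == "3", 1.5, 0.1) +
      rnorm(n, 0, noise_sd)
    df$spheroid_id <- sprintf("s%03d", seq_len(n))
    list(features = df, labels = labels)
  })
}

test_that("a separable dataset yields perfect cross-validated accuracy", {
  d <- sim_features(c(20, 20, 20), seed = 2, noise_sd = 0)
  m <- train_tree(d$features, d$labels, folds = 10, seed = 3)
  expect_equal(m$cv_accuracy, 1.0)
  rec <- classify_spheroids(m, d$features)
  expect_identical(rec$final, d$labels)
  # resubstitution accuracy is never below CV accuracy
  expect_gte(mean(rec$final == d$labels), m$cv_accuracy)
})

test_that("permuted labels give chance-level cross-validated accuracy", {
  d <- sim_features(c(30, 30, 30), seed = 4)
  perm <- withr::with_seed(99, sample(d$labels))
  m <- train_tree(d$features, perm, folds = 10, seed = 5)
  expect_lt(abs(m$cv_accuracy - 1 / 3), 0.15)
})

test_that("the exported tree reproduces rpart predictions exactly", {
  d <- sim_features(c(15, 15, 15), seed = 6, noise_sd = 0.3)
  subset <- feature_names()[c(1, 2, 6:15)]
  df <- d$features[subset]
  df$label <- factor(d$labels)
  fit <- spheropol:::fit_rpart(df, subset)
  m <- train_tree(d$features, d$labels, folds = 5, seed = 7)
  ref <- as.character(predict(fit, df, type = "class"))
  rec <- classify_spheroids(m, d$features)
  expect_identical(rec$predicted, ref)
})

test_that("training is deterministic and survives JSON serialization", {
  d <- sim_features(c(12, 12, 12), seed = 8)
  m1 <- train_tree(d$features, d$labels, folds = 6, seed = 11)
  m2 <- train_tree(d$features, d$labels, folds = 6, seed = 11)
  expect_identical(m1, m2)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m1, path)
  m3 <- read_model_json(path)
  expect_identical(classify_spheroids(m3, d$features)$final,
                   classify_spheroids(m1, d$features)$final)
  expect_equal(m3$cv_accuracy, m1$cv_accuracy)

  e1 <- train_bagged(d$features, d$labels, n_trees = 7, seed = 13)
  e2 <- train_bagged(d$features, d$labels, n_trees = 7, seed = 13)
  expect_identical(e1, e2)
  write_model_json(e1, path)
  e3 <- read_model_json(path)
  expect_identical(classify_spheroids(e3, d$features)$final,
                   classify_spheroids(e1, d$features)$final)
})

test_that("degenerate training inputs are rejected", {
  d <- sim_features(c(10, 10, 10), seed = 9)
  expect_error(train_tree(d$features, rep("1", 30)), "two classes")
  expect_error(train_tree(d$features, d$labels, folds = 100), "folds")
  expect_error(train_tree(d$features[, 1:3], d$labels,
                          subset = feature_names()), "lacks columns")
})

test_that("ensemble voting aggregates majorities with lower-group tie-break", {
  d <- sim_features(c(10, 10, 10), seed = 10)
  # single-tree ensemble behaves as that tree
  e1 <- train_bagged(d$features, d$labels, n_trees = 1, seed = 14)
  rec_e <- classify_spheroids(e1, d$features)
  rec_t <- classify_spheroids(e1$trees[[1]], d$features)
  expect_identical(rec_e$final, rec_t$final)

  # hand-built voting: (1, 3, 3) -> 3 and (1, 3) tie -> 1
  leaf <- function(cls) {
    dist <- setNames(as.list(as.numeric(cls == c("1", "3"))), c("1", "3"))
    structure(list(tree = list(leaf = TRUE, class_distribution = dist),
                   classes = c("1", "3"), feature_subset = character(0)),
              class = "polarity_tree")
  }
  ens <- structure(list(trees = list(leaf("1"), leaf("3"), leaf("3")),
                        n_trees = 3L, classes = c("1", "3")),
                   class = "polarity_ensemble")
  expect_identical(spheropol:::predict_ensemble_one(ens, list()), "3")
  ens2 <- structure(list(trees = list(leaf("1"), leaf("3")), n_trees = 2L,
                         classes = c("1", "3")), class = "polarity_ensemble")
  expect_identical(spheropol:::predict_ensemble_one(ens2, list()), "1")
})

test_that("out-of-bag accuracy tracks single-tree CV on a learnable problem", {
  d <- sim_features(c(25, 25, 25), seed = 15, noise_sd = 0.15)
  m <- train_tree(d$features, d$labels, folds = 10, seed = 16)
  e <- train_bagged(d$features, d$labels, n_trees = 30, seed = 16)
  expect_gte(e$oob_accuracy, m$cv_accuracy - 0.05)
})

test_that("reclassification touches only groups 1 and 3 and fixes planted errors", {
  d <- sim_features(c(20, 20, 20), seed = 17, noise_sd = 0.02)
  sec <- train_secondary_tree(d$features, d$labels, seed = 18)
  expect_true(setequal(sec$classes, c("1", "3")))
  # secondary trained on lumen descriptors only
  expect_true(all(spheropol:::node_features(sec$tree) %in%
                    spheropol:::DEFAULT_SECONDARY_SUBSET()))

  m <- train_tree(d$features, d$labels, folds = 10, seed = 18)
  rec <- classify_spheroids(m, d$features)

  # plant a first-stage error: an aggregate (f9 >> 0) mislabelled group 1
  planted <- rec[1, ]
  planted$predicted <- "1"; planted$final <- "1"
  planted_feats <- d$features[1, ]
  planted_feats$f9_nuclear_initial_slope <- 1.6
  planted_feats$spheroid_id <- planted$spheroid_id <- "planted"
  rec2 <- reclassify(rbind(rec, planted), rbind(d$features, planted_feats), sec)

  expect_identical(rec2$final[rec2$spheroid_id == "planted"], "3")
  expect_true(rec2$reclassified[rec2$spheroid_id == "planted"])
  # group-2 records pass through untouched
  g2 <- rec2$predicted == "2"
  expect_true(all(!rec2$reclassified[g2]))
  expect_identical(rec2$final[g2], rec2$predicted[g2])

  # a secondary that agrees everywhere flags nothing
  agree_count <- sum(rec2$reclassified[rec2$spheroid_id != "planted"])
  expect_equal(agree_count, 0)

  # wrong label set is rejected
  expect_error(reclassify(rec, d$features, m), "groups 1 and 3")
})

test_that("feature importance finds the informative feature and normalises", {
  d <- sim_features(c(25, 25, 25), seed = 19, noise_sd = 0.02)
  # only f1 and f9 carry signal here; f1 separates all three classes
  imp <- feature_importance(d$features, d$labels, n_trees = 15, seed = 20)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-12)
  expect_identical(imp$feature[1], "f1_delta_gp58_gp135")
  expect_gt(imp$importance[1], 0.5)

  # pure-noise features: importance spread, no feature dominates
  withr::with_seed(21, {
    noise <- as.data.frame(setNames(lapply(feature_names(), function(fn)
      rnorm(90)), feature_names()))
    labs <- sample(rep(c("1", "2", "3"), each = 30))
  })
  imp0 <- feature_importance(noise, labs, n_trees = 15, seed = 22)
  expect_lt(max(imp0$importance), 3 / 15)
})
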