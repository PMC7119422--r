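test_that("cross tables count pairs, transpose under rater swap", {
  a <- c("1", "1", "2", "3")
  b <- c("1", "3", "2", "3")
  tab <- cross_table(a, b, c("1", "2", "3"))
  expect_identical(sum(diag(as.matrix(tab))), 3L)
  expect_identical(sum(tab), 4L)
  expect_identical(as.matrix(cross_table(b, a, c("1", "2", "3"))),
                   t(as.matrix(tab)))
  ident <- cross_table(a, a)
  expect_identical(sum(diag(as.matrix(ident))), 4L)
  expect_identical(sum(as.matrix(ident)) - sum(diag(as.matrix(ident))), 0L)
  expect_error(cross_table(a, b[1:3]), "length")
  expect_error(cross_table(a, b, c("1", "2")), "unknown label")
})

test_that("percent agreement reports one decimal, half away from zero", {
  tab <- matrix(c(300, 10, 5, 8, 15, 2, 4, 3, 4), 3, 3, byrow = TRUE)
  expect_equal(percent_agreement(diag(c(5, 5, 5))), 100.0)
  zero_diag <- matrix(c(0, 5, 5, 0), 2, 2)
  expect_equal(percent_agreement(zero_diag), 0.0)
  # 321 / 351 = 91.4529...% -> 91.5 at one decimal
  t351 <- diag(c(250, 30, 41))
  t351[1, 2] <- 10; t351[2, 3] <- 12; t351[3, 1] <- 8
  expect_identical(sum(t351), 351)
  expect_identical(sum(diag(t351)), 321)
  expect_equal(percent_agreement(t351), 91.5)
  expect_equal(percent_agreement(t351, digits = NA), 100 * 321 / 351)
})

test_that("kappa matches the brute-force rating-list recomputation", {
  withr::with_seed(31, {
    for (k in 1:40) {
      K <- sample(c(3, 4), 1)
      tab <- matrix(sample(0:30, K * K, TRUE), K, K)
      if (sum(tab) < 2 || sum(diag(tab)) == sum(tab)) next
      dimnames(tab) <- list(letters[1:K], letters[1:K])
      lists <- expand_table(tab)
      ks <- cohens_kappa(tab)
      expect_equal(ks$kappa, kappa_bruteforce(lists$a, lists$b),
                   tolerance = 1e-12)
    }
  })
})

test_that("kappa hits its landmark values", {
  expect_equal(cohens_kappa(diag(c(10, 20, 5)))$kappa, 1)
  # rows 10/90, cols 90/10: po = pe = 0.18 -> kappa = 0
  tab <- matrix(c(9, 1, 81, 9), 2, 2, byrow = TRUE)
  ks <- cohens_kappa(tab)
  expect_equal(ks$po, 0.18)
  expect_equal(ks$pe, 0.18)
  expect_equal(ks$kappa, 0)
  # rater symmetry and label-permutation invariance
  withr::with_seed(32, {
    t3 <- matrix(sample(1:40, 9), 3, 3)
  })
  expect_equal(cohens_kappa(t3)$kappa, cohens_kappa(t(t3))$kappa,
               tolerance = 1e-12)
  perm <- c(3, 1, 2)
  expect_equal(cohens_kappa(t3[perm, perm])$kappa, cohens_kappa(t3)$kappa,
               tolerance = 1e-12)
  expect_equal(percent_agreement(t3[perm, perm], digits = NA),
               percent_agreement(t3, digits = NA), tolerance = 1e-12)
  expect_error(cohens_kappa(diag(c(50, 0, 0))), "undefined")
})

test_that("kappa standard error matches a multinomial Monte Carlo oracle", {
  # moderately unbalanced 3x3 table; simulate tables from its cell
  # probabilities and compare the analytic SE with the empirical SD of kappa
  tab <- matrix(c(60, 8, 4, 6, 25, 5, 3, 4, 20), 3, 3, byrow = TRUE)
  n <- sum(tab)
  ks <- cohens_kappa(tab)
  p <- as.vector(tab) / n
  withr::with_seed(33, {
    sim <- replicate(600, {
      cells <- matrix(as.vector(stats::rmultinom(1, n, p)), 3, 3)
      (function(x) tryCatch(cohens_kappa(x)$kappa, error = function(e) NA))(cells)
    })
  })
  expect_equal(ks$se_kappa, stats::sd(sim, na.rm = TRUE), tolerance = 0.15)
  # CI is symmetric about kappa and contains it
  expect_true(ks$ci[1] <= ks$kappa && ks$kappa <= ks$ci[2])
  expect_equal(ks$ci[2] - ks$kappa, ks$kappa - ks$ci[1], tolerance = 1e-12)
})

test_that("recall and precision for group 1 follow the table margins", {
  # 10 true group-1 all predicted 1; 2 non-1 items predicted 1
  tab <- matrix(0, 3, 3, dimnames = list(c("1", "2", "3"), c("1", "2", "3")))
  tab[1, 1] <- 10; tab[2, 1] <- 1; tab[3, 1] <- 1; tab[2, 2] <- 5; tab[3, 3] <- 5
  rp <- recall_precision(tab, "1")
  expect_equal(unname(rp["recall"]), 1.0)
  expect_equal(unname(rp["precision"]), 10 / 12, tolerance = 1e-12)
  expect_equal(unname(recall_precision(diag(c(4, 4, 4)))), c(1, 1))
  tab0 <- tab; tab0[1, ] <- c(0, 5, 5)
  expect_equal(unname(recall_precision(tab0, "1")["recall"]), 0)
  tab_na <- tab; tab_na[, 1] <- 0; tab_na[1, 2] <- 10
  expect_error(recall_precision(tab_na, "1"), "precision undefined")
})

test_that("kappa interpretation bands follow the conventional scale", {
  expect_identical(kappa_band(0.78), "substantial")
  expect_identical(kappa_band(0.48), "moderate")
  expect_identical(kappa_band(0.95), "almost perfect")
  expect_identical(kappa_band(0.20), "slight")
  expect_identical(kappa_band(0.40), "fair")
  expect_identical(kappa_band(0.60), "moderate")
  expect_identical(kappa_band(0.80), "substantial")
  expect_identical(kappa_band(0.81), "almost perfect")
  expect_identical(kappa_band(0), "none/chance or disagreement")
  expect_identical(kappa_band(-0.3), "none/chance or disagreement")
})

test_that("multi-rater consensus and pairwise tables are consistent", {
  ratings <- data.frame(
    spheroid_id = rep(c("a", "b", "c", "d"), each = 3),
    rater = rep(c("r1", "r2", "r3"), times = 4),
    label = c("1", "1", "1",   # a: unanimous
              "1", "1", "3",   # b: majority 1
              "1", "2", "3",   # c: unresolved
              "3", "3", "2"),  # d: majority 3
    stringsAsFactors = FALSE)
  cons <- consensus_labels(ratings)
  expect_identical(cons$consensus, c("1", "1", NA, "3"))
  expect_identical(cons$unresolved, c(FALSE, FALSE, TRUE, FALSE))

  pw <- pairwise_tables(ratings, c("1", "2", "3"))
  expect_identical(names(pw), c("r1_vs_r2", "r1_vs_r3", "r2_vs_r3"))
  # each margin equals that rater's label histogram
  r1_hist <- table(factor(ratings$label[ratings$rater == "r1"],
                          levels = c("1", "2", "3")))
  expect_identical(as.integer(rowSums(as.matrix(pw$r1_vs_r2))),
                   as.integer(r1_hist))
  expect_identical(as.integer(rowSums(as.matrix(pw$r1_vs_r3))),
                   as.integer(r1_hist))
})

test_that("kappa agrees with the independent e1071 implementation", {
  skip_if_not_installed("e1071")
  withr::with_seed(34, {
    for (k in 1:10) {
      tab <- matrix(sample(1:50, 9, TRUE), 3, 3)
      expect_equal(cohens_kappa(tab)$kappa,
                   e1071::classAgreement(tab)$kappa, tolerance = 1e-12)
    }
  })
})

test_that("the agreement report carries the summary quantities", {
  tab <- matrix(c(40, 2, 1, 3, 20, 2, 1, 1, 30), 3, 3, byrow = TRUE,
                dimnames = list(c("1", "2", "3"), c("1", "2", "3")))
  rep_lines <- agreement_report(tab)
  expect_true(any(grepl("agreement = 90.0%", rep_lines)))
  expect_true(any(grepl("kappa", rep_lines)))
  expect_true(any(grepl("recall", rep_lines)))
})
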