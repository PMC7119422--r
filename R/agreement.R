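# Interrater-agreement statistics: cross-correlation tables, percent
# agreement, Cohen's kappa with standard error and confidence interval,
# recall/precision for group 1, and the usual kappa interpretation bands.
# A "rater" is an individual or a classification algorithm.

#' Cross-correlation table of two raters
#'
#' @param ratings_a,ratings_b label vectors of equal length (rater A rows,
#'   rater B columns).
#' @param label_order shared label order; defaults to the sorted union.
#' @return a `rating_table`: K x K integer matrix of counts with the labels
#'   as dimnames.
#' @export
cross_table <- function(ratings_a, ratings_b, label_order = NULL) {
  ratings_a <- as.character(ratings_a); ratings_b <- as.character(ratings_b)
  if (length(ratings_a) != length(ratings_b))
    stop("rating lists differ in length")
  if (is.null(label_order))
    label_order <- sort(unique(c(ratings_a, ratings_b)))
  unknown <- setdiff(unique(c(ratings_a, ratings_b)), label_order)
  if (length(unknown))
    stop("unknown label(s): ", paste(unknown, collapse = ", "))
  tab <- table(factor(ratings_a, levels = label_order),
               factor(ratings_b, levels = label_order))
  structure(unclass(tab), class = "rating_table")
}

as_rating_table <- function(counts, labels = NULL) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == ncol(counts), all(counts >= 0))
  if (!is.null(labels)) dimnames(counts) <- list(labels, labels)
  if (is.null(rownames(counts)))
    dimnames(counts) <- list(seq_len(nrow(counts)), seq_len(ncol(counts)))
  structure(counts, class = "rating_table")
}

#' Percent agreement of a cross-correlation table
#'
#' Count of alike-classified items divided by the total, as a percentage
#' reported to one decimal (half away from zero).
#'
#' @param table a [cross_table()] or plain square count matrix.
#' @param digits decimals to report (default 1; `NA` for full precision).
#' @return percentage in `[0, 100]`.
#' @export
percent_agreement <- function(table, digits = 1) {
  tab <- as.matrix(table)
  n <- sum(tab)
  if (n < 1) stop("empty rating table")
  pct <- 100 * sum(diag(tab)) / n
  if (is.na(digits)) pct else round_half_up(pct, digits)
}

#' Cohen's kappa with standard error and confidence interval
#'
#' Chance-corrected agreement: `kappa = (po - pe) / (1 - pe)` with observed
#' agreement `po` (diagonal share) and chance agreement `pe` (product of the
#' marginals). The standard error is the large-sample delta-method estimate
#' of Fleiss, Cohen and Everitt (1969); the confidence interval is
#' `kappa +/- z * SE`, clipped to `[-1, 1]`.
#'
#' @param table a [cross_table()] or square count matrix.
#' @param alpha confidence level is `1 - alpha` (default 0.05).
#' @return list of class `agreement_stats`: `kappa`, `se_kappa`, `ci`
#'   (length-2), `po`, `pe`, `n`, `band` (see [kappa_band()]), `alpha`.
#' @export
cohens_kappa <- function(table, alpha = 0.05) {
  tab <- as.matrix(table)
  n <- sum(tab)
  if (n < 2) stop("need at least two rated items")
  p <- tab / n
  po <- sum(diag(p))
  rowm <- rowSums(p); colm <- colSums(p)
  pe <- sum(rowm * colm)
  if (1 - pe < .Machine$double.eps)
    stop("kappa undefined: degenerate single-category table")
  kap <- (po - pe) / (1 - pe)
  # Fleiss-Cohen-Everitt (1969) large-sample variance
  K <- nrow(p)
  t1 <- 0
  for (i in seq_len(K))
    t1 <- t1 + p[i, i] * ((1 - pe) - (colm[i] + rowm[i]) * (1 - po))^2
  t2 <- 0
  for (i in seq_len(K)) for (j in seq_len(K)) if (i != j)
    t2 <- t2 + p[i, j] * (colm[i] + rowm[j])^2
  t2 <- t2 * (1 - po)^2
  t3 <- (po * pe - 2 * pe + po)^2
  se <- sqrt(max(t1 + t2 - t3, 0) / n) / (1 - pe)^2
  z <- stats::qnorm(1 - alpha / 2)
  ci <- c(max(-1, kap - z * se), min(1, kap + z * se))
  structure(list(kappa = kap, se_kappa = se, ci = ci, po = po, pe = pe,
                 n = n, band = kappa_band(kap), alpha = alpha),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("kappa = %.3f [SE = %.3f; CI(alpha = %.2f) = %.3f to %.3f] (%s agreement)\n",
              x$kappa, x$se_kappa, x$alpha, x$ci[1], x$ci[2], x$band))
  invisible(x)
}

#' Recall and precision for a positive label
#'
#' With truth on the rows: recall (sensitivity) is the diagonal count over
#' the positive row sum; precision (positive predictive value) is the
#' diagonal count over the positive column sum. Group 1 (regular polarity)
#' is the conventional positive class.
#'
#' @param table a [cross_table()] (rows = truth).
#' @param positive_label the positive class (default `"1"`).
#' @return named vector `c(recall, precision)`.
#' @export
recall_precision <- function(table, positive_label = "1") {
  tab <- as.matrix(table)
  labels <- rownames(tab)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(tab)))
  p <- match(as.character(positive_label), labels)
  if (is.na(p)) stop("positive label not in label order")
  rs <- sum(tab[p, ]); cs <- sum(tab[, p])
  if (rs == 0) stop("zero row for positive label: recall undefined")
  if (cs == 0) stop("zero column for positive label: precision undefined")
  c(recall = tab[p, p] / rs, precision = tab[p, p] / cs)
}

#' Interpretation band of a kappa value
#'
#' The conventional scale: 0.01-0.20 slight, 0.21-0.40 fair, 0.41-0.60
#' moderate, 0.61-0.80 substantial, 0.81-1.00 almost perfect; values at or
#' below 0 indicate chance-level agreement or disagreement.
#'
#' @param kappa value in `[-1, 1]`.
#' @return interpretation label string.
#' @export
kappa_band <- function(kappa) {
  stopifnot(kappa >= -1, kappa <= 1)
  if (kappa <= 0) return("none/chance or disagreement")
  if (kappa <= 0.20) return("slight")
  if (kappa <= 0.40) return("fair")
  if (kappa <= 0.60) return("moderate")
  if (kappa <= 0.80) return("substantial")
  "almost perfect"
}

#' Consensus labels across several raters
#'
#' Majority vote per item over a long-form rating table; items without a
#' strict majority are flagged unresolved (`NA` consensus) — in practice
#' those are the spheroids the raters discuss.
#'
#' @param ratings data.frame with columns `spheroid_id`, `rater`, `label`.
#' @return data.frame with `spheroid_id`, `consensus` (`NA` when
#'   unresolved) and `unresolved` flag.
#' @export
consensus_labels <- function(ratings) {
  stopifnot(all(c("spheroid_id", "rater", "label") %in% names(ratings)))
  ids <- unique(ratings$spheroid_id)
  rows <- lapply(ids, function(id) {
    labs <- ratings$label[ratings$spheroid_id == id]
    tab <- sort(table(labs), decreasing = TRUE)
    maj <- tab[1] > length(labs) / 2
    data.frame(spheroid_id = id,
               consensus = if (maj) names(tab)[1] else NA_character_,
               unresolved = !maj, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pairwise rating tables of a multi-rater table
#'
#' @param ratings long-form data.frame (`spheroid_id`, `rater`, `label`).
#' @param label_order shared label order (default sorted union).
#' @return named list of [cross_table()] for every rater pair
#'   (`"A_vs_B"`), computed over the items both raters scored.
#' @export
pairwise_tables <- function(ratings, label_order = NULL) {
  raters <- sort(unique(ratings$rater))
  if (length(raters) < 2L) stop("need at least two raters")
  if (is.null(label_order)) label_order <- sort(unique(ratings$label))
  out <- list()
  for (i in seq_along(raters)) for (j in seq_along(raters)) if (i < j) {
    a <- ratings[ratings$rater == raters[i], c("spheroid_id", "label")]
    b <- ratings[ratings$rater == raters[j], c("spheroid_id", "label")]
    common <- intersect(a$spheroid_id, b$spheroid_id)
    la <- a$label[match(common, a$spheroid_id)]
    lb <- b$label[match(common, b$spheroid_id)]
    out[[paste0(raters[i], "_vs_", raters[j])]] <-
      cross_table(la, lb, label_order)
  }
  out
}

#' Human-readable agreement report
#'
#' Mirrors the summary line used under cross-correlation tables: percentage
#' of agreement and Cohen's kappa of interrater agreement, plus recall and
#' precision for group 1 when present.
#'
#' @param table a [cross_table()].
#' @param alpha significance level for the kappa CI.
#' @return character vector of report lines.
#' @export
agreement_report <- function(table, alpha = 0.05) {
  ks <- cohens_kappa(table, alpha)
  lines <- c(
    sprintf("n = %d spheroids; agreement = %.1f%%", ks$n,
            percent_agreement(table)),
    sprintf("Cohen's kappa = %.2f [SE = %.3f; CI(alpha = %.2f) = %.3f to %.3f]",
            ks$kappa, ks$se_kappa, alpha, ks$ci[1], ks$ci[2]),
    sprintf("interpretation: %s agreement", ks$band))
  if ("1" %in% rownames(as.matrix(table))) {
    rp <- recall_precision(table, "1")
    lines <- c(lines, sprintf("group 1: recall = %.3f, precision = %.3f",
                              rp["recall"], rp["precision"]))
  }
  lines
}
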