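#' Consensus labels from a ratings matrix
#'
#' @param ratings case-by-rater matrix with entries in `{0, 1}` and no
#'   missing values.
#' @param rule `"majority"` (ties broken by `tie`), `"unanimous"` (positive
#'   only if every rater agrees) or `"provided"` (pass through an external
#'   consensus, e.g. one reached by expert discussion).
#' @param tie tie-break for an even rater split under the majority rule;
#'   the default `"positive"` matches an inclusive screening stance.
#' @param consensus external consensus vector, required under
#'   `rule = "provided"`.
#' @return Integer consensus label per case.
#' @export
consensus_labels <- function(ratings, rule = c("majority", "unanimous", "provided"),
                             tie = c("positive", "negative"), consensus = NULL) {
  rule <- match.arg(rule)
  tie <- match.arg(tie)
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("ratings must have no missing entries")
  if (any(!ratings %in% c(0, 1))) stop("ratings must be 0 or 1")
  if (rule == "provided") {
    if (is.null(consensus)) stop("rule = 'provided' requires a consensus vector")
    if (length(consensus) != nrow(ratings))
      stop("consensus length must match the number of cases")
    return(as.integer(consensus))
  }
  if (rule == "unanimous") return(as.integer(rowSums(ratings) == ncol(ratings)))
  frac <- rowMeans(ratings)
  out <- as.integer(frac > 0.5)
  ties <- abs(frac - 0.5) < 1e-12
  out[ties] <- if (tie == "positive") 1L else 0L
  out
}

#' Percent agreement between two label vectors
#'
#' @param a,b equal-length label vectors.
#' @return `100 * matches / n`.
#' @export
pairwise_agreement <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  100 * mean(a == b)
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with the expected
#' agreement computed from the two raters' marginal label frequencies.
#'
#' @param a,b equal-length label vectors; at least two categories must be
#'   represented overall.
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  cats <- sort(unique(c(a, b)))
  if (length(cats) < 2L)
    stop("kappa is undefined: only one category present across both raters")
  n <- length(a)
  po <- mean(a == b)
  pe <- sum(vapply(cats, function(k) mean(a == k) * mean(b == k), numeric(1)))
  if (abs(1 - pe) < 1e-12) return(1)
  (po - pe) / (1 - pe)
}

#' Fleiss' kappa for multiple raters
#'
#' Chance-corrected agreement for `n` cases rated by `m` raters each, with
#' the large-sample z statistic and two-sided p-value.
#'
#' @param ratings case-by-rater matrix with categorical entries (no missing
#'   values); at least two categories must appear.
#' @return A list with `kappa`, `z` and `p`.
#' @export
fleiss_kappa <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("ratings must have no missing entries")
  cats <- sort(unique(as.vector(ratings)))
  if (length(cats) < 2L)
    stop("kappa is undefined: only one category present in the ratings")
  n <- nrow(ratings)
  m <- ncol(ratings)
  counts <- vapply(cats, function(k) rowSums(ratings == k),
                   numeric(n))  # n x categories
  p_j <- colSums(counts) / (n * m)
  P_i <- (rowSums(counts^2) - m) / (m * (m - 1))
  P_bar <- mean(P_i)
  P_e <- sum(p_j^2)
  kappa <- (P_bar - P_e) / (1 - P_e)
  # Large-sample null variance (Fleiss 1971).
  num <- 2 * (P_e - (2 * m - 3) * P_e^2 + 2 * (m - 2) * sum(p_j^3))
  var0 <- num / (n * m * (m - 1) * (1 - P_e)^2)
  z <- kappa / sqrt(var0)
  list(kappa = kappa, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Risk category from a calibrated probability
#'
#' Low is strictly below the lower cut, high strictly above the upper cut,
#' and the boundaries belong to the intermediate band.
#'
#' @param probs probability vector.
#' @param cuts lower and upper cut points, default `c(0.25, 0.75)`.
#' @return Factor with levels `low`, `intermediate`, `high`.
#' @export
risk_category <- function(probs, cuts = c(0.25, 0.75)) {
  out <- ifelse(probs < cuts[1], "low",
                ifelse(probs > cuts[2], "high", "intermediate"))
  factor(out, levels = c("low", "intermediate", "high"))
}

#' Three-way review outcome from the raw ratings
#'
#' @param ratings case-by-rater 0/1 matrix.
#' @return Factor with levels `unanimous_no`, `dissenting`, `unanimous_yes`.
#' @export
review_outcome <- function(ratings) {
  ratings <- as.matrix(ratings)
  frac <- rowMeans(ratings)
  out <- ifelse(frac == 0, "unanimous_no",
                ifelse(frac == 1, "unanimous_yes", "dissenting"))
  factor(out, levels = c("unanimous_no", "dissenting", "unanimous_yes"))
}

# Monte-Carlo Fisher exact test for an r x c table: under fixed margins the
# table probability is proportional to exp(-sum(lfactorial(cells))), so the
# p-value is the chance of a table at most as probable as the observed one.
fisher_mc <- function(tab, n_draws = 1e6, seed = 1L) {
  tab <- as.matrix(tab)
  keep_r <- rowSums(tab) > 0
  keep_c <- colSums(tab) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("dropping empty rows/columns from the contingency table")
    tab <- tab[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L) return(1)
  set.seed(seed)
  obs <- -sum(lfactorial(tab))
  sims <- stats::r2dtable(n_draws, rowSums(tab), colSums(tab))
  stat <- vapply(sims, function(t) -sum(lfactorial(t)), numeric(1))
  (1 + sum(stat <= obs + 1e-7)) / (n_draws + 1)
}

#' Stratify review outcomes by risk category and test for association
#'
#' Cross-tabulates the three-way review outcome against the model's risk
#' categories and computes a Fisher exact p-value for the r x c table by
#' Monte-Carlo sampling of tables with fixed margins (validated against full
#' enumeration on small tables).
#'
#' @param probs per-case calibrated probability.
#' @param consensus_3way factor from [review_outcome()] (or equivalent),
#'   aligned with `probs`.
#' @param cuts risk-category cut points.
#' @param n_draws Monte-Carlo tables to draw.
#' @param seed integer seed.
#' @return A list with `strata_table` (outcome x category counts) and
#'   `fisher_p`.
#' @export
stratify_and_test <- function(probs, consensus_3way, cuts = c(0.25, 0.75),
                              n_draws = 1e6, seed = 1L) {
  if (length(probs) != length(consensus_3way))
    stop("probs and outcomes must be aligned")
  tab <- table(outcome = consensus_3way, category = risk_category(probs, cuts))
  list(strata_table = tab, fisher_p = fisher_mc(tab, n_draws, seed))
}

#' Classification metrics against a review gold standard
#'
#' AUC by the rank (Wilcoxon) statistic with midrank ties; precision, recall
#' and F1 at a probability threshold.
#'
#' @param probs per-case probability.
#' @param consensus 0/1 gold-standard labels; both classes must be present.
#' @param threshold classification threshold, default 0.5.
#' @return A list with `auc`, `f1`, `precision`, `recall`.
#' @export
classification_metrics <- function(probs, consensus, threshold = 0.5) {
  consensus <- as.integer(consensus)
  if (length(unique(consensus)) < 2L)
    stop("AUC is undefined with a single-class consensus")
  n_pos <- sum(consensus == 1L)
  n_neg <- sum(consensus == 0L)
  r <- rank(probs)
  auc <- (sum(r[consensus == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  pred <- as.integer(probs >= threshold)
  tp <- sum(pred == 1L & consensus == 1L)
  precision <- if (sum(pred == 1L) == 0L) NA_real_ else tp / sum(pred == 1L)
  recall <- tp / n_pos
  f1 <- if (is.na(precision) || precision + recall == 0) 0
        else 2 * precision * recall / (precision + recall)
  list(auc = auc, f1 = f1, precision = precision, recall = recall)
}

#' Full agreement report for a chart-review audit
#'
#' Assembles the pairwise percent-agreement and Cohen-kappa matrices among
#' raters, the model's thresholded classification and the consensus; Fleiss'
#' kappa across raters; the risk-category stratification with its
#' Monte-Carlo Fisher test; and classification metrics against consensus.
#'
#' @param ratings case-by-rater 0/1 matrix.
#' @param probs per-case calibrated probability, aligned with `ratings` rows.
#' @param consensus optional externally provided consensus; defaults to the
#'   majority rule with ties positive.
#' @param threshold model classification threshold.
#' @param n_draws,seed Monte-Carlo settings for the Fisher test.
#' @return An object of class `agreement_report`.
#' @export
agreement_report <- function(ratings, probs, consensus = NULL, threshold = 0.5,
                             n_draws = 1e6, seed = 1L) {
  ratings <- as.matrix(ratings)
  if (nrow(ratings) != length(probs)) stop("ratings and probs must be aligned")
  cons <- if (is.null(consensus)) consensus_labels(ratings, "majority")
          else consensus_labels(ratings, "provided", consensus = consensus)
  model <- as.integer(probs >= threshold)
  raters <- colnames(ratings) %||% paste0("rater", seq_len(ncol(ratings)))
  cols <- cbind(ratings, model = model, consensus = cons)
  colnames(cols) <- c(raters, "model", "consensus")
  m <- ncol(cols)
  pct <- matrix(NA_real_, m, m, dimnames = list(colnames(cols), colnames(cols)))
  kap <- pct
  for (i in seq_len(m)) for (j in seq_len(m)) {
    pct[i, j] <- pairwise_agreement(cols[, i], cols[, j])
    kap[i, j] <- if (i == j) 1 else tryCatch(cohen_kappa(cols[, i], cols[, j]),
                                             error = function(e) NA_real_)
  }
  strat <- stratify_and_test(probs, review_outcome(ratings),
                             n_draws = n_draws, seed = seed)
  structure(list(pairwise_pct = pct, cohen_kappa = kap,
                 fleiss = fleiss_kappa(ratings),
                 strata_table = strat$strata_table,
                 fisher_p = strat$fisher_p,
                 metrics = classification_metrics(probs, cons, threshold),
                 consensus = cons),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("agreement_report\n  pairwise percent agreement:\n")
  print(round(x$pairwise_pct, 1))
  cat(sprintf("  Fleiss kappa = %.3f (z = %.1f, p = %.3g)\n",
              x$fleiss$kappa, x$fleiss$z, x$fleiss$p))
  cat(sprintf("  Fisher exact (MC) p = %.4f\n", x$fisher_p))
  with(x$metrics, cat(sprintf(
    "  AUC %.4f, F1 %.4f, precision %.4f, recall %.4f\n",
    auc, f1, precision, recall)))
  invisible(x)
}
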