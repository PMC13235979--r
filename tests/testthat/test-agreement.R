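test_that("consensus rules and the tie-break behave as documented", {
  r <- rbind(c(1, 1, 1, 1), c(1, 1, 0, 0), c(0, 0, 0, 1), c(0, 0, 0, 0))
  expect_equal(consensus_labels(r, "majority"), c(1L, 1L, 0L, 0L))
  expect_equal(consensus_labels(r, "majority", tie = "negative"),
               c(1L, 0L, 0L, 0L))
  expect_equal(consensus_labels(r, "unanimous"), c(1L, 0L, 0L, 0L))
  expect_equal(consensus_labels(r, "provided", consensus = c(0, 1, 1, 0)),
               c(0L, 1L, 1L, 0L))
  expect_error(consensus_labels(r, "provided"), "consensus vector")
  expect_error(consensus_labels(rbind(c(1, NA))), "missing")
})

test_that("pairwise agreement matches hand arithmetic and is symmetric", {
  a <- rep(1, 10); b <- rep(0, 10)
  expect_equal(pairwise_agreement(a, a), 100)
  expect_equal(pairwise_agreement(a, b), 0)
  # 87 matches of 97 charts
  x <- rep(1, 97); y <- x; y[1:10] <- 0
  expect_equal(round(pairwise_agreement(x, y), 1), 89.7)
  set.seed(1)
  u <- rbinom(50, 1, 0.5); v <- rbinom(50, 1, 0.5)
  expect_equal(pairwise_agreement(u, v), pairwise_agreement(v, u))
  expect_error(pairwise_agreement(1:3, 1:4), "equal length")
})

test_that("Cohen's kappa matches the frozen worked example and is chance-level on noise", {
  # hand-computed: po = 0.8, pe = 0.48 -> kappa = 0.32/0.52
  expect_equal(cohen_kappa(c(1, 1, 0, 0, 1), c(1, 0, 0, 0, 1)), 0.6153846,
               tolerance = 1e-6)
  set.seed(4)
  a <- rbinom(10000, 1, 0.5); b <- rbinom(10000, 1, 0.5)
  expect_lt(abs(cohen_kappa(a, b)), 0.05)
  expect_equal(cohen_kappa(a, b), cohen_kappa(b, a))
  expect_error(cohen_kappa(rep(1, 5), rep(1, 5)), "one category")
})

test_that("Fleiss' kappa matches the independent oracle on a worked table", {
  # 5 cases x 3 raters; kappa and z frozen from an independent implementation
  r <- rbind(c(1, 1, 1), c(1, 1, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 1))
  f <- fleiss_kappa(r)
  expect_equal(f$kappa, 0.4444444, tolerance = 1e-6)
  expect_equal(f$z, 1.5936381, tolerance = 1e-6)
  expect_equal(f$p, 2 * pnorm(-abs(f$z)))
  # perfect agreement
  expect_equal(fleiss_kappa(cbind(c(1, 0, 1), c(1, 0, 1), c(1, 0, 1)))$kappa, 1)
  # independent raters are chance-level
  set.seed(11)
  big <- matrix(rbinom(2 * 10000, 1, 0.5), ncol = 2)
  expect_lt(abs(fleiss_kappa(big)$kappa), 0.05)
  expect_error(fleiss_kappa(matrix(1, 4, 3)), "one category")
})

test_that("risk categories use closed boundaries at the cuts", {
  p <- c(0.249, 0.25, 0.5, 0.75, 0.751)
  expect_equal(as.character(risk_category(p)),
               c("low", "intermediate", "intermediate", "intermediate", "high"))
})

test_that("review_outcome distinguishes unanimity from dissent", {
  r <- rbind(c(0, 0, 0, 0), c(1, 0, 0, 0), c(1, 1, 1, 1))
  expect_equal(as.character(review_outcome(r)),
               c("unanimous_no", "dissenting", "unanimous_yes"))
})

test_that("Monte-Carlo Fisher test converges to the exact p-value", {
  t22 <- matrix(c(8, 2, 3, 9), 2)
  exact <- fisher.test(t22)$p.value
  mc <- puprev:::fisher_mc(t22, n_draws = 2e5, seed = 3)
  expect_lt(abs(mc - exact), 0.005)
  # small 3x3: exact enumeration available through the network algorithm
  t33 <- matrix(c(5, 1, 0, 2, 4, 1, 0, 2, 5), 3)
  exact3 <- fisher.test(t33)$p.value
  mc3 <- puprev:::fisher_mc(t33, n_draws = 2e5, seed = 3)
  expect_lt(abs(mc3 - exact3), 0.005)
  # reproducible given the seed
  expect_identical(mc3, puprev:::fisher_mc(t33, n_draws = 2e5, seed = 3))
})

test_that("stratify_and_test handles degenerate and regular tables", {
  out3 <- factor(rep(c("unanimous_no", "dissenting", "unanimous_yes"), each = 10),
                 levels = c("unanimous_no", "dissenting", "unanimous_yes"))
  # constant probabilities: one occupied category, no association possible
  expect_warning(res <- stratify_and_test(rep(0.5, 30), out3, n_draws = 1e3),
                 "empty")
  expect_equal(res$fisher_p, 1)
  # associated case
  p <- c(runif(10, 0, 0.2), runif(10, 0.3, 0.7), runif(10, 0.8, 1))
  res2 <- stratify_and_test(p, out3, n_draws = 1e4, seed = 2)
  expect_equal(sum(res2$strata_table), 30)
  expect_lt(res2$fisher_p, 0.05)
  expect_equal(unname(rowSums(res2$strata_table)), c(10, 10, 10))
})

test_that("classification metrics match brute-force oracles", {
  # AUC over all positive-negative pairs: 3 of 4 ordered correctly
  m <- classification_metrics(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(m$auc, 0.75)
  # perfect separation
  ms <- classification_metrics(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(ms$auc, 1)
  expect_equal(ms$f1, 1)
  # printed-precision/recall world: 97 cases, 39 positive, 48 flagged, 24 TP
  probs <- c(rep(0.9, 24), rep(0.1, 15), rep(0.9, 24), rep(0.1, 34))
  labs <- c(rep(1, 39), rep(0, 58))
  mp <- classification_metrics(probs, labs)
  expect_equal(mp$precision, 0.5)
  expect_equal(round(mp$recall, 4), 0.6154)
  expect_equal(round(mp$f1, 4), 0.5517)
  # AUC invariant under any logit shift (ties the audit to the calibration)
  set.seed(3)
  pr <- runif(200, 0.01, 0.99); y <- rbinom(200, 1, pr)
  expect_equal(classification_metrics(pr, y)$auc,
               classification_metrics(apply_shift(pr, -0.54), y)$auc)
  expect_error(classification_metrics(pr, rep(1, 200)), "single-class")
})

test_that("agreement_report assembles a coherent audit summary", {
  set.seed(17)
  n <- 97
  truth <- rbinom(n, 1, 0.4)
  ratings <- sapply(1:4, function(r) ifelse(rbinom(n, 1, 0.85) == 1, truth,
                                            1 - truth))
  probs <- plogis(qlogis(pmin(pmax(truth * 0.6 + 0.2, 0.05), 0.95)) +
                  rnorm(n, 0, 0.8))
  rep_ <- agreement_report(ratings, probs, n_draws = 1e4, seed = 1)
  expect_equal(unname(diag(rep_$pairwise_pct)), rep(100, 6))
  expect_equal(rep_$pairwise_pct, t(rep_$pairwise_pct))
  expect_true(all(rep_$cohen_kappa[!is.na(rep_$cohen_kappa)] >= -1 &
                  rep_$cohen_kappa[!is.na(rep_$cohen_kappa)] <= 1))
  expect_equal(sum(rep_$strata_table), n)
  expect_gt(rep_$fleiss$kappa, 0.2)  # raters share the same truth signal
  expect_true(is.numeric(rep_$metrics$auc))
})
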