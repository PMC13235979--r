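test_that("make_partition_plan follows the floor rule and partitions the unlabeled set", {
  plan <- make_partition_plan(100, paste0("u", 1:1000), seed = 4)
  expect_equal(plan$k, 10)
  expect_equal(as.integer(table(plan$assignments)), rep(100L, 10))

  # remainder absorbed into the last group
  plan2 <- make_partition_plan(100, paste0("u", 1:150), seed = 4)
  expect_equal(plan2$k, 1)
  expect_equal(sum(plan2$assignments == 1), 150)

  plan3 <- make_partition_plan(7, paste0("u", 1:100), seed = 9)
  expect_equal(plan3$k, 14)
  expect_setequal(names(plan3$assignments), paste0("u", 1:100))
  expect_equal(sum(table(plan3$assignments)), 100)
  expect_equal(sum(plan3$assignments == 14), 7 + 100 %% 7)

  expect_error(make_partition_plan(10, paste0("u", 1:5)), "fewer unlabeled")
  expect_identical(make_partition_plan(7, paste0("u", 1:100), seed = 9)$assignments,
                   plan3$assignments)
})

test_that("the published cohort counts give k = 52 balanced datasets", {
  plan <- make_partition_plan(24625, seq_len(1304495), seed = 1)
  expect_equal(plan$k, 52)
  expect_equal(24625 + 1304495, 1329120)
})

test_that("fit_pu_scores separates separable data and stays flat on no-signal data", {
  # separable: labeled positives carry a private always-on covariate block
  n <- 300
  x <- matrix(rbinom(n * 20, 1, 0.05), n, 20)
  y <- rep(c(1L, 0L), each = n / 2)
  x[y == 1L, 1:3] <- 1
  ds <- pu_dataset(Matrix::Matrix(x, sparse = TRUE), y)
  sc <- fit_pu_scores(ds, fast_cc, v_folds = 3, seed = 1)
  expect_gt(mean(sc$scores_P), mean(sc$scores_U))
  expect_true(all(sc$scores_P >= 1e-6 & sc$scores_P <= 1 - 1e-6))

  # identical rows: scores collapse to the labeled fraction (0.5)
  xc <- Matrix::Matrix(matrix(1, n, 5), sparse = TRUE)
  dsc <- pu_dataset(xc, y)
  scc <- fit_pu_scores(dsc, fast_cc, v_folds = 3, seed = 1)
  expect_true(all(abs(c(scc$scores_P, scc$scores_U) - 0.5) < 0.05))
})

test_that("shuffled labels give chance-level AUC (permutation null)", {
  ch <- generate_cohort(tiny_config(seed = 21))
  set.seed(5)
  y <- sample(ch$labels)  # break the label-feature link
  ds <- pu_dataset(ch$features, y)
  halves <- split_pu(ds)
  rows <- c(which(y == 1L), sample(which(y == 0L), sum(y == 1L)))
  balanced <- puprev:::subset_pu(ds, rows)
  sc <- fit_pu_scores(balanced, fast_cc, v_folds = 3, seed = 2)
  scores <- c(sc$scores_P, sc$scores_U)
  labs <- rep(c(1L, 0L), c(length(sc$scores_P), length(sc$scores_U)))
  auc <- classification_metrics(scores, labs)$auc
  # permutation null for the same score vector
  null_auc <- vapply(1:200, function(i) {
    classification_metrics(scores, sample(labs))$auc
  }, numeric(1))
  expect_gte(auc, quantile(null_auc, 0.005))
  expect_lte(auc, quantile(null_auc, 0.995))
})

test_that("fit_pu_scores validates folds and classes", {
  x <- Matrix::Matrix(matrix(rbinom(40, 1, 0.5), 20, 2), sparse = TRUE)
  expect_error(fit_pu_scores(pu_dataset(x, rep(1L, 20))), "both labeled and unlabeled")
  expect_error(fit_pu_scores(pu_dataset(x, rep(c(1L, 0L), 10)), v_folds = 1),
               "at least 2")
  expect_error(fit_pu_scores(pu_dataset(x, c(1L, rep(0L, 19))), v_folds = 5),
               "at least v_folds")
})

test_that("estimate_densities normalizes on a shared grid", {
  set.seed(3)
  s <- runif(5000)
  d <- estimate_densities(make_score_set(s, s), n_bins = 10)
  expect_identical(d$f_P, d$f_U)  # same multiset, same grid
  width <- diff(d$breaks)[1]
  expect_equal(sum(d$f_P * width), 1, tolerance = 1e-9)
  expect_equal(sum(d$f_U * width), 1, tolerance = 1e-9)
  # uniform scores: every cell near density 1 (multinomial oracle)
  se <- sqrt(0.9 / (5000 * 0.1))
  expect_true(all(abs(d$f_P - 1) < 3 * se))

  expect_error(estimate_densities(make_score_set(runif(10), runif(10))),
               "at least 30")
  expect_error(
    estimate_densities(make_score_set(rep(0.5, 100), rep(0.5, 100)), n_bins = 20),
    "nonempty bins")
})

test_that("estimate_alpha_scar recovers the mixture proportion from densities", {
  set.seed(8)
  sP <- rbeta(10000, 8, 2)
  sU <- c(rbeta(3000, 8, 2), rbeta(7000, 2, 8))
  d <- estimate_densities(make_score_set(sP, sU))
  # analytic oracle: min_s f_U/f_P = 0.3 (Beta(2,8)/Beta(8,2) -> 0 as s -> 1)
  a <- estimate_alpha_scar(d, method = "tail")
  expect_gte(a, 0.25)
  expect_lte(a, 0.35)
  # the per-bin minimum is a noisier lower envelope of the same bound: it
  # must not exceed the analytic value plus noise, but it undershoots
  a_bin <- estimate_alpha_scar(d, method = "bin")
  expect_lte(a_bin, 0.35)
  expect_lte(a_bin, a + 1e-9)
  # identical arms: alpha = 1
  dd <- estimate_densities(make_score_set(sP, sP))
  expect_equal(estimate_alpha_scar(dd), 1)
  expect_equal(estimate_alpha_scar(dd, method = "bin"), 1)
  # disjoint supports: alpha ~ 0
  d0 <- estimate_densities(make_score_set(runif(1000, 0.7, 0.99),
                                          runif(1000, 0.01, 0.3)))
  expect_lte(estimate_alpha_scar(d0), 0.05)
})

test_that("pulscar satisfies its structural invariants", {
  ch <- generate_cohort(small_config(seed = 31))
  fit <- pulscar(ch, fast_cc, v_folds = 3, seed = 31)
  # mean-components identity and range
  expect_equal(fit$alpha$alpha, mean(fit$alpha$per_partition), tolerance = 1e-12)
  expect_true(all(fit$alpha$per_partition >= 0 & fit$alpha$per_partition <= 1))
  # every record carries exactly one probability
  expect_equal(sum(is.na(fit$raw_probs)), 0)
  expect_setequal(names(fit$raw_probs), ch$record_ids)
  # determinism
  fit2 <- pulscar(ch, fast_cc, v_folds = 3, seed = 31)
  expect_identical(fit$alpha$per_partition, fit2$alpha$per_partition)
  expect_identical(fit$raw_probs, fit2$raw_probs)
})

test_that("pulscar k = 1 degenerate case has a single partition equal to alpha", {
  cfg <- synthetic_config(n_records = 800, n_covariates = 60, n_informative = 12,
                          true_alpha = 0.6, coded_fraction = 0.7, seed = 5)
  ch <- generate_cohort(cfg)
  # |U| < 2 |P| here, so k = 1
  fit <- pulscar(ch, fast_cc, v_folds = 3, seed = 5)
  expect_equal(fit$plan$k, 1)
  expect_length(fit$alpha$per_partition, 1)
  expect_equal(fit$alpha$alpha, fit$alpha$per_partition[1])
})

test_that("pulscar recovers the class prior on SCAR data (single-seed screen)", {
  ch <- generate_cohort(synthetic_config(n_records = 10000, n_covariates = 300,
                                         n_informative = 40, seed = 42))
  fit <- pulscar(ch, fast_cc, seed = 42)
  expect_lt(abs(fit$alpha$alpha - true_unlabeled_alpha(ch)), 0.07)
})

test_that("alpha estimates do not undershoot the truth beyond estimation noise", {
  hits <- vapply(1:10, function(s) {
    ch <- generate_cohort(synthetic_config(n_records = 4000, n_covariates = 150,
                                           n_informative = 30, seed = 600 + s))
    fit <- pulscar(ch, fast_cc, v_folds = 3, seed = 600 + s)
    sd_ <- if (is.na(fit$alpha$sd)) 0 else fit$alpha$sd
    fit$alpha$alpha >= true_unlabeled_alpha(ch) - 2 * sd_
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("capped pulscar still scores every unlabeled record", {
  ch <- generate_cohort(small_config(seed = 77))
  fit <- pulscar(ch, fast_cc, v_folds = 3, seed = 77, max_partitions = 3)
  expect_equal(sum(is.na(fit$raw_probs)), 0)
  expect_length(fit$alpha$per_partition, 3)
})
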