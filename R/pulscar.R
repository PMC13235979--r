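#' Partition the unlabeled set into balanced-ensemble groups
#'
#' With extreme class imbalance, the unlabeled set is split into
#' `k = floor(|unlabeled| / size)` disjoint groups (a partition), where
#' `size` defaults to the number of labeled positives. Each group is later
#' paired with all labeled positives to form one balanced dataset; the
#' remainder records join the last group.
#'
#' @param n_labeled number of labeled positives (>= 1).
#' @param unlabeled_ids identifiers of unlabeled records.
#' @param seed integer seed for the shuffle.
#' @param unlabeled_per_partition minimum unlabeled records per group;
#'   defaults to `n_labeled` (the balanced-undersampling rule). Raising it
#'   stabilises estimation for very small labeled sets.
#' @return An object of class `partition_plan` with elements `k`,
#'   `assignments` (named integer vector mapping each unlabeled id to a group
#'   in `1..k`) and `seed`.
#' @export
make_partition_plan <- function(n_labeled, unlabeled_ids, seed = 1L,
                                unlabeled_per_partition = NULL) {
  n_labeled <- as.integer(n_labeled)
  if (n_labeled < 1L) stop("n_labeled must be at least 1")
  n_u <- length(unlabeled_ids)
  size <- max(n_labeled, as.integer(unlabeled_per_partition %||% 0L))
  if (n_u < n_labeled)
    stop("fewer unlabeled than labeled records (k = 0): balanced ",
         "undersampling is undefined; run a single balanced dataset with ",
         "all unlabeled records instead")
  k <- max(1L, n_u %/% size)
  set.seed(seed)
  shuffled <- sample(unlabeled_ids)
  idx <- c(rep(seq_len(k), each = size), rep.int(k, n_u - k * size))
  assignments <- stats::setNames(idx, shuffled)[as.character(unlabeled_ids)]
  structure(list(k = k, assignments = assignments, seed = as.integer(seed)),
            class = "partition_plan")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cross-fitted PU classifier scores for one balanced dataset
#'
#' Fits the configured classifier with stratified v-fold cross-fitting so
#' that every record's score comes from a model that never saw it, then
#' clips scores into `[1e-6, 1 - 1e-6]` so logits stay finite.
#'
#' @param balanced a [pu_dataset()] holding all labeled positives plus one
#'   unlabeled group.
#' @param config a [classifier_config()].
#' @param v_folds number of cross-fitting folds (>= 2).
#' @param seed integer seed for fold assignment.
#' @return An object of class `score_set`: `scores_P` and `scores_U` (named
#'   by record id) and `fold_map`.
#' @export
fit_pu_scores <- function(balanced, config = classifier_config(),
                          v_folds = 5L, seed = 1L) {
  stopifnot(inherits(balanced, "pu_dataset"))
  v_folds <- as.integer(v_folds)
  if (v_folds < 2L) stop("v_folds must be at least 2")
  y <- balanced$labels
  if (!any(y == 1L) || !any(y == 0L))
    stop("balanced dataset must contain both labeled and unlabeled records")
  if (min(sum(y == 1L), sum(y == 0L)) < v_folds)
    stop("each class needs at least v_folds records for stratified folds")
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in c(0L, 1L)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(v_folds), length(idx)))
  }
  x <- balanced$features
  p <- rep(NA_real_, length(y))
  for (f in seq_len(v_folds)) {
    tr <- fold != f
    model <- fit_classifier(x[tr, , drop = FALSE], y[tr], config)
    p[!tr] <- predict_classifier(model, x[!tr, , drop = FALSE], config)
  }
  if (any(!is.finite(p))) stop("classifier produced non-finite scores")
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  names(p) <- balanced$record_ids
  structure(list(scores_P = p[y == 1L], scores_U = p[y == 0L],
                 fold_map = stats::setNames(fold, balanced$record_ids)),
            class = "score_set")
}

#' Shared-bin score densities for the two PU arms
#'
#' Histogram densities of labeled-positive and unlabeled scores on a common
#' grid over `[0, 1]`, together with the empirical survival functions used by
#' the tail-ratio class-prior estimator. The automatic bin count is
#' `max(20, min(100, round(sqrt(min(n_P, n_U)))))`.
#'
#' @param scores a `score_set` from [fit_pu_scores()].
#' @param n_bins number of bins, or `"auto"`.
#' @param tau support floor: grid cells with `f_P >= tau * max(f_P)` form the
#'   support mask.
#' @return An object of class `score_densities` with the grid (`breaks`),
#'   densities `f_P`, `f_U`, `support_mask`, survival functions `surv_P`,
#'   `surv_U` evaluated at the breaks, and the arm sizes.
#' @export
estimate_densities <- function(scores, n_bins = "auto", tau = 0.01) {
  stopifnot(inherits(scores, "score_set"))
  sP <- scores$scores_P
  sU <- scores$scores_U
  if (length(sP) < 30L || length(sU) < 30L)
    stop("need at least 30 scores per arm to estimate densities")
  if (identical(n_bins, "auto"))
    n_bins <- max(20L, min(100L, round(sqrt(min(length(sP), length(sU))))))
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  width <- 1 / n_bins
  cP <- graphics::hist(sP, breaks = breaks, plot = FALSE)$counts
  cU <- graphics::hist(sU, breaks = breaks, plot = FALSE)$counts
  if (sum(cP + cU > 0L) < 5L)
    stop("fewer than 5 nonempty bins; supply more scores or fewer bins")
  f_P <- cP / (length(sP) * width)
  f_U <- cU / (length(sU) * width)
  structure(list(breaks = breaks, mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 f_P = f_P, f_U = f_U,
                 support_mask = f_P >= tau * max(f_P),
                 surv_P = 1 - stats::ecdf(sP)(breaks),
                 surv_U = 1 - stats::ecdf(sU)(breaks),
                 n_P = length(sP), n_U = length(sU)),
            class = "score_densities")
}

#' Class-prior estimate from score densities (SCAR)
#'
#' Under the mixture `f_U = alpha * f_P + (1 - alpha) * f_N` with
#' `f_N >= 0`, `alpha <= f_U(s) / f_P(s)` pointwise, and likewise
#' `alpha <= S_U(s) / S_P(s)` for the survival functions. The default
#' `"tail"` method minimises the survival-function ratio over grid points
#' whose positive-arm tail holds enough mass (at least `min_tail`, and at
#' least 10 observations in each arm), which is markedly less noise-prone
#' than the per-bin density ratio; `"bin"` is the classical minimum density
#' ratio over the support mask.
#'
#' @param densities a `score_densities` from [estimate_densities()].
#' @param method `"tail"` (default) or `"bin"`.
#' @param min_tail minimum positive-arm tail mass at which the tail ratio is
#'   evaluated (default 0.10; thinner tails make the minimum noise-dominated).
#' @return The class-prior estimate, clipped to `[0, 1]`.
#' @export
estimate_alpha_scar <- function(densities, method = c("tail", "bin"),
                                min_tail = 0.10) {
  stopifnot(inherits(densities, "score_densities"))
  method <- match.arg(method)
  if (method == "bin") {
    m <- densities$support_mask
    if (!any(m)) stop("empty support mask: positive-score density vanished")
    a <- min(densities$f_U[m] / densities$f_P[m])
  } else {
    floor_ <- max(min_tail, 10 / densities$n_P, 10 / densities$n_U)
    m <- densities$surv_P >= floor_
    if (!any(m)) stop("no grid point with enough positive tail mass")
    a <- min(densities$surv_U[m] / densities$surv_P[m])
  }
  min(1, max(0, a))
}

#' Class-prior container
#'
#' @param alpha overall class-prior point estimate in `[0, 1]`.
#' @param per_partition per-balanced-dataset estimates (their mean is `alpha`
#'   for PULSCAR).
#' @param method `"PULSCAR"` or `"PULSNAR"`.
#' @param per_cluster optional per-subtype estimates (PULSNAR).
#' @return An object of class `alpha_estimate`.
#' @export
alpha_estimate <- function(alpha, per_partition, method, per_cluster = NULL) {
  structure(list(alpha = alpha, per_partition = per_partition,
                 per_cluster = per_cluster,
                 sd = stats::sd(per_partition), method = method),
            class = "alpha_estimate")
}

#' @export
print.alpha_estimate <- function(x, ...) {
  cat(sprintf("%s class-prior estimate: alpha = %.4f (sd over %d partitions: %.4f)\n",
              x$method, x$alpha, length(x$per_partition),
              if (is.na(x$sd)) 0 else x$sd))
  if (!is.null(x$per_cluster))
    cat("  per-cluster:", paste(sprintf("%.4f", x$per_cluster), collapse = ", "), "\n")
  invisible(x)
}

#' PULSCAR: balanced-ensemble class-prior estimation under SCAR
#'
#' Splits the unlabeled set into `k = floor(|U|/|P|)` groups, pairs each
#' group with all labeled positives, scores every record by stratified
#' cross-fitting within its balanced dataset, estimates the class prior per
#' balanced dataset, and averages the `k` estimates. Each unlabeled record's
#' raw probability is its out-of-fold score from its own partition; each
#' labeled record's is the mean of its scores across the fitted partitions.
#'
#' @param dataset a [pu_dataset()] with at least one labeled positive and at
#'   least as many unlabeled records.
#' @param config a [classifier_config()].
#' @param v_folds cross-fitting folds per balanced dataset.
#' @param n_bins histogram bins for the density step (or `"auto"`).
#' @param seed integer seed.
#' @param max_partitions cap on the number of balanced datasets actually
#'   fitted (sampled without replacement from the plan); `Inf` fits all.
#'   Records in unfitted partitions are scored by averaging the fitted
#'   partitions' full-data models.
#' @param unlabeled_floor minimum unlabeled records per balanced dataset
#'   (see [make_partition_plan()]); 0 keeps the strict balanced rule.
#' @param alpha_method passed to [estimate_alpha_scar()].
#' @return A list with `alpha` (an [alpha_estimate()]), `raw_probs` (named
#'   probability per record) and `plan` (the [make_partition_plan()] used).
#' @export
pulscar <- function(dataset, config = classifier_config(), v_folds = 5L,
                    n_bins = "auto", seed = 1L, max_partitions = Inf,
                    unlabeled_floor = 0L, alpha_method = "tail") {
  stopifnot(inherits(dataset, "pu_dataset"))
  halves <- split_pu(dataset)
  p_idx <- which(dataset$labels == 1L)
  u_idx <- which(dataset$labels == 0L)
  plan <- make_partition_plan(length(p_idx), dataset$record_ids[u_idx],
                              seed = seed,
                              unlabeled_per_partition = unlabeled_floor)
  fitted <- seq_len(plan$k)
  if (is.finite(max_partitions) && plan$k > max_partitions) {
    set.seed(child_seed(seed, 9999L))
    fitted <- sort(sample(fitted, max_partitions))
  }
  alphas <- numeric(length(fitted))
  raw <- stats::setNames(rep(NA_real_, length(dataset$labels)), dataset$record_ids)
  p_scores <- matrix(NA_real_, length(p_idx), length(fitted))
  full_models <- vector("list", length(fitted))
  for (j in seq_along(fitted)) {
    part <- fitted[j]
    u_ids <- names(plan$assignments)[plan$assignments == part]
    rows <- c(p_idx, match(u_ids, dataset$record_ids))
    balanced <- subset_pu(dataset, rows)
    scores <- fit_pu_scores(balanced, config, v_folds,
                            seed = child_seed(seed, part))
    alphas[j] <- estimate_alpha_scar(estimate_densities(scores, n_bins),
                                     method = alpha_method)
    p_scores[, j] <- scores$scores_P[dataset$record_ids[p_idx]]
    raw[names(scores$scores_U)] <- scores$scores_U
    if (length(fitted) < plan$k)
      full_models[[j]] <- fit_classifier(balanced$features, balanced$labels, config)
  }
  raw[dataset$record_ids[p_idx]] <- rowMeans(p_scores)
  uncovered <- names(raw)[is.na(raw)]
  if (length(uncovered)) {
    x <- dataset$features[match(uncovered, dataset$record_ids), , drop = FALSE]
    preds <- vapply(full_models, function(m) {
      pmin(pmax(predict_classifier(m, x, config), 1e-6), 1 - 1e-6)
    }, numeric(length(uncovered)))
    raw[uncovered] <- if (length(uncovered) == 1L) mean(preds) else rowMeans(preds)
  }
  list(alpha = alpha_estimate(mean(alphas), alphas, "PULSCAR"),
       raw_probs = raw, plan = plan, fitted_partitions = fitted)
}
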