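#' Rank covariates by ensemble importance
#'
#' Fits the importance-profile classifier (a sparser penalty than the scoring
#' models) on up to `max_partitions` balanced datasets and averages the
#' absolute coefficient magnitudes, the penalised-regression analogue of mean
#' gain in a tree ensemble. Covariates the models never use get gain exactly
#' zero, so `n_informative` counts the covariates with positive gain.
#'
#' @param dataset a [pu_dataset()].
#' @param config a [classifier_config()] (glmnet engine required).
#' @param seed integer seed.
#' @param max_partitions balanced datasets to average over.
#' @return An object of class `feature_importance`: a data frame
#'   (`covariate_id`, `gain`) in descending gain order with attribute
#'   `n_informative`.
#' @export
rank_features <- function(dataset, config = classifier_config(), seed = 1L,
                          max_partitions = 5L) {
  stopifnot(inherits(dataset, "pu_dataset"))
  if (!any(dataset$labels == 1L) || !any(dataset$labels == 0L))
    stop("feature ranking needs both labeled and unlabeled records")
  p_idx <- which(dataset$labels == 1L)
  u_idx <- which(dataset$labels == 0L)
  plan <- make_partition_plan(length(p_idx), dataset$record_ids[u_idx],
                              seed = seed)
  fitted <- seq_len(min(plan$k, max_partitions))
  gains <- rep(0, ncol(dataset$features))
  for (part in fitted) {
    u_ids <- names(plan$assignments)[plan$assignments == part]
    rows <- c(p_idx, match(u_ids, dataset$record_ids))
    model <- fit_classifier(dataset$features[rows, , drop = FALSE],
                            dataset$labels[rows], config, for_importance = TRUE)
    gains <- gains + classifier_gains(model, config)
  }
  gains <- gains / length(fitted)
  out <- data.frame(covariate_id = dataset$covariate_ids, gain = gains,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$gain), ]
  rownames(out) <- NULL
  structure(out, n_informative = sum(gains > 0), class = c("feature_importance", "data.frame"))
}

# --- Bernoulli mixture EM ----------------------------------------------------

# One EM run on a dense binary matrix; add-one smoothing on the component
# rates keeps log-likelihoods finite. Returns hard assignments and the final
# observed-data log-likelihood.
bernoulli_mixture_em <- function(x, k, seed, init = NULL, max_iter = 80L,
                                 tol = 1e-6) {
  n <- nrow(x)
  if (k == 1L) {
    theta <- matrix((colSums(x) + 1) / (n + 2))
    ll <- sum(x %*% log(theta) + (1 - x) %*% log(1 - theta))
    return(list(cluster = rep(1L, n), loglik = ll))
  }
  set.seed(seed)
  cl0 <- init %||% sample.int(k, n, replace = TRUE)
  theta <- vapply(seq_len(k), function(c) {
    rows <- cl0 == c
    (colSums(x[rows, , drop = FALSE]) + 1) / (max(1L, sum(rows)) + 2)
  }, numeric(ncol(x)))
  pi_ <- rep(1 / k, k)
  ll_prev <- -Inf
  resp <- NULL
  for (it in seq_len(max_iter)) {
    lg <- x %*% log(theta) + (1 - x) %*% log(1 - theta)
    lg <- sweep(lg, 2L, log(pi_), `+`)
    mx <- apply(lg, 1L, max)
    resp <- exp(lg - mx)
    rs <- rowSums(resp)
    ll <- sum(mx + log(rs))
    resp <- resp / rs
    pi_ <- pmax(colMeans(resp), 1e-9)
    pi_ <- pi_ / sum(pi_)
    theta <- vapply(seq_len(k), function(c) {
      (colSums(resp[, c] * x) + 1) / (sum(resp[, c]) + 2)
    }, numeric(ncol(x)))
    if (abs(ll - ll_prev) < tol) break
    ll_prev <- ll
  }
  cl <- apply(resp, 1L, which.max)
  # relabel to consecutive 1..k' (components can empty out)
  cl <- match(cl, sort(unique(cl)))
  list(cluster = cl, loglik = ll)
}

#' Cluster labeled positives into putative subtypes
#'
#' Partitions the labeled positives on the submatrix of gain-positive
#' covariates using a Bernoulli-mixture model fitted by EM (random and
#' Ward-linkage initialisations, best likelihood kept). The cluster count is
#' chosen by AIC over `1..max_clusters`; selecting one component is the
#' single-subtype fallback, which is what SCAR-consistent data produce.
#'
#' @param positives a [pu_dataset()] view holding the labeled positives (at
#'   least 2 records).
#' @param importance a `feature_importance` from [rank_features()].
#' @param max_clusters largest candidate cluster count; values below 2 force
#'   a single cluster with a warning.
#' @param seed integer seed.
#' @param n_clusters optional override pinning the cluster count.
#' @param max_features use at most this many top-gain covariates.
#' @return An object of class `subtype_clustering`: `n_clusters`,
#'   `assignment` (named by record id), `feature_subset`,
#'   `selection_scores` (AIC per candidate count) and `seed`.
#' @export
cluster_positives <- function(positives, importance, max_clusters = 10L,
                              seed = 1L, n_clusters = NULL,
                              max_features = 200L) {
  stopifnot(inherits(positives, "pu_dataset"),
            inherits(importance, "feature_importance"))
  n <- nrow(positives$features)
  if (n < 2L) stop("need at least 2 labeled positives to cluster")
  informative <- importance$covariate_id[importance$gain > 0]
  if (!length(informative)) stop("no informative covariates (all gains zero)")
  if (length(informative) > max_features)
    informative <- informative[seq_len(max_features)]
  x <- as.matrix(positives$features[, match(informative, positives$covariate_ids),
                                    drop = FALSE])
  if (!is.null(n_clusters)) {
    n_clusters <- as.integer(n_clusters)
    fit <- best_em_fit(x, n_clusters, seed)
    cl <- fit$cluster
    if (length(unique(cl)) < n_clusters) {
      # EM emptied a component; fall back to Ward linkage, which always
      # yields the requested number of nonempty groups
      hc <- stats::hclust(stats::dist(x), method = "ward.D2")
      cl <- stats::cutree(hc, n_clusters)
    }
    return(new_subtype_clustering(cl, positives$record_ids,
                                  informative, NULL, seed))
  }
  if (max_clusters < 2L) {
    warning("max_clusters < 2: forcing a single cluster")
    return(new_subtype_clustering(rep(1L, n), positives$record_ids,
                                  informative, NULL, seed))
  }
  kmax <- min(as.integer(max_clusters), n)
  # Ward tree once, reused as initialisation for every candidate count.
  hc <- if (n <= 4000L) stats::hclust(stats::dist(x), method = "ward.D2")
  aic <- rep(NA_real_, kmax)
  assignments <- vector("list", kmax)
  for (k in seq_len(kmax)) {
    fit <- best_em_fit(x, k, seed, hc)
    npar <- k * ncol(x) + (k - 1L)
    aic[k] <- -2 * fit$loglik + 2 * npar
    assignments[[k]] <- fit$cluster
  }
  ksel <- which.min(aic)
  new_subtype_clustering(assignments[[ksel]], positives$record_ids,
                         informative, aic, seed)
}

best_em_fit <- function(x, k, seed, hc = NULL) {
  cands <- list(bernoulli_mixture_em(x, k, child_seed(seed, 37L * k)))
  if (k > 1L) {
    cands <- c(cands,
               list(bernoulli_mixture_em(x, k, child_seed(seed, 37L * k + 1L))))
    if (!is.null(hc))
      cands <- c(cands, list(bernoulli_mixture_em(
        x, k, child_seed(seed, 37L * k + 2L), init = stats::cutree(hc, k))))
  }
  cands[[which.max(vapply(cands, `[[`, numeric(1), "loglik"))]]
}

new_subtype_clustering <- function(cl, ids, feature_subset, scores, seed) {
  if (any(tabulate(cl) == 0L)) stop("empty cluster produced")
  structure(list(n_clusters = length(unique(cl)),
                 assignment = stats::setNames(as.integer(cl), ids),
                 feature_subset = feature_subset,
                 selection_scores = scores, seed = as.integer(seed)),
            class = "subtype_clustering")
}

#' @export
print.subtype_clustering <- function(x, ...) {
  cat(sprintf("subtype_clustering: %d cluster(s) over %d labeled positives\n",
              x$n_clusters, length(x$assignment)))
  print(table(cluster = x$assignment))
  invisible(x)
}

# --- alpha-anchored calibration ---------------------------------------------

#' Anchor unlabeled probabilities to a class-prior estimate
#'
#' Applies the bias-only logit shift (see [solve_shift()]) whose constant
#' makes the probabilities sum to `alpha * |U|`, so the per-record
#' probabilities are consistent with the estimated class prior while the
#' ranking is untouched.
#'
#' @param raw_probs probabilities in `(0, 1)` for the unlabeled records.
#' @param alpha class-prior estimate in `[0, 1]`.
#' @return Shifted probabilities in the input order (names preserved).
#' @export
calibrate_to_alpha <- function(raw_probs, alpha) {
  if (any(raw_probs <= 0 | raw_probs >= 1))
    stop("raw probabilities must lie strictly inside (0, 1)")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  n <- length(raw_probs)
  target <- alpha * n
  if (target == 0) {
    warning("alpha * |U| is zero; anchoring to an epsilon target instead")
    target <- 1e-6 * n
  }
  if (target >= n) return(stats::setNames(rep(1 - 1e-12, n), names(raw_probs)))
  c_hat <- solve_shift(stats::qlogis(raw_probs), target)
  apply_shift(raw_probs, c_hat)
}

#' Combine per-cluster calibrated probabilities
#'
#' Subtypes are modelled as disjoint events, so a record's combined
#' probability is the sum of its per-cluster calibrated probabilities,
#' capped at 1 (the number of capped records is reported as an attribute and
#' a message).
#'
#' @param probs_by_cluster list of equal-length named probability vectors,
#'   one per cluster, aligned on the same records.
#' @return Named combined probability vector with attribute `n_capped`.
#' @export
combine_cluster_probs <- function(probs_by_cluster) {
  stopifnot(is.list(probs_by_cluster), length(probs_by_cluster) >= 1L)
  lens <- lengths(probs_by_cluster)
  if (length(unique(lens)) != 1L)
    stop("per-cluster probability vectors must have equal length")
  total <- Reduce(`+`, probs_by_cluster)
  capped <- total > 1
  if (any(capped))
    message(sum(capped), " record(s) capped at probability 1")
  out <- total
  out[capped] <- 1
  attr(out, "n_capped") <- sum(capped)
  out
}

#' PULSNAR: subtype-aware class-prior estimation under SNAR
#'
#' When labeling propensity depends on the positive subtype (SNAR), the SCAR
#' estimator is driven by the over-labeled subtypes and underestimates the
#' class prior. PULSNAR clusters the labeled positives into putative
#' subtypes, runs the balanced-ensemble SCAR estimator once per cluster
#' (cluster positives versus the full unlabeled set), sums the per-cluster
#' priors (capped at 1), and anchors each cluster's unlabeled probabilities
#' to its own prior before combining them into one calibrated probability per
#' unlabeled record.
#'
#' @param dataset a [pu_dataset()].
#' @param clustering optional [cluster_positives()] result; computed from
#'   [rank_features()] when omitted.
#' @param config a [classifier_config()].
#' @param v_folds cross-fitting folds per balanced dataset.
#' @param seed integer seed.
#' @param max_partitions per-cluster cap on fitted balanced datasets (the
#'   per-cluster plan can hold thousands for small clusters).
#' @param unlabeled_floor minimum unlabeled records per balanced dataset in
#'   the per-cluster runs; stabilises tiny clusters.
#' @param max_clusters forwarded to [cluster_positives()] when `clustering`
#'   is omitted.
#' @return A list with `alpha` (an [alpha_estimate()], method `"PULSNAR"`),
#'   `calibrated_probs` (named, unlabeled records), `probs_by_cluster`,
#'   `clustering` and `importance` (when computed here).
#' @export
pulsnar <- function(dataset, clustering = NULL, config = classifier_config(),
                    v_folds = 5L, seed = 1L, max_partitions = 20L,
                    unlabeled_floor = 500L, max_clusters = 10L) {
  stopifnot(inherits(dataset, "pu_dataset"))
  halves <- split_pu(dataset)
  importance <- NULL
  if (is.null(clustering)) {
    importance <- rank_features(dataset, config, seed = seed)
    clustering <- cluster_positives(halves$positives, importance,
                                    max_clusters = max_clusters, seed = seed)
  }
  if (!setequal(names(clustering$assignment), halves$positives$record_ids))
    stop("clustering must cover exactly the labeled positives")
  u_ids <- halves$unlabeled$record_ids
  clusters <- sort(unique(clustering$assignment))
  single <- length(clusters) == 1L
  per_part <- list()
  alpha_c <- numeric(length(clusters))
  probs_by_cluster <- vector("list", length(clusters))
  u_pos <- which(dataset$labels == 0L)
  for (ci in seq_along(clusters)) {
    cids <- names(clustering$assignment)[clustering$assignment == clusters[ci]]
    rows <- c(match(cids, dataset$record_ids), u_pos)
    sub <- subset_pu(dataset, rows)
    # single-cluster reduction keeps the PULSCAR seed and options exactly
    fit <- pulscar(sub, config, v_folds = v_folds,
                   seed = if (single) seed else child_seed(seed, 500L + ci),
                   max_partitions = if (single) Inf else max_partitions,
                   unlabeled_floor = if (single) 0L else unlabeled_floor)
    alpha_c[ci] <- fit$alpha$alpha
    per_part[[ci]] <- fit$alpha$per_partition
    probs_by_cluster[[ci]] <- calibrate_to_alpha(fit$raw_probs[u_ids],
                                                 alpha_c[ci])
  }
  total <- sum(alpha_c)
  if (total > 1) {
    warning("per-cluster class priors sum to ", round(total, 4),
            "; capping the combined prior at 1")
  }
  names(alpha_c) <- paste0("cluster", clusters)
  combined <- combine_cluster_probs(probs_by_cluster)
  est <- alpha_estimate(min(1, total), unlist(per_part), "PULSNAR",
                        per_cluster = alpha_c)
  list(alpha = est, calibrated_probs = combined,
       probs_by_cluster = probs_by_cluster, clustering = clustering,
       importance = importance)
}
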