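#' Configuration for a synthetic PU cohort
#'
#' Describes a Bernoulli-mixture world for positive-unlabeled (PU) learning:
#' records are latent positives with probability `true_alpha`, latent positives
#' belong to one of `n_subtypes` subtypes, and a positive is *labeled* (coded)
#' with a subtype-specific propensity. Covariates are sparse binary indicators;
#' `n_informative` of them are activated at an elevated rate in positives of
#' the matching subtype, emulating diagnosis/procedure/observation indicators
#' enriched in a phenotype.
#'
#' Labeling propensities are rescaled internally so that the *marginal*
#' probability of a latent positive being labeled equals `coded_fraction`;
#' this pins the observed class imbalance independently of the subtype skew.
#' Equal propensities across subtypes give the SCAR regime (label probability
#' independent of attributes); unequal propensities give SNAR.
#'
#' @param n_records number of records (patients). Must be at least 10.
#' @param n_covariates number of binary covariates.
#' @param true_alpha fraction of all records that are latent positives, in
#'   `[0, 1]`.
#' @param coded_fraction overall probability that a latent positive carries a
#'   label, in `[0, 1]`.
#' @param n_subtypes number of latent positive subtypes (>= 1).
#' @param subtype_weights probability simplex over subtypes; defaults to
#'   equal weights.
#' @param label_propensities per-subtype relative labeling propensity. A
#'   single value (or the default) gives SCAR; a vector of length
#'   `n_subtypes` gives SNAR. Values are rescaled to match `coded_fraction`.
#' @param n_informative number of covariates with subtype-elevated activation
#'   (split as evenly as possible across subtypes). Must be at least
#'   `n_subtypes` and at most `n_covariates`.
#' @param baseline_rate background Bernoulli activation rate for every
#'   covariate.
#' @param lift multiplicative activation increase on a subtype's informative
#'   covariates for positives of that subtype. `baseline_rate * lift` is
#'   capped at 1 (with a warning).
#' @param seed integer seed; identical configurations generate bit-identical
#'   cohorts.
#'
#' @return An object of class `synthetic_config`.
#' @seealso [generate_cohort()]
#' @export
synthetic_config <- function(n_records = 20000L,
                             n_covariates = 500L,
                             true_alpha = 0.25,
                             coded_fraction = 0.25,
                             n_subtypes = 1L,
                             subtype_weights = NULL,
                             label_propensities = NULL,
                             n_informative = 50L,
                             baseline_rate = 0.02,
                             lift = 8,
                             seed = 1L) {
  n_records <- as.integer(n_records)
  n_covariates <- as.integer(n_covariates)
  n_subtypes <- as.integer(n_subtypes)
  n_informative <- as.integer(n_informative)
  if (n_records < 10L) stop("n_records must be at least 10")
  if (n_subtypes < 1L) stop("n_subtypes must be >= 1")
  if (is.null(subtype_weights)) subtype_weights <- rep(1 / n_subtypes, n_subtypes)
  if (length(subtype_weights) != n_subtypes)
    stop("subtype_weights must have length n_subtypes")
  if (abs(sum(subtype_weights) - 1) > 1e-9)
    stop("subtype_weights must sum to 1 (within 1e-9)")
  if (is.null(label_propensities)) label_propensities <- rep(1, n_subtypes)
  if (length(label_propensities) == 1L)
    label_propensities <- rep(label_propensities, n_subtypes)
  if (length(label_propensities) != n_subtypes)
    stop("label_propensities must have length 1 or n_subtypes")
  probs <- c(true_alpha, coded_fraction, baseline_rate, label_propensities,
             subtype_weights)
  if (any(probs < 0 | probs > 1) || any(!is.finite(probs)))
    stop("all probabilities must lie in [0, 1]")
  if (n_informative > n_covariates) stop("n_informative must not exceed n_covariates")
  if (n_subtypes > n_informative)
    stop("n_subtypes must not exceed n_informative (each subtype needs ",
         "at least one informative covariate)")
  if (lift < 0 || !is.finite(lift)) stop("lift must be a finite nonnegative number")
  structure(
    list(n_records = n_records, n_covariates = n_covariates,
         true_alpha = true_alpha, coded_fraction = coded_fraction,
         n_subtypes = n_subtypes, subtype_weights = subtype_weights,
         label_propensities = label_propensities,
         n_informative = n_informative, baseline_rate = baseline_rate,
         lift = lift, seed = as.integer(seed)),
    class = "synthetic_config")
}

#' Construct a PU dataset container
#'
#' Bundles a sparse binary record-by-covariate matrix with its PU labels
#' (1 = labeled positive, 0 = unlabeled) and, for synthetic cohorts, latent
#' ground truth. Every labeled record must be a latent positive when latent
#' truth is present; feature values must be exactly 0 or 1 (absent means 0,
#' so there are no missing entries).
#'
#' @param features a sparse (`Matrix::dgCMatrix`) or dense binary matrix,
#'   records in rows.
#' @param labels integer vector, one per record, in `{0, 1}`.
#' @param record_ids,covariate_ids identifier character vectors; defaults are
#'   generated.
#' @param latent_status optional per-record latent truth in `{0, 1}`
#'   (synthetic cohorts only).
#' @param latent_subtype optional subtype index for latent positives (`NA`
#'   for negatives).
#'
#' @return An object of class `pu_dataset`.
#' @export
pu_dataset <- function(features, labels, record_ids = NULL,
                       covariate_ids = NULL, latent_status = NULL,
                       latent_subtype = NULL) {
  features <- methods::as(methods::as(methods::as(features, "dMatrix"),
                                      "generalMatrix"), "CsparseMatrix")
  vals <- features@x
  if (length(vals) && any(vals != 0 & vals != 1))
    stop("feature values must be exactly 0 or 1")
  n <- nrow(features)
  labels <- as.integer(labels)
  if (length(labels) != n) stop("labels must have one entry per record")
  if (any(!labels %in% c(0L, 1L))) stop("labels must be 0 or 1")
  if (is.null(record_ids)) record_ids <- sprintf("R%06d", seq_len(n))
  if (is.null(covariate_ids)) covariate_ids <- sprintf("C%05d", seq_len(ncol(features)))
  record_ids <- as.character(record_ids)
  covariate_ids <- as.character(covariate_ids)
  if (length(record_ids) != n) stop("record_ids length must equal nrow(features)")
  if (anyDuplicated(record_ids)) stop("duplicate record_ids")
  if (length(covariate_ids) != ncol(features))
    stop("covariate_ids length must equal ncol(features)")
  if (!is.null(latent_status)) {
    latent_status <- as.integer(latent_status)
    if (length(latent_status) != n) stop("latent_status length mismatch")
    if (any(labels == 1L & latent_status == 0L))
      stop("labeled records must be latent positives")
  }
  if (!is.null(latent_subtype) && length(latent_subtype) != n)
    stop("latent_subtype length mismatch")
  rownames(features) <- record_ids
  colnames(features) <- covariate_ids
  structure(
    list(features = features, labels = labels, record_ids = record_ids,
         covariate_ids = covariate_ids, latent_status = latent_status,
         latent_subtype = latent_subtype),
    class = "pu_dataset")
}

#' @export
print.pu_dataset <- function(x, ...) {
  cat(sprintf("pu_dataset: %d records x %d covariates (%.3f%% nonzero)\n",
              nrow(x$features), ncol(x$features),
              100 * length(x$features@x) / prod(dim(x$features))))
  cat(sprintf("  labeled positives: %d; unlabeled: %d\n",
              sum(x$labels == 1L), sum(x$labels == 0L)))
  if (!is.null(x$latent_status))
    cat(sprintf("  latent positives (ground truth): %d\n", sum(x$latent_status)))
  invisible(x)
}

# Row-subset view preserving ids and latent truth.
subset_pu <- function(dataset, idx) {
  pu_dataset(dataset$features[idx, , drop = FALSE],
             dataset$labels[idx],
             record_ids = dataset$record_ids[idx],
             covariate_ids = dataset$covariate_ids,
             latent_status = if (!is.null(dataset$latent_status)) dataset$latent_status[idx],
             latent_subtype = if (!is.null(dataset$latent_subtype)) dataset$latent_subtype[idx])
}

# Even split of informative covariate indices across subtypes.
informative_blocks <- function(config) {
  split(seq_len(config$n_informative),
        rep(seq_len(config$n_subtypes), length.out = config$n_informative))
}

#' Generate a synthetic PU cohort
#'
#' Draws a cohort from the Bernoulli-mixture world described by a
#' [synthetic_config()]: latent positive status, subtype membership, labels
#' with subtype propensities rescaled to the configured `coded_fraction`, and
#' a sparse binary feature matrix in which each subtype's block of informative
#' covariates activates at `min(1, baseline_rate * lift)` in positives of that
#' subtype and at `baseline_rate` everywhere else.
#'
#' @param config a [synthetic_config()].
#' @return A [pu_dataset()] with `latent_status` and `latent_subtype` filled
#'   in, and the generating config attached as attribute `"config"`.
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_records = 500, seed = 7))
#' table(labels = cohort$labels, latent = cohort$latent_status)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_records
  d <- config$n_covariates
  b <- config$baseline_rate

  latent <- stats::rbinom(n, 1L, config$true_alpha)
  pos <- which(latent == 1L)
  subtype <- rep(NA_integer_, n)
  if (length(pos))
    subtype[pos] <- sample.int(config$n_subtypes, length(pos), replace = TRUE,
                               prob = config$subtype_weights)

  # Rescale propensities so E[labeled | positive] = coded_fraction.
  mean_prop <- sum(config$subtype_weights * config$label_propensities)
  scaled <- if (mean_prop > 0) config$coded_fraction / mean_prop * config$label_propensities
            else rep(0, config$n_subtypes)
  if (any(scaled > 1)) {
    warning("rescaled label propensities exceed 1 for some subtypes; capping at 1 ",
            "(the realized coded fraction will fall below coded_fraction)")
    scaled <- pmin(1, scaled)
  }
  labels <- integer(n)
  if (length(pos))
    labels[pos] <- stats::rbinom(length(pos), 1L, scaled[subtype[pos]])

  peak <- b * config$lift
  if (peak > 1) {
    warning(sprintf("baseline_rate * lift = %.3f exceeds 1; capping activation at 1",
                    peak))
    peak <- 1
  }

  # Sparse generation: per column, draw the nonzero count then the rows.
  blocks <- informative_blocks(config)
  nzi <- vector("list", d + config$n_subtypes)
  nzj <- vector("list", d + config$n_subtypes)
  slot <- 0L
  for (j in seq_len(d)) {
    m <- stats::rbinom(1L, n, b)
    if (m > 0L) {
      slot <- slot + 1L
      nzi[[slot]] <- sample.int(n, m)
      nzj[[slot]] <- rep.int(j, m)
    }
  }
  extra <- peak > b  # additional activation for subtype-matched positives
  if (extra) {
    # P(active) = peak for these cells: keep baseline draws, add independent
    # top-up draws with rate (peak - b) / (1 - b); union of events has rate peak.
    topup <- (peak - b) / (1 - b)
    for (k in seq_len(config$n_subtypes)) {
      rows <- which(latent == 1L & subtype == k)
      if (!length(rows)) next
      for (j in blocks[[k]]) {
        m <- stats::rbinom(1L, length(rows), topup)
        if (m > 0L) {
          slot <- slot + 1L
          nzi[[slot]] <- rows[sample.int(length(rows), m)]
          nzj[[slot]] <- rep.int(j, m)
        }
      }
    }
  }
  i <- unlist(nzi[seq_len(slot)], use.names = FALSE)
  j <- unlist(nzj[seq_len(slot)], use.names = FALSE)
  keep <- !duplicated((as.numeric(j) - 1) * n + i)
  features <- Matrix::sparseMatrix(i = i[keep], j = j[keep], x = 1,
                                   dims = c(n, d))

  ds <- pu_dataset(features, labels,
                   latent_status = latent, latent_subtype = subtype)
  attr(ds, "config") <- config
  ds
}

#' Expected nonzero density of a synthetic cohort
#'
#' Closed-form mixture of activation rates implied by a [synthetic_config()];
#' used by sparsity-invariant tests.
#'
#' @param config a [synthetic_config()].
#' @return Expected fraction of nonzero cells.
#' @export
expected_density <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  b <- config$baseline_rate
  peak <- min(1, b * config$lift)
  blocks <- informative_blocks(config)
  d <- config$n_covariates
  # Per subtype k, a positive activates |block_k| covariates at `peak` and the
  # rest at b; negatives activate everything at b.
  pos_rate <- sum(vapply(seq_len(config$n_subtypes), function(k) {
    bl <- length(blocks[[k]])
    config$subtype_weights[k] * (bl * peak + (d - bl) * b) / d
  }, numeric(1)))
  config$true_alpha * pos_rate + (1 - config$true_alpha) * b
}

#' Split a PU dataset into labeled-positive and unlabeled views
#'
#' @param dataset a [pu_dataset()].
#' @return A list with elements `positives` and `unlabeled`, both
#'   [pu_dataset()] views preserving record identifiers.
#' @export
split_pu <- function(dataset) {
  stopifnot(inherits(dataset, "pu_dataset"))
  if (!any(dataset$labels == 1L))
    stop("no labeled positives: PU estimation is undefined")
  list(positives = subset_pu(dataset, which(dataset$labels == 1L)),
       unlabeled = subset_pu(dataset, which(dataset$labels == 0L)))
}
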