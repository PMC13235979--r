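#' Odds ratio with Wald confidence interval
#'
#' Cross-product odds ratio `(a*d)/(b*c)` for an exposed/unexposed by
#' case/control 2x2 table, with the log-scale Wald interval
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. Zero cells are
#' handled by adding 0.5 to every cell when `correction = TRUE` (flagged in
#' the result); otherwise they are an error.
#'
#' @param a,b,c,d nonnegative counts: exposed cases, unexposed cases,
#'   exposed controls, unexposed controls.
#' @param correction apply the 0.5 continuity correction when any cell is
#'   zero.
#' @param conf_level confidence level, default 0.95.
#' @return An object of class `contingency_stats`: the counts, `or_`,
#'   `ci_95` and `corrected`.
#' @export
odds_ratio <- function(a, b, c, d, correction = FALSE, conf_level = 0.95) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("counts must be nonnegative")
  corrected <- FALSE
  if (any(counts == 0)) {
    if (!correction)
      stop("zero cell: odds ratio undefined without the continuity correction")
    counts <- counts + 0.5
    corrected <- TRUE
  }
  or_ <- (counts[1] * counts[4]) / (counts[2] * counts[3])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(sum(1 / counts))
  ci <- exp(log(or_) + c(-1, 1) * z * se)
  structure(list(a = a, b = b, c = c, d = d, or_ = or_, ci_95 = ci,
                 corrected = corrected),
            class = "contingency_stats")
}

#' @export
print.contingency_stats <- function(x, ...) {
  cat(sprintf("OR %.2f (%.2f-%.2f)%s\n", x$or_, x$ci_95[1], x$ci_95[2],
              if (x$corrected) " [continuity corrected]" else ""))
  invisible(x)
}

#' Proportion with a confidence interval
#'
#' Wald interval `p +/- z * sqrt(p (1 - p) / n)` clipped to `[0, 1]`
#' (default, matching the reference tables), or the Wilson score interval.
#'
#' @param x success count.
#' @param n trials (>= 1).
#' @param method `"wald"` or `"wilson"`.
#' @param conf_level confidence level, default 0.95.
#' @return A list with `rate` and `ci_95` (proportions, not percentages).
#' @export
proportion_ci <- function(x, n, method = c("wald", "wilson"),
                          conf_level = 0.95) {
  method <- match.arg(method)
  if (n < 1) stop("n must be at least 1")
  if (x < 0 || x > n) stop("x must lie in [0, n]")
  p <- x / n
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- if (method == "wald") {
    p + c(-1, 1) * z * sqrt(p * (1 - p) / n)
  } else {
    centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    centre + c(-1, 1) * half
  }
  list(rate = p, ci_95 = pmin(1, pmax(0, ci)))
}

#' Assemble the prevalence report
#'
#' Combines the coded count, a class-prior estimate for the unlabeled
#' records and (optionally) the chart-review calibrated extrapolation into
#' the quantities the analysis reports: the coded rate with CI, the combined
#' (coded + imputed) prevalence, the calibrated combined prevalence with CI,
#' and the coded fraction of all documented cases.
#'
#' @param n_total total records.
#' @param n_coded labeled (coded) positives.
#' @param alpha class prior for the unlabeled set: a number or an
#'   [alpha_estimate()].
#' @param calibration optional result of [extrapolate_prevalence()] (fields
#'   `adjusted_sum`, `rate`, `ci`).
#' @return An object of class `prevalence_report`.
#' @export
assemble_prevalence <- function(n_total, n_coded, alpha, calibration = NULL) {
  if (inherits(alpha, "alpha_estimate")) alpha <- alpha$alpha
  if (n_coded > n_total) stop("n_coded cannot exceed n_total")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  n_unlabeled <- n_total - n_coded
  coded <- proportion_ci(n_coded, n_total)
  imputed_sum <- alpha * n_unlabeled
  combined_rate <- (n_coded + imputed_sum) / n_total
  calibrated_combined_rate <- NULL
  coded_fraction <- NULL
  if (!is.null(calibration)) {
    adj <- calibration$adjusted_sum
    calibrated_combined_rate <- list(
      rate = (n_coded + adj) / n_total,
      ci_95 = (n_coded + calibration$ci * n_unlabeled) / n_total)
    # higher adjusted sum -> smaller coded share, so the CI flips
    coded_fraction <- list(
      rate = n_coded / (n_coded + adj),
      ci_95 = c(n_coded / (n_coded + calibration$ci[2] * n_unlabeled),
                n_coded / (n_coded + calibration$ci[1] * n_unlabeled)))
  } else if (alpha == 0) {
    coded_fraction <- list(rate = 1, ci_95 = c(1, 1))
  }
  structure(list(n_total = n_total, n_coded = n_coded,
                 coded_rate = coded$rate, coded_rate_ci = coded$ci_95,
                 alpha = alpha, imputed_sum = imputed_sum,
                 combined_rate = combined_rate,
                 calibrated_combined_rate = calibrated_combined_rate,
                 coded_fraction_of_documented = coded_fraction),
            class = "prevalence_report")
}

#' @export
print.prevalence_report <- function(x, ...) {
  cat(sprintf("prevalence_report (n = %s, coded = %s)\n",
              format(x$n_total, big.mark = ","),
              format(x$n_coded, big.mark = ",")))
  cat(sprintf("  coded rate: %.2f%% (%.2f-%.2f)\n", 100 * x$coded_rate,
              100 * x$coded_rate_ci[1], 100 * x$coded_rate_ci[2]))
  cat(sprintf("  class prior (unlabeled): %.2f%%; combined prevalence: %.2f%%\n",
              100 * x$alpha, 100 * x$combined_rate))
  if (!is.null(x$calibrated_combined_rate))
    cat(sprintf("  calibrated combined prevalence: %.2f%% (%.2f-%.2f)\n",
                100 * x$calibrated_combined_rate$rate,
                100 * x$calibrated_combined_rate$ci_95[1],
                100 * x$calibrated_combined_rate$ci_95[2]))
  if (!is.null(x$coded_fraction_of_documented))
    cat(sprintf("  coded fraction of documented: %.1f%%\n",
                100 * x$coded_fraction_of_documented$rate))
  invisible(x)
}

# --- file formats ------------------------------------------------------------

#' Write a PU dataset to a directory
#'
#' Emits `features.mtx` (MatrixMarket coordinate), `records.tsv`
#' (`record_id`, `label`, and latent truth when present) and
#' `covariates.tsv` (`covariate_id`). Round-trips through
#' [read_pu_dataset()].
#'
#' @param dataset a [pu_dataset()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_pu_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "pu_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(dataset$features, file.path(dir, "features.mtx"))
  rec <- data.frame(record_id = dataset$record_ids, label = dataset$labels,
                    stringsAsFactors = FALSE)
  if (!is.null(dataset$latent_status)) rec$latent_status <- dataset$latent_status
  if (!is.null(dataset$latent_subtype)) rec$latent_subtype <- dataset$latent_subtype
  utils::write.table(rec, file.path(dir, "records.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cov <- data.frame(covariate_id = dataset$covariate_ids,
                    stringsAsFactors = FALSE)
  utils::write.table(cov, file.path(dir, "covariates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a PU dataset from a directory
#'
#' Validates that the MatrixMarket dimensions match the identifier files,
#' that every entry is 0 or 1, and that record identifiers are unique, with
#' a specific error for each failure mode.
#'
#' @param dir directory written by [write_pu_dataset()].
#' @return A [pu_dataset()].
#' @export
read_pu_dataset <- function(dir) {
  features <- Matrix::readMM(file.path(dir, "features.mtx"))
  rec <- utils::read.table(file.path(dir, "records.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE,
                           colClasses = c(record_id = "character"))
  cov <- utils::read.table(file.path(dir, "covariates.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE,
                           colClasses = c(covariate_id = "character"))
  if (nrow(rec) != nrow(features))
    stop(sprintf("dimension mismatch: features.mtx declares %d rows but records.tsv lists %d",
                 nrow(features), nrow(rec)))
  if (nrow(cov) != ncol(features))
    stop(sprintf("dimension mismatch: features.mtx declares %d columns but covariates.tsv lists %d",
                 ncol(features), nrow(cov)))
  if (anyDuplicated(rec$record_id))
    stop("duplicate record_ids in records.tsv")
  features <- methods::as(methods::as(methods::as(features, "dMatrix"),
                                      "generalMatrix"), "CsparseMatrix")
  bad <- which(features@x != 0 & features@x != 1)
  if (length(bad)) {
    j <- findInterval(bad[1] - 1L, features@p[-1]) + 1L
    stop(sprintf("non-binary entry %g at row %d, column %d of features.mtx",
                 features@x[bad[1]], features@i[bad[1]] + 1L, j))
  }
  pu_dataset(features, rec$label, record_ids = rec$record_id,
             covariate_ids = cov$covariate_id,
             latent_status = rec$latent_status,
             latent_subtype = rec$latent_subtype)
}

#' Read a chart-review ratings table
#'
#' Expects a TSV with a `record_id` column, one 0/1 column per rater and an
#' optional `consensus` column.
#'
#' @param path TSV path.
#' @return A list with `ratings` (matrix, rownames = record ids),
#'   `consensus` (or `NULL`) and `record_ids`.
#' @export
read_ratings <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(record_id = "character"))
  rater_cols <- setdiff(names(df), c("record_id", "consensus"))
  ratings <- as.matrix(df[, rater_cols, drop = FALSE])
  rownames(ratings) <- df$record_id
  list(ratings = ratings,
       consensus = if ("consensus" %in% names(df)) df$consensus,
       record_ids = df$record_id)
}

#' Write a JSON report
#'
#' Deterministic JSON (unboxed scalars, full precision) for alpha,
#' calibration, agreement and prevalence outputs.
#'
#' @param x a list or one of the package's result objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  x <- unclass_deep(x)
  x$schema_version <- "1.0"
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

unclass_deep <- function(x) {
  if (inherits(x, "table")) x <- unclass(as.matrix(x))
  if (is.list(x)) {
    x <- lapply(x, unclass_deep)
  }
  if (!is.null(attr(x, "class")) && !is.matrix(x) && !is.data.frame(x))
    attr(x, "class") <- NULL
  x
}
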