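#' Sample one record per probability bin for chart review
#'
#' Audit design for post hoc calibration: the unit interval is cut into
#' `1/bin_width` half-open bins (the last bin is closed at 1), and one record
#' is drawn uniformly at random from every nonempty bin. Probability strata
#' at the extremes that hold no records simply contribute no case, which is
#' how an audit of 97 cases arises from 100 one-percent bins.
#'
#' @param calibrated_probs named probability vector in `[0, 1]`.
#' @param bin_width bin width, default 0.01.
#' @param seed integer seed.
#' @return An object of class `review_design`: a data frame with columns
#'   `bin` (1-based index), `record_id` and `prob`, plus attribute
#'   `n_sampled`.
#' @export
sample_review_bins <- function(calibrated_probs, bin_width = 0.01, seed = 1L) {
  if (!length(calibrated_probs)) stop("no probabilities to sample from")
  if (any(calibrated_probs < 0 | calibrated_probs > 1))
    stop("probabilities must lie in [0, 1]")
  if (is.null(names(calibrated_probs)))
    names(calibrated_probs) <- sprintf("R%06d", seq_along(calibrated_probs))
  n_bins <- as.integer(round(1 / bin_width))
  bin <- pmin(n_bins, floor(calibrated_probs / bin_width) + 1L)  # last bin closed
  set.seed(seed)
  picks <- lapply(sort(unique(bin)), function(b) {
    ids <- names(calibrated_probs)[bin == b]
    id <- if (length(ids) == 1L) ids else sample(ids, 1L)
    data.frame(bin = b, record_id = id, prob = unname(calibrated_probs[id]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, picks)
  attr(out, "n_sampled") <- nrow(out)
  attr(out, "bin_width") <- bin_width
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("review_design", "data.frame")
  out
}

#' Solve the bias-only logit shift
#'
#' Finds the unique constant `c` such that
#' `sum(plogis(logits + c)) = target_sum`. The sum is continuous and
#' strictly increasing in `c`, so the root is found by bracketed
#' root-finding and polished until the residual is at most `1e-9`.
#'
#' @param logits finite logit vector.
#' @param target_sum required sum of shifted probabilities, strictly between
#'   0 and `length(logits)`.
#' @return The shift constant `c`.
#' @export
solve_shift <- function(logits, target_sum) {
  if (any(!is.finite(logits))) stop("logits must be finite")
  n <- length(logits)
  if (target_sum <= 0 || target_sum >= n)
    stop("target_sum must lie strictly between 0 and the number of records")
  f <- function(c) sum(stats::plogis(logits + c)) - target_sum
  lo <- -1; hi <- 1
  while (f(lo) > 0 && lo > -800) lo <- lo * 2
  while (f(hi) < 0 && hi < 800) hi <- hi * 2
  c_hat <- stats::uniroot(f, c(lo, hi), tol = .Machine$double.eps^0.75)$root
  # Newton polish: uniroot's x-tolerance does not bound the residual.
  for (i in 1:50) {
    r <- f(c_hat)
    if (abs(r) <= 1e-10) break
    p <- stats::plogis(logits + c_hat)
    c_hat <- c_hat - r / max(sum(p * (1 - p)), 1e-300)
  }
  if (abs(f(c_hat)) > 1e-9)
    stop("root-finding failed to reach the 1e-9 residual tolerance")
  c_hat
}

#' Apply a logit shift to probabilities
#'
#' Elementwise `plogis(qlogis(p) + c)`: strictly order-preserving for any
#' `c`, identity at `c = 0`.
#'
#' @param probs probabilities strictly inside `(0, 1)`.
#' @param c shift constant.
#' @return Shifted probabilities (names preserved).
#' @export
apply_shift <- function(probs, c) {
  if (any(probs <= 0 | probs >= 1))
    stop("probabilities must lie strictly inside (0, 1)")
  if (c == 0) return(probs)  # exact identity, no logit round-trip error
  stats::plogis(stats::qlogis(probs) + c)
}

# Solve one resample's shift by safeguarded Newton from c = 0; the target
# sum is strictly increasing in c, so Newton with a bisection fallback
# converges in a handful of iterations.
solve_shift_fast <- function(logits, target_sum) {
  c_hat <- 0
  lo <- -800; hi <- 800
  for (i in 1:100) {
    p <- stats::plogis(logits + c_hat)
    r <- sum(p) - target_sum
    if (abs(r) <= 1e-10) return(c_hat)
    if (r > 0) hi <- c_hat else lo <- c_hat
    step <- r / max(sum(p * (1 - p)), 1e-300)
    c_new <- c_hat - step
    if (c_new <= lo || c_new >= hi) c_new <- (lo + hi) / 2
    c_hat <- c_new
  }
  c_hat
}

#' Bootstrap the logit-shift calibration constant
#'
#' Solves the shift on the full reviewed set (target = number of
#' review-confirmed positives), then draws `B` bootstrap resamples of the
#' reviewed cases with replacement, re-solving the shift for each resample's
#' own label sum. Resamples whose labels are all 0 or all 1 admit no finite
#' root and are redrawn (their count is recorded). The 2.5th and 97.5th
#' percentiles of the bootstrap distribution form the 95% CI.
#'
#' @param probs calibrated probabilities of the reviewed cases, in `(0, 1)`.
#' @param labels consensus chart-review labels in `{0, 1}`; both classes
#'   must be present.
#' @param B number of bootstrap resamples (the reference analysis used
#'   100,000; tests use far fewer).
#' @param seed integer seed.
#' @return An object of class `shift_calibration`: `c_hat`, `target_sum`,
#'   `bootstrap_c`, `ci_95`, `B`, `n_redrawn`.
#' @export
bootstrap_shift <- function(probs, labels, B = 100000L, seed = 1L) {
  labels <- as.integer(labels)
  n <- length(probs)
  if (length(labels) != n) stop("probs and labels must have equal length")
  if (n < 2L) stop("need at least 2 reviewed records")
  if (length(unique(labels)) < 2L)
    stop("all consensus labels identical: no finite shift exists")
  logits <- stats::qlogis(pmin(pmax(probs, 1e-6), 1 - 1e-6))
  c_hat <- solve_shift(logits, sum(labels))
  set.seed(seed)
  B <- as.integer(B)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
  sums <- matrix(labels[idx], nrow = B)
  sums <- rowSums(sums)
  bad <- which(sums == 0L | sums == n)
  n_redrawn <- 0L
  while (length(bad)) {
    n_redrawn <- n_redrawn + length(bad)
    idx[bad, ] <- sample.int(n, n * length(bad), replace = TRUE)
    sums[bad] <- rowSums(matrix(labels[idx[bad, , drop = FALSE]],
                                nrow = length(bad)))
    bad <- which(sums == 0L | sums == n)
  }
  boot_c <- vapply(seq_len(B), function(b) {
    solve_shift_fast(logits[idx[b, ]], sums[b])
  }, numeric(1))
  ci <- unname(stats::quantile(boot_c, c(0.025, 0.975)))
  structure(list(c_hat = c_hat, target_sum = sum(labels),
                 bootstrap_c = boot_c, ci_95 = ci, B = B,
                 n_redrawn = n_redrawn, seed = as.integer(seed)),
            class = "shift_calibration")
}

#' @export
print.shift_calibration <- function(x, ...) {
  cat(sprintf("logit-shift calibration: c = %.4f (95%% CI %.4f to %.4f, B = %d)\n",
              x$c_hat, x$ci_95[1], x$ci_95[2], x$B))
  if (x$n_redrawn > 0)
    cat("  degenerate resamples redrawn:", x$n_redrawn, "\n")
  invisible(x)
}

#' Extrapolate the calibrated positive rate to the full unlabeled population
#'
#' Applies the fitted shift to every unlabeled record's calibrated
#' probability; the sum of adjusted probabilities estimates the number of
#' positives among the unlabeled, and the bootstrap CI for the shift maps to
#' a CI for the rate.
#'
#' @param all_unlabeled_probs calibrated probabilities for all unlabeled
#'   records, in `(0, 1)`.
#' @param calib a `shift_calibration` from [bootstrap_shift()].
#' @return A list with `adjusted_sum`, `rate` and `ci` (lower, upper rate
#'   bounds).
#' @export
extrapolate_prevalence <- function(all_unlabeled_probs, calib) {
  stopifnot(inherits(calib, "shift_calibration"))
  # capped/boundary probabilities are clipped before the logit
  all_unlabeled_probs <- pmin(pmax(all_unlabeled_probs, 1e-6), 1 - 1e-6)
  shifted <- apply_shift(all_unlabeled_probs, calib$c_hat)
  n <- length(all_unlabeled_probs)
  lo <- sum(apply_shift(all_unlabeled_probs, calib$ci_95[1])) / n
  hi <- sum(apply_shift(all_unlabeled_probs, calib$ci_95[2])) / n
  list(adjusted_sum = sum(shifted), rate = sum(shifted) / n, ci = c(lo, hi))
}
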