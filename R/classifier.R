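#' Classifier configuration for PU scoring
#'
#' The PU machinery only requires a classifier with a probabilistic output
#' contract: fit on a binary response and return class-1 probabilities for new
#' records. The default engine is cross-fitted L1-penalised logistic
#' regression (`glmnet`), which handles the sparse binary covariate matrices
#' natively. Any engine honouring the contract can be plugged in by supplying
#' `fit` and `predict` functions.
#'
#' `lambda_min_ratio` controls the depth of the lasso path used for *scoring*
#' (small penalty, dense model, well-separated scores);
#' `importance_lambda_min_ratio` is the stronger penalty used when ranking
#' covariates, where a sparse support is wanted.
#'
#' @param engine `"glmnet"` (default) or `"custom"`.
#' @param alpha elastic-net mixing parameter (1 = lasso).
#' @param nlambda length of the regularisation path.
#' @param lambda_min_ratio path floor, as a fraction of the data-derived
#'   maximal lambda, for scoring models.
#' @param importance_lambda_min_ratio path floor for feature-importance
#'   models.
#' @param standardize standardize covariates before fitting (binary 0/1
#'   covariates are left on their natural scale by default).
#' @param maxit maximum glmnet iterations.
#' @param fit,predict for `engine = "custom"`: `fit(x, y)` returning a model,
#'   and `predict(model, x)` returning class-1 probabilities.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(engine = c("glmnet", "custom"),
                              alpha = 1,
                              nlambda = 30L,
                              lambda_min_ratio = 0.01,
                              importance_lambda_min_ratio = 0.05,
                              standardize = FALSE,
                              maxit = 100000L,
                              fit = NULL,
                              predict = NULL) {
  engine <- match.arg(engine)
  if (engine == "custom" && (is.null(fit) || is.null(predict)))
    stop("engine = 'custom' requires both fit and predict functions")
  structure(list(engine = engine, alpha = alpha, nlambda = as.integer(nlambda),
                 lambda_min_ratio = lambda_min_ratio,
                 importance_lambda_min_ratio = importance_lambda_min_ratio,
                 standardize = standardize, maxit = as.integer(maxit),
                 fit = fit, predict = predict),
            class = "classifier_config")
}

# Fit the configured classifier; returns an opaque model object.
fit_classifier <- function(x, y, config, for_importance = FALSE) {
  if (config$engine == "custom") return(config$fit(x, y))
  lmr <- if (for_importance) config$importance_lambda_min_ratio else config$lambda_min_ratio
  suppressWarnings(
    glmnet::glmnet(x, y, family = "binomial", alpha = config$alpha,
                   nlambda = config$nlambda, lambda.min.ratio = lmr,
                   standardize = config$standardize, maxit = config$maxit))
}

# Class-1 probabilities at the end of the fitted path.
predict_classifier <- function(model, x, config) {
  if (config$engine == "custom") return(as.numeric(config$predict(model, x)))
  as.numeric(stats::predict(model, x, s = min(model$lambda), type = "response"))
}

# Absolute coefficient magnitudes as a gain analogue (nonnegative,
# exactly zero for covariates the penalised model never uses).
classifier_gains <- function(model, config) {
  if (config$engine == "custom")
    stop("feature importance requires the glmnet engine")
  abs(as.numeric(stats::coef(model, s = min(model$lambda)))[-1L])
}

# Bounded child seed: keeps every derived seed well inside 32-bit range.
child_seed <- function(seed, i) {
  (abs(as.integer(seed)) %% 100000L) * 10000L + (as.integer(i) %% 10000L)
}
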