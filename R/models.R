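MODEL_FAMILIES <- c("logreg_l1", "svm_linear", "svm_rbf", "svm_poly3")

#' Classifier specification with hyperparameter grid
#'
#' The four shallow classifier families compared by the pipeline: sparse
#' logistic regression with L1 penalty (via glmnet) and support vector
#' machines with linear, radial-basis-function, and degree-3 polynomial
#' kernels (via e1071/libsvm). The default grids are standard log-spaced
#' ranges: inverse regularization strength C in {0.01, 0.1, 1, 10, 100} for
#' the logistic model, the same cost range for the SVMs, and for the rbf
#' kernel a width grid of the scale heuristic (`1 / (p * var(x))`) plus
#' {1e-3, 1e-2, 1e-1, 1}. The polynomial degree is fixed at 3.
#'
#' @param family one of `"logreg_l1"`, `"svm_linear"`, `"svm_rbf"`,
#'   `"svm_poly3"`.
#' @param hyper_grid optional named list of candidate value vectors,
#'   replacing the default grid.
#' @return an object of class `ezloc_model_spec` with the family and the
#'   expanded list of candidate hyperparameter combinations.
#' @export
model_spec <- function(family = MODEL_FAMILIES, hyper_grid = NULL) {
  family <- match.arg(family)
  grid <- hyper_grid %||% switch(family,
    logreg_l1  = list(C = c(0.01, 0.1, 1, 10, 100)),
    svm_linear = list(cost = c(0.01, 0.1, 1, 10, 100)),
    svm_rbf    = list(cost = c(0.01, 0.1, 1, 10, 100),
                      gamma = c("scale", "0.001", "0.01", "0.1", "1")),
    svm_poly3  = list(cost = c(0.01, 0.1, 1, 10, 100)))
  combos <- expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  candidates <- lapply(seq_len(nrow(combos)), function(i) as.list(combos[i, , drop = FALSE]))
  structure(list(family = family, grid = grid, candidates = candidates),
            class = "ezloc_model_spec")
}

#' @export
print.ezloc_model_spec <- function(x, ...) {
  cat(sprintf("<ezloc_model_spec> %s, %d hyperparameter candidates\n",
              x$family, length(x$candidates)))
  invisible(x)
}

## inverse-regularization C maps to the glmnet penalty scale
logreg_lambda <- function(C, n) 1 / (C * n)

## decreasing lambda sequence ending at the target: glmnet converges much
## faster along a warm-started path than cold at a tiny lambda
lambda_path_to <- function(lambda, lambda_max = 1, length_out = 25) {
  if (lambda >= lambda_max) return(c(lambda_max * 1.0001, lambda))
  exp(seq(log(lambda_max), log(lambda), length.out = length_out))
}

resolve_gamma <- function(gamma, x) {
  if (identical(gamma, "scale")) {
    v <- stats::var(as.numeric(x))
    if (!is.finite(v) || v == 0) v <- 1
    1 / (ncol(x) * v)
  } else as.numeric(gamma)
}

#' Fit one classifier at fixed hyperparameters
#'
#' @param spec an `ezloc_model_spec`.
#' @param x numeric feature matrix (already standardized by the caller).
#' @param y character label vector.
#' @param hypers one element of `spec$candidates`.
#' @param positive_class the task's positive label (fixes factor level
#'   order for deterministic fits).
#' @return an internal fitted-model object for [predict_model()].
#' @export
fit_model <- function(spec, x, y, hypers, positive_class) {
  stopifnot(inherits(spec, "ezloc_model_spec"))
  lv <- c(setdiff(unique(y), positive_class), positive_class)
  yf <- factor(y, levels = lv)
  if (nlevels(yf) != 2) stopf("training data must contain exactly 2 classes")
  fit <- switch(spec$family,
    logreg_l1 = {
      lam <- logreg_lambda(hypers$C, nrow(x))
      structure(list(glmnet = glmnet::glmnet(
        x, yf, family = "binomial", alpha = 1,
        lambda = lambda_path_to(lam), standardize = FALSE,
        thresh = 1e-5, maxit = 1e5),
        s = lam), class = "ezloc_logreg_path")
    },
    svm_linear = e1071::svm(x, yf, type = "C-classification",
                            kernel = "linear", cost = hypers$cost,
                            scale = FALSE),
    svm_rbf = e1071::svm(x, yf, type = "C-classification",
                         kernel = "radial", cost = hypers$cost,
                         gamma = resolve_gamma(hypers$gamma, x),
                         scale = FALSE),
    svm_poly3 = e1071::svm(x, yf, type = "C-classification",
                           kernel = "polynomial", degree = 3,
                           gamma = 1 / ncol(x), coef0 = 0,
                           cost = hypers$cost, scale = FALSE))
  structure(list(family = spec$family, fit = fit, levels = lv),
            class = "ezloc_fitted_model")
}

#' Predict labels from a fitted classifier
#'
#' @param model an `ezloc_fitted_model`.
#' @param x numeric feature matrix on the same standardized scale as the
#'   training matrix.
#' @return character vector of predicted labels.
#' @export
predict_model <- function(model, x) {
  stopifnot(inherits(model, "ezloc_fitted_model"))
  if (model$family == "logreg_l1") {
    ## the target lambda is in the fitted path: select its column directly
    ## rather than interpolating
    j <- which.min(abs(model$fit$glmnet$lambda - model$fit$s))
    as.character(predict(model$fit$glmnet, newx = x, type = "class")[, j])
  } else {
    as.character(predict(model$fit, x))
  }
}

## --- feature standardization ----------------------------------------------

## per-feature centering/scaling fitted on the training portion only;
## constant features get unit scale so held-out values pass through centered
scaler_fit <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  structure(list(center = mu, scale = sdv), class = "ezloc_scaler")
}

scaler_apply <- function(scaler, x) {
  stopifnot(inherits(scaler, "ezloc_scaler"))
  sweep(sweep(x, 2, scaler$center, "-"), 2, scaler$scale, "/")
}
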