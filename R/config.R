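#' Experiment configuration
#'
#' Bundles everything one classification experiment needs: the task, the
#' document representation, the classifier family, and the cross-validation
#' protocol (stratified outer k-fold, inner k-fold hyperparameter search,
#' repeated `n_repeats` times with the data reshuffled under seed equal to
#' the repetition index by default).
#'
#' @param task `"side"`, `"localization"` or `"sublocalization"`.
#' @param representation `"bw"` (mixed character/word n-gram bag of words),
#'   `"mean"` or `"tfidf"` (pooled word-embedding representations).
#' @param model `"logreg_l1"`, `"svm_linear"`, `"svm_rbf"` or `"svm_poly3"`.
#' @param n_features total bag-of-words feature budget (ignored for the
#'   embedding representations); 100, 200 and 300 are the sweep values.
#' @param k_outer,k_inner outer and inner cross-validation fold counts.
#' @param n_repeats number of shuffled repetitions.
#' @param seeds integer vector of length `n_repeats`, one shuffling seed per
#'   repetition; defaults to `0:(n_repeats - 1)`.
#' @param embedding_params an [embedding_params()] object.
#' @return an object of class `ezloc_config`.
#' @export
experiment_config <- function(task = "side",
                              representation = c("bw", "mean", "tfidf"),
                              model = c("logreg_l1", "svm_linear",
                                        "svm_rbf", "svm_poly3"),
                              n_features = 200,
                              k_outer = 10, k_inner = 10,
                              n_repeats = 3,
                              seeds = NULL,
                              embedding_params = NULL) {
  task <- match.arg(task, TASKS)
  representation <- match.arg(representation)
  model <- match.arg(model)
  seeds <- seeds %||% (seq_len(n_repeats) - 1L)
  if (length(seeds) != n_repeats) {
    stopf("seeds must have length n_repeats (%d), got %d",
          n_repeats, length(seeds))
  }
  if (representation == "bw") {
    if (!is.numeric(n_features) || n_features < 5) {
      stopf("n_features must be a number >= 5")
    }
    if (!n_features %in% c(100, 200, 300)) {
      message(sprintf("note: n_features = %d is outside the usual sweep {100, 200, 300}",
                      n_features))
    }
  }
  stopifnot(k_outer >= 2, k_inner >= 2, n_repeats >= 1)
  cfg <- structure(list(
    task = task, representation = representation, model = model,
    n_features = as.integer(n_features),
    k_outer = as.integer(k_outer), k_inner = as.integer(k_inner),
    n_repeats = as.integer(n_repeats), seeds = as.integer(seeds),
    embedding_params = embedding_params %||% embedding_params()),
    class = "ezloc_config")
  cfg
}

#' @export
print.ezloc_config <- function(x, ...) {
  cat(sprintf("<ezloc_config> task=%s rep=%s model=%s k=%d/%d repeats=%d seeds=[%s]\n",
              x$task, x$representation, x$model, x$k_outer, x$k_inner,
              x$n_repeats, paste(x$seeds, collapse = ",")))
  if (x$representation == "bw") cat(sprintf("  n_features=%d\n", x$n_features))
  invisible(x)
}

#' Hash of a configuration, recorded in every run log
#' @param config an `ezloc_config`.
#' @return character digest.
#' @export
config_hash <- function(config) object_digest(unclass(config))
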