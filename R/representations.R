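#' Representation builders for the nested cross-validation loop
#'
#' A representation builder pairs a `fit()` step, run on the training
#' portion of each fold only, with a `transform()` step applied to both
#' portions. `bw_representation()` fits the mixed n-gram inventory inside
#' each fold; `embedding_representation()` wraps a pre-trained embedding —
#' the embedding itself is trained once on the learning set (as the
#' pipeline does), while the idf table for `tfidf` pooling remains
#' fold-local.
#'
#' @param n_features total bag-of-words feature budget.
#' @return a list with elements `name`, `fit(train_docs)` and
#'   `transform(docs, state)`.
#' @export
bw_representation <- function(n_features = 200) {
  list(
    name = "bw",
    fit = function(train_docs) {
      suppressWarnings(fit_vocabulary(train_docs, n_features))
    },
    transform = function(docs, state) bow_transform(docs, state))
}

#' @rdname bw_representation
#' @param model a trained `ezloc_embedding`.
#' @param type `"mean"` or `"tfidf"`.
#' @export
embedding_representation <- function(model, type = c("mean", "tfidf")) {
  type <- match.arg(type)
  stopifnot(inherits(model, "ezloc_embedding"))
  list(
    name = type,
    fit = function(train_docs) {
      if (type == "tfidf") compute_idf(train_docs) else NULL
    },
    transform = function(docs, state) {
      suppressWarnings(pool_corpus(docs, model, type = type, idf = state))
    })
}

#' Construct the representation named in a configuration
#'
#' @param config an `ezloc_config`.
#' @param embedding a trained `ezloc_embedding` (required for `mean` and
#'   `tfidf`).
#' @return a representation builder list.
#' @export
representation_for <- function(config, embedding = NULL) {
  if (config$representation == "bw") {
    bw_representation(config$n_features)
  } else {
    if (is.null(embedding)) {
      stopf("the %s representation requires a trained embedding",
            config$representation)
    }
    embedding_representation(embedding, config$representation)
  }
}
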