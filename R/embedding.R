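#' Word-embedding training hyperparameters
#'
#' Defaults follow the pipeline's tuned values: 100-dimensional vectors,
#' 10 negative samples, 300 epochs, a context window of 3 and a minimum
#' word occurrence of 2 (excluding overly rare words and misspellings of
#' frequent ones). Skip-gram is the default algorithm; CBOW is available.
#'
#' @param dimension embedding dimension D (>= 2).
#' @param negative_samples negative samples per positive pair.
#' @param epochs training epochs over the corpus.
#' @param min_count minimum corpus frequency for a word to enter the
#'   vocabulary.
#' @param window context window half-width.
#' @param algorithm `"skipgram"` or `"cbow"`.
#' @param alpha initial learning rate (decays linearly).
#' @param seed integer RNG seed; training is single-threaded and
#'   bit-reproducible given the seed.
#' @return an object of class `embedding_params`.
#' @export
embedding_params <- function(dimension = 100L, negative_samples = 10L,
                             epochs = 300L, min_count = 2L, window = 3L,
                             algorithm = c("skipgram", "cbow"),
                             alpha = 0.025, seed = 0L) {
  algorithm <- match.arg(algorithm)
  stopifnot(dimension >= 2, negative_samples >= 1, epochs >= 1,
            min_count >= 1, window >= 1, alpha > 0)
  structure(list(dimension = as.integer(dimension),
                 negative_samples = as.integer(negative_samples),
                 epochs = as.integer(epochs),
                 min_count = as.integer(min_count),
                 window = as.integer(window),
                 algorithm = algorithm,
                 alpha = alpha,
                 seed = as.integer(seed)),
            class = "embedding_params")
}

#' Train a word embedding on token documents
#'
#' Trains word2vec-style vectors (skip-gram with negative sampling by
#' default) on the supplied documents — typically the learning-set seizure
#' descriptions together with the unlabeled EMR excerpts, which supply
#' syntactically fuller sentences. Words occurring fewer than
#' `params$min_count` times are excluded from the vocabulary. Training is
#' single-threaded and deterministic under the seed.
#'
#' @param docs an `ezloc_tokens` collection (learning set only).
#' @param params an [embedding_params()] object.
#' @return an object of class `ezloc_embedding`: `vocabulary` (character),
#'   `vectors` (|V| x D matrix with word row names), `counts` (training
#'   frequencies), `params`, and `training_corpus_digest`.
#' @export
train_embedding <- function(docs, params = embedding_params()) {
  stopifnot(inherits(docs, "ezloc_tokens"), inherits(params, "embedding_params"))
  if (nrow(docs) == 0) stopf("empty training corpus")
  counts <- table(unlist(docs$tokens, use.names = FALSE))
  counts <- counts[counts >= params$min_count]
  if (length(counts) == 0) {
    stopf("no word reaches min_count = %d; vocabulary is empty", params$min_count)
  }
  ## frequency-sorted vocabulary (ties lexicographic) as in word2vec
  ord <- order(-as.numeric(counts), names(counts), method = "radix")
  vocab <- names(counts)[ord]
  freq <- as.numeric(counts)[ord]

  sentences <- lapply(docs$tokens, function(t) {
    ids <- match(t, vocab)
    as.integer(ids[!is.na(ids)] - 1L)
  })
  sentences <- sentences[lengths(sentences) > 0]
  if (length(sentences) == 0) stopf("no trainable sentences after min_count pruning")

  vec <- .sgns_train_cpp(sentences, freq, params$dimension, params$window,
                         params$negative_samples, params$epochs,
                         params$alpha, params$seed,
                         params$algorithm == "cbow")
  rownames(vec) <- vocab
  stopifnot(all(is.finite(vec)))
  structure(list(vocabulary = vocab, vectors = vec,
                 counts = stats::setNames(freq, vocab), params = params,
                 training_corpus_digest = object_digest(docs$tokens)),
            class = "ezloc_embedding")
}

#' @export
print.ezloc_embedding <- function(x, ...) {
  cat(sprintf("<ezloc_embedding> |V| = %d, D = %d (%s, %d epochs, seed %d)\n",
              length(x$vocabulary), x$params$dimension, x$params$algorithm,
              x$params$epochs, x$params$seed))
  invisible(x)
}

word_vector <- function(model, word) {
  i <- match(word, model$vocabulary)
  if (is.na(i)) stopf("word not in vocabulary: %s", word)
  model$vectors[i, ]
}

#' Persist / load an embedding in the word2vec text format
#'
#' The standard plain-text format: a header line `|V| D`, then one line per
#' word with the word followed by its D coordinates.
#'
#' @param model an `ezloc_embedding`.
#' @param path file path.
#' @return `path` invisibly (`write_embedding`); an `ezloc_embedding`
#'   without training metadata (`read_embedding`).
#' @export
write_embedding <- function(model, path) {
  stopifnot(inherits(model, "ezloc_embedding"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(model$vocabulary), ncol(model$vectors)), con)
  for (i in seq_along(model$vocabulary)) {
    writeLines(paste(model$vocabulary[i],
                     paste(sprintf("%.17g", model$vectors[i, ]), collapse = " ")),
               con)
  }
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  hdr <- as.integer(strsplit(lines[1], " ", fixed = TRUE)[[1]])
  V <- hdr[1]; D <- hdr[2]
  parts <- strsplit(lines[1 + seq_len(V)], " ", fixed = TRUE)
  vocab <- vapply(parts, `[[`, "", 1)
  vec <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(D)))
  rownames(vec) <- vocab
  structure(list(vocabulary = vocab, vectors = vec, counts = NULL,
                 params = NULL, training_corpus_digest = NULL),
            class = "ezloc_embedding")
}

## --- TF-IDF ---------------------------------------------------------------

#' Fit inverse document frequencies on the learning set
#'
#' Smoothed idf: `idf(t) = ln((1 + N) / (1 + df(t))) + 1` with N the number
#' of fitting documents and df the number containing term t. Terms unseen
#' at fit time receive `ln(1 + N) + 1` at transform time (df = 0 in the
#' same formula). Fit on learning-set documents only; transforming held-out
#' documents never updates the table.
#'
#' @param train_docs an `ezloc_tokens` collection.
#' @return an object of class `idf_table` with fields `idf` (named numeric),
#'   `n_docs_fit`, `default_idf`.
#' @export
compute_idf <- function(train_docs) {
  stopifnot(inherits(train_docs, "ezloc_tokens"))
  N <- nrow(train_docs)
  if (N == 0) stopf("cannot fit idf on an empty corpus")
  df <- table(unlist(lapply(train_docs$tokens, unique), use.names = FALSE))
  idf <- log((1 + N) / (1 + as.numeric(df))) + 1
  structure(list(idf = stats::setNames(idf, names(df)),
                 n_docs_fit = N,
                 default_idf = log(1 + N) + 1),
            class = "idf_table")
}

idf_of <- function(idf_table, terms) {
  v <- idf_table$idf[terms]
  v[is.na(v)] <- idf_table$default_idf
  unname(v)
}

## --- document pooling ------------------------------------------------------

pool_tokens <- function(tokens) {
  if (inherits(tokens, "ezloc_tokens")) {
    stopifnot(nrow(tokens) == 1)
    tokens$tokens[[1]]
  } else as.character(tokens)
}

#' Mean-pooled document vector
#'
#' The `mean` representation: the unweighted average of the vectors of the
#' document's in-vocabulary tokens, counted with multiplicity. A document
#' with no in-vocabulary token maps to the zero vector with a warning.
#'
#' @param doc a character vector of tokens, or a 1-row `ezloc_tokens`.
#' @param model an `ezloc_embedding`.
#' @return numeric vector of length D.
#' @export
pool_mean <- function(doc, model) {
  toks <- pool_tokens(doc)
  idx <- match(toks, model$vocabulary)
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0) {
    warnf("document has no in-vocabulary token; returning zero vector")
    return(numeric(ncol(model$vectors)))
  }
  colMeans(model$vectors[idx, , drop = FALSE])
}

#' TF-IDF-pooled document vector
#'
#' The `tfidf` representation: a weighted average of the vectors of the
#' document's distinct in-vocabulary terms, with weight
#' `w(t, d) = tf(t, d) * idf(t)` (raw within-document count times fitted
#' idf), normalized by the total weight. With uniform idf and all-distinct
#' tokens this reduces exactly to [pool_mean()]. Zero total weight (no
#' in-vocabulary term) maps to the zero vector with a warning.
#'
#' @param doc a character vector of tokens, or a 1-row `ezloc_tokens`.
#' @param model an `ezloc_embedding`.
#' @param idf an `idf_table` fitted on the learning set.
#' @return numeric vector of length D.
#' @export
pool_tfidf <- function(doc, model, idf) {
  stopifnot(inherits(idf, "idf_table"))
  toks <- pool_tokens(doc)
  tf <- table(toks)
  terms <- names(tf)
  idx <- match(terms, model$vocabulary)
  keep <- !is.na(idx)
  if (!any(keep)) {
    warnf("document has no in-vocabulary token; returning zero vector")
    return(numeric(ncol(model$vectors)))
  }
  w <- as.numeric(tf)[keep] * idf_of(idf, terms[keep])
  vecs <- model$vectors[idx[keep], , drop = FALSE]
  colSums(vecs * w) / sum(w)
}

#' Pool a whole token collection into a document-vector matrix
#'
#' @param docs an `ezloc_tokens` collection.
#' @param model an `ezloc_embedding`.
#' @param type `"mean"` or `"tfidf"`.
#' @param idf an `idf_table` (required for `"tfidf"`).
#' @return numeric matrix, documents x D, with `doc_id` row names.
#' @export
pool_corpus <- function(docs, model, type = c("mean", "tfidf"), idf = NULL) {
  type <- match.arg(type)
  stopifnot(inherits(docs, "ezloc_tokens"))
  if (type == "tfidf" && is.null(idf)) stopf("tfidf pooling requires an idf table")
  rows <- lapply(docs$tokens, function(t) {
    if (type == "mean") pool_mean(t, model) else pool_tfidf(t, model, idf)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- docs$doc_id
  out
}
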