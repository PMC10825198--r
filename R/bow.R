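## --- n-gram extraction -----------------------------------------------------

## character n-grams within a single token (no crossing of word boundaries)
char_ngrams_of <- function(token, n) {
  L <- nchar(token)
  if (L < n) return(character())
  substring(token, seq_len(L - n + 1), seq_len(L - n + 1) + n - 1)
}

word_ngrams_of <- function(tokens, n) {
  L <- length(tokens)
  if (L < n) return(character())
  if (n == 1) return(tokens)
  vapply(seq_len(L - n + 1), function(i) {
    paste(tokens[i:(i + n - 1)], collapse = " ")
  }, "")
}

doc_char_ngrams <- function(tokens, ns = c(2L, 3L)) {
  unlist(lapply(ns, function(n) {
    unlist(lapply(tokens, char_ngrams_of, n = n), use.names = FALSE)
  }), use.names = FALSE)
}

doc_word_ngrams <- function(tokens, ns = 1:4) {
  unlist(lapply(ns, word_ngrams_of, tokens = tokens), use.names = FALSE)
}

## rank by total corpus count, descending; ties lexicographically ascending
rank_top <- function(count_table, budget) {
  if (length(count_table) == 0) return(character())
  nm <- names(count_table)
  ord <- order(-as.numeric(count_table), nm, method = "radix")
  nm[ord][seq_len(min(budget, length(nm)))]
}

#' Fit the mixed n-gram bag-of-words feature space
#'
#' Builds the `bw` representation's vocabulary from learning-set documents
#' only: character n-grams (n = 2, 3) extracted within tokens of the lemma
#' stream, and word n-grams (n = 1..4) over token tuples. The total feature
#' budget is split 20% character / 80% word (rounding half away from zero;
#' exact for 100/200/300). Within each group, candidates are ranked by total
#' corpus occurrence count, ties broken lexicographically, and the top of
#' each budget retained. A shortfall (fewer distinct candidates than the
#' budget) keeps all available and warns.
#'
#' @param train_docs an `ezloc_tokens` collection (learning set only).
#' @param total_features total number of features (>= 5).
#' @param char_prop proportion of the budget given to character n-grams
#'   (default 0.2).
#' @return an object of class `ngram_inventory` with fields `char_ngrams`,
#'   `word_ngrams`, `total_features`, `char_budget`, `word_budget`,
#'   `fit_doc_count`.
#' @export
fit_vocabulary <- function(train_docs, total_features, char_prop = 0.2) {
  stopifnot(inherits(train_docs, "ezloc_tokens"))
  if (total_features < 5) stopf("total_features must be >= 5")
  total_features <- as.integer(total_features)
  char_budget <- as.integer(round_half_up(char_prop * total_features))
  word_budget <- total_features - char_budget

  char_counts <- table(unlist(lapply(train_docs$tokens, doc_char_ngrams),
                              use.names = FALSE))
  word_counts <- table(unlist(lapply(train_docs$tokens, doc_word_ngrams),
                              use.names = FALSE))
  char_sel <- rank_top(char_counts, char_budget)
  word_sel <- rank_top(word_counts, word_budget)
  if (length(char_sel) < char_budget || length(word_sel) < word_budget) {
    warnf("n-gram shortfall: %d/%d character and %d/%d word features available",
          length(char_sel), char_budget, length(word_sel), word_budget)
  }
  structure(list(char_ngrams = char_sel, word_ngrams = word_sel,
                 total_features = total_features,
                 char_budget = char_budget, word_budget = word_budget,
                 fit_doc_count = nrow(train_docs)),
            class = "ngram_inventory")
}

#' @export
print.ngram_inventory <- function(x, ...) {
  cat(sprintf("<ngram_inventory> %d features (%d char + %d word), fitted on %d docs\n",
              length(x$char_ngrams) + length(x$word_ngrams),
              length(x$char_ngrams), length(x$word_ngrams), x$fit_doc_count))
  invisible(x)
}

#' Transform documents into n-gram count vectors
#'
#' Entry (d, f) is the number of occurrences of feature f in document d
#' (overlapping character n-grams each count once per occurrence).
#' Out-of-inventory patterns are ignored; an empty document yields an
#' all-zero row. Column order is the inventory order: character block then
#' word block. The inventory is read-only here — transforming held-out
#' documents can never alter it.
#'
#' @param docs an `ezloc_tokens` collection.
#' @param inventory a fitted `ngram_inventory`.
#' @return integer matrix, `nrow(docs)` x n_features, with `doc_id` row
#'   names and feature-string column names.
#' @export
bow_transform <- function(docs, inventory) {
  stopifnot(inherits(docs, "ezloc_tokens"), inherits(inventory, "ngram_inventory"))
  feats <- c(inventory$char_ngrams, inventory$word_ngrams)
  n_char <- length(inventory$char_ngrams)
  out <- matrix(0L, nrow = nrow(docs), ncol = length(feats),
                dimnames = list(docs$doc_id, feats))
  n_feat <- length(feats)
  for (i in seq_len(nrow(docs))) {
    toks <- docs$tokens[[i]]
    if (length(toks) == 0) next
    ci <- match(doc_char_ngrams(toks), inventory$char_ngrams)
    wi <- match(doc_word_ngrams(toks), inventory$word_ngrams)
    idx <- c(ci[!is.na(ci)], n_char + wi[!is.na(wi)])
    if (length(idx) > 0) out[i, ] <- tabulate(idx, nbins = n_feat)
  }
  out
}

#' Serialize / reload an n-gram inventory as JSON
#'
#' @param inventory an `ngram_inventory`.
#' @param path JSON file path.
#' @return `path` invisibly (`write_inventory`); an `ngram_inventory`
#'   (`read_inventory`).
#' @export
write_inventory <- function(inventory, path) {
  jsonlite::write_json(unclass(inventory), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_inventory
#' @export
read_inventory <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(char_ngrams = as.character(x$char_ngrams),
                 word_ngrams = as.character(x$word_ngrams),
                 total_features = as.integer(x$total_features),
                 char_budget = as.integer(x$char_budget),
                 word_budget = as.integer(x$word_budget),
                 fit_doc_count = as.integer(x$fit_doc_count)),
            class = "ngram_inventory")
}
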