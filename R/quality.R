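#' Cosine similarity between two vectors
#'
#' `dot(v1, v2) / (||v1|| ||v2||)`, clamped to [-1, 1] against floating
#' point rounding. Symmetric and invariant to positive rescaling of either
#' argument.
#'
#' @param v1,v2 numeric vectors of equal length, both nonzero.
#' @return a number in [-1, 1].
#' @export
cosine_similarity <- function(v1, v2) {
  stopifnot(length(v1) == length(v2))
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stopf("cosine similarity undefined for a zero vector")
  ## identical and antipodal inputs are exact by definition; the general
  ## formula would land within rounding of +/-1
  if (identical(v1, v2)) return(1)
  if (identical(v1, -v2)) return(-1)
  max(-1, min(1, sum(v1 * v2) / (n1 * n2)))
}

## cosine of every vocabulary word against a query vector
all_cosines <- function(model, query) {
  qn <- sqrt(sum(query^2))
  if (qn == 0) stopf("cosine similarity undefined for a zero vector")
  norms <- sqrt(rowSums(model$vectors^2))
  sims <- as.numeric(model$vectors %*% query) / (norms * qn)
  pmin(1, pmax(-1, sims))
}

#' Most similar vocabulary words
#'
#' Ranks the vocabulary by cosine similarity to `target`, excluding the
#' target itself; ties broken lexicographically. This is the word-similarity
#' report primitive (target word, then its k most similar words in
#' descending similarity).
#'
#' @param model an `ezloc_embedding`.
#' @param target a vocabulary word.
#' @param k number of neighbours (default 5).
#' @return data frame with columns `word`, `score`, in rank order.
#' @export
most_similar <- function(model, target, k = 5) {
  if (!target %in% model$vocabulary) stopf("word not in vocabulary: %s", target)
  stopifnot(k >= 1)
  sims <- all_cosines(model, word_vector(model, target))
  keep <- model$vocabulary != target
  words <- model$vocabulary[keep]; sims <- sims[keep]
  ord <- order(-sims, words, method = "radix")
  take <- head(ord, k)
  data.frame(word = words[take], score = sims[take],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Solve a word analogy (a : a* = b : b*)
#'
#' 3CosAdd: returns the vocabulary word maximizing the cosine similarity to
#' `v(a_star) - v(a) + v(b)`, excluding the three query words; ties broken
#' lexicographically. The canonical worked case is
#' "braccio" : "mano" = "gamba" : "piede"-type limb analogies.
#'
#' @param model an `ezloc_embedding`.
#' @param a,a_star,b vocabulary words.
#' @return the predicted word `b_star`.
#' @export
solve_analogy <- function(model, a, a_star, b) {
  for (w in c(a, a_star, b)) {
    if (!w %in% model$vocabulary) stopf("word not in vocabulary: %s", w)
  }
  query <- word_vector(model, a_star) - word_vector(model, a) + word_vector(model, b)
  sims <- all_cosines(model, query)
  keep <- !model$vocabulary %in% c(a, a_star, b)
  words <- model$vocabulary[keep]; sims <- sims[keep]
  if (length(words) == 0) stopf("no candidate words outside the query triple")
  words[order(-sims, words, method = "radix")][1]
}

#' Detect the semantic outlier in a word group
#'
#' Returns the word with the lowest mean cosine similarity to the other
#' words of the group (the word farthest from the group in average
#' similarity); ties broken lexicographically. Permutation-invariant in the
#' input order.
#'
#' @param model an `ezloc_embedding`.
#' @param words character vector of at least 3 distinct vocabulary words.
#' @return the outlier word.
#' @export
detect_outlier <- function(model, words) {
  words <- as.character(words)
  if (length(unique(words)) < 3) stopf("outlier detection needs >= 3 distinct words")
  for (w in words) {
    if (!w %in% model$vocabulary) stopf("word not in vocabulary: %s", w)
  }
  words <- unique(words)
  vecs <- model$vectors[match(words, model$vocabulary), , drop = FALSE]
  n <- length(words)
  mean_sim <- vapply(seq_len(n), function(i) {
    mean(vapply(setdiff(seq_len(n), i), function(j) {
      cosine_similarity(vecs[i, ], vecs[j, ])
    }, 0))
  }, 0)
  words[order(mean_sim, words, method = "radix")][1]
}

#' Intrinsic evaluation report for an embedding
#'
#' Runs the three intrinsic evaluators and collects their outputs in the
#' standard report layouts: a similarity table (target word and its 5 most
#' similar words in descending order), an analogy table (query triple and
#' predicted word) and an outlier table (input quadruplet and identified
#' outlier).
#'
#' @param model an `ezloc_embedding`.
#' @param similarity_targets character vector of target words.
#' @param analogy_queries list of `c(a, a_star, b)` triples.
#' @param outlier_sets list of character vectors (>= 3 words each).
#' @param k neighbours per similarity target.
#' @return an object of class `embedding_report`: list of data frames
#'   `similarity`, `analogy`, `outlier`.
#' @export
eval_embedding <- function(model, similarity_targets = character(),
                           analogy_queries = list(),
                           outlier_sets = list(), k = 5) {
  sim <- do.call(rbind, lapply(similarity_targets, function(t) {
    ms <- most_similar(model, t, k)
    data.frame(target = t, rank = seq_len(nrow(ms)), word = ms$word,
               score = ms$score, stringsAsFactors = FALSE)
  })) %||% data.frame()
  ana <- do.call(rbind, lapply(analogy_queries, function(q) {
    data.frame(a = q[1], a_star = q[2], b = q[3],
               b_star = solve_analogy(model, q[1], q[2], q[3]),
               stringsAsFactors = FALSE)
  })) %||% data.frame()
  out <- do.call(rbind, lapply(outlier_sets, function(ws) {
    data.frame(input_words = paste(ws, collapse = ", "),
               outlier = detect_outlier(model, ws), stringsAsFactors = FALSE)
  })) %||% data.frame()
  structure(list(similarity = sim, analogy = ana, outlier = out),
            class = "embedding_report")
}

#' Write an intrinsic evaluation report
#'
#' Emits `embedding_report.json` plus one CSV per evaluator section.
#'
#' @param report an `embedding_report`.
#' @param out_dir output directory.
#' @return `out_dir` invisibly.
#' @export
write_embedding_report <- function(report, out_dir) {
  stopifnot(inherits(report, "embedding_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(lapply(unclass(report), as.data.frame),
                       file.path(out_dir, "embedding_report.json"),
                       dataframe = "rows", digits = NA)
  for (section in names(report)) {
    if (nrow(report[[section]]) > 0) {
      write.csv(report[[section]],
                file.path(out_dir, sprintf("%s.csv", section)),
                row.names = FALSE)
    }
  }
  invisible(out_dir)
}
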