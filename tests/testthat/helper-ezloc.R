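## Shared fixtures, all built in code.

## toy normalization resources with deterministic behaviour
toy_resources <- function() {
  normalization_resources(
    abbreviations = c(aass = "arti superiori", aoo = "occhi aperti"),
    stoplist = c("il", "la", "alle", "e", "di"),
    lemma_lexicon = c(braccia = "braccio", apre = "aprire", occhi = "occhio",
                      simili = "simile", precedenti = "precedente",
                      mani = "mano"))
}

## an embedding object with hand-planted vectors (no training involved)
fake_embedding <- function(vectors) {
  stopifnot(!is.null(rownames(vectors)))
  structure(list(vocabulary = rownames(vectors), vectors = vectors,
                 counts = NULL, params = NULL,
                 training_corpus_digest = NULL),
            class = "ezloc_embedding")
}

## quick labeled token collection: two disjoint marker vocabularies
separable_token_docs <- function(n_per_class = 20, tokens_per_doc = 10,
                                 seed = 1) {
  with_seed(seed, {
    left_vocab <- c("clonia", "scossa", "tremore", "versione")
    right_vocab <- c("automatismo", "masticazione", "sguardo", "gesto")
    mk <- function(i, cls) {
      vocab <- if (cls == "left") left_vocab else right_vocab
      list(id = sprintf("%s%03d", toupper(substr(cls, 1, 1)), i),
           tokens = sample(vocab, tokens_per_doc, replace = TRUE), cls = cls)
    }
    docs <- c(lapply(seq_len(n_per_class), mk, cls = "left"),
              lapply(seq_len(n_per_class), mk, cls = "right"))
    td <- token_docs(
      doc_id = vapply(docs, `[[`, "", "id"),
      patient_id = vapply(docs, `[[`, "", "id"),
      doc_kind = "seizure",
      side = vapply(docs, `[[`, "", "cls"),
      tokens = lapply(docs, `[[`, "tokens"))
    attr(td, "task") <- "side"
    td
  })
}

## independent brute-force weighted-metric oracle: builds the 2x2 table
## explicitly and applies the definitions directly
oracle_weighted_metrics <- function(y_true, y_pred, pos, neg) {
  n <- length(y_true)
  tab <- matrix(0, 2, 2, dimnames = list(true = c(pos, neg),
                                         pred = c(pos, neg)))
  for (i in seq_len(n)) tab[y_true[i], y_pred[i]] <- tab[y_true[i], y_pred[i]] + 1
  per_class <- function(cls) {
    other <- if (cls == pos) neg else pos
    tp <- tab[cls, cls]; fp <- tab[other, cls]
    fn <- tab[cls, other]; tn <- tab[other, other]
    div <- function(a, b) if (b == 0) 0 else a / b
    precision <- div(tp, tp + fp); recall <- div(tp, tp + fn)
    f1 <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    c(precision = precision, npv = div(tn, tn + fn),
      specificity = div(tn, tn + fp), f1 = f1)
  }
  w_pos <- sum(y_true == pos) / n; w_neg <- 1 - w_pos
  m <- w_pos * per_class(pos) + w_neg * per_class(neg)
  c(accuracy = (tab[pos, pos] + tab[neg, neg]) / n,
    precision_w = m[["precision"]], npv_w = m[["npv"]],
    specificity_w = m[["specificity"]], f1_w = m[["f1"]])
}

## brute-force intrinsic-evaluator oracles (independent full scans)
oracle_cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

oracle_analogy <- function(emb, a, as_, b) {
  q <- emb$vectors[as_, ] - emb$vectors[a, ] + emb$vectors[b, ]
  cand <- setdiff(emb$vocabulary, c(a, as_, b))
  sims <- vapply(cand, function(w) oracle_cosine(emb$vectors[w, ], q), 0)
  cand[order(-sims, cand)][1]
}

oracle_outlier <- function(emb, ws) {
  ms <- vapply(ws, function(w) {
    mean(vapply(setdiff(ws, w), function(u) {
      oracle_cosine(emb$vectors[w, ], emb$vectors[u, ])
    }, 0))
  }, 0)
  ws[order(ms, ws)][1]
}

## exhaustive n-gram enumerator (independent of the bow module internals)
oracle_ngram_count <- function(tokens, pattern, kind) {
  if (kind == "char") {
    n <- nchar(pattern)
    sum(vapply(tokens, function(tok) {
      L <- nchar(tok)
      if (L < n) return(0L)
      sum(vapply(seq_len(L - n + 1), function(i) {
        substr(tok, i, i + n - 1) == pattern
      }, TRUE))
    }, 0L))
  } else {
    parts <- strsplit(pattern, " ", fixed = TRUE)[[1]]
    n <- length(parts)
    L <- length(tokens)
    if (L < n) return(0L)
    sum(vapply(seq_len(L - n + 1), function(i) {
      all(tokens[i:(i + n - 1)] == parts)
    }, TRUE))
  }
}
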