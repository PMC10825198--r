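#' Clean raw clinical text
#'
#' Applies the normalizer's deletion and expansion rules in a fixed order:
#' \enumerate{
#'   \item bracketed spans — `(...)`, `[...]`, `{...}` — are deleted together
#'     with the brackets (internal annotations, electrode montages);
#'   \item any whitespace-delimited token containing a digit is deleted
#'     whole (dates, times, electrode names such as "B2");
#'   \item remaining punctuation is replaced by spaces (accented letters are
#'     preserved — the corpora are Italian);
#'   \item clinical abbreviations are expanded via the abbreviation map,
#'     case-insensitively at word boundaries;
#'   \item the result is lowercased and whitespace-collapsed.
#' }
#' Brackets go first so that punctuation removal cannot destroy the span
#' delimiters. The function is idempotent: cleaning cleaned text is a no-op.
#'
#' @param text character vector of raw texts.
#' @param resources an `ezloc_resources` object (only the abbreviation map
#'   is used here).
#' @return character vector of cleaned texts (may contain empty strings;
#'   the corpus-level length filter handles those downstream).
#' @export
clean_text <- function(text, resources = normalization_resources()) {
  stopifnot(is.character(text))
  x <- text
  ## 1. bracketed spans, innermost first in case of nesting
  repeat {
    x2 <- gsub("\\([^()]*\\)|\\[[^][]*\\]|\\{[^{}]*\\}", " ", x, perl = TRUE)
    if (identical(x2, x)) break
    x <- x2
  }
  ## 2. whole tokens containing a digit
  x <- gsub("\\S*[0-9]\\S*", " ", x, perl = TRUE)
  ## 3. punctuation and symbols -> space (keep letters incl. accents)
  x <- gsub("[^\\p{L}\\s]", " ", x, perl = TRUE)
  ## 4. abbreviation expansion at word boundaries, case-insensitive
  for (abbr in names(resources$abbreviations)) {
    x <- gsub(paste0("(?i)\\b", abbr, "\\b"),
              resources$abbreviations[[abbr]], x, perl = TRUE)
  }
  ## 5. lowercase, collapse whitespace
  x <- tolower(x)
  x <- gsub("\\s+", " ", x, perl = TRUE)
  trimws(x)
}

#' Split cleaned text into tokens
#'
#' Whitespace-delimited split; order preserved, empty tokens dropped.
#'
#' @param cleaned character scalar produced by [clean_text()].
#' @return character vector of tokens (zero-length for empty input).
#' @export
tokenize <- function(cleaned) {
  stopifnot(length(cleaned) == 1)
  if (is.na(cleaned) || !nzchar(trimws(cleaned))) return(character())
  toks <- strsplit(trimws(cleaned), "\\s+", perl = TRUE)[[1]]
  toks[nzchar(toks)]
}

#' Map tokens to their lemmas
#'
#' Dictionary lookup with identity fallback: tokens absent from the lemma
#' lexicon pass through unchanged. Length and order are preserved.
#'
#' @param tokens character vector of lowercased tokens.
#' @param resources an `ezloc_resources` object.
#' @return character vector of lemmas, same length as `tokens`.
#' @export
lemmatize <- function(tokens, resources = normalization_resources()) {
  if (length(tokens) == 0) return(character())
  lex <- resources$lemma_lexicon
  hit <- match(tokens, names(lex))
  out <- tokens
  out[!is.na(hit)] <- unname(lex[hit[!is.na(hit)]])
  out
}

#' Remove stop words
#'
#' @param lemmas character vector of lemmas.
#' @param resources an `ezloc_resources` object.
#' @return the lemmas not in the stop list, original order preserved.
#' @export
remove_stopwords <- function(lemmas, resources = normalization_resources()) {
  lemmas[!lemmas %in% resources$stoplist]
}

#' Run the full normalization chain on a corpus
#'
#' clean -> tokenize -> lemmatize -> stop-word removal, per document.
#' Deterministic: identical input and resources give identical output.
#'
#' @param x an `ezloc_corpus`.
#' @param resources an `ezloc_resources` object.
#' @return an object of class `ezloc_tokens`: a data frame with the corpus
#'   identifier/label columns plus a `tokens` list-column of lemma vectors.
#' @export
preprocess_corpus <- function(x, resources = default_resources()) {
  stopifnot(inherits(x, "ezloc_corpus"))
  toks <- lapply(x$text, function(txt) {
    remove_stopwords(lemmatize(tokenize(clean_text(txt, resources)),
                               resources), resources)
  })
  token_docs(doc_id = x$doc_id, patient_id = x$patient_id,
             doc_kind = x$doc_kind, side = x$side,
             localization = x$localization,
             sublocalization = x$sublocalization, tokens = toks)
}

#' Construct a token-document collection
#'
#' @param doc_id,patient_id,doc_kind,side,localization,sublocalization
#'   per-document metadata vectors.
#' @param tokens list of character vectors (ordered lemmas).
#' @return an `ezloc_tokens` data frame.
#' @export
token_docs <- function(doc_id, patient_id, doc_kind = "seizure",
                       side = NA_character_, localization = NA_character_,
                       sublocalization = NA_character_, tokens = list()) {
  d <- data.frame(doc_id = as.character(doc_id),
                  patient_id = as.character(patient_id),
                  doc_kind = doc_kind, side = side,
                  localization = localization,
                  sublocalization = sublocalization,
                  stringsAsFactors = FALSE)
  d$tokens <- tokens
  structure(d, class = c("ezloc_tokens", "data.frame"))
}

#' @export
print.ezloc_tokens <- function(x, ...) {
  cat(sprintf("<ezloc_tokens> %d documents, %.1f tokens/doc\n",
              nrow(x), mean(lengths(x$tokens))))
  invisible(x)
}

#' Corpus-level exclusion filters
#'
#' Applies the two exclusion rules used when assembling a seizure corpus:
#' documents that after cleaning and tokenization (but before stop-word
#' removal — the length rule is anchored to the cleaning phase) comprise
#' fewer than `min_tokens` tokens, and documents that refer back to
#' previous seizures ("crisi simile alle precedenti" and variants),
#' detected as co-occurrence of all lemmas of any configured pattern.
#' Every exclusion is recorded by id in the report so the (editorial, in
#' origin) exclusion remains auditable. A document failing both rules is
#' counted under the length rule.
#'
#' @param x an `ezloc_corpus` of seizure documents.
#' @param resources an `ezloc_resources` object.
#' @param min_tokens minimum post-cleaning token count (default 20).
#' @param reference_patterns list of character vectors; a document is
#'   excluded when all lemmas of any one vector occur in it. Default:
#'   `list(c("simile", "precedente"))`.
#' @return list with `corpus` (the retained `ezloc_corpus`) and `report`,
#'   a `filter_report` with fields `n_input`, `n_excluded_short`,
#'   `n_excluded_reference`, `n_retained`, `excluded_short_ids`,
#'   `excluded_reference_ids`; the totals always reconcile.
#' @export
filter_corpus <- function(x, resources = default_resources(),
                          min_tokens = 20,
                          reference_patterns = list(c("simile", "precedente"))) {
  stopifnot(inherits(x, "ezloc_corpus"))
  is_seizure <- x$doc_kind == "seizure"
  toks <- lapply(x$text, function(txt) tokenize(clean_text(txt, resources)))
  n_tok <- lengths(toks)
  lemmas <- lapply(toks, lemmatize, resources = resources)

  short <- is_seizure & n_tok < min_tokens
  ref <- is_seizure & !short & vapply(lemmas, function(lm) {
    any(vapply(reference_patterns, function(p) all(p %in% lm), TRUE))
  }, TRUE)

  keep <- !(short | ref)
  report <- structure(list(
    n_input = sum(is_seizure),
    n_excluded_short = sum(short),
    n_excluded_reference = sum(ref),
    n_retained = sum(is_seizure & keep),
    excluded_short_ids = x$doc_id[short],
    excluded_reference_ids = x$doc_id[ref]),
    class = "filter_report")
  stopifnot(report$n_input == report$n_retained +
              report$n_excluded_short + report$n_excluded_reference)
  kept <- corpus(as.data.frame(x)[keep, , drop = FALSE],
                 provenance = attr(x, "provenance"), seed = attr(x, "seed"))
  list(corpus = kept, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> input %d: retained %d, short %d, previous-seizure %d\n",
              x$n_input, x$n_retained, x$n_excluded_short,
              x$n_excluded_reference))
  invisible(x)
}
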