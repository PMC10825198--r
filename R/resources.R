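#' Normalization resources for clinical text
#'
#' Bundles the three pluggable lexical resources the normalizer uses:
#' an abbreviation map (clinical shorthand to its expansion, matched
#' case-insensitively at word boundaries), a stop-word list, and a
#' lemma lexicon (surface form to lemma, with identity fallback for forms
#' not in the lexicon). The bundled defaults cover Italian clinical prose
#' at the scale of the test corpora; all three can be replaced by site
#' resources loaded from plain-text files.
#'
#' @param abbreviations named character vector: `names()` are abbreviations,
#'   values their expansions.
#' @param stoplist character vector of stop words.
#' @param lemma_lexicon named character vector: `names()` are surface forms,
#'   values are lemmas.
#' @return an object of class `ezloc_resources`.
#' @export
normalization_resources <- function(abbreviations = character(),
                                    stoplist = character(),
                                    lemma_lexicon = character()) {
  if (length(abbreviations) > 0 && is.null(names(abbreviations))) {
    stopf("abbreviations must be a named character vector")
  }
  if (length(lemma_lexicon) > 0 && is.null(names(lemma_lexicon))) {
    stopf("lemma_lexicon must be a named character vector")
  }
  names(abbreviations) <- tolower(names(abbreviations))
  names(lemma_lexicon) <- tolower(names(lemma_lexicon))
  structure(list(abbreviations = abbreviations,
                 stoplist = unique(tolower(stoplist)),
                 lemma_lexicon = lemma_lexicon),
            class = "ezloc_resources")
}

#' Load the packaged default Italian resources
#'
#' Reads the resource files shipped under `inst/extdata/`: the abbreviation
#' map (`abbreviations.tsv`, two-column TSV), the stop-word list
#' (`stopwords_it.txt`, one word per line) and the lemma lexicon
#' (`lemma_lexicon_it.tsv`, two-column TSV).
#'
#' @return an `ezloc_resources` object.
#' @export
default_resources <- function() {
  ext <- function(f) system.file("extdata", f, package = "ezloc", mustWork = TRUE)
  normalization_resources(
    abbreviations = read_two_column(ext("abbreviations.tsv")),
    stoplist = read_word_list(ext("stopwords_it.txt")),
    lemma_lexicon = read_two_column(ext("lemma_lexicon_it.tsv")))
}

#' Read a two-column UTF-8 TSV into a named character vector
#' @param path file path; column 1 is the key, column 2 the value.
#' @return named character vector.
#' @export
read_two_column <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 2
  if (any(bad)) stopf("malformed line(s) in %s: %s", path,
                      paste(lines[bad], collapse = "; "))
  stats::setNames(vapply(parts, `[[`, "", 2), vapply(parts, `[[`, "", 1))
}

#' Read a one-word-per-line UTF-8 list
#' @param path file path.
#' @return character vector.
#' @export
read_word_list <- function(path) {
  lines <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}
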