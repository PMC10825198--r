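#' Construct a corpus of clinical text documents
#'
#' A corpus is an ordered collection of raw documents: seizure semiology
#' descriptions (`doc_kind = "seizure"`, optionally labeled with the side,
#' localization and sub-localization of the epileptogenic zone) and
#' anamnestic EMR excerpts (`doc_kind = "emr"`, never labeled, used only to
#' enlarge the embedding-training corpus).
#'
#' Invariants enforced on construction:
#' \itemize{
#'   \item `doc_id` is unique and `text` is non-empty;
#'   \item labels come from the closed vocabularies `left/right`,
#'     `temporal/extra_temporal`, `frontal/posterior`;
#'   \item EMR documents carry no labels;
#'   \item `sublocalization` may be present only when
#'     `localization = "extra_temporal"`.
#' }
#'
#' @param documents data frame with columns `doc_id`, `patient_id`, `text`,
#'   `doc_kind`, and optional `side`, `localization`, `sublocalization`
#'   (NA where absent).
#' @param provenance free-text note on where the corpus came from.
#' @param seed integer seed used to generate the corpus, or `NULL`.
#' @return an object of class `ezloc_corpus` (a data frame).
#' @export
corpus <- function(documents, provenance = "", seed = NULL) {
  required <- c("doc_id", "patient_id", "text", "doc_kind")
  missing_cols <- setdiff(required, names(documents))
  if (length(missing_cols) > 0) {
    stopf("corpus is missing required column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  for (lab in names(LABEL_LEVELS)) {
    if (!lab %in% names(documents)) {
      documents[[lab]] <- rep(NA_character_, nrow(documents))
    }
    documents[[lab]] <- as.character(documents[[lab]])
  }
  documents <- documents[c(required, names(LABEL_LEVELS))]
  documents$doc_id <- as.character(documents$doc_id)
  documents$patient_id <- as.character(documents$patient_id)
  documents$text <- as.character(documents$text)
  documents$doc_kind <- as.character(documents$doc_kind)
  rownames(documents) <- NULL
  validate_corpus_df(documents)
  structure(documents,
            provenance = provenance, seed = seed,
            class = c("ezloc_corpus", "data.frame"))
}

validate_corpus_df <- function(d) {
  if (anyNA(d$doc_id) || anyNA(d$patient_id)) {
    stopf("doc_id and patient_id must be present for every record")
  }
  dup <- d$doc_id[duplicated(d$doc_id)]
  if (length(dup) > 0) {
    stopf("duplicate doc_id: %s", paste(unique(dup), collapse = ", "))
  }
  bad_text <- is.na(d$text) | !nzchar(d$text)
  if (any(bad_text)) {
    stopf("empty text in record(s): %s",
          paste(d$doc_id[bad_text], collapse = ", "))
  }
  bad_kind <- !d$doc_kind %in% c("seizure", "emr")
  if (any(bad_kind)) {
    stopf("unknown doc_kind %s in record(s): %s",
          paste(unique(d$doc_kind[bad_kind]), collapse = ", "),
          paste(d$doc_id[bad_kind], collapse = ", "))
  }
  for (lab in names(LABEL_LEVELS)) {
    vals <- d[[lab]]
    bad <- !is.na(vals) & !vals %in% LABEL_LEVELS[[lab]]
    if (any(bad)) {
      stopf("unknown %s label %s in record(s): %s", lab,
            paste(unique(vals[bad]), collapse = ", "),
            paste(d$doc_id[bad], collapse = ", "))
    }
  }
  emr <- d$doc_kind == "emr"
  labeled <- !is.na(d$side) | !is.na(d$localization) | !is.na(d$sublocalization)
  if (any(emr & labeled)) {
    stopf("EMR documents must carry no labels: %s",
          paste(d$doc_id[emr & labeled], collapse = ", "))
  }
  bad_sub <- !is.na(d$sublocalization) &
    (is.na(d$localization) | d$localization != "extra_temporal")
  if (any(bad_sub)) {
    stopf("sublocalization requires localization = extra_temporal: %s",
          paste(d$doc_id[bad_sub], collapse = ", "))
  }
  invisible(d)
}

#' @export
print.ezloc_corpus <- function(x, ...) {
  kinds <- table(x$doc_kind)
  cat(sprintf("<ezloc_corpus> %d documents (%s), %d patients\n",
              nrow(x),
              paste(sprintf("%s: %d", names(kinds), kinds), collapse = ", "),
              length(unique(x$patient_id))))
  invisible(x)
}

#' Read a corpus from disk
#'
#' Reads a corpus from JSON Lines (one JSON object per line, keys
#' `doc_id`, `patient_id`, `text`, `doc_kind` and nullable `side`,
#' `localization`, `sublocalization`) or from a delimited file (CSV/TSV with
#' the same columns). All corpus invariants are enforced; records with
#' unknown label values are rejected with an error rather than dropped.
#'
#' @param path file path.
#' @param format `"jsonl"` or `"delimited"`; `"delimited"` sniffs the
#'   separator from the file extension (`.tsv` means tab, otherwise comma).
#' @return an `ezloc_corpus`.
#' @export
read_corpus <- function(path, format = c("jsonl", "delimited")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) stopf("empty corpus file: %s", path)
    recs <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                      error = function(e) stopf(
                        "malformed JSON on line %d of %s: %s",
                        i, path, conditionMessage(e)))
      for (k in c("doc_id", "patient_id", "text", "doc_kind")) {
        if (is.null(rec[[k]])) {
          stopf("record on line %d is missing required field '%s'", i, k)
        }
      }
      data.frame(
        doc_id = as.character(rec$doc_id),
        patient_id = as.character(rec$patient_id),
        text = as.character(rec$text),
        doc_kind = as.character(rec$doc_kind),
        side = as.character(rec$side %||% NA),
        localization = as.character(rec$localization %||% NA),
        sublocalization = as.character(rec$sublocalization %||% NA),
        stringsAsFactors = FALSE)
    })
    d <- do.call(rbind, recs)
  } else {
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    d <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  encoding = "UTF-8", na.strings = c("NA", ""))
    for (k in c("doc_id", "patient_id", "text", "doc_kind")) {
      if (!k %in% names(d)) stopf("file %s lacks required column '%s'", path, k)
    }
  }
  corpus(d, provenance = sprintf("read from %s", path))
}

#' Write a corpus as JSON Lines
#'
#' @param x an `ezloc_corpus`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(x, path) {
  stopifnot(inherits(x, "ezloc_corpus"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    rec <- list(doc_id = x$doc_id[i], patient_id = x$patient_id[i],
                text = x$text[i], doc_kind = x$doc_kind[i],
                side = x$side[i], localization = x$localization[i],
                sublocalization = x$sublocalization[i])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null",
                                na = "null"), con)
  }
  invisible(path)
}
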