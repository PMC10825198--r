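## Built-in Italian-flavored lexicon for the generator. Content is nonsense
## prose carrying no clinical meaning; the words are chosen so the
## preprocessing resources (lemma lexicon, stop list, abbreviation map) are
## exercised realistically.

.bg_vocab <- c(
  "crisi", "paziente", "movimento", "testa", "occhio", "sguardo", "fisso",
  "arto", "superiore", "inferiore", "sollevamento", "elevazione",
  "flessione", "estensione", "rotazione", "tronco", "volto", "bocca",
  "respiro", "contrazione", "tremore", "spasmo", "fase", "inizio", "fine",
  "durata", "sonno", "risveglio", "notte", "letto", "espressione",
  "smorfia", "lamento", "grido", "pianto", "sudorazione", "pallore",
  "rossore", "salivazione", "tosse", "caduta", "braccio", "gamba", "mano",
  "piede", "dito", "spalla", "ginocchio", "collo", "fronte", "mento",
  "lingua", "palpebra", "sollevare", "muovere", "aprire", "chiudere",
  "portare", "girare", "iniziare", "durare", "presentare", "mostrare",
  "osservare", "comparire")

.default_markers <- list(
  side = list(left = c("clonia", "scossa", "irrigidimento"),
              right = c("automatismo", "masticazione", "deglutizione")),
  localization = list(temporal = c("epigastrico", "aura", "paura"),
                      extra_temporal = c("ipermotorio", "pedalamento",
                                         "agitazione")),
  sublocalization = list(frontal = c("versione", "vocalizzazione", "postura"),
                         posterior = c("visivo", "nistagmo", "ammiccamento")))

.function_words <- c("il", "la", "di", "a", "da", "in", "con", "su", "per",
                     "e", "che", "si", "non", "del", "alla", "le", "un", "una")

## truncated negative binomial calibrated by moment matching so that the
## [1, 17]-truncated distribution has mean 4.39 and sd 3.63
.seizure_dist_default <- list(mu = 3.505976, size = 0.7267905,
                              min = 1L, max = 17L)

#' Specification for the synthetic corpus generator
#'
#' Describes a corpus of synthetic seizure descriptions with the structural
#' statistics the pipeline assumes: patient-grouped documents whose
#' per-patient count follows a truncated negative binomial calibrated to
#' mean 4.39, sd 3.63 on support 1..17; class-conditional marker
#' vocabularies with tunable signal strength; clinician style profiles;
#' and raw-text noise (dates, bracketed annotations, electrode names,
#' clinical abbreviations, character-swap misspellings).
#'
#' Signal strength `signal` (per task, in [0, 1]) scales the per-token
#' probability `marker_rate * signal` that a content-token slot carries a
#' marker of the document's class for that task. At `signal = 0` no marker
#' is emitted, so the text distribution is independent of the labels.
#' Marker sets of opposing classes are disjoint by construction.
#'
#' @param n_patients number of patients.
#' @param signal signal strength per task; a single number is recycled to
#'   the three tasks, or a named vector
#'   `c(side = , localization = , sublocalization = )`.
#' @param marker_rate per-token marker probability at `signal = 1`.
#' @param seizure_dist list `mu`, `size`, `min`, `max` for the truncated
#'   negative binomial of seizures per patient.
#' @param marker_vocab class-conditional marker lemma sets (nested list
#'   task -> class -> character vector).
#' @param background_vocab character vector of background lemmas (weighted
#'   by a Zipf law over the given order).
#' @param noise_rates named vector: `date_rate`, `bracket_rate`,
#'   `electrode_rate`, `abbreviation_rate` (per-document insertion
#'   probabilities) and `misspelling_rate` (per-token probability of an
#'   adjacent-character swap).
#' @param clinician_styles number of clinician style profiles (each style
#'   perturbs the background word weights).
#' @param doc_length list `mean`, `sd`, `min` for content tokens per
#'   document, plus `short_fraction`, the fraction of deliberately short
#'   (< 20 token) documents.
#' @param label_probs named vector of class probabilities:
#'   `left`, `extra_temporal`, and `frontal` (within extra-temporal).
#' @param seed integer seed; generation is fully deterministic under it.
#' @return an object of class `generator_spec`.
#' @export
generator_spec <- function(n_patients = 120L,
                           signal = 0.5,
                           marker_rate = 0.12,
                           seizure_dist = .seizure_dist_default,
                           marker_vocab = .default_markers,
                           background_vocab = .bg_vocab,
                           noise_rates = c(date_rate = 0.3, bracket_rate = 0.25,
                                           electrode_rate = 0.2,
                                           abbreviation_rate = 0.3,
                                           misspelling_rate = 0.02),
                           clinician_styles = 5L,
                           doc_length = list(mean = 32, sd = 8, min = 22,
                                             short_fraction = 0),
                           label_probs = c(left = 0.5, extra_temporal = 0.58,
                                           frontal = 0.64),
                           seed = 0L) {
  if (length(signal) == 1) {
    signal <- stats::setNames(rep(signal, 3), TASKS)
  }
  stopifnot(all(TASKS %in% names(signal)), all(signal >= 0 & signal <= 1),
            n_patients >= 1, marker_rate > 0, marker_rate <= 1,
            clinician_styles >= 1, doc_length$min >= 1)
  if (seizure_dist$min < 1 || seizure_dist$max <= seizure_dist$min) {
    stopf("seizure_dist support must satisfy 1 <= min < max")
  }
  ## opposing-class marker sets must be disjoint
  for (task in names(marker_vocab)) {
    sets <- marker_vocab[[task]]
    if (length(intersect(sets[[1]], sets[[2]])) > 0) {
      stopf("marker sets for task '%s' overlap: %s", task,
            paste(intersect(sets[[1]], sets[[2]]), collapse = ", "))
    }
  }
  structure(list(n_patients = as.integer(n_patients),
                 signal = signal[TASKS], marker_rate = marker_rate,
                 seizure_dist = seizure_dist, marker_vocab = marker_vocab,
                 background_vocab = background_vocab,
                 noise_rates = noise_rates,
                 clinician_styles = as.integer(clinician_styles),
                 doc_length = doc_length, label_probs = label_probs,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

## rejection sampler for the truncated negative binomial
rtrunc_nbinom <- function(n, dist) {
  out <- integer(0)
  guard <- 0
  while (length(out) < n) {
    draw <- rnbinom(2 * n + 10, mu = dist$mu, size = dist$size)
    out <- c(out, draw[draw >= dist$min & draw <= dist$max])
    guard <- guard + 1
    if (guard > 1000) {
      stopf("seizure count sampler: acceptance region [%d, %d] is too improbable under mu=%.3g, size=%.3g",
            dist$min, dist$max, dist$mu, dist$size)
    }
  }
  out[seq_len(n)]
}

misspell <- function(token) {
  L <- nchar(token)
  if (L < 4) return(token)
  i <- sample(L - 1, 1)
  chars <- strsplit(token, "")[[1]]
  tmp <- chars[i]; chars[i] <- chars[i + 1]; chars[i + 1] <- tmp
  paste(chars, collapse = "")
}

## invert the packaged lemma lexicon: lemma -> surface variants, used to
## emit inflected forms the lemmatizer maps back
surface_variants <- function() {
  lex <- tryCatch(default_resources()$lemma_lexicon, error = function(e) character())
  split(names(lex), unname(lex))
}

#' Generate a synthetic labeled seizure corpus
#'
#' Draws patient labels, seizure counts, clinician styles and documents per
#' the [generator_spec()], and returns both the raw-text corpus and the
#' ground truth (per-document label assignments and planted marker counts,
#' realized seizures-per-patient moments). Deterministic under
#' `spec$seed`; the caller's RNG state is untouched.
#'
#' @param spec a `generator_spec`.
#' @return list with `corpus` (an `ezloc_corpus`) and `truth` (list with
#'   `doc_truth` data frame, `patient_labels` data frame, and
#'   `realized_moments`).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  with_seed(spec$seed, generate_corpus_impl(spec))
}

generate_corpus_impl <- function(spec) {
  variants <- surface_variants()
  n_bg <- length(spec$background_vocab)
  bg_w <- 1 / seq_len(n_bg)  # Zipf weights over the listed order
  ## clinician styles: gamma-perturbed background weights
  style_w <- vapply(seq_len(spec$clinician_styles), function(s) {
    bg_w * rgamma(n_bg, shape = 8, rate = 8)
  }, numeric(n_bg))

  patients <- sprintf("P%04d", seq_len(spec$n_patients))
  lp <- spec$label_probs
  side <- ifelse(stats::runif(spec$n_patients) < lp[["left"]], "left", "right")
  loc <- ifelse(stats::runif(spec$n_patients) < lp[["extra_temporal"]],
                "extra_temporal", "temporal")
  sub <- ifelse(loc == "extra_temporal",
                ifelse(stats::runif(spec$n_patients) < lp[["frontal"]],
                       "frontal", "posterior"),
                NA_character_)
  n_seiz <- rtrunc_nbinom(spec$n_patients, spec$seizure_dist)
  style <- sample.int(spec$clinician_styles, spec$n_patients, replace = TRUE)

  docs <- list(); truth_rows <- list()
  doc_no <- 0
  for (p in seq_len(spec$n_patients)) {
    labels <- c(side = side[p], localization = loc[p], sublocalization = sub[p])
    for (s in seq_len(n_seiz[p])) {
      doc_no <- doc_no + 1
      gen <- generate_document(spec, labels, style_w[, style[p]], variants)
      docs[[doc_no]] <- data.frame(
        doc_id = sprintf("S%05d", doc_no), patient_id = patients[p],
        text = gen$text, doc_kind = "seizure",
        side = side[p], localization = loc[p], sublocalization = sub[p],
        stringsAsFactors = FALSE)
      truth_rows[[doc_no]] <- data.frame(
        doc_id = sprintf("S%05d", doc_no),
        n_markers_side = gen$n_markers[["side"]],
        n_markers_localization = gen$n_markers[["localization"]],
        n_markers_sublocalization = gen$n_markers[["sublocalization"]],
        planted_short = gen$planted_short,
        planted_reference = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  corp <- corpus(do.call(rbind, docs),
                 provenance = sprintf("synthetic corpus, seed %d", spec$seed),
                 seed = spec$seed)
  truth <- list(
    doc_truth = do.call(rbind, truth_rows),
    patient_labels = data.frame(patient_id = patients, side = side,
                                localization = loc, sublocalization = sub,
                                n_seizures = n_seiz, style = style,
                                stringsAsFactors = FALSE),
    realized_moments = c(mean_seizures = mean(n_seiz),
                         sd_seizures = stats::sd(n_seiz)))
  list(corpus = corp, truth = truth)
}

generate_document <- function(spec, labels, bg_weights, variants) {
  dl <- spec$doc_length
  planted_short <- stats::runif(1) < (dl$short_fraction %||% 0)
  L <- if (planted_short) sample(5:14, 1) else
    max(dl$min, round(stats::rnorm(1, dl$mean, dl$sd)))

  ## slot assignment: for each task in order, a slot becomes a class marker
  ## with probability marker_rate * signal; remaining slots are background
  tokens <- character(L)
  n_markers <- stats::setNames(integer(3), TASKS)
  for (i in seq_len(L)) {
    assigned <- FALSE
    for (task in TASKS) {
      ## draw before inspecting the label so that RNG consumption — and
      ## hence the downstream background-text stream — is identical for
      ## every label combination (exact independence at signal 0)
      u <- stats::runif(1)
      cls <- labels[[task]]
      if (is.na(cls)) next
      if (u < spec$marker_rate * spec$signal[[task]]) {
        tokens[i] <- sample(spec$marker_vocab[[task]][[cls]], 1)
        n_markers[[task]] <- n_markers[[task]] + 1L
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      tokens[i] <- sample(spec$background_vocab, 1, prob = bg_weights)
    }
  }
  ## at full signal every labeled document carries at least one marker per
  ## task, making the construction exactly separable
  for (task in TASKS) {
    cls <- labels[[task]]
    if (is.na(cls) || spec$signal[[task]] < 1 || n_markers[[task]] > 0) next
    bg_slots <- which(tokens %in% spec$background_vocab)
    i <- if (length(bg_slots) > 0) bg_slots[sample.int(length(bg_slots), 1)] else
      sample.int(L, 1)
    tokens[i] <- sample(spec$marker_vocab[[task]][[cls]], 1)
    n_markers[[task]] <- n_markers[[task]] + 1L
  }

  ## inflected surface variants (lemmatizer exercise)
  for (i in seq_len(L)) {
    v <- variants[[tokens[i]]]
    if (!is.null(v) && stats::runif(1) < 0.25) tokens[i] <- sample(v, 1)
  }
  ## misspellings
  mr <- spec$noise_rates[["misspelling_rate"]]
  for (i in seq_len(L)) {
    if (stats::runif(1) < mr) tokens[i] <- misspell(tokens[i])
  }
  ## intersperse function words (stop-word exercise)
  out <- character(0)
  for (i in seq_len(L)) {
    if (stats::runif(1) < 0.25) out <- c(out, sample(.function_words, 1))
    out <- c(out, tokens[i])
  }
  ## raw-text noise insertions
  nr <- spec$noise_rates
  insert_at <- function(vec, what) {
    pos <- sample(0:length(vec), 1)
    append(vec, what, after = pos)
  }
  if (stats::runif(1) < nr[["date_rate"]]) {
    out <- insert_at(out, sprintf("alle %d:%02d", sample(7:23, 1),
                                  sample(0:59, 1)))
  }
  if (stats::runif(1) < nr[["bracket_rate"]]) {
    out <- insert_at(out, sprintf("(elettrodo %s%d)",
                                  sample(LETTERS[1:8], 1), sample(1:12, 1)))
  }
  if (stats::runif(1) < nr[["electrode_rate"]]) {
    out <- insert_at(out, sprintf("%s%d", sample(LETTERS[1:8], 1),
                                  sample(1:12, 1)))
  }
  if (stats::runif(1) < nr[["abbreviation_rate"]]) {
    out <- insert_at(out, sample(c("aass", "aoo"), 1))
  }
  ## sentence punctuation
  text <- paste(out, collapse = " ")
  words <- strsplit(text, " ", fixed = TRUE)[[1]]
  brk <- which(stats::runif(length(words)) < 0.08)
  words[brk] <- paste0(words[brk], ",")
  text <- paste0(paste(words, collapse = " "), ".")
  list(text = text, n_markers = n_markers, planted_short = planted_short)
}

#' Generate an unlabeled EMR-style corpus
#'
#' Longer anamnestic-style documents (5-20x the seizure-description content
#' length) over the shared background vocabulary with full-sentence
#' structure, used only to enlarge the embedding-training corpus. The
#' documents contain no class-marker lemmas at all, emulating the upstream
#' removal of conclusion sections that reveal the EZ location.
#'
#' @param spec a `generator_spec`.
#' @param n_docs number of EMR documents.
#' @return an `ezloc_corpus` of `doc_kind = "emr"` documents.
#' @export
generate_emr_corpus <- function(spec, n_docs) {
  stopifnot(inherits(spec, "generator_spec"), n_docs >= 0)
  if (n_docs == 0) {
    return(corpus(data.frame(doc_id = character(), patient_id = character(),
                             text = character(), doc_kind = character(),
                             stringsAsFactors = FALSE),
                  provenance = "empty EMR corpus"))
  }
  with_seed(spec$seed + 90001L, {
    variants <- surface_variants()
    n_bg <- length(spec$background_vocab)
    bg_w <- 1 / seq_len(n_bg)
    docs <- lapply(seq_len(n_docs), function(i) {
      L <- sample(5:20, 1) * spec$doc_length$mean
      toks <- sample(spec$background_vocab, L, replace = TRUE, prob = bg_w)
      for (j in seq_len(L)) {
        v <- variants[[toks[j]]]
        if (!is.null(v) && stats::runif(1) < 0.25) toks[j] <- sample(v, 1)
      }
      out <- character(0)
      for (j in seq_len(L)) {
        if (stats::runif(1) < 0.35) out <- c(out, sample(.function_words, 1))
        out <- c(out, toks[j])
        if (j %% sample(7:12, 1) == 0) {
          out[length(out)] <- paste0(out[length(out)], ".")
        }
      }
      data.frame(doc_id = sprintf("E%05d", i),
                 patient_id = sprintf("EP%04d", i),
                 text = paste(out, collapse = " "), doc_kind = "emr",
                 stringsAsFactors = FALSE)
    })
    corpus(do.call(rbind, docs),
           provenance = sprintf("synthetic EMR corpus, seed %d", spec$seed),
           seed = spec$seed)
  })
}

#' Plant known filter violations into a corpus
#'
#' Rewrites randomly chosen seizure documents to violate the corpus
#' exclusion filters: `n_short` documents are replaced by texts with fewer
#' than 20 post-cleaning tokens, and `n_reference` documents get a
#' previous-seizure reference phrase prepended (keeping their length above
#' threshold, so they are excluded by the reference rule). The returned
#' ground truth records exactly which documents were rewritten, enabling a
#' round-trip check against the filter report.
#'
#' @param x an `ezloc_corpus`.
#' @param n_short,n_reference number of violations of each kind.
#' @param seed integer seed.
#' @return list with `corpus` (rewritten) and `truth` (list
#'   `short_ids`, `reference_ids`).
#' @export
plant_filter_violations <- function(x, n_short, n_reference, seed = 0L) {
  stopifnot(inherits(x, "ezloc_corpus"))
  seiz_idx <- which(x$doc_kind == "seizure")
  if (n_short + n_reference > length(seiz_idx)) {
    stopf("corpus has %d seizure documents; cannot plant %d violations",
          length(seiz_idx), n_short + n_reference)
  }
  with_seed(seed, {
    chosen <- sample(seiz_idx, n_short + n_reference)
    short_idx <- head(chosen, n_short)
    ref_idx <- chosen[seq_len(n_reference) + n_short]
    d <- as.data.frame(x)
    if (n_short > 0) {
      d$text[short_idx] <- vapply(short_idx, function(i) {
        paste(sample(.bg_vocab, sample(4:10, 1)), collapse = " ")
      }, "")
    }
    if (n_reference > 0) {
      d$text[ref_idx] <- paste("Crisi simile alle precedenti.", d$text[ref_idx])
    }
    list(corpus = corpus(d, provenance = attr(x, "provenance"),
                         seed = attr(x, "seed")),
         truth = list(short_ids = d$doc_id[short_idx],
                      reference_ids = d$doc_id[ref_idx]))
  })
}

#' Generate a corpus with planted analogy geometry
#'
#' Builds a small token corpus whose co-occurrence structure plants an
#' additive analogy between two word pairs: the second member of each pair
#' shares its base contexts with the first, plus a common set of relation
#' contexts. A skip-gram embedding trained on the corpus should then solve
#' `a : a_star = b : b_star` by vector offset. The geometry is planted via
#' co-occurrence templates (not by writing vectors directly) so the
#' embedding trainer itself is exercised.
#'
#' @param n_repeats number of times each template sentence is emitted.
#' @param seed integer seed (sentence order shuffling).
#' @return list with `docs` (an `ezloc_tokens`) and `quadruplet`
#'   (named character: `a`, `a_star`, `b`, `b_star`).
#' @export
generate_analogy_corpus <- function(n_repeats = 60, seed = 0L) {
  ctx_a <- c("alto", "lato", "sopra")
  ctx_b <- c("terra", "passo", "corsa")
  ctx_rel <- c("presa", "stretta", "tocco")
  templates <- c(
    lapply(ctx_a, function(w) c("braccio", w)),
    lapply(ctx_a, function(w) c("mano", w)),
    lapply(ctx_rel, function(w) c("mano", w)),
    lapply(ctx_b, function(w) c("gamba", w)),
    lapply(ctx_b, function(w) c("piede", w)),
    lapply(ctx_rel, function(w) c("piede", w)))
  sentences <- rep(templates, n_repeats)
  sentences <- with_seed(seed, sample(sentences))
  docs <- token_docs(doc_id = sprintf("A%05d", seq_along(sentences)),
                     patient_id = "ANALOGY", doc_kind = "seizure",
                     tokens = sentences)
  list(docs = docs,
       quadruplet = c(a = "braccio", a_star = "mano", b = "gamba",
                      b_star = "piede"))
}
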