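test_that("generation is byte-identical under a fixed seed and leaves the RNG alone", {
  spec <- generator_spec(n_patients = 15, seed = 42)
  set.seed(777); before <- runif(3)
  g1 <- generate_corpus(spec)
  g2 <- generate_corpus(spec)
  expect_identical(as.data.frame(g1$corpus), as.data.frame(g2$corpus))
  expect_identical(g1$truth, g2$truth)
  set.seed(777)
  expect_identical(runif(3), before)  # caller RNG state untouched
  g3 <- generate_corpus(generator_spec(n_patients = 15, seed = 43))
  expect_false(identical(g1$corpus$text, g3$corpus$text))
})

test_that("seizures per patient match the target moments on [1, 17]", {
  g <- generate_corpus(generator_spec(n_patients = 500, seed = 1))
  counts <- g$truth$patient_labels$n_seizures
  expect_true(all(counts >= 1 & counts <= 17))
  expect_lt(abs(mean(counts) - 4.39), 0.3)
  expect_lt(abs(sd(counts) - 3.63), 0.5)
  expect_identical(unname(g$truth$realized_moments["mean_seizures"]),
                   mean(counts))
})

test_that("opposing marker sets must be disjoint", {
  mv <- list(side = list(left = c("a", "b"), right = c("b", "c")),
             localization = list(temporal = "t", extra_temporal = "e"),
             sublocalization = list(frontal = "f", posterior = "p"))
  expect_error(generator_spec(marker_vocab = mv), "overlap")
})

test_that("zero signal plants no markers; full signal marks every document", {
  g0 <- generate_corpus(generator_spec(n_patients = 25, signal = 0, seed = 3))
  expect_true(all(g0$truth$doc_truth$n_markers_side == 0))
  expect_true(all(g0$truth$doc_truth$n_markers_localization == 0))
  g1 <- generate_corpus(generator_spec(n_patients = 25, signal = 1, seed = 3))
  expect_true(all(g1$truth$doc_truth$n_markers_side >= 1))
  expect_true(all(g1$truth$doc_truth$n_markers_localization >= 1))
})

test_that("at zero signal the text is independent of the labels (permutation test)", {
  ## statistic: difference in mean per-patient frequency of the most common
  ## background lemma between the two side classes; labels are assigned per
  ## patient, so the permutation is over patient labels (documents of one
  ## patient share a clinician style and are not exchangeable individually)
  p_values <- vapply(1:20, function(s) {
    g <- generate_corpus(generator_spec(n_patients = 40, signal = 0, seed = s))
    toks <- preprocess_corpus(g$corpus)
    per_doc <- vapply(toks$tokens, function(t) sum(t == "crisi") / length(t), 0)
    x <- tapply(per_doc, toks$patient_id, mean)
    lab <- g$truth$patient_labels
    y <- lab$side[match(names(x), lab$patient_id)]
    stat <- function(yy) abs(mean(x[yy == "left"]) - mean(x[yy == "right"]))
    obs <- stat(y)
    perm <- with_seed(1000 + s, vapply(1:499, function(i) stat(sample(y)), 0))
    (1 + sum(perm >= obs)) / (1 + length(perm))  # add-one: valid level
  }, 0)
  expect_gte(mean(p_values > 0.01), 0.95)
})

test_that("raw-text noise is injected at the configured per-document rates", {
  n_docs <- 600
  spec <- generator_spec(n_patients = 140, seed = 9)
  g <- generate_corpus(spec)
  txt <- g$corpus$text[seq_len(min(n_docs, nrow(g$corpus)))]
  n <- length(txt)
  rates <- spec$noise_rates
  ## binomial 99.9% bounds around each configured rate
  check_rate <- function(hits, rate) {
    expect_gt(hits / n, rate - 3.3 * sqrt(rate * (1 - rate) / n))
    expect_lt(hits / n, rate + 3.3 * sqrt(rate * (1 - rate) / n))
  }
  check_rate(sum(grepl("\\(elettrodo [A-H]\\d+\\)", txt)), rates[["bracket_rate"]])
  check_rate(sum(grepl("alle \\d+:\\d+", txt)), rates[["date_rate"]])
  check_rate(sum(grepl("\\b(aass|aoo)\\b", txt)), rates[["abbreviation_rate"]])
})

test_that("every document survives cleaning with at least 20 tokens by default", {
  g <- generate_corpus(generator_spec(n_patients = 40, seed = 10))
  out <- filter_corpus(g$corpus)
  expect_equal(out$report$n_retained, nrow(g$corpus))
})

test_that("planted filter violations are recovered exactly by the filter", {
  spec <- generator_spec(n_patients = 40, seed = 21)
  g <- generate_corpus(spec)
  planted <- plant_filter_violations(g$corpus, n_short = 4, n_reference = 3,
                                     seed = 5)
  out <- filter_corpus(planted$corpus)
  expect_setequal(out$report$excluded_short_ids, planted$truth$short_ids)
  expect_setequal(out$report$excluded_reference_ids,
                  planted$truth$reference_ids)
  expect_equal(out$report$n_retained, nrow(g$corpus) - 7)
  ## planting nothing changes nothing
  same <- plant_filter_violations(g$corpus, 0, 0, seed = 5)
  expect_identical(as.data.frame(same$corpus), as.data.frame(g$corpus))
})

test_that("EMR corpora are long, unlabeled and marker-free", {
  spec <- generator_spec(n_patients = 10, seed = 2)
  expect_equal(nrow(generate_emr_corpus(spec, 0)), 0)
  emr <- generate_emr_corpus(spec, 12)
  expect_equal(nrow(emr), 12)
  expect_true(all(emr$doc_kind == "emr"))
  expect_true(all(is.na(emr$side)))
  toks <- preprocess_corpus(emr)
  lens <- lengths(toks$tokens)
  expect_gt(min(lens), 3 * spec$doc_length$mean)  # 5-20x content length
  all_markers <- unlist(spec$marker_vocab)
  expect_length(intersect(unlist(toks$tokens), all_markers), 0)
  ## EMR lemmas come from the shared background vocabulary
  expect_true(all(unlist(toks$tokens) %in% spec$background_vocab))
})

test_that("adding EMR text never shrinks the trained vocabulary's coverage", {
  spec <- generator_spec(n_patients = 12, seed = 6)
  seiz <- preprocess_corpus(generate_corpus(spec)$corpus)
  emr <- preprocess_corpus(generate_emr_corpus(spec, 10))
  both <- token_docs(c(seiz$doc_id, emr$doc_id),
                     c(seiz$patient_id, emr$patient_id),
                     c(seiz$doc_kind, emr$doc_kind),
                     tokens = c(seiz$tokens, emr$tokens))
  p <- embedding_params(dimension = 10, epochs = 1, seed = 0)
  v_seiz <- train_embedding(seiz, p)$vocabulary
  v_both <- train_embedding(both, p)$vocabulary
  expect_true(all(v_seiz %in% v_both))
  lemmas <- unique(unlist(seiz$tokens))
  expect_gte(mean(lemmas %in% v_both), mean(lemmas %in% v_seiz))
})

test_that("clinician styles change word usage but not the label signal", {
  spec <- generator_spec(n_patients = 60, signal = 0, seed = 33,
                         clinician_styles = 3)
  g <- generate_corpus(spec)
  toks <- preprocess_corpus(g$corpus)
  styles <- g$truth$patient_labels$style[
    match(toks$patient_id, g$truth$patient_labels$patient_id)]
  ## frequency of a common lemma differs across styles
  freq_by_style <- vapply(1:3, function(s) {
    tt <- unlist(toks$tokens[styles == s])
    sum(tt == "crisi") / length(tt)
  }, 0)
  expect_gt(diff(range(freq_by_style)), 0)
})
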