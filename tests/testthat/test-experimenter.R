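test_that("weighted metrics match the hand-derived 2x2 example", {
  out <- compute_weighted_metrics(c("P", "P", "N", "N"),
                                  c("P", "N", "N", "N"), "P")
  expect_equal(unname(out$confusion), c(1, 0, 1, 2))  # TP FP FN TN
  expect_equal(unname(out$metrics[["precision_w"]]), 5 / 6)
  expect_equal(unname(out$metrics[["f1_w"]]),
               0.5 * (2 / 3) + 0.5 * 0.8)
  expect_equal(unname(out$metrics[["accuracy"]]), 0.75)
})

test_that("perfect and degenerate predictions give the expected metric values", {
  y <- rep(c("left", "right"), each = 10)
  perfect <- compute_weighted_metrics(y, y, "left")
  expect_true(all(perfect$metrics == 1))
  expect_false(perfect$flagged)
  one_class <- compute_weighted_metrics(y, rep("left", 20), "left")
  expect_equal(unname(one_class$metrics[["accuracy"]]), 0.5)
  expect_true(one_class$flagged)  # undefined ratios contributed 0
  expect_error(compute_weighted_metrics(y, rep("up", 20), "left"), "label")
})

test_that("weighted metrics equal the brute-force oracle on random pairs", {
  with_seed(71, {
    for (i in 1:50) {
      n <- sample(10:60, 1)
      y <- sample(c("left", "right"), n, replace = TRUE,
                  prob = c(runif(1, 0.2, 0.8), 1))
      if (length(unique(y)) < 2) next
      p <- sample(c("left", "right"), n, replace = TRUE)
      got <- compute_weighted_metrics(y, p, "left", "right")
      want <- oracle_weighted_metrics(y, p, "left", "right")
      expect_equal(got$metrics[names(want)], want, tolerance = 1e-12)
    }
  })
})

test_that("patient-level splitting is exact, disjoint and deterministic", {
  g <- generate_corpus(generator_spec(n_patients = 122, seed = 12))
  sp <- split_by_patient(g$corpus, 15 / 122, seed = 4)
  expect_length(sp$holdout_patient_ids, 15)
  expect_length(sp$learning_patient_ids, 107)
  expect_length(intersect(sp$learning_patient_ids, sp$holdout_patient_ids), 0)
  ## no patient's documents straddle the split
  hold_docs <- g$corpus$patient_id %in% sp$holdout_patient_ids
  expect_setequal(unique(g$corpus$patient_id[hold_docs]),
                  sp$holdout_patient_ids)
  ## determinism
  expect_identical(split_by_patient(g$corpus, 15 / 122, seed = 4), sp)
  ## zero fraction
  sp0 <- split_by_patient(g$corpus, 0, seed = 4)
  expect_length(sp0$holdout_patient_ids, 0)
  expect_length(sp0$learning_patient_ids, 122)
})

test_that("select_task_subset restricts to labeled documents per task", {
  g <- generate_corpus(generator_spec(n_patients = 30, seed = 13))
  toks <- preprocess_corpus(g$corpus)
  side_ds <- select_task_subset(toks, "side")
  expect_equal(nrow(side_ds), nrow(toks))
  sub_ds <- select_task_subset(toks, "sublocalization")
  expect_true(all(sub_ds$localization == "extra_temporal"))
  expect_true(all(sub_ds$sublocalization %in% c("frontal", "posterior")))
  expect_lt(nrow(sub_ds), nrow(toks))
  ## a document lacking the label is excluded with a message
  d <- as.data.frame(g$corpus)
  d$localization[1] <- NA
  d$sublocalization[1] <- NA
  toks2 <- preprocess_corpus(corpus(d))
  expect_message(loc_ds <- select_task_subset(toks2, "localization"),
                 "lacking the label")
  expect_equal(nrow(loc_ds), nrow(toks2) - 1)
})

test_that("outer folds are stratified to within one document per class", {
  g <- generate_corpus(generator_spec(n_patients = 60, seed = 14))
  toks <- preprocess_corpus(g$corpus)
  ds <- select_task_subset(toks, "side")
  y <- ds$side
  for (seed in 0:2) {
    shuffle <- with_seed(seed, sample(length(y)))
    folds <- ezloc:::stratified_folds(y, 10, shuffle)
    for (cls in unique(y)) {
      per_fold <- table(factor(folds[y == cls], levels = 1:10))
      expect_lte(diff(range(per_fold)), 1)
    }
  }
})

test_that("a linearly separable construction reaches weighted F1 = 1", {
  ds <- separable_token_docs(n_per_class = 25)
  cfg <- experiment_config(task = "side", representation = "bw",
                           model = "svm_linear", n_features = 30,
                           k_outer = 5, k_inner = 3, n_repeats = 1, seeds = 0)
  res <- run_nested_cv(ds, bw_representation(30), model_spec("svm_linear"), cfg)
  f1 <- res$aggregate$mean[res$aggregate$metric == "f1_w"]
  expect_equal(f1, 1, tolerance = 1e-9)
})

test_that("nested CV is bit-reproducible for deterministic solvers", {
  ds <- separable_token_docs(n_per_class = 15, seed = 2)
  cfg <- experiment_config(task = "side", representation = "bw",
                           model = "logreg_l1", n_features = 30,
                           k_outer = 5, k_inner = 3, n_repeats = 2,
                           seeds = c(0, 1))
  r1 <- run_nested_cv(ds, bw_representation(30), model_spec("logreg_l1"), cfg)
  r2 <- run_nested_cv(ds, bw_representation(30), model_spec("logreg_l1"), cfg)
  expect_identical(r1$fold_records, r2$fold_records)
})

test_that("aggregates are recomputable from the fold records", {
  ds <- separable_token_docs(n_per_class = 15, seed = 3)
  cfg <- experiment_config(task = "side", representation = "bw",
                           model = "logreg_l1", n_features = 30,
                           k_outer = 5, k_inner = 3, n_repeats = 2,
                           seeds = c(0, 1))
  res <- run_nested_cv(ds, bw_representation(30), model_spec("logreg_l1"), cfg)
  fr <- res$fold_records
  for (m in c("accuracy", "f1_w")) {
    med <- vapply(unique(fr$seed), function(s) {
      median(fr[[m]][fr$seed == s])
    }, 0)
    expect_equal(res$aggregate$mean[res$aggregate$metric == m], mean(med))
    expect_equal(res$aggregate$sd[res$aggregate$metric == m], sd(med))
  }
  ## pooled confusion: summed across folds, averaged across repetitions
  expect_equal(unname(res$pooled_confusion["TP"]),
               sum(fr$TP) / length(unique(fr$seed)))
  ## per-fold confusion counts total the fold size
  expect_true(all(fr$TP + fr$FP + fr$FN + fr$TN == 6))
})

test_that("metrics in each fold record are re-derivable from its confusion", {
  ds <- separable_token_docs(n_per_class = 15, seed = 4)
  cfg <- experiment_config(task = "side", representation = "bw",
                           model = "logreg_l1", n_features = 30,
                           k_outer = 5, k_inner = 3, n_repeats = 1, seeds = 0)
  res <- run_nested_cv(ds, bw_representation(30), model_spec("logreg_l1"), cfg)
  fr <- res$fold_records
  for (i in seq_len(nrow(fr))) {
    expect_equal(fr$accuracy[i], (fr$TP[i] + fr$TN[i]) /
                   (fr$TP[i] + fr$FP[i] + fr$FN[i] + fr$TN[i]))
  }
})

test_that("holdout evaluation reports all combinations and blocks leakage", {
  g <- generate_corpus(generator_spec(n_patients = 40, signal = 0.8, seed = 15))
  toks <- preprocess_corpus(g$corpus)
  sp <- split_by_patient(g$corpus, 0.2, seed = 1)
  learn <- toks[toks$patient_id %in% sp$learning_patient_ids, , drop = FALSE]
  hold <- toks[toks$patient_id %in% sp$holdout_patient_ids, , drop = FALSE]
  emb <- train_embedding(learn, embedding_params(dimension = 30, epochs = 15,
                                                 seed = 0))
  cfg <- experiment_config(task = "side", n_features = 100, k_inner = 3)
  combos <- data.frame(representation = c("bw", "mean", "tfidf"),
                       model = c("svm_linear", "logreg_l1", "svm_rbf"),
                       stringsAsFactors = FALSE)
  tab <- evaluate_holdout(learn, hold, "side", combos = combos,
                          embedding = emb, config = cfg)
  expect_equal(nrow(tab), 3)
  expect_true(all(c("accuracy", "precision_w", "npv_w", "specificity_w",
                    "f1_w") %in% names(tab)))
  expect_true(all(tab$f1_w >= 0 & tab$f1_w <= 1))
  ## leakage canary: a holdout overlapping the learning set fails loudly
  expect_error(evaluate_holdout(learn, learn[1:5, , drop = FALSE], "side",
                                combos = combos[1, , drop = FALSE],
                                embedding = emb, config = cfg),
               "leakage")
  ## empty holdout is a configuration error
  expect_error(evaluate_holdout(learn, hold[0, , drop = FALSE], "side"),
               "empty")
})
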