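#' Patient-level learning/holdout split
#'
#' Assigns whole patients (never individual seizures) to the learning or
#' holdout set, so no patient's documents straddle the split. The holdout
#' patient count is `round(holdout_fraction * n_patients)`. If any labeled
#' class of any task ends up absent from either side, the split is
#' resampled (with a warning) up to `max_attempts` times, then errors.
#' Deterministic given the seed.
#'
#' @param x an `ezloc_corpus` (EMR documents are ignored for patient
#'   counting: only patients with seizure documents are split).
#' @param holdout_fraction fraction of patients to hold out.
#' @param seed integer seed.
#' @param max_attempts resampling bound for the stratification check.
#' @return an object of class `split_spec`: `learning_patient_ids`,
#'   `holdout_patient_ids`, `seed`.
#' @export
split_by_patient <- function(x, holdout_fraction, seed, max_attempts = 100) {
  stopifnot(inherits(x, "ezloc_corpus"),
            holdout_fraction >= 0, holdout_fraction < 1)
  seiz <- x[x$doc_kind == "seizure", , drop = FALSE]
  patients <- sort(unique(seiz$patient_id))
  if (length(patients) < 2) stopf("need at least 2 patients to split")
  n_hold <- as.integer(round(holdout_fraction * length(patients)))

  make_split <- function(attempt) {
    hold <- with_seed(seed + attempt, sample(patients, n_hold))
    structure(list(learning_patient_ids = setdiff(patients, hold),
                   holdout_patient_ids = sort(hold), seed = seed),
              class = "split_spec")
  }
  classes_ok <- function(sp) {
    if (n_hold == 0) return(TRUE)
    for (task in TASKS) {
      lab <- seiz[[task]]
      if (all(is.na(lab))) next
      for (side_ids in list(sp$learning_patient_ids, sp$holdout_patient_ids)) {
        present <- unique(lab[!is.na(lab) & seiz$patient_id %in% side_ids])
        if (!all(LABEL_LEVELS[[task]] %in% present)) return(FALSE)
      }
    }
    TRUE
  }
  for (attempt in 0:(max_attempts - 1)) {
    sp <- make_split(attempt)
    if (classes_ok(sp)) {
      if (attempt > 0) {
        warnf("stratification: resampled patient split %d time(s)", attempt)
      }
      return(sp)
    }
  }
  stopf("could not produce a split with every labeled class on both sides in %d attempts",
        max_attempts)
}

#' Subset a corpus (or token collection) to one classification task
#'
#' Returns the seizure documents carrying a non-missing label for the task.
#' For the frontal-vs-posterior task this restricts to patients with
#' extra-temporal epilepsy, since only those carry a sub-localization
#' label. Documents lacking the label are excluded (and counted in the
#' message).
#'
#' @param x an `ezloc_corpus` or `ezloc_tokens`.
#' @param task `"side"`, `"localization"` or `"sublocalization"`.
#' @return object of the same class restricted to the labeled documents,
#'   with an attribute `task`.
#' @export
select_task_subset <- function(x, task) {
  task <- match.arg(task, TASKS)
  keep <- x$doc_kind == "seizure" & !is.na(x[[task]])
  n_unlabeled <- sum(x$doc_kind == "seizure") - sum(keep)
  if (n_unlabeled > 0) {
    message(sprintf("task %s: excluded %d seizure document(s) lacking the label",
                    task, n_unlabeled))
  }
  if (!any(keep)) stopf("no documents labeled for task '%s'", task)
  out <- x[keep, , drop = FALSE]
  attr(out, "task") <- task
  out
}

## --- stratified k-fold -----------------------------------------------------

## Deal shuffled within-class indices round-robin into k folds so each
## fold's class proportions sit within one document of the global ones.
## `order_idx` is the (already shuffled) document order.
stratified_folds <- function(y, k, order_idx = seq_along(y)) {
  folds <- integer(length(y))
  for (cls in unique(y[order_idx])) {
    idx <- order_idx[y[order_idx] == cls]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

## --- nested cross-validation -----------------------------------------------

#' Repeated stratified nested cross-validation
#'
#' The pipeline's core evaluation protocol. For each repetition seed, the
#' documents are shuffled (random state = the seed) and partitioned into
#' `k_outer` stratified folds. In each outer fold: the representation is
#' fitted on the training portion only (n-gram inventory / idf table are
#' fold-local); features are standardized with training-portion statistics;
#' the hyperparameter grid is searched by inner `k_inner`-fold stratified
#' cross-validation maximizing weighted F1; the winning candidate is refit
#' on the full training portion and evaluated on the test fold. Per-trial
#' medians over folds and their mean/sd across trials are the headline
#' aggregates; confusion counts are summed across folds and averaged
#' across repetitions.
#'
#' @param docs an `ezloc_tokens` collection already restricted to the task
#'   (see [select_task_subset()]).
#' @param representation a representation builder
#'   (see [bw_representation()]).
#' @param spec an `ezloc_model_spec`.
#' @param config an `ezloc_config`.
#' @return an object of class `ezloc_result` with `fold_records` (one row
#'   per seed x fold), `per_trial_medians`, `aggregate`, and
#'   `pooled_confusion`.
#' @export
run_nested_cv <- function(docs, representation, spec, config) {
  stopifnot(inherits(docs, "ezloc_tokens"), inherits(spec, "ezloc_model_spec"),
            inherits(config, "ezloc_config"))
  task <- attr(docs, "task") %||% config$task
  pos <- task_positive_class(task)
  y <- docs[[task]]
  if (anyNA(y)) stopf("documents must all be labeled for task '%s'", task)
  if (length(unique(y)) < 2) stopf("dataset must contain both classes")

  records <- list()
  for (seed in config$seeds) {
    shuffle <- with_seed(seed, sample(nrow(docs)))
    folds <- stratified_folds(y, config$k_outer, shuffle)
    for (fold in seq_len(config$k_outer)) {
      te <- which(folds == fold)
      tr <- which(folds != fold)
      if (length(te) == 0) next
      rec <- evaluate_fold(docs[tr, , drop = FALSE], y[tr],
                           docs[te, , drop = FALSE], y[te],
                           representation, spec, config, pos)
      rec$seed <- seed
      rec$fold <- fold - 1L
      records[[length(records) + 1]] <- rec
    }
  }
  fold_records <- do.call(rbind, lapply(records, as.data.frame,
                                        stringsAsFactors = FALSE))
  build_result(fold_records, config)
}

evaluate_fold <- function(train_docs, y_tr, test_docs, y_te,
                          representation, spec, config, pos) {
  state <- representation$fit(train_docs)
  x_tr <- representation$transform(train_docs, state)
  x_te <- representation$transform(test_docs, state)
  scaler <- scaler_fit(x_tr)
  x_tr <- scaler_apply(scaler, x_tr)
  x_te <- scaler_apply(scaler, x_te)

  best <- select_hypers(x_tr, y_tr, spec, config$k_inner, pos)
  fit <- fit_model(spec, x_tr, y_tr, best, pos)
  pred <- predict_model(fit, x_te)
  m <- compute_weighted_metrics(y_te, pred, pos)
  c(list(chosen_hypers = as.character(jsonlite::toJSON(best, auto_unbox = TRUE))),
    as.list(m$metrics), as.list(m$confusion), list(flagged = m$flagged))
}

## inner stratified grid search maximizing weighted F1; ties keep the
## earliest candidate in grid order (deterministic)
select_hypers <- function(x, y, spec, k_inner, pos) {
  if (length(spec$candidates) == 1) return(spec$candidates[[1]])
  k <- min(k_inner, min(table(y)))
  if (k < 2) return(spec$candidates[[1]])
  folds <- stratified_folds(y, k)
  score_matrix <- if (spec$family == "logreg_l1") {
    ## one warm-started glmnet path per fold scores all C candidates
    lams <- vapply(spec$candidates, function(h) logreg_lambda(h$C, nrow(x)), 0)
    path <- sort(unique(c(lambda_path_to(min(lams)), lams)), decreasing = TRUE)
    vapply(seq_len(k), function(fold) {
      te <- which(folds == fold); tr <- which(folds != fold)
      if (length(unique(y[tr])) < 2) return(rep(NA_real_, length(lams)))
      lv <- c(setdiff(unique(y[tr]), pos), pos)
      fit <- glmnet::glmnet(x[tr, , drop = FALSE], factor(y[tr], levels = lv),
                            family = "binomial", alpha = 1, lambda = path,
                            standardize = FALSE, thresh = 1e-5, maxit = 1e5)
      pred <- predict(fit, x[te, , drop = FALSE], type = "class")
      vapply(lams, function(lam) {
        j <- which.min(abs(fit$lambda - lam))
        compute_weighted_metrics(y[te], pred[, j], pos)$metrics[["f1_w"]]
      }, 0)
    }, numeric(length(spec$candidates)))
  } else {
    vapply(seq_len(k), function(fold) {
      te <- which(folds == fold); tr <- which(folds != fold)
      if (length(unique(y[tr])) < 2) return(rep(NA_real_, length(spec$candidates)))
      vapply(spec$candidates, function(h) {
        fit <- fit_model(spec, x[tr, , drop = FALSE], y[tr], h, pos)
        pred <- predict_model(fit, x[te, , drop = FALSE])
        compute_weighted_metrics(y[te], pred, pos)$metrics[["f1_w"]]
      }, 0)
    }, numeric(length(spec$candidates)))
  }
  scores <- rowMeans(score_matrix, na.rm = TRUE)
  spec$candidates[[which.max(scores)]]
}

build_result <- function(fold_records, config) {
  if (is.null(fold_records) || nrow(fold_records) == 0) {
    stopf("nested cross-validation produced no fold records")
  }
  seeds <- unique(fold_records$seed)
  per_trial <- do.call(rbind, lapply(seeds, function(s) {
    sub <- fold_records[fold_records$seed == s, , drop = FALSE]
    med <- vapply(METRIC_NAMES, function(m) median(sub[[m]]), 0)
    cbind(data.frame(seed = s), as.data.frame(as.list(med)))
  }))
  aggregate <- data.frame(
    metric = METRIC_NAMES,
    mean = vapply(METRIC_NAMES, function(m) mean(per_trial[[m]]), 0),
    sd = vapply(METRIC_NAMES, function(m) stats::sd(per_trial[[m]]), 0),
    row.names = NULL)
  pooled <- vapply(c("TP", "FP", "FN", "TN"), function(cc) {
    sum(fold_records[[cc]]) / length(seeds)
  }, 0)
  structure(list(config = config, config_hash = config_hash(config),
                 fold_records = fold_records,
                 per_trial_medians = per_trial,
                 aggregate = aggregate, pooled_confusion = pooled),
            class = "ezloc_result")
}

#' @export
print.ezloc_result <- function(x, ...) {
  f1 <- x$aggregate[x$aggregate$metric == "f1_w", ]
  cat(sprintf("<ezloc_result> %s/%s/%s: weighted F1 = %.3f +/- %.3f (%d trials x %d folds)\n",
              x$config$task, x$config$representation, x$config$model,
              f1$mean, f1$sd, x$config$n_repeats, x$config$k_outer))
  invisible(x)
}

## --- held-out generalization test ------------------------------------------

#' Evaluate representation/model combinations on a held-out patient set
#'
#' Generalization test in the two-dataset design: every fitted object
#' (n-gram inventory, idf table, scaler, hyperparameters, and the embedding
#' itself) is produced from the learning set only, then each combination is
#' refit on the full learning set and scored once on the held-out
#' seizures. Digests of all fitted objects are taken before and after the
#' holdout transforms and asserted unchanged, so any leakage of holdout
#' data into a fitted object fails loudly.
#'
#' @param learning_docs,holdout_docs `ezloc_tokens` collections restricted
#'   to the task.
#' @param task the classification task.
#' @param combos data frame with columns `representation`
#'   (`bw`/`mean`/`tfidf`) and `model` (model family); defaults to all 12.
#' @param embedding a trained `ezloc_embedding` (learning-set-trained),
#'   required when any combo uses `mean`/`tfidf`.
#' @param config an `ezloc_config` (supplies `n_features` and `k_inner` for
#'   the learning-set hyperparameter search).
#' @return data frame: one row per combination with the five weighted
#'   metrics and confusion counts on the holdout set.
#' @export
evaluate_holdout <- function(learning_docs, holdout_docs, task,
                             combos = NULL, embedding = NULL,
                             config = experiment_config(task = task)) {
  task <- match.arg(task, TASKS)
  if (nrow(holdout_docs) == 0) stopf("holdout set is empty")
  if (any(holdout_docs$doc_id %in% learning_docs$doc_id)) {
    stopf("leakage: document(s) present in both learning and holdout sets")
  }
  if (any(holdout_docs$patient_id %in% learning_docs$patient_id)) {
    stopf("leakage: patient(s) present in both learning and holdout sets")
  }
  pos <- task_positive_class(task)
  y_learn <- learning_docs[[task]]
  y_hold <- holdout_docs[[task]]
  combos <- combos %||% expand.grid(
    representation = c("bw", "mean", "tfidf"),
    model = MODEL_FAMILIES, stringsAsFactors = FALSE)

  if (!is.null(embedding)) {
    emb_digest_before <- object_digest(embedding)
  }
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    rep_name <- combos$representation[i]
    fam <- combos$model[i]
    rep_builder <- if (rep_name == "bw") {
      bw_representation(config$n_features)
    } else {
      if (is.null(embedding)) stopf("combo %s requires an embedding", rep_name)
      embedding_representation(embedding, rep_name)
    }
    state <- rep_builder$fit(learning_docs)
    x_learn <- rep_builder$transform(learning_docs, state)
    scaler <- scaler_fit(x_learn)
    x_learn_s <- scaler_apply(scaler, x_learn)
    spec <- model_spec(fam)
    best <- select_hypers(x_learn_s, y_learn, spec, config$k_inner, pos)
    fit <- fit_model(spec, x_learn_s, y_learn, best, pos)

    state_digest <- object_digest(state)
    scaler_digest <- object_digest(scaler)
    x_hold <- rep_builder$transform(holdout_docs, state)
    x_hold_s <- scaler_apply(scaler, x_hold)
    pred <- predict_model(fit, x_hold_s)
    ## anti-leakage: holdout transforms must leave fitted objects untouched
    stopifnot(identical(state_digest, object_digest(state)),
              identical(scaler_digest, object_digest(scaler)))

    m <- compute_weighted_metrics(y_hold, pred, pos)
    cbind(data.frame(representation = rep_name, model = fam,
                     chosen_hypers = as.character(
                       jsonlite::toJSON(best, auto_unbox = TRUE)),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(m$metrics)),
          as.data.frame(as.list(m$confusion)))
  })
  if (!is.null(embedding)) {
    stopifnot(identical(emb_digest_before, object_digest(embedding)))
  }
  do.call(rbind, rows)
}
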