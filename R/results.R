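METRIC_NAMES <- c("accuracy", "precision_w", "npv_w", "specificity_w", "f1_w")

## full-precision numeric formatting so that write -> read is bit-exact
fmt_num <- function(x) sprintf("%.17g", x)

#' Write an experiment result to a report directory
#'
#' Emits three files plus a configuration echo:
#' \itemize{
#'   \item `per_fold_metrics.csv` — long table with columns
#'     `seed, fold, metric, value`, one row per outer fold and metric;
#'   \item `aggregate_metrics.csv` — per metric, the mean and standard
#'     deviation over the per-trial medians;
#'   \item `confusion.json` — pooled confusion counts (TP, FP, FN, TN
#'     summed across folds and averaged across repetitions) together with
#'     the task and its positive class;
#'   \item `config.json` — the resolved configuration and its hash.
#' }
#' Numeric values are written with 17 significant digits so that
#' [read_result()] reproduces them bit-exactly.
#'
#' @param result an `ezloc_result` from [run_nested_cv()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_result <- function(result, out_dir) {
  stopifnot(inherits(result, "ezloc_result"))
  if (is.null(result$fold_records) || nrow(result$fold_records) == 0) {
    stopf("cannot write an empty result (no fold records)")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) stopf("directory not writable: %s", out_dir)

  fr <- result$fold_records
  long <- do.call(rbind, lapply(METRIC_NAMES, function(m) {
    data.frame(seed = fr$seed, fold = fr$fold, metric = m,
               value = fmt_num(fr[[m]]), stringsAsFactors = FALSE)
  }))
  long <- long[order(long$metric, long$seed, long$fold), ]
  write.csv(long, file.path(out_dir, "per_fold_metrics.csv"),
            row.names = FALSE, quote = TRUE)

  agg <- result$aggregate
  agg_out <- data.frame(metric = agg$metric,
                        mean = fmt_num(agg$mean), sd = fmt_num(agg$sd),
                        stringsAsFactors = FALSE)
  write.csv(agg_out, file.path(out_dir, "aggregate_metrics.csv"),
            row.names = FALSE, quote = TRUE)

  conf <- as.list(result$pooled_confusion)
  jsonlite::write_json(
    list(task = result$config$task,
         positive_class = task_positive_class(result$config$task),
         confusion = conf),
    file.path(out_dir, "confusion.json"),
    auto_unbox = TRUE, digits = 17)

  jsonlite::write_json(
    list(config = unclass_config(result$config),
         config_hash = config_hash(result$config)),
    file.path(out_dir, "config.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

unclass_config <- function(cfg) {
  out <- unclass(cfg)
  out$embedding_params <- unclass(out$embedding_params)
  out
}

#' Read back a written experiment result
#'
#' @param out_dir directory previously written by [write_result()].
#' @return list with `per_fold` (data frame seed/fold/metric/value),
#'   `aggregate` (metric/mean/sd) and `confusion` (named numeric).
#' @export
read_result <- function(out_dir) {
  per_fold <- read.csv(file.path(out_dir, "per_fold_metrics.csv"),
                       stringsAsFactors = FALSE,
                       colClasses = c(value = "character"))
  per_fold$value <- as.numeric(per_fold$value)
  agg <- read.csv(file.path(out_dir, "aggregate_metrics.csv"),
                  stringsAsFactors = FALSE,
                  colClasses = c(mean = "character", sd = "character"))
  agg$mean <- as.numeric(agg$mean)
  agg$sd <- as.numeric(agg$sd)
  conf <- jsonlite::read_json(file.path(out_dir, "confusion.json"),
                              simplifyVector = TRUE)
  list(per_fold = per_fold, aggregate = agg,
       confusion = unlist(conf$confusion), task = conf$task)
}
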