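cv_result_to_list <- function(r) {
  list(family = r$spec$family,
       hyperparameters = r$spec$hyperparameters,
       k = r$k,
       seed = r$seed,
       pca_global = r$pca_global,
       permuted = r$permuted,
       permutation_seed = r$permutation_seed,
       averaged = as.list(r$averaged),
       per_fold = r$per_fold,
       config_hash = config_hash(r$spec))
}

# Stable hash of a classifier configuration (md5 of its canonical JSON).
config_hash <- function(spec) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(list(family = spec$family,
                            hyperparameters = spec$hyperparameters),
                       tmp, digits = NA, auto_unbox = TRUE)
  unname(tools::md5sum(tmp))
}

#' Write evaluation reports
#'
#' Emits `results.json` (full precision: per-classifier averaged and
#' per-fold metrics, seeds, provenance flags, config hash) and
#' `summary.csv` (one row per result, metrics at 4 decimals) into `path`.
#' Output is deterministic given the results: fixed key order and float
#' formatting.
#'
#' @param results non-empty list of [cross_validate()] /
#'   [permutation_control()] results.
#' @param path output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_report <- function(results, path) {
  if (inherits(results, "cv_result")) results <- list(results)
  if (!length(results)) stop("`results` must be non-empty")
  ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create report directory: ", path)
  json_path <- file.path(path, "results.json")
  csv_path <- file.path(path, "summary.csv")
  jsonlite::write_json(lapply(results, cv_result_to_list), json_path,
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  summary <- do.call(rbind, lapply(results, function(r) {
    data.frame(family = r$spec$family,
               permuted = r$permuted,
               k = r$k,
               seed = r$seed,
               as.data.frame(lapply(as.list(r$averaged),
                                    function(v) round(v, 4))))
  }))
  write.csv(summary, csv_path, row.names = FALSE)
  invisible(c(results = json_path, summary = csv_path))
}

#' Bar chart of fold-averaged metrics per classifier
#'
#' @param results list of `cv_result` objects.
#' @param metrics which averaged metrics to draw.
#' @param ... passed to [graphics::barplot()].
#' @return The bar midpoints, invisibly.
#' @export
plot_cv_metrics <- function(results,
                            metrics = c("sensitivity", "specificity",
                                        "precision", "accuracy", "f1",
                                        "auc"),
                            ...) {
  if (inherits(results, "cv_result")) results <- list(results)
  m <- vapply(results, function(r) r$averaged[metrics], numeric(length(metrics)))
  colnames(m) <- vapply(results, function(r) r$spec$family, character(1))
  mid <- graphics::barplot(m, beside = TRUE, ylim = c(0, 1),
                           legend.text = metrics,
                           args.legend = list(x = "topright", cex = 0.7),
                           ylab = "fold-averaged metric", ...)
  invisible(mid)
}
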