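#' Fit the standardization + PCA reduction model
#'
#' Each of the 24 image features is standardized to zero mean and unit SD
#' (constant features are dropped with a warning), a PCA is fitted on the
#' standardized matrix, and the smallest number of leading components whose
#' cumulative explained-variance fraction reaches `threshold` is retained.
#' Patient age never enters the fit; it is z-scored by its own statistics
#' and appended after projection by [apply_reduction()].
#'
#' Component signs follow a deterministic convention (the largest-magnitude
#' loading element of each component is positive) so repeated fits are
#' bit-identical.
#'
#' @param table feature table from [extract_feature_table()] (columns: the
#'   24 features, `age_years`, `label`, optionally `sample_id`).
#' @param threshold cumulative explained-variance fraction in (0, 1\];
#'   default 0.99.
#' @return An object of class `reduction_model`.
#' @export
fit_reduction <- function(table, threshold = 0.99) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop("`threshold` must be in (0, 1]")
  feats <- intersect(feature_names(), names(table))
  if (!length(feats)) stop("`table` has no recognized feature columns")
  if (nrow(table) < 3L)
    stop("need at least 3 samples to fit the reduction, got ", nrow(table))
  X <- as.matrix(table[, feats, drop = FALSE])
  if (anyNA(X)) stop("feature table contains missing values")
  mu <- colMeans(X)
  sig <- apply(X, 2L, sd)
  constant <- sig == 0 | !is.finite(sig)
  if (all(constant)) stop("all feature columns are constant")
  if (any(constant))
    warning("dropping constant feature(s): ",
            paste(feats[constant], collapse = ", "))
  keep <- feats[!constant]
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2L, mu[keep]), 2L, sig[keep],
              "/")
  pc <- prcomp(Xs, center = FALSE, scale. = FALSE)
  evf <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(evf) >= threshold - 1e-12)[1]
  rot <- pc$rotation
  for (j in seq_len(ncol(rot)))         # deterministic sign convention
    if (rot[which.max(abs(rot[, j])), j] < 0) rot[, j] <- -rot[, j]
  structure(
    list(features = keep,
         dropped = feats[constant],
         feature_means = mu[keep],
         feature_sds = sig[keep],
         rotation = rot,
         explained_variance = evf,
         n_components = as.integer(k),
         threshold = threshold,
         age_mean = mean(table$age_years),
         age_sd = sd(table$age_years),
         n_fit = nrow(table)),
    class = "reduction_model")
}

#' @export
print.reduction_model <- function(x, ...) {
  cat(sprintf(
    "<reduction_model: %d features -> %d components (%.2f%% of variance, threshold %.0f%%)>\n",
    length(x$features), x$n_components,
    100 * sum(x$explained_variance[seq_len(x$n_components)]),
    100 * x$threshold))
  invisible(x)
}

#' Project a feature table onto the retained components and append age
#'
#' Standardizes the features with the model's training statistics, projects
#' onto the retained loadings, and appends the patient age z-scored by the
#' model's age mean/SD. The output width is `n_components + 1`.
#'
#' @param model a [fit_reduction()] model.
#' @param table feature table with the model's feature columns.
#' @return Data frame with `sample_id` (if present), `pc_1` ... `pc_k`,
#'   `age_z` and `label`.
#' @export
apply_reduction <- function(model, table) {
  stopifnot(inherits(model, "reduction_model"))
  missing <- setdiff(model$features, names(table))
  if (length(missing))
    stop("table lacks feature column(s): ", paste(missing, collapse = ", "))
  X <- as.matrix(table[, model$features, drop = FALSE])
  Xs <- sweep(sweep(X, 2L, model$feature_means), 2L, model$feature_sds, "/")
  k <- model$n_components
  scores <- Xs %*% model$rotation[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("pc_", seq_len(k))
  age_sd <- if (is.finite(model$age_sd) && model$age_sd > 0) model$age_sd
            else 1
  out <- as.data.frame(scores)
  if ("sample_id" %in% names(table))
    out <- cbind(data.frame(sample_id = table$sample_id,
                            stringsAsFactors = FALSE), out)
  out$age_z <- (table$age_years - model$age_mean) / age_sd
  if ("label" %in% names(table)) out$label <- as.integer(table$label)
  rownames(out) <- NULL
  out
}

#' Serialize / restore a reduction model as JSON
#'
#' @param model a [fit_reduction()] model.
#' @param path file path.
#' @return `write_reduction_json` returns `path` invisibly;
#'   `read_reduction_json` returns the restored `reduction_model`.
#' @export
write_reduction_json <- function(model, path) {
  stopifnot(inherits(model, "reduction_model"))
  obj <- unclass(model)
  obj$rotation <- as.data.frame(obj$rotation)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_reduction_json
#' @export
read_reduction_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rot <- as.matrix(obj$rotation)
  rownames(rot) <- obj$features
  model <- list(features = obj$features,
                dropped = obj$dropped %||% character(0),
                feature_means = setNames(obj$feature_means, obj$features),
                feature_sds = setNames(obj$feature_sds, obj$features),
                rotation = rot,
                explained_variance = obj$explained_variance,
                n_components = as.integer(obj$n_components),
                threshold = obj$threshold,
                age_mean = obj$age_mean,
                age_sd = obj$age_sd,
                n_fit = obj$n_fit)
  structure(model, class = "reduction_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
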