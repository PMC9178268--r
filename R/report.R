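# Result serialization: per-iteration metrics CSV, JSON summary, per-type
# confusion-percentage CSV. Writers are deterministic so identical seeds give
# byte-identical files.

#' Per-iteration metrics as a data frame
#'
#' @param result An `mccv_result`.
#' @return A data frame with one row per MCCV iteration.
#' @export
mccv_metrics <- function(result) {
  stopifnot(inherits(result, "mccv_result"))
  data.frame(
    iteration = seq_along(result$iterations),
    model = vapply(result$iterations, `[[`, character(1), "kind"),
    hyper = vapply(result$iterations, function(r)
      paste(names(r$hyper), unlist(r$hyper), sep = "=", collapse = ";"), character(1)),
    pca_k = vapply(result$iterations, `[[`, numeric(1), "pca_k"),
    auc = vapply(result$iterations, `[[`, numeric(1), "auc"),
    acc = vapply(result$iterations, `[[`, numeric(1), "acc"),
    sensitivity = vapply(result$iterations, `[[`, numeric(1), "sensitivity"),
    specificity = vapply(result$iterations, `[[`, numeric(1), "specificity"))
}

#' Write MCCV results to disk
#'
#' Writes `<prefix>_iterations.csv` (per-iteration metrics),
#' `<prefix>_summary.json` (aggregate metrics, selected-model tally, and the
#' permutation p-value when given), and `<prefix>_confusion.csv` (per-type
#' classification percentages, rows summing to 100).
#'
#' @param result An `mccv_result`.
#' @param prefix Output path prefix.
#' @param permutation Optional `permutation_result` to include.
#' @return Invisibly, the paths written.
#' @export
write_mccv_results <- function(result, prefix, permutation = NULL) {
  stopifnot(inherits(result, "mccv_result"))
  paths <- c(iterations = paste0(prefix, "_iterations.csv"),
             summary = paste0(prefix, "_summary.json"),
             confusion = paste0(prefix, "_confusion.csv"))
  utils::write.csv(mccv_metrics(result), paths["iterations"], row.names = FALSE)
  tally <- table(vapply(result$iterations, `[[`, character(1), "kind"))
  summary <- list(
    feature_class = result$feature_class,
    n_iter = result$n_iter,
    seed = result$seed,
    mean = as.list(result$mean),
    median = as.list(result$median),
    selected_models = as.list(tally))
  if (!is.null(permutation))
    summary$permutation <- list(observed_auc = permutation$observed_auc,
                                n_perm = permutation$n_perm,
                                p_value = permutation$p_value)
  jsonlite::write_json(summary, paths["summary"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  conf <- as.data.frame.matrix(result$confusion_percent)
  conf <- cbind(voc_type = rownames(conf), conf)
  utils::write.csv(conf, paths["confusion"], row.names = FALSE)
  invisible(paths)
}
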