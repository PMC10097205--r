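# Application of fitted bundles to new sequences, and the
# LSPpred/SPLpred consensus.

predict_scores <- function(model, records) {
  feats <- apply_feature_scaling(extract_features(records), model$scaling)
  forest_scores(model$ensemble, feature_matrix(feats,
                                               model$retained_features))
}

#' Predict LSP scores and calls for new records
#'
#' Scores each record with the bundle's ensemble and applies both
#' decision modes: high confidence (score at or above the FPR-calibrated
#' threshold counts as positive) and low confidence (majority score of
#' 0.5 or more).
#'
#' @param object An `lsp_model`.
#' @param records Protein record tibble (validated sequences).
#' @param ... Unused.
#' @return Tibble with columns `protein_id`, `score`, `high`, `low`.
#' @export
predict.lsp_model <- function(object, records, ...) {
  s <- predict_scores(object, records)
  tibble::tibble(
    protein_id = records$id,
    score = s,
    high = s >= object$threshold_high,
    low = s >= object$threshold_low
  )
}

#' Combine LSPpred and SPLpred calls into a consensus
#'
#' @param lsp,spl Prediction tibbles from [predict.lsp_model()] for the
#'   same proteins (matched by `protein_id`).
#' @param mode `"and"` (default: both modules must agree, the
#'   conservative choice consistent with FPR control) or `"or"`.
#' @return Tibble with per-module scores and calls plus `consensus_high`,
#'   `consensus_low`.
#' @export
consensus <- function(lsp, spl, mode = c("and", "or")) {
  mode <- match.arg(mode)
  if (!setequal(lsp$protein_id, spl$protein_id)) {
    stop("prediction tables cover different proteins", call. = FALSE)
  }
  spl <- spl[match(lsp$protein_id, spl$protein_id), , drop = FALSE]
  comb <- if (mode == "and") `&` else `|`
  tibble::tibble(
    protein_id = lsp$protein_id,
    lsppred_score = lsp$score,
    splpred_score = spl$score,
    lsppred_high = lsp$high, lsppred_low = lsp$low,
    splpred_high = spl$high, splpred_low = spl$low,
    consensus_high = comb(lsp$high, spl$high),
    consensus_low = comb(lsp$low, spl$low)
  )
}

#' Run both predictors over a record set
#'
#' @param records Protein record tibble.
#' @param lsppred,splpred Fitted `lsp_model` bundles.
#' @param mode Consensus mode (see [consensus()]).
#' @return The consensus prediction tibble.
#' @export
predict_suite <- function(records, lsppred, splpred, mode = "and") {
  short <- nchar(records$sequence) < 1L
  if (any(short)) {
    warning("skipping ", sum(short), " empty sequence(s)", call. = FALSE)
    records <- records[!short, , drop = FALSE]
  }
  consensus(predict(lsppred, records), predict(splpred, records),
            mode = mode)
}

#' Write predictions with fixed formatting
#'
#' Writes a prediction tibble as TSV with scores printed to six decimal
#' places, so identical inputs give byte-identical files.
#'
#' @param predictions Prediction tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  out <- predictions
  for (col in names(out)) {
    if (is.double(out[[col]])) out[[col]] <- sprintf("%.6f", out[[col]])
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Persist a model bundle as a directory
#'
#' Writes the retained feature list, scaling parameters, thresholds and
#' CV metrics as plain text, and the ensemble itself via [saveRDS()].
#'
#' @param model An `lsp_model`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(tibble::tibble(feature = model$retained_features),
                   file.path(dir, "retained_features.tsv"))
  readr::write_tsv(model$scaling, file.path(dir, "scaling.tsv"))
  meta <- c(model$cv_metrics,
            list(scheme = model$scheme,
                 threshold_high = model$threshold_high,
                 threshold_low = model$threshold_low,
                 seed = model$seed))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(model, file.path(dir, "model.rds"))
  invisible(dir)
}

#' Load a persisted model bundle
#'
#' @param dir Directory written by [write_model()].
#' @return The `lsp_model`.
#' @export
read_model <- function(dir) {
  readRDS(file.path(dir, "model.rds"))
}
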