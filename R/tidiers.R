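# broom-style tidiers and ggplot2 autoplot methods for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cross-validation result
#'
#' One row per fold: AUROC, chosen threshold, TPR and FPR at it.
#'
#' @param x An `lsp_cv`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy lsp_cv
#' @export
tidy.lsp_cv <- function(x, ...) x$folds

#' @rdname tidy.lsp_cv
#' @method glance lsp_cv
#' @export
glance.lsp_cv <- function(x, ...) {
  tibble::tibble(
    n_folds = x$n_folds,
    auroc_mean = mean(x$folds$auroc),
    auroc_sd = stats::sd(x$folds$auroc),
    threshold_mean = mean(x$folds$threshold),
    tpr_mean = mean(x$folds$tpr),
    fpr_target = x$fpr_target
  )
}

#' Tidy a fitted model bundle
#'
#' One row per retained feature with its Gini importance in the final
#' ensemble.
#'
#' @param x An `lsp_model`.
#' @param ... Unused.
#' @return A tibble with columns `feature`, `importance`.
#' @method tidy lsp_model
#' @export
tidy.lsp_model <- function(x, ...) {
  imp <- randomForest::importance(x$ensemble, type = 2)
  tibble::tibble(feature = rownames(imp),
                 importance = unname(imp[, 1])) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' @rdname tidy.lsp_model
#' @method glance lsp_model
#' @export
glance.lsp_model <- function(x, ...) {
  hi <- x$test_report[x$test_report$mode == "high_confidence", ]
  lo <- x$test_report[x$test_report$mode == "low_confidence", ]
  tibble::tibble(
    scheme = as.character(x$scheme),
    n_features = length(x$retained_features),
    threshold_high = x$threshold_high,
    cv_auroc_mean = x$cv_metrics$auroc_mean,
    cv_auroc_sd = x$cv_metrics$auroc_sd,
    cv_tpr_at_threshold = x$cv_metrics$tpr_at_threshold,
    test_balanced_accuracy_high = hi$balanced_accuracy,
    test_balanced_accuracy_low = lo$balanced_accuracy,
    test_fpr_high = hi$fpr
  )
}

#' Tidy an LSPDB
#'
#' The per-protein evidence-score table.
#'
#' @param x An `lspdb`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy lspdb
#' @export
tidy.lspdb <- function(x, ...) x$scores

#' @rdname tidy.lspdb
#' @method glance lspdb
#' @export
glance.lspdb <- function(x, ...) {
  cc <- x$summary$class_counts
  kc <- x$summary$confidence_counts
  tibble::tibble(
    n_genes = nrow(x$classes), n_proteins = nrow(x$protein_gene),
    n_sec = cc[["SEC"]], n_spt = cc[["SPT"]],
    n_unclassified = cc[["UNCLASSIFIED"]], n_nonsec = cc[["NONSEC"]],
    n_secretory_isoform = cc[["SECRETORY_ISOFORM"]],
    n_tm_only = cc[["TM_ONLY"]],
    n_high = kc[["High"]], n_medium = kc[["Medium"]], n_low = kc[["Low"]]
  )
}

#' ROC curves of a cross-validation result
#'
#' Per-fold out-of-fold ROC curves with the FPR target marked.
#'
#' @param object An `lsp_cv`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lsp_cv
#' @export
autoplot.lsp_cv <- function(object, ...) {
  ggplot2::ggplot(object$roc,
                  ggplot2::aes(x = .data$fpr, y = .data$tpr,
                               colour = factor(.data$fold))) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = object$fpr_target,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate",
                  colour = "Fold") +
    ggplot2::theme_minimal()
}

#' Density plot of a modification-bias report
#'
#' Kernel density of prediction scores for the modified and unmodified
#' versions of the paired set.
#'
#' @param object An `lsp_bias`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lsp_bias
#' @export
autoplot.lsp_bias <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("protein_id", "score_modified",
                                  "score_unmodified")],
    cols = -"protein_id", names_to = "version", names_prefix = "score_",
    values_to = "score"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$score,
                                     fill = .data$version)) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::labs(x = "Prediction score", y = "Density", fill = NULL,
                  subtitle = sprintf("mean difference %+.3f",
                                     attr(object, "mean_difference"))) +
    ggplot2::theme_minimal()
}

#' Feature-importance plot for a fitted model
#'
#' Top retained features of the final ensemble by Gini importance.
#'
#' @param model An `lsp_model`.
#' @param top Number of features shown.
#' @return A ggplot.
#' @export
plot_importance <- function(model, top = 20L) {
  d <- utils::head(tidy(model), top)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$importance,
                                  y = stats::reorder(.data$feature,
                                                     .data$importance))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Gini importance", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
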