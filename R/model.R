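# Balanced random-forest training with FPR-calibrated thresholds,
# upper-quartile feature selection and modification-bias estimation.

feature_matrix <- function(features, cols = NULL) {
  num <- dplyr::select(features, -"protein_id")
  if (!is.null(cols)) {
    missing <- setdiff(cols, names(num))
    if (length(missing)) {
      stop("feature(s) absent from table: ",
           paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
    }
    num <- num[, cols, drop = FALSE]
  }
  as.matrix(num)
}

label_factor <- function(label) {
  factor(label, levels = c("negative", "positive"))
}

#' Stratified train/test split
#'
#' Splits a labelled dataset into train and test partitions, preserving
#' the class proportions within rounding. Reproducible by seed.
#'
#' @param dataset An `lsp_dataset`.
#' @param test_fraction Fraction held out (default 0.25).
#' @param seed Integer seed.
#' @return List with elements `train` and `test` (both `lsp_dataset`).
#' @export
stratified_split <- function(dataset, test_fraction = 0.25, seed = 1L) {
  lab <- dataset$records$label
  tab <- table(lab)
  if (any(tab < 2L)) {
    stop("each class needs at least 2 members to split", call. = FALSE)
  }
  rng <- local({
    set.seed(as.integer(seed))
    lapply(split(seq_along(lab), lab), function(idx) {
      k <- max(1L, round(length(idx) * test_fraction))
      sample(idx, k)
    })
  })
  test_idx <- sort(unlist(rng, use.names = FALSE))
  list(train = subset_dataset(dataset, -test_idx),
       test = subset_dataset(dataset, test_idx))
}

#' Train a balanced random forest
#'
#' An ensemble of randomised decision trees in which every tree is grown
#' on a class-balanced bootstrap: the majority class is downsampled (with
#' replacement) to the minority-class count for each tree. Scores are the
#' ensemble's positive-class vote fractions in `[0, 1]`.
#'
#' @param x Numeric feature matrix (rows = proteins).
#' @param label Character vector of `"positive"`/`"negative"` labels.
#' @param ntree Number of trees (default 500).
#' @param mtry Features sampled per split; default `floor(sqrt(p))`.
#' @param seed Integer seed.
#' @param keep_inbag Record per-tree bootstrap counts (for auditing the
#'   balance property).
#' @return A `randomForest` ensemble.
#' @export
train_balanced_forest <- function(x, label, ntree = 500L, mtry = NULL,
                                  seed = 1L, keep_inbag = FALSE) {
  y <- label_factor(label)
  if (nlevels(droplevels(y)) < 2L) {
    stop("training data must contain both classes", call. = FALSE)
  }
  m <- min(table(y))
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  set.seed(as.integer(seed))
  randomForest::randomForest(
    x = x, y = y, ntree = ntree, mtry = mtry,
    strata = y, sampsize = c(negative = m, positive = m),
    replace = TRUE, importance = FALSE, keep.inbag = keep_inbag
  )
}

forest_scores <- function(forest, x) {
  unname(stats::predict(forest, x, type = "prob")[, "positive"])
}

#' Per-fold threshold at an FPR bound
#'
#' The smallest score cutoff (prediction positive when `score >= cutoff`)
#' whose false-positive rate on the given scores does not exceed the
#' target — equivalently the cutoff maximising TPR subject to the FPR
#' bound. If no observed score qualifies, a cutoff just above the highest
#' negative score (FPR 0) is used with a warning.
#'
#' @param scores Numeric scores.
#' @param label `"positive"`/`"negative"` labels.
#' @param fpr_target FPR bound (default 0.05).
#' @return List with `threshold`, `tpr`, `fpr`.
#' @export
fold_threshold <- function(scores, label, fpr_target = 0.05) {
  pos <- scores[label == "positive"]
  neg <- scores[label == "negative"]
  stopifnot(length(pos) > 0L, length(neg) > 0L)
  cand <- sort(unique(scores))
  fpr <- vapply(cand, function(t) mean(neg >= t), 0)
  ok <- which(fpr <= fpr_target)
  if (length(ok)) {
    t <- cand[ok[1L]]
  } else {
    warning("no observed score meets the FPR bound; ",
            "using a cutoff above the maximal negative score",
            call. = FALSE)
    t <- max(neg) + 1e-9
  }
  list(threshold = t,
       tpr = mean(pos >= t),
       fpr = mean(neg >= t))
}

#' Stratified k-fold cross-validation of a balanced forest
#'
#' Assigns samples to stratified folds, trains a balanced forest on each
#' training complement, and records out-of-fold scores, per-fold ROC
#' points and AUROC, Gini feature importances, and the per-fold
#' FPR-bounded threshold with its TPR.
#'
#' @param train An `lsp_dataset` (the training partition).
#' @param n_folds Number of folds (default 5).
#' @param fpr_target Per-fold FPR bound for threshold selection.
#' @param ntree Trees per fold model.
#' @param seed Integer seed (fans out to fold assignment and trees).
#' @return Object of class `lsp_cv`: list with `scores` (tibble:
#'   protein_id, label, score, fold), `folds` (per-fold threshold/TPR/
#'   AUROC), `roc` (per-fold ROC points), `importance` (feature x fold
#'   matrix), `n_folds`, `fpr_target`.
#' @export
cross_validate <- function(train, n_folds = 5L, fpr_target = 0.05,
                           ntree = 500L, seed = 1L) {
  lab <- train$records$label
  if (min(table(lab)) < n_folds) {
    stop("too few members of a class for ", n_folds,
         " stratified folds; reduce n_folds", call. = FALSE)
  }
  x <- feature_matrix(train$features)
  set.seed(as.integer(seed))
  fold_of <- integer(length(lab))
  for (cls in unique(lab)) {
    idx <- sample(which(lab == cls))
    fold_of[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  score_rows <- list(); fold_rows <- list(); roc_rows <- list()
  imp <- matrix(NA_real_, ncol(x), n_folds,
                dimnames = list(colnames(x), NULL))
  for (f in seq_len(n_folds)) {
    tr <- fold_of != f
    fit <- {
      set.seed(as.integer(seed) + f)
      m <- min(table(label_factor(lab[tr])))
      randomForest::randomForest(
        x = x[tr, , drop = FALSE], y = label_factor(lab[tr]),
        ntree = ntree, mtry = max(1L, floor(sqrt(ncol(x)))),
        strata = label_factor(lab[tr]),
        sampsize = c(negative = m, positive = m), replace = TRUE
      )
    }
    imp[, f] <- randomForest::importance(fit, type = 2)[, 1]
    s <- forest_scores(fit, x[!tr, , drop = FALSE])
    l <- lab[!tr]
    score_rows[[f]] <- tibble::tibble(
      protein_id = train$records$id[!tr], label = l, score = s, fold = f
    )
    th <- fold_threshold(s, l, fpr_target)
    auc <- as.numeric(pROC::auc(pROC::roc(
      response = l, predictor = s, levels = c("negative", "positive"),
      direction = "<", quiet = TRUE
    )))
    fold_rows[[f]] <- tibble::tibble(
      fold = f, threshold = th$threshold, tpr = th$tpr, fpr = th$fpr,
      auroc = auc
    )
    cand <- c(-Inf, sort(unique(s)), Inf)
    roc_rows[[f]] <- tibble::tibble(
      fold = f, threshold = cand,
      fpr = vapply(cand, function(t) mean(s[l == "negative"] >= t), 0),
      tpr = vapply(cand, function(t) mean(s[l == "positive"] >= t), 0)
    )
  }
  structure(
    list(scores = dplyr::bind_rows(score_rows),
         folds = dplyr::bind_rows(fold_rows),
         roc = dplyr::bind_rows(roc_rows),
         importance = imp,
         n_folds = n_folds, fpr_target = fpr_target,
         seed = as.integer(seed)),
    class = "lsp_cv"
  )
}

#' @export
print.lsp_cv <- function(x, ...) {
  cat(x$n_folds, "-fold cross-validation\n", sep = "")
  cat(sprintf("mean AUROC %.3f (sd %.3f); mean threshold %.3f at FPR <= %.2f; mean TPR %.3f\n",
              mean(x$folds$auroc), stats::sd(x$folds$auroc),
              mean(x$folds$threshold), x$fpr_target, mean(x$folds$tpr)))
  invisible(x)
}

#' Cross-validated threshold at an FPR bound
#'
#' The mean over folds of the per-fold thresholds that do not exceed the
#' target FPR, together with the mean TPR at those thresholds.
#'
#' @param cv An `lsp_cv` object.
#' @param fpr_target FPR bound; defaults to the one used in
#'   [cross_validate()]. Re-deriving at another target recomputes the
#'   per-fold choice from the stored out-of-fold scores.
#' @return List with `threshold_high` and `tpr_estimate`.
#' @export
threshold_at_fpr <- function(cv, fpr_target = NULL) {
  if (is.null(fpr_target) || identical(fpr_target, cv$fpr_target)) {
    return(list(threshold_high = mean(cv$folds$threshold),
                tpr_estimate = mean(cv$folds$tpr)))
  }
  per_fold <- lapply(split(cv$scores, cv$scores$fold), function(d) {
    fold_threshold(d$score, d$label, fpr_target)
  })
  list(threshold_high = mean(vapply(per_fold, `[[`, 0, "threshold")),
       tpr_estimate = mean(vapply(per_fold, `[[`, 0, "tpr")))
}

#' Upper-quartile feature selection
#'
#' Features whose fold-averaged Gini importance is at least the value of
#' the feature ranked at the upper quartile are retained (ties at the
#' boundary all retained; with distinct importances this keeps
#' `ceiling(0.25 * p)` features, and all features when importances are
#' all equal).
#'
#' @param cv An `lsp_cv` object.
#' @param quantile Retained fraction (default 0.25, the upper quartile).
#' @return Character vector of retained feature names, in registry order.
#' @export
select_top_features <- function(cv, quantile = 0.25) {
  mean_imp <- rowMeans(cv$importance)
  k <- ceiling(quantile * length(mean_imp))
  cutoff <- sort(mean_imp, decreasing = TRUE)[k]
  names(mean_imp)[mean_imp >= cutoff]
}

#' Balanced accuracy
#'
#' Mean of the positive-class and negative-class accuracies:
#' `(TP/(TP+FN) + TN/(TN+FP)) / 2`.
#'
#' @param label `"positive"`/`"negative"` truth labels.
#' @param predicted_positive Logical predictions.
#' @return Numeric scalar.
#' @export
balanced_accuracy <- function(label, predicted_positive) {
  tpr <- mean(predicted_positive[label == "positive"])
  tnr <- mean(!predicted_positive[label == "negative"])
  (tpr + tnr) / 2
}

#' Finalise a model bundle on the full training partition
#'
#' Refits the balanced forest on all training data restricted to the
#' retained features, and evaluates the held-out test partition at both
#' the FPR-calibrated threshold and the 0.5 majority threshold.
#'
#' @param train,test `lsp_dataset` partitions from [stratified_split()].
#' @param cv The `lsp_cv` from [cross_validate()] on `train`.
#' @param retained_features Features to keep; default
#'   [select_top_features()] of `cv`.
#' @param threshold_high Calibrated threshold; default
#'   [threshold_at_fpr()] of `cv`.
#' @param ntree Trees in the final ensemble.
#' @param seed Integer seed.
#' @param scheme_name Optional scheme label stored in the bundle.
#' @return Object of class `lsp_model`: the ensemble plus
#'   `retained_features`, `threshold_high`, `threshold_low` (0.5),
#'   `scaling`, `cv_metrics` and a `test_report` (balanced accuracy and
#'   FPR/TPR at both thresholds).
#' @export
finalize_model <- function(train, test, cv,
                           retained_features = select_top_features(cv),
                           threshold_high = NULL, ntree = 500L, seed = 1L,
                           scheme_name = NULL) {
  if (is.null(threshold_high)) {
    th <- threshold_at_fpr(cv)
    threshold_high <- th$threshold_high
    tpr_estimate <- th$tpr_estimate
  } else {
    tpr_estimate <- NA_real_
  }
  scaling <- fit_feature_scaling(train$features)
  xtr <- feature_matrix(apply_feature_scaling(train$features, scaling),
                        retained_features)
  forest <- train_balanced_forest(xtr, train$records$label, ntree = ntree,
                                  seed = seed)
  xte <- feature_matrix(apply_feature_scaling(test$features, scaling),
                        retained_features)
  s <- forest_scores(forest, xte)
  lab <- test$records$label
  report <- tibble::tibble(
    threshold = c(threshold_high, 0.5),
    mode = c("high_confidence", "low_confidence"),
    balanced_accuracy = c(balanced_accuracy(lab, s >= threshold_high),
                          balanced_accuracy(lab, s >= 0.5)),
    fpr = c(mean(s[lab == "negative"] >= threshold_high),
            mean(s[lab == "negative"] >= 0.5)),
    tpr = c(mean(s[lab == "positive"] >= threshold_high),
            mean(s[lab == "positive"] >= 0.5))
  )
  structure(
    list(
      scheme = scheme_name %||% train$provenance$scheme$name %||% NA,
      ensemble = forest,
      retained_features = retained_features,
      threshold_high = threshold_high,
      threshold_low = 0.5,
      scaling = scaling,
      cv_metrics = list(
        auroc_mean = mean(cv$folds$auroc),
        auroc_sd = stats::sd(cv$folds$auroc),
        tpr_at_threshold = tpr_estimate,
        fpr_target = cv$fpr_target
      ),
      test_report = report,
      seed = as.integer(seed)
    ),
    class = "lsp_model"
  )
}

#' @export
print.lsp_model <- function(x, ...) {
  cat("Balanced random-forest LSP classifier",
      if (!is.na(x$scheme)) paste0("(", x$scheme, ")"), "\n")
  cat(sprintf("  %d retained features; threshold_high %.3f (FPR target %.2f), threshold_low %.2f\n",
              length(x$retained_features), x$threshold_high,
              x$cv_metrics$fpr_target, x$threshold_low))
  cat(sprintf("  CV AUROC %.3f +/- %.3f\n", x$cv_metrics$auroc_mean,
              x$cv_metrics$auroc_sd))
  invisible(x)
}

#' Full training pipeline
#'
#' Convenience wrapper running the complete procedure on a labelled
#' dataset: stratified 75/25 split, stratified 5-fold cross-validation of
#' the balanced forest, FPR-bounded threshold estimation, upper-quartile
#' feature selection, and final refit with test-set evaluation.
#'
#' @param dataset An `lsp_dataset`.
#' @param test_fraction,n_folds,fpr_target,ntree Pipeline parameters.
#' @param seed Master seed; fans out deterministically to the split, the
#'   folds and the trees.
#' @return An `lsp_model` with the `lsp_cv` attached as `$cv`.
#' @export
train_pipeline <- function(dataset, test_fraction = 0.25, n_folds = 5L,
                           fpr_target = 0.05, ntree = 500L, seed = 1L) {
  seed <- as.integer(seed)
  parts <- stratified_split(dataset, test_fraction, seed = seed)
  cv <- cross_validate(parts$train, n_folds = n_folds,
                       fpr_target = fpr_target, ntree = ntree,
                       seed = seed + 1000L)
  model <- finalize_model(parts$train, parts$test, cv, ntree = ntree,
                          seed = seed + 2000L)
  model$cv <- cv
  model$split <- parts
  model
}

#' Estimate prediction bias from sequence modification
#'
#' Scores paired modified/unmodified versions of the same proteins with a
#' fitted model and reports the per-protein signed score difference
#' (modified minus unmodified) and its mean. Large mean shifts indicate
#' the model has learnt the modification itself rather than the biology.
#'
#' @param model An `lsp_model`.
#' @param modified,unmodified Protein record tibbles paired by
#'   `source_id` (or `id` when `source_id` is absent).
#' @return Object of class `lsp_bias`: tibble of per-protein scores and
#'   differences, with the mean difference in `attr(, "mean_difference")`.
#' @export
estimate_bias <- function(model, modified, unmodified) {
  key <- function(r) if ("source_id" %in% names(r)) r$source_id else r$id
  km <- key(modified); ku <- key(unmodified)
  if (!setequal(km, ku)) {
    stop("modified/unmodified sets are not paired by id", call. = FALSE)
  }
  sm <- predict_scores(model, modified)
  su <- predict_scores(model, unmodified)
  out <- tibble::tibble(
    protein_id = km,
    score_modified = sm,
    score_unmodified = su[match(km, ku)],
    difference = sm - su[match(km, ku)]
  )
  structure(out, class = c("lsp_bias", class(out)),
            mean_difference = mean(out$difference))
}

#' @export
print.lsp_bias <- function(x, ...) {
  cat(sprintf("Modification bias over %d pairs: mean score difference %+.4f\n",
              nrow(x), attr(x, "mean_difference")))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
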