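test_that("stratified splitting preserves proportions and partitions the data", {
  ds <- toy_dataset(n_pos = 8, n_neg = 80)
  parts <- stratified_split(ds, 0.25, seed = 2)
  lab_te <- parts$test$records$label
  expect_equal(sum(lab_te == "positive"), 2L)
  expect_equal(sum(lab_te == "negative"), 20L)
  expect_length(intersect(parts$train$records$id, parts$test$records$id),
                0L)
  expect_setequal(c(parts$train$records$id, parts$test$records$id),
                  ds$records$id)
  again <- stratified_split(ds, 0.25, seed = 2)
  expect_identical(again$test$records$id, parts$test$records$id)
  tiny <- toy_dataset(n_pos = 20, n_neg = 20)
  tiny$records$label[tiny$records$label == "positive"][-1] <- "negative"
  expect_error(stratified_split(tiny), "at least 2")
})

test_that("each balanced-forest tree trains on a class-balanced bootstrap", {
  ds <- toy_dataset(n_pos = 10, n_neg = 50, sep = 5)
  x <- as.matrix(ds$features[-1])
  fit <- train_balanced_forest(x, ds$records$label, ntree = 100,
                               seed = 3, keep_inbag = TRUE)
  pos_rows <- ds$records$label == "positive"
  pos_in <- colSums(fit$inbag[pos_rows, ])
  neg_in <- colSums(fit$inbag[!pos_rows, ])
  expect_true(all(pos_in == 10)) # minority count per tree
  expect_true(all(neg_in == 10)) # majority downsampled to match
  # separable data is learnt outright
  expect_true(all(forest_acc <- mean(
    (leaderless:::forest_scores(fit, x) >= 0.5) == pos_rows) == 1))
  expect_error(train_balanced_forest(x, rep("positive", nrow(x))),
               "both classes")
})

test_that("cross-validation scores each sample once and learns separable data", {
  ds <- toy_dataset(n_pos = 20, n_neg = 80, sep = 3)
  cv <- cross_validate(ds, n_folds = 5, ntree = 100, seed = 5)
  expect_equal(sort(cv$scores$protein_id), sort(ds$records$id))
  expect_equal(nrow(cv$scores), nrow(ds$records))
  expect_true(all(cv$folds$auroc >= 0 & cv$folds$auroc <= 1))
  expect_true(all(cv$scores$score >= 0 & cv$scores$score <= 1))
  expect_gt(mean(cv$folds$auroc), 0.95)
  expect_true(all(cv$folds$fpr <= 0.05))
  expect_error(cross_validate(toy_dataset(n_pos = 3, n_neg = 50)),
               "folds")
})

test_that("AUROC is invariant under strictly monotone score transforms", {
  set.seed(8)
  lab <- c(rep("positive", 15), rep("negative", 40))
  s <- c(stats::rnorm(15, 1), stats::rnorm(40))
  auc_of <- function(x) as.numeric(pROC::auc(pROC::roc(
    response = lab, predictor = x, levels = c("negative", "positive"),
    direction = "<", quiet = TRUE)))
  expect_equal(auc_of(s), auc_of(stats::plogis(3 * s + 1)))
})

test_that("the per-fold threshold is the brute-force optimum under the FPR bound", {
  # 20 negatives: the bound permits one false positive, so the threshold
  # sits just above the second-highest negative score
  set.seed(12)
  neg <- sort(stats::runif(20))
  pos <- stats::runif(10, 0.5, 1)
  scores <- c(pos, neg)
  label <- c(rep("positive", 10), rep("negative", 20))
  got <- fold_threshold(scores, label, 0.05)
  expect_lte(mean(neg >= got$threshold), 0.05)
  expect_gt(got$threshold, sort(neg, decreasing = TRUE)[2])
  # against the exhaustive oracle on random instances
  for (i in 1:100) {
    n_pos <- sample(3:30, 1); n_neg <- sample(3:60, 1)
    s <- round(stats::runif(n_pos + n_neg), sample(c(1, 2, 7), 1))
    l <- c(rep("positive", n_pos), rep("negative", n_neg))
    target <- sample(c(0.01, 0.05, 0.2), 1)
    got <- suppressWarnings(fold_threshold(s, l, target))
    want <- threshold_oracle(s, l, target)
    expect_equal(got$threshold, want$threshold)
    expect_equal(got$tpr, want$tpr)
  }
})

test_that("threshold aggregation averages the per-fold choices", {
  ds <- toy_dataset(n_pos = 20, n_neg = 80, sep = 4)
  cv <- cross_validate(ds, ntree = 100, seed = 6)
  th <- threshold_at_fpr(cv)
  expect_equal(th$threshold_high, mean(cv$folds$threshold))
  expect_equal(th$tpr_estimate, mean(cv$folds$tpr))
  # perfectly separated scores give TPR 1 at FPR 0
  sep <- fold_threshold(c(0.9, 0.95, 0.1, 0.2),
                        c("positive", "positive", "negative", "negative"),
                        0.05)
  expect_equal(sep$tpr, 1)
  expect_equal(sep$fpr, 0)
  # re-derivation at another target recomputes from stored fold scores
  th2 <- threshold_at_fpr(cv, fpr_target = 0.2)
  expect_lte(th2$threshold_high, th$threshold_high)
})

test_that("upper-quartile feature selection keeps ceil(p/4) with tie handling", {
  mk_cv <- function(imp) {
    structure(list(importance = cbind(imp, imp),
                   folds = tibble::tibble()), class = "lsp_cv")
  }
  imp <- stats::setNames(seq(0.01, 1, length.out = 100),
                         sprintf("f%03d", 1:100))
  expect_length(select_top_features(mk_cv(imp)), 25L)
  flat <- stats::setNames(rep(0.3, 40), sprintf("f%02d", 1:40))
  expect_length(select_top_features(mk_cv(flat)), 40L)
  perm <- sample(length(imp))
  expect_setequal(select_top_features(mk_cv(imp[perm])),
                  select_top_features(mk_cv(imp)))
})

test_that("balanced accuracy matches the closed form on hand-built tables", {
  # pos accuracy 0.8 (4/5), neg accuracy 0.6 (3/5) -> 0.7
  lab <- c(rep("positive", 5), rep("negative", 5))
  pred <- c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(balanced_accuracy(lab, pred), 0.7)
  # closed form (TP/(TP+FN) + TN/(TN+FP))/2 on random tables
  set.seed(14)
  for (i in 1:20) {
    l <- sample(c("positive", "negative"), 40, TRUE)
    p <- sample(c(TRUE, FALSE), 40, TRUE)
    tp <- sum(l == "positive" & p); fn <- sum(l == "positive" & !p)
    tn <- sum(l == "negative" & !p); fp <- sum(l == "negative" & p)
    expect_equal(balanced_accuracy(l, p),
                 (tp / (tp + fn) + tn / (tn + fp)) / 2)
  }
})

test_that("finalisation restricts to retained features and reports both modes", {
  ds <- toy_dataset(n_pos = 20, n_neg = 80, sep = 3)
  parts <- stratified_split(ds, seed = 7)
  cv <- cross_validate(parts$train, ntree = 100, seed = 7)
  model <- finalize_model(parts$train, parts$test, cv, seed = 7)
  expect_s3_class(model, "lsp_model")
  expect_true(all(model$retained_features %in%
                    names(ds$features)[-1]))
  expect_equal(model$threshold_low, 0.5)
  expect_equal(nrow(model$test_report), 2L)
  # degenerate forced threshold above all scores: no positives predicted,
  # balanced accuracy collapses to 0.5
  forced <- finalize_model(parts$train, parts$test, cv,
                           threshold_high = 1.1, seed = 7)
  hi <- forced$test_report[forced$test_report$mode == "high_confidence", ]
  expect_equal(hi$balanced_accuracy, 0.5)
  expect_equal(hi$tpr, 0)
  # reproducible under a fixed seed
  model2 <- finalize_model(parts$train, parts$test, cv, seed = 7)
  expect_equal(model$test_report, model2$test_report)
})

test_that("bias estimation pairs records and is antisymmetric", {
  ds <- synthetic_benchmark(15, 45, seed = 9)
  model <- train_pipeline(ds, ntree = 100, seed = 9)
  recs <- protein_records(sprintf("b%d", 1:6),
                          replicate(6, random_protein(60)))
  same <- estimate_bias(model, recs, recs)
  expect_equal(attr(same, "mean_difference"), 0)
  mod <- remove_prefix(recs, 10)
  mod$source_id <- mod$id
  recs2 <- recs; recs2$source_id <- recs2$id
  fwd <- estimate_bias(model, mod, recs2)
  bwd <- estimate_bias(model, recs2, mod)
  expect_equal(attr(fwd, "mean_difference"),
               -attr(bwd, "mean_difference"))
  expect_equal(nrow(fwd), 6L)
  stranger <- protein_records("z", random_protein(50))
  expect_error(estimate_bias(model, mod, stranger), "paired")
})

test_that("tidiers expose per-fold metrics and bundle summaries", {
  ds <- toy_dataset(n_pos = 16, n_neg = 60)
  model <- train_pipeline(ds, ntree = 100, seed = 10)
  td <- tidy(model$cv)
  expect_equal(nrow(td), 5L)
  expect_true(all(c("auroc", "threshold", "tpr") %in% names(td)))
  gl <- glance(model)
  expect_equal(gl$n_features, length(model$retained_features))
  expect_s3_class(autoplot(model$cv), "ggplot")
})
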