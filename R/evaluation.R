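# Classification metrics and the three evaluation protocols.

#' Threshold classification metrics
#'
#' Confusion-matrix metrics at a probability threshold, with the resistant
#' class (label 1) as the positive class, plus ranking metrics ([auroc()],
#' [aucpr()]). Precision with zero predicted positives is defined as 0 with a
#' warning.
#'
#' @param labels 0/1 vector; 1 = resistant.
#' @param probabilities Predicted resistance probabilities in \[0, 1\].
#' @param threshold Decision threshold (default 0.5; a probability strictly
#'   above it predicts resistant).
#' @return List with accuracy, precision, recall, f1, auroc, aucpr and the
#'   TP/FP/TN/FN counts.
#' @export
threshold_metrics <- function(labels, probabilities, threshold = 0.5) {
  if (length(labels) != length(probabilities)) stopf("length mismatch")
  if (!all(labels %in% c(0, 1))) stopf("labels must be 0/1")
  if (any(probabilities < 0 | probabilities > 1)) stopf("probabilities must lie in [0, 1]")
  pred <- as.integer(probabilities > threshold)
  tp <- sum(pred == 1L & labels == 1L); fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L); fn <- sum(pred == 0L & labels == 1L)
  precision <- if (tp + fp == 0L) { warnf("no predicted positives; precision defined as 0"); 0 } else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  list(accuracy = (tp + tn) / length(labels), precision = precision,
       recall = recall, f1 = f1,
       auroc = auroc(labels, probabilities),
       aucpr = aucpr(labels, probabilities),
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Area under the ROC curve
#'
#' Computed through the rank (Mann-Whitney) identity: the fraction of
#' (positive, negative) pairs in which the positive scores higher, ties
#' counting one half. Identical to the trapezoidal area under the ROC step
#' curve and invariant to any strictly increasing transform of the scores.
#'
#' @param labels 0/1 vector with both classes present.
#' @param scores Real-valued scores, higher = more likely positive.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(labels, scores) {
  if (length(labels) != length(scores)) stopf("length mismatch")
  pos <- labels == 1; neg <- labels == 0
  n1 <- sum(pos); n0 <- sum(neg)
  if (n1 == 0L || n0 == 0L) stopf("AUROC needs both classes present")
  r <- rank(scores)  # midranks handle ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Average-precision summation over the descending-score sweep:
#' `sum_k (R_k - R_{k-1}) * P_k`. Tied scores enter as one threshold step.
#' Trapezoidal interpolation on PR points is deliberately not used (it is
#' optimistic for PR curves).
#'
#' @inheritParams auroc
#' @return AUCPR in (0, 1\].
#' @export
aucpr <- function(labels, scores) {
  if (length(labels) != length(scores)) stopf("length mismatch")
  n_pos <- sum(labels == 1)
  if (n_pos == 0L) stopf("AUCPR needs at least one positive")
  thr <- sort(unique(scores), decreasing = TRUE)
  ap <- 0; prev_recall <- 0
  for (t in thr) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    precision <- tp / sum(sel)
    recall <- tp / n_pos
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

#' Cross-validation split plans
#'
#' `kfold_splits` builds k folds, stratified by label by default; each record
#' appears in exactly one test set. `lodocv_splits` builds one split per
#' distinct drug (leave-one-drug-out: that drug's pairs are the test set), and
#' `lococv_splits` does the same per cancer type.
#'
#' @param records Response data.frame with `label` (and `drug_id` /
#'   `cancer_type` for the grouped protocols).
#' @param k Number of folds.
#' @param seed Integer seed; plans are deterministic per seed.
#' @param stratified Stratify fold assignment by label.
#' @return A `split_plan`: list of `list(train, test)` index pairs with
#'   attributes `protocol` and `seed`; grouped plans name each split by its
#'   held-out drug/type.
#' @export
kfold_splits <- function(records, k, seed = 1L, stratified = TRUE) {
  n <- nrow(records)
  if (k < 2L || k > n) stopf("k must be in [2, %d], got %s", n, k)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fold <- integer(n)
  if (stratified) {
    for (cl in sort(unique(records$label))) {
      idx <- sample(which(records$label == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    fold[sample.int(n)] <- rep_len(seq_len(k), n)
  }
  plan <- lapply(seq_len(k), function(f)
    list(train = which(fold != f), test = which(fold == f)))
  structure(plan, protocol = sprintf("%d-fold%s", k, if (stratified) "-stratified" else ""),
            seed = seed, class = "split_plan")
}

#' @rdname kfold_splits
#' @export
lodocv_splits <- function(records) {
  grouped_splits(records, records$drug_id, "lodocv")
}

#' @rdname kfold_splits
#' @export
lococv_splits <- function(records) {
  if (is.null(records$cancer_type) || any(is.na(records$cancer_type)))
    stopf("lococv_splits needs a complete cancer_type column")
  grouped_splits(records, records$cancer_type, "lococv")
}

grouped_splits <- function(records, group, protocol) {
  groups <- sort(unique(group))
  if (length(groups) < 2L)
    stopf("%s needs at least two distinct groups (training set would be empty)", protocol)
  plan <- lapply(groups, function(g)
    list(train = which(group != g), test = which(group == g)))
  names(plan) <- groups
  structure(plan, protocol = protocol, seed = NA_integer_, class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("split plan (%s): %d split(s), test sizes %s\n",
              attr(x, "protocol"), length(x),
              paste(vapply(x, function(s) length(s$test), integer(1)), collapse = ", ")))
  invisible(x)
}

# Train on a subset of a dataset's records and score another subset.
fit_and_score <- function(dataset, refs, hp, control, train_idx, test_idx) {
  train_ds <- subset_dataset(dataset, train_idx)
  fit <- refdnn(train_ds, refs = refs,
                hidden_units = hp$hidden_units, lr_ftrl = hp$lr_ftrl,
                lr_adam = hp$lr_adam, l1 = hp$l1, l2 = hp$l2,
                control = control)
  pred <- predict(fit, dataset$expression, dataset$fingerprints,
                  dataset$records[test_idx, , drop = FALSE])
  list(fit = fit, labels = dataset$records$label[test_idx],
       probabilities = pred$p_resistance)
}

subset_dataset <- function(dataset, idx) {
  structure(list(expression = dataset$expression,
                 fingerprints = dataset$fingerprints,
                 records = dataset$records[idx, , drop = FALSE],
                 log = dataset$log), class = "refdnn_dataset")
}

#' Evaluate the model under a split plan
#'
#' Fits a fresh model on each split's training records and scores its test
#' records; used for plain k-fold CV and for the leave-one-drug-out /
#' leave-one-cancer-type-out cold-start protocols.
#'
#' @param dataset A `refdnn_dataset`.
#' @param refs Reference panel (see [refdnn()]).
#' @param plan A `split_plan`.
#' @param hp Named list of the five hyperparameters (`hidden_units`,
#'   `lr_ftrl`, `lr_adam`, `l1`, `l2`); missing entries take [refdnn()]
#'   defaults.
#' @param control A [refdnn_control()].
#' @return List with `per_fold` (data.frame of metrics per split), `mean`,
#'   `sd`, and `pooled` (metrics over all test predictions pooled).
#' @export
evaluate_plan <- function(dataset, refs, plan, hp = list(),
                          control = refdnn_control()) {
  hp <- fill_hp(hp)
  rows <- list(); pooled_y <- c(); pooled_p <- c()
  for (i in seq_along(plan)) {
    ctrl <- control
    ctrl$seed <- substream_seed(control$seed, paste0("fold", i))
    fs <- fit_and_score(dataset, refs, hp, ctrl, plan[[i]]$train, plan[[i]]$test)
    m <- if (length(unique(fs$labels)) < 2L)
      threshold_metrics_safe(fs$labels, fs$probabilities)
    else suppressWarnings(threshold_metrics(fs$labels, fs$probabilities))
    rows[[i]] <- data.frame(split = names(plan)[i] %||% i,
                            accuracy = m$accuracy, precision = m$precision,
                            recall = m$recall, f1 = m$f1,
                            auroc = m$auroc, aucpr = m$aucpr,
                            n_test = length(fs$labels))
    pooled_y <- c(pooled_y, fs$labels); pooled_p <- c(pooled_p, fs$probabilities)
  }
  per_fold <- do.call(rbind, rows)
  num <- c("accuracy", "precision", "recall", "f1", "auroc", "aucpr")
  list(per_fold = per_fold,
       mean = colMeans(per_fold[num], na.rm = TRUE),
       sd = apply(per_fold[num], 2L, stats::sd, na.rm = TRUE),
       pooled = suppressWarnings(threshold_metrics(pooled_y, pooled_p)))
}

# Metrics tolerant of single-class test sets (possible under LODOCV/LOCOCV):
# ranking metrics are undefined there and reported as NA.
threshold_metrics_safe <- function(labels, probabilities, threshold = 0.5) {
  pred <- as.integer(probabilities > threshold)
  tp <- sum(pred == 1L & labels == 1L); fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L); fn <- sum(pred == 0L & labels == 1L)
  precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  list(accuracy = (tp + tn) / length(labels), precision = precision,
       recall = recall, f1 = f1, auroc = NA_real_, aucpr = NA_real_,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

fill_hp <- function(hp) {
  defaults <- list(hidden_units = 16L, lr_ftrl = 0.5, lr_adam = 0.003,
                   l1 = 0.02, l2 = 0.01)
  utils::modifyList(defaults, hp)
}

#' Nested cross-validation
#'
#' Outer folds give an unbiased performance estimate; inside each outer
#' training set a Bayesian hyperparameter search is run against the mean
#' accuracy of an inner k-fold CV, the best hyperparameters are refit on the
#' full outer training set, and the refit model is scored on the outer test
#' fold. No outer-test record ever enters its own inner loop (asserted).
#'
#' @param dataset A `refdnn_dataset`.
#' @param refs Reference panel.
#' @param space A [search_space()] for the five hyperparameters.
#' @param k_outer,k_inner Outer / inner fold counts (defaults 5 and 3).
#' @param n_calls Hyperparameter-search evaluations per outer fold.
#' @param seed Integer seed.
#' @param control A [refdnn_control()].
#' @return List with `per_fold` metrics, `mean`, `sd`, and `chosen` (the
#'   hyperparameters picked in each outer fold).
#' @export
nested_cv <- function(dataset, refs = NULL, space = search_space(),
                      k_outer = 5L, k_inner = 3L, n_calls = 20L, seed = 1L,
                      control = refdnn_control()) {
  outer_plan <- kfold_splits(dataset$records, k_outer,
                             seed = substream_seed(seed, "outer"))
  rows <- list(); chosen <- list()
  for (i in seq_along(outer_plan)) {
    tr_idx <- outer_plan[[i]]$train
    te_idx <- outer_plan[[i]]$test
    stopifnot(length(intersect(tr_idx, te_idx)) == 0L)
    inner_ds <- subset_dataset(dataset, tr_idx)
    obj <- function(hp) cv_objective(inner_ds, refs, hp, k = k_inner,
                                     seed = substream_seed(seed, paste0("inner", i)),
                                     control = control)
    bo <- bayes_optimize(obj, space, n_calls = n_calls,
                         seed = substream_seed(seed, paste0("bo", i)))
    ctrl <- control
    ctrl$seed <- substream_seed(seed, paste0("refit", i))
    fs <- fit_and_score(dataset, refs, fill_hp(bo$best), ctrl, tr_idx, te_idx)
    m <- suppressWarnings(threshold_metrics(fs$labels, fs$probabilities))
    rows[[i]] <- data.frame(fold = i, accuracy = m$accuracy,
                            precision = m$precision, recall = m$recall,
                            f1 = m$f1, auroc = m$auroc, aucpr = m$aucpr)
    chosen[[i]] <- bo$best
  }
  per_fold <- do.call(rbind, rows)
  num <- c("accuracy", "precision", "recall", "f1", "auroc", "aucpr")
  list(per_fold = per_fold, mean = colMeans(per_fold[num]),
       sd = apply(per_fold[num], 2L, stats::sd), chosen = chosen)
}
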