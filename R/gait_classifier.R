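# Distance-based kNN classification of strides with stratified five-fold
# cross-validation, intermediate-condition assignment, and the per-timepoint
# variability summary.

#' Label one stride by k nearest training strides
#'
#' Majority label among the `k` training strides at smallest distance.
#' Distance ties are broken by lower training index, making the rule
#' deterministic. `k` must be odd so a two-class vote cannot tie.
#'
#' @param distances Numeric vector of distances to each training stride.
#' @param train_labels Character vector of training labels, same length.
#' @param k Positive odd integer, `k <= length(distances)`.
#' @return The winning label (character scalar).
#' @export
knn_label <- function(distances, train_labels, k = 1L) {
  n <- length(distances)
  if (!n) stopf("empty distance row")
  if (length(train_labels) != n) stopf("labels/distances length mismatch")
  if (!is_count(k) || k > n) stopf("k must be a positive integer <= %d", n)
  if (k %% 2 == 0) stopf("k must be odd to avoid vote ties")
  nb <- order(distances, seq_len(n))[seq_len(k)]
  votes <- table(train_labels[nb])
  names(votes)[which.max(votes)]
}

#' Label one stride by smaller mean distance to each class
#'
#' Alternative decision rule to [knn_label()]: the stride is assigned to the
#' class whose training strides are closer on average (a nearest-centroid
#' rule in distance space). Ties go to the first class level encountered.
#'
#' @inheritParams knn_label
#' @return The winning label (character scalar).
#' @export
centroid_label <- function(distances, train_labels) {
  n <- length(distances)
  if (!n) stopf("empty distance row")
  if (length(train_labels) != n) stopf("labels/distances length mismatch")
  means <- tapply(distances, train_labels, mean)
  names(means)[which.min(means)]
}

#' Stratified fold plan for cross-validation
#'
#' Partitions `n_per_class` strides of each class into `n_folds` folds whose
#' sizes differ by at most one, after shuffling with `seed`. The same
#' permutation is applied to both classes (they are size-equalized upstream),
#' which keeps the plan exactly symmetric under swapping the class roles.
#'
#' @param n_per_class Strides per class (>= `n_folds`).
#' @param seed Integer seed; default 17.
#' @param n_folds Number of folds; default 5 (each fold holds 20% of each
#'   class as test data).
#' @return An object of class `fold_plan` with `assignment` (fold index per
#'   stride, in 1..n_folds), `n_folds`, `seed`.
#' @export
make_folds <- function(n_per_class, seed = 17L, n_folds = 5L) {
  if (!is_count(n_per_class) || n_per_class < n_folds) {
    stopf("need at least %d strides per class, got %s", n_folds, format(n_per_class))
  }
  perm <- with_seed(seed, sample.int(n_per_class))
  assignment <- integer(n_per_class)
  assignment[perm] <- rep_len(seq_len(n_folds), n_per_class)
  structure(list(assignment = assignment, n_folds = as.integer(n_folds),
                 seed = as.integer(seed)),
            class = "fold_plan")
}

#' F1 score
#'
#' `2 * precision * recall / (precision + recall)`, defined as 0 when both
#' precision and recall are 0. Errors if the truth contains no positive-class
#' instances (recall undefined).
#'
#' @param truth,predicted Equal-length label vectors.
#' @param positive The positive-class label (default `"POST_P"`).
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(truth, predicted, positive = "POST_P") {
  if (length(truth) != length(predicted)) stopf("label vectors differ in length")
  pos_true <- truth == positive
  pos_pred <- predicted == positive
  if (!any(pos_true)) stopf("no positive-class ('%s') instances in truth; recall undefined", positive)
  tp <- sum(pos_true & pos_pred)
  precision <- if (any(pos_pred)) tp / sum(pos_pred) else 0
  recall <- tp / sum(pos_true)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Cross-validated two-class stride classification
#'
#' Equalizes the two classes by truncating the larger one to the size of the
#' smaller (dropping the latest-collected strides), then runs stratified
#' `n_folds`-fold cross-validation: in each fold the held-out 20% of both
#' classes is labeled by [knn_label()] against the remaining 80%, using the
#' pairwise stride distance as the lone feature.
#'
#' @param pre [stride_set] for the baseline class (labelled `PRE_NP`).
#' @param post [stride_set] for the changed class (labelled `POST_P`).
#' @param metric `"euclidean"` or `"dtw"`.
#' @param config A [dtw_config].
#' @param k Odd neighbor count; default 1 (plain nearest neighbor).
#' @param seed Fold-shuffle seed; default 17.
#' @param n_folds Number of folds; default 5.
#' @param rule Decision rule: `"knn"` (default) or
#'   `"nearest-centroid-distance"` ([centroid_label()]).
#' @return A `classification_result`: per-fold and mean/SD per-class
#'   accuracies, pooled accuracy, and F1 with `POST_P` positive.
#' @export
cross_validate <- function(pre, post, metric = c("euclidean", "dtw"),
                           config = dtw_config(), k = 1L, seed = 17L,
                           n_folds = 5L,
                           rule = c("knn", "nearest-centroid-distance")) {
  metric <- match.arg(metric)
  rule <- match.arg(rule)
  stopifnot(inherits(pre, "stride_set"), inherits(post, "stride_set"))
  if (!n_strides(pre) || !n_strides(post)) stopf("both stride sets must be non-empty")
  if (pre$L != post$L) stopf("stride sets differ in normalized length")
  n <- min(n_strides(pre), n_strides(post))
  a <- pre$values[seq_len(n), , drop = FALSE]
  b <- post$values[seq_len(n), , drop = FALSE]
  keys_a <- apply(a, 1L, paste, collapse = "\r")
  keys_b <- apply(b, 1L, paste, collapse = "\r")
  if (any(keys_b %in% keys_a)) {
    warnf("identical strides appear in both classes; the classes are not distinguishable")
  }
  plan <- make_folds(n, seed = seed, n_folds = n_folds)
  fold_acc <- matrix(NA_real_, n_folds, 2L,
                     dimnames = list(NULL, c("PRE_NP", "POST_P")))
  pooled_truth <- character()
  pooled_pred <- character()
  for (f in seq_len(n_folds)) {
    te <- which(plan$assignment == f)
    tr <- which(plan$assignment != f)
    train_mat <- rbind(a[tr, , drop = FALSE], b[tr, , drop = FALSE])
    labels <- rep(c("PRE_NP", "POST_P"), each = length(tr))
    test_mat <- rbind(a[te, , drop = FALSE], b[te, , drop = FALSE])
    truth <- rep(c("PRE_NP", "POST_P"), each = length(te))
    dm <- pairwise_distances(test_mat, train_mat, metric = metric,
                             config = config, train_labels = labels)
    pred <- if (rule == "knn") {
      apply(dm$values, 1L, knn_label, train_labels = labels, k = k)
    } else {
      apply(dm$values, 1L, centroid_label, train_labels = labels)
    }
    fold_acc[f, "PRE_NP"] <- mean(pred[truth == "PRE_NP"] == "PRE_NP")
    fold_acc[f, "POST_P"] <- mean(pred[truth == "POST_P"] == "POST_P")
    pooled_truth <- c(pooled_truth, truth)
    pooled_pred <- c(pooled_pred, pred)
  }
  structure(
    list(metric = metric, k = as.integer(k),
         window = if (metric == "dtw") config$window else NULL,
         n_folds = as.integer(n_folds), seed = as.integer(seed),
         n_per_class = n,
         fold_accuracy = as.data.frame(cbind(fold = seq_len(n_folds), fold_acc)),
         accuracy_mean = colMeans(fold_acc),
         accuracy_sd = apply(fold_acc, 2L, stats::sd),
         pooled_accuracy = mean(pooled_truth == pooled_pred),
         f1 = f1_score(pooled_truth, pooled_pred, positive = "POST_P"),
         fractions = list()),
    class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> metric=%s k=%d folds=%d (n=%d/class)\n",
              x$metric, x$k, x$n_folds, x$n_per_class))
  cat(sprintf("  accuracy PRE_NP %.3f +/- %.3f | POST_P %.3f +/- %.3f | F1 %.3f\n",
              x$accuracy_mean[["PRE_NP"]], x$accuracy_sd[["PRE_NP"]],
              x$accuracy_mean[["POST_P"]], x$accuracy_sd[["POST_P"]], x$f1))
  for (cond in names(x$fractions)) {
    cat(sprintf("  %s: %.3f PRE_NP / %.3f POST_P\n", cond,
                x$fractions[[cond]][["PRE_NP"]], x$fractions[[cond]][["POST_P"]]))
  }
  invisible(x)
}

#' Assign an intermediate condition to the baseline or changed class
#'
#' Labels every stride of `target` (e.g. the mid-training or post-rest
#' condition) against the full equalized `PRE_NP`/`POST_P` training sets and
#' returns the two classified fractions. The fractions sum to exactly 1.
#'
#' @param target [stride_set] to classify.
#' @param pre_train,post_train Training [stride_set]s.
#' @inheritParams cross_validate
#' @return Named numeric vector `c(PRE_NP = ..., POST_P = ...)`.
#' @export
classify_condition <- function(target, pre_train, post_train,
                               metric = c("euclidean", "dtw"),
                               config = dtw_config(), k = 1L,
                               rule = c("knn", "nearest-centroid-distance")) {
  metric <- match.arg(metric)
  rule <- match.arg(rule)
  stopifnot(inherits(target, "stride_set"))
  if (!n_strides(target)) stopf("target stride set is empty")
  n <- min(n_strides(pre_train), n_strides(post_train))
  if (!n) stopf("both training sets must be non-empty")
  train_mat <- rbind(pre_train$values[seq_len(n), , drop = FALSE],
                     post_train$values[seq_len(n), , drop = FALSE])
  labels <- rep(c("PRE_NP", "POST_P"), each = n)
  dm <- pairwise_distances(target$values, train_mat, metric = metric,
                           config = config, train_labels = labels)
  pred <- if (rule == "knn") {
    apply(dm$values, 1L, knn_label, train_labels = labels, k = k)
  } else {
    apply(dm$values, 1L, centroid_label, train_labels = labels)
  }
  frac_pre <- mean(pred == "PRE_NP")
  c(PRE_NP = frac_pre, POST_P = 1 - frac_pre)
}

#' Ratio of two dispersion summaries, larger over smaller
#'
#' @param a,b Positive dispersion summaries (e.g. mean per-timepoint SDs).
#' @return `max(a, b) / min(a, b)`, always >= 1.
#' @export
f_ratio <- function(a, b) {
  if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0) {
    stopf("dispersion summaries must be positive and finite")
  }
  max(a, b) / min(a, b)
}

#' Per-timepoint variability summary for two conditions
#'
#' For each condition, the sample standard deviation (denominator `n - 1`)
#' across strides is taken at each of the `L` normalized timepoints and
#' averaged over timepoints. The F-value is the ratio of the two mean
#' per-timepoint SDs, larger over smaller, a dispersion-change summary
#' (not an ANOVA F statistic).
#'
#' @param pre,post [stride_set]s with the same `L` and at least 2 strides each.
#' @return Object of class `variance_summary` with `mean_sd_pre`,
#'   `mean_sd_post`, `f_value`.
#' @export
variance_summary <- function(pre, post) {
  stopifnot(inherits(pre, "stride_set"), inherits(post, "stride_set"))
  if (n_strides(pre) < 2L || n_strides(post) < 2L) {
    stopf("need at least 2 strides per condition to compute an SD")
  }
  if (pre$L != post$L) stopf("stride sets differ in normalized length")
  m_pre <- mean(apply(pre$values, 2L, stats::sd))
  m_post <- mean(apply(post$values, 2L, stats::sd))
  structure(list(mean_sd_pre = m_pre, mean_sd_post = m_post,
                 f_value = f_ratio(m_pre, m_post)),
            class = "variance_summary")
}

#' @export
print.variance_summary <- function(x, ...) {
  cat(sprintf("<variance_summary> mean per-timepoint SD: pre %.4f, post %.4f; F = %.4f\n",
              x$mean_sd_pre, x$mean_sd_post, x$f_value))
  invisible(x)
}
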