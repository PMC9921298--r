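# Stride-to-stride distance metrics: normed Euclidean and banded DTW with
# squared local errors. The DTW inner loop is compiled (src/dtw.cpp); the
# returned value is the raw accumulated cost Theta(n, m) -- any strictly
# monotone transform of a metric leaves nearest-neighbor decisions unchanged,
# so no path normalization is applied.

#' DTW configuration
#'
#' @param window Warping-window half-width: the maximum allowed index offset
#'   `|i - j|` when matching samples (a Sakoe-Chiba band, in samples). `Inf`
#'   disables the constraint. Default 10 samples, i.e. a 10% band at the
#'   default normalized stride length of 101.
#' @return An object of class `dtw_config`.
#' @export
dtw_config <- function(window = 10) {
  if (!is.numeric(window) || length(window) != 1L || is.na(window) || window < 0) {
    stopf("window must be a single non-negative number (or Inf)")
  }
  structure(list(window = window, local_metric = "squared"), class = "dtw_config")
}

#' Default warping window for a given stride length
#'
#' A 10% band: `ceiling(0.10 * L)` samples.
#'
#' @param L Normalized stride length.
#' @return Integer window size.
#' @export
default_dtw_window <- function(L) as.integer(ceiling(0.10 * L))

#' Normed Euclidean distance between two equal-length strides
#'
#' The root-mean-square pointwise difference
#' `sqrt(sum((x_i - y_i)^2) / n)`.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Non-negative scalar; zero iff `x == y`.
#' @export
euclidean_normed <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) {
    stopf("length mismatch: %d vs %d", length(x), length(y))
  }
  if (!length(x)) stopf("empty input")
  sqrt(mean((x - y)^2))
}

#' Dynamic time warping distance between two strides
#'
#' Accumulated squared-error cost of the optimal monotone, complete alignment
#' of `x` and `y` under a Sakoe-Chiba band of half-width `config$window`.
#' Every index of each sequence is matched, matching is monotonically
#' increasing, and the cost of matching `x_i` to `y_j` is `(x_i - y_j)^2`.
#'
#' @param x,y Non-empty numeric vectors (lengths may differ).
#' @param config A [dtw_config].
#' @return Non-negative scalar accumulated cost.
#' @export
dtw_distance <- function(x, y, config = dtw_config()) {
  stopifnot(inherits(config, "dtw_config"))
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x); m <- length(y)
  if (!n || !m) stopf("empty input")
  w <- config$window
  if (abs(n - m) > w) {
    stopf("warping band of width %g admits no path for lengths %d vs %d", w, n, m)
  }
  w_eff <- if (is.finite(w)) as.integer(w) else as.integer(max(n, m))
  dtw_cost_cpp(x, y, w_eff)
}

#' Pairwise distance matrix between two stride sets
#'
#' Computes the full test-by-train matrix of stride distances under one
#' metric; this matrix is the sole feature source for classification.
#'
#' @param test,train [stride_set] objects (or plain matrices, strides in
#'   rows) sharing the same normalized length `L`.
#' @param metric `"euclidean"` or `"dtw"`.
#' @param config A [dtw_config] (used for `metric = "dtw"`).
#' @param train_labels Optional per-column condition labels; defaults to the
#'   training set's condition replicated over its strides.
#' @return An object of class `distance_matrix`: list with `values`
#'   (n_test x n_train), `metric`, and `train_labels`.
#' @export
pairwise_distances <- function(test, train, metric = c("euclidean", "dtw"),
                               config = dtw_config(), train_labels = NULL) {
  metric <- match.arg(metric)
  a <- if (inherits(test, "stride_set")) test$values else as.matrix(test)
  b <- if (inherits(train, "stride_set")) train$values else as.matrix(train)
  if (!nrow(b)) stopf("training set is empty")
  if (!nrow(a)) stopf("test set is empty")
  if (ncol(a) != ncol(b)) stopf("stride length mismatch: %d vs %d", ncol(a), ncol(b))
  if (is.null(train_labels) && inherits(train, "stride_set")) {
    train_labels <- rep(train$condition, nrow(b))
  }
  if (!is.null(train_labels) && length(train_labels) != nrow(b)) {
    stopf("train_labels length (%d) != number of training strides (%d)",
          length(train_labels), nrow(b))
  }
  values <- if (metric == "euclidean") {
    L <- ncol(a)
    tb <- t(b)
    out <- matrix(0, nrow(a), nrow(b))
    for (i in seq_len(nrow(a))) {
      out[i, ] <- sqrt(colSums((tb - a[i, ])^2) / L)
    }
    out
  } else {
    w <- config$window
    w_eff <- if (is.finite(w)) as.integer(w) else as.integer(max(ncol(a), ncol(b)))
    dtw_pairwise_cpp(a, b, w_eff)
  }
  structure(list(values = values, metric = metric, train_labels = train_labels),
            class = "distance_matrix")
}
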