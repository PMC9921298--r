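# From raw tri-axial recording + foot-contact events to fixed-length
# magnitude strides.
#
# A stride (gait cycle) runs from one foot strike to the next strike of the
# same foot. Event times map to sample indices by floor(t * sample_rate), and
# stride windows are half-open [strike_k, strike_{k+1}), so consecutive
# strides partition the samples between the first and last strike exactly.

#' Segment a recording into strides at same-side foot strikes
#'
#' @param recording A [gyro_recording].
#' @param events A [gait_events] table.
#' @param side Which side's foot strikes delimit strides (`"pro"` by default:
#'   the sensor is worn on the prosthetic-side thigh).
#' @param max_duration_factor Optional stride-admission hook: drop strides
#'   whose duration exceeds this multiple of the median stride duration.
#'   `NULL` (default) applies no rejection.
#' @return List of `stride` objects (possibly empty if fewer than 2 strikes),
#'   each with `start_time`, `end_time`, `duration` (s) and `samples`
#'   (n x 3 matrix of raw angular velocities).
#' @export
segment_strides <- function(recording, events, side = "pro",
                            max_duration_factor = NULL) {
  stopifnot(inherits(recording, "gyro_recording"), inherits(events, "gait_events"))
  side <- match.arg(side, GAIT_SIDES)
  strikes <- events$time_s[events$side == side & events$event == "foot_strike"]
  strikes <- sort(strikes)
  if (length(strikes) < 2L) return(list())
  span <- recording_span(recording)
  eps <- 1e-9
  if (any(strikes < span[1] - eps | strikes > span[2] + eps)) {
    stopf("foot strike at t=%.4g s lies outside the recording span [%.4g, %.4g]",
          strikes[which(strikes < span[1] - eps | strikes > span[2] + eps)][1],
          span[1], span[2])
  }
  fs <- recording$sample_rate
  idx0 <- floor((strikes - recording$start_time) * fs)  # 0-based sample index
  strides <- vector("list", length(strikes) - 1L)
  for (k in seq_len(length(strikes) - 1L)) {
    if (idx0[k + 1L] <= idx0[k]) {
      stopf("degenerate stride: strikes at %.4g and %.4g s span no samples",
            strikes[k], strikes[k + 1L])
    }
    rows <- (idx0[k] + 1L):idx0[k + 1L]
    strides[[k]] <- structure(
      list(start_time = strikes[k], end_time = strikes[k + 1L],
           duration = strikes[k + 1L] - strikes[k],
           samples = recording$gyro[rows, , drop = FALSE]),
      class = "stride")
  }
  if (!is.null(max_duration_factor)) {
    dur <- vapply(strides, `[[`, numeric(1), "duration")
    strides <- strides[dur <= max_duration_factor * stats::median(dur)]
  }
  strides
}

#' Angular-velocity magnitude of a stride
#'
#' Per-sample Euclidean norm `sqrt(vx^2 + vy^2 + vz^2)` collapsing the three
#' gyroscope axes to a single non-negative signal.
#'
#' @param stride A `stride` from [segment_strides()], or an n x 3 numeric
#'   matrix of angular velocities.
#' @return Numeric vector of magnitudes, same length as the input.
#' @export
stride_magnitude <- function(stride) {
  m <- if (inherits(stride, "stride")) stride$samples else as.matrix(stride)
  if (!nrow(m)) stopf("stride is empty")
  if (!all(is.finite(m))) stopf("stride contains non-finite components")
  sqrt(rowSums(m^2))
}

#' Resample a signal to a fixed length over normalized stride time
#'
#' Interpolates `values` onto `L` points uniformly spanning normalized time
#' `[0, 1]`. With linear interpolation the first and last input values are
#' preserved exactly and the operation is idempotent at length `L`.
#'
#' @param values Numeric vector of length >= 2.
#' @param L Target length (integer >= 2); default 101, i.e. 0--100% of the
#'   gait cycle in 1% steps.
#' @param method `"linear"` (default) or `"cubic"` spline interpolation.
#' @return Numeric vector of length `L`.
#' @export
time_normalize <- function(values, L = 101L, method = c("linear", "cubic")) {
  method <- match.arg(method)
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stopf("cannot time-normalize a degenerate stride of %d sample(s)", n)
  if (!is_count(L) || L < 2) stopf("L must be an integer >= 2")
  x <- seq(0, 1, length.out = n)
  xout <- seq(0, 1, length.out = L)
  if (method == "linear") {
    stats::approx(x, values, xout = xout)$y
  } else {
    stats::spline(x, values, xout = xout, method = "fmm")$y
  }
}

#' Construct a stride set
#'
#' A stride set is the unit of input to the distance metrics and classifier:
#' a matrix of time-normalized angular-velocity magnitude strides (one row per
#' stride, `L` columns).
#'
#' @param values Numeric matrix, strides in rows, all of length `L`.
#' @param condition One of [GAIT_CONDITIONS].
#' @param durations Optional numeric vector of source stride durations (s).
#' @return An object of class `stride_set`.
#' @export
stride_set <- function(values, condition = "PRE_NP", durations = NULL) {
  values <- as.matrix(values)
  condition <- match.arg(condition, GAIT_CONDITIONS)
  if (nrow(values) && !all(is.finite(values))) stopf("stride set contains non-finite values")
  if (!is.null(durations) && length(durations) != nrow(values)) {
    stopf("durations length (%d) != number of strides (%d)", length(durations), nrow(values))
  }
  structure(list(values = values, condition = condition, L = ncol(values),
                 durations = durations),
            class = "stride_set")
}

#' @export
print.stride_set <- function(x, ...) {
  cat(sprintf("<stride_set> %s: %d strides x L=%d\n", x$condition,
              nrow(x$values), x$L))
  invisible(x)
}

#' Number of strides in a stride set
#' @param x A `stride_set`.
#' @return Integer count.
#' @export
n_strides <- function(x) nrow(x$values)

#' Build a normalized magnitude stride set from a recording
#'
#' Composes the preprocessing pipeline: segment at same-side foot strikes,
#' resample each of the three axes independently to length `L`, then take the
#' per-sample angular-velocity magnitude. (Resampling axes before the
#' magnitude, rather than after, follows the stated processing order; the two
#' differ only by interpolation error.)
#'
#' @inheritParams segment_strides
#' @inheritParams time_normalize
#' @return A [stride_set] with one row per detected gait cycle (zero rows if
#'   fewer than two strikes).
#' @export
build_stride_set <- function(recording, events, side = "pro", L = 101L,
                             method = c("linear", "cubic"),
                             max_duration_factor = NULL) {
  method <- match.arg(method)
  strides <- segment_strides(recording, events, side = side,
                             max_duration_factor = max_duration_factor)
  if (!length(strides)) {
    return(stride_set(matrix(numeric(), 0L, L), condition = recording$condition,
                      durations = numeric()))
  }
  vals <- t(vapply(strides, function(s) {
    ax <- apply(s$samples, 2L, time_normalize, L = L, method = method)
    sqrt(rowSums(ax^2))
  }, numeric(L)))
  stride_set(vals, condition = recording$condition,
             durations = vapply(strides, `[[`, numeric(1), "duration"))
}
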