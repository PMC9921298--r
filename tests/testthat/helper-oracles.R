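# Independent oracles and small fixture builders used across the suite.

# Brute-force DTW: minimum summed squared error over ALL monotone complete
# warping paths from (1,1) to (n,m), enumerated by depth-first search with
# steps (1,0), (0,1), (1,1). Exact for integer-valued inputs. Independent of
# the dynamic-programming implementation under test.
dtw_brute_force <- function(x, y) {
  n <- length(x); m <- length(y)
  rec <- function(i, j, acc) {
    acc <- acc + (x[i] - y[j])^2
    if (i == n && j == m) return(acc)
    best <- Inf
    if (i < n) best <- min(best, rec(i + 1L, j, acc))
    if (j < m) best <- min(best, rec(i, j + 1L, acc))
    if (i < n && j < m) best <- min(best, rec(i + 1L, j + 1L, acc))
    best
  }
  rec(1L, 1L, 0)
}

# Dense-grid double-support oracle: fraction of a fine time grid over the
# cycle during which both feet are in stance, from explicit stance intervals.
double_support_grid <- function(pro_iv, np_iv, cycle, n_grid = 2e5) {
  tt <- seq(cycle[1], cycle[2], length.out = n_grid + 1)[-(n_grid + 1)]
  in_stance <- function(iv, t) {
    out <- rep(FALSE, length(t))
    for (i in seq_len(nrow(iv))) out <- out | (t >= iv[i, 1] & t < iv[i, 2])
    out
  }
  100 * mean(in_stance(pro_iv, tt) & in_stance(np_iv, tt))
}

# A recording whose magnitude is exactly a given per-stride profile: the
# profile is written onto fixed direction cosines with no noise.
recording_from_profiles <- function(profiles, sample_rate = 100,
                                    condition = "PRE_NP") {
  u <- c(0.8, 0.5, 0.33); u <- u / sqrt(sum(u^2))
  m <- unlist(profiles, use.names = FALSE)
  gyro_recording(outer(m, u), sample_rate, condition = condition)
}

# Events with strikes of one side at the given times; foot offs are
# interleaved midway between strikes to satisfy the alternation invariant
# (segmentation only reads the strikes).
strike_events <- function(times, side = "pro") {
  times <- sort(times)
  if (!length(times)) {
    return(gait_events(data.frame(time_s = numeric(), side = character(),
                                  event = character())))
  }
  strikes <- data.frame(time_s = times, side = side, event = "foot_strike")
  if (length(times) < 2L) return(gait_events(strikes))
  offs <- data.frame(time_s = times[-length(times)] + diff(times) / 2,
                     side = side, event = "foot_off")
  ev <- rbind(strikes, offs)
  gait_events(ev[order(ev$time_s), ])
}

# A stride_set holding the given matrix directly.
as_stride_set <- function(mat, condition = "PRE_NP") {
  stride_set(as.matrix(mat), condition = condition)
}

# Two clearly separated Gaussian-stride classes drawn directly in normalized
# time (bypasses the session generator; used for classifier unit tests).
two_class_sets <- function(n = 30, L = 101, delta = 5, noise = 0.3, seed = 1) {
  phase <- seq(0, 1, length.out = L)
  base <- 10 * exp(-0.5 * ((phase - 0.5) / 0.1)^2)
  set.seed(seed)
  pre <- t(replicate(n, base + rnorm(L, 0, noise)))
  post <- t(replicate(n, base + delta * exp(-0.5 * ((phase - 0.3) / 0.1)^2) +
                        rnorm(L, 0, noise)))
  list(pre = as_stride_set(pre, "PRE_NP"), post = as_stride_set(post, "POST_P"))
}
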