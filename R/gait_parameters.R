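# Spatiotemporal and kinematic gait parameters from events, joint angles, and
# foot positions, plus the significance machinery that decides whether a
# participant's gait changed between conditions.

GAIT_PARAMETERS <- c("STANCE_TIME_PRO", "STANCE_TIME_NONPRO",
                     "STANCE_SYMMETRY_RATIO", "DOUBLE_SUPPORT_PCT",
                     "STEP_LENGTH_PRO", "STEP_LENGTH_NONPRO",
                     "KNEE_ROM_PRO", "KNEE_ROM_NONPRO",
                     "HIP_ROM_PRO", "HIP_ROM_NONPRO")

#' Per-stride stance times for one side
#'
#' Stance time of a foot strike is the time to the following same-side foot
#' off. A leading foot off (stance already underway at trial start) is
#' ignored; a trailing strike with no following off is skipped with a warning.
#'
#' @param events A [gait_events] table.
#' @param side `"pro"` or `"nonpro"`.
#' @return Numeric vector of stance times (s), with the corresponding strike
#'   times as the `"strike_times"` attribute.
#' @export
stance_time <- function(events, side = c("pro", "nonpro")) {
  side <- match.arg(side)
  ev <- events[events$side == side, ]
  ev <- ev[order(ev$time_s), ]
  if (nrow(ev) && ev$event[1] == "foot_off") ev <- ev[-1L, ]  # leading off
  if (!nrow(ev)) return(structure(numeric(), strike_times = numeric()))
  # after dropping the leading off, events strictly alternate S,O,S,O,...
  if (nrow(ev) %% 2 == 1L) {
    warnf("trailing foot strike at t=%.4g s has no foot off; cycle skipped", ev$time_s[nrow(ev)])
    ev <- ev[-nrow(ev), ]
  }
  strikes <- ev$time_s[ev$event == "foot_strike"]
  offs <- ev$time_s[ev$event == "foot_off"]
  structure(offs - strikes, strike_times = strikes)
}

#' Stance-time symmetry ratio
#'
#' Prosthetic over non-prosthetic stance time; 1.0 means symmetric, values
#' below 1 mean reduced prosthetic-side stance (the clinically typical
#' deficit).
#'
#' @param stance_pro,stance_nonpro Positive stance times (s); vectorized.
#' @return `stance_pro / stance_nonpro`.
#' @export
stance_symmetry_ratio <- function(stance_pro, stance_nonpro) {
  if (any(stance_pro <= 0) || any(stance_nonpro <= 0)) {
    stopf("stance times must be positive")
  }
  stance_pro / stance_nonpro
}

# stance intervals for one side as a 2-column matrix (start, end).
# A leading foot off opens an interval at -Inf (stance underway at trial
# start); a trailing strike closes at +Inf (foot still down at trial end).
stance_intervals <- function(events, side) {
  ev <- events[events$side == side, ]
  ev <- ev[order(ev$time_s), ]
  if (!nrow(ev)) return(matrix(numeric(), 0L, 2L))
  starts <- numeric(); ends <- numeric()
  if (ev$event[1] == "foot_off") {
    starts <- -Inf; ends <- ev$time_s[1]
    ev <- ev[-1L, ]
  }
  if (nrow(ev)) {
    strikes <- ev$time_s[ev$event == "foot_strike"]
    offs <- ev$time_s[ev$event == "foot_off"]
    if (length(strikes) > length(offs)) offs <- c(offs, Inf)
    starts <- c(starts, strikes)
    ends <- c(ends, offs)
  }
  cbind(start = starts, end = ends)
}

#' Double-support percentage of a gait cycle
#'
#' Fraction of the cycle `[cycle_start, cycle_end)` during which both feet
#' are simultaneously in stance, computed by intersecting the two sides'
#' stance intervals and clipping to the cycle, as a percentage of cycle
#' duration.
#'
#' @param events A [gait_events] table covering both sides.
#' @param cycle_start,cycle_end Cycle bounds in seconds (`end > start`).
#' @return Percentage in `[0, 100]`, or `NA` (with a warning) when one side
#'   has no stance interval overlapping the cycle.
#' @export
double_support_pct <- function(events, cycle_start, cycle_end) {
  if (cycle_end <= cycle_start) stopf("empty cycle interval")
  ip <- stance_intervals(events, "pro")
  inp <- stance_intervals(events, "nonpro")
  overlaps <- function(iv) nrow(iv) && any(pmin(iv[, 2], cycle_end) > pmax(iv[, 1], cycle_start))
  if (!overlaps(ip) || !overlaps(inp)) {
    warnf("no stance from one side overlaps the cycle [%.4g, %.4g); double support undefined",
          cycle_start, cycle_end)
    return(NA_real_)
  }
  total <- 0
  for (i in seq_len(nrow(ip))) {
    lo <- pmax(ip[i, 1], inp[, 1], cycle_start)
    hi <- pmin(ip[i, 2], inp[, 2], cycle_end)
    total <- total + sum(pmax(0, hi - lo))
  }
  100 * total / (cycle_end - cycle_start)
}

#' Per-step step lengths for one side
#'
#' Step length of side `s` at one of its foot strikes is the forward position
#' of foot `s` minus the forward position of the contralateral foot, both
#' looked up at the nearest sample to the strike instant. Strikes outside
#' either trace's span are skipped with a warning.
#'
#' @param positions Named list (`pro`, `nonpro`) of [foot_position_trace]s.
#' @param events A [gait_events] table.
#' @param side Side whose strikes define the steps.
#' @return Numeric vector of step lengths (m) with strike times as the
#'   `"strike_times"` attribute.
#' @export
step_length <- function(positions, events, side = c("pro", "nonpro")) {
  side <- match.arg(side)
  other <- setdiff(GAIT_SIDES, side)
  tr_s <- positions[[side]]; tr_o <- positions[[other]]
  stopifnot(inherits(tr_s, "foot_position_trace"), inherits(tr_o, "foot_position_trace"))
  strikes <- sort(events$time_s[events$side == side & events$event == "foot_strike"])
  lookup <- function(tr, t) {
    i <- round((t - tr$start_time) * tr$sample_rate) + 1
    if (i < 1 || i > length(tr$positions)) return(NA_real_)
    tr$positions[i]
  }
  vals <- numeric(0); kept <- numeric(0)
  for (t in strikes) {
    ps <- lookup(tr_s, t); po <- lookup(tr_o, t)
    if (is.na(ps) || is.na(po)) {
      warnf("strike at t=%.4g s outside position trace span; step skipped", t)
      next
    }
    vals <- c(vals, ps - po); kept <- c(kept, t)
  }
  structure(vals, strike_times = kept)
}

#' Range of motion of a joint angle within a cycle
#'
#' Max minus min of the angle over samples falling in `[start, end)`.
#'
#' @param trace An [angle_trace].
#' @param start,end Cycle bounds in seconds.
#' @return ROM in degrees (>= 0).
#' @export
range_of_motion <- function(trace, start, end) {
  stopifnot(inherits(trace, "angle_trace"))
  tt <- trace_time(trace)
  sel <- tt >= start & tt < end
  if (!any(sel)) stopf("no angle samples in [%.4g, %.4g)", start, end)
  diff(range(trace$values[sel]))
}

#' Per-stride gait parameters for every condition of a session
#'
#' Computes the ten common gait parameters, one sample per prosthetic-side
#' gait cycle, for each condition in the session: stance times (both sides),
#' stance-time symmetry ratio, double-support percentage, step lengths (both
#' sides), and knee/hip flexion-extension ROM (both sides).
#'
#' @param session A synthetic session from [generate_session()] or a session
#'   read with [read_session()]: a list with a `conditions` element whose
#'   entries hold `events`, `angles`, and `positions`.
#' @return Long data frame with columns `condition`, `parameter`,
#'   `stride_index`, `value`.
#' @export
session_parameters <- function(session) {
  rows <- list()
  joint_param <- c(HIP_PRO = "HIP_ROM_PRO", HIP_NONPRO = "HIP_ROM_NONPRO",
                   KNEE_PRO = "KNEE_ROM_PRO", KNEE_NONPRO = "KNEE_ROM_NONPRO")
  for (cond in names(session$conditions)) {
    cd <- session$conditions[[cond]]
    st_pro <- stance_time(cd$events, "pro")
    st_np <- stance_time(cd$events, "nonpro")
    strikes <- sort(cd$events$time_s[cd$events$side == "pro" &
                                       cd$events$event == "foot_strike"])
    n_cyc <- length(strikes) - 1L
    if (n_cyc < 1L) next
    n_use <- min(n_cyc, length(st_pro), length(st_np))
    add <- function(parameter, idx, value) {
      rows[[length(rows) + 1L]] <<- data.frame(
        condition = cond, parameter = parameter, stride_index = idx,
        value = value, stringsAsFactors = FALSE)
    }
    add("STANCE_TIME_PRO", seq_len(n_use), as.numeric(st_pro)[seq_len(n_use)])
    add("STANCE_TIME_NONPRO", seq_len(n_use), as.numeric(st_np)[seq_len(n_use)])
    add("STANCE_SYMMETRY_RATIO", seq_len(n_use),
        stance_symmetry_ratio(as.numeric(st_pro)[seq_len(n_use)],
                              as.numeric(st_np)[seq_len(n_use)]))
    ds <- vapply(seq_len(n_cyc), function(k) {
      double_support_pct(cd$events, strikes[k], strikes[k + 1L])
    }, numeric(1))
    add("DOUBLE_SUPPORT_PCT", seq_len(n_cyc), ds)
    if (!is.null(cd$positions)) {
      sl_pro <- step_length(cd$positions, cd$events, "pro")
      sl_np <- step_length(cd$positions, cd$events, "nonpro")
      add("STEP_LENGTH_PRO", seq_along(sl_pro), as.numeric(sl_pro))
      add("STEP_LENGTH_NONPRO", seq_along(sl_np), as.numeric(sl_np))
    }
    if (!is.null(cd$angles)) {
      for (j in names(joint_param)) {
        tr <- cd$angles[[j]]
        if (is.null(tr)) next
        rom <- vapply(seq_len(n_cyc), function(k) {
          range_of_motion(tr, strikes[k], strikes[k + 1L])
        }, numeric(1))
        add(joint_param[[j]], seq_len(n_cyc), rom)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(condition = character(), parameter = character(),
                      stride_index = integer(), value = numeric()))
  }
  do.call(rbind, rows)
}

#' Significance report across walking conditions
#'
#' For each gait parameter, runs a one-way ANOVA of per-stride values across
#' the walking conditions; where the omnibus test rejects at `alpha`, Tukey
#' HSD post-hoc comparisons identify which condition pairs differ. A
#' parameter is flagged `changed` when the `PRE_NP` vs `POST_P` pair is
#' significant; the participant's gait is deemed changed overall when at
#' least 50% of the testable parameters are flagged. Parameters with fewer
#' than 2 conditions of at least 3 samples are marked untestable and excluded
#' from the denominator.
#'
#' @param samples Long data frame with columns `condition`, `parameter`,
#'   `value` (e.g. from [session_parameters()]).
#' @param alpha Significance level; default 0.05.
#' @return An object of class `significance_report`: `parameters` (data frame
#'   with `parameter`, `n`, `testable`, `omnibus_p`, `omnibus_significant`,
#'   `pre_post_p`, `changed`), `pairwise` (named list of Tukey tables),
#'   `n_changed`, `n_testable`, `overall_changed`, `alpha`.
#' @export
significance_report <- function(samples, alpha = 0.05) {
  stopifnot(all(c("condition", "parameter", "value") %in% names(samples)))
  samples <- samples[is.finite(samples$value), ]
  params <- unique(samples$parameter)
  res <- data.frame(parameter = params, n = NA_integer_, testable = FALSE,
                    omnibus_p = NA_real_, omnibus_significant = FALSE,
                    pre_post_p = NA_real_, changed = FALSE,
                    stringsAsFactors = FALSE)
  pairwise <- list()
  for (i in seq_along(params)) {
    sub <- samples[samples$parameter == params[i], ]
    counts <- table(sub$condition)
    res$n[i] <- nrow(sub)
    if (sum(counts >= 3) < 2) next  # untestable
    res$testable[i] <- TRUE
    sub$condition <- factor(sub$condition,
                            levels = intersect(GAIT_CONDITIONS, names(counts)))
    fit <- stats::aov(value ~ condition, data = sub)
    p_omni <- summary(fit)[[1]][["Pr(>F)"]][1]
    res$omnibus_p[i] <- p_omni
    if (is.finite(p_omni) && p_omni < alpha) {
      res$omnibus_significant[i] <- TRUE
      tk <- stats::TukeyHSD(fit)$condition
      pairwise[[params[i]]] <- tk
      pair_names <- strsplit(rownames(tk), "-", fixed = TRUE)
      hit <- vapply(pair_names, function(p) setequal(p, c("PRE_NP", "POST_P")), logical(1))
      if (any(hit)) {
        res$pre_post_p[i] <- tk[which(hit)[1], "p adj"]
        res$changed[i] <- res$pre_post_p[i] < alpha
      }
    }
  }
  n_testable <- sum(res$testable)
  n_changed <- sum(res$changed)
  structure(list(parameters = res, pairwise = pairwise,
                 n_changed = n_changed, n_testable = n_testable,
                 overall_changed = n_testable > 0 && n_changed / n_testable >= 0.5,
                 alpha = alpha),
            class = "significance_report")
}

#' @export
print.significance_report <- function(x, ...) {
  cat(sprintf("<significance_report> %d/%d parameters changed (alpha=%g) -> overall %s\n",
              x$n_changed, x$n_testable, x$alpha,
              if (x$overall_changed) "CHANGED" else "not changed"))
  print(x$parameters[, c("parameter", "n", "testable", "omnibus_p", "pre_post_p", "changed")],
        row.names = FALSE)
  invisible(x)
}
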