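# Synthetic four-condition gait sessions: gyroscope signal, foot-contact
# events, joint angles and foot positions with per-stride ground truth.
#
# Each stride's angular-velocity magnitude is a baseline plus a sum of
# Gaussian bumps in normalized stride time; the changed-gait class shifts
# bump amplitudes/centers by a controllable offset, and intermediate
# conditions interpolate between the two waveforms. The magnitude is
# decomposed onto fixed direction cosines so that the per-sample norm
# recovers the waveform exactly before additive noise.

default_waveform <- function() {
  data.frame(center = c(0.12, 0.72), width = c(0.10, 0.09),
             amplitude = c(120, 260))
}

default_rom_means <- function() {
  matrix(c(40, 42, 52, 55,
           46, 46, 58, 60),
         nrow = 4L, dimnames = list(GAIT_JOINTS, c("pre", "post")))
}

default_step_means <- function() {
  matrix(c(0.58, 0.60,
           0.66, 0.66),
         nrow = 2L, dimnames = list(GAIT_SIDES, c("pre", "post")))
}

#' Configuration for a synthetic gait session
#'
#' Defaults emulate a single-session gait-training protocol: roughly 100--125
#' strides per condition at 100 Hz, a two-bump thigh-like angular-velocity
#' magnitude profile (a moderate early-stance bump and a dominant swing-phase
#' bump), a changed-gait class whose bump amplitudes and timings are offset
#' enough to make the two classes clearly separable, and intermediate
#' conditions blended between the two.
#'
#' @param n_strides_per_condition Strides per condition; `NULL` (default)
#'   draws one count per condition uniformly from 100--125.
#' @param sample_rate Sampling rate in Hz; default 100.
#' @param stride_duration_mean,stride_duration_sd Stride duration
#'   distribution (s), truncated at > 0.3 s; defaults 1.1 and 0.05.
#' @param waveform Data frame of Gaussian bump parameters (`center` in
#'   normalized time `[0, 1)`, `width`, `amplitude` in deg/s).
#' @param baseline Constant magnitude floor in deg/s; default 25.
#' @param class_shift List with per-bump `amplitude` (deg/s) and `center`
#'   offsets applied to the fully changed (`POST_P`) waveform.
#' @param shape_jitter List with `amplitude_sd` (deg/s) and `center_sd`:
#'   per-stride jitter of bump parameters.
#' @param additive_noise_sd Per-axis additive sensor noise SD in deg/s.
#' @param variance_ratio Multiplier on the changed class's stochastic SDs
#'   (shape jitter and additive noise); interpolated with the blend so that
#'   the post/pre mean per-timepoint SD ratio approximates this value.
#' @param mid_blend,postnp_blend Blend `lambda` in `[0, 1]` placing `MID_P` /
#'   `POST_NP` between the baseline (`0`) and changed (`1`) waveforms;
#'   defaults 0.75 (training largely, not fully, consolidated mid-session)
#'   and 1 (short-term retention after the rest).
#' @param stance_fraction Fraction of the cycle each foot is in stance;
#'   default 0.62.
#' @param phase_offset Contralateral phase lag as a fraction of the cycle;
#'   default 0.5.
#' @param rom_mean 4 x 2 matrix of joint ROM means (deg), rows
#'   [GAIT_JOINTS], columns `pre`/`post`.
#' @param rom_jitter_sd Per-stride ROM jitter SD (deg); default 2.
#' @param angle_base Named numeric of joint angle minima (deg).
#' @param step_length_mean 2 x 2 matrix of step-length means (m), rows
#'   `pro`/`nonpro`, columns `pre`/`post`.
#' @param step_jitter_sd Per-step jitter SD (m); default 0.02.
#' @param seed Root seed; all randomness flows from it through named
#'   substreams.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_strides_per_condition = NULL,
                         sample_rate = 100,
                         stride_duration_mean = 1.1,
                         stride_duration_sd = 0.05,
                         waveform = default_waveform(),
                         baseline = 25,
                         class_shift = list(amplitude = c(40, 60),
                                            center = c(0.02, -0.03)),
                         shape_jitter = list(amplitude_sd = 8, center_sd = 0.01),
                         additive_noise_sd = 6,
                         variance_ratio = 1,
                         mid_blend = 0.75,
                         postnp_blend = 1,
                         stance_fraction = 0.62,
                         phase_offset = 0.5,
                         rom_mean = default_rom_means(),
                         rom_jitter_sd = 2,
                         angle_base = c(HIP_PRO = -10, HIP_NONPRO = -10,
                                        KNEE_PRO = 0, KNEE_NONPRO = 0),
                         step_jitter_sd = 0.02,
                         step_length_mean = default_step_means(),
                         seed = 1L) {
  cfg <- list(n_strides_per_condition = n_strides_per_condition,
              sample_rate = sample_rate,
              stride_duration_mean = stride_duration_mean,
              stride_duration_sd = stride_duration_sd,
              waveform = waveform, baseline = baseline,
              class_shift = class_shift, shape_jitter = shape_jitter,
              additive_noise_sd = additive_noise_sd,
              variance_ratio = variance_ratio,
              mid_blend = mid_blend, postnp_blend = postnp_blend,
              stance_fraction = stance_fraction, phase_offset = phase_offset,
              rom_mean = rom_mean, rom_jitter_sd = rom_jitter_sd,
              angle_base = angle_base,
              step_length_mean = step_length_mean,
              step_jitter_sd = step_jitter_sd,
              seed = as.integer(seed))
  with(cfg, {
    if (!is.null(n_strides_per_condition) && !is_count(n_strides_per_condition)) {
      stopf("n_strides_per_condition must be NULL or a positive integer")
    }
    if (sample_rate <= 0) stopf("sample_rate must be positive")
    if (stride_duration_mean <= 0.3) stopf("stride_duration_mean must exceed 0.3 s")
    if (stride_duration_sd < 0 || shape_jitter$amplitude_sd < 0 ||
        shape_jitter$center_sd < 0 || additive_noise_sd < 0 ||
        rom_jitter_sd < 0 || step_jitter_sd < 0) {
      stopf("standard deviations must be non-negative")
    }
    if (variance_ratio <= 0) stopf("variance_ratio must be positive")
    if (mid_blend < 0 || mid_blend > 1 || postnp_blend < 0 || postnp_blend > 1) {
      stopf("blend parameters must lie in [0, 1]")
    }
    if (stance_fraction <= 0 || stance_fraction >= 1) {
      stopf("stance_fraction must lie strictly between 0 and 1")
    }
    if (phase_offset <= 0 || phase_offset >= 1) {
      stopf("phase_offset must lie strictly between 0 and 1")
    }
    if (length(class_shift$amplitude) != nrow(waveform) ||
        length(class_shift$center) != nrow(waveform)) {
      stopf("class_shift must provide one amplitude and one center offset per bump")
    }
  })
  structure(cfg, class = "synth_config")
}

# one condition: recording + events + angles + positions + per-cycle truth
generate_condition <- function(cfg, condition, lambda, n, seed) {
  with_seed(seed, {
    fs <- cfg$sample_rate
    sf <- cfg$stance_fraction
    po <- cfg$phase_offset
    scale <- 1 + lambda * (cfg$variance_ratio - 1)
    n_str <- n + 1L  # one spare stride of signal so late events stay in span

    # -- durations (truncated normal, > 0.3 s) --
    d <- rnorm(n_str, cfg$stride_duration_mean, cfg$stride_duration_sd)
    while (any(d <= 0.3)) {
      bad <- d <= 0.3
      d[bad] <- rnorm(sum(bad), cfg$stride_duration_mean, cfg$stride_duration_sd)
    }
    ns <- pmax(2L, as.integer(round(d * fs)))
    d_eff <- ns / fs
    starts0 <- cumsum(c(0L, ns))      # 0-based sample offsets, length n_str+1
    n_total <- starts0[n_str + 1L]

    # -- per-stride jittered bump parameters around the baseline shape --
    nb <- nrow(cfg$waveform)
    amp <- matrix(rep(cfg$waveform$amplitude, each = n_str), n_str, nb) +
      matrix(rnorm(n_str * nb, 0, cfg$shape_jitter$amplitude_sd), n_str, nb)
    cen <- matrix(rep(cfg$waveform$center, each = n_str), n_str, nb) +
      matrix(rnorm(n_str * nb, 0, cfg$shape_jitter$center_sd), n_str, nb)
    amp <- pmax(amp, 0)

    # The stride's waveform is the class-mean profile (class shift applied,
    # no jitter) plus a scaled stride-to-stride deviation field. Deviations
    # are the baseline waveform's response to the jittered bump parameters,
    # so the per-timepoint SD is the same for both classes up to the variance
    # multiplier: shape change and variability change stay decoupled.
    amp0 <- cfg$waveform$amplitude + lambda * cfg$class_shift$amplitude
    cen0 <- cfg$waveform$center + lambda * cfg$class_shift$center
    mag <- vector("list", n_str)
    for (k in seq_len(n_str)) {
      phase <- (seq_len(ns[k]) - 1) / ns[k]
      m0 <- rep(cfg$baseline, ns[k])    # class mean
      dev <- rep(0, ns[k])              # jitter response of the baseline shape
      for (bmp in seq_len(nb)) {
        w <- cfg$waveform$width[bmp]
        m0 <- m0 + amp0[bmp] * exp(-0.5 * ((phase - cen0[bmp]) / w)^2)
        dev <- dev + amp[k, bmp] * exp(-0.5 * ((phase - cen[k, bmp]) / w)^2) -
          cfg$waveform$amplitude[bmp] *
            exp(-0.5 * ((phase - cfg$waveform$center[bmp]) / w)^2)
      }
      mag[[k]] <- pmax(0, m0 + scale * dev)
    }
    m_all <- unlist(mag, use.names = FALSE)
    u <- c(0.8, 0.5, 0.33); u <- u / sqrt(sum(u^2))
    gyro <- outer(m_all, u) +
      matrix(rnorm(n_total * 3L, 0, cfg$additive_noise_sd * scale), ncol = 3L)
    rec <- gyro_recording(gyro, fs, participant_id = "synthetic",
                          condition = condition)

    # -- events: n cycles delimited by n+1 prosthetic-side strikes --
    t_strike_pro <- starts0[seq_len(n + 1L)] / fs
    t_off_pro <- t_strike_pro + sf * d_eff[seq_len(n + 1L)]
    t_strike_np <- t_strike_pro[seq_len(n)] + po * d_eff[seq_len(n)]
    t_off_np <- t_strike_np + sf * d_eff[seq_len(n)]
    ev <- rbind(
      data.frame(time_s = t_strike_pro, side = "pro", event = "foot_strike"),
      data.frame(time_s = t_off_pro, side = "pro", event = "foot_off"),
      data.frame(time_s = t_strike_np, side = "nonpro", event = "foot_strike"),
      data.frame(time_s = t_off_np, side = "nonpro", event = "foot_off"))
    ev <- ev[order(ev$time_s, ev$side, ev$event), ]
    rownames(ev) <- NULL
    events <- gait_events(ev)

    # -- joint angles: raised-cosine arc per stride reaching the target ROM --
    rom_target <- cfg$rom_mean[, "pre"] + lambda * (cfg$rom_mean[, "post"] - cfg$rom_mean[, "pre"])
    rom <- matrix(NA_real_, n_str, length(GAIT_JOINTS),
                  dimnames = list(NULL, GAIT_JOINTS))
    angles <- list()
    for (j in GAIT_JOINTS) {
      rom[, j] <- pmax(0, rnorm(n_str, rom_target[[j]], cfg$rom_jitter_sd))
      vals <- unlist(lapply(seq_len(n_str), function(k) {
        phase <- (seq_len(ns[k]) - 1) / ns[k]
        cfg$angle_base[[j]] + rom[k, j] * (1 - cos(2 * pi * phase)) / 2
      }), use.names = FALSE)
      angles[[j]] <- angle_trace(vals, fs, joint = j)
    }

    # -- foot positions: plant during stance, linear advance during swing --
    step_target <- cfg$step_length_mean[, "pre"] +
      lambda * (cfg$step_length_mean[, "post"] - cfg$step_length_mean[, "pre"])
    step_pro <- rnorm(n + 1L, step_target[["pro"]], cfg$step_jitter_sd)
    step_np <- rnorm(n, step_target[["nonpro"]], cfg$step_jitter_sd)
    plant_pro <- numeric(n + 1L)
    plant_np <- numeric(n)
    np_start <- -step_pro[1L]          # intact foot planted behind at t = 0
    prev_np <- np_start
    for (k in seq_len(n + 1L)) {
      plant_pro[k] <- prev_np + step_pro[k]
      if (k <= n) {
        plant_np[k] <- plant_pro[k] + step_np[k]
        prev_np <- plant_np[k]
      }
    }
    guard <- 2 / fs  # swing ends just before the strike so the plant is read exactly
    tt <- (seq_len(n_total) - 1) / fs
    knots_pro_t <- c(0, as.vector(rbind(t_off_pro[seq_len(n)],
                                        t_strike_pro[seq_len(n) + 1L] - guard)))
    knots_pro_p <- c(plant_pro[1L], as.vector(rbind(plant_pro[seq_len(n)],
                                                    plant_pro[seq_len(n) + 1L])))
    pos_pro <- stats::approx(knots_pro_t, knots_pro_p, xout = tt, rule = 2)$y
    knots_np_t <- c(0, as.vector(rbind(
      c(0, t_off_np[seq_len(n - 1L)]) + guard,  # still planted just after previous off
      t_strike_np - guard)))
    knots_np_p <- c(np_start, as.vector(rbind(c(np_start, plant_np[seq_len(n - 1L)]),
                                              plant_np)))
    # hold each plant through its stance: append off-time knots
    knots_np_t <- c(knots_np_t, t_off_np)
    knots_np_p <- c(knots_np_p, plant_np)
    ord <- order(knots_np_t)
    kt <- knots_np_t[ord]; kp <- knots_np_p[ord]
    keep <- !duplicated(kt)
    pos_np <- stats::approx(kt[keep], kp[keep], xout = tt, rule = 2)$y
    positions <- list(
      pro = foot_position_trace(pos_pro, fs, side = "pro"),
      nonpro = foot_position_trace(pos_np, fs, side = "nonpro"))

    truth <- data.frame(
      condition = condition, stride_index = seq_len(n), blend = lambda,
      duration = d_eff[seq_len(n)],
      stance_pro = sf * d_eff[seq_len(n)],
      stance_nonpro = sf * d_eff[seq_len(n)],
      step_pro = step_pro[seq_len(n)],
      step_nonpro = step_np,
      rom_HIP_PRO = rom[seq_len(n), "HIP_PRO"],
      rom_HIP_NONPRO = rom[seq_len(n), "HIP_NONPRO"],
      rom_KNEE_PRO = rom[seq_len(n), "KNEE_PRO"],
      rom_KNEE_NONPRO = rom[seq_len(n), "KNEE_NONPRO"],
      stringsAsFactors = FALSE)

    list(recording = rec, events = events, angles = angles,
         positions = positions, n_cycles = n, truth = truth)
  })
}

#' Generate a synthetic four-condition gait session
#'
#' Produces, per walking condition, a gyroscope recording, a gait-event
#' table, joint-angle traces, and foot-position traces, together with
#' per-stride ground truth. The baseline condition uses the configured
#' waveform unchanged; the changed condition applies the full class shift;
#' intermediate conditions interpolate with their blend parameter.
#' Deterministic for a fixed `config$seed`.
#'
#' @param config A [synth_config].
#' @param conditions Subset of [GAIT_CONDITIONS] to generate; default all four.
#' @return An object of class `synth_session`: `conditions` (named list of
#'   per-condition data), `truth` (per-stride ground-truth data frame),
#'   `config`.
#' @export
generate_session <- function(config = synth_config(),
                             conditions = GAIT_CONDITIONS) {
  stopifnot(inherits(config, "synth_config"))
  conditions <- match.arg(conditions, GAIT_CONDITIONS, several.ok = TRUE)
  lambda <- c(PRE_NP = 0, MID_P = config$mid_blend, POST_P = 1,
              POST_NP = config$postnp_blend)
  n_str <- if (is.null(config$n_strides_per_condition)) {
    with_seed(substream_seed(config$seed, "n_strides"),
              sample(100:125, length(GAIT_CONDITIONS), replace = TRUE))
  } else {
    rep(config$n_strides_per_condition, length(GAIT_CONDITIONS))
  }
  names(n_str) <- GAIT_CONDITIONS
  out <- list()
  for (cond in conditions) {
    out[[cond]] <- generate_condition(
      config, cond, lambda[[cond]], n_str[[cond]],
      substream_seed(config$seed, paste0("condition_", cond)))
  }
  truth <- do.call(rbind, lapply(out, `[[`, "truth"))
  rownames(truth) <- NULL
  structure(list(conditions = out, truth = truth, config = config),
            class = "synth_session")
}

#' @export
print.synth_session <- function(x, ...) {
  cat("<synth_session>\n")
  for (cond in names(x$conditions)) {
    cat(sprintf("  %s: %d cycles, %d samples @ %g Hz\n", cond,
                x$conditions[[cond]]$n_cycles,
                nrow(x$conditions[[cond]]$recording$gyro),
                x$conditions[[cond]]$recording$sample_rate))
  }
  invisible(x)
}

#' Generate a no-change control session
#'
#' Delegates to [generate_session()] with the class shift zeroed, the
#' variance ratio set to 1, and the changed-class kinematic and step-length
#' means reset to baseline, emulating a session in which no intervention
#' alters the gait. Ground-truth blends are reported as 0 for every
#' condition.
#'
#' @param config A [synth_config]; its class-contrast fields are overridden.
#' @return A `synth_session`.
#' @export
generate_no_change_session <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  config$class_shift$amplitude[] <- 0
  config$class_shift$center[] <- 0
  config$variance_ratio <- 1
  config$rom_mean[, "post"] <- config$rom_mean[, "pre"]
  config$step_length_mean[, "post"] <- config$step_length_mean[, "pre"]
  session <- generate_session(config)
  session$truth$blend <- 0
  session
}

#' Write a session's files to a directory
#'
#' Writes, per condition, `gyro_<condition>.csv`, `events_<condition>.csv`,
#' `angles_<condition>.csv`, and `positions_<condition>.csv` in the package's
#' CSV dialects, plus `truth.csv` when ground truth is present.
#'
#' @param session A `synth_session` (or compatible list).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cond in names(session$conditions)) {
    cd <- session$conditions[[cond]]
    write_gyro_csv(cd$recording, file.path(dir, sprintf("gyro_%s.csv", cond)))
    write_events_csv(cd$events, file.path(dir, sprintf("events_%s.csv", cond)))
    if (!is.null(cd$angles)) {
      write_angles_csv(cd$angles, file.path(dir, sprintf("angles_%s.csv", cond)))
    }
    if (!is.null(cd$positions)) {
      write_positions_csv(cd$positions, file.path(dir, sprintf("positions_%s.csv", cond)))
    }
  }
  if (!is.null(session$truth)) {
    utils::write.csv(session$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read a session from a directory of CSV files
#'
#' Companion to [write_session()]: reads whichever conditions have a
#' `gyro_<condition>.csv` / `events_<condition>.csv` pair, plus optional
#' angle and position files.
#'
#' @param dir Directory containing the session files.
#' @param sample_rate Declared gyroscope sampling rate in Hz.
#' @param participant_id Participant identifier for the recordings.
#' @return A session list compatible with [run_report()] and
#'   [session_parameters()].
#' @export
read_session <- function(dir, sample_rate = 100, participant_id = "unknown") {
  out <- list()
  for (cond in GAIT_CONDITIONS) {
    gpath <- file.path(dir, sprintf("gyro_%s.csv", cond))
    epath <- file.path(dir, sprintf("events_%s.csv", cond))
    if (!file.exists(gpath) || !file.exists(epath)) next
    cd <- list(
      recording = read_gyro_csv(gpath, participant_id = participant_id,
                                condition = cond, sample_rate = sample_rate),
      events = read_events_csv(epath))
    apath <- file.path(dir, sprintf("angles_%s.csv", cond))
    ppath <- file.path(dir, sprintf("positions_%s.csv", cond))
    if (file.exists(apath)) cd$angles <- read_angles_csv(apath)
    if (file.exists(ppath)) cd$positions <- read_positions_csv(ppath)
    strikes <- cd$events$time_s[cd$events$side == "pro" &
                                  cd$events$event == "foot_strike"]
    cd$n_cycles <- max(0L, length(strikes) - 1L)
    out[[cond]] <- cd
  }
  if (!length(out)) stopf("no condition files found under %s", dir)
  structure(list(conditions = out, truth = NULL, config = NULL),
            class = "synth_session")
}
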