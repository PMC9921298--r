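make_events <- function(...) gait_events(rbind(...))
row_ev <- function(t, side, event) data.frame(time_s = t, side = side, event = event)

test_that("stance times pair each strike with the following same-side off", {
  ev <- make_events(row_ev(0.0, "pro", "foot_strike"), row_ev(0.62, "pro", "foot_off"))
  expect_equal(as.numeric(stance_time(ev, "pro")), 0.62)

  ev2 <- make_events(row_ev(0.0, "pro", "foot_strike"), row_ev(0.6, "pro", "foot_off"),
                     row_ev(1.0, "pro", "foot_strike"), row_ev(1.6, "pro", "foot_off"))
  expect_equal(as.numeric(stance_time(ev2, "pro")), c(0.6, 0.6))

  # a leading off (stance underway at trial start) is ignored
  ev3 <- make_events(row_ev(0.1, "pro", "foot_off"), row_ev(0.5, "pro", "foot_strike"),
                     row_ev(1.1, "pro", "foot_off"))
  expect_equal(as.numeric(stance_time(ev3, "pro")), 0.6)

  # a trailing strike is skipped with a warning
  ev4 <- make_events(row_ev(0.0, "pro", "foot_strike"), row_ev(0.6, "pro", "foot_off"),
                     row_ev(1.0, "pro", "foot_strike"))
  expect_warning(st <- stance_time(ev4, "pro"), "trailing")
  expect_equal(as.numeric(st), 0.6)
})

test_that("stance symmetry ratio is directional and reciprocal", {
  expect_equal(stance_symmetry_ratio(0.6, 0.6), 1.0)
  expect_equal(stance_symmetry_ratio(0.5, 0.625), 0.8)
  expect_equal(stance_symmetry_ratio(0.625, 0.5), 1.25)
  expect_error(stance_symmetry_ratio(0, 0.5), "positive")
  set.seed(31)
  a <- runif(20, 0.4, 0.9); b <- runif(20, 0.4, 0.9)
  expect_equal(stance_symmetry_ratio(a, b) * stance_symmetry_ratio(b, a),
               rep(1, 20))
})

test_that("double support intersects the two sides' stance intervals", {
  # pro stance [0, 0.65]; nonpro stances [-0.35, 0.15] and [0.5, 1.15];
  # cycle [0, 1] -> overlap 0.15 + 0.15 = 0.30 -> 30%
  ev <- make_events(
    row_ev(0.00, "pro", "foot_strike"), row_ev(0.65, "pro", "foot_off"),
    row_ev(0.15, "nonpro", "foot_off"),  # leading off: stance since before 0
    row_ev(0.50, "nonpro", "foot_strike"), row_ev(1.15, "nonpro", "foot_off"))
  got <- double_support_pct(ev, 0, 1)
  expect_equal(got, 30.0, tolerance = 1e-9)
  # dense-grid oracle agrees
  oracle <- double_support_grid(matrix(c(0, 0.65), 1),
                                matrix(c(-0.35, 0.15, 0.5, 1.15), 2, byrow = TRUE),
                                c(0, 1))
  expect_equal(got, oracle, tolerance = 0.02)

  # instantaneous transfer: off exactly at the contralateral strike -> 0%
  ev2 <- make_events(
    row_ev(0.0, "pro", "foot_strike"), row_ev(0.5, "pro", "foot_off"),
    row_ev(0.5, "nonpro", "foot_strike"), row_ev(1.0, "nonpro", "foot_off"))
  expect_equal(double_support_pct(ev2, 0, 1), 0)

  # both feet down throughout -> 100%
  ev3 <- make_events(row_ev(-0.2, "pro", "foot_strike"),
                     row_ev(-0.1, "nonpro", "foot_strike"))
  expect_equal(double_support_pct(ev3, 0, 1), 100)

  # missing contralateral stance in the cycle -> NA with a warning
  ev4 <- make_events(row_ev(0.0, "pro", "foot_strike"), row_ev(0.6, "pro", "foot_off"))
  expect_warning(na <- double_support_pct(ev4, 0, 1), "undefined")
  expect_true(is.na(na))
})

test_that("double- and single-support durations partition the cycle", {
  # randomized stance layouts against the dense-grid oracle
  set.seed(32)
  for (rep in 1:10) {
    d <- runif(1, 0.9, 1.3)
    sf <- runif(1, 0.55, 0.7)
    po <- runif(1, 0.4, 0.6)
    strikes <- cumsum(c(0, d, d, d))
    df <- rbind(
      data.frame(time_s = strikes, side = "pro", event = "foot_strike"),
      data.frame(time_s = strikes + sf * d, side = "pro", event = "foot_off"),
      data.frame(time_s = strikes + po * d, side = "nonpro", event = "foot_strike"),
      data.frame(time_s = strikes + (po + sf) * d, side = "nonpro", event = "foot_off"))
    ev <- gait_events(df[order(df$time_s), ])
    cyc <- c(strikes[2], strikes[3])
    ds <- double_support_pct(ev, cyc[1], cyc[2])
    pro_iv <- cbind(strikes, strikes + sf * d)
    np_iv <- cbind(strikes + po * d, strikes + (po + sf) * d)
    expect_equal(ds, double_support_grid(pro_iv, np_iv, cyc), tolerance = 0.05)
    # both-feet-down time equals stance overlap: with both sides in stance a
    # fraction sf of the cycle, total support partitions as
    # single = 2 * (sf - ds) and no-foot = 1 - 2 * sf + ds of the cycle
    no_foot <- 1 - 2 * sf + ds / 100
    expect_gte(no_foot, -1e-9)
    expect_equal((ds / 100) + 2 * (sf - ds / 100) + no_foot, 1, tolerance = 1e-9)
  }
})

test_that("step length is the inter-foot forward distance at the strike", {
  fs <- 100
  tt <- seq(0, 2, by = 1 / fs)
  pos <- list(pro = foot_position_trace(rep(1.30, length(tt)), fs, "pro"),
              nonpro = foot_position_trace(rep(0.65, length(tt)), fs, "nonpro"))
  ev <- make_events(row_ev(1.0, "pro", "foot_strike"))
  expect_equal(as.numeric(step_length(pos, ev, "pro")), 0.65)

  # feet level -> 0
  pos2 <- list(pro = foot_position_trace(rep(1, length(tt)), fs, "pro"),
               nonpro = foot_position_trace(rep(1, length(tt)), fs, "nonpro"))
  expect_equal(as.numeric(step_length(pos2, ev, "pro")), 0)

  # strike outside the trace span is skipped with a warning
  ev2 <- make_events(row_ev(5.0, "pro", "foot_strike"))
  expect_warning(sl <- step_length(pos, ev2, "pro"), "skipped")
  expect_length(sl, 0L)
})

test_that("range of motion is max minus min and shift-invariant", {
  fs <- 100
  tt <- seq(0, 1, by = 1 / fs)
  tr <- angle_trace(30 * sin(2 * pi * tt), fs, "KNEE_PRO")
  expect_equal(range_of_motion(tr, 0, 1), 60, tolerance = 1e-2)
  expect_equal(range_of_motion(angle_trace(rep(12, 50), fs, "HIP_PRO"), 0, 0.5), 0)
  saw <- angle_trace(seq(10, 70, length.out = 101), fs, "KNEE_NONPRO")
  expect_equal(range_of_motion(saw, 0, 1.01), 60)
  shifted <- angle_trace(tr$values + 17.3, fs, "KNEE_PRO")
  expect_equal(range_of_motion(shifted, 0, 1), range_of_motion(tr, 0, 1))
  expect_error(range_of_motion(tr, 5, 6), "no angle samples")
})

test_that("significance report flags huge shifts and applies the 50% rule", {
  set.seed(33)
  n <- 100
  conds <- rep(GAIT_CONDITIONS, each = n)
  # one parameter shifted by 5 pooled SDs between PRE_NP and POST_P
  shifted <- rnorm(4 * n) + ifelse(conds %in% c("POST_P", "POST_NP"), 5, 0)
  flat <- rnorm(4 * n)
  samples <- rbind(
    data.frame(condition = conds, parameter = "STEP_LENGTH_PRO", value = shifted),
    data.frame(condition = conds, parameter = "STANCE_TIME_PRO", value = flat))
  rep1 <- significance_report(samples)
  pars <- rep1$parameters
  expect_true(pars$changed[pars$parameter == "STEP_LENGTH_PRO"])
  expect_false(pars$changed[pars$parameter == "STANCE_TIME_PRO"])
  # 1 of 2 testable parameters changed -> >= 50% -> overall changed
  expect_true(rep1$overall_changed)

  # untestable parameters are excluded from the denominator
  tiny <- data.frame(condition = c("PRE_NP", "POST_P"), parameter = "KNEE_ROM_PRO",
                     value = c(1, 2))
  rep2 <- significance_report(rbind(samples, tiny))
  expect_false(rep2$parameters$testable[rep2$parameters$parameter == "KNEE_ROM_PRO"])
  expect_equal(rep2$n_testable, 2L)

  # power at a huge effect: flagged in (nearly) every replicate
  hits <- vapply(1:20, function(r) {
    v <- rnorm(4 * n) + ifelse(conds == "POST_P", 5, 0)
    s <- data.frame(condition = conds, parameter = "HIP_ROM_PRO", value = v)
    significance_report(s)$parameters$changed[1]
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("session parameters recover the generator's ground truth", {
  cfg <- synth_config(n_strides_per_condition = 60, seed = 41)
  s <- generate_session(cfg, conditions = c("PRE_NP", "POST_P"))
  params <- session_parameters(s)
  truth <- s$truth
  for (cond in c("PRE_NP", "POST_P")) {
    tr <- truth[truth$condition == cond, ]
    get <- function(p) params$value[params$condition == cond & params$parameter == p]
    n <- nrow(tr)
    # per-stride agreement for stance and step (first n cycles)
    expect_equal(get("STANCE_TIME_PRO")[seq_len(n)], tr$stance_pro, tolerance = 1e-9)
    expect_equal(get("STANCE_TIME_NONPRO")[seq_len(n)], tr$stance_nonpro, tolerance = 1e-9)
    expect_equal(get("STEP_LENGTH_PRO")[seq_len(n)], tr$step_pro, tolerance = 1e-6)
    expect_equal(get("STEP_LENGTH_NONPRO")[seq_len(n)], tr$step_nonpro, tolerance = 1e-6)
    # ROM per cycle agrees with the jittered per-stride target
    expect_equal(get("HIP_ROM_PRO")[seq_len(n)], tr$rom_HIP_PRO, tolerance = 1e-2)
    expect_equal(get("KNEE_ROM_NONPRO")[seq_len(n)], tr$rom_KNEE_NONPRO, tolerance = 1e-2)
  }
  # means recover the configured targets within 3 standard errors
  pre <- truth[truth$condition == "PRE_NP", ]
  se <- cfg$step_jitter_sd / sqrt(nrow(pre))
  expect_lt(abs(mean(pre$step_pro) - cfg$step_length_mean["pro", "pre"]), 3 * se)
  se_rom <- cfg$rom_jitter_sd / sqrt(nrow(pre))
  expect_lt(abs(mean(pre$rom_HIP_PRO) - cfg$rom_mean["HIP_PRO", "pre"]), 3 * se_rom)
})
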