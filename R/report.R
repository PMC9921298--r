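# End-to-end session report: preprocessing -> distances -> classification ->
# variance summary -> gait-parameter significance -> mean +/- SD curves.

#' Run the full gait-change analysis on one session
#'
#' Builds normalized magnitude stride sets for every condition present,
#' cross-validates the `PRE_NP` vs `POST_P` classifier under the requested
#' metrics, assigns the intermediate conditions (`MID_P`, `POST_NP`) to one
#' of the two classes when they are present (absent conditions are marked as
#' such, not errors), summarizes per-timepoint stride variability, tests the
#' common gait parameters across conditions, and extracts per-condition mean
#' +/- SD magnitude curves. The bundle is fully reproducible from the logged
#' configuration and seed.
#'
#' @param session A session from [generate_session()] or [read_session()].
#' @param metrics Character vector, subset of `c("euclidean", "dtw")`.
#' @param k Odd neighbor count for the classifier; default 1.
#' @param dtw_window Warping-window half-width in samples; default
#'   `default_dtw_window(L)`.
#' @param L Normalized stride length; default 101.
#' @param alpha Significance level for the parameter tests; default 0.05.
#' @param seed Fold-shuffle seed; default 17.
#' @param side Side whose strikes segment strides; default `"pro"`.
#' @param outdir Optional output directory; when given, writes
#'   `classification_<metric>.json`, `variance.json`, `significance.json`,
#'   `curves.csv`, and `run_config.json`.
#' @return A list (invisibly when writing) with elements `classification`
#'   (named by metric), `variance`, `significance`, `curves`, and `config`.
#' @export
run_report <- function(session, metrics = c("euclidean", "dtw"), k = 1L,
                       dtw_window = NULL, L = 101L, alpha = 0.05, seed = 17L,
                       side = "pro", outdir = NULL) {
  metrics <- match.arg(metrics, c("euclidean", "dtw"), several.ok = TRUE)
  if (is.null(dtw_window)) dtw_window <- default_dtw_window(L)
  cfg <- dtw_config(dtw_window)
  have <- names(session$conditions)
  need <- c("PRE_NP", "POST_P")
  if (!all(need %in% have)) {
    stopf("session must contain PRE_NP and POST_P (found: %s)",
          paste(have, collapse = ", "))
  }
  sets <- lapply(session$conditions, function(cd) {
    build_stride_set(cd$recording, cd$events, side = side, L = L)
  })

  classification <- list()
  for (metric in metrics) {
    res <- cross_validate(sets$PRE_NP, sets$POST_P, metric = metric,
                          config = cfg, k = k, seed = seed)
    for (cond in c("MID_P", "POST_NP")) {
      res$fractions[[cond]] <- if (cond %in% have && n_strides(sets[[cond]]) > 0) {
        classify_condition(sets[[cond]], sets$PRE_NP, sets$POST_P,
                           metric = metric, config = cfg, k = k)
      } else {
        c(PRE_NP = NA_real_, POST_P = NA_real_)  # condition absent
      }
    }
    classification[[metric]] <- res
  }

  variance <- variance_summary(sets$PRE_NP, sets$POST_P)

  params <- session_parameters(session)
  significance <- if (nrow(params)) significance_report(params, alpha = alpha) else NULL

  curves <- do.call(rbind, lapply(names(sets), function(cond) {
    v <- sets[[cond]]$values
    if (!nrow(v)) return(NULL)
    data.frame(condition = cond, timepoint = seq_len(ncol(v)) - 1L,
               mean = colMeans(v), sd = apply(v, 2L, stats::sd),
               stringsAsFactors = FALSE)
  }))
  rownames(curves) <- NULL

  run_config <- list(metrics = metrics, k = as.integer(k),
                     dtw_window = dtw_window, L = as.integer(L),
                     alpha = alpha, seed = as.integer(seed), side = side,
                     conditions_present = have)
  bundle <- list(classification = classification, variance = variance,
                 significance = significance, curves = curves,
                 config = run_config)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (metric in names(classification)) {
      write_result_json(classification[[metric]],
                        file.path(outdir, sprintf("classification_%s.json", metric)))
    }
    jsonlite::write_json(unclass(variance), file.path(outdir, "variance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(significance)) {
      sig <- list(parameters = significance$parameters,
                  n_changed = significance$n_changed,
                  n_testable = significance$n_testable,
                  overall_changed = significance$overall_changed,
                  alpha = significance$alpha)
      jsonlite::write_json(sig, file.path(outdir, "significance.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           dataframe = "columns", na = "null")
    }
    utils::write.csv(curves, file.path(outdir, "curves.csv"), row.names = FALSE)
    jsonlite::write_json(run_config, file.path(outdir, "run_config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(bundle))
  }
  bundle
}
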