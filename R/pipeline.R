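# End-to-end orchestration: signals -> coupling -> waves -> motion ->
# cohort statistics, with deterministic TSV/JSON outputs.

#' Pipeline configuration
#'
#' Aggregates every analysis constant with its study default: the
#' 0.01-0.1 Hz infra-slow band, +/-16 s lag grid with the +3.2 s coupling
#' lag, 70 positional bins with the 80% involvement rule and the
#' 0.01/0.05 p cutoffs, and the menopause-age split at 51 with three
#' ordered groups.
#'
#' @param ... overrides of any default field (unknown names error).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    bandpass_low_hz = 0.01, bandpass_high_hz = 0.1,
    max_lag_seconds = 16, coupling_lag_seconds = 3.2,
    n_bins = 70L, min_involvement = 0.8, p_wave = 0.01, p_none = 0.05,
    wave_window_seconds = 8,
    split_age = 51, n_groups = 3L,
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown pipeline_config field(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$bandpass_low_hz > 0,
            cfg$bandpass_low_hz < cfg$bandpass_high_hz,
            cfg$min_involvement >= 0, cfg$min_involvement <= 1,
            cfg$p_wave > 0, cfg$p_wave <= cfg$p_none, cfg$p_none < 1)
  class(cfg) <- "pipeline_config"
  cfg
}

# 32-bit FNV-1a hash of a string, as hex; stamps outputs with the config.
# Arithmetic is split into 16-bit halves so every product stays exact in
# doubles.
fnv1a_hex <- function(s) {
  bytes <- as.integer(charToRaw(s))
  prime <- 16777619
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    lo <- bitwXor(as.integer(lo), b)
    h <- (lo * prime + ((hi * prime) %% 65536) * 65536) %% 2^32
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

config_hash <- function(cfg) {
  fnv1a_hex(paste(deparse(unclass(cfg)), collapse = ""))
}

#' Run the full analysis pipeline on a cohort
#'
#' Executes the stages in order for every subject: per-run bandpass and
#' z-normalization, gBOLD extraction and amplitude, gBOLD-CSF coupling
#' from run-averaged cross-correlation functions, PG-binned wave
#' detection and classification, framewise displacement, then the cohort
#' statistics (group assignment, age residualization, earlier-vs-later
#' t-tests on coupling and amplitude, age ANOVA, ordinal trend tests,
#' memory-score comparison and the wave-count/memory correlation in the
#' earlier group). A subject with a missing (`NULL`) run is averaged over
#' the remaining runs and logged; any stage failure aborts with the stage
#' and offending subject named.
#'
#' @param cohort a [simulate_cohort()] result (imaging included), or a
#'   compatible list with `geometry`, `phenotypes`, `subjects`.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for TSV/JSON outputs; created if
#'   needed. `NULL` skips writing.
#' @return Invisibly, a list with `metrics` (per-subject data.frame),
#'   `grouped` (the [assign_groups()] table joined with metrics),
#'   `stats` (named list of [stat_result()]), `group_ccf`, `log`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(),
                         out_dir = NULL) {
  stage <- function(name, subject, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed for subject ", subject, ": ",
           conditionMessage(e), call. = FALSE))
  }
  geometry <- cohort$geometry
  binning <- bin_by_gradient(geometry, config$n_bins)
  log <- list(config_hash = config_hash(config), seed = config$seed,
              n_subjects = length(cohort$subjects), runs_read = 0L,
              runs_missing = 0L, segments_found = 0L,
              events_per_label = stats::setNames(
                as.list(integer(length(wave_labels))), wave_labels))
  subj_rows <- list()
  subj_ccfs <- list()
  for (s in cohort$subjects) {
    sid <- s$subject_id
    runs <- Filter(Negate(is.null), s$runs)
    log$runs_missing <- log$runs_missing + (length(s$runs) - length(runs))
    log$runs_read <- log$runs_read + length(runs)
    if (length(runs) == 0L)
      stop("stage 'signals' failed for subject ", sid, ": no runs")
    amp <- numeric(0)
    pairs <- list()
    counts <- stats::setNames(integer(length(wave_labels)), wave_labels)
    mfd <- numeric(0)
    total_dur <- 0
    for (r in runs) {
      prep <- stage("signals", sid, {
        filtered <- znorm(bandpass(r$run, config$bandpass_low_hz,
                                   config$bandpass_high_hz))
        gbold <- extract_gbold(filtered)
        csf <- bandpass(r$csf, config$bandpass_low_hz,
                        config$bandpass_high_hz)
        list(filtered = filtered, gbold = gbold, csf = csf)
      })
      amp <- c(amp, gbold_amplitude(prep$gbold))
      pairs[[length(pairs) + 1L]] <- list(gbold = prep$gbold,
                                          csf = prep$csf)
      evs <- stage("waves", sid, {
        binned <- bin_series(prep$filtered, binning)
        segs <- segment_by_troughs(prep$gbold)
        lapply(seq_len(nrow(segs)), function(i)
          classify_segment(peak_table(binned, segs[i, ]), binning,
                           segs[i, ], config$p_wave, config$p_none,
                           config$min_involvement))
      })
      log$segments_found <- log$segments_found + length(evs)
      cw <- count_waves(evs)
      for (l in wave_labels) counts[[l]] <- counts[[l]] + cw[[l]]
      total_dur <- total_dur + ncol(r$run$data) * r$run$tr_seconds
      mfd <- c(mfd, stage("motion", sid,
                          framewise_displacement(r$motion)$mfd))
    }
    coup <- stage("coupling", sid,
                  subject_coupling(pairs, config$coupling_lag_seconds,
                                   config$max_lag_seconds))
    subj_ccfs[[sid]] <- coup$mean_ccf
    for (l in wave_labels)
      log$events_per_label[[l]] <- log$events_per_label[[l]] + counts[[l]]
    subj_rows[[sid]] <- data.frame(
      subject_id = sid, n_runs = length(runs),
      coupling = coup$subject_value, amplitude = mean(amp),
      mfd = mean(mfd), duration_s = total_dur,
      n_bottom_up = counts[["bottom_up"]],
      n_top_down = counts[["top_down"]],
      n_no_propagation = counts[["no_propagation"]])
  }
  metrics <- do.call(rbind, subj_rows)
  rownames(metrics) <- NULL
  group_ccf <- group_mean_ccf(subj_ccfs)
  # cohort statistics on the derived metrics joined with phenotypes
  ph <- cohort$phenotypes
  keep_cols <- intersect(c("subject_id", "age_at_mri", "age_at_menopause",
                           "education_years", "bmi", "psmt_score",
                           "ravlt_score"), names(ph))
  tab <- merge(ph[, keep_cols], metrics, by = "subject_id")
  grouped <- tryCatch(
    assign_groups(tab, config$split_age, config$n_groups),
    error = function(e) stop("stage 'cohort_stats' failed: ",
                             conditionMessage(e), call. = FALSE))
  stats_out <- cohort_statistics(grouped)
  log$group_sizes <- as.integer(table(grouped$group))
  out <- list(metrics = metrics, grouped = grouped, stats = stats_out,
              group_ccf = group_ccf, log = log)
  if (!is.null(out_dir)) write_pipeline_outputs(out, config, out_dir)
  invisible(out)
}

#' Headline cohort statistics on a grouped subject table
#'
#' Runs the report-style statistics on any table carrying `group`,
#' `age_at_mri`, `coupling`, `amplitude`, wave counts, and (optionally)
#' memory scores: age-adjusted earlier-vs-later two-sample t-tests on
#' coupling and amplitude, the age ANOVA across groups, ordinal trend
#' tests, the memory-score group comparison, and the age-adjusted
#' wave-count/memory correlation within the earlier group.
#'
#' @param grouped an [assign_groups()] result joined with derived metrics.
#' @return Named list of [stat_result()] objects.
#' @export
cohort_statistics <- function(grouped) {
  g <- grouped$group
  lev <- levels(g)
  first <- lev[1]; last <- lev[length(lev)]
  adj <- function(v) residualize_age(v, grouped$age_at_mri)
  out <- list()
  out$age_anova <- anova_oneway(grouped$age_at_mri, g)
  for (m in c("coupling", "amplitude")) {
    if (is.null(grouped[[m]])) next
    r <- adj(grouped[[m]])
    out[[paste0(m, "_t")]] <- two_sample_t(r[g == first], r[g == last])
    out[[paste0(m, "_trend")]] <- ordinal_trend(r, g)
  }
  if (!is.null(grouped$psmt_score)) {
    sc <- exclude_missing_scores(grouped, "psmt_score")
    r <- residualize_age(sc$psmt_score, sc$age_at_mri)
    out$psmt_t <- two_sample_t(r[sc$group == first],
                               r[sc$group == last])
    if (!is.null(sc$n_bottom_up)) {
      e <- sc[sc$group == first, ]
      out$wave_psmt_cor <- correlate(
        residualize_age(e$n_bottom_up, e$age_at_mri),
        residualize_age(e$psmt_score, e$age_at_mri))
    }
  }
  out
}

write_pipeline_outputs <- function(out, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(out$grouped, file.path(out_dir, "subject_metrics.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  st <- do.call(rbind, lapply(names(out$stats), function(nm) {
    s <- out$stats[[nm]]
    data.frame(name = nm, test = s$test, statistic = s$statistic,
               p = s$p, estimate = s$estimate,
               n = paste(s$n, collapse = "/"))
  }))
  utils::write.table(st, file.path(out_dir, "group_stats.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_ccf_tsv(out$group_ccf, file.path(out_dir, "group_mean_ccf.tsv"))
  jsonlite::write_json(
    c(out$log, list(config = unclass(config))),
    file.path(out_dir, "pipeline_log.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
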