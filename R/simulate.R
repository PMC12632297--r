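# Seeded generator of synthetic cohorts with the statistical structure
# every pipeline stage assumes: infra-slow band-limited vertex noise,
# injected global events propagating along the principal gradient, a CSF
# signal negatively coupled to gBOLD at a fixed lag, random-walk motion
# traces, and subject covariates with planted group/correlation effects.

#' Configuration of a synthetic cohort
#'
#' All defaults describe the emulated study conditions: four 478-frame
#' runs at TR 0.8 s per subject, infra-slow (0.01-0.1 Hz) AR(1) vertex
#' noise, global events at ~2.5 per minute with amplitude twice the noise
#' SD, a CSF signal lagging gBOLD by 3.2 s with negative sign, and a
#' 124-subject covariate model whose planted effects mirror the reported
#' group differences (weaker coupling and amplitude with earlier
#' menopause, and a wave-count/memory correlation in the earlier group).
#' The surface is reduced to 2,000 vertices for desk-scale runtime; the
#' 70 positional bins are kept so wave statistics stay comparable.
#'
#' @param ... overrides of any default field (unknown names error).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    # cohort / acquisition structure
    n_subjects = 124L, n_vertices = 2000L, n_bins = 70L, n_parcels = 68L,
    n_runs = 4L, n_frames = 478L, tr_seconds = 0.8,
    # vertex noise model
    ar_coef = 0.4, vertex_sd = 1,
    # global events
    event_rate_per_min = 2.5, event_amplitude = 2, event_duration_s = 8,
    propagation_span_s = 6,
    direction_mix = c(bottom_up = 0.45, top_down = 0.35,
                      synchronous = 0.20),
    # CSF model: csf(t) = -gain * gbold(t - lag) + noise
    csf_lag_s = 3.2, csf_gain = 1, csf_noise_sd = 0.5,
    # motion random walk (per-frame step SDs; mm and radians)
    motion_step_sd = c(translation = 0.05, rotation = 0.001),
    # covariate model
    meno_age_mean = 50, meno_age_sd = 4, meno_age_range = c(38, 58),
    mri_age_slope = 0.45, mri_age_intercept = 36, mri_age_sd = 3.5,
    education_mean = 15.4, education_sd = 1.7,
    bmi_mean = 27, bmi_sd = 5,
    # planted metric-level effects (per year of menopause age, ref 50)
    coupling_base = -0.35, coupling_slope_per_year = 0.013,
    coupling_age_slope_per_year = 0.004, coupling_sd = 0.18,
    amplitude_base = 0.4, amplitude_slope_per_year = 0.011,
    amplitude_age_slope_per_year = -0.002, amplitude_sd = 0.1,
    wave_count_base = 14, wave_count_slope_per_year = 0.3,
    wave_count_sd = 5,
    psmt_mean = 95, psmt_sd = 12, psmt_slope_per_year = 0.8,
    psmt_age_slope_per_year = -0.4,
    ravlt_mean = 8.5, ravlt_sd = 3, ravlt_slope_per_year = 0.2,
    memory_rho = 0.46, earlier_proxy_age = 49,
    missing_score_rate = 0.08,
    # planted imaging-level effects (multipliers per year, ref 50)
    event_amp_slope_per_year = 0.02, csf_noise_slope_per_year = 0.03,
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown sim_config field(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$event_rate_per_min >= 0, cfg$event_amplitude >= 0,
            cfg$csf_noise_sd >= 0, all(cfg$direction_mix >= 0),
            sum(cfg$direction_mix) <= 1 + 1e-9)
  lagk <- cfg$csf_lag_s / cfg$tr_seconds
  if (abs(lagk - round(lagk)) > 1e-9)
    stop("csf_lag_s must be a multiple of the TR")
  class(cfg) <- "sim_config"
  cfg
}

#' Synthetic surface geometry
#'
#' Principal-gradient scores drawn from a smooth 1-D latent (a low-order
#' random Fourier perturbation of a linear ramp, plus a tiny jitter to
#' keep scores distinct), centered to zero mean. Parcels are assigned as
#' contiguous PG blocks, standing in for a 68-parcel cortical atlas.
#'
#' @param n_vertices number of vertices (default 2000).
#' @param n_bins intended positional bins (validated only).
#' @param n_parcels number of contiguous parcels (default 68).
#' @param seed RNG seed.
#' @return A [surface_geometry()].
#' @export
make_geometry <- function(n_vertices = 2000, n_bins = 70,
                          n_parcels = 68, seed = 1) {
  if (n_bins > n_vertices)
    stop("n_bins must not exceed n_vertices")
  set.seed(seed)
  u <- seq(0, 1, length.out = n_vertices)
  pg <- u
  for (j in 1:4)
    pg <- pg + stats::rnorm(1, 0, 0.08 / j) * sin(j * pi * u +
                                                  stats::runif(1, 0, 2 * pi))
  pg <- pg + stats::rnorm(n_vertices, 0, 1e-3)
  pg <- pg - mean(pg)
  parcel <- integer(n_vertices)
  ord <- order(pg, seq_len(n_vertices))
  parcel[ord] <- as.integer(
    floor((seq_len(n_vertices) - 1L) * n_parcels / n_vertices)) + 1L
  surface_geometry(pg, parcel)
}

#' Simulate one resting-state run with planted global events
#'
#' Vertex noise is AR(1) in time, band-limited to 0.01-0.1 Hz, and scaled
#' to `vertex_sd`. Global events are Gaussian bumps whose center time at
#' each vertex is `onset + span * q` for bottom-up events (q = the
#' vertex's PG rank fraction), reversed for top-down, and constant
#' (`onset + span/2`) for synchronous events. The CSF signal is the
#' negative, lag-delayed copy of the run's gBOLD signal plus white noise
#' (noise SD expressed relative to the gBOLD SD); motion is a Gaussian
#' random walk.
#'
#' @param cfg a [sim_config()].
#' @param geometry a [surface_geometry()] (shared across subjects).
#' @param effects per-subject multipliers: list with `event_amp`,
#'   `csf_noise`, `event_rate` (defaults 1).
#' @param seed RNG seed for this run.
#' @param run_label run identifier.
#' @return List with `run` (surface `bold_run`), `csf` (`signal1d`),
#'   `motion` (`motion_params`), `events` (data.frame of ground truth:
#'   `onset_s`, `direction`, `amplitude`).
#' @export
simulate_run <- function(cfg, geometry, effects = list(), seed = 1,
                         run_label = "run") {
  eff <- utils::modifyList(list(event_amp = 1, csf_noise = 1,
                                event_rate = 1), effects)
  set.seed(seed)
  nv <- geometry$n_vertices
  nf <- cfg$n_frames
  tr <- cfg$tr_seconds
  dur_s <- nf * tr
  if (cfg$event_duration_s > dur_s)
    stop("event duration exceeds the run length")
  # infra-slow AR(1) noise
  X <- matrix(stats::rnorm(nv * nf), nv, nf)
  for (t in 2:nf) X[, t] <- cfg$ar_coef * X[, t - 1L] + X[, t]
  X <- bandpass_matrix(X, 0.01, 0.1, tr)
  sds <- apply(X, 1L, stats::sd)
  X <- X / sds * cfg$vertex_sd
  # planted events
  n_events <- max(0L, as.integer(round(
    cfg$event_rate_per_min * dur_s / 60 * eff$event_rate)))
  events <- data.frame(onset_s = numeric(0), direction = character(0),
                       amplitude = numeric(0))
  if (n_events > 0L && cfg$event_amplitude > 0) {
    mix <- cfg$direction_mix / sum(cfg$direction_mix)
    dirs <- sample(names(mix), n_events, replace = TRUE, prob = mix)
    edge <- cfg$propagation_span_s + cfg$event_duration_s / 2
    slot <- (dur_s - 2 * edge) / n_events
    onsets <- edge + (seq_len(n_events) - 0.5) * slot +
      stats::runif(n_events, -slot / 4, slot / 4)
    q <- (rank(geometry$pg_score, ties.method = "first") - 1) / (nv - 1)
    tvec <- (seq_len(nf) - 1L) * tr
    sigma <- cfg$event_duration_s / 4
    A <- cfg$event_amplitude * cfg$vertex_sd * eff$event_amp
    span <- cfg$propagation_span_s
    for (k in seq_len(n_events)) {
      centers <- switch(dirs[k],
        bottom_up = onsets[k] + span * q,
        top_down = onsets[k] + span * (1 - q),
        synchronous = rep(onsets[k] + span / 2, nv))
      X <- X + A * exp(-0.5 * (outer(centers, tvec, "-") / sigma)^2)
    }
    events <- data.frame(onset_s = onsets, direction = dirs,
                         amplitude = A)
  }
  run <- bold_run(X, tr, space = "surface", run_label = run_label)
  # CSF: negative lag-delayed copy of gBOLD + noise (circular shift)
  g <- extract_gbold(znorm(run))$values
  lagk <- as.integer(round(cfg$csf_lag_s / tr))
  shifted <- g[((seq_len(nf) - 1L - lagk) %% nf) + 1L]
  csf_vals <- -cfg$csf_gain * shifted +
    stats::rnorm(nf, 0, cfg$csf_noise_sd * eff$csf_noise * stats::sd(g))
  csf <- signal1d(csf_vals, tr, label = "CSF")
  # motion random walk
  steps <- cbind(
    matrix(stats::rnorm(3L * nf, 0, cfg$motion_step_sd[["translation"]]),
           nf, 3L),
    matrix(stats::rnorm(3L * nf, 0, cfg$motion_step_sd[["rotation"]]),
           nf, 3L))
  motion <- motion_params(apply(steps, 2L, cumsum))
  list(run = run, csf = csf, motion = motion, events = events)
}

#' Simulate subject-level covariates and derived metrics
#'
#' The generator's covariate model: menopause ages drawn on a stratified
#' normal grid (guaranteeing spread on both sides of the group split),
#' MRI ages linearly tied to menopause age plus noise (so the overlap
#' exclusion has work to do), education/BMI draws, and the planted
#' metric-level effects — coupling and amplitude shifting linearly with
#' menopause age and with MRI age, wave counts with menopause age, memory
#' scores correlated (rho) with bottom-up wave counts among
#' earlier-menopause subjects. Setting every `*_slope_per_year` and
#' `memory_rho` to zero gives the null cohort used for calibration.
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed (defaults to `cfg$seed`).
#' @return data.frame with phenotype columns, derived metrics
#'   (`coupling`, `amplitude`, `n_bottom_up`, `n_top_down`), scores, and
#'   imaging-effect multipliers (`event_amp_mult`, `csf_noise_mult`).
#' @export
simulate_subject_metrics <- function(cfg, seed = cfg$seed) {
  set.seed(seed)
  n <- cfg$n_subjects
  # stratified normal draw: quantile grid in random order, jittered
  meno <- cfg$meno_age_mean + cfg$meno_age_sd *
    stats::qnorm((sample(n) - stats::runif(n)) / n)
  meno <- pmin(pmax(meno, cfg$meno_age_range[1]), cfg$meno_age_range[2])
  mri <- cfg$mri_age_intercept + cfg$mri_age_slope * meno +
    stats::rnorm(n, 0, cfg$mri_age_sd)
  mri <- pmax(mri, meno + 1)  # scan happens after menopause
  dm <- meno - 50
  da <- mri - mean(mri)
  coupling <- cfg$coupling_base - cfg$coupling_slope_per_year * dm +
    cfg$coupling_age_slope_per_year * da +
    stats::rnorm(n, 0, cfg$coupling_sd)
  amplitude <- cfg$amplitude_base + cfg$amplitude_slope_per_year * dm +
    cfg$amplitude_age_slope_per_year * da +
    stats::rnorm(n, 0, cfg$amplitude_sd)
  amplitude <- pmax(amplitude, 0.01)
  n_bu_raw <- cfg$wave_count_base + cfg$wave_count_slope_per_year * dm +
    stats::rnorm(n, 0, cfg$wave_count_sd)
  n_bu <- pmax(0L, as.integer(round(n_bu_raw)))
  n_td <- pmax(0L, as.integer(round(
    cfg$wave_count_base * 0.8 + stats::rnorm(n, 0, cfg$wave_count_sd))))
  # memory scores: correlated with bottom-up count in the earlier-proxy
  # subset, noise elsewhere
  score_with_rho <- function(mean, sdv, slope, age_slope = 0) {
    z_bu <- as.numeric(scale(n_bu_raw - cfg$wave_count_slope_per_year * dm))
    eps <- stats::rnorm(n)
    rho <- cfg$memory_rho
    z <- ifelse(meno < cfg$earlier_proxy_age,
                rho * z_bu + sqrt(max(0, 1 - rho^2)) * eps, eps)
    mean + slope * dm + age_slope * da + sdv * z
  }
  psmt <- score_with_rho(cfg$psmt_mean, cfg$psmt_sd,
                         cfg$psmt_slope_per_year,
                         cfg$psmt_age_slope_per_year)
  ravlt <- score_with_rho(cfg$ravlt_mean, cfg$ravlt_sd,
                          cfg$ravlt_slope_per_year)
  if (cfg$missing_score_rate > 0) {
    psmt[stats::runif(n) < cfg$missing_score_rate] <- NA_real_
    ravlt[stats::runif(n) < cfg$missing_score_rate] <- NA_real_
  }
  data.frame(
    subject_id = sprintf("sub-%04d", seq_len(n)),
    age_at_mri = round(mri, 1), age_at_menopause = round(meno, 1),
    education_years = round(pmax(8, stats::rnorm(
      n, cfg$education_mean, cfg$education_sd))),
    bmi = round(pmax(16, stats::rnorm(n, cfg$bmi_mean, cfg$bmi_sd)), 1),
    psmt_score = round(psmt, 1), ravlt_score = round(ravlt, 1),
    coupling = coupling, amplitude = amplitude,
    n_bottom_up = n_bu, n_top_down = n_td,
    event_amp_mult = pmax(0.2, 1 + cfg$event_amp_slope_per_year * dm),
    csf_noise_mult = pmax(0.2, 1 - cfg$csf_noise_slope_per_year * dm))
}

#' Simulate a full synthetic cohort
#'
#' Draws the covariate table with [simulate_subject_metrics()], builds a
#' shared [make_geometry()] map, and (unless `imaging = FALSE`) generates
#' every subject's runs with [simulate_run()], applying the per-subject
#' imaging effect multipliers. Per-subject and per-run seeds are derived
#' deterministically from the master seed, so the whole cohort is
#' bit-identical under a fixed `cfg`.
#'
#' @param cfg a [sim_config()].
#' @param imaging generate imaging runs (default TRUE); `FALSE` returns
#'   covariates and geometry only.
#' @return List of class `synthetic_cohort`: `config`, `geometry`,
#'   `phenotypes` (data.frame, also carrying derived ground-truth
#'   metrics), `subjects` (list; each has `subject_id`, `runs` = list of
#'   [simulate_run()] outputs), and `ground_truth` (per-run event table).
#' @export
simulate_cohort <- function(cfg, imaging = TRUE) {
  metrics <- simulate_subject_metrics(cfg)
  geometry <- make_geometry(cfg$n_vertices, cfg$n_bins, cfg$n_parcels,
                            seed = cfg$seed)
  set.seed(cfg$seed + 1L)
  run_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 cfg$n_subjects * cfg$n_runs),
                      cfg$n_subjects, cfg$n_runs)
  run_labels <- c("AP1", "PA1", "AP2", "PA2")[seq_len(cfg$n_runs)]
  subjects <- NULL
  gt <- NULL
  if (imaging) {
    subjects <- lapply(seq_len(cfg$n_subjects), function(i) {
      eff <- list(event_amp = metrics$event_amp_mult[i],
                  csf_noise = metrics$csf_noise_mult[i])
      runs <- lapply(seq_len(cfg$n_runs), function(r)
        simulate_run(cfg, geometry, eff, seed = run_seeds[i, r],
                     run_label = run_labels[r]))
      names(runs) <- run_labels
      list(subject_id = metrics$subject_id[i], runs = runs)
    })
    gt <- do.call(rbind, lapply(seq_along(subjects), function(i) {
      do.call(rbind, lapply(run_labels, function(r) {
        ev <- subjects[[i]]$runs[[r]]$events
        if (nrow(ev) == 0L) return(NULL)
        cbind(subject_id = metrics$subject_id[i], run = r, ev)
      }))
    }))
  }
  structure(list(config = cfg, geometry = geometry, phenotypes = metrics,
                 subjects = subjects, ground_truth = gt),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, %s imaging, %d vertices\n",
              nrow(x$phenotypes),
              if (is.null(x$subjects)) "no" else "with",
              x$geometry$n_vertices))
  invisible(x)
}
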