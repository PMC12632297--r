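# Detection and classification of infra-slow waves propagating along the
# cortical principal gradient: PG binning, trough-based segmentation of
# the gBOLD time course, per-bin peak timing, timing-position correlation
# classification, wave counting, and wave-locked averaging.

#' Bin vertices along the principal gradient
#'
#' Vertices are sorted by PG score (ties broken by vertex index) and split
#' into `n_bins` contiguous groups of near-equal count (occupancies differ
#' by at most one vertex). Equal-count bins keep every bin mean equally
#' stable; bin rank along ascending PG then serves as the position
#' variable for the propagation test.
#'
#' @param geometry a [surface_geometry()] with finite PG scores.
#' @param n_bins number of positional bins (default 70).
#' @return An object of class `gradient_binning`: `n_bins`,
#'   `bin_of_vertex` (integer per vertex, 1 = lowest PG), `bin_sizes`.
#' @export
bin_by_gradient <- function(geometry, n_bins = 70) {
  pg <- geometry$pg_score
  n <- length(pg)
  if (n_bins > n) stop("more bins (", n_bins, ") than vertices (", n, ")")
  ord <- order(pg, seq_len(n))
  ranks <- integer(n)
  ranks[ord] <- seq_len(n)
  bin <- as.integer(floor((ranks - 1L) * n_bins / n)) + 1L
  structure(list(n_bins = as.integer(n_bins), bin_of_vertex = bin,
                 bin_sizes = tabulate(bin, n_bins)),
            class = "gradient_binning")
}

#' Average a surface run within each PG bin
#'
#' @param run a surface `bold_run`.
#' @param binning a [bin_by_gradient()] result for the same vertex set.
#' @return An object of class `binned_series`: `data`
#'   (`n_bins x n_frames`), `tr_seconds`.
#' @export
bin_series <- function(run, binning) {
  if (nrow(run$data) != length(binning$bin_of_vertex))
    stop("run vertex count does not match the binning")
  sums <- rowsum(run$data, group = binning$bin_of_vertex)
  m <- sums / binning$bin_sizes[as.integer(rownames(sums))]
  dimnames(m) <- NULL
  structure(list(data = m, tr_seconds = run$tr_seconds),
            class = "binned_series")
}

#' Segment a gBOLD time course at its troughs
#'
#' Troughs are strict local minima of the (band-limited) gBOLD signal: a
#' frame lower than both neighbors. Consecutive troughs delimit half-open
#' segments `[start, end)`; partial data before the first and after the
#' last trough are discarded. Each segment's `gbold_peak_frame` is the
#' frame of the gBOLD maximum inside it. No prominence threshold is
#' applied: the 0.01-0.1 Hz filter already suppresses spurious minima.
#'
#' @param gbold a `signal1d` (the whole-surface mean, band-limited).
#' @return data.frame with columns `start_frame`, `end_frame` (half-open),
#'   `gbold_peak_frame`; zero rows when fewer than two troughs exist.
#' @export
segment_by_troughs <- function(gbold) {
  v <- gbold$values
  n <- length(v)
  interior <- seq.int(2L, n - 1L)
  troughs <- interior[v[interior] < v[interior - 1L] &
                      v[interior] < v[interior + 1L]]
  if (length(troughs) < 2L)
    return(data.frame(start_frame = integer(0), end_frame = integer(0),
                      gbold_peak_frame = integer(0)))
  start <- troughs[-length(troughs)]
  end <- troughs[-1L]
  peak <- mapply(function(s, e) s - 1L + which.max(v[s:(e - 1L)]),
                 start, end)
  data.frame(start_frame = start, end_frame = end,
             gbold_peak_frame = as.integer(peak))
}

# Strict local maxima of a vector, plateau-aware: a maximal run of equal
# values higher than both flanking values counts once, at its earliest
# frame. Endpoints never qualify.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  runs <- rle(x)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  k <- length(runs$values)
  if (k < 3L) return(integer(0))
  mid <- seq.int(2L, k - 1L)
  is_max <- runs$values[mid] > runs$values[mid - 1L] &
            runs$values[mid] > runs$values[mid + 1L]
  starts[mid][is_max]
}

#' Per-bin peak table for one segment
#'
#' Within the segment, finds for each PG bin the largest strict local peak
#' of the bin's time course: among all strict local maxima inside
#' `[start, end)` (segment-edge frames never qualify; plateau ties take
#' the earliest frame), the one with the greatest value. Bins with no
#' local maximum are missing. Delays are reported in seconds relative to
#' the segment's gBOLD peak frame.
#'
#' @param binned a [bin_series()] result.
#' @param seg one row of [segment_by_troughs()] output (data.frame or
#'   list with `start_frame`, `end_frame`, `gbold_peak_frame`).
#' @return An object of class `peak_table`: `delay_seconds` (numeric per
#'   bin, `NA` = missing), `peak_frame` (integer per bin),
#'   `involvement_fraction`.
#' @export
peak_table <- function(binned, seg) {
  s <- seg$start_frame
  e <- seg$end_frame
  if (s < 1L || e > ncol(binned$data) + 1L || e - s < 1L)
    stop("segment outside the run")
  frames <- s:(e - 1L)
  nb <- nrow(binned$data)
  delay <- rep(NA_real_, nb)
  pkf <- rep(NA_integer_, nb)
  for (b in seq_len(nb)) {
    x <- binned$data[b, frames]
    lm_idx <- local_maxima(x)
    if (length(lm_idx) == 0L) next
    best <- lm_idx[which.max(x[lm_idx])]
    pkf[b] <- frames[best]
    delay[b] <- (frames[best] - seg$gbold_peak_frame) * binned$tr_seconds
  }
  structure(list(delay_seconds = delay, peak_frame = pkf,
                 involvement_fraction = mean(!is.na(delay))),
            class = "peak_table")
}

#' Classify one segment as a propagating wave (or not)
#'
#' A segment qualifies as a global event only when local peaks were found
#' in at least `min_involvement` of the positional bins (default 80%).
#' Qualifying segments get a Pearson correlation between the per-bin peak
#' delays and the bin positions along ascending PG, with a two-sided
#' t-distribution test (n = bins with a peak). Classification:
#' significant positive correlation (p < `p_wave`) = `bottom_up`
#' (SM-to-DMN wave); significant negative = `top_down` (DMN-to-SM);
#' p > `p_none` = `no_propagation` (a global peak without propagation);
#' the band `p_wave <= p <= p_none` is `unclassified` and excluded from
#' wave counts. Segments failing the involvement rule (or with fewer than
#' 3 peaked bins) are `excluded_low_involvement`.
#'
#' @param pt a [peak_table()].
#' @param binning the [bin_by_gradient()] used (for `n_bins`).
#' @param seg the segment row (carried into the result).
#' @param p_wave significance cutoff for wave labels (default 0.01).
#' @param p_none lower cutoff for `no_propagation` (default 0.05).
#' @param min_involvement minimum fraction of bins with a peak
#'   (default 0.8).
#' @return An object of class `wave_event`: `segment`, `r`, `p`,
#'   `n_bins_used`, `involvement`, `label`.
#' @export
classify_segment <- function(pt, binning, seg, p_wave = 0.01,
                             p_none = 0.05, min_involvement = 0.8) {
  ok <- !is.na(pt$delay_seconds)
  nuse <- sum(ok)
  mk <- function(label, r = NA_real_, p = NA_real_) {
    structure(list(segment = seg, r = r, p = p, n_bins_used = nuse,
                   involvement = pt$involvement_fraction, label = label),
              class = "wave_event")
  }
  if (pt$involvement_fraction < min_involvement || nuse < 3L)
    return(mk("excluded_low_involvement"))
  pos <- seq_len(binning$n_bins)[ok]  # bin rank along ascending PG
  r <- stats::cor(pt$delay_seconds[ok], pos)
  p <- cor_pvalue(r, nuse)
  label <- if (is.na(p)) "no_propagation"
    else if (p < p_wave && r > 0) "bottom_up"
    else if (p < p_wave && r < 0) "top_down"
    else if (p > p_none) "no_propagation"
    else "unclassified"
  mk(label, r, p)
}

# Two-sided p-value for a Pearson correlation via the t distribution,
# df = n - 2; |r| = 1 gives p = 0.
cor_pvalue <- function(r, n) {
  if (is.na(r)) return(NA_real_)
  if (abs(r) >= 1) return(0)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

#' @export
print.wave_event <- function(x, ...) {
  cat(sprintf("<wave_event> %s (r = %.3f, p = %.3g, involvement = %.2f)\n",
              x$label, x$r, x$p, x$involvement))
  invisible(x)
}

wave_labels <- c("bottom_up", "top_down", "no_propagation",
                 "unclassified", "excluded_low_involvement")

#' Tally wave events by label
#'
#' Counts events of each label. When `duration_seconds` is supplied,
#' per-minute rates are added so runs (or subjects) of unequal duration
#' can be compared; raw counts across subjects should only be compared
#' when session durations are equal.
#'
#' @param events list of `wave_event` objects (possibly from several runs
#'   of one subject; subject counts are the sum over runs).
#' @param duration_seconds optional total duration the events came from.
#' @return Named integer vector of counts over all labels (plus
#'   `rate_per_min_*` entries when a duration is given), as a list.
#' @export
count_waves <- function(events, duration_seconds = NULL) {
  labels <- vapply(events, `[[`, character(1), "label")
  counts <- vapply(wave_labels, function(l) sum(labels == l), integer(1))
  out <- as.list(counts)
  out$n_segments <- length(events)
  if (!is.null(duration_seconds)) {
    mins <- duration_seconds / 60
    for (l in c("bottom_up", "top_down", "no_propagation"))
      out[[paste0("rate_per_min_", l)]] <- counts[[l]] / mins
  }
  out
}

#' Wave-locked average of the binned series
#'
#' Averages the bin-by-time excerpt around each selected event's gBOLD
#' peak: the spatiotemporal shape of the mean wave. Events whose window
#' exits the run are dropped.
#'
#' @param binned a [bin_series()] result.
#' @param events list of `wave_event` objects.
#' @param label keep only events with this label (default `"bottom_up"`);
#'   `NULL` keeps all.
#' @param window_seconds half-width of the symmetric window around the
#'   gBOLD peak (default 8 s).
#' @return An object of class `wave_locked_average`: `data`
#'   (`n_bins x (2w+1)`), `rel_time_seconds`, `event_count`; `NULL` when
#'   no event survives.
#' @export
wave_locked_average <- function(binned, events, label = "bottom_up",
                                window_seconds = 8) {
  if (!is.null(label))
    events <- Filter(function(e) e$label == label, events)
  w <- as.integer(round(window_seconds / binned$tr_seconds))
  nf <- ncol(binned$data)
  keep <- Filter(function(e) {
    p <- e$segment$gbold_peak_frame
    p - w >= 1L && p + w <= nf
  }, events)
  if (length(keep) == 0L) return(NULL)
  acc <- 0
  for (e in keep) {
    p <- e$segment$gbold_peak_frame
    acc <- acc + binned$data[, (p - w):(p + w), drop = FALSE]
  }
  structure(list(data = acc / length(keep),
                 rel_time_seconds = seq.int(-w, w) * binned$tr_seconds,
                 event_count = length(keep)),
            class = "wave_locked_average")
}

#' Correlate wave-locked activation with a covariate across subjects
#'
#' At every (bin, relative-time) cell, correlates the subjects' mean
#' wave-locked activation with a behavioral covariate, after residualizing
#' both on age at MRI (the cohort's age adjustment). Cells are reported as
#' Pearson r with a two-sided p; the paper-style display thresholds at raw
#' p < 0.05. A constant covariate leaves the correlation undefined: the
#' map is returned flagged missing.
#'
#' @param subject_maps list (one per subject) of `wave_locked_average`
#'   objects on identical grids (`NULL` subjects are dropped together with
#'   their covariate entries).
#' @param covariate numeric per subject (e.g. PSMT score).
#' @param ages age at MRI per subject; `NULL` skips the adjustment.
#' @return List with matrices `r`, `p`, `t` (`n_bins x n_times`), `n`
#'   subjects used, and `missing` flag.
#' @export
wave_score_map <- function(subject_maps, covariate, ages = NULL) {
  keep <- !vapply(subject_maps, is.null, logical(1)) & !is.na(covariate)
  subject_maps <- subject_maps[keep]
  covariate <- covariate[keep]
  if (!is.null(ages)) ages <- ages[keep]
  n <- length(subject_maps)
  dims <- dim(subject_maps[[1]]$data)
  if (stats::sd(covariate) == 0) {
    na <- matrix(NA_real_, dims[1], dims[2])
    return(list(r = na, p = na, t = na, n = n, missing = TRUE))
  }
  cube <- vapply(subject_maps, function(m) m$data,
                 matrix(0, dims[1], dims[2]))
  if (!is.null(ages)) {
    covariate <- residualize_age(covariate, ages)
    flat <- matrix(cube, nrow = dims[1] * dims[2])
    flat <- t(apply(flat, 1L, residualize_age, ages = ages))
    cube <- array(flat, dim = c(dims, n))
  }
  rmat <- matrix(NA_real_, dims[1], dims[2])
  for (i in seq_len(dims[1]))
    for (j in seq_len(dims[2])) {
      v <- cube[i, j, ]
      if (stats::sd(v) > 0) rmat[i, j] <- stats::cor(v, covariate)
    }
  pmat <- matrix(cor_pvalue_vec(rmat, n), dims[1], dims[2])
  tmat <- rmat * sqrt((n - 2) / pmax(1 - rmat^2, .Machine$double.eps))
  list(r = rmat, p = pmat, t = tmat, n = n, missing = FALSE)
}

cor_pvalue_vec <- function(r, n) {
  vapply(as.numeric(r), cor_pvalue, numeric(1), n = n)
}

#' Export wave events as TSV
#' @param events list of `wave_event` objects.
#' @param tr_seconds TR used to convert frames to seconds.
#' @param path output path.
#' @param subject,run optional identifiers repeated per row.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, tr_seconds, path,
                             subject = NA, run = NA) {
  df <- do.call(rbind, lapply(events, function(e) {
    data.frame(subject = subject, run = run,
               start_s = (e$segment$start_frame - 1L) * tr_seconds,
               end_s = (e$segment$end_frame - 1L) * tr_seconds,
               r = e$r, p = e$p, label = e$label,
               involvement = e$involvement)
  }))
  if (is.null(df))
    df <- data.frame(subject = character(0), run = character(0),
                     start_s = numeric(0), end_s = numeric(0),
                     r = numeric(0), p = numeric(0), label = character(0),
                     involvement = numeric(0))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
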