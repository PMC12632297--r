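# Cross-correlation functions, gBOLD-CSF coupling at a fixed lag,
# parcel-level gBOLD presence and rBOLD-CSF coupling, and their
# run/subject/group averaging.
#
# Lag convention (fixed): values[tau] = cor(first(t), second(t + tau)).
# Positive tau therefore means the second signal (CSF) is shifted earlier
# by tau before correlating, i.e. CSF changes FOLLOW gBOLD changes by tau.
# Under the generative model csf(t) = -gain * gbold(t - L) + noise, the
# cross-correlation function has its negative peak at tau = +L, matching
# the empirical negative peak at +3.2 s.

#' Cross-correlation function over a symmetric lag grid
#'
#' For each lag tau on the grid `-max_lag..+max_lag` (step = TR), computes
#' the Pearson correlation between the overlapping frames of the two
#' signals only: the overlap is truncated at the ends and means/SDs are
#' recomputed per lag (no padding, no FFT wraparound).
#'
#' @param first,second `signal1d` objects of equal length and TR.
#' @param max_lag_seconds largest |lag|, a TR multiple (default 16 s).
#' @return An object of class `xcorr_fn`: list with `lags_seconds`,
#'   `values`, `tr_seconds`.
#' @export
xcorr <- function(first, second, max_lag_seconds = 16) {
  if (length(first$values) != length(second$values))
    stop("signals must have equal length")
  if (abs(first$tr_seconds - second$tr_seconds) > 1e-9)
    stop("signals must share the same TR")
  tr <- first$tr_seconds
  kmax <- max_lag_seconds / tr
  if (abs(kmax - round(kmax)) > 1e-9)
    stop("`max_lag_seconds` must be a multiple of the TR")
  kmax <- as.integer(round(kmax))
  n <- length(first$values)
  if (n <= 2L * kmax)
    stop("signals too short: need more than ", 2L * kmax, " frames")
  ks <- seq.int(-kmax, kmax)
  vals <- vapply(ks, function(k) {
    if (k >= 0L) {
      x <- first$values[seq_len(n - k)]
      y <- second$values[seq.int(1L + k, n)]
    } else {
      x <- first$values[seq.int(1L - k, n)]
      y <- second$values[seq_len(n + k)]
    }
    stats::cor(x, y)
  }, numeric(1))
  structure(list(lags_seconds = ks * tr, values = vals, tr_seconds = tr),
            class = "xcorr_fn")
}

#' @export
print.xcorr_fn <- function(x, ...) {
  i <- which.min(x$values)
  cat(sprintf("<xcorr_fn> lags %g..%g s (step %g), min r = %.3f at %+.1f s\n",
              min(x$lags_seconds), max(x$lags_seconds), x$tr_seconds,
              x$values[i], x$lags_seconds[i]))
  invisible(x)
}

#' Read a cross-correlation function at one exact lag
#'
#' The coupling summary is the correlation at a fixed lag (+3.2 s, where
#' the group-mean function shows its negative peak). The lag must sit on
#' the computed grid: no interpolation is performed.
#'
#' @param cc an `xcorr_fn`.
#' @param lag_seconds requested lag (default +3.2).
#' @return The correlation value at that lag.
#' @export
coupling_at_lag <- function(cc, lag_seconds = 3.2) {
  i <- which(abs(cc$lags_seconds - lag_seconds) < 1e-9)
  if (length(i) != 1L)
    stop("lag ", lag_seconds, " s is not on the computed grid (step ",
         cc$tr_seconds, " s); no interpolation")
  cc$values[i]
}

#' Subject-level gBOLD-CSF coupling
#'
#' Computes one cross-correlation function per run, averages them
#' pointwise across the subject's runs, and reads the coupling value at
#' the fixed lag from the averaged function. Per-run values at the same
#' lag are retained for diagnostics.
#'
#' @param runs list of runs; each element a list with components `gbold`
#'   and `csf` (both `signal1d`).
#' @param lag_seconds coupling lag (default +3.2 s).
#' @param max_lag_seconds lag-grid half-width (default 16 s).
#' @return An object of class `coupling_result`: `per_run` (numeric),
#'   `subject_value`, `lag_used_seconds`, `mean_ccf` (an `xcorr_fn`).
#' @export
subject_coupling <- function(runs, lag_seconds = 3.2, max_lag_seconds = 16) {
  if (length(runs) < 1L) stop("need at least one run")
  ccs <- lapply(runs, function(r) xcorr(r$gbold, r$csf, max_lag_seconds))
  vals <- t(vapply(ccs, `[[`, numeric(length(ccs[[1]]$values)), "values"))
  mean_ccf <- ccs[[1]]
  mean_ccf$values <- colMeans(vals)
  structure(list(
    per_run = vapply(ccs, coupling_at_lag, numeric(1),
                     lag_seconds = lag_seconds),
    subject_value = coupling_at_lag(mean_ccf, lag_seconds),
    lag_used_seconds = lag_seconds,
    mean_ccf = mean_ccf),
    class = "coupling_result")
}

#' @export
print.coupling_result <- function(x, ...) {
  cat(sprintf("<coupling_result> %d run(s), value at %+.1f s = %.3f\n",
              length(x$per_run), x$lag_used_seconds, x$subject_value))
  invisible(x)
}

#' Parcel-level gBOLD presence
#'
#' Zero-lag Pearson correlation of each parcel's regional BOLD signal
#' with the whole-surface mean signal: how strongly each region engages
#' in global activity. Constant (or missing) parcel signals yield `NA`.
#'
#' @param parcels named list of `signal1d` (or `NULL`) from
#'   [parcel_means()].
#' @param surface_mean the whole-surface mean `signal1d`.
#' @return Named numeric vector (a parcel map), values in `[-1, 1]` or
#'   `NA`.
#' @export
gbold_presence <- function(parcels, surface_mean) {
  vapply(parcels, function(p) {
    if (is.null(p) || stats::sd(p$values) == 0) return(NA_real_)
    stats::cor(p$values, surface_mean$values)
  }, numeric(1))
}

#' Parcel-level rBOLD-CSF coupling
#'
#' Each parcel's regional BOLD signal correlated with the CSF signal at
#' the fixed coupling lag; exactly the composition of [xcorr()] and
#' [coupling_at_lag()] applied per parcel.
#'
#' @param parcels named list of `signal1d` (or `NULL`).
#' @param csf the CSF `signal1d`.
#' @param lag_seconds coupling lag (default +3.2 s).
#' @param max_lag_seconds lag-grid half-width.
#' @return Named numeric vector, values in `[-1, 1]` or `NA`.
#' @export
rbold_csf_coupling <- function(parcels, csf, lag_seconds = 3.2,
                               max_lag_seconds = 16) {
  vapply(parcels, function(p) {
    if (is.null(p) || stats::sd(p$values) == 0) return(NA_real_)
    coupling_at_lag(xcorr(p, csf, max_lag_seconds), lag_seconds)
  }, numeric(1))
}

#' Group-mean cross-correlation function with standard-error band
#'
#' Pointwise mean and standard error of the mean across subjects'
#' cross-correlation functions (all on the same lag grid).
#'
#' @param subjects list of `xcorr_fn` objects.
#' @return An `xcorr_fn` with an extra `sem` component.
#' @export
group_mean_ccf <- function(subjects) {
  if (length(subjects) < 1L) stop("need at least one subject")
  vals <- t(vapply(subjects, `[[`, numeric(length(subjects[[1]]$values)),
                   "values"))
  out <- subjects[[1]]
  out$values <- colMeans(vals)
  out$sem <- if (nrow(vals) > 1L)
    apply(vals, 2L, stats::sd) / sqrt(nrow(vals))
  else rep(0, ncol(vals))
  out
}

#' Export a cross-correlation function as TSV (lag_s, r, sem)
#' @param cc an `xcorr_fn` (with or without `sem`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ccf_tsv <- function(cc, path) {
  df <- data.frame(lag_s = cc$lags_seconds, r = cc$values,
                   sem = if (is.null(cc$sem)) NA_real_ else cc$sem)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a parcel map as TSV (parcel_id, parcel_name, value)
#' @param map named numeric vector from [gbold_presence()] or
#'   [rbold_csf_coupling()].
#' @param geometry the [surface_geometry()] whose parcel table names the
#'   map entries.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_parcel_map_tsv <- function(map, geometry, path) {
  pt <- geometry$parcel_table
  df <- data.frame(parcel_id = pt$parcel_id, parcel_name = pt$parcel_name,
                   value = unname(map[pt$parcel_name]))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
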