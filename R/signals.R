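# Temporal filtering, standardization, and signal extraction: the gBOLD
# signal (spatial mean of z-normalized courses), the CSF inflow signal,
# parcel means, and the gBOLD amplitude metric.

#' Zero-phase infra-slow bandpass filter
#'
#' Band-limits every unit's time course to `[low_hz, high_hz]` with a
#' forward-backward (zero-phase) Butterworth filter, order 2 per pass.
#' Zero-phase filtering is essential here: the coupling analysis reads
#' correlation values at specific lags, and a causal filter would shift
#' them. The default band 0.01-0.1 Hz isolates the infra-slow range where
#' global BOLD activity lives.
#'
#' The run must be long enough for the filter transient: at least three
#' cycles of `low_hz`.
#'
#' @param x a `bold_run`, `signal1d`, or numeric matrix/vector.
#' @param low_hz,high_hz band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < Nyquist`.
#' @param tr_seconds sampling interval; taken from `x` when it carries one.
#' @return Object of the same type as `x`, filtered per unit.
#' @export
bandpass <- function(x, low_hz = 0.01, high_hz = 0.1, tr_seconds = NULL) {
  UseMethod("bandpass")
}

#' @export
bandpass.bold_run <- function(x, low_hz = 0.01, high_hz = 0.1,
                              tr_seconds = NULL) {
  x$data <- bandpass_matrix(x$data, low_hz, high_hz, x$tr_seconds)
  x
}

#' @export
bandpass.signal1d <- function(x, low_hz = 0.01, high_hz = 0.1,
                              tr_seconds = NULL) {
  x$values <- drop(bandpass_matrix(matrix(x$values, nrow = 1L),
                                   low_hz, high_hz, x$tr_seconds))
  x
}

#' @export
bandpass.default <- function(x, low_hz = 0.01, high_hz = 0.1,
                             tr_seconds = NULL) {
  if (is.null(tr_seconds))
    stop("`tr_seconds` is required for plain numeric input")
  if (is.matrix(x)) {
    bandpass_matrix(x, low_hz, high_hz, tr_seconds)
  } else {
    drop(bandpass_matrix(matrix(x, nrow = 1L), low_hz, high_hz, tr_seconds))
  }
}

bandpass_matrix <- function(m, low_hz, high_hz, tr_seconds) {
  fs <- 1 / tr_seconds
  ny <- fs / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < ny))
    stop("need 0 < low_hz < high_hz < Nyquist (", ny, " Hz)")
  n <- ncol(m)
  if (n * tr_seconds < 3 / low_hz)
    stop("run too short for the filter transient: need >= 3 cycles of ",
         low_hz, " Hz (", 3 / low_hz, " s), have ", n * tr_seconds, " s")
  bf <- signal::butter(2, c(low_hz, high_hz) / ny, type = "pass")
  # remove the DC offset first: 0 Hz is outside the band, and a large
  # mean would otherwise leak into the filtfilt edge transients
  mu <- rowMeans(m)
  out <- m - mu
  for (i in seq_len(nrow(m)))
    out[i, ] <- signal::filtfilt(bf, out[i, ])
  out
}

#' Per-unit z-normalization
#'
#' Standardizes each unit's time course by subtracting its mean and
#' dividing by its standard deviation. Zero-variance units cannot be
#' standardized; they are set to all-zero and flagged (attribute
#' `zero_variance_units`), never an abort, since an empty voxel should not
#' kill a run.
#'
#' @param run a `bold_run` (or numeric matrix with `tr_seconds` ignored).
#' @return The run with per-unit mean 0 and SD 1 (flagged units all-zero).
#' @export
znorm <- function(run) {
  m <- if (inherits(run, "bold_run")) run$data else run
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, stats::sd)
  flat <- sdv == 0 | !is.finite(sdv)
  sdv[flat] <- 1
  out <- (m - mu) / sdv
  out[flat, ] <- 0
  if (inherits(run, "bold_run")) {
    run$data <- out
    attr(run, "zero_variance_units") <- which(flat)
    run
  } else {
    attr(out, "zero_variance_units") <- which(flat)
    out
  }
}

#' Extract the global BOLD (gBOLD) signal
#'
#' The gBOLD signal is the unweighted spatial mean, at each frame, of the
#' (already z-normalized) unit time courses: over all gray-matter voxels
#' for volumetric runs, or over all cortical vertices for surface runs.
#' For volumetric runs loaded with [read_volume_run()], only the
#' gray-matter units enter the mean.
#'
#' @param run a z-normalized `bold_run`.
#' @return A `signal1d` labelled `"gBOLD"`.
#' @export
extract_gbold <- function(run) {
  m <- run$data
  gray <- attr(run, "gray_units")
  if (!is.null(gray)) m <- m[gray, , drop = FALSE]
  if (nrow(m) == 0L) stop("no units to average")
  signal1d(colMeans(m), run$tr_seconds, label = "gBOLD")
}

#' Extract the CSF inflow signal
#'
#' Mean over the CSF ROI voxels (bottom acquisition slice) at each frame,
#' then z-normalized for readability; Pearson correlation downstream is
#' unaffected by the normalization.
#'
#' @param run a `bold_run` loaded with [read_volume_run()], or any
#'   `bold_run` if `csf_units` gives the rows.
#' @param masks optional [mask_set()] (unused when the run already carries
#'   a `csf_units` attribute).
#' @param csf_units optional logical/integer row selector overriding the
#'   attribute.
#' @return A `signal1d` labelled `"CSF"`.
#' @export
extract_csf <- function(run, masks = NULL, csf_units = NULL) {
  if (is.null(csf_units)) csf_units <- attr(run, "csf_units")
  if (is.null(csf_units))
    stop("no CSF unit map: load the run with read_volume_run() or pass `csf_units`")
  m <- run$data[csf_units, , drop = FALSE]
  if (nrow(m) == 0L) stop("CSF ROI selects no units")
  v <- colMeans(m)
  s <- stats::sd(v)
  if (s == 0) stop("CSF signal has zero variance")
  signal1d((v - mean(v)) / s, run$tr_seconds, label = "CSF")
}

#' Parcel-mean (regional BOLD) signals
#'
#' Averages the surface run within each parcel of the geometry's parcel
#' table, yielding one regional BOLD (rBOLD) time course per parcel in
#' declared parcel order. Vertices with parcel id 0 (medial wall /
#' unassigned) are excluded. A parcel with zero vertices yields a signal
#' flagged missing (`NULL` entry, named).
#'
#' @param run a surface `bold_run`.
#' @param geometry a [surface_geometry()].
#' @return Named list of `signal1d` (or `NULL` for empty parcels), one per
#'   row of `geometry$parcel_table`.
#' @export
parcel_means <- function(run, geometry) {
  if (nrow(run$data) != geometry$n_vertices)
    stop("run has ", nrow(run$data), " vertices; geometry declares ",
         geometry$n_vertices)
  ids <- geometry$parcel_table$parcel_id
  out <- stats::setNames(vector("list", length(ids)),
                         geometry$parcel_table$parcel_name)
  assigned <- geometry$parcel_id != 0L
  sums <- rowsum(run$data[assigned, , drop = FALSE],
                 group = geometry$parcel_id[assigned])
  counts <- table(geometry$parcel_id[assigned])
  for (k in seq_along(ids)) {
    id <- as.character(ids[k])
    if (!id %in% rownames(sums)) next  # empty parcel -> missing
    out[[k]] <- signal1d(sums[id, ] / counts[[id]], run$tr_seconds,
                         label = names(out)[k])
  }
  out
}

#' gBOLD amplitude
#'
#' Strength of global activity in one run, defined as the temporal
#' standard deviation of the gBOLD signal. Because gBOLD is the mean of
#' unit-variance voxel courses, its SD directly measures how synchronously
#' the brain fluctuates: stronger/more frequent global events give a
#' larger SD. A subject's value is the mean over that subject's runs
#' (see [run_pipeline()]); this function scores a single run.
#'
#' Note this metric is one reasonable operationalization of "amplitude";
#' envelope- or peak-based measures are alternatives (see the methods
#' vignette).
#'
#' @param gbold a `signal1d` from a single run.
#' @return Non-negative scalar.
#' @export
gbold_amplitude <- function(gbold) {
  v <- gbold$values
  sqrt(mean((v - mean(v))^2))
}
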