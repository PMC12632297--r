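#' BOLD run container
#'
#' A `bold_run` holds one resting-state fMRI run as a units-by-frames
#' matrix (units are voxels for volumetric data or vertices for
#' surface-sampled data; the frame axis is always last) together with the
#' repetition time. This is the raw material of every processing stage.
#'
#' @param data numeric matrix, `n_units x n_frames`.
#' @param tr_seconds repetition time in seconds (the study protocol uses
#'   0.8 s).
#' @param space either `"surface"` or `"volume_graymatter"`.
#' @param run_label free-text run identifier, e.g. `"AP1"`.
#'
#' @return An object of class `bold_run` with elements `data`,
#'   `tr_seconds`, `space`, `run_label`.
#' @export
bold_run <- function(data, tr_seconds,
                     space = c("surface", "volume_graymatter"),
                     run_label = "run") {
  space <- match.arg(space)
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix (units x frames)")
  if (ncol(data) < 2L)
    stop("a bold_run needs at least 2 frames")
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L ||
      !is.finite(tr_seconds) || tr_seconds <= 0)
    stop("`tr_seconds` must be a single positive number")
  if (anyNA(data) || any(!is.finite(data)))
    stop("`data` contains missing or non-finite values")
  structure(
    list(data = data, tr_seconds = tr_seconds, space = space,
         run_label = run_label),
    class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf("<bold_run '%s'> %d units x %d frames, TR = %g s, space = %s\n",
              x$run_label, nrow(x$data), ncol(x$data), x$tr_seconds, x$space))
  invisible(x)
}

#' @export
dim.bold_run <- function(x) dim(x$data)

#' Single time course at fixed TR
#'
#' Container for one signal sampled at the fMRI frame rate: the gBOLD
#' signal, the CSF inflow signal, or a parcel mean.
#'
#' @param values numeric vector, one value per frame.
#' @param tr_seconds repetition time in seconds.
#' @param label free-text description.
#' @return An object of class `signal1d`.
#' @export
signal1d <- function(values, tr_seconds, label = "") {
  if (!is.numeric(values) || length(values) < 2L)
    stop("`values` must be a numeric vector of length >= 2")
  if (any(!is.finite(values)))
    stop("`values` contains non-finite entries")
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0)
    stop("`tr_seconds` must be a single positive number")
  structure(list(values = as.numeric(values), tr_seconds = tr_seconds,
                 label = label),
            class = "signal1d")
}

#' @export
print.signal1d <- function(x, ...) {
  cat(sprintf("<signal1d '%s'> %d frames, TR = %g s, sd = %.4g\n",
              x$label, length(x$values), x$tr_seconds, stats::sd(x$values)))
  invisible(x)
}

#' @export
length.signal1d <- function(x) length(x$values)

#' Volumetric mask pair: gray matter and bottom-slice CSF ROI
#'
#' Both masks are logical 3-D arrays on the acquisition grid. The CSF
#' inflow ROI must lie entirely within the declared bottom slice of the
#' acquisition (where inflowing unsaturated fluid produces the strongest
#' signal), which is validated here rather than computed: drawing the ROI
#' is an upstream manual step.
#'
#' @param gray_matter logical 3-D array.
#' @param csf_roi logical 3-D array, same grid.
#' @param bottom_slice index of the bottom acquisition slice along the
#'   third axis (default 1).
#' @return An object of class `mask_set`.
#' @export
mask_set <- function(gray_matter, csf_roi, bottom_slice = 1L) {
  if (!is.array(gray_matter) || length(dim(gray_matter)) != 3L)
    stop("`gray_matter` must be a 3-D array")
  if (!is.array(csf_roi) || !identical(dim(csf_roi), dim(gray_matter)))
    stop("`csf_roi` must be a 3-D array on the same grid as `gray_matter`")
  gray_matter <- gray_matter != 0
  csf_roi <- csf_roi != 0
  if (!any(gray_matter)) stop("gray-matter mask is empty")
  if (!any(csf_roi)) stop("CSF ROI mask is empty")
  slice_idx <- slice.index(csf_roi, 3L)
  if (any(slice_idx[csf_roi] != bottom_slice))
    stop("CSF ROI must lie entirely within the bottom acquisition slice")
  structure(list(gray_matter = gray_matter, csf_roi = csf_roi,
                 bottom_slice = as.integer(bottom_slice)),
            class = "mask_set")
}

#' Surface geometry: per-vertex principal-gradient score and parcel id
#'
#' The principal gradient (PG) orders cortex from unimodal sensory-motor
#' (low scores) to transmodal default-mode regions (high scores); it is an
#' input map here, derived upstream from connectivity embedding. Parcel id
#' 0 marks unassigned vertices (medial wall); other ids must reference the
#' declared parcel table (DKT-68 style, 68 cortical parcels by default).
#'
#' @param pg_score numeric vector, one finite score per vertex.
#' @param parcel_id integer vector, same length; 0 = unassigned.
#' @param parcel_table data.frame with columns `parcel_id`, `parcel_name`;
#'   defaults to generic names for the ids present.
#' @return An object of class `surface_geometry`.
#' @export
surface_geometry <- function(pg_score, parcel_id = NULL, parcel_table = NULL) {
  if (!is.numeric(pg_score) || any(!is.finite(pg_score)))
    stop("`pg_score` must be a numeric vector of finite values")
  n <- length(pg_score)
  if (is.null(parcel_id)) parcel_id <- integer(n)
  parcel_id <- as.integer(parcel_id)
  if (length(parcel_id) != n)
    stop("`parcel_id` must have one entry per vertex")
  ids <- sort(unique(parcel_id[parcel_id != 0L]))
  if (is.null(parcel_table)) {
    parcel_table <- data.frame(parcel_id = ids,
                               parcel_name = sprintf("parcel_%03d", ids))
  }
  if (!all(ids %in% parcel_table$parcel_id))
    stop("parcel ids present in `parcel_id` missing from `parcel_table`")
  structure(list(n_vertices = n, pg_score = as.numeric(pg_score),
                 parcel_id = parcel_id, parcel_table = parcel_table),
            class = "surface_geometry")
}

#' @export
print.surface_geometry <- function(x, ...) {
  cat(sprintf("<surface_geometry> %d vertices, %d parcels, PG range [%.3g, %.3g]\n",
              x$n_vertices, nrow(x$parcel_table),
              min(x$pg_score), max(x$pg_score)))
  invisible(x)
}

#' Cohort statistic result
#'
#' Uniform container for every test the cohort-statistics stage reports.
#'
#' @param test name of the test.
#' @param statistic test statistic.
#' @param p p-value.
#' @param estimate effect estimate (mean difference, r, or slope).
#' @param n sample size(s) used.
#' @param ... extra named fields (e.g. `collinear`).
#' @return An object of class `stat_result`.
#' @export
stat_result <- function(test, statistic, p, estimate = NA_real_, n = NA, ...) {
  structure(list(test = test, statistic = statistic, p = p,
                 estimate = estimate, n = n, ...),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s: statistic = %.4g, p = %.4g, estimate = %.4g (n = %s)\n",
              x$test, x$statistic, x$p, x$estimate,
              paste(x$n, collapse = "/")))
  invisible(x)
}
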