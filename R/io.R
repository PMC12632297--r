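# Readers and writers for every external representation the pipeline
# touches. No computation here beyond validation and layout; readers never
# reorder units or frames, and each reader is the inverse of the matching
# writer on generated data.

#' Read a masked 4-D NIfTI run
#'
#' Loads a 4-D functional volume, applies the mask pair, and returns the
#' masked voxels as a `bold_run` (voxel axis first, frame axis last). The
#' retained voxels are the union of the gray-matter and CSF masks, in
#' column-major (linear index) order; attributes record the voxel-to-unit
#' map so the CSF extraction can find its rows again.
#'
#' @param path path to a 4-D NIfTI file.
#' @param masks a [mask_set()] on the same grid.
#' @return A `bold_run` (space `"volume_graymatter"`) with attributes
#'   `unit_voxel` (linear voxel index per unit), `gray_units` and
#'   `csf_units` (logical per unit).
#' @export
read_volume_run <- function(path, masks) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop("expected a 4-D NIfTI volume, got ", length(d), " dimensions")
  if (!identical(d[1:3], dim(masks$gray_matter)))
    stop("mask grid ", paste(dim(masks$gray_matter), collapse = "x"),
         " does not match volume grid ", paste(d[1:3], collapse = "x"))
  tr <- RNifti::pixdim(img)[4]
  if (!is.finite(tr) || tr <= 0)
    stop("non-positive TR in NIfTI header")
  keep <- which(masks$gray_matter | masks$csf_roi)
  vol <- matrix(as.numeric(img), prod(d[1:3]), d[4])
  run <- bold_run(vol[keep, , drop = FALSE], tr_seconds = tr,
                  space = "volume_graymatter",
                  run_label = sub("\\.nii(\\.gz)?$", "", basename(path)))
  attr(run, "unit_voxel") <- keep
  attr(run, "gray_units") <- masks$gray_matter[keep]
  attr(run, "csf_units") <- masks$csf_roi[keep]
  run
}

#' Write a 4-D array as NIfTI (fixture writer)
#'
#' @param arr4d numeric 4-D array (x, y, z, frame).
#' @param path output path (`.nii`).
#' @param tr_seconds repetition time stored in the header.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(arr4d, path, tr_seconds) {
  stopifnot(length(dim(arr4d)) == 4L)
  img <- RNifti::asNifti(arr4d)
  RNifti::pixdim(img) <- c(1, 1, 1, tr_seconds)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a surface-sampled run from a dense matrix file
#'
#' Surface time series are accepted as a plain dense matrix file
#' (tab-separated, vertices in rows, frames in columns, no header). The
#' vertex count must equal the geometry's.
#'
#' @param path path to the matrix file.
#' @param geometry a [surface_geometry()].
#' @param tr_seconds repetition time (not stored in the plain format).
#' @param run_label run identifier.
#' @return A `bold_run` with space `"surface"`.
#' @export
read_surface_run <- function(path, geometry, tr_seconds = 0.8,
                             run_label = NULL) {
  m <- as.matrix(utils::read.table(path, header = FALSE, sep = "\t"))
  dimnames(m) <- NULL
  if (nrow(m) != geometry$n_vertices)
    stop("file has ", nrow(m), " vertices but geometry declares ",
         geometry$n_vertices)
  if (is.null(run_label))
    run_label <- sub("\\.[^.]*$", "", basename(path))
  bold_run(m, tr_seconds = tr_seconds, space = "surface",
           run_label = run_label)
}

#' Write a surface run as a dense matrix file
#'
#' @param run a `bold_run`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_surface_run <- function(run, path) {
  utils::write.table(run$data, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read rigid-body realignment parameters
#'
#' Whitespace- or tab-separated table with at least six columns, one row
#' per frame, in the FSL/HCP "Movement_Regressors" column order: three
#' translations (mm) then three rotations (radians by default). Extra
#' columns (e.g. parameter derivatives) are ignored.
#'
#' @param path path to the table.
#' @return A numeric `T x 6` matrix of class `motion_params` with columns
#'   `tx, ty, tz, rx, ry, rz`.
#' @export
read_motion_params <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) < 6L)
    stop("motion parameter file has ", ncol(m), " columns; need >= 6")
  m <- m[, 1:6, drop = FALSE]
  motion_params(m)
}

#' Motion parameter container
#'
#' @param m numeric `T x 6` matrix: translations (mm) then rotations
#'   (radians).
#' @return `m` with class `motion_params` and standard column names.
#' @export
motion_params <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) != 6L) stop("motion parameters must have exactly 6 columns")
  if (any(!is.finite(m))) stop("non-finite motion parameters")
  dimnames(m) <- list(NULL, c("tx", "ty", "tz", "rx", "ry", "rz"))
  class(m) <- c("motion_params", "matrix", "array")
  m
}

#' Write motion parameters
#' @param mp a `motion_params` matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_motion_params <- function(mp, path) {
  utils::write.table(unclass(mp), path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' Tab-separated with a header row. Mandatory columns: `subject_id`,
#' `age_at_mri`, `age_at_menopause`. Optional: `education_years`, `bmi`,
#' `psmt_score`, `ravlt_score`. Missing scores may be encoded as empty
#' cells, `NaN`, or the sentinel 999, all of which become `NA` in the
#' score columns. Rows reporting an age at menopause later than the age at
#' MRI are physiologically impossible (a last period after the scan) and
#' are flagged in the `excluded` column rather than dropped, so callers
#' can report exclusion counts.
#'
#' @param path path to the TSV file.
#' @return A data.frame of class `phenotype_table` with an added logical
#'   `excluded` column.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  mandatory <- c("subject_id", "age_at_mri", "age_at_menopause")
  miss <- setdiff(mandatory, names(df))
  if (length(miss))
    stop("phenotype table missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(df$subject_id))
    stop("duplicated subject_id in phenotype table")
  score_cols <- intersect(c("psmt_score", "ravlt_score"), names(df))
  for (sc in score_cols) {
    v <- suppressWarnings(as.numeric(df[[sc]]))
    v[!is.na(v) & v == 999] <- NA_real_
    v[is.nan(v)] <- NA_real_
    df[[sc]] <- v
  }
  df$excluded <- !is.na(df$age_at_menopause) & !is.na(df$age_at_mri) &
    df$age_at_menopause > df$age_at_mri
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Write a phenotype table
#' @param df phenotype data.frame (the `excluded` column, if present, is
#'   not written).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(df, path) {
  df <- as.data.frame(df)
  df$excluded <- NULL
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Export a 1-D signal as two-column TSV (frame_time_s, value)
#' @param sig a `signal1d`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signal_tsv <- function(sig, path) {
  df <- data.frame(
    frame_time_s = (seq_along(sig$values) - 1L) * sig$tr_seconds,
    value = sig$values)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
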