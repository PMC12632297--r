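# Head-motion metrics: framewise displacement and session-mean FD, plus
# the confound check re-testing metrics after motion adjustment.

#' Framewise displacement
#'
#' For each frame transition i -> i+1, FD is the sum of the absolute
#' increments of all six rigid-body realignment parameters:
#' `FD_i = |d tx| + |d ty| + |d tz| + |d rx| + |d ry| + |d rz|`.
#' Rotation increments (radians) are summed directly with translations
#' (mm), with no 50-mm sphere conversion, so the value mixes units; this
#' matches the common summed-parameter FD variant used when FD serves as
#' a relative quality index rather than a physical distance. The session
#' mean mFD summarizes one run/session.
#'
#' @param mp a [motion_params()] matrix (`T x 6`, T >= 2).
#' @return An object of class `fd_series`: `fd` (length T-1), `mfd`.
#' @export
framewise_displacement <- function(mp) {
  m <- unclass(mp)
  if (!is.matrix(m) || ncol(m) != 6L)
    stop("motion parameters must be a T x 6 matrix")
  if (nrow(m) < 2L) stop("need at least 2 frames for FD")
  fd <- rowSums(abs(diff(m)))
  structure(list(fd = fd, mfd = mean(fd)), class = "fd_series")
}

#' @export
print.fd_series <- function(x, ...) {
  cat(sprintf("<fd_series> %d transitions, mFD = %.4g\n",
              length(x$fd), x$mfd))
  invisible(x)
}

#' Motion-confound check for a subject-level metric
#'
#' Asks whether head motion could explain a metric's group difference or
#' correlation: (1) correlates the metric with mFD across subjects,
#' (2) compares mFD between two groups if given, and (3) re-tests the
#' metric after residualizing mFD out of it. If the metric's association
#' with a confounded driver is genuine, it survives the adjustment; the
#' partial correlation of the adjusted metric with mFD is ~0 by
#' construction.
#'
#' @param metric numeric per subject.
#' @param mfd session-mean FD per subject.
#' @param groups optional factor/character with exactly two levels for the
#'   group comparison.
#' @return List of [stat_result()] objects: `metric_vs_mfd`,
#'   `mfd_group_test` (when `groups` given), `adjusted_group_test` /
#'   `adjusted_metric` (residuals).
#' @export
motion_adjustment_check <- function(metric, mfd, groups = NULL) {
  out <- list(metric_vs_mfd = correlate(metric, mfd))
  if (stats::sd(mfd) == 0) {
    adjusted <- metric - mean(metric)
  } else {
    adjusted <- stats::resid(stats::lm(metric ~ mfd))
  }
  out$adjusted_metric <- as.numeric(adjusted)
  if (!is.null(groups)) {
    g <- factor(groups)
    if (nlevels(g) != 2L) stop("`groups` must have exactly two levels")
    lv <- levels(g)
    out$mfd_group_test <- if (stats::sd(mfd) == 0)
      stat_result("two_sample_t", statistic = NA_real_, p = NA_real_,
                  n = as.integer(table(g)))
    else two_sample_t(mfd[g == lv[1]], mfd[g == lv[2]])
    out$adjusted_group_test <-
      two_sample_t(adjusted[g == lv[1]], adjusted[g == lv[2]])
  }
  out
}

#' Export a framewise-displacement series as TSV
#' @param fd an `fd_series`.
#' @param path output path.
#' @param tr_seconds optional TR to add a time column.
#' @return `path`, invisibly.
#' @export
write_fd_tsv <- function(fd, path, tr_seconds = NULL) {
  df <- data.frame(transition = seq_along(fd$fd), fd = fd$fd)
  if (!is.null(tr_seconds))
    df$time_s <- (df$transition - 1L) * tr_seconds
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
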