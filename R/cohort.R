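# Cohort construction and every statistical comparison the analysis
# reports: menopause-timing groups with MRI-age overlap matching, age
# residualization, two-sample t-tests, one-way ANOVA, ordinal trend
# regression, Pearson correlation, and the wave-memory regression model.

#' Build menopause-timing groups with MRI-age overlap matching
#'
#' Reproduces the cohort-construction flow: (1) split subjects into two
#' groups at `split_age` (age at menopause below vs at-or-above, the U.S.
#' average menopause age of 51 by default); (2) find the overlapping range
#' of the two groups' ages at MRI; (3) exclude subjects whose age at MRI
#' falls outside that range (this matches the groups on scan age);
#' (4) sort the remaining subjects by age at menopause (ties by
#' subject id) and cut them into `n_groups` equal-size ordered groups
#' (earlier / intermediate / later menopause). When the remaining count is
#' not divisible by `n_groups`, the earlier groups take the extra subject
#' (sizes differ by at most one).
#'
#' Rows already flagged `excluded` (impossible age ordering) are dropped
#' first. The result is deterministic and invariant to input row order.
#'
#' @param ph a [read_phenotypes()] table (or compatible data.frame).
#' @param split_age menopause-age split point (default 51).
#' @param n_groups number of ordered groups (default 3).
#' @return The included subjects as a data.frame with an ordered factor
#'   column `group` (levels `earlier < intermediate < later` for 3
#'   groups), sorted by (age at menopause, subject id). Attributes:
#'   `overlap_range`, `n_excluded_overlap`, `n_input`.
#' @export
assign_groups <- function(ph, split_age = 51, n_groups = 3) {
  ph <- as.data.frame(ph)
  if (!is.null(ph$excluded)) ph <- ph[!ph$excluded, , drop = FALSE]
  n_input <- nrow(ph)
  early <- ph$age_at_menopause < split_age
  if (!any(early) || all(early))
    stop("the menopause-age split at ", split_age,
         " leaves one side empty")
  lo <- max(min(ph$age_at_mri[early]), min(ph$age_at_mri[!early]))
  hi <- min(max(ph$age_at_mri[early]), max(ph$age_at_mri[!early]))
  inside <- ph$age_at_mri >= lo & ph$age_at_mri <= hi
  kept <- ph[inside, , drop = FALSE]
  kept <- kept[order(kept$age_at_menopause, kept$subject_id), , drop = FALSE]
  n <- nrow(kept)
  if (n < n_groups) stop("too few subjects (", n, ") for ", n_groups,
                         " groups")
  base <- n %/% n_groups
  sizes <- rep(base, n_groups) + (seq_len(n_groups) <= n %% n_groups)
  lev <- if (n_groups == 3) c("earlier", "intermediate", "later")
         else paste0("g", seq_len(n_groups))
  kept$group <- factor(rep(lev, times = sizes), levels = lev,
                       ordered = TRUE)
  rownames(kept) <- NULL
  attr(kept, "overlap_range") <- c(lo, hi)
  attr(kept, "n_excluded_overlap") <- n_input - n
  attr(kept, "n_input") <- n_input
  kept
}

#' Residualize the linear effect of age at MRI
#'
#' Ordinary least squares of the measure on (intercept, age); returns the
#' residuals, which are exactly orthogonal to age. `NA` measures give `NA`
#' residuals and do not enter the fit.
#'
#' @param values numeric measure per subject.
#' @param ages age at MRI per subject.
#' @return Numeric residuals, same length as `values`.
#' @export
residualize_age <- function(values, ages) {
  if (length(values) != length(ages))
    stop("`values` and `ages` must have equal length")
  fit <- stats::lm(values ~ ages, na.action = stats::na.exclude)
  as.numeric(stats::resid(fit))
}

#' Classical two-sample t-test (pooled variance)
#'
#' @param x,y numeric samples (NA dropped).
#' @return A [stat_result()] with the t statistic, two-sided p, and the
#'   mean difference `mean(x) - mean(y)`.
#' @export
two_sample_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  ht <- stats::t.test(x, y, var.equal = TRUE)
  stat_result("two_sample_t", statistic = unname(ht$statistic),
              p = ht$p.value, estimate = mean(x) - mean(y),
              n = c(length(x), length(y)))
}

#' One-way ANOVA across groups
#'
#' @param values numeric measure per subject.
#' @param groups factor/character group labels.
#' @return A [stat_result()] with the F statistic and p.
#' @export
anova_oneway <- function(values, groups) {
  g <- factor(groups)
  keep <- !is.na(values)
  ht <- stats::oneway.test(values[keep] ~ g[keep], var.equal = TRUE)
  stat_result("anova_oneway", statistic = unname(ht$statistic),
              p = ht$p.value, n = as.integer(table(g[keep])))
}

#' Ordinal trend test across ordered menopause-timing groups
#'
#' Tests for a linear relationship between the (age-adjusted) metric and
#' menopause timing. The ordered group is coded numerically (1, 2, 3 for
#' earlier/intermediate/later) and used as the predictor in an ordinary
#' linear regression of the metric; the slope's two-sided p is reported.
#' With `predictor = "menopause_age"` the raw age at menopause replaces
#' the group code.
#'
#' @param values numeric metric per subject.
#' @param groups ordered factor of group labels.
#' @param predictor `"group_rank"` (default) or `"menopause_age"`.
#' @param menopause_age required when `predictor = "menopause_age"`.
#' @return A [stat_result()] with the slope (estimate), its t statistic
#'   and p.
#' @export
ordinal_trend <- function(values, groups,
                          predictor = c("group_rank", "menopause_age"),
                          menopause_age = NULL) {
  predictor <- match.arg(predictor)
  x <- if (predictor == "group_rank") as.numeric(factor(groups,
         levels = levels(factor(groups)), ordered = FALSE))
       else {
         if (is.null(menopause_age))
           stop("`menopause_age` required for predictor = \"menopause_age\"")
         menopause_age
       }
  fit <- stats::lm(values ~ x)
  sm <- summary(fit)$coefficients
  stat_result("ordinal_trend", statistic = sm["x", "t value"],
              p = sm["x", "Pr(>|t|)"], estimate = sm["x", "Estimate"],
              n = sum(!is.na(values)))
}

#' Pearson correlation with two-sided p
#'
#' @param x,y numeric vectors (pairwise-complete).
#' @return A [stat_result()] with r as the estimate.
#' @export
correlate <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  if (stats::sd(x[keep]) == 0 || stats::sd(y[keep]) == 0)
    return(stat_result("pearson_correlation", statistic = NA_real_,
                       p = NA_real_, estimate = NA_real_, n = sum(keep)))
  ht <- stats::cor.test(x[keep], y[keep])
  stat_result("pearson_correlation", statistic = unname(ht$statistic),
              p = ht$p.value, estimate = unname(ht$estimate),
              n = sum(keep))
}

#' Wave-activation vs memory regression
#'
#' Multiple linear regression with age at MRI and the memory task score as
#' predictors and the propagation intensity (wave activation) as the
#' response; reports the task-score coefficient and its two-sided p.
#' Collinear predictors (rank-deficient design) are flagged in the result
#' (`collinear = TRUE`, statistic `NA`), never silently dropped.
#'
#' @param activation propagation intensity per subject (response).
#' @param age age at MRI per subject.
#' @param score memory task score per subject.
#' @return A [stat_result()] for the score coefficient, with a
#'   `collinear` flag.
#' @export
wave_memory_model <- function(activation, age, score) {
  keep <- !is.na(activation) & !is.na(age) & !is.na(score)
  X <- cbind(1, age[keep], score[keep])
  collinear <- qr(X)$rank < ncol(X)
  if (collinear) {
    return(stat_result("wave_memory_model", statistic = NA_real_,
                       p = NA_real_, estimate = NA_real_, n = sum(keep),
                       collinear = TRUE))
  }
  fit <- stats::lm(activation[keep] ~ age[keep] + score[keep])
  sm <- summary(fit)$coefficients
  stat_result("wave_memory_model", statistic = sm[3, "t value"],
              p = sm[3, "Pr(>|t|)"], estimate = sm[3, "Estimate"],
              n = sum(keep), collinear = FALSE)
}

#' Drop subjects with missing or sentinel-coded task scores
#'
#' Removes records whose score is `NA`, `NaN`, or the sentinel 999 (the
#' missing-data coding of the source questionnaires).
#'
#' @param records data.frame of subject records.
#' @param score_name column name of the score.
#' @return The records with offending rows removed.
#' @export
exclude_missing_scores <- function(records, score_name) {
  v <- records[[score_name]]
  if (is.null(v)) stop("no column `", score_name, "` in records")
  keep <- !is.na(v) & v != 999
  records[keep, , drop = FALSE]
}
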