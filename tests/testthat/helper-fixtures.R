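# Shared fixtures and independent brute-force oracles. All fixtures are
# generated in code under fixed seeds; nothing is read from disk.

make_run <- function(n_units = 20, n_frames = 60, tr = 0.8, seed = 1,
                     space = "surface") {
  set.seed(seed)
  bold_run(matrix(rnorm(n_units * n_frames), n_units, n_frames),
           tr_seconds = tr, space = space)
}

make_sig <- function(values, tr = 0.8, label = "sig") {
  signal1d(values, tr_seconds = tr, label = label)
}

# explicit-slicing Pearson cross-correlation, independent of xcorr()
bf_xcorr <- function(x, y, kmax) {
  n <- length(x)
  sapply(-kmax:kmax, function(k) {
    if (k >= 0) { a <- x[1:(n - k)]; b <- y[(1 + k):n] }
    else { a <- x[(1 - k):n]; b <- y[1:(n + k)] }
    ma <- sum(a) / length(a); mb <- sum(b) / length(b)
    sum((a - ma) * (b - mb)) /
      sqrt(sum((a - ma)^2) * sum((b - mb)^2))
  })
}

# brute-force framewise displacement: explicit double loop
bf_fd <- function(mp) {
  out <- numeric(nrow(mp) - 1)
  for (i in seq_len(nrow(mp) - 1)) {
    s <- 0
    for (j in 1:6) s <- s + abs(mp[i + 1, j] - mp[i, j])
    out[i] <- s
  }
  out
}

# all permutations of a vector (small n only)
all_perms <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], p)
  out
}

# hand-built peak_table for classification tests
fake_peak_table <- function(delays) {
  structure(list(delay_seconds = delays,
                 peak_frame = rep(NA_integer_, length(delays)),
                 involvement_fraction = mean(!is.na(delays))),
            class = "peak_table")
}

fake_segment <- function(start = 1L, end = 50L, peak = 25L) {
  list(start_frame = as.integer(start), end_frame = as.integer(end),
       gbold_peak_frame = as.integer(peak))
}

# Crafted 124-row phenotype table reproducing the cohort-construction
# flow: split at menopause age 51, MRI-age overlap [52.9, 66.5], exactly
# 34 excluded, 90 retained, tertiles of 30.
crafted_phenotypes_124 <- function(shuffle_seed = NULL) {
  # group A: menopause < 51 (60 subjects): 14 with MRI age below 52.9,
  # 46 inside [52.9, 66.5] (one at exactly 66.5 to set the upper edge)
  a_meno <- seq(38, 50.9, length.out = 60)
  a_mri <- c(seq(47, 52.8, length.out = 14),
             seq(53, 66.5, length.out = 46))
  # group B: menopause >= 51 (64 subjects): 44 inside (one at exactly
  # 52.9 to set the lower edge), 20 above 66.5
  b_meno <- seq(51, 56.4, length.out = 64)
  b_mri <- c(seq(52.9, 66.4, length.out = 44),
             seq(66.6, 78, length.out = 20))
  df <- data.frame(
    subject_id = sprintf("sub-%03d", 1:124),
    age_at_menopause = c(a_meno, b_meno),
    age_at_mri = c(a_mri, b_mri))
  df$age_at_mri <- pmax(df$age_at_mri, df$age_at_menopause + 0.5)
  if (!is.null(shuffle_seed)) {
    set.seed(shuffle_seed)
    df <- df[sample(nrow(df)), ]
  }
  df
}

# small, quick simulated run for wave tests
quick_cfg <- function(...) {
  sim_config(n_vertices = 350L, n_frames = 478L, ...)
}
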