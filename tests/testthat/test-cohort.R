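test_that("group assignment: split, overlap exclusion, equal tertiles", {
  # crafted 12-subject table: MRI-age overlap [53, 66] excludes 3 of 12
  ph <- data.frame(
    subject_id = sprintf("s%02d", 1:12),
    age_at_menopause = c(44, 46, 47, 48, 49, 50, 51, 52, 53, 54, 55, 56),
    age_at_mri = c(50, 52, 55, 60, 64, 66, 53, 58, 61, 63, 65, 70))
  g <- assign_groups(ph)
  expect_equal(nrow(g), 9)
  expect_equal(attr(g, "n_excluded_overlap"), 3)
  expect_equal(attr(g, "overlap_range"), c(53, 66))
  expect_equal(as.integer(table(g$group)), c(3, 3, 3))
  # groups ordered by menopause age
  expect_true(max(g$age_at_menopause[g$group == "earlier"]) <=
              min(g$age_at_menopause[g$group == "intermediate"]))

  # degenerate menopause ages: tie-broken by subject id, sizes equal
  ph2 <- ph
  ph2$age_at_menopause <- c(rep(50, 6), rep(52, 6))
  g2 <- assign_groups(ph2)
  expect_equal(as.integer(table(g2$group)), c(3, 3, 3))
  expect_equal(g2$subject_id, sort(g2$subject_id))
})

test_that("group assignment is invariant to input row order", {
  ph <- crafted_phenotypes_124()
  g1 <- assign_groups(ph)
  g2 <- assign_groups(crafted_phenotypes_124(shuffle_seed = 99))
  expect_equal(g1$subject_id, g2$subject_id)
  expect_equal(g1$group, g2$group)
})

test_that("the 124-subject flow reproduces 90 retained and 30/30/30", {
  ph <- crafted_phenotypes_124()
  g <- assign_groups(ph, split_age = 51, n_groups = 3)
  expect_equal(attr(g, "n_input"), 124)
  expect_equal(attr(g, "n_excluded_overlap"), 34)
  expect_equal(nrow(g), 90)
  expect_equal(as.integer(table(g$group)), c(30, 30, 30))
  expect_equal(attr(g, "overlap_range"), c(52.9, 66.5))
})

test_that("age residualization is orthogonal to age", {
  set.seed(61)
  ages <- rnorm(50, 59, 4)
  v <- rnorm(50)
  r <- residualize_age(v, ages)
  expect_lt(abs(sum(r * ages)), 1e-10)
  expect_lt(abs(sum(r)), 1e-10)

  expect_lt(max(abs(residualize_age(2 * ages, ages))), 1e-10)

  # uncorrelated values: residuals ~ centered values
  v2 <- rnorm(2000)
  ages2 <- rnorm(2000, 59, 4)
  expect_equal(residualize_age(v2, ages2), v2 - mean(v2),
               tolerance = 0.05)

  # NA handling: NA in, NA out, others unaffected by the NA row
  v3 <- c(v[1:10], NA, v[12:50])
  r3 <- residualize_age(v3, ages)
  expect_true(is.na(r3[11]))
  expect_equal(length(r3), 50)
})

test_that("pooled t-test matches the closed form on a 3+3 toy sample", {
  x <- c(1, 2, 3); y <- c(2, 4, 6)
  res <- two_sample_t(x, y)
  sp2 <- (2 * var(x) + 2 * var(y)) / 4
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(t_hand), df = 4), tolerance = 1e-12)
  expect_equal(res$estimate, -2)
  expect_equal(res$n, c(3, 3))

  same <- two_sample_t(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  swap <- two_sample_t(y, x)
  expect_equal(swap$statistic, -res$statistic, tolerance = 1e-12)
})

test_that("one-way ANOVA: F = t^2 for two groups, closed form for three", {
  set.seed(62)
  x <- rnorm(10); y <- rnorm(12)
  a <- anova_oneway(c(x, y), rep(c("a", "b"), c(10, 12)))
  t2 <- two_sample_t(x, y)$statistic^2
  expect_equal(a$statistic, t2, tolerance = 1e-12)

  z <- rnorm(8)
  vals <- c(x, y, z); grp <- rep(c("a", "b", "c"), c(10, 12, 8))
  a3 <- anova_oneway(vals, grp)
  # hand-computed F
  gm <- mean(vals)
  ssb <- 10 * (mean(x) - gm)^2 + 12 * (mean(y) - gm)^2 +
    8 * (mean(z) - gm)^2
  ssw <- sum((x - mean(x))^2) + sum((y - mean(y))^2) +
    sum((z - mean(z))^2)
  f_hand <- (ssb / 2) / (ssw / 27)
  expect_equal(a3$statistic, f_hand, tolerance = 1e-12)
  expect_equal(a3$p, pf(f_hand, 2, 27, lower.tail = FALSE),
               tolerance = 1e-12)

  flat <- anova_oneway(rep(c(1, 2, 3), 3),
                       rep(c("a", "b", "c"), each = 3))
  expect_equal(flat$statistic, 0, tolerance = 1e-12)
})

test_that("ordinal trend test: flat, monotone, and order reversal", {
  g <- factor(rep(c("earlier", "intermediate", "later"), each = 3),
              levels = c("earlier", "intermediate", "later"),
              ordered = TRUE)
  flat <- ordinal_trend(rep(c(1, 2, 3), 3), g)
  expect_equal(flat$estimate, 0, tolerance = 1e-12)
  expect_equal(flat$p, 1, tolerance = 1e-12)

  set.seed(63)
  mono <- ordinal_trend(as.numeric(g) + rnorm(9, 0, 0.01), g)
  expect_lt(mono$p, 0.01)
  expect_gt(mono$estimate, 0)

  rev_g <- factor(as.character(g),
                  levels = c("later", "intermediate", "earlier"),
                  ordered = TRUE)
  vals <- as.numeric(g) + rnorm(9, 0, 0.2)
  expect_equal(ordinal_trend(vals, rev_g)$estimate,
               -ordinal_trend(vals, g)$estimate, tolerance = 1e-12)

  # menopause age as the alternative predictor
  meno <- c(44, 45, 46, 50, 50, 51, 53, 54, 55)
  alt <- ordinal_trend(vals, g, predictor = "menopause_age",
                       menopause_age = meno)
  fit <- lm(vals ~ meno)
  expect_equal(alt$estimate, unname(coef(fit)[2]), tolerance = 1e-12)
})

test_that("correlation: closed form on 5 points, identity, null band", {
  x <- c(1, 2, 4, 5, 9); y <- c(2, 1, 5, 4, 8)
  res <- correlate(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$estimate, r_hand, tolerance = 1e-12)
  t_hand <- r_hand * sqrt(3 / (1 - r_hand^2))
  expect_equal(res$p, 2 * pt(-abs(t_hand), 3), tolerance = 1e-12)

  expect_equal(correlate(x, x)$estimate, 1)

  set.seed(64)
  a <- rnorm(200); b <- rnorm(200)
  expect_lt(abs(correlate(a, b)$estimate), 3.5 / sqrt(200))
})

test_that("wave-memory regression recovers planted coefficients, flags collinearity", {
  set.seed(65)
  n <- 120
  age <- rnorm(n, 59, 4)
  score <- rnorm(n, 95, 12)
  activation <- 0.5 + 0.02 * age + 0.04 * score + rnorm(n, 0, 0.3)
  res <- wave_memory_model(activation, age, score)
  se <- 0.3 / sqrt(sum((score - mean(score))^2))  # approx coefficient SE
  expect_lt(abs(res$estimate - 0.04), 4 * se)
  expect_false(res$collinear)

  # activation driven by age only: score coefficient indistinguishable
  # from zero
  act2 <- 1 + 0.05 * age + rnorm(n, 0, 0.2)
  res2 <- wave_memory_model(act2, age, score)
  expect_gt(res2$p, 0.01)
  expect_lt(abs(res2$estimate), 4 * 0.2 / sqrt(sum((score - mean(score))^2)))

  res3 <- wave_memory_model(activation, age, 2 * age)
  expect_true(res3$collinear)
  expect_true(is.na(res3$statistic))
})

test_that("missing-score exclusion drops 999 and NA, keeps the rest", {
  rec <- data.frame(subject_id = 1:6,
                    psmt_score = c(95, 999, NA, 80, NaN, 110))
  out <- exclude_missing_scores(rec, "psmt_score")
  expect_equal(out$subject_id, c(1, 4, 6))
  full <- data.frame(subject_id = 1:3, psmt_score = c(1, 2, 3))
  expect_equal(exclude_missing_scores(full, "psmt_score"), full)
  expect_error(exclude_missing_scores(full, "nope"), "nope")
})

test_that("t-test power on planted effects matches the noncentral t", {
  # planted 0.8 SD group effect, n = 30/group: empirical rejection rate
  # at alpha = 0.05 within Monte-Carlo error of the analytic power
  set.seed(66)
  reps <- 200
  rej <- mean(replicate(reps, {
    two_sample_t(rnorm(30, 0.8), rnorm(30))$p < 0.05
  }))
  target <- power.t.test(n = 30, delta = 0.8, sd = 1,
                         sig.level = 0.05)$power
  expect_lt(abs(rej - target), 0.05 + 2 * sqrt(target * (1 - target) / reps))
})
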