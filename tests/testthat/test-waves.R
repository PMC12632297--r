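test_that("PG binning: equal counts, mirror symmetry, ascending ranges", {
  geo <- surface_geometry(rnorm(140))
  b <- bin_by_gradient(geo, 70)
  expect_true(all(b$bin_sizes == 2))

  # reversing the sign of distinct PG scores exactly mirrors the bins
  set.seed(31)
  pg <- rnorm(350)
  b1 <- bin_by_gradient(surface_geometry(pg), 70)
  b2 <- bin_by_gradient(surface_geometry(-pg), 70)
  expect_equal(b2$bin_of_vertex, 70L + 1L - b1$bin_of_vertex)

  # arbitrary n: occupancies differ by <= 1, within-bin PG ranges ascend
  pg <- rnorm(503)
  b3 <- bin_by_gradient(surface_geometry(pg), 70)
  expect_lte(max(b3$bin_sizes) - min(b3$bin_sizes), 1)
  rng <- sapply(1:70, function(k) range(pg[b3$bin_of_vertex == k]))
  expect_true(all(rng[1, -1] >= rng[2, -70]))

  expect_error(bin_by_gradient(surface_geometry(rnorm(10)), 70), "bins")
})

test_that("bin series equals the group-by mean and is linear", {
  set.seed(32)
  geo <- surface_geometry(rnorm(30))
  b <- bin_by_gradient(geo, 30)  # one vertex per bin
  run <- make_run(30, 20, seed = 33)
  bs <- bin_series(run, b)
  ord <- order(geo$pg_score, seq_along(geo$pg_score))
  expect_equal(bs$data, run$data[ord, ], tolerance = 1e-12)

  b5 <- bin_by_gradient(geo, 5)
  bs5 <- bin_series(run, b5)
  for (k in 1:5) {
    brute <- colMeans(run$data[b5$bin_of_vertex == k, , drop = FALSE])
    expect_equal(bs5$data[k, ], brute, tolerance = 1e-12)
  }

  run2 <- make_run(30, 20, seed = 34)
  mix <- bold_run(3 * run$data + run2$data, 0.8)
  expect_equal(bin_series(mix, b5)$data,
               3 * bs5$data + bin_series(run2, b5)$data,
               tolerance = 1e-12)
})

test_that("trough segmentation matches a brute-force local-minima scan", {
  tr <- 0.8
  # one full sinusoid cycle sampled trough-to-trough: troughs at 16 s and
  # 32 s (frames 21, 41) delimit exactly one segment, peak mid-segment
  t <- (0:45) * tr
  v <- -cos(2 * pi * t / 16)
  segs <- segment_by_troughs(make_sig(v, tr))
  expect_equal(nrow(segs), 1)
  expect_equal(segs$start_frame, 21L)
  expect_equal(segs$end_frame, 41L)
  expect_equal(segs$gbold_peak_frame,
               segs$start_frame + (segs$end_frame - segs$start_frame) %/% 2)

  expect_equal(nrow(segment_by_troughs(make_sig(1:20, tr))), 0)

  set.seed(35)
  v <- drop(bandpass(rnorm(478), tr_seconds = tr))
  segs <- segment_by_troughs(make_sig(v, tr))
  interior <- 2:477
  troughs <- interior[v[interior] < v[interior - 1] &
                      v[interior] < v[interior + 1]]
  expect_equal(segs$start_frame, troughs[-length(troughs)])
  expect_equal(segs$end_frame, troughs[-1])
  for (i in seq_len(nrow(segs))) {
    f <- segs$start_frame[i]:(segs$end_frame[i] - 1)
    expect_equal(segs$gbold_peak_frame[i], f[which.max(v[f])])
    # partition: segments tile [first trough, last trough)
    if (i > 1) expect_equal(segs$start_frame[i], segs$end_frame[i - 1])
  }
})

test_that("peak table: delays relative to the gBOLD peak, exhaustive scan", {
  tr <- 0.8
  set.seed(36)
  g <- drop(bandpass(rnorm(478), tr_seconds = tr))
  segs <- segment_by_troughs(make_sig(g, tr))
  seg <- segs[which.max(segs$end_frame - segs$start_frame), ]

  # a bin equal to gBOLD has delay 0; one delayed by 2 frames, +2 TR
  shift2 <- g[((seq_len(478) - 1 - 2) %% 478) + 1]
  binned <- structure(list(data = rbind(g, shift2), tr_seconds = tr),
                      class = "binned_series")
  pt <- peak_table(binned, seg)
  expect_equal(pt$delay_seconds[1], 0)
  expect_equal(pt$delay_seconds[2], 2 * tr, tolerance = 1e-12)

  # random smooth courses: largest local peak matches an exhaustive scan
  m <- t(sapply(1:8, function(i) drop(bandpass(rnorm(478),
                                               tr_seconds = tr))))
  binned <- structure(list(data = m, tr_seconds = tr),
                      class = "binned_series")
  pt <- peak_table(binned, seg)
  frames <- seg$start_frame:(seg$end_frame - 1)
  for (b in 1:8) {
    x <- m[b, frames]
    cand <- which(seq_along(x) > 1 & seq_along(x) < length(x) &
                  x > c(NA, x[-length(x)]) & x > c(x[-1], NA))
    if (length(cand) == 0) {
      expect_true(is.na(pt$delay_seconds[b]))
    } else {
      best <- frames[cand[which.max(x[cand])]]
      expect_equal(pt$peak_frame[b], best)
      expect_equal(pt$delay_seconds[b],
                   (best - seg$gbold_peak_frame) * tr)
    }
  }
})

test_that("plateau peaks resolve to the earliest tied frame", {
  x <- c(0, 1, 3, 3, 3, 1, 0, 2, 0)
  expect_equal(infraslow:::local_maxima(x), c(3L, 8L))
  # plateaus and peaks touching segment edges never qualify
  expect_equal(infraslow:::local_maxima(c(5, 4, 3, 4, 5)), integer(0))
})

test_that("classification: perfect propagation, direction, involvement rule", {
  binning <- list(n_bins = 70L)
  seg <- fake_segment()
  up <- classify_segment(fake_peak_table(seq(-2, 2, length.out = 70)),
                         binning, seg)
  expect_equal(up$label, "bottom_up")
  expect_equal(up$r, 1)
  expect_equal(up$p, 0)

  down <- classify_segment(fake_peak_table(seq(2, -2, length.out = 70)),
                           binning, seg)
  expect_equal(down$label, "top_down")
  expect_equal(down$r, -1)

  # 80% involvement boundary: 55/70 peaked bins excluded, 56/70 retained
  d55 <- seq(-2, 2, length.out = 70); d55[1:15] <- NA
  expect_equal(classify_segment(fake_peak_table(d55), binning, seg)$label,
               "excluded_low_involvement")
  d56 <- seq(-2, 2, length.out = 70); d56[1:14] <- NA
  expect_equal(classify_segment(fake_peak_table(d56), binning, seg)$label,
               "bottom_up")

  # degenerate: fewer than 3 peaked bins
  d2 <- rep(NA_real_, 70); d2[1:2] <- c(0, 1)
  expect_equal(classify_segment(fake_peak_table(d2), binning, seg,
                                min_involvement = 0)$label,
               "excluded_low_involvement")
})

test_that("classification p-values match cor.test over all permutations", {
  # exhaustive permutation oracle at 7 bins: the label rule must agree
  # with cor.test's two-sided p for every arrangement of delays
  binning <- list(n_bins = 7L)
  seg <- fake_segment()
  d <- c(0.3, -1.1, 2.2, 0.7, -0.4, 1.5, -2.0)
  perms <- all_perms(1:7)
  labels <- character(length(perms))
  agree <- TRUE
  for (k in seq_along(perms)) {
    e <- classify_segment(fake_peak_table(d[perms[[k]]]), binning, seg)
    ct <- suppressWarnings(cor.test(d[perms[[k]]], 1:7))
    expected <- if (ct$p.value < 0.01 && ct$estimate > 0) "bottom_up"
      else if (ct$p.value < 0.01 && ct$estimate < 0) "top_down"
      else if (ct$p.value > 0.05) "no_propagation"
      else "unclassified"
    agree <- agree && identical(e$label, expected) &&
      abs(e$p - ct$p.value) < 1e-12
    labels[k] <- e$label
  }
  expect_true(agree)
  # i.i.d. delays land in no_propagation at about the null rate
  expect_equal(mean(labels == "no_propagation"),
               mean(sapply(perms, function(p)
                 suppressWarnings(cor.test(d[p], 1:7)$p.value)) > 0.05),
               tolerance = 1e-12)
})

test_that("wave counting tallies labels and rate-normalizes", {
  expect_equal(count_waves(list())$n_segments, 0)
  expect_equal(count_waves(list())$bottom_up, 0L)

  mk <- function(label) structure(list(label = label),
                                  class = "wave_event")
  evs <- list(mk("bottom_up"), mk("bottom_up"), mk("top_down"),
              mk("no_propagation"), mk("excluded_low_involvement"))
  cw <- count_waves(evs, duration_seconds = 382.4)
  expect_equal(cw$bottom_up, 2L)
  expect_equal(cw$top_down, 1L)
  expect_equal(cw$no_propagation, 1L)
  expect_equal(cw$excluded_low_involvement, 1L)
  expect_equal(cw$n_segments, 5)
  expect_equal(cw$rate_per_min_bottom_up, 2 / (382.4 / 60))
  # labelled tally = list length minus excluded
  expect_equal(cw$bottom_up + cw$top_down + cw$no_propagation +
                 cw$unclassified, 5 - cw$excluded_low_involvement)
})

test_that("wave-locked average equals the brute-force event mean", {
  set.seed(37)
  tr <- 0.8
  m <- matrix(rnorm(10 * 200), 10, 200)
  binned <- structure(list(data = m, tr_seconds = tr),
                      class = "binned_series")
  mk_ev <- function(peak) structure(
    list(segment = list(gbold_peak_frame = peak), label = "bottom_up"),
    class = "wave_event")

  one <- wave_locked_average(binned, list(mk_ev(100)), window_seconds = 8)
  w <- round(8 / tr)
  expect_equal(one$data, m[, (100 - w):(100 + w)])
  expect_equal(one$event_count, 1)

  two_same <- wave_locked_average(binned, list(mk_ev(100), mk_ev(100)),
                                  window_seconds = 8)
  expect_equal(two_same$data, one$data)

  peaks <- c(30, 80, 150)
  got <- wave_locked_average(binned, lapply(peaks, mk_ev),
                             window_seconds = 8)
  brute <- Reduce(`+`, lapply(peaks, function(p)
    m[, (p - w):(p + w)])) / 3
  expect_equal(got$data, brute, tolerance = 1e-12)
  # events whose window exits the run are dropped
  edge <- wave_locked_average(binned, lapply(c(5, 100), mk_ev),
                              window_seconds = 8)
  expect_equal(edge$event_count, 1)
})

test_that("wave-score map: constant covariate flagged, per-cell oracle", {
  set.seed(38)
  n <- 15
  maps <- lapply(1:n, function(i) structure(
    list(data = matrix(rnorm(6 * 4), 6, 4)),
    class = "wave_locked_average"))
  covar <- rnorm(n)
  ages <- rnorm(n, 59, 4)

  const <- wave_score_map(maps, rep(1, n), ages)
  expect_true(const$missing)
  expect_true(all(is.na(const$r)))

  res <- wave_score_map(maps, covar, ages)
  rc <- residualize_age(covar, ages)
  for (i in 1:6) for (j in 1:4) {
    cell <- sapply(maps, function(m) m$data[i, j])
    ct <- cor.test(residualize_age(cell, ages), rc)
    expect_equal(res$r[i, j], unname(ct$estimate), tolerance = 1e-9)
    expect_equal(res$p[i, j], ct$p.value, tolerance = 1e-9)
  }

  # covariate equal to one cell's values gives r = 1 there (no age adj.)
  covar2 <- sapply(maps, function(m) m$data[2, 3])
  res2 <- wave_score_map(maps, covar2, ages = NULL)
  expect_equal(res2$r[2, 3], 1, tolerance = 1e-12)
})

test_that("negating the PG map swaps wave directions, |r| and p unchanged", {
  cfg <- quick_cfg(event_rate_per_min = 2.5,
                   direction_mix = c(bottom_up = 0.6, top_down = 0.4,
                                     synchronous = 0))
  geo <- make_geometry(350, 70, 68, seed = 41)
  sim <- simulate_run(cfg, geo, seed = 42)
  run <- znorm(bandpass(sim$run))
  g <- extract_gbold(run)
  segs <- segment_by_troughs(g)

  classify_all <- function(geometry) {
    b <- bin_by_gradient(geometry, 70)
    bs <- bin_series(run, b)
    lapply(seq_len(nrow(segs)), function(i)
      classify_segment(peak_table(bs, segs[i, ]), b, segs[i, ]))
  }
  ev1 <- classify_all(geo)
  ev2 <- classify_all(surface_geometry(-geo$pg_score, geo$parcel_id,
                                       geo$parcel_table))
  swap <- c(bottom_up = "top_down", top_down = "bottom_up",
            no_propagation = "no_propagation",
            unclassified = "unclassified",
            excluded_low_involvement = "excluded_low_involvement")
  for (i in seq_along(ev1)) {
    expect_equal(ev2[[i]]$label, unname(swap[ev1[[i]]$label]))
    expect_equal(abs(ev2[[i]]$r), abs(ev1[[i]]$r), tolerance = 1e-12)
    expect_equal(ev2[[i]]$p, ev1[[i]]$p, tolerance = 1e-12)
  }
})

test_that("time reversal maps a clean bottom-up wave to top-down", {
  # single strong propagating event, no noise: deterministic labels
  cfg <- quick_cfg(event_rate_per_min = 60 / 382.4,  # exactly one event
                   event_amplitude = 50,
                   direction_mix = c(bottom_up = 1, top_down = 0,
                                     synchronous = 0))
  geo <- make_geometry(350, 70, 68, seed = 43)
  sim <- simulate_run(cfg, geo, seed = 44)

  classify_run <- function(run) {
    run <- znorm(bandpass(run))
    g <- extract_gbold(run)
    b <- bin_by_gradient(geo, 70)
    bs <- bin_series(run, b)
    segs <- segment_by_troughs(g)
    evs <- lapply(seq_len(nrow(segs)), function(i)
      classify_segment(peak_table(bs, segs[i, ]), b, segs[i, ]))
    vapply(evs, `[[`, character(1), "label")
  }
  fwd <- classify_run(sim$run)
  expect_true("bottom_up" %in% fwd)
  expect_false("top_down" %in% fwd)

  rev_run <- bold_run(sim$run$data[, ncol(sim$run$data):1],
                      sim$run$tr_seconds, space = "surface")
  bwd <- classify_run(rev_run)
  expect_true("top_down" %in% bwd)
  expect_false("bottom_up" %in% bwd)
})
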