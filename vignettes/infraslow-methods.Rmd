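---
title: "Methods: infra-slow global BOLD activity, CSF coupling, and propagating waves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: infra-slow global BOLD activity, CSF coupling, and propagating waves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infraslow)
```

## The measurements

Resting-state fMRI exhibits a highly structured infra-slow (< 0.1 Hz)
*global* activity: large, brain-wide excursions of the mean BOLD signal
that are coupled to cerebrospinal-fluid (CSF) inflow and often organized
as waves traveling across the cortical hierarchy. This package computes,
from preprocessed runs, the derived measures that characterize this
activity and the cohort statistics that relate them to menopause timing
and episodic-memory performance:

* **gBOLD** — the spatial mean, per frame, of z-normalized unit time
  courses (gray-matter voxels for volumetric data; all cortical vertices
  for surface data). `extract_gbold()`.
* **gBOLD amplitude** — the temporal SD of a run's gBOLD signal,
  averaged over a subject's runs. Because gBOLD averages unit-variance
  courses, its SD directly measures global synchrony. The source
  analyses never state their amplitude formula; temporal SD is this
  package's operationalization, chosen over envelope- or peak-based
  measures because it is parameter-free and monotone in the strength and
  rate of global events (a property the test suite verifies on synthetic
  runs). `gbold_amplitude()`.
* **gBOLD–CSF coupling** — Pearson cross-correlation between gBOLD and
  the CSF inflow signal on the lag grid −16…+16 s (step = TR), averaged
  pointwise over a subject's runs, read out at the fixed lag +3.2 s
  where the group-mean function has its negative peak. `xcorr()`,
  `subject_coupling()`.
* **Parcel maps** — gBOLD presence (zero-lag correlation of each
  parcel's mean signal with the whole-surface mean) and rBOLD–CSF
  coupling (each parcel's correlation with CSF at +3.2 s), computed on a
  68-parcel cortical atlas. `gbold_presence()`, `rbold_csf_coupling()`.
* **Propagating waves** — classification of each global event as
  bottom-up (sensory-motor toward default-mode), top-down, or
  non-propagating, from the timing of per-bin peaks along the cortical
  principal gradient (PG). `segment_by_troughs()`, `peak_table()`,
  `classify_segment()`.
* **Head motion** — framewise displacement summed over the six
  rigid-body parameter increments, and its session mean.
  `framewise_displacement()`.

## Lag convention

The cross-correlation value at lag $\tau$ is
$\mathrm{corr}\{g(t),\, c(t+\tau)\}$ for gBOLD $g$ and CSF $c$: positive
$\tau$ means CSF changes *follow* gBOLD changes. Under the generative
model $c(t) = -\gamma\, g(t - L) + \varepsilon(t)$ the function has its
negative peak at $\tau = +L$, reproducing the empirical negative peak at
+3.2 s. Published descriptions of this coupling state only the lag
value, not the sign convention, so anyone comparing against another
toolchain should check this first. Correlations are computed on
truncated overlaps with per-lag means and SDs (no padding, no FFT
wraparound), and the coupling read-out is an exact grid lookup — no
interpolation, an off-grid lag is an error.

## Wave detection

Vertices are sorted by PG score and split into 70 bins of equal count
(ties broken by vertex index). "Evenly divided" could also mean equal
PG-value width; equal count was chosen because it makes every bin mean
equally stable and makes bin rank monotonically equivalent to mean PG
score, so rank serves as the position variable. The whole-surface mean
is segmented at its strict local minima — no prominence threshold, since
the 0.01–0.1 Hz filter already suppresses spurious minima. Within each
trough-to-trough segment, each bin contributes its largest strict local
peak (segment-edge frames never qualify; plateau ties resolve to the
earliest frame), and the delay of that peak relative to the segment's
gBOLD peak is correlated with bin rank:

* involvement < 80% of bins (or fewer than 3 peaked bins) → excluded —
  the event was not truly global;
* $p < 0.01$ with $r > 0$ → bottom-up wave; $r < 0$ → top-down;
* $p > 0.05$ → global peak without propagation;
* $0.01 \le p \le 0.05$ → explicitly *unclassified*: the source
  classification assigns this band to no category, so these segments are
  excluded from every count rather than silently folded into a class.

The p-value is the two-sided t-distribution test on $r$ with $n$ = the
number of peaked bins. Wave counts per subject are summed over runs; raw
counts are only comparable across subjects when session durations are
equal, so `count_waves()` can also report per-minute rates.

## Filtering and normalization

The infra-slow band 0.01–0.1 Hz is isolated with a forward–backward
Butterworth filter, order 2 per pass. Zero-phase filtering is essential:
a causal filter would shift the lag structure that the coupling read-out
depends on. The mean is removed before filtering (0 Hz is out of band,
and a large offset would otherwise leak into the edge transients). The
per-run processing order is bandpass → z-normalize → extract. Units with
zero variance are set to zero and flagged rather than aborting a run.
At TR 0.8 s the realized filter passes a 0.05 Hz sinusoid at ~99%
amplitude and attenuates 0.5 Hz power below 10⁻⁴ of input; runs shorter
than three cycles of the low edge (300 s) are rejected rather than
filtered badly.

## Cohort construction and statistics

Subjects are split at menopause age 51 (the U.S. average); the
overlapping range of the two groups' ages at MRI is computed, subjects
outside it are excluded (matching the groups on scan age), and the
remainder is sorted by menopause age (ties by subject id) and cut into
three equal tertiles — earlier, intermediate, later. When the count is
not divisible by three the earlier groups take the extra subject. Before
group comparisons, the linear effect of age at MRI is regressed out of
each measure (OLS residuals, exactly orthogonal to age). Group contrasts
use the classical pooled-variance two-sample t-test; the trend over the
three ordered groups is tested by linear regression on the group code
1/2/3 — "ordinal regression" is ambiguous for a continuous response, and
trend coding is the interpretation implemented here, with
`predictor = "menopause_age"` available to use the raw menopause age
instead. Memory scores coded 999/NaN are treated as missing and those
subjects dropped. No multiple-testing correction is applied anywhere;
wave-map cells are thresholded at raw p < 0.05, mirroring the analyses
this package reproduces. The pooled-sample age residualization makes the
subsequent two-group t-tests mildly conservative (empirical size ≈ 3.5%
at nominal 5%, measured by the test suite's null-calibration check);
this is a property of the published procedure itself.

## The synthetic cohort generator

Real data for this analysis sit behind a controlled-access archive, so
`simulate_cohort()` generates cohorts with the statistical structure the
pipeline assumes:

* **vertex noise**: temporally AR(1) (coefficient 0.4), band-limited to
  0.01–0.1 Hz, scaled to unit SD. This is the simplest model preserving
  the infra-slow autocorrelation that inflates naive wave-test
  calibration; the suite measures the resulting false-wave rate instead
  of assuming nominal calibration.
* **global events**: Gaussian bumps (duration 8 s, ≈2.5 events/min,
  amplitude 2 noise-SD) whose per-vertex center time runs along the PG
  rank over a 6 s span (bottom-up), reversed (top-down), or constant
  (synchronous).
* **CSF**: $-\gamma\, g(t-3.2\,\mathrm{s})$ plus white noise (SD half
  the gBOLD SD, i.e. SNR 2). A lagged negative copy, not a negative
  derivative: only the empirical negative peak at +3.2 s is specified by
  the source analyses, and the copy model pins it exactly.
* **motion**: Gaussian random walks (step SD 0.05 mm translations,
  0.001 rad rotations), giving mFD values in the realistic ~0.1–0.2
  range.
* **covariates**: menopause ages on a stratified normal grid
  (mean 50, SD 4), MRI ages linearly tied to menopause age plus noise so
  the overlap exclusion has work to do; planted linear effects of
  menopause timing on coupling (−0.013/yr from base −0.35, SD 0.18) and
  amplitude (+0.011/yr from base 0.4, SD 0.1), chosen to reproduce the
  reported effect sizes (≈0.6 and ≈1.0 pooled-SD group differences over
  the ≈8.5-year spread between extreme tertiles, with the
  between-subject SDs typical of these metrics in aging cohorts); and a
  wave-count/memory correlation of 0.46 among earlier-menopause
  subjects. Setting every slope and the correlation to zero yields the
  null cohorts used for calibration.

The surface is reduced to 2,000 vertices by default (tests and the
acceptance script use 350–700) against the 59,412 of a full surface
mesh; the 70 bins are kept so wave statistics remain comparable. What
the generator does *not* emulate: volumetric anatomy, scanner artifacts,
respiration/cardiac physiology, spatially correlated vertex noise, and
1/f spectra. Passing tests therefore demonstrate the pipeline's
correctness and its statistical behavior under this model — not
performance on real scanner data.

## Numerical choices and degenerate inputs

* Pearson p-values use the exact t-transform $t = r\sqrt{(n-2)/(1-r^2)}$
  with $|r| = 1 \mapsto p = 0$; they agree with `cor.test` to machine
  precision (verified exhaustively over all permutations at 7 bins).
* Equal-count binning assigns vertex of ascending-PG rank $k$ (1-based)
  to bin $\lfloor (k-1) B / n \rfloor + 1$; occupancies differ by at
  most one, and for $B \mid n$ negating the PG map mirrors the bins
  exactly.
* Segments are half-open `[start, end)`; unions tile the span between
  first and last trough with no overlap.
* Fewer than two troughs → zero segments; a monotone signal has no
  waves, not an error.
* Collinear predictors in the wave–memory regression are flagged, never
  silently dropped; constant covariates make correlation maps missing,
  not zero.
* Runs are validated at load: no missing values, TR > 0, ≥ 2 frames;
  phenotype rows with a menopause age above the MRI age are flagged
  excluded (an impossible ordering), and duplicated subject ids are an
  error.

## Problem sizes

The test suite runs cohorts of 12–18 subjects at 150–700 vertices and
the full 478-frame, TR 0.8 s run geometry; the acceptance script uses
10-subject groups for lag recovery (120 replicates), five 700-vertex
runs per wave direction, 100-replicate power/recovery checks, and a
200-replicate null calibration. These sizes were chosen so the complete
analysis reruns comfortably on a laptop while keeping every Monte-Carlo
margin far from its threshold.

## Known limitations

* Surface I/O accepts plain dense matrices (TSV), not GIFTI/CIFTI
  containers; convert upstream.
* The FD formula sums rotation increments (radians) directly with
  translations (mm) — a unit-mixing quality index, not a physical
  displacement; no 50-mm sphere conversion is applied, and rotational
  units of the input realignment files are the caller's responsibility.
* gBOLD amplitude as temporal SD is one defensible choice among several;
  comparisons against analyses using envelope-based amplitudes should
  expect scale differences.
* The wave classifier inherits the spatial correlation of binned noise:
  under pure noise the fraction of segments labeled as waves can exceed
  the nominal 1% of the p < 0.01 rule; the suite bounds it rather than
  assuming nominal calibration.

## A minimal session

```{r example, eval = FALSE}
cfg <- sim_config(n_subjects = 18L, n_vertices = 400L, n_runs = 2L,
                  seed = 42L)
cohort <- simulate_cohort(cfg)
res <- run_pipeline(cohort, pipeline_config(), out_dir = "results")
res$stats$coupling_t      # earlier vs later, age-adjusted coupling
res$stats$amplitude_trend # ordinal trend of gBOLD amplitude
res$group_ccf             # group-mean cross-correlation function
```
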