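---
title: "Methods: COP stabilometry, condition statistics, and the synthetic sway cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: COP stabilometry, condition statistics, and the synthetic sway cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posturo)
```

This vignette documents the models, conventions and design choices behind
`posturo`: how COP trajectories are derived and segmented, how each
stabilometric measure is defined, which conventions the nonparametric
statistics follow, what the synthetic cohort does and does not emulate,
and the numerical edge cases.

## COP derivation and preprocessing

A force plate reports three forces and three moments about its sensor
origin. For a plate whose origin sits a vertical distance $h$ below the
surface, the point of force application on the surface is

$$\mathrm{COP}_x = \frac{-M_y - F_x h}{F_z}, \qquad
  \mathrm{COP}_y = \frac{M_x - F_y h}{F_z}.$$

`compute_cop()` applies this formula and maps the two components onto the
anteroposterior (AP) and mediolateral (ML) body axes through a
configurable `axis_map` (component assignment and sign per axis), because
plate mounting conventions vary and the measures are sign-sensitive in
tests even though the battery itself is symmetric. Defaults: AP from the
$-M_y$ component, ML from $M_x$, positive signs, $h = 0$. Division by a
near-zero vertical load is refused outright: any sample with
$|F_z| \le 10\,\mathrm{N}$ (configurable) raises an "unloaded plate" error
naming the first offending index, rather than producing silently huge
excursions.

Preprocessing is deliberately minimal. The default pipeline applies *no*
filter — only per-axis mean removal — because raw stabilograms are the
reference processing for this measure battery. An optional zero-phase
low-pass (4th-order Butterworth run forward and backward, so no phase
distortion biases the velocity measure) is available for noisy hardware;
its cutoff must be below Nyquist. Centering is explicit and enforced: the
measures refuse an uncentered trajectory instead of silently fixing it, so
a pipeline cannot accidentally compute distances from an arbitrary origin.

**Trial windows.** Sessions are segmented on a half-open grid
$[t_0, t_0 + 20\,\mathrm{s})$ at integer sample boundaries: each 20-s
trial at 200 Hz holds exactly 4000 samples and no sample belongs to two
trials. (The alternative inclusive-endpoint convention would share the
boundary sample between consecutive windows; we chose the partition.)
Manual start synchronization between the stimulus and the plate implies an
unknown trial-onset latency; no alignment correction is attempted, and
explicit start markers can be supplied where they are known.

## The measure battery

All measures operate on the centered trajectory $x_1,\dots,x_N$ (mm) per
axis at sampling rate $f_s$:

- **Mean distance** $\mathrm{MD} = \frac1N \sum_i |x_i|$.
- **Mean velocity** $V = \frac{\sum_i |x_{i+1}-x_i|}{(N-1)/f_s}$. The
  denominator is $(N-1)/f_s$, not $N/f_s$: a path of $N$ samples has
  $N-1$ increments.
- **95% confidence ellipse area**
  $2\pi F_{0.95}(2, N-2)\sqrt{s_{AP}^2 s_{ML}^2 - s_{APML}^2}$ with sample
  (co)variances $s$. The critical value is computed from $N$ rather than
  hard-coded at its large-$N$ limit 3.00, so the ellipse is exact at all
  trial lengths. Semi-axes are $\sqrt{2 F \lambda_i}$ on the covariance
  eigenvalues; a collinear path (singular covariance) is returned as a
  flagged degenerate ellipse with area 0, not an error.
- **Mean frequency** $\mathrm{Mf} = V / (4\sqrt2\,\mathrm{MD})$, the
  frequency of the sinusoid whose total excursion per unit time matches
  the observed path relative to its mean distance. For a pure sinusoid of
  frequency $f$, $\mathrm{MD} = 2A/\pi$ and $V = 4Af$, so
  $\mathrm{Mf} = (\pi/2\sqrt2) f \approx 1.11 f$. Verbal definitions of
  this measure are ambiguous about the constant ($4\sqrt2$ vs $2\pi$
  conventions); we adopt the directional $4\sqrt2$ form of the canonical
  stabilometry battery and expose the constant as an argument for
  sensitivity analysis. Note that published condition tables cannot
  adjudicate the constant, because averaging a ratio across trials differs
  from the ratio of averages. A constant series makes Mf undefined; it is
  returned as `NA` with an explicit flag, never silently dropped.

Trials aggregate to one value per participant-condition by the per-field
arithmetic mean; any undefined trial measure makes the aggregate undefined
and carries the flag forward. Homogeneity (distances and velocities scale
linearly, area quadratically, Mf invariantly), time-reversal invariance
and translation invariance are enforced by property tests, and every
measure is checked to $10^{-9}$ relative tolerance against a literal
brute-force recomputation on short random paths.

## Condition statistics

The pipeline is nonparametric by design; the Shapiro–Wilk screen is
reported per condition for description only and never gates the analysis.

**Friedman omnibus.** Within-participant midranks across the $k = 6$
conditions, with the tie-corrected statistic
$\chi^2_F = (k-1)\sum_j (R_j - n(k+1)/2)^2 / (A - C)$ where $A$ is the sum
of squared ranks and $C = nk(k+1)^2/4$; without ties this reduces to the
textbook $\frac{12}{nk(k+1)}\sum_j R_j^2 - 3n(k+1)$. A table in which
every participant's values are constant gives statistic 0 and $p = 1$.
The p-value uses the $\chi^2_{k-1}$ asymptotic; incomplete blocks are an
error that lists the missing cells.

**Planned contrasts.** Four a-priori Wilcoxon signed-rank comparisons —
condition 2 vs 1, 4 vs 1, 5 vs 1, and 6 vs 5 — isolate the somatosensory,
visual, and vestibular contributions respectively. Conventions, chosen to
match mainstream statistical software behaviour:

- zero differences are discarded (Pratt's method is available by flag);
- $|d|$ ties receive midranks, and the normal-approximation variance is
  tie-corrected;
- for effective $n \le 15$ the two-sided p comes from exact enumeration of
  all $2^n$ sign patterns over the observed ranks
  ($p = 2\min(P(W\le w), P(W\ge w))$, capped at 1);
- the $z$ value from the approximation formula is reported in both modes,
  with no continuity correction by default. The continuity-corrected
  approximation tracks the exact p within 0.03 over the $8 \le n \le 15$
  range; the uncorrected default runs closer to the asymptotic behaviour
  of common software but is slightly anti-conservative at small $n$ — the
  exact mode is what small-sample inference should use.
- all differences zero yields a flagged degenerate result ($p = 1$,
  $r = 0$) rather than an error.

Effect sizes follow Rosenthal, $r = |Z|/\sqrt n$ with $n$ the number of
pairs entering the contrast (before zero-difference removal), matching how
$n$ is counted in cohort reports. Participants with a flagged or missing
value in either condition of a contrast are excluded listwise, and the
exclusion count is part of the result. No multiple-comparison adjustment
is applied because the contrasts are planned; every report carries that
caveat explicitly. A sign-flip permutation oracle
(`wilcoxon_permutation_p()`) provides an independent check of the exact
path in the test suite.

## Questionnaire scoring

The three instruments ship their item maps as editable YAML assets rather
than code, because the maps are instrument conventions, not algorithms:

- **SSQ**: 16 symptoms rated 0–3; three overlapping 7-item subscales
  (nausea, oculomotor, disorientation). Subscale score = raw item sum ×
  weight (9.54 / 7.58 / 13.92); total = sum of the three *unweighted* raw
  sums × 3.74; shared items count toward every subscale containing them.
  Totals strictly above 100 classify as actively ill.
- **iPQ**: 14 items on a 1–5 ordinal scale; one general item plus spatial
  presence (5), involvement (4), experienced realism (4). The canonical
  igroup keying marks three items reverse-scored; they are inverted
  ($6 - x$ on the 1–5 scale) before summing. The published anchor range
  for this instrument varies; we implement 1–5, which fixes the maximum
  total at 70 and the neutral reference at 35, consistent with the
  "half of maximum" interpretation. Reversal maps the range onto itself,
  so the attainable extremes are unchanged by keying.
- **SUS**: Brooke scoring; odd (positively keyed) items contribute
  $x - 1$, even items $5 - x$, total × 2.5 onto 0–100.

All scorers validate counts and ranges deterministically and name the
first offending item; the batch scorer files invalid respondents into an
error sidecar instead of aborting the cohort.

## The synthetic sway cohort

`generate_cohort()` emulates the *statistical* structure the analysis
chain assumes — not sway physiology. Per trial and axis, white Gaussian
noise is zero-phase low-pass filtered at a per-condition cutoff, centered,
and rescaled so its RMS equals the per-condition target amplitude times a
participant effect times per-trial noise. This is the simplest generator
in which amplitude and bandwidth independently steer the two measure
families: the distance/velocity/area measures scale with RMS, while the
mean-frequency measures depend (to first order) only on the bandwidth.

- **Participant effect**: one lognormal multiplier per participant
  ($\tau = 0.25$ log-mm by default, chosen to match the roughly 27%
  coefficient of variation of the reference cohort's baseline mean
  distance), shared across all of that participant's conditions — this
  induces the within-subject correlation that the Friedman and Wilcoxon
  procedures exploit. The true cross-condition correlation structure of
  real cohorts is unknown; a single multiplicative effect is an assumption
  and is stated as such.
- **Trial noise**: lognormal with scale 0.1, a typical trial-to-trial
  variation for 20-s quiet-stance measures.
- **AP and ML are generated independently** (published condition tables
  provide no cross-correlation information), so ellipse covariances are
  near-diagonal — a known simplification.
- **Determinism**: every trial's seed derives from the cohort seed and its
  (participant, condition, trial) labels, so cohorts are bit-reproducible
  and individual trials can be regenerated in isolation.

**Calibration.** `calibrate_sway_params()` matches first moments only:
it simulates a noise-free-between-subjects cohort (24 participants × 3
trials per iteration, enough to push Monte-Carlo error below the 2%
matching tolerance), compares the computed condition means of the AP/ML
mean distance and mean frequency to the target table, and updates
amplitudes and cutoffs multiplicatively. Because RMS rescaling makes the
mean distance independent of the cutoff (Gaussian marginal:
$\mathrm{MD} = \sigma\sqrt{2/\pi}$) and Mf independent of the amplitude,
the updates decouple and converge in a few iterations. The fitted
parameters ship as a versioned YAML asset; SD matching is not attempted by
default. Velocity and area targets are not matched separately — they
follow from the same amplitude and bandwidth and land near the reference
values, somewhat high for velocity because the generator's spectrum is
flat below the cutoff rather than decaying like real sway.

The calibrated defaults place the foam conditions (4–6) well above the
firm conditions (1–3) in amplitude, AP cutoffs rising and ML cutoffs
falling with task difficulty — reproducing the direction-dependent
frequency pattern (AP mean frequency increases, ML decreases) that is the
headline qualitative finding the cohort must recover. The fitted cutoffs
are not strictly monotone across all six conditions because the reference
means themselves are not (condition 6 dips below 5 in both directions);
the calibration follows the data over an idealized monotone ordering.

**What passing tests show — and don't.** The synthetic cohort validates
the *chain*: measure formulas, rank statistics, flag propagation, report
plumbing, and the qualitative orderings. It does not validate the
measures' sensitivity on real sway, which has heavier spectral tails,
intermittent control, AP–ML coupling, and nonstationarity the generator
deliberately omits.

## Numerical choices and degenerate inputs

- Ellipse degeneracy: relative determinant below $10^{-12}$ of the larger
  axis variance squared → degenerate flag, area 0.
- Centering tolerance: a trajectory claiming `centered` must have axis
  means within $10^{-9}$ mm.
- Time-axis validation: uniform sampling within $10^{-6}$ s jitter.
- Unloaded-plate threshold: 10 N on $|F_z|$, configurable.
- Exact Wilcoxon enumeration is capped at $n_\mathrm{eff} \le 15$ by
  default ($2^{15}$ patterns); beyond that the tie-corrected normal
  approximation takes over.
- Report formatting pins mm/mm²/Hz values at 2 decimals in the
  human-readable table (the conventional reporting precision) while the
  JSON artifact retains full precision.

## Problem sizes used in validation

The shipped test suite generates cohorts at the full study geometry
(23 participants × 6 conditions × 3 × 20-s trials at 200 Hz, ~2 s to
generate and measure); the ellipse-coverage property averages 100–200
seeded 4000-sample trajectories; the contrast type-I-error property uses
1000 measure-level null replicates; and the ordering-recovery property
checks 20 independent cohort seeds. These sizes put Monte-Carlo error
comfortably inside each property's acceptance band while keeping the full
suite under a couple of minutes.

## Known limitations

- The generator is a statistical stand-in (filtered noise), not an
  inverted-pendulum or rambling–trembling model.
- Velocity/area condition means are consequences of the calibrated
  amplitude/bandwidth, not independently matched targets.
- Only first moments are calibrated; between-subject SDs are emergent
  from $\tau$ and only roughly match a real cohort's spread.
- Confidence intervals for $r$ are not produced; their construction in
  published condition tables is often unclear, and we do not guess.
- No C3D/proprietary plate formats, multi-plate stitching, or real-time
  streaming; CSV in, CSV/JSON out.
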