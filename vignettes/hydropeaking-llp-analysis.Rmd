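---
title: "Methods: pressure-based hydrodynamics and behaviour inference for hydropeaking flume experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pressure-based hydrodynamics and behaviour inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrollp)
```

## The experiment this package models

Hydropeaking — the rapid discharge fluctuation downstream of a hydropower
plant — exposes fish to abrupt changes in velocity, turbulence and
vorticity. A standard way to study mitigation options is an indoor flume
experiment: schools of fish are exposed to a simulated single-peak event
(base flow ramped to a sustained peak) or to constant base flow, with or
without instream structures offered as flow refuges. `hydrollp` implements
the full analysis chain of such an experiment:

* **Event arithmetic.** The severity of the event is summarised by the
  *flow ratio* (peak discharge / base discharge; 60/7 ≈ 8.6 at the default
  study conditions) and the *up-ramping rate* (depth rise / ramp duration;
  15.7 cm / 28.12 s ≈ 0.56 cm/s — note that 15.7/28.12 = 0.5583, which
  *truncates* to 0.55 but *rounds* to 0.56; the package reports the
  computed value and rounds half-up at the reporting layer).
* **Hydrodynamic characterisation** with an artificial lateral line probe
  (LLP): a streamlined body carrying six differential pressure sensors in
  three pairs — (1,2) on the nose, (3,4) and (5,6) on the flanks — sampled
  at 200 Hz, moved over a measurement grid covering the flume.
* **Fish responses**: blood glucose (mg/dl) and lactate (mM) per fish, and
  an ethogram of ten behaviour metrics counted per replicate school.
* **Inference**: Kruskal–Wallis tests with Nemenyi pairwise contrasts,
  correspondence analysis of the behaviour contingency tables, and
  two-way distance-based PERMANOVA.

## Pressure-derived flow variables

For a trace \(p_{i,j}\) (sensor \(i\), sample \(j = 1..n\)) the per-cell
variables are

\[
\bar p_i = \tfrac1n \sum_j p_{i,j}, \qquad
\bar p'_i = \tfrac1n \sum_j |p_{i,j} - \bar p_i|,
\]
\[
\bar p_{12} = \tfrac{1}{2n}\sum_j (p_{1,j} + p_{2,j}), \qquad
\bar p'_{12} = \tfrac12 (\bar p'_1 + \bar p'_2),
\]
\[
\Delta\bar p_{1\text{–}6} =
\frac{\sum_{k=1}^{3} \sum_j (p_{2k-1,j} - p_{2k,j})^2}{N}.
\]

\(\bar p_{12}\) tracks the dynamic pressure \(q = \tfrac12 \rho v^2\) and
is therefore a velocity proxy; \(\bar p'_{12}\) (a mean absolute
deviation) tracks turbulence intensity; \(\Delta\bar p_{1\text{–}6}\)
responds to antisymmetric left/right pressure differences, i.e. to the
size and periodicity of shed vortices.

**The asymmetry normaliser \(N\) is the one genuinely ambiguous numerical
choice.** Typeset renderings of this statistic circulate with an
\(n^3\) denominator, but a literal \(n^3\) makes the value collapse
towards zero for any realistic recording length (at 200 Hz × 60 s,
\(n = 12{,}000\) and \(n^3 \approx 1.7\times10^{12}\)), which is
inconsistent with the stable log-scale magnitudes such experiments report
across events of different severity. `hydrollp` therefore defaults to
`pairmean` — divide by \(m\,n = 3n\), the mean squared pair difference
over pairs and time — and keeps `literal` (\(n^3\)) and `timemean`
(\(n\)) selectable via the `mode` argument so the choice is explicit and
auditable, never silent. The log transform is the natural logarithm
(configurable base), defined only for positive raw values; a
symmetric field yields raw 0 and a flagged `NA` log.

No detrending or filtering is applied before these statistics: the
variables are defined on the raw differential signals.

## The measurement grid and the 9/36 split

The default grid is 15 streamwise rows × 3 lateral columns = 45 cells
(0.7 m flume width / 3 ≈ 0.233 m lateral cell, matching the probe body
length). Zones `C1`–`C5` are streamwise bands of three rows, `C1` most
upstream. Three structures sit in an alternating pattern; the three cells
straight downstream of each form its wake ("structure area",
\(3 \times 3 = 9\) cells), and the remaining 36 cells are the "flume
area". The only hard constraint a published summary imposes is that
9/36 split, so grid shape, structure positions and the wake rule
(straight-downstream triple rather than a diagonal fan) are configurable;
the defaults are the package's own choice. Structure-area summaries are
minima per variable (the best shelter available); flume-area summaries
are mean ± SD with the sample (n−1) convention — the SD convention is not
dictated by anything upstream, and n−1 is the conservative default.

## The synthetic data module

The generators are first-class, tested code: they define the study
conditions under which the pipeline is exercised.

**Pressure traces** (`generate_llp_trace()`): the front pair carries the
dynamic-pressure baseline \(\tfrac12\rho v^2\) (ρ = 1000 kg/m³, g = 9.81
m/s², both configurable) plus Gaussian noise of SD `turbulence_sd` plus
an *in-phase* oscillation; each lateral pair carries zero-mean noise plus
an *antiphase* sinusoid of amplitude `vortex_amplitude` at the shedding
frequency (odd sensor +, even sensor −). This makes the construction
exactly invertible by the metrics: the front mean recovers \(q\) (the
test suite checks regression slope 1 ± 0.02 over v = 0.1–1.0 m/s), a
single antiphase pair of amplitude \(A\) contributes \(2A^2/3\) to the
`pairmean` asymmetry, and the in-phase front oscillation contributes
nothing. The scenario validator enforces a resolvable oscillation
(sampling rate > 2 × shedding frequency).

**Field scenarios** (`generate_field_scenario()`): wake cells get reduced
velocity (×0.3) and elevated vortex amplitude, structure-adjacent cells
get accelerated flow (×1.3), hydropeaking scales all velocities by the
flow ratio relative to base flow and raises the depth by 15.7 cm, and
v-shaped structures (`R2`) shed 1.6× larger vortices than solid pyramids
(`R1`). Scaling velocity by the full flow ratio is deliberately the
simplest monotone rule; continuity with the concurrent depth rise would
give a smaller factor (~3.3×), so the synthetic hydropeaking contrast is
stronger than a physical flume would show. Every invariant the pipeline
relies on (wake < flume in front pressure, HP > BF cellwise, asymmetry
concentrated in wakes) is monotone in this choice and unaffected by it.
The default per-cell recording length is 60 s (a per-cell measurement
time is rarely reported for grid surveys; 60 s at 200 Hz gives
12,000 samples, ample for stable means).

**Behaviour counts** (`generate_behaviour_counts()`): negative-binomial
with shared dispersion 5, because reported behaviour frequencies in this
kind of experiment show variance well above Poisson; `dispersion = Inf`
degrades exactly to Poisson (tested by a variance/mean check on 10,000
draws). Structure-use metrics under `R0` are *absent* (`NA`), not zero —
a fish cannot use a structure that is not there — so downstream rank
tests over structure use compare 4 groups (df = 3) while activity metrics
compare 5 (df = 4).

**Physiology** (`generate_physiology()`): per-treatment Gaussians
truncated at zero, one record per fish (5 replicates × 5 fish × 5
treatments = 125). The single external calibration point is the R2HP
lactate elevation, 5.06 ± 0.49 mM; the other treatment means are free
parameters chosen once to give contrasts of the magnitude a barely-to-
moderately significant flume study shows (glucose 45–51 mg/dl, SD 8;
lactate 3.8–4.0 mM, SD 0.9 elsewhere). A flat-mean variant of the same
generator is used for type-I calibration: over 500 simulated experiments
the Kruskal–Wallis rejection rate at α = 0.05 stays within 0.05 ± 0.02.

**What the generators do not emulate**: sensor drift, cross-channel
correlated turbulence, non-stationary ramp transients within a recording,
richer von Kármán wake spectra, behavioural time-correlation within a
school, and fish-to-fish covariance of glucose and lactate. Passing tests
therefore demonstrate that the *analysis chain* is correct and calibrated
under its stated assumptions, not that real flume data meet those
assumptions.

## The inference procedures

All four procedures are implemented from first principles (the
established community implementations serve as independent cross-checks
in the test suite, never as the implementation).

**Kruskal–Wallis** uses mid-ranks and the standard tie correction
\(1-\sum(t^3-t)/(N^3-N)\); an all-tied sample is defined as \(H = 0\),
p = 1. The p-value is the χ² upper tail with k−1 df.

**Nemenyi pairwise contrasts** default to the `chisq` variant
(\((\bar R_i-\bar R_j)^2/[\tfrac{N(N+1)}{12}(1/n_i+1/n_j)]\), χ² upper
tail with k−1 df) because pairwise contrasts in this literature are
reported as χ² statistics; the `tukey` variant (studentized range with k
groups) is retained for sensitivity analysis. Published pairwise
*p*-values in this area do not always match either textbook mapping
exactly, so the package treats the statistic as primary and documents the
p mapping rather than reverse-engineering one.

**Correspondence analysis** decomposes the standardized residual matrix
\(D_r^{-1/2}(P - rc^\top)D_c^{-1/2}\) by SVD. Principal inertias are
squared singular values; their sum equals χ²/N (tested against an
independent χ² computation); scores are reported in principal coordinates
for both rows and columns (symmetric scaling), which reproduce χ²
distances among profiles. A table whose rows are exactly proportional has
total inertia 0 and is flagged `degenerate` (proportions `NA`) instead of
dividing by zero. Zero margins are an error at the CA stage;
`aggregate_for_ca()` flags them beforehand. The CA contingency tables are
treatment-aggregated by default (replicates summed): the ordination is
meant to display *event-level* trends, and replicate-level rows are
available via `level = "replicate"` for sensitivity.

**PERMANOVA** works on the Gower-centred inner-product matrix of squared
Euclidean distances; explained sums of squares are traces of hat-matrix
projections, terms are sequential in the order given (default: flow
event, then configuration — the event effect is the primary question, and
with the unbalanced design (no `R0BF` cell) sequential SS makes the
ordering explicit rather than hiding it). Permutations shuffle raw
observations; p = (#{permuted F ≥ observed F} + 1)/(B + 1), so with the
default B = 999 the smallest reportable p is 0.001 and p is never 0. The
observed pseudo-F is deterministic; only the p-value depends on the seed.
With one response column and one factor the pseudo-F equals the classical
ANOVA F exactly (tested), and the two-way sequential table matches
`vegan::adonis2(..., by = "terms")` to 1e-8 (tested).

## Behaviour coding rules

A behaviour occurrence belongs to the zone where it *began*; a start
exactly on a zone boundary goes to the upstream (lower-indexed) zone — a
documented tie-break, since boundary starts are otherwise undefined.
Individual metrics require group size 1, group metrics 2 up to the school
size. `tabulate_frequencies()` zero-fills unobserved combinations and
codes `R0` structure metrics as absent; `events_from_frequencies()` is
the exact inverse up to event detail, and the round-trip is tested.

## Reproducibility and problem sizes

Every generator takes an explicit seed, derives per-cell/per-stage
sub-seeds, and restores the caller's RNG state, so identical inputs give
bit-identical outputs without perturbing the session. The pipeline logs
input counts, the seed and a config hash when `verbose = TRUE`.

The test suite runs the full pipeline at the study design (45 cells × 5
treatments, 125 fish, 250 count rows) with per-cell recordings shortened
to 2 s where only spatial structure matters, and at the full 60 s where
signal-recovery precision matters (dynamic-pressure slope, asymmetry
recovery). Calibration loops use 500 simulated experiments; permutation
tests use 999 permutations in pipeline runs and 99–199 inside simulation
loops, sizes chosen so the whole suite completes in well under a minute
while keeping Monte-Carlo error far below every asserted tolerance.

## Known limitations

* The synthetic hydropeaking velocity contrast is stronger than
  continuity would give (see above); absolute synthetic pressures should
  not be compared to published flume tables, only their ordering and
  spatial structure.
* The Nemenyi p mapping for published pairwise contrasts is ambiguous in
  this literature; statistics are primary.
* The literal \(n^3\) asymmetry mode is retained for comparability but is
  not meaningful for long recordings.
* XLSX supplements are ingested only after conversion to the canonical
  CSV schemas; the package deliberately reads delimited text only.
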