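---
title: "Quantifying pairwise bacterial competition with a transient dye: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pairwise bacterial competition with a transient dye: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyecomp)
```

## The measurement problem

Pairwise competition assays follow the relative abundance of two bacterial
genotypes or species in coculture over time. When one competitor is stained
with a transient fluorescent dye before mixing, the two types can be told
apart in an imaging flow cytometer without genetic modification — but the
dye is not renewed after staining, so each division splits the membrane
signal between daughters and per-cell intensity roughly halves each
generation. The analysis problem is therefore a drifting two-class
classification: decide per cell, from its dye-channel intensity, whether it
descends from the stained inoculum, while the stained distribution slides
towards the unstained background.

`dyecomp` implements the full analysis chain: gating, ROC-based threshold
fitting from monoculture controls, coculture frequency estimation,
reconciliation against dilution plating, competition statistics, and a
ground-truth simulator that makes every stage testable.

## Gating

Bacterial events are isolated in two stages: a polygon gate in the (dye
intensity, autofluorescence intensity) plane separating cells from other
objects, and a closed brightfield-area interval (default 2–150 area units)
separating bacteria from much larger ciliate predators. The default polygon
(`default_cell_gate()`) is the instrument gate used in the assay this
package operationalises.

Two deliberate conventions:

* **Boundary-inclusive membership.** "Values retained: 2–150" reads as a
  closed interval, and with floating-point coordinates an open boundary is
  untestable anyway. The polygon predicate counts points on an edge or
  vertex as inside (relative tolerance `1e-9`).
* **Ray casting in production, winding number as oracle.** The production
  predicate is a vectorised ray-casting test with explicit on-edge
  detection; the test suite checks it against an independent winding-number
  implementation on randomised point clouds (points nearer to an edge than
  the tolerance are excluded from the comparison, since the two rules may
  legitimately differ there).

Gating output is always a subset of its input, preserves event order, is
idempotent, and attaches per-stage retention counts for provenance.

## Threshold fitting

Thresholds are fitted on monoculture controls, where each cell's class is
known: a stained monoculture of one competitor against an unstained
monoculture of its competitor. A cell is called stained when its dye
intensity is **greater than or equal to** the threshold; the inclusive rule
is applied identically during fitting, validation and coculture
classification.

**Candidate set.** Every distinct observed intensity across both controls
is a candidate threshold, plus a sentinel above the maximum so the
all-unstained point exists. Any threshold strictly between two consecutive
observed values yields the same confusion counts as one of these
candidates, so the observed set exhausts all achievable ROC points; a dense
grid would add nothing. The sweep is computed in `O(n log n)` by sorting,
and the suite verifies exact equality with a literal `O(n^2)` enumeration.

**Selection criteria.** Two are exposed, because both are used in this
assay tradition:

* `closest_topleft` (default): minimise the Euclidean distance
  `sqrt(FPR^2 + (1 - TPR)^2)` to the perfect corner of ROC space.
* `balanced_accuracy`: maximise `(TPR + TNR) / 2`.

With roughly balanced class sizes the two usually coincide; they can differ
on asymmetric data. Ties are broken by lower FPR, then by higher threshold,
a deliberately conservative rule: when several candidates are equally good,
prefer the one that calls fewer cells stained. Under perfect separation
this selects the smallest observed stained intensity.

**General versus per-time-point thresholds.** `pooled_threshold()` supports
both pooling all sampling times before the sweep (`"general"`) and fitting
each time point separately. The general threshold integrates the gradual
dye decline and is the default throughout the pipeline: recalculating per
time point buys little accuracy while multiplying the number of fitted
quantities, and a single threshold is applied uniformly to cocultures where
class labels are unknowable.

**Competitor-specific versus unified thresholds.**
`compare_threshold_strategies()` contrasts one threshold per stained
competitor with a single threshold pooled over both control pairs. Whenever
the two competitors differ — most simply in autofluorescence — separate
thresholds dominate, and the pipeline fits them per stained competitor.

## Coculture frequencies

`classify_events()` applies the fitted threshold to gated coculture events;
`estimate_frequency()` converts the counts to a stained fraction with a 95%
Wilson score interval. Wilson was chosen over the Wald interval because it
behaves correctly at observed fractions of 0 and 1, which occur routinely
at extreme starting ratios.

An optional Rogan–Gladen correction
(`correct_frequency()` = `(p_obs - FPR) / (TPR - FPR)`, clipped to [0, 1])
inverts the expected misclassification given the control-measured error
rates. It is an extension, reported alongside and never in place of the raw
classified fraction, and requires `TPR > FPR` (an informative classifier).

Frequencies are always reported for a named focal competitor; when the
focal competitor is the unstained one the estimate is `1 - freq_stained`.
Making the focal explicit removes the sign ambiguity that otherwise creeps
into trajectory plots.

## Plate-count reconciliation

Dilution plating provides the reference estimate. The counting convention
is: only plates whose **total** colony count lies in the closed interval
[30, 300] are evaluable, and among evaluable plates the one with the
highest total is used. The two sentences of the convention are composed as
filter-first, then arg-max; the 30–300 bound is read against the plate
total rather than per morphotype, consistent with "30 to 300 colonies" as a
statement about countability of the plate. A series with no evaluable plate
yields a flagged empty estimate, never an error, so screening whole
experiments cannot abort mid-run.

Method agreement is summarised by Pearson correlation with its t-test
p-value plus the least-squares slope, and two correlations (e.g. with and
without predator) are compared with the Fisher z statistic
`(atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`.

## Competition dynamics

Per replicate coculture, `fit_frequency_trend()` returns the OLS slope of
frequency versus time and the logit-scale slope `s_logit` of
`ln(f/(1-f))` versus time. Under discrete selection with constant relative
fitness `w` and `g` generations per hour, logit frequency is exactly linear
with slope `g ln(w)`, so `s_logit` is a per-hour selection rate; the
package never infers generations itself — converting `s_logit` to
per-generation fitness requires the user to supply `g`, typically from OD
doublings.

Boundary frequencies are handled by the Haldane–Anscombe pseudo-count
`(x + 0.5)/(n + 1)` when counts are available, else by clipping to
`[1e-3, 1 - 1e-3]`.

`aggregate_trends()` averages replicate slopes per condition and tests the
mean against zero with a normal z-test. This per-replicate-OLS +
across-replicate aggregation design is deliberate: the scientific quantity
is the per-condition temporal trend, and a linear mixed model with random
intercepts — the conventional alternative — is off-the-shelf machinery that
adds a dependency and an inferential layer without changing that quantity
materially at three replicates per condition. Users wanting the mixed-model
analysis can feed the package's frequency table to `lme4`/`lmerTest`
directly.

Carrying capacity is defined in the assay sense: the maximum OD600 a
culture reaches, averaged across replicates per condition.

## The simulator

`simulate_experiment()` generates a complete labelled experiment:
monoculture control series for both competitors, cocultures over a full
ratio × stained-assignment × predator × replicate × time design, plate
series, OD curves, and a ground-truth table. All randomness flows from one
seed; identical seeds give byte-identical outputs.

The generative model, and what each default means:

* **Stained intensity**: `exp(N(stain_log_mean, stain_log_sd)) *
  2^-(g + eps) + autofluorescence`. The `2^-g` factor is the dye-halving
  law; `eps ~ N(0, dilution_noise_sd)` (default 0.3 generations) absorbs
  asynchronous division so the halving stays exact in expectation without
  an age-structured model. Dye and autofluorescence add on the linear scale
  because detector counts are additive.
* **Unstained intensity**: log-normal autofluorescence
  (`autofluor_log_mean = log(3)`, sd 0.8 natural-log units), with an
  optional per-competitor log-mean offset to create inter-competitor
  differences.
* **Defaults of the `paperlike` preset**: 2000 events per sample, six
  2-hourly time points over 10 h, ratios 0.1/0.5/0.9, both stained
  assignments, two predator levels, three replicates; one generation per
  2-h interval, i.e. five generations over the assay. `stain_log_mean =
  log(9000)` with `stain_log_sd = 1.6` places the t = 0 stained and
  unstained distributions in slight overlap — the regime where threshold
  choice actually matters — and puts the failure point of a fixed t = 0
  threshold between four and five generations, the applicability window a
  transient dye is expected to have. t = 0 classification accuracy under
  these defaults is ≈ 0.999.
* **Selection**: frequencies follow the discrete recursion
  `f_g = w^g f0 / (w^g f0 + 1 - f0)` with default `w = 0.8` (the focal
  competitor declines); optional per-interval survival multipliers
  (defaults 0.9 vs 0.7) let predation offset the fitness deficit.
* **Plates**: totals are Poisson with expectation proportional to the
  culture's current OD times `10^-dilution_exponent`, the focal count
  binomially thinned at the true frequency. The default dilution design
  (exponents 3.79–7.29, `plated_volume_equivalent = 6e6`) yields at least
  one evaluable plate in ≥ 95% of series.
* **OD**: logistic growth (`od0 = 0.02`, `r = 1.2/h`, `K = 0.45`) with
  N(0, 0.005) measurement noise; growth starts around 2 h and saturates by
  ~6 h, matching typical dilute-medium batch culture.

What the simulator does **not** emulate: mechanistic predator–prey
kinetics, biofilm or aggregation artifacts, instrument-specific noise
(saturation, spillover, doublets), differential staining efficiency between
species, and growth-phase-dependent division rates (generations per
interval are constant). Passing tests on simulated data therefore
demonstrate the correctness of the estimators under the assay's idealised
assumptions, not robustness to every failure mode of real cytometry data.

## Numerical choices and degenerate inputs

* Negative background-subtracted intensities are preserved end to end;
  the candidate-threshold sweep and the `>=` rule tolerate them.
* The ROC sentinel threshold is `Inf`, so the all-unstained point exists
  without inventing a finite pseudo-candidate.
* Ties in threshold selection: lower FPR, then higher threshold.
* Empty gated cocultures yield `NA` frequency rows, flagged, not errors;
  empty retention-curve time points are omitted with a warning.
* Polygon on-edge tolerance is relative (`1e-9` of the gate's coordinate
  scale), so gates in raw intensity units (order `1e7`) behave like gates
  in normalised units.

## Problem sizes used by the tests

The test-suite and verification-script problem sizes are chosen as the
smallest that make the statistical assertions sharp: 500 random ROC
instances at n ≤ 200 against the exhaustive oracle; 50 simulated
experiments (three time points, ≤ 2 generations) for end-to-end frequency
recovery (MAE ≤ 0.02); 100 trajectories of 2000-cell samples for
selection-rate recovery; 1e5 events per generation for the halving law
(tolerance ± 0.05 log2 units); 20 seeds for the generation-limit curve; and
1000 randomised series for the plate rule. These settings run in well under
a minute each on one core.

## Known limitations

Classification quality is inherently transient: beyond four to five
generations the stained distribution has slid into the background and no
fixed threshold performs well — the package measures and reports this
decay (`retention_curve()`, fixed-threshold evaluation over time) but
cannot beat it. Only two competitors are supported; overlapping dye spectra
make multi-way discrimination a different problem. Mixture-model (EM)
classification, which could extend the usable window by modelling the
sliding component explicitly, is a possible extension and deliberately out
of scope.
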