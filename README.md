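# dyecomp

Quantify pairwise competition between bacterial genotypes or species in
coculture when one competitor carries a **transient fluorescent dye** and
samples are measured by imaging flow cytometry.

Distinguishing two bacterial competitors in a mixed culture is hard: the
cells are small, morphologically similar, and present in huge numbers.
Constitutive fluorescent markers require genetic modification; sequencing is
slow and expensive for high-replicate, short-term assays. Transiently
staining one competitor avoids both — but the dye is not renewed after
staining, so the per-cell signal halves with each division and the stained
population drifts towards the unstained background over the assay.
`dyecomp` is for experimental ecologists and evolution researchers running
such assays: it turns per-cell event tables into competitor frequency
trajectories, selection rates, and carrying capacities, with the
classification threshold fitted objectively from control data.

## The core method

A cell with dye-channel intensity *x* is classified stained iff *x* ≥ *t*.
The threshold *t* is fitted on monoculture controls (known labels) by an
exhaustive ROC sweep: every distinct observed intensity is a candidate, and
for each the true-positive rate TPR (stained control ≥ *t*) and
false-positive rate FPR (unstained control ≥ *t*) are computed. The optimal
threshold minimises the distance to the perfect corner of ROC space,

&nbsp;&nbsp;&nbsp;&nbsp;*t*\* = argmin √(FPR² + (1 − TPR)²),

with maximisation of balanced accuracy (TPR + TNR)/2 as an alternative
criterion. Controls pooled across sampling times give a single "general"
threshold that already integrates the dye decay; one threshold is fitted
per stained competitor. Coculture frequencies follow with Wilson 95%
intervals, are reconciled against dilution-plate counts (30–300-colony
rule), and per-replicate trends are estimated as OLS slopes of frequency
and of logit frequency versus time — under discrete selection,
logit *f* is linear with slope *g*·ln *w* (generations/h × log relative
fitness). A fully parameterised simulator generates ground-truth-labelled
synthetic experiments, including the per-division dye halving
*I* ∝ 2^(−generations).

## Worked example

Simulate a paper-scale experiment (2 competitors, ratios 0.1/0.5/0.9, both
stained assignments, ± predator, 3 replicates, 6 time points, 2000 cells
per sample) and run the full pipeline:

```r
library(dyecomp)

ds  <- simulate_experiment(paperlike_config(seed = 42))
rep <- run_pipeline(ds)
rep
#> <pipeline_report> dyecomp 0.1.0 (config a4e0fcf9)
#>   threshold [a stained]: 20.4463 (accuracy 0.9905)
#>   threshold [b stained]: 20.101 (accuracy 0.9898)
#>   frequencies: 216 coculture samples
#>   condition trends: 12 conditions
#>   plate agreement: r = 0.993 (n = 216)
```

The fitted classifier for "competitor a stained" is a regular model object:

```r
rep$thresholds[["a"]]
#> Fluorescence classification threshold (criterion: closest_topleft)
#>   threshold: 20.4463
#>   TPR 0.9892  TNR 0.9918  accuracy 0.9905  average 0.9905
```

`threshold = 20.4` is the dye intensity above which a gated cell is called
stained; TPR/TNR ≈ 0.99 say that ~1% of control cells of either class are
misclassified at that cut. Frequencies per coculture sample come with
Wilson intervals (`freq_focal` is the frequency of the named focal
competitor, here "a"):

```r
head(rep$frequencies[, c("sample_id", "time_h", "freq_stained",
                         "ci_low", "ci_high")], 3)
#>               sample_id time_h freq_stained     ci_low    ci_high
#> 1 cc_r0.1_sa_p0_rep1_t0      0       0.1020 0.08948985 0.11603612
#> 2 cc_r0.1_sa_p0_rep1_t2      2       0.0825 0.07122771 0.09537303
#> 3 cc_r0.1_sa_p0_rep1_t4      4       0.0720 0.06147313 0.08416786
```

and the per-condition trend table aggregates replicate slopes (frequency
per hour) with a z-test against zero — here competitor a declines without
the predator and is rescued by it, exactly as the simulation programmed:

```r
subset(rep$condition_trends, !flagged)[1:2, ]
#>                          condition k   mean_slope           se       p_value
#> 1  ratio=0.1|stained=a|predator=no 3 -0.006661905 5.851527e-05  0.000000e+00
#> 2 ratio=0.1|stained=a|predator=yes 3  0.001604762 5.959377e-04  7.084730e-03
```

A thin command-line wrapper (`inst/cli/dyecomp`) exposes the stages as
`simulate`, `threshold`, `classify`, `analyze`, `validate` and `run`
subcommands for shell pipelines.

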