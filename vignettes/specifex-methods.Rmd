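---
title: "Methods: dual-cohort specificity analysis for eIF2B-related leukodystrophy"
author: "specifex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-cohort specificity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and study design

`specifex` reproduces, as reusable functions, the statistical pipeline
for identifying genes deregulated *specifically* in eIF2B-mutated
fibroblasts, as distinct from deregulation shared across
leukodystrophies. The design it models is a matched-couple, dual-cohort
two-channel microarray experiment: two cohorts (eIF2B-mutated patients,
and patients with other leukodystrophies, "OL"), ten patient/control
couples per cohort, each subject assayed under ER stress (1 µM
thapsigargin) and vehicle, each array co-hybridizing the sample channel
(G) with a pooled-control reference channel (R). Downstream stages add
qPCR validation in fibroblasts, cross-platform concordance, and
splice-isoform analysis (PLP/DM20, GFAP pan/α/δ) in brain tissue across
three developmental stages.

Because no primary data are publicly deposited, the package's
synthetic-data generator is the canonical input source: it emulates the
design's statistical structure and carries a ground-truth table so that
every downstream statistic can be checked against what was implanted.

## The synthetic generator

Log intensities are built additively:

```
log G[g, a] = baseline_g + array_a + disease shift + stress shift + noise
log R[g, a] = baseline_g + array_a + noise
```

with per-gene baselines `N(8, 1.5)` on the natural-log scale, per-array
offsets `N(0, 0.1)`, and observation noise `N(0, 0.05)` in both
channels. Baseline draws below 2 are redrawn: the expression-rate
statistic is a *ratio of corrected log values*, which loses meaning
near zero.

Implanted classes (defaults encode the published study counts):

* `shared_de` (183 = 253 − 70): shift −0.6 in the patients of **both**
  cohorts;
* `specific_down` (67) / `specific_up` (3): shifted **only** in eIF2B
  patients. The shift is chosen on the rate scale: for implanted rate
  `r` drawn from [0.66, 0.88] (down) or [1.06, 1.07] (up), the shift is
  `baseline · (r − 1)`, so the expected corrected-log-value ratio
  patient/control equals `r` exactly. With baselines near 8 the
  selection thresholds 0.9/1.05 correspond to log shifts of roughly
  −0.8/+0.4.
* `stress` (150): a per-gene shift `N(0, 0.5)` applied to every
  thapsigargin array, identical across groups — a treatment main
  effect that the ANOVA's treatment factor absorbs, never a
  status effect.

The array's noise magnitudes are not published; the defaults above are
asserted as this package's defaults, not as estimates of the original
arrays. The generator does not simulate probe-level structure, scanner
effects, dye bias, or intensity-dependent variance, so passing
recovery tests demonstrates correctness of the statistics, not
robustness to real-array artefacts.

The qPCR generator uses standard amplification kinetics,
`Ct = ct0_g − log2(relative expression) + noise`, with `ct0` per gene
in 22–30 cycles, B2M fixed at 20, replicate noise 0.2 cycles (2 RT
batches × 2 duplicates), and censoring at 40 cycles recorded with an
explicit flag. The implanted qPCR fold of a gene is its implanted
rate, applied in the cohorts its class prescribes.

The brain panel implants stage-specific folds into control baselines
chosen to mimic developmental expression: GFAP peaking in childhood;
PLP-family transcripts below detection in control foetal brain
(censored at 40 cycles), rising post-natally. Defaults: GFAPδ
mutated/control folds 2.0 / 4.5 / 7.0 (foetus / child / adult), pan-
and α-GFAP folds 1, post-natal PLP-family reduction 0.3, foetal
PLP+DM20/PLP ratio increase 2.0, 13-gene panel folds 1.5 (foetal) and
0.6 (post-natal). Group sizes default to 2/6, 7/5 and 2/3
(mutated/control); the child control group is set to 5 rather than the
literal 3 of the published roster so the Mann–Whitney test has usable
resolution at this scale (it is configurable back to 3).

Each generated table consumes its own seed derived from the master
seed, so stages are individually reproducible; identical configuration
and seed give byte-identical written outputs.

## Normalization

The correction formula is applied exactly as printed:

```
corrected_i = G_log_i − R_log_i + mean_i(R_log)
```

with the gene-wise mean reference level taken over **all** arrays
("across the different conditions"), not per treatment. Two recorded
choices: the log is natural (the source states only "logarithmic
transformation"; base is a config option), and standardization
defaults to *log only* — the correction already removes array- and
reference-level effects, and z-scaling each array before correcting
would double-normalize. Per-array centring/scaling remains available
as an explicit mode, and the order (standardize, then correct) is the
one implemented.

## Gene-wise ANOVA and selection

The additive fixed-effects decomposition is computed vectorized over
genes. In the balanced complete designs used here the factor subspaces
are orthogonal, so `SS_f = Σ_l n_l (mean_l − grand)²` and the residual
is total minus the factor sums; `F = (SS_f/df_f)/(SS_res/df_res)` with
p from the F distribution. Unbalanced designs require an explicit
opt-in and then use Type-I sequential sums of squares. Tests verify
equivalence with an explicit least-squares `aov()` fit to 1e-8
relative tolerance.

Numerical conventions: per-gene sums of squares below
`n · (1e-9 · scale)²` are clamped to zero so that effects that vanish
up to rounding can never produce spurious F ratios in noise-free data;
zero-variance genes report F = 0, p = 1 (conservative, logged); a real
effect over a zero residual reports F = ∞, p = 0.

The FDR procedure is not named in the source; Benjamini–Hochberg is
used (via `stats::p.adjust`) with the printed threshold 0.12 % applied
to q. The cross-cohort model compares eIF2B patients with OL patients
(controls excluded), factors cohort + treatment, couple variance in
the residual; its significance threshold is not printed and defaults
to the same 0.12 %. The expression rate is the ratio of corrected log
values exactly as printed — scale-dependent, but it is the statistic
the thresholds 0.9/1.05 were defined for. Selection intersects the
three filters; relaxing any threshold can only grow the set.

## Enrichment

The z-score is the hypergeometric standard score: for universe N,
category K, hit list n and overlap k, `μ = nK/N`,
`σ² = n(K/N)(1−K/N)(N−n)/(N−1)`, `z = (k−μ)/σ`, significant when
z > 3. This is the canonical "number of standard deviations" reading;
a binomial-variance mode is provided for sensitivity. No multiple-
testing adjustment is applied to z (the z > 3 rule is used raw). The
universe is an explicit required input because the original
annotation database's universe is unknowable; published z magnitudes
depend on that proprietary database and are not reproduced. The
packaged GMT is a synthetic example over the generator's gene symbols.

## qPCR and concordance

ΔCt is taken against B2M (fibroblasts and brain isoform panels) or
against the arithmetic mean of GAPDH and HPRT Cts where a dual
reference is wanted — the combination rule is not stated in the
source; the mean-of-Cts convention equals normalizing expression by
the geometric mean of reference expressions. The couple rate is
`2^−(ΔCt_patient − ΔCt_control)` with the leading minus: the Methods
formula carries it, the validation-table legend omits it, and the
direction of the printed rates (under-expressed genes < 1) shows the
legend's version is a typo. Treatments are averaged per couple, then
couples averaged. Censored Cts never enter means; a censored target
reports expression 0 ("undetectable"), never an extrapolation.

Concordance correlates per-couple microarray log ratios with
per-couple ΔΔCt (Pearson). A couple is discordant for a gene when
`sign(micro log ratio) ≠ sign(−ΔΔCt)`; couples discordant for ≥ 8 of
the 10 panel genes are excluded (the published exclusion narrative is
not operational; this sign rule is this package's declared
interpretation). N defaults to the number of retained couples. Cohort
correlations are compared with the Fisher transform and
`z = (Zf1−Zf2)/√(1/(N1−3)+1/(N2−3))`, two-sided normal p. When only
R² is available the positive root is used.

## Isoforms

Expressions are `2^−ΔCt` per sample; ratios are computed per sample
and then summarized (the alternative — ratios of group means — is not
the default; figure legends do not state the order, and per-sample
ratios give each donor equal weight). DM20 is extrapolated as
`(PLP+DM20) − PLP`; a negative extrapolation (possible under noise) is
flagged and its ratios withheld, never clipped. Samples with a
censored target are excluded from ratios. Stage-wise group tests
report `mean(mutated)/mean(control)` and a two-sided Mann–Whitney
p-value, reported as not computable when either group has a single
sample.

The Mann–Whitney wrapper uses the exact null distribution when both
groups are small (min n ≤ 8) and tie-free, and the tie-corrected
normal approximation otherwise, recording which was used.

## Problem sizes and determinism

The default simulation is 2000 genes × 80 arrays, which the vectorized
ANOVA handles in well under a second; the full pipeline runs in a few
seconds. Test-suite Monte-Carlo sizes (200 null-ANOVA simulations for
FDR calibration, 1000 null correlations, 2000 Fisher-Z replicates,
10⁶ hypergeometric draws) were chosen so that Monte-Carlo error is
several times smaller than the asserted tolerances. All randomness
flows from explicit seeds; identical seeds reproduce identical
reports.

## Known limitations

* The generator implants couple-constant effects, so cross-platform
  per-couple correlations in simulated data are driven by noise alone;
  the concordance machinery is therefore validated by its own oracles
  (hand Pearson, Fisher-Z calibration) rather than by high simulated
  R².
* One intensity per gene per channel; no probe-level or image-level
  simulation, no dye-swap handling, no loess/quantile normalization —
  the fixed-dye reference design does not need them.
* Published per-gene results (validation-table FDRs and rates,
  enrichment z magnitudes, Fisher-Z p-values) depend on unpublished
  primary data or a proprietary annotation database and are
  deliberately not targets; the validation-table Fisher-Z p-values are
  additionally not reproducible from the printed R² under any obvious
  N, so the Fisher-Z implementation is checked against an
  arbitrary-precision evaluation of the printed formulas instead.
* Protein-level (western blot) quantification is out of scope.
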