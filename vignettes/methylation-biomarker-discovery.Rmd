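---
title: "Discovering blood methylation biomarkers with methmark"
author: "methmark authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering blood methylation biomarkers with methmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methmark)
```

## The problem

Case/control epigenome-wide association studies (EWAS) on Illumina
450K-style arrays measure, at each CpG probe, a *beta value*
$\beta = M/(M+U) \in [0,1]$ — the fraction of methylated molecules.
Finding a blood biomarker from such data requires a chain of
well-understood but easy-to-get-wrong steps: probe-level quality
control, correction of the two probe chemistries, batch adjustment,
accounting for leukocyte composition, differential testing, marker
selection, and honest evaluation. `methmark` implements that chain
end-to-end and ships a synthetic-data generator with known ground truth
so every stage can be validated quantitatively.

## The generator: what it emulates

`generator_config()` describes a cohort. Betas arise as

1. a per-probe base level drawn from a sharply bimodal mixture
   (Beta(1.5, 18), Beta(18, 1.5), Beta(8, 8) at weights
   0.42/0.38/0.20), matching the peaked low/high methylation profile of
   real arrays — a softer base distribution makes the three-state
   decomposition used by BMIQ unstable, on synthetic and real data
   alike;
2. six latent cell-type profiles, identical except at a configurable
   set of discriminating probes, each hypermethylated in exactly one
   leukocyte type; per-sample cell proportions are Dirichlet draws
   (default concentrations 3, 5, 8, 3, 4, 27 for B, CD8T, CD4T, NK,
   monocytes, granulocytes — granulocyte-dominated, as in whole blood)
   and mixing happens **in beta space**, because a beta value is a
   molecule fraction and fractions mix linearly over cell populations;
3. compression of type-II probes toward 0.5 (default attenuation 0.75),
   emulating the reduced dynamic range of the type-II chemistry;
4. the planted case effect: `planted_dmp_count` probes (drawn from
   mid-range, autosomal, unflagged, non-discriminating probes) receive
   `delta_beta` (default 0.10) in the case group, added **after** the
   type-II compression so the realized group difference equals the
   configured one;
5. batch location/scale perturbations and Gaussian probe noise **in
   logit space** (default noise sd 0.15, batch shift sd 0.2), then the
   inverse-logit map back to $[0,1]$, clipped to
   $[10^{-6}, 1-10^{-6}]$ to avoid logit singularities;
6. detection p-value and bead-count failures planted entry-wise
   (defaults 0.002 and 0.01), and clinical scores drawn as truncated
   normals at the configured group means (ADOS 7.0 vs 1.5, ASSQ-R
   28.6 vs 6.1, matched IQ).

What it does **not** emulate: realistic genomic coordinates or probe
manifests, probe-specific variance structure, correlated probes within
regions, within-group association between methylation and clinical
severity (scores depend on group only — so a group-separating marker
will show a marginal clinical correlation here even though none was
planted within groups), age/sex effects on methylation, or non-Gaussian
batch pathologies. Tests passing on this generator therefore validate
the *machinery*; they do not certify performance on any real cohort.

## Quality control

`filter_probes()` removes, in order: probes with detection $p > 0.01$
in one or more samples; probes with bead count $< 3$ in strictly more
than 5% of samples; sex-chromosome probes; SNP-overlapping probes;
cross-reactive probes. Each removal is attributed to the first rule
that fires, so the report's counts add up to the input probe count and
the filter is idempotent. The strictly-greater reading of the 5% bead
rule is the conventional one; the boundary case (exactly 5%) is
retained.

## BMIQ normalization

Per sample, three-state beta mixtures are fitted separately to type-I
and type-II betas by EM: exact beta-density responsibilities, and a
weighted maximum-likelihood M-step solving the digamma system

$$\psi(a) - \psi(a+b) = \mathbb{E}_w[\log x], \qquad
  \psi(b) - \psi(a+b) = \mathbb{E}_w[\log(1-x)]$$

by damped Newton iteration (moment matching failed to converge on
realistic samples; the ML M-step converges in a few dozen EM sweeps).
Initialization is deterministic: observations are split at the
conventional methylation-state cutoffs 0.2/0.75 (with a tercile
fallback), and the type-II fit is warm-started from the converged
type-I fit so that the two state decompositions align — without that
alignment the two EMs can partition the same mass differently and the
mapping degrades.

Type-II values classified unmethylated (U) are mapped onto the type-I
U distribution by parametric quantile matching
($q_{U1}^{-1}(F_{U2}(x))$), likewise methylated (M); the intermediate
interval is carried by linear dilation between the two transformed
boundaries. Two numerical guards matter: region boundaries come from
the value axis (not the class labels), which makes the composite map
globally monotone, and each parametric map is capped at the central
90% of its component's CDF — in the far tails a tiny perturbation of
the fitted shapes moves extreme quantiles a lot, and the linear
dilation is more stable there. Type-I values are returned bit-identical.

## Batch adjustment

`batch_adjust()` works on logit-scale values and applies the named
batch variables sequentially (default: sex, then array batch), each via
the parametric empirical-Bayes location/scale model (ComBat, through
the `sva` package) with the group effect protected in the model matrix.
A variable with a single level is skipped; a singleton batch or perfect
batch/group confounding is an error. Whether sex is best treated as a
batch or a covariate is study-specific; the default mirrors the
workflow this package reproduces, and `batch_variables` is free.

## Cell-type deconvolution

`estimate_proportions()` solves, per sample, the constrained projection
$\min_{\omega \ge 0} \|y - R\omega\|^2$ over the reference profiles
$R$ (nonnegative least squares via `pracma::lsqnonneg`), then
renormalizes $\omega$ to sum to one, keeping the raw residual norm so
the renormalization hides nothing. The package ships no real reference:
the generator's latent profiles serve as a synthetic stand-in
(`truth$cell_reference`), and a real 450K reference can be supplied in
the same TSV format. Recovery on constructed mixtures is within
$\pm 0.05$ per proportion at additive noise sd 0.02.

## Differential methylation

`call_dmps()` fits probe-wise OLS **on beta values** (the selection
rule is expressed in beta units; M-value modelling is deliberately not
used), reports the covariate-adjusted group coefficient alongside the
raw group mean difference, and moderates variances empirically:
$(d_0, s_0^2)$ are estimated by moment matching of $\log s^2$ against
the scaled-F marginal (the `trigamma` inversion solved by Newton), the
posterior variance is $(d_0 s_0^2 + d s^2)/(d_0 + d)$, and the
moderated $t$ has $d_0 + d$ degrees of freedom, capped at the pooled
residual df. The two limits are exact: $d_0 = 0$ reproduces the
ordinary $t$, $d_0 = \infty$ pools fully with $s_0^2$ equal to the mean
variance. Selection keeps probes with BH-FDR $\le 0.1$ **and**
$|\Delta\beta| \ge 0.1$. Note a knife-edge property of that rule: if
the true effect is exactly 0.1, each probe's empirical effect clears
the cutoff about half the time, so "recall" of planted probes through
the joint rule hovers near 0.5 even when the FDR component alone finds
essentially all of them. The default screening model carries no
covariates; a covariate-adjusted design is one argument away.

## CALF marker selection

`greedy_fit()` restricts weights to $\pm 1$ on z-scored features
(unit weights are only meaningful on a common scale — the largest free
choice in this module, recorded here deliberately). Each step evaluates
every remaining (feature, sign) pair added to the running signed sum
and accepts the best only on strict improvement of the metric (Pearson
correlation of the score with the labels by default; AUC available),
stopping at the feature limit (default 10). Ties break to the lowest
feature index, then $+1$. For the Pearson metric the sweep uses exact
closed-form updates of $\mathrm{cov}(s, y)$ and $\mathrm{var}(s)$ from
the feature covariance matrix, so one full refit costs $O(p)$ per step
— this is what makes the resampling wrappers cheap.

`permutation_test()` reruns the *entire* greedy procedure on 2000
uniformly permuted label vectors; the empirical p is
$\max(b, 1)/N$ with $b$ the count of permuted final metrics at or above
the observed one, giving an attainable floor of $1/2000 = 5\times
10^{-4}$ under strong separation. The $(b+1)/(N+1)$ estimator is
available behind a flag. `stability_selection()` draws
$\lceil 0.8\, n_{\text{class}}\rceil$ samples per class without
replacement, 2000 times, re-z-scoring within each subsample;
`consensus_markers()` intersects features selected in at least 750
trials with the full-data model, ordered by stability count.

## Random forest importance

The forest (compiled, in `src/`) grows 500 trees on bootstrap samples,
sampling `mtry` features per node and splitting at midpoints between
consecutive distinct values to maximize the weighted Gini decrease;
ties break to the lowest feature index, then the lowest threshold, so a
fixed seed reproduces the forest bit for bit. Mean decrease Gini is the
node-proportion-weighted sum of decreases per feature divided by the
tree count, and per tree these decreases exactly telescope to root
impurity minus leaf impurity — an invariant the tests assert. `mtry`
is tuned by repeated stratified 10-fold cross-validation over the
neighborhood $\lfloor\sqrt p\rfloor \pm 2$ (three repeats by default;
the repeat count is a free choice), ties to the smallest value.

## Evaluation

`roc_auc()` is the Mann–Whitney statistic with tie correction.
`adjusted_auc()` fits `label ~ marker + covariates` by IRLS and scores
the linear predictor, falling back (and logging) to the unadjusted
marker under separation. Confidence intervals are class-stratified
percentile bootstrap with 2000 replications — percentile rather than
BCa as the simplest reproducible reading, and stratified resampling
means no replicate can lose a class. The operating point maximizes
Youden's $J$ over midpoint thresholds, ties to the higher specificity;
the criterion behind any published sensitivity/specificity pair is
rarely stated, so the Youden choice is logged in every report.

## Orchestration, sizes and determinism

`run_pipeline()` chains QC → BMIQ → batch → deconvolution → DMPs →
forest + CALF → consensus → ROC, writes every artifact as TSV/JSON
under one output directory, and derives per-stage seeds from the global
seed by stage-name hashing, so a rerun with the same config is
byte-identical. The numbered scripts under `analysis/` present the
same chain as a narrative workflow at a 5000-probe, 30 + 30-sample
scale; the test suite exercises the stages at 500–20000 probes and the
resampling wrappers at 200–2000 iterations, sizes chosen to make the
statistical assertions sharp at desk scale. Every default that encodes
a study setting (0.1/0.1 selection, limit 10, 2000/2000/0.8/750
resampling, 500 trees, 2000 bootstrap replications) is asserted by a
table-driven test.

## Known limitations

BMIQ's linear dilation matches the intermediate region only to first
order; the deconvolution reference is synthetic unless the user
supplies one; the forest implements classification with Gini importance
only (no permutation importance, no regression mode); CALF's
continuous-outcome mode and weight magnitudes beyond $\pm 1$ are out of
scope; and the generator's independence assumptions (between probes,
and between clinical scores and methylation within groups) make some
real-data failure modes invisible to the test suite.
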