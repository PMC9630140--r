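---
title: "Quantifying canalized caste differentiation with antcaste"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying canalized caste differentiation with antcaste}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antcaste)
```

## The problem

Social-insect colonies produce discrete adult phenotypes — reproductive
gynes (future queens) and non-reproductive workers — from the same genome.
Early larvae of the two castes are morphologically indistinguishable, yet
their transcriptomes already begin to diverge, and development appears to
*canalize*: between-caste expression differences grow with each stage while
within-caste variation shrinks, so that trajectories converge robustly onto
one of the two target phenotypes. antcaste implements a coherent set of
estimators for this process on per-individual expression profiles ordered
by developmental stage:

* **Backward caste prediction** (`bpa_run()`): transfer caste labels from a
  late, morphologically distinguishable stage to earlier, unlabelled stages.
* **Developmental potential** (`developmental_potential()`): a per-individual
  commitment score $\Delta$ based on Manhattan distances to next-stage caste
  centroids.
* **Gene-level canalization** (`canalization_score()`): a per-gene score
  combining expression divergence with its developmental trend.
* Supporting machinery: trajectory networks, cross-species stage alignment,
  body-size-adjusted differential expression, two-phase threshold
  regression, and a planted-truth simulator.

## Data model and normalization

An `ExpressionDataset` is a gene × sample matrix plus per-sample metadata
(species, stage with an explicit total order, caste, optional body length
in mm). Values enter raw (counts or TPM) and are transformed once by
`log_normalize()` to $\log_2(x + 1)$; every statistic in the package
operates on this log2 scale and refuses raw input, so the convention is
explicit rather than guessed. Missing entries are rejected, never imputed.

Two further normalizations are separate, logged steps:

* `standardize_within_stage()` z-scores each gene within each stage
  (sample SD, $n-1$ denominator; zero-variance genes map to zeros so
  shapes stay aligned). This is required before distance-based scores so
  stages contribute comparable units.
* `batch_adjust()` removes a batch covariate per gene by shifting each
  batch to the common grand mean and rescaling each batch's residuals to
  the pooled (df-weighted) variance. This deterministic location–scale
  adjustment is the default; an empirical-Bayes variant (`eb = TRUE`,
  delegating to the sva package) is available but off by default because
  the contract we rely on is exactly mean equalization plus variance
  pooling. The grand mean per gene is preserved to numerical precision.

## Backward prediction

Each round of `bpa_run()` treats two adjacent stages: the later one carries
trusted (or previously predicted) labels, the earlier one is to be
predicted.

1. *Normalization*: both stages are combined and `batch_adjust()` removes
   the stage effect (stage as batch), always on the full gene set.
2. *Feature selection*: PCA is fitted on the prediction-stage samples only
   (they define the axes; centring uses their means), optionally after
   restricting to caste marker genes. Training samples are projected
   through the same centring and rotation, and each of the top `n_pcs`
   (default 10) projected scores is screened by one-way ANOVA against the
   training labels. All axes with Bonferroni-adjusted $p < 0.05$ are kept;
   if none pass, the single minimum-p axis is used so at least one axis is
   always available. PC signs are fixed (largest-magnitude loading
   positive) so runs are bit-reproducible.
3. *Training*: a two-class linear discriminant with shared covariance and
   equal priors (class frequencies in a discovery sample reflect sampling,
   not prevalence; empirical priors are a flag). With equal priors the
   posterior is logistic in the discriminant score, which makes the
   label-swap symmetry $p \leftrightarrow 1-p$ exact. A singular pooled
   covariance is ridge-regularized with a logged strength.
4. *Prediction*: posterior probabilities for the earlier stage; a hard
   label needs posterior $\ge 0.9$ by default, everything else stays
   unassigned and is excluded from later training rounds.

**Score calibration.** Because the PC axes are estimated from the
prediction samples themselves in a $n \ll p$ regime, the prediction
scores have systematically larger spread along those axes than the
projected training scores (the axes partly fit prediction-specific
noise). Applying a discriminant trained at the training-score scale to
raw prediction scores therefore produces overconfident posteriors even
when no class signal exists. `bpa_predict_stage()` consequently
location/scale-matches the prediction scores to the training score
distribution on each selected axis before applying the discriminant —
the same philosophy as step 1, applied at the axis level. On null
simulations this brings the confident-assignment fraction from ~0.7 down
to well under 0.1 without affecting accuracy when signal is present.

## Developmental potential

After within-stage standardization, each stage-$t$ individual $i$ is scored
against the stage-$t{+}1$ caste centroids:

$$\Delta_{i,t} = \frac{\mathrm{dist}(i, \mathrm{worker}_{t+1}) -
\mathrm{dist}(i, \mathrm{gyne}_{t+1})}{\mathrm{dist}(\mathrm{gyne}_{t+1},
\mathrm{worker}_{t+1})}$$

with Manhattan ($L_1$) distances. $\Delta = +1$ at the gyne centroid,
$-1$ at the worker centroid, and 0 at their coordinate-wise midpoint
(an $L_1$ identity). Values are reported unclipped; outliers may exceed
$\pm 1$. Identical centroids are a hard error rather than a silent NaN.

## Gene-level canalization

At each stage with both castes the per-gene divergence statistic is

$$t_g = \frac{\overline{\mathrm{Exp}}_{\mathrm{gyne}} -
\overline{\mathrm{Exp}}_{\mathrm{worker}}}{s_p}, \qquad
s_p = \sqrt{S_{\mathrm{gyne}}^2 + S_{\mathrm{worker}}^2}$$

with sample standard deviations and deliberately *no* $1/n$ factors: this
is the literal published form of the statistic, a divergence-to-spread
ratio rather than a calibrated test statistic. The Welch-style
$\sqrt{S_g^2/n_g + S_w^2/n_w}$ form is available behind `welch = TRUE` for
users who want sampling-variance units; the default follows the printed
definition. When $s_p = 0$ with equal means, $t = 0$; with unequal means
$t$ is undefined (`NA`) and the gene is excluded from trend tests with a
reported count — never $\pm\infty$.

The trend statistic is a one-sided (increasing) Spearman correlation of
$|t_g|$ against the stage index, giving $P_g$, and

$$C_g = -\log_{10}(P_g) \times t_{g,\mathrm{final}}$$

where the final stage defaults to the last one supplied (the late pupal
stage in the motivating design, when morphological differentiation is
essentially complete). A gene is *canalized* when $P_g < 0.05$ and
$|C_g| > 3$; both thresholds are arguments. The p-value is exact: the
tie-free case uses the exact Spearman null for $n \le 9$ stages, tied
$|t|$ series are handled by full permutation enumeration for $n \le 7$,
and only larger $n$ fall back to the asymptotic approximation. With $n$
stages the smallest attainable one-sided p is $1/n!$ — at four stages
that is $1/24 \approx 0.042$, so the $P<0.05$ gate is attainable only by
a perfectly monotone $|t|$ series; this is worth knowing when choosing
how many stages to score.

Cross-species conservation (`conserved_canalization_test()`) compares
same-direction canalized genes through a one-to-one orthologue map against
the independence expectation $\sum_{\mathrm{dir}} n_{A} n_{B} / U$ and
tests enrichment with the package's own exact Fisher test
(`fisher_exact_2x2()`, minimum-likelihood two-sided convention — the
convention matters at the second decimal for small tables, and the
doubling convention would disagree with the worked example in the test
suite).

## Expression models

`size_adjusted_deg()` fits `Exp ~ caste + log(body length)` per gene by
ordinary least squares on log2 expression. The bespoke content here is
the model formula and the decision rule (BH-adjusted caste $p < 0.05$
*and* robust $|\log_2 \mathrm{FC}|$ above a threshold, default
$\log_2 1.6$), not count-level dispersion modelling: the gaussian
approximation on log2 values keeps the estimator transparent, and the DE
step is isolated behind its own interface so a count-model backend could
be substituted. The fold-change is re-estimated by Huber M-estimation
(tuning constant 1.345, MAD scale) so single outlier individuals cannot
inflate it.

`threshold_regression()` fits the continuous two-phase (hinge) model
$y = a + b_1 x + b_2 \max(0, x - c)$ over a grid of candidate breaks $c$
— the unique observed body lengths with 10% trimmed from each end, and at
least two distinct values required on each side, so both slopes are
identifiable. The printed two-slope form of the model has no intercept,
but the continuous segmented model family it names requires continuity at
the break, so a continuous hinge with intercept is fitted and
$\alpha = b_1$, $\beta = b_1 + b_2$ are reported. Significance against
the single-slope null uses $n\log(\mathrm{RSS}_0/\mathrm{RSS}_1)$ with a
$\chi^2_1$ approximation by default; because the changepoint null is
non-standard this is labelled in the output and a parametric bootstrap
(`bootstrap = N`) is provided. The recovered break is only meaningful to
the local grid resolution, which the fit object exposes.

## What the simulator emulates — and what it does not

`simulate_dataset()` generates log2-scale expression as
baseline + stage offset + caste effect + gaussian noise:

* caste effects ramp linearly, $E_{\max}\, s/S$ at stage $s$ of $S$, with
  gene-specific direction, for a configurable fraction of genes
  (default 10%);
* within-caste SD shrinks linearly across stages (1.0 → 0.3 by default) —
  together with the ramp this is the canalization signature;
* stage offsets (SD 2) are shared by castes, giving the backward
  prediction a real batch structure to remove;
* body length grows linearly per caste with noise, so size is correlated
  with both stage and caste, a genuine confound for the DE model;
* optional genes driven purely by log body length, and an optional hinge
  gene with caste-specific break positions (0.7 mm worker / 1.4 mm gyne
  in the `threshold_shift` preset).

The ramp starts at $E_{\max}/S$, not zero, because in the emulated system
caste is determined before the first sampled stage; a zero first-stage
effect would make early-stage caste prediction undefined rather than
merely hard. The default sizes (4 stages × 2 castes × 12 individuals,
600 genes; 5 × 20 × 200 for the threshold preset) were chosen once as a
realistic desk-scale rendering of a per-individual larval RNA-seq design
and keep the whole validation suite fast.

Deliberately **not** emulated: negative-binomial count noise (an optional
count mode exercises the I/O path, but all in-scope statistics operate on
log2 values), library-size variation, real gene counts, correlated gene
modules, or sex structure. Passing tests therefore demonstrate that the
estimators recover planted structure under gaussian log-scale noise with
independent genes — they do not certify performance under real count
overdispersion or correlated backgrounds.

## Numerical conventions

* Sample SD ($n-1$) everywhere, including $t_g$ components and
  within-stage standardization.
* Average ranks for Spearman ties; constant vectors give `NA` similarities
  with a warning, never silent zeros.
* Argmin ties in stage alignment break toward the earlier stage and are
  reported; grid ties in threshold regression break toward the smaller
  break.
* PCA signs fixed by the largest-magnitude loading; all simulator and
  layout randomness flows through explicit seeds and global RNG state is
  restored afterwards.
* `fisher_exact_2x2()` sums point probabilities $\le$ the observed one
  with a $1 + 10^{-7}$ relative tolerance, matching standard practice.

## A worked run

```{r example, eval = FALSE}
library(antcaste)
sim <- simulate_dataset(default_scenarios()$strong_canalization, seed = 1)
ds <- sim$dataset

# backward prediction: labels only at the last stage
masked <- ds
masked$metadata$caste[masked$metadata$stage != "S4"] <- "unknown"
run <- bpa_run(masked, labelled_stage = "S4", target_stage = "S1")
print(run)

# commitment scores and canalized genes
std <- standardize_within_stage(ds)
pot <- developmental_potential(std, "S3", "S4")
canal <- canalization_score(ds)
print(canal)
```

The same flow is available non-interactively: `run_pipeline()` executes a
YAML-configured step list with a JSON manifest (config hash, file
checksums, per-step parameters), and `exec/antcaste` exposes each step as
a shell subcommand.

## Known limitations

* The gaussian DE approximation will be anti-conservative on raw counts
  with strong mean–variance coupling; feed it log-normalized data only.
* The $\chi^2_1$ LRT for the threshold model is approximate; use the
  bootstrap option when the decision matters.
* With fewer than five stages the canalization trend test has very coarse
  p-value granularity (see above).
* The backward iteration propagates only confident labels; if castes are
  genuinely balanced but weakly separated at some intermediate stage, the
  run can halt early (it does so loudly, with partial results).
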