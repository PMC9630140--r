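# antcaste

Tools for tracking and quantifying **canalized caste differentiation**
across developmental-stage transcriptomes of social insects.

Colonies produce two discrete adult phenotypes from one genome:
reproductive gynes (future queens) and workers. Early larvae look
identical, but their transcriptomes diverge progressively — and
development *canalizes*: between-caste expression differences grow stage
by stage while within-caste variation shrinks. antcaste provides the
estimators needed to measure this process from per-individual expression
matrices:

* **Backward caste prediction** (`bpa_run()`) — transfers caste labels
  from a late, labelled stage to earlier unlabelled stages, one adjacent
  stage pair at a time: stage-as-batch normalization, PCA on the
  prediction stage, ANOVA selection of caste axes among the projected
  training scores, and a two-class linear discriminant that assigns hard
  labels only at posterior ≥ 0.9.
* **Developmental potential** — the commitment score
  `Δ = (dist(i, worker_{t+1}) − dist(i, gyne_{t+1})) / dist(gyne_{t+1}, worker_{t+1})`
  with Manhattan distances on within-stage standardized expression:
  +1 at the gyne centroid, −1 at the worker centroid.
* **Gene-level canalization** — per stage
  `t_g = (mean_gyne − mean_worker) / sqrt(S_gyne² + S_worker²)`; the trend
  p-value `P_g` of |t| against stage order (one-sided exact Spearman) and
  `C_g = −log10(P_g) × t_final`; a gene is canalized when `P_g < 0.05`
  and `|C_g| > 3`.
* Supporting machinery: Spearman similarity trajectory networks with 0.8
  edge pruning and Fruchterman–Reingold layout, cross-species stage
  alignment through one-to-one orthologues, body-size-adjusted
  differential expression (`Exp ~ caste + log(body length)` with robust
  fold-changes), two-phase (hinge) body-length threshold regression with
  a likelihood-ratio test, an exact two-sided Fisher test, relative
  tissue-expression profiles, and a planted-truth simulator
  (`simulate_dataset()`, `default_scenarios()`) that makes every
  estimator testable without external data.

## A worked example

```r
library(antcaste)

sim <- simulate_dataset(default_scenarios()$strong_canalization, seed = 1)
ds  <- sim$dataset

masked <- ds
masked$metadata$caste[masked$metadata$stage != "S4"] <- "unknown"
run <- bpa_run(masked, labelled_stage = "S4", target_stage = "S1")
print(run)
#> BPA run: S4 -> S1 (confidence 0.90)
#>   S3: 24/24 confidently assigned (PCs 1)
#>   S2: 24/24 confidently assigned (PCs 1,5)
#>   S1: 24/24 confidently assigned (PCs 1,6)

canal <- canalization_score(ds)
print(canal)
#> Canalization table: 600 genes over stages S1, S2, S3, S4 (final S4)
#> canalized (P < 0.05, |C| > 3): 60  [gyne-biased:32, worker-biased:28]
```

Every sample at the earliest stage is confidently assigned (the preset
plants a strong caste signal), and the 60 genes carrying the planted
canalization signature are recovered — here with no false positives among
the 540 null genes (compare `sim$truth$genes`).

The threshold-regression workflow recovers heterochronic shifts between
castes:

```r
simt <- simulate_dataset(default_scenarios()$threshold_shift, seed = 1)
print(caste_threshold_comparison(simt$dataset, "gene_hinge"))
#> Caste threshold comparison for gene gene_hinge
#>   gyne: threshold 1.4 mm (p = 3.19e-72 *)
#>   worker: threshold 0.688 mm (p = 6.71e-38 *)
#>   difference (gyne - worker): 0.7118 mm (grid resolution 0.0726)
```

A YAML-driven pipeline (`run_pipeline()`) and a shell front end
(`exec/antcaste` with subcommands `simulate network align bpa potential
canalize deg threshold pipeline`) wrap the same functions and write TSV
outputs plus a JSON run manifest.

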