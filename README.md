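# cobindsig

Tools for linking transcription-factor **co-binding at gene promoters**
to **expression signatures** and **patient outcome**, motivated by the
regulatory biology of glioblastoma, where a HIF-1α/TCF1 complex under
hypoxia and TCF4 under normoxia compete over the promoters of neuronal
differentiation genes, and where the burden of up-regulated Wnt pathway
genes stratifies patient survival.

The package implements, as reusable and separately testable stages:

* **Peak-to-TSS annotation** — strand-aware assignment of ChIP-seq peak
  summits to genes within a closed window around the TSS (default
  −2 kb … +6 kb in transcription direction), from BED6/narrowPeak and
  GFF3/TSV inputs (0-based half-open internally).
* **Co-binding architecture** — joint TSS-distance densities, composite
  summit profiles around shared anchors, and detection of the composite
  binding-window geometry: a shared-occupancy window (both factors ≥ 50%
  of their own profile maximum) flanked by factor-specific windows. The
  canonical planted geometry is a 40 bp shared window upstream of the
  anchor with two consecutive 20 bp factor-specific downstream flanks.
* **SAM-style differential expression** — the moderated statistic
  `d_i = (mean₂ − mean₁)/(s_i + s₀)` with a Tusher-style s₀ percentile
  search and a balanced label-permutation FDR (exhaustive 70 splits for
  4 vs 4 designs), selecting the largest gene set with estimated
  FDR ≤ target.
* **Signature set algebra** — gene lists combined with `∩ ∪ \`
  (left-to-right, parenthesized), each signature carrying its provenance
  expression.
* **Burden survival** — per-gene cohort z-scores, per-patient counts of
  panel genes with `z ≥ 1.5`, stratification at `burden ≥ 7`,
  Kaplan-Meier/log-rank, and a single-covariate Cox (Breslow ties) Wald
  scan over every achievable burden cutoff.
* **Limiting dilution** — single-hit Poisson frequency estimation
  (`fraction negative = e^(−f·n)`) by weighted log-linear regression
  through the origin, with a two-slope contrast between conditions, plus
  the 0–18 immunohistochemistry combined score (positivity bin 0–6 ×
  intensity 0–3).
* **A synthetic-data generator** for every input class, with recorded
  ground truth, so each stage is validated by parameter recovery.

See `vignettes/cobinding-pipeline.Rmd` for the model details, parameter
defaults, and design decisions.

## Worked example

```r
library(cobindsig)

## plant the canonical architecture on 2,000 genes and recover it
ann   <- simulate_annotation(2000, c(chr1 = 4e7), min_spacing = 15000, seed = 1)
specs <- planted_architecture_specs(ann$gene_id, background_per_mb = 2)
pa <- simulate_peaks(ann, specs$a, seed = 2)
pb <- simulate_peaks(ann, specs$b, seed = 3)
pairs <- cobound_genes(assign_peaks(pa$peaks, ann), assign_peaks(pb$peaks, ann))
prof  <- composite_profiles(rbind(pa$peaks, pb$peaks),
                            tss_anchors(ann, pairs$gene_id))
detect_architecture(prof)
#> architecture_call (threshold 0.5 x track max)
#>   shared window: [-40, 0] bp (width 40)
#>   TCF1:hypoxia specific: [0, 20]; mean offset -9.4 bp
#>   HIF1A:hypoxia specific: [20, 40]; mean offset -3.5 bp

## burden-driven survival: planted HR 3 at burden >= 7 of a 44-gene panel
pe <- simulate_panel_expression(400, seed = 4)
sv <- simulate_survival(pe$matrix, survival_spec(), seed = 5)
bt <- burden_table(pe$matrix, sv$survival, sprintf("WNT%02d", 1:44))
lr  <- logrank_test(bt$stratum, bt$time, bt$event)
cox <- cox_binary(bt$time, bt$event, bt$stratum == "high")
#> log-rank chi2 = 86.4 (p = 1.46e-20); Cox HR = 2.91 [2.31, 3.68]

## limiting dilution at a true frequency of 1/100
dilution_fit(simulate_dilution(dilution_spec(0.01), seed = 6))
#> dilution_fit: frequency 1/103.7 (f = 0.0096459),
#>               95% CI [0.0073496, 0.011942], 5 doses
```

The architecture call reproduces the planted 40/20/20 bp geometry with
the factor order intact; the Cox confidence interval covers the planted
hazard ratio of 3; the dilution CI covers the planted frequency 0.01.

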