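---
title: "From co-binding architecture to survival burden: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From co-binding architecture to survival burden: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis chain

`cobindsig` implements a chain that starts with transcription-factor peak
calls near gene promoters and ends at patient stratification:

1. **Peak-to-TSS annotation.** Each peak's summit is assigned to genes
   whose strand-oriented distance `d = (summit - TSS) * strand` falls in
   a closed window around the TSS, by default `[-2000, +6000]` bp
   (negative = upstream in transcription direction). The window is the
   promoter-proximal regulatory neighbourhood used throughout; it is a
   configuration value, not a constant.
2. **Co-binding.** Genes bound by both factors of a designated pair
   (in glioblastoma biology, HIF-1α and TCF1 under hypoxia), with one
   representative peak per gene per factor (minimal `|d|`, ties toward
   the more upstream peak, then peak start).
3. **Composite profiles and architecture.** Summit counts per offset bin
   around per-gene anchors, averaged over anchors; a bin is *occupied*
   when a factor's profile reaches 50% of its own maximum (scale-free
   per-factor threshold). The *shared window* is the longest run of bins
   occupied by all factors; *factor-specific windows* are runs occupied
   by exactly one. This operationalizes the composite geometry of a
   shared-occupancy window flanked by consecutive factor-specific
   windows, and makes its widths and order measurable quantities.
4. **Signatures.** Gene lists combined with explicit set algebra
   (`∩`, `∪`, `\`, left-to-right with parentheses), with the expression
   recorded as the signature's provenance. Any unexplained manual
   curation between published list sizes is represented only as a
   user-supplied filter list, never inferred.
5. **Differential expression.** A SAM-style moderated statistic
   `d = (m2 - m1)/(s + s0)` with permutation FDR (details below).
6. **Burden survival.** Per-gene cohort z-scores, per-patient counts of
   panel genes with `z >= 1.5`, stratification at `burden >= 7`,
   Kaplan-Meier curves, log-rank test, and a single-covariate Cox
   (Breslow ties) Wald scan over every achievable cutoff.
7. **Limiting dilution.** Single-hit Poisson frequency estimation from
   negative-well fractions, with a two-slope contrast for comparing
   conditions.

# Anchors: a degeneracy worth knowing about

The natural anchor for a co-bound gene is the mean of its two
representative summits (`anchor_positions()`). But with exactly two
summits per gene, both offsets relative to their own mean are
`±(s_A - s_B)/2`: the two factors' profiles around pair-mean anchors are
*exact mirror images of each other*, whatever geometry was planted. A
left-shared/right-specific architecture can therefore never be read off
profiles anchored this way; the construction is structurally symmetric.
Read-density profiles do not suffer from this because reads spread over
the whole fragment distribution, but summit profiles do.

`composite_profiles()` therefore accepts any anchor table, and the
architecture stage anchors on the annotation's TSS positions
(`tss_anchors()`) by default, which are summit-independent.
`anchor_positions()` is retained for the co-localization scatter and for
workflows where a summit-centred reference is wanted, and the CLI
exposes both (`--anchors pair-mean`).

# The SAM statistic and its FDR

* `s_i` is the pooled equal-variance standard error of the group mean
  difference; the two-class unpaired case is the one exercised here
  (e.g. tumor core vs periphery, n = 4 vs 4).
* `s0` follows the percentile search of Tusher et al.: among the 5%
  quantiles of `{s_i}`, pick the one minimizing the coefficient of
  variation of the d spread (MAD/0.64) across 100 s-quantile windows.
  Below 100 genes the search is unstable and the median of `{s_i}` is
  used.
* Permutations are balanced label splits. With 4 + 4 samples all 70
  splits are enumerated — at this scale exhaustion removes Monte-Carlo
  noise entirely and makes the result seed-free. Larger designs draw
  `n_permutations` distinct random splits (excluding the observed one).
* For each symmetric cutoff `c` on `|d|`, the estimated false-call count
  is the **mean** exceedance `#{|d*| >= c}` over permutations, and
  `FDR(c)` = estimated false calls / observed calls. The significant set
  is the largest one with `FDR <= target`.

Why the mean and not the per-cutoff median? When the enumeration is
exhaustive the observed split is one of its own permutations, so the
mean-based rule is an add-one estimator: the top gene is called only
when fewer than `target * B` of the `B` splits produce an equally
extreme maximum — a Westfall-Young-style max-statistic test whose
false-positive rate on null data is `~3/70 ≈ 4%` at a 5% target. The
median of the (mostly zero) exceedance counts, by contrast, collapses to
zero whenever the observed maximum ranks in the top half of the
permutation maxima, which on pure-null data happens about half the
time and would call one spurious gene accordingly. The median is still
reported per cutoff in `fdr_table`, and `estimator = "median"` is
available for comparison.

# Burden survival: what the generator emulates

`simulate_panel_expression()` gives every patient a continuous pathway
activation level `w ~ U(0, 0.5)` and shifts each panel gene by 6
noise-SD units with probability `w`. Two consequences are intentional:

* the realized burden (panel genes at cohort `z >= 1.5`) spreads
  smoothly across its range instead of separating into two distant
  modes, so neighbouring cutoffs produce genuinely different strata and
  a Wald scan has something to localize;
* the planted threshold is *exact by construction*: the survival
  simulator computes each patient's burden with the same
  `zscore_matrix()`/`burden_scores()` code and applies the hazard ratio
  to `burden >= 7`, so recovery tests measure the pipeline, not the
  generator's calibration.

Event times are exponential with
`log-hazard = log(baseline) + log(HR) * 1(burden >= 7)`; censoring is
independent uniform on `(0, m)` with `m` solved numerically so the
expected censored fraction matches `censoring_rate` (default 0.2).
Default cohort size is 519, the size of a TCGA glioblastoma cohort
split 33 / 486 by this kind of burden rule. The z-threshold comparison
defaults to `>=` (the stratum partition "0-6" vs ">=7"); a strict `>`
is available because the two conventions both appear in practice and
differ only for patients sitting exactly on the threshold.

The cutoff scan reports **every** cutoff with both strata non-empty and
flags the minimal-p row with an explicit multiple-testing caveat; a
single "significant cutoff" is a selection over correlated tests and is
never auto-applied silently.

# Limiting dilution

Under the single-hit Poisson model the negative-well fraction at dose
`n` is `exp(-f n)`, so `ln(p)` is linear through the origin with slope
`-f`. The fit is weighted least squares with delta-method
inverse-variance weights `wells * p/(1 - p)`; doses with `p = 1` use a
half-count continuity correction in the weight only, dose-0 control
rows and all-positive doses (log undefined) are excluded, and at least
two usable doses are required. The 95% CI uses the t distribution on
`n_doses - 1` degrees of freedom, which keeps coverage honest at the
4-6 doses typical of a 96-well design. Condition comparisons use the
two-slope contrast with Welch-Satterthwaite degrees of freedom, the
regression analogue of the covariance-analysis slope test.

# Numerical choices and conventions

* **Coordinates** are 0-based half-open everywhere inside the package
  (BED convention); GFF3 is converted at the I/O boundary
  (`+` gene at 1-based 1001..2000 → TSS 1000; `-` gene → TSS 1999).
* **Missing narrowPeak summits** (offset -1) fall back to the interval
  midpoint `floor((start + end)/2)`.
* **Peak scores** are kept but unfiltered by default (`score_min=`
  opt-in), since no filtering rule beyond the caller's own thresholds
  is assumed.
* **Anchor rounding** is half-down (`floor` of the summit mean).
* **Window membership** is summit-based and closed on both bounds
  (`+6000` is in, `+6001` is out); interval-overlap membership and an
  unstranded window are configuration switches, because either reading
  is defensible when a method description does not pin them down.
* **Occupancy runs** are strict (gap tolerance 0) by default;
  `gap_tolerance` can bridge single noisy bins.
* **Cox ties** use Breslow's approximation, named in the output;
  monotone likelihoods are flagged (`infinite = TRUE`) rather than
  returned as large finite estimates.
* **Ward clustering** is `hclust`'s `ward.D2` (variance criterion on
  unsquared Euclidean distances); small instances are validated against
  an exhaustive Lance-Williams agglomeration in the tests.
* **Tie-breaks** are documented and deterministic throughout: upstream
  peak then peak start for representative assignments, lexicographic
  gene id in fold-change rankings.

# What the tests do and do not show

The synthetic module plants: uniform-mixture summit offsets around gene
anchors (the 40 bp + 2 × 20 bp geometry), group-shifted Gaussian
log-expression, burden-thresholded exponential survival, and binomial
single-hit well counts. Problem sizes in the recovery suite are the
package's validation conditions: 5,000 co-bound genes × 10 replicates
for architecture; 200 genes × 500 peaks × 20 fixtures against the
brute-force assignment oracle; 1,000 genes, 4 vs 4, exhaustive
70-permutation SAM nulls × 40 replicates and 50 planted genes at
3 SD, 10 vs 10 × 20 replicates; cohorts of 400 × 50 (cutoff scan) and
× 100 (HR coverage); 100 dilution replicates at f = 0.01.

Passing these says the pipeline recovers what its own generative model
plants. Real ChIP-seq and microarray data violate that model in known
ways the generator deliberately omits: read-level noise and peak-caller
artefacts, probe effects and batch structure, correlated genes,
non-proportional hazards, copy-number confounding. Results on real data
inherit those caveats; the recovery suite bounds implementation error,
not biological validity.

# Known limitations

* Two-factor architecture only; a third factor can be profiled on the
  same anchors but does not enter the overlap definition.
* No significance test of co-occurrence against genomic background, and
  no motif analysis — the windows are descriptive.
* The Cox stage is single-covariate by design; clinical covariates are
  out of scope.
* The limiting-dilution CI is the regression CI; likelihood-based
  single-hit confidence machinery is not reimplemented.
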