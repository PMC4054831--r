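---
title: "Methods: composition-adjusted paired EWAS for saliva methylomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composition-adjusted paired EWAS for saliva methylomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salivamix)
```

## The measurement model

A β value is the fraction of methylated cytosines at a CpG across the
DNA molecules of a sample. Saliva DNA comes from two main sources —
buccal epithelium and leukocytes — whose methylomes differ at a large
fraction of CpGs. For a two-cell-type fluid the bulk measurement is a
convex combination of the two cell-type profiles,

$$\beta_{ij} = p_i\,\beta_j^{(a)} + (1-p_i)\,\beta_j^{(b)} + \varepsilon_{ij},$$

with $p_i$ the per-sample proportion of type $a$ (buccal) and
$\varepsilon$ technical noise. Two consequences drive everything in
this package:

* at any CpG, the measured β is **linear in $p$** with slope
  $\beta_j^{(a)} - \beta_j^{(b)}$;
* at a CpG that is near-binary between the cell types (a **marker**),
  the measured β *is* an estimate of $p$ up to an affine map.

In a paired design (monozygotic twins discordant for a perinatal
phenotype), within-pair differences in $p$ masquerade as within-pair
methylation differences at every composition-dependent CpG. The
adjustment strategy removes exactly this component, CpG by CpG.

## Marker-based adjustment

1. **Screening** (`screen_discriminative`): CpGs are ranked by the
   absolute reference-panel difference $|\beta^{(a)} - \beta^{(b)}|$
   and the top k (default 10) become marker candidates. Ties are broken
   by panel order with a warning.
2. **Selection** (`select_marker`): each candidate is used as the
   regressor of a per-CpG ordinary least-squares model; the candidate
   whose model passes the affected rule at the largest number of CpGs —
   i.e. whose measurements behave most linearly across the cohort — is
   selected. This favours markers whose own technical noise is small,
   because noise in the regressor attenuates every fit.
3. **Outlier exclusion** (`detect_outlier_samples`): samples whose
   marker β is more extreme than median ± 3 MAD indicate compositions
   outside the range where a single linear fit is trustworthy; the
   whole pair is excluded from fitting (the paired test cannot use a
   half pair anyway). The rule can be disabled (`n_mad = Inf`).
4. **Fitting** (`fit_marker_models`): every non-marker CpG is regressed
   on the marker β (or several markers jointly, e.g. leukocyte-subtype
   markers) across non-excluded samples. A CpG is **affected** when its
   overall regression P falls below `affected_p` (default 0.01,
   unadjusted for multiplicity). The threshold is a declared package
   default: it matches the significance convention used everywhere else
   in the analysis, and selective adjustment is deliberately
   conservative — a CpG with no demonstrable composition dependence is
   left untouched rather than perturbed by a noisy slope estimate.
5. **Adjustment** (`adjust_for_composition`): for affected CpGs,
   $\beta^{adj} = \beta - \sum_k \hat s_k\,(m_k - \bar m_k)$, where
   $m_k$ is marker $k$'s β and the anchor $\bar m_k$ defaults to its
   mean over non-excluded samples. Anchoring at the cohort mean keeps
   adjusted values on the observed β scale (re-expressing every sample
   at the cohort's average composition); the anchor is configurable
   since any fixed reference composition is equally valid for a paired
   test. Results are truncated to [0, 1] and truncations counted.
   Unaffected CpGs and the markers themselves are copied bit-identically.

By the least-squares residual property, adjusted CpGs are exactly
orthogonal to the marker before truncation; the tests assert
$|r| < 0.05$ after truncation in noisy simulations, and exact
preservation of unaffected CpGs.

## Paired testing and MVP calling

Per CpG, the two-sided **exact Wilcoxon signed-rank** P-value is
computed from the full null distribution of the signed-rank statistic.
The implementation builds the distribution by a generating-function
convolution over doubled midranks, which is arithmetically identical to
enumerating all $2^n$ sign assignments — and therefore remains exact
under ties, where the null distribution becomes data-dependent. Choices
and conventions:

* zero differences are dropped before ranking (classical treatment;
  Pratt's zero-rank method is available via `zero_method = "pratt"`);
* the two-sided P is `min(1, 2 * min(P(W ≤ w), P(W ≥ w)))` — the
  doubling convention, whose floor at n untied nonzero pairs is
  $2 \cdot 2^{-n}$ (3.05 × 10⁻⁵ at n = 16);
* above 25 nonzero pairs (mode `"auto"`) a normal approximation with
  the exact tie-adapted variance $\sum r_i^2/4$ and a continuity
  correction is used;
* no multiple-testing correction is applied by default: MVP calling
  deliberately uses an uncorrected P < 0.01 so that a *negative*
  genome-wide result is not attributable to over-correction, and the
  effect-size filter |mean Δβ| > 0.05 (the practical validatability
  limit of array measurements) carries the specificity burden.

`call_mvps` intersects one or more analysis variants (e.g. single- and
multi-marker adjustment): an MVP must pass both thresholds in every
variant, and counts are reported at each filter stage.

Supporting statistics: `fisher_exact_rxc` enumerates all r×c tables
with the observed margins depth-first and sums the probabilities of
tables no more probable than the observed one (Freeman–Halton), with a
relative tolerance of 1e-9 guarding floating-point ties;
`power_paired_t` evaluates the noncentral-t power function, the
parametric stand-in for the signed-rank test's intractable power (at n
= 16 pairs, Δβ = 0.05, sd 0.025, α = 0.01 it gives > 0.99, verified by
Monte-Carlo in the tests); `paired_t_test` wraps `stats::t.test`.

## Validation statistics

**Deep bisulfite sequencing (DBS).** Reads carry binary calls per CpG.
`filter_reads` drops reads below a conversion-rate estimate of 0.95 or
above 20% missing calls — declared defaults in the spirit of standard
amplicon QC, since published filters rarely state exact thresholds.
`amplicon_methylation` computes per-CpG fractions over non-missing
calls. `cross_platform_concordance` computes per-sample (or per-CpG)
Pearson correlations between array and read-derived values;
`snp_allele_balance`/`paired_allele_noise` use heterozygous amplicon
SNPs — where the true within-pair allele-fraction difference is
exactly zero — to estimate the technical noise floor against which
candidate methylation differences must be judged.

**SIRPH.** Primer-extension peak areas give the methylation index
MI = AC/(AC+AT), the assay's analogue of β. `sirph_association`
reuses the *same* fitting/adjustment code path as arrays (asserted by
an identical-output test), then applies the exact paired Wilcoxon per
element CpG.

## The synthetic-data generator

The generator is the package's test bed and defines its study
conditions:

* **Reference panel**: two cell types; a chosen number of
  discriminative CpGs with |Δref| ≥ `separation` (drawn uniformly up to
  0.93); all background CpGs differ by at most 0.05 — below the MVP
  effect threshold, so composition alone cannot turn a background CpG
  into an MVP. Baseline means are uniform on [0.05, 0.95].
* **Cohort**: per-sample proportions uniform on [0.1, 0.9] by default —
  the wide composition range observed in real saliva. A
  `pair_correlation` parameter makes co-twins' compositions similar (no
  published estimate of that correlation exists, so it is a tunable,
  defaulting to 0.3 in the pipeline), and `heavy_shift` adds a
  systematic composition offset to the heavier co-twin, reproducing
  group-associated confounding. Noise is additive Gaussian on the β
  scale, truncated to [0, 1]; this matches the linearity assumption of
  the adjustment model. Simulated detection P-values are
  background-level with a small failure rate, and chromosomes are
  assigned so the Y-filter has work to do.
* **Reads**: per-CpG Bernoulli calls at the true β; unconverted
  unmethylated cytosines appear methylated with probability
  1 − conversion_rate; a per-read conversion estimate is simulated from
  25 non-CpG cytosines.
* **Peak areas**: AC = β·A + noise, AT = (1−β)·A + noise, truncated at
  0.

Identical seed and arguments give bit-identical output (the generators
save and restore the caller's RNG state).

What the generator does **not** emulate: probe-chemistry differences
between assay generations, cross-hybridization, batch effects,
logit-scale heteroscedasticity of array noise, PCR amplification bias
in reads (read noise is purely binomial, so simulated allele-balance
noise is a lower bound on real assay noise), and more than two cell
types mixing simultaneously. Passing tests therefore demonstrate the
*algorithms* are correct under the stated model, not that real saliva
data meet the model.

## Simulation scenarios and sizes

Tests and the acceptance script use sizes chosen to make sampling error
small relative to the tested margins while keeping the suite quick:
mixture-series recovery pools 110 estimates (RMSE margin 0.03 vs an
expected ≈ 0.022 at noise 0.02); the confounded-null contrast uses
2,000 CpGs (800 composition-dependent), 16 pairs and 100 replicates;
effect recovery injects Δβ = 0.10 at 60 mid-range, composition-
independent CpGs of a 16-pair cohort; Monte-Carlo power checks use
20,000–50,000 replicates. The default pipeline configuration (2,000
CpGs, 25 discriminative, 17 pairs, noise sd 0.02) is a scaled-down but
structurally faithful analogue of a genome-wide cohort; because its
background CpGs are deliberately composition-poor, the fraction of
CpGs adjusted (~15%) is smaller than in real saliva data, where
cell-type differences are pervasive.

## Numerical choices and degenerate inputs

* β invariant violations on load are errors naming the offending
  CpG/sample — never clamped.
* Zero-variance samples/CpGs: correlations are reported `NA` with a
  warning and counted separately; a zero-variance marker is an error.
* Rank-deficient multi-marker designs drop later markers with a
  warning (stable, order-dependent, documented).
* All tie-breaks (screening, marker selection) use stable input order
  with warnings.
* Truncation to [0, 1] after adjustment is counted and reported.
* Exact signed-rank counts are exact in double precision up to n = 50;
  the exact path is capped at n = 25 by default where the normal
  approximation is already excellent.
* Freeman–Halton enumeration is guarded by a table cap (default 5e6)
  rather than silently switching to an approximation.

## Known limitations

* The adjustment is the marker-regression scheme only; it is not a
  full constrained deconvolution over many cell types, and a marker
  that is itself phenotype-associated would remove true signal.
* Selective adjustment keys on a per-CpG regression P, so with many
  CpGs some composition-dependent CpGs will escape adjustment (false
  negatives of the affected rule) and a small fraction of independent
  CpGs will be adjusted with near-zero slopes (harmless in practice).
* The exact test's discreteness makes it conservative at small n; the
  attainable level, not the nominal one, is what simulations reproduce.
* `run_study` is a demonstration harness over the synthetic generator;
  real data enter through the TSV readers and the same stage functions.
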