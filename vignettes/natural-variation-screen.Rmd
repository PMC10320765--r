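---
title: "A natural-variation screen for condition-dependent TF activity: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A natural-variation screen for condition-dependent TF activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senescreen)
```

## The model behind the screen

In an interspecies F1 hybrid, the two parental alleles of a gene are
transcribed in the same nucleus. *Trans*-acting factors (TF concentrations,
signaling state) act equally on both alleles, so a difference in
allele-specific expression (ASE) isolates *cis*-acting sequence variation.
A *condition-dependent* ASE difference — here, an allele-by-senescence
interaction — further isolates *cis* variants whose effect is switched by the
condition. If such variants concentrate in the binding sites of one TF across
the genome, that TF's activity is itself condition-dependent: the variants
act as genetically encoded reporters of the factor's regulatory engagement
during senescence.

The per-gene statistic is the interaction term of an ordinary two-factor
fixed-effects ANOVA,

$$y_{acr} = \mu + \alpha_a + \gamma_c + (\alpha\gamma)_{ac} + \varepsilon_{acr},$$

fit to the TPM of allele $a$, condition $c$, replicate $r$. Genes in the top
quartile of the interaction $F$ are called ΔASE⁺. Per TF, target genes
(those with a binding site overlapping the 5-kb strand-aware window upstream
of the TSS) are cross-classified by binding-site variant presence and ΔASE,
and the 2×2 table is Fisher-tested, with Benjamini–Hochberg correction across
the TFs that survive the 250-targets-per-cell eligibility filter.

The companion gene-set statistic is directional: for a per-gene log₂
ratio profile $r_g$ (senescent/control, species A/B, knockdown/control, ...)
and a term $T$, $s = \sum_{g \in T} r_g$. Coordinated shifts of either sign
make $|s|$ large; $|s|$ is compared against size-matched gene sets resampled
without replacement from all profiled genes.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `window` | 5000 | bp | upstream target-assignment window |
| `quantile` (ΔASE) | 0.75 | — | top-quartile interaction-F call |
| `min_per_cell` | 250 | genes | per-TF eligibility filter |
| `n_resamples` | 10000 | draws | resampling null for gene sets |
| `pseudocount` | 0.5 | TPM | log-ratio stabilizer |
| `ase_scale` | `"tpm"` | — | ANOVA analysis scale |

The first four are the screen's published operating points and are kept as
package defaults. The pseudocount is our own choice: the source procedure is
silent on zeros, and 0.5 TPM is the smallest conventional stabilizer;
`pseudocount = 0` is allowed when the caller guarantees positive means.

Two readings in the published procedure were genuinely open:

* **"counts in more than half the samples"** is read as a *strict*
  inequality on the number of nonzero-count samples (3 of 6 is dropped).
* **Analysis scale.** The ANOVA input is raw TPM, because TPM is what the
  published pipeline states it used; a `log2(TPM + 0.5)` option is provided
  (`ase_scan(..., scale = "log2")`) and exercised in the tests. On the raw
  scale the NB mean–variance relation makes the test mildly anti-conservative
  for very low-expressed genes; at the simulated depths the null interaction
  p-values are uniform to KS distance < 0.05 (verified per run by
  `scripts/acceptance.R`).
* **"Multivariate ANOVA" across the irradiation timecourse** is implemented
  as a per-gene one-way fixed-effects ANOVA on log₂(TPM+1) across timepoint
  labels (`timecourse_anova`). A true MANOVA across genes would need an
  explicit gene-set structure the procedure does not define; the per-gene
  reading is the one the rest of the pipeline can consume.
* **ΔASE is ranked by F, not p.** In the balanced design both orders
  coincide; F is what the published rule names.
* **Gene-level variant aggregation** is "any in-window site carries a
  variant" (most inclusive reading); `n_variants` sums across sites for the
  density profiles. Window membership is ≥ 1 bp overlap by default, with a
  full-containment option (`assign_targets(..., containment = TRUE)`).
* **Resampling p-value direction.** The published wording counts resamples
  in which the *true* score exceeds the random one, which would assign large
  p to strong enrichment. The package uses the conventional exceedance count
  with the add-one (permutation-standard) estimator
  $p = (1 + \#\{|s_{rand}| \ge |s_{true}|\})/(N+1)$, which never returns 0;
  the printed convention remains available as
  `p_method = "proportion_printed"`.
* **Boundary convention for variants in sites.** A 1-based SNV at `pos`
  lies in the 0-based half-open site `[start, end)` iff
  `start <= pos - 1 < end`; offsets use the variant midpoint `pos - 1 + 0.5`
  so distances are symmetric for even and odd site lengths.

## What the synthetic generator emulates

The generator reproduces the study's *design*: a balanced 2-allele ×
2-condition × R-replicate allele-resolved count matrix over an annotated
genome, binding sites for a TF panel in 5-kb upstream windows, an
interspecies SNV catalog concentrated near site centers, and gene sets. Its
defaults are the package's study conditions: 4000 genes on 19 chromosomes,
20 TFs with a site upstream of 90% of genes, one causal TF whose sites carry
variants at rate 0.6 (0.2 elsewhere), and a planted allele-by-condition
interaction of 1.5 log₂ units given to each variant-bearing causal-TF target
with probability 0.1.

Noise model: per-gene baselines are log-normal (meanlog 5, sdlog 1, in count
units); allele and condition main effects are small Normal(0, 0.1 log₂)
nuisances; counts are negative-binomial with a single global dispersion of
0.05, the magnitude typical of bulk RNA-seq biological replicates — the
source profiles report no within-genotype variance estimate, so this is a
free parameter of the artifact, not an estimate. Expected counts are
rescaled per sample to a 2×10⁶ library before the NB draw, so TPM
normalization has real work to do.

Two generator-level design decisions matter for interpretation:

* **Disjoint site slots.** Within one gene's window, sites of different TFs
  occupy non-overlapping slots. Overlapping placement would let one TF's
  variants sit inside another TF's sites, inflating realized background
  variant rates (~0.33 for a nominal 0.2) and making per-TF rates
  uncontrollable; disjoint placement keeps the realized rates exactly at the
  nominal parameters and makes the causal TF's 2×2 table exactly
  reconstructible from the recorded ground truth. Real ChIP-derived site
  catalogs do overlap across factors, so on real data the screen's per-TF
  signals are correlated in a way these simulations deliberately exclude.
* **Planting rate 0.1.** The ΔASE budget is fixed at 25% of tested genes, so
  planting δ on a fraction $f$ of the causal TF's variant-bearing targets
  drains the variant-free/ΔASE⁺ cell roughly as
  $(k - f\,m)\cdot\frac{|{\rm var}^-|}{n - f\,m}$ with $k$ the budget and $m$
  the variant-bearing target count; above $f \approx 0.15$ that cell falls
  under the 250-gene eligibility filter and the causal TF would eliminate
  *itself* from its own screen. 0.1 keeps all four cells near or above 270
  in expectation while leaving a strong planted signal (median odds ratio
  ≈ 1.5, Fisher p ≲ 10⁻⁷).

A corollary of the published operating point: with 4000 genes and a 0.2
background variant rate, a background TF's variant⁺/ΔASE⁺ cell is ~180 < 250,
so under the recovery conditions the eligible family usually contains the
causal TF alone and BH is close to an identity there. The null-calibration
studies therefore use a 0.5/0.5 variant rate, at which all 20 TFs are
eligible and the false-discovery proportion of the whole family is
measurable.

What passing tests do **not** show about real data: no mapping bias or
allele-assignment error, no correlated site catalogs (above), no
overdispersion heterogeneity across genes, no library composition effects
beyond the global rescaling, and TSS-distal regulation is out of frame
entirely. The screen's behavior under those realities must be judged on real
inputs, which drop into the same BED/VCF/TSV readers.

## Numerical choices and degenerate inputs

* The interaction F is computed from the closed-form balanced sums-of-squares
  decomposition, vectorized across genes; the test suite verifies equality
  with `stats::aov` fits to 10⁻⁹ on random instances. Zero residual variance
  flags a gene `degenerate` (F undefined); degenerate genes leave the
  quartile denominator.
* ΔASE ties at the quartile threshold break by ascending gene id, so calls
  are deterministic and rerun-stable.
* Fisher's two-sided p sums hypergeometric point probabilities ≤ that of the
  observed table (via `stats::fisher.test`); the reported odds ratio is the
  sample estimate ad/bc with the usual 0/∞ conventions, matching the 2×2
  counts a reader would recompute.
* Kernel densities evaluate on a grid extending 4 bandwidths beyond the data
  so the trapezoid integral is 1 within 10⁻³ even for single-valued strata.
* Every stochastic stage draws from its own stream seeded by
  `op_seed(master_seed, op_name)`, so stages are decoupled: changing the TF
  panel cannot perturb the count noise, and identical (inputs, config, seed)
  reruns are byte-identical on disk.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run the full screen at the default
study scale (4000 genes × 20 TFs × 12 samples): 20 recovery seeds, 10 null
seeds, and 5 × 2000-gene uniformity checks, plus enumeration-scale oracles —
about three minutes end to end on one CPU. Module tests use 200–1500-gene
studies chosen to keep each property sharp but cheap.

## Known limitations

* The screen is correlational: an enriched TF marks condition-dependent
  *cis* variation at its sites, not a validated mechanism.
* The 2×2 collapses variant dosage; `n_variants` and the position profiles
  (`variant_position_profile`) are descriptive companions, not tests.
* Eligibility (250 per cell) interacts with study size: underpowered TF
  panels silently shrink the tested family — the manifest records the
  eligible count per run for exactly this reason.
* The resampling null holds term composition fixed and permutes nothing
  about inter-gene correlation; correlated members (e.g. co-regulated
  paralogs) make the null anti-conservative, as for all gene-sampling
  enrichment tests of this family.
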