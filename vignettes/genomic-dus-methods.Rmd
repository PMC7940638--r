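---
title: "Methods: genomic evaluation of DUS variety registration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genomic evaluation of DUS variety registration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genomicDUS)
```

## The problem

Plant Variety Rights are granted to varieties that pass DUS testing:
a candidate must be **D**istinct from all common-knowledge varieties,
**U**niform across the seeds that constitute it, and **S**table across
generations. In practice DUS rests on a fixed catalogue of morphological
traits — in UK barley, 28 ordinal scores covering growth habit, leaf, ear
and grain characters. That design has three quantitative weaknesses this
package makes measurable:

1. many DUS traits have low narrow-sense heritability, so their scores vary
   between trial environments and scoring organizations;
2. the combinatorial space of trait profiles shrinks as breeding narrows
   the gene pool, so new varieties become harder to tell apart; and
3. small diagnostic marker sets lose their discriminating power in closely
   related germplasm.

The package implements the alternative: *genomic DUS*, where distinctness,
uniformity and stability are decided from genome-wide marker distances
rather than morphology, together with all the quantitative-genetic
machinery needed to evaluate both systems side by side on a common panel.

## The synthetic panel

Real national-list genotype collections are typically permission-restricted,
so the package ships a generator whose defaults emulate the structure of the
UK barley panel: 432 spring, 372 winter and 5 "alternative" inbred
varieties, ~40k biallelic SNPs on 7 chromosomes of 150 cM each
(`panel_config()`).

* **Population structure.** Ancestral allele frequencies are uniform on
  (0.1, 0.9); each seasonal type draws its own frequencies from a
  Balding–Nichols (F-model) distribution around the ancestral value with
  divergence `between_type_divergence` (default 0.35). The default was
  chosen so the within-type and between-type distance distributions
  separate the way the real panel's do (within-type normalized Manhattan
  distances roughly 0.05–0.65, between-type 0.45–0.95); setting the
  divergence to 0 collapses the types into one population.
* **Relatedness and LD.** Only `founder_count` lines per type (default 40)
  are drawn independently; all later varieties are F6 inbreds bred by
  crossing two earlier varieties of the same type through the package's own
  meiosis engine, over `pedigree_depth` generations. This produces long
  shared haplotypes, duplicated marker columns, and a realistic pedigree —
  the features that make mixed-model GWAS and minimum-distance screening
  non-trivial.
* **What it does not emulate.** Real barley LD decay, selection, or actual
  allele frequencies. Passing tests therefore demonstrate correctness of
  the statistical machinery under a realistic *class* of structure, not
  numerical agreement with any particular real panel.

### Traits

Each of the 28 default trait specifications (`default_trait_specs()`)
carries a target heritability matching the published combined-panel
estimates for the corresponding barley DUS trait (from 0.01 for grain husk
up to 1.00 for ear row number), an ordinal scale (1–9, or binary {1, 9} for
traits 3, 23 and 26), season-restricted segregation (traits 3 and 12 only
in winter, 27 only in spring), a missingness rate (five traits above 10%,
maximum 78%), and a target genetic correlation with yield (non-zero for 12
traits, negative for ear attitude and plant length).

A trait's latent liability is

$$\ell = \sqrt{h^2}\, g + \sqrt{1 - h^2}\, \varepsilon,$$

with \(g\) a standardized genetic value built from `n_qtl` causal markers
and \(\varepsilon\) standard normal, so the liability's heritability equals
the target by construction. The liability is discretized onto the trait's
scale through equal-probability normal quantile thresholds, which preserves
the heritability *on the liability scale*. Discretization attenuates the
heritability of the observed score: negligibly for 9-level traits
(REML on scores recovers ~0.73 for a 0.78-target trait), strongly for
binary traits (the biserial factor \(2/\pi\)). Parameter-recovery checks
therefore run on the latent liabilities, where the simulation truth is
defined; analyses of real ordinal scores inherit the same attenuation the
original analysis had.

Yield breeding values are a weighted sum of the standardized trait genetic
values (weights = the target genetic correlations) plus an independent
polygenic remainder, so each trait attains approximately its target
\(\rho_g\) with yield; the construction is exact only when trait genetic
values are mutually independent, which holds approximately for traits with
disjoint QTL.

## Mixed models

### Relationship matrix

`compute_grm()` is VanRaden method 1: dosages centered by twice the allele
frequency, cross-product scaled by \(2\sum_m p_m(1-p_m)\) over polymorphic
markers. For a fully inbred panel the raw diagonal averages ~2 (inbred
lines carry twice the Hardy–Weinberg dosage variance), which would make
\(h^2 = \sigma_g^2/(\sigma_g^2+\sigma_e^2)\) systematically
uninterpretable as the genetic fraction of line variance. The default
`normalize = TRUE` rescales to mean diagonal 1 — the usual convention for
inbred line panels — and `normalize = FALSE` returns the raw VanRaden
matrix.

### Univariate REML

`reml_univariate()` fits \(y = X\beta + g + e\), \(g \sim N(0,
\sigma_g^2 A)\), \(e \sim N(0, \sigma_e^2 I)\). With a single random
effect the restricted likelihood profiles exactly over the variance ratio
\(\lambda = \sigma_g^2/\sigma_e^2\) in the eigenbasis of \(A\): a coarse
grid over \(\log\lambda \in [-15, 15]\) brackets the optimum and golden
section refines it, making the fit deterministic and exact up to 1-D
optimizer tolerance (unit tests compare the maximized likelihood against a
dense-matrix brute-force evaluation). Ordinal DUS scores are analysed as
numeric responses, exactly as the source analysis did — no threshold model.
Default fixed effects are intercept, listing year (continuous) and seasonal
type (dropped automatically in single-type subsets). Standard errors of
\(h^2\) come from the observed information of \((\sigma_g^2, \sigma_e^2)\)
by the delta method. A fit at the \(\lambda\) grid edge is reported as
`"boundary"`; zero residual variance as `"degenerate"` — never silently.

### Bivariate REML

`reml_bivariate()` fits the two-trait model with unstructured \(2\times2\)
genetic and residual covariances (Kronecker products with \(A\) and
\(I\)). In the eigenbasis of \(A\) the restricted likelihood factorizes
over per-eigenvalue \(2\times2\) blocks, so each evaluation is \(O(n)\).
Variances are log-transformed and correlations atanh-transformed, so all
constraints hold automatically; the optimizer (BFGS) is warm-started from
the two univariate fits plus a moment estimate of the residual
correlation. (An EM warm start was considered and dropped: the quasi-Newton
iteration converges reliably from the univariate start on this model
family, and EM steps added no robustness in testing.) The phenotypic
correlation is always computed exactly from the fitted components,

$$\rho_y = \frac{\rho_g \sigma_{g1}\sigma_{g2} + \rho_e \sigma_{e1}\sigma_{e2}}
{\sqrt{(\sigma_{g1}^2+\sigma_{e1}^2)(\sigma_{g2}^2+\sigma_{e2}^2)}},$$

and correlations within \(10^{-3}\) of \(\pm1\) are flagged as boundary
fits. `fix_rho = 0` constrains both correlations to zero, which must (and
in tests does) reproduce the two univariate fits.

### Yield BLUEs

`yield_blues()` delegates to `lme4::lmer` with variety fixed and
management, management:year, management:year:variety and
management:year:location random, then extracts estimated marginal variety
means with `emmeans` — the same model family used to summarize
multi-environment VCU trials. The management covariate is a 0/1 property of
the variety (listed before/after the trial-regime switch year). Degenerate
noise-free fits fall back to a fixed-effects model, which gives identical
BLUEs in the balanced case.

## GWAS

`run_gwas()` adds one marker at a time to the univariate mixed model and
Wald-tests its effect. Variance components are estimated once on the null
model and reused (the P3D approximation); the scan then reduces to
weighted least squares in the whitened eigenbasis, vectorized across
markers. `exact = TRUE` re-estimates REML per marker for small fixtures;
with an identity kinship and no polygenic signal the scan reproduces the
OLS F-test to numerical precision. Markers monomorphic in the analysis set,
or perfectly confounded with the fixed effects, are reported as `NA` rather
than given a meaningless p-value.

FDR control is Storey's q-value with the smoother \(\pi_0\) estimate
(`fdr_qvalues()`), falling back to \(\pi_0 = 1\) — exactly
Benjamini–Hochberg — when the smoother fails; the fallback is logged.
q-values are computed within each trait-by-population scan, not pooled.

Because inbred panels carry long-range LD, a major locus can lift markers
on other chromosomes above threshold. `conditional_rescan()` repeats a scan
once with the top marker (when it exceeds \(-\log_{10} p = 10\), the
configurable default) added to the fixed effects and excluded from testing;
shadow peaks collapse while real secondary loci survive. Both scans are
retained.

A note on calibration testing: the KS uniformity check of null-trait
p-values presumes independent tests. On a pedigree panel, duplicated marker
columns produce tied, perfectly dependent p-values that fail KS regardless
of the validity of each test, so the null-calibration checks run on a
panel of unrelated founder lines, while localization and re-scan checks
use the full pedigree panel with LD.

## Meiosis and crossing schemes

The gamete simulator treats crossovers as a Poisson process on the cM scale
with no interference. At marker resolution this is equivalent to a Markov
chain along the chromosome that switches parental haplotype between
adjacent markers \(d\) cM apart with the Haldane probability
\((1 - e^{-2d/100})/2\), and starts each chromosome from a random
haplotype. The Markov form vectorizes across whole cohorts, so 10,000
progeny are simulated in seconds. Haldane is the default because every
downstream expectation is then analytically checkable; a per-interval
Kosambi approximation sits behind `map_function = "kosambi"`.

`simulate_cross()` builds the F1 of two inbred parents and applies the
scheme: F6 = five selfing generations by single-seed descent, BC1S4 = one
backcross (recurrent parent configurable, first-listed by default — the
choice the original description leaves open) then four selfings. Closed
forms validated in tests: residual F6 heterozygosity \(2^{-5} = 3.125\%\),
BC1S4 donor-allele frequency \(1/4\), heterozygosity halving per selfing
generation, and per-locus F6 fixation probability \((1 - 2^{-5})/2 =
0.484375\) from the selfing-chain enumeration (an exact-dosage match to a
parent at \(k\) unlinked segregating loci therefore occurs with probability
\(0.484375^k\); residual heterozygotes match neither parent).

`match_report()` counts exact marker-subset matches of progeny against
parents, the registered sibling, and each other, with a 1000-resample
bootstrap for the mean and percentile CI, plus an occurrence table of
distinct subset haplotypes. With small diagnostic panels (4–22 segregating
markers) simulated progeny frequently collide with their parents and each
other; with ≥500 genome-wide markers collisions essentially vanish — the
core argument against small DUS marker sets.

## Genomic DUS decisions

All decisions use the per-marker-normalized Manhattan distance: the mean
absolute dosage difference, which for inbred {0,2} coding equals
\(2(1-\text{similarity})\) and lives in [0, 2]. Normalizing per marker
(rather than using raw sums) makes the 0.05 threshold transferable across
panel sizes; raw sums are available via `normalize = FALSE`.

* **Distinctness / EDV** (`distinctness_screen()`): a candidate is distinct
  iff its minimum distance to the reference panel is at least the threshold
  (default 0.05); otherwise it is flagged as a potential essentially
  derived variety. Nearest-neighbour ties break by reference order and are
  logged. The distance report prints both the panel size and the pair
  count, so either convention for counting comparisons is checkable.
* **Uniformity** (`uniformity_metric()`): maximum and mean pairwise
  distance among the seeds of a lot, passed against a ceiling — by default
  the candidate's minimum distance to the reference panel, i.e. seeds of a
  variety must be closer to one another than the variety is to anything
  else.
* **Stability** (`stability_metric()`): per-marker allele-frequency change
  between the application-time and commercial seed lots, standardized by
  binomial sampling variance of both lots plus Wright–Fisher drift over the
  stated effective size and generations. The original proposal names the
  drift-accounting requirement without a model; the binomial/Wright–Fisher
  null with a user-supplied effective size is this package's concrete
  choice, and the z-like statistic is calibrated against a simulated drift
  null in tests.
* **Marker requirement** (`marker_subsample_curve()`): correlation between
  trait-profile distances and marker distances across random marker subsets
  on a \(10^{0.1}\) grid (one subset per size by default, with a
  `replicates` flag for smoother curves; the full marker count is always
  included in the grid). High-heritability traits (\(h^2 > 0.5\))
  correlate substantially more strongly with marker distances than
  low-heritability traits, and the curve's increments shrink beyond a few
  hundred markers.

Trait distances average over the traits observed in both varieties of a
pair (the normalized convention), because varieties differ in missingness;
raw sums are available behind the same flag. Binary 1/9 traits are recoded
to 1/2 first (`recode_binary_traits()`) so one scale step means one class
everywhere.

## Concordance between scoring organizations

`per_variety_discrepancy()` compares two organizations' score tables on
cells present in both, reporting per-variety mean absolute difference and
consistency (fraction of exact matches), with the overall mean and SD taken
over per-variety means (so n counts varieties). The attached test is a
two-sided one-sample t-test of the per-variety mean absolute differences
against zero — the natural null of "no systematic discrepancy", made
explicit here because the original summary does not state its null.
`per_trait_bias()` is the signed per-trait mean difference
(first argument minus second). `rolling_trait_distance()` slides a
20-variety window along submission order and returns the mean pairwise
trait distance per window — the trait-combinatorial-space series.

## Problem sizes and numerical choices

Simulation-based checks in the test suite and acceptance script use panels
of 200–500 varieties with 1000–3000 markers, 20 replicates for parameter
recovery, 10,000 gametes/progeny for meiosis expectations and 1000 progeny
per crossing-scheme comparison; these sizes give Monte-Carlo error
comfortably inside each assertion's tolerance while a full run stays
around a minute. Other numerical choices: GRM eigenvalues floored at
\(10^{-9}\) (with a message when the matrix was not numerically PSD);
\(\log\lambda\) searched on \([-15, 15]\); p-values of exactly zero floored
at the smallest positive double before q-value computation; missing trait
scores use `NA` as the single sentinel everywhere.

## Known limitations

* Ordinal scores are analysed as numeric, faithfully to the source
  analysis; a threshold model would estimate liability-scale parameters
  directly but is out of scope.
* The yield-correlation construction is approximate when traits share QTL.
* The generator injects missingness completely at random; no informative
  missingness mechanism is modeled (none is described for the real data).
* The drift null in `stability_metric()` treats markers independently;
  linked drift would need a genome-wide simulation null.
* The published concordance and curation counts for the real NIAB/SASA
  tables can only be recomputed when those permission-restricted tables are
  supplied under `inst/extdata/`; the corresponding acceptance checks fail
  until then by design.
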