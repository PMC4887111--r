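---
title: "cypdose: from CYP1B1 allele activities to glaucoma genotype-phenotype verdicts"
author: "cypdose authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cypdose methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cypdose)
```

## The problem

CYP1B1 is a cytochrome P450 monooxygenase with two activities relevant to
glaucoma: it produces retinoic acid from retinol — critical for ocular
development — and it metabolizes 17beta-estradiol. Biallelic CYP1B1 defects
cause primary congenital glaucoma (PCG, autosomal recessive); heterozygous
variants are recurrently found in primary and juvenile open-angle glaucoma
(POAG/JOAG), where estradiol handling is the proposed mechanism. `cypdose`
implements the quantitative chain that links a panel of in vitro allele
activities to phenotype-level statements:

1. **Assay normalization** — dual-luciferase (retinol/RARE reporter) and
   luminogenic-substrate (estradiol) plate arithmetic with replicate
   statistics.
2. **Turnover analysis** — cycloheximide-chase densitometry, percent-of-wild-type
   levels per time point, and a stability call.
3. **Allelic dosage** — per-genotype activity inference from per-allele
   measurements.
4. **Concordance classification** — a rule-based verdict per reported
   genotype (`YES`/`NO`/`INCONCLUSIVE`/`PREDICTED`).
5. **Flexibility screen** — anisotropic elastic-network normal modes,
   mode 7–9 RMSF, and log2 mutant/wild-type ratio profiles with segment
   summaries and ensemble PCA.

A curated 23-variant catalog (percent-of-wild-type activities with SEMs,
reported genotypes and phenotypes, published inferred activities, verdicts
and stability labels) ships as a plain-text fixture, so the whole chain is
reproducible offline.

## Assay normalization

Both assays express a variant's activity as a percentage of the wild-type
signal on the same plate.

**Estradiol** (`normalizeEstradiol`): three steps per replicate —
subtract the mean no-cell background, subtract the mean background-corrected
empty-vector signal (endogenous activity), then divide by the mean wild-type
net signal. **Retinol** (`normalizeRetinol`): subtract the mean firefly
signal of the non-inducible negative control, subtract the mean corrected
empty-vector firefly signal, then divide each well's firefly value by its own
Renilla reading before referencing to wild type; the per-well ratio cancels
transfection efficiency exactly.

Two choices deserve comment:

* **Clamping.** Negative per-replicate net signals are clamped to zero
  before averaging. Published activity tables report hard zeros
  ("0.00 ± 0.00") for fully inactive variants, which is only possible if
  negative noise excursions are not propagated; clamping reproduces that
  behaviour and guarantees non-negative estimates.
* **Empty-vector correction order.** The empty-vector signal is itself
  background-corrected before subtraction, and subtraction happens before
  the Renilla division. The alternative (correcting after division) differs
  only when the empty-vector reporter signal is substantial; with a host
  line essentially free of endogenous CYP1B1 it is negligible, and the
  subtract-then-divide order follows the kit's stated calculation.

Replicate statistics use the pooled-variance Student's t-test
(`twoSampleT`), matching the reported analysis; Welch's correction is
available by flag. Zero-variance degeneracies are resolved explicitly
(identical constant groups give t = 0, p = 1; distinct constant groups are
flagged degenerate with p = 0). The default significance threshold is 0.01,
the level used for the published turnover comparisons; the assay papers
quote 0.05/0.005 for subsets, so the threshold is an argument, not a
constant.

## Turnover analysis

`normalizeDensitometry` forms the CYP1B1/beta-actin ratio per lane, averages
replicate transfections per time point, and expresses each sample as percent
of wild type at the matching time point. `classifyStability` calls a sample
`UNSTABLE` when at least one post-zero time point lies below 100% with
two-sided p < 0.01. The published analysis never states its exact decision
rule ("deviation in decay"); for that reason the fixture also carries the
published stable/unstable labels, so the published count of 11 unstable
mutants is testable independently of this package's rule. On noise-free
exponential decay the percent-of-wild-type level at time t equals
100·exp(−(k_mut − k_wt)·t) to machine precision, which the tests assert at
1e-9.

## Allelic dosage

`inferGenotypeActivity` implements the two-allele average: homozygotes carry
their allele's activity; heterozygotes average the allele with a 100%
wild-type dose; compound heterozygotes average the two mutant alleles, with
frameshift/deletion partners contributing 0% (their activity is inferred
null) and unassayed missense partners making the genotype indeterminate.
Retinol and estradiol activities are computed independently and rounded to
integer percent, halves away from zero.

The published genotype-level integers are reproduced for 77 of 84
determinate cells. The seven exceptions (flagged, never silently matched)
are single-integer rounding discrepancies whose provenance cannot be traced
to any consistent rule — some cells round .12/.29/.35 fractions up, one
truncates a .71 fraction. They are surfaced by `runPipeline` and pinned in
the tests.

## Concordance classification

The decision model is qualitative in its source: for PCG, both very low and
excessive retinoic acid production interfere with eye development, and the
disease is recessive, so a heterozygote is discordant unless its inferred
retinol activity reaches the excess range even with a wild-type allele. For
POAG/JOAG, estradiol metabolism outside a normal band is consistent with
disease (low: estradiol accumulation and myocilin upregulation; high: ROS
generation). JOAG is handled by the POAG rule plus an informational
digenic-MYOC code, since no standalone JOAG mechanism is described.

The numeric cut-offs are this package's operationalization
(`classifierThresholds`): retinol ≤ 25% is "null-like", ≥ 120% is "excess";
estradiol inside [80, 120]% is "normal". They were chosen once to separate
the observed clusters of inferred values — null (0), heterozygote floor
(50), normal (~100), excess (≥ 122) — and reproduce, among others, the
boundary pair Q144H (steroid 57 → concordant) versus D530G (steroid 94 →
discordant). The boundary between "slightly reduced" and "not significant"
is a design choice, not a published fact; all four thresholds are arguments.
Verdicts for genotypes with inferred retinol exactly 0 or ≥ 120 are
insensitive to sweeping the low cut-off across [5, 45], which the tests
check.

Four fixture rows carry published verdicts that contradict their own printed
numbers under any fixed rule set (e.g. a printed "Inconclusive" despite
determinate inferred activities). These are resolved by an explicit override
channel in the fixture rather than by contorting the rules; `runPipeline`
lists them in every summary.

## Elastic-network flexibility screen

`buildHessian` constructs the standard anisotropic network model: sites are
alpha carbons (or all heavy atoms), pairs within a cutoff are connected by
uniform springs, and the 3N×3N Hessian has off-diagonal blocks
−γ·(r_ij r_ijᵀ)/|r_ij|². Defaults: 15 Å cutoff for CA models (8 Å is
customary for heavy-atom models), γ = 1 in arbitrary units — the NMA package
the published analysis relied on does not restate its constants, so the
conventional ANM defaults are used and everything is configurable.

`enmModes` performs a dense symmetric eigen-decomposition with eigenvalues
ascending; a connected structure has exactly six numerically zero modes
(rigid translations/rotations), so mode 7 is the first internal motion.
`modeRMSF` averages modes 7–9 by default: per residue,
f_i = sqrt(mean_k |e_k(i)|²/λ_k), i.e. 1/λ weighting per mode, mass-free,
then averaged over the range. Mutant-versus-wild-type comparison uses
`log2FlexRatio`, log2((f_mut + ε)/(f_wt + ε)) with ε = 1e-9 guarding exact
zeros; positive values mean increased mutant flexibility. Because a CA-only
elastic network is sequence-blind, mutant profiles require either
externally built mutant coordinates or heavy-atom models;
`substituteAndPrune` offers an explicit approximation (relabel the residue,
keep atoms shared by both residue types).

`summarizeSegments` reduces ratio profiles over named P450 blocks (B-C
loop, F-G region, ...). The published analysis never gives numeric residue
ranges for these blocks, so the shipped defaults (`defaultSegments`) are a
literature-style convenience marked non-authoritative; quantitative work
should supply its own ranges.

Essential-dynamics comparison: `superposeEnsemble` (SVD Kabsch fit),
`ensemblePCA` (covariance of flattened coordinates, descending variances),
and `pcDistance`, the Euclidean distance over the first three principal
components. "PC k" as a scalar is ambiguous in the source; the default
summary (`pcSummary`) is the component variance, with the mean projection
selectable — meaningful only on a common basis.

## Synthetic data: what it does and does not show

All pipeline inputs can be generated in-package with the statistical
structure the analysis assumes: multiplicative lognormal noise for
luminescence and densitometry (reporter signals are strictly positive and
CV-parameterized — the standard choice absent a published noise model),
per-well transfection-efficiency factors that multiply both firefly and
Renilla readings, exponential protein decay after translational arrest, and
ideal toy structures (helix, extended, palindromic) with correlated Gaussian
coordinate ensembles of known covariance. Defaults follow the published
designs: technical triplicates, chase sampling at 0/4/8/12 h, 2 µM retinol
and 10 µg/ml cycloheximide retained as metadata.

Every simulator is deterministic under a fixed seed and exactly invertible
by its pipeline stage at zero noise; these round trips are what the tests
prove. What they do not show: real plates have positional effects and
pipetting drift that are not i.i.d. lognormal; real densitometry saturates;
real mutant structures differ from relabelled wild-type coordinates; and the
wet-lab percentages themselves (e.g. 337.84% for one variant's estradiol
activity) are measured facts that can only be propagated, not recomputed.
The synthetic checks validate the arithmetic and its statistical
calibration, not the biology.

## Numerical choices and problem sizes

Rounding is half-away-from-zero (documented above). Eigen-decompositions
are checked against an independent dense factorization (singular values) to
1e-8 relative error and against a finite-difference Hessian oracle; rigid
modes are detected at 1e-8 of the spectral maximum. Test and acceptance runs
use 10–30-residue toys, 500–1,000-member ensembles, 10,000 null replicates
for the t-test calibration and 200 chase simulations for the power check —
sizes at which every quantity is stable to well inside its asserted
tolerance while the whole suite runs in seconds.

## Known limitations

* The dosage model is a fixed two-allele average by design of its source —
  no penetrance, expression or population-genetic modelling.
* The classifier encodes one published decision model with invented numeric
  cut-offs; it is a research artifact, not a clinical tool.
* The ENM screen ranks relative flexibility changes; it does not replace
  molecular dynamics, tunnel analysis or docking, which are out of scope.
* Genomic-coordinate (VCF/HGVS) parsing is out of scope; the catalog is
  protein-level.
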