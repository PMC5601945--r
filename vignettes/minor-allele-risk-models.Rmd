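---
title: "Minor-allele burden and weighted genetic risk scores: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minor-allele burden and weighted genetic risk scores: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

Common polygenic disorders are driven by very many variants of
individually small effect.  One way of summarizing that burden is to ask
how many *minor alleles* — at each biallelic SNP, the allele with
control-population frequency below 0.5 — a person carries across the
genotyped genome.  If risk alleles are disproportionately minor alleles,
cases will carry a slightly but measurably higher *minor-allele content*
(MAC) than controls, and a score that weights each minor allele by its
estimated effect should discriminate cases from controls in an
independent cohort.

`magrs` implements that analysis end to end for case-control SNP-array
cohorts: genotype QC, minor-allele assignment from controls, MAC and its
group comparisons, LD pruning, per-SNP logistic weights, weighted
genetic risk scores (wGRS) and conventional polygenic risk scores (PRS),
a grid of prediction models over frequency/LD/p-value thresholds,
external and internal cross-validation, and best-model selection.
Because real schizophrenia cohorts of this design are controlled-access,
the package ships a generative simulator that reproduces the *structure*
of such data and carries ground truth for validation.

# The quantities

## Minor-allele content

For subject $i$ over a panel of informative SNPs (minor allele defined,
genotype non-missing),

$$\mathrm{MAC}_i \;=\; \frac{\sum_j d_{ij}}{2\,n_i},$$

where $d_{ij} \in \{0,1,2\}$ counts minor alleles and $n_i$ is the
number of usable SNPs for that subject.  The $2 n_i$ denominator
(per-allele normalization) makes MAC the fraction of carried alleles
that are minor, so a Hardy-Weinberg subject's expected MAC equals the
panel's mean MAF — the magnitude one observes in practice (about 0.24 on
a cleaned genome-wide array panel).  A literal per-SNP denominator
(`denominator = "snps"`, range $[0,2]$) is available for comparison.
Non-informative SNPs — control MAF exactly 0.5 (a tie under the strict
"< 0.5" rule), monomorphic, or with no non-missing control genotype —
are excluded everywhere, and a subject's own missing genotypes are
excluded from that subject's denominator.

Group comparisons use the classical two-sample z-test on means (unbiased
variances, two-tailed normal p), the variance-ratio F-test (larger
variance in the numerator, two-tailed), and the 1-df Pearson chi-square
for two proportions without continuity correction.  These are simple,
fully specified contracts that are testable against closed forms.

## Risk scores

Per-SNP weights come from univariate maximum-likelihood logistic
regression of case status on minor-allele dosage with intercept.  The
wGRS applies the genotype weight rule
$w \in \{1, 0.5, 0\}$ for homozygous-minor / heterozygous /
homozygous-major — equivalently $d/2$ — times the fitted log-odds
$\beta$:

$$\mathrm{wGRS}_i = \sum_j \tfrac{d_{ij}}{2}\,\beta_j,
\qquad
\mathrm{PRS}_i = \sum_j d_{ij}\,\log_{10}\mathrm{OR}_j .$$

Because the regression uses dosage $\{0,1,2\}$ while the wGRS weight is
$d/2$, a $\beta$ acts "per minor-allele pair"; the two conventions are
consistent by construction.  For the PRS the allele-count coding
$\{0,1,2\}$ with $\log_{10}$ weights follows the established
polygenic-scoring convention; whether the source analyses weighted
dosage or the $\{0,0.5,1\}$ genotype rule is not documented, so the
package fixes the conventional choice and exposes both score types.
A missing genotype contributes 0 to either score and decrements that
subject's `n_snps_used`, which is carried as the covariate in the
variance-explained model rather than being imputed — imputation would
silently shift score magnitudes between subjects with different
missingness.

Raw scores are reported.  An optional training-mean-centered wGRS
variant (`center = TRUE`) is provided because centered scores (cases
positive, controls negative) are common in practice, but no claim is
made that any particular published absolute score scale is reproduced —
centering conventions are rarely documented.

## Evaluation

* **AUC** is the rank-based Mann-Whitney statistic (ties counted 0.5),
  with a DeLong 95% interval from case/control placement variances.
* **TPR at 100% specificity** is the fraction of cases *strictly* above
  the maximum control score; a tie with the best control would cost a
  control and is not counted.  Its interval is Clopper-Pearson on the
  case count — exact coverage, no tuning.
* **Nagelkerke variance explained** is
  $R^2_N(\text{score} + \text{covariate}) - R^2_N(\text{covariate})$
  with the per-subject SNP-use count as the covariate and
  $R^2_N = \frac{1-\exp\{(2/n)(\ell_0-\ell)\}}{1-\exp\{(2/n)\ell_0\}}$.
  Differences negative by numerical noise (below $10^{-12}$) are
  clipped to zero.

# LD pruning

"LD-independent" SNP sets are produced by a greedy left-to-right scan
per chromosome: for each still-retained SNP, any later SNP within a
200 kb window whose genotype $r^2$ (squared Pearson correlation of
dosages over pairwise-complete subjects — composite LD, no phasing)
exceeds the threshold triggers a removal.  The published description of
such pruning names only the threshold and the window, so the scan
semantics here are this package's own fully specified contract: the
member of the offending pair with the lower MAF is removed (at equal
MAF, the larger position), which keeps the better-measured, more
informative marker and is deterministic.  A pair with a constant dosage
vector has undefined correlation and is treated as $r^2 = 0$ — it can
never exceed a threshold.  The windowed correlation pass is computed
once and shared across all eight thresholds
(0.8, 0.7, ..., 0.1), and an unsorted SNP table is an explicit error
rather than a silent sort.

# The model grids and cross-validation

Three families of prediction models are built from a training cohort
only:

| family | groups | p-thresholds | models |
|---|---|---|---|
| wGRS, total SNPs | MAF < 0.5, 0.4, 0.3, 0.2, 0.1 | 26 | 130 |
| wGRS, LD-independent | $r^2$ 0.8 ... 0.1 | 26 | 208 |
| PRS | total + 8 LD sets (MAF < 0.5) | 26 | 234 |

The 26 p-value thresholds are
1, 0.6, 0.5, 0.4, 0.3, 0.2, 0.19, ..., 0.11, 0.1, 0.09, ..., 0.01,
0.005 (strict "<" everywhere).  A cell whose SNP list is empty is kept
in the grid but marked unevaluable.

**External cross-validation** trains every per-SNP component —
minor-allele status, weights, p-values, pruned sets — on the training
cohort and evaluates scores on the held-out cohort; the two cohorts are
first harmonized by `snp_id` intersection with counted-allele
reconciliation (swapped orders flip dosages; strand flips resolve
through base complements; palindromic A/T and C/G SNPs with discordant
allele order are ambiguous and dropped).  Overlapping subject ids are a
hard error.  Nothing computed from validation labels can reach a
weight or SNP list; the permutation tests in the test suite act as a
leakage canary.

**Internal cross-validation** partitions one cohort into 10 random
near-equal folds (sizes differ by at most one; 2154 subjects give four
folds of 216 and six of 215).  By default each training fold refits the
minor-allele assignment, the weights and the p-value SNP selection —
reusing whole-cohort estimates would leak the held-out labels through
the weights.  The LD-pruned sets *are* reused across folds: pruning
sees genotypes and MAFs only, never phenotypes, so no label information
flows through it, and re-pruning per fold would triple the cost for no
statistical gain.  A `refit = "none"` flag reproduces the leaky variant
deliberately, for comparison.  Fold draws that leave a fold without
both classes are redrawn (up to 100 attempts), and a stratified option
is available.

**Best-model selection** first applies a performance screen
(defaults: AUC > 0.57, and TPR ≥ 2% for total-SNP models or ≥ 2.78%
for LD-independent models), then ranks by AUC, breaking ties by TPR,
then Nagelkerke $\Delta R^2$, then the *smaller* SNP count, then the
lexicographic model id.  "Maximize AUC, TPR and $\Delta R^2$ together"
is not a total order, so the package fixes this deterministic
lexicographic composite; the screen thresholds are configurable and
`screen = NULL` ranks every evaluable model.

# The simulator

`simulate_cohorts()` draws independent cohorts sharing one SNP panel
and one set of true effects:

* **Haplotypes**: a blockwise AR(1) latent Gaussian (block size 10,
  correlation `ld_rho`) thresholded at each SNP's target-MAF quantile;
  genotype = sum of two independent haplotypes, so Hardy-Weinberg holds
  marginally and LD decays with marker distance and vanishes across
  blocks.
* **Phenotype**: liability = sum of causal risk-allele dosages times
  their effects plus standard-normal noise; a subject is a case when
  liability exceeds the threshold implied by the prevalence.  A
  logistic phenotype model is available for sensitivity checks.
* **Risk orientation**: each causal SNP's risk allele is its minor
  allele with probability `minor_risk_prob` ($q$).  $q > 0.5$ is the
  single knob that creates the case MAC excess; $q = 0.5$ abolishes it
  regardless of heritability.

Defaults are chosen once to emulate a two-cohort array study at desk
scale: 500 cases + 500 controls per cohort (the real cohorts of this
design run 800–1150 per arm), 5000 SNPs in blocks of 10 over 5
chromosomes at ~4 kb spacing (so a 200 kb window spans ~50 markers, as
on a dense array), MAF uniform on (0.01, 0.5), causal fraction 0.05,
liability effect SD 0.15, $q = 0.7$, prevalence 0.01 (the lifetime
risk figure for the motivating disorder), 1% MCAR missingness, and
`ld_rho = 0.9`.  The latent correlation is deliberately high because
dichotomization attenuates it: at $\rho = 0.9$ realized adjacent-pair
genotype $r^2$ is about 0.5.  A consequence worth knowing is that
genotype $r^2 > 0.8$ essentially never occurs under this model, so the
0.8 and 0.7 pruning thresholds remove little — real arrays, with their
near-duplicate probes, prune much harder at those thresholds.

Case-control sampling at 1% prevalence is made exact and cheap by a
two-stage scheme: candidates are screened on liabilities computed from
their causal-SNP latents alone, and only accepted subjects have the
remaining latents drawn from the exact AR(1) Gaussian conditional given
those causal latents.  This is distributionally identical to rejection
sampling of whole genomes (the conditional is the true conditional);
the test suite verifies that realized MAFs and block LD are unchanged
when the conditional path is exercised.

What the simulator does **not** emulate: realistic recombination maps
or haplotype-block irregularity, ancestry structure and admixture,
genotyping batch effects, informative missingness, rare-variant
architecture.  Passing tests therefore demonstrate that the pipeline's
statistics and bookkeeping are correct and calibrated under a clean
polygenic model — not that any particular real-data effect size will be
reproduced.

# Numerical choices

* Per-SNP logistic fits use Newton/IRLS vectorized across SNP columns,
  relative tolerance $10^{-8}$, at most 50 iterations; missing dosages
  enter with weight 0.  Fits with complete separation (runaway slope),
  constant dosage, a singular information matrix or non-convergence are
  flagged unusable and excluded from models rather than clipped.
* The HWE filter is the 1-df Pearson chi-square (an exact enumeration
  test is available), tested in controls by default; the filter
  removes SNPs with HWE $p <$ 0.01, missingness $>$ 5% and MAF $<$ 1%.
  The missingness rule is read as *excluding* SNPs above the cut —
  the purpose of the filter is to drop poorly genotyped markers.
  MAF for the filter is computed on all subjects by default
  (`maf_sample = "controls"` is available).
* Monomorphic SNPs return HWE $p = 1$ (no departure assessable) with a
  flag.
* Degenerate group tests are flagged rather than silently propagated:
  zero variance in both z-test groups gives $z = 0, p = 1$ at equal
  means and infinite $z$ otherwise; a zero-variance F denominator is an
  infinite F; a pooled proportion of 0 or 1 yields $\chi^2 = 0, p = 1$.
* All randomness (simulation, fold assignment) flows from explicit
  seeds; identical seeds reproduce outputs byte-for-byte, including
  through the command-line interface.

# Problem sizes used in validation

The shipped test-and-acceptance runs use, as this package's own
validation design: oracle equivalence checks on hundreds of small
random instances (exhaustive pair-counting AUC, optimizer-verified
logistic fits, closed-form z/F/chi-square values); null calibration on
200 replicate cohort pairs of 150+150 subjects by 300 SNPs (z-test
rejection rate, externally validated AUC, TPR exchangeability); and
signal recovery on 20 replicate pairs at the full default scale
(5000 SNPs, 500+500 per cohort, $q = 1$) checking case MAC excess,
best-model external AUC and the in-sample versus out-of-sample
separation ordering.

# Known limitations

* No covariate adjustment (ancestry principal components, sex) in the
  per-SNP regressions or the Nagelkerke models; the package targets the
  unadjusted design it implements and validates.
* No imputation, sex chromosomes, multi-allelic variants or VCF input.
* The greedy pruning contract is one deterministic choice among several
  reasonable window-scan semantics; survivor sets from other tools will
  differ in detail while satisfying the same pairwise constraint.
* Nagelkerke $\Delta R^2$ on a validation cohort uses validation labels
  to fit the two nested models; that is its standard definition, but it
  is a goodness-of-fit measure, not an additional out-of-sample claim
  beyond AUC/TPR.
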