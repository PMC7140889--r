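---
title: "Methods: cross-trait molecular comorbidity analysis from GWAS summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-trait molecular comorbidity analysis from GWAS summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosstrait)
```

# The problem

Two complex diseases that co-occur within individuals more often than chance
— endometriosis and migraine are the motivating pair — may do so because one
causes the other, because they share environmental risk factors, or because
they share genetic architecture. With only GWAS *summary statistics* (per-SNP
effect sizes, standard errors and p-values; no individual genotypes), a
surprising amount of this question is answerable. `crosstrait` implements the
full battery of summary-statistics methods for the job: effect-direction
concordance (SECA), LD score regression for heritability and genetic
correlation, cross-disorder meta-analysis, two-sample Mendelian
randomization, gene-based association with overlap statistics, and pathway
over-representation — plus a synthetic-data generator with known ground
truth so every stage is testable without consortium data access.

# Data model and harmonization

The universal currency is a tibble of per-SNP records: variant ID,
chromosome, 1-based position, effect and other allele, log-odds effect
`beta`, its standard error, p-value, sample size and (optionally) effect
allele frequency. Invariant enforcement (`validate_sumstats()`) drops rows
with blank or duplicate IDs, identical or non-ACGT alleles, non-positive
standard errors, or p-values outside (0, 1] — mirroring the routine
exclusion of variants without rsIDs.

`harmonize_pair()` aligns two tables to a shared effect allele per SNP:
swapped allele order flips the sign (and complements the frequency), and
strand flips are resolved by base complementation. Palindromic SNPs (A/T,
C/G) are ambiguous from alleles alone; the default drops them, and an
optional mode orients them by allele frequency when both frequencies are at
least 0.08 from 0.5. That margin is the conventional cutoff below which
minor/major assignment is unreliable. Harmonization is an involution on
orientation: re-coding either input cannot change the aligned effects.

LD enters as a *block-diagonal reference*: an ordered list of SNP blocks,
each with a correlation matrix, zero correlation across blocks. This is the
one abstraction shared by clumping, LD scores, locus definition, gene-based
tests and simulation. `clump_snps()` performs p-value-informed greedy
selection — visit SNPs by ascending dataset-1 p-value, retain a SNP iff its
r² with every retained SNP is below the threshold. Ties in p are broken by
(chromosome, position, ID) so the output is deterministic. The SECA default
r² < 0.1 matches the independence criterion used for effective-test
counting; the published analyses do not state SECA's own clumping r², so
0.1 is a documented package choice, not an inferred one.

# SNP effect concordance (SECA)

Both traits' p-values are partitioned at the 12 cutoffs
0.01, 0.05, 0.1, 0.2, ..., 1.0, giving a 12×12 grid of nested SNP subsets.
Per cell, the 2×2 table of effect directions (trait 1 up/down × trait 2
up/down) is tested with a two-sided Fisher exact test; the package computes
the conditional hypergeometric p (summing tables as or less probable than
the observed one) with its own vectorised routine because the permutation
stage needs tens of thousands of such tests; it is cross-checked against
`stats::fisher.test` in the test suite. The reported odds ratio is the
sample odds ratio, the convention of SECA output.

Two summaries follow. The binomial excess test counts cells that are both
nominally significant (p ≤ 0.05) and concordant (OR > 1) and refers the
count to Binomial(144, 0.025) — 0.025 because under sign symmetry a cell is
significant *and* in the concordant direction with half the nominal rate.
Because the 144 cells are nested and highly dependent, this nominal tail is
only a summary; inference rests on the permutation: each permutation flips
dataset 2's effect signs independently per SNP (dataset 1 conditions the
subsets, so it is held fixed; p-values are untouched, so subset membership
is invariant), the grid is rebuilt, and empirical p-values use the add-one
formula `(1 + #more extreme)/(n_perm + 1)` — never smaller than
`1/(n_perm + 1)`, which with the default 1000 permutations floors at
9.99 × 10⁻⁴. A Clopper–Pearson interval accompanies the excess-subset p.

A calibration fact worth knowing: under the null, the excess-subset *count*
is usually zero, so its permutation p has a large atom at 1 (it is valid —
super-uniform — but discrete). The minimum-cell-p statistic is effectively
continuous and its permutation p is close to uniform under the null; the
test suite checks exactly these two properties.

# LD score regression

Under an infinitesimal polygenic model, the expected association chi-square
of SNP j is `1 + n·h²·ℓ_j/m` where `ℓ_j = Σ_k r²_jk` is its LD score.
`fit_h2()` regresses chi-square on `n·ℓ/m`: the slope estimates the
observed-scale SNP heritability, the intercept captures confounding
inflation and can be fixed (e.g. to 1) when none is assumed. Weights
`1/(ℓ·(1 + n·h²·ℓ/m)²)` — with the h² plugged in from an unweighted pre-fit
— counteract both LD-induced double counting and the heteroscedasticity of
chi-squares; this single-step weighting reproduces the published two-step
estimator's behaviour to well within jackknife error at the scales used
here. Chi-squares above `max(80, 0.001·n)` are removed first, the standard
guard against single-locus leverage. Standard errors come from a
delete-a-block jackknife over 200 contiguous SNP blocks (reduced with a
warning when SNPs are few).

The bivariate fit regresses the z-score product on `√(n₁n₂)·ℓ/m`; the slope
is the genetic covariance and `r_G = gencov/√(h²₁·h²₂)`. Without sample
overlap the covariance intercept is truly zero and can be constrained; the
jackknife is joint over all three regressions so the ratio's standard error
reflects their shared sampling noise. When either heritability estimate is
non-positive, `r_G` is reported missing with a diagnostic rather than a
complex number.

For a case-control trait, `obs_to_liability()` rescales by
`K²(1−K)²/(K_s(1−K_s)·φ(z)²)` (population prevalence K, sample prevalence
K_s, z the normal quantile at 1−K). At K = K_s = 0.5 the factor is π/2.
The published liability heritabilities (11.44% for endometriosis at
K_s = 0.082, K = 0.08) require the consortium data themselves and are not
desk-reproducible; the conversion arithmetic is what the package reproduces.

A design note on desk-scale precision: with free intercepts and only
80–400 LD blocks, the regression intercept is weakly identified (all the
leverage is far from x = 0), so intercept-free recovery is noisy — a
property of the design matrix, not the estimator. Parameter-recovery
checks therefore run with intercepts constrained to their true values
(1 and 0), exactly the constraints the motivating analysis used on real
data.

# Cross-disorder meta-analysis

`fixed_effect_meta()` is the usual inverse-variance combination.
Heterogeneity between two disorders' effects is the rule, not the
exception, so the Han–Eskin RE2 statistic is fitted per SNP: the
likelihood-ratio test of (mean, between-study variance) = (0, 0) against a
free mean and non-negative variance, with the profile over the variance
maximised numerically (the zero boundary checked explicitly). P-values use
the asymptotic equal mixture ½χ²₁ + ½χ²₂; the tabulated small-sample
corrections of the original software are out of scope, making the p
slightly conservative at two studies. With coinciding study estimates the
statistic collapses to the fixed-effect likelihood ratio — a test-suite
identity. SNPs passing 5 × 10⁻⁸ (genome-wide) or 1 × 10⁻⁵ (suggestive) on
the chosen model are grouped into loci by LD-block membership with the
smallest-p member as index SNP; block membership is a documented choice,
since the published locus count does not state its delimitation rule.

# Two-sample Mendelian randomization

Instruments are exposure SNPs at p < 5 × 10⁻⁸, clumped at r² < 0.001, then
harmonized against the outcome (no proxy search — absent instruments are
dropped and counted). Per instrument the Wald ratio `β_out/β_exp` carries
the first-order standard error `se_out/|β_exp|` (a second-order version is
available behind a flag), and instrument strength is the approximate
F-statistic `(β_exp/se_exp)²`.

Estimators: IVW (inverse-variance weighted mean of ratios) defaults to
multiplicative random effects — the fixed-effect standard error scaled by
`max(1, √(Q/(k−1)))` — because over-dispersion among instruments is common;
on the published 11-instrument ratio table this reproduces the printed
standard error (0.05) where the fixed-effect value (0.03) does not, and
both modes are exposed. MR-Egger orients exposure effects positive and adds
a free intercept estimating average directional pleiotropy (residual
dispersion is bounded below by 1, and slope/intercept p-values use the t
distribution with k−2 df). The weighted median interpolates the
inverse-variance-weighted empirical median of ratios and takes its standard
error from a seeded parametric bootstrap; simple and weighted modes smooth
the ratio distribution with a normal kernel at the modified Silverman
bandwidth `0.9·min(sd, mad)·k^(−1/5)` times a scale factor φ. Cochran's Q
(about IVW, df k−1) and Q′ (about the Egger fit, df k−2) quantify
heterogeneity, and leave-one-out refits expose single influential
instruments. All estimators are equivariant under rescaling of the exposure
— another test-suite identity.

# Gene-based tests and overlap

SNPs map to genes by position with ±0 kb padding (1-based inclusive at both
ends). The gene statistic is the *best SNP* — the minimum SNP p in the gene
— calibrated by simulating z-vectors from MVN(0, R) with the gene's LD
matrix (repaired to the nearest positive semi-definite matrix when numeric
noise demands), converting to two-sided p-values, and minimising. The
empirical p uses the add-one formula and an escalating simulation count
(10³, 10⁴, ... up to a cap) until at least 10 exceedances accumulate, so
small p-values receive proportionally more precision. Under identity LD the
result matches the Šidák form `1 − (1 − p_min)^m`; under perfect LD it
matches `p_min`.

Neighbouring genes' best SNPs are correlated, so the number of *effective*
independent gene tests Me is computed by partitioning top SNPs into
independence blocks at r² < 0.1 and applying the Li–Ji eigenvalue rule
`Σ(1(λ ≥ 1) + (λ − ⌊λ⌋))` within blocks. Me drives the Bonferroni
genome-wide gene threshold `0.05/Me` (17,104 effective genes gives
2.92 × 10⁻⁶) and the overlap inference: with discovery and target gene sets
thresholded at 0.1/0.05/0.01, the expected overlap proportion is the
target's effective significant count over its total effective count, the
observed effective overlap is the raw overlap scaled by the discovery set's
effective/raw ratio (rounded to an integer, as the published table prints),
and the one-sided exact binomial tail `P(X ≥ k)` tests the excess. One
arithmetic subtlety is reproduced deliberately: the published binomial
p-values follow from the *printed, rounded* expected proportions (0.086,
0.151, 0.026), so the packaged printed-table fixtures feed those; on new
data the package uses the exact ratio. Fisher's combined p across the two
traits is the χ²₄ tail of `−2(ln p₁ + ln p₂)`, applied to genes nominally
associated with both.

# Enrichment

`enrich()` is a hypergeometric over-representation test of a query gene
list against GMT gene sets over an explicit background (the published
analysis does not state its background universe, so the package requires
one). Terms are filtered to 5–350 members after background intersection,
the recommended band for interpretable pathways. The proprietary g:SCS
adjustment exists only inside the g:Profiler codebase; the package adjusts
by Benjamini–Hochberg (any `p.adjust` method is accepted), so published
adjusted p-values are not reproduction targets. Tabular output only; the
enrichment-map visual clustering of the motivating study is out of scope.

# The synthetic-data generator

`gen_joint_sumstats()` draws, per SNP, true effects for both traits jointly
— variances `h²_k/m`, correlation r_G — and per LD block observes
`z_k = √(n_k)·R·β_k + ε`, `ε ~ MVN(0, R)`, independently across traits (no
sample overlap, matching the motivating data's construction). Effects are
reported on the z scale (`se = 1/√n`). This is exactly the sampling model
LD score regression assumes, so `E[χ²] = 1 + n·h²·ℓ/m` holds by
construction — the generator and the estimator are *not* the same code
path, and recovery of (h², r_G) is a genuine end-to-end check. Defaults are
the package's standard study conditions: m = 20,000 SNPs, n = 50,000 per
trait, h² = 0.10, r_G = 0.38, AR(1) blocks of 50 SNPs at ρ = 0.5 — r_G and
h² echo the motivating estimates, and block size 50 at ρ = 0.5 gives LD
scores in the realistic 1.3–3 range at a size a laptop handles in seconds.
A causal-fraction knob departs from the infinitesimal model when sparsity
is wanted; case-control liability simulation is not generated directly
(observed-scale statistics plus stated prevalences exercise the conversion
arithmetic instead).

What the generator does *not* emulate: minor-allele-frequency-dependent
architectures, varying per-SNP sample sizes, population stratification,
sample overlap, or realistic genome-wide LD maps. Passing tests demonstrate
the estimators are correct under their assumed models at desk scale — not
that any real dataset satisfies those assumptions.

`gen_mr_scenario()` draws exposure-increasing instruments at genome-wide
strength and outcome effects `θ·β_x + α + noise` with
`α ~ N(pleiotropy_mean, pleiotropy_sd²)`: a nonzero mean injects
directional pleiotropy (recovered by the Egger intercept, biasing IVW), a
nonzero sd injects balanced heterogeneity.

# Numerical choices, degenerate inputs, limitations

* Empirical p-values always use the add-one formula; seeded RNG everywhere
  randomness exists, and reruns of the pipeline are byte-identical.
* Fisher tests with a degenerate margin report OR missing and p = 1; empty
  grid cells are recorded as missing, not errors.
* The RE2 profile optimiser brackets the between-study variance by the
  squared estimate range and checks the boundary at zero explicitly.
* Best-SNP LD submatrices are repaired by eigenvalue clipping with a log
  line; the jackknife block count shrinks automatically (with a warning)
  when SNPs are few.
* Problem sizes in the test suite (m up to 20,000, 20 LDSC recovery seeds,
  100 MR replicates, 50 SECA null runs at 99 permutations) were chosen as
  the smallest that make the Monte Carlo bands meaningful.
* Known limitations: no >2-study meta-analysis bookkeeping, no MR-PRESSO /
  multivariable MR / Steiger filtering, no proxy-SNP search, no partitioned
  heritability, and the RE2 p is asymptotic. The pipeline trusts upstream
  genotype QC entirely.

# Pipeline

`run_pipeline()` executes harmonize → clump → SECA → LDSC → meta → MR →
genes → overlap → enrichment from one nested-list or YAML configuration,
writing per-stage TSVs and a consolidated JSON summary; every stochastic
stage takes its seed from the config, a failing stage halts the run with
its name, and earlier outputs are preserved. Configured defaults echo the
motivating analysis settings (5 × 10⁻⁸, 1 × 10⁻⁵, MR clump r² 0.001, SECA
r² 0.1, overlap thresholds 0.01/0.05/0.1, term sizes 5–350). An example:

```{r pipeline, eval = FALSE}
report <- run_pipeline(
  list(simulate = list(m_snps = 5000, n_genes = 100, n_terms = 30),
       seeds = list(simulate = 1, seca = 2, mr = 3, genes = 4)),
  out_dir = "crosstrait-run")
report
```
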