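---
title: "Polygenic scores for refractive error: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polygenic scores for refractive error: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`refpgs` implements a complete derivation-and-evaluation pipeline for
polygenic scores (PGS) of spherical equivalent refractive error (avSER,
diopters; negative = myopia), together with the downstream test of
whether such a score predicts severe myopic macular degeneration (MMD)
beyond refractive error itself. Because the cohorts this class of study
uses are access-controlled, the package ships a synthetic-data generator
whose outputs have the statistical structure every stage assumes; all
statistical machinery is exercised and validated on those cohorts.

## The synthetic cohorts

`simulatePanel()` draws effect-allele dosages for up to 22 autosomes
under Hardy–Weinberg equilibrium through a Gaussian copula: within each
block of `ld_block_size` adjacent SNPs the latent variables follow an
AR(1) process with correlation `ld_rho`, and blocks never span a
chromosome boundary. The induced *dosage* correlation is attenuated
relative to the latent correlation; `copulaDosageCorrelation()` is the
Monte-Carlo oracle for the induced value and anchors the tests. Allele
frequencies are uniform on `[maf_low, maf_high]` (default 0.05–0.5).

`simulatePhenotypes()` builds avSER as genetic value plus covariate
terms plus Gaussian noise. A fraction `p_causal` (default 1%) of SNPs
receives normal effects, rescaled so the sample genetic variance equals
`h2 * ser_sd^2`; the default heritability 0.3 is the value the shrinkage
grid selected on the real tuning data, and the trait moments (mean
−0.28 D, SD 2.72 D) and age structure (mean 58, SD 8) follow the
published demographic table for the adult cohort. Covariate effects are
mild and conventional: −0.01 D per year of age, +0.1 D for female sex,
−0.15 D per education year (education is the classical environmental
correlate of myopia). Ancestry PCs are exchangeable standard-normal
noise by default (`pc_mode = "noise"`): the default cohort is
homogeneous, so PCs act only as inert covariates; `pc_mode = "computed"`
runs a real PCA of the panel.

The age-of-onset of spectacle wear (AOSW) is generated by a monotone
onset model: expected onset `16 + 2 * avSER` years plus Gaussian noise
(SD 3), clamped to `[5, Age]`. Participants whose avSER exceeds 0 D, or
whose modeled onset lies beyond their current age, are flagged
never-wearers and carry no numeric AOSW. This is the simplest model with
the direction the analysis relies on (more myopic, earlier spectacles).
It is a stand-in, not a claim about how AOSW arises in any real cohort;
in particular it makes spectacle wear purely myopia-driven, whereas real
spectacle wear includes hyperopic and presbyopic corrections. The
never-wearer policy downstream is exclusion from the inference model
(the model needs a numeric AOSW).

Per-eye META-PM grades come from a participant-eye-level logit model:
`logit(p_severe) = -6.6 + log(1.28) * (-avSER) + beta_direct * pgs`. The
slope per diopter matches the published odds ratio of 1.28; the
intercept places participant-level severe prevalence near 0.3%, the
published order of magnitude; `beta_direct = 0` by default, encoding
full mediation (given avSER, grades are independent of the PGS). Severe
eyes are graded C3 vs C4 in the 169:49 proportion of the published
grade table; simulating at eye level exercises the worse-eye coding.
Family clusters default to a size distribution of 80% singletons, 15%
pairs, 5% triples.

Every generator is a pure function of `(config, seed)`; each stage sets
a child seed `seed + offset` (panel +1, phenotypes +2, AOSW +3, MMD +4,
families +5) so stages can be re-run independently.

What the simulator does **not** emulate: realistic human LD maps and
allele-frequency spectra, imputation artefacts, the X chromosome,
cryptic relatedness beyond family labels, assortative mating, genetic
nurture, or gene–environment interplay. Passing tests therefore show
that the *machinery* is correct under the assumed structure, not that
the real-data effect sizes would be reproduced.

## GWAS and principal components

`runGwas()` is an ordinary-least-squares single-variant scan with the
conventional covariate set (age, age², sex, genotyping array, 10 PCs).
Phenotype and dosages are residualized on the covariates once; per-SNP
slopes on residuals are algebraically the joint fits, and the residual
degrees of freedom are corrected for the covariate count plus the SNP.
A linear model stands in for the mixed model used at biobank scale: the
synthetic cohorts contain no confounding population or relatedness
structure for a random effect to absorb, and family structure is
handled by design (family-aware partitioning) rather than by a
variance component. P-values use the normal approximation, consistent
with the meta-analysis downstream; at the simulated sample sizes the
difference from the t reference is far below any tolerance used.
Missing dosages are mean-imputed per variant. Constant dosages return
`beta = 0, se = Inf, p = 1`.

## The LOCO AOSW-inference stage

The proxy-phenotype stage infers avSER from AOSW with a fixed
regression specification: orthogonal polynomials of AOSW (order 10),
Age (order 3), EduYears (order 2), a sex term, the raw EduYears × AOSW
product, a predictive PGS main effect and PGS × orthogonal-AOSW
interactions up to order 2 — 20 non-intercept design columns. The
orthogonal bases are any orthonormal basis of the monomial span built
on the training rows and frozen; fitted values, the testable contract,
are invariant to the basis choice. The EduYears × AOSW product uses raw
AOSW (the specification is ambiguous on this point; the raw product is
implemented and documented, not silently changed). Prediction inputs
are clamped to the training range before evaluating the bases: a
degree-10 polynomial is numerically explosive under extrapolation, and
out-of-range onset ages carry no usable information.

Because the inferred phenotype of a GWAS participant contains a PGS
term evaluated on their own genotypes, a genome-wide PGS would leak
every tested SNP's own weight into the phenotype it is tested against.
The leave-one-chromosome-out (LOCO) scheme fits 22 inference models,
each with a PGS omitting one chromosome, and assembles the final
summary statistics by taking chromosome *k*'s rows from the run whose
PGS omitted chromosome *k* — a pure row selection
(`assembleLocoGwas()`), leaving betas and SEs untouched.

The predictive weights behind the LOCO scores are either a single
infinitesimal shrink `n*h2/(n*h2 + m)` of the GWAS betas or a
per-block ridge solve against an LD reference; the two coincide at
identity LD, which is the closed-form oracle in the tests.
`locoLeakageExperiment()` packages the three-arm demonstration (LOCO /
full-genome / covariate-only inference). The cohort is split 3:2:3
across the weights GWAS, the inference model and the inferred-phenotype
GWAS: the weights sample must stay large enough that the predictive
score retains information after conditioning on AOSW, otherwise the
inference model assigns the score a negligible coefficient and there is
no leakage to demonstrate in either direction. The covariate-only arm
is the leak-free benchmark: no genotype of the GWAS sample enters its
phenotype.

## Meta-analysis and the union assembly

`mtagMeta()` implements the moment-based multi-trait combination: per
variant, a generalized-least-squares estimator over the genetic
covariance `Omega` (estimated by the cross-product moment estimator and
projected to the nearest PSD matrix when not supplied) and the sampling
covariance `Sigma = diag(se²)`. The cohorts are treated as
non-overlapping, so no sample-overlap correction is implemented — a
documented limitation. Two limits anchor the implementation: a single
cohort passes through unchanged, and rank-1 `Omega` with equal SEs
reduces to inverse-variance weighting. Allele alignment flips signs on
swapped alleles, drops irreconcilable allele pairs with a count, and is
an involution.

Variants absent from some cohorts enter through the two-stage union:
a second meta-analysis of the cohorts that do cover them, with
`assembleUnion()` concatenating the disjoint row sets (every output
variant traceable to exactly one source).

## Shrinkage, the grid and the baseline

`gibbsGrid()` is a point-normal (spike-and-slab) Gibbs sampler run per
LD block on the standardized scale: slab variance `h2/(m*p)`, spike
probability `1 − p`, marginal sampling variance `1/n`. The grid axes
are the conventional ones — heritability {0.1, 0.2, 0.3, 0.4}, causal
fraction {1e-5 … 1} (the axis often labelled a p-value threshold),
sparsity {TRUE, FALSE} — 48 cells. Defaults of 500 iterations with 100
burn-in match the source method's order of magnitude; the update order
is fixed genome order for reproducibility. Posterior means are
Rao-Blackwellised (averages of conditional means rather than draws),
which halves Monte-Carlo noise and makes the identity-LD, `p = 1` cell
agree with the infinitesimal closed form exactly; the single-SNP cell
is checked against direct numerical integration of the two-component
posterior. The sparse rule zeroes SNPs whose average posterior
inclusion probability falls below the prior causal fraction `p`; the
exact zeroing rule used upstream is not published, so this simple
documented rule is used. PSD repair of LD blocks floors eigenvalues at
1e-8 and renormalizes the diagonal. `clumpThreshold()` is the standard
greedy clumping-plus-thresholding baseline with ties broken by genome
order. `tunePgs()` selects the grid cell maximizing incremental
adjusted R² on a held-out tuning sample and emits the full grid report.

## Evaluation battery

Refraction categories are boundary-inclusive: myopia ≤ −0.50 D,
moderate myopia ≤ −3.00 D, HM5 ≤ −5.00 D, HM6 ≤ −6.00 D, moderate
hyperopia ≥ +3.00 D. Scores are standardized within ancestry group
before evaluation. Incremental R² is the difference of *adjusted* R²
between the covariate+score and covariate-only models (the adjusted
difference can sit slightly below the raw difference); the point
estimate is the bootstrap median and the CI the 2.5th/97.5th
percentiles of 2000 participant resamples. AUROC is the midrank
Mann–Whitney statistic (ties half credit) with a stratified percentile
bootstrap — cases and controls resampled separately so every replicate
retains both classes; score-only ranking by default, with a
covariate-adjusted variant deliberately out of the default path. ROC
comparison is the paired bootstrap difference test. Tail odds ratios
use the 2×2 table with Wald CIs on the log OR and the Haldane–Anscombe
0.5 correction on zero cells. Deciles are assigned by stable rank
(ties to the lower decile — documented because heavily tied synthetic
scores otherwise make decile sizes ambiguous) with exact binomial CIs.
Trajectory summaries are stratified band means only (participants with
at least three measurements), deliberately not a longitudinal mixed
model.

## The MMD stage

`partitionTranches()` shuffles families (seeded) and greedily assigns
each to the currently smallest of five tranches, so relatives never
straddle a training/scoring boundary. `crossfitPgs()` re-derives the
score five times, each time without one tranche (fixed external
summary statistics reused across folds, shrinkage parameters frozen
rather than re-tuned per fold — re-tuning would be valid but slower and
is not what the frozen-parameter design needs), and scores only the
held-out tranche. For the MMD models the score is oriented so that
higher values mean greater myopia susceptibility, matching how such
odds ratios are reported. `logisticAssoc()` fits the nested logistic
models — PGS with covariates, with and without refractive error — by
maximum likelihood or by Firth's Jeffreys-penalized score modification
(implemented in-package: Newton iteration on the modified score with
step halving), the recommended route for ~0.3% outcomes. The SER
exposure is −avSER, so "per diopter more negative" reads as OR > 1 for
myopia. Wald CIs throughout (the CI method upstream is unstated;
profile intervals for the Firth fit are a known refinement not
implemented).

## Numerical and design notes

- Expected score accuracy is summarized by `daetwylerExpectedR2()`,
  `h2/(1 + m_eff/(n*h2))`. Evaluated at the LD-adjusted full marker
  count this is the infinitesimal-architecture floor; with the default
  sparse architecture (1% causal) the tuned sparse score exceeds that
  floor severalfold, as it should. The end-to-end check therefore
  evaluates the formula at the effective dimensionality of the
  *selected* model — the LD-adjusted count of non-zero tuned weights —
  and both readings are computable from the same objects.
- Problem sizes in the shipped tests: the anti-leakage experiment uses
  n = 4000, m = 4400 over 10 seeds; mediation recovery n = 50,000 per
  replicate with a 440-SNP panel (the panel only supplies genetic
  values there); end-to-end recovery n = 5000/1000/1000 with m = 5000
  over 10 seeds. These sizes were chosen as the smallest at which the
  respective signals are comfortably resolved.
- Degenerate inputs: zero-variance dosages are dropped from LD blocks
  (warning) and return null statistics from the GWAS; zero-variance
  score groups and single-class outcomes are errors; a singular
  combined covariance in the meta-analysis falls back to
  inverse-variance weighting with a warning.
- TSV dialects are UTF-8, tab-separated, `.` for missing; weight files
  follow the scoring-file convention (header comments, rsID /
  effect allele / effect weight columns); VCF output carries dosages in
  a DS FORMAT field, 1-based positions.

## Known limitations

Linear-regression GWAS (no mixed model), diagonal sampling covariance
in the meta-analysis (no overlap correction), a single simple
never-wearer mechanism, no X chromosome, no real LD maps, and the
LDpred2-auto / lassosum / BayesR family of alternatives deliberately
out of scope beyond the clumping baseline.
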