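# refpgs

Derivation and evaluation of polygenic scores (PGS) for refractive
error, and the test of whether such a score predicts severe myopic
macular degeneration (MMD) once refractive error itself is accounted
for.

Refractive error (spherical equivalent, avSER, in diopters; negative =
myopia) is a highly polygenic trait. A PGS is a weighted allele-dosage
sum `s_i = Σ_j w_j x_ij` whose weights are derived from GWAS summary
statistics. This package implements the full modern derivation chain on
synthetic cohorts, for statistical geneticists and methodologists who
want a tested, reproducible desk-scale version of the design used in
large biobank studies:

- **Synthetic cohorts** (`simulatePanel()`, `simulatePhenotypes()`,
  `simulateAosw()`, `simulateMmd()`, `assignFamilies()`): block-LD
  genotypes via a Gaussian copula, a heritable avSER, an
  age-of-onset-of-spectacle-wear (AOSW) observation process, covariates,
  family clusters and per-eye META-PM grades.
- **GWAS** (`runGwas()`, `computePcs()`): covariate-adjusted
  single-variant scans (age, age², sex, array, 10 PCs) and genetic PCs.
- **LOCO proxy-phenotype stage** (`buildLocoWeightSet()`,
  `fitAoswModel()`, `inferPhenotype()`, `assembleLocoGwas()`): avSER
  inferred from AOSW by
  `avSER ~ poly(AOSW,10) + poly(Age,3) + Sex + poly(EduYears,2) +
  EduYears×AOSW + PGS + PGS×poly(AOSW,2)`
  under a 22-fold leave-one-chromosome-out scheme, so no chromosome's
  own SNPs inform the phenotype they are tested against
  (`locoLeakageExperiment()` demonstrates why).
- **Multi-trait meta-analysis** (`alignAlleles()`, `mtagMeta()`,
  `assembleUnion()`): moment-based GLS combination over a genetic
  covariance Ω and sampling covariance Σ, with the two-stage union for
  variants missing from some cohorts.
- **LD-aware shrinkage** (`buildLdBlocks()`, `gibbsGrid()`,
  `clumpThreshold()`, `scoreSamples()`, `tunePgs()`): point-normal
  Gibbs posterior means over the grid h² ∈ {0.1…0.4} × causal fraction
  {1e-5…1} × sparsity, tuned on a hold-out sample, against a
  clumping+thresholding baseline.
- **Evaluation** (`evaluatePgs()`, `incrementalR2()`, `aurocCI()`,
  `tailOr()`, `decileRisk()`, `trajectoryBands()`): incremental
  adjusted R², midrank AUROC per refraction category, tail odds ratios
  and decile risk, all with bootstrap CIs.
- **MMD mediation stage** (`partitionTranches()`, `crossfitPgs()`,
  `worseEye()`, `severeIndicator()`, `logisticAssoc()`,
  `firthLogistic()`): family-aware five-tranche cross-fitted scores and
  nested (standard or Firth) logistic models of severe MMD.

`runPipeline()` wires all stages into one reproducible experiment.

## Worked example

End-to-end run on a small synthetic study (1200 participants, 440 SNPs
over 22 chromosomes; four meta-analyzed cohorts):

```r
library(refpgs)
cfg <- simConfig(n_samples = 1200, n_snps = 440, seed = 7)
res <- runPipeline(cfg,
                   grid = shrinkGrid(p_causal = c(0.01, 0.1, 1),
                                     n_iter = 200, burn_in = 50, seed = 7),
                   n_boot = 500)
res$evaluation
```

```
EvalReport (n = 180 , 500 bootstrap replicates)
  incremental R2 = 0.240 (0.149-0.347)
  AUROC myopia             = 0.743 (0.664-0.813)
  AUROC moderate_myopia    = 0.782 (0.684-0.869)
  AUROC moderate_hyperopia = 0.679 (0.559-0.790)
  AUROC hm5                = 0.775 (0.628-0.896)
  AUROC hm6                = 0.808 (0.712-0.906)
```

The tuned score explains 24% of test-set avSER variance beyond the
covariates (the simulated heritability is 30%), and ranks participants
with high myopia (avSER ≤ −6 D, "hm6") above others with probability
0.81. The clumping baseline reaches `res$baseline_test_r2` = 0.098 on
the same test set.

The mediation question needs more cases, so it is run at larger n:

```r
cfg <- simConfig(n_samples = 50000, n_snps = 440, seed = 42)
panel <- simulatePanel(cfg)
cohort <- simulatePhenotypes(panel, cfg)
pgs <- standardizePgs(-cohort$true_genetic_value)  # myopia-risk orientation
cohort <- simulateMmd(cohort, cfg, pgs = pgs)
severe <- as.integer(severeIndicator(
  worseEye(cohort$eye_grade_right, cohort$eye_grade_left)) == "severe")
logisticAssoc(severe, pgs, cohort$avSER, include_ser = FALSE)
logisticAssoc(severe, pgs, cohort$avSER, include_ser = TRUE)
```

```
MmdResult ( 182 cases / 49818 controls, standard logistic, unadjusted )
  OR per SD of PGS = 1.441 (1.265-1.641), p = 3.89e-08
MmdResult ( 182 cases / 49818 controls, standard logistic, SER-adjusted )
  OR per SD of PGS = 0.989 (0.842-1.163), p = 0.897
  OR per diopter more negative SER = 1.288 (1.207-1.373), p = 1.27e-14
```

With no direct PGS→MMD path in the generative model, the PGS is
strongly associated with severe MMD on its own (OR 1.44 per SD) but the
association vanishes once refractive error enters the model (OR 0.99,
CI spanning 1), while refractive error stays at OR 1.29 per diopter
more negative — the full-mediation signature.

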