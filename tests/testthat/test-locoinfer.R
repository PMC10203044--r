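test_that("LOCO weights exclude their chromosome and cover the genome", {
  cfg <- tiny_config()
  sim <- simulateCohort(cfg)
  ss <- runGwas(sim$panel, sim$cohort$avSER)
  w7 <- buildLocoWeights(ss, excluded = 7)
  expect_false(any(as.data.frame(w7)$chromosome == 7))
  set <- buildLocoWeightSet(ss)
  expect_setequal(excludedChromosomes(set), 1:22)
  expect_error(buildLocoWeights(ss, excluded = 23), "1\\.\\.22")
})

test_that("ridge weights equal marginal-scaled weights under identity LD", {
  cfg <- tiny_config()
  sim <- simulateCohort(cfg)
  ss <- runGwas(sim$panel, sim$cohort$avSER)
  ids <- as.data.frame(ss)
  ids <- ids$variant_id[ids$chromosome != 3]
  ld_id <- identity_ld(ids, block_size = 2)
  wm <- as.data.frame(buildLocoWeights(ss, 3, method = "marginal"))
  wr <- as.data.frame(buildLocoWeights(ss, 3, method = "ridge",
                                       ld = ld_id))
  expect_equal(wm$weight, wr$weight, tolerance = 1e-8)
})

test_that("the inference design has the specified column count", {
  cfg <- simConfig(n_samples = 800, n_snps = 44, seed = 6)
  sim <- simulateCohort(cfg)
  pgs <- standardizePgs(sim$cohort$true_genetic_value)
  fit <- fitAoswModel(sim$cohort, pgs)
  expect_equal(fit$n_design_cols, 20)  # 10+3+1+2+1+1+2
  expect_equal(length(coef(fit$fit)), 21)  # + intercept
  ## applying the fit to its own training rows reproduces fitted values
  train <- sim$cohort[!sim$cohort$never_wearer &
                        !is.na(sim$cohort$AOSW), ]
  pred <- inferPhenotype(fit, train, pgs[!sim$cohort$never_wearer &
                                           !is.na(sim$cohort$AOSW)])
  expect_equal(unname(pred), unname(fitted(fit$fit)), tolerance = 1e-8)
})

test_that("a noiseless AOSW signal is recovered out of sample", {
  cfg <- simConfig(n_samples = 3000, n_snps = 44, aosw_sd = 0,
                   aosw_threshold = 100, seed = 14)  # everyone wears
  sim <- simulateCohort(cfg)
  co <- sim$cohort
  pgs <- standardizePgs(co$true_genetic_value)
  tr <- 1:1500
  te <- 1501:3000
  ## keep only rows clear of the AOSW clamp so AOSW is an exact monotone
  ## function of avSER
  ok_tr <- tr[co$AOSW[tr] > 5 & co$AOSW[tr] < co$Age[tr]]
  ok_te <- te[co$AOSW[te] > 5 & co$AOSW[te] < co$Age[te]]
  ## a noiseless fit legitimately triggers the perfect-fit warning
  fit <- suppressWarnings(fitAoswModel(co[ok_tr, ], pgs[ok_tr]))
  pred <- inferPhenotype(fit, co[ok_te, ], pgs[ok_te])
  expect_gt(cor(pred, co$avSER[ok_te]), 0.99)

  ## permuting AOSW destroys the information
  set.seed(1)
  co_perm <- co[ok_tr, ]
  co_perm$AOSW <- sample(co_perm$AOSW)
  fit_perm <- fitAoswModel(co_perm, pgs[ok_tr])
  co_perm_te <- co[ok_te, ]
  set.seed(2)
  co_perm_te$AOSW <- sample(co_perm_te$AOSW)
  pred_perm <- inferPhenotype(fit_perm, co_perm_te, pgs[ok_te])
  r2_perm <- cor(pred_perm, co$avSER[ok_te])^2
  ## baseline keeps every non-AOSW predictor, including the PGS
  dtr <- cbind(co[ok_tr, ], pgs = pgs[ok_tr])
  base <- lm(avSER ~ Age + Sex + EduYears + pgs, data = dtr)
  dte <- cbind(co[ok_te, ], pgs = pgs[ok_te])
  r2_base <- cor(predict(base, dte), co$avSER[ok_te])^2
  expect_lte(r2_perm, r2_base + 0.01)
})

test_that("inference adds covariate information beyond raw AOSW", {
  cfg <- simConfig(n_samples = 4000, n_snps = 44, seed = 15)
  sim <- simulateCohort(cfg)
  co <- sim$cohort
  pgs <- standardizePgs(co$true_genetic_value)
  tr <- 1:2000
  te <- which(!co$never_wearer & seq_len(nrow(co)) > 2000)
  fit <- fitAoswModel(co[tr, ], pgs[tr])
  pred <- inferPhenotype(fit, co[te, ], pgs[te])
  expect_gt(abs(cor(pred, co$avSER[te])),
            abs(cor(co$AOSW[te], co$avSER[te])))
})

test_that("LOCO assembly is a pure per-chromosome selection", {
  cfg <- simConfig(n_samples = 200, n_snps = 30, n_chromosomes = 3,
                   seed = 7)
  sim <- simulateCohort(cfg)
  runs <- lapply(1:3, function(k)
    runGwas(sim$panel, sim$cohort$avSER + 0.01 * k))
  out <- as.data.frame(assembleLocoGwas(runs, 1:3))
  expect_equal(nrow(out), 30)
  ## equals naive per-row lookup
  for (k in 1:3) {
    src <- as.data.frame(runs[[k]])
    src <- src[src$chromosome == k, ]
    got <- out[out$chromosome == k, ]
    expect_equal(got$beta, src$beta)
    expect_equal(got$se, src$se)
  }
  expect_error(assembleLocoGwas(runs[c(1, 1, 2)], c(1, 1, 2)),
               "duplicate")
  expect_error(assembleLocoGwas(runs[1:2], 1:2), "chromosome")
})

test_that("LOCO scores carry no information about the excluded chromosome", {
  cfg <- simConfig(n_samples = 1000, n_snps = 220, p_causal = 0.2,
                   ld_rho = 0, ld_block_size = 1, seed = 18)
  p <- simulatePanel(cfg)
  co <- simulatePhenotypes(p, cfg)
  ss <- runGwas(p, co$avSER)
  w1 <- locoWeights(buildLocoWeightSet(ss), 1)
  s1 <- scoreSamples(p, w1)
  ## genetic value contributed by chromosome 1 alone
  v <- variantInfo(p)
  chr1 <- v$chromosome == 1
  g1 <- colSums(dosageMatrix(p)[chr1, , drop = FALSE])
  ## the aggregate chr-1 dosage burden must be uncorrelated with the
  ## genome-minus-chr1 score
  expect_lt(abs(cor(s1, g1)), 2 / sqrt(1000) * 2)
})
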