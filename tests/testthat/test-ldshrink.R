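test_that("LD blocks have unit diagonals and match direct correlations", {
  cfg <- simConfig(n_samples = 500, n_snps = 30, n_chromosomes = 3,
                   ld_block_size = 3, ld_rho = 0.6, seed = 19)
  p <- simulatePanel(cfg)
  ld <- buildLdBlocks(p, 3)
  expect_equal(nBlocks(ld), 12)  # ceil(10/3) blocks per chromosome
  for (R in blockMatrices(ld))
    expect_equal(unname(diag(R)), rep(1, nrow(R)))
  ## 3-variant block equals the hand-computed correlation matrix
  G <- dosageMatrix(p)
  ids1 <- blockIds(ld)[[1]]
  idx <- match(ids1, variantInfo(p)$variant_id)
  hand <- matrix(1, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    xi <- G[idx[i], ]; xj <- G[idx[j], ]
    hand[i, j] <- sum((xi - mean(xi)) * (xj - mean(xj))) /
      sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
  }
  expect_equal(blockMatrices(ld)[[1]], hand, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("independent variants yield near-diagonal blocks", {
  cfg <- simConfig(n_samples = 5000, n_snps = 20, n_chromosomes = 2,
                   ld_rho = 0, ld_block_size = 10, seed = 20)
  ld <- buildLdBlocks(simulatePanel(cfg), 10)
  off <- unlist(lapply(blockMatrices(ld), function(R)
    R[upper.tri(R)]))
  expect_lt(max(abs(off)), 0.05)
})

test_that("Gibbs posterior means equal the infinitesimal closed form", {
  cfg <- simConfig(n_samples = 3000, n_snps = 100, n_chromosomes = 2,
                   ld_rho = 0, seed = 2)
  sim <- simulateCohort(cfg)
  ss <- runGwas(sim$panel, sim$cohort$avSER)
  ids <- variantInfo(sim$panel)$variant_id
  ld_id <- identity_ld(ids, block_size = 10)
  w <- gibbsGrid(ss, ld_id,
                 shrinkGrid(h2 = 0.3, p_causal = 1, sparse = FALSE,
                            n_iter = 100, burn_in = 20),
                 n_gwas = 3000)[[1]]
  df <- as.data.frame(w)
  ssd <- as.data.frame(ss)[match(df$variant_id,
                                 as.data.frame(ss)$variant_id), ]
  expected <- ssd$beta * (0.3 / 100) / (0.3 / 100 + 1 / 3000)
  expect_equal(df$weight, expected, tolerance = 1e-3)
  ## contraction: posterior means never exceed the marginal betas
  expect_true(all(abs(df$weight) <= abs(ssd$beta) + 1e-12))
})

test_that("single-SNP point-normal weight matches 1-D quadrature", {
  cfg <- simConfig(n_samples = 3000, n_snps = 44, seed = 2)
  sim <- simulateCohort(cfg)
  ss <- runGwas(sim$panel, sim$cohort$avSER)
  ssd <- as.data.frame(ss)
  for (j in c(1, 7)) {
    one <- SumStats(ssd[j, , drop = FALSE])
    ld1 <- identity_ld(ssd$variant_id[j],
                       chromosome = ssd$chromosome[j])
    w <- gibbsGrid(one, ld1,
                   shrinkGrid(h2 = 0.1, p_causal = 0.3, sparse = FALSE,
                              n_iter = 200, burn_in = 50),
                   n_gwas = 3000)[[1]]
    z <- ssd$beta[j] / ssd$se[j]
    r <- z / sqrt(3000 + z^2)
    q <- spikeSlabPosteriorMean(r, 3000, 0.1 / 0.3, 0.3)
    expect_equal(as.data.frame(w)$weight, q * ssd$beta[j] / r,
                 tolerance = 1e-3)
  }
})

test_that("sparse mode zeroes nearly all weights on a null simulation", {
  cfg <- simConfig(n_samples = 2000, n_snps = 220, h2 = 0, ld_rho = 0,
                   seed = 23)
  p <- simulatePanel(cfg)
  co <- simulatePhenotypes(p, cfg)
  ss <- runGwas(p, co$avSER)
  ld <- buildLdBlocks(p, 10)
  w <- gibbsGrid(ss, ld,
                 shrinkGrid(h2 = 0.3, p_causal = 1e-5, sparse = TRUE,
                            n_iter = 100, burn_in = 20))[[1]]
  expect_gte(mean(as.data.frame(w)$weight == 0), 0.99)
})

test_that("grid determinism: same seed gives identical weight lists", {
  cfg <- tiny_config()
  sim <- simulateCohort(cfg)
  ss <- runGwas(sim$panel, sim$cohort$avSER)
  ld <- buildLdBlocks(sim$panel, 2)
  g <- shrinkGrid(h2 = 0.2, p_causal = c(0.1, 1), sparse = TRUE,
                  n_iter = 50, burn_in = 10, seed = 5)
  w1 <- gibbsGrid(ss, ld, g)
  w2 <- gibbsGrid(ss, ld, g)
  for (i in seq_along(w1))
    expect_identical(as.data.frame(w1[[i]])$weight,
                     as.data.frame(w2[[i]])$weight)
})

test_that("clumping matches the brute-force greedy rule", {
  cfg <- simConfig(n_samples = 800, n_snps = 20, n_chromosomes = 2,
                   ld_block_size = 5, ld_rho = 0.7, seed = 24)
  sim <- simulateCohort(cfg)
  ss <- runGwas(sim$panel, sim$cohort$avSER)
  ld <- buildLdBlocks(sim$panel, 5)
  ssd <- as.data.frame(ss)
  for (r2m in c(0.1, 0.3)) for (pm in c(0.5, 1)) {
    got <- as.data.frame(clumpThreshold(ss, ld, r2m, pm))$variant_id
    expect_setequal(got, clump_bruteforce(ssd, ld, r2m, pm))
  }
  ## r2_max = 1, p_max = 1 retains everything with raw betas
  all_w <- as.data.frame(clumpThreshold(ss, ld, 1, 1))
  expect_equal(nrow(all_w), 20)
  expect_equal(all_w$weight,
               ssd$beta[match(all_w$variant_id, ssd$variant_id)])
})

test_that("perfectly correlated SNPs keep exactly one index", {
  G <- rbind(c(0, 1, 2, 1, 0, 2, 1, 1), c(0, 1, 2, 1, 0, 2, 1, 1))
  v <- data.frame(chromosome = 1L, position = 1:2,
                  variant_id = c("a", "b"), effect_allele = "A",
                  other_allele = "G", allele_frequency = rowMeans(G) / 2)
  p <- GenotypePanel(G, v, paste0("s", 1:8))
  ld <- buildLdBlocks(p, 2)
  ss <- make_sumstats(c(0.2, 0.2), c(0.05, 0.05), ids = c("a", "b"))
  kept <- as.data.frame(clumpThreshold(ss, ld, 0.9, 1))$variant_id
  expect_equal(kept, "a")  # equal p: first in genome order wins
})

test_that("scoring equals hand-computed dot products and is linear", {
  G <- matrix(c(0, 1, 2, 1,
                2, 0, 1, 1,
                1, 1, 0, 2), nrow = 3, byrow = TRUE)
  v <- data.frame(chromosome = 1L, position = 1:3,
                  variant_id = c("a", "b", "c"), effect_allele = "A",
                  other_allele = "G", allele_frequency = rowMeans(G) / 2)
  p <- GenotypePanel(G, v, paste0("s", 1:4))
  w <- WeightVector(data.frame(variant_id = c("a", "b", "c"),
                               chromosome = 1L, effect_allele = "A",
                               weight = c(0.5, -1, 2)))
  s <- scoreSamples(p, w)
  hand <- drop(t(G) %*% c(0.5, -1, 2))
  expect_equal(unname(s), hand, ignore_attr = TRUE)
  w2 <- WeightVector(data.frame(variant_id = c("a", "b", "c"),
                                chromosome = 1L, effect_allele = "A",
                                weight = 2 * c(0.5, -1, 2)))
  expect_equal(unname(scoreSamples(p, w2)), 2 * hand,
               ignore_attr = TRUE)
  ## flipped effect allele reflects the dosage
  wf <- WeightVector(data.frame(variant_id = "a", chromosome = 1L,
                                effect_allele = "G", weight = 1))
  expect_equal(unname(scoreSamples(p, wf)), 2 - G[1, ],
               ignore_attr = TRUE)
  ## all-zero weights, zero scores
  w0 <- WeightVector(data.frame(variant_id = c("a", "b"),
                                chromosome = 1L, effect_allele = "A",
                                weight = c(0, 0)))
  expect_true(all(scoreSamples(p, w0) == 0))
  ## zero overlap errors
  wx <- WeightVector(data.frame(variant_id = "zz", chromosome = 1L,
                                effect_allele = "A", weight = 1))
  expect_error(scoreSamples(p, wx), "overlap")
})

test_that("tuning selects the argmax and reports every grid cell", {
  cfg <- simConfig(n_samples = 1000, n_snps = 110, seed = 26)
  sim <- simulateCohort(cfg)
  ss <- runGwas(sim$panel, sim$cohort$avSER)
  ld <- buildLdBlocks(sim$panel, 10)
  g <- shrinkGrid(n_iter = 30, burn_in = 5, seed = 3)
  cands <- gibbsGrid(ss, ld, g)
  expect_equal(length(cands), 48)       # 4 x 6 x 2 cells
  tn <- tunePgs(cands, sim$panel, sim$cohort$avSER,
                gwasCovariates(sim$cohort))
  expect_equal(nrow(tn$report), 48)
  ## selection equals independently recomputed argmax
  r2 <- vapply(cands, function(w) {
    s <- scoreSamples(sim$panel, w)
    f1 <- lm(sim$cohort$avSER ~ s + gwasCovariates(sim$cohort))
    f0 <- lm(sim$cohort$avSER ~ gwasCovariates(sim$cohort))
    summary(f1)$adj.r.squared - summary(f0)$adj.r.squared
  }, numeric(1))
  expect_equal(tn$best_index, which.max(r2))
  expect_error(tunePgs(list(), sim$panel, sim$cohort$avSER), "empty")
})
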