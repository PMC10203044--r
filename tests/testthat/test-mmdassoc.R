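test_that("tranche partition keeps families together and sizes balanced", {
  cfg <- simConfig(n_samples = 1000, n_snps = 44, n_families = 1000,
                   seed = 3)
  sim <- simulateCohort(cfg)
  part <- partitionTranches(sim$cohort, k = 5, seed = 1)
  expect_equal(unname(part$sizes), rep(200, 5))  # all singletons

  ## a 10-member family stays together
  co <- sim$cohort
  co$family_id[1:10] <- "famBIG"
  part2 <- suppressWarnings(partitionTranches(co, k = 5, seed = 1))
  expect_equal(length(unique(part2$tranche[1:10])), 1)
  ## every family wholly within one tranche
  expect_true(all(vapply(split(part2$tranche, co$family_id),
                         function(x) length(unique(x)) == 1,
                         logical(1))))
})

test_that("greedy assignment matches brute-force smallest-bin replay", {
  fams <- rep(paste0("f", 1:12), times = c(5, 1, 3, 2, 2, 4, 1, 1, 3,
                                           2, 5, 1))
  co <- data.frame(family_id = fams)
  part <- partitionTranches(co, k = 3, seed = 7)
  ## replay: same seeded shuffle, assign each family to smallest bin
  fam_idx <- split(seq_len(nrow(co)), co$family_id)
  set.seed(7)
  ord <- sample(seq_along(fam_idx))
  bins <- numeric(3)
  expect_tranche <- integer(nrow(co))
  for (fi in ord) {
    t <- which.min(bins)
    expect_tranche[fam_idx[[fi]]] <- t
    bins[t] <- bins[t] + length(fam_idx[[fi]])
  }
  expect_equal(part$tranche, expect_tranche)
})

test_that("worse-eye grading matches the exhaustive truth table", {
  lv <- c("C0", "C2", "C3", "C4")
  pairs <- expand.grid(r = lv, l = lv, stringsAsFactors = FALSE)
  got <- worseEye(pairs$r, pairs$l)
  truth <- apply(pairs, 1, function(x)
    lv[max(match(x[1], lv), match(x[2], lv))])
  expect_equal(got, unname(truth))
  ## single-eye participants use the available eye
  expect_equal(worseEye(c(NA, "C3"), c("C2", NA)), c("C2", "C3"))
  expect_error(worseEye(NA_character_, NA_character_), "missing")
  expect_error(worseEye("C1", "C0"), "grades")
})

test_that("severe indicator follows the C3/C4 rule", {
  expect_equal(severeIndicator(c("C3", "C4")), c("severe", "severe"))
  expect_equal(severeIndicator(c("C0", "C2")), c("normal", "normal"))
  expect_error(severeIndicator("C9"), "unknown")
  ## monotonicity of severe(worseEye(.)): upgrading an eye never
  ## downgrades the participant
  lv <- c("C0", "C2", "C3", "C4")
  for (r in lv) for (l in lv) for (ri in which(lv == r):4) {
    before <- severeIndicator(worseEye(r, l))
    after <- severeIndicator(worseEye(lv[ri], l))
    expect_false(before == "severe" && after == "normal")
  }
})

test_that("Firth fit is finite under separation and matches glm otherwise", {
  ## quasi-separated 20-row toy
  x <- c(rnorm(10, -2, 0.3), rnorm(10, 2, 0.3))
  y <- rep(c(0, 1), each = 10)
  X <- cbind(1, x)
  g <- suppressWarnings(glm.fit(X, y, family = binomial()))
  f <- firthLogistic(X, y)
  expect_gt(abs(g$coefficients[2]), 10)    # standard fit diverges
  expect_lt(abs(f$coefficients[2]), 10)    # Firth stays finite
  expect_true(f$converged)

  ## well-separated large-n fits agree within 2% relative
  set.seed(51)
  n <- 20000
  x2 <- rnorm(n)
  y2 <- rbinom(n, 1, plogis(-2 + 0.5 * x2))
  X2 <- cbind(1, x2)
  g2 <- glm.fit(X2, y2, family = binomial())
  f2 <- firthLogistic(X2, y2)
  expect_lt(abs(f2$coefficients[2] - g2$coefficients[2]) /
              abs(g2$coefficients[2]), 0.02)
})

test_that("logisticAssoc reports ORs on the stated scales", {
  set.seed(52)
  n <- 30000
  ser <- rnorm(n, -0.3, 2.7)
  pgs <- rnorm(n)
  eta <- -6.3 + log(1.3) * (-ser) + log(1.4) * pgs
  y <- rbinom(n, 1, plogis(eta))
  res <- logisticAssoc(y, pgs, ser, include_ser = TRUE)
  expect_lt(abs(res$or_ser - 1.3), 0.1)
  expect_lt(abs(res$or_pgs - 1.4), 0.15)
  expect_true(res$ci_pgs[1] <= res$or_pgs &&
                res$or_pgs <= res$ci_pgs[2])
  expect_equal(res$n_cases + res$n_controls, n)
  ## Firth route gives nearly identical answers at this n
  resf <- logisticAssoc(y, pgs, ser, include_ser = TRUE, firth = TRUE)
  expect_lt(abs(resf$or_pgs - res$or_pgs) / res$or_pgs, 0.02)
  expect_error(logisticAssoc(rep(1, 10), rnorm(10), rnorm(10)),
               "classes")
})

test_that("cross-fitting is structurally independent of the held tranche", {
  cfg <- simConfig(n_samples = 600, n_snps = 110, n_families = 600,
                   seed = 55)
  sim <- simulateCohort(cfg)
  part <- partitionTranches(sim$cohort, k = 3, seed = 2)
  sc <- crossfitPgs(sim$panel, sim$cohort, part, method = "marginal")
  ## permuting phenotypes within tranche 1 leaves tranche-1 scores alone
  co2 <- sim$cohort
  i1 <- which(part$tranche == 1)
  set.seed(9)
  co2$avSER[i1] <- sample(co2$avSER[i1])
  sc2 <- crossfitPgs(sim$panel, co2, part, method = "marginal")
  expect_equal(sc[i1], sc2[i1])
  ## but other tranches' scores change (their training data changed)
  expect_false(isTRUE(all.equal(sc[-i1], sc2[-i1])))

  ## k = 1 is forbidden
  part1 <- list(tranche = rep(1L, 600), k = 1, sizes = 600,
                family_id = sim$cohort$family_id)
  class(part1) <- "TranchePartition"
  expect_error(crossfitPgs(sim$panel, sim$cohort, part1), "forbidden")
})

test_that("in-sample scoring is inflated relative to cross-fitting", {
  cfg <- simConfig(n_samples = 900, n_snps = 220, h2 = 0, seed = 56)
  sim <- simulateCohort(cfg)
  part <- partitionTranches(sim$cohort, k = 3, seed = 3)
  cf <- crossfitPgs(sim$panel, sim$cohort, part, method = "marginal")
  ## naive in-sample score: weights from a GWAS on everyone
  ss <- runGwas(sim$panel, sim$cohort$avSER)
  df <- as.data.frame(ss)
  w <- WeightVector(data.frame(variant_id = df$variant_id,
                               chromosome = df$chromosome,
                               effect_allele = df$effect_allele,
                               weight = df$beta))
  naive <- scoreSamples(sim$panel, w)
  ## under the null the cross-fit correlation is near zero, the naive one
  ## is mechanically inflated
  expect_gt(cor(naive, sim$cohort$avSER),
            abs(cor(cf, sim$cohort$avSER)) + 0.1)
})

test_that("prevalence arithmetic matches the published counts", {
  expect_equal(prevalencePct(169, 75869, 2), 0.22)
  expect_equal(prevalencePct(49, 75869, 2), 0.06)
  expect_equal(prevalencePct(3, 1227, 1), 0.2)
  expect_equal(prevalencePct(0, 100), 0)
  expect_error(prevalencePct(1, 0), "positive")
  expect_error(prevalencePct(5, 2), "0..n")
})
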