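test_that("refraction categories are boundary-inclusive and nested", {
  f <- classifyRefraction(c(-6, -0.49, 3, -5, -3, -0.5, 0))
  expect_true(all(unlist(f[1, c("hm6", "hm5", "moderate_myopia",
                                "myopia")])))
  expect_false(any(unlist(f[2, ])))
  expect_true(f$moderate_hyperopia[3])
  expect_false(f$myopia[3])
  expect_true(f$hm5[4]); expect_false(f$hm6[4])
  expect_true(f$moderate_myopia[5]); expect_false(f$hm5[5])
  expect_true(f$myopia[6]); expect_false(f$moderate_myopia[6])
  ## nesting over a grid of values
  g <- classifyRefraction(seq(-10, 5, by = 0.25))
  expect_true(all(!g$hm6 | g$hm5))
  expect_true(all(!g$hm5 | g$moderate_myopia))
  expect_true(all(!g$moderate_myopia | g$myopia))
  expect_false(any(g$moderate_hyperopia & g$myopia))
  expect_error(classifyRefraction(c(1, NA)), "finite")
})

test_that("standardization is exact within groups", {
  set.seed(31)
  x <- rnorm(100, 5, 3)
  grp <- rep(c("a", "b"), 50)
  z <- standardizePgs(x, grp)
  for (g in c("a", "b")) {
    expect_lt(abs(mean(z[grp == g])), 1e-12)
    expect_equal(sd(z[grp == g]), 1)
  }
  ## hand-standardized two-group toy
  toy <- c(1, 2, 3, 10, 20, 30)
  gt <- rep(c("a", "b"), each = 3)
  expect_equal(standardizePgs(toy, gt),
               c((c(1, 2, 3) - 2) / 1, (c(10, 20, 30) - 20) / 10))
  ## single group equals the global z-score
  expect_equal(standardizePgs(x), (x - mean(x)) / sd(x))
  expect_error(standardizePgs(c(1, 1, 2), c("a", "a", "b")), "group")
})

test_that("incremental R2 of a perfect predictor is 1", {
  set.seed(32)
  y <- rnorm(200)
  out <- incrementalR2(y, y, n_boot = 50, seed = 1)
  expect_equal(out$point, 1)
  expect_equal(out$estimate, 1)
})

test_that("incremental R2 is invariant to affine rescaling of the score", {
  set.seed(33)
  y <- rnorm(300)
  s <- 0.5 * y + rnorm(300)
  covar <- cbind(rnorm(300))
  a <- incrementalR2(y, s, covar, n_boot = 100, seed = 7)
  b <- incrementalR2(y, 3 * s - 10, covar, n_boot = 100, seed = 7)
  expect_equal(a$estimate, b$estimate, tolerance = 1e-10)
  expect_equal(a$ci, b$ci, tolerance = 1e-10)
})

test_that("noise-score CI covers zero in at least 90% of replicates", {
  hits <- vapply(1:20, function(r) {
    set.seed(400 + r)
    y <- rnorm(2000)
    s <- rnorm(2000)
    ci <- incrementalR2(y, s, n_boot = 400, seed = r)$ci
    ci[1] <= 0 && ci[2] >= 0
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("bootstrap CIs are seeded and shrink with sample size", {
  set.seed(35)
  y <- rnorm(5000); s <- 0.4 * y + rnorm(5000)
  a1 <- incrementalR2(y[1:500], s[1:500], n_boot = 300, seed = 9)
  a2 <- incrementalR2(y[1:500], s[1:500], n_boot = 300, seed = 9)
  expect_identical(a1, a2)
  big <- incrementalR2(y, s, n_boot = 300, seed = 9)
  expect_lt(diff(big$ci), diff(a1$ci))
})

test_that("AUROC equals exhaustive pair counting, including ties", {
  ## 6-observation toy with a tie
  lab <- c(1, 1, 1, 0, 0, 0)
  sc <- c(3, 2, 1, 2, 0, -1)
  expect_equal(aurocCI(lab, sc, n_boot = 10)$auroc,
               auroc_bruteforce(lab, sc))
  ## all n <= 30 instances under a seeded sweep
  set.seed(36)
  for (rep in 1:25) {
    n <- sample(4:30, 1)
    lab <- c(1, 0, rbinom(n - 2, 1, 0.5))
    sc <- sample(round(rnorm(n), 1), n)  # duplicates induce ties
    expect_equal(aurocCI(lab, sc, n_boot = 2)$auroc,
                 auroc_bruteforce(lab, sc))
  }
  ## independent cross-check against pROC's implementation
  skip_if_not_installed("pROC")
  set.seed(37)
  lab <- rbinom(200, 1, 0.3); sc <- rnorm(200) + lab
  expect_equal(aurocCI(lab, sc, n_boot = 2)$auroc,
               as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                              direction = "<"))))
})

test_that("AUROC extremes behave: perfect separation and chance level", {
  lab <- rep(c(1, 0), each = 50)
  expect_equal(aurocCI(lab, c(rnorm(50) + 100, rnorm(50)),
                       n_boot = 10)$auroc, 1.0)
  set.seed(38)
  lab2 <- rbinom(5000, 1, 0.5)
  expect_lt(abs(aurocCI(lab2, rnorm(5000), n_boot = 10)$auroc - 0.5),
            0.02)
  expect_error(aurocCI(rep(1, 10), rnorm(10)), "both classes")
})

test_that("ROC comparison is calibrated and detects real differences", {
  set.seed(39)
  y <- rbinom(800, 1, 0.3)
  s1 <- y + rnorm(800)
  s2 <- y + rnorm(800, 0, 4)     # much weaker
  cmp <- compareAuroc(y, s1, s2, n_boot = 300, seed = 2)
  expect_lt(cmp$p, 0.01)
  expect_gt(cmp$auroc1, cmp$auroc2)
  cmp_same <- compareAuroc(y, s1, s1, n_boot = 300, seed = 2)
  expect_equal(cmp_same$p, 1)
})

test_that("tail OR equals the direct 2x2 formula", {
  ## enriched toy table: a=10, b=90 in tail; c=10, d=890 outside
  z <- c(seq(-3, -2, length.out = 100), seq(0, 3, length.out = 900))
  lab <- c(rep(1, 10), rep(0, 90), rep(1, 10), rep(0, 890))
  out <- tailOr(z, lab, tail = 0.1, side = "low")
  expect_equal(out$table, c(a = 10, b = 90, c = 10, d = 890))
  expect_equal(out$or, (10 * 890) / (90 * 10), tolerance = 1e-12)
  ## side symmetry: high tail on -z equals low tail on z
  out2 <- tailOr(-z, lab, tail = 0.1, side = "high")
  expect_equal(out2$or, out$or)
  ## independent scores: CI covers 1 in most replicates
  hits <- vapply(1:20, function(r) {
    set.seed(500 + r)
    zz <- rnorm(2000); ll <- rbinom(2000, 1, 0.1)
    ci <- tailOr(zz, ll, 0.1)$ci
    ci[1] <= 1 && ci[2] >= 1
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("decile risk conserves cases and tracks a liability model", {
  set.seed(41)
  z <- rnorm(10000)
  liab <- -z + rnorm(10000)            # low score = high liability
  lab <- as.integer(liab > quantile(liab, 0.95))
  out <- decileRisk(z, lab)
  expect_equal(sum(out$table$cases), sum(lab))
  expect_equal(sum(out$table$n), 10000)
  ## monotone decrease of prevalence across deciles
  ct <- suppressWarnings(cor.test(out$table$decile,
                                  out$table$prevalence,
                                  method = "spearman"))
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
  ## independent scores: flat prevalence near the overall rate
  set.seed(42)
  lab2 <- rbinom(10000, 1, 0.1)
  out2 <- decileRisk(rnorm(10000), lab2)
  expect_true(all(abs(out2$table$prevalence - 0.1) < 0.04))
})

test_that("relative change reproduces the published arithmetic", {
  expect_equal(round(relativeChange(0.190, 0.112, "improvement")), 70)
  expect_equal(round(relativeChange(0.020, 0.190, "decrease")), 89)
  expect_equal(relativeChange(0.15, 0.15), 0)
  expect_error(relativeChange(0.1, 0), "positive")
})

test_that("trajectory bands stratify, filter, and order correctly", {
  set.seed(43)
  ages <- c(7, 10, 11, 12, 15)
  n <- 600
  z <- rnorm(n)
  ## slope depends on the score: lower score, faster myopia progression
  sm <- outer(rep(1, n), rep(0, 5)) +
    outer(0.3 * z, ages - 7) / 8 + matrix(rnorm(n * 5, 0, 0.1), n, 5)
  sm[1:50, 4:5] <- NA                      # only 3 visits: still included
  sm[51:100, 2:5] <- NA                    # 1 visit: excluded
  out <- trajectoryBands(ages, sm, z)
  expect_equal(sum(out$n[out$age == 7]), n - 50)
  final <- out[out$age == 15, ]
  expect_true(all(diff(final$mean_avSER) > 0))  # ordered at final age
  ## identical scores put everyone in one band
  out2 <- trajectoryBands(ages, sm, rep(0, n))
  expect_equal(length(unique(out2$band)), 1)
  expect_error(trajectoryBands(ages, sm[1:2, ] * NA, z[1:2]),
               "enough measurements")
})
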