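## Synthetic cohort generators. Every generator is a pure function of
## (config, seed): a fixed per-stage child seed (master seed + offset) is
## set on entry.

.child_seed <- function(config, offset) {
  s <- (as.integer(config@seed) + offset) %% .Machine$integer.max
  set.seed(s)
  invisible(s)
}

## even split of n_snps over chromosomes, every chromosome non-empty
.chromosome_counts <- function(n_snps, n_chrom) {
  base <- n_snps %/% n_chrom
  extra <- n_snps %% n_chrom
  counts <- rep(base, n_chrom)
  if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1
  counts
}

#' Simulate a genotype panel with block LD
#'
#' Dosages are drawn under Hardy-Weinberg equilibrium through a Gaussian
#' copula: per haplotype, latent variables follow an AR(1) process with
#' correlation `ld_rho` within each block of `ld_block_size` adjacent SNPs
#' (blocks never span chromosomes); an allele is carried when the latent
#' variable falls below the MAF quantile, and the dosage is the sum over
#' the two haplotypes. The induced dosage correlation is smaller than
#' `ld_rho` (copula attenuation); [copulaDosageCorrelation()] gives a
#' Monte-Carlo estimate of the induced value.
#'
#' @param config a [SimConfig-class].
#' @return a [GenotypePanel-class]; `allele_frequency` in the variant
#'   metadata is the realized dosage mean / 2.
#' @export
simulatePanel <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  .child_seed(config, 1L)
  n <- config@n_samples
  m <- config@n_snps
  counts <- .chromosome_counts(m, config@n_chromosomes)
  mafs <- runif(m, config@maf_low, config@maf_high)
  rho <- config@ld_rho
  bs <- config@ld_block_size

  dos <- matrix(0, nrow = m, ncol = n)
  idx <- 0L
  for (chr in seq_along(counts)) {
    left <- counts[chr]
    while (left > 0) {
      b <- min(bs, left)
      thr <- qnorm(mafs[idx + seq_len(b)])
      block <- matrix(0L, nrow = n, ncol = b)
      for (h in 1:2) {
        z <- matrix(rnorm(n * b), nrow = n, ncol = b)
        if (b > 1 && rho > 0) {
          for (j in 2:b) z[, j] <- rho * z[, j - 1] +
              sqrt(1 - rho^2) * z[, j]
        }
        block <- block + (z < rep(thr, each = n))
      }
      dos[idx + seq_len(b), ] <- t(block)
      idx <- idx + b
      left <- left - b
    }
  }

  variants <- data.frame(
    chromosome = rep(seq_along(counts), counts),
    position = unlist(lapply(counts, seq_len)) * 1000L,
    variant_id = sprintf("snp%d_%d", rep(seq_along(counts), counts),
                         unlist(lapply(counts, seq_len))),
    effect_allele = "A", other_allele = "G",
    allele_frequency = rowMeans(dos) / 2,
    stringsAsFactors = FALSE
  )
  GenotypePanel(dos, variants, sprintf("id%06d", seq_len(n)))
}

#' Monte-Carlo estimate of the copula-induced adjacent-dosage correlation
#'
#' Independent oracle for the LD structure of [simulatePanel()]: simulates
#' a single two-SNP block at large n and returns the empirical dosage
#' correlation induced by latent correlation `rho` at allele frequency
#' `maf`.
#'
#' @param rho latent AR(1) correlation.
#' @param maf allele frequency (both SNPs).
#' @param n_mc Monte-Carlo sample size.
#' @param seed RNG seed.
#' @export
copulaDosageCorrelation <- function(rho, maf, n_mc = 2e5, seed = 1) {
  set.seed(seed)
  thr <- qnorm(maf)
  d1 <- d2 <- numeric(n_mc)
  for (h in 1:2) {
    z1 <- rnorm(n_mc)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n_mc)
    d1 <- d1 + (z1 < thr)
    d2 <- d2 + (z2 < thr)
  }
  cor(d1, d2)
}

#' Simulate phenotypes and covariates
#'
#' avSER = genetic value + covariate terms + Gaussian noise. A random
#' `p_causal` fraction of SNPs receives normal effects, rescaled so the
#' sample genetic variance equals `h2 * ser_sd^2`; noise variance is set
#' so the total trait variance equals `ser_sd^2` (covariate contribution
#' included). Age ~ N(58, 8) truncated to \[40, 70\], Sex ~ Bernoulli(0.55)
#' (1 = female), EduYears is 21 for degree holders (35%) else uniform on
#' 14..19, genotyping array ~ Bernoulli(0.1), PCs are exchangeable noise or
#' computed from the panel per `pc_mode`.
#'
#' `true_genetic_value` retains the genetic component for testing; when
#' `h2 = 0` the trait carries no genetic signal and the column stores the
#' standardized raw genetic score so diagnostic correlations remain
#' defined.
#'
#' @param panel a [GenotypePanel-class] from [simulatePanel()].
#' @param config the same [SimConfig-class].
#' @return a cohort data.frame (one row per participant).
#' @export
simulatePhenotypes <- function(panel, config) {
  stopifnot(is(panel, "GenotypePanel"))
  if (nVariants(panel) != config@n_snps ||
      nSamples(panel) != config@n_samples)
    stop("panel dimensions do not match config")
  .child_seed(config, 2L)
  n <- nSamples(panel)
  m <- nVariants(panel)
  X <- dosageMatrix(panel)

  n_causal <- max(1L, round(config@p_causal * m))
  causal <- sort(sample.int(m, n_causal))
  b <- rnorm(n_causal)
  g_raw <- drop(crossprod(X[causal, , drop = FALSE], b))
  vg <- var(g_raw)
  sigma2 <- config@ser_sd^2
  if (config@h2 > 0 && vg > 0) {
    g <- (g_raw - mean(g_raw)) * sqrt(config@h2 * sigma2 / vg)
    tgv <- g
  } else {
    g <- rep(0, n)
    tgv <- if (vg > 0) (g_raw - mean(g_raw)) / sqrt(vg) else rep(0, n)
  }

  Age <- pmin(pmax(rnorm(n, 58, 8), 40), 70)
  Sex <- rbinom(n, 1, 0.55)
  degree <- rbinom(n, 1, 0.35)
  EduYears <- ifelse(degree == 1, 21, sample(14:19, n, replace = TRUE))
  array <- rbinom(n, 1, 0.1)

  cov_term <- config@beta_age * Age + config@beta_sex * Sex +
    config@beta_edu * EduYears
  cov_term <- cov_term - mean(cov_term)
  noise_var <- sigma2 * (1 - config@h2) - var(cov_term)
  if (noise_var < 0)
    stop("covariate effects too large for ser_sd at this h2")
  avSER <- config@ser_mean + g + cov_term + rnorm(n, 0, sqrt(noise_var))

  pcs <- if (config@pc_mode == "computed") {
    computePcs(panel, 10)
  } else {
    matrix(rnorm(n * 10), n, 10)
  }
  colnames(pcs) <- paste0("PC", 1:10)

  data.frame(
    sample_id = sampleIds(panel),
    avSER = avSER, Age = Age, Sex = Sex, EduYears = EduYears,
    array = array, pcs,
    ancestry = "EUR",
    true_genetic_value = tgv,
    stringsAsFactors = FALSE
  )
}

#' Simulate age of onset of spectacle wear
#'
#' Monotone-in-myopia onset model: expected onset age is
#' `aosw_intercept + aosw_slope * avSER` (more negative avSER, earlier
#' onset) plus Gaussian noise. Participants whose avSER exceeds
#' `aosw_threshold` or whose modeled onset exceeds their current age are
#' flagged never-wearers (AOSW = NA); otherwise AOSW is clamped to
#' \[5, Age\].
#'
#' @param cohort cohort data.frame with `avSER` and `Age`.
#' @param config a [SimConfig-class].
#' @return the cohort with `AOSW` and `never_wearer` columns.
#' @export
simulateAosw <- function(cohort, config) {
  if (!"avSER" %in% names(cohort)) stop("cohort lacks avSER")
  .child_seed(config, 3L)
  onset <- config@aosw_intercept + config@aosw_slope * cohort$avSER +
    rnorm(nrow(cohort), 0, config@aosw_sd)
  never <- cohort$avSER > config@aosw_threshold | onset > cohort$Age
  aosw <- pmin(pmax(onset, 5), cohort$Age)
  aosw[never] <- NA_real_
  cohort$AOSW <- aosw
  cohort$never_wearer <- never
  cohort
}

#' Simulate per-eye META-PM grades
#'
#' Per-eye severe-MMD indicators are Bernoulli with
#' `logit(p) = mmd_intercept + mmd_beta_ser * (-avSER) +
#' mmd_beta_direct * pgs`; severe eyes are graded C3 with probability
#' `mmd_c3_frac` (else C4), non-severe eyes C2 with probability
#' `mmd_c2_frac` (else C0). The default `mmd_beta_direct = 0` encodes full
#' mediation: given avSER, grades are independent of the PGS.
#'
#' @param cohort cohort data.frame with `avSER`.
#' @param config a [SimConfig-class].
#' @param pgs per-sample score (preferably standardized); NULL is treated
#'   as zero.
#' @return the cohort with `eye_grade_right` and `eye_grade_left` columns.
#' @export
simulateMmd <- function(cohort, config, pgs = NULL) {
  if (!"avSER" %in% names(cohort)) stop("cohort lacks avSER")
  if (is.null(pgs)) pgs <- rep(0, nrow(cohort))
  stopifnot(length(pgs) == nrow(cohort))
  .child_seed(config, 4L)
  eta <- config@mmd_intercept + config@mmd_beta_ser * (-cohort$avSER) +
    config@mmd_beta_direct * pgs
  p <- plogis(eta)
  draw_eye <- function() {
    severe <- rbinom(length(p), 1, p) == 1
    g <- character(length(p))
    g[severe] <- ifelse(runif(sum(severe)) < config@mmd_c3_frac,
                        "C3", "C4")
    g[!severe] <- ifelse(runif(sum(!severe)) < config@mmd_c2_frac,
                         "C2", "C0")
    g
  }
  cohort$eye_grade_right <- draw_eye()
  cohort$eye_grade_left <- draw_eye()
  cohort
}

#' Assign family clusters
#'
#' When `n_families` is set, participants are partitioned into exactly
#' that many families (singletons plus randomly allocated extras);
#' otherwise family sizes are drawn i.i.d. from `family_size_probs` until
#' the cohort is covered (the last family is trimmed). Membership is
#' randomized.
#'
#' @param cohort cohort data.frame.
#' @param config a [SimConfig-class].
#' @return the cohort with a `family_id` column.
#' @export
assignFamilies <- function(cohort, config) {
  n <- nrow(cohort)
  .child_seed(config, 5L)
  if (!is.na(config@n_families)) {
    k <- as.integer(config@n_families)
    if (k > n) stop("n_families exceeds number of participants")
    sizes <- rep(1L, k)
    if (n > k) {
      extra <- table(sample.int(k, n - k, replace = TRUE))
      sizes[as.integer(names(extra))] <-
        sizes[as.integer(names(extra))] + as.integer(extra)
    }
  } else {
    pr <- config@family_size_probs / sum(config@family_size_probs)
    sz <- as.integer(names(pr))
    sizes <- integer(0)
    while (sum(sizes) < n) {
      sizes <- c(sizes, sample(sz, max(16, ceiling(n / mean(sz))),
                               replace = TRUE, prob = pr))
    }
    keep <- which(cumsum(sizes) >= n)[1]
    sizes <- sizes[seq_len(keep)]
    sizes[keep] <- sizes[keep] - (sum(sizes) - n)
    sizes <- sizes[sizes > 0]
  }
  fam <- rep(seq_along(sizes), sizes)
  cohort$family_id <- sprintf("fam%05d", fam[sample.int(n)])
  cohort
}

#' Simulate a complete cohort
#'
#' Convenience wrapper: panel, phenotypes, AOSW and families in one call.
#'
#' @param config a [SimConfig-class].
#' @return list with elements `panel` and `cohort`.
#' @export
simulateCohort <- function(config) {
  panel <- simulatePanel(config)
  cohort <- simulatePhenotypes(panel, config)
  cohort <- simulateAosw(cohort, config)
  cohort <- assignFamilies(cohort, config)
  list(panel = panel, cohort = cohort)
}
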