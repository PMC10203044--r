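## End-to-end orchestration: simulate -> GWAS -> LOCO AOSW-inferred GWAS
## -> meta-analysis (with two-stage union) -> shrinkage -> tuning ->
## evaluation -> cross-fitted MMD models. Stages communicate only through
## the returned bundle; the whole run is a pure function of
## (config, arguments).

#' Run the full pipeline on one synthetic study
#'
#' Emulates the real study design at desk scale: the cohort is split into
#' a base avSER GWAS sample, an AOSW-model sample, an AOSW-inferred GWAS
#' sample, a tuning sample and a test sample. Optional external cohorts
#' (fresh draws from the same configuration, standing in for independent
#' consortium summary statistics) enter the meta-analysis; a random
#' fraction of their variants is withheld to exercise the two-stage union
#' assembly. Shrinkage candidates from the Gibbs grid are tuned on the
#' tuning sample and evaluated on the test sample against a
#' clumping+thresholding baseline; the cross-fitted PGS feeds nested
#' logistic models of severe MMD.
#'
#' @param config a [SimConfig-class].
#' @param splits named fractions (gwas, model, aosw_gwas, tuning, test)
#'   summing to <= 1.
#' @param grid a [ShrinkGrid-class].
#' @param include_loco include the AOSW-inferred GWAS in the
#'   meta-analysis?
#' @param n_external number of external synthetic GWAS cohorts (0 to
#'   disable).
#' @param external_missing_frac fraction of variants withheld from the
#'   external cohorts (exercises the union assembly).
#' @param r2_max,p_max clumping baseline thresholds.
#' @param n_boot bootstrap replicates for evaluation.
#' @param mmd run the MMD stage?
#' @param loco_h2 assumed heritability for the LOCO predictive weights.
#' @return a report bundle (list).
#' @export
runPipeline <- function(config = simConfig(),
                        splits = c(gwas = 0.30, model = 0.20,
                                   aosw_gwas = 0.25, tuning = 0.10,
                                   test = 0.15),
                        grid = shrinkGrid(n_iter = 300, burn_in = 60,
                                          seed = config@seed),
                        include_loco = TRUE, n_external = 2,
                        external_missing_frac = 0.05,
                        r2_max = 0.5, p_max = 0.1,
                        n_boot = 200, mmd = TRUE, loco_h2 = 0.3) {
  stopifnot(sum(splits) <= 1 + 1e-9)
  sim <- simulateCohort(config)
  panel <- sim$panel
  cohort <- sim$cohort
  n <- nrow(cohort)

  set.seed(config@seed + 10L)
  idx <- sample.int(n)
  sizes <- floor(splits * n)
  groups <- rep(names(splits), sizes)
  part <- split(idx[seq_along(groups)], groups)

  cov_of <- function(i) gwasCovariates(cohort[i, , drop = FALSE])
  ss_avser <- runGwas(panel[, part$gwas], cohort$avSER[part$gwas],
                      cov_of(part$gwas))

  ss_aosw <- NULL
  if (include_loco) {
    locoset <- buildLocoWeightSet(ss_avser, method = "marginal",
                                  h2 = loco_h2)
    runs <- list()
    excl <- excludedChromosomes(locoset)
    for (k in excl) {
      w <- locoWeights(locoset, k)
      pgs_model <- scoreSamples(panel[, part$model], w)
      fit <- fitAoswModel(cohort[part$model, , drop = FALSE], pgs_model)
      pgs_infer <- scoreSamples(panel[, part$aosw_gwas], w)
      inferred <- inferPhenotype(fit, cohort[part$aosw_gwas, ,
                                             drop = FALSE], pgs_infer)
      ok <- which(!is.na(inferred))
      rows <- part$aosw_gwas[ok]
      runs[[as.character(k)]] <- runGwas(panel[, rows], inferred[ok],
                                         cov_of(rows))
    }
    ss_aosw <- assembleLocoGwas(runs, excl)
  }

  ukb <- if (include_loco) list(avSER = ss_avser, aosw = ss_aosw)
         else list(avSER = ss_avser)
  externals <- list()
  if (n_external > 0) {
    for (e in seq_len(n_external)) {
      cfg_e <- config
      cfg_e@seed <- config@seed + 100L * e
      panel_e <- simulatePanel(cfg_e)
      cohort_e <- simulatePhenotypes(panel_e, cfg_e)
      ss_e <- runGwas(panel_e, cohort_e$avSER, gwasCovariates(cohort_e))
      externals[[paste0("external", e)]] <- ss_e
    }
    ## withhold a variant subset from the externals (two-stage union)
    set.seed(config@seed + 20L)
    all_ids <- as.data.frame(ss_avser)$variant_id
    miss_ids <- sample(all_ids,
                       floor(external_missing_frac * length(all_ids)))
    externals <- lapply(externals, function(s) {
      d <- as.data.frame(s)
      SumStats(d[!d$variant_id %in% miss_ids, , drop = FALSE])
    })
  }

  if (length(externals)) {
    meta_full <- mtagMeta(alignAlleles(c(ukb, externals)))
    if (length(ukb) > 1) {
      meta_subset <- mtagMeta(alignAlleles(ukb))
    } else {
      meta_subset <- ukb[[1]]
    }
    only_ids <- setdiff(as.data.frame(meta_subset)$variant_id,
                        as.data.frame(meta_full)$variant_id)
    meta_ss <- assembleUnion(meta_full, meta_subset, only_ids)
  } else if (length(ukb) > 1) {
    meta_ss <- mtagMeta(alignAlleles(ukb))
  } else {
    meta_ss <- ukb[[1]]
  }

  ld <- buildLdBlocks(panel, config@ld_block_size)
  cands <- gibbsGrid(meta_ss, ld, grid)
  tuned <- tunePgs(cands, panel[, part$tuning],
                   cohort$avSER[part$tuning], cov_of(part$tuning))
  baseline <- clumpThreshold(meta_ss, ld, r2_max = r2_max, p_max = p_max)

  test_idx <- part$test
  score_test <- scoreSamples(panel[, test_idx], tuned$best)
  base_test <- scoreSamples(panel[, test_idx], baseline)
  cov_test <- cov_of(test_idx)
  eval_report <- evaluatePgs(cohort$avSER[test_idx], score_test,
                             cov_test, n_boot = n_boot,
                             seed = config@seed + 30L)
  baseline_r2 <- .incremental_r2_point(cohort$avSER[test_idx],
                                       base_test, cov_test)

  mmd_out <- NULL
  if (mmd) {
    partn <- partitionTranches(cohort, k = 5, seed = config@seed + 40L)
    cf <- crossfitPgs(panel, cohort, partn,
                      covariates = gwasCovariates(cohort),
                      method = "marginal", h2 = loco_h2)
    ## risk orientation: higher score = greater myopia susceptibility
    cf_z <- standardizePgs(-cf)
    cohort_mmd <- simulateMmd(cohort, config, pgs = cf_z)
    grade <- worseEye(cohort_mmd$eye_grade_right,
                      cohort_mmd$eye_grade_left)
    severe <- as.integer(severeIndicator(grade) == "severe")
    cov_all <- gwasCovariates(cohort)
    mmd_out <- list(
      partition = partn, crossfit_score = cf, grade = grade,
      n_severe = sum(severe),
      unadjusted = if (sum(severe) > 0)
        logisticAssoc(severe, cf_z, cohort$avSER, cov_all,
                      include_ser = FALSE) else NULL,
      adjusted = if (sum(severe) > 0)
        logisticAssoc(severe, cf_z, cohort$avSER, cov_all,
                      include_ser = TRUE) else NULL,
      adjusted_firth = if (sum(severe) > 0)
        logisticAssoc(severe, cf_z, cohort$avSER, cov_all,
                      include_ser = TRUE, firth = TRUE) else NULL
    )
  }

  list(config = config, splits = part,
       sumstats = list(avser = ss_avser, aosw = ss_aosw, meta = meta_ss,
                       n_meta_cohorts = length(ukb) + length(externals)),
       tuned = tuned, baseline = baseline,
       evaluation = eval_report,
       test_scores = list(tuned = score_test, baseline = base_test),
       tuned_test_r2 = eval_report$incremental_r2,
       baseline_test_r2 = baseline_r2,
       mmd = mmd_out)
}
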