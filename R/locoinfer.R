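## Leave-one-chromosome-out (LOCO) machinery: genome-minus-one-chromosome
## predictive weights, the AOSW -> avSER inference model, and assembly of
## the 22 per-chromosome GWAS runs into one set of summary statistics.
## The LOCO scheme prevents a chromosome's own SNPs from informing the
## phenotype used to test them.

#' Genome-minus-one-chromosome predictive weights
#'
#' Builds a predictive weight vector from GWAS summary statistics with one
#' chromosome excluded. `method = "marginal"` shrinks every GWAS beta by
#' the single infinitesimal factor `c = n*h2 / (n*h2 + m)` (m = number of
#' included variants, n = median GWAS sample size); `method = "ridge"`
#' solves the per-block closed form `(R + m/(n*h2) I)^-1 beta` against an
#' LD reference, which reduces to the marginal factor when every block is
#' the identity.
#'
#' @param sumstats a [SumStats-class] covering all chromosomes.
#' @param excluded chromosome to omit (1..22).
#' @param method "marginal" or "ridge".
#' @param h2 assumed SNP-heritability for the shrink (default 0.3).
#' @param ld [LDBlockSet-class]; required for `method = "ridge"`.
#' @return a [WeightVector-class] with no variant on `excluded`.
#' @export
buildLocoWeights <- function(sumstats, excluded,
                             method = c("marginal", "ridge"),
                             h2 = 0.3, ld = NULL) {
  method <- match.arg(method)
  if (!excluded %in% 1:22) stop("excluded chromosome must be in 1..22")
  ss <- as.data.frame(sumstats)
  keep <- ss$chromosome != excluded
  ss <- ss[keep, , drop = FALSE]
  m <- nrow(ss)
  n <- stats::median(ss$n)
  lambda <- m / (n * h2)
  if (method == "marginal") {
    w <- ss$beta / (1 + lambda)
  } else {
    if (is.null(ld)) stop("ridge method requires an LD reference")
    w <- ss$beta / (1 + lambda)  # default for variants outside the blocks
    names(w) <- ss$variant_id
    for (i in seq_along(ld@ids)) {
      ids <- intersect(ld@ids[[i]], ss$variant_id)
      if (length(ids) < 1) next
      j <- match(ids, ld@ids[[i]])
      R <- ld@mats[[i]][j, j, drop = FALSE]
      b <- ss$beta[match(ids, ss$variant_id)]
      w[ids] <- solve(R + diag(lambda, length(ids)), b)
    }
    w <- unname(w)
  }
  WeightVector(
    data.frame(variant_id = ss$variant_id, chromosome = ss$chromosome,
               effect_allele = ss$effect_allele, weight = w,
               stringsAsFactors = FALSE),
    provenance = list(method = method, excluded = excluded, h2 = h2)
  )
}

#' Full LOCO weight set
#'
#' One [buildLocoWeights()] call per chromosome present in the summary
#' statistics.
#'
#' @inheritParams buildLocoWeights
#' @return a [LocoWeightSet-class].
#' @export
buildLocoWeightSet <- function(sumstats, method = c("marginal", "ridge"),
                               h2 = 0.3, ld = NULL) {
  method <- match.arg(method)
  chroms <- sort(unique(as.data.frame(sumstats)$chromosome))
  LocoWeightSet(
    lapply(chroms, function(k)
      buildLocoWeights(sumstats, k, method = method, h2 = h2, ld = ld)),
    chroms
  )
}

.aosw_formula <- function(spec, with_pgs = TRUE) {
  terms <- c(sprintf("poly(AOSW, %d)", spec@aosw_order),
             sprintf("poly(Age, %d)", spec@age_order))
  if (spec@include_sex) terms <- c(terms, "Sex")
  terms <- c(terms, sprintf("poly(EduYears, %d)", spec@edu_order))
  if (spec@include_edu_aosw) terms <- c(terms, "I(EduYears * AOSW)")
  if (with_pgs)
    terms <- c(terms, "pgs",
               sprintf("pgs:poly(AOSW, %d)", spec@pgs_aosw_order))
  stats::as.formula(paste("avSER ~", paste(terms, collapse = " + ")))
}

#' Fit the AOSW -> avSER inference model
#'
#' Least squares of avSER on orthogonal polynomials of AOSW (order 10),
#' Age (order 3) and EduYears (order 2), Sex, the raw EduYears x AOSW
#' product, the LOCO PGS main effect, and PGS x orthogonal-AOSW
#' interactions up to order 2 (20 non-intercept design columns at the
#' default spec). Orthogonal bases are built on the training rows and
#' frozen for out-of-sample application. Never-wearers (no numeric AOSW)
#' are excluded from training.
#'
#' @param cohort cohort data.frame with `avSER`, `AOSW`, `Age`, `Sex`,
#'   `EduYears`.
#' @param loco_pgs per-sample LOCO score aligned to `cohort` rows, or
#'   NULL for a covariate-only inference model (no genotype information
#'   enters the phenotype).
#' @param spec an [AoswModelSpec-class].
#' @return an `AoswModelFit` (S3): the frozen fit plus training
#'   statistics.
#' @export
fitAoswModel <- function(cohort, loco_pgs = NULL, spec = aoswModelSpec()) {
  with_pgs <- !is.null(loco_pgs)
  if (with_pgs) stopifnot(length(loco_pgs) == nrow(cohort))
  need <- c("avSER", "AOSW", "Age", "Sex", "EduYears")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort lacks columns: ", paste(miss, collapse = ", "))
  d <- data.frame(avSER = cohort$avSER, AOSW = cohort$AOSW,
                  Age = cohort$Age, Sex = cohort$Sex,
                  EduYears = cohort$EduYears)
  if (with_pgs) d$pgs <- loco_pgs
  d <- d[stats::complete.cases(d), , drop = FALSE]
  f <- .aosw_formula(spec, with_pgs)
  n_cols <- spec@aosw_order + spec@age_order + spec@edu_order +
    spec@include_sex + spec@include_edu_aosw +
    if (with_pgs) 1 + spec@pgs_aosw_order else 0
  if (nrow(d) <= n_cols + 1)
    stop("fewer training rows than design columns")
  fit <- stats::lm(f, data = d)
  if (anyNA(coef(fit)))
    stop("collinear design; dropped terms: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  num <- c("AOSW", "Age", "EduYears", if (with_pgs) "pgs")
  out <- list(fit = fit, spec = spec, n_train = nrow(d),
              r2 = summary(fit)$r.squared, n_design_cols = n_cols,
              with_pgs = with_pgs,
              ranges = lapply(d[num], range))
  class(out) <- "AoswModelFit"
  out
}

#' @export
print.AoswModelFit <- function(x, ...) {
  cat("AoswModelFit:", x$n_design_cols, "design columns,", x$n_train,
      "training rows, R2 =", round(x$r2, 3), "\n")
  invisible(x)
}

#' Infer refractive error from AOSW
#'
#' Applies a frozen [fitAoswModel()] fit to new participants. Rows with a
#' missing predictor (in particular never-wearers, whose AOSW is NA under
#' the default policy) receive NA. Numeric predictors are clamped to the
#' training range before evaluating the orthogonal polynomial bases: a
#' degree-10 basis is numerically unstable under extrapolation, and out-
#' of-range onset ages carry no usable refraction information anyway.
#'
#' @param fit an `AoswModelFit`.
#' @param cohort cohort data.frame with the model's predictors.
#' @param loco_pgs per-sample LOCO score aligned to `cohort` rows.
#' @return numeric vector of AOSW-inferred avSER (diopters).
#' @export
inferPhenotype <- function(fit, cohort, loco_pgs = NULL) {
  stopifnot(inherits(fit, "AoswModelFit"))
  if (isTRUE(fit$with_pgs) && is.null(loco_pgs))
    stop("this fit requires a LOCO score")
  need <- c("AOSW", "Age", "Sex", "EduYears")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort lacks predictor columns: ",
         paste(miss, collapse = ", "))
  nd <- data.frame(AOSW = cohort$AOSW, Age = cohort$Age,
                   Sex = cohort$Sex, EduYears = cohort$EduYears)
  if (isTRUE(fit$with_pgs)) {
    stopifnot(length(loco_pgs) == nrow(cohort))
    nd$pgs <- loco_pgs
  }
  for (nm in names(fit$ranges))
    nd[[nm]] <- pmin(pmax(nd[[nm]], fit$ranges[[nm]][1]),
                     fit$ranges[[nm]][2])
  ok <- stats::complete.cases(nd)
  out <- rep(NA_real_, nrow(nd))
  if (any(ok)) out[ok] <- predict(fit$fit, newdata = nd[ok, , drop = FALSE])
  out
}

#' Assemble a LOCO GWAS from 22 per-exclusion runs
#'
#' Pure row selection: the output row for every variant is taken from the
#' run whose excluded chromosome equals that variant's chromosome; betas
#' and SEs are unchanged from the source runs.
#'
#' @param runs list of [SumStats-class], each covering all chromosomes.
#' @param exclusions integer vector: the chromosome excluded from the PGS
#'   used for each run (parallel to `runs`).
#' @return a [SumStats-class] with every variant exactly once.
#' @export
assembleLocoGwas <- function(runs, exclusions) {
  if (length(runs) != length(exclusions))
    stop("runs and exclusions must be parallel")
  if (anyDuplicated(exclusions))
    stop("duplicate exclusion tags: ",
         paste(exclusions[duplicated(exclusions)], collapse = ", "))
  pieces <- lapply(seq_along(runs), function(i) {
    df <- as.data.frame(runs[[i]])
    df[df$chromosome == exclusions[i], , drop = FALSE]
  })
  out <- do.call(rbind, pieces)
  all_chr <- unique(unlist(lapply(runs,
                                  function(r) as.data.frame(r)$chromosome)))
  missing_chr <- setdiff(all_chr, exclusions)
  if (length(missing_chr))
    stop("no run excludes chromosome(s): ",
         paste(missing_chr, collapse = ", "))
  out <- out[order(out$chromosome, out$position), , drop = FALSE]
  rownames(out) <- NULL
  if (anyDuplicated(out$variant_id))
    stop("assembly produced duplicate variants")
  SumStats(out)
}

#' Anti-leakage experiment: LOCO vs full-genome vs covariate-only
#'
#' Runs the AOSW-inference GWAS three ways on one simulated study and
#' returns the mean per-SNP chi-square of each arm. The cohort is split
#' into a weights-GWAS sample, an inference-model sample and a GWAS
#' sample. In the `full` arm a single genome-wide predictive score enters
#' both the inference model and the phenotype of the GWAS sample, so each
#' tested SNP's own weight leaks into the phenotype and inflates its
#' statistic. The `loco` arm excludes each tested chromosome from the
#' score. The `heldout` benchmark infers the phenotype without any PGS
#' term, so no genotype of the GWAS sample enters its phenotype -- the
#' mechanically leak-free reference.
#'
#' @param seed replicate seed.
#' @param n_samples,n_snps study size (split 3:2:3 across the weights,
#'   inference-model and inferred-GWAS samples, keeping the weights GWAS
#'   large enough for a usable predictive score at desk scale).
#' @param loco_h2 assumed heritability for the predictive weights.
#' @param config optional [SimConfig-class] overriding the default study
#'   conditions (its seed is replaced by `seed`).
#' @return list of mean chi-squares: `loco`, `full`, `heldout`.
#' @export
locoLeakageExperiment <- function(seed, n_samples = 4000, n_snps = 4400,
                                  loco_h2 = 0.3, config = NULL) {
  if (is.null(config))
    config <- simConfig(n_samples = n_samples, n_snps = n_snps,
                        seed = seed)
  else config@seed <- seed
  sim <- simulateCohort(config)
  panel <- sim$panel
  co <- sim$cohort
  n <- nrow(co)
  set.seed(seed + 7L)
  idx <- sample.int(n)
  iW <- idx[seq_len(floor(0.375 * n))]
  iM <- idx[(floor(0.375 * n) + 1):floor(0.625 * n)]
  iG <- idx[(floor(0.625 * n) + 1):n]

  ss_w <- runGwas(panel[, iW], co$avSER[iW],
                  gwasCovariates(co[iW, , drop = FALSE]))
  cov_g <- function(rows) gwasCovariates(co[rows, , drop = FALSE])
  mean_chisq <- function(ss) {
    d <- as.data.frame(ss)
    mean((d$beta / d$se)^2)
  }
  gwas_on <- function(pheno_g) {
    ok <- which(!is.na(pheno_g))
    rows <- iG[ok]
    runGwas(panel[, rows], pheno_g[ok], cov_g(rows))
  }

  ## full-genome arm: one score for everything
  dfw <- as.data.frame(ss_w)
  c_all <- 1 / (1 + nrow(dfw) / (stats::median(dfw$n) * loco_h2))
  w_full <- WeightVector(data.frame(
    variant_id = dfw$variant_id, chromosome = dfw$chromosome,
    effect_allele = dfw$effect_allele, weight = c_all * dfw$beta))
  fit_full <- fitAoswModel(co[iM, , drop = FALSE],
                           scoreSamples(panel[, iM], w_full))
  inf_full <- inferPhenotype(fit_full, co[iG, , drop = FALSE],
                             scoreSamples(panel[, iG], w_full))
  chisq_full <- mean_chisq(gwas_on(inf_full))

  ## LOCO arm: 22 runs, assemble per excluded chromosome
  locoset <- buildLocoWeightSet(ss_w, h2 = loco_h2)
  runs <- list()
  excl <- excludedChromosomes(locoset)
  for (k in excl) {
    wk <- locoWeights(locoset, k)
    fit_k <- fitAoswModel(co[iM, , drop = FALSE],
                          scoreSamples(panel[, iM], wk))
    inf_k <- inferPhenotype(fit_k, co[iG, , drop = FALSE],
                            scoreSamples(panel[, iG], wk))
    runs[[as.character(k)]] <- gwas_on(inf_k)
  }
  chisq_loco <- mean_chisq(assembleLocoGwas(runs, excl))

  ## held-out benchmark: covariate-only inference, no genotype enters
  fit_0 <- fitAoswModel(co[iM, , drop = FALSE], NULL)
  inf_0 <- inferPhenotype(fit_0, co[iG, , drop = FALSE])
  chisq_heldout <- mean_chisq(gwas_on(inf_0))

  list(loco = chisq_loco, full = chisq_full, heldout = chisq_heldout)
}
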