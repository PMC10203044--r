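## Central S4 classes: simulation configuration, genotype container,
## summary statistics, PGS weights, LD blocks, shrinkage grid.

#' Simulation configuration
#'
#' Holds every parameter of the synthetic-cohort generator: genotype panel
#' dimensions and LD structure, trait architecture, covariate effects, the
#' AOSW (age-of-onset of spectacle wear) observation model, the myopic
#' macular degeneration (MMD) outcome model, and family structure. All
#' generators are pure functions of `(config, seed)`.
#'
#' @slot n_samples,n_snps,n_chromosomes panel dimensions; variants are
#'   spread evenly over `n_chromosomes` autosomes (every chromosome
#'   non-empty).
#' @slot maf_low,maf_high minor-allele-frequency range, in (0, 0.5].
#' @slot ld_block_size,ld_rho LD blocks of `ld_block_size` adjacent SNPs
#'   with latent AR(1) correlation `ld_rho` in \[0,1); blocks never span a
#'   chromosome boundary.
#' @slot h2 narrow-sense heritability of avSER in \[0,1\].
#' @slot p_causal fraction of SNPs with non-zero effect, in (0,1].
#' @slot ser_mean,ser_sd avSER mean and SD in diopters.
#' @slot beta_age,beta_sex,beta_edu covariate effects on avSER (D per year,
#'   D for female vs male, D per education year).
#' @slot aosw_intercept,aosw_slope,aosw_sd,aosw_threshold onset model:
#'   expected onset age = intercept + slope * avSER (slope > 0 so more
#'   negative avSER means earlier onset), Gaussian noise `aosw_sd`;
#'   participants with avSER above `aosw_threshold` or modeled onset beyond
#'   current age are flagged never-wearers.
#' @slot mmd_intercept,mmd_beta_ser,mmd_beta_direct per-eye severe-MMD
#'   logit model: `intercept + beta_ser * (-avSER) + beta_direct * pgs`.
#' @slot mmd_c3_frac fraction of severe eyes graded C3 (rest C4).
#' @slot mmd_c2_frac fraction of non-severe eyes graded C2 (rest C0).
#' @slot n_families number of family clusters (NA = draw family sizes from
#'   `family_size_probs` until the cohort is covered).
#' @slot family_size_probs named numeric vector of family-size
#'   probabilities, names are sizes.
#' @slot pc_mode "noise" (exchangeable standard-normal stand-ins for
#'   ancestry PCs in a homogeneous cohort) or "computed" (PCA of the
#'   panel).
#' @slot seed master seed; per-stage child seeds are `seed + stage offset`
#'   (panel +1, phenotypes +2, AOSW +3, MMD +4, families +5).
#' @export
setClass("SimConfig",
  representation(
    n_samples = "numeric", n_snps = "numeric", n_chromosomes = "numeric",
    maf_low = "numeric", maf_high = "numeric",
    ld_block_size = "numeric", ld_rho = "numeric",
    h2 = "numeric", p_causal = "numeric",
    ser_mean = "numeric", ser_sd = "numeric",
    beta_age = "numeric", beta_sex = "numeric", beta_edu = "numeric",
    aosw_intercept = "numeric", aosw_slope = "numeric",
    aosw_sd = "numeric", aosw_threshold = "numeric",
    mmd_intercept = "numeric", mmd_beta_ser = "numeric",
    mmd_beta_direct = "numeric", mmd_c3_frac = "numeric",
    mmd_c2_frac = "numeric",
    n_families = "numeric", family_size_probs = "numeric",
    pc_mode = "character", seed = "numeric"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  chk <- function(cond, m) if (!isTRUE(cond)) msg <<- c(msg, m)
  chk(object@n_samples >= 1, "n_samples must be >= 1")
  chk(object@n_snps >= 1, "n_snps must be >= 1")
  chk(object@n_chromosomes >= 1 && object@n_chromosomes <= 22,
      "n_chromosomes must be in 1..22")
  chk(object@n_snps >= object@n_chromosomes,
      "n_snps must be >= n_chromosomes (every chromosome non-empty)")
  chk(object@maf_low > 0 && object@maf_high <= 0.5 &&
        object@maf_low <= object@maf_high,
      "maf_low/maf_high must satisfy 0 < maf_low <= maf_high <= 0.5")
  chk(object@ld_block_size >= 1, "ld_block_size must be >= 1")
  chk(object@ld_rho >= 0 && object@ld_rho < 1, "ld_rho must be in [0,1)")
  chk(object@h2 >= 0 && object@h2 <= 1, "h2 must be in [0,1]")
  chk(object@p_causal > 0 && object@p_causal <= 1,
      "p_causal must be in (0,1]")
  chk(object@ser_sd > 0, "ser_sd must be > 0")
  chk(object@aosw_sd >= 0, "aosw_sd must be >= 0")
  chk(object@aosw_slope >= 0, "aosw_slope must be >= 0")
  chk(object@mmd_c3_frac >= 0 && object@mmd_c3_frac <= 1,
      "mmd_c3_frac must be in [0,1]")
  chk(object@mmd_c2_frac >= 0 && object@mmd_c2_frac <= 1,
      "mmd_c2_frac must be in [0,1]")
  chk(is.na(object@n_families) ||
        (object@n_families >= 1 && object@n_families <= object@n_samples),
      "n_families must be in 1..n_samples (or NA)")
  chk(all(object@family_size_probs >= 0) &&
        sum(object@family_size_probs) > 0 &&
        !is.null(names(object@family_size_probs)),
      "family_size_probs must be a named non-negative vector")
  chk(object@pc_mode %in% c("noise", "computed"),
      "pc_mode must be 'noise' or 'computed'")
  chk(is.finite(object@mmd_beta_ser) && is.finite(object@mmd_beta_direct),
      "MMD model parameters must be finite")
  if (length(msg)) msg else TRUE
})

#' Genotype panel
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one assay,
#' `"dosage"`: a variants x samples matrix of effect-allele dosages in
#' \[0, 2\]. Row metadata carries `chromosome`, `position`, `variant_id`,
#' `effect_allele`, `other_allele`, `allele_frequency`; variants are sorted
#' by (chromosome, position).
#'
#' @export
setClass("GenotypePanel", contains = "SummarizedExperiment")

setValidity("GenotypePanel", function(object) {
  msg <- character()
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    return("assay 'dosage' is required")
  d <- SummarizedExperiment::assay(object, "dosage")
  rd <- SummarizedExperiment::rowData(object)
  need <- c("chromosome", "position", "variant_id", "effect_allele",
            "other_allele", "allele_frequency")
  miss <- setdiff(need, colnames(rd))
  if (length(miss))
    return(paste("missing rowData columns:", paste(miss, collapse = ", ")))
  if (anyNA(d) || min(d) < -1e-9 || max(d) > 2 + 1e-9)
    msg <- c(msg, "dosages must lie in [0, 2]")
  if (anyDuplicated(rd$variant_id))
    msg <- c(msg, "variant_ids must be unique")
  o <- order(rd$chromosome, rd$position)
  if (!identical(o, seq_len(nrow(rd))))
    msg <- c(msg, "variants must be sorted by (chromosome, position)")
  if (any(rd$chromosome < 1 | rd$chromosome > 22))
    msg <- c(msg, "chromosome must be in 1..22")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypePanel
#'
#' @param dosages variants x samples numeric matrix of dosages in \[0,2\].
#' @param variants data.frame with columns `chromosome`, `position`,
#'   `variant_id`, `effect_allele`, `other_allele`, `allele_frequency`.
#' @param sample_ids character vector of sample identifiers.
#' @return a [GenotypePanel-class] object.
#' @export
GenotypePanel <- function(dosages, variants, sample_ids) {
  stopifnot(nrow(dosages) == nrow(variants),
            ncol(dosages) == length(sample_ids))
  rownames(dosages) <- variants$variant_id
  colnames(dosages) <- sample_ids
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosages),
    rowData = S4Vectors::DataFrame(variants)
  )
  new("GenotypePanel", se)
}

#' GWAS summary statistics
#'
#' A [S4Vectors::DFrame] subclass with one row per variant and columns
#' `variant_id`, `chromosome`, `position`, `effect_allele`, `other_allele`,
#' `beta` (D per effect-allele dose), `se`, `n`, `p`,
#' `allele_frequency`. Validity enforces `se > 0`, `p` in (0,1\], unique
#' ids, and consistency of `p` with `2*pnorm(-|beta/se|)`.
#'
#' @export
setClass("SumStats", contains = "DFrame")

setValidity("SumStats", function(object) {
  need <- c("variant_id", "chromosome", "position", "effect_allele",
            "other_allele", "beta", "se", "n", "p", "allele_frequency")
  miss <- setdiff(need, colnames(object))
  if (length(miss))
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  msg <- character()
  if (anyDuplicated(object$variant_id))
    msg <- c(msg, "variant_ids must be unique")
  if (any(object$se <= 0, na.rm = TRUE))
    msg <- c(msg, "se must be > 0")
  if (any(object$p <= 0 | object$p > 1, na.rm = TRUE))
    msg <- c(msg, "p must be in (0,1]")
  z <- ifelse(is.finite(object$se), abs(object$beta / object$se), 0)
  pref <- 2 * stats::pnorm(-z)
  bad <- abs(object$p - pref) > 1e-6 * pmax(pref, 1e-300)
  if (any(bad, na.rm = TRUE))
    msg <- c(msg, "p inconsistent with two-sided normal beta/se")
  if (length(msg)) msg else TRUE
})

#' Construct SumStats from a data.frame
#'
#' @param df data.frame of per-variant association results; `p` is filled
#'   from `beta`/`se` under the two-sided normal approximation when absent.
#' @export
SumStats <- function(df) {
  if (!"p" %in% colnames(df)) {
    z <- ifelse(is.finite(df$se), abs(df$beta / df$se), 0)
    df$p <- 2 * stats::pnorm(-z)
  }
  new("SumStats", S4Vectors::DataFrame(df, check.names = FALSE))
}

#' PGS weight vector
#'
#' A [S4Vectors::DFrame] subclass with columns `variant_id`, `chromosome`,
#' `effect_allele`, `weight` (D per effect-allele dose). Provenance (method
#' or grid cell) lives in `metadata()`.
#'
#' @export
setClass("WeightVector", contains = "DFrame")

setValidity("WeightVector", function(object) {
  need <- c("variant_id", "chromosome", "effect_allele", "weight")
  miss <- setdiff(need, colnames(object))
  if (length(miss))
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  msg <- character()
  if (anyDuplicated(object$variant_id))
    msg <- c(msg, "variant_ids must be unique")
  if (any(!is.finite(object$weight)))
    msg <- c(msg, "weights must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a WeightVector
#' @param df data.frame with `variant_id`, `chromosome`, `effect_allele`,
#'   `weight` columns.
#' @param provenance optional list stored in `metadata()`.
#' @export
WeightVector <- function(df, provenance = list()) {
  out <- new("WeightVector", S4Vectors::DataFrame(df, check.names = FALSE))
  S4Vectors::metadata(out) <- provenance
  out
}

#' Leave-one-chromosome-out weight set
#'
#' Holds 22 (or `n_chromosomes`) [WeightVector-class] entries; entry `k`
#' carries no weight for any variant on excluded chromosome `k`.
#'
#' @slot weights list of WeightVector.
#' @slot excluded integer vector of excluded chromosomes, parallel to
#'   `weights`.
#' @export
setClass("LocoWeightSet",
  representation(weights = "list", excluded = "integer"))

setValidity("LocoWeightSet", function(object) {
  if (length(object@weights) != length(object@excluded))
    return("weights and excluded must have equal length")
  if (anyDuplicated(object@excluded))
    return("excluded chromosomes must be unique")
  for (i in seq_along(object@weights)) {
    w <- object@weights[[i]]
    if (!is(w, "WeightVector")) return("entries must be WeightVector")
    if (any(w$chromosome == object@excluded[i]))
      return(sprintf("entry %d contains its excluded chromosome %d",
                     i, object@excluded[i]))
  }
  TRUE
})

#' @rdname LocoWeightSet-class
#' @param weights list of [WeightVector-class].
#' @param excluded integer vector of excluded chromosomes.
#' @export
LocoWeightSet <- function(weights, excluded) {
  new("LocoWeightSet", weights = weights, excluded = as.integer(excluded))
}

#' LD block set
#'
#' Block-diagonal LD reference: per block, the variant ids and the
#' symmetric unit-diagonal correlation matrix (PSD within 1e-8 after
#' eigenvalue flooring). Blocks partition the variant universe and never
#' span chromosomes.
#'
#' @slot ids list of character vectors (variant ids per block).
#' @slot mats list of correlation matrices.
#' @slot chromosome integer chromosome per block.
#' @export
setClass("LDBlockSet",
  representation(ids = "list", mats = "list", chromosome = "integer"))

setValidity("LDBlockSet", function(object) {
  if (length(object@ids) != length(object@mats) ||
      length(object@ids) != length(object@chromosome))
    return("ids, mats and chromosome must be parallel")
  all_ids <- unlist(object@ids)
  if (anyDuplicated(all_ids)) return("blocks must partition variant ids")
  for (i in seq_along(object@mats)) {
    m <- object@mats[[i]]
    if (nrow(m) != length(object@ids[[i]]))
      return("block matrix dimension mismatch")
    if (max(abs(diag(m) - 1)) > 1e-8) return("diagonals must be 1")
    if (max(abs(m - t(m))) > 1e-8) return("matrices must be symmetric")
  }
  TRUE
})

#' Point-normal shrinkage grid
#'
#' The tuning grid for the Gibbs shrinkage: SNP-heritability values,
#' causal-fraction values (the grid axis the upstream method labels a
#' "p-value threshold"), sparsity flags, and sampler settings.
#'
#' @slot h2 numeric vector of assumed heritabilities.
#' @slot p_causal numeric vector of causal fractions.
#' @slot sparse logical vector.
#' @slot n_iter,burn_in Gibbs iterations and burn-in (n_iter > burn_in).
#' @slot seed sampler seed.
#' @export
setClass("ShrinkGrid",
  representation(h2 = "numeric", p_causal = "numeric", sparse = "logical",
                 n_iter = "numeric", burn_in = "numeric", seed = "numeric"))

setValidity("ShrinkGrid", function(object) {
  msg <- character()
  if (!length(object@h2) || !length(object@p_causal) ||
      !length(object@sparse))
    msg <- c(msg, "grids must be non-empty")
  if (any(object@h2 <= 0 | object@h2 > 1))
    msg <- c(msg, "h2 values must be in (0,1]")
  if (any(object@p_causal <= 0 | object@p_causal > 1))
    msg <- c(msg, "p_causal values must be in (0,1]")
  if (!(object@n_iter > object@burn_in && object@burn_in >= 0))
    msg <- c(msg, "need n_iter > burn_in >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname ShrinkGrid-class
#' @param h2,p_causal,sparse grid axes (defaults: the standard grid
#'   h2 = 0.1..0.4, p = 1e-5..1, sparse = TRUE/FALSE -> 48 cells).
#' @param n_iter,burn_in,seed sampler settings.
#' @export
shrinkGrid <- function(h2 = c(0.1, 0.2, 0.3, 0.4),
                       p_causal = c(1e-5, 1e-4, 1e-3, 1e-2, 1e-1, 1),
                       sparse = c(TRUE, FALSE),
                       n_iter = 500, burn_in = 100, seed = 1L) {
  new("ShrinkGrid", h2 = h2, p_causal = p_causal, sparse = sparse,
      n_iter = n_iter, burn_in = burn_in, seed = seed)
}

#' AOSW inference model specification
#'
#' Specification of the model that infers avSER from AOSW: orthogonal
#' polynomial orders for AOSW (10), Age (3) and EduYears (2), a Sex term,
#' the raw EduYears x AOSW product, the LOCO PGS main effect and the
#' PGS x orthogonal-AOSW interaction up to order 2. EduYears is set to 21
#' for degree holders before fitting.
#'
#' @slot aosw_order,age_order,edu_order,pgs_aosw_order polynomial orders.
#' @slot include_sex,include_edu_aosw term-inclusion flags.
#' @slot edu_degree_years EduYears value assigned to degree holders.
#' @export
setClass("AoswModelSpec",
  representation(aosw_order = "numeric", age_order = "numeric",
                 edu_order = "numeric", pgs_aosw_order = "numeric",
                 include_sex = "logical", include_edu_aosw = "logical",
                 edu_degree_years = "numeric"))

setValidity("AoswModelSpec", function(object) {
  if (object@aosw_order < 1 || object@age_order < 1 ||
      object@edu_order < 1 || object@pgs_aosw_order < 1)
    return("polynomial orders must be >= 1")
  TRUE
})

#' @rdname AoswModelSpec-class
#' @param aosw_order,age_order,edu_order,pgs_aosw_order polynomial orders.
#' @param include_sex,include_edu_aosw term-inclusion flags.
#' @param edu_degree_years EduYears assigned to degree holders.
#' @export
aoswModelSpec <- function(aosw_order = 10, age_order = 3, edu_order = 2,
                          pgs_aosw_order = 2, include_sex = TRUE,
                          include_edu_aosw = TRUE, edu_degree_years = 21) {
  new("AoswModelSpec", aosw_order = aosw_order, age_order = age_order,
      edu_order = edu_order, pgs_aosw_order = pgs_aosw_order,
      include_sex = include_sex, include_edu_aosw = include_edu_aosw,
      edu_degree_years = edu_degree_years)
}
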