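#' Build a simulation configuration
#'
#' Defaults emulate a UK-Biobank-scale adult cohort at desk scale: mean age
#' 58 (SD 8), avSER mean -0.28 D with SD 2.72 D, heritability 0.3 (the
#' value selected on the real tuning sample), 1% causal SNPs, per-eye
#' severe-MMD model with OR 1.28 per diopter more negative refraction and
#' no direct PGS effect (full mediation), severe grades split C3:C4 =
#' 169:49, and participant-level severe prevalence near 0.3%.
#'
#' @param n_samples,n_snps,n_chromosomes panel dimensions.
#' @param maf_low,maf_high allele-frequency range.
#' @param ld_block_size,ld_rho LD block size and latent AR(1) correlation.
#' @param h2 heritability of avSER.
#' @param p_causal causal fraction.
#' @param ser_mean,ser_sd avSER mean/SD in diopters.
#' @param beta_age,beta_sex,beta_edu covariate effects on avSER.
#' @param aosw_intercept,aosw_slope,aosw_sd,aosw_threshold onset model.
#' @param mmd_intercept,mmd_beta_ser,mmd_beta_direct per-eye severe-MMD
#'   logit model.
#' @param mmd_c3_frac,mmd_c2_frac grade mixing fractions.
#' @param n_families number of families, or NA to draw sizes from
#'   `family_size_probs`.
#' @param family_size_probs named probabilities of family sizes.
#' @param pc_mode "noise" or "computed".
#' @param seed master seed.
#' @return a validated [SimConfig-class].
#' @examples
#' cfg <- simConfig(n_samples = 200, n_snps = 110, seed = 1)
#' panel <- simulatePanel(cfg)
#' @export
simConfig <- function(n_samples = 2000, n_snps = 2200, n_chromosomes = 22,
                      maf_low = 0.05, maf_high = 0.5,
                      ld_block_size = 10, ld_rho = 0.5,
                      h2 = 0.3, p_causal = 0.01,
                      ser_mean = -0.28, ser_sd = 2.72,
                      beta_age = -0.01, beta_sex = 0.1, beta_edu = -0.15,
                      aosw_intercept = 16, aosw_slope = 2, aosw_sd = 3,
                      aosw_threshold = 0,
                      mmd_intercept = -6.6, mmd_beta_ser = log(1.28),
                      mmd_beta_direct = 0,
                      mmd_c3_frac = 169 / 218, mmd_c2_frac = 0.05,
                      n_families = NA_real_,
                      family_size_probs = c("1" = 0.8, "2" = 0.15,
                                            "3" = 0.05),
                      pc_mode = "noise", seed = 1L) {
  new("SimConfig",
      n_samples = n_samples, n_snps = n_snps,
      n_chromosomes = n_chromosomes,
      maf_low = maf_low, maf_high = maf_high,
      ld_block_size = ld_block_size, ld_rho = ld_rho,
      h2 = h2, p_causal = p_causal,
      ser_mean = ser_mean, ser_sd = ser_sd,
      beta_age = beta_age, beta_sex = beta_sex, beta_edu = beta_edu,
      aosw_intercept = aosw_intercept, aosw_slope = aosw_slope,
      aosw_sd = aosw_sd, aosw_threshold = aosw_threshold,
      mmd_intercept = mmd_intercept, mmd_beta_ser = mmd_beta_ser,
      mmd_beta_direct = mmd_beta_direct, mmd_c3_frac = mmd_c3_frac,
      mmd_c2_frac = mmd_c2_frac,
      n_families = n_families, family_size_probs = family_size_probs,
      pc_mode = pc_mode, seed = seed)
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@n_samples, "samples x", object@n_snps,
      "SNPs over", object@n_chromosomes, "chromosomes\n")
  cat("  MAF [", object@maf_low, ",", object@maf_high, "], LD blocks of",
      object@ld_block_size, "(rho =", object@ld_rho, ")\n")
  cat("  h2 =", object@h2, ", p_causal =", object@p_causal,
      ", avSER ~", object@ser_mean, "+/-", object@ser_sd, "D\n")
  cat("  seed =", object@seed, "\n")
})

## ---- accessors ----

#' @rdname GenotypePanel
#' @param panel a GenotypePanel.
#' @export
dosageMatrix <- function(panel) SummarizedExperiment::assay(panel, "dosage")

#' @rdname GenotypePanel
#' @export
variantInfo <- function(panel)
  as.data.frame(SummarizedExperiment::rowData(panel))

#' @rdname GenotypePanel
#' @export
sampleIds <- function(panel) colnames(panel)

#' @rdname GenotypePanel
#' @export
nVariants <- function(panel) nrow(panel)

#' @rdname GenotypePanel
#' @export
nSamples <- function(panel) ncol(panel)

setMethod("show", "GenotypePanel", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  cat("GenotypePanel:", nrow(object), "variants x", ncol(object),
      "samples,", length(unique(rd$chromosome)), "chromosomes\n")
})

setMethod("show", "LocoWeightSet", function(object) {
  cat("LocoWeightSet:", length(object@weights),
      "weight vectors; excluded chromosomes:",
      paste(sort(object@excluded), collapse = ","), "\n")
})

#' @rdname LocoWeightSet-class
#' @param x a LocoWeightSet.
#' @param chromosome excluded chromosome whose entry to fetch.
#' @export
locoWeights <- function(x, chromosome) {
  i <- match(chromosome, x@excluded)
  if (is.na(i)) stop("no entry excluding chromosome ", chromosome)
  x@weights[[i]]
}

#' @rdname LocoWeightSet-class
#' @export
excludedChromosomes <- function(x) x@excluded

setMethod("show", "LDBlockSet", function(object) {
  cat("LDBlockSet:", length(object@mats), "blocks,",
      length(unlist(object@ids)), "variants\n")
})

#' @rdname LDBlockSet-class
#' @param x an LDBlockSet.
#' @export
nBlocks <- function(x) length(x@mats)

#' @rdname LDBlockSet-class
#' @export
blockIds <- function(x) x@ids

#' @rdname LDBlockSet-class
#' @export
blockMatrices <- function(x) x@mats

setMethod("show", "ShrinkGrid", function(object) {
  cat("ShrinkGrid:", length(object@h2), "h2 x", length(object@p_causal),
      "p x", length(object@sparse), "sparsity =",
      length(object@h2) * length(object@p_causal) * length(object@sparse),
      "cells;", object@n_iter, "iterations (", object@burn_in,
      "burn-in )\n")
})

#' Enumerate grid cells
#' @param grid a [ShrinkGrid-class].
#' @return data.frame with one row per (h2, p_causal, sparse) cell.
#' @export
gridCells <- function(grid) {
  expand.grid(h2 = grid@h2, p_causal = grid@p_causal,
              sparse = grid@sparse, KEEP.OUT.ATTRS = FALSE)
}
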