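## LD-aware shrinkage of meta-analyzed effects into a polygenic score:
## block LD reference, point-normal Gibbs grid, clumping + thresholding
## baseline, scoring, and tuning-sample selection.

#' Build a block LD reference from a panel
#'
#' Per-block Pearson correlation of standardized dosages. Blocks are runs
#' of `block_size` adjacent variants within a chromosome (never spanning
#' chromosomes), matching the simulator's block abstraction.
#' Zero-variance variants are dropped with a warning. Each matrix is
#' PSD-repaired by flooring eigenvalues at 1e-8 and renormalizing to unit
#' diagonal.
#'
#' @param panel a [GenotypePanel-class].
#' @param block_size number of adjacent SNPs per block.
#' @return an [LDBlockSet-class].
#' @export
buildLdBlocks <- function(panel, block_size) {
  stopifnot(nVariants(panel) > 0, block_size >= 1)
  G <- dosageMatrix(panel)
  v <- variantInfo(panel)
  sds <- apply(G, 1, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance variant(s) dropped from the ",
            "LD reference")
    G <- G[sds > 0, , drop = FALSE]
    v <- v[sds > 0, , drop = FALSE]
  }
  ids <- mats <- list()
  chrs <- integer(0)
  for (chr in unique(v$chromosome)) {
    idx <- which(v$chromosome == chr)
    starts <- seq(1, length(idx), by = block_size)
    for (s in starts) {
      rows <- idx[s:min(length(idx), s + block_size - 1)]
      R <- stats::cor(t(G[rows, , drop = FALSE]))
      e <- eigen((R + t(R)) / 2, symmetric = TRUE)
      if (min(e$values) < 1e-8) {
        R <- e$vectors %*% diag(pmax(e$values, 1e-8),
                                length(e$values)) %*% t(e$vectors)
        R <- stats::cov2cor(R)
      }
      ids <- c(ids, list(v$variant_id[rows]))
      mats <- c(mats, list(R))
      chrs <- c(chrs, chr)
    }
  }
  new("LDBlockSet", ids = ids, mats = mats, chromosome = chrs)
}

#' Point-normal Gibbs shrinkage over a parameter grid
#'
#' For every grid cell (h2, p, sparsity), posterior-mean weights from a
#' spike-and-slab Gibbs sampler run per LD block on the standardized
#' scale: slab variance `h2/(m*p)`, spike probability `1 - p`, marginal
#' sampling variance `1/n`. Posterior means are Rao-Blackwellised averages
#' over post-burn-in sweeps, so with identity LD and `p = 1` the weights
#' equal the infinitesimal closed form `beta * (h2/m) / (h2/m + 1/n)`
#' exactly. `sparse = TRUE` zeroes SNPs whose posterior inclusion
#' probability falls below the prior causal fraction `p`. A fixed seed
#' makes the whole grid reproducible.
#'
#' @param sumstats a [SumStats-class] aligned to the LD universe.
#' @param ld an [LDBlockSet-class].
#' @param grid a [ShrinkGrid-class].
#' @param n_gwas GWAS sample size (default: median of the `n` column).
#' @return list of [WeightVector-class], one per grid cell, each carrying
#'   its cell in `metadata()`.
#' @export
gibbsGrid <- function(sumstats, ld, grid, n_gwas = NULL) {
  ss <- as.data.frame(sumstats)
  universe <- unlist(ld@ids)
  if (!all(universe %in% ss$variant_id))
    stop("sumstats do not cover the LD variant universe")
  ss <- ss[match(universe, ss$variant_id), , drop = FALSE]
  if (is.null(n_gwas)) n_gwas <- stats::median(ss$n)
  if (n_gwas <= 1) stop("n_gwas must exceed 1")
  m <- nrow(ss)
  z <- ss$beta / ss$se
  r_marg <- z / sqrt(n_gwas + z^2)
  ## back-conversion to the per-dose scale; exact inverse of the forward
  ## map so identity-LD closed forms hold on the beta scale
  scale_back <- ifelse(abs(r_marg) > 0, ss$beta / r_marg,
                       ss$se * sqrt(n_gwas))
  blocks <- lapply(ld@ids, function(id) match(id, ss$variant_id))
  cells <- gridCells(grid)
  out <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    h2 <- cells$h2[ci]
    p <- cells$p_causal[ci]
    s2 <- h2 / (m * p)
    set.seed((grid@seed + ci) %% .Machine$integer.max)
    w_std <- pip <- numeric(m)
    for (bi in seq_along(blocks)) {
      idx <- blocks[[bi]]
      res <- gibbs_block_cpp(ld@mats[[bi]], r_marg[idx], n_gwas, s2, p,
                             as.integer(grid@n_iter),
                             as.integer(grid@burn_in))
      w_std[idx] <- res$postmean
      pip[idx] <- res$pip
    }
    w <- w_std * scale_back
    if (cells$sparse[ci]) w[pip < p] <- 0
    out[[ci]] <- WeightVector(
      data.frame(variant_id = ss$variant_id, chromosome = ss$chromosome,
                 effect_allele = ss$effect_allele, weight = w,
                 stringsAsFactors = FALSE),
      provenance = list(method = "gibbs", h2 = h2, p_causal = p,
                        sparse = cells$sparse[ci])
    )
  }
  out
}

#' Single-SNP spike-and-slab posterior mean by quadrature
#'
#' Independent 1-D oracle for the Gibbs sampler: numerical integration of
#' the two-component posterior for one SNP with marginal estimate `r`,
#' sampling variance `1/n`, slab variance `s2`, inclusion prior `p`.
#'
#' @param r marginal standardized effect.
#' @param n sample size.
#' @param s2 slab variance.
#' @param p prior inclusion probability.
#' @export
spikeSlabPosteriorMean <- function(r, n, s2, p) {
  lik_slab <- stats::integrate(function(b)
    dnorm(r, b, sqrt(1 / n)) * dnorm(b, 0, sqrt(s2)),
    -Inf, Inf, rel.tol = 1e-10)$value
  num <- stats::integrate(function(b)
    b * dnorm(r, b, sqrt(1 / n)) * dnorm(b, 0, sqrt(s2)),
    -Inf, Inf, rel.tol = 1e-10)$value
  lik_spike <- dnorm(r, 0, sqrt(1 / n))
  post_in <- p * lik_slab / (p * lik_slab + (1 - p) * lik_spike)
  if (p >= 1) post_in <- 1
  post_in * num / lik_slab
}

#' Clumping and thresholding baseline
#'
#' Greedy selection of index SNPs in ascending p-value order (ties broken
#' by genome order); a candidate is removed when its squared correlation
#' with an already-retained index SNP in the same LD block exceeds
#' `r2_max`. Weights are the raw GWAS betas of the survivors with
#' `p <= p_max`.
#'
#' @param sumstats a [SumStats-class].
#' @param ld an [LDBlockSet-class] (cross-block correlation is zero).
#' @param r2_max,p_max thresholds in (0, 1].
#' @return a [WeightVector-class].
#' @export
clumpThreshold <- function(sumstats, ld, r2_max, p_max) {
  stopifnot(r2_max > 0, r2_max <= 1, p_max > 0, p_max <= 1)
  ss <- as.data.frame(sumstats)
  block_of <- integer(nrow(ss))
  pos_in_block <- integer(nrow(ss))
  for (bi in seq_along(ld@ids)) {
    j <- match(ld@ids[[bi]], ss$variant_id)
    ok <- !is.na(j)
    block_of[j[ok]] <- bi
    pos_in_block[j[ok]] <- which(ok)
  }
  ord <- order(ss$p, ss$chromosome, ss$position)
  retained <- logical(nrow(ss))
  kept_by_block <- vector("list", length(ld@ids))
  for (i in ord) {
    b <- block_of[i]
    if (b > 0 && length(kept_by_block[[b]])) {
      r2 <- ld@mats[[b]][pos_in_block[i],
                         pos_in_block[kept_by_block[[b]]]]^2
      if (any(r2 > r2_max)) next
    }
    retained[i] <- TRUE
    if (b > 0) kept_by_block[[b]] <- c(kept_by_block[[b]], i)
  }
  keep <- retained & ss$p <= p_max
  WeightVector(
    data.frame(variant_id = ss$variant_id[keep],
               chromosome = ss$chromosome[keep],
               effect_allele = ss$effect_allele[keep],
               weight = ss$beta[keep], stringsAsFactors = FALSE),
    provenance = list(method = "clump_threshold", r2_max = r2_max,
                      p_max = p_max)
  )
}

#' Score samples with a weight vector
#'
#' `score_i = sum_j w_j * dose_ij` over the variants shared between
#' weights and panel, with allele-flip handling: when the weight's effect
#' allele is the panel's other allele the dosage is reflected (`2 -
#' dose`). Variants absent from the panel, or with irreconcilable alleles,
#' are skipped (count reported via attribute `n_skipped`).
#'
#' @param panel a [GenotypePanel-class].
#' @param weights a [WeightVector-class].
#' @return numeric per-sample score with attribute `n_skipped`.
#' @export
scoreSamples <- function(panel, weights) {
  w <- as.data.frame(weights)
  v <- variantInfo(panel)
  idx <- match(w$variant_id, v$variant_id)
  present <- !is.na(idx)
  same <- present & w$effect_allele == v$effect_allele[idx]
  flip <- present & !same & w$effect_allele == v$other_allele[idx]
  use <- same | flip
  if (!any(use)) stop("no overlapping variants between weights and panel")
  n_skipped <- sum(!use)
  idx_use <- idx[use]
  sgn <- ifelse(same[use], 1, -1)
  ww <- w$weight[use] * sgn
  offset <- 2 * sum(w$weight[use][sgn < 0])
  G <- dosageMatrix(panel)
  score <- drop(crossprod(G[idx_use, , drop = FALSE], ww)) + offset
  attr(score, "n_skipped") <- n_skipped
  score
}

## incremental adjusted R2 point estimate (shared with pgseval)
.adj_r2 <- function(y, X) {
  fit <- stats::lm.fit(X, y)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  n <- length(y)
  p <- fit$rank - 1
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

.incremental_r2_point <- function(pheno, score, covariates) {
  n <- length(pheno)
  X0 <- cbind(rep(1, n), covariates)
  X1 <- cbind(X0, score)
  .adj_r2(pheno, X1) - .adj_r2(pheno, X0)
}

#' Select the best candidate weights on a tuning sample
#'
#' Scores every candidate on the tuning panel and selects the one
#' maximizing the incremental adjusted R-squared of the phenotype on the
#' score given covariates. The full grid report (one row per candidate)
#' mirrors the accuracy-over-grid summary used to pick shrinkage settings.
#'
#' @param candidates list of [WeightVector-class].
#' @param tuning_panel a [GenotypePanel-class], disjoint from the GWAS
#'   samples (caller-asserted).
#' @param tuning_pheno numeric phenotype for the tuning samples.
#' @param covariates covariate matrix (no intercept) or NULL.
#' @return list: `best` (WeightVector), `best_index`, `report`
#'   (data.frame with provenance columns and `incremental_r2`).
#' @export
tunePgs <- function(candidates, tuning_panel, tuning_pheno,
                    covariates = NULL) {
  if (!length(candidates)) stop("empty candidate list")
  rows <- lapply(seq_along(candidates), function(i) {
    s <- scoreSamples(tuning_panel, candidates[[i]])
    prov <- S4Vectors::metadata(candidates[[i]])
    r2 <- .incremental_r2_point(tuning_pheno, s, covariates)
    data.frame(candidate = i,
               method = if (is.null(prov$method)) NA else prov$method,
               h2 = if (is.null(prov$h2)) NA else prov$h2,
               p_causal = if (is.null(prov$p_causal)) NA
                          else prov$p_causal,
               sparse = if (is.null(prov$sparse)) NA else prov$sparse,
               incremental_r2 = r2)
  })
  report <- do.call(rbind, rows)
  best <- which.max(report$incremental_r2)
  list(best = candidates[[best]], best_index = best, report = report)
}

#' Effective marker count of a score against an LD reference
#'
#' The LD-adjusted number of independent markers: the count of variants
#' carrying non-zero weight, divided by the average LD score (per-variant
#' sum of within-block r^2, self included). With `weights = NULL` the
#' whole LD universe is counted -- the infinitesimal reading.
#'
#' @param ld an [LDBlockSet-class].
#' @param weights optional [WeightVector-class]; only its non-zero
#'   entries are counted.
#' @return effective marker count (numeric).
#' @export
effectiveMarkerCount <- function(ld, weights = NULL) {
  ell <- mean(unlist(lapply(ld@mats, function(R) rowSums(R^2))))
  m <- if (is.null(weights)) length(unlist(ld@ids))
       else sum(as.data.frame(weights)$weight != 0)
  m / ell
}

#' Expected squared accuracy of a polygenic score
#'
#' The classical expectation `h2 / (1 + m_eff / (n * h2))` for the
#' proportion of phenotypic variance captured by a score estimated from
#' a GWAS of n samples over m_eff effective markers. Evaluated at the
#' effective dimensionality of the selected model this approximates the
#' accuracy of a tuned sparse score; evaluated at the full marker count
#' it gives the infinitesimal-architecture floor, which a sparse
#' architecture can exceed severalfold.
#'
#' @param h2 trait SNP-heritability.
#' @param n GWAS sample size.
#' @param m_eff effective marker count (see [effectiveMarkerCount()]).
#' @export
daetwylerExpectedR2 <- function(h2, n, m_eff) {
  h2 / (1 + m_eff / (n * h2))
}
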