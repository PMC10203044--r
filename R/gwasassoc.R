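## Per-SNP covariate-adjusted association testing and PC computation.
## Linear regression stands in for a mixed model: the synthetic cohorts
## carry no cryptic relatedness beyond explicit family labels, so a fixed
## covariate set suffices.

#' Default GWAS covariate matrix
#'
#' Age, age-squared, sex, genotyping array and the first `n_pcs` PCs, as
#' used throughout the pipeline.
#'
#' @param cohort cohort data.frame.
#' @param n_pcs number of PC columns to include (default 10; 0 drops
#'   them).
#' @return numeric covariate matrix (no intercept column).
#' @export
gwasCovariates <- function(cohort, n_pcs = 10) {
  out <- cbind(Age = cohort$Age, Age2 = cohort$Age^2, Sex = cohort$Sex,
               array = cohort$array)
  if (n_pcs > 0) {
    pcs <- as.matrix(cohort[paste0("PC", seq_len(n_pcs))])
    out <- cbind(out, pcs)
  }
  out
}

#' Single-variant association scan
#'
#' For each SNP, the least-squares effect of the phenotype on dosage given
#' covariates. Phenotype and dosages are residualized on the covariates
#' (plus intercept) once; per-SNP slopes on the residuals are algebraically
#' identical to the joint per-SNP fits, and the residual degrees of freedom
#' `n - p - 2` (p covariates, intercept, SNP) are used for the standard
#' error. P-values use the two-sided normal approximation, consistent with
#' the downstream meta-analysis; at the sample sizes simulated the
#' difference from the t reference is negligible. Missing dosages are
#' mean-imputed per variant. A zero-variance dosage yields `beta = 0`,
#' `se = Inf`, `p = 1`.
#'
#' @param panel a [GenotypePanel-class].
#' @param phenotype numeric vector, length `nSamples(panel)`.
#' @param covariates numeric matrix (columns = covariates, no intercept),
#'   or NULL for an intercept-only adjustment. Must be full rank after
#'   adding the intercept.
#' @return a [SumStats-class] with one row per variant.
#' @export
runGwas <- function(panel, phenotype, covariates = NULL) {
  stopifnot(is(panel, "GenotypePanel"))
  n <- nSamples(panel)
  if (length(phenotype) != n)
    stop("phenotype length must equal the number of samples")
  X <- cbind(`(Intercept)` = rep(1, n), covariates)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("covariate matrix is rank deficient; offending columns: ",
         paste(dropped, collapse = ", "))
  }
  p <- ncol(X)
  y_res <- qr.resid(qx, phenotype)
  yss <- sum(y_res^2)

  G <- dosageMatrix(panel)
  if (anyNA(G)) {
    rm <- rowMeans(G, na.rm = TRUE)
    na_idx <- which(is.na(G))
    G[na_idx] <- rm[(na_idx - 1) %% nrow(G) + 1]
  }
  ## residualize dosages on covariates in chunks: G_res = G - (G X) B
  ## where B = (X'X)^-1 X' applied rowwise
  m <- nVariants(panel)
  beta <- se <- numeric(m)
  chunk <- max(1L, floor(2e7 / n))
  for (s in seq(1, m, by = chunk)) {
    rows <- s:min(m, s + chunk - 1)
    Gc <- G[rows, , drop = FALSE]
    coefs <- t(qr.coef(qx, t(Gc)))       # (rows) x p
    Gc_res <- Gc - coefs %*% t(X)
    gg <- rowSums(Gc_res^2)
    gy <- drop(Gc_res %*% y_res)
    b <- ifelse(gg > 1e-12, gy / gg, 0)
    sse <- pmax(yss - b^2 * gg, 0)
    df <- n - p - 1
    s2 <- sse / df
    beta[rows] <- b
    se[rows] <- ifelse(gg > 1e-12, sqrt(s2 / gg), Inf)
  }
  if (all(abs(y_res) < 1e-12)) beta[] <- 0  # constant phenotype
  se[!(se > 0)] <- Inf                      # degenerate fits

  v <- variantInfo(panel)
  SumStats(data.frame(
    variant_id = v$variant_id, chromosome = v$chromosome,
    position = v$position, effect_allele = v$effect_allele,
    other_allele = v$other_allele,
    beta = beta, se = se, n = n,
    allele_frequency = v$allele_frequency,
    stringsAsFactors = FALSE
  ))
}

#' Genetic principal components
#'
#' PCs of the column-standardized dosage matrix (samples in rows of the
#' result). Columns are orthogonal with unit variance. Zero-variance
#' variants are dropped before standardization.
#'
#' @param panel a [GenotypePanel-class].
#' @param k number of components, `0 <= k <= min(n_samples, n_snps)`;
#'   `k = 0` returns an n x 0 matrix.
#' @return numeric matrix `nSamples(panel)` x `k`.
#' @export
computePcs <- function(panel, k) {
  n <- nSamples(panel)
  m <- nVariants(panel)
  if (k < 0 || k > min(n, m)) stop("k must be in 0..min(n_samples, n_snps)")
  if (k == 0) return(matrix(0, n, 0))
  G <- dosageMatrix(panel)               # m x n
  sds <- apply(G, 1, sd)
  keep <- sds > 0
  Z <- (G[keep, , drop = FALSE] - rowMeans(G[keep, , drop = FALSE])) /
    sds[keep]
  ## eigen-decompose the smaller Gram matrix
  K <- crossprod(Z)                      # n x n sample covariance kernel
  e <- eigen(K, symmetric = TRUE)
  U <- e$vectors[, seq_len(k), drop = FALSE]
  pcs <- scale(U)                        # unit-variance, orthogonal
  attr(pcs, "scaled:center") <- NULL
  attr(pcs, "scaled:scale") <- NULL
  colnames(pcs) <- paste0("PC", seq_len(k))
  pcs
}
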