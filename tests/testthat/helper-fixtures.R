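## Shared fixtures and independent oracles used across test files.

tiny_config <- function(...) {
  simConfig(n_samples = 300, n_snps = 44, n_chromosomes = 22,
            ld_block_size = 2, seed = 1, ...)
}

## hand-rolled SumStats builder for toys
make_sumstats <- function(beta, se, chromosome = 1L, n = 1000,
                          effect = "A", other = "G",
                          ids = paste0("v", seq_along(beta)),
                          position = seq_along(beta), af = 0.3) {
  SumStats(data.frame(
    variant_id = ids, chromosome = chromosome, position = position,
    effect_allele = effect, other_allele = other,
    beta = beta, se = se, n = n, allele_frequency = af,
    stringsAsFactors = FALSE))
}

## identity-LD block set over the given ids
identity_ld <- function(ids, block_size = length(ids), chromosome = 1L) {
  starts <- seq(1, length(ids), by = block_size)
  blocks <- lapply(starts, function(s)
    ids[s:min(length(ids), s + block_size - 1)])
  new("LDBlockSet", ids = blocks,
      mats = lapply(blocks, function(b) diag(length(b))),
      chromosome = rep(as.integer(chromosome), length(blocks)))
}

## independent AUROC oracle: exhaustive pair enumeration, ties half credit
auroc_bruteforce <- function(labels, scores) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  tot <- 0
  for (a in cases) for (b in controls)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(controls))
}

## independent per-SNP OLS oracle: direct normal-equations solve of the
## joint model phenotype ~ intercept + covariates + dosage
gwas_bruteforce <- function(G, y, covariates = NULL) {
  n <- length(y)
  out <- data.frame(beta = numeric(nrow(G)), se = numeric(nrow(G)))
  for (j in seq_len(nrow(G))) {
    X <- cbind(1, covariates, G[j, ])
    XtX <- crossprod(X)
    bhat <- solve(XtX, crossprod(X, y))
    res <- y - X %*% bhat
    s2 <- sum(res^2) / (n - ncol(X))
    vc <- s2 * solve(XtX)
    out$beta[j] <- bhat[ncol(X)]
    out$se[j] <- sqrt(vc[ncol(X), ncol(X)])
  }
  out
}

## independent greedy clumping oracle: literal replay of the rule
clump_bruteforce <- function(ss_df, ld, r2_max, p_max) {
  ord <- order(ss_df$p, ss_df$chromosome, ss_df$position)
  kept <- character(0)
  blk <- function(id) {
    for (i in seq_along(blockIds(ld)))
      if (id %in% blockIds(ld)[[i]]) return(i)
    NA_integer_
  }
  for (i in ord) {
    id <- ss_df$variant_id[i]
    b <- blk(id)
    drop <- FALSE
    if (!is.na(b)) {
      ids_b <- blockIds(ld)[[b]]
      for (k in kept[kept %in% ids_b]) {
        r <- blockMatrices(ld)[[b]][match(id, ids_b), match(k, ids_b)]
        if (r^2 > r2_max) drop <- TRUE
      }
    }
    if (!drop) kept <- c(kept, id)
  }
  kept[kept %in% ss_df$variant_id[ss_df$p <= p_max]]
}
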