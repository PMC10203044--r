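## Multi-trait meta-analysis of cohort summary statistics (moment-based
## generalized least squares over a genetic covariance Omega and a
## sampling covariance Sigma), plus the two-stage union assembly for
## variants missing from some cohorts.

#' Align cohorts to a shared variant universe
#'
#' Matches variants across cohorts by id, flips the beta sign (and allele
#' frequency) where effect/other alleles are swapped relative to the first
#' cohort, and drops variants whose allele pairs do not match under either
#' orientation. Only variants present in every cohort are retained.
#' Aligning an already-aligned set is a no-op.
#'
#' @param inputs list of [SumStats-class], optionally named with cohort
#'   labels.
#' @return a `MetaInputs` (S3): matrices `beta`, `se` (variants x
#'   cohorts), `n` matrix, variant metadata, and `n_dropped` (allele
#'   mismatches).
#' @export
alignAlleles <- function(inputs) {
  stopifnot(length(inputs) >= 1)
  dfs <- lapply(inputs, as.data.frame)
  for (i in seq_along(dfs))
    if (anyDuplicated(dfs[[i]]$variant_id))
      stop("duplicate variant ids in cohort ", i)
  ids <- Reduce(intersect, lapply(dfs, `[[`, "variant_id"))
  ref <- dfs[[1]][match(ids, dfs[[1]]$variant_id), , drop = FALSE]
  k <- length(dfs)
  beta <- se <- nmat <- matrix(NA_real_, length(ids), k)
  drop_mask <- rep(FALSE, length(ids))
  for (i in seq_len(k)) {
    d <- dfs[[i]][match(ids, dfs[[i]]$variant_id), , drop = FALSE]
    same <- d$effect_allele == ref$effect_allele &
      d$other_allele == ref$other_allele
    swap <- d$effect_allele == ref$other_allele &
      d$other_allele == ref$effect_allele
    drop_mask <- drop_mask | !(same | swap)
    beta[, i] <- ifelse(swap, -d$beta, d$beta)
    se[, i] <- d$se
    nmat[, i] <- d$n
  }
  keep <- !drop_mask
  labels <- names(inputs)
  if (is.null(labels)) labels <- paste0("cohort", seq_len(k))
  out <- list(
    beta = beta[keep, , drop = FALSE],
    se = se[keep, , drop = FALSE],
    n = nmat[keep, , drop = FALSE],
    variants = ref[keep, c("variant_id", "chromosome", "position",
                           "effect_allele", "other_allele",
                           "allele_frequency")],
    labels = labels,
    n_dropped = sum(drop_mask)
  )
  class(out) <- "MetaInputs"
  out
}

#' @export
print.MetaInputs <- function(x, ...) {
  cat("MetaInputs:", nrow(x$beta), "aligned variants x", ncol(x$beta),
      "cohorts (", x$n_dropped, "dropped on allele mismatch )\n")
  invisible(x)
}

## moment estimator of the genetic effect covariance: mean beta cross
## products minus the mean sampling covariance, projected to nearest PSD
.estimate_omega <- function(beta, se) {
  k <- ncol(beta)
  omega <- crossprod(beta) / nrow(beta)
  diag(omega) <- diag(omega) - colMeans(se^2)
  e <- eigen((omega + t(omega)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% diag(vals, k) %*% t(e$vectors)
}

#' Multi-trait meta-analysis
#'
#' Per-variant generalized-least-squares combination of the cohort effect
#' estimates: with genetic covariance `Omega` (moment-estimated from beta
#' cross-products when not supplied) and per-variant sampling covariance
#' `Sigma = diag(se^2)` (cohorts are non-overlapping), the estimator for
#' the target trait is
#' `beta* = w' A^-1 beta / (w' A^-1 w)` with `w = Omega[, t]/Omega[t, t]`
#' and `A = Omega - w w' Omega[t, t] + Sigma`, with standard error
#' `1/sqrt(w' A^-1 w)`. A single cohort passes through unchanged; a
#' singular combined covariance falls back to inverse-variance weighting
#' for that variant with a warning.
#'
#' @param meta a `MetaInputs` from [alignAlleles()].
#' @param omega optional genetic covariance matrix (traits x traits),
#'   mainly for tests.
#' @param target index of the trait whose updated statistics are returned.
#' @return a [SumStats-class].
#' @export
mtagMeta <- function(meta, omega = NULL, target = 1L) {
  stopifnot(inherits(meta, "MetaInputs"))
  k <- ncol(meta$beta)
  m <- nrow(meta$beta)
  if (m < 1) stop("no aligned variants")
  if (k == 1) {
    out <- meta$variants
    out$beta <- meta$beta[, 1]
    out$se <- meta$se[, 1]
    out$n <- meta$n[, 1]
    return(SumStats(out))
  }
  if (is.null(omega)) omega <- .estimate_omega(meta$beta, meta$se)
  stopifnot(nrow(omega) == k, ncol(omega) == k)
  w <- omega[, target] / omega[target, target]
  resid_omega <- omega - tcrossprod(w) * omega[target, target]
  beta_out <- se_out <- numeric(m)
  n_fallback <- 0L
  for (j in seq_len(m)) {
    A <- resid_omega + diag(meta$se[j, ]^2, k)
    Ainv_w <- tryCatch(solve(A, w), error = function(e) NULL)
    if (is.null(Ainv_w)) {
      n_fallback <- n_fallback + 1L
      iv <- 1 / meta$se[j, ]^2
      beta_out[j] <- sum(iv * meta$beta[j, ]) / sum(iv)
      se_out[j] <- sqrt(1 / sum(iv))
    } else {
      denom <- sum(w * Ainv_w)
      beta_out[j] <- sum(Ainv_w * meta$beta[j, ]) / denom
      se_out[j] <- sqrt(1 / denom)
    }
  }
  if (n_fallback > 0)
    warning(n_fallback,
            " variant(s) fell back to inverse-variance weighting")
  out <- meta$variants
  out$beta <- beta_out
  out$se <- se_out
  out$n <- round(rowSums(meta$n))
  SumStats(out)
}

#' Two-stage union assembly
#'
#' Combines the all-cohort meta-analysis with a subset meta-analysis for
#' variants missing from some cohorts: the output is the full-meta rows
#' plus the subset-meta rows restricted to `subset_only_ids`. Every output
#' variant is traceable to exactly one source.
#'
#' @param meta_full [SumStats-class] from the all-cohort meta-analysis.
#' @param meta_subset [SumStats-class] from the subset meta-analysis.
#' @param subset_only_ids variant ids present only in the subset run; must
#'   be disjoint from `meta_full` ids and contained in `meta_subset` ids.
#' @return a [SumStats-class] with `nrow(meta_full) +
#'   length(subset_only_ids)` rows.
#' @export
assembleUnion <- function(meta_full, meta_subset, subset_only_ids) {
  full <- as.data.frame(meta_full)
  sub <- as.data.frame(meta_subset)
  overlap <- intersect(subset_only_ids, full$variant_id)
  if (length(overlap))
    stop("subset_only_ids overlap meta_full: ",
         paste(head(overlap, 5), collapse = ", "),
         if (length(overlap) > 5) " ...")
  missing <- setdiff(subset_only_ids, sub$variant_id)
  if (length(missing))
    stop("subset_only_ids absent from meta_subset: ",
         paste(head(missing, 5), collapse = ", "))
  add <- sub[match(subset_only_ids, sub$variant_id), , drop = FALSE]
  out <- rbind(full, add)
  out <- out[order(out$chromosome, out$position, out$variant_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  SumStats(out)
}
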