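## Myopic macular degeneration (MMD) analysis: family-aware five-tranche
## cross-fitted PGS, worse-eye META-PM coding, severe indicator, nested
## standard/Firth logistic models, prevalence arithmetic.

.grade_levels <- c("C0", "C2", "C3", "C4")

#' Family-aware tranche partition
#'
#' Families are shuffled (seeded) and greedily assigned to the currently
#' smallest tranche, so every family lies wholly within one tranche and
#' tranche sizes stay approximately equal. A family larger than
#' `(1 + tolerance) * n/k` triggers a warning but is still assigned.
#'
#' @param cohort cohort data.frame with `family_id`.
#' @param k number of tranches (default 5).
#' @param seed shuffle seed.
#' @param tolerance allowed relative deviation of tranche sizes (default
#'   0.1).
#' @return a `TranchePartition` (S3): integer tranche label per row.
#' @export
partitionTranches <- function(cohort, k = 5, seed = 1, tolerance = 0.1) {
  if (!"family_id" %in% names(cohort)) stop("cohort lacks family_id")
  n <- nrow(cohort)
  fam <- split(seq_len(n), cohort$family_id)
  sizes <- lengths(fam)
  if (any(sizes > n / k * (1 + tolerance)))
    warning("a family exceeds the tranche-size tolerance; ",
            "assigned anyway")
  set.seed(seed)
  ord <- sample(seq_along(fam))
  tr_size <- numeric(k)
  tranche <- integer(n)
  for (fi in ord) {
    t <- which.min(tr_size)
    tranche[fam[[fi]]] <- t
    tr_size[t] <- tr_size[t] + sizes[fi]
  }
  out <- list(tranche = tranche, k = k, sizes = tr_size,
              family_id = cohort$family_id)
  class(out) <- "TranchePartition"
  out
}

#' @export
print.TranchePartition <- function(x, ...) {
  cat("TranchePartition:", x$k, "tranches, sizes",
      paste(x$sizes, collapse = "/"), "\n")
  invisible(x)
}

#' Cross-fitted PGS
#'
#' For each tranche t, the full derivation (GWAS on all other tranches,
#' optional meta-analysis with fixed external summary statistics,
#' shrinkage with frozen parameters) is run without tranche t, and
#' tranche t is then scored. Every participant's score thus derives from
#' a model never trained on them or their relatives.
#'
#' @param panel a [GenotypePanel-class] covering the cohort.
#' @param cohort cohort data.frame (row-aligned with panel samples) with
#'   the phenotype column.
#' @param partition a `TranchePartition` from [partitionTranches()].
#' @param phenotype name of the phenotype column (default "avSER").
#' @param covariates covariate matrix (no intercept) or NULL.
#' @param external_sumstats list of fixed [SumStats-class] reused across
#'   folds (may be empty).
#' @param method "marginal" (single-factor shrink), "gibbs"
#'   (point-normal, one frozen cell), or "clump".
#' @param h2,p_causal,sparse frozen shrinkage parameters.
#' @param ld [LDBlockSet-class] for gibbs/clump (built from the panel
#'   when NULL).
#' @param r2_max,p_max clumping thresholds.
#' @param n_iter,burn_in,seed Gibbs settings.
#' @return numeric per-sample cross-fitted score.
#' @export
crossfitPgs <- function(panel, cohort, partition, phenotype = "avSER",
                        covariates = NULL, external_sumstats = list(),
                        method = c("marginal", "gibbs", "clump"),
                        h2 = 0.3, p_causal = 0.1, sparse = TRUE,
                        ld = NULL, r2_max = 0.5, p_max = 0.1,
                        n_iter = 200, burn_in = 50, seed = 1) {
  method <- match.arg(method)
  stopifnot(inherits(partition, "TranchePartition"),
            nrow(cohort) == nSamples(panel))
  if (partition$k < 2)
    stop("cross-fitting requires at least 2 tranches; ",
         "training and scoring on the same tranche is forbidden")
  y <- cohort[[phenotype]]
  if (is.null(y)) stop("phenotype column not found: ", phenotype)
  if (method %in% c("gibbs", "clump") && is.null(ld))
    ld <- buildLdBlocks(panel, block_size = 10)
  score <- numeric(nrow(cohort))
  for (t in seq_len(partition$k)) {
    test_idx <- which(partition$tranche == t)
    train_idx <- which(partition$tranche != t)
    gwas <- runGwas(panel[, train_idx], y[train_idx],
                    if (is.null(covariates)) NULL
                    else covariates[train_idx, , drop = FALSE])
    ss <- if (length(external_sumstats)) {
      mtagMeta(alignAlleles(c(list(gwas), external_sumstats)))
    } else gwas
    w <- switch(method,
      marginal = {
        df <- as.data.frame(ss)
        c_shrink <- 1 / (1 + nrow(df) / (stats::median(df$n) * h2))
        WeightVector(data.frame(
          variant_id = df$variant_id, chromosome = df$chromosome,
          effect_allele = df$effect_allele,
          weight = c_shrink * df$beta, stringsAsFactors = FALSE),
          provenance = list(method = "marginal", h2 = h2))
      },
      gibbs = gibbsGrid(ss, ld,
                        shrinkGrid(h2 = h2, p_causal = p_causal,
                                   sparse = sparse, n_iter = n_iter,
                                   burn_in = burn_in,
                                   seed = seed + t))[[1]],
      clump = clumpThreshold(ss, ld, r2_max = r2_max, p_max = p_max)
    )
    score[test_idx] <- scoreSamples(panel[, test_idx], w)
  }
  score
}

#' Worse-eye META-PM grade
#'
#' The participant grade is the worse of the two eyes under the ordering
#' C0 < C2 < C3 < C4; a participant with one missing eye uses the other.
#'
#' @param right,left character vectors of per-eye grades (NA = missing).
#' @return character vector of participant grades.
#' @export
worseEye <- function(right, left) {
  stopifnot(length(right) == length(left))
  ok <- function(g) is.na(g) | g %in% .grade_levels
  if (!all(ok(right)) || !all(ok(left)))
    stop("grades must be in ", paste(.grade_levels, collapse = ", "))
  if (any(is.na(right) & is.na(left)))
    stop("both eyes missing for some participant(s)")
  r <- match(right, .grade_levels)
  l <- match(left, .grade_levels)
  .grade_levels[pmax(r, l, na.rm = TRUE)]
}

#' Severe-MMD indicator
#'
#' C3 (patchy atrophy) and C4 (macular atrophy) are "severe"; C0 and C2
#' are "normal" (diffuse atrophy is grouped with no maculopathy because
#' its grading is unreliable).
#'
#' @param grade character vector of META-PM grades.
#' @return character vector, "severe" or "normal".
#' @export
severeIndicator <- function(grade) {
  if (!all(grade %in% .grade_levels))
    stop("unknown grade(s): ",
         paste(unique(grade[!grade %in% .grade_levels]), collapse = ", "))
  ifelse(grade %in% c("C3", "C4"), "severe", "normal")
}

#' Firth bias-reduced logistic regression
#'
#' Penalized-likelihood logistic fit with the Jeffreys-prior score
#' modification: the score is `X'(y - p + h (1/2 - p))` with `h` the
#' leverages of the weighted design, solved by Newton iteration with step
#' halving. Returns finite estimates under separation.
#'
#' @param X design matrix including the intercept column.
#' @param y binary response.
#' @param maxit,tol iteration control.
#' @return list: `coefficients`, `vcov` (inverse penalized information),
#'   `converged`, `iterations`.
#' @export
firthLogistic <- function(X, y, maxit = 100, tol = 1e-8) {
  X <- as.matrix(X)
  beta <- rep(0, ncol(X))
  loglik_pen <- function(b) {
    eta <- drop(X %*% b)
    p <- plogis(eta)
    W <- p * (1 - p)
    info <- crossprod(X, X * W)
    sum(y * eta - log1p(exp(eta))) + 0.5 * determinant(info)$modulus
  }
  ll <- loglik_pen(beta)
  it <- 0
  converged <- FALSE
  while (it < maxit) {
    it <- it + 1
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    W <- p * (1 - p)
    info <- crossprod(X, X * W)
    info_inv <- solve(info)
    h <- rowSums((X %*% info_inv) * X) * W
    U <- drop(crossprod(X, y - p + h * (0.5 - p)))
    delta <- drop(info_inv %*% U)
    step <- 1
    repeat {
      cand <- beta + step * delta
      ll_new <- loglik_pen(cand)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      step <- step / 2
      if (step < 1e-6) break
    }
    beta <- beta + step * delta
    ll <- loglik_pen(beta)
    if (max(abs(step * delta)) < tol) {
      converged <- TRUE
      break
    }
  }
  eta <- drop(X %*% beta)
  W <- plogis(eta) * (1 - plogis(eta))
  vc <- solve(crossprod(X, X * W))
  names(beta) <- colnames(X)
  dimnames(vc) <- list(colnames(X), colnames(X))
  list(coefficients = beta, vcov = vc, converged = converged,
       iterations = it)
}

#' Nested logistic models for severe MMD
#'
#' Multivariable logistic regression of the severe-MMD indicator on the
#' standardized PGS, covariates, and optionally refractive error. The SER
#' exposure is `-avSER` (per diopter more negative), so a positive
#' coefficient reads as increased risk with more myopia. Wald CIs
#' throughout. `firth = TRUE` uses the Jeffreys-penalized fit, advisable
#' with few cases or separation.
#'
#' @param outcome binary vector (1 = severe) or "severe"/"normal"
#'   character.
#' @param pgs raw or standardized score (standardized internally).
#' @param avSER refractive error (diopters).
#' @param covariates covariate matrix or NULL.
#' @param include_ser include refractive error as a covariate?
#' @param firth use Firth bias-reduced fitting?
#' @return an `MmdResult` (S3).
#' @export
logisticAssoc <- function(outcome, pgs, avSER, covariates = NULL,
                          include_ser = TRUE, firth = FALSE) {
  if (is.character(outcome)) outcome <- as.integer(outcome == "severe")
  outcome <- as.integer(outcome)
  if (length(unique(outcome)) < 2)
    stop("both outcome classes must be present")
  z <- standardizePgs(pgs)
  ser_neg <- -avSER
  X <- cbind(`(Intercept)` = 1, pgs = z)
  if (include_ser) X <- cbind(X, ser_neg = ser_neg)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  if (firth) {
    fit <- firthLogistic(X, outcome)
    if (!fit$converged) warning("Firth fit did not converge")
    est <- fit$coefficients
    se <- sqrt(diag(fit$vcov))
  } else {
    gfit <- stats::glm.fit(X, outcome, family = stats::binomial())
    if (!gfit$converged)
      warning("glm did not converge; consider firth = TRUE")
    est <- gfit$coefficients
    W <- gfit$weights
    se <- sqrt(diag(solve(crossprod(X, X * W))))
    names(se) <- names(est)
  }
  ci <- function(term) exp(est[term] + c(-1, 1) * qnorm(0.975) * se[term])
  pval <- function(term) 2 * pnorm(-abs(est[term] / se[term]))
  out <- list(
    or_pgs = unname(exp(est["pgs"])),
    ci_pgs = unname(ci("pgs")),
    p_pgs = unname(pval("pgs")),
    or_ser = if (include_ser) unname(exp(est["ser_neg"])) else NULL,
    ci_ser = if (include_ser) unname(ci("ser_neg")) else NULL,
    p_ser = if (include_ser) unname(pval("ser_neg")) else NULL,
    include_ser = include_ser, firth = firth,
    n_cases = sum(outcome == 1), n_controls = sum(outcome == 0),
    coefficients = est, se = se
  )
  class(out) <- "MmdResult"
  out
}

#' @export
print.MmdResult <- function(x, ...) {
  cat("MmdResult (", x$n_cases, "cases /", x$n_controls, "controls,",
      if (x$firth) "Firth" else "standard", "logistic,",
      if (x$include_ser) "SER-adjusted" else "unadjusted", ")\n")
  cat(sprintf("  OR per SD of PGS = %.3f (%.3f-%.3f), p = %.3g\n",
              x$or_pgs, x$ci_pgs[1], x$ci_pgs[2], x$p_pgs))
  if (x$include_ser)
    cat(sprintf(
      "  OR per diopter more negative SER = %.3f (%.3f-%.3f), p = %.3g\n",
      x$or_ser, x$ci_ser[1], x$ci_ser[2], x$p_ser))
  invisible(x)
}

#' Prevalence as a rounded percentage
#'
#' @param count,n case count and denominator (`0 <= count <= n`, n > 0).
#' @param decimals decimal places.
#' @return `100 * count / n`, rounded.
#' @examples
#' prevalencePct(169, 75869, 2)  # 0.22
#' @export
prevalencePct <- function(count, n, decimals = 2) {
  if (n <= 0) stop("n must be positive")
  if (count < 0 || count > n) stop("count must be in 0..n")
  round(100 * count / n, decimals)
}
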