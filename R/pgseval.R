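## Evaluation battery: refraction categories, standardization, incremental
## R2 and AUROC with bootstrap CIs, ROC comparison, tail odds ratios,
## decile risk, relative-performance arithmetic, trajectory bands.

#' Refraction category flags
#'
#' Boundary-inclusive classification of avSER (diopters): myopia <= -0.50,
#' moderate myopia <= -3.00, HM5 <= -5.00, HM6 <= -6.00, moderate
#' hyperopia >= +3.00. The high-myopia flags are nested (HM6 implies HM5
#' implies moderate myopia implies myopia), and moderate hyperopia is
#' exclusive of myopia.
#'
#' @param avSER numeric vector of avSER in diopters (finite).
#' @return data.frame of logical columns `myopia`, `moderate_myopia`,
#'   `moderate_hyperopia`, `hm5`, `hm6`.
#' @export
classifyRefraction <- function(avSER) {
  if (any(!is.finite(avSER))) stop("avSER must be finite")
  data.frame(
    myopia = avSER <= -0.50,
    moderate_myopia = avSER <= -3.00,
    moderate_hyperopia = avSER >= 3.00,
    hm5 = avSER <= -5.00,
    hm6 = avSER <= -6.00
  )
}

#' Standardize a PGS within groups
#'
#' Mean 0, SD 1 within each group (e.g. ancestry); with a single group
#' this is the global z-score.
#'
#' @param scores numeric vector.
#' @param groups grouping factor/vector (NULL = one group).
#' @return numeric vector of z-scores.
#' @export
standardizePgs <- function(scores, groups = NULL) {
  if (is.null(groups)) groups <- rep(1L, length(scores))
  stopifnot(length(groups) == length(scores))
  out <- numeric(length(scores))
  for (g in unique(groups)) {
    i <- which(groups == g)
    if (length(i) < 2) stop("group ", g, " has fewer than 2 members")
    s <- sd(scores[i])
    if (s == 0) stop("group ", g, " has zero variance")
    out[i] <- (scores[i] - mean(scores[i])) / s
  }
  out
}

#' Incremental adjusted R-squared with bootstrap CI
#'
#' Difference of adjusted R-squared between the full model (covariates +
#' score) and the baseline model (covariates only). The point estimate is
#' the bootstrap median and the CI the 2.5th/97.5th percentiles over
#' `n_boot` resamples of participants; deterministic given `seed`.
#'
#' @param pheno,score aligned numeric vectors.
#' @param covariates covariate matrix (no intercept) or NULL.
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed RNG seed.
#' @return list: `estimate` (bootstrap median), `ci` (length 2),
#'   `point` (no-resampling value), `n_boot`.
#' @export
incrementalR2 <- function(pheno, score, covariates = NULL, n_boot = 2000,
                          seed = 1) {
  n <- length(pheno)
  stopifnot(length(score) == n)
  if (!is.null(covariates)) covariates <- as.matrix(covariates)
  p <- if (is.null(covariates)) 0 else ncol(covariates)
  if (n < p + 3) stop("too few observations for the covariate count")
  point <- .incremental_r2_point(pheno, score, covariates)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    .incremental_r2_point(pheno[i], score[i],
                          if (is.null(covariates)) NULL
                          else covariates[i, , drop = FALSE])
  }, numeric(1))
  list(estimate = stats::median(boots),
       ci = unname(stats::quantile(boots, c(0.025, 0.975))),
       point = point, n_boot = n_boot)
}

## midrank (Mann-Whitney) AUROC; ties get half credit
.auroc_point <- function(labels, scores) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUROC with bootstrap CI
#'
#' Midrank (Mann-Whitney) AUROC: the probability that a random case
#' outranks a random control, ties counted half. The CI is a stratified
#' percentile bootstrap (cases and controls resampled separately, so both
#' classes persist in every replicate); deterministic given `seed`.
#'
#' @param labels binary vector (1 = case); both classes must be present.
#' @param scores numeric vector.
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed RNG seed.
#' @return list: `auroc`, `ci`, `n_boot`.
#' @export
aurocCI <- function(labels, scores, n_boot = 2000, seed = 1) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("both classes must be present")
  point <- .auroc_point(labels, scores)
  i1 <- which(labels == 1)
  i0 <- which(labels == 0)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    j <- c(sample(i1, length(i1), replace = TRUE),
           sample(i0, length(i0), replace = TRUE))
    .auroc_point(labels[j], scores[j])
  }, numeric(1))
  list(auroc = point,
       ci = unname(stats::quantile(boots, c(0.025, 0.975))),
       n_boot = n_boot)
}

#' Paired bootstrap comparison of two AUROCs
#'
#' Both scores are evaluated on the same participants; the test statistic
#' is the observed AUROC difference divided by the bootstrap SD of the
#' difference, referred to the standard normal (two-sided).
#'
#' @param labels shared binary labels.
#' @param scores1,scores2 the two scores.
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed.
#' @return list: `auroc1`, `auroc2`, `difference`, `statistic`, `p`.
#' @export
compareAuroc <- function(labels, scores1, scores2, n_boot = 2000,
                         seed = 1) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  a1 <- .auroc_point(labels, scores1)
  a2 <- .auroc_point(labels, scores2)
  i1 <- which(labels == 1)
  i0 <- which(labels == 0)
  set.seed(seed)
  d <- vapply(seq_len(n_boot), function(b) {
    j <- c(sample(i1, length(i1), replace = TRUE),
           sample(i0, length(i0), replace = TRUE))
    .auroc_point(labels[j], scores1[j]) -
      .auroc_point(labels[j], scores2[j])
  }, numeric(1))
  s <- sd(d)
  stat <- if (s == 0) 0 else (a1 - a2) / s
  list(auroc1 = a1, auroc2 = a2, difference = a1 - a2, statistic = stat,
       p = 2 * pnorm(-abs(stat)))
}

#' Tail odds ratio
#'
#' 2x2 odds ratio of tail membership (lowest or highest `tail` fraction of
#' the score) against case status, with a Wald CI on the log odds ratio
#' and the Haldane-Anscombe 0.5 correction applied to all cells when any
#' cell is zero.
#'
#' @param zscores standardized scores.
#' @param labels binary case labels.
#' @param tail tail fraction (e.g. 0.05, 0.10, 0.25).
#' @param side "low" (most myopia-susceptible tail) or "high".
#' @return list: `or`, `ci`, `table` (a, b, c, d).
#' @export
tailOr <- function(zscores, labels, tail = 0.05,
                   side = c("low", "high")) {
  side <- match.arg(side)
  labels <- as.integer(labels)
  if (sum(labels == 1) < 1 || sum(labels == 0) < 1)
    stop("need at least one case and one control")
  thr <- stats::quantile(zscores, if (side == "low") tail else 1 - tail)
  in_tail <- if (side == "low") zscores <= thr else zscores >= thr
  a <- sum(in_tail & labels == 1)
  b <- sum(in_tail & labels == 0)
  cc <- sum(!in_tail & labels == 1)
  d <- sum(!in_tail & labels == 0)
  cells <- c(a = a, b = b, c = cc, d = d)
  if (any(cells == 0)) cells <- cells + 0.5
  if (any(cells == 0.5 & c(a, b, cc, d) + 0.5 != cells))
    stop("degenerate 2x2 table")
  or <- (cells["a"] * cells["d"]) / (cells["b"] * cells["c"])
  se <- sqrt(sum(1 / cells))
  ci <- exp(log(or) + c(-1, 1) * qnorm(0.975) * se)
  list(or = unname(or), ci = unname(ci),
       table = c(a = a, b = b, c = cc, d = d))
}

#' Absolute risk by score decile
#'
#' Deciles by score rank (stable order, ties to the lower decile);
#' per-decile case proportion with exact binomial CI, plus the overall
#' prevalence reference.
#'
#' @param zscores standardized scores (n >= 10).
#' @param labels binary case labels.
#' @return list: `table` (decile, n, cases, prevalence, ci_low, ci_high),
#'   `overall_prevalence`.
#' @export
decileRisk <- function(zscores, labels) {
  n <- length(zscores)
  if (n < 10) stop("need at least 10 observations")
  labels <- as.integer(labels)
  r <- rank(zscores, ties.method = "first")
  dec <- ceiling(10 * r / n)
  rows <- lapply(1:10, function(d) {
    i <- which(dec == d)
    k <- sum(labels[i])
    ci <- stats::binom.test(k, length(i))$conf.int
    data.frame(decile = d, n = length(i), cases = k,
               prevalence = k / length(i),
               ci_low = ci[1], ci_high = ci[2])
  })
  list(table = do.call(rbind, rows),
       overall_prevalence = mean(labels))
}

#' Relative change between two accuracies
#'
#' `improvement` is `100 * (a - b) / b` (a = new accuracy, b =
#' reference); `decrease` is `100 * (b - a) / b` (accuracy lost relative
#' to the reference). Rounding is left to the caller.
#'
#' @param a,b accuracy values (e.g. incremental R2); the reference `b`
#'   must be positive.
#' @param type "improvement" or "decrease".
#' @return percent change (unrounded).
#' @examples
#' round(relativeChange(0.190, 0.112, "improvement"))  # 70
#' round(relativeChange(0.020, 0.190, "decrease"))     # 89
#' @export
relativeChange <- function(a, b, type = c("improvement", "decrease")) {
  type <- match.arg(type)
  if (b <= 0) stop("reference accuracy must be positive")
  if (type == "improvement") 100 * (a - b) / b else 100 * (b - a) / b
}

#' Mean refraction trajectories by PGS percentile band
#'
#' Participants are stratified into bands between consecutive PGS
#' percentiles (below the first, between adjacent cut points, above the
#' last); within each band the mean avSER at each age is reported.
#' Participants with fewer than `min_ages` non-missing measurements are
#' excluded.
#'
#' @param ages numeric vector of measurement ages (columns of
#'   `ser_matrix`).
#' @param ser_matrix participants x ages matrix of avSER (NA = missing
#'   visit).
#' @param zscores per-participant standardized PGS.
#' @param percentiles cut points in (0, 100), default c(5, 25, 50, 75,
#'   95).
#' @param min_ages minimum non-missing measurements (default 3).
#' @return data.frame: band, age, mean avSER, n.
#' @export
trajectoryBands <- function(ages, ser_matrix, zscores,
                            percentiles = c(5, 25, 50, 75, 95),
                            min_ages = 3) {
  stopifnot(ncol(ser_matrix) == length(ages),
            nrow(ser_matrix) == length(zscores))
  keep <- rowSums(!is.na(ser_matrix)) >= min_ages
  if (!any(keep)) stop("no participant has enough measurements")
  sm <- ser_matrix[keep, , drop = FALSE]
  z <- zscores[keep]
  cuts <- stats::quantile(z, sort(percentiles) / 100)
  band <- findInterval(z, cuts, left.open = TRUE) + 1L
  labels <- c(paste0("<=P", sort(percentiles)[1]),
              paste0("P", head(sort(percentiles), -1), "-P",
                     sort(percentiles)[-1]),
              paste0(">P", max(percentiles)))
  rows <- list()
  for (bi in sort(unique(band))) {
    i <- which(band == bi)
    for (ai in seq_along(ages)) {
      v <- sm[i, ai]
      rows[[length(rows) + 1L]] <- data.frame(
        band = labels[bi], age = ages[ai],
        mean_avSER = mean(v, na.rm = TRUE), n = sum(!is.na(v)))
    }
  }
  do.call(rbind, rows)
}

#' Full evaluation report for one test sample
#'
#' Incremental R2, per-category AUROC, tail odds ratios and decile risk,
#' all with bootstrap CIs where applicable.
#'
#' @param avSER phenotype vector (diopters).
#' @param score raw PGS (standardized internally within `groups`).
#' @param covariates covariate matrix or NULL.
#' @param groups standardization groups (NULL = one group).
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed.
#' @return an `EvalReport` (S3 list).
#' @export
evaluatePgs <- function(avSER, score, covariates = NULL, groups = NULL,
                        n_boot = 2000, seed = 1) {
  z <- standardizePgs(score, groups)
  cats <- classifyRefraction(avSER)
  inc <- incrementalR2(avSER, z, covariates, n_boot = n_boot, seed = seed)
  auroc <- list()
  for (nm in colnames(cats)) {
    lab <- as.integer(cats[[nm]])
    ## risk direction: myopia categories are enriched in the low tail
    s <- if (nm == "moderate_hyperopia") z else -z
    auroc[[nm]] <- if (length(unique(lab)) == 2)
      aurocCI(lab, s, n_boot = n_boot, seed = seed) else NULL
  }
  tails <- list()
  if (any(cats$hm6) && !all(cats$hm6)) {
    for (tl in c(0.05, 0.10, 0.25))
      tails[[paste0("hm6_low", tl * 100)]] <-
        tailOr(z, as.integer(cats$hm6), tail = tl, side = "low")
  }
  dec <- if (any(cats$hm6) && !all(cats$hm6))
    decileRisk(z, as.integer(cats$hm6)) else NULL
  out <- list(incremental_r2 = inc, auroc = auroc, tail_or = tails,
              decile_risk = dec, n = length(avSER), n_boot = n_boot)
  class(out) <- "EvalReport"
  out
}

#' @export
print.EvalReport <- function(x, ...) {
  cat("EvalReport (n =", x$n, ",", x$n_boot, "bootstrap replicates)\n")
  cat(sprintf("  incremental R2 = %.3f (%.3f-%.3f)\n",
              x$incremental_r2$estimate, x$incremental_r2$ci[1],
              x$incremental_r2$ci[2]))
  for (nm in names(x$auroc)) {
    a <- x$auroc[[nm]]
    if (!is.null(a))
      cat(sprintf("  AUROC %-18s = %.3f (%.3f-%.3f)\n", nm, a$auroc,
                  a$ci[1], a$ci[2]))
  }
  invisible(x)
}
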