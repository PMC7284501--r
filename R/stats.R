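#' Mean, SD and n of a group of clearances
#'
#' @param values numeric vector, at least one value.
#' @return list(mean, sd, n); sd is NA for n = 1 (sample SD with n-1
#'   denominator is undefined).
#' @examples
#' groupSummary(c(0.1, 0.3))
#' @export
groupSummary <- function(values) {
  if (length(values) < 1) stop("need at least one value")
  list(mean = mean(values),
       sd = if (length(values) >= 2) stats::sd(values) else NA_real_,
       n = length(values))
}

#' Two-sided unpaired t-test
#'
#' Student (pooled-variance) form by default, mirroring the classical
#' two-group comparison; Welch's unequal-variance form behind
#' \code{varEqual = FALSE}. Degenerate zero-variance inputs are guarded: if
#' both groups are constant the p-value is 1 for equal means and 0 (the
#' limiting value) for different means.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param varEqual pooled (TRUE, default) or Welch (FALSE).
#' @return Two-sided p-value.
#' @examples
#' twoGroupTest(c(1, 2, 3), c(2, 3, 4))
#' @export
twoGroupTest <- function(a, b, varEqual = TRUE) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    return(if (mean(a) == mean(b)) 1 else 0)
  stats::t.test(a, b, var.equal = varEqual)$p.value
}

#' One-way ANOVA with Tukey HSD multiple comparisons
#'
#' Omnibus F-test across groups followed by Tukey's honestly-significant-
#' difference adjusted p-values for every pair (Tukey-Kramer for unbalanced
#' groups). Unadjusted pairwise p-values (pooled-MSE t-tests on the same
#' error degrees of freedom) are reported alongside. If every observation is
#' identical the degenerate case is resolved as F = 0 with all p-values 1.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2).
#' @return list with \code{F}, \code{p} (omnibus), \code{df} (between,
#'   within), and \code{pairwise}: data.frame(group1, group2, diff, lwr, upr,
#'   p_raw, p_adj).
#' @examples
#' anovaTukey(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(5, 6, 7)))
#' @export
anovaTukey <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least 2 groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be named")
  if (any(vapply(groups, length, 1L) < 2))
    stop("each group needs at least 2 values")
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups), vapply(groups, length, 1L)),
                   levels = names(groups))
  k <- length(groups)
  N <- length(values)
  pairs <- utils::combn(names(groups), 2)
  if (stats::var(values) == 0) {
    pairwise <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                           diff = 0, lwr = 0, upr = 0, p_raw = 1, p_adj = 1,
                           stringsAsFactors = FALSE)
    return(list(F = 0, p = 1, df = c(k - 1, N - k), pairwise = pairwise))
  }
  d <- data.frame(y = values, g = labels)
  fit <- stats::aov(y ~ g, data = d)
  ss <- summary(fit)[[1]]
  Fstat <- ss[["F value"]][1]
  p <- ss[["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit)$g
  ## TukeyHSD orders pairs as "level2-level1"; align with our enumeration.
  tk_names <- rownames(tk)
  mse <- ss[["Mean Sq"]][2]
  dfw <- N - k
  pairwise <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                         diff = NA_real_, lwr = NA_real_, upr = NA_real_,
                         p_raw = NA_real_, p_adj = NA_real_,
                         stringsAsFactors = FALSE)
  for (j in seq_len(ncol(pairs))) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    key <- paste0(g2, "-", g1)
    krev <- paste0(g1, "-", g2)
    row <- if (key %in% tk_names) tk[key, ] else {
      r <- tk[krev, ]; c(-r[1], -r[3], -r[2], r[4])
    }
    pairwise$diff[j] <- row[1]
    pairwise$lwr[j] <- row[2]
    pairwise$upr[j] <- row[3]
    pairwise$p_adj[j] <- row[4]
    n1 <- length(groups[[g1]]); n2 <- length(groups[[g2]])
    tstat <- (mean(groups[[g2]]) - mean(groups[[g1]])) /
      sqrt(mse * (1 / n1 + 1 / n2))
    pairwise$p_raw[j] <- 2 * stats::pt(-abs(tstat), dfw)
  }
  list(F = Fstat, p = p, df = c(k - 1, dfw), pairwise = pairwise)
}

#' Fold change of group means with a bootstrap confidence interval
#'
#' The effect size used for inhibitor and genotype contrasts: the ratio of
#' the test group's mean clearance to the reference group's. Uncertainty
#' comes from a seeded bootstrap over animals, resampling each group
#' independently (stratified), with \code{nBoot} resamples. The default
#' interval is a studentized (bootstrap-t) interval on the log fold: each
#' resample's log fold is centred and scaled by its own delta-method standard
#' error, and the resulting t quantiles are applied to the observed log fold.
#' At the small group sizes typical of perfusion studies (n = 4-10) the plain
#' percentile interval is anti-conservative (the resampled means shrink the
#' variance by (n-1)/n per group), while the studentized interval holds close
#' to nominal coverage; \code{ciMethod = "percentile"} restores the simpler
#' interval. Groups where the standard error degenerates to zero collapse to
#' the point estimate.
#'
#' @param reference,test numeric vectors of per-animal values; the reference
#'   mean must be positive.
#' @param nBoot bootstrap resamples (default 10000).
#' @param seed optional seed for the bootstrap (local; does not disturb the
#'   caller's RNG state).
#' @param conf confidence level (default 0.95).
#' @param ciMethod "student-t" (default) or "percentile".
#' @param varEqual passed to \code{\link{twoGroupTest}} for the reported
#'   p-value.
#' @return One-row data.frame: group summaries, \code{fold_change},
#'   \code{fold_ci_lo}, \code{fold_ci_hi}, \code{p_value}, \code{test_name}.
#'   The p-value is NA when either group has fewer than 2 animals.
#' @examples
#' foldChange(c(0.1, 0.12, 0.09), c(0.4, 0.38, 0.45), nBoot = 1000, seed = 1)
#' @export
foldChange <- function(reference, test, nBoot = 10000, seed = NULL,
                       conf = 0.95, ciMethod = c("student-t", "percentile"),
                       varEqual = TRUE) {
  ciMethod <- match.arg(ciMethod)
  if (length(reference) < 1 || length(test) < 1)
    stop("both groups must be non-empty")
  if (mean(reference) <= 0) stop("reference mean must be positive")
  fold <- mean(test) / mean(reference)
  nr <- length(reference)
  nt <- length(test)
  alpha <- (1 - conf) / 2
  resamples <- .withSeed(seed, {
    R <- matrix(reference[sample.int(nr, nr * nBoot, replace = TRUE)],
                nrow = nr)
    Tm <- matrix(test[sample.int(nt, nt * nBoot, replace = TRUE)], nrow = nt)
    list(mr = colMeans(R), mt = colMeans(Tm),
         vr = if (nr > 1) (colSums(R^2) - nr * colMeans(R)^2) / (nr - 1)
              else rep(0, nBoot),
         vt = if (nt > 1) (colSums(Tm^2) - nt * colMeans(Tm)^2) / (nt - 1)
              else rep(0, nBoot))
  })
  seLog <- function(m1, v1, n1, m2, v2, n2)
    sqrt(v1 / (n1 * m1^2) + v2 / (n2 * m2^2))
  se_hat <- if (nr > 1 && nt > 1)
    seLog(mean(reference), stats::var(reference), nr,
          mean(test), stats::var(test), nt) else 0
  if (ciMethod == "student-t" && is.finite(se_hat) && se_hat > 0) {
    th <- log(fold)
    tstar <- (log(resamples$mt / resamples$mr) - th) /
      seLog(resamples$mr, resamples$vr, nr, resamples$mt, resamples$vt, nt)
    tq <- stats::quantile(tstar[is.finite(tstar)], c(1 - alpha, alpha),
                          names = FALSE)
    ci <- exp(c(th - tq[1] * se_hat, th - tq[2] * se_hat))
  } else if (ciMethod == "student-t") {
    ## degenerate spread: the interval collapses onto the estimate
    ci <- c(fold, fold)
  } else {
    boot <- resamples$mt / resamples$mr
    ci <- stats::quantile(boot[is.finite(boot)], c(alpha, 1 - alpha),
                          names = FALSE)
  }
  p <- if (nr >= 2 && nt >= 2) twoGroupTest(reference, test, varEqual)
       else NA_real_
  data.frame(mean_ref = mean(reference),
             sd_ref = if (nr >= 2) stats::sd(reference) else NA_real_,
             n_ref = nr,
             mean_test = mean(test),
             sd_test = if (nt >= 2) stats::sd(test) else NA_real_,
             n_test = nt,
             fold_change = fold, fold_ci_lo = ci[1], fold_ci_hi = ci[2],
             p_value = p,
             test_name = if (varEqual) "Student t" else "Welch t",
             stringsAsFactors = FALSE)
}

#' Group comparisons across a per-sample result table
#'
#' Within each stratum (by default each region), compares every level of
#' \code{compareCol} against the reference level on the chosen value column:
#' fold change of group means with a bootstrap CI for every pair, and -- when
#' the stratum has three or more levels -- a one-way ANOVA whose Tukey HSD
#' adjusted p-value replaces the pairwise t-test p. Samples flagged
#' \code{below_vascular_background} are retained (their clearance is 0, a
#' meaningful low value); flow-marker samples should not be in \code{pk}.
#'
#' @param pk data.frame from \code{\link{runPipeline}}.
#' @param compareCol column whose levels are compared (default
#'   \code{"treatment"}; use \code{"group"} for genotype or disease-state
#'   contrasts).
#' @param referenceLevel the reference level of \code{compareCol}.
#' @param stratifyBy columns defining strata (default \code{"region"}).
#' @param valueCol value column to compare (default \code{"Kin"}).
#' @param nBoot,seed,conf bootstrap settings, see \code{\link{foldChange}}.
#' @return data.frame of comparison rows (one per stratum x non-reference
#'   level), with \code{test_name} recording which test produced
#'   \code{p_value}.
#' @export
compareGroups <- function(pk, compareCol = "treatment",
                          referenceLevel = "none", stratifyBy = "region",
                          valueCol = "Kin", nBoot = 10000, seed = NULL,
                          conf = 0.95) {
  stopifnot(all(c(compareCol, stratifyBy, valueCol) %in% names(pk)))
  strata <- unique(pk[, stratifyBy, drop = FALSE])
  out <- list()
  for (srow in seq_len(nrow(strata))) {
    keep <- rep(TRUE, nrow(pk))
    for (col in stratifyBy)
      keep <- keep & pk[[col]] == strata[[col]][srow]
    sub <- pk[keep, , drop = FALSE]
    levels_here <- unique(sub[[compareCol]])
    if (!(referenceLevel %in% levels_here)) {
      warning("stratum without reference level skipped: ",
              paste(unlist(strata[srow, ]), collapse = "/"))
      next
    }
    others <- setdiff(levels_here, referenceLevel)
    if (length(others) == 0) next
    groups <- split(sub[[valueCol]], sub[[compareCol]])
    use_anova <- length(levels_here) >= 3 &&
      all(vapply(groups, length, 1L) >= 2)
    tk <- if (use_anova) anovaTukey(groups) else NULL
    for (lev in others) {
      cmp <- foldChange(groups[[referenceLevel]], groups[[lev]],
                        nBoot = nBoot, seed = seed, conf = conf)
      if (use_anova) {
        pw <- tk$pairwise
        hit <- (pw$group1 == referenceLevel & pw$group2 == lev) |
               (pw$group2 == referenceLevel & pw$group1 == lev)
        cmp$p_value <- pw$p_adj[hit][1]
        cmp$test_name <- "one-way ANOVA + Tukey HSD"
      }
      row <- data.frame(stratum = paste(unlist(strata[srow, , drop = FALSE]),
                                        collapse = "/"),
                        reference_group = referenceLevel, test_group = lev,
                        stringsAsFactors = FALSE)
      out[[length(out) + 1]] <- cbind(row, cmp)
    }
  }
  if (length(out) == 0) return(emptyComparisons())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
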