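test_that("group summaries use the sample SD and drop it at n = 1", {
  s <- groupSummary(c(0.1))
  expect_equal(s$mean, 0.1)
  expect_true(is.na(s$sd))
  expect_equal(s$n, 1)
  s <- groupSummary(c(0.1, 0.3))
  expect_equal(s$mean, 0.2)
  expect_equal(s$sd, sqrt(0.02))          # n-1 denominator
  s <- groupSummary(rep(2.5, 6))
  expect_equal(s$sd, 0)
  expect_error(groupSummary(numeric(0)), "at least one")
})

test_that("the pooled t-test matches the closed-form oracle", {
  # independent oracle: pooled-variance t computed from first principles
  pooledT <- function(a, b) {
    n1 <- length(a); n2 <- length(b)
    sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
    t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    2 * pt(-abs(t), n1 + n2 - 2)
  }
  set.seed(14)
  for (rep in 1:5) {
    a <- rnorm(5, 0, 1); b <- rnorm(7, 0.8, 1.3)
    expect_equal(twoGroupTest(a, b), pooledT(a, b), tolerance = 1e-10)
  }
  expect_equal(twoGroupTest(c(1, 2, 3), c(1, 2, 3)), 1)
  # degenerate zero-variance groups
  expect_equal(twoGroupTest(c(1, 1), c(1, 1)), 1)
  expect_equal(twoGroupTest(c(1, 1), c(2, 2)), 0)
  expect_error(twoGroupTest(1, c(1, 2)), "at least 2")
  # Welch differs from Student under unequal variance
  a <- c(1, 2, 3, 4); b <- c(10, 30, 50, 80, 100)
  expect_false(twoGroupTest(a, b) == twoGroupTest(a, b, varEqual = FALSE))
})

test_that("one-way ANOVA and Tukey HSD match a sums-of-squares oracle", {
  # worked example, checked against explicit sums of squares + ptukey
  g <- list(ctrl = c(0.10, 0.12, 0.09, 0.11, 0.10),
            ela = c(0.40, 0.35, 0.45, 0.38, 0.42),
            mk = c(0.20, 0.22, 0.19, 0.25, 0.21))
  res <- anovaTukey(g)

  vals <- unlist(g); N <- length(vals); k <- 3
  grand <- mean(vals)
  ssb <- sum(vapply(g, function(x) length(x) * (mean(x) - grand)^2, 1))
  ssw <- sum(vapply(g, function(x) sum((x - mean(x))^2), 1))
  Fref <- (ssb / (k - 1)) / (ssw / (N - k))
  pref <- pf(Fref, k - 1, N - k, lower.tail = FALSE)
  expect_equal(res$F, Fref, tolerance = 1e-8)
  expect_equal(res$p, pref, tolerance = 1e-8)

  mse <- ssw / (N - k)
  for (j in seq_len(nrow(res$pairwise))) {
    x1 <- g[[res$pairwise$group1[j]]]; x2 <- g[[res$pairwise$group2[j]]]
    se <- sqrt(mse / 2 * (1 / length(x1) + 1 / length(x2)))  # Tukey-Kramer
    q <- abs(mean(x2) - mean(x1)) / se
    expect_equal(res$pairwise$p_adj[j],
                 ptukey(q, k, N - k, lower.tail = FALSE), tolerance = 1e-8)
    traw <- abs(mean(x2) - mean(x1)) / sqrt(mse * (1/length(x1) + 1/length(x2)))
    expect_equal(res$pairwise$p_raw[j], 2 * pt(-traw, N - k),
                 tolerance = 1e-8)
  }

  # unbalanced groups go through the Kramer form without error
  g2 <- list(a = rnorm(4), b = rnorm(9), c = rnorm(6))
  expect_silent(anovaTukey(g2))
  expect_error(anovaTukey(list(a = c(1, 2))), "2 groups")
  expect_error(anovaTukey(list(a = c(1, 2), b = 3)), "at least 2 values")
})

test_that("identical groups give F = 0 with all p-values 1", {
  g <- list(a = rep(1, 4), b = rep(1, 5), c = rep(1, 3))
  res <- anovaTukey(g)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  expect_true(all(res$pairwise$p_adj == 1))
})

test_that("Tukey-adjusted p never falls below the raw pairwise p", {
  set.seed(55)
  for (rep in 1:50) {
    k <- sample(3:5, 1)
    g <- lapply(seq_len(k), function(i) rnorm(sample(4:10, 1)))
    names(g) <- paste0("g", seq_len(k))
    res <- anovaTukey(g)
    expect_true(all(res$pairwise$p_adj >= res$pairwise$p_raw - 1e-12))
  }
})

test_that("fold changes behave as ratios of group means with sane CIs", {
  a <- c(0.1, 0.12, 0.09)
  fc <- foldChange(a, a, nBoot = 2000, seed = 1)
  expect_equal(fc$fold_change, 1)
  expect_true(fc$fold_ci_lo <= 1 && 1 <= fc$fold_ci_hi)

  # zero-variance 2x shift: degenerate CI collapses onto the estimate
  fc <- foldChange(c(2, 2, 2), c(4, 4, 4), nBoot = 500, seed = 1)
  expect_equal(fc$fold_change, 2)
  expect_equal(fc$fold_ci_lo, 2)
  expect_equal(fc$fold_ci_hi, 2)

  # reciprocity of the point estimate
  b <- c(0.4, 0.37, 0.44, 0.41)
  f1 <- foldChange(a, b, nBoot = 500, seed = 2)$fold_change
  f2 <- foldChange(b, a, nBoot = 500, seed = 2)$fold_change
  expect_equal(f1 * f2, 1, tolerance = 1e-12)

  # seeded bootstrap is reproducible and leaves the global RNG alone
  set.seed(10); r1 <- runif(1)
  set.seed(10)
  c1 <- foldChange(a, b, nBoot = 1000, seed = 9)
  r2 <- runif(1)
  expect_identical(r1, r2)
  c2 <- foldChange(a, b, nBoot = 1000, seed = 9)
  expect_identical(c1, c2)

  expect_error(foldChange(c(-1, 1), b), "positive")
  expect_error(foldChange(numeric(0), b), "non-empty")
})

test_that("compareGroups assembles per-stratum comparisons with Tukey p", {
  sc <- defaultRatScenario(seed = 8)
  st <- generateStudy(sc)
  pk <- runPipeline(st$experiment, estimateFlow(st$flowExperiment))
  cmp <- compareGroups(pk, nBoot = 500, seed = 3)
  # 3 regions x 4 non-reference treatments
  expect_equal(nrow(cmp), 12)
  expect_true(all(cmp$test_name == "one-way ANOVA + Tukey HSD"))
  expect_true(all(cmp$fold_ci_lo <= cmp$fold_change + 1e-12))
  expect_true(all(cmp$fold_change <= cmp$fold_ci_hi + 1e-12))
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))
  # a two-level stratum falls back to the t-test
  two <- pk[pk$treatment %in% c("none", "elacridar"), ]
  cmp2 <- compareGroups(two, nBoot = 200, seed = 3)
  expect_true(all(cmp2$test_name == "Student t"))
  # missing reference level in a stratum is skipped with a warning per stratum
  warns <- capture_warnings(
    cmp3 <- compareGroups(pk[pk$treatment != "none", ], nBoot = 100,
                          seed = 1))
  expect_length(warns, 3)
  expect_true(all(grepl("skipped", warns)))
  expect_equal(nrow(cmp3), 0)
})
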