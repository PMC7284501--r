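test_that("an exact line is fit exactly, with closed-form OLS agreement", {
  std <- data.frame(known_fmol = c(10, 50, 250),
                    area_ratio = 0.02 * c(10, 50, 250))
  curve <- fitCalibration(std, weighting = "none")
  expect_equal(curveSlope(curve), 0.02, tolerance = 1e-12)
  expect_equal(curveIntercept(curve), 0, tolerance = 1e-12)
  expect_equal(rSquared(curve), 1, tolerance = 1e-12)
  expect_equal(loqFmol(curve), 10)

  # closed-form OLS oracle on noisy points (unweighted)
  std2 <- data.frame(known_fmol = c(10, 50, 250),
                     area_ratio = c(0.21, 1.02, 5.01))
  c2 <- fitCalibration(std2, weighting = "none")
  x <- std2$known_fmol; y <- std2$area_ratio
  bref <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  aref <- mean(y) - bref * mean(x)
  expect_equal(curveSlope(c2), bref, tolerance = 1e-10)
  expect_equal(curveIntercept(c2), aref, tolerance = 1e-10)

  # 1/x weighting matches the weighted normal equations
  c3 <- fitCalibration(std2, weighting = "1/x")
  w <- 1 / x
  xw <- sum(w * x) / sum(w); yw <- sum(w * y) / sum(w)
  bw <- sum(w * (x - xw) * (y - yw)) / sum(w * (x - xw)^2)
  expect_equal(curveSlope(c3), bw, tolerance = 1e-10)
  expect_equal(curveIntercept(c3), yw - bw * xw, tolerance = 1e-10)
})

test_that("duplicate standard levels enter the fit as replicates", {
  std <- data.frame(known_fmol = c(10, 10, 50, 50, 250, 250),
                    area_ratio = c(0.19, 0.23, 0.99, 1.05, 4.98, 5.04))
  curve <- fitCalibration(std, weighting = "none")
  x <- std$known_fmol; y <- std$area_ratio
  bref <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(curveSlope(curve), bref, tolerance = 1e-10)
  expect_equal(curve@nStandards, 6)
})

test_that("degenerate calibrations are rejected with diagnostics", {
  expect_error(fitCalibration(data.frame(known_fmol = c(10, 50),
                                         area_ratio = c(0.2, 1))),
               "3 distinct")
  down <- data.frame(known_fmol = c(10, 50, 250),
                     area_ratio = c(5, 1, 0.2))
  expect_error(fitCalibration(down), "non-positive slope")
})

test_that("quantification applies the LOQ rule and the <LOQ token", {
  std <- data.frame(known_fmol = c(5, 10, 50, 250),
                    area_ratio = 0.02 * c(5, 10, 50, 250))
  curve <- fitCalibration(std)
  expect_equal(loqFmol(curve), 5)

  # area ratio at the intercept -> amount 0 -> below LOQ
  r <- quantifyProtein(curveIntercept(curve), curve, 50)
  expect_true(r$below_loq)
  expect_identical(r$display, "<LOQ")
  expect_true(is.na(r$concentration_fmol_per_ug))

  # negative back-calculation is below LOQ too, never a negative number
  r <- quantifyProtein(curveIntercept(curve) - 0.01, curve, 50)
  expect_true(r$below_loq)
  expect_identical(r$display, "<LOQ")

  # a clean on-curve sample: 75 fmol / 50 ug = 1.5 fmol/ug
  r <- quantifyProtein(0.02 * 75, curve, 50)
  expect_false(r$below_loq)
  expect_equal(r$concentration_fmol_per_ug, 1.5, tolerance = 1e-12)

  # every numeric report corresponds to an amount >= LOQ; monotone in ratio
  ratios <- seq(0, 0.1, length.out = 60)
  res <- quantifyProtein(ratios, curve, 50)
  expect_true(all(res$amount_fmol[!res$below_loq] >= loqFmol(curve)))
  conc <- res$concentration_fmol_per_ug[!res$below_loq]
  expect_true(all(diff(conc) >= 0))
  expect_error(quantifyProtein(0.5, curve, 0), "positive")
})

test_that("the generator inverts exactly at zero noise and unbiasedly under noise", {
  sim <- generateMrmAreas(1.5, noiseCv = 0, seed = 1)
  curve <- fitCalibration(sim$standards)
  r <- quantifyProtein(sim$samples$area_ratio, curve,
                       sim$samples$digested_protein_ug)
  expect_equal(r$concentration_fmol_per_ug, 1.5, tolerance = 1e-10)

  # same seed, same tables
  s1 <- generateMrmAreas(1.5, noiseCv = 0.05, seed = 7)
  s2 <- generateMrmAreas(1.5, noiseCv = 0.05, seed = 7)
  expect_identical(s1, s2)

  # law of large numbers at fixed truth; each replicate digest carries its
  # own calibration series, so curve error averages out too
  n <- 400
  conc <- vapply(seq_len(n), function(i) {
    sim <- generateMrmAreas(1.5, noiseCv = 0.05, seed = 21000 + i)
    quantifyProtein(sim$samples$area_ratio, fitCalibration(sim$standards),
                    50)$concentration_fmol_per_ug
  }, 1)
  mc_se <- sd(conc) / sqrt(n)
  expect_lt(abs(mean(conc) - 1.5), 3 * mc_se)
})

test_that("a batch table is quantified per peptide with tokens preserved", {
  std <- data.frame(known_fmol = c(5, 10, 50, 250),
                    area_ratio = 0.02 * c(5, 10, 50, 250))
  curves <- list(pepA = fitCalibration(std))
  tab <- data.frame(sample_id = c("s1", "s2"), protein = "BCRP",
                    peptide = "pepA", area_ratio = c(1.5, 0.001),
                    digested_protein_ug = 50,
                    species_specificity = "human+rat shared",
                    stringsAsFactors = FALSE)
  res <- quantifyTable(tab, curves)
  expect_equal(nrow(res), 2)
  expect_false(res$below_loq[1])
  expect_identical(res$display[2], "<LOQ")
  expect_identical(res$species_specificity[1], "human+rat shared")
  expect_error(quantifyTable(transform(tab, peptide = "pepX", protein = "X"),
                             curves), "no calibration curve")
})
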