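test_that("each clearance equation matches hand arithmetic", {
  # vascular volume
  expect_equal(vascularVolume(0, 100), 0)
  expect_equal(vascularVolume(1200, 100), 12)
  expect_error(vascularVolume(10, 0), "positive")
  # scale identity: Xstar = c * CstarPerf gives Vv = c
  for (c in c(0.5, 3, 40))
    expect_equal(vascularVolume(c * 222, 222), c)

  # vascular correction keeps the sign
  expect_equal(correctedTissueAmount(500, 12, 10), 380)
  expect_equal(correctedTissueAmount(120, 12, 10), 0)
  expect_equal(correctedTissueAmount(100, 12, 10), -20)
  expect_error(correctedTissueAmount(100, -1, 10), "non-negative")

  # distribution volume clamps negatives for reporting
  expect_equal(distributionVolume(380, 10), 38)
  expect_equal(distributionVolume(0, 10), 0)
  expect_equal(distributionVolume(-20, 10), 0)

  # clearance
  expect_equal(transportClearance(12, 120), 0.10)
  expect_equal(transportClearance(0, 120), 0)
  expect_equal(transportClearance(21.6, 120), 0.18)
  expect_error(transportClearance(12, 0), "positive")

  # extraction and the 30 percent rule (>= 30 is flow dependent)
  expect_equal(extraction(0.10, 5.0), 2.0)
  expect_false(isFlowDependent(extraction(0.10, 5.0)))
  expect_equal(extraction(5, 5), 100)
  expect_true(isFlowDependent(100))
  expect_equal(extraction(0, 5), 0)
  expect_true(isFlowDependent(30))
  expect_false(isFlowDependent(29.999))
  expect_error(extraction(1, 0), "positive")
})

test_that("flow is the per-region mean of flow-marker clearances", {
  # two diazepam samples engineered to Kin 3.0 and 5.0 (uL/s/g)
  perf <- defaultPerfusate(Cperf = 600, CstarPerf = 222)
  tab <- makeSampleTable(n = 2, tracer = "diazepam", T = 60,
                         Xstar = c(0, 0),
                         Xtot = c(3.0 * 60 * 600, 5.0 * 60 * 600))
  fl <- estimateFlow(PerfusionExperiment(tab, perf))
  expect_equal(fl$F, 4.0)
  expect_equal(fl$n, 2)

  one <- estimateFlow(PerfusionExperiment(tab[1, ], perf))
  expect_equal(one$F, 3.0)

  expect_error(estimateFlow(PerfusionExperiment(makeSampleTable(1), perf)),
               "diazepam")
})

test_that("samples without a flow reference get a flag, not E = 0", {
  perf <- defaultPerfusate()
  ex <- PerfusionExperiment(makeSampleTable(2,
    region = c("cerebrum", "brainstem")), perf)
  flow <- data.frame(region = "cerebrum", species = "rat", F = 5, n = 3)
  pk <- runPipeline(ex, flow)
  expect_false(is.na(pk$E[1]))
  expect_true(is.na(pk$E[2]))
  expect_match(pk$flags[2], "missing_flow_reference")
  expect_false(grepl("missing_flow_reference", pk$flags[1]))
})

test_that("the pipeline equals a naive per-sample reference on random batches", {
  tab <- randomSamples(1000, seed = 202)
  perf <- defaultPerfusate(Cperf = 660, CstarPerf = 222)
  flow <- data.frame(region = rep(c("cerebrum", "cerebellum", "brainstem"), 2),
                     species = rep(c("rat", "mouse"), each = 3),
                     F = c(30, 15, 10, 20, 12, 8), n = 5)
  pk <- runPipeline(PerfusionExperiment(tab, perf), flow)
  ref <- naivePK(tab, 660, 222, flow)
  expect_equal(pk$Vv, ref$Vv, tolerance = 1e-12)
  expect_equal(pk$Xtissue, ref$Xtissue, tolerance = 1e-12)
  expect_equal(pk$Vtissue, ref$Vtissue, tolerance = 1e-12)
  expect_equal(pk$Kin, ref$Kin, tolerance = 1e-12)
  expect_equal(pk$E, ref$E, tolerance = 1e-12)

  # batch equals single-sample runs: per-sample independence
  singles <- do.call(rbind, lapply(seq_len(20), function(r)
    runPipeline(PerfusionExperiment(tab[r, ], perf), flow)))
  expect_equal(singles$Kin, pk$Kin[1:20])
  expect_equal(singles$flags, pk$flags[1:20])
})

test_that("algebraic inversion holds whenever no clamp fired", {
  tab <- randomSamples(400, seed = 7)
  perf <- defaultPerfusate(Cperf = 660, CstarPerf = 222)
  pk <- runPipeline(PerfusionExperiment(tab, perf))
  ok <- pk$Xtissue >= 0
  expect_gt(sum(ok), 0)
  expect_equal(pk$Vv * 222, tab$Xstar_dpm_per_g, tolerance = 1e-12)
  expect_equal(pk$Kin[ok] * tab$T_s[ok] * 660 + pk$Vv[ok] * 660,
               tab$Xtot_dpm_per_g[ok], tolerance = 1e-12)
})

test_that("reported volumes are monotone in Xtot and scale covariant", {
  perf <- defaultPerfusate()
  xt <- seq(0, 300, by = 10)
  tab <- makeSampleTable(length(xt), Xtot = xt, Xstar = 1200)
  pk <- runPipeline(PerfusionExperiment(tab, perf))
  expect_true(all(diff(pk$Vtissue) >= 0))
  expect_true(all(diff(pk$Kin) >= 0))

  # multiply every dpm quantity and both concentrations by one factor
  for (k in c(0.1, 7)) {
    tab2 <- tab
    tab2$Xtot_dpm_per_g <- tab$Xtot_dpm_per_g * k
    tab2$Xstar_dpm_per_g <- tab$Xstar_dpm_per_g * k
    perf2 <- defaultPerfusate(Cperf = 10 * k, CstarPerf = 100 * k)
    pk2 <- runPipeline(PerfusionExperiment(tab2, perf2))
    expect_equal(pk2$Vv, pk$Vv, tolerance = 1e-12)
    expect_equal(pk2$Vtissue, pk$Vtissue, tolerance = 1e-12)
    expect_equal(pk2$Kin, pk$Kin, tolerance = 1e-12)
  }
})

test_that("below-background samples are flagged and clamped end to end", {
  perf <- defaultPerfusate()
  ex <- PerfusionExperiment(makeSampleTable(1, Xtot = 100, Xstar = 1200), perf)
  pk <- runPipeline(ex)
  expect_equal(pk$Xtissue, -20)
  expect_equal(pk$Vtissue_signed, -2)
  expect_equal(pk$Vtissue, 0)
  expect_equal(pk$Kin, 0)
  expect_match(pk$flags, "below_vascular_background")
})
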