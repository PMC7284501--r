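# Builders and independent oracles shared across the suite.

makeSampleTable <- function(n = 1, sample_id = sprintf("s%d", seq_len(n)),
                            animal_id = sprintf("a%d", seq_len(n)),
                            species = "rat", region = "cerebrum",
                            group = "control", treatment = "none",
                            tracer = "SN38", Xtot = 500, Xstar = 1200,
                            T = 120) {
  data.frame(sample_id = sample_id, animal_id = animal_id, species = species,
             region = region, group = group, treatment = treatment,
             tracer = tracer, Xtot_dpm_per_g = Xtot, Xstar_dpm_per_g = Xstar,
             T_s = T, stringsAsFactors = FALSE)
}

defaultPerfusate <- function(Cperf = 10, CstarPerf = 100) {
  PerfusateSpec(Cperf = Cperf, CstarPerf = CstarPerf)
}

# Deliberately naive scalar reference of the five clearance equations,
# written independently of the pipeline (explicit loop, no clamping tricks).
naivePK <- function(samples, Cperf, CstarPerf, flowTable = NULL) {
  out <- data.frame(Vv = numeric(nrow(samples)), Xtissue = NA_real_,
                    Vtissue = NA_real_, Kin = NA_real_, E = NA_real_)
  for (r in seq_len(nrow(samples))) {
    Vv <- samples$Xstar_dpm_per_g[r] / CstarPerf
    Xt <- samples$Xtot_dpm_per_g[r] - Vv * Cperf
    Vt <- if (Xt < 0) 0 else Xt / Cperf
    Kin <- Vt / samples$T_s[r]
    E <- NA_real_
    if (!is.null(flowTable)) {
      hit <- flowTable$region == samples$region[r] &
        flowTable$species == samples$species[r]
      if (any(hit)) E <- 100 * Kin / flowTable$F[which(hit)[1]]
    }
    out$Vv[r] <- Vv; out$Xtissue[r] <- Xt; out$Vtissue[r] <- Vt
    out$Kin[r] <- Kin; out$E[r] <- E
  }
  out
}

# Random valid sample batch for property tests.
randomSamples <- function(n, seed) {
  set.seed(seed)
  makeSampleTable(
    n = n,
    region = sample(c("cerebrum", "cerebellum", "brainstem"), n, TRUE),
    species = sample(c("rat", "mouse"), n, TRUE),
    Xtot = runif(n, 0, 5e4),
    Xstar = runif(n, 0, 1e4),
    T = runif(n, 30, 300))
}
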