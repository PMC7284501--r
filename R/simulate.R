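## ---- counter-based per-sample substreams -----------------------------------
## Two exact Lehmer steps (48271 mod 2^31-1) mix the root seed with the
## sample counter; every product stays below 2^53, so the scheme is exact in
## doubles and a sample's draws depend only on (root seed, counter), never on
## how many samples were generated before it.
.lehmer <- function(x) (48271 * x) %% 2147483647

.sampleSeed <- function(root, index) {
  s <- .lehmer((abs(root) %% 2147483646) + 1)
  s <- .lehmer(((s + index) %% 2147483646) + 1)
  as.integer(s)
}

## Evaluate code under a temporary seed, restoring the caller's RNG state.
.withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else suppressWarnings(rm(list = ".Random.seed", envir = genv))
  })
  set.seed(seed)
  force(code)
}

## Mean-preserving lognormal multiplier with coefficient of variation cv.
.lognormMult <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sig <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -sig^2 / 2, sd = sig))
}

#' Construct a simulation scenario
#'
#' See \linkS4class{SimScenario} for the meaning of each component. Defaults
#' give a three-region rat study; \code{\link{defaultRatScenario}} and
#' \code{\link{defaultMouseScenario}} bundle complete parameterizations.
#'
#' @param species "rat" or "mouse".
#' @param regions data.frame(region, F_true, Vv_true, PS_passive).
#' @param transporters data.frame(name, activity, genotype_present).
#' @param inhibitorEffects named list: treatment -> named numeric vector of
#'   fractional inhibitions in [0,1].
#' @param knockouts named list: group -> transporter names knocked out.
#' @param biologicalCV lognormal CV of per-animal physiology.
#' @param counting list with Cperf, CstarPerf, CperfFlow (dpm/uL),
#'   backgroundDpm (dpm/g), specimenMass_g, poisson (logical).
#' @param design data.frame(group, treatment, n) replicated over regions.
#' @param T,flowT perfusion times (s) of the test tracer and flow marker.
#' @param flowN flow-marker animals per region.
#' @param flowPSFactor flow-marker PS_app as a multiple of F.
#' @param seed root seed of the per-sample substreams.
#' @return A validated \linkS4class{SimScenario}.
#' @export
SimScenario <- function(species = "rat", regions, transporters,
                        inhibitorEffects = list(), knockouts = list(),
                        biologicalCV = 0.25,
                        counting = list(Cperf = 660, CstarPerf = 222,
                                        CperfFlow = 600, backgroundDpm = 0,
                                        specimenMass_g = 0.4, poisson = TRUE),
                        design, T = 120, flowT = 60, flowN = 5,
                        flowPSFactor = 40, seed = 1) {
  defaults <- list(Cperf = 660, CstarPerf = 222, CperfFlow = 600,
                   backgroundDpm = 0, specimenMass_g = 0.4, poisson = TRUE)
  for (k in names(defaults))
    if (is.null(counting[[k]])) counting[[k]] <- defaults[[k]]
  new("SimScenario", species = species, regions = as.data.frame(regions),
      transporters = as.data.frame(transporters),
      inhibitorEffects = inhibitorEffects, knockouts = knockouts,
      biologicalCV = biologicalCV, counting = counting,
      design = as.data.frame(design), T = T, flowT = flowT, flowN = flowN,
      flowPSFactor = flowPSFactor, seed = seed)
}

#' Apparent permeability under saturable efflux
#'
#' Efflux enters as a divisor on the passive permeability-surface product:
#' \deqn{PS_{app} = PS_{passive} / (1 + \sum_t a_t g_t (1 - i_t))}
#' where \eqn{a_t \ge 0} is the transporter's activity, \eqn{g_t} is 1 when
#' the genotype carries the transporter and 0 when it is knocked out, and
#' \eqn{i_t \in [0,1]} is the fractional inhibition by the applied treatment.
#' The divisor form keeps \eqn{PS_{app}} strictly positive and makes a
#' knockout and complete inhibition exactly equivalent.
#'
#' @param PSpassive passive permeability-surface product (uL/s/g).
#' @param transporters data.frame(name, activity, genotype_present).
#' @param treatment treatment label; matched against
#'   \code{names(inhibitorEffects)}, unmatched means no inhibition.
#' @param inhibitorEffects named list of named fractional-inhibition vectors.
#' @return Apparent PS (uL/s/g).
#' @examples
#' tr <- data.frame(name = "P-gp", activity = 3, genotype_present = TRUE)
#' apparentPS(1, tr)                                   # 1/4
#' apparentPS(1, tr, "valspodar", list(valspodar = c("P-gp" = 1)))  # 1
#' @export
apparentPS <- function(PSpassive, transporters, treatment = "none",
                       inhibitorEffects = list()) {
  if (PSpassive < 0) stop("PSpassive must be non-negative")
  if (nrow(transporters) == 0) return(PSpassive)
  a <- transporters$activity
  g <- as.numeric(transporters$genotype_present)
  i <- rep(0, nrow(transporters))
  eff <- inhibitorEffects[[treatment]]
  if (!is.null(eff)) {
    idx <- match(names(eff), transporters$name)
    ok <- !is.na(idx)
    i[idx[ok]] <- eff[ok]
  }
  PSpassive / (1 + sum(a * g * (1 - i)))
}

#' Crone-Renkin single-capillary uptake clearance
#'
#' \deqn{K_{in} = F (1 - e^{-PS_{app}/F})}
#' The model that makes low-extraction uptake flow independent
#' (\eqn{K_{in} \to PS_{app}} as \eqn{PS_{app}/F \to 0}) and a highly
#' permeable marker flow limited (\eqn{K_{in} \to F}, i.e. 100 percent
#' extracted).
#'
#' @param PSapp apparent permeability-surface product (uL/s/g),
#'   non-negative.
#' @param F perfusion flow (uL/s/g), positive.
#' @return True uptake clearance (uL/s/g); vectorized.
#' @examples
#' croneRenkinKin(0.18, 36)          # ~0.18 (0.5 percent extraction)
#' croneRenkinKin(40 * 36, 36) / 36  # ~1: fully extracted
#' @export
croneRenkinKin <- function(PSapp, F) {
  if (any(F <= 0)) stop("flow F must be positive")
  if (any(PSapp < 0)) stop("PSapp must be non-negative")
  F * (-expm1(-PSapp / F))
}

## Ground-truth clearance for one design cell (no noise applied).
.cellTruth <- function(scenario, region, group, treatment, tracer) {
  rr <- scenario@regions[scenario@regions$region == region, , drop = FALSE]
  if (nrow(rr) != 1) stop("region not in scenario: ", region)
  tr <- scenario@transporters
  ko <- scenario@knockouts[[group]]
  if (!is.null(ko) && nrow(tr) > 0)
    tr$genotype_present <- tr$genotype_present & !(tr$name %in% ko)
  if (tracer == "diazepam") {
    PSapp <- scenario@flowPSFactor * rr$F_true
  } else {
    PSapp <- apparentPS(rr$PS_passive, tr, treatment,
                        scenario@inhibitorEffects)
  }
  list(F = rr$F_true, Vv = rr$Vv_true, PSapp = PSapp,
       Kin = croneRenkinKin(PSapp, rr$F_true))
}

#' Generate one simulated perfusion sample
#'
#' Draws one animal's tissue sample under the scenario's ground truth:
#' per-animal lognormal biological variability (mean preserving, CV =
#' \code{biologicalCV}) on the true clearance and vascular volume, then total
#' dpm constructed by inverting the measurement model
#' (\code{Xtot = (Vv + Kin T) Cperf + background}), then Poisson counting
#' noise on total counts given the specimen mass. The sample's draws are a
#' pure function of \code{(scenario seed, index)}.
#'
#' @param scenario a \linkS4class{SimScenario}.
#' @param region,group,treatment design cell labels (must exist in the
#'   scenario).
#' @param tracer "SN38" (test tracer, perfused \code{T} s) or "diazepam"
#'   (flow marker, perfused \code{flowT} s at its own perfusate
#'   concentration).
#' @param index sample counter selecting the random substream.
#' @return One-row data.frame: the sample-table columns plus ground-truth
#'   columns \code{PS_app}, \code{Kin_true}, \code{Vv_true} (scenario level)
#'   and \code{Kin_animal}, \code{Vv_animal} (after biological variability).
#' @export
generateSample <- function(scenario, region, group, treatment = "none",
                           tracer = "SN38", index = 1) {
  stopifnot(is(scenario, "SimScenario"))
  tru <- .cellTruth(scenario, region, group, treatment, tracer)
  cnt <- scenario@counting
  if (tracer == "diazepam") {
    Cperf <- cnt$CperfFlow
    T <- scenario@flowT
  } else {
    Cperf <- cnt$Cperf
    T <- scenario@T
  }
  .withSeed(.sampleSeed(scenario@seed, index), {
    mult <- .lognormMult(2, scenario@biologicalCV)
    Kin_animal <- tru$Kin * mult[1]
    Vv_animal <- tru$Vv * mult[2]
    Xtot <- (Vv_animal + Kin_animal * T) * Cperf + cnt$backgroundDpm
    Xstar <- Vv_animal * cnt$CstarPerf + cnt$backgroundDpm
    if (isTRUE(cnt$poisson)) {
      m <- cnt$specimenMass_g
      Xtot <- stats::rpois(1, Xtot * m) / m
      Xstar <- stats::rpois(1, Xstar * m) / m
    }
    data.frame(
      sample_id = sprintf("S%04d", index),
      animal_id = sprintf("A%04d", index),
      species = scenario@species, region = region, group = group,
      treatment = treatment, tracer = tracer,
      Xtot_dpm_per_g = Xtot, Xstar_dpm_per_g = Xstar, T_s = T,
      PS_app = tru$PSapp, Kin_true = tru$Kin, Vv_true = tru$Vv,
      Kin_animal = Kin_animal, Vv_animal = Vv_animal,
      stringsAsFactors = FALSE)
  })
}

#' Generate a complete simulated perfusion study
#'
#' Enumerates the full factorial design (every region crossed with every
#' design row), adds \code{flowN} flow-marker animals per region (perfused
#' \code{flowT} s at the flow marker's perfusate concentration), and returns
#' the test-tracer experiment, the flow-marker experiment, and a per-sample
#' ground-truth table for recovery scoring. Every sample carries the
#' vascular-marker co-perfusion. Optionally writes \code{samples.csv},
#' \code{diazepam.csv}, \code{truth.csv} and \code{scenario-echo.yml} to a
#' directory.
#'
#' @param scenario a \linkS4class{SimScenario}.
#' @param dir optional output directory.
#' @return list with \code{experiment} and \code{flowExperiment}
#'   (\linkS4class{PerfusionExperiment} objects) and \code{truth}
#'   (data.frame keyed by \code{sample_id}).
#' @examples
#' study <- generateStudy(defaultRatScenario(seed = 7))
#' flow <- estimateFlow(study$flowExperiment)
#' pk <- runPipeline(study$experiment, flow)
#' head(pk[, c("region", "treatment", "Kin", "E")])
#' @export
generateStudy <- function(scenario, dir = NULL) {
  stopifnot(is(scenario, "SimScenario"))
  regions <- scenario@regions$region
  design <- scenario@design
  rows <- list()
  index <- 0
  for (region in regions) {
    for (d in seq_len(nrow(design))) {
      for (rep in seq_len(design$n[d])) {
        index <- index + 1
        rows[[index]] <- generateSample(scenario, region, design$group[d],
                                        design$treatment[d], "SN38", index)
      }
    }
  }
  for (region in regions) {
    for (rep in seq_len(scenario@flowN)) {
      index <- index + 1
      rows[[index]] <- generateSample(scenario, region, "flow", "none",
                                      "diazepam", index)
    }
  }
  all <- do.call(rbind, rows)
  truth_cols <- c("sample_id", "region", "group", "treatment", "tracer",
                  "PS_app", "Kin_true", "Vv_true", "Kin_animal", "Vv_animal")
  truth <- all[, truth_cols]
  samples <- all[, .SAMPLE_COLUMNS]
  is_flow <- samples$tracer == "diazepam"
  cnt <- scenario@counting
  perf <- PerfusateSpec(Cperf = cnt$Cperf, CstarPerf = cnt$CstarPerf)
  perfFlow <- PerfusateSpec(Cperf = cnt$CperfFlow, CstarPerf = cnt$CstarPerf)
  experiment <- PerfusionExperiment(samples[!is_flow, , drop = FALSE], perf)
  flowExperiment <- PerfusionExperiment(samples[is_flow, , drop = FALSE],
                                        perfFlow)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.csv(perfusionSamples(experiment),
                     file.path(dir, "samples.csv"), row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(perfusionSamples(flowExperiment),
                     file.path(dir, "diazepam.csv"), row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE,
                     quote = FALSE)
    writeLines(.scenarioToYaml(scenario), file.path(dir, "scenario-echo.yml"))
  }
  list(experiment = experiment, flowExperiment = flowExperiment,
       truth = truth)
}

.scenarioToYaml <- function(sc) {
  num <- function(x) sprintf("%.17g", x)
  out <- c(sprintf("species: %s", sc@species),
           sprintf("biological_cv: %s", num(sc@biologicalCV)),
           sprintf("T_s: %s", num(sc@T)),
           sprintf("flow_T_s: %s", num(sc@flowT)),
           sprintf("flow_n: %d", as.integer(sc@flowN)),
           sprintf("flow_ps_factor: %s", num(sc@flowPSFactor)),
           sprintf("seed: %d", as.integer(sc@seed)),
           "counting:")
  for (k in names(sc@counting))
    out <- c(out, sprintf("  %s: %s", k, as.character(sc@counting[[k]])))
  out <- c(out, "regions:")
  for (r in seq_len(nrow(sc@regions)))
    out <- c(out, sprintf("  - {region: %s, F_true: %s, Vv_true: %s, PS_passive: %s}",
                          sc@regions$region[r], num(sc@regions$F_true[r]),
                          num(sc@regions$Vv_true[r]),
                          num(sc@regions$PS_passive[r])))
  out <- c(out, "transporters:")
  for (r in seq_len(nrow(sc@transporters)))
    out <- c(out, sprintf("  - {name: %s, activity: %s, genotype_present: %s}",
                          sc@transporters$name[r],
                          num(sc@transporters$activity[r]),
                          tolower(as.character(sc@transporters$genotype_present[r]))))
  out <- c(out, "design:")
  for (r in seq_len(nrow(sc@design)))
    out <- c(out, sprintf("  - {group: %s, treatment: %s, n: %d}",
                          sc@design$group[r], sc@design$treatment[r],
                          as.integer(sc@design$n[r])))
  out
}

#' Default rat inhibitor-panel scenario
#'
#' Three regions with flows ordered cerebrum > cerebellum > brainstem and
#' vascular volumes higher in cerebellum/brainstem than cerebrum; four efflux
#' transporters (P-gp, Bcrp, an Mrp pool, and a third elacridar-sensitive
#' transporter); the five-arm inhibitor design (none, valspodar, Ko143,
#' elacridar, MK571) at n = 5 per cell. Passive permeabilities are set so the
#' untreated test tracer's extraction falls in the 0.5-2 percent
#' flow-independent window with control clearances near 0.18, 0.10 and
#' 0.09 uL/s/g in cerebrum, cerebellum and brainstem.
#'
#' @param seed root seed.
#' @param biologicalCV per-animal lognormal CV (default 0.25).
#' @param n animals per design cell (default 5).
#' @param poisson apply Poisson counting noise (default TRUE).
#' @return A \linkS4class{SimScenario}.
#' @export
defaultRatScenario <- function(seed = 1, biologicalCV = 0.25, n = 5,
                               poisson = TRUE) {
  regions <- data.frame(
    region = c("cerebrum", "cerebellum", "brainstem"),
    F_true = c(30, 15, 10),
    Vv_true = c(10, 18, 16),
    PS_passive = 7 * c(0.18, 0.10, 0.09),
    stringsAsFactors = FALSE)
  transporters <- data.frame(
    name = c("P-gp", "Bcrp", "ET3", "Mrp"),
    activity = c(0.75, 0.75, 4, 0.5),
    genotype_present = TRUE, stringsAsFactors = FALSE)
  inhibitorEffects <- list(
    valspodar = c("P-gp" = 1),
    Ko143 = c("Bcrp" = 1),
    elacridar = c("P-gp" = 1, "Bcrp" = 1, "ET3" = 1),
    MK571 = c("Mrp" = 1))
  design <- data.frame(
    group = "control",
    treatment = c("none", "valspodar", "Ko143", "elacridar", "MK571"),
    n = n, stringsAsFactors = FALSE)
  SimScenario(species = "rat", regions = regions,
              transporters = transporters,
              inhibitorEffects = inhibitorEffects,
              biologicalCV = biologicalCV,
              counting = list(specimenMass_g = 0.4, poisson = poisson),
              design = design, seed = seed)
}

#' Default mouse wild-type vs triple-knockout scenario
#'
#' Wild-type and TKO (P-gp and Bcrp knocked out) groups crossed with no
#' inhibitor, elacridar and MK571. Elacridar inhibits P-gp, Bcrp and the
#' third elacridar-sensitive transporter, so the TKO group (efflux by the
#' third transporter and Mrp still intact) sits strictly between wild type
#' and elacridar-treated animals.
#'
#' @inheritParams defaultRatScenario
#' @return A \linkS4class{SimScenario}.
#' @export
defaultMouseScenario <- function(seed = 1, biologicalCV = 0.25, n = 5,
                                 poisson = TRUE) {
  regions <- data.frame(
    region = c("cerebrum", "cerebellum", "brainstem"),
    F_true = c(20, 12, 8),
    Vv_true = c(8, 14, 12),
    PS_passive = 8 * c(0.12, 0.072, 0.06),
    stringsAsFactors = FALSE)
  transporters <- data.frame(
    name = c("P-gp", "Bcrp", "ET3", "Mrp"),
    activity = c(2, 2, 2.4, 0.6),
    genotype_present = TRUE, stringsAsFactors = FALSE)
  inhibitorEffects <- list(
    elacridar = c("P-gp" = 1, "Bcrp" = 1, "ET3" = 1),
    MK571 = c("Mrp" = 1))
  design <- expand.grid(group = c("WT", "TKO"),
                        treatment = c("none", "elacridar", "MK571"),
                        stringsAsFactors = FALSE)
  design$n <- n
  SimScenario(species = "mouse", regions = regions,
              transporters = transporters,
              inhibitorEffects = inhibitorEffects,
              knockouts = list(TKO = c("P-gp", "Bcrp")),
              biologicalCV = biologicalCV,
              counting = list(Cperf = 660, CstarPerf = 222, CperfFlow = 600,
                              specimenMass_g = 0.15, poisson = poisson),
              design = design, seed = seed)
}

#' Rat control / sham / DIPG scenario
#'
#' Three groups sharing identical barrier physiology (the modelled situation
#' of an intact blood-brain barrier in tumor-bearing animals), no inhibitor,
#' n = 8 per cell.
#'
#' @inheritParams defaultRatScenario
#' @return A \linkS4class{SimScenario}.
#' @export
dipgRatScenario <- function(seed = 1, biologicalCV = 0.25, n = 8,
                            poisson = TRUE) {
  sc <- defaultRatScenario(seed = seed, biologicalCV = biologicalCV,
                           poisson = poisson)
  sc@design <- data.frame(group = c("control", "sham", "DIPG"),
                          treatment = "none", n = n,
                          stringsAsFactors = FALSE)
  validObject(sc)
  sc
}

#' Two-arm scenario with a known inhibitor fold effect
#'
#' Single-region (cerebrum) control vs elacridar design in which the
#' inhibitor multiplies the apparent permeability by exactly \code{psFold}
#' (two transporters of equal activity, both fully inhibited). Used for
#' fold-change recovery studies; the true clearance fold is the
#' Crone-Renkin-transformed ratio, marginally below \code{psFold} at these
#' low extractions.
#'
#' @param psFold true fold increase in apparent PS under the inhibitor.
#' @inheritParams defaultRatScenario
#' @return A \linkS4class{SimScenario}.
#' @export
inhibitorRecoveryScenario <- function(psFold = 4, seed = 1,
                                      biologicalCV = 0.25, n = 5,
                                      poisson = TRUE) {
  stopifnot(psFold >= 1)
  regions <- data.frame(region = "cerebrum", F_true = 36, Vv_true = 10,
                        PS_passive = 0.18 * psFold, stringsAsFactors = FALSE)
  transporters <- data.frame(
    name = c("P-gp", "Bcrp"),
    activity = rep((psFold - 1) / 2, 2),
    genotype_present = TRUE, stringsAsFactors = FALSE)
  design <- data.frame(group = "control",
                       treatment = c("none", "elacridar"), n = n,
                       stringsAsFactors = FALSE)
  SimScenario(species = "rat", regions = regions,
              transporters = transporters,
              inhibitorEffects = list(elacridar = c("P-gp" = 1, "Bcrp" = 1)),
              biologicalCV = biologicalCV,
              counting = list(specimenMass_g = 0.4, poisson = poisson),
              design = design, seed = seed, flowN = 2)
}
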