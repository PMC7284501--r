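#' @import methods
NULL

## Closed vocabularies at the data boundary. Regions beyond the three
## dissected structures are accepted through the "other:<name>" escape hatch.
.REGIONS <- c("cerebrum", "cerebellum", "brainstem")
.SPECIES <- c("rat", "mouse")
.TRACERS <- c("SN38", "diazepam", "other")

.SAMPLE_COLUMNS <- c("sample_id", "animal_id", "species", "region", "group",
                     "treatment", "tracer", "Xtot_dpm_per_g",
                     "Xstar_dpm_per_g", "T_s")

.validRegion <- function(x) {
  x %in% .REGIONS | grepl("^other:.+$", x)
}

## Returns a character vector of problems (empty if valid); row numbers refer
## to the table as given.
.validateSamples <- function(df) {
  problems <- character(0)
  missing_cols <- setdiff(.SAMPLE_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    return(sprintf("missing mandatory column(s): %s",
                   paste(missing_cols, collapse = ", ")))
  }
  if (nrow(df) == 0) return(problems)
  bad <- which(!.validRegion(as.character(df$region)))
  if (length(bad) > 0) {
    problems <- c(problems, sprintf(
      "row %d: unknown region '%s' (allowed: %s, or 'other:<name>')",
      bad, df$region[bad], paste(.REGIONS, collapse = ", ")))
  }
  bad <- which(!(df$species %in% .SPECIES))
  if (length(bad) > 0) {
    problems <- c(problems, sprintf(
      "row %d: unknown species '%s' (allowed: %s)",
      bad, df$species[bad], paste(.SPECIES, collapse = ", ")))
  }
  bad <- which(!(df$tracer %in% .TRACERS))
  if (length(bad) > 0) {
    problems <- c(problems, sprintf(
      "row %d: unknown tracer '%s' (allowed: %s)",
      bad, df$tracer[bad], paste(.TRACERS, collapse = ", ")))
  }
  for (col in c("Xtot_dpm_per_g", "Xstar_dpm_per_g", "T_s")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad) > 0) {
      problems <- c(problems, sprintf("row %d: non-numeric %s", bad, col))
      next
    }
    if (col == "T_s") {
      bad <- which(v <= 0)
      if (length(bad) > 0)
        problems <- c(problems,
                      sprintf("row %d: non-positive perfusion time T_s", bad))
    } else {
      bad <- which(v < 0)
      if (length(bad) > 0)
        problems <- c(problems, sprintf("row %d: negative %s", bad, col))
    }
  }
  problems
}

#' Perfusate composition
#'
#' Tracer and vascular-marker concentrations of the perfusion fluid, the pump
#' flow rate, and any efflux-transporter inhibitors added to the fluid. All
#' downstream volumes and clearances are referenced to these concentrations,
#' so units are fixed: dpm per microlitre for the two isotope channels,
#' mL per minute for the pump setting.
#'
#' @slot Cperf test-tracer concentration in the perfusion fluid (dpm/uL)
#' @slot CstarPerf vascular-marker (sucrose channel) concentration (dpm/uL)
#' @slot flowRate pump flow rate (mL/min)
#' @slot inhibitors named numeric vector, inhibitor name -> concentration (uM)
#' @export
setClass("PerfusateSpec",
  representation(Cperf = "numeric", CstarPerf = "numeric",
                 flowRate = "numeric", inhibitors = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@Cperf) != 1 || !is.finite(object@Cperf) ||
        object@Cperf <= 0)
      msg <- c(msg, "Cperf must be a single positive number")
    if (length(object@CstarPerf) != 1 || !is.finite(object@CstarPerf) ||
        object@CstarPerf <= 0)
      msg <- c(msg, "CstarPerf must be a single positive number")
    if (length(object@flowRate) != 1 || !is.finite(object@flowRate) ||
        object@flowRate <= 0)
      msg <- c(msg, "flowRate must be a single positive number")
    if (length(object@inhibitors) > 0 &&
        (is.null(names(object@inhibitors)) || any(names(object@inhibitors) == "")))
      msg <- c(msg, "inhibitors must be a named numeric vector")
    if (length(msg) == 0) TRUE else msg
  })

#' Construct a PerfusateSpec
#'
#' @param Cperf test-tracer concentration (dpm/uL); must be positive.
#' @param CstarPerf vascular-marker concentration (dpm/uL); must be positive.
#' @param flowRate pump flow rate (mL/min).
#' @param inhibitors named numeric vector of inhibitor concentrations (uM);
#'   empty by default.
#' @return A \linkS4class{PerfusateSpec} object.
#' @examples
#' PerfusateSpec(Cperf = 660, CstarPerf = 222, flowRate = 10)
#' @export
PerfusateSpec <- function(Cperf, CstarPerf, flowRate = 10,
                          inhibitors = numeric(0)) {
  new("PerfusateSpec", Cperf = as.numeric(Cperf),
      CstarPerf = as.numeric(CstarPerf), flowRate = as.numeric(flowRate),
      inhibitors = inhibitors)
}

#' A batch of perfused tissue samples plus their perfusate
#'
#' Container pairing a validated sample table (one row per dissected tissue:
#' dual-isotope counts, perfusion time, design labels) with the
#' \linkS4class{PerfusateSpec} the animals were perfused with. The sample
#' table keeps the CSV schema column names (see \code{\link{readSamples}}).
#'
#' @slot samples data.frame with the documented sample columns
#' @slot perfusate a \linkS4class{PerfusateSpec}
#' @export
setClass("PerfusionExperiment",
  representation(samples = "data.frame", perfusate = "PerfusateSpec"),
  validity = function(object) {
    problems <- .validateSamples(object@samples)
    if (length(problems) == 0) TRUE else problems
  })

#' Construct a PerfusionExperiment
#'
#' @param samples data.frame with columns \code{sample_id, animal_id, species,
#'   region, group, treatment, tracer, Xtot_dpm_per_g, Xstar_dpm_per_g, T_s}.
#' @param perfusate a \linkS4class{PerfusateSpec}.
#' @return A validated \linkS4class{PerfusionExperiment}.
#' @export
PerfusionExperiment <- function(samples, perfusate) {
  samples <- as.data.frame(samples)[, .SAMPLE_COLUMNS, drop = FALSE]
  for (col in c("Xtot_dpm_per_g", "Xstar_dpm_per_g", "T_s"))
    samples[[col]] <- as.numeric(samples[[col]])
  for (col in c("sample_id", "animal_id", "species", "region", "group",
                "treatment", "tracer"))
    samples[[col]] <- as.character(samples[[col]])
  rownames(samples) <- NULL
  new("PerfusionExperiment", samples = samples, perfusate = perfusate)
}

#' Simulation scenario: ground-truth physiology and study design
#'
#' Everything needed to generate a perfusion study with known truth: regional
#' flow, vascular volume and passive permeability-surface product; saturable
#' efflux-transporter activities; which transporters each inhibitor treatment
#' blocks (fractional inhibition in [0,1]); which transporters each
#' experimental group has knocked out; biological and counting noise; and the
#' factorial design (group x treatment x n per region).
#'
#' @slot species "rat" or "mouse"
#' @slot regions data.frame(region, F_true, Vv_true, PS_passive); units
#'   uL/s/g, uL/g, uL/s/g
#' @slot transporters data.frame(name, activity, genotype_present)
#' @slot inhibitorEffects named list: treatment -> named numeric of fractional
#'   inhibition per transporter
#' @slot knockouts named list: group -> character vector of transporter names
#'   absent in that group's genotype
#' @slot biologicalCV lognormal coefficient of variation of per-animal
#'   physiology (fraction)
#' @slot counting list(Cperf, CstarPerf, CperfFlow, backgroundDpm,
#'   specimenMass_g, poisson)
#' @slot design data.frame(group, treatment, n)
#' @slot T test-tracer perfusion time (s)
#' @slot flowT flow-marker perfusion time (s)
#' @slot flowN flow-marker animals per region
#' @slot flowPSFactor PS_app of the flow marker as a multiple of F (large so
#'   its extraction is ~100 percent)
#' @slot seed root seed for the counter-based per-sample substreams
#' @export
setClass("SimScenario",
  representation(species = "character", regions = "data.frame",
                 transporters = "data.frame", inhibitorEffects = "list",
                 knockouts = "list", biologicalCV = "numeric",
                 counting = "list", design = "data.frame", T = "numeric",
                 flowT = "numeric", flowN = "numeric",
                 flowPSFactor = "numeric", seed = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (!all(c("region", "F_true", "Vv_true", "PS_passive") %in%
             names(object@regions)))
      msg <- c(msg, "regions needs columns region, F_true, Vv_true, PS_passive")
    else {
      if (any(object@regions$F_true <= 0))
        msg <- c(msg, "F_true must be positive")
      if (any(object@regions$Vv_true < 0 | object@regions$PS_passive < 0))
        msg <- c(msg, "Vv_true and PS_passive must be non-negative")
    }
    if (nrow(object@transporters) > 0) {
      if (!all(c("name", "activity", "genotype_present") %in%
               names(object@transporters)))
        msg <- c(msg, "transporters needs columns name, activity, genotype_present")
      else if (any(object@transporters$activity < 0))
        msg <- c(msg, "transporter activities must be non-negative")
    }
    for (tr in names(object@inhibitorEffects)) {
      i <- object@inhibitorEffects[[tr]]
      if (any(i < 0 | i > 1))
        msg <- c(msg, sprintf("inhibitor '%s': fractional inhibition outside [0,1]", tr))
    }
    if (object@biologicalCV < 0 || object@biologicalCV >= 1)
      msg <- c(msg, "biologicalCV must be in [0, 1)")
    if (!all(c("group", "treatment", "n") %in% names(object@design)))
      msg <- c(msg, "design needs columns group, treatment, n")
    else if (any(object@design$n < 1))
      msg <- c(msg, "design n must be >= 1")
    if (object@T <= 0 || object@flowT <= 0)
      msg <- c(msg, "perfusion times must be positive")
    if (length(msg) == 0) TRUE else msg
  })

#' Calibration curve for isotope-dilution peptide quantification
#'
#' Weighted least-squares line of light/heavy MRM area ratio on known peptide
#' amount, with the lowest reliably back-calculated standard recorded as the
#' limit of quantification.
#'
#' @slot slope fitted slope (area ratio per fmol); must be positive for an
#'   accepted curve
#' @slot intercept fitted intercept (area ratio)
#' @slot rSquared coefficient of determination of the weighted fit
#' @slot loqFmol limit of quantification (fmol on column)
#' @slot weighting "1/x" or "none"
#' @slot nStandards number of standard points used
#' @export
setClass("CalibrationCurve",
  representation(slope = "numeric", intercept = "numeric",
                 rSquared = "numeric", loqFmol = "numeric",
                 weighting = "character", nStandards = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (object@slope <= 0) msg <- c(msg, "slope must be positive")
    if (object@rSquared < 0 || object@rSquared > 1 + 1e-12)
      msg <- c(msg, "rSquared must lie in [0, 1]")
    if (object@loqFmol < 0) msg <- c(msg, "loqFmol must be non-negative")
    if (length(msg) == 0) TRUE else msg
  })
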