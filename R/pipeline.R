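#' Vascular volume from the non-penetrating marker
#'
#' The marker (here the sucrose channel) does not cross an intact
#' blood-brain barrier, so its apparent tissue distribution volume
#' \deqn{V_v = X^* / C^*_{perf}}
#' measures the vascular space of the dissected tissue (uL/g) and doubles as
#' a barrier-integrity readout.
#'
#' @param Xstar marker amount in tissue (dpm/g), non-negative.
#' @param CstarPerf marker concentration in the perfusion fluid (dpm/uL),
#'   positive.
#' @return Vascular volume Vv (uL/g); vectorized over \code{Xstar}.
#' @examples
#' vascularVolume(1200, 100)  # 12 uL/g
#' @export
vascularVolume <- function(Xstar, CstarPerf) {
  if (any(!is.finite(CstarPerf)) || any(CstarPerf <= 0))
    stop("CstarPerf must be positive")
  if (any(Xstar < 0, na.rm = TRUE)) stop("Xstar must be non-negative")
  Xstar / CstarPerf
}

#' Vascular-corrected tracer amount in tissue
#'
#' Subtracts the tracer held in the vascular space (\code{Vv * Cperf}) from
#' the total measured amount. The signed value is returned: counting noise
#' can push genuinely low-uptake samples below the vascular background, and a
#' silent clamp here would bias group means. Use
#' \code{\link{distributionVolume}} for the clamped, reportable volume.
#'
#' @param Xtot total tracer amount in tissue (dpm/g).
#' @param Vv vascular volume (uL/g), non-negative.
#' @param Cperf tracer concentration in the perfusion fluid (dpm/uL),
#'   positive.
#' @return Signed Xtissue (dpm/g). A negative value means the sample sits
#'   below the vascular background (flag it downstream).
#' @examples
#' correctedTissueAmount(500, 12, 10)  # 380 dpm/g
#' @export
correctedTissueAmount <- function(Xtot, Vv, Cperf) {
  if (any(!is.finite(Cperf)) || any(Cperf <= 0)) stop("Cperf must be positive")
  if (any(Vv < 0, na.rm = TRUE)) stop("Vv must be non-negative")
  Xtot - Vv * Cperf
}

#' Apparent tissue distribution volume of the tracer
#'
#' \deqn{V_{tissue} = X_{tissue} / C_{perf}}
#' Negative corrected amounts are reported as zero (the tracer signal is
#' indistinguishable from vascular background); the signed volume is kept by
#' \code{\link{runPipeline}} for diagnostics.
#'
#' @param Xtissue vascular-corrected tracer amount (dpm/g), may be negative.
#' @param Cperf tracer concentration in the perfusion fluid (dpm/uL).
#' @return Reported distribution volume (uL/g), clamped at zero.
#' @examples
#' distributionVolume(380, 10)  # 38 uL/g
#' distributionVolume(-20, 10)  # 0: below vascular background
#' @export
distributionVolume <- function(Xtissue, Cperf) {
  if (any(!is.finite(Cperf)) || any(Cperf <= 0)) stop("Cperf must be positive")
  pmax(Xtissue, 0) / Cperf
}

#' Initial transport clearance
#'
#' The single-time-point uptake clearance
#' \deqn{K_{in} = V_{tissue} / T}
#' valid while tracer distribution is in its initial linear phase (the assay
#' uses 120 s for the test tracer, 60 s for the flow marker).
#'
#' @param Vtissue apparent distribution volume (uL/g).
#' @param T perfusion time (s), positive.
#' @return Kin (uL/s/g).
#' @examples
#' transportClearance(12, 120)  # 0.10 uL/s/g
#' @export
transportClearance <- function(Vtissue, T) {
  if (any(!is.finite(T)) || any(T <= 0)) stop("perfusion time T must be positive")
  Vtissue / T
}

#' Tissue extraction against the perfusion flow
#'
#' \deqn{E(\%) = 100 \cdot K_{in} / F}
#' where F is the regional perfusion flow measured with a fully extracted
#' flow marker. Extraction below 30 percent is flow independent; at or above
#' 30 percent the clearance tracks flow and the sample is flagged.
#'
#' @param Kin transport clearance (uL/s/g).
#' @param F perfusion flow (uL/s/g), positive.
#' @return Extraction in percent; vectorized.
#' @seealso \code{\link{isFlowDependent}}
#' @examples
#' extraction(0.10, 5)  # 2 percent, flow independent
#' @export
extraction <- function(Kin, F) {
  if (any(!is.finite(F)) || any(F <= 0)) stop("flow F must be positive")
  100 * Kin / F
}

#' @rdname extraction
#' @param E extraction in percent.
#' @return \code{isFlowDependent}: logical, TRUE when E >= 30.
#' @export
isFlowDependent <- function(E) {
  E >= 30
}

#' Estimate regional perfusion flow from flow-marker animals
#'
#' Runs the full clearance pipeline on animals perfused with the flow marker
#' (a compound whose single-pass extraction is ~100 percent, so its Kin
#' equals the flow) and averages Kin per region and species. Flow is never
#' pooled across species, and regions without flow-marker samples are simply
#' absent from the result (downstream extraction is then reported missing,
#' not zero).
#'
#' @param flowExperiment a \linkS4class{PerfusionExperiment} whose samples
#'   all have \code{tracer == "diazepam"}; its perfusate carries the flow
#'   marker's own concentration.
#' @return data.frame(region, species, F, n) with F in uL/s/g.
#' @export
estimateFlow <- function(flowExperiment) {
  stopifnot(is(flowExperiment, "PerfusionExperiment"))
  s <- perfusionSamples(flowExperiment)
  if (nrow(s) == 0) stop("no flow-marker samples provided")
  if (any(s$tracer != "diazepam"))
    stop("all flow-marker samples must have tracer 'diazepam'")
  pk <- runPipeline(flowExperiment, flow = NULL)
  agg <- stats::aggregate(Kin ~ region + species, data = pk, FUN = mean)
  n <- stats::aggregate(Kin ~ region + species, data = pk, FUN = length)
  out <- data.frame(region = agg$region, species = agg$species, F = agg$Kin,
                    n = n$Kin, stringsAsFactors = FALSE)
  out[order(out$region), , drop = FALSE]
}

#' Run the full clearance pipeline on a batch of samples
#'
#' Applies, per sample and independently of batch composition: vascular
#' volume, vascular correction, distribution volume (clamped at zero with the
#' signed value retained), transport clearance, and -- when a flow estimate is
#' available for the sample's region and species -- extraction with the
#' 30 percent flow-independence rule. Quality flags:
#' \describe{
#'   \item{below_vascular_background}{corrected tracer amount was negative;
#'     Vtissue and Kin are reported as 0.}
#'   \item{flow_dependent}{extraction >= 30 percent.}
#'   \item{missing_flow_reference}{no flow estimate for this region/species;
#'     E is NA, not zero.}
#' }
#'
#' @param experiment a \linkS4class{PerfusionExperiment}.
#' @param flow optional data.frame(region, species, F, n) from
#'   \code{\link{estimateFlow}}; NULL disables extraction.
#' @return data.frame with one row per sample: identifiers, \code{Vv},
#'   \code{Xtissue} (signed), \code{Vtissue_signed}, \code{Vtissue},
#'   \code{Kin}, \code{E}, and \code{flags} (semicolon-separated tokens).
#' @examples
#' sp <- PerfusateSpec(Cperf = 10, CstarPerf = 100)
#' ex <- PerfusionExperiment(data.frame(
#'   sample_id = "s1", animal_id = "a1", species = "rat",
#'   region = "cerebrum", group = "control", treatment = "none",
#'   tracer = "SN38", Xtot_dpm_per_g = 500, Xstar_dpm_per_g = 1200,
#'   T_s = 120), sp)
#' runPipeline(ex)
#' @export
runPipeline <- function(experiment, flow = NULL) {
  stopifnot(is(experiment, "PerfusionExperiment"))
  s <- perfusionSamples(experiment)
  p <- perfusate(experiment)
  if (nrow(s) == 0)
    stop("experiment contains no samples")

  Vv <- vascularVolume(s$Xstar_dpm_per_g, p@CstarPerf)
  Xtissue <- correctedTissueAmount(s$Xtot_dpm_per_g, Vv, p@Cperf)
  Vt_signed <- Xtissue / p@Cperf
  Vtissue <- distributionVolume(Xtissue, p@Cperf)
  Kin <- transportClearance(Vtissue, s$T_s)

  E <- rep(NA_real_, nrow(s))
  have_flow <- rep(FALSE, nrow(s))
  if (!is.null(flow) && nrow(flow) > 0) {
    key <- paste(s$region, s$species, sep = "\r")
    fkey <- paste(flow$region, flow$species, sep = "\r")
    idx <- match(key, fkey)
    have_flow <- !is.na(idx)
    E[have_flow] <- extraction(Kin[have_flow], flow$F[idx[have_flow]])
  }

  flags <- character(nrow(s))
  addFlag <- function(flags, which, token) {
    ifelse(which, ifelse(flags == "", token, paste(flags, token, sep = ";")),
           flags)
  }
  flags <- addFlag(flags, Xtissue < 0, "below_vascular_background")
  flags <- addFlag(flags, have_flow & isFlowDependent(E), "flow_dependent")
  flags <- addFlag(flags, !have_flow, "missing_flow_reference")

  data.frame(sample_id = s$sample_id, animal_id = s$animal_id,
             species = s$species, region = s$region, group = s$group,
             treatment = s$treatment, tracer = s$tracer, T_s = s$T_s,
             Vv = Vv, Xtissue = Xtissue, Vtissue_signed = Vt_signed,
             Vtissue = Vtissue, Kin = Kin, E = E, flags = flags,
             stringsAsFactors = FALSE)
}
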