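#' Fit an isotope-dilution calibration curve
#'
#' Weighted least-squares line of light/heavy MRM area ratio on known peptide
#' amount. The default 1/x weighting is the usual choice for isotope-dilution
#' curves spanning a wide concentration range (it balances the relative error
#' across levels). The limit of quantification is defined operationally: the
#' lowest standard level whose mean back-calculated amount falls within
#' 20 percent of nominal.
#'
#' @param standards data.frame with columns \code{known_fmol} (amount on
#'   column) and \code{area_ratio}; at least 3 distinct positive levels.
#'   Duplicate levels are allowed and enter the fit as replicate points.
#' @param weighting "1/x" (default) or "none".
#' @return A \linkS4class{CalibrationCurve}; a fitted slope <= 0 rejects the
#'   curve with an error, as does the absence of any standard level passing
#'   the back-calculation accuracy rule.
#' @examples
#' std <- data.frame(known_fmol = c(10, 50, 250),
#'                   area_ratio = c(0.21, 1.02, 5.01))
#' fitCalibration(std)
#' @export
fitCalibration <- function(standards, weighting = c("1/x", "none")) {
  weighting <- match.arg(weighting)
  stopifnot(all(c("known_fmol", "area_ratio") %in% names(standards)))
  if (any(standards$known_fmol < 0) || any(standards$area_ratio < 0))
    stop("standards must have non-negative amounts and area ratios")
  use <- standards
  if (weighting == "1/x" && any(use$known_fmol == 0)) {
    warning("zero-amount standards excluded from the 1/x-weighted fit")
    use <- use[use$known_fmol > 0, , drop = FALSE]
  }
  if (length(unique(use$known_fmol[use$known_fmol > 0])) < 3)
    stop("need at least 3 distinct non-zero standard levels")
  w <- if (weighting == "1/x") 1 / use$known_fmol else rep(1, nrow(use))
  fit <- stats::lm(area_ratio ~ known_fmol, data = use, weights = w)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || slope <= 0)
    stop("calibration curve rejected: non-positive slope (",
         format(slope), ")")
  ## weighted R^2 computed directly (summary.lm warns on an exact fit)
  ybar <- sum(w * use$area_ratio) / sum(w)
  sst <- sum(w * (use$area_ratio - ybar)^2)
  r2 <- if (sst == 0) 1 else
    min(1, max(0, 1 - sum(w * stats::residuals(fit)^2) / sst))
  levels_fmol <- sort(unique(use$known_fmol[use$known_fmol > 0]))
  back_ok <- vapply(levels_fmol, function(lv) {
    ratios <- use$area_ratio[use$known_fmol == lv]
    back <- (mean(ratios) - intercept) / slope
    abs(back - lv) / lv <= 0.20
  }, TRUE)
  if (!any(back_ok))
    stop("calibration curve rejected: no standard level back-calculates ",
         "within 20 percent of nominal")
  loq <- levels_fmol[which(back_ok)[1]]
  new("CalibrationCurve", slope = slope, intercept = intercept,
      rSquared = r2, loqFmol = loq, weighting = weighting,
      nStandards = nrow(use))
}

#' Absolute protein concentration from a peptide area ratio
#'
#' Back-calculates the peptide amount from the calibration curve,
#' \code{(area_ratio - intercept) / slope}, and divides by the digested
#' protein mass to give fmol per microgram of protein. Amounts below the
#' curve's limit of quantification (including negative back-calculations)
#' are reported as the \code{"<LOQ"} token with no numeric concentration.
#'
#' The fixed amount of stable-isotope-labeled internal standard spiked into
#' every digest (\code{spikedStandardFmol}, 750 fmol in the assay this
#' models) is carried as metadata only: the light/heavy area ratio already
#' normalizes by it, on both standards and samples, so it cancels out of the
#' arithmetic.
#'
#' @param areaRatio light/heavy area ratio(s); vectorized.
#' @param curve an accepted \linkS4class{CalibrationCurve}.
#' @param digestedProteinUg micrograms of protein digested per sample,
#'   positive.
#' @param protein,sampleId optional labels carried into the result.
#' @param speciesSpecificity optional note (e.g. a peptide shared between
#'   human and rat orthologs) carried into the result.
#' @param spikedStandardFmol internal-standard spike, metadata only.
#' @return data.frame with one row per ratio: labels, \code{amount_fmol}
#'   (back-calculated, signed), \code{concentration_fmol_per_ug} (NA below
#'   LOQ), \code{below_loq} (logical) and \code{display} (the number, or
#'   \code{"<LOQ"}).
#' @examples
#' std <- data.frame(known_fmol = c(10, 50, 250),
#'                   area_ratio = c(0.2, 1.0, 5.0))
#' curve <- fitCalibration(std)
#' quantifyProtein(1.5, curve, digestedProteinUg = 50)
#' @export
quantifyProtein <- function(areaRatio, curve, digestedProteinUg,
                            protein = NA_character_,
                            sampleId = NA_character_,
                            speciesSpecificity = NA_character_,
                            spikedStandardFmol = 750) {
  stopifnot(is(curve, "CalibrationCurve"))
  if (any(digestedProteinUg <= 0))
    stop("digestedProteinUg must be positive")
  amount <- (areaRatio - curve@intercept) / curve@slope
  below <- amount < curve@loqFmol
  conc <- ifelse(below, NA_real_, amount / digestedProteinUg)
  data.frame(protein = protein, sample_id = sampleId,
             species_specificity = speciesSpecificity,
             amount_fmol = amount,
             concentration_fmol_per_ug = conc,
             below_loq = below,
             display = ifelse(below, "<LOQ",
                              vapply(conc, function(x)
                                if (is.na(x)) "<LOQ" else sprintf("%.6g", x),
                                "")),
             stringsAsFactors = FALSE)
}

#' Quantify a table of sample MRM measurements
#'
#' Batch version of \code{\link{quantifyProtein}}: each row of
#' \code{samplesMrm} is quantified against the calibration curve of its
#' peptide (or protein, if the curve list is keyed by protein).
#'
#' @param samplesMrm data.frame with columns \code{sample_id, protein,
#'   peptide, area_ratio, digested_protein_ug} and optionally
#'   \code{species_specificity}.
#' @param curves named list of \linkS4class{CalibrationCurve} objects keyed
#'   by peptide or protein.
#' @return data.frame of per-row quantification results.
#' @export
quantifyTable <- function(samplesMrm, curves) {
  need <- c("sample_id", "protein", "peptide", "area_ratio",
            "digested_protein_ug")
  stopifnot(all(need %in% names(samplesMrm)))
  out <- vector("list", nrow(samplesMrm))
  for (r in seq_len(nrow(samplesMrm))) {
    key <- samplesMrm$peptide[r]
    if (!(key %in% names(curves))) key <- samplesMrm$protein[r]
    if (!(key %in% names(curves)))
      stop("no calibration curve for peptide/protein: ",
           samplesMrm$peptide[r], "/", samplesMrm$protein[r])
    spec <- if ("species_specificity" %in% names(samplesMrm))
      samplesMrm$species_specificity[r] else NA_character_
    out[[r]] <- quantifyProtein(samplesMrm$area_ratio[r], curves[[key]],
                                samplesMrm$digested_protein_ug[r],
                                protein = samplesMrm$protein[r],
                                sampleId = samplesMrm$sample_id[r],
                                speciesSpecificity = spec)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate MRM areas for standards and samples
#'
#' Generates a calibration series and sample area ratios from a latent linear
#' response (\code{ratio = slope * fmol + intercept}) with multiplicative
#' lognormal noise of coefficient of variation \code{noiseCv}, reproducibly
#' from a seed. Inverting the generator through
#' \code{\link{fitCalibration}} and \code{\link{quantifyProtein}} recovers
#' the true concentration exactly at zero noise.
#'
#' @param trueConcFmolPerUg true protein concentration(s), fmol per ug.
#' @param digestedProteinUg protein digested per sample (ug; 50 in the assay
#'   this models).
#' @param standardsFmol standard amounts on column (fmol).
#' @param standardReplicates replicate measurements per standard level.
#' @param responseSlope,responseIntercept latent response line.
#' @param noiseCv multiplicative lognormal CV applied to every area ratio.
#' @param seed optional seed (local to this call).
#' @return list(standards, samples): data.frames ready for
#'   \code{\link{fitCalibration}} and \code{\link{quantifyTable}}.
#' @examples
#' sim <- generateMrmAreas(1.5, noiseCv = 0, seed = 1)
#' curve <- fitCalibration(sim$standards)
#' quantifyProtein(sim$samples$area_ratio, curve, 50)
#' @export
generateMrmAreas <- function(trueConcFmolPerUg, digestedProteinUg = 50,
                             standardsFmol = c(5, 10, 25, 50, 100, 250, 500),
                             standardReplicates = 1,
                             responseSlope = 0.02, responseIntercept = 0,
                             noiseCv = 0.05, seed = NULL) {
  stopifnot(responseSlope > 0, noiseCv >= 0)
  .withSeed(seed, {
    sf <- rep(standardsFmol, each = standardReplicates)
    std_ratio <- (responseIntercept + responseSlope * sf) *
      .lognormMult(length(sf), noiseCv)
    amounts <- trueConcFmolPerUg * digestedProteinUg
    smp_ratio <- (responseIntercept + responseSlope * amounts) *
      .lognormMult(length(amounts), noiseCv)
    list(standards = data.frame(known_fmol = sf, area_ratio = std_ratio),
         samples = data.frame(
           sample_id = sprintf("sim%02d", seq_along(amounts)),
           true_conc_fmol_per_ug = trueConcFmolPerUg,
           digested_protein_ug = digestedProteinUg,
           area_ratio = smp_ratio,
           stringsAsFactors = FALSE))
  })
}
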