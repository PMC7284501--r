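---
title: "Measuring blood-brain barrier transport with in situ brain perfusion: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring blood-brain barrier transport with in situ brain perfusion: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bbbPK)
```

## The measurement problem

In situ brain perfusion replaces the cerebral blood supply with an
artificial perfusate of known composition, infused through the carotid
artery for a short, fixed time (120 s for the test tracer here; 60 s for the
flow marker). The animal is then decapitated, brain regions (cerebrum,
cerebellum, brainstem) are dissected, and two isotope channels are counted
per tissue: the test tracer and a co-perfused vascular marker (sucrose) that
cannot cross an intact blood-brain barrier. The quantities of interest are
the tissue's vascular volume, the tracer's barrier clearance, and how that
clearance responds to efflux-transporter inhibitors or knockouts.

## The clearance model

All calculations are algebraic and unit-rigid (dpm/g for tissue counts,
dpm/uL for perfusate concentrations, seconds, uL/g, uL/s/g):

* Vascular volume: $V_v = X^* / C^*_{perf}$. Because the marker stays
  intravascular, this is the tissue's perfused vascular space, and a rise in
  it signals barrier leakage.
* Vascular correction: $X_{tissue} = X_{tot} - V_v C_{perf}$. The tracer
  sitting in the vascular space is subtracted; what remains entered the
  tissue.
* Distribution volume: $V_{tissue} = X_{tissue} / C_{perf}$.
* Initial clearance: $K_{in} = V_{tissue} / T$, valid while uptake is in its
  initial linear phase — a single-time-point design; no multi-time
  regression is attempted.
* Extraction: $E(\%) = 100 \, K_{in} / F$, where $F$ is the regional
  perfusion flow measured with a fully extracted flow marker (diazepam).
  Below 30 % extraction, uptake is flow independent; at or above 30 % the
  sample is flagged `flow_dependent`.

Two representation choices matter in practice:

* **Negative corrected amounts are kept, flagged, and clamped only for
  reporting.** Counting noise pushes genuinely low-uptake samples below the
  vascular background. Silently keeping negatives corrupts group means with
  physically impossible volumes; silently zeroing them hides the event. The
  pipeline reports $V_{tissue} = \max(X_{tissue}, 0)/C_{perf}$, keeps the
  signed value in `Vtissue_signed`, and flags the row
  `below_vascular_background`.
* **A missing flow reference is a flag, not a zero.** $E = 0$ is a
  meaningful measurement; a region without flow-marker animals gets `E = NA`
  and `missing_flow_reference`. Flow is averaged per region and per species
  and never pooled across species, since regional flows differ and the two
  species are perfused at different pump rates. Extraction uses the
  region's mean flow, not an animal-paired value, because the flow marker is
  perfused in separate animals.

## The simulator

The generator exists so every downstream stage can be tested by parameter
recovery against known truth; it emulates the study design, not any
particular dataset.

**Transport physics.** True clearance follows the Crone-Renkin
single-capillary model, $K_{in} = F(1 - e^{-PS_{app}/F})$, which produces
both regimes the assay relies on: at low $PS_{app}/F$, $K_{in} \to PS_{app}$
(flow-independent), and at high $PS_{app}/F$, $K_{in} \to F$ (the
100 %-extracted flow marker, simulated at $PS_{app} = 40F$). Efflux enters
as a divisor on the passive permeability,
$PS_{app} = PS_{passive} / (1 + \sum_t a_t g_t (1 - i_t))$, with activity
$a_t \ge 0$, genotype indicator $g_t$, and fractional inhibition
$i_t \in [0,1]$. The divisor form was chosen over a subtractive clearance
because it can never drive $PS_{app}$ negative, and it makes a knockout
($g_t = 0$) exactly equivalent to complete inhibition ($i_t = 1$) by
construction. A "third elacridar-sensitive transporter" (`ET3`) is a
first-class entity, so the dissociation between dual-inhibitor treatment and
the double-knockout genotype — the mechanistically interesting case — is
simulable: `defaultMouseScenario()` encodes elacridar as inhibiting P-gp,
Bcrp and ET3 while the TKO group lacks only P-gp/Bcrp, which forces the
ordering Kin(WT) < Kin(TKO) < Kin(TKO + elacridar).

**Noise model.** Two independently switchable layers: (1) per-animal
biological variability as a mean-preserving lognormal multiplier on the true
clearance and vascular volume (default CV 25 %, the magnitude suggested by
published group SDs of this assay, e.g. clearances reported as
0.10 +/- 0.03); (2) counting noise as Poisson on total disintegrations,
given a specimen mass (default 0.4 g rat, 0.15 g mouse). Perfusate
concentrations default to the assay's nominal radioactivity levels converted
to dpm/uL (660 for the test tracer, 222 for the sucrose channel, 600 for the
flow marker), which makes relative counting error small next to biological
CV — the dpm scale is otherwise arbitrary and documented as such, since
specimen masses and raw count magnitudes are not part of the published
design. Background dpm defaults to zero because the estimator does not model
background; the field exists and is exercised in tests.

**Default physiology.** Regional flows keep the ordering
cerebrum > cerebellum > brainstem (30/15/10 uL/s/g rat) and vascular volumes
are higher in cerebellum and brainstem than cerebrum (18/16 vs 10 uL/g),
matching the qualitative regional physiology of the assay. Passive
permeabilities are set so untreated control clearances sit near 0.18, 0.10
and 0.09 uL/s/g with extractions of 0.6-0.9 % — inside the 0.5-2 %
flow-independent window where this tracer operates. Transporter activities
(P-gp 0.75, Bcrp 0.75, ET3 4, Mrp 0.5 in the rat default) give the
qualitative inhibitor pattern: single P-gp or Bcrp inhibition does little,
dual+ET3 inhibition (elacridar) gives a several-fold increase, Mrp
inhibition an intermediate one. These defaults are configuration, not
claims: the divisor model cannot reproduce every published fold
simultaneously (with shared activities, the elacridar and MK-571 folds
constrain each other), so the defaults aim at the correct ordering and
magnitudes rather than exact printed values, which were derived from
unpublished raw counts.

**Seeding.** One root seed per scenario; each sample's draws come from a
substream selected by two exact Lehmer steps (multiplier 48271 modulo
$2^{31}-1$; every intermediate stays below $2^{53}$, so the arithmetic is
exact in doubles) mixing the root seed with the sample counter. Generating a
sample neither depends on how many samples precede it nor perturbs the
caller's RNG state.

**What the simulator does not model** — and hence what passing recovery
tests do not show about real data: capillary heterogeneity, tracer
metabolism during the perfusion, plasma-protein binding, tumor-compartment
uptake, within-animal correlation across regions (each simulated sample is
an independent animal), and any barrier damage mechanism (group labels such
as control/sham/DIPG share identical physiology in `dipgRatScenario()`,
encoding the intact-barrier case).

## The statistical layer

Group results are mean +/- SD (n-1 denominator; SD undefined at n = 1).
Two-group contrasts use the Student (pooled) t-test to mirror the assay's
customary analysis, with Welch behind a flag. Multi-group contrasts use
one-way ANOVA with Tukey HSD adjusted p-values (Tukey-Kramer for the
unbalanced group sizes, n = 4-10, that these studies produce). ANOVA is run
within each stratum (region by default) rather than pooled with region as a
factor; factorial designs across region x group are handled as one-way
ANOVA per stratum, a documented simplification — no interaction terms are
estimated. Degenerate inputs are resolved explicitly: all-identical
observations give F = 0 with p = 1, and a zero-variance two-group comparison
returns p = 1 for equal means and the limiting p = 0 otherwise. The
significance threshold is 0.05 throughout.

**Fold changes.** Effect sizes are ratios of group mean clearances with a
seeded, stratified bootstrap over animals (default 10,000 resamples). The
default interval is a studentized (bootstrap-t) interval on the log fold:
each resample's log fold is centred and scaled by its own delta-method
standard error, and the resulting t quantiles are applied to the observed
log fold. The plain percentile interval (available as
`ciMethod = "percentile"`) is anti-conservative at these group sizes — a
resampled mean of n observations understates the sampling variance by a
factor of $(n-1)/n$ per group, which at n = 5 is a ~10 % deficit in spread
before skewness costs anything — and our replicate-study checks confirm its
coverage falls short of nominal while the studentized interval holds within
the 90-99 % band (the acceptance script recomputes this coverage on every
run). Zero-spread groups collapse the interval onto the point estimate.

## Proteomics quantification

The targeted-proteomics step converts light/heavy MRM area ratios into
absolute protein concentrations. Calibration is a weighted least-squares
line of area ratio on known amount; 1/x weighting is the default because
isotope-dilution curves span orders of magnitude and unweighted fits let the
top standards dominate. A curve is rejected outright for a non-positive
slope. The limit of quantification is operational: the lowest standard level
whose mean back-calculated amount lands within +/-20 % of nominal. Samples
back-calculating below the LOQ — including negative back-calculations —
are reported as the token `<LOQ`, never as a number, so downstream tables
preserve censoring. The fixed internal-standard spike (750 fmol per digest)
is metadata: the light/heavy ratio already normalizes by it on both sides of
the calibration. Peptides that cannot distinguish species orthologs (the
human/rodent shared case) carry a `species_specificity` annotation through
to reports rather than being silently merged. Replicate digests are reported
individually alongside their mean, not collapsed.

## Problem sizes and numerical tolerances

The test suite and acceptance script use sizes chosen to make Monte-Carlo
error small relative to the property being checked while keeping a full run
in the low minutes: 1,000 random samples for the equation-oracle
equivalence (tolerance 1e-12 relative, pure algebra), 200 replicate studies
for fold-change recovery (bootstrap 5,000-10,000), 5,000-10,000 null
datasets for ANOVA type-I calibration, 400 replicate digests for proteomics
unbiasedness, and 4,000 samples for the generator's law-of-large-numbers
check (judged at 3 Monte-Carlo SEs). Report files format doubles with 17
significant digits so that write/read round trips are bit-exact, and
identical inputs produce byte-identical outputs.

## Known limitations

* Single-time-point clearance assumes linear uptake over the perfusion
  window; it cannot detect backflux (no $k_{out}$ modelling), and the
  Crone-Renkin relation is used only to generate data, never inverted to
  estimate PS from measured extraction.
* The efflux divisor model is a deliberately minimal mechanism; activities
  are scenario-level (shared across regions), so region-specific transporter
  expression must be encoded as separate scenarios.
* The bootstrap interval is calibrated for ratios of means of positive,
  moderately skewed data at small n; heavily censored groups (many
  below-background zeros) will degrade it.
* LOQ handling censors at the curve level only; no imputation or
  maximum-likelihood treatment of `<LOQ` values is attempted in group
  statistics.
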