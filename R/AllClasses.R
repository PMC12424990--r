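## S4 class definitions for the whole package. Validity methods enforce the
## cheap structural invariants; full scheme diagnostics live in
## validateScheme(), which returns a report instead of failing.

setClassUnion("numericOrNULL", c("numeric", "NULL"))

## ---------------------------------------------------------------------------
## Ion cloud
## ---------------------------------------------------------------------------

#' Configuration of the synthetic precursor-cloud generator
#'
#' Parameters of the synthetic peptide precursor ion cloud: the per-charge
#' linear trend of reduced ion mobility (1/K0) against m/z, the Gaussian
#' scatter around those trend lines, per-charge log-normal peptide masses
#' (converted to m/z with the proton mass), log-normal intensities, LC
#' elution parameters, and the fragment-ion model (3-10 fragments per
#' precursor, uniform m/z inside the MS2 scan range, Dirichlet relative
#' intensities). Defaults emulate a tryptic-digest timsTOF ion map in which
#' charge 2-3 ions at similar mobility spread over an interquartile range of
#' about 70 m/z, with the singly-charged trend lying at higher 1/K0 than the
#' multiply-charged trends at equal m/z.
#'
#' @slot nIons number of precursors to generate.
#' @slot chargeProbs named numeric, probability of each charge state
#'   (names are the charge values); must sum to 1.
#' @slot trendSlope,trendIntercept named numeric, per-charge coefficients of
#'   the linear 1/K0 = intercept + slope * m/z trend.
#' @slot imScatterSd standard deviation (1/K0 units) of Gaussian scatter of
#'   ion mobility around the charge trend line.
#' @slot massMeanlog,massSdlog named numeric, per-charge log-normal peptide
#'   neutral-mass parameters (Da).
#' @slot intensityLognorm numeric(2), (meanlog, sdlog) of precursor
#'   intensities.
#' @slot rtFwhmS LC peak full width at half maximum, seconds.
#' @slot gradientLengthS LC gradient length, seconds; elution apexes are
#'   uniform over it.
#' @slot mzRange,imRange numeric(2), bounds of the precursor ion space; ions
#'   are rejection-sampled until they fall inside.
#' @slot ms2Range numeric(2), MS2 scan range for fragment m/z sampling.
#' @slot nFragRange integer(2), inclusive range of fragments per precursor.
#' @slot seed RNG seed; identical seeds give byte-identical clouds.
#'
#' @seealso [cloudGenConfig()], [generateSyntheticCloud()]
#' @export
setClass("CloudGenConfig",
  representation(
    nIons = "numeric",
    chargeProbs = "numeric",
    trendSlope = "numeric",
    trendIntercept = "numeric",
    imScatterSd = "numeric",
    massMeanlog = "numeric",
    massSdlog = "numeric",
    intensityLognorm = "numeric",
    rtFwhmS = "numeric",
    gradientLengthS = "numeric",
    mzRange = "numeric",
    imRange = "numeric",
    ms2Range = "numeric",
    nFragRange = "numeric",
    seed = "numeric"
  )
)

setValidity("CloudGenConfig", function(object) {
  msg <- character()
  p <- object@chargeProbs
  if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-8)
    msg <- c(msg, "chargeProbs must lie in [0,1] and sum to 1")
  if (is.null(names(p)) || any(is.na(suppressWarnings(as.integer(names(p))))))
    msg <- c(msg, "chargeProbs must be named by integer charge states")
  for (s in c("trendSlope", "trendIntercept", "massMeanlog", "massSdlog")) {
    v <- slot(object, s)
    if (!all(names(p) %in% names(v)))
      msg <- c(msg, sprintf("%s must carry a value for every charge state", s))
  }
  if (object@imScatterSd <= 0) msg <- c(msg, "imScatterSd must be > 0")
  if (object@rtFwhmS <= 0) msg <- c(msg, "rtFwhmS must be > 0")
  if (object@gradientLengthS <= 0) msg <- c(msg, "gradientLengthS must be > 0")
  if (length(object@mzRange) != 2 || diff(object@mzRange) <= 0)
    msg <- c(msg, "mzRange must be increasing numeric(2)")
  if (length(object@imRange) != 2 || diff(object@imRange) <= 0)
    msg <- c(msg, "imRange must be increasing numeric(2)")
  if (length(object@ms2Range) != 2 || diff(object@ms2Range) <= 0)
    msg <- c(msg, "ms2Range must be increasing numeric(2)")
  if (length(object@nFragRange) != 2 || object@nFragRange[1] < 1 ||
      object@nFragRange[2] < object@nFragRange[1])
    msg <- c(msg, "nFragRange must be increasing integer(2) with min >= 1")
  if (length(msg)) msg else TRUE
})

#' Precursor ion cloud in m/z x ion-mobility space
#'
#' A collection of charged peptide precursor species, each with m/z, charge,
#' reduced ion mobility 1/K0, abundance and a Gaussian LC elution profile
#' (apex and FWHM), plus their fragment ions (m/z and relative intensity).
#' The cloud is the "precursor ion space" that acquisition schemes are
#' designed over.
#'
#' @slot ions data.frame with columns `id`, `mz`, `charge`, `inv_k0`,
#'   `intensity`, `rt_apex_s`, `rt_fwhm_s`.
#' @slot fragments data.frame with columns `parent_id`, `mz`,
#'   `rel_intensity`.
#' @slot mzRange,imRange numeric(2) bounds; every ion lies inside them.
#' @slot gradientLengthS gradient length in seconds.
#'
#' @seealso [generateSyntheticCloud()], [readCloudTable()]
#' @export
setClass("IonCloud",
  representation(
    ions = "data.frame",
    fragments = "data.frame",
    mzRange = "numeric",
    imRange = "numeric",
    gradientLengthS = "numeric"
  )
)

.ION_COLS <- c("id", "mz", "charge", "inv_k0", "intensity",
               "rt_apex_s", "rt_fwhm_s")
.FRAG_COLS <- c("parent_id", "mz", "rel_intensity")

setValidity("IonCloud", function(object) {
  msg <- character()
  io <- object@ions
  if (!all(.ION_COLS %in% names(io)))
    msg <- c(msg, paste("ions must have columns:", paste(.ION_COLS, collapse = ", ")))
  if (!all(.FRAG_COLS %in% names(object@fragments)))
    msg <- c(msg, paste("fragments must have columns:", paste(.FRAG_COLS, collapse = ", ")))
  if (nrow(io)) {
    if (anyDuplicated(io$id)) msg <- c(msg, "ion ids must be unique")
    if (any(io$mz <= 0)) msg <- c(msg, "mz must be > 0")
    if (any(io$charge < 1)) msg <- c(msg, "charge must be >= 1")
    if (any(io$inv_k0 <= 0.4) || any(io$inv_k0 >= 2.0))
      msg <- c(msg, "inv_k0 must lie in (0.4, 2.0)")
    if (any(io$intensity < 0)) msg <- c(msg, "intensity must be >= 0")
    if (any(io$rt_fwhm_s <= 0)) msg <- c(msg, "rt_fwhm_s must be > 0")
  }
  fr <- object@fragments
  if (nrow(fr)) {
    if (any(fr$rel_intensity <= 0) || any(fr$rel_intensity > 1))
      msg <- c(msg, "fragment rel_intensity must lie in (0, 1]")
    sums <- tapply(fr$rel_intensity, fr$parent_id, sum)
    if (any(sums > 1 + 1e-9))
      msg <- c(msg, "per-parent fragment rel_intensity must sum to <= 1")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Acquisition scheme
## ---------------------------------------------------------------------------

#' PASEF acquisition scheme: subcycles, frames and slice-steps
#'
#' Tabular model of a DIA-PASEF acquisition cycle. A cycle is an ordered set
#' of subcycles; a subcycle is an ordered set of frames (optionally one MS1
#' frame first); an MS2 ("PASEF") frame is an ordered set of slice-steps,
#' each pairing an ion-mobility interval with a Q1 isolation window. All
#' intervals follow the half-open convention `[lo, hi)` in both m/z and
#' 1/K0, so abutting steps never isolate the same point twice.
#'
#' @slot frames data.frame with columns `subcycle`, `frame`, `kind`
#'   ("MS1" or "MS2"), `fill_time_ms`, `repeats`. `frame` numbers frames
#'   consecutively across the whole cycle.
#' @slot steps data.frame with columns `subcycle`, `frame`, `step`,
#'   `im_lo`, `im_hi`, `mz_lo`, `mz_hi`, `ce_ev` (NA when unset).
#' @slot mzRange,imRange numeric(2) overall bounds of the scheme.
#' @slot label free-text description.
#'
#' @seealso [acquisitionScheme()], [design1F()], [designDiapasefReference()]
#' @export
setClass("AcquisitionScheme",
  representation(
    frames = "data.frame",
    steps = "data.frame",
    mzRange = "numeric",
    imRange = "numeric",
    label = "character"
  )
)

.FRAME_COLS <- c("subcycle", "frame", "kind", "fill_time_ms", "repeats")
.STEP_COLS <- c("subcycle", "frame", "step", "im_lo", "im_hi",
                "mz_lo", "mz_hi", "ce_ev")

setValidity("AcquisitionScheme", function(object) {
  msg <- character()
  fr <- object@frames
  st <- object@steps
  if (!all(.FRAME_COLS %in% names(fr)))
    msg <- c(msg, paste("frames must have columns:", paste(.FRAME_COLS, collapse = ", ")))
  if (!all(.STEP_COLS %in% names(st)))
    msg <- c(msg, paste("steps must have columns:", paste(.STEP_COLS, collapse = ", ")))
  if (length(msg)) return(msg)
  if (!nrow(fr)) msg <- c(msg, "scheme must contain at least one subcycle with frames")
  if (nrow(fr)) {
    if (!all(fr$kind %in% c("MS1", "MS2")))
      msg <- c(msg, "frame kind must be 'MS1' or 'MS2'")
    if (any(fr$fill_time_ms <= 0)) msg <- c(msg, "fill_time_ms must be > 0")
    if (any(fr$repeats < 1)) msg <- c(msg, "repeats must be >= 1")
    if (!any(fr$kind == "MS2")) msg <- c(msg, "scheme must contain an MS2 frame")
    for (sc in unique(fr$subcycle)) {
      if (!any(fr$kind[fr$subcycle == sc] == "MS2"))
        msg <- c(msg, sprintf("subcycle %s has no MS2 frame", sc))
    }
  }
  ## NOTE: inverted step intervals are deliberately NOT a validity failure;
  ## parsing and validation are separate concerns and validateScheme()
  ## reports interval geometry problems as diagnostics.
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Designer configuration and CE ramp
## ---------------------------------------------------------------------------

#' Configuration of the Slice-PASEF scheme designer
#'
#' @slot nImSteps number of contiguous ion-mobility slices per MS2 frame.
#' @slot qLo,qHi envelope quantiles of multiply-charged precursor m/z used
#'   to place each slice's Q1 window.
#' @slot padMz symmetric window padding in Thomson.
#' @slot minWidthMz minimum Q1 window width in Thomson; narrower envelope
#'   windows are widened symmetrically to this floor.
#' @slot fillTimeMs TIMS accumulation/ramp time per frame, milliseconds.
#' @slot ms1PerSubcycle 0 or 1 MS1 frames at the start of each subcycle.
#' @slot boundaryMode "midpoint" or "balanced" splitting of the 1F window in
#'   multi-frame designs; "balanced" places boundaries at per-step
#'   intensity quantiles of the isolated ions.
#' @slot shiftSubcycles when TRUE, multi-frame cycles alternate two subcycle
#'   variants whose m/z boundaries are offset by half a segment.
#' @slot ceRamp a [CERamp-class] used to fill per-step collision energies,
#'   or NULL to leave them unset.
#'
#' @seealso [designConfig()], [design1F()], [designMultiframe()]
#' @export
setClass("DesignConfig",
  representation(
    nImSteps = "numeric",
    qLo = "numeric",
    qHi = "numeric",
    padMz = "numeric",
    minWidthMz = "numeric",
    fillTimeMs = "numeric",
    ms1PerSubcycle = "numeric",
    boundaryMode = "character",
    shiftSubcycles = "logical",
    ceRamp = "ANY"
  )
)

setValidity("DesignConfig", function(object) {
  msg <- character()
  if (object@nImSteps < 1) msg <- c(msg, "nImSteps must be >= 1")
  if (!(object@qLo >= 0 && object@qLo < object@qHi && object@qHi <= 1))
    msg <- c(msg, "need 0 <= qLo < qHi <= 1")
  if (object@minWidthMz <= 0) msg <- c(msg, "minWidthMz must be > 0")
  if (object@padMz < 0) msg <- c(msg, "padMz must be >= 0")
  if (object@fillTimeMs <= 0) msg <- c(msg, "fillTimeMs must be > 0")
  if (!object@ms1PerSubcycle %in% c(0, 1))
    msg <- c(msg, "ms1PerSubcycle must be 0 or 1")
  if (!object@boundaryMode %in% c("midpoint", "balanced"))
    msg <- c(msg, "boundaryMode must be 'midpoint' or 'balanced'")
  if (!(is.null(object@ceRamp) || is(object@ceRamp, "CERamp")))
    msg <- c(msg, "ceRamp must be NULL or a CERamp")
  if (length(msg)) msg else TRUE
})

#' Collision-energy ramp over ion mobility
#'
#' Piecewise-linear collision energy as a function of reduced ion mobility,
#' defined by ordered (1/K0, CE) anchor pairs and clamped to the terminal
#' anchors outside their range. The default anchors, 20 eV at 1/K0 = 0.60
#' and 59 eV at 1/K0 = 1.60, are typical timsTOF DIA settings.
#'
#' @slot invK0 strictly increasing anchor positions, V s/cm^2.
#' @slot ceEv collision energies at the anchors, eV.
#'
#' @seealso [ceRamp()], [ceAt()]
#' @export
setClass("CERamp", representation(invK0 = "numeric", ceEv = "numeric"))

setValidity("CERamp", function(object) {
  msg <- character()
  if (length(object@invK0) < 2) msg <- c(msg, "need >= 2 anchors")
  if (length(object@invK0) != length(object@ceEv))
    msg <- c(msg, "invK0 and ceEv must have equal length")
  if (length(object@invK0) >= 2 && any(diff(object@invK0) <= 0))
    msg <- c(msg, "anchor invK0 must be strictly increasing")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Evaluator
## ---------------------------------------------------------------------------

#' Analytic figures of merit of a scheme against a cloud
#'
#' @slot cycleTimeMs total time of one full DIA cycle (all frames, MS1 and
#'   repeats included), milliseconds.
#' @slot dutyCycle intensity-weighted mean per-precursor MS/MS duty fraction
#'   over multiply-charged ions, in `[0, 1]`.
#' @slot coverage fraction of multiply-charged cloud intensity isolated at
#'   least once per cycle.
#' @slot dutyCycleCount,coverageCount the same two quantities with every ion
#'   weighted equally instead of by intensity.
#' @slot pointsPerPeak LC peak FWHM divided by the cycle time.
#'
#' @seealso [schemeMetrics()], [precursorDutyCycle()], [dutyRatio()]
#' @export
setClass("CycleMetrics",
  representation(
    cycleTimeMs = "numeric",
    dutyCycle = "numeric",
    coverage = "numeric",
    dutyCycleCount = "numeric",
    coverageCount = "numeric",
    pointsPerPeak = "numeric"
  )
)

setValidity("CycleMetrics", function(object) {
  msg <- character()
  if (object@cycleTimeMs <= 0) msg <- c(msg, "cycleTimeMs must be > 0")
  for (s in c("dutyCycle", "coverage")) {
    v <- slot(object, s)
    if (!is.na(v) && (v < 0 || v > 1))
      msg <- c(msg, sprintf("%s must lie in [0, 1]", s))
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Simulator and matcher configuration
## ---------------------------------------------------------------------------

#' Configuration of the in-silico acquisition simulator
#'
#' @slot mzJitterPpm Gaussian m/z measurement noise, ppm (1 sd).
#' @slot imJitterSd Gaussian 1/K0 measurement noise (1 sd).
#' @slot intensityCv multiplicative run-to-run intensity noise: one
#'   log-normal factor with this coefficient of variation is drawn per
#'   precursor per simulated run and applied to all of its peaks.
#' @slot noisePeaksPerFrame count of spurious background peaks added to each
#'   MS2 frame.
#' @slot switchLossFraction optional quadrupole-switch loss model: fraction
#'   of signal removed from the first [switchLossSpan] of each slice-step
#'   that follows a discontinuous Q1 jump (0 disables the model).
#' @slot switchLossSpan fraction of a post-switch step treated as affected
#'   by the switch.
#' @slot seed RNG seed; fixed seed gives an identical frame stream.
#'
#' @seealso [simConfig()], [simulateAcquisition()]
#' @export
setClass("SimConfig",
  representation(
    mzJitterPpm = "numeric",
    imJitterSd = "numeric",
    intensityCv = "numeric",
    noisePeaksPerFrame = "numeric",
    switchLossFraction = "numeric",
    switchLossSpan = "numeric",
    seed = "numeric"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  for (s in c("mzJitterPpm", "imJitterSd", "intensityCv",
              "noisePeaksPerFrame", "switchLossFraction", "switchLossSpan")) {
    if (slot(object, s) < 0) msg <- c(msg, sprintf("%s must be >= 0", s))
  }
  if (object@switchLossFraction > 1)
    msg <- c(msg, "switchLossFraction must be <= 1")
  if (object@switchLossSpan > 1) msg <- c(msg, "switchLossSpan must be <= 1")
  if (length(msg)) msg else TRUE
})

#' Configuration of the fragment matcher
#'
#' @slot mzTolPpm fragment/precursor mass tolerance in ppm (default 15, a
#'   typical fixed DIA search tolerance for timsTOF data).
#' @slot imTol ion-mobility tolerance in 1/K0 units.
#'
#' @seealso [matchConfig()], [candidateFrames()], [extractXic()]
#' @export
setClass("MatchConfig", representation(mzTolPpm = "numeric", imTol = "numeric"))

setValidity("MatchConfig", function(object) {
  msg <- character()
  if (object@mzTolPpm <= 0) msg <- c(msg, "mzTolPpm must be > 0")
  if (object@imTol <= 0) msg <- c(msg, "imTol must be > 0")
  if (length(msg)) msg else TRUE
})

#' Extracted ion chromatogram of one precursor
#'
#' Per-cycle trace of a precursor's summed best-peak fragment signal, with
#' its apex, the trapezoidal area of the contiguous region at or above half
#' the apex (in intensity x cycle units, so the quantity scales with both
#' per-frame signal and sampling rate), and the measured number of cycles at
#' or above half the apex (points at FWHM).
#'
#' @slot trace data.frame with columns `cycle`, `rt_s`, `intensity`
#'   (rt strictly increasing).
#' @slot apex apex intensity of the trace.
#' @slot area quantity: trapezoidal area over the contiguous above-half-apex
#'   region, in intensity x cycle-index units.
#' @slot pointsAtFwhm count of cycles in that region.
#' @slot allZero TRUE when the trace carried no signal.
#'
#' @seealso [extractXic()], [quantifyXic()]
#' @export
setClass("XIC",
  representation(
    trace = "data.frame",
    apex = "numeric",
    area = "numeric",
    pointsAtFwhm = "numeric",
    allZero = "logical"
  )
)

setValidity("XIC", function(object) {
  msg <- character()
  tr <- object@trace
  if (!all(c("cycle", "rt_s", "intensity") %in% names(tr)))
    msg <- c(msg, "trace must have columns cycle, rt_s, intensity")
  else if (nrow(tr)) {
    if (any(diff(tr$rt_s) <= 0)) msg <- c(msg, "trace rt_s must be strictly increasing")
    if (any(tr$intensity < 0)) msg <- c(msg, "trace intensities must be >= 0")
  }
  if (length(msg)) msg else TRUE
})
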