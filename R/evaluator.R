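## Analytic figures of merit: per-precursor MS/MS duty cycle, scheme-level
## duty/coverage/cycle-time/points-per-peak, and scheme comparison.

#' Per-precursor MS/MS duty cycle
#'
#' Fraction of the cycle's total MS2 fill time during which a precursor at
#' `(mz, invK0)` is being fragmented:
#' `sum(fill * repeats over MS2 frames isolating the point) /
#'  sum(fill * repeats over all MS2 frames)`.
#' MS1 frames are excluded from numerator and denominator -- this is what
#' makes a single-frame slicing scheme score exactly 100% and a
#' non-overlapping 8-frame reference score exactly 12.5% (= 1/8) even when
#' MS1 scans are present. A point outside every window scores 0.
#'
#' @param scheme an [AcquisitionScheme-class].
#' @param mz,invK0 query coordinates (equal-length vectors are recycled).
#' @return numeric vector of duty fractions in `[0, 1]`.
#' @export
precursorDutyCycle <- function(scheme, mz, invK0) {
  fr <- scheme@frames
  ms2 <- fr[fr$kind == "MS2", , drop = FALSE]
  denom <- sum(ms2$fill_time_ms * ms2$repeats)
  k <- max(length(mz), length(invK0))
  mz <- rep_len(mz, k)
  invK0 <- rep_len(invK0, k)
  num <- numeric(k)
  for (i in seq_len(nrow(ms2))) {
    hit <- frameIsolates(scheme, ms2$subcycle[i], ms2$frame[i], mz, invK0)
    num <- num + hit * ms2$fill_time_ms[i] * ms2$repeats[i]
  }
  num / denom
}

#' Figures of merit of a scheme against an ion cloud
#'
#' Computes one full-cycle summary: `cycleTimeMs` is the sum of fill times
#' over all frames (MS1 and repeats included); `dutyCycle` is the
#' intensity-weighted mean of [precursorDutyCycle()] over the
#' multiply-charged (z >= 2) ions; `coverage` is the fraction of
#' multiply-charged intensity isolated at least once per cycle; and
#' `pointsPerPeak` is `1000 * peakFwhmS / cycleTimeMs`. Ion-count-weighted
#' (unweighted) versions of duty and coverage are reported alongside.
#'
#' @param scheme an [AcquisitionScheme-class].
#' @param cloud an [IonCloud-class].
#' @param peakFwhmS LC peak FWHM in seconds used for points-per-peak
#'   (default: median of the cloud's per-ion FWHM).
#' @return a [CycleMetrics-class]. An empty cloud yields NaN duty and
#'   coverage with a warning.
#' @export
schemeMetrics <- function(scheme, cloud, peakFwhmS = NULL) {
  fr <- scheme@frames
  cycle_ms <- sum(fr$fill_time_ms * fr$repeats)
  io <- ions(cloud)
  multi <- io[io$charge >= 2, , drop = FALSE]
  if (is.null(peakFwhmS)) {
    peakFwhmS <- if (nrow(io)) stats::median(io$rt_fwhm_s) else 1
  }
  if (!nrow(multi)) {
    warning("cloud has no multiply charged ions; duty cycle and coverage are undefined",
            call. = FALSE)
    duty_w <- duty_c <- cov_w <- cov_c <- NaN
  } else {
    duty <- precursorDutyCycle(scheme, multi$mz, multi$inv_k0)
    w <- multi$intensity
    duty_w <- sum(duty * w) / sum(w)
    duty_c <- mean(duty)
    cov_w <- sum((duty > 0) * w) / sum(w)
    cov_c <- mean(duty > 0)
  }
  new("CycleMetrics", cycleTimeMs = cycle_ms, dutyCycle = duty_w,
      coverage = cov_w, dutyCycleCount = duty_c, coverageCount = cov_c,
      pointsPerPeak = 1000 * peakFwhmS / cycle_ms)
}

#' Ratio of MS/MS duty cycles of two schemes
#'
#' The expected ratio of per-precursor MS/MS signal between two schemes
#' with equal fill times, e.g. 8 for a 1-frame slicing scheme against an
#' 8-frame reference, or 2 for a 4-frame scheme against it.
#'
#' @param a,b [CycleMetrics-class] objects (numerator, denominator).
#' @return `dutyCycle(a) / dutyCycle(b)`.
#' @export
dutyRatio <- function(a, b) {
  stopIfNot(is(a, "CycleMetrics") && is(b, "CycleMetrics"),
            "dutyRatio expects two CycleMetrics objects")
  stopIfNot(isTRUE(dutyCycle(b) > 0), "denominator scheme has zero duty cycle")
  dutyCycle(a) / dutyCycle(b)
}
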