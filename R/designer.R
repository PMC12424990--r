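## Construction of 1F/2F/4F Slice-PASEF schemes and reference dia-PASEF
## schemes from an ion cloud; CE ramps; frame-repeat arithmetic.

#' Create a designer configuration
#'
#' @param nImSteps contiguous ion-mobility slices per MS2 frame (default 20).
#' @param qLo,qHi m/z envelope quantiles per slice (defaults 0.005 / 0.995:
#'   each window spans essentially the whole multiply-charged population of
#'   its mobility slice).
#' @param padMz symmetric Q1 padding in Thomson (default 5).
#' @param minWidthMz minimum Q1 window width in Thomson (default 50,
#'   matching the lower end of typical 1-frame slice widths; upper widths
#'   emerge from the envelope and are uncapped).
#' @param fillTimeMs TIMS accumulation/ramp time per frame (default 100 ms).
#' @param ms1PerSubcycle 0 or 1 MS1 frames opening each subcycle (default 1).
#' @param boundaryMode "midpoint" (equal m/z segments) or "balanced"
#'   (per-step intensity quantiles) for multi-frame splits.
#' @param shiftSubcycles alternate two subcycle variants with boundaries
#'   offset by half a segment (default TRUE).
#' @param ceRamp optional [CERamp-class] to fill per-step collision
#'   energies; default [ceRamp()].
#' @return a validated [DesignConfig-class].
#' @export
designConfig <- function(nImSteps = 20, qLo = 0.005, qHi = 0.995, padMz = 5,
                         minWidthMz = 50, fillTimeMs = 100,
                         ms1PerSubcycle = 1,
                         boundaryMode = c("midpoint", "balanced"),
                         shiftSubcycles = TRUE, ceRamp = slicepasef::ceRamp()) {
  boundaryMode <- match.arg(boundaryMode)
  new("DesignConfig", nImSteps = nImSteps, qLo = qLo, qHi = qHi,
      padMz = padMz, minWidthMz = minWidthMz, fillTimeMs = fillTimeMs,
      ms1PerSubcycle = ms1PerSubcycle, boundaryMode = boundaryMode,
      shiftSubcycles = shiftSubcycles, ceRamp = ceRamp)
}

## Per-slice [qLo, qHi] m/z envelope of multiply charged ions, padded and
## widened to the minimum width; empty slices interpolated from neighbours.
.sliceWindows <- function(cloud, cfg) {
  io <- ions(cloud)
  multi <- io[io$charge >= 2, , drop = FALSE]
  if (!nrow(multi)) {
    stop("design requires multiply charged (z >= 2) ions in the cloud",
         call. = FALSE)
  }
  imr <- imRange(cloud)
  n <- as.integer(cfg@nImSteps)
  edges <- seq(imr[1], imr[2], length.out = n + 1L)
  win <- data.frame(step = seq_len(n), im_lo = edges[-(n + 1L)],
                    im_hi = edges[-1L], mz_lo = NA_real_, mz_hi = NA_real_,
                    n = 0L)
  bin <- findInterval(multi$inv_k0, edges, rightmost.closed = FALSE)
  bin[multi$inv_k0 >= imr[2]] <- n  # top edge closed for design purposes
  bin[bin < 1L] <- 1L
  for (b in seq_len(n)) {
    v <- multi$mz[bin == b]
    if (!length(v)) next
    qq <- quantileLower(v, c(cfg@qLo, cfg@qHi))
    win$mz_lo[b] <- qq[1]
    win$mz_hi[b] <- qq[2]
    win$n[b] <- length(v)
  }
  ## empty slices: linear interpolation between nearest non-empty slices,
  ## constant extrapolation at the edges (quasi-continuous slicing must not
  ## leave holes)
  filled <- which(!is.na(win$mz_lo))
  if (!length(filled)) stop("no ion-mobility slice contains multiply charged ions",
                            call. = FALSE)
  mid <- (win$im_lo + win$im_hi) / 2
  if (length(filled) == 1L) {
    win$mz_lo <- win$mz_lo[filled]
    win$mz_hi <- win$mz_hi[filled]
  } else {
    win$mz_lo <- approx(mid[filled], win$mz_lo[filled], xout = mid, rule = 2)$y
    win$mz_hi <- approx(mid[filled], win$mz_hi[filled], xout = mid, rule = 2)$y
  }
  ## pad, then widen symmetrically to the floor
  win$mz_lo <- win$mz_lo - cfg@padMz
  win$mz_hi <- win$mz_hi + cfg@padMz
  deficit <- cfg@minWidthMz - (win$mz_hi - win$mz_lo)
  widen <- pmax(deficit, 0) / 2
  win$mz_lo <- win$mz_lo - widen
  win$mz_hi <- win$mz_hi + widen
  win
}

.applyCe <- function(steps, ramp) {
  if (is.null(ramp)) return(steps)
  steps$ce_ev <- ceAt(ramp, (steps$im_lo + steps$im_hi) / 2)
  steps
}

.mzRangeFromSteps <- function(cloud, steps) {
  c(min(mzRange(cloud)[1], min(steps$mz_lo)),
    max(mzRange(cloud)[2], max(steps$mz_hi)))
}

#' Design a 1-frame Slice-PASEF scheme
#'
#' The whole multiply-charged precursor space is sampled in quasi-continuous
#' ion-mobility slices by a single MS2 frame per subcycle: the scheme's one
#' subcycle holds an optional MS1 frame and one MS2 frame of `nImSteps`
#' contiguous IM slices. Each slice's Q1 window spans the `[qLo, qHi]` m/z
#' envelope of the multiply-charged ions in that slice, padded by `padMz`
#' and widened symmetrically to at least `minWidthMz`; slices containing no
#' ions inherit windows interpolated from their neighbours. Singly-charged
#' ions are excluded by geometry: their trend lies at higher 1/K0, outside
#' the diagonal envelope of the multiply-charged population. Every isolated
#' precursor enjoys a 100% MS/MS duty cycle under this scheme.
#'
#' @param cloud an [IonCloud-class] with multiply-charged ions.
#' @param cfg a [DesignConfig-class].
#' @return an [AcquisitionScheme-class] labelled `"slice-1F"`.
#' @export
design1F <- function(cloud, cfg = designConfig()) {
  validObject(cfg)
  win <- .sliceWindows(cloud, cfg)
  frames <- data.frame(subcycle = 1L, frame = 1L, kind = "MS2",
                       fill_time_ms = cfg@fillTimeMs, repeats = 1L)
  steps <- data.frame(subcycle = 1L, frame = 1L, step = win$step,
                      im_lo = win$im_lo, im_hi = win$im_hi,
                      mz_lo = win$mz_lo, mz_hi = win$mz_hi,
                      ce_ev = NA_real_)
  if (cfg@ms1PerSubcycle >= 1) {
    frames$frame <- 2L
    steps$frame <- 2L
    frames <- rbind(data.frame(subcycle = 1L, frame = 1L, kind = "MS1",
                               fill_time_ms = cfg@fillTimeMs, repeats = 1L),
                    frames)
  }
  steps <- .applyCe(steps, cfg@ceRamp)
  acquisitionScheme(frames, steps, .mzRangeFromSteps(cloud, steps),
                    imRange(cloud), label = "slice-1F")
}

#' Design a 2- or 4-frame Slice-PASEF scheme
#'
#' Starts from the 1-frame windows and splits every slice's Q1 window into
#' `nFrames` contiguous m/z segments; frame `j` of a subcycle takes segment
#' `j` across all slices, trading MS/MS duty cycle (1/`nFrames` per
#' precursor) for reduced spectral complexity. With
#' `boundaryMode = "balanced"` the split boundaries are per-slice
#' intensity-weighted quantiles of the isolated ions, so each frame carries
#' an equal share of precursor signal; with `"midpoint"` the segments are
#' equal-width. With `shiftSubcycles` the cycle alternates two subcycle
#' variants whose boundaries are offset by half a segment (clamped to the
#' window edges), so consecutive subcycles slice the space at interleaved
#' positions.
#'
#' @inheritParams design1F
#' @param nFrames 2 or 4 MS2 frames per subcycle.
#' @return an [AcquisitionScheme-class] labelled `"slice-2F"`/`"slice-4F"`.
#' @export
designMultiframe <- function(cloud, cfg = designConfig(), nFrames = 2) {
  validObject(cfg)
  stopIfNot(nFrames %in% c(2, 4), "nFrames must be 2 or 4")
  nFrames <- as.integer(nFrames)
  win <- .sliceWindows(cloud, cfg)
  io <- ions(cloud)
  multi <- io[io$charge >= 2, , drop = FALSE]

  boundaries <- function(w) {
    ## inner boundaries of the nFrames segments of one slice window
    if (cfg@boundaryMode == "midpoint") {
      seq(w$mz_lo, w$mz_hi, length.out = nFrames + 1L)[2:nFrames]
    } else {
      inside <- multi$mz >= w$mz_lo & multi$mz < w$mz_hi &
        multi$inv_k0 >= w$im_lo & multi$inv_k0 < w$im_hi
      if (sum(inside) < nFrames) {
        seq(w$mz_lo, w$mz_hi, length.out = nFrames + 1L)[2:nFrames]
      } else {
        weightedQuantileLower(multi$mz[inside], multi$intensity[inside],
                              seq_len(nFrames - 1L) / nFrames)
      }
    }
  }

  n_subcycles <- if (cfg@shiftSubcycles) 2L else 1L
  frames <- list()
  steps <- list()
  frame_id <- 0L
  for (sc in seq_len(n_subcycles)) {
    if (cfg@ms1PerSubcycle >= 1) {
      frame_id <- frame_id + 1L
      frames[[length(frames) + 1L]] <- data.frame(
        subcycle = sc, frame = frame_id, kind = "MS1",
        fill_time_ms = cfg@fillTimeMs, repeats = 1L)
    }
    seg_bounds <- lapply(seq_len(nrow(win)), function(b) {
      w <- win[b, ]
      inner <- boundaries(w)
      if (sc == 2L) {
        ## half-a-segment shift (half the mean segment width), clamped
        half_seg <- (w$mz_hi - w$mz_lo) / nFrames / 2
        inner <- pmin(pmax(inner + half_seg, w$mz_lo), w$mz_hi)
      }
      c(w$mz_lo, inner, w$mz_hi)
    })
    for (j in seq_len(nFrames)) {
      frame_id <- frame_id + 1L
      frames[[length(frames) + 1L]] <- data.frame(
        subcycle = sc, frame = frame_id, kind = "MS2",
        fill_time_ms = cfg@fillTimeMs, repeats = 1L)
      steps[[length(steps) + 1L]] <- data.frame(
        subcycle = sc, frame = frame_id, step = win$step,
        im_lo = win$im_lo, im_hi = win$im_hi,
        mz_lo = vapply(seg_bounds, `[`, numeric(1), j),
        mz_hi = vapply(seg_bounds, `[`, numeric(1), j + 1L),
        ce_ev = NA_real_)
    }
  }
  frames <- do.call(rbind, frames)
  steps <- .applyCe(do.call(rbind, steps), cfg@ceRamp)
  acquisitionScheme(frames, steps, .mzRangeFromSteps(cloud, steps),
                    imRange(cloud), label = sprintf("slice-%dF", nFrames))
}

#' Design a reference dia-PASEF scheme
#'
#' Classical dia-PASEF: `nFrames * windowsPerFrame` fixed-width,
#' non-overlapping Q1 windows tile the m/z range and are laid out diagonally
#' in m/z x mobility space -- the window of rank `k` (ordered by m/z)
#' occupies the `k`-th of equally many ion-mobility strata. Frames
#' interleave the strata: frame `f` carries the windows of rank
#' `f, f + nFrames, f + 2 nFrames, ...`, so each frame stacks
#' `windowsPerFrame` windows at well-separated mobilities and every point of
#' the covered diagonal polygon is isolated by exactly one frame per cycle.
#'
#' @param mzRange,imRange numeric(2) covered ranges.
#' @param windowWidth Q1 window width in Thomson; `windowWidth *
#'   (nFrames * windowsPerFrame)` must equal the m/z span (a mismatch is an
#'   error suggesting the exact width).
#' @param nFrames MS2 frames per cycle (e.g. 8).
#' @param windowsPerFrame stacked windows per frame (e.g. 3).
#' @param fillTimeMs fill time per frame, milliseconds.
#' @param ms1PerCycle 0 or 1 MS1 frames opening the cycle.
#' @param ceRamp optional [CERamp-class] for per-step collision energies.
#' @return an [AcquisitionScheme-class] labelled `"dia-pasef-ref"` with one
#'   subcycle containing all frames.
#' @export
designDiapasefReference <- function(mzRange, imRange, windowWidth = 25,
                                    nFrames = 8, windowsPerFrame = 3,
                                    fillTimeMs = 100, ms1PerCycle = 0,
                                    ceRamp = NULL) {
  n_win <- as.integer(nFrames) * as.integer(windowsPerFrame)
  span <- mzRange[2] - mzRange[1]
  if (abs(n_win * windowWidth - span) > 1e-6) {
    stop(sprintf(paste0("window tiling mismatch: %d windows of %.4f Th cover ",
                        "%.4f Th but the m/z span is %.4f Th; use windowWidth = %.4f"),
                 n_win, windowWidth, n_win * windowWidth, span, span / n_win),
         call. = FALSE)
  }
  im_h <- (imRange[2] - imRange[1]) / n_win
  rank <- seq_len(n_win)
  win <- data.frame(
    rank = rank,
    mz_lo = mzRange[1] + (rank - 1L) * windowWidth,
    mz_hi = mzRange[1] + rank * windowWidth,
    im_lo = imRange[1] + (rank - 1L) * im_h,
    im_hi = imRange[1] + rank * im_h,
    frame = ((rank - 1L) %% as.integer(nFrames)) + 1L
  )
  frame_offset <- if (ms1PerCycle >= 1) 1L else 0L
  frames <- data.frame(subcycle = 1L,
                       frame = seq_len(nFrames) + frame_offset,
                       kind = "MS2", fill_time_ms = fillTimeMs, repeats = 1L)
  if (ms1PerCycle >= 1) {
    frames <- rbind(data.frame(subcycle = 1L, frame = 1L, kind = "MS1",
                               fill_time_ms = fillTimeMs, repeats = 1L),
                    frames)
  }
  steps <- do.call(rbind, lapply(seq_len(nFrames), function(f) {
    sub <- win[win$frame == f, , drop = FALSE]
    sub <- sub[order(sub$im_lo), , drop = FALSE]
    data.frame(subcycle = 1L, frame = f + frame_offset,
               step = seq_len(nrow(sub)),
               im_lo = sub$im_lo, im_hi = sub$im_hi,
               mz_lo = sub$mz_lo, mz_hi = sub$mz_hi, ce_ev = NA_real_)
  }))
  steps <- .applyCe(steps, ceRamp)
  acquisitionScheme(frames, steps, mzRange, imRange, label = "dia-pasef-ref")
}

#' Collision-energy ramps over ion mobility
#'
#' `ceRamp()` builds a piecewise-linear collision-energy ramp from anchor
#' points; `ceAt()` evaluates it, clamping to the terminal anchors outside
#' their range. The default anchors (20 eV at 1/K0 = 0.60, 59 eV at
#' 1/K0 = 1.60) are typical timsTOF DIA settings.
#'
#' @param invK0 strictly increasing anchor mobilities.
#' @param ceEv collision energies (eV) at the anchors.
#' @return `ceRamp()` a [CERamp-class]; `ceAt()` a numeric vector of eV.
#' @examples
#' ceAt(ceRamp(), 1.10)  # midpoint of the default linear ramp: 39.5 eV
#' @export
ceRamp <- function(invK0 = c(0.60, 1.60), ceEv = c(20, 59)) {
  new("CERamp", invK0 = invK0, ceEv = ceEv)
}

#' @rdname ceRamp
#' @param ramp a [CERamp-class].
#' @param at mobilities (1/K0) to evaluate at.
#' @export
ceAt <- function(ramp, at) {
  validObject(ramp)
  approx(ramp@invK0, ramp@ceEv, xout = at, rule = 2)$y
}

#' Frame repeats that keep enough chromatographic points per peak
#'
#' Repeating each MS2 frame of a short subcycle raises signal-to-noise
#' (repeat spectra are merged before peak picking) but lengthens the cycle.
#' This returns the largest repeat count `r >= 1` such that an LC peak of
#' the given FWHM is still sampled at least `minPoints` times per FWHM:
#' `peakFwhmS / ((ms1PerSubcycle + r * ms2FramesPerSubcycle) * frameTimeS)
#' >= minPoints`. If even `r = 1` violates the floor, 1 is returned with a
#' warning.
#'
#' @param peakFwhmS LC peak full width at half maximum, seconds.
#' @param frameTimeS time per frame (fill), seconds.
#' @param ms2FramesPerSubcycle MS2 frames per subcycle.
#' @param ms1PerSubcycle MS1 frames per subcycle (0 or 1).
#' @param minPoints minimum cycles per peak FWHM (default 3).
#' @return integer repeat count.
#' @examples
#' computeFrameRepeats(1.2, 0.1, 1, 1)  # 3: cycle 0.4 s, exactly 3 points
#' @export
computeFrameRepeats <- function(peakFwhmS, frameTimeS, ms2FramesPerSubcycle,
                                ms1PerSubcycle = 1, minPoints = 3) {
  stopIfNot(peakFwhmS > 0 && frameTimeS > 0 && ms2FramesPerSubcycle > 0,
            "all times and frame counts must be > 0")
  points_at <- function(r) {
    peakFwhmS / ((ms1PerSubcycle + r * ms2FramesPerSubcycle) * frameTimeS)
  }
  r_max <- floor((peakFwhmS / (minPoints * frameTimeS) - ms1PerSubcycle) /
                   ms2FramesPerSubcycle + 1e-9)
  if (is.na(r_max) || r_max < 1) {
    if (points_at(1) < minPoints) {
      warning(sprintf(paste0("even a single acquisition per frame yields only ",
                             "%.2f points per peak FWHM (< %g); returning 1"),
                      points_at(1), minPoints), call. = FALSE)
    }
    return(1L)
  }
  as.integer(r_max)
}
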