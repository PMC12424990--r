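## Ion-mobility-aware fragment matching against boundary-annotated frame
## spectra: frame candidacy, multi-frame best-peak fragment intensities,
## repeat merging, XIC extraction, quantification, CV summaries.

#' Create a matcher configuration
#'
#' @param mzTolPpm fragment/precursor m/z tolerance in ppm; default 15, a
#'   typical fixed DIA search tolerance for timsTOF data.
#' @param imTol ion-mobility tolerance in 1/K0 units; default 0.05.
#' @return a validated [MatchConfig-class].
#' @export
matchConfig <- function(mzTolPpm = 15, imTol = 0.05) {
  new("MatchConfig", mzTolPpm = mzTolPpm, imTol = imTol)
}

## peak rows compatible with a precursor: Q1 boundaries contain the
## precursor m/z (half-open) and ion mobility within tolerance
.precursorCompatible <- function(peaks, precMz, precIm, imTol) {
  peaks$q1_lo <= precMz & precMz < peaks$q1_hi &
    abs(peaks$inv_k0 - precIm) <= imTol
}

.asPrecursorRow <- function(precursor) {
  p <- as.list(precursor)
  stopIfNot(!is.null(p$mz) && !is.null(p$inv_k0),
            "precursor must carry mz and inv_k0")
  p
}

#' Frames of a subcycle a precursor must be queried against
#'
#' In sliced acquisition every MS2 frame spans a broad precursor m/z range,
#' so whether a precursor needs to be queried against a frame is decided by
#' its expected ion mobility in addition to its m/z: a frame is a candidate
#' iff it contains at least one peak whose annotated Q1 boundaries contain
#' the precursor m/z and whose ion mobility lies within `imTol` of the
#' precursor's. Only peaks with matching isolation boundaries are considered
#' by the downstream fragment matching.
#'
#' @param precursor a one-row data.frame or list with `mz` and `inv_k0`.
#' @param frames frame-stream rows of one subcycle instance (one `cycle` x
#'   `subcycle` combination).
#' @param cfg a [MatchConfig-class].
#' @return sorted integer vector of candidate `frame` indices.
#' @export
candidateFrames <- function(precursor, frames, cfg = matchConfig()) {
  p <- .asPrecursorRow(precursor)
  ms2 <- frames[frames$kind == "MS2", , drop = FALSE]
  if (!nrow(ms2)) return(integer())
  ok <- .precursorCompatible(ms2, p$mz, p$inv_k0, cfg@imTol)
  sort(unique(ms2$frame[ok]))
}

#' Best-peak fragment intensity across the frames of a subcycle
#'
#' Each fragment ion is compared against all frames of the subcycle; the
#' frame holding the most intense matching peak wins and that peak's
#' intensity is taken as the fragment's intensity in the subcycle. A peak
#' matches when its annotated Q1 boundaries contain the precursor m/z, its
#' ion mobility is within `imTol` of the precursor's, and its m/z is within
#' `mzTolPpm` of the fragment m/z. Returns 0 when nothing matches; an
#' intensity tie is broken towards the lowest frame index so reprocessing is
#' deterministic.
#'
#' @param fragmentMz fragment m/z in Thomson.
#' @param precursor a one-row data.frame or list with `mz` and `inv_k0`.
#' @param frames frame-stream rows of one subcycle instance (repeat-merge
#'   them first with [mergeRepeats()] if the scheme uses frame repeats).
#' @param cfg a [MatchConfig-class].
#' @return the fragment's intensity in this subcycle.
#' @export
fragmentIntensityMultiframe <- function(fragmentMz, precursor, frames,
                                        cfg = matchConfig()) {
  p <- .asPrecursorRow(precursor)
  ms2 <- frames[frames$kind == "MS2", , drop = FALSE]
  if (!nrow(ms2)) return(0)
  ok <- .precursorCompatible(ms2, p$mz, p$inv_k0, cfg@imTol) &
    abs(ms2$mz - fragmentMz) <= fragmentMz * cfg@mzTolPpm * 1e-6
  if (!any(ok)) return(0)
  hits <- ms2[ok, , drop = FALSE]
  best <- which(hits$intensity == max(hits$intensity))
  if (length(best) > 1) best <- best[which.min(hits$frame[best])]
  hits$intensity[best]
}

#' Merge the spectra of consecutive frame repeats
#'
#' Frames acquired several times in succession are merged prior to peak
#' picking to raise signal-to-noise: peaks sharing identical Q1 boundaries
#' whose m/z agree within `mzTolPpm` and whose ion mobilities agree within
#' `imTol` are combined into one peak with summed intensity and
#' intensity-weighted mean m/z and ion mobility. Peaks finding no partner
#' pass through unchanged, so total intensity is conserved exactly. All
#' input rows must belong to repeats of one frame (same `subcycle` and
#' `frame`, consecutive `repeat_index`, identical step geometry, i.e. the
#' same set of annotated Q1 boundary pairs); anything else is a contract
#' error.
#'
#' @param frames frame-stream rows of the repeats of one frame.
#' @param cfg a [MatchConfig-class].
#' @return a single merged frame spectrum (`repeat_index` 1, earliest
#'   `rt_s`), sorted by m/z.
#' @export
mergeRepeats <- function(frames, cfg = matchConfig()) {
  if (!nrow(frames)) return(frames)
  stopIfNot(length(unique(frames$subcycle)) == 1 &&
              length(unique(frames$frame)) == 1,
            "mergeRepeats expects repeats of a single frame")
  reps <- sort(unique(frames$repeat_index))
  stopIfNot(all(diff(reps) == 1),
            "repeat indices must be consecutive")
  if (length(reps) > 1) {
    geom <- lapply(reps, function(r) {
      sub <- frames[frames$repeat_index == r, ]
      unique(sub[order(sub$q1_lo, sub$q1_hi), c("q1_lo", "q1_hi")])
    })
    for (g in geom[-1]) {
      stopIfNot(isTRUE(all.equal(geom[[1]], g, check.attributes = FALSE)),
                "repeats have mismatched step geometry (Q1 boundary sets differ)")
    }
  }
  out <- list()
  for (key in unique(paste(frames$q1_lo, frames$q1_hi))) {
    sub <- frames[paste(frames$q1_lo, frames$q1_hi) == key, , drop = FALSE]
    sub <- sub[order(sub$mz), , drop = FALSE]
    cl <- integer(nrow(sub))
    cl_mz <- numeric(0)   # running intensity-weighted mean m/z per cluster
    cl_im <- numeric(0)
    cl_w <- numeric(0)
    for (i in seq_len(nrow(sub))) {
      assigned <- FALSE
      if (length(cl_mz)) {
        j <- length(cl_mz)  # peaks are mz-sorted; only the last cluster can match
        if (abs(sub$mz[i] - cl_mz[j]) <= cl_mz[j] * cfg@mzTolPpm * 1e-6 &&
            abs(sub$inv_k0[i] - cl_im[j]) <= cfg@imTol) {
          w <- sub$intensity[i]
          cl_mz[j] <- (cl_mz[j] * cl_w[j] + sub$mz[i] * w) / (cl_w[j] + w)
          cl_im[j] <- (cl_im[j] * cl_w[j] + sub$inv_k0[i] * w) / (cl_w[j] + w)
          cl_w[j] <- cl_w[j] + w
          cl[i] <- j
          assigned <- TRUE
        }
      }
      if (!assigned) {
        cl_mz <- c(cl_mz, sub$mz[i])
        cl_im <- c(cl_im, sub$inv_k0[i])
        cl_w <- c(cl_w, sub$intensity[i])
        cl[i] <- length(cl_mz)
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      cycle = sub$cycle[1], rt_s = min(sub$rt_s),
      subcycle = sub$subcycle[1], frame = sub$frame[1],
      repeat_index = 1L, kind = sub$kind[1],
      mz = cl_mz, intensity = cl_w, inv_k0 = cl_im,
      q1_lo = sub$q1_lo[1], q1_hi = sub$q1_hi[1],
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  res <- res[order(res$mz), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Extract a per-cycle ion chromatogram for one precursor
#'
#' For every DIA cycle of the stream, repeats of each frame are merged
#' (intensities of matching peaks summed), each fragment then takes the
#' intensity of its best matching peak over the frames of each subcycle
#' ([fragmentIntensityMultiframe()] semantics), fragment intensities are
#' summed, and subcycle values are summed into one point per cycle. The
#' resulting trace is quantified as the trapezoidal area of the contiguous
#' region at or above half the apex, measured in intensity x cycle units so
#' that the quantity grows with both per-frame signal and sampling rate;
#' `pointsAtFwhm` counts the cycles in that region.
#'
#' @param precursor one-row data.frame (or list) with `mz` and `inv_k0`.
#' @param fragmentMz numeric vector of the precursor's fragment m/z values.
#' @param stream frame-stream data.frame from [simulateAcquisition()] or
#'   [readFrameStream()], sorted by time.
#' @param cfg a [MatchConfig-class].
#' @return an [XIC-class].
#' @export
extractXic <- function(precursor, fragmentMz, stream, cfg = matchConfig()) {
  p <- .asPrecursorRow(precursor)
  dt <- data.table::as.data.table(stream)
  cycles <- dt[, list(rt_s = min(rt_s)), by = cycle]
  data.table::setorder(cycles, cycle)
  ms2 <- dt[kind == "MS2" & q1_lo <= p$mz & p$mz < q1_hi &
              abs(inv_k0 - p$inv_k0) <= cfg@imTol]
  trace <- data.frame(cycle = cycles$cycle, rt_s = cycles$rt_s, intensity = 0)
  if (nrow(ms2) && length(fragmentMz)) {
    hits <- data.table::rbindlist(Filter(nrow,
      lapply(seq_along(fragmentMz), function(j) {
        fm <- fragmentMz[j]
        sub <- ms2[abs(mz - fm) <= fm * cfg@mzTolPpm * 1e-6]
        if (nrow(sub)) sub[, frag := j]
        sub
      })))
    if (nrow(hits)) {
      ## best peak within each repeat spectrum, summed over repeats
      ## (merge), best frame per subcycle, summed over fragments and
      ## subcycles
      per_rep <- hits[, list(intensity = max(intensity)),
                      by = list(cycle, subcycle, frame, repeat_index, frag)]
      per_frame <- per_rep[, list(intensity = sum(intensity)),
                           by = list(cycle, subcycle, frame, frag)]
      per_frag <- per_frame[, list(intensity = max(intensity)),
                            by = list(cycle, subcycle, frag)]
      per_cycle <- per_frag[, list(intensity = sum(intensity)),
                            by = cycle]
      m <- match(per_cycle$cycle, trace$cycle)
      trace$intensity[m[!is.na(m)]] <- per_cycle$intensity[!is.na(m)]
    }
  }
  .xicFromTrace(trace)
}

.xicFromTrace <- function(trace) {
  apex <- if (nrow(trace)) max(trace$intensity) else 0
  if (apex <= 0) {
    return(new("XIC", trace = trace, apex = 0, area = 0, pointsAtFwhm = 0,
               allZero = TRUE))
  }
  half <- apex / 2
  i_apex <- which.max(trace$intensity)
  lo <- i_apex
  while (lo > 1 && trace$intensity[lo - 1] >= half) lo <- lo - 1
  hi <- i_apex
  while (hi < nrow(trace) && trace$intensity[hi + 1] >= half) hi <- hi + 1
  region <- trace$intensity[lo:hi]
  area <- if (length(region) == 1) {
    region
  } else {
    sum((region[-1] + region[-length(region)]) / 2)
  }
  new("XIC", trace = trace, apex = apex, area = area,
      pointsAtFwhm = length(region), allZero = FALSE)
}

#' Quantify an extracted ion chromatogram
#'
#' `"halfmax_area"` (default) returns the trapezoidal area of the
#' contiguous region at or above half the apex; `"total"` the trapezoidal
#' area of the whole trace. Both are in intensity x cycle units. An
#' all-zero trace quantifies as 0 (flagged on the [XIC-class]).
#'
#' @param xic an [XIC-class].
#' @param method quantification region.
#' @return a single nonnegative number.
#' @export
quantifyXic <- function(xic, method = c("halfmax_area", "total")) {
  method <- match.arg(method)
  if (xic@allZero) return(0)
  if (method == "halfmax_area") return(xic@area)
  v <- xic@trace$intensity
  if (length(v) == 1) return(v)
  sum((v[-1] + v[-length(v)]) / 2)
}

#' Coefficients of variation across replicate quantities
#'
#' CV is the standard deviation (n - 1 denominator) of the untransformed
#' quantities divided by their mean, reported only for precursors measured
#' in at least `minN` replicates (default 3); entries failing that policy,
#' or with zero mean, are flagged as suppressed with `cv = NA`.
#'
#' @param quantities data.frame with columns `precursor_id`, `run`,
#'   `quantity` (one row per precursor per replicate run).
#' @param minN minimum replicate count for a CV to be reported.
#' @return data.frame with columns `precursor_id`, `n`, `mean`, `sd`, `cv`,
#'   `suppressed`.
#' @export
cvSummary <- function(quantities, minN = 3) {
  stopIfNot(all(c("precursor_id", "run", "quantity") %in% names(quantities)),
            "quantities must have columns precursor_id, run, quantity")
  ids <- unique(quantities$precursor_id)
  out <- lapply(ids, function(id) {
    v <- quantities$quantity[quantities$precursor_id == id]
    n <- length(v)
    m <- mean(v)
    s <- if (n >= 2) sd(v) else NA_real_
    suppressed <- n < minN || !is.finite(m) || m == 0
    data.frame(precursor_id = id, n = n, mean = m, sd = s,
               cv = if (suppressed) NA_real_ else s / m,
               suppressed = suppressed, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
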