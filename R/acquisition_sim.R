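## In-silico acquisition: cloud + scheme + gradient window -> time-ordered
## stream of frame spectra whose peaks carry Q1 isolation-boundary
## annotations.

#' Create a simulator configuration
#'
#' Defaults add mild measurement noise: 5 ppm m/z jitter, 0.005 1/K0
#' jitter, a 10% run-to-run intensity coefficient of variation, and 20
#' spurious background peaks per MS2 frame. `intensityCv` is modelled as a
#' single log-normal factor (mean 1) drawn once per precursor per simulated
#' run and applied to all of that precursor's peaks -- run-to-run variation
#' in recovered abundance rather than per-spectrum shot noise -- so the CV
#' measured on replicate quantities recovers the injected value. The
#' optional quadrupole-switch loss model removes `switchLossFraction` of the
#' signal from the first `switchLossSpan` of every slice-step that follows a
#' discontinuous Q1 jump (windows that merely shift while overlapping, as in
#' quasi-continuous slicing, are unaffected).
#'
#' @param mzJitterPpm,imJitterSd,intensityCv,noisePeaksPerFrame,seed see
#'   [SimConfig-class].
#' @param switchLossFraction,switchLossSpan switch-loss model; fraction 0
#'   (default) disables it, and the magnitude of the real effect is not
#'   quantified, so any nonzero setting is a what-if.
#' @return a validated [SimConfig-class].
#' @export
simConfig <- function(mzJitterPpm = 5, imJitterSd = 0.005, intensityCv = 0.1,
                      noisePeaksPerFrame = 20, switchLossFraction = 0,
                      switchLossSpan = 0.1, seed = 42) {
  new("SimConfig", mzJitterPpm = mzJitterPpm, imJitterSd = imJitterSd,
      intensityCv = intensityCv, noisePeaksPerFrame = noisePeaksPerFrame,
      switchLossFraction = switchLossFraction, switchLossSpan = switchLossSpan,
      seed = seed)
}

.noiselessSimConfig <- function(seed = 42) {
  simConfig(mzJitterPpm = 0, imJitterSd = 0, intensityCv = 0,
            noisePeaksPerFrame = 0, seed = seed)
}

## Expanded frame schedule of one cycle: one row per physical frame
## occurrence (repeats unrolled), with its time offset from cycle start.
.frameSchedule <- function(scheme) {
  fr <- scheme@frames
  occ <- fr[rep(seq_len(nrow(fr)), fr$repeats), , drop = FALSE]
  occ$repeat_index <- unlist(lapply(fr$repeats, seq_len))
  occ$offset_ms <- cumsum(c(0, occ$fill_time_ms[-nrow(occ)]))
  rownames(occ) <- NULL
  occ
}

## Which step of an MS2 frame isolates each precursor; NA when none.
## Steps are IM-disjoint, so at most one step matches.
.stepAssignment <- function(scheme, subcycle, frame, io) {
  st <- scheme@steps
  st <- st[st$subcycle == subcycle & st$frame == frame, , drop = FALSE]
  st <- st[order(st$step), , drop = FALSE]
  idx <- rep(NA_integer_, nrow(io))
  for (i in seq_len(nrow(st))) {
    hit <- io$inv_k0 >= st$im_lo[i] & io$inv_k0 < st$im_hi[i] &
      io$mz >= st$mz_lo[i] & io$mz < st$mz_hi[i]
    idx[hit & is.na(idx)] <- i
  }
  list(steps = st, idx = idx)
}

## Per-step attenuation factor under the switch-loss model: a step whose Q1
## window does not overlap the previous step's window follows a
## discontinuous quadrupole jump and loses `fraction` of the signal in its
## first `span`.
.switchAttenuation <- function(st, fraction, span) {
  n <- nrow(st)
  att <- rep(1, n)
  if (fraction <= 0 || n < 2) return(att)
  for (i in 2:n) {
    disjoint <- st$mz_lo[i] >= st$mz_hi[i - 1] || st$mz_hi[i] <= st$mz_lo[i - 1]
    if (disjoint) att[i] <- 1 - fraction * span
  }
  att
}

#' Simulate acquisition of a cloud under a scheme
#'
#' Tiles the retention-time window with full DIA cycles and emits one
#' spectrum per physical frame occurrence (repeats unrolled). In an MS2
#' frame, every precursor whose expected `(mz, 1/K0)` is isolated by one of
#' the frame's slice-steps contributes one annotated peak per fragment with
#' intensity
#' `precursor intensity x Gaussian elution factor at the frame time x
#'  fragment relative intensity x (fill time / 100 ms) x noise factors`,
#' annotated with the isolating step's Q1 boundaries and the precursor's
#' (jittered) ion mobility. MS1 frames carry precursor peaks annotated with
#' the scheme's full m/z range. Intensities scale linearly with fill time
#' referenced to 100 ms, the accumulation-time proportionality that
#' underlies duty-cycle arithmetic. A fixed seed gives an identical stream.
#'
#' @param cloud an [IonCloud-class] with fragments.
#' @param scheme a valid [AcquisitionScheme-class].
#' @param sim a [SimConfig-class].
#' @param rtWindow numeric(2) `(start, end)` in seconds, or a single number
#'   meaning `(0, rtWindow)`. Must fit at least one full cycle.
#' @return a data.frame frame stream with columns `cycle`, `rt_s`,
#'   `subcycle`, `frame`, `repeat_index`, `kind`, `mz`, `intensity`,
#'   `inv_k0`, `q1_lo`, `q1_hi`, ordered by time then m/z within each frame.
#' @seealso [writeFrameStream()], [extractXic()]
#' @export
simulateAcquisition <- function(cloud, scheme, sim = simConfig(),
                                rtWindow = c(0, 60)) {
  validObject(scheme)
  if (length(rtWindow) == 1) rtWindow <- c(0, rtWindow)
  cycle_s <- sum(scheme@frames$fill_time_ms * scheme@frames$repeats) / 1000
  n_cycles <- floor((rtWindow[2] - rtWindow[1]) / cycle_s + 1e-9)
  if (n_cycles < 1) {
    stop(sprintf("rtWindow (%.3f s) is shorter than one cycle (%.3f s)",
                 rtWindow[2] - rtWindow[1], cycle_s), call. = FALSE)
  }
  io <- ions(cloud)
  frags <- fragments(cloud)
  sched <- .frameSchedule(scheme)

  withSeed(sim@seed, {
    ## one run-level multiplicative factor per precursor (mean 1, CV = cv)
    if (sim@intensityCv > 0 && nrow(io)) {
      s <- sqrt(log(1 + sim@intensityCv^2))
      run_factor <- rlnorm(nrow(io), meanlog = -s^2 / 2, sdlog = s)
    } else {
      run_factor <- rep(1, max(nrow(io), 1L))
    }

    ## per-frame-occurrence template of emitted peaks (cycle-independent part)
    templates <- vector("list", nrow(sched))
    frag_parent_idx <- match(frags$parent_id, io$id)
    for (k in seq_len(nrow(sched))) {
      occ <- sched[k, ]
      if (occ$kind == "MS1") {
        if (!nrow(io)) next
        templates[[k]] <- data.table::data.table(
          occ_row = k, prec = seq_len(nrow(io)), mz0 = io$mz,
          base = io$intensity * run_factor * occ$fill_time_ms / 100,
          q1_lo = scheme@mzRange[1], q1_hi = scheme@mzRange[2]
        )
      } else {
        asg <- .stepAssignment(scheme, occ$subcycle, occ$frame, io)
        att <- .switchAttenuation(asg$steps, sim@switchLossFraction,
                                  sim@switchLossSpan)
        prec_in <- which(!is.na(asg$idx))
        if (!length(prec_in)) next
        fsel <- which(frag_parent_idx %in% prec_in)
        if (!length(fsel)) next
        p <- frag_parent_idx[fsel]
        stp <- asg$idx[p]
        templates[[k]] <- data.table::data.table(
          occ_row = k, prec = p, mz0 = frags$mz[fsel],
          base = io$intensity[p] * run_factor[p] * frags$rel_intensity[fsel] *
            att[stp] * occ$fill_time_ms / 100,
          q1_lo = asg$steps$mz_lo[stp], q1_hi = asg$steps$mz_hi[stp]
        )
      }
    }
    template <- data.table::rbindlist(templates)

    parts <- vector("list", n_cycles)
    for (cc in seq_len(n_cycles)) {
      t0 <- rtWindow[1] + (cc - 1) * cycle_s
      if (nrow(template)) {
        rt <- t0 + sched$offset_ms[template$occ_row] / 1000
        elu <- elutionFactor(rt, io$rt_apex_s[template$prec],
                             io$rt_fwhm_s[template$prec])
        keep <- which(elu > 1e-12 & template$base > 0)
        dt <- template[keep]
        dt[, `:=`(cycle = cc, rt_s = rt[keep], intensity = base * elu[keep],
                  inv_k0 = io$inv_k0[prec])]
      } else {
        dt <- data.table::data.table()
      }
      ## spurious background peaks, uniform over each MS2 frame's steps
      if (sim@noisePeaksPerFrame > 0) {
        nparts <- list()
        for (k in which(sched$kind == "MS2")) {
          st <- scheme@steps
          st <- st[st$subcycle == sched$subcycle[k] & st$frame == sched$frame[k],
                   , drop = FALSE]
          if (!nrow(st)) next
          m <- as.integer(sim@noisePeaksPerFrame)
          pick <- sample.int(nrow(st), m, replace = TRUE)
          nparts[[length(nparts) + 1L]] <- data.table::data.table(
            occ_row = k, prec = NA_integer_,
            mz0 = runif(m, 100, max(scheme@mzRange[2], 1000)),
            base = 0, cycle = cc,
            rt_s = t0 + sched$offset_ms[k] / 1000,
            intensity = rlnorm(m, log(50), 1),
            inv_k0 = st$im_lo[pick] + runif(m) * (st$im_hi[pick] - st$im_lo[pick]),
            q1_lo = st$mz_lo[pick], q1_hi = st$mz_hi[pick]
          )
        }
        if (length(nparts)) {
          dt <- data.table::rbindlist(c(list(dt), nparts), use.names = TRUE,
                                      fill = TRUE)
        }
      }
      parts[[cc]] <- dt
    }
    out <- data.table::rbindlist(parts, use.names = TRUE, fill = TRUE)
    if (!nrow(out)) {
      return(.emptyFrameStream())
    }
    ## measurement jitter
    out[, mz := mz0 * (1 + if (sim@mzJitterPpm > 0)
      rnorm(.N, 0, sim@mzJitterPpm * 1e-6) else 0)]
    if (sim@imJitterSd > 0) out[, inv_k0 := inv_k0 + rnorm(.N, 0, sim@imJitterSd)]
    out[, `:=`(subcycle = sched$subcycle[occ_row],
               frame = sched$frame[occ_row],
               repeat_index = sched$repeat_index[occ_row],
               kind = sched$kind[occ_row])]
    data.table::setorder(out, rt_s, mz)
    res <- as.data.frame(out[, list(cycle, rt_s, subcycle, frame, repeat_index,
                                    kind, mz, intensity, inv_k0, q1_lo, q1_hi)])
    res
  })
}

.STREAM_COLS <- c("cycle", "rt_s", "subcycle", "frame", "repeat_index",
                  "kind", "mz", "intensity", "inv_k0", "q1_lo", "q1_hi")

.emptyFrameStream <- function() {
  out <- data.frame(cycle = integer(), rt_s = numeric(), subcycle = integer(),
                    frame = integer(), repeat_index = integer(),
                    kind = character(), mz = numeric(), intensity = numeric(),
                    inv_k0 = numeric(), q1_lo = numeric(), q1_hi = numeric(),
                    stringsAsFactors = FALSE)
  out
}

#' Count Q1 transitions within one MS2 frame
#'
#' A TIMS ramp traverses a frame's slice-steps in order; every step-to-step
#' transition where the Q1 window changes is a quadrupole move. Transitions
#' are classified as overlapping shifts (the new window overlaps the
#' previous one, as in quasi-continuous slicing) or discontinuous switches
#' (disjoint windows, as between the stacked windows of classical
#' dia-PASEF); only the latter trigger the optional switch-loss model of
#' [simConfig()].
#'
#' @param scheme an [AcquisitionScheme-class].
#' @param subcycle,frame identify the MS2 frame.
#' @return list with `transitions` (count of Q1 changes), `discontinuous`
#'   (count of disjoint jumps) and `shifts` (overlapping moves).
#' @export
q1SwitchCount <- function(scheme, subcycle, frame) {
  fr <- scheme@frames
  row <- fr$subcycle == subcycle & fr$frame == frame
  stopIfNot(any(row) && all(fr$kind[row] == "MS2"),
            "q1SwitchCount is defined for MS2 frames only")
  st <- scheme@steps
  st <- st[st$subcycle == subcycle & st$frame == frame, , drop = FALSE]
  st <- st[order(st$step), , drop = FALSE]
  trans <- 0L
  disc <- 0L
  if (nrow(st) >= 2) {
    for (i in 2:nrow(st)) {
      changed <- st$mz_lo[i] != st$mz_lo[i - 1] || st$mz_hi[i] != st$mz_hi[i - 1]
      if (changed) {
        trans <- trans + 1L
        disjoint <- st$mz_lo[i] >= st$mz_hi[i - 1] || st$mz_hi[i] <= st$mz_lo[i - 1]
        if (disjoint) disc <- disc + 1L
      }
    }
  }
  list(transitions = trans, discontinuous = disc, shifts = trans - disc)
}

#' Read and write simulated frame streams
#'
#' Tab-separated with header
#' `cycle rt_s subcycle frame repeat_index kind mz intensity inv_k0 q1_lo q1_hi`.
#'
#' @param stream a frame-stream data.frame from [simulateAcquisition()].
#' @param path file path.
#' @return `writeFrameStream` returns `path` invisibly; `readFrameStream`
#'   returns the stream data.frame.
#' @export
writeFrameStream <- function(stream, path) {
  write.table(stream[, .STREAM_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeFrameStream
#' @export
readFrameStream <- function(path) {
  tab <- read.delim(path, sep = "\t", header = TRUE)
  missing_cols <- setdiff(.STREAM_COLS, names(tab))
  if (length(missing_cols)) {
    stop(sprintf("frame stream '%s' is missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  tab[, .STREAM_COLS]
}
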