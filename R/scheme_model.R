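## Acquisition-scheme construction, validation, point isolation, and the
## plain-text method-table dialect.

#' Construct an acquisition scheme from frame and step tables
#'
#' Low-level constructor; the designer functions ([design1F()],
#' [designMultiframe()], [designDiapasefReference()]) are the usual way to
#' obtain schemes.
#'
#' @param frames data.frame with columns `subcycle`, `frame`, `kind`
#'   ("MS1"/"MS2"), `fill_time_ms`, `repeats`.
#' @param steps data.frame with columns `subcycle`, `frame`, `step`,
#'   `im_lo`, `im_hi`, `mz_lo`, `mz_hi`, `ce_ev`.
#' @param mzRange,imRange numeric(2) overall bounds.
#' @param label free-text scheme label.
#' @return an [AcquisitionScheme-class].
#' @export
acquisitionScheme <- function(frames, steps, mzRange, imRange, label = "") {
  frames <- as.data.frame(frames)[, .FRAME_COLS]
  if (!"ce_ev" %in% names(steps)) steps$ce_ev <- NA_real_
  steps <- as.data.frame(steps)[, .STEP_COLS]
  o <- order(frames$subcycle, frames$frame)
  frames <- frames[o, , drop = FALSE]
  rownames(frames) <- NULL
  o <- order(steps$subcycle, steps$frame, steps$step)
  steps <- steps[o, , drop = FALSE]
  rownames(steps) <- NULL
  new("AcquisitionScheme", frames = frames, steps = steps,
      mzRange = as.numeric(mzRange), imRange = as.numeric(imRange),
      label = label)
}

#' Validate an acquisition scheme and report violations
#'
#' Unlike the constructor's validity method (which only enforces structural
#' sanity), this returns a diagnostic report listing every violation:
#' steps outside the scheme bounds, overlapping ion-mobility intervals
#' within one frame, Q1 windows narrower than the instrument minimum, and
#' subcycles without MS2 frames. Parsing and validation are deliberately
#' separate: [readMethodTable()] accepts geometrically nonsensical files so
#' that this function can diagnose them.
#'
#' @param scheme an [AcquisitionScheme-class].
#' @param minWidthMz instrument minimum Q1 width in Thomson (default 2).
#' @return data.frame with columns `severity` ("error"/"warning"),
#'   `subcycle`, `frame`, `step`, `message`; zero rows when clean.
#' @export
validateScheme <- function(scheme, minWidthMz = 2) {
  st <- scheme@steps
  fr <- scheme@frames
  rep_row <- function(severity, subcycle, frame, step, message) {
    data.frame(severity = severity, subcycle = subcycle, frame = frame,
               step = step, message = message, stringsAsFactors = FALSE)
  }
  out <- list()
  for (i in seq_len(nrow(st))) {
    s <- st[i, ]
    if (s$im_lo >= s$im_hi) {
      out[[length(out) + 1L]] <- rep_row("error", s$subcycle, s$frame, s$step,
        sprintf("inverted IM interval [%.4f, %.4f]", s$im_lo, s$im_hi))
    }
    if (s$mz_lo >= s$mz_hi) {
      out[[length(out) + 1L]] <- rep_row("error", s$subcycle, s$frame, s$step,
        sprintf("inverted m/z window [%.4f, %.4f]", s$mz_lo, s$mz_hi))
    } else if (s$mz_hi - s$mz_lo < minWidthMz) {
      out[[length(out) + 1L]] <- rep_row("error", s$subcycle, s$frame, s$step,
        sprintf("Q1 width %.4f Th below instrument minimum %.4f Th",
                s$mz_hi - s$mz_lo, minWidthMz))
    }
    if (s$mz_lo < scheme@mzRange[1] - 1e-9 || s$mz_hi > scheme@mzRange[2] + 1e-9) {
      out[[length(out) + 1L]] <- rep_row("warning", s$subcycle, s$frame, s$step,
        "Q1 window extends outside the scheme m/z range")
    }
    if (s$im_lo < scheme@imRange[1] - 1e-9 || s$im_hi > scheme@imRange[2] + 1e-9) {
      out[[length(out) + 1L]] <- rep_row("warning", s$subcycle, s$frame, s$step,
        "IM interval extends outside the scheme 1/K0 range")
    }
  }
  ## pairwise-disjoint IM intervals within each MS2 frame
  key <- interaction(st$subcycle, st$frame, drop = TRUE)
  for (k in levels(key)) {
    sub <- st[key == k, , drop = FALSE]
    if (nrow(sub) < 2) next
    sub <- sub[order(sub$im_lo), , drop = FALSE]
    ov <- which(sub$im_hi[-nrow(sub)] > sub$im_lo[-1] + 1e-12)
    for (i in ov) {
      out[[length(out) + 1L]] <- rep_row("error", sub$subcycle[1], sub$frame[1],
        sub$step[i + 1],
        sprintf("IM interval overlaps previous step ([%.4f, %.4f] vs [%.4f, %.4f])",
                sub$im_lo[i + 1], sub$im_hi[i + 1], sub$im_lo[i], sub$im_hi[i]))
    }
  }
  for (sc in unique(fr$subcycle)) {
    sub <- fr[fr$subcycle == sc, , drop = FALSE]
    if (!any(sub$kind == "MS2")) {
      out[[length(out) + 1L]] <- rep_row("error", sc, NA, NA,
                                         "subcycle has no MS2 frame")
    }
    for (f in sub$frame[sub$kind == "MS2"]) {
      if (!any(st$subcycle == sc & st$frame == f)) {
        out[[length(out) + 1L]] <- rep_row("error", sc, f, NA,
                                           "MS2 frame has no slice-steps")
      }
    }
  }
  if (!length(out)) {
    return(data.frame(severity = character(), subcycle = numeric(),
                      frame = numeric(), step = numeric(),
                      message = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Does an MS2 frame isolate a point of the precursor space?
#'
#' A frame isolates `(mz, invK0)` iff one of its slice-steps satisfies
#' `im_lo <= invK0 < im_hi` and `mz_lo <= mz < mz_hi` (half-open on the
#' upper bounds, so abutting steps assign every point to exactly one step).
#'
#' @param scheme an [AcquisitionScheme-class].
#' @param subcycle,frame identify the frame (as in `schemeFrames(scheme)`).
#' @param mz,invK0 query coordinates; vectors of equal length are recycled
#'   against each other.
#' @return logical vector, one element per query point.
#' @export
frameIsolates <- function(scheme, subcycle, frame, mz, invK0) {
  fr <- scheme@frames
  row <- fr$subcycle == subcycle & fr$frame == frame
  stopIfNot(any(row), "no such frame in scheme")
  stopIfNot(all(fr$kind[row] == "MS2"), "frameIsolates is defined for MS2 frames only")
  st <- scheme@steps
  st <- st[st$subcycle == subcycle & st$frame == frame, , drop = FALSE]
  k <- max(length(mz), length(invK0))
  mz <- rep_len(mz, k)
  invK0 <- rep_len(invK0, k)
  res <- logical(k)
  for (i in seq_len(nrow(st))) {
    res <- res | (invK0 >= st$im_lo[i] & invK0 < st$im_hi[i] &
                    mz >= st$mz_lo[i] & mz < st$mz_hi[i])
  }
  res
}

## ---------------------------------------------------------------------------
## Method-table dialect
## ---------------------------------------------------------------------------
##
## Plain-text, comma-separated, one row per slice-step:
##   #MS Type,Cycle Id,Start IM,End IM,Start Mass,End Mass,CE
## `MS Type` is MS1 or PASEF; `Cycle Id` is the frame index within the full
## DIA cycle; floats are printed at 4 decimals; CE is blank when unset.
## Lines starting `##` carry metadata the row schema cannot express
## (scheme label/bounds and per-frame subcycle, fill time and repeat
## counts); files without them are read with defaults (one subcycle per
## MS1-delimited group, 100 ms fill, 1 repeat).

.fmt4 <- function(x) {
  ifelse(is.na(x), "", formatC(x, format = "f", digits = 4))
}

#' Write and read plain-text method-definition tables
#'
#' The on-disk dialect is a comma-separated table with header
#' `#MS Type,Cycle Id,Start IM,End IM,Start Mass,End Mass,CE`, one row per
#' slice-step (`MS Type` = PASEF) or MS1 frame, floats at 4 decimal places,
#' CE blank when unset -- the shape of text-table method files that
#' instrument control software imports. Additional `##`-prefixed metadata
#' lines record the scheme label, bounds, and per-frame subcycle membership,
#' fill time and repeat count, so that `readMethodTable(writeMethodTable(x))`
#' reproduces `x` field-wise at 4-decimal precision. Files lacking metadata
#' lines are still readable: subcycles are inferred from MS1 rows (or a
#' single subcycle assumed), with 100 ms fill and 1 repeat.
#'
#' Reading performs no geometric validation beyond row syntax; run
#' [validateScheme()] on the result.
#'
#' @param scheme an [AcquisitionScheme-class].
#' @param path file path.
#' @return `writeMethodTable` returns `path` invisibly; `readMethodTable`
#'   returns an [AcquisitionScheme-class].
#' @export
writeMethodTable <- function(scheme, path) {
  fr <- scheme@frames
  st <- scheme@steps
  lines <- c(
    sprintf("## slicepasef method table"),
    sprintf("## label=%s", scheme@label),
    sprintf("## mz_range=%s,%s", .fmt4(scheme@mzRange[1]), .fmt4(scheme@mzRange[2])),
    sprintf("## im_range=%s,%s", .fmt4(scheme@imRange[1]), .fmt4(scheme@imRange[2])),
    sprintf("## frame subcycle=%d frame=%d kind=%s fill_time_ms=%s repeats=%d",
            fr$subcycle, fr$frame, fr$kind, .fmt4(fr$fill_time_ms), fr$repeats),
    "#MS Type,Cycle Id,Start IM,End IM,Start Mass,End Mass,CE"
  )
  rows <- character()
  for (i in seq_len(nrow(fr))) {
    sc <- fr$subcycle[i]; f <- fr$frame[i]
    if (fr$kind[i] == "MS1") {
      rows <- c(rows, paste("MS1", f,
                            .fmt4(scheme@imRange[1]), .fmt4(scheme@imRange[2]),
                            .fmt4(scheme@mzRange[1]), .fmt4(scheme@mzRange[2]),
                            "", sep = ","))
    } else {
      sub <- st[st$subcycle == sc & st$frame == f, , drop = FALSE]
      rows <- c(rows, paste("PASEF", f,
                            .fmt4(sub$im_lo), .fmt4(sub$im_hi),
                            .fmt4(sub$mz_lo), .fmt4(sub$mz_hi),
                            .fmt4(sub$ce_ev), sep = ","))
    }
  }
  writeLines(c(lines, rows), path)
  invisible(path)
}

#' @rdname writeMethodTable
#' @export
readMethodTable <- function(path) {
  raw <- readLines(path)
  meta <- raw[startsWith(raw, "##")]
  body <- raw[!startsWith(raw, "##")]
  body <- body[nzchar(trimws(body))]
  header <- "#MS Type,Cycle Id,Start IM,End IM,Start Mass,End Mass,CE"
  if (!length(body) || trimws(body[1]) != header) {
    stop(sprintf("method table '%s': missing or unrecognized header line", path),
         call. = FALSE)
  }
  label <- ""
  mz_range <- NULL
  im_range <- NULL
  frame_meta <- list()
  for (m in meta) {
    m <- trimws(sub("^##", "", m))
    if (startsWith(m, "label=")) label <- sub("^label=", "", m)
    if (startsWith(m, "mz_range=")) {
      mz_range <- as.numeric(strsplit(sub("^mz_range=", "", m), ",")[[1]])
    }
    if (startsWith(m, "im_range=")) {
      im_range <- as.numeric(strsplit(sub("^im_range=", "", m), ",")[[1]])
    }
    if (startsWith(m, "frame ")) {
      kv <- strsplit(strsplit(sub("^frame ", "", m), " +")[[1]], "=")
      vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
      frame_meta[[vals[["frame"]]]] <- vals
    }
  }
  rows <- lapply(seq_along(body)[-1], function(i) {
    line <- body[i]
    fields <- strsplit(line, ",", fixed = TRUE)[[1]]
    fields <- c(fields, rep("", max(0, 7 - length(fields))))
    type <- trimws(fields[1])
    if (!type %in% c("MS1", "PASEF")) {
      stop(sprintf("method table '%s' line %d: unknown row type '%s'",
                   path, which(raw == line)[1], type), call. = FALSE)
    }
    num <- suppressWarnings(as.numeric(fields[2:6]))
    if (any(is.na(num))) {
      stop(sprintf("method table '%s' line %d: non-numeric field",
                   path, which(raw == line)[1]), call. = FALSE)
    }
    ce <- suppressWarnings(as.numeric(fields[7]))
    list(type = type, frame = as.integer(num[1]), im_lo = num[2], im_hi = num[3],
         mz_lo = num[4], mz_hi = num[5], ce = ce)
  })
  if (!length(rows)) stop(sprintf("method table '%s' has no data rows", path),
                          call. = FALSE)
  frame_ids <- unique(vapply(rows, function(r) r$frame, integer(1)))
  types <- vapply(frame_ids, function(f) {
    rows[[which(vapply(rows, function(r) r$frame, integer(1)) == f)[1]]]$type
  }, character(1))
  ## subcycle assignment: from metadata if present, else MS1 rows delimit
  ## subcycles, else everything is one subcycle
  subcycle_of <- function(f, kind_f) {
    key <- as.character(f)
    if (!is.null(frame_meta[[key]])) return(as.integer(frame_meta[[key]][["subcycle"]]))
    ms1_ids <- frame_ids[types == "MS1"]
    if (length(ms1_ids)) return(sum(ms1_ids <= f))
    1L
  }
  frames <- data.frame(
    subcycle = vapply(seq_along(frame_ids), function(i)
      subcycle_of(frame_ids[i], types[i]), integer(1)),
    frame = frame_ids,
    kind = ifelse(types == "MS1", "MS1", "MS2"),
    fill_time_ms = vapply(frame_ids, function(f) {
      key <- as.character(f)
      if (!is.null(frame_meta[[key]]))
        as.numeric(frame_meta[[key]][["fill_time_ms"]]) else 100
    }, numeric(1)),
    repeats = vapply(frame_ids, function(f) {
      key <- as.character(f)
      if (!is.null(frame_meta[[key]]))
        as.integer(frame_meta[[key]][["repeats"]]) else 1L
    }, integer(1)),
    stringsAsFactors = FALSE
  )
  step_rows <- Filter(function(r) r$type == "PASEF", rows)
  steps <- if (length(step_rows)) {
    df <- do.call(rbind, lapply(step_rows, function(r) {
      data.frame(frame = r$frame, im_lo = r$im_lo, im_hi = r$im_hi,
                 mz_lo = r$mz_lo, mz_hi = r$mz_hi, ce_ev = r$ce)
    }))
    df$subcycle <- frames$subcycle[match(df$frame, frames$frame)]
    df$step <- stats::ave(df$frame, df$frame, FUN = seq_along)
    df[, .STEP_COLS]
  } else {
    data.frame(subcycle = integer(), frame = integer(), step = integer(),
               im_lo = numeric(), im_hi = numeric(), mz_lo = numeric(),
               mz_hi = numeric(), ce_ev = numeric())
  }
  if (is.null(mz_range)) {
    mz_range <- if (nrow(steps)) c(min(steps$mz_lo), max(steps$mz_hi)) else c(100, 1700)
  }
  if (is.null(im_range)) {
    im_range <- if (nrow(steps)) c(min(steps$im_lo), max(steps$im_hi)) else c(0.6, 1.6)
  }
  acquisitionScheme(frames, steps, mz_range, im_range, label)
}
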