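## Synthesis, IO and descriptive geometry of precursor ion clouds.

#' Create a cloud-generator configuration
#'
#' Returns a [CloudGenConfig-class] with defaults that emulate a tryptic
#' whole-proteome digest on a timsTOF: three charge states whose 1/K0 rises
#' linearly with m/z (the singly-charged trend lying above the
#' multiply-charged ones), Gaussian mobility scatter around each trend, and
#' per-charge log-normal peptide masses. The default scatter and trend
#' geometry are calibrated so that charge 2-3 ions inside a narrow mobility
#' bin spread over an interquartile range of about 70 m/z.
#'
#' @param nIons number of precursors (default 50000).
#' @param chargeProbs named probabilities per charge state.
#' @param trendSlope,trendIntercept named per-charge linear coefficients of
#'   1/K0 against m/z.
#' @param imScatterSd Gaussian 1/K0 scatter around the trend.
#' @param massMeanlog,massSdlog named per-charge log-normal neutral-mass
#'   parameters (Da).
#' @param intensityLognorm numeric(2) (meanlog, sdlog) of intensities.
#' @param rtFwhmS LC peak FWHM in seconds.
#' @param gradientLengthS gradient length in seconds.
#' @param mzRange,imRange bounds of the generated precursor space.
#' @param ms2Range MS2 scan range for fragment m/z.
#' @param nFragRange integer(2) fragments per precursor (inclusive).
#' @param seed RNG seed.
#' @return a validated [CloudGenConfig-class].
#' @examples
#' cfg <- cloudGenConfig(nIons = 100, seed = 1)
#' cloud <- generateSyntheticCloud(cfg)
#' nIons(cloud)
#' @export
cloudGenConfig <- function(nIons = 50000,
                           chargeProbs = c("1" = 0.15, "2" = 0.55, "3" = 0.30),
                           trendSlope = c("1" = 8.0e-4, "2" = 6.2e-4, "3" = 5.6e-4),
                           trendIntercept = c("1" = 0.55, "2" = 0.40, "3" = 0.42),
                           imScatterSd = 0.025,
                           massMeanlog = c("1" = log(720), "2" = log(1500),
                                           "3" = log(2700)),
                           massSdlog = c("1" = 0.25, "2" = 0.25, "3" = 0.22),
                           intensityLognorm = c(9.2, 1.1),
                           rtFwhmS = 3,
                           gradientLengthS = 300,
                           mzRange = c(400, 1200),
                           imRange = c(0.6, 1.3),
                           ms2Range = c(300, 1000),
                           nFragRange = c(3, 10),
                           seed = 42) {
  new("CloudGenConfig",
      nIons = nIons, chargeProbs = chargeProbs,
      trendSlope = trendSlope, trendIntercept = trendIntercept,
      imScatterSd = imScatterSd,
      massMeanlog = massMeanlog, massSdlog = massSdlog,
      intensityLognorm = intensityLognorm,
      rtFwhmS = rtFwhmS, gradientLengthS = gradientLengthS,
      mzRange = mzRange, imRange = imRange, ms2Range = ms2Range,
      nFragRange = nFragRange, seed = seed)
}

.PROTON_MASS <- 1.00728

#' Construct an ion cloud from tables
#'
#' @param ions data.frame with columns `id`, `mz`, `charge`, `inv_k0`,
#'   `intensity`, `rt_apex_s`, `rt_fwhm_s`.
#' @param fragments data.frame with columns `parent_id`, `mz`,
#'   `rel_intensity` (default: none).
#' @param mzRange,imRange bounds; default inferred from the ions with a
#'   small margin.
#' @param gradientLengthS gradient length in seconds (default: covers the
#'   latest apex).
#' @return a validated [IonCloud-class].
#' @export
ionCloud <- function(ions,
                     fragments = data.frame(parent_id = character(),
                                            mz = numeric(),
                                            rel_intensity = numeric()),
                     mzRange = NULL, imRange = NULL, gradientLengthS = NULL) {
  ions <- as.data.frame(ions)
  fragments <- as.data.frame(fragments)
  if (is.null(mzRange)) {
    mzRange <- if (nrow(ions)) range(ions$mz) + c(-1, 1) else c(100, 2000)
  }
  if (is.null(imRange)) {
    imRange <- if (nrow(ions)) {
      pmin(pmax(range(ions$inv_k0) + c(-0.01, 0.01), 0.4001), 1.9999)
    } else c(0.5, 1.6)
  }
  if (is.null(gradientLengthS)) {
    gradientLengthS <- if (nrow(ions)) max(ions$rt_apex_s, 1) else 1
  }
  new("IonCloud", ions = ions[, .ION_COLS], fragments = fragments[, .FRAG_COLS],
      mzRange = as.numeric(mzRange), imRange = as.numeric(imRange),
      gradientLengthS = gradientLengthS)
}

#' Generate a synthetic precursor ion cloud
#'
#' Samples `nIons` precursors: a charge state from `chargeProbs`, a neutral
#' peptide mass from the per-charge log-normal (converted to m/z with the
#' proton mass), and a reduced ion mobility from the charge's linear trend
#' plus Gaussian scatter. Ions falling outside `mzRange` x `imRange` are
#' rejection-resampled so the final cloud lies fully inside its bounds.
#' Elution apexes are uniform over the gradient; each precursor receives
#' 3-10 fragment ions with m/z uniform in the MS2 scan range and
#' Dirichlet-distributed relative intensities. A fixed seed gives a
#' byte-identical cloud.
#'
#' @param config a [CloudGenConfig-class].
#' @return an [IonCloud-class]. `nIons <= 0` yields an empty cloud.
#' @seealso [cloudGenConfig()], [fitImTrendlines()], [mzQuantileEnvelope()]
#' @export
generateSyntheticCloud <- function(config) {
  validObject(config)
  n <- floor(config@nIons)
  if (n <= 0) {
    return(.emptyCloud(config@mzRange, config@imRange, config@gradientLengthS))
  }
  withSeed(config@seed, {
    charges_avail <- as.integer(names(config@chargeProbs))
    charge <- charges_avail[sample.int(length(charges_avail), n, replace = TRUE,
                                       prob = config@chargeProbs)]
    key <- as.character(charge)
    mz <- numeric(n)
    inv_k0 <- numeric(n)
    todo <- rep(TRUE, n)
    ## rejection-sample until every ion is inside the configured box
    for (iter in 1:200) {
      idx <- which(todo)
      if (!length(idx)) break
      m <- length(idx)
      mass <- rlnorm(m, config@massMeanlog[key[idx]], config@massSdlog[key[idx]])
      mz_i <- mass / charge[idx] + .PROTON_MASS
      im_i <- config@trendIntercept[key[idx]] +
        config@trendSlope[key[idx]] * mz_i + rnorm(m, 0, config@imScatterSd)
      mz[idx] <- mz_i
      inv_k0[idx] <- im_i
      todo[idx] <- mz_i < config@mzRange[1] | mz_i >= config@mzRange[2] |
        im_i < config@imRange[1] | im_i >= config@imRange[2]
    }
    if (any(todo)) {
      stop("rejection sampling failed to place all ions inside mzRange x imRange; ",
           "the configured trends are incompatible with the bounds", call. = FALSE)
    }
    ions <- data.frame(
      id = sprintf("ion%06d", seq_len(n)),
      mz = mz,
      charge = charge,
      inv_k0 = inv_k0,
      intensity = rlnorm(n, config@intensityLognorm[1], config@intensityLognorm[2]),
      rt_apex_s = runif(n, 0, config@gradientLengthS),
      rt_fwhm_s = rep(config@rtFwhmS, n),
      stringsAsFactors = FALSE
    )
    nf <- sample(seq(config@nFragRange[1], config@nFragRange[2]), n, replace = TRUE)
    parent <- rep(ions$id, nf)
    total <- sum(nf)
    frag_mz <- runif(total, config@ms2Range[1], config@ms2Range[2])
    ## Dirichlet(1, ..., 1) relative intensities per parent, summing to 1
    g <- rgamma(total, shape = 1)
    gsum <- tapply(g, rep(seq_len(n), nf), sum)
    rel <- g / rep(as.numeric(gsum), nf)
    fragments <- data.frame(
      parent_id = parent, mz = frag_mz, rel_intensity = rel,
      stringsAsFactors = FALSE
    )
    new("IonCloud", ions = ions, fragments = fragments,
        mzRange = config@mzRange, imRange = config@imRange,
        gradientLengthS = config@gradientLengthS)
  })
}

.emptyCloud <- function(mzRange, imRange, gradientLengthS) {
  ions <- data.frame(id = character(), mz = numeric(), charge = integer(),
                     inv_k0 = numeric(), intensity = numeric(),
                     rt_apex_s = numeric(), rt_fwhm_s = numeric(),
                     stringsAsFactors = FALSE)
  fragments <- data.frame(parent_id = character(), mz = numeric(),
                          rel_intensity = numeric(), stringsAsFactors = FALSE)
  new("IonCloud", ions = ions, fragments = fragments,
      mzRange = mzRange, imRange = imRange, gradientLengthS = gradientLengthS)
}

#' Read and write precursor cloud tables
#'
#' The cloud table is tab-separated with header
#' `id mz charge inv_k0 intensity rt_apex_s rt_fwhm_s`; the optional
#' fragment table has header `parent_id mz rel_intensity`. Malformed rows
#' (non-numeric fields) are rejected with their row numbers; a missing
#' required column is a format error.
#'
#' @param path path of the precursor table.
#' @param fragmentsPath optional path of a fragment table.
#' @param mzRange,imRange,gradientLengthS cloud bounds; by default inferred
#'   from the data (with a small margin in m/z and 1/K0).
#' @return an [IonCloud-class]; a header-only table yields an empty cloud.
#' @export
readCloudTable <- function(path, fragmentsPath = NULL, mzRange = NULL,
                           imRange = NULL, gradientLengthS = NULL) {
  tab <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character")
  missing_cols <- setdiff(.ION_COLS, names(tab))
  if (length(missing_cols)) {
    stop(sprintf("cloud table '%s' is missing required column(s): %s",
                 path, paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  num_cols <- setdiff(.ION_COLS, "id")
  for (cc in num_cols) {
    vals <- suppressWarnings(as.numeric(tab[[cc]]))
    bad <- which(is.na(vals) & nzchar(tab[[cc]]))
    bad <- union(bad, which(!nzchar(tab[[cc]])))
    if (length(bad)) {
      stop(sprintf("cloud table '%s': non-numeric value in column '%s' at data row(s) %s",
                   path, cc, paste(sort(bad), collapse = ", ")), call. = FALSE)
    }
    tab[[cc]] <- vals
  }
  tab$charge <- as.integer(tab$charge)
  fragments <- data.frame(parent_id = character(), mz = numeric(),
                          rel_intensity = numeric(), stringsAsFactors = FALSE)
  if (!is.null(fragmentsPath)) {
    ft <- read.delim(fragmentsPath, sep = "\t", header = TRUE,
                     check.names = FALSE, colClasses = "character")
    missing_cols <- setdiff(.FRAG_COLS, names(ft))
    if (length(missing_cols)) {
      stop(sprintf("fragment table '%s' is missing required column(s): %s",
                   fragmentsPath, paste(missing_cols, collapse = ", ")),
           call. = FALSE)
    }
    for (cc in c("mz", "rel_intensity")) {
      vals <- suppressWarnings(as.numeric(ft[[cc]]))
      bad <- which(is.na(vals))
      if (length(bad)) {
        stop(sprintf("fragment table '%s': non-numeric value in column '%s' at data row(s) %s",
                     fragmentsPath, cc, paste(sort(bad), collapse = ", ")),
             call. = FALSE)
      }
      ft[[cc]] <- vals
    }
    fragments <- ft[, .FRAG_COLS]
  }
  if (is.null(mzRange)) {
    mzRange <- if (nrow(tab)) range(tab$mz) + c(-1, 1) else c(100, 2000)
  }
  if (is.null(imRange)) {
    imRange <- if (nrow(tab)) {
      pmin(pmax(range(tab$inv_k0) + c(-0.01, 0.01), 0.4001), 1.9999)
    } else c(0.5, 1.6)
  }
  if (is.null(gradientLengthS)) {
    gradientLengthS <- if (nrow(tab)) max(tab$rt_apex_s, 1) else 1
  }
  new("IonCloud", ions = tab[, .ION_COLS], fragments = fragments,
      mzRange = mzRange, imRange = imRange, gradientLengthS = gradientLengthS)
}

#' @rdname readCloudTable
#' @param cloud an [IonCloud-class] to write.
#' @export
writeCloudTable <- function(cloud, path, fragmentsPath = NULL) {
  write.table(ions(cloud), path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(fragmentsPath)) {
    write.table(fragments(cloud), fragmentsPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Fit per-charge linear trends of ion mobility against m/z
#'
#' Least-squares fit of 1/K0 on m/z separately for each requested charge
#' state, reflecting the proportional change of m/z and mobility within a
#' charge state on a TIMS ion map.
#'
#' @param cloud an [IonCloud-class].
#' @param charges integer vector of charge states to fit.
#' @return data.frame with one row per fitted charge: `charge`, `slope`,
#'   `intercept`, `slope_se`, `residual_sd`, `n`. A charge with fewer than
#'   two ions is omitted with a warning.
#' @export
fitImTrendlines <- function(cloud, charges = c(2L, 3L)) {
  io <- ions(cloud)
  out <- lapply(sort(unique(as.integer(charges))), function(z) {
    sub <- io[io$charge == z, , drop = FALSE]
    if (nrow(sub) < 2) {
      warning(sprintf("charge %d has fewer than 2 ions; omitted from trend fit", z),
              call. = FALSE)
      return(NULL)
    }
    fit <- lm(inv_k0 ~ mz, data = sub)
    cf <- coef(fit)
    se <- sqrt(diag(vcov(fit)))
    data.frame(charge = z, slope = unname(cf["mz"]),
               intercept = unname(cf["(Intercept)"]),
               slope_se = unname(se["mz"]),
               residual_sd = summary(fit)$sigma,
               n = nrow(sub))
  })
  out <- Filter(Negate(is.null), out)
  if (!length(out)) {
    return(data.frame(charge = integer(), slope = numeric(),
                      intercept = numeric(), slope_se = numeric(),
                      residual_sd = numeric(), n = integer()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-mobility-bin m/z quantile envelope
#'
#' Splits an ion-mobility range into bins of fixed width and computes, per
#' bin, lower-interpolation empirical quantiles (order statistic at
#' `ceiling(q * n)`) of the m/z of ions with the stated charges. The
#' envelope is what guides Q1 window placement: it describes where the
#' multiply-charged precursor population sits in m/z at each mobility.
#'
#' @param cloud an [IonCloud-class].
#' @param imBinWidth bin width in 1/K0 units.
#' @param qLo,qHi quantile fractions, `0 <= qLo < qHi <= 1`.
#' @param charges charge states included (default 2 and up to the maximum
#'   present).
#' @param imRange numeric(2) range to bin; defaults to the cloud's.
#' @return data.frame with one row per bin: `im_lo`, `im_hi`, `mz_lo`
#'   (quantile at `qLo`), `mz_hi` (quantile at `qHi`), `n`, `empty`.
#'   Empty bins carry NA quantiles and `empty = TRUE`.
#' @export
mzQuantileEnvelope <- function(cloud, imBinWidth = 0.01, qLo = 0.25,
                               qHi = 0.75, charges = NULL, imRange = NULL) {
  stopIfNot(qLo >= 0 && qLo < qHi && qHi <= 1, "need 0 <= qLo < qHi <= 1")
  stopIfNot(imBinWidth > 0, "imBinWidth must be > 0")
  io <- ions(cloud)
  if (is.null(charges)) charges <- unique(io$charge[io$charge >= 2])
  if (is.null(imRange)) imRange <- imRange(cloud)
  sel <- io[io$charge %in% charges, , drop = FALSE]
  n_bins <- max(1L, ceiling((imRange[2] - imRange[1]) / imBinWidth - 1e-9))
  lo <- imRange[1] + (seq_len(n_bins) - 1L) * imBinWidth
  hi <- pmin(lo + imBinWidth, imRange[2])
  res <- data.frame(im_lo = lo, im_hi = hi, mz_lo = NA_real_,
                    mz_hi = NA_real_, n = 0L, empty = TRUE)
  if (nrow(sel)) {
    bin <- findInterval(sel$inv_k0, c(lo, imRange[2]), rightmost.closed = FALSE)
    keep <- bin >= 1L & bin <= n_bins & sel$inv_k0 < imRange[2]
    bin <- bin[keep]
    mzv <- sel$mz[keep]
    for (b in unique(bin)) {
      v <- mzv[bin == b]
      qq <- quantileLower(v, c(qLo, qHi))
      res$mz_lo[b] <- qq[1]
      res$mz_hi[b] <- qq[2]
      res$n[b] <- length(v)
      res$empty[b] <- FALSE
    }
  }
  res
}
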