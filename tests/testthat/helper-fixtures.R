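# Fixtures built in code and shared across test files.

# Hand-laid cloud: explicit coordinates, no randomness.
tinyCloud <- function() {
  ions <- data.frame(
    id = c("p1", "p2", "p3"),
    mz = c(500, 700, 900),
    charge = c(2L, 2L, 3L),
    inv_k0 = c(0.85, 0.95, 0.90),
    intensity = c(1000, 2000, 500),
    rt_apex_s = c(10, 15, 20),
    rt_fwhm_s = c(2, 2, 2),
    stringsAsFactors = FALSE
  )
  fragments <- data.frame(
    parent_id = rep(ions$id, each = 2),
    mz = c(350, 450, 520, 640, 410, 610),
    rel_intensity = rep(c(0.6, 0.4), 3),
    stringsAsFactors = FALSE
  )
  ionCloud(ions, fragments, mzRange = c(400, 1000), imRange = c(0.75, 1.1),
           gradientLengthS = 30)
}

# Single hand-laid precursor with two fragments; apex centred in the run.
oneIonCloud <- function(rtFwhm = 2, apex = 10, gradient = 20, invK0 = 0.9) {
  ions <- data.frame(id = "p1", mz = 600, charge = 2L, inv_k0 = invK0,
                     intensity = 1000, rt_apex_s = apex, rt_fwhm_s = rtFwhm,
                     stringsAsFactors = FALSE)
  fragments <- data.frame(parent_id = c("p1", "p1"), mz = c(350, 750),
                          rel_intensity = c(0.5, 0.5), stringsAsFactors = FALSE)
  ionCloud(ions, fragments, mzRange = c(400, 1000), imRange = c(0.6, 1.2),
           gradientLengthS = gradient)
}

# 1F-like scheme built by hand: nSteps contiguous IM slices sharing one
# broad Q1 window (plus optional MS1 frame).
flatSliceScheme <- function(nSteps = 4, imRange = c(0.6, 1.2),
                            mzWin = c(400, 1000), fill = 100, ms1 = FALSE,
                            repeats = 1L) {
  edges <- seq(imRange[1], imRange[2], length.out = nSteps + 1)
  ms2_id <- if (ms1) 2L else 1L
  frames <- data.frame(subcycle = 1L, frame = ms2_id, kind = "MS2",
                       fill_time_ms = fill, repeats = repeats)
  if (ms1) {
    frames <- rbind(data.frame(subcycle = 1L, frame = 1L, kind = "MS1",
                               fill_time_ms = fill, repeats = 1L), frames)
  }
  steps <- data.frame(subcycle = 1L, frame = ms2_id, step = seq_len(nSteps),
                      im_lo = edges[-(nSteps + 1)], im_hi = edges[-1],
                      mz_lo = mzWin[1], mz_hi = mzWin[2], ce_ev = NA_real_)
  acquisitionScheme(frames, steps, mzWin, imRange, label = "flat-1F")
}

# Reference 8x3 dia-PASEF scheme over a standard box.
refScheme <- function(fill = 100, ms1 = 0) {
  designDiapasefReference(mzRange = c(400, 1000), imRange = c(0.6, 1.2),
                          windowWidth = 25, nFrames = 8, windowsPerFrame = 3,
                          fillTimeMs = fill, ms1PerCycle = ms1)
}

# Random valid scheme for round-trip property tests; all float fields are
# multiples of 1e-4 so the 4-decimal file format is lossless.
randomScheme <- function(seed) {
  set.seed(seed)
  r4 <- function(x) round(x, 4)
  n_subcycles <- sample(1:2, 1)
  frames <- list()
  steps <- list()
  fid <- 0L
  for (sc in seq_len(n_subcycles)) {
    if (runif(1) < 0.5) {
      fid <- fid + 1L
      frames[[length(frames) + 1L]] <- data.frame(
        subcycle = sc, frame = fid, kind = "MS1",
        fill_time_ms = r4(runif(1, 50, 200)), repeats = 1L)
    }
    for (f in seq_len(sample(1:3, 1))) {
      fid <- fid + 1L
      n_steps <- sample(1:5, 1)
      edges <- r4(sort(runif(n_steps + 1, 0.6, 1.4)))
      while (any(diff(edges) < 1e-3)) {
        edges <- r4(sort(runif(n_steps + 1, 0.6, 1.4)))
      }
      frames[[length(frames) + 1L]] <- data.frame(
        subcycle = sc, frame = fid, kind = "MS2",
        fill_time_ms = r4(runif(1, 50, 200)), repeats = sample(1:3, 1))
      mz_lo <- r4(runif(n_steps, 300, 900))
      steps[[length(steps) + 1L]] <- data.frame(
        subcycle = sc, frame = fid, step = seq_len(n_steps),
        im_lo = edges[-(n_steps + 1)], im_hi = edges[-1],
        mz_lo = mz_lo, mz_hi = mz_lo + r4(runif(n_steps, 10, 300)),
        ce_ev = ifelse(runif(n_steps) < 0.5, NA_real_, r4(runif(n_steps, 20, 60))))
    }
  }
  acquisitionScheme(do.call(rbind, frames), do.call(rbind, steps),
                    mzRange = c(100, 1700), imRange = c(0.6, 1.4),
                    label = sprintf("random-%d", seed))
}

# Small default-geometry cloud for simulation tests (seeded, fast).
simCloud <- function(nIons = 300, seed = 7, gradient = 40, fwhm = 3) {
  cfg <- cloudGenConfig(nIons = nIons, seed = seed, gradientLengthS = gradient,
                        rtFwhmS = fwhm)
  generateSyntheticCloud(cfg)
}

noNoise <- function(seed = 1) {
  simConfig(mzJitterPpm = 0, imJitterSd = 0, intensityCv = 0,
            noisePeaksPerFrame = 0, seed = seed)
}
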