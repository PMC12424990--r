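test_that("a 1F-isolated precursor appears in every MS2 frame of every cycle", {
  cloud <- oneIonCloud(rtFwhm = 4, apex = 5, gradient = 10)
  sch <- flatSliceScheme(nSteps = 4, ms1 = TRUE)
  stream <- simulateAcquisition(cloud, sch, noNoise(), c(0, 10))
  ms2 <- stream[stream$kind == "MS2", ]
  # 2 fragments in each of the 50 cycles (cycle = 200 ms)
  expect_equal(length(unique(stream$cycle)), 50L)
  expect_equal(as.integer(table(ms2$cycle)), rep(2L, 50))
  # MS1 frames carry the precursor with full-range boundaries
  ms1 <- stream[stream$kind == "MS1", ]
  expect_equal(unique(ms1$mz), 600)
  expect_equal(unique(ms1$q1_lo), 400)
  expect_equal(unique(ms1$q1_hi), 1000)
})

test_that("under the 8-frame reference the per-cycle signal is 1/8 of 1F", {
  # flat elution; m/z 600 at 1/K0 0.81 sits on the reference diagonal
  cloud <- oneIonCloud(rtFwhm = 1e6, apex = 0, gradient = 10, invK0 = 0.81)
  one <- flatSliceScheme(nSteps = 4, fill = 100, ms1 = FALSE)
  ref <- refScheme(fill = 100, ms1 = 0)
  s1 <- simulateAcquisition(cloud, one, noNoise(), c(0, 8))
  sr <- simulateAcquisition(cloud, ref, noNoise(), c(0, 8))
  sr_ms2 <- sr[sr$kind == "MS2", ]
  # isolated in exactly one MS2 frame per cycle
  expect_equal(as.integer(table(sr_ms2$cycle)), rep(2L, 10))
  expect_equal(length(unique(sr_ms2$frame)), 1L)
  # per-cycle summed fragment signal: 1F equals the source intensity
  # (duty 1), the reference 1/8 of the 1F per-unit-time signal
  per_cycle_1f <- sum(s1$intensity[s1$kind == "MS2" & s1$cycle == 1])
  per_cycle_ref <- sum(sr_ms2$intensity[sr_ms2$cycle == 1])
  expect_equal(per_cycle_1f, 1000)
  expect_equal(per_cycle_ref, 1000)
  # per unit time: 80 1F cycles vs 10 ref cycles in 8 s -> ratio 8
  expect_equal(sum(s1$intensity[s1$kind == "MS2"]) /
                 sum(sr_ms2$intensity), 8)
})

test_that("signal conservation: emitted MS2 signal matches the analytic product", {
  cloud <- tinyCloud()
  sch <- flatSliceScheme(nSteps = 4, imRange = c(0.75, 1.1), fill = 50,
                         ms1 = TRUE)
  stream <- simulateAcquisition(cloud, sch, noNoise(), c(0, 30))
  io <- ions(cloud)
  fr <- fragments(cloud)
  ms2 <- stream[stream$kind == "MS2", ]
  for (i in seq_len(nrow(io))) {
    fmz <- fr$mz[fr$parent_id == io$id[i]]
    mine <- ms2[ms2$mz %in% fmz, ]
    duty <- precursorDutyCycle(sch, io$mz[i], io$inv_k0[i])
    for (cc in unique(mine$cycle)) {
      rt <- unique(mine$rt_s[mine$cycle == cc])
      expected <- io$intensity[i] *
        exp(-4 * log(2) * (rt - io$rt_apex_s[i])^2 / io$rt_fwhm_s[i]^2) *
        duty * (50 / 100)
      expect_equal(sum(mine$intensity[mine$cycle == cc]), expected,
                   tolerance = 1e-12)
    }
  }
})

test_that("every annotated peak's parent lies within its Q1 boundaries", {
  cloud <- simCloud(200, seed = 10)
  sch <- design1F(cloud, designConfig(ms1PerSubcycle = 1))
  stream <- simulateAcquisition(cloud, sch, noNoise(), c(0, 5))
  ms2 <- stream[stream$kind == "MS2", ]
  io <- ions(cloud)
  fr <- fragments(cloud)
  parent <- fr$parent_id[match(ms2$mz, fr$mz)]
  pmz <- io$mz[match(parent, io$id)]
  pim <- io$inv_k0[match(parent, io$id)]
  expect_false(anyNA(parent))
  expect_true(all(ms2$q1_lo <= pmz & pmz < ms2$q1_hi))
  st <- schemeSteps(sch)
  step_of <- vapply(seq_len(nrow(ms2)), function(i) {
    which(st$mz_lo == ms2$q1_lo[i] & st$mz_hi == ms2$q1_hi[i])[1]
  }, integer(1))
  expect_true(all(pim >= st$im_lo[step_of] & pim < st$im_hi[step_of]))
})

test_that("the stream is reproducible under a fixed seed and round-trips to TSV", {
  cloud <- simCloud(100, seed = 11)
  sch <- flatSliceScheme(nSteps = 4, imRange = imRange(cloud),
                         mzWin = c(400, 1200))
  sim <- simConfig(seed = 5)  # full default noise
  a <- simulateAcquisition(cloud, sch, sim, c(0, 3))
  b <- simulateAcquisition(cloud, sch, sim, c(0, 3))
  expect_identical(a, b)
  c2 <- simulateAcquisition(cloud, sch, simConfig(seed = 6), c(0, 3))
  expect_false(identical(a, c2))

  path <- withr::local_tempfile(fileext = ".tsv")
  writeFrameStream(a, path)
  back <- readFrameStream(path)
  expect_equal(back$mz, a$mz, tolerance = 1e-12)
  expect_equal(back$intensity, a$intensity, tolerance = 1e-12)
  expect_equal(back$kind, a$kind)
})

test_that("rt windows shorter than one cycle are rejected", {
  cloud <- oneIonCloud()
  sch <- flatSliceScheme(nSteps = 2, fill = 500, ms1 = TRUE)  # 1 s cycle
  expect_error(simulateAcquisition(cloud, sch, noNoise(), c(0, 0.5)),
               "shorter than one cycle")
})

test_that("Q1 transitions are classified into shifts and discontinuous switches", {
  # hand-laid quasi-continuous frame: 20 slices whose windows all shift but
  # always overlap their neighbour
  edges <- seq(0.6, 1.2, length.out = 21)
  steps <- data.frame(subcycle = 1L, frame = 1L, step = 1:20,
                      im_lo = edges[-21], im_hi = edges[-1],
                      mz_lo = 400 + (0:19) * 20, mz_hi = 500 + (0:19) * 20,
                      ce_ev = NA_real_)
  frames <- data.frame(subcycle = 1L, frame = 1L, kind = "MS2",
                       fill_time_ms = 100, repeats = 1L)
  one <- acquisitionScheme(frames, steps, c(400, 880), c(0.6, 1.2))
  sw <- q1SwitchCount(one, 1, 1)
  expect_equal(sw$transitions, 19L)   # 20 quasi-continuous slices
  expect_equal(sw$discontinuous, 0L)  # neighbouring windows overlap
  # a designed 1F scheme also never jumps discontinuously
  cloud <- generateSyntheticCloud(cloudGenConfig(nIons = 5000, seed = 12))
  d1 <- design1F(cloud, designConfig(ms1PerSubcycle = 0))
  fr1 <- schemeFrames(d1)
  swd <- q1SwitchCount(d1, fr1$subcycle[1], fr1$frame[1])
  expect_lte(swd$transitions, 19L)
  expect_equal(swd$discontinuous, 0L)
  ref <- refScheme()
  frr <- schemeFrames(ref)
  swr <- q1SwitchCount(ref, frr$subcycle[1], frr$frame[1])
  expect_equal(swr$transitions, 2L)   # 3 stacked disjoint windows
  expect_equal(swr$discontinuous, 2L)
})

test_that("the switch-loss model dents the reference but not the 1F advantage", {
  cloud <- oneIonCloud(rtFwhm = 1e6, apex = 0, gradient = 10, invK0 = 0.81)
  one <- flatSliceScheme(nSteps = 4, fill = 100, ms1 = FALSE)
  ref <- refScheme(fill = 100, ms1 = 0)
  loss <- simConfig(mzJitterPpm = 0, imJitterSd = 0, intensityCv = 0,
                    noisePeaksPerFrame = 0, switchLossFraction = 0.5,
                    switchLossSpan = 0.1, seed = 1)
  sr_plain <- simulateAcquisition(cloud, ref, noNoise(), c(0, 8))
  sr_loss <- simulateAcquisition(cloud, ref, loss, c(0, 8))
  s1_loss <- simulateAcquisition(cloud, one, loss, c(0, 8))
  sig <- function(s) sum(s$intensity[s$kind == "MS2"])
  # the affected precursor sits in a post-switch step of the reference
  st <- schemeSteps(ref)
  expect_lte(sig(sr_loss), sig(sr_plain))
  expect_gte(sig(s1_loss) / sig(sr_loss), 8)
})
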