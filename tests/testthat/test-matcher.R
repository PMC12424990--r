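# Helper: a hand-laid subcycle of frame spectra with annotated boundaries.
twoFrameSubcycle <- function() {
  data.frame(
    cycle = 1L, rt_s = c(0.1, 0.1, 0.2, 0.2),
    subcycle = 1L, frame = c(1L, 1L, 2L, 2L), repeat_index = 1L,
    kind = "MS2",
    mz = c(350.000, 500.000, 350.000, 520.000),
    intensity = c(100, 80, 250, 60),
    inv_k0 = 0.90,
    q1_lo = c(400, 400, 400, 400), q1_hi = c(700, 700, 700, 700),
    stringsAsFactors = FALSE
  )
}

test_that("frame candidacy is decided by m/z containment and ion mobility", {
  frames <- twoFrameSubcycle()
  prec <- list(mz = 500, inv_k0 = 0.90)
  expect_equal(candidateFrames(prec, frames), c(1L, 2L))
  # IM exclusion at the default tolerance 0.05
  expect_equal(candidateFrames(list(mz = 500, inv_k0 = 0.70), frames),
               integer(0))
  # m/z outside every annotated boundary
  expect_equal(candidateFrames(list(mz = 900, inv_k0 = 0.90), frames),
               integer(0))
})

test_that("candidate sets equal a brute-force scan over every peak", {
  cloud <- simCloud(150, seed = 13)
  sch <- design1F(cloud, designConfig(ms1PerSubcycle = 0, nImSteps = 10))
  stream <- simulateAcquisition(cloud, sch, simConfig(seed = 3), c(0, 2))
  sub <- stream[stream$cycle == 1 & stream$subcycle == 1, ]
  cfg <- matchConfig()
  set.seed(31)
  mzq <- runif(1000, 300, 1300)
  imq <- runif(1000, 0.55, 1.35)
  for (i in seq_len(1000)) {
    got <- candidateFrames(list(mz = mzq[i], inv_k0 = imq[i]), sub, cfg)
    oracle <- integer(0)
    ms2 <- sub[sub$kind == "MS2", ]
    for (f in unique(ms2$frame)) {
      pk <- ms2[ms2$frame == f, ]
      if (any(pk$q1_lo <= mzq[i] & mzq[i] < pk$q1_hi &
                abs(pk$inv_k0 - imq[i]) <= cfg@imTol)) {
        oracle <- c(oracle, f)
      }
    }
    expect_identical(got, sort(oracle))
  }
})

test_that("fragment intensity takes the best frame's peak with a stable tie-break", {
  frames <- twoFrameSubcycle()
  prec <- list(mz = 500, inv_k0 = 0.90)
  # 100 in frame 1 vs 250 in frame 2 at the same fragment m/z
  expect_equal(fragmentIntensityMultiframe(350, prec, frames), 250)
  # no matching peak anywhere
  expect_equal(fragmentIntensityMultiframe(600, prec, frames), 0)
  # exact tie: the lower frame index wins, intensity unchanged
  tie <- frames
  tie$intensity <- c(250, 80, 250, 60)
  expect_equal(fragmentIntensityMultiframe(350, prec, tie), 250)
  # matching respects the precursor boundary constraint: precursor outside
  # the annotated window finds nothing even at the right fragment m/z
  expect_equal(fragmentIntensityMultiframe(350, list(mz = 900, inv_k0 = 0.9),
                                           frames), 0)
})

test_that("repeat merging sums intensities and conserves total signal", {
  rep1 <- data.frame(cycle = 1L, rt_s = 0.1, subcycle = 1L, frame = 1L,
                     repeat_index = 1L, kind = "MS2", mz = 350,
                     intensity = 50, inv_k0 = 0.9, q1_lo = 400, q1_hi = 700,
                     stringsAsFactors = FALSE)
  rep2 <- rep1
  rep2$repeat_index <- 2L
  rep2$rt_s <- 0.2
  merged <- mergeRepeats(rbind(rep1, rep2))
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$intensity, 100)
  expect_equal(merged$mz, 350)

  # single repeat: identity (modulo bookkeeping columns)
  one <- mergeRepeats(rep1)
  expect_equal(one$mz, rep1$mz)
  expect_equal(one$intensity, rep1$intensity)

  # randomized repeat sets conserve total intensity exactly
  set.seed(41)
  for (r in 1:5) {
    n_rep <- sample(2:4, 1)
    base <- data.frame(
      cycle = 1L, rt_s = 0, subcycle = 1L, frame = 1L, repeat_index = 1L,
      kind = "MS2",
      mz = round(runif(30, 300, 1000), 3),
      intensity = runif(30, 1, 100),
      inv_k0 = round(runif(30, 0.7, 1.1), 3),
      q1_lo = sample(c(400, 600), 30, replace = TRUE), q1_hi = 0,
      stringsAsFactors = FALSE)
    base$q1_hi <- base$q1_lo + 200
    reps <- do.call(rbind, lapply(seq_len(n_rep), function(k) {
      b <- base
      b$repeat_index <- k
      b$rt_s <- k / 10
      b$intensity <- runif(30, 1, 100)
      b
    }))
    merged <- mergeRepeats(reps)
    expect_equal(sum(merged$intensity), sum(reps$intensity), tolerance = 1e-12)
  }

  # mismatched geometry across repeats is a contract error
  bad2 <- rep2
  bad2$q1_lo <- 450
  expect_error(mergeRepeats(rbind(rep1, bad2)), "mismatched step geometry")
})

test_that("XIC sampling density follows the cycle time", {
  # 1F with MS1 at 100 ms fill: 0.2 s cycle; FWHM 2 s -> ~10 points at FWHM
  cloud <- oneIonCloud(rtFwhm = 2, apex = 10, gradient = 20, invK0 = 0.81)
  one <- flatSliceScheme(nSteps = 4, fill = 100, ms1 = TRUE)
  stream <- simulateAcquisition(cloud, one, noNoise(), c(0, 20))
  fmz <- fragments(cloud)$mz
  prec <- ions(cloud)[1, ]
  xic <- extractXic(prec, fmz, stream)
  expect_gte(pointsAtFwhm(xic), 9)
  expect_lte(pointsAtFwhm(xic), 11)
  # 800 ms reference cycle: strictly fewer points at FWHM
  ref <- refScheme(fill = 100, ms1 = 0)
  stream_ref <- simulateAcquisition(cloud, ref, noNoise(), c(0, 20))
  xic_ref <- extractXic(prec, fmz, stream_ref)
  expect_gt(pointsAtFwhm(xic_ref), 0)
  expect_lt(pointsAtFwhm(xic_ref), pointsAtFwhm(xic))
})

test_that("the half-apex trapezoid quantity matches the closed form on a triangle", {
  # hand-laid stream producing a symmetric triangular trace 10,20,...,50,...,10
  tri <- c(1, 2, 3, 4, 5, 4, 3, 2, 1) * 10
  stream <- data.frame(
    cycle = seq_along(tri), rt_s = seq_along(tri) * 0.1, subcycle = 1L,
    frame = 1L, repeat_index = 1L, kind = "MS2", mz = 350, intensity = tri,
    inv_k0 = 0.9, q1_lo = 400, q1_hi = 700, stringsAsFactors = FALSE)
  xic <- extractXic(list(mz = 500, inv_k0 = 0.9), 350, stream)
  expect_equal(xicApex(xic), 50)
  # region at or above 25: 30,40,50,40,30 -> trapezoid 160, 5 points
  expect_equal(pointsAtFwhm(xic), 5)
  expect_equal(quantifyXic(xic), 160)
  # all-zero trace -> flagged, quantity 0
  stream0 <- stream
  stream0$intensity <- 0
  xic0 <- extractXic(list(mz = 500, inv_k0 = 0.9), 350, stream0)
  expect_true(xic0@allZero)
  expect_equal(quantifyXic(xic0), 0)
})

test_that("CV follows the sd/mean definition and the n >= 3 reporting policy", {
  q <- data.frame(precursor_id = rep(c("a", "b", "c"), times = c(3, 3, 2)),
                  run = c(1:3, 1:3, 1:2),
                  quantity = c(5, 5, 5, 1, 2, 3, 1, 2))
  cv <- cvSummary(q)
  expect_equal(cv$cv[cv$precursor_id == "a"], 0)
  expect_equal(cv$cv[cv$precursor_id == "b"], 0.5)  # sd 1 / mean 2
  expect_true(cv$suppressed[cv$precursor_id == "c"])
  expect_true(is.na(cv$cv[cv$precursor_id == "c"]))
})

test_that("replicate CV recovers the injected run-to-run noise", {
  cloud <- simCloud(250, seed = 17, gradient = 10, fwhm = 1.5)
  sch <- design1F(cloud, designConfig(ms1PerSubcycle = 0))
  cfg <- matchConfig()
  io <- ions(cloud)
  multi <- io[io$charge >= 2, ]
  fr <- fragments(cloud)
  quantify_run <- function(sim) {
    stream <- simulateAcquisition(cloud, sch, sim, c(0, 10))
    vapply(seq_len(nrow(multi)), function(i) {
      fmz <- fr$mz[fr$parent_id == multi$id[i]]
      quantifyXic(extractXic(multi[i, ], fmz, stream, cfg))
    }, numeric(1))
  }
  # identical seeds, no noise: replicate CV is exactly zero
  qa <- quantify_run(noNoise(seed = 50))
  qb <- quantify_run(noNoise(seed = 50))
  expect_identical(qa, qb)

  # injected intensity CV of 0.1: median measured CV within [0.08, 0.12]
  cv_inj <- 0.1
  runs <- lapply(1:5, function(r) {
    sim <- simConfig(mzJitterPpm = 0, imJitterSd = 0, intensityCv = cv_inj,
                     noisePeaksPerFrame = 0, seed = 100 + r)
    data.frame(precursor_id = multi$id, run = r,
               quantity = quantify_run(sim), stringsAsFactors = FALSE)
  })
  q <- do.call(rbind, runs)
  q <- q[q$quantity > 0, ]
  cv <- cvSummary(q)
  cv <- cv[!cv$suppressed, ]
  expect_gte(nrow(cv), 200)
  med <- median(cv$cv)
  expect_gte(med, 0.8 * cv_inj)
  expect_lte(med, 1.2 * cv_inj)
})
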