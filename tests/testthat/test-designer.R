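test_that("1F design slices contiguously, floors widths and captures the cloud", {
  cloud <- generateSyntheticCloud(cloudGenConfig(seed = 42))
  sch <- design1F(cloud)
  st <- schemeSteps(sch)
  expect_equal(nrow(st), 20L)
  # contiguous partition of the IM range
  expect_equal(st$im_lo[-1], st$im_hi[-nrow(st)])
  expect_equal(st$im_lo[1], imRange(cloud)[1])
  expect_equal(st$im_hi[nrow(st)], imRange(cloud)[2])
  # widths at or above the floor
  expect_true(all(st$mz_hi - st$mz_lo >= 50 - 1e-9))
  # >= 99% of multiply-charged intensity isolated
  io <- ions(cloud)
  multi <- io[io$charge >= 2, ]
  duty <- precursorDutyCycle(sch, multi$mz, multi$inv_k0)
  expect_gte(sum(multi$intensity[duty > 0]) / sum(multi$intensity), 0.99)
  # singly charged ions excluded by the diagonal envelope
  z1 <- io[io$charge == 1, ]
  expect_equal(sum(precursorDutyCycle(sch, z1$mz, z1$inv_k0) > 0), 0L)
})

test_that("a degenerate envelope falls back to the minimum width", {
  set.seed(2)
  n <- 500
  ions <- data.frame(id = sprintf("i%d", 1:n), mz = runif(n, 499, 501),
                     charge = 2L, inv_k0 = runif(n, 0.8, 1.0),
                     intensity = 1, rt_apex_s = 10, rt_fwhm_s = 2)
  cloud <- ionCloud(ions, mzRange = c(400, 600), imRange = c(0.8, 1.0))
  sch <- design1F(cloud, designConfig(nImSteps = 5, padMz = 0))
  st <- schemeSteps(sch)
  expect_equal(st$mz_hi - st$mz_lo, rep(50, 5))
  centers <- (st$mz_lo + st$mz_hi) / 2
  expect_true(all(abs(centers - 500) < 2))
})

test_that("multi-frame windows partition the 1F windows exactly", {
  cloud <- simCloud(2000, seed = 3)
  for (nF in c(2L, 4L)) {
    cfg <- designConfig(shiftSubcycles = FALSE)
    one <- design1F(cloud, cfg)
    multi <- designMultiframe(cloud, cfg, nF)
    st1 <- schemeSteps(one)
    st1 <- st1[order(st1$step), ]
    stm <- schemeSteps(multi)
    for (k in st1$step) {
      seg <- stm[stm$step == k, ]
      seg <- seg[order(seg$mz_lo), ]
      expect_equal(nrow(seg), nF)
      expect_equal(seg$mz_lo[1], st1$mz_lo[st1$step == k])
      expect_equal(seg$mz_hi[nF], st1$mz_hi[st1$step == k])
      # contiguous: segment j's upper edge is segment j+1's lower edge
      expect_equal(seg$mz_lo[-1], seg$mz_hi[-nF])
    }
  }
})

test_that("balanced boundaries sit at the intensity midpoint for uniform ions", {
  set.seed(8)
  n <- 2000
  ions <- data.frame(id = sprintf("i%d", 1:n), mz = runif(n, 400, 800),
                     charge = 2L, inv_k0 = runif(n, 0.8, 0.9),
                     intensity = 1, rt_apex_s = 10, rt_fwhm_s = 2)
  cloud <- ionCloud(ions, mzRange = c(400, 800), imRange = c(0.8, 0.9))
  cfg <- designConfig(nImSteps = 1, boundaryMode = "balanced",
                      shiftSubcycles = FALSE, padMz = 0,
                      qLo = 0, qHi = 1, ms1PerSubcycle = 0)
  sch <- designMultiframe(cloud, cfg, 2)
  st <- schemeSteps(sch)
  boundary <- sort(unique(c(st$mz_lo, st$mz_hi)))[2]
  window_mid <- (min(st$mz_lo) + max(st$mz_hi)) / 2
  expect_lt(abs(boundary - window_mid), 2)
  # and it matches the brute-force weighted-quantile oracle exactly
  inside <- ions$mz >= min(st$mz_lo) & ions$mz < max(st$mz_hi)
  sorted <- sort(ions$mz[inside])
  expect_equal(boundary, sorted[ceiling(0.5 * length(sorted))])
})

test_that("shifted subcycles offset the boundaries by half a segment", {
  cloud <- simCloud(2000, seed = 4)
  sch <- designMultiframe(cloud, designConfig(shiftSubcycles = TRUE,
                                              ms1PerSubcycle = 1), 4)
  fr <- schemeFrames(sch)
  expect_equal(nSubcycles(sch), 2L)
  expect_equal(sum(fr$kind == "MS2"), 8L)
  expect_equal(sum(fr$kind == "MS1"), 2L)
  st <- schemeSteps(sch)
  for (k in unique(st$step)) {
    s1 <- st[st$subcycle == 1 & st$step == k, ]
    s2 <- st[st$subcycle == 2 & st$step == k, ]
    b1 <- sort(s1$mz_lo)[-1]          # inner boundaries, subcycle 1
    b2 <- sort(s2$mz_lo)[-1]
    w <- max(s1$mz_hi) - min(s1$mz_lo)
    half_seg <- w / 4 / 2
    # interior boundaries shift by exactly half a segment (midpoint mode;
    # clamping can only bite at the window edges)
    expect_equal(b2, pmin(b1 + half_seg, max(s1$mz_hi)), tolerance = 1e-9)
  }
})

test_that("the dia-PASEF reference tiles m/z with diagonally stacked windows", {
  sch <- refScheme()
  st <- schemeSteps(sch)
  expect_equal(nrow(st), 24L)
  expect_equal(unname(st$mz_hi - st$mz_lo), rep(25, 24))
  # non-overlapping in m/z, tiling 400-1000
  edges <- sort(st$mz_lo)
  expect_equal(edges, seq(400, 975, by = 25))
  # every point of the covered polygon hit by exactly one of 8 frames
  fr <- schemeFrames(sch)
  centers_mz <- (st$mz_lo + st$mz_hi) / 2
  centers_im <- (st$im_lo + st$im_hi) / 2
  hits <- rowSums(vapply(seq_len(nrow(fr)), function(i) {
    frameIsolates(sch, fr$subcycle[i], fr$frame[i], centers_mz, centers_im)
  }, logical(24)))
  expect_equal(hits, rep(1, 24))

  # degenerate single-window scheme
  deg <- designDiapasefReference(c(400, 1000), c(0.6, 1.2), 600, 1, 1)
  stdeg <- schemeSteps(deg)
  expect_equal(nrow(stdeg), 1L)
  expect_equal(c(stdeg$mz_lo, stdeg$mz_hi), c(400, 1000))
  expect_equal(c(stdeg$im_lo, stdeg$im_hi), c(0.6, 1.2))

  # tiling mismatch suggests the right width
  expect_error(designDiapasefReference(c(400, 1000), c(0.6, 1.2), 30, 8, 3),
               "25\\.0000")
})

test_that("collision-energy ramps interpolate linearly and clamp", {
  ramp <- ceRamp(c(0.60, 1.60), c(20, 59))
  expect_equal(ceAt(ramp, 0.60), 20)
  expect_equal(ceAt(ramp, 1.60), 59)
  expect_equal(ceAt(ramp, 1.10), 39.5)
  expect_equal(ceAt(ramp, 0.40), 20)   # clamped below
  expect_equal(ceAt(ramp, 1.80), 59)   # clamped above
  # monotone when anchors are
  grid <- seq(0.4, 1.8, by = 0.01)
  expect_true(all(diff(ceAt(ramp, grid)) >= 0))
  expect_error(ceRamp(c(1.0, 0.5), c(20, 59)), "increasing")
})

test_that("frame repeats maximise sampling under the points-per-peak floor", {
  expect_equal(computeFrameRepeats(1.2, 0.1, 1, 1), 3L)
  expect_warning(r <- computeFrameRepeats(0.2, 0.1, 4, 1), "points per peak")
  expect_equal(r, 1L)
  # brute-force check over a grid: returned r satisfies the floor (or is 1)
  # and r+1 would violate it; doubling the FWHM never decreases r
  grid <- expand.grid(fwhm = c(0.5, 1, 2, 4), frame = c(0.05, 0.1, 0.2),
                      ms2 = c(1, 2, 4), ms1 = c(0, 1))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    r <- suppressWarnings(computeFrameRepeats(g$fwhm, g$frame, g$ms2, g$ms1))
    pts <- function(r) g$fwhm / ((g$ms1 + r * g$ms2) * g$frame)
    if (pts(1) >= 3) {
      expect_gte(pts(r), 3)
      expect_lt(pts(r + 1), 3)
    } else {
      expect_equal(r, 1L)
    }
    r2 <- suppressWarnings(computeFrameRepeats(2 * g$fwhm, g$frame, g$ms2, g$ms1))
    expect_gte(r2, r)
  }
})
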