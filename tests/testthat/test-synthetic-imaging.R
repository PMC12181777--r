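test_that("gelation opacity is unimodal in the crosslinker-to-polymer ratio", {
  opAt <- function(ca, alg = 1.0) opacityFromConcentrations(
    gelationParams(alginatePct = alg, cacl2Pct = ca))

  # too little calcium: bead nearly invisible
  g <- gelationParams(alginatePct = 1.0, cacl2Pct = 0.1)
  expect_lte(opacityFromConcentrations(g), g@visibilityFloor)

  # rising branch of the screen at fixed alginate
  ladder <- vapply(c(0.1, 0.5, 1.0, 1.5), opAt, numeric(1), alg = 1.5)
  expect_true(all(diff(ladder) > 0))

  # past the critical ratio opacity falls again
  expect_lt(opAt(10, 1.5), opAt(1.5, 1.5))
  expect_lt(opAt(5, 1.5), opAt(1.5, 1.5))

  expect_error(opacityFromConcentrations(
    gelationParams(alginatePct = 0, cacl2Pct = 1)), "domain")

  # unimodality property: increasing below rCrit, decreasing above,
  # continuous at the peak
  g0 <- gelationParams()
  rGrid <- exp(seq(log(0.05), log(20), length.out = 60))
  ops <- vapply(rGrid, function(r) opacityFromConcentrations(
    gelationParams(alginatePct = 1, cacl2Pct = r)), numeric(1))
  below <- rGrid < g0@rCrit
  expect_true(all(diff(ops[below]) > 0))
  expect_true(all(diff(ops[!below]) < 0))
  eps <- 1e-6
  expect_equal(
    opacityFromConcentrations(gelationParams(1, g0@rCrit - eps)),
    opacityFromConcentrations(gelationParams(1, g0@rCrit + eps)),
    tolerance = 1e-4)
  expect_true(all(ops <= g0@peakOpacity))
})

test_that("the opacity time course rises, saturates and decays per the model", {
  d <- disintegrationParams(tEdta = 300, kDecay = 0.01, kRise = 0.02,
                            baselineOpacity = 0.1, plateauOpacity = 0.8)
  expect_equal(opacityTimeCourse(d, t = 0), 0.1)

  noEdta <- disintegrationParams(kRise = 0.02)
  expect_equal(opacityTimeCourse(noEdta, t = 1e6),
               noEdta@plateauOpacity, tolerance = 1e-8)

  # half-life identity: one decay half-life after EDTA the excess over
  # baseline has halved
  oE <- opacityTimeCourse(d, t = 300)
  oHalf <- opacityTimeCourse(d, t = 300 + log(2) / d@kDecay)
  expect_equal(oHalf, 0.1 + (oE - 0.1) / 2)

  # continuity at the EDTA addition time
  expect_equal(opacityTimeCourse(d, t = 300 - 1e-9),
               opacityTimeCourse(d, t = 300 + 1e-9), tolerance = 1e-6)

  # non-decreasing before EDTA
  tt <- seq(0, 299, by = 10)
  expect_true(all(diff(opacityTimeCourse(d, t = tt)) >= 0))
})

test_that("rendering matches the disk + blur + noise + quantize contract", {
  cam0 <- smallCam(noiseSigma = 0, blurRadius = 0)

  # opacity 0 on a zero background: nothing but background
  f0 <- renderFrame(smallScene(opacity = 0, backgroundLevel = 13), cam0)
  expect_true(all(framePixels(f0) == 13))

  # opacity 1, background 0: a perfect 255 disk on black
  f1 <- renderFrame(smallScene(opacity = 1, backgroundLevel = 0), cam0)
  g1 <- toGray(f1)
  disk <- trueDiskMask(320, 240, 40)
  expect_true(all(g1[disk] == 255))
  expect_true(all(g1[!disk] == 0))

  # noisy disk mean sits on the continuous level (sampling distribution)
  camN <- smallCam(noiseSigma = 5, blurRadius = 0, seed = 21)
  fN <- renderFrame(smallScene(opacity = 0.5, backgroundLevel = 0), camN)
  m <- mean(toGray(fN)[disk])
  expect_lt(abs(m - 127.5), 3 * 5 / sqrt(sum(disk)))

  # a bead that does not fit is a render error
  expect_error(renderFrame(wellScene(radius = 300), smallCam()),
               "render error")

  # determinism: equal seeds give bit-identical frames
  expect_identical(framePixels(renderFrame(smallScene(), smallCam(seed = 5))),
                   framePixels(renderFrame(smallScene(), smallCam(seed = 5))))
  expect_false(identical(
    framePixels(renderFrame(smallScene(), smallCam(seed = 5))),
    framePixels(renderFrame(smallScene(), smallCam(seed = 6)))))
})

test_that("noise-free disk means are strictly ordered with opacity", {
  cam <- smallCam(noiseSigma = 0, blurRadius = 1)
  disk <- trueDiskMask(320, 240, 40)
  means <- vapply(seq(0.1, 1, by = 0.1), function(o)
    mean(toGray(renderFrame(smallScene(opacity = o), cam))[disk]),
    numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("the simulated screen covers the 4 x 6 grid with truth attached", {
  scr <- simulateScreen(cam = smallCam(seed = 2), scene = smallScene())
  expect_identical(length(scr$frames), 24L)
  expect_identical(nrow(scr$truth), 24L)

  # conservation of truth: recorded opacity equals the forward model
  recomputed <- vapply(seq_len(24), function(i) opacityFromConcentrations(
    gelationParams(alginatePct = scr$truth$alginate[i],
                   cacl2Pct = scr$truth$cacl2[i])), numeric(1))
  expect_equal(scr$truth$opacity, recomputed)

  # per-alginate-row the true opacity peaks at an interior CaCl2 value
  for (alg in unique(scr$truth$alginate)) {
    row <- scr$truth[scr$truth$alginate == alg, ]
    row <- row[order(row$cacl2), ]
    peak <- which.max(row$opacity)
    expect_gt(peak, 1)
    expect_lt(peak, nrow(row))
  }

  one <- simulateScreen(1.5, 1.0, cam = smallCam(), scene = smallScene())
  expect_identical(length(one$frames), 1L)
})

test_that("time-lapse simulation is reproducible and tracks the truth", {
  d <- disintegrationParams(tEdta = 600)
  pre <- simulateTimelapse(d, c(20, 40, 60, 300), smallCam(),
                           smallScene())
  expect_true(all(diff(pre$truth$opacity) >= 0))

  empty <- simulateTimelapse(d, numeric(0), smallCam(), smallScene())
  expect_identical(length(empty$frames), 0L)

  a <- simulateTimelapse(d, c(10, 20, 30), smallCam(seed = 4), smallScene())
  b <- simulateTimelapse(d, c(10, 20, 30), smallCam(seed = 4), smallScene())
  for (i in 1:3)
    expect_identical(framePixels(a$frames[[i]]), framePixels(b$frames[[i]]))
  expect_error(simulateTimelapse(d, c(10, 10), smallCam(), smallScene()),
               "strictly increasing")
})
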