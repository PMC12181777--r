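test_that("grayscale conversion applies the documented luminance weights", {
  # pure gray input is unchanged
  g <- matrix(77L, 10, 12)
  fr <- frame(array(g, dim = c(10, 12, 3)))
  expect_identical(toGray(fr), g)

  zero <- frame(array(0L, dim = c(4, 4, 3)))
  expect_true(all(toGray(zero) == 0L))

  # hand-computed 2 x 2 example with 0.299/0.587/0.114 weights
  px <- array(0L, dim = c(2, 2, 3))
  px[1, 1, ] <- c(10L, 20L, 30L)    # 2.99 + 11.74 + 3.42  = 18.15 -> 18
  px[1, 2, ] <- c(100L, 150L, 200L) # 29.9 + 88.05 + 22.8  = 140.75 -> 141
  px[2, 1, ] <- c(255L, 0L, 0L)     # 76.245 -> 76
  px[2, 2, ] <- c(0L, 0L, 255L)     # 29.07 -> 29
  expect_identical(toGray(frame(px)),
                   matrix(c(18L, 76L, 141L, 29L), 2, 2))

  expect_error(toGray("not a frame"), "format error")
})

test_that("histogram equalization follows the cumulative-histogram mapping", {
  # constant image: degenerate histogram, returned unchanged
  const <- matrix(42L, 8, 8)
  expect_identical(enhanceContrast(const), const)

  # two-level image {10 on 25 %, 20 on 75 %}: F(10) = 0.25 = Fmin -> 0,
  # F(20) = 1 -> 255
  img <- matrix(20L, 10, 10)
  img[1:25] <- 10L
  out <- enhanceContrast(img)
  expect_identical(sort(unique(as.vector(out))), c(0L, 255L))
  expect_true(all(out[img == 10L] == 0L))
  expect_true(all(out[img == 20L] == 255L))

  # low-contrast two-mode histogram: separation expands to >= 64 levels
  faint <- matrix(8L, 20, 20)
  faint[8:13, 8:13] <- 20L
  eq <- enhanceContrast(faint)
  expect_gte(mean(eq[faint == 20L]) - mean(eq[faint == 8L]), 64)

  # rank order preserved and dynamic range never shrinks (random images)
  set.seed(3)
  for (i in 1:10) {
    m <- matrix(sample(0:255, 400, replace = TRUE,
                       prob = dexp(0:255, 1 / 30)), 20, 20)
    e <- enhanceContrast(m)
    lv <- sort(unique(as.vector(m)))
    expect_true(!is.unsorted(e[match(lv, m)]))
    expect_gte(diff(range(e)), diff(range(m)))
  }
})

test_that("segmentation recovers clean beads and reports absence honestly", {
  cam0 <- smallCam(noiseSigma = 0, blurRadius = 0)
  fr <- renderFrame(smallScene(opacity = 0.8, backgroundLevel = 0), cam0)
  mask <- segmentBead(fr)
  expect_true(mask@found)
  expect_gte(iou(mask@mask, trueDiskMask(320, 240, 40)), 0.98)
  expect_identical(mask@area, sum(mask@mask))

  blank <- renderFrame(smallScene(beadPresent = FALSE), smallCam(seed = 8))
  expect_false(segmentBead(blank)@found)
})

test_that("equalization is what rescues faint transparent beads", {
  cam <- smallCam(noiseSigma = 4, blurRadius = 1, seed = 42)
  faint <- renderFrame(smallScene(opacity = 0.1), cam)
  expect_false(segmentBead(faint, segmentationConfig(equalize = "never"))@found)
  expect_true(segmentBead(faint, segmentationConfig(equalize = "auto"))@found)

  # reported intensities are invariant to equalization when masks agree
  bright <- renderFrame(smallScene(opacity = 0.8), smallCam(seed = 2))
  mNever <- segmentBead(bright, segmentationConfig(equalize = "never"))
  mAlways <- segmentBead(bright, segmentationConfig(equalize = "always"))
  if (identical(mNever@mask, mAlways@mask))
    expect_identical(measureIntensity(bright, mNever),
                     measureIntensity(bright, mAlways))
})

test_that("fixed-threshold segmentation equals the flood-fill reference on small frames", {
  cfg <- segmentationConfig(equalize = "never", thresholdMethod = "fixed",
                            fixedThreshold = 100, minArea = 1,
                            morphRadius = 0L, minContrast = 0)
  set.seed(5)
  for (i in 1:15) {
    g <- matrix(sample(c(0L, 60L, 160L, 220L), 32 * 32, replace = TRUE,
                       prob = c(0.7, 0.1, 0.1, 0.1)), 32, 32)
    fr <- frame(array(g, dim = c(32, 32, 3)))
    got <- segmentBead(fr, cfg)
    ref <- refSegment(g, 100)
    if (is.null(ref)) {
      expect_false(got@found)
    } else {
      expect_true(got@found)
      expect_identical(got@mask, ref)
    }
  }
})

test_that("intensity statistics are exact on uniform disks and unbiased under noise", {
  cam0 <- smallCam(noiseSigma = 0, blurRadius = 0)
  fr <- renderFrame(smallScene(opacity = 100 / 255, backgroundLevel = 0),
                    cam0)
  mask <- segmentBead(fr)
  res <- measureIntensity(fr, mask)
  expect_equal(res$mean, 100)
  expect_equal(res$sd, 0)
  expect_identical(res$nPixels, as.integer(mask@area))
  expect_equal(unlist(res[c("p5", "p25", "p50", "p75", "p95")]),
               rep(100, 5), ignore_attr = TRUE)

  camN <- smallCam(noiseSigma = 5, blurRadius = 0, seed = 13)
  frN <- renderFrame(smallScene(opacity = 200 / 255, backgroundLevel = 0),
                     camN)
  disk <- trueDiskMask(320, 240, 40)
  exact <- new("BeadMask", mask = disk, area = sum(disk),
               centroid = c(160, 120), found = TRUE)
  resN <- measureIntensity(frN, exact)
  expect_lt(abs(resN$mean - 200), 3 * 5 / sqrt(sum(disk)))

  notFound <- new("BeadMask", mask = matrix(FALSE, 240, 320), area = 0,
                  centroid = c(NA_real_, NA_real_), found = FALSE)
  expect_error(measureIntensity(frN, notFound), "no bead")
})

test_that("forward model and inverse analysis agree exactly without noise", {
  cam0 <- smallCam(noiseSigma = 0, blurRadius = 0)
  for (o in seq(0.1, 1, by = 0.1)) {
    fr <- renderFrame(smallScene(opacity = o, backgroundLevel = 0), cam0)
    mask <- segmentBead(fr)
    expect_true(mask@found, info = paste("opacity", o))
    expect_equal(measureIntensity(fr, mask)$mean, round(o * 255),
                 info = paste("opacity", o))
  }
})

test_that("measured intensity is monotone in true opacity at fixed noise", {
  means <- vapply(seq(0.2, 1, by = 0.1), function(o) {
    fr <- renderFrame(smallScene(opacity = o),
                      smallCam(noiseSigma = 3, seed = 31))
    measureIntensity(fr, segmentBead(fr))$mean
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("screen summaries keep not-found conditions distinct from zeros", {
  one <- simulateScreen(1.5, 1.5, cam = smallCam(seed = 6),
                        scene = smallScene())
  tab <- summarizeScreen(one)
  expect_identical(nrow(tab), 1L)
  expect_true(tab$found)
  expect_gt(tab$mean, 150)

  blank <- list(truth = data.frame(alginate = 1.5, cacl2 = 0.1),
                frames = list(renderFrame(smallScene(beadPresent = FALSE),
                                          smallCam(seed = 12))))
  tabNF <- summarizeScreen(blank)
  expect_false(tabNF$found)
  expect_true(is.na(tabNF$mean))
})

test_that("time-lapse analysis recovers the generating kinetics", {
  d <- disintegrationParams(tEdta = 300, kDecay = 0.01, kRise = 0.01)
  tl <- simulateTimelapse(d, seq(0, 950, by = 50),
                          smallCam(noiseSigma = 3, blurRadius = 1,
                                   seed = 11),
                          smallScene())
  res <- analyzeTimelapse(tl)
  expect_true(res$fit@onsetFound)
  expect_lte(abs(res$fit@onsetT - 300), 50)   # within one frame interval
  expect_lt(abs(res$fit@kDecayHat / 0.01 - 1), 0.05)
  expect_true(all(res$timeSeries$found))
  expect_true(all(diff(res$timeSeries$t) > 0))

  # no EDTA, no onset
  quiet <- simulateTimelapse(disintegrationParams(), seq(0, 950, by = 50),
                             smallCam(seed = 14), smallScene())
  expect_false(analyzeTimelapse(quiet)$fit@onsetFound)

  # noise-free series reproduces the opacity -> 255 mapping within rounding
  clean <- simulateTimelapse(d, seq(0, 950, by = 50),
                             smallCam(noiseSigma = 0, blurRadius = 0),
                             smallScene(backgroundLevel = 0))
  resC <- analyzeTimelapse(clean)
  expect_true(all(abs(resC$timeSeries$mean -
                        round(clean$truth$opacity * 255)) <= 0.5))

  expect_error(fitDisintegration(c(0, 10, 20), c(1, 2, 3)), "4 time points")
})
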