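#' Construct gelation opacity parameters
#'
#' Defaults place the opacity peak at crosslinker-to-polymer ratio
#' `R = 1`: at 1.5 % w/v alginate the most opaque beads form near 1.5 % w/v
#' CaCl2, with transparency returning at 5 % and 10 %.
#'
#' @param alginatePct,cacl2Pct concentrations, % w/v.
#' @param rCrit ratio at peak opacity.
#' @param riseScale,fallScale bump widths on the log-R axis below/above
#'   `rCrit`.
#' @param peakOpacity maximum opacity.
#' @param visibilityFloor opacity below which a bead is difficult to
#'   visualize without contrast enhancement.
#' @return a [GelationParams-class].
#' @export
gelationParams <- function(alginatePct = 1.5, cacl2Pct = 1.0, rCrit = 1.0,
                           riseScale = 0.8, fallScale = 1.0,
                           peakOpacity = 0.9, visibilityFloor = 0.15) {
  new("GelationParams", alginatePct = alginatePct, cacl2Pct = cacl2Pct,
      rCrit = rCrit, riseScale = riseScale, fallScale = fallScale,
      peakOpacity = peakOpacity, visibilityFloor = visibilityFloor)
}

#' Bead opacity from formulation concentrations
#'
#' Phenomenological unimodal model in the crosslinker-to-polymer ratio
#' `R = cacl2Pct / alginatePct`: an asymmetric log-normal bump
#' `peakOpacity * exp(-log(R / rCrit)^2 / (2 s^2))` with width
#' `s = riseScale` below `rCrit` and `s = fallScale` above.  Opacity is
#' strictly increasing in `R` below the critical ratio, peaks exactly at
#' `rCrit`, and strictly decreases beyond it — too little calcium leaves
#' the network too sparse to scatter light, while excess calcium yields
#' weaker, more transparent gels.
#'
#' @param g a [GelationParams-class]; both concentrations must be > 0.
#' @return opacity in `[0, 1]`.
#' @examples
#' opacityFromConcentrations(gelationParams(alginatePct = 1.5, cacl2Pct = 1.5))
#' @export
opacityFromConcentrations <- function(g) {
  if (g@alginatePct <= 0 || g@cacl2Pct <= 0)
    stop("domain error: concentrations must be > 0", call. = FALSE)
  r <- g@cacl2Pct / g@alginatePct
  s <- if (r < g@rCrit) g@riseScale else g@fallScale
  g@peakOpacity * exp(-log(r / g@rCrit)^2 / (2 * s^2))
}

#' Construct disintegration kinetics parameters
#'
#' Defaults describe the monitored formulation (1.5 % alginate, 1.0 %
#' calcium): the bead matures from a faint baseline toward its plateau
#' opacity over minutes; EDTA chelation, when scheduled, dissolves the
#' network exponentially.
#'
#' @param tEdta EDTA addition time, s (`NA` = never added).
#' @param kDecay post-EDTA decay rate, 1/s.
#' @param kRise pre-EDTA maturation rate, 1/s.
#' @param baselineOpacity,plateauOpacity opacity range of the time course.
#' @return a [DisintegrationParams-class].
#' @export
disintegrationParams <- function(tEdta = NA_real_, kDecay = 0.01,
                                 kRise = 0.01, baselineOpacity = 0.1,
                                 plateauOpacity = 0.85) {
  new("DisintegrationParams", tEdta = as.numeric(tEdta), kDecay = kDecay,
      kRise = kRise, baselineOpacity = baselineOpacity,
      plateauOpacity = plateauOpacity)
}

#' Ground-truth opacity time course
#'
#' Before `tEdta`: a saturating rise from `baselineOpacity` toward `base`
#' with rate `kRise` (non-decreasing).  From `tEdta` on: exponential
#' relaxation toward `baselineOpacity` with rate `kDecay`, continuous at
#' the change point.
#'
#' @param d a [DisintegrationParams-class].
#' @param base opacity the well would plateau at; defaults to the
#'   parameter set's `plateauOpacity`, but can be supplied from
#'   [opacityFromConcentrations()] to couple the two models.
#' @param t time(s) in seconds, vectorized.
#' @return opacity value(s) in `[0, 1]`.
#' @export
opacityTimeCourse <- function(d, base = d@plateauOpacity, t) {
  stopifnot(all(t >= 0))
  b <- d@baselineOpacity
  rise <- function(tt) b + (base - b) * (1 - exp(-d@kRise * tt))
  if (is.na(d@tEdta)) return(rise(t))
  oEdta <- rise(d@tEdta)
  ifelse(t < d@tEdta, rise(t),
         b + (oEdta - b) * exp(-d@kDecay * (t - d@tEdta)))
}

#' Construct a well scene
#'
#' @param beadPresent logical.
#' @param opacity bead opacity in `[0, 1]`.
#' @param radius bead radius, px.
#' @param centerOffset (dx, dy) px from the image centre.
#' @param backgroundLevel dark background grey level (default 6).
#' @return a [WellScene-class].
#' @export
wellScene <- function(beadPresent = TRUE, opacity = 0.7, radius = 80,
                      centerOffset = c(0, 0), backgroundLevel = 6) {
  new("WellScene", beadPresent = beadPresent, opacity = opacity,
      radius = radius, centerOffset = as.numeric(centerOffset),
      backgroundLevel = backgroundLevel)
}

#' Construct a camera model
#'
#' @param width,height resolution, px (default 640 x 480).
#' @param noiseSigma additive Gaussian noise sd, intensity units.
#' @param blurRadius disk blur kernel radius, px (0 disables).
#' @param seed integer seed; equal seeds render bit-identical frames.
#' @return a [CameraModel-class].
#' @export
cameraModel <- function(width = 640, height = 480, noiseSigma = 3,
                        blurRadius = 1, seed = 1L) {
  new("CameraModel", width = as.integer(width), height = as.integer(height),
      noiseSigma = noiseSigma, blurRadius = blurRadius,
      seed = as.integer(seed))
}

#' Wrap a pixel array as a Frame
#'
#' @param pixels integer array `height x width x 3` (0-255), or a matrix
#'   replicated across the three channels.
#' @return a [Frame-class].
#' @export
frame <- function(pixels) {
  if (is.matrix(pixels))
    pixels <- array(pixels, dim = c(nrow(pixels), ncol(pixels), 3))
  storage.mode(pixels) <- "integer"
  new("Frame", pixels = pixels)
}

#' Render a well scene to an 8-bit RGB frame
#'
#' Forward camera model: pixels inside the bead disk take the continuous
#' level `background + opacity * (255 - background)`, outside the
#' background level; the image is then optionally blurred with a
#' normalized disk kernel, zero-mean Gaussian noise is added from the
#' camera's seed, and values are clipped to 0-255 and quantized to 8 bits.
#' Quantization happens once at the end, so a noise-free render has disk
#' level `round(background + opacity * (255 - background))` while noisy
#' disk means stay centred on the continuous level.  The same luminance
#' noise field is applied to all three channels.  Rendering is
#' bit-identical for equal seeds and leaves the caller's RNG untouched.
#'
#' @param scene a [WellScene-class]; the bead must fit inside the frame.
#' @param cam a [CameraModel-class].
#' @return a [Frame-class].
#' @examples
#' fr <- renderFrame(wellScene(opacity = 0.8), cameraModel(noiseSigma = 0))
#' @export
renderFrame <- function(scene, cam) {
  w <- cam@width; h <- cam@height
  img <- matrix(as.numeric(scene@backgroundLevel), nrow = h, ncol = w)
  if (scene@beadPresent) {
    cx <- w / 2 + scene@centerOffset[1]
    cy <- h / 2 + scene@centerOffset[2]
    r <- scene@radius
    if (cx - r < 0 || cx + r > w || cy - r < 0 || cy + r > h)
      stop("render error: bead does not fit within the frame", call. = FALSE)
    level <- scene@backgroundLevel +
      scene@opacity * (255 - scene@backgroundLevel)
    # pixel centres at (col - 0.5, row - 0.5)
    dx2 <- (seq_len(w) - 0.5 - cx)^2
    dy2 <- (seq_len(h) - 0.5 - cy)^2
    disk <- outer(dy2, dx2, `+`) <= r^2
    img[disk] <- level
  }
  if (cam@blurRadius > 0) {
    br <- makeBrush(2L * as.integer(ceiling(cam@blurRadius)) + 1L, "disc")
    img <- filter2(img, br / sum(br))
  }
  if (cam@noiseSigma > 0)
    img <- img + withSeed(cam@seed, rnorm(length(img), 0, cam@noiseSigma))
  img <- matrix(as.numeric(img), nrow = h, ncol = w)  # drop Image class
  img[img < 0] <- 0
  img[img > 255] <- 255
  frame(round(img))
}

# per-frame seed stream: deterministic offsets from the camera seed,
# kept well below .Machine$integer.max
.derivedSeed <- function(seed, i) as.integer((seed + 7919 * i) %% 2147483647)

#' Simulate the concentration screen
#'
#' Forward model of the combinatorial screen: for every (alginate, CaCl2)
#' pair, bead opacity at the capture time point is drawn from
#' [opacityFromConcentrations()] and rendered.  The default grids are the
#' screen's 4 x 6 design: alginate 0.5-2.0 % by four, CaCl2 0.1-10 % by
#' six.  Ground truth is retained alongside every frame.
#'
#' @param alginateList,cacl2List concentration grids, % w/v.
#' @param g a [GelationParams-class] template (its concentrations are
#'   overwritten per cell).
#' @param cam a [CameraModel-class]; each cell uses a deterministic
#'   per-cell seed derived from `cam@seed`.
#' @param scene a [WellScene-class] template (opacity overwritten).
#' @param tCapture capture time after combination, s (default 30 min);
#'   recorded in the truth table — the gelation model is the end-point
#'   opacity at this time.
#' @return list with `truth` (data.frame `alginate`, `cacl2`, `R`,
#'   `opacity`, `radius`, `seed`, `tCapture`) and `frames` (list of
#'   [Frame-class], row-matched to `truth`).
#' @export
simulateScreen <- function(alginateList = c(0.5, 1.0, 1.5, 2.0),
                           cacl2List = c(0.1, 0.5, 1.0, 1.5, 5.0, 10.0),
                           g = gelationParams(), cam = cameraModel(),
                           scene = wellScene(), tCapture = 1800) {
  stopifnot(length(alginateList) > 0, length(cacl2List) > 0)
  grid <- expand.grid(cacl2 = cacl2List, alginate = alginateList)
  frames <- vector("list", nrow(grid))
  truth <- data.frame(alginate = grid$alginate, cacl2 = grid$cacl2,
                      R = grid$cacl2 / grid$alginate,
                      opacity = NA_real_, radius = scene@radius,
                      seed = NA_integer_, tCapture = tCapture)
  for (i in seq_len(nrow(grid))) {
    gi <- g
    gi@alginatePct <- grid$alginate[i]
    gi@cacl2Pct <- grid$cacl2[i]
    op <- opacityFromConcentrations(gi)
    sc <- scene; sc@opacity <- op
    ci <- cam; ci@seed <- .derivedSeed(cam@seed, i)
    frames[[i]] <- renderFrame(sc, ci)
    truth$opacity[i] <- op
    truth$seed[i] <- ci@seed
  }
  list(truth = truth, frames = frames)
}

#' Simulate a disintegration time-lapse
#'
#' Renders one well at each scheduled time with ground-truth opacity from
#' [opacityTimeCourse()].  The per-frame noise seeds are derived
#' deterministically from `cam@seed`, so a rerun with the same seed is
#' bit-identical.
#'
#' @param d a [DisintegrationParams-class].
#' @param schedule strictly increasing capture times, s.
#' @param cam a [CameraModel-class].
#' @param scene a [WellScene-class] template.
#' @param base plateau opacity passed to [opacityTimeCourse()].
#' @return list with `truth` (data.frame `t`, `opacity`, `seed`) and
#'   `frames` (row-matched list of [Frame-class]).
#' @export
simulateTimelapse <- function(d, schedule, cam = cameraModel(),
                              scene = wellScene(),
                              base = d@plateauOpacity) {
  if (length(schedule) == 0L)
    return(list(truth = data.frame(t = numeric(), opacity = numeric(),
                                   seed = integer()),
                frames = list()))
  if (length(schedule) > 1L && any(diff(schedule) <= 0))
    stop("schedule must be strictly increasing", call. = FALSE)
  ops <- opacityTimeCourse(d, base, schedule)
  frames <- vector("list", length(schedule))
  seeds <- integer(length(schedule))
  for (i in seq_along(schedule)) {
    sc <- scene; sc@opacity <- ops[i]
    ci <- cam; ci@seed <- .derivedSeed(cam@seed, i)
    frames[[i]] <- renderFrame(sc, ci)
    seeds[i] <- ci@seed
  }
  list(truth = data.frame(t = schedule, opacity = ops, seed = seeds),
       frames = frames)
}
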