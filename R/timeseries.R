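#' Summarize a concentration screen
#'
#' Runs the full inverse analysis over a screen grid: per frame, bead
#' isolation then intensity measurement.  Conditions where no bead is
#' found are reported as not-found rather than zero.
#'
#' @param screen list with `truth` (data.frame holding at least `alginate`
#'   and `cacl2`) and `frames` (row-matched list of [Frame-class]), as
#'   returned by [simulateScreen()].
#' @param cfg a [SegmentationConfig-class].
#' @return data.frame: one row per condition with `alginate`, `cacl2`,
#'   `found`, and the [measureIntensity()] columns (`NA` when not found).
#' @export
summarizeScreen <- function(screen, cfg = segmentationConfig()) {
  truth <- screen$truth
  stopifnot(nrow(truth) >= 1L, length(screen$frames) == nrow(truth))
  na <- data.frame(mean = NA_real_, sd = NA_real_, nPixels = NA_integer_,
                   p5 = NA_real_, p25 = NA_real_, p50 = NA_real_,
                   p75 = NA_real_, p95 = NA_real_)
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    mask <- segmentBead(screen$frames[[i]], cfg)
    stats <- if (mask@found) measureIntensity(screen$frames[[i]], mask) else na
    cbind(data.frame(alginate = truth$alginate[i], cacl2 = truth$cacl2[i],
                     found = mask@found), stats)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# saturating-rise fit used for the pre-onset segment and the no-onset
# reference model; falls back to a straight line when the nonlinear fit
# cannot converge (few points, flat series)
.fitRise <- function(t, y) {
  rss <- function(fit) sum(resid(fit)^2)
  fit <- tryCatch({
    k0 <- max(1 / max(diff(range(t)), 1), 1e-4)
    nlsLM(y ~ a + b * (1 - exp(-k * t)),
          start = list(a = min(y), b = diff(range(y)), k = k0),
          control = minpack.lm::nls.lm.control(maxiter = 200))
  }, error = function(e) NULL)
  lfit <- lm(y ~ t)
  if (is.null(fit) || !is.finite(rss(fit)) || rss(fit) > rss(lfit))
    list(rss = rss(lfit)) else list(rss = rss(fit))
}

# exponential relaxation y = b + A exp(-k (t - t0)) fitted from t0 on
.fitDecay <- function(t, y, t0) {
  tryCatch({
    b0 <- min(y)
    a0 <- max(y[1] - b0, 1)
    k0 <- 1 / max(diff(range(t)), 1)
    fit <- nlsLM(y ~ b + A * exp(-k * (t - t0)),
                 start = list(b = b0, A = a0, k = k0),
                 lower = c(b = 0, A = 0, k = 1e-6),
                 control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- coef(fit)
    list(rss = sum(resid(fit)^2), k = unname(cf["k"]), b = unname(cf["b"]),
         A = unname(cf["A"]))
  }, error = function(e) NULL)
}

#' Fit disintegration kinetics to an intensity time series
#'
#' Change-point detection by exhaustive two-segment scan (the series are
#' short): every observed time point is tried as the disintegration onset;
#' the points before it are fitted with a saturating rise, the points from
#' it on with an exponential relaxation `b + A exp(-k (t - onset))`, and
#' the onset minimizing the total residual sum of squares wins.  The onset
#' is accepted only when the two-segment fit improves on the best
#' single-segment (no-onset) fit by at least `minImprovement` and the
#' fitted decay amplitude `A` exceeds `minDrop` intensity levels —
#' otherwise the series is reported as having no detectable onset.
#'
#' @param t observation times, s (>= 4 points, strictly increasing).
#' @param y mean intensities, 0-255 scale.
#' @param minImprovement accept the split only if its total RSS is below
#'   this fraction of the single-segment RSS (default 0.5).
#' @param minDrop minimum fitted decay amplitude, intensity levels.
#' @return a [DisintegrationFit-class].
#' @export
fitDisintegration <- function(t, y, minImprovement = 0.5, minDrop = 10) {
  if (length(t) < 4L) stop("fit error: need at least 4 time points",
                           call. = FALSE)
  if (any(diff(t) <= 0)) stop("fit error: times must be strictly increasing",
                              call. = FALSE)
  n <- length(t)
  rss0 <- .fitRise(t, y)$rss

  best <- NULL
  for (s in 3:(n - 2)) {   # need >= 3 points on each side for stable fits
    pre <- .fitRise(t[1:s], y[1:s])
    post <- .fitDecay(t[s:n], y[s:n], t[s])
    if (is.null(post)) next
    total <- pre$rss + post$rss
    if (is.null(best) || total < best$rss)
      best <- list(rss = total, onset = t[s], k = post$k, b = post$b,
                   A = post$A)
  }

  noOnset <- new("DisintegrationFit", onsetT = NA_real_,
                 kDecayHat = NA_real_, baselineHat = NA_real_,
                 rss = rss0, onsetFound = FALSE)
  if (is.null(best)) return(noOnset)
  improved <- best$rss < minImprovement * rss0
  if (!improved || best$A < minDrop) return(noOnset)
  new("DisintegrationFit", onsetT = best$onset, kDecayHat = best$k,
      baselineHat = best$b, rss = best$rss, onsetFound = TRUE)
}

#' Analyze a well time-lapse end to end
#'
#' Segments and measures every frame into a well time series, then fits
#' the disintegration kinetics to the frames where a bead was found.
#'
#' @param series list with `truth` (data.frame holding `t`) and `frames`
#'   (row-matched list of [Frame-class]), as from [simulateTimelapse()].
#' @param cfg a [SegmentationConfig-class].
#' @param minImprovement,minDrop change-point acceptance settings, see
#'   [fitDisintegration()].
#' @return list with `timeSeries` (data.frame `t`, `found`, plus the
#'   [measureIntensity()] columns) and `fit` (a
#'   [DisintegrationFit-class]).
#' @export
analyzeTimelapse <- function(series, cfg = segmentationConfig(),
                             minImprovement = 0.5, minDrop = 10) {
  tvec <- series$truth$t
  if (length(tvec) < 4L)
    stop("fit error: need at least 4 time points", call. = FALSE)
  na <- data.frame(mean = NA_real_, sd = NA_real_, nPixels = NA_integer_,
                   p5 = NA_real_, p25 = NA_real_, p50 = NA_real_,
                   p75 = NA_real_, p95 = NA_real_)
  rows <- lapply(seq_along(tvec), function(i) {
    mask <- segmentBead(series$frames[[i]], cfg)
    stats <- if (mask@found) measureIntensity(series$frames[[i]], mask)
             else na
    cbind(data.frame(t = tvec[i], found = mask@found), stats)
  })
  ts <- do.call(rbind, rows)
  rownames(ts) <- NULL
  okRows <- ts[ts$found, , drop = FALSE]
  if (nrow(okRows) == 0L)
    stop("analysis error: no bead found in any frame", call. = FALSE)
  if (nrow(okRows) < 4L)
    stop("fit error: fewer than 4 usable time points", call. = FALSE)
  fit <- fitDisintegration(okRows$t, okRows$mean,
                           minImprovement = minImprovement,
                           minDrop = minDrop)
  list(timeSeries = ts, fit = fit)
}
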