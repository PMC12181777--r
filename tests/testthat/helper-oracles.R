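# Independent reference implementations used as oracles.  These stay
# deliberately naive (queues, flood fill, exhaustive loops) and share no
# code with the package internals they check.

# true disk mask for a rendered scene, matching the renderer's pixel-centre
# convention
trueDiskMask <- function(width, height, radius, offset = c(0, 0)) {
  cx <- width / 2 + offset[1]
  cy <- height / 2 + offset[2]
  outer((seq_len(height) - 0.5 - cy)^2,
        (seq_len(width) - 0.5 - cx)^2, `+`) <= radius^2
}

iou <- function(a, b) sum(a & b) / sum(a | b)

# discrete-time single-camera queue: requests arrive at each interval for
# every well in order; the camera serves FIFO, one capture per perWellTime
refSchedule <- function(wells, intervals, perWellTime) {
  requests <- data.frame(
    requested = rep(intervals, each = length(wells)),
    well = rep(wells, times = length(intervals)))
  realized <- numeric(nrow(requests))
  freeAt <- -Inf
  for (i in seq_len(nrow(requests))) {
    start <- max(requests$requested[i], freeAt)
    realized[i] <- start
    freeAt <- start + perWellTime
  }
  cbind(requests, realized = realized)
}

# exhaustive pixelwise threshold + 4-connected flood fill + selection of the
# component nearest the image centre
refSegment <- function(gray, threshold, minArea = 1) {
  fg <- gray > threshold
  labels <- matrix(0L, nrow(fg), ncol(fg))
  nextLab <- 0L
  for (i in seq_len(nrow(fg))) for (j in seq_len(ncol(fg))) {
    if (!fg[i, j] || labels[i, j] > 0L) next
    nextLab <- nextLab + 1L
    queue <- list(c(i, j))
    labels[i, j] <- nextLab
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        q <- p + d
        if (q[1] < 1 || q[1] > nrow(fg) || q[2] < 1 || q[2] > ncol(fg)) next
        if (fg[q[1], q[2]] && labels[q[1], q[2]] == 0L) {
          labels[q[1], q[2]] <- nextLab
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
  }
  if (nextLab == 0L) return(NULL)
  comps <- lapply(seq_len(nextLab), function(k) which(labels == k))
  comps <- comps[vapply(comps, length, integer(1)) >= minArea]
  if (!length(comps)) return(NULL)
  ctr <- c(nrow(fg) / 2, ncol(fg) / 2)
  d2 <- vapply(comps, function(idx) {
    rc <- arrayInd(idx, dim(fg))
    sum((colMeans(rc) - ctr)^2)
  }, numeric(1))
  out <- matrix(FALSE, nrow(fg), ncol(fg))
  out[comps[[which.min(d2)]]] <- TRUE
  out
}

# small frames keep the pixel loops cheap
smallCam <- function(...) cameraModel(width = 320, height = 240, ...)
smallScene <- function(...) wellScene(radius = 40, ...)
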