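# S4 containers for the virtual deck, the forward imaging model and the
# inverse analysis.  Tabular results (plans, event logs, screen summaries,
# time series) are plain data.frames.

.LABWARE_KINDS <- c("microplate", "tip_rack", "vial_rack", "tool_holder")

# one deck slot footprint; labware must fit inside it
.SLOT_LENGTH <- 128
.SLOT_WIDTH <- 85
.N_SLOTS <- 11L

#' Labware geometry
#'
#' Geometry of one piece of labware: a microplate, tip rack, vial rack or the
#' holder for the camera pick-and-place tool.  Coordinates are millimetres
#' from the labware front-left corner; wells are addressed `A1` style with
#' `A` the first row and columns 1-based.
#'
#' @slot name text identifier (load name).
#' @slot kind one of `"microplate"`, `"tip_rack"`, `"vial_rack"`,
#'   `"tool_holder"`.
#' @slot rows,cols grid dimensions; well count is `rows * cols`.
#' @slot wellPitch centre-to-centre spacing in mm (square grid).
#' @slot a1Offset numeric length-2, (x, y) mm of well A1 from the corner.
#' @slot wellDepth well depth in mm (used only by the collision check).
#' @slot wellVolume nominal well volume in microlitres.
#' @slot footprint numeric length-2, (length, width) mm; must fit a deck
#'   slot (128 x 85 mm).
#' @seealso [labwareDefinition()], [loadLabwareDefinition()]
#' @exportClass LabwareDefinition
setClass("LabwareDefinition",
  representation(
    name = "character", kind = "character",
    rows = "integer", cols = "integer",
    wellPitch = "numeric", a1Offset = "numeric",
    wellDepth = "numeric", wellVolume = "numeric",
    footprint = "numeric"))

setValidity("LabwareDefinition", function(object) {
  msg <- character()
  if (length(object@kind) != 1L || !object@kind %in% .LABWARE_KINDS)
    msg <- c(msg, sprintf("kind must be one of %s",
                          paste(.LABWARE_KINDS, collapse = ", ")))
  if (length(object@rows) != 1L || is.na(object@rows) || object@rows < 1L)
    msg <- c(msg, "rows must be >= 1")
  if (length(object@cols) != 1L || is.na(object@cols) || object@cols < 1L)
    msg <- c(msg, "cols must be >= 1")
  if (length(object@a1Offset) != 2L)
    msg <- c(msg, "a1Offset must have length 2")
  if (length(object@footprint) != 2L)
    msg <- c(msg, "footprint must have length 2")
  else if (object@footprint[1] > .SLOT_LENGTH ||
           object@footprint[2] > .SLOT_WIDTH)
    msg <- c(msg, sprintf(
      "footprint %.1f x %.1f mm exceeds the %d x %d mm deck slot",
      object@footprint[1], object@footprint[2], .SLOT_LENGTH, .SLOT_WIDTH))
  if (length(object@wellPitch) != 1L || object@wellPitch <= 0)
    msg <- c(msg, "wellPitch must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Deck layout
#'
#' Occupancy of the handler's 11 deck slots.  Each slot holds at most one
#' [LabwareDefinition-class]; empty slots are `NULL`.
#'
#' @slot slots list of length 11, elements `NULL` or `LabwareDefinition`.
#' @seealso [deckLayout()], [defaultDeck()], [deckSlot()]
#' @exportClass DeckLayout
setClass("DeckLayout", representation(slots = "list"))

setValidity("DeckLayout", function(object) {
  if (length(object@slots) != .N_SLOTS)
    return(sprintf("slots list must have length %d", .N_SLOTS))
  ok <- vapply(object@slots, function(s)
    is.null(s) || is(s, "LabwareDefinition"), logical(1))
  if (!all(ok)) return("slots must be NULL or LabwareDefinition")
  TRUE
})

#' An 8-bit RGB frame
#'
#' A captured or rendered image: integer array of dimension
#' `height x width x 3`, values 0-255.  Channel order is R, G, B.
#'
#' @slot pixels integer array `c(height, width, 3)` with values in 0-255.
#' @seealso [frame()], [renderFrame()], [capture()]
#' @exportClass Frame
setClass("Frame", representation(pixels = "array"))

setValidity("Frame", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L)
    return("pixels must be a height x width x 3 array")
  v <- object@pixels
  if (anyNA(v) || min(v) < 0 || max(v) > 255)
    return("pixel values must be in 0..255")
  if (any(v != round(v)))
    return("pixel values must be integers (8-bit)")
  TRUE
})

#' Gelation opacity parameters
#'
#' Phenomenological model of bead opacity as a function of the
#' crosslinker-to-polymer ratio `R = cacl2Pct / alginatePct`.  Opacity is a
#' unimodal bump in `R`, peaking at `rCrit`: crosslinking efficiency rises
#' with calcium up to a critical ratio and the gel becomes more transparent
#' beyond it.
#'
#' @slot alginatePct,cacl2Pct concentrations in % w/v (must be > 0).
#' @slot rCrit ratio at peak opacity (dimensionless).
#' @slot riseScale,fallScale widths of the bump on the log-R axis, below and
#'   above `rCrit` respectively.
#' @slot peakOpacity maximum opacity, in `[0, 1]`.
#' @slot visibilityFloor opacity below which a bead is considered difficult
#'   to visualize without contrast enhancement.
#' @seealso [gelationParams()], [opacityFromConcentrations()]
#' @exportClass GelationParams
setClass("GelationParams",
  representation(
    alginatePct = "numeric", cacl2Pct = "numeric",
    rCrit = "numeric", riseScale = "numeric", fallScale = "numeric",
    peakOpacity = "numeric", visibilityFloor = "numeric"))

setValidity("GelationParams", function(object) {
  msg <- character()
  if (object@rCrit <= 0) msg <- c(msg, "rCrit must be > 0")
  if (object@riseScale <= 0 || object@fallScale <= 0)
    msg <- c(msg, "riseScale and fallScale must be > 0")
  if (object@peakOpacity < 0 || object@peakOpacity > 1)
    msg <- c(msg, "peakOpacity must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Disintegration (EDTA chelation) kinetics parameters
#'
#' Ground-truth time course of bead opacity: a saturating rise from
#' `baselineOpacity` toward a plateau while the calcium-alginate network
#' matures, then, if EDTA is added at `tEdta`, an exponential relaxation
#' back toward `baselineOpacity` as chelation removes the crosslinking
#' calcium.
#'
#' @slot tEdta EDTA addition time in seconds, or `NA` for no addition.
#' @slot kDecay post-EDTA decay rate, 1/s (must be > 0 when `tEdta` is set).
#' @slot kRise pre-EDTA maturation rate, 1/s.
#' @slot baselineOpacity,plateauOpacity opacities in `[0, 1]`,
#'   `baseline <= plateau`.
#' @seealso [disintegrationParams()], [opacityTimeCourse()]
#' @exportClass DisintegrationParams
setClass("DisintegrationParams",
  representation(
    tEdta = "numeric", kDecay = "numeric", kRise = "numeric",
    baselineOpacity = "numeric", plateauOpacity = "numeric"))

setValidity("DisintegrationParams", function(object) {
  msg <- character()
  if (!is.na(object@tEdta) && object@kDecay <= 0)
    msg <- c(msg, "kDecay must be > 0 when tEdta is set")
  if (object@kRise < 0) msg <- c(msg, "kRise must be >= 0")
  rng <- c(object@baselineOpacity, object@plateauOpacity)
  if (any(rng < 0 | rng > 1))
    msg <- c(msg, "opacities must be in [0, 1]")
  if (object@baselineOpacity > object@plateauOpacity)
    msg <- c(msg, "baselineOpacity must be <= plateauOpacity")
  if (length(msg)) msg else TRUE
})

#' Ground-truth state of one well
#'
#' The physical truth behind a rendered frame: whether a bead is present,
#' its opacity, radius and position, and the dark background level.
#'
#' @slot beadPresent logical flag.
#' @slot opacity bead opacity in `[0, 1]`.
#' @slot radius bead radius in pixels.
#' @slot centerOffset numeric length-2, (dx, dy) px from the image centre.
#' @slot backgroundLevel background grey level 0-255 (near 0: wells are
#'   imaged against a black background).
#' @seealso [wellScene()], [renderFrame()]
#' @exportClass WellScene
setClass("WellScene",
  representation(
    beadPresent = "logical", opacity = "numeric", radius = "numeric",
    centerOffset = "numeric", backgroundLevel = "numeric"))

setValidity("WellScene", function(object) {
  msg <- character()
  if (object@opacity < 0 || object@opacity > 1)
    msg <- c(msg, "opacity must be in [0, 1]")
  if (object@radius <= 0) msg <- c(msg, "radius must be > 0")
  if (length(object@centerOffset) != 2L)
    msg <- c(msg, "centerOffset must have length 2")
  if (object@backgroundLevel < 0 || object@backgroundLevel > 255)
    msg <- c(msg, "backgroundLevel must be in 0..255")
  if (length(msg)) msg else TRUE
})

#' Camera model for rendering
#'
#' Resolution plus a simple optics/noise model: optional disk-kernel blur to
#' soften bead edges and additive zero-mean Gaussian noise, quantized to
#' 8 bits at the end.  Rendering with an equal seed is bit-identical.
#'
#' @slot width,height resolution in px (defaults 640 x 480).
#' @slot noiseSigma noise standard deviation in intensity units.
#' @slot blurRadius disk blur kernel radius in px (0 disables).
#' @slot seed integer RNG seed for the noise field.
#' @seealso [cameraModel()], [renderFrame()]
#' @exportClass CameraModel
setClass("CameraModel",
  representation(
    width = "integer", height = "integer",
    noiseSigma = "numeric", blurRadius = "numeric", seed = "integer"))

setValidity("CameraModel", function(object) {
  msg <- character()
  if (object@width < 1L || object@height < 1L)
    msg <- c(msg, "width and height must be >= 1")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (object@blurRadius < 0) msg <- c(msg, "blurRadius must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Segmentation configuration
#'
#' Controls the bead-isolation pipeline: grayscale conversion, optional
#' histogram equalization, thresholding, morphological cleanup, and
#' connected-component selection.
#'
#' @slot equalize `"auto"` (equalize when the grayscale dynamic range
#'   p99 - p1 falls below `contrastTrigger`), `"always"` or `"never"`.
#' @slot contrastTrigger dynamic-range threshold (levels) for auto mode.
#' @slot thresholdMethod `"otsu"` or `"fixed"`.
#' @slot fixedThreshold threshold 0-255, required iff method is `"fixed"`.
#' @slot minArea discard connected components smaller than this (px).
#' @slot morphRadius radius (px) of the disk brush used for morphological
#'   open then close; 0 disables.
#' @slot centerBias when `TRUE`, prefer the surviving component whose
#'   centroid is nearest the image centre; otherwise the largest.
#' @slot minContrast detection-significance guard: a component is accepted
#'   only if its mean level on the working (possibly equalized) image
#'   exceeds the background mean by at least this many levels.
#' @seealso [segmentationConfig()], [segmentBead()]
#' @exportClass SegmentationConfig
setClass("SegmentationConfig",
  representation(
    equalize = "character", contrastTrigger = "numeric",
    thresholdMethod = "character", fixedThreshold = "numeric",
    minArea = "numeric", morphRadius = "integer",
    centerBias = "logical", minContrast = "numeric"))

setValidity("SegmentationConfig", function(object) {
  msg <- character()
  if (!object@equalize %in% c("auto", "always", "never"))
    msg <- c(msg, "equalize must be auto, always or never")
  if (!object@thresholdMethod %in% c("otsu", "fixed"))
    msg <- c(msg, "thresholdMethod must be otsu or fixed")
  if (object@thresholdMethod == "fixed" && is.na(object@fixedThreshold))
    msg <- c(msg, "fixedThreshold is required when thresholdMethod = fixed")
  if (object@thresholdMethod == "otsu" && !is.na(object@fixedThreshold))
    msg <- c(msg, "fixedThreshold must be NA when thresholdMethod = otsu")
  if (length(msg)) msg else TRUE
})

#' Binary bead mask
#'
#' Result of [segmentBead()]: a logical matrix matching the frame, with at
#' most one connected component after selection.  Absence of a bead is a
#' result (`found = FALSE`, `area = 0`), not an error.
#'
#' @slot mask logical matrix `height x width`.
#' @slot area number of TRUE pixels.
#' @slot centroid numeric length-2, (x, y) px of the component centroid.
#' @slot found logical flag.
#' @exportClass BeadMask
setClass("BeadMask",
  representation(
    mask = "matrix", area = "numeric", centroid = "numeric",
    found = "logical"))

setValidity("BeadMask", function(object) {
  msg <- character()
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
  if (!object@found && object@area != 0)
    msg <- c(msg, "found = FALSE implies area = 0")
  if (object@area != sum(object@mask))
    msg <- c(msg, "area must equal the number of TRUE mask pixels")
  if (length(msg)) msg else TRUE
})

#' Fitted disintegration kinetics
#'
#' Change-point plus exponential-decay fit of a well's intensity time
#' series.  When no onset improves the fit enough (`onsetFound = FALSE`)
#' the kinetic fields are `NA`.
#'
#' @slot onsetT detected onset time, s.
#' @slot kDecayHat fitted decay rate, 1/s.
#' @slot baselineHat fitted post-decay baseline intensity (0-255 scale).
#' @slot rss total residual sum of squares of the two-segment fit.
#' @slot onsetFound logical flag.
#' @seealso [fitDisintegration()], [analyzeTimelapse()]
#' @exportClass DisintegrationFit
setClass("DisintegrationFit",
  representation(
    onsetT = "numeric", kDecayHat = "numeric", baselineHat = "numeric",
    rss = "numeric", onsetFound = "logical"))

setValidity("DisintegrationFit", function(object) {
  if (!object@onsetFound &&
      !(is.na(object@onsetT) && is.na(object@kDecayHat) &&
        is.na(object@baselineHat)))
    return("onsetFound = FALSE implies NA kinetic fields")
  TRUE
})

#' A camera source
#'
#' Abstraction over frame acquisition: a mock source renders synthetic
#' scenes; a real driver is out of scope.  [capture()] fails on a closed
#' source.
#'
#' @slot width,height configured resolution in px.
#' @slot open logical; whether the source can acquire.
#' @slot frameFun zero-argument function returning a [Frame-class].
#' @seealso [mockCameraSource()], [capture()]
#' @exportClass CameraSource
setClass("CameraSource",
  representation(
    width = "integer", height = "integer",
    open = "logical", frameFun = "function"))

#' Protocol configuration
#'
#' Parameters of the two-pipette hydrogel screening protocol: which wells
#' receive crosslinker (CaCl2), the alginate droplets to deliver with air
#' gaps, the imaging interval schedule, deck slot assignments, pipette
#' volume classes and nominal step durations.
#'
#' @slot cacl2Wells data.frame with columns `slot`, `well`, `concentration`
#'   (% w/v), `volume` (uL).
#' @slot alginateDroplets data.frame with columns `concentration` (% w/v)
#'   and `volume` (uL); one droplet per target well.
#' @slot imagingIntervals strictly increasing capture times (s) after
#'   dispense.
#' @slot perWellImageTime seconds the camera needs per well (default 5).
#' @slot plateSlot,tipRack1000Slot,tipRack300Slot,vialSlot,toolSlot deck
#'   slot assignments (defaults 1, 8, 9, 10, 11).
#' @slot rightMaxVolume,leftMaxVolume pipette capacities in uL (defaults
#'   1000 and 300).
#' @slot airGapVolume air segment volume (uL) between aspirated droplets.
#' @slot durations named numeric of nominal step durations in seconds.
#' @seealso [protocolConfig()], [planHydrogelScreen()]
#' @exportClass ProtocolConfig
setClass("ProtocolConfig",
  representation(
    cacl2Wells = "data.frame", alginateDroplets = "data.frame",
    imagingIntervals = "numeric", perWellImageTime = "numeric",
    plateSlot = "integer", tipRack1000Slot = "integer",
    tipRack300Slot = "integer", vialSlot = "integer", toolSlot = "integer",
    rightMaxVolume = "numeric", leftMaxVolume = "numeric",
    airGapVolume = "numeric", durations = "numeric"))

setValidity("ProtocolConfig", function(object) {
  msg <- character()
  iv <- object@imagingIntervals
  if (length(iv) > 1L && any(diff(iv) <= 0))
    msg <- c(msg, "imagingIntervals must be strictly increasing")
  if (object@perWellImageTime <= 0)
    msg <- c(msg, "perWellImageTime must be > 0")
  if (nrow(object@cacl2Wells) &&
      any(object@cacl2Wells$volume <= 0))
    msg <- c(msg, "cacl2 volumes must be > 0")
  if (nrow(object@alginateDroplets) &&
      any(object@alginateDroplets$volume <= 0))
    msg <- c(msg, "droplet volumes must be > 0")
  if (length(msg)) msg else TRUE
})
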