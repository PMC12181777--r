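#' Total screening capacity of a deck layout
#'
#' Number of unique formulation conditions a layout can monitor: the sum of
#' well counts over all microplate-kind labware.  A fully loaded deck with
#' six 96-well microplates can monitor 576 combinations.
#'
#' @param layout a [DeckLayout-class].
#' @return integer count of microplate wells.
#' @examples
#' conditionCapacity(defaultDeck())  # 96: one microplate on slot 1
#' @export
setGeneric("conditionCapacity", function(layout)
  standardGeneric("conditionCapacity"))

#' Deck coordinate of a well
#'
#' Maps a well address on a slotted labware to the deck (x, y) coordinate in
#' mm: slot origin + A1 offset + grid offsets of `(col - 1)` and the row
#' index times the well pitch.  Deterministic and injective over the wells
#' of one labware.
#'
#' @param layout a [DeckLayout-class].
#' @param slot slot index 1-11; must be occupied.
#' @param address well address text such as `"A1"`.
#' @return named numeric `c(x = , y = )` in mm.
#' @export
setGeneric("wellPosition", function(layout, slot, address)
  standardGeneric("wellPosition"))

#' Number of wells (or positions) on a labware
#'
#' @param x a [LabwareDefinition-class].
#' @return integer, `rows * cols`.
#' @export
setGeneric("wellCount", function(x) standardGeneric("wellCount"))

#' Get or set the labware in a deck slot
#'
#' @param layout a [DeckLayout-class].
#' @param i slot index 1-11.
#' @param value a [LabwareDefinition-class] or `NULL`.
#' @return `deckSlot` returns the labware or `NULL`.
#' @export
setGeneric("deckSlot", function(layout, i) standardGeneric("deckSlot"))

#' @rdname deckSlot
#' @export
setGeneric("deckSlot<-", function(layout, i, value)
  standardGeneric("deckSlot<-"))

#' Acquire one frame from a camera source
#'
#' @param source a [CameraSource-class]; must be open.
#' @return a [Frame-class] at the source's configured resolution.
#' @export
setGeneric("capture", function(source) standardGeneric("capture"))

#' Pixel array of a frame
#'
#' @param x a [Frame-class].
#' @return integer array `height x width x 3`, values 0-255.
#' @export
setGeneric("framePixels", function(x) standardGeneric("framePixels"))

#' @describeIn conditionCapacity sum of microplate well counts.
setMethod("conditionCapacity", "DeckLayout", function(layout) {
  counts <- vapply(layout@slots, function(s) {
    if (!is.null(s) && s@kind == "microplate") wellCount(s) else 0L
  }, integer(1))
  sum(counts)
})

#' @describeIn wellCount rows times columns.
setMethod("wellCount", "LabwareDefinition", function(x) x@rows * x@cols)

#' @describeIn framePixels slot accessor.
setMethod("framePixels", "Frame", function(x) x@pixels)

setMethod("show", "LabwareDefinition", function(object) {
  cat(sprintf("LabwareDefinition '%s' (%s)\n", object@name, object@kind))
  cat(sprintf("  %d rows x %d cols = %d positions, pitch %.2f mm\n",
              object@rows, object@cols, wellCount(object), object@wellPitch))
  cat(sprintf("  footprint %.1f x %.1f mm, well depth %.1f mm, volume %.0f uL\n",
              object@footprint[1], object@footprint[2],
              object@wellDepth, object@wellVolume))
})

setMethod("show", "DeckLayout", function(object) {
  cat("DeckLayout (11 slots)\n")
  for (i in seq_along(object@slots)) {
    s <- object@slots[[i]]
    if (is.null(s))
      cat(sprintf("  slot %2d: <empty>\n", i))
    else
      cat(sprintf("  slot %2d: %s (%s, %d positions)\n",
                  i, s@name, s@kind, wellCount(s)))
  }
  cat(sprintf("  screening capacity: %d conditions\n",
              conditionCapacity(object)))
})

setMethod("show", "Frame", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("Frame %d x %d px, 3-channel 8-bit RGB, range [%d, %d]\n",
              d[2], d[1], min(object@pixels), max(object@pixels)))
})

setMethod("show", "BeadMask", function(object) {
  if (object@found)
    cat(sprintf("BeadMask: found, area %d px, centroid (%.1f, %.1f)\n",
                as.integer(object@area),
                object@centroid[1], object@centroid[2]))
  else
    cat("BeadMask: no bead found\n")
})

setMethod("show", "DisintegrationFit", function(object) {
  if (object@onsetFound)
    cat(sprintf(
      "DisintegrationFit: onset %.1f s, k_decay %.4g 1/s, baseline %.1f (rss %.3g)\n",
      object@onsetT, object@kDecayHat, object@baselineHat, object@rss))
  else
    cat("DisintegrationFit: no disintegration onset detected\n")
})

setMethod("show", "CameraModel", function(object) {
  cat(sprintf(
    "CameraModel %d x %d px, noise sigma %.1f, blur radius %.1f, seed %d\n",
    object@width, object@height, object@noiseSigma, object@blurRadius,
    object@seed))
})

setMethod("show", "WellScene", function(object) {
  if (object@beadPresent)
    cat(sprintf(
      "WellScene: bead opacity %.3f, radius %.0f px, offset (%+.0f, %+.0f), background %d\n",
      object@opacity, object@radius, object@centerOffset[1],
      object@centerOffset[2], as.integer(object@backgroundLevel)))
  else
    cat(sprintf("WellScene: empty well, background %d\n",
                as.integer(object@backgroundLevel)))
})
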