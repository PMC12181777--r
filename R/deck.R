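# The deck is a fixed 3 x 4 grid of 11 usable slots (the 12th corner is the
# fixed trash on the physical machine and is not modelled).  Slot origins
# follow the vendor's slot spacing.
.SLOT_PITCH_X <- 132.5
.SLOT_PITCH_Y <- 90.5

slotOrigin <- function(slot) {
  slot <- as.integer(slot)
  if (is.na(slot) || slot < 1L || slot > .N_SLOTS)
    stop("slot index must be in 1..11", call. = FALSE)
  c(x = ((slot - 1L) %% 3L) * .SLOT_PITCH_X,
    y = ((slot - 1L) %/% 3L) * .SLOT_PITCH_Y)
}

#' Construct a deck layout
#'
#' @param slots named list mapping slot indices (`"1"`..`"11"`) to
#'   [LabwareDefinition-class] objects; unlisted slots are empty.
#' @return a [DeckLayout-class].
#' @examples
#' deckLayout(list("1" = standardLabware("plate96")))
#' @export
deckLayout <- function(slots = list()) {
  full <- vector("list", .N_SLOTS)
  if (length(slots)) {
    idx <- as.integer(names(slots))
    if (anyNA(idx) || any(idx < 1L | idx > .N_SLOTS))
      stop("slot indices must be in 1..11", call. = FALSE)
    if (anyDuplicated(idx))
      stop("at most one labware per slot", call. = FALSE)
    full[idx] <- slots
  }
  new("DeckLayout", slots = full)
}

#' Built-in labware definitions
#'
#' Stock geometries used by [defaultDeck()]: a 96-well microplate (8 x 12,
#' 9 mm pitch), 1000 uL and 300 uL tip racks (8 x 12), a 54-position 2 mL
#' vial rack (6 x 9 grid; the rack's capacity is fixed, its arrangement is a
#' package assumption), and the camera tool holder plate with six evenly
#' spaced holes (2 x 3).
#'
#' @param which one of `"plate96"`, `"tiprack1000"`, `"tiprack300"`,
#'   `"vialrack54"`, `"toolholder"`.
#' @return a [LabwareDefinition-class].
#' @export
standardLabware <- function(which = c("plate96", "tiprack1000", "tiprack300",
                                      "vialrack54", "toolholder")) {
  which <- match.arg(which)
  switch(which,
    plate96 = labwareDefinition(
      "standard_96_wellplate_360ul", "microplate", 8, 12,
      wellPitch = 9, a1Offset = c(14.38, 11.24),
      wellDepth = 10.67, wellVolume = 360, footprint = c(127.76, 85)),
    tiprack1000 = labwareDefinition(
      "standard_96_tiprack_1000ul", "tip_rack", 8, 12,
      wellPitch = 9, a1Offset = c(14.38, 11.24),
      wellDepth = 97.8, wellVolume = 1000, footprint = c(127.76, 85)),
    tiprack300 = labwareDefinition(
      "standard_96_tiprack_300ul", "tip_rack", 8, 12,
      wellPitch = 9, a1Offset = c(14.38, 11.24),
      wellDepth = 64.7, wellVolume = 300, footprint = c(127.76, 85)),
    vialrack54 = labwareDefinition(
      "custom_54_vialrack_2000ul", "vial_rack", 6, 9,
      wellPitch = 13.5, a1Offset = c(10, 8.75),
      wellDepth = 33, wellVolume = 2000, footprint = c(128, 85)),
    toolholder = labwareDefinition(
      "camera_toolholder_6pos", "tool_holder", 2, 3,
      wellPitch = 40, a1Offset = c(24, 22.5),
      wellDepth = 60, wellVolume = 0, footprint = c(128, 85)))
}

#' The demo deck layout
#'
#' The deck as set up for the example hydrogel screening protocol:
#' slot 1 a 96-well plate, slot 8 a 1000 uL tip rack, slot 9 a 300 uL tip
#' rack, slot 10 the 2 mL vial rack, slot 11 the camera tool holder with the
#' pick-and-place tool.  All other slots are empty.
#'
#' @return a [DeckLayout-class].
#' @export
defaultDeck <- function() {
  deckLayout(list(
    "1" = standardLabware("plate96"),
    "8" = standardLabware("tiprack1000"),
    "9" = standardLabware("tiprack300"),
    "10" = standardLabware("vialrack54"),
    "11" = standardLabware("toolholder")))
}

#' @describeIn deckSlot retrieve the labware in a slot (or `NULL`).
setMethod("deckSlot", "DeckLayout", function(layout, i) {
  i <- as.integer(i)
  if (is.na(i) || i < 1L || i > .N_SLOTS)
    stop("slot index must be in 1..11", call. = FALSE)
  layout@slots[[i]]
})

#' @describeIn deckSlot replace the labware in a slot.
setReplaceMethod("deckSlot", "DeckLayout", function(layout, i, value) {
  i <- as.integer(i)
  if (is.na(i) || i < 1L || i > .N_SLOTS)
    stop("slot index must be in 1..11", call. = FALSE)
  layout@slots[[i]] <- value
  validObject(layout)
  layout
})

#' @describeIn wellPosition slot origin + A1 offset + grid offset.
setMethod("wellPosition", "DeckLayout", function(layout, slot, address) {
  lw <- deckSlot(layout, slot)
  if (is.null(lw))
    stop("lookup error: deck slot ", slot, " is empty", call. = FALSE)
  ad <- parseWellAddress(address)
  if (ad$row > lw@rows || ad$col > lw@cols)
    stop(sprintf(
      "address error: '%s' is outside the %d x %d grid of '%s'",
      address, lw@rows, lw@cols, lw@name), call. = FALSE)
  org <- slotOrigin(slot)
  c(x = unname(org["x"]) + lw@a1Offset[1] + (ad$col - 1L) * lw@wellPitch,
    y = unname(org["y"]) + lw@a1Offset[2] + (ad$row - 1L) * lw@wellPitch)
})
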