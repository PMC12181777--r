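#' Construct a labware definition
#'
#' @param name text identifier.
#' @param kind one of `"microplate"`, `"tip_rack"`, `"vial_rack"`,
#'   `"tool_holder"`.
#' @param rows,cols grid dimensions.
#' @param wellPitch centre-to-centre spacing, mm.  96-well plates default to
#'   the 9 mm ANSI/SLAS pitch.
#' @param a1Offset numeric length-2: (x, y) of well A1 from the labware
#'   front-left corner, mm.
#' @param wellDepth well depth, mm.
#' @param wellVolume nominal well volume, uL.
#' @param footprint numeric length-2: (length, width), mm; must fit one
#'   128 x 85 mm deck slot.
#' @return a validated [LabwareDefinition-class].
#' @examples
#' labwareDefinition("plate96", "microplate", 8, 12)
#' @export
labwareDefinition <- function(name, kind, rows, cols,
                              wellPitch = 9,
                              a1Offset = c(14.38, 11.24),
                              wellDepth = 10.67,
                              wellVolume = 360,
                              footprint = c(127.76, 85)) {
  new("LabwareDefinition", name = as.character(name), kind = as.character(kind),
      rows = as.integer(rows), cols = as.integer(cols),
      wellPitch = as.numeric(wellPitch), a1Offset = as.numeric(a1Offset),
      wellDepth = as.numeric(wellDepth), wellVolume = as.numeric(wellVolume),
      footprint = as.numeric(footprint))
}

# mapping from Opentrons-style displayCategory to our kind enum
.CATEGORY_KIND <- c(wellPlate = "microplate", tipRack = "tip_rack",
                    tubeRack = "vial_rack", reservoir = "vial_rack",
                    toolHolder = "tool_holder", other = "tool_holder")

.schemaStop <- function(field, why) {
  stop(sprintf("labware schema error: field '%s' %s", field, why),
       call. = FALSE)
}

.need <- function(doc, field) {
  v <- doc[[field]]
  if (is.null(v)) .schemaStop(field, "is missing")
  v
}

#' Load a labware definition from JSON
#'
#' Reads either (a) a documented subset of the Opentrons labware-definition
#' schema (`ordering` column-major A1-down-then-right, per-well `x`/`y`
#' coordinates in mm from the labware front-left corner, `dimensions`,
#' `parameters$loadName`, `metadata$displayCategory`), or (b) the normalized
#' flat form written by [writeLabwareDefinition()].  Unknown extra fields
#' are ignored.  Loading, serializing and loading again round-trips to an
#' equal definition.
#'
#' @param document path to a JSON file, a JSON string, or an already-parsed
#'   list.
#' @return a validated [LabwareDefinition-class].
#' @seealso [writeLabwareDefinition()]
#' @export
loadLabwareDefinition <- function(document) {
  doc <- if (is.list(document)) document
    else if (length(document) == 1L && file.exists(document))
      jsonlite::read_json(document, simplifyVector = TRUE)
    else jsonlite::fromJSON(document, simplifyVector = TRUE)
  if (!is.list(doc)) .schemaStop("<document>", "is not a JSON object")

  if (!is.null(doc$ordering) && !is.null(doc$wells))
    .loadOpentronsLabware(doc)
  else
    .loadNormalizedLabware(doc)
}

.loadOpentronsLabware <- function(doc) {
  ordering <- .need(doc, "ordering")
  # jsonlite simplifies the list of column arrays into a matrix with one
  # row per column array; split back into columns
  if (is.matrix(ordering)) ordering <- asplit(ordering, 1)
  if (!length(ordering) || !length(ordering[[1]]))
    .schemaStop("ordering", "must be a non-empty list of columns")
  rows <- length(ordering[[1]])
  cols <- length(ordering)

  wells <- .need(doc, "wells")
  a1 <- wells[["A1"]]
  if (is.null(a1)) .schemaStop("wells.A1", "is missing")
  for (f in c("x", "y")) if (is.null(a1[[f]])) .schemaStop(paste0("wells.A1.", f), "is missing")

  # pitch from the nearest grid neighbour; default 9 mm for single wells
  pitch <- 9
  if (rows > 1L) {
    b1 <- wells[[ordering[[1]][2]]]
    if (!is.null(b1)) pitch <- abs(as.numeric(b1$y) - as.numeric(a1$y))
  } else if (cols > 1L) {
    a2 <- wells[[ordering[[2]][1]]]
    if (!is.null(a2)) pitch <- abs(as.numeric(a2$x) - as.numeric(a1$x))
  }

  dims <- .need(doc, "dimensions")
  fp <- c(as.numeric(dims$xDimension %||% NA), as.numeric(dims$yDimension %||% NA))
  if (anyNA(fp)) .schemaStop("dimensions", "must give xDimension and yDimension")
  if (fp[1] > .SLOT_LENGTH || fp[2] > .SLOT_WIDTH)
    stop(sprintf(
      "labware geometry error: footprint %.1f x %.1f mm exceeds the %d x %d mm deck slot",
      fp[1], fp[2], .SLOT_LENGTH, .SLOT_WIDTH), call. = FALSE)

  cat0 <- doc$metadata$displayCategory %||% "other"
  kind <- .CATEGORY_KIND[[cat0]] %||% "tool_holder"
  name <- doc$parameters$loadName %||% doc$metadata$displayName
  if (is.null(name)) .schemaStop("parameters.loadName", "is missing")

  labwareDefinition(
    name = name, kind = kind, rows = rows, cols = cols, wellPitch = pitch,
    a1Offset = c(as.numeric(a1$x), as.numeric(a1$y)),
    wellDepth = as.numeric(a1$depth %||% 0),
    wellVolume = as.numeric(a1$totalLiquidVolume %||% 0),
    footprint = fp)
}

.loadNormalizedLabware <- function(doc) {
  for (f in c("name", "kind", "rows", "cols", "well_pitch", "a1_offset",
              "footprint"))
    if (is.null(doc[[f]])) .schemaStop(f, "is missing")
  if (!is.numeric(doc$rows) || doc$rows < 1)
    .schemaStop("rows", "must be >= 1")
  if (!is.numeric(doc$cols) || doc$cols < 1)
    .schemaStop("cols", "must be >= 1")
  labwareDefinition(
    name = doc$name, kind = doc$kind, rows = doc$rows, cols = doc$cols,
    wellPitch = doc$well_pitch, a1Offset = unlist(doc$a1_offset),
    wellDepth = doc$well_depth %||% 0, wellVolume = doc$well_volume %||% 0,
    footprint = unlist(doc$footprint))
}

#' Serialize a labware definition to normalized JSON
#'
#' Writes the flat normalized form re-readable by
#' [loadLabwareDefinition()].
#'
#' @param lw a [LabwareDefinition-class].
#' @param path output file; when `NULL`, the JSON text is returned.
#' @return invisibly, the JSON text.
#' @export
writeLabwareDefinition <- function(lw, path = NULL) {
  doc <- list(name = lw@name, kind = lw@kind, rows = lw@rows, cols = lw@cols,
              well_pitch = lw@wellPitch, a1_offset = lw@a1Offset,
              well_depth = lw@wellDepth, well_volume = lw@wellVolume,
              footprint = lw@footprint)
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}
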