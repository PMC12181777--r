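# capture-on-message camera service: newline-delimited JSON messages in,
# one saved PNG + index row + acknowledgement per well-formed message

.MSG_FIELDS <- c("run_id", "well", "slot", "sim_time", "sequence")

#' Build a capture message
#'
#' @param runId run identifier text.
#' @param well canonical well address, e.g. `"A1"`.
#' @param slot deck slot index.
#' @param simTime simulated time of the request, s.
#' @param sequence integer >= 0, strictly increasing within a run.
#' @return named list with wire-format fields.
#' @export
captureMessage <- function(runId, well, slot, simTime, sequence) {
  list(run_id = as.character(runId), well = as.character(well),
       slot = as.integer(slot), sim_time = as.numeric(simTime),
       sequence = as.integer(sequence))
}

#' Encode / decode capture messages
#'
#' Wire format: one JSON object per line (newline-delimited JSON).
#' `decodeCaptureMessage(encodeCaptureMessage(m))` is the identity for all
#' valid messages; decoding failures raise an error that carries the raw
#' payload.
#'
#' @param msg a message from [captureMessage()].
#' @return `encodeCaptureMessage`: a single-line JSON string.
#' @export
encodeCaptureMessage <- function(msg) {
  stopifnot(all(.MSG_FIELDS %in% names(msg)))
  unclass(jsonlite::toJSON(msg[.MSG_FIELDS], auto_unbox = TRUE, digits = NA))
}

#' @rdname encodeCaptureMessage
#' @param line raw wire bytes / text of one message.
#' @return `decodeCaptureMessage`: the decoded message list.
#' @export
decodeCaptureMessage <- function(line) {
  bad <- function(why) stop(sprintf(
    "decode error: %s; payload: %s", why,
    deparse(substr(paste(line, collapse = ""), 1, 200))), call. = FALSE)
  if (length(line) != 1L || !nzchar(trimws(line))) bad("empty message")
  msg <- tryCatch(jsonlite::fromJSON(line, simplifyVector = TRUE),
                  error = function(e) bad(conditionMessage(e)))
  if (!is.list(msg)) bad("not a JSON object")
  missing <- setdiff(.MSG_FIELDS, names(msg))
  if (length(missing)) bad(paste("missing field(s):",
                                 paste(missing, collapse = ", ")))
  if (!is.numeric(msg$sequence) || msg$sequence < 0 ||
      msg$sequence != round(msg$sequence)) bad("sequence must be an integer >= 0")
  if (!is.numeric(msg$slot)) bad("slot must be numeric")
  captureMessage(msg$run_id, msg$well, msg$slot, msg$sim_time, msg$sequence)
}

#' Mock camera source backed by the synthetic renderer
#'
#' @param scene a [WellScene-class] rendered on every capture, or `NULL`
#'   when `frameFun` is given.
#' @param cam a [CameraModel-class] fixing resolution and noise.
#' @param frameFun optional zero-argument function returning a
#'   [Frame-class]; overrides `scene`.
#' @return an open [CameraSource-class].
#' @examples
#' fr <- capture(mockCameraSource())
#' dim(framePixels(fr))  # 480 640 3
#' @export
mockCameraSource <- function(scene = wellScene(), cam = cameraModel(),
                             frameFun = NULL) {
  if (is.null(frameFun)) frameFun <- function() renderFrame(scene, cam)
  new("CameraSource", width = cam@width, height = cam@height,
      open = TRUE, frameFun = frameFun)
}

#' Close a camera source
#'
#' @param source a [CameraSource-class].
#' @return the source with `open = FALSE`.
#' @export
closeCameraSource <- function(source) {
  source@open <- FALSE
  source
}

#' @describeIn capture acquire via the source's frame function; errors if
#'   the source is closed.
setMethod("capture", "CameraSource", function(source) {
  if (!source@open)
    stop("acquisition error: camera source is closed", call. = FALSE)
  fr <- source@frameFun()
  stopifnot(is(fr, "Frame"))
  fr
})

.recordFilename <- function(msg)
  sprintf("%s_%d_%s_%d.png", msg$run_id, msg$slot, msg$well, msg$sequence)

#' Run the capture-on-message camera service over a message stream
#'
#' For every well-formed message: acquire one frame from the source, save
#' it losslessly as PNG under the filename scheme
#' `<run_id>_<slot>_<well>_<sequence>.png`, append a row to the CSV index,
#' and reply with an acknowledgement carrying the filename.  Malformed
#' messages and sequence regressions get an error reply and produce no
#' file; serving continues.  The service is request-driven only: zero
#' messages means zero files.
#'
#' @param messages character vector of newline-delimited JSON lines, a file
#'   path, or a connection.
#' @param source an open [CameraSource-class].
#' @param outDir writable output directory (created if needed).
#' @param indexFile CSV index filename inside `outDir`.
#' @param latestFrame when `TRUE`, additionally overwrite `latest.png`
#'   after each capture (stand-in for a live-feed display).
#' @param state environment tracking the last sequence number per run;
#'   pass the same environment across calls to keep the regression check
#'   stateful over multiple message batches.
#' @return invisibly, a list with `records` (data.frame `filename`, `well`,
#'   `slot`, `simTime`, `sequence`, `captureWallTime`) and `replies`
#'   (character vector of JSON acknowledgement lines, one per message).
#' @seealso [cameraServeSocket()] for the TCP front end.
#' @export
cameraServe <- function(messages, source = mockCameraSource(),
                        outDir = tempfile("captures"),
                        indexFile = "index.csv", latestFrame = FALSE,
                        state = new.env(parent = emptyenv())) {
  if (inherits(messages, "connection")) messages <- readLines(messages)
  else if (length(messages) == 1L && file.exists(messages) &&
           !grepl("[{]", messages)) messages <- readLines(messages)
  ok <- dir.exists(outDir) || dir.create(outDir, recursive = TRUE)
  if (!ok || file.access(outDir, mode = 2) != 0L)
    stop("startup error: output directory is not writable", call. = FALSE)
  indexPath <- file.path(outDir, indexFile)

  lastSeq <- state
  records <- list()
  replies <- character(length(messages))

  for (i in seq_along(messages)) {
    reply <- tryCatch({
      msg <- decodeCaptureMessage(messages[i])
      prev <- get0(msg$run_id, envir = lastSeq, ifnotfound = -1L)
      if (msg$sequence <= prev)
        stop("sequence regression: ", msg$sequence, " after ", prev,
             call. = FALSE)
      fr <- capture(source)
      fn <- .recordFilename(msg)
      png::writePNG(framePixels(fr) / 255, file.path(outDir, fn))
      if (latestFrame)
        png::writePNG(framePixels(fr) / 255, file.path(outDir, "latest.png"))
      assign(msg$run_id, msg$sequence, envir = lastSeq)
      rec <- data.frame(filename = fn, well = msg$well, slot = msg$slot,
                        simTime = msg$sim_time, sequence = msg$sequence,
                        captureWallTime = as.numeric(Sys.time()),
                        stringsAsFactors = FALSE)
      write.table(rec, indexPath, sep = ",", row.names = FALSE,
                  col.names = !file.exists(indexPath), append = file.exists(indexPath))
      records[[length(records) + 1L]] <- rec
      jsonlite::toJSON(list(status = "ok", filename = fn), auto_unbox = TRUE)
    }, error = function(e) {
      jsonlite::toJSON(list(status = "error",
                            reason = conditionMessage(e)), auto_unbox = TRUE)
    })
    replies[i] <- unclass(reply)
  }

  recs <- if (length(records)) do.call(rbind, records) else
    data.frame(filename = character(), well = character(), slot = integer(),
               simTime = numeric(), sequence = integer(),
               captureWallTime = numeric(), stringsAsFactors = FALSE)
  invisible(list(records = recs, replies = replies))
}

#' Serve capture messages over a localhost TCP socket
#'
#' Thin network front end to [cameraServe()]: accepts one client, reads
#' newline-delimited JSON messages, writes one acknowledgement line per
#' message, and stops after `maxMessages` or when the client disconnects.
#' Intended for the command-line interface; the line-stream
#' [cameraServe()] is the testable core.
#'
#' @param port TCP port to listen on.
#' @param source,outDir,indexFile as in [cameraServe()].
#' @param maxMessages stop after this many messages.
#' @param timeout accept/read timeout, s.
#' @return invisibly, the [cameraServe()] result for the received lines.
#' @export
cameraServeSocket <- function(port, source = mockCameraSource(),
                              outDir = tempfile("captures"),
                              indexFile = "index.csv",
                              maxMessages = Inf, timeout = 30) {
  srv <- serverSocket(port)
  on.exit(close(srv), add = TRUE)
  con <- socketAccept(srv, blocking = TRUE, timeout = timeout)
  on.exit(close(con), add = TRUE)
  state <- new.env(parent = emptyenv())
  allRecords <- list()
  nseen <- 0L
  while (nseen < maxMessages) {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0L) break
    nseen <- nseen + 1L
    res <- cameraServe(ln, source, outDir, indexFile, state = state)
    writeLines(res$replies, con)
    flush(con)
    allRecords[[length(allRecords) + 1L]] <- res$records
  }
  invisible(do.call(rbind, allRecords))
}
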