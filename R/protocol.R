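.STEP_OPS <- c("pick_up_tip", "drop_tip", "pick_up_tool", "return_tool",
               "aspirate", "dispense_partial", "touch_coalesce",
               "move_to_well", "capture_image", "delay")

# nominal step durations, seconds; only the 5 s capture figure is a
# measured quantity, the rest are configurable estimates
.DEFAULT_DURATIONS <- c(
  pick_up_tip = 2, drop_tip = 2, pick_up_tool = 10, return_tool = 10,
  aspirate = 2, dispense_partial = 2, touch_coalesce = 2,
  move_to_well = 2, capture_image = 5, delay = 0)

#' Construct a protocol configuration
#'
#' Defaults reproduce the demo hydrogel screen: 1.0 % w/v CaCl2 dispensed
#' into wells A1-A3 of the plate on slot 1 (200 uL each), one 20 uL droplet
#' of 1.5 % w/v alginate per well delivered with air gaps in between, one
#' image per well right after dispensing, and the nine-point imaging
#' interval schedule (20 s to 30 min) for time-lapse monitoring.
#'
#' @param cacl2Wells data.frame(slot, well, concentration, volume).
#' @param alginateDroplets data.frame(concentration, volume); one row per
#'   target well (a single row is recycled).
#' @param imagingIntervals strictly increasing seconds after dispense.
#' @param perWellImageTime seconds per single-well capture (default 5).
#' @param plateSlot,tipRack1000Slot,tipRack300Slot,vialSlot,toolSlot deck
#'   slots (defaults 1, 8, 9, 10, 11).
#' @param rightMaxVolume,leftMaxVolume pipette capacities, uL.  The left
#'   (liquid-handling) pipette defaults to the 300 uL class matching the
#'   300 uL tip rack on slot 9.
#' @param airGapVolume air segment volume between droplets, uL.
#' @param durations named numeric overriding nominal step durations (s).
#' @return a [ProtocolConfig-class].
#' @export
protocolConfig <- function(
    cacl2Wells = data.frame(slot = 1L, well = c("A1", "A2", "A3"),
                            concentration = 1.0, volume = 200),
    alginateDroplets = data.frame(concentration = 1.5, volume = 20),
    imagingIntervals = c(20, 40, 60, 300, 600, 900, 1200, 1500, 1800),
    perWellImageTime = 5,
    plateSlot = 1L, tipRack1000Slot = 8L, tipRack300Slot = 9L,
    vialSlot = 10L, toolSlot = 11L,
    rightMaxVolume = 1000, leftMaxVolume = 300,
    airGapVolume = 10, durations = numeric()) {
  dur <- .DEFAULT_DURATIONS
  if (length(durations)) dur[names(durations)] <- durations
  new("ProtocolConfig",
      cacl2Wells = cacl2Wells, alginateDroplets = alginateDroplets,
      imagingIntervals = as.numeric(imagingIntervals),
      perWellImageTime = as.numeric(perWellImageTime),
      plateSlot = as.integer(plateSlot),
      tipRack1000Slot = as.integer(tipRack1000Slot),
      tipRack300Slot = as.integer(tipRack300Slot),
      vialSlot = as.integer(vialSlot), toolSlot = as.integer(toolSlot),
      rightMaxVolume = as.numeric(rightMaxVolume),
      leftMaxVolume = as.numeric(leftMaxVolume),
      airGapVolume = as.numeric(airGapVolume), durations = dur)
}

.step <- function(op, mount = NA_character_, slot = NA_integer_,
                  well = NA_character_, volume = NA_real_,
                  label = NA_character_, durations = .DEFAULT_DURATIONS) {
  data.frame(op = op, mount = mount, slot = as.integer(slot), well = well,
             volume = volume, label = label,
             duration = unname(durations[[op]]),
             stringsAsFactors = FALSE)
}

.emptyPlan <- function() {
  data.frame(op = character(), mount = character(), slot = integer(),
             well = character(), volume = numeric(), label = character(),
             duration = numeric(), stringsAsFactors = FALSE)
}

.requireKind <- function(layout, slot, kind, what) {
  lw <- deckSlot(layout, slot)
  if (is.null(lw) || lw@kind != kind)
    stop(sprintf("plan error: expected %s (%s) on slot %d", what, kind, slot),
         call. = FALSE)
  lw
}

#' Plan the two-pipette hydrogel screening protocol
#'
#' Produces the ordered hardware-agnostic step list of the demo protocol:
#' the right (1000 uL) pipette picks up a tip from the 1000 uL rack,
#' distributes CaCl2 from the vial rack into the configured wells, drops its
#' tip and instead friction-fits the camera pick-and-place tool; the left
#' pipette picks up a tip and aspirates the alginate droplets separated by
#' air gaps; each droplet is then delivered by two-sub-step coalescence
#' dispensing (`dispense_partial` immediately followed by `touch_coalesce`)
#' and the camera captures an image over that well before moving on.  All
#' dispenses, including CaCl2, use the two-sub-step pair.
#'
#' Droplets are aspirated in reverse well order so that the tip-most (last
#' aspirated) segment matches the first well dispensed.
#'
#' @param config a [ProtocolConfig-class].
#' @param layout a [DeckLayout-class]; must hold the configured tip racks,
#'   vial rack, microplate and tool holder.
#' @param toolWorkingHeight camera working height in mm; every occupied
#'   labware other than the target plate and the tool holder must be
#'   shorter, else a plan (collision) error is raised.
#' @return a data.frame plan (columns `op`, `mount`, `slot`, `well`,
#'   `volume`, `label`, `duration`) with the config attached as attribute
#'   `"config"`.
#' @seealso [simulateProtocol()], [volumeLedger()]
#' @export
planHydrogelScreen <- function(config = protocolConfig(),
                               layout = defaultDeck(),
                               toolWorkingHeight = 100) {
  wellsDf <- config@cacl2Wells
  if (nrow(wellsDf) == 0L) return(structure(.emptyPlan(), config = config))

  .requireKind(layout, config@tipRack1000Slot, "tip_rack", "1000 uL tip rack")
  .requireKind(layout, config@tipRack300Slot, "tip_rack", "300 uL tip rack")
  vialRack <- .requireKind(layout, config@vialSlot, "vial_rack", "vial rack")
  .requireKind(layout, config@toolSlot, "tool_holder", "camera tool holder")
  for (i in seq_len(nrow(wellsDf))) {
    plate <- .requireKind(layout, wellsDf$slot[i], "microplate", "microplate")
    ad <- parseWellAddress(wellsDf$well[i])
    if (ad$row > plate@rows || ad$col > plate@cols)
      stop("plan error: well ", wellsDf$well[i], " outside plate grid",
           call. = FALSE)
  }

  # single collision rule: camera must clear everything but the target plate
  for (i in seq_len(.N_SLOTS)) {
    lw <- deckSlot(layout, i)
    if (is.null(lw) || i %in% c(wellsDf$slot, config@toolSlot)) next
    if (lw@wellDepth >= toolWorkingHeight)
      stop(sprintf(
        "plan error: labware '%s' on slot %d (height %.0f mm) collides with the camera tool (working height %.0f mm)",
        lw@name, i, lw@wellDepth, toolWorkingHeight), call. = FALSE)
  }

  drops <- config@alginateDroplets
  n <- nrow(wellsDf)
  if (nrow(drops) == 1L && n > 1L) drops <- drops[rep(1L, n), , drop = FALSE]
  if (nrow(drops) != n)
    stop("plan error: need one alginate droplet per CaCl2 well (or a single ",
         "droplet row to recycle)", call. = FALSE)
  if (any(drops$volume + config@airGapVolume > config@leftMaxVolume))
    stop("capacity error: a droplet plus its air gap exceeds the left ",
         "pipette volume", call. = FALSE)
  if (any(wellsDf$volume > config@rightMaxVolume))
    stop("capacity error: a CaCl2 volume exceeds the right pipette volume",
         call. = FALSE)

  dur <- config@durations
  vialAddr <- labwareAddresses(vialRack)
  solutions <- unique(c(sprintf("CaCl2 %.2f%%", wellsDf$concentration),
                        sprintf("alginate %.2f%%", drops$concentration)))
  if (length(solutions) > length(vialAddr))
    stop("plan error: more solutions than vial rack positions", call. = FALSE)
  vialOf <- setNames(vialAddr[seq_along(solutions)], solutions)

  steps <- list()
  add <- function(...) steps[[length(steps) + 1L]] <<- .step(..., durations = dur)

  # (1) right pipette tip from the 1000 uL rack
  add("pick_up_tip", "right", config@tipRack1000Slot)

  # (2) CaCl2 distribution, chunked to the right pipette capacity
  i <- 1L
  while (i <= n) {
    conc <- wellsDf$concentration[i]
    lab <- sprintf("CaCl2 %.2f%%", conc)
    j <- i
    total <- 0
    while (j <= n && wellsDf$concentration[j] == conc &&
           total + wellsDf$volume[j] <= config@rightMaxVolume) {
      total <- total + wellsDf$volume[j]
      j <- j + 1L
    }
    add("aspirate", "right", config@vialSlot, vialOf[[lab]], total, lab)
    for (k in i:(j - 1L)) {
      add("move_to_well", "right", wellsDf$slot[k], wellsDf$well[k])
      add("dispense_partial", "right", wellsDf$slot[k], wellsDf$well[k],
          wellsDf$volume[k], lab)
      add("touch_coalesce", "right", wellsDf$slot[k], wellsDf$well[k],
          wellsDf$volume[k], lab)
    }
    i <- j
  }

  # (3)-(5) tool change: right drops its tip and lifts the camera tool,
  # left takes a 300 uL tip for the alginate work
  add("drop_tip", "right", config@tipRack1000Slot)
  add("pick_up_tip", "left", config@tipRack300Slot)
  add("pick_up_tool", "right", config@toolSlot)

  # (6)-(8) alginate passes: aspirate a batch of droplets with air gaps,
  # then per well dispense (two sub-steps) and capture
  remaining <- seq_len(n)
  while (length(remaining)) {
    batch <- integer()
    total <- 0
    for (k in remaining) {
      extra <- drops$volume[k] + if (length(batch)) config@airGapVolume else 0
      if (total + extra > config@leftMaxVolume) break
      total <- total + extra
      batch <- c(batch, k)
    }
    # reverse aspiration so LIFO dispensing pairs droplet k with well k
    for (k in rev(batch)) {
      lab <- sprintf("alginate %.2f%%", drops$concentration[k])
      add("aspirate", "left", config@vialSlot, vialOf[[lab]],
          drops$volume[k], lab)
      if (k != batch[1L])
        add("aspirate", "left", config@vialSlot, vialOf[[lab]],
            config@airGapVolume, "air")
    }
    for (k in batch) {
      lab <- sprintf("alginate %.2f%%", drops$concentration[k])
      add("move_to_well", "left", wellsDf$slot[k], wellsDf$well[k])
      add("dispense_partial", "left", wellsDf$slot[k], wellsDf$well[k],
          drops$volume[k], lab)
      add("touch_coalesce", "left", wellsDf$slot[k], wellsDf$well[k],
          drops$volume[k], lab)
      add("move_to_well", "right", wellsDf$slot[k], wellsDf$well[k])
      add("capture_image", "right", wellsDf$slot[k], wellsDf$well[k])
    }
    remaining <- setdiff(remaining, batch)
  }

  # (9) stow the tool, then the left tip
  add("return_tool", "right", config@toolSlot)
  add("drop_tip", "left", config@tipRack300Slot)

  plan <- do.call(rbind, steps)
  rownames(plan) <- NULL
  structure(plan, config = config)
}

.newPipetteState <- function(maxVolume) {
  list(tip = FALSE, tool = FALSE, segments = list(), pending = NULL,
       maxVolume = maxVolume)
}

.heldVolume <- function(st)
  sum(vapply(st$segments, function(s) s$volume, numeric(1)), 0)

#' Simulate a protocol plan
#'
#' Executes a plan against per-mount pipette state machines, producing a
#' timestamped event log.  Simulated time advances by each step's nominal
#' duration; `capture_image` steps invoke the `camera` callback with
#' `(well, simTime)`.  State violations (aspirating while the tool is held,
#' picking up the tool with a tip attached, dispensing more than is held)
#' produce an `error` event and halt the simulation.  Execution is
#' deterministic: identical plan and layout give an identical log.
#'
#' @param plan data.frame from [planHydrogelScreen()] (its `"config"`
#'   attribute supplies pipette capacities; defaults are used otherwise).
#' @param layout a [DeckLayout-class] (retained for interface symmetry).
#' @param camera `NULL` or `function(well, simTime)`.
#' @param clockStart simulation start time, s.
#' @return the event log: data.frame with columns `simTime`, `op`, `mount`,
#'   `slot`, `well`, `volume`, `label`, `outcome` (`ok`/`error`), `detail`.
#' @seealso [volumeLedger()]
#' @export
simulateProtocol <- function(plan, layout = defaultDeck(), camera = NULL,
                             clockStart = 0) {
  config <- attr(plan, "config")
  rightMax <- if (is.null(config)) 1000 else config@rightMaxVolume
  leftMax <- if (is.null(config)) 300 else config@leftMaxVolume
  st <- list(right = .newPipetteState(rightMax),
             left = .newPipetteState(leftMax))
  t <- clockStart
  ev <- vector("list", nrow(plan))
  halt <- FALSE

  for (i in seq_len(nrow(plan))) {
    row <- plan[i, ]
    m <- row$mount
    err <- NULL
    if (!row$op %in% .STEP_OPS) {
      err <- paste0("unknown op '", row$op, "'")
    } else if (row$op %in% c("pick_up_tip", "drop_tip", "pick_up_tool",
                             "return_tool", "aspirate", "dispense_partial",
                             "touch_coalesce") && !m %in% c("left", "right")) {
      err <- "step requires a pipette mount"
    } else {
      s <- if (m %in% c("left", "right")) st[[m]] else NULL
      err <- switch(row$op,
        pick_up_tip = if (s$tip) "tip already attached"
                      else if (s$tool) "tool held",
        drop_tip = if (!s$tip) "no tip attached",
        pick_up_tool = if (s$tip) "state-machine error: tip attached"
                       else if (s$tool) "tool already held",
        return_tool = if (!s$tool) "no tool held",
        aspirate = if (s$tool) "state-machine error: tool held"
          else if (!s$tip) "no tip attached"
          else if (.heldVolume(s) + row$volume > s$maxVolume)
            sprintf("capacity error: %.0f + %.0f uL exceeds %.0f uL",
                    .heldVolume(s), row$volume, s$maxVolume),
        dispense_partial = {
          if (s$tool) "state-machine error: tool held"
          else if (!s$tip) "no tip attached"
          else if (!is.null(s$pending)) "pending droplet not yet coalesced"
          else {
            # expel trailing air, then check the tip-most liquid segment
            segs <- s$segments
            while (length(segs) && segs[[length(segs)]]$kind == "air")
              segs <- segs[-length(segs)]
            if (!length(segs)) "volume error: nothing held to dispense"
            else if (segs[[length(segs)]]$volume < row$volume - 1e-9)
              sprintf("volume error: dispense %.0f uL exceeds held segment %.0f uL",
                      row$volume, segs[[length(segs)]]$volume)
            else NULL
          }
        },
        touch_coalesce = if (is.null(s$pending))
          "no pending droplet to coalesce",
        capture_image = if (!st$right$tool && !st$left$tool)
          "no camera tool attached",
        NULL)
    }

    if (is.null(err)) {
      # apply the state transition
      if (m %in% c("left", "right")) s <- st[[m]]
      switch(row$op,
        pick_up_tip = { s$tip <- TRUE },
        drop_tip = { s$tip <- FALSE; s$segments <- list(); s$pending <- NULL },
        pick_up_tool = { s$tool <- TRUE },
        return_tool = { s$tool <- FALSE },
        aspirate = {
          kind <- if (identical(row$label, "air")) "air" else "liquid"
          s$segments[[length(s$segments) + 1L]] <-
            list(kind = kind, volume = row$volume, label = row$label)
        },
        dispense_partial = {
          while (length(s$segments) &&
                 s$segments[[length(s$segments)]]$kind == "air")
            s$segments <- s$segments[-length(s$segments)]
          top <- s$segments[[length(s$segments)]]
          if (top$volume - row$volume > 1e-9) {
            s$segments[[length(s$segments)]]$volume <- top$volume - row$volume
          } else {
            s$segments <- s$segments[-length(s$segments)]
          }
          s$pending <- list(volume = row$volume, label = top$label)
        },
        touch_coalesce = { s$pending <- NULL },
        capture_image = if (!is.null(camera)) camera(row$well, t),
        NULL)
      if (m %in% c("left", "right")) st[[m]] <- s
      outcome <- "ok"; detail <- ""
    } else {
      outcome <- "error"; detail <- err; halt <- TRUE
    }

    ev[[i]] <- data.frame(
      simTime = t, op = row$op, mount = row$mount, slot = row$slot,
      well = row$well, volume = row$volume, label = row$label,
      outcome = outcome, detail = detail, stringsAsFactors = FALSE)
    t <- t + row$duration
    if (halt) break
  }

  log <- do.call(rbind, ev[!vapply(ev, is.null, logical(1))])
  if (is.null(log))
    log <- data.frame(simTime = numeric(), op = character(),
                      mount = character(), slot = integer(),
                      well = character(), volume = numeric(),
                      label = character(), outcome = character(),
                      detail = character(), stringsAsFactors = FALSE)
  attr(log, "finalState") <- st
  log
}

#' Per-solution liquid balance of an event log
#'
#' Conservation bookkeeping: for every liquid label, the total aspirated
#' must equal the total dispensed (via `touch_coalesce`) plus any residual
#' still held or dropped with a tip.  Air segments are excluded.
#'
#' @param log event log from [simulateProtocol()].
#' @return data.frame with columns `label`, `aspirated`, `dispensed`,
#'   `residual`, `conserved`.  A label dispensed without matching
#'   aspiration is flagged `conserved = FALSE`.
#' @export
volumeLedger <- function(log) {
  ok <- log[log$outcome == "ok", , drop = FALSE]
  asp <- ok[ok$op == "aspirate" & ok$label != "air", , drop = FALSE]
  disp <- ok[ok$op == "touch_coalesce" & !is.na(ok$label), , drop = FALSE]
  labels <- union(unique(asp$label), unique(disp$label))
  if (!length(labels))
    return(data.frame(label = character(), aspirated = numeric(),
                      dispensed = numeric(), residual = numeric(),
                      conserved = logical()))
  res <- data.frame(
    label = labels,
    aspirated = vapply(labels, function(l)
      sum(asp$volume[asp$label == l]), numeric(1)),
    dispensed = vapply(labels, function(l)
      sum(disp$volume[disp$label == l]), numeric(1)),
    stringsAsFactors = FALSE)
  res$residual <- res$aspirated - res$dispensed
  res$conserved <- res$residual >= -1e-9
  rownames(res) <- NULL
  res
}

#' Serialize an imaging schedule for one camera
#'
#' Each well gets one capture per interval.  Because a single camera serves
#' all wells, simultaneous requests are serialized: captures run in well
#' order and a later capture is shifted to at least `perWellTime` after the
#' previous one.  Realized times are never earlier than requested.
#'
#' @param wells character vector of well addresses.
#' @param intervals strictly increasing requested times, s.
#' @param perWellTime seconds per single-well capture (default 5).
#' @return list with `schedule` (data.frame `interval`, `well`, `requested`,
#'   `realized`), `totalDuration` (last realized time), `feasible`, and
#'   `violatedIntervals` (intervals whose spacing is smaller than
#'   `length(wells) * perWellTime`, so shifts overrun into them).
#' @examples
#' scheduleImaging(c("A1", "A2"), intervals = 10, perWellTime = 5)
#' @export
scheduleImaging <- function(wells, intervals, perWellTime = 5) {
  stopifnot(perWellTime > 0)
  if (length(intervals) > 1L && any(diff(intervals) <= 0))
    stop("intervals must be strictly increasing", call. = FALSE)
  n <- length(wells)
  if (n == 0L || length(intervals) == 0L)
    return(list(schedule = data.frame(interval = numeric(), well = character(),
                                      requested = numeric(),
                                      realized = numeric()),
                totalDuration = 0, feasible = TRUE,
                violatedIntervals = numeric()))
  requested <- rep(intervals, each = n)
  well <- rep(wells, times = length(intervals))
  realized <- numeric(length(requested))
  realized[1] <- requested[1]
  for (i in seq_along(requested)[-1])
    realized[i] <- max(requested[i], realized[i - 1] + perWellTime)
  sched <- data.frame(interval = requested, well = well,
                      requested = requested, realized = realized,
                      stringsAsFactors = FALSE)
  violated <- if (length(intervals) > 1L)
    intervals[-1][diff(intervals) < n * perWellTime] else numeric()
  list(schedule = sched, totalDuration = realized[length(realized)],
       feasible = length(violated) == 0L, violatedIntervals = violated)
}

#' Generate a random valid protocol configuration
#'
#' Seeded generator used by the engine's property checks: random well sets
#' on the slot-1 plate, random CaCl2 and alginate concentrations and
#' volumes within pipette capacity, and a random increasing interval
#' schedule.
#'
#' @param seed integer seed; the caller's RNG state is preserved.
#' @return a [ProtocolConfig-class].
#' @export
randomProtocolConfig <- function(seed) {
  withSeed(seed, {
    n <- sample(1:6, 1)
    plate <- standardLabware("plate96")
    wells <- sample(labwareAddresses(plate), n)
    conc <- round(runif(1, 0.5, 5), 1)
    protocolConfig(
      cacl2Wells = data.frame(
        slot = 1L, well = wells, concentration = conc,
        volume = sample(seq(50, 300, by = 10), n, replace = TRUE)),
      alginateDroplets = data.frame(
        concentration = round(runif(n, 0.5, 2), 2),
        volume = sample(seq(10, 30, by = 5), n, replace = TRUE)),
      imagingIntervals = sort(sample(seq(20, 1800, by = 20),
                                     sample(2:5, 1))))
  })
}
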