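test_that("the demo plan reproduces the two-pipette protocol structure", {
  plan <- planHydrogelScreen()

  # three CaCl2 dispenses into A1, A2, A3 on slot 1
  ca <- plan[plan$op == "dispense_partial" & grepl("CaCl2", plan$label), ]
  expect_identical(nrow(ca), 3L)
  expect_identical(ca$well, c("A1", "A2", "A3"))
  expect_true(all(ca$slot == 1L))

  # protocol order: right tip first, tool change after the CaCl2 pass
  expect_identical(plan$op[1], "pick_up_tip")
  expect_identical(plan$mount[1], "right")
  expect_identical(plan$slot[1], 8L)
  expect_lt(max(which(plan$op == "dispense_partial" &
                        grepl("CaCl2", plan$label))),
            which(plan$op == "pick_up_tool"))
  expect_identical(plan$slot[plan$op == "pick_up_tool"], 11L)
  expect_identical(plan$slot[plan$op == "pick_up_tip" &
                               plan$mount == "left"], 9L)

  # left pipette holds 3 liquid segments separated by air gaps
  leftAsp <- plan[plan$op == "aspirate" & plan$mount == "left", ]
  expect_identical(sum(leftAsp$label != "air"), 3L)
  expect_identical(leftAsp$label != "air",
                   c(TRUE, FALSE, TRUE, FALSE, TRUE))

  # every partial dispense is immediately followed by coalescence on the
  # same target
  dp <- which(plan$op == "dispense_partial")
  expect_identical(plan$op[dp + 1L], rep("touch_coalesce", length(dp)))
  expect_identical(plan$well[dp + 1L], plan$well[dp])

  # one capture per well, over that well
  caps <- plan[plan$op == "capture_image", ]
  expect_identical(caps$well, c("A1", "A2", "A3"))
})

test_that("planning fails cleanly on missing labware and over-capacity loads", {
  cfg <- protocolConfig()
  bare <- deckLayout(list("1" = standardLabware("plate96")))
  expect_error(planHydrogelScreen(cfg, bare), "plan error")

  over <- protocolConfig(alginateDroplets = data.frame(concentration = 1.5,
                                                       volume = 400))
  expect_error(planHydrogelScreen(over), "capacity error")

  none <- protocolConfig(cacl2Wells = data.frame(slot = integer(),
                                                 well = character(),
                                                 concentration = numeric(),
                                                 volume = numeric()))
  empty <- planHydrogelScreen(none)
  expect_identical(nrow(empty), 0L)
})

test_that("a tall labware in the camera's path is a collision plan error", {
  layout <- defaultDeck()
  deckSlot(layout, 5) <- labwareDefinition(
    "tall_flask_rack", "vial_rack", 2, 2, wellPitch = 20,
    a1Offset = c(20, 20), wellDepth = 150, wellVolume = 5e4,
    footprint = c(120, 80))
  expect_error(planHydrogelScreen(layout = layout), "collides")
})

test_that("simulation executes the demo plan cleanly and invokes the camera", {
  plan <- planHydrogelScreen()
  seen <- list()
  log <- simulateProtocol(plan, camera = function(well, t)
    seen[[length(seen) + 1L]] <<- list(well = well, t = t))

  expect_true(all(log$outcome == "ok"))
  expect_identical(nrow(log), nrow(plan))
  expect_true(all(diff(log$simTime) >= 0))
  expect_identical(vapply(seen, `[[`, "", "well"), c("A1", "A2", "A3"))

  # final state: no tips, no tool, nothing held
  st <- attr(log, "finalState")
  for (m in c("left", "right")) {
    expect_false(st[[m]]$tip)
    expect_false(st[[m]]$tool)
    expect_length(st[[m]]$segments, 0L)
  }
})

test_that("state violations produce an error event and halt the simulation", {
  plan <- planHydrogelScreen()
  # schedule an aspirate on the right pipette while it holds the tool
  toolRow <- which(plan$op == "pick_up_tool")
  bad <- plan[c(seq_len(toolRow), which(plan$op == "aspirate")[1]), ]
  attr(bad, "config") <- attr(plan, "config")
  bad$mount[nrow(bad)] <- "right"
  log <- simulateProtocol(bad)
  expect_identical(log$outcome[nrow(log)], "error")
  expect_match(log$detail[nrow(log)], "tool held")
  expect_identical(nrow(log), nrow(bad))  # halted at the offending step

  emptyLog <- simulateProtocol(planHydrogelScreen(
    protocolConfig(cacl2Wells = data.frame(slot = integer(),
                                           well = character(),
                                           concentration = numeric(),
                                           volume = numeric()))))
  expect_identical(nrow(emptyLog), 0L)
})

test_that("the volume ledger conserves every solution", {
  log <- simulateProtocol(planHydrogelScreen())
  led <- volumeLedger(log)
  expect_true(all(led$conserved))
  expect_equal(led$aspirated, led$dispensed + led$residual)
  ca <- led[grepl("CaCl2", led$label), ]
  expect_equal(ca$dispensed, 3 * 200)

  expect_identical(nrow(volumeLedger(log[0, ])), 0L)

  # an unmatched dispense (no aspiration) is flagged
  fake <- log[log$op == "touch_coalesce", ][1, ]
  fake$label <- "phantom 1.00%"
  expect_false(volumeLedger(rbind(log, fake))$conserved[
    volumeLedger(rbind(log, fake))$label == "phantom 1.00%"])
})

test_that("imaging schedules serialize a single camera correctly", {
  one <- scheduleImaging("A1", 30, 5)
  expect_equal(one$schedule$realized, 30)
  expect_equal(one$totalDuration, 30)

  two <- scheduleImaging(c("A1", "A2"), 10, 5)
  expect_equal(two$schedule$realized, c(10, 15))

  plate <- as.vector(outer(LETTERS[1:8], 1:12, paste0))
  full <- scheduleImaging(plate, c(20, 40, 60, 300, 600, 900, 1200, 1500,
                                   1800), 5)
  expect_identical(nrow(full$schedule), 96L * 9L)
  expect_false(full$feasible)  # 96 wells x 5 s overruns the early gaps
  expect_true(40 %in% full$violatedIntervals)
})

test_that("schedule serialization matches a discrete queue oracle", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(1:6, 1)
    wells <- paste0("A", seq_len(n))
    iv <- sort(sample(seq(10, 200, by = 10), sample(1:4, 1)))
    pwt <- sample(2:7, 1)
    got <- scheduleImaging(wells, iv, pwt)$schedule
    ref <- refSchedule(wells, iv, pwt)
    expect_equal(got$realized, ref$realized)
    expect_identical(anyDuplicated(got$realized), 0L)
    expect_true(all(got$realized >= got$requested))
    if (length(iv) == 1L || all(diff(iv) >= n * pwt))
      expect_true(all(got$realized - got$requested <= (n - 1) * pwt))
  }
})

test_that("lifecycle pairing, conservation and determinism hold over random plans", {
  for (seed in 1:100) {
    cfg <- randomProtocolConfig(seed)
    plan <- planHydrogelScreen(cfg)
    log <- simulateProtocol(plan)
    expect_true(all(log$outcome == "ok"), info = paste("seed", seed))

    # tip and tool lifecycles pair up
    expect_identical(sum(log$op == "pick_up_tip"), sum(log$op == "drop_tip"),
                     info = paste("seed", seed))
    expect_identical(sum(log$op == "pick_up_tool"),
                     sum(log$op == "return_tool"), info = paste("seed", seed))

    led <- volumeLedger(log)
    expect_true(all(led$conserved), info = paste("seed", seed))
    expect_true(all(abs(led$residual) < 1e-9), info = paste("seed", seed))
  }
  # determinism: identical plan -> identical event log
  plan <- planHydrogelScreen(randomProtocolConfig(42))
  expect_identical(simulateProtocol(plan), simulateProtocol(plan))
})
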