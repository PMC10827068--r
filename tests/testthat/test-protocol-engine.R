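test_that("the six-segment stimulation/washout protocol behaves as published", {
  tc <- runProtocol(exampleNet(), tutorialProtocol())
  a <- activities(tc)
  t <- timePoints(tc)
  expect_equal(segmentBoundaries(tc), seq(0, 60, by = 10))
  # segment 1: inputs off, nothing moves
  expect_true(all(a[t <= 10, ] == 0))
  # A stimulation: at t = 20 species A, C, E are at activity 1
  at20 <- a[t == 20, ]
  expect_equal(unname(at20[c("A", "C", "E")]), rep(1, 3), tolerance = 1e-2)
  expect_lt(max(at20[c("B", "D")]), 1e-2)
  # washout of A: everything decays again by t = 30
  expect_lt(max(a[t == 30, ]), 0.01)
  # B stimulation: B and D rise, E stays off
  at40 <- a[t == 40, ]
  expect_equal(unname(at40[c("B", "D")]), rep(1, 2), tolerance = 1e-2)
  expect_lt(at40["E"], 1e-2)
  # final segment, both inputs on: A and B rise to 1 while E, whose only
  # drive is act(A) * inhib(B), falls toward 0
  seg6 <- a[t >= 50, ]
  expect_equal(unname(a[t == 60, c("A", "B")]), rep(1, 2), tolerance = 1e-2)
  # E shows a brief transient while A outruns B, then relaxes toward 0
  expect_lt(a[t == 60, "E"], 0.05)
  peak <- which.max(seg6[, "E"])
  expect_true(all(diff(seg6[peak:nrow(seg6), "E"]) <= 1e-9))
})

test_that("a single-step protocol equals simulateSegment", {
  m <- setReactionWeight(exampleNet(), "r1", 1)
  p <- simulationProtocol(list(protocolStep(10)), nOutPerStep = 51L)
  tcP <- runProtocol(m, p)
  tcS <- simulateSegment(m, duration = 10, nOut = 51L)
  expect_equal(timePoints(tcP), timePoints(tcS))
  expect_equal(activities(tcP), activities(tcS))
})

test_that("protocols of identical no-change steps match one long step", {
  m <- setReactionWeight(exampleNet(), "r1", 1)
  many <- runProtocol(m, simulationProtocol(
    rep(list(protocolStep(5)), 4L), nOutPerStep = 26L))
  one <- runProtocol(m, simulationProtocol(list(protocolStep(20)),
                                           nOutPerStep = 101L))
  expect_equal(unname(finalState(many)), unname(finalState(one)),
               tolerance = 1e-6)
})

test_that("cardiac development protocol reproduces the published dynamics", {
  tc <- runProtocol(cardiacDevNet(), cardiacProtocol())
  a <- activities(tc)
  t <- timePoints(tc)
  # pre-stimulus: ISL1 holds at 1 (its repressor is absent), others at 0
  expect_true(all(abs(a[t <= 2, "ISL1"] - 1) < 1e-6))
  expect_true(all(a[t <= 2, c("GATA6", "NKX25", "TBX1", "PITX2")] < 1e-6))
  # after the GATA6 input turns on: NKX25, TBX1, PITX2 increase and ISL1
  # decreases
  final <- finalState(tc)
  expect_equal(unname(final[c("GATA6", "NKX25", "TBX1", "PITX2")]),
               rep(1, 4), tolerance = 1e-2)
  expect_lt(final["ISL1"], 0.05)
  post <- a[t > 2, ]
  expect_true(all(diff(post[, "ISL1"]) <= 1e-9))
  for (s in c("NKX25", "TBX1", "PITX2"))
    expect_true(all(diff(post[, s]) >= -1e-9))
})

test_that("invalid protocol changes abort before integration, naming the step", {
  m <- exampleNet()
  p <- simulationProtocol(list(protocolStep(5),
                               protocolStep(5, weights = c(r99 = 1))))
  expect_error(runProtocol(m, p), "step 2")
  p2 <- simulationProtocol(list(
    protocolStep(5, species = list(A = list(tau = -1)))))
  expect_error(runProtocol(m, p2), "step 1")
})

test_that("knockout protocol: repressed targets stay on, downstream lags", {
  base <- runProtocol(cardiacDevNet(), cardiacProtocol(nOut = 201L))
  ko <- runKnockoutProtocol(cardiacDevNet(), "NKX25",
                            cardiacProtocol(nOut = 201L))
  # the knocked-out gene is identically silent
  expect_true(all(activities(ko)[, "NKX25"] == 0))
  # ISL1 is never suppressed
  expect_true(all(abs(activities(ko)[, "ISL1"] - 1) < 1e-6))
  # TBX1 and PITX2 still rise, but cross half-activation strictly later
  expect_gt(timeToReach(ko, "TBX1", 0.5), timeToReach(base, "TBX1", 0.5))
  expect_gt(timeToReach(ko, "PITX2", 0.5), timeToReach(base, "PITX2", 0.5))
  expect_lt(timeToReach(ko, "TBX1", 0.5), Inf)
  expect_lt(timeToReach(ko, "PITX2", 0.5), Inf)
})

test_that("knocking out a species with no outgoing reactions leaves the rest alone", {
  base <- runProtocol(cardiacDevNet(), cardiacProtocol())
  ko <- runKnockoutProtocol(cardiacDevNet(), "PITX2", cardiacProtocol())
  others <- setdiff(speciesIds(cardiacDevNet()), "PITX2")
  expect_equal(activities(ko)[, others], activities(base)[, others],
               tolerance = 1e-5)
})

test_that("knocked-out species decay no slower than free exponential decay", {
  m <- cardiacDevNet()  # ISL1 starts at 1
  ko <- applyKnockout(m, "ISL1")
  tc <- runProtocol(ko, cardiacProtocol())
  bound <- 1 * exp(-timePoints(tc) / 1)
  expect_true(all(activities(tc)[, "ISL1"] <= bound + 1e-6))
})

test_that("knockout screen reports deltas against the stimulated baseline", {
  scr <- knockoutScreen(cardiacDevNet())
  expect_true(scr@baselineConverged)
  expect_true(all(scr@converged))
  expect_identical(scr@targets, speciesIds(cardiacDevNet()))
  base <- screenBaseline(scr)
  # stimulated baseline: all activators on, ISL1 repressed to 0
  expect_equal(unname(base), c(1, 1, 1, 0, 1), tolerance = 1e-3)
  d <- screenDeltas(scr)
  # NKX25 knockout de-represses ISL1 fully
  expect_equal(d["NKX25", "ISL1"], 1, tolerance = 1e-3)
  # the knocked-out species' own delta is minus its baseline value
  for (s in scr@targets)
    expect_equal(d[s, s], -unname(base[s]), tolerance = 1e-3)
  # exact bookkeeping: delta = knockout steady state - baseline
  expect_identical(scr@deltas, sweep(scr@knockoutStates, 2L, base))
})

test_that("screen results do not depend on target-list order", {
  s1 <- knockoutScreen(cardiacDevNet(), targets = c("NKX25", "GATA6"))
  s2 <- knockoutScreen(cardiacDevNet(), targets = c("GATA6", "NKX25"))
  expect_identical(s1@targets, s2@targets)
  expect_identical(screenDeltas(s1), screenDeltas(s2))
  expect_identical(screenBaseline(s1), screenBaseline(s2))
})

test_that("screening an already-silent species yields a zero delta row", {
  m <- applyKnockout(cardiacDevNet(), "PITX2")
  scr <- knockoutScreen(m, targets = "PITX2")
  expect_equal(max(abs(screenDeltas(scr))), 0, tolerance = 1e-6)
})

test_that("protocol files round-trip through YAML and JSON", {
  p <- simulationProtocol(list(
    protocolStep(2),
    protocolStep(8, weights = c(r1 = 1),
                 species = list(NKX25 = list(ymax = 0)))),
    nOutPerStep = 41L)
  yml <- tempfile(fileext = ".yaml")
  writeLines(c(
    "n_out_per_step: 41",
    "steps:",
    "  - duration: 2",
    "  - duration: 8",
    "    weights: {r1: 1}",
    "    species:",
    "      NKX25: {ymax: 0}"), yml)
  q <- readProtocol(yml)
  expect_equal(q@nOutPerStep, 41L)
  expect_equal(length(q@steps), 2L)
  expect_equal(q@steps[[2L]]$duration, 8)
  expect_equal(q@steps[[2L]]$weights$r1, 1)
  expect_equal(q@steps[[2L]]$species$NKX25$ymax, 0)
  tc1 <- runProtocol(cardiacDevNet(), p)
  tc2 <- runProtocol(cardiacDevNet(), q)
  expect_equal(activities(tc1), activities(tc2))

  jsn <- tempfile(fileext = ".json")
  writeLines(paste0(
    '{"n_out_per_step": 41, "steps": [{"duration": 2}, ',
    '{"duration": 8, "weights": {"r1": 1}, ',
    '"species": {"NKX25": {"ymax": 0}}}]}'), jsn)
  qj <- readProtocol(jsn)
  tc3 <- runProtocol(cardiacDevNet(), qj)
  expect_equal(activities(tc3), activities(tc2))
})
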