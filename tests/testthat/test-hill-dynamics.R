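test_that("hill shape matches the constraint-solving oracle", {
  # expected values frozen from oracleHillShape (numerical root of the
  # anchor constraints f(1)=1, f(ec50)=1/2 with beta = 1 + k^n)
  s <- hillShape(1.4, 0.5)
  expect_equal(s$beta, 2.564906, tolerance = 1e-6)
  expect_equal(s$k, 1.376957, tolerance = 1e-6)
  s <- hillShape(2, 0.5)
  expect_equal(s$beta, 1.5, tolerance = 1e-9)
  expect_equal(s$k, 1 / sqrt(2), tolerance = 1e-9)
  # oracle agreement on a parameter grid
  for (n in c(0.8, 1.4, 2, 3.7)) {
    for (ec50 in c(0.2, 0.35, 0.5, 0.6)) {
      if (ec50^n >= 0.5) next
      o <- oracleHillShape(n, ec50)
      s <- hillShape(n, ec50)
      expect_equal(s$beta, o$beta, tolerance = 1e-9)
      expect_equal(s$k, o$k, tolerance = 1e-9)
    }
  }
})

test_that("hill shape satisfies its three anchor constraints", {
  grid <- expand.grid(n = c(1.1, 1.4, 2, 4), ec50 = c(0.25, 0.4, 0.5))
  for (i in seq_len(nrow(grid))) {
    n <- grid$n[i]; ec50 <- grid$ec50[i]
    if (ec50^n >= 0.5) next
    s <- hillShape(n, ec50)
    expect_equal(hillAct(0, s), 0, tolerance = 1e-9)
    expect_equal(hillAct(ec50, s), 0.5, tolerance = 1e-9)
    expect_equal(hillAct(1, s), 1, tolerance = 1e-9)
  }
})

test_that("hill shape rejects parameters outside the existence domain", {
  expect_error(hillShape(1, 0.5), "ec50\\^n")     # 0.5^1 = 1/2 exactly
  expect_error(hillShape(0.5, 0.6), "ec50\\^n")   # 0.6^0.5 > 1/2
  expect_error(hillShape(-1, 0.5), "n > 0")
  expect_error(hillShape(1.4, 0), "0 < ec50 < 1")
  expect_error(hillShape(1.4, 1), "0 < ec50 < 1")
})

test_that("activation is monotone, complementary to inhibition, and clamped", {
  xs <- seq(0, 1, length.out = 201L)
  for (n in c(0.9, 1.4, 2.5)) {
    for (ec50 in c(0.3, 0.45)) {
      s <- hillShape(n, ec50)
      a <- hillAct(xs, s)
      expect_true(all(diff(a) >= -1e-12))
      expect_true(all(a >= 0 & a <= 1))
      expect_equal(a + hillInhib(xs, s), rep(1, length(xs)),
                   tolerance = 1e-12)
    }
  }
  s <- hillShape(1.4, 0.5)
  expect_identical(hillAct(2, s), hillAct(1, s))  # inputs above 1 clamp
  expect_error(hillAct(-0.1, s), ">= 0")
  expect_equal(hillInhib(0, s), 1)
  expect_equal(hillInhib(1, s), 0)
  expect_equal(hillInhib(0.5, s), 0.5)
})

test_that("reaction flux implements w * AND(terms), inputs give w", {
  m <- exampleNet()
  y <- setNames(c(1, 0, 0, 0, 0), speciesIds(m))  # A on, B off
  expect_equal(reactionFlux(m, "r1", y), 0)       # input off
  m1 <- setReactionWeight(m, "r1", 1)
  expect_equal(reactionFlux(m1, "r1", y), 1)      # input on, state-independent
  expect_equal(reactionFlux(m1, "r1", rep(0.3, 5)), 1)
  # r5 "A & !B => E": act(1) * inhib(0) = 1
  expect_equal(reactionFlux(m, "r5", y), 1, tolerance = 1e-12)
  # and with B fully on the inhibition annihilates the flux
  expect_equal(reactionFlux(m, "r5", c(1, 1, 0, 0, 0)), 0, tolerance = 1e-12)
  # intermediate: product of the two Hill branches
  s <- hillShape(1.4, 0.5)
  y2 <- c(0.7, 0.2, 0, 0, 0)
  expect_equal(reactionFlux(m, "r5", y2),
               hillAct(0.7, s) * (1 - hillAct(0.2, s)), tolerance = 1e-12)
})

test_that("node drive folds incoming fluxes with an order-invariant OR", {
  m <- exampleNet()
  y <- c(0.5, 0.5, 0, 0.2, 0.5)
  # C receives r3 (from A) and r6 (from E): both act(0.5) = 0.5 -> OR 0.75
  expect_equal(nodeDrive(m, "C", y), 0.75, tolerance = 1e-12)
  # single-input species: drive equals that flux
  expect_equal(nodeDrive(m, "D", y), reactionFlux(m, "r4", y),
               tolerance = 1e-12)
  # no incoming reactions -> zero drive
  m2 <- networkModel(species = data.frame(id = c("A", "B")),
                     reactions = data.frame(id = "r1", rule = "=> A"))
  expect_equal(nodeDrive(m2, "B", c(1, 1)), 0)
  # OR identity element: adding a zero-weight reaction changes nothing
  m3 <- setReactionWeight(m, "r6", 0)
  expect_equal(nodeDrive(m3, "C", y), reactionFlux(m3, "r3", y),
               tolerance = 1e-12)
  # permuting reaction declaration order leaves the drive unchanged
  rx <- reactionTable(m)[c(6, 3, 1, 5, 2, 4), ]
  m4 <- networkModel(speciesTable(m),
                     data.frame(id = rx$id, rule = rx$rule,
                                weight = rx$weight, n = rx$n,
                                ec50 = rx$ec50))
  for (sid in speciesIds(m))
    expect_equal(nodeDrive(m4, sid, y), nodeDrive(m, sid, y),
                 tolerance = 1e-12)
})

test_that("rhs has the relaxation form and respects the activity box", {
  m <- exampleNet()  # both inputs off
  expect_equal(unname(ldeRHS(m, rep(0, 5))), rep(0, 5))
  # single constitutively driven species: dy/dt = (1 - y)/tau
  m1 <- networkModel(species = data.frame(id = "A"),
                     reactions = data.frame(id = "r1", rule = "=> A",
                                            weight = 1))
  expect_equal(unname(ldeRHS(m1, 0)), 1)
  expect_equal(unname(ldeRHS(m1, 0.25)), 0.75)
  # knocked-out species pins its derivative at -y/tau; at y = 0 it is 0
  ko <- applyKnockout(cardiacDevNet(), "NKX25")
  expect_equal(unname(ldeRHS(ko, c(1, 0, 1, 1, 1)))[2L], 0)
  # on the faces of [0, ymax] the flow points inward
  set.seed(42)
  for (rep in 1:20) {
    y <- runif(5)
    dy <- unname(ldeRHS(m, y))
    expect_true(all(dy <= (1 - y) + 1e-12 & dy >= -y - 1e-12))
  }
  expect_error(ldeRHS(m, c(0, NA, 0, 0, 0)), "finite")
})

test_that("rhs agrees with the naive brute-force oracle on random models", {
  set.seed(7)
  for (i in 1:100) {
    m <- randomNetwork(nSpecies = sample(2:7, 1L),
                       nReactions = sample(1:10, 1L),
                       pInput = runif(1, 0.1, 0.5), pInhib = runif(1),
                       seed = i)
    y <- runif(nSpecies(m))
    expect_equal(unname(ldeRHS(m, y)), oracleRHS(m, y), tolerance = 1e-12)
  }
})

test_that("integration reproduces the closed-form single-node response", {
  # one input reaction into one species: y(t) = ymax (1 - exp(-t/tau))
  m <- networkModel(
    species = data.frame(id = "A", tau = 2, ymax = 0.8),
    reactions = data.frame(id = "r1", rule = "=> A", weight = 1))
  tc <- simulateSegment(m, duration = 10, nOut = 51L)
  expected <- 0.8 * (1 - exp(-timePoints(tc) / 2))
  expect_equal(unname(activities(tc)[, 1L]), expected, tolerance = 1e-5)
  # at t = 5 tau the response has reached 99.33% of ymax
  tc2 <- simulateSegment(m, duration = 10, nOut = 101L)
  expect_equal(activities(tc2)[timePoints(tc2) == 10, "A"] / 0.8,
               1 - exp(-5), tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("segment integration satisfies the semigroup property", {
  m <- setReactionWeight(setReactionWeight(exampleNet(), "r1", 1), "r2", 1)
  one <- simulateSegment(m, duration = 20, nOut = 41L)
  a <- simulateSegment(m, duration = 10, nOut = 21L)
  b <- simulateSegment(m, y0 = finalState(a), duration = 10, nOut = 21L)
  expect_equal(unname(finalState(one)), unname(finalState(b)),
               tolerance = 1e-6)
  # first output row is y0 exactly
  expect_identical(unname(activities(b)[1L, ]), unname(finalState(a)))
})

test_that("trajectories of random models stay inside [0, ymax]", {
  for (seed in 1:12) {
    m <- randomNetwork(nSpecies = 6L, nReactions = 9L, pInput = 0.3,
                       pInhib = 0.4, seed = seed)
    tc <- simulateSegment(m, duration = 50, nOut = 101L)
    ymax <- speciesTable(m)$ymax
    a <- activities(tc)
    expect_true(all(a >= -1e-6))
    expect_true(all(t(a) <= ymax + 1e-6))
  }
})

test_that("steady state solves the stimulated and conflicting fixed points", {
  m <- setReactionWeight(exampleNet(), "r1", 1)
  ss <- steadyState(m)
  expect_true(ss$converged)
  expect_equal(unname(ss$y), c(1, 0, 1, 0, 1), tolerance = 1e-3)
  # with both inputs on, E's sole drive act(A) * inhib(B) -> 0
  m2 <- setReactionWeight(m, "r2", 1)
  ss2 <- steadyState(m2)
  expect_true(ss2$converged)
  expect_equal(unname(ss2$y["E"]), 0, tolerance = 1e-3)
  expect_equal(unname(ss2$y[c("A", "B")]), c(1, 1), tolerance = 1e-3)
  # all inputs off from the origin: converged immediately
  ss0 <- steadyState(exampleNet())
  expect_true(ss0$converged)
  expect_identical(ss0$t, 0)
  expect_equal(unname(ss0$y), rep(0, 5))
})
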