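# Independent oracles used across the suite.

# Normalized-Hill constants found numerically from the anchor constraints
# alone: f(1) = 1 forces beta = 1 + k^n, then k^n is the root of
# f(ec50) - 1/2 on (0, Inf). Stays independent of the closed form used in
# the implementation.
oracleHillShape <- function(n, ec50) {
  e <- ec50^n
  g <- function(K) (1 + K) * e / (K + e) - 0.5
  K <- uniroot(g, c(1e-12, 1e12), tol = 1e-15)$root
  list(n = n, ec50 = ec50, beta = 1 + K, k = K^(1 / n))
}

oracleHillAct <- function(x, sh) {
  x <- min(max(x, 0), 1)
  min(max(sh$beta * x^sh$n / (sh$k^sh$n + x^sh$n), 0), 1)
}

# Naive per-node right-hand side: loops over species, re-collects and
# re-evaluates every reaction term from the model tables each time, and
# folds the OR pairwise left-to-right.
oracleRHS <- function(model, y) {
  sp <- speciesTable(model)
  rx <- reactionTable(model)
  dy <- numeric(nrow(sp))
  for (i in seq_len(nrow(sp))) {
    fluxes <- c()
    for (j in seq_len(nrow(rx))) {
      if (rx$target[j] != sp$id[i]) next
      sh <- hillShape(rx$n[j], rx$ec50[j])
      f <- rx$weight[j]
      terms <- rx$terms[[j]]
      for (t in seq_len(nrow(terms))) {
        a <- oracleHillAct(y[match(terms$species[t], sp$id)], sh)
        f <- f * if (terms$sign[t] == "-") 1 - a else a
      }
      fluxes <- c(fluxes, f)
    }
    phi <- 0
    for (f in fluxes) phi <- phi + f - phi * f
    dy[i] <- (phi * sp$ymax[i] - y[i]) / sp$tau[i]
  }
  dy
}

# The staged tutorial stimulation/washout protocol for the five-species
# network: all inputs off, A on, A off, B on, B off, both on.
tutorialProtocol <- function(duration = 10, nOut = 101L) {
  simulationProtocol(list(
    protocolStep(duration),
    protocolStep(duration, weights = c(r1 = 1)),
    protocolStep(duration, weights = c(r1 = 0)),
    protocolStep(duration, weights = c(r2 = 1)),
    protocolStep(duration, weights = c(r2 = 0)),
    protocolStep(duration, weights = c(r1 = 1, r2 = 1))),
    nOutPerStep = nOut)
}

# The cardiac-development protocol: 2 tau-units unstimulated, then 8 with
# the GATA6 input on.
cardiacProtocol <- function(nOut = 101L) {
  simulationProtocol(list(
    protocolStep(2),
    protocolStep(8, weights = c(r1 = 1))),
    nOutPerStep = nOut)
}

# first time at which a species crosses the given activity level
timeToReach <- function(tc, species, level) {
  y <- activities(tc)[, species]
  i <- which(y >= level)[1L]
  if (is.na(i)) Inf else timePoints(tc)[i]
}
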