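# Pre-resolve everything the right-hand side needs: per-reaction source
# indices, signs, weight, and the normalized-Hill constants. Integer index
# work here keeps the rhs itself free of id lookups.
.compileModel <- function(model) {
  sp <- model@species
  rx <- model@reactions
  issues <- validateModel(model)
  errs <- issues[issues$severity == "error", , drop = FALSE]
  if (nrow(errs))
    stop("model has validation errors:\n  ",
         paste(errs$location, errs$message, sep = ": ", collapse = "\n  "))
  nsp <- nrow(sp)
  reactions <- lapply(seq_len(nrow(rx)), function(j) {
    shape <- hillShape(rx$n[j], rx$ec50[j])
    terms <- rx$terms[[j]]
    list(target = match(rx$target[j], sp$id),
         src = match(terms$species, sp$id),
         inhib = terms$sign == "-",
         w = rx$weight[j],
         n = shape$n, beta = shape$beta, kn = shape$k^shape$n)
  })
  list(nsp = nsp, ids = sp$id, yinit = sp$yinit, ymax = sp$ymax,
       tau = sp$tau, reactions = reactions)
}

.compiledFlux <- function(r, y) {
  f <- r$w
  for (t in seq_along(r$src)) {
    x <- min(max(y[r$src[t]], 0), 1)
    xn <- x^r$n
    a <- min(max(r$beta * xn / (r$kn + xn), 0), 1)
    f <- f * if (r$inhib[t]) 1 - a else a
  }
  f
}

# phi: fuzzy-OR (a + b - a*b) fold of all incoming reaction fluxes per
# species, computed as 1 - prod(1 - flux); species with no incoming
# reactions get phi = 0.
.compiledDrive <- function(cm, y) {
  comp <- rep(1, cm$nsp)
  for (r in cm$reactions) {
    comp[r$target] <- comp[r$target] * (1 - .compiledFlux(r, y))
  }
  pmin(pmax(1 - comp, 0), 1)
}

.compiledRHS <- function(cm, y) {
  (.compiledDrive(cm, y) * cm$ymax - y) / cm$tau
}

#' Flux of a single reaction at a given state
#'
#' An input reaction (no source terms) contributes its weight `w`
#' regardless of state — a constitutive environmental stimulus. A regulated
#' reaction contributes `w` times the product over its terms of the
#' normalized Hill activation (activating terms) or inhibition (inhibiting
#' terms), i.e. AND logic between the terms of one rule. The result lies in
#' `[0, w]`.
#'
#' @param model a [NetworkModel-class].
#' @param reactionId reaction id.
#' @param y activity vector in model species order.
#' @return the reaction flux, a number in `[0, 1]`.
#' @export
reactionFlux <- function(model, reactionId, y) {
  j <- .reactionIndex(model, reactionId)
  rx <- model@reactions
  shape <- hillShape(rx$n[j], rx$ec50[j])
  terms <- rx$terms[[j]]
  f <- rx$weight[j]
  for (t in seq_len(nrow(terms))) {
    x <- y[.speciesIndex(model, terms$species[t])]
    a <- hillAct(x, shape)
    f <- f * if (terms$sign[t] == "-") 1 - a else a
  }
  unname(f)
}

#' Total drive on a species (crosstalk OR of incoming fluxes)
#'
#' Fluxes of all reactions targeting the species are merged with the
#' probabilistic OR `OR(a, b) = a + b - a*b`, folded associatively — the
#' result is independent of reaction order. A species with no incoming
#' reactions has drive 0; one whose only regulators are inhibitors receives
#' full drive while the repressors are absent.
#'
#' @param model a [NetworkModel-class].
#' @param speciesId species id.
#' @param y activity vector in model species order.
#' @return the drive `phi` in `[0, 1]`.
#' @export
nodeDrive <- function(model, speciesId, y) {
  .speciesIndex(model, speciesId)
  idx <- incomingIndex(model)[[speciesId]]
  comp <- 1
  for (j in idx)
    comp <- comp * (1 - reactionFlux(model, model@reactions$id[j], y))
  min(max(1 - comp, 0), 1)
}

#' Logic-based ODE right-hand side
#'
#' For each species i, `dy_i/dt = (phi_i(y) * ymax_i - y_i) / tau_i` where
#' `phi_i` is the fuzzy-OR drive of [nodeDrive()]. Since `phi` lies in
#' `[0, 1]`, the flow never leaves the box `[0, ymax]` componentwise; a
#' knocked-out species (`ymax = 0`) decays exponentially to zero.
#'
#' @param model a [NetworkModel-class].
#' @param y activity vector in model species order.
#' @param t time (the system is autonomous; accepted for solver interfaces).
#' @return named derivative vector.
#' @export
ldeRHS <- function(model, y, t = 0) {
  if (any(!is.finite(y))) stop("state vector must be finite")
  if (length(y) != nSpecies(model))
    stop("state length must equal the number of species")
  cm <- .compileModel(model)
  stats::setNames(.compiledRHS(cm, y), cm$ids)
}

.integrate <- function(cm, y0, times, rtol = 1e-6, atol = 1e-8) {
  func <- function(t, y, parms) list(.compiledRHS(cm, y))
  out <- deSolve::ode(y = y0, times = times, func = func, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(out, "istate")[1L] < 0)
    stop("ODE integration failed near t = ",
         signif(out[nrow(out), 1L], 6L))
  unname(as.matrix(out)[, -1L, drop = FALSE])
}

#' Integrate one simulation segment
#'
#' Integrates the logic-based ODE system with an adaptive-step solver
#' (lsoda; relative tolerance 1e-6, absolute 1e-8) over `[0, duration]`
#' with the model's current parameters, reporting on an evenly spaced grid
#' of `nOut` points including both endpoints. The first output row is `y0`
#' exactly.
#'
#' @param model a valid [NetworkModel-class].
#' @param y0 initial activity vector (defaults to the model's `yinit`).
#' @param duration segment length in tau-units (> 0).
#' @param nOut number of output points (>= 2).
#' @return a [TimeCourse-class].
#' @examples
#' m <- setReactionWeight(exampleNet(), "r1", 1)
#' tc <- simulateSegment(m, duration = 10)
#' finalState(tc)
#' @export
simulateSegment <- function(model, y0 = initialState(model), duration = 10,
                            nOut = 101L) {
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be > 0")
  if (nOut < 2L) stop("nOut must be >= 2")
  cm <- .compileModel(model)
  if (length(y0) != cm$nsp)
    stop("y0 length must equal the number of species")
  if (any(!is.finite(y0))) stop("y0 must be finite")
  times <- seq(0, duration, length.out = nOut)
  act <- .integrate(cm, unname(y0), times)
  new("TimeCourse", times = times, activities = act,
      speciesIds = cm$ids, segmentBoundaries = c(0, duration))
}

#' Integrate to steady state
#'
#' Integrates forward in chunks until the scaled derivative criterion
#' `max_i |dy_i/dt| * tau_i < tol` is met or until `tCap` is reached.
#' Non-convergence (e.g. a sustained oscillation) is reported through the
#' `converged` flag, never as an error.
#'
#' @param model a valid [NetworkModel-class].
#' @param y0 initial activity vector (defaults to the model's `yinit`).
#' @param tol convergence tolerance on the scaled derivative (default 1e-6).
#' @param tCap time cap (default `500 * max(tau)`).
#' @return list with `y` (named steady-state vector), `converged` (logical)
#'   and `t` (integration time used).
#' @export
steadyState <- function(model, y0 = initialState(model), tol = 1e-6,
                        tCap = NULL) {
  if (!is.numeric(tol) || tol <= 0) stop("tol must be > 0")
  cm <- .compileModel(model)
  if (is.null(tCap)) tCap <- 500 * max(cm$tau)
  y <- unname(y0)
  if (length(y) != cm$nsp) stop("y0 length must equal the number of species")
  t <- 0
  chunk <- 20 * max(cm$tau)
  repeat {
    if (max(abs(.compiledRHS(cm, y)) * cm$tau) < tol)
      return(list(y = stats::setNames(y, cm$ids), converged = TRUE, t = t))
    if (t >= tCap)
      return(list(y = stats::setNames(y, cm$ids), converged = FALSE, t = t))
    span <- min(chunk, tCap - t)
    act <- .integrate(cm, y, c(0, span / 2, span))
    y <- act[nrow(act), ]
    t <- t + span
  }
}
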