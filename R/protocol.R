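#' Create a protocol step
#'
#' One segment of a staged simulation: a duration plus the parameter
#' changes applied instantaneously at its start. Changes persist into later
#' steps, mirroring the interactive idiom of editing a weight and pressing
#' "Simulate!" repeatedly.
#'
#' @param duration segment length in tau-units (> 0).
#' @param weights named numeric of reaction-weight overrides,
#'   e.g. `c(r1 = 1)`.
#' @param species named list of species overrides, each a list with `ymax`
#'   and/or `tau`, e.g. `list(NKX25 = list(ymax = 0))`.
#' @return a step suitable for [simulationProtocol()].
#' @export
protocolStep <- function(duration, weights = NULL, species = NULL) {
  if (!is.numeric(duration) || length(duration) != 1L ||
      !is.finite(duration) || duration <= 0)
    stop("duration must be a single positive number")
  if (!is.null(weights)) {
    weights <- as.list(weights)
    if (is.null(names(weights)) || any(!nzchar(names(weights))))
      stop("weights must be named by reaction id")
  }
  if (!is.null(species)) {
    if (is.null(names(species)) || any(!nzchar(names(species))))
      stop("species changes must be named by species id")
    for (ch in species) {
      if (!all(names(ch) %in% c("ymax", "tau")))
        stop("species overrides may set only 'ymax' and/or 'tau'")
    }
  }
  list(duration = duration, weights = weights, species = species)
}

#' Assemble a simulation protocol
#'
#' @param steps list of steps from [protocolStep()] (a single step may be
#'   passed bare).
#' @param nOutPerStep output points per segment (default 101).
#' @return a [SimulationProtocol-class].
#' @examples
#' p <- simulationProtocol(list(
#'   protocolStep(10),
#'   protocolStep(10, weights = c(r1 = 1))))
#' @export
simulationProtocol <- function(steps, nOutPerStep = 101L) {
  if (!is.null(steps$duration)) steps <- list(steps)
  new("SimulationProtocol", steps = steps,
      nOutPerStep = as.integer(nOutPerStep))
}

#' Read a protocol file
#'
#' Protocol files are YAML or JSON with the schema
#' ```
#' steps:
#'   - duration: 10
#'   - duration: 10
#'     weights: {r1: 1}
#'     species:
#'       NKX25: {ymax: 0}
#' n_out_per_step: 101
#' ```
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a [SimulationProtocol-class].
#' @export
readProtocol <- function(path) {
  if (!file.exists(path)) stop("protocol file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  if (is.null(raw$steps)) stop("protocol file has no 'steps' entry")
  steps <- lapply(raw$steps, function(s) {
    protocolStep(duration = s$duration,
                 weights = if (length(s$weights)) unlist(s$weights),
                 species = s$species)
  })
  nOut <- if (!is.null(raw$n_out_per_step)) raw$n_out_per_step else 101L
  simulationProtocol(steps, nOutPerStep = nOut)
}

.applyStep <- function(model, step, stepIndex) {
  tryCatch({
    for (rid in names(step$weights))
      model <- setReactionWeight(model, rid, step$weights[[rid]])
    for (sid in names(step$species)) {
      ch <- step$species[[sid]]
      model <- .setSpeciesParams(model, sid, ymax = ch$ymax, tau = ch$tau)
    }
    model
  }, error = function(e) {
    stop("invalid change in protocol step ", stepIndex, ": ",
         conditionMessage(e), call. = FALSE)
  })
}

#' Run a staged simulation protocol
#'
#' For each step in order: apply its parameter changes, integrate for its
#' duration starting from the previous segment's final state (the first
#' segment starts at the model's `yinit`), and append the segment on a
#' continuous global time axis. Parameter changes are step functions at
#' segment boundaries and persist until changed again. All changes are
#' validated before any integration starts.
#'
#' @param model a valid [NetworkModel-class].
#' @param protocol a [SimulationProtocol-class].
#' @return a [TimeCourse-class] spanning all segments, with
#'   `segmentBoundaries` recording where parameters changed.
#' @examples
#' tc <- runProtocol(exampleNet(), simulationProtocol(list(
#'   protocolStep(10),
#'   protocolStep(10, weights = c(r1 = 1)))))
#' round(finalState(tc), 3)
#' @export
runProtocol <- function(model, protocol) {
  stopifnot(is(protocol, "SimulationProtocol"))
  validObject(protocol)
  # validate every step against the evolving model before integrating
  probe <- model
  for (i in seq_along(protocol@steps))
    probe <- .applyStep(probe, protocol@steps[[i]], i)

  y <- unname(initialState(model))
  tOffset <- 0
  times <- numeric()
  act <- NULL
  boundaries <- 0
  for (i in seq_along(protocol@steps)) {
    step <- protocol@steps[[i]]
    model <- .applyStep(model, step, i)
    seg <- simulateSegment(model, y0 = y, duration = step$duration,
                           nOut = protocol@nOutPerStep)
    segAct <- seg@activities
    segTimes <- seg@times + tOffset
    if (is.null(act)) {
      act <- segAct
      times <- segTimes
    } else {
      # drop the duplicated boundary row; continuation state is exact
      act <- rbind(act, segAct[-1L, , drop = FALSE])
      times <- c(times, segTimes[-1L])
    }
    y <- segAct[nrow(segAct), ]
    tOffset <- tOffset + step$duration
    boundaries <- c(boundaries, tOffset)
  }
  new("TimeCourse", times = times, activities = act,
      speciesIds = speciesIds(model), segmentBoundaries = boundaries)
}

#' Run a protocol under a gene knockout
#'
#' Convenience composition of [applyKnockout()] and [runProtocol()].
#'
#' @param model a valid [NetworkModel-class].
#' @param speciesId species to knock out (`ymax = 0`).
#' @param protocol a [SimulationProtocol-class].
#' @return a [TimeCourse-class].
#' @export
runKnockoutProtocol <- function(model, speciesId, protocol) {
  runProtocol(applyKnockout(model, speciesId), protocol)
}

.inputReactionIds <- function(model) {
  rx <- model@reactions
  rx$id[vapply(rx$terms, nrow, integer(1L)) == 0L]
}

#' Systematic in-silico knockout screen
#'
#' Computes the steady state of the model under given input settings
#' (default: every input reaction switched on, `w = 1` — a stimulated
#' baseline), then for each target species sets `ymax = 0` and recomputes.
#' Reported deltas are knockout steady state minus baseline. Steady states
#' are found by integration to convergence, which is robust to
#' multistability; per-row non-convergence is flagged, never fatal.
#'
#' @param model a valid [NetworkModel-class].
#' @param inputs named numeric of input-reaction weight settings; defaults
#'   to `w = 1` for every input reaction. Non-input reactions may be set
#'   too.
#' @param targets species ids to knock out, or `"all"` (default).
#' @param tol,tCap passed to [steadyState()].
#' @return a [KnockoutScreenResult-class]; rows ordered by species index.
#' @examples
#' scr <- knockoutScreen(cardiacDevNet(), targets = "NKX25")
#' screenDeltas(scr)["NKX25", "ISL1"]  # ISL1 de-repressed: +1
#' @export
knockoutScreen <- function(model, inputs = NULL, targets = "all",
                           tol = 1e-6, tCap = NULL) {
  if (is.null(inputs)) {
    ids <- .inputReactionIds(model)
    inputs <- stats::setNames(rep(1, length(ids)), ids)
  }
  for (rid in names(inputs))
    model <- setReactionWeight(model, rid, inputs[[rid]])
  if (identical(targets, "all")) {
    targets <- speciesIds(model)
  } else {
    for (id in targets) .speciesIndex(model, id)
    # deterministic ordering by species index, whatever order was given
    targets <- speciesIds(model)[sort(match(targets, speciesIds(model)))]
  }
  base <- steadyState(model, tol = tol, tCap = tCap)
  nsp <- nSpecies(model)
  koStates <- matrix(NA_real_, length(targets), nsp,
                     dimnames = list(targets, speciesIds(model)))
  converged <- logical(length(targets))
  for (i in seq_along(targets)) {
    ko <- applyKnockout(model, targets[i])
    ss <- steadyState(ko, tol = tol, tCap = tCap)
    koStates[i, ] <- ss$y
    converged[i] <- ss$converged
  }
  deltas <- sweep(koStates, 2L, base$y)
  new("KnockoutScreenResult", baseline = base$y, knockoutStates = koStates,
      deltas = deltas, converged = converged,
      baselineConverged = base$converged, targets = targets)
}
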