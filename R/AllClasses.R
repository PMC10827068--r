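#' @import methods
NULL

.SPECIES_COLS <- c("module", "id", "name", "yinit", "ymax", "tau")
.REACTION_COLS <- c("module", "id", "rule", "weight", "n", "ec50")

#' NetworkModel: a logic-based differential equation network
#'
#' Container for a parsed network model: a species table (one row per node,
#' carrying the state parameters `yinit`, `ymax`, `tau`) and a reaction table
#' (one row per activating/inhibiting rule, carrying `weight`, `n`, `ec50`
#' and the parsed rule terms). Species order defines the state-vector index
#' order used by all simulation routines. Columns beyond the recognized set
#' are preserved verbatim as metadata (references, notes, ...).
#'
#' The validity method checks structure only (required columns, term
#' resolution is deliberately deferred): full domain validation, which
#' returns issues rather than raising, is provided by [validateModel()].
#'
#' @slot species data.frame with columns `module`, `id`, `name`, `yinit`,
#'   `ymax`, `tau` plus any metadata columns.
#' @slot reactions data.frame with columns `module`, `id`, `rule`, `weight`,
#'   `n`, `ec50`, a list-column `terms` (each element a data.frame with
#'   `species` and `sign` in `"+"`/`"-"`) and a `target` column, plus
#'   metadata columns.
#'
#' @seealso [networkModel()], [validateModel()], [exampleNet()]
#' @exportClass NetworkModel
setClass("NetworkModel",
  representation(species = "data.frame", reactions = "data.frame"))

setValidity("NetworkModel", function(object) {
  msgs <- character()
  sp <- object@species
  rx <- object@reactions
  miss <- setdiff(.SPECIES_COLS, names(sp))
  if (length(miss))
    msgs <- c(msgs, paste0("species table missing column(s): ",
                           paste(miss, collapse = ", ")))
  miss <- setdiff(c(.REACTION_COLS, "terms", "target"), names(rx))
  if (length(miss))
    msgs <- c(msgs, paste0("reaction table missing column(s): ",
                           paste(miss, collapse = ", ")))
  if (!length(msgs)) {
    if (!is.character(sp$id)) msgs <- c(msgs, "species ids must be character")
    if (!is.character(rx$id)) msgs <- c(msgs, "reaction ids must be character")
    if (!is.list(rx$terms)) msgs <- c(msgs, "reactions$terms must be a list-column")
  }
  if (length(msgs)) msgs else TRUE
})

#' TimeCourse: simulated species activities over time
#'
#' @slot times strictly increasing numeric vector (unitless, tau-units).
#' @slot activities numeric matrix, one row per time point, one column per
#'   species (in model species order).
#' @slot speciesIds column labels for `activities`.
#' @slot segmentBoundaries times at which protocol parameters changed
#'   (includes the start and end of the simulated interval).
#'
#' @seealso [simulateSegment()], [runProtocol()], [writeTimeCourse()]
#' @exportClass TimeCourse
setClass("TimeCourse",
  representation(times = "numeric", activities = "matrix",
                 speciesIds = "character", segmentBoundaries = "numeric"))

setValidity("TimeCourse", function(object) {
  msgs <- character()
  if (nrow(object@activities) != length(object@times))
    msgs <- c(msgs, "activities must have one row per time point")
  if (ncol(object@activities) != length(object@speciesIds))
    msgs <- c(msgs, "activities must have one column per species id")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    msgs <- c(msgs, "times must be strictly increasing")
  if (!all(is.finite(object@activities)))
    msgs <- c(msgs, "activities must be finite")
  if (length(msgs)) msgs else TRUE
})

#' SimulationProtocol: an ordered sequence of staged simulation steps
#'
#' Reproduces the interactive change-parameters-then-simulate workflow:
#' each step carries a duration plus reaction-weight and species-parameter
#' overrides that take effect instantaneously at the segment boundary and
#' persist into later steps. Integration of each step starts from the
#' previous step's final state.
#'
#' @slot steps list of steps as created by [protocolStep()].
#' @slot nOutPerStep number of output points per segment.
#'
#' @seealso [simulationProtocol()], [runProtocol()], [readProtocol()]
#' @exportClass SimulationProtocol
setClass("SimulationProtocol",
  representation(steps = "list", nOutPerStep = "integer"))

setValidity("SimulationProtocol", function(object) {
  msgs <- character()
  if (!length(object@steps)) msgs <- c(msgs, "protocol needs at least one step")
  for (s in object@steps) {
    if (!is.list(s) || is.null(s$duration) || !is.numeric(s$duration) ||
        s$duration <= 0) {
      msgs <- c(msgs, "every step needs a positive numeric duration")
      break
    }
  }
  if (object@nOutPerStep < 2) msgs <- c(msgs, "nOutPerStep must be >= 2")
  if (length(msgs)) msgs else TRUE
})

#' KnockoutScreenResult: outcome of a systematic knockout screen
#'
#' @slot baseline named steady-state activity vector of the unperturbed
#'   (but input-stimulated) model.
#' @slot knockoutStates matrix, one row per knocked-out species, of
#'   steady-state activities under that knockout.
#' @slot deltas matrix of `knockoutStates` minus the baseline (row-wise).
#' @slot converged logical, per-knockout convergence flag.
#' @slot baselineConverged logical scalar.
#' @slot targets ids of the knocked-out species (row labels).
#'
#' @seealso [knockoutScreen()]
#' @exportClass KnockoutScreenResult
setClass("KnockoutScreenResult",
  representation(baseline = "numeric", knockoutStates = "matrix",
                 deltas = "matrix", converged = "logical",
                 baselineConverged = "logical", targets = "character"))

setValidity("KnockoutScreenResult", function(object) {
  msgs <- character()
  if (nrow(object@knockoutStates) != length(object@targets))
    msgs <- c(msgs, "one knockout row per target required")
  if (!identical(dim(object@deltas), dim(object@knockoutStates)))
    msgs <- c(msgs, "deltas and knockoutStates must have identical shape")
  if (length(object@converged) != length(object@targets))
    msgs <- c(msgs, "one convergence flag per target required")
  if (length(msgs)) msgs else TRUE
})
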