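#' @exportMethod nSpecies
#' @exportMethod nReactions
#' @exportMethod speciesIds
#' @exportMethod reactionIds
#' @exportMethod speciesTable
#' @exportMethod reactionTable
#' @exportMethod initialState
#' @exportMethod incomingIndex
#' @exportMethod timePoints
#' @exportMethod activities
#' @exportMethod segmentBoundaries
#' @exportMethod finalState
#' @exportMethod screenDeltas
#' @exportMethod screenBaseline
#' @exportMethod show
#' @exportMethod plot
#' @name ldenet-methods
NULL

#' @rdname NetworkModel-class
#' @param object,x a [NetworkModel-class] (or other package object).
#' @export
setGeneric("nSpecies", function(x) standardGeneric("nSpecies"))
#' @rdname NetworkModel-class
#' @export
setGeneric("nReactions", function(x) standardGeneric("nReactions"))
#' @rdname NetworkModel-class
#' @export
setGeneric("speciesIds", function(x) standardGeneric("speciesIds"))
#' @rdname NetworkModel-class
#' @export
setGeneric("reactionIds", function(x) standardGeneric("reactionIds"))
#' @rdname NetworkModel-class
#' @export
setGeneric("speciesTable", function(x) standardGeneric("speciesTable"))
#' @rdname NetworkModel-class
#' @export
setGeneric("reactionTable", function(x) standardGeneric("reactionTable"))
#' @rdname NetworkModel-class
#' @export
setGeneric("initialState", function(x) standardGeneric("initialState"))
#' @rdname NetworkModel-class
#' @export
setGeneric("incomingIndex", function(x) standardGeneric("incomingIndex"))

setMethod("nSpecies", "NetworkModel", function(x) nrow(x@species))
setMethod("nReactions", "NetworkModel", function(x) nrow(x@reactions))
setMethod("speciesIds", "NetworkModel", function(x) x@species$id)
setMethod("reactionIds", "NetworkModel", function(x) x@reactions$id)
setMethod("speciesTable", "NetworkModel", function(x) x@species)
setMethod("reactionTable", "NetworkModel", function(x) x@reactions)

setMethod("initialState", "NetworkModel", function(x) {
  stats::setNames(x@species$yinit, x@species$id)
})

# target species id -> integer indices of reactions producing it
setMethod("incomingIndex", "NetworkModel", function(x) {
  idx <- split(seq_len(nrow(x@reactions)), x@reactions$target)
  out <- stats::setNames(vector("list", nSpecies(x)), x@species$id)
  out[names(idx)] <- idx
  out[vapply(out, is.null, logical(1L))] <- list(integer())
  out
})

setMethod("show", "NetworkModel", function(object) {
  cat("NetworkModel with", nSpecies(object), "species and",
      nReactions(object), "reactions\n")
  cat("  species:", paste(utils::head(speciesIds(object), 8L),
                          collapse = ", "),
      if (nSpecies(object) > 8L) "..." else "", "\n")
  rx <- object@reactions
  for (i in seq_len(min(nrow(rx), 10L)))
    cat(sprintf("  %s: %s (w=%g, n=%g, ec50=%g)\n", rx$id[i],
                renderRule(rx$terms[[i]], rx$target[i]),
                rx$weight[i], rx$n[i], rx$ec50[i]))
  if (nrow(rx) > 10L) cat("  ... and", nrow(rx) - 10L, "more reactions\n")
})

#' @rdname TimeCourse-class
#' @param x,object a [TimeCourse-class].
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))
#' @rdname TimeCourse-class
#' @export
setGeneric("activities", function(x) standardGeneric("activities"))
#' @rdname TimeCourse-class
#' @export
setGeneric("segmentBoundaries", function(x) standardGeneric("segmentBoundaries"))
#' @rdname TimeCourse-class
#' @export
setGeneric("finalState", function(x) standardGeneric("finalState"))

setMethod("timePoints", "TimeCourse", function(x) x@times)
setMethod("activities", "TimeCourse", function(x) {
  a <- x@activities
  colnames(a) <- x@speciesIds
  a
})
setMethod("speciesIds", "TimeCourse", function(x) x@speciesIds)
setMethod("segmentBoundaries", "TimeCourse", function(x) x@segmentBoundaries)
setMethod("finalState", "TimeCourse", function(x) {
  stats::setNames(x@activities[nrow(x@activities), ], x@speciesIds)
})

#' @rdname TimeCourse-class
#' @param row.names,optional,... passed on conventionally; unused.
#' @export
as.data.frame.TimeCourse <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  data.frame(time = x@times, activities(x), check.names = FALSE)
}

setMethod("show", "TimeCourse", function(object) {
  cat("TimeCourse:", length(object@times), "time points x",
      length(object@speciesIds), "species, t in [",
      min(object@times), ",", max(object@times), "]\n")
  cat("  segment boundaries:",
      paste(signif(object@segmentBoundaries, 6L), collapse = ", "), "\n")
  cat("  final state:\n")
  print(round(finalState(object), 4L))
})

setMethod("show", "SimulationProtocol", function(object) {
  cat("SimulationProtocol with", length(object@steps), "step(s),",
      object@nOutPerStep, "output points per step\n")
  for (i in seq_along(object@steps)) {
    s <- object@steps[[i]]
    chg <- c(
      if (length(s$weights))
        paste0(names(s$weights), "=", unlist(s$weights)),
      if (length(s$species))
        vapply(names(s$species), function(id) {
          paste0(id, "{", paste(names(s$species[[id]]), "=",
                                unlist(s$species[[id]]), collapse = ", "),
                 "}")
        }, character(1L)))
    cat(sprintf("  step %d: duration %g%s\n", i, s$duration,
                if (length(chg)) paste0(" | ", paste(chg, collapse = ", "))
                else " | no changes"))
  }
})

#' @rdname KnockoutScreenResult-class
#' @param x,object a [KnockoutScreenResult-class].
#' @export
setGeneric("screenDeltas", function(x) standardGeneric("screenDeltas"))
#' @rdname KnockoutScreenResult-class
#' @export
setGeneric("screenBaseline", function(x) standardGeneric("screenBaseline"))

setMethod("screenDeltas", "KnockoutScreenResult", function(x) x@deltas)
setMethod("screenBaseline", "KnockoutScreenResult", function(x) x@baseline)

#' @rdname KnockoutScreenResult-class
#' @param row.names,optional,... conventional arguments; unused.
#' @export
as.data.frame.KnockoutScreenResult <- function(x, row.names = NULL,
                                               optional = FALSE, ...) {
  data.frame(knockout = x@targets, converged = x@converged,
             x@deltas, check.names = FALSE)
}

setMethod("show", "KnockoutScreenResult", function(object) {
  cat("KnockoutScreenResult:", length(object@targets),
      "knockout(s), baseline converged:", object@baselineConverged, "\n")
  cat("  baseline steady state:\n")
  print(round(object@baseline, 4L))
  cat("  deltas (knockout - baseline):\n")
  print(round(object@deltas, 4L))
})
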