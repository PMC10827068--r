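#' Export a network as Cytoscape SIF plus edge attributes
#'
#' Writes `<prefix>.sif` with one line per rule term,
#' `SOURCE<TAB>activates|inhibits<TAB>TARGET`, and `<prefix>_edges.tsv`
#' with per-edge attributes (reaction id, weight, n, ec50). Input reactions
#' have no source species, but SIF requires one, so they are emitted from a
#' pseudo-node named `INPUT_<target>`. Line order is deterministic:
#' reaction order, then term order within a rule.
#'
#' @param model a [NetworkModel-class].
#' @param prefix output path prefix (no extension).
#' @return invisibly, the two written paths.
#' @examples
#' p <- exportCytoscapeEdges(exampleNet(), file.path(tempdir(), "exampleNet"))
#' readLines(p[1])
#' @export
exportCytoscapeEdges <- function(model, prefix) {
  rx <- model@reactions
  sif <- character()
  attrs <- list()
  for (j in seq_len(nrow(rx))) {
    terms <- rx$terms[[j]]
    if (!nrow(terms)) {
      edges <- data.frame(source = paste0("INPUT_", rx$target[j]),
                          interaction = "activates",
                          stringsAsFactors = FALSE)
    } else {
      edges <- data.frame(source = terms$species,
                          interaction = ifelse(terms$sign == "-",
                                               "inhibits", "activates"),
                          stringsAsFactors = FALSE)
    }
    sif <- c(sif, paste(edges$source, edges$interaction, rx$target[j],
                        sep = "\t"))
    attrs[[j]] <- data.frame(
      source = edges$source, interaction = edges$interaction,
      target = rx$target[j], reaction = rx$id[j], weight = rx$weight[j],
      n = rx$n[j], ec50 = rx$ec50[j], stringsAsFactors = FALSE)
  }
  sifPath <- paste0(prefix, ".sif")
  tsvPath <- paste0(prefix, "_edges.tsv")
  writeLines(sif, sifPath)
  attrTab <- if (length(attrs)) do.call(rbind, attrs) else
    data.frame(source = character(), interaction = character(),
               target = character(), reaction = character(),
               weight = numeric(), n = numeric(), ec50 = numeric())
  utils::write.table(attrTab, tsvPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(sif = sifPath, edges = tsvPath))
}

#' Write a time course as tidy CSV
#'
#' One row per output point, a `time` column then one column per species
#' id. Segment boundaries are recorded in a `#` comment header so staged
#' protocols can be reconstructed.
#'
#' @param tc a [TimeCourse-class].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
writeTimeCourse <- function(tc, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# segment_boundaries: ",
                    paste(format(tc@segmentBoundaries, digits = 17),
                          collapse = ",")), con)
  utils::write.csv(as.data.frame(tc), con, row.names = FALSE)
  invisible(path)
}

#' Read a time course written by [writeTimeCourse()]
#'
#' @param path CSV path.
#' @return a [TimeCourse-class].
#' @export
readTimeCourse <- function(path) {
  if (!file.exists(path)) stop("time-course file not found: ", path)
  lines <- readLines(path, n = 5L)
  bnd <- grep("^# segment_boundaries:", lines, value = TRUE)
  boundaries <- if (length(bnd))
    as.numeric(strsplit(sub("^# segment_boundaries:\\s*", "", bnd[1L]),
                        ",")[[1L]])
  else numeric()
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  act <- as.matrix(df[, -1L, drop = FALSE])
  new("TimeCourse", times = df$time,
      activities = unname(act), speciesIds = colnames(act),
      segmentBoundaries = boundaries)
}

#' Plot a time course
#'
#' Base-graphics line plot of every species' activity over time, with
#' dotted vertical lines at segment boundaries.
#'
#' @param x a [TimeCourse-class].
#' @param y ignored.
#' @param ... passed to [graphics::matplot()].
#' @export
plotTimeCourse <- function(x, y, ...) {
  graphics::matplot(x@times, x@activities, type = "l", lty = 1,
                    xlab = "time (tau units)", ylab = "activity", ...)
  graphics::abline(v = x@segmentBoundaries, lty = 3, col = "grey")
  graphics::legend("topleft", legend = x@speciesIds, lty = 1,
                   col = seq_along(x@speciesIds), bty = "n", cex = 0.8)
  invisible(x)
}

setMethod("plot", signature(x = "TimeCourse", y = "missing"),
          function(x, y, ...) plotTimeCourse(x, ...))
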