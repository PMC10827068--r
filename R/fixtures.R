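#' The five-species tutorial network
#'
#' A minimal signaling network of five species (A--E) and six reactions:
#' two input reactions feeding A and B (both off at build time, `w = 0`),
#' A activating C, B activating D, the AND/NOT rule `A & !B => E`, and E
#' activating C (so C receives crosstalk from two reactions, OR-combined).
#' All species use `tau = 1`, `yinit = 0`, `ymax = 1`; all reactions use
#' `n = 1.4`, `ec50 = 0.5`.
#'
#' @return a valid [NetworkModel-class].
#' @examples
#' exampleNet()
#' @export
exampleNet <- function() {
  networkModel(
    species = data.frame(
      id = c("A", "B", "C", "D", "E"),
      name = c("A", "B", "C", "D", "E"),
      yinit = 0, ymax = 1, tau = 1,
      stringsAsFactors = FALSE),
    reactions = data.frame(
      id = paste0("r", 1:6),
      rule = c("=> A", "=> B", "A => C", "B => D", "A & !B => E", "E => C"),
      weight = c(0, 0, 1, 1, 1, 1),
      n = 1.4, ec50 = 0.5,
      stringsAsFactors = FALSE))
}

#' The cardiac development gene-regulatory network
#'
#' Five transcription factors governing differentiation of anterior second
#' heart field progenitors: GATA6 (input-driven), NKX25 and TBX1
#' (activated by GATA6, with NKX25 reinforcing TBX1), PITX2 (activated by
#' TBX1 and NKX25), and ISL1, which marks the progenitor state and is
#' repressed by NKX25. ISL1 starts at `yinit = 1` because progenitors begin
#' with high ISL1 while its repressor NKX25 starts at 0; the GATA6 input
#' reaction starts off (`w = 0`). Other parameters are the defaults.
#'
#' @return a valid [NetworkModel-class].
#' @examples
#' cardiacDevNet()
#' @export
cardiacDevNet <- function() {
  networkModel(
    species = data.frame(
      id = c("GATA6", "NKX25", "TBX1", "ISL1", "PITX2"),
      name = c("GATA6", "NKX2-5", "TBX1", "ISL1", "PITX2"),
      yinit = c(0, 0, 0, 1, 0), ymax = 1, tau = 1,
      stringsAsFactors = FALSE),
    reactions = data.frame(
      id = paste0("r", 1:7),
      rule = c("=> GATA6", "GATA6 => NKX25", "GATA6 => TBX1",
               "NKX25 => TBX1", "TBX1 => PITX2", "NKX25 => PITX2",
               "!NKX25 => ISL1"),
      weight = c(0, 1, 1, 1, 1, 1, 1),
      n = 1.4, ec50 = 0.5,
      stringsAsFactors = FALSE))
}

#' Random valid network generator
#'
#' Generates reproducible random models for property testing. Species are
#' named `S1..Sn` with default parameters; each reaction is an input
#' reaction with probability `pInput`, otherwise it has 1--3 source terms
#' drawn uniformly from the species, each inhibiting with probability
#' `pInhib`. At least one input reaction is always present so the network
#' can be driven; isolated species are allowed (they exercise zero-drive
#' decay). Reaction weights are drawn uniformly from `[0, 1]`; `n` and
#' `ec50` keep their defaults. The generated model always passes
#' [validateModel()].
#'
#' @param nSpecies,nReactions counts (>= 1).
#' @param pInput probability a reaction is an input reaction.
#' @param pInhib probability a source term is inhibiting.
#' @param seed integer seed; the global RNG state is restored on exit.
#' @return a valid [NetworkModel-class].
#' @export
randomNetwork <- function(nSpecies = 6L, nReactions = 8L, pInput = 0.25,
                          pInhib = 0.3, seed = 1L) {
  stopifnot(nSpecies >= 1L, nReactions >= 1L,
            pInput >= 0, pInput <= 1, pInhib >= 0, pInhib <= 1)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  ids <- paste0("S", seq_len(nSpecies))
  rules <- character(nReactions)
  isInput <- stats::runif(nReactions) < pInput
  isInput[1L] <- TRUE  # guarantee the network can be driven
  for (j in seq_len(nReactions)) {
    target <- sample(ids, 1L)
    if (isInput[j]) {
      rules[j] <- paste("=>", target)
    } else {
      k <- sample(1:3, 1L)
      src <- sample(ids, min(k, nSpecies))
      bang <- ifelse(stats::runif(length(src)) < pInhib, "!", "")
      rules[j] <- paste(paste0(bang, src, collapse = " & "), "=>", target)
    }
  }
  networkModel(
    species = data.frame(id = ids, stringsAsFactors = FALSE),
    reactions = data.frame(
      id = paste0("r", seq_len(nReactions)),
      rule = rules,
      weight = round(stats::runif(nReactions), 3L),
      stringsAsFactors = FALSE))
}

#' Write the built-in models as workbooks
#'
#' Emits `exampleNet.xlsx` and `cardiacDevNet.xlsx` into `dir`.
#'
#' @param dir output directory, created if needed.
#' @return invisibly, the written paths.
#' @export
writeFixtureWorkbooks <- function(dir = "models") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(file.path(dir, "exampleNet.xlsx"),
             file.path(dir, "cardiacDevNet.xlsx"))
  writeModelWorkbook(exampleNet(), paths[1L])
  writeModelWorkbook(cardiacDevNet(), paths[2L])
  invisible(paths)
}
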