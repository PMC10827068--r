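.PARAM_DEFAULTS <- list(yinit = 0, ymax = 1, tau = 1,
                        weight = 1, n = 1.4, ec50 = 0.5)

.speciesRow <- function(id, name = id, yinit = 0, ymax = 1, tau = 1,
                        module = "") {
  data.frame(module = module, id = id, name = name,
             yinit = yinit, ymax = ymax, tau = tau,
             stringsAsFactors = FALSE)
}

#' Assemble a NetworkModel from species and reaction tables
#'
#' `species` needs at least an `id` column; `name` defaults to the id and
#' blank/missing parameters are filled with the standard defaults
#' (`yinit = 0`, `ymax = 1`, `tau = 1`). `reactions` needs `id` and `rule`
#' columns; `weight = 1`, `n = 1.4`, `ec50 = 0.5` are filled in where
#' missing. Rules are parsed on assembly; extra columns in either table are
#' carried along as metadata. The constructor is deliberately lenient about
#' domain errors (e.g. a rule referencing an undeclared species) so that
#' [validateModel()] can report them all at once.
#'
#' @param species data.frame of species.
#' @param reactions data.frame of reactions.
#' @return a [NetworkModel-class] object.
#' @examples
#' m <- networkModel(
#'   species = data.frame(id = c("A", "B")),
#'   reactions = data.frame(id = c("r1", "r2"), rule = c("=> A", "A => B"),
#'                          weight = c(1, 1)))
#' nSpecies(m)
#' @export
networkModel <- function(species, reactions) {
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(species$id)) stop("species table needs an 'id' column")
  if (is.null(reactions$id) || is.null(reactions$rule))
    stop("reactions table needs 'id' and 'rule' columns")
  species$id <- as.character(species$id)
  reactions$id <- as.character(reactions$id)
  # the apostrophe is a spreadsheet text marker, not part of the rule
  reactions$rule <- sub("^'", "", trimws(as.character(reactions$rule)))
  if (is.null(species$name)) species$name <- species$id
  species$name <- ifelse(is.na(species$name) | !nzchar(species$name),
                         species$id, as.character(species$name))
  if (is.null(species$module)) species$module <- rep("", nrow(species))
  if (is.null(reactions$module)) reactions$module <- rep("", nrow(reactions))
  for (col in c("yinit", "ymax", "tau")) {
    if (is.null(species[[col]])) species[[col]] <- rep(NA_real_, nrow(species))
    species[[col]] <- suppressWarnings(as.numeric(species[[col]]))
    species[[col]][is.na(species[[col]])] <- .PARAM_DEFAULTS[[col]]
  }
  for (col in c("weight", "n", "ec50")) {
    if (is.null(reactions[[col]]))
      reactions[[col]] <- rep(NA_real_, nrow(reactions))
    reactions[[col]] <- suppressWarnings(as.numeric(reactions[[col]]))
    reactions[[col]][is.na(reactions[[col]])] <- .PARAM_DEFAULTS[[col]]
  }
  parsed <- lapply(reactions$rule, function(r) {
    tryCatch(parseRule(r), error = function(e) e)
  })
  bad <- vapply(parsed, inherits, logical(1L), "error")
  if (any(bad))
    stop("unparseable rule(s):\n  ",
         paste(vapply(parsed[bad], conditionMessage, character(1L)),
               collapse = "\n  "))
  reactions$terms <- lapply(parsed, `[[`, "terms")
  reactions$target <- vapply(parsed, `[[`, character(1L), "target")
  species <- species[, c(.SPECIES_COLS,
                         setdiff(names(species), .SPECIES_COLS)), drop = FALSE]
  core <- c(.REACTION_COLS, "terms", "target")
  reactions <- reactions[, c(core, setdiff(names(reactions), core)),
                         drop = FALSE]
  rownames(species) <- NULL
  rownames(reactions) <- NULL
  new("NetworkModel", species = species, reactions = reactions)
}

.issue <- function(severity, location, message) {
  data.frame(severity = severity, location = location, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a NetworkModel
#'
#' Collects every domain violation rather than stopping at the first:
#' duplicate species or reaction ids, invalid id tokens, rules referencing
#' undeclared species, parameters outside their domains (`tau > 0`,
#' `ymax >= 0`, `yinit >= 0`, `0 <= weight <= 1`, `n > 0`, `0 < ec50 < 1`),
#' and the normalized-Hill existence condition `ec50^n < 1/2` without which
#' the activation function cannot pass through its three anchor points.
#' `yinit > ymax` is reported as a warning, everything else as an error.
#'
#' @param model a [NetworkModel-class].
#' @return data.frame with columns `severity` (`"error"`/`"warning"`),
#'   `location` and `message`; zero rows means the model is valid.
#' @export
validateModel <- function(model) {
  sp <- model@species
  rx <- model@reactions
  issues <- list()
  add <- function(sev, loc, msg) issues[[length(issues) + 1L]] <<-
    .issue(sev, loc, msg)

  dup <- unique(sp$id[duplicated(sp$id)])
  for (d in dup) add("error", paste0("species:", d), "duplicate species id")
  dup <- unique(rx$id[duplicated(rx$id)])
  for (d in dup) add("error", paste0("reaction:", d), "duplicate reaction id")
  for (i in seq_len(nrow(sp))) {
    loc <- paste0("species:", sp$id[i])
    if (!grepl(.ID_RE, sp$id[i]))
      add("error", loc, "species id is not a valid token")
    if (!is.finite(sp$tau[i]) || sp$tau[i] <= 0)
      add("error", loc, "tau must be > 0")
    if (!is.finite(sp$ymax[i]) || sp$ymax[i] < 0)
      add("error", loc, "ymax must be >= 0")
    if (!is.finite(sp$yinit[i]) || sp$yinit[i] < 0)
      add("error", loc, "yinit must be >= 0")
    else if (is.finite(sp$ymax[i]) && sp$yinit[i] > sp$ymax[i])
      add("warning", loc, "yinit exceeds ymax")
  }
  for (i in seq_len(nrow(rx))) {
    loc <- paste0("reaction:", rx$id[i])
    if (!is.finite(rx$weight[i]) || rx$weight[i] < 0 || rx$weight[i] > 1)
      add("error", loc, "weight must be in [0, 1]")
    if (!is.finite(rx$n[i]) || rx$n[i] <= 0)
      add("error", loc, "Hill coefficient n must be > 0")
    if (!is.finite(rx$ec50[i]) || rx$ec50[i] <= 0 || rx$ec50[i] >= 1)
      add("error", loc, "ec50 must be in (0, 1)")
    else if (is.finite(rx$n[i]) && rx$n[i] > 0 &&
             rx$ec50[i]^rx$n[i] >= 0.5)
      add("error", loc,
          "ec50^n must be < 1/2 for the normalized Hill function to exist")
    if (!(rx$target[i] %in% sp$id))
      add("error", loc, paste0("rule targets undeclared species '",
                               rx$target[i], "'"))
    terms <- rx$terms[[i]]
    unknown <- setdiff(terms$species, sp$id)
    for (u in unknown)
      add("error", loc, paste0("rule references undeclared species '", u, "'"))
  }
  if (!length(issues))
    return(.issue(character(), character(), character())[0, ])
  out <- do.call(rbind, issues)
  rownames(out) <- NULL
  out
}

.speciesIndex <- function(model, id) {
  i <- match(id, model@species$id)
  if (is.na(i)) stop("unknown species id: ", dQuote(id))
  i
}

.reactionIndex <- function(model, id) {
  i <- match(id, model@reactions$id)
  if (is.na(i)) stop("unknown reaction id: ", dQuote(id))
  i
}

#' Knock out a species
#'
#' Returns a modified copy of the model with the species' maximal activity
#' `ymax` set to 0 — the in-silico equivalent of a gene knockout: the
#' species' production term vanishes and its activity decays to zero with
#' its own time constant. All other parameters are untouched and the input
#' model is never modified.
#'
#' @param model a [NetworkModel-class].
#' @param speciesId id of the species to knock out.
#' @return the perturbed model.
#' @examples
#' ko <- applyKnockout(cardiacDevNet(), "NKX25")
#' speciesTable(ko)[speciesTable(ko)$id == "NKX25", "ymax"]
#' @export
applyKnockout <- function(model, speciesId) {
  i <- .speciesIndex(model, speciesId)
  model@species$ymax[i] <- 0
  model
}

#' Set a reaction weight
#'
#' Returns a modified copy of the model with the given reaction's weight
#' changed; used to switch environmental stimuli on (`w = 1`) and off
#' (`w = 0`, "washout").
#'
#' @param model a [NetworkModel-class].
#' @param reactionId reaction id, e.g. `"r1"`.
#' @param w new weight in `[0, 1]`.
#' @return the modified model.
#' @export
setReactionWeight <- function(model, reactionId, w) {
  if (!is.numeric(w) || length(w) != 1L || !is.finite(w) || w < 0 || w > 1)
    stop("weight must be a single number in [0, 1]")
  i <- .reactionIndex(model, reactionId)
  model@reactions$weight[i] <- w
  model
}

.setSpeciesParams <- function(model, speciesId, ymax = NULL, tau = NULL) {
  i <- .speciesIndex(model, speciesId)
  if (!is.null(ymax)) {
    if (!is.numeric(ymax) || !is.finite(ymax) || ymax < 0)
      stop("ymax must be a finite number >= 0")
    model@species$ymax[i] <- ymax
  }
  if (!is.null(tau)) {
    if (!is.numeric(tau) || !is.finite(tau) || tau <= 0)
      stop("tau must be a finite number > 0")
    model@species$tau[i] <- tau
  }
  model
}
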