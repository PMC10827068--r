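.ID_RE <- "^[A-Za-z0-9_]+$"

#' Parse a reaction rule string
#'
#' Rules follow the minimal logic grammar `[term ("&" term)*] "=>" target`
#' where a term is a species id optionally prefixed by `!` (inhibition).
#' A rule with an empty antecedent (`=> A`) is an input reaction modeling a
#' constitutive environmental stimulus. A single leading apostrophe is
#' stripped first — the spreadsheet convention that keeps Excel from
#' interpreting a leading `=` as a formula.
#'
#' @param ruleText the rule string, e.g. `"A & !B => E"`.
#' @return list with `terms` (data.frame with columns `species`, `sign`,
#'   sign being `"+"` or `"-"`, in textual order; zero rows for an input
#'   reaction) and `target` (the target species id).
#' @examples
#' parseRule("A & !B => E")
#' parseRule("'=> GATA6")   # input reaction
#' @export
parseRule <- function(ruleText) {
  if (!is.character(ruleText) || length(ruleText) != 1L || is.na(ruleText))
    stop("ruleText must be a single string")
  raw <- ruleText
  txt <- sub("^'", "", trimws(ruleText))
  if (!grepl("=>", txt, fixed = TRUE))
    stop("malformed rule (no '=>'): ", dQuote(raw))
  parts <- strsplit(txt, "=>", fixed = TRUE)[[1L]]
  if (length(parts) > 2L)
    stop("malformed rule (multiple '=>'): ", dQuote(raw))
  lhs <- if (length(parts) >= 1L) trimws(parts[1L]) else ""
  rhs <- if (length(parts) == 2L) trimws(parts[2L]) else ""
  if (!nzchar(rhs))
    stop("malformed rule (empty target): ", dQuote(raw))
  if (!grepl(.ID_RE, rhs))
    stop("malformed rule (invalid target token ", dQuote(rhs), "): ", dQuote(raw))
  if (!nzchar(lhs)) {
    return(list(terms = data.frame(species = character(), sign = character(),
                                   stringsAsFactors = FALSE),
                target = rhs))
  }
  toks <- trimws(strsplit(lhs, "&", fixed = TRUE)[[1L]])
  # strsplit drops a trailing empty piece ("A & " -> "A"); re-check directly
  if (grepl("&\\s*$", lhs) || any(!nzchar(toks)))
    stop("malformed rule (dangling '&'): ", dQuote(raw))
  sign <- ifelse(startsWith(toks, "!"), "-", "+")
  ids <- trimws(sub("^!", "", toks))
  bad <- !nzchar(ids) | !grepl(.ID_RE, ids)
  if (any(bad)) {
    if (any(!nzchar(ids)))
      stop("malformed rule ('!' without species id): ", dQuote(raw))
    stop("malformed rule (invalid species token ",
         dQuote(ids[bad][1L]), "): ", dQuote(raw))
  }
  list(terms = data.frame(species = ids, sign = sign, stringsAsFactors = FALSE),
       target = rhs)
}

#' Render parsed rule terms back to a rule string
#'
#' Inverse of [parseRule()] up to whitespace: inhibiting terms are prefixed
#' with `!`, terms joined with `" & "`, then `" => "` and the target.
#'
#' @param terms data.frame with columns `species` and `sign`.
#' @param target target species id.
#' @return canonical rule string.
#' @export
renderRule <- function(terms, target) {
  lhs <- if (nrow(terms)) {
    paste(ifelse(terms$sign == "-", paste0("!", terms$species), terms$species),
          collapse = " & ")
  } else ""
  trimws(paste(lhs, "=>", target))
}
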