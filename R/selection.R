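## Atom-selection mini-grammar:
##   expr    := term ('or' term)*
##   term    := factor ('and' factor)*
##   factor  := 'not' factor | '(' expr ')' | primary
##   primary := 'chain' ID | 'resid' A[-B] | 'resname' NAME |
##              'name' NAME | 'group' COFACTOR
## Matching of names is case-insensitive. Errors report the character
## position of the offending token.

#' Select atoms by expression
#'
#' @param structure An `etk_structure`.
#' @param expression Selection string, e.g. `"resid 1-10 and name CA"`,
#'   `"group FES or group HEME"`, `"not resname HOH"`.
#' @return Sorted integer vector of 1-based atom indices (possibly empty).
#' @examples
#' \dontrun{
#' select_atoms(s, "chain A and resid 340-360")
#' }
#' @export
select_atoms <- function(structure, expression) {
  stopifnot(inherits(structure, "etk_structure"),
            is.character(expression), length(expression) == 1L)
  toks <- .sel_tokenize(expression)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  mask <- .sel_expr(st, structure)
  if (st$pos <= nrow(st$toks))
    .sel_err(st, "unexpected trailing token")
  which(mask)
}

.sel_tokenize <- function(expr) {
  m <- gregexpr("\\(|\\)|[^\\s()]+", expr, perl = TRUE)[[1]]
  if (m[1] == -1) stop("empty selection expression")
  data.frame(
    text = regmatches(expr, list(m))[[1]],
    at = as.integer(m),
    stringsAsFactors = FALSE
  )
}

.sel_err <- function(st, msg) {
  if (st$pos <= nrow(st$toks))
    stop(sprintf("selection error at position %d ('%s'): %s",
                 st$toks$at[st$pos], st$toks$text[st$pos], msg))
  stop("selection error at end of expression: ", msg)
}

.sel_peek <- function(st) {
  if (st$pos > nrow(st$toks)) NA_character_ else st$toks$text[st$pos]
}

.sel_take <- function(st) {
  t <- .sel_peek(st)
  if (is.na(t)) .sel_err(st, "unexpected end of expression")
  st$pos <- st$pos + 1L
  t
}

.sel_expr <- function(st, s) {
  out <- .sel_term(st, s)
  while (!is.na(.sel_peek(st)) && tolower(.sel_peek(st)) == "or") {
    .sel_take(st)
    out <- out | .sel_term(st, s)
  }
  out
}

.sel_term <- function(st, s) {
  out <- .sel_factor(st, s)
  while (!is.na(.sel_peek(st)) && tolower(.sel_peek(st)) == "and") {
    .sel_take(st)
    out <- out & .sel_factor(st, s)
  }
  out
}

.sel_factor <- function(st, s) {
  t <- .sel_peek(st)
  if (is.na(t)) .sel_err(st, "expected a selection clause")
  if (tolower(t) == "not") {
    .sel_take(st)
    return(!.sel_factor(st, s))
  }
  if (t == "(") {
    .sel_take(st)
    out <- .sel_expr(st, s)
    if (is.na(.sel_peek(st)) || .sel_peek(st) != ")")
      .sel_err(st, "expected ')'")
    .sel_take(st)
    return(out)
  }
  .sel_primary(st, s)
}

.sel_primary <- function(st, s) {
  at <- s$atoms
  kw <- tolower(.sel_take(st))
  if (!kw %in% c("chain", "resid", "resname", "name", "group")) {
    st$pos <- st$pos - 1L
    .sel_err(st, "unknown keyword (expected chain/resid/resname/name/group)")
  }
  arg <- .sel_take(st)
  switch(kw,
    chain = toupper(at$chain) == toupper(arg),
    resname = toupper(at$resname) == toupper(arg),
    name = toupper(at$name) == toupper(arg),
    group = {
      g <- s$cofactor_groups[[toupper(arg)]]
      mask <- rep(FALSE, nrow(at))
      if (!is.null(g)) mask[g] <- TRUE
      mask
    },
    resid = {
      ok <- grepl("^[0-9]+(-[0-9]+)?$", arg)
      if (!ok) {
        st$pos <- st$pos - 1L
        .sel_err(st, "resid expects A or A-B")
      }
      ab <- as.integer(strsplit(arg, "-", fixed = TRUE)[[1]])
      if (length(ab) == 1L) at$resid == ab
      else at$resid >= ab[1] & at$resid <= ab[2]
    }
  )
}
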