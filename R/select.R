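## Selection mini-language over topology atom records.
##
## Grammar:  expr    := term ('or' term)*
##           term    := factor ('and' factor)*
##           factor  := 'not' factor | '(' expr ')' | primitive
##           primitive := ('resname'|'name'|'element') VALUE+ | 'unit' INT+ |
##                        'resid' INT[:INT]+ | 'all' | 'none'
## Multiple values after a keyword are an implicit union:
## "resname DG DA" matches either residue name.

.tokenizeSelection <- function(expression) {
  pat <- "\\(|\\)|[^()\\s]+"
  m <- gregexpr(pat, expression, perl = TRUE)[[1]]
  if (m[1] == -1) stop("empty selection expression")
  data.frame(token = regmatches(expression, gregexpr(pat, expression,
                                                     perl = TRUE))[[1]],
             pos = as.integer(m), stringsAsFactors = FALSE)
}

#' Select atoms with a small query language
#'
#' Builds a labelled atom group from a boolean expression over residue
#' names, atom names, elements, unit ids and residue indices. Keywords:
#' `resname`, `name`, `element`, `unit`, `resid` (values may be ranges like
#' `2:13`), `all`, `none`, combined with `and`, `or`, `not` and parentheses.
#' Several values after one keyword form a union: `resname DG DA`.
#'
#' Selections are pure: the same topology and expression always give the
#' same index set.
#'
#' @param topology a [Topology-class].
#' @param expression selection text, e.g. `"resname DG and unit 1"`.
#' @param label label for the group; defaults to the expression.
#' @return a [GroupSelection-class]; empty selections are allowed.
#' @export
#' @examples
#' topo <- telomericTopology()
#' g1 <- selectAtoms(topo, "resname DG and unit 1")
selectAtoms <- function(topology, expression, label = expression) {
  a <- topology@atoms
  toks <- .tokenizeSelection(expression)
  i <- 0
  peek <- function() if (i < nrow(toks)) toks$token[i + 1] else NA_character_
  advance <- function() { i <<- i + 1; toks$token[i] }
  fail <- function(msg) {
    at <- if (i < nrow(toks)) sprintf("'%s' at position %d", toks$token[i + 1],
                                      toks$pos[i + 1]) else "end of expression"
    stop("selection syntax error: ", msg, " near ", at)
  }
  keywords <- c("resname", "name", "element", "unit", "resid", "all", "none",
                "and", "or", "not", "(", ")")

  primitive <- function() {
    kw <- tolower(peek())
    if (is.na(kw)) fail("expected a term")
    if (kw == "all") { advance(); return(rep(TRUE, nrow(a))) }
    if (kw == "none") { advance(); return(rep(FALSE, nrow(a))) }
    if (!kw %in% c("resname", "name", "element", "unit", "resid"))
      fail("expected a keyword")
    advance()
    vals <- character(0)
    while (!is.na(peek()) && !tolower(peek()) %in% keywords)
      vals <- c(vals, advance())
    if (!length(vals)) fail(sprintf("keyword '%s' needs a value", kw))
    switch(kw,
      resname = toupper(a$resname) %in% toupper(vals),
      name    = toupper(a$name) %in% toupper(vals),
      element = toupper(a$element) %in% toupper(vals),
      unit    = a$unit %in% suppressWarnings(as.integer(vals)),
      resid   = {
        ids <- unlist(lapply(vals, function(v) {
          if (grepl("^[0-9]+:[0-9]+$", v)) {
            rng <- as.integer(strsplit(v, ":")[[1]])
            seq(rng[1], rng[2])
          } else {
            id <- suppressWarnings(as.integer(v))
            if (is.na(id)) fail(sprintf("bad resid '%s'", v))
            id
          }
        }))
        a$resid %in% ids
      })
  }

  factor_ <- function() {
    kw <- tolower(peek())
    if (identical(kw, "not")) { advance(); return(!factor_()) }
    if (identical(kw, "(")) {
      advance()
      v <- expr()
      if (!identical(peek(), ")")) fail("expected ')'")
      advance()
      return(v)
    }
    primitive()
  }
  term <- function() {
    v <- factor_()
    while (identical(tolower(peek()), "and")) { advance(); v <- v & factor_() }
    v
  }
  expr <- function() {
    v <- term()
    while (identical(tolower(peek()), "or")) { advance(); v <- v | term() }
    v
  }

  mask <- expr()
  if (i < nrow(toks)) fail("unexpected trailing input")
  GroupSelection(label, which(mask))
}
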