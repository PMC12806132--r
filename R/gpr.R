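#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules encode the boolean gene requirements of a reaction: `and`
#' joins members of an enzyme complex (all genes required), `or` joins
#' isozymes (any gene suffices). The grammar accepts `and`/`or` in any
#' case, parentheses, and whitespace-delimited gene identifiers; `and`
#' binds tighter than `or`. There is no negation operator (none occurs
#' in constraint-based models).
#'
#' @param rule_text A single character string, e.g. `"(g1 and g2) or g3"`.
#'   Empty or whitespace-only input yields `NULL` (no gene association).
#' @return A `gpr` object: a nested list with `kind` one of
#'   `"gene"`, `"and"`, `"or"`; gene nodes carry `gene`, operator nodes
#'   carry `children` (two or more).
#' @examples
#' ast <- parse_gpr("(g1 and g2) or g3")
#' gpr_to_string(ast)
#' @export
parse_gpr <- function(rule_text) {
  stopifnot(is.character(rule_text), length(rule_text) == 1L)
  if (is.na(rule_text) || !nzchar(trimws(rule_text))) return(NULL)
  toks <- gpr_tokenize(rule_text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  ast <- gpr_parse_or(st)
  if (st$pos <= length(st$toks$type)) {
    stop(sprintf("GPR parse error: unexpected token '%s' at position %d",
                 st$toks$text[st$pos], st$toks$at[st$pos]), call. = FALSE)
  }
  ast
}

gpr_tokenize <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  type <- character(0); tok <- character(0); at <- integer(0)
  i <- 1L; n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch == "(" || ch == ")") {
      type <- c(type, ch); tok <- c(tok, ch); at <- c(at, i)
      i <- i + 1L
      next
    }
    j <- i
    while (j <= n && !grepl("^[\\s()]$", chars[j], perl = TRUE)) j <- j + 1L
    word <- paste(chars[i:(j - 1L)], collapse = "")
    lw <- tolower(word)
    type <- c(type, if (lw %in% c("and", "or")) lw else "gene")
    tok <- c(tok, word); at <- c(at, i)
    i <- j
  }
  list(type = type, text = tok, at = at)
}

gpr_peek <- function(st) {
  if (st$pos > length(st$toks$type)) NA_character_ else st$toks$type[st$pos]
}

gpr_parse_or <- function(st) {
  children <- list(gpr_parse_and(st))
  while (identical(gpr_peek(st), "or")) {
    st$pos <- st$pos + 1L
    children <- c(children, list(gpr_parse_and(st)))
  }
  if (length(children) == 1L) children[[1]]
  else structure(list(kind = "or", children = children), class = "gpr")
}

gpr_parse_and <- function(st) {
  children <- list(gpr_parse_atom(st))
  while (identical(gpr_peek(st), "and")) {
    st$pos <- st$pos + 1L
    children <- c(children, list(gpr_parse_atom(st)))
  }
  if (length(children) == 1L) children[[1]]
  else structure(list(kind = "and", children = children), class = "gpr")
}

gpr_parse_atom <- function(st) {
  tt <- gpr_peek(st)
  if (is.na(tt)) {
    stop("GPR parse error: unexpected end of rule", call. = FALSE)
  }
  if (tt == "(") {
    open_at <- st$toks$at[st$pos]
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st)
    if (!identical(gpr_peek(st), ")")) {
      stop(sprintf("GPR parse error: unbalanced parenthesis opened at position %d",
                   open_at), call. = FALSE)
    }
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tt == "gene") {
    g <- st$toks$text[st$pos]
    st$pos <- st$pos + 1L
    return(structure(list(kind = "gene", gene = g), class = "gpr"))
  }
  stop(sprintf("GPR parse error: dangling operator '%s' at position %d",
               st$toks$text[st$pos], st$toks$at[st$pos]), call. = FALSE)
}

#' Render a GPR abstract syntax tree back to rule text
#'
#' Produces a fully parenthesised infix form; `parse_gpr()` of the output
#' recovers an identical tree.
#'
#' @param gpr A `gpr` object or `NULL`.
#' @return A character string (`""` for `NULL`).
#' @export
gpr_to_string <- function(gpr) {
  if (is.null(gpr)) return("")
  switch(gpr$kind,
    gene = gpr$gene,
    and = paste0("(", paste(vapply(gpr$children, gpr_to_string, ""),
                            collapse = " and "), ")"),
    or = paste0("(", paste(vapply(gpr$children, gpr_to_string, ""),
                           collapse = " or "), ")"),
    stop("invalid GPR node kind: ", gpr$kind)
  )
}

#' Genes referenced by a GPR tree
#'
#' @param gpr A `gpr` object or `NULL`.
#' @return Character vector of unique gene identifiers (empty for `NULL`).
#' @export
gpr_genes <- function(gpr) {
  if (is.null(gpr)) return(character(0))
  if (gpr$kind == "gene") return(gpr$gene)
  unique(unlist(lapply(gpr$children, gpr_genes)))
}

#' Score a GPR tree against per-gene expression (minSum)
#'
#' Implements the minSum convention used to turn gene expression into a
#' single reaction activity score: AND nodes (complexes) take the minimum
#' of their children, OR nodes (isozymes) take the sum. Gene leaves look
#' their value up in `expr`; genes absent from `expr` are handled per
#' `missing_policy`: `"skip"` drops them from the parent aggregation
#' (an AND over only-absent children is itself absent), `"zero"` scores
#' them 0. A fully absent tree returns `NA`, signalling that the reaction
#' carries no expression constraint.
#'
#' @param gpr A `gpr` object (or `NULL`, which returns `NA`).
#' @param expr Named numeric vector of expression values in `[0, 1]`.
#' @param missing_policy `"skip"` (default) or `"zero"`.
#' @return A single numeric score, or `NA_real_` if no leaf resolves.
#' @examples
#' evaluate_gpr_minsum(parse_gpr("g1 or g2"), c(g1 = 0.2, g2 = 0.7))
#' @export
evaluate_gpr_minsum <- function(gpr, expr, missing_policy = c("skip", "zero")) {
  missing_policy <- match.arg(missing_policy)
  if (is.null(gpr)) return(NA_real_)
  rec <- function(node) {
    if (node$kind == "gene") {
      v <- if (node$gene %in% names(expr)) unname(expr[[node$gene]]) else NA_real_
      if (is.na(v) && missing_policy == "zero") v <- 0
      return(v)
    }
    vals <- vapply(node$children, rec, numeric(1))
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L) return(NA_real_)
    if (node$kind == "and") min(vals) else sum(vals)
  }
  rec(gpr)
}
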