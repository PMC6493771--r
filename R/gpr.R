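#' Parse a gene-protein-reaction (GPR) rule
#'
#' Parses the boolean gene association string of a reaction into an
#' expression tree.  Both the `and`/`or` and the `&`/`|` spellings are
#' accepted, case-insensitively, with arbitrary parenthesisation.  An empty
#' or whitespace-only string yields `NULL` (no gene association).
#'
#' The tree is a nested list: leaves are `list(op = "gene", gene = <id>)`,
#' internal nodes `list(op = "and"|"or", args = list(...))`.
#'
#' @param text GPR string, e.g. `"(g1 and g2) or g3"`.
#' @return a GPR tree, or `NULL` for an empty rule.
#' @examples
#' gpr_genes(parse_gpr("(g1 and g2) or g3"))
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || length(text) == 0L || is.na(text)) return(NULL)
  text <- trimws(text)
  if (!nzchar(text)) return(NULL)
  toks <- gpr_tokenize(text)
  state <- new.env(parent = emptyenv())
  state$toks <- toks
  state$pos <- 1L
  tree <- gpr_parse_or(state)
  if (state$pos <= length(state$toks)) {
    stop("malformed GPR near token '", state$toks[state$pos], "': ", text)
  }
  tree
}

gpr_tokenize <- function(text) {
  text <- gsub("&&", " & ", text, fixed = TRUE)
  text <- gsub("||", " | ", text, fixed = TRUE)
  text <- gsub("([()&|])", " \\1 ", text)
  toks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

gpr_peek <- function(state) {
  if (state$pos > length(state$toks)) NA_character_ else state$toks[state$pos]
}

gpr_is_op <- function(tok, op) {
  !is.na(tok) && (tolower(tok) == op || tok == switch(op, and = "&", or = "|"))
}

gpr_parse_or <- function(state) {
  args <- list(gpr_parse_and(state))
  while (gpr_is_op(gpr_peek(state), "or")) {
    state$pos <- state$pos + 1L
    args <- c(args, list(gpr_parse_and(state)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
}

gpr_parse_and <- function(state) {
  args <- list(gpr_parse_atom(state))
  while (gpr_is_op(gpr_peek(state), "and")) {
    state$pos <- state$pos + 1L
    args <- c(args, list(gpr_parse_atom(state)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
}

gpr_parse_atom <- function(state) {
  tok <- gpr_peek(state)
  if (is.na(tok)) stop("malformed GPR: unexpected end of rule")
  if (tok == "(") {
    state$pos <- state$pos + 1L
    inner <- gpr_parse_or(state)
    if (!identical(gpr_peek(state), ")")) stop("malformed GPR: missing ')'")
    state$pos <- state$pos + 1L
    return(inner)
  }
  if (tok %in% c(")", "&", "|") || tolower(tok) %in% c("and", "or")) {
    stop("malformed GPR: unexpected token '", tok, "'")
  }
  state$pos <- state$pos + 1L
  list(op = "gene", gene = tok)
}

#' Collect the gene ids of a GPR tree
#'
#' Gene-to-reaction association in the enrichment statistics is plain set
#' membership in the rule, not boolean evaluation, so only the deduplicated
#' leaf set matters.
#'
#' @param tree a GPR tree from [parse_gpr()] (or `NULL`).
#' @return character vector of unique gene ids (empty for `NULL`).
#' @export
gpr_genes <- function(tree) {
  if (is.null(tree)) return(character(0))
  if (identical(tree$op, "gene")) return(tree$gene)
  unique(unlist(lapply(tree$args, gpr_genes), use.names = FALSE))
}

#' Render a GPR tree back to a rule string
#' @param tree a GPR tree (or `NULL`).
#' @return a single string (`""` for `NULL`).
#' @export
gpr_to_string <- function(tree) {
  if (is.null(tree)) return("")
  if (identical(tree$op, "gene")) return(tree$gene)
  parts <- vapply(tree$args, function(a) {
    s <- gpr_to_string(a)
    if (!identical(a$op, "gene")) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", tree$op, " "))
}
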