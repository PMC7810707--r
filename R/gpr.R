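# Gene-protein-reaction (GPR) boolean rules.
#
# A GPR is stored as its string form ("g1 and (g2 or g3)") and parsed on
# demand into a tree: a leaf is a character scalar gene id, an inner node
# is list(op = "and"|"or", args = list(...)). The empty rule ("" or NULL)
# is represented as NULL and evaluates TRUE, so that exchange and
# spontaneous reactions are never penalised by expression-based model
# extraction.

#' Parse a GPR rule string
#'
#' Grammar: `expr := term ('or' term)*`, `term := factor ('and' factor)*`,
#' `factor := gene | '(' expr ')'`. Keywords are case-insensitive; gene
#' ids may contain alphanumerics, `_`, `.`, `:` and `-`.
#'
#' @param rule character scalar (may be `""`/`NA` for the empty rule) or
#'   an already parsed tree, returned unchanged.
#' @return `NULL` for the empty rule, otherwise a parse tree.
#' @examples
#' parse_gpr("g1 and (g2 or g3)")
#' @export
parse_gpr <- function(rule) {
  if (is.null(rule)) return(NULL)
  if (is.list(rule)) return(rule)  # already a tree
  stopifnot(is.character(rule), length(rule) == 1L)
  if (is.na(rule) || !nzchar(trimws(rule))) return(NULL)

  toks <- regmatches(rule, gregexpr("\\(|\\)|[A-Za-z0-9_.:-]+", rule))[[1]]
  leftover <- gsub("\\(|\\)|[A-Za-z0-9_.:-]+|\\s+", "", rule)
  if (nzchar(leftover)) {
    stop(gpr_error(sprintf("unparseable characters in GPR rule: '%s'", rule)))
  }
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  is_kw <- function(t, kw) !is.na(t) && tolower(t) == kw

  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) stop(gpr_error("unexpected end of GPR rule"))
    if (t == "(") {
      advance()
      e <- parse_expr()
      if (!identical(peek(), ")")) stop(gpr_error("unbalanced '(' in GPR rule"))
      advance()
      return(e)
    }
    if (t == ")" || is_kw(t, "and") || is_kw(t, "or")) {
      stop(gpr_error(sprintf("unexpected token '%s' in GPR rule", t)))
    }
    advance()
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (is_kw(peek(), "and")) {
      advance()
      args <- c(args, list(parse_factor()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  }
  parse_expr <- function() {
    args <- list(parse_term())
    while (is_kw(peek(), "or")) {
      advance()
      args <- c(args, list(parse_term()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  }

  tree <- parse_expr()
  if (!is.na(peek())) {
    stop(gpr_error(sprintf("trailing token '%s' in GPR rule", peek())))
  }
  tree
}

gpr_error <- function(msg) {
  errorCondition(msg, class = c("cf_gpr_error", "cf_error"))
}

#' Evaluate a GPR rule against a set of present genes
#'
#' AND nodes require all children, OR nodes any child. The empty rule
#' evaluates `TRUE`: reactions without gene association (exchanges,
#' spontaneous reactions) are treated as always available.
#'
#' @param gpr rule string or parsed tree.
#' @param present_genes character vector of present gene ids.
#' @return logical scalar.
#' @examples
#' evaluate_gpr("g1 and g2", "g1")   # FALSE
#' evaluate_gpr("g1 or g2", "g1")    # TRUE
#' @export
evaluate_gpr <- function(gpr, present_genes) {
  tree <- parse_gpr(gpr)
  if (is.null(tree)) return(TRUE)
  eval_node <- function(node) {
    if (is.character(node)) return(node %in% present_genes)
    vals <- vapply(node$args, eval_node, logical(1))
    if (node$op == "and") all(vals) else any(vals)
  }
  eval_node(tree)
}

#' Genes referenced by a GPR rule
#'
#' Returns the set of leaf gene ids, ignoring the AND/OR structure.
#'
#' @inheritParams evaluate_gpr
#' @return character vector (sorted, unique); empty for the empty rule.
#' @export
gpr_genes <- function(gpr) {
  tree <- parse_gpr(gpr)
  if (is.null(tree)) return(character())
  collect <- function(node) {
    if (is.character(node)) return(node)
    unlist(lapply(node$args, collect))
  }
  sort(unique(collect(tree)))
}

#' Render a parsed GPR tree back to its string form
#' @inheritParams evaluate_gpr
#' @return character scalar; `""` for the empty rule.
#' @export
deparse_gpr <- function(gpr) {
  tree <- parse_gpr(gpr)
  if (is.null(tree)) return("")
  render <- function(node, parent_op = NULL) {
    if (is.character(node)) return(node)
    sep <- if (node$op == "and") " and " else " or "
    s <- paste(vapply(node$args, render, character(1), parent_op = node$op),
               collapse = sep)
    if (!is.null(parent_op) && parent_op != node$op) paste0("(", s, ")") else s
  }
  render(tree)
}
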