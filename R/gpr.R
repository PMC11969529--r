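#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules are boolean expressions over gene identifiers linking genes to
#' the reactions they catalyse, e.g. `"(G0001 and G0002) or G0003"` for an
#' enzyme complex with an isozyme. Accepted operators are `and`/`or`
#' (case-insensitive) and the symbols `&`/`|`; parentheses group
#' sub-expressions. The empty string denotes a reaction with no gene
#' association (spontaneous or unannotated transport).
#'
#' @param text GPR rule as a single string; `NA` or `""` mean "no rule".
#' @return A parse tree: nested lists with elements `op` (`"and"`, `"or"` or
#'   `"gene"`) and either `args` (list of subtrees) or `gene` (identifier);
#'   `NULL` for an empty rule.
#' @examples
#' parse_gpr("(G0001 and G0002) or G0003")
#' @export
parse_gpr <- function(text) {
  if (length(text) != 1L) stop("parse_gpr expects a single string")
  if (is.na(text) || !nzchar(trimws(text))) return(NULL)
  toks <- .gpr_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  tree <- .gpr_parse_or(st)
  if (st$pos <= length(st$toks)) {
    stop(sprintf("malformed GPR %s: unexpected token '%s'", sQuote(text),
                 st$toks[st$pos]))
  }
  tree
}

.gpr_tokenize <- function(text) {
  text <- gsub("&", " and ", text, fixed = TRUE)
  text <- gsub("|", " or ", text, fixed = TRUE)
  text <- gsub("(", " ( ", text, fixed = TRUE)
  text <- gsub(")", " ) ", text, fixed = TRUE)
  toks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

.gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

.gpr_next <- function(st) {
  tok <- .gpr_peek(st)
  st$pos <- st$pos + 1L
  tok
}

.gpr_parse_or <- function(st) {
  args <- list(.gpr_parse_and(st))
  while (!is.na(.gpr_peek(st)) && tolower(.gpr_peek(st)) == "or") {
    .gpr_next(st)
    args <- c(args, list(.gpr_parse_and(st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
}

.gpr_parse_and <- function(st) {
  args <- list(.gpr_parse_atom(st))
  while (!is.na(.gpr_peek(st)) && tolower(.gpr_peek(st)) == "and") {
    .gpr_next(st)
    args <- c(args, list(.gpr_parse_atom(st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
}

.gpr_parse_atom <- function(st) {
  tok <- .gpr_next(st)
  if (is.na(tok)) stop("malformed GPR: unexpected end of expression")
  if (tok == "(") {
    tree <- .gpr_parse_or(st)
    if (is.na(.gpr_peek(st)) || .gpr_next(st) != ")") {
      stop("malformed GPR: missing closing parenthesis")
    }
    return(tree)
  }
  if (tok == ")" || tolower(tok) %in% c("and", "or")) {
    stop(sprintf("malformed GPR: unexpected token '%s'", tok))
  }
  list(op = "gene", gene = tok)
}

#' Evaluate a GPR rule against gene evidence scores
#'
#' Implements the standard complex/isozyme semantics: `and` nodes (subunits
#' of one complex, limited by the scarcest subunit) take the minimum of
#' their children, `or` nodes (interchangeable isozymes) the maximum.
#' Genes absent from `gene_scores` score 0. An empty rule returns `NA`,
#' the "no evidence" sentinel, which is distinct from a measured score of
#' 0; evidence-neutral reactions are never penalised during extraction.
#'
#' @param gpr A rule string or a tree from [parse_gpr()].
#' @param gene_scores Named numeric vector of non-negative evidence scores
#'   (typically mean TPM per gene).
#' @return A single numeric score, or `NA` for an empty rule.
#' @examples
#' evaluate_gpr("G1 and G2", c(G1 = 5, G2 = 2))            # 2
#' evaluate_gpr("(G1 and G2) or G3", c(G1 = 1, G2 = 0, G3 = 4))  # 4
#' @export
evaluate_gpr <- function(gpr, gene_scores) {
  if (is.character(gpr) || (length(gpr) == 1L && is.na(gpr))) gpr <- parse_gpr(gpr)
  if (is.null(gpr)) return(NA_real_)
  stopifnot(is.numeric(gene_scores))
  if (any(!is.finite(gene_scores)) || any(gene_scores < 0)) {
    stop("gene scores must be finite and non-negative")
  }
  .gpr_eval(gpr, gene_scores)
}

.gpr_eval <- function(tree, scores) {
  if (tree$op == "gene") {
    s <- scores[tree$gene]
    return(if (is.na(s)) 0 else unname(s))
  }
  vals <- vapply(tree$args, .gpr_eval, numeric(1), scores = scores)
  if (tree$op == "and") min(vals) else max(vals)
}

#' List the genes referenced by a GPR rule
#'
#' @inheritParams evaluate_gpr
#' @return Character vector of unique gene identifiers (empty for an empty
#'   rule).
#' @export
gpr_genes <- function(gpr) {
  if (is.character(gpr) || (length(gpr) == 1L && is.na(gpr))) gpr <- parse_gpr(gpr)
  if (is.null(gpr)) return(character(0))
  if (identical(gpr$op, "gene")) return(gpr$gene)
  unique(unlist(lapply(gpr$args, gpr_genes)))
}
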