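#' Parse a gene-protein-reaction rule
#'
#' GPR rules are boolean expressions over gene identifiers in which `or`
#' joins isozymes (any one suffices) and `and` joins protein-complex
#' subunits (all are required). The grammar accepts `and`/`or` in any case,
#' the symbols `&`, `&&`, `|`, `||`, and parentheses; any other token is a
#' gene identifier.
#'
#' The returned tree is normalised: nested nodes with the same operator are
#' flattened, duplicate children are merged, and single-child nodes collapse
#' to the child, so `"g1 or g1"` parses to the plain gene `g1`.
#'
#' @param rule character scalar; `""` (or `NA`) yields the empty rule,
#'   meaning the reaction needs no gene and can never be disabled by
#'   knockouts.
#' @return A GPR expression: `NULL` for the empty rule, or a nested list with
#'   fields `op` (`"gene"`, `"and"`, `"or"`), `id` (genes) and `args`
#'   (operator children).
#' @export
#' @examples
#' parse_gpr("g1 and (g2 or g3)")
parse_gpr <- function(rule) {
  if (is.null(rule) || length(rule) == 0 || is.na(rule) ||
      !nzchar(trimws(rule))) {
    return(NULL)
  }
  toks <- gpr_tokenize(rule)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  expr <- gpr_parse_or(st, rule)
  if (st$pos <= length(st$toks)) {
    stop("GPR parse error in \"", rule, "\": unexpected token '",
         st$toks[st$pos], "' at position ", st$pos, call. = FALSE)
  }
  gpr_normalize(expr)
}

gpr_tokenize <- function(rule) {
  rule <- gsub("&&", " & ", rule, fixed = TRUE)
  rule <- gsub("||", " | ", rule, fixed = TRUE)
  rule <- gsub("([()&|])", " \\1 ", rule)
  toks <- strsplit(trimws(rule), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

gpr_peek <- function(st) {
  if (st$pos > length(st$toks)) NA_character_ else st$toks[st$pos]
}

gpr_is_or <- function(tok) !is.na(tok) && (tolower(tok) == "or" || tok == "|")
gpr_is_and <- function(tok) !is.na(tok) && (tolower(tok) == "and" || tok == "&")

gpr_parse_or <- function(st, rule) {
  args <- list(gpr_parse_and(st, rule))
  while (gpr_is_or(gpr_peek(st))) {
    st$pos <- st$pos + 1L
    args[[length(args) + 1L]] <- gpr_parse_and(st, rule)
  }
  if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
}

gpr_parse_and <- function(st, rule) {
  args <- list(gpr_parse_atom(st, rule))
  while (gpr_is_and(gpr_peek(st))) {
    st$pos <- st$pos + 1L
    args[[length(args) + 1L]] <- gpr_parse_atom(st, rule)
  }
  if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
}

gpr_parse_atom <- function(st, rule) {
  tok <- gpr_peek(st)
  if (is.na(tok)) {
    stop("GPR parse error in \"", rule, "\": empty operand at position ",
         st$pos, call. = FALSE)
  }
  if (tok == "(") {
    st$pos <- st$pos + 1L
    e <- gpr_parse_or(st, rule)
    if (!identical(gpr_peek(st), ")")) {
      stop("GPR parse error in \"", rule,
           "\": unbalanced parentheses at position ", st$pos, call. = FALSE)
    }
    st$pos <- st$pos + 1L
    return(e)
  }
  if (tok %in% c(")", "&", "|") || gpr_is_or(tok) || gpr_is_and(tok)) {
    stop("GPR parse error in \"", rule, "\": empty operand before '", tok,
         "' at position ", st$pos, call. = FALSE)
  }
  st$pos <- st$pos + 1L
  list(op = "gene", id = tok)
}

## Flatten same-operator nesting, deduplicate children, collapse singletons.
gpr_normalize <- function(expr) {
  if (is.null(expr) || expr$op == "gene") return(expr)
  kids <- list()
  for (a in expr$args) {
    a <- gpr_normalize(a)
    if (!is.null(a$op) && a$op == expr$op) {
      kids <- c(kids, a$args)
    } else {
      kids <- c(kids, list(a))
    }
  }
  keys <- vapply(kids, gpr_deparse, character(1))
  kids <- kids[!duplicated(keys)]
  if (length(kids) == 1L) return(kids[[1L]])
  list(op = expr$op, args = kids)
}

#' Deparse a GPR expression back to rule text
#'
#' @param expr a GPR expression from [parse_gpr()].
#' @return character scalar; `""` for the empty rule.
#' @export
gpr_deparse <- function(expr) {
  if (is.null(expr)) return("")
  if (expr$op == "gene") return(expr$id)
  parts <- vapply(expr$args, function(a) {
    s <- gpr_deparse(a)
    if (!is.null(a$op) && a$op != "gene" && a$op != expr$op) {
      s <- paste0("(", s, ")")
    }
    s
  }, character(1))
  paste(parts, collapse = paste0(" ", expr$op, " "))
}

#' Genes referenced by a GPR expression
#'
#' @param expr a GPR expression.
#' @return character vector of gene ids (unique, in first-appearance order).
#' @export
gpr_genes <- function(expr) {
  if (is.null(expr)) return(character(0))
  if (expr$op == "gene") return(expr$id)
  unique(unlist(lapply(expr$args, gpr_genes)))
}

#' Evaluate a GPR rule under a gene knockout
#'
#' Genes in `deleted` are set to `FALSE`, all others to `TRUE`. The empty
#' rule evaluates `TRUE`: a reaction without gene annotation cannot be
#' disabled through gene knockouts.
#'
#' @param expr a GPR expression from [parse_gpr()].
#' @param deleted character vector of knocked-out gene ids.
#' @return logical scalar: is the reaction still catalysable?
#' @export
#' @examples
#' evaluate_gpr(parse_gpr("gA or gB"), deleted = "gA")   # isozyme escape
#' evaluate_gpr(parse_gpr("gA and gB"), deleted = "gA")  # complex broken
evaluate_gpr <- function(expr, deleted = character(0)) {
  if (is.null(expr)) return(TRUE)
  switch(expr$op,
    gene = !(expr$id %in% deleted),
    and = all(vapply(expr$args, evaluate_gpr, logical(1), deleted = deleted)),
    or = any(vapply(expr$args, evaluate_gpr, logical(1), deleted = deleted)),
    stop("invalid GPR node op: ", expr$op)
  )
}

#' Minimal gene-deletion sets disabling a GPR rule
#'
#' Computes every inclusion-minimal subset `D` of `allowed` such that the
#' rule evaluates `FALSE` when all genes in `D` are knocked out. Genes
#' outside `allowed` are fixed to "present", so an isozyme branch carried by
#' an unremovable gene makes the rule impossible to disable (empty result).
#'
#' The computation runs structurally over the expression tree: a gene leaf
#' contributes itself (if allowed), an `and` node is disabled by disabling
#' any child (union of child families), an `or` node needs every child
#' disabled (cross-product union). This is the prime-implicant expansion of
#' the rule's complement restricted to `allowed`; intermediate families are
#' pruned to antichains.
#'
#' @param expr a GPR expression.
#' @param allowed character vector of knockable gene ids.
#' @param max_terms guard on the intermediate term count; rules whose
#'   expansion exceeds it abort with an error suggesting a higher cap.
#' @return list of character vectors (each sorted), an antichain; empty list
#'   if the rule cannot be disabled within `allowed`.
#' @export
#' @examples
#' minimal_deletion_sets(parse_gpr("g1 or g2"), c("g1", "g2"))
#' minimal_deletion_sets(parse_gpr("g1 and g2"), c("g1", "g2"))
minimal_deletion_sets <- function(expr, allowed, max_terms = 10000L) {
  fam <- mds_rec(expr, allowed, max_terms)
  fam <- lapply(fam, function(s) sort(unique(s)))
  fam <- unique(fam)
  minimize_family(fam)
}

mds_rec <- function(expr, allowed, max_terms) {
  if (is.null(expr)) return(list())
  if (expr$op == "gene") {
    if (expr$id %in% allowed) return(list(expr$id))
    return(list())
  }
  if (expr$op == "and") {
    fam <- list()
    for (a in expr$args) {
      fam <- c(fam, mds_rec(a, allowed, max_terms))
      if (length(fam) > max_terms) {
        stop("GPR deletion-set expansion exceeded ", max_terms,
             " terms; raise max_terms to compute this rule", call. = FALSE)
      }
    }
    return(fam)
  }
  ## or: every child must be disabled -> cross product
  fam <- list(character(0))
  for (a in expr$args) {
    child <- mds_rec(a, allowed, max_terms)
    if (!length(child)) return(list())  # one branch cannot be disabled
    fam <- unlist(lapply(fam, function(s) {
      lapply(child, function(t) unique(c(s, t)))
    }), recursive = FALSE)
    if (length(fam) > max_terms) {
      stop("GPR deletion-set expansion exceeded ", max_terms,
           " terms; raise max_terms to compute this rule", call. = FALSE)
    }
    fam <- minimize_family(lapply(fam, function(s) sort(s)))
  }
  fam
}

## Remove sets that contain another member; returns an antichain,
## ordered by (size, lexicographic key) for reproducibility.
minimize_family <- function(fam) {
  if (length(fam) <= 1L) return(fam)
  fam <- unique(lapply(fam, function(s) sort(unique(s))))
  sizes <- lengths(fam)
  keys <- vapply(fam, paste, character(1), collapse = "\r")
  ord <- order(sizes, keys)
  fam <- fam[ord]
  keep <- logical(length(fam))
  kept <- list()
  for (i in seq_along(fam)) {
    dominated <- any(vapply(kept, function(s) all(s %in% fam[[i]]), logical(1)))
    if (!dominated) {
      keep[i] <- TRUE
      kept[[length(kept) + 1L]] <- fam[[i]]
    }
  }
  fam[keep]
}
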