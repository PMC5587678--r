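#' Build the gene-knockout matrix G
#'
#' Each row of the binary g x n matrix `G` records the set of reactions
#' disabled by the simultaneous knockout of one functionally interrelated
#' subset of knockable genes: for every reaction, the inclusion-minimal
#' deletion subsets of `allowed = genes_L + target gene` are computed from
#' its GPR rule (see [minimal_deletion_sets()]); the distinct gene sets are
#' pooled as rows, and each row's blocked-reaction pattern is then
#' recomputed *globally* — a row marks every column whose rule fails under
#' that knockout, not only the reaction that generated it. The vector `a`
#' holds each row's gene count, the weights of the knockout-minimisation
#' objective.
#'
#' With one-to-one GPRs and every gene knockable, `G` reduces to the
#' identity pattern over gene-annotated reactions — the reaction-knockout
#' special case.
#'
#' @param model an `irreversible_model` (any `metabolic_model` is accepted;
#'   columns are matched by reaction id).
#' @param genes_L character vector of lowly expressed (knockable) genes.
#' @param target_gene the gene the cut sets must pass through; always added
#'   to the knockable set.
#' @param max_terms guard forwarded to [minimal_deletion_sets()].
#' @return an object of class `knockout_matrix`: list with `gene_sets`
#'   (list of character vectors), `blocked` (list of integer column
#'   indices), `a` (integer gene counts), `G` (sparse pattern matrix),
#'   `allowed`, and `target_gene`.
#' @export
build_knockout_matrix <- function(model, genes_L, target_gene,
                                  max_terms = 10000L) {
  if (!is.null(target_gene) && !(target_gene %in% model$genes)) {
    stop("target gene '", target_gene, "' is not in the model", call. = FALSE)
  }
  allowed <- unique(c(genes_L, target_gene))
  n <- length(model$rxns)
  sets <- list()
  for (j in seq_len(n)) {
    fam <- minimal_deletion_sets(model$rules[[j]], allowed, max_terms)
    sets <- c(sets, fam)
  }
  sets <- unique(lapply(sets, function(s) sort(s)))
  ## global blocked pattern per row
  blocked <- lapply(sets, function(s) {
    which(!vapply(model$rules, evaluate_gpr, logical(1), deleted = s))
  })
  g <- length(sets)
  G <- if (g) {
    Matrix::sparseMatrix(
      i = rep(seq_len(g), lengths(blocked)),
      j = unlist(blocked), x = 1, dims = c(g, n))
  } else {
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(0, n))
  }
  structure(list(gene_sets = sets, blocked = blocked,
                 a = lengths(sets), G = G, allowed = allowed,
                 target_gene = target_gene),
            class = "knockout_matrix")
}

#' @export
print.knockout_matrix <- function(x, ...) {
  cat("<knockout_matrix> ", length(x$gene_sets), " rows over ",
      length(x$allowed), " knockable genes\n", sep = "")
  if (!is.null(x$target_gene)) {
    cat("  target gene: ", x$target_gene, " (in ",
        sum(vapply(x$gene_sets, function(s) x$target_gene %in% s,
                   logical(1))), " rows)\n", sep = "")
  }
  invisible(x)
}

#' Tidy a knockout matrix
#'
#' @param x a `knockout_matrix`.
#' @param ... unused.
#' @return tibble with one row per G row: `row`, `genes` (list column),
#'   `a`, `n_blocked`.
#' @export
tidy.knockout_matrix <- function(x, ...) {
  tibble::tibble(row = seq_along(x$gene_sets),
                 genes = x$gene_sets,
                 a = x$a,
                 n_blocked = lengths(x$blocked))
}

## rows of K whose gene set contains `gene`
rows_with_gene <- function(K, gene) {
  which(vapply(K$gene_sets, function(s) gene %in% s, logical(1)))
}
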