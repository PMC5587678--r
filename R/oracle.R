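#' Brute-force enumeration of genetic minimal cut sets
#'
#' Ground truth for small models: iterates over all subsets of
#' `candidate_genes` in deterministic order (by size, then
#' lexicographically), reports a subset when it cuts the target task (see
#' [check_cut()]) and no previously reported set is contained in it. By
#' this subset-free screening the reported families form an antichain of
#' inclusion-minimal cuts. Intended as the validation oracle for the MILP
#' path; a hard guard refuses candidate sets larger than 20 genes.
#'
#' @param model a `metabolic_model`.
#' @param candidate_genes genes the cuts may draw from (default: all model
#'   genes).
#' @param max_size largest subset size to test (default: all of them).
#' @param tol flux tolerance for [check_cut()].
#' @return an `oracle_report`: list with `families` (list of sorted gene
#'   sets), `candidate_genes`, `max_size` and `exhaustive` (`TRUE` when
#'   every subset up to `|candidates|` was screened).
#' @export
#' @examples
#' rep <- brute_force_gmcs(make_fixture("isozyme_demo"))
#' rep$families
brute_force_gmcs <- function(model, candidate_genes = model$genes,
                             max_size = length(candidate_genes),
                             tol = 1e-6) {
  candidate_genes <- sort(unique(candidate_genes))
  if (length(candidate_genes) > 20) {
    stop(length(candidate_genes), " candidate genes exceed the exhaustive-",
         "search guard (20); use the MILP enumeration instead",
         call. = FALSE)
  }
  families <- list()
  sizes <- seq_len(min(max_size, length(candidate_genes)))
  for (k in sizes) {
    combos <- utils::combn(candidate_genes, k, simplify = FALSE)
    for (s in combos) {
      dominated <- any(vapply(families, function(f) all(f %in% s),
                              logical(1)))
      if (dominated) next
      if (check_cut(model, s, tol)) {
        families[[length(families) + 1L]] <- s
      }
    }
  }
  exhaustive <- max_size >= length(candidate_genes)
  structure(list(families = families, candidate_genes = candidate_genes,
                 max_size = max_size, exhaustive = exhaustive),
            class = "oracle_report")
}

#' @export
print.oracle_report <- function(x, ...) {
  cat("<oracle_report> ", length(x$families), " minimal cut set(s) over ",
      length(x$candidate_genes), " candidate genes",
      if (x$exhaustive) " (exhaustive)" else
        sprintf(" (up to size %d)", x$max_size), "\n", sep = "")
  for (f in x$families) cat("  {", paste(f, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Cut sets passing through a particular gene
#'
#' @param report an `oracle_report`.
#' @param target_gene gene id.
#' @return list of gene sets containing `target_gene`.
#' @export
filter_through_gene <- function(report, target_gene) {
  Filter(function(s) target_gene %in% s, report$families)
}
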