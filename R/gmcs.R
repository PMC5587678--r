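#' Does a gene set cut the target task?
#'
#' Disables every reaction whose GPR rule evaluates false under the
#' knockout (both bounds set to zero), then maximises the target flux under
#' steady state. The set is a cut when the maximal flux falls below `tol`.
#' This LP predicate is shared by the MILP pipeline and the brute-force
#' oracle, so the two routes can only disagree on search, never on
#' feasibility.
#'
#' @param model a `metabolic_model` (any form).
#' @param gene_set character vector of knocked-out genes.
#' @param tol flux tolerance.
#' @return logical scalar.
#' @export
#' @examples
#' m <- make_fixture("isozyme_demo")
#' check_cut(m, "gA")             # FALSE: gB keeps the isozyme step alive
#' check_cut(m, c("gA", "gB"))    # TRUE
check_cut <- function(model, gene_set, tol = 1e-6) {
  off <- !vapply(model$rules, evaluate_gpr, logical(1), deleted = gene_set)
  lb <- model$lb; ub <- model$ub
  lb[off] <- 0; ub[off] <- 0
  j <- match(model$target, model$rxns)
  obj <- numeric(length(model$rxns)); obj[j] <- 1
  res <- lp_solve(obj, model$S, rep("=", length(model$mets)),
                  numeric(length(model$mets)), lb = lb, ub = ub,
                  maximize = TRUE)
  if (res$status == "infeasible") return(TRUE)
  if (res$status == "unbounded") return(FALSE)
  res$objective < tol
}

#' Verify and shrink a candidate solution to a gMCS
#'
#' The union of the gene sets of the selected knockout rows is first
#' verified to cut the target task (an explicit LP check — a failure here
#' indicates the big-M linking was too loose and the constant should be
#' raised). Because selected rows may overlap in genes, the union can
#' exceed inclusion minimality, so genes other than the target are then
#' greedily removed in a deterministic order (longest id first, ties
#' lexicographic) whenever the remainder still cuts. Minimality of the
#' result is verified gene-by-gene: no single-gene removal may leave a cut,
#' which by monotonicity of the cut property certifies that no proper
#' subset cuts.
#'
#' @param candidate result of [solve_next()].
#' @param model the `irreversible_model` the MILP was built on.
#' @param K the [build_knockout_matrix()] used.
#' @param target_gene the gene the cut must contain.
#' @param tol flux tolerance for the LP checks.
#' @return one-row `gmcs_set` tibble (columns `target_gene`, `genes`,
#'   `objective`, `status`, `verified_cut`, `verified_minimal`).
#' @export
extract_and_shrink <- function(candidate, model, K, target_gene,
                               tol = 1e-6) {
  stopifnot(candidate$status %in% c("optimal", "feasible"))
  gene_set <- sort(unique(unlist(K$gene_sets[candidate$active_rows])))
  if (!check_cut(model, gene_set, tol)) {
    stop("internal consistency failure: the selected knockout rows do not ",
         "block the target task; raise big_m in gmcs_config()",
         call. = FALSE)
  }
  ## deterministic shrink order: longest gene id first, ties lexicographic
  repeat {
    removable <- setdiff(gene_set, target_gene)
    removable <- removable[order(-nchar(removable), removable)]
    dropped <- FALSE
    for (h in removable) {
      trial <- setdiff(gene_set, h)
      if (check_cut(model, trial, tol)) {
        gene_set <- trial
        dropped <- TRUE
        break
      }
    }
    if (!dropped) break
  }
  verified_cut <- check_cut(model, gene_set, tol)
  verified_minimal <- all(vapply(gene_set, function(h) {
    !check_cut(model, setdiff(gene_set, h), tol)
  }, logical(1)))
  gmcs_set_row(target_gene, sort(gene_set), candidate$objective,
               candidate$status, verified_cut, verified_minimal)
}

gmcs_set_row <- function(target_gene, genes, objective, status,
                         verified_cut = NA, verified_minimal = NA) {
  out <- tibble::tibble(target_gene = target_gene,
                        genes = list(genes),
                        objective = as.numeric(objective),
                        status = status,
                        verified_cut = verified_cut,
                        verified_minimal = verified_minimal)
  class(out) <- c("gmcs_set", class(out))
  out
}

#' Enumerate genetic minimal cut sets through a target gene
#'
#' The full pipeline on a preprocessed model: builds the knockout matrix
#' over `genes_L` plus the target gene, assembles the dual-problem MILP,
#' and then alternates solve / verify-shrink / exclusion-cut until
#' `max_solutions` distinct cut sets are found, the MILP becomes infeasible
#' (enumeration exhausted), or a solve times out. Duplicate gene sets
#' arising from different row selections are dropped. Every returned set is
#' verified to cut the task and to be inclusion-minimal; a solve that times
#' out without an incumbent yields a single `timeout_none` row with an
#' empty gene set.
#'
#' @param model a `metabolic_model`; reversible models are split (and, by
#'   default, FVA-reduced) internally.
#' @param genes_L character vector of lowly expressed genes (the knockout
#'   alphabet); the target gene is added automatically.
#' @param target_gene gene whose essentiality is being probed.
#' @param cfg a [gmcs_config()].
#' @param reduce run [fva_reduce()] before the search (default `TRUE`).
#' @return a `gmcs_set` tibble, one row per distinct gMCS.
#' @export
#' @examples
#' m <- make_fixture("figure1_like")
#' enumerate_gmcs(m, genes_L = c("g4", "g5", "g9"), target_gene = "g2")
enumerate_gmcs <- function(model, genes_L, target_gene,
                           cfg = gmcs_config(), reduce = TRUE) {
  if (!inherits(model, "irreversible_model")) {
    model <- split_reversible(model)
    if (reduce) model <- fva_reduce(model)
  }
  genes_L <- intersect(genes_L, model$genes)
  K <- build_knockout_matrix(model, genes_L, target_gene,
                             max_terms = cfg$max_terms)
  milp <- build_dual_milp(model, K, target_gene, cfg)
  results <- NULL
  seen <- character(0)
  deadline <- proc.time()[["elapsed"]] + cfg$time_limit_s * cfg$max_solutions
  while (is.null(results) || nrow(results) < cfg$max_solutions) {
    cand <- solve_next(milp, cfg)
    if (cand$status == "infeasible") break
    if (cand$status == "timeout_no_incumbent") {
      if (is.null(results)) {
        results <- gmcs_set_row(target_gene, character(0), NA_real_,
                                "timeout_none", FALSE, FALSE)
      }
      break
    }
    row <- extract_and_shrink(cand, model, K, target_gene, tol = cfg$tol)
    row$status <- if (cand$status == "optimal") "proven_optimal" else
      "feasible_shrunk"
    key <- paste(row$genes[[1]], collapse = "\r")
    ## a shrunk set can fail full minimality when the target gene itself is
    ## redundant (a subset without it already cuts): not a gMCS, exclude
    ## and move on
    if (row$verified_cut && row$verified_minimal && !(key %in% seen)) {
      seen <- c(seen, key)
      results <- if (is.null(results)) row else
        dplyr::bind_rows(results, row)
    }
    milp <- add_exclusion_cut(milp, cand$active_rows, row$genes[[1]])
    if (proc.time()[["elapsed"]] > deadline) break
  }
  if (is.null(results)) {
    results <- gmcs_set_row(target_gene, character(0), NA_real_,
                            "infeasible", FALSE, FALSE)[0, ]
  }
  class(results) <- c("gmcs_set", setdiff(class(results), "gmcs_set"))
  results
}

#' Essentiality verdict for a target gene in one expression context
#'
#' A gene is predicted essential when at least one of its gMCSs has every
#' partner gene (the set minus the target) lowly expressed: the context has
#' already silenced the backup routes, so losing the target alone blocks
#' the task. The verdict is `"undetermined"` when the enumeration produced
#' no usable cut set (time-out). Cut sets are inherent to the reference
#' network, so a single enumeration can be mapped onto any number of
#' expression contexts.
#'
#' @param gmcs a `gmcs_set` tibble (or list of character vectors).
#' @param genes_L lowly expressed genes of the context.
#' @param target_gene the gene under scrutiny.
#' @return tibble with `target_gene`, `verdict` (`"essential"`,
#'   `"not_essential"`, `"undetermined"`) and `witness` (list column; the
#'   first qualifying cut set, `character(0)` otherwise).
#' @export
essentiality_verdict <- function(gmcs, genes_L, target_gene) {
  sets <- if (inherits(gmcs, "data.frame")) {
    ok <- gmcs$status != "timeout_none" & lengths(gmcs$genes) > 0
    gmcs$genes[ok]
  } else {
    gmcs
  }
  timeout_only <- inherits(gmcs, "data.frame") &&
    (nrow(gmcs) == 0 || all(gmcs$status == "timeout_none"))
  sets <- Filter(function(s) target_gene %in% s, sets)
  if (!length(sets)) {
    verdict <- if (timeout_only) "undetermined" else "not_essential"
    return(tibble::tibble(target_gene = target_gene, verdict = verdict,
                          witness = list(character(0))))
  }
  for (s in sets) {
    partners <- setdiff(s, target_gene)
    if (all(partners %in% genes_L)) {
      return(tibble::tibble(target_gene = target_gene,
                            verdict = "essential", witness = list(s)))
    }
  }
  tibble::tibble(target_gene = target_gene, verdict = "not_essential",
                 witness = list(character(0)))
}

#' @export
print.gmcs_set <- function(x, ...) {
  cat("<gmcs_set> ", nrow(x), " cut set(s)\n", sep = "")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %d. {%s}  [%s%s]\n", i,
                paste(x$genes[[i]], collapse = ", "), x$status[i],
                if (isTRUE(x$verified_minimal[i])) ", verified minimal"
                else ""))
  }
  invisible(x)
}

#' Tidy a gMCS result set
#'
#' @param x a `gmcs_set`.
#' @param ... unused.
#' @return plain tibble with `target_gene`, `genes` (comma-joined string),
#'   `size`, `objective`, `status`, `verified_cut`, `verified_minimal`.
#' @export
tidy.gmcs_set <- function(x, ...) {
  tibble::tibble(target_gene = x$target_gene,
                 genes = vapply(x$genes, paste, character(1),
                                collapse = ","),
                 size = lengths(x$genes),
                 objective = x$objective,
                 status = x$status,
                 verified_cut = x$verified_cut,
                 verified_minimal = x$verified_minimal)
}

#' Summarise a gMCS result set
#'
#' @param x a `gmcs_set`.
#' @param ... unused.
#' @return one-row tibble: counts per status, smallest and largest set
#'   size, and whether all results were verified.
#' @export
glance.gmcs_set <- function(x, ...) {
  solved <- x$status %in% c("proven_optimal", "feasible_shrunk")
  tibble::tibble(n_sets = sum(solved),
                 n_optimal = sum(x$status == "proven_optimal"),
                 n_timeout = sum(x$status == "timeout_none"),
                 min_size = if (any(solved)) min(lengths(x$genes[solved]))
                            else NA_integer_,
                 max_size = if (any(solved)) max(lengths(x$genes[solved]))
                            else NA_integer_,
                 all_verified = all(x$verified_cut[solved] &
                                      x$verified_minimal[solved]))
}
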