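#' Construct a constraint-based metabolic model
#'
#' The central container: an m x n stoichiometric matrix `S` (products
#' positive, educts negative), per-reaction flux bounds, GPR rules, the gene
#' universe and the id of the target reaction (the metabolic task to block,
#' typically biomass). `S` is stored sparse so genome-scale models fit
#' comfortably.
#'
#' @param mets character vector of metabolite ids (rows of `S`).
#' @param rxns character vector of reaction ids (columns of `S`).
#' @param S numeric matrix or `Matrix` sparse matrix, `length(mets)` x
#'   `length(rxns)`.
#' @param lb,ub numeric flux bounds per reaction (arbitrary flux units).
#' @param gpr character vector of GPR rule strings per reaction (`""` for
#'   none).
#' @param genes character vector of gene ids; defaults to the genes
#'   referenced by the rules.
#' @param target id of the target reaction; must be one of `rxns`.
#' @param id optional model id.
#' @return An object of class `metabolic_model`: a list with the fields
#'   above plus `rules`, the parsed GPR expressions.
#' @export
metabolic_model <- function(mets, rxns, S, lb, ub, gpr = rep("", length(rxns)),
                            genes = NULL, target, id = "model") {
  S <- methods::as(methods::as(Matrix::Matrix(S, sparse = TRUE), "dMatrix"),
                   "CsparseMatrix")
  dimnames(S) <- list(mets, rxns)
  rules <- lapply(gpr, parse_gpr)
  if (is.null(genes)) genes <- unique(unlist(lapply(rules, gpr_genes)))
  m <- structure(
    list(id = id, mets = as.character(mets), rxns = as.character(rxns),
         S = S, lb = as.numeric(lb), ub = as.numeric(ub),
         gpr = as.character(gpr), rules = rules,
         genes = as.character(genes), target = target),
    class = "metabolic_model")
  validate_model(m)
}

#' Validate a metabolic model
#'
#' Checks the structural invariants: matching dimensions, ordered bounds,
#' a known target reaction and GPR rules that only reference genes present
#' in the model's gene list.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly unchanged, or an error naming the offending
#'   record.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  m <- length(model$mets); n <- length(model$rxns)
  if (nrow(model$S) != m || ncol(model$S) != n) {
    stop("model '", model$id, "': S is ", nrow(model$S), "x", ncol(model$S),
         " but there are ", m, " metabolites and ", n, " reactions",
         call. = FALSE)
  }
  if (anyDuplicated(model$rxns)) {
    stop("model '", model$id, "': duplicated reaction id '",
         model$rxns[duplicated(model$rxns)][1], "'", call. = FALSE)
  }
  if (anyDuplicated(model$mets)) {
    stop("model '", model$id, "': duplicated metabolite id '",
         model$mets[duplicated(model$mets)][1], "'", call. = FALSE)
  }
  if (length(model$lb) != n || length(model$ub) != n) {
    stop("model '", model$id, "': bounds length != number of reactions",
         call. = FALSE)
  }
  bad <- which(model$lb > model$ub)
  if (length(bad)) {
    stop("model '", model$id, "': reaction '", model$rxns[bad[1]],
         "' has lower bound ", model$lb[bad[1]], " > upper bound ",
         model$ub[bad[1]], call. = FALSE)
  }
  if (!(model$target %in% model$rxns)) {
    stop("model '", model$id, "': target reaction '", model$target,
         "' not found", call. = FALSE)
  }
  for (j in seq_len(n)) {
    unknown <- setdiff(gpr_genes(model$rules[[j]]), model$genes)
    if (length(unknown)) {
      stop("model '", model$id, "': GPR of reaction '", model$rxns[j],
           "' references unknown gene '", unknown[1], "'", call. = FALSE)
    }
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n", sep = "")
  cat("  metabolites: ", length(x$mets), "\n", sep = "")
  cat("  reactions:   ", length(x$rxns),
      " (", sum(x$lb < 0), " reversible)\n", sep = "")
  cat("  genes:       ", length(x$genes), "\n", sep = "")
  cat("  target:      ", x$target, "\n", sep = "")
  if (inherits(x, "irreversible_model")) {
    cat("  irreversible form (", nrow(x$origin), " columns mapped)\n",
        sep = "")
  }
  invisible(x)
}

#' Exchange reactions of a model
#'
#' Exchange (boundary) reactions are identified structurally as columns of
#' `S` with exactly one non-zero entry: they import or drain a single
#' metabolite across the system boundary.
#'
#' @param model a `metabolic_model`.
#' @return character vector of reaction ids.
#' @export
exchange_reactions <- function(model) {
  nz <- Matrix::colSums(model$S != 0)
  model$rxns[nz == 1]
}

#' Maximum flux through a reaction
#'
#' Solves the flux-balance LP: maximise the flux of `rxn` subject to the
#' steady-state constraint `S r = 0` and the model's bounds.
#'
#' @param model a `metabolic_model`.
#' @param rxn reaction id; defaults to the model's target reaction.
#' @return numeric scalar, the optimal flux (0 when the LP has no positive
#'   optimum); errors if the flux balance is infeasible.
#' @export
max_flux <- function(model, rxn = model$target) {
  j <- match(rxn, model$rxns)
  if (is.na(j)) stop("unknown reaction '", rxn, "'", call. = FALSE)
  n <- length(model$rxns)
  obj <- numeric(n); obj[j] <- 1
  res <- lp_solve(obj, model$S, rep("=", length(model$mets)),
                  numeric(length(model$mets)),
                  lb = model$lb, ub = model$ub, maximize = TRUE)
  if (res$status == "infeasible") {
    stop("flux balance infeasible for model '", model$id, "'", call. = FALSE)
  }
  if (res$status == "unbounded") return(Inf)
  res$objective
}
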