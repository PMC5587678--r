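#' Apply a growth-medium specification
#'
#' Overwrites the flux bounds of the listed exchange reactions; with
#' `closed_by_default = TRUE` every exchange reaction *not* listed has its
#' uptake closed (lower bound raised to 0), emulating a defined medium where
#' only the stated nutrients are available. Secretion is never touched.
#'
#' @param model a `metabolic_model`.
#' @param medium tibble/data frame with columns `reaction`, `lower_bound`,
#'   `upper_bound` (see [read_medium_table()]).
#' @param closed_by_default close uptake on unlisted exchange reactions.
#' @return the model with updated bounds.
#' @export
apply_medium <- function(model, medium, closed_by_default = FALSE) {
  ex <- exchange_reactions(model)
  if (nrow(medium)) {
    bad <- setdiff(medium$reaction, ex)
    if (length(bad)) {
      stop("medium lists non-exchange or unknown reaction(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (any(medium$lower_bound > medium$upper_bound)) {
      i <- which(medium$lower_bound > medium$upper_bound)[1]
      stop("medium bound for '", medium$reaction[i], "' has lb > ub",
           call. = FALSE)
    }
  }
  if (closed_by_default) {
    unlisted <- setdiff(ex, medium$reaction)
    j <- match(unlisted, model$rxns)
    model$lb[j] <- pmax(model$lb[j], 0)
  }
  if (nrow(medium)) {
    j <- match(medium$reaction, model$rxns)
    model$lb[j] <- medium$lower_bound
    model$ub[j] <- medium$upper_bound
  }
  validate_model(model)
  model
}

#' Split reversible reactions into irreversible pairs
#'
#' Every reaction with a negative lower bound becomes two columns: the
#' forward copy with bounds `[0, ub]` and a reverse copy (negated
#' stoichiometry, id suffixed `_rev`) with bounds `[0, -lb]`. Both copies
#' inherit the parent's GPR rule, so a knockout disables the pair together.
#' Afterwards all fluxes are non-negative, the form the dual-problem MILP is
#' built on. Non-finite upper bounds are capped at `inf_bound`.
#'
#' @param model a `metabolic_model`.
#' @param inf_bound finite cap replacing infinite bounds (flux units).
#' @return an `irreversible_model`: the model plus an `origin` tibble
#'   mapping each column to `(parent reaction, direction)`.
#' @export
split_reversible <- function(model, inf_bound = 1000) {
  if (inherits(model, "irreversible_model")) return(model)
  lb <- model$lb; ub <- model$ub
  ub[!is.finite(ub)] <- inf_bound
  lb[!is.finite(lb)] <- -inf_bound
  rev_idx <- which(lb < 0)
  rev_ids <- if (length(rev_idx)) paste0(model$rxns[rev_idx], "_rev")
             else character(0)
  ids <- c(model$rxns, rev_ids)
  gpr <- c(model$gpr, model$gpr[rev_idx])
  parent <- c(model$rxns, model$rxns[rev_idx])
  direction <- c(rep("fwd", length(model$rxns)), rep("rev", length(rev_idx)))
  new_lb <- rep(0, length(ids))
  new_ub <- c(pmax(ub, 0), -lb[rev_idx])
  S2 <- if (length(rev_idx)) {
    cbind(model$S, -model$S[, rev_idx, drop = FALSE])
  } else {
    model$S
  }
  out <- metabolic_model(model$mets, ids, S2, new_lb, new_ub, gpr,
                         genes = model$genes, target = model$target,
                         id = model$id)
  out$origin <- tibble::tibble(column = ids, parent = parent,
                               direction = direction)
  class(out) <- c("irreversible_model", class(out))
  out
}

#' Remove blocked reactions by flux-variability analysis
#'
#' On an irreversible model the minimum flux of every column is 0, so one
#' maximisation LP per column suffices: columns whose maximal flux falls
#' below `tol` can never carry flux and are removed, together with
#' metabolites that no longer participate in any reaction. The target
#' reaction must survive; if it is itself blocked the metabolic task is
#' infeasible in this medium and an error is raised.
#'
#' The operation is idempotent and preserves the maximal target flux.
#'
#' @param model an `irreversible_model` from [split_reversible()].
#' @param tol blocked-flux tolerance on LP objective values.
#' @return the reduced `irreversible_model`.
#' @export
fva_reduce <- function(model, tol = 1e-9) {
  stopifnot(inherits(model, "irreversible_model"))
  stopifnot(tol > 0)
  n <- length(model$rxns)
  m <- length(model$mets)
  vmax <- numeric(n)
  dirs <- rep("=", m)
  rhs <- numeric(m)
  for (j in seq_len(n)) {
    obj <- numeric(n); obj[j] <- 1
    res <- lp_solve(obj, model$S, dirs, rhs, lb = model$lb, ub = model$ub,
                    maximize = TRUE)
    vmax[j] <- if (res$status == "optimal") res$objective else 0
  }
  keep <- vmax >= tol
  tj <- match(model$target, model$rxns)
  if (!keep[tj]) {
    stop("target task infeasible in this medium: reaction '", model$target,
         "' cannot carry flux", call. = FALSE)
  }
  if (all(keep)) return(model)
  S2 <- model$S[, keep, drop = FALSE]
  live_met <- Matrix::rowSums(S2 != 0) > 0
  out <- metabolic_model(model$mets[live_met], model$rxns[keep],
                         S2[live_met, , drop = FALSE],
                         model$lb[keep], model$ub[keep], model$gpr[keep],
                         genes = model$genes, target = model$target,
                         id = model$id)
  out$origin <- model$origin[keep, , drop = FALSE]
  class(out) <- c("irreversible_model", class(out))
  out
}

#' Standard preprocessing pipeline
#'
#' Convenience wrapper: [apply_medium()] (when a medium is given), then
#' [split_reversible()], then [fva_reduce()].
#'
#' @param model a `metabolic_model`.
#' @param medium optional medium table.
#' @param closed_by_default see [apply_medium()].
#' @param tol see [fva_reduce()].
#' @param inf_bound see [split_reversible()].
#' @return a reduced `irreversible_model`.
#' @export
preprocess_model <- function(model, medium = NULL, closed_by_default = FALSE,
                             tol = 1e-9, inf_bound = 1000) {
  if (!is.null(medium)) {
    model <- apply_medium(model, medium, closed_by_default)
  }
  fva_reduce(split_reversible(model, inf_bound = inf_bound), tol = tol)
}
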