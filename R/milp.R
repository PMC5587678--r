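#' Solve a mixed-integer linear program by branch and bound
#'
#' Depth-first branch and bound over a designated set of binary variables,
#' with LP relaxations solved by [lp_solve()]. Branching is deterministic
#' (most fractional binary, smallest index on ties; the zero branch is
#' explored first), so repeated runs return the same incumbent.
#'
#' Pruning uses the integrality of the objective when all objective
#' coefficients on binary variables are integers and continuous variables
#' carry zero cost, which is the case for the knockout-minimisation
#' objective.
#'
#' @param obj,mat,dir,rhs,lb,ub as in [lp_solve()].
#' @param bin_idx integer indices of the binary variables.
#' @param time_limit wall-clock budget in seconds.
#' @param int_tol tolerance for calling a relaxed binary integral.
#'
#' @return list with `status` (`"optimal"`, `"feasible"` for a time-limited
#'   incumbent, `"infeasible"`, `"timeout_no_incumbent"`), `objective`, `x`.
#' @keywords internal
#' @export
milp_solve <- function(obj, mat, dir, rhs, lb, ub, bin_idx,
                       time_limit = 300, int_tol = 1e-6) {
  mat <- as.matrix(mat)
  n <- length(obj)
  lb <- rep_len(lb, n)
  ub <- rep_len(ub, n)
  t0 <- proc.time()[["elapsed"]]

  if (!length(bin_idx)) {
    rel <- lp_solve(obj, mat, dir, rhs, lb, ub)
    st <- if (rel$status == "optimal") "optimal" else "infeasible"
    return(list(status = st, objective = rel$objective, x = rel$x))
  }

  integral_obj <- all(obj[-bin_idx] == 0) &&
    all(abs(obj[bin_idx] - round(obj[bin_idx])) < 1e-12)

  best_obj <- Inf
  best_x <- NULL
  timed_out <- FALSE

  ## stack of nodes: each node fixes some binaries via lb/ub overrides
  stack <- list(list(lb = lb, ub = ub))
  while (length(stack)) {
    if (proc.time()[["elapsed"]] - t0 > time_limit) {
      timed_out <- TRUE
      break
    }
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL

    rel <- lp_solve(obj, mat, dir, rhs, node$lb, node$ub)
    if (rel$status != "optimal") next   # infeasible or unbounded branch
    bound <- rel$objective
    if (integral_obj) bound <- ceiling(bound - 1e-6)
    if (bound >= best_obj) next

    zf <- rel$x[bin_idx]
    frac <- abs(zf - round(zf))
    if (all(frac <= int_tol)) {
      ## integral candidate
      if (rel$objective < best_obj - 1e-9) {
        best_obj <- rel$objective
        best_x <- rel$x
        best_x[bin_idx] <- round(best_x[bin_idx])
      }
      next
    }
    j <- bin_idx[which.max(frac)]
    up <- node; up$lb[j] <- 1; up$ub[j] <- 1
    dn <- node; dn$lb[j] <- 0; dn$ub[j] <- 0
    ## push 1-branch first so the 0-branch is explored first (LIFO)
    stack[[length(stack) + 1L]] <- up
    stack[[length(stack) + 1L]] <- dn
  }

  if (is.null(best_x)) {
    status <- if (timed_out) "timeout_no_incumbent" else "infeasible"
    return(list(status = status, objective = NA_real_, x = NULL))
  }
  status <- if (timed_out) "feasible" else "optimal"
  list(status = status, objective = best_obj, x = best_x)
}
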