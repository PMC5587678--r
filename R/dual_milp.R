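#' Enumeration configuration for the gMCS search
#'
#' Bundles the constants of the dual-problem MILP and the enumeration
#' protocol. `r_star` is the minimal flux demanded of the target task in the
#' primal, `c` forces the task constraint to be limiting in the dual, `b`
#' forces the target gene's knockout rows to be active, and `alpha`/`big_m`
#' are the small/large constants linking the binary selection variables `z`
#' to the continuous dual variables `v` (`z = 0` forces `v = 0`, `z = 1`
#' forces `v >= alpha`). The defaults follow common minimal-cut-set MILP
#' practice; the returned gene-set families are insensitive to doubling
#' `big_m` and halving `alpha`.
#'
#' @param max_solutions number of cut sets to enumerate.
#' @param time_limit_s wall-clock budget per MILP solve, seconds.
#' @param alpha,big_m,c,b,r_star positive MILP constants.
#' @param max_terms GPR expansion guard, see [minimal_deletion_sets()].
#' @param tol flux tolerance used by verification LPs.
#' @return list of class `gmcs_config`.
#' @export
gmcs_config <- function(max_solutions = 3, time_limit_s = 300,
                        alpha = 1e-3, big_m = 1e3, c = 1, b = 1, r_star = 1,
                        max_terms = 10000L, tol = 1e-6) {
  stopifnot(max_solutions >= 1, time_limit_s > 0, alpha > 0, big_m > alpha,
            c > 0, b > 0, r_star > 0)
  structure(list(max_solutions = max_solutions, time_limit_s = time_limit_s,
                 alpha = alpha, big_m = big_m, c = c, b = b, r_star = r_star,
                 max_terms = max_terms, tol = tol),
            class = "gmcs_config")
}

#' Build the dual-problem MILP for gMCS search
#'
#' Assembles the mixed-integer program whose feasible points certify, via
#' duality, that a selected combination of gene-knockout rows blocks the
#' target task, and whose optimum is a genetic minimal cut set through the
#' target gene.
#'
#' Variables (in column order): `u` (one free variable per metabolite, the
#' duals of the steady-state constraints), `v >= 0` (one per knockout row),
#' `w >= 0` (the dual of the target-task demand), `x >= 0` (n + 1
#' redundancy multipliers), `eps, delta >= 0` (per-row slacks active only on
#' unselected rows), and binary `z` (row selection). Constraint blocks:
#'
#' * dual feasibility `S'u + G'v - t w >= 0` over reaction columns;
#' * task activation `r* w >= c`;
#' * target forcing: the summed `v` over every row containing the target
#'   gene is at least `b` (with a single such row this is the plain
#'   unit-vector constraint);
#' * redundancy: `S x = 0`, `G x - eps + delta = d`, `-t'x + r* x_{n+1} =
#'   0`, where `d` marks the target rows;
#' * linking: `alpha z <= v <= M z` and `eps + delta <= M (1 - z)`.
#'
#' The objective minimises `sum(a_k z_k)`, the weighted number of knocked-
#' out genes. Free/continuous variables are capped at `±M` for boundedness.
#'
#' @param model an `irreversible_model` (all lower bounds zero).
#' @param K a [build_knockout_matrix()] result whose rows cover the target
#'   gene.
#' @param target_gene gene id the cut sets must contain.
#' @param cfg a [gmcs_config()].
#' @return list of class `dual_milp` with the constraint system, variable
#'   index maps and accumulated exclusion cuts.
#' @export
build_dual_milp <- function(model, K, target_gene, cfg = gmcs_config()) {
  stopifnot(inherits(model, "irreversible_model"))
  g <- length(K$gene_sets)
  if (g == 0) {
    stop("knockout matrix is empty: no knockout can block any reaction",
         call. = FALSE)
  }
  tgt_rows <- rows_with_gene(K, target_gene)
  if (!length(tgt_rows)) {
    stop("no knockout row contains target gene '", target_gene,
         "'; no gMCS through it can exist", call. = FALSE)
  }
  m <- length(model$mets)
  n <- length(model$rxns)
  tj <- match(model$target, model$rxns)

  ## variable layout
  iu <- seq_len(m)
  iv <- m + seq_len(g)
  iw <- m + g + 1L
  ix <- m + g + 1L + seq_len(n + 1L)
  ie <- m + g + n + 2L + seq_len(g)
  id <- m + g + n + g + 2L + seq_len(g)
  iz <- m + g + n + 2L * g + 2L + seq_len(g)
  nv <- m + g + n + 3L * g + 2L

  St <- Matrix::t(model$S)
  Gt <- Matrix::t(K$G)
  tvec <- numeric(n); tvec[tj] <- 1
  M <- cfg$big_m

  rows <- list(); dirs <- character(0); rhs <- numeric(0)
  add <- function(r, d, b) {
    rows[[length(rows) + 1L]] <<- r
    dirs <<- c(dirs, d); rhs <<- c(rhs, b)
  }
  zrow <- function() numeric(nv)

  ## dual feasibility: S'u + G'v - t w >= 0   (n rows)
  blockA <- Matrix::Matrix(0, n, nv, sparse = TRUE)
  blockA[, iu] <- St
  blockA[, iv] <- Gt
  blockA[, iw] <- -tvec
  ## task activation: r* w >= c
  r_task <- zrow(); r_task[iw] <- cfg$r_star
  ## target forcing: sum v over target rows >= b
  r_force <- zrow(); r_force[iv[tgt_rows]] <- 1
  ## redundancy block:
  ##   S x = 0                      (m rows)
  ##   G x - eps + delta = d        (g rows)
  ##   -t'x + r* x_{n+1} = 0        (1 row)
  blockR <- Matrix::Matrix(0, m + g + 1L, nv, sparse = TRUE)
  blockR[seq_len(m), ix[seq_len(n)]] <- model$S
  blockR[m + seq_len(g), ix[seq_len(n)]] <- K$G
  blockR[m + seq_len(g), ie] <- -Matrix::Diagonal(g)
  blockR[m + seq_len(g), id] <- Matrix::Diagonal(g)
  blockR[m + g + 1L, ix[seq_len(n)]] <- -tvec
  blockR[m + g + 1L, ix[n + 1L]] <- cfg$r_star
  dvec <- numeric(m + g + 1L)
  dvec[m + tgt_rows] <- 1
  ## linking: v - M z <= 0 ; v - alpha z >= 0 ; eps + delta + M z <= M
  blockL <- Matrix::Matrix(0, 3L * g, nv, sparse = TRUE)
  blockL[seq_len(g), iv] <- Matrix::Diagonal(g)
  blockL[seq_len(g), iz] <- -M * Matrix::Diagonal(g)
  blockL[g + seq_len(g), iv] <- Matrix::Diagonal(g)
  blockL[g + seq_len(g), iz] <- -cfg$alpha * Matrix::Diagonal(g)
  blockL[2L * g + seq_len(g), ie] <- Matrix::Diagonal(g)
  blockL[2L * g + seq_len(g), id] <- Matrix::Diagonal(g)
  blockL[2L * g + seq_len(g), iz] <- M * Matrix::Diagonal(g)

  mat <- rbind(blockA,
               Matrix::Matrix(matrix(c(r_task, r_force), 2, nv,
                                     byrow = TRUE), sparse = TRUE),
               blockR, blockL)
  dir <- c(rep(">=", n), ">=", ">=",
           rep("=", m + g + 1L),
           rep("<=", g), rep(">=", g), rep("<=", g))
  rhs <- c(numeric(n), cfg$c, cfg$b, dvec, numeric(g), numeric(g),
           rep(M, g))

  lb <- numeric(nv); ub <- numeric(nv)
  lb[iu] <- -M;  ub[iu] <- M
  lb[iv] <- 0;   ub[iv] <- M
  lb[iw] <- 0;   ub[iw] <- M
  lb[ix] <- 0;   ub[ix] <- M
  lb[ie] <- 0;   ub[ie] <- M
  lb[id] <- 0;   ub[id] <- M
  lb[iz] <- 0;   ub[iz] <- 1

  obj <- numeric(nv)
  obj[iz] <- K$a

  structure(list(obj = obj, mat = mat, dir = dir, rhs = rhs,
                 lb = lb, ub = ub, bin_idx = iz,
                 idx = list(u = iu, v = iv, w = iw, x = ix, eps = ie,
                            delta = id, z = iz),
                 K = K, model = model, target_gene = target_gene,
                 cfg = cfg, n_cuts = 0L),
            class = "dual_milp")
}

#' Solve the current MILP for the next candidate
#'
#' @param milp a `dual_milp`.
#' @param cfg optional config overriding the one stored in `milp` (the time
#'   limit is taken from here).
#' @return list with `status` (`"optimal"`, `"feasible"`, `"infeasible"`,
#'   `"timeout_no_incumbent"`), `active_rows` (indices of selected knockout
#'   rows) and `objective`.
#' @export
solve_next <- function(milp, cfg = milp$cfg) {
  res <- milp_solve(milp$obj, milp$mat, milp$dir, milp$rhs, milp$lb,
                    milp$ub, milp$bin_idx, time_limit = cfg$time_limit_s)
  if (res$status %in% c("infeasible", "timeout_no_incumbent")) {
    return(list(status = res$status, active_rows = integer(0),
                objective = NA_real_))
  }
  z <- res$x[milp$idx$z]
  list(status = res$status, active_rows = which(z > 0.5),
       objective = res$objective)
}

#' Append exclusion cuts after a solution
#'
#' Adds the integer cut `sum(z_k, k in active) <= |active| - 1`, which bars
#' the exact row selection from reappearing, plus a gene-level cut barring
#' any future selection whose row-union covers the reported gene set: for
#' each gene of the set an auxiliary indicator (continuous, forced to 1 by
#' any active row containing the gene) is added, and their sum is bounded
#' by `|gene_set| - 1`. Without the second cut a different row combination
#' could re-derive the same (or a superset) gene set.
#'
#' @param milp a `dual_milp`.
#' @param active_rows integer indices of the selected rows.
#' @param gene_set the verified, shrunk cut set reported for this solution.
#' @return the extended `dual_milp`.
#' @export
add_exclusion_cut <- function(milp, active_rows, gene_set = NULL) {
  if (!length(active_rows)) {
    stop("cannot add an exclusion cut for an empty row selection",
         call. = FALSE)
  }
  nv <- ncol(milp$mat)
  r <- numeric(nv)
  r[milp$idx$z[active_rows]] <- 1
  milp$mat <- rbind(milp$mat, Matrix::Matrix(matrix(r, 1, nv),
                                             sparse = TRUE))
  milp$dir <- c(milp$dir, "<=")
  milp$rhs <- c(milp$rhs, length(active_rows) - 1)

  if (!is.null(gene_set) && length(gene_set)) {
    p <- length(gene_set)
    rows_per_gene <- lapply(gene_set, function(h) rows_with_gene(milp$K, h))
    n_force <- sum(lengths(rows_per_gene))
    old_nv <- ncol(milp$mat)
    ## append p auxiliary columns y_h in [0, 1]
    milp$mat <- cbind(milp$mat,
                      Matrix::Matrix(0, nrow(milp$mat), p, sparse = TRUE))
    milp$obj <- c(milp$obj, numeric(p))
    milp$lb <- c(milp$lb, numeric(p))
    milp$ub <- c(milp$ub, rep(1, p))
    ## forcing rows: y_h - z_k >= 0 for every row k containing gene h
    force <- Matrix::Matrix(0, n_force, ncol(milp$mat), sparse = TRUE)
    fr <- 0L
    for (h in seq_len(p)) {
      for (k in rows_per_gene[[h]]) {
        fr <- fr + 1L
        force[fr, old_nv + h] <- 1
        force[fr, milp$idx$z[k]] <- -1
      }
    }
    cover <- Matrix::Matrix(0, 1, ncol(milp$mat), sparse = TRUE)
    cover[1, old_nv + seq_len(p)] <- 1
    milp$mat <- rbind(milp$mat, force, cover)
    milp$dir <- c(milp$dir, rep(">=", n_force), "<=")
    milp$rhs <- c(milp$rhs, numeric(n_force), p - 1)
  }
  milp$n_cuts <- milp$n_cuts + 1L
  milp
}
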