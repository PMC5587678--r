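#' Solve a linear program
#'
#' Dense two-phase simplex solver for the small linear programs the package
#' builds: flux-variability maximisations, cut-verification flux balances and
#' the relaxations inside the branch-and-bound MILP layer. Handles general
#' variable bounds (including free and negatively bounded variables) and
#' mixed `<=` / `>=` / `=` constraint rows.
#'
#' The solver uses Dantzig pricing with an automatic switch to Bland's rule
#' after a pivot budget, which guarantees termination on degenerate problems.
#' It is written for the model sizes this package targets on the desk
#' (hundreds of variables); genome-scale flux balance is supported but slow.
#'
#' @param obj numeric objective coefficients, one per variable.
#' @param mat constraint matrix (dense or `Matrix` sparse), one row per
#'   constraint.
#' @param dir character vector of constraint directions, each one of
#'   `"<="`, `">="`, `"="`.
#' @param rhs numeric right-hand sides.
#' @param lb,ub variable bounds, recycled to the number of variables;
#'   `-Inf`/`Inf` allowed.
#' @param maximize logical; maximise instead of minimise.
#' @param tol numeric feasibility/pivot tolerance.
#'
#' @return A list with elements `status` (`"optimal"`, `"infeasible"` or
#'   `"unbounded"`), `objective` and `x` (the primal solution on the original
#'   variables, `NULL` unless optimal).
#' @keywords internal
#' @export
lp_solve <- function(obj, mat, dir, rhs, lb = 0, ub = Inf,
                     maximize = FALSE, tol = 1e-9) {
  mat <- as.matrix(mat)
  n <- length(obj)
  stopifnot(ncol(mat) == n, nrow(mat) == length(rhs), length(dir) == nrow(mat))
  lb <- rep_len(lb, n)
  ub <- rep_len(ub, n)
  if (any(lb > ub)) {
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  }
  if (maximize) obj <- -obj

  ## Shift/split variables so every solver variable is >= 0.
  ## map: list per original variable describing the reconstruction.
  cols <- list()   # columns of transformed problem, as list of (orig index, sign)
  shift <- numeric(n)
  extra_rows <- list()  # upper-bound rows on transformed columns
  for (j in seq_len(n)) {
    if (is.finite(lb[j])) {
      shift[j] <- lb[j]
      cols[[length(cols) + 1L]] <- c(j, 1)
      if (is.finite(ub[j])) {
        extra_rows[[length(extra_rows) + 1L]] <-
          c(length(cols), ub[j] - lb[j])
      }
    } else if (is.finite(ub[j])) {
      ## x = ub - x', x' >= 0
      shift[j] <- ub[j]
      cols[[length(cols) + 1L]] <- c(j, -1)
    } else {
      cols[[length(cols) + 1L]] <- c(j, 1)
      cols[[length(cols) + 1L]] <- c(j, -1)
    }
  }
  nt <- length(cols)
  orig <- vapply(cols, `[`, numeric(1), 1L)
  sgn <- vapply(cols, `[`, numeric(1), 2L)

  A <- mat[, orig, drop = FALSE] * rep(sgn, each = nrow(mat))
  b <- rhs - as.vector(mat %*% shift)
  cvec <- obj[orig] * sgn
  obj_const <- sum(obj * shift)

  if (length(extra_rows)) {
    ub_mat <- matrix(0, length(extra_rows), nt)
    ub_rhs <- numeric(length(extra_rows))
    for (i in seq_along(extra_rows)) {
      ub_mat[i, extra_rows[[i]][1]] <- 1
      ub_rhs[i] <- extra_rows[[i]][2]
    }
    A <- rbind(A, ub_mat)
    b <- c(b, ub_rhs)
    dir <- c(dir, rep("<=", length(extra_rows)))
  }

  res <- simplex_core(cvec, A, dir, b, tol)
  if (res$status != "optimal") {
    return(list(status = res$status, objective = NA_real_, x = NULL))
  }
  x <- numeric(n)
  for (k in seq_len(nt)) {
    x[orig[k]] <- x[orig[k]] + sgn[k] * res$x[k]
  }
  x <- x + shift
  objective <- sum(obj * x)
  if (maximize) objective <- -objective
  list(status = "optimal", objective = objective, x = x)
}

## Two-phase tableau simplex on: min c'x  s.t.  A x (dir) b, x >= 0.
## Returns status and the transformed-variable solution.
simplex_core <- function(cvec, A, dir, b, tol = 1e-9) {
  m <- nrow(A)
  n <- ncol(A)

  ## normalise rows to b >= 0
  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
    dir[neg] <- c("<=" = ">=", ">=" = "<=", "=" = "=")[dir[neg]]
  }

  n_slack <- sum(dir != "=")
  need_art <- dir == "=" | dir == ">="
  n_art <- sum(need_art)

  ncols <- n + n_slack + n_art
  T_ <- matrix(0, m, ncols)
  T_[, seq_len(n)] <- A
  slack_idx <- integer(0)
  art_idx <- integer(0)
  basis <- integer(m)
  sc <- n
  ac <- n + n_slack
  for (i in seq_len(m)) {
    if (dir[i] == "<=") {
      sc <- sc + 1L
      T_[i, sc] <- 1
      basis[i] <- sc
      slack_idx <- c(slack_idx, sc)
    } else if (dir[i] == ">=") {
      sc <- sc + 1L
      T_[i, sc] <- -1
      slack_idx <- c(slack_idx, sc)
      ac <- ac + 1L
      T_[i, ac] <- 1
      basis[i] <- ac
      art_idx <- c(art_idx, ac)
    } else {
      ac <- ac + 1L
      T_[i, ac] <- 1
      basis[i] <- ac
      art_idx <- c(art_idx, ac)
    }
  }

  ## Phase 1
  if (n_art > 0) {
    c1 <- numeric(ncols)
    c1[art_idx] <- 1
    ph1 <- simplex_iterate(T_, b, c1, basis, tol, forbid = integer(0))
    if (ph1$status == "unbounded") {
      return(list(status = "infeasible", x = NULL))
    }
    if (ph1$objective > 1e-7) {
      return(list(status = "infeasible", x = NULL))
    }
    T_ <- ph1$T_; b <- ph1$b; basis <- ph1$basis
    ## drive artificials out of the basis where possible
    for (i in seq_len(m)) {
      if (basis[i] %in% art_idx) {
        cand <- which(abs(T_[i, seq_len(n + n_slack)]) > tol)
        cand <- setdiff(cand, basis)
        if (length(cand)) {
          j <- cand[1]
          piv <- T_[i, j]
          T_[i, ] <- T_[i, ] / piv
          b[i] <- b[i] / piv
          other <- setdiff(seq_len(m), i)
          fac <- T_[other, j]
          T_[other, ] <- T_[other, ] - outer(fac, T_[i, ])
          b[other] <- b[other] - fac * b[i]
          basis[i] <- j
        }
        ## rows where no pivot exists are redundant; the artificial stays
        ## basic at zero and is forbidden from re-entering in phase 2.
      }
    }
  }

  c2 <- numeric(ncols)
  c2[seq_len(n)] <- cvec
  ph2 <- simplex_iterate(T_, b, c2, basis, tol, forbid = art_idx)
  if (ph2$status == "unbounded") {
    return(list(status = "unbounded", x = NULL))
  }
  x <- numeric(ncols)
  x[ph2$basis] <- ph2$b
  list(status = "optimal", x = x[seq_len(n)], objective = ph2$objective)
}

## Pivot loop: min c'x over the tableau (T_, b) with the given basis.
simplex_iterate <- function(T_, b, cvec, basis, tol, forbid,
                            bland_after = 2000L, max_iter = 100000L) {
  m <- nrow(T_)
  ncols <- ncol(T_)
  allowed <- setdiff(seq_len(ncols), forbid)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) {
      stop("simplex iteration limit exceeded; the LP appears to cycle")
    }
    cb <- cvec[basis]
    red <- cvec - as.vector(crossprod(T_, cb))  # reduced costs
    red[forbid] <- Inf
    if (iter <= bland_after) {
      j <- allowed[which.min(red[allowed])]
      if (red[j] >= -tol) break
    } else {
      negs <- allowed[red[allowed] < -tol]
      if (!length(negs)) break
      j <- negs[1]
    }
    col <- T_[, j]
    pos <- which(col > tol)
    if (!length(pos)) {
      return(list(status = "unbounded"))
    }
    ratio <- b[pos] / col[pos]
    rmin <- min(ratio)
    ties <- pos[ratio <= rmin + tol]
    i <- ties[which.min(basis[ties])]  # Bland-style leaving tie-break
    piv <- T_[i, j]
    T_[i, ] <- T_[i, ] / piv
    b[i] <- b[i] / piv
    other <- setdiff(seq_len(m), i)
    fac <- T_[other, j]
    nz <- other[abs(fac) > 0]
    if (length(nz)) {
      T_[nz, ] <- T_[nz, ] - outer(fac[abs(fac) > 0], T_[i, ])
      b[nz] <- b[nz] - fac[abs(fac) > 0] * b[i]
    }
    b[b < 0 & b > -tol] <- 0
    basis[i] <- j
  }
  list(status = "optimal", T_ = T_, b = b, basis = basis,
       objective = sum(cvec[basis] * b))
}
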