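#' Solve a linear program with a dense two-phase simplex
#'
#' Minimises (or maximises) `obj %*% x` subject to `A x (dir) rhs`,
#' `0 <= x <= upper`. All variables are implicitly nonnegative; finite upper
#' bounds are handled as additional rows. Bland's anti-cycling rule is used
#' throughout, which guarantees termination at the cost of some speed --
#' acceptable at the problem sizes this package targets (tens of variables).
#'
#' No pre-installed LP solver is available to this package, and the flux
#' systems solved here are tiny, so a self-contained textbook implementation
#' is used rather than an external backend.
#'
#' @param obj numeric objective coefficients, length n.
#' @param A dense constraint matrix (m x n).
#' @param dir character vector of m comparison directions: `"<="`, `">="`, `"="`.
#' @param rhs numeric right-hand sides, length m.
#' @param upper optional numeric upper bounds per variable (`Inf` allowed).
#' @param maximize if `TRUE`, maximise the objective.
#' @param tol pivot tolerance.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `x` (primal solution, length n) and `objval`.
#' @keywords internal
lp_solve <- function(obj, A, dir, rhs, upper = NULL, maximize = FALSE,
                     tol = 1e-9) {
  n <- length(obj)
  if (is.null(dim(A))) A <- matrix(A, ncol = n)
  stopifnot(ncol(A) == n, nrow(A) == length(rhs), length(dir) == nrow(A))
  if (!all(dir %in% c("<=", ">=", "="))) stop("bad constraint direction")

  # fold finite upper bounds into <= rows
  if (!is.null(upper)) {
    stopifnot(length(upper) == n)
    fin <- which(is.finite(upper))
    if (length(fin)) {
      Ub <- matrix(0, length(fin), n)
      Ub[cbind(seq_along(fin), fin)] <- 1
      A <- rbind(A, Ub)
      dir <- c(dir, rep("<=", length(fin)))
      rhs <- c(rhs, upper[fin])
    }
  }
  m <- nrow(A)
  cvec <- if (maximize) -obj else obj

  # normalise rows to rhs >= 0
  neg <- rhs < 0
  if (any(neg)) {
    A[neg, , drop = FALSE] -> blk
    A[neg, ] <- -blk
    rhs[neg] <- -rhs[neg]
    dir[neg] <- c("<=" = ">=", ">=" = "<=", "=" = "=")[dir[neg]]
  }

  n_le <- sum(dir == "<=")
  n_ge <- sum(dir == ">=")
  n_eq <- sum(dir == "=")
  n_art <- n_ge + n_eq
  ncols <- n + n_le + n_ge + n_art

  Tab <- matrix(0, m, ncols + 1)
  Tab[, seq_len(n)] <- A
  Tab[, ncols + 1] <- rhs
  basis <- integer(m)
  slack_col <- n
  art_col <- n + n_le + n_ge
  surp_col <- n + n_le
  art_cols <- integer(0)
  for (i in seq_len(m)) {
    if (dir[i] == "<=") {
      slack_col <- slack_col + 1
      Tab[i, slack_col] <- 1
      basis[i] <- slack_col
    } else {
      if (dir[i] == ">=") {
        surp_col <- surp_col + 1
        Tab[i, surp_col] <- -1
      }
      art_col <- art_col + 1
      Tab[i, art_col] <- 1
      basis[i] <- art_col
      art_cols <- c(art_cols, art_col)
    }
  }
  is_art <- rep(FALSE, ncols)
  is_art[art_cols] <- TRUE
  banned <- rep(FALSE, ncols)

  pivot <- function(Tab, zrow, basis, prow, pcol) {
    piv <- Tab[prow, pcol]
    Tab[prow, ] <- Tab[prow, ] / piv
    fac <- Tab[, pcol]
    fac[prow] <- 0
    Tab <- Tab - outer(fac, Tab[prow, ])
    zrow <- zrow - zrow[pcol] * Tab[prow, ]
    basis[prow] <- pcol
    list(Tab = Tab, zrow = zrow, basis = basis)
  }

  run_phase <- function(Tab, basis, cost, banned) {
    # reduced-cost row: z_j = cost_j - cost_B' Tab_j  (for current basis form)
    cb <- cost[basis]
    zrow <- c(cost, 0) - as.vector(cb %*% Tab)
    maxit <- 500L * (m + ncols)
    # Dantzig pricing by default; after a long degenerate stall switch to
    # Bland's rule, whose termination guarantee breaks any cycle
    stall <- 0L
    bland <- FALSE
    for (it in seq_len(maxit)) {
      red <- zrow[seq_len(ncols)]
      red[banned] <- 0
      if (!any(red < -tol)) {
        return(list(Tab = Tab, basis = basis, zrow = zrow, status = "optimal"))
      }
      q <- if (bland) which(red < -tol)[1L] else which.min(red)
      colq <- Tab[, q]
      pos <- which(colq > tol)
      if (!length(pos)) {
        return(list(Tab = Tab, basis = basis, zrow = zrow,
                    status = "unbounded"))
      }
      ratio <- Tab[pos, ncols + 1] / colq[pos]
      rmin <- min(ratio)
      ties <- pos[ratio <= rmin + tol]
      p <- ties[which.min(basis[ties])]  # Bland tie-break on basis index
      if (rmin <= tol) {
        stall <- stall + 1L
        if (stall > 2L * (m + 10L)) bland <- TRUE
      } else {
        stall <- 0L
      }
      up <- pivot(Tab, zrow, basis, p, q)
      Tab <- up$Tab; zrow <- up$zrow; basis <- up$basis
    }
    stop("simplex iteration limit exceeded")
  }

  # phase 1
  if (n_art > 0) {
    cost1 <- rep(0, ncols)
    cost1[art_cols] <- 1
    ph1 <- run_phase(Tab, basis, cost1, banned)
    if (ph1$status != "optimal") stop("phase-1 simplex unbounded (bug)")
    Tab <- ph1$Tab; basis <- ph1$basis
    art_val <- sum(Tab[basis %in% art_cols, ncols + 1])
    # absolute threshold: with big-M rows (rhs up to U) a relative test
    # would wave through slightly-infeasible systems
    if (art_val > 1e-6) {
      return(list(status = "infeasible", x = NULL, objval = NA_real_))
    }
    # drive remaining artificials out of the basis
    for (i in which(is_art[basis])) {
      row <- Tab[i, seq_len(ncols)]
      piv <- which(!is_art & abs(row) > tol)
      if (length(piv)) {
        up <- pivot(Tab, numeric(ncols + 1), basis, i, piv[1L])
        Tab <- up$Tab; basis <- up$basis
      }
      # else: redundant row; artificial stays basic at value 0 (harmless)
    }
    banned <- banned | is_art
  }

  # phase 2
  cost2 <- c(cvec, rep(0, ncols - n))
  ph2 <- run_phase(Tab, basis, cost2, banned)
  if (ph2$status == "unbounded") {
    return(list(status = "unbounded", x = NULL, objval = NA_real_))
  }
  Tab <- ph2$Tab; basis <- ph2$basis
  x <- numeric(ncols)
  x[basis] <- Tab[, ncols + 1]
  xs <- x[seq_len(n)]
  ov <- sum(cvec * xs)
  list(status = "optimal", x = xs, objval = if (maximize) -ov else ov)
}
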