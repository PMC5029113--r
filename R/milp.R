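#' Solve a mixed-integer linear program by branch-and-bound
#'
#' Depth-first branch-and-bound over binary variables on top of [lp_solve()],
#' with optional disjunctive ("indicator") constraints handled by constraint
#' branching. Specialised to the models used in this package: all integer
#' variables are binaries (source-usage indicators), objectives have integer
#' coefficients on the binaries, and every variable is bounded above.
#'
#' A disjunction demands `ge_row %*% x >= ge_rhs` **or** `x[zero_vars] = 0`.
#' Rather than encoding it with a big-M indicator binary (whose LP
#' relaxation is so weak that proving infeasibility degenerates into
#' exhaustive search), a node whose LP optimum violates a disjunction is
#' split into one child per disjunct. Both children satisfy the disjunction
#' permanently, so the tree stays finite.
#'
#' @param obj,A,dir,rhs,upper as in [lp_solve()].
#' @param int_idx indices of binary variables (must have `upper == 1`).
#' @param maximize if `TRUE`, maximise.
#' @param first_feasible stop at the first integral feasible solution.
#' @param obj_integral if `TRUE`, the objective is integral at every
#'   integral point, allowing bound rounding.
#' @param int_tol integrality tolerance; also the activity tolerance for
#'   disjunction satisfaction.
#' @param node_limit safety cap on explored nodes.
#' @param branch_first subset of `int_idx` to branch on preferentially.
#' @param disjunctions list of disjunctive constraints, each a list with
#'   `ge_row` (length-n numeric), `ge_rhs` (scalar) and `zero_vars`
#'   (variable indices).
#' @param fix0_implies named list: when binary `j` (name = index) is fixed
#'   to 0, also fix these variable indices to 0. Used for the source-pool
#'   links `v_j <= U b_j`, where propagating the implication keeps the
#'   child LP's infeasibility gap at flux scale instead of flux/U scale
#'   (big-M numerics).
#' @return list with `status` (`"optimal"`, `"infeasible"`), `x`, `objval`,
#'   `nodes`.
#' @keywords internal
milp_solve <- function(obj, A, dir, rhs, upper, int_idx,
                       maximize = FALSE, first_feasible = FALSE,
                       obj_integral = TRUE, int_tol = 1e-6,
                       node_limit = 100000L, branch_first = int_idx,
                       disjunctions = list(), fix0_implies = list()) {
  n <- length(obj)
  stopifnot(all(upper[int_idx] <= 1 + 1e-12))
  best <- NULL
  best_obj <- Inf  # in minimisation sense
  sgn_obj <- if (maximize) -obj else obj
  nodes <- 0L

  # node state: extra rows (as a list of (vec, dir, rhs)) + upper bounds
  stack <- list(list(rows = list(), ub = upper))

  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nodes <- nodes + 1L
    if (nodes > node_limit) stop("MILP node limit exceeded")

    A2 <- A; dir2 <- dir; rhs2 <- rhs
    if (length(node$rows)) {
      A2 <- rbind(A2, do.call(rbind, lapply(node$rows, `[[`, 1L)))
      dir2 <- c(dir2, vapply(node$rows, `[[`, "", 2L))
      rhs2 <- c(rhs2, vapply(node$rows, function(r) r[[3L]], 0))
    }
    rel <- lp_solve(sgn_obj, A2, dir2, rhs2, upper = node$ub)
    if (rel$status == "infeasible") next
    if (rel$status != "optimal") stop("unbounded LP relaxation (missing bounds?)")
    lb_node <- rel$objval
    if (obj_integral && !first_feasible) lb_node <- ceiling(lb_node - 1e-6)
    if (!first_feasible && lb_node >= best_obj - 1e-9) next

    xi <- rel$x[int_idx]
    frac <- abs(xi - round(xi))
    if (all(frac <= int_tol)) {
      # integral: check the disjunctions before accepting
      viol <- 0L
      worst <- -Inf
      for (d in seq_along(disjunctions)) {
        dj <- disjunctions[[d]]
        act <- if (length(dj$zero_vars)) max(rel$x[dj$zero_vars]) else 0
        lhs <- sum(dj$ge_row * rel$x)
        if (act > int_tol && lhs < dj$ge_rhs - int_tol) {
          gap <- min(act, dj$ge_rhs - lhs)
          if (gap > worst) { worst <- gap; viol <- d }
        }
      }
      if (viol == 0L) {
        val <- sum(sgn_obj * rel$x)
        if (val < best_obj - 1e-9 || (first_feasible && is.null(best))) {
          best_obj <- val
          x <- rel$x
          x[int_idx] <- round(xi)
          best <- x
        }
        if (first_feasible) break
        next
      }
      dj <- disjunctions[[viol]]
      # disjunct B: no consumer active
      ubB <- node$ub
      ubB[dj$zero_vars] <- 0
      stack[[length(stack) + 1L]] <- list(rows = node$rows, ub = ubB)
      # disjunct A: strict net production
      rowsA <- c(node$rows, list(list(dj$ge_row, ">=", dj$ge_rhs)))
      stack[[length(stack) + 1L]] <- list(rows = rowsA, ub = node$ub)
      next
    }
    pref <- intersect(branch_first, int_idx[frac > int_tol])
    j <- if (length(pref)) {
      fp <- abs(rel$x[pref] - round(rel$x[pref]))
      pref[which.max(fp)]
    } else {
      int_idx[which.max(frac)]
    }
    # explore b_j = 0 first (favours small-cardinality source sets), so push
    # the b_j = 1 child first (stack is LIFO)
    ej <- rep(0, n); ej[j] <- 1
    stack[[length(stack) + 1L]] <-
      list(rows = c(node$rows, list(list(ej, ">=", 1))), ub = node$ub)
    ub0 <- node$ub
    ub0[j] <- 0
    imp <- fix0_implies[[as.character(j)]]
    if (length(imp)) ub0[imp] <- 0
    stack[[length(stack) + 1L]] <- list(rows = node$rows, ub = ub0)
  }

  if (is.null(best)) {
    return(list(status = "infeasible", x = NULL, objval = NA_real_,
                nodes = nodes))
  }
  list(status = "optimal", x = best,
       objval = if (maximize) -best_obj else best_obj, nodes = nodes)
}
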