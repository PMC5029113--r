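#' Solve one enumeration MILP
#'
#' Finds a minimum-cardinality source set able to produce the targets, among
#' the sets that do not contain any of the `excluded` sets. One binary `b_j`
#' per source gates the flux of its source-pool reaction (`b_j <= v_j <=
#' U b_j`, so a chosen source supplies at least one unit); each excluded set
#' `I` contributes the cut `sum_{j in I} b_j <= |I| - 1`, which removes `I`
#' and every superset from the feasible region. An infeasible MILP certifies
#' that no unexcluded precursor set remains.
#'
#' @param net a normalized `metabolic_network`.
#' @param excluded list of character vectors (source sets already found).
#' @param config an [sps_config()]; `config$mode` selects the flux model.
#' @return `NULL` if infeasible, else a list with `sources` (sorted ids),
#'   `objective` (cardinality), `flux` (named, original reactions only) and
#'   `support`.
#' @export
solve_one <- function(net, excluded = list(), config = sps_config()) {
  stopifnot(inherits(net, "metabolic_network"))
  if (!is_normalized(net)) stop("solve_one() expects a normalized network")
  if (!length(net$targets)) stop("network has no targets")
  model <- .enum_model(net, config)
  .solve_one_model(model, net, excluded, config)
}

.enum_model <- function(net, config) {
  aug <- augment_network(net, pool_sources = TRUE, pool_target = TRUE)
  model <- .sps_milp_model(aug, net, config, mode = config$mode, with_b = TRUE)
  if (config$target_level == "max") {
    # phase 0: maximal achievable pooled-target production with all sources
    tb_row <- model$tbar_row
    obj <- model$A[tb_row, ]
    rel <- lp_solve(obj, model$A[-tb_row, , drop = FALSE],
                    model$dir[-tb_row], model$rhs[-tb_row],
                    upper = model$upper, maximize = TRUE)
    if (rel$status != "optimal" || rel$objval <= config$support_tol) {
      model$infeasible_at_max <- TRUE
    } else {
      model$rhs[tb_row] <- rel$objval * (1 - 1e-6)
    }
  }
  model
}

.solve_one_model <- function(model, net, excluded, config) {
  if (isTRUE(model$infeasible_at_max)) return(NULL)
  A <- model$A; dir <- model$dir; rhs <- model$rhs
  for (I in excluded) {
    idx <- model$b_idx[match(I, model$b_sources)]
    if (anyNA(idx)) stop("excluded set mentions unknown source(s)")
    cut <- rep(0, model$nvar)
    cut[idx] <- 1
    A <- rbind(A, cut)
    dir <- c(dir, "<=")
    rhs <- c(rhs, length(I) - 1)
  }
  obj <- rep(0, model$nvar)
  obj[model$b_idx] <- 1
  res <- milp_solve(obj, A, dir, rhs, upper = model$upper,
                    int_idx = model$int_idx, branch_first = model$b_idx,
                    disjunctions = model$disjunctions,
                    fix0_implies = model$fix0_implies)
  if (res$status != "optimal") return(NULL)
  bv <- res$x[model$b_idx]
  chosen <- sort(model$b_sources[bv > 0.5])
  # clean witness: re-solve the LP with the binaries fixed (and, in the
  # machinery-duplicating mode, the found solution's disjunct choices
  # frozen), minimising total flux so certificates sit at a minimal-flux
  # vertex instead of at the bound U
  Fx <- matrix(0, length(model$int_idx), model$nvar)
  Fx[cbind(seq_along(model$int_idx), model$int_idx)] <- 1
  A3 <- rbind(A, Fx)
  dir3 <- c(dir, rep("=", nrow(Fx)))
  rhs3 <- c(rhs, round(res$x[model$int_idx]))
  ub3 <- model$upper
  for (dj in model$disjunctions) {
    if (length(dj$zero_vars) &&
        max(res$x[dj$zero_vars]) > config$support_tol) {
      A3 <- rbind(A3, dj$ge_row)
      dir3 <- c(dir3, ">=")
      rhs3 <- c(rhs3, dj$ge_rhs)
    } else {
      ub3[dj$zero_vars] <- 0
    }
  }
  obj2 <- rep(0, model$nvar)
  obj2[model$v_idx] <- 1
  rel <- lp_solve(obj2, A3, dir3, rhs3, upper = ub3)
  stopifnot(rel$status == "optimal")
  flux <- stats::setNames(rel$x[model$v_idx], model$v_names)
  if (any(flux > 0.99 * config$upper_bound)) {
    warning("a flux is within 1% of the upper bound U; ",
            "verdicts may be bound-limited")
  }
  flux <- flux[model$orig_reactions]
  support <- names(flux)[flux > config$support_tol]
  stopifnot(length(chosen) == round(res$objval))
  list(sources = chosen, objective = length(chosen), flux = flux,
       support = support)
}

.enum_result <- function(solutions, mode, config, iterations, reason,
                         method) {
  ord <- order(vapply(solutions, function(s) length(s$sources), 0L),
               vapply(solutions, function(s) paste(s$sources, collapse = ","),
                      ""))
  structure(list(solutions = solutions[ord], mode = mode, config = config,
                 iterations = iterations, terminated_reason = reason,
                 method = method),
            class = "sps_enumeration")
}

#' @export
print.sps_enumeration <- function(x, ...) {
  cat(sprintf("%d minimal precursor set(s) [mode %s, method %s, %s]\n",
              length(x$solutions), x$mode, x$method, x$terminated_reason))
  for (s in x$solutions) {
    cat("  {", paste(s$sources, collapse = ", "), "}\n")
  }
  invisible(x)
}

#' Source sets of an enumeration result
#' @param res an `sps_enumeration`.
#' @return list of sorted character vectors.
#' @export
solution_sets <- function(res) lapply(res$solutions, `[[`, "sources")

.is_antichain <- function(sets) {
  n <- length(sets)
  if (n < 2) return(TRUE)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && all(sets[[i]] %in% sets[[j]])) return(FALSE)
    }
  }
  TRUE
}

#' Enumerate all minimal stoichiometric precursor sets
#'
#' The main entry point. Three interchangeable algorithms:
#'
#' * `"milp"` -- iterated mixed-integer programming: repeatedly find a
#'   minimum-cardinality unexcluded precursor set ([solve_one()]), append an
#'   exclusion cut, and stop when the MILP turns infeasible. Every returned
#'   set is inclusion-minimal and the family is exactly the antichain of all
#'   minimal solutions.
#' * `"combi"` -- combinatorial cross-check: combine minimal topological
#'   factories of the many-to-one transformed network and keep the feasible
#'   combinations (see [combi_enumerate()]). Exponential in bad cases; kept
#'   as an independent route.
#' * `"brute"` -- exhaustive subset oracle: test every subset of the sources
#'   in ascending cardinality with monotone pruning. Reference
#'   implementation for testing; exponential in the number of sources.
#'
#' Each MILP solution is additionally re-checked to be minimal by
#' [reduce_to_minimal()]; a shrinkable solution would indicate an internal
#' error and aborts.
#'
#' @param net a `metabolic_network` (normalized internally if needed).
#' @param config an [sps_config()]; `config$mode` selects the flux model.
#' @param method `"milp"`, `"combi"` or `"brute"`.
#' @return an `sps_enumeration`: `solutions` (each with `sources`, `flux`,
#'   `support`), `mode`, `config`, `iterations`, `terminated_reason`
#'   (`"exhausted"`, `"max_solutions"` or `"time_limit"`), `method`.
#' @export
#' @examples
#' net <- topo_vs_stoich_network(check = FALSE)
#' enumerate_minimal_sps(net)
enumerate_minimal_sps <- function(net, config = sps_config(),
                                  method = c("milp", "combi", "brute")) {
  method <- match.arg(method)
  net <- normalize_network(net)
  switch(method,
         milp = .milp_enumerate(net, config),
         combi = combi_enumerate(net, config),
         brute = brute_enumerate(net, config))
}

.milp_enumerate <- function(net, config) {
  t0 <- Sys.time()
  model <- .enum_model(net, config)
  solutions <- list()
  reason <- "exhausted"
  it <- 0L
  last_card <- 0L
  repeat {
    if (length(solutions) >= config$max_solutions) {
      reason <- "max_solutions"; break
    }
    if (as.numeric(Sys.time() - t0, units = "secs") > config$time_limit) {
      reason <- "time_limit"; break
    }
    sol <- .solve_one_model(model, net, lapply(solutions, `[[`, "sources"),
                            config)
    it <- it + 1L
    if (is.null(sol)) break
    # safety verification: the MILP optimum must already be minimal
    red <- reduce_to_minimal(net, sol$sources, mode = config$mode,
                             config = config)
    if (!identical(red, sol$sources)) {
      stop("internal error: MILP returned a non-minimal precursor set {",
           paste(sol$sources, collapse = ","), "} reducible to {",
           paste(red, collapse = ","), "}")
    }
    if (sol$objective < last_card) {
      stop("internal error: MILP objective decreased across iterations")
    }
    last_card <- sol$objective
    solutions[[length(solutions) + 1L]] <- sol
  }
  res <- .enum_result(solutions, config$mode, config, it, reason, "milp")
  if (!.is_antichain(solution_sets(res))) {
    stop("internal error: enumeration result is not an antichain")
  }
  res
}

#' Brute-force enumeration over all source subsets
#'
#' Tests subsets of the source set in ascending cardinality with the modal
#' membership oracle. Monotonicity of feasibility (adding sources never
#' breaks a solution) allows pruning every superset of a found solution;
#' each remaining feasible subset is therefore inclusion-minimal. Reference
#' oracle: exponential in `|sources|`.
#'
#' @inheritParams enumerate_minimal_sps
#' @return an `sps_enumeration`.
#' @export
brute_enumerate <- function(net, config = sps_config()) {
  net <- normalize_network(net)
  t0 <- Sys.time()
  xs <- sort(net$sources)
  solutions <- list()
  reason <- "exhausted"
  it <- 0L
  for (k in 0:length(xs)) {
    if (reason != "exhausted") break
    # k = 0 is the empty set: feasible when the network contains an
    # autocatalytic subnetwork able to amplify the targets from nothing
    combs <- if (k == 0L) list(character(0))
             else utils::combn(xs, k, simplify = FALSE)
    for (X in combs) {
      if (length(solutions) >= config$max_solutions) {
        reason <- "max_solutions"; break
      }
      if (as.numeric(Sys.time() - t0, units = "secs") > config$time_limit) {
        reason <- "time_limit"; break
      }
      if (any(vapply(solutions, function(s) all(s$sources %in% X),
                     logical(1)))) {
        next
      }
      it <- it + 1L
      cert <- check_sps(net, X, mode = config$mode, config = config)
      if (cert$feasible) {
        solutions[[length(solutions) + 1L]] <-
          list(sources = X, objective = length(X), flux = cert$flux,
               support = cert$active_reactions)
      }
    }
  }
  .enum_result(solutions, config$mode, config, it, reason, "brute")
}
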