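#' Solver configuration
#'
#' Collects every numeric knob of the feasibility and enumeration machinery.
#' Strict inequalities of the flux models are encoded as `>= epsilon`
#' (target production), `>= delta` (flux of a reaction asserted to be in a
#' factory) and `>= eps_bar` (machinery-duplicating net production); the
#' defaults `epsilon = 0.5`, `eps_bar = 0.5`, `U = 1000` follow the
#' reference constants this method is normally run with, and `delta` is kept
#' small (`0.001`) so that factory membership does not distort flux ratios.
#'
#' @param epsilon lower bound standing in for "target production > 0"
#'   (flux units per unit time; any positive value gives the same verdicts
#'   because feasible fluxes rescale, provided `epsilon << U`).
#' @param eps_bar lower bound standing in for the machinery-duplicating
#'   strict net production.
#' @param upper_bound `U`, per-flux upper bound; also the big-M scale.
#' @param delta lower bound on the flux of reactions asserted active in
#'   [check_s_factory()].
#' @param support_tol absolute threshold above which a flux is counted as
#'   active (the support of a certificate).
#' @param mode flux model: `"accumulate"` (internal compounds may
#'   accumulate), `"steady-state"` (internal compounds must balance
#'   exactly), or `"md"` (machinery-duplicating: every internal substrate of
#'   an active reaction must be strictly net-produced).
#' @param max_solutions stop an enumeration after this many solutions.
#' @param time_limit wall-clock limit in seconds for a whole enumeration.
#' @param target_level `"epsilon"` demands target production `>= epsilon`;
#'   `"max"` first maximises target production by LP and then demands that
#'   maximal level (enumerates the precursor sets supporting maximal yield).
#' @param seed integer recorded in run manifests (the algorithms themselves
#'   are deterministic).
#' @return an object of class `sps_config`.
#' @export
sps_config <- function(epsilon = 0.5, eps_bar = 0.5, upper_bound = 1000,
                       delta = 0.001, support_tol = 1e-6,
                       mode = c("accumulate", "steady-state", "md"),
                       max_solutions = Inf, time_limit = Inf,
                       target_level = c("epsilon", "max"), seed = 1L) {
  mode <- match.arg(mode)
  target_level <- match.arg(target_level)
  stopifnot(epsilon > 0, epsilon <= upper_bound, eps_bar > 0,
            eps_bar <= upper_bound, upper_bound > 1, delta > 0,
            support_tol > 0)
  structure(list(epsilon = epsilon, eps_bar = eps_bar,
                 upper_bound = upper_bound, delta = delta,
                 support_tol = support_tol, mode = mode,
                 max_solutions = max_solutions, time_limit = time_limit,
                 target_level = target_level, seed = as.integer(seed)),
            class = "sps_config")
}

.mode_of <- function(mode, config) if (is.null(mode)) config$mode else mode

# constraint directions for the compound rows of a (possibly augmented)
# network: ">=" everywhere except an exact balance on internal compounds in
# steady state. `free` rows are dropped by the callers.
.row_dirs <- function(compounds, sources, targets, mode, pooled = NULL) {
  dirs <- stats::setNames(rep(">=", length(compounds)), compounds)
  if (mode == "steady-state") {
    internal <- setdiff(compounds, c(sources, targets, pooled))
    dirs[internal] <- "="
  }
  dirs
}

.certificate <- function(feasible, flux = NULL, support = character(0),
                         mode, objective = NA_real_, tolerance = NA_real_) {
  structure(list(feasible = feasible, flux = flux,
                 active_reactions = support, mode = mode,
                 objective = objective, tolerance = tolerance),
            class = "sps_certificate")
}

#' @export
print.sps_certificate <- function(x, ...) {
  cat(sprintf("certificate (%s): %s\n", x$mode,
              if (x$feasible) "feasible" else "infeasible"))
  if (x$feasible) {
    cat("  active reactions:", paste(x$active_reactions, collapse = ", "),
        "\n")
  }
  invisible(x)
}

# re-verify a witness flux against the raw constraint system (certificate
# soundness: a solver bug must surface as an error, never as a wrong verdict)
.verify_certificate <- function(net, flux, X, mode, config) {
  S <- .stoich_dense(net)
  v <- stats::setNames(rep(0, ncol(S)), colnames(S))
  v[names(flux)] <- flux
  np <- as.vector(S %*% v)
  names(np) <- rownames(S)
  tol <- 1e-6 * max(1, config$upper_bound * 1e-3)
  non_src <- setdiff(rownames(S), X)
  ok <- all(np[non_src] >= -tol) && all(np[net$targets] > tol)
  if (mode == "steady-state") {
    internal <- setdiff(rownames(S), c(X, net$targets))
    ok <- ok && all(abs(np[internal]) <= tol)
  }
  if (mode == "md") {
    F <- names(flux)[flux > config$support_tol]
    Y <- setdiff(substrates_of(net, F), union(X, net$sources))
    ok <- ok && all(np[Y] > tol)
  }
  if (!ok) {
    stop("internal error: witness flux fails re-verification (mode ", mode,
         ")")
  }
  invisible(TRUE)
}

#' Decide whether a source subset is a stoichiometric precursor set
#'
#' Membership oracle: `X` is a stoichiometric precursor set of the network's
#' targets if some flux vector `v >= 0` produces every target strictly while
#' no compound outside `X` has negative net production (`"accumulate"`), or
#' while every internal compound balances exactly (`"steady-state"`). The
#' test maximises pooled-target production subject to those constraints; a
#' strictly positive optimum certifies membership and its support is a
#' stoichiometric factory from `X`. The machinery-duplicating mode delegates
#' to [check_md_sps()], which needs integer variables.
#'
#' @param net a normalized `metabolic_network`.
#' @param X character vector, subset of `net$sources`.
#' @param mode override `config$mode`.
#' @param config an [sps_config()].
#' @return an `sps_certificate` with the verdict, witness flux and support.
#' @export
#' @examples
#' net <- topo_vs_stoich_network(check = FALSE)
#' check_sps(net, "p1")$feasible    # TRUE
#' check_sps(net, "p3")$feasible    # FALSE: topology alone is not enough
check_sps <- function(net, X, mode = NULL, config = sps_config()) {
  mode <- .mode_of(mode, config)
  stopifnot(inherits(net, "metabolic_network"), all(X %in% net$sources))
  if (!is_normalized(net)) stop("check_sps() expects a normalized network")
  if (mode == "md") return(check_md_sps(net, X, config))

  # pool the sources in X so that supply, like every flux, is capped at U;
  # this keeps the membership oracle's semantics identical to the
  # enumeration MILP's (which models availability through pool reactions)
  aug <- augment_network(net, pool_sources = TRUE, pool_target = TRUE,
                         sources = intersect(net$sources, X))
  S <- .stoich_dense(aug)
  tbar <- attr(aug, "pooled_target")
  dirs <- .row_dirs(rownames(S), net$sources, net$targets, mode,
                    pooled = tbar)
  obj <- S[tbar, ]
  res <- lp_solve(obj, S, unname(dirs), rep(0, nrow(S)),
                  upper = rep(config$upper_bound, ncol(S)), maximize = TRUE)
  if (res$status == "unbounded") stop("unexpected unbounded LP (U bound lost?)")
  # verdict threshold: at least epsilon of pooled target within the flux cap
  # U, the same producibility semantics the enumeration MILP enforces (with
  # an unbounded LP any positive optimum would scale, but U is finite)
  feasible <- res$status == "optimal" &&
    res$objval >= config$epsilon * (1 - 1e-9)
  if (!feasible) {
    return(.certificate(FALSE, mode = mode, objective = res$objval,
                        tolerance = config$support_tol))
  }
  flux <- stats::setNames(res$x, colnames(S))
  flux <- flux[reaction_ids(net)]  # drop pools and the pooled-target reaction
  support <- names(flux)[flux > config$support_tol]
  .verify_certificate(net, flux[support], X, mode, config)
  .certificate(TRUE, flux = flux, support = support, mode = mode,
               objective = res$objval, tolerance = config$support_tol)
}

#' Verify a candidate stoichiometric factory
#'
#' Decides whether the reaction set `F` is a stoichiometric factory from `X`
#' to the network targets under the given mode: a flux must exist that is
#' strictly positive exactly on `F` (encoded as `v_i >= delta` on `F`,
#' `v_i = 0` elsewhere), keeps every non-`X` compound's net production
#' nonnegative (exactly zero on internals in steady state), and produces
#' every target strictly. In machinery-duplicating mode the non-source
#' substrates of `F` must also be strictly net-produced.
#'
#' @param net a normalized `metabolic_network`.
#' @param F character vector of reaction ids.
#' @param X character vector, subset of `net$sources`.
#' @inheritParams check_sps
#' @return an `sps_certificate`.
#' @export
check_s_factory <- function(net, F, X, mode = NULL, config = sps_config()) {
  mode <- .mode_of(mode, config)
  stopifnot(inherits(net, "metabolic_network"),
            all(F %in% reaction_ids(net)), all(X %in% net$sources))
  if (!is_normalized(net)) stop("check_s_factory() expects a normalized network")
  S <- .stoich_dense(net)
  nr <- ncol(S)
  rids <- colnames(S)
  upper <- stats::setNames(rep(0, nr), rids)
  upper[F] <- config$upper_bound

  dirs <- .row_dirs(rownames(S), X, net$targets, mode)
  keep <- setdiff(rownames(S), X)
  A <- S[keep, , drop = FALSE]
  dir <- unname(dirs[keep])
  rhs <- rep(0, length(keep))
  # strict target production
  strict <- net$targets
  if (mode == "md") {
    strict <- union(strict, setdiff(substrates_of(net, F),
                                    union(X, net$sources)))
  }
  eps <- if (mode == "md") config$eps_bar else config$epsilon
  for (cmp in strict) {
    A <- rbind(A, S[cmp, ])
    dir <- c(dir, ">=")
    rhs <- c(rhs, eps)
  }
  # membership strictness
  if (length(F)) {
    M <- matrix(0, length(F), nr)
    M[cbind(seq_along(F), match(F, rids))] <- 1
    A <- rbind(A, M)
    dir <- c(dir, rep(">=", length(F)))
    rhs <- c(rhs, rep(config$delta, length(F)))
  }
  res <- lp_solve(rep(0, nr), A, dir, rhs, upper = unname(upper))
  if (res$status != "optimal") {
    return(.certificate(FALSE, mode = mode))
  }
  flux <- stats::setNames(res$x, rids)
  .verify_certificate(net, flux[F], X, mode, config)
  .certificate(TRUE, flux = flux, support = sort(F), mode = mode)
}

#' Decide machinery-duplicating precursor-set membership
#'
#' `X` is a machinery-duplicating precursor set if some flux produces the
#' targets strictly, accumulates nowhere outside `X`, and strictly
#' net-produces every non-source substrate of an active reaction. The "is a
#' substrate of an active reaction" condition is disjunctive (either compound
#' `j` is net-produced above `eps_bar`, or none of its consumers carries
#' flux), so the decision is a small MILP with one indicator binary per
#' consumed compound, solved in feasibility mode.
#'
#' @inheritParams check_sps
#' @return an `sps_certificate`.
#' @export
check_md_sps <- function(net, X, config = sps_config()) {
  stopifnot(inherits(net, "metabolic_network"), all(X %in% net$sources))
  if (!is_normalized(net)) stop("check_md_sps() expects a normalized network")
  aug <- augment_network(net, pool_sources = TRUE, pool_target = TRUE,
                         sources = intersect(net$sources, X))
  model <- .md_milp_model(aug, net, config, with_b = FALSE)
  res <- milp_solve(rep(0, model$nvar), model$A, model$dir, model$rhs,
                    upper = model$upper, int_idx = model$int_idx,
                    first_feasible = TRUE,
                    disjunctions = model$disjunctions)
  if (res$status != "optimal") {
    return(.certificate(FALSE, mode = "md"))
  }
  flux <- stats::setNames(res$x[model$v_idx], model$v_names)
  flux <- flux[model$orig_reactions]
  support <- names(flux)[flux > config$support_tol]
  .verify_certificate(net, flux[support], X, "md", config)
  .certificate(TRUE, flux = flux, support = support, mode = "md")
}

# Build compound rows + machinery-duplicating disjunction rows for an
# augmented network. Returns the LP/MILP skeleton shared by check_md_sps()
# and the enumeration engine. When `with_b` is TRUE, source-usage binaries
# and their linking rows are included (enumeration); otherwise the pools are
# simply bounded by U (membership test for a fixed X).
.md_milp_model <- function(aug, net, config, with_b) {
  .sps_milp_model(aug, net, config, mode = "md", with_b = with_b)
}

.sps_milp_model <- function(aug, net, config, mode, with_b = TRUE) {
  S <- .stoich_dense(aug)
  U <- config$upper_bound
  rids <- colnames(S)
  nv <- length(rids)
  pools <- attr(aug, "source_pool_reactions")   # source id -> pool rid
  tbar <- attr(aug, "pooled_target")
  rbar <- attr(aug, "pooled_target_reaction")
  orig <- setdiff(rids, c(unname(pools), rbar))

  nb <- if (with_b) length(pools) else 0L
  b_idx <- if (nb) nv + seq_len(nb) else integer(0)

  # machinery-duplicating disjunctions: one per consumed non-source compound
  # (either net-produce it above eps_bar, or switch all its consumers off);
  # handled by constraint branching, not big-M indicators, mirroring the
  # indicator-constraint formulation solvers use for numerical stability
  md_cmp <- character(0)
  Qj <- list()
  if (mode == "md") {
    consumers <- lapply(stats::setNames(rownames(S), rownames(S)),
                        function(cmp) rids[S[cmp, ] < 0 & !(rids %in% pools)])
    md_cmp <- setdiff(rownames(S), net$sources)
    md_cmp <- md_cmp[vapply(consumers[md_cmp], length, 0L) > 0L]
    Qj <- consumers[md_cmp]
  }
  nvar <- nv + nb

  rows <- list(); dirs <- character(0); rhs <- numeric(0)
  add_row <- function(r, d, b) {
    rows[[length(rows) + 1L]] <<- r
    dirs[length(dirs) + 1L] <<- d
    rhs[length(rhs) + 1L] <<- b
  }
  pad <- function(v) c(v, rep(0, nvar - length(v)))

  dirv <- .row_dirs(rownames(S), net$sources, net$targets,
                    if (mode == "md") "accumulate" else mode, pooled = tbar)
  for (cmp in rownames(S)) {
    if (identical(cmp, tbar)) {
      add_row(pad(S[cmp, ]), ">=", config$epsilon)
    } else {
      add_row(pad(S[cmp, ]), dirv[[cmp]], 0)
    }
  }
  if (with_b) {
    for (k in seq_along(pools)) {
      vj <- match(pools[[k]], rids)
      r1 <- rep(0, nvar); r1[b_idx[k]] <- 1; r1[vj] <- -1   # b_j <= v_j
      add_row(r1, "<=", 0)
      r2 <- rep(0, nvar); r2[vj] <- 1; r2[b_idx[k]] <- -U   # v_j <= U b_j
      add_row(r2, "<=", 0)
    }
  }
  disj <- lapply(seq_along(md_cmp), function(k) {
    list(ge_row = pad(S[md_cmp[k], ]), ge_rhs = config$eps_bar,
         zero_vars = match(Qj[[k]], rids))
  })
  A <- do.call(rbind, rows)
  upper <- c(rep(U, nv), rep(1, nb))
  list(A = A, dir = dirs, rhs = rhs, upper = upper, nvar = nvar,
       tbar_row = match(tbar, rownames(S)),
       v_idx = seq_len(nv), v_names = rids, b_idx = b_idx,
       b_sources = if (nb) names(pools) else character(0),
       int_idx = b_idx, disjunctions = disj,
       fix0_implies = if (nb) stats::setNames(
         lapply(seq_len(nb), function(k) match(pools[[k]], rids)),
         as.character(b_idx)) else list(),
       orig_reactions = orig, pools = pools, rbar = rbar)
}

#' Decide stoichiometric cut-set membership
#'
#' `X` is a stoichiometric cut set if removing it from the environment makes
#' the targets unproducible, i.e. if the complement of `X` in the source set
#' is not a stoichiometric precursor set.
#'
#' @inheritParams check_sps
#' @return `TRUE`/`FALSE`.
#' @export
check_scs <- function(net, X, mode = NULL, config = sps_config()) {
  mode <- .mode_of(mode, config)
  stopifnot(all(X %in% net$sources))
  !check_sps(net, setdiff(net$sources, X), mode = mode,
             config = config)$feasible
}

#' Shrink a feasible source set to an inclusion-minimal one
#'
#' Greedy elimination in lexicographic compound-id order: each source is
#' dropped if the remainder is still a precursor set under the given mode.
#' The result is inclusion-minimal; which minimal subset is returned depends
#' only on the (deterministic) elimination order.
#'
#' @inheritParams check_sps
#' @return character vector (sorted): an inclusion-minimal feasible subset
#'   of `X`.
#' @export
reduce_to_minimal <- function(net, X, mode = NULL, config = sps_config()) {
  mode <- .mode_of(mode, config)
  X <- sort(unique(X))
  if (!check_sps(net, X, mode = mode, config = config)$feasible) {
    stop("reduce_to_minimal(): the given source set is not feasible")
  }
  for (x in X) {
    cand <- setdiff(X, x)
    if (check_sps(net, cand, mode = mode, config = config)$feasible) {
      X <- cand
    }
  }
  X
}
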