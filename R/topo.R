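#' Topological factory test
#'
#' `F` is a topological factory from `X` to the targets when every target
#' and every substrate of a reaction in `F` is either a source in `X` or a
#' product of some reaction in `F` (quantities are ignored). A pure set
#' containment test.
#'
#' @param net a `metabolic_network`.
#' @param F character vector of reaction ids.
#' @param X character vector of source ids.
#' @param targets targets to reach (defaults to the network's).
#' @return `TRUE`/`FALSE`.
#' @export
is_topological_factory <- function(net, F, X, targets = net$targets) {
  stopifnot(all(F %in% reaction_ids(net)))
  need <- union(targets, substrates_of(net, F))
  have <- union(products_of(net, F), X)
  all(need %in% have)
}

#' Find a hypergraph path between two compounds
#'
#' A (simple) path from `m` to `t` within the reaction set `F` is a chain of
#' distinct compounds `m = m0, ..., mn = t` and distinct reactions
#' `r1, ..., rn` with `m_{i-1}` a substrate of `r_i` and `m_i` a product of
#' `r_i`. Breadth-first search over the compound successor relation; a
#' shortest such chain cannot repeat a reaction, so BFS suffices.
#'
#' @param net a `metabolic_network`.
#' @param F reaction ids the path may use.
#' @param m,t compound ids; `m == t` yields the empty path.
#' @return `NULL` if no path exists, else a list with `metabolites`
#'   (`m0...mn`) and `reactions` (`r1...rn`).
#' @export
find_hyperpath <- function(net, F, m, t) {
  stopifnot(m %in% net$compounds, t %in% net$compounds)
  if (identical(m, t)) return(list(metabolites = m, reactions = character(0)))
  prev <- list()
  seen <- m
  queue <- list(m)
  while (length(queue)) {
    cur <- queue[[1L]]
    queue <- queue[-1L]
    for (rid in F) {
      r <- net$reactions[[rid]]
      if (!(cur %in% names(r$substrates))) next
      for (p in names(r$products)) {
        if (p %in% seen) next
        seen <- c(seen, p)
        prev[[p]] <- c(cur, rid)
        if (identical(p, t)) {
          mets <- t; rxns <- character(0)
          while (!identical(mets[1L], m)) {
            step <- prev[[mets[1L]]]
            mets <- c(step[1L], mets)
            rxns <- c(step[2L], rxns)
          }
          return(list(metabolites = mets, reactions = rxns))
        }
        queue[[length(queue) + 1L]] <- p
      }
    }
  }
  NULL
}

#' Validate a minimal topological factory in a many-to-one network
#'
#' In a many-to-one network (every reaction has a single product), a
#' reaction set `H` with inferred sources `X = Subs(H) n sources` is a
#' minimal topological factory to the targets exactly when (1) every
#' non-source substrate of `H` -- and every produced target -- is produced
#' by exactly one reaction of `H`, and (2) every product of `H` has a
#' hypergraph path to a target inside `H`. This equivalence is what makes
#' the backward-branching enumerator below exhaustive. (The unique-producer
#' condition must include produced targets: a second producer of a target
#' has a single product in a many-to-one network and is therefore always
#' removable, even though it is not anyone's substrate.)
#'
#' @param psi_net a many-to-one `metabolic_network` (see [many_to_one()]).
#' @param H character vector of reaction ids of `psi_net`.
#' @return `TRUE`/`FALSE`.
#' @export
validate_minimal_mto_factory <- function(psi_net, H) {
  stopifnot(all(H %in% reaction_ids(psi_net)))
  if (!length(H)) {
    return(all(psi_net$targets %in% psi_net$sources))
  }
  X <- intersect(substrates_of(psi_net, H), psi_net$sources)
  internal_subs <- setdiff(substrates_of(psi_net, H), X)
  prods <- unlist(lapply(psi_net$reactions[H], function(r) names(r$products)))
  counts <- table(prods)
  # condition 1: exactly one producer per non-source substrate and per
  # produced target
  if (!all(internal_subs %in% names(counts))) return(FALSE)
  uniq <- union(internal_subs, intersect(psi_net$targets, names(counts)))
  if (any(counts[uniq] != 1L)) return(FALSE)
  # targets must be covered as well (factory-hood)
  if (!all(psi_net$targets %in% union(names(counts), X))) return(FALSE)
  # condition 2: every product reaches a target
  for (mm in unique(prods)) {
    ok <- FALSE
    for (tt in psi_net$targets) {
      if (!is.null(find_hyperpath(psi_net, H, mm, tt))) { ok <- TRUE; break }
    }
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Enumerate all minimal topological factories of a many-to-one network
#'
#' Backward branching from the targets: maintain the set of needed-but-
#' unproduced non-source compounds, repeatedly take the lexicographically
#' smallest one and branch over its (single-product) producers. Since a
#' producer is only ever added for a compound that has none, every
#' enumerated set satisfies the exactly-one-producer condition; candidates
#' are then filtered through [validate_minimal_mto_factory()] and
#' deduplicated by reaction set.
#'
#' @param psi_net a many-to-one `metabolic_network`.
#' @param max_factories abort if more than this many candidate factories are
#'   generated (combinatorial blow-up guard).
#' @return list of factories, each a list with `reactions` (sorted ids),
#'   `footprint` (sources consumed) and `kind = "topological"`.
#' @export
enumerate_mto_factories <- function(psi_net, max_factories = 100000L) {
  stopifnot(inherits(psi_net, "metabolic_network"))
  multi <- vapply(psi_net$reactions, function(r) length(r$products) > 1L,
                  logical(1))
  if (any(multi)) stop("enumerate_mto_factories() expects a many-to-one network")
  producers <- lapply(stats::setNames(psi_net$compounds, psi_net$compounds),
                      function(cmp) {
                        ids <- reaction_ids(psi_net)
                        ids[vapply(psi_net$reactions, function(r)
                          cmp %in% names(r$products), logical(1))]
                      })
  need0 <- sort(setdiff(psi_net$targets, psi_net$sources))
  found <- new.env(parent = emptyenv())
  n_found <- 0L
  res <- list()
  stack <- list(list(H = character(0), need = need0))
  while (length(stack)) {
    st <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (!length(st$need)) {
      key <- paste(sort(st$H), collapse = "|")
      if (is.null(found[[key]])) {
        found[[key]] <- TRUE
        if (validate_minimal_mto_factory(psi_net, st$H)) {
          n_found <- n_found + 1L
          if (n_found > max_factories) {
            stop("enumerate_mto_factories(): more than ", max_factories,
                 " factories; raise max_factories or use the MILP engine")
          }
          res[[n_found]] <- list(
            reactions = sort(st$H),
            footprint = intersect(substrates_of(psi_net, st$H),
                                  psi_net$sources),
            kind = "topological")
        }
      }
      next
    }
    m <- st$need[1L]
    for (rid in producers[[m]]) {
      if (rid %in% st$H) next  # would duplicate a producer of m: impossible
      H2 <- c(st$H, rid)
      produced <- unique(unlist(lapply(psi_net$reactions[H2], function(r)
        names(r$products))))
      subs2 <- substrates_of(psi_net, H2)
      need2 <- sort(setdiff(union(st$need[-1L],
                                  setdiff(subs2, psi_net$sources)),
                            produced))
      stack[[length(stack) + 1L]] <- list(H = H2, need = need2)
    }
    # a needed compound with no producer: branch dies (no push)
  }
  # canonical order for reproducibility
  keys <- vapply(res, function(f) paste(f$reactions, collapse = ","), "")
  res[order(keys)]
}

#' Enumerate all minimal topological precursor sets
#'
#' The minimal topological precursor sets of a network are the
#' inclusion-minimal source footprints of the minimal topological factories
#' of its many-to-one transform (retransforming a factory activates each
#' original reaction any of whose copies is used, which leaves the
#' footprint unchanged).
#'
#' @param net a `metabolic_network` (normalized internally).
#' @param max_factories passed to [enumerate_mto_factories()].
#' @return list of sorted character vectors, an antichain.
#' @export
enumerate_minimal_tps <- function(net, max_factories = 100000L) {
  net <- normalize_network(net)
  fac <- enumerate_mto_factories(many_to_one(net),
                                 max_factories = max_factories)
  fps <- unique(lapply(fac, function(f) sort(f$footprint)))
  .minimal_antichain(fps)
}

.minimal_antichain <- function(sets) {
  if (!length(sets)) return(list())
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (i != j && keep[i] &&
          all(sets[[j]] %in% sets[[i]]) &&
          !setequal(sets[[i]], sets[[j]])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  sets <- sets[keep]
  sets[order(vapply(sets, length, 0L),
             vapply(sets, paste, "", collapse = ","))]
}

#' Combinatorial enumeration of minimal stoichiometric precursor sets
#'
#' Cross-check engine built on the structural fact that every minimal
#' stoichiometric factory is a union of minimal topological factories of
#' the many-to-one transform: enumerate those factories, then test unions
#' of k = 1, 2, ... of their source footprints for stoichiometric
#' feasibility under the requested mode, reducing each feasible union to an
#' inclusion-minimal set. Combinations whose footprint already contains a
#' recorded solution are pruned, repeated footprints are memoised, and the
#' scan stops when every combination at some level was pruned or the
#' factory count is exhausted. Exponential in bad cases -- the MILP engine
#' is the practical choice; this one exists as an independent route.
#'
#' @inheritParams enumerate_minimal_sps
#' @param max_factories guard passed to [enumerate_mto_factories()]; if the
#'   transform has more distinct factory footprints than `max_footprints`
#'   the function aborts with guidance to use the MILP engine.
#' @param max_footprints combination-space guard.
#' @return an `sps_enumeration`; each solution additionally records
#'   `found_at_k`, the number of combined factories that first exposed it.
#' @export
combi_enumerate <- function(net, config = sps_config(),
                            max_factories = 100000L, max_footprints = 20L) {
  net <- normalize_network(net)
  if (config$mode == "steady-state") {
    warning("combi_enumerate(): the factory-decomposition argument ",
            "underlying this enumerator is only established for the ",
            "accumulation and machinery-duplicating models; under exact ",
            "steady state it can miss minimal solutions that require ",
            "disposal-only sources. Prefer the MILP engine for this mode.")
  }
  t0 <- Sys.time()
  fac <- enumerate_mto_factories(many_to_one(net),
                                 max_factories = max_factories)
  fps <- unique(lapply(fac, function(f) sort(f$footprint)))
  if (length(fps) > max_footprints) {
    stop("combi_enumerate(): ", length(fps), " distinct factory footprints; ",
         "the combinatorial route is impractical here -- use ",
         'enumerate_minimal_sps(method = "milp")')
  }
  solutions <- list()
  tested <- new.env(parent = emptyenv())
  reason <- "exhausted"
  it <- 0L
  K <- length(fps)
  k <- 0L
  while (k < K && reason == "exhausted") {
    k <- k + 1L
    any_evaluated <- FALSE
    for (comb in utils::combn(seq_len(K), k, simplify = FALSE)) {
      if (length(solutions) >= config$max_solutions) {
        reason <- "max_solutions"; break
      }
      if (as.numeric(Sys.time() - t0, units = "secs") > config$time_limit) {
        reason <- "time_limit"; break
      }
      X <- sort(unique(unlist(fps[comb])))
      if (any(vapply(solutions, function(s) all(s$sources %in% X),
                     logical(1)))) {
        next
      }
      key <- paste0("X:", paste(X, collapse = "|"))  # X may be empty
      if (!is.null(tested[[key]])) next
      tested[[key]] <- TRUE
      any_evaluated <- TRUE
      it <- it + 1L
      cert <- check_sps(net, X, mode = config$mode, config = config)
      if (!cert$feasible) next
      Xmin <- reduce_to_minimal(net, X, mode = config$mode, config = config)
      if (any(vapply(solutions, function(s) setequal(s$sources, Xmin),
                     logical(1)))) {
        next
      }
      cmin <- check_sps(net, Xmin, mode = config$mode, config = config)
      solutions[[length(solutions) + 1L]] <-
        list(sources = Xmin, objective = length(Xmin), flux = cmin$flux,
             support = cmin$active_reactions, found_at_k = k)
    }
    if (!any_evaluated && reason == "exhausted" && k > 1L) break
  }
  res <- .enum_result(solutions, config$mode, config, it, reason, "combi")
  if (!.is_antichain(solution_sets(res))) {
    stop("internal error: combi result is not an antichain")
  }
  res
}
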