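#' Example networks
#'
#' Small networks used throughout the documentation and test-suite. Each
#' builder can verify, at construction time, the list of structural and
#' stoichiometric properties the network is meant to illustrate
#' (`check = TRUE`); a failed property is a construction error, so the
#' fixtures cannot silently drift away from their intended behaviour.
#'
#' * `toy_chain_network()`: two reactions,
#'   `r1: 1 c1 + 2 c2 -> 1 c3`, `r2: 3 c3 -> 1 c4`, sources `{c1, c2}`,
#'   target `{c4}` -- the minimal example of non-unit coefficients.
#' * `krebs_toy_network()`: a three-reaction regenerating cycle
#'   (`r1: p + a -> c`, `r2: c -> b`, `r3: b -> a + t`) with source `p` and
#'   target `t`. The internal compounds `a`, `b`, `c` are regenerated
#'   (net production zero at unit flux), the way oxaloacetate is regenerated
#'   by the Krebs cycle. `{p}` is a stoichiometric precursor set under both
#'   the accumulation and steady-state models, but no precursor set exists
#'   under the machinery-duplicating model, which demands strictly positive
#'   net production of every internal substrate.
#' * `topo_vs_stoich_network()`: ten compounds, eight unit-coefficient
#'   reactions, sources `{p1, p2, p3}`, target `{t}`. Its minimal
#'   topological precursor sets (`{p1}`, `{p3}`) and minimal stoichiometric
#'   precursor sets (`{p1}`, `{p2, p3}`) differ: `{p3}` is topologically
#'   sufficient but admits no feasible flux, and `{p2, p3}` is not a union
#'   of minimal topological solutions.
#' * `decoy_factories_network(n)`: one reaction `r1: p1 -> t` plus `n - 1`
#'   reactions feeding a flux-deficient cycle. The many-to-one transform has
#'   `n` minimal topological factories of which only one yields a feasible
#'   flux -- the case where the combinatorial enumerator wastes work.
#' * `combination_blowup_network(n)`: `r_a1: a -> t`, `r_a2: a -> b`,
#'   `r_prime: (n-1) b -> c_1 + ... + c_n`, and `r_i: c_i + p_i -> a`. Every
#'   single source is a topological precursor set, but the only
#'   stoichiometric precursor set is all `n` sources together -- the
#'   combinatorial enumerator succeeds only when combining all `n` factories.
#'
#' @param n number of sources (>= 2).
#' @param check run the property checklist after construction.
#' @return a `metabolic_network`.
#' @name example_networks
NULL

.flag <- function(ok, what) if (!ok) stop("fixture checklist failed: ", what)

.setlist_eq <- function(a, b) {
  key <- function(l) sort(vapply(l, function(s) paste(sort(s), collapse = ","),
                                 ""))
  identical(key(a), key(b))
}

#' @rdname example_networks
#' @export
toy_chain_network <- function(check = TRUE) {
  net <- metabolic_network(
    list(reaction("r1", c(c1 = 1, c2 = 2), c(c3 = 1)),
         reaction("r2", c(c3 = 3), c(c4 = 1))),
    sources = c("c1", "c2"), targets = "c4")
  if (check) {
    S <- stoich_matrix(net)
    .flag(all(S[, "r1"] == c(-1, -2, 1, 0)), "column r1")
    .flag(all(S[, "r2"] == c(0, 0, -3, 1)), "column r2")
    .flag(is_topological_factory(net, c("r1", "r2"), c("c1", "c2")),
          "c4 topologically reachable from {c1, c2}")
  }
  net
}

#' @rdname example_networks
#' @export
krebs_toy_network <- function(check = TRUE) {
  net <- metabolic_network(
    list(reaction("r1", c(p = 1, a = 1), c(c = 1)),
         reaction("r2", c(c = 1), c(b = 1)),
         reaction("r3", c(b = 1), c(a = 1, t = 1))),
    sources = "p", targets = "t")
  if (check) {
    S <- stoich_matrix(net)
    v <- c(r1 = 1, r2 = 1, r3 = 1)
    net_prod <- as.vector(S %*% v)
    names(net_prod) <- rownames(S)
    .flag(all(net_prod[c("a", "b", "c")] == 0), "cycle regenerates a, b, c")
    .flag(net_prod["t"] == 1, "unit flux produces one t")
  }
  net
}

#' @rdname example_networks
#' @export
topo_vs_stoich_network <- function(check = TRUE) {
  net <- metabolic_network(
    list(reaction("r1", c(p1 = 1, b = 1), c(c = 1)),
         reaction("r2", c(a = 1), c(b = 1)),
         reaction("r3", c(b = 1, c = 1), c(a = 1, d = 1)),
         reaction("r4", c(d = 1), c(b = 1, t = 1)),
         reaction("r5", c(e = 1), c(t = 1)),
         reaction("r6", c(e = 1), c(f = 1)),
         reaction("r7", c(f = 1, p3 = 1), c(e = 1)),
         reaction("r8", c(p2 = 1, p3 = 1), c(t = 1))),
    sources = c("p1", "p2", "p3"), targets = "t")
  if (check) {
    cfg <- sps_config()
    .flag(.setlist_eq(enumerate_minimal_tps(net), list("p1", "p3")),
          "minimal topological precursor sets are {p1} and {p3}")
    sps <- enumerate_minimal_sps(net, cfg)$solutions
    .flag(.setlist_eq(lapply(sps, `[[`, "sources"),
                      list("p1", c("p2", "p3"))),
          "minimal stoichiometric precursor sets are {p1} and {p2,p3}")
    .flag(is_topological_factory(net, c("r1", "r3", "r4"), "p1"),
          "{r1,r3,r4} is a topological factory from {p1}")
    .flag(!check_s_factory(net, c("r1", "r3", "r4"), "p1", config = cfg)$feasible,
          "{r1,r3,r4} is not a stoichiometric factory (r2 is required)")
    .flag(check_s_factory(net, c("r1", "r2", "r3", "r4"), "p1", config = cfg)$feasible,
          "{r1,r2,r3,r4} is a stoichiometric factory from {p1}")
    .flag(is_topological_factory(net, c("r7", "r6", "r5"), "p3"),
          "{r7,r6,r5} is a topological factory from {p3}")
    .flag(check_s_factory(net, "r8", c("p2", "p3"), config = cfg)$feasible,
          "{r8} is a stoichiometric factory from {p2,p3}")
  }
  net
}

#' @rdname example_networks
#' @export
decoy_factories_network <- function(n, check = TRUE) {
  stopifnot(n >= 2)
  srcs <- paste0("p", seq_len(n))
  rx <- list(reaction("r1", c(p1 = 1), c(t = 1)))
  for (i in 2:n) {
    rx[[i]] <- reaction(paste0("r", i),
                        stats::setNames(1, paste0("p", i)), c(c = 1))
  }
  rx <- c(rx, list(reaction("r_a", c(c = 1, b = 1), c(a = 1)),
                   reaction("r_b", c(a = 1), c(b = 1)),
                   reaction("r_t", c(a = 1), c(t = 1))))
  net <- metabolic_network(rx, sources = srcs, targets = "t")
  if (check) {
    f <- enumerate_mto_factories(many_to_one(net))
    .flag(length(f) == n, sprintf("%d minimal many-to-one factories", n))
    sps <- enumerate_minimal_sps(net, sps_config())$solutions
    .flag(.setlist_eq(lapply(sps, `[[`, "sources"), list("p1")),
          "unique minimal stoichiometric precursor set {p1}")
  }
  net
}

#' @rdname example_networks
#' @export
combination_blowup_network <- function(n, check = TRUE) {
  stopifnot(n >= 2)
  srcs <- paste0("p", seq_len(n))
  cs <- paste0("c", seq_len(n))
  rx <- list(reaction("r_a1", c(a = 1), c(t = 1)),
             reaction("r_a2", c(a = 1), c(b = 1)),
             reaction("r_prime", c(b = n - 1),
                      stats::setNames(rep(1, n), cs)))
  for (i in seq_len(n)) {
    rx[[3 + i]] <- reaction(paste0("r", i),
                            stats::setNames(c(1, 1), c(cs[i], srcs[i])),
                            c(a = 1))
  }
  net <- metabolic_network(rx, sources = srcs, targets = "t")
  if (check) {
    f <- enumerate_mto_factories(many_to_one(net))
    .flag(length(f) == n, sprintf("%d minimal many-to-one factories", n))
    sps <- enumerate_minimal_sps(net, sps_config())$solutions
    .flag(.setlist_eq(lapply(sps, `[[`, "sources"), list(srcs)),
          "the only minimal stoichiometric precursor set is all sources")
  }
  net
}

#' Generate a random metabolic network
#'
#' Rejection-samples a random directed hypergraph until at least one subset
#' of the sources is a topological precursor set of the target (checked by
#' forward closure from all sources), so that every generated network admits
#' at least one candidate solution. Reproducible for a fixed seed. Sizes are
#' deliberately capped small (<= 10 sources) so the exhaustive
#' `2^|sources|` brute-force oracle stays tractable in tests.
#'
#' @param n_compounds number of internal compounds.
#' @param n_reactions number of reactions.
#' @param max_subs,max_prods maximal substrate/product side sizes.
#' @param coeff_choices pool of stoichiometric coefficients to draw from.
#' @param n_sources,n_targets number of source/target compounds.
#' @param seed integer seed (mandatory: networks are identified by it).
#' @param max_tries rejection-sampling budget.
#' @return a normalized `metabolic_network`.
#' @export
random_network <- function(n_compounds = 8, n_reactions = 14, max_subs = 2,
                           max_prods = 2, coeff_choices = c(1, 1, 1, 2),
                           n_sources = 4, n_targets = 1, seed,
                           max_tries = 200) {
  stopifnot(n_compounds >= 1, n_reactions >= 1, n_sources >= 1,
            n_sources <= 10, n_targets >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ints <- paste0("m", seq_len(n_compounds))
  srcs <- paste0("x", seq_len(n_sources))
  tgts <- paste0("t", seq_len(n_targets))
  for (try in seq_len(max_tries)) {
    rx <- vector("list", n_reactions)
    for (k in seq_len(n_reactions)) {
      ns <- sample.int(max_subs, 1)
      np <- sample.int(max_prods, 1)
      subs <- sample(c(ints, srcs), ns)
      prods <- sample(setdiff(c(ints, tgts), subs), np)
      rx[[k]] <- reaction(
        paste0("r", k),
        stats::setNames(sample(coeff_choices, ns, replace = TRUE), subs),
        stats::setNames(sample(coeff_choices, np, replace = TRUE), prods))
    }
    net <- metabolic_network(rx, sources = srcs, targets = tgts,
                             compounds = c(ints, srcs, tgts))
    # forward closure from all sources must reach every target
    avail <- srcs
    repeat {
      fire <- vapply(net$reactions, function(r)
        all(names(r$substrates) %in% avail), logical(1))
      nxt <- unique(c(avail, unlist(lapply(net$reactions[fire], function(r)
        names(r$products)))))
      if (length(nxt) == length(avail)) break
      avail <- nxt
    }
    if (all(tgts %in% avail)) return(normalize_network(net))
  }
  stop("random_network(): rejection budget exceeded; relax the parameters")
}
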