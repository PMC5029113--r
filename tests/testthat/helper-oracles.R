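# shared helpers: canonical keys for solution families and brute-force
# oracles kept deliberately naive (their value is independence, not speed)

solset_key <- function(sets) {
  paste(sort(vapply(sets, function(s) paste(sort(s), collapse = ","), "")),
        collapse = ";")
}

expect_same_family <- function(a, b) {
  expect_identical(solset_key(a), solset_key(b))
}

# all inclusion-minimal stoichiometric factories from X, by exhaustive
# subset scan over the reaction set
brute_minimal_s_factories <- function(net, X, mode = "accumulate",
                                      config = sps_config()) {
  rids <- names(net$reactions)
  feas <- list()
  for (k in seq_along(rids)) {
    for (F in utils::combn(rids, k, simplify = FALSE)) {
      if (check_s_factory(net, F, X, mode = mode, config = config)$feasible) {
        feas[[length(feas) + 1L]] <- sort(F)
      }
    }
  }
  keep <- vapply(feas, function(f)
    !any(vapply(feas, function(g)
      length(g) < length(f) && all(g %in% f), logical(1))), logical(1))
  feas[keep]
}

# minimal-topological-factory test by definition: H is a factory from its
# own source footprint and no proper subset is one from the same footprint
brute_is_minimal_topofactory <- function(psi, H) {
  X <- intersect(substrates_of(psi, H), psi$sources)
  if (!is_topological_factory(psi, H, X)) return(FALSE)
  if (!length(H)) return(TRUE)
  for (k in 0:(length(H) - 1L)) {
    subs <- if (k == 0L) list(character(0))
            else utils::combn(H, k, simplify = FALSE)
    for (Hp in subs) {
      if (is_topological_factory(psi, Hp, X)) return(FALSE)
    }
  }
  TRUE
}

# multiply every stoichiometric coefficient by a global constant
scale_network <- function(net, c) {
  rx <- lapply(net$reactions, function(r)
    reaction(r$id, r$substrates * c, r$products * c, r$reversible))
  metabolic_network(unname(rx), net$sources, net$targets,
                    compounds = net$compounds)
}

all_fixture_networks <- function() {
  list(toy = toy_chain_network(check = FALSE),
       cycle = krebs_toy_network(check = FALSE),
       contrast = topo_vs_stoich_network(check = FALSE),
       decoy = decoy_factories_network(3, check = FALSE),
       blowup = combination_blowup_network(3, check = FALSE))
}
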