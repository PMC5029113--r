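# topological factories, hypergraph paths, many-to-one enumeration, combi

contrast <- topo_vs_stoich_network(check = FALSE)
cyc <- krebs_toy_network(check = FALSE)
cfg <- sps_config()

test_that("topological factory containment test", {
  expect_true(is_topological_factory(contrast, c("r1", "r3", "r4"), "p1"))
  expect_false(is_topological_factory(contrast, c("r1", "r3"), "p1"))
  expect_true(is_topological_factory(contrast, c("r7", "r6", "r5"), "p3"))
  # vacuous containment: no reactions needed when the targets are sources
  tiny <- metabolic_network(list(reaction("r", c(a = 1), c(b = 1))),
                            sources = "a", targets = "b",
                            allow_source_target_overlap = TRUE)
  expect_true(is_topological_factory(tiny, character(0), X = "b",
                                     targets = "b"))
})

test_that("hypergraph paths follow the substrate/product chain conditions", {
  p <- find_hyperpath(cyc, c("r1", "r2", "r3"), "c", "t")
  expect_identical(p$metabolites, c("c", "b", "t"))
  expect_identical(p$reactions, c("r2", "r3"))
  expect_identical(find_hyperpath(cyc, character(0), "t", "t"),
                   list(metabolites = "t", reactions = character(0)))
  expect_null(find_hyperpath(contrast, "r8", "a", "t"))
  # returned chain satisfies both incidence conditions
  q <- find_hyperpath(contrast, names(contrast$reactions), "p1", "t")
  for (i in seq_along(q$reactions)) {
    r <- contrast$reactions[[q$reactions[i]]]
    expect_true(q$metabolites[i] %in% names(r$substrates))
    expect_true(q$metabolites[i + 1] %in% names(r$products))
  }
  expect_false(anyDuplicated(q$reactions) > 0)
})

test_that("minimality validator matches the definition on hand cases", {
  d3 <- decoy_factories_network(3, check = FALSE)
  psi <- many_to_one(d3)
  # the p2-fed factory through the deficient cycle is minimal
  expect_true(validate_minimal_mto_factory(
    psi, c("r2", "r_a", "r_b", "r_t")))
  # without the feeder, c has no producer
  expect_false(validate_minimal_mto_factory(psi, c("r_a", "r_b", "r_t")))
  # a duplicated producer of t violates exactly-one on nothing but fails
  # the path/minimality conditions
  expect_false(validate_minimal_mto_factory(psi, c("r1", "r2", "r_a",
                                                   "r_b", "r_t")))
})

test_that("minimality validator is equivalent to brute force (exhaustive)", {
  nets <- list(krebs_toy_network(check = FALSE),
               decoy_factories_network(3, check = FALSE),
               combination_blowup_network(3, check = FALSE))
  for (net in nets) {
    psi <- many_to_one(normalize_network(net))
    rids <- names(psi$reactions)
    for (k in seq_along(rids)) {
      for (H in utils::combn(rids, k, simplify = FALSE)) {
        expect_identical(validate_minimal_mto_factory(psi, H),
                         brute_is_minimal_topofactory(psi, H),
                         info = paste(H, collapse = ","))
      }
    }
  }
})

test_that("many-to-one factory enumeration matches counts and brute force", {
  for (n in c(3, 5)) {
    fd <- enumerate_mto_factories(many_to_one(
      decoy_factories_network(n, check = FALSE)))
    expect_length(fd, n)
    fb <- enumerate_mto_factories(many_to_one(
      combination_blowup_network(n, check = FALSE)))
    expect_length(fb, n)
  }
  # exhaustive cross-check on the contrast network's transform
  psi <- many_to_one(contrast)
  rids <- names(psi$reactions)
  brute <- list()
  for (k in seq_along(rids)) {
    for (H in utils::combn(rids, k, simplify = FALSE)) {
      if (validate_minimal_mto_factory(psi, H)) {
        brute[[length(brute) + 1L]] <- sort(H)
      }
    }
  }
  enum <- lapply(enumerate_mto_factories(psi), `[[`, "reactions")
  expect_same_family(enum, brute)
})

test_that("minimal topological precursor sets are the minimal footprints", {
  expect_same_family(enumerate_minimal_tps(contrast), list("p1", "p3"))
  expect_same_family(enumerate_minimal_tps(cyc), list("p"))
  b3 <- combination_blowup_network(3, check = FALSE)
  expect_same_family(enumerate_minimal_tps(b3),
                     list("p1", "p2", "p3"))
  # every stoichiometric solution is topologically supported
  for (net in list(contrast, cyc, b3)) {
    tps <- enumerate_minimal_tps(net)
    for (X in solution_sets(enumerate_minimal_sps(net, cfg))) {
      expect_true(any(vapply(tps, function(tp) all(tp %in% X),
                             logical(1))))
    }
  }
})

test_that("combi agrees with the MILP engine on the fixtures", {
  expect_same_family(solution_sets(combi_enumerate(contrast, cfg)),
                     list("p1", c("p2", "p3")))
  cd <- combi_enumerate(decoy_factories_network(5, check = FALSE), cfg)
  expect_same_family(solution_sets(cd), list("p1"))
  expect_identical(cd$solutions[[1]]$found_at_k, 1L)
  cb <- combi_enumerate(combination_blowup_network(4, check = FALSE), cfg)
  expect_same_family(solution_sets(cb), list(paste0("p", 1:4)))
  expect_identical(cb$solutions[[1]]$found_at_k, 4L)
})

test_that("combi warns for steady state, where its completeness can fail", {
  # regression fixture: a network whose minimal steady-state solution
  # {x1, x3, x5} is not a union of factory footprints (disposal sources);
  # the MILP and brute-force routes agree, combi provably cannot find it
  net <- random_network(n_compounds = 10, n_reactions = 22, max_subs = 3,
                        coeff_choices = c(1, 1, 2, 3), n_sources = 6,
                        seed = 1007)
  scfg <- sps_config(mode = "steady-state")
  milp <- solution_sets(enumerate_minimal_sps(net, scfg))
  expect_same_family(milp, solution_sets(brute_enumerate(net, scfg)))
  expect_true(any(vapply(milp, function(s)
    setequal(s, c("x1", "x3", "x5")), logical(1))))
  expect_warning(comb <- combi_enumerate(net, scfg), "steady state")
  # combi stays sound (finds only true minimal solutions) but incomplete
  for (s in solution_sets(comb)) {
    expect_true(any(vapply(milp, function(m) setequal(m, s), logical(1))))
  }
  expect_lt(length(comb$solutions), length(milp))
})
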