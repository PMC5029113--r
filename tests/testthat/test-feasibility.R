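# LP/MILP membership oracles and minimal-subset reduction

contrast <- topo_vs_stoich_network(check = FALSE)
cyc <- krebs_toy_network(check = FALSE)
cfg <- sps_config()

test_that("precursor-set membership matches the worked examples", {
  c1 <- check_sps(contrast, "p1", config = cfg)
  expect_true(c1$feasible)
  expect_setequal(c1$active_reactions, c("r1", "r2", "r3", "r4"))
  expect_false(check_sps(contrast, "p3", config = cfg)$feasible)
  expect_true(check_sps(contrast, c("p1", "p2", "p3"), config = cfg)$feasible)
  # the cycle toy is feasible from {p} in both relaxed and exact balance
  expect_true(check_sps(cyc, "p", mode = "accumulate", config = cfg)$feasible)
  st <- check_sps(cyc, "p", mode = "steady-state", config = cfg)
  expect_true(st$feasible)
  # its witness is the (scaled) unit flux around the cycle
  fl <- st$flux[c("r1", "r2", "r3")]
  expect_true(all(fl > 0))
  expect_equal(unname(fl / fl[1]), c(1, 1, 1), tolerance = 1e-6)
})

test_that("stoichiometric factory verification distinguishes the candidates", {
  expect_true(check_s_factory(cyc, c("r1", "r2", "r3"), "p",
                              config = cfg)$feasible)
  # without r2 the cycle cannot regenerate a: not a factory from {p1}
  expect_false(check_s_factory(contrast, c("r1", "r3", "r4"), "p1",
                               config = cfg)$feasible)
  expect_true(check_s_factory(contrast, c("r1", "r2", "r3", "r4"), "p1",
                              config = cfg)$feasible)
  expect_true(check_s_factory(contrast, "r8", c("p2", "p3"),
                              config = cfg)$feasible)
  # asserted-active reactions must carry flux: empty factory cannot produce
  expect_false(check_s_factory(contrast, character(0), "p1",
                               config = cfg)$feasible)
})

test_that("machinery-duplicating membership rejects regenerating cycles", {
  expect_false(check_md_sps(cyc, "p", cfg)$feasible)
  # a single straight-through reaction has no internal substrates
  one <- metabolic_network(list(reaction("r", c(p = 1), c(t = 1))),
                           sources = "p", targets = "t")
  c1 <- check_md_sps(one, "p", cfg)
  expect_true(c1$feasible)
  expect_identical(c1$active_reactions, "r")
  # {p1} on the contrast network: the only route runs through the
  # b/c/a/d cycle whose summed net production is identically zero
  expect_false(check_md_sps(contrast, "p1", cfg)$feasible)
  expect_true(check_md_sps(contrast, c("p2", "p3"), cfg)$feasible)
})

test_that("cut-set membership is the complement test", {
  expect_true(check_scs(contrast, c("p1", "p3"), config = cfg))
  expect_false(check_scs(contrast, "p1", config = cfg))
  expect_true(check_scs(contrast, c("p1", "p2", "p3"), config = cfg))
  # brute-force cross-check over every subset
  xs <- contrast$sources
  for (k in 0:3) {
    combs <- if (k == 0) list(character(0))
             else utils::combn(xs, k, simplify = FALSE)
    for (X in combs) {
      expect_identical(
        check_scs(contrast, X, config = cfg),
        !check_sps(contrast, setdiff(xs, X), config = cfg)$feasible)
    }
  }
})

test_that("greedy reduction returns a lexicographically-determined minimal set", {
  expect_identical(reduce_to_minimal(contrast, c("p1", "p2", "p3"),
                                     config = cfg),
                   c("p2", "p3"))  # p1 removable first, then neither
  expect_identical(reduce_to_minimal(contrast, "p1", config = cfg), "p1")
  b3 <- combination_blowup_network(3, check = FALSE)
  expect_identical(reduce_to_minimal(b3, c("p1", "p2", "p3"), config = cfg),
                   c("p1", "p2", "p3"))
  expect_error(reduce_to_minimal(contrast, "p3", config = cfg),
               "not feasible")
})

test_that("feasibility is monotone and invariant to scaling and epsilon", {
  nets <- all_fixture_networks()
  nets$rand <- random_network(seed = 99)
  for (net in nets) {
    net <- normalize_network(net)
    xs <- net$sources
    sub_pool <- if (length(xs) > 1) {
      utils::combn(xs, length(xs) - 1L, simplify = FALSE)
    } else {
      list(character(0))
    }
    for (X in c(sub_pool, list(xs))) {
      for (m in c("accumulate", "steady-state")) {
        v <- check_sps(net, X, mode = m, config = cfg)$feasible
        # monotone: adding any source never breaks feasibility
        if (v) {
          for (x in setdiff(xs, X)) {
            expect_true(check_sps(net, union(X, x), mode = m,
                                  config = cfg)$feasible)
          }
        }
        # one global coefficient scaling changes no verdict
        expect_identical(
          check_sps(scale_network(net, 2.5), X, mode = m,
                    config = cfg)$feasible, v)
        # epsilon 0.5 vs 1.0 (both << U): rescaling argument
        expect_identical(
          check_sps(net, X, mode = m,
                    config = sps_config(epsilon = 1))$feasible, v)
      }
      # machinery-duplicating membership implies plain membership
      if (check_md_sps(net, X, cfg)$feasible) {
        expect_true(check_sps(net, X, mode = "accumulate",
                              config = cfg)$feasible)
      }
    }
  }
})

test_that("certificates satisfy the raw constraint system they claim", {
  for (m in c("accumulate", "steady-state")) {
    cert <- check_sps(contrast, "p1", mode = m, config = cfg)
    S <- as.matrix(stoich_matrix(contrast))
    np <- as.numeric(S %*% cert$flux[colnames(S)])
    names(np) <- rownames(S)
    expect_true(all(np[setdiff(rownames(S), "p1")] >= -1e-6))
    expect_gt(np[["t"]], 0)
    if (m == "steady-state") {
      expect_equal(unname(np[c("a", "b", "c", "d", "e", "f")]),
                   rep(0, 6), tolerance = 1e-6)
    }
  }
  md <- check_md_sps(contrast, c("p2", "p3"), cfg)
  S <- as.matrix(stoich_matrix(contrast))
  np <- as.numeric(S %*% md$flux[colnames(S)])
  names(np) <- rownames(S)
  Y <- setdiff(substrates_of(contrast, md$active_reactions),
               c(contrast$sources))
  expect_true(all(np[c("t", Y)] > 0))
})
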