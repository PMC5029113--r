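# network model, normalization, matrix assembly, transforms

test_that("reaction and network constructors validate their input", {
  expect_error(reaction("r", c(a = 1), c(a = 2)), "both sides")
  expect_error(reaction("r", c(a = -1), c(b = 1)), "> 0")
  expect_error(reaction("", c(a = 1), c(b = 1)), "non-empty")
  expect_error(
    metabolic_network(list(reaction("r", c(a = 1), c(b = 1))),
                      sources = "zz", targets = "b"),
    "unknown compound")
  expect_error(
    metabolic_network(list(reaction("r", c(a = 1), c(b = 1)),
                           reaction("r", c(b = 1), c(a = 1))),
                      sources = "a", targets = "b"),
    "duplicated reaction")
  expect_error(
    metabolic_network(list(reaction("r", c(a = 1), c(b = 1))),
                      sources = "a", targets = "a"),
    "both source and target")
  # zero-substrate reactions are reserved for internally built pools
  expect_error(
    metabolic_network(list(reaction("r", numeric(0), c(b = 1))),
                      sources = character(0), targets = "b"),
    "empty substrate")
})

test_that("normalize splits reversible reactions and isolates produced sources", {
  net <- metabolic_network(
    list(reaction("r5", c(a = 1), c(b = 1), reversible = TRUE),
         reaction("r9", c(b = 1), c(x = 1))),
    sources = "x", targets = "b")
  nn <- normalize_network(net)
  expect_true(all(c("r5_fwd", "r5_rev", "r9") %in% names(nn$reactions)))
  expect_identical(nn$reactions$r5_rev$substrates, c(b = 1))
  expect_identical(nn$reactions$r5_rev$products, c(a = 1))
  # x is produced by r9: a dummy source x_src and r_src_x: x_src -> x appear
  expect_true("x_src" %in% nn$compounds)
  expect_identical(nn$sources, "x_src")
  expect_identical(nn$reactions$r_src_x$substrates, c(x_src = 1))
  expect_identical(nn$reactions$r_src_x$products, c(x = 1))
  expect_false(any(nn$sources %in% products_of(nn)))
  # idempotence, and a fixed point on an already-normal network
  expect_identical(normalize_network(nn), nn)
  fix <- topo_vs_stoich_network(check = FALSE)
  expect_identical(normalize_network(fix), fix)
})

test_that("stoichiometric matrix encodes products positive, substrates negative", {
  net <- toy_chain_network()
  S <- stoich_matrix(net)
  expect_s4_class(S, "dgCMatrix")
  expect_identical(dimnames(S), list(c("c1", "c2", "c3", "c4"),
                                     c("r1", "r2")))
  expect_equal(as.numeric(S[, "r1"]), c(-1, -2, 1, 0))
  expect_equal(as.numeric(S[, "r2"]), c(0, 0, -3, 1))
  # empty reaction list
  empty <- metabolic_network(list(), sources = "a", targets = "b",
                             compounds = c("a", "b"))
  expect_equal(dim(stoich_matrix(empty)), c(2L, 0L))
  # unit flux on the regenerating cycle: zero net at internals, +1 at target
  k <- krebs_toy_network()
  v <- rep(1, 3)
  np <- as.numeric(stoich_matrix(k) %*% v)
  names(np) <- k$compounds
  expect_equal(unname(np[c("a", "b", "c")]), c(0, 0, 0))
  expect_equal(unname(np[["t"]]), 1)
  # matrix encoding conserves reaction-wise net contributions
  net2 <- topo_vs_stoich_network(check = FALSE)
  S2 <- as.matrix(stoich_matrix(net2))
  v2 <- seq_len(ncol(S2))
  byhand <- stats::setNames(rep(0, length(net2$compounds)), net2$compounds)
  for (i in seq_along(net2$reactions)) {
    r <- net2$reactions[[i]]
    byhand[names(r$products)] <- byhand[names(r$products)] +
      r$products * v2[i]
    byhand[names(r$substrates)] <- byhand[names(r$substrates)] -
      r$substrates * v2[i]
  }
  expect_equal(as.numeric(S2 %*% v2), unname(byhand))
})

test_that("many-to-one transform splits multi-product reactions only", {
  net <- topo_vs_stoich_network(check = FALSE)
  psi <- many_to_one(net)
  # r3: b + c -> a + d and r4: d -> b + t are the only multi-product ones
  expect_setequal(names(psi$reactions),
                  c("r1", "r2", "r3_a", "r3_d", "r4_b", "r4_t",
                    "r5", "r6", "r7", "r8"))
  expect_identical(psi$reactions$r3_a$substrates, c(b = 1, c = 1))
  expect_identical(psi$reactions$r3_a$products, c(a = 1))
  expect_identical(psi$reactions$r3_d$products, c(d = 1))
  # psi copies share the substrate side and partition the product side
  map <- attr(psi, "mto_map")
  for (orig in names(net$reactions)) {
    copies <- names(map)[map == orig]
    r <- net$reactions[[orig]]
    for (cp in copies) {
      expect_identical(psi$reactions[[cp]]$substrates, r$substrates)
    }
    prods <- unlist(lapply(psi$reactions[copies],
                           function(x) names(x$products)))
    expect_setequal(prods, names(r$products))
  }
  # idempotence: a many-to-one network transforms to itself
  expect_identical(names(many_to_one(psi)$reactions), names(psi$reactions))
  # wide product side: n copies with the full substrate multiset
  b4 <- combination_blowup_network(4, check = FALSE)
  psib <- many_to_one(b4)
  copies <- grep("^r_prime_", names(psib$reactions), value = TRUE)
  expect_length(copies, 4)
  for (cp in copies) {
    expect_identical(psib$reactions[[cp]]$substrates, c(b = 3))
  }
})

test_that("augment adds pools and the pooled target deterministically", {
  net <- topo_vs_stoich_network(check = FALSE)
  aug <- augment_network(net)
  pools <- attr(aug, "source_pool_reactions")
  expect_identical(unname(pools), c("pool_p1", "pool_p2", "pool_p3"))
  for (p in pools) {
    expect_length(aug$reactions[[p]]$substrates, 0)
    expect_equal(unname(aug$reactions[[p]]$products), 1)
  }
  expect_identical(attr(aug, "pooled_target"), "t_bar")
  rbar <- aug$reactions[[attr(aug, "pooled_target_reaction")]]
  expect_identical(rbar$substrates, c(t = 1))
  expect_identical(rbar$products, c(t_bar = 1))
  # identity case
  id <- augment_network(net, pool_sources = FALSE, pool_target = FALSE)
  expect_identical(names(id$reactions), names(net$reactions))
  expect_identical(id$compounds, net$compounds)
  # single-target pooling on the cycle toy
  k <- augment_network(krebs_toy_network(check = FALSE),
                       pool_sources = FALSE)
  expect_identical(k$reactions$r_bar$substrates, c(t = 1))
})
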