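mk_mpr <- function(...) {
  convert_data_model(
    syngraph_from_equations(lapply(list(...), build_chemical_equation)),
    "monopartite_reactions"
  )
}

test_that("node substitution cost derives from chemistry", {
  m1 <- canonicalize_molecule("CCO")
  m1b <- canonicalize_molecule("OCC")
  m2 <- canonicalize_molecule("CCCO")
  ce <- build_chemical_equation("CCO.CC(=O)O>>CC(=O)OCC.O")
  expect_identical(node_substitution_cost(m1, m1b), 0)
  expect_identical(node_substitution_cost(m1, ce), 1)
  # independent fingerprint oracle
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(c(a = "CCO", b = "CCCO")))
  fp <- ChemmineR::as.matrix(ChemmineR::fingerprintOB(sdf, "ECFP4"))
  tan <- sum(fp[1, ] & fp[2, ]) / sum(fp[1, ] | fp[2, ])
  expect_equal(node_substitution_cost(m1, m2), 1 - tan)
})

test_that("frozen edit-path examples: extra producer costs node+edge, a swapped step costs its dissimilarity", {
  chain <- mk_mpr("NC>>NCO", "NCO>>NCOC")
  chain_plus <- mk_mpr("NC>>NCO", "NCO>>NCOC", "NOO>>NC")
  # one inserted reaction node + one inserted edge under unit costs
  expect_identical(ged(chain, chain_plus), 2)
  expect_identical(oracle_ged(chain, chain_plus,
                              pin_roots = TRUE), 2)

  swapped <- mk_mpr("NO>>NCO", "NCO>>NCOC")
  ce_a <- build_chemical_equation("NC>>NCO")
  ce_b <- build_chemical_equation("NO>>NCO")
  expect_equal(ged(chain, swapped),
               1 - chemical_similarity(ce_a, ce_b))
})

test_that("ged is a pseudometric on routes: zero self-distance, symmetry, triangle spot-check", {
  gs <- lapply(c(21, 22, 23), random_small_mpr)
  for (g in gs) expect_identical(ged(g, g), 0)
  for (i in 1:2) {
    for (j in (i + 1):3) {
      expect_equal(ged(gs[[i]], gs[[j]]), ged(gs[[j]], gs[[i]]))
    }
  }
  d12 <- ged(gs[[1]], gs[[2]])
  d23 <- ged(gs[[2]], gs[[3]])
  d13 <- ged(gs[[1]], gs[[3]])
  expect_lte(d13, d12 + d23 + 1e-9)
})

test_that("search equals exhaustive enumeration, rooted and unrooted, on small graphs", {
  p_free <- ged_params(use_roots = FALSE)
  for (s in 1:6) {
    g1 <- random_small_mpr(s)
    g2 <- random_small_mpr(s + 50)
    expect_equal(ged(g1, g2, p_free), oracle_ged(g1, g2, p_free))
    expect_equal(ged(g1, g2), oracle_ged(g1, g2, pin_roots = TRUE))
  }
})

test_that("adding one leaf step moves the distance by at most one node plus one edge", {
  base <- generate_route(route_spec(3, seed = 31))$route
  other <- generate_route(route_spec(2, seed = 32))$route
  a <- convert_data_model(other, "monopartite_reactions")
  b <- convert_data_model(base, "monopartite_reactions")
  grown <- perturb_route(base, 1, seed = 33)
  b2 <- convert_data_model(grown$route, "monopartite_reactions")
  expect_lte(ged(a, b2), ged(a, b) + 2 + 1e-9)
})

test_that("the approximate mode is an upper bound that is exact on identical routes", {
  g1 <- random_small_mpr(61)
  g2 <- random_small_mpr(62)
  exact <- ged(g1, g2)
  approx <- ged(g1, g2, ged_params(method = "approximate"))
  expect_gte(approx, exact - 1e-9)
  expect_identical(ged(g1, g1, ged_params(method = "approximate")), 0)
})

test_that("cross-model comparison is refused", {
  rt <- generate_route(route_spec(2, seed = 71))$route
  expect_error(ged(rt, convert_data_model(rt, "monopartite_reactions")),
               class = "synkit_model_mismatch")
})

test_that("distance matrices are symmetric, zero-diagonal, and parallel-stable", {
  rt <- generate_route(route_spec(2, seed = 81))$route
  dm0 <- route_distance_matrix(list(rt, rt, rt))
  expect_true(all(dm0$values == 0))

  routes <- lapply(1:6, function(s) {
    generate_route(random_route_spec(s + 300))$route
  })
  serial <- route_distance_matrix(routes)
  expect_identical(serial$values, t(serial$values))
  expect_true(all(diag(serial$values) == 0))
  expect_true(all(serial$values >= 0))
  parallel4 <- route_distance_matrix(routes, parallel = TRUE, n_workers = 4L)
  expect_identical(parallel4$values, serial$values)

  expect_error(route_distance_matrix(routes[1]),
               class = "synkit_insufficient_input")

  td <- tidy(serial)
  expect_identical(nrow(td), 15L)
  expect_true(all(c("route_a", "route_b", "distance") %in% names(td)))
})
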