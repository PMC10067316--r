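# helpers building small graphs from explicit reaction SMILES
mk_bip <- function(..., label = "") {
  syngraph_from_equations(lapply(list(...), build_chemical_equation),
                          source_label = label)
}
mk_mpr <- function(...) convert_data_model(mk_bip(...), "monopartite_reactions")

test_that("roots and leaves follow degrees in the synthetic direction", {
  chain <- mk_mpr("NC>>NCO", "NCO>>NCOC", "NCOC>>NCOCC")
  rl <- roots_and_leaves(chain)
  expect_length(rl$roots, 1L)
  expect_length(rl$leaves, 1L)

  y <- mk_mpr("NC>>NCC", "NO>>NOC", "NCC.NOC>>NCCNOC")
  rl <- roots_and_leaves(y)
  expect_length(rl$roots, 1L)
  expect_length(rl$leaves, 2L)

  expect_error(roots_and_leaves(new_syngraph(list())),
               class = "synkit_empty_graph")
})

test_that("graph equality is order-free, reagent-blind, and policy-sensitive", {
  a <- mk_bip("NC>>NCO", "NCO.NCC>>NCONCC")
  b <- mk_bip("NCC.NCO>>NCONCC", "NC>>NCO")   # permuted input order
  expect_true(syngraph_equal(a, b))

  with_reagent <- mk_bip("NC>[H+]>NCO", "NCO.NCC>>NCONCC")
  expect_true(syngraph_equal(a, with_reagent))

  iso1 <- syngraph_from_equations(list(
    build_chemical_equation("C[C@H](O)CC>>C[C@H](N)CC")
  ))
  iso2 <- syngraph_from_equations(list(
    build_chemical_equation("C[C@@H](O)CC>>C[C@@H](N)CC")
  ))
  expect_false(syngraph_equal(iso1, iso2))
  ns1 <- syngraph_from_equations(list(build_chemical_equation(
    "C[C@H](O)CC>>C[C@H](N)CC", policy = "canonical-smiles-no-stereo"
  )))
  ns2 <- syngraph_from_equations(list(build_chemical_equation(
    "C[C@@H](O)CC>>C[C@@H](N)CC", policy = "canonical-smiles-no-stereo"
  )))
  expect_true(syngraph_equal(ns1, ns2))

  mpr <- convert_data_model(a, "monopartite_reactions")
  expect_error(syngraph_equal(a, mpr), class = "synkit_model_mismatch")
})

test_that("merge is a union with value-object deduplication", {
  g <- mk_bip("NC>>NCO", "NCO>>NCOC")
  expect_true(syngraph_equal(merge_syngraphs(list(g, g)), g))

  # two 3-step routes sharing only their final (root) reaction
  final <- "NCOC>>NCOCO"
  ra <- mk_bip("NC>>NCO", "NCO>>NCOC", final)
  rb <- mk_bip("NOC>>NOCO", "NOCO>>NCOC", final)
  merged <- merge_syngraphs(list(ra, rb))
  n_ce <- sum(vapply(merged$nodes, function(n) {
    n$kind == "chemical_equation"
  }, TRUE))
  expect_identical(n_ce, 5L)

  expect_error(merge_syngraphs(list()), class = "synkit_empty_graph")
  expect_error(
    merge_syngraphs(list(g, convert_data_model(g, "monopartite_reactions"))),
    class = "synkit_model_mismatch"
  )
})

test_that("merge is idempotent, commutative and associative on random routes", {
  routes <- lapply(1:9, function(s) {
    generate_route(random_route_spec(s))$route
  })
  withr::with_seed(11, {
    for (trial in 1:10) {
      idx <- sample(9, 3)
      x <- routes[[idx[1]]]; y <- routes[[idx[2]]]; z <- routes[[idx[3]]]
      expect_true(syngraph_equal(merge_syngraphs(list(x, x)), x))
      expect_true(syngraph_equal(merge_syngraphs(list(x, y)),
                                 merge_syngraphs(list(y, x))))
      expect_true(syngraph_equal(
        merge_syngraphs(list(merge_syngraphs(list(x, y)), z)),
        merge_syngraphs(list(x, merge_syngraphs(list(y, z))))
      ))
      m <- merge_syngraphs(list(x, y))
      if (length(m$nodes) > length(x$nodes)) {
        expect_true(is_subset(x, m))
      }
    }
  })
})

test_that("is_subset means proper containment of nodes and relations", {
  full <- generate_route(route_spec(3, branch_points = list(c(3, 2)),
                                    seed = 5))$route
  # drop the branch: keep only main-chain equations (those whose product
  # feeds the next step or is the target)
  eqs <- Filter(synkit:::is_chemical_equation, full$nodes)
  # truncate by removing one starting-material-side equation (a leaf of
  # the monopartite-reactions projection): that intermediate is sourced
  # rather than synthesized
  mpr <- convert_data_model(full, "monopartite_reactions")
  leaf_ce <- roots_and_leaves(mpr)$leaves[1]
  kept <- eqs[setdiff(names(eqs), leaf_ce)]
  truncated <- syngraph_from_equations(kept)
  expect_true(is_subset(truncated, full))
  expect_false(is_subset(full, truncated))
  expect_false(is_subset(full, full))

  disjoint <- generate_route(route_spec(2, seed = 77))$route
  expect_false(is_subset(disjoint, full))
})

test_that("routes validate as single-root acyclic covers", {
  g <- mk_bip("NC>>NCO", "NCO>>NCOC")
  expect_s3_class(as_synroute(g), "synroute")
  two_targets <- merge_syngraphs(list(
    mk_bip("NC>>NCO"), mk_bip("NOC>>NOCC")
  ))
  expect_error(as_synroute(two_targets), class = "synkit_not_a_route")
  cyc <- mk_bip("NC>>NO", "NO>>NC")
  expect_error(as_synroute(cyc), class = "synkit_cyclic_input")
})
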