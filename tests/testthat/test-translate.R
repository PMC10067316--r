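casp_tree <- function(target, reactions) {
  # reactions: list of list(smiles = <optional>, precursors = chr vector)
  list(
    type = "mol", smiles = target,
    children = lapply(reactions, function(r) {
      c(
        if (!is.null(r$smiles)) list(type = "reaction", smiles = r$smiles)
        else list(type = "reaction",
                  smiles = paste0(paste(r$precursors, collapse = "."),
                                  ">>", target)),
        list(children = lapply(r$precursors, function(p) {
          list(type = "mol", smiles = p, children = list())
        }))
      )
    })
  )
}

test_that("CASP tree reading maps mol/reaction nodes onto the bipartite model", {
  tree <- casp_tree("NCCO", list(list(precursors = c("NC", "NCO"))))
  g <- read_casp_tree(tree, source_label = "toolA")
  kinds <- vapply(g$nodes, function(n) n$kind, "")
  expect_identical(sum(kinds == "molecule"), 3L)
  expect_identical(sum(kinds == "chemical_equation"), 1L)
  expect_identical(sum(synkit:::out_degrees(g)), 3L)
  expect_identical(g$source_label, "toolA")
  expect_length(roots_and_leaves(g)$roots, 1L)
})

test_that("uid-equal precursors shared by two branches collapse to one node", {
  tree <- list(
    type = "mol", smiles = "NCONOC", children = list(list(
      type = "reaction", smiles = "NCO.NOC>>NCONOC",
      children = list(
        list(type = "mol", smiles = "NCO", children = list(list(
          type = "reaction", smiles = "NC>>NCO",
          children = list(list(type = "mol", smiles = "NC",
                               children = list()))
        ))),
        list(type = "mol", smiles = "NOC", children = list(list(
          type = "reaction", smiles = "NC>>NOC",
          children = list(list(type = "mol", smiles = "NC",
                               children = list()))
        )))
      )
    ))
  )
  g <- read_casp_tree(tree)
  uid_nc <- canonicalize_molecule("NC")$uid
  # one shared starting material feeding two reactions
  expect_identical(sum(names(g$nodes) == uid_nc), 1L)
  expect_length(g$children[[uid_nc]], 2L)
})

test_that("dialect violations are rejected", {
  expect_error(
    read_casp_tree(list(type = "reaction", smiles = "NC>>NCO",
                        children = list())),
    class = "synkit_dialect"
  )
  expect_error(
    read_casp_tree(list(type = "mol", smiles = "NCO", children = list(
      list(type = "mol", smiles = "NC", children = list())
    ))),
    class = "synkit_dialect"
  )
})

test_that("node/edge JSON round trip is the identity for all three data models", {
  rt <- generate_route(route_spec(3, branch_points = list(c(2, 1)),
                                  seed = 9))$route
  for (model in c("bipartite", "monopartite_reactions",
                  "monopartite_molecules")) {
    g <- convert_data_model(rt, model)
    doc <- write_node_edge_json(g)
    back <- read_node_edge_json(doc)
    expect_identical(back$data_model, model)
    expect_true(syngraph_equal(g, back))
  }
})

test_that("node order in the file does not matter; dangling edges do", {
  g <- generate_route(route_spec(2, seed = 4))$route
  doc <- jsonlite::fromJSON(write_node_edge_json(g)$payload,
                            simplifyVector = FALSE)
  doc$nodes <- rev(doc$nodes)
  expect_true(syngraph_equal(g, read_node_edge_json(doc)))

  doc$edges[[1]]$target <- "nonexistent-uid"
  expect_error(read_node_edge_json(doc), class = "synkit_dangling_edge")
})

test_that("DOT export is deterministic and kind-aware", {
  g <- syngraph_from_equations(list(
    build_chemical_equation("NC.NO>>NCNO")
  ))
  dot <- write_dot(g)$payload
  expect_identical(length(grep("shape=", strsplit(dot, "\n")[[1]])), 4L)
  expect_identical(length(grep("->", strsplit(dot, "\n")[[1]])), 3L)
  expect_identical(write_dot(g)$payload, dot)

  mpr <- convert_data_model(
    generate_route(route_spec(3, seed = 2))$route, "monopartite_reactions"
  )
  lines <- strsplit(write_dot(mpr)$payload, "\n")[[1]]
  expect_false(any(grepl("shape=ellipse", lines)))
  expect_identical(sum(grepl("shape=box", lines)), 3L)
})

test_that("translate pipelines always pass through SynGraph and the registry is extensible", {
  rt <- generate_route(route_spec(2, seed = 6))$route
  doc <- translate("syngraph", rt, "node_edge_json", "bipartite")
  expect_s3_class(doc, "route_document")
  back <- translate("node_edge_json", doc$payload, "syngraph", "bipartite")
  expect_true(syngraph_equal(rt, back))

  dot <- translate("node_edge_json", doc$payload, "dot_text",
                   "monopartite_reactions")
  expect_identical(dot$format_name, "dot_text")

  expect_error(translate("foo", doc$payload, "dot_text", "bipartite"),
               class = "synkit_unknown_format")
  expect_error(translate("syngraph", rt, "foo", "bipartite"),
               class = "synkit_unknown_format")
  # a reader-less format cannot start a pipeline
  expect_error(translate("dot_text", dot$payload, "syngraph", "bipartite"),
               class = "synkit_unknown_format")

  # registering one writer connects it to every readable format
  register_route_format("edge_count_txt", write = function(g) {
    synkit:::new_route_document("edge_count_txt",
                                as.character(sum(synkit:::out_degrees(g))))
  })
  withr::defer(rm("edge_count_txt", envir = synkit:::.format_registry))
  readable <- list_route_formats()
  expect_true("edge_count_txt" %in% readable$format)
  out <- translate("node_edge_json", doc$payload, "edge_count_txt",
                   "bipartite")
  expect_identical(out$payload, as.character(sum(synkit:::out_degrees(rt))))
})
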