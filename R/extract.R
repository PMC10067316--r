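#' Enumerate the distinct synthetic routes in a route catalog
#'
#' A SynTree — the merge of several routes sharing one target — can hold
#' molecules producible by more than one reaction (convergence points). A
#' route commits to exactly one producing reaction at every such point and
#' then takes the necessary-and-sufficient closure down to the starting
#' materials. This function enumerates all such selections, so on a tree
#' whose convergence points offer \eqn{k_1, k_2, \ldots} alternatives it
#' returns \eqn{\prod k_i} pairwise distinct routes.
#'
#' @param tree A `syngraph` in bipartite (or monopartite_reactions, which
#'   is converted) form with a single target molecule.
#' @return List of `synroute` objects (bipartite).
#' @export
#' @examples
#' tr <- generate_tree(c(2, 2), seed = 1)
#' length(extract_routes(tr$tree))
extract_routes <- function(tree) {
  stopifnot(is_syngraph(tree))
  if (tree$data_model == "monopartite_molecules") {
    stop_synkit("lossy_conversion",
                "route extraction needs explicit chemical equations")
  }
  if (tree$data_model == "monopartite_reactions") {
    tree <- convert_data_model(tree, "bipartite")
  }
  if (!is_acyclic(tree)) {
    stop_synkit("cyclic_input", "route extraction requires an acyclic graph")
  }
  rl <- roots_and_leaves(tree)
  if (length(rl$roots) != 1L) {
    stop_synkit("ambiguous_target",
                "route extraction needs a single target molecule; found ",
                length(rl$roots), " roots")
  }
  pm <- parents_map(tree)
  memo <- new.env(parent = emptyenv())

  # all reaction-uid sets that can deliver this molecule
  routes_for_mol <- function(mol_uid) {
    if (!is.null(memo[[mol_uid]])) return(memo[[mol_uid]])
    producers <- Filter(function(u) {
      node_kind(tree$nodes[[u]]) == "chemical_equation"
    }, pm[[mol_uid]])
    res <- if (!length(producers)) {
      list(character(0))
    } else {
      out <- list()
      for (r in producers) {
        reactant_sets <- lapply(pm[[r]], routes_for_mol)
        combos <- Reduce(function(acc, alts) {
          unlist(lapply(acc, function(a) {
            lapply(alts, function(b) union(a, b))
          }), recursive = FALSE)
        }, reactant_sets, list(character(0)))
        out <- c(out, lapply(combos, function(s) union(s, r)))
      }
      out
    }
    memo[[mol_uid]] <- res
    res
  }

  ce_sets <- routes_for_mol(rl$roots)
  keys <- vapply(ce_sets, function(s) paste(sort(s), collapse = "|"), "")
  ce_sets <- ce_sets[!duplicated(keys)]
  lapply(ce_sets, function(s) {
    as_synroute(syngraph_from_equations(tree$nodes[s],
                                        source_label = tree$source_label))
  })
}
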