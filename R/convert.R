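#' Convert a SynGraph between graph data models
#'
#' Conversion between data models is orthogonal to translation between
#' file formats: any format pipeline passes through SynGraph, and SynGraph
#' alone changes the model. Rules:
#'
#' * bipartite -> monopartite_reactions: equation nodes only; edge
#'   R1 -> R2 when some product of R1 is a reactant of R2.
#' * bipartite -> monopartite_molecules: molecule nodes only; edge
#'   M1 -> M2 when some equation consumes M1 and produces M2.
#' * monopartite_reactions -> bipartite: molecule nodes are rebuilt from
#'   the equations' role maps, so a bipartite -> monopartite_reactions ->
#'   bipartite round trip preserves the reactant/product structure.
#' * monopartite_molecules -> anything else is refused: the equations are
#'   only implicit in that model, so the conversion would have to invent
#'   chemistry.
#'
#' @param g A `syngraph`.
#' @param target Target data model name.
#' @return A `syngraph` in the target model (`g` itself if already there).
#' @export
#' @examples
#' ce1 <- build_chemical_equation("CCO.CC(=O)O>>CC(=O)OCC")
#' ce2 <- build_chemical_equation("CC(=O)OCC.NCC>>CC(=O)NCC.CCO")
#' g <- syngraph_from_equations(list(ce1, ce2))
#' convert_data_model(g, "monopartite_reactions")
convert_data_model <- function(g, target) {
  stopifnot(is_syngraph(g))
  target <- check_data_model(target)
  if (g$data_model == target) return(g)
  if (g$data_model == "monopartite_molecules") {
    stop_synkit("lossy_conversion",
                "monopartite_molecules carries no chemical equations; ",
                "conversion to ", target, " is refused")
  }
  was_route <- inherits(g, "synroute")
  bip <- if (g$data_model == "bipartite") g else bipartite_from_mpr(g)
  out <- switch(target,
    bipartite = bip,
    monopartite_reactions = mpr_from_bipartite(bip),
    monopartite_molecules = mpm_from_bipartite(bip)
  )
  out$source_label <- g$source_label
  if (was_route && target != "monopartite_molecules") {
    out <- as_synroute(out)
  }
  out
}

graph_equations <- function(g) {
  Filter(is_chemical_equation, g$nodes)
}

mpr_from_bipartite <- function(g) {
  ces <- graph_equations(g)
  from <- character(0)
  to <- character(0)
  for (a in ces) {
    for (b in ces) {
      if (a$uid != b$uid &&
          length(intersect(a$role_map$product, b$role_map$reactant))) {
        from <- c(from, a$uid)
        to <- c(to, b$uid)
      }
    }
  }
  new_syngraph(ces, data.frame(from = from, to = to),
               data_model = "monopartite_reactions",
               source_label = g$source_label)
}

mpm_from_bipartite <- function(g) {
  ces <- graph_equations(g)
  mols <- list()
  from <- character(0)
  to <- character(0)
  for (ce in ces) {
    for (u in c(ce$role_map$reactant, ce$role_map$product)) {
      mols[[u]] <- ce$molecules[[u]]
    }
    for (r in ce$role_map$reactant) {
      for (p in ce$role_map$product) {
        from <- c(from, r)
        to <- c(to, p)
      }
    }
  }
  new_syngraph(mols, data.frame(from = from, to = to),
               data_model = "monopartite_molecules",
               source_label = g$source_label)
}

bipartite_from_mpr <- function(g) {
  out <- syngraph_from_equations(graph_equations(g),
                                 source_label = g$source_label)
  out
}
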