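#' The SynGraph data model
#'
#' A SynGraph is the central graph object: an adjacency mapping in which
#' every key is a node (a molecule or a chemical equation, both value
#' objects identified by structure-derived uids) and its value is the
#' unordered, duplicate-free collection of child nodes. Edges run in the
#' synthetic direction, parent (precursor side) to child (target side), and
#' stay implicit in the mapping. Every node appears as a key, possibly with
#' no children, so roots (out-degree 0) and leaves (in-degree 0) are always
#' well defined.
#'
#' Three data models are supported:
#' * `"bipartite"`: molecule and chemical-equation nodes, edges map role
#'   relationships (reactant molecule -> equation -> product molecule);
#'   reagents are attributes of the equation, not graph nodes.
#' * `"monopartite_reactions"`: chemical-equation nodes only; an edge
#'   means a product of one equation is a reactant of the next.
#' * `"monopartite_molecules"`: molecule nodes only; an edge means some
#'   equation consumes the parent and produces the child (the equations
#'   themselves are implicit, making this model lossy).
#'
#' @param nodes uid-keyed list of node objects.
#' @param edges Two-column data frame or matrix of uids (`from`, `to`),
#'   or NULL for an edgeless graph.
#' @param data_model One of the three model names above.
#' @param source_label Free-text provenance tag.
#' @return A `syngraph` object.
#' @export
#' @examples
#' ce <- build_chemical_equation("CCO.CC(=O)O>>CC(=O)OCC")
#' g <- syngraph_from_equations(list(ce))
#' roots_and_leaves(g)
new_syngraph <- function(nodes, edges = NULL, data_model = "bipartite",
                         source_label = "") {
  data_model <- check_data_model(data_model)
  if (is.null(names(nodes)) && length(nodes)) {
    names(nodes) <- vapply(nodes, function(n) n$uid, "")
  }
  uids <- names(nodes) %||% character(0)
  if (anyDuplicated(uids)) nodes <- nodes[!duplicated(uids)]
  uids <- names(nodes) %||% character(0)
  children <- stats::setNames(
    replicate(length(uids), character(0), simplify = FALSE), uids
  )
  if (!is.null(edges) && NROW(edges) > 0) {
    from <- as.character(edges[[1]])
    to <- as.character(edges[[2]])
    bad <- !(from %in% uids) | !(to %in% uids)
    if (any(bad)) {
      stop_synkit("dangling_edge", "edge references unknown uid(s): ",
                  paste(unique(c(from[bad], to[bad])), collapse = ", "))
    }
    if (any(from == to)) {
      stop_synkit("invalid_graph", "self-loops are not allowed")
    }
    for (i in seq_along(from)) {
      children[[from[i]]] <- c(children[[from[i]]], to[i])
    }
    children <- lapply(children, function(ch) sort(unique(ch)))
  }
  g <- structure(
    list(
      nodes = nodes[order(uids)],
      children = children[order(uids)],
      data_model = data_model,
      source_label = source_label
    ),
    class = "syngraph"
  )
  check_partiteness(g)
  g
}

check_data_model <- function(data_model) {
  models <- c("bipartite", "monopartite_molecules", "monopartite_reactions")
  if (!is.character(data_model) || length(data_model) != 1L ||
      !data_model %in% models) {
    stop_synkit("model_mismatch", "unknown data model '", data_model,
                "'; available: ", paste(models, collapse = ", "))
  }
  data_model
}

check_partiteness <- function(g) {
  kinds <- vapply(g$nodes, node_kind, "")
  if (g$data_model == "monopartite_molecules" && any(kinds != "molecule")) {
    stop_synkit("invalid_graph",
                "monopartite_molecules graph contains non-molecule nodes")
  }
  if (g$data_model == "monopartite_reactions" &&
      any(kinds != "chemical_equation")) {
    stop_synkit("invalid_graph",
                "monopartite_reactions graph contains non-reaction nodes")
  }
  if (g$data_model == "bipartite") {
    for (u in names(g$children)) {
      for (v in g$children[[u]]) {
        if (node_kind(g$nodes[[u]]) == node_kind(g$nodes[[v]])) {
          stop_synkit("invalid_graph",
                      "bipartite edges must connect molecule and ",
                      "chemical_equation nodes (", u, " -> ", v, ")")
        }
      }
    }
  }
  invisible(g)
}

#' Build a bipartite SynGraph from chemical equations
#'
#' Molecule nodes are taken from each equation's reactant and product roles
#' (reagents stay inside the equation), with edges reactant -> equation and
#' equation -> product. uid-equal molecules shared across equations
#' collapse onto a single node, which is how separate steps link into a
#' route.
#'
#' @param equations List of [chemical_equation][build_chemical_equation()] objects.
#' @param source_label Provenance tag.
#' @return A bipartite `syngraph`.
#' @export
syngraph_from_equations <- function(equations, source_label = "") {
  nodes <- list()
  from <- character(0)
  to <- character(0)
  for (ce in equations) {
    nodes[[ce$uid]] <- ce
    for (u in ce$role_map$reactant) {
      nodes[[u]] <- ce$molecules[[u]]
      from <- c(from, u)
      to <- c(to, ce$uid)
    }
    for (u in ce$role_map$product) {
      nodes[[u]] <- ce$molecules[[u]]
      from <- c(from, ce$uid)
      to <- c(to, u)
    }
  }
  new_syngraph(nodes, data.frame(from = from, to = to),
               data_model = "bipartite", source_label = source_label)
}

is_syngraph <- function(x) inherits(x, "syngraph")

syngraph_uids <- function(g) names(g$nodes)

in_degrees <- function(g) {
  ins <- stats::setNames(integer(length(g$nodes)), names(g$nodes))
  for (ch in g$children) for (v in ch) ins[[v]] <- ins[[v]] + 1L
  ins
}

out_degrees <- function(g) {
  vapply(g$children, length, 0L)
}

parents_map <- function(g) {
  pm <- stats::setNames(
    replicate(length(g$nodes), character(0), simplify = FALSE),
    names(g$nodes)
  )
  for (u in names(g$children)) {
    for (v in g$children[[u]]) pm[[v]] <- c(pm[[v]], u)
  }
  pm
}

#' Roots and leaves of a SynGraph
#'
#' Roots are nodes with no outgoing edge (the target side in the synthetic
#' direction); leaves have no incoming edge (starting materials).
#'
#' @param g A `syngraph`.
#' @return List with character vectors `roots` and `leaves` (uids).
#' @export
roots_and_leaves <- function(g) {
  stopifnot(is_syngraph(g))
  if (length(g$nodes) == 0L) {
    stop_synkit("empty_graph", "graph has no nodes")
  }
  list(
    roots = names(g$children)[out_degrees(g) == 0L],
    leaves = names(g$children)[in_degrees(g) == 0L]
  )
}

#' Structural equality of two SynGraphs
#'
#' Two graphs are equal when they hold the same key-value pairs: the same
#' node uids and, per node, the same child collections. Because uids derive
#' from reactants and products only, two routes that differ merely in
#' reagents (or in input ordering) compare equal.
#'
#' @param a,b `syngraph` objects sharing a data model.
#' @return `TRUE` or `FALSE`.
#' @export
syngraph_equal <- function(a, b) {
  stopifnot(is_syngraph(a), is_syngraph(b))
  if (a$data_model != b$data_model) {
    stop_synkit("model_mismatch", "cannot compare a ", a$data_model,
                " graph with a ", b$data_model, " graph")
  }
  if (!identical(sort(names(a$nodes)), sort(names(b$nodes)))) return(FALSE)
  for (u in names(a$children)) {
    if (!identical(a$children[[u]], b$children[[u]])) return(FALSE)
  }
  TRUE
}

#' Merge SynGraphs by graph union
#'
#' Key-wise union of the adjacency mappings; uid-equal nodes collapse onto
#' one node. Merging routes that share a target yields the route catalog
#' (SynTree) from which distinct routes can be re-extracted.
#'
#' @param graphs List of `syngraph` objects sharing a data model.
#' @return The union `syngraph`.
#' @export
merge_syngraphs <- function(graphs) {
  if (is_syngraph(graphs)) graphs <- list(graphs)
  if (!length(graphs)) {
    stop_synkit("empty_graph", "no graphs to merge")
  }
  models <- unique(vapply(graphs, function(g) g$data_model, ""))
  if (length(models) != 1L) {
    stop_synkit("model_mismatch", "cannot merge graphs with mixed data ",
                "models: ", paste(models, collapse = ", "))
  }
  nodes <- list()
  children <- list()
  for (g in graphs) {
    for (u in names(g$nodes)) {
      nodes[[u]] <- g$nodes[[u]]
      children[[u]] <- sort(unique(c(children[[u]], g$children[[u]])))
    }
  }
  ord <- order(names(nodes))
  structure(
    list(
      nodes = nodes[ord],
      children = children[ord],
      data_model = models,
      source_label = paste(
        unique(vapply(graphs, function(g) g$source_label, "")),
        collapse = "+"
      )
    ),
    class = "syngraph"
  )
}

#' Is one SynGraph a proper subset of another?
#'
#' `TRUE` when every node and every parent-child relation of `candidate`
#' exists in `reference` and the two graphs are not equal — the case where
#' a route shares only part of another's synthetic steps (for example a
#' branch truncated because an intermediate is sourced instead of made).
#' The test works directly on the adjacency mapping; no isomorphism search
#' is involved.
#'
#' @param candidate,reference `syngraph` objects sharing a data model.
#' @return `TRUE` or `FALSE`.
#' @export
is_subset <- function(candidate, reference) {
  stopifnot(is_syngraph(candidate), is_syngraph(reference))
  if (candidate$data_model != reference$data_model) {
    stop_synkit("model_mismatch", "cannot compare a ", candidate$data_model,
                " graph with a ", reference$data_model, " graph")
  }
  if (!all(names(candidate$nodes) %in% names(reference$nodes))) return(FALSE)
  for (u in names(candidate$children)) {
    if (!all(candidate$children[[u]] %in% reference$children[[u]])) {
      return(FALSE)
    }
  }
  !syngraph_equal(candidate, reference)
}

# DFS cycle check; returns TRUE when the graph is acyclic
is_acyclic <- function(g) {
  color <- stats::setNames(integer(length(g$nodes)), names(g$nodes))
  visit <- function(u) {
    color[[u]] <<- 1L
    for (v in g$children[[u]]) {
      if (color[[v]] == 1L) return(FALSE)
      if (color[[v]] == 0L && !visit(v)) return(FALSE)
    }
    color[[u]] <<- 2L
    TRUE
  }
  for (u in names(g$nodes)) {
    if (color[[u]] == 0L && !visit(u)) return(FALSE)
  }
  TRUE
}

#' Validate a SynGraph as a single-root synthetic route
#'
#' A SynRoute is a SynGraph with exactly one root (the target), no cycles,
#' and every node on some leaf-to-root path — the necessary-and-sufficient
#' set of steps assembling one target compound.
#'
#' @param g A `syngraph`.
#' @return `g` with class `synroute` prepended.
#' @export
as_synroute <- function(g) {
  stopifnot(is_syngraph(g))
  if (!is_acyclic(g)) {
    stop_synkit("cyclic_input", "route graphs must be acyclic")
  }
  rl <- roots_and_leaves(g)
  if (length(rl$roots) != 1L) {
    stop_synkit("not_a_route", "a route needs exactly one root; found ",
                length(rl$roots))
  }
  # every node must reach the root
  pm <- parents_map(g)
  reach <- character(0)
  frontier <- rl$roots
  while (length(frontier)) {
    reach <- c(reach, frontier)
    frontier <- setdiff(unique(unlist(pm[frontier])), reach)
  }
  if (!setequal(reach, names(g$nodes))) {
    stop_synkit("not_a_route",
                "disconnected nodes cannot belong to a single route")
  }
  if (!inherits(g, "synroute")) class(g) <- c("synroute", class(g))
  g
}

is_synroute <- function(x) {
  inherits(x, "synroute") ||
    (is_syngraph(x) && !inherits(try(as_synroute(x), silent = TRUE),
                                 "try-error"))
}

#' @export
print.syngraph <- function(x, ...) {
  kinds <- vapply(x$nodes, node_kind, "")
  n_edges <- sum(out_degrees(x))
  cat("<", if (inherits(x, "synroute")) "synroute" else "syngraph", "> ",
      x$data_model, ": ", sum(kinds == "molecule"), " molecules, ",
      sum(kinds == "chemical_equation"), " chemical equations, ",
      n_edges, " edges", sep = "")
  if (nzchar(x$source_label)) cat("  [", x$source_label, "]", sep = "")
  cat("\n")
  invisible(x)
}
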