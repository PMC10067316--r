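# Translation between route data formats. SynGraph is the mandatory hub:
# every pipeline is read(format) -> SynGraph -> convert(model) -> write(format),
# so adding one reader/writer pair connects a new format to all others.

.format_registry <- new.env(parent = emptyenv())

#' Register a route file format
#'
#' Extends the translation registry with a reader and/or writer without
#' touching existing formats. Readers take `(payload, policy, source_label)`
#' and return a `syngraph`; writers take a `syngraph` and return document
#' text.
#'
#' @param name Format name.
#' @param read,write Functions as described, or NULL when the direction is
#'   unsupported.
#' @export
register_route_format <- function(name, read = NULL, write = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  .format_registry[[name]] <- list(read = read, write = write)
  invisible(name)
}

#' List registered route formats
#' @return Tibble with `format`, `readable`, `writable`.
#' @export
list_route_formats <- function() {
  nms <- sort(ls(.format_registry))
  tibble::tibble(
    format = nms,
    readable = vapply(nms, function(n) !is.null(.format_registry[[n]]$read),
                      TRUE),
    writable = vapply(nms, function(n) !is.null(.format_registry[[n]]$write),
                      TRUE)
  )
}

get_format <- function(name) {
  if (is.null(.format_registry[[name]])) {
    stop_synkit("unknown_format", "unknown format '", name,
                "'; registered: ",
                paste(sort(ls(.format_registry)), collapse = ", "))
  }
  .format_registry[[name]]
}

new_route_document <- function(format_name, payload) {
  structure(list(format_name = format_name, payload = payload),
            class = "route_document")
}

#' @export
print.route_document <- function(x, ...) {
  cat("<route_document> format:", x$format_name, "\n")
  cat(substr(x$payload, 1, 400))
  if (nchar(x$payload) > 400) cat("\n...")
  cat("\n")
  invisible(x)
}

# Accept a file path, raw document text, or an already-parsed list.
payload_to_json <- function(payload) {
  if (is.list(payload)) return(payload)
  stopifnot(is.character(payload), length(payload) == 1L)
  txt <- if (file.exists(payload)) {
    paste(readLines(payload, warn = FALSE), collapse = "\n")
  } else {
    payload
  }
  jsonlite::fromJSON(txt, simplifyVector = FALSE)
}

#' Read a CASP-style nested route tree
#'
#' The nested-tree dialect most CASP tools emit: a JSON tree of alternating
#' `mol` and `reaction` nodes, each bearing a `smiles` string and a
#' `children` list, rooted at the target molecule. Every `mol` node becomes
#' a Molecule; every `reaction` node becomes a ChemicalEquation whose
#' reactants are its child molecules and whose product is its parent
#' molecule — unless the node carries its own reaction SMILES, which is
#' preferred because it can retain reagent information. Extra keys are
#' ignored. Edges run child to parent (the synthetic direction);
#' uid-equal nodes are deduplicated.
#'
#' @param payload File path, JSON text, or parsed list. A top-level JSON
#'   array is treated as the first route (use [process_routes()] for
#'   batches).
#' @param policy Identity policy for all molecules.
#' @param source_label Provenance tag.
#' @return A bipartite `syngraph`.
#' @export
read_casp_tree <- function(payload, policy = "canonical-isomeric-smiles",
                           source_label = "") {
  doc <- payload_to_json(payload)
  if (!is.null(doc$type) || !is.null(doc$smiles)) {
    tree <- doc
  } else if (length(doc) >= 1L && is.list(doc[[1]])) {
    tree <- doc[[1]]
  } else {
    stop_synkit("dialect", "document is not a CASP tree")
  }
  equations <- list()
  walk <- function(node, parent_kind, parent_smiles) {
    kind <- node$type %||% if (!is.null(node$smiles) &&
                               grepl(">", node$smiles)) "reaction" else "mol"
    if (identical(parent_kind, kind)) {
      stop_synkit("dialect", "a '", kind, "' node cannot be the child of a '",
                  parent_kind, "' node")
    }
    if (is.null(node$smiles)) {
      stop_synkit("dialect", "every tree node needs a 'smiles' string")
    }
    kids <- node$children %||% list()
    if (kind == "reaction") {
      kid_smiles <- vapply(kids, function(k) k$smiles %||% "", "")
      if (grepl(">", node$smiles)) {
        ce <- build_chemical_equation(node$smiles, policy = policy)
      } else if (length(kids)) {
        ce <- equation_from_sides(kid_smiles, parent_smiles, policy = policy)
      } else {
        stop_synkit("dialect", "reaction node without precursors or ",
                    "reaction SMILES")
      }
      equations[[length(equations) + 1L]] <<- ce
    }
    for (k in kids) walk(k, kind, node$smiles)
  }
  root_kind <- tree$type %||% "mol"
  if (!identical(root_kind, "mol")) {
    stop_synkit("dialect", "the tree root must be the target molecule, ",
                "not a '", root_kind, "' node")
  }
  walk(tree, NULL, NULL)
  if (!length(equations)) {
    # bare target with no steps: a graph of one molecule
    m <- canonicalize_molecule(tree$smiles, policy = policy)
    return(new_syngraph(list(m), NULL, "bipartite", source_label))
  }
  syngraph_from_equations(equations, source_label = source_label)
}

#' Write / read the flat node-and-edge JSON dialect
#'
#' The document holds the graph as two lists of dictionaries: `nodes`
#' (uid, kind, structure string) and `edges` (source uid, target uid),
#' plus the data model and source label. Reading rebuilds every node from
#' its structure string, so `read_node_edge_json(write_node_edge_json(g))`
#' equals `g` under [syngraph_equal()] for all three data models.
#'
#' @param g A `syngraph`.
#' @return `write_node_edge_json`: a `route_document`;
#'   `read_node_edge_json`: a `syngraph`.
#' @export
write_node_edge_json <- function(g) {
  stopifnot(is_syngraph(g))
  uids <- sort(names(g$nodes))
  nodes <- lapply(uids, function(u) {
    n <- g$nodes[[u]]
    list(
      uid = u,
      kind = if (n$kind == "molecule") "mol" else "reaction",
      structure = if (n$kind == "molecule") n$canonical_form
                  else n$reaction_string
    )
  })
  edges <- list()
  for (u in uids) {
    for (v in g$children[[u]]) {
      edges[[length(edges) + 1L]] <- list(source = u, target = v)
    }
  }
  doc <- list(
    data_model = g$data_model,
    source = g$source_label,
    nodes = nodes,
    edges = edges
  )
  new_route_document(
    "node_edge_json",
    as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE))
  )
}

#' @rdname write_node_edge_json
#' @param payload File path, JSON text, parsed list, or `route_document`.
#' @param policy Identity policy for rebuilding the nodes.
#' @param source_label Provenance tag; defaults to the document's own.
#' @export
read_node_edge_json <- function(payload,
                                policy = "canonical-isomeric-smiles",
                                source_label = NULL) {
  if (inherits(payload, "route_document")) payload <- payload$payload
  doc <- payload_to_json(payload)
  if (is.null(doc$nodes)) {
    stop_synkit("dialect", "document has no 'nodes' list")
  }
  data_model <- doc$data_model %||% "bipartite"
  nodes <- list()
  uid_map <- character(0)   # file uid -> recomputed uid
  for (n in doc$nodes) {
    obj <- if (identical(n$kind, "reaction")) {
      build_chemical_equation(n$structure, policy = policy)
    } else {
      canonicalize_molecule(n$structure, policy = policy)
    }
    uid_map[[n$uid]] <- obj$uid
    nodes[[obj$uid]] <- obj
  }
  from <- character(0)
  to <- character(0)
  for (e in doc$edges %||% list()) {
    if (!e$source %in% names(uid_map) || !e$target %in% names(uid_map)) {
      stop_synkit("dangling_edge", "edge references unknown uid: ",
                  e$source, " -> ", e$target)
    }
    from <- c(from, uid_map[[e$source]])
    to <- c(to, uid_map[[e$target]])
  }
  new_syngraph(nodes, data.frame(from = from, to = to),
               data_model = data_model,
               source_label = source_label %||% (doc$source %||% ""))
}

#' Export a SynGraph as Graphviz DOT text
#'
#' Presentation-only export (no reader): molecule nodes are drawn as
#' ellipses, chemical-equation nodes as boxes, labelled with their
#' canonical structure strings. Nodes and edges are emitted in sorted uid
#' order, so equal graphs produce byte-identical documents.
#'
#' @param g A `syngraph`.
#' @return A `route_document` holding DOT text.
#' @export
write_dot <- function(g) {
  stopifnot(is_syngraph(g))
  uids <- sort(names(g$nodes))
  esc <- function(x) gsub("\"", "\\\"", x, fixed = TRUE)
  lines <- c("digraph syngraph {", "  rankdir=LR;")
  for (u in uids) {
    n <- g$nodes[[u]]
    shape <- if (n$kind == "molecule") "ellipse" else "box"
    lines <- c(lines, sprintf("  \"%s\" [shape=%s, label=\"%s\"];",
                              u, shape, esc(node_label(n))))
  }
  for (u in uids) {
    for (v in g$children[[u]]) {
      lines <- c(lines, sprintf("  \"%s\" -> \"%s\";", u, v))
    }
  }
  lines <- c(lines, "}")
  new_route_document("dot_text", paste(lines, collapse = "\n"))
}

#' Translate a route document between formats (through SynGraph)
#'
#' Runs the full pipeline read -> SynGraph -> [convert_data_model()] ->
#' write. `input_format = "syngraph"` accepts a `syngraph` object directly
#' and `output_format = "syngraph"` returns one, which is how in-memory
#' consumers plug into the same registry.
#'
#' @param input_format,output_format Registered format names or
#'   `"syngraph"`.
#' @param payload Document (path, text, parsed list) or `syngraph`.
#' @param out_data_model Data model of the output.
#' @param policy Identity policy used when reading.
#' @param source_label Provenance tag for the routes read.
#' @return A `route_document`, or a `syngraph` when
#'   `output_format = "syngraph"`.
#' @export
#' @examples
#' rt <- generate_route(route_spec(depth = 2, seed = 1))
#' doc <- translate("syngraph", rt$route, "dot_text", "monopartite_reactions")
translate <- function(input_format, payload, output_format,
                      out_data_model = "bipartite",
                      policy = "canonical-isomeric-smiles",
                      source_label = "") {
  g <- if (identical(input_format, "syngraph")) {
    stopifnot(is_syngraph(payload))
    payload
  } else {
    fmt <- get_format(input_format)
    if (is.null(fmt$read)) {
      stop_synkit("unknown_format", "format '", input_format,
                  "' has no reader")
    }
    fmt$read(payload, policy, source_label)
  }
  g <- convert_data_model(g, out_data_model)
  if (identical(output_format, "syngraph")) return(g)
  fmt <- get_format(output_format)
  if (is.null(fmt$write)) {
    stop_synkit("unknown_format", "format '", output_format,
                "' has no writer")
  }
  fmt$write(g)
}

# built-in formats
register_builtin_formats <- function() {
  register_route_format(
    "casp_tree_json",
    read = function(payload, policy, source_label) {
      read_casp_tree(payload, policy, source_label)
    }
  )
  register_route_format(
    "node_edge_json",
    read = function(payload, policy, source_label) {
      read_node_edge_json(payload, policy, source_label)
    },
    write = write_node_edge_json
  )
  register_route_format("dot_text", write = write_dot)
}
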