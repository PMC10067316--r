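#' Process a batch of CASP route files end to end
#'
#' The high-level facade: reads every input file (each tagged with the
#' name of the CASP source that produced it), translates the routes into
#' SynGraphs, converts them to the requested data model, writes them in
#' the requested format, and runs the requested functionalities -
#' descriptor calculation and/or GED-based clustering. A file that fails
#' to read is recorded as a per-file failure and the batch continues; the
#' batch aborts only when every file fails.
#'
#' @param input Named character vector or list mapping file path to source
#'   label, e.g. `c("r1.json" = "aizynthfinder")`. A file may hold one
#'   route or a JSON array of routes, in either the CASP nested-tree or
#'   the node/edge dialect (auto-detected).
#' @param output_dir Where output files go (created if needed).
#' @param output_format `"node_edge_json"` (default), `"csv"` (node and
#'   edge tables), or `"dot_text"`.
#' @param out_data_model Data model of the written routes (default
#'   bipartite).
#' @param functionalities Subset of `"compute_descriptors"`,
#'   `"clustering"`; unknown names are rejected before any file I/O.
#' @param descriptors Descriptor names for `compute_descriptors`
#'   (default `"all"`).
#' @param clustering_method Optional override passed to
#'   [cluster_routes()].
#' @param ged_params [ged_params()] for the distance matrix.
#' @param policy Identity policy for all chemistry.
#' @param parallelization,n_cpu Parallel distance-matrix computation.
#' @param write_files Set FALSE to skip writing and only return results.
#' @return A `process_output` object: `routes` (list of syngraphs in the
#'   output model), `descriptors` (tibble or NULL), `clustering`
#'   (`route_cluster_result` or NULL), `distance_matrix`, `files` (paths
#'   written), `failures` (tibble), `log` (character).
#' @export
#' @examples
#' \donttest{
#' rt <- generate_route(route_spec(depth = 2, seed = 1))
#' f <- tempfile(fileext = ".json")
#' writeLines(write_node_edge_json(rt$route)$payload, f)
#' out <- process_routes(stats::setNames("demo", f),
#'                       output_dir = tempdir(),
#'                       functionalities = "compute_descriptors")
#' out$descriptors
#' }
process_routes <- function(input,
                           output_dir = ".",
                           output_format = "node_edge_json",
                           out_data_model = "bipartite",
                           functionalities = NULL,
                           descriptors = "all",
                           clustering_method = NULL,
                           ged_params = synkit::ged_params(),
                           policy = "canonical-isomeric-smiles",
                           parallelization = FALSE,
                           n_cpu = 1L,
                           write_files = TRUE) {
  known_fun <- c("compute_descriptors", "clustering")
  bad <- setdiff(functionalities, known_fun)
  if (length(bad)) {
    stop_synkit("unknown_functionality", "unknown functionality ",
                paste(bad, collapse = ", "), "; available: ",
                paste(known_fun, collapse = ", "))
  }
  out_data_model <- check_data_model(out_data_model)
  if (!output_format %in% c("node_edge_json", "csv", "dot_text")) {
    stop_synkit("unknown_format", "unknown output format '", output_format,
                "'; available: node_edge_json, csv, dot_text")
  }
  paths <- names(input)
  labels <- unname(unlist(input))
  if (is.null(paths) || any(!nzchar(paths))) {
    stop_synkit("spec", "'input' must map file paths to source labels")
  }

  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))

  routes <- list()
  fail_path <- character(0)
  fail_error <- character(0)
  for (i in seq_along(paths)) {
    res <- tryCatch(
      read_routes_file(paths[i], labels[i], policy),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      fail_path <- c(fail_path, paths[i])
      fail_error <- c(fail_error, conditionMessage(res))
      note("read FAILED: ", paths[i], " (", conditionMessage(res), ")")
    } else {
      routes <- c(routes, res)
      note("read: ", paths[i], " [", labels[i], "]: ", length(res),
           " route(s)")
    }
  }
  failures <- tibble::tibble(path = fail_path, error = fail_error)
  if (!length(routes)) {
    stop_synkit("empty_batch", "no input file could be read (",
                nrow(failures), " failure(s))")
  }
  note("total routes: ", length(routes))

  out_routes <- lapply(routes, convert_data_model, target = out_data_model)
  note("converted to ", out_data_model)

  files <- character(0)
  if (write_files) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    files <- write_routes_output(out_routes, output_dir, output_format)
    note("wrote routes (", output_format, "): ",
         paste(basename(files), collapse = ", "))
  }

  desc_tbl <- NULL
  if ("compute_descriptors" %in% functionalities) {
    desc_tbl <- compute_route_descriptors(routes, names = descriptors)
    note("descriptors: ", length(unique(desc_tbl$descriptor)),
         " per route")
    if (write_files) {
      f <- file.path(output_dir, "descriptors.csv")
      utils::write.csv(desc_tbl, f, row.names = FALSE)
      files <- c(files, f)
    }
  }

  clust <- NULL
  dm <- NULL
  if ("clustering" %in% functionalities) {
    dm <- route_distance_matrix(routes, params = ged_params,
                                parallel = parallelization,
                                n_workers = n_cpu)
    clust <- cluster_routes(dm, method = clustering_method, routes = routes)
    note("clustering (", clust$method_used, "): ",
         length(unique(clust$labels[clust$labels != -1L])), " cluster(s)")
    if (write_files) {
      f1 <- file.path(output_dir, "clusters.csv")
      utils::write.csv(tidy(clust), f1, row.names = FALSE)
      f2 <- file.path(output_dir, "cluster_summary.csv")
      utils::write.csv(clust$summary, f2, row.names = FALSE)
      files <- c(files, f1, f2)
    }
  }

  structure(
    list(routes = out_routes, descriptors = desc_tbl, clustering = clust,
         distance_matrix = dm, files = files, failures = failures,
         log = log),
    class = "process_output"
  )
}

# read one file that may hold a single route or an array of routes, in
# either supported JSON dialect
read_routes_file <- function(path, label, policy) {
  doc <- payload_to_json(path)
  as_route_list <- function(d) {
    if (!is.null(d$nodes)) {
      list(read_node_edge_json(d, policy = policy, source_label = label))
    } else if (!is.null(d$smiles) || !is.null(d$type)) {
      list(read_casp_tree(d, policy = policy, source_label = label))
    } else {
      stop_synkit("dialect", "unrecognized route document in ", path)
    }
  }
  if (is.null(names(doc)) && length(doc) && is.list(doc[[1]])) {
    out <- list()
    for (k in seq_along(doc)) {
      rs <- as_route_list(doc[[k]])
      rs[[1]]$source_label <- paste0(label, "_", k)
      out <- c(out, rs)
    }
    out
  } else {
    as_route_list(doc)
  }
}

write_routes_output <- function(routes, output_dir, output_format) {
  if (output_format == "node_edge_json") {
    docs <- lapply(routes, function(g) {
      jsonlite::fromJSON(write_node_edge_json(g)$payload,
                         simplifyVector = FALSE)
    })
    f <- file.path(output_dir, "routes.json")
    writeLines(as.character(jsonlite::toJSON(docs, auto_unbox = TRUE,
                                             pretty = TRUE)), f)
    f
  } else if (output_format == "dot_text") {
    f <- file.path(output_dir, "routes.dot")
    writeLines(paste(vapply(routes, function(g) write_dot(g)$payload, ""),
                     collapse = "\n\n"), f)
    f
  } else {
    node_rows <- list()
    edge_rows <- list()
    for (i in seq_along(routes)) {
      g <- routes[[i]]
      id <- if (nzchar(g$source_label)) g$source_label else paste0("route_", i)
      for (u in sort(names(g$nodes))) {
        n <- g$nodes[[u]]
        node_rows[[length(node_rows) + 1L]] <- data.frame(
          route_id = id, uid = u,
          kind = if (n$kind == "molecule") "mol" else "reaction",
          structure = node_label(n)
        )
        for (v in g$children[[u]]) {
          edge_rows[[length(edge_rows) + 1L]] <- data.frame(
            route_id = id, source = u, target = v
          )
        }
      }
    }
    f1 <- file.path(output_dir, "routes_nodes.csv")
    f2 <- file.path(output_dir, "routes_edges.csv")
    utils::write.csv(do.call(rbind, node_rows), f1, row.names = FALSE)
    utils::write.csv(do.call(rbind, edge_rows), f2, row.names = FALSE)
    c(f1, f2)
  }
}

#' @export
print.process_output <- function(x, ...) {
  cat("<process_output> ", length(x$routes), " route(s)", sep = "")
  if (nrow(x$failures)) cat(", ", nrow(x$failures), " failed file(s)",
                            sep = "")
  cat("\n")
  if (!is.null(x$descriptors)) {
    cat("  descriptors: ", nrow(x$descriptors), " rows\n", sep = "")
  }
  if (!is.null(x$clustering)) print(x$clustering)
  if (length(x$files)) {
    cat("  files:", paste(basename(x$files), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Catalog of available options and defaults
#'
#' Lists the registered route formats, graph data models, descriptors,
#' GED methods and clustering methods together with their defaults — the
#' interactive companion to [process_routes()].
#'
#' @param print Print the catalog (default TRUE).
#' @return (Invisibly) a list of tibbles/vectors behind the printout.
#' @export
#' @examples
#' h <- route_helper(print = FALSE)
#' h$data_models
route_helper <- function(print = TRUE) {
  cat0 <- function(...) if (print) cat(..., sep = "")
  info <- list(
    formats = list_route_formats(),
    data_models = tibble::tibble(
      data_model = c("bipartite", "monopartite_molecules",
                     "monopartite_reactions"),
      default = c(TRUE, FALSE, FALSE)
    ),
    identity_policies = tibble::tibble(
      policy = identity_policies(),
      default = identity_policies() == "canonical-isomeric-smiles"
    ),
    descriptors = list_route_descriptors(),
    ged_methods = tibble::tibble(
      method = c("exact", "approximate"),
      default = c(TRUE, FALSE)
    ),
    clustering_methods = tibble::tibble(
      method = c("agglomerative", "density"),
      note = c("default for < 15 routes; silhouette-optimized k",
               "default for >= 15 routes; may emit noise label -1")
    ),
    functionalities = c("compute_descriptors", "clustering"),
    defaults = list(output_format = "node_edge_json",
                    out_data_model = "bipartite",
                    descriptors = "all",
                    linkage = "single")
  )
  cat0("synkit options\n==============\n")
  cat0("formats: ", paste(info$formats$format, collapse = ", "), "\n")
  cat0("data models: ",
       paste(info$data_models$data_model, collapse = ", "),
       " (default: bipartite)\n")
  cat0("identity policies: ",
       paste(info$identity_policies$policy, collapse = ", "),
       " (default: canonical-isomeric-smiles)\n")
  cat0("descriptors: ",
       paste(info$descriptors$descriptor, collapse = ", "),
       " (default: all)\n")
  cat0("ged methods: exact (default), approximate\n")
  cat0("clustering: agglomerative (< 15 routes), density (otherwise); ",
       "default linkage: single\n")
  cat0("functionalities: ",
       paste(info$functionalities, collapse = ", "), "\n")
  invisible(info)
}
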