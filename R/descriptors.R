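# Route descriptors. All descriptors are defined on the
# monopartite-reactions projection of a route; conversion happens
# internally, so values are invariant to the input representation.

.descriptor_registry <- new.env(parent = emptyenv())

#' Register a named route descriptor
#'
#' The descriptor module is a factory: registering a new calculator makes
#' it available to [compute_route_descriptors()], [process_routes()] and
#' [route_helper()] without modifying existing code. The calculator
#' receives the monopartite-reactions projection of the route.
#'
#' @param name Descriptor name.
#' @param fn `function(mpr_route)` returning one number.
#' @param description One-line description shown by the helper.
#' @export
#' @examples
#' register_route_descriptor("n_leaves", function(mpr) {
#'   length(roots_and_leaves(mpr)$leaves)
#' }, "number of starting-material reactions")
register_route_descriptor <- function(name, fn, description = "") {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  .descriptor_registry[[name]] <- list(fn = fn, description = description)
  invisible(name)
}

#' List registered route descriptors
#' @return Tibble with `descriptor` and `description`.
#' @export
list_route_descriptors <- function() {
  nms <- sort(ls(.descriptor_registry))
  tibble::tibble(
    descriptor = nms,
    description = vapply(nms,
                         function(n) .descriptor_registry[[n]]$description, "")
  )
}

# validated monopartite-reactions projection of a route
route_mpr <- function(route) {
  stopifnot(is_syngraph(route))
  g <- convert_data_model(route, "monopartite_reactions")
  rl <- roots_and_leaves(g)
  if (length(rl$roots) != 1L) {
    stop_synkit("not_a_route",
                "descriptors are defined for single-target routes; found ",
                length(rl$roots), " roots")
  }
  as_synroute(g)
}

#' Route descriptors
#'
#' Scalar descriptors of a route's size and shape, all measured on the
#' monopartite-reactions projection:
#'
#' * `n_steps(route)`: number of unique chemical-equation nodes.
#' * `longest_linear_sequence(route)`: maximum number of reactions on any
#'   path from a starting-material reaction to the root reaction.
#' * `n_branches(route)`: how often the route departs from linearity,
#'   counted as \eqn{\sum_c \max(0, \mathrm{indegree}(c) - 1)} — 0 for a
#'   linear route, 1 per binary convergence. `convention = "parents"`
#'   instead counts every reaction feeding a convergent step.
#' * `convergence(route)`: longest linear sequence divided by the number
#'   of steps; 1 for linear routes, smaller for more convergent ones.
#' * `avg_branching_factor(route)`: non-root nodes divided by non-leaf
#'   nodes; needs at least two reactions.
#'
#' @param route A `synroute` (any data model except
#'   monopartite_molecules).
#' @param convention For `n_branches`, `"departures"` (default) or
#'   `"parents"`; see above.
#' @return A single number.
#' @name route-descriptors
NULL

#' @rdname route-descriptors
#' @export
n_steps <- function(route) {
  length(route_mpr(route)$nodes)
}

#' @rdname route-descriptors
#' @export
longest_linear_sequence <- function(route) {
  g <- route_mpr(route)
  memo <- new.env(parent = emptyenv())
  pm <- parents_map(g)
  depth <- function(u) {
    if (!is.null(memo[[u]])) return(memo[[u]])
    ps <- pm[[u]]
    d <- if (!length(ps)) 1L else 1L + max(vapply(ps, depth, 0L))
    memo[[u]] <- d
    d
  }
  root <- roots_and_leaves(g)$roots
  depth(root)
}

#' @rdname route-descriptors
#' @export
n_branches <- function(route, convention = c("departures", "parents")) {
  convention <- match.arg(convention)
  g <- route_mpr(route)
  ins <- in_degrees(g)
  if (convention == "departures") {
    sum(pmax(0L, ins - 1L))
  } else {
    # every parent feeding a step that other parents also feed
    sum(vapply(names(g$children), function(u) {
      any(ins[g$children[[u]]] > 1L)
    }, TRUE))
  }
}

#' @rdname route-descriptors
#' @export
convergence <- function(route) {
  longest_linear_sequence(route) / n_steps(route)
}

#' @rdname route-descriptors
#' @export
avg_branching_factor <- function(route) {
  g <- route_mpr(route)
  n <- length(g$nodes)
  non_leaf <- sum(in_degrees(g) >= 1L)
  if (non_leaf == 0L) {
    stop_synkit("undefined_descriptor",
                "average branching factor is undefined for a single-step ",
                "route (no non-leaf nodes)")
  }
  (n - 1) / non_leaf
}

register_builtin_descriptors <- function() {
  register_route_descriptor(
    "n_steps", n_steps,
    "number of unique chemical-equation nodes"
  )
  register_route_descriptor(
    "longest_linear_sequence", longest_linear_sequence,
    "reactions on the longest starting-material-to-target path"
  )
  register_route_descriptor(
    "n_branches", n_branches,
    "departures from linearity (0 for linear routes)"
  )
  register_route_descriptor(
    "convergence", convergence,
    "longest linear sequence / number of steps"
  )
  register_route_descriptor(
    "avg_branching_factor", avg_branching_factor,
    "non-root nodes / non-leaf nodes"
  )
}

#' Compute route descriptors as a tidy table
#'
#' @param route A `synroute`, or a list of them.
#' @param names Character vector of registered descriptor names, or
#'   `"all"` (default) for every registered descriptor.
#' @param route_id Label(s) for the route(s); defaults to the routes'
#'   source labels (or their list index).
#' @return Tibble with columns `route_id`, `descriptor`, `value`.
#' @export
#' @examples
#' rt <- generate_route(route_spec(depth = 3, seed = 7))
#' compute_route_descriptors(rt$route)
compute_route_descriptors <- function(route, names = "all",
                                      route_id = NULL) {
  if (is_syngraph(route)) {
    routes <- list(route)
  } else {
    routes <- route
  }
  if (identical(names, "all")) {
    names <- sort(ls(.descriptor_registry))
  }
  unknown <- setdiff(names, ls(.descriptor_registry))
  if (length(unknown)) {
    stop_synkit("unknown_descriptor", "unknown descriptor(s) ",
                paste(unknown, collapse = ", "), "; registered: ",
                paste(sort(ls(.descriptor_registry)), collapse = ", "))
  }
  if (is.null(route_id)) {
    route_id <- vapply(seq_along(routes), function(i) {
      lbl <- routes[[i]]$source_label
      if (nzchar(lbl)) lbl else paste0("route_", i)
    }, "")
  }
  purrr::map2_dfr(routes, route_id, function(rt, id) {
    mpr <- route_mpr(rt)
    tibble::tibble(
      route_id = id,
      descriptor = names,
      # a descriptor undefined for this route (e.g. the branching factor
      # of a single-step route) reports NA instead of aborting the batch
      value = unname(vapply(names, function(n) {
        tryCatch(as.numeric(.descriptor_registry[[n]]$fn(mpr)),
                 synkit_undefined_descriptor = function(e) NA_real_)
      }, 0))
    )
  })
}
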