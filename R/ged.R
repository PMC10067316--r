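#' Parameters for the chemistry-aware graph edit distance
#'
#' Node insertion and deletion cost 1 by default. Substituting a node by
#' one of the same kind costs one minus their fingerprint similarity (zero
#' for uid-equal nodes); substituting across kinds (molecule for chemical
#' equation) costs 1, the same as an insert/delete swap. Each inserted or
#' deleted edge costs 1; preserved edges are free.
#'
#' @param insertion_cost,deletion_cost Node insertion/deletion costs.
#' @param edge_insertion_cost,edge_deletion_cost Edge costs.
#' @param fingerprint_params A [fingerprint_params()] bundle for the
#'   substitution similarities.
#' @param use_roots Pin the roots of two routes onto each other during the
#'   search (default TRUE): faster, and chemically sensible since routes
#'   share their target position.
#' @param method `"exact"` (branch-and-bound over node mappings, default)
#'   or `"approximate"` (beam search; an upper bound, for larger graphs).
#' @param beam_width Beam width of the approximate method.
#' @return A `ged_params` list.
#' @export
ged_params <- function(insertion_cost = 1, deletion_cost = 1,
                       edge_insertion_cost = 1, edge_deletion_cost = 1,
                       fingerprint_params = synkit::fingerprint_params(),
                       use_roots = TRUE,
                       method = c("exact", "approximate"),
                       beam_width = 5L) {
  stopifnot(insertion_cost >= 0, deletion_cost >= 0,
            edge_insertion_cost >= 0, edge_deletion_cost >= 0)
  structure(
    list(
      insertion_cost = insertion_cost,
      deletion_cost = deletion_cost,
      edge_insertion_cost = edge_insertion_cost,
      edge_deletion_cost = edge_deletion_cost,
      fingerprint_params = fingerprint_params,
      use_roots = isTRUE(use_roots),
      method = match.arg(method),
      beam_width = as.integer(beam_width)
    ),
    class = "ged_params"
  )
}

#' Node substitution cost
#'
#' One minus the chemical similarity for same-kind nodes (0 when the uids
#' are equal), 1 across kinds.
#'
#' @param a,b Molecule or chemical-equation objects.
#' @param params A [ged_params()] bundle.
#' @return Cost in \[0, 1\].
#' @export
node_substitution_cost <- function(a, b, params = ged_params()) {
  if (node_kind(a) != node_kind(b)) return(1)
  if (identical(a$uid, b$uid)) return(0)
  1 - chemical_similarity(a, b, params$fingerprint_params)
}

# adjacency as a logical matrix in uid order
adjacency_matrix <- function(g) {
  uids <- names(g$nodes)
  m <- matrix(FALSE, length(uids), length(uids),
              dimnames = list(uids, uids))
  for (u in uids) m[u, g$children[[u]]] <- TRUE
  m
}

#' Graph edit distance between two SynGraphs
#'
#' The minimum total cost of node insertions, deletions and substitutions
#' (with their induced edge edits) transforming one graph into a graph
#' isomorphic to the other, using the chemical substitution costs of
#' [node_substitution_cost()]. The default search is exact branch-and-bound
#' over node mappings; `ged(g, g) = 0`, and the distance is symmetric when
#' insertion and deletion costs match.
#'
#' @param a,b `syngraph` objects sharing a data model.
#' @param params A [ged_params()] bundle.
#' @return Distance (non-negative number).
#' @export
#' @examples
#' r1 <- generate_route(route_spec(depth = 2, seed = 1))$route
#' r2 <- generate_route(route_spec(depth = 2, seed = 2))$route
#' ged(convert_data_model(r1, "monopartite_reactions"),
#'     convert_data_model(r2, "monopartite_reactions"))
ged <- function(a, b, params = ged_params()) {
  stopifnot(is_syngraph(a), is_syngraph(b))
  if (a$data_model != b$data_model) {
    stop_synkit("model_mismatch", "cannot compare a ", a$data_model,
                " graph with a ", b$data_model, " graph")
  }
  n1 <- length(a$nodes)
  n2 <- length(b$nodes)
  if (n1 == 0L && n2 == 0L) return(0)
  if (n1 == 0L) return(n2 * params$insertion_cost +
                         sum(adjacency_matrix(b)) *
                         params$edge_insertion_cost)
  if (n2 == 0L) return(n1 * params$deletion_cost +
                         sum(adjacency_matrix(a)) *
                         params$edge_deletion_cost)

  A1 <- adjacency_matrix(a)
  A2 <- adjacency_matrix(b)
  sub <- matrix(0, n1, n2)
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      sub[i, j] <- node_substitution_cost(a$nodes[[i]], b$nodes[[j]], params)
    }
  }

  # node order: roots first when pinned, otherwise high-degree first so
  # edge mismatches surface early
  deg1 <- rowSums(A1) + colSums(A1)
  order1 <- order(-deg1)
  pin <- NULL
  if (params$use_roots) {
    r1 <- which(vapply(seq_len(n1), function(i) {
      length(a$children[[i]]) == 0L
    }, TRUE))
    r2 <- which(vapply(seq_len(n2), function(j) {
      length(b$children[[j]]) == 0L
    }, TRUE))
    if (length(r1) == 1L && length(r2) == 1L) {
      pin <- c(r1, r2)
      order1 <- c(r1, setdiff(order1, r1))
    }
  }

  if (params$method == "approximate") {
    ged_beam(A1, A2, sub, params, order1, pin)
  } else {
    ged_exact(A1, A2, sub, params, order1, pin)
  }
}

# incremental edge cost of assigning g1 node i -> j (0 = deletion), given
# earlier assignments m (g1 index -> g2 index or 0) over nodes `done`
edge_delta <- function(i, j, done, m, A1, A2, params) {
  cost <- 0
  for (u in done) {
    v <- m[u]
    e1f <- A1[i, u]; e1b <- A1[u, i]
    e2f <- j > 0 && v > 0 && A2[j, v]
    e2b <- j > 0 && v > 0 && A2[v, j]
    if (e1f && !e2f) cost <- cost + params$edge_deletion_cost
    if (!e1f && e2f) cost <- cost + params$edge_insertion_cost
    if (e1b && !e2b) cost <- cost + params$edge_deletion_cost
    if (!e1b && e2b) cost <- cost + params$edge_insertion_cost
  }
  cost
}

# cost of inserting the unmatched g2 nodes plus their incident edges
insertion_tail <- function(m, A2, params) {
  n2 <- ncol(A2)
  used <- m[m > 0]
  unused <- setdiff(seq_len(n2), used)
  cost <- length(unused) * params$insertion_cost
  if (length(unused)) {
    touch <- matrix(FALSE, n2, n2)
    touch[unused, ] <- TRUE
    touch[, unused] <- TRUE
    cost <- cost + sum(A2 & touch) * params$edge_insertion_cost
  }
  cost
}

ged_exact <- function(A1, A2, sub, params, order1, pin) {
  n1 <- nrow(sub)
  n2 <- ncol(sub)
  best <- Inf
  m <- integer(n1)

  lower_bound <- function(pos, used2) {
    remaining <- if (pos > n1) integer(0) else order1[pos:n1]
    r1 <- length(remaining)
    u2 <- n2 - sum(used2)
    lb <- max(0, u2 - r1) * params$insertion_cost
    for (i in remaining) {
      opts <- params$deletion_cost
      if (u2 > 0) {
        opts <- min(opts, min(sub[i, !used2]))
      }
      lb <- lb + opts
    }
    lb
  }

  used2 <- rep(FALSE, n2)
  recurse <- function(pos, cost, done) {
    if (cost + lower_bound(pos, used2) >= best) return()
    if (pos > n1) {
      total <- cost + insertion_tail(m, A2, params)
      if (total < best) best <<- total
      return()
    }
    i <- order1[pos]
    cands <- which(!used2)
    if (pos == 1L && !is.null(pin)) cands <- pin[2]
    cands <- cands[order(sub[i, cands])]
    for (j in cands) {
      d <- sub[i, j] + edge_delta(i, j, done, m, A1, A2, params)
      if (cost + d < best) {
        m[i] <<- j
        used2[j] <<- TRUE
        recurse(pos + 1L, cost + d, c(done, i))
        used2[j] <<- FALSE
        m[i] <<- 0L
      }
    }
    if (is.null(pin) || pos > 1L) {
      d <- params$deletion_cost + edge_delta(i, 0L, done, m, A1, A2, params)
      if (cost + d < best) {
        m[i] <<- 0L
        recurse(pos + 1L, cost + d, c(done, i))
      }
    }
  }
  recurse(1L, 0, integer(0))
  best
}

# beam search over the same state space; returns an upper bound on the GED
ged_beam <- function(A1, A2, sub, params, order1, pin) {
  n1 <- nrow(sub)
  n2 <- ncol(sub)
  beam <- list(list(m = integer(n1), used2 = rep(FALSE, n2),
                    cost = 0, done = integer(0)))
  for (pos in seq_len(n1)) {
    i <- order1[pos]
    nxt <- list()
    for (st in beam) {
      cands <- which(!st$used2)
      if (pos == 1L && !is.null(pin)) cands <- pin[2]
      for (j in c(cands, 0L)) {
        if (j == 0L && !is.null(pin) && pos == 1L) next
        d <- (if (j > 0) sub[i, j] else params$deletion_cost) +
          edge_delta(i, j, st$done, st$m, A1, A2, params)
        m2 <- st$m
        m2[i] <- j
        u2 <- st$used2
        if (j > 0) u2[j] <- TRUE
        nxt[[length(nxt) + 1L]] <- list(m = m2, used2 = u2,
                                        cost = st$cost + d,
                                        done = c(st$done, i))
      }
    }
    costs <- vapply(nxt, function(s) s$cost, 0)
    beam <- nxt[order(costs)][seq_len(min(params$beam_width, length(nxt)))]
  }
  min(vapply(beam, function(s) {
    s$cost + insertion_tail(s$m, A2, params)
  }, 0))
}

#' Pairwise route distance matrix
#'
#' Computes the GED between every pair of routes (upper triangle, then
#' mirrored) on a chosen data model — by default the monopartite-reactions
#' projection, where route comparison concentrates on the chemistry of the
#' steps. Fingerprints are computed once per node and cached, and the pair
#' loop can fan out over forked workers; the parallel result is identical
#' to the serial one because every pair is computed independently and
#' deterministically.
#'
#' @param routes List of `synroute` objects (length >= 2).
#' @param params A [ged_params()] bundle.
#' @param parallel Fork the pair loop over `n_workers` processes.
#' @param n_workers Number of workers when `parallel = TRUE`.
#' @param data_model Model on which distances are computed.
#' @param route_ids Labels; default from source labels or index.
#' @return A `route_distance_matrix`: list with `route_ids` and the
#'   symmetric, zero-diagonal `values` matrix.
#' @export
route_distance_matrix <- function(routes, params = ged_params(),
                                  parallel = FALSE, n_workers = 2L,
                                  data_model = "monopartite_reactions",
                                  route_ids = NULL) {
  if (length(routes) < 2L) {
    stop_synkit("insufficient_input",
                "a distance matrix needs at least 2 routes")
  }
  if (is.null(route_ids)) {
    route_ids <- vapply(seq_along(routes), function(i) {
      lbl <- routes[[i]]$source_label
      if (nzchar(lbl)) lbl else paste0("route_", i)
    }, "")
  }
  route_ids <- make.unique(route_ids)
  gs <- lapply(routes, convert_data_model, target = data_model)
  # warm the fingerprint cache once, before any forking
  for (g in gs) {
    for (n in g$nodes) node_fingerprint(n, params$fingerprint_params)
  }
  n <- length(gs)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  worker <- function(k) {
    ged(gs[[pairs[k, 1]]], gs[[pairs[k, 2]]], params)
  }
  vals <- if (parallel) {
    unlist(parallel::mclapply(seq_len(nrow(pairs)), worker,
                              mc.cores = max(1L, as.integer(n_workers))))
  } else {
    vapply(seq_len(nrow(pairs)), worker, 0)
  }
  values <- matrix(0, n, n, dimnames = list(route_ids, route_ids))
  values[pairs] <- vals
  values <- values + t(values)
  structure(list(route_ids = route_ids, values = values),
            class = "route_distance_matrix")
}

#' @export
print.route_distance_matrix <- function(x, ...) {
  cat("<route_distance_matrix> ", length(x$route_ids), " routes\n", sep = "")
  print(round(x$values, 3))
  invisible(x)
}

#' @export
tidy.route_distance_matrix <- function(x, ...) {
  n <- length(x$route_ids)
  idx <- which(upper.tri(x$values), arr.ind = TRUE)
  tibble::tibble(
    route_a = x$route_ids[idx[, 1]],
    route_b = x$route_ids[idx[, 2]],
    distance = x$values[idx]
  )
}

#' @export
autoplot.route_distance_matrix <- function(object, ...) {
  df <- expand.grid(route_a = object$route_ids, route_b = object$route_ids,
                    stringsAsFactors = FALSE)
  df$distance <- as.vector(object$values)
  ggplot2::ggplot(df, ggplot2::aes(.data$route_a, .data$route_b,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "GED",
                  title = "Route distance matrix") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
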