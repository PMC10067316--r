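# Independent oracles and fixture helpers shared across the test files.

# Exhaustive graph edit distance: enumerates every injective partial node
# mapping between the two graphs and prices each complete assignment from
# scratch. Deliberately independent of the package's branch-and-bound
# search (no shared search code, no pruning, no incremental costing); only
# the node substitution cost function is shared, and that is itself tested
# against direct fingerprint computation. With `pin_roots = TRUE` the
# enumeration is restricted to mappings sending root to root, matching the
# search's rooted mode.
oracle_ged <- function(a, b, params = ged_params(), pin_roots = FALSE) {
  n1 <- length(a$nodes)
  n2 <- length(b$nodes)
  uids1 <- names(a$nodes)
  uids2 <- names(b$nodes)
  edge_idx <- function(g, uids) {
    from <- integer(0)
    to <- integer(0)
    for (u in names(g$children)) {
      for (v in g$children[[u]]) {
        from <- c(from, match(u, uids))
        to <- c(to, match(v, uids))
      }
    }
    cbind(from, to)
  }
  e1 <- edge_idx(a, uids1)
  e2 <- edge_idx(b, uids2)
  sub <- matrix(0, max(n1, 1), max(n2, 1))
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      sub[i, j] <- node_substitution_cost(a$nodes[[i]], b$nodes[[j]], params)
    }
  }
  pin <- NULL
  if (pin_roots) {
    r1 <- which(vapply(uids1, function(u) length(a$children[[u]]) == 0L, TRUE))
    r2 <- which(vapply(uids2, function(u) length(b$children[[u]]) == 0L, TRUE))
    if (length(r1) == 1L && length(r2) == 1L) pin <- c(r1, r2)
  }
  price <- function(map) {
    cost <- 0
    for (i in seq_len(n1)) {
      cost <- cost + if (map[i] > 0) sub[i, map[i]] else params$deletion_cost
    }
    cost <- cost + (n2 - sum(map > 0)) * params$insertion_cost
    img <- matrix(FALSE, max(n2, 1), max(n2, 1))  # g2 edges covered by g1
    if (nrow(e1)) {
      for (k in seq_len(nrow(e1))) {
        p <- map[e1[k, 1]]
        q <- map[e1[k, 2]]
        covered <- p > 0 && q > 0 &&
          any(e2[, 1] == p & e2[, 2] == q)
        if (covered) img[p, q] <- TRUE else {
          cost <- cost + params$edge_deletion_cost
        }
      }
    }
    if (nrow(e2)) {
      for (k in seq_len(nrow(e2))) {
        if (!img[e2[k, 1], e2[k, 2]]) {
          cost <- cost + params$edge_insertion_cost
        }
      }
    }
    cost
  }
  best <- Inf
  recurse <- function(i, map, used) {
    if (i > n1) {
      best <<- min(best, price(map))
      return()
    }
    js <- if (!is.null(pin) && i == pin[1]) pin[2] else seq_len(n2)
    for (j in js) {
      if (!used[j]) {
        map[i] <- j
        used[j] <- TRUE
        recurse(i + 1L, map, used)
        used[j] <- FALSE
      }
    }
    if (is.null(pin) || i != pin[1]) {
      map[i] <- 0L
      recurse(i + 1L, map, used)
    }
  }
  if (n1 == 0L) return(price(integer(0)))
  recurse(1L, integer(n1), rep(FALSE, max(n2, 1)))
  best
}

# random small route whose monopartite-reactions projection has <= max_nodes
# reaction nodes, with varied topology
random_small_mpr <- function(seed, max_nodes = 4L) {
  withr::with_seed(seed * 7919L, {
    depth <- sample(seq_len(min(3L, max_nodes)), 1L)
    branch <- list()
    room <- max_nodes - depth
    if (depth >= 2L && room >= 1L && stats::runif(1) < 0.5) {
      branch <- list(c(sample(seq_len(depth), 1L), sample(seq_len(room), 1L)))
    }
    spec <- route_spec(depth, branch_points = branch,
                       seed = sample.int(10000L, 1L))
    convert_data_model(generate_route(spec)$route, "monopartite_reactions")
  })
}

# random route spec used by descriptor/round-trip/merge properties
random_route_spec <- function(seed, max_depth = 4L) {
  withr::with_seed(seed * 104729L, {
    depth <- sample(seq_len(max_depth), 1L)
    branch <- list()
    if (depth >= 2L && stats::runif(1) < 0.6) {
      branch <- list(c(sample(2:depth, 1L), sample(seq_len(2L), 1L)))
      if (stats::runif(1) < 0.3) {
        branch <- c(branch, list(c(sample(2:depth, 1L),
                                   sample(seq_len(2L), 1L))))
      }
    }
    route_spec(depth, branch_points = branch, seed = sample.int(100000L, 1L))
  })
}

# planted two-block distance matrix; intra-block distances far below
# inter-block ones
planted_block_matrix <- function(seed) {
  withr::with_seed(seed, {
    n1 <- sample(3:6, 1L)
    n2 <- sample(3:6, 1L)
    n <- n1 + n2
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        same <- (i <= n1) == (j <= n1)
        d[i, j] <- d[j, i] <- if (same) stats::runif(1, 0.01, 0.2) else
          stats::runif(1, 4, 6)
      }
    }
    rownames(d) <- colnames(d) <- paste0("r", seq_len(n))
    list(d = d, labels = rep(1:2, c(n1, n2)))
  })
}

# partition equality up to label renaming
same_partition <- function(a, b) {
  identical(
    as.integer(factor(a, levels = unique(a))),
    as.integer(factor(b, levels = unique(b)))
  )
}

# reaction-SMILES writings of the same chemical equation with permuted
# molecule order and optional extra reagents
permuted_reaction_writing <- function(reactants, products, reagents = character(0)) {
  paste0(
    paste(sample(reactants), collapse = "."), ">",
    if (length(reagents)) paste(sample(reagents), collapse = ".") else "",
    ">", paste(sample(products), collapse = ".")
  )
}
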