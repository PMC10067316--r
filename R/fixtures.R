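# Seeded synthetic-route generator. Routes are built from a small alphabet
# of valid acyclic SMILES "codewords", every one starting with N and
# continuing with C/O atoms. Products are concatenations of their
# reactants' SMILES: because no codeword contains a second N, every
# concatenation is uniquely decodable, and because a concatenation never
# ends in N, no two distinct chains can collide by being read in reverse.
# The toy reactions are not meant to be chemically sensible - the identity
# and graph layers never inspect mechanism - but every generated string is
# valid, parseable chemistry, and the descriptor values of each route are
# known by construction.

#' Default molecule alphabet for the route generator
#'
#' Twenty small amine/ether-like SMILES codewords (`N` followed by one to
#' four C/O atoms), chosen so that concatenations of codewords are uniquely
#' decodable (see the source comment).
#'
#' @return Character vector of SMILES.
#' @export
default_molecule_alphabet <- function() {
  tails <- character(0)
  for (k in 1:3) {
    grid <- do.call(expand.grid, c(rep(list(c("C", "O")), k),
                                   stringsAsFactors = FALSE))
    tails <- c(tails, apply(grid, 1, paste, collapse = ""))
  }
  extra4 <- c("CCCC", "CCCO", "CCOC", "COCC", "OCCC", "CCOO")
  paste0("N", c(tails, extra4))
}

# per-chain unique marker codeword, longer than any alphabet entry
chain_marker <- function(chain_id) {
  paste0("N", strrep("C", 5L + chain_id))
}

#' Specification of a synthetic fixture route
#'
#' @param depth Number of reactions along the main chain (>= 1).
#' @param branch_points List of `c(position, branch_depth)` pairs: a side
#'   chain of `branch_depth` reactions whose product feeds the main-chain
#'   reaction at `position` (1 = the starting-material end).
#' @param seed Integer seed; generation is deterministic given
#'   (spec, seed).
#' @param alphabet Molecule alphabet; see [default_molecule_alphabet()].
#' @return A `route_spec` list.
#' @export
route_spec <- function(depth, branch_points = list(), seed = 1L,
                       alphabet = default_molecule_alphabet()) {
  if (!is.numeric(depth) || depth < 1) {
    stop_synkit("spec", "depth must be >= 1")
  }
  if (length(branch_points) && !is.list(branch_points)) {
    branch_points <- list(branch_points)
  }
  for (bp in branch_points) {
    if (length(bp) != 2L || bp[1] < 1 || bp[1] > depth || bp[2] < 1) {
      stop_synkit("spec", "each branch point is c(position, depth) with ",
                  "1 <= position <= main depth and depth >= 1")
    }
  }
  structure(
    list(depth = as.integer(depth),
         branch_points = lapply(branch_points, as.integer),
         seed = as.integer(seed), alphabet = alphabet),
    class = "route_spec"
  )
}

#' Generate a seeded synthetic route with known descriptor values
#'
#' Builds a bipartite route per the spec: a main chain of `depth`
#' concatenation reactions plus the requested side branches. Alongside the
#' route it returns the descriptor values implied by the construction
#' (computed from the chain arithmetic while building, not from the graph),
#' which makes the generator an independent ground truth for the
#' descriptor module.
#'
#' @param spec A [route_spec()].
#' @param policy Identity policy for the molecules.
#' @return List with `route` (a bipartite `synroute`) and `expected`
#'   (named list: `n_steps`, `longest_linear_sequence`, `n_branches`,
#'   `convergence`, `avg_branching_factor` - the last is `NA` for
#'   single-step routes, where it is undefined).
#' @export
#' @examples
#' rt <- generate_route(route_spec(depth = 3, branch_points = list(c(3, 2)),
#'                                 seed = 11))
#' rt$expected$n_steps
generate_route <- function(spec, policy = "canonical-isomeric-smiles") {
  stopifnot(inherits(spec, "route_spec"))
  withr::with_seed(spec$seed, {
    draw <- function() sample(spec$alphabet, 1L)
    reactions <- list()   # list of list(reactants=chr, product=chr)
    indeg <- integer(0)   # by-construction in-degree per reaction

    build_chain <- function(len, marker, extra_at = list()) {
      inter <- paste0(draw(), marker)
      idx <- integer(len)
      for (j in seq_len(len)) {
        reactants <- c(inter, draw(), extra_at[[as.character(j)]])
        product <- paste(reactants, collapse = "")
        reactions[[length(reactions) + 1L]] <<-
          list(reactants = reactants, product = product)
        deg <- (j > 1L) + length(extra_at[[as.character(j)]])
        indeg[length(indeg) + 1L] <<- as.integer(deg)
        idx[j] <- length(reactions)
        inter <- product
      }
      list(product = inter, idx = idx)
    }

    # branches first, so their products can feed the main chain
    extra <- list()
    for (b in seq_along(spec$branch_points)) {
      bp <- spec$branch_points[[b]]
      ch <- build_chain(bp[2], chain_marker(b))
      key <- as.character(bp[1])
      extra[[key]] <- c(extra[[key]], ch$product)
    }
    build_chain(spec$depth, chain_marker(0L), extra)

    n <- length(reactions)
    lls <- spec$depth
    for (bp in spec$branch_points) {
      lls <- max(lls, bp[2] + (spec$depth - bp[1] + 1L))
    }
    non_leaf <- sum(indeg >= 1L)
    expected <- list(
      n_steps = n,
      longest_linear_sequence = as.integer(lls),
      n_branches = sum(pmax(0L, indeg - 1L)),
      convergence = lls / n,
      avg_branching_factor = if (non_leaf > 0L) (n - 1) / non_leaf
                             else NA_real_
    )

    equations <- lapply(reactions, function(r) {
      equation_from_sides(r$reactants, r$product, policy = policy)
    })
    route <- as_synroute(syngraph_from_equations(
      equations, source_label = paste0("fixture_seed", spec$seed)
    ))
    list(route = route, expected = expected)
  })
}

#' Perturb a route with edits of known cost bound
#'
#' Applies `edits` random edits, each with a constructed edit path whose
#' cost on the monopartite-reactions projection is known, and returns the
#' perturbed route together with the cumulative bound - by construction,
#' `ged(original, perturbed) <= ged_bound`. Edit kinds:
#'
#' * `swap`: replace one starting-material molecule of one reaction with a
#'   fresh molecule (bound: 1 - reaction similarity of old vs new step);
#' * `add_step`: give one starting material a producing reaction (bound:
#'   node insertion + one edge insertion).
#'
#' @param route A bipartite `synroute`.
#' @param edits Number of edits (0 returns an equal route, bound 0).
#' @param seed Integer seed.
#' @param params [ged_params()] used to price the swap bound.
#' @return List with `route` and `ged_bound`.
#' @export
perturb_route <- function(route, edits, seed = 1L, params = ged_params()) {
  stopifnot(is_syngraph(route))
  if (edits > length(route$nodes)) {
    stop_synkit("spec", "cannot apply ", edits, " edits to a route of ",
                length(route$nodes), " nodes")
  }
  withr::with_seed(seed, {
    equations <- unname(graph_equations(route))
    bound <- 0
    touched <- character(0)   # leaf uids already edited
    fresh_id <- 0L
    fresh_mol <- function() {
      fresh_id <<- fresh_id + 1L
      paste0("N", strrep("O", 1L + fresh_id), strrep("C", 10L))
    }
    for (e in seq_len(edits)) {
      g <- syngraph_from_equations(equations)
      leaf_uids <- setdiff(roots_and_leaves(g)$leaves, touched)
      leaf_uids <- Filter(function(u) is_molecule(g$nodes[[u]]), leaf_uids)
      if (!length(leaf_uids)) {
        stop_synkit("spec", "route has no remaining editable starting ",
                    "materials")
      }
      leaf <- sample(leaf_uids, 1L)
      op <- sample(c("swap", "add_step"), 1L)
      if (op == "swap") {
        ce_idx <- which(vapply(equations, function(ce) {
          leaf %in% ce$role_map$reactant
        }, TRUE))[1]
        old_ce <- equations[[ce_idx]]
        old_smiles <- vapply(
          unlist(rep(old_ce$role_map$reactant,
                     old_ce$stoichiometry$reactant[old_ce$role_map$reactant])),
          function(u) old_ce$molecules[[u]]$canonical_form, ""
        )
        keep <- old_smiles != old_ce$molecules[[leaf]]$canonical_form
        # drop one occurrence of the leaf, add the fresh molecule
        drop_one <- which(!keep)[1]
        new_reactants <- c(old_smiles[-drop_one], fresh_mol())
        prod_smiles <- vapply(old_ce$role_map$product, function(u) {
          old_ce$molecules[[u]]$canonical_form
        }, "")
        new_ce <- equation_from_sides(new_reactants, prod_smiles,
                                      policy = old_ce$policy)
        equations[[ce_idx]] <- new_ce
        bound <- bound +
          (1 - chemical_similarity(old_ce, new_ce,
                                   params$fingerprint_params))
        touched <- c(touched, new_ce$role_map$reactant)
      } else {
        leaf_smiles <- g$nodes[[leaf]]$canonical_form
        new_ce <- equation_from_sides(fresh_mol(), leaf_smiles,
                                      policy = g$nodes[[leaf]]$policy)
        # one inserted node plus one inserted edge per step consuming the
        # leaf on the monopartite-reactions projection
        consumers <- sum(vapply(equations, function(ce) {
          leaf %in% ce$role_map$reactant
        }, TRUE))
        equations[[length(equations) + 1L]] <- new_ce
        bound <- bound + params$insertion_cost +
          consumers * params$edge_insertion_cost
        touched <- c(touched, leaf, new_ce$role_map$reactant)
      }
    }
    out <- as_synroute(syngraph_from_equations(
      equations, source_label = paste0(route$source_label, "_perturbed")
    ))
    list(route = out, ged_bound = bound)
  })
}

#' Generate a route catalog (SynTree) with a known route count
#'
#' Builds a chain of intermediates toward one target in which the j-th
#' intermediate from the top can be delivered by `n_alternatives[j]`
#' different reactions (distinct co-reactants). Every extractable route
#' passes through every convergence point, so the number of distinct
#' routes is exactly `prod(n_alternatives)`.
#'
#' @param n_alternatives Integer vector: alternatives per convergence
#'   point, top (target side) first.
#' @param seed Integer seed.
#' @param alphabet Molecule alphabet.
#' @param policy Identity policy.
#' @return List with `tree` (bipartite `syngraph`) and `n_routes`.
#' @export
#' @examples
#' tr <- generate_tree(c(2, 2), seed = 3)
#' tr$n_routes
generate_tree <- function(n_alternatives, seed = 1L,
                          alphabet = default_molecule_alphabet(),
                          policy = "canonical-isomeric-smiles") {
  if (!length(n_alternatives) || any(n_alternatives < 1)) {
    stop_synkit("spec", "n_alternatives must be a non-empty vector of ",
                "counts >= 1")
  }
  n_alternatives <- as.integer(n_alternatives)
  J <- length(n_alternatives)
  withr::with_seed(seed, {
    # intermediates M_J (a starting material) up to M_0 (the target)
    m <- character(J + 1L)
    m[J + 1L] <- paste0(sample(alphabet, 1L), chain_marker(0L))
    for (j in J:1) {
      m[j] <- paste0(m[j + 1L], sample(alphabet, 1L))
    }
    equations <- list()
    for (j in seq_len(J)) {
      partners <- sample(alphabet, n_alternatives[j])
      for (i in seq_len(n_alternatives[j])) {
        equations[[length(equations) + 1L]] <- equation_from_sides(
          c(m[j + 1L], partners[i]), m[j], policy = policy
        )
      }
    }
    tree <- syngraph_from_equations(
      equations, source_label = paste0("tree_seed", seed)
    )
    list(tree = tree, n_routes = prod(n_alternatives))
  })
}
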