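#' Build a ChemicalEquation value object from reaction SMILES
#'
#' Parses `reactants>agents>products` (or `reactants>>products`) text,
#' canonicalizes every structure, and attributes roles. Role attribution:
#' molecules in the agent block become reagents, and any molecule whose uid
#' appears identically among both reactants and products is reassigned to
#' the reagent role (it is a spectator at the identity level used here).
#'
#' The equation's `uid` is a hash of the sorted reactant uids and sorted
#' product uids only, so it is invariant to the order of molecules within a
#' role and to any change confined to reagents — the identity layer that
#' makes two CASP routes comparable irrespective of reaction conditions.
#' Duplicate molecules within a role are recorded as stoichiometric
#' coefficients but do not enter the uid.
#'
#' @param reaction_string Reaction SMILES.
#' @param policy Identity policy applied to every molecule;
#'   see [identity_policies()].
#' @return An object of class `chemical_equation` with fields `role_map`
#'   (uids per role), `molecules` (uid-keyed catalog of [molecule][canonicalize_molecule()]
#'   objects), `stoichiometry`, `reaction_string` (canonical form), `uid`.
#' @export
#' @examples
#' ce <- build_chemical_equation("CCO.CC(=O)O>>CC(=O)OCC.O")
#' ce$role_map$reactant
build_chemical_equation <- function(reaction_string,
                                    policy = "canonical-isomeric-smiles") {
  policy <- check_policy(policy)
  if (!is.character(reaction_string) || length(reaction_string) != 1L ||
      is.na(reaction_string)) {
    stop_synkit("malformed_reaction", "reaction text must be a single string")
  }
  blocks <- strsplit(reaction_string, ">", fixed = TRUE)[[1]]
  if (length(blocks) == 2L) blocks <- c(blocks, "")
  if (length(blocks) != 3L) {
    stop_synkit("malformed_reaction",
                "expected 'reactants>agents>products' or ",
                "'reactants>>products': '", reaction_string, "'")
  }
  split_block <- function(block) {
    if (!nzchar(block)) return(character(0))
    parts <- strsplit(block, ".", fixed = TRUE)[[1]]
    parts[nzchar(parts)]
  }
  mols_of <- function(smls) lapply(smls, canonicalize_molecule, policy = policy)

  reactants <- mols_of(split_block(blocks[1]))
  reagents <- mols_of(split_block(blocks[2]))
  products <- mols_of(split_block(blocks[3]))

  uid_of <- function(ms) vapply(ms, function(m) m$uid, "")
  r_uids <- uid_of(reactants)
  p_uids <- uid_of(products)

  # spectators: same uid verbatim on both sides -> reagent
  spectator <- intersect(unique(r_uids), unique(p_uids))
  if (length(spectator)) {
    reagents <- c(reagents, reactants[r_uids %in% spectator])
    reactants <- reactants[!r_uids %in% spectator]
    products <- products[!p_uids %in% spectator]
    r_uids <- uid_of(reactants)
    p_uids <- uid_of(products)
  }
  if (length(reactants) == 0L || length(products) == 0L) {
    stop_synkit("malformed_reaction",
                "reaction needs at least one reactant and one product ",
                "after role attribution: '", reaction_string, "'")
  }
  g_uids <- uid_of(reagents)

  catalog <- list()
  for (m in c(reactants, reagents, products)) catalog[[m$uid]] <- m

  stoich <- list(
    reactant = table_counts(r_uids),
    reagent = table_counts(g_uids),
    product = table_counts(p_uids)
  )
  role_map <- list(
    reactant = sort(unique(r_uids)),
    reagent = sort(unique(g_uids)),
    product = sort(unique(p_uids))
  )

  canon_side <- function(uids) {
    paste(sort(vapply(uids, function(u) catalog[[u]]$canonical_form, "")),
          collapse = ".")
  }
  canonical_rxn <- paste0(
    canon_side(r_uids), ">", canon_side(g_uids), ">", canon_side(p_uids)
  )
  identity_key <- paste0(
    paste(role_map$reactant, collapse = "."), ">>",
    paste(role_map$product, collapse = ".")
  )

  structure(
    list(
      kind = "chemical_equation",
      input_string = reaction_string,
      reaction_string = canonical_rxn,
      role_map = role_map,
      molecules = catalog,
      stoichiometry = stoich,
      identity_string = identity_key,
      uid = node_uid("CE", policy, identity_key),
      policy = policy
    ),
    class = c("chemical_equation", "synkit_node")
  )
}

table_counts <- function(uids) {
  if (!length(uids)) return(integer(0))
  tab <- table(uids)
  stats::setNames(as.integer(tab), names(tab))
}

#' @export
print.chemical_equation <- function(x, ...) {
  cat("<chemical_equation> ", x$reaction_string, "\n  uid: ", x$uid,
      "  (", length(x$role_map$reactant), " reactants, ",
      length(x$role_map$reagent), " reagents, ",
      length(x$role_map$product), " products)\n", sep = "")
  invisible(x)
}

is_chemical_equation <- function(x) inherits(x, "chemical_equation")

# Assemble a chemical_equation from precursor and product molecule SMILES,
# used by tree readers and the fixture generator.
equation_from_sides <- function(reactant_smiles, product_smiles,
                                policy = "canonical-isomeric-smiles") {
  build_chemical_equation(
    paste0(paste(reactant_smiles, collapse = "."), ">>",
           paste(product_smiles, collapse = ".")),
    policy = policy
  )
}
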