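#' Identity policies for molecular value objects
#'
#' A Molecule is a *value object*: its identity (`uid`) derives entirely from
#' its structure under a chosen policy. Three policies are available:
#'
#' * `"canonical-isomeric-smiles"` (default): canonical SMILES retaining
#'   stereochemistry. Stereoisomers are distinct nodes.
#' * `"canonical-smiles-no-stereo"`: canonical SMILES after removing
#'   stereo marks; stereoisomers collapse onto one node.
#' * `"inchikey"`: the InChIKey string, which also normalizes tautomers
#'   more aggressively than SMILES canonicalization.
#'
#' Switching to a coarser policy may merge nodes but never splits a pair
#' that was uid-equal under the finer policy.
#'
#' @return Character vector of the registered policy names.
#' @export
#' @examples
#' identity_policies()
identity_policies <- function() {
  c("canonical-isomeric-smiles", "canonical-smiles-no-stereo", "inchikey")
}

check_policy <- function(policy) {
  policy <- policy %||% "canonical-isomeric-smiles"
  if (!policy %in% identity_policies()) {
    stop_synkit("unknown_policy", "unknown identity policy '", policy,
                "'; registered: ", paste(identity_policies(), collapse = ", "))
  }
  policy
}

molecule_identity_string <- function(canonical, policy) {
  switch(policy,
    "canonical-isomeric-smiles" = canonical,
    "canonical-smiles-no-stereo" = ob_canonical_smiles(strip_stereo(canonical)),
    "inchikey" = ob_inchikey(canonical)
  )
}

#' Build a Molecule value object from a structure string
#'
#' Validates and canonicalizes a SMILES string and derives the identity
#' string (`uid`) under the requested policy. Two molecules written
#' differently (atom order, aromatic vs. Kekulé form) receive the same uid;
#' canonicalization is idempotent, so the canonical form is a fixed point.
#'
#' @param input_string SMILES of the structure.
#' @param policy Identity policy name; see [identity_policies()].
#' @return An object of class `molecule` with fields `input_string`,
#'   `canonical_form` (canonical isomeric SMILES), `identity_string`,
#'   `uid` and `policy`.
#' @export
#' @examples
#' m1 <- canonicalize_molecule("OCC")
#' m2 <- canonicalize_molecule("CCO")
#' m1$uid == m2$uid
canonicalize_molecule <- function(input_string,
                                  policy = "canonical-isomeric-smiles") {
  policy <- check_policy(policy)
  if (!smiles_is_valid(input_string)) {
    stop_synkit("invalid_structure",
                "not a valid structure: '", input_string, "'")
  }
  canonical <- ob_canonical_smiles(input_string)
  ident <- molecule_identity_string(canonical, policy)
  structure(
    list(
      kind = "molecule",
      input_string = input_string,
      canonical_form = canonical,
      identity_string = ident,
      uid = node_uid("M", policy, ident),
      policy = policy
    ),
    class = c("molecule", "synkit_node")
  )
}

node_uid <- function(prefix, policy, ident) {
  paste0(prefix, substr(rlang::hash(paste0(policy, "\r", ident)), 1, 16))
}

#' @export
print.molecule <- function(x, ...) {
  cat("<molecule> ", x$canonical_form, "  uid: ", x$uid,
      "  policy: ", x$policy, "\n", sep = "")
  invisible(x)
}

is_molecule <- function(x) inherits(x, "molecule")

node_kind <- function(x) x$kind

# display label used by DOT export and printing
node_label <- function(x) {
  if (x$kind == "molecule") x$canonical_form else x$reaction_string
}
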