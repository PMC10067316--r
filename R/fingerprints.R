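#' Fingerprint and similarity parameters
#'
#' Bundles the choices used wherever chemical similarity is computed:
#' circular (ECFP) fingerprints for molecules, a difference fingerprint for
#' reactions, and the Tanimoto metric — the combination commonly used when
#' weighting route comparisons with chemistry.
#'
#' @param molecular_fp_type One of `"ecfp4"` (default: circular, radius 2),
#'   `"ecfp2"`, `"ecfp6"`, `"fp2"` (linear-fragment).
#' @param reaction_fp_type `"difference"` (default: stoichiometry-weighted
#'   product-minus-reactant bit counts) or `"structural"` (concatenated
#'   reactant and product bit unions).
#' @param similarity_metric `"tanimoto"` (default) or `"dice"`.
#' @return A `fingerprint_params` list.
#' @export
#' @examples
#' fingerprint_params()
fingerprint_params <- function(molecular_fp_type = "ecfp4",
                               reaction_fp_type = "difference",
                               similarity_metric = "tanimoto") {
  molecular_fp_type <- match.arg(molecular_fp_type,
                                 c("ecfp4", "ecfp2", "ecfp6", "fp2"))
  reaction_fp_type <- match.arg(reaction_fp_type,
                                c("difference", "structural"))
  similarity_metric <- match.arg(similarity_metric, c("tanimoto", "dice"))
  structure(
    list(
      molecular_fp_type = molecular_fp_type,
      reaction_fp_type = reaction_fp_type,
      similarity_metric = similarity_metric
    ),
    class = "fingerprint_params"
  )
}

ob_fp_name <- function(fp_type) {
  c(ecfp2 = "ECFP2", ecfp4 = "ECFP4", ecfp6 = "ECFP6", fp2 = "FP2")[[fp_type]]
}

# 0/1 integer fingerprint of a canonical SMILES, cached per (type, smiles)
smiles_fingerprint <- function(canonical_smiles, fp_type) {
  cache_get_or(paste0("fp\r", fp_type, "\r", canonical_smiles), function() {
    sdf <- suppressWarnings(
      ChemmineR::smiles2sdf(stats::setNames(canonical_smiles, "m"))
    )
    fp <- ChemmineR::fingerprintOB(sdf, ob_fp_name(fp_type))
    as.integer(ChemmineR::as.matrix(fp)[1, ])
  })
}

molecule_fingerprint <- function(m, params) {
  smiles_fingerprint(m$canonical_form, params$molecular_fp_type)
}

# Reaction difference fingerprint: stoichiometry-weighted sum of product
# molecule fingerprints minus the reactant sum. Reagents are excluded, in
# line with the reactant/product identity layer.
reaction_fingerprint <- function(ce, params) {
  side_sum <- function(role) {
    uids <- ce$role_map[[role]]
    counts <- ce$stoichiometry[[role]]
    acc <- NULL
    for (u in uids) {
      fp <- smiles_fingerprint(ce$molecules[[u]]$canonical_form,
                               params$molecular_fp_type)
      fp <- fp * as.integer(counts[[u]])
      acc <- if (is.null(acc)) fp else acc + fp
    }
    acc
  }
  r <- side_sum("reactant")
  p <- side_sum("product")
  if (params$reaction_fp_type == "difference") {
    d <- p - r
    # positive/negative split keeps the vector non-negative so the
    # min/max Tanimoto below stays in [0, 1]
    c(pmax(d, 0L), pmax(-d, 0L))
  } else {
    c(pmin(r, 1L), pmin(p, 1L))
  }
}

node_fingerprint <- function(node, params) {
  key <- paste0("nfp\r", params$molecular_fp_type, "\r",
                params$reaction_fp_type, "\r", node$uid)
  cache_get_or(key, function() {
    if (node$kind == "molecule") {
      molecule_fingerprint(node, params)
    } else {
      reaction_fingerprint(node, params)
    }
  })
}

# generalized (min/max) Tanimoto and Dice for non-negative count vectors;
# reduces to the usual bit-vector form on 0/1 input
vector_similarity <- function(x, y, metric) {
  smin <- sum(pmin(x, y))
  if (metric == "tanimoto") {
    smax <- sum(pmax(x, y))
    if (smax == 0) return(1)
    smin / smax
  } else {
    tot <- sum(x) + sum(y)
    if (tot == 0) return(1)
    2 * smin / tot
  }
}

#' Chemical similarity between two nodes of the same kind
#'
#' Fingerprint similarity between two molecules or two chemical equations.
#' Symmetric, bounded in \[0, 1\], and exactly 1 for uid-equal inputs.
#'
#' @param a,b Two [molecule][canonicalize_molecule()] objects or two
#'   [chemical_equation][build_chemical_equation()] objects.
#' @param params A [fingerprint_params()] bundle.
#' @return Similarity in \[0, 1\].
#' @export
#' @examples
#' m1 <- canonicalize_molecule("CCO")
#' m2 <- canonicalize_molecule("CCCO")
#' chemical_similarity(m1, m2)
chemical_similarity <- function(a, b, params = fingerprint_params()) {
  if (!inherits(a, "synkit_node") || !inherits(b, "synkit_node")) {
    stop_synkit("type_mismatch",
                "similarity is defined for molecule/chemical_equation objects")
  }
  if (node_kind(a) != node_kind(b)) {
    stop_synkit("type_mismatch",
                "cannot compare a ", node_kind(a), " with a ", node_kind(b))
  }
  if (identical(a$uid, b$uid)) return(1)
  vector_similarity(node_fingerprint(a, params), node_fingerprint(b, params),
                    params$similarity_metric)
}
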