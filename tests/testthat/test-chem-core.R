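test_that("molecule uids are canonical: writing variants collapse, invalid input errors", {
  expect_identical(canonicalize_molecule("OCC")$uid,
                   canonicalize_molecule("CCO")$uid)
  expect_identical(canonicalize_molecule("C1=CC=CC=C1")$uid,
                   canonicalize_molecule("c1ccccc1")$uid)
  # canonicalization is a fixed point
  m <- canonicalize_molecule("OC(C)CC")
  expect_identical(canonicalize_molecule(m$canonical_form)$uid, m$uid)
  expect_identical(canonicalize_molecule(m$canonical_form)$canonical_form,
                   m$canonical_form)
  for (bad in c("C(", "C1CC", "", "C)O", "Xx")) {
    expect_error(canonicalize_molecule(bad), class = "synkit_invalid_structure")
  }
  # the offending string is named in the message
  expect_error(canonicalize_molecule("C("), regexp = "C\\(")
})

test_that("identity policies: stereoisomers split under isomeric SMILES, merge under no-stereo and coarser policies never split", {
  s1 <- "C[C@H](O)CC"
  s2 <- "C[C@@H](O)CC"
  expect_false(canonicalize_molecule(s1)$uid == canonicalize_molecule(s2)$uid)
  expect_identical(
    canonicalize_molecule(s1, "canonical-smiles-no-stereo")$uid,
    canonicalize_molecule(s2, "canonical-smiles-no-stereo")$uid
  )
  ik <- canonicalize_molecule("CCO", "inchikey")
  expect_match(ik$identity_string, "^[A-Z]{14}-[A-Z]{10}-[A-Z]$")
  # uid-equal under the fine policy stays uid-equal under the coarse ones
  for (s in c("CCO", "NCCO", s1, "c1ccccc1")) {
    variants <- c(s, paste(rev(strsplit(s, "")[[1]]), collapse = ""))
    variants <- variants[vapply(variants, synkit:::smiles_is_valid, TRUE)]
    for (pol in identity_policies()) {
      uids <- vapply(variants, function(v) {
        canonicalize_molecule(v, pol)$uid
      }, "")
      expect_length(unique(uids), 1L)
    }
  }
})

test_that("chemical equation roles: agents become reagents, spectators are reassigned, identity ignores order and reagents", {
  ce <- build_chemical_equation("CCO.CC(=O)O>>CC(=O)OCC.O")
  expect_length(ce$role_map$reactant, 2L)
  expect_length(ce$role_map$product, 2L)
  expect_length(ce$role_map$reagent, 0L)

  with_agent <- build_chemical_equation("CC(=O)O.CCO>[H+]>CC(=O)OCC.O")
  expect_identical(with_agent$uid, ce$uid)
  expect_length(with_agent$role_map$reagent, 1L)

  permuted <- build_chemical_equation("CC(=O)O.CCO>>O.CC(=O)OCC")
  expect_identical(permuted$uid, ce$uid)

  # a molecule present verbatim on both sides is a spectator -> reagent
  spectator <- build_chemical_equation("CCO.CC>>CC.CCOC")
  expect_identical(spectator$role_map$reagent,
                   canonicalize_molecule("CC")$uid)
  expect_length(spectator$role_map$reactant, 1L)

  expect_error(build_chemical_equation("CCO>>CCO"),
               class = "synkit_malformed_reaction")
  expect_error(build_chemical_equation("CCO>>"),
               class = "synkit_malformed_reaction")
  expect_error(build_chemical_equation(">>CCO"),
               class = "synkit_malformed_reaction")
})

test_that("equation uid is invariant under random permutations and reagent additions", {
  alphabet <- default_molecule_alphabet()
  withr::with_seed(42, {
    for (i in 1:30) {
      reactants <- sample(alphabet, sample(1:3, 1))
      products <- sample(setdiff(alphabet, reactants), sample(1:2, 1))
      base <- build_chemical_equation(
        permuted_reaction_writing(reactants, products)
      )
      again <- build_chemical_equation(
        permuted_reaction_writing(
          reactants, products,
          reagents = sample(alphabet, sample(0:2, 1))
        )
      )
      expect_identical(again$uid, base$uid)
    }
  })
})

test_that("stoichiometry records duplicates without entering the identity", {
  ce <- build_chemical_equation("CCO.CCO.NC>>NCCOCCO")
  single <- build_chemical_equation("CCO.NC>>NCCOCCO")
  uid_etoh <- canonicalize_molecule("CCO")$uid
  expect_identical(unname(ce$stoichiometry$reactant[uid_etoh]), 2L)
  expect_identical(ce$uid, single$uid)
})

test_that("chemical similarity matches an independent fingerprint computation and honors the metric contracts", {
  m1 <- canonicalize_molecule("CCO")
  m2 <- canonicalize_molecule("CCCO")
  s <- chemical_similarity(m1, m2)
  # independent oracle: fingerprints straight from the chemistry backend
  # and the Tanimoto ratio |a&b|/|a|b| computed by hand, bypassing the
  # package's similarity code
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(c(a = "CCO", b = "CCCO")))
  fp <- ChemmineR::as.matrix(ChemmineR::fingerprintOB(sdf, "ECFP4"))
  tan <- sum(fp[1, ] & fp[2, ]) / sum(fp[1, ] | fp[2, ])
  expect_equal(s, tan)
  expect_gt(s, 0)
  expect_lt(s, 1)
  expect_identical(chemical_similarity(m1, m1), 1)
  expect_equal(chemical_similarity(m2, m1), s)

  ce <- build_chemical_equation("CCO.CC(=O)O>>CC(=O)OCC.O")
  expect_error(chemical_similarity(m1, ce), class = "synkit_type_mismatch")

  # reagent-only differences do not move reaction similarity off 1
  ce2 <- build_chemical_equation("CCO.CC(=O)O>[H+]>CC(=O)OCC.O")
  expect_identical(chemical_similarity(ce, ce2), 1)
})

test_that("similarity is symmetric and bounded on random molecule pairs", {
  alphabet <- default_molecule_alphabet()
  withr::with_seed(7, {
    for (i in 1:15) {
      pair <- sample(alphabet, 2)
      a <- canonicalize_molecule(pair[1])
      b <- canonicalize_molecule(pair[2])
      s_ab <- chemical_similarity(a, b)
      expect_gte(s_ab, 0)
      expect_lte(s_ab, 1)
      expect_equal(chemical_similarity(b, a), s_ab)
    }
  })
})
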