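test_that("feature assignment follows the four-type rules", {
  eth <- parse_smiles("CCO")
  f <- assign_features(eth)
  expect_equal(f[[1]], "H")            # terminal CH3, no N/O neighbor
  expect_equal(f[[2]], character(0))   # C bonded to O: not hydrophobic
  expect_equal(f[[3]], c("D", "A"))    # hydroxyl O

  benz <- assign_features(parse_smiles("c1ccccc1"))
  expect_true(all(vapply(benz, identical, logical(1), "R")))

  pyr <- assign_features(parse_smiles("c1ccncc1"))
  expect_equal(pyr[[4]], c("A", "R"))  # ring N: acceptor, no H, aromatic

  # positively charged N is not an acceptor but still donates its H
  amm <- assign_features(parse_smiles("C[NH3+]"))
  expect_equal(amm[[2]], "D")

  # halogens and sulfur are hydrophobic
  hal <- assign_features(parse_smiles("ClCS"))
  expect_true("H" %in% hal[[1]])
  expect_true("H" %in% hal[[3]])
})

test_that("FPD histograms count feature pairs at topological distances", {
  benz <- parse_smiles("c1ccccc1")
  fpd <- compute_fpd(benz)
  expect_equal(unname(fpd$raw["RR", 1:3]), c(6, 6, 3))
  expect_equal(sum(fpd$raw) - sum(fpd$raw["RR", ]), 0)
  expect_equal(sum(fpd$norm["RR", ]), 1)

  # ethane-1,2-diol: two D+A oxygens at distance 3; same-atom (distance-0)
  # D/A pairings are excluded
  diol <- compute_fpd(parse_smiles("OCCO"))
  expect_equal(unname(diol$raw["DD", 3]), 1)
  expect_equal(unname(diol$raw["AA", 3]), 1)
  expect_equal(unname(diol$raw["DA", 3]), 2)
  expect_equal(sum(diol$raw), 4)

  # featureless molecule: all zero, normalized rows stay all-zero
  none <- compute_fpd(parse_smiles("[SiH4]"))
  expect_true(all(none$raw == 0))
  expect_true(all(none$norm == 0))

  # distances beyond 10 bonds accumulate in the last bin
  chain <- parse_smiles(paste0("OC", strrep("C", 11), "CO"))
  fc <- compute_fpd(chain)
  expect_gt(fc$raw["DD", 10], 0)
})

test_that("SHED entropies match a direct entropy computation", {
  benz <- parse_smiles("c1ccccc1")
  shed <- compute_shed(compute_fpd(benz))
  expect_equal(unname(unclass(shed)["RR"]), oracle_entropy(c(6, 6, 3)))
  expect_equal(unname(unclass(shed)["DD"]), 0)
  expect_true(all(unclass(shed) >= 0 & unclass(shed) <= log(10) + 1e-12))

  # single-populated-bin distribution has zero entropy
  diol <- compute_shed(compute_fpd(parse_smiles("OCCO")))
  expect_equal(unname(unclass(diol)["DD"]), 0)

  for (m in random_molecules(20, seed = 401)) {
    fpd <- compute_fpd(m)
    shed <- unclass(compute_shed(fpd))
    for (pn in rownames(fpd$raw)) {
      expect_equal(unname(shed[pn]), oracle_entropy(fpd$raw[pn, ]),
                   info = paste(m$id, pn))
    }
  }
})

test_that("PHRAG fragments are canonical feature-labeled paths", {
  # methane: no feature pairs at all
  expect_equal(compute_phrag(parse_smiles("C"))$total_count, 0L)

  # hydroquinone: the two para oxygens are 5 bonds apart through 4 aromatic
  # interiors -> fragment DRRRRD (among the D/A endpoint combinations)
  hq <- compute_phrag(parse_smiles("Oc1ccc(O)cc1"))
  expect_true("DRRRRD" %in% names(hq$fragments))
  expect_true("ARRRRA" %in% names(hq$fragments))
  expect_equal(hq$total_count, sum(hq$fragments))

  # fragments are direction-canonical: string <= its label-wise reversal
  for (m in random_molecules(15, seed = 402)) {
    ph <- compute_phrag(m)
    expect_equal(ph$total_count, sum(ph$fragments), info = m$id)
  }

  # determinism
  m <- parse_smiles("O=C1CC(c2ccccc2)Oc2ccccc21")
  expect_identical(compute_phrag(m)$fragments, compute_phrag(m)$fragments)
})

test_that("descriptors are invariant to atom input order", {
  withr::with_seed(403, {
    for (m in random_molecules(12, seed = 404)) {
      perm <- sample(n_atoms(m))
      mp <- permute_molecule(m, perm)
      d1 <- build_descriptors(m)
      d2 <- build_descriptors(mp)
      expect_identical(d1$phrag$fragments, d2$phrag$fragments, info = m$id)
      expect_equal(d1$fpd$raw, d2$fpd$raw, info = m$id)
      expect_equal(unclass(d1$shed), unclass(d2$shed), info = m$id)
    }
  })
})

test_that("SHED inside build_descriptors is consistent with compute chain", {
  for (m in random_molecules(10, seed = 405)) {
    d <- build_descriptors(m)
    expect_identical(unclass(d$shed),
                     unclass(compute_shed(compute_fpd(m))), info = m$id)
  }
})

test_that("adding a feature-bearing atom never decreases PHRAG support", {
  withr::with_seed(406, {
    for (m in random_molecules(10, seed = 407)) {
      before <- compute_phrag(m)$total_count
      dec <- targetfish:::.decorate(m)
      if (n_atoms(dec) == n_atoms(m)) next   # nothing eligible to decorate
      after <- compute_phrag(dec)$total_count
      expect_gte(after, before)
    }
  })
})

test_that("descriptor JSON export writes one stable block per molecule", {
  path <- withr::local_tempfile(fileext = ".json")
  mols <- list(parse_smiles("CCO", id = "eth"),
               parse_smiles("Oc1ccccc1", id = "phen"))
  write_descriptors_json(lapply(mols, build_descriptors), path)
  parsed <- jsonlite::read_json(path)
  expect_length(parsed, 2L)
  expect_equal(parsed[[2]]$id, "phen")
  expect_named(parsed[[1]], c("id", "phrag", "fpd", "shed"))
  expect_length(parsed[[1]]$shed, 10L)
})
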