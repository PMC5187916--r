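make_phrag <- function(counts) {
  structure(list(fragments = counts, total_count = sum(counts)),
            class = "phrag_profile")
}

make_fpd <- function(rows) {
  raw <- matrix(0, 10, 10,
                dimnames = list(targetfish:::.PAIR_NAMES, paste0("d", 1:10)))
  for (pn in names(rows)) raw[pn, seq_along(rows[[pn]])] <- rows[[pn]]
  rs <- rowSums(raw); norm <- raw
  norm[rs > 0, ] <- raw[rs > 0, , drop = FALSE] / rs[rs > 0]
  structure(list(raw = raw, norm = norm), class = "fpd_profile")
}

test_that("PHRAG Dice similarity handles overlap and empty profiles", {
  a <- make_phrag(c(x = 2L))
  b <- make_phrag(c(x = 1L, y = 1L))
  expect_equal(phrag_similarity(a, b), 0.5)
  expect_equal(phrag_similarity(a, a), 1)
  expect_equal(phrag_similarity(make_phrag(c(x = 3L)), make_phrag(c(y = 2L))), 0)
  e <- make_phrag(stats::setNames(integer(0), character(0)))
  expect_equal(phrag_similarity(e, e), 1)
  expect_equal(phrag_similarity(e, a), 0)
})

test_that("FPD similarity is mean histogram intersection over active pairs", {
  a <- make_fpd(list(RR = c(1, 0)))
  b <- make_fpd(list(RR = c(0.5, 0.5)))
  expect_equal(fpd_similarity(a, b), 0.5)
  expect_equal(fpd_similarity(a, a), 1)
  # same pair populated, disjoint bins -> 0
  d1 <- make_fpd(list(DA = c(1, 0, 0)))
  d2 <- make_fpd(list(DA = c(0, 0, 1)))
  expect_equal(fpd_similarity(d1, d2), 0)
  # a pair present in exactly one molecule contributes 0 to the mean
  ab <- make_fpd(list(RR = c(1), DA = c(1)))
  expect_equal(fpd_similarity(a, ab), 0.5)
  # both featureless -> indistinguishable
  e <- make_fpd(list())
  expect_equal(fpd_similarity(e, e), 1)
})

test_that("SHED distance is the Euclidean norm", {
  z <- structure(rep(0, 10), class = "shed_vector")
  a <- structure(c(3, 4, rep(0, 8)), class = "shed_vector")
  expect_equal(shed_distance(a, z), 5)
  expect_equal(shed_distance(a, a), 0)
  u <- structure(c(1, rep(0, 9)), class = "shed_vector")
  expect_equal(shed_distance(u, z), 1)
})

test_that("comparators are symmetric and self-comparison is exact", {
  mols <- random_molecules(12, seed = 501)
  ds <- lapply(mols, build_descriptors)
  for (i in seq(1, length(ds) - 1, by = 2)) {
    a <- ds[[i]]; b <- ds[[i + 1]]
    expect_equal(phrag_similarity(a$phrag, b$phrag),
                 phrag_similarity(b$phrag, a$phrag))
    expect_equal(fpd_similarity(a$fpd, b$fpd), fpd_similarity(b$fpd, a$fpd))
    expect_equal(shed_distance(a$shed, b$shed), shed_distance(b$shed, a$shed))
    expect_equal(phrag_similarity(a$phrag, a$phrag), 1)
    expect_equal(fpd_similarity(a$fpd, a$fpd), 1)
    expect_equal(shed_distance(a$shed, a$shed), 0)
    expect_true(phrag_similarity(a$phrag, b$phrag) >= 0 &&
                phrag_similarity(a$phrag, b$phrag) <= 1)
    expect_true(fpd_similarity(a$fpd, b$fpd) >= 0 &&
                fpd_similarity(a$fpd, b$fpd) <= 1)
  }
})

test_that("find_neighbors flags the applicability domain correctly", {
  gen <- generate_library(library_spec(n_targets = 2, series_per_target = 1,
                                       analogs_per_series = 5, seed = 11))
  lib <- gen$library
  # a query identical to a library molecule is a perfect passing hit
  self <- build_descriptors(lib$molecules[[1]])
  hits <- find_neighbors(self, lib)
  top <- hits[hits$ref_id == names(lib$molecules)[1], ]
  expect_equal(top$phrag_sim, 1)
  expect_equal(top$fpd_sim, 1)
  expect_equal(top$shed_dist, 0)
  expect_true(top$passes)
  # hits cover the whole library, sorted by descending phrag_sim
  expect_equal(nrow(hits), length(lib$molecules))
  expect_true(!is.unsorted(rev(hits$phrag_sim)))
  # pass flag is exactly the AND of the three criteria
  cfg <- threshold_config()
  expect_equal(hits$passes,
               hits$phrag_sim >= cfg$phrag_min &
               hits$fpd_sim >= cfg$fpd_min &
               hits$shed_dist <= cfg$shed_max)
})

test_that("a feature-rich query finds no neighbors among featureless ones", {
  recs <- data.frame(
    ref_id = c("N1", "N2"), inchikey = "",
    smiles = c("CC(C)C", "CCC(C)C"),   # pure hydrocarbons: H features only
    uniprot = "T0001", target_name = "t", activity_type = "pIC50",
    pact = 5, source_db = "SYNTH", functional_class = "EC",
    stringsAsFactors = FALSE)
  lib <- annotated_library(recs)
  q <- build_descriptors(parse_smiles("Nc1ccc(O)cc1O", id = "rich"))
  hits <- find_neighbors(q, lib)
  expect_false(any(hits$passes))
})

test_that("relaxing thresholds never removes a passing hit", {
  gen <- generate_library(library_spec(n_targets = 2, series_per_target = 1,
                                       analogs_per_series = 4, seed = 13))
  q <- generate_query_analogs(gen$library, gen$truth, n_queries = 5,
                              seed = 14)
  strict <- threshold_config()
  relaxed <- threshold_config(phrag_min = 0.5, fpd_min = 0.6, shed_max = 1.5)
  for (qm in q$molecules) {
    ds <- build_descriptors(qm)
    h1 <- find_neighbors(ds, gen$library, strict)
    h2 <- find_neighbors(ds, gen$library, relaxed)
    expect_true(all(h1$ref_id[h1$passes] %in% h2$ref_id[h2$passes]))
  }
})

test_that("find_neighbors agrees with a brute-force comparator", {
  gen <- generate_library(library_spec(n_targets = 2, series_per_target = 2,
                                       analogs_per_series = 5, seed = 15))
  lib <- gen$library
  q <- generate_query_analogs(lib, gen$truth, n_queries = 3, seed = 16)
  cfg <- threshold_config()
  for (qm in q$molecules) {
    ds <- build_descriptors(qm)
    hits <- find_neighbors(ds, lib, cfg)
    # brute force: Dice from raw multisets, intersection from raw
    # histograms, Euclidean from per-pair entropies, all via the oracles
    for (rid in names(lib$molecules)) {
      rd <- build_descriptors(lib$molecules[[rid]])
      exp_phrag <- oracle_dice(ds$phrag$fragments, rd$phrag$fragments)
      h <- hits[hits$ref_id == rid, ]
      expect_equal(h$phrag_sim, exp_phrag, info = rid)
      exp_shed <- sqrt(sum((vapply(rownames(ds$fpd$raw), function(pn)
        oracle_entropy(ds$fpd$raw[pn, ]), numeric(1)) -
        vapply(rownames(rd$fpd$raw), function(pn)
          oracle_entropy(rd$fpd$raw[pn, ]), numeric(1)))^2))
      expect_equal(h$shed_dist, exp_shed, info = rid)
      expect_equal(h$passes,
                   h$phrag_sim >= cfg$phrag_min && h$fpd_sim >= cfg$fpd_min &&
                   h$shed_dist <= cfg$shed_max, info = rid)
    }
  }
})
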