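test_that("library generation is seeded, counted, and annotated", {
  spec <- library_spec(n_targets = 2, series_per_target = 1,
                       analogs_per_series = 5, seed = 31)
  gen <- generate_library(spec)
  expect_equal(nrow(gen$library$records), 10L)
  expect_equal(length(unique(gen$library$records$uniprot)), 2L)
  expect_equal(nrow(gen$truth), 10L)
  # identical seed -> byte-identical CSV
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_library_csv(generate_library(spec)$library, p1,
                    header_comments = paste0("seed=", spec$seed))
  write_library_csv(generate_library(spec)$library, p2,
                    header_comments = paste0("seed=", spec$seed))
  expect_identical(readLines(p1), readLines(p2))
  # different seed -> different structures
  gen2 <- generate_library(library_spec(n_targets = 2, series_per_target = 1,
                                        analogs_per_series = 5, seed = 32))
  expect_false(identical(gen$library$records$smiles,
                         gen2$library$records$smiles))
})

test_that("zero affinity spread pins every analog at the target mean", {
  spec <- library_spec(n_targets = 2, series_per_target = 1,
                       analogs_per_series = 4, affinity_mean = c(5, 8),
                       affinity_sd = 0, seed = 33)
  gen <- generate_library(spec)
  pacts <- split(gen$library$records$pact, gen$library$records$uniprot)
  expect_true(all(pacts[["T0001"]] == 5))
  expect_true(all(pacts[["T0002"]] == 8))
})

test_that("library_spec validates its inputs", {
  expect_error(library_spec(scaffolds = character(0)),
               class = "targetfish_spec_error")
  expect_error(library_spec(n_targets = 10, series_per_target = 3),
               class = "targetfish_spec_error")
})

test_that("query analogs are fresh decorations with recorded truth", {
  gen <- generate_library(library_spec(n_targets = 2, series_per_target = 1,
                                       analogs_per_series = 5, seed = 34))
  expect_equal(nrow(generate_query_analogs(gen$library, gen$truth,
                                           n_queries = 0, seed = 1)$truth), 0L)
  q <- generate_query_analogs(gen$library, gen$truth, n_queries = 8,
                              seed = 35)
  expect_length(q$molecules, 8L)
  expect_false(any(names(q$molecules) %in% names(gen$library$molecules)))
  # truth rows point at real library members and their targets
  expect_true(all(q$truth$source_ref %in% gen$truth$ref_id))
  expect_equal(q$truth$uniprot,
               gen$truth$uniprot[match(q$truth$source_ref, gen$truth$ref_id)])
  # reproducible per seed
  q2 <- generate_query_analogs(gen$library, gen$truth, n_queries = 8,
                               seed = 35)
  expect_identical(vapply(q$molecules, mol_to_smiles, character(1)),
                   vapply(q2$molecules, mol_to_smiles, character(1)))
  # each query has exactly one more heavy atom than its source
  for (i in seq_len(nrow(q$truth))) {
    expect_equal(n_atoms(q$molecules[[q$truth$query_id[i]]]),
                 n_atoms(gen$library$molecules[[q$truth$source_ref[i]]]) + 1L)
  }
})

test_that("queries' nearest library compound lies in the planted series", {
  gen <- generate_library(library_spec(seed = 42))
  q <- generate_query_analogs(gen$library, gen$truth, n_queries = 40,
                              seed = 36)
  ldesc <- library_descriptors(gen$library)
  ok <- vapply(seq_len(nrow(q$truth)), function(i) {
    dq <- build_descriptors(q$molecules[[q$truth$query_id[i]]])
    sims <- vapply(names(ldesc), function(r)
      phrag_similarity(dq$phrag, ldesc[[r]]$phrag), numeric(1))
    best <- names(ldesc)[which.max(sims)]
    gen$truth$uniprot[match(best, gen$truth$ref_id)] == q$truth$uniprot[i]
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("noise-free plates hit the 4PL asymptotes and midpoint exactly", {
  sp <- plate_spec(ic50 = 1e-6, concentrations = c(1e-12, 1e-6, 1),
                   noise_sd_inhibition = 0, noise_sd_rfu = 0,
                   replicates = 1, seed = 37)
  plate <- simulate_plate(sp)
  times <- seq(0, 30, 5)
  ec <- as.numeric(plate[plate$role == "EC", paste0("t", times)][1, ])
  slope_ec <- kinetic_slope(times, ec)
  inh <- vapply(which(plate$role == "S"), function(i) {
    relative_inhibition(
      slope_ec, kinetic_slope(times, as.numeric(plate[i, paste0("t", times)])))
  }, numeric(1))
  expect_equal(inh[2], 50)            # c = ic50 -> midpoint
  # far ends of the curve sit at the model values, near the asymptotes
  expect_equal(inh[1], four_pl(1e-12, 0, 100, 1, 1e-6))
  expect_equal(inh[3], four_pl(1, 0, 100, 1, 1e-6))
  expect_lt(inh[1], 0.001)
  expect_gt(inh[3], 99.999)
})

test_that("plate simulation is byte-reproducible per seed", {
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_plate_csv(simulate_plate(plate_spec(ic50 = 5e-7, seed = 38)), p1)
  write_plate_csv(simulate_plate(plate_spec(ic50 = 5e-7, seed = 38)), p2)
  expect_identical(readLines(p1), readLines(p2))
  p3 <- withr::local_tempfile(fileext = ".csv")
  write_plate_csv(simulate_plate(plate_spec(ic50 = 5e-7, seed = 39)), p3)
  expect_false(identical(readLines(p1), readLines(p3)))
})
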