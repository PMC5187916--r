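#!/usr/bin/env Rscript
# Stage 1: generate the study inputs — a synthetic annotated
# compound-target library with planted analog series, and query compounds
# that are fresh analogs of library members (so every query has a known
# true target). Writes results/library.csv, results/library_truth.csv,
# results/queries.smi, results/query_truth.csv.

suppressPackageStartupMessages(library(targetfish))

seed <- 42
dir.create("results", showWarnings = FALSE)

spec <- library_spec(seed = seed)   # 4 targets x 2 series x 6 analogs
gen <- generate_library(spec)
queries <- generate_query_analogs(gen$library, gen$truth, n_queries = 100,
                                  seed = seed + 1)

write_library_csv(gen$library, "results/library.csv",
                  header_comments = paste0("seed=", seed))
write.csv(gen$truth, "results/library_truth.csv", row.names = FALSE)
write_smiles_file(queries$molecules, "results/queries.smi",
                  header_comments = paste0("seed=", seed + 1))
write.csv(queries$truth, "results/query_truth.csv", row.names = FALSE)

message(sprintf(
  "library: %d compounds on %d targets; %d query analogs written",
  length(gen$library$molecules), length(unique(gen$truth$uniprot)),
  length(queries$molecules)))
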