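#!/usr/bin/env Rscript
# Stage 2: compute the three 2-D descriptor families (PHRAG fragment
# multisets, feature-pair distance distributions, Shannon entropies) for
# every query compound. Writes results/descriptors.json.

suppressPackageStartupMessages(library(targetfish))

queries <- read_smiles_file("results/queries.smi")
descriptors <- lapply(queries, build_descriptors)
write_descriptors_json(descriptors, "results/descriptors.json")

n_frag <- vapply(descriptors, function(d) d$phrag$total_count, numeric(1))
message(sprintf(
  "descriptors for %d queries; PHRAG fragments per molecule: %d-%d (median %d)",
  length(descriptors), min(n_frag), max(n_frag), as.integer(median(n_frag))))
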