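# Synthetic inputs for the whole pipeline: an annotated compound-target
# library built from planted analog series (seeded decoration edits of
# drug-like scaffolds), query compounds generated as fresh analogs of
# library members (so each query has a known true target), and simulated
# fluorescence assay plates with Gaussian noise.

#' Default scaffold set for synthetic analog series
#'
#' Twelve elaborated natural-product-like scaffolds (prenylated and
#' alkylated polyphenols, fused N-heterocycles with polar handles),
#' 26-32 heavy atoms each. Each scaffold populates all four pharmacophore
#' classes redundantly — several hydroxyl/amine donors spread over the
#' structure, carbonyl/ether acceptors, an aliphatic hydrophobic chain, and
#' aromatic rings — so that a single decoration edit perturbs the
#' feature-pair distributions instead of creating them from nothing, the
#' way one substituent change behaves within a real congeneric series.
#' Distinct scaffolds remain well separated in descriptor space.
#'
#' @return Named character vector of SMILES.
#' @export
default_scaffolds <- function() {
  c(
    lavandulyl_flavanone =
      "CC(C)=CCC(C(=C)C)c1c(O)cc(O)c(C2CC(=O)c3c(O)cc(O)cc3O2)c1O",
    prenyl_flavanone =
      "CC(C)=CCc1c(O)cc(O)c(C2CC(=O)c3c(O)cc(O)cc3O2)c1CC=C(C)C",
    prenyl_flavone =
      "CC(C)=CCc1c(O)cc(O)c2c(=O)c(CC(C)C)c(-c3cc(O)c(O)cc3O)oc12",
    prenyl_chalcone =
      "CC(C)=CCc1cc(C(=O)C=Cc2cc(O)c(O)cc2CC=C(C)C)c(O)cc1O",
    geranyl_coumarin =
      "CC(CCC=C(C)C)c1c(O)c(O)c2c(CC(C)C)cc(=O)oc2c1OC(C)CO",
    prenyl_xanthone =
      "CC(C)=CCc1c(O)cc2oc3cc(O)c(CC(C)C)c(O)c3c(=O)c2c1O",
    prenyl_isoflavone =
      "CC(C)=CCc1c(O)cc(CC(C)C)c(-c2coc3cc(O)cc(O)c3c2=O)c1O",
    lipophilic_indole =
      "CC(C)CCc1c(CCC(N)=O)c2cc(O)c(CC(C)C)c(O)c2c1CC(C)O",
    aryl_piperazinone =
      "CC(C)Cc1cc(CC(C)C)c(C(=O)N2CCN(c3cc(O)c(O)c(O)n3)CC2)cc1O",
    prenyl_benzofuran =
      "CC(C)=CCc1c(O)cc2c(CC(C)C)c(C(=O)NCC(C)O)oc2c1O",
    alkyl_pteridinone =
      "CC(C)CCc1nc2c(=O)[nH]c(NCC(C)O)nc2n1CC(O)C(C)O",
    geranyl_naphthoquinone =
      "CC(CCC=C(C)C)c1cc(O)c2C(=O)C(CC(C)O)=C(NCC(C)C)C(=O)c2c1O"
  )
}

#' Specification of a synthetic annotated library
#'
#' @param n_targets Number of synthetic protein targets (>= 1).
#' @param series_per_target Analog series planted per target.
#' @param analogs_per_series Compounds per series.
#' @param affinity_mean Per-target mean pActivity (recycled/defaulted to an
#'   even spread over 5.5-8, typical lead-like potency).
#' @param affinity_sd Per-target pActivity standard deviation (default 0.4,
#'   within-series spread of a congeneric series).
#' @param scaffolds SMILES pool; each series takes its own scaffold, so at
#'   least `n_targets * series_per_target` are required.
#' @param seed Integer seed governing every random choice.
#' @return A `library_spec` list.
#' @export
library_spec <- function(n_targets = 4, series_per_target = 2,
                         analogs_per_series = 6,
                         affinity_mean = seq(5.5, 8, length.out = n_targets),
                         affinity_sd = 0.4,
                         scaffolds = default_scaffolds(), seed = 42) {
  stopifnot(n_targets >= 1, series_per_target >= 1, analogs_per_series >= 1,
            all(affinity_sd >= 0))
  if (length(scaffolds) == 0L)
    .tf_error("scaffold list is empty", "targetfish_spec_error")
  need <- n_targets * series_per_target
  if (length(scaffolds) < need)
    .tf_error(sprintf("need %d scaffolds (one per series), got %d",
                      need, length(scaffolds)), "targetfish_spec_error")
  structure(list(n_targets = as.integer(n_targets),
                 series_per_target = as.integer(series_per_target),
                 analogs_per_series = as.integer(analogs_per_series),
                 affinity_mean = rep_len(affinity_mean, n_targets),
                 affinity_sd = rep_len(affinity_sd, n_targets),
                 scaffolds = scaffolds, seed = as.integer(seed)),
            class = "library_spec")
}

# one decoration edit: append methyl / hydroxyl / amino at a random carbon
# that still carries a hydrogen
.decorate <- function(mol) {
  eligible <- which(mol$atoms$element == "C" & mol$atoms$implicit_h >= 1L)
  if (length(eligible) == 0L) return(mol)
  atom <- eligible[sample.int(length(eligible), 1L)]
  el <- c("C", "O", "N")[sample.int(3L, 1L)]
  atoms <- mol$atoms
  atoms$implicit_h[atom] <- atoms$implicit_h[atom] - 1L
  atoms <- rbind(atoms, data.frame(element = el, charge = 0L,
                                   aromatic = FALSE,
                                   implicit_h = c(C = 3L, O = 1L, N = 2L)[[el]],
                                   stringsAsFactors = FALSE))
  n <- nrow(atoms)
  bonds <- rbind(mol$bonds, data.frame(a1 = atom, a2 = n, order = 1))
  g <- igraph::add_edges(igraph::make_empty_graph(n = n, directed = FALSE),
                         rbind(bonds$a1, bonds$a2))
  topo <- igraph::distances(g)
  nm <- paste0("a", seq_len(n))
  dimnames(topo) <- list(nm, nm)
  structure(list(id = mol$id, atoms = atoms, bonds = bonds,
                 topo_dist = topo), class = "molecule")
}

#' Generate a synthetic annotated library with planted analog series
#'
#' Each series grows `analogs_per_series` compounds from its scaffold by 1-3
#' seeded decoration edits (methyl/hydroxyl/amino on a random carbon with a
#' free hydrogen); every analog is annotated to its series' target with a
#' pActivity drawn from that target's Normal(mean, sd), activity type pIC50.
#' Fully reproducible per seed.
#'
#' @param spec A [library_spec()].
#' @return list with `library` (an `annotated_library`) and `truth`
#'   (data.frame `ref_id` -> `uniprot`, the planted ground truth).
#' @export
generate_library <- function(spec = library_spec()) {
  stopifnot(inherits(spec, "library_spec"))
  set.seed(spec$seed)
  scaffold_mols <- lapply(spec$scaffolds,
                          function(s) parse_smiles(s, id = s))
  rows <- list(); counter <- 0L
  for (t in seq_len(spec$n_targets)) {
    uniprot <- sprintf("T%04d", t)
    tname <- sprintf("synthetic target %d", t)
    for (s in seq_len(spec$series_per_target)) {
      scaffold <- scaffold_mols[[(t - 1L) * spec$series_per_target + s]]
      for (a in seq_len(spec$analogs_per_series)) {
        counter <- counter + 1L
        m <- scaffold
        for (e in seq_len(sample.int(3L, 1L))) m <- .decorate(m)
        rows[[counter]] <- data.frame(
          ref_id = sprintf("REF%05d", counter),
          inchikey = "",
          smiles = mol_to_smiles(m),
          uniprot = uniprot,
          target_name = tname,
          activity_type = "pIC50",
          pact = stats::rnorm(1L, spec$affinity_mean[t], spec$affinity_sd[t]),
          source_db = "SYNTH",
          functional_class = "EC",
          stringsAsFactors = FALSE)
      }
    }
  }
  records <- do.call(rbind, rows)
  lib <- annotated_library(records)
  truth <- records[, c("ref_id", "uniprot")]
  rownames(truth) <- NULL
  list(library = lib, truth = truth)
}

#' Generate query analogs with known true targets
#'
#' Each query is one fresh decoration edit of a randomly chosen library
#' compound; the truth table records which compound it came from and hence
#' its planted target. Query IDs never collide with library ref IDs.
#'
#' @param lib The `annotated_library` from [generate_library()].
#' @param truth Its truth table.
#' @param n_queries Number of queries (0 allowed).
#' @param seed Integer seed.
#' @return list with `molecules` (named list of `molecule`) and `truth`
#'   (data.frame `query_id`, `source_ref`, `uniprot`).
#' @export
generate_query_analogs <- function(lib, truth, n_queries = 100, seed = 1) {
  stopifnot(inherits(lib, "annotated_library"), n_queries >= 0)
  set.seed(seed)
  mols <- list()
  rows <- list()
  ref_ids <- names(lib$molecules)
  for (q in seq_len(n_queries)) {
    src <- ref_ids[sample.int(length(ref_ids), 1L)]
    qid <- sprintf("Q%04d", q)
    m <- .decorate(lib$molecules[[src]])
    m$id <- qid
    mols[[qid]] <- m
    rows[[q]] <- data.frame(
      query_id = qid, source_ref = src,
      uniprot = truth$uniprot[match(src, truth$ref_id)],
      stringsAsFactors = FALSE)
  }
  list(molecules = mols,
       truth = if (n_queries > 0L) do.call(rbind, rows) else
         data.frame(query_id = character(0), source_ref = character(0),
                    uniprot = character(0), stringsAsFactors = FALSE))
}

#' Write query molecules to a .smi file
#'
#' @param molecules Named list of `molecule` objects.
#' @param path Output path.
#' @param header_comments Optional leading `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_smiles_file <- function(molecules, path, header_comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header_comments) writeLines(paste0("# ", h), con)
  for (id in names(molecules))
    writeLines(paste(mol_to_smiles(molecules[[id]]), id, sep = "\t"), con)
  invisible(path)
}

#' Specification of a simulated assay plate
#'
#' @param ic50 True IC50 (molar).
#' @param concentrations Tested concentrations (molar); default 7 log-spaced
#'   decades from 1e-9 to 1e-3 M.
#' @param bottom,top,hill True 4PL parameters (default 0%, 100%, 1).
#' @param slope_ec_mean Mean enzyme-control slope (RFU/min, default 100).
#' @param noise_sd_inhibition Gaussian noise on percent inhibition
#'   (default 3).
#' @param noise_sd_rfu Gaussian noise on the enzyme-control slope
#'   (RFU/min, default 2).
#' @param replicates Sample wells per concentration (default 2).
#' @param n_ec Enzyme-control wells (default 3).
#' @param seed Integer seed.
#' @return A `plate_spec` list.
#' @export
plate_spec <- function(ic50, concentrations = 10^seq(-9, -3),
                       bottom = 0, top = 100, hill = 1,
                       slope_ec_mean = 100, noise_sd_inhibition = 3,
                       noise_sd_rfu = 2, replicates = 2, n_ec = 3,
                       seed = 1) {
  stopifnot(ic50 > 0, all(concentrations > 0), noise_sd_inhibition >= 0,
            noise_sd_rfu >= 0, replicates >= 1, n_ec >= 1)
  structure(list(ic50 = ic50, concentrations = sort(concentrations),
                 bottom = bottom, top = top, hill = hill,
                 slope_ec_mean = slope_ec_mean,
                 noise_sd_inhibition = noise_sd_inhibition,
                 noise_sd_rfu = noise_sd_rfu,
                 replicates = as.integer(replicates),
                 n_ec = as.integer(n_ec), seed = as.integer(seed)),
            class = "plate_spec")
}

#' Simulate an assay plate of kinetic fluorescence traces
#'
#' Enzyme-control wells get linear RFU ramps with slope
#' `slope_ec_mean + N(0, noise_sd_rfu)`; each sample well's slope is
#' `slope_ec_mean * (1 - inhibition/100)` where inhibition is the true 4PL
#' value at its concentration plus `N(0, noise_sd_inhibition)`; one blank
#' well is flat. Traces are sampled every 5 min from 0 to 30 min (covering
#' the 25-30 min slope window). Reproducible per seed.
#'
#' @param spec A [plate_spec()].
#' @return data.frame with `well_id`, `role` (`EC`/`S`/`blank`),
#'   `concentration_M`, and RFU columns `t0` ... `t30`; the spec is attached
#'   as attribute `"spec"`.
#' @export
simulate_plate <- function(spec) {
  stopifnot(inherits(spec, "plate_spec"))
  set.seed(spec$seed)
  times <- seq(0, 30, by = 5)
  tcols <- paste0("t", times)
  make_row <- function(well_id, role, conc, slope) {
    r <- data.frame(well_id = well_id, role = role, concentration_M = conc,
                    stringsAsFactors = FALSE)
    r[tcols] <- as.list(slope * times)
    r
  }
  rows <- list()
  for (k in seq_len(spec$n_ec)) {
    slope <- spec$slope_ec_mean + stats::rnorm(1L, 0, spec$noise_sd_rfu)
    rows[[length(rows) + 1L]] <- make_row(sprintf("EC%d", k), "EC",
                                          NA_real_, slope)
  }
  rows[[length(rows) + 1L]] <- make_row("BL1", "blank", NA_real_, 0)
  w <- 0L
  for (conc in spec$concentrations) {
    for (r in seq_len(spec$replicates)) {
      w <- w + 1L
      inh <- four_pl(conc, spec$bottom, spec$top, spec$hill, spec$ic50) +
        stats::rnorm(1L, 0, spec$noise_sd_inhibition)
      rows[[length(rows) + 1L]] <- make_row(
        sprintf("S%03d", w), "S", conc,
        spec$slope_ec_mean * (1 - inh / 100))
    }
  }
  plate <- do.call(rbind, rows)
  rownames(plate) <- NULL
  attr(plate, "spec") <- spec
  plate
}

#' Write a simulated plate to CSV
#'
#' @param plate data.frame from [simulate_plate()].
#' @param path Output path.
#' @param header_comments Optional leading `#` comment lines (the seed is
#'   recorded automatically when the plate carries its spec).
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(plate, path, header_comments = NULL) {
  spec <- attr(plate, "spec")
  if (!is.null(spec) && !any(grepl("^seed=", header_comments)))
    header_comments <- c(header_comments, paste0("seed=", spec$seed))
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header_comments) writeLines(paste0("# ", h), con)
  utils::write.csv(plate, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a plate CSV
#'
#' @param path CSV path (leading `#` comment lines are skipped).
#' @return Plate data.frame suitable for [analyze_plate()].
#' @export
read_plate_csv <- function(path) {
  if (!file.exists(path))
    .tf_error(paste0("no such file: ", path), "targetfish_io_error")
  utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                  check.names = FALSE)
}
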