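# Independent brute-force oracles and small fixture builders shared by the
# test files. Oracles deliberately re-derive quantities from first
# principles (direct formula evaluation, exhaustive enumeration) rather
# than calling the implementation paths they check.

# direct evaluation of the IDW formula F = sum(d^-p * f) / sum(d^-p)
oracle_idw <- function(f, d, p) {
  w <- d^(-p)
  sum(w * f) / sum(w)
}

# Shannon entropy in nats of a count vector, by the definition
oracle_entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  if (length(p) == 0) return(0)
  -sum(p * log(p))
}

# multiset Dice coefficient from two named count vectors
oracle_dice <- function(a, b) {
  if (sum(a) == 0 && sum(b) == 0) return(1)
  if (sum(a) == 0 || sum(b) == 0) return(0)
  keys <- union(names(a), names(b))
  ca <- ifelse(keys %in% names(a), a[keys], 0)
  cb <- ifelse(keys %in% names(b), b[keys], 0)
  2 * sum(pmin(ca, cb, na.rm = TRUE)) / (sum(a) + sum(b))
}

# permute the atom order of a molecule, remapping bonds and distances
permute_molecule <- function(mol, perm) {
  inv <- order(perm)   # inv[old] = new position
  atoms <- mol$atoms[perm, , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- data.frame(a1 = inv[mol$bonds$a1], a2 = inv[mol$bonds$a2],
                      order = mol$bonds$order)
  topo <- mol$topo_dist[perm, perm, drop = FALSE]
  nm <- paste0("a", seq_len(nrow(atoms)))
  dimnames(topo) <- list(nm, nm)
  structure(list(id = mol$id, atoms = atoms, bonds = bonds,
                 topo_dist = topo), class = "molecule")
}

# a small pool of parseable SMILES with varied chemistry for property tests
fixture_smiles <- function() {
  c("CCO", "c1ccccc1", "Oc1ccccc1", "c1ccncc1", "OCCO", "CC(=O)O",
    "CC(C)=CCO", "Nc1ccc(O)cc1", "O=C1CC(c2ccccc2)Oc2ccccc21",
    "O=c1cc(-c2ccccc2)oc2ccccc12", "c1ccc2[nH]ccc2c1", "CC(C)Cc1ccccc1",
    "OC(=O)c1ccccc1O", "CSc1ccccc1", "FC(F)(F)c1ccc(N)cc1",
    "Clc1ccc(C(=O)NC)cc1", "CN1CCN(c2ccccn2)CC1", "CC(N)C(=O)O",
    "Oc1ccc2ccccc2c1", "O=c1ccc2ccccc2o1")
}

# random decorated molecules drawn from the fixture pool under a local seed
random_molecules <- function(n, seed) {
  withr::with_seed(seed, {
    pool <- fixture_smiles()
    lapply(seq_len(n), function(i) {
      m <- parse_smiles(pool[[sample.int(length(pool), 1L)]],
                        id = paste0("rnd", i))
      k <- sample.int(3L, 1L) - 1L
      for (e in seq_len(k)) m <- targetfish:::.decorate(m)
      m
    })
  })
}

# a tiny 3-compound, 2-target library for I/O and prediction tests
tiny_library_records <- function() {
  data.frame(
    ref_id = c("AT-5-1", "CMPD-B", "CMPD-C"),
    inchikey = c("FVNFXIPJDHVJGE-REZTVBANSA-N", "", ""),
    smiles = c("CC(C)=CCC(C(=C)C)c1c(O)ccc(C2CC(=O)c3c(O)cc(O)cc3O2)c1O",
               "Oc1ccc2ccccc2c1", "CN1CCN(c2ccccn2)CC1"),
    uniprot = c("P43235", "T0002", "T0002"),
    target_name = c("Cathepsin K", "synthetic target 2",
                    "synthetic target 2"),
    activity_type = c("pIC50", "pIC50", "pKi"),
    pact = c(6.77, 5.2, 7.4),
    source_db = c("ChemblDB, PubChem, Binding DB", "SYNTH", "SYNTH"),
    functional_class = c("EC, FD, PS", "EC", "EC"),
    stringsAsFactors = FALSE)
}
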