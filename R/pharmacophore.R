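# Pharmacophore feature assignment and the three 2-D descriptor families
# used for ligand-based target fishing:
#   PHRAG - multiset of feature-labeled shortest-path fragments,
#   FPD   - per feature pair, histogram of counts over topological distance,
#   SHED  - Shannon entropies (nats) of the normalized FPD histograms.

# feature alphabet, in canonical order: Donor, Acceptor, Hydrophobic, aRomatic
.FEATURES <- c("D", "A", "H", "R")

# the 10 unordered feature pairs, ordered by the alphabet above
.PAIR_NAMES <- c("DD", "DA", "DH", "DR", "AA", "AH", "AR", "HH", "HR", "RR")

.N_DIST_BINS <- 10L   # topological distances > 10 accumulate in bin 10

.pair_name <- function(f1, f2) {
  o <- order(match(c(f1, f2), .FEATURES))
  paste0(c(f1, f2)[o][1L], c(f1, f2)[o][2L])
}

#' Assign pharmacophoric features to every atom
#'
#' The classic four-type alphabet, one set per heavy atom (an atom may carry
#' several features):
#' \describe{
#'   \item{D (donor)}{N or O bearing at least one hydrogen.}
#'   \item{A (acceptor)}{any O; any N that is not positively charged and has
#'     at most 3 heavy-atom neighbors.}
#'   \item{H (hydrophobic)}{non-aromatic carbon with no N/O neighbor; S and
#'     the halogens.}
#'   \item{R (aromatic)}{any atom flagged aromatic. Aromatic carbons are
#'     typed R only — their lipophilic character is carried by the R
#'     channel, not double-counted as H.}
#' }
#'
#' @param mol A `molecule`.
#' @return A list (one element per atom) of character vectors, each a subset
#'   of `c("D", "A", "H", "R")` in that order.
#' @examples
#' assign_features(parse_smiles("CCO"))[[3]]   # hydroxyl O: "D" "A"
#' @export
assign_features <- function(mol) {
  at <- mol$atoms
  n <- nrow(at)
  nbr <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
    nbr[[a]] <- c(nbr[[a]], b)
    nbr[[b]] <- c(nbr[[b]], a)
  }
  lapply(seq_len(n), function(a) {
    el <- at$element[a]
    f <- character(0)
    if (el %in% c("N", "O") && at$implicit_h[a] >= 1L) f <- c(f, "D")
    if (el == "O" ||
        (el == "N" && at$charge[a] <= 0L && length(nbr[[a]]) <= 3L))
      f <- c(f, "A")
    if ((el == "C" && !at$aromatic[a] &&
         !any(at$element[nbr[[a]]] %in% c("N", "O"))) ||
        el %in% c("S", "F", "Cl", "Br", "I"))
      f <- c(f, "H")
    if (at$aromatic[a]) f <- c(f, "R")
    f[order(match(f, .FEATURES))]
  })
}

#' Feature-pair distance distributions (FPD)
#'
#' For every unordered pair of distinct feature-bearing atoms and every
#' combination of features they present, one count is added at their
#' topological distance (bond count, capped at bin 10). Atoms carrying k
#' features contribute to k pairings; same-atom pairs (distance 0) are
#' excluded. Histograms are kept raw and normalized to unit mass.
#'
#' @param mol A `molecule`.
#' @param feats Output of [assign_features()]; computed if missing.
#' @return An `fpd_profile`: list with `raw` and `norm`, both 10 x 10
#'   matrices (feature pairs x distance bins). Rows of `norm` sum to 1 or
#'   are all zero.
#' @export
compute_fpd <- function(mol, feats = assign_features(mol)) {
  raw <- matrix(0, nrow = length(.PAIR_NAMES), ncol = .N_DIST_BINS,
                dimnames = list(.PAIR_NAMES, paste0("d", 1:.N_DIST_BINS)))
  idx <- which(lengths(feats) > 0L)
  if (length(idx) >= 2L) {
    for (ii in seq_along(idx)[-length(idx)]) {
      for (jj in seq((ii + 1L), length(idx))) {
        a <- idx[ii]; b <- idx[jj]
        d <- mol$topo_dist[a, b]
        if (!is.finite(d) || d < 1) next
        bin <- min(as.integer(d), .N_DIST_BINS)
        for (f1 in feats[[a]]) for (f2 in feats[[b]]) {
          pn <- .pair_name(f1, f2)
          raw[pn, bin] <- raw[pn, bin] + 1
        }
      }
    }
  }
  rs <- rowSums(raw)
  norm <- raw
  nz <- rs > 0
  norm[nz, ] <- raw[nz, , drop = FALSE] / rs[nz]
  structure(list(raw = raw, norm = norm), class = "fpd_profile")
}

#' Shannon entropy descriptors (SHED)
#'
#' One entropy per feature pair, computed in nats on the normalized FPD
#' histogram: `H = -sum(p * log(p))` over nonzero bins. An empty
#' distribution scores 0; the maximum over 10 bins is `log(10)`.
#'
#' @param fpd An `fpd_profile` from [compute_fpd()].
#' @return Named numeric vector of length 10 (class `shed_vector`).
#' @export
compute_shed <- function(fpd) {
  stopifnot(inherits(fpd, "fpd_profile"))
  h <- apply(fpd$norm, 1L, function(p) {
    p <- p[p > 0]
    if (length(p) == 0L) 0 else -sum(p * log(p))
  })
  structure(h, class = "shed_vector")
}

#' Pharmacophoric fragments (PHRAG)
#'
#' For every unordered pair of feature-bearing atoms at shortest-path
#' distance 2 to 6 bonds, one fragment string is emitted per choice of
#' feature label at each endpoint: the two endpoint labels flanking the
#' interior atom labels along the path (`.` for featureless interior atoms;
#' multi-feature interior atoms contribute their full sorted label).
#' Among all shortest paths between the pair, the one giving the
#' lexicographically smallest fragment (in either reading direction) is
#' used, making the profile independent of atom input order.
#'
#' @param mol A `molecule`.
#' @param feats Output of [assign_features()]; computed if missing.
#' @return A `phrag_profile`: list with `fragments` (named integer vector,
#'   a multiset) and `total_count`.
#' @export
compute_phrag <- function(mol, feats = assign_features(mol)) {
  idx <- which(lengths(feats) > 0L)
  frags <- character(0)
  interior_label <- vapply(seq_len(n_atoms(mol)), function(a) {
    if (length(feats[[a]]) == 0L) "." else paste(feats[[a]], collapse = "")
  }, character(1))
  if (length(idx) >= 2L) {
    for (ii in seq_along(idx)[-length(idx)]) {
      for (jj in seq((ii + 1L), length(idx))) {
        a <- idx[ii]; b <- idx[jj]
        d <- mol$topo_dist[a, b]
        if (!is.finite(d) || d < 2 || d > 6) next
        paths <- .all_shortest_paths(mol, a, b)
        interiors <- lapply(paths, function(p)
          interior_label[p[-c(1L, length(p))]])
        # one fragment per feature-label choice at each endpoint, with the
        # label staying attached to its own atom; canonical form is the
        # smaller of the fragment and its label-wise reversal, minimized
        # over all shortest paths
        for (f1 in feats[[a]]) for (f2 in feats[[b]]) {
          best <- NULL
          for (interior in interiors) {
            cand1 <- paste0(f1, paste(interior, collapse = ""), f2)
            cand2 <- paste0(f2, paste(rev(interior), collapse = ""), f1)
            cand <- if (cand1 <= cand2) cand1 else cand2
            if (is.null(best) || cand < best) best <- cand
          }
          frags <- c(frags, best)
        }
      }
    }
  }
  tab <- table(frags)
  fragments <- stats::setNames(as.integer(tab), names(tab))
  structure(list(fragments = fragments,
                 total_count = sum(fragments)),
            class = "phrag_profile")
}

# all shortest paths a -> b as integer vectors of atom indices, found by
# backward walking on the distance matrix (predecessor = neighbor one bond
# closer to a)
.all_shortest_paths <- function(mol, a, b) {
  dist_a <- mol$topo_dist[a, ]
  nbr <- vector("list", n_atoms(mol))
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
    nbr[[i]] <- c(nbr[[i]], j)
    nbr[[j]] <- c(nbr[[j]], i)
  }
  walk <- function(v) {
    if (v == a) return(list(a))
    preds <- nbr[[v]][dist_a[nbr[[v]]] == dist_a[v] - 1]
    out <- list()
    for (u in preds) {
      for (p in walk(u)) out <- c(out, list(c(p, v)))
    }
    out
  }
  walk(b)
}

#' Build the full descriptor set for one molecule
#'
#' Convenience wrapper computing features once and all three descriptor
#' families from them.
#'
#' @param mol A `molecule`.
#' @return A `descriptor_set`: list with `id`, `phrag`, `fpd`, `shed`.
#' @export
build_descriptors <- function(mol) {
  feats <- assign_features(mol)
  fpd <- compute_fpd(mol, feats)
  structure(list(id = mol$id,
                 phrag = compute_phrag(mol, feats),
                 fpd = fpd,
                 shed = compute_shed(fpd)),
            class = "descriptor_set")
}

#' @export
print.descriptor_set <- function(x, ...) {
  cat(sprintf("<descriptors %s: %d PHRAG fragments, FPD mass %d, mean SHED %.3f>\n",
              x$id, x$phrag$total_count, as.integer(sum(x$fpd$raw)),
              mean(unclass(x$shed))))
  invisible(x)
}

#' Write descriptor sets to JSON
#'
#' One object per molecule with `id`, `phrag` (fragment -> count), `fpd`
#' (per-pair raw histograms) and `shed` blocks, in stable key order.
#'
#' @param descriptors A list of `descriptor_set` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_descriptors_json <- function(descriptors, path) {
  payload <- lapply(descriptors, function(d) {
    list(
      id = d$id,
      phrag = as.list(d$phrag$fragments),
      fpd = apply(d$fpd$raw, 1L, function(r) as.vector(r), simplify = FALSE),
      shed = as.list(stats::setNames(as.numeric(unclass(d$shed)),
                                     .PAIR_NAMES))
    )
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
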