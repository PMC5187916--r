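# Descriptor comparators and applicability-domain neighbor retrieval.
#
# A reference compound counts as a neighbor of a query when its PHRAG
# similarity is at least 0.76, its FPD similarity at least 0.87, and its
# SHED Euclidean distance at most 0.52 (the published applicability
# domain). All library compounds are scored; only passing hits feed the
# affinity interpolation.

#' Applicability-domain thresholds
#'
#' @param phrag_min Minimum PHRAG Dice similarity (default 0.76).
#' @param fpd_min Minimum FPD histogram-intersection similarity
#'   (default 0.87).
#' @param shed_max Maximum SHED Euclidean distance (default 0.52).
#' @param mode `"all"` (default) requires every criterion; `"any"` accepts a
#'   hit passing at least one.
#' @return A `threshold_config` list.
#' @export
threshold_config <- function(phrag_min = 0.76, fpd_min = 0.87,
                             shed_max = 0.52, mode = c("all", "any")) {
  mode <- match.arg(mode)
  stopifnot(phrag_min >= 0, phrag_min <= 1,
            fpd_min >= 0, fpd_min <= 1, shed_max >= 0)
  structure(list(phrag_min = phrag_min, fpd_min = fpd_min,
                 shed_max = shed_max, mode = mode),
            class = "threshold_config")
}

#' PHRAG similarity: Dice coefficient on fragment multisets
#'
#' `2 * sum(min(count_a, count_b)) / (total_a + total_b)`. Two empty
#' profiles are indistinguishable and score 1; exactly one empty scores 0.
#'
#' @param a,b `phrag_profile` objects.
#' @return Similarity in \[0, 1\].
#' @export
phrag_similarity <- function(a, b) {
  stopifnot(inherits(a, "phrag_profile"), inherits(b, "phrag_profile"))
  ta <- a$total_count; tb <- b$total_count
  if (ta == 0L && tb == 0L) return(1)
  if (ta == 0L || tb == 0L) return(0)
  shared <- intersect(names(a$fragments), names(b$fragments))
  common <- sum(pmin(a$fragments[shared], b$fragments[shared]))
  2 * common / (ta + tb)
}

#' FPD similarity: mean histogram intersection over populated feature pairs
#'
#' For each of the 10 feature pairs populated in at least one molecule, the
#' intersection `sum(min(p, q))` of the normalized histograms (0 when the
#' pair is empty in exactly one molecule); the similarity is the mean over
#' those pairs. Two entirely featureless molecules score 1.
#'
#' @param a,b `fpd_profile` objects.
#' @return Similarity in \[0, 1\].
#' @export
fpd_similarity <- function(a, b) {
  stopifnot(inherits(a, "fpd_profile"), inherits(b, "fpd_profile"))
  ma <- rowSums(a$raw) > 0
  mb <- rowSums(b$raw) > 0
  active <- ma | mb
  if (!any(active)) return(1)
  per_pair <- vapply(which(active), function(i) {
    if (ma[i] && mb[i]) sum(pmin(a$norm[i, ], b$norm[i, ])) else 0
  }, numeric(1))
  mean(per_pair)
}

#' SHED distance: Euclidean norm of the entropy-vector difference
#'
#' @param a,b `shed_vector` objects (length 10).
#' @return Non-negative distance.
#' @export
shed_distance <- function(a, b) {
  va <- as.numeric(unclass(a)); vb <- as.numeric(unclass(b))
  stopifnot(length(va) == 10L, length(vb) == 10L)
  sqrt(sum((va - vb)^2))
}

#' Score a query against every library compound
#'
#' Computes all three comparisons for every reference molecule and flags the
#' hits inside the applicability domain. Hits are returned for the whole
#' library (passing and failing), sorted by descending PHRAG similarity with
#' `ref_id` as the tie-break.
#'
#' @param query A `descriptor_set` (see [build_descriptors()]).
#' @param lib An `annotated_library`.
#' @param cfg A [threshold_config()].
#' @return A data.frame with `query_id`, `ref_id`, `phrag_sim`, `fpd_sim`,
#'   `shed_dist`, `passes`.
#' @export
find_neighbors <- function(query, lib, cfg = threshold_config()) {
  stopifnot(inherits(query, "descriptor_set"),
            inherits(lib, "annotated_library"),
            inherits(cfg, "threshold_config"))
  ref_ids <- names(lib$molecules)
  ds <- library_descriptors(lib)
  phrag_sim <- vapply(ref_ids, function(r)
    phrag_similarity(query$phrag, ds[[r]]$phrag), numeric(1))
  fpd_sim <- vapply(ref_ids, function(r)
    fpd_similarity(query$fpd, ds[[r]]$fpd), numeric(1))
  shed_dist <- vapply(ref_ids, function(r)
    shed_distance(query$shed, ds[[r]]$shed), numeric(1))
  crit <- cbind(phrag_sim >= cfg$phrag_min,
                fpd_sim >= cfg$fpd_min,
                shed_dist <= cfg$shed_max)
  passes <- if (cfg$mode == "all") rowSums(crit) == 3L else rowSums(crit) >= 1L
  out <- data.frame(query_id = query$id, ref_id = ref_ids,
                    phrag_sim = phrag_sim, fpd_sim = fpd_sim,
                    shed_dist = shed_dist, passes = passes,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$phrag_sim, out$ref_id), , drop = FALSE]
}
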