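# Inverse-distance-weighted (IDW) affinity interpolation.
#
# Passing neighbors are grouped per (target, activity type); the query's
# predicted pActivity F is the weighted mean of the neighbors' experimental
# values f_i, with weights W_i = d_i^-p / sum_j d_j^-p. The default power is
# p = 2. Activity types are never pooled: a pKi is interpolated only from
# pKi annotations. For the PHRAG and FPD channels the distance is one minus
# the similarity; the SHED channel is a distance already.

#' IDW configuration
#'
#' @param power Positive power parameter p (default 2).
#' @param channel Distance channel: `"PHRAG"` (default, `d = 1 - phrag_sim`),
#'   `"FPD"` (`d = 1 - fpd_sim`) or `"SHED"` (the Euclidean entropy distance
#'   itself).
#' @param zero_eps Distances below this are treated as exact matches: the
#'   prediction is then the plain mean over those near-zero neighbors (the
#'   weight formula diverges at d = 0).
#' @return An `idw_config` list.
#' @export
idw_config <- function(power = 2, channel = c("PHRAG", "FPD", "SHED"),
                       zero_eps = 1e-9) {
  channel <- match.arg(channel)
  stopifnot(is.numeric(power), length(power) == 1L, power > 0,
            zero_eps >= 0)
  structure(list(power = power, channel = channel, zero_eps = zero_eps),
            class = "idw_config")
}

#' Inverse-distance-weighted interpolation
#'
#' `F = sum(W_i * f_i)` with `W_i = d_i^-p / sum_j(d_j^-p)`. If any distance
#' falls below `zero_eps`, F is the arithmetic mean of the values at those
#' near-zero distances (exact-match override).
#'
#' @param f Neighbor values (e.g. pActivities).
#' @param d Non-negative distances, same length as `f`.
#' @param p Positive power (default 2).
#' @param zero_eps Exact-match cutoff (default 1e-9).
#' @return The interpolated value, always within `range(f)`.
#' @examples
#' idw_interpolate(c(10, 0), c(1, 2))   # weights 0.8 / 0.2 -> 8
#' idw_interpolate(6.77, 0.159)         # single neighbor -> 6.77
#' @export
idw_interpolate <- function(f, d, p = 2, zero_eps = 1e-9) {
  if (length(f) == 0L || length(f) != length(d))
    .tf_error("idw_interpolate needs matching non-empty value/distance vectors",
              "targetfish_validation_error")
  if (any(!is.finite(f)) || any(!is.finite(d)) || any(d < 0))
    .tf_error("distances must be finite and non-negative",
              "targetfish_validation_error")
  if (p <= 0)
    .tf_error("power must be positive", "targetfish_validation_error")
  near <- d < zero_eps
  if (any(near)) return(mean(f[near]))
  w <- d^(-p)
  sum(w * f) / sum(w)
}

#' Predict targets for one query from its neighbor hits
#'
#' Passing hits are joined to the library's annotations and grouped by
#' `(uniprot, activity_type)`; within each group the neighbor distances are
#' derived from the configured channel and the group's pActivities are
#' IDW-interpolated into one prediction. The nearest neighbor supplies the
#' reported evidence fields (`ref_nn`, `sim`, `ref_pact`, source database,
#' target name, functional class).
#'
#' @param query_id Query identifier (must match `hits$query_id`).
#' @param hits data.frame from [find_neighbors()].
#' @param lib The `annotated_library` the hits were computed against.
#' @param cfg An [idw_config()].
#' @return data.frame with one row per predicted (target, activity type),
#'   sorted by descending predicted pActivity: columns `query_id`,
#'   `uniprot`, `target_name`, `activity_type`, `pact_pred`, `n`, `ref_nn`,
#'   `sim`, `ref_pact`, `source_db`, `functional_class`, `ann` (constant
#'   `"PRD"`), and a `neighbors` list-column of per-neighbor evidence
#'   (`ref_id`, `f`, `d`, `w`). Empty (0-row) when no hit passes.
#' @export
predict_targets <- function(query_id, hits, lib, cfg = idw_config()) {
  stopifnot(inherits(lib, "annotated_library"), inherits(cfg, "idw_config"))
  empty <- data.frame(query_id = character(0), uniprot = character(0),
                      target_name = character(0), activity_type = character(0),
                      pact_pred = numeric(0), n = integer(0),
                      ref_nn = character(0), sim = numeric(0),
                      ref_pact = numeric(0), source_db = character(0),
                      functional_class = character(0), ann = character(0),
                      stringsAsFactors = FALSE)
  empty$neighbors <- list()
  pass <- hits[hits$passes & hits$query_id == query_id, , drop = FALSE]
  if (nrow(pass) == 0L) return(empty)

  ann <- merge(pass, lib$records, by = "ref_id")
  if (nrow(ann) == 0L) return(empty)
  ann$d <- switch(cfg$channel,
                  PHRAG = 1 - ann$phrag_sim,
                  FPD = 1 - ann$fpd_sim,
                  SHED = ann$shed_dist)
  ann$channel_sim <- switch(cfg$channel,
                            PHRAG = ann$phrag_sim,
                            FPD = ann$fpd_sim,
                            SHED = 1 / (1 + ann$shed_dist))

  groups <- split(ann, paste(ann$uniprot, ann$activity_type, sep = "\r"))
  rows <- lapply(groups, function(g) {
    g <- g[order(g$d, g$ref_id), , drop = FALSE]
    f <- g$pact; d <- g$d
    F_hat <- idw_interpolate(f, d, p = cfg$power, zero_eps = cfg$zero_eps)
    near <- d < cfg$zero_eps
    w <- if (any(near)) ifelse(near, 1 / sum(near), 0) else {
      raw <- d^(-cfg$power); raw / sum(raw)
    }
    nn <- g[1L, ]
    out <- data.frame(query_id = query_id, uniprot = nn$uniprot,
                      target_name = nn$target_name,
                      activity_type = nn$activity_type,
                      pact_pred = F_hat, n = nrow(g),
                      ref_nn = nn$ref_id, sim = nn$channel_sim,
                      ref_pact = nn$pact, source_db = nn$source_db,
                      functional_class = nn$functional_class, ann = "PRD",
                      stringsAsFactors = FALSE)
    out$neighbors <- list(data.frame(ref_id = g$ref_id, f = f, d = d, w = w,
                                     stringsAsFactors = FALSE))
    out
  })
  res <- do.call(rbind, rows)
  res <- res[order(-res$pact_pred, res$uniprot, res$activity_type), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Run target fishing for a set of query molecules
#'
#' Convenience wrapper: builds descriptors for each query, retrieves
#' neighbors, and row-binds the per-query predictions.
#'
#' @param queries Named list of `molecule` objects (e.g. from
#'   [read_smiles_file()]).
#' @param lib An `annotated_library`.
#' @param thresholds A [threshold_config()].
#' @param idw An [idw_config()].
#' @return list with `predictions` (row-bound data.frame) and `hits` (the
#'   full per-query comparison table).
#' @export
fish_targets <- function(queries, lib, thresholds = threshold_config(),
                         idw = idw_config()) {
  all_hits <- list(); all_pred <- list()
  for (qid in names(queries)) {
    ds <- build_descriptors(queries[[qid]])
    ds$id <- qid
    hits <- find_neighbors(ds, lib, thresholds)
    hits$query_id <- qid
    all_hits[[qid]] <- hits
    all_pred[[qid]] <- predict_targets(qid, hits, lib, idw)
  }
  list(predictions = do.call(rbind, c(all_pred, list(make.row.names = FALSE))),
       hits = do.call(rbind, c(all_hits, list(make.row.names = FALSE))))
}
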