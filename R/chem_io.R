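# Library, query, and report file formats.
#
# The annotated reference library is a CSV with nine columns (one row per
# compound-target-activity annotation); the prediction report is a TSV
# mirroring the fields of a target-fishing report (annotation type,
# predicted pActivity, nearest-neighbor evidence, source database, target
# identity and functional class).

.LIBRARY_COLUMNS <- c("ref_id", "inchikey", "smiles", "uniprot",
                      "target_name", "activity_type", "pact",
                      "source_db", "functional_class")
.ACTIVITY_TYPES <- c("pKi", "pKd", "pIC50")

.tf_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "targetfish_error", "error")))
}

#' Construct an annotated compound-target library
#'
#' Validates records, parses each compound's SMILES, and collapses duplicate
#' `(ref_id, uniprot, activity_type)` annotations to their mean pActivity
#' (the affinity interpolation expects one value per neighbor-target pair).
#'
#' @param records data.frame with columns `ref_id`, `inchikey`, `smiles`,
#'   `uniprot`, `target_name`, `activity_type` (one of pKi/pKd/pIC50),
#'   `pact`, `source_db`, `functional_class`.
#' @return An `annotated_library`: the deduplicated `records`, a `molecules`
#'   map (`ref_id` -> `molecule`), a lazily filled descriptor cache, and
#'   `n_dropped`, the number of rows discarded for unparseable SMILES.
#' @export
annotated_library <- function(records) {
  missing_cols <- setdiff(.LIBRARY_COLUMNS, names(records))
  if (length(missing_cols) > 0L) {
    .tf_error(paste0("library is missing column(s): ",
                     paste(missing_cols, collapse = ", ")),
              "targetfish_format_error")
  }
  records <- records[, .LIBRARY_COLUMNS]
  if (any(!records$activity_type %in% .ACTIVITY_TYPES))
    .tf_error("activity_type must be one of pKi, pKd, pIC50",
              "targetfish_validation_error")
  if (any(!is.finite(records$pact)))
    .tf_error("pact must be finite", "targetfish_validation_error")
  if (any(!nzchar(records$uniprot)))
    .tf_error("uniprot must be non-empty", "targetfish_validation_error")

  # parse each distinct compound once; drop annotations of bad structures
  molecules <- list()
  bad <- character(0)
  for (rid in unique(records$ref_id)) {
    smi <- records$smiles[records$ref_id == rid][1L]
    mol <- tryCatch(parse_smiles(smi, id = rid), error = function(e) NULL)
    if (is.null(mol)) bad <- c(bad, rid) else molecules[[rid]] <- mol
  }
  n_dropped <- sum(records$ref_id %in% bad)
  if (n_dropped > 0L) {
    warning(sprintf("dropped %d annotation row(s) with unparseable SMILES (%s)",
                    n_dropped, paste(bad, collapse = ", ")), call. = FALSE)
    records <- records[!records$ref_id %in% bad, , drop = FALSE]
  }

  # duplicate (ref_id, uniprot, activity_type) -> mean pact
  key <- paste(records$ref_id, records$uniprot, records$activity_type,
               sep = "\r")
  if (anyDuplicated(key)) {
    pact <- tapply(records$pact, key, mean)
    first <- records[!duplicated(key), , drop = FALSE]
    first$pact <- as.numeric(pact[paste(first$ref_id, first$uniprot,
                                        first$activity_type, sep = "\r")])
    records <- first
  }
  rownames(records) <- NULL

  structure(list(records = records, molecules = molecules,
                 descriptor_cache = new.env(parent = emptyenv()),
                 n_dropped = n_dropped),
            class = "annotated_library")
}

#' @export
print.annotated_library <- function(x, ...) {
  cat(sprintf("<annotated library: %d compounds, %d annotations, %d targets>\n",
              length(x$molecules), nrow(x$records),
              length(unique(x$records$uniprot))))
  invisible(x)
}

#' Read an annotated library from CSV
#'
#' Expects the nine-column schema of [annotated_library()]; comment lines
#' starting with `#` are skipped. Rows whose SMILES fail to parse are
#' dropped with a warning; duplicate annotations are averaged.
#'
#' @param path CSV file path.
#' @return An `annotated_library`.
#' @export
read_annotation_library <- function(path) {
  if (!file.exists(path))
    .tf_error(paste0("no such file: ", path), "targetfish_io_error")
  records <- utils::read.csv(path, stringsAsFactors = FALSE,
                             comment.char = "#",
                             colClasses = c(pact = "numeric"))
  annotated_library(records)
}

#' Write an annotated library to CSV
#'
#' @param lib An `annotated_library` (or a records data.frame).
#' @param path Output path.
#' @param header_comments Optional character vector written as leading `#`
#'   comment lines (e.g. the generator seed).
#' @return `path`, invisibly.
#' @export
write_library_csv <- function(lib, path, header_comments = NULL) {
  records <- if (inherits(lib, "annotated_library")) lib$records else lib
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header_comments) writeLines(paste0("# ", h), con)
  utils::write.csv(records, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Compute (and cache) descriptor sets for every library compound
#'
#' @param lib An `annotated_library`.
#' @return Named list of `descriptor_set` objects, keyed by `ref_id`.
#' @export
library_descriptors <- function(lib) {
  stopifnot(inherits(lib, "annotated_library"))
  cache <- lib$descriptor_cache
  for (rid in names(lib$molecules)) {
    if (is.null(cache[[rid]]))
      cache[[rid]] <- build_descriptors(lib$molecules[[rid]])
  }
  mget(names(lib$molecules), envir = cache)
}

#' Write a Table-1-style prediction report
#'
#' TSV with columns `QUERY_ID`, `TARGET_NAME`, `UNIPROT`, `ANN`, `ACT_TYPE`,
#' `PACT_PRED`, `REF_NN`, `SIM`, `REF_pACT`, `SOURCE_DB`, `FUNCTIONAL`; one
#' row per (query, target, activity type). `PACT_PRED` is printed with 2
#' decimals and `SIM` with 3.
#'
#' @param predictions data.frame from [predict_targets()] (possibly row-bound
#'   across queries); may be empty.
#' @param path Output path.
#' @param header_comments Optional `#` comment lines written first.
#' @return `path`, invisibly.
#' @export
write_prediction_report <- function(predictions, path,
                                    header_comments = NULL) {
  cols <- c("QUERY_ID", "TARGET_NAME", "UNIPROT", "ANN", "ACT_TYPE",
            "PACT_PRED", "REF_NN", "SIM", "REF_pACT", "SOURCE_DB",
            "FUNCTIONAL")
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header_comments) writeLines(paste0("# ", h), con)
  writeLines(paste(cols, collapse = "\t"), con)
  if (!is.null(predictions) && nrow(predictions) > 0L) {
    for (i in seq_len(nrow(predictions))) {
      p <- predictions[i, ]
      writeLines(paste(c(p$query_id, p$target_name, p$uniprot, p$ann,
                         p$activity_type, sprintf("%.2f", p$pact_pred),
                         p$ref_nn, sprintf("%.3f", p$sim),
                         format(p$ref_pact), p$source_db,
                         p$functional_class), collapse = "\t"), con)
    }
  }
  invisible(path)
}
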