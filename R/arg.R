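# Antibiotic-resistance-gene (ARG) profiling: alignment-hit filtering,
# per-host presence filtering, and drug-class abundance aggregation.

#' Filter ARG alignment hits by identity and mutual coverage
#'
#' Retains hits with percent identity `>= min_ident` and *mutual* coverage
#' -- both query and subject coverage -- `>= min_cov` (all comparisons
#' inclusive, "at least"). The retained gene-family (subject) ids are
#' de-duplicated.
#'
#' @param hits data frame with columns `qseqid`, `sseqid`, `pident`,
#'   `qcovhsp`, `scovhsp` (the tabular alignment columns of a
#'   protein-vs-protein search).
#' @param min_ident minimum percent identity (default 90).
#' @param min_cov minimum percent coverage required of both query and
#'   subject (default 80).
#' @return Character vector of unique retained subject ids.
#' @export
filter_arg_hits <- function(hits, min_ident = 90, min_cov = 80) {
  need <- c("sseqid", "pident", "qcovhsp", "scovhsp")
  if (!all(need %in% names(hits))) {
    stop("hits need columns: ", paste(need, collapse = ", "))
  }
  pct <- c("pident", "qcovhsp", "scovhsp")
  for (col in pct) {
    v <- hits[[col]]
    if (anyNA(v) || any(v < 0 | v > 100)) stop("'", col, "' must be in [0, 100]")
  }
  keep <- hits$pident >= min_ident &
    hits$qcovhsp >= min_cov & hits$scovhsp >= min_cov
  unique(as.character(hits$sseqid[keep]))
}

#' Per-host presence filter for ARGs
#'
#' An ARG is retained when it is present (abundance strictly greater than
#' 0) in at least `min_samples` samples of at least one host.
#'
#' @param abundance samples x ARG abundance matrix (nonnegative).
#' @param host_of host label per sample, named by sample id or parallel to
#'   the rows.
#' @param min_samples per-host sample threshold (default 3).
#' @return Character vector of retained ARG (column) names.
#' @export
arg_presence_filter <- function(abundance, host_of, min_samples = 3) {
  if (!is.matrix(abundance)) abundance <- as.matrix(abundance)
  if (any(abundance < 0)) stop("negative abundances")
  ids <- rownames(abundance)
  if (!is.null(names(host_of))) {
    if (!all(ids %in% names(host_of))) stop("host label missing for some samples")
    host_of <- host_of[ids]
  } else if (length(host_of) != nrow(abundance)) {
    stop("'host_of' must be named by sample id or parallel to the rows")
  }
  pos <- abundance > 0
  keep <- rep(FALSE, ncol(abundance))
  for (h in unique(as.character(host_of))) {
    keep <- keep | colSums(pos[host_of == h, , drop = FALSE]) >= min_samples
  }
  colnames(abundance)[keep]
}

#' Aggregate ARG abundances into drug classes
#'
#' Sums per-sample ARG abundances within each drug class. An ARG mapped to
#' several classes contributes its full abundance to each (resistance
#' classes overlap; the class table is not a partition), and ARGs missing
#' from the map fall into an `unclassified` bucket, so that summing the
#' `unclassified` bucket together with each ARG counted once conserves the
#' total ARG mass.
#'
#' @param abundance samples x ARG abundance matrix.
#' @param class_map data frame with columns `arg_id`, `drug_class` (an
#'   `arg_id` may appear in several rows).
#' @return Numeric matrix samples x drug classes.
#' @export
arg_class_abundance <- function(abundance, class_map) {
  if (!is.matrix(abundance)) abundance <- as.matrix(abundance)
  stopifnot(all(c("arg_id", "drug_class") %in% names(class_map)))
  args <- colnames(abundance)
  unmapped <- setdiff(args, class_map$arg_id)
  if (length(unmapped) > 0L) {
    class_map <- rbind(class_map[, c("arg_id", "drug_class")],
                       data.frame(arg_id = unmapped, drug_class = "unclassified"))
  }
  class_map <- class_map[class_map$arg_id %in% args, , drop = FALSE]
  classes <- sort(unique(class_map$drug_class))
  out <- matrix(0, nrow(abundance), length(classes),
                dimnames = list(rownames(abundance), classes))
  for (cl in classes) {
    members <- unique(class_map$arg_id[class_map$drug_class == cl])
    out[, cl] <- rowSums(abundance[, members, drop = FALSE])
  }
  out
}
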