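# Rule-based screening: MAG quality grades, genome-bin assignment from
# Mash distances, SGB presence/prevalence and host-sharing categories.
# Threshold comparisons are strict ('>', '<') exactly as the grading rules
# are stated; boundary behaviour is unit-tested.

#' Grade MAG quality from completeness and contamination
#'
#' `high` requires completeness > 90 and contamination < 5; otherwise
#' `medium` requires completeness > 50 and contamination < 10; everything
#' else is `low`. The three grades partition the input space (low is
#' "neither high nor medium", the discard class).
#'
#' @param completeness percent in `[0, 100]` (vectorised).
#' @param contamination percent `>= 0` (vectorised).
#' @return Character vector of grades: `"high"`, `"medium"` or `"low"`.
#' @export
classify_mag_quality <- function(completeness, contamination) {
  if (!is.numeric(completeness) || !is.numeric(contamination)) {
    stop("completeness and contamination must be numeric")
  }
  if (anyNA(completeness) || anyNA(contamination)) stop("missing values")
  if (any(completeness < 0 | completeness > 100)) {
    stop("completeness must be in [0, 100]")
  }
  if (any(contamination < 0)) stop("contamination must be >= 0")
  ifelse(completeness > 90 & contamination < 5, "high",
         ifelse(completeness > 50 & contamination < 10, "medium", "low"))
}

#' Assign a MAG to a genome bin from Mash distances
#'
#' The MAG is assigned to the nearest bin (minimum Mash distance; ties are
#' broken by the lexicographically smallest bin id) at the species (SGB),
#' genus (GGB) or family (FGB) level when the distance is below 0.05, 0.15
#' or 0.30 respectively; beyond 0.30 the MAG is `novel`.
#'
#' @param distances named numeric vector of Mash distances in `[0, 1]`,
#'   one per candidate bin.
#' @param thresholds increasing distance cutoffs for `SGB`, `GGB`, `FGB`.
#' @return List with `nearest_bin_id`, `nearest_distance` and `level`
#'   (`"SGB"`, `"GGB"`, `"FGB"` or `"novel"`).
#' @export
assign_genome_bin <- function(distances, thresholds = c(SGB = 0.05, GGB = 0.15, FGB = 0.30)) {
  if (length(distances) == 0L) stop("empty distance map")
  if (is.null(names(distances)) || any(names(distances) == "")) {
    stop("'distances' must be named by bin id")
  }
  if (anyNA(distances) || any(distances < 0 | distances > 1)) {
    stop("Mash distances must be in [0, 1]")
  }
  dmin <- min(distances)
  cand <- sort(names(distances)[distances == dmin])
  level <- if (dmin < thresholds[["SGB"]]) "SGB"
           else if (dmin < thresholds[["GGB"]]) "GGB"
           else if (dmin < thresholds[["FGB"]]) "FGB"
           else "novel"
  list(nearest_bin_id = cand[[1L]], nearest_distance = dmin, level = level)
}

#' Presence and prevalence of taxa by host
#'
#' A taxon (SGB) is present in a host when at least `min_samples` of that
#' host's samples carry it at relative abundance `>= min_abund`;
#' prevalence is the fraction of the host's samples at or above the
#' abundance cutoff.
#'
#' @param abundance samples x taxa relative-abundance matrix.
#' @param host_of host label per sample, named by sample id or parallel to
#'   the rows.
#' @param min_abund abundance detection threshold (default `1e-5`).
#' @param min_samples minimum detected samples for presence (default 3).
#' @return Data frame, one row per taxon x host, with columns `sgb_id`,
#'   `host`, `n_detected`, `prevalence`, `present`.
#' @export
presence_filter <- function(abundance, host_of, min_abund = 1e-5, min_samples = 3) {
  if (!is.matrix(abundance)) abundance <- as.matrix(abundance)
  ids <- rownames(abundance)
  if (!is.null(names(host_of))) {
    if (!all(ids %in% names(host_of))) stop("host label missing for some samples")
    host_of <- host_of[ids]
  } else if (length(host_of) != nrow(abundance)) {
    stop("'host_of' must be named by sample id or parallel to the rows")
  }
  hosts <- sort(unique(as.character(host_of)))
  hit <- abundance >= min_abund
  out <- lapply(hosts, function(h) {
    rows <- host_of == h
    ndet <- colSums(hit[rows, , drop = FALSE])
    data.frame(sgb_id = colnames(abundance), host = h,
               n_detected = as.integer(ndet),
               prevalence = as.numeric(ndet) / sum(rows),
               present = ndet >= min_samples)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Host-sharing category of a presence profile
#'
#' Maps the exact set of hosts a taxon is present in onto the study's
#' sharing categories for cats, dogs and humans: host-unique classes,
#' `companion-shared` (cats and dogs but not humans), the two
#' animal+human pairs, `all-hosts`, or `absent`.
#'
#' @param present named logical vector with entries `cat`, `dog`, `human`
#'   (or a one-taxon subset of the data frame from [presence_filter()]).
#' @return A single category string.
#' @export
sharing_category <- function(present) {
  if (is.data.frame(present)) {
    present <- stats::setNames(present$present, present$host)
  }
  need <- c("cat", "dog", "human")
  if (!all(need %in% names(present))) {
    stop("'present' must name cat, dog and human")
  }
  set <- need[as.logical(present[need])]
  key <- paste(set, collapse = "+")
  switch(key,
    "cat"           = "cat-unique",
    "dog"           = "dog-unique",
    "human"         = "human-unique",
    "cat+dog"       = "companion-shared",
    "cat+human"     = "cat+human",
    "dog+human"     = "dog+human",
    "cat+dog+human" = "all-hosts",
    "absent")
}

#' Inclusion rule for novel SGBs in a marker database
#'
#' A newly assembled SGB is represented in the reference database only
#' when it is backed by at least `min_genomes` genomes (default 5).
#'
#' @param n_genomes nonnegative genome count (vectorised).
#' @param min_genomes inclusion threshold.
#' @return Logical: include the SGB?
#' @export
novel_sgb_database_rule <- function(n_genomes, min_genomes = 5) {
  if (any(n_genomes < 0)) stop("genome counts must be >= 0")
  n_genomes >= min_genomes
}
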