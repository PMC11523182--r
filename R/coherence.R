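# Host coherence (niche-association) scores.
#
# For each host with enough strains, the host-specific score contrasts the
# median within-host strain distance against the median distance from that
# host's strains to all other strains; the SGB-level score is the
# unweighted mean of the defined host scores. Scores live in [0, 1]:
# 0 = strains fully mixed across hosts, near 1 = host-exclusive lineages.

#' SGB eligibility for coherence scoring
#'
#' An SGB qualifies for a coherence score when its strains are (1) shared
#' across at least two hosts, (2) drawn from at least `min_total` samples
#' overall, and (3) at least `min_host` samples in each of at least two
#' hosts.
#'
#' @param inventory data frame with columns `sgb_id`, `host`, `n_samples`
#'   (long form: one row per SGB x host), or a named list of named host
#'   count vectors.
#' @param min_total minimum total strain count (default 20).
#' @param min_host minimum per-host strain count (default 5) required in at
#'   least two hosts.
#' @return Data frame with columns `sgb_id`, `n_total`, `n_hosts`,
#'   `n_hosts_min`, `eligible`, `reason` (empty string when eligible).
#' @export
eligible_sgbs <- function(inventory, min_total = 20, min_host = 5) {
  if (is.list(inventory) && !is.data.frame(inventory)) {
    inventory <- do.call(rbind, lapply(names(inventory), function(s) {
      cnt <- inventory[[s]]
      data.frame(sgb_id = s, host = names(cnt), n_samples = as.numeric(cnt))
    }))
  }
  stopifnot(all(c("sgb_id", "host", "n_samples") %in% names(inventory)))
  if (any(inventory$n_samples < 0)) stop("negative strain counts")
  out <- lapply(split(inventory, inventory$sgb_id), function(g) {
    n <- g$n_samples[g$n_samples > 0]
    hosts_present <- sum(g$n_samples > 0)
    total <- sum(g$n_samples)
    n_min <- sum(g$n_samples >= min_host)
    reasons <- character(0)
    if (hosts_present < 2L) reasons <- c(reasons, "not shared across >=2 hosts")
    if (total < min_total) {
      reasons <- c(reasons, sprintf("fewer than %d samples in total", min_total))
    }
    if (n_min < 2L) {
      reasons <- c(reasons,
                   sprintf("fewer than 2 hosts with >=%d samples", min_host))
    }
    data.frame(sgb_id = g$sgb_id[[1L]], n_total = total,
               n_hosts = hosts_present, n_hosts_min = n_min,
               eligible = length(reasons) == 0L,
               reason = paste(reasons, collapse = "; "))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Host-specific coherence score
#'
#' Let W be the finite pairwise distances among strains of host `host`, and
#' B the finite distances from those strains to strains of every other
#' host. The score is
#' `max(0, (median(B) - median(W)) / median(B))`: 0 when within-host
#' strains are no closer to each other than to foreign strains, 1 when the
#' host's strains are identical but distinct from all others. The score is
#' undefined (`NA`) when more than `max_saturated` of the relevant pairs
#' are saturated, or when `median(B)` cannot be formed; it is 0 when
#' `median(B) = 0`.
#'
#' @param dm symmetric distance matrix (strain ids as dimnames; `NA` marks
#'   saturated pairs).
#' @param host_of host label per strain, named by strain id (or parallel to
#'   the matrix rows).
#' @param host the focal host label.
#' @param min_strains minimum number of focal-host strains (default 5).
#' @param max_saturated maximum tolerated fraction of saturated pairs in
#'   the union of W and B before the score is declared undefined.
#' @return A single score in `[0, 1]`, or `NA` when undefined.
#' @export
host_coherence_score <- function(dm, host_of, host, min_strains = 5,
                                 max_saturated = 0.5) {
  validate_distance_matrix(dm)
  ids <- rownames(dm)
  if (is.null(names(host_of))) {
    if (length(host_of) != length(ids)) {
      stop("'host_of' must be named by strain id or parallel to dm")
    }
    names(host_of) <- ids
  }
  if (!all(ids %in% names(host_of))) stop("host label missing for some strains")
  host_of <- host_of[ids]
  in_h <- which(host_of == host)
  if (length(in_h) < min_strains) {
    stop(sprintf("host '%s' has %d strains; need >= %d",
                 host, length(in_h), min_strains))
  }
  out_h <- which(host_of != host)
  if (length(out_h) < 1L) stop("no strains from any other host")
  wmat <- dm[in_h, in_h, drop = FALSE]
  W <- wmat[upper.tri(wmat)]
  B <- as.vector(dm[in_h, out_h, drop = FALSE])
  pool <- c(W, B)
  if (mean(is.na(pool)) > max_saturated) return(NA_real_)
  W <- W[!is.na(W)]
  B <- B[!is.na(B)]
  if (length(B) == 0L || length(W) == 0L) return(NA_real_)
  medB <- stats::median(B)
  if (medB == 0) return(0)
  max(0, (medB - stats::median(W)) / medB)
}

#' Mean coherence over host-specific scores
#'
#' Unweighted arithmetic mean of the defined (non-`NA`) host-specific
#' scores, the SGB-level summary.
#'
#' @param host_scores numeric vector of host-specific scores (may contain
#'   `NA` for undefined hosts).
#' @return The mean, or `NA` if no score is defined.
#' @export
mean_coherence <- function(host_scores) {
  s <- host_scores[!is.na(host_scores)]
  if (length(s) == 0L) return(NA_real_)
  mean(s)
}

#' Coherence score for one SGB
#'
#' Computes host-specific scores for every host with at least
#' `min_strains` strains (hosts below the cutoff still contribute their
#' strains to other hosts' between-host pools but receive no score of
#' their own), then averages them without weighting. Eligibility per the
#' sharing/sample-count rules is reported alongside.
#'
#' @param dm symmetric K2P distance matrix for the SGB's strains.
#' @param host_of host label per strain, named by strain id.
#' @param min_strains per-host minimum for a host score (default 5).
#' @param sgb_id optional label carried into the result.
#' @param min_total,min_host eligibility thresholds, see [eligible_sgbs()].
#' @return An object of class `coherence_result`: list with `sgb_id`,
#'   `host_scores` (named, `NA` = undefined), `mean_score`, `n_per_host`,
#'   `eligible`, `reason`.
#' @export
coherence_score <- function(dm, host_of, min_strains = 5,
                            sgb_id = NA_character_,
                            min_total = 20, min_host = 5) {
  validate_distance_matrix(dm)
  ids <- rownames(dm)
  if (is.null(names(host_of))) {
    if (length(host_of) != length(ids)) {
      stop("'host_of' must be named by strain id or parallel to dm")
    }
    names(host_of) <- ids
  }
  host_of <- host_of[ids]
  counts <- table(host_of)
  scored_hosts <- names(counts)[counts >= min_strains]
  if (length(scored_hosts) == 0L) {
    stop(sprintf("no host with >= %d strains", min_strains))
  }
  scores <- vapply(scored_hosts, function(h) {
    if (sum(host_of != h) < 1L) return(NA_real_)
    host_coherence_score(dm, host_of, h, min_strains = min_strains)
  }, numeric(1))
  elig <- eligible_sgbs(
    data.frame(sgb_id = "x", host = names(counts), n_samples = as.numeric(counts)),
    min_total = min_total, min_host = min_host
  )
  structure(
    list(sgb_id = sgb_id,
         host_scores = scores,
         mean_score = mean_coherence(scores),
         n_per_host = stats::setNames(as.integer(counts), names(counts)),
         eligible = elig$eligible[[1L]],
         reason = elig$reason[[1L]]),
    class = "coherence_result"
  )
}

#' @export
print.coherence_result <- function(x, ...) {
  cat("Coherence score", if (!is.na(x$sgb_id)) paste0("for ", x$sgb_id), "\n")
  for (h in names(x$host_scores)) {
    cat(sprintf("  %-10s n=%-4d score=%s\n", h, x$n_per_host[[h]],
                formatC(x$host_scores[[h]], digits = 3, format = "f")))
  }
  cat(sprintf("  mean coherence: %s  (eligible: %s%s)\n",
              formatC(x$mean_score, digits = 3, format = "f"),
              x$eligible,
              if (nzchar(x$reason)) paste0("; ", x$reason) else ""))
  invisible(x)
}

#' Tabulate coherence results
#'
#' Flattens one or more `coherence_result` objects into the per-SGB output
#' table (scores rounded to 3 decimals).
#'
#' @param results a `coherence_result` or list of them.
#' @param hosts host columns to report; defaults to the union observed.
#' @return Data frame with counts and scores per host plus the mean score,
#'   eligibility flag and reason.
#' @export
coherence_table <- function(results, hosts = NULL) {
  if (inherits(results, "coherence_result")) results <- list(results)
  if (is.null(hosts)) {
    hosts <- sort(unique(unlist(lapply(results, function(r) names(r$n_per_host)))))
  }
  rows <- lapply(results, function(r) {
    n <- stats::setNames(rep(0L, length(hosts)), hosts)
    n[names(r$n_per_host)] <- r$n_per_host
    s <- stats::setNames(rep(NA_real_, length(hosts)), hosts)
    s[names(r$host_scores)] <- round(r$host_scores, 3)
    out <- data.frame(sgb_id = r$sgb_id)
    for (h in hosts) out[[paste0("n_", h)]] <- n[[h]]
    for (h in hosts) out[[paste0("score_", h)]] <- s[[h]]
    out$mean_score <- round(r$mean_score, 3)
    out$eligible <- r$eligible
    out$reason <- r$reason
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
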