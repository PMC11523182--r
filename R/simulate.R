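# Synthetic data with known ground truth: host-structured strain
# alignments evolved under the K80 substitution model, host-structured
# relative-abundance tables, and planted fixtures for the screening and
# ARG rules. Every generator is deterministic given its seed.

k80_site_probs <- function(t, kappa) {
  # Rates scaled so t = expected substitutions/site: alpha + 2*beta = 1,
  # alpha/beta = kappa.
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  e1 <- exp(-4 * beta * t)
  e2 <- exp(-2 * (alpha + beta) * t)
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2        # the single transition target
  p_tv <- 0.25 - 0.25 * e1                   # each of two transversion targets
  p_same <- 1 - p_ts - 2 * p_tv
  c(same = p_same, ts = p_ts, tv = p_tv)
}

#' Evolve a DNA sequence under the K80 model
#'
#' Mutates each site independently for branch length `t` (expected
#' substitutions per site) under Kimura's two-parameter model with
#' transition/transversion rate ratio `kappa`, using the model's closed-form
#' site transition probabilities. Draws come from R's current RNG stream;
#' seed the stream (or use the higher-level simulators, which take a
#' `seed`) for reproducibility.
#'
#' @param seq character string over `A,C,G,T`.
#' @param t branch length `>= 0`.
#' @param kappa transition/transversion rate ratio (default 2).
#' @return The evolved sequence (character string, same length).
#' @export
evolve_sequence <- function(seq, t, kappa = 2) {
  if (t < 0) stop("branch length must be >= 0")
  if (kappa < 0) stop("kappa must be >= 0")
  bases <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  if (any(!bases %in% c("A", "C", "G", "T"))) {
    stop("sequence must be over A,C,G,T")
  }
  if (t == 0) return(paste(bases, collapse = ""))
  p <- k80_site_probs(t, kappa)
  L <- length(bases)
  # fate per site: 0 = unchanged, 1 = transition, 2/3 = the two transversions
  fate <- sample.int(4L, L, replace = TRUE,
                     prob = c(p[["same"]], p[["ts"]], p[["tv"]], p[["tv"]])) - 1L
  idx <- c(A = 1L, C = 2L, G = 3L, T = 4L)[bases]
  # target tables indexed by current base: transition partner, and the two
  # transversion partners (A: G | C,T; C: T | A,G; G: A | C,T; T: C | A,G)
  ts_to <- c("G", "T", "A", "C")
  tv1_to <- c("C", "A", "C", "A")
  tv2_to <- c("T", "G", "T", "G")
  out <- bases
  out[fate == 1L] <- ts_to[idx[fate == 1L]]
  out[fate == 2L] <- tv1_to[idx[fate == 2L]]
  out[fate == 3L] <- tv2_to[idx[fate == 3L]]
  paste(out, collapse = "")
}

random_sequence <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

#' Simulate a host-structured strain alignment
#'
#' Star-within-star genealogy: a uniform random root sequence, one host
#' ancestor per host at branch length `t_b` from the root, and each strain
#' at branch length `t_w` from its host ancestor, all under K80. The
#' expected K2P distance is `2 * t_w` within a host and `2 * (t_w + t_b)`
#' between hosts, so the expected coherence score is
#' `t_b / (t_w + t_b)`. A fraction `mixing` of strains then has its host
#' label re-drawn uniformly at random (label shuffling, the no-signal
#' control at `mixing = 1`); the pre-shuffle truth is recorded.
#'
#' @param hosts host labels (default `c("cat", "dog", "human")`).
#' @param n_per_host strains per host (`>= 5`).
#' @param L alignment length in sites.
#' @param t_w within-host branch length (expected substitutions/site).
#' @param t_b root-to-host-ancestor branch length.
#' @param kappa transition/transversion rate ratio.
#' @param mixing fraction in `[0, 1]` of strains whose label is reassigned.
#' @param seed integer seed (mandatory).
#' @param sgb_id label for the simulated SGB.
#' @return A list with `alignment` (an [aligned_strain_set()] whose host
#'   labels are the post-mixing observed labels) and `truth` (data frame:
#'   `strain_id`, `true_host`, `observed_host`, `relabelled`), plus the
#'   parameters under `params`.
#' @export
simulate_strain_set <- function(hosts = c("cat", "dog", "human"),
                                n_per_host = 20, L = 5000,
                                t_w = 0.01, t_b = 0.09,
                                kappa = 2, mixing = 0, seed,
                                sgb_id = "SGB_sim") {
  if (missing(seed)) stop("'seed' is required")
  stopifnot(n_per_host >= 5, L >= 1, t_w >= 0, t_b >= 0,
            mixing >= 0, mixing <= 1, length(hosts) >= 2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  root <- random_sequence(L)
  ancestors <- lapply(hosts, function(h) evolve_sequence(root, t_b, kappa))
  names(ancestors) <- hosts
  seqs <- character(0)
  true_host <- character(0)
  for (h in hosts) {
    for (i in seq_len(n_per_host)) {
      id <- sprintf("%s_%02d", h, i)
      seqs[[id]] <- evolve_sequence(ancestors[[h]], t_w, kappa)
      true_host[[id]] <- h
    }
  }
  observed <- true_host
  n <- length(seqs)
  n_mix <- round(mixing * n)
  relabelled <- rep(FALSE, n)
  names(relabelled) <- names(seqs)
  if (n_mix > 0) {
    pick <- sample(names(seqs), n_mix)
    observed[pick] <- sample(hosts, n_mix, replace = TRUE)
    relabelled[pick] <- TRUE
  }
  list(
    alignment = aligned_strain_set(seqs, observed, sgb_id = sgb_id),
    truth = data.frame(strain_id = names(seqs),
                       true_host = unname(true_host[names(seqs)]),
                       observed_host = unname(observed[names(seqs)]),
                       relabelled = unname(relabelled)),
    params = list(hosts = hosts, n_per_host = n_per_host, L = L,
                  t_w = t_w, t_b = t_b, kappa = kappa,
                  mixing = mixing, seed = seed)
  )
}

#' Simulate a host-structured relative-abundance table
#'
#' Log-normal baseline abundances per taxon, with `n_signature` taxa per
#' host multiplied by `1 + effect` in that host's samples; rows are
#' renormalised to sum to 1. `effect = 0` gives an exchangeable (null)
#' community.
#'
#' @param hosts host labels.
#' @param n_per_host samples per host.
#' @param n_taxa number of taxa.
#' @param n_signature signature taxa per host (distinct across hosts).
#' @param effect multiplicative enrichment `>= 0` of signature taxa.
#' @param sdlog log-normal dispersion of baselines and per-sample noise.
#' @param seed integer seed (mandatory).
#' @return A list with `abundance` (samples x taxa matrix, rows summing to
#'   1), `host_of` (named), and `signature` (named list host -> taxa).
#' @export
simulate_abundance_table <- function(hosts = c("cat", "dog", "human"),
                                     n_per_host = 20, n_taxa = 50,
                                     n_signature = 5, effect = 2,
                                     sdlog = 1, seed) {
  if (missing(seed)) stop("'seed' is required")
  stopifnot(effect >= 0, n_taxa >= length(hosts) * n_signature)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  taxa <- sprintf("SGB%03d", seq_len(n_taxa))
  base <- stats::rlnorm(n_taxa, meanlog = 0, sdlog = sdlog)
  sig <- split(taxa[seq_len(length(hosts) * n_signature)],
               rep(hosts, each = n_signature))
  sample_ids <- unlist(lapply(hosts, function(h) {
    sprintf("%s_s%02d", h, seq_len(n_per_host))
  }))
  host_of <- stats::setNames(rep(hosts, each = n_per_host), sample_ids)
  m <- matrix(0, length(sample_ids), n_taxa,
              dimnames = list(sample_ids, taxa))
  for (s in sample_ids) {
    lambda <- base * stats::rlnorm(n_taxa, meanlog = 0, sdlog = sdlog)
    boost <- taxa %in% sig[[host_of[[s]]]]
    lambda[boost] <- lambda[boost] * (1 + effect)
    m[s, ] <- lambda / sum(lambda)
  }
  list(abundance = m, host_of = host_of, signature = sig)
}

#' Planted fixtures for the screening and ARG rules
#'
#' Draws small tables that exercise every branch and boundary of the MAG
#' quality grading, genome-bin assignment and ARG hit filtering rules, with
#' the intended outcome stored alongside each record so rule outputs can be
#' checked against the planted truth.
#'
#' @param seed integer seed (mandatory).
#' @param n_random extra random records per table on top of the fixed
#'   boundary cases.
#' @return List of data frames `mag` (completeness, contamination,
#'   expected_grade), `mash` (mag_id, bin ids/distances in long form,
#'   expected_bin, expected_level) plus `mash_wide` as a list of named
#'   vectors, and `arg_hits` (alignment columns plus `expected_keep`).
#' @export
simulate_screening_fixtures <- function(seed, n_random = 20) {
  if (missing(seed)) stop("'seed' is required")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  grade_rule <- function(comp, cont) {
    ifelse(comp > 90 & cont < 5, "high",
           ifelse(comp > 50 & cont < 10, "medium", "low"))
  }
  comp <- c(95, 60, 95, 90, 50, 91, 91, 30, 100, 0,
            stats::runif(n_random, 0, 100))
  cont <- c(2, 8, 7, 4, 9, 5, 10, 2, 0, 20,
            stats::runif(n_random, 0, 20))
  mag <- data.frame(
    mag_id = sprintf("MAG%03d", seq_along(comp)),
    completeness = comp, contamination = cont,
    expected_grade = grade_rule(comp, cont)
  )

  level_rule <- function(d) {
    if (d < 0.05) "SGB" else if (d < 0.15) "GGB" else if (d < 0.30) "FGB" else "novel"
  }
  dmins <- c(0.03, 0.12, 0.28, 0.35, 0.05, 0.15, 0.30, 0.0,
             stats::runif(n_random, 0, 0.5))
  mash_wide <- list()
  mash_rows <- list()
  for (i in seq_along(dmins)) {
    mag_id <- sprintf("Q%03d", i)
    # two decoy bins strictly farther than the planted minimum, plus a
    # planted tie on the first record to exercise the tie-break
    d <- c(B2 = dmins[[i]],
           B3 = min(1, dmins[[i]] + stats::runif(1, 0.05, 0.3)),
           B4 = min(1, dmins[[i]] + stats::runif(1, 0.05, 0.3)))
    expected_bin <- "B2"
    if (i == 1L) {
      d <- c(d, B1 = dmins[[i]])
      expected_bin <- "B1"  # lexicographic tie-break
    }
    mash_wide[[mag_id]] <- d
    mash_rows[[mag_id]] <- data.frame(
      mag_id = mag_id, bin_id = names(d), distance = unname(d),
      expected_bin = expected_bin,
      expected_level = level_rule(dmins[[i]])
    )
  }
  mash <- do.call(rbind, mash_rows)
  rownames(mash) <- NULL

  pid <- c(92, 89, 95, 90, 90, 100, 89.99, 90.01,
           stats::runif(n_random, 80, 100))
  qc <- c(85, 95, 85, 80, 79.9, 100, 80, 80,
          stats::runif(n_random, 60, 100))
  sc <- c(85, 95, 70, 80, 80, 100, 80, 80,
          stats::runif(n_random, 60, 100))
  arg_hits <- data.frame(
    qseqid = sprintf("CARD%03d", seq_along(pid)),
    sseqid = sprintf("UniRef90_%03d", seq_along(pid)),
    pident = pid, qcovhsp = qc, scovhsp = sc,
    expected_keep = pid >= 90 & qc >= 80 & sc >= 80
  )

  list(mag = mag, mash = mash, mash_wide = mash_wide, arg_hits = arg_hits)
}
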