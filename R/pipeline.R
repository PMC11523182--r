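# End-to-end orchestration: simulate -> distances -> coherence;
# abundance -> ordination -> PERMANOVA; screening; ARG. Configured by a
# YAML file or an equivalent nested list; every stochastic stage draws
# from the single top-level seed, so a config determines its outputs
# byte-for-byte. A thin command-line wrapper over run_pipeline() ships in
# inst/scripts/run_pipeline.R.

write_fasta <- function(seqs, path, width = 80L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a pipeline configuration
#'
#' Checks the schema of a pipeline config: a top-level integer `seed`,
#' and in-range thresholds wherever a stage overrides a default
#' (percentages in `[0, 100]`, fractions in `[0, 1]`, positive counts).
#'
#' @param config nested list (or path to a YAML file).
#' @return The config as a list, invisibly; errors describe the first
#'   violated field.
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or YAML path")
  if (is.null(config$seed) || !is.numeric(config$seed) ||
      config$seed != round(config$seed)) {
    stop("config needs an integer 'seed'")
  }
  chk <- function(value, lo, hi, what) {
    if (!is.null(value) && (!is.numeric(value) || value < lo || value > hi)) {
      stop(sprintf("config field '%s' must be in [%s, %s]", what, lo, hi))
    }
  }
  sc <- config$screening
  chk(sc$max_contamination_high, 0, 100, "screening.max_contamination_high")
  chk(sc$min_completeness_high, 0, 100, "screening.min_completeness_high")
  chk(sc$min_abund, 0, 1, "screening.min_abund")
  ar <- config$arg
  chk(ar$min_ident, 0, 100, "arg.min_ident")
  chk(ar$min_cov, 0, 100, "arg.min_cov")
  st <- config$strains
  chk(st$mixing, 0, 1, "strains.mixing")
  pm <- config$permanova
  if (!is.null(pm$permutations) && pm$permutations < 99) {
    stop("config field 'permanova.permutations' must be >= 99")
  }
  invisible(config)
}

#' Run the analysis pipeline from a configuration
#'
#' Executes the stages named in the config against simulated inputs with
#' known ground truth and writes plain-text artifacts (FASTA + TSV) plus a
#' machine-readable JSON run log (package version, seed, parameters, and
#' MD5 checksums of every output) to `output_dir`.
#'
#' Stages (each optional; presence of the section enables it):
#' \describe{
#'   \item{`strains`}{simulate a host-structured alignment, compute the
#'     K2P distance matrix and the coherence score table.}
#'   \item{`community`}{simulate an abundance table; Bray-Curtis PCoA with
#'     optional frequency correction, taxon positions, and one-factor
#'     PERMANOVA on host.}
#'   \item{`screening`}{planted MAG/Mash fixtures graded and assigned.}
#'   \item{`arg`}{planted ARG hits filtered; class profile of a simulated
#'     ARG abundance table.}
#' }
#'
#' @param config nested list or path to a YAML file; see
#'   [validate_pipeline_config()].
#' @param output_dir directory for artifacts (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   paths written.
#' @export
run_pipeline <- function(config, output_dir) {
  config <- validate_pipeline_config(config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  paths <- character(0)
  results <- list(seed = seed)
  p <- function(name) file.path(output_dir, name)

  if (!is.null(config$strains)) {
    st <- config$strains
    sim <- simulate_strain_set(
      hosts = st$hosts %||% c("cat", "dog", "human"),
      n_per_host = st$n_per_host %||% 20,
      L = st$L %||% 5000,
      t_w = st$t_w %||% 0.01, t_b = st$t_b %||% 0.09,
      kappa = st$kappa %||% 2, mixing = st$mixing %||% 0,
      seed = seed
    )
    dm <- k2p_distance_matrix(sim$alignment, min_sites = st$min_sites %||% 100)
    coh <- coherence_score(dm, stats::setNames(sim$alignment$host,
                                               sim$alignment$ids),
                           sgb_id = sim$alignment$sgb_id)
    paths <- c(paths,
               write_fasta(sim$alignment$sequences, p("strains.fasta")),
               write_tsv(sim$truth, p("strain_truth.tsv")),
               write_distance_matrix(dm, p("k2p_distances.tsv")),
               write_tsv(coherence_table(coh), p("coherence.tsv")))
    results$strains <- list(sim = sim, dm = dm, coherence = coh)
  }

  if (!is.null(config$community)) {
    cm <- config$community
    sim <- simulate_abundance_table(
      hosts = cm$hosts %||% c("cat", "dog", "human"),
      n_per_host = cm$n_per_host %||% 20,
      n_taxa = cm$n_taxa %||% 50,
      n_signature = cm$n_signature %||% 5,
      effect = cm$effect %||% 2,
      seed = seed + 1L
    )
    d <- bray_curtis(sim$abundance)
    ord <- pcoa(d, k = cm$axes %||% 2)
    raw_scores <- ord$scores
    if (isTRUE(cm$frequency_correct %||% TRUE)) {
      ord <- frequency_correct(ord, sim$host_of)
    }
    pos <- feature_positions(ord, sim$abundance)
    pm <- permanova(d, sim$host_of,
                    permutations = config$permanova$permutations %||% 999,
                    seed = seed + 2L)
    paths <- c(paths,
               write_tsv(data.frame(sample_id = rownames(sim$abundance),
                                    sim$abundance, check.names = FALSE),
                         p("abundance.tsv")),
               write_tsv(data.frame(axis = seq_along(ord$eigenvalues),
                                    eigenvalue = ord$eigenvalues),
                         p("pcoa_eigenvalues.tsv")),
               write_tsv(data.frame(sample_id = rownames(raw_scores),
                                    raw_scores, check.names = FALSE),
                         p("pcoa_scores_raw.tsv")),
               write_tsv(data.frame(sample_id = rownames(ord$scores),
                                    ord$scores, check.names = FALSE),
                         p("pcoa_scores.tsv")),
               write_tsv(data.frame(taxon = rownames(pos), pos,
                                    check.names = FALSE),
                         p("taxon_positions.tsv")),
               write_tsv(data.frame(factor = "host", R2 = pm$R2,
                                    pseudo_F = pm$pseudo_F, p = pm$p,
                                    n_permutations = pm$n_permutations,
                                    seed = pm$seed),
                         p("permanova.tsv")))
    results$community <- list(sim = sim, ordination = ord,
                              positions = pos, permanova = pm)
  }

  if (!is.null(config$screening) || !is.null(config$arg)) {
    fx <- simulate_screening_fixtures(seed = seed + 3L)
    if (!is.null(config$screening)) {
      mag <- fx$mag
      mag$grade <- classify_mag_quality(mag$completeness, mag$contamination)
      bins <- do.call(rbind, lapply(names(fx$mash_wide), function(q) {
        a <- assign_genome_bin(fx$mash_wide[[q]])
        data.frame(mag_id = q, nearest_bin_id = a$nearest_bin_id,
                   nearest_distance = a$nearest_distance, level = a$level)
      }))
      paths <- c(paths,
                 write_tsv(mag, p("mag_quality.tsv")),
                 write_tsv(bins, p("bin_assignments.tsv")))
      results$screening <- list(mag = mag, bins = bins)
    }
    if (!is.null(config$arg)) {
      retained <- filter_arg_hits(fx$arg_hits,
                                  min_ident = config$arg$min_ident %||% 90,
                                  min_cov = config$arg$min_cov %||% 80)
      paths <- c(paths,
                 write_tsv(data.frame(arg_id = retained), p("arg_retained.tsv")))
      results$arg <- list(hits = fx$arg_hits, retained = retained)
    }
  }

  log <- list(
    package = "strainniche",
    version = as.character(utils::packageVersion("strainniche")),
    r_version = R.version.string,
    seed = seed,
    config = config,
    outputs = as.list(tools::md5sum(paths))
  )
  jsonlite::write_json(log, p("run_log.json"), auto_unbox = TRUE, pretty = TRUE)
  writeLines(c(sprintf("strainniche pipeline, seed %d", seed),
               sprintf("wrote %d artifacts to %s", length(paths), output_dir)),
             p("run_log.txt"))
  invisible(c(results, list(paths = c(paths, p("run_log.json")))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
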