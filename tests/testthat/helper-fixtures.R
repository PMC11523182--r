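# Shared fixtures and independent oracles used across the suite.
# Oracles are deliberately naive (character loops, double loops over group
# sums) and never call the implementation paths they check.

random_dm <- function(n, seed, max_d = 1) {
  set.seed(seed)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0, max_d)
  m <- m + t(m)
  ids <- sprintf("s%02d", seq_len(n))
  dimnames(m) <- list(ids, ids)
  m
}

random_seqs <- function(n, L, seed) {
  set.seed(seed)
  stats::setNames(
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1)),
    sprintf("s%02d", seq_len(n))
  )
}

# site-count oracle: plain character loop
oracle_pair_counts <- function(a, b) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  stopifnot(length(av) == length(bv))
  pur <- c("A", "G")
  n <- 0L; ts <- 0L; tv <- 0L
  for (i in seq_along(av)) {
    x <- av[i]; y <- bv[i]
    if (x %in% c("N", "-") || y %in% c("N", "-")) next
    n <- n + 1L
    if (x == y) next
    if ((x %in% pur) == (y %in% pur)) ts <- ts + 1L else tv <- tv + 1L
  }
  list(n = n, ts = ts, tv = tv)
}

oracle_k2p <- function(n, ts, tv, min_sites = 100) {
  if (n < min_sites) return(NA_real_)
  P <- ts / n; Q <- tv / n
  if ((1 - 2 * P - Q) <= 0 || (1 - 2 * Q) <= 0) return(NA_real_)
  -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
}

# brute-force PERMANOVA sums of squares over explicit pair loops
oracle_permanova_r2 <- function(d, groups) {
  n <- nrow(d)
  ss_tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) ss_tot <- ss_tot + d[i, j]^2
  ss_tot <- ss_tot / n
  ss_w <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    ng <- length(idx)
    if (ng < 2) next
    acc <- 0
    for (ii in seq_len(ng - 1)) for (jj in (ii + 1):ng) {
      acc <- acc + d[idx[ii], idx[jj]]^2
    }
    ss_w <- ss_w + acc / ng
  }
  1 - ss_w / ss_tot
}

host_labels <- function(aln) stats::setNames(aln$host, aln$ids)
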