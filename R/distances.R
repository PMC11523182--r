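# Kimura 2-parameter distances with pairwise deletion.
#
# Internal representation: alignments are encoded as integer matrices
# (A=1, C=2, G=3, T=4; N and '-' -> NA) so per-pair site comparisons are
# vectorised. Purines are {A,G}, pyrimidines {C,T}; a mismatch within a
# class is a transition, across classes a transversion.

encode_alignment <- function(x) {
  seqs <- if (inherits(x, "aligned_strain_set")) x$sequences else toupper(x)
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = NA_integer_, `-` = NA_integer_)
  m <- matrix(NA_integer_, nrow = length(seqs), ncol = nchar(seqs[[1L]]),
              dimnames = list(names(seqs), NULL))
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[[i]], "", fixed = TRUE)[[1L]]
    v <- code[ch]
    if (length(v) != ncol(m)) stop("sequences are not aligned")
    m[i, ] <- v
  }
  m
}

#' Transition/transversion site counts for one aligned pair
#'
#' Compares two aligned sequences site by site under pairwise deletion:
#' sites where either sequence has `N` or `-` are excluded. At comparable
#' sites, mismatches are classified as transitions (A<->G, C<->T) or
#' transversions (purine <-> pyrimidine).
#'
#' @param a,b aligned sequences of equal length: character strings over
#'   `A,C,G,T,N,-` or integer-encoded vectors.
#' @return A list of class `site_counts` with `n` (comparable sites), `ts`
#'   (transitions), `tv` (transversions) and the proportions `P = ts/n`,
#'   `Q = tv/n` (`NaN` when `n = 0`).
#' @export
pair_site_counts <- function(a, b) {
  if (is.character(a)) a <- encode_alignment(stats::setNames(a, "a"))[1L, ]
  if (is.character(b)) b <- encode_alignment(stats::setNames(b, "b"))[1L, ]
  if (length(a) != length(b)) stop("sequences have different lengths")
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  a <- a[ok]; b <- b[ok]
  diff <- a != b
  # purines coded 1 (A) and 3 (G): both odd; pyrimidines 2 (C), 4 (T): even
  same_class <- (a %% 2L) == (b %% 2L)
  ts <- sum(diff & same_class)
  tv <- sum(diff & !same_class)
  structure(list(n = n, ts = ts, tv = tv,
                 P = ts / n, Q = tv / n),
            class = "site_counts")
}

#' Kimura 2-parameter distance from site counts
#'
#' Evaluates the K2P closed form
#' `d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))` with `P` and `Q` the
#' transition and transversion proportions over comparable sites. The
#' distance is saturated (returned as `NA`) when the logarithm's argument
#' is non-positive -- divergence too high for the model to invert -- or
#' when fewer than `min_sites` sites were comparable, where the estimate
#' would be unstable.
#'
#' @param counts a `site_counts` object from [pair_site_counts()], or a
#'   list/vector with elements `n`, `ts`, `tv`.
#' @param min_sites minimum comparable sites for a defined estimate.
#' @return A nonnegative distance in expected substitutions per site, or
#'   `NA` (saturated/undefined).
#' @export
k2p_distance <- function(counts, min_sites = 100) {
  n <- counts[["n"]]; ts <- counts[["ts"]]; tv <- counts[["tv"]]
  if (n < min_sites) return(NA_real_)
  P <- ts / n
  Q <- tv / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  d <- -0.5 * log(w1 * sqrt(w2))
  max(d, 0)
}

#' Pairwise K2P distance matrix for an aligned strain set
#'
#' Computes all pairwise Kimura 2-parameter distances under pairwise
#' deletion. Saturated or short-overlap pairs propagate as `NA` entries;
#' the diagonal is 0 and the matrix is symmetric by construction.
#'
#' @param x an [aligned_strain_set()] (or named character vector of aligned
#'   sequences).
#' @param min_sites passed to [k2p_distance()].
#' @return Symmetric numeric matrix with strain ids as dimnames.
#' @export
k2p_distance_matrix <- function(x, min_sites = 100) {
  m <- encode_alignment(x)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 strains for a distance matrix")
  ids <- rownames(m)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  ok <- !is.na(m)
  cls <- m %% 2L  # 1 = purine, 0 = pyrimidine (NA where uninformative)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      use <- ok[i, ] & ok[j, ]
      a <- m[i, use]; b <- m[j, use]
      diff <- a != b
      ts <- sum(diff & cls[i, use] == cls[j, use])
      tv <- sum(diff) - ts
      d[i, j] <- d[j, i] <- k2p_distance(list(n = sum(use), ts = ts, tv = tv),
                                         min_sites = min_sites)
    }
  }
  d
}
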