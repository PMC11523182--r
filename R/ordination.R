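# Bray-Curtis ordination, frequency-corrected PCoA and one-factor PERMANOVA.

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = 1 - 2 * sum_j min(x_j, y_j) / (sum(x) + sum(y))`, computed
#' over taxon relative abundances.
#'
#' @param x numeric matrix, samples x taxa, nonnegative, each row with a
#'   positive total.
#' @return Symmetric dissimilarity matrix in `[0, 1]` with sample ids as
#'   dimnames.
#' @export
bray_curtis <- function(x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 samples")
  if (any(x < 0)) stop("negative abundances")
  if (any(rowSums(x) <= 0)) {
    stop("all-zero sample(s): ",
         paste(rownames(x)[rowSums(x) <= 0], collapse = ", "))
  }
  d <- as.matrix(vegan::vegdist(x, method = "bray"))
  dimnames(d) <- list(rownames(x), rownames(x))
  d
}

#' Principal coordinates analysis (classical MDS)
#'
#' Gower double-centering of `-d^2/2` followed by eigendecomposition.
#' Sample scores are the eigenvectors scaled by the square root of their
#' eigenvalues; axes with non-positive eigenvalues are dropped (no
#' Lingoes/Cailliez correction).
#'
#' @param d symmetric finite dissimilarity matrix.
#' @param k number of axes requested; if fewer positive axes exist, the
#'   available ones are returned with a warning.
#' @return An object of class `pcoa_result`: list with `eigenvalues`
#'   (positive, non-increasing), `scores` (samples x axes, columns
#'   `PC1..`), `corrected` (logical), `divisor` (`NULL` until
#'   [frequency_correct()] is applied).
#' @export
pcoa <- function(d, k = 2) {
  validate_distance_matrix(d)
  if (anyNA(d)) stop("PCoA requires a finite dissimilarity matrix")
  n <- nrow(d)
  ids <- rownames(d)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- which(e$values > max(tol, 0))
  if (length(pos) == 0L) {
    scores <- matrix(0, n, 1, dimnames = list(ids, "PC1"))
    return(structure(list(eigenvalues = 0, scores = scores,
                          corrected = FALSE, divisor = NULL),
                     class = "pcoa_result"))
  }
  if (k > length(pos)) {
    warning(sprintf("only %d positive axes available (requested %d)",
                    length(pos), k))
    k <- length(pos)
  }
  keep <- pos[seq_len(k)]
  scores <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), nrow = k)
  dimnames(scores) <- list(ids, paste0("PC", seq_len(k)))
  structure(list(eigenvalues = e$values[pos], scores = scores,
                 corrected = FALSE, divisor = NULL),
            class = "pcoa_result")
}

#' Frequency-correct ordination scores by group size
#'
#' Divides every sample's principal coordinate scores by the size of the
#' sample's group, de-emphasising over-represented groups in unbalanced
#' designs (e.g. dividing all cat samples' scores by the number of cat
#' samples). Applying the correction twice is an error.
#'
#' @param ord a `pcoa_result`.
#' @param group_of group label per sample, named by sample id (or parallel
#'   to the score rows).
#' @param group_sizes optional named vector of group sizes; defaults to the
#'   observed group counts in `group_of`.
#' @return The corrected `pcoa_result` (with `corrected = TRUE` and the
#'   per-sample `divisor` recorded).
#' @export
frequency_correct <- function(ord, group_of, group_sizes = NULL) {
  stopifnot(inherits(ord, "pcoa_result"))
  if (isTRUE(ord$corrected)) stop("scores are already frequency-corrected")
  ids <- rownames(ord$scores)
  if (is.null(names(group_of))) {
    if (length(group_of) != length(ids)) {
      stop("'group_of' must be named by sample id or parallel to the scores")
    }
    names(group_of) <- ids
  }
  if (!all(ids %in% names(group_of))) stop("group label missing for some samples")
  group_of <- group_of[ids]
  if (is.null(group_sizes)) {
    tab <- table(group_of)
    group_sizes <- stats::setNames(as.numeric(tab), names(tab))
  }
  if (!all(group_of %in% names(group_sizes))) {
    stop("unknown group: ",
         paste(setdiff(group_of, names(group_sizes)), collapse = ", "))
  }
  div <- group_sizes[group_of]
  if (any(div < 1)) stop("group sizes must be >= 1")
  ord$scores <- ord$scores / div
  ord$corrected <- TRUE
  ord$divisor <- stats::setNames(as.numeric(div), ids)
  ord
}

#' Abundance-weighted taxon positions in an ordination
#'
#' Places each taxon at the abundance-weighted average of the sample
#' scores: `pos[j, k] = sum_i a[i, j] * s[i, k] / sum_i a[i, j]`, using the
#' scores exactly as held in `ord` (corrected if the ordination has been
#' frequency-corrected). A taxon with zero total abundance has an
#' undefined (`NA`) position.
#'
#' @param ord a `pcoa_result`.
#' @param abundance samples x taxa abundance matrix (rows matching the
#'   ordination's samples).
#' @param taxa taxa to place; defaults to all columns.
#' @return Matrix taxa x axes of weighted-average scores.
#' @export
feature_positions <- function(ord, abundance, taxa = colnames(abundance)) {
  stopifnot(inherits(ord, "pcoa_result"))
  ids <- rownames(ord$scores)
  if (!all(ids %in% rownames(abundance))) {
    stop("abundance table is missing ordination samples")
  }
  if (!all(taxa %in% colnames(abundance))) {
    stop("unknown taxa: ", paste(setdiff(taxa, colnames(abundance)), collapse = ", "))
  }
  a <- abundance[ids, taxa, drop = FALSE]
  tot <- colSums(a)
  pos <- t(a) %*% ord$scores / ifelse(tot > 0, tot, NA_real_)
  pos[tot == 0, ] <- NA_real_
  dimnames(pos) <- list(taxa, colnames(ord$scores))
  pos
}

# Sum-of-squares decomposition for a grouping of a distance matrix:
# SS_total = sum_{i<j} d_ij^2 / n; SS_within = sum over groups of the
# analogous within-group term with the group's size as divisor.
permanova_ss <- function(d2, groups) {
  n <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1L) {
      sub <- d2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  c(total = ss_total, within = ss_within)
}

#' One-factor PERMANOVA
#'
#' Permutational multivariate analysis of variance for a single grouping
#' factor on a dissimilarity matrix (Anderson's pseudo-F from distance
#' sums of squares). `R2 = 1 - SS_within / SS_total`;
#' `F = (SS_between / (g - 1)) / (SS_within / (n - g))`. The p-value
#' counts label permutations with `F >= F_observed`:
#' `p = (count + 1) / (n_permutations + 1)`.
#'
#' @param d symmetric finite dissimilarity matrix.
#' @param groups factor/character of group labels, named by sample id or
#'   parallel to the matrix rows; at least two distinct groups.
#' @param permutations number of label permutations (>= 99).
#' @param seed integer seed for the permutation stream (mandatory, for
#'   reproducibility).
#' @return An object of class `permanova_result`: list with `R2`,
#'   `pseudo_F`, `p`, `n_permutations`, `seed`, `n`, `n_groups`.
#' @export
permanova <- function(d, groups, permutations = 999, seed) {
  validate_distance_matrix(d)
  if (anyNA(d)) stop("PERMANOVA requires a finite dissimilarity matrix")
  if (missing(seed)) stop("'seed' is required")
  if (permutations < 99) stop("use at least 99 permutations")
  ids <- rownames(d)
  if (!is.null(names(groups))) {
    if (!all(ids %in% names(groups))) stop("group label missing for some samples")
    groups <- groups[ids]
  } else if (length(groups) != length(ids)) {
    stop("'groups' must be named by sample id or parallel to d")
  }
  groups <- as.character(groups)
  g <- length(unique(groups))
  n <- nrow(d)
  if (g < 2L) stop("need at least 2 groups")
  d2 <- d^2
  ss <- permanova_ss(d2, groups)
  ss_between <- ss[["total"]] - ss[["within"]]
  R2 <- ss_between / ss[["total"]]
  Fobs <- (ss_between / (g - 1)) / (ss[["within"]] / (n - g))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  count <- 0L
  for (b in seq_len(permutations)) {
    gp <- sample(groups)
    ssp <- permanova_ss(d2, gp)
    ssb <- ssp[["total"]] - ssp[["within"]]
    Fp <- (ssb / (g - 1)) / (ssp[["within"]] / (n - g))
    if (Fp >= Fobs) count <- count + 1L
  }
  structure(list(R2 = R2, pseudo_F = Fobs,
                 p = (count + 1) / (permutations + 1),
                 n_permutations = permutations, seed = seed,
                 n = n, n_groups = g),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA (one factor): n = %d, groups = %d\n", x$n, x$n_groups))
  cat(sprintf("  R2 = %.4f  pseudo-F = %.3f  p = %.4g (%d permutations, seed %d)\n",
              x$R2, x$pseudo_F, x$p, x$n_permutations, x$seed))
  invisible(x)
}

# Save/restore the global RNG state so seeded routines do not perturb the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
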