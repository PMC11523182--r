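#' Construct an aligned strain set
#'
#' Container for an equal-length DNA alignment of per-sample consensus
#' strains with a host label attached to every strain. Sequences are stored
#' upper-case over the alphabet `A`, `C`, `G`, `T`, `N`, `-`; `N` and `-`
#' both mean "no information at this site" and are excluded pair-by-pair
#' when distances are computed (pairwise deletion). IUPAC ambiguity codes
#' other than `N` are rejected rather than silently resolved, since
#' resolution would bias transition/transversion proportions.
#'
#' @param sequences named character vector of aligned sequences; names are
#'   the strain (sample) identifiers and must be unique.
#' @param host character vector of host labels, either named by strain id or
#'   parallel to `sequences`.
#' @param sgb_id optional label for the species-level genome bin (SGB) the
#'   alignment belongs to.
#' @return An object of class `aligned_strain_set` with elements `ids`,
#'   `sequences` (named, upper-case), `host` (named), `sgb_id` and `L`
#'   (alignment length).
#' @export
aligned_strain_set <- function(sequences, host, sgb_id = NA_character_) {
  if (is.null(names(sequences)) || anyNA(names(sequences)) ||
      any(names(sequences) == "")) {
    stop("'sequences' must be a named character vector (strain ids)")
  }
  ids <- names(sequences)
  if (anyDuplicated(ids)) {
    stop("duplicated strain ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  sequences <- toupper(as.character(sequences))
  names(sequences) <- ids
  lens <- nchar(sequences)
  if (length(sequences) < 1L || any(lens < 1L)) {
    stop("alignment must contain at least one non-empty sequence")
  }
  if (length(unique(lens)) != 1L) {
    stop("sequences are not aligned: lengths ", paste(unique(lens), collapse = ", "))
  }
  bad <- grepl("[^ACGTN-]", sequences)
  if (any(bad)) {
    stop("illegal characters (only A,C,G,T,N,- allowed) in: ",
         paste(ids[bad], collapse = ", "))
  }
  if (is.null(names(host))) {
    if (length(host) != length(sequences)) {
      stop("'host' must be named by strain id or parallel to 'sequences'")
    }
    names(host) <- ids
  }
  if (!all(ids %in% names(host))) {
    stop("missing host label for: ",
         paste(setdiff(ids, names(host)), collapse = ", "))
  }
  host <- host[ids]
  if (anyNA(host)) stop("host labels must be non-missing")
  structure(
    list(ids = ids, sequences = sequences, host = as.character(host),
         sgb_id = sgb_id, L = lens[[1L]]),
    class = "aligned_strain_set"
  )
}

#' @export
print.aligned_strain_set <- function(x, ...) {
  cat("Aligned strain set", if (!is.na(x$sgb_id)) paste0("(", x$sgb_id, ")"), "\n")
  cat("  strains:", length(x$ids), " sites:", x$L, "\n")
  cat("  hosts:  ", paste(sprintf("%s=%d", names(table(x$host)), table(x$host)),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Read an aligned FASTA of consensus strains
#'
#' Reads a multiple sequence alignment in FASTA format (one record per
#' sample-consensus strain, as produced by strain-level profilers) and joins
#' host labels from a sample metadata table. The record identifier is the
#' header text up to the first whitespace, matching the one-strain-per-sample
#' convention.
#'
#' @param path path to an aligned FASTA file (optionally gzipped).
#' @param metadata a sample table as returned by [read_sample_table()], or
#'   any data frame with columns `sample_id` and `host`.
#' @param sgb_id optional SGB label stored on the result.
#' @return An [aligned_strain_set()].
#' @export
read_strain_alignment <- function(path, metadata, sgb_id = NA_character_) {
  stopifnot(is.data.frame(metadata),
            all(c("sample_id", "host") %in% names(metadata)))
  seqs <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  x <- toupper(as.character(seqs))
  names(x) <- ids
  unknown <- setdiff(ids, metadata$sample_id)
  if (length(unknown) > 0L) {
    stop("alignment records not found in metadata: ",
         paste(unknown, collapse = ", "))
  }
  host <- stats::setNames(as.character(metadata$host), metadata$sample_id)
  aligned_strain_set(x, host[ids], sgb_id = sgb_id)
}

#' Read a sample metadata table
#'
#' Tab-delimited with a header; requires columns `sample_id` and `host`,
#' and optionally carries `study`, `housing` and `age_years`.
#'
#' @param path path to a TSV file.
#' @return A data frame with one row per sample.
#' @export
read_sample_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("sample_id", "host") %in% names(x))) {
    stop("sample table needs columns 'sample_id' and 'host'")
  }
  if (anyDuplicated(x$sample_id)) stop("duplicated sample_id in sample table")
  if (anyNA(x$host) || any(x$host == "")) stop("missing host label in sample table")
  if ("age_years" %in% names(x)) {
    age <- x$age_years
    if (any(!is.na(age) & age < 0)) stop("negative age_years in sample table")
  }
  x
}

#' Read a relative-abundance table
#'
#' Tab-delimited, samples in rows (first column = sample id), taxa in
#' columns. Empty cells are read as 0. Values must be nonnegative and each
#' row must sum to at most 1 (plus a small tolerance), i.e. relative
#' abundances.
#'
#' @param path path to a TSV file.
#' @param tol tolerance on row sums exceeding 1.
#' @return Numeric matrix, samples x taxa, with sample ids as rownames.
#' @export
read_abundance_table <- function(path, tol = 1e-6) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(x[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicated sample rows: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  m <- as.matrix(x[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  m[is.na(m)] <- 0
  if (any(m < 0)) stop("negative abundance values")
  rs <- rowSums(m)
  if (any(rs > 1 + tol)) {
    stop("row sums exceed 1 + tol for: ",
         paste(ids[rs > 1 + tol], collapse = ", "))
  }
  rownames(m) <- ids
  m
}

#' Write a distance matrix to a labelled square TSV
#'
#' Writes the full square matrix with an id header row and id first column,
#' six decimal places, scaled by `scale` (use `scale = 100` for the
#' per-100-bases convention of EMBOSS distmat output). Saturated/undefined
#' entries (`NA`) are written as the literal `NA`.
#'
#' @param dm symmetric numeric matrix with identical row/column names; `NA`
#'   marks a saturated or undefined distance.
#' @param path output path.
#' @param scale positive multiplier applied on write (1 = substitutions per
#'   site; 100 = per 100 sites).
#' @return `path`, invisibly.
#' @seealso [read_distance_matrix()]
#' @export
write_distance_matrix <- function(dm, path, scale = 1) {
  validate_distance_matrix(dm)
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0)
  ids <- rownames(dm)
  out <- dm * scale
  txt <- format(round(out, 6), nsmall = 6, trim = TRUE, scientific = FALSE)
  txt[is.na(out)] <- "NA"
  lines <- c(
    paste(c("id", ids), collapse = "\t"),
    vapply(seq_along(ids), function(i) {
      paste(c(ids[i], txt[i, ]), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a labelled distance matrix TSV
#'
#' Reads the square format written by [write_distance_matrix()]. A
#' triangular file (EMBOSS-style, with one empty half) is accepted and
#' mirrored into the canonical full square form. `NA` cells become `NA`
#' (the saturated marker).
#'
#' @param path input path.
#' @param scale positive divisor applied on read (matching the `scale` the
#'   file was written with).
#' @return Symmetric numeric matrix with a zero diagonal.
#' @export
read_distance_matrix <- function(path, scale = 1) {
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0)
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                         row.names = 1L)
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m)) stop("distance matrix is not square")
  rownames(m) <- rownames(x)
  colnames(m) <- colnames(x)
  if (!identical(rownames(m), colnames(m))) {
    stop("row and column ids differ in distance matrix")
  }
  m <- m / scale
  # mirror a triangular dialect: a cell empty on one side only is copied over
  lower <- m[lower.tri(m)]
  upper <- t(m)[lower.tri(m)]
  fill <- is.na(lower) & !is.na(upper)
  lower[fill] <- upper[fill]
  fill2 <- is.na(upper) & !is.na(lower)
  upper[fill2] <- lower[fill2]
  m[lower.tri(m)] <- lower
  mt <- t(m)
  mt[lower.tri(mt)] <- upper
  m <- t(mt)
  diag(m) <- 0
  validate_distance_matrix(m, tol = 1e-9)
  m
}

#' Validate a distance matrix
#'
#' Checks the invariants of the canonical distance structure: square,
#' identical row/column ids, symmetric up to `tol`, zero diagonal, finite
#' entries nonnegative (`NA` allowed as the saturated marker).
#'
#' @param dm numeric matrix.
#' @param tol symmetry tolerance.
#' @return `dm`, invisibly.
#' @export
validate_distance_matrix <- function(dm, tol = 1e-8) {
  if (!is.matrix(dm) || !is.numeric(dm)) stop("distance matrix must be a numeric matrix")
  if (nrow(dm) != ncol(dm)) stop("distance matrix is not square")
  if (is.null(rownames(dm)) || !identical(rownames(dm), colnames(dm))) {
    stop("distance matrix must have identical row and column names")
  }
  if (any(abs(diag(dm)) > tol, na.rm = TRUE) || anyNA(diag(dm))) {
    stop("distance matrix diagonal must be 0")
  }
  a <- dm[lower.tri(dm)]
  b <- t(dm)[lower.tri(dm)]
  same <- (is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & abs(a - b) <= tol)
  if (!all(same)) stop("distance matrix is not symmetric")
  if (any(dm < 0, na.rm = TRUE)) stop("negative distances")
  invisible(dm)
}
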