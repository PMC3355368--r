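# Proteomes and probe-set frequency patterns: the normalized per-gene probe
# occurrence frequencies that encode each organism, plus the pattern-level
# correlation and the column standardization used for visual comparison.

#' Construct a proteome
#'
#' @param organism_id Organism identifier (row label in frequency matrices).
#' @param proteins Named character vector of amino-acid sequences; names are
#'   protein ids and must be unique.  Sequences are uppercased.
#' @param gene_count Number of protein-coding genes used as the normalization
#'   denominator; defaults to the number of proteins.
#' @return An object of class `proteome`.
#' @export
proteome <- function(organism_id, proteins, gene_count = length(proteins)) {
  stopifnot(is.character(proteins), length(proteins) >= 1)
  if (is.null(names(proteins)) || anyNA(names(proteins)) ||
      any(!nzchar(names(proteins)))) {
    names(proteins) <- paste0("protein_", seq_along(proteins))
  }
  if (anyDuplicated(names(proteins))) {
    stop("duplicate protein ids in proteome ", organism_id, call. = FALSE)
  }
  gene_count <- as.integer(gene_count)
  stopifnot(gene_count >= 1)
  structure(list(organism_id = as.character(organism_id),
                 proteins = toupper(proteins),
                 gene_count = gene_count),
            class = "proteome")
}

#' @export
print.proteome <- function(x, ...) {
  cat(sprintf("<proteome %s> %d proteins, %d protein-coding genes\n",
              x$organism_id, length(x$proteins), x$gene_count))
  invisible(x)
}

#' Read a proteome from a multi-FASTA amino-acid file
#'
#' @param path FASTA file of amino-acid sequences.
#' @param organism_id Organism identifier; defaults to the file name without
#'   extension.
#' @param gene_count Number of protein-coding genes; defaults to the number
#'   of FASTA records when no annotation is available.
#' @param strict Error on duplicate record ids (otherwise they are made
#'   unique with a warning).
#' @return A `proteome`.
#' @export
read_proteome <- function(path, organism_id = NULL, gene_count = NULL,
                          strict = FALSE) {
  if (is.null(organism_id)) {
    organism_id <- sub("\\.[^.]*$", "", basename(path))
  }
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  seqs <- toupper(as.character(aa))
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids)) {
    if (strict) stop("duplicate record ids in ", path, call. = FALSE)
    warning("duplicate record ids in ", path, "; made unique", call. = FALSE)
    ids <- make.unique(ids)
  }
  names(seqs) <- ids
  if (is.null(gene_count)) gene_count <- length(seqs)
  proteome(organism_id, seqs, gene_count)
}

#' Write a proteome to FASTA
#'
#' @param p A `proteome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(p, path) {
  stopifnot(inherits(p, "proteome"))
  aa <- Biostrings::AAStringSet(p$proteins)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

# Per-protein occurrence counts: proteins x probes integer matrix.  The
# truncation experiments subset its rows, so probe scanning happens once per
# proteome no matter how many truncations are drawn.
probe_count_table <- function(probes, p, wildcard_nonstandard = TRUE) {
  stopifnot(inherits(p, "proteome"), length(probes) >= 1)
  counts <- vapply(probes, function(pr) {
    vapply(p$proteins, count_occurrences, integer(1), probe = pr,
           wildcard_nonstandard = wildcard_nonstandard, USE.NAMES = FALSE)
  }, integer(length(p$proteins)))
  counts <- matrix(counts, nrow = length(p$proteins),
                   dimnames = list(names(p$proteins), probe_ids(probes)))
  counts
}

probe_ids <- function(probes) {
  ids <- vapply(probes, function(p) p$id, character(1))
  blank <- !nzchar(ids)
  ids[blank] <- paste0("probe_", which(blank))
  make.unique(ids)
}

#' Normalized frequency of one probe in a proteome
#'
#' Total occurrence count of the probe across all proteins (overlapping
#' matches included), divided by the proteome's number of protein-coding
#' genes.
#'
#' @param probe A `probe`.
#' @param p A `proteome`.
#' @param wildcard_nonstandard Passed to [count_occurrences()].
#' @return Non-negative real.
#' @export
probe_frequency <- function(probe, p, wildcard_nonstandard = TRUE) {
  stopifnot(inherits(p, "proteome"))
  total <- sum(vapply(p$proteins, count_occurrences, integer(1), probe = probe,
                      wildcard_nonstandard = wildcard_nonstandard))
  total / p$gene_count
}

#' Probe-set frequency pattern of a proteome
#'
#' The vector of normalized frequencies of every probe in the set, aligned to
#' the probe order.  Zero-frequency probes are retained.
#'
#' @param probes List of `probe` objects.
#' @param p A `proteome`.
#' @param wildcard_nonstandard Passed to [count_occurrences()].
#' @return Named numeric vector (names are probe ids).
#' @export
frequency_pattern <- function(probes, p, wildcard_nonstandard = TRUE) {
  counts <- probe_count_table(probes, p, wildcard_nonstandard)
  colSums(counts) / p$gene_count
}

#' Probe-set frequency matrix of several proteomes
#'
#' @param probes List of `probe` objects (columns).
#' @param proteomes List of `proteome` objects (rows); organism ids must be
#'   unique.
#' @param wildcard_nonstandard Passed to [count_occurrences()].
#' @return Numeric matrix, rows named by organism id, columns by probe id.
#' @export
build_matrix <- function(probes, proteomes, wildcard_nonstandard = TRUE) {
  stopifnot(length(proteomes) >= 1)
  ids <- vapply(proteomes, function(p) p$organism_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate organism ids", call. = FALSE)
  rows <- lapply(proteomes, frequency_pattern, probes = probes,
                 wildcard_nonstandard = wildcard_nonstandard)
  m <- do.call(rbind, rows)
  rownames(m) <- ids
  m
}

#' Correlation between two probe-set frequency patterns
#'
#' Pearson product-moment correlation coefficient of two aligned frequency
#' vectors, the similarity used to compare probe-set patterns.
#'
#' @param a,b Numeric vectors of equal length (>= 2).
#' @return Real in \[-1, 1\].
#' @export
pattern_cc <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined: zero-variance frequency pattern",
         call. = FALSE)
  }
  stats::cor(a, b)
}

#' Standardize a frequency matrix column-wise
#'
#' Replaces every column by its z-scores across organisms, \eqn{(f - \mu) /
#' \sigma}, with the population (divide-by-N) standard deviation so that
#' standardized figures are reproducible bit-for-bit.  Constant columns
#' (sigma = 0) map to all zeros.
#'
#' @param m Frequency matrix with >= 2 rows (organisms).
#' @return Matrix of the same shape and dimnames.
#' @export
standardize_matrix <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2) {
    stop("standardization needs at least 2 organisms", call. = FALSE)
  }
  mu <- colMeans(m)
  sigma <- sqrt(colMeans(sweep(m, 2, mu)^2))
  out <- sweep(m, 2, mu)
  nz <- sigma > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, sigma[nz], "/")
  out[, !nz] <- 0
  out
}

#' Write / read a frequency matrix as TSV
#'
#' The dialect is a header row of probe ids preceded by an `organism_id`
#' column, then one row per organism.  [read_matrix_tsv()] inverts
#' [write_matrix_tsv()] exactly.
#'
#' @param m Numeric matrix with organism row names and probe column names.
#' @param path Output path.
#' @return `path` invisibly (write) / the matrix (read).
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(organism_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
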