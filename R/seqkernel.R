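#' BLOSUM62 substitution matrix
#'
#' Returns the BLOSUM62 scoring matrix shipped with Biostrings, cached after
#' first use. This is the default scoring for [align_pair()], mirroring blastp
#' defaults (BLOSUM62, gap existence 11, gap extension 1).
#'
#' @return Integer matrix with amino-acid row/column names (includes `X`).
#' @export
blosum62 <- function() {
  if (is.null(.stalkscan_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .stalkscan_env$blosum62 <- e$BLOSUM62
  }
  .stalkscan_env$blosum62
}

#' Read a substitution matrix from an NCBI-style text file
#'
#' Parses the plain-text matrix format used by BLAST (`#` comments, one header
#' row of residue letters, one labelled row per residue).
#'
#' @param path Path to the matrix file.
#' @return Numeric matrix with residue dimnames.
#' @export
read_substitution_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  mat <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(length(header))))
  rownames(mat) <- vapply(rows, `[`, character(1), 1)
  colnames(mat) <- header
  mat
}

#' Align two protein sequences
#'
#' Optimal global alignment with affine gap penalties and free terminal gaps
#' (Gotoh algorithm), the pipeline's stand-in for blastp. Percent identity is
#' the fraction of identical residues over aligned columns of the core region
#' (terminal gap columns are excluded from the denominator; internal gap
#' columns count as mismatches). Coverage is the percentage of each sequence's
#' residues lying inside the core aligned region. Tie-breaking in the
#' traceback is deterministic: diagonal > up > left, and gap closure is
#' preferred over extension.
#'
#' Non-standard residue letters (B, Z, J, U, O, ...) are mapped to `X`,
#' scored by the matrix's `X` column, and never counted as identities.
#'
#' @param a,b Protein sequences (single strings), non-empty.
#' @param submat Substitution matrix; default [blosum62()].
#' @param gap_open,gap_extend Affine gap penalties; a gap of length L costs
#'   `gap_open + gap_extend * L`. Defaults 11 and 1 (blastp defaults).
#' @param alignment If `TRUE`, also return the padded aligned strings
#'   (terminal gaps shown as `-`).
#' @return An object of class `alignment_stats`: list with `score`, `pid`,
#'   `query_cov`, `subject_cov`, `aligned_cols`, `n_ident` (and `aln_a`,
#'   `aln_b` when `alignment = TRUE`).
#' @examples
#' align_pair("ACDEFGHIK", "ACDEFGHIR")$pid # 8/9 = 88.9
#' @export
align_pair <- function(a, b, submat = blosum62(), gap_open = 11,
                       gap_extend = 1, alignment = FALSE) {
  stopifnot(is.character(a), is.character(b), length(a) == 1, length(b) == 1)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  res <- align_pair_cpp(a, b, submat, gap_open, gap_extend, alignment)
  structure(res, class = "alignment_stats")
}

#' @export
print.alignment_stats <- function(x, ...) {
  cat(sprintf("alignment: score %.1f, pid %.2f%%, cov %.1f/%.1f%%, %d cols\n",
              x$score, x$pid, x$query_cov, x$subject_cov, x$aligned_cols))
  invisible(x)
}

#' Batch alignment statistics for indexed sequence pairs
#'
#' Vectorised form of [align_pair()] over pairs `(ai[p], bi[p])` of `seqs`,
#' used by the graph-building and AAI stages.
#'
#' @param seqs Character vector of protein sequences.
#' @param ai,bi Integer indices into `seqs` (1-based), equal length.
#' @inheritParams align_pair
#' @return data.frame with columns `i`, `j`, `score`, `pid`, `query_cov`,
#'   `subject_cov`, `aligned_cols`, `n_ident`.
#' @export
align_stats <- function(seqs, ai, bi, submat = blosum62(), gap_open = 11,
                        gap_extend = 1) {
  if (length(ai) == 0) {
    return(data.frame(i = integer(), j = integer(), score = numeric(),
                      pid = numeric(), query_cov = numeric(),
                      subject_cov = numeric(), aligned_cols = numeric(),
                      n_ident = numeric()))
  }
  m <- align_stats_batch_cpp(seqs, as.integer(ai), as.integer(bi), submat,
                             gap_open, gap_extend)
  cbind(data.frame(i = as.integer(ai), j = as.integer(bi)), as.data.frame(m))
}

#' k-mer prescreen for a sequence pair
#'
#' Fast gate before full alignment: `TRUE` when the two sequences share at
#' least `min_shared` distinct k-mers. Never `FALSE` for identical sequences
#' when `min_shared <= nchar - k + 1`.
#'
#' @param a,b Protein sequences.
#' @param k k-mer size (>= 3).
#' @param min_shared Minimum number of shared distinct k-mers.
#' @return Logical scalar.
#' @export
kmer_prescreen <- function(a, b, k = 4, min_shared = 1) {
  stopifnot(k >= 3)
  shared_kmer_count_cpp(a, b, as.integer(k)) >= min_shared
}

# All candidate pairs among seqs sharing >= min_shared distinct k-mers
# (inverted-index pass in C++). Returns data.frame(i, j, shared) with i < j.
candidate_pairs <- function(seqs, k = 4, min_shared = 1) {
  m <- kmer_candidate_pairs_cpp(seqs, as.integer(k), as.integer(min_shared))
  as.data.frame(m)
}

# Ungapped identity of equal-length sequences (used by the truth ledger)
hamming_pid <- function(a, b) hamming_pid_cpp(a, b)
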