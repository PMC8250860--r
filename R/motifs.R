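# Literal short-motif scanning (c-di-GMP binding and glycosyltransferase
# motifs), center-star multiple alignment, and identical-column counting.

STANDARD_AA <- "ACDEFGHIKLMNPQRSTVWY"

#' Built-in short protein motifs
#'
#' The c-di-GMP binding motifs RxxD and RxxxR and the glycosyltransferase
#' motifs QxxRW, DxD and TED. Motif letters are standard IUPAC one-letter
#' amino-acid codes (R arginine, Q glutamine, D aspartate, T threonine,
#' E glutamate, W tryptophan); `x` matches any of the 20 standard residues
#' but never a gap.
#'
#' @return data.frame with columns `name`, `pattern`, `length`.
#' @export
motif_patterns <- function() {
  data.frame(name = c("RxxD", "RxxxR", "QxxRW", "DxD", "TED"),
             pattern = c("RxxD", "RxxxR", "QxxRW", "DxD", "TED"),
             length = c(4L, 5L, 5L, 3L, 3L),
             stringsAsFactors = FALSE)
}

# compile a motif pattern into an overlap-reporting regex
motif_regex <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  body <- paste(vapply(chars, function(c)
    if (c == "x") paste0("[", STANDARD_AA, "]") else c, character(1)),
    collapse = "")
  paste0("(?=", body, ")")
}

#' Scan a protein sequence for literal motifs
#'
#' Reports all occurrences, including overlapping ones (e.g. TED and DxD can
#' overlap), as 1-based inclusive residue positions on the ungapped sequence,
#' sorted by start then motif name.
#'
#' @param seq Protein sequence (single string, non-empty).
#' @param patterns Motif table as from [motif_patterns()] (columns `name`,
#'   `pattern`, `length`).
#' @param protein_id Optional id recorded in the output.
#' @return data.frame with columns `protein_id`, `motif`, `start`, `end`,
#'   `match`.
#' @export
scan_motifs <- function(seq, patterns = motif_patterns(), protein_id = NA_character_) {
  stopifnot(is.character(seq), length(seq) == 1, nzchar(seq))
  seq <- toupper(seq)
  hits <- list()
  for (r in seq_len(nrow(patterns))) {
    m <- gregexpr(motif_regex(patterns$pattern[r]), seq, perl = TRUE)[[1]]
    starts <- as.integer(m)
    starts <- starts[starts > 0]
    if (length(starts)) {
      len <- patterns$length[r]
      hits[[length(hits) + 1]] <- data.frame(
        protein_id = protein_id, motif = patterns$name[r], start = starts,
        end = starts + len - 1L,
        match = substring(seq, starts, starts + len - 1L))
    }
  }
  if (!length(hits))
    return(data.frame(protein_id = character(), motif = character(),
                      start = integer(), end = integer(), match = character()))
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Center-star multiple sequence alignment
#'
#' Small-scale MSA for conserved-residue counting: the center is the sequence
#' maximizing the summed pairwise alignment score against all others (ties by
#' input order); every other sequence is aligned to the center pairwise and
#' gaps are merged under "once a gap, always a gap".
#'
#' @param seqs Character vector of protein sequences (>= 2); names become row
#'   ids.
#' @param submat Substitution matrix.
#' @param gap_open,gap_extend Affine gap penalties (see [align_pair()]).
#' @return Object of class `msa`: list with `ids`, `rows` (equal-length
#'   aligned strings, `-` for gaps), `center` (index of the center sequence).
#' @export
center_star_msa <- function(seqs, submat = blosum62(), gap_open = 11,
                            gap_extend = 1) {
  n <- length(seqs)
  stopifnot(n >= 2, all(nzchar(seqs)))
  ids <- if (is.null(names(seqs))) paste0("seq", seq_len(n)) else names(seqs)
  pair_idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  st <- align_stats(unname(seqs), pair_idx[, 1], pair_idx[, 2], submat = submat,
                    gap_open = gap_open, gap_extend = gap_extend)
  total <- numeric(n)
  for (r in seq_len(nrow(st))) {
    total[st$i[r]] <- total[st$i[r]] + st$score[r]
    total[st$j[r]] <- total[st$j[r]] + st$score[r]
  }
  center <- which.max(total)
  others <- setdiff(seq_len(n), center)
  alns <- lapply(others, function(i)
    align_pair(seqs[[center]], seqs[[i]], submat = submat, gap_open = gap_open,
               gap_extend = gap_extend, alignment = TRUE))
  # gap counts before each center residue (slots 1..nc+1), per alignment
  nc <- nchar(seqs[[center]])
  gap_profile <- function(aln_center) {
    chars <- strsplit(aln_center, "")[[1]]
    slots <- integer(nc + 1)
    pos <- 1L
    for (ch in chars) {
      if (ch == "-") slots[pos] <- slots[pos] + 1L else pos <- pos + 1L
    }
    slots
  }
  profiles <- lapply(alns, function(a) gap_profile(a$aln_a))
  master <- Reduce(pmax, profiles, integer(nc + 1))
  # expand an aligned pair (center row, other row) to the master gap profile
  expand <- function(aln_center, aln_other, prof) {
    ca <- strsplit(aln_center, "")[[1]]
    ot <- strsplit(aln_other, "")[[1]]
    out <- character(0)
    pos <- 1L # current slot
    i <- 1L
    while (pos <= nc + 1L) {
      seen <- 0L
      while (i <= length(ca) && ca[i] == "-") {
        out <- c(out, ot[i]); seen <- seen + 1L; i <- i + 1L
      }
      out <- c(out, rep("-", master[pos] - seen))
      if (pos <= nc) { out <- c(out, ot[i]); i <- i + 1L }
      pos <- pos + 1L
    }
    paste(out, collapse = "")
  }
  center_row <- {
    res <- character(0)
    cseq <- strsplit(seqs[[center]], "")[[1]]
    for (pos in seq_len(nc + 1)) {
      res <- c(res, rep("-", master[pos]))
      if (pos <= nc) res <- c(res, cseq[pos])
    }
    paste(res, collapse = "")
  }
  rows <- character(n)
  rows[center] <- center_row
  for (k in seq_along(others))
    rows[others[k]] <- expand(alns[[k]]$aln_a, alns[[k]]$aln_b, profiles[[k]])
  stopifnot(length(unique(nchar(rows))) == 1)
  structure(list(ids = ids, rows = setNames(rows, ids), center = center),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("MSA: %d sequences x %d columns (center: %s)\n",
              length(x$rows), nchar(x$rows[1]), x$ids[x$center]))
  invisible(x)
}

#' Remove gaps from MSA rows
#' @param msa An [center_star_msa()] result.
#' @return Character vector of ungapped sequences.
#' @export
ungap_msa <- function(msa) {
  setNames(gsub("-", "", msa$rows, fixed = TRUE), msa$ids)
}

#' Count identical (fully conserved, gap-free) MSA columns
#'
#' @param msa An [center_star_msa()] result (or any list with equal-length
#'   `rows`).
#' @return List with `count` and `positions` (1-based column indices).
#' @export
identical_columns <- function(msa) {
  mat <- do.call(rbind, strsplit(unname(msa$rows), ""))
  same <- apply(mat, 2, function(col)
    all(col != "-") && length(unique(col)) == 1)
  list(count = sum(same), positions = which(same))
}

#' Map ungapped residue positions into MSA column space
#'
#' @param msa An [center_star_msa()] result.
#' @param row Row index or id.
#' @param positions 1-based residue positions on the ungapped sequence.
#' @return Integer vector of MSA column indices.
#' @export
msa_columns_of <- function(msa, row, positions) {
  chars <- strsplit(unname(msa$rows[row]), "")[[1]]
  res_cols <- which(chars != "-")
  stopifnot(all(positions >= 1 & positions <= length(res_cols)))
  res_cols[positions]
}

#' Write motif hits for a set of proteins as TSV
#' @param proteins Named character vector of sequences.
#' @param path Output path.
#' @param patterns Motif table (default [motif_patterns()]).
#' @return The hit data.frame, invisibly.
#' @export
write_motif_tsv <- function(proteins, path, patterns = motif_patterns()) {
  hits <- do.call(rbind, lapply(names(proteins), function(id)
    scan_motifs(proteins[[id]], patterns, protein_id = id)))
  if (is.null(hits))
    hits <- data.frame(protein_id = character(), motif = character(),
                       start = integer(), end = integer(), match = character())
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(hits)
}
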