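# The core inference: gene families present in every trait-positive genome
# and absent from every trait-negative genome, with coverage auditing and
# sub-threshold homolog follow-up.

#' Extract trait-unique gene families
#'
#' Families with at least one member in every positive (stalk) genome and
#' zero members in every negative (stalk-less) genome, at the pan-genome's
#' clustering threshold. Absence means zero members at that threshold; use
#' [distant_homolog_search()] to recover sub-threshold homologs afterwards.
#'
#' @param pan A [build_pangenome()] result.
#' @param traits A [trait_table()]; every pan genome must be labelled.
#' @return Object of class `trait_unique_set`: list with `threshold`,
#'   `family_ids`, `gene_count`, `members` (family -> genome -> gene ids).
#' @export
trait_unique_families <- function(pan, traits) {
  missing <- setdiff(pan$genomes, names(traits$assignments))
  if (length(missing))
    stop("genome(s) missing from trait table: ", paste(missing, collapse = ", "))
  pos <- intersect(pan$genomes, traits$positives)
  neg <- intersect(pan$genomes, traits$negatives)
  P <- pan$matrix > 0
  in_all_pos <- colSums(P[pos, , drop = FALSE]) == length(pos)
  in_no_neg <- colSums(P[neg, , drop = FALSE]) == 0
  fam_ids <- colnames(pan$matrix)[in_all_pos & in_no_neg]
  fams <- pan$families[vapply(pan$families, `[[`, character(1), "family_id")
                       %in% fam_ids]
  members <- setNames(lapply(fams, `[[`, "members"),
                      vapply(fams, `[[`, character(1), "family_id"))
  # hard invariant: no returned family may touch a negative genome
  for (f in members)
    stopifnot(all(lengths(f[neg]) == 0), all(lengths(f[pos]) > 0))
  structure(list(threshold = pan$threshold, family_ids = fam_ids,
                 gene_count = sum(unlist(lapply(members, lengths))),
                 members = members),
            class = "trait_unique_set")
}

#' @export
print.trait_unique_set <- function(x, ...) {
  cat(sprintf("trait-unique set at %g%%: %d families, %d genes\n",
              x$threshold, length(x$family_ids), x$gene_count))
  invisible(x)
}

#' Screen for trait-unique families across an identity threshold sweep
#'
#' Builds one pan-genome per threshold (alignments computed once and shared)
#' and runs [trait_unique_families()] on each, then reports the union of
#' families found at any threshold within `union_range` (families are
#' deduplicated across thresholds by their member gene sets; gene and family
#' counts are reported per threshold and for the union).
#'
#' @param genomes List of [new_genome()] objects.
#' @param traits A [trait_table()].
#' @param thresholds Percent identity thresholds (default 30..90 by 10).
#' @param union_range Inclusive range of thresholds entering the union report
#'   (default `c(30, 80)`, excluding the 90% tier).
#' @param min_len,pre_pid,pre_cov,min_cov,inflation,submat Passed to
#'   [build_pangenome()] / [pangenome_precompute()].
#' @return List with `sets` (threshold -> `trait_unique_set`), `pans`
#'   (threshold -> pan-genome), `union` (data.frame: one row per distinct
#'   gene set: `gene_ids`, `thresholds`, `n_genes`) and `union_gene_ids`.
#' @export
threshold_sweep <- function(genomes, traits, thresholds = seq(30, 90, by = 10),
                            union_range = c(30, 80), min_len = 40,
                            pre_pid = 95, pre_cov = 90, min_cov = 40,
                            inflation = 1.5, submat = blosum62()) {
  stopifnot(all(thresholds >= 0 & thresholds <= 100))
  thresholds <- sort(thresholds)
  cache <- pangenome_precompute(genomes, min_len = min_len, pre_pid = pre_pid,
                                pre_cov = pre_cov, submat = submat)
  pans <- lapply(thresholds, function(th)
    build_pangenome(genomes, min_pid = th, min_cov = min_cov,
                    inflation = inflation, submat = submat, cache = cache))
  names(pans) <- as.character(thresholds)
  sets <- lapply(pans, trait_unique_families, traits = traits)
  in_union <- thresholds >= union_range[1] & thresholds <= union_range[2]
  seen <- list()
  for (th in as.character(thresholds[in_union])) {
    for (fid in sets[[th]]$family_ids) {
      genes <- sort(unlist(sets[[th]]$members[[fid]], use.names = FALSE))
      key <- paste(genes, collapse = ";")
      if (is.null(seen[[key]]))
        seen[[key]] <- list(gene_ids = genes, thresholds = th)
      else seen[[key]]$thresholds <- c(seen[[key]]$thresholds, th)
    }
  }
  union_df <- data.frame(
    gene_ids = vapply(seen, function(x) paste(x$gene_ids, collapse = ";"),
                      character(1)),
    thresholds = vapply(seen, function(x) paste(x$thresholds, collapse = ","),
                        character(1)),
    n_genes = vapply(seen, function(x) length(x$gene_ids), integer(1)),
    row.names = NULL)
  list(sets = sets, pans = pans, union = union_df,
       union_gene_ids = sort(unique(unlist(lapply(seen, `[[`, "gene_ids")))))
}

#' Audit query coverage within trait-unique families
#'
#' Aligns every member of each family to the family's longest member; the
#' family passes when all members have mutual coverage `>= min_cov`. Failures
#' are flagged, never dropped: a family carrying a split-gene fragment (a gene
#' divided across two contigs) is retained with its flag, matching how such
#' assembly artifacts should be treated.
#'
#' @param tus A [trait_unique_families()] result.
#' @param pan The pan-genome the set came from (source of sequences).
#' @param min_cov Minimum mutual coverage in percent (default 70).
#' @param submat Substitution matrix.
#' @return List with `pass` (named logical per family) and `flags`
#'   (data.frame: family_id, gene_id, query_cov, subject_cov for each failing
#'   member).
#' @export
coverage_filter <- function(tus, pan, min_cov = 70, submat = blosum62()) {
  pass <- setNames(logical(length(tus$family_ids)), tus$family_ids)
  flags <- list()
  for (fid in tus$family_ids) {
    genes <- sort(unlist(tus$members[[fid]], use.names = FALSE))
    longest <- genes[order(-nchar(pan$proteins[genes]), genes)][1]
    ok <- TRUE
    for (g in setdiff(genes, longest)) {
      st <- align_pair(pan$proteins[[g]], pan$proteins[[longest]],
                       submat = submat)
      if (st$query_cov < min_cov || st$subject_cov < min_cov) {
        ok <- FALSE
        flags[[length(flags) + 1]] <- data.frame(
          family_id = fid, gene_id = g, query_cov = st$query_cov,
          subject_cov = st$subject_cov)
      }
    }
    pass[fid] <- ok
  }
  flags <- if (length(flags)) do.call(rbind, flags) else
    data.frame(family_id = character(), gene_id = character(),
               query_cov = numeric(), subject_cov = numeric())
  list(pass = pass, flags = flags)
}

#' Search outgroup genomes for distant (sub-threshold) homologs
#'
#' For every trait-unique family and outgroup genome, reports the best hit
#' of the family representative with `floor_pid <= pid < ceiling_pid` and
#' coverage (minimum of the two) `>= min_cov`. This recovers homologs that
#' the presence/absence screen deliberately treats as absent, e.g. distantly
#' related copies in trait-negative genomes.
#'
#' @param tus A [trait_unique_families()] result.
#' @param pan The pan-genome the set came from.
#' @param outgroups List of [new_genome()] objects to search.
#' @param floor_pid,ceiling_pid Identity window in percent (defaults 20, 40;
#'   the ceiling is exclusive).
#' @param min_cov Minimum mutual coverage in percent (default 50).
#' @param submat Substitution matrix.
#' @return data.frame with columns `family_id`, `genome_id`, `gene_id`,
#'   `pid`, `coverage`.
#' @export
distant_homolog_search <- function(tus, pan, outgroups, floor_pid = 20,
                                   ceiling_pid = 40, min_cov = 50,
                                   submat = blosum62()) {
  hits <- list()
  for (fid in tus$family_ids) {
    genes <- sort(unlist(tus$members[[fid]], use.names = FALSE))
    rep_id <- genes[order(-nchar(pan$proteins[genes]), genes)][1]
    rep_seq <- pan$proteins[[rep_id]]
    for (og in outgroups) {
      st <- align_stats(c(rep_seq, og$genes$protein), rep(1L, nrow(og$genes)),
                        seq_len(nrow(og$genes)) + 1L, submat = submat)
      st$coverage <- pmin(st$query_cov, st$subject_cov)
      st <- st[st$pid >= floor_pid & st$pid < ceiling_pid &
                 st$coverage >= min_cov, , drop = FALSE]
      if (nrow(st)) {
        best <- st[order(-st$pid, -st$score, og$genes$gene_id[st$j - 1L]), ][1, ]
        hits[[length(hits) + 1]] <- data.frame(
          family_id = fid, genome_id = og$genome_id,
          gene_id = og$genes$gene_id[best$j - 1L],
          pid = best$pid, coverage = best$coverage)
      }
    }
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(family_id = character(), genome_id = character(),
               gene_id = character(), pid = numeric(), coverage = numeric())
}

#' Write a per-threshold trait-unique report as TSV
#' @param tus A [trait_unique_families()] result.
#' @param coverage Optional [coverage_filter()] result for the same set.
#' @param path Output path.
#' @export
write_trait_report <- function(tus, path, coverage = NULL) {
  rows <- lapply(tus$family_ids, function(fid) {
    m <- tus$members[[fid]]
    data.frame(family_id = fid, threshold = tus$threshold,
               n_genes = sum(lengths(m)),
               genomes = paste(names(m)[lengths(m) > 0], collapse = ";"),
               gene_ids = paste(unlist(m, use.names = FALSE), collapse = ";"),
               coverage_pass = if (is.null(coverage)) NA else
                 unname(coverage$pass[fid]))
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(family_id = character(), threshold = numeric(),
               n_genes = integer(), genomes = character(),
               gene_ids = character(), coverage_pass = logical())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
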