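# Syntenic cassette detection: contiguous runs of trait-unique genes within a
# genome, order conservation across genomes, and flanking neighborhoods.

#' Find contiguous cassettes of a gene set within a genome
#'
#' Maximal runs of the given genes along each contig in which at most
#' `max_gap` non-member genes intervene between consecutive members
#' (locus-rank difference `<= max_gap + 1`). Every member gene falls in
#' exactly one cassette.
#'
#' @param gene_ids Character vector of member gene ids (must exist in the
#'   genome).
#' @param genome A [new_genome()] object.
#' @param max_gap Maximum number of intervening non-member genes (default 1).
#' @return List of `cassette` objects: `genome_id`, `contig_id`, `gene_ids`
#'   (genomic order), `locus_ranks`, `strands`.
#' @export
find_cassettes <- function(gene_ids, genome, max_gap = 1) {
  g <- genome$genes
  unknown <- setdiff(gene_ids, g$gene_id)
  if (length(unknown))
    stop("gene id(s) not in genome '", genome$genome_id, "': ",
         paste(unknown, collapse = ", "))
  m <- g[g$gene_id %in% gene_ids, , drop = FALSE]
  out <- list()
  for (ct in unique(m$contig_id)) {
    mc <- m[m$contig_id == ct, , drop = FALSE]
    mc <- mc[order(mc$locus_rank), , drop = FALSE]
    run <- cumsum(c(1L, diff(mc$locus_rank) > max_gap + 1L))
    for (r in unique(run)) {
      rows <- mc[run == r, , drop = FALSE]
      out[[length(out) + 1]] <- structure(
        list(genome_id = genome$genome_id, contig_id = ct,
             gene_ids = rows$gene_id, locus_ranks = rows$locus_rank,
             strands = rows$strand, max_gap = max_gap),
        class = "cassette")
    }
  }
  out
}

#' Test order conservation of cassettes across genomes
#'
#' Maps each genome's largest cassette to a family-order signature and calls
#' the synteny shared when every genome's signature equals the reference
#' signature or its full reversal (cassettes are drawn strand-normalized, so
#' reversal counts as shared). Genomes whose members are split across several
#' cassettes are reported with a `fragmented` flag and judged by their largest
#' fragment; they are never grounds for failure on their own.
#'
#' @param cassettes Named list: genome_id -> list of cassettes (as returned by
#'   [find_cassettes()]).
#' @param gene2family Named character vector mapping gene ids to family ids
#'   (e.g. `pan$gene2family`).
#' @return Object of class `synteny_report`: list with `is_shared`,
#'   `reference` (family signature), `per_genome` data.frame (genome_id,
#'   signature, orientation, fragmented, n_cassettes).
#' @export
shared_synteny <- function(cassettes, gene2family) {
  stopifnot(length(cassettes) >= 1, !is.null(names(cassettes)))
  sig_of <- function(cas) {
    fams <- unname(gene2family[cas$gene_ids])
    fams[!duplicated(fams)] # paralog / split-fragment duplicates collapse
  }
  rows <- lapply(sort(names(cassettes)), function(gid) {
    cl <- cassettes[[gid]]
    if (length(cl) == 0)
      return(data.frame(genome_id = gid, signature = "", orientation = NA,
                        fragmented = NA, n_cassettes = 0L))
    sizes <- vapply(cl, function(x) length(x$gene_ids), integer(1))
    main <- cl[[which.max(sizes)]]
    data.frame(genome_id = gid, signature = paste(sig_of(main), collapse = ">"),
               orientation = NA_character_, fragmented = length(cl) > 1,
               n_cassettes = length(cl))
  })
  per_genome <- do.call(rbind, rows)
  ref <- strsplit(per_genome$signature[1], ">", fixed = TRUE)[[1]]
  rev_ref <- paste(rev(ref), collapse = ">")
  fwd_ref <- paste(ref, collapse = ">")
  per_genome$orientation <- ifelse(per_genome$signature == fwd_ref, "forward",
                                   ifelse(per_genome$signature == rev_ref,
                                          "reverse", NA))
  is_shared <- all(!is.na(per_genome$orientation)) && per_genome$n_cassettes[1] > 0
  structure(list(is_shared = is_shared, reference = ref,
                 per_genome = per_genome),
            class = "synteny_report")
}

#' @export
print.synteny_report <- function(x, ...) {
  cat(sprintf("synteny %s across %d genomes; reference: %s\n",
              if (x$is_shared) "SHARED" else "NOT shared",
              nrow(x$per_genome), paste(x$reference, collapse = ">")))
  invisible(x)
}

#' Flanking gene neighborhood of a cassette
#'
#' Up to `k` genes on each side of the cassette, in locus order on the same
#' contig, with their products. Cassettes at a contig edge return fewer
#' flanking genes without error.
#'
#' @param genome A [new_genome()] object.
#' @param cassette A cassette from [find_cassettes()].
#' @param k Number of flanking genes per side (default 5).
#' @return List with `upstream` and `downstream` data.frames of gene records.
#' @export
neighborhood <- function(genome, cassette, k = 5) {
  g <- genome$genes[genome$genes$contig_id == cassette$contig_id, , drop = FALSE]
  g <- g[order(g$locus_rank), , drop = FALSE]
  lo <- min(cassette$locus_ranks)
  hi <- max(cassette$locus_ranks)
  list(upstream = g[g$locus_rank >= lo - k & g$locus_rank < lo, , drop = FALSE],
       downstream = g[g$locus_rank > hi & g$locus_rank <= hi + k, , drop = FALSE])
}

#' Write a synteny report as TSV (textual stand-in for synteny plots)
#' @param report A [shared_synteny()] result.
#' @param path Output path.
#' @export
write_synteny_tsv <- function(report, path) {
  df <- report$per_genome
  df$is_shared <- report$is_shared
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
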