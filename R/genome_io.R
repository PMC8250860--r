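#' Construct a genome object
#'
#' A genome is an ordered collection of annotated coding sequences. Genes are
#' sorted by (contig, start) and `locus_rank` (0-based position within its
#' contig, by start coordinate) is assigned here; any rank present in the
#' input is recomputed.
#'
#' @param genome_id Genome identifier.
#' @param genes data.frame with columns `gene_id`, `contig_id`, `start`,
#'   `end`, `strand` (`+`/`-`), `product`, `protein`.
#' @return Object of class `genome`: list with `genome_id`, `genes`
#'   (data.frame incl. `locus_rank`), `n_contigs`.
#' @export
new_genome <- function(genome_id, genes) {
  need <- c("gene_id", "contig_id", "start", "end", "strand", "product", "protein")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop("genes table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id in genome '", genome_id, "': ",
         genes$gene_id[duplicated(genes$gene_id)][1])
  if (any(genes$start < 1) || any(genes$end < genes$start))
    stop("malformed coordinates: need 1 <= start <= end")
  if (any(!nzchar(genes$protein)))
    stop("empty protein sequence for gene ",
         genes$gene_id[!nzchar(genes$protein)][1])
  if (any(!genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  o <- order(genes$contig_id, genes$start, genes$end, genes$gene_id)
  genes <- genes[o, need, drop = FALSE]
  genes$locus_rank <- stats::ave(seq_len(nrow(genes)), genes$contig_id,
                                 FUN = seq_along) - 1L
  rownames(genes) <- NULL
  structure(list(genome_id = genome_id, genes = genes,
                 n_contigs = length(unique(genes$contig_id))),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("genome '%s': %d genes on %d contig(s)\n",
              x$genome_id, nrow(x$genes), x$n_contigs))
  invisible(x)
}

#' Load a genome from a GFF3 + protein FASTA pair
#'
#' Reads Prokka-style output: CDS features with `ID` attributes from the GFF3
#' and the matching protein sequences from the companion `.faa` (FASTA headers
#' keyed by the same IDs; description after the first whitespace is ignored).
#' Proteins are never re-translated and any nucleotide `##FASTA` block
#' embedded in the GFF is skipped. A trailing stop symbol `*` on a protein is
#' stripped; internal stops are kept (and later rejected by
#' [filter_partial()]).
#'
#' @param gff_path Path to GFF3 file (CDS features carry `ID=` attributes).
#' @param faa_path Path to protein FASTA keyed by the same IDs.
#' @param genome_id Identifier to assign; defaults to the GFF basename.
#' @return A [new_genome()] object.
#' @export
load_genome <- function(gff_path, faa_path,
                        genome_id = sub("\\.gff3?$", "", basename(gff_path))) {
  lines <- readLines(gff_path)
  fasta_at <- which(lines == "##FASTA")
  body_end <- if (length(fasta_at)) fasta_at[1] - 1L else length(lines)
  body <- lines[seq_len(body_end)]
  feat <- which(!startsWith(body, "#") & nzchar(body))
  # pre-validate coordinates so malformed rows are reported with line numbers
  for (ln in feat) {
    f <- strsplit(body[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9) stop("GFF3 parse error at line ", ln, ": fewer than 9 fields")
    s <- suppressWarnings(as.integer(f[4])); e <- suppressWarnings(as.integer(f[5]))
    if (is.na(s) || is.na(e) || e < s || s < 1)
      stop("GFF3 parse error at line ", ln, ": malformed coordinates '",
           f[4], "'..'", f[5], "'")
  }
  gr <- rtracklayer::import(gff_path, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0) stop("no CDS features in ", gff_path)
  ids <- as.character(gr$ID)
  if (anyNA(ids) || any(!nzchar(ids)))
    stop("CDS feature without ID attribute in ", gff_path)
  prod <- if (!is.null(gr$product)) as.character(gr$product) else
    rep(NA_character_, length(gr))
  prod[is.na(prod)] <- "hypothetical protein"

  aa <- Biostrings::readAAStringSet(faa_path)
  names(aa) <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1)
  missing <- setdiff(ids, names(aa))
  if (length(missing))
    stop("protein FASTA is missing ID(s): ", paste(missing, collapse = ", "))
  prot <- sub("\\*$", "", as.character(aa[ids]))
  if (any(!nzchar(prot)))
    stop("CDS without protein sequence: ", ids[!nzchar(prot)][1])

  genes <- data.frame(
    gene_id = ids,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+"),
    product = prod,
    protein = unname(prot),
    stringsAsFactors = FALSE)
  new_genome(genome_id, genes)
}

#' Write a genome as a GFF3 + protein FASTA pair
#'
#' Inverse of [load_genome()]; round trips are lossless for the fields the
#' pipeline uses.
#'
#' @param genome A [new_genome()] object.
#' @param gff_path,faa_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_genome_files <- function(genome, gff_path, faa_path) {
  g <- genome$genes
  attrs <- sprintf("ID=%s;product=%s", g$gene_id, g$product)
  rows <- sprintf("%s\tstalkscan\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                  g$contig_id, g$start, g$end, g$strand, attrs)
  contigs <- unique(g$contig_id)
  regions <- vapply(contigs, function(ct)
    sprintf("##sequence-region %s 1 %d", ct, max(g$end[g$contig_id == ct]) + 200L),
    character(1))
  writeLines(c("##gff-version 3", regions, rows), gff_path)
  aa <- Biostrings::AAStringSet(setNames(g$protein, g$gene_id))
  Biostrings::writeXStringSet(aa, faa_path, width = 70)
  invisible(c(gff_path, faa_path))
}

#' Build a trait table
#'
#' Assigns each genome one label from `stalk`, `dread`, `amorphous`. The
#' binary screen always contrasts stalk (positives) against the rest
#' (negatives), i.e. dread and amorphous genomes are collectively
#' "stalk-less".
#'
#' @param assignments Named character vector: `genome_id -> label`.
#' @return Object of class `trait_table`: list with `assignments`,
#'   `positives`, `negatives`.
#' @export
trait_table <- function(assignments) {
  allowed <- c("stalk", "dread", "amorphous")
  if (length(assignments) == 0) stop("trait table is empty")
  if (is.null(names(assignments)) || any(!nzchar(names(assignments))))
    stop("assignments must be named by genome_id")
  if (anyDuplicated(names(assignments)))
    stop("duplicated genome_id in trait table: ",
         names(assignments)[duplicated(names(assignments))][1])
  bad <- setdiff(unique(assignments), allowed)
  if (length(bad))
    stop("unknown trait label(s) ", paste(bad, collapse = ", "),
         "; allowed labels: ", paste(allowed, collapse = ", "))
  structure(list(assignments = assignments,
                 positives = names(assignments)[assignments == "stalk"],
                 negatives = names(assignments)[assignments != "stalk"]),
            class = "trait_table")
}

#' Read a trait table from TSV
#'
#' @param path TSV with columns `genome_id` and `trait`
#'   (labels in stalk/dread/amorphous).
#' @return A [trait_table()] object.
#' @export
read_trait_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("trait table is empty: ", path)
  if (!all(c("genome_id", "trait") %in% names(df)))
    stop("trait table must have columns genome_id and trait")
  trait_table(setNames(df$trait, df$genome_id))
}

#' Write a trait table to TSV
#' @param traits A [trait_table()] object.
#' @param path Output TSV path.
#' @export
write_trait_table <- function(traits, path) {
  df <- data.frame(genome_id = names(traits$assignments),
                   trait = unname(traits$assignments))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a presence/absence table (Roary-style CSV)
#'
#' One row per gene family: `family_id`, `n_genomes`, `n_genes`, then one
#' column per genome listing member gene ids (semicolon-joined for paralogs,
#' empty when absent).
#'
#' @param pan A pan-genome from [build_pangenome()].
#' @param path Output CSV path.
#' @export
write_presence_absence <- function(pan, path) {
  rows <- lapply(pan$families, function(f) {
    cells <- vapply(pan$genomes, function(g)
      paste(f$members[[g]], collapse = ";"), character(1))
    c(family_id = f$family_id,
      n_genomes = as.character(sum(nzchar(cells))),
      n_genes = as.character(sum(lengths(f$members))),
      cells)
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", quote = TRUE, row.names = FALSE)
  invisible(path)
}

#' Read a presence/absence CSV back into a count matrix
#'
#' @param path CSV written by [write_presence_absence()].
#' @return List with `matrix` (genome x family member counts) and `members`
#'   (named list family -> genome -> gene ids).
#' @export
read_presence_absence <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  genomes <- setdiff(names(df), c("family_id", "n_genomes", "n_genes"))
  mat <- sapply(df[genomes], function(col)
    vapply(strsplit(col, ";", fixed = TRUE), function(x) sum(nzchar(x)), integer(1)))
  mat <- matrix(as.integer(t(mat)), nrow = length(genomes),
                dimnames = list(genomes, df$family_id))
  members <- lapply(seq_len(nrow(df)), function(r)
    lapply(setNames(genomes, genomes), function(g) {
      x <- strsplit(df[[g]][r], ";", fixed = TRUE)[[1]]
      x[nzchar(x)]
    }))
  names(members) <- df$family_id
  list(matrix = mat, members = members)
}

# quote a Newick label when it contains characters outside the safe set
newick_label <- function(x) {
  ifelse(grepl("[][ \t():;,']", x),
         paste0("'", gsub("'", "''", x), "'"), x)
}

#' Write an ultrametric merge tree as Newick
#'
#' Branch lengths follow the ultrametric convention for agglomerative
#' clustering: a node sits at depth `height/2`, so two leaves merged at
#' height 0.2 become `(A:0.1,B:0.1);`. Leaf names containing spaces or other
#' Newick-reserved characters are single-quoted.
#'
#' @param tree An `upgma_tree` (see [upgma()]): list with hclust-style
#'   `merge`, `height`, `labels`.
#' @param path Optional output path; when `NULL` the string is returned only.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  depth <- tree$height / 2
  rec <- function(node) {
    # negative index = leaf, positive = internal merge row
    if (node < 0) list(str = newick_label(tree$labels[-node]), d = 0)
    else {
      l <- rec(tree$merge[node, 1]); r <- rec(tree$merge[node, 2])
      d <- depth[node]
      list(str = sprintf("(%s:%g,%s:%g)", l$str, d - l$d, r$str, d - r$d), d = d)
    }
  }
  nwk <- if (length(tree$labels) == 1) {
    paste0(newick_label(tree$labels), ";")
  } else paste0(rec(nrow(tree$merge))$str, ";")
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}
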