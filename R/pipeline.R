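# End-to-end orchestration: load inputs, run the threshold sweep, AAI,
# synteny, motifs and COG enrichment, and write a report bundle with a
# MANIFEST of completed stages.

#' Pipeline configuration
#'
#' Collects every tunable the analysis uses: the identity threshold sweep
#' (default 30-90% in steps of 10), the union range for the headline
#' trait-unique report (default 30-80%, excluding the 90% tier), the coverage
#' audit threshold (70%), AAI ortholog thresholds (30% identity / 70%
#' coverage), MCL inflation (1.5), the synteny gap allowance (1), the number
#' of accumulation permutations (100) and the master seed (42).
#'
#' @param genome_dir Directory containing `<id>.gff3` + `<id>.faa` pairs.
#' @param trait_path Trait table TSV.
#' @param out_dir Output directory.
#' @param cog_path Optional gene -> COG category TSV.
#' @param thresholds Identity thresholds for the sweep.
#' @param union_range Inclusive threshold range entering the union report.
#' @param min_cov Coverage audit threshold in percent.
#' @param aai_min_pid,aai_min_cov AAI ortholog thresholds.
#' @param screen_threshold Threshold whose pan-genome feeds the partition,
#'   synteny, motif and COG stages (default 50).
#' @param heaps_threshold Threshold whose pan-genome feeds the accumulation
#'   curve and Heaps fit (default 80).
#' @param inflation MCL inflation.
#' @param max_gap Synteny gap allowance.
#' @param n_perm Accumulation permutations.
#' @param seed Master seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(genome_dir, trait_path, out_dir, cog_path = NULL,
                            thresholds = seq(30, 90, by = 10),
                            union_range = c(30, 80), min_cov = 70,
                            aai_min_pid = 30, aai_min_cov = 70,
                            screen_threshold = 50, heaps_threshold = 80,
                            inflation = 1.5, max_gap = 1, n_perm = 100,
                            seed = 42) {
  thresholds <- sort(thresholds)
  stopifnot(all(thresholds > 0 & thresholds <= 100),
            screen_threshold %in% thresholds, heaps_threshold %in% thresholds)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Load all genome pairs from a directory
#'
#' @param genome_dir Directory with `<id>.gff3` and matching `<id>.faa`.
#' @return List of [new_genome()] objects, sorted by id.
#' @export
load_genome_dir <- function(genome_dir) {
  gffs <- sort(list.files(genome_dir, pattern = "\\.gff3?$", full.names = TRUE))
  if (length(gffs) == 0)
    stop("no GFF3 files found in ", genome_dir)
  lapply(gffs, function(gff) {
    id <- sub("\\.gff3?$", "", basename(gff))
    faa <- file.path(genome_dir, paste0(id, ".faa"))
    if (!file.exists(faa)) stop("missing protein FASTA for genome ", id)
    load_genome(gff, faa, genome_id = id)
  })
}

#' Run the full trait-association analysis
#'
#' Executes, in order: genome loading, the pan-genome threshold sweep with
#' the trait-unique screen, the coverage audit, AAI + UPGMA clustering,
#' accumulation/Heaps, synteny cassette detection for the screen hits at the
#' screen threshold, motif scanning of the hit proteins, optional COG
#' enrichment, and a top-level JSON summary. Every completed stage is
#' appended to `MANIFEST` in the output directory; on failure the partial
#' outputs and MANIFEST are retained.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the summary list (also written to `summary.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- file.path(out, "MANIFEST")
  if (file.exists(manifest)) unlink(manifest)
  done <- function(stage) cat(stage, "\n", sep = "", file = manifest,
                              append = TRUE)

  genomes <- load_genome_dir(config$genome_dir)
  traits <- read_trait_table(config$trait_path)
  done("load")

  sweep <- threshold_sweep(genomes, traits, thresholds = config$thresholds,
                           union_range = config$union_range,
                           inflation = config$inflation)
  for (th in names(sweep$pans)) {
    write_presence_absence(sweep$pans[[th]],
                           file.path(out, sprintf("presence_absence_%s.csv", th)))
    part <- partition_pangenome(sweep$pans[[th]])
    utils::write.table(data.frame(subdivision = names(part$counts),
                                  families = unname(part$counts)),
                       file.path(out, sprintf("partition_%s.tsv", th)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_trait_report(sweep$sets[[th]],
                       file.path(out, sprintf("trait_unique_%s.tsv", th)))
  }
  utils::write.table(sweep$union, file.path(out, "trait_unique_union.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  done("sweep")

  th_screen <- as.character(config$screen_threshold)
  pan <- sweep$pans[[th_screen]]
  tus <- sweep$sets[[th_screen]]
  cov <- coverage_filter(tus, pan, min_cov = config$min_cov)
  write_trait_report(tus, file.path(out, "trait_unique_screen.tsv"), coverage = cov)
  done("coverage")

  aai <- aai_matrix_and_cluster(genomes, min_pid = config$aai_min_pid,
                                min_cov = config$aai_min_cov)
  write_aai_tsv(aai$aai, file.path(out, "aai_matrix.tsv"))
  write_newick(aai$dend, file.path(out, "aai_upgma.nwk"))
  done("aai")

  acc <- accumulation_and_heaps(sweep$pans[[as.character(config$heaps_threshold)]],
                                n_perm = config$n_perm, seed = config$seed)
  utils::write.table(acc$curve, file.path(out, "accumulation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(acc$heaps, file.path(out, "heaps_fit.json"),
                       auto_unbox = TRUE, digits = NA)
  done("heaps")

  screen_genes <- unlist(lapply(tus$members, function(m)
    unlist(m, use.names = FALSE)), use.names = FALSE)
  cassettes <- list()
  for (g in genomes) {
    ids <- intersect(screen_genes, g$genes$gene_id)
    if (length(ids))
      cassettes[[g$genome_id]] <- find_cassettes(ids, g, max_gap = config$max_gap)
  }
  synteny <- if (length(cassettes))
    shared_synteny(cassettes, pan$gene2family) else NULL
  if (!is.null(synteny))
    write_synteny_tsv(synteny, file.path(out, "synteny.tsv"))
  done("synteny")

  hit_proteins <- pan$proteins[screen_genes]
  motif_hits <- write_motif_tsv(hit_proteins, file.path(out, "motifs.tsv"))
  done("motifs")

  cog_summary <- NULL
  if (!is.null(config$cog_path)) {
    assign <- read_cog_table(config$cog_path)
    part <- partition_pangenome(pan)
    enr <- cog_enrichment(assign, part, pan)
    utils::write.table(enr, file.path(out, "cog_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sig <- enr[!enr$degenerate & enr$q_value < 0.05, ]
    cog_summary <- list(n_tests = nrow(enr), n_significant = nrow(sig),
                        top = if (nrow(sig)) sig$category[which.min(sig$q_value)]
                              else NA)
    done("cogs")
  }

  summary <- list(
    n_genomes = length(genomes),
    thresholds = config$thresholds,
    screen_threshold = config$screen_threshold,
    families_per_threshold = lapply(sweep$pans, function(p) length(p$families)),
    trait_unique_per_threshold = lapply(sweep$sets, function(s)
      list(families = length(s$family_ids), genes = s$gene_count)),
    union_families = nrow(sweep$union),
    union_genes = length(sweep$union_gene_ids),
    coverage_flagged = unname(tus$family_ids[!cov$pass]),
    heaps = acc$heaps,
    synteny_shared = if (!is.null(synteny)) synteny$is_shared else NA,
    synteny_reference = if (!is.null(synteny)) synteny$reference else NULL,
    fragmented_genomes = if (!is.null(synteny))
      synteny$per_genome$genome_id[synteny$per_genome$fragmented %in% TRUE]
      else character(0),
    n_motif_hits = nrow(motif_hits),
    cogs = cog_summary,
    seed = config$seed)
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  done("summary")
  invisible(summary)
}
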