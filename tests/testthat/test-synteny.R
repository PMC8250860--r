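# Cassette detection, order conservation, neighborhoods.

rank_genome <- function(id, n, contig = "c1") {
  new_genome(id, data.frame(
    gene_id = sprintf("%s_%03d", id, 1:n), contig_id = contig,
    start = (1:n) * 1000, end = (1:n) * 1000 + 300, strand = "+",
    product = paste("protein", 1:n),
    protein = vapply(rep(90, n), function(l) {
      paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], l, replace = TRUE),
            collapse = "")
    }, character(1)), stringsAsFactors = FALSE))
}

test_that("cassettes are maximal runs under the gap allowance", {
  set.seed(71)
  g <- rank_genome("G", 20)
  ids <- function(r) g$genes$gene_id[g$genes$locus_rank %in% r]
  # ranks 5,6,7 -> one cassette of 3
  cas <- find_cassettes(ids(5:7), g, max_gap = 1)
  expect_length(cas, 1)
  expect_equal(cas[[1]]$locus_ranks, 5:7)
  # ranks 5 and 8: gap of 2 exceeds max_gap 1 -> two cassettes
  cas2 <- find_cassettes(ids(c(5, 8)), g, max_gap = 1)
  expect_length(cas2, 2)
  # but max_gap 2 bridges them
  cas3 <- find_cassettes(ids(c(5, 8)), g, max_gap = 2)
  expect_length(cas3, 1)
  # cassettes partition the member set
  cas4 <- find_cassettes(ids(c(0, 1, 5, 6, 12)), g, max_gap = 1)
  expect_setequal(unlist(lapply(cas4, `[[`, "gene_ids")),
                  ids(c(0, 1, 5, 6, 12)))
  expect_equal(sum(lengths(lapply(cas4, `[[`, "gene_ids"))), 5L)
  # unknown gene ids are an error
  expect_error(find_cassettes("nope", g), "not in genome")
})

test_that("shared synteny accepts identical and reversed orders only", {
  set.seed(72)
  g1 <- rank_genome("S1", 10)
  g2 <- rank_genome("S2", 10)
  g3 <- rank_genome("S3", 10)
  # families A,B,C at ranks 3,4,5 in g1/g2 (g2 reversed), permuted in g3
  fam <- c("FA", "FB", "FC")
  g2f <- c(setNames(fam, g1$genes$gene_id[4:6]),
           setNames(rev(fam), g2$genes$gene_id[4:6]),
           setNames(fam[c(2, 1, 3)], g3$genes$gene_id[4:6]))
  cas <- list(S1 = find_cassettes(g1$genes$gene_id[4:6], g1),
              S2 = find_cassettes(g2$genes$gene_id[4:6], g2))
  rep1 <- shared_synteny(cas, g2f)
  expect_true(rep1$is_shared)
  expect_equal(sort(unique(rep1$per_genome$orientation)),
               c("forward", "reverse"))
  # a permuted internal order breaks sharing
  cas$S3 <- find_cassettes(g3$genes$gene_id[4:6], g3)
  rep2 <- shared_synteny(cas, g2f)
  expect_false(rep2$is_shared)
})

test_that("neighborhoods honor k and contig edges", {
  set.seed(73)
  g <- rank_genome("G", 25)
  memb <- g$genes$gene_id[g$genes$locus_rank %in% 10:15]
  cas <- find_cassettes(memb, g, max_gap = 1)[[1]]
  nb <- neighborhood(g, cas, k = 5)
  expect_equal(nb$upstream$locus_rank, 5:9)
  expect_equal(nb$downstream$locus_rank, 16:20)
  expect_true(all(nzchar(nb$upstream$product)))
  # cassette at the contig start has an empty upstream side
  cas0 <- find_cassettes(g$genes$gene_id[g$genes$locus_rank %in% 0:2], g)[[1]]
  nb0 <- neighborhood(g, cas0, k = 5)
  expect_equal(nrow(nb0$upstream), 0)
  expect_equal(nb0$downstream$locus_rank, 3:7)
})

test_that("the planted cluster forms one conserved cassette per positive genome", {
  comm <- generate_community(synth_config(
    n_positive = 5, n_dread = 1, n_amorphous = 1, n_core = 15, n_accessory = 6,
    n_unique = 3, cluster_size = 4, neighbor_size = 3, dread_mode = FALSE,
    split_gene = FALSE, seed = 37))
  pan <- build_pangenome(comm$genomes, 50)
  tus <- trait_unique_families(pan, comm$traits)
  genes <- unlist(lapply(tus$members, function(m) unlist(m, use.names = FALSE)),
                  use.names = FALSE)
  cassettes <- list()
  for (g in comm$genomes) {
    ids <- intersect(genes, g$genes$gene_id)
    if (length(ids))
      cassettes[[g$genome_id]] <- find_cassettes(ids, g, max_gap = 1)
  }
  expect_setequal(names(cassettes), comm$traits$positives)
  expect_true(all(lengths(cassettes) == 1))
  rep <- shared_synteny(cassettes, pan$gene2family)
  expect_true(rep$is_shared)
  expect_length(rep$reference, 4)
  expect_false(any(rep$per_genome$fragmented))

  # the neighbor cassette genes sit directly adjacent in carrier genomes
  nb_genes <- unlist(lapply(comm$truth$members[comm$truth$neighbor_family_ids],
                            function(m) unlist(m, use.names = FALSE)),
                     use.names = FALSE)
  g1 <- comm$genomes[[1]]
  cas1 <- cassettes[[g1$genome_id]][[1]]
  nb <- neighborhood(g1, cas1, k = 3)
  flank <- c(nb$upstream$gene_id, nb$downstream$gene_id)
  expect_gte(length(intersect(flank, nb_genes)), 3)
})

test_that("split cassettes are flagged fragmented but can still share synteny", {
  comm <- generate_community(synth_config(
    n_positive = 4, n_dread = 1, n_amorphous = 1, n_core = 12, n_accessory = 5,
    n_unique = 2, cluster_size = 3, dread_mode = FALSE, split_gene = TRUE,
    seed = 39))
  pan <- build_pangenome(comm$genomes, 50)
  tus <- trait_unique_families(pan, comm$traits)
  genes <- unlist(lapply(tus$members, function(m) unlist(m, use.names = FALSE)),
                  use.names = FALSE)
  cassettes <- list()
  for (g in comm$genomes) {
    ids <- intersect(genes, g$genes$gene_id)
    if (length(ids)) cassettes[[g$genome_id]] <- find_cassettes(ids, g)
  }
  rep <- shared_synteny(cassettes, pan$gene2family)
  sg <- comm$truth$split$genome_id
  expect_true(rep$per_genome$fragmented[rep$per_genome$genome_id == sg])
  expect_true(all(!rep$per_genome$fragmented[rep$per_genome$genome_id != sg]))
  expect_true(rep$is_shared)
})
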