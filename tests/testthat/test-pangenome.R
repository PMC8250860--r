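# Pan-genome construction: filtering, pre-clustering, similarity graph vs a
# brute-force all-pairs oracle, MCL vs an independent matrix-iteration
# reference, partitioning, and accumulation/Heaps behavior.

simple_genome <- function(id, proteins) {
  n <- length(proteins)
  new_genome(id, data.frame(
    gene_id = sprintf("%s_%03d", id, seq_len(n)), contig_id = "c1",
    start = seq_len(n) * 2000, end = seq_len(n) * 2000 + nchar(proteins) * 3 + 2,
    strand = "+", product = "hypothetical protein", protein = proteins,
    stringsAsFactors = FALSE))
}

test_that("filter_partial removes short and internally-stopped proteins", {
  set.seed(3)
  genes <- data.frame(gene_id = paste0("g", 1:4),
                      protein = c(random_protein_seq(35), random_protein_seq(40),
                                  random_protein_seq(300),
                                  paste0(random_protein_seq(100), "*",
                                         random_protein_seq(50))))
  f <- filter_partial(genes, min_len = 40)
  expect_equal(f$retained$gene_id, c("g2", "g3"))
  expect_equal(f$rejected$gene_id, c("g1", "g4"))
  all_ok <- filter_partial(genes[2:3, ], min_len = 40)
  expect_equal(nrow(all_ok$rejected), 0)
})

test_that("precluster absorbs duplicates and keeps divergent sequences apart", {
  set.seed(4)
  a <- random_protein_seq(200)
  b <- mutate_to_identity(a, 50)$seq # far below pre_pid
  genes <- data.frame(gene_id = c("dup1", "dup2", "far"),
                      protein = c(a, a, b))
  pre <- precluster(genes, pre_pid = 95, pre_cov = 90)
  expect_length(pre$members, 2)
  expect_setequal(pre$members[[which(vapply(pre$members, length, 1L) == 2)]],
                  c("dup1", "dup2"))
  # planted 100%-identical duplicates across a community are absorbed
  # identity targets capped below pre_pid so only exact duplicates merge
  comm <- generate_community(synth_config(
    n_positive = 3, n_dread = 1, n_amorphous = 1, n_core = 8, n_accessory = 3,
    n_unique = 2, dread_mode = FALSE, split_gene = FALSE,
    core_pid = c(70, 88), accessory_pid = c(60, 88), seed = 10))
  genes2 <- stalkscan:::combine_genes(comm$genomes)
  dup <- genes2[c(1, 1, 2), ]
  dup$gene_id <- c("d1", "d2", "other")
  pre2 <- precluster(rbind(genes2, dup))
  expect_equal(length(pre2$members),
               length(unique(c(genes2$protein, dup$protein))))
  expect_setequal(unlist(pre2$members, use.names = FALSE),
                  c(genes2$gene_id, dup$gene_id))
})

test_that("similarity graph equals exhaustive all-pairs alignment", {
  set.seed(6)
  seqs <- character(0)
  for (fam in 1:4) {
    ref <- random_protein_seq(150)
    seqs <- c(seqs, ref, mutate_to_identity(ref, 80)$seq,
              mutate_to_identity(ref, 60)$seq)
  }
  seqs <- c(seqs, replicate(8, random_protein_seq(150)))
  reps <- data.frame(gene_id = sprintf("r%02d", seq_along(seqs)), protein = seqs)
  for (min_pid in c(30, 50, 70)) {
    g <- build_similarity_graph(reps, min_pid = min_pid)
    # brute force: all pairs, no prescreen
    expected <- character(0)
    for (i in seq_along(seqs)) for (j in seq_along(seqs)) {
      if (i >= j) next
      st <- align_pair(seqs[i], seqs[j])
      if (st$pid >= min_pid && st$query_cov >= 40 && st$subject_cov >= 40)
        expected <- c(expected, paste(reps$gene_id[i], reps$gene_id[j]))
    }
    got <- paste(g$edges$from, g$edges$to)
    expect_setequal(got, expected)
  }
})

test_that("edge threshold semantics are respected around the boundary", {
  set.seed(7)
  ref <- random_protein_seq(200)
  pair55 <- mutate_to_identity(ref, 55)$seq
  reps <- data.frame(gene_id = c("a", "b"), protein = c(ref, pair55))
  pid <- align_pair(ref, pair55)$pid
  g_above <- build_similarity_graph(reps, min_pid = pid + 1)
  g_below <- build_similarity_graph(reps, min_pid = pid - 1)
  g_exact <- build_similarity_graph(reps, min_pid = pid)
  expect_equal(nrow(g_above$edges), 0)
  expect_equal(nrow(g_below$edges), 1)
  expect_equal(nrow(g_exact$edges), 1) # >= is inclusive
})

test_that("MCL matches the independent matrix-iteration oracle", {
  tri2 <- list(
    nodes = paste0("n", 1:6),
    edges = data.frame(from = c("n1", "n2", "n3", "n4", "n5", "n6"),
                       to = c("n2", "n3", "n1", "n5", "n6", "n4"),
                       pid = 80))
  g <- structure(c(tri2, threshold = 50), class = "similarity_graph")
  got <- mcl_cluster(g, inflation = 1.5)
  expect_equal(canon_clusters(got),
               canon_clusters(list(paste0("n", 1:3), paste0("n", 4:6))))
  expect_equal(canon_clusters(got),
               canon_clusters(oracle_mcl(tri2$nodes, tri2$edges)))

  # single isolated node
  iso <- structure(list(nodes = "solo",
                        edges = data.frame(from = character(),
                                           to = character(), pid = numeric()),
                        threshold = 50), class = "similarity_graph")
  expect_equal(mcl_cluster(iso), list("solo"))

  # 12-node barbell: two K6 joined by one weak edge
  nodes <- sprintf("b%02d", 1:12)
  e <- list()
  for (i in 1:5) for (j in (i + 1):6) {
    e[[length(e) + 1]] <- data.frame(from = nodes[i], to = nodes[j], pid = 100)
    e[[length(e) + 1]] <- data.frame(from = nodes[i + 6], to = nodes[j + 6],
                                     pid = 100)
  }
  e[[length(e) + 1]] <- data.frame(from = nodes[6], to = nodes[7], pid = 1)
  edges <- do.call(rbind, e)
  g2 <- structure(list(nodes = nodes, edges = edges, threshold = 0),
                  class = "similarity_graph")
  got2 <- mcl_cluster(g2, inflation = 1.5)
  expect_equal(canon_clusters(got2),
               canon_clusters(list(nodes[1:6], nodes[7:12])))
  expect_equal(canon_clusters(got2),
               canon_clusters(oracle_mcl(nodes, edges)))

  # randomized small weighted graphs
  set.seed(8)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    nd <- sprintf("x%02d", 1:n)
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- runif(nrow(pairs)) < 0.4
    if (!any(keep)) next
    ed <- data.frame(from = nd[pairs[keep, 1]], to = nd[pairs[keep, 2]],
                     pid = round(runif(sum(keep), 30, 100), 1))
    gr <- structure(list(nodes = nd, edges = ed, threshold = 0),
                    class = "similarity_graph")
    expect_equal(canon_clusters(mcl_cluster(gr)),
                 canon_clusters(oracle_mcl(nd, ed)), info = paste("rep", rep))
  }
})

test_that("two-genome pan-genomes behave at the composition extremes", {
  set.seed(12)
  shared <- replicate(6, random_protein_seq(150))
  g1 <- simple_genome("GA", shared)
  g2 <- simple_genome("GB", shared)
  pan <- build_pangenome(list(g1, g2), 50)
  part <- partition_pangenome(pan)
  expect_equal(unname(part$counts["core"]), 6L)
  expect_equal(unname(part$counts["total"]), 6L)

  g3 <- simple_genome("GC", replicate(5, random_protein_seq(150)))
  g4 <- simple_genome("GD", replicate(5, random_protein_seq(150)))
  pan2 <- build_pangenome(list(g3, g4), 50)
  part2 <- partition_pangenome(pan2)
  expect_equal(unname(part2$counts["unique"]), 10L)
  expect_equal(unname(part2$counts["core"]), 0L)

  expect_error(build_pangenome(list(g1, g1), 50), "duplicate")
})

test_that("partition counts are conserved and follow presence patterns", {
  set.seed(13)
  fam_all <- random_protein_seq(150)
  fam_two <- random_protein_seq(150)
  fam_one <- random_protein_seq(150)
  g1 <- simple_genome("P1", c(fam_all, fam_two, fam_one))
  g2 <- simple_genome("P2", c(fam_all, fam_two))
  g3 <- simple_genome("P3", c(fam_all))
  part <- partition_pangenome(build_pangenome(list(g1, g2, g3), 50))
  expect_equal(unname(part$counts[c("core", "accessory", "unique")]),
               c(1L, 1L, 1L))
  expect_equal(sum(part$counts[c("core", "accessory", "unique")]),
               unname(part$counts["total"]))
})

test_that("pan-genome recovers the generator's family structure", {
  comm <- generate_community(synth_config(
    n_positive = 4, n_dread = 1, n_amorphous = 1, n_core = 15, n_accessory = 6,
    n_unique = 3, dread_mode = FALSE, split_gene = FALSE, seed = 42))
  pan <- build_pangenome(comm$genomes, 50)
  # every retained gene in exactly one family
  expect_equal(sort(names(pan$gene2family)),
               sort(unlist(lapply(pan$families, `[[`, "gene_ids"),
                           use.names = FALSE)))
  expect_equal(sum(pan$matrix), length(pan$gene2family))
  # family count and presence patterns equal the truth ledger
  expect_equal(length(pan$families), nrow(comm$truth$families))
  truth_patterns <- sort(vapply(comm$truth$members, function(m)
    paste(sort(names(m)[lengths(m) > 0]), collapse = ";"), character(1)))
  found_patterns <- sort(vapply(pan$families, function(f)
    paste(sort(names(f$members)[lengths(f$members) > 0]), collapse = ";"),
    character(1)))
  expect_equal(unname(found_patterns), unname(truth_patterns))
})

test_that("families at a higher threshold refine those at a lower one", {
  comm <- generate_community(synth_config(
    n_positive = 4, n_dread = 1, n_amorphous = 1, n_core = 12, n_accessory = 5,
    n_unique = 2, dread_mode = FALSE, split_gene = FALSE, seed = 17))
  cache <- pangenome_precompute(comm$genomes)
  thresholds <- c(30, 40, 50, 60, 70, 80, 90)
  pans <- lapply(thresholds, function(th)
    build_pangenome(comm$genomes, th, cache = cache))
  for (k in seq_along(thresholds)[-1]) {
    lo <- pans[[k - 1]]$gene2family
    hi <- pans[[k]]$gene2family
    # each high-threshold family maps into exactly one low-threshold family
    split_map <- tapply(lo[names(hi)], hi, function(x) length(unique(x)))
    expect_true(all(split_map == 1),
                info = paste("threshold", thresholds[k]))
  }
})

test_that("accumulation curves are monotone and Heaps fits are exact on power laws", {
  # exact power law: every genome contributes 7 new families
  g <- 7; n <- 10
  sizes <- g * (1:n)
  fit <- fit_heaps(1:n, sizes)
  expect_equal(fit$gamma, 1, tolerance = 1e-9)
  expect_equal(fit$kappa, g, tolerance = 1e-9)
  expect_true(fit$is_open)
  # identical genomes: pan size constant, closed
  fit2 <- fit_heaps(1:n, rep(120, n))
  expect_equal(fit2$gamma, 0, tolerance = 1e-12)
  expect_false(fit2$is_open)

  comm <- generate_community(synth_config(
    n_positive = 4, n_dread = 1, n_amorphous = 1, n_core = 12, n_accessory = 8,
    n_unique = 4, dread_mode = FALSE, split_gene = FALSE, seed = 19))
  pan <- build_pangenome(comm$genomes, 50)
  # per-permutation monotonicity, checked via the recorded curve summaries
  acc <- accumulation_and_heaps(pan, n_perm = 25, seed = 7)
  expect_true(all(diff(acc$curve$median_pan) >= 0))
  expect_true(all(diff(acc$curve$median_core) <= 0))
  expect_true(all(diff(acc$curve$mean_pan) >= 0))
  expect_true(all(diff(acc$curve$mean_core) <= 0))
  # determinism under the seed
  acc2 <- accumulation_and_heaps(pan, n_perm = 25, seed = 7)
  expect_equal(acc2$curve, acc$curve)
})
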