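# The presence/absence trait screen: inclusion/exclusion rules, planted
# cluster recovery, coverage flags, distant homolog follow-up, monotonicity.

# small community shared across tests in this file
screen_comm <- generate_community(synth_config(
  n_positive = 5, n_dread = 1, n_amorphous = 1, n_core = 20, n_accessory = 8,
  n_unique = 3, cluster_size = 3, neighbor_size = 2, n_decoys = 2,
  dread_mode = TRUE, split_gene = TRUE, seed = 23))
screen_pan <- build_pangenome(screen_comm$genomes, 50)
screen_tus <- trait_unique_families(screen_pan, screen_comm$traits)

test_that("the screen applies the all-positives / no-negatives rule exactly", {
  pos <- screen_comm$traits$positives
  neg <- screen_comm$traits$negatives
  P <- screen_pan$matrix > 0
  for (fid in colnames(screen_pan$matrix)) {
    in_all_pos <- all(P[pos, fid])
    in_no_neg <- !any(P[neg, fid])
    expect_equal(fid %in% screen_tus$family_ids, in_all_pos && in_no_neg,
                 info = fid)
  }
  # a decoy (all positives + one negative) is never returned
  for (tid in screen_comm$truth$decoy_family_ids) {
    decoy_genes <- unlist(screen_comm$truth$members[[tid]], use.names = FALSE)
    decoy_fams <- unique(screen_pan$gene2family[decoy_genes])
    expect_length(intersect(decoy_fams, screen_tus$family_ids), 0)
  }
})

test_that("the screen recovers exactly the planted cluster families", {
  planted <- sort(unname(unlist(lapply(
    screen_comm$truth$members[screen_comm$truth$cluster_family_ids],
    function(m) unlist(m[screen_comm$traits$positives], use.names = FALSE)))))
  found <- sort(unname(unlist(lapply(screen_tus$members, function(m)
    unlist(m, use.names = FALSE)))))
  expect_equal(found, planted)
  expect_length(screen_tus$family_ids, length(screen_comm$truth$cluster_family_ids))
})

test_that("genomes missing from the trait table are an error", {
  tt <- trait_table(setNames("stalk", screen_pan$genomes[1]))
  expect_error(trait_unique_families(screen_pan, tt), "missing from trait table")
})

test_that("coverage filter flags exactly the split-gene family", {
  cov <- coverage_filter(screen_tus, screen_pan, min_cov = 70)
  split_fam <- unname(screen_pan$gene2family[
    screen_comm$truth$split$fragment_gene_ids[1]])
  expect_false(cov$pass[split_fam])
  expect_true(all(cov$pass[setdiff(names(cov$pass), split_fam)]))
  expect_true(all(cov$flags$family_id == split_fam))
  # flagged fragments have sub-threshold coverage against the longest member
  expect_true(all(pmin(cov$flags$query_cov, cov$flags$subject_cov) < 70))
})

test_that("distant homolog search recovers dread-genome homologs in the window", {
  outgroups <- Filter(function(g)
    screen_comm$traits$assignments[g$genome_id] == "dread", screen_comm$genomes)
  hits <- distant_homolog_search(screen_tus, screen_pan, outgroups,
                                 floor_pid = 20, ceiling_pid = 40)
  expect_true(all(hits$pid >= 20 & hits$pid < 40))
  expect_true(all(hits$coverage >= 50))
  # every reported gene is a planted homolog from the ledger
  expect_true(all(hits$gene_id %in% screen_comm$truth$dread_gene_ids))
  # most planted homologs fall inside the window (targets 25-38 vs members)
  expect_gte(nrow(hits), length(screen_comm$truth$cluster_family_ids) - 1)
  # ceiling semantics: nothing at or above the ceiling
  none <- distant_homolog_search(screen_tus, screen_pan, outgroups,
                                 floor_pid = 20, ceiling_pid = 20)
  expect_equal(nrow(none), 0)
})

test_that("removing a positive genome can only grow the trait-unique set", {
  drop_id <- screen_comm$traits$positives[3]
  kept <- setdiff(screen_pan$genomes, drop_id)
  genomes2 <- Filter(function(g) g$genome_id != drop_id, screen_comm$genomes)
  pan2 <- build_pangenome(genomes2, 50)
  tt2 <- trait_table(screen_comm$traits$assignments[kept])
  tus2 <- trait_unique_families(pan2, tt2)
  # compare by member gene sets (family ids differ between pans)
  sets1 <- vapply(screen_tus$members, function(m)
    paste(sort(setdiff(unlist(m, use.names = FALSE),
                       screen_comm$genomes[[match(drop_id, screen_pan$genomes)]]$genes$gene_id)),
          collapse = ";"), character(1))
  sets2 <- vapply(tus2$members, function(m)
    paste(sort(unlist(m, use.names = FALSE)), collapse = ";"), character(1))
  expect_true(all(sets1 %in% sets2))
  expect_gte(length(tus2$family_ids), length(screen_tus$family_ids))
})

test_that("threshold sweep finds a ~60% cluster at low thresholds only", {
  comm <- generate_community(synth_config(
    n_positive = 4, n_dread = 1, n_amorphous = 1, n_core = 15, n_accessory = 6,
    n_unique = 3, cluster_size = 3, cluster_pid = c(60, 60),
    dread_mode = FALSE, split_gene = FALSE, seed = 31))
  sweep <- threshold_sweep(comm$genomes, comm$traits,
                           thresholds = c(30, 40, 50, 60, 80, 90))
  for (th in c("30", "40", "50", "60"))
    expect_length(sweep$sets[[th]]$family_ids, 3)
  for (th in c("80", "90"))
    expect_length(sweep$sets[[th]]$family_ids, 0)
  # a 100%-identical cluster is found at every threshold
  comm2 <- generate_community(synth_config(
    n_positive = 4, n_dread = 1, n_amorphous = 1, n_core = 15, n_accessory = 6,
    n_unique = 3, cluster_size = 3, cluster_pid = c(100, 100),
    dread_mode = FALSE, split_gene = FALSE, seed = 32))
  sweep2 <- threshold_sweep(comm2$genomes, comm2$traits,
                            thresholds = c(30, 60, 90))
  for (th in names(sweep2$sets))
    expect_length(sweep2$sets[[th]]$family_ids, 3)
  # union report covers the requested range and deduplicates gene sets
  expect_equal(sort(unique(sweep2$union$n_genes)), 4L)
  expect_equal(nrow(sweep2$union), 3L)
})
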