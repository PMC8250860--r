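# Synthetic-community generator: annotated genome sets with the statistical
# structure the trait screen assumes (shared core pool, patterned accessory
# genes, strain-specific genes, a planted trait-linked syntenic cluster,
# decoy families, distant homologs in some trait-negative genomes, and a
# split-gene assembly artifact), plus a machine-readable truth ledger.

#' Configuration for the synthetic community
#'
#' Defaults mirror the 16-genome study design the screen targets: 11
#' trait-positive (stalk) genomes and 5 trait-negative ones (2 dread + 3
#' amorphous), a planted six-gene trait-linked cluster at mid-range
#' conservation (55-75% member identity), a five-gene conserved neighbor
#' cassette directly adjacent to it, decoy families that miss the screen rule
#' by exactly one negative genome, distant homologs of the cluster (25-38%
#' identity) in the dread genomes, and one positive genome carrying one
#' cluster gene split across two contigs.
#'
#' Divergence within a family is substitution-only over a family-wide set of
#' variable positions, so member identities stay close to the family target
#' (both to the family reference and pairwise) and coverage stays ~100%; the
#' split-gene artifact is the only coverage perturbation.
#'
#' @param n_positive,n_dread,n_amorphous Genome counts per trait group
#'   (defaults 11/2/3).
#' @param n_core Core families present in all genomes (default 150, test
#'   scale).
#' @param n_accessory Accessory families (default 60), each present in a
#'   contiguous block of 2..n-1 genomes over a fixed genome ordering
#'   (phylogeny-like patterning).
#' @param n_unique Strain-specific families per genome (default 10).
#' @param cluster_size Planted trait-linked cluster size (default 6).
#' @param cluster_pid Identity target range in percent for cluster members
#'   (default `c(55, 75)`).
#' @param neighbor_size Conserved cassette adjacent to the cluster (default
#'   5); these families also occur in negatives and are never trait-unique.
#' @param n_decoys Families present in all positives plus exactly one
#'   negative (default 2), near-miss controls for the screen's negation rule.
#' @param dread_mode Plant distant homologs of every cluster family in the
#'   dread genomes (default `TRUE`).
#' @param dread_pid Identity target range for distant homologs (default
#'   `c(25, 38)`).
#' @param split_gene Split one cluster gene of one positive genome into two
#'   fragments on two contigs (default `TRUE`).
#' @param core_pid,accessory_pid,neighbor_pid Identity target ranges for the
#'   other family classes.
#' @param len_meanlog,len_sdlog Protein length distribution (lognormal,
#'   median 300 aa).
#' @param cog_assign_prob Fraction of genes receiving a COG category.
#' @param enriched_category COG letter injected into all planted cluster and
#'   decoy genes (default `"M"`).
#' @param seed RNG seed (default 42).
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n_positive = 11, n_dread = 2, n_amorphous = 3,
                         n_core = 150, n_accessory = 60, n_unique = 10,
                         cluster_size = 6, cluster_pid = c(55, 75),
                         neighbor_size = 5, n_decoys = 2,
                         dread_mode = TRUE, dread_pid = c(25, 38),
                         split_gene = TRUE,
                         core_pid = c(70, 95), accessory_pid = c(60, 90),
                         neighbor_pid = c(60, 85),
                         len_meanlog = log(300), len_sdlog = 0.35,
                         cog_assign_prob = 0.8, enriched_category = "M",
                         seed = 42) {
  cfg <- as.list(environment())
  stopifnot(n_positive >= 2, n_dread + n_amorphous >= 1,
            all(c(cluster_pid, core_pid, accessory_pid, dread_pid) > 0),
            all(c(cluster_pid, core_pid, accessory_pid, dread_pid) <= 100),
            cluster_size >= 1, n_core >= 0, n_accessory >= 0, n_unique >= 0)
  structure(cfg, class = "synth_config")
}

# replacement letters drawn with BLOSUM-favored probabilities, never the
# original residue
blosum_replace <- function(orig, n) {
  aa <- strsplit(STANDARD_AA, "")[[1]]
  if (is.null(.stalkscan_env$repl_weights)) {
    B <- blosum62()[aa, aa]
    W <- exp(B / 2)
    diag(W) <- 0
    .stalkscan_env$repl_weights <- W
  }
  sample(aa, n, replace = TRUE, prob = .stalkscan_env$repl_weights[orig, ])
}

# vectorised: one replacement per original residue
blosum_replace_vec <- function(origs) {
  out <- character(length(origs))
  for (l in unique(origs)) {
    sel <- origs == l
    out[sel] <- blosum_replace(l, sum(sel))
  }
  out
}

random_protein <- function(len) {
  aa <- strsplit(STANDARD_AA, "")[[1]]
  paste0("M", paste(sample(aa, len - 1, replace = TRUE), collapse = ""))
}

#' Mutate a protein to a target percent identity
#'
#' Substitution-only divergence: `round((1 - target/100) * L)` uniformly
#' chosen positions are replaced by BLOSUM-favored different residues, so the
#' realized ungapped identity equals the target up to rounding (always within
#' 2 points for sequences of 25+ residues). Deterministic under `seed`.
#'
#' @param seq Protein sequence.
#' @param target_pid Target percent identity in (0, 100].
#' @param seed RNG seed (optional; uses current RNG state when `NULL`).
#' @return List with `seq` (mutated sequence) and `realized_pid`.
#' @export
mutate_to_identity <- function(seq, target_pid, seed = NULL) {
  stopifnot(target_pid > 0, target_pid <= 100)
  with_seed(seed, {
    L <- nchar(seq)
    m <- round((1 - target_pid / 100) * L)
    if (m == 0) return(list(seq = seq, realized_pid = 100))
    chars <- strsplit(seq, "")[[1]]
    pos <- sample.int(L, m)
    chars[pos] <- blosum_replace_vec(chars[pos])
    list(seq = paste(chars, collapse = ""), realized_pid = 100 * (L - m) / L)
  })
}

# family with a shared set of variable positions: every member randomizes the
# same positions, so pairwise identities track the target, not its square
make_family <- function(ref, target_pid, member_names) {
  L <- nchar(ref)
  m <- round((1 - target_pid / 100) * L)
  V <- if (m > 0) sample.int(L, m) else integer(0)
  refc <- strsplit(ref, "")[[1]]
  members <- vapply(member_names, function(nm) {
    chars <- refc
    if (m > 0)
      chars[V] <- blosum_replace_vec(refc[V])
    paste(chars, collapse = "")
  }, character(1))
  list(members = members, variable = V, realized_pid = 100 * (L - m) / L)
}

# a more distant homolog of the same family: variable set is a superset of
# the family's, so identity to every member stays near the homolog target
make_distant_homolog <- function(ref, variable, target_pid) {
  L <- nchar(ref)
  m_h <- round((1 - target_pid / 100) * L)
  extra <- setdiff(seq_len(L), variable)
  V_h <- c(variable, sample(extra, max(0, m_h - length(variable))))
  refc <- strsplit(ref, "")[[1]]
  chars <- refc
  chars[V_h] <- blosum_replace_vec(refc[V_h])
  list(seq = paste(chars, collapse = ""), realized_pid = 100 * (L - length(V_h)) / L)
}

#' Generate a synthetic community with a truth ledger
#'
#' Builds annotated genomes (1-3 contigs each, consistent coordinates) whose
#' gene content follows the configured family plan, with the planted cluster
#' contiguous and order-conserved in every positive genome and the neighbor
#' cassette directly adjacent to it. The ledger records every planted family,
#' its members per genome, target and realized identities, the trait pattern,
#' decoys, distant-homolog placements and the split-gene artifact, so every
#' pipeline stage can be scored without re-alignment.
#'
#' @param config A [synth_config()].
#' @return List with `genomes` (list of [new_genome()]), `truth` (ledger),
#'   `traits` (a [trait_table()]), `cogs` (named character gene -> category),
#'   `config`.
#' @export
generate_community <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  genes_per_genome <- cfg$n_core + cfg$n_accessory + cfg$n_unique +
    cfg$cluster_size + cfg$neighbor_size + cfg$n_decoys + 2
  if (genes_per_genome * (3 * 1500 + 3 + 200) > 1e8)
    stop("config demands more genes than coordinate space allows")

  pos_ids <- sprintf("STK%02d", seq_len(cfg$n_positive))
  drd_ids <- if (cfg$n_dread > 0) sprintf("DRD%02d", seq_len(cfg$n_dread)) else character(0)
  amo_ids <- if (cfg$n_amorphous > 0) sprintf("AMO%02d", seq_len(cfg$n_amorphous)) else character(0)
  all_ids <- c(pos_ids, drd_ids, amo_ids)
  n_gen <- length(all_ids)
  traits <- trait_table(setNames(c(rep("stalk", cfg$n_positive),
                                   rep("dread", cfg$n_dread),
                                   rep("amorphous", cfg$n_amorphous)), all_ids))

  with_seed(cfg$seed, {
    rand_len <- function(n, lo = 80, hi = 1200)
      pmin(pmax(round(rlnorm(n, cfg$len_meanlog, cfg$len_sdlog)), lo), hi)

    fams <- list() # truth_id -> list(type, target, realized, members, product, variable, ref)
    add_family <- function(type, target, member_genomes, len = NULL,
                           product = "hypothetical protein") {
      id <- sprintf("T%04d", length(fams) + 1L)
      L <- if (is.null(len)) rand_len(1) else len
      ref <- random_protein(L)
      fam <- make_family(ref, target, member_genomes)
      fams[[id]] <<- list(truth_id = id, type = type, target_pid = target,
                          realized_pid = fam$realized_pid,
                          members = as.list(fam$members), ref = ref,
                          variable = fam$variable, product = product)
      id
    }

    for (i in seq_len(cfg$n_core))
      add_family("core", runif(1, cfg$core_pid[1], cfg$core_pid[2]), all_ids,
                 product = "conserved hypothetical protein")
    for (i in seq_len(cfg$n_accessory)) {
      # accessory families are phylogenetically patterned, never trait-linked:
      # reject blocks that would replicate the exact positives-only pattern
      repeat {
        size <- sample(2:(n_gen - 1), 1)
        start <- sample.int(n_gen, 1)
        block <- all_ids[((start + seq_len(size) - 2L) %% n_gen) + 1L]
        trait_like <- all(pos_ids %in% block) &&
          !any(setdiff(all_ids, pos_ids) %in% block)
        if (!trait_like) break
      }
      add_family("accessory", runif(1, cfg$accessory_pid[1], cfg$accessory_pid[2]),
                 block, product = "putative protein")
    }
    for (g in all_ids) for (i in seq_len(cfg$n_unique))
      add_family("unique", 100, g)

    cluster_ids <- vapply(seq_len(cfg$cluster_size), function(i)
      add_family("cluster", runif(1, cfg$cluster_pid[1], cfg$cluster_pid[2]),
                 pos_ids, len = sample(250:450, 1)), character(1))

    neighbor_products <- c("ATP-ADP antiporter", "phosphomannose isomerase",
                           "N-acetylmuramoyl-L-alanine amidase",
                           "ABC transporter permease", "hypothetical protein")
    neighbor_ids <- vapply(seq_len(cfg$neighbor_size), function(i) {
      extra <- if (i < cfg$neighbor_size || length(amo_ids) == 0) drd_ids else amo_ids[1]
      add_family("neighbor", runif(1, cfg$neighbor_pid[1], cfg$neighbor_pid[2]),
                 c(pos_ids, extra),
                 product = neighbor_products[min(i, length(neighbor_products))])
    }, character(1))

    negs <- traits$negatives
    decoy_ids <- vapply(seq_len(cfg$n_decoys), function(i)
      add_family("decoy", runif(1, cfg$cluster_pid[1], cfg$cluster_pid[2]),
                 c(pos_ids, negs[((i - 1) %% length(negs)) + 1])), character(1))

    # distant homologs of the planted cluster in the dread genomes
    dread_hits <- list()
    if (cfg$dread_mode && length(drd_ids) > 0) {
      for (tid in cluster_ids) {
        f <- fams[[tid]]
        for (dg in drd_ids) {
          t_h <- runif(1, cfg$dread_pid[1], cfg$dread_pid[2])
          h <- make_distant_homolog(f$ref, f$variable, t_h)
          fams[[tid]]$members[[dg]] <- h$seq
          dread_hits[[length(dread_hits) + 1]] <- data.frame(
            truth_id = tid, genome_id = dg, target_pid = t_h,
            realized_pid = h$realized_pid)
        }
      }
    }

    # split-gene artifact: second positive genome carries cluster gene 1 as
    # two fragments on two contigs (C-terminal part stays in the cassette)
    split_info <- NULL
    if (cfg$split_gene && cfg$n_positive >= 2) {
      sg <- pos_ids[2]
      tid <- cluster_ids[1]
      full <- fams[[tid]]$members[[sg]]
      cut <- floor(nchar(full) * 0.55)
      split_info <- list(genome_id = sg, truth_id = tid,
                         frag_n = substr(full, 1, cut),
                         frag_c = substr(full, cut + 1, nchar(full)))
      fams[[tid]]$members[[sg]] <- split_info$frag_c # cassette keeps part 2
    }

    # ---- genome layout ----
    genomes <- list()
    truth_members <- lapply(fams, function(f)
      setNames(vector("list", n_gen), all_ids))
    dread_gene_ids <- character(0)
    split_fragment_ids <- character(0)
    cogs <- character(0)

    for (g in all_ids) {
      entries <- list() # (truth_id, protein, product, block)
      for (tid in names(fams)) {
        f <- fams[[tid]]
        if (!is.null(f$members[[g]]))
          entries[[length(entries) + 1]] <- list(
            truth_id = tid, protein = f$members[[g]], product = f$product,
            block = if (f$type %in% c("cluster", "neighbor")) "cassette"
                    else if (f$type == "cluster") "cluster" else "free")
      }
      is_dread_carrier <- cfg$dread_mode && g %in% drd_ids
      blocks <- vapply(entries, `[[`, character(1), "block")
      tids <- vapply(entries, `[[`, character(1), "truth_id")
      # dread genomes carry cluster homologs contiguously as well
      if (is_dread_carrier)
        blocks[tids %in% cluster_ids] <- "cassette"
      cass_order <- c(cluster_ids, neighbor_ids)
      cass_sel <- which(blocks == "cassette")
      cass_sel <- cass_sel[order(match(tids[cass_sel], cass_order))]
      free_sel <- setdiff(seq_along(entries), cass_sel)
      free_sel <- sample(free_sel)

      n_contigs <- sample(1:3, 1)
      force_second <- !is.null(split_info) && g == split_info$genome_id
      if (force_second) n_contigs <- max(2L, n_contigs)
      contig_of <- sample.int(n_contigs, length(free_sel), replace = TRUE)
      cass_contig <- if (length(cass_sel)) sample.int(n_contigs, 1) else NA

      per_contig <- lapply(seq_len(n_contigs), function(ct) free_sel[contig_of == ct])
      if (length(cass_sel)) {
        ct <- cass_contig
        at <- sample(0:length(per_contig[[ct]]), 1)
        per_contig[[ct]] <- append(per_contig[[ct]], cass_sel, after = at)
      }
      # split fragment (N-terminal part) goes on a different contig
      extra_frag <- NULL
      if (force_second) {
        other_ct <- if (!is.na(cass_contig)) (cass_contig %% n_contigs) + 1L else 1L
        extra_frag <- list(contig = other_ct, protein = split_info$frag_n,
                           truth_id = split_info$truth_id)
      }

      rows <- list()
      k <- 0L
      for (ct in seq_len(n_contigs)) {
        idxs <- per_contig[[ct]]
        prots <- lapply(entries[idxs], `[[`, "protein")
        tid_ct <- vapply(entries[idxs], `[[`, character(1), "truth_id")
        prod_ct <- vapply(entries[idxs], `[[`, character(1), "product")
        if (!is.null(extra_frag) && extra_frag$contig == ct) {
          at <- sample(0:length(prots), 1)
          prots <- append(prots, list(extra_frag$protein), after = at)
          tid_ct <- append(tid_ct, extra_frag$truth_id, after = at)
          prod_ct <- append(prod_ct, "hypothetical protein", after = at)
        }
        pos <- sample(50:150, 1)
        for (e in seq_along(prots)) {
          k <- k + 1L
          gene_id <- sprintf("%s_%05d", g, k)
          len_nt <- 3L * nchar(prots[[e]]) + 3L
          rows[[k]] <- data.frame(
            gene_id = gene_id, contig_id = sprintf("%s_c%d", g, ct),
            start = pos, end = pos + len_nt - 1L,
            strand = sample(c("+", "-"), 1), product = prod_ct[e],
            protein = prots[[e]], stringsAsFactors = FALSE)
          truth_members[[tid_ct[e]]][[g]] <-
            c(truth_members[[tid_ct[e]]][[g]], gene_id)
          if (is_dread_carrier && tid_ct[e] %in% cluster_ids)
            dread_gene_ids <- c(dread_gene_ids, gene_id)
          if (force_second && tid_ct[e] == split_info$truth_id)
            split_fragment_ids <- c(split_fragment_ids, gene_id)
          pos <- pos + len_nt + sample(20:200, 1)
        }
      }
      gdf <- do.call(rbind, rows)
      genomes[[g]] <- new_genome(g, gdf)
      # COG assignment: baseline random, planted cluster/decoy genes enriched
      assigned <- runif(nrow(gdf)) < cfg$cog_assign_prob
      cats <- sample(COG_CATEGORIES, nrow(gdf), replace = TRUE)
      planted <- vapply(gdf$gene_id, function(id) any(vapply(
        c(cluster_ids, decoy_ids), function(tid)
          id %in% truth_members[[tid]][[g]], logical(1))), logical(1))
      cats[planted] <- cfg$enriched_category
      assigned[planted] <- TRUE
      cogs <- c(cogs, setNames(cats[assigned], gdf$gene_id[assigned]))
    }

    # realized pairwise identities among positive-genome members (full-length)
    fam_table <- do.call(rbind, lapply(names(fams), function(tid) {
      f <- fams[[tid]]
      mem <- truth_members[[tid]]
      genomes_in <- names(mem)[lengths(mem) > 0]
      seqs <- unlist(f$members[intersect(genomes_in, pos_ids)])
      seqs <- seqs[nchar(seqs) == nchar(f$ref)] # exclude fragments
      min_pw <- NA_real_
      if (length(seqs) >= 2) {
        pw <- combn(seq_along(seqs), 2, function(ij)
          hamming_pid(seqs[ij[1]], seqs[ij[2]]))
        min_pw <- min(pw)
      }
      data.frame(truth_id = tid, type = f$type, target_pid = f$target_pid,
                 realized_pid = f$realized_pid, min_pairwise_pid = min_pw,
                 n_genomes = length(genomes_in),
                 genomes = paste(genomes_in, collapse = ";"),
                 stringsAsFactors = FALSE)
    }))

    truth <- list(
      families = fam_table,
      members = truth_members,
      cluster_family_ids = cluster_ids,
      neighbor_family_ids = neighbor_ids,
      decoy_family_ids = decoy_ids,
      dread_hits = if (length(dread_hits)) do.call(rbind, dread_hits) else NULL,
      dread_gene_ids = dread_gene_ids,
      split = if (!is.null(split_info)) list(
        genome_id = split_info$genome_id, truth_id = split_info$truth_id,
        fragment_gene_ids = split_fragment_ids) else NULL,
      seed = cfg$seed)

    list(genomes = unname(genomes), truth = truth, traits = traits,
         cogs = cogs, config = cfg)
  })
}

#' Write a generated community to disk
#'
#' Emits `genomes/<id>.gff3` + `genomes/<id>.faa` per genome, `traits.tsv`,
#' `cogs.tsv` and `truth.json` under `out_dir`. Refuses to write into an
#' existing non-empty directory unless `force = TRUE`.
#'
#' @param community A [generate_community()] result.
#' @param out_dir Output directory.
#' @param force Overwrite into a non-empty directory.
#' @return `out_dir`, invisibly.
#' @export
emit_files <- function(community, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force)
    stop("output directory exists and is not empty: ", out_dir,
         " (use force = TRUE)")
  dir.create(file.path(out_dir, "genomes"), recursive = TRUE, showWarnings = FALSE)
  for (g in community$genomes)
    write_genome_files(g, file.path(out_dir, "genomes", paste0(g$genome_id, ".gff3")),
                       file.path(out_dir, "genomes", paste0(g$genome_id, ".faa")))
  write_trait_table(community$traits, file.path(out_dir, "traits.tsv"))
  cog_df <- data.frame(gene_id = names(community$cogs),
                       categories = unname(community$cogs))
  utils::write.table(cog_df, file.path(out_dir, "cogs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(community$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
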