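# Pan-genome construction: partial-sequence filtering, greedy pre-clustering
# (CD-HIT style), all-vs-all similarity graph over representatives, Markov
# clustering, and the genome x family presence/absence matrix.

# Combine the gene tables of several genomes into one data.frame
combine_genes <- function(genomes) {
  ids <- vapply(genomes, `[[`, character(1), "genome_id")
  if (anyDuplicated(ids))
    stop("duplicate genome_ids: ", ids[duplicated(ids)][1])
  do.call(rbind, lapply(genomes, function(g)
    cbind(genome_id = g$genome_id, g$genes, stringsAsFactors = FALSE)))
}

#' Filter partial coding sequences
#'
#' Removes genes whose protein is shorter than `min_len` or contains an
#' internal stop symbol (`*`), before pan-genome construction.
#'
#' @param genes data.frame of gene records (needs a `protein` column).
#' @param min_len Minimum protein length in residues (default 40).
#' @return List with `retained` and `rejected` data.frames.
#' @export
filter_partial <- function(genes, min_len = 40) {
  stopifnot(min_len >= 1)
  ok <- nchar(genes$protein) >= min_len & !grepl("*", genes$protein, fixed = TRUE)
  list(retained = genes[ok, , drop = FALSE],
       rejected = genes[!ok, , drop = FALSE])
}

#' Greedy pre-clustering of near-identical sequences
#'
#' Single greedy longest-first pass: each gene joins the first existing
#' representative (in representative creation order) with percent identity
#' `>= pre_pid` and mutual coverage `>= pre_cov`, otherwise it becomes a new
#' representative. Captures near-identical redundancy before the similarity
#' graph, leaving threshold-sensitive divergence to MCL.
#'
#' @param genes data.frame of (filtered) gene records with `gene_id`, `protein`.
#' @param pre_pid Identity threshold in percent (default 95).
#' @param pre_cov Mutual coverage threshold in percent (default 90).
#' @param submat Substitution matrix.
#' @return List with `members` (named list representative gene_id -> member
#'   gene_ids, representative included) and `assignment` (named character:
#'   gene_id -> representative gene_id).
#' @export
precluster <- function(genes, pre_pid = 95, pre_cov = 90, submat = blosum62()) {
  n <- nrow(genes)
  ord <- order(-nchar(genes$protein), genes$gene_id)
  seqs <- genes$protein[ord]
  ids <- genes$gene_id[ord]
  # candidate neighbours by shared 5-mers; a pair at >= pre_pid identity and
  # mutual coverage shares at least ~(1 - 5*(1-pid))*(L-4) distinct 5-mers,
  # so requiring half of that never loses a true near-duplicate while
  # excluding ordinary within-family similarity
  cand <- candidate_pairs(seqs, k = 5, min_shared = 3)
  if (nrow(cand)) {
    lens <- nchar(seqs)
    need <- pmax(3, floor(0.5 * (pmin(lens[cand$i], lens[cand$j]) - 4)))
    cand <- cand[cand$shared >= need, , drop = FALSE]
  }
  adj <- vector("list", n)
  if (nrow(cand)) {
    for (r in seq_len(nrow(cand))) {
      i <- cand$i[r]; j <- cand$j[r]
      lo <- min(i, j); hi <- max(i, j)
      adj[[hi]] <- c(adj[[hi]], lo) # earlier (longer) gene is candidate rep
    }
  }
  rep_of <- integer(n) # index into ord-space
  rep_order <- integer(0)
  is_rep <- logical(n)
  for (g in seq_len(n)) {
    assigned <- FALSE
    cands <- adj[[g]]
    cands <- cands[is_rep[cands]]
    if (length(cands)) {
      # "first representative": representative creation order
      cands <- cands[order(match(cands, rep_order))]
      for (r in cands) {
        st <- align_pair(seqs[g], seqs[r], submat = submat)
        if (st$pid >= pre_pid && st$query_cov >= pre_cov &&
            st$subject_cov >= pre_cov) {
          rep_of[g] <- r
          assigned <- TRUE
          break
        }
      }
    }
    if (!assigned) {
      rep_of[g] <- g
      is_rep[g] <- TRUE
      rep_order <- c(rep_order, g)
    }
  }
  members <- split(ids, ids[rep_of])
  members <- members[ids[rep_order]] # representative creation order
  list(members = members,
       assignment = setNames(ids[rep_of], ids))
}

#' Build the all-vs-all protein similarity graph
#'
#' Aligns candidate pairs (k-mer prescreen, then full alignment) among
#' representative sequences and keeps undirected edges where percent identity
#' is `>= min_pid` and both coverages are `>= min_cov`. The graph-stage
#' coverage floor is deliberately lenient (default 40%): with free terminal
#' gaps, two unrelated proteins can align a short segment above 30% identity,
#' and the floor removes such spurious edges while still letting split-gene
#' fragments (~45-55% of their full-length homologs) cluster with their
#' family. Strict coverage auditing happens downstream in
#' [coverage_filter()].
#'
#' @param reps data.frame with `gene_id`, `protein` for representatives.
#' @param min_pid Minimum percent identity for an edge.
#' @param min_cov Minimum mutual coverage in percent (default 40; 0 disables).
#' @param stats Optional precomputed [align_stats()] table over candidate
#'   pairs of `reps` (columns `i`, `j`, `pid`, `query_cov`, `subject_cov`).
#' @param submat Substitution matrix.
#' @return Object of class `similarity_graph`: list with `nodes`, `edges`
#'   (data.frame `from`, `to`, `pid`), `threshold`.
#' @export
build_similarity_graph <- function(reps, min_pid, min_cov = 40, stats = NULL,
                                   submat = blosum62()) {
  stopifnot(nrow(reps) >= 1)
  if (is.null(stats)) stats <- rep_pair_stats(reps, submat)
  keep <- stats$pid >= min_pid
  if (min_cov > 0)
    keep <- keep & stats$query_cov >= min_cov & stats$subject_cov >= min_cov
  keep[is.na(keep)] <- FALSE
  e <- stats[keep, , drop = FALSE]
  structure(list(nodes = reps$gene_id,
                 edges = data.frame(from = reps$gene_id[e$i],
                                    to = reps$gene_id[e$j],
                                    pid = e$pid, stringsAsFactors = FALSE),
                 threshold = min_pid),
            class = "similarity_graph")
}

# Alignment statistics over k-mer candidate pairs of representatives.
# min_shared = 4 pins the prescreen's detection limit near 40% identity for
# typical (300 aa) proteins: a pair at identity p shares ~L*p^4 distinct
# 4-mers (plus ~0.5 background), so pairs at >= 50% identity are essentially
# never missed while random pairs are rejected with p > 0.99. Homologs below
# ~40% identity are deliberately left to distant_homolog_search(), which
# aligns without a prescreen.
rep_pair_stats <- function(reps, submat = blosum62(), min_shared = 4) {
  cand <- candidate_pairs(reps$protein, k = 4, min_shared = min_shared)
  cand <- filter_background(cand, nchar(reps$protein), min_shared)
  align_stats(reps$protein, cand$i, cand$j, submat = submat)
}

# Drop candidate pairs whose shared 4-mer count is consistent with chance.
# Two unrelated sequences of lengths La, Lb share ~La*Lb/20^4 distinct 4-mers
# by chance (20-letter alphabet); we require the observed count to exceed
# that background by 4 standard deviations plus a margin of 2. A pair at
# >= 45% identity shares ~0.45^4 * minL true 4-mers on top of background,
# which clears the cut at all realistic lengths; this pins the prescreen's
# effective detection limit at roughly 40-45% identity.
filter_background <- function(cand, lens, min_shared) {
  if (nrow(cand) == 0) return(cand)
  lambda <- lens[cand$i] * lens[cand$j] / 20^4
  need <- pmax(min_shared, ceiling(lambda + 4 * sqrt(lambda) + 2))
  cand[cand$shared >= need, , drop = FALSE]
}

#' Markov clustering of a similarity graph
#'
#' MCL with pinned numerics: self-loop weight equal to the node's maximum
#' incident edge weight (1 for isolated nodes), expansion by squaring the
#' column-stochastic matrix, elementwise inflation, pruning of entries below
#' `prune`, and convergence when the maximum elementwise change drops below
#' `tol`. Clusters are read from attractor rows; a node attracted to several
#' attractor systems goes to the one with the largest flow, ties broken by
#' lexicographically smallest node id. Disconnected components are clustered
#' independently (MCL flow can never cross components).
#'
#' @param graph A [build_similarity_graph()] result.
#' @param inflation Inflation exponent (> 1), default 1.5.
#' @param tol Convergence tolerance on the max elementwise change.
#' @param max_iter Maximum iterations; non-convergence yields the current
#'   interpretation with a warning.
#' @param prune Entries below this value are zeroed after inflation.
#' @return List of character vectors (node sets), a partition of all nodes.
#' @export
mcl_cluster <- function(graph, inflation = 1.5, tol = 1e-6, max_iter = 100,
                        prune = 1e-5) {
  stopifnot(inflation > 1)
  ig <- igraph::graph_from_data_frame(
    graph$edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = graph$nodes))
  comp <- igraph::components(ig)$membership
  clusters <- list()
  for (cid in sort(unique(comp))) {
    nodes <- sort(names(comp)[comp == cid])
    if (length(nodes) == 1) {
      clusters <- c(clusters, list(nodes))
      next
    }
    sel <- graph$edges$from %in% nodes
    e <- graph$edges[sel, , drop = FALSE]
    W <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
    W[cbind(e$from, e$to)] <- e$pid
    W[cbind(e$to, e$from)] <- e$pid
    clusters <- c(clusters, mcl_dense(W, inflation, tol, max_iter, prune))
  }
  clusters[order(vapply(clusters, min, character(1)))]
}

# dense MCL on one connected component
mcl_dense <- function(W, inflation, tol, max_iter, prune) {
  nodes <- rownames(W)
  loop <- apply(W, 1, max)
  loop[loop <= 0] <- 1
  diag(W) <- loop
  M <- sweep(W, 2, colSums(W), "/")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2[M2 < prune] <- 0
    cs <- colSums(M2)
    cs[cs == 0] <- 1
    M2 <- sweep(M2, 2, cs, "/")
    if (max(abs(M2 - M)) < tol) {
      M <- M2
      converged <- TRUE
      break
    }
    M <- M2
  }
  if (!converged)
    warning("MCL did not converge after ", max_iter,
            " iterations; interpreting current matrix")
  attractors <- nodes[diag(M) > 0]
  if (length(attractors) == 0) attractors <- nodes[1]
  # attractor systems: attractors linked by positive flow share a cluster
  asys <- setNames(seq_along(attractors), attractors)
  for (i in seq_along(attractors)) for (j in seq_along(attractors)) {
    if (i < j && (M[attractors[i], attractors[j]] > 0 ||
                  M[attractors[j], attractors[i]] > 0)) {
      old <- asys[j]
      asys[asys == old] <- asys[i]
    }
  }
  groups <- split(attractors, asys)
  assign_to <- setNames(rep(NA_integer_, length(nodes)), nodes)
  for (gi in seq_along(groups)) assign_to[groups[[gi]]] <- gi
  for (nd in nodes[is.na(assign_to)]) {
    flows <- M[attractors, nd]
    mx <- max(flows)
    if (mx > 0) {
      best <- sort(attractors[flows == mx])[1] # ties: lexicographic node id
      assign_to[nd] <- assign_to[best]
    } else {
      groups <- c(groups, list(nd))
      assign_to[nd] <- length(groups)
    }
  }
  unname(lapply(split(nodes, assign_to), sort))
}

#' Build a pan-genome at one identity threshold
#'
#' Full composition: [filter_partial()] -> [precluster()] ->
#' [build_similarity_graph()] -> [mcl_cluster()] -> re-expansion of
#' pre-cluster members into gene families, plus the genome x family count
#' matrix. Paralogs (several members of one genome in a family) are kept in
#' one family.
#'
#' @param genomes List of [new_genome()] objects (>= 2, unique ids).
#' @param min_pid Minimum percent identity defining the similarity graph.
#' @param min_len Partial-sequence filter length (default 40 aa).
#' @param pre_pid,pre_cov Pre-clustering thresholds (defaults 95/90).
#' @param min_cov Graph-stage coverage filter (default 40, see
#'   [build_similarity_graph()]).
#' @param inflation MCL inflation (default 1.5).
#' @param submat Substitution matrix.
#' @param cache Optional result of [pangenome_precompute()], shared across a
#'   threshold sweep so alignments are computed once.
#' @return Object of class `pangenome`: list with `threshold`, `families`
#'   (each: `family_id`, `members` genome -> gene ids, `representative`),
#'   `genomes`, `matrix` (genome x family counts), `gene2family`,
#'   `gene_genome`, `proteins`.
#' @export
build_pangenome <- function(genomes, min_pid, min_len = 40, pre_pid = 95,
                            pre_cov = 90, min_cov = 40, inflation = 1.5,
                            submat = blosum62(), cache = NULL) {
  if (is.null(cache))
    cache <- pangenome_precompute(genomes, min_len = min_len, pre_pid = pre_pid,
                                  pre_cov = pre_cov, submat = submat)
  graph <- build_similarity_graph(cache$reps, min_pid, min_cov = min_cov,
                                  stats = cache$stats, submat = submat)
  clusters <- mcl_cluster(graph, inflation = inflation)
  genome_ids <- vapply(genomes, `[[`, character(1), "genome_id")
  pre_members <- cache$pre$members
  gene_genome <- setNames(cache$genes$genome_id, cache$genes$gene_id)
  proteins <- setNames(cache$genes$protein, cache$genes$gene_id)

  fams <- lapply(clusters, function(nodes) {
    gene_ids <- sort(unlist(pre_members[nodes], use.names = FALSE))
    members <- lapply(setNames(genome_ids, genome_ids), function(g)
      gene_ids[gene_genome[gene_ids] == g])
    rep_id <- gene_ids[order(-nchar(proteins[gene_ids]), gene_ids)][1]
    list(members = members, representative = rep_id, gene_ids = gene_ids)
  })
  sizes <- vapply(fams, function(f) length(f$gene_ids), integer(1))
  firsts <- vapply(fams, function(f) f$gene_ids[1], character(1))
  fams <- fams[order(-sizes, firsts)]
  for (i in seq_along(fams)) fams[[i]]$family_id <- sprintf("F%05d", i)

  mat <- matrix(0L, length(genome_ids), length(fams),
                dimnames = list(genome_ids,
                                vapply(fams, `[[`, character(1), "family_id")))
  g2f <- character(0)
  for (f in fams) {
    mat[, f$family_id] <- vapply(genome_ids, function(g)
      length(f$members[[g]]), integer(1))
    g2f[f$gene_ids] <- f$family_id
  }
  structure(list(threshold = min_pid, families = fams, genomes = genome_ids,
                 matrix = mat, gene2family = g2f, gene_genome = gene_genome,
                 proteins = proteins),
            class = "pangenome")
}

#' @export
print.pangenome <- function(x, ...) {
  cat(sprintf("pan-genome at %g%% identity: %d families, %d genomes, %d genes\n",
              x$threshold, length(x$families), length(x$genomes),
              length(x$gene2family)))
  invisible(x)
}

#' Precompute the threshold-independent pan-genome stages
#'
#' Filtering, pre-clustering, and all candidate-pair alignments are identical
#' for every identity threshold; a sweep reuses this cache.
#'
#' @inheritParams build_pangenome
#' @return List with `genes` (filtered gene table incl. `genome_id`), `pre`
#'   (pre-clustering), `reps` (representative table), `stats` (alignment
#'   statistics over candidate representative pairs).
#' @export
pangenome_precompute <- function(genomes, min_len = 40, pre_pid = 95,
                                 pre_cov = 90, submat = blosum62()) {
  stopifnot(length(genomes) >= 2)
  all_genes <- combine_genes(genomes)
  filt <- filter_partial(all_genes, min_len = min_len)
  genes <- filt$retained
  pre <- precluster(genes, pre_pid = pre_pid, pre_cov = pre_cov, submat = submat)
  reps <- genes[match(names(pre$members), genes$gene_id), , drop = FALSE]
  stats <- rep_pair_stats(reps, submat)
  list(genes = genes, rejected = filt$rejected, pre = pre, reps = reps,
       stats = stats)
}

#' Partition a pan-genome into core / accessory / strain-specific families
#'
#' Core families are present in all n genomes, accessory in 2..n-1, and
#' strain-specific (unique) in exactly 1.
#'
#' @param pan A [build_pangenome()] result.
#' @return List with `counts` (core, accessory, unique, total) and `class`
#'   (named character per family).
#' @export
partition_pangenome <- function(pan) {
  n <- length(pan$genomes)
  present <- colSums(pan$matrix > 0)
  cls <- ifelse(present == n, "core", ifelse(present == 1, "unique", "accessory"))
  counts <- c(core = sum(cls == "core"), accessory = sum(cls == "accessory"),
              unique = sum(cls == "unique"), total = length(cls))
  list(counts = counts, class = setNames(cls, colnames(pan$matrix)),
       n_genomes_per_family = present)
}

#' Fit Heaps' law to a gene accumulation curve
#'
#' Least-squares fit of `log(size) ~ log(N)`; the pan-genome is called open
#' when the exponent gamma exceeds 0.01.
#'
#' @param N Number of genomes (1..n).
#' @param sizes Pan-genome sizes at each N.
#' @return List with `kappa`, `gamma`, `is_open`.
#' @export
fit_heaps <- function(N, sizes) {
  stopifnot(length(N) == length(sizes), length(N) >= 2)
  fit <- stats::lm(log(sizes) ~ log(N))
  gamma <- unname(coef(fit)[2])
  kappa <- exp(unname(coef(fit)[1]))
  list(kappa = kappa, gamma = gamma, is_open = gamma > 0.01)
}

#' Gene accumulation curves and Heaps-law openness
#'
#' For `n_perm` random genome orderings, records pan-genome size, core-genome
#' size and new families per added genome, then fits Heaps' law to the median
#' pan sizes.
#'
#' @param pan A [build_pangenome()] result.
#' @param n_perm Number of random genome orderings (default 100).
#' @param seed RNG seed for the permutations (default 42).
#' @return List with `curve` (data.frame: N, mean/median/sd of pan and core
#'   sizes, median new families) and `heaps` ([fit_heaps()] result).
#' @export
accumulation_and_heaps <- function(pan, n_perm = 100, seed = 42) {
  stopifnot(n_perm >= 1)
  P <- pan$matrix > 0
  n <- nrow(P)
  pan_sizes <- matrix(0L, n_perm, n)
  core_sizes <- matrix(0L, n_perm, n)
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      ord <- sample.int(n)
      Q <- P[ord, , drop = FALSE]
      first_seen <- apply(Q, 2, which.max)              # first genome with family
      absent_at <- apply(!Q, 2, function(x)             # first genome lacking it
        if (any(x)) which.max(x) else n + 1L)
      pan_sizes[p, ] <- vapply(seq_len(n), function(N)
        sum(first_seen <= N), integer(1))
      core_sizes[p, ] <- vapply(seq_len(n), function(N)
        sum(absent_at > N), integer(1))
    }
  })
  new_genes <- t(apply(pan_sizes, 1, function(x) diff(c(0L, x))))
  curve <- data.frame(
    N = seq_len(n),
    mean_pan = colMeans(pan_sizes), median_pan = apply(pan_sizes, 2, median),
    sd_pan = apply(pan_sizes, 2, sd),
    mean_core = colMeans(core_sizes), median_core = apply(core_sizes, 2, median),
    sd_core = apply(core_sizes, 2, sd),
    median_new = apply(new_genes, 2, median))
  list(curve = curve, heaps = fit_heaps(curve$N, curve$median_pan), seed = seed)
}
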