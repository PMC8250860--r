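# Average amino-acid identity (AAI) from reciprocal best hits, Bray-Curtis
# dissimilarity of AAI profiles, and average-linkage (UPGMA) clustering.

#' Two-way AAI between a pair of genomes
#'
#' Aligns candidate gene pairs between the two proteomes, finds the best hit
#' of every gene in each direction (by percent identity, ties by score then
#' lexicographic gene id), keeps reciprocal pairs passing the identity and
#' coverage thresholds, and reports the mean and standard deviation of their
#' identities. Coverage is the alignment span over the length of the shorter
#' sequence of the pair (CompareM-style defaults: 30% identity, 70% coverage).
#'
#' @param a,b [new_genome()] objects.
#' @param min_pid Minimum percent identity of an ortholog pair (default 30).
#' @param min_cov Minimum coverage in percent of the shorter sequence
#'   (default 70).
#' @param submat Substitution matrix.
#' @return Object of class `aai_result`: list with `genome_a`, `genome_b`,
#'   `mean_pid`, `sd_pid`, `n_orthologs`. With zero orthologs the mean and sd
#'   are `NA`.
#' @export
compute_aai <- function(a, b, min_pid = 30, min_cov = 70, submat = blosum62()) {
  ga <- a$genes; gb <- b$genes
  seqs <- c(ga$protein, gb$protein)
  na <- nrow(ga)
  # background-aware prescreen, detection limit ~40% identity (see
  # rep_pair_stats); orthologs passing the AAI thresholds share far more
  cand <- candidate_pairs(seqs, k = 4, min_shared = 3)
  cand <- cand[(cand$i <= na) != (cand$j <= na), , drop = FALSE] # cross-genome only
  cand <- filter_background(cand, nchar(seqs), 3)
  st <- align_stats(seqs, cand$i, cand$j, submat = submat)
  if (nrow(st)) {
    ia <- pmin(st$i, st$j); ib <- pmax(st$i, st$j) - na
    cov_short <- ifelse(nchar(ga$protein)[ia] <= nchar(gb$protein)[ib],
                        ifelse(st$i <= na, st$query_cov, st$subject_cov),
                        ifelse(st$i <= na, st$subject_cov, st$query_cov))
    hits <- data.frame(ia = ia, ib = ib, pid = st$pid, score = st$score,
                       cov = cov_short)
    hits <- hits[hits$pid >= min_pid & hits$cov >= min_cov, , drop = FALSE]
  } else hits <- data.frame(ia = integer(), ib = integer(), pid = numeric(),
                            score = numeric(), cov = numeric())
  n_orth <- 0L; mean_pid <- NA_real_; sd_pid <- NA_real_
  if (nrow(hits)) {
    best_of <- function(df, key_col, other_ids) {
      # best partner per gene: max pid, ties by score, then lexicographic id
      o <- order(df[[key_col]], -df$pid, -df$score, other_ids)
      df <- df[o, , drop = FALSE]
      df[!duplicated(df[[key_col]]), , drop = FALSE]
    }
    best_a <- best_of(hits, "ia", gb$gene_id[hits$ib])
    best_b <- best_of(hits, "ib", ga$gene_id[hits$ia])
    key_a <- paste(best_a$ia, best_a$ib)
    key_b <- paste(best_b$ia, best_b$ib)
    rec <- best_a[key_a %in% key_b, , drop = FALSE]
    n_orth <- nrow(rec)
    if (n_orth > 0) {
      mean_pid <- mean(rec$pid)
      sd_pid <- if (n_orth > 1) sd(rec$pid) else 0
    }
  }
  structure(list(genome_a = a$genome_id, genome_b = b$genome_id,
                 mean_pid = mean_pid, sd_pid = sd_pid, n_orthologs = n_orth),
            class = "aai_result")
}

#' Bray-Curtis dissimilarity of two numeric profiles
#'
#' `sum(|x - y|) / sum(x + y)` over shared coordinates.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Dissimilarity in `[0, 1]` for non-negative input.
#' @export
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y))
  s <- sum(x + y)
  if (s == 0) return(0)
  sum(abs(x - y)) / s
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Plain O(n^3) agglomeration on a dissimilarity matrix. At each step the pair
#' with the smallest average dissimilarity is merged; ties are broken by the
#' lexicographically smallest label pair. Merge heights are the average
#' dissimilarity between the merged clusters (cophenetic convention, as in
#' `hclust(method = "average")`).
#'
#' @param d Symmetric dissimilarity matrix with dimnames.
#' @return Object of class `upgma_tree`: hclust-style `merge` matrix,
#'   `height`, `labels`.
#' @export
upgma <- function(d) {
  labels <- rownames(d)
  n <- length(labels)
  stopifnot(n >= 2, all(dim(d) == n))
  active <- seq_len(n)
  node_of <- -seq_len(n)          # hclust convention: leaves negative
  sizes <- rep(1L, n)
  firsts <- labels                # lexicographic tie-break key per cluster
  D <- d
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    k <- length(active)
    best <- NULL
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      key <- sort(c(firsts[i], firsts[j]))
      if (is.null(best) || D[i, j] < best$d - 1e-12 ||
          (abs(D[i, j] - best$d) <= 1e-12 &&
           (key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2])))) {
        best <- list(i = i, j = j, d = D[i, j], key = key)
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- sort(c(node_of[i], node_of[j]))
    height[step] <- best$d
    new_row <- (D[i, ] * sizes[i] + D[j, ] * sizes[j]) / (sizes[i] + sizes[j])
    keep <- setdiff(seq_len(k), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], new_row[keep]),
               c(new_row[keep], 0))
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
    node_of <- c(node_of[keep], step)
    firsts <- c(firsts[keep], min(best$key))
    active <- seq_len(k - 1)
  }
  structure(list(merge = merge, height = height, labels = labels),
            class = "upgma_tree")
}

#' All-pairs AAI matrix and its UPGMA dendrogram
#'
#' Computes AAI for every genome pair, then clusters genomes by the
#' dissimilarity of their AAI profiles. By default the dissimilarity is the
#' Bray-Curtis distance between AAI profile rows, excluding the self and
#' mutual entries of the pair; alternatively `method = "identity"` uses
#' `1 - AAI/100` directly.
#'
#' @param genomes List of [new_genome()] objects (>= 2).
#' @param min_pid,min_cov AAI ortholog thresholds, see [compute_aai()].
#' @param method Profile dissimilarity: `"braycurtis"` (default) or
#'   `"identity"`.
#' @param submat Substitution matrix.
#' @return List with `aai` (class `aai_matrix`: `genomes`, `values`, `sds`,
#'   `counts`) and `dend` (an [upgma()] tree).
#' @export
aai_matrix_and_cluster <- function(genomes, min_pid = 30, min_cov = 70,
                                   method = c("braycurtis", "identity"),
                                   submat = blosum62()) {
  method <- match.arg(method)
  stopifnot(length(genomes) >= 2)
  ids <- vapply(genomes, `[[`, character(1), "genome_id")
  n <- length(ids)
  V <- matrix(100, n, n, dimnames = list(ids, ids))
  S <- matrix(0, n, n, dimnames = list(ids, ids))
  C <- matrix(0L, n, n, dimnames = list(ids, ids))
  diag(C) <- vapply(genomes, function(g) nrow(g$genes), integer(1))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    r <- compute_aai(genomes[[i]], genomes[[j]], min_pid = min_pid,
                     min_cov = min_cov, submat = submat)
    V[i, j] <- V[j, i] <- r$mean_pid
    S[i, j] <- S[j, i] <- r$sd_pid
    C[i, j] <- C[j, i] <- r$n_orthologs
  }
  if (method == "braycurtis") {
    # profile coordinates where either AAI is undefined (no orthologs) are
    # excluded; a pair with no shared defined coordinate gets dissimilarity 1
    D <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      others <- setdiff(seq_len(n), c(i, j))
      x <- V[i, others]; y <- V[j, others]
      ok <- !is.na(x) & !is.na(y)
      D[i, j] <- D[j, i] <- if (any(ok)) bray_curtis(x[ok], y[ok]) else 1
    }
  } else {
    D <- 1 - V / 100
    D[is.na(D)] <- 1
    diag(D) <- 0
  }
  aai <- structure(list(genomes = ids, values = V, sds = S, counts = C),
                   class = "aai_matrix")
  list(aai = aai, dend = upgma(D), dissimilarity = D)
}

#' Group genomes at a species-like AAI rank
#'
#' Connected components of the graph whose edges join genome pairs with AAI
#' strictly above `cutoff` (default 95%, the conventional species boundary).
#'
#' @param aai An `aai_matrix` (from [aai_matrix_and_cluster()]).
#' @param cutoff AAI percent cutoff (strict `>`).
#' @return List of character vectors of genome ids.
#' @export
species_groups <- function(aai, cutoff = 95) {
  V <- aai$values
  A <- V > cutoff
  A[is.na(A)] <- FALSE # undefined AAI can never join genomes
  diag(A) <- TRUE
  ig <- igraph::graph_from_adjacency_matrix(A, mode = "max")
  comp <- igraph::components(ig)$membership
  grps <- split(names(comp), comp)
  grps <- lapply(grps, sort)
  unname(grps[order(vapply(grps, min, character(1)))])
}

#' Write an AAI matrix as TSV
#' @param aai An `aai_matrix`.
#' @param path Output path.
#' @export
write_aai_tsv <- function(aai, path) {
  df <- data.frame(genome_id = aai$genomes, round(aai$values, 4),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
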