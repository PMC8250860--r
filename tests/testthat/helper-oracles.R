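# Independent reference implementations ("oracles") used to validate the
# package's optimized code paths. These deliberately use naive algorithms.

# ---- brute-force alignment oracle ------------------------------------------
# Enumerates every global alignment of a and b as a sequence of columns
# (D = aligned pair, U = residue of a over a gap, L = residue of b over a
# gap), scores each under the same model as the DP kernel (free terminal gap
# runs, affine internal gaps costing open + ext * len), and returns the
# maximum score plus the set of percent identities among score-optimal
# alignments. Feasible for sequences up to ~7 residues.
oracle_align <- function(a, b, submat = stalkscan::blosum62(),
                         open = 11, ext = 1) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  n <- length(ac); m <- length(bc)
  best <- -Inf
  pids <- numeric(0)
  score_alignment <- function(moves) {
    k <- length(moves)
    # terminal gap runs: maximal run of U's or L's at the very start / end
    lead <- 0L
    if (moves[1] != "D") {
      while (lead < k && moves[lead + 1] == moves[1]) lead <- lead + 1L
    }
    trail <- 0L
    if (lead < k && moves[k] != "D") {
      while (trail < k - lead && moves[k - trail] == moves[k]) trail <- trail + 1L
    }
    core <- moves[seq_len(k)][seq.int(lead + 1, k - trail)]
    if (lead + trail >= k) return(NULL) # empty core alignment not allowed
    score <- 0
    ident <- 0L
    i <- sum(moves[seq_len(lead)] == "U")
    j <- sum(moves[seq_len(lead)] == "L")
    run <- "" # current gap run type
    for (mv in core) {
      if (mv == "D") {
        i <- i + 1L; j <- j + 1L
        score <- score + submat[ac[i], bc[j]]
        if (ac[i] == bc[j]) ident <- ident + 1L
        run <- ""
      } else {
        if (mv == "U") i <- i + 1L else j <- j + 1L
        score <- score - ext - (if (run != mv) open else 0)
        run <- mv
      }
    }
    list(score = score, pid = 100 * ident / length(core))
  }
  rec <- function(i, j, moves) {
    if (i == n && j == m) {
      r <- score_alignment(moves)
      if (is.null(r)) return()
      if (r$score > best + 1e-9) {
        best <<- r$score
        pids <<- r$pid
      } else if (abs(r$score - best) <= 1e-9) {
        pids <<- union(pids, r$pid)
      }
      return()
    }
    if (i < n && j < m) rec(i + 1, j + 1, c(moves, "D"))
    if (i < n) rec(i + 1, j, c(moves, "U"))
    if (j < m) rec(i, j + 1, c(moves, "L"))
  }
  rec(0L, 0L, character(0))
  list(score = best, pids = pids)
}

# ---- MCL reference oracle ---------------------------------------------------
# Literal matrix iteration on the full graph (no component decomposition),
# with the same pinned numerics: self-loops at max incident weight, expansion
# power 2, elementwise inflation, pruning below 1e-5, column renormalization,
# convergence below 1e-6. Clusters read from attractor rows; attractors with
# mutual flow merge; other nodes go to the attractor with the largest flow,
# ties to the lexicographically smallest node id.
oracle_mcl <- function(nodes, edges, inflation = 1.5, tol = 1e-6,
                       max_iter = 100, prune = 1e-5) {
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      W[edges$from[r], edges$to[r]] <- edges$pid[r]
      W[edges$to[r], edges$from[r]] <- edges$pid[r]
    }
  }
  loop <- apply(W, 1, max)
  loop[loop <= 0] <- 1
  diag(W) <- loop
  M <- sweep(W, 2, colSums(W), "/")
  for (it in seq_len(max_iter)) {
    M2 <- (M %*% M)^inflation
    M2[M2 < prune] <- 0
    cs <- colSums(M2); cs[cs == 0] <- 1
    M2 <- sweep(M2, 2, cs, "/")
    if (max(abs(M2 - M)) < tol) { M <- M2; break }
    M <- M2
  }
  att <- nodes[diag(M) > 0]
  grp <- setNames(seq_along(att), att)
  for (i in seq_along(att)) for (j in seq_along(att)) {
    if (i < j && (M[att[i], att[j]] > 0 || M[att[j], att[i]] > 0)) {
      grp[grp == grp[j]] <- grp[i]
    }
  }
  assign_to <- setNames(rep(NA_integer_, n), nodes)
  assign_to[att] <- grp
  for (nd in nodes[is.na(assign_to)]) {
    flows <- M[att, nd]
    if (max(flows) > 0) {
      assign_to[nd] <- grp[sort(att[flows == max(flows)])[1]]
    } else assign_to[nd] <- max(assign_to, na.rm = TRUE) + 1L
  }
  out <- lapply(split(nodes, assign_to), sort)
  unname(out[order(vapply(out, min, character(1)))])
}

# canonicalize a clustering (list of sets) for comparison
canon_clusters <- function(cl) {
  cl <- lapply(cl, sort)
  cl[order(vapply(cl, min, character(1)))]
}

# ---- UPGMA cophenetic oracle ------------------------------------------------
# cophenetic distances implied by an upgma_tree (height of the smallest
# cluster containing both leaves), for comparison with stats::hclust.
cophenetic_from_upgma <- function(tree) {
  n <- length(tree$labels)
  members <- vector("list", nrow(tree$merge))
  D <- matrix(0, n, n, dimnames = list(tree$labels, tree$labels))
  leafset <- function(node) {
    if (node < 0) -node else members[[node]]
  }
  for (s in seq_len(nrow(tree$merge))) {
    l <- leafset(tree$merge[s, 1]); r <- leafset(tree$merge[s, 2])
    for (x in l) for (y in r) {
      D[x, y] <- D[y, x] <- tree$height[s]
    }
    members[[s]] <- c(l, r)
  }
  D
}

# ---- naive motif matcher ----------------------------------------------------
naive_motif_scan <- function(seq, patterns = stalkscan::motif_patterns()) {
  chars <- strsplit(toupper(seq), "")[[1]]
  std <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  out <- list()
  for (r in seq_len(nrow(patterns))) {
    pat <- strsplit(patterns$pattern[r], "")[[1]]
    L <- length(pat)
    if (length(chars) < L) next
    for (s in seq_len(length(chars) - L + 1)) {
      win <- chars[s:(s + L - 1)]
      ok <- all(ifelse(pat == "x", win %in% std, win == pat))
      if (ok)
        out[[length(out) + 1]] <- data.frame(
          motif = patterns$name[r], start = s, end = s + L - 1L)
    }
  }
  if (!length(out))
    return(data.frame(motif = character(), start = integer(), end = integer()))
  df <- do.call(rbind, out)
  df <- df[order(df$start, df$motif), ]
  rownames(df) <- NULL
  df
}

# ---- Fisher / hypergeometric enumeration oracle -----------------------------
# Two-sided Fisher exact p for table (a, b, c, d): sum of hypergeometric
# probabilities over the support that do not exceed the observed probability.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b       # row 1 total (in partition)
  n2 <- c + d      # row 2 total
  k <- a + c       # column 1 total (with category)
  support <- max(0, k - n2):min(m, k)
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# ---- misc -------------------------------------------------------------------
random_protein_seq <- function(len, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
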