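# COG category distribution per pan-genome subdivision and Fisher-exact
# enrichment testing with Benjamini-Hochberg correction.

COG_CATEGORIES <- strsplit("JAKLBDYVTMNZWUOCGEFHIPQRS", "")[[1]]

#' Read a gene -> COG category table from TSV
#'
#' @param path TSV with columns `gene_id` and `categories` (one or more COG
#'   single-letter categories, concatenated; empty = unassigned).
#' @return Named character vector `gene_id -> categories` (possibly several
#'   letters per gene), unassigned genes omitted.
#' @export
read_cog_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("gene_id", "categories") %in% names(df)))
    stop("COG table must have columns gene_id and categories")
  x <- setNames(df$categories, df$gene_id)
  x[nzchar(x)]
}

# expand a gene->categories map to one row per (gene, single letter)
expand_cogs <- function(assign) {
  letters_per_gene <- strsplit(unname(assign), "")
  data.frame(gene_id = rep(names(assign), lengths(letters_per_gene)),
             category = unlist(letters_per_gene),
             stringsAsFactors = FALSE)
}

#' COG category distribution per pan-genome subdivision and genome
#'
#' Counts genes per COG category within each subdivision (core / accessory /
#' unique) and within each genome. A gene annotated with several categories
#' contributes to each of them.
#'
#' @param assign Named character vector `gene_id -> categories`
#'   (see [read_cog_table()]).
#' @param partition A [partition_pangenome()] result.
#' @param pan The pan-genome the partition came from.
#' @return List with `by_subdivision` and `by_genome` (count data.frames with
#'   `fraction` columns).
#' @export
category_distribution <- function(assign, partition, pan) {
  assign <- assign[names(assign) %in% names(pan$gene2family)]
  if (length(assign) == 0) {
    empty <- data.frame(group = character(), category = character(),
                        count = integer(), fraction = numeric())
    return(list(by_subdivision = empty, by_genome = empty))
  }
  long <- expand_cogs(assign)
  long$subdivision <- unname(partition$class[pan$gene2family[long$gene_id]])
  long$genome <- unname(pan$gene_genome[long$gene_id])
  tab <- function(group) {
    counts <- as.data.frame(table(group = group, category = long$category),
                            stringsAsFactors = FALSE)
    names(counts)[3] <- "count"
    totals <- tapply(counts$count, counts$group, sum)
    counts$fraction <- counts$count / as.numeric(totals[counts$group])
    counts[order(counts$group, counts$category), ]
  }
  list(by_subdivision = tab(long$subdivision), by_genome = tab(long$genome))
}

#' Fisher-exact enrichment of one COG category in one subdivision
#'
#' Two-sided Fisher exact test on the 2x2 table of assigned genes: rows
#' in/out of the subdivision, columns with/without the category. Degenerate
#' margins (a zero row or column) return an undefined odds ratio and p = 1
#' with a flag.
#'
#' @param assign Named character vector `gene_id -> categories`.
#' @param partition A [partition_pangenome()] result.
#' @param pan The pan-genome.
#' @param category COG single-letter category.
#' @param subdivision One of `"core"`, `"accessory"`, `"unique"`.
#' @return List with `category`, `subdivision`, `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `p_value`, `degenerate`.
#' @export
enrichment_test <- function(assign, partition, pan, category,
                            subdivision = "accessory") {
  assign <- assign[names(assign) %in% names(pan$gene2family)]
  stopifnot(length(assign) > 0)
  has_cat <- vapply(strsplit(unname(assign), ""), function(x)
    category %in% x, logical(1))
  in_part <- partition$class[pan$gene2family[names(assign)]] == subdivision
  a <- sum(in_part & has_cat); b <- sum(in_part & !has_cat)
  cc <- sum(!in_part & has_cat); d <- sum(!in_part & !has_cat)
  degenerate <- (a + b == 0) || (cc + d == 0) || (a + cc == 0) || (b + d == 0)
  if (degenerate) {
    or <- NA_real_; p <- 1
  } else {
    ft <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE))
    or <- unname(ft$estimate); p <- ft$p.value
  }
  list(category = category, subdivision = subdivision, a = a, b = b, c = cc,
       d = d, odds_ratio = or, p_value = p, degenerate = degenerate)
}

#' Enrichment of every COG category across subdivisions
#'
#' Runs [enrichment_test()] for each observed category in each subdivision and
#' applies Benjamini-Hochberg correction across all tests of the call.
#'
#' @inheritParams enrichment_test
#' @param subdivisions Subdivisions to test (default all three).
#' @return data.frame with columns `category`, `subdivision`, `a`, `b`, `c`,
#'   `d`, `odds_ratio`, `p_value`, `q_value`, `degenerate`.
#' @export
cog_enrichment <- function(assign, partition, pan,
                           subdivisions = c("core", "accessory", "unique")) {
  assign <- assign[names(assign) %in% names(pan$gene2family)]
  cats <- sort(unique(unlist(strsplit(unname(assign), ""))))
  rows <- list()
  for (sub in subdivisions) for (cat in cats) {
    r <- enrichment_test(assign, partition, pan, cat, sub)
    rows[[length(rows) + 1]] <- as.data.frame(r)
  }
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out[order(out$subdivision, out$category), ]
}
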