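#' Upper-tail hypergeometric probability
#'
#' Exact probability of observing `k` or more query genes in a set of size
#' `K`, drawing `n` genes from a universe of `N`: `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`.
#'
#' @param N Universe size.
#' @param K Genes in the set (within the universe).
#' @param n Query size (within the universe).
#' @param k Overlap.
#' @return Probability in (0, 1].
#' @export
hypergeom_upper <- function(N, K, n, k) {
  .assert(k >= 0 && K >= 0 && n >= 0 && N >= 0, "negative hypergeometric parameter")
  .assert(k <= min(n, K) && max(n, K) <= N,
          "hypergeometric bounds violated: need k <= min(n, K) <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment over one family of p-values (wraps
#' [stats::p.adjust()] with input validation).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, in input order.
#' @export
bh_adjust <- function(p) {
  .assert(all(is.finite(p)) && all(p >= 0 & p <= 1), "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Seed-family overrepresentation among derepressed genes
#'
#' For each seed family, tests whether genes carrying a replicated PAR-CLIP
#' hit for that family (support in at least the configured number of
#' replicas) are overrepresented among the genes up-regulated after sponge
#' treatment, by an exact hypergeometric test over the expression-filtered
#' gene universe. q-values are BH-adjusted across families (one family of
#' tests).
#'
#' @param up_genes Character vector of up-regulated genes (relaxed call set).
#' @param hit_table data.frame from [gene_hit_table()].
#' @param universe Character vector: the expression-filtered gene universe.
#' @return data.frame with `family_id`, `N`, `n`, `K`, `k`, `ratio`, `p`, `q`.
#' @export
seed_enrichment <- function(up_genes, hit_table, universe) {
  .assert(length(universe) > 0L, "empty gene universe")
  universe <- unique(universe)
  q_genes <- intersect(unique(up_genes), universe)
  fams <- sort(unique(hit_table$family_id))
  rows <- lapply(fams, function(f) {
    hits <- hit_table$gene_id[hit_table$family_id == f & hit_table$hit]
    Kset <- intersect(hits, universe)
    k <- length(intersect(q_genes, Kset))
    data.frame(
      family_id = f, N = length(universe), n = length(q_genes),
      K = length(Kset), k = k,
      ratio = if (length(Kset) > 0) k / length(Kset) else NA_real_,
      p = hypergeom_upper(length(universe), length(Kset), length(q_genes), k),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(family_id = character(), N = integer(), n = integer(),
                      K = integer(), k = integer(), ratio = numeric(),
                      p = numeric(), q = numeric(), stringsAsFactors = FALSE))
  }
  out$q <- bh_adjust(out$p)
  out
}

#' Intersect derepression and replicated PAR-CLIP binding into target calls
#'
#' The headline rule: a gene is called a direct target iff its log2 fold
#' change under the family-specific sponge exceeds the relaxed cutoff AND at
#' least one seed family of interest has PAR-CLIP support in at least the
#' required number of replicas. Output is sorted by descending log2 fold
#' change, ties broken by gene id.
#'
#' @param de_results data.frame from [de_test()].
#' @param hit_table data.frame from [gene_hit_table()].
#' @param families_of_interest Character vector of family ids.
#' @param de_cfg A [de_config()] (supplies the relaxed cutoff).
#' @return data.frame with `gene_id`, `log2fc`, `families`,
#'   `replicas_supporting`, `site_types`.
#' @export
intersect_targets <- function(de_results, hit_table, families_of_interest,
                              de_cfg = de_config()) {
  up <- de_results[de_results$log2fc > de_cfg$relaxed_log2fc, c("gene_id", "log2fc")]
  ht <- hit_table[hit_table$hit & hit_table$family_id %in% families_of_interest, , drop = FALSE]
  genes <- intersect(up$gene_id, unique(ht$gene_id))
  if (!length(genes)) {
    return(data.frame(gene_id = character(), log2fc = numeric(),
                      families = character(), replicas_supporting = character(),
                      site_types = character(), stringsAsFactors = FALSE))
  }
  rows <- lapply(genes, function(g) {
    h <- ht[ht$gene_id == g, , drop = FALSE]
    data.frame(
      gene_id = g,
      log2fc = up$log2fc[match(g, up$gene_id)],
      families = paste(h$family_id, collapse = ","),
      replicas_supporting = paste(sprintf("%s:%d", h$family_id, h$n_replicas),
                                  collapse = ","),
      site_types = paste(sort(unique(unlist(strsplit(h$site_types, ",")))),
                         collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$log2fc, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene-set overlap statistics (MSigDB-style table)
#'
#' For each gene set: K = members in the universe, k = overlap with the query
#' (within the universe), the overlap ratio k/K, an exact upper-tail
#' hypergeometric p-value, and BH q-values across the sets. Sets disjoint
#' from the universe are reported with `K = 0` and excluded from the BH
#' family.
#'
#' @param query Character vector of query genes.
#' @param gene_sets A `GeneSetCollection` from [load_gmt()].
#' @param universe Gene universe; defaults to the union of all set members
#'   and the query.
#' @return data.frame with `set_name`, `description`, `N`, `n`, `K`, `k`,
#'   `ratio`, `p`, `q`.
#' @export
set_overlap_stats <- function(query, gene_sets, universe = NULL) {
  stopifnot(inherits(gene_sets, "GeneSetCollection"))
  if (is.null(universe)) {
    universe <- union(unique(unlist(gene_sets$sets, use.names = FALSE)), query)
  }
  universe <- unique(universe)
  q_genes <- intersect(unique(query), universe)
  rows <- lapply(names(gene_sets$sets), function(s) {
    members <- intersect(gene_sets$sets[[s]], universe)
    K <- length(members)
    k <- length(intersect(q_genes, members))
    data.frame(
      set_name = s, description = gene_sets$description[[s]],
      N = length(universe), n = length(q_genes), K = K, k = k,
      ratio = if (K > 0) k / K else NA_real_,
      p = if (K > 0) hypergeom_upper(length(universe), K, length(q_genes), k)
          else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  tested <- out$K > 0
  if (any(tested)) out$q[tested] <- bh_adjust(out$p[tested])
  rownames(out) <- NULL
  out
}
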