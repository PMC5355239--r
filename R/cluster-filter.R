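#' Post-calling cluster filter configuration
#'
#' Defaults follow the published analysis: clusters restricted to 3'UTRs, a
#' retained cluster must carry a (non-6mer) seed match within 3 nt of its
#' mode location, replicate cluster overlap requires at least 10 shared bp,
#' and a gene-level PAR-CLIP hit requires support from at least 2 replicas.
#'
#' @param restrict_to_3utr Keep only 3'UTR clusters?
#' @param seed_mode_window_nt Half-width (nt) of the window around the mode
#'   location a seed match must intersect.
#' @param exclude_6mer Exclude 6mer sites from all seed-based filters?
#' @param min_cluster_overlap_bp Minimum replicate cluster overlap (bp).
#' @param min_replicas_for_hit Replicas required for a gene-level hit.
#' @param window_mode `"intersect"` (seed interval intersects the window) or
#'   `"start"` (seed start within the window).
#' @param overlap_mode `"pairwise"` (every replica pair overlaps by the
#'   minimum) or `"common_core"` (the common intersection reaches it).
#' @return Validated list of class `filter_config`.
#' @export
filter_config <- function(restrict_to_3utr = TRUE,
                          seed_mode_window_nt = 3L,
                          exclude_6mer = TRUE,
                          min_cluster_overlap_bp = 10L,
                          min_replicas_for_hit = 2L,
                          window_mode = c("intersect", "start"),
                          overlap_mode = c("pairwise", "common_core")) {
  cfg <- list(
    restrict_to_3utr = isTRUE(restrict_to_3utr),
    seed_mode_window_nt = as.integer(seed_mode_window_nt),
    exclude_6mer = isTRUE(exclude_6mer),
    min_cluster_overlap_bp = as.integer(min_cluster_overlap_bp),
    min_replicas_for_hit = as.integer(min_replicas_for_hit),
    window_mode = match.arg(window_mode),
    overlap_mode = match.arg(overlap_mode)
  )
  .assert(cfg$seed_mode_window_nt >= 0L, "seed_mode_window_nt must be >= 0")
  .assert(cfg$min_cluster_overlap_bp >= 1L, "min_cluster_overlap_bp must be >= 1")
  .assert(cfg$min_replicas_for_hit >= 1L, "min_replicas_for_hit must be >= 1")
  structure(cfg, class = "filter_config")
}

#' Restrict clusters to 3'UTRs
#'
#' @param clusters Annotated cluster `GRanges` (see [annotate_clusters()]).
#' @return The subset with `region_label == "3UTR"`.
#' @export
filter_utr3 <- function(clusters) {
  lab <- S4Vectors::mcols(clusters)$region_label
  .assert(!is.null(lab), "clusters must be annotated first (annotate_clusters)")
  clusters[!is.na(lab) & lab == "3UTR"]
}

#' Retain clusters with a seed match near the mode location
#'
#' A cluster is kept iff at least one seed match (6mers excluded by default)
#' intersects the window `mode_location +/- seed_mode_window_nt` on the same
#' strand. The retained matches are recorded per cluster in the metadata
#' columns `seed_families` and `seed_site_types` (comma-separated, unique)
#' and in the `matches` attribute (a long-format data.frame).
#'
#' @param clusters Cluster `GRanges` with `mode_location` metadata.
#' @param sites Seed-site `GRanges` from [scan_utr3_sites()].
#' @param cfg A [filter_config()].
#' @return Filtered `GRanges`; attribute `matches` maps clusters to sites.
#' @export
seed_proximity_filter <- function(clusters, sites, cfg = filter_config()) {
  if (cfg$exclude_6mer && length(sites)) {
    sites <- sites[S4Vectors::mcols(sites)$site_type != "6mer"]
  }
  if (!length(clusters) || !length(sites)) {
    out <- clusters[integer(0)]
    attr(out, "matches") <- data.frame(
      cluster = integer(), gene_id = character(), family_id = character(),
      site_type = character(), stringsAsFactors = FALSE
    )
    return(out)
  }
  w <- cfg$seed_mode_window_nt
  mode <- S4Vectors::mcols(clusters)$mode_location
  .assert(!is.null(mode), "clusters lack mode_location metadata")
  windows <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(clusters),
    IRanges::IRanges(mode - w, mode + w),
    strand = BiocGenerics::strand(clusters)
  )
  subj <- if (cfg$window_mode == "start") {
    GenomicRanges::resize(sites, width = 1L, fix = "start", ignore.strand = TRUE)
  } else {
    sites
  }
  hits <- GenomicRanges::findOverlaps(windows, subj, ignore.strand = FALSE)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  keep <- sort(unique(q))
  matches <- data.frame(
    cluster = match(q, keep),
    gene_id = S4Vectors::mcols(sites)$gene_id[s],
    family_id = S4Vectors::mcols(sites)$family_id[s],
    site_type = S4Vectors::mcols(sites)$site_type[s],
    stringsAsFactors = FALSE
  )
  out <- clusters[keep]
  fam <- vapply(seq_along(keep), function(i) {
    paste(sort(unique(matches$family_id[matches$cluster == i])), collapse = ",")
  }, "")
  st <- vapply(seq_along(keep), function(i) {
    paste(sort(unique(matches$site_type[matches$cluster == i])), collapse = ",")
  }, "")
  S4Vectors::mcols(out)$seed_families <- fam
  S4Vectors::mcols(out)$seed_site_types <- st
  attr(out, "matches") <- matches
  out
}

#' Gene-level replicate overlap
#'
#' Per-replica gene counts, pairwise shared fractions computed with respect
#' to the smaller set (the published convention), and the genes present in
#' all replicas.
#'
#' @param replicas List (length >= 2) of cluster `GRanges` with `gene_id`
#'   metadata, or of character vectors of gene identifiers.
#' @return list with `genes_per_replica` (named int), `pairwise` (data.frame
#'   `i`, `j`, `shared`, `fraction_of_smaller`), `genes_in_all` (character).
#' @export
gene_overlap <- function(replicas) {
  .assert(length(replicas) >= 2L, "need at least two replicas")
  sets <- lapply(replicas, function(r) {
    if (is.character(r)) unique(r)
    else unique(stats::na.omit(S4Vectors::mcols(r)$gene_id))
  })
  n <- length(sets)
  pw <- do.call(rbind, lapply(seq_len(n - 1L), function(i) {
    do.call(rbind, lapply((i + 1L):n, function(j) {
      shared <- length(intersect(sets[[i]], sets[[j]]))
      smaller <- min(length(sets[[i]]), length(sets[[j]]))
      data.frame(
        i = i, j = j, shared = shared,
        fraction_of_smaller = if (smaller > 0) shared / smaller else NA_real_
      )
    }))
  }))
  list(
    genes_per_replica = stats::setNames(lengths(sets), paste0("replica", seq_len(n))),
    pairwise = pw,
    genes_in_all = sort(Reduce(intersect, sets))
  )
}

#' Multi-replica cluster overlap groups
#'
#' Reports groups of one cluster per replica that mutually overlap. Under
#' `overlap_mode = "pairwise"` every replica pair in a group must share at
#' least `min_cluster_overlap_bp`; under `"common_core"` the common
#' intersection of all members must. Each cluster joins at most one group;
#' candidates are resolved greedily left-to-right along the genome.
#'
#' @param replicas List (length >= 2) of cluster `GRanges`.
#' @param cfg A [filter_config()].
#' @return list with `n_groups` and `groups` (data.frame `group`, `replica`,
#'   `chrom`, `start`, `end`).
#' @export
cluster_overlap <- function(replicas, cfg = filter_config()) {
  .assert(length(replicas) >= 2L, "need at least two replicas")
  minbp <- cfg$min_cluster_overlap_bp
  tabs <- lapply(replicas, function(gr) {
    df <- data.frame(
      chrom = as.character(GenomeInfoDb::seqnames(gr)),
      strand = as.character(BiocGenerics::strand(gr)),
      start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
      used = FALSE, stringsAsFactors = FALSE
    )
    df[order(df$chrom, df$strand, df$start, df$end), , drop = FALSE]
  })
  ov_bp <- function(a, b) {
    if (a$chrom != b$chrom || a$strand != b$strand) return(0L)
    max(0L, min(a$end, b$end) - max(a$start, b$start) + 1L)
  }
  groups <- list()
  for (a_idx in seq_len(nrow(tabs[[1L]]))) {
    anchor <- tabs[[1L]][a_idx, ]
    if (anchor$used) next
    pick <- list(anchor)
    sel <- c(a_idx, rep(NA_integer_, length(tabs) - 1L))
    ok <- TRUE
    for (r in 2L:length(tabs)) {
      cand <- which(!tabs[[r]]$used &
                      tabs[[r]]$chrom == anchor$chrom &
                      tabs[[r]]$strand == anchor$strand &
                      tabs[[r]]$start <= anchor$end &
                      tabs[[r]]$end >= anchor$start)
      found <- FALSE
      for (ci in cand) {
        b <- tabs[[r]][ci, ]
        pair_ok <- all(vapply(pick, function(p) ov_bp(p, b) >= minbp, TRUE))
        if (cfg$overlap_mode == "common_core") {
          core_s <- max(vapply(c(pick, list(b)), function(p) p$start, 1L))
          core_e <- min(vapply(c(pick, list(b)), function(p) p$end, 1L))
          pair_ok <- (core_e - core_s + 1L) >= minbp
        }
        if (pair_ok) {
          pick[[r]] <- b
          sel[r] <- ci
          found <- TRUE
          break
        }
      }
      if (!found) { ok <- FALSE; break }
    }
    if (ok) {
      tabs[[1L]]$used[a_idx] <- TRUE
      for (r in 2L:length(tabs)) tabs[[r]]$used[sel[r]] <- TRUE
      groups[[length(groups) + 1L]] <- do.call(rbind, lapply(seq_along(pick), function(r) {
        data.frame(
          group = length(groups) + 1L, replica = r,
          chrom = pick[[r]]$chrom, start = pick[[r]]$start, end = pick[[r]]$end,
          stringsAsFactors = FALSE
        )
      }))
    }
  }
  list(
    n_groups = length(groups),
    groups = if (length(groups)) do.call(rbind, groups) else
      data.frame(group = integer(), replica = integer(), chrom = character(),
                 start = integer(), end = integer(), stringsAsFactors = FALSE)
  )
}

#' Gene x seed-family replica support table
#'
#' For every gene with at least one filtered cluster anywhere, counts in how
#' many replicas the gene has a seed-filtered cluster containing each family,
#' and flags a hit when that count reaches `min_replicas_for_hit`. Site types
#' observed across replicas are aggregated per gene x family.
#'
#' @param replicas List of outputs of [seed_proximity_filter()] (one per
#'   replica; the `matches` attribute is used).
#' @param cfg A [filter_config()].
#' @return data.frame with `gene_id`, `family_id`, `n_replicas`, `hit`,
#'   `site_types`.
#' @export
gene_hit_table <- function(replicas, cfg = filter_config()) {
  .assert(length(replicas) >= 2L, "need at least two replicas")
  per_rep <- lapply(seq_along(replicas), function(r) {
    m <- attr(replicas[[r]], "matches")
    .assert(!is.null(m), "replica %d lacks seed-match records; run seed_proximity_filter", r)
    if (!nrow(m)) return(NULL)
    u <- unique(m[, c("gene_id", "family_id", "site_type")])
    u$replica <- r
    u
  })
  all_m <- do.call(rbind, per_rep)
  if (is.null(all_m) || !nrow(all_m)) {
    return(data.frame(gene_id = character(), family_id = character(),
                      n_replicas = integer(), hit = logical(),
                      site_types = character(), stringsAsFactors = FALSE))
  }
  key <- paste(all_m$gene_id, all_m$family_id, sep = "\r")
  agg <- lapply(split(all_m, key), function(d) {
    data.frame(
      gene_id = d$gene_id[1L], family_id = d$family_id[1L],
      n_replicas = length(unique(d$replica)),
      site_types = paste(sort(unique(d$site_type)), collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, agg)
  out$hit <- out$n_replicas >= cfg$min_replicas_for_hit
  out <- out[order(out$gene_id, out$family_id),
             c("gene_id", "family_id", "n_replicas", "hit", "site_types")]
  rownames(out) <- NULL
  out
}
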