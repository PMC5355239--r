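#' PAR-CLIP cluster-calling configuration
#'
#' Defaults reproduce the published PARalyzer parameterization: Gaussian
#' kernel bandwidth 3 nt, T>C conversion, minimum 5 reads per group/cluster/
#' KDE, minimum cluster size 10 nt, at least 1 conversion location and 1
#' conversion event per cluster, minimum read length 13 nt, no
#' non-conversion mismatches tolerated, and cluster boundaries extended to
#' read ends.
#'
#' @param bandwidth Gaussian kernel bandwidth (nt).
#' @param conversion Conversion type; only `"T>C"` is supported.
#' @param min_read_count_per_group Minimum reads for a read group.
#' @param min_read_count_per_cluster Minimum reads overlapping a cluster.
#' @param min_read_count_for_kde Minimum reads in a group before KDE is run.
#' @param min_cluster_size Minimum cluster span (nt).
#' @param min_conversion_locations Minimum distinct conversion positions.
#' @param min_conversion_count Minimum conversion events.
#' @param min_read_count_for_cluster_inclusion Reads required to keep a
#'   cluster (identical to the per-cluster minimum in this implementation).
#' @param min_read_length Reads shorter than this are dropped on ingest.
#' @param max_non_conversion_mismatches Reads with more non-T>C mismatches
#'   than this are dropped on ingest.
#' @param extend_by_read Extend cluster boundaries to the outermost ends of
#'   overlapping reads?
#' @param max_seed_match_length Longest seed-site type considered (8 = up to
#'   8mer sites).
#' @return A validated list of class `parclip_config`.
#' @export
parclip_config <- function(bandwidth = 3,
                           conversion = "T>C",
                           min_read_count_per_group = 5L,
                           min_read_count_per_cluster = 5L,
                           min_read_count_for_kde = 5L,
                           min_cluster_size = 10L,
                           min_conversion_locations = 1L,
                           min_conversion_count = 1L,
                           min_read_count_for_cluster_inclusion = 5L,
                           min_read_length = 13L,
                           max_non_conversion_mismatches = 0L,
                           extend_by_read = TRUE,
                           max_seed_match_length = 8L) {
  .assert(identical(conversion, "T>C"), "only T>C conversion is supported")
  cfg <- list(
    bandwidth = bandwidth, conversion = conversion,
    min_read_count_per_group = as.integer(min_read_count_per_group),
    min_read_count_per_cluster = as.integer(min_read_count_per_cluster),
    min_read_count_for_kde = as.integer(min_read_count_for_kde),
    min_cluster_size = as.integer(min_cluster_size),
    min_conversion_locations = as.integer(min_conversion_locations),
    min_conversion_count = as.integer(min_conversion_count),
    min_read_count_for_cluster_inclusion = as.integer(min_read_count_for_cluster_inclusion),
    min_read_length = as.integer(min_read_length),
    max_non_conversion_mismatches = as.integer(max_non_conversion_mismatches),
    extend_by_read = isTRUE(extend_by_read),
    max_seed_match_length = as.integer(max_seed_match_length)
  )
  counts <- unlist(cfg[grepl("^min_", names(cfg))])
  .assert(all(counts > 0L), "all minimum-count parameters must be positive")
  .assert(bandwidth > 0, "bandwidth must be positive")
  .assert(cfg$max_non_conversion_mismatches >= 0L, "mismatch tolerance must be >= 0")
  structure(cfg, class = "parclip_config")
}

# ---- alignment container ---------------------------------------------------

.new_alignments <- function(chrom, strand, start, width, mm_pos, mm_ref, mm_read) {
  df <- data.frame(
    chrom = as.character(chrom), strand = as.character(strand),
    start = as.integer(start), width = as.integer(width),
    stringsAsFactors = FALSE
  )
  df$mm_pos <- mm_pos
  df$mm_ref <- mm_ref
  df$mm_read <- mm_read
  .assert(all(df$strand %in% c("+", "-")), "read strand must be + or -")
  for (i in seq_len(nrow(df))) {
    p <- df$mm_pos[[i]]
    if (length(p)) {
      .assert(all(p >= df$start[i] & p < df$start[i] + df$width[i]),
              "mismatch position outside read %d", i)
    }
  }
  class(df) <- c("parclip_alignments", "data.frame")
  df
}

#' Read / write the 7-column alignment TSV
#'
#' Tabular alignment interchange format: `chrom`, `strand`, `start` (1-based,
#' leftmost genomic), `length`, and comma-separated `mm_pos` (genomic 1-based
#' position), `mm_ref`, `mm_read` for per-read mismatches (`.` when none).
#' Records are assumed to be unique-mapper alignments.
#'
#' @param path TSV path.
#' @return `read_alignments_tsv`: a `parclip_alignments` data.frame with
#'   list-columns `mm_pos`, `mm_ref`, `mm_read`.
#' @export
read_alignments_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "integer",
                                         "integer", "character", "character",
                                         "character"))
  .assert(all(c("chrom", "strand", "start", "length", "mm_pos", "mm_ref", "mm_read")
              %in% names(df)),
          "alignment TSV must have columns chrom, strand, start, length, mm_pos, mm_ref, mm_read")
  .new_alignments(df$chrom, df$strand, df$start, df$length,
                  .uncollapse_int(df$mm_pos),
                  .uncollapse_chr(df$mm_ref),
                  .uncollapse_chr(df$mm_read))
}

#' @rdname read_alignments_tsv
#' @param aln A `parclip_alignments` data.frame.
#' @export
write_alignments_tsv <- function(aln, path) {
  out <- data.frame(
    chrom = aln$chrom, strand = aln$strand, start = aln$start, length = aln$width,
    mm_pos = vapply(aln$mm_pos, .collapse, ""),
    mm_ref = vapply(aln$mm_ref, .collapse, ""),
    mm_read = vapply(aln$mm_read, .collapse, ""),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Reconstruct per-read mismatches from SAM via Rsamtools (MD/NM tags).
# Only gapless alignments (pure-match CIGARs) are supported; anything else is
# rejected with advice to use the TSV path.
.read_alignments_sam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("rname", "strand", "pos", "qwidth", "seq", "cigar"),
    tag = c("MD", "NM")
  )
  b <- Rsamtools::scanBam(bam, param = p)[[1L]]
  keep <- !is.na(b$pos)
  md <- b$tag$MD[keep]
  .assert(!any(is.na(md)),
          "SAM records lack MD tags; mismatches are unrecoverable - supply the 7-column TSV instead")
  cigar <- b$cigar[keep]
  .assert(all(grepl("^[0-9]+M$", cigar)),
          "SAM records with indels/clipping are not supported - supply the 7-column TSV instead")
  seqs <- as.character(b$seq[keep])
  pos <- b$pos[keep]
  n <- length(pos)
  mm_pos <- vector("list", n); mm_ref <- vector("list", n); mm_read <- vector("list", n)
  for (i in seq_len(n)) {
    toks <- regmatches(md[i], gregexpr("[0-9]+|\\^[A-Z]+|[A-Z]", md[i]))[[1L]]
    .assert(!any(startsWith(toks, "^")),
            "SAM records with deletions are not supported - supply the 7-column TSV instead")
    off <- 0L; ps <- integer(0); rf <- character(0); rd <- character(0)
    for (t in toks) {
      if (grepl("^[0-9]+$", t)) {
        off <- off + as.integer(t)
      } else {
        off <- off + 1L
        ps <- c(ps, pos[i] + off - 1L)
        rf <- c(rf, t)
        rd <- c(rd, substr(seqs[i], off, off))
      }
    }
    mm_pos[[i]] <- ps; mm_ref[[i]] <- rf; mm_read[[i]] <- rd
  }
  .new_alignments(as.character(b$rname[keep]), as.character(b$strand[keep]),
                  pos, b$qwidth[keep], mm_pos, mm_ref, mm_read)
}

# conversion indicator in genome coordinates: T>C on +, A>G on - (which is
# T>C in read orientation)
.is_conversion <- function(strand, ref, read) {
  (strand == "+" & ref == "T" & read == "C") |
    (strand == "-" & ref == "A" & read == "G")
}

#' Ingest PAR-CLIP alignments with read-level filters
#'
#' Loads alignments from SAM (MD/NM tags required, gapless records) or the
#' 7-column TSV, then applies the read-level filters: minimum read length and
#' the non-conversion mismatch budget (with the default budget of 0, any read
#' carrying a mismatch other than T>C in read orientation is dropped; on the
#' minus strand a genomic A>G is the read-orientation T>C).
#'
#' @param x Path to a `.sam`/`.tsv` file, or a `parclip_alignments` data.frame.
#' @param cfg A [parclip_config()].
#' @param apply_filters Apply the read-level filters? Set `FALSE` to obtain
#'   the raw ingest, e.g. for [mutation_profile()] over all mismatch events.
#' @return A `parclip_alignments` data.frame.
#' @export
ingest_alignments <- function(x, cfg = parclip_config(), apply_filters = TRUE) {
  aln <- if (is.character(x)) {
    ext <- tolower(tools::file_ext(x))
    switch(ext,
      sam = .read_alignments_sam(x),
      bam = .read_alignments_sam(x),
      tsv = read_alignments_tsv(x),
      txt = read_alignments_tsv(x),
      stop("unsupported alignment extension '", ext, "'")
    )
  } else {
    .assert(inherits(x, "parclip_alignments"), "x must be a path or parclip_alignments")
    x
  }
  if (!apply_filters || nrow(aln) == 0L) return(aln)
  keep_len <- aln$width >= cfg$min_read_length
  n_noncv <- vapply(seq_len(nrow(aln)), function(i) {
    sum(!.is_conversion(aln$strand[i], aln$mm_ref[[i]], aln$mm_read[[i]]))
  }, 1L)
  out <- aln[keep_len & n_noncv <= cfg$max_non_conversion_mismatches, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mismatch (mutation-class) profile of an alignment set
#'
#' Tabulates all mismatch events by class in read orientation (minus-strand
#' records are complemented), as percentages of all mismatch events: the
#' diagnostic in which PAR-CLIP libraries show a dominant T>C share.
#'
#' @param aln A `parclip_alignments` data.frame.
#' @return data.frame with `class` (12 rows, `"X>Y"`), `count`, `percent`;
#'   attribute `empty = TRUE` when no mismatches exist.
#' @export
mutation_profile <- function(aln) {
  bases <- c("A", "C", "G", "T")
  classes <- as.vector(outer(bases, bases, function(a, b) paste0(a, ">", b)))
  classes <- classes[substr(classes, 1, 1) != substr(classes, 3, 3)]
  ref <- unlist(aln$mm_ref, use.names = FALSE)
  read <- unlist(aln$mm_read, use.names = FALSE)
  strand <- rep(aln$strand, lengths(aln$mm_ref))
  if (length(ref)) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    minus <- strand == "-"
    ref[minus] <- comp[ref[minus]]
    read[minus] <- comp[read[minus]]
    cls <- paste0(ref, ">", read)
    count <- vapply(classes, function(k) sum(cls == k), 1L)
  } else {
    count <- rep(0L, length(classes))
  }
  total <- sum(count)
  out <- data.frame(
    class = classes, count = count,
    percent = if (total > 0) 100 * count / total else rep(0, length(classes)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "empty") <- total == 0L
  out
}

#' Chain overlapping reads into read groups
#'
#' Reads on the same chromosome and strand are chained by transitive overlap
#' (1-based closed intervals; a shared base suffices). Groups with fewer than
#' `min_read_count_per_group` reads are discarded.
#'
#' @param aln A `parclip_alignments` data.frame.
#' @param cfg A [parclip_config()].
#' @return List of `read_group` objects: `list(chrom, strand, start, end,
#'   reads)` with `reads` the member alignments.
#' @export
group_reads <- function(aln, cfg = parclip_config()) {
  if (nrow(aln) == 0L) return(list())
  ord <- order(aln$chrom, aln$strand, aln$start, aln$start + aln$width)
  aln <- aln[ord, , drop = FALSE]
  end <- aln$start + aln$width - 1L
  key <- paste(aln$chrom, aln$strand)
  new_grp <- c(TRUE, key[-1L] != key[-length(key)] |
                 aln$start[-1L] > cummax_by(end, key)[-length(key)])
  gid <- cumsum(new_grp)
  groups <- split(seq_len(nrow(aln)), gid)
  out <- lapply(groups, function(idx) {
    reads <- aln[idx, , drop = FALSE]
    rownames(reads) <- NULL
    structure(list(
      chrom = reads$chrom[1L], strand = reads$strand[1L],
      start = min(reads$start), end = max(reads$start + reads$width - 1L),
      reads = reads
    ), class = "read_group")
  })
  out <- out[vapply(out, function(g) nrow(g$reads), 1L) >= cfg$min_read_count_per_group]
  names(out) <- NULL
  out
}

# running max of `x` restarted at each new value of `key`
cummax_by <- function(x, key) {
  out <- x
  for (i in seq_along(x)[-1L]) {
    if (key[i] == key[i - 1L]) out[i] <- max(out[i - 1L], x[i])
  }
  out
}

# positions in [start, end] of the group's chromosome whose reference base is
# the sense-strand T (genomic T on +, genomic A on -)
.sense_t_positions <- function(group, genome) {
  .assert(group$chrom %in% names(genome),
          "sequence '%s' not found in FASTA store", group$chrom)
  s <- as.character(Biostrings::subseq(genome[[group$chrom]], group$start, group$end))
  target <- if (group$strand == "+") "T" else "A"
  group$start - 1L + which(strsplit(s, "")[[1L]] == target)
}

#' Two-signal kernel density estimate over a read group
#'
#' At every position of the group span, evaluates a Gaussian kernel density
#' estimate `(1/m) * sum G((p - x)/bandwidth)` over (a) all T>C conversion
#' events and (b) all non-converted sense-strand T positions covered by reads
#' (one event per read and position, so both signals are read-count
#' weighted). Each signal is normalized by its own event count `m`, making
#' the two comparable as densities: conversion evidence concentrated at a
#' crosslink site then locally exceeds the diffuse non-conversion density.
#' The comparison of the two signals defines cluster candidate regions.
#'
#' @param group A `read_group` from [group_reads()].
#' @param genome `DNAStringSet` of reference sequences.
#' @param cfg A [parclip_config()].
#' @return list with `pos` (group positions), `conversion`, `nonconversion`
#'   (densities), and `conv_events` (genomic positions, with multiplicity).
#' @export
kde_signal <- function(group, genome, cfg = parclip_config()) {
  pos <- group$start:group$end
  reads <- group$reads
  tpos <- .sense_t_positions(group, genome)
  conv_events <- integer(0)
  nonconv_events <- integer(0)
  for (i in seq_len(nrow(reads))) {
    r_start <- reads$start[i]; r_end <- r_start + reads$width[i] - 1L
    conv_i <- reads$mm_pos[[i]][.is_conversion(reads$strand[i],
                                               reads$mm_ref[[i]],
                                               reads$mm_read[[i]])]
    conv_events <- c(conv_events, conv_i)
    covered_t <- tpos[tpos >= r_start & tpos <= r_end]
    nonconv_events <- c(nonconv_events, setdiff(covered_t, conv_i))
  }
  kern <- function(events) {
    if (!length(events)) return(numeric(length(pos)))
    rowSums(stats::dnorm(outer(pos, events, "-") / cfg$bandwidth)) / length(events)
  }
  list(
    pos = pos,
    conversion = kern(conv_events),
    nonconversion = kern(nonconv_events),
    conv_events = conv_events
  )
}

#' Call conversion-evidence clusters within a read group
#'
#' Candidate intervals are maximal runs of positions where the conversion
#' density strictly exceeds the non-conversion density. With
#' `extend_by_read`, each candidate is extended to the outermost ends of the
#' reads overlapping it. Candidates failing the minimum cluster size, read
#' count, conversion-location or conversion-count thresholds are discarded.
#' The mode location is the position of maximal conversion density within the
#' cluster span (leftmost on ties).
#'
#' @inheritParams kde_signal
#' @return [GenomicRanges::GRanges] of clusters with metadata `read_count`,
#'   `conv_count`, `conv_locs`, `mode_location`.
#' @export
call_clusters <- function(group, genome, cfg = parclip_config()) {
  empty <- GenomicRanges::GRanges(
    read_count = integer(), conv_count = integer(),
    conv_locs = integer(), mode_location = integer()
  )
  if (nrow(group$reads) < cfg$min_read_count_for_kde) return(empty)
  sig <- kde_signal(group, genome, cfg)
  above <- sig$conversion > sig$nonconversion
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  reads <- group$reads
  r_start <- reads$start; r_end <- reads$start + reads$width - 1L
  out <- list()
  for (k in runs) {
    cand_s <- sig$pos[starts[k]]; cand_e <- sig$pos[ends[k]]
    ov <- r_start <= cand_e & r_end >= cand_s
    span_s <- cand_s; span_e <- cand_e
    if (cfg$extend_by_read && any(ov)) {
      span_s <- min(span_s, r_start[ov]); span_e <- max(span_e, r_end[ov])
    }
    n_reads <- sum(r_start <= span_e & r_end >= span_s)
    conv_in <- sig$conv_events[sig$conv_events >= span_s & sig$conv_events <= span_e]
    if (span_e - span_s + 1L < cfg$min_cluster_size) next
    if (n_reads < cfg$min_read_count_per_cluster ||
        n_reads < cfg$min_read_count_for_cluster_inclusion) next
    if (length(unique(conv_in)) < cfg$min_conversion_locations) next
    if (length(conv_in) < cfg$min_conversion_count) next
    in_span <- sig$pos >= span_s & sig$pos <= span_e
    mode_loc <- sig$pos[in_span][which.max(sig$conversion[in_span])]
    gr <- GenomicRanges::GRanges(group$chrom,
      IRanges::IRanges(span_s, span_e),
      strand = group$strand,
      read_count = n_reads, conv_count = length(conv_in),
      conv_locs = length(unique(conv_in)), mode_location = mode_loc
    )
    out[[length(out) + 1L]] <- gr
  }
  if (!length(out)) return(empty)
  do.call(c, out)
}

#' Call clusters over a whole alignment set
#'
#' Convenience wrapper: [group_reads()] then [call_clusters()] per group.
#'
#' @param aln A `parclip_alignments` data.frame (post-ingest filters).
#' @inheritParams kde_signal
#' @return Sorted `GRanges` of clusters.
#' @export
call_parclip_clusters <- function(aln, genome, cfg = parclip_config()) {
  groups <- group_reads(aln, cfg)
  res <- lapply(groups, call_clusters, genome = genome, cfg = cfg)
  res <- res[vapply(res, length, 1L) > 0L]
  if (!length(res)) {
    return(GenomicRanges::GRanges(
      read_count = integer(), conv_count = integer(),
      conv_locs = integer(), mode_location = integer()
    ))
  }
  # the seqlevel-merge warning when concatenating across contigs is benign
  all_cl <- suppressWarnings(do.call(c, res))
  BiocGenerics::sort(all_cl, ignore.strand = TRUE)
}

#' Annotate clusters with gene and region labels
#'
#' Each cluster is labeled by the region class with which it shares the most
#' bases; ties are broken by the fixed precedence 3UTR, CDS, 5UTR, intron,
#' noncoding (in that order). Clusters without any overlap are labeled
#' `intergenic`.
#'
#' @param clusters `GRanges` from [call_parclip_clusters()].
#' @param regions `GRanges` from [derive_regions()].
#' @return `clusters` with added metadata `gene_id`, `region_label`.
#' @export
annotate_clusters <- function(clusters, regions) {
  precedence <- c("3UTR", "CDS", "5UTR", "intron", "noncoding")
  lab <- rep("intergenic", length(clusters))
  gene <- rep(NA_character_, length(clusters))
  if (length(clusters) && length(regions)) {
    hits <- GenomicRanges::findOverlaps(clusters, regions, ignore.strand = FALSE)
    if (length(hits)) {
      q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
      ov_w <- GenomicRanges::width(IRanges::pintersect(
        GenomicRanges::ranges(clusters)[q], GenomicRanges::ranges(regions)[s]
      ))
      rl <- S4Vectors::mcols(regions)$label[s]
      prec <- match(rl, precedence, nomatch = length(precedence) + 1L)
      for (i in unique(q)) {
        sel <- which(q == i)
        best <- sel[order(-ov_w[sel], prec[sel])][1L]
        lab[i] <- rl[best]
        gene[i] <- S4Vectors::mcols(regions)$gene_id[s[best]]
      }
    }
  }
  S4Vectors::mcols(clusters)$gene_id <- gene
  S4Vectors::mcols(clusters)$region_label <- lab
  clusters
}

#' Region occupancy of annotated clusters
#'
#' @param clusters Annotated `GRanges` from [annotate_clusters()].
#' @return data.frame with `region_label`, `n`, `percent` (summing to 100).
#' @export
region_occupancy <- function(clusters) {
  lab <- S4Vectors::mcols(clusters)$region_label
  .assert(!is.null(lab), "clusters must be annotated first (annotate_clusters)")
  tab <- table(lab)
  data.frame(
    region_label = names(tab), n = as.integer(tab),
    percent = 100 * as.integer(tab) / length(clusters),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write clusters as BED6+4
#'
#' Extra columns: read_count, conv_count, conv_locs, mode_location.
#'
#' @param clusters Cluster `GRanges`.
#' @param path Output path.
#' @export
write_clusters_bed <- function(clusters, path) {
  if (!length(clusters)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(clusters)),
    start = GenomicRanges::start(clusters) - 1L, # BED half-open
    end = GenomicRanges::end(clusters),
    name = sprintf("cluster_%d", seq_along(clusters)),
    score = 0L,
    strand = as.character(BiocGenerics::strand(clusters)),
    read_count = S4Vectors::mcols(clusters)$read_count,
    conv_count = S4Vectors::mcols(clusters)$conv_count,
    conv_locs = S4Vectors::mcols(clusters)$conv_locs,
    mode_location = S4Vectors::mcols(clusters)$mode_location,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
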