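#' Load transcript models from GTF or BED12
#'
#' Reads an Ensembl-dialect GTF or a BED12 file and returns one transcript
#' model per transcript record. All coordinates are represented internally as
#' 1-based closed intervals ([IRanges::IRanges()] convention); BED input is
#' converted on read by rtracklayer.
#'
#' For BED12 input the `name` field may be `"<gene_id>|<transcript_id>"`;
#' a plain name is used for both identifiers.
#'
#' @param path Path to a `.gtf` or `.bed` (BED12) file.
#' @param format `"auto"` (from extension), `"gtf"` or `"bed"`.
#' @return A `TranscriptSet`: list with
#'   * `tx`: data.frame with `transcript_id`, `gene_id`, `chrom`, `strand`,
#'     `cds_start`, `cds_end` (genomic, `NA` for non-coding transcripts);
#'   * `exons`: [GenomicRanges::GRangesList] of exons, named by transcript.
#' @export
load_transcripts <- function(path, format = c("auto", "gtf", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      gtf = "gtf", gff = "gtf",
      bed = "bed",
      stop("cannot guess annotation format from extension '", ext, "'")
    )
  }
  if (format == "bed") .load_transcripts_bed12(path) else .load_transcripts_gtf(path)
}

.load_transcripts_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (!("blocks" %in% names(S4Vectors::mcols(gr)))) {
    # BED6: one exon spanning the record
    S4Vectors::mcols(gr)$blocks <-
      IRanges::IRangesList(lapply(IRanges::width(gr), function(w) IRanges::IRanges(1L, w)))
  }
  nm <- S4Vectors::mcols(gr)$name
  .assert(!anyNA(nm) && !any(nm == ""), "BED12 records must carry a name field")
  parts <- strsplit(nm, "|", fixed = TRUE)
  gene_id <- vapply(parts, `[`, "", 1L)
  tx_id <- vapply(parts, function(p) p[length(p)], "")
  .assert(!anyDuplicated(tx_id), "duplicate transcript names in BED12 input")

  blocks <- IRanges::shift(S4Vectors::mcols(gr)$blocks, GenomicRanges::start(gr) - 1L)
  nb <- S4Vectors::elementNROWS(blocks)
  flat <- GenomicRanges::GRanges(
    rep(as.character(GenomeInfoDb::seqnames(gr)), nb),
    unlist(blocks, use.names = FALSE),
    strand = rep(as.character(BiocGenerics::strand(gr)), nb)
  )
  exl <- S4Vectors::split(flat, factor(rep(tx_id, nb), levels = tx_id))

  thick <- S4Vectors::mcols(gr)$thick
  has_cds <- !is.null(thick) & IRanges::width(thick) > 0L
  cds_start <- ifelse(has_cds, IRanges::start(thick), NA_integer_)
  cds_end <- ifelse(has_cds, IRanges::end(thick), NA_integer_)

  .new_transcript_set(
    data.frame(
      transcript_id = tx_id, gene_id = gene_id,
      chrom = as.character(GenomeInfoDb::seqnames(gr)),
      strand = as.character(BiocGenerics::strand(gr)),
      cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
      stringsAsFactors = FALSE
    ),
    exl
  )
}

.load_transcripts_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  m <- S4Vectors::mcols(gr)
  .assert(all(c("type", "gene_id", "transcript_id") %in% names(m)),
          "GTF must carry type, gene_id and transcript_id attributes")
  ex <- gr[m$type == "exon"]
  .assert(length(ex) > 0L, "GTF contains no exon records")
  ex_tx <- S4Vectors::mcols(ex)$transcript_id
  ex_gene <- S4Vectors::mcols(ex)$gene_id
  S4Vectors::mcols(ex) <- NULL
  exl <- S4Vectors::split(ex, ex_tx)

  cds <- gr[m$type == "CDS"]
  cds_by_tx <- if (length(cds)) split(as.data.frame(cds), S4Vectors::mcols(cds)$transcript_id) else list()

  tx_id <- names(exl)
  first <- match(tx_id, ex_tx)
  tx <- data.frame(
    transcript_id = tx_id,
    gene_id = ex_gene[first],
    chrom = as.character(GenomeInfoDb::seqnames(ex))[first],
    strand = as.character(BiocGenerics::strand(ex))[first],
    cds_start = NA_integer_, cds_end = NA_integer_,
    stringsAsFactors = FALSE
  )
  for (id in names(cds_by_tx)) {
    i <- match(id, tx$transcript_id)
    tx$cds_start[i] <- min(cds_by_tx[[id]]$start)
    tx$cds_end[i] <- max(cds_by_tx[[id]]$end)
  }
  .new_transcript_set(tx, exl[tx$transcript_id])
}

.new_transcript_set <- function(tx, exons) {
  exons <- GenomicRanges::GRangesList(exons)
  # re-split exons sorted by start per transcript, preserving tx order
  key <- factor(rep(names(exons), S4Vectors::elementNROWS(exons)),
                levels = tx$transcript_id)
  ord <- order(as.integer(key), GenomicRanges::start(unlist(exons, use.names = FALSE)))
  flat <- unlist(exons, use.names = FALSE)[ord]
  kf <- key[ord]
  exons <- S4Vectors::split(flat, kf)

  s <- GenomicRanges::start(flat); e <- GenomicRanges::end(flat)
  n <- length(flat)
  if (n > 1L) {
    same <- as.integer(kf)[-1L] == as.integer(kf)[-n]
    bad <- same & s[-1L] <= e[-n]
    .assert(!any(bad), "overlapping exons for transcript %s",
            as.character(kf[c(FALSE, bad)][1L]))
  }
  coding <- !is.na(tx$cds_start)
  if (any(coding)) {
    .assert(all(tx$cds_start[coding] <= tx$cds_end[coding]),
            "inverted CDS for transcript %s",
            tx$transcript_id[coding & tx$cds_start > tx$cds_end][1L])
    ends <- IRanges::IRanges(c(tx$cds_start[coding], tx$cds_end[coding]), width = 1L)
    ends_tx <- rep(tx$transcript_id[coding], 2L)
    hits <- IRanges::findOverlaps(ends, IRanges::ranges(flat))
    ok_pair <- ends_tx[S4Vectors::queryHits(hits)] ==
      as.character(kf)[S4Vectors::subjectHits(hits)]
    covered <- tabulate(S4Vectors::queryHits(hits)[ok_pair], length(ends)) > 0L
    .assert(all(covered), "CDS outside exons for transcript %s",
            ends_tx[!covered][1L])
  }
  structure(list(tx = tx, exons = exons), class = "TranscriptSet")
}

#' @export
print.TranscriptSet <- function(x, ...) {
  cat(sprintf(
    "TranscriptSet: %d transcripts, %d genes (%d coding)\n",
    nrow(x$tx), length(unique(x$tx$gene_id)), sum(!is.na(x$tx$cds_start))
  ))
  invisible(x)
}

#' Derive labeled gene regions (5'UTR / CDS / 3'UTR / intron)
#'
#' Partitions each transcript span into labeled intervals. For coding
#' transcripts, exonic sequence 5' of the CDS is `5UTR` and 3' of it `3UTR`
#' (strand-aware); gaps between exons are `intron`. Non-coding transcripts
#' get `noncoding_label` over their exons; by default they are thereby
#' excluded from 3'UTR-restricted analyses downstream.
#'
#' @param ts A `TranscriptSet` from [load_transcripts()].
#' @param noncoding_label Label used for exons of non-coding transcripts.
#' @return A [GenomicRanges::GRanges] with metadata columns `label`,
#'   `transcript_id`, `gene_id`.
#' @export
derive_regions <- function(ts, noncoding_label = "noncoding") {
  stopifnot(inherits(ts, "TranscriptSet"))
  ex_all <- unlist(ts$exons, use.names = FALSE)
  tx_of <- rep(names(ts$exons), S4Vectors::elementNROWS(ts$exons))
  i_tx <- match(tx_of, ts$tx$transcript_id)
  s <- GenomicRanges::start(ex_all); e <- GenomicRanges::end(ex_all)
  chrom <- as.character(GenomeInfoDb::seqnames(ex_all))
  strand <- ts$tx$strand[i_tx]
  cs <- ts$tx$cds_start[i_tx]; ce <- ts$tx$cds_end[i_tx]
  gene <- ts$tx$gene_id[i_tx]; txid <- tx_of
  coding <- !is.na(cs)

  piece <- function(sel, ps, pe, lab) {
    keep <- sel & ps <= pe
    data.frame(chrom = chrom[keep], start = ps[keep], end = pe[keep],
               strand = strand[keep], label = lab[keep],
               transcript_id = txid[keep], gene_id = gene[keep],
               stringsAsFactors = FALSE)
  }
  left_lab <- ifelse(strand == "+", "5UTR", "3UTR")
  right_lab <- ifelse(strand == "+", "3UTR", "5UTR")
  pieces <- rbind(
    piece(coding & s < cs, s, pmin(e, cs - 1L), left_lab),
    piece(coding, pmax(s, cs), pmin(e, ce), rep("CDS", length(s))),
    piece(coding & e > ce, pmax(s, ce + 1L), e, right_lab),
    piece(!coding, s, e, rep(noncoding_label, length(s)))
  )
  # introns: gaps between consecutive exons of the same transcript (exons are
  # stored sorted by start)
  n <- length(s)
  if (n > 1L) {
    same_tx <- txid[-1L] == txid[-n]
    gap <- same_tx & s[-1L] > e[-n] + 1L
    idx <- which(gap)
    pieces <- rbind(pieces, data.frame(
      chrom = chrom[idx], start = e[idx] + 1L, end = s[idx + 1L] - 1L,
      strand = strand[idx], label = rep("intron", length(idx)),
      transcript_id = txid[idx], gene_id = gene[idx],
      stringsAsFactors = FALSE
    ))
  }
  gr <- GenomicRanges::GRanges(pieces$chrom,
    IRanges::IRanges(pieces$start, pieces$end), strand = pieces$strand)
  S4Vectors::mcols(gr)$label <- pieces$label
  S4Vectors::mcols(gr)$transcript_id <- pieces$transcript_id
  S4Vectors::mcols(gr)$gene_id <- pieces$gene_id
  BiocGenerics::sort(gr, ignore.strand = TRUE)
}

#' Write labeled regions to BED6 / read them back
#'
#' The BED name field stores `gene_id|transcript_id|label` so that a
#' write/read round trip reproduces the regions exactly; scores are 0.
#'
#' @param regions `GRanges` from [derive_regions()].
#' @param path Output path.
#' @return `write_regions_bed`: the path, invisibly. `load_regions_bed`: a
#'   `GRanges` with `label`, `transcript_id`, `gene_id` metadata columns.
#' @export
write_regions_bed <- function(regions, path) {
  gr <- regions
  S4Vectors::mcols(gr) <- NULL
  S4Vectors::mcols(gr)$name <- paste(
    S4Vectors::mcols(regions)$gene_id,
    S4Vectors::mcols(regions)$transcript_id,
    S4Vectors::mcols(regions)$label,
    sep = "|"
  )
  S4Vectors::mcols(gr)$score <- 0
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname write_regions_bed
#' @export
load_regions_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  parts <- strsplit(S4Vectors::mcols(gr)$name, "|", fixed = TRUE)
  .assert(all(lengths(parts) == 3L), "region BED names must be gene|transcript|label")
  out <- gr
  S4Vectors::mcols(out) <- NULL
  S4Vectors::mcols(out)$label <- vapply(parts, `[`, "", 3L)
  S4Vectors::mcols(out)$transcript_id <- vapply(parts, `[`, "", 2L)
  S4Vectors::mcols(out)$gene_id <- vapply(parts, `[`, "", 1L)
  out
}

#' Load a FASTA file as a DNAStringSet
#'
#' Sequence names are truncated at the first whitespace.
#'
#' @param path FASTA path.
#' @return A [Biostrings::DNAStringSet].
#' @export
load_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  names(s) <- sub("\\s.*$", "", names(s))
  s
}

#' Gene-level 3'UTR intervals
#'
#' The union of `3UTR` intervals across a gene's transcripts, reduced per
#' gene. This gene-level union is the coordinate frame used for seed-site
#' scanning and cluster assignment.
#'
#' @param regions `GRanges` from [derive_regions()].
#' @return A named [GenomicRanges::GRangesList], one reduced range set per gene.
#' @export
utr3_by_gene <- function(regions) {
  utr <- regions[S4Vectors::mcols(regions)$label == "3UTR"]
  if (!length(utr)) return(GenomicRanges::GRangesList())
  grl <- S4Vectors::split(utr, S4Vectors::mcols(utr)$gene_id)
  GenomicRanges::reduce(grl)
}

#' Extract a gene's 3'UTR sequence in transcript orientation
#'
#' Concatenates the gene's (reduced) 3'UTR intervals and returns the sense
#' strand 5'->3'; minus-strand genes are reverse-complemented.
#'
#' @param gene_id Gene identifier.
#' @param genome `DNAStringSet` keyed by chromosome name.
#' @param utr3 `GRangesList` from [utr3_by_gene()].
#' @return A character scalar (possibly empty).
#' @export
utr3_sequence <- function(gene_id, genome, utr3) {
  if (!(gene_id %in% names(utr3))) return("")
  gr <- BiocGenerics::sort(utr3[[gene_id]])
  if (!length(gr)) return("")
  chrom <- as.character(GenomeInfoDb::seqnames(gr))[1L]
  .assert(chrom %in% names(genome), "sequence '%s' not found in FASTA store", chrom)
  pieces <- vapply(seq_along(gr), function(i) {
    as.character(Biostrings::subseq(genome[[chrom]],
      start = GenomicRanges::start(gr)[i], end = GenomicRanges::end(gr)[i]
    ))
  }, "")
  s <- paste(pieces, collapse = "")
  if (as.character(BiocGenerics::strand(gr))[1L] == "-") revcomp(s) else s
}

#' Project 3'UTR coordinates onto the genome
#'
#' Maps a 1-based interval in a gene's 3'UTR (transcript orientation, as
#' reported by [scan_utr()]) to genomic coordinates, splitting across UTR
#' pieces where necessary.
#'
#' @param gene_id Gene identifier.
#' @param utr3 `GRangesList` from [utr3_by_gene()].
#' @param start 1-based start offset within the UTR sequence.
#' @param width Interval width in nucleotides.
#' @return A reduced [GenomicRanges::GRanges] of the covered genomic positions.
#' @export
utr3_to_genomic <- function(gene_id, utr3, start, width) {
  .assert(gene_id %in% names(utr3), "gene '%s' has no 3'UTR intervals", gene_id)
  lay <- .utr3_layout(utr3)[[gene_id]]
  total <- sum(lay$widths)
  .assert(start >= 1L && start + width - 1L <= total,
          "UTR interval [%d, %d] outside UTR of length %d for gene %s",
          start, start + width - 1L, total, gene_id)
  gpos <- sort(.map_utr_pos(lay, start:(start + width - 1L)))
  GenomicRanges::reduce(GenomicRanges::GRanges(
    lay$chrom, IRanges::IRanges(gpos, gpos), strand = lay$strand
  ))
}

# plain-vector layout of each gene's (reduced, sorted) 3'UTR pieces in
# transcript orientation; cached per GRangesList object
.utr3_layout <- function(utr3) {
  cached <- attr(utr3, "spongeclip_layout")
  if (!is.null(cached)) return(cached)
  flat <- unlist(utr3, use.names = FALSE)
  gene_of <- rep(names(utr3), S4Vectors::elementNROWS(utr3))
  chrom <- as.character(GenomeInfoDb::seqnames(flat))
  strand <- as.character(BiocGenerics::strand(flat))
  s <- GenomicRanges::start(flat); e <- GenomicRanges::end(flat)
  out <- lapply(split(seq_along(flat), factor(gene_of, levels = names(utr3))), function(i) {
    st <- strand[i[1L]]
    if (st == "-") i <- rev(i) # transcript order: decreasing genomic position
    list(chrom = chrom[i[1L]], strand = st, starts = s[i], ends = e[i],
         widths = e[i] - s[i] + 1L, cum = cumsum(c(0L, e[i] - s[i] + 1L)))
  })
  out
}

# map 1-based UTR offsets (transcript orientation) to genomic positions
.map_utr_pos <- function(lay, pos) {
  idx <- findInterval(pos - 1L, lay$cum)
  off <- pos - lay$cum[idx]
  if (lay$strand == "+") lay$starts[idx] + off - 1L else lay$ends[idx] - off + 1L
}

#' Load a GMT gene-set collection
#'
#' Tab-separated: set name, description, then member genes. Members are
#' de-duplicated, so the set size K counts each gene once.
#'
#' @param path GMT path.
#' @return A `GeneSetCollection`: list with `sets` (named list of unique
#'   member vectors) and `description` (named character).
#' @export
load_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  .assert(length(bad) == 0L, "GMT line %d has fewer than 3 fields", bad[1L])
  nm <- vapply(fields, `[`, "", 1L)
  .assert(!anyDuplicated(nm), "duplicate gene-set names in GMT")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  .assert(all(lengths(sets) > 0L), "GMT contains an empty gene set")
  names(sets) <- nm
  desc <- vapply(fields, `[`, "", 2L)
  names(desc) <- nm
  structure(list(sets = sets, description = desc), class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf(
    "GeneSetCollection: %d sets, K in [%d, %d]\n",
    length(x$sets), min(lengths(x$sets)), max(lengths(x$sets))
  ))
  invisible(x)
}
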