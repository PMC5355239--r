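#' Derive a seed motif from a mature miRNA sequence
#'
#' Extracts the given positions of a mature miRNA (RNA alphabet, 5'->3') and
#' returns the DNA representation (U -> T), still in miRNA orientation. The
#' canonical 7-nt seed motif is positions 2-8; the 8-nt motif is positions
#' 1-8.
#'
#' @param mature_seq Mature miRNA sequence (A/C/G/U, case-insensitive).
#' @param positions Integer vector of consecutive positions, e.g. `2:8`.
#' @return DNA motif string, upper case.
#' @export
derive_seed <- function(mature_seq, positions) {
  s <- toupper(mature_seq)
  .assert(grepl("^[ACGUT]+$", s), "mature sequence contains non-RNA letters")
  .assert(nchar(s) >= 9L, "mature miRNA sequence must be at least 9 nt")
  positions <- as.integer(positions)
  .assert(all(diff(positions) == 1L), "positions must be consecutive")
  .assert(min(positions) >= 1L && max(positions) <= nchar(s),
          "positions %d-%d out of bounds for sequence of length %d",
          min(positions), max(positions), nchar(s))
  rna_to_dna(substr(s, min(positions), max(positions)))
}

#' Construct a seed family
#'
#' A seed family groups miRNAs sharing the 7-nt seed motif (positions 2-8,
#' DNA representation, miRNA 5'->3'). `motif8` extends it by position 1; when
#' both are given, `motif7` must equal positions 2-8 of `motif8`.
#'
#' @param family_id Family identifier.
#' @param motif7 7-nt DNA motif (miRNA positions 2-8).
#' @param motif8 8-nt DNA motif (miRNA positions 1-8), or `NA`.
#' @param members Character vector of member miRNA names.
#' @return A one-row data.frame with `members` collapsed by `";"`.
#' @export
seed_family <- function(family_id, motif7, motif8 = NA_character_, members = character()) {
  motif7 <- toupper(motif7)
  .assert(grepl("^[ACGT]{7}$", motif7), "motif7 must be 7 nt of A/C/G/T, got '%s'", motif7)
  if (!is.na(motif8)) {
    motif8 <- toupper(motif8)
    .assert(grepl("^[ACGT]{8}$", motif8), "motif8 must be 8 nt of A/C/G/T, got '%s'", motif8)
    .assert(substr(motif8, 2L, 8L) == motif7,
            "motif7 (%s) must equal positions 2-8 of motif8 (%s)", motif7, motif8)
  }
  data.frame(
    family_id = family_id, motif7 = motif7, motif8 = motif8,
    members = paste(members, collapse = ";"), stringsAsFactors = FALSE
  )
}

#' Load a seed-family table
#'
#' Tab-separated with columns `family_id`, `motif7`, `motif8`, `members`
#' (members separated by `";"`). The packaged default
#' (`default_family_table()`) carries the miR-17-92 cluster families with the
#' published motif assignments.
#'
#' @param path TSV path.
#' @return data.frame with one row per family.
#' @export
load_family_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .assert(all(c("family_id", "motif7", "motif8", "members") %in% names(df)),
          "family table must have columns family_id, motif7, motif8, members")
  out <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    seed_family(df$family_id[i], df$motif7[i],
                ifelse(is.na(df$motif8[i]) | df$motif8[i] == "", NA_character_, df$motif8[i]),
                strsplit(df$members[i], ";", fixed = TRUE)[[1L]])
  }))
  .assert(!anyDuplicated(out$family_id), "duplicate family_id in family table")
  out
}

#' @rdname load_family_table
#' @export
default_family_table <- function() {
  load_family_table(system.file("extdata", "mir17_92_families.tsv",
                                package = "spongeclip", mustWork = TRUE))
}

#' Target-site search pattern for a seed family
#'
#' Converts a family's miRNA-orientation motif into the DNA pattern searched
#' on the 3'UTR sense strand: the seed region pairs Watson-Crick with the
#' site, so the site pattern is the reverse complement of the motif; A1-type
#' sites additionally carry an `A` opposite miRNA position 1 regardless of
#' the miRNA residue there.
#'
#' @param motif7 7-nt seed motif (miRNA positions 2-8, DNA).
#' @param site_type One of `"6mer"`, `"7mer-m8"`, `"7mer-A1"`, `"8mer"`.
#' @return DNA pattern string to search on the UTR sense strand.
#' @export
site_pattern <- function(motif7, site_type = c("8mer", "7mer-m8", "7mer-A1", "6mer")) {
  site_type <- match.arg(site_type)
  core <- revcomp(substr(motif7, 1L, 6L)) # complement of miRNA positions 2-7
  switch(site_type,
    "6mer" = core,
    "7mer-A1" = paste0(core, "A"),
    "7mer-m8" = revcomp(motif7),
    "8mer" = paste0(revcomp(motif7), "A")
  )
}

#' Published-style motif label for a site type
#'
#' Returns the miRNA-orientation string conventionally printed for a site
#' type: the 7-nt motif for 7mer sites, the 8-nt motif for 8mer sites, and
#' for A1-type sites the first 7 nt of the 8-nt motif (position 1 stands in
#' for the site's A1).
#'
#' @param family One row of a family table (list or data.frame row).
#' @inheritParams site_pattern
#' @return Character label.
#' @export
seed_label <- function(family, site_type = c("8mer", "7mer-m8", "7mer-A1", "6mer")) {
  site_type <- match.arg(site_type)
  switch(site_type,
    "8mer" = family$motif8,
    "7mer-m8" = family$motif7,
    "7mer-A1" = substr(family$motif8, 1L, 7L),
    "6mer" = substr(family$motif7, 1L, 6L)
  )
}

#' Scan a 3'UTR sequence for typed seed-match sites
#'
#' Finds all occurrences of each family's site patterns on the UTR sense
#' strand (5'->3', transcript orientation). At a given locus the longest
#' matching site type wins (8mer over 7mer-m8/7mer-A1 over 6mer); overlapping
#' matches of different families are all reported. 6mer sites are omitted
#' unless `include_6mer = TRUE`, matching the downstream exclusion of 6mers
#' from all seed-based analyses.
#'
#' @param utr_seq UTR sequence (character scalar, sense strand).
#' @param families Family table (data.frame as from [load_family_table()]).
#' @param include_6mer Keep 6mer matches?
#' @return data.frame with `start` (1-based in the UTR), `width`,
#'   `site_type`, `family_id`.
#' @export
scan_utr <- function(utr_seq, families, include_6mer = FALSE) {
  empty <- data.frame(
    start = integer(), width = integer(),
    site_type = character(), family_id = character(), stringsAsFactors = FALSE
  )
  if (is.na(utr_seq) || nchar(utr_seq) < 6L) return(empty)
  subject <- Biostrings::DNAString(toupper(utr_seq))
  n <- length(subject)
  out <- list(empty)
  for (i in seq_len(nrow(families))) {
    motif7 <- families$motif7[i]
    core <- site_pattern(motif7, "6mer")
    m8_base <- substr(site_pattern(motif7, "7mer-m8"), 1L, 1L)
    hits <- Biostrings::matchPattern(core, subject)
    if (!length(hits)) next
    o <- BiocGenerics::start(hits) # core occupies o .. o+5
    has_m8 <- o > 1L & substr(rep(as.character(subject), length(o)), o - 1L, o - 1L) == m8_base
    has_a1 <- o + 6L <= n & substr(rep(as.character(subject), length(o)), o + 6L, o + 6L) == "A"
    site_type <- ifelse(has_m8 & has_a1, "8mer",
      ifelse(has_m8, "7mer-m8", ifelse(has_a1, "7mer-A1", "6mer"))
    )
    start <- ifelse(has_m8, o - 1L, o)
    width <- 6L + has_m8 + has_a1
    out[[length(out) + 1L]] <- data.frame(
      start = as.integer(start), width = as.integer(width),
      site_type = site_type, family_id = families$family_id[i],
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (!include_6mer) res <- res[res$site_type != "6mer", , drop = FALSE]
  res <- res[order(res$start, res$family_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Scan all gene 3'UTRs and project sites to genomic coordinates
#'
#' Runs [scan_utr()] over every gene's 3'UTR sequence and returns both the
#' UTR-frame table and the genomic projection of each site (via the gene's
#' exonic 3'UTR map), the frame in which PAR-CLIP clusters live.
#'
#' @param genome `DNAStringSet` of chromosome sequences.
#' @param utr3 `GRangesList` from [utr3_by_gene()].
#' @inheritParams scan_utr
#' @return A [GenomicRanges::GRanges] of sites with metadata columns
#'   `gene_id`, `family_id`, `site_type`, `utr_start`.
#' @export
scan_utr3_sites <- function(genome, utr3, families, include_6mer = FALSE) {
  layout <- .utr3_layout(utr3)
  # bulk sequence extraction, then per-gene scan with plain-vector mapping
  flat <- unlist(utr3, use.names = FALSE)
  gene_of <- rep(names(utr3), S4Vectors::elementNROWS(utr3))
  chroms <- as.character(GenomeInfoDb::seqnames(flat))
  .assert(all(chroms %in% names(genome)), "sequence '%s' not found in FASTA store",
          paste(setdiff(chroms, names(genome)), collapse = ","))
  pieces <- as.character(Biostrings::subseq(genome[chroms],
    start = GenomicRanges::start(flat), end = GenomicRanges::end(flat)))
  seqs <- vapply(split(pieces, factor(gene_of, levels = names(utr3))),
                 paste, "", collapse = "")
  minus <- vapply(layout, function(l) l$strand == "-", TRUE)
  seqs[minus] <- revcomp(seqs[minus])

  acc <- list()
  for (g in names(utr3)) {
    hits <- scan_utr(seqs[[g]], families, include_6mer)
    if (!nrow(hits)) next
    lay <- layout[[g]]
    g1 <- .map_utr_pos(lay, hits$start)
    g2 <- .map_utr_pos(lay, hits$start + hits$width - 1L)
    acc[[length(acc) + 1L]] <- data.frame(
      chrom = lay$chrom, start = pmin(g1, g2), end = pmax(g1, g2),
      strand = lay$strand, gene_id = g, family_id = hits$family_id,
      site_type = hits$site_type, utr_start = hits$start,
      stringsAsFactors = FALSE
    )
  }
  if (!length(acc)) {
    return(GenomicRanges::GRanges(
      gene_id = character(), family_id = character(),
      site_type = character(), utr_start = integer()
    ))
  }
  df <- do.call(rbind, acc)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr)$gene_id <- df$gene_id
  S4Vectors::mcols(gr)$family_id <- df$family_id
  S4Vectors::mcols(gr)$site_type <- df$site_type
  S4Vectors::mcols(gr)$utr_start <- df$utr_start
  BiocGenerics::sort(gr, ignore.strand = TRUE)
}
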