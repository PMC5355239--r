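#' Synthetic-dataset configuration
#'
#' Defines the simulated study: single-transcript genes with 5'UTR/CDS/3'UTR
#' structure; a subset of "true target" genes whose 3'UTRs carry planted seed
#' sites of the configured families with a crosslink T placed 2 nt upstream
#' of each site; PAR-CLIP replicas with T>C conversion at crosslink sites
#' (rate `site_conversion_rate`, emulating libraries whose T>C share
#' dominates all mismatch classes) plus a uniform sequencing-error floor; and
#' negative-binomial RNA-seq counts in which true targets are derepressed by
#' `target_log2fc` under the family-specific sponge and unchanged under a
#' non-targeting sponge.
#'
#' @param rng_seed Integer seed; all outputs are byte-deterministic given it.
#'   Per-stage streams are derived from it, so keep it below ~2e9.
#' @param n_genes Number of genes.
#' @param n_true_targets Number of genes receiving planted sites and a true
#'   expression effect.
#' @param utr3_len_range 3'UTR length range (nt, uniform).
#' @param utr5_len_range,cds_len_range 5'UTR and CDS length ranges (nt).
#' @param families Seed-family table rows to plant (default: the miR-17 and
#'   miR-19 families of the shipped table).
#' @param sites_per_target Range of planted sites per target gene.
#' @param site_conversion_rate Per-read T>C conversion probability at the
#'   crosslink position.
#' @param background_error_rate Per-base sequencing error probability (and
#'   off-site T>C rate).
#' @param reads_per_true_site Range of reads per planted site per replica.
#' @param background_reads_per_gene Range of scattered background reads.
#' @param read_len_range Read length range (nt).
#' @param parclip_replicas Number of PAR-CLIP replicas.
#' @param n_per_condition RNA-seq replicates per condition (target sponge,
#'   control sponge, non-targeting sponge).
#' @param target_log2fc True derepression effect (log2).
#' @param nb_dispersion Negative-binomial dispersion (variance = mu +
#'   dispersion * mu^2).
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline mean parameters
#'   (median exp(meanlog) counts).
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(rng_seed = 1L,
                       n_genes = 500L,
                       n_true_targets = 50L,
                       utr3_len_range = c(200L, 2000L),
                       utr5_len_range = c(100L, 300L),
                       cds_len_range = c(300L, 900L),
                       families = NULL,
                       sites_per_target = c(1L, 3L),
                       site_conversion_rate = 0.4,
                       background_error_rate = 0.002,
                       reads_per_true_site = c(8L, 20L),
                       background_reads_per_gene = c(0L, 5L),
                       read_len_range = c(20L, 35L),
                       parclip_replicas = 3L,
                       n_per_condition = 3L,
                       target_log2fc = 0.6,
                       nb_dispersion = 0.08,
                       baseline_meanlog = log(200),
                       baseline_sdlog = 1) {
  if (is.null(families)) {
    tab <- default_family_table()
    families <- tab[tab$family_id %in% c("miR-17-5p/20-5p/106-5p", "miR-19-3p"), ]
  }
  cfg <- list(
    rng_seed = as.integer(rng_seed), n_genes = as.integer(n_genes),
    n_true_targets = as.integer(n_true_targets),
    utr3_len_range = as.integer(utr3_len_range),
    utr5_len_range = as.integer(utr5_len_range),
    cds_len_range = as.integer(cds_len_range),
    families = families,
    sites_per_target = as.integer(sites_per_target),
    site_conversion_rate = site_conversion_rate,
    background_error_rate = background_error_rate,
    reads_per_true_site = as.integer(reads_per_true_site),
    background_reads_per_gene = as.integer(background_reads_per_gene),
    read_len_range = as.integer(read_len_range),
    parclip_replicas = as.integer(parclip_replicas),
    n_per_condition = as.integer(n_per_condition),
    target_log2fc = target_log2fc, nb_dispersion = nb_dispersion,
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog
  )
  .assert(cfg$n_true_targets <= cfg$n_genes, "more targets than genes")
  .assert(cfg$site_conversion_rate >= 0 && cfg$site_conversion_rate <= 1 &&
            cfg$background_error_rate >= 0 && cfg$background_error_rate <= 1,
          "rates must lie in [0, 1]")
  .assert(cfg$parclip_replicas >= 2L, "need at least 2 PAR-CLIP replicas")
  .assert(cfg$nb_dispersion >= 0, "dispersion must be >= 0")
  structure(cfg, class = "sim_config")
}

.runi <- function(n, range) {
  if (range[1L] == range[2L]) rep(range[1L], n) else sample(range[1L]:range[2L], n, replace = TRUE)
}

#' Generate the synthetic gene annotation and genome
#'
#' One single-exon transcript per gene, each on its own contig, with random
#' uniform base composition; gene strands are random. Layout per gene:
#' 5'UTR, CDS, 3'UTR (transcript order).
#'
#' @param cfg A [sim_config()].
#' @return list with `transcripts` (a `TranscriptSet`), `genome`
#'   (`DNAStringSet`), and `layout` (per-gene data.frame with `gene_id`,
#'   `chrom`, `strand`, `utr5_len`, `cds_len`, `utr3_len`, `length`).
#' @export
make_annotation <- function(cfg = sim_config()) {
  set.seed(cfg$rng_seed)
  n <- cfg$n_genes
  gene_id <- sprintf("G%04d", seq_len(n))
  u5 <- .runi(n, cfg$utr5_len_range)
  cds <- .runi(n, cfg$cds_len_range)
  u3 <- .runi(n, cfg$utr3_len_range)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  L <- u5 + cds + u3
  seqs <- vapply(L, function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, "")
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- gene_id
  cds_start <- ifelse(strand == "+", u5 + 1L, u3 + 1L)
  cds_end <- cds_start + cds - 1L
  tx <- data.frame(
    transcript_id = paste0(gene_id, ".t1"), gene_id = gene_id,
    chrom = gene_id, strand = strand,
    cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
    stringsAsFactors = FALSE
  )
  flat <- GenomicRanges::GRanges(gene_id, IRanges::IRanges(1L, L), strand = strand)
  exons <- S4Vectors::split(flat, factor(tx$transcript_id, levels = tx$transcript_id))
  list(
    transcripts = .new_transcript_set(tx, exons),
    genome = genome,
    layout = data.frame(
      gene_id = gene_id, chrom = gene_id, strand = strand,
      utr5_len = u5, cds_len = cds, utr3_len = u3, length = L,
      stringsAsFactors = FALSE
    )
  )
}

# 1-based genomic position of 1-based 3'UTR offset for single-exon genes
.utr_pos_to_genomic <- function(layout_row, utr_pos) {
  if (layout_row$strand == "+") {
    layout_row$utr5_len + layout_row$cds_len + utr_pos
  } else {
    layout_row$utr3_len - utr_pos + 1L
  }
}

#' Plant typed seed sites into target 3'UTRs
#'
#' Selects `n_true_targets` genes, writes 1-3 seed-site patterns (types
#' 7mer-m8 / 7mer-A1 / 8mer) per target into their 3'UTR sequence, sets a
#' crosslink `T` two nucleotides 5' of every site, and rewrites any chance
#' occurrence of the planted families' core patterns elsewhere, so that
#' non-target genes carry no planted-family site and target genes carry
#' exactly the recorded ones. Adjacent bases are adjusted so that the
#' recorded site type is exactly what [scan_utr()] reports.
#'
#' @param cfg A [sim_config()].
#' @param annotation Output of [make_annotation()]; its genome is modified.
#' @return list with `annotation` (updated genome), `truth` (per-gene
#'   data.frame `gene_id`, `is_target`, `true_log2fc`) and `sites` (per-site
#'   data.frame with UTR and genomic coordinates of sites and crosslinks).
#' @export
plant_sites <- function(cfg = sim_config(), annotation = make_annotation(cfg)) {
  set.seed(cfg$rng_seed + 1L)
  layout <- annotation$layout
  genome_chr <- as.character(annotation$genome)
  fams <- cfg$families
  targets <- sort(sample(layout$gene_id, cfg$n_true_targets))
  site_types <- c("7mer-m8", "7mer-A1", "8mer")
  other_base <- function(b, avoid = character()) {
    sample(setdiff(c("A", "C", "G", "T"), c(b, avoid)), 1L)
  }
  sites_out <- list()
  for (i in seq_len(nrow(layout))) {
    row <- layout[i, ]
    g_start <- if (row$strand == "+") row$utr5_len + row$cds_len + 1L else 1L
    utr_g <- substr(genome_chr[[row$gene_id]], g_start, g_start + row$utr3_len - 1L)
    if (row$strand == "-") utr_g <- revcomp(utr_g)
    utr <- strsplit(utr_g, "")[[1L]]
    protected <- integer(0)
    planted <- list() # per site: list(start, width, family_id)
    if (row$gene_id %in% targets) {
      n_sites <- .runi(1L, cfg$sites_per_target)
      starts <- integer(0)
      for (s in seq_len(n_sites)) {
        cand <- setdiff(10:(length(utr) - 12L), unlist(lapply(starts, function(x) (x - 45L):(x + 45L))))
        if (!length(cand)) break
        starts <- c(starts, sample(cand, 1L))
      }
      for (st in starts) {
        fi <- sample(seq_len(nrow(fams)), 1L)
        ty <- sample(site_types, 1L)
        pat <- strsplit(site_pattern(fams$motif7[fi], ty), "")[[1L]]
        w <- length(pat)
        utr[st:(st + w - 1L)] <- pat
        m8b <- substr(site_pattern(fams$motif7[fi], "7mer-m8"), 1L, 1L)
        # crosslink T two nt upstream of the site
        utr[st - 2L] <- "T"
        # pin the flanks that determine the scanned site type, and protect
        # only those: the remaining neighbours stay mutable for scrubbing
        protected <- c(protected, st:(st + w - 1L), st - 2L)
        if (ty == "7mer-A1") {
          if (utr[st - 1L] == m8b) utr[st - 1L] <- other_base(m8b)
          protected <- c(protected, st - 1L)
        }
        if (ty == "7mer-m8") {
          if (utr[st + w] == "A") utr[st + w] <- other_base("A")
          protected <- c(protected, st + w)
        }
        planted[[length(planted) + 1L]] <- list(
          start = st, width = w, family_id = fams$family_id[fi],
          site_type = ty, crosslink = st - 2L
        )
      }
    }
    # scrub chance core occurrences of every planted family outside the
    # planted intervals (mutating only unprotected positions)
    planted_iv <- lapply(planted, function(p) p$start:(p$start + p$width - 1L))
    for (fi in seq_len(nrow(fams))) {
      core <- site_pattern(fams$motif7[fi], "6mer")
      own_iv <- unlist(planted_iv[vapply(planted, function(p) p$family_id == fams$family_id[fi], TRUE)])
      repeat {
        s_chr <- paste(utr, collapse = "")
        occ <- gregexpr(core, s_chr, fixed = TRUE)[[1L]]
        occ <- occ[occ > 0L]
        occ <- occ[!vapply(occ, function(o) all((o:(o + 5L)) %in% own_iv), TRUE)]
        # an occurrence fully inside a planted interval of another family is
        # left in place (only possible by pattern containment, not with the
        # default families)
        occ <- occ[vapply(occ, function(o) any(!((o:(o + 5L)) %in% protected)), TRUE)]
        if (!length(occ)) break
        o <- occ[1L]
        mutable <- setdiff(o:(o + 5L), protected)
        p <- mutable[ceiling(length(mutable) / 2)]
        utr[p] <- other_base(utr[p])
      }
    }
    # write the UTR back into the genome
    piece <- paste(utr, collapse = "")
    if (row$strand == "-") piece <- revcomp(piece)
    substr(genome_chr[[row$gene_id]], g_start, g_start + length(utr) - 1L) <- piece
    if (length(planted)) {
      sites_out[[length(sites_out) + 1L]] <- do.call(rbind, lapply(planted, function(p) {
        data.frame(
          gene_id = row$gene_id, chrom = row$chrom, strand = row$strand,
          family_id = p$family_id, site_type = p$site_type,
          utr_start = p$start, width = p$width,
          crosslink_utr = p$crosslink,
          crosslink_genomic = .utr_pos_to_genomic(row, p$crosslink),
          site_genomic_start = min(.utr_pos_to_genomic(row, p$start),
                                   .utr_pos_to_genomic(row, p$start + p$width - 1L)),
          site_genomic_end = max(.utr_pos_to_genomic(row, p$start),
                                 .utr_pos_to_genomic(row, p$start + p$width - 1L)),
          stringsAsFactors = FALSE
        )
      }))
    }
  }
  genome <- Biostrings::DNAStringSet(genome_chr)
  names(genome) <- names(annotation$genome)
  annotation$genome <- genome
  truth <- data.frame(
    gene_id = layout$gene_id,
    is_target = layout$gene_id %in% targets,
    true_log2fc = ifelse(layout$gene_id %in% targets, cfg$target_log2fc, 0),
    stringsAsFactors = FALSE
  )
  sites <- if (length(sites_out)) do.call(rbind, sites_out) else NULL
  list(annotation = annotation, truth = truth, sites = sites)
}

#' Simulate one PAR-CLIP replica
#'
#' For every planted site, draws reads spanning its crosslink position; each
#' read converts the crosslink T with probability `site_conversion_rate`,
#' converts other covered sense-strand Ts at the background error rate, and
#' carries uniform sequencing errors at the same rate. Background reads are
#' scattered over all gene regions. Each replica uses an independent RNG
#' stream derived from the configuration seed.
#'
#' @param cfg A [sim_config()].
#' @param annotation Output of [make_annotation()] after [plant_sites()].
#' @param sites The `sites` data.frame from [plant_sites()].
#' @param replica Replica index (1-based).
#' @return A `parclip_alignments` data.frame.
#' @export
simulate_parclip <- function(cfg, annotation, sites, replica = 1L) {
  set.seed(cfg$rng_seed + 1000L * as.integer(replica) + 7L)
  layout <- annotation$layout
  genome <- annotation$genome
  bases <- c("A", "C", "G", "T")
  reads <- list()
  add_read <- function(chrom, strand, start, len, seq_chars, sense_t, crosslink = NA_integer_) {
    pos_g <- start:(start + len - 1L)
    is_t <- pos_g %in% sense_t
    conv <- logical(len)
    if (!is.na(crosslink) && crosslink %in% pos_g) {
      idx <- match(crosslink, pos_g)
      if (is_t[idx]) conv[idx] <- stats::runif(1L) < cfg$site_conversion_rate
    }
    other_t <- if (is.na(crosslink)) which(is_t) else which(is_t & pos_g != crosslink)
    if (length(other_t)) {
      conv[other_t] <- stats::runif(length(other_t)) < cfg$background_error_rate
    }
    err <- stats::runif(len) < cfg$background_error_rate & !conv
    mm_idx <- which(conv | err)
    mm_ref <- seq_chars[mm_idx]
    mm_read <- character(length(mm_idx))
    for (j in seq_along(mm_idx)) {
      if (conv[mm_idx[j]]) {
        mm_read[j] <- if (strand == "+") "C" else "G"
      } else {
        mm_read[j] <- sample(setdiff(bases, seq_chars[mm_idx[j]]), 1L)
      }
    }
    list(chrom = chrom, strand = strand, start = start, width = len,
         mm_pos = pos_g[mm_idx], mm_ref = mm_ref, mm_read = mm_read)
  }
  chrom_cache <- new.env(parent = emptyenv())
  get_chars <- function(chrom) {
    if (is.null(chrom_cache[[chrom]])) {
      chrom_cache[[chrom]] <- strsplit(as.character(genome[[chrom]]), "")[[1L]]
    }
    chrom_cache[[chrom]]
  }
  if (!is.null(sites)) {
    for (i in seq_len(nrow(sites))) {
      s <- sites[i, ]
      row <- layout[layout$gene_id == s$gene_id, ]
      chars <- get_chars(s$chrom)
      sense_t <- which(chars == if (s$strand == "+") "T" else "A")
      n_reads <- .runi(1L, cfg$reads_per_true_site)
      for (r in seq_len(n_reads)) {
        len <- .runi(1L, cfg$read_len_range)
        offset <- sample.int(len, 1L) - 1L
        start <- s$crosslink_genomic - offset
        start <- max(1L, min(start, row$length - len + 1L))
        reads[[length(reads) + 1L]] <- add_read(
          s$chrom, s$strand, start, len, chars[start:(start + len - 1L)],
          sense_t, s$crosslink_genomic
        )
      }
    }
  }
  for (i in seq_len(nrow(layout))) {
    row <- layout[i, ]
    n_bg <- .runi(1L, cfg$background_reads_per_gene)
    if (n_bg == 0L) next
    chars <- get_chars(row$chrom)
    sense_t <- which(chars == if (row$strand == "+") "T" else "A")
    for (r in seq_len(n_bg)) {
      len <- .runi(1L, cfg$read_len_range)
      start <- sample.int(max(1L, row$length - len + 1L), 1L)
      reads[[length(reads) + 1L]] <- add_read(
        row$chrom, row$strand, start, len, chars[start:(start + len - 1L)],
        sense_t
      )
    }
  }
  .new_alignments(
    vapply(reads, `[[`, "", "chrom"),
    vapply(reads, `[[`, "", "strand"),
    vapply(reads, `[[`, 1L, "start"),
    vapply(reads, `[[`, 1L, "width"),
    lapply(reads, `[[`, "mm_pos"),
    lapply(reads, `[[`, "mm_ref"),
    lapply(reads, `[[`, "mm_read")
  )
}

#' Simulate sponge RNA-seq count matrices
#'
#' Negative-binomial counts (variance = mu + dispersion * mu^2) around a
#' log-normal baseline, with per-sample depth factors. True-target means are
#' multiplied by `2^target_log2fc` in target-sponge samples only; the
#' non-targeting sponge carries no planted effect.
#'
#' @param cfg A [sim_config()].
#' @param truth The `truth` data.frame from [plant_sites()].
#' @param include_other Also simulate the non-targeting sponge condition?
#' @return list with `counts` (genes x samples integer matrix) and `samples`
#'   (data.frame `sample`, `condition`, `replicate`).
#' @export
simulate_counts <- function(cfg, truth, include_other = TRUE) {
  set.seed(cfg$rng_seed + 9000L)
  n <- nrow(truth)
  baseline <- stats::rlnorm(n, cfg$baseline_meanlog, cfg$baseline_sdlog)
  conds <- c("target_sponge", "control_sponge", if (include_other) "other_sponge")
  samples <- do.call(rbind, lapply(conds, function(cn) {
    data.frame(
      sample = sprintf("%s_%d", cn, seq_len(cfg$n_per_condition)),
      condition = cn, replicate = seq_len(cfg$n_per_condition),
      stringsAsFactors = FALSE
    )
  }))
  depth <- stats::runif(nrow(samples), 0.8, 1.25)
  counts <- matrix(0L, nrow = n, ncol = nrow(samples),
                   dimnames = list(truth$gene_id, samples$sample))
  for (j in seq_len(nrow(samples))) {
    mu <- baseline * depth[j]
    if (samples$condition[j] == "target_sponge") {
      mu <- mu * ifelse(truth$is_target, 2^cfg$target_log2fc, 1)
    }
    counts[, j] <- if (cfg$nb_dispersion > 0) {
      stats::rnbinom(n, mu = mu, size = 1 / cfg$nb_dispersion)
    } else {
      stats::rpois(n, lambda = mu)
    }
  }
  list(counts = counts, samples = samples)
}

#' Generate a complete synthetic dataset (optionally written to disk)
#'
#' Runs [make_annotation()], [plant_sites()], [simulate_parclip()] per
#' replica and [simulate_counts()]; when `outdir` is given, writes
#' `genome.fa`, `transcripts.bed` (BED12), `parclip_rep<i>.tsv`,
#' `counts.tsv`, `samples.tsv`, `truth_genes.tsv`, `truth_sites.tsv` and
#' `families.tsv`. All outputs are byte-deterministic for a fixed seed.
#'
#' @param cfg A [sim_config()].
#' @param outdir Output directory, or `NULL` to skip writing.
#' @return list with `annotation`, `truth`, `sites`, `parclip` (list of
#'   alignment sets), `rnaseq` (counts + samples), `config`.
#' @export
simulate_dataset <- function(cfg = sim_config(), outdir = NULL) {
  ann <- make_annotation(cfg)
  planted <- plant_sites(cfg, ann)
  parclip <- lapply(seq_len(cfg$parclip_replicas), function(r) {
    simulate_parclip(cfg, planted$annotation, planted$sites, r)
  })
  rnaseq <- simulate_counts(cfg, planted$truth)
  out <- list(
    annotation = planted$annotation, truth = planted$truth,
    sites = planted$sites, parclip = parclip, rnaseq = rnaseq, config = cfg
  )
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    Biostrings::writeXStringSet(out$annotation$genome, file.path(outdir, "genome.fa"))
    write_transcripts_bed12(out$annotation$transcripts, file.path(outdir, "transcripts.bed"))
    for (r in seq_along(parclip)) {
      write_alignments_tsv(parclip[[r]], file.path(outdir, sprintf("parclip_rep%d.tsv", r)))
    }
    counts_df <- data.frame(gene_id = rownames(rnaseq$counts), rnaseq$counts,
                            check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(counts_df, file.path(outdir, "counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(rnaseq$samples, file.path(outdir, "samples.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(out$truth, file.path(outdir, "truth_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(out$sites, file.path(outdir, "truth_sites.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cfg$families, file.path(outdir, "families.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Write a TranscriptSet as BED12
#'
#' @param ts A `TranscriptSet`.
#' @param path Output path.
#' @export
write_transcripts_bed12 <- function(ts, path) {
  rows <- vapply(seq_len(nrow(ts$tx)), function(i) {
    row <- ts$tx[i, ]
    ex <- ts$exons[[row$transcript_id]]
    chrom_start <- min(GenomicRanges::start(ex)) - 1L # BED 0-based half-open
    chrom_end <- max(GenomicRanges::end(ex))
    thick_s <- if (is.na(row$cds_start)) chrom_start else row$cds_start - 1L
    thick_e <- if (is.na(row$cds_start)) chrom_start else row$cds_end
    paste(
      row$chrom, chrom_start, chrom_end,
      paste(row$gene_id, row$transcript_id, sep = "|"),
      0L, row$strand, thick_s, thick_e, "0,0,0", length(ex),
      paste0(paste(GenomicRanges::width(ex), collapse = ","), ","),
      paste0(paste(GenomicRanges::start(ex) - 1L - chrom_start, collapse = ","), ","),
      sep = "\t"
    )
  }, "")
  writeLines(rows, path)
  invisible(path)
}
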