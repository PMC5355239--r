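# Shared in-code fixtures: tiny genomes, alignment builders, and a cached
# default pipeline run reused across end-to-end tests.

# genome with a single contig of `len` 'A's, with 'T' at the given positions
mk_genome <- function(len = 300L, t_at = integer(0), name = "chr1") {
  chars <- rep("A", len)
  chars[t_at] <- "T"
  g <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(g) <- name
  g
}

# build a parclip_alignments data.frame from per-read specs
# reads: list of list(start, width, conv = genomic positions converted (T>C),
#                     mm = optional list(pos, ref, read))
mk_aln <- function(reads, chrom = "chr1", strand = "+") {
  n <- length(reads)
  conv_read <- if (strand == "+") "C" else "G"
  conv_ref <- if (strand == "+") "T" else "A"
  mm_pos <- lapply(reads, function(r) {
    c(as.integer(r$conv %||0% integer(0)), as.integer(r$mm$pos %||0% integer(0)))
  })
  mm_ref <- lapply(reads, function(r) {
    c(rep(conv_ref, length(r$conv %||0% integer(0))), r$mm$ref %||0% character(0))
  })
  mm_read <- lapply(reads, function(r) {
    c(rep(conv_read, length(r$conv %||0% integer(0))), r$mm$read %||0% character(0))
  })
  df <- data.frame(
    chrom = chrom, strand = strand,
    start = vapply(reads, function(r) as.integer(r$start), 1L),
    width = vapply(reads, function(r) as.integer(r$width), 1L),
    stringsAsFactors = FALSE
  )
  df$mm_pos <- mm_pos
  df$mm_ref <- mm_ref
  df$mm_read <- mm_read
  class(df) <- c("parclip_alignments", "data.frame")
  df
}

`%||0%` <- function(a, b) if (is.null(a)) b else a

# a stack of identical reads all converted at `conv_at`
mk_stack <- function(n, start, width, conv_at = integer(0), chrom = "chr1",
                     strand = "+") {
  mk_aln(replicate(n, list(start = start, width = width, conv = conv_at),
                   simplify = FALSE), chrom = chrom, strand = strand)
}

rbind_aln <- function(...) {
  out <- do.call(rbind, list(...))
  class(out) <- c("parclip_alignments", "data.frame")
  out
}

# naive per-position double-loop KDE oracle (mirrors the normalized
# two-signal definition independently of the vectorized implementation)
kde_naive <- function(group, genome, cfg = parclip_config()) {
  pos <- group$start:group$end
  chars <- strsplit(as.character(genome[[group$chrom]]), "")[[1]]
  target <- if (group$strand == "+") "T" else "A"
  conv <- numeric(length(pos))
  nonconv <- numeric(length(pos))
  n_conv <- 0L
  n_nonconv <- 0L
  for (i in seq_len(nrow(group$reads))) {
    r <- group$reads[i, ]
    conv_pos <- r$mm_pos[[1]][
      (r$strand == "+" & r$mm_ref[[1]] == "T" & r$mm_read[[1]] == "C") |
        (r$strand == "-" & r$mm_ref[[1]] == "A" & r$mm_read[[1]] == "G")
    ]
    for (p in conv_pos) {
      n_conv <- n_conv + 1L
      for (j in seq_along(pos)) {
        conv[j] <- conv[j] + stats::dnorm((pos[j] - p) / cfg$bandwidth)
      }
    }
    for (g in r$start:(r$start + r$width - 1L)) {
      if (g <= length(chars) && chars[g] == target && !(g %in% conv_pos)) {
        n_nonconv <- n_nonconv + 1L
        for (j in seq_along(pos)) {
          nonconv[j] <- nonconv[j] + stats::dnorm((pos[j] - g) / cfg$bandwidth)
        }
      }
    }
  }
  list(
    conversion = if (n_conv) conv / n_conv else conv,
    nonconversion = if (n_nonconv) nonconv / n_nonconv else nonconv
  )
}

# random read group over a random genome, for KDE property tests
random_group <- function(seed) {
  set.seed(seed)
  len <- 200L
  chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  genome <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(genome) <- "chr1"
  t_pos <- which(chars == "T")
  n <- sample(5:12, 1)
  reads <- lapply(seq_len(n), function(i) {
    w <- sample(15:30, 1)
    s <- sample(seq_len(len - w), 1)
    cov_t <- t_pos[t_pos >= s & t_pos < s + w]
    conv <- cov_t[stats::runif(length(cov_t)) < 0.3]
    list(start = s, width = w, conv = conv)
  })
  aln <- mk_aln(reads)
  groups <- group_reads(aln, parclip_config(min_read_count_per_group = 1L))
  list(group = groups[[1]], genome = genome)
}

# cached default-configuration pipeline run (the study conditions), reused by
# the end-to-end tests so the expensive run happens once per test session
.acceptance_cache <- new.env(parent = emptyenv())
default_run <- function() {
  if (is.null(.acceptance_cache$run)) {
    outdir <- file.path(tempdir(), "spongeclip_default_run")
    res <- run_pipeline("all", outdir = outdir)
    .acceptance_cache$run <- list(res = res, outdir = outdir)
  }
  .acceptance_cache$run
}
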