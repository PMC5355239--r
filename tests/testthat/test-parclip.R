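test_that("read-level ingest filters apply length and mismatch budgets", {
  aln <- mk_aln(list(
    list(start = 100, width = 12, conv = 105),            # too short
    list(start = 100, width = 20, conv = integer(0)),     # clean, kept
    list(start = 100, width = 20, conv = 110,
         mm = list(pos = 112, ref = "G", read = "A")),    # non-conversion mm
    list(start = 100, width = 20, conv = c(110, 114))     # two conversions ok
  ))
  kept <- ingest_alignments(aln, parclip_config())
  expect_equal(nrow(kept), 2L)
  expect_equal(kept$width, c(20L, 20L))
  expect_equal(lengths(kept$mm_pos), c(0L, 2L))
  # raw ingest keeps everything
  expect_equal(nrow(ingest_alignments(aln, apply_filters = FALSE)), 4L)
  # minus strand: genomic A>G is the read-orientation conversion, kept
  minus <- mk_aln(list(list(start = 100, width = 20, conv = 110)), strand = "-")
  expect_equal(nrow(ingest_alignments(minus)), 1L)
})

test_that("alignment TSV round trip preserves mismatch records", {
  aln <- mk_aln(list(
    list(start = 5, width = 20, conv = c(10, 12)),
    list(start = 50, width = 25, conv = integer(0))
  ))
  path <- tempfile(fileext = ".tsv")
  write_alignments_tsv(aln, path)
  back <- read_alignments_tsv(path)
  expect_equal(back$start, aln$start)
  expect_equal(back$mm_pos, aln$mm_pos)
  expect_equal(back$mm_ref, aln$mm_ref)
})

test_that("SAM records with MD tags yield per-read mismatches", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:1000",
    paste("r1", 0, "chr1", 101, 255, "20M", "*", 0, 0,
          "AAAACAAAAAAAAAAAAAAA", strrep("I", 20), "MD:Z:4T15", "NM:i:1",
          sep = "\t"),
    paste("r2", 16, "chr1", 201, 255, "20M", "*", 0, 0,
          "AAAAAAAAAAAAAAAAAAAA", strrep("I", 20), "MD:Z:20", "NM:i:0",
          sep = "\t")
  ), sam)
  aln <- ingest_alignments(sam, apply_filters = FALSE)
  expect_equal(nrow(aln), 2L)
  r1 <- aln[aln$start == 101, ]
  expect_equal(r1$mm_pos[[1]], 105L)
  expect_equal(r1$mm_ref[[1]], "T")
  expect_equal(r1$mm_read[[1]], "C")
  expect_equal(aln$strand[aln$start == 201], "-")

  bad <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:1000",
    paste("r1", 0, "chr1", 101, 255, "10M2D10M", "*", 0, 0,
          "AAAACAAAAAAAAAAAAAAA", strrep("I", 20), "MD:Z:10^AC10", "NM:i:2",
          sep = "\t")
  ), bad)
  expect_error(ingest_alignments(bad, apply_filters = FALSE), "TSV")
})

test_that("mutation profiles tabulate mismatch classes in read orientation", {
  aln <- mk_aln(c(
    replicate(7, list(start = 100, width = 20, conv = 105), simplify = FALSE),
    replicate(3, list(start = 100, width = 20, conv = integer(0),
                      mm = list(pos = 106, ref = "G", read = "A")),
              simplify = FALSE)
  ))
  prof <- mutation_profile(aln)
  expect_equal(prof$percent[prof$class == "T>C"], 70)
  expect_equal(prof$percent[prof$class == "G>A"], 30)
  expect_equal(sum(prof$percent), 100)
  # minus-strand A>G is T>C in read orientation
  minus <- mk_aln(list(list(start = 100, width = 20, conv = 105)), strand = "-")
  pm <- mutation_profile(minus)
  expect_equal(pm$percent[pm$class == "T>C"], 100)
  empty <- mutation_profile(mk_aln(list(list(start = 1, width = 20, conv = integer(0)))))
  expect_true(attr(empty, "empty"))
  expect_equal(sum(empty$count), 0L)
})

test_that("read groups chain by overlap and respect the minimum count", {
  four <- mk_stack(4, 100, 30, conv_at = 110)
  expect_length(group_reads(four), 0L)
  five <- mk_stack(5, 100, 30, conv_at = 110)
  g <- group_reads(five)
  expect_length(g, 1L)
  expect_equal(c(g[[1]]$start, g[[1]]$end), c(100, 129))
  two <- rbind_aln(mk_stack(5, 100, 30), mk_stack(5, 500, 30))
  expect_length(group_reads(two), 2L)
  # a shared base chains; a 1-bp gap does not
  chained <- rbind_aln(mk_stack(3, 100, 30), mk_stack(3, 129, 30))
  expect_length(group_reads(chained), 1L)
  gapped <- rbind_aln(mk_stack(5, 100, 30), mk_stack(5, 130, 30))
  expect_length(group_reads(gapped), 2L)
})

test_that("kde_signal equals the naive double-loop oracle", {
  for (seed in 1:20) {
    rg <- random_group(seed)
    sig <- kde_signal(rg$group, rg$genome)
    want <- kde_naive(rg$group, rg$genome)
    expect_lt(max(abs(sig$conversion - want$conversion)), 1e-9)
    expect_lt(max(abs(sig$nonconversion - want$nonconversion)), 1e-9)
  }
})

test_that("kde signal is symmetric about a single conversion event", {
  genome <- mk_genome(300, t_at = 110)
  aln <- mk_stack(6, 100, 21, conv_at = 110) # reads centered on the event
  g <- group_reads(aln)[[1]]
  sig <- kde_signal(g, genome)
  expect_equal(which.max(sig$conversion), match(110, sig$pos))
  i <- match(110, sig$pos)
  expect_equal(sig$conversion[i - 5], sig$conversion[i + 5], tolerance = 1e-12)
  # all reads converted at every covered T: no non-conversion signal
  expect_true(all(sig$nonconversion == 0))
})

test_that("clusters form at conversion sites and respect all thresholds", {
  genome <- mk_genome(400, t_at = c(110, 300))
  aln <- mk_stack(6, 100, 30, conv_at = 110)
  cl <- call_parclip_clusters(aln, genome)
  expect_length(cl, 1L)
  expect_equal(S4Vectors::mcols(cl)$mode_location, 110)
  expect_gte(GenomicRanges::end(cl), 129)
  expect_lte(GenomicRanges::start(cl), 100)
  expect_equal(S4Vectors::mcols(cl)$read_count, 6L)

  cfg <- parclip_config()
  expect_true(all(GenomicRanges::width(cl) >= cfg$min_cluster_size))
  expect_true(all(S4Vectors::mcols(cl)$conv_locs >= cfg$min_conversion_locations))

  # flanking unconverted Ts confine the candidate run to a few nt around the
  # crosslink: without read extension it fails the minimum cluster size
  genome2 <- mk_genome(400, t_at = c(105, 110, 115))
  cfg_noext <- parclip_config(extend_by_read = FALSE)
  expect_length(call_parclip_clusters(aln, genome2, cfg_noext), 0L)
  expect_length(call_parclip_clusters(aln, genome2, parclip_config()), 1L)

  # a group without conversion evidence yields nothing
  clean <- mk_stack(6, 100, 30)
  expect_length(call_parclip_clusters(clean, genome), 0L)
})

test_that("two conversion hotspots in one group yield two clusters", {
  genome <- mk_genome(400, t_at = c(110, seq(126, 146, 4), 160))
  hot1 <- mk_stack(6, 100, 30, conv_at = 110)
  hot2 <- mk_stack(6, 145, 30, conv_at = 160)
  bridge <- mk_stack(5, 120, 30) # unconverted coverage over the gap Ts
  aln <- rbind_aln(hot1, bridge, hot2)
  expect_length(group_reads(aln), 1L)
  cl <- call_parclip_clusters(aln, genome)
  expect_length(cl, 2L)
  expect_equal(sort(S4Vectors::mcols(cl)$mode_location), c(110, 160))
})

test_that("cluster calling is invariant to read input order", {
  set.seed(21)
  rg <- random_group(33)
  genome <- rg$genome
  aln <- rg$group$reads
  cfg <- parclip_config(min_read_count_per_group = 2L,
                        min_read_count_per_cluster = 2L,
                        min_read_count_for_kde = 2L,
                        min_read_count_for_cluster_inclusion = 2L)
  cl1 <- call_parclip_clusters(aln, genome, cfg)
  shuf <- aln[sample(nrow(aln)), , drop = FALSE]
  class(shuf) <- class(aln)
  cl2 <- call_parclip_clusters(shuf, genome, cfg)
  expect_equal(as.data.frame(cl1), as.data.frame(cl2))
})

test_that("clusters annotate by maximal region overlap with fixed precedence", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t0\t300\tgeneA|txA\t0\t+\t100\t200\t0\t1\t300,\t0,", bed)
  regions <- derive_regions(load_transcripts(bed))
  mk_cl <- function(s, e) {
    GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e), strand = "+",
                           read_count = 5L, conv_count = 1L, conv_locs = 1L,
                           mode_location = as.integer((s + e) %/% 2))
  }
  inside <- annotate_clusters(mk_cl(210, 240), regions)
  expect_equal(S4Vectors::mcols(inside)$region_label, "3UTR")
  expect_equal(S4Vectors::mcols(inside)$gene_id, "geneA")
  # straddles CDS/3UTR with 60% in the 3'UTR
  straddle <- annotate_clusters(mk_cl(193, 212), regions)
  expect_equal(S4Vectors::mcols(straddle)$region_label, "3UTR")
  # exact tie broken by precedence (3UTR over CDS)
  tie <- annotate_clusters(mk_cl(196, 205), regions)
  expect_equal(S4Vectors::mcols(tie)$region_label, "3UTR")
  outside <- annotate_clusters(mk_cl(500, 520), regions)
  expect_equal(S4Vectors::mcols(outside)$region_label, "intergenic")
  occ <- region_occupancy(c(inside, straddle, outside))
  expect_equal(sum(occ$percent), 100)
  expect_equal(occ$n[occ$region_label == "3UTR"], 2L)
})
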