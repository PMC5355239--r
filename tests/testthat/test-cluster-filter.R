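# clusters and seed sites constructed directly in the genomic frame
mk_clusters <- function(starts, ends, modes, labels = "3UTR", genes = "geneA",
                        strand = "+", chrom = "chr1") {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends), strand = strand)
  S4Vectors::mcols(gr)$read_count <- 6L
  S4Vectors::mcols(gr)$conv_count <- 2L
  S4Vectors::mcols(gr)$conv_locs <- 1L
  S4Vectors::mcols(gr)$mode_location <- as.integer(modes)
  S4Vectors::mcols(gr)$gene_id <- genes
  S4Vectors::mcols(gr)$region_label <- labels
  gr
}

mk_sites <- function(starts, widths, types, fams = "miR-17", genes = "geneA",
                     strand = "+", chrom = "chr1") {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, width = widths),
                               strand = strand)
  S4Vectors::mcols(gr)$gene_id <- genes
  S4Vectors::mcols(gr)$family_id <- fams
  S4Vectors::mcols(gr)$site_type <- types
  S4Vectors::mcols(gr)$utr_start <- starts
  gr
}

test_that("3'UTR restriction keeps only 3'UTR-labeled clusters", {
  cl <- mk_clusters(c(100, 200, 300), c(130, 230, 330), c(110, 210, 310),
                    labels = c("3UTR", "CDS", "3UTR"))
  expect_equal(GenomicRanges::start(filter_utr3(cl)), c(100, 300))
  expect_length(filter_utr3(cl[0]), 0L)
  bare <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10))
  expect_error(filter_utr3(bare), "annotate")
})

test_that("seed proximity filter uses the mode-location window", {
  cl <- mk_clusters(100, 140, 120)
  # site starting exactly at the mode location: kept
  keep <- seed_proximity_filter(cl, mk_sites(120, 7, "7mer-m8"))
  expect_length(keep, 1L)
  expect_equal(S4Vectors::mcols(keep)$seed_families, "miR-17")
  # site interval touching the window edge (mode + 3): kept
  edge <- seed_proximity_filter(cl, mk_sites(123, 7, "7mer-m8"))
  expect_length(edge, 1L)
  # nearest site 5 bp beyond the window: dropped
  far <- seed_proximity_filter(cl, mk_sites(128, 7, "7mer-m8"))
  expect_length(far, 0L)
  # a 6mer inside the window does not count
  six <- seed_proximity_filter(cl, mk_sites(120, 6, "6mer"))
  expect_length(six, 0L)
  six_ok <- seed_proximity_filter(cl, mk_sites(120, 6, "6mer"),
                                  filter_config(exclude_6mer = FALSE))
  expect_length(six_ok, 1L)
  # start-distance mode: interval overlap is not enough
  ov_only <- seed_proximity_filter(cl, mk_sites(117, 7, "7mer-m8"),
                                   filter_config(window_mode = "start"))
  expect_length(ov_only, 1L) # start 117 within [117, 123]
  ov_only2 <- seed_proximity_filter(cl, mk_sites(116, 7, "7mer-m8"),
                                    filter_config(window_mode = "start"))
  expect_length(ov_only2, 0L)
})

test_that("filtering is monotone in window size and 6mer exclusion", {
  set.seed(31)
  cl <- mk_clusters(seq(100, 1000, 50), seq(140, 1040, 50),
                    seq(115, 1015, 50))
  sites <- mk_sites(sample(100:1050, 60, replace = TRUE),
                    sample(6:8, 60, replace = TRUE),
                    sample(c("6mer", "7mer-m8", "8mer"), 60, replace = TRUE))
  kept <- lapply(c(5L, 3L, 1L, 0L), function(w) {
    length(seed_proximity_filter(cl, sites, filter_config(seed_mode_window_nt = w)))
  })
  expect_true(all(diff(unlist(kept)) <= 0))
  with6 <- seed_proximity_filter(cl, sites, filter_config(exclude_6mer = FALSE))
  without6 <- seed_proximity_filter(cl, sites, filter_config(exclude_6mer = TRUE))
  expect_lte(length(without6), length(with6))
})

test_that("gene-level replicate overlap follows the smaller-set convention", {
  go <- gene_overlap(list(c("A", "B", "C"), c("B", "C"), c("B")))
  expect_equal(go$genes_in_all, "B")
  expect_true(all(go$genes_in_all %in% c("A", "B", "C")))
  go2 <- gene_overlap(list(sprintf("G%02d", 1:10), sprintf("G%02d", 7:11)))
  expect_equal(go2$pairwise$shared, 4L)
  expect_equal(go2$pairwise$fraction_of_smaller, 4 / 5)
  go3 <- gene_overlap(list(c("A", "B"), c("A", "B")))
  expect_equal(go3$pairwise$fraction_of_smaller, 1)
  expect_error(gene_overlap(list(c("A"))), "two replicas")
})

test_that("replicate cluster overlap requires the minimum shared bases", {
  gr1 <- mk_clusters(100, 129, 110)
  expect_equal(cluster_overlap(list(gr1, mk_clusters(121, 139, 125)))$n_groups, 0L)
  expect_equal(cluster_overlap(list(gr1, mk_clusters(120, 139, 125)))$n_groups, 1L)
  # pairwise rule across three replicas: a chain is not a group
  a <- mk_clusters(100, 120, 110)
  b <- mk_clusters(109, 140, 120)
  c3 <- mk_clusters(129, 160, 140)
  expect_equal(cluster_overlap(list(a, b, c3))$n_groups, 0L)
  # for plain intervals the pairwise rule and the common-core rule coincide
  # (the common core equals the overlap of the extreme pair)
  x <- mk_clusters(100, 140, 120)
  y <- mk_clusters(105, 145, 120)
  z <- mk_clusters(131, 170, 140)
  expect_equal(cluster_overlap(list(x, y, z))$n_groups, 1L)
  expect_equal(cluster_overlap(list(x, y, z),
                               filter_config(overlap_mode = "common_core"))$n_groups, 1L)
  z2 <- mk_clusters(135, 170, 140) # core [135,140] = 6 bp < 10 = min pairwise
  expect_equal(cluster_overlap(list(x, y, z2))$n_groups, 0L)
  expect_equal(cluster_overlap(list(x, y, z2),
                               filter_config(overlap_mode = "common_core"))$n_groups, 0L)
})

test_that("cluster overlap grouping is invariant to replica order on sparse instances", {
  set.seed(17)
  for (rep in 1:10) {
    reps <- lapply(1:3, function(r) {
      starts <- sort(sample(seq(1, 2000, by = 60), 8)) + sample(0:20, 8, replace = TRUE)
      mk_clusters(starts, starts + sample(20:40, 8, replace = TRUE),
                  starts + 10)
    })
    base <- cluster_overlap(reps)$n_groups
    for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
      expect_equal(cluster_overlap(reps[perm])$n_groups, base)
    }
  }
})

test_that("gene hit table counts replica support per gene and family", {
  mk_filtered <- function(genes, fams, types) {
    cl <- mk_clusters(seq(100, by = 100, length.out = length(genes)),
                      seq(140, by = 100, length.out = length(genes)),
                      seq(110, by = 100, length.out = length(genes)),
                      genes = genes)
    attr(cl, "matches") <- data.frame(
      cluster = seq_along(genes), gene_id = genes, family_id = fams,
      site_type = types, stringsAsFactors = FALSE
    )
    cl
  }
  r1 <- mk_filtered(c("gA", "gB"), c("f1", "f2"), c("8mer", "7mer-m8"))
  r2 <- mk_filtered("gB", "f2", "7mer-A1")
  r3 <- mk_filtered(c("gA", "gB"), c("f1", "f1"), c("7mer-m8", "7mer-m8"))
  ht <- gene_hit_table(list(r1, r2, r3))
  # f1 in replicas 1 and 3 for gA: a hit
  expect_true(ht$hit[ht$gene_id == "gA" & ht$family_id == "f1"])
  # f2 seen for gB in replicas 1 and 2: hit; f1 for gB only once: no hit
  expect_true(ht$hit[ht$gene_id == "gB" & ht$family_id == "f2"])
  expect_false(ht$hit[ht$gene_id == "gB" & ht$family_id == "f1"])
  # both flags reported for the two-family gene
  expect_equal(sort(ht$family_id[ht$gene_id == "gB"]), c("f1", "f2"))
  # site types aggregated across replicas
  expect_equal(ht$site_types[ht$gene_id == "gB" & ht$family_id == "f2"],
               "7mer-A1,7mer-m8")
})
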