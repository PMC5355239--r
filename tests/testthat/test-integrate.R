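test_that("upper-tail hypergeometric matches exhaustive enumeration (N <= 12)", {
  # oracle: enumerate all size-n draws from a universe with K marked items
  enum_upper <- function(N, K, n, k) {
    if (n == 0) return(if (k == 0) 1 else 0)
    draws <- utils::combn(N, n)
    mean(colSums(draws <= K) >= k)
  }
  for (N in c(2, 5, 8, 10, 12)) {
    for (K in c(0, 1, N %/% 2, N)) {
      for (n in c(0, 1, N %/% 2, N)) {
        for (k in 0:min(n, K)) {
          expect_equal(hypergeom_upper(N, K, n, k), enum_upper(N, K, n, k),
                       tolerance = 1e-12,
                       label = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
        }
      }
    }
  }
  expect_equal(hypergeom_upper(10, 5, 4, 4), 5 / 210, tolerance = 1e-12)
  expect_equal(hypergeom_upper(10, 5, 4, 0), 1)
  expect_equal(hypergeom_upper(7, 7, 7, 7), 1)
  expect_error(hypergeom_upper(10, 5, 4, 5), "bounds")
})

test_that("BH adjustment equals the hand step-up formula", {
  step_up <- function(p) {
    m <- length(p)
    o <- order(p)
    q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
    pmin(1, q_sorted)[order(o)]
  }
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(71)
  for (rep in 1:50) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, step_up(p), tolerance = 1e-12)
    expect_true(all(q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-12)) # monotone in raw p
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("seed-family enrichment is computed over the filtered universe", {
  universe <- sprintf("g%03d", 1:200)
  hit_table <- data.frame(
    gene_id = c(sprintf("g%03d", 1:30), sprintf("g%03d", 101:110)),
    family_id = c(rep("fA", 30), rep("fB", 10)),
    n_replicas = 3L, hit = TRUE,
    site_types = "8mer", stringsAsFactors = FALSE
  )
  up <- sprintf("g%03d", 1:25) # 25 of the 30 fA hit genes
  enr <- seed_enrichment(up, hit_table, universe)
  a <- enr[enr$family_id == "fA", ]
  expect_equal(a$K, 30L)
  expect_equal(a$k, 25L)
  expect_lt(a$p, 1e-10)
  b <- enr[enr$family_id == "fB", ]
  expect_equal(b$k, 0L)
  expect_equal(b$p, 1)
  # a family with no hits at all
  ht2 <- rbind(hit_table,
               data.frame(gene_id = "g150", family_id = "fC", n_replicas = 1L,
                          hit = FALSE, site_types = "7mer-m8"))
  enr2 <- seed_enrichment(up, ht2, universe)
  expect_equal(enr2$K[enr2$family_id == "fC"], 0L)
  expect_equal(enr2$p[enr2$family_id == "fC"], 1)
  expect_error(seed_enrichment(up, hit_table, character(0)), "universe")
})

test_that("enrichment p-values are near-uniform under a permuted null", {
  set.seed(72)
  universe <- sprintf("g%04d", 1:1000)
  hit_genes <- sample(universe, 200)
  hit_table <- data.frame(gene_id = hit_genes, family_id = "fA",
                          n_replicas = 2L, hit = TRUE, site_types = "8mer",
                          stringsAsFactors = FALSE)
  ks <- vapply(1:200, function(i) {
    up <- sample(universe, 300) # no association with the hit set
    seed_enrichment(up, hit_table, universe)$k
  }, 1L)
  # the hypergeometric p is discrete; its randomized version
  # P(X > k) + U * P(X = k) is exactly Uniform(0,1) under the null
  u <- phyper(ks, 200, 800, 300, lower.tail = FALSE) +
    runif(length(ks)) * dhyper(ks, 200, 800, 300)
  expect_gt(stats::ks.test(u, "punif")$p.value, 0.01)
  # and the reported upper-tail p is valid (conservative): P(p <= a) <= a
  ps <- vapply(ks, function(k) hypergeom_upper(1000, 200, 300, k), 1)
  for (a in c(0.01, 0.05, 0.2)) {
    expect_lte(mean(ps <= a), a + 3 * sqrt(a * (1 - a) / length(ps)))
  }
})

test_that("target calls require derepression and replicated binding", {
  de <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    log2fc = c(0.4, 0.4, 0.2, 0.9),
    p = 0.1, fdr = 0.5, stringsAsFactors = FALSE
  )
  ht <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    family_id = "miR-17",
    n_replicas = c(2L, 1L, 3L, 2L),
    hit = c(TRUE, FALSE, TRUE, TRUE),
    site_types = "8mer", stringsAsFactors = FALSE
  )
  calls <- intersect_targets(de, ht, "miR-17")
  expect_equal(calls$gene_id, c("g4", "g1")) # sorted by descending log2fc
  expect_false("g2" %in% calls$gene_id)      # only 1 replica
  expect_false("g3" %in% calls$gene_id)      # log2fc below the relaxed cutoff
  # deterministic and order-invariant
  calls2 <- intersect_targets(de[sample(4), ], ht[sample(4), ], "miR-17")
  expect_equal(calls, calls2)
  # a family outside the families of interest does not support a call
  expect_equal(nrow(intersect_targets(de, ht, "miR-99")), 0L)
})

test_that("gene-set overlap statistics reproduce k/K ratios exactly", {
  # worked example mirroring a published five-pathway table: K and k pairs
  sizes <- c(GENERIC_TRANSCRIPTION = 352, SMAD2_3_NUCLEAR = 82,
             PPARA_ACTIVATES = 104, SMAD_HETEROTRIMER = 38, TGFBR = 55)
  ks <- c(10, 4, 4, 3, 3)
  members <- lapply(seq_along(sizes), function(i) {
    sprintf("SET%d_G%04d", i, seq_len(sizes[i]))
  })
  gmt <- tempfile(fileext = ".gmt")
  writeLines(vapply(seq_along(sizes), function(i) {
    paste(c(names(sizes)[i], "desc", members[[i]]), collapse = "\t")
  }, ""), gmt)
  gs <- load_gmt(gmt)
  query <- c(unlist(lapply(seq_along(sizes), function(i) members[[i]][seq_len(ks[i])])),
             sprintf("EXTRA_G%03d", 1:40))
  res <- set_overlap_stats(query, gs)
  res <- res[match(names(sizes), res$set_name), ]
  expect_equal(res$K, unname(sizes))
  expect_equal(res$k, ks)
  expect_equal(round(res$ratio, 4), c(0.0284, 0.0488, 0.0385, 0.0789, 0.0545))
  expect_true(all(res$k <= res$K))
  # query equal to the universe: every set fully covered at p = 1
  full <- set_overlap_stats(unique(unlist(gs$sets)), gs,
                            universe = unique(unlist(gs$sets)))
  expect_equal(full$k, full$K)
  expect_equal(full$ratio, rep(1, 5))
  expect_equal(full$p, rep(1, 5))
  # a set disjoint from the universe is flagged and excluded from BH
  gs2 <- gs
  gs2$sets$DISJOINT <- c("nowhere1", "nowhere2")
  gs2$description <- c(gs2$description, DISJOINT = "d")
  res2 <- set_overlap_stats(query, gs2, universe = unique(unlist(gs$sets)))
  expect_equal(res2$K[res2$set_name == "DISJOINT"], 0L)
  expect_true(is.na(res2$q[res2$set_name == "DISJOINT"]))
})
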