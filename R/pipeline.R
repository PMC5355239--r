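#' Load (or default) the pipeline configuration
#'
#' YAML with optional sections `sim`, `parclip`, `filter`, `de`, and scalar
#' keys `families_file`, `gene_sets_file`, `families_of_interest`. Keys in
#' the `parclip` section use the PARalyzer-style `.ini` names (`BANDWIDTH`,
#' `MINIMUM_READ_COUNT_PER_GROUP`, ...) so a configuration can be compared
#' line by line against a PARalyzer run; they map onto [parclip_config()].
#' Unknown keys are rejected with the list of valid ones.
#'
#' @param path YAML path, or `NULL` for the built-in defaults.
#' @return list with elements `sim`, `parclip`, `filter`, `de`,
#'   `families`, `families_of_interest`, `gene_sets_file`.
#' @export
load_pipeline_config <- function(path = NULL) {
  ini_map <- c(
    BANDWIDTH = "bandwidth",
    CONVERSION = "conversion",
    MINIMUM_READ_COUNT_PER_GROUP = "min_read_count_per_group",
    MINIMUM_READ_COUNT_PER_CLUSTER = "min_read_count_per_cluster",
    MINIMUM_READ_COUNT_FOR_KDE = "min_read_count_for_kde",
    MINIMUM_CLUSTER_SIZE = "min_cluster_size",
    MINIMUM_CONVERSION_LOCATIONS_FOR_CLUSTER = "min_conversion_locations",
    MINIMUM_CONVERSION_COUNT_FOR_CLUSTER = "min_conversion_count",
    MINIMUM_READ_COUNT_FOR_CLUSTER_INCLUSION = "min_read_count_for_cluster_inclusion",
    MINIMUM_READ_LENGTH = "min_read_length",
    MAXIMUM_NUMBER_OF_NON_CONVERSION_MISMATCHES = "max_non_conversion_mismatches",
    EXTEND_BY_READ = "extend_by_read",
    MAXIMUM_SEED_MATCH_LENGTH = "max_seed_match_length"
  )
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  known_top <- c("sim", "parclip", "filter", "de", "families_file",
                 "gene_sets_file", "families_of_interest")
  bad <- setdiff(names(raw), known_top)
  .assert(length(bad) == 0L, "unknown config keys: %s (valid: %s)",
          paste(bad, collapse = ", "), paste(known_top, collapse = ", "))
  pc <- raw$parclip
  if (!is.null(pc)) {
    badp <- setdiff(names(pc), names(ini_map))
    .assert(length(badp) == 0L, "unknown parclip config keys: %s (valid: %s)",
            paste(badp, collapse = ", "), paste(names(ini_map), collapse = ", "))
    names(pc) <- ini_map[names(pc)]
  }
  check_args <- function(given, fn, section) {
    badk <- setdiff(names(given), names(formals(fn)))
    .assert(length(badk) == 0L, "unknown %s config keys: %s (valid: %s)",
            section, paste(badk, collapse = ", "),
            paste(names(formals(fn)), collapse = ", "))
    given
  }
  families <- if (!is.null(raw$families_file)) {
    load_family_table(raw$families_file)
  } else {
    default_family_table()
  }
  sim_args <- check_args(raw$sim %||% list(), sim_config, "sim")
  list(
    sim = do.call(sim_config, sim_args),
    parclip = do.call(parclip_config, pc %||% list()),
    filter = do.call(filter_config, check_args(raw$filter %||% list(), filter_config, "filter")),
    de = do.call(de_config, check_args(raw$de %||% list(), de_config, "de")),
    families = families,
    families_of_interest = raw$families_of_interest %||% families$family_id,
    gene_sets_file = raw$gene_sets_file
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write cluster tables as TSV
#'
#' Full-fidelity TSV serialization of cluster `GRanges` (all metadata
#' columns), used between pipeline stages; see [write_clusters_bed()] for the
#' BED6+4 interchange form.
#'
#' @param clusters Cluster `GRanges`.
#' @param path TSV path.
#' @export
write_clusters_tsv <- function(clusters, path) {
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(clusters)),
    start = GenomicRanges::start(clusters),
    end = GenomicRanges::end(clusters),
    strand = as.character(BiocGenerics::strand(clusters)),
    as.data.frame(S4Vectors::mcols(clusters)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clusters_tsv
#' @export
read_clusters_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  extra <- setdiff(names(df), c("chrom", "start", "end", "strand"))
  for (cn in extra) S4Vectors::mcols(gr)[[cn]] <- df[[cn]]
  gr
}

.report_add <- function(report, stage, metric, value) {
  rbind(report, data.frame(stage = stage, metric = metric, value = value,
                           stringsAsFactors = FALSE))
}

#' Run the targetome pipeline
#'
#' Orchestrates the stages end-to-end on a synthetic dataset with known
#' truth. `"all"` runs simulate, callclusters, filterclusters, de, enrich and
#' intersect in order; a single stage name runs that stage against the
#' outputs already present in `outdir`. Stage outputs are written under
#' `outdir` with stable filenames, and a run report (per-stage record counts
#' and every threshold applied) is written to `run_report.tsv`.
#'
#' @param stage One of `"all"`, `"simulate"`, `"callclusters"`,
#'   `"filterclusters"`, `"de"`, `"enrich"`, `"intersect"`.
#' @param config Path to a YAML configuration, a list from
#'   [load_pipeline_config()], or `NULL` for defaults.
#' @param outdir Output directory (created if needed).
#' @param seed Optional integer overriding the configured RNG seed.
#' @return Invisibly, a list with the stage results and the `report`
#'   data.frame.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "callclusters",
                                   "filterclusters", "de", "enrich", "intersect"),
                         config = NULL, outdir = tempfile("spongeclip_run_"),
                         seed = NULL) {
  stage <- match.arg(stage)
  cfg <- if (is.list(config) && !is.null(config$parclip)) config else load_pipeline_config(config)
  if (!is.null(seed)) {
    cfg$sim$rng_seed <- as.integer(seed)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  data_dir <- file.path(outdir, "data")
  report <- data.frame(stage = character(), metric = character(),
                       value = character(), stringsAsFactors = FALSE)
  for (nm in names(cfg$parclip)) {
    report <- .report_add(report, "config", paste0("parclip.", nm),
                          as.character(cfg$parclip[[nm]]))
  }
  for (nm in names(cfg$filter)) {
    report <- .report_add(report, "config", paste0("filter.", nm),
                          as.character(cfg$filter[[nm]]))
  }
  for (nm in c("cpm_cutoff", "cpm_min_samples", "fc_cutoff", "fdr_cutoff", "relaxed_log2fc")) {
    report <- .report_add(report, "config", paste0("de.", nm),
                          as.character(cfg$de[[nm]]))
  }
  report <- .report_add(report, "config", "rng_seed", as.character(cfg$sim$rng_seed))

  results <- list()
  stages <- if (stage == "all") {
    c("simulate", "callclusters", "filterclusters", "de", "enrich", "intersect")
  } else {
    stage
  }

  for (st in stages) {
    if (st == "simulate") {
      simulate_dataset(cfg$sim, data_dir)
      report <- .report_add(report, "simulate", "n_genes", cfg$sim$n_genes)
      report <- .report_add(report, "simulate", "n_true_targets", cfg$sim$n_true_targets)
      report <- .report_add(report, "simulate", "parclip_replicas", cfg$sim$parclip_replicas)
    } else if (st == "callclusters") {
      .assert(file.exists(file.path(data_dir, "genome.fa")),
              "missing input %s: run the simulate stage first",
              file.path(data_dir, "genome.fa"))
      genome <- load_fasta(file.path(data_dir, "genome.fa"))
      ts <- load_transcripts(file.path(data_dir, "transcripts.bed"))
      regions <- derive_regions(ts)
      rep_files <- sort(list.files(data_dir, "^parclip_rep[0-9]+\\.tsv$", full.names = TRUE))
      .assert(length(rep_files) >= 2L, "missing PAR-CLIP replica alignments in %s", data_dir)
      for (r in seq_along(rep_files)) {
        raw <- ingest_alignments(rep_files[r], cfg$parclip, apply_filters = FALSE)
        aln <- ingest_alignments(raw, cfg$parclip)
        prof <- mutation_profile(raw)
        clusters <- call_parclip_clusters(aln, genome, cfg$parclip)
        clusters <- annotate_clusters(clusters, regions)
        write_clusters_tsv(clusters, file.path(outdir, sprintf("clusters_rep%d.tsv", r)))
        write_clusters_bed(clusters, file.path(outdir, sprintf("clusters_rep%d.bed", r)))
        utils::write.table(prof, file.path(outdir, sprintf("mutation_profile_rep%d.tsv", r)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(region_occupancy(clusters),
                           file.path(outdir, sprintf("occupancy_rep%d.tsv", r)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        report <- .report_add(report, "callclusters", sprintf("rep%d.reads_in", r), nrow(raw))
        report <- .report_add(report, "callclusters", sprintf("rep%d.reads_filtered", r), nrow(aln))
        report <- .report_add(report, "callclusters", sprintf("rep%d.clusters", r), length(clusters))
      }
    } else if (st == "filterclusters") {
      genome <- load_fasta(file.path(data_dir, "genome.fa"))
      ts <- load_transcripts(file.path(data_dir, "transcripts.bed"))
      regions <- derive_regions(ts)
      utr3 <- utr3_by_gene(regions)
      sites <- scan_utr3_sites(genome, utr3, cfg$families,
                               include_6mer = !cfg$filter$exclude_6mer)
      cl_files <- sort(list.files(outdir, "^clusters_rep[0-9]+\\.tsv$", full.names = TRUE))
      .assert(length(cl_files) >= 2L, "missing cluster tables: run callclusters first")
      filtered <- list()
      for (r in seq_along(cl_files)) {
        cl <- read_clusters_tsv(cl_files[r])
        cl3 <- if (cfg$filter$restrict_to_3utr) filter_utr3(cl) else cl
        fl <- seed_proximity_filter(cl3, sites, cfg$filter)
        filtered[[r]] <- fl
        write_clusters_tsv(fl, file.path(outdir, sprintf("filtered_rep%d.tsv", r)))
        report <- .report_add(report, "filterclusters", sprintf("rep%d.clusters_in", r), length(cl))
        report <- .report_add(report, "filterclusters", sprintf("rep%d.clusters_3utr", r), length(cl3))
        report <- .report_add(report, "filterclusters", sprintf("rep%d.clusters_seed", r), length(fl))
      }
      hits <- gene_hit_table(filtered, cfg$filter)
      utils::write.table(hits, file.path(outdir, "gene_hit_table.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      go <- gene_overlap(filtered)
      co <- cluster_overlap(filtered, cfg$filter)
      overlap_summary <- rbind(
        data.frame(metric = paste0("genes_", names(go$genes_per_replica)),
                   value = as.numeric(go$genes_per_replica), stringsAsFactors = FALSE),
        data.frame(metric = sprintf("genes_shared_frac_%d_%d", go$pairwise$i, go$pairwise$j),
                   value = go$pairwise$fraction_of_smaller, stringsAsFactors = FALSE),
        data.frame(metric = "genes_in_all", value = length(go$genes_in_all),
                   stringsAsFactors = FALSE),
        data.frame(metric = "cluster_overlap_groups", value = co$n_groups,
                   stringsAsFactors = FALSE)
      )
      utils::write.table(overlap_summary, file.path(outdir, "overlap_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report <- .report_add(report, "filterclusters", "genes_in_all", length(go$genes_in_all))
      results$hit_table <- hits
    } else if (st == "de") {
      cf <- file.path(data_dir, "counts.tsv")
      .assert(file.exists(cf), "missing input %s: run the simulate stage first", cf)
      cdf <- utils::read.delim(cf, check.names = FALSE, stringsAsFactors = FALSE)
      counts <- as.matrix(cdf[, -1, drop = FALSE])
      rownames(counts) <- cdf[[1L]]
      samples <- utils::read.delim(file.path(data_dir, "samples.tsv"),
                                   stringsAsFactors = FALSE)
      keep <- cpm_filter(counts, cfg$de)
      de <- de_test(counts[keep, , drop = FALSE], samples,
                    c("target_sponge", "control_sponge"), cfg$de)
      calls <- call_de(de, cfg$de)
      de$up_strict <- de$gene_id %in% calls$up_strict
      de$down_strict <- de$gene_id %in% calls$down_strict
      de$up_relaxed <- de$gene_id %in% calls$up_relaxed
      utils::write.table(de, file.path(outdir, "de_results.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if ("other_sponge" %in% samples$condition) {
        de_other <- de_test(counts[keep, , drop = FALSE], samples,
                            c("other_sponge", "control_sponge"), cfg$de)
        utils::write.table(de_other, file.path(outdir, "de_results_other.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        spec <- specificity_screen(de, de_other, cfg$de)
        report <- .report_add(report, "de", "specificity_overlap_k", spec$k)
        report <- .report_add(report, "de", "specificity_overlap_p", signif(spec$p, 6))
      }
      report <- .report_add(report, "de", "genes_total", nrow(counts))
      report <- .report_add(report, "de", "genes_cpm_filtered", length(keep))
      report <- .report_add(report, "de", "up_strict", length(calls$up_strict))
      report <- .report_add(report, "de", "down_strict", length(calls$down_strict))
      report <- .report_add(report, "de", "up_relaxed", length(calls$up_relaxed))
      results$de <- de
    } else if (st == "enrich") {
      de <- utils::read.delim(file.path(outdir, "de_results.tsv"), stringsAsFactors = FALSE)
      hits <- utils::read.delim(file.path(outdir, "gene_hit_table.tsv"), stringsAsFactors = FALSE)
      up_relaxed <- de$gene_id[de$log2fc > cfg$de$relaxed_log2fc]
      enr <- seed_enrichment(up_relaxed, hits, de$gene_id)
      utils::write.table(enr, file.path(outdir, "seed_enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(cfg$gene_sets_file)) {
        gmt <- load_gmt(cfg$gene_sets_file)
        sos <- set_overlap_stats(up_relaxed, gmt)
        utils::write.table(sos, file.path(outdir, "gene_set_overlap.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      report <- .report_add(report, "enrich", "families_tested", nrow(enr))
      if (nrow(enr)) {
        report <- .report_add(report, "enrich", "min_family_p", signif(min(enr$p), 6))
      }
      results$enrichment <- enr
    } else if (st == "intersect") {
      de <- utils::read.delim(file.path(outdir, "de_results.tsv"), stringsAsFactors = FALSE)
      hits <- utils::read.delim(file.path(outdir, "gene_hit_table.tsv"), stringsAsFactors = FALSE)
      calls <- intersect_targets(de, hits, cfg$families_of_interest, cfg$de)
      utils::write.table(calls, file.path(outdir, "target_calls.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report <- .report_add(report, "intersect", "target_calls", nrow(calls))
      results$target_calls <- calls
    }
  }
  utils::write.table(report, file.path(outdir, "run_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  results$report <- report
  results$outdir <- outdir
  invisible(results)
}
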