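#' Differential-expression configuration
#'
#' Defaults follow the published analysis: genes kept when CPM exceeds 10 in
#' strictly more than 2 samples; strict DE calls at |fold change| > 1.5 and
#' BH FDR < 0.1; the deliberately non-stringent derepression cutoff is
#' log2 fold change > 0.3 with no FDR condition (miRNAs typically shift mRNA
#' abundance only mildly).
#'
#' @param cpm_cutoff CPM threshold.
#' @param cpm_min_samples A gene is kept when CPM exceeds the cutoff in
#'   strictly more than this many samples.
#' @param fc_cutoff Strict fold-change threshold (linear scale).
#' @param fdr_cutoff Strict BH FDR threshold.
#' @param relaxed_log2fc Relaxed up-regulation cutoff (log2 scale, no FDR).
#' @param prior_count Prior count added before log2-CPM.
#' @return Validated list of class `de_config`.
#' @export
de_config <- function(cpm_cutoff = 10, cpm_min_samples = 2L, fc_cutoff = 1.5,
                      fdr_cutoff = 0.1, relaxed_log2fc = 0.3, prior_count = 0.5) {
  cfg <- list(
    cpm_cutoff = cpm_cutoff, cpm_min_samples = as.integer(cpm_min_samples),
    fc_cutoff = fc_cutoff, fdr_cutoff = fdr_cutoff,
    relaxed_log2fc = relaxed_log2fc, prior_count = prior_count
  )
  .assert(all(unlist(cfg) > 0), "all DE thresholds must be positive")
  structure(cfg, class = "de_config")
}

#' Counts per million
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @param lib_sizes Library sizes; defaults to column sums.
#' @return Matrix of CPM values.
#' @export
cpm <- function(counts, lib_sizes = colSums(counts)) {
  .assert(all(lib_sizes > 0), "zero library size")
  sweep(counts, 2L, lib_sizes, "/") * 1e6
}

#' Expression filter: CPM above cutoff in more than k samples
#'
#' @param counts Genes x samples count matrix (rownames = gene ids).
#' @param cfg A [de_config()].
#' @return Character vector of retained gene ids.
#' @export
cpm_filter <- function(counts, cfg = de_config()) {
  .assert(!any(counts < 0), "counts must be non-negative")
  x <- cpm(counts)
  keep <- rowSums(x > cfg$cpm_cutoff) > cfg$cpm_min_samples
  rownames(counts)[keep]
}

# single-pair TMM factor (weighted trimmed mean of M-values)
.tmm_pair <- function(obs, ref, lib_obs, lib_ref,
                      logratio_trim = 0.3, sum_trim = 0.05) {
  fin <- obs > 0 & ref > 0
  obs <- obs[fin]; ref <- ref[fin]
  if (!length(obs)) return(1)
  logR <- log2((obs / lib_obs) / (ref / lib_ref))
  absE <- (log2(obs / lib_obs) + log2(ref / lib_ref)) / 2
  v <- (lib_obs - obs) / lib_obs / obs + (lib_ref - ref) / lib_ref / ref
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1
  hiL <- n + 1 - loL
  loS <- floor(n * sum_trim) + 1
  hiS <- n + 1 - loS
  keep <- rank(logR) >= loL & rank(logR) <= hiL &
    rank(absE) >= loS & rank(absE) <= hiS
  f <- sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  if (!is.finite(f)) f <- 0
  2^f
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values between-sample normalization: per-sample factors
#' computed against a reference column (the sample whose upper-quartile
#' expression is closest to the mean), with 30% trimming on log-ratios, 5% on
#' average log-abundance, and precision weighting; factors are rescaled so
#' their geometric mean is 1. Effective library sizes are `colSums(counts) *
#' factors`.
#'
#' @param counts Genes x samples count matrix.
#' @return Numeric vector of normalization factors (one per sample).
#' @export
tmm_factors <- function(counts) {
  .assert(ncol(counts) >= 1L, "empty count matrix")
  lib <- colSums(counts)
  .assert(all(lib > 0), "zero library size")
  nonzero <- rowSums(counts) > 0
  if (sum(nonzero) <= 1L) {
    warning("degenerate count matrix (<= 1 expressed gene); returning unit factors")
    return(rep(1, ncol(counts)))
  }
  x <- counts[nonzero, , drop = FALSE]
  f75 <- vapply(seq_len(ncol(x)), function(j) {
    stats::quantile(x[, j], 0.75) / lib[j]
  }, 1)
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(x)), function(j) {
    .tmm_pair(x[, j], x[, ref], lib[j], lib[ref])
  }, 1)
  f / exp(mean(log(f)))
}

# Newton solve of trigamma(y) = x (as in empirical-Bayes variance moment
# matching); x > 0
.trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (iter in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, deriv = 2L)
      y <- y + dif
      if (abs(dif / y) < 1e-8) break
    }
    y
  }, 1)
}

# moment-match a scaled-F prior to observed sample variances s2 on df degrees
# of freedom; returns list(df_prior, var_prior)
.fit_f_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) {
    # degenerate input (e.g. constant log-cpm): no shrinkage target exists
    warning("too few positive variances for empirical Bayes moment matching; ",
            "using an uninformative prior")
    return(list(df_prior = Inf, var_prior = max(mean(s2), 1e-8)))
  }
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (evar > 0) {
    df_prior <- 2 * .trigamma_inverse(evar)
    var_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    df_prior <- Inf
    var_prior <- exp(emean)
  }
  list(df_prior = df_prior, var_prior = var_prior)
}

#' Moderated two-sample differential expression test
#'
#' Minimal count-based DE: log2-CPM with a prior count on TMM-effective
#' library sizes; per-gene two-sample comparison of means with an
#' empirical-Bayes moderated t-statistic whose prior degrees of freedom and
#' prior variance are moment-matched on the distribution of log sample
#' variances; two-sided p-values; BH-adjusted FDR over the tested genes.
#'
#' @param counts Genes x samples count matrix (rownames = gene ids), already
#'   restricted to the expression-filtered genes.
#' @param samples data.frame with columns `sample` (matching `colnames(counts)`)
#'   and `condition`.
#' @param contrast Length-2 character: `c(test_condition, reference_condition)`;
#'   log2 fold changes are test minus reference.
#' @param cfg A [de_config()].
#' @return data.frame with `gene_id`, `log2fc`, `t`, `p`, `fdr`.
#' @export
de_test <- function(counts, samples, contrast = c("target_sponge", "control_sponge"),
                    cfg = de_config()) {
  .assert(length(contrast) == 2L, "contrast must name two conditions")
  .assert(all(contrast %in% samples$condition),
          "conditions %s absent from sample sheet",
          paste(setdiff(contrast, samples$condition), collapse = ", "))
  sel <- samples$condition %in% contrast
  samples <- samples[sel, , drop = FALSE]
  .assert(all(samples$sample %in% colnames(counts)), "sample sheet/count matrix mismatch")
  counts <- counts[, samples$sample, drop = FALSE]
  grp <- samples$condition == contrast[1L]
  n1 <- sum(grp); n2 <- sum(!grp)
  .assert(n1 >= 2L && n2 >= 2L, "each compared condition needs at least 2 replicates")

  eff_lib <- colSums(counts) * tmm_factors(counts)
  logcpm <- log2(sweep(counts + cfg$prior_count, 2L, eff_lib + 1, "/") * 1e6)

  m1 <- rowMeans(logcpm[, grp, drop = FALSE])
  m2 <- rowMeans(logcpm[, !grp, drop = FALSE])
  ss1 <- rowSums((logcpm[, grp, drop = FALSE] - m1)^2)
  ss2 <- rowSums((logcpm[, !grp, drop = FALSE] - m2)^2)
  df <- n1 + n2 - 2L
  s2 <- (ss1 + ss2) / df

  prior <- .fit_f_prior(s2, df)
  if (is.finite(prior$df_prior)) {
    s2_post <- (prior$df_prior * prior$var_prior + df * s2) / (prior$df_prior + df)
    df_total <- df + prior$df_prior
  } else {
    s2_post <- rep(prior$var_prior, length(s2))
    df_total <- Inf
  }
  tstat <- (m1 - m2) / sqrt(s2_post * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(abs(tstat), df = df_total, lower.tail = FALSE)
  data.frame(
    gene_id = rownames(counts),
    log2fc = m1 - m2, t = tstat, p = p, fdr = bh_adjust(p),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Threshold DE results into strict and relaxed call sets
#'
#' @param results data.frame from [de_test()].
#' @param cfg A [de_config()].
#' @return list with `up_strict`, `down_strict` (|FC| > `fc_cutoff` and FDR <
#'   `fdr_cutoff`) and `up_relaxed` (log2FC > `relaxed_log2fc`, no FDR
#'   condition) gene-id vectors.
#' @export
call_de <- function(results, cfg = de_config()) {
  lfc_cut <- log2(cfg$fc_cutoff)
  list(
    up_strict = results$gene_id[results$log2fc > lfc_cut & results$fdr < cfg$fdr_cutoff],
    down_strict = results$gene_id[results$log2fc < -lfc_cut & results$fdr < cfg$fdr_cutoff],
    up_relaxed = results$gene_id[results$log2fc > cfg$relaxed_log2fc]
  )
}

#' Overlap of strict DE responses between two sponges
#'
#' Hypergeometric overlap between the strict DE gene sets (up and down
#' combined) of two contrasts computed on the same gene universe; used to
#' check that a family-specific sponge response is not shared with an
#' unrelated sponge.
#'
#' @param results_target,results_other data.frames from [de_test()] on the
#'   same universe.
#' @param cfg A [de_config()].
#' @param exclude_shared Also report the target-sponge strict set with the
#'   shared genes removed (`shared_excluded`)? Off by default.
#' @return list with `N`, `K`, `n`, `k`, `p` (upper-tail hypergeometric), and
#'   `shared_excluded` when requested.
#' @export
specificity_screen <- function(results_target, results_other, cfg = de_config(),
                               exclude_shared = FALSE) {
  .assert(setequal(results_target$gene_id, results_other$gene_id),
          "contrasts must be computed on the same gene universe")
  universe <- results_target$gene_id
  a <- call_de(results_target, cfg)
  b <- call_de(results_other, cfg)
  set_a <- union(a$up_strict, a$down_strict)
  set_b <- union(b$up_strict, b$down_strict)
  k <- length(intersect(set_a, set_b))
  out <- list(
    N = length(universe), K = length(set_a), n = length(set_b), k = k,
    p = hypergeom_upper(length(universe), length(set_a), length(set_b), k)
  )
  if (exclude_shared) out$shared_excluded <- sort(setdiff(set_a, set_b))
  out
}
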