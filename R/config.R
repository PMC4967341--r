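#' Pipeline configuration
#'
#' Bundles every tunable threshold of the pipeline with its default. The
#' defaults encode the published analysis settings: reads below mapping
#' quality 30 and bases below base quality 17 are discarded when calling
#' methylation; DMRs require a methylation difference of at least 0.3 over at
#' least four CpGs with a per-CpG q-value at most 1e-4; NDRs are kept below
#' an empirical FDR of 0.01; region enrichment uses one million matched
#' random sets; histone signatures are clustered with k = 3 over 25-bp bins
#' spanning regions plus 1-kb flanks, and per-cluster changes are tested at
#' Bonferroni-corrected alpha 0.001.
#'
#' @param mapq_min minimum mapping quality; reads with `mapq < mapq_min` are
#'   excluded (boundary value passes).
#' @param baseq_min minimum base quality; bases with `baseq < baseq_min` are
#'   ignored (boundary value passes).
#' @param dmr_min_diff minimum absolute group mean methylation difference for
#'   a DMR.
#' @param dmr_min_cpgs minimum number of CpGs in a DMR.
#' @param dmr_q_cutoff per-CpG q-value cutoff defining candidate DMR sites.
#' @param dmr_max_gap_bp maximum gap between consecutive CpGs within one DMR
#'   candidate run.
#' @param smooth_window_bp minimum full width of the methylation smoothing
#'   window. The default (100 bp) keeps the kernel below the size of the
#'   smallest regions of interest (85 bp upward); pass 2000 together with
#'   `smooth_min_sites = 70` for broad-domain smoothing of
#'   CpG-sparse differences.
#' @param smooth_min_sites minimum number of CpGs (including the centre site)
#'   in a smoothing window; the window expands until it holds this many.
#' @param efdr_cutoff empirical FDR below which an NDR is called.
#' @param n_shuffles number of full shuffle re-runs pooled into the eFDR
#'   null. With `S` shuffles the smallest attainable eFDR of a top-ranked
#'   call is `1/(S+1)`, so `S` must comfortably exceed `1/efdr_cutoff / k`
#'   for `k` expected true calls; 20 leaves margin at the 0.01 gate.
#' @param flank_bp flank width cap for the Fisher contrast and for signal
#'   matrices (1 kb).
#' @param n_permutations number of simulated region sets in
#'   [permutation_enrichment()].
#' @param min_cpgs_matched minimum CpG count a matched random region must
#'   contain (rejection-sampled).
#' @param kmeans_k number of clusters for histone-signature clustering.
#' @param bin_size_bp ChIP/input bin width.
#' @param alpha_bonferroni significance level applied to
#'   Bonferroni-adjusted paired-test p-values.
#' @param border_tol_bp border tolerance (bp) for calling two overlapping
#'   peaks "same borders" in [classify_overlap()].
#' @param rng_seed integer seed threaded through stochastic steps
#'   (shuffling, permutation sampling, k-means restarts); `NULL` leaves the
#'   RNG state untouched.
#' @return a list of class `"pipeline_config"`.
#' @export
#' @examples
#' cfg <- pipeline_config()
#' cfg$dmr_min_diff
pipeline_config <- function(mapq_min = 30L,
                            baseq_min = 17L,
                            dmr_min_diff = 0.3,
                            dmr_min_cpgs = 4L,
                            dmr_q_cutoff = 1e-4,
                            dmr_max_gap_bp = 300L,
                            smooth_window_bp = 100,
                            smooth_min_sites = 3L,
                            efdr_cutoff = 0.01,
                            n_shuffles = 20L,
                            flank_bp = 1000L,
                            n_permutations = 1e6,
                            min_cpgs_matched = 4L,
                            kmeans_k = 3L,
                            bin_size_bp = 25L,
                            alpha_bonferroni = 0.001,
                            border_tol_bp = 0L,
                            rng_seed = NULL) {
  cfg <- list(
    mapq_min = mapq_min, baseq_min = baseq_min,
    dmr_min_diff = dmr_min_diff, dmr_min_cpgs = as.integer(dmr_min_cpgs),
    dmr_q_cutoff = dmr_q_cutoff, dmr_max_gap_bp = as.integer(dmr_max_gap_bp),
    smooth_window_bp = smooth_window_bp,
    smooth_min_sites = as.integer(smooth_min_sites),
    efdr_cutoff = efdr_cutoff, n_shuffles = as.integer(n_shuffles),
    flank_bp = as.integer(flank_bp),
    n_permutations = n_permutations,
    min_cpgs_matched = as.integer(min_cpgs_matched),
    kmeans_k = as.integer(kmeans_k), bin_size_bp = as.integer(bin_size_bp),
    alpha_bonferroni = alpha_bonferroni,
    border_tol_bp = as.integer(border_tol_bp),
    rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)
  )
  with(cfg, {
    stopifnot(
      mapq_min >= 0, baseq_min >= 0,
      dmr_min_diff >= 0, dmr_min_diff <= 1,
      dmr_min_cpgs >= 1, dmr_q_cutoff > 0, dmr_q_cutoff <= 1,
      dmr_max_gap_bp > 0, smooth_window_bp > 0, smooth_min_sites >= 1,
      efdr_cutoff > 0, efdr_cutoff <= 1, n_shuffles >= 1,
      flank_bp > 0, n_permutations >= 1, min_cpgs_matched >= 0,
      kmeans_k >= 1, bin_size_bp >= 1,
      alpha_bonferroni > 0, alpha_bonferroni <= 1, border_tol_bp >= 0
    )
  })
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("methnome pipeline configuration\n")
  flat <- unlist(lapply(x, function(v) if (is.null(v)) "NULL" else format(v)))
  cat(paste0("  ", format(names(flat)), " = ", flat, collapse = "\n"), "\n")
  invisible(x)
}
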