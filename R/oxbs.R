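# 5hmC inference from paired bisulfite / oxidative-bisulfite counts.
# BS reads 5mC + 5hmC as cytosine; oxBS reads only 5mC, so the
# hydroxymethylated fraction is the (clipped) difference of the two
# proportions.

#' Estimate 5mC and 5hmC from paired BS/oxBS counts
#'
#' Per site, `fraction_5mc = oxbs_meth / oxbs_total` and `fraction_5hmc =
#' max(0, bs_meth / bs_total - fraction_5mc)`; when the raw difference is
#' negative (sampling noise) the estimate is clipped to 0 and flagged.
#' Standard errors come from the binomial delta method: the SE of a
#' difference of two independent proportions. Sites with zero total in
#' either assay are skipped (dropped rows are reported via the `skipped`
#' attribute), never estimated.
#'
#' @param pairs data.frame with columns `bs_meth`, `bs_total`, `oxbs_meth`,
#'   `oxbs_total` (plus any id columns, carried through).
#' @return the input rows with `bs_total > 0` and `oxbs_total > 0`, plus
#'   columns `fraction_5mc`, `fraction_5hmc`, `se_5mc`, `se_5hmc`,
#'   `clipped`; attribute `skipped` = number of dropped sites.
#' @export
#' @examples
#' estimate_5hmc(data.frame(bs_meth = 80, bs_total = 100,
#'                          oxbs_meth = 60, oxbs_total = 100))
estimate_5hmc <- function(pairs) {
  assert_columns(pairs, c("bs_meth", "bs_total", "oxbs_meth", "oxbs_total"),
                 "BS/oxBS pair table")
  with(pairs, {
    if (any(bs_meth < 0) || any(oxbs_meth < 0) ||
        any(bs_meth > bs_total) || any(oxbs_meth > oxbs_total)) {
      stop2("need 0 <= meth <= total in both assays")
    }
  })
  ok <- pairs$bs_total > 0 & pairs$oxbs_total > 0
  skipped <- sum(!ok)
  if (skipped) {
    message(sprintf("estimate_5hmc: skipping %d site(s) with zero coverage", skipped))
  }
  out <- pairs[ok, , drop = FALSE]
  p_bs <- out$bs_meth / out$bs_total
  p_ox <- out$oxbs_meth / out$oxbs_total
  raw <- p_bs - p_ox
  out$fraction_5mc <- p_ox
  out$fraction_5hmc <- pmax(0, raw)
  out$clipped <- raw < 0
  out$se_5mc <- sqrt(p_ox * (1 - p_ox) / out$oxbs_total)
  out$se_5hmc <- sqrt(p_bs * (1 - p_bs) / out$bs_total +
                        p_ox * (1 - p_ox) / out$oxbs_total)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Region-level 5mC/5hmC time course
#'
#' Coverage-weighted mean 5mC and 5hmC fractions per region per timepoint,
#' for differentiation time courses. Weights are the per-site mean of the
#' two assay depths. Regions without any estimated site at a timepoint get
#' `NA`.
#'
#' @param estimates output of [estimate_5hmc()] with additional columns
#'   `chrom`, `pos` (0-based) and `timepoint` (numeric, e.g. hours).
#' @param regions `GRanges` of target regions (e.g. DMR amplicons).
#' @return data.frame `region`, `timepoint`, `mean_5mc`, `mean_5hmc`,
#'   `n_sites`, ordered by region then timepoint.
#' @export
timecourse_summary <- function(estimates, regions) {
  assert_columns(estimates, c("chrom", "pos", "timepoint",
                              "fraction_5mc", "fraction_5hmc"),
                 "5hmC estimate table")
  region_names <- S4Vectors::mcols(regions)$name %||%
    paste0("region_", seq_along(regions))
  tps <- sort(unique(estimates$timepoint))
  sgr <- GenomicRanges::GRanges(estimates$chrom,
                                IRanges::IRanges(estimates$pos + 1,
                                                 estimates$pos + 1))
  hits <- GenomicRanges::findOverlaps(sgr, regions)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  grid <- expand.grid(region = region_names, timepoint = tps,
                      stringsAsFactors = FALSE)
  grid$mean_5mc <- NA_real_
  grid$mean_5hmc <- NA_real_
  grid$n_sites <- 0L
  if (length(qi)) {
    w <- (estimates$bs_total[qi] + estimates$oxbs_total[qi]) / 2
    key <- paste(si, estimates$timepoint[qi])
    wsum <- rowsum(w, key)
    m5mc <- rowsum(w * estimates$fraction_5mc[qi], key) / wsum
    m5hmc <- rowsum(w * estimates$fraction_5hmc[qi], key) / wsum
    nsite <- rowsum(rep(1L, length(qi)), key)
    parts <- strsplit(rownames(wsum), " ", fixed = TRUE)
    ri <- as.integer(vapply(parts, `[`, "", 1))
    ti <- as.numeric(vapply(parts, `[`, "", 2))
    gi <- match(paste(region_names[ri], ti), paste(grid$region, grid$timepoint))
    grid$mean_5mc[gi] <- m5mc[, 1]
    grid$mean_5hmc[gi] <- m5hmc[, 1]
    grid$n_sites[gi] <- nsite[, 1]
  }
  grid[order(match(grid$region, region_names), grid$timepoint), ]
}
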