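# Smoothing-based differential methylation calling between two groups of
# methylomes: kernel-smooth each sample, form a per-CpG t-like statistic on
# the smoothed group difference, take maximal runs of significant same-sign
# CpGs as candidates and filter them on size and mean difference.

#' Kernel-smooth per-sample methylation fractions
#'
#' For every CpG the smoothed fraction is a tricube-kernel, coverage-weighted
#' mean of the raw fractions in a window that spans at least `window_bp` and
#' contains at least `min_sites` CpGs (the window widens until it does).
#' Chromosome boundaries are never crossed. A chromosome holding fewer than
#' `min_sites` CpGs is smoothed with all of its sites and flagged.
#'
#' The default bandwidth (100 bp / 3 sites) keeps the kernel narrower than
#' the smallest regions the caller is meant to resolve (85 bp and up);
#' widen it (e.g. 2000 bp / 70 sites) for broad, CpG-sparse differences.
#'
#' @param table methylation site table (one context, e.g. HCG; all samples).
#' @param window_bp minimum full window width in bp.
#' @param min_sites minimum CpGs per window (including the centre).
#' @return object of class `smoothed_methylome`: list with `chrom`, `pos`,
#'   `samples`, matrices `raw`, `smoothed`, `cov` (sites x samples), and
#'   `flagged_chroms`.
#' @export
smooth_methylation <- function(table, window_bp = 100, min_sites = 3) {
  validate_site_table(table)
  samples <- sort(unique(table$sample_id))
  key <- paste(table$chrom, table$pos)
  sites <- unique(data.frame(chrom = table$chrom, pos = table$pos,
                             stringsAsFactors = FALSE))
  sites <- sites[order(sites$chrom, sites$pos), ]
  n <- nrow(sites)
  skey <- paste(sites$chrom, sites$pos)
  row <- match(key, skey)
  col <- match(table$sample_id, samples)
  raw <- matrix(NA_real_, n, length(samples), dimnames = list(NULL, samples))
  cov <- matrix(0, n, length(samples), dimnames = list(NULL, samples))
  cov[cbind(row, col)] <- table$total
  raw[cbind(row, col)] <- ifelse(table$total > 0, table$meth / table$total, NA)
  smoothed <- matrix(NA_real_, n, length(samples), dimnames = list(NULL, samples))
  halfw <- window_bp / 2
  flagged <- character(0)
  for (chrom in unique(sites$chrom)) {
    idx <- which(sites$chrom == chrom)
    pos <- sites$pos[idx]
    m <- length(idx)
    if (m < min_sites) flagged <- c(flagged, chrom)
    rawc <- raw[idx, , drop = FALSE]
    covc <- cov[idx, , drop = FALSE]
    rawc0 <- rawc; rawc0[is.na(rawc0)] <- 0
    # window bounds: at least halfw each side, widened symmetrically (in
    # distance) until the window holds min_sites sites
    lo <- findInterval(pos - halfw - 0.5, pos) + 1L
    hi <- findInterval(pos + halfw + 0.5, pos, left.open = TRUE)
    for (i in seq_len(m)) {
      l <- lo[i]; h <- hi[i]
      while (h - l + 1L < min_sites) {
        dl <- if (l > 1L) pos[i] - pos[l - 1L] else Inf
        dr <- if (h < m) pos[h + 1L] - pos[i] else Inf
        if (!is.finite(dl) && !is.finite(dr)) break
        if (dl <= dr) l <- l - 1L else h <- h + 1L
      }
      if (h - l + 1L >= min_sites && (l < lo[i] || h > hi[i])) {
        # the window is distance-defined: take every site within the radius
        # that the expansion reached
        dmax <- max(pos[i] - pos[l], pos[h] - pos[i])
        while (l > 1L && pos[i] - pos[l - 1L] <= dmax) l <- l - 1L
        while (h < m && pos[h + 1L] - pos[i] <= dmax) h <- h + 1L
      }
      j <- l:h
      hdist <- max(halfw, abs(pos[j] - pos[i]) + 1)
      w <- tricube((pos[j] - pos[i]) / hdist) * covc[j, , drop = FALSE]
      den <- colSums(w)
      num <- colSums(w * rawc0[j, , drop = FALSE])
      smoothed[idx[i], ] <- ifelse(den > 0, num / den, NA)
    }
  }
  structure(list(chrom = sites$chrom, pos = sites$pos, samples = samples,
                 raw = raw, smoothed = smoothed, cov = cov,
                 flagged_chroms = flagged),
            class = "smoothed_methylome")
}

#' Per-CpG signed statistic and q-value
#'
#' Computes the signed group difference of smoothed fractions at each CpG,
#' standardised by a locally pooled standard error: the across-sample
#' sampling variance of the difference is averaged over a small window of
#' neighbouring CpGs (few samples make the single-site variance estimate
#' very unstable) and the resulting SE is floored at its 75th percentile
#' across all sites, so near-zero local variance cannot inflate the
#' statistic. Two-sided p-values use the standard normal reference and are
#' Benjamini-Hochberg adjusted over all sites. With a single sample per
#' group the statistic degrades to a z-score whose scale is pooled from the
#' genome-wide background (`mad` of the differences); the result carries a
#' `pooled_background` flag in that case.
#'
#' @param smoothed a [smooth_methylation()] result.
#' @param group1,group2 sample ids of the two groups (group1 is the
#'   reference state; positive differences mean higher methylation there).
#' @param pool_sites half-width (in CpGs) of the variance-pooling window;
#'   wide pooling (default 50) removes the chi-square noise of the
#'   few-sample variance estimate so the statistic's scale is set by the
#'   local background, not by single-site fluctuations.
#' @return data.frame `chrom`, `pos`, `diff` (smoothed group1 - group2),
#'   `se`, `stat`, `p`, `q`, with attribute `pooled_background`.
#' @export
per_cpg_statistic <- function(smoothed, group1, group2, pool_sites = 50) {
  s <- smoothed
  if (!all(c(group1, group2) %in% s$samples)) {
    stop2("unknown sample id in group definition")
  }
  if (length(group1) < 1 || length(group2) < 1) {
    stop2("each group needs at least one sample")
  }
  m1 <- rowMeans(s$smoothed[, group1, drop = FALSE])
  m2 <- rowMeans(s$smoothed[, group2, drop = FALSE])
  d <- m1 - m2
  pooled <- length(group1) < 2 && length(group2) < 2
  if (!pooled) {
    v1 <- if (length(group1) >= 2) {
      apply(s$smoothed[, group1, drop = FALSE], 1, stats::var) / length(group1)
    } else 0
    v2 <- if (length(group2) >= 2) {
      apply(s$smoothed[, group2, drop = FALSE], 1, stats::var) / length(group2)
    } else 0
    v <- v1 + v2
    # pool the (chi-square-noisy) variance over neighbouring CpGs, within
    # chromosomes
    vp <- numeric(length(v))
    for (idx in split(seq_along(v), s$chrom)) {
      vp[idx] <- running_mean(v[idx], pool_sites)
    }
    se <- sqrt(vp)
    floorv <- quantile(se, 0.75, na.rm = TRUE, names = FALSE)
    denom <- pmax(se, floorv, 1e-8) # epsilon guards the all-identical case
  } else {
    se <- rep(NA_real_, length(d))
    denom <- rep(max(mad(d, center = 0), 1e-8), length(d))
  }
  stat <- d / denom
  p <- 2 * pnorm(-abs(stat))
  q <- p.adjust(p, method = "BH")
  counts <- function(group) {
    mm <- s$raw[, group, drop = FALSE] * s$cov[, group, drop = FALSE]
    mm[is.na(mm)] <- 0
    list(meth = rowSums(mm), total = rowSums(s$cov[, group, drop = FALSE]))
  }
  c1 <- counts(group1); c2 <- counts(group2)
  out <- data.frame(chrom = s$chrom, pos = s$pos, diff = d, se = se,
                    stat = stat, p = p, q = q,
                    meth1 = c1$meth, total1 = c1$total,
                    meth2 = c2$meth, total2 = c2$total,
                    stringsAsFactors = FALSE)
  attr(out, "pooled_background") <- pooled
  out
}

#' Find differentially methylated regions
#'
#' Candidates are maximal runs of same-sign CpGs with `q <= q_cutoff`, with
#' at most `max_gap_bp` between consecutive CpGs and not crossing
#' chromosomes. Run ends are trimmed where the smoothed difference falls
#' below half the reporting threshold, so smoothing shoulders do not define
#' region boundaries. A candidate is reported when it holds at least
#' `min_cpgs` CpGs and the coverage-weighted raw group methylation
#' difference over its CpGs is at least `min_diff` in absolute value (the
#' smoothed difference drives detection; the reported methylation
#' difference of the region is the actual one). The region spans the first
#' to last CpG of the run (end exclusive: last position + 1). Direction is
#' `loss` when the second group has lost methylation relative to the first
#' (positive difference), `gain` otherwise. No region-level p-value is
#' attached; the per-CpG q-values are the only significance measure.
#'
#' @param stats per-CpG statistics from [per_cpg_statistic()].
#' @param min_diff minimum |mean smoothed difference|.
#' @param min_cpgs minimum CpGs per region.
#' @param q_cutoff per-CpG q-value cutoff.
#' @param max_gap_bp maximum intra-region CpG gap.
#' @return `GRanges` with metadata `name`, `n_cpgs`, `mean_diff`,
#'   `direction`, `min_q`, `max_abs_stat`.
#' @export
find_dmrs <- function(stats, min_diff = 0.3, min_cpgs = 4, q_cutoff = 1e-4,
                      max_gap_bp = 300) {
  member <- !is.na(stats$q) & stats$q <= q_cutoff & stats$diff != 0
  empty <- GenomicRanges::GRanges()
  if (!any(member)) return(empty)
  ord <- order(stats$chrom, stats$pos)
  st <- stats[ord, ]
  member <- member[ord]
  sgn <- sign(st$diff)
  n <- nrow(st)
  newrun <- rep(TRUE, n)
  i <- 2:n
  newrun[i] <- !(member[i] & member[i - 1] &
                   st$chrom[i] == st$chrom[i - 1] &
                   sgn[i] == sgn[i - 1] &
                   (st$pos[i] - st$pos[i - 1]) <= max_gap_bp)
  runid <- cumsum(newrun)
  keep <- which(member)
  runs <- split(keep, runid[keep])
  res <- lapply(runs, function(j) {
    # trim run ends lacking site-level support: smoothing spills signal
    # onto neighbouring CpGs, so a boundary site must show both a solid
    # smoothed difference and a same-direction raw difference of its own
    dirn <- sign(st$diff[j[1]])
    ad <- abs(st$diff[j])
    rawd <- dirn * (st$meth1[j] / st$total1[j] - st$meth2[j] / st$total2[j])
    solid <- which(ad >= min_diff / 2 & !is.na(rawd) & rawd >= min_diff / 2)
    if (!length(solid)) return(NULL)
    j <- j[min(solid):max(solid)]
    if (length(j) < min_cpgs) return(NULL)
    raw_md <- sum(st$meth1[j]) / sum(st$total1[j]) -
      sum(st$meth2[j]) / sum(st$total2[j])
    if (!is.finite(raw_md) || abs(raw_md) < min_diff) return(NULL)
    data.frame(chrom = st$chrom[j[1]], start = st$pos[j[1]],
               end = st$pos[j[length(j)]] + 1L, n_cpgs = length(j),
               mean_diff = raw_md, smooth_mean_diff = mean(st$diff[j]),
               direction = if (raw_md > 0) "loss" else "gain",
               min_q = min(st$q[j]), max_abs_stat = max(abs(st$stat[j])),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res) || nrow(res) == 0) return(empty)
  as_genomic_regions(res$chrom, res$start, res$end,
                     name = paste0("dmr_", seq_len(nrow(res))),
                     n_cpgs = res$n_cpgs, mean_diff = res$mean_diff,
                     smooth_mean_diff = res$smooth_mean_diff,
                     direction = res$direction, min_q = res$min_q,
                     max_abs_stat = res$max_abs_stat)
}

#' Mean methylation of regions, per sample
#'
#' Coverage-weighted mean of site fractions within each region (sites with
#' zero coverage contribute nothing); a region with no covered CpG yields
#' `NA`, never 0.
#'
#' @param table methylation site table.
#' @param regions `GRanges`.
#' @return matrix regions x samples of mean methylated fractions.
#' @export
region_mean_methylation <- function(table, regions) {
  validate_site_table(table)
  samples <- sort(unique(table$sample_id))
  out <- matrix(NA_real_, length(regions), length(samples),
                dimnames = list(names(regions) %||% NULL, samples))
  if (!nrow(table) || !length(regions)) return(out)
  sgr <- GenomicRanges::GRanges(table$chrom,
                                IRanges::IRanges(table$pos + 1, table$pos + 1))
  hits <- GenomicRanges::findOverlaps(sgr, regions)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ok <- table$total[qi] > 0
  qi <- qi[ok]; si <- si[ok]
  if (!length(qi)) return(out)
  col <- match(table$sample_id[qi], samples)
  key <- paste(si, col)
  msum <- rowsum(as.numeric(table$meth[qi]), key)
  tsum <- rowsum(as.numeric(table$total[qi]), key)
  parts <- strsplit(rownames(msum), " ", fixed = TRUE)
  ri <- as.integer(vapply(parts, `[`, "", 1))
  ci <- as.integer(vapply(parts, `[`, "", 2))
  out[cbind(ri, ci)] <- msum[, 1] / tsum[, 1]
  out
}

#' Call DMRs between two groups of methylomes
#'
#' Orchestrates [smooth_methylation()], [per_cpg_statistic()] and
#' [find_dmrs()]. Ambiguous GCG-context CpGs are excluded up front when the
#' table carries context annotation (they confound NOMe-derived material);
#' set `exclude_gcg = FALSE` for tables known to be pure WGBS.
#'
#' @param table methylation site table covering both groups.
#' @param group1,group2 sample ids (group1 = reference state).
#' @param config a [pipeline_config()].
#' @param exclude_gcg drop GCG-context sites before calling.
#' @return `GRanges` of DMR calls (see [find_dmrs()]).
#' @export
call_dmrs <- function(table, group1, group2, config = pipeline_config(),
                      exclude_gcg = TRUE) {
  if (exclude_gcg && "context" %in% names(table)) {
    table <- table[is.na(table$context) | table$context != "GCG", ]
  }
  table <- table[table$sample_id %in% c(group1, group2), ]
  sm <- smooth_methylation(table, window_bp = config$smooth_window_bp,
                           min_sites = config$smooth_min_sites)
  st <- per_cpg_statistic(sm, group1, group2)
  find_dmrs(st, min_diff = config$dmr_min_diff,
            min_cpgs = config$dmr_min_cpgs,
            q_cutoff = config$dmr_q_cutoff,
            max_gap_bp = config$dmr_max_gap_bp)
}
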