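# NOMe-seq NDR calling: binomial-HMM segmentation of GCH methylation,
# one-sided Fisher contrast of each putative NDR against its flanking
# background, and an empirical FDR from full shuffle re-runs.

# exact one-sided hypergeometric upper tail: P(X >= a) for a 2x2 table
# [a, n1 - a; c, n2 - c], testing whether the first row is enriched
hyper_test_greater <- function(a, n1, c, n2) {
  stats::phyper(a - 1, a + c, (n1 - a) + (n2 - c), n1, lower.tail = FALSE)
}

#' Fisher's exact flank contrast for a putative NDR
#'
#' One-sided exact test of whether GCH methylation (accessibility) inside a
#' putative NDR exceeds that of its flanking background, from the 2x2 table
#' `[inside meth, inside unmeth; flank meth, flank unmeth]`. The p-value is
#' the exact hypergeometric upper tail; no continuity approximation.
#'
#' @param inside_meth,inside_total counts inside the NDR.
#' @param flank_meth,flank_total pooled counts of both flanks.
#' @return list with `p` and the 2x2 `counts` table; `p` is `NA` when either
#'   margin is empty (test undefined).
#' @export
#' @examples
#' fisher_flank_test(30, 40, 10, 80)$p # ~1e-10, strong enrichment
fisher_flank_test <- function(inside_meth, inside_total,
                              flank_meth, flank_total) {
  counts <- matrix(c(inside_meth, inside_total - inside_meth,
                     flank_meth, flank_total - flank_meth),
                   2, 2, byrow = TRUE,
                   dimnames = list(c("inside", "flank"),
                                   c("meth", "unmeth")))
  if (any(counts < 0)) stop2("negative count in Fisher table")
  if (inside_total == 0 || flank_total == 0) {
    return(list(p = NA_real_, counts = counts))
  }
  p <- hyper_test_greater(inside_meth, inside_total, flank_meth, flank_total)
  list(p = p, counts = counts)
}

#' Shuffle GCH methylation values
#'
#' Permutes the per-site (meth, total) value pairs uniformly at random
#' across GCH positions, separately within each chromosome. Positions stay
#' fixed; the marginal multiset of value pairs (and hence the coverage
#' structure) is preserved exactly while all spatial signal is destroyed.
#'
#' @param gch_table GCH methylation site table.
#' @param seed RNG seed.
#' @return the table with `meth`/`total` permuted.
#' @export
shuffle_gch <- function(gch_table, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- gch_table
  for (idx in split(seq_len(nrow(out)), out$chrom)) {
    perm <- sample(length(idx))
    out$meth[idx] <- gch_table$meth[idx][perm]
    out$total[idx] <- gch_table$total[idx][perm]
  }
  out
}

#' Empirical false-discovery rates from shuffle nulls
#'
#' For each observed p-value, the eFDR estimates the expected number of
#' null (shuffled) discoveries at that threshold per shuffle, divided by
#' the number of observed discoveries:
#' `eFDR(p) = [(1 + #null <= p) / (S + 1)] / max(1, #observed <= p)`,
#' clipped to \[0, 1\] and made monotone non-decreasing in p (each value is
#' replaced by the minimum over all larger p, step-up). The add-one in the
#' numerator is the standard finite-sample permutation correction: no call
#' can ever claim an eFDR below `1/(S+1)` times its rank, so a finite
#' shuffle null cannot be beaten by luck alone.
#'
#' @param observed_p p-values of the observed putative NDRs.
#' @param null_p pooled p-values from all shuffle re-runs.
#' @param n_shuffles number of full shuffle re-runs that produced `null_p`.
#' @return numeric vector of eFDRs aligned with `observed_p`.
#' @export
compute_efdr <- function(observed_p, null_p, n_shuffles) {
  if (n_shuffles < 1) stop2("need at least one shuffle")
  if (!length(observed_p)) return(numeric(0))
  ord <- order(observed_p)
  po <- observed_p[ord]
  pn <- sort(null_p)
  n_null_le <- findInterval(po, pn)        # counts <= with ties included
  n_obs_le <- findInterval(po, po)
  raw <- ((n_null_le + 1) / (n_shuffles + 1)) / pmax(1, n_obs_le)
  raw <- pmin(1, pmax(0, raw))
  adj <- rev(cummin(rev(raw)))             # monotone non-decreasing in p
  out <- numeric(length(po))
  out[ord] <- adj
  out
}

# flanks: min(ndr width, flank_bp) of territory on each side, clipped at
# chromosome bounds and at adjacent putative NDRs
ndr_flanks <- function(ndrs, flank_bp, chrom_bounds) {
  df <- regions_to_frame(ndrs)
  o <- order(df$chrom, df$start)
  w <- pmin(df$end - df$start, flank_bp)
  left_start <- df$start - w
  left_end <- df$start
  right_start <- df$end
  right_end <- df$end + w
  for (k in seq_along(o)) {
    i <- o[k]
    if (k > 1 && df$chrom[o[k - 1]] == df$chrom[i]) {
      left_start[i] <- max(left_start[i], df$end[o[k - 1]])
    }
    if (k < length(o) && df$chrom[o[k + 1]] == df$chrom[i]) {
      right_end[i] <- min(right_end[i], df$start[o[k + 1]])
    }
    lo <- chrom_bounds$lo[[df$chrom[i]]] %||% 0
    hi <- chrom_bounds$hi[[df$chrom[i]]] %||% Inf
    left_start[i] <- max(left_start[i], lo)
    right_end[i] <- min(right_end[i], hi)
  }
  list(left_start = left_start, left_end = pmax(left_end, left_start),
       right_start = pmin(right_start, right_end), right_end = right_end)
}

# sum GCH counts over [start, end) intervals; returns meth/total matrices
interval_counts <- function(tab, chrom, start, end) {
  meth <- total <- numeric(length(start))
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    rows <- which(tab$chrom == ch)
    pos <- tab$pos[rows]
    o <- order(pos)
    pos <- pos[o]
    cm <- cumsum(as.numeric(tab$meth[rows][o]))
    ct <- cumsum(as.numeric(tab$total[rows][o]))
    hi <- findInterval(end[sel] - 0.5, pos)
    lo <- findInterval(start[sel] - 0.5, pos)
    meth[sel] <- ifelse(hi > 0, cm[pmax(hi, 1)], 0) - ifelse(lo > 0, cm[pmax(lo, 1)], 0)
    total[sel] <- ifelse(hi > 0, ct[pmax(hi, 1)], 0) - ifelse(lo > 0, ct[pmax(lo, 1)], 0)
  }
  list(meth = meth, total = total)
}

# segment + Fisher: the core of one NDR-calling pass (shared between the
# observed data and each shuffle re-run)
segment_and_test <- function(gch_table, hmm, flank_bp) {
  seg <- segment_gch(gch_table, hmm)
  ndrs <- seg$ndrs
  if (!length(ndrs)) {
    return(list(ndrs = ndrs, p = numeric(0), dropped = 0L))
  }
  bounds <- list(lo = lapply(split(gch_table$pos, gch_table$chrom), min),
                 hi = lapply(split(gch_table$pos + 1, gch_table$chrom), max))
  df <- regions_to_frame(ndrs)
  fl <- ndr_flanks(ndrs, flank_bp, bounds)
  inside <- interval_counts(gch_table, df$chrom, df$start, df$end)
  left <- interval_counts(gch_table, df$chrom, fl$left_start, fl$left_end)
  right <- interval_counts(gch_table, df$chrom, fl$right_start, fl$right_end)
  fm <- left$meth + right$meth
  ft <- left$total + right$total
  p <- ifelse(inside$total > 0 & ft > 0,
              hyper_test_greater(inside$meth, inside$total, fm, ft),
              NA_real_)
  keep <- !is.na(p)
  mc <- S4Vectors::mcols(ndrs)
  mc$inside_meth <- inside$meth; mc$inside_total <- inside$total
  mc$flank_meth <- fm; mc$flank_total <- ft
  mc$fisher_p <- p
  S4Vectors::mcols(ndrs) <- mc
  list(ndrs = ndrs[keep], p = p[keep], dropped = sum(!keep))
}

#' Call nucleosome-depleted regions from GCH methylation
#'
#' Full NDR-calling pipeline: exclude ambiguous GCG sites, fit the two-state
#' binomial HMM ([fit_hmm()]), Viterbi-segment into putative NDRs
#' ([segment_gch()]), contrast each against its flanks with the exact
#' one-sided Fisher test, re-run segmentation and testing on `n_shuffles`
#' tables with shuffled GCH values to build the null, and keep NDRs with
#' [compute_efdr()] below the cutoff. Putative NDRs whose Fisher test is
#' undefined (no covered GCH in region or flanks) are dropped and counted in
#' the `dropped` attribute.
#'
#' @param gch_table methylation site table; rows with context other than GCH
#'   (in particular GCG) are excluded at entry when context is annotated.
#' @param config a [pipeline_config()] (uses `flank_bp`, `n_shuffles`,
#'   `efdr_cutoff`, `rng_seed`).
#' @param hmm optional pre-fitted [binomial_hmm()]; fitted from the data
#'   when `NULL`.
#' @param keep_all return all tested putative NDRs, not only those passing
#'   the eFDR gate (a `called` column marks the calls).
#' @return `GRanges` of NDR calls with metadata `n_gch`, `inside_meth`,
#'   `inside_total`, `flank_meth`, `flank_total`, `fisher_p`, `efdr`,
#'   `called`; attributes `hmm`, `dropped`, `n_putative`.
#' @export
call_ndrs <- function(gch_table, config = pipeline_config(), hmm = NULL,
                      keep_all = FALSE) {
  if ("context" %in% names(gch_table)) {
    gch_table <- gch_table[!is.na(gch_table$context) &
                             gch_table$context == "GCH", ]
  }
  if (!nrow(gch_table)) stop2("no GCH sites in input")
  if (is.null(hmm)) hmm <- fit_hmm(gch_table)
  obs <- segment_and_test(gch_table, hmm, config$flank_bp)
  null_p <- numeric(0)
  if (length(obs$p)) {
    for (s in seq_len(config$n_shuffles)) {
      sh <- shuffle_gch(gch_table, seed = derive_seed(config$rng_seed, s))
      nul <- segment_and_test(sh, hmm, config$flank_bp)
      null_p <- c(null_p, nul$p)
    }
  }
  ndrs <- obs$ndrs
  efdr <- compute_efdr(obs$p, null_p, config$n_shuffles)
  if (length(ndrs)) {
    S4Vectors::mcols(ndrs)$efdr <- efdr
    S4Vectors::mcols(ndrs)$called <- efdr < config$efdr_cutoff
  }
  out <- if (keep_all) ndrs else ndrs[S4Vectors::mcols(ndrs)$called]
  attr(out, "hmm") <- hmm
  attr(out, "dropped") <- obs$dropped
  attr(out, "n_putative") <- length(obs$ndrs) + obs$dropped
  out
}
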