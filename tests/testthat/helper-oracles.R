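# Independent oracles used across the suite. Each re-derives the quantity
# under test by brute force (enumeration, naive loops, closed forms) on a
# code path disjoint from the implementation.

# filter-and-count methylation calling, one naive loop per site
oracle_call_methylation <- function(records, mapq_min = 30, baseq_min = 17) {
  strand <- if ("strand" %in% names(records)) records$strand else rep("+", nrow(records))
  keys <- unique(data.frame(chrom = records$chrom, pos = records$pos,
                            strand = strand, sample_id = records$sample_id,
                            stringsAsFactors = FALSE))
  keys <- keys[order(keys$chrom, keys$pos, keys$strand, keys$sample_id), ]
  meth <- total <- integer(nrow(keys))
  for (i in seq_len(nrow(keys))) {
    m <- t <- 0L
    for (j in seq_len(nrow(records))) {
      if (records$chrom[j] != keys$chrom[i] || records$pos[j] != keys$pos[i] ||
          strand[j] != keys$strand[i] ||
          records$sample_id[j] != keys$sample_id[i]) next
      if (records$mapping_quality[j] < mapq_min) next
      if (records$base_quality[j] < baseq_min) next
      if (records$observed_base[j] == "C") { m <- m + 1L; t <- t + 1L }
      else if (records$observed_base[j] == "T") t <- t + 1L
    }
    meth[i] <- m; total[i] <- t
  }
  out <- cbind(keys, meth = meth, total = total)
  out <- out[total > 0, ] # sites with no passing C/T observation never appear
  rownames(out) <- NULL
  out
}

# trinucleotide scan of a single sequence, plus strand only
oracle_context_scan <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  out <- character(0)
  pos <- integer(0)
  for (i in 2:(length(chars) - 1)) {
    if (chars[i] != "C") next
    up <- chars[i - 1]; down <- chars[i + 1]
    ctx <- if (up == "G" && down == "G") "GCG"
      else if (up == "G") "GCH"
      else if (down == "G") "HCG"
      else "HCH"
    out <- c(out, ctx); pos <- c(pos, i - 1L)
  }
  data.frame(pos = pos, context = out, stringsAsFactors = FALSE)
}

# total HMM likelihood by summing over all 2^n state paths
oracle_enum_loglik <- function(hmm, meth, total) {
  n <- length(meth)
  paths <- as.matrix(expand.grid(rep(list(1:2), n)))
  probs <- apply(paths, 1, function(s) {
    p <- hmm$init[s[1]] * dbinom(meth[1], total[1], hmm$p[s[1]])
    if (n > 1) for (i in 2:n) {
      p <- p * hmm$trans[s[i - 1], s[i]] * dbinom(meth[i], total[i], hmm$p[s[i]])
    }
    p
  })
  log(sum(probs))
}

# best state path by exhaustive enumeration
oracle_enum_viterbi <- function(hmm, meth, total) {
  n <- length(meth)
  paths <- as.matrix(expand.grid(rep(list(1:2), n)))
  logp <- apply(paths, 1, function(s) {
    lp <- log(hmm$init[s[1]]) + dbinom(meth[1], total[1], hmm$p[s[1]], log = TRUE)
    if (n > 1) for (i in 2:n) {
      lp <- lp + log(hmm$trans[s[i - 1], s[i]]) +
        dbinom(meth[i], total[i], hmm$p[s[i]], log = TRUE)
    }
    lp
  })
  best <- which.max(logp)
  list(states = unname(paths[best, ]), logprob = max(logp))
}

# one-sided hypergeometric upper tail by direct log-choose summation
oracle_hyper_tail <- function(a, n1, c, n2) {
  K <- a + c; N <- n1 + n2
  ks <- a:min(n1, K)
  if (a > min(n1, K)) return(0)
  sum(exp(lchoose(K, ks) + lchoose(N - K, n1 - ks) - lchoose(N, n1)))
}

# textbook Benjamini-Hochberg: sort, scale by n/rank, cumulative minimum
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(n / (n:1) * p[o]))
  q[ro]
}

# naive O(n * window) coverage-weighted tricube smoother (one sample)
oracle_smooth <- function(pos, frac, cov, window_bp, min_sites) {
  n <- length(pos)
  out <- numeric(n)
  halfw <- window_bp / 2
  for (i in seq_len(n)) {
    h <- halfw
    while (sum(abs(pos - pos[i]) <= h) < min(min_sites, n)) h <- h + 1
    j <- which(abs(pos - pos[i]) <= h)
    hdist <- max(halfw, max(abs(pos[j] - pos[i])) + 1)
    w <- (1 - pmin(abs((pos[j] - pos[i]) / hdist), 1)^3)^3 * cov[j]
    f <- ifelse(cov[j] > 0, frac[j], 0)
    out[i] <- sum(w * f) / sum(w)
  }
  out
}

# brute-force pairwise interval overlap (0-based half-open frames)
oracle_any_overlap <- function(qdf, adf) {
  vapply(seq_len(nrow(qdf)), function(i) {
    any(adf$chrom == qdf$chrom[i] &
          adf$start < qdf$end[i] & adf$end > qdf$start[i])
  }, logical(1))
}

# independent matched-region sampler + enrichment p, written against the
# data-frame representation rather than GRanges
oracle_enrichment_p <- function(query_df, annot_df, cpg_pos, genome_len,
                                n_sims, min_cpgs = 4) {
  widths <- query_df$end - query_df$start
  observed <- mean(oracle_any_overlap(query_df, annot_df))
  exceed <- 0
  for (s in seq_len(n_sims)) {
    starts <- integer(length(widths))
    for (k in seq_along(widths)) {
      repeat {
        st <- sample.int(genome_len - widths[k] + 1, 1) - 1L
        if (sum(cpg_pos >= st & cpg_pos < st + widths[k]) >= min_cpgs) break
      }
      starts[k] <- st
    }
    sim_df <- data.frame(chrom = query_df$chrom[1], start = starts,
                         end = starts + widths)
    if (mean(oracle_any_overlap(sim_df, annot_df)) >= observed) {
      exceed <- exceed + 1
    }
  }
  exceed / n_sims
}

# merge intervals and report count/total bp, by sorting and sweeping
oracle_merge_summary <- function(df) {
  if (!nrow(df)) return(list(count = 0L, total_bp = 0L))
  o <- order(df$chrom, df$start)
  df <- df[o, ]
  count <- 0L; bp <- 0
  cur_chrom <- ""; cur_start <- cur_end <- -Inf
  for (i in seq_len(nrow(df))) {
    if (df$chrom[i] != cur_chrom || df$start[i] > cur_end) {
      if (count > 0) bp <- bp + (cur_end - cur_start)
      count <- count + 1L
      cur_chrom <- df$chrom[i]; cur_start <- df$start[i]; cur_end <- df$end[i]
    } else {
      cur_end <- max(cur_end, df$end[i])
    }
  }
  bp <- bp + (cur_end - cur_start)
  list(count = count, total_bp = bp)
}

# reciprocal overlap fraction between a call set and a truth set: how many
# truth regions are covered >= frac by a call that is itself covered >= frac
recovered_regions <- function(calls, truth, frac = 0.5) {
  if (!length(calls)) return(0L)
  hits <- GenomicRanges::findOverlaps(calls, truth, ignore.strand = TRUE)
  if (!length(hits)) return(0L)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  inter <- pmin(BiocGenerics::end(calls)[qi], BiocGenerics::end(truth)[si]) -
    pmax(BiocGenerics::start(calls)[qi], BiocGenerics::start(truth)[si]) + 1
  ok <- inter >= frac * BiocGenerics::width(calls)[qi] &
    inter >= frac * BiocGenerics::width(truth)[si]
  length(unique(si[ok]))
}
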