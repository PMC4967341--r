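make_table <- function(pos, meth, total, sample_id, chrom = "chr1") {
  data.frame(chrom = chrom, pos = pos, strand = "+", context = "HCG",
             sample_id = sample_id, meth = meth, total = total,
             stringsAsFactors = FALSE)
}

test_that("smoothing reproduces constants, single sites, and the naive oracle", {
  # constant raw fraction stays put
  tab <- make_table(seq(0, 990, by = 30), 5, 10, "s1")
  sm <- smooth_methylation(tab)
  expect_equal(unname(sm$smoothed[, 1]), rep(0.5, nrow(tab)))
  # a single site on a contig smooths to its raw value
  one <- make_table(100, 3, 10, "s1")
  expect_equal(unname(smooth_methylation(one)$smoothed[1, 1]), 0.3)
  # 200 random sites vs the brute-force weighted-mean loop
  set.seed(99)
  pos <- sort(sample(1:20000, 200))
  total <- rpois(200, 20) + 1L
  meth <- rbinom(200, total, runif(200))
  tab <- make_table(pos, meth, total, "s1")
  for (params in list(c(100, 3), c(2000, 70))) {
    sm <- smooth_methylation(tab, window_bp = params[1], min_sites = params[2])
    ref <- oracle_smooth(pos, meth / total, total, params[1], params[2])
    expect_equal(unname(sm$smoothed[, 1]), ref, tolerance = 1e-12)
  }
  # smoothed values stay inside [0, 1] and preserve site order
  expect_true(all(sm$smoothed >= 0 & sm$smoothed <= 1))
  expect_equal(sm$pos, pos)
})

test_that("per-CpG statistic vanishes for identical groups and its BH step matches the textbook oracle", {
  set.seed(3)
  pos <- sort(sample(1:50000, 400))
  total <- rpois(400, 30) + 1L
  meth <- rbinom(400, total, 0.8)
  tab <- rbind(make_table(pos, meth, total, "a1"),
               make_table(pos, meth, total, "a2"),
               make_table(pos, meth, total, "b1"),
               make_table(pos, meth, total, "b2"))
  st <- per_cpg_statistic(smooth_methylation(tab), c("a1", "a2"), c("b1", "b2"))
  expect_equal(st$stat, rep(0, 400))
  expect_equal(st$q, rep(1, 400))
  # BH adjustment agrees with sort-and-cummin on random p-values
  set.seed(4)
  p <- runif(1000)
  expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  # group errors
  expect_error(per_cpg_statistic(smooth_methylation(tab), character(0), "b1"),
               "at least one")
})

test_that("planted blocks raise the statistic and are called as single DMRs", {
  g <- simulate_genome(5e4, 0.4, seed = 41)
  dmrs6 <- plant_dmrs(g$sites, n_dmrs = 1, n_cpgs = 6, delta = 0.6, seed = 42)
  sim <- simulate_methylomes(g$sites, dmrs6, coverage = 60, donor_sd = 0, seed = 43)
  calls <- call_dmrs(sim$table, c("mono_1", "mono_2"), c("mac_1", "mac_2"))
  expect_equal(length(calls), 1L)
  expect_equal(as.character(S4Vectors::mcols(calls)$direction), "loss")
  expect_equal(recovered_regions(calls, dmrs6), 1L)
  # |statistic| is larger inside the block than outside on average
  sm <- smooth_methylation(sim$table[sim$table$context == "HCG", ])
  st <- per_cpg_statistic(sm, c("mono_1", "mono_2"), c("mac_1", "mac_2"))
  tf <- regions_to_frame(dmrs6)
  inside <- st$pos >= tf$start & st$pos < tf$end
  expect_gt(mean(abs(st$stat[inside])), mean(abs(st$stat[!inside])))
  # a 3-CpG block is below the minimum size: zero calls
  dmrs3 <- plant_dmrs(g$sites, n_dmrs = 1, n_cpgs = 3, delta = 0.6, seed = 44)
  sim3 <- simulate_methylomes(g$sites, dmrs3, coverage = 60, donor_sd = 0, seed = 45)
  calls3 <- call_dmrs(sim3$table, c("mono_1", "mono_2"), c("mac_1", "mac_2"))
  expect_equal(length(calls3), 0L)
})

test_that("DMR counts are monotone non-increasing in min_diff and min_cpgs", {
  g <- simulate_genome(1e5, 0.4, seed = 51)
  dmrs <- plant_dmrs(g$sites, n_dmrs = 8, n_cpgs = 4:12,
                     delta = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6),
                     min_separation_bp = 3000, seed = 52)
  sim <- simulate_methylomes(g$sites, dmrs, coverage = 30, seed = 53)
  sm <- smooth_methylation(sim$table[sim$table$context == "HCG", ])
  st <- per_cpg_statistic(sm, c("mono_1", "mono_2"), c("mac_1", "mac_2"))
  counts_diff <- vapply(c(0.1, 0.2, 0.3, 0.4, 0.5), function(d) {
    length(find_dmrs(st, min_diff = d))
  }, numeric(1))
  expect_true(all(diff(counts_diff) <= 0))
  counts_cpgs <- vapply(c(2, 4, 6, 10), function(k) {
    length(find_dmrs(st, min_cpgs = k))
  }, numeric(1))
  expect_true(all(diff(counts_cpgs) <= 0))
  # every emitted DMR satisfies its own invariants
  calls <- find_dmrs(st, min_diff = 0.3, min_cpgs = 4)
  if (length(calls)) {
    mc <- S4Vectors::mcols(calls)
    expect_true(all(mc$n_cpgs >= 4))
    expect_true(all(abs(mc$mean_diff) >= 0.3))
    expect_true(all(BiocGenerics::width(calls) >= 1))
  }
})

test_that("direction accounting matches the planted truth at high coverage", {
  g <- simulate_genome(2e5, 0.4, seed = 61)
  dmrs <- plant_dmrs(g$sites, n_dmrs = 10, n_cpgs = 8, delta = 0.4,
                     gain_fraction = 0.3, min_separation_bp = 4000, seed = 62)
  # mid-range baseline so gains (+0.4) stay inside [0, 1] unclipped
  sim <- simulate_methylomes(g$sites, dmrs, coverage = 200, baseline = 0.5,
                             donor_sd = 0, seed = 63)
  calls <- call_dmrs(sim$table, c("mono_1", "mono_2"), c("mac_1", "mac_2"))
  hits <- GenomicRanges::findOverlaps(calls, dmrs)
  expect_equal(length(hits), length(dmrs)) # all recovered, one call each
  got <- as.character(S4Vectors::mcols(calls)$direction[S4Vectors::queryHits(hits)])
  truth <- as.character(S4Vectors::mcols(dmrs)$direction[S4Vectors::subjectHits(hits)])
  expect_equal(got, truth)
})

test_that("region mean methylation is the coverage-weighted mean with NA for empty regions", {
  tab <- make_table(c(10, 20), c(3, 7), c(10, 10), "s1")
  regions <- as_genomic_regions("chr1", c(0, 1000), c(100, 1100))
  m <- region_mean_methylation(tab, regions)
  expect_equal(unname(m[1, "s1"]), 0.5) # (3+7)/(10+10)
  expect_true(is.na(m[2, "s1"]))
  # zero-coverage sites are excluded, not counted as zero
  tab0 <- make_table(c(10, 20), c(3, 0), c(10, 0), "s1")
  expect_equal(unname(region_mean_methylation(tab0, regions)[1, "s1"]), 0.3)
  # 50 random regions vs a brute-force per-region loop
  set.seed(71)
  pos <- sort(sample(1:30000, 300))
  total <- rpois(300, 15)
  meth <- rbinom(300, total, 0.6)
  tab <- make_table(pos, meth, total, "s1")
  starts <- sample(1:29000, 50)
  rg <- as_genomic_regions("chr1", starts, starts + sample(100:800, 50, TRUE))
  m <- region_mean_methylation(tab, rg)
  rdf <- regions_to_frame(rg)
  ref <- vapply(seq_len(50), function(i) {
    j <- which(pos >= rdf$start[i] & pos < rdf$end[i] & total > 0)
    if (!length(j)) return(NA_real_)
    sum(meth[j]) / sum(total[j])
  }, numeric(1))
  expect_equal(unname(m[, "s1"]), ref)
})
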