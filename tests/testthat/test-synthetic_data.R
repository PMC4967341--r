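test_that("genome simulation is deterministic and its catalogue matches a brute-force scan", {
  g1 <- simulate_genome(2e4, 0.5, seed = 123)
  g2 <- simulate_genome(2e4, 0.5, seed = 123)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$sites, g2$sites)
  # context counts partition the cytosines of both strands
  seq <- as.character(g1$genome)[[1]]
  chars <- strsplit(seq, "")[[1]]
  n_c <- sum(chars[2:(length(chars) - 1)] == "C")
  n_g <- sum(chars[2:(length(chars) - 1)] == "G")
  expect_equal(nrow(g1$sites), n_c + n_g)
  # plus-strand catalogue equals the independent trinucleotide scan
  plus <- g1$sites[g1$sites$strand == "+", ]
  ref <- oracle_context_scan(seq)
  expect_equal(plus$pos, ref$pos)
  expect_equal(plus$context, ref$context)
  expect_error(simulate_genome(2e4, 0), "GC")
  expect_error(simulate_genome(100, 0.5), "10 kb")
})

test_that("planted methylome deltas are recovered by empirical group means", {
  g <- simulate_genome(3e4, 0.4, seed = 5)
  dmrs <- plant_dmrs(g$sites, n_dmrs = 2, n_cpgs = 8, delta = 0.4,
                     gain_fraction = 0, min_separation_bp = 3000, seed = 6)
  sim <- simulate_methylomes(g$sites, dmrs, coverage = 1000, donor_sd = 0,
                             conversion_error = 0, seed = 7)
  tab <- sim$table
  m <- region_mean_methylation(tab, dmrs)
  mono <- rowMeans(m[, grep("mono", colnames(m)), drop = FALSE])
  mac <- rowMeans(m[, grep("mac", colnames(m)), drop = FALSE])
  expect_true(all(abs((mono - mac) - 0.4) < 0.05))
  # null genome: per-site group differences stay within 3 standard errors
  null <- simulate_methylomes(g$sites, NULL, coverage = 1000, donor_sd = 0,
                              conversion_error = 0, seed = 8)
  nt <- null$table
  agg <- function(ct) {
    s <- nt[nt$celltype == ct, ]
    rowsum(s$meth, s$pos) / rowsum(s$total, s$pos)
  }
  d <- agg("mono") - agg("mac")
  se <- sqrt(2 * 0.85 * 0.15 / 2000)
  expect_gt(mean(abs(d) < 3 * se), 0.99)
  # determinism
  again <- simulate_methylomes(g$sites, NULL, coverage = 1000, donor_sd = 0,
                               conversion_error = 0, seed = 8)
  expect_identical(null$table, again$table)
})

test_that("NOMe simulation separates open and closed GCH emission", {
  g <- simulate_genome(1e5, 0.4, seed = 9)
  ndrs <- plant_ndrs(1e5, n_ndrs = 4, width = 500, seed = 10)
  nome <- simulate_nome(g$sites, ndrs, p_open = 0.5, p_closed = 0.05,
                        coverage = 50, seed = 11)
  tab <- nome$table
  gch <- tab[tab$context == "GCH", ]
  sgr <- GenomicRanges::GRanges(gch$chrom, IRanges::IRanges(gch$pos + 1, gch$pos + 1))
  inside <- GenomicRanges::countOverlaps(sgr, ndrs) > 0
  f_in <- sum(gch$meth[inside]) / sum(gch$total[inside])
  f_out <- sum(gch$meth[!inside]) / sum(gch$total[!inside])
  expect_gt(f_in, f_out)
  expect_lt(abs(f_in - 0.5), 0.05)
  expect_lt(abs(f_out - 0.05), 0.02)
  # GCG rows flagged exactly where the genome has G-C-G
  gcg <- tab[tab$context == "GCG", ]
  expect_true(all(classify_context(g$genome, gcg$chrom, gcg$pos, gcg$strand) == "GCG"))
  # HCH rows emit near the conversion error rate
  expect_lt(hch_rate(tab), 0.02)
})

test_that("oxBS simulation obeys the BS/oxBS count laws", {
  # no 5hmC: the two assays agree within sampling error
  s0 <- simulate_oxbs(50, frac_5mc = 0.5, frac_5hmc = 0, coverage = 5000, seed = 1)
  expect_lt(abs(mean(s0$pairs$bs_meth / s0$pairs$bs_total) -
                  mean(s0$pairs$oxbs_meth / s0$pairs$oxbs_total)), 0.01)
  # 5mC 0.6 + 5hmC 0.2: BS reads ~0.8, oxBS ~0.6
  s1 <- simulate_oxbs(50, 0.6, 0.2, coverage = 10000, seed = 2)
  expect_lt(abs(mean(s1$pairs$bs_meth / s1$pairs$bs_total) - 0.8), 0.01)
  expect_lt(abs(mean(s1$pairs$oxbs_meth / s1$pairs$oxbs_total) - 0.6), 0.01)
  expect_error(simulate_oxbs(10, 0.7, 0.5), "exceed")
})

test_that("TFBS track hits the configured fraction of query regions", {
  g <- simulate_genome(2e5, 0.4, seed = 20)
  dmrs <- plant_dmrs(g$sites, n_dmrs = 10, min_separation_bp = 2000, seed = 21)
  # enrichment 1, no background: every region overlaps at least one TFBS
  t1 <- simulate_tfbs_track(dmrs, 2e5, enrichment_fraction = 1,
                            background_per_mb = 0, seed = 22)
  expect_equal(overlap_fraction(dmrs, t1), 1)
  # enrichment 0, background 0: empty track
  t0 <- simulate_tfbs_track(dmrs, 2e5, enrichment_fraction = 0,
                            background_per_mb = 0, seed = 23)
  expect_equal(length(t0), 0L)
  # Monte-Carlo mean of the overlap fraction approximates the setting
  fr <- vapply(1:50, function(s) {
    overlap_fraction(dmrs, simulate_tfbs_track(dmrs, 2e5, 0.7, 0, seed = 100 + s))
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.7), 0.06)
})

test_that("chip matrix generator reproduces its signatures and is deterministic", {
  noise0 <- simulate_chip_matrix(n_regions = 30, noise_sd = 0, seed = 31)
  # rows of the same class are identical without noise
  for (cl in unique(noise0$labels)) {
    rows <- noise0$matrix$values[noise0$labels == cl, , drop = FALSE]
    expect_equal(max(apply(rows, 2, function(x) diff(range(x)))), 0)
  }
  # H3K27ac gain (mac - mono) positive in classes 1-2, ~0 in class 3
  cm <- simulate_chip_matrix(n_regions = 120, noise_sd = 0.1, seed = 32)
  cd <- cm$matrix$coldata
  k27 <- function(ct) rowMeans(cm$matrix$values[, cd$mark == "H3K27ac" &
                                                  cd$celltype == ct &
                                                  cd$segment == "body"])
  gain <- k27("mac") - k27("mono")
  expect_gt(mean(gain[cm$labels == 1]), 1)
  expect_gt(mean(gain[cm$labels == 2]), 1)
  expect_lt(abs(mean(gain[cm$labels == 3])), 0.1)
  # determinism
  again <- simulate_chip_matrix(n_regions = 120, noise_sd = 0.1, seed = 32)
  expect_identical(cm$matrix$values, again$matrix$values)
})

test_that("simulation parameter container validates its domains", {
  p <- simulation_params()
  expect_s3_class(p, "simulation_params")
  expect_equal(p$n_samples, 2L)
  expect_error(simulation_params(ndr_p_open = 0.01, ndr_p_closed = 0.05))
  expect_error(simulation_params(gc_content = 1.2))
})
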