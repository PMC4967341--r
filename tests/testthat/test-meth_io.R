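test_that("context classification matches its definition and the exclusion rules", {
  g <- c(chr1 = "TACGTGCATGCGATCTA")
  #        0123456789...
  expect_equal(classify_context(g, "chr1", 2, "+"), "HCG")  # ACG
  expect_equal(classify_context(g, "chr1", 6, "+"), "GCH")  # GCA
  expect_equal(classify_context(g, "chr1", 10, "+"), "GCG") # GCG, flagged class
  expect_equal(classify_context(g, "chr1", 14, "+"), "HCH") # TCT
  # reverse strand: read on the complement
  g2 <- c(c1 = "ACGT")
  expect_equal(classify_context(g2, "c1", 2, "-"), "HCG") # G at 2; minus triplet ACG
  # errors
  expect_error(classify_context(g, "chr1", 0, "+"), "edge")
  expect_error(classify_context(g, "chr1", 1, "+"), "not a cytosine")
})

test_that("context classes partition all cytosines on a random sequence", {
  set.seed(42)
  seq <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE), collapse = "")
  g <- c(chrZ = seq)
  cat <- catalog_cytosines(g, strands = "+")
  ref <- oracle_context_scan(seq)
  expect_equal(cat$pos, ref$pos)
  expect_equal(cat$context, ref$context)
  # exhaustive: each C gets exactly one class
  expect_true(all(cat$context %in% c("HCG", "GCH", "GCG", "HCH")))
  n_c <- sum(strsplit(seq, "")[[1]][2:999] == "C")
  expect_equal(nrow(cat), n_c)
})

test_that("methylation calling applies strict quality filters with passing boundaries", {
  rec <- data.frame(
    chrom = "chr1", pos = 10L,
    observed_base = c("C", "T", "C"),
    mapping_quality = c(40, 40, 20),
    base_quality = c(30, 30, 30),
    sample_id = "s1", stringsAsFactors = FALSE
  )
  tab <- call_methylation(rec)
  expect_equal(tab$meth, 1L)   # third record fails mapq < 30
  expect_equal(tab$total, 2L)
  # boundary values pass: thresholds are strict "lower than"
  tab <- call_methylation(data.frame(
    chrom = "chr1", pos = 3L, observed_base = "C",
    mapping_quality = 30, base_quality = 17, sample_id = "s1"
  ))
  expect_equal(tab$meth, 1L)
  expect_equal(tab$total, 1L)
  # empty input -> empty table, no error
  expect_equal(nrow(call_methylation(rec[0, ])), 0L)
})

test_that("methylation calling equals the naive filter-and-count oracle and is order-invariant", {
  set.seed(7)
  n <- 1000
  rec <- data.frame(
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    pos = sample(1:40, n, replace = TRUE),
    observed_base = sample(c("C", "T", "A", "G"), n, replace = TRUE,
                           prob = c(0.4, 0.4, 0.1, 0.1)),
    mapping_quality = sample(0:60, n, replace = TRUE),
    base_quality = sample(0:40, n, replace = TRUE),
    sample_id = sample(c("s1", "s2"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  got <- call_methylation(rec)
  ref <- oracle_call_methylation(rec)
  expect_equal(got$meth, ref$meth)
  expect_equal(got$total, ref$total)
  expect_equal(got$pos, ref$pos)
  # permutation of the record stream changes nothing
  perm <- call_methylation(rec[sample(n), ])
  expect_equal(perm, got)
  # invariants: fractions in [0, 1], sum meth <= sum total
  expect_true(all(got$meth <= got$total))
  expect_true(sum(got$meth) <= sum(got$total))
})

test_that("methylation bedGraph round-trips losslessly and validates on read", {
  set.seed(11)
  tab <- data.frame(
    chrom = "chr1", pos = sort(sample(1:5000, 100)), strand = "+",
    context = sample(c("HCG", "GCH", "GCG", "HCH"), 100, replace = TRUE),
    sample_id = "s1",
    total = rpois(100, 20), stringsAsFactors = FALSE
  )
  tab$meth <- rbinom(100, tab$total, 0.5)
  path <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph_methylation(tab, path)
  back <- read_bedgraph_methylation(path)
  expect_equal(back[names(tab)], tab[names(tab)])
  # single row semantics
  p2 <- withr::local_tempfile()
  writeLines("chr1\t10\t11\t3\t10\tHCG", p2)
  one <- read_bedgraph_methylation(p2)
  expect_equal(one$pos, 10L)
  expect_equal(meth_fraction(one), 0.3)
  # meth > total is a validation error naming the line
  writeLines(c("chr1\t10\t11\t3\t10\tHCG", "chr1\t20\t21\t11\t10\tHCG"), p2)
  expect_error(read_bedgraph_methylation(p2), "line 2")
  writeLines("chr1\t10\t11\t3", p2)
  expect_error(read_bedgraph_methylation(p2), "fewer than 6")
})

test_that("BED I/O preserves coordinates and attributes and rejects bad intervals", {
  gr <- as_genomic_regions(rep("chr1", 114), (0:113) * 100, (0:113) * 100 + 50,
                           name = paste0("DMR", 1:114))
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(gr, path)
  back <- read_bed(path)
  expect_equal(regions_to_frame(back)[c("chrom", "start", "end", "name")],
               regions_to_frame(gr)[c("chrom", "start", "end", "name")])
  p2 <- withr::local_tempfile()
  writeLines("chr1\t0\t100\tDMR33", p2)
  one <- read_bed(p2)
  expect_equal(regions_to_frame(one),
               data.frame(chrom = "chr1", start = 0, end = 100, name = "DMR33"))
  writeLines(c("chr1\t0\t100", "chr1\t200\t150"), p2)
  expect_error(read_bed(p2), "line 2")
  expect_error(as_genomic_regions("chr1", 10, 10), "end")
  expect_error(as_genomic_regions("chr1", -1, 10), "start")
})

test_that("HCH conversion-control rate is the coverage-weighted mean", {
  tab <- data.frame(chrom = "c", pos = 1:3, strand = "+",
                    context = c("HCH", "HCH", "GCH"), sample_id = "s",
                    meth = c(1, 0, 5), total = c(10, 30, 10))
  expect_equal(hch_rate(tab), 1 / 40)
  expect_true(is.na(hch_rate(tab[3, ])))
})
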