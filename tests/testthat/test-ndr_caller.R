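gch_tab <- function(pos, meth, total, chrom = "chr1") {
  data.frame(chrom = chrom, pos = pos, strand = "+", context = "GCH",
             sample_id = "nome", meth = meth, total = total,
             stringsAsFactors = FALSE)
}

test_that("HMM constructor enforces its invariants", {
  h <- binomial_hmm(0.3, 0.02, 0.99)
  expect_equal(unname(h$p), c(0.3, 0.02))
  expect_equal(rowSums(h$trans), c(1, 1))
  expect_error(binomial_hmm(0.02, 0.3), "p_closed < p_open")
  expect_error(binomial_hmm(0.3, 0.02, trans = matrix(c(1, 1, 0, 0.5), 2)),
               "summing to 1")
})

test_that("forward likelihood and Viterbi agree with exhaustive path enumeration", {
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(2:8, 1)
    hmm <- binomial_hmm(runif(1, 0.3, 0.8), runif(1, 0.01, 0.2),
                        runif(1, 0.6, 0.99))
    total <- rpois(n, 15)
    meth <- rbinom(n, total, sample(c(0.05, 0.5), n, replace = TRUE))
    expect_equal(forward_loglik(hmm, meth, total),
                 oracle_enum_loglik(hmm, meth, total), tolerance = 1e-9)
    v <- viterbi_path(hmm, meth, total)
    ref <- oracle_enum_viterbi(hmm, meth, total)
    expect_equal(v$logprob, ref$logprob, tolerance = 1e-9)
    expect_equal(v$states, ref$states)
  }
})

test_that("posterior state probabilities sum to one at every site", {
  set.seed(18)
  hmm <- binomial_hmm(0.5, 0.05, 0.95)
  total <- rpois(500, 20)
  meth <- rbinom(500, total, 0.1)
  post <- posterior_states(hmm, meth, total)
  expect_true(all(abs(rowSums(post) - 1) < 1e-9))
})

test_that("Baum-Welch recovers planted emission probabilities with a monotone likelihood", {
  set.seed(19)
  n <- 10000
  trans <- matrix(c(0.99, 0.01, 0.01, 0.99), 2, byrow = TRUE)
  states <- integer(n); states[1] <- 2
  for (i in 2:n) states[i] <- if (runif(1) < trans[states[i - 1], states[i - 1]])
    states[i - 1] else 3 - states[i - 1]
  total <- rpois(n, 20)
  meth <- rbinom(n, total, c(0.5, 0.05)[states])
  fit <- fit_hmm(gch_tab(seq_len(n) * 30, meth, total))
  expect_lt(abs(fit$p[["open"]] - 0.5), 0.03)
  expect_lt(abs(fit$p[["closed"]] - 0.05), 0.03)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  # errors
  expect_error(fit_hmm(gch_tab(1:5, 0, 0)), "10 GCH sites")
  expect_error(fit_hmm(gch_tab(1:20, rep(0, 20), rep(0, 20))), "zero coverage")
})

test_that("homogeneous data yields no NDR calls after the full gate", {
  set.seed(20)
  n <- 2000
  total <- rpois(n, 20)
  meth <- rbinom(n, total, 0.07)
  tab <- gch_tab(sort(sample(1:1e5, n)), meth, total)
  calls <- suppressWarnings(call_ndrs(tab, pipeline_config(rng_seed = 1)))
  expect_equal(length(calls), 0L)
})

test_that("segmentation turns decoded open runs into regions spanning first to last site", {
  hmm <- binomial_hmm(0.5, 0.05, 0.9)
  pos <- c(10, 20, 30, 40, 50, 60)
  tab <- gch_tab(pos, c(0, 10, 9, 0, 0, 0), c(20, 20, 20, 20, 20, 20))
  seg <- segment_gch(tab, hmm)
  expect_equal(regions_to_frame(seg$ndrs)[c("start", "end")],
               data.frame(start = 20, end = 31))
  expect_equal(S4Vectors::mcols(seg$ndrs)$n_gch, 2)
  expect_equal(nrow(regions_to_frame(seg$background)), 2)
  # all-background decode: empty NDR set, background covers all sites
  tab0 <- gch_tab(pos, rep(0, 6), rep(20, 6))
  seg0 <- segment_gch(tab0, hmm)
  expect_equal(length(seg0$ndrs), 0L)
  expect_equal(regions_to_frame(seg0$background)[c("start", "end")],
               data.frame(start = 10, end = 61))
})

test_that("Fisher flank contrast equals the hypergeometric tail and handles edge tables", {
  r <- fisher_flank_test(30, 40, 10, 80)
  expect_equal(r$p, oracle_hyper_tail(30, 40, 10, 80), tolerance = 1e-12)
  expect_lt(r$p, 1e-6)
  expect_equal(unname(r$counts), matrix(c(30, 10, 10, 70), 2, byrow = TRUE))
  # identical rates: no one-sided enrichment
  expect_gte(fisher_flank_test(20, 40, 20, 40)$p, 0.5)
  # zero inside total: undefined
  expect_true(is.na(fisher_flank_test(0, 0, 10, 40)$p))
  expect_error(fisher_flank_test(5, 3, 1, 2), "negative")
})

test_that("GCH shuffling preserves the value multiset and the mean fraction", {
  set.seed(21)
  tab <- gch_tab(sort(sample(1:5e4, 500)), rbinom(500, 20, 0.2), 20)
  tab$total <- rpois(500, 20)
  tab$meth <- pmin(tab$meth, tab$total)
  sh1 <- shuffle_gch(tab, seed = 1)
  sh2 <- shuffle_gch(tab, seed = 2)
  pair <- function(t) sort(paste(t$meth, t$total))
  expect_equal(pair(sh1), pair(tab))
  expect_equal(pair(sh2), pair(tab))
  expect_false(identical(sh1$meth, sh2$meth))
  expect_identical(sh1$pos, tab$pos)
  expect_equal(sum(sh1$meth) / sum(sh1$total), sum(tab$meth) / sum(tab$total))
})

test_that("eFDR follows its closed form, is monotone, and is stable under shuffle duplication", {
  S <- 20
  obs <- c(1e-10, 1e-8, 1e-6, 1e-4)
  nullp <- runif(200, 0.01, 1)
  e <- compute_efdr(obs, nullp, S)
  # no null at or below any observed p: raw (1/(S+1))/rank, monotonised
  raw <- (1 / (S + 1)) / seq_along(obs)
  expect_equal(e, rev(cummin(rev(raw))))
  expect_true(all(diff(e[order(obs)]) >= 0))
  # self-null: bulk of calls get eFDR near 1
  set.seed(22)
  p <- runif(300)
  e_self <- compute_efdr(p, p, 1)
  expect_gt(mean(e_self > 0.5), 0.9)
  # duplicating every shuffle moves eFDR by at most the finite-sample term
  nullp2 <- rep(nullp, 2)
  e2 <- compute_efdr(obs, nullp2, 2 * S)
  expect_true(all(abs(e2 - e) <= 1 / (S + 1)))
  expect_error(compute_efdr(obs, nullp, 0), "at least one")
})

test_that("planted NDRs are recovered and carry small eFDRs", {
  g <- simulate_genome(3e5, 0.4, seed = 23)
  ndrs <- plant_ndrs(3e5, n_ndrs = 5, width = 500, seed = 24)
  nome <- simulate_nome(g$sites, ndrs, p_open = 0.5, p_closed = 0.05,
                        coverage = 20, seed = 25)
  cfg <- pipeline_config(rng_seed = 26)
  calls <- call_ndrs(nome$table, cfg)
  expect_gte(recovered_regions(calls, ndrs), 4L)
  expect_true(all(S4Vectors::mcols(calls)$efdr < 0.01))
  # deterministic under a fixed seed
  again <- call_ndrs(nome$table, cfg)
  expect_identical(regions_to_frame(calls), regions_to_frame(again))
})

test_that("the cell state with more planted NDRs yields more called peaks and covered bp", {
  g <- simulate_genome(4e5, 0.4, seed = 27)
  n_mono <- plant_ndrs(4e5, n_ndrs = 4, width = 400, seed = 28)
  n_mac <- plant_ndrs(4e5, n_ndrs = 12, width = 500, seed = 29)
  cfg <- pipeline_config(rng_seed = 30)
  calls_mono <- call_ndrs(simulate_nome(g$sites, n_mono, seed = 31)$table, cfg)
  calls_mac <- call_ndrs(simulate_nome(g$sites, n_mac, seed = 32)$table, cfg)
  s1 <- summarize_peaks(calls_mono); s2 <- summarize_peaks(calls_mac)
  expect_gt(s2$count, s1$count)
  expect_gt(s2$total_bp, s1$total_bp)
})

test_that("peak summaries match a brute-force merge", {
  expect_equal(summarize_peaks(GenomicRanges::GRanges()),
               list(count = 0L, total_bp = 0L))
  two <- as_genomic_regions("c", c(0, 200), c(100, 300))
  expect_equal(summarize_peaks(two), list(count = 2L, total_bp = 200L))
  set.seed(33)
  df <- data.frame(chrom = sample(c("c1", "c2"), 1000, TRUE),
                   start = sample(1:5000, 1000, TRUE))
  df$end <- df$start + sample(1:300, 1000, TRUE)
  gr <- as_genomic_regions(df$chrom, df$start, df$end)
  got <- summarize_peaks(gr)
  ref <- oracle_merge_summary(df)
  expect_equal(got$count, ref$count)
  expect_equal(as.numeric(got$total_bp), as.numeric(ref$total_bp))
})
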