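# Matched random-region permutation enrichment: are query regions (DMRs)
# overlapping an annotation (TFBS track) more often than length- and
# CpG-matched random regions? Plus the overlap classifier relating query
# regions to two peak sets (gained / lost / shared).

#' Index the CpG positions of a genome
#'
#' @param genome named `DNAStringSet` or named character vector.
#' @return list with `cpg` (per-chromosome sorted 0-based positions of the
#'   C of each CG dinucleotide) and `lengths` (chromosome lengths).
#' @export
cpg_index <- function(genome) {
  seqs <- genome_as_strings(genome)
  cpg <- lapply(seqs, function(s) {
    m <- gregexpr("CG", s, fixed = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m) - 1L
  })
  list(cpg = cpg, lengths = nchar(seqs))
}

# number of indexed CpGs in [start, start + width) -- vectorised
count_cpgs <- function(positions, start, width) {
  findInterval(start + width - 0.5, positions) -
    findInterval(start - 0.5, positions)
}

# vectorised matched sampler: one start per template length, rejection-
# resampled until each region holds >= min_cpgs CpGs
sample_matched_starts <- function(widths, index, min_cpgs, max_attempts) {
  chroms <- names(index$lengths)
  lens <- as.numeric(index$lengths)
  n <- length(widths)
  chrom_i <- if (length(chroms) == 1) rep(1L, n) else {
    sample(length(chroms), n, replace = TRUE, prob = lens)
  }
  start <- floor(runif(n) * pmax(1, lens[chrom_i] - widths + 1))
  todo <- seq_len(n)
  for (attempt in seq_len(max_attempts)) {
    ok <- rep(FALSE, length(todo))
    for (ci in unique(chrom_i[todo])) {
      sel <- todo[chrom_i[todo] == ci]
      ok[match(sel, todo)] <-
        count_cpgs(index$cpg[[ci]], start[sel], widths[sel]) >= min_cpgs
    }
    todo <- todo[!ok]
    if (!length(todo)) break
    if (attempt == max_attempts) {
      stop2("could not place a matched region of length %d with >= %d CpGs after %d attempts",
            widths[todo[1]], min_cpgs, max_attempts)
    }
    chrom_i[todo] <- if (length(chroms) == 1) 1L else {
      sample(length(chroms), length(todo), replace = TRUE, prob = lens)
    }
    start[todo] <- floor(runif(length(todo)) * pmax(1, lens[chrom_i[todo]] - widths[todo] + 1))
  }
  list(chrom = chroms[chrom_i], start = start)
}

#' Sample one random region matched to a template
#'
#' Uniform placement over the genome (chromosome chosen proportional to its
#' length, start uniform over the valid range) of an interval with exactly
#' the template's length, rejection-resampled until it contains at least
#' `min_cpgs` reference CpGs.
#'
#' @param template_width template region length in bp.
#' @param index a [cpg_index()].
#' @param min_cpgs minimum CpG count.
#' @param max_attempts resampling budget before giving up.
#' @return `GRanges` of length 1.
#' @export
sample_matched_region <- function(template_width, index, min_cpgs = 4,
                                  max_attempts = 10000) {
  s <- sample_matched_starts(template_width, index, min_cpgs, max_attempts)
  as_genomic_regions(s$chrom, s$start, s$start + template_width)
}

#' Fraction of query regions overlapping an annotation
#'
#' Fraction with at least 1 bp overlap with at least one annotation
#' interval.
#'
#' @param regions,annotation `GRanges`.
#' @return number in \[0, 1\].
#' @export
overlap_fraction <- function(regions, annotation) {
  if (!length(regions)) return(NA_real_)
  mean(GenomicRanges::countOverlaps(regions, annotation,
                                    ignore.strand = TRUE) > 0)
}

#' Enrichment result
#'
#' Container for a matched-region permutation test. The empirical p-value is
#' the plain exceedance fraction `n_exceed / n_sims` (a tie counts as an
#' exceedance): with 21 of 1,000,000 simulated sets matching or beating the
#' observed fraction, `empirical_p` is exactly 0.000021.
#'
#' @param observed_fraction observed overlap fraction.
#' @param n_exceed simulations with fraction >= observed.
#' @param n_sims number of simulations.
#' @param sim_fractions optional vector of per-simulation fractions.
#' @return list of class `enrichment_result` with `empirical_p`.
#' @export
#' @examples
#' enrichment_result(103 / 114, 21, 1e6)$empirical_p # 2.1e-05
enrichment_result <- function(observed_fraction, n_exceed, n_sims,
                              sim_fractions = NULL) {
  stopifnot(observed_fraction >= 0, observed_fraction <= 1,
            n_exceed >= 0, n_exceed <= n_sims, n_sims >= 1)
  structure(list(observed_fraction = observed_fraction,
                 n_exceed = as.numeric(n_exceed),
                 n_sims = as.numeric(n_sims),
                 empirical_p = n_exceed / n_sims,
                 sim_fractions = sim_fractions),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "matched-region permutation enrichment\n  observed fraction %.4f; %g of %g simulations >= observed\n  empirical p = %.6g\n",
    x$observed_fraction, x$n_exceed, x$n_sims, x$empirical_p))
  invisible(x)
}

#' Matched random-region permutation enrichment test
#'
#' Simulates `n_sims` region sets, each mirroring the query set's length
#' multiset (one matched region per query region, each containing at least
#' `min_cpgs` CpGs), and counts how many sets reach an overlap fraction at
#' least as high as the observed one.
#'
#' @param query query regions (`GRanges`), e.g. DMRs.
#' @param annotation annotation intervals (`GRanges`), e.g. a TFBS track.
#' @param genome genome (for the CpG index) or a precomputed [cpg_index()].
#' @param n_sims number of simulated sets.
#' @param min_cpgs minimum CpGs per matched region.
#' @param seed RNG seed.
#' @param keep_sims retain the per-simulation fractions.
#' @param max_attempts rejection-sampling budget per region.
#' @return an [enrichment_result()].
#' @export
permutation_enrichment <- function(query, annotation, genome, n_sims = 1000,
                                   min_cpgs = 4, seed = NULL,
                                   keep_sims = FALSE, max_attempts = 10000) {
  if (n_sims < 1) stop2("n_sims must be at least 1")
  if (!length(query)) stop2("empty query set")
  index <- if (is.list(genome) && !is.null(genome$cpg)) genome else cpg_index(genome)
  if (!is.null(seed)) set.seed(seed)
  observed <- overlap_fraction(query, annotation)
  widths <- BiocGenerics::width(query)
  nq <- length(widths)
  # sample all sims at once; sets are contiguous blocks of nq regions
  s <- sample_matched_starts(rep(widths, n_sims), index, min_cpgs, max_attempts)
  sim_gr <- as_genomic_regions(s$chrom, s$start,
                               s$start + rep(widths, n_sims))
  hit <- GenomicRanges::countOverlaps(sim_gr, annotation,
                                      ignore.strand = TRUE) > 0
  frac <- colMeans(matrix(hit, nrow = nq))
  n_exceed <- sum(frac >= observed)
  enrichment_result(observed, n_exceed, n_sims,
                    sim_fractions = if (keep_sims) frac else NULL)
}

#' Classify query regions by their overlap with two peak sets
#'
#' Relates each query region (e.g. a DMR) to the accessibility peaks of two
#' cell states: `none` (no overlapping peak in either state), `gained`
#' (peak only in state 2), `lost` (peak only in state 1), `shared_same`
#' (peaks in both whose borders match within `border_tol_bp` at both ends)
#' or `shared_different_borders`. The five classes partition any input.
#'
#' @param query query regions (`GRanges`).
#' @param peaks1,peaks2 peak sets of the two cell states; merged internally
#'   so each set is non-overlapping.
#' @param border_tol_bp border tolerance for `shared_same`.
#' @return factor of classes, one per query region, with a `table` of
#'   class counts as attribute `counts`.
#' @export
classify_overlap <- function(query, peaks1, peaks2, border_tol_bp = 0) {
  classes <- c("none", "gained", "lost", "shared_same",
               "shared_different_borders")
  p1 <- GenomicRanges::reduce(peaks1, ignore.strand = TRUE)
  p2 <- GenomicRanges::reduce(peaks2, ignore.strand = TRUE)
  h1 <- GenomicRanges::findOverlaps(query, p1, ignore.strand = TRUE)
  h2 <- GenomicRanges::findOverlaps(query, p2, ignore.strand = TRUE)
  in1 <- seq_along(query) %in% S4Vectors::queryHits(h1)
  in2 <- seq_along(query) %in% S4Vectors::queryHits(h2)
  res <- rep("none", length(query))
  res[!in1 & in2] <- "gained"
  res[in1 & !in2] <- "lost"
  both <- which(in1 & in2)
  for (i in both) {
    a <- p1[S4Vectors::subjectHits(h1)[S4Vectors::queryHits(h1) == i]]
    b <- p2[S4Vectors::subjectHits(h2)[S4Vectors::queryHits(h2) == i]]
    same <- FALSE
    for (j in seq_along(a)) {
      ds <- abs(BiocGenerics::start(b) - BiocGenerics::start(a)[j])
      de <- abs(BiocGenerics::end(b) - BiocGenerics::end(a)[j])
      if (any(ds <= border_tol_bp & de <= border_tol_bp)) { same <- TRUE; break }
    }
    res[i] <- if (same) "shared_same" else "shared_different_borders"
  }
  f <- factor(res, levels = classes)
  attr(f, "counts") <- table(f)
  f
}
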