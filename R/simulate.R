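# Synthetic-data generators. Every generator is a pure function of its
# arguments plus `seed`; with a fixed seed the output is bitwise
# reproducible. Defaults emulate the motivating two-cell-type study design:
# two donors per group, high baseline CpG methylation with mostly-demethylating
# DMRs (96% loss / 4% gain), Poisson coverage, symmetric bisulfite conversion
# error, and NOMe accessibility emitted at p_open inside planted NDRs.

#' Simulation parameters
#'
#' Default study conditions for the synthetic generators. Individual
#' generators take these values as arguments; this constructor documents and
#' validates them in one place.
#'
#' @param genome_length toy genome length in bp (>= 10 kb).
#' @param gc_content genome GC fraction (human-like 0.4).
#' @param n_samples donors per group.
#' @param coverage mean WGBS coverage (Poisson).
#' @param baseline_meth baseline CpG methylated fraction outside DMRs.
#' @param conversion_error symmetric bisulfite conversion error rate: a truly
#'   methylated base reads unmethylated (over-conversion) and vice versa
#'   (failed conversion) at this rate.
#' @param donor_sd per-donor baseline shift SD (set 0 to disable).
#' @param dmr_delta planted methylation difference (or range thereof).
#' @param gain_fraction fraction of planted DMRs that gain (rather than
#'   lose) methylation in the second cell type.
#' @param ndr_p_open,ndr_p_closed GCH methylation probability inside /
#'   outside planted accessible regions (`p_open > p_closed`).
#' @param nome_coverage mean NOMe-seq coverage (Poisson).
#' @param oxbs_coverage mean read depth per targeted BS/oxBS assay.
#' @return list of class `"simulation_params"`.
#' @export
simulation_params <- function(genome_length = 1e6,
                              gc_content = 0.4,
                              n_samples = 2L,
                              coverage = 30,
                              baseline_meth = 0.85,
                              conversion_error = 0.005,
                              donor_sd = 0.02,
                              dmr_delta = 0.4,
                              gain_fraction = 4 / 114,
                              ndr_p_open = 0.5,
                              ndr_p_closed = 0.05,
                              nome_coverage = 20,
                              oxbs_coverage = 2000) {
  stopifnot(
    genome_length >= 1e4, gc_content > 0, gc_content < 1,
    n_samples >= 1, coverage > 0, nome_coverage > 0, oxbs_coverage > 0,
    baseline_meth >= 0, baseline_meth <= 1,
    conversion_error >= 0, conversion_error < 0.5, donor_sd >= 0,
    all(dmr_delta >= 0), all(dmr_delta <= 1),
    gain_fraction >= 0, gain_fraction <= 1,
    ndr_p_open > ndr_p_closed, ndr_p_closed > 0, ndr_p_open < 1
  )
  structure(as.list(environment()), class = "simulation_params")
}

#' Simulate a toy genome
#'
#' I.i.d. bases at the requested GC content, plus the full cytosine catalogue
#' (every non-edge cytosine on both strands with its context class).
#'
#' @param genome_length length in bp (>= 10 kb).
#' @param gc_content GC fraction, strictly inside (0, 1).
#' @param chrom chromosome name.
#' @param seed RNG seed.
#' @return list with `genome` (named `DNAStringSet`) and `sites`
#'   (the [catalog_cytosines()] frame).
#' @export
simulate_genome <- function(genome_length = 1e6, gc_content = 0.4,
                            chrom = "chr1", seed = NULL) {
  if (gc_content <= 0 || gc_content >= 1) stop2("degenerate GC content")
  if (genome_length < 1e4) stop2("genome_length must be at least 10 kb")
  if (!is.null(seed)) set.seed(seed)
  probs <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
             G = gc_content / 2, T = (1 - gc_content) / 2)
  seq <- paste(sample(names(probs), genome_length, replace = TRUE, prob = probs),
               collapse = "")
  genome <- Biostrings::DNAStringSet(setNames(seq, chrom))
  list(genome = genome, sites = catalog_cytosines(genome))
}

# place n non-overlapping intervals of the given widths, separated by at
# least min_separation, uniformly at random on [0, genome_length)
place_regions <- function(genome_length, widths, min_separation, chrom) {
  n <- length(widths)
  slack <- genome_length - sum(widths) - (n - 1) * min_separation
  if (slack <= 0) stop2("genome too short to place %d regions", n)
  gaps <- as.vector(rmultinom(1, size = floor(slack), prob = rep(1, n + 1)))
  starts <- cumsum(c(0, widths[-n] + min_separation)) + cumsum(gaps[-(n + 1)])
  as_genomic_regions(rep(chrom, n), starts, starts + widths)
}

#' Plant differentially methylated regions on a CpG catalogue
#'
#' Picks non-overlapping blocks of consecutive plus-strand CpGs and assigns
#' each a methylation difference and a direction (loss of methylation in the
#' second cell type, or gain for a small minority). The returned regions
#' span first to last CpG of the block (end exclusive).
#'
#' @param sites cytosine catalogue from [simulate_genome()].
#' @param n_dmrs number of DMRs to plant.
#' @param n_cpgs integer vector of admissible block sizes (sampled per DMR).
#' @param delta methylation difference(s), sampled per DMR.
#' @param gain_fraction probability that a DMR gains methylation.
#' @param min_separation_bp minimum distance between planted blocks.
#' @param max_gap_bp maximum distance between consecutive CpGs inside a
#'   block: focal DMRs are locally CpG-dense (the motivating regions span
#'   85-1697 bp with four or more CpGs), and a block interrupted by a long
#'   CpG-free stretch would not be one contiguous region.
#' @param seed RNG seed.
#' @return `GRanges` with metadata `n_cpgs`, `delta`, `direction`.
#' @export
plant_dmrs <- function(sites, n_dmrs = 20, n_cpgs = 6:12, delta = 0.4,
                       gain_fraction = 4 / 114, min_separation_bp = 5000,
                       max_gap_bp = 150, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cpg <- sites[sites$strand == "+" & sites$context == "HCG", ]
  cpg <- cpg[order(cpg$chrom, cpg$pos), ]
  pick <- function(x, n) if (length(x) == 1) rep(x, n) else sample(x, n, replace = TRUE)
  sizes <- pick(n_cpgs, n_dmrs)
  deltas <- pick(delta, n_dmrs)
  dirs <- ifelse(runif(n_dmrs) < gain_fraction, "gain", "loss")
  chosen <- list()
  occupied <- integer(0) # indices of CpGs already used or too close
  for (i in seq_len(n_dmrs)) {
    ok <- FALSE
    for (attempt in 1:1000) {
      start_idx <- sample(nrow(cpg) - sizes[i], 1)
      idx <- start_idx:(start_idx + sizes[i] - 1)
      if (length(unique(cpg$chrom[idx])) > 1) next
      if (any(diff(cpg$pos[idx]) > max_gap_bp)) next
      lo <- cpg$pos[idx[1]] - min_separation_bp
      hi <- cpg$pos[idx[length(idx)]] + min_separation_bp
      clash <- any(vapply(chosen, function(r) {
        r$chrom == cpg$chrom[idx[1]] && r$lo < hi && r$hi > lo
      }, logical(1)))
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok) stop2("could not place DMR %d without overlap", i)
    chosen[[i]] <- list(chrom = cpg$chrom[idx[1]],
                        start = cpg$pos[idx[1]],
                        end = cpg$pos[idx[length(idx)]] + 1L,
                        lo = lo, hi = hi)
  }
  gr <- as_genomic_regions(
    vapply(chosen, `[[`, "", "chrom"),
    vapply(chosen, `[[`, 0, "start"),
    vapply(chosen, `[[`, 0, "end"),
    name = paste0("dmr_", seq_len(n_dmrs)),
    n_cpgs = sizes, delta = deltas, direction = dirs
  )
  sort(GenomicRanges::GRanges(gr))
}

# binomial observation with symmetric conversion error
observe_binom <- function(total, fraction, err) {
  p <- fraction * (1 - err) + (1 - fraction) * err
  rbinom(length(total), total, p)
}

#' Simulate WGBS methylomes for two cell types with planted DMRs
#'
#' Every plus-strand CpG carries the baseline methylated fraction; inside a
#' planted DMR the second cell type is shifted down (`loss`) or up (`gain`)
#' by the region's delta, clipped to \[0, 1\] with a warning if needed.
#' Observed counts are `total ~ Poisson(coverage)` and
#' `meth ~ Binomial(total, f(1-err) + (1-f)err)`. An optional per-donor
#' baseline shift (shared between that donor's two cell states) mimics
#' donor-to-donor variation.
#'
#' @param sites cytosine catalogue.
#' @param dmrs planted DMRs from [plant_dmrs()] (may be `NULL` for a null
#'   genome).
#' @param n_samples donors per cell type.
#' @param coverage mean coverage.
#' @param baseline baseline methylated fraction.
#' @param conversion_error symmetric error rate.
#' @param donor_sd per-donor shift SD.
#' @param cell_types names of the two cell states (first is the reference
#'   state, e.g. monocyte).
#' @param seed RNG seed.
#' @return list with `table` (methylation site table over all samples,
#'   contexts HCG/GCG at CpG sites) and `truth` (planted DMRs, baseline,
#'   per-donor shifts, and the per-site true fraction matrix).
#' @export
simulate_methylomes <- function(sites, dmrs = NULL, n_samples = 2,
                                coverage = 30, baseline = 0.85,
                                conversion_error = 0.005, donor_sd = 0.02,
                                cell_types = c("mono", "mac"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cpg <- sites[sites$strand == "+" & sites$context %in% c("HCG", "GCG"), ]
  cpg <- cpg[order(cpg$chrom, cpg$pos), ]
  n <- nrow(cpg)
  f1 <- rep(baseline, n)
  f2 <- rep(baseline, n)
  if (!is.null(dmrs) && length(dmrs)) {
    sgr <- GenomicRanges::GRanges(cpg$chrom, IRanges::IRanges(cpg$pos + 1, cpg$pos + 1))
    hits <- GenomicRanges::findOverlaps(sgr, dmrs)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    sign <- ifelse(S4Vectors::mcols(dmrs)$direction[si] == "loss", -1, 1)
    f2[qi] <- baseline + sign * S4Vectors::mcols(dmrs)$delta[si]
    if (any(f2 < 0 | f2 > 1)) {
      warning("planted delta pushed a fraction outside [0, 1]; clipped")
      f2 <- pmin(1, pmax(0, f2))
    }
  }
  shifts <- rnorm(n_samples, 0, donor_sd)
  tabs <- list()
  truth_frac <- matrix(NA_real_, n, 2,
                       dimnames = list(NULL, cell_types))
  truth_frac[, 1] <- f1; truth_frac[, 2] <- f2
  for (d in seq_len(n_samples)) {
    for (ct in seq_along(cell_types)) {
      f <- pmin(1, pmax(0, truth_frac[, ct] + shifts[d]))
      total <- rpois(n, coverage)
      meth <- observe_binom(total, f, conversion_error)
      tabs[[length(tabs) + 1]] <- data.frame(
        chrom = cpg$chrom, pos = cpg$pos, strand = cpg$strand,
        context = cpg$context,
        sample_id = paste0(cell_types[ct], "_", d),
        celltype = cell_types[ct], donor = d,
        meth = meth, total = total, stringsAsFactors = FALSE
      )
    }
  }
  table <- do.call(rbind, tabs)
  rownames(table) <- NULL
  list(table = table,
       truth = list(dmrs = dmrs, baseline = baseline,
                    donor_shifts = shifts, fractions = truth_frac,
                    cell_types = cell_types))
}

#' Plant nucleosome-depleted regions
#'
#' Uniformly places non-overlapping accessible intervals.
#'
#' @param genome_length genome length (bp).
#' @param n_ndrs number of regions.
#' @param width NDR width in bp (vector recycled).
#' @param min_separation_bp minimum distance between regions.
#' @param chrom chromosome name.
#' @param seed RNG seed.
#' @return `GRanges` with a `name` column.
#' @export
plant_ndrs <- function(genome_length, n_ndrs = 10, width = 500,
                       min_separation_bp = 2000, chrom = "chr1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gr <- place_regions(genome_length, rep_len(width, n_ndrs),
                      min_separation_bp, chrom)
  S4Vectors::mcols(gr)$name <- paste0("ndr_", seq_len(n_ndrs))
  gr
}

#' Simulate a NOMe-seq methylation table
#'
#' GCH sites emit methylated counts at `p_open` inside planted NDRs and
#' `p_closed` outside (exogenous GpC methyltransferase acts only on
#' accessible chromatin). GCG sites are generated the same way but flagged
#' by their context for downstream exclusion; HCH sites emit at the
#' conversion error rate and serve as conversion controls. Endogenous CpG
#' (HCG) methylation is co-generated when `cpg_baseline` is not `NULL`, so
#' DMR/NDR co-location can be planted.
#'
#' @param sites cytosine catalogue.
#' @param ndrs planted accessible regions (`GRanges`), or `NULL`.
#' @param p_open,p_closed GCH emission probabilities (open vs closed).
#' @param coverage mean coverage (Poisson).
#' @param conversion_error symmetric conversion error rate.
#' @param sample_id sample label.
#' @param cpg_baseline baseline HCG methylated fraction, or `NULL` to omit
#'   HCG rows.
#' @param cpg_dmrs optional planted DMRs applied to the HCG fractions (uses
#'   the `delta`/`direction` metadata; this sample is treated as the second
#'   cell state).
#' @param seed RNG seed.
#' @return list with `table` (contexts GCH, GCG, HCH and optionally HCG) and
#'   `truth` (`ndrs`, `p_open`, `p_closed`).
#' @export
simulate_nome <- function(sites, ndrs = NULL, p_open = 0.5, p_closed = 0.05,
                          coverage = 20, conversion_error = 0.005,
                          sample_id = "nome", cpg_baseline = NULL,
                          cpg_dmrs = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (p_open <= p_closed) stop2("p_open must exceed p_closed")
  s <- sites[order(sites$chrom, sites$pos, sites$strand), ]
  gpc <- s[s$context %in% c("GCH", "GCG"), ]
  open <- rep(FALSE, nrow(gpc))
  if (!is.null(ndrs) && length(ndrs)) {
    sgr <- GenomicRanges::GRanges(gpc$chrom, IRanges::IRanges(gpc$pos + 1, gpc$pos + 1))
    open <- GenomicRanges::countOverlaps(sgr, ndrs) > 0
  }
  frac <- ifelse(open, p_open, p_closed)
  total <- rpois(nrow(gpc), coverage)
  meth <- observe_binom(total, frac, conversion_error)
  out <- data.frame(chrom = gpc$chrom, pos = gpc$pos, strand = gpc$strand,
                    context = gpc$context, sample_id = sample_id,
                    meth = meth, total = total, stringsAsFactors = FALSE)
  hch <- s[s$context == "HCH", ]
  if (nrow(hch)) {
    total <- rpois(nrow(hch), coverage)
    meth <- observe_binom(total, 0, conversion_error)
    out <- rbind(out, data.frame(
      chrom = hch$chrom, pos = hch$pos, strand = hch$strand,
      context = hch$context, sample_id = sample_id,
      meth = meth, total = total, stringsAsFactors = FALSE
    ))
  }
  if (!is.null(cpg_baseline)) {
    hcg <- s[s$context == "HCG" & s$strand == "+", ]
    f <- rep(cpg_baseline, nrow(hcg))
    if (!is.null(cpg_dmrs) && length(cpg_dmrs)) {
      sgr <- GenomicRanges::GRanges(hcg$chrom, IRanges::IRanges(hcg$pos + 1, hcg$pos + 1))
      hits <- GenomicRanges::findOverlaps(sgr, cpg_dmrs)
      qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
      sign <- ifelse(S4Vectors::mcols(cpg_dmrs)$direction[si] == "loss", -1, 1)
      f[qi] <- pmin(1, pmax(0, cpg_baseline + sign * S4Vectors::mcols(cpg_dmrs)$delta[si]))
    }
    total <- rpois(nrow(hcg), coverage)
    meth <- observe_binom(total, f, conversion_error)
    out <- rbind(out, data.frame(
      chrom = hcg$chrom, pos = hcg$pos, strand = hcg$strand,
      context = hcg$context, sample_id = sample_id,
      meth = meth, total = total, stringsAsFactors = FALSE
    ))
  }
  out <- out[order(out$chrom, out$pos, out$strand), ]
  rownames(out) <- NULL
  list(table = out,
       truth = list(ndrs = ndrs, p_open = p_open, p_closed = p_closed))
}

#' Simulate paired BS / oxBS counts
#'
#' In bisulfite sequencing both 5mC and 5hmC read as cytosine; after
#' oxidation (oxBS) only 5mC does. Counts are drawn accordingly:
#' `bs_meth ~ Binomial(bs_total, 5mC + 5hmC)` and
#' `oxbs_meth ~ Binomial(oxbs_total, 5mC)`.
#'
#' @param n_sites number of CpG sites.
#' @param frac_5mc,frac_5hmc true fractions (recycled per site);
#'   `5mC + 5hmC <= 1` is enforced.
#' @param coverage mean depth per assay (Poisson); sites drawn with total 0
#'   are emitted as such (excluded downstream by the estimator).
#' @param seed RNG seed.
#' @return list with `pairs` (data.frame `chrom`, `pos`, `bs_meth`,
#'   `bs_total`, `oxbs_meth`, `oxbs_total`) and `truth`.
#' @export
simulate_oxbs <- function(n_sites = 10, frac_5mc = 0.6, frac_5hmc = 0.2,
                          coverage = 2000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f5mc <- rep_len(frac_5mc, n_sites)
  f5hmc <- rep_len(frac_5hmc, n_sites)
  if (any(f5mc + f5hmc > 1)) stop2("5mC + 5hmC must not exceed 1")
  bs_total <- rpois(n_sites, coverage)
  oxbs_total <- rpois(n_sites, coverage)
  pairs <- data.frame(
    chrom = "amplicon", pos = seq_len(n_sites) * 10L,
    bs_meth = rbinom(n_sites, bs_total, f5mc + f5hmc),
    bs_total = bs_total,
    oxbs_meth = rbinom(n_sites, oxbs_total, f5mc),
    oxbs_total = oxbs_total,
    stringsAsFactors = FALSE
  )
  list(pairs = pairs, truth = list(frac_5mc = f5mc, frac_5hmc = f5hmc))
}

#' Simulate a transcription-factor binding site track
#'
#' Places one short interval inside a configurable fraction of the query
#' regions (so that fraction of them contains at least one TFBS) plus
#' uniform background intervals at a genome-wide density.
#'
#' @param regions query regions (e.g. planted DMRs), `GRanges`.
#' @param genome_length genome length in bp.
#' @param enrichment_fraction fraction of regions that receive a TFBS.
#' @param background_per_mb background interval density.
#' @param tfbs_width TFBS width in bp.
#' @param chrom chromosome name.
#' @param seed RNG seed.
#' @return `GRanges` of TFBS intervals.
#' @export
simulate_tfbs_track <- function(regions, genome_length,
                                enrichment_fraction = 0.9,
                                background_per_mb = 100, tfbs_width = 150,
                                chrom = "chr1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  starts <- numeric(0)
  if (length(regions)) {
    hit <- runif(length(regions)) < enrichment_fraction
    r0 <- BiocGenerics::start(regions)[hit] - 1L
    r1 <- BiocGenerics::end(regions)[hit]
    # anchor inside the region; at least 1 bp overlap is guaranteed because
    # the TFBS starts within [start, end - 1]
    starts <- c(starts, r0 + floor(runif(sum(hit)) * pmax(1, r1 - r0 - tfbs_width + 1)))
  }
  n_bg <- rpois(1, background_per_mb * genome_length / 1e6)
  if (n_bg > 0) {
    starts <- c(starts, floor(runif(n_bg) * (genome_length - tfbs_width)))
  }
  if (!length(starts)) {
    return(GenomicRanges::GRanges())
  }
  sort(as_genomic_regions(rep(chrom, length(starts)), starts, starts + tfbs_width))
}

#' Default histone signature table
#'
#' Mean log2(ChIP/input) level per (class, mark, cell state) for the three
#' canonical chromatin signatures at differentially methylated regions:
#' class 1 gains the active-enhancer marks (H3K27ac, H3K4me1, H3K4me3) and
#' loses H3K27me3 upon differentiation; class 2 shows the same gains on a
#' constitutive H3K36me3 (transcribed) background; class 3 is constitutively
#' marked with a reduced H3K4me1 signal in the differentiated state.
#'
#' @return numeric array `[class, mark, celltype]`.
#' @export
chip_signatures <- function() {
  marks <- c("H3K27ac", "H3K4me1", "H3K4me3", "H3K36me3", "H3K27me3", "H3K9me3")
  sig <- array(0, dim = c(3, 6, 2),
               dimnames = list(class = paste0("class", 1:3), mark = marks,
                               celltype = c("mono", "mac")))
  sig[1, c("H3K27ac", "H3K4me1", "H3K4me3"), "mac"] <- c(2, 2, 1.5)
  sig[1, "H3K27me3", "mono"] <- 1.5
  sig[2, c("H3K27ac", "H3K4me1", "H3K4me3"), "mac"] <- c(2, 2, 1.5)
  sig[2, "H3K36me3", c("mono", "mac")] <- 1.5
  sig[3, c("H3K27ac", "H3K4me1", "H3K4me3"), "mono"] <- c(2, 2, 1.5)
  sig[3, c("H3K27ac", "H3K4me1", "H3K4me3"), "mac"] <- c(2, 1.2, 1.5)
  sig
}

#' Simulate a binned histone-signature signal matrix
#'
#' Draws a true signature class per region and emits binned log2(ChIP/input)
#' profiles for every (mark, cell state, replicate): the class's mean level
#' shaped over the bins (linear ramp across each flank, plateau over the
#' scaled region body) plus i.i.d. Gaussian noise.
#'
#' @param n_regions number of regions.
#' @param signatures `[class, mark, celltype]` mean array; see
#'   [chip_signatures()].
#' @param class_probs class sampling probabilities.
#' @param noise_sd Gaussian noise SD per bin.
#' @param n_reps replicates per cell state.
#' @param flank_bins,body_bins bins per flank / per scaled body.
#' @param seed RNG seed.
#' @return list with `matrix` (a `signal_matrix`: `values`, `coldata`,
#'   `regions`) and `labels` (true class per region).
#' @export
simulate_chip_matrix <- function(n_regions = 114,
                                 signatures = chip_signatures(),
                                 class_probs = c(1, 1, 1) / 3,
                                 noise_sd = 0.1, n_reps = 2,
                                 flank_bins = 40, body_bins = 40,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_class <- dim(signatures)[1]
  marks <- dimnames(signatures)$mark
  celltypes <- dimnames(signatures)$celltype
  labels <- sample(n_class, n_regions, replace = TRUE, prob = class_probs)
  shape <- c(seq(0, 1, length.out = flank_bins + 1)[-1],
             rep(1, body_bins),
             rev(seq(0, 1, length.out = flank_bins + 1)[-1]))
  nbin <- length(shape)
  coldata <- expand.grid(bin = seq_len(nbin), rep = seq_len(n_reps),
                         celltype = celltypes, mark = marks,
                         stringsAsFactors = FALSE)
  coldata$segment <- rep(c(rep("flank5", flank_bins), rep("body", body_bins),
                           rep("flank3", flank_bins)),
                         times = nrow(coldata) / nbin)
  values <- matrix(0, n_regions, nrow(coldata))
  for (j in seq_len(nrow(coldata))) {
    mu <- signatures[labels, coldata$mark[j], coldata$celltype[j]]
    values[, j] <- mu * shape[coldata$bin[j]]
  }
  values <- values + rnorm(length(values), 0, noise_sd)
  rownames(values) <- paste0("region_", seq_len(n_regions))
  mat <- structure(list(values = values, coldata = coldata,
                        regions = rownames(values)),
                   class = "signal_matrix")
  list(matrix = mat, labels = labels)
}
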