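# Histone-signature analysis at regulatory regions: binned log2(ChIP/input)
# signal matrices over region bodies (rescaled to a common width) plus
# fixed flanks, k-means clustering of the region profiles, and paired tests
# of per-cluster per-mark change between the two cell states.

#' Build a binned log2(ChIP/input) signal matrix
#'
#' For each region, the signal is read from total-count-normalised binned
#' coverage: per bin, `log2((chip/chip_total + pc) / (input/input_total +
#' pc))`. Each flank contributes `flank_bp / bin_size` unscaled bins; the
#' region body is resampled to exactly `body_bins` bins by linear
#' interpolation over its original bins (regions are thereby scaled to a
#' common length). Bins beyond a contig edge become `NA`.
#'
#' @param regions `GRanges` of query regions.
#' @param chip_bins,input_bins binned counts: data.frame `chrom`, `start`
#'   (bin start, multiple of `bin_size`), `count`, plus identical grouping
#'   columns `mark`, `celltype` and optionally `rep` in both tables.
#' @param bin_size bin width in bp.
#' @param flank_bp flank width.
#' @param body_bins number of bins the region body is rescaled to.
#' @param pseudocount added on the normalised scale.
#' @param chip_totals,input_totals optional named totals per track (names
#'   `mark|celltype|rep`); defaults to the per-track sum of provided bins.
#' @param seqlens optional named chromosome lengths for edge clipping.
#' @return a `signal_matrix`: list with `values` (regions x columns),
#'   `coldata` (`mark`, `celltype`, `rep`, `segment`, `bin`) and `regions`.
#' @export
build_signal_matrix <- function(regions, chip_bins, input_bins,
                                bin_size = 25, flank_bp = 1000,
                                body_bins = 40, pseudocount = 1e-9,
                                chip_totals = NULL, input_totals = NULL,
                                seqlens = NULL) {
  assert_columns(chip_bins, c("chrom", "start", "count"), "ChIP bin table")
  assert_columns(input_bins, c("chrom", "start", "count"), "input bin table")
  track_id <- function(df) {
    id <- df$mark %||% "signal"
    if (!is.null(df$celltype)) id <- paste(id, df$celltype, sep = "|")
    if (!is.null(df$rep)) id <- paste(id, df$rep, sep = "|")
    id
  }
  chip_bins$.track <- track_id(chip_bins)
  input_bins$.track <- track_id(input_bins)
  tracks <- sort(unique(chip_bins$.track))
  if (!setequal(tracks, unique(input_bins$.track))) {
    stop2("ChIP and input tables must cover the same tracks")
  }
  flank_bins <- as.integer(flank_bp / bin_size)
  rdf <- regions_to_frame(regions)
  n <- nrow(rdf)
  norm_lookup <- function(bins, totals) {
    sp <- split(bins, bins$.track)
    lapply(sp, function(b) {
      tot <- totals[[b$.track[1]]] %||% sum(b$count)
      if (tot <= 0) stop2("track %s has non-positive total count", b$.track[1])
      v <- b$count / tot + pseudocount
      names(v) <- paste(b$chrom, as.integer(b$start))
      v
    })
  }
  chip_lk <- norm_lookup(chip_bins, as.list(chip_totals %||% list()))
  input_lk <- norm_lookup(input_bins, as.list(input_totals %||% list()))
  grid_value <- function(lk, chrom, pos) {
    # map an arbitrary coordinate to its containing genomic bin
    key <- paste(chrom, as.integer(floor(pos / bin_size) * bin_size))
    v <- lk[key]
    v[is.na(v)] <- pseudocount # absent bin = zero count
    off <- pos < 0
    if (!is.null(seqlens)) off <- off | pos >= (seqlens[chrom] %||% Inf)
    v[off] <- NA
    unname(v)
  }
  blocks <- list()
  coldata <- list()
  for (tr in tracks) {
    block <- matrix(NA_real_, n, 2 * flank_bins + body_bins)
    for (i in seq_len(n)) {
      ch <- rdf$chrom[i]
      left <- rdf$start[i] - flank_bp + bin_size * (seq_len(flank_bins) - 1)
      right <- rdf$end[i] + bin_size * (seq_len(flank_bins) - 1)
      body_orig <- seq(rdf$start[i], rdf$end[i] - 1, by = bin_size)
      val <- function(pos) {
        log2(grid_value(chip_lk[[tr]], ch, pos) /
               grid_value(input_lk[[tr]], ch, pos))
      }
      body_v <- val(body_orig)
      body_r <- if (length(body_v) == 1) rep(body_v, body_bins) else {
        approx(seq(0, 1, length.out = length(body_v)), body_v,
               xout = seq(0, 1, length.out = body_bins))$y
      }
      block[i, ] <- c(val(left), body_r, val(right))
    }
    parts <- strsplit(tr, "|", fixed = TRUE)[[1]]
    nb <- 2 * flank_bins + body_bins
    coldata[[tr]] <- data.frame(
      mark = parts[1],
      celltype = if (length(parts) >= 2) parts[2] else NA,
      rep = if (length(parts) >= 3) parts[3] else 1,
      segment = c(rep("flank5", flank_bins), rep("body", body_bins),
                  rep("flank3", flank_bins)),
      bin = seq_len(nb), stringsAsFactors = FALSE
    )
    blocks[[tr]] <- block
  }
  values <- do.call(cbind, blocks)
  rownames(values) <- S4Vectors::mcols(regions)$name %||%
    paste0("region_", seq_len(n))
  structure(list(values = values, coldata = do.call(rbind, coldata),
                 regions = rownames(values)),
            class = "signal_matrix")
}

#' Cluster regions by their histone signatures
#'
#' k-means over the full signal matrix (all marks, cell states, replicates
#' and bins as features). Missing values are imputed as row means first.
#' Runs `nstart` restarts and keeps the best inertia; labels are
#' canonicalised by descending cluster size (ties by first occurrence) so a
#' fixed seed yields identical, comparable labels.
#'
#' @param mat a `signal_matrix` (or bare numeric matrix).
#' @param k number of clusters.
#' @param seed RNG seed for the restarts.
#' @param nstart number of random restarts.
#' @return list with `labels` (1..k per region), `centers`, `sizes`,
#'   `tot_withinss`.
#' @export
cluster_regions <- function(mat, k = 3, seed = NULL, nstart = 10) {
  values <- if (inherits(mat, "signal_matrix")) mat$values else mat
  if (k > nrow(values)) stop2("k exceeds the number of regions")
  if (anyNA(values)) {
    rm <- rowMeans(values, na.rm = TRUE)
    idx <- which(is.na(values), arr.ind = TRUE)
    values[idx] <- rm[idx[, 1]]
  }
  if (!is.null(seed)) set.seed(seed)
  distinct <- unique(values)
  if (nrow(distinct) < k) {
    # degenerate input: fewer distinct profiles than clusters; each distinct
    # profile becomes its own cluster, ranked by size
    grp <- match(data.frame(t(values)), data.frame(t(distinct)))
    sizes <- tabulate(grp, nbins = nrow(distinct))
    ord <- order(-sizes, seq_along(sizes))
    labels <- match(grp, ord)
    return(list(labels = labels,
                centers = distinct[ord, , drop = FALSE],
                sizes = sizes[ord], tot_withinss = 0))
  }
  km <- suppressWarnings(kmeans(values, centers = k, nstart = nstart,
                                iter.max = 50))
  size_order <- order(-km$size, seq_len(k))
  relabel <- match(seq_len(k), size_order)
  labels <- relabel[km$cluster]
  list(labels = labels,
       centers = km$centers[size_order, , drop = FALSE],
       sizes = km$size[size_order],
       tot_withinss = km$tot.withinss)
}

#' Per-cluster, per-mark paired change tests
#'
#' For each region the signal of a mark in one cell state is summarised as
#' the mean over that mark's bins and replicates; for every (cluster, mark)
#' pair a paired Student's t-test compares the two cell states across the
#' cluster's regions. P-values are Bonferroni-corrected over all
#' `n_clusters x n_marks` tests; a pair is significant when the adjusted p
#' is below `alpha`. Clusters with fewer than two regions are skipped and
#' flagged.
#'
#' @param mat a `signal_matrix` with exactly two cell states.
#' @param labels cluster labels from [cluster_regions()].
#' @param alpha significance level on the adjusted p-values.
#' @param celltype_order optional two cell state names; the test statistic
#'   is `second - first` (differentiation change). Defaults to the order of
#'   appearance in the matrix.
#' @return data.frame `cluster`, `mark`, `n`, `mean_change`, `t`, `p`,
#'   `p_adj`, `significant`, `skipped`.
#' @export
cluster_mark_tests <- function(mat, labels, alpha = 0.001,
                               celltype_order = NULL) {
  stopifnot(inherits(mat, "signal_matrix"))
  cd <- mat$coldata
  cts <- celltype_order %||% unique(cd$celltype)
  if (length(cts) != 2) stop2("need exactly two cell states")
  marks <- unique(cd$mark)
  clusters <- sort(unique(labels))
  n_tests <- length(clusters) * length(marks)
  res <- list()
  for (mk in marks) {
    m1 <- rowMeans(mat$values[, cd$mark == mk & cd$celltype == cts[1],
                              drop = FALSE], na.rm = TRUE)
    m2 <- rowMeans(mat$values[, cd$mark == mk & cd$celltype == cts[2],
                              drop = FALSE], na.rm = TRUE)
    change <- m2 - m1
    for (cl in clusters) {
      x <- change[labels == cl]
      if (length(x) < 2) {
        res[[length(res) + 1]] <- data.frame(
          cluster = cl, mark = mk, n = length(x),
          mean_change = mean(x), t = NA_real_, p = NA_real_,
          skipped = TRUE, stringsAsFactors = FALSE)
        next
      }
      if (sd(x) == 0) {
        # degenerate: identical paired values; no change iff all zero
        p <- if (all(x == 0)) 1 else 0
        tt <- if (all(x == 0)) 0 else Inf * sign(mean(x))
      } else {
        ht <- t.test(x)
        p <- ht$p.value
        tt <- unname(ht$statistic)
      }
      res[[length(res) + 1]] <- data.frame(
        cluster = cl, mark = mk, n = length(x), mean_change = mean(x),
        t = tt, p = p, skipped = FALSE, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  out$p_adj <- pmin(1, out$p * n_tests)
  out$significant <- !out$skipped & !is.na(out$p_adj) & out$p_adj < alpha
  rownames(out) <- NULL
  out[order(out$cluster, match(out$mark, marks)),
      c("cluster", "mark", "n", "mean_change", "t", "p", "p_adj",
        "significant", "skipped")]
}
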