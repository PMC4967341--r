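#' Construct a set of genomic regions
#'
#' Builds a `GRanges` from 0-based half-open coordinates (BED semantics),
#' validating the interval invariants (`start >= 0`, `end > start`, non-empty
#' chromosome names). Any further vectors in `...` become metadata columns.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open.
#' @param ... optional per-region attributes (name, score, ...).
#' @param seqlengths optional named vector of chromosome lengths; when given,
#'   regions must lie within bounds.
#' @return a `GRanges`.
#' @export
#' @examples
#' as_genomic_regions("chr1", 0, 100, name = "DMR33")
as_genomic_regions <- function(chrom, start, end, ..., seqlengths = NULL) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(is.na(chrom)) || any(!nzchar(chrom))) {
    stop2("chromosome names must be non-empty")
  }
  if (any(start < 0)) stop2("region start must be >= 0")
  if (any(end <= start)) stop2("region end must be greater than start")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  extras <- list(...)
  if (length(extras)) {
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(extras)
  }
  if (!is.null(seqlengths)) {
    sl <- seqlengths[as.character(GenomicRanges::seqnames(gr))]
    if (any(is.na(sl)) || any(end > sl)) {
      stop2("region extends beyond chromosome bounds")
    }
  }
  gr
}

#' Flatten regions to a 0-based half-open data frame
#'
#' Inverse of [as_genomic_regions()]: `GRanges` out, BED-style frame back.
#'
#' @param gr a `GRanges`.
#' @return data.frame with `chrom`, `start`, `end` plus metadata columns.
#' @export
regions_to_frame <- function(gr) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    stringsAsFactors = FALSE
  )
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(mc)) df <- cbind(df, mc)
  rownames(df) <- NULL
  df
}

#' Read a BED file
#'
#' Parses BED3+ (tab- or space-separated). Columns 4-6 are interpreted as
#' name, score and strand when present; any further columns are kept as
#' `extra1`, `extra2`, ... metadata. Lines starting with `track`, `browser`
#' or `#` are skipped. Coordinates are validated (`end > start`), and a
#' malformed line raises an error naming the line number.
#'
#' @param path file path.
#' @return a `GRanges` (possibly empty).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) {
    return(GenomicRanges::GRanges())
  }
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop2("BED parse error at line %d: fewer than 3 fields", lineno[which(nf < 3)[1]])
  }
  ncol_use <- min(nf)
  mat <- t(vapply(fields, function(f) f[seq_len(ncol_use)], character(ncol_use)))
  start <- suppressWarnings(as.numeric(mat[, 2]))
  end <- suppressWarnings(as.numeric(mat[, 3]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop2("BED parse error at line %d: non-numeric coordinates", lineno[bad[1]])
  }
  bad <- which(end <= start)
  if (length(bad)) {
    stop2("BED validation error at line %d: end <= start", lineno[bad[1]])
  }
  extras <- list()
  if (ncol_use >= 4) extras$name <- mat[, 4]
  if (ncol_use >= 5) extras$score <- suppressWarnings(as.numeric(mat[, 5]))
  if (ncol_use >= 7) {
    for (j in 7:ncol_use) extras[[paste0("extra", j - 6)]] <- mat[, j]
  }
  gr <- do.call(as_genomic_regions, c(list(mat[, 1], start, end), extras))
  if (ncol_use >= 6) {
    st <- mat[, 6]
    st[!st %in% c("+", "-")] <- "*"
    BiocGenerics::strand(gr) <- st
  }
  gr
}

#' Write regions as BED
#'
#' Emits BED6 plus any further metadata columns (`n_cpgs`, `mean_diff`, ...)
#' as extra tab-separated fields, 0-based half-open.
#'
#' @param gr a `GRanges`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  df <- regions_to_frame(gr)
  mcnames <- setdiff(names(df), c("chrom", "start", "end"))
  name <- if ("name" %in% mcnames) df$name else rep(".", nrow(df))
  score <- if ("score" %in% mcnames) df$score else rep(0, nrow(df))
  st <- as.character(BiocGenerics::strand(gr))
  st[st == "*"] <- "."
  out <- data.frame(df$chrom, df$start, df$end, name, score, st,
                    stringsAsFactors = FALSE)
  extra <- setdiff(mcnames, c("name", "score"))
  if (length(extra)) out <- cbind(out, df[extra])
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a genome FASTA
#'
#' @param path FASTA file path.
#' @return a named `DNAStringSet`.
#' @export
read_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write a genome FASTA
#'
#' @param genome named `DNAStringSet` or named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  if (!methods::is(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(unlist(genome))
  }
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Count and total length of a peak set
#'
#' Merges overlapping or adjacent intervals and reports how many merged
#' peaks remain and how many base pairs they cover, the summary used to
#' compare accessibility between cell states (peak count and Mbp covered).
#'
#' @param peaks a `GRanges`.
#' @return list with `count` and `total_bp`.
#' @export
#' @examples
#' gr <- as_genomic_regions(c("c", "c"), c(0, 200), c(100, 300))
#' summarize_peaks(gr) # 2 peaks, 200 bp
summarize_peaks <- function(peaks) {
  if (length(peaks) == 0) {
    return(list(count = 0L, total_bp = 0L))
  }
  merged <- GenomicRanges::reduce(peaks, ignore.strand = TRUE)
  list(count = length(merged), total_bp = sum(BiocGenerics::width(merged)))
}
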