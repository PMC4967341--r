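# Cytosine context classes. H = A, C or T.
#   HCG - endogenous CpG readout
#   GCH - chromatin accessibility readout (GpC methyltransferase target)
#   GCG - ambiguous (both CpG and GpC); flagged, excluded downstream
#   HCH - neither; bisulfite conversion control
CONTEXT_CLASSES <- c("HCG", "GCH", "GCG", "HCH")

genome_as_strings <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    s <- as.character(genome)
  } else if (is.character(genome)) {
    s <- genome
  } else {
    stop2("genome must be a DNAStringSet or a named character vector")
  }
  if (is.null(names(s)) || any(!nzchar(names(s)))) {
    stop2("genome sequences must be named by chromosome")
  }
  s
}

revcomp_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Classify the trinucleotide context of a cytosine
#'
#' Determines whether a cytosine sits in HCG, GCH, GCG or HCH context (H =
#' A/C/T) from the reference genome, reading the reverse strand on the
#' complement. GCG sites are ambiguous between endogenous CpG and enzymatic
#' GpC methylation and are flagged for exclusion by downstream consumers.
#'
#' @param genome named `DNAStringSet` or named character vector.
#' @param chrom chromosome name(s), recycled against `pos`.
#' @param pos 0-based position(s) of the cytosine.
#' @param strand `"+"` or `"-"`, recycled.
#' @return character vector of context classes.
#' @export
#' @examples
#' g <- c(chr1 = "AACGTGCAT")
#' classify_context(g, "chr1", 2, "+") # the C in ACG -> HCG
classify_context <- function(genome, chrom, pos, strand = "+") {
  seqs <- genome_as_strings(genome)
  n <- max(length(chrom), length(pos), length(strand))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.numeric(pos), n)
  strand <- rep_len(as.character(strand), n)
  if (!all(chrom %in% names(seqs))) {
    stop2("unknown chromosome: %s",
          paste(unique(setdiff(chrom, names(seqs))), collapse = ", "))
  }
  lens <- nchar(seqs)[chrom]
  if (any(pos < 0 | pos >= lens)) stop2("position outside chromosome")
  if (any(pos == 0 | pos == lens - 1)) {
    stop2("position at contig edge: context requires both neighbouring bases")
  }
  # 0-based [pos-1, pos+1] is 1-based substring(pos, pos+2)
  tri <- toupper(substring(seqs[chrom], pos, pos + 2))
  minus <- strand == "-"
  if (any(minus)) tri[minus] <- revcomp_chr(tri[minus])
  centre <- substring(tri, 2, 2)
  if (any(centre != "C")) {
    stop2("context undefined: position %s is not a cytosine on strand %s",
          pos[centre != "C"][1], strand[centre != "C"][1])
  }
  up <- substring(tri, 1, 1)
  down <- substring(tri, 3, 3)
  ctx <- ifelse(up == "G",
                ifelse(down == "G", "GCG", "GCH"),
                ifelse(down == "G", "HCG", "HCH"))
  unname(ctx)
}

#' Catalogue every cytosine in a genome with its context
#'
#' Scans both strands (reverse-strand cytosines are Gs on the reference) and
#' classifies each non-edge cytosine into one of the four context classes.
#' Cytosines at contig edges lack a neighbour and are omitted.
#'
#' @param genome named `DNAStringSet` or named character vector.
#' @param strands strands to scan, default both.
#' @return data.frame `chrom`, `pos` (0-based), `strand`, `context`, sorted
#'   by position.
#' @export
catalog_cytosines <- function(genome, strands = c("+", "-")) {
  seqs <- genome_as_strings(genome)
  out <- list()
  for (chrom in names(seqs)) {
    chars <- strsplit(toupper(seqs[[chrom]]), "")[[1]]
    L <- length(chars)
    if (L < 3) next
    for (st in strands) {
      base <- if (st == "+") "C" else "G"
      p <- which(chars == base)          # 1-based
      p <- p[p > 1 & p < L]              # drop edges
      if (!length(p)) next
      if (st == "+") {
        up <- chars[p - 1]; down <- chars[p + 1]
      } else {
        # on the minus strand the preceding base is the complement of the
        # reference base downstream, and vice versa
        up <- chartr("ACGT", "TGCA", chars[p + 1])
        down <- chartr("ACGT", "TGCA", chars[p - 1])
      }
      ctx <- ifelse(up == "G",
                    ifelse(down == "G", "GCG", "GCH"),
                    ifelse(down == "G", "HCG", "HCH"))
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom, pos = p - 1L, strand = st, context = ctx,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), context = character()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$pos, res$strand), ]
  rownames(res) <- NULL
  res
}

#' Call methylation from per-base read records
#'
#' Aggregates a stream of aligned read-base observations into per-site
#' methylation counts. A record contributes only if its mapping quality and
#' base quality are at or above the configured minima (records with
#' `mapq < mapq_min` or `baseq < baseq_min` are excluded; the boundary
#' values pass) and its observed base is C (methylated, bisulfite-protected)
#' or T (unmethylated, converted). Other bases never count.
#'
#' @param records data.frame with columns `chrom`, `pos` (0-based),
#'   `observed_base`, `mapping_quality`, `base_quality`, `sample_id` and
#'   optionally `strand` (defaults to `"+"`).
#' @param config a [pipeline_config()].
#' @param genome optional genome; when supplied, each site is annotated with
#'   its [classify_context()] class.
#' @param collapse_strands if `TRUE`, minus-strand CpG observations are
#'   folded onto the plus-strand position of the same CpG (position - 1).
#'   Off by default.
#' @return a methylation site table: data.frame with `chrom`, `pos`,
#'   `strand`, `context` (NA when no genome given), `sample_id`, `meth`,
#'   `total`.
#' @export
call_methylation <- function(records, config = pipeline_config(),
                             genome = NULL, collapse_strands = FALSE) {
  empty <- data.frame(chrom = character(), pos = integer(),
                      strand = character(), context = character(),
                      sample_id = character(), meth = integer(),
                      total = integer(), stringsAsFactors = FALSE)
  if (nrow(records) == 0) return(empty)
  assert_columns(records, c("chrom", "pos", "observed_base",
                            "mapping_quality", "base_quality", "sample_id"),
                 "read record table")
  if (any(records$mapping_quality < 0) || any(records$base_quality < 0)) {
    stop2("qualities must be non-negative")
  }
  strand <- if ("strand" %in% names(records)) records$strand else rep("+", nrow(records))
  keep <- records$mapping_quality >= config$mapq_min &
    records$base_quality >= config$baseq_min &
    records$observed_base %in% c("C", "T")
  r <- records[keep, , drop = FALSE]
  strand <- strand[keep]
  if (nrow(r) == 0) return(empty)
  pos <- r$pos
  if (collapse_strands) {
    pos <- ifelse(strand == "-", pos - 1L, pos)
    strand <- rep("+", length(pos))
  }
  key <- paste(r$chrom, pos, strand, r$sample_id, sep = "\r")
  meth <- rowsum((r$observed_base == "C") + 0L, key)
  total <- rowsum(rep(1L, nrow(r)), key)
  parts <- strsplit(rownames(meth), "\r", fixed = TRUE)
  tab <- data.frame(
    chrom = vapply(parts, `[`, "", 1),
    pos = as.integer(vapply(parts, `[`, "", 2)),
    strand = vapply(parts, `[`, "", 3),
    sample_id = vapply(parts, `[`, "", 4),
    meth = as.integer(meth[, 1]),
    total = as.integer(total[, 1]),
    stringsAsFactors = FALSE
  )
  tab$context <- if (!is.null(genome)) {
    classify_context(genome, tab$chrom, tab$pos, tab$strand)
  } else {
    NA_character_
  }
  tab <- tab[order(tab$chrom, tab$pos, tab$strand, tab$sample_id),
             c("chrom", "pos", "strand", "context", "sample_id", "meth", "total")]
  rownames(tab) <- NULL
  validate_site_table(tab)
}

#' Validate a methylation site table
#'
#' Checks the invariants every consumer relies on: `0 <= meth <= total`,
#' contexts (when present) within the four classes, and uniqueness of
#' `(chrom, pos, strand, sample_id)`.
#'
#' @param table methylation site table.
#' @return the table, invisibly validated (returned unchanged).
#' @export
validate_site_table <- function(table) {
  assert_columns(table, c("chrom", "pos", "strand", "sample_id", "meth", "total"),
                 "methylation site table")
  if (any(table$meth < 0) || any(table$total < 0) ||
      any(table$meth > table$total)) {
    stop2("site table validation error: need 0 <= meth <= total")
  }
  ctx <- table$context
  if (!is.null(ctx) && any(!is.na(ctx) & !ctx %in% CONTEXT_CLASSES)) {
    stop2("site table validation error: unknown context class")
  }
  key <- paste(table$chrom, table$pos, table$strand, table$sample_id)
  if (anyDuplicated(key)) {
    stop2("site table validation error: duplicated (chrom, pos, strand, sample)")
  }
  table
}

#' Methylated fraction of each site
#'
#' `meth / total`; `NA` where `total` is 0.
#'
#' @param table methylation site table.
#' @return numeric vector.
#' @export
meth_fraction <- function(table) {
  ifelse(table$total > 0, table$meth / table$total, NA_real_)
}

#' Read / write bedGraph-like methylation tables
#'
#' The interchange format is a headerless TSV with columns `chrom`, `start`,
#' `end` (= start + 1), `meth`, `total`, `context` and optionally
#' `sample_id`; 0-based half-open, one cytosine per row. The round trip
#' through [write_bedgraph_methylation()] and back is lossless.
#'
#' @param path file path.
#' @return [read_bedgraph_methylation()]: a methylation site table (strand
#'   is set to `"+"`; bedGraph rows are strandless).
#' @export
read_bedgraph_methylation <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !grepl("^(track|#)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) {
    return(validate_site_table(data.frame(
      chrom = character(), pos = integer(), strand = character(),
      context = character(), sample_id = character(),
      meth = integer(), total = integer(), stringsAsFactors = FALSE
    )))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6)) {
    stop2("methylation bedGraph parse error at line %d: fewer than 6 fields",
          lineno[which(nf < 6)[1]])
  }
  get <- function(k) vapply(fields, `[`, "", k)
  num <- function(k, label) {
    v <- suppressWarnings(as.numeric(get(k)))
    if (anyNA(v)) {
      stop2("methylation bedGraph parse error at line %d: non-numeric %s",
            lineno[which(is.na(v))[1]], label)
    }
    v
  }
  start <- num(2, "start"); end <- num(3, "end")
  meth <- num(4, "meth"); total <- num(5, "total")
  bad <- which(end != start + 1)
  if (length(bad)) {
    stop2("methylation bedGraph validation error at line %d: end != start + 1",
          lineno[bad[1]])
  }
  bad <- which(meth > total | meth < 0)
  if (length(bad)) {
    stop2("methylation bedGraph validation error at line %d: need 0 <= meth <= total",
          lineno[bad[1]])
  }
  ctx <- get(6)
  bad <- which(!ctx %in% CONTEXT_CLASSES)
  if (length(bad)) {
    stop2("methylation bedGraph validation error at line %d: unknown context '%s'",
          lineno[bad[1]], ctx[bad[1]])
  }
  tab <- data.frame(
    chrom = get(1), pos = as.integer(start), strand = "+", context = ctx,
    sample_id = if (max(nf) >= 7) get(7) else "sample",
    meth = as.integer(meth), total = as.integer(total),
    stringsAsFactors = FALSE
  )
  validate_site_table(tab)
}

#' @param table methylation site table to write.
#' @param include_sample write the `sample_id` column (7th field).
#' @rdname read_bedgraph_methylation
#' @export
write_bedgraph_methylation <- function(table, path, include_sample = TRUE) {
  validate_site_table(table)
  out <- data.frame(table$chrom, table$pos, table$pos + 1L,
                    table$meth, table$total, table$context,
                    stringsAsFactors = FALSE)
  if (include_sample) out <- cbind(out, table$sample_id)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Bisulfite conversion control rate
#'
#' Coverage-weighted mean methylated fraction over HCH sites. HCH cytosines
#' are targeted neither by endogenous CpG methylation nor by the GpC
#' methyltransferase, so any signal here estimates the bisulfite
#' non-conversion rate.
#'
#' @param table methylation site table containing HCH rows.
#' @return a single number in \[0, 1\] (`NA` when no covered HCH site).
#' @export
hch_rate <- function(table) {
  h <- table[!is.na(table$context) & table$context == "HCH" & table$total > 0, ]
  if (!nrow(h)) return(NA_real_)
  sum(h$meth) / sum(h$total)
}
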