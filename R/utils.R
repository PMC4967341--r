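`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tricube kernel
#'
#' `(1 - min(|u|, 1)^3)^3`, the weight function used by the methylation
#' smoother.
#'
#' @param u numeric vector of scaled distances.
#' @return numeric vector of weights in \[0, 1\].
#' @keywords internal
tricube <- function(u) {
  (1 - pmin(abs(u), 1)^3)^3
}

#' Adjusted Rand index between two labelings
#'
#' Hubert-Arabie adjusted Rand index, used to score cluster recovery against
#' planted class labels. 1 means identical partitions up to relabeling; 0 is
#' the chance expectation.
#'
#' @param a,b vectors of cluster labels of equal length.
#' @return a single number, at most 1.
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)) # 1
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- ai * bj / n2
  maxi <- (ai + bj) / 2
  if (maxi == expected) return(1) # both partitions trivial
  (nij - expected) / (maxi - expected)
}

# centred running mean with half-width k sites, NA-tolerant
running_mean <- function(x, k) {
  n <- length(x)
  ok <- !is.na(x)
  cs <- cumsum(c(0, ifelse(ok, x, 0)))
  cn <- cumsum(c(0, as.numeric(ok)))
  lo <- pmax(seq_len(n) - k, 1)
  hi <- pmin(seq_len(n) + k, n)
  cnt <- cn[hi + 1] - cn[lo]
  out <- (cs[hi + 1] - cs[lo]) / cnt
  out[cnt == 0] <- NA_real_
  out
}

# stop() with a consistent prefix-free message built via sprintf
stop2 <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop2("%s is missing required column(s): %s", what,
          paste(miss, collapse = ", "))
  }
  invisible(df)
}

# seeds derived from one user seed for independent stages; keeps every draw
# reproducible from a single integer while avoiding stream reuse
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 69069 + as.numeric(k) * 1013) %% 2147483399)
}
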