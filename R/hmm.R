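# Two-state binomial hidden Markov model over per-site (meth, total) GCH
# counts. State 1 is the accessible (NDR) state with the higher emission
# probability; state 2 is background. Fitting is Baum-Welch with a
# deterministic initialisation; decoding is Viterbi.

#' Construct a two-state binomial HMM
#'
#' @param p_open,p_closed binomial success probabilities of the accessible
#'   and background state (`0 < p_closed < p_open < 1`).
#' @param self_transition probability of staying in the current state, or a
#'   full 2x2 matrix via `trans`.
#' @param trans optional 2x2 transition matrix (rows: from open/closed),
#'   overriding `self_transition`.
#' @param init initial state distribution `(open, closed)`.
#' @return list of class `binomial_hmm`.
#' @export
binomial_hmm <- function(p_open = 0.3, p_closed = 0.02,
                         self_transition = 0.99, trans = NULL,
                         init = c(0.5, 0.5)) {
  if (is.null(trans)) {
    trans <- matrix(c(self_transition, 1 - self_transition,
                      1 - self_transition, self_transition),
                    2, 2, byrow = TRUE)
  }
  hmm <- structure(list(p = c(open = p_open, closed = p_closed),
                        trans = trans, init = init / sum(init)),
                   class = "binomial_hmm")
  validate_hmm(hmm)
}

validate_hmm <- function(hmm) {
  p <- hmm$p
  if (!(p[2] > 0 && p[2] < p[1] && p[1] < 1)) {
    stop2("need 0 < p_closed < p_open < 1")
  }
  if (any(hmm$trans < 0) || any(abs(rowSums(hmm$trans) - 1) > 1e-8)) {
    stop2("transition rows must be probabilities summing to 1")
  }
  if (abs(sum(hmm$init) - 1) > 1e-8 || any(hmm$init < 0)) {
    stop2("initial distribution must sum to 1")
  }
  hmm
}

#' @export
print.binomial_hmm <- function(x, ...) {
  cat("two-state binomial HMM\n")
  cat(sprintf("  p_open = %.4f, p_closed = %.4f\n", x$p[1], x$p[2]))
  cat(sprintf("  self-transitions: open %.4f, closed %.4f\n",
              x$trans[1, 1], x$trans[2, 2]))
  if (!is.null(x$loglik)) {
    cat(sprintf("  fitted: loglik %.3f after %d iterations (%s)\n",
                x$loglik, x$n_iter,
                if (isTRUE(x$converged)) "converged" else "max_iter reached"))
  }
  invisible(x)
}

# split a GCH table into per-chromosome (meth, total) sequences, sorted
gch_sequences <- function(gch_table) {
  tab <- gch_table[order(gch_table$chrom, gch_table$pos), ]
  lapply(split(seq_len(nrow(tab)), tab$chrom), function(i) {
    list(chrom = tab$chrom[i[1]], pos = tab$pos[i],
         meth = as.integer(tab$meth[i]), total = as.integer(tab$total[i]))
  })
}

#' Log-likelihood of a count sequence under a binomial HMM
#'
#' Forward-algorithm marginal likelihood (summed over all state paths).
#'
#' @param hmm a [binomial_hmm()].
#' @param meth,total integer count vectors.
#' @return log-likelihood.
#' @export
forward_loglik <- function(hmm, meth, total) {
  fb <- .bhmm_forward_backward(as.integer(meth), as.integer(total),
                               hmm$p, hmm$trans, hmm$init)
  fb$loglik
}

#' Posterior state probabilities
#'
#' @inheritParams forward_loglik
#' @return matrix sites x 2 (open, closed) of posterior probabilities; rows
#'   sum to 1.
#' @export
posterior_states <- function(hmm, meth, total) {
  fb <- .bhmm_forward_backward(as.integer(meth), as.integer(total),
                               hmm$p, hmm$trans, hmm$init)
  colnames(fb$gamma) <- c("open", "closed")
  fb$gamma
}

#' Viterbi state path
#'
#' @inheritParams forward_loglik
#' @return list with `states` (1 = open/NDR, 2 = closed/background) and
#'   `logprob` of the best path.
#' @export
viterbi_path <- function(hmm, meth, total) {
  v <- .bhmm_viterbi(as.integer(meth), as.integer(total),
                     hmm$p, hmm$trans, hmm$init)
  list(states = v$states + 1L, logprob = v$logprob)
}

#' Fit a two-state binomial HMM by Baum-Welch
#'
#' Expectation-maximisation on per-site (meth, total) counts, pooled across
#' chromosomes. The log-likelihood is monotone non-decreasing across
#' iterations (checked; a decrease beyond numerical tolerance is an internal
#' error). Iteration stops after `max_iter` rounds or when the
#' log-likelihood improves by less than `tol`. The returned states are
#' canonicalised so that `p_open > p_closed`. Initialisation is
#' deterministic for reproducibility (`init` argument); supply different
#' starting points for restarts.
#'
#' @param gch_table methylation site table restricted to GCH context (GCG
#'   must already be excluded), >= 10 sites.
#' @param init starting model, a [binomial_hmm()].
#' @param max_iter maximum EM iterations.
#' @param tol log-likelihood convergence tolerance.
#' @return a fitted `binomial_hmm` with elements `loglik`, `loglik_trace`,
#'   `n_iter`, `converged`.
#' @export
fit_hmm <- function(gch_table, init = binomial_hmm(0.3, 0.02, 0.99),
                    max_iter = 100, tol = 1e-6) {
  if (nrow(gch_table) < 10) stop2("need at least 10 GCH sites to fit the HMM")
  if (all(gch_table$total == 0)) stop2("all sites have zero coverage")
  seqs <- gch_sequences(gch_table)
  p <- unname(init$p); trans <- init$trans; pi0 <- init$init
  trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    ll <- 0
    meth_w <- c(0, 0); total_w <- c(0, 0)
    xi <- matrix(0, 2, 2)
    g1 <- c(0, 0)
    for (sq in seqs) {
      fb <- .bhmm_forward_backward(sq$meth, sq$total, p, trans, pi0)
      ll <- ll + fb$loglik
      meth_w <- meth_w + fb$meth_w
      total_w <- total_w + fb$total_w
      xi <- xi + fb$xi
      g1 <- g1 + fb$gamma[1, ]
    }
    if (ll < prev - 1e-8 * max(1, abs(prev))) {
      stop2("internal error: Baum-Welch log-likelihood decreased (%.6g -> %.6g)",
            prev, ll)
    }
    trace <- c(trace, ll)
    if (is.finite(prev) && ll - prev < tol) { converged <- TRUE; break }
    prev <- ll
    # M-step
    p <- ifelse(total_w > 0, meth_w / total_w, p)
    p <- pmin(1 - 1e-6, pmax(1e-6, p))
    rs <- rowSums(xi)
    if (all(rs > 0)) trans <- xi / rs
    trans <- pmin(pmax(trans, 1e-9), 1 - 1e-9)
    trans <- trans / rowSums(trans)
    pi0 <- g1 / sum(g1)
  }
  if (p[1] < p[2]) { # canonicalise: state 1 = open
    p <- rev(p)
    trans <- trans[2:1, 2:1]
    pi0 <- rev(pi0)
  }
  hmm <- structure(list(p = c(open = p[1], closed = p[2]), trans = trans,
                        init = pi0, loglik = trace[length(trace)],
                        loglik_trace = trace, n_iter = length(trace),
                        converged = converged),
                   class = "binomial_hmm")
  if (!(p[2] > 0 && p[2] < p[1] && p[1] < 1)) {
    # degenerate fit (homogeneous data); return as-is, downstream gates
    # discard everything
    warning("fitted emission probabilities are degenerate (p_open <= p_closed)")
  }
  hmm
}

#' Segment a GCH table into putative NDRs and background
#'
#' Viterbi-decodes each chromosome and turns maximal runs of open-state
#' sites into putative nucleosome-depleted regions spanning the first to
#' last site of the run (end exclusive = last position + 1); complement runs
#' become background regions.
#'
#' @param gch_table GCH methylation site table.
#' @param hmm fitted or user-supplied [binomial_hmm()].
#' @return list with `ndrs` and `background` (`GRanges`, each with `n_gch`).
#' @export
segment_gch <- function(gch_table, hmm) {
  seqs <- gch_sequences(gch_table)
  collect <- function(open_state) {
    rows <- list()
    for (sq in seqs) {
      v <- .bhmm_viterbi(sq$meth, sq$total, hmm$p, hmm$trans, hmm$init)
      open <- v$states == 0L
      sel <- if (open_state) open else !open
      if (!any(sel)) next
      r <- rle(sel)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      ok <- which(r$values)
      rows[[length(rows) + 1]] <- data.frame(
        chrom = sq$chrom,
        start = sq$pos[starts[ok]],
        end = sq$pos[ends[ok]] + 1,
        n_gch = r$lengths[ok], stringsAsFactors = FALSE
      )
    }
    if (!length(rows)) return(GenomicRanges::GRanges())
    df <- do.call(rbind, rows)
    as_genomic_regions(df$chrom, df$start, df$end, n_gch = df$n_gch)
  }
  list(ndrs = collect(TRUE), background = collect(FALSE))
}
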