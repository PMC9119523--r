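#' TMM normalization factors
#'
#' Trimmed mean of M-values scaling factors for a raw count matrix. For
#' each sample, log2 gene-wise expression ratios (M-values) and average
#' log2 abundances (A-values) against a reference sample are computed over
#' genes expressed in both; the extreme 30% of M and 5% of A are trimmed
#' (two-sided) and the factor is `2^mean(M)` over the remainder. The
#' reference is the sample whose upper-quartile of depth-scaled counts is
#' closest to the across-sample mean upper-quartile. Factors are rescaled
#' to geometric mean 1, so the effective library size of sample `s` is
#' `colSums(counts)[s] * factor[s]`.
#'
#' @param counts non-negative count matrix (genes x samples), >= 2 samples.
#' @param trim_m two-sided trim fraction on M-values (default 0.30).
#' @param trim_a two-sided trim fraction on A-values (default 0.05).
#' @return named numeric vector of normalization factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("TMM needs >= 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("all-zero sample(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  # upper-quartile of depth-scaled counts picks the reference
  uq <- apply(sweep(counts, 2, lib, "/"), 2, stats::quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(s) {
    pair_tmm(counts[, s], counts[, ref], lib[s], lib[ref], trim_m, trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

# unweighted trimmed mean of M-values for one sample against the reference
pair_tmm <- function(y, r, ny, nr, trim_m, trim_a) {
  keep <- y > 0 & r > 0
  y <- y[keep]; r <- r[keep]
  if (!length(y)) return(1)
  m <- log2((y / ny) / (r / nr))
  a <- 0.5 * log2((y / ny) * (r / nr))
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  rm_ <- rank(m); ra <- rank(a)
  inside <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(inside)) return(1)
  2^mean(m[inside])
}

#' TMM-normalized log2 counts per million
#'
#' Converts raw counts to log2(CPM) on TMM effective library sizes. A small
#' prior count (default 0.25, scaled per sample in proportion to effective
#' depth so the offset is depth-fair) keeps zeros finite:
#' `log2((y + p_s) / (L_s + 2 p_s) * 1e6)` with `p_s` the scaled prior and
#' `L_s` the effective library size.
#'
#' @param x an [expression_matrix()] of raw counts with >= 2 samples.
#' @param prior_count prior count added before the log (default 0.25).
#' @param trim_m,trim_a trim fractions passed to [tmm_factors()].
#' @return an `expr_matrix` on the `log2_cpm` scale; TMM factors are kept
#'   in `attr(result, "tmm_factors")`.
#' @export
tmm_log2_cpm <- function(x, prior_count = 0.25, trim_m = 0.30,
                         trim_a = 0.05) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$value_scale != "raw_counts")
    stop("tmm_log2_cpm expects raw counts, got ", x$value_scale)
  counts <- as.matrix(x$values)
  f <- tmm_factors(counts, trim_m, trim_a)
  eff <- colSums(counts) * f
  pc <- prior_count * eff / mean(eff)
  logcpm <- log2(sweep(sweep(counts, 2, pc, "+"), 2, eff + 2 * pc, "/") * 1e6)
  out <- expression_matrix(logcpm, x$metadata, "log2_cpm")
  attr(out, "tmm_factors") <- f
  out
}
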