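# small in-code fixtures shared across test files

toy_counts <- function(n_genes = 6, n_samples = 4, seed = 42,
                       groups = rep("tumor", n_samples)) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_samples, 50), n_genes, n_samples,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  md <- data.frame(sample_id = colnames(m), group = groups)
  expression_matrix(m, md, "raw_counts")
}

toy_log_matrix <- function(values, groups, value_scale = "log2_cpm",
                           extra = NULL) {
  md <- data.frame(sample_id = colnames(values), group = groups)
  if (!is.null(extra)) md <- cbind(md, extra)
  expression_matrix(values, md, value_scale)
}

# brute-force unweighted TMM per the published definition: M/A trimming
# against a reference column, computed directly from first principles
oracle_tmm <- function(counts, trim_m = 0.3, trim_a = 0.05) {
  lib <- colSums(counts)
  uq <- apply(counts, 2, function(x) quantile(x / sum(x), 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  f <- sapply(seq_len(ncol(counts)), function(s) {
    y <- counts[, s]; r <- counts[, ref]
    keep <- y > 0 & r > 0
    m <- log2((y[keep] / lib[s]) / (r[keep] / lib[ref]))
    a <- 0.5 * log2((y[keep] / lib[s]) * (r[keep] / lib[ref]))
    n <- length(m)
    lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
    sel <- rank(m) >= lo_m & rank(m) <= hi_m &
      rank(a) >= lo_a & rank(a) <= hi_a
    2^mean(m[sel])
  })
  f / exp(mean(log(f)))
}

# maximize the 1-covariate Cox partial likelihood on a beta grid
oracle_cox_hr <- function(time, event, stem, grid = seq(-4, 4, by = 1e-4)) {
  ll <- vapply(grid, function(b) {
    ord <- order(time)
    t_o <- time[ord]; e_o <- event[ord]; x_o <- stem[ord]
    risk <- exp(b * x_o)
    sum(vapply(which(e_o == 1), function(i) {
      b * x_o[i] - log(sum(risk[t_o >= t_o[i]]))
    }, numeric(1)))
  }, numeric(1))
  exp(grid[which.max(ll)])
}
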