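#' Impute consensus purity for samples without a tumor compartment
#'
#' Normal tissues and stem-cell cultures have no tumor purity of their
#' own; for joint modelling they receive a random consensus-purity value
#' close to zero, drawn from Normal(mu, sigma) truncated to \[0, 1\]
#' (rejection sampling, so the truncated distribution is exact). Defaults
#' mu = 0.08 (the 0.05 percentile of the empirical purity distribution)
#' and sigma = 0.03.
#'
#' @param sample_ids identifiers of the samples to impute.
#' @param mu,sigma mean and sd of the (truncated) normal.
#' @param seed integer seed; draws are deterministic given the seed.
#' @return named numeric vector of imputed purities in \[0, 1\].
#' @export
impute_cpe <- function(sample_ids, mu = 0.08, sigma = 0.03, seed = 1) {
  stopifnot(sigma >= 0)
  n <- length(sample_ids)
  p <- local_rng(seed)(function() {
    if (sigma == 0) return(rep(mu, n))
    out <- stats::rnorm(n, mu, sigma)
    bad <- which(out < 0 | out > 1)
    while (length(bad)) {
      out[bad] <- stats::rnorm(length(bad), mu, sigma)
      bad <- bad[out[bad] < 0 | out[bad] > 1]
    }
    out
  })
  names(p) <- sample_ids
  p
}

stem_groups <- c("normal", "ESC", "iPSC", "ASC", "PSC")

#' Regress tumor purity out of log-expression
#'
#' Fits, per gene, an ordinary least-squares model of the TMM-normalized
#' log2(CPM) on consensus tumor purity P, and subtracts the linear part:
#' corrected = Y - beta1 * P (the intercept is retained). Tumor samples
#' without a purity value are removed (with a message); normal/stem-cell
#' samples receive imputed purity via [impute_cpe()]. Genes with zero
#' variance get slope 0 (correction is the identity for them).
#'
#' @param m an `expr_matrix` on the `log2_cpm` (or other log) scale.
#' @param purity optional named purity vector overriding
#'   `m$metadata$purity`.
#' @param mu,sigma,seed imputation parameters, see [impute_cpe()].
#' @param fit_on `"all"` (default; tumors plus imputed normals/SC, so
#'   normals are corrected on the same model) or `"tumor"`.
#' @return list with `corrected` (an `expr_matrix`; only retained samples),
#'   `model` (class `purity_model`: per-gene `intercept`, `slope`, the
#'   purity vector used, imputation parameters) and `dropped` (ids of
#'   tumor samples removed for missing purity).
#' @export
correct_purity <- function(m, purity = NULL, mu = 0.08, sigma = 0.03,
                           seed = 1, fit_on = c("all", "tumor")) {
  stopifnot(inherits(m, "expr_matrix"))
  fit_on <- match.arg(fit_on)
  md <- m$metadata
  p <- md$purity
  names(p) <- md$sample_id
  if (!is.null(purity)) p[names(purity)] <- purity
  is_tumor <- !md$group %in% stem_groups
  dropped <- md$sample_id[is_tumor & is.na(p)]
  if (length(dropped))
    message("dropping ", length(dropped),
            " tumor sample(s) without purity: ",
            paste(utils::head(dropped, 5), collapse = ", "))
  need_imp <- !is_tumor & is.na(p)
  if (any(need_imp))
    p[need_imp] <- impute_cpe(md$sample_id[need_imp], mu, sigma, seed)
  keep <- !md$sample_id %in% dropped
  x <- subset_expr(m, samples = which(keep))
  p <- p[keep]
  fit_idx <- if (fit_on == "tumor") which(is_tumor[keep]) else
    seq_along(p)
  pf <- p[fit_idx]
  if (stats::var(pf) == 0)
    stop("purity is constant across fitting samples; slope unidentifiable")
  v <- as.matrix(x$values)
  # vectorized per-gene OLS: slope = cov(Y, P) / var(P)
  pc <- pf - mean(pf)
  slope <- as.vector(v[, fit_idx, drop = FALSE] %*% pc) / sum(pc^2)
  names(slope) <- rownames(v)
  intercept <- rowMeans(v[, fit_idx, drop = FALSE]) - slope * mean(pf)
  corrected <- v - outer(slope, p)
  model <- structure(list(intercept = intercept, slope = slope,
                          purity = p, mu = mu, sigma = sigma, seed = seed,
                          fit_on = fit_on),
                     class = "purity_model")
  list(corrected = expression_matrix(corrected, x$metadata, x$value_scale),
       model = model, dropped = dropped)
}

#' @export
print.purity_model <- function(x, ...) {
  cat(sprintf("purity_model: %d genes, %d samples (fit on %s)\n",
              length(x$slope), length(x$purity), x$fit_on))
  cat(sprintf("  slope: median %.3f, IQR [%.3f, %.3f]\n",
              stats::median(x$slope),
              stats::quantile(x$slope, 0.25), stats::quantile(x$slope, 0.75)))
  invisible(x)
}

#' Per-gene R-squared of expression on purity
#'
#' Diagnostic for the purity correction: the squared correlation between
#' each gene's values and the purity vector (0 for zero-variance genes).
#'
#' @param m an `expr_matrix`.
#' @param purity named purity vector covering the samples of `m`.
#' @return numeric vector of per-gene R-squared values.
#' @export
purity_r2 <- function(m, purity) {
  v <- as.matrix(m$values)
  p <- purity[colnames(v)]
  sv <- apply(v, 1, stats::sd)
  r2 <- rep(0, nrow(v))
  ok <- sv > 0
  r2[ok] <- (apply(v[ok, , drop = FALSE], 1, stats::cor, y = p))^2
  names(r2) <- rownames(v)
  r2
}
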