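#' Fit a signature-restricted principal-component stemness axis
#'
#' Restricts the (purity-corrected) expression matrix to the signature
#' genes and fits a PCA over samples: genes are mean-centered (no
#' unit-variance scaling by default) and loadings come from the
#' eigendecomposition of the sample covariance in the signature subspace.
#' The first component is the stemness axis. Because an eigenvector's
#' sign is arbitrary, the axis is oriented so that the mean PC1 score of
#' ESC/iPSC samples is negative — the "stem" side of the axis is low.
#' All sample groups (tumor, normal, stem cells) enter the fit; clustering
#' medians downstream use tumor samples only.
#'
#' @param m an `expr_matrix` (log scale, typically purity-corrected).
#' @param signature a [gene_signature()] (or character vector of genes).
#' @param k number of components to retain (default 2, capped at the
#'   rank).
#' @param scale_genes also scale genes to unit variance (default FALSE).
#' @return an object of class `stemness_axis` with elements
#'   `signature` (name), `genes` (subset used), `center` (per-gene means),
#'   `loadings` (genes x k), `var_explained` (fractions of the subspace
#'   variance, non-increasing), `orientation` (+1/-1, applied to PC1),
#'   `scores` (training-sample scores, PC1 oriented) and `groups`.
#' @examples
#' sim <- simulate_bulk(n_genes = 300, seed = 7)
#' lc <- tmm_log2_cpm(sim$expr)
#' ax <- fit_stemness_axis(lc, sim$truth$signature_genes)
#' ax
#' @export
fit_stemness_axis <- function(m, signature, k = 2, scale_genes = FALSE) {
  stopifnot(inherits(m, "expr_matrix"))
  genes <- if (inherits(signature, "gene_signature")) signature$genes else
    as.character(signature)
  sig_name <- if (inherits(signature, "gene_signature")) signature$name else
    "signature"
  genes <- intersect(genes, rownames(m$values))
  if (length(genes) < 2)
    stop("fewer than 2 signature genes present in the matrix")
  x <- t(as.matrix(m$values[genes, , drop = FALSE])) # samples x genes
  pc <- stats::prcomp(x, center = TRUE, scale. = scale_genes)
  rank <- sum(pc$sdev > pc$sdev[1] * 1e-12)
  if (k > rank) stop(sprintf("k = %d exceeds rank %d", k, rank))
  var_expl <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  groups <- m$metadata$group
  sc_idx <- groups %in% c("ESC", "iPSC")
  orientation <- 1
  if (any(sc_idx)) {
    if (mean(scores[sc_idx, 1]) > 0) orientation <- -1
  } else {
    warning("no ESC/iPSC samples; axis orientation left as fitted")
  }
  scores[, 1] <- scores[, 1] * orientation
  structure(list(signature = sig_name, genes = genes,
                 center = pc$center,
                 scale = if (scale_genes) pc$scale else NULL,
                 loadings = loadings, var_explained = var_expl,
                 orientation = orientation, scores = scores,
                 groups = stats::setNames(groups, m$metadata$sample_id),
                 metadata = m$metadata),
            class = "stemness_axis")
}

#' @export
print.stemness_axis <- function(x, ...) {
  cat(sprintf("stemness_axis on '%s': %d genes, %d samples\n",
              x$signature, length(x$genes), nrow(x$scores)))
  cat(sprintf("  variance explained: %s\n",
              paste(sprintf("PC%d %.1f%%", seq_along(x$var_explained),
                            100 * x$var_explained), collapse = ", ")))
  cat(sprintf("  orientation: %+d (stem side = negative PC1)\n",
              x$orientation))
  invisible(x)
}

#' @export
summary.stemness_axis <- function(object, ...) {
  sc <- object$scores[, 1]
  by_grp <- tapply(sc, object$groups, function(v)
    c(n = length(v), mean = mean(v), sd = stats::sd(v)))
  out <- do.call(rbind, by_grp)
  cat(sprintf("stemness_axis '%s' — PC1 score by group:\n", object$signature))
  print(round(out, 3))
  invisible(out)
}

#' @export
coef.stemness_axis <- function(object, ...) object$loadings

#' Project samples onto a fitted stemness axis
#'
#' Scores new samples as `(x - center) . loadings`, with PC1 multiplied by
#' the fitted orientation. Axis genes missing from `newdata` contribute 0
#' after centering (their term is dropped), with a message.
#'
#' @param object a `stemness_axis`.
#' @param newdata an `expr_matrix` or genes x samples matrix; omit to get
#'   the training scores.
#' @param k components to return (default 1, the stemness axis).
#' @param ... unused.
#' @return samples x k matrix of scores (a named vector when `k = 1`).
#' @export
predict.stemness_axis <- function(object, newdata = NULL, k = 1, ...) {
  if (is.null(newdata)) {
    sc <- object$scores[, seq_len(k), drop = FALSE]
    return(if (k == 1) sc[, 1] else sc)
  }
  v <- if (inherits(newdata, "expr_matrix")) newdata$values else newdata
  v <- as.matrix(v)
  present <- intersect(object$genes, rownames(v))
  if (length(present) < length(object$genes))
    message(length(object$genes) - length(present),
            " axis gene(s) absent from newdata contribute 0")
  xm <- t(v[present, , drop = FALSE]) -
    matrix(object$center[present], ncol(v), length(present), byrow = TRUE)
  if (!is.null(object$scale))
    xm <- sweep(xm, 2, object$scale[present], "/")
  sc <- xm %*% object$loadings[present, seq_len(k), drop = FALSE]
  sc[, 1] <- sc[, 1] * object$orientation
  rownames(sc) <- colnames(v)
  if (k == 1) sc[, 1] else sc
}

#' @export
plot.stemness_axis <- function(x, ...) {
  sc <- x$scores
  grp <- factor(x$groups)
  if (ncol(sc) >= 2) {
    graphics::plot(sc[, 1], sc[, 2], col = as.integer(grp), pch = 16,
                   xlab = sprintf("PC1 (%.0f%%)", 100 * x$var_explained[1]),
                   ylab = sprintf("PC2 (%.0f%%)", 100 * x$var_explained[2]),
                   ...)
  } else {
    graphics::stripchart(sc[, 1] ~ grp, method = "jitter", pch = 16,
                         xlab = "PC1 score", ...)
  }
  graphics::legend("topright", legend = levels(grp), col = seq_along(levels(grp)),
                   pch = 16, cex = 0.8)
  invisible(x)
}

#' Assign tumor samples to Stem/Normal clusters by a median rule
#'
#' Under the fixed orientation (stem side negative), a tumor sample is
#' `Stem` when its PC1 score is strictly below the threshold and `Normal`
#' otherwise (ties at the median go to `Normal`). The threshold is the
#' median score over all tumor samples (`global_median`) or within each
#' tumor project (`per_tumor_median`); only tumor samples enter the
#' median. Projects with fewer than 2 samples are excluded under the
#' per-tumor rule (with a message).
#'
#' @param scores named numeric vector of PC1 scores for tumor samples.
#' @param project character vector of tumor-type codes aligned with
#'   `scores`.
#' @param rule `"global_median"` or `"per_tumor_median"`.
#' @param patient_id optional per-sample patient identifiers, carried
#'   through for survival analysis.
#' @return object of class `cluster_assignment`: data.frame with columns
#'   `sample_id`, `project`, `patient_id`, `score`, `cluster`, plus
#'   attributes `rule` and `thresholds`.
#' @export
assign_clusters <- function(scores, project,
                            rule = c("global_median", "per_tumor_median"),
                            patient_id = NULL) {
  rule <- match.arg(rule)
  stopifnot(length(scores) == length(project))
  if (is.null(patient_id)) patient_id <- names(scores)
  df <- data.frame(sample_id = names(scores), project = as.character(project),
                   patient_id = patient_id, score = as.numeric(scores),
                   stringsAsFactors = FALSE)
  if (rule == "global_median") {
    thr <- stats::median(df$score)
    df$cluster <- ifelse(df$score < thr, "Stem", "Normal")
    thresholds <- c(global = thr)
  } else {
    sizes <- table(df$project)
    small <- names(sizes)[sizes < 2]
    if (length(small)) {
      message("excluding project(s) with < 2 samples: ",
              paste(small, collapse = ", "))
      df <- df[!df$project %in% small, , drop = FALSE]
    }
    thresholds <- tapply(df$score, df$project, stats::median)
    df$cluster <- ifelse(df$score < thresholds[df$project], "Stem", "Normal")
  }
  structure(df, class = c("cluster_assignment", "data.frame"),
            rule = rule, thresholds = thresholds)
}

#' Signature intensity per tumor type, with Wilson confidence intervals
#'
#' The signature intensity of tumor type j is `I_j = N_stem / (N_stem +
#' N_normal)`, the fraction of that tumor's samples falling in the Stem
#' cluster. The 95% CI is the Wilson score interval (normal approximation
#' of the proportion test without continuity correction).
#'
#' @param assignment a [assign_clusters()] result.
#' @param conf_level confidence level (default 0.95).
#' @return data.frame (class `intensity_result`) with columns `project`,
#'   `n_stem`, `n_normal`, `intensity`, `ci_lo`, `ci_hi`.
#' @export
signature_intensity <- function(assignment, conf_level = 0.95) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  if (!nrow(assignment)) stop("no samples in assignment")
  projects <- sort(unique(assignment$project))
  rows <- lapply(projects, function(pj) {
    cl <- assignment$cluster[assignment$project == pj]
    ns <- sum(cl == "Stem"); nn <- sum(cl == "Normal")
    ci <- wilson_ci(ns, ns + nn, conf_level)
    data.frame(project = pj, n_stem = ns, n_normal = nn,
               intensity = ns / (ns + nn), ci_lo = ci[1], ci_hi = ci[2])
  })
  structure(do.call(rbind, rows),
            class = c("intensity_result", "data.frame"))
}

#' Wilson score interval for a binomial proportion
#'
#' Closed-form score interval (no continuity correction): with
#' `p = k/n` and `z` the normal quantile,
#' `(p + z^2/2n ± z*sqrt(p(1-p)/n + z^2/4n^2)) / (1 + z^2/n)`.
#'
#' @param k number of successes.
#' @param n number of trials (> 0).
#' @param conf_level confidence level.
#' @return numeric `c(lo, hi)`, a subset of \[0, 1\].
#' @export
wilson_ci <- function(k, n, conf_level = 0.95) {
  if (n <= 0) stop("n must be positive")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  mid <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, mid - half), min(1, mid + half))
}
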