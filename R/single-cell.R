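#' Depth-normalize UMI counts to log2 scale
#'
#' Per cell: `log2(1 + count * scale_factor / cell_total)`. Zeros stay
#' zero, so sparsity is preserved; the transform is invariant to
#' multiplying all of a cell's counts by a constant. Cells with zero total
#' counts are dropped with a message.
#'
#' @param umi an `expr_matrix` of raw UMI counts (sparse or dense).
#' @param scale_factor target depth (default 1e4, the common single-cell
#'   convention).
#' @return an `expr_matrix` on the `log2_norm` scale.
#' @export
normalize_cells <- function(umi, scale_factor = 1e4) {
  stopifnot(inherits(umi, "expr_matrix"))
  if (umi$value_scale != "raw_counts")
    stop("normalize_cells expects raw counts")
  v <- umi$values
  totals <- if (inherits(v, "sparseMatrix")) Matrix::colSums(v) else colSums(v)
  zero <- totals == 0
  if (all(zero)) stop("all cells have zero total counts")
  if (any(zero)) {
    message("dropping ", sum(zero), " cell(s) with zero total counts")
    v <- v[, !zero, drop = FALSE]
    totals <- totals[!zero]
  }
  if (inherits(v, "CsparseMatrix")) {
    out <- v
    # column index of each stored entry, from the column pointers
    cols <- rep(seq_len(ncol(v)), diff(v@p))
    out@x <- log2(1 + v@x * scale_factor / totals[cols])
  } else {
    out <- log2(1 + sweep(as.matrix(v), 2, scale_factor / totals, "*"))
  }
  md <- umi$metadata[colnames(out), , drop = FALSE]
  expression_matrix(out, md, "log2_norm")
}

#' Project single cells onto a bulk-derived stemness axis
#'
#' Scores each cell with the bulk PC1 loadings: the cell's normalized
#' profile, restricted to the axis genes and centered by the bulk
#' per-gene means, is projected onto the loadings and multiplied by the
#' fitted orientation. Axis genes absent from the cell matrix are treated
#' as zero expression, i.e. they contribute `-center * loading` under
#' bulk centering (`center = "axis"`, default; cross-platform location
#' shifts can instead be absorbed by re-centering on the cell dataset
#' with `center = "data"`).
#'
#' @param axis a [fit_stemness_axis()] model.
#' @param cells an `expr_matrix` of depth-normalized log2 values (see
#'   [normalize_cells()]).
#' @param min_overlap minimum fraction of axis genes that must be present
#'   in the cell matrix (default 0.5); below this an error is raised.
#' @param center `"axis"` (bulk means) or `"data"` (cell-dataset means).
#' @return data.frame of class `cell_scores`: `cell_id`, `patient_id`,
#'   `cell_class`, `lesion`, `score` (signed PC1 projection) and
#'   `abs_score` (degree of signature reactivation).
#' @export
project_cells <- function(axis, cells, min_overlap = 0.5,
                          center = c("axis", "data")) {
  stopifnot(inherits(axis, "stemness_axis"), inherits(cells, "expr_matrix"))
  center <- match.arg(center)
  present <- intersect(axis$genes, rownames(cells$values))
  if (length(present) / length(axis$genes) < min_overlap)
    stop(sprintf("only %d/%d axis genes present (< min_overlap = %.2f)",
                 length(present), length(axis$genes), min_overlap))
  v <- cells$values[present, , drop = FALSE]
  v <- as.matrix(v)
  mu <- if (center == "axis") axis$center[present] else rowMeans(v)
  w <- axis$loadings[present, 1]
  # absent axis genes have value 0: contribution -sum(center*loading)
  absent <- setdiff(axis$genes, present)
  offset <- if (center == "axis" && length(absent))
    -sum(axis$center[absent] * axis$loadings[absent, 1]) else 0
  score <- (as.vector(crossprod(v, w)) - sum(mu * w) + offset) *
    axis$orientation
  md <- cells$metadata
  cls <- if ("cell_class" %in% names(md)) md$cell_class else md$group
  out <- data.frame(cell_id = md$sample_id, patient_id = md$patient_id,
                    cell_class = cls, lesion = md$lesion,
                    score = score, abs_score = abs(score),
                    stringsAsFactors = FALSE)
  structure(out, class = c("cell_scores", "data.frame"))
}

#' One-way ANOVA variance decomposition of cell scores
#'
#' Fraction of score variance attributable to differences between groups
#' (eta-squared = between-group SS / total SS), with the F-test p-value —
#' here the intertumoral (between-patient) share of single-cell stemness
#' heterogeneity.
#'
#' @param scores a `cell_scores` data.frame (or numeric vector).
#' @param group grouping factor; defaults to `patient_id` when `scores`
#'   is a `cell_scores` object.
#' @return list with `fraction` (eta-squared), `F`, `df`, `p`.
#' @export
variance_decomposition <- function(scores, group = NULL) {
  if (inherits(scores, "cell_scores")) {
    if (is.null(group)) group <- scores$patient_id
    y <- scores$score
  } else {
    y <- as.numeric(scores)
  }
  group <- factor(group)
  if (nlevels(group) < 2) stop("need >= 2 groups")
  fit <- stats::aov(y ~ group)
  tab <- summary(fit)[[1]]
  ss <- tab[["Sum Sq"]]
  list(fraction = ss[1] / sum(ss),
       F = tab[["F value"]][1],
       df = tab[["Df"]],
       p = tab[["Pr(>F)"]][1])
}

#' Compare stemness scores between lesion classes
#'
#' Per-class summaries (n, median, IQR) and two-sided Wilcoxon rank-sum
#' tests for every pair of lesion classes, BH-adjusted.
#'
#' @param scores a `cell_scores` data.frame.
#' @param class_col column holding the class labels (default `"lesion"`;
#'   use `"cell_class"` for cancer/normal/stem comparisons).
#' @return list with `summary` (per-class) and `tests` (pairwise
#'   data.frame: `class_a`, `class_b`, `delta_median`, `p`, `p_adj`).
#' @export
compare_lesions <- function(scores, class_col = "lesion") {
  stopifnot(inherits(scores, "cell_scores"))
  cls <- scores[[class_col]]
  keep <- !is.na(cls)
  cls <- as.character(cls[keep]); y <- scores$score[keep]
  lev <- sort(unique(cls))
  if (length(lev) < 2)
    stop("need >= 2 lesion classes, found: ",
         paste(lev, collapse = ", "))
  summ <- do.call(rbind, lapply(lev, function(l) {
    v <- y[cls == l]
    data.frame(class = l, n = length(v), median = stats::median(v),
               q25 = stats::quantile(v, 0.25), q75 = stats::quantile(v, 0.75),
               row.names = NULL)
  }))
  pairs <- utils::combn(lev, 2)
  tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    w <- stats::wilcox.test(y[cls == a], y[cls == b], exact = FALSE)
    data.frame(class_a = a, class_b = b,
               delta_median = stats::median(y[cls == a]) -
                 stats::median(y[cls == b]),
               p = w$p.value, row.names = NULL)
  }))
  tests$p_adj <- bh_adjust(tests$p)
  list(summary = summ, tests = tests)
}

#' Per-group bimodality diagnostic of cell scores
#'
#' Descriptive flag for score distributions that look bimodal within a
#' group (e.g. per patient): reports the bimodality coefficient
#' `(skew^2 + 1) / (kurtosis + 3 * (n-1)^2 / ((n-2)(n-3)))`; values above
#' 5/9 (the uniform's value) are conventionally taken as suggestive of
#' bimodality. A descriptive summary, not a test.
#'
#' @param scores a `cell_scores` data.frame.
#' @param group grouping vector (default patient).
#' @return data.frame with `group`, `n`, `bimodality`, `flagged`.
#' @export
bimodality_summary <- function(scores, group = scores$patient_id) {
  stopifnot(inherits(scores, "cell_scores"))
  out <- do.call(rbind, lapply(split(scores$score, group), function(v) {
    n <- length(v)
    if (n < 4) return(data.frame(n = n, bimodality = NA_real_,
                                 flagged = NA))
    m <- mean(v); s <- stats::sd(v)
    skew <- mean((v - m)^3) / s^3
    kurt <- mean((v - m)^4) / s^4 - 3
    bc <- (skew^2 + 1) / (kurt + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
    data.frame(n = n, bimodality = bc, flagged = bc > 5 / 9)
  }))
  out$group <- rownames(out)
  rownames(out) <- NULL
  out[c("group", "n", "bimodality", "flagged")]
}
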