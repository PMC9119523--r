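#' Gene signature
#'
#' A named gene list with per-gene provenance tags. Kinds distinguish the
#' stemness signature itself from the proliferation, EMT/MET and
#' expression-matched control sets it is compared against.
#'
#' @param name signature name.
#' @param genes character vector of gene identifiers (deduplicated).
#' @param kind one of `"stemness"`, `"proliferation"`, `"emt_met"`,
#'   `"control"`.
#' @param tags optional character vector (same length as `genes` after
#'   deduplication, or named by gene) recording provenance:
#'   `"atlas"`, `"timeseries"`, `"knockdown"`, `"curated"`, ...
#' @return an object of class `gene_signature`.
#' @export
gene_signature <- function(name, genes,
                           kind = c("stemness", "proliferation", "emt_met",
                                    "control"),
                           tags = NULL) {
  kind <- match.arg(kind)
  genes <- as.character(genes)
  if (!length(genes)) stop("empty gene signature: ", name)
  if (anyDuplicated(genes)) {
    keep <- !duplicated(genes)
    if (!is.null(tags) && is.null(names(tags))) tags <- tags[keep]
    genes <- genes[keep]
  }
  if (!is.null(tags)) {
    if (!is.null(names(tags))) tags <- tags[genes]
    names(tags) <- genes
  }
  structure(list(name = name, genes = genes, kind = kind, tags = tags),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature '%s' (%s): %d genes\n",
              x$name, x$kind, length(x$genes)))
  if (!is.null(x$tags)) {
    tb <- table(x$tags)
    cat("  provenance:", paste(sprintf("%s=%d", names(tb), tb),
                               collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.gene_signature <- function(x) length(x$genes)

#' Read a gene list file
#'
#' Accepts one-identifier-per-line text or a two-column TSV `(id, tag)`.
#'
#' @inheritParams gene_signature
#' @param path file path.
#' @return a `gene_signature`.
#' @export
read_gene_signature <- function(path, name = basename(path),
                                kind = "stemness") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 1)
  if (length(parts) && length(parts[[1]]) >= 2) {
    tags <- vapply(parts, `[`, character(1), 2)
    gene_signature(name, ids, kind, tags = tags)
  } else {
    gene_signature(name, ids, kind)
  }
}

#' Selection thresholds for a signature-assembly dataset
#'
#' Holds the per-dataset cutoffs: `log2fc_threshold` on the log fold-change
#' between the stem-like target group and each comparison group,
#' `expr_threshold` on the overall expression level E (log2 of summed
#' linear-scale expression across all samples), and `min_comparisons`, the
#' number of comparisons a gene must pass.
#'
#' @param log2fc_threshold log2 fold-change cutoff.
#' @param expr_threshold cutoff on E.
#' @param min_comparisons minimum number of passing comparisons.
#' @param target_group group label in which the stemness program is active.
#' @param comparison_groups labels compared against; defaults to all other
#'   groups present in the data at selection time.
#' @export
selector_config <- function(log2fc_threshold, expr_threshold,
                            min_comparisons = 1, target_group = NULL,
                            comparison_groups = NULL) {
  stopifnot(is.finite(log2fc_threshold), is.finite(expr_threshold),
            min_comparisons >= 1)
  structure(list(log2fc_threshold = log2fc_threshold,
                 expr_threshold = expr_threshold,
                 min_comparisons = min_comparisons,
                 target_group = target_group,
                 comparison_groups = comparison_groups),
            class = "selector_config")
}

# E: log2 of the sum of linear-scale expression across all samples.
# Input values are log2-scale; `e_mode = "sum_log"` switches to the
# alternative reading (sum of the log values, then log2 is skipped).
expr_level <- function(values, e_mode = c("log_sum", "sum_log")) {
  e_mode <- match.arg(e_mode)
  if (e_mode == "log_sum") log2(rowSums(2^values)) else rowSums(values)
}

#' Select stem-enriched genes from a tissue-atlas dataset
#'
#' For each comparison group, computes the log2 fold-change between the
#' target (stem-like) group mean and the comparison group mean on the
#' log2-scale values, and keeps genes exceeding `log2fc_threshold` in at
#' least `min_comparisons` comparisons with expression level
#' E > `expr_threshold`.
#'
#' @param m an `expr_matrix` on a log2 scale with a `group` metadata column
#'   holding tissue/cell-line labels.
#' @param cfg a [selector_config()]; `target_group` is required,
#'   `comparison_groups` defaults to every other group in `m`.
#' @param e_mode definition of E: `"log_sum"` (log2 of summed linear
#'   expression, default) or `"sum_log"`.
#' @return character vector of selected gene identifiers.
#' @export
atlas_select <- function(m, cfg, e_mode = "log_sum") {
  stopifnot(inherits(m, "expr_matrix"), inherits(cfg, "selector_config"))
  groups <- m$metadata$group
  if (is.null(cfg$target_group) || !cfg$target_group %in% groups)
    stop("unknown target group: ", cfg$target_group)
  comp <- cfg$comparison_groups
  if (is.null(comp)) comp <- setdiff(unique(groups), cfg$target_group)
  bad <- setdiff(comp, groups)
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  v <- as.matrix(m$values)
  tmean <- rowMeans(v[, groups == cfg$target_group, drop = FALSE])
  npass <- rowSums(vapply(comp, function(g) {
    tmean - rowMeans(v[, groups == g, drop = FALSE]) > cfg$log2fc_threshold
  }, logical(nrow(v))))
  e <- expr_level(v, e_mode)
  rownames(v)[npass >= cfg$min_comparisons & e > cfg$expr_threshold]
}

#' Select genes down-regulated along a differentiation time course
#'
#' Compares the first (undifferentiated) and last time points of an ESC
#' differentiation series; genes higher at the first time point by more
#' than `log2fc_threshold`, with E above `expr_threshold`, are kept.
#'
#' @param m an `expr_matrix` on a log2 scale with a numeric `timepoint`
#'   metadata column for one cell line.
#' @inheritParams atlas_select
#' @return character vector of selected gene identifiers.
#' @export
timeseries_select <- function(m, cfg, e_mode = "log_sum") {
  stopifnot(inherits(m, "expr_matrix"), inherits(cfg, "selector_config"))
  tp <- m$metadata$timepoint
  if (is.null(tp) || length(unique(tp[!is.na(tp)])) < 2)
    stop("need a numeric `timepoint` metadata column with >= 2 time points")
  tp <- as.numeric(tp)
  v <- as.matrix(m$values)
  first <- rowMeans(v[, tp == min(tp, na.rm = TRUE), drop = FALSE])
  last <- rowMeans(v[, tp == max(tp, na.rm = TRUE), drop = FALSE])
  e <- expr_level(v, e_mode)
  rownames(v)[(first - last) > cfg$log2fc_threshold & e > cfg$expr_threshold]
}

#' Select genes dependent on pluripotency factors across knockdowns
#'
#' Each experiment contrasts control versus knockdown of one pluripotency
#' transcription factor. Genes whose expression decreases upon knockdown
#' (log2 FC control vs knockdown above the threshold; flip with
#' `direction = "up"`) and with E above the threshold in at least one
#' experiment are unioned.
#'
#' @param experiments list of `expr_matrix` objects, each with metadata
#'   `group` in `{"control", "knockdown"}`.
#' @inheritParams atlas_select
#' @param direction `"down"` (default: kept genes drop on knockdown) or
#'   `"up"`.
#' @return character vector (union over experiments).
#' @export
knockdown_select <- function(experiments, cfg, direction = c("down", "up"),
                             e_mode = "log_sum") {
  direction <- match.arg(direction)
  if (!length(experiments)) stop("empty experiment list")
  sel <- lapply(experiments, function(m) {
    stopifnot(inherits(m, "expr_matrix"))
    groups <- m$metadata$group
    if (!all(c("control", "knockdown") %in% groups))
      stop("knockdown experiment needs 'control' and 'knockdown' groups")
    v <- as.matrix(m$values)
    fc <- rowMeans(v[, groups == "control", drop = FALSE]) -
      rowMeans(v[, groups == "knockdown", drop = FALSE])
    if (direction == "up") fc <- -fc
    e <- expr_level(v, e_mode)
    rownames(v)[fc > cfg$log2fc_threshold & e > cfg$expr_threshold]
  })
  unique(unlist(sel))
}

#' Collapse duplicate probes to one row per gene
#'
#' Keeps, for each gene, the probe with the highest mean expression —
#' the conventional microarray reduction before gene-level selection.
#'
#' @param m an `expr_matrix` whose rownames are probe identifiers.
#' @param probe2gene data.frame or two-column matrix mapping probe id to
#'   gene id (columns `probe`, `gene` or positional).
#' @return an `expr_matrix` with gene rownames, one row per gene.
#' @export
collapse_probes <- function(m, probe2gene) {
  stopifnot(inherits(m, "expr_matrix"))
  probe2gene <- as.data.frame(probe2gene)
  names(probe2gene)[1:2] <- c("probe", "gene")
  v <- as.matrix(m$values)
  probe2gene <- probe2gene[probe2gene$probe %in% rownames(v), , drop = FALSE]
  mu <- rowMeans(v)[probe2gene$probe]
  ord <- order(probe2gene$gene, -mu)
  probe2gene <- probe2gene[ord, ]
  keep <- probe2gene[!duplicated(probe2gene$gene), ]
  v <- v[keep$probe, , drop = FALSE]
  rownames(v) <- keep$gene
  expression_matrix(v, m$metadata, m$value_scale)
}

#' Assemble the stemness signature from selected gene lists
#'
#' Intersects the per-dataset selections, adds manually curated stemness
#' genes, removes tissue-specific, proliferation and cell-cycle/
#' proliferation-annotated genes, and optionally maps the result through an
#' ortholog table. Removal order is immaterial: a single set difference
#' against the union of exclusion sets is taken.
#'
#' @param source_lists non-empty list of character vectors (per-dataset
#'   selections to intersect).
#' @param curated character vector of curated additions (may be empty).
#' @param tissue_specific,cellcycle character vectors of genes to exclude.
#' @param proliferation a `gene_signature` of kind `"proliferation"` (or
#'   character vector) to exclude.
#' @param ortholog_map optional two-column data.frame `(source_id,
#'   target_id)`; retained genes absent from the map are dropped with a
#'   warning.
#' @param name signature name.
#' @return a `gene_signature` of kind `"stemness"` with provenance tags
#'   (`"intersection"` or `"curated"`).
#' @export
assemble_stemness <- function(source_lists, curated = character(),
                              tissue_specific = character(),
                              proliferation = character(),
                              cellcycle = character(),
                              ortholog_map = NULL, name = "stemness") {
  if (!length(source_lists)) stop("source_lists must be non-empty")
  inter <- Reduce(intersect, lapply(source_lists, as.character))
  if (inherits(proliferation, "gene_signature"))
    proliferation <- proliferation$genes
  pooled <- union(inter, curated <- as.character(curated))
  drop <- unique(c(as.character(tissue_specific), proliferation,
                   as.character(cellcycle)))
  kept <- setdiff(pooled, drop)
  if (!length(kept)) stop("assembly produced an empty signature")
  tags <- ifelse(kept %in% inter, "intersection", "curated")
  names(tags) <- kept
  if (!is.null(ortholog_map)) {
    ortholog_map <- as.data.frame(ortholog_map)
    names(ortholog_map)[1:2] <- c("source_id", "target_id")
    hit <- match(kept, ortholog_map$source_id)
    if (anyNA(hit)) {
      warning("dropping ", sum(is.na(hit)),
              " gene(s) missing from the ortholog map: ",
              paste(utils::head(kept[is.na(hit)], 5), collapse = ", "))
    }
    tags <- tags[!is.na(hit)]
    kept <- ortholog_map$target_id[hit[!is.na(hit)]]
    names(tags) <- NULL # identities changed; re-key after dedup
  }
  gene_signature(name, kept, "stemness", tags = tags)
}

#' Pairwise overlap between gene signatures
#'
#' @param signatures list of `gene_signature` objects (or character
#'   vectors), named.
#' @return list with `counts` (symmetric intersection sizes; diagonal =
#'   set sizes) and `fractions` (above the diagonal the count divided by
#'   the row set's size, below by the column set's size).
#' @export
overlap_matrix <- function(signatures) {
  sets <- lapply(signatures, function(s)
    if (inherits(s, "gene_signature")) s$genes else as.character(s))
  nm <- names(sets)
  if (is.null(nm)) nm <- paste0("set", seq_along(sets))
  k <- length(sets)
  counts <- matrix(0L, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) for (j in seq_len(k))
    counts[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  sizes <- lengths(sets)
  fractions <- counts / 1
  for (i in seq_len(k)) for (j in seq_len(k))
    fractions[i, j] <- counts[i, j] / if (j > i) sizes[i] else sizes[j]
  list(counts = counts, fractions = fractions)
}

#' Expression-matched random control signature
#'
#' Samples non-signature genes, without replacement, from mean-expression
#' bins so that the control set reproduces the signature's bin histogram.
#' Bins are equal-width over the range of per-gene mean expression.
#'
#' @param m an `expr_matrix` (log scale recommended).
#' @param signature a `gene_signature`.
#' @param n_bins number of mean-expression bins (default 10).
#' @param seed integer seed; same seed, same control set.
#' @return a `gene_signature` of kind `"control"`.
#' @export
matched_control_set <- function(m, signature, n_bins = 10, seed = 1) {
  stopifnot(inherits(m, "expr_matrix"), inherits(signature, "gene_signature"))
  mu <- rowMeans(as.matrix(m$values))
  breaks <- seq(min(mu), max(mu), length.out = n_bins + 1)
  bin <- cut(mu, breaks, include.lowest = TRUE, labels = FALSE)
  in_sig <- names(mu) %in% signature$genes
  sig_hist <- tabulate(bin[in_sig], nbins = n_bins)
  picked <- local_rng(seed)(function() {
    out <- character(0)
    for (b in which(sig_hist > 0)) {
      cand <- names(mu)[bin == b & !in_sig]
      if (length(cand) < sig_hist[b])
        stop(sprintf("bin %d has %d candidate(s) but needs %d",
                     b, length(cand), sig_hist[b]))
      out <- c(out, sample(cand, sig_hist[b]))
    }
    out
  })
  gene_signature(paste0(signature$name, "_control"), picked, "control")
}

# run `f` under a private RNG state seeded with `seed`, restoring the
# caller's stream afterwards
local_rng <- function(seed) {
  function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    f()
  }
}
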