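#' Expression matrix with per-sample metadata
#'
#' Container for a genes x samples expression matrix together with a
#' per-sample metadata table. The matrix may be dense (`matrix`) or sparse
#' (`Matrix::dgCMatrix`, typical for UMI counts). Metadata carries, per
#' sample: `group` (free-text category; the recognized stem-cell related
#' values are `"tumor"`, `"normal"`, `"ESC"`, `"iPSC"`, `"ASC"`, `"PSC"`),
#' `project` (tumor-type code or `NA`), `purity` (consensus purity estimate
#' in \[0, 1\] or `NA`), `patient_id` and `lesion`
#' (`"primary"`/`"metastatic"`/`"normal"`/`NA`).
#'
#' @param values numeric matrix (genes x samples) with unique rownames
#'   (gene identifiers) and colnames (sample identifiers).
#' @param metadata data.frame with one row per sample. Must contain a
#'   `group` column; `project`, `purity`, `patient_id`, `lesion` and
#'   `timepoint` are optional and filled with `NA` when absent. Rows are
#'   matched to samples by a `sample_id` column or by rownames.
#' @param value_scale one of `"raw_counts"`, `"log2_cpm"`,
#'   `"log2_microarray"`, `"log2_norm"` (depth-normalized log2 single-cell
#'   values).
#' @return an object of class `expr_matrix`: a list with elements `values`,
#'   `metadata`, `value_scale`.
#' @examples
#' x <- matrix(rpois(6, 10), 3, 2,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' md <- data.frame(sample_id = c("s1", "s2"), group = c("tumor", "normal"))
#' em <- expression_matrix(x, md, "raw_counts")
#' em
#' @export
expression_matrix <- function(values, metadata,
                              value_scale = c("raw_counts", "log2_cpm",
                                              "log2_microarray", "log2_norm")) {
  value_scale <- match.arg(value_scale)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(utils::head(unique(rownames(values)[duplicated(rownames(values))]), 3),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(utils::head(unique(colnames(values)[duplicated(colnames(values))]), 3),
               collapse = ", "))
  metadata <- as.data.frame(metadata)
  if ("sample_id" %in% names(metadata)) {
    rownames(metadata) <- as.character(metadata$sample_id)
  }
  missing <- setdiff(colnames(values), rownames(metadata))
  if (length(missing))
    stop("metadata missing sample(s): ", paste(missing, collapse = ", "))
  metadata <- metadata[colnames(values), , drop = FALSE]
  metadata$sample_id <- colnames(values)
  if (!"group" %in% names(metadata))
    stop("metadata must contain a `group` column")
  for (col in c("project", "patient_id", "lesion"))
    if (!col %in% names(metadata)) metadata[[col]] <- NA_character_
  if (!"purity" %in% names(metadata)) metadata$purity <- NA_real_
  metadata$purity <- as.numeric(metadata$purity)
  ok <- is.na(metadata$purity) | (metadata$purity >= 0 & metadata$purity <= 1)
  if (!all(ok))
    stop("purity outside [0,1] for sample(s): ",
         paste(metadata$sample_id[!ok], collapse = ", "))
  if (value_scale == "raw_counts" && min_value(values) < 0)
    stop("raw counts must be non-negative")
  structure(list(values = values, metadata = metadata,
                 value_scale = value_scale),
            class = "expr_matrix")
}

# minimum that works for both dense and dgCMatrix without densifying
min_value <- function(m) {
  if (inherits(m, "sparseMatrix")) min(0, min(m@x, Inf)) else min(m)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$value_scale))
  grp <- table(x$metadata$group)
  cat("  groups:", paste(sprintf("%s=%d", names(grp), grp), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by genes and/or samples
#'
#' @param x an [expression_matrix()].
#' @param genes,samples character vectors of identifiers (or logical/numeric
#'   indices); `NULL` keeps all.
#' @return an `expr_matrix` restricted to the requested rows/columns.
#' @export
subset_expr <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  v <- x$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  expression_matrix(v, x$metadata[colnames(v), , drop = FALSE], x$value_scale)
}

#' Read an expression matrix with sample metadata
#'
#' TSV layout: first column gene id, header row of sample ids. MTX layout:
#' Matrix-Market triplet file (1-based indices per the standard) with
#' `<path>.genes` / `<path>.barcodes` sidecar files holding row and column
#' identifiers, one per line. Metadata is a TSV keyed by a `sample_id`
#' column.
#'
#' @param path path to the matrix file.
#' @param format `"tsv"` or `"mtx"`.
#' @param metadata_path path to the per-sample metadata TSV.
#' @param value_scale passed to [expression_matrix()].
#' @return an `expr_matrix`, genes and samples ordered as in the file.
#' @seealso [write_expression()]
#' @export
read_expression <- function(path, format = c("tsv", "mtx"), metadata_path,
                            value_scale = "raw_counts") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (!file.exists(metadata_path)) stop("file not found: ", metadata_path)
  if (format == "tsv") {
    tab <- utils::read.delim(path, check.names = FALSE, row.names = 1)
    num <- vapply(tab, is.numeric, logical(1))
    if (!all(num))
      stop("non-numeric cells in column(s): ",
           paste(names(tab)[!num], collapse = ", "))
    values <- as.matrix(tab)
  } else {
    values <- as(Matrix::readMM(path), "CsparseMatrix")
    genes <- readLines(paste0(path, ".genes"))
    cells <- readLines(paste0(path, ".barcodes"))
    if (nrow(values) != length(genes) || ncol(values) != length(cells))
      stop(sprintf("dimension mismatch: matrix %dx%d vs %d genes, %d barcodes",
                   nrow(values), ncol(values), length(genes), length(cells)))
    dimnames(values) <- list(genes, cells)
  }
  md <- utils::read.delim(metadata_path, check.names = FALSE,
                          colClasses = c(sample_id = "character"))
  expression_matrix(values, md, value_scale)
}

#' Write an expression matrix and its metadata
#'
#' Inverse of [read_expression()]; round-trips exactly for integer counts
#' and to numeric printing precision otherwise.
#'
#' @inheritParams read_expression
#' @param x an `expr_matrix`.
#' @export
write_expression <- function(x, path, format = c("tsv", "mtx"),
                             metadata_path) {
  stopifnot(inherits(x, "expr_matrix"))
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- data.frame(gene_id = rownames(x$values),
                      as.data.frame(as.matrix(x$values),
                                    check.names = FALSE),
                      check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    Matrix::writeMM(methods::as(methods::as(x$values, "dMatrix"),
                                "TsparseMatrix"), path)
    writeLines(rownames(x$values), paste0(path, ".genes"))
    writeLines(colnames(x$values), paste0(path, ".barcodes"))
  }
  utils::write.table(x$metadata, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Filter genes by expression level
#'
#' Keeps genes with CPM above `min_cpm` in at least `min_samples` samples,
#' the conventional pre-normalization filter for count matrices.
#'
#' @param x an `expr_matrix` of raw counts.
#' @param min_cpm CPM threshold (default 1).
#' @param min_samples minimum number of samples exceeding the threshold.
#' @return the filtered `expr_matrix`.
#' @export
filter_genes <- function(x, min_cpm = 1, min_samples = 2) {
  stopifnot(inherits(x, "expr_matrix"), x$value_scale == "raw_counts")
  lib <- colSums(x$values)
  cpm <- sweep(as.matrix(x$values), 2, lib / 1e6, "/")
  keep <- rowSums(cpm > min_cpm) >= min_samples
  subset_expr(x, genes = which(keep))
}
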