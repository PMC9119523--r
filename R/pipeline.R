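#' Run the bulk stemness-signature pipeline end to end
#'
#' Orchestrates: TMM log2-CPM normalization, purity correction, fitting
#' the signature-restricted stemness axis, Stem/Normal clustering under
#' both median rules, per-tumor signature intensity, survival comparison
#' (when a clinical table is supplied), and single-cell projection (when
#' a UMI matrix is supplied). Every stage writes its output as a
#' plain-text file under `out_dir` and is recorded in a manifest with an
#' MD5 checksum; re-running with the same inputs and seeds reproduces
#' identical checksums.
#'
#' @param expr an `expr_matrix` of raw counts (or a path readable by
#'   [read_expression()] given `metadata_path`).
#' @param signature a [gene_signature()] (or character vector).
#' @param out_dir output directory (created if needed).
#' @param clinical optional [clinical_table()] (or TSV path) enabling the
#'   survival stage.
#' @param cells optional `expr_matrix` of UMI counts enabling the
#'   single-cell stage.
#' @param metadata_path metadata TSV when `expr` is a path.
#' @param purity_mu,purity_sigma,seed purity-imputation parameters.
#' @param k number of axis components.
#' @param cluster_rule rule for the intensity clustering
#'   (`"global_median"`); survival always uses `"per_tumor_median"`.
#' @return invisibly, a list with the fitted objects and `manifest`
#'   (data.frame: stage, file, md5).
#' @export
run_pipeline <- function(expr, signature, out_dir,
                         clinical = NULL, cells = NULL,
                         metadata_path = NULL,
                         purity_mu = 0.08, purity_sigma = 0.03, seed = 1,
                         k = 2, cluster_rule = "global_median") {
  if (is.character(expr)) {
    if (is.null(metadata_path))
      stop("metadata_path required when expr is a file path")
    expr <- read_expression(expr, "tsv", metadata_path)
  }
  stopifnot(inherits(expr, "expr_matrix"))
  if (is.character(clinical)) clinical <- read_clinical(clinical)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(stage, file) {
    manifest[[length(manifest) + 1]] <<-
      data.frame(stage = stage, file = basename(file),
                 md5 = unname(tools::md5sum(file)))
  }
  run_stage <- function(stage, f) {
    tryCatch(f(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }

  lc <- run_stage("normalize", function() tmm_log2_cpm(expr))
  f <- file.path(out_dir, "log2_cpm.tsv")
  write_expression(lc, f, "tsv", file.path(out_dir, "metadata.tsv"))
  note("normalize", f)

  pc <- run_stage("purity", function()
    correct_purity(lc, mu = purity_mu, sigma = purity_sigma, seed = seed))
  f <- file.path(out_dir, "corrected.tsv")
  write_expression(pc$corrected, f, "tsv",
                   file.path(out_dir, "metadata_corrected.tsv"))
  note("purity", f)

  axis <- run_stage("fit_axis", function()
    fit_stemness_axis(pc$corrected, signature, k = k))
  f <- file.path(out_dir, "axis.tsv")
  write_axis(axis, f)
  note("fit_axis", f)
  note("fit_axis", paste0(f, ".json"))

  md <- pc$corrected$metadata
  tum <- md$group == "tumor" & !is.na(md$project)
  scores <- predict(axis)[md$sample_id[tum]]
  cl_global <- run_stage("cluster", function()
    assign_clusters(scores, md$project[tum], cluster_rule,
                    patient_id = md$patient_id[tum]))
  f <- file.path(out_dir, "clusters.tsv")
  utils::write.table(as.data.frame(cl_global), f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  note("cluster", f)

  inten <- run_stage("intensity", function() signature_intensity(cl_global))
  f <- file.path(out_dir, "intensity.tsv")
  utils::write.table(as.data.frame(inten), f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  note("intensity", f)

  surv <- NULL
  if (!is.null(clinical)) {
    cl_pt <- assign_clusters(scores, md$project[tum], "per_tumor_median",
                             patient_id = md$patient_id[tum])
    surv <- run_stage("survival", function()
      cluster_survival(cl_pt, clinical))
    f <- file.path(out_dir, "survival.tsv")
    utils::write.table(as.data.frame(surv), f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note("survival", f)
  }

  sc <- NULL
  if (!is.null(cells)) {
    sc <- run_stage("sc_score", function()
      project_cells(axis, normalize_cells(cells)))
    f <- file.path(out_dir, "cell_scores.tsv")
    utils::write.table(as.data.frame(sc), f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note("sc_score", f)
  }

  manifest <- do.call(rbind, manifest)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(normalized = lc, corrected = pc, axis = axis,
                 clusters = cl_global, intensity = inten, survival = surv,
                 cell_scores = sc, manifest = manifest))
}

#' Serialize a stemness axis to TSV plus a JSON sidecar
#'
#' The TSV holds one row per gene (`gene`, `mean`, `loading_PC1`, ...);
#' the `<path>.json` sidecar stores variance-explained fractions and the
#' orientation sign.
#'
#' @param axis a `stemness_axis`.
#' @param path output TSV path.
#' @export
write_axis <- function(axis, path) {
  stopifnot(inherits(axis, "stemness_axis"))
  tab <- data.frame(gene = axis$genes, mean = axis$center,
                    axis$loadings, check.names = FALSE)
  names(tab)[-(1:2)] <- paste0("loading_", colnames(axis$loadings))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(signature = axis$signature,
                            var_explained = axis$var_explained,
                            orientation = axis$orientation),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized stemness axis
#'
#' @param path TSV path written by [write_axis()].
#' @return a `stemness_axis` usable with [predict.stemness_axis()] and
#'   [project_cells()] (training scores are not stored).
#' @export
read_axis <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  loadings <- as.matrix(tab[, grep("^loading_", names(tab)), drop = FALSE])
  colnames(loadings) <- sub("^loading_", "", colnames(loadings))
  rownames(loadings) <- tab$gene
  structure(list(signature = meta$signature, genes = tab$gene,
                 center = stats::setNames(tab$mean, tab$gene), scale = NULL,
                 loadings = loadings,
                 var_explained = meta$var_explained,
                 orientation = meta$orientation,
                 scores = NULL, groups = NULL, metadata = NULL),
            class = "stemness_axis")
}
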