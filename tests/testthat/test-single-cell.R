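toy_umi <- function(counts, patients = NULL, classes = NULL,
                    lesions = NULL) {
  n <- ncol(counts)
  md <- data.frame(sample_id = colnames(counts),
                   group = if (is.null(classes)) "cancer" else classes,
                   cell_class = if (is.null(classes)) "cancer" else classes,
                   patient_id = if (is.null(patients)) "P1" else patients,
                   lesion = if (is.null(lesions)) "primary" else lesions)
  expression_matrix(counts, md, "raw_counts")
}

test_that("cell normalization matches the closed-form transform and is
           depth invariant", {
  counts <- matrix(c(0, 2, 8, 0,
                     5, 0, 1, 4,
                     0, 0, 0, 6,
                     3, 1, 2, 0,
                     2, 7, 0, 0), 5, 4, byrow = TRUE,
                   dimnames = list(paste0("g", 1:5), paste0("c", 1:4)))
  x <- toy_umi(counts)
  norm <- normalize_cells(x, scale_factor = 1e4)
  want <- log2(1 + sweep(counts, 2, 1e4 / colSums(counts), "*"))
  expect_equal(as.matrix(norm$values), want)
  expect_equal(as.matrix(norm$values)[counts == 0], rep(0, sum(counts == 0)))
  # doubling a cell's counts changes nothing after normalization
  x2 <- x; x2$values[, 2] <- x$values[, 2] * 2
  norm2 <- normalize_cells(x2)
  expect_equal(as.matrix(norm2$values)[, 2],
               as.matrix(normalize_cells(x)$values)[, 2])
  # sparse input takes the sparse path and agrees with the dense one
  xs <- x
  xs$values <- methods::as(Matrix::Matrix(counts, sparse = TRUE),
                           "CsparseMatrix")
  expect_equal(as.matrix(normalize_cells(xs)$values), want)
  # zero-total cells are dropped with a message
  counts0 <- counts; counts0[, 3] <- 0
  expect_message(n0 <- normalize_cells(toy_umi(counts0)), "zero total")
  expect_equal(ncol(n0$values), 3)
})

sc_axis <- function(seed = 50) {
  sim <- simulate_bulk(n_genes = 1000, n_signature = 150, seed = seed)
  cx <- correct_purity(tmm_log2_cpm(sim$expr), seed = seed)
  fit_stemness_axis(cx$corrected, sim$truth$signature_genes)
}

test_that("cell projection is linear and zero at the axis gene means", {
  ax <- sc_axis()
  mu <- matrix(ax$center, dimnames = list(ax$genes, "mu"))
  vals <- cbind(mu, 2 * mu, 0.5 * mu)
  colnames(vals) <- c("c1", "c2", "c3")
  cells <- toy_umi(vals)
  cells$value_scale <- "log2_norm" # already on the axis scale
  cs <- project_cells(ax, cells)
  expect_equal(cs$score[1], 0, tolerance = 1e-10)
  # pseudobulk equals the mean of cell scores (linearity)
  pb <- matrix(rowMeans(as.matrix(cells$values)),
               dimnames = list(rownames(cells$values), "pb"))
  pbx <- toy_umi(pb)
  pbx$value_scale <- "log2_norm"
  expect_equal(project_cells(ax, pbx)$score, mean(cs$score),
               tolerance = 1e-8)
})

test_that("projected scores track the planted latent despite dropout at
           80% sparsity", {
  # signature size comparable to the full stemness set, so the projection
  # can average over dropout
  simb <- simulate_bulk(n_genes = 2000, n_signature = 500, seed = 51)
  cx <- correct_purity(tmm_log2_cpm(simb$expr), seed = 51)
  ax <- fit_stemness_axis(cx$corrected, simb$truth$signature_genes)
  simc <- simulate_cells(n_patients = 8, cells_per_patient = 60,
                         normal_cells_per_patient = 20, dropout = 0.8,
                         n_genes = 2000, n_signature = 500,
                         depth_meanlog = log(1e4), seed = 51)
  sparsity <- 1 - length(simc$umi$values@x) / prod(dim(simc$umi$values))
  expect_gte(sparsity, 0.8)
  cs <- project_cells(ax, normalize_cells(simc$umi))
  rho <- cor(cs$score, simc$truth$z[cs$cell_id], method = "spearman")
  expect_gte(abs(rho), 0.8)
})

test_that("insufficient gene overlap raises an error; absent genes
           contribute -mean*loading", {
  ax <- sc_axis(seed = 52)
  simc <- simulate_cells(n_patients = 2, cells_per_patient = 10,
                         normal_cells_per_patient = 0, seed = 52)
  norm <- normalize_cells(simc$umi)
  few <- subset_expr(norm, genes = ax$genes[1:10])
  expect_error(project_cells(ax, few), "min_overlap")
  # dropping some axis genes shifts every score by the same constant
  full <- project_cells(ax, norm)
  drop5 <- subset_expr(norm, genes = setdiff(rownames(norm$values),
                                             ax$genes[1:5]))
  part <- project_cells(ax, drop5)
  manual <- as.vector(
    crossprod(as.matrix(norm$values)[ax$genes[1:5], part$cell_id,
                                     drop = FALSE],
              ax$loadings[ax$genes[1:5], 1])) * ax$orientation
  # treating a dropped gene as zero removes only its observed term
  expect_equal(part$score, full$score - manual, tolerance = 1e-8)
})

test_that("variance decomposition has the right limits and matches aov", {
  g <- rep(letters[1:4], each = 25)
  set.seed(53)
  y_within <- rnorm(100)
  vd <- variance_decomposition(y_within, g)
  expect_lt(vd$fraction, 0.1)
  y_between <- rep(c(0, 2, 4, 6), each = 25)
  vd2 <- variance_decomposition(y_between, g)
  expect_equal(vd2$fraction, 1)
  expect_true(vd$fraction >= 0 && vd$fraction <= 1)
  expect_error(variance_decomposition(y_within, rep("a", 100)), ">= 2")
})

test_that("lesion comparison detects a planted shift and validates input", {
  set.seed(54)
  mk_scores <- function(y, lesion) {
    structure(data.frame(cell_id = seq_along(y), patient_id = "P1",
                         cell_class = "cancer", lesion = lesion,
                         score = y, abs_score = abs(y)),
              class = c("cell_scores", "data.frame"))
  }
  y <- c(rnorm(500), rnorm(500, 1), rnorm(500, -0.2))
  lesion <- rep(c("primary", "metastatic", "normal"), each = 500)
  res <- compare_lesions(mk_scores(y, lesion))
  met_pri <- res$tests[res$tests$class_a == "metastatic" &
                         res$tests$class_b == "primary", ]
  expect_lt(met_pri$p_adj, 0.01)
  expect_gt(met_pri$delta_median, 0.5)
  # identical distributions: no median difference, large p
  y0 <- rep(rnorm(300), 2)
  res0 <- compare_lesions(mk_scores(y0, rep(c("primary", "metastatic"),
                                            each = 300)))
  expect_equal(res0$tests$delta_median, 0)
  expect_gt(res0$tests$p, 0.9)
  expect_error(compare_lesions(mk_scores(rnorm(10), rep("primary", 10))),
               ">= 2")
})

test_that("cancer cells are more score-variable than normal cells on
           planted-signal data", {
  ax <- sc_axis(seed = 55)
  simc <- simulate_cells(n_patients = 10, cells_per_patient = 80,
                         normal_cells_per_patient = 40, seed = 55)
  cs <- project_cells(ax, normalize_cells(simc$umi))
  expect_gt(var(cs$score[cs$cell_class == "cancer"]),
            var(cs$score[cs$cell_class == "normal"]))
})

test_that("bimodality summary flags a two-mode patient", {
  set.seed(56)
  y <- c(rnorm(200, -2, .3), rnorm(200, 2, .3), rnorm(200))
  cs <- structure(data.frame(cell_id = seq_along(y),
                             patient_id = rep(c("bimodal", "bimodal",
                                                "unimodal"), each = 200),
                             cell_class = "cancer", lesion = "primary",
                             score = y, abs_score = abs(y)),
                  class = c("cell_scores", "data.frame"))
  bs <- bimodality_summary(cs)
  expect_true(bs$flagged[bs$group == "bimodal"])
  expect_false(bs$flagged[bs$group == "unimodal"])
})
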