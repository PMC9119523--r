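#' Simulate a bulk expression cohort with a latent stemness gradient
#'
#' Generates raw counts for a cohort spanning normal tissues, adult stem
#' cells, several tumor projects, and ESC/iPSC cultures. A latent
#' stemness level `z` per sample drives a subset of signature genes
#' (log2 effect `loading * z`); group latent means are ordered
#' normal <= ASC < tumors < ESC/iPSC. Tumor samples are contaminated by
#' admixed normal tissue: on the linear scale the expected profile is
#' `purity * pure_tumor_profile + (1 - purity) * normal_profile`, with
#' purity drawn from a Beta distribution — the generative assumption
#' behind consensus-purity regression. Counts follow a negative-binomial
#' observation model around the mixed mean with log-normal library sizes;
#' `dispersion = 0` returns the deterministic expected counts (the
#' noiseless limit).
#'
#' @param n_genes total genes (default 2000).
#' @param n_signature genes loading on the latent axis (default 200).
#' @param n_normal,n_asc,n_esc,n_ipsc samples per non-tumor group.
#' @param tumor_projects named integer vector: samples per tumor project.
#' @param latent_means named list/vector of group latent means
#'   (`normal`, `ASC`, `ESC`, `iPSC`) plus `tumor_project_means`, one per
#'   project.
#' @param latent_sd within-group sd of the latent level.
#' @param loading_range range of per-gene loadings for signature genes.
#' @param noise_sd per-gene, per-sample log2 biological noise sd.
#' @param purity_shape `c(alpha, beta)` of the Beta purity distribution.
#' @param lib_size_meanlog,lib_size_sdlog log-normal library sizes.
#' @param dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); 0 gives the deterministic limit.
#' @param baseline_range range of baseline log2 expression.
#' @param seed integer seed; the same seed reproduces the matrix exactly.
#' @return list with `expr` (an `expr_matrix` of raw counts with full
#'   metadata) and `truth`: `z` (named latent levels), `purity` (true
#'   tumor purities), `signature_genes`, `contaminated_genes` (genes whose
#'   tumor and normal profiles differ, i.e. the signature genes) and
#'   `mixing` (per-gene log-scale effect underlying the contamination).
#' @export
simulate_bulk <- function(n_genes = 2000, n_signature = 200,
                          n_normal = 80, n_asc = 10, n_esc = 15,
                          n_ipsc = 15,
                          tumor_projects = c(TA = 70, TB = 70, TC = 70,
                                             TD = 70),
                          latent_means = list(normal = 0, ASC = 0.3,
                                              ESC = 3, iPSC = 3,
                                              tumor_project_means =
                                                c(0.8, 1.2, 1.6, 2.0)),
                          latent_sd = 0.6,
                          loading_range = c(0.5, 1),
                          noise_sd = 0.3,
                          purity_shape = c(8, 3),
                          lib_size_meanlog = log(5e5), lib_size_sdlog = 0.25,
                          dispersion = 0.1,
                          baseline_range = c(3, 9),
                          seed = 1) {
  stopifnot(n_signature <= n_genes,
            length(latent_means$tumor_project_means) == length(tumor_projects))
  local_rng(seed)(function() {
    genes <- sprintf("g%04d", seq_len(n_genes))
    sig <- genes[seq_len(n_signature)]
    mu_g <- stats::runif(n_genes, baseline_range[1], baseline_range[2])
    l_g <- numeric(n_genes)
    l_g[seq_len(n_signature)] <- stats::runif(n_signature, loading_range[1],
                                              loading_range[2])
    groups <- c(rep("normal", n_normal), rep("ASC", n_asc),
                rep(names(tumor_projects), tumor_projects),
                rep("ESC", n_esc), rep("iPSC", n_ipsc))
    project <- ifelse(groups %in% names(tumor_projects), groups, NA)
    group_kind <- ifelse(is.na(project), groups, "tumor")
    n <- length(groups)
    ids <- sprintf("s%04d", seq_len(n))
    gm <- numeric(n)
    gm[group_kind == "normal"] <- latent_means$normal
    gm[group_kind == "ASC"] <- latent_means$ASC
    gm[group_kind == "ESC"] <- latent_means$ESC
    gm[group_kind == "iPSC"] <- latent_means$iPSC
    for (i in seq_along(tumor_projects))
      gm[project %in% names(tumor_projects)[i]] <-
        latent_means$tumor_project_means[i]
    z <- gm + stats::rnorm(n, 0, latent_sd)
    purity <- rep(NA_real_, n)
    is_tumor <- group_kind == "tumor"
    purity[is_tumor] <- stats::rbeta(sum(is_tumor), purity_shape[1],
                                     purity_shape[2])
    noise <- if (noise_sd > 0)
      matrix(stats::rnorm(n_genes * n, 0, noise_sd), n_genes, n) else 0
    lam_pure <- 2^(mu_g + outer(l_g, z) + noise)
    lam_ref <- 2^(mu_g + l_g * latent_means$normal) # admixed normal profile
    lam <- lam_pure
    lam[, is_tumor] <- sweep(lam_pure[, is_tumor, drop = FALSE], 2,
                             purity[is_tumor], "*") +
      outer(lam_ref, 1 - purity[is_tumor])
    lib <- stats::rlnorm(n, lib_size_meanlog, lib_size_sdlog)
    mu <- sweep(lam, 2, lib / colSums(lam), "*")
    counts <- if (dispersion > 0)
      matrix(stats::rnbinom(n_genes * n, mu = mu, size = 1 / dispersion),
             n_genes, n) else round(mu)
    dimnames(counts) <- list(genes, ids)
    md <- data.frame(sample_id = ids, group = group_kind, project = project,
                     purity = purity, patient_id = ids,
                     lesion = ifelse(is_tumor, "primary",
                                     ifelse(group_kind == "normal",
                                            "normal", NA)))
    list(expr = expression_matrix(counts, md, "raw_counts"),
         truth = list(z = stats::setNames(z, ids),
                      purity = stats::setNames(purity, ids),
                      signature_genes = sig,
                      contaminated_genes = sig,
                      mixing = stats::setNames(l_g, genes)))
  })
}

#' Simulate survival times for Stem/Normal clusters
#'
#' Exponential event times with the baseline hazard multiplied by the
#' hazard ratio for Stem samples; independent exponential censoring with
#' rate chosen so that roughly `censoring_rate` of baseline-arm samples
#' are censored (`censoring_rate = 0` disables censoring).
#'
#' @param clusters either a [assign_clusters()] result (one row per
#'   sample) or `NULL` to generate `n_per_arm` patients per cluster.
#' @param n_per_arm patients per arm when `clusters` is `NULL`.
#' @param baseline_hazard hazard of the Normal cluster.
#' @param hr true hazard ratio (Stem vs Normal).
#' @param censoring_rate approximate fraction censored.
#' @param project project code written to the table.
#' @param seed integer seed.
#' @return a [clinical_table()] with attribute `truth` (the per-patient
#'   cluster labels).
#' @export
simulate_survival <- function(clusters = NULL, n_per_arm = 300,
                              baseline_hazard = 0.1, hr = 2,
                              censoring_rate = 0.2, project = "SIM",
                              seed = 1) {
  if (is.null(clusters)) {
    lab <- rep(c("Stem", "Normal"), each = n_per_arm)
    ids <- sprintf("p%05d", seq_along(lab))
    proj <- rep(project, length(lab))
  } else {
    lab <- clusters$cluster
    ids <- clusters$patient_id
    proj <- clusters$project
  }
  local_rng(seed)(function() {
    h <- baseline_hazard * ifelse(lab == "Stem", hr, 1)
    t_event <- stats::rexp(length(h), rate = h)
    if (censoring_rate > 0) {
      hc <- baseline_hazard * censoring_rate / (1 - censoring_rate)
      t_cens <- stats::rexp(length(h), rate = hc)
    } else {
      t_cens <- rep(Inf, length(h))
    }
    out <- clinical_table(data.frame(
      patient_id = ids, time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens), project = proj))
    attr(out, "truth") <- stats::setNames(lab, ids)
    out
  })
}

#' Simulate a single-cell UMI cohort with patient-level structure
#'
#' Cancer cells carry a latent stemness level composed of a patient
#' effect plus a cell effect; the two components are rescaled after
#' sampling so that the planted between-patient fraction of the latent
#' sum of squares equals `var_fraction` exactly (one-way ANOVA on the
#' noiseless latent values recovers it to machine precision). Normal
#' cells have a weaker, patient-free latent level, so planted cancer-cell
#' score variance exceeds normal-cell score variance. Cells from
#' metastatic patients get an additional latent shift. Counts are
#' per-cell Poisson around depth-scaled rates with Bernoulli dropout.
#'
#' @param n_patients number of patients (default 20).
#' @param cells_per_patient cancer cells per patient (default 200).
#' @param normal_cells_per_patient normal cells per patient (default 50).
#' @param var_fraction planted between-patient fraction of cancer-cell
#'   latent variance (default 0.135).
#' @param total_sd total latent sd of cancer cells (default 1).
#' @param cancer_mean mean latent stemness of cancer cells (default 1.5).
#' @param normal_sd latent sd of normal cells (default 0.3).
#' @param lesion_effect latent shift added to cancer cells of metastatic
#'   patients (default 0; set > 0 to plant a lesion difference).
#' @param frac_metastatic fraction of patients whose tumor cells are
#'   metastatic (default 0.5 when `lesion_effect > 0`, else 0).
#' @param dropout per-entry Bernoulli dropout probability (default 0.2).
#' @param n_genes,n_signature gene-universe and signature sizes.
#' @param depth_meanlog,depth_sdlog log-normal per-cell depths.
#' @param loading_range,baseline_range as in [simulate_bulk()].
#' @param seed integer seed.
#' @return list with `umi` (sparse `expr_matrix` of raw counts; metadata
#'   columns `patient_id`, `cell_class`, `lesion`, `group`) and `truth`:
#'   `z` (latent per cell), `signature_genes`, `var_fraction` (the exact
#'   planted latent between-patient fraction), `lesion` (per patient).
#' @export
simulate_cells <- function(n_patients = 20, cells_per_patient = 200,
                           normal_cells_per_patient = 50,
                           var_fraction = 0.135, total_sd = 1,
                           cancer_mean = 1.5, normal_sd = 0.3,
                           lesion_effect = 0,
                           frac_metastatic = if (lesion_effect > 0) 0.5 else 0,
                           dropout = 0.2, n_genes = 1000, n_signature = 150,
                           depth_meanlog = log(5000), depth_sdlog = 0.3,
                           loading_range = c(0.5, 1),
                           baseline_range = c(1, 5), seed = 1) {
  stopifnot(var_fraction >= 0, var_fraction < 1, dropout >= 0, dropout <= 1)
  local_rng(seed)(function() {
    genes <- sprintf("g%04d", seq_len(n_genes))
    sig <- genes[seq_len(n_signature)]
    mu_g <- stats::runif(n_genes, baseline_range[1], baseline_range[2])
    l_g <- numeric(n_genes)
    l_g[seq_len(n_signature)] <- stats::runif(n_signature, loading_range[1],
                                              loading_range[2])
    patients <- sprintf("P%02d", seq_len(n_patients))
    lesion_p <- rep("primary", n_patients)
    n_met <- round(frac_metastatic * n_patients)
    if (n_met > 0) lesion_p[seq_len(n_met)] <- "metastatic"
    names(lesion_p) <- patients
    # cancer-cell latent: exact between/within sum-of-squares split
    nc <- cells_per_patient
    b <- stats::rnorm(n_patients)
    b <- b - mean(b)
    e <- stats::rnorm(n_patients * nc)
    pat_of_cell <- rep(seq_len(n_patients), each = nc)
    e <- e - stats::ave(e, pat_of_cell) # center within patient
    tot_ss <- total_sd^2 * (n_patients * nc)
    if (var_fraction > 0 && sum(b^2) > 0)
      b <- b * sqrt(var_fraction * tot_ss / (nc * sum(b^2)))
    else b <- b * 0
    e <- e * sqrt((1 - var_fraction) * tot_ss / sum(e^2))
    z_cancer <- cancer_mean + b[pat_of_cell] + e +
      ifelse(lesion_p[pat_of_cell] == "metastatic", lesion_effect, 0)
    nn <- normal_cells_per_patient
    z_normal <- stats::rnorm(n_patients * nn, 0, normal_sd)
    z <- c(z_cancer, z_normal)
    cls <- c(rep("cancer", length(z_cancer)), rep("normal", length(z_normal)))
    pat <- patients[c(pat_of_cell, rep(seq_len(n_patients), each = nn))]
    lesion <- ifelse(cls == "cancer", lesion_p[pat], "normal")
    n_cells <- length(z)
    ids <- sprintf("c%05d", seq_len(n_cells))
    rate <- 2^(mu_g + outer(l_g, z))
    depth <- stats::rlnorm(n_cells, depth_meanlog, depth_sdlog)
    mu <- sweep(rate, 2, depth / colSums(rate), "*")
    if (dropout > 0)
      mu <- mu * (matrix(stats::runif(n_genes * n_cells), n_genes, n_cells) >=
                    dropout)
    counts <- matrix(stats::rpois(n_genes * n_cells, mu), n_genes, n_cells,
                     dimnames = list(genes, ids))
    umi <- methods::as(Matrix::Matrix(counts, sparse = TRUE),
                       "CsparseMatrix")
    md <- data.frame(sample_id = ids, group = cls, cell_class = cls,
                     patient_id = pat, lesion = lesion,
                     project = NA_character_)
    list(umi = expression_matrix(umi, md, "raw_counts"),
         truth = list(z = stats::setNames(z, ids), signature_genes = sig,
                      var_fraction = var_fraction, lesion = lesion_p))
  })
}

#' Construct a signature-assembly fixture with planted stemness genes
#'
#' Builds miniature log2-scale datasets exercising every selector: two
#' tissue atlases (stem-like target group vs several tissues), three
#' differentiation time courses, and two pluripotency-factor knockdown
#' experiments. Planted genes exceed every dataset's thresholds with a
#' wide margin; decoys are constructed to fail at least one selector
#' (atlas-only, timeseries-only, knockdown-only, globally flat, or
#' low-expression). Returned selector configurations use fold-change 0.05
#' and expression-level 3 cutoffs.
#'
#' @param seed integer seed.
#' @param n_genes gene-universe size (default 100).
#' @param n_planted planted stemness genes (default 10).
#' @return list with `atlas` (list of 2 `expr_matrix`), `atlas_cfg`,
#'   `timeseries` (list of 3), `ts_cfg`, `knockdown` (list of 2),
#'   `kd_cfg`, `planted` (gene ids), `decoys` (named list by class).
#' @export
simulate_assembly_fixture <- function(seed = 1, n_genes = 100,
                                      n_planted = 10) {
  stopifnot(n_planted <= n_genes - 40)
  local_rng(seed)(function() {
    genes <- sprintf("g%03d", seq_len(n_genes))
    planted <- genes[seq_len(n_planted)]
    # decoy classes occupy the following 40 genes
    decoys <- list(atlas_only = genes[n_planted + 1:10],
                   ts_only = genes[n_planted + 11:20],
                   kd_only = genes[n_planted + 21:30],
                   low_expr = genes[n_planted + 31:40])
    base <- stats::runif(n_genes, 4, 8)
    base[genes %in% decoys$low_expr] <- -6 # below the E cutoff everywhere
    eff <- 2 # planted log2 effect, far above the 0.05 cutoff
    mk <- function(up_in_first, groups, extra_md = NULL) {
      n <- length(groups)
      # noise well below the 0.05 fold-change cutoff so decoys cannot
      # cross a threshold by chance
      v <- matrix(base + stats::rnorm(n_genes * n, 0, 0.01), n_genes, n)
      first <- groups == groups[1]
      v[up_in_first, first] <- v[up_in_first, first] + eff
      dimnames(v) <- list(genes, sprintf("%s_%d", groups, seq_len(n)))
      md <- data.frame(sample_id = colnames(v), group = groups)
      if (!is.null(extra_md)) md <- cbind(md, extra_md)
      expression_matrix(v, md, "log2_microarray")
    }
    up_atlas <- genes %in% c(planted, decoys$atlas_only, decoys$low_expr)
    up_ts <- genes %in% c(planted, decoys$ts_only, decoys$low_expr)
    up_kd <- genes %in% c(planted, decoys$kd_only, decoys$low_expr)
    atlas <- list(
      mk(up_atlas, rep(c("blastocyst", "liver", "brain", "muscle", "skin"),
                       each = 2)),
      mk(up_atlas, rep(c("mESC", "kidney", "lung", "heart", "spleen"),
                       each = 2)))
    atlas_cfg <- list(
      selector_config(0.05, 3, min_comparisons = 4,
                      target_group = "blastocyst"),
      selector_config(0.05, 3, min_comparisons = 4, target_group = "mESC"))
    ts <- lapply(c("J1", "R1", "v6.5"), function(line) {
      tp <- rep(c(0, 168, 336), each = 2) # hours over 14 days
      mk(up_ts, rep(paste0(line, "_t", c(0, 168, 336)), each = 2),
         extra_md = data.frame(timepoint = tp))
    })
    ts_cfg <- selector_config(0.05, 3)
    kd <- lapply(c("POU5F1", "NANOG"), function(tf) {
      mk(up_kd, rep(c("control", "knockdown"), each = 2))
    })
    kd_cfg <- selector_config(0.05, 3)
    list(atlas = atlas, atlas_cfg = atlas_cfg, timeseries = ts,
         ts_cfg = ts_cfg, knockdown = kd, kd_cfg = kd_cfg,
         planted = planted, decoys = decoys)
  })
}
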