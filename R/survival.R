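#' Validate a clinical survival table
#'
#' @param df data.frame with columns `patient_id`, `time` (non-negative),
#'   `event` (0/1) and `project`.
#' @return the validated data.frame (class `clinical_table`).
#' @export
clinical_table <- function(df) {
  df <- as.data.frame(df)
  need <- c("patient_id", "time", "event", "project")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("clinical table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(df$time < 0)) stop("negative survival times")
  if (!all(df$event %in% c(0, 1))) stop("event must be 0/1")
  if (anyDuplicated(df[c("patient_id", "project")]))
    stop("duplicate patient within a project")
  structure(df, class = c("clinical_table", "data.frame"))
}

#' Read a clinical survival TSV
#'
#' Columns: `patient_id`, `time`, `event`, `project`.
#'
#' @param path file path.
#' @return a [clinical_table()].
#' @export
read_clinical <- function(path) {
  clinical_table(utils::read.delim(path,
                                   colClasses = c(patient_id = "character")))
}

#' Cox proportional-hazards comparison of Stem vs Normal clusters
#'
#' For each tumor project, fits a proportional-hazards model with a single
#' binary covariate (Stem = 1, Normal = 0; Efron tie handling) on overall
#' survival, reporting the hazard ratio with its Wald 95% CI and p-value,
#' the logrank test p-value, and Benjamini-Hochberg adjusted Wald p-values
#' across projects. Projects with no events or an empty cluster are
#' flagged non-estimable (`NA` estimates, `estimable = FALSE`).
#'
#' @param assignment a [assign_clusters()] result (typically under the
#'   per-tumor-median rule, which yields balanced clusters).
#' @param clinical a [clinical_table()]; joined by `patient_id` and
#'   `project`.
#' @param conf_level confidence level for the hazard-ratio CI.
#' @return data.frame (class `survival_result`) with one row per project:
#'   `project`, `n`, `n_events`, `hr`, `ci_lo`, `ci_hi`, `p_wald`,
#'   `p_logrank`, `p_adj`, `estimable`.
#' @export
cluster_survival <- function(assignment, clinical, conf_level = 0.95) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  clinical <- clinical_table(clinical)
  dat <- merge(as.data.frame(assignment)[c("patient_id", "project", "cluster")],
               clinical, by = c("patient_id", "project"))
  if (!nrow(dat)) stop("no overlap between assignment and clinical table")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  rows <- lapply(sort(unique(dat$project)), function(pj) {
    d <- dat[dat$project == pj, , drop = FALSE]
    na_row <- data.frame(project = pj, n = nrow(d), n_events = sum(d$event),
                         hr = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                         p_wald = NA_real_, p_logrank = NA_real_,
                         estimable = FALSE)
    if (sum(d$event) < 1 || length(unique(d$cluster)) < 2) return(na_row)
    d$stem <- as.integer(d$cluster == "Stem")
    fit <- tryCatch(
      survival::coxph(survival::Surv(time, event) ~ stem, data = d,
                      ties = "efron"),
      error = function(e) NULL)
    if (is.null(fit) || is.na(stats::coef(fit))) return(na_row)
    beta <- unname(stats::coef(fit))
    se <- sqrt(unname(stats::vcov(fit)[1, 1]))
    lr <- survival::survdiff(survival::Surv(time, event) ~ stem, data = d)
    p_lr <- stats::pchisq(lr$chisq, df = 1, lower.tail = FALSE)
    data.frame(project = pj, n = nrow(d), n_events = sum(d$event),
               hr = exp(beta), ci_lo = exp(beta - z * se),
               ci_hi = exp(beta + z * se),
               p_wald = 2 * stats::pnorm(-abs(beta / se)),
               p_logrank = p_lr, estimable = TRUE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  est <- which(out$estimable)
  out$p_adj[est] <- bh_adjust(out$p_wald[est])
  structure(out, class = c("survival_result", "data.frame"))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate correction (delegates to
#' [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
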