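# File exchange and the end-to-end pipeline driver.
#
# Canonical exchange format is a long-format TSV (UTF-8, header row, '.'
# decimal): one row per patient-drug cell for LC50 matrices, plus an
# `imputation` index column for imputation sets. Wide tables are lossy for
# censor flags, so long format is the source of truth.

#' Write / read a normalized LC50 matrix as long-format TSV
#'
#' @param x an [lc50_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_lc50_table <- function(x, path) {
  values <- as_values_matrix(x)
  long <- data.frame(
    patient_id = rep(rownames(values), times = ncol(values)),
    drug = rep(colnames(values), each = nrow(values)),
    value = as.vector(values),
    stringsAsFactors = FALSE
  )
  long <- long[!is.na(long$value), , drop = FALSE]
  long$value <- sprintf("%.17g", long$value)  # lossless double round-trip
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lc50_table
#' @param patients optional character vector fixing the row order (defaults
#'   to order of first appearance).
#' @param panel drug panel used to validate drug ids; `NULL` skips.
#' @export
read_lc50_table <- function(path, patients = NULL, panel = all_drug_panel()) {
  long <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "drug", "value")
  miss <- setdiff(need, names(long))
  if (length(miss)) stop("missing columns in ", path, ": ", paste(miss, collapse = ", "))
  if (!is.null(panel)) match_drug(unique(long$drug), panel)
  bad <- !is.na(long$value) & (long$value < -1e-8 | long$value > 1 + 1e-8)
  if (any(bad)) {
    k <- which(bad)[1]
    stop(sprintf("normalized LC50 out of [0, 1] at patient %s, drug %s: %g",
                 long$patient_id[k], long$drug[k], long$value[k]))
  }
  dup <- duplicated(long[, c("patient_id", "drug")])
  if (any(dup)) stop("duplicate patient-drug rows in ", path)
  ids <- patients %||% unique(long$patient_id)
  drugs <- if (is.null(panel)) unique(long$drug) else
    intersect(panel$drug, unique(long$drug))
  values <- matrix(NA_real_, length(ids), length(drugs),
                   dimnames = list(ids, drugs))
  values[cbind(match(long$patient_id, ids), match(long$drug, drugs))] <- long$value
  lc50_matrix(values)
}

#' Write / read an imputation set as one long-format TSV
#'
#' @param imputations an [impute_chained()] result.
#' @param path file path.
#' @export
write_imputation_set <- function(imputations, path) {
  rows <- lapply(seq_along(imputations$imputations), function(i) {
    mm <- imputations$imputations[[i]]
    data.frame(patient_id = rep(rownames(mm), times = ncol(mm)),
               drug = rep(colnames(mm), each = nrow(mm)),
               imputation = i, value = sprintf("%.17g", as.vector(mm)),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_imputation_set
#' @export
read_imputation_set <- function(path) {
  long <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "drug", "imputation", "value")
  miss <- setdiff(need, names(long))
  if (length(miss)) stop("missing columns in ", path, ": ", paste(miss, collapse = ", "))
  ids <- unique(long$patient_id)
  drugs <- unique(long$drug)
  ms <- sort(unique(long$imputation))
  mats <- lapply(ms, function(i) {
    li <- long[long$imputation == i, , drop = FALSE]
    values <- matrix(NA_real_, length(ids), length(drugs),
                     dimnames = list(ids, drugs))
    values[cbind(match(li$patient_id, ids), match(li$drug, drugs))] <- li$value
    values
  })
  structure(list(imputations = mats, m = length(mats), maxit = NA_integer_,
                 donors = NA_integer_, seed = NULL, method = "file",
                 excluded = character(0)),
            class = "imputation_set")
}

#' Read a clinical covariate table (TSV/CSV by extension)
#'
#' @param path file with at least a `patient_id` column.
#' @export
read_clinical_table <- function(path) {
  out <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    utils::read.delim(path, stringsAsFactors = FALSE)
  }
  if (!"patient_id" %in% names(out)) stop("clinical table needs a patient_id column")
  if (anyDuplicated(out$patient_id)) stop("duplicate patient_id in ", path)
  out
}

#' Read a pipeline configuration (YAML or JSON by extension)
#'
#' @param path configuration file.
#' @export
read_pipeline_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Run the full pharmacotyping pipeline
#'
#' Chains the analysis stages on a synthetic cohort (or user-supplied
#' matrix): cohort simulation, imputation, consensus clustering, drug-MRD
#' association (per lineage), and survival comparisons, returning all stage
#' outputs plus a machine-readable run manifest.
#'
#' @param config a [cohort_config()] describing the synthetic cohort, or a
#'   list with elements `lc50` (an `lc50_matrix`), `clinical`, `mrd`,
#'   `survival` for file-based input.
#' @param seed master seed for the run.
#' @param m number of imputations.
#' @param k cluster count.
#' @param maxit imputation burn-in cycles.
#' @param threshold consensus assignment threshold; defaults to a majority
#'   of `m` (5 when m = 10).
#' @param min_obs per-column observation threshold passed to
#'   [impute_chained()]; small demonstration cohorts need a lower value
#'   than the default `max(10, 2 * n_drugs)`.
#' @return Object of class `pharmacotype_run`: list with `cohort`,
#'   `imputations`, `clustering`, `profiles`, `association` (per lineage),
#'   `survival` (log-rank + Cox + KM across clusters), and `manifest`.
#' @export
run_pipeline <- function(config = cohort_config(), seed = 1L, m = 10L,
                         k = 6L, maxit = 10L, threshold = NULL,
                         min_obs = NULL) {
  threshold <- threshold %||% max(1L, as.integer(ceiling(m / 2)))
  stages <- character(0)
  tick <- function(s) stages <<- c(stages, s)

  if (inherits(config, "cohort_config")) {
    cohort <- simulate_cohort(config, seed = seed)
    tick("simulate")
  } else {
    cohort <- config
    if (is.null(cohort$lc50)) stop("input bundle must contain an lc50 matrix")
    tick("load")
  }

  imp <- impute_chained(cohort$lc50, m = m, maxit = maxit, seed = seed + 1L,
                        min_obs = min_obs)
  tick("impute")

  cl <- stack_and_cluster(imp, k = k, threshold = threshold)
  tick("cluster")

  mrd15 <- transform_mrd(cohort$mrd$day15)
  assoc <- lapply(split(seq_len(nrow(cohort$clinical)), cohort$clinical$lineage),
                  function(idx) {
    if (length(idx) < 30) return(NULL)
    associate_mrd(as_values_matrix(cohort$lc50)[idx, , drop = FALSE],
                  mrd15[idx],
                  covariates = cohort$clinical[idx, c("protocol", "age", "wbc")])
  })
  tick("associate")

  profiles <- profile_clusters(cl$final, cohort$lc50,
                               subtypes = cohort$clinical$subtype,
                               mrd_categories = categorize_mrd(cohort$mrd$day15, 15))
  tick("profile")

  surv <- NULL
  if (!is.null(cohort$survival)) {
    sdf <- data.frame(time = cohort$survival$efs_time,
                      event = cohort$survival$event,
                      arm = cohort$survival$arm,
                      cluster = factor(cl$final),
                      stringsAsFactors = FALSE)
    sdf <- sdf[stats::complete.cases(sdf), , drop = FALSE]
    surv <- list(
      km = km_estimate(sdf$time, sdf$event, sdf$cluster),
      logrank = logrank_test(sdf$time, sdf$event, sdf$cluster),
      cox = tryCatch(cox_fit(sdf, terms = "cluster", arm = "arm"),
                     error = function(e) e),
      n = nrow(sdf)
    )
    tick("survival")
  }

  manifest <- list(
    stages = stages,
    seed = seed,
    n_patients = nrow(as_values_matrix(cohort$lc50)),
    n_drugs = ncol(as_values_matrix(cohort$lc50)),
    observed_cells = sum(!is.na(as_values_matrix(cohort$lc50))),
    stacked_dim = dim(do.call(rbind, imp$imputations)),
    m = m, k = k, maxit = maxit, threshold = threshold,
    assigned = sum(!is.na(cl$final)),
    unassigned = sum(is.na(cl$final))
  )
  structure(list(cohort = cohort, imputations = imp, clustering = cl,
                 profiles = profiles, association = assoc, survival = surv,
                 manifest = manifest),
            class = "pharmacotype_run")
}

#' @export
print.pharmacotype_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("pharmacotype_run: %d patients x %d drugs (%d observed cells)\n",
              m$n_patients, m$n_drugs, m$observed_cells))
  cat(sprintf("stages: %s\n", paste(m$stages, collapse = " -> ")))
  cat(sprintf("stacked matrix %d x %d; %d assigned / %d unassigned\n",
              m$stacked_dim[1], m$stacked_dim[2], m$assigned, m$unassigned))
  invisible(x)
}

#' Render summary figures for a pipeline run
#'
#' Writes (as PDF) the cluster heatmap over assigned patients, a forest
#' plot of the MRD association coefficients, and Kaplan-Meier curves per
#' cluster. Figures whose upstream results are missing are skipped with a
#' warning.
#'
#' @param run a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
render_reports <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  final <- run$clustering$final
  values <- as_values_matrix(run$cohort$lc50)
  assigned <- !is.na(final)
  if (any(assigned)) {
    f <- file.path(dir, "cluster_heatmap.pdf")
    grDevices::pdf(f, width = 8, height = 6)
    ord <- order(final[assigned])
    mat <- Reduce(`+`, run$imputations$imputations) / run$imputations$m
    mat <- mat[assigned, , drop = FALSE][ord, , drop = FALSE]
    graphics::image(t(mat), axes = FALSE, col = grDevices::hcl.colors(50, "RdBu", rev = TRUE),
                    main = "Pharmacotype clusters (mean imputed LC50)")
    graphics::axis(1, at = seq(0, 1, length.out = ncol(mat)),
                   labels = colnames(mat), las = 2, cex.axis = 0.6)
    grDevices::dev.off()
    files <- c(files, f)
  } else {
    warning("no assigned patients; skipping cluster heatmap")
  }

  assoc <- Filter(Negate(is.null), run$association)
  if (length(assoc)) {
    f <- file.path(dir, "mrd_forest.pdf")
    grDevices::pdf(f, width = 7, height = 6)
    a <- assoc[[1]]
    a <- a[!is.na(a$beta), , drop = FALSE]
    o <- order(a$beta)
    sig_pos <- !is.na(a$p_bh) & a$p_bh < 0.05 & a$beta > 0
    sig_neg <- !is.na(a$p_bh) & a$p_bh < 0.05 & a$beta < 0
    col <- ifelse(sig_pos, "red3", ifelse(sig_neg, "blue3", "black"))[o]
    graphics::plot(a$beta[o], seq_along(o), xlim = range(c(a$ci_lower, a$ci_upper)),
                   pch = 16, col = col, yaxt = "n",
                   xlab = "beta (log10 MRD per unit LC50)", ylab = "",
                   main = "Drug LC50 vs day-15 MRD")
    graphics::segments(a$ci_lower[o], seq_along(o), a$ci_upper[o], seq_along(o), col = col)
    graphics::abline(v = 0, lty = 2)
    graphics::axis(2, at = seq_along(o), labels = a$drug[o], las = 2, cex.axis = 0.6)
    grDevices::dev.off()
    files <- c(files, f)
  } else {
    warning("no association results; skipping forest plot")
  }

  if (!is.null(run$survival)) {
    f <- file.path(dir, "km_clusters.pdf")
    grDevices::pdf(f, width = 7, height = 6)
    graphics::plot(run$survival$km$fit, col = seq_len(run$clustering$k),
                   xlab = "Years from diagnosis", ylab = "EFS",
                   main = sprintf("EFS by pharmacotype cluster (log-rank p = %.3g)",
                                  run$survival$logrank$p))
    grDevices::dev.off()
    files <- c(files, f)
  } else {
    warning("no survival results; skipping KM curves")
  }
  invisible(files)
}
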