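# Pharmacotype clusters: hierarchical clustering of the stacked imputed
# LC50 matrices with a consensus assignment rule.
#
# All m completed matrices are stacked ((m*N) x D), clustered with
# agglomerative hierarchical clustering on Manhattan distances, and the
# tree is cut at k clusters. Because every patient's m replicate rows hang
# off one shared tree, the cluster labels are automatically comparable
# across imputations; a patient receives a final label only when the same
# label recurs in at least `threshold` of the m replicates.

#' Consensus clustering of stacked imputed LC50 matrices
#'
#' @param imputations an [impute_chained()] result (all matrices complete).
#' @param k number of clusters to cut the tree at (6 in the study design).
#' @param linkage agglomeration method: `"complete"` (default) or
#'   `"average"`; both are compatible with Manhattan distances (Ward is
#'   Euclidean-specific). Complete linkage is the default because a fixed-k
#'   cut of an average-linkage tree on imputed data tends to spend clusters
#'   on outlier twigs, merging true groups.
#' @param threshold minimum number of replicate labels required for a final
#'   assignment (5 of 10 by default). A tie between two labels that both
#'   reach the threshold leaves the patient unassigned with a tie flag.
#' @return Object of class `consensus_clustering`: list with `k`, `labels`
#'   (m x N matrix of per-imputation labels), `final` (per-patient label,
#'   `NA` when unassigned), `tie` (logical), `tree` (hclust of the stacked
#'   matrix), `threshold`, `m`, `assigned_fraction`.
#' @export
stack_and_cluster <- function(imputations, k = 6L,
                              linkage = c("complete", "average"),
                              threshold = 5L) {
  linkage <- match.arg(linkage)
  mats <- imputations$imputations
  m <- length(mats)
  if (any(vapply(mats, anyNA, logical(1)))) stop("imputed matrices must be complete")
  n <- nrow(mats[[1]])
  stacked <- do.call(rbind, mats)
  if (k < 2) stop("k must be at least 2")
  if (k > nrow(unique(stacked))) stop("k exceeds the number of distinct rows")
  tree <- stats::hclust(stats::dist(stacked, method = "manhattan"),
                        method = linkage)
  cut <- stats::cutree(tree, k = k)
  labels <- matrix(cut, nrow = m, ncol = n, byrow = TRUE,
                   dimnames = list(NULL, rownames(mats[[1]])))
  cons <- consensus_assign(labels, threshold = threshold)
  structure(list(k = k, labels = labels, final = cons$final, tie = cons$tie,
                 tree = tree, linkage = linkage, threshold = threshold, m = m,
                 assigned_fraction = mean(!is.na(cons$final))),
            class = "consensus_clustering")
}

#' @export
print.consensus_clustering <- function(x, ...) {
  cat(sprintf("consensus_clustering: k=%d, m=%d, threshold=%d; %d/%d patients assigned (%.1f%%)\n",
              x$k, x$m, x$threshold, sum(!is.na(x$final)), length(x$final),
              100 * x$assigned_fraction))
  invisible(x)
}

#' Consensus label from replicate cluster assignments
#'
#' The label reaching at least `threshold` of the `m` replicate assignments
#' wins; if two labels both reach the threshold (a 5/5 split at m = 10) or
#' none does, the patient is left unassigned.
#'
#' @param labels an m x N matrix of replicate labels (or a length-m vector
#'   for one patient).
#' @param threshold minimum count for assignment.
#' @return List with `final` (per-patient label, `NA` if unassigned) and
#'   `tie` (logical: unassigned because two labels tied at the threshold).
#' @export
#' @examples
#' consensus_assign(c(1, 1, 1, 1, 2, 2, 2, 2, 3, 3))       # unassigned
#' consensus_assign(rep(3, 10))                             # 3
consensus_assign <- function(labels, threshold = 5L) {
  if (is.null(dim(labels))) labels <- matrix(labels, ncol = 1)
  one <- function(v) {
    tab <- table(v)
    top <- tab[tab >= threshold]
    if (length(top) == 1L) {
      c(final = as.integer(names(top)), tie = 0L)
    } else {
      c(final = NA_integer_, tie = as.integer(length(top) > 1L))
    }
  }
  res <- apply(labels, 2, one)
  list(final = stats::setNames(res["final", ], colnames(labels)),
       tie = res["tie", ] == 1L)
}

#' Hierarchical clustering of drugs by correlation distance
#'
#' Distance between two drugs is `1 - r` where `r` is the Pearson
#' correlation of their LC50 columns over pairwise-complete observations;
#' used for ordering drugs in heatmaps.
#'
#' @param x [lc50_matrix()], plain matrix, or [impute_chained()] result (in
#'   which case the element-wise mean of the imputed matrices is used).
#' @param linkage agglomeration method.
#' @return An `hclust` tree over drugs.
#' @export
cluster_drugs <- function(x, linkage = "average") {
  if (inherits(x, "imputation_set")) {
    x <- Reduce(`+`, x$imputations) / length(x$imputations)
  }
  values <- as_values_matrix(x)
  if (ncol(values) < 3) stop("need at least 3 drugs")
  sds <- apply(values, 2, stats::sd, na.rm = TRUE)
  if (any(is.na(sds) | sds == 0)) {
    stop("zero-variance drug column(s): ",
         paste(colnames(values)[is.na(sds) | sds == 0], collapse = ", "))
  }
  r <- stats::cor(values, use = "pairwise.complete.obs")
  if (anyNA(r)) {
    bad <- unique(colnames(r)[which(is.na(r), arr.ind = TRUE)[, 2]])
    stop("correlation undefined (insufficient pairwise overlap) for: ",
         paste(bad, collapse = ", "))
  }
  stats::hclust(stats::as.dist(1 - r), method = linkage)
}

#' Per-cluster drug sensitivity and composition profiles
#'
#' @param final per-patient consensus labels (`NA` = unassigned, excluded).
#' @param x [lc50_matrix()] or matrix of normalized LC50 values.
#' @param subtypes optional per-patient molecular subtype labels.
#' @param mrd_categories optional per-patient MRD category factor (one time
#'   point).
#' @return Object of class `cluster_profiles`: list with `medians` (cluster
#'   x drug median LC50), `subtype_fractions`, `mrd_fractions` (fractions
#'   sum to 1 per cluster), `sizes`, and chi-squared heterogeneity tests
#'   `subtype_test` / `mrd_test` across clusters.
#' @export
profile_clusters <- function(final, x, subtypes = NULL, mrd_categories = NULL) {
  values <- as_values_matrix(x)
  keep <- !is.na(final)
  if (!any(keep)) stop("no assigned patients to profile")
  final <- final[keep]
  values <- values[keep, , drop = FALSE]
  clusters <- sort(unique(final))
  medians <- t(vapply(clusters, function(cl) {
    apply(values[final == cl, , drop = FALSE], 2, stats::median, na.rm = TRUE)
  }, numeric(ncol(values))))
  rownames(medians) <- clusters

  frac_table <- function(v) {
    v <- factor(v[keep])
    tab <- table(final, v)
    test <- if (all(dim(tab) >= 2)) {
      suppressWarnings(stats::chisq.test(tab))
    }  # heterogeneity undefined for a single cluster or single category
    list(fractions = prop.table(tab, margin = 1), test = test)
  }
  st <- if (!is.null(subtypes)) frac_table(subtypes) else NULL
  mr <- if (!is.null(mrd_categories)) frac_table(mrd_categories) else NULL

  structure(list(
    medians = medians,
    sizes = table(final),
    subtype_fractions = st$fractions,
    subtype_test = st$test,
    mrd_fractions = mr$fractions,
    mrd_test = mr$test
  ), class = "cluster_profiles")
}

#' @export
print.cluster_profiles <- function(x, ...) {
  cat("cluster_profiles:", nrow(x$medians), "clusters; sizes:",
      paste(sprintf("%s=%d", names(x$sizes), x$sizes), collapse = ", "), "\n")
  if (!is.null(x$subtype_test)) {
    cat(sprintf("subtype heterogeneity: X2=%.2f, p=%.3g\n",
                x$subtype_test$statistic, x$subtype_test$p.value))
  }
  invisible(x)
}
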