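# Chained-equations multiple imputation (sequential regression) of the
# LC50 matrix, implemented in-repo.
#
# Engine: missing cells are initialized with column medians; columns are
# then visited in order of descending missingness, each regressed on all
# other columns over its observed rows with a Bayesian linear model, and
# missing entries are filled by predictive mean matching (type-1 matching,
# 5 donors): a donor is drawn from the observed values whose predicted mean
# (under the posterior-mode coefficients) is closest to the missing cell's
# prediction under the posterior draw. Because every imputed value is an
# observed donor value, imputations automatically respect the [0, 1] range
# of normalized LC50 values. A small relative ridge stabilizes the normal
# equations for collinear or degenerate columns.

# One completed copy of `values` (matrix with NAs), imputed in place.
impute_once <- function(values, maxit = 10L, donors = 5L, ridge = 1e-5) {
  mask <- is.na(values)
  p <- ncol(values)
  # median initialization
  for (j in seq_len(p)) {
    if (any(mask[, j])) {
      values[mask[, j], j] <- stats::median(values[!mask[, j], j])
    }
  }
  visit <- order(colSums(mask), decreasing = TRUE)
  visit <- visit[colSums(mask)[visit] > 0]
  if (!length(visit)) return(values)

  for (it in seq_len(maxit)) {
    for (j in visit) {
      obs <- !mask[, j]
      y <- values[obs, j]
      X <- cbind(1, values[, -j, drop = FALSE])
      Xo <- X[obs, , drop = FALSE]
      Xw <- X[!obs, , drop = FALSE]
      S <- crossprod(Xo)
      diag(S) <- diag(S) * (1 + ridge) + ridge
      R <- chol(S)
      beta_hat <- backsolve(R, forwardsolve(t(R), crossprod(Xo, y)))
      res <- y - Xo %*% beta_hat
      df <- max(length(y) - ncol(Xo), 1)
      sigma2 <- sum(res^2) / stats::rchisq(1, df)
      V <- chol2inv(R)
      beta_star <- beta_hat +
        t(chol(V + diag(ridge * mean(diag(V)) + 1e-12, ncol(V)))) %*%
        stats::rnorm(ncol(Xo)) * sqrt(sigma2)
      yhat_obs <- drop(Xo %*% beta_hat)
      yhat_mis <- drop(Xw %*% beta_star)
      k <- min(donors, length(y))
      # k nearest donors by predicted mean: search a clamped window around
      # the insertion point in the sorted predictions (exact, O(k) per cell)
      ord <- order(yhat_obs)
      ys <- yhat_obs[ord]
      yv <- y[ord]
      n_o <- length(ys)
      n_w <- length(yhat_mis)
      pos <- findInterval(yhat_mis, ys)
      cand <- pmin(pmax(outer(pos, (-k):k, `+`), 1L), n_o)
      D <- abs(matrix(ys[cand], n_w) - yhat_mis)
      if (ncol(cand) > 1) {
        dup <- cand[, -1, drop = FALSE] == cand[, -ncol(cand), drop = FALSE]
        D[, -1][dup] <- Inf      # clamped window edges duplicate candidates
      }
      # draw a random rank in 1..k per cell, then peel off row minima rank
      # by rank (max.col is vectorized across all missing cells)
      rk <- sample.int(k, n_w, replace = TRUE)
      donor <- integer(n_w)
      for (t in seq_len(max(rk))) {
        mc <- max.col(-D, ties.method = "first")
        idx <- cbind(seq_len(n_w), mc)
        hit <- rk == t
        donor[hit] <- cand[idx][hit]
        D[idx] <- Inf
      }
      values[!obs, j] <- yv[donor]
    }
  }
  values
}

#' Multiple imputation of an LC50 matrix by chained equations
#'
#' Produces `m` completed copies of the matrix by sequential regression with
#' predictive mean matching (see the module comments for engine details).
#' Observed cells are never altered. Columns with fewer than
#' `max(10, 2 * ncol)` observed values are excluded (with a warning) or
#' raise an error, depending on `on_sparse_column`; all-missing rows are an
#' error.
#'
#' @param x an [lc50_matrix()] or a numeric matrix with `NA` for missing
#'   cells (any real-valued scale is accepted; the \[0,1\] constraint applies
#'   to `lc50_matrix` inputs only).
#' @param m number of imputed datasets (10 in the study design).
#' @param maxit burn-in cycles through the columns per dataset.
#' @param donors predictive-mean-matching donor pool size.
#' @param seed integer seed making the whole set reproducible; the caller's
#'   RNG state is left untouched.
#' @param on_sparse_column `"exclude"` or `"error"`.
#' @param min_obs minimum observed values required per column with missing
#'   cells; defaults to `max(10, 2 * ncol)`.
#' @return Object of class `imputation_set`: list with `imputations` (list
#'   of `m` completed matrices), `m`, `maxit`, `donors`, `seed`, `method`,
#'   and `excluded` (names of dropped columns).
#' @export
impute_chained <- function(x, m = 10L, maxit = 10L, donors = 5L, seed = NULL,
                           on_sparse_column = c("exclude", "error"),
                           min_obs = NULL) {
  on_sparse_column <- match.arg(on_sparse_column)
  values <- as_values_matrix(x)
  if (ncol(values) < 2) stop("imputation needs at least 2 columns")
  if (any(rowSums(!is.na(values)) == 0)) {
    stop("all-missing rows are not allowed; drop them before imputation")
  }
  min_obs <- min_obs %||% max(10L, 2L * ncol(values))
  n_obs <- colSums(!is.na(values))
  sparse <- n_obs < min_obs & n_obs < nrow(values)  # tiny complete matrices pass
  excluded <- character(0)
  if (any(sparse)) {
    if (on_sparse_column == "error") {
      stop("columns below the observation threshold (", min_obs, "): ",
           paste(colnames(values)[sparse], collapse = ", "))
    }
    excluded <- colnames(values)[sparse]
    warning("excluding sparse column(s): ", paste(excluded, collapse = ", "))
    values <- values[, !sparse, drop = FALSE]
    if (ncol(values) < 2) stop("fewer than 2 columns remain after exclusion")
  }
  imputations <- with_seed(seed, {
    lapply(seq_len(m), function(i) {
      out <- impute_once(values, maxit = maxit, donors = donors)
      if (any(!is.finite(out))) {
        stop("divergent chain: non-finite values in imputation ", i)
      }
      out
    })
  })
  structure(list(imputations = imputations, m = m, maxit = maxit,
                 donors = donors, seed = seed,
                 method = "pmm-chained", excluded = excluded),
            class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  d <- dim(x$imputations[[1]])
  cat(sprintf("imputation_set: m=%d completed %d x %d matrices (%s, maxit=%d, donors=%d)\n",
              x$m, d[1], d[2], x$method, x$maxit, x$donors))
  if (length(x$excluded)) cat("excluded columns:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Leave-one-out validation of the imputation procedure
#'
#' For each selected observed cell, the cell is masked, the full chained
#' imputation is rerun with `m` datasets, and the mean, standard deviation
#' and a t-based 95% interval of the `m` imputed values are recorded; the
#' cell is "covered" when the true observed value falls inside the interval.
#'
#' @inheritParams impute_chained
#' @param cells either `NULL` (all observed cells when there are at most
#'   5,000, otherwise 2,000 sampled with the seed), a single count to
#'   subsample, or a two-column matrix of (row, column) indices.
#' @param conf interval coverage level.
#' @return Object of class `loo_report`: list with `cells` (data.frame:
#'   row, col, observed, imputed_mean, imputed_sd, ci_lower, ci_upper,
#'   covered) and `coverage` (fraction covered).
#' @export
loo_validate <- function(x, m = 10L, maxit = 10L, donors = 5L, seed = NULL,
                         cells = NULL, conf = 0.95) {
  values <- as_values_matrix(x)
  if (ncol(values) < 2) stop("imputation needs at least 2 columns")
  obs_idx <- which(!is.na(values), arr.ind = TRUE)
  if (!nrow(obs_idx)) stop("matrix has no observed cells")

  report <- with_seed(seed, {
    if (is.null(cells)) {
      cells <- if (nrow(obs_idx) <= 5000) nrow(obs_idx) else 2000L
    }
    if (is.matrix(cells)) {
      sel <- cells
    } else {
      cells <- as.integer(cells)
      if (cells > nrow(obs_idx)) {
        stop("requested more cells than there are observed values")
      }
      sel <- obs_idx[sample.int(nrow(obs_idx), cells), , drop = FALSE]
    }
    tq <- stats::qt(1 - (1 - conf) / 2, df = m - 1)
    rows <- apply(sel, 1, function(ij) {
      i <- ij[1]; j <- ij[2]
      truth <- values[i, j]
      masked <- values
      masked[i, j] <- NA
      draws <- vapply(seq_len(m), function(r) {
        impute_once(masked, maxit = maxit, donors = donors)[i, j]
      }, numeric(1))
      mu <- mean(draws); s <- stats::sd(draws)
      lo <- mu - tq * s; hi <- mu + tq * s
      c(i, j, truth, mu, s, lo, hi, as.numeric(truth >= lo & truth <= hi))
    })
    as.data.frame(t(rows))
  })
  names(report) <- c("row", "col", "observed", "imputed_mean", "imputed_sd",
                     "ci_lower", "ci_upper", "covered")
  structure(list(cells = report, coverage = mean(report$covered),
                 m = m, conf = conf),
            class = "loo_report")
}

#' @export
print.loo_report <- function(x, ...) {
  cat(sprintf("leave-one-out imputation validation: %d cells, %.0f%% CI coverage = %.3f\n",
              nrow(x$cells), 100 * x$conf, x$coverage))
  invisible(x)
}

#' Compare observed and imputed value distributions per drug
#'
#' Observed-value deciles define the bins; the imputed values (pooled over
#' the `m` datasets, at the originally missing cells only) are binned
#' identically and compared with a chi-squared test; p values are BH
#' adjusted across the drug family. Bins with fewer than 5 combined counts
#' are merged into their left neighbor.
#'
#' @param x the original (incomplete) matrix or `lc50_matrix`.
#' @param imputations an [impute_chained()] result.
#' @return data.frame with `drug`, `statistic`, `df`, `p`, `p_bh`,
#'   `n_observed`, `n_imputed`.
#' @export
compare_distributions <- function(x, imputations) {
  values <- as_values_matrix(x)
  drugs <- colnames(imputations$imputations[[1]])
  rows <- lapply(drugs, function(d) {
    obs <- values[, d]
    miss <- is.na(obs)
    obs <- obs[!miss]
    imp <- unlist(lapply(imputations$imputations, function(mm) mm[miss, d]))
    out <- data.frame(drug = d, statistic = NA_real_, df = NA_real_,
                      p = NA_real_, n_observed = length(obs),
                      n_imputed = length(imp), stringsAsFactors = FALSE)
    if (!length(imp) || length(obs) < 10) return(out)
    br <- unique(stats::quantile(obs, probs = 0:10 / 10, names = FALSE))
    br[1] <- -Inf; br[length(br)] <- Inf
    if (length(br) < 3) return(out)
    co <- table(cut(obs, br))
    ci <- table(cut(imp, br))
    counts <- rbind(observed = as.numeric(co), imputed = as.numeric(ci))
    # merge sparse bins leftward until all combined bin totals reach 5
    while (ncol(counts) > 2 && any(colSums(counts) < 5)) {
      k <- which(colSums(counts) < 5)[1]
      tgt <- if (k == 1) 2 else k - 1
      counts[, tgt] <- counts[, tgt] + counts[, k]
      counts <- counts[, -k, drop = FALSE]
    }
    if (ncol(counts) < 2) return(out)
    if (identical(as.numeric(counts[1, ]) / sum(counts[1, ]),
                  as.numeric(counts[2, ]) / sum(counts[2, ]))) {
      out$statistic <- 0; out$df <- ncol(counts) - 1; out$p <- 1
      return(out)
    }
    ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
    out$statistic <- unname(ct$statistic)
    out$df <- unname(ct$parameter)
    out$p <- ct$p.value
    out
  })
  out <- do.call(rbind, rows)
  out$p_bh <- NA_real_
  ok <- !is.na(out$p)
  out$p_bh[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  out
}

#' Compare regression coefficients from measured versus imputed data
#'
#' For each drug, the MRD regression coefficient is estimated once from the
#' measured values only (rows where the drug was assayed) and once pooled
#' across the imputed datasets (Rubin's rules: the pooled estimate is the
#' mean of the per-dataset coefficients); the two coefficient vectors are
#' then compared by Pearson correlation.
#'
#' @param x original matrix or `lc50_matrix`.
#' @param imputations an [impute_chained()] result.
#' @param mrd_log10 log10 MRD response, one value per patient (row).
#' @param covariates optional data.frame of adjustment covariates (see
#'   [regress_lc50_on_mrd()]).
#' @return List with `table` (per-drug measured and pooled beta), `r`,
#'   `p`, `n_drugs`.
#' @export
compare_coefficients <- function(x, imputations, mrd_log10, covariates = NULL) {
  values <- as_values_matrix(x)
  drugs <- colnames(imputations$imputations[[1]])
  if (length(drugs) < 3) stop("need at least 3 drugs to correlate coefficients")
  beta_of <- function(lc50, keep) {
    fit <- tryCatch(
      regress_lc50_on_mrd(lc50[keep], mrd_log10[keep],
                          covariates = if (is.null(covariates)) NULL
                                       else covariates[keep, , drop = FALSE]),
      error = function(e) NULL
    )
    if (is.null(fit)) NA_real_ else fit$beta
  }
  tab <- do.call(rbind, lapply(drugs, function(d) {
    keep_meas <- !is.na(values[, d]) & !is.na(mrd_log10)
    b_meas <- beta_of(values[, d], keep_meas)
    b_imp <- mean(vapply(imputations$imputations, function(mm) {
      beta_of(mm[, d], !is.na(mrd_log10))
    }, numeric(1)))
    data.frame(drug = d, beta_measured = b_meas, beta_imputed = b_imp,
               stringsAsFactors = FALSE)
  }))
  ok <- stats::complete.cases(tab[, c("beta_measured", "beta_imputed")])
  r <- NA_real_; p <- NA_real_
  if (sum(ok) >= 3 &&
      stats::sd(tab$beta_measured[ok]) > 0 && stats::sd(tab$beta_imputed[ok]) > 0) {
    ct <- stats::cor.test(tab$beta_measured[ok], tab$beta_imputed[ok])
    r <- unname(ct$estimate); p <- ct$p.value
  } else {
    warning("correlation undefined (fewer than 3 valid pairs or zero variance)")
  }
  list(table = tab, r = r, p = p, n_drugs = sum(ok))
}
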