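# Permutation-based group comparison of network metrics: per-density tests,
# AUC summary tests, and nodal comparisons with FDR correction. Group labels
# are shuffled *before* residualization, so the covariate regression is
# honestly recomputed for every permutation.

# default nuisance covariates: everything except WMH-type columns, which are
# reserved for the optional adjusted resilience analysis
.default_covariates <- function(cohort) {
  nm <- names(cohort$covariates)
  nm[!grepl("^wmh", nm, ignore.case = TRUE)]
}

# Residualize -> correlate -> nested-threshold -> metric curves for one
# labeling of the cohort. Lean on purpose: this is the permutation hot path.
# Returns metrics x densities x groups array (groups in level order).
.metric_curves <- function(thickness, labels, covariates, covariate_names,
                           grid, metrics, per_group = TRUE,
                           rank_absolute = FALSE) {
  R <- ncol(thickness)
  Emax <- R * (R - 1) / 2
  groups <- levels(labels)
  out <- array(NA_real_, dim = c(length(metrics), length(grid), length(groups)),
               dimnames = list(metrics, NULL, groups))
  funs <- .metric_registry[metrics]
  resid_all <- NULL
  if (!per_group && length(covariate_names) >= 0) {
    X <- cbind(1, as.matrix(covariates[, covariate_names, drop = FALSE]))
    resid_all <- thickness - X %*% qr.coef(qr(X), thickness)
  }
  for (gi in seq_along(groups)) {
    idx <- which(labels == groups[gi])
    if (per_group) {
      Y <- thickness[idx, , drop = FALSE]
      X <- cbind(1, as.matrix(covariates[idx, covariate_names, drop = FALSE]))
      res <- Y - X %*% qr.coef(qr(X), Y)
    } else {
      res <- resid_all[idx, , drop = FALSE]
    }
    r <- stats::cor(res)
    if (anyNA(r)) r[is.na(r)] <- 0
    diag(r) <- 0
    eo <- .edge_order(r, rank_absolute)
    need_g <- any(.metric_needs_graph[metrics])
    A <- matrix(0, R, R)
    prevE <- 0L
    for (di in seq_along(grid)) {
      E <- as.integer(.round_half_up(grid[di] * Emax))
      if (E > prevE) {
        sel <- (prevE + 1L):E
        A[cbind(eo$i[sel], eo$j[sel])] <- 1
        A[cbind(eo$j[sel], eo$i[sel])] <- 1
        prevE <- E
      }
      g <- if (need_g)
        igraph::make_undirected_graph(c(rbind(eo$i[seq_len(E)],
                                              eo$j[seq_len(E)])), n = R)
      else NULL
      for (mi in seq_along(funs)) out[mi, di, gi] <- funs[[mi]](A, g)
    }
  }
  out
}

#' Permutation comparison of global network metrics between groups
#'
#' For each of `n_perm` permutations the group labels are shuffled across
#' subjects (preserving group sizes) and the full pipeline — covariate
#' residualization, Pearson association, density thresholding, metric
#' computation — is recomputed, yielding a null distribution of group
#' differences at every density and for the area under the metric-vs-density
#' curve (trapezoidal rule). Two-tailed p-values use the add-one estimator
#' `(1 + #{|null| >= |observed|}) / (n_perm + 1)`, which counts the observed
#' labeling in its own null and therefore never returns 0.
#'
#' If a thresholded network is fragmented at some density, path-based
#' metrics average over reachable pairs (flagged in the observed curves);
#' the permutation is kept so the null sample size stays fixed.
#'
#' @param cohort a validated, *non*-residualized `cohort_table`.
#' @param metrics character vector from [comparable_metrics()].
#' @param grid density grid (see [density_grid()]).
#' @param n_perm number of permutations (1000 is conventional; below 100 a
#'   warning is issued because p-values are unstable).
#' @param seed RNG seed; the full result is bit-reproducible under it.
#' @param covariate_names covariates to residualize against; defaults to all
#'   covariate columns except WMH-type ones.
#' @param per_group,rank_absolute passed to the pipeline (see
#'   [residualize()] and [threshold_at_density()]).
#' @return a `permutation_result`: observed curves per group, observed
#'   differences (first group level minus second), per-density and AUC
#'   p-values, the permutation null differences, and 2.5/97.5 percentile
#'   null bands per density.
#' @export
permute_compare <- function(cohort, metrics = "transitivity",
                            grid = density_grid(), n_perm = 1000, seed = 1,
                            covariate_names = NULL, per_group = TRUE,
                            rank_absolute = FALSE) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (isTRUE(attr(cohort, "residualized")))
    stop("pass the raw cohort; residualization is recomputed per permutation")
  metrics <- match.arg(metrics, comparable_metrics(), several.ok = TRUE)
  if (n_perm < 100)
    warning("n_perm < 100 gives unstable p-values")
  covariate_names <- covariate_names %||% .default_covariates(cohort)
  th <- cohort$thickness
  labels <- cohort$group
  covs <- cohort$covariates
  obs <- .metric_curves(th, labels, covs, covariate_names, grid, metrics,
                        per_group, rank_absolute)
  obs_diff <- obs[, , 1, drop = FALSE][, , 1] - obs[, , 2, drop = FALSE][, , 1]
  obs_diff <- matrix(obs_diff, nrow = length(metrics),
                     dimnames = list(metrics, NULL))
  null_diffs <- array(NA_real_,
                      dim = c(n_perm, length(grid), length(metrics)),
                      dimnames = list(NULL, NULL, metrics))
  set.seed(.sub_seed(seed, 11L))
  for (p in seq_len(n_perm)) {
    lp <- labels[sample.int(length(labels))]
    cur <- .metric_curves(th, lp, covs, covariate_names, grid, metrics,
                          per_group, rank_absolute)
    null_diffs[p, , ] <- t(cur[, , 1, drop = FALSE][, , 1] -
                           cur[, , 2, drop = FALSE][, , 1])
  }
  p_density <- matrix(NA_real_, length(metrics), length(grid),
                      dimnames = list(metrics, NULL))
  ci_lo <- ci_hi <- p_density
  obs_auc <- stats::setNames(numeric(length(metrics)), metrics)
  p_auc <- stats::setNames(numeric(length(metrics)), metrics)
  for (mi in seq_along(metrics)) {
    nd <- null_diffs[, , mi, drop = FALSE][, , 1, drop = FALSE]
    nd <- matrix(nd, nrow = n_perm)
    p_density[mi, ] <- (1 + colSums(abs(nd) >=
        rep(abs(obs_diff[mi, ]), each = n_perm))) / (n_perm + 1)
    ci_lo[mi, ] <- apply(nd, 2, stats::quantile, probs = 0.025, names = FALSE)
    ci_hi[mi, ] <- apply(nd, 2, stats::quantile, probs = 0.975, names = FALSE)
    obs_auc[mi] <- .trapz(grid, obs_diff[mi, ])
    null_auc <- apply(nd, 1, function(y) .trapz(grid, y))
    p_auc[mi] <- (1 + sum(abs(null_auc) >= abs(obs_auc[mi]))) / (n_perm + 1)
  }
  structure(list(
    metrics = metrics, grid = grid, groups = levels(labels),
    observed = obs, observed_diff = obs_diff,
    auc_observed = obs_auc, p_auc = p_auc,
    p_density = p_density,
    ci_band = list(lower = ci_lo, upper = ci_hi),
    null_diffs = null_diffs, n_perm = n_perm, seed = seed,
    covariates = covariate_names),
    class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("permutation_result:", x$n_perm, "permutations, grid",
      format(min(x$grid)), "-", format(max(x$grid)),
      "(", length(x$grid), "densities ), diff =",
      x$groups[1], "-", x$groups[2], "\n")
  for (m in x$metrics)
    cat(sprintf("  %-22s AUC diff % .5f  p_auc %.4f  (density p: %s)\n",
                m, x$auc_observed[m], x$p_auc[m],
                paste(sprintf("%.3f", x$p_density[m, ]), collapse = " ")))
  invisible(x)
}

#' AUC summary of a permutation comparison
#'
#' Area under the metric-vs-density difference curve (trapezoidal rule over
#' the grid, which may be non-uniform), with a two-tailed add-one
#' permutation p-value — a single summary of group difference that is less
#' sensitive to the choice of any one threshold.
#'
#' @param result a `permutation_result` from [permute_compare()].
#' @param grid grid to integrate over; defaults to the result's own grid.
#' @return data.frame with `metric`, `auc_diff`, `p_auc`.
#' @export
auc_compare <- function(result, grid = result$grid) {
  stopifnot(inherits(result, "permutation_result"))
  if (length(grid) < 2) stop("AUC needs at least two densities")
  out <- lapply(seq_along(result$metrics), function(mi) {
    obs <- .trapz(grid, result$observed_diff[mi, ])
    nulls <- apply(matrix(result$null_diffs[, , mi], nrow = result$n_perm),
                   1, function(y) .trapz(grid, y))
    data.frame(metric = result$metrics[mi], auc_diff = obs,
               p_auc = (1 + sum(abs(nulls) >= abs(obs))) / (result$n_perm + 1))
  })
  do.call(rbind, out)
}

# nodal metric values for one labeling at a single density
.nodal_values <- function(thickness, labels, covariates, covariate_names,
                          density, metrics, per_group, rank_absolute) {
  groups <- levels(labels)
  R <- ncol(thickness)
  out <- array(NA_real_, dim = c(R, length(metrics), length(groups)),
               dimnames = list(colnames(thickness), metrics, groups))
  for (gi in seq_along(groups)) {
    idx <- which(labels == groups[gi])
    Y <- thickness[idx, , drop = FALSE]
    X <- cbind(1, as.matrix(covariates[idx, covariate_names, drop = FALSE]))
    res <- Y - X %*% qr.coef(qr(X), Y)
    r <- stats::cor(res)
    if (anyNA(r)) r[is.na(r)] <- 0
    diag(r) <- 0
    A <- .adj(suppressWarnings(threshold_at_density(
      structure(r, class = c("association_matrix", "matrix", "array")),
      density, rank_absolute)))
    for (m in metrics) {
      out[, m, gi] <- switch(m,
        degree = colSums(A),
        clustering = unname(nodal_clustering(A)),
        betweenness = unname(node_betweenness(A)))
    }
  }
  out
}

#' Permutation comparison of nodal metrics with FDR correction
#'
#' Between-group differences in nodal degree, clustering and betweenness at
#' a single density (conventionally the minimum density), tested by the
#' same label-permutation scheme as [permute_compare()] and corrected for
#' multiple comparisons across regions by Benjamini-Hochberg FDR within
#' each metric.
#'
#' @inheritParams permute_compare
#' @param density single density; both observed group networks must be
#'   connected at it (i.e. `density >= D_min`) unless
#'   `require_connected = FALSE`.
#' @param metrics subset of `c("degree", "clustering", "betweenness")`.
#' @param require_connected error when an observed group network is
#'   fragmented at `density` (default TRUE; the nodal metrics themselves
#'   remain well defined on fragmented graphs).
#' @return data.frame: `region`, `metric`, `diff` (first level minus
#'   second), `p`, `p_fdr`.
#' @export
nodal_compare <- function(cohort, density, n_perm = 1000, seed = 1,
                          covariate_names = NULL,
                          metrics = c("degree", "clustering", "betweenness"),
                          per_group = TRUE, rank_absolute = FALSE,
                          require_connected = TRUE) {
  stopifnot(inherits(cohort, "cohort_table"))
  metrics <- match.arg(metrics, several.ok = TRUE)
  covariate_names <- covariate_names %||% .default_covariates(cohort)
  th <- cohort$thickness
  labels <- cohort$group
  covs <- cohort$covariates
  if (require_connected) {
    resid <- residualize(cohort, covariate_names, per_group)
    for (g in levels(labels)) {
      net <- suppressWarnings(threshold_at_density(
        build_association(resid, g), density, rank_absolute))
      if (igraph::components(.as_graph(net))$no != 1)
        stop("group ", g, " network is fragmented at density ", density,
             "; choose a density >= D_min")
    }
  }
  obs <- .nodal_values(th, labels, covs, covariate_names, density, metrics,
                       per_group, rank_absolute)
  obs_diff <- obs[, , 1] - obs[, , 2]
  obs_diff <- matrix(obs_diff, ncol = length(metrics),
                     dimnames = list(colnames(th), metrics))
  exceed <- matrix(0, nrow(obs_diff), length(metrics))
  set.seed(.sub_seed(seed, 13L))
  for (p in seq_len(n_perm)) {
    lp <- labels[sample.int(length(labels))]
    cur <- .nodal_values(th, lp, covs, covariate_names, density, metrics,
                         per_group, rank_absolute)
    nd <- matrix(cur[, , 1] - cur[, , 2], ncol = length(metrics))
    exceed <- exceed + (abs(nd) >= abs(obs_diff))
  }
  pmat <- (1 + exceed) / (n_perm + 1)
  out <- do.call(rbind, lapply(seq_along(metrics), function(mi)
    data.frame(region = rownames(obs_diff), metric = metrics[mi],
               diff = obs_diff[, mi], p = pmat[, mi],
               p_fdr = stats::p.adjust(pmat[, mi], method = "BH"),
               row.names = NULL)))
  attr(out, "density") <- density
  attr(out, "n_perm") <- n_perm
  out
}
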