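# Network robustness: sequential node removal (random failure or targeted
# attack by betweenness), tracking the size of the largest remaining
# component, plus permutation comparison of degradation curves between
# groups with an optional extra-covariate (e.g. WMH) adjusted variant.

# Largest-component size after each removal in `ord` (a permutation of
# 1..n). Computed by reverse node addition with union-find, O((n + m) a(n))
# per order. Returns an integer vector of length n: lcc[k] = LCC size after
# the first k removals (lcc[n] = 0).
.lcc_after_removals <- function(nb, ord) {
  n <- length(nb)
  parent <- integer(n)
  csize <- integer(n)
  present <- logical(n)
  rev_best <- integer(n + 1)   # rev_best[m + 1] = LCC with last m nodes present
  best <- 0L
  for (t in n:1) {
    v <- ord[t]
    present[v] <- TRUE
    parent[v] <- v
    csize[v] <- 1L
    rv <- v
    for (u in nb[[v]]) {
      if (present[u]) {
        # find roots with path halving
        ru <- u
        while (parent[ru] != ru) {
          parent[ru] <- parent[parent[ru]]
          ru <- parent[ru]
        }
        while (parent[rv] != rv) {
          parent[rv] <- parent[parent[rv]]
          rv <- parent[rv]
        }
        if (ru != rv) {
          if (csize[ru] < csize[rv]) { tmp <- ru; ru <- rv; rv <- tmp }
          parent[rv] <- ru
          csize[ru] <- csize[ru] + csize[rv]
          rv <- ru
        }
      }
    }
    if (csize[rv] > best) best <- csize[rv]
    rev_best[n - t + 2] <- best
  }
  rev_best[(n:1)]
}

.adjacency_neighbors <- function(A) {
  lapply(seq_len(nrow(A)), function(i) which(A[i, ] != 0))
}

.attack_curve <- function(fractions, lcc_ratio, mode, n_repeats = NULL,
                          order = NULL, group = NULL) {
  structure(list(fractions_removed = fractions, lcc_ratio = lcc_ratio,
                 mode = mode, n_repeats = n_repeats, order = order,
                 group = group),
            class = "attack_curve")
}

#' @export
print.attack_curve <- function(x, ...) {
  cat("attack_curve (", x$mode, "):", length(x$fractions_removed) - 1,
      "removals", if (!is.null(x$n_repeats)) paste0(", ", x$n_repeats,
      " repeats"), "\n")
  invisible(x)
}

#' Random-failure degradation curve
#'
#' Removes nodes one at a time in uniformly random order and records the
#' size of the largest remaining component (as a fraction of the original
#' node count) after each removal; the curve is averaged over `n_repeats`
#' random orders. The curve starts at fraction 0 (no removal) and ends at 0
#' when all nodes are removed; it is non-increasing for every individual
#' removal sequence.
#'
#' @param net a connected `binary_network` (conventionally thresholded at
#'   the minimum density so every region participates).
#' @param seed RNG seed; curves are bit-reproducible under it.
#' @param n_repeats number of random removal orders to average (default 50).
#' @return an `attack_curve` with `fractions_removed = 0, 1/R, ..., 1` and
#'   the mean `lcc_ratio` (per-repeat curves in attribute `repeats`).
#' @export
random_failure <- function(net, seed = NULL, n_repeats = 50) {
  A <- .adj(net)
  n <- nrow(A)
  if (n == 0) stop("empty network")
  if (igraph::components(.as_graph(A))$no != 1)
    warning("network is not connected; curve starts below 1")
  if (!is.null(seed)) set.seed(seed)
  nb <- .adjacency_neighbors(A)
  lcc0 <- max(igraph::components(.as_graph(A))$csize)
  curves <- matrix(NA_real_, n_repeats, n + 1)
  for (r in seq_len(n_repeats)) {
    ord <- sample.int(n)
    curves[r, ] <- c(lcc0, .lcc_after_removals(nb, ord)) / n
  }
  out <- .attack_curve(fractions = (0:n) / n, lcc_ratio = colMeans(curves),
                       mode = "random", n_repeats = n_repeats,
                       group = attr(net, "group"))
  attr(out, "repeats") <- curves
  out
}

#' Targeted-attack degradation curve
#'
#' Removes nodes in rank order of decreasing betweenness centrality
#' (computed once on the intact network; ties broken by higher degree, then
#' lexicographic region label) and records the largest remaining component
#' after each removal. `recompute = TRUE` re-ranks betweenness on the
#' remaining subgraph after every removal, as a sensitivity variant.
#'
#' @param net a connected `binary_network`.
#' @param recompute recompute betweenness after each removal (default FALSE:
#'   static ranking).
#' @return an `attack_curve` (deterministic; the removal order is stored in
#'   `$order`).
#' @export
targeted_attack <- function(net, recompute = FALSE) {
  A <- .adj(net)
  n <- nrow(A)
  if (n == 0) stop("empty network")
  labels <- rownames(A) %||% sprintf("R%04d", seq_len(n))
  lcc0 <- max(igraph::components(.as_graph(A))$csize)
  if (!recompute) {
    b <- node_betweenness(A)
    deg <- colSums(A)
    ord <- order(-b, -deg, labels)
    lcc <- .lcc_after_removals(.adjacency_neighbors(A), ord)
  } else {
    remaining <- seq_len(n)
    ord <- integer(n)
    lcc <- integer(n)
    for (k in seq_len(n)) {
      sub <- A[remaining, remaining, drop = FALSE]
      b <- node_betweenness(sub)
      deg <- colSums(sub)
      pick <- order(-b, -deg, labels[remaining])[1]
      ord[k] <- remaining[pick]
      remaining <- remaining[-pick]
      lcc[k] <- if (length(remaining) == 0) 0L else
        max(igraph::components(.as_graph(
          A[remaining, remaining, drop = FALSE]))$csize)
    }
  }
  .attack_curve(fractions = (0:n) / n, lcc_ratio = c(lcc0, lcc) / n,
                mode = "targeted", order = labels[ord],
                group = attr(net, "group"))
}

#' Permutation comparison of network resilience between groups
#'
#' Builds each group's network at the minimum density, simulates degradation
#' (random failure averaged over `n_repeats` orders, or deterministic
#' targeted attack), and compares the largest-remaining-component curves
#' between groups at every removal fraction against a label-permutation
#' null with full pipeline recomputation (residualization, association,
#' minimum density, attack). Supplying `extra_covariates` (e.g. a WMH
#' volume column) adds them to the residualization throughout, giving the
#' covariate-adjusted variant; a missing column is an error — no imputation.
#'
#' @inheritParams permute_compare
#' @param mode `"targeted"` or `"random"`.
#' @param extra_covariates optional extra covariate columns.
#' @param n_repeats random orders per curve in random mode.
#' @return list of class `resilience_comparison`: observed curves per group,
#'   per-fraction observed difference (first level minus second), add-one
#'   two-tailed p-values, and the minimum density used.
#' @export
compare_resilience <- function(cohort, mode = c("targeted", "random"),
                               grid = density_grid(), n_perm = 1000,
                               seed = 1, covariate_names = NULL,
                               extra_covariates = NULL, n_repeats = 50,
                               per_group = TRUE, rank_absolute = FALSE) {
  stopifnot(inherits(cohort, "cohort_table"))
  mode <- match.arg(mode)
  covariate_names <- covariate_names %||% .default_covariates(cohort)
  if (!is.null(extra_covariates)) {
    missing <- setdiff(extra_covariates, names(cohort$covariates))
    if (length(missing) > 0)
      stop("extra covariate(s) absent from cohort: ",
           paste(missing, collapse = ", "), " (no imputation is performed)")
    covariate_names <- union(covariate_names, extra_covariates)
  }
  th <- cohort$thickness
  labels <- cohort$group
  covs <- cohort$covariates
  n <- ncol(th)

  curves_for <- function(lab, rng_stream) {
    resid_c <- cohort
    resid_c$group <- lab
    resid_c <- residualize(resid_c, covariate_names, per_group)
    assoc <- lapply(levels(lab), function(g) build_association(resid_c, g))
    dmin <- tryCatch(find_min_density(assoc, grid, rank_absolute),
                     error = function(e) NA_real_)
    frag <- is.na(dmin)
    if (frag) dmin <- max(grid)  # fall back to densest grid point, flagged
    out <- vapply(assoc, function(a) {
      net <- suppressWarnings(threshold_at_density(a, dmin, rank_absolute))
      if (mode == "targeted") targeted_attack(net)$lcc_ratio
      else {
        set.seed(rng_stream)
        suppressWarnings(random_failure(net, n_repeats = n_repeats))$lcc_ratio
      }
    }, numeric(n + 1))
    list(curves = out, dmin = dmin, fragmented = frag)
  }

  obs <- curves_for(labels, .sub_seed(seed, 21L))
  obs_diff <- obs$curves[, 1] - obs$curves[, 2]
  exceed <- numeric(n + 1)
  set.seed(.sub_seed(seed, 22L))
  perm_labels <- replicate(n_perm, labels[sample.int(length(labels))],
                           simplify = FALSE)
  frag_count <- 0L
  for (p in seq_len(n_perm)) {
    cur <- curves_for(perm_labels[[p]], .sub_seed(seed, 1000L + p))
    frag_count <- frag_count + cur$fragmented
    nd <- cur$curves[, 1] - cur$curves[, 2]
    exceed <- exceed + (abs(nd) >= abs(obs_diff))
  }
  structure(list(
    mode = mode, d_min = obs$dmin, fractions = (0:n) / n,
    groups = levels(labels),
    curves = stats::setNames(list(obs$curves[, 1], obs$curves[, 2]),
                             levels(labels)),
    observed_diff = obs_diff,
    p = (1 + exceed) / (n_perm + 1),
    n_perm = n_perm, n_repeats = if (mode == "random") n_repeats else NULL,
    covariates = covariate_names, seed = seed,
    fragmented_permutations = frag_count),
    class = "resilience_comparison")
}

#' @export
print.resilience_comparison <- function(x, ...) {
  cat("resilience_comparison (", x$mode, ") at D_min =", x$d_min, "\n")
  sig <- which(x$p < 0.05)
  cat("  significant fractions (p < 0.05):",
      if (length(sig)) paste(format(x$fractions[sig]), collapse = " ")
      else "none", "\n")
  invisible(x)
}
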