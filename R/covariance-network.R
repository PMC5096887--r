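#' Residualize regional thickness against nuisance covariates
#'
#' Per region, ordinary-least-squares regression of thickness on the named
#' covariates (with intercept); the residuals replace the raw thickness, so
#' downstream inter-regional correlations reflect only covariate-adjusted
#' variation. By default the regression is fitted within each group
#' separately, so each group's covariance structure is adjusted against its
#' own covariate effects; `per_group = FALSE` pools both groups into one fit.
#'
#' Residualization is idempotent: residualizing the result against the same
#' covariates returns it unchanged (to numerical tolerance), and the
#' downstream association matrix is invariant to affine rescaling of any
#' covariate.
#'
#' @param cohort a validated `cohort_table`.
#' @param covariate_names character vector of covariate columns; the
#'   conventional set is age, gender, an illness-burden score and mean
#'   cortical thickness. Empty vector fits intercept-only models (group-mean
#'   centering).
#' @param per_group fit within each group separately (default) or pooled.
#' @return a `cohort_table` whose thickness matrix holds the residuals
#'   (flagged so the positivity check is skipped).
#' @export
residualize <- function(cohort, covariate_names, per_group = TRUE) {
  stopifnot(inherits(cohort, "cohort_table"))
  missing <- setdiff(covariate_names, names(cohort$covariates))
  if (length(missing) > 0)
    stop("covariate(s) not present: ", paste(missing, collapse = ", "))
  th <- cohort$thickness
  cov <- cohort$covariates[, covariate_names, drop = FALSE]
  blocks <- if (per_group) split(seq_along(cohort$group), cohort$group)
            else list(all = seq_along(cohort$group))
  res <- th
  for (idx in blocks) {
    X <- cbind(`(Intercept)` = 1, as.matrix(cov[idx, , drop = FALSE]))
    if (length(idx) < ncol(X) + 1)
      stop("need at least ", ncol(X) + 1, " subjects per fitted model, got ",
           length(idx))
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      sds <- apply(X[, -1, drop = FALSE], 2, stats::sd)
      culprit <- if (any(sds == 0)) names(sds)[sds == 0][1]
                 else colnames(X)[-1][1]
      stop("rank-deficient covariate design (constant or collinear covariate: ",
           culprit, ")")
    }
    res[idx, ] <- th[idx, , drop = FALSE] -
      X %*% qr.coef(qx, th[idx, , drop = FALSE])
  }
  out <- cohort
  out$thickness <- res
  attr(out, "residualized") <- TRUE
  attr(out, "covariates_removed") <- covariate_names
  out
}

#' Build a group's inter-regional Pearson association matrix
#'
#' Pearson correlation of (residualized) thickness between every pair of
#' regions across the subjects of one group; the diagonal (self-connections)
#' is set to 0.
#'
#' @param cohort a (typically residualized) `cohort_table`.
#' @param group one of the two group labels.
#' @return symmetric `association_matrix` with zero diagonal, off-diagonal
#'   entries in `[-1, 1]`, and attributes `group` and `n_subjects`.
#' @export
build_association <- function(cohort, group) {
  stopifnot(inherits(cohort, "cohort_table"))
  group <- as.character(group)
  if (!group %in% levels(cohort$group))
    stop("unknown group: ", group)
  idx <- which(cohort$group == group)
  if (length(idx) < 3) stop("group ", group, " has fewer than 3 subjects")
  Y <- cohort$thickness[idx, , drop = FALSE]
  sds <- apply(Y, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance region: ",
         paste(colnames(Y)[sds == 0], collapse = ", "))
  r <- stats::cor(Y)
  diag(r) <- 0
  structure(r, group = group, n_subjects = length(idx),
            class = c("association_matrix", "matrix", "array"))
}

# Pair ranking shared by thresholding and nested density curves: upper-tri
# pairs ordered by descending correlation (signed by default), ties broken
# by ascending (row, column) index so results are seed-free.
.edge_order <- function(assoc, rank_absolute = FALSE) {
  R <- nrow(assoc)
  ut <- which(upper.tri(assoc))
  v <- assoc[ut]
  if (rank_absolute) v <- abs(v)
  i <- ((ut - 1L) %% R) + 1L   # row index
  j <- ((ut - 1L) %/% R) + 1L  # column index
  o <- order(-v, i, j)
  list(i = i[o], j = j[o])
}

#' Binary undirected network from density thresholding
#'
#' Keeps the `E = round(density * R(R-1)/2)` largest correlations as edges
#' (round half away from zero). Ranking is on signed correlations by
#' default, so strong negative correlations are never edges;
#' `rank_absolute = TRUE` ranks on magnitude instead. Ties are broken by
#' ascending (row, column) pair index, deterministically.
#'
#' Thresholds are nested: the edge set at a lower density is a subset of the
#' edge set at any higher density.
#'
#' @param assoc an `association_matrix` (any symmetric zero-diagonal matrix
#'   works).
#' @param density fraction of realized edges, in (0, 1].
#' @param rank_absolute rank by `|R|` rather than signed `R`.
#' @return a `binary_network`: 0/1 adjacency matrix with region dimnames and
#'   attributes `density`, `n_edges`, `group`.
#' @export
threshold_at_density <- function(assoc, density, rank_absolute = FALSE) {
  R <- nrow(assoc)
  if (length(density) != 1 || !is.finite(density) || density <= 0)
    stop("density must be a single value in (0, 1]")
  if (density > 1) stop("density > 1 requested")
  Emax <- R * (R - 1) / 2
  E <- .round_half_up(density * Emax)
  if (E < R - 1)
    warning("only ", E, " edges at density ", density,
            "; graph cannot be connected (needs >= ", R - 1, ")")
  eo <- .edge_order(assoc, rank_absolute)
  A <- matrix(0, R, R, dimnames = dimnames(assoc))
  if (E > 0) {
    sel <- seq_len(E)
    A[cbind(eo$i[sel], eo$j[sel])] <- 1
    A[cbind(eo$j[sel], eo$i[sel])] <- 1
  }
  binary_network(A, density = density, group = attr(assoc, "group"))
}

#' Construct a binary network object from an adjacency matrix
#' @param adjacency symmetric 0/1 matrix with zero diagonal.
#' @param density nominal density (defaults to the realized edge fraction).
#' @param group optional group label.
#' @return a `binary_network`.
#' @export
binary_network <- function(adjacency, density = NULL, group = NULL) {
  A <- as.matrix(adjacency)
  storage.mode(A) <- "double"
  R <- nrow(A)
  if (R != ncol(A) || any(A != t(A)) || any(diag(A) != 0) ||
      !all(A %in% c(0, 1)))
    stop("adjacency must be a symmetric 0/1 matrix with zero diagonal")
  if (is.null(dimnames(A)))
    dimnames(A) <- list(paste0("R", 1:R), paste0("R", 1:R))
  E <- sum(A) / 2
  structure(A, density = density %||% (E / (R * (R - 1) / 2)),
            n_edges = E, group = group,
            class = c("binary_network", "matrix", "array"))
}

#' @export
print.binary_network <- function(x, ...) {
  cat("binary_network:", nrow(x), "nodes,", attr(x, "n_edges"),
      "edges (density ", format(attr(x, "density")), ")")
  if (!is.null(attr(x, "group"))) cat(" group:", attr(x, "group"))
  cat("\n")
  invisible(x)
}

# igraph view of a binary network / adjacency matrix
.as_graph <- function(net) {
  igraph::graph_from_adjacency_matrix(unclass(as.matrix(net)),
                                      mode = "undirected", diag = FALSE)
}

#' Density grid constructor
#'
#' @param from,to,by grid limits and step; the conventional analysis grid is
#'   0.10 to 0.20 in steps of 0.01, spanning sparse-but-connectable network
#'   densities.
#' @return strictly increasing numeric vector of densities in (0, 1).
#' @export
density_grid <- function(from = 0.10, to = 0.20, by = 0.01) {
  g <- round(seq(from, to, by = by), 10)
  if (any(g <= 0) || any(g >= 1) || is.unsorted(g, strictly = TRUE))
    stop("densities must be strictly increasing and inside (0, 1)")
  g
}

#' Minimum density connecting every group's network
#'
#' The smallest grid density at which each group's thresholded network forms
#' a single connected component containing all regions, so that no analyzed
#' network is fragmented.
#'
#' @param assoc_list list of `association_matrix` objects (one per group).
#' @param grid density grid from [density_grid()].
#' @param rank_absolute passed to [threshold_at_density()].
#' @return the minimum density (scalar). Errors if no grid density connects
#'   all groups, reporting each group's largest component size at the top of
#'   the grid.
#' @export
find_min_density <- function(assoc_list, grid = density_grid(),
                             rank_absolute = FALSE) {
  if (length(grid) == 0) stop("empty density grid")
  if (inherits(assoc_list, "association_matrix")) assoc_list <- list(assoc_list)
  for (d in grid) {
    ok <- vapply(assoc_list, function(a) {
      net <- suppressWarnings(threshold_at_density(a, d, rank_absolute))
      comp <- igraph::components(.as_graph(net))
      comp$no == 1
    }, logical(1))
    if (all(ok)) return(d)
  }
  lcc <- vapply(assoc_list, function(a) {
    net <- suppressWarnings(threshold_at_density(a, max(grid), rank_absolute))
    max(igraph::components(.as_graph(net))$csize)
  }, numeric(1))
  labs <- vapply(seq_along(assoc_list),
                 function(k) attr(assoc_list[[k]], "group") %||% paste0("group", k),
                 character(1))
  stop("no grid density connects all groups; largest components at density ",
       max(grid), ": ",
       paste(labs, lcc, sep = " = ", collapse = ", "))
}
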