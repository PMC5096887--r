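# Global and nodal graph measures for binary undirected networks.
#
# Shortest-path machinery (BFS distances, betweenness, components) and the
# greedy modularity optimizer are delegated to igraph; clustering and
# transitivity use direct adjacency algebra (cheap closed forms, and the hot
# path of the permutation engine). Every measure is cross-checked against
# hand-written brute-force oracles in the test suite.

.adj <- function(net) {
  A <- unclass(as.matrix(net))
  attributes(A)[setdiff(names(attributes(A)), c("dim", "dimnames"))] <- NULL
  A
}

# all-pairs shortest-path matrix (hops); Inf for unreachable
.distances <- function(A) igraph::distances(
  igraph::graph_from_adjacency_matrix(A, mode = "undirected", diag = FALSE))

#' Characteristic path length
#'
#' Mean shortest-path length over all connected node pairs; the standard
#' integration measure. On a disconnected graph only reachable pairs enter
#' the average and the result carries attribute `disconnected = TRUE`; an
#' edgeless graph returns a flagged `NA` sentinel.
#'
#' @param net a `binary_network` (or plain 0/1 adjacency matrix).
#' @return scalar path length (`>= 1` on any connected graph with more than
#'   one node), with attribute `disconnected`.
#' @export
char_path_length <- function(net) {
  A <- .adj(net)
  D <- .distances(A)
  off <- upper.tri(D)
  finite <- off & is.finite(D)
  if (!any(finite))
    return(structure(NA_real_, disconnected = TRUE))
  structure(mean(D[finite]), disconnected = any(off & !is.finite(D)))
}

#' Global efficiency
#'
#' Mean inverse shortest-path length over all node pairs, with `1/Inf = 0`
#' for disconnected pairs; an integration measure robust to fragmentation.
#'
#' @inheritParams char_path_length
#' @return scalar in `[0, 1]`.
#' @export
global_efficiency <- function(net) {
  A <- .adj(net)
  n <- nrow(A)
  if (n < 2) return(0)
  D <- .distances(A)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Nodal clustering coefficients
#'
#' Fraction of each node's neighbor pairs that are themselves connected:
#' `2 * triangles_i / (k_i (k_i - 1))`, defined as 0 for degree < 2.
#'
#' @inheritParams char_path_length
#' @return named numeric vector, one value in `[0, 1]` per node.
#' @export
nodal_clustering <- function(net) {
  A <- .adj(net)
  k <- colSums(A)
  A2 <- A %*% A
  tri2 <- rowSums(A2 * A)   # = diag(A^3) = 2 * triangles at node
  c_i <- ifelse(k < 2, 0, tri2 / (k * (k - 1)))
  stats::setNames(c_i, rownames(A))
}

#' Network clustering coefficient (mean nodal clustering)
#' @inheritParams char_path_length
#' @return scalar in `[0, 1]`.
#' @export
clustering_coefficient <- function(net) mean(nodal_clustering(net))

#' Transitivity
#'
#' Whole-network triangle density: `3 * triangles / connected triples`.
#' Unlike the mean clustering coefficient it is not dominated by low-degree
#' nodes. Returns 0 when the graph has no connected triple.
#'
#' @inheritParams char_path_length
#' @return scalar in `[0, 1]`.
#' @export
transitivity <- function(net) {
  A <- .adj(net)
  k <- colSums(A)
  triples <- sum(k * (k - 1))
  if (triples == 0) return(0)
  A2 <- A %*% A
  sum(A2 * A) / triples     # trace(A^3) = 6 * triangles = 2 * (3 * triangles)
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of the subgraph induced by the
#' node's neighbors (the node itself excluded); nodes with fewer than two
#' neighbors contribute 0.
#'
#' @inheritParams char_path_length
#' @return scalar in `[0, 1]`.
#' @export
local_efficiency <- function(net) {
  A <- .adj(net)
  n <- nrow(A)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] != 0)
    if (length(nb) < 2) return(0)
    sub <- A[nb, nb, drop = FALSE]
    m <- length(nb)
    D <- .distances(sub)
    inv <- 1 / D
    inv[!is.finite(inv)] <- 0
    diag(inv) <- 0
    sum(inv) / (m * (m - 1))
  }, numeric(1))
  mean(vals)
}

#' Newman modularity by deterministic greedy agglomeration
#'
#' Partition quality `Q = sum_m (e_m / E - (d_m / 2E)^2)` (within-module
#' edge fraction minus squared degree fraction), maximized by the
#' fast-greedy agglomerative merge sequence (no random restarts, so the
#' result is reproducible without a seed).
#'
#' @inheritParams char_path_length
#' @return list with `Q` (scalar in `[-0.5, 1]`) and `membership` (named
#'   integer module assignment).
#' @export
modularity_partition <- function(net) {
  A <- .adj(net)
  if (sum(A) == 0) stop("modularity is undefined on an edgeless graph")
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected", diag = FALSE)
  fc <- igraph::cluster_fast_greedy(g)
  mem <- as.integer(igraph::membership(fc))
  Q <- igraph::modularity(g, mem)
  if (Q < 0) {   # never worse than the trivial single-module partition (Q = 0)
    mem <- rep(1L, nrow(A))
    Q <- 0
  }
  list(Q = Q, membership = stats::setNames(mem, rownames(A)))
}

#' Nodal betweenness centrality
#'
#' Unnormalized shortest-path betweenness: for each unordered pair of other
#' nodes, the fraction of their shortest paths passing through the node,
#' summed over pairs (Brandes accumulation).
#'
#' @inheritParams char_path_length
#' @return named non-negative numeric vector.
#' @export
node_betweenness <- function(net) {
  A <- .adj(net)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected", diag = FALSE)
  b <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  stats::setNames(as.numeric(b), rownames(A))
}

#' Nodal metrics table
#' @inheritParams char_path_length
#' @return data.frame with one row per region: `degree`, `clustering`,
#'   `betweenness`.
#' @export
nodal_metrics <- function(net) {
  A <- .adj(net)
  data.frame(region = rownames(A) %||% paste0("R", seq_len(nrow(A))),
             degree = as.integer(colSums(A)),
             clustering = unname(nodal_clustering(A)),
             betweenness = unname(node_betweenness(A)),
             row.names = NULL)
}

#' Degree-preserving random reference networks
#'
#' Double-edge-swap (Maslov-Sneppen) rewiring: repeated swaps of edge pairs
#' that preserve every node's degree exactly, with `100 * E` swap attempts
#' per reference. Used to normalize clustering and path length when
#' assessing small-world organization. By default each reference is redrawn
#' until connected (normalization references must support finite path
#' lengths).
#'
#' @param net a connected `binary_network`.
#' @param n_networks number of references (default 20).
#' @param seed RNG seed for reproducibility.
#' @param require_connected redraw disconnected rewires (default TRUE).
#' @param max_redraw redraw budget per reference.
#' @return list of `binary_network` objects with identical degree sequences.
#' @export
random_reference <- function(net, n_networks = 20, seed = NULL,
                             require_connected = TRUE, max_redraw = 50) {
  A <- .adj(net)
  E <- sum(A) / 2
  if (E < 2) stop("graph too small to rewire (fewer than 2 edges)")
  if (n_networks < 1) stop("n_networks must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected", diag = FALSE)
  lapply(seq_len(n_networks), function(j) {
    for (try in seq_len(max_redraw)) {
      gr <- igraph::rewire(g, igraph::keeping_degseq(niter = 100 * E))
      if (!require_connected || igraph::is_connected(gr)) {
        Ar <- igraph::as_adjacency_matrix(gr, sparse = FALSE)
        dimnames(Ar) <- dimnames(A)
        return(binary_network(Ar, density = attr(net, "density"),
                              group = attr(net, "group")))
      }
    }
    stop("could not draw a connected degree-preserving reference within ",
         max_redraw, " attempts")
  })
}

#' Small-world indices against reference networks
#'
#' `gamma = Cp(net) / mean Cp(refs)`, `lambda = Lp(net) / mean Lp(refs)`
#' (ratio of means over the reference set), `sigma = gamma / lambda`.
#' `sigma > 1` indicates small-world organization: clustering well above the
#' degree-matched random expectation at a comparable path length.
#'
#' When `net` is connected every reference must be connected (disconnected
#' rewires are redrawn by [random_reference()]). When `net` is itself
#' fragmented — possible below the minimum density, where no connected
#' degree-preserving reference may even exist — path lengths of network and
#' references alike are averaged over reachable pairs, keeping the
#' normalization like-for-like.
#'
#' @param net a `binary_network`.
#' @param refs nonempty list of reference networks, typically from
#'   [random_reference()].
#' @return named list `gamma`, `lambda`, `sigma`.
#' @export
small_world <- function(net, refs) {
  if (length(refs) == 0) stop("reference list is empty")
  lp_net <- char_path_length(net)
  if (is.na(lp_net)) stop("path length undefined: network has no edges")
  lp_refs_raw <- lapply(refs, char_path_length)
  if (!isTRUE(attr(lp_net, "disconnected")) &&
      any(vapply(lp_refs_raw, function(l)
        is.na(l) || isTRUE(attr(l, "disconnected")), logical(1))))
    stop("all reference networks must be connected")
  lp_refs <- vapply(lp_refs_raw, as.numeric, numeric(1))
  cp_refs <- vapply(refs, clustering_coefficient, numeric(1))
  gamma <- clustering_coefficient(net) / mean(cp_refs)
  lambda <- as.numeric(lp_net) / mean(lp_refs)
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda)
}

#' All global metrics of one network
#'
#' @param net a `binary_network`.
#' @param refs optional list of reference networks; when supplied the
#'   normalized measures gamma, lambda and sigma are included.
#' @return named list: `char_path_length`, `global_efficiency`,
#'   `clustering_coefficient`, `local_efficiency`, `transitivity`,
#'   `modularity`, and optionally `gamma`, `lambda`, `sigma`.
#' @export
global_metrics <- function(net, refs = NULL) {
  out <- list(
    char_path_length = as.numeric(char_path_length(net)),
    global_efficiency = global_efficiency(net),
    clustering_coefficient = clustering_coefficient(net),
    local_efficiency = local_efficiency(net),
    transitivity = transitivity(net),
    modularity = modularity_partition(net)$Q)
  if (!is.null(refs)) out <- c(out, small_world(net, refs))
  out
}

# fast metric registry used by the permutation engine: each entry maps a
# plain adjacency matrix (plus a pre-built igraph view, reused across
# metrics at the same density) to a scalar
.metric_registry <- list(
  char_path_length = function(A, g) {
    D <- igraph::distances(g)
    off <- upper.tri(D)
    finite <- off & is.finite(D)
    if (!any(finite)) NA_real_ else mean(D[finite])
  },
  global_efficiency = function(A, g) {
    n <- nrow(A)
    if (n < 2) return(0)
    inv <- 1 / igraph::distances(g)
    inv[!is.finite(inv)] <- 0
    diag(inv) <- 0
    sum(inv) / (n * (n - 1))
  },
  clustering_coefficient = function(A, g) mean(nodal_clustering(A)),
  local_efficiency = function(A, g) local_efficiency(A),
  transitivity = function(A, g) transitivity(A),
  modularity = function(A, g)
    max(0, igraph::modularity(g, igraph::membership(igraph::cluster_fast_greedy(g))))
)

.metric_needs_graph <- c(char_path_length = TRUE, global_efficiency = TRUE,
                         clustering_coefficient = FALSE,
                         local_efficiency = FALSE, transitivity = FALSE,
                         modularity = TRUE)

#' Names of the global metrics available to permutation comparison
#' @return character vector.
#' @export
comparable_metrics <- function() names(.metric_registry)
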