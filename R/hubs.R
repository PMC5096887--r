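#' Identify hub regions by the betweenness 2SD rule
#'
#' A region is a hub if its betweenness centrality is at least `z_threshold`
#' standard deviations above the mean nodal betweenness of the same network
#' (inclusive boundary). The z-scores use the population standard deviation
#' over the network's nodes — the network is the full population, not a
#' sample — so hub membership is invariant under any positive rescaling of
#' betweenness. Hub analysis is conventionally run at the minimum density.
#'
#' @param net a `binary_network` with at least 3 nodes.
#' @param region_labels node labels (defaults to the adjacency dimnames).
#' @param z_threshold hub cutoff in SD units (default 2).
#' @return a `hub_set` data.frame (`region`, `betweenness`, `z`), sorted by
#'   descending z, with attributes `group`, `density`, `z_threshold`. A
#'   network with zero betweenness variance (e.g. a complete graph) yields
#'   an empty hub set with a warning.
#' @export
identify_hubs <- function(net, region_labels = NULL, z_threshold = 2) {
  A <- .adj(net)
  if (nrow(A) < 3) stop("hub identification needs at least 3 nodes")
  region_labels <- region_labels %||% rownames(A) %||%
    paste0("R", seq_len(nrow(A)))
  b <- unname(node_betweenness(A))
  s <- sqrt(mean((b - mean(b))^2))   # population SD over the R nodes
  if (s == 0) {
    warning("betweenness has zero variance; no hubs can be identified")
    z <- rep(NA_real_, length(b))
    keep <- integer(0)
  } else {
    z <- (b - mean(b)) / s
    keep <- which(z >= z_threshold)
  }
  keep <- keep[order(-z[keep])]
  out <- data.frame(region = region_labels[keep], betweenness = b[keep],
                    z = z[keep], row.names = NULL)
  structure(out, group = attr(net, "group"), density = attr(net, "density"),
            z_threshold = z_threshold,
            class = c("hub_set", "data.frame"))
}

#' @export
print.hub_set <- function(x, ...) {
  cat("hub_set (z >=", attr(x, "z_threshold"), ")")
  if (!is.null(attr(x, "group"))) cat(" group:", attr(x, "group"))
  cat("\n")
  if (nrow(x) == 0) cat("  no hubs\n") else print.data.frame(x)
  invisible(x)
}
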