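path3 <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
star5 <- local({
  A <- matrix(0, 5, 5); A[1, 2:5] <- A[2:5, 1] <- 1
  dimnames(A) <- list(paste0("n", 1:5), paste0("n", 1:5)); A
})
complete <- function(n) {
  A <- matrix(1, n, n) - diag(n)
  dimnames(A) <- list(paste0("n", 1:n), paste0("n", 1:n)); A
}

test_that("integration measures match closed forms and the BFS oracle", {
  expect_equal(as.numeric(char_path_length(path3)), 4 / 3)
  expect_equal(as.numeric(char_path_length(complete(6))), 1)
  expect_equal(global_efficiency(path3), 5 / 6)
  expect_equal(global_efficiency(complete(7)), 1)
  # two disconnected dyads: 2 pairs at distance 1 out of 6
  two_k2 <- matrix(0, 4, 4); two_k2[1, 2] <- two_k2[2, 1] <- 1
  two_k2[3, 4] <- two_k2[4, 3] <- 1
  expect_equal(global_efficiency(two_k2), 1 / 3)
  lp <- char_path_length(two_k2)
  expect_true(attr(lp, "disconnected"))
  expect_equal(as.numeric(lp), 1)   # reachable pairs only
  expect_true(is.na(char_path_length(matrix(0, 3, 3))))
  set.seed(1)
  for (i in 1:10) {
    A <- random_adjacency(10, 0.4, connected = TRUE)
    expect_equal(as.numeric(char_path_length(A)), oracle_path_length(A))
    expect_equal(global_efficiency(A), oracle_efficiency(A))
  }
})

test_that("segregation measures match enumeration oracles", {
  expect_equal(clustering_coefficient(complete(3)), 1)
  expect_equal(transitivity(complete(3)), 1)
  expect_equal(clustering_coefficient(star5), 0)
  expect_equal(transitivity(star5), 0)
  ring <- ring_lattice(8, 2)
  expect_equal(clustering_coefficient(ring), 0.5)
  expect_equal(transitivity(ring), 0.5)
  expect_equal(local_efficiency(complete(4)), 1)
  expect_equal(local_efficiency(star5), 0)
  # transitivity equals mean clustering on vertex-transitive graphs
  for (spec in list(c(10, 2), c(12, 3), c(9, 4))) {
    rl <- ring_lattice(spec[1], spec[2])
    expect_equal(transitivity(rl), clustering_coefficient(rl))
  }
  set.seed(2)
  for (i in 1:10) {
    A <- random_adjacency(10, 0.5)
    expect_equal(unname(nodal_clustering(A)), oracle_clustering(A))
    expect_equal(transitivity(A), oracle_transitivity(A))
    expect_equal(local_efficiency(A), oracle_local_efficiency(A))
  }
})

test_that("betweenness matches the path-counting oracle", {
  b <- node_betweenness(star5)
  expect_equal(unname(b), c(6, 0, 0, 0, 0))   # C(4,2) leaf pairs via center
  expect_equal(unname(node_betweenness(path3)), c(0, 1, 0))
  set.seed(3)
  for (i in 1:10) {
    A <- random_adjacency(10, 0.35)
    expect_equal(unname(node_betweenness(A)), oracle_betweenness(A))
  }
})

test_that("greedy modularity finds known optima and bounds the gap", {
  two_tri <- matrix(0, 6, 6)
  two_tri[1:3, 1:3] <- 1; two_tri[4:6, 4:6] <- 1; diag(two_tri) <- 0
  mp <- modularity_partition(two_tri)
  expect_equal(mp$Q, 0.5)
  expect_equal(mp$Q, oracle_modularity_opt(two_tri))
  expect_equal(length(unique(mp$membership)), 2)
  expect_equal(modularity_partition(complete(5))$Q, 0)
  expect_error(modularity_partition(matrix(0, 4, 4)), "edgeless")
  # nodal degree bookkeeping
  nm <- nodal_metrics(star5)
  expect_equal(sum(nm$degree), 2 * 4)
  expect_equal(nm$betweenness[nm$degree == 1], rep(0, 4))
})

test_that("adding an edge never hurts integration", {
  set.seed(4)
  for (i in 1:15) {
    A <- random_adjacency(9, 0.35, connected = TRUE)
    hole <- which(A == 0 & upper.tri(A))
    if (length(hole) == 0) next
    pick <- sample(hole, 1)
    B <- A; B[pick] <- 1; B <- pmax(B, t(B))
    expect_lte(as.numeric(char_path_length(B)), as.numeric(char_path_length(A)))
    expect_gte(global_efficiency(B), global_efficiency(A))
  }
})

test_that("degree-preserving rewiring keeps degrees, is seeded, kills lattice clustering", {
  set.seed(5)
  A <- random_adjacency(20, 0.3, connected = TRUE)
  refs <- random_reference(A, n_networks = 3, seed = 99)
  for (r in refs)
    expect_equal(sort(colSums(unclass(r))), sort(colSums(A)))
  refs2 <- random_reference(A, n_networks = 3, seed = 99)
  expect_identical(lapply(refs, unclass), lapply(refs2, unclass))
  # rewired lattices lose clustering on average
  lat <- ring_lattice(24, 3)
  cp <- clustering_coefficient(lat)
  cps <- vapply(1:20, function(s)
    clustering_coefficient(random_reference(lat, 1, seed = s)[[1]]),
    numeric(1))
  expect_lt(mean(cps), cp)
  expect_error(random_reference(path3[1:2, 1:2]), "fewer than 2 edges")
})

test_that("small-world indices self-normalize and detect lattice shortcuts", {
  A <- random_adjacency(15, 0.4, connected = TRUE)
  net <- binary_network(A)
  sw <- small_world(net, list(net, net))
  expect_equal(sw$gamma, 1)
  expect_equal(sw$lambda, 1)
  expect_equal(sw$sigma, 1)
  # lattice with a few shortcuts: strongly clustered, short paths -> sigma > 1
  ws <- ring_lattice(40, 3)
  set.seed(6)
  for (k in 1:6) {
    ij <- sample(40, 2)
    ws[ij[1], ij[2]] <- ws[ij[2], ij[1]] <- 1
  }
  refs <- random_reference(ws, n_networks = 10, seed = 7)
  expect_gt(small_world(ws, refs)$sigma, 1)
})

test_that("gamma and lambda are near 1 for matched-density random graphs", {
  vals <- sapply(1:20, function(s) {
    set.seed(s)
    g <- igraph::sample_gnp(200, 0.05)
    while (!igraph::is_connected(g)) g <- igraph::sample_gnp(200, 0.05)
    A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
    dimnames(A) <- list(paste0("n", 1:200), paste0("n", 1:200))
    net <- binary_network(A)
    refs <- random_reference(net, n_networks = 3, seed = s)
    unlist(small_world(net, refs)[c("gamma", "lambda")])
  })
  expect_lt(abs(mean(vals["gamma", ]) - 1), 0.1)
  expect_lt(abs(mean(vals["lambda", ]) - 1), 0.1)
})
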