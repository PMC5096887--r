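# Independent brute-force oracles used to validate the graph measures.
# Everything here is deliberately naive (explicit BFS, triple loops,
# exhaustive partition enumeration) and shares no code with the package.

oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier) > 0) {
      d <- d + 1
      nxt <- integer(0)
      for (v in frontier) for (u in which(A[v, ] != 0))
        if (!is.finite(dist[u])) { dist[u] <- d; nxt <- c(nxt, u) }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist
  }
  D
}

oracle_path_length <- function(A) {
  D <- oracle_distances(A)
  v <- D[upper.tri(D)]
  v <- v[is.finite(v)]
  if (length(v) == 0) NA_real_ else mean(v)
}

oracle_efficiency <- function(A) {
  n <- nrow(A)
  if (n < 2) return(0)
  D <- oracle_distances(A)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    tot <- tot + if (is.finite(D[i, j])) 1 / D[i, j] else 0
  tot / (n * (n - 1))
}

oracle_clustering <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] != 0)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (a in seq_along(nb)) for (b in seq_along(nb)) if (a < b)
      links <- links + A[nb[a], nb[b]]
    2 * links / (k * (k - 1))
  }, numeric(1))
}

oracle_transitivity <- function(A) {
  n <- nrow(A)
  triangles <- 0
  triples <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i < j && j < k) {
      e <- A[i, j] + A[i, k] + A[j, k]
      if (e == 3) triangles <- triangles + 1
    }
    if (i != j && j != k && i < k && A[j, i] && A[j, k])
      triples <- triples + 1
  }
  if (triples == 0) 0 else 3 * triangles / triples
}

oracle_local_efficiency <- function(A) {
  n <- nrow(A)
  mean(vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] != 0)
    if (length(nb) < 2) return(0)
    oracle_efficiency(A[nb, nb, drop = FALSE])
  }, numeric(1)))
}

# betweenness by explicit shortest-path counting on the BFS DAG: number of
# shortest s-t paths through v is npaths(s,v) * npaths(v,t) when
# d(s,v) + d(v,t) = d(s,t)
oracle_betweenness <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  npaths <- function(s) {
    cnt <- numeric(n)
    cnt[s] <- 1
    for (d in seq_len(n)) for (v in which(D[s, ] == d))
      cnt[v] <- sum(cnt[which(A[v, ] != 0 & D[s, ] == d - 1)])
    cnt
  }
  NP <- t(vapply(seq_len(n), npaths, numeric(n)))  # NP[s, v]
  b <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) if (s < t && is.finite(D[s, t]))
    for (v in seq_len(n)) if (v != s && v != t &&
                              is.finite(D[s, v]) && is.finite(D[v, t]) &&
                              D[s, v] + D[v, t] == D[s, t])
      b[v] <- b[v] + NP[s, v] * NP[v, t] / NP[s, t]
  b
}

# all set partitions of 1..n as membership vectors (restricted growth
# strings); Bell(8) = 4140
oracle_partitions <- function(n) {
  out <- list()
  rec <- function(mem, k, maxm) {
    if (k > n) { out[[length(out) + 1]] <<- mem; return(invisible()) }
    for (m in seq_len(maxm + 1)) {
      mem[k] <- m
      rec(mem, k + 1, max(maxm, m))
    }
  }
  rec(integer(n), 1, 0)
  out
}

oracle_Q <- function(A, mem) {
  E <- sum(A) / 2
  if (E == 0) return(NA_real_)
  deg <- colSums(A)
  q <- 0
  for (m in unique(mem)) {
    idx <- which(mem == m)
    e_m <- sum(A[idx, idx]) / 2
    q <- q + e_m / E - (sum(deg[idx]) / (2 * E))^2
  }
  q
}

oracle_modularity_opt <- function(A) {
  max(vapply(oracle_partitions(nrow(A)), function(mem) oracle_Q(A, mem),
             numeric(1)))
}

oracle_connected <- function(A) all(is.finite(oracle_distances(A)))

# Erdos-Renyi adjacency, optionally resampled until connected
random_adjacency <- function(n, p, connected = FALSE, max_tries = 200) {
  for (i in seq_len(max_tries)) {
    A <- matrix(0, n, n)
    ut <- which(upper.tri(A))
    A[ut] <- stats::rbinom(length(ut), 1, p)
    A <- A + t(A)
    dimnames(A) <- list(paste0("n", 1:n), paste0("n", 1:n))
    if (!connected || oracle_connected(A)) return(A)
  }
  stop("could not draw a connected graph")
}

# ring lattice: n nodes, each linked to `k` neighbors per side
ring_lattice <- function(n, k) {
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (s in seq_len(k)) {
    j <- ((i - 1 + s) %% n) + 1
    A[i, j] <- A[j, i] <- 1
  }
  dimnames(A) <- list(paste0("n", 1:n), paste0("n", 1:n))
  A
}

adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ni <- rowSums(tab)
  nj <- colSums(tab)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  idx <- sum_comb(tab)
  exp_idx <- sum_comb(ni) * sum_comb(nj) / choose(n, 2)
  max_idx <- (sum_comb(ni) + sum_comb(nj)) / 2
  (idx - exp_idx) / (max_idx - exp_idx)
}

# small manual cohort: two groups of `n_per` subjects over `R` regions with
# supplied per-group covariance; covariates drawn simply
manual_cohort <- function(sigma_a, sigma_b, n_per = 20, base = 2.3, seed = 1) {
  set.seed(seed)
  R <- nrow(sigma_a)
  th <- rbind(MASS::mvrnorm(n_per, rep(0, R), sigma_a),
              MASS::mvrnorm(n_per, rep(0, R), sigma_b)) + base
  colnames(th) <- sprintf("roi_%02d", 1:R)
  n <- 2 * n_per
  cohort_table(th, rep(c("A", "B"), each = n_per),
               data.frame(age = stats::runif(n, 60, 84),
                          gender = stats::rbinom(n, 1, 0.3),
                          illness = stats::rgamma(n, 4, 1)),
               subject_id = sprintf("s%03d", 1:n))
}
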