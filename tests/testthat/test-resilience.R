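complete_net <- function(n) {
  A <- matrix(1, n, n) - diag(n)
  dimnames(A) <- list(paste0("n", 1:n), paste0("n", 1:n))
  binary_network(A)
}

test_that("attack curves match closed forms on symmetric graphs", {
  k8 <- complete_net(8)
  rf <- random_failure(k8, seed = 1, n_repeats = 5)
  # complete graphs stay complete: after 2 removals the LCC is 6/8
  expect_equal(rf$lcc_ratio[3], 0.75)
  expect_equal(rf$lcc_ratio[1], 1)
  expect_equal(rf$lcc_ratio[9], 0)
  ta <- targeted_attack(k8)
  expect_equal(ta$lcc_ratio, rf$lcc_ratio)   # full symmetry: same curve
  expect_equal(ta$lcc_ratio, (8:0) / 8)
})

test_that("targeted attack removes the most central node first", {
  A <- matrix(0, 5, 5); A[1, 2:5] <- A[2:5, 1] <- 1
  dimnames(A) <- list(paste0("n", 1:5), paste0("n", 1:5))
  star <- binary_network(A)
  ta <- targeted_attack(star)
  expect_equal(ta$order[1], "n1")
  expect_equal(ta$lcc_ratio[2], 0.2)   # leaves isolated once the hub is gone
  # barbell: two K5 joined by a bridge node; the bridge carries all
  # cross-side shortest paths
  B <- matrix(0, 11, 11)
  B[1:5, 1:5] <- 1; B[6:10, 6:10] <- 1; diag(B) <- 0
  B[11, c(1, 6)] <- B[c(1, 6), 11] <- 1
  dimnames(B) <- list(paste0("n", 1:11), paste0("n", 1:11))
  tb <- targeted_attack(binary_network(B))
  expect_equal(tb$order[1], "n11")
  expect_equal(tb$lcc_ratio[2], 5 / 11)
  # recompute-after-removal variant agrees here (bridge is removed first)
  expect_equal(targeted_attack(binary_network(B), recompute = TRUE)$order[1],
               "n11")
})

test_that("largest-component bookkeeping matches direct component search", {
  set.seed(2)
  for (i in 1:10) {
    A <- random_adjacency(12, 0.25)
    ord <- sample.int(12)
    lcc <- sconet:::.lcc_after_removals(sconet:::.adjacency_neighbors(A), ord)
    for (k in c(1, 4, 8, 12)) {
      keep <- setdiff(seq_len(12), ord[seq_len(k)])
      expected <- if (length(keep) == 0) 0 else
        max(igraph::components(igraph::graph_from_adjacency_matrix(
          A[keep, keep, drop = FALSE], mode = "undirected"))$csize)
      expect_equal(lcc[k], expected)
    }
    expect_true(all(diff(lcc) <= 0))   # monotone for every sequence
  }
})

test_that("random-failure curves average the exact single-removal expectation", {
  # path graph: removing node i leaves max(i-1, n-i) connected nodes
  n <- 10
  P <- matrix(0, n, n)
  for (i in 1:(n - 1)) P[i, i + 1] <- P[i + 1, i] <- 1
  dimnames(P) <- list(paste0("n", 1:n), paste0("n", 1:n))
  exact <- mean(sapply(1:n, function(i) max(i - 1, n - i))) / n
  expect_lt(exact, 1 - 1 / n)   # splitting is likely on a path
  rf <- random_failure(binary_network(P), seed = 3, n_repeats = 500)
  expect_lt(abs(rf$lcc_ratio[2] - exact), 0.02)
  # reproducibility
  rf2 <- random_failure(binary_network(P), seed = 3, n_repeats = 500)
  expect_identical(rf$lcc_ratio, rf2$lcc_ratio)
})

test_that("identical groups show zero resilience difference, p = 1", {
  set.seed(4)
  R <- 10; n <- 8
  th <- matrix(2.3 + rnorm(n * R, sd = 0.1), n, R,
               dimnames = list(NULL, sprintf("roi_%02d", 1:R)))
  covs <- data.frame(age = runif(n, 60, 84))
  cohort <- cohort_table(rbind(th, th), rep(c("A", "B"), each = n),
                         rbind(covs, covs),
                         subject_id = sprintf("s%03d", 1:(2 * n)))
  rc <- compare_resilience(cohort, mode = "targeted",
                           grid = density_grid(0.3, 0.6, 0.1),
                           n_perm = 19, seed = 5)
  expect_equal(rc$observed_diff, rep(0, R + 1))
  expect_true(all(rc$p == 1))
})

test_that("a WMH-style covariate must exist before adjustment", {
  spec <- synthetic_spec(n_regions = 8, n_subjects = c(6, 6), n_modules = 2,
                         within_rho = c(0.5, 0.5))
  cohort <- generate_cohort(spec, seed = 6)$cohort
  cohort$covariates$wmh <- NULL
  expect_error(compare_resilience(cohort, extra_covariates = "wmh",
                                  n_perm = 19),
               "wmh.*no imputation")
})

test_that("a covariate that drives the group difference attenuates it", {
  # group B's extra module-1 covariance is carried entirely by the wmh
  # score; adjusting for wmh should shrink the resilience difference
  set.seed(7)
  R <- 16; n <- 20
  spec <- synthetic_spec(n_regions = R, n_subjects = c(n, n), n_modules = 2,
                         within_rho = c(0.45, 0.45), between_rho = c(0.1, 0.1),
                         covariate_effects = list())
  g <- generate_cohort(spec, seed = 7)
  cohort <- g$cohort
  idx_b <- which(cohort$group == "patient")
  loading <- c(rep(0.12, R / 2), rep(0, R / 2))
  wmh_c <- scale(cohort$covariates$wmh[idx_b])[, 1]
  cohort$thickness[idx_b, ] <- cohort$thickness[idx_b, ] +
    outer(wmh_c, loading)
  cohort$covariates$mean_thickness <- rowMeans(cohort$thickness)
  base_covs <- c("age", "gender", "illness")
  unadj <- compare_resilience(cohort, mode = "targeted",
                              grid = density_grid(0.2, 0.5, 0.05),
                              n_perm = 49, seed = 8,
                              covariate_names = base_covs)
  adj <- compare_resilience(cohort, mode = "targeted",
                            grid = density_grid(0.2, 0.5, 0.05),
                            n_perm = 49, seed = 8,
                            covariate_names = base_covs,
                            extra_covariates = "wmh")
  expect_lt(mean(abs(adj$observed_diff)), mean(abs(unadj$observed_diff)))
})
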