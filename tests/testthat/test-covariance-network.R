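make_cohort <- function(n = 12, R = 5, seed = 1, f = NULL) {
  set.seed(seed)
  th <- matrix(2.3 + rnorm(n * R, sd = 0.1), n, R,
               dimnames = list(NULL, paste0("roi_", seq_len(R))))
  age <- runif(n, 60, 84)
  if (!is.null(f)) th <- th + outer(f(age), rep(1, R))
  cohort_table(th, rep(c("ctl", "pat"), length.out = n),
               data.frame(age = age, gender = rbinom(n, 1, 0.3)),
               subject_id = paste0("s", seq_len(n)))
}

test_that("residualization removes covariate effects as OLS residuals", {
  cohort <- make_cohort(20, 6, seed = 2)
  res <- residualize(cohort, c("age", "gender"))
  # per-group residual means are 0 (intercept included)
  for (g in levels(cohort$group))
    expect_lt(max(abs(colMeans(res$thickness[cohort$group == g, ]))), 1e-12)
  # intercept-only = group-mean centering
  res0 <- residualize(cohort, character(0))
  ctr <- cohort$thickness
  for (g in levels(cohort$group)) {
    idx <- cohort$group == g
    ctr[idx, ] <- sweep(ctr[idx, , drop = FALSE], 2,
                        colMeans(ctr[idx, , drop = FALSE]))
  }
  expect_equal(res0$thickness, ctr)
  # thickness exactly linear in age -> zero residuals
  lin <- make_cohort(20, 4, seed = 3)
  lin$thickness[, 2] <- 1 + 0.02 * lin$covariates$age
  rlin <- residualize(lin, "age")
  expect_lt(max(abs(rlin$thickness[, 2])), 1e-12)
  # rank-deficient design names the constant covariate
  bad <- make_cohort(20, 4, seed = 4)
  bad$covariates$flat <- 1
  expect_error(residualize(bad, c("age", "flat")), "flat")
})

test_that("residualization is idempotent and covariate-scale invariant", {
  cohort <- make_cohort(24, 8, seed = 5)
  res1 <- residualize(cohort, c("age", "gender"))
  res2 <- residualize(res1, c("age", "gender"))
  expect_lt(max(abs(res1$thickness - res2$thickness)), 1e-10)
  # affine rescaling of a covariate leaves the association matrix unchanged
  scaled <- cohort
  scaled$covariates$age <- 3 * scaled$covariates$age + 7
  a1 <- build_association(residualize(cohort, c("age", "gender")), "ctl")
  a2 <- build_association(residualize(scaled, c("age", "gender")), "ctl")
  expect_lt(max(abs(a1 - a2)), 1e-10)
})

test_that("association matrices are Pearson correlations with zero diagonal", {
  cohort <- make_cohort(12, 5, seed = 6)
  cohort$thickness[, 2] <- cohort$thickness[, 1]           # identical
  cohort$thickness[, 3] <- 9 - cohort$thickness[, 1]       # negated
  res <- residualize(cohort, character(0))
  a <- build_association(res, "ctl")
  expect_equal(a[1, 2], 1)
  expect_equal(a[1, 3], -1)
  expect_true(all(diag(a) == 0))
  expect_true(isSymmetric(unclass(a)))
  expect_true(all(abs(a[upper.tri(a)]) <= 1))
  expect_equal(attr(a, "n_subjects"), 6L)
  # zero-variance region is refused by name
  flat <- make_cohort(12, 4, seed = 7)
  flat$thickness[, 3] <- 2.5
  expect_error(build_association(residualize(flat, character(0)), "ctl"),
               "roi_3")
  expect_error(build_association(res, "nosuch"), "unknown group")
})

test_that("empirical correlations converge to the generating block structure", {
  # 2-block spec, strong within / zero between correlation, n = 200;
  # no covariate confounds so raw correlations estimate the blocks directly
  spec <- synthetic_spec(n_regions = 8, n_subjects = c(200, 200),
                         n_modules = 2, within_rho = c(0.8, 0.8),
                         between_rho = c(0, 0), noise_sd = 0.02,
                         covariate_effects = list())
  g <- generate_cohort(spec, seed = 8)
  res <- residualize(g$cohort, character(0))
  a <- build_association(res, "control")
  truth <- g$truth$correlation$control
  within <- g$truth$modules[col(a)] == g$truth$modules[row(a)] &
    upper.tri(a)
  between <- !within & upper.tri(a)
  expect_lt(abs(mean(a[within]) - truth[1, 2]), 0.05)
  expect_lt(abs(mean(a[between]) - truth[1, 8]), 0.05)
})

test_that("density thresholding keeps the top signed correlations", {
  set.seed(9)
  r <- matrix(runif(68 * 68, -1, 1), 68, 68)
  r <- (r + t(r)) / 2; diag(r) <- 0
  net <- threshold_at_density(r, 0.10)
  expect_equal(attr(net, "n_edges"), 228)   # round(0.10 * 68 * 67 / 2)
  full <- threshold_at_density(r, 1.0)
  expect_equal(attr(full, "n_edges"), 68 * 67 / 2)
  expect_true(all(full[upper.tri(full)] == 1))
  # top-1 selection on a tiny matrix
  r3 <- matrix(0, 3, 3)
  r3[1, 2] <- r3[2, 1] <- 0.9
  r3[1, 3] <- r3[3, 1] <- 0.5
  r3[2, 3] <- r3[3, 2] <- 0.1
  net3 <- suppressWarnings(threshold_at_density(r3, 1 / 3))
  expect_equal(sum(net3), 2)
  expect_equal(net3[1, 2], 1)
  # strong negative correlations are not edges under signed ranking
  r3[2, 3] <- r3[3, 2] <- -0.95
  net3b <- suppressWarnings(threshold_at_density(r3, 2 / 3))
  expect_equal(unclass(net3b)[2, 3], 0)
  expect_equal(suppressWarnings(threshold_at_density(r3, 2 / 3,
               rank_absolute = TRUE))[2, 3], 1)
  expect_warning(threshold_at_density(r, 0.005), "cannot be connected")
  expect_error(threshold_at_density(r, 1.2), "density > 1")
})

test_that("thresholds are nested and largest components grow with density", {
  set.seed(10)
  for (rep in 1:5) {
    r <- matrix(rnorm(20^2), 20, 20)
    r <- (r + t(r)) / 2; diag(r) <- 0
    prev <- NULL
    prev_lcc <- 0
    for (d in seq(0.1, 0.9, by = 0.2)) {
      net <- suppressWarnings(threshold_at_density(r, d))
      if (!is.null(prev)) expect_true(all(net[prev == 1] == 1))
      lcc <- max(igraph::components(igraph::graph_from_adjacency_matrix(
        unclass(net), mode = "undirected"))$csize)
      expect_gte(lcc, prev_lcc)
      prev <- unclass(net)
      prev_lcc <- lcc
    }
  }
})

test_that("minimum density is the first grid point connecting every group", {
  # spanning path planted in the top R-1 correlations
  R <- 10
  a <- matrix(0.01, R, R); diag(a) <- 0
  for (i in 1:(R - 1)) a[i, i + 1] <- a[i + 1, i] <- 0.9 - 0.01 * i
  grid <- c(0.1, 0.2, 0.3)   # E = 4, 9, 14; the path needs 9 edges
  expect_equal(find_min_density(list(a), grid), 0.2)
  # two groups: the harder group sets the threshold
  b <- matrix(0.01, R, R); diag(b) <- 0
  b[1:5, 1:5] <- 0.9; b[6:10, 6:10] <- 0.9; diag(b) <- 0
  b[1, 6] <- b[6, 1] <- 0.5   # single bridge ranked below clique edges
  expect_equal(find_min_density(list(a, b), c(0.1, 0.2, 0.3, 0.5)), 0.5)
  expect_error(find_min_density(list(b), c(0.1, 0.2)),
               "largest components at density 0.2")
})
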