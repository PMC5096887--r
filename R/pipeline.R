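# End-to-end orchestration: one config drives residualization, association,
# minimum density, metric curves, permutation/AUC comparison, nodal
# comparison, resilience and hub identification, with all outputs written as
# labeled CSV plus a JSON manifest recording seed and configuration.

#' Assemble a run configuration
#'
#' @param input path to a cohort table file (NULL to simulate instead).
#' @param schema column schema for [read_cohort()] (ignored when
#'   simulating).
#' @param simulate a `synthetic_spec` used when `input` is NULL.
#' @param covariates nuisance covariate columns (NULL: all non-WMH columns).
#' @param grid density grid.
#' @param n_perm permutations for all statistical comparisons.
#' @param seed master seed; every random component draws a named substream
#'   from it.
#' @param metrics global metrics to compare (see [comparable_metrics()]).
#' @param resilience_modes subset of `c("targeted", "random")`.
#' @param resilience_covariates optional extra covariates for an adjusted
#'   resilience variant (e.g. `"wmh"`).
#' @param n_ref reference networks for small-world normalization.
#' @param n_repeats random-failure removal orders.
#' @param hub_z hub z-score threshold.
#' @param out_dir output directory.
#' @return a `run_config` list.
#' @export
run_config <- function(input = NULL, schema = NULL, simulate = NULL,
                       covariates = NULL, grid = density_grid(),
                       n_perm = 1000, seed = 1,
                       metrics = comparable_metrics(),
                       resilience_modes = c("targeted", "random"),
                       resilience_covariates = NULL,
                       n_ref = 20, n_repeats = 50, hub_z = 2,
                       out_dir = "sconet-results") {
  if (is.null(input) && is.null(simulate))
    simulate <- synthetic_spec(seed = seed)
  if (n_perm < 1) stop("n_perm must be >= 1")
  structure(list(input = input, schema = schema, simulate = simulate,
                 covariates = covariates, grid = grid, n_perm = n_perm,
                 seed = seed, metrics = metrics,
                 resilience_modes = resilience_modes,
                 resilience_covariates = resilience_covariates,
                 n_ref = n_ref, n_repeats = n_repeats, hub_z = hub_z,
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Recognized keys mirror the arguments of [run_config()]; `grid` is given
#' as `{from, to, by}` and `schema` as a mapping with `group_col`,
#' `covariate_cols` and `region_cols`/`region_prefix`.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  g <- if (!is.null(y$grid))
    density_grid(y$grid$from, y$grid$to, y$grid$by) else density_grid()
  run_config(input = y$input, schema = y$schema,
             covariates = unlist(y$covariates),
             grid = g, n_perm = y$n_perm %||% 1000, seed = y$seed %||% 1,
             metrics = y$metrics %||% comparable_metrics(),
             resilience_modes = y$resilience_modes %||% c("targeted", "random"),
             resilience_covariates = unlist(y$resilience_covariates),
             n_ref = y$n_ref %||% 20, n_repeats = y$n_repeats %||% 50,
             hub_z = y$hub_z %||% 2,
             out_dir = y$out_dir %||% "sconet-results")
}

#' Run the full structural covariance network analysis
#'
#' Executes residualize, associate, minimum density, threshold grid, global
#' metric curves with small-world normalization, permutation/AUC
#' comparisons, nodal comparisons at the minimum density, resilience in the
#' requested modes (plus the covariate-adjusted variant when configured),
#' and hub identification. Each stage's outputs are written as labeled CSV
#' under `config$out_dir`; a `manifest.json` records the package version,
#' seed, configuration hash and completed stages. A stage failure aborts
#' with the stage name after writing the partial manifest.
#'
#' @param config a `run_config`.
#' @return (invisibly) a list with the in-memory results of every stage.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "sconet",
                   version = as.character(utils::packageVersion("sconet")),
                   r_version = R.version.string,
                   seed = config$seed,
                   n_perm = config$n_perm,
                   grid = config$grid,
                   stages = character(0))
  res <- list()
  stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e) {
      manifest$error <<- paste0("stage '", name, "': ", conditionMessage(e))
      jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages <<- c(manifest$stages, name)
    out
  }

  res$cohort <- stage("input", {
    if (!is.null(config$input)) read_cohort(config$input, config$schema)
    else generate_cohort(config$simulate, seed = config$seed)$cohort
  })
  covs <- config$covariates %||% .default_covariates(res$cohort)
  manifest$covariates <- covs
  groups <- levels(res$cohort$group)

  res$association <- stage("association", {
    resid <- residualize(res$cohort, covs)
    assoc <- lapply(groups, function(g) build_association(resid, g))
    names(assoc) <- groups
    for (g in groups)
      write_matrix(assoc[[g]],
                   file.path(config$out_dir, paste0("association_", g, ".csv")))
    assoc
  })

  res$d_min <- stage("min_density", {
    d <- tryCatch(find_min_density(res$association, config$grid),
                  error = function(e) NA_real_)
    if (is.na(d)) {
      # no grid density connects every group: analyze at the top of the
      # grid and flag it, rather than aborting the whole run
      manifest$d_min_fallback <<- TRUE
      d <- max(config$grid)
    }
    d
  })
  res$networks <- stage("threshold", {
    nets <- lapply(res$association, function(a)
      suppressWarnings(threshold_at_density(a, res$d_min)))
    for (g in groups)
      write_matrix(nets[[g]],
                   file.path(config$out_dir,
                             paste0("adjacency_", g, "_dmin.csv")))
    nets
  })

  res$metric_curves <- stage("metrics", {
    tabs <- lapply(groups, function(g) {
      rows <- lapply(seq_along(config$grid), function(di) {
        net <- suppressWarnings(threshold_at_density(res$association[[g]],
                                                     config$grid[di]))
        # no connected degree-preserving reference exists e.g. for networks
        # with isolated nodes; report unnormalized metrics in that case
        refs <- tryCatch(
          random_reference(net, n_networks = config$n_ref,
                           seed = .sub_seed(config$seed, 300L + di)),
          error = function(e) NULL)
        gm <- global_metrics(net, refs)
        if (is.null(refs))
          gm <- c(gm, list(gamma = NA_real_, lambda = NA_real_,
                           sigma = NA_real_))
        as.data.frame(c(list(density = config$grid[di]), gm))
      })
      tab <- do.call(rbind, rows)
      utils::write.csv(tab, file.path(config$out_dir,
                                      paste0("metrics_", g, ".csv")),
                       row.names = FALSE)
      tab
    })
    names(tabs) <- groups
    tabs
  })

  res$comparison <- stage("comparison", {
    pr <- permute_compare(res$cohort, metrics = config$metrics,
                          grid = config$grid, n_perm = config$n_perm,
                          seed = config$seed, covariate_names = covs)
    summ <- auc_compare(pr)
    utils::write.csv(summ, file.path(config$out_dir, "auc_comparison.csv"),
                     row.names = FALSE)
    band <- do.call(rbind, lapply(pr$metrics, function(m)
      data.frame(metric = m, density = pr$grid, diff = pr$observed_diff[m, ],
                 p = pr$p_density[m, ], ci_lower = pr$ci_band$lower[m, ],
                 ci_upper = pr$ci_band$upper[m, ])))
    utils::write.csv(band, file.path(config$out_dir, "density_comparison.csv"),
                     row.names = FALSE)
    pr
  })

  res$nodal <- stage("nodal", {
    nod <- nodal_compare(res$cohort, density = res$d_min,
                         n_perm = config$n_perm, seed = config$seed,
                         covariate_names = covs,
                         require_connected = !isTRUE(manifest$d_min_fallback))
    utils::write.csv(nod, file.path(config$out_dir, "nodal_comparison.csv"),
                     row.names = FALSE)
    nod
  })

  res$resilience <- stage("resilience", {
    out <- list()
    for (mode in config$resilience_modes) {
      rc <- compare_resilience(res$cohort, mode = mode, grid = config$grid,
                               n_perm = config$n_perm, seed = config$seed,
                               covariate_names = covs,
                               n_repeats = config$n_repeats)
      tab <- data.frame(fraction = rc$fractions,
                        stats::setNames(as.data.frame(rc$curves), groups),
                        diff = rc$observed_diff, p = rc$p)
      utils::write.csv(tab, file.path(config$out_dir,
                                      paste0("resilience_", mode, ".csv")),
                       row.names = FALSE)
      out[[mode]] <- rc
      if (!is.null(config$resilience_covariates)) {
        rca <- compare_resilience(res$cohort, mode = mode, grid = config$grid,
                                  n_perm = config$n_perm, seed = config$seed,
                                  covariate_names = covs,
                                  extra_covariates = config$resilience_covariates,
                                  n_repeats = config$n_repeats)
        taba <- data.frame(fraction = rca$fractions,
                           stats::setNames(as.data.frame(rca$curves), groups),
                           diff = rca$observed_diff, p = rca$p)
        utils::write.csv(taba,
                         file.path(config$out_dir,
                                   paste0("resilience_", mode, "_adjusted.csv")),
                         row.names = FALSE)
        out[[paste0(mode, "_adjusted")]] <- rca
      }
    }
    out
  })

  res$hubs <- stage("hubs", {
    hs <- lapply(groups, function(g)
      identify_hubs(res$networks[[g]], z_threshold = config$hub_z))
    names(hs) <- groups
    tab <- do.call(rbind, lapply(groups, function(g) {
      h <- hs[[g]]
      if (nrow(h) == 0) return(NULL)
      data.frame(group = g, h)
    }))
    if (is.null(tab))
      tab <- data.frame(group = character(), region = character(),
                        betweenness = numeric(), z = numeric())
    utils::write.csv(tab, file.path(config$out_dir, "hubs.csv"),
                     row.names = FALSE)
    hs
  })

  cfg_json <- jsonlite::toJSON(config[setdiff(names(config),
                                              c("schema", "simulate"))],
                               auto_unbox = TRUE, digits = NA)
  manifest$config_hash <- unname(tools::md5sum(
    local({ f <- tempfile(); writeLines(cfg_json, f); f })))
  manifest$d_min <- res$d_min
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
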