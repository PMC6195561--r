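#' Default pipeline configuration
#'
#' Study conditions for a fully synthetic end-to-end run: landscapes are
#' drawn from the three activity archetypes, each with a centred square
#' protected area surrounded by unprotected forest, 14 modelled disturbance
#' years on a 17-year climate series (3 years of history keep lags 0-3
#' usable), 30 m cells. Outside the protected area, the low- and
#' moderate-activity generators emulate human land use (larger, more compact
#' patches at a higher rate); the high-activity generator uses the identical
#' process on both sides.
#'
#' Driver coefficients per archetype follow the cluster-specific estimates of
#' the global analysis this pipeline emulates: immediate positive
#' temperature effect amplified by dry years for the high-activity group,
#' weaker lagged negative temperature / positive precipitation effects for
#' the low group, and a negative temperature effect with a negative
#' interaction for the moderate group.
#'
#' @param n_per_archetype named integer vector of landscape counts.
#' @param protected_dim protected-area square edge, in cells.
#' @param margin_cells unprotected margin width around the protected area;
#'   default accommodates the full MBR-diagonal buffer.
#' @param n_years climate series length; disturbance years are
#'   `start_year..n_years`.
#' @param start_year first modelled disturbance year.
#' @param pixel_fraction pixel sampling fraction for the driver models; at
#'   this problem size every pixel is kept by default.
#' @param bootstrap_B parametric bootstrap replicates for cluster summaries.
#' @param n_perm permutations for the association and contrast tests.
#' @param n_sim response-curve simulation draws.
#' @param dem_roughness vertical relief (m) of the synthetic DEMs.
#' @param mode disturbance generator mode for the pattern analyses.
#' @return a config list.
#' @export
pipeline_config <- function(n_per_archetype = c(low = 18, moderate = 23,
                                                high = 9),
                            protected_dim = 80,
                            margin_cells = NULL,
                            n_years = 17, start_year = 4,
                            pixel_fraction = 1.0,
                            bootstrap_B = 199,
                            n_perm = 999,
                            n_sim = 999,
                            dem_roughness = 60,
                            mode = "patchy") {
  ## margin matches the MBR-diagonal buffer width exactly, so the outside
  ## growth region coincides with the buffer along the straight edges and
  ## outside patches are clipped by the grid edge symmetrically with inside
  ## patches at the protected boundary
  margin_cells <- margin_cells %||% floor(sqrt(2) * protected_dim)
  drivers <- list(
    low = driver_params(beta0 = beta0_for_pland(0.31, n_years - start_year + 1),
                        beta_T = -0.20, beta_P = 0.33, beta_TP = 0,
                        beta_TRI = 0.30, sigma_b = 0.25, lag = 2),
    moderate = driver_params(beta0 = beta0_for_pland(4.6, n_years - start_year + 1),
                             beta_T = -0.30, beta_P = 0, beta_TP = -0.17,
                             beta_TRI = -0.05, sigma_b = 0.25, lag = 3),
    high = driver_params(beta0 = beta0_for_pland(21.5, n_years - start_year + 1),
                         beta_T = 0.59, beta_P = -0.10, beta_TP = -0.43,
                         beta_TRI = -0.10, sigma_b = 0.25, lag = 0)
  )
  ## outside-process modifiers: human land use enlarges and regularises
  ## patches in the low/moderate groups; the high group is process-identical
  outside <- list(
    low = list(area_scale = 10, irregularity = 0.15, rate_logit_shift = 1.5),
    moderate = list(area_scale = 10, irregularity = 0.15, rate_logit_shift = 1.0),
    high = list(area_scale = 1, irregularity = NA, rate_logit_shift = 0)
  )
  list(n_per_archetype = n_per_archetype, protected_dim = protected_dim,
       margin_cells = margin_cells, n_years = n_years,
       start_year = start_year, pixel_fraction = pixel_fraction,
       bootstrap_B = bootstrap_B, n_perm = n_perm, n_sim = n_sim,
       dem_roughness = dem_roughness, mode = mode,
       drivers = drivers, outside = outside,
       climate = list(t_sd = 0.8, p_sd = 150, ar = 0.3),
       cell_size_m = 30)
}

## 31-bit polynomial rolling hash of the deparsed config, for the manifest
config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Simulate a full set of study landscapes
#'
#' Generates, per landscape: a DEM, a per-landscape climate series, a
#' protected-area mask (centred square), a random intercept, and
#' first-disturbance-year grids from the archetype's generative process —
#' one process inside the protected area and (optionally modified) one in
#' the unprotected surroundings. Also draws the ecological context tables.
#'
#' @param config a [pipeline_config()].
#' @param seed master seed; all stage seeds derive from it.
#' @return list: `landscapes` (list of per-landscape bundles), `context`
#'   (agents/species/traits tables), `archetypes` (character vector),
#'   `config`.
#' @export
simulate_landscapes <- function(config = pipeline_config(), seed = 1) {
  archetypes <- rep(names(config$n_per_archetype), config$n_per_archetype)
  n <- length(archetypes)
  dim_grid <- config$protected_dim + 2 * config$margin_cells
  landscapes <- vector("list", n)
  for (i in seq_len(n)) {
    arch_name <- archetypes[i]
    arch <- landscape_archetype(arch_name)
    pars <- config$drivers[[arch_name]]
    s <- stage_seed(seed, i * 10)
    dem <- generate_dem(dim_grid, dim_grid, config$dem_roughness,
                        seed = s)
    climate <- with_seed(stage_seed(seed, i * 10 + 1), function() {
      generate_climate_series(config$n_years, seed = NULL,
                              t_mean = stats::runif(1, 1, 12),
                              t_sd = config$climate$t_sd,
                              p_mean = stats::runif(1, 700, 2000),
                              p_sd = config$climate$p_sd,
                              ar = config$climate$ar)
    })
    het <- with_seed(stage_seed(seed, i * 10 + 2), function() {
      list(b = stats::rnorm(1, 0, pars$sigma_b),
           ## landscapes differ in patch geometry, not only in rate:
           ## per-landscape jitter on shape irregularity and patch-size cap
           irr_jit = stats::runif(1, -0.05, 0.05),
           amax_fac = exp(stats::rnorm(1, 0, 0.15)))
    })
    b <- het$b
    arch$shape_irregularity <- min(1, max(0, arch$shape_irregularity +
                                            het$irr_jit))
    arch$amax_cells <- max(arch$amin_cells + 1,
                           round(arch$amax_cells * het$amax_fac))
    forest <- matrix(TRUE, dim_grid, dim_grid)
    protected <- matrix(FALSE, dim_grid, dim_grid)
    core <- config$margin_cells + seq_len(config$protected_dim)
    protected[core, core] <- TRUE

    om <- config$outside[[arch_name]]
    identical_process <- om$area_scale == 1 && om$rate_logit_shift == 0 &&
      is.na(om$irregularity)
    if (identical_process) {
      ## natural disturbance does not stop at the protected-area fence:
      ## one process over the whole landscape; patches straddling the
      ## boundary are clipped analytically by the stratified metrics
      whole <- generate_disturbance_series(
        forest, dem, climate,
        truth = list(params = pars, b = b, archetype = arch),
        mode = config$mode, seed = stage_seed(seed, i * 10 + 3),
        start_year = config$start_year)
      dist_grid <- whole$values
    } else {
      ## human land use outside: a different process that does stop at the
      ## fence (larger, more compact patches at a higher rate)
      inside <- generate_disturbance_series(
        forest & protected, dem, climate,
        truth = list(params = pars, b = b, archetype = arch),
        mode = config$mode, seed = stage_seed(seed, i * 10 + 3),
        start_year = config$start_year)
      arch_out <- arch
      arch_out$shape_irregularity <- om$irregularity
      arch_out$amin_cells <- arch$amin_cells * om$area_scale
      arch_out$amax_cells <- arch$amax_cells * om$area_scale
      pars_out <- pars
      pars_out$beta0 <- pars$beta0 + om$rate_logit_shift
      outside <- generate_disturbance_series(
        forest & !protected, dem, climate,
        truth = list(params = pars_out, b = b, archetype = arch_out),
        mode = config$mode, seed = stage_seed(seed, i * 10 + 4),
        start_year = config$start_year)
      dist_grid <- inside$values + outside$values
    }
    landscapes[[i]] <- list(
      landscape_id = i, archetype = arch_name,
      dem = dem, climate = climate, forest = forest, protected = protected,
      disturbance = structure(ds_grid(dist_grid),
                              start_year = config$start_year,
                              years = config$start_year:config$n_years),
      truth = list(params = pars, b = b, archetype = arch, seed = s))
  }
  context <- generate_context_tables(archetypes,
                                     seed = stage_seed(seed, 9001))
  list(landscapes = landscapes, context = context, archetypes = archetypes,
       config = config)
}

## top-2 genera per landscape from basal-area shares
top_genera <- function(species_tab, traits) {
  gmap <- stats::setNames(traits$genus, traits$species)
  lapply(split(species_tab, species_tab$landscape_id), function(s) {
    by_g <- tapply(s$share, gmap[s$species], sum)
    names(sort(by_g, decreasing = TRUE))[seq_len(min(2, length(by_g)))]
  })
}

#' Run the full disturbance-pattern analysis pipeline
#'
#' End-to-end: simulate landscapes (or accept a pre-simulated set), compute
#' the four pattern metrics per landscape on the protected stratum, cluster
#' landscapes with a BIC-selected Gaussian mixture and summarise clusters by
#' parametric bootstrap, run the agent/genus homogeneity and trait tests,
#' contrast patch patterns inside vs outside protected areas per cluster,
#' and fit the climate/topography driver models (lag selection, model
#' comparison, response curves) per cluster. Optionally writes all result
#' tables as CSV plus a reproducibility manifest.
#'
#' @param config a [pipeline_config()].
#' @param seed master seed.
#' @param out_dir optional output directory for CSV artifacts.
#' @param sim optional pre-simulated result of [simulate_landscapes()].
#' @return a result bundle (list); see elements `metrics`, `model`,
#'   `assignments`, `cluster_summary`, `context_tests`, `contrast`,
#'   `drivers`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1,
                         out_dir = NULL, sim = NULL) {
  sim <- sim %||% simulate_landscapes(config, seed)
  lss <- sim$landscapes

  ## --- pattern metrics on the protected stratum -------------------------
  metrics <- do.call(rbind, lapply(lss, function(ls) {
    m <- landscape_metrics((ls$disturbance$values != 0 & ls$protected) * 1L,
                           ls$protected * 1L, config$cell_size_m)
    cbind(landscape_id = ls$landscape_id, archetype = ls$archetype, m)
  }))

  ## --- mixture clustering ----------------------------------------------
  X <- preprocess_metrics(metrics)
  tr <- attr(X, "transform")
  model <- select_model(X, K_range = 1:6,
                        families = c("spherical", "diagonal",
                                     "full_equal", "full"),
                        n_init = 40, ridge = 0.02,
                        seed = stage_seed(seed, 21))
  asg <- assign_clusters(model, X)
  assignments <- data.frame(
    landscape_id = metrics$landscape_id[tr$kept_rows],
    archetype = metrics$archetype[tr$kept_rows],
    cluster = asg$labels)
  csum <- parametric_bootstrap_summary(model, X, B = config$bootstrap_B,
                                       seed = stage_seed(seed, 22))
  ## raw-scale cluster summary: back-transform matched bootstrap means
  raw_rows <- list()
  for (k in seq_len(model$K)) {
    bm <- csum$boot_means[, k, , drop = FALSE]
    dim(bm) <- c(dim(csum$boot_means)[1], model$d)
    bm <- bm[stats::complete.cases(bm), , drop = FALSE]
    raw_b <- if (nrow(bm)) inverse_preprocess(bm, tr) else NULL
    raw_m <- inverse_preprocess(model$means[k, ], tr)
    for (j in seq_along(tr$features)) {
      raw_rows[[length(raw_rows) + 1]] <- data.frame(
        cluster = k, feature = tr$features[j], mean = raw_m[1, j],
        lower = if (!is.null(raw_b)) stats::quantile(raw_b[, j], 0.025, names = FALSE) else NA,
        upper = if (!is.null(raw_b)) stats::quantile(raw_b[, j], 0.975, names = FALSE) else NA)
    }
  }
  cluster_summary <- list(feature_scale = csum$summary,
                          raw_scale = do.call(rbind, raw_rows),
                          B_failed = csum$B_failed)

  ## --- context: agents, genera, traits ----------------------------------
  cl_of <- stats::setNames(assignments$cluster, assignments$landscape_id)
  ctx <- sim$context
  traits <- trait_profile(ctx$species, ctx$traits)
  traits <- traits[traits$landscape_id %in% names(cl_of), ]
  if (model$K >= 2) {
    agents2 <- lapply(split(ctx$agents, ctx$agents$landscape_id),
                      function(a) a$agent[order(a$rank)])
    keep_ids <- names(agents2)[names(agents2) %in% names(cl_of)]
    chi2_agents <- permutation_chi2_test(agents2[keep_ids],
                                         unname(cl_of[keep_ids]),
                                         n_perm = config$n_perm,
                                         seed = stage_seed(seed, 31))
    genera2 <- top_genera(ctx$species, ctx$traits)
    chi2_genera <- permutation_chi2_test(genera2[keep_ids],
                                         unname(cl_of[keep_ids]),
                                         n_perm = config$n_perm,
                                         seed = stage_seed(seed, 32))
    trait_tests <- list()
    for (v in c("dominance_pct", "conifer_pct", "max_height_m",
                "wood_density_g_cm3")) {
      pw <- pairwise_kw_fdr(traits[[v]],
                            cl_of[as.character(traits$landscape_id)],
                            n_perm = config$n_perm,
                            seed = stage_seed(seed, 33 + match(v, names(traits))))
      trait_tests[[v]] <- pw
    }
  } else {
    warning("single cluster selected: association tests across clusters skipped")
    chi2_agents <- chi2_genera <- NULL
    trait_tests <- list()
  }
  context_tests <- list(agents = chi2_agents, genera = chi2_genera,
                        traits = trait_tests, trait_profile = traits)

  ## --- protected vs unprotected contrast --------------------------------
  strat <- do.call(rbind, lapply(lss, function(ls) {
    sm <- stratified_metrics(ls$disturbance, ls$forest, ls$protected,
                             cell_size_m = config$cell_size_m)
    cbind(landscape_id = ls$landscape_id, sm)
  }))
  strat$cluster <- cl_of[as.character(strat$landscape_id)]
  contrast_tests <- list()
  for (v in c("awmps_ha", "awm_par_m_per_ha")) {
    df <- data.frame(landscape_id = strat$landscape_id,
                     cluster = strat$cluster, stratum = strat$stratum,
                     value = strat[[v]])
    contrast_tests[[v]] <- tryCatch(
      compare_strata(df, n_perm = config$n_perm,
                     seed = stage_seed(seed, 41 + match(v, c("awmps_ha", "awm_par_m_per_ha")))),
      error = function(e) NULL)
  }
  contrast <- list(metrics = strat, tests = contrast_tests)

  ## --- drivers per cluster ----------------------------------------------
  drivers <- list()
  for (k in sort(unique(assignments$cluster))) {
    ids <- assignments$landscape_id[assignments$cluster == k]
    if (length(ids) < 2) next
    tabs <- list(); anoms <- list()
    for (id in ids) {
      ls <- lss[[id]]
      tri <- compute_tri(ls$dem, window = 7)
      fmask <- ls$forest & ls$protected
      triz <- matrix(NA_real_, nrow(fmask), ncol(fmask))
      tv <- tri$tri[fmask]
      triz[fmask] <- if (stats::sd(tv) == 0) 0 else zscore(tv)
      an <- climate_anomalies(ls$climate)
      an$landscape_id <- id
      anoms[[length(anoms) + 1]] <- an
      tabs[[length(tabs) + 1]] <- build_pixel_year_table(
        ls$disturbance, fmask, triz, an, lag = 0,
        years = config$start_year:config$n_years, landscape_id = id)
    }
    tab <- do.call(rbind, tabs)
    anom <- do.call(rbind, anoms)
    sampled <- sample_case_control(tab, config$pixel_fraction,
                                   seed = stage_seed(seed, 50 + k))
    run_driver <- function(nAGQ) {
      lag_sel <- select_lag(sampled, anom, lags = 0:3, nAGQ = nAGQ)
      best <- lag_sel$fits[[as.character(lag_sel$best_lag)]]
      ## model comparison at the selected lag
      key <- paste(sampled$landscape_id, sampled$year - lag_sel$best_lag)
      idx <- match(key, paste(anom$landscape_id, anom$year))
      tab_best <- sampled
      tab_best$t_anom <- anom$t_anom[idx]
      tab_best$p_anom <- anom$p_anom[idx]
      cmp <- compare_models(tab_best, nAGQ = nAGQ)
      rc <- simulate_response_curves(best, n_sim = config$n_sim,
                                     seed = stage_seed(seed, 60 + k))
      list(cluster = k, n_landscapes = length(ids), lag = lag_sel,
           fit = best, comparison = cmp, response_curves = rc)
    }
    ## Laplace fit first; fall back to the faster PIRLS-only approximation
    ## when the inner optimisation fails on a sparse cluster
    res <- tryCatch(run_driver(1), error = function(e1) {
      tryCatch(run_driver(0), error = function(e2) {
        warning("driver analysis failed for cluster ", k, ": ",
                conditionMessage(e2))
        NULL
      })
    })
    drivers[[as.character(k)]] <- res
  }

  manifest <- list(seed = seed, config_hash = config_hash(config),
                   n_landscapes = length(lss),
                   archetypes = table(sim$archetypes),
                   K_selected = model$K, family = model$family,
                   preprocessing = tr[c("log_features", "eps", "center", "scale")],
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))

  bundle <- list(sim = sim, metrics = metrics, model = model,
                 assignments = assignments, cluster_summary = cluster_summary,
                 context_tests = context_tests, contrast = contrast,
                 drivers = drivers, manifest = manifest)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' Write pipeline result tables as CSV
#'
#' @param bundle a [run_pipeline()] result.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  w(bundle$metrics[order(bundle$metrics$landscape_id), ], "metrics.csv")
  w(bundle$model$bic_table, "bic_table.csv")
  w(bundle$assignments, "memberships.csv")
  w(bundle$cluster_summary$feature_scale, "cluster_summary_features.csv")
  w(bundle$cluster_summary$raw_scale, "cluster_summary_raw.csv")
  ct <- bundle$context_tests
  if (!is.null(ct$agents)) {
    w(data.frame(test = c("agents_chi2", "genera_chi2"),
                 statistic = c(ct$agents$statistic, ct$genera$statistic),
                 p_value = c(ct$agents$p_value, ct$genera$p_value)),
      "context_chi2.csv")
  }
  if (length(ct$traits)) {
    w(do.call(rbind, lapply(names(ct$traits), function(v)
      cbind(trait = v, ct$traits[[v]]))), "context_trait_tests.csv")
  }
  w(bundle$contrast$metrics, "contrast_metrics.csv")
  tst <- bundle$contrast$tests
  if (length(tst)) {
    w(do.call(rbind, lapply(names(tst), function(v)
      if (!is.null(tst[[v]])) cbind(metric = v, tst[[v]]))),
      "contrast_tests.csv")
  }
  drv <- bundle$drivers
  if (length(drv)) {
    coefs <- do.call(rbind, lapply(drv, function(d) {
      if (is.null(d)) return(NULL)
      data.frame(cluster = d$cluster, term = names(d$fit$beta),
                 estimate = unname(d$fit$beta), se = d$fit$se,
                 sigma_b = d$fit$sigma_b, lag = d$lag$best_lag)
    }))
    w(coefs, "glmm_coefficients.csv")
    w(do.call(rbind, lapply(drv, function(d)
      if (!is.null(d)) cbind(cluster = d$cluster, d$lag$aic_table))),
      "lag_aic.csv")
    w(do.call(rbind, lapply(drv, function(d)
      if (!is.null(d)) cbind(cluster = d$cluster, d$comparison$table))),
      "model_comparison.csv")
    w(do.call(rbind, lapply(drv, function(d)
      if (!is.null(d)) cbind(cluster = d$cluster, d$response_curves))),
      "response_curves.csv")
  }
  mf <- bundle$manifest
  writeLines(c(
    sprintf("seed: %d", mf$seed),
    sprintf("config_hash: %s", mf$config_hash),
    sprintf("n_landscapes: %d", mf$n_landscapes),
    sprintf("K_selected: %d", mf$K_selected),
    sprintf("family: %s", mf$family),
    sprintf("r_version: %s", mf$r_version),
    sprintf("timestamp: %s", mf$timestamp)),
    file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}
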