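test_that("TRI: flat surface, translation invariance, ramp closed form, oracle", {
  expect_true(all(compute_tri(matrix(5, 10, 10), 7)$tri == 0))
  set.seed(3)
  z <- matrix(rnorm(144), 12, 12)
  expect_equal(compute_tri(z, 5)$tri, compute_tri(z + 100, 5)$tri)
  ramp <- matrix(rep(1:20, each = 15) * 3.2, 15, 20)  # step 3.2 m per column
  tri <- compute_tri(ramp, 7)
  expect_equal(tri$tri[8, 10], sqrt(196 / 48) * 3.2, tolerance = 1e-12)
  # full-grid agreement with the explicit-loop oracle, including edges
  expect_equal(compute_tri(z, 7)$tri, oracle_tri(z, 7), tolerance = 1e-12)
  expect_error(compute_tri(z, 4), "odd")
  expect_error(compute_tri(z, 15), "extent")
})

test_that("z-scoring: fixture, moments, affine invariance, guards", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(8)
  x <- rnorm(50)
  z <- zscore(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(zscore(3 * x + 7), z)
  expect_error(zscore(rep(2, 5)), "zero standard deviation")
  expect_error(zscore(1), "at least 2")
})

test_that("risk-set expansion: record counts match the per-pixel oracle", {
  f <- matrix(TRUE, 6, 6)
  d <- matrix(0L, 6, 6)
  d[1, 1] <- 6L    # disturbed in year 6 -> years 4,5,6 = 3 records
  d[2, 2] <- 4L    # first modelled year -> 1 record
  d[3, 3] <- 17L   # last year -> 14 records
  an <- data.frame(year = 1:17, t_anom = rnorm(17), p_anom = rnorm(17))
  tab <- build_pixel_year_table(d, f, matrix(0, 6, 6), an, lag = 0,
                                years = 4:17)
  # oracle: per-pixel min(first, last) - 4 + 1
  first <- d[f]
  expected <- sum(ifelse(first == 0, 14, pmin(first, 17) - 4 + 1))
  expect_equal(nrow(tab), expected)
  expect_equal(sum(tab$disturbed), 3)
  expect_equal(nrow(tab[tab$pixel == which(f)[1], ]), 3)

  # lag joins anomalies at year - lag
  tab2 <- build_pixel_year_table(d, f, matrix(0, 6, 6), an, lag = 2,
                                 years = 4:17)
  expect_equal(tab2$t_anom, an$t_anom[tab2$year - 2])
  expect_error(build_pixel_year_table(d, f, matrix(0, 6, 6),
                                      an[an$year > 3, ], lag = 2, years = 4:17),
               "cover")
})

test_that("case-control sampling: balance, offsets, fraction bookkeeping", {
  set.seed(10)
  tab <- data.frame(landscape_id = rep(1:3, each = 4000),
                    pixel = rep(1:1200, each = 10),
                    year = rep(1:10, 1200),
                    disturbed = rbinom(12000, 1, 0.02),
                    tri = rnorm(12000), t_anom = rnorm(12000),
                    p_anom = rnorm(12000))
  s <- sample_case_control(tab, pixel_fraction = 1, seed = 4)
  meta <- attr(s, "sampling")
  by_ls <- split(s, s$landscape_id)
  for (i in seq_along(by_ls)) {
    npres <- sum(by_ls[[i]]$disturbed)
    expect_lte(abs(sum(1 - by_ls[[i]]$disturbed) - npres), 1)
    f_abs <- meta$f_abs[i]
    expect_equal(unique(by_ls[[i]]$offset), log(1 / f_abs))
  }
  expect_equal(attr(s, "population")$n_records, nrow(tab))

  # pixel_fraction = 1 with an already balanced population: offset ~ 0
  bal <- data.frame(landscape_id = 1, pixel = 1:100, year = 1,
                    disturbed = rep(0:1, 50), tri = 0, t_anom = 0, p_anom = 0)
  sb <- sample_case_control(bal, 1, seed = 1)
  expect_equal(unique(sb$offset), 0)
  expect_error(sample_case_control(tab, 0), "pixel_fraction")

  # intercept-correction magnitude: prevalence 0.01 balanced to 0.5
  # removes log(99) from the sampled log-odds
  expect_equal(log(1 / ((0.01 / 0.99) / (0.5 / 0.5))) - log(99), 0,
               tolerance = 1e-12)
})

test_that("GLMM reduces to plain logistic regression when sigma_b ~ 0", {
  pars <- driver_params(beta0 = -2.5, beta_T = 0.4, beta_P = -0.2,
                        beta_TP = 0.1, beta_TRI = -0.15, sigma_b = 0, lag = 0)
  st <- sim_glmm_study(4, 30, pars, seed = 61, pixel_fraction = 1)
  pop <- st$population
  fit <- fit_glmm(pop, use_offset = FALSE)
  oracle <- glm(disturbed ~ t_anom * p_anom + tri, binomial(), data = pop)
  expect_true(fit$boundary)  # sigma_b estimated at the 0 boundary
  expect_equal(unname(fit$beta[names(coef(oracle))]),
               unname(coef(oracle)), tolerance = 1e-4)
  expect_equal(fit$sigma_b, 0, tolerance = 1e-3)
})

test_that("case-control fit with offsets matches the full-population fit", {
  pars <- driver_params(beta0 = -3.2, beta_T = 0.5, beta_P = -0.25,
                        beta_TP = -0.2, beta_TRI = -0.1, sigma_b = 0.4, lag = 0)
  st <- sim_glmm_study(8, 35, pars, seed = 71, pixel_fraction = 1)
  full <- fit_glmm(st$population, use_offset = FALSE)
  cc <- fit_glmm(st$sampled)
  for (nm in names(full$beta)) {
    se_comb <- sqrt(full$se[nm]^2 + cc$se[nm]^2)
    expect_lt(abs(full$beta[nm] - cc$beta[nm]), 4 * se_comb + 0.05)
  }
})

test_that("corrected intercept recovers population prevalence", {
  pars <- driver_params(beta0 = -4, beta_T = 0.4, beta_P = -0.2,
                        beta_TP = -0.1, beta_TRI = -0.1, sigma_b = 0.4, lag = 0)
  st <- sim_glmm_study(10, 35, pars, seed = 81, pixel_fraction = 0.5)
  fit <- fit_glmm(st$sampled)
  prev_pred <- predicted_prevalence(fit, st$population)
  prev_pop <- mean(st$population$disturbed)
  expect_equal(prev_pred, prev_pop, tolerance = 0.2)
  # generative intercept itself recovered on the population scale
  expect_lt(abs(fit$corrected_intercept - pars$beta0), 4 * fit$se[1] + 0.1)
})

test_that("lag selection recovers a generative 2-year lag", {
  pars <- driver_params(beta0 = -3.8, beta_T = 0.6, beta_P = -0.3,
                        beta_TP = -0.4, beta_TRI = -0.1, sigma_b = 0.3, lag = 2)
  st <- sim_glmm_study(10, 30, pars, seed = 91, pixel_fraction = 1)
  sel <- select_lag(st$sampled, st$anomalies, lags = 0:3)
  expect_equal(sel$best_lag, 2)
  expect_equal(nrow(sel$aic_table), 4)
  expect_false(sel$unstable)
})

test_that("model comparison ranks and LRT dfs are as defined", {
  pars <- driver_params(beta0 = -3.5, beta_T = 0.7, beta_P = -0.3,
                        beta_TP = -0.3, beta_TRI = -0.1, sigma_b = 0.3, lag = 0)
  st <- sim_glmm_study(8, 30, pars, seed = 95, pixel_fraction = 1)
  cmp <- compare_models(st$sampled)
  expect_equal(cmp$table$model[which.min(cmp$table$aic)], "full")
  expect_equal(cmp$lrt$df, c(3, 1))
  expect_lt(cmp$lrt$p_value[1], 0.01)
  # identical model vs itself: LRT statistic 0
  expect_equal(2 * (cmp$fits$full$loglik - cmp$fits$full$loglik), 0)
  # nested likelihoods are ordered
  expect_gte(cmp$fits$full$loglik, cmp$fits$spatial_only$loglik - 1e-6)
  expect_gte(cmp$fits$spatial_only$loglik, cmp$fits$null$loglik - 1e-6)
})

test_that("response curves: collapse without uncertainty, coverage of plug-in", {
  pars <- driver_params(beta0 = -3, beta_T = 0.6, beta_P = -0.2,
                        beta_TP = -0.3, beta_TRI = -0.1, sigma_b = 0.3, lag = 0)
  st <- sim_glmm_study(6, 30, pars, seed = 97, pixel_fraction = 1)
  fit <- fit_glmm(st$sampled)
  rc <- simulate_response_curves(fit, temp_grid = seq(-2, 2, 0.5),
                                 n_sim = 500, seed = 3)
  expect_true(all(rc$lower <= rc$upper))
  expect_gte(mean(rc$plugin >= rc$lower & rc$plugin <= rc$upper), 0.95)

  fit0 <- fit
  fit0$vcov <- fit$vcov * 0
  rc0 <- simulate_response_curves(fit0, temp_grid = c(-1, 0, 1),
                                  precip_levels = 0, n_sim = 200, seed = 2)
  expect_equal(rc0$median, rc0$plugin, tolerance = 1e-6)
  expect_lt(max(rc0$upper - rc0$lower), 1e-6)

  # positive beta_T with negative interaction: steepest rise when dry
  rc2 <- simulate_response_curves(fit, temp_grid = c(-2, 2), n_sim = 200,
                                  seed = 4)
  rise <- function(p) {
    sub <- rc2[rc2$p_anom == p, ]
    sub$plugin[sub$t_anom == 2] - sub$plugin[sub$t_anom == -2]
  }
  expect_gt(rise(-1), rise(1))
})
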