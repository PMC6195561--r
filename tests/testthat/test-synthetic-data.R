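test_that("DEM generator: flat limit, determinism, roughness monotonicity", {
  flat <- generate_dem(12, 12, 0, seed = 1)
  expect_true(all(flat$values == flat$values[1, 1]))
  expect_true(all(compute_tri(flat, 7)$tri == 0))

  a <- generate_dem(20, 20, 0.5, seed = 5)
  b <- generate_dem(20, 20, 0.5, seed = 5)
  expect_identical(a$values, b$values)

  lo <- generate_dem(30, 30, 0.1, seed = 9)
  hi <- generate_dem(30, 30, 1.0, seed = 9)
  expect_gt(mean(oracle_tri(hi$values, 7)), mean(oracle_tri(lo$values, 7)))
  expect_error(generate_dem(5, 20, 1, seed = 1), "7 x 7")
})

test_that("climate series: length, units, constant flag, autocorrelation", {
  cl <- generate_climate_series(14, seed = 3)
  expect_equal(nrow(cl), 14)
  expect_named(cl, c("year", "tmean_c", "prec_mm"))
  expect_error(generate_climate_series(3, seed = 1), "at least 4")

  const <- generate_climate_series(10, seed = 2, t_sd = 0, p_sd = 0)
  expect_true(attr(const, "constant"))
  expect_equal(var(const$tmean_c), 0)

  long <- generate_climate_series(10000, seed = 8, ar = 0)
  r1 <- cor(long$tmean_c[-1], long$tmean_c[-10000])
  expect_lt(abs(r1), 0.02)
  long2 <- generate_climate_series(10000, seed = 8, ar = 0.6)
  r2 <- cor(long2$tmean_c[-1], long2$tmean_c[-10000])
  expect_equal(r2, 0.6, tolerance = 0.05)
})

test_that("pixel_iid disturbance matches the closed-form survival product", {
  pars <- driver_params(beta0 = qlogis(0.01), beta_T = 0, beta_P = 0,
                        beta_TP = 0, beta_TRI = 0, sigma_b = 0, lag = 0)
  f <- matrix(TRUE, 120, 120)
  dem <- generate_dem(120, 120, 0, seed = 1)
  cl <- generate_climate_series(17, seed = 2)
  d <- generate_disturbance_series(f, dem, cl, list(params = pars, b = 0),
                                   "pixel_iid", seed = 77, start_year = 4)
  frac <- mean(d$values != 0)
  p_expect <- 1 - 0.99^14
  mc_se <- sqrt(p_expect * (1 - p_expect) / length(f))
  expect_equal(frac, p_expect, tolerance = 5 * mc_se / p_expect)
  # risk-set rule: single year per pixel, all within modelled years
  expect_true(all(d$values %in% c(0, 4:17)))
})

test_that("extreme negative baseline yields zero disturbance", {
  pars <- driver_params(beta0 = -50, sigma_b = 0, lag = 0)
  f <- matrix(TRUE, 20, 20)
  d <- generate_disturbance_series(f, generate_dem(20, 20, 30, seed = 1),
                                   generate_climate_series(17, seed = 2),
                                   list(params = pars, b = 0),
                                   "pixel_iid", seed = 3)
  expect_true(all(d$values == 0))
})

test_that("generator is deterministic under a fixed seed", {
  pars <- driver_params(beta0 = -3, sigma_b = 0, lag = 1)
  f <- matrix(TRUE, 25, 25)
  dem <- generate_dem(25, 25, 40, seed = 4)
  cl <- generate_climate_series(17, seed = 5)
  arch <- landscape_archetype("moderate")
  for (mode in c("pixel_iid", "patchy")) {
    d1 <- generate_disturbance_series(f, dem, cl,
                                      list(params = pars, b = 0.2, archetype = arch),
                                      mode, seed = 11)
    d2 <- generate_disturbance_series(f, dem, cl,
                                      list(params = pars, b = 0.2, archetype = arch),
                                      mode, seed = 11)
    expect_identical(d1$values, d2$values)
  }
})

test_that("lag exceeding climate history is rejected", {
  pars <- driver_params(beta0 = -3, lag = 3, sigma_b = 0)
  f <- matrix(TRUE, 10, 10)
  expect_error(
    generate_disturbance_series(f, generate_dem(10, 10, 10, seed = 1),
                                generate_climate_series(10, seed = 2),
                                list(params = pars, b = 0), "pixel_iid",
                                seed = 3, start_year = 2),
    "lag")
})

test_that("patchy mode draws patch areas from the configured law", {
  # one big year so patches rarely merge; compare realised areas to the law
  arch <- landscape_archetype("moderate")
  arch$amax_cells <- 40
  pars <- driver_params(beta0 = qlogis(0.004), sigma_b = 0, lag = 0)
  areas <- c()
  for (s in 1:6) {
    f <- matrix(TRUE, 80, 80)
    d <- generate_disturbance_series(f, generate_dem(80, 80, 0, seed = s),
                                     generate_climate_series(17, seed = 100 + s),
                                     list(params = pars, b = 0, archetype = arch),
                                     "patchy", seed = 200 + s)
    ps <- label_patches(d$values != 0)
    areas <- c(areas, ps$area_ha / 0.09)
  }
  expect_gt(length(areas), 40)
  ref <- with_seed(1, function() rtrunc_power(5000, arch$alpha, 1, 40))
  # merged patches inflate the tail; compare medians on the rank scale
  expect_equal(median(areas), median(round(ref)), tolerance = 0.5)
  expect_true(max(areas) <= 3 * arch$amax_cells)  # little merging at this rate
})

test_that("pixel_iid realised log-odds recover the generative coefficients", {
  # the generator's own oracle: plain logistic regression on the full
  # population recovers beta before any GLMM machinery exists
  pars <- driver_params(beta0 = -3.5, beta_T = 0.5, beta_P = -0.3,
                        beta_TP = 0, beta_TRI = -0.2, sigma_b = 0, lag = 0)
  f <- matrix(TRUE, 70, 70)
  dem <- generate_dem(70, 70, 60, seed = 31)
  cl <- generate_climate_series(17, seed = 32)
  d <- generate_disturbance_series(f, dem, cl, list(params = pars, b = 0),
                                   "pixel_iid", seed = 33)
  tri <- compute_tri(dem, 7)
  triz <- matrix(0, 70, 70); triz[f] <- zscore(tri$tri[f])
  an <- data.frame(year = cl$year, t_anom = zscore(cl$tmean_c),
                   p_anom = zscore(cl$prec_mm))
  tab <- build_pixel_year_table(d, f, triz, an, lag = 0, landscape_id = 1)
  g <- glm(disturbed ~ t_anom + p_anom + tri, binomial(), data = tab)
  est <- coef(g)
  se <- sqrt(diag(vcov(g)))
  expect_lt(abs(est[["t_anom"]] - 0.5), 4 * se[["t_anom"]])
  expect_lt(abs(est[["p_anom"]] + 0.3), 4 * se[["p_anom"]])
  expect_lt(abs(est[["tri"]] + 0.2), 4 * se[["tri"]])
})

test_that("context tables: ranked agents, share sums, degenerate distribution", {
  ctx <- generate_context_tables(rep(c("low", "moderate", "high"), each = 5),
                                 seed = 10)
  expect_equal(nrow(ctx$agents), 30)         # two ranked agents per landscape
  expect_true(all(tapply(ctx$agents$rank, ctx$agents$landscape_id,
                         function(r) identical(sort(r), 1:2))))
  sums <- tapply(ctx$species$share, ctx$species$landscape_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))

  deg <- list(low = c(wind = 1, fire = 0))
  ctx2 <- generate_context_tables(rep("low", 6), agent_distributions = deg,
                                  seed = 3)
  expect_true(all(ctx2$agents$agent[ctx2$agents$rank == 1] == "wind"))
  bad <- list(low = c(wind = 0.5, fire = 0.2))
  expect_error(generate_context_tables("low", agent_distributions = bad),
               "sum to 1")
})

test_that("agent draw frequencies match the specified distribution", {
  dist <- list(low = c(wind = 0.5, fire = 0.3, beetle = 0.2))
  ctx <- generate_context_tables(rep("low", 5000),
                                 agent_distributions = dist, seed = 77)
  top1 <- ctx$agents$agent[ctx$agents$rank == 1]
  freq <- table(top1) / length(top1)
  expect_equal(unname(freq[["wind"]]), 0.5, tolerance = 0.04)
  expect_equal(unname(freq[["fire"]]), 0.3, tolerance = 0.06)
})
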