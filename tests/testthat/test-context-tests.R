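test_that("weighted trait means: fixtures and renormalisation rule", {
  expect_equal(weighted_trait_mean(c(a = 1), c(a = 42)), 42)
  expect_equal(weighted_trait_mean(c(a = 0.5, b = 0.5), c(a = 20, b = 40)), 30)
  # missing trait -> renormalise over covered species
  expect_warning(
    wm <- weighted_trait_mean(c(a = 0.6, b = 0.2, c = 0.2),
                              c(a = 10, b = 30)),
    "renormalis")
  expect_equal(wm, (0.6 * 10 + 0.2 * 30) / 0.8)
  expect_error(weighted_trait_mean(c(a = 1), c(b = 5)), "no trait coverage")
  expect_error(weighted_trait_mean(c(a = 0.7), c(a = 5)), "sum to 1")
})

test_that("trait profiles summarise dominance, conifer share and CWMs", {
  sp <- data.frame(landscape_id = c(1, 1, 2, 2),
                   species = c("A", "B", "A", "C"),
                   share = c(0.7, 0.3, 0.5, 0.5))
  tr <- data.frame(species = c("A", "B", "C"),
                   max_height_m = c(30, 50, 20),
                   wood_density_g_cm3 = c(0.5, 0.4, 0.6),
                   is_conifer = c(TRUE, FALSE, FALSE))
  p <- trait_profile(sp, tr)
  expect_equal(p$dominance_pct, c(70, 50))
  expect_equal(p$conifer_pct, c(70, 50))
  expect_equal(p$max_height_m, c(0.7 * 30 + 0.3 * 50, 0.5 * 30 + 0.5 * 20))
})

test_that("Pearson chi-squared matches hand computation and stats::chisq.test", {
  expect_equal(pearson_chi2(matrix(c(10, 0, 0, 10), 2)), 20)
  prop <- matrix(c(2, 4, 3, 6), 2)  # proportional rows -> independence
  expect_equal(pearson_chi2(prop), 0)
  set.seed(12)
  for (rep in 1:20) {
    tab <- matrix(rpois(12, 8) + 1, 4, 3)
    expect_equal(pearson_chi2(tab),
                 unname(suppressWarnings(
                   chisq.test(tab, correct = FALSE)$statistic)))
  }
  expect_error(pearson_chi2(matrix(0, 2, 2)), "empty")
})

test_that("top-2 contingency construction keeps category pairs per landscape", {
  cats <- list(c("wind", "fire"), c("fire", "beetle"), c("wind", "beetle"))
  tab <- top_category_table(cats, c("A", "A", "B"))
  expect_equal(sum(tab), 6)
  expect_equal(tab["fire", "A"], 2L)
  expect_equal(tab["beetle", "B"], 1L)
})

test_that("permutation chi2: degenerate table, p bounds, enumeration oracle", {
  same <- replicate(6, c("wind", "fire"), simplify = FALSE)
  r <- permutation_chi2_test(same, rep(c("A", "B"), 3), n_perm = 99, seed = 1)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  cats <- list(c("w", "f"), c("w", "f"), c("w", "b"),
               c("b", "d"), c("b", "d"), c("f", "d"))
  cl <- c(1, 1, 1, 2, 2, 2)
  r2 <- permutation_chi2_test(cats, cl, n_perm = 9999, seed = 42)
  expect_gte(r2$p_value, 1 / 10000)
  expect_lte(r2$p_value, 1)
  exact <- oracle_chi2_exact_p(cats, cl)
  # MC with add-one estimator vs exhaustive enumeration (20 distinct splits)
  expect_lt(abs(r2$p_value - exact), 4 * sqrt(exact / 9999) + 2e-4)
})

test_that("KW statistic: hand fixture, ties, identical values, oracle", {
  expect_equal(kruskal_wallis_H(1:6, rep(1:2, each = 3)), 3.857, tolerance = 1e-3)
  expect_equal(kruskal_wallis_H(rep(5, 8), rep(1:2, 4)), 0)
  set.seed(33)
  for (rep in 1:20) {
    x <- sample(1:6, 15, replace = TRUE)   # plenty of ties
    g <- sample(1:3, 15, replace = TRUE)
    if (length(unique(g)) < 2) next
    expect_equal(kruskal_wallis_H(x, g),
                 unname(kruskal.test(x, g)$statistic))
  }
})

test_that("permutation KW agrees with exact enumeration on tiny problems", {
  x <- c(1, 2, 3, 10, 11, 12)        # maximally separated, n1 = 3: p = 0.1
  exact <- oracle_kw_exact_p(x, 3)
  expect_equal(exact, 2 / 20)
  r <- permutation_kw_test(x, rep(1:2, each = 3), n_perm = 9999, seed = 5)
  expect_lt(abs(r$p_value - exact), 4 * sqrt(exact * (1 - exact) / 9999) + 2e-4)
  expect_error(permutation_kw_test(x, rep(1, 6)), "2 groups")
})

test_that("Benjamini-Hochberg adjustment across pairwise tests", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), c(0.03, 0.03, 0.03))
  set.seed(9)
  vals <- c(rnorm(8), rnorm(8, 5), rnorm(8, 10))
  lab <- rep(c("a", "b", "c"), each = 8)
  pw <- pairwise_kw_fdr(vals, lab, n_perm = 499, seed = 3)
  expect_equal(nrow(pw), 3)
  expect_equal(pw$p_adj, p.adjust(pw$p_value, "BH"))
  expect_true(all(pw$p_adj >= pw$p_value))
})

test_that("add-one estimator keeps p-values strictly positive", {
  set.seed(2)
  x <- c(rnorm(5), rnorm(5, 50))
  r <- permutation_kw_test(x, rep(1:2, each = 5), n_perm = 199, seed = 1)
  expect_gte(r$p_value, 1 / 200)
})

test_that("permutation KW is calibrated under the null", {
  set.seed(71)
  p <- replicate(300, {
    x <- rnorm(12)
    permutation_kw_test(x, rep(1:3, each = 4), n_perm = 99)$p_value
  })
  rej <- mean(p <= 0.05)
  expect_gte(rej, 0.02)
  expect_lte(rej, 0.09)
})
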