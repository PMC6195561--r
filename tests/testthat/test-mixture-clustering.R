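make_blobs <- function(n_per, means, sd = 1, d = 4, seed = 1) {
  with_seed(seed, function() {
    do.call(rbind, lapply(means, function(m)
      matrix(rnorm(n_per * d, mean = m, sd = sd), n_per, d)))
  })
}

test_that("preprocessing: identity config, z-score moments, rank preservation", {
  set.seed(5)
  df <- data.frame(pland_pct = runif(20, 0.1, 30),
                   edge_density_m_per_ha = runif(20, 1, 50),
                   awmps_ha = runif(20, 0.09, 100),
                   awm_par_m_per_ha = runif(20, 200, 1300))
  ident <- preprocess_metrics(df, log_features = character(0), zscore = FALSE)
  expect_equal(unname(ident[, ]), unname(as.matrix(df)))

  Z <- preprocess_metrics(df)
  expect_true(all(abs(colMeans(Z)) < 1e-12))
  expect_true(all(abs(apply(Z, 2, sd) - 1) < 1e-12))
  for (j in 1:4) {
    expect_equal(cor(Z[, j], as.matrix(df)[, j], method = "spearman"), 1)
  }
  # exact inverse
  back <- inverse_preprocess(Z, attr(Z, "transform"))
  expect_equal(unname(back), unname(as.matrix(df)), tolerance = 1e-10)
})

test_that("rows with missing metrics are dropped with a warning", {
  df <- data.frame(pland_pct = c(1, 2, 3), edge_density_m_per_ha = c(1, 2, 3),
                   awmps_ha = c(0.1, NA, 0.3), awm_par_m_per_ha = c(5, 6, 7))
  expect_warning(X <- preprocess_metrics(df), "dropped")
  expect_equal(nrow(X), 2)
})

test_that("K = 1 EM equals the closed-form Gaussian MLE", {
  set.seed(2)
  X <- matrix(rnorm(200), 50, 4)
  f <- fit_gmm_em(X, 1, "full", n_init = 1, seed = 1)
  expect_equal(as.vector(f$means), colMeans(X), tolerance = 1e-9)
  expect_equal(f$covariances[[1]], cov(X) * 49 / 50, tolerance = 1e-6)
  fd <- fit_gmm_em(X, 1, "diagonal", n_init = 1, seed = 1)
  # equality up to the default covariance ridge (1e-6 of the mean variance)
  expect_equal(unname(fd$covariances[[1]]),
               unname(apply(X, 2, function(x) mean((x - mean(x))^2))),
               tolerance = 1e-5)
})

test_that("log-likelihood is non-decreasing in every EM restart", {
  X <- make_blobs(30, list(0, 4, -4), sd = 1.2, seed = 31)
  for (fam in c("spherical", "diagonal", "full")) {
    f <- fit_gmm_em(X, 3, fam, n_init = 10, seed = 7)
    for (tr in f$loglik_traces) {
      expect_true(all(diff(tr) >= -1e-7 * (1 + abs(tr[-1]))))
    }
  }
})

test_that("well-separated components are recovered with correct assignment", {
  X <- make_blobs(40, list(0, 100), sd = 1, seed = 13)
  f <- fit_gmm_em(X, 2, "diagonal", n_init = 3, seed = 5)
  mu <- f$means[order(f$means[, 1]), ]
  # at separation 100 SD the component means are the block sample means
  expect_equal(unname(mu[1, ]), unname(colMeans(X[1:40, ])), tolerance = 1e-6)
  expect_equal(unname(mu[2, ]), unname(colMeans(X[41:80, ])), tolerance = 1e-6)
  expect_lt(max(abs(mu[1, ] - 0)), 0.1 * 5)   # within sampling error of truth
  expect_lt(max(abs(mu[2, ] - 100)), 0.1 * 5)
  lab <- assign_clusters(f, X)$labels
  expect_equal(length(unique(lab[1:40])), 1)
  expect_equal(length(unique(lab[41:80])), 1)
  expect_true(lab[1] != lab[41])
})

test_that("n_params per family and the BIC convention are as defined", {
  X <- make_blobs(30, list(0, 6), d = 4, seed = 3)
  for (fam in c("spherical", "diagonal", "full")) {
    f <- fit_gmm_em(X, 2, fam, n_init = 2, seed = 9)
    np_expect <- switch(fam, spherical = 2 * 4 + 1 + 1,
                        diagonal = 2 * 4 + 1 + 8,
                        full = 2 * 4 + 1 + 20)
    expect_equal(f$n_params, np_expect)
    expect_equal(f$bic, 2 * f$loglik - np_expect * log(nrow(X)))
  }
})

test_that("fit agrees with the reference mixture implementation", {
  skip_if_not_installed("mclust")
  suppressMessages(withr::local_package("mclust"))  # Mclust needs attachment
  X <- make_blobs(50, list(-3, 3), d = 2, sd = 1, seed = 17)
  f <- fit_gmm_em(X, 2, "diagonal", n_init = 5, seed = 2)
  mc <- mclust::Mclust(X, G = 2, modelNames = "VVI", verbose = FALSE)
  expect_equal(f$loglik, mc$loglik, tolerance = 1e-4)
  ours <- f$means[order(f$means[, 1]), ]
  theirs <- t(mc$parameters$mean)[order(t(mc$parameters$mean)[, 1]), ]
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-3)
})

test_that("model selection finds one blob and three blobs", {
  X1 <- make_blobs(60, list(0), sd = 1, seed = 23)
  s1 <- select_model(X1, K_range = 1:4, families = "diagonal", seed = 4)
  expect_equal(s1$K, 1)
  X3 <- make_blobs(30, list(0, 10, -10), sd = 1, seed = 29)
  s3 <- select_model(X3, K_range = 1:5, families = "diagonal", seed = 4)
  expect_equal(s3$K, 3)
  expect_true(all(c("K", "family", "bic") %in% names(s3$bic_table)))
})

test_that("responsibilities are normalised, peaked at means, split at midpoint", {
  f <- fit_gmm_em(make_blobs(40, list(0, 20), d = 2, seed = 37), 2,
                  "spherical", n_init = 2, seed = 1)
  r <- assign_clusters(f, f$means)$responsibilities
  expect_true(all(abs(rowSums(r) - 1) < 1e-12))
  expect_true(all(apply(r, 1, max) > 0.999))
  mid <- matrix(colMeans(f$means), 1)
  rm <- assign_clusters(f, mid)$responsibilities
  expect_equal(as.vector(rm), c(0.5, 0.5), tolerance = 0.05)
})

test_that("label partition is invariant to row permutation", {
  X <- make_blobs(25, list(0, 7, 14), d = 3, seed = 41)
  f1 <- fit_gmm_em(X, 3, "diagonal", n_init = 5, seed = 6)
  perm <- with_seed(8, function() sample(nrow(X)))
  f2 <- fit_gmm_em(X[perm, ], 3, "diagonal", n_init = 5, seed = 6)
  l1 <- assign_clusters(f1, X)$labels
  l2 <- assign_clusters(f2, X)$labels
  cross <- table(l1, l2)
  expect_true(all(rowSums(cross > 0) == 1) && all(colSums(cross > 0) == 1))
})

test_that("parametric bootstrap: B = 0 means-only, CI width shrinks with n", {
  X <- make_blobs(40, list(0, 8), d = 2, seed = 43)
  f <- fit_gmm_em(X, 2, "diagonal", n_init = 2, seed = 3)
  s0 <- parametric_bootstrap_summary(f, X, B = 0, seed = 1)
  expect_true(all(is.na(s0$summary$lower)))
  expect_equal(nrow(s0$summary), 2 * 2)

  widths <- sapply(c(30, 120, 480), function(n) {
    Xn <- make_blobs(n / 2, list(0, 8), d = 2, seed = 47)
    fn <- fit_gmm_em(Xn, 2, "diagonal", n_init = 2, seed = 3)
    sn <- parametric_bootstrap_summary(fn, Xn, B = 60, seed = 5)
    mean(sn$summary$upper - sn$summary$lower)
  })
  # ~1/sqrt(n): quadrupling n should roughly halve the width
  slope <- coef(lm(log(widths) ~ log(c(30, 120, 480))))[2]
  expect_lt(slope, -0.3)
  expect_gt(slope, -0.8)
})

test_that("bootstrap component matching is a bijection on permuted means", {
  A <- matrix(c(0, 0, 5, 5, 10, 0), 3, 2, byrow = TRUE)
  B <- A[c(3, 1, 2), ] + 0.1
  p <- disturbscape:::match_components(A, B)
  expect_equal(p, c(2L, 3L, 1L))
})
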