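#' Preprocess landscape metrics into a clustering feature matrix
#'
#' The four pattern metrics span several orders of magnitude (patch sizes
#' from < 1 ha to thousands of ha), so by default the three strictly positive,
#' wide-ranging metrics (pland, edge density, AWMPS) are natural-log
#' transformed — with a per-column offset of half the smallest nonzero value
#' where zeros occur — and all features are then z-scored. Every choice is
#' recorded in the returned attributes so runs are self-describing, and an
#' exact inverse transform is available via [inverse_preprocess()].
#'
#' @param metrics data.frame with columns `pland_pct`,
#'   `edge_density_m_per_ha`, `awmps_ha`, `awm_par_m_per_ha` (extra columns
#'   ignored). Rows with missing metric values are dropped with a warning.
#' @param log_features columns to log-transform (default the three listed
#'   above; set `character(0)` together with `zscore = FALSE` for identity).
#' @param zscore whether to z-score columns after transformation.
#' @return numeric matrix (rows = complete landscapes) with attribute
#'   `transform` (list: `features`, `log_features`, `eps`, `center`, `scale`,
#'   `kept_rows`).
#' @export
preprocess_metrics <- function(metrics,
                               log_features = c("pland_pct",
                                                "edge_density_m_per_ha",
                                                "awmps_ha"),
                               zscore = TRUE) {
  features <- c("pland_pct", "edge_density_m_per_ha", "awmps_ha",
                "awm_par_m_per_ha")
  features <- features[features %in% names(metrics)]
  X <- as.matrix(metrics[, features, drop = FALSE])
  keep <- stats::complete.cases(X)
  if (!all(keep)) {
    warning(sum(!keep), " row(s) with missing metrics dropped before clustering")
    X <- X[keep, , drop = FALSE]
  }
  eps <- stats::setNames(numeric(length(features)), features)
  for (j in log_features) {
    if (!j %in% features) next
    x <- X[, j]
    if (any(x <= 0)) eps[j] <- min(x[x > 0]) / 2
    X[, j] <- log(x + eps[j])
  }
  center <- rep(0, ncol(X)); scale <- rep(1, ncol(X))
  if (zscore) {
    center <- colMeans(X)
    scale <- apply(X, 2, stats::sd)
    if (any(scale == 0)) stop("constant feature column: cannot z-score")
    X <- sweep(sweep(X, 2, center), 2, scale, "/")
  }
  attr(X, "transform") <- list(features = features,
                               log_features = intersect(log_features, features),
                               eps = eps, center = center, scale = scale,
                               kept_rows = which(keep))
  X
}

#' Invert the metric preprocessing transform
#'
#' @param Z matrix (or vector) on the feature scale.
#' @param transform the `transform` attribute of a [preprocess_metrics()]
#'   result.
#' @return matrix on the raw metric scale.
#' @export
inverse_preprocess <- function(Z, transform) {
  Z <- rbind(Z)  # vectors become one-row matrices
  X <- sweep(sweep(Z, 2, transform$scale, "*"), 2, transform$center, "+")
  for (j in transform$log_features) {
    jj <- match(j, transform$features)
    X[, jj] <- exp(X[, jj]) - transform$eps[j]
  }
  colnames(X) <- transform$features
  X
}

## per-component log density matrix (n x K); column-wise arithmetic keeps
## the EM hot path free of sweep/apply allocation overhead
gmm_logdens <- function(X, means, covs, family) {
  n <- nrow(X); d <- ncol(X); K <- nrow(means)
  L <- matrix(0, n, K)
  for (k in seq_len(K)) {
    if (family == "spherical") {
      s2 <- covs[[k]]
      q <- 0
      for (j in seq_len(d)) q <- q + (X[, j] - means[k, j])^2
      L[, k] <- -0.5 * (d * log(2 * pi * s2) + q / s2)
    } else if (family == "diagonal") {
      v <- covs[[k]]
      q <- 0
      for (j in seq_len(d)) q <- q + (X[, j] - means[k, j])^2 / v[j]
      L[, k] <- -0.5 * (d * log(2 * pi) + sum(log(v)) + q)
    } else {
      xc <- X - rep(means[k, ], each = n)
      ch <- chol(covs[[k]])
      z <- backsolve(ch, t(xc), transpose = TRUE)
      L[, k] <- -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(ch))) +
                          colSums(z^2))
    }
  }
  L
}

## deterministic Ward-linkage initial partition (first restart): robust for
## elongated, collinear clusters where random seeding rarely finds the basin
gmm_init_hclust <- function(X, K) {
  n <- nrow(X)
  hard <- stats::cutree(stats::hclust(stats::dist(X), method = "ward.D2"), K)
  R <- matrix(0, n, K)
  R[cbind(seq_len(n), hard)] <- 1
  (R + 1 / n) / rowSums(R + 1 / n)
}

## k-means++ style seeding: spread centers, then hard-assign
gmm_init_resp <- function(X, K) {
  n <- nrow(X)
  centers <- matrix(NA_real_, K, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2_to <- function(m) {
    q <- 0
    for (j in seq_along(m)) q <- q + (X[, j] - m[j])^2
    q
  }
  if (K > 1) {
    d2min <- d2_to(centers[1, ])
    for (k in 2:K) {
      if (sum(d2min) == 0) {
        centers[k, ] <- X[sample.int(n, 1), ]
      } else {
        centers[k, ] <- X[sample.int(n, 1, prob = d2min), ]
      }
      d2min <- pmin(d2min, d2_to(centers[k, ]))
    }
  }
  dmat <- matrix(0, n, K)
  for (k in seq_len(K)) dmat[, k] <- d2_to(centers[k, ])
  hard <- max.col(-dmat, ties.method = "first")
  R <- matrix(0, n, K)
  R[cbind(seq_len(n), hard)] <- 1
  ## soften so every component has mass
  (R + 1 / n) / rowSums(R + 1 / n)
}

gmm_mstep <- function(X, R, family, ridge) {
  n <- nrow(X); d <- ncol(X); K <- ncol(R)
  Nk <- colSums(R)
  if (any(Nk < 2)) stop("component collapsed (insufficient responsibility mass)")
  weights <- Nk / n
  means <- crossprod(R, X) / Nk
  covs <- vector("list", K)
  ## ridge delta*I is added to every covariance: it regularises the thin
  ## directions that arise from near-deterministic relationships among
  ## features, and being common to all components it largely cancels in
  ## model comparisons
  if (family == "spherical") {
    tot <- 0
    for (k in seq_len(K)) {
      for (j in seq_len(d)) tot <- tot + sum(R[, k] * (X[, j] - means[k, j])^2)
    }
    s2 <- tot / (n * d) + ridge
    for (k in seq_len(K)) covs[[k]] <- s2
  } else if (family == "diagonal") {
    for (k in seq_len(K)) {
      v <- numeric(d)
      for (j in seq_len(d)) v[j] <- sum(R[, k] * (X[, j] - means[k, j])^2)
      covs[[k]] <- v / Nk[k] + ridge
    }
  } else if (family == "full_equal") {
    S <- matrix(0, d, d)
    for (k in seq_len(K)) {
      xc <- X - rep(means[k, ], each = n)
      S <- S + crossprod(xc * R[, k], xc)
    }
    S <- S / n + diag(ridge, d)
    for (k in seq_len(K)) covs[[k]] <- S
  } else {
    for (k in seq_len(K)) {
      xc <- X - rep(means[k, ], each = n)
      covs[[k]] <- crossprod(xc * R[, k], xc) / Nk[k] + diag(ridge, d)
    }
  }
  list(weights = weights, means = means, covs = covs)
}

gmm_n_params <- function(K, d, family) {
  K * d + (K - 1) + switch(family,
                           spherical = 1,
                           diagonal = K * d,
                           full_equal = d * (d + 1) / 2,
                           full = K * d * (d + 1) / 2)
}

#' Fit a Gaussian finite mixture by EM
#'
#' Expectation-maximisation for a K-component Gaussian mixture under one of
#' four covariance families: `"spherical"` (one shared variance scalar),
#' `"diagonal"` (per-component diagonal), `"full_equal"` (one unrestricted
#' covariance shared by all components — the equal-shape model that keeps
#' elongated, parallel clusters from being split by per-component shape
#' freedom) or `"full"` (per-component unrestricted). The first restart is
#' initialised from a deterministic Ward-linkage hierarchical partition (the
#' standard model-based initialisation, robust for elongated clusters);
#' further restarts use k-means++-style seeding. The best restart (by
#' converged log-likelihood) is returned.
#' Every fitted covariance receives a ridge `delta * I` (default
#' `delta = 1e-6 * mean(diag(cov(X)))`), which keeps near-singular thin
#' directions well conditioned; restarts whose components lose nearly all
#' responsibility mass are discarded and re-drawn.
#'
#' @param X numeric matrix (n x d).
#' @param K number of components (< n).
#' @param family covariance family.
#' @param n_init number of random restarts.
#' @param tol EM stops when the log-likelihood improves by less than `tol`.
#' @param max_iter iteration cap per restart.
#' @param seed integer seed (NULL = use current RNG stream).
#' @param ridge covariance ridge delta; NULL for the default.
#' @return object of class `ds_gmm`: `K`, `family`, `weights`, `means`
#'   (K x d), `covariances` (list), `loglik`, `n_params`, `bic`
#'   (= 2 loglik - n_params log n; larger is better), `n_iter`, `converged`,
#'   `loglik_traces` (per-restart iteration traces), `best_restart`, `n`, `d`.
#' @export
fit_gmm_em <- function(X, K, family = c("diagonal", "spherical",
                                        "full_equal", "full"),
                       n_init = 5, tol = 1e-8, max_iter = 500, seed = NULL,
                       ridge = NULL) {
  family <- family[1]
  if (!family %in% c("diagonal", "spherical", "full_equal", "full")) {
    stop("unknown covariance family: ", family)
  }
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (n <= K) stop("need more observations than components")
  if (is.null(ridge)) {
    ridge <- 1e-6 * mean(apply(X, 2, stats::var))
    if (!is.finite(ridge) || ridge <= 0) ridge <- 1e-12
  }
  ridge_used <- ridge
  with_seed(seed, function() {
    best <- NULL; traces <- list()
    attempts <- 0
    while (length(traces) < n_init && attempts < 4 * n_init) {
      attempts <- attempts + 1
      res <- tryCatch({
        ## first attempt: deterministic hierarchical initialisation;
        ## subsequent restarts: random k-means++ seeding
        R <- if (attempts == 1) gmm_init_hclust(X, K) else gmm_init_resp(X, K)
        par <- gmm_mstep(X, R, family, ridge)
        ll_prev <- -Inf; trace <- numeric(0); converged <- FALSE
        for (it in seq_len(max_iter)) {
          L <- gmm_logdens(X, par$means, par$covs, family)
          A <- sweep(L, 2, log(par$weights), "+")
          amax <- A[, 1]
          if (K > 1) for (k in 2:K) amax <- pmax(amax, A[, k])
          lse <- amax + log(rowSums(exp(A - amax)))
          ll <- sum(lse)
          trace <- c(trace, ll)
          R <- exp(A - lse)
          if (ll - ll_prev < tol && it > 1) { converged <- TRUE; break }
          ll_prev <- ll
          par <- gmm_mstep(X, R, family, ridge)
        }
        if (min(colSums(R)) < 2) stop("component supported by fewer than 2 points")
        if (!is.finite(ll)) stop("non-finite log-likelihood")
        list(par = par, loglik = ll, trace = trace, n_iter = it,
             converged = converged)
      }, error = function(e) NULL)
      if (is.null(res)) next
      traces[[length(traces) + 1]] <- res$trace
      if (is.null(best) || res$loglik > best$loglik) {
        best <- res
        best$restart <- length(traces)
      }
    }
    if (is.null(best)) stop("all EM restarts failed (component collapse)")
    np <- gmm_n_params(K, d, family)
    structure(list(K = K, family = family,
                   weights = best$par$weights,
                   means = best$par$means,
                   covariances = best$par$covs,
                   loglik = best$loglik,
                   n_params = np,
                   bic = 2 * best$loglik - np * log(n),
                   n_iter = best$n_iter,
                   converged = best$converged,
                   loglik_traces = traces,
                   best_restart = best$restart,
                   ridge = ridge_used,
                   n = n, d = d),
              class = "ds_gmm")
  })
}

#' @method print ds_gmm
#' @export
print.ds_gmm <- function(x, ...) {
  cat(sprintf("<ds_gmm: K=%d, family=%s, loglik=%.3f, BIC=%.3f>\n",
              x$K, x$family, x$loglik, x$bic))
  invisible(x)
}

#' Select a mixture model by BIC
#'
#' Fits every (K, family) combination and returns the fit maximising
#' BIC = 2 loglik - n_params log n (larger-is-better convention), together
#' with the full BIC table.
#'
#' @param X feature matrix.
#' @param K_range candidate component counts (default 1..9).
#' @param families candidate covariance families.
#' @param n_init,tol,max_iter,ridge passed to [fit_gmm_em()].
#' @param seed integer seed.
#' @return the winning `ds_gmm`, with an extra element `bic_table`
#'   (data.frame: K, family, loglik, n_params, bic).
#' @export
select_model <- function(X, K_range = 1:9,
                         families = c("spherical", "diagonal",
                                      "full_equal", "full"),
                         n_init = 20, tol = 1e-8, max_iter = 500,
                         seed = NULL, ridge = NULL) {
  X <- as.matrix(X)
  rows <- list(); fits <- list()
  for (fam in families) {
    for (K in K_range) {
      if (K >= nrow(X)) next
      ## need enough observations to place K means in d dimensions
      if (nrow(X) <= K * (ncol(X) + 1)) next
      f <- tryCatch(
        fit_gmm_em(X, K, fam, n_init = n_init, tol = tol,
                   max_iter = max_iter, ridge = ridge,
                   seed = if (is.null(seed)) NULL else
                     stage_seed(seed, K * 31 + match(fam, families))),
        error = function(e) NULL)
      rows[[length(rows) + 1]] <- data.frame(
        K = K, family = fam,
        loglik = if (is.null(f)) NA_real_ else f$loglik,
        n_params = gmm_n_params(K, ncol(X), fam),
        bic = if (is.null(f)) NA_real_ else f$bic)
      fits[length(fits) + 1] <- list(f)  # keeps NULL placeholders aligned
    }
  }
  tab <- do.call(rbind, rows)
  if (all(is.na(tab$bic))) stop("no mixture model could be fitted")
  best <- fits[[which.max(tab$bic)]]
  best$bic_table <- tab
  best
}

#' Assign observations to mixture components
#'
#' Maximum-a-posteriori labels with posterior responsibilities; posterior
#' ties are broken toward the lowest component index.
#'
#' @param model a `ds_gmm`.
#' @param X feature matrix on the model's scale.
#' @return list: `labels` (integer), `responsibilities` (n x K, rows sum
#'   to 1).
#' @export
assign_clusters <- function(model, X) {
  X <- rbind(as.matrix(X))
  L <- gmm_logdens(X, model$means, model$covariances, model$family)
  A <- sweep(L, 2, log(model$weights), "+")
  amax <- A[, 1]
  if (ncol(A) > 1) for (k in 2:ncol(A)) amax <- pmax(amax, A[, k])
  R <- exp(A - amax)
  R <- R / rowSums(R)
  list(labels = max.col(R, ties.method = "first"), responsibilities = R)
}

## sample n points from a fitted mixture
rmixture <- function(n, model) {
  z <- sample.int(model$K, n, replace = TRUE, prob = model$weights)
  d <- model$d
  X <- matrix(0, n, d)
  for (k in seq_len(model$K)) {
    idx <- which(z == k)
    if (!length(idx)) next
    S <- if (is.matrix(model$covariances[[k]])) model$covariances[[k]]
         else diag(model$covariances[[k]], d)
    ch <- chol(S)
    X[idx, ] <- matrix(stats::rnorm(length(idx) * d), ncol = d) %*% ch
    X[idx, ] <- sweep(X[idx, , drop = FALSE], 2, model$means[k, ], "+")
  }
  X
}

## minimum-cost bijective matching of rows of A to rows of B (K x d means);
## exhaustive for K <= 7, greedy with collision repair otherwise
match_components <- function(A, B) {
  K <- nrow(A)
  D <- as.matrix(stats::dist(rbind(A, B)))[seq_len(K), K + seq_len(K)]
  if (K <= 7) {
    perms <- permutations_of(K)
    costs <- vapply(perms, function(p) sum(D[cbind(seq_len(K), p)]), 0)
    perms[[which.min(costs)]]
  } else {
    p <- integer(K); used <- logical(K)
    for (k in order(apply(D, 1, min))) {
      j <- order(D[k, ])
      j <- j[!used[j]][1]
      p[k] <- j; used[j] <- TRUE
    }
    p
  }
}

permutations_of <- function(K) {
  if (K == 1) return(list(1L))
  sub <- permutations_of(K - 1)
  out <- list()
  for (p in sub) {
    for (pos in 0:(K - 1)) {
      out[[length(out) + 1]] <- append(p, K, after = pos)
    }
  }
  out
}

#' Parametric-bootstrap cluster summary
#'
#' Draws `B` synthetic datasets of size n from the fitted mixture, refits the
#' same (K, family) model on each, matches refitted components to the
#' original ones by minimum-cost assignment on the mean-distance matrix, and
#' summarises component means with percentile confidence intervals. Failed
#' refits are dropped and counted.
#'
#' @param model a `ds_gmm` fitted to `X`.
#' @param X the original feature matrix (for labels and n).
#' @param B bootstrap replicates (`B = 0` returns means without intervals).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @param n_init restarts per refit.
#' @return list of class `ds_cluster_summary`: `summary` (data.frame:
#'   cluster, feature, mean, lower, upper), `labels`, `B_used`, `B_failed`,
#'   `boot_means` (B x K x d array, matched).
#' @export
parametric_bootstrap_summary <- function(model, X, B = 9999, level = 0.95,
                                         seed = NULL, n_init = 2) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X); K <- model$K
  labels <- assign_clusters(model, X)$labels
  alpha <- (1 - level) / 2
  boot <- with_seed(seed, function() {
    out <- array(NA_real_, c(B, K, d))
    failed <- 0
    for (b in seq_len(B)) {
      Xb <- rmixture(n, model)
      fb <- tryCatch(
        fit_gmm_em(Xb, K, model$family, n_init = n_init, tol = 1e-6,
                   max_iter = 200, ridge = model$ridge),
        error = function(e) NULL)
      if (is.null(fb)) { failed <- failed + 1; next }
      p <- match_components(model$means, fb$means)
      out[b, , ] <- fb$means[p, , drop = FALSE]
    }
    list(means = out, failed = failed)
  })
  feat <- colnames(X) %||% paste0("f", seq_len(d))
  rows <- list()
  for (k in seq_len(K)) {
    for (j in seq_len(d)) {
      bs <- if (B > 0) boot$means[, k, j] else numeric(0)
      bs <- bs[!is.na(bs)]
      rows[[length(rows) + 1]] <- data.frame(
        cluster = k, feature = feat[j], mean = model$means[k, j],
        lower = if (length(bs)) stats::quantile(bs, alpha, names = FALSE) else NA_real_,
        upper = if (length(bs)) stats::quantile(bs, 1 - alpha, names = FALSE) else NA_real_)
    }
  }
  structure(list(summary = do.call(rbind, rows), labels = labels,
                 B_used = B - boot$failed, B_failed = boot$failed,
                 boot_means = boot$means),
            class = "ds_cluster_summary")
}
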