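#' Topographic ruggedness index
#'
#' Root-mean-square elevation difference between a focal cell and all other
#' cells in an odd moving window (default 7 x 7, ~100 m radius at 30 m
#' resolution):
#' \deqn{TRI = \sqrt{ \mathrm{mean}_{c \ne focal} (z_c - z_{focal})^2 }}
#' Windows are truncated at grid edges (the mean runs over available cells),
#' which keeps edge cells on the same scale as interior cells. The classical
#' 3 x 3 index sums squared differences instead; `method = "sum"` provides
#' that variant (per-landscape z-scoring downstream absorbs the constant
#' factor between the two on interior cells).
#'
#' @param dem elevation grid (matrix or [ds_grid()]).
#' @param window odd window size >= 3.
#' @param method `"rms"` (default) or `"sum"`.
#' @return list of class `ds_tri`: `tri` (matrix, raw index), `window`.
#' @export
compute_tri <- function(dem, window = 7, method = c("rms", "sum")) {
  method <- match.arg(method)
  z <- grid_values(dem)
  if (window %% 2 != 1 || window < 3) stop("`window` must be odd and >= 3")
  nr <- nrow(z); nc <- ncol(z)
  if (window > nr || window > nc) stop("window exceeds grid extent")
  r <- (window - 1) %/% 2
  ssq <- matrix(0, nr, nc)
  cnt <- matrix(0, nr, nc)
  for (dr in -r:r) {
    rs <- 1:nr + dr
    ok_r <- rs >= 1 & rs <= nr
    for (dc in -r:r) {
      if (dr == 0 && dc == 0) next
      cs <- 1:nc + dc
      ok_c <- cs >= 1 & cs <= nc
      diff2 <- (z[rs[ok_r], cs[ok_c], drop = FALSE] -
                  z[ok_r, ok_c, drop = FALSE])^2
      ssq[ok_r, ok_c] <- ssq[ok_r, ok_c] + diff2
      cnt[ok_r, ok_c] <- cnt[ok_r, ok_c] + 1
    }
  }
  tri <- if (method == "rms") sqrt(ssq / cnt) else ssq
  structure(list(tri = tri, window = window, method = method),
            class = "ds_tri")
}

#' Z-score a vector (per-landscape scaling)
#'
#' `(x - mean(x)) / sd(x)` with the sample (n-1) standard deviation; used to
#' scale climate series and TRI values to zero mean and unit SD within each
#' landscape, so that coefficients are comparable across landscapes.
#'
#' @param x numeric vector with at least 2 distinct values.
#' @return z-scored vector.
#' @export
zscore <- function(x) {
  if (length(x) < 2) stop("need at least 2 values to z-score")
  s <- stats::sd(x)
  if (s == 0) stop("zero standard deviation: z-scores undefined")
  (x - mean(x)) / s
}

#' Build the pixel-year risk-set table for one landscape
#'
#' One record per forest pixel per year while the pixel is at risk: a pixel
#' contributes records from the first modelled year up to and including its
#' first disturbance year, then leaves the risk set (single-loss-year
#' convention). Climate anomalies are joined at `year - lag`.
#'
#' @param disturbance first-disturbance-year grid (calendar indices;
#'   0 = never), e.g. from [generate_disturbance_series()].
#' @param forest logical forest mask.
#' @param tri_z matrix of per-landscape z-scored TRI values (forest cells).
#' @param anomalies data.frame `year`, `t_anom`, `p_anom` covering
#'   `min(years) - lag` onwards.
#' @param lag climate lag in years (0-3).
#' @param years calendar years modelled; default the `years` attribute of
#'   `disturbance`.
#' @param landscape_id identifier stored in the table.
#' @return data.frame: `landscape_id`, `pixel`, `year`, `disturbed`, `tri`,
#'   `t_anom`, `p_anom`.
#' @export
build_pixel_year_table <- function(disturbance, forest, tri_z, anomalies,
                                   lag = 0, years = NULL, landscape_id = 1L) {
  d <- grid_values(disturbance)
  f <- grid_values(forest) != 0 & !is.na(grid_values(forest))
  years <- years %||% attr(disturbance, "years")
  if (is.null(years)) stop("`years` not given and not recorded on `disturbance`")
  need <- range(years) - lag
  if (!all((years - lag) %in% anomalies$year)) {
    stop("anomalies do not cover lagged years ", need[1], "..", need[2])
  }
  fidx <- which(f)
  first <- d[fidx]
  y0 <- min(years); y1 <- max(years)
  ## years at risk per pixel: y0..min(first, y1), or all years if never
  last <- ifelse(first == 0L, y1, pmin(first, y1))
  nrec <- last - y0 + 1L
  keep <- nrec > 0L
  fidx <- fidx[keep]; first <- first[keep]; last <- last[keep]
  nrec <- nrec[keep]
  pixel <- rep(fidx, nrec)
  year <- as.integer(sequence(nrec) + y0 - 1L)
  disturbed <- as.integer(rep(first, nrec) == year)
  ai <- match(year - lag, anomalies$year)
  data.frame(landscape_id = landscape_id,
             pixel = pixel,
             year = year,
             disturbed = disturbed,
             tri = tri_z[pixel],
             t_anom = anomalies$t_anom[ai],
             p_anom = anomalies$p_anom[ai])
}

#' Case-control sampling of a pixel-year table
#'
#' Two-stage sampling per landscape, following the rare-events design:
#' (1) a simple random sample of `pixel_fraction` of the pixels (keeping all
#' records of a sampled pixel); (2) within each landscape, all presence
#' records (disturbed = 1) are kept and absences are down-sampled to the
#' presence count. The per-landscape absence sampling fraction is recorded
#' and attached as an offset `log(f_pres / f_abs)` so that model estimates —
#' including the intercept — are on the population scale when the offset is
#' included in the linear predictor. Landscapes without any presence keep a
#' small absence sample (size = the median kept-absence count of the other
#' landscapes, or 50) with a warning.
#'
#' @param table a pixel-year data.frame from [build_pixel_year_table()]
#'   (possibly several landscapes stacked).
#' @param pixel_fraction fraction of pixels sampled per landscape, in (0, 1].
#' @param seed integer seed.
#' @return the sampled table with an `offset` column, plus attribute
#'   `sampling` (per-landscape data.frame: counts, fractions) and
#'   `population` (overall presence/record counts of the input).
#' @export
sample_case_control <- function(table, pixel_fraction = 0.10, seed = NULL) {
  if (pixel_fraction <= 0 || pixel_fraction > 1) {
    stop("`pixel_fraction` must be in (0, 1]")
  }
  pop_pres <- sum(table$disturbed)
  pop_n <- nrow(table)
  with_seed(seed, function() {
    parts <- split(table, table$landscape_id)
    kept <- vector("list", length(parts))
    meta <- vector("list", length(parts))
    no_pres <- character(0)
    for (i in seq_along(parts)) {
      sub <- parts[[i]]
      px <- unique(sub$pixel)
      n_take <- max(1L, round(pixel_fraction * length(px)))
      px_s <- if (pixel_fraction >= 1) px else sample(px, n_take)
      sub <- sub[sub$pixel %in% px_s, ]
      pres <- sub[sub$disturbed == 1L, ]
      abs_ <- sub[sub$disturbed == 0L, ]
      n_pres <- nrow(pres); n_abs <- nrow(abs_)
      n_keep <- min(n_abs, n_pres)
      if (n_pres == 0) {
        no_pres <- c(no_pres, names(parts)[i])
        n_keep <- NA_integer_  # resolved below
      }
      meta[[i]] <- data.frame(landscape_id = sub$landscape_id[1],
                              n_pixels_pop = length(px),
                              n_pixels_sampled = length(px_s),
                              n_pres = n_pres, n_abs_pop = n_abs,
                              n_abs_kept = n_keep)
      kept[[i]] <- list(pres = pres, abs_ = abs_)
    }
    meta <- do.call(rbind, meta)
    if (length(no_pres)) {
      warning("landscape(s) without presences retained with a default absence sample: ",
              paste(no_pres, collapse = ", "))
      fallback <- stats::median(meta$n_abs_kept, na.rm = TRUE)
      if (!is.finite(fallback) || fallback < 1) fallback <- 50
      meta$n_abs_kept[is.na(meta$n_abs_kept)] <-
        pmin(meta$n_abs_pop[is.na(meta$n_abs_kept)], round(fallback))
    }
    out <- vector("list", length(kept))
    for (i in seq_along(kept)) {
      pres <- kept[[i]]$pres; abs_ <- kept[[i]]$abs_
      n_keep <- meta$n_abs_kept[i]
      abs_k <- if (n_keep >= nrow(abs_)) abs_ else abs_[sample.int(nrow(abs_), n_keep), ]
      f_abs <- if (nrow(abs_) > 0) nrow(abs_k) / nrow(abs_) else 1
      chunk <- rbind(pres, abs_k)
      chunk$offset <- log(1 / f_abs)  # f_pres = 1 within sampled pixels
      out[[i]] <- chunk
    }
    meta$f_pres <- 1
    meta$f_abs <- ifelse(meta$n_abs_pop > 0, meta$n_abs_kept / meta$n_abs_pop, 1)
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    attr(res, "sampling") <- meta
    attr(res, "population") <- list(n_pres = pop_pres, n_records = pop_n,
                                    prevalence = pop_pres / pop_n)
    res
  })
}

#' Fit the binomial random-intercept driver model
#'
#' Logistic mixed model of annual pixel-level disturbance probability:
#' `disturbed ~ t_anom * p_anom + tri + (1 | landscape_id)` with a binomial
#' error distribution and logit link, fitted by Laplace-approximated maximum
#' likelihood (lme4). Case-control sampling offsets, when present, enter the
#' linear predictor so fixed effects — including the intercept — are
#' population-scale. The classical single-shift corrected intercept
#' (sample-prevalence vs population-prevalence log-odds) is reported
#' alongside for reference.
#'
#' @param table sampled pixel-year table (needs columns `disturbed`,
#'   `t_anom`, `p_anom`, `tri`, `landscape_id`; optional `offset`).
#' @param formula model formula; default the full driver model. The
#'   spatial-only and null models used in [compare_models()] replace the
#'   fixed part with `tri` only, or an intercept only.
#' @param use_offset include the case-control offset column (default TRUE
#'   when present).
#' @param nAGQ integration points for lme4 (1 = Laplace).
#' @return object of class `ds_glmm`: `beta`, `se`, `vcov`, `sigma_b`,
#'   `ranef` (per-landscape predicted intercepts), `loglik`, `aic`,
#'   `n_params`, `corrected_intercept`, `boundary` (TRUE when sigma_b hit 0),
#'   `fit` (the underlying merMod), `n`.
#' @export
fit_glmm <- function(table,
                     formula = disturbed ~ t_anom * p_anom + tri +
                       (1 | landscape_id),
                     use_offset = "offset" %in% names(table),
                     nAGQ = 1) {
  if (length(unique(table$landscape_id)) < 2) {
    stop("need at least 2 landscapes for a random-intercept model")
  }
  off <- if (use_offset && "offset" %in% names(table)) table$offset else NULL
  ## large sampling offsets (rare-event down-sampling can give |offset| ~ 10)
  ## destabilise the PIRLS start; fit with the offset centred and shift the
  ## intercept back to the population scale afterwards
  off_center <- 0
  if (!is.null(off)) {
    off_center <- mean(off)
    off <- off - off_center
  }
  ## glmer resolves `offset` in the formula environment; make `off` visible
  ## regardless of where the formula was created
  environment(formula) <- environment()
  fit <- suppressMessages(lme4::glmer(
    formula, data = table, family = stats::binomial(),
    offset = off, nAGQ = nAGQ,
    control = lme4::glmerControl(check.conv.singular = "ignore",
                                 calc.derivs = TRUE)))
  beta <- lme4::fixef(fit)
  beta[1] <- beta[1] - off_center  # back to the population scale
  V <- as.matrix(stats::vcov(fit))
  se <- sqrt(diag(V))
  sigma_b <- sqrt(unname(lme4::VarCorr(fit)$landscape_id[1, 1]))
  ll <- as.numeric(stats::logLik(fit))
  np <- attr(stats::logLik(fit), "df")
  ## classical single-shift intercept correction: remove the sample-vs-
  ## population prevalence log-odds shift (exact when sampling fractions are
  ## uniform across landscapes); with offsets in the model the fitted
  ## intercept is already population-scale and the shift is ~0.
  pop <- attr(table, "population")
  corrected <- unname(beta[1])
  if (!use_offset && !is.null(pop)) {
    ybar <- mean(table$disturbed)
    tau <- pop$prevalence
    corrected <- unname(beta[1]) -
      (stats::qlogis(ybar) - stats::qlogis(tau))
  }
  structure(list(beta = beta, se = se, vcov = V, sigma_b = sigma_b,
                 ranef = lme4::ranef(fit)$landscape_id[, 1],
                 loglik = ll, aic = 2 * np - 2 * ll, n_params = np,
                 corrected_intercept = corrected,
                 boundary = sigma_b < 1e-6,
                 fit = fit, n = nrow(table)),
            class = "ds_glmm")
}

#' @method print ds_glmm
#' @export
print.ds_glmm <- function(x, ...) {
  cat(sprintf("<ds_glmm: n=%d, sigma_b=%.3f, AIC=%.1f>\n", x$n, x$sigma_b,
              x$aic))
  print(data.frame(estimate = x$beta, se = x$se,
                   z = x$beta / x$se,
                   p = 2 * stats::pnorm(-abs(x$beta / x$se))))
  invisible(x)
}

#' Predicted population prevalence from a fitted driver model
#'
#' Mean inverse-logit linear predictor over the supplied (population-scale)
#' records using the corrected intercept and the predicted landscape
#' intercepts; recovers the population per-record disturbance rate when the
#' case-control correction is right.
#'
#' @param model a `ds_glmm`.
#' @param table population pixel-year table (no offsets needed).
#' @return scalar predicted prevalence.
#' @export
predicted_prevalence <- function(model, table) {
  b <- model$beta
  lev <- rownames(lme4::ranef(model$fit)$landscape_id)
  bl <- model$ranef[match(as.character(table$landscape_id), lev)]
  bl[is.na(bl)] <- 0
  eta <- model$corrected_intercept +
    b[["t_anom"]] * table$t_anom + b[["p_anom"]] * table$p_anom +
    b[["t_anom:p_anom"]] * table$t_anom * table$p_anom +
    b[["tri"]] * table$tri + bl
  mean(stats::plogis(eta))
}

#' Select the climate lag by AIC
#'
#' Refits the full driver model with anomalies joined at each candidate lag
#' on an identically constructed sample (the same pixel-year records; only
#' the anomaly columns change), and returns the lag minimising AIC.
#'
#' @param table sampled pixel-year table (records define the risk set; its
#'   `t_anom`/`p_anom` columns are replaced per lag).
#' @param anomalies data.frame `landscape_id`, `year`, `t_anom`, `p_anom`
#'   covering `min(year) - max(lags)`.
#' @param lags candidate lags (default 0:3).
#' @param nAGQ passed to [fit_glmm()].
#' @return list: `best_lag`, `aic_table` (data.frame lag, aic, loglik),
#'   `fits` (per-lag `ds_glmm`s), `unstable` (TRUE when all AIC differences
#'   are < 2, i.e. selection is within noise).
#' @export
select_lag <- function(table, anomalies, lags = 0:3, nAGQ = 1) {
  fits <- list(); rows <- list()
  for (L in lags) {
    key_t <- paste(table$landscape_id, table$year - L)
    key_a <- paste(anomalies$landscape_id, anomalies$year)
    idx <- match(key_t, key_a)
    if (anyNA(idx)) stop("anomalies do not cover lag ", L)
    tab <- table
    tab$t_anom <- anomalies$t_anom[idx]
    tab$p_anom <- anomalies$p_anom[idx]
    f <- fit_glmm(tab, nAGQ = nAGQ)
    fits[[as.character(L)]] <- f
    rows[[length(rows) + 1]] <- data.frame(lag = L, aic = f$aic,
                                           loglik = f$loglik)
  }
  tab <- do.call(rbind, rows)
  best <- tab$lag[which.min(tab$aic)]
  list(best_lag = best, aic_table = tab, fits = fits,
       unstable = max(tab$aic) - min(tab$aic) < 2)
}

#' Compare full, spatial-only and null driver models
#'
#' Fits, on the identical sample, the full model (climate anomalies, their
#' interaction, and TRI), a spatial-only model (TRI only) and a null model
#' (intercept only), all with the landscape random intercept; ranks them by
#' AIC and reports likelihood-ratio tests of full vs spatial-only (df = 3)
#' and spatial-only vs null (df = 1) against the chi-squared reference.
#'
#' @param table sampled pixel-year table with anomaly and TRI columns.
#' @param nAGQ passed to [fit_glmm()].
#' @return list: `table` (data.frame model, aic, loglik, df), `lrt`
#'   (data.frame comparison, chisq, df, p_value), `fits`.
#' @export
compare_models <- function(table, nAGQ = 1) {
  full <- fit_glmm(table, nAGQ = nAGQ)
  spat <- fit_glmm(table, disturbed ~ tri + (1 | landscape_id), nAGQ = nAGQ)
  null <- fit_glmm(table, disturbed ~ 1 + (1 | landscape_id), nAGQ = nAGQ)
  tab <- data.frame(
    model = c("full", "spatial_only", "null"),
    aic = c(full$aic, spat$aic, null$aic),
    loglik = c(full$loglik, spat$loglik, null$loglik),
    df = c(full$n_params, spat$n_params, null$n_params))
  lrt <- data.frame(
    comparison = c("full_vs_spatial", "spatial_vs_null"),
    chisq = c(2 * (full$loglik - spat$loglik),
              2 * (spat$loglik - null$loglik)),
    df = c(3, 1))
  lrt$chisq <- pmax(lrt$chisq, 0)
  lrt$p_value <- stats::pchisq(lrt$chisq, lrt$df, lower.tail = FALSE)
  list(table = tab, lrt = lrt,
       fits = list(full = full, spatial_only = spat, null = null))
}

## nearest positive-semidefinite repair by eigenvalue clipping
nearest_psd <- function(V) {
  e <- eigen((V + t(V)) / 2, symmetric = TRUE)
  if (min(e$values) >= 0) return(V)
  warning("covariance not positive semidefinite: repaired by eigenvalue clipping")
  e$vectors %*% diag(pmax(e$values, 0), nrow(V)) %*% t(e$vectors)
}

#' Simulated disturbance-probability response curves
#'
#' Draws `n_sim` coefficient vectors from the multivariate normal
#' approximation to the sampling distribution of the fixed effects
#' (`MVN(beta_hat, vcov)`), and for each draw evaluates the inverse-logit
#' predicted disturbance probability over a temperature-anomaly grid at
#' fixed precipitation-anomaly levels, with TRI = 0, random intercept 0 and
#' the population-scale (corrected) intercept. Returns the pointwise median
#' and the 2.5/97.5% quantiles of the simulated predictions.
#'
#' @param model a `ds_glmm` from the full driver model.
#' @param temp_grid temperature-anomaly grid (SD units).
#' @param precip_levels precipitation-anomaly levels (SD units).
#' @param n_sim number of coefficient draws (default 9999).
#' @param seed integer seed.
#' @param level interval coverage (default 0.95).
#' @return data.frame: `t_anom`, `p_anom`, `median`, `lower`, `upper`,
#'   `plugin` (the deterministic curve at beta_hat).
#' @export
simulate_response_curves <- function(model, temp_grid = seq(-2, 2, by = 0.1),
                                     precip_levels = c(-1, 0, 1),
                                     n_sim = 9999, seed = NULL, level = 0.95) {
  b <- model$beta
  nm <- names(b)
  V <- nearest_psd(model$vcov)
  draws <- with_seed(seed, function() {
    ch <- chol(V + diag(1e-12, nrow(V)))
    matrix(stats::rnorm(n_sim * length(b)), n_sim) %*% ch
  })
  draws <- sweep(draws, 2, b, "+")
  colnames(draws) <- nm
  ## population-scale intercept replaces the fitted one (same uncertainty)
  draws[, 1] <- draws[, 1] - b[[1]] + model$corrected_intercept
  alpha <- (1 - level) / 2
  out <- list()
  for (p in precip_levels) {
    for (tt in temp_grid) {
      eta <- draws[, 1] + draws[, "t_anom"] * tt + draws[, "p_anom"] * p +
        draws[, "t_anom:p_anom"] * tt * p
      pr <- stats::plogis(eta)
      plug <- stats::plogis(model$corrected_intercept + b[["t_anom"]] * tt +
                              b[["p_anom"]] * p + b[["t_anom:p_anom"]] * tt * p)
      out[[length(out) + 1]] <- data.frame(
        t_anom = tt, p_anom = p,
        median = stats::median(pr),
        lower = stats::quantile(pr, alpha, names = FALSE),
        upper = stats::quantile(pr, 1 - alpha, names = FALSE),
        plugin = plug)
    }
  }
  do.call(rbind, out)
}
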