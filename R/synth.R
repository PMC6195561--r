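#' Landscape archetype presets
#'
#' Three generator archetypes spanning the observed range of disturbance
#' activity in temperate-forest landscapes: `low` (rare, small, complex
#' patches), `moderate` (intermediate prevalence and patch size) and `high`
#' (large, compact patches affecting a fifth of the forest over the period).
#' `target_pland` is the percent of forest area disturbed over the study
#' period; the patch-size law is a truncated power law on patch area (cells);
#' `shape_irregularity` in \[0,1\] moves patch growth from compact (0) to
#' dendritic (1).
#'
#' @param name one of `"low"`, `"moderate"`, `"high"`.
#' @return a list with fields `name`, `target_pland`, `alpha`, `amin_cells`,
#'   `amax_cells`, `shape_irregularity`.
#' @export
landscape_archetype <- function(name = c("low", "moderate", "high")) {
  name <- match.arg(name)
  presets <- list(
    low      = list(target_pland = 0.31, alpha = 2.8, amin_cells = 1,
                    amax_cells = 10,   shape_irregularity = 0.85),
    moderate = list(target_pland = 4.6,  alpha = 1.9, amin_cells = 1,
                    amax_cells = 150,  shape_irregularity = 0.50),
    high     = list(target_pland = 21.5, alpha = 1.5, amin_cells = 1,
                    amax_cells = 800,  shape_irregularity = 0.10)
  )
  a <- presets[[name]]
  stopifnot(a$target_pland > 0, a$target_pland < 100, a$amin_cells >= 1)
  c(list(name = name), a)
}

#' Generative driver parameters for the disturbance process
#'
#' Fixed-effect coefficients on the anomaly / ruggedness z-score scale, the
#' baseline log-odds of annual disturbance, the standard deviation of the
#' landscape random intercept, and the climate lag (years).
#'
#' @param beta0 baseline log-odds of disturbance per pixel-year.
#' @param beta_T,beta_P,beta_TP,beta_TRI coefficients for the temperature
#'   anomaly, precipitation anomaly, their interaction, and the z-scored
#'   topographic ruggedness index.
#' @param sigma_b SD of the landscape random intercept (>= 0).
#' @param lag climate lag in years (0-3).
#' @return a list of class `ds_driver_params`.
#' @export
driver_params <- function(beta0 = -4.6, beta_T = 0.6, beta_P = -0.3,
                          beta_TP = -0.4, beta_TRI = -0.1,
                          sigma_b = 0.5, lag = 0) {
  if (sigma_b < 0) stop("`sigma_b` must be non-negative")
  if (!lag %in% 0:3) stop("`lag` must be in 0..3")
  structure(list(beta0 = beta0, beta_T = beta_T, beta_P = beta_P,
                 beta_TP = beta_TP, beta_TRI = beta_TRI,
                 sigma_b = sigma_b, lag = as.integer(lag)),
            class = "ds_driver_params")
}

#' Baseline log-odds that yields a target period prevalence
#'
#' Inverts the survival identity: a constant annual disturbance probability q
#' gives period prevalence 1 - (1-q)^n over n years.
#'
#' @param target_pland percent of forest disturbed over the period.
#' @param n_years number of disturbance years.
#' @return baseline log-odds (logit of annual probability).
#' @export
beta0_for_pland <- function(target_pland, n_years = 14) {
  q <- 1 - (1 - target_pland / 100)^(1 / n_years)
  stats::qlogis(q)
}

#' Sample a truncated power law
#'
#' Continuous inverse-CDF sampling of a density proportional to x^(-alpha) on
#' \[xmin, xmax\], used for patch areas.
#'
#' @param n number of draws.
#' @param alpha exponent (> 0, != 1).
#' @param xmin,xmax truncation bounds (0 < xmin < xmax).
#' @return numeric vector.
#' @export
rtrunc_power <- function(n, alpha, xmin, xmax) {
  stopifnot(xmin > 0, xmax > xmin, alpha > 0)
  u <- stats::runif(n)
  if (abs(alpha - 1) < 1e-12) {
    exp(log(xmin) + u * (log(xmax) - log(xmin)))
  } else {
    a1 <- 1 - alpha
    (u * (xmax^a1 - xmin^a1) + xmin^a1)^(1 / a1)
  }
}

## separable Gaussian blur with edge truncation + renormalisation
gauss_blur <- function(m, sd_cells) {
  r <- max(1L, ceiling(3 * sd_cells))
  w <- stats::dnorm(-r:r, sd = sd_cells)
  blur1 <- function(x) {          # along rows (dimension 1)
    nr <- nrow(x)
    acc <- matrix(0, nr, ncol(x)); wt <- matrix(0, nr, ncol(x))
    for (s in -r:r) {
      src <- (1:nr) + s
      ok <- src >= 1 & src <= nr
      acc[ok, ] <- acc[ok, ] + w[s + r + 1] * x[src[ok], ]
      wt[ok, ] <- wt[ok, ] + w[s + r + 1]
    }
    acc / wt
  }
  t(blur1(t(blur1(m))))
}

#' Generate a synthetic digital elevation model
#'
#' A smoothed Gaussian random field: white noise blurred with a Gaussian
#' kernel, normalised to unit standard deviation and scaled by `roughness`
#' (vertical relief, m). `roughness = 0` yields a perfectly flat surface.
#' Expected mean terrain ruggedness scales linearly (hence strictly
#' monotonically) with `roughness`.
#'
#' @param n_rows,n_cols grid dimensions (>= 7 each).
#' @param roughness vertical scale of the field in metres (>= 0).
#' @param seed integer seed.
#' @param smooth_sd_cells Gaussian blur SD in cells (controls horizontal
#'   correlation length; default 2 cells = 60 m).
#' @param base_elev_m mean elevation.
#' @return a [ds_grid()] of elevations (m).
#' @export
generate_dem <- function(n_rows, n_cols, roughness, seed,
                         smooth_sd_cells = 2, base_elev_m = 500) {
  if (n_rows < 7 || n_cols < 7) stop("DEM dimensions must be at least 7 x 7")
  if (roughness < 0) stop("`roughness` must be non-negative")
  vals <- with_seed(seed, function() {
    if (roughness == 0) return(matrix(base_elev_m, n_rows, n_cols))
    z <- gauss_blur(matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols),
                    smooth_sd_cells)
    base_elev_m + roughness * (z - mean(z)) / stats::sd(as.vector(z))
  })
  ds_grid(vals, cell_size_m = 30)
}

#' Generate an annual climate series for one landscape
#'
#' Stationary AR(1) series of mean annual temperature (deg C) and annual
#' precipitation sum (mm) with configurable means, marginal SDs and lag-1
#' autocorrelation. SD = 0 produces a constant series, flagged with attribute
#' `constant = TRUE` because anomalies (z-scores) are undefined downstream.
#'
#' @param n_years series length (>= 4 so that lags 0-3 remain usable).
#' @param seed integer seed.
#' @param t_mean,t_sd temperature mean / marginal SD (deg C).
#' @param p_mean,p_sd precipitation mean / marginal SD (mm).
#' @param ar lag-1 autocorrelation in \[0, 1).
#' @return data.frame with columns `year` (1..n_years), `tmean_c`, `prec_mm`.
#' @export
generate_climate_series <- function(n_years, seed, t_mean = 6, t_sd = 0.8,
                                    p_mean = 1200, p_sd = 150, ar = 0.3) {
  if (n_years < 4) stop("`n_years` must be at least 4 (lags 0-3 must be usable)")
  if (ar < 0 || ar >= 1) stop("`ar` must be in [0, 1)")
  ar1 <- function(n, mu, sd) {
    if (sd == 0) return(rep(mu, n))
    x <- numeric(n)
    x[1] <- stats::rnorm(1, mu, sd)
    se <- sd * sqrt(1 - ar^2)
    for (t in seq_len(n - 1)) x[t + 1] <- mu + ar * (x[t] - mu) + stats::rnorm(1, 0, se)
    x
  }
  out <- with_seed(seed, function() {
    data.frame(year = seq_len(n_years),
               tmean_c = ar1(n_years, t_mean, t_sd),
               prec_mm = pmax(ar1(n_years, p_mean, p_sd), 1))
  })
  attr(out, "constant") <- (t_sd == 0 || p_sd == 0)
  out
}

## linear predictor pieces shared by both generator modes
climate_anomalies <- function(climate) {
  data.frame(year = climate$year,
             t_anom = zscore(climate$tmean_c),
             p_anom = zscore(climate$prec_mm))
}

#' Generate a disturbance-year raster with known generative truth
#'
#' Simulates annual severe canopy disturbance on a forest mask over years
#' `start_year..n_years` of the climate series, recording the first
#' disturbance year per pixel (0 = never disturbed; a pixel leaves the risk
#' set after its first disturbance, matching a single-loss-year product).
#'
#' Two modes:
#' * `pixel_iid`: each at-risk pixel is disturbed in year t independently
#'   with probability
#'   `plogis(beta0 + beta_T*T + beta_P*P + beta_TP*T*P + beta_TRI*TRI + b)`,
#'   where T, P are per-landscape climate anomalies at `year - lag`, TRI is
#'   the per-landscape z-scored ruggedness index and b the landscape random
#'   intercept. This matches the driver model's likelihood exactly and is
#'   the mode used for parameter-recovery validation.
#' * `patchy`: the same linear predictor sets the per-year expected disturbed
#'   area, which is realised as discrete patches: patch areas drawn from the
#'   archetype's truncated power law, grown by stochastic region spreading
#'   from a seed cell (frontier cells weighted between compactness and
#'   uniform by `shape_irregularity`). This mode produces realistic spatial
#'   aggregation for the pattern-metric analyses.
#'
#' @param forest logical forest mask (matrix or [ds_grid()]).
#' @param dem elevation grid (matrix or [ds_grid()]), congruent with `forest`.
#' @param climate data.frame from [generate_climate_series()].
#' @param truth list with `params` (a [driver_params()]), `b` (landscape
#'   random intercept, scalar) and, for `patchy` mode, `archetype`
#'   (a [landscape_archetype()]).
#' @param mode `"pixel_iid"` or `"patchy"`.
#' @param seed integer seed.
#' @param start_year first simulated disturbance year (calendar index into
#'   `climate`); default 4 keeps lags 0-3 usable.
#' @return a [ds_grid()] of integer first-disturbance calendar-year indices
#'   (0 = never), with attributes `start_year` and `years`.
#' @export
generate_disturbance_series <- function(forest, dem, climate, truth,
                                        mode = c("pixel_iid", "patchy"),
                                        seed, start_year = 4) {
  mode <- match.arg(mode)
  f <- grid_values(forest) != 0 & !is.na(grid_values(forest))
  stopifnot_congruent(forest, dem)
  p <- truth$params
  if (!inherits(p, "ds_driver_params")) stop("truth$params must be driver_params()")
  years <- start_year:nrow(climate)
  if (min(years) - p$lag < 1) {
    stop("lag ", p$lag, " exceeds available climate history before year ",
         start_year)
  }
  if (isTRUE(attr(climate, "constant"))) {
    stop("constant climate series: anomalies undefined")
  }
  an <- climate_anomalies(climate)
  tri <- compute_tri(dem, window = 7)
  triz <- matrix(NA_real_, nrow(f), ncol(f))
  ## flat terrain has constant TRI: all relative complexity contributions 0
  triz[f] <- if (stats::sd(tri$tri[f]) == 0) 0 else zscore(tri$tri[f])
  b <- truth$b %||% 0

  vals <- with_seed(seed, function() {
    first <- matrix(0L, nrow(f), ncol(f))
    if (mode == "pixel_iid") {
      fidx <- which(f)
      eta0 <- p$beta0 + p$beta_TRI * triz[fidx] + b
      at_risk <- rep(TRUE, length(fidx))
      for (y in years) {
        tt <- an$t_anom[y - p$lag]; pp <- an$p_anom[y - p$lag]
        eta <- eta0 + p$beta_T * tt + p$beta_P * pp + p$beta_TP * tt * pp
        pr <- stats::plogis(eta)
        hit <- at_risk & stats::runif(length(fidx)) < pr
        first[fidx[hit]] <- y
        at_risk <- at_risk & !hit
      }
    } else {
      arch <- truth$archetype
      if (is.null(arch)) stop("patchy mode requires truth$archetype")
      mean_area <- mean(rtrunc_power(2000, arch$alpha, arch$amin_cells,
                                     arch$amax_cells))
      for (y in years) {
        tt <- an$t_anom[y - p$lag]; pp <- an$p_anom[y - p$lag]
        q <- stats::plogis(p$beta0 + p$beta_T * tt + p$beta_P * pp +
                             p$beta_TP * tt * pp + b)
        at_risk <- f & first == 0L
        n_risk <- sum(at_risk)
        if (n_risk == 0) break
        n_patches <- stats::rpois(1, q * n_risk / mean_area)
        for (k in seq_len(n_patches)) {
          target <- max(arch$amin_cells,
                        round(rtrunc_power(1, arch$alpha, arch$amin_cells,
                                           arch$amax_cells)))
          first <- grow_patch(first, f, triz, y, target,
                              arch$shape_irregularity, p$beta_TRI)
        }
      }
    }
    first
  })
  g <- ds_grid(vals, cell_size_m = grid_cell_size(forest))
  attr(g, "start_year") <- start_year
  attr(g, "years") <- years
  g
}

## stochastic region growing of one patch; returns updated first-year grid
grow_patch <- function(first, f, triz, year, target_cells, irregularity,
                       beta_tri) {
  nr <- nrow(first); nc <- ncol(first)
  at_risk <- f & first == 0L
  risk_idx <- which(at_risk)
  if (length(risk_idx) == 0) return(first)
  ## seed cell: terrain preference on the generative TRI coefficient
  w <- exp(beta_tri * triz[risk_idx])
  seed_cell <- risk_idx[sample.int(length(risk_idx), 1, prob = w)]

  neighbors8 <- function(i) {
    r <- ((i - 1L) %% nr) + 1L; cc <- ((i - 1L) %/% nr) + 1L
    rs <- rep(r + (-1:1), 3); cs <- rep(cc + (-1:1), each = 3)
    ok <- rs >= 1 & rs <= nr & cs >= 1 & cs <= nc & !(rs == r & cs == cc)
    (cs[ok] - 1L) * nr + rs[ok]
  }
  in_patch <- rep(FALSE, nr * nc)
  nb_count <- integer(nr * nc)   # patch neighbours per cell
  frontier <- integer(0)
  add_cell <- function(i) {
    in_patch[i] <<- TRUE
    first[i] <<- year
    at_risk[i] <<- FALSE
    nbs <- neighbors8(i)
    nb_count[nbs] <<- nb_count[nbs] + 1L
    new_f <- nbs[at_risk[nbs] & !in_patch[nbs]]
    frontier <<- unique(c(frontier, new_f))
  }
  add_cell(seed_cell)
  size <- 1L
  while (size < target_cells && length(frontier) > 0) {
    frontier <- frontier[at_risk[frontier]]
    if (length(frontier) == 0) break
    wts <- (1 - irregularity) * nb_count[frontier] / 8 + irregularity
    pick <- frontier[sample.int(length(frontier), 1, prob = wts)]
    frontier <- frontier[frontier != pick]
    add_cell(pick)
    size <- size + 1L
  }
  first
}

#' Default species pool with disturbance-relevant traits
#'
#' A small synthetic pool of temperate tree species with plausible maximum
#' height (m), wood density (g/cm^3) and conifer flags, spanning the
#' broadleaf/conifer trait contrast (conifers taller, lower wood density).
#'
#' @return data.frame: `species`, `genus`, `max_height_m`,
#'   `wood_density_g_cm3`, `is_conifer`.
#' @export
default_species_pool <- function() {
  data.frame(
    species = c("Fagus sylvatica", "Nothofagus pumilio", "Acer saccharum",
                "Quercus robur", "Betula pendula", "Eucalyptus regnans",
                "Picea abies", "Abies alba", "Pseudotsuga menziesii",
                "Pinus contorta", "Tsuga heterophylla", "Larix decidua"),
    genus = c("Fagus", "Nothofagus", "Acer", "Quercus", "Betula",
              "Eucalyptus", "Picea", "Abies", "Pseudotsuga", "Pinus",
              "Tsuga", "Larix"),
    max_height_m = c(40, 30, 35, 35, 25, 90, 55, 55, 80, 35, 55, 45),
    wood_density_g_cm3 = c(0.58, 0.55, 0.56, 0.56, 0.51, 0.49,
                           0.37, 0.35, 0.45, 0.40, 0.42, 0.47),
    is_conifer = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                   TRUE, TRUE, TRUE, TRUE, TRUE, TRUE)
  )
}

## ranked top-2 draw without replacement; zero-probability categories can
## still fill rank 2 (uniformly) when the distribution is degenerate
draw_top2 <- function(pd) {
  first <- sample(names(pd), 1, prob = pd)
  rest <- pd[setdiff(names(pd), first)]
  second <- if (sum(rest) > 0) {
    sample(names(rest), 1, prob = rest)
  } else {
    sample(names(rest), 1)
  }
  c(first, second)
}

#' Default per-archetype disturbance-agent distributions
#'
#' Categorical probabilities over agents for each activity archetype: wind
#' dominates low-activity landscapes, bark beetles and fire rise with
#' activity, and fire dominates the high-activity archetype.
#'
#' @return named list of named probability vectors (each sums to 1).
#' @export
default_agent_distributions <- function() {
  list(
    low      = c(wind = 0.50, other_biotic = 0.20, fire = 0.10,
                 drought = 0.10, bark_beetle = 0.10),
    moderate = c(bark_beetle = 0.30, fire = 0.30, wind = 0.25,
                 drought = 0.10, other_biotic = 0.05),
    high     = c(fire = 0.55, bark_beetle = 0.25, drought = 0.15,
                 wind = 0.05, other_biotic = 0.00)
  )
}

## default per-archetype species sampling preference over the pool
default_species_pref <- function(pool) {
  pref <- list(
    low      = ifelse(pool$is_conifer, 0.3, 1),
    moderate = rep(1, nrow(pool)),
    high     = ifelse(pool$is_conifer, 1, 0.35)
  )
  lapply(pref, function(w) w / sum(w))
}

#' Generate per-landscape ecological context tables
#'
#' Emulates the expert-questionnaire variables: the two most important
#' disturbance agents per landscape (ranked), tree-species basal-area shares
#' and the species trait table. Agent draws follow the per-archetype
#' categorical distributions; shares are Dirichlet draws with geometrically
#' decaying concentration, giving a configurable dominance of the leading
#' species (flatter shares for the high-activity archetype).
#'
#' @param archetypes character vector: archetype name per landscape.
#' @param agent_distributions named list (archetype -> named probabilities
#'   summing to 1); default [default_agent_distributions()].
#' @param species_pool trait table; default [default_species_pool()].
#' @param seed integer seed.
#' @param n_species species per landscape.
#' @param dominance_decay named vector (archetype -> decay in (0,1)); share
#'   concentration for the k-th species is proportional to decay^(k-1).
#' @return list of data.frames: `agents` (landscape_id, rank, agent),
#'   `species` (landscape_id, species, share), `traits` (the pool).
#' @export
generate_context_tables <- function(archetypes,
                                    agent_distributions = default_agent_distributions(),
                                    species_pool = default_species_pool(),
                                    seed = 1, n_species = 5,
                                    dominance_decay = c(low = 0.35,
                                                        moderate = 0.40,
                                                        high = 0.75)) {
  for (nm in unique(archetypes)) {
    pd <- agent_distributions[[nm]]
    if (is.null(pd) || abs(sum(pd) - 1) > 1e-9 || any(pd < 0)) {
      stop("agent distribution for archetype '", nm,
           "' is missing or does not sum to 1")
    }
  }
  pref <- default_species_pref(species_pool)
  with_seed(seed, function() {
    n <- length(archetypes)
    agents <- vector("list", n); species <- vector("list", n)
    for (i in seq_len(n)) {
      arch <- archetypes[i]
      pd <- agent_distributions[[arch]]
      top2 <- draw_top2(pd)
      agents[[i]] <- data.frame(landscape_id = i, rank = 1:2, agent = top2)
      sp <- sample(species_pool$species, n_species,
                   prob = pref[[arch]] %||% rep(1, nrow(species_pool)))
      conc <- dominance_decay[[arch]]^(seq_len(n_species) - 1)
      g <- stats::rgamma(n_species, shape = conc * 6)
      share <- g / sum(g)
      species[[i]] <- data.frame(landscape_id = i, species = sp, share = share)
    }
    list(agents = do.call(rbind, agents),
         species = do.call(rbind, species),
         traits = species_pool)
  })
}
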