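# Independent brute-force oracles used to validate the package's optimised
# implementations. These deliberately use naive algorithms (stack flood fill,
# explicit window loops, exhaustive enumeration) and share no code with R/.

# flood-fill connected-component labelling (stack-based, no recursion)
oracle_label <- function(d, connectivity = 8) {
  nr <- nrow(d); nc <- ncol(d)
  lab <- matrix(0L, nr, nc)
  nbrs <- if (connectivity == 8) {
    cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1), dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  }
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!d[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j)); lab[i, j] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(nbrs))) {
        r <- p[1] + nbrs[k, 1]; cc <- p[2] + nbrs[k, 2]
        if (r >= 1 && r <= nr && cc >= 1 && cc <= nc &&
            d[r, cc] && lab[r, cc] == 0L) {
          lab[r, cc] <- cur
          stack[[length(stack) + 1]] <- c(r, cc)
        }
      }
    }
  }
  lab
}

# per-patch area (cells) and perimeter (edges) by explicit edge enumeration
oracle_patch_stats <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  ids <- sort(unique(lab[lab > 0]))
  area <- perim <- stats::setNames(numeric(length(ids)), ids)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    id <- lab[i, j]
    if (id == 0) next
    area[as.character(id)] <- area[as.character(id)] + 1
    for (k in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      r <- i + k[1]; cc <- j + k[2]
      outside <- r < 1 || r > nr || cc < 1 || cc > nc || lab[r, cc] != id
      if (outside) perim[as.character(id)] <- perim[as.character(id)] + 1
    }
  }
  list(area_cells = unname(area), perimeter_edges = unname(perim))
}

# TRI by explicit per-cell window loop
oracle_tri <- function(z, window = 7) {
  r <- (window - 1) / 2
  nr <- nrow(z); nc <- ncol(z)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0; cnt <- 0
    for (di in -r:r) for (dj in -r:r) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
        acc <- acc + (z[ii, jj] - z[i, j])^2
        cnt <- cnt + 1
      }
    }
    out[i, j] <- sqrt(acc / cnt)
  }
  out
}

# Euclidean distance to nearest TRUE cell, brute force over all pairs
oracle_distance <- function(mask, cell = 30) {
  tgt <- which(mask, arr.ind = TRUE)
  out <- matrix(Inf, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    out[i, j] <- sqrt(min((tgt[, 1] - i)^2 + (tgt[, 2] - j)^2))
  }
  out * cell
}

# exact permutation p-value for the two-group KW statistic (upper tail),
# enumerating all assignments of n1 positions out of n
oracle_kw_exact_p <- function(values, n1) {
  n <- length(values)
  obs <- kruskal_wallis_H(values, rep(1:2, c(n1, n - n1)))
  combs <- utils::combn(n, n1)
  stats <- apply(combs, 2, function(idx) {
    g <- rep(2L, n); g[idx] <- 1L
    kruskal_wallis_H(values, g)
  })
  mean(stats >= obs - 1e-12)
}

# exact permutation p-value for the top-2 chi-squared homogeneity test,
# enumerating all distinct orderings of the cluster label multiset
oracle_chi2_exact_p <- function(categories, clusters) {
  obs <- pearson_chi2(top_category_table(categories, clusters))
  perms <- unique_perms(clusters)
  stats <- vapply(perms, function(cl)
    pearson_chi2(top_category_table(categories, cl)), 0)
  mean(stats >= obs - 1e-12)
}

unique_perms <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (v in unique(x)) {
    rest <- x[-match(v, x)]
    for (p in unique_perms(rest)) out[[length(out) + 1]] <- c(v, p)
  }
  unique(out)
}

# small helper: simulate a pixel_iid study and return population + sampled
# pixel-year tables (shared by several GLMM tests)
sim_glmm_study <- function(n_landscapes, npx, pars, seed,
                           n_years = 17, start_year = 4,
                           pixel_fraction = 0.1, roughness = 60) {
  tabs <- list(); anoms <- list()
  for (i in seq_len(n_landscapes)) {
    dem <- generate_dem(npx, npx, roughness, seed = stage_seed(seed, i * 7))
    cl <- generate_climate_series(n_years, seed = stage_seed(seed, i * 7 + 1))
    b <- with_seed(stage_seed(seed, i * 7 + 2),
                   function() stats::rnorm(1, 0, pars$sigma_b))
    f <- matrix(TRUE, npx, npx)
    dist <- generate_disturbance_series(f, dem, cl, list(params = pars, b = b),
                                        "pixel_iid",
                                        seed = stage_seed(seed, i * 7 + 3),
                                        start_year = start_year)
    tri <- compute_tri(dem, 7)
    triz <- matrix(0, npx, npx)
    tv <- tri$tri[f]
    triz[f] <- if (stats::sd(tv) == 0) 0 else zscore(tv)
    an <- generate_climate_series(n_years, seed = stage_seed(seed, i * 7 + 1))
    an <- data.frame(year = an$year,
                     t_anom = zscore(an$tmean_c), p_anom = zscore(an$prec_mm),
                     landscape_id = i)
    anoms[[i]] <- an
    tabs[[i]] <- build_pixel_year_table(dist, f, triz, an, lag = 0,
                                        landscape_id = i)
  }
  pop <- do.call(rbind, tabs)
  anom <- do.call(rbind, anoms)
  sampled <- suppressWarnings(
    sample_case_control(pop, pixel_fraction, seed = stage_seed(seed, 999)))
  list(population = pop, sampled = sampled, anomalies = anom)
}
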