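#' Weighted trait mean for one landscape
#'
#' Community-weighted trait mean: species basal-area shares times species
#' trait values. Species with a positive share but no trait value are dropped
#' and the remaining shares renormalised (with a warning); if no species with
#' positive share has trait coverage, an error is raised.
#'
#' @param shares named numeric vector of species shares (should sum to 1
#'   within 1e-6).
#' @param trait named numeric vector of trait values (names = species).
#' @return weighted mean trait value.
#' @export
weighted_trait_mean <- function(shares, trait) {
  if (abs(sum(shares) - 1) > 1e-6) {
    stop("species shares must sum to 1 (got ", sum(shares), ")")
  }
  covered <- names(shares)[names(shares) %in% names(trait) &
                             !is.na(trait[names(shares)])]
  covered <- covered[shares[covered] > 0]
  if (!length(covered)) stop("no trait coverage for any species with share > 0")
  if (sum(shares[covered]) < sum(shares[shares > 0]) - 1e-12) {
    warning("trait missing for some species; renormalising over covered species")
  }
  w <- shares[covered] / sum(shares[covered])
  sum(w * trait[covered])
}

#' Per-landscape trait profile
#'
#' Dominance (% share of the single most prevalent species), conifer share
#' (%), and community-weighted maximum height and wood density per landscape.
#'
#' @param species data.frame `landscape_id`, `species`, `share`.
#' @param traits data.frame `species`, `max_height_m`, `wood_density_g_cm3`,
#'   `is_conifer`.
#' @return data.frame: `landscape_id`, `dominance_pct`, `conifer_pct`,
#'   `max_height_m`, `wood_density_g_cm3`.
#' @export
trait_profile <- function(species, traits) {
  h <- stats::setNames(traits$max_height_m, traits$species)
  wd <- stats::setNames(traits$wood_density_g_cm3, traits$species)
  conif <- stats::setNames(as.numeric(traits$is_conifer), traits$species)
  out <- lapply(split(species, species$landscape_id), function(s) {
    sh <- stats::setNames(s$share, s$species)
    data.frame(landscape_id = s$landscape_id[1],
               dominance_pct = 100 * max(sh),
               conifer_pct = 100 * weighted_trait_mean(sh, conif),
               max_height_m = weighted_trait_mean(sh, h),
               wood_density_g_cm3 = weighted_trait_mean(sh, wd))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$landscape_id), ]
}

#' Pearson chi-squared statistic of homogeneity
#'
#' \eqn{\sum (O - E)^2 / E} with expected counts from the product of margins.
#'
#' @param tab integer matrix of counts (rows = categories, cols = groups).
#' @return the statistic.
#' @export
pearson_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  if (sum(tab) == 0) stop("empty contingency table")
  rs <- rowSums(tab); cs <- colSums(tab)
  keep_r <- rs > 0; keep_c <- cs > 0
  tab <- tab[keep_r, keep_c, drop = FALSE]
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

#' Build a category-by-cluster contingency table from top-k lists
#'
#' Each landscape contributes one count for each of its listed categories
#' (by default its two most important agents or genera) in its cluster's
#' column.
#'
#' @param categories list (one element per landscape) of character vectors.
#' @param clusters cluster label per landscape.
#' @return integer matrix, rows = categories, cols = clusters.
#' @export
top_category_table <- function(categories, clusters) {
  stopifnot(length(categories) == length(clusters))
  cat_flat <- unlist(categories, use.names = FALSE)
  cl_flat <- rep(clusters, lengths(categories))
  tab <- table(factor(cat_flat), factor(cl_flat))
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  names(dimnames(m)) <- NULL
  m
}

## add-one Monte-Carlo p-value
mc_pvalue <- function(stat_obs, stat_perm) {
  (1 + sum(stat_perm >= stat_obs - 1e-12)) / (1 + length(stat_perm))
}

#' Permutation chi-squared test of homogeneity
#'
#' Observed Pearson chi-squared from the category-by-cluster table built with
#' [top_category_table()]; the null distribution permutes cluster labels
#' across landscapes, keeping each landscape's category multiset intact (the
#' landscape is the permutation unit). The Monte-Carlo p-value uses the
#' add-one estimator, so it is never 0.
#'
#' @param categories list of per-landscape category vectors (e.g. top-2
#'   agents).
#' @param clusters cluster label per landscape (>= 2 distinct values).
#' @param n_perm permutation count (default 9999).
#' @param seed integer seed.
#' @return list: `statistic`, `p_value`, `table`, `n_perm`.
#' @export
permutation_chi2_test <- function(categories, clusters, n_perm = 9999,
                                  seed = NULL) {
  if (n_perm < 1) stop("`n_perm` must be at least 1")
  if (length(unique(clusters)) < 2) stop("need at least 2 clusters")
  tab <- top_category_table(categories, clusters)
  obs <- pearson_chi2(tab)
  perm <- with_seed(seed, function() {
    vapply(seq_len(n_perm), function(b) {
      pearson_chi2(top_category_table(categories, sample(clusters)))
    }, 0)
  })
  list(statistic = obs, p_value = mc_pvalue(obs, perm), table = tab,
       n_perm = n_perm)
}

#' Kruskal-Wallis H statistic (midranks, tie-corrected)
#'
#' \eqn{H = \frac{12}{N(N+1)} \sum n_i (\bar R_i - (N+1)/2)^2} divided by the
#' tie-correction factor \eqn{1 - \sum (t^3 - t)/(N^3 - N)}.
#'
#' @param values numeric vector.
#' @param groups group label per value (>= 2 groups).
#' @return the H statistic (0 when all values are identical).
#' @export
kruskal_wallis_H <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  N <- length(values)
  r <- rank(values)
  ni <- tabulate(groups)
  rbar <- rowsum(r, groups)[, 1] / ni
  H <- 12 / (N * (N + 1)) * sum(ni * (rbar - (N + 1) / 2)^2)
  t <- tabulate(match(values, values))  # tie-group sizes (zeros drop out)
  corr <- 1 - sum(t^3 - t) / (N^3 - N)
  if (corr == 0) return(0)  # all values identical
  H / corr
}

#' Permutation Kruskal-Wallis test
#'
#' Upper-tail Monte-Carlo test on H (H is non-negative, so the "two-tailed"
#' convention for this statistic is the standard upper-tail test), with the
#' add-one p-value estimator.
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @param n_perm permutation count.
#' @param seed integer seed.
#' @return list: `statistic`, `p_value`, `n_perm`.
#' @export
permutation_kw_test <- function(values, groups, n_perm = 9999, seed = NULL) {
  if (n_perm < 1) stop("`n_perm` must be at least 1")
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  obs <- kruskal_wallis_H(values, groups)
  perm <- with_seed(seed, function() {
    vapply(seq_len(n_perm), function(b) {
      kruskal_wallis_H(values, groups[sample.int(length(groups))])
    }, 0)
  })
  list(statistic = obs, p_value = mc_pvalue(obs, perm), n_perm = n_perm)
}

#' Pairwise permutation Kruskal-Wallis tests with FDR correction
#'
#' Runs the permutation KW test for every pair of groups and adjusts the
#' p-values with the Benjamini-Hochberg false-discovery-rate procedure across
#' the pairs.
#'
#' @param values numeric vector.
#' @param labels group labels.
#' @param n_perm permutations per pair.
#' @param seed integer seed; per-pair seeds are derived from it.
#' @return data.frame: `group1`, `group2`, `H`, `p_value`, `p_adj`.
#' @export
pairwise_kw_fdr <- function(values, labels, n_perm = 9999, seed = NULL) {
  labels <- as.factor(labels)
  lv <- levels(labels)
  if (length(lv) < 2) stop("need at least 2 groups")
  pairs <- utils::combn(lv, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    sel <- labels %in% pairs[, i]
    r <- permutation_kw_test(values[sel], droplevels(labels[sel]), n_perm,
                             seed = if (is.null(seed)) NULL else
                               stage_seed(seed, i))
    data.frame(group1 = pairs[1, i], group2 = pairs[2, i],
               H = r$statistic, p_value = r$p_value)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out
}
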