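#' Disturbance-pattern metrics stratified inside / outside a protected area
#'
#' Clips the period-aggregated disturbance map to each stratum (protected
#' area, and a surrounding buffer of width equal to the diagonal of the
#' protected area's minimum bounding rectangle) before patch delineation, so
#' a patch straddling the boundary contributes clipped pieces to both strata.
#' Each stratum's edge density and percent disturbed use that stratum's own
#' forest area as denominator.
#'
#' @param disturbance first-disturbance-year grid (0 = never).
#' @param forest logical forest mask.
#' @param protected logical protected-area mask.
#' @param buffer optional logical buffer mask; computed with
#'   [build_buffer()] at distance [mbr_diagonal()] of `protected` when NULL.
#' @param cell_size_m cell size when inputs are bare matrices.
#' @return data.frame with rows `inside` and `outside` and the metric
#'   columns of [landscape_metrics()], plus `stratum`.
#' @export
stratified_metrics <- function(disturbance, forest, protected, buffer = NULL,
                               cell_size_m = 30) {
  d <- grid_values(disturbance); f <- grid_values(forest)
  p <- grid_values(protected)
  cs <- grid_cell_size(disturbance, cell_size_m)
  stopifnot_congruent(d, f); stopifnot_congruent(d, p)
  prot <- p != 0 & !is.na(p)
  if (is.null(buffer)) {
    buffer <- build_buffer(prot, mbr_diagonal(prot, cs), cs)
  }
  buf <- grid_values(buffer) != 0
  if (any(prot & buf)) stop("buffer overlaps the protected mask")
  fm <- f != 0 & !is.na(f)
  dd <- d != 0 & !is.na(d)
  one <- function(mask, name) {
    m <- landscape_metrics((dd & mask & fm) * 1L, (fm & mask) * 1L, cs)
    cbind(stratum = name, m)
  }
  rbind(one(prot, "inside"), one(buf, "outside"))
}

#' Compare a patch metric between strata within each cluster
#'
#' For each disturbance-activity cluster, a Monte-Carlo Kruskal-Wallis test
#' of inside vs outside metric values across landscapes. By default the
#' permutation respects the paired structure (both strata come from the same
#' landscape): the null is generated by independently swapping the stratum
#' labels within each landscape. `paired = FALSE` permutes stratum labels
#' freely across all observations instead.
#'
#' @param df data.frame with columns `landscape_id`, `cluster`, `stratum`
#'   (`"inside"`/`"outside"`) and `value`; rows with missing values are
#'   dropped, and landscapes missing either stratum are excluded from the
#'   paired test.
#' @param n_perm permutations.
#' @param seed integer seed.
#' @param paired use the within-landscape stratum-swap null (default TRUE).
#' @return data.frame: `cluster`, `n_landscapes`, `H`, `p_value`; clusters
#'   with fewer than 2 complete landscapes are skipped with a warning.
#' @export
compare_strata <- function(df, n_perm = 9999, seed = NULL, paired = TRUE) {
  stopifnot(all(c("landscape_id", "cluster", "stratum", "value") %in% names(df)))
  df <- df[!is.na(df$value), ]
  rows <- list()
  cl_i <- 0
  for (cl in sort(unique(df$cluster))) {
    cl_i <- cl_i + 1
    sub <- df[df$cluster == cl, ]
    wide <- merge(sub[sub$stratum == "inside", c("landscape_id", "value")],
                  sub[sub$stratum == "outside", c("landscape_id", "value")],
                  by = "landscape_id", suffixes = c("_in", "_out"))
    if (nrow(wide) < 2) {
      warning("cluster ", cl, " skipped: fewer than 2 landscapes with both strata")
      next
    }
    vin <- wide$value_in; vout <- wide$value_out
    n <- nrow(wide)
    obs <- kruskal_wallis_H(c(vin, vout), rep(c("in", "out"), each = n))
    perm <- with_seed(if (is.null(seed)) NULL else stage_seed(seed, cl_i),
                      function() {
      vapply(seq_len(n_perm), function(b) {
        if (paired) {
          sw <- stats::runif(n) < 0.5
          a <- ifelse(sw, vout, vin)
          b2 <- ifelse(sw, vin, vout)
          kruskal_wallis_H(c(a, b2), rep(c("in", "out"), each = n))
        } else {
          kruskal_wallis_H(c(vin, vout),
                           sample(rep(c("in", "out"), each = n)))
        }
      }, 0)
    })
    rows[[length(rows) + 1]] <- data.frame(
      cluster = cl, n_landscapes = n, H = obs,
      p_value = mc_pvalue(obs, perm))
  }
  if (!length(rows)) stop("no cluster had enough data for the contrast")
  do.call(rbind, rows)
}
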