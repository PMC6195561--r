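#' Delineate disturbance patches on a binary grid
#'
#' Connected-component labelling of disturbed cells under an eight-neighbour
#' adjacency rule (diagonal contact joins cells into one patch), the standard
#' convention for raster disturbance-pattern analysis. Disturbances are
#' aggregated over the whole study period (any year > 0) before labelling.
#'
#' Patch perimeter counts every cell edge that adjoins a non-patch cell —
#' background or the grid boundary — times the cell size. Under 8-adjacency a
#' cell edge can never adjoin a different patch (edge-sharing cells are always
#' co-labelled), so patch perimeters are well defined.
#'
#' @param disturbed logical matrix or [ds_grid()]; `TRUE`/non-zero = disturbed.
#' @param connectivity 8 (default) or 4.
#' @param cell_size_m cell size in metres when `disturbed` is a bare matrix.
#' @return an object of class `ds_patches`: list with `labels` (integer
#'   matrix, 0 = background, patches numbered 1..n in row-major order of
#'   first cell), `area_ha`, `perimeter_m` (per-patch vectors), `n_patches`,
#'   `cell_size_m`.
#' @export
label_patches <- function(disturbed, connectivity = 8, cell_size_m = 30) {
  if (!connectivity %in% c(4, 8)) stop("`connectivity` must be 4 or 8")
  m <- grid_values(disturbed)
  cs <- grid_cell_size(disturbed, cell_size_m)
  d <- m != 0 & !is.na(m)
  nr <- nrow(d); nc <- ncol(d)
  on <- which(d)
  labels <- matrix(0L, nr, nc)
  if (length(on) == 0) {
    return(structure(list(labels = labels, area_ha = numeric(0),
                          perimeter_m = numeric(0), n_patches = 0L,
                          cell_size_m = cs),
                     class = "ds_patches"))
  }
  ## compact vertex ids for disturbed cells
  vid <- integer(nr * nc)
  vid[on] <- seq_along(on)

  offsets <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offsets <- c(offsets, list(c(1L, 1L), c(1L, -1L)))
  rows <- ((on - 1L) %% nr) + 1L
  cols <- ((on - 1L) %/% nr) + 1L
  edges <- vector("list", length(offsets))
  for (k in seq_along(offsets)) {
    dr <- offsets[[k]][1]; dc <- offsets[[k]][2]
    r2 <- rows + dr; c2 <- cols + dc
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- d[nb]
    edges[[k]] <- rbind(vid[on[ok][hit]], vid[nb[hit]])
  }
  e <- do.call(cbind, edges)
  g <- igraph::make_graph(edges = as.vector(e), n = length(on), directed = FALSE)
  memb <- igraph::components(g)$membership
  ## renumber components 1..k by row-major order of their first cell
  first <- tapply(seq_along(on), memb, min)
  renum <- integer(max(memb))
  renum[as.integer(names(sort(first)))] <- seq_along(first)
  lab <- renum[memb]
  labels[on] <- lab

  n_patch <- max(lab)
  area_cells <- tabulate(lab, nbins = n_patch)

  ## per-cell exposed 4-edges = 4 - number of 4-adjacent disturbed cells
  nb4 <- matrix(0L, nr, nc)
  nb4[-1, ] <- nb4[-1, ] + d[-nr, ]
  nb4[-nr, ] <- nb4[-nr, ] + d[-1, ]
  nb4[, -1] <- nb4[, -1] + d[, -nc]
  nb4[, -nc] <- nb4[, -nc] + d[, -1]
  exposed <- 4L - nb4[on]
  perim_cells <- as.numeric(rowsum(exposed, lab)[, 1])

  structure(list(labels = labels,
                 area_ha = area_cells * cell_ha(cs),
                 perimeter_m = perim_cells * cs,
                 n_patches = as.integer(n_patch),
                 cell_size_m = cs),
            class = "ds_patches")
}

#' @method print ds_patches
#' @export
print.ds_patches <- function(x, ...) {
  cat(sprintf("<ds_patches: %d patches, %.2f ha, %.0f m edge>\n",
              x$n_patches, sum(x$area_ha), sum(x$perimeter_m)))
  invisible(x)
}

#' Percent of forest area disturbed
#'
#' @param disturbed,forest logical matrices or [ds_grid()]s; disturbed cells
#'   must lie within the forest mask.
#' @return percentage in \[0, 100\].
#' @export
percent_disturbed <- function(disturbed, forest) {
  dd <- grid_values(disturbed); ff <- grid_values(forest)
  stopifnot_congruent(dd, ff)
  d <- dd != 0 & !is.na(dd)
  f <- ff != 0 & !is.na(ff)
  nf <- sum(f)
  if (nf == 0) stop("forest mask is empty")
  if (any(d & !f)) stop("disturbed cells found outside the forest mask")
  100 * sum(d) / nf
}

#' Edge density of disturbance patches (m/ha)
#'
#' Total perimeter of all disturbance patches divided by the forest area of
#' the landscape (or stratum).
#'
#' @param patches a `ds_patches` from [label_patches()].
#' @param forest logical matrix or [ds_grid()]; its true-cell area is the
#'   denominator. A scalar is taken as forest area in hectares directly.
#' @return metres of edge per hectare of forest.
#' @export
edge_density <- function(patches, forest) {
  area_ha <- if (is.numeric(forest) && length(forest) == 1) {
    forest
  } else {
    ff <- grid_values(forest)
    sum(ff != 0 & !is.na(ff)) * cell_ha(grid_cell_size(forest, patches$cell_size_m))
  }
  if (area_ha <= 0) stop("forest area must be positive")
  sum(patches$perimeter_m) / area_ha
}

#' Area-weighted mean patch size (ha)
#'
#' Mean patch area with each patch weighted by its own area:
#' \eqn{\sum a_i^2 / \sum a_i}. Returns `NA` (flagged missing) when there are
#' no patches.
#'
#' @param patches a `ds_patches`.
#' @return hectares, or `NA_real_` for an empty patch set.
#' @export
awm_patch_size <- function(patches) {
  if (patches$n_patches == 0) return(NA_real_)
  a <- patches$area_ha
  sum(a^2) / sum(a)
}

#' Area-weighted mean perimeter-area ratio (m/ha)
#'
#' Area-weighted mean of per-patch perimeter/area ratios, which reduces
#' algebraically to total perimeter / total area:
#' \eqn{\sum (p_i/a_i) a_i / \sum a_i = \sum p_i / \sum a_i}. Higher values
#' indicate smaller and/or more complex (less compact) patches; the maximum
#' attainable at 30 m resolution is a single cell, 120/0.09 = 1333.33 m/ha.
#'
#' @param patches a `ds_patches`.
#' @return m/ha, or `NA_real_` for an empty patch set.
#' @export
awm_par <- function(patches) {
  if (patches$n_patches == 0) return(NA_real_)
  sum(patches$perimeter_m) / sum(patches$area_ha)
}

#' The four disturbance-pattern metrics for one landscape (or stratum)
#'
#' Aggregates disturbances over the whole period, labels patches under the
#' 8-neighbour rule and returns percent of forest disturbed, edge density,
#' area-weighted mean patch size and area-weighted mean perimeter-area ratio.
#' Zero-disturbance inputs yield pland = 0, edge density = 0 and flagged
#' missing (`NA`) patch-level metrics.
#'
#' @param disturbance integer grid of first-disturbance year (0 = never) or a
#'   logical disturbed mask; matrix or [ds_grid()].
#' @param forest logical forest mask, congruent with `disturbance`.
#' @param cell_size_m cell size in metres when inputs are bare matrices.
#' @return one-row data.frame: `pland_pct`, `edge_density_m_per_ha`,
#'   `awmps_ha`, `awm_par_m_per_ha`, `n_patches`.
#' @export
landscape_metrics <- function(disturbance, forest, cell_size_m = 30) {
  dd <- grid_values(disturbance)
  d <- dd != 0 & !is.na(dd)
  cs <- grid_cell_size(disturbance, cell_size_m)
  ps <- label_patches(d, connectivity = 8, cell_size_m = cs)
  data.frame(
    pland_pct = percent_disturbed(d, forest),
    edge_density_m_per_ha = edge_density(ps, forest),
    awmps_ha = awm_patch_size(ps),
    awm_par_m_per_ha = awm_par(ps),
    n_patches = ps$n_patches
  )
}
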