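#' Planar raster grid
#'
#' A minimal planar grid container: a numeric matrix of cell values (row 1 is
#' the northernmost row, as in ESRI ASCII grids) plus the cell size in metres
#' and the coordinates of the lower-left corner. All landscape rasters in this
#' package (forest masks, disturbance-year grids, DEMs, protected-area masks)
#' are `ds_grid` objects on congruent 30 m lattices; no projection or geodesy
#' is attached — coordinates are planar by design.
#'
#' @param values numeric or integer matrix.
#' @param cell_size_m cell edge length in metres (default 30).
#' @param xll,yll coordinates of the lower-left grid corner.
#' @param nodata value flagged as missing on disk (default -9999).
#' @return an object of class `ds_grid`.
#' @export
ds_grid <- function(values, cell_size_m = 30, xll = 0, yll = 0, nodata = -9999) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (cell_size_m <= 0) stop("`cell_size_m` must be positive")
  structure(
    list(values = values, cell_size_m = cell_size_m,
         xll = xll, yll = yll, nodata = nodata),
    class = "ds_grid"
  )
}

#' @method print ds_grid
#' @export
print.ds_grid <- function(x, ...) {
  cat(sprintf("<ds_grid %d x %d, cell %g m, origin (%g, %g)>\n",
              nrow(x$values), ncol(x$values), x$cell_size_m, x$xll, x$yll))
  invisible(x)
}

#' @export
dim.ds_grid <- function(x) dim(x$values)

## accept a ds_grid or a bare matrix; return the value matrix
grid_values <- function(x) {
  if (inherits(x, "ds_grid")) x$values else if (is.matrix(x)) x else
    stop("expected a ds_grid or a matrix")
}

grid_cell_size <- function(x, default = 30) {
  if (inherits(x, "ds_grid")) x$cell_size_m else default
}

## cell area in hectares
cell_ha <- function(cell_size_m) cell_size_m^2 / 1e4

stopifnot_congruent <- function(a, b) {
  if (!identical(dim(grid_values(a)), dim(grid_values(b)))) {
    stop("grids are not congruent: shapes differ")
  }
  if (inherits(a, "ds_grid") && inherits(b, "ds_grid") &&
      !isTRUE(all.equal(a$cell_size_m, b$cell_size_m))) {
    stop("grids are not congruent: cell sizes differ")
  }
  invisible(TRUE)
}

#' Read a grid from an ESRI ASCII raster file
#'
#' @param path file path.
#' @return a [ds_grid()].
#' @export
read_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, n = 6)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  needed <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(needed %in% names(hdr))) stop("malformed ESRI ASCII header in ", path)
  nodata <- hdr[["nodata_value"]] %||% -9999
  n_hdr <- 5L + ("nodata_value" %in% names(hdr))
  vals <- scan(path, skip = n_hdr, quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("ESRI ASCII body has ", length(vals), " values, expected ",
         hdr$ncols * hdr$nrows)
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA
  ds_grid(m, cell_size_m = hdr$cellsize, xll = hdr$xllcorner,
          yll = hdr$yllcorner, nodata = nodata)
}

#' Write a grid to an ESRI ASCII raster file
#'
#' Integer-valued grids round-trip losslessly; floating point grids are
#' written with full precision (`format` with 17 significant digits).
#'
#' @param grid a [ds_grid()] or matrix.
#' @param path output path.
#' @export
write_grid <- function(grid, path) {
  g <- if (inherits(grid, "ds_grid")) grid else ds_grid(grid)
  m <- g$values
  m[is.na(m)] <- g$nodata
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", g$xll),
    sprintf("yllcorner %.10g", g$yll),
    sprintf("cellsize %.10g", g$cell_size_m),
    sprintf("NODATA_value %.10g", g$nodata)
  )
  body <- apply(m, 1, function(r) paste(format(r, digits = 17, trim = TRUE,
                                               scientific = FALSE),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Diagonal of the minimum bounding rectangle of a mask
#'
#' Length, in metres, of the diagonal of the axis-aligned bounding box of the
#' true cells of a mask. Extents span the outer edges of the extreme cells, so
#' a single true cell has width = height = one cell size. This distance is the
#' buffer width used to delimit the unprotected surroundings of a protected
#' landscape: it scales with landscape size.
#'
#' @param mask logical matrix or [ds_grid()] with 0/1 values.
#' @param cell_size_m cell size in metres, used when `mask` is a bare matrix.
#' @return distance in metres.
#' @export
mbr_diagonal <- function(mask, cell_size_m = 30) {
  m <- grid_values(mask)
  cs <- grid_cell_size(mask, cell_size_m)
  idx <- which(m != 0 & !is.na(m), arr.ind = TRUE)
  if (nrow(idx) == 0) stop("mask is empty: minimum bounding rectangle undefined")
  h <- (diff(range(idx[, 1])) + 1) * cs
  w <- (diff(range(idx[, 2])) + 1) * cs
  sqrt(w^2 + h^2)
}

#' Euclidean distance (m) from each cell to the nearest true cell of a mask
#'
#' Cell-centre to cell-centre distances via an exact Euclidean distance
#' transform. True cells have distance 0.
#'
#' @param mask logical matrix or [ds_grid()].
#' @param cell_size_m cell size (m) when `mask` is a bare matrix.
#' @return numeric matrix of distances in metres.
#' @export
distance_to_mask <- function(mask, cell_size_m = 30) {
  m <- grid_values(mask)
  cs <- grid_cell_size(mask, cell_size_m)
  img <- matrix(as.numeric(!(m != 0 & !is.na(m))), nrow(m), ncol(m))
  ## distmap: distance of non-zero pixels to the nearest zero (= mask) pixel
  d <- EBImage::distmap(img, metric = "euclidean")
  as.matrix(d) * cs
}

#' Build a buffer mask around a protected-area mask
#'
#' Cells outside the protected mask whose centre lies within `distance_m`
#' (Euclidean, centre-to-centre) of the nearest protected cell centre. The
#' buffer never overlaps the protected mask; downstream analyses intersect it
#' with the forest mask.
#'
#' @param protected logical matrix or [ds_grid()].
#' @param distance_m buffer width in metres (> 0); typically
#'   `mbr_diagonal(protected)`.
#' @param cell_size_m cell size (m) when `protected` is a bare matrix.
#' @return logical matrix.
#' @export
build_buffer <- function(protected, distance_m, cell_size_m = 30) {
  if (distance_m <= 0) stop("`distance_m` must be positive")
  m <- grid_values(protected)
  prot <- m != 0 & !is.na(m)
  if (all(prot)) {
    warning("protected mask covers the whole grid: buffer is empty")
    return(matrix(FALSE, nrow(m), ncol(m)))
  }
  d <- distance_to_mask(prot, grid_cell_size(protected, cell_size_m))
  buf <- !prot & d <= distance_m
  buf
}
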