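## Multilevel B-spline approximation (MBA) of scattered data.
##
## A hierarchy of uniform cubic tensor-product B-spline control lattices is
## fitted coarse-to-fine; each level fits the residuals left by the previous
## levels with the local least-squares "BA" update, and the fitted surface
## is the sum over levels. Control points that no data point touches stay at
## zero, so far extrapolation decays smoothly toward zero.

## Cubic uniform B-spline basis at local coordinate s in [0, 1].
bspline_basis <- function(s) {
  rbind((1 - s)^3 / 6,
        (3 * s^3 - 6 * s^2 + 4) / 6,
        (-3 * s^3 + 3 * s^2 + 3 * s + 1) / 6,
        s^3 / 6)
}

## Cell index and local coordinate for positions u in [0, 1] over m cells.
## u = 1 falls in the last cell with s = 1 so evaluation stays defined on
## the closed unit interval.
cell_coord <- function(u, m) {
  i <- pmin(floor(u * m), m - 1)
  list(i = i, s = u * m - i)
}

#' Fit a single B-spline control lattice to scattered data (BA update)
#'
#' One level of the multilevel scheme: for every data point the 4 x 4
#' neighbourhood of control points receives a candidate coefficient
#' `w * z / sum(w^2)` (with `w` the tensor B-spline weights at the point),
#' and each lattice coefficient is the weighted average
#' `sum(w^2 * candidate) / sum(w^2)` over all contributing points.
#' Coefficients with no contributing point are zero. A single data point is
#' reproduced exactly by this update (algebraic identity).
#'
#' @param x,y Point coordinates in the unit square.
#' @param z Values at the points.
#' @param m,n Number of lattice cells along x and y (>= 1). The lattice has
#'   `(m + 3) x (n + 3)` control points (one-cell margin each side, as cubic
#'   B-splines require).
#' @return `(m + 3) x (n + 3)` matrix of control coefficients.
#' @export
ba_fit <- function(x, y, z, m, n = m) {
  stopifnot(length(x) == length(y), length(x) == length(z), m >= 1, n >= 1)
  if (any(x < 0 | x > 1 | y < 0 | y > 1))
    stop("points must lie in the unit square")
  if (any(!is.finite(z))) stop("values must be finite")
  cx <- cell_coord(x, m); cy <- cell_coord(y, n)
  Bx <- bspline_basis(cx$s)   # 4 x N
  By <- bspline_basis(cy$s)
  N <- length(x)
  ## sum of squared tensor weights per point
  sw2 <- colSums(Bx^2) * colSums(By^2)
  num <- matrix(0, m + 3, n + 3)
  den <- matrix(0, m + 3, n + 3)
  nrow_phi <- m + 3
  for (k in 1:4) {
    for (l in 1:4) {
      w <- Bx[k, ] * By[l, ]
      idx <- (cx$i + k) + (cy$i + l - 1) * nrow_phi   # 1-based linear index
      w2 <- w^2
      contrib <- rowsum(cbind(w2 * (w * z / sw2), w2), idx)
      at <- as.integer(rownames(contrib))
      num[at] <- num[at] + contrib[, 1]
      den[at] <- den[at] + contrib[, 2]
    }
  }
  phi <- num
  nz <- den > 0
  phi[nz] <- num[nz] / den[nz]
  phi
}

## Evaluate one control lattice at unit-square positions.
eval_lattice <- function(phi, m, n, x, y) {
  cx <- cell_coord(x, m); cy <- cell_coord(y, n)
  Bx <- bspline_basis(cx$s)
  By <- bspline_basis(cy$s)
  out <- numeric(length(x))
  nrow_phi <- m + 3
  for (k in 1:4) {
    for (l in 1:4) {
      idx <- (cx$i + k) + (cy$i + l - 1) * nrow_phi
      out <- out + Bx[k, ] * By[l, ] * phi[idx]
    }
  }
  out
}

#' Multilevel B-spline approximation of scattered data
#'
#' Coarse-to-fine fit: level 1 applies [ba_fit()] on the data over a
#' `base_resolution`-cell lattice; each subsequent level doubles the lattice
#' resolution and fits the residuals at the data points; the fitted surface
#' is the sum of all levels. Residual magnitude at the data points is
#' non-increasing across levels and, for smooth fields, drops below
#' `1e-6` of the data range within about five or six levels.
#'
#' @param x,y Coordinates. Either already in the unit square, or in
#'   longitude/latitude together with `bbox`, in which case they are
#'   normalized via [normalize_coords()] and predictions accept lon/lat.
#' @param z Values to approximate.
#' @param n_levels Number of levels (>= 1). Levels are capped so the finest
#'   cell is no smaller than 1e-6 of the domain (error otherwise).
#' @param base_resolution Cells along each axis of the coarsest lattice.
#' @param bbox Optional `c(lon_min, lon_max, lat_min, lat_max)`; see above.
#' @return Object of class `"mbs_surface"`: list of per-level control
#'   lattices plus the normalization record (or `NULL`).
#' @examples
#' set.seed(1)
#' x <- runif(50); y <- runif(50)
#' z <- sin(2 * pi * x) + y^2
#' s <- mbs_fit(x, y, z, n_levels = 6)
#' max(abs(predict(s, x, y) - z))   # small residual at the data
#' @export
mbs_fit <- function(x, y, z, n_levels = 6, base_resolution = 4, bbox = NULL) {
  if (n_levels < 1) stop("n_levels must be >= 1")
  norm <- NULL
  if (!is.null(bbox)) {
    nc <- normalize_coords(x, y, bbox)
    x <- nc$x; y <- nc$y; norm <- nc$norm
  }
  if (length(x) < 1) stop("need at least one point")
  finest <- base_resolution * 2^(n_levels - 1)
  if (1 / finest < 1e-6)
    stop("resolution limit: finest lattice cell smaller than 1e-6 of domain")
  resid <- z
  levels <- vector("list", n_levels)
  m <- base_resolution
  for (lev in seq_len(n_levels)) {
    phi <- ba_fit(x, y, resid, m, m)
    resid <- resid - eval_lattice(phi, m, m, x, y)
    levels[[lev]] <- list(m = m, n = m, phi = phi)
    m <- m * 2
  }
  structure(list(levels = levels, base_resolution = base_resolution,
                 n_levels = n_levels, norm = norm,
                 max_data_resid = max(abs(resid))),
            class = "mbs_surface")
}

#' @export
print.mbs_surface <- function(x, ...) {
  cat(sprintf("Multilevel B-spline surface: %d levels, base %d cells, finest %d cells\n",
              x$n_levels, x$base_resolution,
              x$base_resolution * 2^(x$n_levels - 1)))
  cat(sprintf("  max |residual| at data points: %.3g\n", x$max_data_resid))
  if (!is.null(x$norm))
    cat(sprintf("  domain: lon [%.4f, %.4f], lat [%.4f, %.4f]\n",
                x$norm$bbox[1], x$norm$bbox[2], x$norm$bbox[3], x$norm$bbox[4]))
  invisible(x)
}

#' Evaluate a multilevel B-spline surface at points
#'
#' Deterministic tensor B-spline evaluation summed over levels. Queries
#' outside the fitted domain are still evaluated (the surface decays toward
#' zero away from the data) but flagged in the `"outside"` attribute.
#'
#' @param object An `"mbs_surface"`.
#' @param x,y Query coordinates: lon/lat if the surface was fitted with a
#'   `bbox`, unit-square otherwise.
#' @param ... Unused.
#' @return Numeric vector of surface values with logical attribute
#'   `"outside"` marking extrapolated queries.
#' @export
predict.mbs_surface <- function(object, x, y, ...) {
  if (!is.null(object$norm)) {
    nc <- normalize_coords(x, y, object$norm$bbox)
    x <- nc$x; y <- nc$y
  }
  outside <- x < 0 | x > 1 | y < 0 | y > 1
  xc <- pmin(pmax(x, 0), 1)
  yc <- pmin(pmax(y, 0), 1)
  out <- numeric(length(xc))
  for (lev in object$levels)
    out <- out + eval_lattice(lev$phi, lev$m, lev$n, xc, yc)
  attr(out, "outside") <- outside
  out
}

#' Map longitude/latitude to the unit square
#'
#' Affine, invertible map of a lon/lat bounding box onto the unit square.
#' Longitudes are scaled by `cos(mean latitude)` first (local planar
#' metric), so the recorded `aspect` ratio (metric width / height) reflects
#' true ground distances; at mid-latitudes a box square in degrees is
#' noticeably wider than tall in degrees per kilometre.
#'
#' @param lon,lat Coordinate vectors.
#' @param bbox `c(lon_min, lon_max, lat_min, lat_max)` with positive extent.
#' @return List with `x`, `y` in the unit square and the normalization
#'   record `norm` (bbox, mean latitude, metric aspect ratio).
#' @export
normalize_coords <- function(lon, lat, bbox) {
  if (length(bbox) != 4 || bbox[2] <= bbox[1] || bbox[4] <= bbox[3])
    stop("invalid extent: bbox must be c(lon_min, lon_max, lat_min, lat_max)")
  mean_lat <- mean(bbox[3:4])
  coslat <- cos(mean_lat * pi / 180)
  width <- (bbox[2] - bbox[1]) * coslat
  height <- bbox[4] - bbox[3]
  list(x = (lon - bbox[1]) * coslat / width,
       y = (lat - bbox[3]) / height,
       norm = list(bbox = bbox, mean_lat = mean_lat,
                   coslat = coslat, aspect = width / height))
}

#' Invert [normalize_coords()]
#'
#' @param x,y Unit-square coordinates.
#' @param norm Normalization record from [normalize_coords()].
#' @return List with `lon`, `lat`.
#' @export
denormalize_coords <- function(x, y, norm) {
  list(lon = norm$bbox[1] + x * (norm$bbox[2] - norm$bbox[1]),
       lat = norm$bbox[3] + y * (norm$bbox[4] - norm$bbox[3]))
}

#' Regular lon/lat raster
#'
#' Container for an interpolated ratio or dose field on a regular grid.
#' `values` is an `nrows x ncols` matrix whose first row is the
#' northernmost; `xll`/`yll` locate the south-west corner of the raster
#' (cell edges, not centres), matching the plain-text ESRI ASCII grid
#' dialect used by [write_esri_ascii()].
#'
#' @param xll,yll South-west corner (degrees).
#' @param cellsize Cell size (degrees, > 0).
#' @param values Matrix `nrows x ncols`, row 1 = north. `NA` entries are
#'   written as the nodata sentinel.
#' @param nodata Missing-value sentinel (default -9999).
#' @return Object of class `"grid_field"`.
#' @export
grid_field <- function(xll, yll, cellsize, values, nodata = -9999) {
  stopifnot(is.matrix(values), cellsize > 0)
  structure(list(xll = xll, yll = yll, cellsize = cellsize,
                 ncols = ncol(values), nrows = nrow(values),
                 values = values, nodata = nodata),
            class = "grid_field")
}

#' @export
print.grid_field <- function(x, ...) {
  cat(sprintf("grid_field: %d cols x %d rows, cell %g deg, SW corner (%g, %g)\n",
              x$ncols, x$nrows, x$cellsize, x$xll, x$yll))
  v <- x$values[is.finite(x$values)]
  if (length(v))
    cat(sprintf("  values: [%.4g, %.4g], %d missing\n",
                min(v), max(v), sum(!is.finite(x$values))))
  invisible(x)
}

## Cell-centre coordinates of a grid_field; row 1 = north.
grid_centres <- function(field) {
  lon <- field$xll + (seq_len(field$ncols) - 0.5) * field$cellsize
  lat <- field$yll + (field$nrows - seq_len(field$nrows) + 0.5) * field$cellsize
  list(lon = lon, lat = lat)
}

#' Evaluate a surface onto a regular lon/lat grid
#'
#' Evaluates an `"mbs_surface"` (fitted with a bbox) at the cell centres of
#' a regular grid covering the surface's bounding box.
#'
#' @param surface An `"mbs_surface"` with a normalization record.
#' @param ncols,nrows Grid dimensions. If `nrows` is `NULL` it is chosen
#'   from the metric aspect ratio so cells are approximately square on the
#'   ground.
#' @return A [grid_field()].
#' @export
evaluate_grid <- function(surface, ncols = 100, nrows = NULL) {
  if (is.null(surface$norm))
    stop("surface was fitted in the unit square; no geographic extent known")
  bbox <- surface$norm$bbox
  if (is.null(nrows))
    nrows <- max(2L, as.integer(round(ncols / surface$norm$aspect)))
  cellsize_x <- (bbox[2] - bbox[1]) / ncols
  cellsize_y <- (bbox[4] - bbox[3]) / nrows
  ## one common cellsize keeps the raster square-celled in degrees; cover
  ## the box with the larger of the two
  cellsize <- max(cellsize_x, cellsize_y)
  ncols <- as.integer(ceiling((bbox[2] - bbox[1]) / cellsize))
  nrows <- as.integer(ceiling((bbox[4] - bbox[3]) / cellsize))
  lon <- bbox[1] + (seq_len(ncols) - 0.5) * cellsize
  lat <- bbox[3] + (nrows - seq_len(nrows) + 0.5) * cellsize
  pts <- expand.grid(lat = lat, lon = lon)   # column-major: rows vary first
  vals <- predict(surface, pts$lon, pts$lat)
  grid_field(bbox[1], bbox[3], cellsize,
             matrix(as.numeric(vals), nrow = nrows, ncol = ncols))
}

#' Fill missing Te-129m/Cs-137 ratios by spatial interpolation
#'
#' Fits a multilevel B-spline surface to the records that carry a measured
#' (decay-corrected) `r_t`, evaluates it at the records where `r_t` is
#' missing, and returns both the completed records and the interpolated
#' raster. Interpolated values below zero are clamped to zero (count
#' reported); measured values are never altered.
#'
#' @param records `data.frame` with columns `lon`, `lat`, `r_t` (`NA` where
#'   missing).
#' @param bbox Bounding box; defaults to the records' extent padded by 5\%.
#' @param n_levels,base_resolution Passed to [mbs_fit()].
#' @param ncols Raster width for the returned field.
#' @return List: `records` (with `r_t` filled and a character column
#'   `r_t_origin`, `"measured"` or `"interpolated"`), `field` (a
#'   [grid_field()]), `surface`, `n_clamped`.
#' @export
interpolate_missing_ratios <- function(records, bbox = NULL,
                                       n_levels = 6, base_resolution = 4,
                                       ncols = 100) {
  stopifnot(all(c("lon", "lat", "r_t") %in% names(records)))
  measured <- !is.na(records$r_t)
  if (!any(measured))
    stop("cannot interpolate: no record carries a measured r_t")
  if (is.null(bbox)) {
    padx <- diff(range(records$lon)) * 0.05 + 1e-6
    pady <- diff(range(records$lat)) * 0.05 + 1e-6
    bbox <- c(min(records$lon) - padx, max(records$lon) + padx,
              min(records$lat) - pady, max(records$lat) + pady)
  }
  surface <- mbs_fit(records$lon[measured], records$lat[measured],
                     records$r_t[measured],
                     n_levels = n_levels, base_resolution = base_resolution,
                     bbox = bbox)
  records$r_t_origin <- ifelse(measured, "measured", "interpolated")
  n_clamped <- 0L
  if (any(!measured)) {
    fill <- predict(surface, records$lon[!measured], records$lat[!measured])
    fill <- as.numeric(fill)
    n_clamped <- sum(fill < 0)
    if (n_clamped > 0) {
      bd_log("clamped %d negative interpolated r_t value(s) to 0", n_clamped)
      fill[fill < 0] <- 0
    }
    records$r_t[!measured] <- fill
  }
  field <- evaluate_grid(surface, ncols = ncols)
  field$values[field$values < 0] <- 0
  list(records = records, field = field, surface = surface,
       n_clamped = n_clamped)
}

#' Write a raster in the ESRI ASCII grid dialect
#'
#' Plain-text raster: six header lines (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`, each followed by a single space
#' and the value) and then one line per row, north to south, values
#' space-separated with up to 10 significant digits. `NA` cells are written
#' as the nodata sentinel.
#'
#' @param field A [grid_field()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(field, path) {
  stopifnot(inherits(field, "grid_field"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", field$ncols),
               sprintf("nrows %d", field$nrows),
               sprintf("xllcorner %.10g", field$xll),
               sprintf("yllcorner %.10g", field$yll),
               sprintf("cellsize %.10g", field$cellsize),
               sprintf("NODATA_value %.10g", field$nodata)), con)
  v <- field$values
  v[!is.finite(v)] <- field$nodata
  writeLines(apply(v, 1, function(row) paste(sprintf("%.10g", row),
                                             collapse = " ")), con)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File written by [write_esri_ascii()] (or any conforming
#'   ESRI ASCII raster).
#' @return A [grid_field()] with nodata cells set to `NA`.
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  vals <- do.call(rbind, lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  vals[vals == hdr$nodata_value] <- NA
  grid_field(hdr$xllcorner, hdr$yllcorner, hdr$cellsize, vals,
             nodata = hdr$nodata_value)
}
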