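# Gridded climate fields and the post-glacial anomaly / change-velocity chain.

#' Construct a climate grid
#'
#' A regular raster of one climate variable for one epoch.  Values are stored
#' north-up (first row = northernmost cells); \code{NA} marks nodata cells.
#'
#' @param values numeric matrix, north-up.
#' @param cellsize cell size, in \code{units}.
#' @param xll,yll coordinates of the lower-left corner of the grid.
#' @param units \code{"km"} for a projected grid or \code{"degrees"} for a
#'   geographic lon/lat grid.  Spatial gradients on degree grids are converted
#'   to per-km using 111.32 km per degree and a cos(latitude) correction on
#'   the east-west span.
#' @param variable,epoch optional metadata tags (e.g. \code{"MAT"},
#'   \code{"current"}).
#' @param nodata sentinel written to/read from ESRI ASCII files.
#' @return An object of class \code{climate_grid}.
#' @export
climate_grid <- function(values, cellsize, xll = 0, yll = 0,
                         units = c("km", "degrees"),
                         variable = NA_character_, epoch = NA_character_,
                         nodata = -9999) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  units <- match.arg(units)
  if (nrow(values) < 3 || ncol(values) < 3)
    stop("climate grid must be at least 3 x 3 cells")
  if (!is.numeric(cellsize) || cellsize <= 0) stop("cellsize must be > 0")
  if (any(!is.finite(values) & !is.na(values)))
    stop("non-finite values in grid (use NA for nodata)")
  structure(list(values = values, cellsize = cellsize, xll = xll, yll = yll,
                 units = units, variable = variable, epoch = epoch,
                 nodata = nodata),
            class = "climate_grid")
}

#' @export
print.climate_grid <- function(x, ...) {
  cat(sprintf("Climate grid [%s, %s]: %d x %d cells, cellsize %g %s, origin (%g, %g), %d nodata\n",
              x$variable, x$epoch, nrow(x$values), ncol(x$values),
              x$cellsize, x$units, x$xll, x$yll, sum(is.na(x$values))))
  invisible(x)
}

KM_PER_DEGREE <- 111.32

check_registered <- function(a, b, what = "grids") {
  if (!identical(dim(a$values), dim(b$values)))
    stop(what, " are not co-registered: dimensions differ")
  if (abs(a$cellsize - b$cellsize) > 1e-9 ||
      abs(a$xll - b$xll) > 1e-9 || abs(a$yll - b$yll) > 1e-9 ||
      !identical(a$units, b$units))
    stop(what, " are not co-registered: cell size, origin or units differ")
  invisible(TRUE)
}

#' Cell-wise mean of several co-registered grids
#'
#' Used to average the LGM fields of several paleoclimate general circulation
#' models into one consensus field.  A cell is nodata in the output iff it is
#' nodata in any input.
#'
#' @param grids list of at least two co-registered \code{climate_grid}s of the
#'   same variable and epoch.
#' @return A \code{climate_grid}.
#' @export
multi_model_mean <- function(grids) {
  if (!is.list(grids) || length(grids) < 2)
    stop("need at least two grids to average")
  g1 <- grids[[1]]
  for (g in grids[-1]) {
    check_registered(g1, g)
    if (!is.na(g1$variable) && !is.na(g$variable) && !identical(g1$variable, g$variable))
      stop("grids measure different variables")
    if (!is.na(g1$epoch) && !is.na(g$epoch) && !identical(g1$epoch, g$epoch))
      stop("grids are from different epochs")
  }
  vals <- Reduce(`+`, lapply(grids, `[[`, "values")) / length(grids)
  out <- g1
  out$values <- vals
  out
}

#' Temporal climate anomaly between two epochs
#'
#' Cell-wise \code{current - past}; with mean annual temperature this is the
#' temperature anomaly since the Last Glacial Maximum.
#'
#' @param current,past co-registered grids of the same variable.
#' @return A \code{climate_grid} tagged \code{epoch = "anomaly"}.
#' @export
grid_anomaly <- function(current, past) {
  check_registered(current, past)
  if (!is.na(current$variable) && !is.na(past$variable) &&
      !identical(current$variable, past$variable))
    stop("anomaly requires grids of the same variable")
  out <- current
  out$values <- current$values - past$values
  out$epoch <- "anomaly"
  out
}

#' Magnitude of the local spatial climate gradient
#'
#' Central differences over the four rook neighbours of each interior cell:
#' \code{sqrt(((E - W) / (2 dx))^2 + ((N - S) / (2 dy))^2)}, in variable units
#' per km.  Edge cells, and cells with any nodata neighbour, are nodata.
#'
#' @param grid a \code{climate_grid} (at least 3 x 3).
#' @return A \code{climate_grid} of gradient magnitudes.
#' @export
spatial_gradient <- function(grid) {
  v <- grid$values
  ny <- nrow(v); nx <- ncol(v)
  if (ny < 3 || nx < 3) stop("gradient stencil needs at least 3 x 3 cells")
  if (identical(grid$units, "degrees")) {
    dy <- grid$cellsize * KM_PER_DEGREE
    # latitude of each row's cell centres (row 1 is northernmost)
    lat <- grid$yll + (ny - seq_len(ny) + 0.5) * grid$cellsize
    dx <- grid$cellsize * KM_PER_DEGREE * cos(lat * pi / 180)
  } else {
    dy <- grid$cellsize
    dx <- rep(grid$cellsize, ny)
  }
  out <- matrix(NA_real_, ny, nx)
  i <- 2:(ny - 1); j <- 2:(nx - 1)
  gx <- (v[i, j + 1] - v[i, j - 1]) / (2 * dx[i])
  gy <- (v[i - 1, j] - v[i + 1, j]) / (2 * dy)
  out[i, j] <- sqrt(gx^2 + gy^2)
  res <- grid
  res$values <- out
  res
}

#' Climate-change velocity
#'
#' The temporal anomaly divided by the local spatial gradient: the
#' displacement (km) needed to keep the variable constant over the epoch
#' contrast.  The anomaly enters as a magnitude; a gradient floor prevents
#' infinite velocities on flat terrain.
#'
#' @param anom anomaly grid (variable units).
#' @param grad spatial-gradient grid (variable units per km).
#' @param floor positive gradient floor (variable units per km).
#' @return A \code{climate_grid} of velocities in km.
#' @export
change_velocity <- function(anom, grad, floor = 1e-6) {
  if (!is.numeric(floor) || floor <= 0) stop("gradient floor must be > 0")
  check_registered(anom, grad)
  out <- anom
  out$values <- abs(anom$values) / pmax(grad$values, floor)
  out$epoch <- "velocity"
  out
}

# Row/column of the cell containing (x, y); errors name the offending site.
grid_cell_index <- function(grid, x, y, site) {
  ny <- nrow(grid$values); nx <- ncol(grid$values)
  fx <- (x - grid$xll) / grid$cellsize
  fy <- (y - grid$yll) / grid$cellsize
  if (fx < 0 || fx > nx || fy < 0 || fy > ny)
    stop(sprintf("site '%s' falls outside the grid extent", site))
  col <- min(floor(fx) + 1, nx)
  row_from_bottom <- min(floor(fy) + 1, ny)
  c(row = ny - row_from_bottom + 1, col = col)
}

extract_cells <- function(grid, x, y, sites, what = "grid") {
  vapply(seq_along(x), function(k) {
    idx <- grid_cell_index(grid, x[k], y[k], sites[k])
    val <- grid$values[idx["row"], idx["col"]]
    if (is.na(val))
      stop(sprintf("site '%s' falls on a nodata cell of the %s", sites[k], what))
    val
  }, numeric(1))
}

#' Derive the four historical predictors at site locations
#'
#' From co-registered current and LGM grids of temperature and precipitation,
#' computes per site: the signed anomalies TA and PA, the raw change
#' velocities (km), and their log-transformed versions TCV and PCV.
#'
#' @param current_t,lgm_t,current_p,lgm_p co-registered \code{climate_grid}s.
#' @param sites data frame with columns \code{site}, \code{x}, \code{y}
#'   (coordinates in the grids' units; lon/lat for degree grids).
#' @param log_base base of the velocity log transform (default 10).
#' @param log_offset pseudo-offset added to raw velocities before the log
#'   (default 0; an error is raised if any raw velocity + offset is <= 0).
#' @param gradient_floor floor for the spatial gradient (units per km).
#' @param per_year if \code{TRUE}, scale velocities to km per year by dividing
#'   by the 21,000-year epoch contrast; default reports the full-epoch
#'   displacement.
#' @return Data frame with columns \code{site, TA, PA, raw_TCV, raw_PCV, TCV,
#'   PCV}; the transform parameters are recorded as attributes.
#' @export
derive_historical <- function(current_t, lgm_t, current_p, lgm_p, sites,
                              log_base = 10, log_offset = 0,
                              gradient_floor = 1e-6, per_year = FALSE) {
  stopifnot(is.data.frame(sites), all(c("site", "x", "y") %in% names(sites)))
  check_registered(current_t, lgm_t, "temperature grids")
  check_registered(current_p, lgm_p, "precipitation grids")
  check_registered(current_t, current_p, "temperature and precipitation grids")

  ta_grid <- grid_anomaly(current_t, lgm_t)
  pa_grid <- grid_anomaly(current_p, lgm_p)
  tv_grid <- change_velocity(ta_grid, spatial_gradient(current_t), gradient_floor)
  pv_grid <- change_velocity(pa_grid, spatial_gradient(current_p), gradient_floor)

  sid <- as.character(sites$site)
  ta <- extract_cells(ta_grid, sites$x, sites$y, sid, "temperature anomaly grid")
  pa <- extract_cells(pa_grid, sites$x, sites$y, sid, "precipitation anomaly grid")
  tv <- extract_cells(tv_grid, sites$x, sites$y, sid, "temperature velocity grid")
  pv <- extract_cells(pv_grid, sites$x, sites$y, sid, "precipitation velocity grid")
  if (per_year) {
    tv <- tv / 21000
    pv <- pv / 21000
  }
  if (any(tv + log_offset <= 0) || any(pv + log_offset <= 0))
    stop("raw velocity + log_offset <= 0 at some site; increase 'log_offset'")
  out <- data.frame(site = sid, TA = ta, PA = pa,
                    raw_TCV = tv, raw_PCV = pv,
                    TCV = log(tv + log_offset, base = log_base),
                    PCV = log(pv + log_offset, base = log_base),
                    stringsAsFactors = FALSE)
  attr(out, "log_base") <- log_base
  attr(out, "log_offset") <- log_offset
  attr(out, "gradient_floor") <- gradient_floor
  attr(out, "per_year") <- per_year
  out
}

#' Read an ESRI ASCII grid
#'
#' @param path path to a \code{.asc} file (6-line header, north-up rows).
#' @inheritParams climate_grid
#' @return A \code{climate_grid}.
#' @export
read_ascii_grid <- function(path, units = "km", variable = NA_character_,
                            epoch = NA_character_) {
  lines <- readLines(path, n = 6)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  req <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(req %in% names(hdr)))
    stop("not an ESRI ASCII grid: missing header field(s) ",
         paste(setdiff(req, names(hdr)), collapse = ", "))
  nodata <- hdr[["nodata_value"]] %||% -9999
  vals <- scan(path, skip = 6, quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("grid body has ", length(vals), " values, expected ",
         hdr$ncols * hdr$nrows)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  climate_grid(m, cellsize = hdr$cellsize, xll = hdr$xllcorner,
               yll = hdr$yllcorner, units = units, variable = variable,
               epoch = epoch, nodata = nodata)
}

#' Write a climate grid as ESRI ASCII
#'
#' @param grid a \code{climate_grid}.
#' @param path output path.
#' @export
write_ascii_grid <- function(grid, path) {
  v <- grid$values
  v[is.na(v)] <- grid$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(v)),
    paste("nrows", nrow(v)),
    paste("xllcorner", format(grid$xll, digits = 15)),
    paste("yllcorner", format(grid$yll, digits = 15)),
    paste("cellsize", format(grid$cellsize, digits = 15)),
    paste("NODATA_value", format(grid$nodata, digits = 15))
  ), con)
  utils::write.table(format(v, digits = 15, trim = TRUE, scientific = FALSE),
                     con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
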