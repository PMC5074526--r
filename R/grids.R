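# Raster data model shared by all spatial stages: a lon/lat grid of square
# cells, layers of values with a nodata mask, and stacks of co-registered
# layers. Internal row order is row 1 = northernmost (the ESRI ASCII layout);
# cells are half-open, so a point on an edge belongs to the cell with index
# floor((coord - origin) / cell_size).

#' Define a lon/lat grid
#'
#' A `grid_spec` describes a regular grid of square cells in geographic
#' coordinates: its dimensions, the lower-left corner, the cell size in
#' degrees, and the nodata sentinel used on disk. Every layer, stack,
#' occurrence set and map in the package is bound to one of these.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param x_min,y_min Coordinates of the lower-left grid corner, in degrees.
#' @param cell_size Cell edge length in degrees; cells are square.
#' @param nodata Sentinel value written for masked cells in ASCII output.
#' @return An object of class `grid_spec`.
#' @examples
#' spec <- grid_spec(60, 60, x_min = -120, y_min = 40, cell_size = 1/3)
#' spec
#' @export
grid_spec <- function(n_rows, n_cols, x_min, y_min, cell_size, nodata = -9999) {
  if (length(n_rows) != 1L || n_rows < 1 || n_rows != round(n_rows))
    stop("n_rows must be a positive integer")
  if (length(n_cols) != 1L || n_cols < 1 || n_cols != round(n_cols))
    stop("n_cols must be a positive integer")
  if (!is.finite(cell_size) || cell_size <= 0)
    stop("cell_size must be > 0")
  x_max <- x_min + n_cols * cell_size
  y_max <- y_min + n_rows * cell_size
  tol <- 1e-9
  if (x_min < -180 - tol || x_max > 180 + tol)
    stop("grid exceeds longitude range [-180, 180]")
  if (y_min < -90 - tol || y_max > 90 + tol)
    stop("grid exceeds latitude range [-90, 90]")
  structure(list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max,
    cell_size = cell_size, nodata = nodata
  ), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d rows x %d cols, cell %g deg\n",
              x$n_rows, x$n_cols, x$cell_size))
  cat(sprintf("  lon [%g, %g], lat [%g, %g], nodata %g\n",
              x$x_min, x$x_max, x$y_min, x$y_max, x$nodata))
  invisible(x)
}

same_spec <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$x_min - b$x_min) < tol && abs(a$y_min - b$y_min) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}

#' Construct a raster layer
#'
#' A `grid_layer` holds one variable on a [grid_spec()]: an `n_rows` by
#' `n_cols` numeric matrix whose first row is the northernmost, with `NA`
#' marking nodata cells. Nodata cells are excluded from all statistics.
#'
#' @param spec A [grid_spec()].
#' @param values Numeric matrix (`n_rows` x `n_cols`) or vector of length
#'   `n_rows * n_cols` filled row-wise from the north; `NA` = nodata.
#' @param name Layer name (used for stacking and file naming).
#' @return An object of class `grid_layer`.
#' @export
grid_layer <- function(spec, values, name = "layer") {
  stopifnot(inherits(spec, "grid_spec"))
  if (!is.matrix(values))
    values <- matrix(as.numeric(values), nrow = spec$n_rows,
                     ncol = spec$n_cols, byrow = TRUE)
  if (nrow(values) != spec$n_rows || ncol(values) != spec$n_cols)
    stop(sprintf("values are %d x %d but spec is %d x %d",
                 nrow(values), ncol(values), spec$n_rows, spec$n_cols))
  storage.mode(values) <- "double"
  structure(list(spec = spec, name = as.character(name), values = values),
            class = "grid_layer")
}

#' @export
print.grid_layer <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<grid_layer> '%s' on %d x %d grid; %d valid cells",
              x$name, x$spec$n_rows, x$spec$n_cols, length(v)))
  if (length(v))
    cat(sprintf("; range [%g, %g]", min(v), max(v)))
  cat("\n")
  invisible(x)
}

#' @export
plot.grid_layer <- function(x, main = x$name, ...) {
  s <- x$spec
  # image() draws row 1 at the bottom; flip so north is up
  z <- t(x$values[s$n_rows:1, , drop = FALSE])
  graphics::image(
    x = s$x_min + (seq_len(s$n_cols) - 0.5) * s$cell_size,
    y = s$y_min + (seq_len(s$n_rows) - 0.5) * s$cell_size,
    z = z, xlab = "longitude", ylab = "latitude", main = main,
    col = grDevices::hcl.colors(64, "viridis"), useRaster = TRUE, ...)
  invisible(x)
}

#' Stack co-registered layers
#'
#' A `climate_stack` is an ordered, uniquely named collection of
#' [grid_layer()]s sharing one [grid_spec()] (climate and any extra raster
#' covariates such as soil properties). When cell vectors are extracted for
#' modelling, the joint nodata mask (union over layers) is applied.
#'
#' @param layers A list of `grid_layer` objects (or several passed via `...`).
#' @param ... Additional layers.
#' @return An object of class `climate_stack`.
#' @export
climate_stack <- function(layers, ...) {
  if (inherits(layers, "grid_layer")) layers <- list(layers)
  layers <- c(layers, list(...))
  if (!length(layers)) stop("a climate_stack needs at least one layer")
  if (!all(vapply(layers, inherits, TRUE, "grid_layer")))
    stop("all elements must be grid_layer objects")
  spec <- layers[[1L]]$spec
  for (l in layers[-1L])
    if (!same_spec(spec, l$spec))
      stop(sprintf("layer '%s' is not on the same grid as '%s'",
                   l$name, layers[[1L]]$name))
  nms <- vapply(layers, `[[`, "", "name")
  if (anyDuplicated(nms))
    stop("duplicate layer names: ", paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(layers) <- nms
  structure(list(spec = spec, layers = layers), class = "climate_stack")
}

#' @export
print.climate_stack <- function(x, ...) {
  cat(sprintf("<climate_stack> %d layers on %d x %d grid\n",
              length(x$layers), x$spec$n_rows, x$spec$n_cols))
  cat("  ", paste(names(x$layers), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
`[[.climate_stack` <- function(x, i) x$layers[[i]]

#' @export
names.climate_stack <- function(x) names(x$layers)

#' Extract the cell-by-variable matrix of a stack
#'
#' Returns the values of every layer for the requested cells as a matrix with
#' one column per layer. Cell ids are R column-major indices into the layer
#' matrix (row 1 = north).
#'
#' @param stack A [climate_stack()].
#' @param cells Integer cell ids; default all cells.
#' @return Numeric matrix `length(cells)` x `n_layers` with layer names as
#'   column names; rows with any masked layer contain `NA`.
#' @export
stack_matrix <- function(stack, cells = NULL) {
  stopifnot(inherits(stack, "climate_stack"))
  if (is.null(cells)) cells <- seq_len(stack$spec$n_rows * stack$spec$n_cols)
  m <- vapply(stack$layers, function(l) l$values[cells], numeric(length(cells)))
  if (!is.matrix(m)) m <- matrix(m, nrow = length(cells),
                                 dimnames = list(NULL, names(stack$layers)))
  m
}

#' Cell ids valid in every layer of a stack
#'
#' @param stack A [climate_stack()].
#' @return Integer vector of cell ids finite across all layers (the
#'   complement of the joint nodata mask).
#' @export
valid_cells <- function(stack) {
  ok <- is.finite(stack$layers[[1L]]$values)
  for (l in stack$layers[-1L]) ok <- ok & is.finite(l$values)
  which(ok)
}

#' Map lon/lat points to grid cells
#'
#' Cells are half-open: a point maps to the cell with column
#' `floor((lon - x_min)/cell_size)` and row counted from the top. Points
#' outside the grid (including on the top/right outer edges) get `NA`.
#'
#' @param spec A [grid_spec()].
#' @param lon,lat Coordinate vectors in degrees.
#' @return Integer vector of cell ids (column-major), `NA` for points off-grid.
#' @export
cell_of <- function(spec, lon, lat) {
  stopifnot(inherits(spec, "grid_spec"))
  col <- floor((lon - spec$x_min) / spec$cell_size) + 1
  row_from_south <- floor((lat - spec$y_min) / spec$cell_size) + 1
  row <- spec$n_rows - row_from_south + 1
  ok <- !is.na(col) & !is.na(row) &
    col >= 1 & col <= spec$n_cols & row >= 1 & row <= spec$n_rows
  out <- rep(NA_integer_, length(lon))
  out[ok] <- as.integer((col[ok] - 1) * spec$n_rows + row[ok])
  out
}

#' Cell-centre coordinates
#'
#' @param spec A [grid_spec()].
#' @param cells Integer cell ids; default all.
#' @return Data frame with columns `lon`, `lat` of cell centres.
#' @export
cell_centers <- function(spec, cells = NULL) {
  if (is.null(cells)) cells <- seq_len(spec$n_rows * spec$n_cols)
  row <- (cells - 1L) %% spec$n_rows + 1L
  col <- (cells - 1L) %/% spec$n_rows + 1L
  data.frame(lon = spec$x_min + (col - 0.5) * spec$cell_size,
             lat = spec$y_max - (row - 0.5) * spec$cell_size)
}

#' Read an ESRI ASCII grid
#'
#' Parses the standard header (`NCOLS`, `NROWS`, `XLLCORNER`, `YLLCORNER`,
#' `CELLSIZE`, optional `NODATA_value`) followed by `NROWS * NCOLS`
#' whitespace-separated values, row 1 being the northernmost. Nodata cells
#' become `NA`. Only square cells are accepted (`DX`/`DY` headers are
#' rejected rather than silently resampled).
#'
#' @param path Path to the `.asc` file.
#' @param name Layer name; defaults to the file stem.
#' @return A [grid_layer()].
#' @export
read_ascii_grid <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 0L
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(tok) == 2L && grepl("^[A-Za-z_]", tok[1L]) &&
        !is.na(suppressWarnings(as.numeric(tok[2L])))) {
      hdr[[tolower(tok[1L])]] <- as.numeric(tok[2L])
      i <- i + 1L
    } else break
  }
  if (any(c("dx", "dy") %in% names(hdr)))
    stop("non-square cells (DX/DY headers) are not supported")
  for (key in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (is.null(hdr[[key]]))
      stop("malformed ESRI ASCII header: missing key ", toupper(key))
  vals <- scan(text = paste(lines[-seq_len(i)], collapse = "\n"),
               what = double(), quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop(sprintf("dimension error: header promises %d x %d = %d values, found %d",
                 nr, nc, nr * nc, length(vals)))
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  vals[vals == nodata] <- NA_real_
  spec <- grid_spec(nr, nc, hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
                    nodata = nodata)
  grid_layer(spec, matrix(vals, nrow = nr, ncol = nc, byrow = TRUE), name)
}

#' Write an ESRI ASCII grid
#'
#' Writes a [grid_layer()] in the format read by [read_ascii_grid()]; `NA`
#' cells are written as the spec's nodata sentinel. Values are printed with
#' enough significant digits (15) that a write/read round trip reproduces
#' the layer to within printed precision.
#'
#' @param layer A [grid_layer()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ascii_grid <- function(layer, path) {
  stopifnot(inherits(layer, "grid_layer"))
  s <- layer$spec
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("NCOLS %d", s$n_cols),
    sprintf("NROWS %d", s$n_rows),
    sprintf("XLLCORNER %.10g", s$x_min),
    sprintf("YLLCORNER %.10g", s$y_min),
    sprintf("CELLSIZE %.10g", s$cell_size),
    sprintf("NODATA_value %.10g", s$nodata)
  ), con)
  v <- layer$values
  v[!is.finite(v)] <- s$nodata
  txt <- formatC(t(v), digits = 15, format = "g")
  writeLines(apply(matrix(txt, nrow = s$n_cols), 2L, paste, collapse = " "), con)
  invisible(path)
}

#' Read a directory or set of ASCII grids as a stack
#'
#' @param paths Either a directory (all `*.asc` files, sorted) or a character
#'   vector of file paths. Layer names are file stems.
#' @return A [climate_stack()].
#' @export
read_stack <- function(paths) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- sort(list.files(paths, pattern = "\\.asc$", full.names = TRUE))
  if (!length(paths)) stop("no .asc files found")
  climate_stack(lapply(paths, read_ascii_grid))
}

#' Geodesic cell areas in square kilometres
#'
#' On a spherical Earth of radius `R` = 6371 km, the area of a lon/lat cell
#' spanning `cell_size` degrees of longitude between latitudes `phi_bot` and
#' `phi_top` is `R^2 * d_lambda * (sin(phi_top) - sin(phi_bot))` with
#' `d_lambda` the longitude span in radians. Areas therefore depend on the
#' row (latitude band) only.
#'
#' @param spec A [grid_spec()].
#' @param radius_km Earth radius; default 6371 km (authalic-style mean).
#' @return A [grid_layer()] named `"cell_area_km2"` of per-cell areas.
#' @export
cell_areas <- function(spec, radius_km = 6371) {
  stopifnot(inherits(spec, "grid_spec"))
  tol <- 1e-9
  if (spec$y_max > 90 + tol || spec$y_min < -90 - tol)
    stop("cells extend beyond +/-90 degrees latitude")
  top <- spec$y_max - (seq_len(spec$n_rows) - 1) * spec$cell_size
  bot <- top - spec$cell_size
  band <- radius_km^2 * (spec$cell_size * pi / 180) *
    (sin(pmin(top, 90) * pi / 180) - sin(pmax(bot, -90) * pi / 180))
  grid_layer(spec, matrix(band, nrow = spec$n_rows, ncol = spec$n_cols),
             name = "cell_area_km2")
}
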