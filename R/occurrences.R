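# Species presence records: CSV ingestion with Darwin-Core-style columns,
# coordinate cleaning, per-grid-cell thinning, and the random train/test
# split used for model evaluation.

#' Construct an occurrence set
#'
#' @param species Species name.
#' @param lon,lat Coordinate vectors, degrees; must lie in
#'   `[-180, 180] x [-90, 90]`.
#' @param provenance Free-text source note.
#' @param cleaning Optional cleaning report list (counts of dropped rows).
#' @return An object of class `occurrence_set` with a `points` data frame.
#' @export
occurrence_set <- function(species, lon, lat, provenance = "",
                           cleaning = NULL) {
  lon <- as.numeric(lon); lat <- as.numeric(lat)
  if (length(lon) != length(lat)) stop("lon and lat lengths differ")
  if (length(lon) && (any(abs(lon) > 180) || any(abs(lat) > 90)))
    stop("coordinates outside [-180,180] x [-90,90]")
  if (is.null(cleaning))
    cleaning <- list(n_raw = length(lon), dropped_missing = 0L,
                     dropped_range = 0L)
  structure(list(species = as.character(species),
                 points = data.frame(lon = lon, lat = lat),
                 provenance = provenance, cleaning = cleaning),
            class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("<occurrence_set> %s: %d records", x$species, nrow(x$points)))
  cl <- x$cleaning
  if (!is.null(cl) && (cl$dropped_missing + cl$dropped_range) > 0)
    cat(sprintf(" (cleaned from %d: %d missing, %d out-of-range dropped)",
                cl$n_raw, cl$dropped_missing, cl$dropped_range))
  cat("\n")
  invisible(x)
}

find_column <- function(nms, aliases) {
  hit <- which(tolower(nms) %in% tolower(aliases))
  if (length(hit)) hit[1L] else NA_integer_
}

#' Read and clean occurrence records from CSV
#'
#' Expects Darwin-Core-style columns `species`, `decimalLongitude`,
#' `decimalLatitude` (case-insensitive; `lon`/`longitude` and
#' `lat`/`latitude` accepted as aliases — GBIF-style exports vary). Extra
#' columns are ignored. Rows with missing or non-numeric coordinates, and
#' rows with coordinates outside the valid lon/lat range, are dropped and
#' counted in the cleaning report.
#'
#' @param path CSV file path.
#' @param species If given, keep only rows whose species column matches;
#'   otherwise all rows are used and the species name is taken from the
#'   first row (or `"unknown"`).
#' @return An [occurrence_set()] with a cleaning report.
#' @export
read_occurrences <- function(path, species = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE, comment.char = "#")
  i_lon <- find_column(names(df), c("decimallongitude", "lon", "longitude"))
  i_lat <- find_column(names(df), c("decimallatitude", "lat", "latitude"))
  i_sp  <- find_column(names(df), "species")
  missing_cols <- c(
    if (is.na(i_lon)) "decimalLongitude",
    if (is.na(i_lat)) "decimalLatitude",
    if (is.na(i_sp)) "species")
  if (length(missing_cols))
    stop("occurrence CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!is.null(species)) df <- df[df[[i_sp]] == species, , drop = FALSE]
  sp_name <- if (!is.null(species)) species
             else if (nrow(df)) as.character(df[[i_sp]][1L]) else "unknown"
  n_raw <- nrow(df)
  lon <- suppressWarnings(as.numeric(df[[i_lon]]))
  lat <- suppressWarnings(as.numeric(df[[i_lat]]))
  miss <- is.na(lon) | is.na(lat)
  lon <- lon[!miss]; lat <- lat[!miss]
  oor <- abs(lon) > 180 | abs(lat) > 90
  cleaning <- list(n_raw = n_raw, dropped_missing = sum(miss),
                   dropped_range = sum(oor))
  if (n_raw == 0L)
    warning("no occurrence rows for '", sp_name, "' in ", path)
  occurrence_set(sp_name, lon[!oor], lat[!oor],
                 provenance = path, cleaning = cleaning)
}

#' Thin occurrences to one record per grid cell
#'
#' De-duplicates records at the model's grid scale (prevents
#' pseudo-replication when multiple records fall in one cell): keeps the
#' first record encountered per cell, drops records off the grid, and — if a
#' stack is supplied — drops records on cells masked in any layer.
#'
#' @param occ An [occurrence_set()].
#' @param spec A [grid_spec()].
#' @param stack Optional [climate_stack()] providing the nodata mask.
#' @return A thinned [occurrence_set()]; also records the thinning counts.
#' @export
thin_to_cells <- function(occ, spec, stack = NULL) {
  stopifnot(inherits(occ, "occurrence_set"))
  cells <- cell_of(spec, occ$points$lon, occ$points$lat)
  keep <- !is.na(cells)
  if (!is.null(stack)) {
    ok <- rep(FALSE, spec$n_rows * spec$n_cols)
    ok[valid_cells(stack)] <- TRUE
    keep[keep] <- ok[cells[keep]]
  }
  keep[keep] <- !duplicated(cells[keep])
  out <- occurrence_set(occ$species, occ$points$lon[keep],
                        occ$points$lat[keep],
                        provenance = occ$provenance, cleaning = occ$cleaning)
  out$cells <- cells[keep]
  out$thinning <- list(n_in = nrow(occ$points), n_out = sum(keep))
  out
}

#' Split occurrences into training and testing sets
#'
#' Uniformly random split by record. The training size is
#' `round(train_fraction * n)`, clamped so both parts are non-empty; the
#' same seed always yields the same split.
#'
#' @param occ An [occurrence_set()] with at least 2 records.
#' @param train_fraction Proportion assigned to training; default 0.75.
#' @param seed Integer seed.
#' @return List with elements `train` and `test`, both [occurrence_set()]s.
#' @export
split_train_test <- function(occ, train_fraction = 0.75, seed = 1L) {
  stopifnot(inherits(occ, "occurrence_set"))
  n <- nrow(occ$points)
  if (n < 2L) stop("need at least 2 records to split")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  n_train <- min(max(round(train_fraction * n), 1L), n - 1L)
  idx <- with_seed(seed, sample.int(n, n_train))
  take <- function(i) occurrence_set(occ$species, occ$points$lon[i],
                                     occ$points$lat[i],
                                     provenance = occ$provenance)
  list(train = take(sort(idx)), test = take(setdiff(seq_len(n), idx)))
}

# Evaluate an expression with a private RNG state so package functions are
# seed-reproducible without disturbing the caller's random stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
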