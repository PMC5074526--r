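# Suitable-area computation on classified habitat maps and the
# baseline -> future change metrics (delta, percent change, ratio) used to
# rank species by projected habitat gain. Areas are geodesic km^2 from
# latitude-dependent cell areas, never cell counts.

#' Area of a habitat class in km^2
#'
#' Sums the geodesic cell areas over cells of the requested class.
#' `which_class = "suitable"` counts classes 1 and 2 together (all suitable
#' habitat); `2` is the suitable high-risk class, `1` the low-risk class.
#'
#' @param map Classified habitat `grid_layer` (codes 0/1/2, from
#'   [classify_map()]).
#' @param areas Cell-area `grid_layer` from [cell_areas()] on the same grid.
#' @param which_class `1`, `2` or `"suitable"`.
#' @return Area in km^2 (>= 0).
#' @export
habitat_area <- function(map, areas, which_class = 2) {
  stopifnot(inherits(map, "grid_layer"), inherits(areas, "grid_layer"))
  if (!same_spec(map$spec, areas$spec))
    stop("habitat map and cell-area layer are on different grids")
  sel <- if (identical(which_class, "suitable")) map$values >= 1
         else map$values == which_class
  sum(areas$values[which(sel)])
}

#' Baseline-to-future habitat change metrics
#'
#' Computes the suitable-area pair and its change for one habitat class:
#' `delta = area_future - area_baseline`, `pct_change = 100 * delta /
#' area_baseline` and `ratio = area_future / area_baseline`. When the
#' baseline area is zero the percent change and ratio are undefined (`NA`)
#' and `new_habitat_flag` is set if any future habitat appears — the
#' "no habitat now, habitat later" case is reported, never a division
#' error.
#'
#' @param baseline,future Classified habitat maps on the same grid.
#' @param areas Cell-area layer from [cell_areas()].
#' @param which_class `1`, `2` (default: the high-risk class that drives
#'   prioritisation) or `"suitable"`.
#' @return An object of class `habitat_change` with fields
#'   `area_baseline`, `area_future`, `delta`, `pct_change`, `ratio`,
#'   `new_habitat_flag`, `which_class`.
#' @export
change_metrics <- function(baseline, future, areas, which_class = 2) {
  if (!same_spec(baseline$spec, future$spec))
    stop("baseline and future maps are on different grids")
  a0 <- habitat_area(baseline, areas, which_class)
  a1 <- habitat_area(future, areas, which_class)
  delta <- a1 - a0
  structure(list(
    area_baseline = a0, area_future = a1, delta = delta,
    pct_change = if (a0 > 0) 100 * delta / a0 else NA_real_,
    ratio = if (a0 > 0) a1 / a0 else NA_real_,
    new_habitat_flag = a0 == 0 && a1 > 0,
    which_class = which_class
  ), class = "habitat_change")
}

#' @export
print.habitat_change <- function(x, ...) {
  cat(sprintf("<habitat_change> class %s: baseline %.1f km2 -> future %.1f km2\n",
              format(x$which_class), x$area_baseline, x$area_future))
  if (x$new_habitat_flag)
    cat(sprintf("  new habitat: +%.1f km2 from a zero baseline\n", x$delta))
  else if (is.na(x$pct_change))
    cat("  no habitat in either period\n")
  else
    cat(sprintf("  delta %+.1f km2 (%+.1f%%, ratio %.3g)\n",
                x$delta, x$pct_change, x$ratio))
  invisible(x)
}
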