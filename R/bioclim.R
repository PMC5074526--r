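# Derivation of the 19 standard bioclimatic variables (BIO1..BIO19) from
# monthly temperature and precipitation climatologies, following the
# ANUCLIM/Worldclim definitions. Quarters are circular windows of three
# consecutive calendar months (Dec-Jan-Feb wraps); ties between windows go
# to the earliest window in calendar order. Units: degrees C and mm (no
# integer x10 packing).

#' Bundle monthly climatologies
#'
#' Holds the 36 monthly layers (tmin, tmax, prec for months 1..12) on one
#' grid, from which the bioclim variables are derived. Monthly mean
#' temperature is defined as `(tmin + tmax) / 2`.
#'
#' @param tmin,tmax Lists of 12 [grid_layer()]s (or matrices) of monthly
#'   minimum / maximum temperature, degrees C.
#' @param prec List of 12 layers of monthly precipitation, mm (non-negative).
#' @param spec A [grid_spec()]; required if the layers are bare matrices.
#' @return An object of class `monthly_climate`.
#' @export
monthly_climate <- function(tmin, tmax, prec, spec = NULL) {
  as_layers <- function(x, prefix) {
    missing <- if (length(x) < 12L) (length(x) + 1L):12L else integer()
    missing <- sort(union(missing, which(vapply(x, is.null, TRUE))))
    if (length(missing) || length(x) != 12L)
      stop(sprintf("%s: expected 12 monthly layers, missing months %s",
                   prefix, paste(missing, collapse = ", ")))
    lapply(1:12, function(m) {
      l <- x[[m]]
      if (inherits(l, "grid_layer")) return(l)
      if (is.null(spec)) stop("spec is required when layers are bare matrices")
      grid_layer(spec, l, sprintf("%s_%02d", prefix, m))
    })
  }
  tmin <- as_layers(tmin, "tmin"); tmax <- as_layers(tmax, "tmax")
  prec <- as_layers(prec, "prec")
  sp <- tmin[[1L]]$spec
  all_l <- c(tmin, tmax, prec)
  if (!all(vapply(all_l, function(l) same_spec(sp, l$spec), TRUE)))
    stop("all 36 monthly layers must share one grid")
  for (m in 1:12) {
    bad <- tmax[[m]]$values < tmin[[m]]$values
    if (any(bad, na.rm = TRUE))
      stop(sprintf("tmax < tmin on %d cells in month %d", sum(bad, na.rm = TRUE), m))
    if (any(prec[[m]]$values < 0, na.rm = TRUE))
      stop(sprintf("negative precipitation in month %d", m))
  }
  structure(list(spec = sp, tmin = tmin, tmax = tmax, prec = prec),
            class = "monthly_climate")
}

#' @export
print.monthly_climate <- function(x, ...) {
  cat(sprintf("<monthly_climate> 36 monthly layers on %d x %d grid\n",
              x$spec$n_rows, x$spec$n_cols))
  invisible(x)
}

# cells x 12 matrix of one monthly variable
monthly_matrix <- function(mc, what) {
  m <- vapply(mc[[what]], function(l) as.vector(l$values),
              numeric(mc$spec$n_rows * mc$spec$n_cols))
  if (!is.matrix(m)) m <- matrix(m, nrow = 1L)  # single-cell grid
  m
}

#' Derive the 19 bioclimatic variables
#'
#' Computes BIO1..BIO19 from a [monthly_climate()]:
#' annual mean temperature (BIO1); mean diurnal range (BIO2); isothermality
#' `100 * BIO2 / BIO7` (BIO3); temperature seasonality, 100 x population SD
#' of monthly means (BIO4); max temperature of warmest month (BIO5); min
#' temperature of coldest month (BIO6); annual range `BIO5 - BIO6` (BIO7);
#' mean temperature of the wettest / driest / warmest / coldest quarter
#' (BIO8-BIO11); annual precipitation (BIO12); precipitation of wettest /
#' driest month (BIO13, BIO14); precipitation seasonality, the coefficient
#' of variation with the monthly mean offset by +1 mm so fully arid cells
#' stay finite (BIO15); precipitation of the wettest / driest / warmest /
#' coldest quarter (BIO16-BIO19). Quarters are circular 3-month windows;
#' ties pick the earliest window. Where the annual temperature range is zero
#' BIO3 is set to 0.
#'
#' @param monthly A [monthly_climate()].
#' @return A [climate_stack()] of 19 layers named `BIO1`..`BIO19`.
#' @export
derive_bioclim <- function(monthly) {
  stopifnot(inherits(monthly, "monthly_climate"))
  spec <- monthly$spec
  Tn <- monthly_matrix(monthly, "tmin")
  Tx <- monthly_matrix(monthly, "tmax")
  P  <- monthly_matrix(monthly, "prec")
  Tm <- (Tn + Tx) / 2
  ncell <- nrow(Tm)

  # circular 3-month window aggregation: W[m, w] = 1 if month m in window w
  W <- matrix(0, 12, 12)
  for (w in 1:12) W[(w + 0:2 - 1) %% 12 + 1, w] <- 1
  qT <- Tm %*% W / 3   # quarterly mean temperature, cells x 12 windows
  qP <- P %*% W        # quarterly precipitation totals

  pick <- function(q, decreasing) {
    # earliest window attaining the max (or min); NA rows stay NA
    z <- if (decreasing) q else -q
    idx <- rep(NA_integer_, nrow(z))
    ok <- rowSums(is.na(z)) == 0L
    if (any(ok)) idx[ok] <- max.col(z[ok, , drop = FALSE], ties.method = "first")
    idx
  }
  at <- function(q, idx) {
    out <- rep(NA_real_, length(idx))
    ok <- !is.na(idx)
    out[ok] <- q[cbind(which(ok), idx[ok])]
    out
  }
  wetq  <- pick(qP, TRUE);  dryq  <- pick(qP, FALSE)
  warmq <- pick(qT, TRUE);  coldq <- pick(qT, FALSE)

  sd_pop <- function(M) sqrt(rowMeans(M^2) - rowMeans(M)^2)

  b <- vector("list", 19)
  b[[1]] <- rowMeans(Tm)
  b[[2]] <- rowMeans(Tx - Tn)
  b[[5]] <- apply(Tx, 1L, max)
  b[[6]] <- apply(Tn, 1L, min)
  b[[7]] <- b[[5]] - b[[6]]
  b[[3]] <- ifelse(b[[7]] == 0, 0, 100 * b[[2]] / b[[7]])
  b[[4]] <- 100 * sd_pop(Tm)
  b[[8]]  <- at(qT, wetq);  b[[9]]  <- at(qT, dryq)
  b[[10]] <- at(qT, warmq); b[[11]] <- at(qT, coldq)
  b[[12]] <- rowSums(P)
  b[[13]] <- apply(P, 1L, max)
  b[[14]] <- apply(P, 1L, min)
  b[[15]] <- 100 * sd_pop(P) / (rowMeans(P) + 1)
  b[[16]] <- at(qP, wetq);  b[[17]] <- at(qP, dryq)
  b[[18]] <- at(qP, warmq); b[[19]] <- at(qP, coldq)

  layers <- lapply(1:19, function(i)
    grid_layer(spec, matrix(b[[i]], spec$n_rows, spec$n_cols),
               name = paste0("BIO", i)))
  climate_stack(layers)
}
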