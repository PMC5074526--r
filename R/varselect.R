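# Collinearity-based covariate selection: a pairwise Pearson prefilter
# followed by iterative elimination on the variance inflation factor,
# mirroring common practice in ecological niche modelling. The matrix rows
# are intended to be the model's background sample so that the selection
# reflects the fitting domain.

new_selection_report <- function(kept, dropped, cor_matrix = NULL,
                                 vif = NULL) {
  structure(list(kept = kept, dropped = dropped, cor_matrix = cor_matrix,
                 vif = vif), class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> kept %d, dropped %d variable(s)\n",
              length(x$kept), nrow(x$dropped)))
  if (nrow(x$dropped)) {
    cat("dropped:\n")
    print(x$dropped, row.names = FALSE)
  }
  if (!is.null(x$vif)) {
    cat("final VIFs:\n")
    print(round(x$vif, 3))
  }
  invisible(x)
}

empty_dropped <- function() data.frame(variable = character(),
                                       reason = character(),
                                       statistic = numeric(),
                                       stringsAsFactors = FALSE)

drop_constants <- function(x, dropped) {
  sds <- apply(x, 2L, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  if (any(const))
    dropped <- rbind(dropped, data.frame(
      variable = colnames(x)[const], reason = "constant",
      statistic = sds[const], stringsAsFactors = FALSE))
  list(x = x[, !const, drop = FALSE], dropped = dropped)
}

as_var_matrix <- function(x) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  storage.mode(x) <- "double"
  x[stats::complete.cases(x), , drop = FALSE]
}

#' Pairwise Pearson correlation prefilter
#'
#' Repeatedly, while any pair of remaining variables has absolute Pearson
#' correlation strictly greater than `threshold`, takes the most correlated
#' pair and drops the member with the larger mean absolute correlation
#' against all remaining variables (ties broken towards the later input
#' column). Zero-variance variables are dropped first with reason
#' `"constant"`. Deterministic given the input column order.
#'
#' @param x Numeric matrix or data frame, cells x variables; rows with any
#'   `NA` are removed.
#' @param threshold Absolute-correlation threshold; default 0.7.
#' @return A `selection_report` with `kept`, `dropped` (variable, reason,
#'   statistic) and the full initial correlation matrix.
#' @export
pearson_prefilter <- function(x, threshold = 0.7) {
  x <- as_var_matrix(x)
  if (ncol(x) < 2L) stop("need at least 2 variables")
  if (nrow(x) < 3L) stop("need at least 3 complete rows")
  dc <- drop_constants(x, empty_dropped())
  x <- dc$x; dropped <- dc$dropped
  cm <- if (ncol(x) >= 2L) stats::cor(x) else NULL
  keep <- colnames(x)
  order_rank <- stats::setNames(seq_along(keep), keep)
  while (length(keep) >= 2L) {
    A <- abs(cm[keep, keep, drop = FALSE]); diag(A) <- 0
    worst <- max(A)
    if (worst <= threshold) break
    ij <- which(A == worst, arr.ind = TRUE)[1L, ]
    pair <- keep[ij]
    mean_abs <- rowSums(A[pair, , drop = FALSE]) / (length(keep) - 1L)
    # larger mean |r| goes; ties -> later input order
    victim <- pair[order(-mean_abs, -order_rank[pair])][1L]
    dropped <- rbind(dropped, data.frame(
      variable = victim, reason = "pearson", statistic = worst,
      stringsAsFactors = FALSE))
    keep <- setdiff(keep, victim)
  }
  new_selection_report(keep, dropped, cor_matrix = cm)
}

# VIF of each column of x regressed on all the others by least squares;
# perfect collinearity yields Inf rather than an error.
vif_values <- function(x) {
  p <- ncol(x)
  vapply(seq_len(p), function(j) {
    y <- x[, j]
    tss <- sum((y - mean(y))^2)
    if (tss == 0) return(Inf)
    X <- cbind(1, x[, -j, drop = FALSE])
    fit <- stats::lm.fit(X, y)
    r2 <- 1 - sum(fit$residuals^2) / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE) |> stats::setNames(colnames(x))
}

#' Iterative variance-inflation-factor filter
#'
#' Computes `VIF_j = 1 / (1 - R2_j)` from the least-squares regression of
#' each variable on all other remaining variables and, while the maximum
#' VIF exceeds `threshold`, drops that variable and recomputes. Perfect
#' collinearity gives an infinite VIF and an immediate drop, never a
#' numerical failure. Constant variables are dropped first.
#'
#' @param x Numeric matrix or data frame, cells x variables (typically the
#'   output of [pearson_prefilter()] applied to the background sample).
#' @param threshold VIF threshold; default 10.
#' @param report Optional `selection_report` from [pearson_prefilter()]
#'   whose `kept`/`dropped` records are carried forward.
#' @return A `selection_report`; its `vif` element holds the final VIF of
#'   every kept variable (all `<= threshold`).
#' @export
vif_filter <- function(x, threshold = 10, report = NULL) {
  x <- as_var_matrix(x)
  dropped <- empty_dropped()
  cm <- NULL
  if (!is.null(report)) {
    x <- x[, report$kept, drop = FALSE]
    dropped <- report$dropped
    cm <- report$cor_matrix
  }
  dc <- drop_constants(x, dropped)
  x <- dc$x; dropped <- dc$dropped
  while (ncol(x) >= 2L) {
    v <- vif_values(x)
    worst <- max(v)
    if (worst <= threshold) break
    # ties -> later input order
    j <- max(which(v == worst))
    dropped <- rbind(dropped, data.frame(
      variable = colnames(x)[j], reason = "vif", statistic = worst,
      stringsAsFactors = FALSE))
    x <- x[, -j, drop = FALSE]
  }
  final_vif <- if (ncol(x) >= 2L) vif_values(x)
               else stats::setNames(rep(1, ncol(x)), colnames(x))
  new_selection_report(colnames(x), dropped, cor_matrix = cm,
                       vif = final_vif)
}

#' Sequential Pearson + VIF variable selection
#'
#' Applies [pearson_prefilter()] then [vif_filter()] with the study's
#' conventional thresholds (|r| > 0.7, VIF > 10).
#'
#' @param x Numeric matrix or data frame, cells x variables.
#' @param pearson,vif Thresholds for the two stages.
#' @return A `selection_report` combining both stages.
#' @export
select_variables <- function(x, pearson = 0.7, vif = 10) {
  vif_filter(x, threshold = vif,
             report = pearson_prefilter(x, threshold = pearson))
}

#' Write a selection report as CSV
#'
#' @param report A `selection_report`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_selection_report <- function(report, path) {
  rows <- rbind(
    data.frame(variable = report$kept, status = "kept", reason = "",
               statistic = if (is.null(report$vif)) NA_real_
                           else unname(report$vif[report$kept]),
               stringsAsFactors = FALSE),
    if (nrow(report$dropped))
      data.frame(variable = report$dropped$variable, status = "dropped",
                 reason = report$dropped$reason,
                 statistic = report$dropped$statistic,
                 stringsAsFactors = FALSE))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
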