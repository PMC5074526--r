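# Presence-background model evaluation: rank-based ROC/AUC, the two
# threshold rules used to classify continuous suitability into habitat
# classes, and the three-class map itself. Specificity is computed against
# the background sample, the standard stand-in for absences in
# presence-only modelling.

#' Presence-background AUC
#'
#' Rank-based (Mann-Whitney) area under the ROC curve with midrank tie
#' handling: the probability that a random presence scores above a random
#' background point, counting ties as one half. Identical to brute-force
#' pair counting `(#{pres > bg} + 0.5 #{pres = bg}) / (n_pres * n_bg)`.
#'
#' @param presence_scores,background_scores Non-empty numeric vectors.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(presence_scores, background_scores) {
  np <- length(presence_scores); nb <- length(background_scores)
  if (!np || !nb) stop("presence and background scores must be non-empty")
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Discrimination band of an AUC value
#'
#' Maps AUC to the conventional labels: above 0.9 excellent, above 0.8 very
#' good, above 0.7 good, above 0.5 poor, otherwise random-ish (0.5 means no
#' discrimination). Bounds are open from below: the value must exceed the
#' bound to earn the label.
#'
#' @param auc_value AUC in `[0, 1]`.
#' @return One of `"random-ish"`, `"poor"`, `"good"`, `"very good"`,
#'   `"excellent"`.
#' @export
auc_band <- function(auc_value) {
  if (is.na(auc_value) || auc_value < 0 || auc_value > 1)
    stop("AUC must be in [0, 1]")
  if (auc_value > 0.9) "excellent"
  else if (auc_value > 0.8) "very good"
  else if (auc_value > 0.7) "good"
  else if (auc_value > 0.5) "poor"
  else "random-ish"
}

#' Least training presence threshold
#'
#' The minimum suitability score among training presences; classifying at
#' this threshold keeps every training presence suitable (100% training
#' sensitivity). Used as the lower bound of suitable low-risk habitat.
#'
#' @param training_presence_scores Non-empty numeric vector.
#' @return The threshold.
#' @export
ltp_threshold <- function(training_presence_scores) {
  if (!length(training_presence_scores))
    stop("no training presence scores")
  min(training_presence_scores)
}

#' Sensitivity-specificity sum maximization threshold
#'
#' Scans every distinct observed score as a candidate threshold and returns
#' the one maximizing `sensitivity(presence >= t) + specificity(background
#' < t)`; ties go to the smallest threshold. Marks the lower bound of
#' suitable high-risk habitat.
#'
#' @param presence_scores,background_scores Non-empty numeric vectors.
#' @return The threshold.
#' @export
max_sss_threshold <- function(presence_scores, background_scores) {
  if (!length(presence_scores) || !length(background_scores))
    stop("presence and background scores must be non-empty")
  cand <- sort(unique(c(presence_scores, background_scores)))
  np <- length(presence_scores); nb <- length(background_scores)
  # integer-valued objective (sens + spec scaled by np * nb): exact
  # comparisons, so ties resolve deterministically to the smallest cut
  sums <- vapply(cand, function(t)
    sum(presence_scores >= t) * nb + sum(background_scores < t) * np,
    numeric(1))
  cand[which.max(sums)]  # which.max -> first (smallest) maximizer
}

#' Pair the two habitat thresholds
#'
#' Bundles the least-training-presence (low) and max-SSS (high) thresholds.
#' With few presences the LTP can exceed the max-SSS threshold; in that
#' case the high threshold is raised to the low one and the pair is
#' flagged rather than failing.
#'
#' @param t_low,t_high Thresholds in `[0, 1]`.
#' @return An object of class `threshold_pair` with `t_low`, `t_high`,
#'   `flagged`.
#' @export
threshold_pair <- function(t_low, t_high) {
  if (t_low < 0 || t_low > 1 || t_high < 0 || t_high > 1)
    stop("thresholds must lie in [0, 1]")
  flagged <- t_low > t_high
  if (flagged) t_high <- t_low
  structure(list(t_low = t_low, t_high = t_high, flagged = flagged),
            class = "threshold_pair")
}

#' @export
print.threshold_pair <- function(x, ...) {
  cat(sprintf("<threshold_pair> low %.4f, high %.4f%s\n", x$t_low, x$t_high,
              if (x$flagged) " [flagged: LTP exceeded maxSSS]" else ""))
  invisible(x)
}

#' Classify a suitability map into habitat classes
#'
#' Three classes: 0 = unsuitable (score below the low threshold), 1 =
#' suitable low-risk habitat (at or above the low threshold but below the
#' high one), 2 = suitable high-risk habitat (at or above the high
#' threshold). Both comparisons are inclusive at the threshold; nodata
#' propagates.
#'
#' @param suit A suitability `grid_layer` with values in `[0, 1]`.
#' @param thresholds A [threshold_pair()], or `t_low` as a number.
#' @param t_high High threshold when `thresholds` is numeric.
#' @return A `grid_layer` of integer classes 0/1/2.
#' @export
classify_map <- function(suit, thresholds, t_high = NULL) {
  stopifnot(inherits(suit, "grid_layer"))
  if (!inherits(thresholds, "threshold_pair"))
    thresholds <- threshold_pair(thresholds, t_high)
  v <- suit$values
  cls <- ifelse(v >= thresholds$t_high, 2,
                ifelse(v >= thresholds$t_low, 1, 0))
  grid_layer(suit$spec, cls, name = paste0(suit$name, "_class"))
}
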