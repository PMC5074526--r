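# Two-axis prioritisation: combine each species' invasiveness category with
# its projected change in suitable high-risk habitat into a ranked table,
# plus the side-by-side comparison of ranking by risk alone, by habitat
# change alone, and by the combined rule.

category_tier <- function(category) {
  t <- match(category, RISK_CATEGORIES)
  if (anyNA(t))
    stop("unknown category label(s): ",
         paste(unique(category[is.na(t)]), collapse = ", "))
  t
}

as_priority_input <- function(entries) {
  df <- do.call(rbind, lapply(entries, function(e) {
    risk <- e$risk %||% e[[2L]]
    chg <- e$change %||% e[[3L]]
    data.frame(
      species = e$species %||% risk$species,
      category = risk$category, score = risk$score,
      area_baseline = chg$area_baseline, area_future = chg$area_future,
      delta = chg$delta, pct_change = chg$pct_change, ratio = chg$ratio,
      new_habitat = isTRUE(chg$new_habitat_flag),
      stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(df$species))
    stop("duplicate species in prioritisation input: ",
         paste(unique(df$species[duplicated(df$species)]), collapse = ", "))
  df
}

#' Rank species by risk category and habitat gain
#'
#' Sorts species lexicographically by invasiveness category tier
#' (descending), then by the change in suitable high-risk habitat area
#' (descending), then by species name, and assigns priority ranks and
#' tiers. Tier `"high"` requires a category of at least Highly Invasive
#' together with a positive habitat-change delta (or newly appearing
#' habitat from a zero baseline); `"low"` is a category of Modestly
#' Invasive or below with no habitat gain; everything else is `"watch"`.
#'
#' @param entries A list whose elements each carry `species`, a
#'   `risk_result` (element `risk`) and a `habitat_change` (element
#'   `change`), e.g. `list(list(species=, risk=, change=), ...)`.
#' @param rank_within Rank ties within the same delta by `"category"`
#'   (default, the lexicographic rule) or by `"score"` (numeric risk score
#'   instead of the six-level category).
#' @return A data frame of class `priority_table`, one row per species in
#'   rank order with columns `priority_rank`, `priority_tier`, `species`,
#'   `category`, `score`, the habitat areas and change metrics.
#' @export
prioritize <- function(entries, rank_within = c("category", "score")) {
  rank_within <- match.arg(rank_within)
  df <- as_priority_input(entries)
  tier_num <- category_tier(df$category)
  primary <- if (rank_within == "category") tier_num else df$score
  ord <- order(-primary, -df$delta, df$species)
  df <- df[ord, , drop = FALSE]
  tier_num <- tier_num[ord]
  gain <- df$delta > 0 | df$new_habitat
  df$priority_tier <- ifelse(
    tier_num >= category_tier("Highly Invasive") & gain, "high",
    ifelse(tier_num <= category_tier("Modestly Invasive") & !gain, "low",
           "watch"))
  df$priority_rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df <- df[, c("priority_rank", "priority_tier", "species", "category",
               "score", "area_baseline", "area_future", "delta",
               "pct_change", "ratio", "new_habitat")]
  class(df) <- c("priority_table", "data.frame")
  df
}

#' @export
print.priority_table <- function(x, ...) {
  cat("Species priorities (risk category x high-risk habitat change)\n")
  y <- as.data.frame(x)
  y$delta <- round(y$delta, 1)
  y$pct_change <- round(y$pct_change, 1)
  y$ratio <- round(y$ratio, 3)
  y$area_baseline <- round(y$area_baseline, 1)
  y$area_future <- round(y$area_future, 1)
  y$score <- round(y$score, 1)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Compare risk-only, habitat-only and combined rankings
#'
#' Emits the three orderings side by side: by risk score alone, by
#' high-risk habitat-change delta alone, and by the combined
#' category-then-delta rule of [prioritize()]. Ties break by species name.
#'
#' @param entries As in [prioritize()].
#' @return Data frame with columns `rank`, `by_risk_score`,
#'   `by_habitat_change`, `combined`.
#' @export
comparison_table <- function(entries) {
  df <- as_priority_input(entries)
  by_risk <- df$species[order(-df$score, df$species)]
  by_delta <- df$species[order(-df$delta, df$species)]
  combined <- prioritize(entries)$species
  data.frame(rank = seq_len(nrow(df)), by_risk_score = by_risk,
             by_habitat_change = by_delta, combined = combined,
             stringsAsFactors = FALSE)
}
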