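# Schema-driven invasiveness risk scoring: 21 criteria grouped around four
# attributes (ecological impact, invasive characteristics, dispersal
# ability, feasibility of control), summed to a 0-100 score computed over
# answered criteria only, then mapped to one of six category bands. The
# shipped default schema is an editable stand-in with the documented
# structure; the scoring and categorization rules are fixed.

RISK_GROUPS <- c("ecological impact", "invasive characteristics",
                 "dispersal ability", "feasibility of control")

RISK_CATEGORIES <- c("Very Weakly Invasive", "Weakly Invasive",
                     "Modestly Invasive", "Moderately Invasive",
                     "Highly Invasive", "Extremely Invasive")

#' Load a risk-criteria schema
#'
#' Reads a YAML schema of scoring criteria. Each criterion has an `id`, a
#' `prompt`, a `group` (one of the four attribute groups), a non-negative
#' `max_points`, and a map of allowed answer `levels` to points. The
#' shipped default (`system.file("extdata", "default_schema.yaml", package
#' = "invacast")`, loaded when `path` is `NULL`) has exactly 21 criteria in
#' the four groups with group maxima 40/25/25/10 and total 100.
#'
#' @param path Schema file path, or `NULL` for the shipped default.
#' @return An object of class `criteria_schema`.
#' @export
load_schema <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "default_schema.yaml",
                        package = "invacast", mustWork = TRUE)
  y <- yaml::read_yaml(path)
  if (is.null(y$criteria) || !length(y$criteria))
    stop("schema has no criteria")
  problems <- character()
  ids <- vapply(y$criteria, function(cr) as.character(cr$id %||% ""), "")
  if (any(ids == "")) problems <- c(problems, "criterion without an id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    problems <- c(problems, paste0("duplicate criterion id(s): ",
                                   paste(dup, collapse = ", ")))
  for (cr in y$criteria) {
    id <- as.character(cr$id %||% "?")
    grp <- as.character(cr$group %||% "")
    if (!grp %in% RISK_GROUPS)
      problems <- c(problems,
                    sprintf("criterion %s: unknown group '%s'", id, grp))
    mp <- cr$max_points
    if (is.null(mp) || !is.numeric(mp) || mp < 0)
      problems <- c(problems,
                    sprintf("criterion %s: max_points must be >= 0", id))
    lv <- unlist(cr$levels)
    if (is.null(lv) || !length(lv))
      problems <- c(problems, sprintf("criterion %s: no answer levels", id))
    else if (is.numeric(mp) &&
             (any(lv > mp) || any(lv < 0)))
      problems <- c(problems,
                    sprintf("criterion %s: level points outside [0, %g]",
                            id, mp))
  }
  groups <- unique(vapply(y$criteria,
                          function(cr) as.character(cr$group %||% ""), ""))
  extra <- setdiff(groups, RISK_GROUPS)
  if (length(extra))
    problems <- c(problems, paste0("group(s) outside the four attributes: ",
                                   paste(extra, collapse = ", ")))
  if (length(problems))
    stop("invalid schema:\n  ", paste(problems, collapse = "\n  "))
  structure(list(name = y$name %||% basename(path),
                 prescreen_note = y$prescreen_note %||% "",
                 criteria = y$criteria),
            class = "criteria_schema")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.criteria_schema <- function(x, ...) {
  grp <- vapply(x$criteria, function(cr) cr$group, "")
  mx <- vapply(x$criteria, function(cr) as.numeric(cr$max_points), 0)
  cat(sprintf("<criteria_schema> '%s': %d criteria, total %g points\n",
              x$name, length(x$criteria), sum(mx)))
  for (g in RISK_GROUPS[RISK_GROUPS %in% grp])
    cat(sprintf("  %-26s %2d criteria, %3g points\n", g, sum(grp == g),
                sum(mx[grp == g])))
  invisible(x)
}

#' Construct a scorecard
#'
#' @param species Species name.
#' @param answers Named list/vector mapping criterion ids to either a level
#'   name from the schema, a numeric point value, or `"unknown"`/`NA` for
#'   traits that could not be assessed.
#' @param notes Free-text assessor notes.
#' @return An object of class `scorecard`.
#' @export
scorecard <- function(species, answers, notes = "") {
  structure(list(species = as.character(species), answers = as.list(answers),
                 notes = notes), class = "scorecard")
}

#' Read a scorecard from YAML
#'
#' @param path YAML file with fields `species`, `answers` (criterion id ->
#'   level name, points, or `unknown`) and optional `notes`.
#' @return A [scorecard()].
#' @export
read_scorecard <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$species)) stop("scorecard missing 'species': ", path)
  scorecard(y$species, y$answers %||% list(), y$notes %||% "")
}

is_unknown_answer <- function(a) {
  is.null(a) || (length(a) == 1L && is.na(a)) ||
    (is.character(a) && tolower(a) %in% c("unknown", "u", "na"))
}

#' Score a scorecard against a schema
#'
#' The risk score is `100 * earned / possible` where both sums run over
#' answered criteria only — criteria marked unknown are excluded from
#' numerator and denominator alike, so the score reflects known traits.
#' Per-group subtotals and the answered fraction are reported; when fewer
#' than `min_answered` of the criteria are answered the result is flagged
#' `insufficient` rather than silently trusted.
#'
#' @param card A [scorecard()].
#' @param schema A `criteria_schema` from [load_schema()].
#' @param min_answered Minimum answered fraction before flagging; default
#'   0.8.
#' @return An object of class `risk_result` with `score` (0-100),
#'   `category`, `answered_fraction`, `insufficient`, `groups` (per-group
#'   earned/possible), `species`.
#' @export
total_score <- function(card, schema, min_answered = 0.8) {
  stopifnot(inherits(card, "scorecard"), inherits(schema, "criteria_schema"))
  ids <- vapply(schema$criteria, function(cr) as.character(cr$id), "")
  unknown_ids <- setdiff(names(card$answers), ids)
  if (length(unknown_ids))
    stop("scorecard answers reference unknown criterion id(s): ",
         paste(unknown_ids, collapse = ", "))
  earned <- possible <- numeric(length(ids))
  answered <- logical(length(ids))
  grp <- vapply(schema$criteria, function(cr) cr$group, "")
  for (k in seq_along(ids)) {
    cr <- schema$criteria[[k]]
    a <- card$answers[[ids[k]]]
    if (is_unknown_answer(a)) next
    pts <- if (is.numeric(a)) a
    else {
      lv <- unlist(cr$levels)
      if (!a %in% names(lv))
        stop(sprintf("criterion %s: answer '%s' is not a schema level (%s)",
                     ids[k], a, paste(names(lv), collapse = ", ")))
      unname(lv[[a]])
    }
    if (pts < 0 || pts > cr$max_points)
      stop(sprintf("criterion %s: %g points outside [0, %g]",
                   ids[k], pts, cr$max_points))
    answered[k] <- TRUE
    earned[k] <- pts
    possible[k] <- cr$max_points
  }
  if (!any(answered)) stop("no criteria answered for ", card$species)
  score <- 100 * sum(earned) / sum(possible)
  frac <- mean(answered)
  groups <- do.call(rbind, lapply(RISK_GROUPS, function(g) {
    s <- answered & grp == g
    data.frame(group = g, earned = sum(earned[s]),
               possible = sum(possible[s]), n_answered = sum(s),
               n_criteria = sum(grp == g), stringsAsFactors = FALSE)
  }))
  structure(list(species = card$species, score = score,
                 category = categorize(score), answered_fraction = frac,
                 insufficient = frac < min_answered, groups = groups),
            class = "risk_result")
}

#' @export
print.risk_result <- function(x, ...) {
  cat(sprintf("<risk_result> %s: %.1f / 100 -> %s\n", x$species, x$score,
              x$category))
  cat(sprintf("  answered %.0f%% of criteria%s\n",
              100 * x$answered_fraction,
              if (x$insufficient) " [flagged: insufficient information]" else ""))
  invisible(x)
}

#' Map a risk score to its invasiveness category
#'
#' Band edges: 80 and above is Extremely Invasive; 70 up to (but not
#' including) 80 Highly; 60-70 Moderately; 50-60 Modestly; 40-50 Weakly;
#' below 40 Very Weakly Invasive. Intervals are half-open so non-integer
#' scores always land in exactly one band.
#'
#' @param score Numeric score in `[0, 100]`.
#' @return Category label (character).
#' @export
categorize <- function(score) {
  if (!is.finite(score) || score < 0 || score > 100)
    stop("score must lie in [0, 100]")
  if (score >= 80) "Extremely Invasive"
  else if (score >= 70) "Highly Invasive"
  else if (score >= 60) "Moderately Invasive"
  else if (score >= 50) "Modestly Invasive"
  else if (score >= 40) "Weakly Invasive"
  else "Very Weakly Invasive"
}

#' Write risk results as CSV
#'
#' One row per species with score, category, answered fraction, flag and
#' per-group subtotals.
#'
#' @param results List of `risk_result` objects.
#' @param path Output CSV path.
#' @param params Optional named list written as `#` header comments.
#' @return Invisibly, `path`.
#' @export
write_risk_results <- function(results, path, params = NULL) {
  rows <- do.call(rbind, lapply(results, function(r) {
    g <- r$groups
    sub <- stats::setNames(g$earned, paste0(gsub(" ", "_", g$group), "_pts"))
    cbind(data.frame(species = r$species, score = r$score,
                     category = r$category,
                     answered_fraction = r$answered_fraction,
                     insufficient = r$insufficient,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(sub)))
  }))
  write_csv_commented(rows, path, params)
  invisible(path)
}

# CSV writer that prefixes '# key: value' provenance comments.
write_csv_commented <- function(df, path, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(params) && length(params))
    writeLines(sprintf("# %s: %s", names(params),
                       vapply(params, function(p) paste(format(p), collapse = " "), "")),
               con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
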