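test_that("the shipped default schema has 21 criteria in 4 groups", {
  schema <- load_schema()
  expect_s3_class(schema, "criteria_schema")
  expect_length(schema$criteria, 21)
  groups <- unique(vapply(schema$criteria, function(cr) cr$group, ""))
  expect_setequal(groups, c("ecological impact", "invasive characteristics",
                            "dispersal ability", "feasibility of control"))
  expect_equal(sum(vapply(schema$criteria,
                          function(cr) as.numeric(cr$max_points), 0)), 100)
})

test_that("schema validation names the offending criteria", {
  write_schema <- function(criteria) {
    p <- withr::local_tempfile(fileext = ".yaml", .local_envir = parent.frame())
    yaml::write_yaml(list(name = "bad", criteria = criteria), p)
    p
  }
  base_cr <- function(id, group = "ecological impact", max_points = 10,
                      levels = list(none = 0, high = 10))
    list(id = id, prompt = "p", group = group, max_points = max_points,
         levels = levels)
  # a fifth group name is rejected
  expect_error(load_schema(write_schema(list(
    base_cr("a"), base_cr("b", group = "economic impact")))),
    "economic impact")
  # duplicate ids
  expect_error(load_schema(write_schema(list(base_cr("a"), base_cr("a")))),
               "duplicate")
  # negative maximum
  expect_error(load_schema(write_schema(list(
    base_cr("a", max_points = -5, levels = list(none = 0))))), "max_points")
  # level points exceeding the maximum
  expect_error(load_schema(write_schema(list(
    base_cr("a", max_points = 5, levels = list(high = 9))))),
    "outside \\[0, 5\\]")
})

test_that("scores normalize over answered criteria only", {
  schema <- load_schema()
  # all criteria at maximum -> exactly 100
  expect_equal(total_score(all_max_card(schema), schema)$score, 100)
  # all criteria at zero -> exactly 0
  zero <- scorecard("z", stats::setNames(
    as.list(rep(0, 21)), vapply(schema$criteria, function(cr) cr$id, "")))
  expect_equal(total_score(zero, schema)$score, 0)
  # 30 points earned of 50 answerable, rest unknown -> exactly 60
  card <- scorecard("sp", list(
    EI1 = "severe", EI2 = "severe", EI3 = "moderate", EI4 = "minor",
    IC3 = "short", IC6 = "no", IC7 = "no"))
  res <- total_score(card, schema)
  expect_equal(sum(res$groups$earned), 30)
  expect_equal(sum(res$groups$possible), 50)
  expect_equal(res$score, 60)
  expect_equal(res$answered_fraction, 7 / 21)
  expect_true(res$insufficient)  # below the 0.8 answered default
  # numeric answers are accepted and bounded
  expect_error(total_score(scorecard("sp", list(EI1 = 99)), schema),
               "outside")
  expect_error(total_score(scorecard("sp", list(XX = 1)), schema),
               "unknown criterion")
  expect_error(total_score(scorecard("sp", list(EI1 = "unknown")), schema),
               "no criteria answered")
})

test_that("raising one answer never lowers score or category", {
  schema <- load_schema()
  ids <- vapply(schema$criteria, function(cr) cr$id, "")
  base <- stats::setNames(as.list(rep(0, 21)), ids)
  base$EI1 <- 10; base$DA1 <- 5  # some signal
  cats <- c("Very Weakly Invasive", "Weakly Invasive", "Modestly Invasive",
            "Moderately Invasive", "Highly Invasive", "Extremely Invasive")
  prev <- total_score(scorecard("sp", base), schema)
  for (id in c("EI2", "IC1", "FC1")) {
    cr <- schema$criteria[[match(id, ids)]]
    up <- base; up[[id]] <- as.numeric(cr$max_points)
    res <- total_score(scorecard("sp", up), schema)
    expect_gte(res$score, prev$score)
    expect_gte(match(res$category, cats), match(prev$category, cats))
  }
})

test_that("scores are invariant to rescaling all point values", {
  # a two-criterion schema and its x3 rescaled twin give identical scores
  mk <- function(k) {
    p <- withr::local_tempfile(fileext = ".yaml", .local_envir = parent.frame())
    yaml::write_yaml(list(name = "s", criteria = list(
      list(id = "a", prompt = "p", group = "ecological impact",
           max_points = 10 * k, levels = list(none = 0, mid = 4 * k, high = 10 * k)),
      list(id = "b", prompt = "p", group = "dispersal ability",
           max_points = 5 * k, levels = list(none = 0, high = 5 * k)))), p)
    load_schema(p)
  }
  card <- scorecard("sp", list(a = "mid", b = "high"))
  expect_equal(total_score(card, mk(1))$score, total_score(card, mk(3))$score)
})

test_that("category bands match the published cut points exactly", {
  expect_equal(categorize(80), "Extremely Invasive")
  expect_equal(categorize(79), "Highly Invasive")
  expect_equal(categorize(39.9), "Very Weakly Invasive")
  cases <- list(
    c(100, NA), c(80, NA), c(79.999, NA), c(70, NA), c(69.999, NA),
    c(60, NA), c(59.999, NA), c(50, NA), c(49.999, NA), c(40, NA),
    c(39.999, NA), c(0, NA))
  expected <- c("Extremely Invasive", "Extremely Invasive",
                "Highly Invasive", "Highly Invasive",
                "Moderately Invasive", "Moderately Invasive",
                "Modestly Invasive", "Modestly Invasive",
                "Weakly Invasive", "Weakly Invasive",
                "Very Weakly Invasive", "Very Weakly Invasive")
  for (i in seq_along(cases))
    expect_equal(categorize(cases[[i]][1]), expected[i],
                 info = paste("score", cases[[i]][1]))
  expect_error(categorize(101), "\\[0, 100\\]")
  expect_error(categorize(-1), "\\[0, 100\\]")
})
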