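# penalized negative objective for the numeric oracle:
# logZ(lambda) - lambda . p_bar + sum beta |lambda|
maxent_objective <- function(lambda, P, B, beta) {
  eta <- B %*% lambda
  m <- max(eta)
  lz <- m + log(sum(exp(eta - m)))
  lz - sum(lambda * colMeans(P)) + sum(beta * abs(lambda))
}

test_that("single binary feature with no penalty matches the closed form", {
  # background: 5 cells with f=1, 5 with f=0; presence mean 0.8
  # moment matching: e^l * 5 / (e^l * 5 + 5) = 0.8  =>  lambda = log 4
  P <- matrix(c(rep(1, 8), rep(0, 2)), ncol = 1, dimnames = list(NULL, "f"))
  B <- matrix(c(rep(1, 5), rep(0, 5)), ncol = 1, dimnames = list(NULL, "f"))
  m <- fit_maxent(P, B, reg_multiplier = 0, tol = 1e-12)
  expect_equal(unname(m$weights), log(4), tolerance = 1e-4)
  expect_true(m$converged)
})

test_that("overwhelming regularization shrinks all weights to zero", {
  set.seed(5)
  P <- matrix(runif(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  B <- matrix(runif(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  m <- fit_maxent(P, B, reg_multiplier = 1e6)
  expect_equal(unname(m$weights), c(0, 0))
  # uniform q: logistic prediction is exactly 0.5 everywhere
  expect_equal(predict(m, B), rep(0.5, 30))
  expect_equal(m$entropy, log(30))
})

test_that("the fitted distribution is normalized and satisfies the KKT box", {
  set.seed(17)
  for (rep_i in 1:5) {
    d <- sample(2:5, 1)
    P <- matrix(runif(15 * d), 15, d)
    B <- matrix(runif(200 * d), 200, d)
    colnames(P) <- colnames(B) <- paste0("f", 1:d)
    m <- fit_maxent(P, B, reg_multiplier = 1, tol = 1e-8)
    q <- predict(m, B, type = "raw")
    expect_equal(sum(q), 1, tolerance = 1e-8)
    gap <- abs(m$background_expectations - m$presence_means)
    expect_true(all(gap <= m$beta + 1e-4),
                info = sprintf("replicate %d: max excess %.2e", rep_i,
                               max(gap - m$beta)))
  }
})

test_that("small instances match a direct numeric optimization oracle", {
  set.seed(23)
  for (rep_i in 1:3) {
    P <- matrix(runif(24), 12, 2, dimnames = list(NULL, c("a", "b")))
    B <- matrix(runif(80), 40, 2, dimnames = list(NULL, c("a", "b")))
    m <- fit_maxent(P, B, reg_multiplier = 1, tol = 1e-12, max_iter = 50000)
    beta <- m$beta
    orc <- stats::optim(c(0, 0), maxent_objective, P = P, B = B, beta = beta,
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 20000))
    expect_equal(-m$objective, orc$value, tolerance = 1e-5)
    expect_equal(unname(m$weights), orc$par, tolerance = 1e-3)
  }
})

test_that("stronger regularization never grows the weight norm", {
  set.seed(31)
  P <- matrix(runif(30), 15, 2, dimnames = list(NULL, c("a", "b")))
  B <- matrix(runif(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  norms <- sapply(c(0.5, 1, 2), function(r)
    sum(abs(fit_maxent(P, B, reg_multiplier = r, tol = 1e-10)$weights)))
  expect_true(all(diff(norms) <= 1e-6))
})

test_that("prediction is invariant to constant shifts in the linear score", {
  set.seed(41)
  B <- matrix(runif(100), 50, 2, dimnames = list(NULL, c("a", "b")))
  P <- matrix(runif(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  m <- fit_maxent(P, B)
  # adding a constant c to lambda . f multiplies exp() by e^c but the
  # normalizer absorbs it: recompute logZ with shifted eta
  shifted <- m
  shifted$logZ <- m$logZ + 5
  raw <- predict(m, B, type = "raw")
  eta_shift <- exp(as.vector(B %*% m$weights) + 5 - shifted$logZ)
  expect_equal(eta_shift, raw)
})

test_that("background sampling is seed-stable, masked-aware and capped", {
  st <- random_stack(tiny_spec(8), mask = c(3L, 17L))
  s1 <- sample_background(st, 20, seed = 5)
  s2 <- sample_background(st, 20, seed = 5)
  expect_identical(s1, s2)
  expect_length(s1, 20)
  expect_false(any(c(3L, 17L) %in% s1))
  expect_warning(all_cells <- sample_background(st, 10000, seed = 1),
                 "using all")
  expect_setequal(all_cells, valid_cells(st))
})

test_that("feature expansion scales to [0,1] on background and clamps beyond", {
  env <- cbind(x = c(0, 5, 10), y = c(100, 150, 200))
  ex <- feature_expansion(env)
  F <- expand_features(ex, env)
  expect_true(all(F >= 0 & F <= 1))
  expect_equal(colnames(F), c("x", "y", "x^2", "y^2"))
  # out-of-range values clamp, never extrapolate
  F2 <- expand_features(ex, cbind(x = c(-5, 20), y = c(0, 400)))
  expect_equal(unname(F2[, "x"]), c(0, 1))
  expect_equal(unname(F2[, "y"]), c(0, 1))
  expect_error(expand_features(ex, cbind(x = 1)), "missing covariate")
})

test_that("a strong-niche virtual species is recovered with high AUC", {
  sim <- simulate_study(grid_spec(60, 60, -120, 40, 1/3), seed = 2,
                        n_presences = 400)
  m <- suppressWarnings(maxent_sdm(sim$occurrences, sim$baseline_bioclim,
                                   seed = 2))
  expect_gte(m$evaluation$auc_test, 0.85)
  suit <- predict(m, sim$baseline_bioclim)
  v <- suit$values[is.finite(suit$values)]
  expect_true(all(v >= 0 & v <= 1))
})

test_that("fitted models survive a serialization round trip", {
  sim <- simulate_study(grid_spec(30, 30, -120, 40, 2/3), seed = 6,
                        n_presences = 120)
  m <- suppressWarnings(maxent_sdm(sim$occurrences, sim$baseline_bioclim,
                                   seed = 6))
  p <- withr::local_tempfile(fileext = ".yaml")
  write_maxent_sdm(m, p)
  back <- read_maxent_sdm(p)
  expect_equal(predict(back, sim$baseline_bioclim)$values,
               predict(m, sim$baseline_bioclim)$values, tolerance = 1e-12)
  expect_equal(back$thresholds$t_high, m$thresholds$t_high)
})

test_that("projection reports missing covariates and propagates nodata", {
  sim <- simulate_study(grid_spec(20, 20, -120, 40, 1), seed = 9,
                        n_presences = 60)
  m <- suppressWarnings(maxent_sdm(sim$occurrences, sim$baseline_bioclim,
                                   seed = 9))
  partial <- climate_stack(sim$baseline_bioclim$layers[
    setdiff(names(sim$baseline_bioclim), m$variables[1])])
  expect_error(predict(m, partial), m$variables[1], fixed = TRUE)
  # mask a cell in one needed layer -> nodata there in the prediction
  st <- sim$baseline_bioclim
  st$layers[[m$variables[1]]]$values[5, 5] <- NA
  suit <- predict(m, st)
  expect_true(is.na(suit$values[5, 5]))
})
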