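# Presence-background maximum-entropy habitat-suitability model.
#
# The model is a Gibbs distribution over a background sample of landscape
# cells, q_lambda(x) = exp(lambda . f(x)) / Z_lambda, fitted by maximizing
# the L1-penalized presence log-likelihood
#     (1/n) sum_i lambda . f(x_i) - log Z_lambda - sum_j beta_j |lambda_j|
# which is concave in lambda. At the optimum the KKT conditions confine the
# fitted feature expectations to a box around the presence feature means:
# |E_q[f_j] - mean_presence f_j| <= beta_j. Suitability is reported on the
# logistic scale p = c q~ / (1 + c q~) with c = exp(H), H the entropy of the
# fitted distribution over the background, so that a featureless model
# scores exactly 0.5 everywhere.

soft_threshold <- function(z, a) sign(z) * pmax(abs(z) - a, 0)

log_sum_exp <- function(v) {
  m <- max(v)
  m + log(sum(exp(v - m)))
}

#' Sample background cells from a stack
#'
#' Draws `n` distinct cells uniformly without replacement from the cells
#' valid in every layer (the standard landscape background of
#' presence-background modelling; presences are not excluded). If fewer
#' than `n` valid cells exist, all are used with a warning.
#'
#' @param stack A [climate_stack()].
#' @param n Target sample size; default 10000.
#' @param seed Integer seed; the same seed always returns the same cells.
#' @return Sorted integer vector of cell ids.
#' @export
sample_background <- function(stack, n = 10000, seed = 1L) {
  ok <- valid_cells(stack)
  if (!length(ok)) stop("stack has no valid cells")
  if (n >= length(ok)) {
    if (n > length(ok))
      warning(sprintf("requested %d background cells but only %d valid; using all",
                      n, length(ok)))
    return(ok)
  }
  sort(with_seed(seed, sample(ok, n)))
}

#' Define a feature expansion over environmental variables
#'
#' Records per-variable scaling constants (min and max on the background
#' sample) and the feature classes to build. Variables are min-max scaled to
#' `[0, 1]` on the background and clamped to `[0, 1]` wherever the expansion
#' is later applied, so projection onto novel climates never extrapolates in
#' feature space. Default feature classes are linear + quadratic; forward
#' hinge features with evenly spaced knots are optional.
#'
#' @param env Background matrix, cells x variables (named columns).
#' @param quadratic Add squared features? Default `TRUE`.
#' @param hinge Add hinge features? Default `FALSE`.
#' @param n_hinges Number of interior hinge knots per variable.
#' @return An object of class `feature_expansion`.
#' @export
feature_expansion <- function(env, quadratic = TRUE, hinge = FALSE,
                              n_hinges = 4L) {
  env <- as.matrix(env)
  if (is.null(colnames(env))) stop("env must have named columns")
  structure(list(
    variables = colnames(env),
    mins = apply(env, 2L, min, na.rm = TRUE),
    maxs = apply(env, 2L, max, na.rm = TRUE),
    quadratic = quadratic, hinge = hinge,
    knots = if (hinge) seq(0, 1, length.out = n_hinges + 2L)[-c(1L, n_hinges + 2L)]
            else numeric()
  ), class = "feature_expansion")
}

#' Apply a feature expansion
#'
#' @param expansion A [feature_expansion()].
#' @param env Matrix or data frame of raw environmental values containing
#'   every variable of the expansion.
#' @return Feature matrix with scaled values in `[0, 1]`.
#' @export
expand_features <- function(expansion, env) {
  env <- as.matrix(env)
  missing <- setdiff(expansion$variables, colnames(env))
  if (length(missing))
    stop("missing covariate(s): ", paste(missing, collapse = ", "))
  vars <- expansion$variables
  rng <- expansion$maxs - expansion$mins
  S <- vapply(vars, function(v) {
    if (rng[[v]] == 0) rep(0.5, nrow(env))
    else pmin(pmax((env[, v] - expansion$mins[[v]]) / rng[[v]], 0), 1)
  }, numeric(nrow(env)))
  if (!is.matrix(S)) S <- matrix(S, nrow = nrow(env),
                                 dimnames = list(NULL, vars))
  out <- S
  if (expansion$quadratic) {
    Q <- S^2
    colnames(Q) <- paste0(vars, "^2")
    out <- cbind(out, Q)
  }
  if (expansion$hinge) {
    for (k in expansion$knots) {
      Hf <- pmax((S - k) / (1 - k), 0)
      colnames(Hf) <- sprintf("hinge(%s,%.3g)", vars, k)
      out <- cbind(out, Hf)
    }
  }
  out
}

#' Fit a penalized maximum-entropy model on feature rows
#'
#' Low-level fitter operating directly on expanded feature matrices.
#' Maximizes the L1-penalized presence log-likelihood over the Gibbs
#' distribution defined on the background rows, by monotone proximal
#' gradient descent (iterative soft-thresholding with backtracking line
#' search) on the equivalent convex minimization. Per-feature penalties
#' default to `beta_j = reg_multiplier * s_j / sqrt(n)` with `s_j` the
#' presence standard deviation of feature j, floored at 0.001 so constant
#' features stay regularized.
#'
#' @param presences Feature matrix of presence rows (>= 1 row).
#' @param background Feature matrix of background rows (>= 2 rows), same
#'   columns as `presences`.
#' @param reg_multiplier Non-negative scalar multiplying all penalties;
#'   0 disables regularization.
#' @param beta Optional explicit per-feature penalty vector overriding the
#'   default.
#' @param tol Relative objective-change convergence tolerance.
#' @param max_iter Iteration cap.
#' @return An object of class `maxent_model` with elements `weights`,
#'   `beta`, `logZ` (over the background), `entropy`, `presence_means`,
#'   `background_expectations`, `background` (the feature matrix defining
#'   the normalizer), `iterations`, `converged`, `objective` (final
#'   penalized log-likelihood).
#' @export
fit_maxent <- function(presences, background, reg_multiplier = 1.0,
                       beta = NULL, tol = 1e-6, max_iter = 5000L) {
  P <- as.matrix(presences); B <- as.matrix(background)
  if (nrow(P) < 1L) stop("no valid presences")
  if (nrow(B) < 2L) stop("need at least 2 background rows")
  if (ncol(P) != ncol(B)) stop("presence and background feature sets differ")
  if (reg_multiplier < 0) stop("reg_multiplier must be >= 0")
  storage.mode(P) <- "double"; storage.mode(B) <- "double"
  d <- ncol(B)
  feat_names <- colnames(B)
  if (is.null(feat_names)) feat_names <- paste0("f", seq_len(d))
  n <- nrow(P)
  p_bar <- colMeans(P)
  if (is.null(beta)) {
    s <- if (n > 1L) apply(P, 2L, stats::sd) else rep(0, d)
    beta <- reg_multiplier * pmax(s, 1e-3) / sqrt(n)
  } else {
    beta <- rep_len(beta, d)
  }

  smooth_obj <- function(lambda) {
    eta <- drop(B %*% lambda)
    lz <- log_sum_exp(eta)
    list(g = lz - sum(lambda * p_bar), eta = eta, logZ = lz)
  }
  lambda <- rep(0, d)
  st <- smooth_obj(lambda)
  q <- exp(st$eta - st$logZ)
  grad <- drop(crossprod(B, q)) - p_bar
  obj <- st$g + sum(beta * abs(lambda))
  step <- 1.0
  iters <- 0L; converged <- FALSE
  for (it in seq_len(max_iter)) {
    iters <- it
    repeat {
      cand <- soft_threshold(lambda - step * grad, step * beta)
      delta <- cand - lambda
      st_new <- smooth_obj(cand)
      if (st_new$g <= st$g + sum(grad * delta) + sum(delta^2) / (2 * step) + 1e-12)
        break
      step <- step / 2
      if (step < 1e-12) { st_new <- st; cand <- lambda; break }
    }
    obj_new <- st_new$g + sum(beta * abs(cand))
    rel <- abs(obj - obj_new) / max(1, abs(obj))
    lambda <- cand; st <- st_new; obj <- obj_new
    q <- exp(st$eta - st$logZ)
    grad <- drop(crossprod(B, q)) - p_bar
    step <- min(step * 1.25, 1e6)
    if (rel < tol) { converged <- TRUE; break }
  }
  Eq <- drop(crossprod(B, q))
  entropy <- st$logZ - sum(lambda * Eq)
  structure(list(
    weights = stats::setNames(lambda, feat_names),
    beta = stats::setNames(beta, feat_names),
    reg_multiplier = reg_multiplier,
    presence_means = stats::setNames(p_bar, feat_names),
    background_expectations = stats::setNames(Eq, feat_names),
    logZ = st$logZ, entropy = entropy,
    background = B, n_presence = n,
    iterations = iters, converged = converged,
    objective = -obj
  ), class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("<maxent_model> %d features, %d presences, %d background rows\n",
              length(x$weights), x$n_presence, nrow(x$background)))
  cat(sprintf("  penalized log-likelihood %.6g after %d iteration(s)%s\n",
              x$objective, x$iterations,
              if (x$converged) "" else " (not converged)"))
  cat(sprintf("  nonzero weights: %d of %d; entropy H = %.4g\n",
              sum(x$weights != 0), length(x$weights), x$entropy))
  invisible(x)
}

#' @export
coef.maxent_model <- function(object, ...) object$weights

#' Predict suitability from expanded feature rows
#'
#' @param object A `maxent_model`.
#' @param features Feature matrix with the model's columns.
#' @param type `"logistic"` (default) for the 0-1 suitability index
#'   `c q~ / (1 + c q~)` with `c = exp(H)`, or `"raw"` for the normalized
#'   Gibbs density `exp(lambda . f - logZ)`.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.maxent_model <- function(object, features,
                                 type = c("logistic", "raw"), ...) {
  type <- match.arg(type)
  F <- as.matrix(features)
  raw <- exp(drop(F %*% object$weights) - object$logZ)
  if (type == "raw") return(raw)
  cq <- exp(object$entropy) * raw
  cq / (1 + cq)
}

#' Serialize a fitted SDM to a structured text file
#'
#' Writes everything needed to reproduce predictions (variables, scaling
#' constants, feature weights, penalties, `logZ`, entropy, thresholds and
#' the run seed) as YAML. The background feature matrix itself is not
#' stored; predictions depend on it only through `logZ` and the entropy.
#'
#' @param object A `maxent_sdm`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_maxent_sdm <- function(object, path) {
  stopifnot(inherits(object, "maxent_sdm"))
  e <- object$expansion
  yaml::write_yaml(list(
    variables = as.list(e$variables),
    mins = as.list(stats::setNames(as.numeric(e$mins), e$variables)),
    maxs = as.list(stats::setNames(as.numeric(e$maxs), e$variables)),
    quadratic = e$quadratic, hinge = e$hinge, knots = as.numeric(e$knots),
    weights = as.list(object$fit$weights),
    beta = as.list(object$fit$beta),
    reg_multiplier = object$fit$reg_multiplier,
    logZ = object$fit$logZ, entropy = object$fit$entropy,
    t_low = object$thresholds$t_low, t_high = object$thresholds$t_high,
    seed = object$seed, species = object$species
  ), path, precision = 15)
  invisible(path)
}

#' Load a serialized SDM
#'
#' @param path Path written by [write_maxent_sdm()].
#' @return A `maxent_sdm` object sufficient for prediction and
#'   classification (without the original background sample).
#' @export
read_maxent_sdm <- function(path) {
  y <- yaml::read_yaml(path)
  vars <- unlist(y$variables)
  expansion <- structure(list(
    variables = vars,
    mins = stats::setNames(unlist(y$mins)[vars], vars),
    maxs = stats::setNames(unlist(y$maxs)[vars], vars),
    quadratic = y$quadratic, hinge = y$hinge,
    knots = as.numeric(y$knots)
  ), class = "feature_expansion")
  fit <- structure(list(
    weights = unlist(y$weights), beta = unlist(y$beta),
    reg_multiplier = y$reg_multiplier,
    logZ = y$logZ, entropy = y$entropy
  ), class = "maxent_model")
  structure(list(species = y$species, fit = fit, expansion = expansion,
                 thresholds = threshold_pair(y$t_low, y$t_high),
                 seed = y$seed),
            class = "maxent_sdm")
}

#' Fit a presence-background habitat-suitability model
#'
#' The package's central fitting function. Given cleaned occurrences and a
#' covariate stack it (1) optionally thins records to one per grid cell,
#' (2) splits them into training and testing sets, (3) draws a uniform
#' background sample of valid cells, (4) optionally removes collinear
#' covariates by the Pearson + VIF rule on the background sample, (5)
#' min-max scales and expands the surviving covariates into linear (+
#' quadratic, optional hinge) features, (6) fits the L1-penalized
#' maximum-entropy model, and (7) evaluates it: training and held-out AUC
#' against seeded background samples, the least-training-presence threshold
#' and the sensitivity-specificity-sum-maximization threshold.
#'
#' All randomness derives from `seed`: the train/test split uses `seed`,
#' the training background `seed + 1`, and the evaluation background
#' `seed + 2`.
#'
#' @param occ An [occurrence_set()].
#' @param stack A [climate_stack()] of covariates.
#' @param background_n Background sample size (default 10000; capped at the
#'   number of valid cells).
#' @param reg_multiplier L1 penalty multiplier, default 1.
#' @param quadratic,hinge Feature classes; default linear + quadratic.
#' @param train_fraction Training proportion of occurrences, default 0.75.
#' @param thin Thin occurrences to one per cell first? Default `TRUE`.
#' @param select Apply Pearson/VIF covariate selection? Default `TRUE`.
#' @param pearson_threshold,vif_threshold Selection thresholds (0.7, 10).
#' @param seed Master seed for this fit.
#' @param tol,max_iter Optimizer convergence controls.
#' @return An object of class `maxent_sdm` with components `fit`
#'   (`maxent_model`), `expansion`, `selection` (`selection_report` or
#'   `NULL`), `thresholds` ([threshold_pair()]), `evaluation` (train/test
#'   AUC and band), `species`, `n_train`, `n_test`, `seed`.
#' @seealso [predict.maxent_sdm()], [classify_map()], [change_metrics()]
#' @examples
#' sim <- simulate_study(grid_spec(30, 30, -120, 40, 2/3), seed = 7,
#'                       n_presences = 150)
#' m <- maxent_sdm(sim$occurrences, sim$baseline_bioclim, seed = 7)
#' m
#' @export
maxent_sdm <- function(occ, stack, background_n = 10000,
                       reg_multiplier = 1.0, quadratic = TRUE,
                       hinge = FALSE, train_fraction = 0.75, thin = TRUE,
                       select = TRUE, pearson_threshold = 0.7,
                       vif_threshold = 10, seed = 1L, tol = 1e-6,
                       max_iter = 5000L) {
  stopifnot(inherits(occ, "occurrence_set"), inherits(stack, "climate_stack"))
  if (thin) occ <- thin_to_cells(occ, stack$spec, stack)
  if (nrow(occ$points) < 2L)
    stop("fewer than 2 occurrence records on valid cells")
  parts <- split_train_test(occ, train_fraction, seed = seed)

  bg_cells <- sample_background(stack, background_n, seed = seed + 1L)
  bg_env <- stack_matrix(stack, bg_cells)
  selection <- NULL
  if (select && ncol(bg_env) >= 2L) {
    selection <- select_variables(bg_env, pearson = pearson_threshold,
                                  vif = vif_threshold)
    if (!length(selection$kept)) stop("covariate selection kept no variables")
    bg_env <- bg_env[, selection$kept, drop = FALSE]
  }

  env_at <- function(o) {
    cells <- cell_of(stack$spec, o$points$lon, o$points$lat)
    m <- stack_matrix(stack, cells[!is.na(cells)])
    m <- m[, colnames(bg_env), drop = FALSE]
    m[stats::complete.cases(m), , drop = FALSE]
  }
  expansion <- feature_expansion(bg_env, quadratic = quadratic, hinge = hinge)
  F_bg <- expand_features(expansion, bg_env)
  F_train <- expand_features(expansion, env_at(parts$train))
  F_test <- expand_features(expansion, env_at(parts$test))
  if (!nrow(F_train)) stop("no valid presences")

  fit <- fit_maxent(F_train, F_bg, reg_multiplier = reg_multiplier,
                    tol = tol, max_iter = max_iter)

  train_scores <- predict(fit, F_train)
  bg_scores <- predict(fit, F_bg)
  eval_bg_cells <- sample_background(stack, length(bg_cells), seed = seed + 2L)
  eval_bg <- stack_matrix(stack, eval_bg_cells)[, colnames(bg_env), drop = FALSE]
  eval_bg_scores <- predict(fit, expand_features(expansion, eval_bg))
  test_scores <- if (nrow(F_test)) predict(fit, F_test) else numeric()
  train_auc <- auc(train_scores, bg_scores)
  test_auc <- if (length(test_scores)) auc(test_scores, eval_bg_scores)
              else NA_real_
  thresholds <- threshold_pair(ltp_threshold(train_scores),
                               max_sss_threshold(train_scores, bg_scores))

  structure(list(
    species = occ$species, fit = fit, expansion = expansion,
    selection = selection, thresholds = thresholds,
    evaluation = list(
      auc_train = train_auc, auc_test = test_auc,
      band = auc_band(if (is.na(test_auc)) train_auc else test_auc)),
    variables = colnames(bg_env),
    n_train = nrow(F_train), n_test = nrow(F_test),
    background_n = length(bg_cells), seed = seed
  ), class = "maxent_sdm")
}

#' @export
print.maxent_sdm <- function(x, ...) {
  cat(sprintf("<maxent_sdm> species '%s'\n", x$species))
  cat(sprintf("  covariates: %s\n", paste(x$variables, collapse = ", ")))
  cat(sprintf("  %d training / %d testing presences, %d background cells\n",
              x$n_train, x$n_test, x$background_n))
  if (!is.null(x$evaluation))
    cat(sprintf("  AUC train %.3f / test %.3f (%s)\n",
                x$evaluation$auc_train, x$evaluation$auc_test,
                x$evaluation$band))
  cat(sprintf("  thresholds: low %.4f (LTP), high %.4f (max SSS)%s\n",
              x$thresholds$t_low, x$thresholds$t_high,
              if (isTRUE(x$thresholds$flagged)) " [flagged: LTP > maxSSS]" else ""))
  invisible(x)
}

#' @export
summary.maxent_sdm <- function(object, ...) {
  print(object)
  cat("\nfeature weights (nonzero):\n")
  w <- coef(object)
  print(round(w[w != 0], 4))
  if (!is.null(object$selection) && nrow(object$selection$dropped)) {
    cat("\ncovariates dropped by collinearity filter:\n")
    print(object$selection$dropped, row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.maxent_sdm <- function(object, ...) object$fit$weights

#' @export
plot.maxent_sdm <- function(x, stack = NULL, ...) {
  if (is.null(stack)) {
    w <- coef(x)
    graphics::barplot(w, las = 2, cex.names = 0.7,
                      main = sprintf("%s: feature weights", x$species),
                      ylab = "weight")
  } else {
    plot(predict(x, stack), main = sprintf("%s: suitability", x$species), ...)
  }
  invisible(x)
}

#' Project a fitted SDM onto a climate stack
#'
#' Produces the logistic (or raw) suitability surface on any co-variate
#' stack containing the model's variables — baseline or future climate.
#' Cells missing any covariate become nodata; covariate values outside the
#' background's range are clamped into the scaled `[0, 1]` feature space.
#'
#' @param object A `maxent_sdm`.
#' @param stack A [climate_stack()], or a matrix/data frame of raw
#'   covariate values (one row per prediction).
#' @param type `"logistic"` (default) or `"raw"`.
#' @param ... Unused.
#' @return A `grid_layer` of suitability in `[0, 1]` when `stack` is a
#'   `climate_stack`; otherwise a numeric vector.
#' @export
predict.maxent_sdm <- function(object, stack, type = c("logistic", "raw"),
                               ...) {
  type <- match.arg(type)
  if (!inherits(stack, "climate_stack")) {
    F <- expand_features(object$expansion, stack)
    return(predict(object$fit, F, type = type))
  }
  missing <- setdiff(object$expansion$variables, names(stack$layers))
  if (length(missing))
    stop("stack is missing covariate layer(s): ",
         paste(missing, collapse = ", "))
  sub <- climate_stack(stack$layers[object$expansion$variables])
  cells <- valid_cells(sub)
  env <- stack_matrix(sub, cells)
  pred <- predict(object$fit, expand_features(object$expansion, env),
                  type = type)
  vals <- rep(NA_real_, stack$spec$n_rows * stack$spec$n_cols)
  vals[cells] <- pred
  grid_layer(stack$spec,
             matrix(vals, stack$spec$n_rows, stack$spec$n_cols),
             name = paste0("suitability_", object$species))
}
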