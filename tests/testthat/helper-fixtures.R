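# Shared fixtures: all inputs are built in code at test time.

tiny_spec <- function(n = 2, cell = 1, x = -10, y = 0)
  grid_spec(n, n, x_min = x, y_min = y, cell_size = cell)

# constant monthly climate on a tiny grid
const_climate <- function(tmin = 5, tmax = 15, prec = 50, spec = tiny_spec()) {
  mk <- function(v) lapply(1:12, function(m)
    matrix(v, spec$n_rows, spec$n_cols))
  monthly_climate(mk(tmin), mk(tmax), mk(prec), spec = spec)
}

# single-cell climate from explicit monthly vectors
cell_climate <- function(tmean, prec, diurnal = 1) {
  spec <- grid_spec(1, 1, 0, 0, 1)
  monthly_climate(
    tmin = lapply(tmean - diurnal, function(v) matrix(v, 1, 1)),
    tmax = lapply(tmean + diurnal, function(v) matrix(v, 1, 1)),
    prec = lapply(prec, function(v) matrix(v, 1, 1)),
    spec = spec)
}

# brute-force circular-quarter oracle: stats over all 12 windows of 3
# consecutive months (wrapping), independent of the package implementation
quarter_oracle <- function(tmean, prec) {
  qT <- sapply(1:12, function(w) mean(tmean[(w + 0:2 - 1) %% 12 + 1]))
  qP <- sapply(1:12, function(w) sum(prec[(w + 0:2 - 1) %% 12 + 1]))
  list(qT = qT, qP = qP,
       bio8 = qT[which.max(qP)], bio9 = qT[which.min(qP)],
       bio10 = qT[which.max(qT)], bio11 = qT[which.min(qT)],
       bio16 = qP[which.max(qP)], bio17 = qP[which.min(qP)],
       bio18 = qP[which.max(qT)], bio19 = qP[which.min(qT)])
}

# pair-counting AUC oracle
auc_oracle <- function(pres, bg) {
  wins <- ties <- 0
  for (p in pres) for (b in bg) {
    if (p > b) wins <- wins + 1
    else if (p == b) ties <- ties + 1
  }
  (wins + 0.5 * ties) / (length(pres) * length(bg))
}

# exhaustive-scan max-SSS oracle (integer counts keep comparisons exact)
max_sss_oracle <- function(pres, bg) {
  cand <- sort(unique(c(pres, bg)))
  best_t <- cand[1]; best <- -Inf
  for (t in cand) {
    s <- sum(pres >= t) * length(bg) + sum(bg < t) * length(pres)
    if (s > best) { best <- s; best_t <- t }
  }
  best_t
}

# small stack of independent uniform layers (for background sampling tests)
random_stack <- function(spec = tiny_spec(6), n_layers = 3, seed = 1,
                         mask = integer()) {
  set.seed(seed)
  layers <- lapply(seq_len(n_layers), function(i) {
    v <- matrix(runif(spec$n_rows * spec$n_cols), spec$n_rows, spec$n_cols)
    v[mask] <- NA
    grid_layer(spec, v, paste0("var", i))
  })
  climate_stack(layers)
}

# a filled scorecard answering every criterion at its maximum level
all_max_card <- function(schema, species = "sp") {
  answers <- lapply(schema$criteria, function(cr) {
    lv <- unlist(cr$levels)
    names(lv)[which.max(lv)]
  })
  names(answers) <- vapply(schema$criteria, function(cr) cr$id, "")
  scorecard(species, answers)
}

make_risk <- function(species, score)
  structure(list(species = species, score = score,
                 category = categorize(score), answered_fraction = 1,
                 insufficient = FALSE), class = "risk_result")

make_change <- function(baseline, future)
  structure(list(area_baseline = baseline, area_future = future,
                 delta = future - baseline,
                 pct_change = if (baseline > 0) 100 * (future - baseline) / baseline else NA_real_,
                 ratio = if (baseline > 0) future / baseline else NA_real_,
                 new_habitat_flag = baseline == 0 && future > 0,
                 which_class = 2), class = "habitat_change")
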