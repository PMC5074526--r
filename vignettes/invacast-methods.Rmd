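---
title: "Methods: habitat suitability, risk scoring and prioritisation in invacast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: habitat suitability, risk scoring and prioritisation in invacast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invacast)
```

`invacast` combines two independent lines of evidence about a potential
plant invader — a trait-based invasiveness score and a climate-driven
habitat-suitability projection — into a single ranked priority list. This
vignette is the package's own account of the models, the parameters that
matter, the numerical choices, and what the simulated validation does and
does not demonstrate.

## 1. The maximum-entropy suitability model

### Model

Presence-only records carry no absences, so the model contrasts presences
with a *background* sample of landscape cells. Over the background, the
model is the Gibbs distribution

$$ q_\lambda(x) = \frac{\exp(\lambda \cdot f(x))}{Z_\lambda}, \qquad
   Z_\lambda = \sum_{x \in \text{background}} \exp(\lambda \cdot f(x)), $$

whose weights maximize the penalized presence log-likelihood

$$ \frac{1}{n}\sum_{i=1}^{n} \lambda \cdot f(x_i) \;-\; \log Z_\lambda
   \;-\; \sum_j \beta_j\,|\lambda_j| . $$

This objective is concave, and its optimum is the maximum-entropy
distribution whose feature expectations lie within $\beta_j$ of the
presence means (the KKT box constraint
$|E_q[f_j] - \bar f_j| \le \beta_j$, verified post hoc in the tests). The
assumptions are those of any correlative distribution model: occurrences
sample the environments a species can occupy, the species is near
equilibrium with climate, and the chosen covariates capture the relevant
gradients. For invaders mid-expansion the first two are approximations —
pooling native and invaded ranges mitigates but does not remove this.

### Features

Covariates are min–max scaled to $[0,1]$ on the background, and the
default expansion is **linear + quadratic** per covariate, enough to
express unimodal (Gaussian-like) responses while keeping small instances
amenable to independent numeric verification. Forward hinge features with
evenly spaced knots are available (`hinge = TRUE`) but off by default.
When projecting onto new climates, covariates are clamped into the
background's scaled range, so features never extrapolate beyond $[0,1]$.

### Regularization

$\beta_j = r \, s_j / \sqrt{n}$, with $s_j$ the presence standard
deviation of feature $j$, $n$ the number of presences, and $r$ the
`reg_multiplier` (default 1, dimensionless). The $1/\sqrt n$ scaling makes
the penalty commensurate with the sampling error of the presence mean; a
floor of $10^{-3}$ on $s_j$ keeps constant features regularized. Setting
$r = 0$ removes the penalty entirely (used by the closed-form tests);
increasing $r$ can only shrink $\sum_j |\lambda_j|$ (a tested property of
the penalty path).

### Optimizer

Monotone proximal-gradient descent (iterative soft-thresholding) with
backtracking line search on the smooth part, step growth 1.25 after each
accepted step. Convergence is declared when the relative change of the
penalized objective falls below `tol` (default $10^{-6}$), capped at
`max_iter` (default 5000) iterations; both are part of the function's
contract. The log-partition uses the log-sum-exp guard, so large weights
never overflow. Tests verify agreement with a direct Nelder–Mead
optimization of the same objective on two-feature instances and with the
single-feature moment-matching closed form.

### Suitability output

The raw output $\tilde q(x) = \exp(\lambda \cdot f(x) - \log Z)$ is the
normalized Gibbs density. The reported 0–1 index is the logistic transform
$p = c\tilde q/(1 + c\tilde q)$ with $c = \exp(H)$, $H$ the entropy of the
fitted distribution over the background: a model with no information
($\lambda = 0$) then scores exactly 0.5 everywhere, which anchors the
scale. Both outputs are available; thresholds are computed on the logistic
scale.

## 2. Covariates and their selection

The 19 bioclimatic variables are derived from monthly `tmin`/`tmax`/`prec`
climatologies under the standard conventions: monthly mean temperature is
$(t_{\min}+t_{\max})/2$; quarters are *circular* windows of three
consecutive calendar months (December–February wraps); temperature
seasonality (BIO4) is $100\times$ the population standard deviation of
monthly means; precipitation seasonality (BIO15) is the coefficient of
variation with the monthly mean offset by $+1$ mm so fully arid cells stay
finite (a documented deviation that matters only where mean precipitation
is near zero). Two tie-break and degeneracy rules are fixed: equal
quarters resolve to the earliest calendar window, and isothermality (BIO3)
is defined as 0 where the annual range is zero. Temperatures are °C and
precipitation mm throughout — the integer ×10 packing of some distributed
datasets is deliberately not reproduced.

Collinearity filtering runs in the order Pearson then VIF, on the
background sample rather than every map cell, so that selection reflects
the fitting domain. The Pearson stage repeatedly takes the most correlated
pair with $|r|$ strictly above 0.7 and drops the member with the larger
mean absolute correlation against the remaining variables (ties to the
later input column); the VIF stage iteratively removes the variable with
the largest $\mathrm{VIF} = 1/(1-R^2) > 10$, with exact collinearity
yielding an infinite VIF and an immediate drop rather than a numerical
failure. Both thresholds are exposed (`pearson_threshold`,
`vif_threshold`). Which variables survive depends on the dataset; the
report records every drop with its statistic so the selection is
reproducible.

## 3. Evaluation, thresholds and habitat change

Records are thinned to one per grid cell (half-open cells, first record
kept — deterministic), split 75/25 into training and testing uniformly at
random by record (no spatial blocking is attempted), and evaluated by
rank-based AUC with midrank ties: the probability that a random presence
outscores a random background cell. Test AUC uses the held-out quarter
against a freshly seeded background sample of the same size.

Two thresholds cut continuous suitability into three classes:

* `t_low`, the **least training presence** threshold — the minimum
  suitability among training presences, guaranteeing 100% training
  sensitivity; cells at or above it are *suitable low-risk habitat*;
* `t_high`, the **max sensitivity + specificity** threshold — the scan
  over observed scores maximizing sensitivity plus specificity
  (specificity measured against the background, the standard stand-in for
  absences). Cells at or above it are *suitable high-risk habitat*.

The scan compares the integer-valued count form of the objective, so ties
are exact and resolve to the smallest candidate threshold. Thresholds are
computed on the training set only, consistent with the "training presence"
definition of the lower cut. With very few presences `t_low` can exceed
`t_high`; the pair is then repaired (`t_high` raised to `t_low`) and
flagged rather than treated as an error.

Areas are geodesic: each cell contributes
$R^2\,\Delta\lambda\,(\sin\varphi_{top}-\sin\varphi_{bot})$ km² with $R =
6371$ km, so counts of poleward cells are not inflated. Change metrics
(delta, percent change, ratio) default to the high-risk class, which is
the prioritisation axis; a zero-baseline future gain is reported as
new-habitat with the undefined percent/ratio left `NA` by design.

## 4. Risk scoring and prioritisation

The scoring engine is schema-driven: 21 criteria in the four attribute
groups (ecological impact, invasive characteristics, dispersal ability,
feasibility of control), each with a points ladder. The shipped default
schema is an *editable stand-in* with that structure and group maxima
40/25/25/10 (a common weighting for biodiversity-focused ranking forms);
the arithmetic, which is fixed, is

$$ \text{score} = 100 \cdot
   \frac{\sum_{\text{answered}} \text{earned}}
        {\sum_{\text{answered}} \text{max points}} $$

with unknown answers excluded from numerator and denominator alike, so
partial knowledge is never penalized. A result answering less than 80% of
criteria (configurable) is flagged "insufficient information" instead of
being silently trusted. Category bands are half-open intervals with cut
points 40/50/60/70/80, so non-integer scores always land in exactly one
band. Proprietary climate-match pre-screening is out of scope; the schema
carries a free-text pre-screen note instead.

Prioritisation is deliberately lexicographic — category tier first, then
the high-risk habitat delta, then species name — because the combination
of the two axes is a policy judgement, not an estimable quantity; a
`rank_within = "score"` option ranks by the numeric score instead of the
six-level category, and the comparison table always shows what ranking by
either axis alone would have produced. The "high" priority tier requires
at least a Highly Invasive category *and* a projected habitat gain (or new
habitat from a zero baseline).

## 5. The virtual-species generator

The generator exists so that every stage can be validated against known
truth. It emulates:

* smooth, spatially autocorrelated monthly temperature and precipitation
  fields — a latitudinal gradient ($25 - 0.5\,|\text{lat}|$ °C annual
  mean by default), a July-peaked seasonal cosine (amplitude 15 °C), and
  white noise convolved with a small box kernel (temperature SD 0.5 °C,
  precipitation SD 8 mm);
* a virtual species with a Gaussian niche on derived bioclim variables
  (default optimum BIO1 = 6 °C, BIO12 = 850 mm; breadths 1.5 °C and
  200 mm), whose true suitability and true suitable area (cutoff 0.5) are
  analytic;
* presence sampling proportional to true suitability, at cell centres;
* a future climate that is the baseline plus a uniform +3 °C and a ×1.1
  precipitation multiplier — so, e.g., future BIO1 minus baseline BIO1 is
  exactly 3 everywhere, a property the tests assert.

The default optimum sits just beyond the warm edge of the default
baseline grid (latitudes 40–60, annual means ≈ −5 to 5 °C), so warming
moves the optimum poleward onto the grid and the true suitable area
grows — the poleward-expansion situation the pipeline is designed to
rank. The default breadths constitute a strong niche: the suitability
truth itself separates suitability-weighted presences from uniform
background cells with an AUC of about 0.9, so excellent discrimination is
attainable in principle; this was fixed from the data-generating truth,
not from any fitted model.

What the generator does **not** emulate — and therefore what passing tests
do not demonstrate about real data: spatial sampling bias in occurrence
records, topography and non-climatic constraints (soils enter only if
supplied as extra covariate layers), niche shapes beyond smooth unimodal
responses, dispersal limits, biotic interactions, and non-uniform climate
change. Recovery results on the simulator are a check of internal
correctness and calibration, not of transferability to any real region.

## 6. Validation design and problem sizes

The test-suite checks were sized to run comfortably on a single CPU while
keeping each statistical check well-powered:

* oracle equivalences (AUC pair counting, max-SSS exhaustive scan,
  VIF normal equations, bioclim 12-window scan, maxent closed forms and
  Nelder–Mead comparison) on hundreds of small random instances;
* null calibration: the full model fitted to 200 uniformly placed
  presences on a 60 × 60 synthetic grid, 50 seeded replicates — mean
  held-out AUC must sit at chance (0.45–0.55). This is also the quantity
  `scripts/acceptance.R` recomputes;
* parameter recovery: the full pipeline on the generator defaults
  (100 × 100 grid at 0.2°, 500 presences, +3 °C future), 20 seeds — the
  sign of the estimated high-risk area change must match the true
  suitable-area change and held-out AUC must reach 0.85 in at least 90%
  of seeds;
* determinism: a complete two-run pipeline comparison on a 30 × 30
  workspace, byte-identical priority tables required.

All randomness flows from explicit integer seeds through a private RNG
scope (`with_seed`), so package calls never disturb the caller's random
stream and identical seeds give identical results, including across the
train/test split (`seed`), training background (`seed + 1`) and
evaluation background (`seed + 2`) of one model fit.

## 7. Known limitations

* The estimator ships with linear + quadratic features by default;
  strongly multimodal or threshold responses need `hinge = TRUE`, at the
  cost of more features to regularize.
* Specificity and AUC are computed against background, not true absences;
  their absolute values depend on the extent of the background landscape
  (AUC on a larger, more heterogeneous extent is optimistically larger).
* Thinning keeps one record per cell but does not correct broader spatial
  sampling bias.
* The grid model is unprojected lon/lat with square cells; there is no
  reprojection or resampling — inputs must be co-registered beforehand,
  and non-square cells are rejected rather than resampled.
* The default risk schema is a structural stand-in; real assessments
  should load the jurisdiction's own criteria file.
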