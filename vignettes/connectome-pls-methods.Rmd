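---
title: "Methods: behavioral PLS and segregation analysis of functional connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavioral PLS and segregation analysis of functional connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model the package implements, the
conventions and numerical choices it makes where several are defensible, the
design of the synthetic cohort generator, and the limits of what the test
suite can show about real data.

## The model

### Behavioral PLS

Let `Y` be the n x V design matrix of z-scored subject variables (here age
in years and D1-receptor binding potential, both standardized with the
sample SD, n−1 divisor) and `X` the n x E matrix of connectome edges in the
canonical row-major upper-triangle order. The variables-by-edges correlation
matrix `R = cor(Y, X)` is decomposed by SVD, `R = U S Vᵀ`. We call the
edge-side singular vectors (columns of `V`) *brain saliences* and the
variable-side vectors *design saliences*, independent of how `R` is stored.
Brain scores are `X v` per latent variable (LV); the cross-block variance
fraction of LV i is `sᵢ²/Σs²`. The assumptions are those of the correlation
matrix itself: linear marginal associations, no subject weighting, and
subjects exchangeable under the null.

Because V is small (2 here) and E large (34,716 at study scale), the SVD is
computed from the V x V Gram matrix `RRᵀ`: its eigenvalues are the squared
singular values, its eigenvectors the design saliences, and brain saliences
follow as `Rᵀu/s`. This is algebraically the SVD at a fraction of the cost;
the test suite checks it against a direct decomposition at 1e-8.

### Inference

*Permutation test.* Design rows are permuted with edges fixed; each LV's
observed singular value is compared with the permutation distribution of the
same-ranked singular value. The Monte-Carlo p uses the add-one estimator
`(1 + #{s* ≥ s}) / (n_perm + 1)`, so the smallest attainable p with 1000
permutations is 1/1001 and p = 0 is never reported. Two alternatives are
built in: comparison against the permuted *maximum* singular value
(conservative for lower-ranked LVs), and exhaustive enumeration of all n!
permutations for n ≤ 8, whose p is the exact proportion (identity included,
so again p > 0). Per-rank testing is the default; for the dominant LV the
two conventions coincide.

*Bootstrap ratios.* Subjects are resampled with replacement and the PLS
refit per replicate. The resampled quantity is the singular-value-scaled
salience `v·s = Rᵀu` — the projection of the replicate correlation matrix
onto the design direction — rather than the unit-norm salience: the
unit-norm constraint couples all edges through the normalization and makes
the bootstrap SE understate sampling variability (empirically, null
`|BSR| > 2.8` rates near 5% instead of the nominal ≈0.5%). With the scaled
salience the BSR behaves like a standard normal deviate under the null; the
acceptance suite verifies the `|BSR| > 2.8` exceedance lies in
[0.002, 0.010] over >10,000 null edges. Replicates are aligned to the
original fit by per-LV sign flip (dot product); an orthogonal-procrustes
alignment is available for designs where neighboring LVs have similar
singular values. Replicates in which a design variable becomes constant are
redrawn and counted. Implementation note: replicates are evaluated through
per-subject resampling weights against the fixed edge matrix (no n x E copy
per replicate), which is numerically identical to explicit row indexing and
about two orders of magnitude faster.

*Sign convention.* The sign of an LV is pure convention. `fit_pls()` makes
the largest-magnitude design-salience entry positive, which is deterministic
and applied identically to permutation and bootstrap replicates. For an
aging study that convention usually orients the dominant LV along *age*, so
that higher brain scores mean more dedifferentiated connectomes.
`orient_lv(fit, "d1dr_bpnd")` flips LVs so the receptor's design salience is
positive — higher scores then mean more segregated, youth-like connectomes —
and all reported group comparisons and the worked examples use that
orientation. Both orientations describe the same model.

### System segregation

`S = (W − B)/W` with `W`/`B` the mean within-/between-network edge value.
Negative Fisher-z edges are zeroed before averaging by default, following
the metric's standard formulation; `keep` and `absolute` policies are
available and recorded per call, since published pipelines differ and the
choice changes the score's range. `S` is undefined when `W = 0` (an error,
not an NA), is invariant to positive rescaling of all edges, and decreases
strictly in `B` for fixed `W > 0`.

### Network-block permutation test

The BSR matrix is thresholded at `|BSR| ≥ 2.8` into a positive (0/1) and a
negative (0/−1) matrix; block (A,B) averages all distinct node pairs with
the diagonal excluded (within-network blocks use their unordered pairs;
networks of size 1 have no within pairs and report `NA`). The null shuffles
node-to-network labels, preserving network sizes exactly in every draw.
Positive blocks are tested one-sided against null means ≥ observed, negative
blocks against null means ≤ observed, both with the add-one estimator —
"more extreme" is defined per sign.

### Downstream statistics

- Working-memory tasks are T-standardized (mean 50, SD 10, sample-SD
  divisor) and averaged into a composite; subjects missing any task are
  excluded (complete-case), a package choice where no published convention
  exists.
- `fit_ols()` reports, per focal predictor, the drop-one adjusted-R²
  increment `ΔR²adj = R²adj(full) − R²adj(without predictor)`. This is one
  of several "per-predictor adjusted R²" conventions (semi-partial and
  partial variants exist); it is labeled as such in every report rather than
  asserted as canonical.
- "Age-adjusted D1DR" means residuals of an OLS regression on age with
  intercept, computed within the analysis subsample (age ≥ 40 for the
  maintenance comparison); the linear form is a package choice.
- The two-group split of 1-D values scans all sorted-split thresholds and
  minimizes within-cluster sum of squares — the global optimum of
  two-cluster k-means in one dimension, but deterministic. Lloyd iterations
  from extreme-point starts can stall in local optima on overlapping data
  (the test suite demonstrates this), which is why the exhaustive scan is
  used instead of a seeded k-means. Ties cannot straddle the boundary;
  adding a constant to all values leaves the partition unchanged.
- ANCOVA is an OLS partial F-test on the group indicator (df 1, n−k−1) with
  covariate-adjusted group means evaluated at the covariate means.

### Graph construction

RMS displacement at volume t is the root of the mean of the six squared
backward differences of the rigid-body parameters, rotations first converted
to arc length at a 50 mm radius; the first volume is 0 and volumes above
0.25 mm receive one-hot spike regressors. The radius, the RMS-vs-sum choice
and the threshold are parameters, since conventions differ across pipelines.
Cleaning is one joint least-squares regression per node: trends, expanded
confounds (raw, squares, backward-difference derivatives, squared
derivatives; all-constant columns dropped), spike regressors, and
sine/cosine regressors at every discrete Fourier frequency of the run
outside the 0.008–0.09 Hz band — fitting the spectral and nuisance
regressors simultaneously avoids re-introducing removed variance, and makes
the operation idempotent for a fixed design. The whole-brain mean signal is
included by default and excludable (`include_global_signal = FALSE`) to
mirror no-GSR sensitivity pipelines. Correlations are clipped to
±(1 − 1e−7) before `atanh` so degenerate pairs stay finite (logged when
triggered), and the diagonal is set to zero.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes, at
the study's scale: 30 subjects per decade from 20 to 80 (50% female per
decade), D1DR binding potential with mean 1.95 at the age-40 knot, slopes
−0.008/yr before and −0.011/yr after, and residual SD 0.2 — values chosen
to reproduce the binding-potential levels, the mid-life regime shift, and an
age–D1DR correlation of about −0.66 typical of lifespan PET samples.

Connectome edges follow a block model: Fisher-z baselines 0.6 within and 0.3
between networks, plus, on a randomly chosen 25% of edges in each class,

    edge = baseline + β_age·z(age) + β_d1·z(D1DR) + λ·η + ε,

with η a standard-normal subject factor shared across affected edges and ε
independent edge noise (SD 0.1). The signs implement dedifferentiation:
affected within-network edges lose connectivity with age and gain with
D1DR, between-network edges the reverse. The subject factor η is the one
structural addition beyond the minimal slopes-plus-noise model, and it is
load-bearing: with only two observed variables and independent edge noise,
the latent correlations of any planted pattern are confined to the ellipse
`rᵀΣ⁻¹r = 1` of the design correlation matrix, so the empirically plausible
pair (−0.8 with age, +0.6 with D1DR) is unreachable — it would require an
age–D1DR correlation near −0.96. η represents individual differences in
expression of the dedifferentiation pattern not explained by age or
receptor availability, and places the planted latent correlations strictly
inside the feasible region at the targeted values.

The default effect magnitudes (within 0.0875, between 0.056, split into the
β and λ components via `c₀ = Σ⁻¹r` at the population age–D1DR correlation)
were calibrated once so that (i) the planted latent correlations are
approximately −0.8 (age) and +0.6 (D1DR), and (ii) the dominant salience
pattern is recoverable at n = 180 with cosine ≥ 0.9 — affected
within-network edges then correlate with age at up to |r| ≈ 0.5, at the
upper end of what lifespan connectivity samples show. The recorded ground
truth is computed, not assumed: `true_salience` is the unit-norm top
singular vector of the edges-by-design covariance pattern restricted to
affected edges (exactly invariant to rescaling all betas), and the planned
latent correlations follow in closed form including the η and edge-noise
attenuation, using the realized sample covariance of the cohort.

Working memory is generated from the planted pattern: a latent ability
`γ·z(true score) + noise` with γ = 0.35 (chosen to give a standardized
brain-score–working-memory coefficient near 0.3), measured by three tasks
with loading 0.6 each, mapped to the documented integer ranges (letter
0–48, number 0–108, spatial 0–30).

What the generator does **not** emulate: spatial embedding of parcels,
heavy-tailed or heteroscedastic edge noise, motion artifacts correlated
with age, scanner or session effects, network-specific effect
topographies, and any nonlinearity in the age trends beyond the D1DR knot.
Passing recovery tests therefore shows the estimator chain is correct and
calibrated under the assumed structure — not that real data satisfy that
structure.

## Numerical choices and degenerate inputs

- Edge order is row-major upper-triangular (i < j), fixed everywhere;
  vectorize/unvectorize round-trip exactly.
- Symmetry tolerance for input matrices is 1e−8; nonzero diagonals are
  zeroed with a warning; non-finite entries are errors.
- Zero-variance edges get correlation 0 (with a logged count) instead of
  being dropped, preserving edge indexing; zero-variance design columns are
  errors.
- Singular vectors with singular value ≤ 1e−12·max are returned as zero
  vectors; bootstrap SEs of exactly zero yield `NA` ratios.
- The r-clipping bound 1 − 1e−7 caps Fisher z at ≈ 8.4.
- Exhaustive permutation is limited to n ≤ 8 (40,320 refits).
- D1DR draws are truncated at 0 (binding potentials are non-negative).

## Scales used by the test suite

Validation studies run at sizes chosen to exercise the full pipeline within
a short default test run: oracle comparisons on ≤ 10 nodes / ≤ 8 subjects;
type-I calibration on 200 null cohorts of n = 60 with 20-node graphs and
200 permutations; BSR calibration on one null cohort of n = 180 with a
150-node graph (11,175 edges) and 500 bootstraps; parameter recovery and
the directional replication at the full 180-subject, 264-node scale, with
the group-direction checks averaged over 40 replicate 100-node cohorts
because the receptor's unique (age-independent) contribution is small by
design — matching the modest partial effects such studies report — and a
single cohort's group difference in working memory is sign-unstable.

## Known limitations

- Only the behavioral (correlation-based) PLS variant is implemented; no
  task PLS, multi-block, or regularized variants.
- The permutation test treats subjects as exchangeable; family structure or
  site effects would need a restricted permutation scheme.
- Percentile bootstrap CIs for latent correlations inherit the optimism of
  in-sample scores; they quantify stability, not out-of-sample effect size.
- The cleaning module is a simplified stand-in for a full fMRI preprocessing
  pipeline: no slice timing, realignment, distortion correction, or spatial
  normalization — it starts from extracted node timeseries.
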