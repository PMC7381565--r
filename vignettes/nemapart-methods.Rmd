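---
title: "Methods: partitioning contemporary and historical drivers of soil nematode communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partitioning contemporary and historical drivers of soil nematode communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question and the inference chain

Soil nematode diversity varies along large-scale gradients, and both
contemporary conditions (current climate, soil chemistry) and historical
legacies (climate change since the Last Glacial Maximum, ~21,000 years ago)
are candidate drivers. Because these drivers are strongly collinear across a
latitudinal gradient, single-predictor regressions cannot separate them.
`nemapart` implements the full chain needed to ask how much of the variation
in diversity and composition is *uniquely* attributable to each of three
predictor sets — climatic {MAT, MAP, TS, PS}, soil {SOC, TN, pH}, historical
{TA, PA, TCV, PCV} — and how much is shared among them.

The chain is:

1. **Historical predictors** (`derive_historical`). From co-registered
   current and LGM grids of mean annual temperature and precipitation:
   anomaly = current − LGM (signed); spatial gradient = central differences
   over the four rook neighbours, in variable units per km; change velocity
   = |anomaly| / gradient, in km; TCV and PCV are log10 of the raw
   velocities.
2. **Responses** (`diversity_table`, `jaccard_dist`, `braycurtis_dist`).
   Genus richness, Shannon's diversity $-\sum_i p_i \ln p_i$, and pairwise
   Jaccard $(b+c)/(a+b+c)$ and Bray–Curtis
   $\sum_i |x_{ij}-x_{ik}| / (\sum_i x_{ij} + \sum_i x_{ik})$ dissimilarity.
3. **Variation partitioning** (`en_varpart`). Elastic-net regressions of the
   response on all seven combinations of the three sets; the adjusted
   $R^2 = 1-(1-R^2)(n-1)/(n-p-1)$ of each combination, averaged over
   repeated cross-validation runs, enters an inclusion–exclusion
   decomposition into three pure, three pairwise-shared and one
   triple-shared fraction. Significance of each fraction comes from
   permuting the response.
4. **Composition analyses** (`nmds_ord`, `env_vector_fit`, `mantel_test`,
   `db_varpart`). NMDS ordination, environmental vectors with permutation
   p-values, a Mantel test against great-circle spatial distance, and the
   distance-based analogue of the partition: site-pair dissimilarities
   regressed on per-set Euclidean distances computed over all principal
   components of the standardized set variables.

## The elastic-net fits

The elastic net blends ridge and lasso penalties; `alpha` sets the blend and
`lambda` the shrinkage. Both are tuned by fivefold cross-validation,
selecting the pair that minimizes CV RMSE. Choices the tuning procedure had
to make, and why:

* **Grid.** `alpha` defaults to {0.05, 0.10, …, 1.0}; the `lambda` path per
  alpha is glmnet's own 50-point geometric path from the data-derived
  $\lambda_{max}$, **plus an exact unpenalized endpoint at
  $\lambda = 0$** computed by least squares (which is what the elastic net
  degenerates to there). The endpoint lets CV select the OLS model when no
  shrinkage helps, and makes noiseless relationships reach $R^2 = 1$
  exactly.
* **Standardization.** Predictors are centred and scaled to unit variance
  before penalization (penalties are not scale-invariant); coefficients are
  reported on the standardized scale.
* **Tie-breaking.** Among (alpha, lambda) pairs whose CV RMSE ties within
  1e-12, the smallest alpha and then the largest lambda wins: the most
  shrunken, most parsimonious model, deterministically.
* **$R^2$.** In-sample on the full-data refit at the selected pair, so one
  model yields one $R^2_{adj}$ per CV run; the mean over `repeats` runs
  (default 100) damps fold-assignment noise.
* **$p$ in the adjustment** counts the predictors *offered* to the model,
  not those surviving shrinkage (an option switches to selected-only).
  With 16 sites and 11 predictors the full-model adjustment is severe —
  negative adjusted $R^2$ and negative fractions are expected and retained
  as-is in the arithmetic.

## Permutation inference

Null distributions for the seven fractions and three set totals are built by
randomly reordering the response and re-running the entire partition
(default: re-tuning alpha and lambda per permutation, the more conservative
choice; reusing the observed tuning is available as `retune = FALSE`). The
reported p-value is $(1 + \#\{null \ge obs\})/(1 + n_{perm})$, and a
fraction is additionally flagged significant when it exceeds the 95%
quantile of its null — both one-sided, matching the quantile rule.

When only some fractions are of interest, `perm_fractions` restricts the
per-permutation refits to the combinations those fractions need (for
example, the null of a set total needs only that set's model). The null
distribution of the requested fraction is identical to the full
recomputation; it is purely a pruning of unused work.

The null permutations default to `repeats_null = 10` CV repeats against 100
for the observed partition: a fidelity knob documented here because the
999-permutation, 7-combination refit is the computational bottleneck of the
whole method.

`morans_i` checks full-model residuals for spatial autocorrelation with
inverse-great-circle-distance, row-standardized weights (the weighting is a
package choice; the statistic follows the standard
$(n/S_0)\, z'Wz / z'z$ form) and a two-sided permutation p-value measured as
departure from the permutation mean.

## The distance-based partition

Strictly-lower triangles of the response and predictor distance matrices are
unfolded and regressed by least squares; the same adjusted-$R^2$ formula is
applied with $n$ = number of site pairs and $p$ = number of distance
predictors. Site pairs are not independent, so these adjusted values are
descriptive rather than inferential — the permutation test, which relabels
*sites* (simultaneous row/column permutation, never independent triangle
entries), carries the inference. Per-set distances are Euclidean over all
principal components of the standardized set variables, which equals the
Euclidean distance on the standardized variables themselves (orthogonal
rotation); constant variables are dropped with a warning.

## The synthetic generator

`sim_dataset` emulates the targeted study design: 16 sites spanning 22–40°N,
three plots per site averaged to site level, ~150 individuals identified per
plot (a multinomial draw), and a 64-genus pool. Its statistical skeleton:

* Each predictor set is driven by one latent factor
  $L_s = \sqrt{\rho}\, z + \sqrt{1-\rho}\, \varepsilon_s$, with $z$
  standardized latitude, so any two set latents correlate at $\rho$
  (`cross_set_correlation`, default 0.6 — field tables of this kind are
  highly collinear). The 11 observed variables are noisy linear readouts of
  their set latent on realistic scales (e.g. MAT in °C declining northward,
  TCV as log10 km).
* A latent diversity driver $d = \sum_s e_s L_s + \mathrm{noise}$ applies
  the configured `effect_sizes` (standardized slopes). Communities follow
  Gaussian niche curves along $d$ with genus optima spread uniformly and a
  common baseline breadth; the *effective* breadth widens with $d$
  (`evenness_gain`), so sites high on the driver are richer and more even.
  A lognormal genus-amplitude term gives the uneven abundance distribution
  typical of nematode samples.
* Defaults (`niche_breadth = 0.35`, `evenness_gain = 0.5`,
  `noise_sd = 1.1`, effects climatic −1, soil −0.4, historical −0.2) were
  chosen once to reproduce the descriptive regime of genus-level field
  data on such gradients — site richness roughly 10–45 of 64 genera
  (mean ≈ 27), Shannon ≈ 2–3.5, diversity–latitude correlations around
  −0.7, and a full-model adjusted $R^2$ that is modest and highly variable
  at 16 sites — and are not tuned further.
* `truth` records the analytic generating fractions: the population $R^2$
  of $d$ on each subset of latents follows from their known joint-normal
  covariance and passes through the same inclusion–exclusion as the
  estimator. `sim_null_dataset` zeroes all effects, giving the type-I-error
  harness.
* One master seed feeds named substreams (coordinates, environment,
  driver, community, grids), so adding one component never perturbs
  another's draws, and plot-level variance is exposed (`plot_sd`) rather
  than fixed — nothing in the emulated design pins it.

What the generator does **not** emulate: the spatial covariance of real
climate rasters, phylogenetic structure among genera, seasonal dynamics,
and non-linear latitude–environment links. Passing tests therefore
demonstrate that the estimator recovers known structure under the stated
sampling design, not that any particular field system satisfies the
generator's assumptions.

## Paleo-grid numerics

* Gradient stencil: symmetric central differences over the four rook
  neighbours; edge cells and cells with a nodata neighbour are nodata (no
  one-sided fallback, keeping the stencil unbiased).
* Degree-referenced grids convert spans to km with 111.32 km/degree and a
  cos(latitude) correction on the east–west span.
* Velocity uses the anomaly magnitude and a gradient floor (default 1e-6
  units/km) so flat cells give large finite velocities rather than
  infinities; the anomaly stays signed where it is used directly as the TA
  predictor.
* The log transform defaults to base 10 with zero offset and raises an
  error if a raw velocity is not positive; velocities are the full-epoch
  displacement by default, with an option to scale per year (divide by
  21,000).

## Degenerate inputs and conventions

* Bray–Curtis against an all-empty site equals 1 (the formula's limit) with
  a warning; between two empty sites it is undefined and errors. The
  validated community container refuses empty sites outright.
* Presence means abundance strictly greater than 0 — site means are
  fractional after plot averaging, so no arbitrary cut-off is imposed.
* Constant responses, constant predictors, insufficient degrees of freedom
  ($n - p - 1 \le 0$) and sites outside a grid's extent raise immediate,
  named errors.
* NMDS defaults: k = 2, 50 random starts, vegan's convergence machinery;
  ordination scores are centred. envfit directions are unit vectors.

## Problem sizes in the shipped tests

The test suite exercises the chain at sizes chosen to make Monte-Carlo
bands tight while keeping a full run in minutes: 2,000 sites for latent
correlation checks, 100–500 sites for recovery runs, 200 replicates at 199
permutations for type-I calibration of the partition, Mantel and envfit
tests (nominal 5% rule expected to reject in 1–12% of replicates), and 50
replicates for the pure-climatic recovery rate. The acceptance script runs
the whole pipeline at the emulated study size (16 sites) with 25 observed
CV repeats, 199 response permutations and 999 distance/Mantel permutations.

## Known limitations

* With 16 sites and 11 predictors the adjusted-$R^2$ penalty is close to
  its breakdown point ($n-p-1 = 4$); fraction estimates are noisy and often
  negative, which is faithful to the method rather than a defect of it.
* The distance-based adjusted $R^2$ treats non-independent pairs as
  observations (see above); only the permutation p-values are inferential.
* GeoTIFF input is not supported; grids are exchanged as ESRI ASCII text.
* The elastic-net engine requires at least two predictors per combination,
  which every three-set table satisfies.
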