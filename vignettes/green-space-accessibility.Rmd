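---
title: "Measuring multi-modal green-space accessibility and community deprivation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring multi-modal green-space accessibility and community deprivation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greenaccess)
```

## The problem

Urban green spaces (UGS) deliver measurable public-health benefits —
physical activity, heat relief, mental health — but only to residents who
can actually reach them. Simple per-capita ratios hide both the competition
for a space (a large park next to a dense district serves each person less)
and the transport reality (a park 2 km away is reachable by bicycle but not
on foot for many). `greenaccess` implements an accessibility measure that
accounts for both, across walking, cycling and public transport
simultaneously, and a regression machinery for asking the equity question:
do communities with more disadvantaged residents systematically get less?

## The accessibility model

The measure is a multi-mode two-step floating catchment area (2SFCA)
statistic. Travel times between community anchor nodes and green-space
entrances are shortest paths over a road network whose edges carry one of
nine road classes; each travel mode has a fixed speed per class
(`default_speed_table()`), with walking and cycling confined to street
classes (5 and 15 km/h) and public transport running on everything
(20–50 km/h, 50 km/h on subway track). A class closed to a mode simply does
not exist in that mode's graph, so routes differ structurally between
modes, not just in speed.

**Step 1** gives every green space $j$ a supply–demand ratio

$$V_j = \frac{S_j}{\sum_{v=1}^{3}\;\sum_{k:\,d_{jk}(M_v)\le d_0(M_v)} P_{k,M_v}}$$

where $S_j$ is its area (m²), $d_{jk}(M_v)$ the travel time to community
$k$ by mode $v$, $d_0(M_v)$ the mode's catchment threshold, and $P_{k,M_v}$
the community population travelling by that mode. Note the symmetric
denominator: each mode's catchment accumulates that same mode's population.
(Statements of this denominator sometimes appear with the first mode's
population repeated in the second term; the package deliberately uses the
symmetric form, which is the one consistent with the step-2 aggregation.)

**Step 2** aggregates the reachable ratios per community, weighting modes
by their population shares:

$$A_i = \frac{\sum_{v=1}^{3} P_{i,M_v} \sum_{j:\,d_{ij}(M_v)\le d_0(M_v)} V_j}{\sum_{v=1}^{3} P_{i,M_v}}$$

$A_i$ is in m² of green space per person. Conventions, all deliberate:

* Catchment membership is inclusive ($\le$).
* Mode order is fixed: $M_1$ walking, $M_2$ cycling, $M_3$ public transport.
* A green space whose catchments contain no population gets $V_j = 0$ and a
  `zero_demand` flag rather than an error; synthetic scenarios legitimately
  produce such spaces. Flagged spaces are excluded from the conservation
  identity below.
* Per-mode accessibility columns (`access_walking` etc.) answer "what would
  this community score with its entire population on that mode", i.e. the
  plain catchment sum $\sum_j V_j$; the integrated score is the
  population-weighted mixture.
* Multi-entrance spaces (including belt parks split into parts) are reached
  through their nearest entrance: the travel time to a space is the minimum
  over its entrance nodes.
* A community with zero total population cannot be scored and is dropped
  with a warning.

The model obeys an exact bookkeeping identity used throughout the tests:
when zero-demand spaces are excluded,
$\sum_i P_i A_i = \sum_j S_j$ — every supplied square metre is allocated to
exactly one person-share. The implementation reproduces this to floating
point (relative error below $10^{-9}$ on every generated city), and scaling
all areas by $c$ scales every $V_j$ and $A_i$ by $c$.

### Thresholds from trip surveys

Catchment thresholds default to 18/23/33 minutes for
walking/cycling/public transport. They can be re-estimated from a trip
survey: the empirical cumulative share of trips no longer than $t$ minutes
rises steeply up to a typical travel time and flattens beyond it.
`estimate_threshold()` evaluates that curve on the integer-minute grid,
fits a continuous two-segment piecewise-linear function by least squares at
every interior integer breakpoint, and returns the breakpoint with minimal
residual sum of squares. Ties go to the smallest minute. If no breakpoint
beats a single straight line (relative improvement below $10^{-10}$, with
an absolute floor of $10^{-12}$ for exactly linear curves), the curve has
no inflection: the boundary candidate is returned with a warning and a
`degenerate` flag. At least 30 trips per mode are required.

### Network conventions

Coordinates are planar metres (a projected CRS); the package does no
geodesy — reprojection is input preparation. Edges are bidirectional unless
a `oneway` flag restricts them. Points snap to their nearest node with a
500 m default tolerance, ties broken by the smallest node id; the access
leg is free, since the data model measures node-to-node times. Public
transport has no headways or transfer penalties — cost is purely
speed-over-class — but a constant `boarding_min` penalty per moving trip is
available on `travel_time_matrix()` (default 0).

## The deprivation model

Deprivation is the systematic association of low accessibility with
disadvantaged community composition. Five covariates describe composition,
all proportions in $[0,1]$: residents over 65, unemployed, illiterate, with
less than junior-middle-school education, and migrants. Their marginal
effects on accessibility are plainly heterogeneous across communities, so a
linear model's single coefficient is the wrong summary. The package uses
kernel regularized least squares (KRLS): with the Gaussian kernel
$K_{ij} = \exp(-\lVert x_i - x_j\rVert^2/\sigma^2)$ on standardized
covariates, the fit is $\hat y = Kc$, $c = (K + \lambda I)^{-1} y$, and the
pointwise marginal effect of covariate $d$ at observation $i$ has the
closed form

$$\frac{\partial \hat y_i}{\partial x_d} = -\frac{2}{\sigma^2} \sum_j c_j K_{ij} (x_{id} - x_{jd}),$$

rescaled to original units. Tables report, per covariate and mode, the
average effect, its P25/P50/P75 quantiles (heterogeneity), a delta-method
standard error and significance stars.

Numerical and inferential choices:

* $\sigma^2 = D$ (the number of covariates), the standard choice on
  standardized designs; overridable.
* $\lambda$ minimises the exact leave-one-out SSE via the ridge identity
  $e_i^{\text{loo}} = (y_i - \hat y_i)/(1 - H_{ii})$, with a deterministic
  golden-section search on $\log\lambda \in [\log 10^{-6}, \log 10^{3}]$,
  tolerance $10^{-4}$. The identity is exact: the tests verify it against
  brute-force refit-without-$i$ to $10^{-8}$. Everything is computed from
  one eigendecomposition of $K$, so the search is cheap and the fit is
  fully deterministic.
* Inference on the average effect uses the delta method: the average
  derivative is linear in $c$, and $\mathrm{cov}(c) = \hat\sigma^2 (K +
  \lambda I)^{-2}$ with $\hat\sigma^2$ the residual variance over the
  residual effective degrees of freedom; p-values are two-sided normal.
  This assumes exchangeable (effectively independent) communities — see the
  limitations below.
* Quantiles use linear interpolation between closest ranks (R type 7);
  on small n this choice visibly affects P25/P75 and is therefore pinned.
* Standardization of covariates and response is the default and can be
  disabled (`standardize = FALSE`); effects are always reported in original
  units (m² per person, per unit covariate — a proportion moving 0 to 1).
* A constant response (e.g. change-on-change between identical timepoints)
  is fit exactly by its mean: zero effects, p-values of 1, rather than an
  error.
* `best_subset()` enumerates all non-empty covariate subsets up to a
  requested size, refits each, and picks the minimal-LOO-SSE subset; ties
  go to the smaller subset, then enumeration order. The exhaustive search
  is capped at 15 candidates.

`cross_sectional_analysis()` runs one KRLS fit per travel mode (plus the
integrated score) with the covariates entering jointly — fitting them
one-at-a-time is possible by passing a single covariate. For dynamics,
`change_analysis()` regresses $A_i(t_2) - A_i(t_1)$ on
$\mathrm{SES}(t_2) - \mathrm{SES}(t_1)$ over the communities present at
both timepoints.

## The synthetic city

Real community-level census and green-space registries are typically
restricted, so the generator produces complete, seeded study regions.
`generate_city()` builds:

* a grid-with-diagonals road network — by default 20 × 20 nodes at 1600 m
  spacing (a ~30 km metropolitan extent) — with edge classes drawn from a
  street-dominated mix over the nine classes;
* 200 communities of 300–1500 residents anchored at nodes, with a
  Dirichlet(4, 3, 3) walking/cycling/transit population split (no published
  mode-share table exists for this setting; walking-heavy is the package's
  modelling choice);
* SES proportions with Beta marginals matching published community-level
  moments (e.g. proportion over 65: mean 0.24, sd 0.07; less educated:
  mean 0.46, sd 0.15), drawn through a Gaussian copula whose latent field
  can carry district-scale spatial autocorrelation (`ses_range_frac`,
  `ses_nugget`); targets outside the Beta-feasible region
  ($s^2 \ge m(1-m)$) are rejected;
* 30 green spaces in three levels (2 city-level of 3–6 × 10⁵ m², 8
  district-level of 0.6–1.5 × 10⁵ m², 20 community-level of 1.5–3 × 10⁴
  m²), placed at community nodes with probability
  $\propto \exp(\sum_c \gamma_c z_c)$, where $z_c$ is the community's
  standardized SES covariate and $\gamma$ the `coupling` vector — negative
  coupling steers supply away from disadvantaged communities, planting a
  known deprivation mechanism on the supply side rather than writing
  accessibility directly;
* belt parks: a configurable fraction of spaces is emitted as multiple
  part-records at adjacent nodes whose areas partition the whole (each part
  one entrance), and other spaces may carry a second entrance;
* trip surveys from a two-slope cumulative model with planted breakpoints
  (18/23/33 min by default) — the deterministic sampling option produces
  the exact quantiles of that model, which `estimate_threshold()` recovers
  exactly; random sampling recovers them within a minute at n = 1000;
* growth: `evolve_scenario()` densifies the network toward a target edge
  multiplier with new short links, scales populations and adds green
  spaces, preserving community ids for change analyses.

The same seed reproduces every table byte for byte.

### Why these defaults

The geometry is chosen so that the three catchments are structurally
different, as they are in a real provincial capital: at 1600 m spacing the
18-minute walking catchment is essentially the home neighbourhood, cycling
reaches a few kilometres, and 33 minutes of public transport spans most of
the region (transit coverage of city-level spaces is routinely near 100%
in generated cities). If the city were small relative to the cycling and
transit catchments, every community would reach every space by those modes
and spatial allocation would be irrelevant — accessibility analysis would
have nothing to measure.

SES is drawn independently across communities by default
(`ses_nugget = 1`). This is a deliberate statistical choice: the KRLS
p-values assume exchangeable units, and when both accessibility (inherently
spatially smooth) and SES are smooth spatial fields, chance alignment of
the two fields produces large, "significant" effects in a substantial share
of null cities — spatial confounding, not deprivation. With independent
SES the null behaves nominally (about 5% of null cities show a significant
effect at $\alpha = 0.05$) while planted supply-side coupling is still
detected essentially always on the walking mode, whose neighbourhood-scale
catchment carries the signal. Setting `ses_nugget < 1` produces the more
realistic clustered-disadvantage cities, with the explicit caveat that
nominal significance is then anti-conservative. This caveat applies equally
to analyses of real cities: disadvantage is spatially clustered, and the
method — here as in its published uses — does not correct for spatial
autocorrelation.

### What passing tests do and do not show

The generator emulates the *structure* of the real inputs (network classes,
population splits, SES marginals, leveled and multi-entrance green spaces,
survey curves), not their full texture: street topology is a grid, land use
is absent, travel speeds are deterministic, SES covariates are mutually
independent, and the deprivation mechanism is purely supply-side. Tests
passing on these cities validate the computational pipeline — the 2SFCA
algebra, routing, threshold estimation, KRLS estimation and inference — and
the recoverability of a known planted mechanism. They do not validate
substantive conclusions about any real city.

## Numerical scale of the test suite

The test suite runs the conservation identity on 20 full-scale cities
(200 communities, ~30 spaces), compares routing against a hand-written
Floyd–Warshall oracle on 50 random networks of up to 60 nodes and the
2SFCA engine against a brute-force implementation on 100 random instances,
verifies the leave-one-out identity at n = 25 and the closed-form
derivatives against central finite differences (h = 10⁻⁵, agreement to
10⁻⁵), and measures planted-deprivation detection and null false-positive
rates over 50 seeds each. `scripts/acceptance.R` re-measures the same
quantities at comparable sizes (reported alongside each value). These
sizes give each property enough instances to be meaningful while keeping
the default run in tens of seconds.

## Known limitations

* No distance decay within catchments (no Gaussian or kernel-weighted
  2SFCA variants) and no quality weighting of green spaces; supply is area.
* Public transport is speed-over-class only: no schedules, headways,
  transfers or congestion (a constant boarding penalty is the only knob).
* Access legs are free within the snap tolerance.
* Inference assumes exchangeable communities; spatially autocorrelated
  covariates make it anti-conservative (see above). No MAUP correction:
  results are conditional on the community partition supplied.
* The fitted KRLS surface interpolates only up to the floating-point rank
  of the kernel matrix; at very small $\lambda$ residuals bottom out near
  the eigenvalue truncation level rather than exactly zero.
* Dense kernel algebra assumes community counts up to a few thousand.
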