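# greenaccess

Per-capita access to urban green space is a public-health resource: it is
where city residents exercise, cool off and meet, and it is rarely shared
equally. `greenaccess` is an R package for quantifying that inequality. It
measures how many square metres of green space each residential community can
actually reach — by walking, cycling or public transport over the real road
network — and then asks whether the communities that get the least are the
ones that are already disadvantaged (older, unemployed, illiterate, less
educated, or migrant populations). It is aimed at spatial epidemiologists,
urban-planning researchers and health-equity analysts.

Because fine-grained community census data are usually restricted, the
package ships a seeded synthetic-city generator that emulates every input
(road networks with class-specific speeds, communities with socioeconomic
structure, leveled green spaces, trip surveys, multi-year growth scenarios),
so the entire pipeline is reproducible and testable end to end.

## The model

**Multi-mode two-step floating catchment area (2SFCA).** Each green space
*j* with area *S<sub>j</sub>* (m²) serves the population that can reach it
within a mode-specific threshold travel time *d₀(Mₙ)* — by default 18 min
walking, 23 min cycling, 33 min public transport, estimated as the
inflection points of cumulative trip-frequency curves. Step 1 computes its
supply–demand ratio over the union of the three mode catchments:

```
V_j = S_j / ( Σ_{k: d_jk(M1) ≤ d0(M1)} P_k,M1
            + Σ_{k: d_jk(M2) ≤ d0(M2)} P_k,M2
            + Σ_{k: d_jk(M3) ≤ d0(M3)} P_k,M3 )
```

where *d<sub>jk</sub>(Mₙ)* is the network travel time between space *j* and
community *k* by mode *Mₙ* and *P<sub>k,Mₙ</sub>* the community population
travelling by that mode. Step 2 sums the reachable ratios per community,
weighting each mode by its population share:

```
A_i = ( P_i,M1 Σ_{j: d_ij(M1) ≤ d0(M1)} V_j
      + P_i,M2 Σ_{j: d_ij(M2) ≤ d0(M2)} V_j
      + P_i,M3 Σ_{j: d_ij(M3) ≤ d0(M3)} V_j ) / Σ_v P_i,Mv
```

*A<sub>i</sub>* is the community's accessibility in m² of green space per
person. Travel times come from mode-specific shortest paths over a
road-class-typed network (walking/cycling at 5/15 km/h on streets only;
public transport on every class at 20–50 km/h, including subway track).

**Deprivation via kernel regularized least squares (KRLS).** Accessibility
is regressed on community socioeconomic proportions with Gaussian-kernel
ridge regression, `c = (K + λI)⁻¹ y`, which yields closed-form pointwise
partial derivatives ∂ŷᵢ/∂x<sub>d</sub> — heterogeneous marginal effects at
every community. The package reports their average, P25/P50/P75 quantiles,
delta-method standard errors and significance stars per covariate and mode;
a significant negative effect of a disadvantage indicator is the signature
of deprivation. λ is chosen by exact leave-one-out cross-validation and an
exhaustive best-subset search over covariate sets is available.

## Worked example

```r
library(greenaccess)

# a 20 x 20-node city, 200 communities, 38 green-space records, with green
# space deliberately steered away from less-educated communities
city <- generate_city(scenario_config(seed = 42,
                                      coupling = c(less_educated = -3)))
res <- city_access(city)          # travel times, ratios V_j, scores A_i
head(flag_below_standard(res$access), 4)
#>   community_id access_walking access_cycling access_transit access_integrated
#> 1 C1                        0           0              4.37              1.68
#> 2 C2                        0           0             32.1              11.1
#> 3 C3                        0           2.51          26.7               5.80
#> 4 C4                        0           3.40          26.7               9.34
```

Walking access is scarce (most communities have no green space within 18
min on foot), transit access is broad, and the integrated score mixes the
modes by population share. `below_standard` flags communities under the
12 m²/person National Ecological Garden City benchmark. The level-stratified
view separates city-, district- and community-level green space:

```r
summarize_access(stratified_accessibility(city$communities, city$ugs, res$ttms))
#>   mode              total level1 level2 level3
#> 1 walking           0.699  0.262  0.297  0.141
#> 2 cycling           5.62   1.97   2.45   1.21
#> 3 public_transport 36.7   14.3   14.8    7.62
#> 4 integrated       13.1    5.09   5.32   2.69
```

The deprivation analysis recovers the planted inequity — for walking, a one
unit increase in the less-educated share costs about 5 m²/person (p < 0.01),
with the P25/P75 spread showing how heterogeneous the effect is:

```r
ses <- dplyr::rename(city$communities[c("id", "older", "unemployed",
                                        "illiterate", "less_educated",
                                        "migrants")], community_id = id)
cross_sectional_analysis(res$access, ses, modes = "walking")
#>   covariate     mode      avg   p25   p50   p75    se p_value stars
#> 4 less_educated walking -5.08 -8.99 -1.71  1.29  1.68 0.00254 **
#> ...
```

Thresholds can be re-derived from a trip survey
(`estimate_threshold(generate_trip_survey(seed = 43))` returns 18/23/33
min), and `run_pipeline(demo_pipeline_config(), "out/")` chains every stage
and writes deterministic CSVs plus a manifest. A thin CLI wrapping the same
functions is installed at `inst/cli/greenaccess`.

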