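---
title: "Methods: multi-phase spatial cluster analysis of overdose incident rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-phase spatial cluster analysis of overdose incident rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odhotspot)
```

## The problem

Opioid overdose burden is strongly spatially structured within cities:
emergency-medical-service (EMS) incident rates differ by an order of
magnitude between adjacent census block groups. `odhotspot` implements a
multi-phase areal workflow for locating that structure and profiling it:

1. **Record cleaning** under explicit exclusion rules and construction of
   block-group incident rates per 1,000 adult population per year.
2. **Rate classification** with exact Jenks natural breaks (choropleth
   logic).
3. **Global clustering test**: Ripley's K function with isotropic edge
   correction against a Monte-Carlo complete-spatial-randomness (CSR)
   envelope.
4. **Local clustering**: local Moran's I (LISA) on queen-contiguity
   weights with conditional permutation inference, yielding the five-way
   High-High / Low-Low / Low-High / High-Low / not-significant map.
5. **Conditional cluster tables**: median splits of sociodemographic
   covariates and facility-access distances, hot/cold-spot fractions per
   stratum, and a 0.6 conditional-probability screen for variable pairs.

Because the motivating municipal data (EMS extracts, ACS covariates,
facility registries) cannot ship with a package, a **synthetic-city
generator** is a first-class module: it produces a polygon lattice with
planted hot blocks, correlated covariates, facilities and a contaminated
incident stream, so every downstream stage is exercised end to end by the
test suite.

## Models and statistics

### Rates

For block $b$ with adult population $P_b > 0$ and $c_b$ retained incidents
over $Y$ years, the rate is $r_b = 1000\,(c_b / Y)/P_b$. $Y$ is an
explicit parameter and never inferred from timestamps: study periods and
averaging windows frequently disagree in source data, so silent inference
is a footgun. Blocks with $P_b = 0$ are excluded from rates and from all
downstream statistics, and reported.

Exclusion rules are applied in a fixed order — missing geocode, outside
study area, unassociated disposition code, cancelled/false alarm,
duplicate — so the tally is a partition of the input (each record counted
exactly once). A duplicate is a repeated record id or a repeated
(coordinates, timestamp, disposition) triple among records surviving the
earlier rules; the first occurrence is kept.

### Ripley's K

With $N$ points in a window of area $A$ and intensity
$\hat\lambda = N/A$,

$$\hat K(t) = \frac{A}{N^2}\sum_i \sum_{j \ne i}
  w(l_i, l_j)^{-1}\, \mathbf{1}(d_{ij} < t),$$

where $w(l_i, l_j)$ is the fraction of the circumference of the circle
centred at $l_i$ through $l_j$ lying inside the window (isotropic edge
correction). The indicator is strict, so ties at exactly $t$ are
excluded. Under CSR, $K(t) = \pi t^2$.

One finite-sample property of this normalization is worth knowing: for
$N$ uniform points, conditioning on a point shows
$E[\hat K(t)] = \pi t^2 (N-1)/N$ exactly — a deterministic $-1/N$ bias
(1% at $N = 100$). The alternative normalization $A/(N(N-1))$ is exactly
unbiased, but this package keeps $A/N^2$ because that is the estimator
the workflow it implements defines (and the one its worked examples pin
down). The envelope comparison is unaffected: observed and simulated
$\hat K$ share the same normalization.

The CSR envelope simulates `n_sims` (default 999) patterns of $N$ uniform
points; with level $\alpha$ the bounds at each radius are the $r$-th
smallest and largest simulated $\hat K$, $r = \lceil \alpha (n_\text{sims}
+ 1)/2 \rceil$ (999 sims, $\alpha = 0.01$ give the 5th order statistics).
The envelope is **pointwise**, not simultaneous: reading "clustered at
every distance" across many radii carries a multiplicity caveat, which we
document rather than correct, matching standard practice for this kind of
map-level description.

**Edge-weight computation.** For axis-aligned rectangular windows the
in-window circumference fraction has a closed form (edge arcs
$2\arccos(d/r)$ with corner-overlap corrections). For arbitrary simple
polygons we compute the exact intersection angles of the circle with every
edge and classify each arc by its midpoint. We chose exact arc
intersection over uniform sampling of the circumference because the test
suite demands agreement with an independent brute-force oracle to $10^{-9}$
relative error, which no practical sampling density reaches; the oracle
itself uses adaptive bisection of the arc-containment indicator, a
deliberately different route. The closed form is valid while a circle
never reaches two opposite window edges at once; the default radius grid
(64 radii up to one quarter of the shorter window extent) guarantees this.

### Local Moran's I

For deviations $z_i$ from the mean over analyzed blocks and
$m_2 = \sum_i z_i^2 / n$,

$$I_i = \frac{z_i}{m_2} \sum_j w_{ij} z_j,$$

with row-standardized queen-contiguity weights (blocks are neighbors if
their polygons share any boundary point; a snapping tolerance, default 0,
is available for dirty polygons). With no islands,
$\sum_i I_i = n \cdot I_\text{global}$ exactly, and the package tests this
identity to $10^{-10}$.

Inference is by **conditional permutation**: unit $i$'s value is held
fixed and its neighbors' values are drawn without replacement from the
remaining $n - 1$ values; the pseudo p-value is
$(\text{extreme count} + 1)/(n_\text{perm} + 1)$, one-sided in the
direction of the observed $I_i$ (the convention of the GeoDa lineage).
Significant units are categorized by the signs of $z_i$ and the lag:
HH and LL are clusters (hot and cold spots), LH and HL spatial outliers.
A significant unit with a zero deviation or zero lag has no quadrant and
is classified not-significant. No multiple-testing correction is applied
(the workflow reads the map at a raw $\alpha = 0.01$, with 9,999
permutations by default); this is a documented caveat, not an oversight.

**Size of the directional test.** Because the tail is chosen by the sign
of the observed statistic, the *total* fraction of significant units under
an i.i.d. null is close to $2\alpha$ — upper tail (HH/LL) and lower tail
(LH/HL) each contribute $\alpha$. Hot/cold-spot detection — the output
this workflow reports — is therefore sized at $\alpha$: the acceptance
suite verifies that the HH$\,\cup\,$LL fraction under an i.i.d. null is
$0.01$ within three binomial standard errors, and we document (rather than
hide) that the four-category union runs at about twice that.

### Jenks natural breaks

Classification minimizes the sum of squared deviations from class means
(SDCM) over contiguous partitions of the sorted values, solved **exactly**
by dynamic programming on the distinct values weighted by multiplicity —
so tied observations can never straddle a class boundary and right-closed
class intervals are well defined. Goodness of variance fit is
$\text{GVF} = 1 - \text{SDCM}/\text{SDAM}$; the class count is the
smallest $k$ in a candidate range (default 2–9) reaching a GVF target
(default 0.85), falling back to the GVF-maximizing $k$. The source
workflow states the GVF criterion but not its threshold; 0.85 is a common
cartographic rule of thumb and is configurable.

### Conditional cluster tables

Covariates (percent male, percent below poverty, percent bachelor-or-
higher, per-capita income, crime rate) and per-type facility distances
(units of 10 miles = 16,093.4 m, planar from block centroids) are
median-split, ties to "low". For each variable pair the LISA categories
are cross-tabulated over the $2 \times 2$ strata; the reported fractions
condition on spot type — $P(\text{level} \mid \text{HH})$, denominator =
number of hot spots — matching the "x% of the hot spots were in ..."
phrasing; the inverse conditioning is also computable from the emitted
counts. A pair is retained when some level combination exceeds the screen
threshold (strictly greater than 0.6) for both variables. With $h$ hot
spots all fractions are multiples of $1/h$.

## The synthetic city: what it emulates, what it does not

Defaults are fixed once, chosen to echo the scale of a mid-sized US city
study area, and are not tuned against test outcomes:

* **Lattice**: 14 × 20 = 280 square-kilometre block groups (the study
  scale this workflow was built for), anchored near Cincinnati, Ohio and
  carried in UTM zone 16N meters; exported as WGS84 GeoJSON.
* **Population**: log-normal, median ≈ 980, `sdlog` 0.5 — matching a
  median block-group adult population of ~978 with realistic right skew
  and an IQR of roughly 650–700.
* **Incidents**: per block and year, Poisson with mean
  $P_b/1000 \times \text{base rate} \times \text{hot multiplier}$, points
  uniform within the block. The base rate default is 1.0 incidents per
  1,000 adults per year — between the motivating study's median block
  rate (0.26) and its implied city-wide mean (~5, dominated by hot
  spots) — giving on the order of 2,000 clean incidents over six years.
* **Hot region**: a contiguous 3 × 3 block square at 5× the base rate.
* **Covariates**: Gaussian fields smoothed over the lattice queen
  neighborhood (two passes) for spatial correlation, transformed to
  marginals centered on realistic values (e.g. median income ≈ \$24,700,
  crime rate ≈ 7.65 per 1,000); hot blocks are shifted toward higher
  percent male/poverty/crime and lower education/income.
* **Contamination**: exact duplicate copies, cancelled flags, missing
  geocodes, out-of-area points (within one window-width of the boundary,
  so the containment filter is exercised non-trivially), and optionally
  unassociated disposition codes; defaults total ≈ 20% of the clean
  stream, echoing the ~20% attrition typical of EMS extracts.

The generator does **not** emulate street networks, within-period temporal
trends, demographic microsimulation, or any dependence between covariates
and the incident process beyond the planted hot region. A green
planted-recovery test therefore establishes that the pipeline detects a
strong contiguous rate excess at realistic sample sizes — not that it
would reproduce any particular real city's map.

## Numerical choices and degenerate inputs

* All randomness flows from explicit seeds through a save/restore helper
  (`with_seed()`); stage seeds derive deterministically from one master
  seed, so single stages re-run from saved intermediates reproduce the
  full-run artifacts byte for byte.
* Point-on-boundary containment uses a relative tolerance band
  ($10^{-9}$ of the coordinate scale); a point on a shared block boundary
  is assigned to the containing block with the lowest id.
* WGS84 ↔ UTM uses the standard truncated transverse-Mercator series;
  round-trip displacement is far below 1 m at city scale (tested). The
  UTM zone is taken from the window centroid, with a warning if the
  window spans more than two zones.
* The study window travels through GeoJSON as a foreign top-level member;
  reconstructing it from the WGS84 bounding box would rotate and inflate
  a rectangular window (meridian convergence) and silently degrade the
  edge-correction fast path.
* Constant rate vectors give $I_i \equiv 0$ and no inference; constant
  covariates give a degenerate all-"low" median split with a warning.
* Coincident points define no circle: `edge_weight()` refuses them;
  `k_function()` requires $N \ge 2$ and drops non-positive radii with a
  warning.

## Known limitations

* Pointwise (not simultaneous) CSR envelopes; raw-$\alpha$ LISA with no
  false-discovery control.
* Planar Euclidean facility distances, not road-network travel.
* Queen contiguity from exact coordinate contact; polygons from sources
  with digitizing noise need a nonzero snapping tolerance.
* The K-function edge correction's rectangle closed form assumes radii at
  most one quarter of the shorter window extent (the default grid); wider
  custom grids fall back to the generic polygon path only when the window
  is not an axis-aligned rectangle, so keep custom radii within that
  range for rectangular windows.
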