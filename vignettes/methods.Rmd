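---
title: "Attributing deforestation to commodities and accounting its committed carbon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing deforestation to commodities and accounting its committed carbon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(carbofoot)
library(dplyr)
```

## The problem

Tree-cover loss observed by satellite is not the same thing as
deforestation, and deforestation is not the same thing as commodity
production. A forest-loss pixel may be rotational clearing inside a managed
plantation, a wildfire that is never followed by agriculture, or genuine
conversion of natural forest to cropland, pasture or a planted forest. Only
the last of these should be charged to a commodity, and only sometimes can
the commodity be identified from maps; elsewhere the attribution must fall
back on agricultural statistics. `carbofoot` implements this chain as a
desk-scale, fully testable pipeline:

1. **Spatial attribution** classifies every loss pixel by a sequential
   hierarchy of evidence (commodity maps, land-use maps, land-use mosaics,
   dominant-driver fallback), excluding non-commodity fire.
2. **Statistical attribution** allocates the spatially unresolved remainder
   to land uses and then to crops with a two-step land balance on
   region-year statistics.
3. **Carbon accounting** books the committed emissions of each converted
   hectare (AGB, BGB, deadwood, litter and soil organic carbon, minus the
   replacing commodity's mature plant stock).
4. **Peat drainage** accrues annual emissions for conversions on peat,
   which — unlike the one-off committed losses — keep accumulating every
   year.
5. **Quality scoring** attaches an Integrated Quality Index (IQI) to every
   region–commodity–year estimate.

## Forest definition and spatial attribution

A pixel counts as natural forest when its year-2000 tree-cover density is
at least `tcd_threshold` (default 25%, configurable) *and* it lies outside
the managed-plantation mask. Loss on non-forest pixels is reported as
degradation/rotational clearing, never attributed to a commodity.

For a forest pixel lost in year $t$, candidate datasets are scanned
commodity-level first, then land use, then mosaic; ties within a level are
broken by the dataset's rubric score, then registry order. An annual
dataset may claim the pixel only if it first observes a class there within
$[t, t + \mathrm{lag}]$ and no later than its last valid year; a static map
is valid for all $t$ up to its last valid year (tree crops persist, so no
lower bound is imposed). Agriculture is attributed **before** fire: a pixel
carrying both a pasture signal and a fire mark is pasture; a fire-only
pixel is non-commodity fire loss, excluded from deforestation. Pixels that
survive all of this fall to dominant-driver datasets
(`commodity_driven`/`shifting_agriculture` feed the statistical
agriculture pool, `forestry` the plantation pool, `other` is kept as a
non-commodity residual) and finally to `unattributed`, which also enters
the statistical pool. Each pixel is claimed exactly once.

Two deliberately resolved ambiguities: the fire match is exact-year by
default (`fire_window_years = 0`, exposed in the configuration), and each
pixel belongs wholly to the region given by its region-id code — no
sub-pixel boundary splitting.

The default attribution lag is **3 years** for both the spatial and the
statistical step. Published sensitivity analyses in this literature test 1
and 5 years as bounds without printing a baseline; we take the midpoint and
expose both lags in the configuration.

## The two-step land balance

Unresolved deforestation pools per region-year are: the three single
land-use pools (spatially evidenced cropland, pasture, plantation), the
cropland–pasture mosaic, and unresolved agriculture. Statistical land-use
expansion over the lag window is `gross` by default (sum of positive
year-on-year increments; `net` uses the endpoint difference, so
within-window abandonment cancels — abandonment is netted inside the
expansion computation, not after allocation).

Allocation rules:

* Single land-use pools pass through unchanged (the land use is spatially
  evidenced).
* The mosaic pool splits between cropland and pasture in proportion to
  their expansions.
* The unresolved pool is allocated **cropland-first** by default: cropland
  expansion is satisfied before the remainder is split between pasture and
  plantation — modelling cropland that displaces pasture into the forest
  frontier. With `cropland_first` off the pool is split proportionally.
* With `restrict_by_stats` on (the default), the combined claims of the two
  statistically split pools on each land use are capped at that land use's
  expansion, scaling both pools down proportionally where they compete, and
  the excess is reported as deforestation `without_production`. Pools
  facing all-zero or missing expansions become `unallocated`. Residual
  classes are always reported, never dropped, so pools are conserved
  exactly.

Cropland allocations are then split across crops in proportion to their
positive harvested-area expansions. With `multicropping` on (default), each
year's harvested areas are first divided by the cropping intensity
$CI = \max(1, \sum_c H_c / A_{cropland})$ so double cropping does not claim
land twice; a uniform $CI$ cancels out of the shares. Pasture maps to the
combined class `cattle_meat_leather` (the economic meat/leather split is
out of scope) and plantations to `forestry_products`.

## Committed carbon emissions

For each deforested hectare the five committed stocks are:

$$E = \big[\mathrm{AGB}(1 + r + d_b + l_b)\big] \times 0.47
      + s_{u,b}\,\mathrm{SOC} $$

with $r$ the root-to-shoot ratio, $d_b, l_b$ biome-specific deadwood and
litter proportions of AGB, 0.47 the biomass-to-carbon ratio, and $s_{u,b}$
the fraction of the 0–100 cm SOC stock lost under replacing land use $u$ in
biome $b$. Net emissions deduct the replacing commodity's mature plant
carbon stock (group fallback when the commodity has no entry), scaled by
`plant_stock_scale` (default 1.0; 0.75 represents pre-harvest average
stocks). Everything is converted to CO2 with 44/12. Emissions are
*committed*: booked once at the loss year, with no decay curves.

Numerical choices worth stating:

* Negative net emissions (replacing stock above the forest's carbon) are
  allowed and reported — flooring them would silently break conservation.
* Pixels on peat contribute **no** SOC component here; their soil carbon is
  handled by the drainage module, avoiding double counting. A test asserts
  the total SOC component over peat pixels is exactly zero.
* The elevation/precipitation dimensions of deadwood/litter look-ups are
  collapsed to biome-only defaults (tropical 7%/3%, temperate 10%/5%,
  boreal 12%/8% of AGB), configuration-extensible. SOC loss fractions
  default to 25–30% under cropland, 10–12% under pasture and 8–10% under
  plantations, in line with meta-analyses of land-use change; pools whose
  replacing land use is genuinely unknown (mosaic, unresolved) use the mean
  of the three fractions.
* Statistically attributed commodities bear pool emissions in proportion to
  their share of the pool's forest-loss area; the apportionment conserves
  the pool total to machine precision, and plant-stock deduction is applied
  per aggregated commodity area (equivalent to per-pixel deduction when
  stocks are uniform per commodity).

## Peat drainage

Deforestation on peat (post-2000 only) accrues an annual emission equal to
area times a land-use × biome emission factor, from the deforestation year
**inclusive** until the study end year — a hectare drained for oil palm in
2010 is charged its 54.41 MgCO2 factor thirteen times by 2022. The
inclusive count is forced by that printed worked example. Fixed horizons
(5/10/15 years) and no accumulation are available as sensitivity settings.
Oil palm has its own factor; other crops use their biome's cropland factor.
Factors other than the tropical oil-palm value are configuration defaults
of typical literature magnitude, and are expected to be replaced by the
user's own look-up table in serious use.

Peat under spatially attributed commodities follows its commodity directly.
Peat in unresolved pools is split evenly among the commodities identified
by **that pool's** statistical allocation in that region-year (an empty set
reports the area as `unallocated`). Scoping the even split to the pool —
rather than to every commodity in the country — keeps pasture-pool peat
with cattle and makes noiseless recovery exact; a proportional-to-area
split is available via `peat$split = "proportional"`. The even split is
applied per region-year.

## Quality index

Every estimate's IQI is the forest-loss-weighted mean of contributing
sources' overall accuracy times rubric score,

$$\mathrm{IQI}_{i,t} = \frac{\sum_j (\mathrm{FL}_{i,j}\,\mathrm{OA}_j\,
\mathrm{Score}_j)_t}{\mathrm{FL}_{i,t}},$$

where statistically attributed contributions have OA multiplied by the mean
of the land-use and production flag scores (official 1.0, semi-official
0.75, estimated 0.5, imputed/unofficial 0.25; an absent production flag
counts as 1, the officially-reported case). The rubric score is the mean of
three equally weighted sub-scores — spatial granularity, temporal
granularity, explicitness — declared per dataset in the registry.
Contributions that reach the statistics with no spatial source at all (the
unattributed pool) carry a configurable fallback block: OA 0.85 and
sub-scores (1, 1, 0): the loss layer sees every pixel every year but says
nothing about the driver. Bands follow the half-open edges
IQI ≥ 0.6 (`dLUC_commodity`), 0.55 ≤ IQI < 0.6 (`dLUC_landuse`),
IQI < 0.55 (`sLUC`), read literally from the published band labels. The IQI
is reported alongside estimates, never used to filter them.

## The synthetic landscape and what passing tests mean

The generator (`generate_landscape()`) emulates the pipeline's inputs with
embedded ground truth. Conversion events are clustered rectangles (frontier
clearing is spatially clustered, and clusters make the mosaic and
degradation regimes meaningful); loss years are uniform over 2001–2022.
Default composition: 60% natural forest (density 30–95%), 12% managed
plantations, 12% sparse woody cover (density 5–24%), the rest open; 15% of
the area on peat; 10% of loss clusters each for non-commodity fire,
rotational clearing and sparse-cover loss. The default commodity mix spans
soy, maize, rice, oil palm, cattle and forestry products. Commodity maps
cover 80% of crop pixels with 5% label noise (labels swap among crops only,
never forest/non-forest, so area conservation is exact by construction);
10% of crop/pasture pixels are labelled only as mosaic. Commodity-map
observations lag the loss year by 0–5 years (probabilities 0.45, 0.2, 0.15,
0.1, 0.05, 0.05) — tree crops are typically mapped only some years after
clearing — while land-use maps observe at the loss year. Carbon layers are
piecewise-uniform by biome (e.g. tropical AGB 100–400 Mg/ha) and are
recorded into the ground truth at generation time, so emission recovery is
exact rather than distributional.

The statistics tables are exact annual series: base areas plus cumulative
true conversions. Because of that, the statistical-recovery experiment runs
with a **one-year** balance window, where expansions match conversions
one-to-one and recovery is exact; the default three-year window smooths
crop shares across adjacent years, so it is not the right instrument for
an exact-recovery check (it remains the default for ordinary runs).

Passing tests on this landscape demonstrate internal correctness —
conservation, exclusivity, oracle equivalence, exact recovery in the
noiseless limit, directionally correct sensitivity — not accuracy on real
data: the generator does not emulate the error structure of real global
products, georeferenced misalignment, or the year-2000 secondary-forest
blind spot (regrowth after 2000 is invisible to the density baseline and
therefore uncounted, as in the real system).

Problem sizes used by the test-suite: 64×64 pixel landscapes (0.09 ha
pixels, 2001–2022, two regions) for the conservation and sensitivity
suites, 50×50 for the brute-force oracle comparison; these sizes keep every
property checkable in seconds while exercising all code paths.

## A small worked run

```{r}
L <- generate_landscape(landscape_params(seed = 7))
run <- run_footprint(L)
run$checks
head(run$footprint, 5)
sensitivity_run(L, NULL, list(tcd_threshold = 75, peat_horizon = "5"))
```

## Known limitations

* The grid is abstract and planar: no reprojection, no latitude-dependent
  pixel areas; all layers must be pre-aligned.
* Secondary-forest loss, forest gain, degradation severity, non-CO2 gases,
  time-resolved SOC/BGB decay and trade re-allocation are out of scope.
* The cattle meat/leather economic split and value-based co-product
  allocation are not modelled.
* Look-up defaults (deadwood/litter, SOC fractions, plant stocks, peat
  factors beyond tropical oil palm) are typical-magnitude placeholders
  meant to be replaced by a user's own tables through the configuration.
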