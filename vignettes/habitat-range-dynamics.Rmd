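---
title: "Habitat-range dynamics from land use and biome shifts: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat-range dynamics from land use and biome shifts: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habitatrange)
```

## The model

`habitatrange` estimates how the habitat ranges of terrestrial vertebrates
change through time when two pressures act on them: the conversion of natural
vegetation to cropland, pasture and urban land, and climate-driven shifts in
the distribution of biomes. The unit of analysis is the species; the unit of
space is a cell of a regular latitude–longitude grid (0.5° in the default
configuration, with a 6×-finer 5-arc-minute grid used only for
rasterisation).

Three fields define a species' situation in a cell:

* the **extent-of-occurrence (EOO) coverage fraction** `e` — the proportion
  of the cell inside the species' occurrence envelope, fixed in time;
* the **potential natural biome** of the cell at time *t*, a categorical
  code; the species holds a set of suitable biome codes, derived from its
  habitat categories through a crosswalk table;
* the **land-use class fractions** `f_k(t)` for `k ∈ {cropland, pasture,
  urban}`; the species holds a set of artificial classes it tolerates.

From these, two per-cell habitat fractions are formed. The *potential
natural* fraction is `e · 1{biome suitable}`: the part of the EOO the
species could occupy if no land had been converted. The *actual* fraction
splits the cell into the natural remainder `1 − Σ f_k` and the class
fractions, and retains what the species tolerates:

```
actual = e · [ (1 − Σ_k f_k) · 1{biome suitable} + Σ_k f_k · 1{class k tolerated} ]
```

Summing `fraction × spherical cell area` over the grid gives the range sizes
`A_potential(t)` and `A_actual(t)` in km². All relative statistics use the
potential range at the pre-industrial reference year `t0 = 1850` as the
baseline:

```
ΔA(t) = 100% · ( A_actual(t) / A_potential(t0) − 1 )
```

with the climate-only variant substituting `A_potential(t)` in the
numerator. Species with `A_potential(t0) = 0` have no defined change and are
excluded from every across-species statistic.

### Extended versus strict accounting

The formula above (the default, `mode = "extended"`) credits tolerated
artificial land anywhere in the EOO — including cells whose natural biome is
unsuitable. This is the only accounting under which the conversion of
unsuitable natural vegetation to tolerated cropland or pasture can *expand*
a range, an effect the historical record clearly shows for commensal and
open-habitat species. The alternative (`mode = "strict"`) counts artificial
land only inside the potential range, which guarantees
`A_actual(t) ≤ A_potential(t)` at every time. The two modes answer slightly
different questions and genuinely disagree for biome-marginal,
cropland-tolerant species; both ship, both are exercised by the analytic
fixture, and the mode is an explicit argument everywhere.

## Spatial primitives and their conventions

* **Cell areas** use the spherical-zone formula
  `R² · Δλ · (sin φ₂ − sin φ₁)` with `R = 6371 km`; a full-globe grid sums
  to `4πR²` to machine precision, which the tests assert.
* **Polygon rasterisation** follows the centre rule: a fine cell belongs to
  a polygon iff its centre lies inside, with a centre exactly on an edge
  counting as *inside* (a deterministic tie-break that matters for
  axis-aligned range polygons on regular grids). Coarse coverage is the
  flagged-subcell count divided by 36; an area-weighted option exists but is
  off by default, since with row-constant cell areas the two differ only for
  patterns asymmetric within a cell. Rings crossing the antimeridian must be
  pre-split by the caller; single rings are rigidly shifted by whole turns
  of 360° into the grid frame.
* **Fine-to-coarse aggregation** of fractions is area-weighted summation, so
  total class area is conserved exactly (relative error below 1e−10 is
  asserted; in practice it sits at machine epsilon).
* **Temporal pairing**: land use is annual after 2000 but biome maps are
  decadal, so each land-use year is paired with the temporally nearest biome
  map, ties going to the earlier map.

## Land use and its harmonisation

Historical land use carries three variants (`lower ≤ baseline ≤ upper`) on
47 time points (decadal 1700–2000, annual 2001–2016); projections run
decadal 2020–2100. Projections are spliced onto the reconstruction by the
additive junction rule: per class and cell, the historical-minus-projected
difference at 2010 is added to every projected time step, clamped to
[0, 1]; if clamping pushes a cell's class sum above 1 the classes are
rescaled proportionally, preserving their ratios. At the junction the
harmonised series equals the reconstruction exactly — the tests assert this
to machine precision.

Cells whose ingested class fractions sum above 1 (a real artefact of
upstream datasets) are rescaled proportionally on ingest and counted; the
count is attached to the series. "Converted area" everywhere means the
class sum capped at 1, times cell area.

## Climate correction

Simulated climate is bias-corrected and downscaled by the delta method:
`out = sim(t) + (obs_ref − sim_ref)`, per cell and month, after
nearest-neighbour regridding of the simulation onto the observational grid.
The additive rule is applied to all three variables (temperature,
precipitation, percent sunshine), with precipitation clamped at 0 and
sunshine to [0, 100] afterwards; an additive-with-clamp rule was chosen over
a ratio rule for precipitation as the simplest faithful delta, and the
clamp never fires on physically consistent inputs. Reference matching uses
a 1900–1930 mean historically and the single year 2006 for projections
(both configurable). Biome classification at time *t* consumes the climate
averaged over the closed window `[t − 30, t]` — 31 annual fields; a missing
year is an error naming the gap, not a silent skip.

## Statistics

* **Percentiles** of ΔA across included species use linear interpolation
  between order statistics (`stats::quantile` type 7). The convention is
  pinned by an independent sort-and-rank oracle in the tests.
* **Critical losses** count species with `ΔA < −50` strictly; a species at
  exactly −50% is not critical. Grouped by primary mega-biome, shares are
  reported under both normalisations (within the group and of all included
  species), since both readings are in circulation.
* The **primary mega-biome** of a species is the mega-biome whose member
  biomes contribute the largest share of its baseline potential range area,
  ties to the lexicographically lowest label.
* The **marginal-loss curve** pairs the across-species median loss with the
  cumulative converted area and differentiates by successive differences;
  intervals with no new conversion yield undefined marginals rather than
  zeros.
* The **bootstrap** resamples species with replacement (resample size =
  number of species, 10⁴ resamples, fixed Mersenne–Twister seed, global RNG
  state untouched) and summarises each percentile by mean and SD. The SD
  estimates the sampling standard error of the percentile; the tests assert
  that the bootstrap mean recentres the median to well within three of
  them. With all-equal inputs every SD is exactly 0.
* **Multi-model aggregation** is the pointwise mean and *sample* SD
  (n − 1 denominator) across climate-model curves; a single model yields an
  `NA` band, flagged rather than fabricated.

### Sensitivity variants

The **no-migration** variant zeroes the EOO in cells whose *present-day*
(2016) biome is unsuitable before computing future ranges, so only cells
suitable both now and at the projection time count. The 1850 baseline is
deliberately kept from the unfiltered extent: the filter restricts where a
species may persist, not what its pre-industrial range was. Filtered ranges
are pointwise subsets of the main analysis, so projected losses are, by
construction, at least as large — asserted at every species/time in the
tests. The **static-biomes** variant freezes biome maps at the present-day
state, isolating the land-use signal; when biomes are genuinely constant it
reproduces the main analysis exactly.

## The scenario registry

Historical runs cross 47 time points with 3 land-use variants (141 runs);
future runs cross 9 time points, the RCP/SSP registry and 3 climate models.
The registry is an explicit table, not a rule, because usable combinations
are dictated by which land-use projections exist; the default holds 16
combinations (all 20 minus SSPs 1–4 under RCP 8.5), giving 432 future runs.

## The synthetic world

Real inputs of this kind (range polygons, habitat preference tables, land-use
reconstructions, vegetation-model output) are large downloads; the package
instead generates worlds with the statistical structure the analysis
assumes, and every stage is tested against them.

* **Grid**: 0.5° over a 60° × 30° window (120 × 60 cells) — large enough
  for latitudinal structure, small enough that the full 47-year,
  three-variant pipeline runs in seconds.
* **Species** (150; 50 per group): rectangular EOOs with log-uniform sizes,
  so small-ranged species exist; species centred in the tropical band
  (|lat| < 15°) draw sizes scaled by 0.35. Suitable biomes are drawn from
  the biomes present in the EOO at 1850 (always keeping the modal one, so
  baselines are nonzero); tolerance of cropland/pasture/urban is drawn with
  probabilities 0.25/0.40/0.05.
* **Land use**: per-cell logistic conversion `asymptote · logis(r(t − mid))`
  with rate 0.05/yr, asymptote 0.85 scaled by per-cell noise, midpoint 1900
  outside the tropics and 1985 inside — the late-onset structure that
  concentrates recent conversion where ranges are small. Class shares are
  0.6/0.3/0.1; lower/upper variants scale the baseline by ∓10%.
* **Toy climate and biomes**: annual-mean temperature
  `28 − 0.8·|lat| + warming`, with 0.8 °C per century of historical warming
  after 1900 and RCP-specific rates (1.2–4.3 °C/century) in projections;
  the 0.8 °C/deg gradient keeps the tropical/temperate boundary inside the
  domain under the strongest warming. Precipitation is a time-constant
  tropics-wet pattern with longitudinal moisture bands. Six biomes arise
  from three temperature bands (cuts at 5 and 18 °C) × two moisture bands
  (cut at 60 mm/month), values exactly on a cut falling to the lower band.
  This classifier is a deliberately simple, fully documented stand-in for a
  process vegetation model — it is *not* an emulation of one. Future climate
  models are emulated as ±1 °C temperature offsets by 2100.
* **Projections** start from a 5%-biased copy of the 2010 state (so
  harmonisation has real work to do) and scale by SSP-specific trends
  (SSP1 −0.35 … SSP3 +0.60 over 2010–2100, amplified 1.5× in the tropics).

What the generator does **not** emulate: realistic species-richness
patterns, coastlines and ocean masks (every cell is terrestrial), EOO shapes
beyond rectangles, historical reconstruction logic, or vegetation-model
physics. Passing tests therefore demonstrate the correctness of the
*method* — the accounting, the statistics, the orderings and invariants —
not the realism of any particular number the synthetic world produces.

## The analytic fixture

`analytic_fixture()` builds a 4 × 4-cell world with three species and three
time points in which every quantity is a hand-computed exact rational: each
species' EOO is confined to a single latitude row, so per-row cell areas
factor out of all relative statistics, and the two row-area constants were
evaluated independently from the spherical-zone formula and frozen. The
fixture covers a declining natural-habitat specialist, a cropland-tolerant
species whose range expands in extended mode but is flat in strict mode,
and a zero-baseline species that must be excluded. The pipeline must
reproduce the fixture's ledger — areas, changes, percentiles,
critical-loss shares, in both modes — exactly.

```{r fixture}
fx <- analytic_fixture()
res <- run_pipeline(fx, mode = "extended")
subset(res$ranges, species_id == "bird_B",
       select = c(year, A_actual_km2, delta_pct))
```

## Problem sizes and numerical choices

The default test and analysis configuration uses the 120 × 60-cell world
with 150 species, 47 historical and 9 future time points; a full
three-variant historical run takes ~15 s and the complete test suite ~20 s
on one core. These sizes were chosen so the full pipeline — not a stub — is
exercised everywhere while iteration stays interactive. Numerical
tie-breaks are all deterministic and documented: boundary-inclusive
point-in-polygon, earliest interval on peak-conversion rate ties, earlier
map on temporal-pairing ties, lower band on classification-threshold ties,
lowest label on mega-biome ties. Degenerate inputs (zero-cell grids,
empty registries, empty change vectors, missing junction or window years)
raise errors naming the problem rather than producing silent zeros.

## Known limitations

* One primary biome per 0.5° cell: sub-cell mosaics and microclimates are
  invisible, so ranges of species tied to non-primary biomes are
  underestimated and the converse overestimated.
* No habitat connectivity, fragmentation, dispersal speed, hunting,
  invasive-species or disease effects; estimates are upper bounds on actual
  occupancy.
* Ranges cannot leave the EOO envelope, which bounds climate-driven
  expansion for species pushed beyond their documented limits.
* Coastal cells are treated as fully terrestrial (no ocean mask).
* The NetCDF/GeoTIFF formats common for such data are not read directly;
  the documented long-CSV and GeoJSON layouts are the interchange contract.
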