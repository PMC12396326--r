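---
title: "Methods: a millennial bookkeeping model of northern land carbon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a millennial bookkeeping model of northern land carbon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleocarb)
```

## The problem

Between the Last Glacial Maximum (LGM, 21 ka BP) and the preindustrial
(PI, 0 ka on this package's axis), the northern extratropics (>23°N) went
through ice-sheet collapse, permafrost thaw, shelf inundation, wholesale
biome redistribution and the birth of the modern peatland domain. Each of
those transitions moved carbon between land and atmosphere on a scale of
tens to hundreds of Pg C per millennium. `paleocarb` implements a gridded
bookkeeping reconstruction of those stocks and transfers at millennial
resolution: it is not a process model but an accounting machine whose
inputs are climate fields, biome evidence, and curve- or density-based
descriptions of each carbon pool.

Because the original forcing (transient climate-model output, pollen
databases, soil-carbon inventories, GIS layers) cannot ship with a
package, every input is emulated by a seeded synthetic-world generator
with known ground truth. That turns each stage into something testable:
the classifier must recover a truth we planted, the permafrost model must
recover a bias we injected, the ledger must return the trajectories the
generator was configured with.

## The synthetic world

`make_domain()` builds the 23–90°N grid (1° cells by default; a 5° "quick"
grid for fast test cycles) with areas from the spherical band formula and
R = 6371 km. Cell centres sit at half-resolution offsets; the northernmost
row may be partial so the cap is always covered exactly.

`simulate_climate()` produces two pseudo climate-model ensembles over the
22 millennial slices. Both share one deglacial warming trajectory —
piecewise linear in time, full glacial anomaly (default −15 °C) at and
before 17 ka, a knee at 10 ka, zero at 0 ka — a meridional MAAT gradient,
a latitude-dependent seasonal amplitude, and smooth seeded spatial noise.
The second ensemble (`pseudo_trace`) differs by a constant −5 °C MAAT
bias, mirroring the kind of systematic offset that real reconstructions
must correct before using absolute temperatures. Because the bias is
exactly constant and the noise shared, the two ensembles bracket the
pipeline's per-model machinery without injecting uncontrolled divergence;
the residual divergence that drives inter-model terms comes from the
bias interacting with nonlinear thresholds downstream.

Six variables are emitted per slice: mean annual air temperature, warmest
and coldest month temperatures, their range, annual precipitation and
growing-season precipitation. An aridity sector (precipitation scaled far
below the zonal profile) guarantees desert and grassland/savanna cells;
a warm moist southern fringe provides (warm-)temperate and tropical
forest; cold summers produce tundra. The "true" biome map follows an
ordered threshold decision list over these variables
(`default_biome_rules()`); the rules are deterministic, complete by
construction, and checked for completeness at every application.

`simulate_ice_and_sea()` lays two continental sectors, ice sheets that
retreat monotonically from 17 to 5 ka (cold-based ice being their
high-latitude subset), and shelf margins exposed at the LGM and inundated
between 16 and 7 ka. The default shelf width (11° of longitude per sector
edge) makes the area lost to the sea comparable to the area gained from
the ice, so soil area grows modestly toward the present while mean carbon
density declines — the structural behaviour the ledger is designed to
expose.

What the generator does *not* emulate: real spatial patterns of any
climate model, orbital forcing, meltwater pulses, sub-millennial
variability (the multi-century averaging of a transient simulation is
collapsed into one slice per millennium), ice-dammed lakes (treated as
soil), or a Caspian-Sea analogue. Tests passing on this world therefore
demonstrate the correctness of the accounting and estimation machinery,
not fidelity to any real geography.

## Biome model

Training data are pollen-style point samples: `sample_pollen_sites()`
draws sites (duplicates allowed, as in real compilations) from unglaciated
land, copies the true label, corrupts a configurable fraction (default
10%) with a uniformly wrong class, and flags a share as "protected" —
standing in for a source database whose interpretations are exempt from
filtering. Default sample sizes mirror the study conditions: ~15,610
Holocene points (9–0 ka) and ~7,164 deglacial points (21–10 ka).

Training hygiene, the part that matters scientifically:

* `filter_training()` removes tundra labels at sites with mean annual
  temperature above 5 °C — implausible interpretations — unless protected.
* `augment_deserts()` compensates the near-absence of desert evidence in
  pollen data: 242 modern desert sites at 0 ka for the Holocene model,
  the 6-ka desert rows copied into the deglacial set, and 40 random
  desert sites at 21 ka. Requested counts are drawn with replacement from
  the eligible desert cells (they are point locations, and the sampling
  design permits duplicates); a world without desert cells is an error,
  never a silent skip.
* Two separate classifiers per climate model: Holocene (9–0 ka) and
  deglacial (21–10 ka); the 10-ka slice is scored by the deglacial model
  and 9 ka by the Holocene model.

The ensemble is a random forest (via `ranger`, 500 trees by default,
fully grown, seeded, single-threaded for bit-reproducibility) in
*probability* mode: the per-class vote fraction is interpreted directly as
the biome's areal fraction of a grid cell, so several biomes can share a
cell and the downstream carbon arithmetic is linear in the votes.
Covariates are the six climate variables plus a fixed synthetic elevation
field (real reconstructions include topography as a predictor).
On the default world with ≤10% label noise the held-out accuracy exceeds
0.8 on average and 0.7 in every slice, which is the package's acceptance
surface for this module.

## Permafrost

Permafrost fraction is a two-parameter logistic in adjusted mean annual
air temperature, `1/(1 + exp((T - T0)/s))` with defaults T0 = −6 °C,
s = 1.5 °C. The published relationship this emulates is cited but not
printed in the source literature, so the logistic form and its parameters
are this package's design choice, config-exposed. "Continuous" permafrost
is where the fraction reaches 0.99 — a numerical stand-in for 100%
coverage.

Temperature adjustments mirror the calibration a real reconstruction
needs: a per-model base offset (+5 °C for `pseudo_trace`, cancelling its
bias) and a deglacial ramp of −1 °C per millennium between 10 and 17 ka
(constant −7 °C beyond), progressively deepening glacial cold so the LGM
extent reaches its empirically constrained position. The ramp is anchored
at zero at 10 ka by default; the alternative anchoring (a full step
already at 10 ka) is selectable because the textual description admits
both readings. The ramp adds to the base offset rather than replacing it,
again a documented choice where the source is silent.
`calibrate_offsets()` grid-searches the base offset in 0.5 °C steps
against a reference extent at 0 ka (scoring symmetric-difference area,
optionally on a sub-mask, e.g. one sector) and reports residual misfit at
6 and 21 ka without touching the ramp.

## The carbon ledger

Seven pools are carried per millennium: mineral land soil, mineral soil on
the exposed shelf, inundated shelf soil, peat, deep loess, subglacial, and
post-glacial accruing soil.

**Mineral soil** (0–2 m): cell stock =
`area × [(1 − peat_frac − slope_frac) × Σ_c frac_c × tf(c, state) +
slope_frac × 3 kg m⁻²]`, where `tf` is the transfer-function table (mean
and SD per biome × permafrost state; permafrost state is the continuous
mask) and the slope term prices steep terrain independently of biome.
Stocks are computed per climate model and averaged; the inter-model gap is
kept as a diagnostic. Pool SDs treat each transfer function's error as
fully correlated across the cells it applies to and independent between
(class, state) pairs — the dominant error is in the density estimate, not
in cell-level sampling.

**Deep loess** (>2 m, including one extra metre of original deposit so
nothing below the biome-priced 2 m is double-counted; the 2–3 m interval
of non-loess soils is excluded domain-wide): four regions whose configured
areas (2.3 M km²), depths and frozen densities give 363 Pg C at 21 ka.
Deposition of 35 Pg C between 21 and 17 ka raises the peak to 398 Pg C.
When region cells leave the continuous-permafrost mask, the thawed share
of the frozen stock is lost within that millennium, with 10% retained as
a passive pool (>90% loss on thaw). Bookkeeping runs at region level per
climate model; the cell masks only set thaw fractions, which makes totals
resolution-independent. Uncertainty combines the regional area and depth
SDs (first-order, treated as independent) with half the inter-model
spread. The default world's geography is calibrated so the thaw
chronology matches the depositional-era stasis (no loss before 17 ka),
mid-deglacial losses in the southern regions, an 11–10 ka Siberian
collapse, and a present-day remainder near 57 Pg C.

**Peat**: the pool is `450 Pg C × stock_fraction(t)`, with monotone
normalized curves for stock and area that are ~0 at 16 ka and exactly 1
at 0 ka; increments follow bell-shaped schedules peaking at 8 ka (stock)
and 9 ka (area), which reproduces an early-Holocene maximum uptake of
~60 Pg C per millennium. Stock is distributed over cells with peat
initiated by `t` proportionally to their PI extent, scaled so the total
area follows the area curve — full PI extent is reached only at the final
step. Cells south of 38°N without initiation data are assigned 12 ka.
Uncertainty: PI extent ±10% and stock ±36%, plus a back-in-time ramp from
±50% at 16 ka to 0 at PI, combined by root-sum-of-variances. The peat
fraction of each cell is removed from the mineral-soil area to avoid
double counting.

**Post-glacial accrual**: deglaciated cells build carbon as
`Ce × (1 − exp(−k t))` toward the biome equilibrium (transfer-function
based, split 0–1/1–2 m), with k = 1 per millennium for forest and tundra
(≥95% of equilibrium after three millennia) and k = 0.5 for grassland
(deliberately short of it). After three millennia the cell hands over to
the biome-based mineral stock.

**Subglacial**: tundra soil (35 kg C m⁻² over 0–2 m) under cold-based
ice, plus peat to 1 m over 1% of that area; released to the atmosphere as
the cold-based area shrinks, ending by 5 ka. Its relative SD (50%) encodes
that this pool is hypothetical.

**Shelf**: soil on cells that are land at `t` but ocean at PI forms the
exposed-shelf pool (priced like land mineral soil from the same
classifier fractions — the source treats it "similarly to land", which we
implement as identically). When cells are inundated, their stock moves to
the inundated pool — conserved exactly, never decaying — while 30%
(range 0–66%; SD half the fraction) of the transferred carbon is assumed
to cycle via the atmosphere. That cycled flux enters net changes but
never stocks, which is why cumulative net losses can exceed the stock
drawdown by exactly the cumulative cycled flux.

**Net and gross changes**: per-pool deltas between consecutive millennia;
the net land–atmosphere transfer is the total stock delta minus the
cycled flux. Change uncertainty uses the stock dispersion index
`V = σ²/μ` — implemented exactly as printed in the source even though it
is not the conventional dimensionless coefficient of variation — averaged
over the two millennia and scaled by |Δ| (`E = mean(V_t, V_{t+1})·|Δ|`),
with pools combined by root-sum-of-variances. Gross changes compare
per-cell maps so redistribution is visible even when the net is small.

## Atmosphere

`pgc_to_ppm()` converts a carbon transfer to a CO₂ mixing-ratio change
via moles of carbon over moles of air, with a 5.15 × 10²¹ g atmosphere.
Molar masses (28.966, 12.011 g mol⁻¹) are not stated by the source; with
them, 1 ppm ≈ 2.13 Pg C, which reproduces both quoted conversions: a
440 Pg C deglacial release at the 25% millennial airborne fraction gives
~52 ppm, and the ~370 Pg C Holocene peat-driven gain at the ~13% uptake
response gives ~23 ppm. Releases and uptakes are treated asymmetrically
(airborne fraction vs uptake response); `ppm_series()` supports both
per-millennium conversion and the cumulative-sum convention in which the
headline numbers are quoted. `icecore_millennial_delta()` bins an
ice-core record by millennium and telescopes consecutive differences to
last-minus-first per bin, reporting sparse bins as missing rather than
zero.

## Numerical and design choices

* **Time axis**: integer ka BP, 21 → 0; "the change at t" means
  stock(t) − stock(t+1) intervals walked oldest-first.
* **Determinism**: one run seed; every stage derives a sub-seed, all
  forests are seeded and single-threaded, so a configuration reproduces
  bit-identically.
* **Resolution**: the test suite runs the full pipeline on the 5° quick
  grid (the package's CI scale) and uses the 1° grid only for stages that
  need latitudinal precision without the classifier (permafrost
  calibration recovery, the loess trajectory); the acceptance script runs
  the full 1° reconstruction. Pool totals are carried by densities and
  region-level bookkeeping, so they are grid-size independent to within a
  few percent; delineation-dependent quantities (e.g. the loess remainder)
  are sharper at 1°.
* **Prescribed-trajectory recovery** is tested on a low-noise world:
  climate noise moves the continuous-permafrost boundary, which is a
  property of the (synthetic) climate, not of the ledger; damping the
  noise isolates what the test is about — that the ledger returns the
  trajectories the generator encodes.
* **Degenerate inputs**: empty loess specs yield identically zero pools;
  single-class training sets yield a unit vote for that class; empty
  holdout slices are omitted with a warning; argmax ties resolve to the
  lowest class index in the fixed ordering (affects accuracy metrics
  only, never stocks, which use fractions).
* **Readvance** of ice or sea is rejected, not modelled — it does not
  occur in the reconstructed interval.

## Known limitations

Phytomass, fire, lakes, human land use and CH₄ partitioning are out of
scope, as in the source reconstruction. The synthetic world's inter-model
divergence is milder than between real climate models (constant bias,
shared noise), so inter-model uncertainty terms are exercised but small.
Emergent headline trajectories (e.g. the LGM-to-PI total stock change)
depend on the synthetic geography and transfer-function defaults and are
reported as what this world produces, not as reconstructions of the real
quantity; only the printed-arithmetic conversions and the
curve-calibrated pools carry over directly.
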