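---
title: "An individual-based model of green turtle foraging, migration, and nesting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An individual-based model of green turtle foraging, migration, and nesting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model in one paragraph

`seaturtleIBM` simulates a population of adult female green sea turtles
(*Chelonia mydas*) on a gridded seascape. Each turtle is a capital breeder
cycling through five internal states: she **feeds** on a seagrass patch,
accumulating energy; occasionally undertakes a **foraging migration** to
another patch when her patch is depleted; starts a **prenesting migration**
to her natal rookery once her stored energy covers the whole reproductive
cycle; **nests** for a strategy-dependent number of days; and finally makes
a **postnesting migration** back to her last feeding patch. Feeding patches
regrow logistically and are depleted in proportion to the number of turtles
grazing them, so turtles interact indirectly through resource competition.
Movement is straight-line swimming at a fixed motor speed with a
wall-following coastal avoidance heuristic and, under one scenario, passive
drift in a current field. Migratory corridors, feeding hot spots, rookery
mixing at feeding grounds, remigration intervals and rookery reproductive
output are all *emergent*: none is imposed directly.

## Entities, scales, and scheduling

The world is a grid of square cells, 7 km on a side by default (the
reference world is 567 x 577 cells, 3,969 x 4,039 km, mapped onto
25-65°E / 30°S-10°N with an equirectangular y-to-latitude conversion).
Cells are terrestrial (barriers), plain ocean, nesting sites, or feeding
patches. Turtles live in continuous coordinates on this grid; the occupied
cell is found by floor division by the cell size.

A time step is half a day. At each step all turtles are processed first
(in a freshly shuffled order), then all patches. Within a step turtles
never read other turtles' state — they interact only through the patch
resource levels, which are updated in the patch phase — so the engine
processes the turtle phase as vectorized state-groups from a
start-of-step snapshot while the per-step shuffle drives the order of the
random draws. This preserves both the distributional content of
randomized scheduling and exact per-seed reproducibility, at a small
fraction of the cost of an agent-by-agent loop.

A default run is 36,500 steps (about 50 years); the first 1,500 steps
(about two years) are a burn-in during which nothing is observed, so that
the arbitrary initial state (uniform random energies, uniform random
patch resource levels) does not contaminate the statistics. Desk-scale
runs shrink the population and the horizon, never the cell size.

## The energy budget

With `phi[p, t]` the resource level of patch `p`:

* **Feeding** (per step): `energy += alpha * phi[p, t]`, with `alpha` the
  depletion coefficient (default 0.001/day). The same coefficient scales
  the patch's loss, `alpha * N[p, t] * phi[p, t]`, so individual intake
  and patch depletion are consistent.
* **Migrating** (per step): `energy -= delta_eps_m` (default 10/day).
* **Nesting** (per step): `energy -= delta_eps_n` (default 5/day), for
  `T_n = S_N * T_n_max` days (default `T_n_max` 100 days).

A feeding turtle starts her prenesting migration exactly when

```
energy >= eps_cycle = 2 * delta_eps_m * d / c + S_N * T_n_max * delta_eps_n
```

where `d` is the distance from her current patch to her natal site and
`c` the motor speed (65 km/day, a tracked field value). The threshold is
deterministic and inclusive; a deterministic trigger is testable, and the
"approximately" of a stochastic trigger would only blur the emergent
remigration intervals. Energy may go negative during unexpectedly long
migrations — there is no mortality in the model — and such excursions are
counted in the run metadata rather than clamped, so the energy ledger
closes exactly: final energy = initial + gains - migration costs -
nesting costs, which the test suite asserts to floating-point accuracy.

The initial energy is drawn uniformly between 0 and `eps_cycle` computed
from the individual's *own* initial patch (not a global constant): the
cycle requirement is the natural energy scale of each individual, and
using her own distance avoids a systematic head start for turtles
allocated to far patches.

## Behavioral strategies

Two indices in [0, 1], fixed and equal for all turtles within a run:

* `S_F`, foraging patch fidelity. The per-step probability of leaving a
  patch is `P_leave = (1 - S_F)/1000 * (1 - logistic((phi - b)/a))` with
  `a = 50` (steepness) and `b = 300` (leaving threshold) in resource
  units. The curve decreases in `phi` (rich patches are never abandoned)
  and in `S_F`; the 1/1000 ceiling makes patch departures rare events on
  the half-day scale, so "movers" (`S_F` near 0) churn between patches
  over months, not days.
* `S_N`, nesting allocation. Scales both the nesting duration
  (`S_N * T_n_max`) and therefore the nesting energy spend: "investment"
  nesters (`S_N` near 1) nest long and expensively and consequently breed
  rarely; "conservative" nesters breed cheap and often.

When a turtle leaves a patch, the destination is drawn with probability
proportional to `(1 - d_rel)^lambda`, where `d_rel` rescales the distance
from the current patch into [0, 1] using the minimum and maximum pairwise
patch distances of the landscape, and `lambda = 5`. This encodes
knowledge of *where* patches are (decaying with distance) without
knowledge of their resource levels. The same kernel, measured from the
natal site, assigns the initial patch at setup. Rows whose weights are
all zero (only possible in degenerate registries where every candidate
sits at the maximum distance) fall back to a uniform draw.

## Movement and coast avoidance

A migrating turtle covers `c/2` km per step straight toward her target;
if the remaining distance is shorter, she lands exactly on the target.
Arrival is a closed ball of radius `detection_range_km` (default 7 km,
one cell; the value is a free design parameter).

Coastal cells within the 100 km sensing radius block movement. The
avoidance is a wall follower: if the heading toward the target is blocked
over the next step length, the heading rotates in 15° increments up to
the minimal angle that clears. The turn side is chosen at the first
obstruction of a migration leg (the side with the smaller clearing angle;
ties go left) and memorized. While following, the swimming direction
persists from step to step: it is first relaxed one increment back
toward the target when that is clear, kept when not, and rotated further
in the memorized direction when even the current heading is blocked — so
the turtle hugs the coast and peels off onto the direct course as soon
as it clears. The memorized side is
**reversed** when a postnesting migration starts, which makes out-and-back
routes approximately symmetric around barriers, and cleared when foraging
migrations start or end and when a new prenesting migration starts (the
side is re-derived at the next obstruction). A turtle fully enclosed by
land (impossible in the shipped worlds, possible in hand-built ones)
stays put and the event is counted.

Blocking is tested by sampling the ray every half cell plus its endpoint;
at 7 km cells nothing larger than a cell corner can slip between samples,
and as a belt-and-braces measure the motor endpoint is truncated back to
the last ocean point along its segment, so the no-land invariant is exact
rather than probabilistic. The persistence of the wall-follow heading is
not cosmetic: a follower that restarted from the target heading every
step can be trapped in a limit cycle when an opposing drift cancels each
step's progress, whereas the persistent heading keeps tracing the
obstacle.

Under the currents scenario the half-step current vector of the occupied
cell is added to the motor displacement — plain vector addition of the
motor and drift velocities. Turtles do not anticipate drift. Two
numerical guards are needed. First, when the local drift per step
exceeds the detection range, a turtle could orbit her target forever
without ever being inside it; the terminal docking step (clear path,
target within one step) therefore takes no drift, and every other step
does. Second, the drift leg is truncated at the coast *separately* from
the checked-clear motor leg: currents can pin a turtle against a shore
but never strand her on land or cancel her motor progress along it.
Scenario 2 with an all-zero current field is bit-identical to scenario 1
under the same seed, which the tests assert.

## Resource dynamics and the calibration of beta

Patches follow a logistic-growth/linear-grazing update, clamped to
`[0, phi_max]`:

```
phi[t+1] = phi[t] + beta * phi[t] * (1 - phi[t]/phi_max)
                  - alpha * N[t] * phi[t]
```

The regrowth coefficient is not free: it is set to
`beta = 2 * alpha * N_T / N_F` so that with the population spread evenly
over the patches (`N = N_T / N_F`) the stationary level is exactly
`phi_max / 2` — resources neither blow up nor collapse at the design
point, and the total system resource is stationary. The engine recomputes
`beta` from the *actual* `N_T` and `N_F` of each run, so down-scaled runs
keep the same equilibrium structure. All daily rates are divided by two
once, at initialization, for the half-day step.

`phi_max` is a pure scale parameter (1,000 by default): gains, leave
thresholds and depletion all scale with it, so its absolute value is a
calibration convention, not a claim about seagrass biomass.

A **perturbation** (scenario 3) is a latitude band of reduced
productivity: patches within `d_sigma_max` degrees latitude of
`sigma_y` lose `sigma_i * beta * (d_sigma_max / d) * phi` per step, where
`d` is the latitudinal distance. The `1/d` law diverges at the
perturbation latitude, so `d` is floored at one cell's latitude extent
and the result clamped at zero — placing the band south of all patches
keeps `d` positive in the shipped scenario, and the floor makes the
operator total for any geometry. The default band sits one degree south
of the southernmost patch with a 10° range and intensity 0.2, i.e. the
southern feeding grounds are degraded, the northern ones untouched.

## Initialization

Rookery allocation follows the relative weights of the 14 reference
rookeries (10,000 : 5,000 x 3 : 2,000 x 2 : 200 x 8, summing to 30,600).
Rookeries whose proportional share floors at or below the minimum
allocation (45 turtles at the 7,000 scale, rescaled proportionally for
smaller populations) receive exactly that minimum; the rest of the
population is apportioned among the larger rookeries by largest
remainder. This reproduces both the exact total and the fixed 45-turtle
contingent of the smallest rookeries.

## The synthetic seascapes

The original study ran on GIS-derived maps of the south-west Indian
Ocean. The package does not reproduce those rasters; instead
`generate_synthetic_landscape()` builds worlds with the same structural
features, deterministically per seed:

* **`reference`** — the full study-scale grid (567 x 577 cells of 7 km) with a
  western continental coastline (anchored on the real coast's
  longitudes), an elongated Madagascar-like barrier island, a channel
  between them, 14 rookeries carrying the reference trigrams and weights
  at their approximate true positions, 47 feeding patches clustered along
  the coasts, and a basin-scale counterclockwise gyre (peak 25 km/day)
  giving a southward western-boundary flow through the channel.
* **`channel`** — a 140 x 160 miniature with the same motifs (coast,
  barrier island, 4 island rookeries with 10,000/5,000/2,000/200 weights,
  24 coastal patches, a 30 km/day gyre), sized for desk experiments.
* **`minimal`** — a 20 x 20 all-ocean world with one site and two patches;
  the smallest world on which the full state machine turns.

What these worlds emulate: barrier-constrained corridors, coastal patch
clustering, rookery weight asymmetry, distance structure between
rookeries and feeding grounds, gyre-style drift. What they do not:
bathymetry, seasonal currents, the true shapes of coastlines and seagrass
beds. Tests passing on them therefore validate the *mechanisms* and the
*directional* strategy findings, not site-specific predictions for the
real region.

## Observation and statistics

After burn-in the engine records, per patch, time usage (turtle-steps),
post-nesting and foraging arrival counts, and post-nesting arrivals
broken down by rookery of origin; per nesting event, the turtle, site,
step and post-nesting energy; and Bernoulli track samples (probability
1/500 per migrating turtle-step, pre- and postnesting legs only —
sampling a *rate* rather than a fixed stride keeps records independent of
turtle indexing). From these:

* `origin_diversity()` — normalized Shannon index
  `-sum(r ln r)/ln(N_N)` of the origin mix of a patch's post-nesting
  visitors, in [0, 1] by construction.
* `remigration_intervals()` — per-individual mean time between successive
  nesting events, in years; individuals with fewer than two recorded
  events are excluded.
* `reproductive_output()` — per rookery,
  `S_N * sum(energy_after / interval_days)` over repeat nesting events.
  The raw value has units of energy per day; comparisons across scales
  should use matched run lengths and population sizes.
* `kernel_density()` — Gaussian product-kernel utilization distribution
  of pooled track positions (default: normal-reference bandwidth, 125
  positions subsampled per run without replacement, i.e. 10,000 for an
  80-run scenario), on the landscape grid.

## Problem sizes and the calibration target

The cost of nesting relative to feeding and swimming was calibrated by
aiming the emergent mean individual remigration interval at the 2-7 year
band reported across wild populations. With the shipped defaults
(`alpha` 0.001/day, `phi_max` 1000, `delta_eps_m` 10/day, `delta_eps_n`
5/day, `T_n_max` 100 days, `a` 50, `b` 300, `lambda` 5) a desk-scale
reference run — 500 turtles on the full reference seascape, two years of
burn-in plus about twenty observed years — lands near 3.1 years. The test
suite and the acceptance script re-run exactly these conditions; the
directional strategy comparisons use the reference world at 300 turtles
and five replicate seed pairs per arm, sizes chosen so the whole suite
stays comfortably re-runnable on a laptop. At that scale the
perturbation effects (by nesting strategy and by rookery) are strong
enough for significant one-sided rank tests; the current-induced
mover-stayer differential is real but small relative to replicate noise,
so the suite asserts its direction (of the mean paired loss and of the
rank statistic) rather than a significance level — a powered test of
that contrast needs full-scale runs.

## Known limitations

No mortality, no demography, no males or juveniles, no metabolic
maintenance term (assumed state-independent and omitted), no seasonality
in currents or seagrass growth, no learning or evolution of strategies
(strategies are run-level constants, though stored per agent), planar
geometry (no great-circle correction — consistent with the grid's own km
scale), and synthetic rather than GIS seascapes. The reproductive output
statistic weighs energy at nesting against remigration intervals; it is a
relative index for comparing scenarios and strategies, not an absolute
count of hatchlings.
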