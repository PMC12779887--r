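---
title: "goosesim: model description and methodological choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{goosesim: model description and methodological choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goosesim)
```

## The model in brief

`goosesim` is a spatially explicit individual-based model of four goose
species wintering on a managed grassland landscape: barnacle goose (BAG,
*Branta leucopsis*, the smallest), greater white-fronted goose (WFG),
pink-footed goose (PFG), and greylag goose (GLG, the largest). The agents
are flocks of fixed size (1000 / 100 / 200 / 400 geese respectively). The
landscape is a grid of 1-ha patches typed as roost, other, scaring-area
grassland (scaring of foraging geese is allowed), accommodation-area
grassland (geese are tolerated and damage is compensated), or nature-area
grassland. The season runs from November 1 to May 15 (195 days) at an
hourly resolution — 4680 steps at full length.

Each hour a flock follows a decision tree. In daylight it roosts once its
per-goose mass has reached the day's maximum (the empirical daily mean
weight plus a species-specific maximal additional weight) and otherwise
forages. Foraging patches come from a 100-entry memory of visited
locations — scored by age-discounted expected net energy gain — or, when
memory fails, from a composite random walk (an exponential "Brownian"
component mixed with a bounded-Pareto truncated-Lévy component). Flocks
may join conspecifics near their destination, accept or reject a patch by
its sward height, and are displaced ~2 km in a random direction when
scared (most likely in scaring areas). At night an under-weight flock may
forage if at least eight hours of rest remain before sunrise and the moon
is bright enough; otherwise it roosts, reusing its previous roost when
that is within 10 km. Intake depletes the sward; grass regrows daily from
temperature and radiation. A flock dies when its per-goose mass falls
below the species minimum.

Species interact *only* through the shared sward. Because the four species
use different sward heights efficiently, depletion produces both
exploitative competition (small-billed barnacle geese crop swards below
the heights larger species can use) and facilitation (larger species graze
tall swards down toward the barnacle optimum).

## Movement

Random foraging flights draw their length \(x\) (in hm = patch units) from
the mixture survival

\[
P_x = P_{BW}\,e^{-\lambda x} + (1-P_{BW})\Bigl(1 -
\frac{1 - x_{min}^{\mu-1}x^{1-\mu}}{1 - (x_{min}/x_{max})^{\mu-1}}\Bigr),
\qquad x_{min}=1.
\]

As printed, the exponential term is not conditioned on \(x \ge x_{min}\),
so the expression is marginally improper at \(x_{min}\) (it evaluates to
\(P_{BW}e^{-\lambda} + (1-P_{BW}) < 1\)). `crw_survival(..., form =
"printed")` evaluates exactly this expression; the sampler `sample_step`
shifts the exponential component to start at \(x_{min}\) so that every
draw is a legal flight length, and `crw_survival(..., form = "sampling")`
is the exact survival of that sampler. Monte-Carlo oracle tests compare
the sampler against the sampling form; analytic tests pin the printed
form. `fit_crw` maximizes the likelihood of the mixture density (the
derivative of the sampling-form survival) over \((P_{BW}, \lambda, \mu)\)
with \(x_{max}\) fixed at the sample maximum; a least-squares fit to the
log empirical survival (`method = "ls_icfd"`) is available as an
alternative criterion because the original description ("MLE of the
calculated inverse cumulative frequency distribution on the observed one")
admits both readings.

Flight duration over \(d\) patches is \(T = e^S \cdot d L_{patch}/v\) with
\(S = 10 / (1 + c_1 (d L_{patch} c_3)^{c_2})\): geese circle before
landing, so short hops are disproportionately expensive, and \(T\)
approaches the straight-line time as \(d\) grows. Note a small quirk of
the printed coefficients: for the barnacle parameterization \(T(1) >
T(2)\) — the sigmoid decays faster than the linear term grows below
\(d \approx 2\) — so monotonicity in distance holds from 2 patches on.

## Foraging functional response

The published parameter table gives, per species, a bite-mass slope
\(b_1\) (g/m), a second coefficient \(b_2\), a handling coefficient \(c\)
(s/m), a minimal cropping time \(t_{crop}\) (s), a maximal chewing rate
\(r_{chew}\) (g/s) and a maximal instantaneous rate \(i_{max}\) (g/s), but
not the functional form, which lives in an earlier model. `goosesim` uses
a documented default:

\[
m(h) = \min\bigl(b_1\,h\,e^{-h/h_{access}},\; b_2 h_{cap}\bigr),\qquad
\tau(h) = \max(t_{crop},\, m(h)/r_{chew}) + c\,h,\qquad
r(h) = \min\bigl(i_{max},\, m(h)/\tau(h)\bigr)
\]

with \(h\) the sward height (m), \(m\) the bite mass (g dry matter) and
\(\tau\) the time per bite (s). Two elements are deliberate extensions of
the obvious Holling-style skeleton:

* **The accessibility factor** \(e^{-h/h_{access}}\) encodes declining
  bite quality and sward accessibility in tall, stemmy vegetation; without
  it, the table's small \(c\) values make every species' response purely
  saturating, which removes the sward-height mechanism (barnacle geese
  would be indifferent between a 2-cm lawn and a 15-cm spring sward, and
  neither facilitation nor competition could emerge). \(h_{access}\)
  defaults to 0.03 m (BAG), 0.25 m (GLG), 0.10 m (PFG, WFG) — small-billed
  grazers lose efficiency in tall swards much sooner than large-billed
  ones. These are model defaults, not literature values, and sit in the
  config next to the other functional-response parameters.
* **The cap** \(b_2 h_{cap}\) (with \(h_{cap}=0.01\) m) bounds the
  digestively feasible bite. The published \(b_2\) values are typeset
  ambiguously; the bundled parse (7 / 6 / 102 / 129) is marked provisional
  in the config and the cap rarely binds under the defaults.

The whole response sits behind `intake_rate()`, so an alternative form is
a one-line swap; the tests pin the contract (zero at bare ground, bounded
by \(i_{max}\), unimodal-or-saturating) rather than the curve.

`optimal_height()` returns the *smallest* grid height attaining the
maximal rate — the shortest sward delivering full intake — because the
\(i_{max}\) ceiling produces plateaus. Under the defaults the optima order
as BAG (1.1 cm) < WFG (2.5 cm) < PFG (3.4 cm) < GLG (9.3 cm), the ordering
that makes barnacle geese the beneficiaries of grazing by the larger
species, and the full-rate windows nest in the same way (a sward cropped
to 2 cm is still at full rate for BAG, far below it for GLG).

## Energetics

Hourly net energy per goose is metabolizable intake
(\(g \cdot e_{grass} \cdot q_{assim}\)) minus activity costs at the
foraging, flight or resting metabolic rate for the seconds spent in each
activity (always summing to 3600 s). Mass moves by
\(\Delta E / e_{tissue}\) and is capped at the day's maximum weight. The
conversion constants (\(e_{grass} = 17.8\) kJ/g dry matter,
\(q_{assim} = 0.35\), \(e_{tissue} = 34.3\) kJ/g) are config defaults of
the usual waterfowl magnitude. Grazing removes
\(r(h)\cdot t_{forage}\cdot n\) grams at start-of-hour height (an explicit
discretization choice), bounded by the standing crop so the grass-mass
ledger balances exactly: 150 000 g of dry matter corresponds to 1 cm of
height on a 1-ha patch.

## Exogenous drivers

* **Grass growth.** A light-use-efficiency surrogate: daily increment
  (cm) \(= g_{max}\min(1, R/R_{ref})\,\mathrm{clamp}((T-T_{base})/(T_{opt}-
  T_{base}), 0, 1)\) with defaults \(g_{max}=0.15\) cm/day, \(R_{ref}=15\)
  MJ m\(^{-2}\) day\(^{-1}\), \(T_{base}=5\,°C\), \(T_{opt}=18\,°C\).
  Height-dependent growth (GHDGG) is available as a Gaussian factor
  peaking at `h_opt` (default 7 cm); it is off by default — sensitivity
  runs of the original system showed growth detail does not change the
  qualitative outcomes, and the detailed empirical growth curves are not
  reproducible from published material.
* **Light and moon.** Sunrise/sunset from the standard solar-declination
  formula at latitude 53.2° N. Moonlight is "sufficient" when the
  illuminated fraction of a 29.53-day phase cycle reaches the threshold
  (default 0.5) and the moon is plausibly up (within ±6.2 h of an
  approximate transit that advances ~50 min/day, putting the full moon up
  all night). These are deliberately coarse, documented approximations —
  they gate a behavioural rule, not an ephemeris.
* **Weight calendars.** The empirical daily mean weights are not
  published; the fixture generator anchors the curve at the species'
  initial weight in early November and adds a sigmoidal spring gain
  (midpoint mid-March, ~60% of the maximal additional weight) — geese
  fatten before spring migration and the maximum weight is mean + extra.
* **Population trajectories.** A downward-opening quadratic per species,
  parameterized by (peak count, peak day, edge fraction), peaking on
  simulation day 92 (February 1) and clipped at zero. The daily flock
  count is the trajectory divided by flock size; arrivals spawn at the
  species' arrival roost sites, departures retire the most recently
  arrived flocks first.

## Scheduling and reproducibility

Hour 0 of each day applies grass growth (and advances an ungrazed
reference twin used for yield loss), then adjusts flock counts. Flocks
step in an order re-randomized every hour. The run uses one seeded RNG
stream; `run_simulation(land, config, seed)` is bit-reproducible given the
same inputs. Within an hour, movement decisions read start-of-hour sward
heights and conspecific positions (a snapshot), while depletion is applied
sequentially — flocks later in the random order see the standing crop left
by earlier ones.

## Economics

Yield loss compares final sward heights on agricultural grassland (scaring
+ accommodation; nature excluded by default, includable by flag) against
the ungrazed reference: €\(= \sum \max(0, \Delta h_{cm}) \times 150
\times 0.25\), i.e. €37.50 per cm per ha. Total costs add €10 per scaring
event and a configurable appraisal cost per affected agricultural patch
(default €0 — the source prices scaring explicitly but not appraisal).

## Scaled-down study conditions

The headline full-scale experiment (700×700 patches, up to ~900 000 geese,
11\(^4\) = 14 641 runs) is supported by the code but is cluster-scale. The
package's own experiments — used by its tests and by
`scripts/acceptance.R` — run a desk-scale analogue chosen once and stated
here:

* 100×100-patch landscape generated with the full system's patch-type
  proportions (scaring 28.4%, accommodation 3.2%, nature 2.6%, roost
  1.6%), nature clustered near roosts;
* populations at 1/100 of the wintering maxima (so 0–8 flocks per species
  at peak), quadratic trajectories unchanged;
* **arrival sites scaled with landscape area** (shared between species):
  the full system packs ~8–13 flocks per active roost site, and that local
  crowding — not the global population — is what saturates the small
  near-roost nature areas. Keeping the full-region site counts on a small
  grid would spread flocks so thinly that no patch ever experiences
  competition;
* 120-day season (November 1 – February 28, covering the January–February
  population peak) for sweep runs; 195 days elsewhere;
* a two-level factorial over the four species (fractions 0.5 and 2.0 of
  the scaled maxima, 16 combinations) plus a centre point at 1.25,
  replicated over 5 seeds and analysed with `fit_importance()` — the same
  factorial-plus-normalized-coefficients analysis used at full scale, at a
  size a desk machine completes in minutes.

One directional result does **not** reproduce at this scale and the
package reports it as such rather than adjusting conditions to force it:
the increase of every species' agricultural-foraging fraction with total
goose numbers. That direction requires the small near-roost nature areas
to saturate — to be grazed below usability — as numbers grow. At 1/100
populations on a 100×100 grid the per-hectare goose density is about half
the full system's, seasonal offtake stays well below the nature standing
crop, and nature swards equilibrate near species-preferred heights instead
of collapsing; partially grazed safe swards then mildly attract the
small-billed species (the very mechanism that produces the correct
facilitation signs), leaving the slope flat to slightly negative for three
of the four species. The corresponding acceptance test states the
full-scale expectation verbatim and is allowed to fail.

What the desk scale can and cannot show: sign-level, mechanism-level
behaviour (fractions shifting toward agricultural land with numbers, the
barnacle/large-species facilitation signs, greylag's larger per-goose
damage) is reproducible; magnitudes — absolute yield losses, scaring-event
counts, the R² of importance regressions — are not, and the package makes
no claim that they are. The synthetic landscape also preserves only
composition and qualitative clustering, not real geography, and synthetic
weather/weight/track fixtures are smooth idealizations: passing tests
demonstrate internal consistency and parameter recoverability, not
empirical validation against field data.

## Calibration procedures

The data-to-parameter chain runs on plain GPS-fix tables (animal, time,
projected x/y in metres, speed): roost cells are 100-m cells visited on
≥4 distinct nights between 0:00 and 4:00 local (species-pooled, since
roosts are shared); flight segments chain consecutive fixes with recorded
speed strictly above 12 m/s and gaps ≤15 min; flight-time coefficients are
fitted by nonlinear least squares on the sigmoid scale \(\log(Tv/d)\);
hourly displacements (60 ± 5 min pairs, ≥1 hm) feed the step-length fit.
The flock-size rule is the 20th percentile (inverse-ECDF quantile) of
observed flock sizes. The track generator plants known roosts, CRW
parameters and flight coefficients, and times the evening roost return off
the hourly grid so it cannot contaminate hourly displacement samples —
every stage of the chain is therefore testable against planted truth.

## Numerical and degenerate-input choices

* Grid bounds are hard: random-walk draws and scare bearings that leave
  the grid are re-drawn (20 and 100 attempts, then a uniform fallback /
  error). No wrap-around.
* A flock rejected by `max_relocations` (default 3) patches in one hour
  settles on the last one — an hour has to end somewhere; the alternative
  (resting instead) suppresses foraging time at low sward quality.
* Memory is deduplicating: re-visiting a cell refreshes its entry rather
  than duplicating it, so one cell cannot monopolize the 100 slots.
* At most one disturbance per flock-hour.
* Flight time within an hour is capped at 3600 s; the hourly activity
  ledger always sums to exactly 3600 s.
* `fit_crw` uses three starting points and transformed coordinates
  (logit/log/log); non-convergence is an explicit error, never a silent
  default.

## Known limitations

* The functional response (form and the \(h_{access}\), \(b_2\) defaults)
  is a documented surrogate; anyone with the original closed form can swap
  it in behind `intake_rate()`.
* No nutrient return from droppings, no thermoregulatory weather
  dependence of metabolic rates, no within-flock heterogeneity, no
  interspecific flock joining (attraction is same-species only, as in the
  source system).
* Sward-height dynamics ignore trampling and senescence; GHDGG is a
  single Gaussian hook, not the full empirical growth model.
* The moon and sun models are approximations good to tens of minutes;
  they only gate night foraging.
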