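---
title: "Climate-sensitive stand dynamics in standclim: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Climate-sensitive stand dynamics in standclim: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(standclim)
```

## What the package models

`standclim` projects forest carbon and species composition over a century
for a network of inventory plots, in the tradition of empirical cohort
growth-and-yield simulators with a climate extension. Each plot carries
live tree cohorts (species, trees/ha, DBH, height) and a snag pool; the
projection advances in 10-year cycles. Climate enters through species
viability scores and through a climate-change mortality rule keyed to each
cohort's establishment climate, and disturbance enters through an
empirical regime estimated from repeat inventory measurements. The design
target is the class of questions asked of such simulators in long-term
National Forest planning: how sensitive are century-scale carbon and
composition projections to the climate-mortality parameterisation and to
the disturbance probabilities?

## Species viability and the three mortality pathways

A species' **viability score** under a climate vector $x$ is a product of
Gaussian niche kernels over climate metrics (defaults: mean annual
temperature, degC; mean annual precipitation, mm):

$$v_s(x) = \prod_k \exp\!\left(-\tfrac{1}{2}\left(\frac{x_k - \mu_{s,k}}{\sigma_{s,k}}\right)^2\right),$$

a parametric stand-in for the presence/absence-trained viability models
used operationally. The score is 1 at the niche optimum; species are
treated as rarely viable below 0.5. Three mortality pathways use it:

1. **Envelope mortality** (`envelope_survival_multiplier`). Above the 0.5
   threshold nothing happens; below it, cohort density survives each cycle
   with fraction $v/0.5$, a linear ramp to zero. The ramp keeps envelope
   mortality gradual, deliberately distinct from the sudden whole-cohort
   kills of the elevation-window rule.
2. **Viability-modified carrying capacity** (`effective_max_sdi`). A
   plot's maximum stand density index is its basal-area-weighted mean of
   species base maximum SDI, multiplied by the basal-area-weighted mean
   viability (floored at 0.2 to avoid a zero-capacity singularity — a
   numerical guard, visible in the configuration). As climate favours
   sparser-growing species the capacity falls and density-dependent
   mortality follows.
3. **Elevation-window rule** (`dclim_triggered`). A cohort dies whole when
   for *any* metric the climate change since its establishment exceeds
   $\tau_k = m \cdot |g_k| \cdot (300 + 150)$, where $g_k$ is the
   metric's lapse with elevation and $m$ the severity multiplier
   (off / 2 / 1 / 0.5). The +300 m / −150 m window approximates one seed
   zone. With the standard temperature lapse −0.0065 degC/m the default
   threshold is $\tau_{MAT} = 2.925$ degC. "Any metric" is the
   conservative reading of a rule enforced jointly by several metrics with
   no published combination formula; `semantics = "all"` is available.
   The rule is independent of viability: a killed cohort's species can be
   replanted immediately, with the current climate as its new baseline
   (`reset_establishment`), restoring immunity until climate drifts beyond
   the window again.

## Stand dynamics

Density is tracked in Reineke's stand density index,
$SDI = \sum_i n_i (d_i / 25.4)^{1.605}$. Diameter growth is a saturating
increment model, $\Delta d = r_{max}(1 - d/d_{max})\max(0, 1 - 0.7\,\rho)$
per year with $\rho$ the SDI ratio at cycle start; heights follow a
saturating height–diameter curve hard-capped at a per-species maximum
height, mirroring the operational practice of capping simulated heights at
regionally observed maxima. When SDI exceeds 85% of the effective maximum
(the conventional zone where density-dependent mortality operates), all
cohort densities are scaled by one factor bringing SDI exactly to the
ceiling; killed density becomes snags.

**Regeneration** plants 1235 seedlings/ha — read as a *total*, split
equally among up to 4 species with viability ≥ 0.5 (highest scores first,
ties by species code) — whenever stocking (SDI relative to the effective
maximum) falls strictly below 40%, at every cycle the trigger holds. No
seed source is required, so species migrate freely; if nothing is viable,
nothing is planted. **Snags** retain their death dimensions and lose a
fixed fraction of density per cycle (default retention 0.7); the paper
this design follows counts standing dead carbon but gives no fall rates,
so the retention is a package choice, configurable and set to 1 in the
conservation checks.

## The empirical disturbance regime

From a remeasurement table, `estimate_regime` computes, per class
(harvest, fire, stress), the decadal probability as the proportion of
remeasured plots disturbed, and keeps the observed proportions of basal
area killed as the magnitude distribution (an ECDF; a class with no events
is a vertical line at 0). During simulation each class is drawn
independently per plot and cycle; reserved plots are never harvested;
magnitudes are drawn by type-1 inverse transform from the ECDF. Events
apply mortality proportionally across cohorts — the plot-level magnitude
definition makes uniform thinning the exact reproduction — with harvest
removing trees and fire/stress transferring them to snags. Multiple
classes may hit one plot in one cycle (the per-class proportions imply no
joint model) and apply in the fixed order harvest → fire → stress.
Probabilities are held constant over the horizon; sensitivity runs scale
them by 0 / 0.5 / 1 / 2 (capped at 1), leaving magnitudes untouched.

A plot can appear in the remeasurement table once per class: the
generator draws classes independently, so the same plot may record, say,
both a fire and a harvest in one remeasurement window, and the
probability denominator is the count of distinct remeasured plots.

## The synthetic study system

The generator builds the study conditions rather than emulating any
particular forest:

* **Landscape**: plots uniform over 500–2000 m elevation; normals follow
  a regional base climate (6 degC, 800 mm at 1250 m) along lapse rates of
  −0.0065 degC/m (standard environmental lapse rate) and +0.5 mm/m;
  expansion factor 2400 ha/plot (the national inventory sampling
  intensity); 34% of plots reserved, the reserved share of a
  wilderness-dominated forest.
* **Species pool** (default 8): niche optima spread evenly along the
  realized climate line, warm-dry to cool-wet, extended 3 degC past the
  warm end so warming climates stay colonisable; breadths scale with the
  optimum spacing with a generous precipitation floor (temperature is the
  dominant control on montane distributions). Construction guarantees at
  least one species viable at every climate on the gradient. Growth and
  allometric parameters are drawn from fixed realistic ranges.
* **Disturbance truth**: default decadal probabilities 0.132 / 0.093 /
  0.335 (harvest / fire / stress), the dry-mixed-conifer inventory
  values; magnitude mixtures put mass at zero for fire and stress (40%
  zero for stress) and keep harvest strictly positive with an occasional
  complete removal.
* **Warming scenario**: deterministic ramps from the normals, default
  linear to +3.0 degC and +50 mm at year 100. The temperature delta sits
  at the upper end of the moderate-pathway range (1.4–3.1 degC) and was
  fixed a priori so that, with a single temperature metric and the
  standard lapse rate, the elevation-window rule engages within the
  century at default severity — the operational system tests the rule
  against several climate metrics at once, which makes its effective
  threshold easier to exceed than a single-metric emulation at the mean
  warming. Trajectories carry no interannual noise; stochasticity enters
  only through disturbance draws.

What passing tests on this system do **not** show: agreement with any real
forest's absolute carbon (the published magnitudes derive from operational
growth equations, allometries and downscaled climate grids that are out of
scope here), realistic spatial structure (no fire spread, no dispersal
limitation), or species-specific climate-mortality behaviour. The checks
are property-based: estimator recovery, conservation, trigger arithmetic,
monotonicity of sensitivity orderings, and qualitative trajectory shape.

## The factorial experiment and common random numbers

`run_factorial` crosses climate scenario (none, warming) × window-rule
multiplier (off, 2, 1, 0.5) × disturbance multiplier (0, 0.5, 1, 2) ×
replicates (default 10): 320 runs. Replicate seeds derive from the master
seed by a fixed counter; by default the cell index does not enter the
seed, so cells sharing a replicate index see identical uniform draws
(**common random numbers**). The disturbance step always consumes exactly
six uniforms per plot-cycle — an occurrence and a magnitude draw per
class, drawn whether or not the event occurs — so streams stay aligned
across cells, occurrence sets are nested in the probability multiplier,
and paired cell comparisons are free of replicate noise. Set
`crn = FALSE` for fully independent runs, matching a design where every
cell is an independent experiment.

The cycle order is fixed: climate update → window-rule mortality →
envelope mortality → disturbance → growth → density mortality →
regeneration → snag decay. The source system grows and kills within a
cycle without a published ordering; this order guarantees regeneration
sees post-mortality stocking, and it is deliberately not configurable so
results are reproducible from (inventory, configuration, seed) alone.

## Numerical choices and degenerate inputs

* Conservation: disturbance and density mortality are linear density
  scalings, so live-BA loss equals snag gain (or harvest removal) to
  floating-point accuracy; tests enforce 1e-9 relative.
* ECDF sampling uses the right-continuous type-1 inverse; ties and
  duplicated magnitudes need no special handling.
* Empty plots: SDI and carbon are 0; carrying capacity falls back to pool
  means; stocking 0 triggers regeneration whenever any species is viable.
* Establishment climates of trees present at simulation start are
  initialised to the plot's 1960–1990 normals — the no-change scenario
  therefore never triggers the window rule, bit-exactly.
* Results files print numerics at 17 significant digits so
  write → read round-trips are bit-exact.

## Problem sizes and expected behaviour

The scenario-shape checks use a 300-plot landscape with 10 replicates;
the factorial uses 100 plots — sizes chosen to be comparable to a single
National Forest's projection plot set while keeping a full 320-run
factorial a few minutes' work on one core. Under these defaults the
no-change scenario at the base (dry-forest) disturbance level is roughly
flat in carbon over the century — the heavy stress regime approximately
offsets growth — and rises when disturbance is halved or zeroed; the
warming scenario peaks early and declines well below the no-change end
value, with losses ordered by window-rule severity (off ≥ 2 ≥ 1 ≥ 0.5)
and composition shifting toward warm-adapted species by about 2 degC of
basal-area-weighted niche-optimum temperature. Under no climate change
that optimum only jitters near zero, an order of magnitude below the
warming shift, as disturbance losses are replanted with locally suited
species.

## Known limitations

Growth and allometry are simplified stands-in for regional variant
equations and the operational volume library; viability is parametric,
not the published random-forest models; disturbance probabilities are
time-constant; there is no natural regeneration rate model, no
below-ground carbon, and no species-specific elevation window. These
match the boundaries of the sensitivity questions the package targets
rather than operational carbon reporting.
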