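---
title: "Census-based carbonate budgets: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Census-based carbonate budgets: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of the science it implements: the
budget model and its assumptions, the parameters that matter and their
defaults, what the synthetic generator does and does not emulate, the
numerical choices made where the method left room, and the known limits of
the approach.

## The budget model

A site's net carbonate production (kg CaCO₃ m⁻² yr⁻¹) is assembled from
census data as

$$\mathrm{net} = \mathrm{gross} + \mathrm{sgn}(\mathrm{sediment})\cdot s
  - (\mathrm{parrotfish} + \mathrm{urchin} + \mathrm{macroboring})
  \;[-\; \mathrm{Acanthaster}]$$

**Gross production.** Each coral taxon contributes
$m_j \, (x_j/100)\, d_j \, g_j \times 10$, where $x_j$ is its planar
percent cover, $d_j$ its skeletal bulk density (g cm⁻³), $g_j$ its
vertical extension rate (cm yr⁻¹), and $m_j$ a morphology adjustment for
how much of the covered area actually deposits carbonate. The taxon sum,
plus coralline-algae production $0.018 \cdot pca \times 10$, is multiplied
by rugosity $r$ (substrate-following length ÷ planar length, ≥ 1), which
converts planar cover to the true accreting surface. The ×10 factors are
explicit unit conversions (g cm⁻² → kg m⁻²), deliberately not folded into
the trait table.

Two cover conventions coexist and are easy to confuse. Coral covers are
percentages because the trait rates are per-area-of-colony; coralline
algae and macroborer covers are carried as proportions (0–1) because their
rates (0.018 g cm⁻² yr⁻¹ and 10 kg m⁻² yr⁻¹) are defined at *full cover*.
Reading the coralline term as percent would produce 18 kg m⁻² yr⁻¹ at
full cover — physically implausible — so the proportion reading is used
and documented prominently.

**Cover from intercepts.** Intercept lengths are recorded along the
substrate-following tape. Projecting each intercept to its planar extent
and dividing by the planar tape length is algebraically identical to
dividing the raw intercept by the contour length, so per-taxon cover is
`100 · intercept / contour`. This keeps covers summing to 100 within a
transect and applies the rugosity correction exactly once, in the gross
equation. Mean coral density $D$ is the cover-weighted mean of trait
densities over live coral taxa; a site with no live coral has $D = 0$ and
every $D$-dependent term vanishes.

**Sedimentation** is a fixed magnitude (default 0.4 kg m⁻² yr⁻¹) whose
sign flips by regime: calcareous sediment supplements accretion; high
terrigenous deposition smothers corals and is entered negative.

**Erosion.** Parrotfish erosion multiplies three per-individual
allometries in body length $L$ — bite volume $e^{1.32+0.06L}/1000$ cm³,
scarring proportion $\mathrm{logit}^{-1}(-2.46+0.089L)$, and daily bite
rate $60[(4.31+brc-0.36) - 0.045\cdot\mathit{reeftime}\cdot L]$ — by the
site coral density, 365 days and 10⁻³ kg g⁻¹. The bite rate is clamped at
zero: the printed linear form goes negative for large fish at small $brc$,
and negative bite rates are meaningless. Urchin erosion uses
group-specific test-diameter allometries (*Diadema* $10^{-6}d^{3.42}$,
*Echinometra* $4\cdot10^{-4}d^{1.98}$, other $10^{-4}d^{2.32}$, each
×0.365×0.57); macroboring is linear in borer cover with a conservative
10 kg m⁻² yr⁻¹ full-cover constant. The per-survey sums are divided by the
total surveyed areas (six transects × 120 m² for fish, × 6 m² for urchin
belts): the source equations yield kg yr⁻¹ per surveyed area, and the
division is required for dimensional consistency with the budget.

**Sea-star consumption.** The *Acanthaster* model is a Holling type-II
functional response. The attack rate comes from search geometry: at live
coral cover $R$ percent, the mean free distance between corals is taken
as $(100-R)/10$ m, the sea star searches a circle with that diameter,
covering ground at 504 m d⁻¹ for 12 active hours. Ingestion is
$aR/(1+ahR)$ with handling time $h = 3.5$ d per colony, rescaled by 4.53
to match observed average consumption. Per-transect consumption scales the
mean count per transect by 0.01 m² d⁻¹, the coral density, ×10 and ×365;
division by the 50 m² belt yields the per-m² reduction. The reduction is
clamped at gross production: predation can at most zero a site's
production, never drive it negative. A guard constant $\varepsilon =
10^{-10}$ keeps the attack rate finite at $R = 100$ (the literal reading
"10¹⁰" would swamp every term; the stated purpose of the constant — keeping
the searched area non-zero where corals are present — identifies it as a
small positive guard). The model's intermediate quantities are
dimensionally heterogeneous as published; the implementation reproduces
the published algebra as an empirical recipe rather than re-deriving
units, and exposes every constant in `acanthaster_params()`.

Because the reduction is linear in the count at fixed $R$ (ingestion
depends only on cover), the sea-star density that zeroes a site's gross
production has a closed form; `density_threshold()` returns it as an
integer count per belt set, per 100 m², and as a percentage of
live-coral-cover units. With the default constants this rule is far more
permissive than one would expect from published outbreak impacts —
moderate covers give ingestion rates of order 0.1 — which is a property of
the printed constants, reported as computed, not calibrated away.

**Accretion and sea level.** Net production converts to vertical accretion
by the concave quadratic $Cp + Cp(Cp\,\alpha)$, $\alpha = -0.01949$, with
maximum at $-1/(2\alpha) \approx 25.65$ kg m⁻² yr⁻¹. Accretion is computed
from the net *including* the sea-star reduction by default (flaggable),
and `keeps_up()` uses ≥ at the boundary — a reef accreting exactly at the
rise rate keeps up; real comparisons never land on the boundary, so the
convention is cosmetic but documented. Scenario rates are RCP2.6/4.5/6.0/
8.5 at 5, 6.5, 6.7 and 9 mm yr⁻¹.

**Reporting conventions.** `habitat_summary()` reports "erosion" as
parrotfish + urchins (the mobile grazers), with macroboring inside the net
and the sea-star column separate — the convention of habitat-level budget
tables in this literature. "Net" excludes the sea-star reduction;
`net_with_acanthaster` carries it.

## The threshold model

The coral-cover threshold model is the additive mixed model

$$G_i = \beta_0 + f(\mathrm{cover}_i) + \mathrm{habitat}_i + a_{site(i)}
  + \varepsilon_i$$

fitted by MCMC in JAGS. $f$ is an O'Sullivan penalized spline: cubic
B-splines with interior knots at cover quantiles (default 20), boundary
knots pinned at 0 and 100 so curves are defined on the whole cover axis,
and an integrated-squared-second-derivative penalty computed exactly by
Simpson's rule. The penalty's spectral decomposition splits the basis into
an unpenalized null space (absorbed by the intercept and linear fixed
effect) and a penalized part whose coefficients are i.i.d. normal random
effects — so the smoothing parameter is the ratio of two variances and is
estimated with everything else. Priors are deliberately diffuse: Normal(0,
10²) on fixed effects, half-Cauchy(5) on all standard deviations. Knot
count, placement, basis order and prior scales are not pinned down by the
method's published description; these defaults are the package's own
choices and every one is configurable.

**Threshold extraction.** Per posterior draw, the expected curve for a
habitat (random intercepts at zero) is evaluated on a 0.1%-cover grid and
the smallest cover at which it reaches zero from below is found by
bracketing plus linear interpolation. Draws already non-negative at zero
cover get threshold 0; draws whose curve never reaches zero are censored
at the boundary and their fraction is reported. Per-draw extraction (rather
than extracting from the posterior-mean curve) yields credible intervals
directly; habitat differences are per-draw differences, preserving the
joint posterior.

**Identifiability note.** With one observation per site — the natural
granularity of site-level budgets — the site and residual variances are
separated only by their priors, and those two parameters mix slowly. The
defaults therefore run thinned chains (4 chains, warmup 3000, 1000 draws
at thin 10; about 5 s for 48 sites), which brings split-R̂ below 1.05 on
all reported parameters; any value above 1.05 triggers a warning, never a
silent pass. The threshold itself uses the population curve with random
effects at zero, so it is insensitive to how the two variances split.
Fits are bitwise reproducible for a fixed seed, sampler and version set.

## The synthetic generator

The generator emulates the survey *design*: two islands, 24 sites each
(one with inner/patch/outer strata at 8/8/8 — the real campaign allocated
by reef-type area, which is not reproducible without the coastline
geometry — one with inner/outer at 12/12), six 10 m line-intercept
transects per site, 0.6 × 10 m urchin belts, 5 × 10 m sea-star belts and
30 × 4 m fish transects. Habitat mean coral covers (30/35/28% for
inner/patch/outer, sd 7–10) and taxon mixtures (inshore *Porites*
dominance; encrusting *Montipora* and tabular *Acropora* offshore) were
chosen once so that gross production lands in the 7–9 kg m⁻² yr⁻¹ range
characteristic of productive Pacific reefs, with sea-star outbreak sites
(~15 per 300 m², far above the 30 ha⁻¹ outbreak line) on one island's
outer reefs and a high-terrigenous stratum on its inner reefs.

Distributional forms are documented stand-ins, since only the geometry is
fixed by the field protocol: Dirichlet taxon mixtures (concentration 60),
truncated-normal site covers, multinomial allocation of each transect's
centimetres (so segments sum exactly to the tape), uniform per-transect
rugosity in [1.2, 2.0], Poisson counts with gamma urchin sizes and
lognormal fish lengths, Poisson sea stars. Real surveys have features the
generator does not attempt: spatial autocorrelation along coasts,
inter-taxon segment contiguity, observer error in intercepts and fish
lengths, and size-structured sea-star populations. Passing recovery tests
therefore demonstrates that the pipeline arithmetic is faithful and that
parameter recovery works under the design's sampling noise — not that the
model is robust to real-world measurement error.

The ground-truth table carries analytically expected gross production per
site (from the drawn covers, traits and realized rugosity), so the
pipeline's estimates can be checked for recovery; the residual difference
is multinomial sampling noise of the 1000-point transects, a ~2% mean
relative error at the default geometry.

The threshold-model generator is separate and deliberately minimal: linear
habitat curves `net = slope · (cover − crossing)` with configured
crossings (defaults 12/10/7% for inner/patch/outer, slope 0.2, site sd
0.5, residual sd 0.7, covers uniform on [2, 60]). Parallel linear curves
make habitat effects pure vertical offsets — exactly the structure the
model estimates — so the generating crossing is unambiguously the true
threshold.

## Trait table

The shipped `traits.csv` carries representative literature-scale values
(Indo-Pacific skeletal densities 1.3–1.5 g cm⁻³; extensions 0.6–2 cm yr⁻¹
for massive and encrusting forms, 5–7 for acroporids; morphology
adjustments ≤ 1 for open branching and tabular forms) and is a documented,
editable stand-in: real analyses should substitute locally calibrated
values. Parrotfish bite-rate constants are unpublished in the source
literature; the package default is 20, and any species resolved through
the default is named in a warning rather than silently filled.

## Problem sizes and runtimes

The test suite and the acceptance script run the campaign at its native
size (48 sites) and the threshold model at 48 observations; a full
pipeline run including one default-spec fit takes well under a minute on
one CPU. The replicate recovery study uses 20 campaigns with two-chain,
800-draw (thin 5) fits — roughly 30 s total — sizes chosen as the package's
own validation budget; heavier MCMC settings change the credible-interval
smoothness, not the conclusions.

## Known limitations

* Micro-bioerosion and chemical dissolution are outside the budget (as in
  the census methodology it follows); abiotic/wave erosion likewise.
* The sea-star model reproduces its source algebra verbatim; its
  intermediate units are heterogeneous, and the implied zero-production
  density rule is sensitive to the rescaling constant. Treat absolute
  reduction magnitudes as the model's, not as field calibrations.
* Sedimentation is a two-level sign rule, not a measured flux.
* The threshold model assumes a shared smooth cover effect across habitats
  (habitat enters as an offset); habitat-specific smooths would need more
  sites per stratum than the design provides.
* With one observation per site the random-intercept variance is
  prior-identified; it is retained for design fidelity and for datasets
  with repeated site visits.
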