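---
title: "Behaviour models for GPS-collared Sahelian cattle herds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behaviour models for GPS-collared Sahelian cattle herds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdhmm)
```

## The model and its assumptions

`herdhmm` treats a herd as a system occupying exactly one latent mobility
state per 30-minute fix interval — a finite-state reading of herd
behaviour in which each state mixes spontaneous animal behaviour with
herding decisions. For the three-state model these are, in canonical
order of mean step length, *resting*, *foraging* and *travelling*. The
observation attached to each interval is a pair of trajectory metrics
derived from consecutive GPS fixes: the step length (metres per
interval) and the turning angle (radians in $(-\pi, \pi]$, the signed
change between successive movement bearings, counter-clockwise
positive).

State $i$ emits:

* **step lengths** from a zero-inflated positive law: a point mass
  $\zeta_i$ at exactly zero (computed distance below $10^{-6}$ m) mixed
  with a continuous positive law. The default continuous family is the
  **normal truncated to $(0,\infty)$ and renormalised**, parameterised
  by the *untruncated* mean $\mu_i$ and SD $\sigma_i$. Herd-movement
  step laws are often reported simply as "normal", which has support on
  negative lengths; truncation is the smallest correction that yields a
  valid density while keeping the printed $\mu, \sigma$ readable in the
  usual way. A gamma law with the same mean and SD is selectable
  (`step_family = "gamma"`) for users who prefer the other common
  convention. The choice is recorded in serialized models.
* **turning angles** from a von Mises law with mean direction $\mu'_i$
  and concentration $\kappa_i$ ($\kappa = 0$ is the circular uniform).
  The first angle of a segment and angles adjacent to zero steps are
  undefined and contribute a factor of one to the likelihood.

State dynamics follow a Markov chain with transition matrix $\Gamma$.
Off-diagonal entries carry linear predictors
$\eta_{ij}(z) = \beta^0_{ij} + \beta_{ij}^\top z$ in exogenous covariates
$z$ (collar temperature in the shipped examples), mapped to
probabilities by a row-wise multinomial logit with the diagonal as
reference category, so every row sums to one for every covariate value.
Segments (maximal runs of uninterrupted 30-min fixes) are treated as
independent realisations sharing one initial distribution $\Pi$.

Key independence assumptions: the single collared animal represents its
herd; observations are conditionally independent given the states; and
gaps are non-informative (gap-containing stretches are dropped rather
than interpolated, so the model never sees irregular intervals).

## Fitting

The forward algorithm evaluates $\ln L$ in scaled arithmetic (stable at
$10^5$+ observations; the recursions are implemented in C++). Fitting
minimises $-\ln L$ by quasi-Newton `nlm` over unconstrained working
parameters: $\log \mu$, $\log \sigma$, $\log \kappa$,
$\mathrm{logit}\,\zeta$, the angle mean through an
$\mathrm{atan2}(\sin, \cos)$ wrap (well-behaved when the optimum sits at
$\pm\pi$, as resting angle means do), raw $\beta$, and multinomial
logits for $\Pi$. Iteration cap 1000, gradient tolerance $10^{-6}$,
finite-difference gradients. The objective returns a large finite
penalty ($10^{15}$) outside the numerically safe region — in particular
for $\sigma_i < 0.1$ m, which closes off the classic mixture degeneracy
of a density spike on one observation; 0.1 m is far below GPS noise, so
no genuine optimum is excluded.

Because the surface is multimodal (hill-climbing from one start can land
on local optima such as swapped or merged states), `multistart_fit()`
draws many starting points uniformly within per-parameter sampling
limits. For three states the default limits are those used for the
published field model (step means 5–100 / 50–250 / 100–1000 m, matching
SDs, angle means $\pm 3$ rad with the travelling state narrowed to
$\pm 0.5$, concentrations 0.1–1 / 1.5–5 / 1–15, zero-inflation started at
the observed zero-step fraction $p_0$ for the lowest state and
$p_0/100$ elsewhere). The limits constrain *initialisation only* — the
optimiser may leave them, which is how a fitted concentration can end up
below its sampling band. For other state counts, geometric bands spread
over the same overall 5–1000 m range. Each restart is canonicalized
(states relabelled by ascending $\mu$, ties by $\sigma$ then original
index, with $\Pi$, $\beta$ and emissions permuted consistently — the
likelihood is unchanged), the best $\ln L$ wins, and the **consensus** is
the fraction of converged restarts within $\Delta = 0.5$ log-units of
the best; 0.5 log-units is well inside the resolution at which two
restarts can be called the same optimum while far above arithmetic
noise.

State counts are compared by $\mathrm{BIC} = k \ln n - 2 \ln L$.
`select_n_states()` reports two $k$ conventions side by side: the
standard free-parameter count ($5N$ emissions $+ N(N-1)$ transition
intercepts $+ (N-1)$ initial probabilities, so 23 for $N = 3$) and the
bare state count, a convention that also circulates for this model
family. The default ranking uses free parameters. The range is capped at
6 states: beyond that, fits are combinatorially expensive and the extra
states absorb noise rather than behaviour.

## The synthetic survey generator

`simulate_survey()` emulates the structure of a multi-herd Sahelian
collar survey so every downstream stage can be tested against ground
truth. What it reproduces:

* 30-min fixes over a configurable span; collar temperature as a
  diurnal cycle (~26–40 °C, peaking mid-afternoon);
* resident herds tethered at night: the *state sequence itself* is
  forced to resting between sunset + 1 h and sunrise − 1 h, so
  decoded-state recovery tests remain meaningful (a post-hoc position
  override would break the state/observation pairing);
* transhumant herds on a phase schedule (default: an eastward
  agropastoral leg on day 15/90 of the span, a northward pastoral leg on
  day 40/90, return on day 75/90, targets 25 and 72 km out): by day the
  herd travels toward the phase target with tightly concentrated
  headings, by night it rests; after arrival ordinary state dynamics
  resume, anchored within 1.5 km of the target (emulating herding back
  to a camp);
* isotropic Gaussian GPS noise. Collar accuracy is stated as a quantile
  ("95% of fixes within 10 m"), not a distribution; the per-axis scale
  is calibrated so the Rayleigh 95% radial quantile equals 10 m, i.e.
  $\sigma = 10/\sqrt{-2\ln 0.05} \approx 4.09$ m;
* missing fixes at a per-fix gap rate (default 0.2%, keeping overall
  losses near the few-percent level typical of field surveys), a collar
  swap on the first herd (two assignment periods tiling the span), and
  a concentric land-use map — homefields within 1 km of the village,
  bushfields to 3 km, rangelands beyond, with a fallow block and a wet
  lowland inset — mirroring the concentric organisation of agropastoral
  village territories.

What it does **not** reproduce: vegetation and biomass dynamics,
water-point attraction, inter-herd interactions, DOP-correlated error
bursts, or collar failure. Passing recovery tests therefore show that
the estimator inverts its own generative family at realistic noise and
sample sizes — not that three states suffice for any particular field
dataset.

Goal-directed journey headings are drawn toward the target rather than
from the travelling state's von Mises turn law, so a model fitted to a
full synthetic survey recovers a travelling angle concentration below
the emission value used for free steps; this is a deliberate realism
trade-off, and exact emission-level recovery is tested on
`simulate_series()` output instead.

## Data preparation choices

* Segmentation tolerance: inter-fix gaps outside 30 ± 5 min cut a
  segment; runs shorter than 10 fixes are dropped. Chosen so that
  surviving segments contribute usable turning-angle runs; both are
  configurable. Every removal is tallied per rule and the identity
  `collected = usable + sum(removals)` holds exactly.
* Rows missing coordinates or timestamps are removed as `incomplete`;
  missing DOP or temperature is retained (DOP is informative but not
  required). Collar swaps yield distinct per-animal series; no
  cross-animal stitching.
* Distances default to great-circle (haversine, R = 6371 km) directly on
  WGS84; a planar mode (local azimuthal-equidistant frame) is provided
  and is the mode with exact rotation invariance. At herd scale the two
  agree to well under 0.5%.
* Season labels follow the calendar (Nov–Feb cold dry, Mar–May warm dry,
  Jun–Oct rainy). Day/night is computed in **local apparent solar time**
  at the dataset centre from the standard NOAA solar equations
  (refraction-corrected zenith 90.833°), not a civil timezone — day is
  defined relative to the sun, which is what tethering practice follows.
  Latitudes beyond 60° are rejected (polar cases out of scope).
* Land-use joins test containment in geographic coordinates with a
  closed-boundary rule (edge points are inside; among same-priority
  overlaps the lowest polygon id wins; layers are tried in decreasing
  priority, fine map before coarse). Boundary handling in source data
  workflows is rarely specified; these rules are a stated contract
  chosen for determinism, not a reconstruction of any particular GIS
  behaviour.

## Transhumance phase detection

No published algorithm exists for turning decoded tracks into departure
dates, stops and stop-duration classes, so the package states one:
daily centroids (planar mean of the day's fixes); departure is the
first day of a run of ≥ 2 days outside the home-area polygon; stops are
greedy maximal runs of daily centroids within 2 km of the running stop
centroid lasting ≥ 3 days; the return date is the first day back inside
the home area after the day of maximum displacement; stop durations are
grouped by seeded 1-D k-means (best of 50 starts, classes relabelled by
ascending mean) into 3 classes by default. All five parameters are
exposed. The procedure is validated against the synthetic generator's
schedule (departure and return recovered within ±1 day) and an
exhaustive small k-means oracle; on field data the parameters should be
read as a reproducible convention.

## Numerical notes

* Forward/Viterbi are checked against exhaustive-path enumeration on
  hundreds of seeded instances (≤ 8 observations, ≤ 3 states) at
  $10^{-10}$ tolerance; Viterbi ties break toward the lower state index.
* The von Mises normaliser uses the exponentially scaled Bessel $I_0$,
  stable at large $\kappa$; sampling uses the Best–Fisher rejection
  method, and truncated-normal sampling uses exact inverse-CDF draws.
* All reference distances use R = 6371 km; positions are simulated on a
  local planar frame and re-expressed in WGS84 (distortion at herd
  scale is below GPS noise).
* Determinism: every stochastic entry point takes a seed; the pipeline
  derives per-stage child seeds from the global one, and identical
  configurations reproduce byte-identical outputs (the JSON-lines log,
  which records wall-clock timings, is the one exception).

## Problem sizes used in the shipped checks

Parameter-recovery and covariate-recovery checks run at 30,000 simulated
steps with 10 and 3 restarts respectively; the state-count selection
study runs 10 replicates of 10,000 steps over 2–4 states with 3 restarts
each; end-to-end pipeline checks use 20–30 day surveys of 2–3 herds.
These sizes put standard errors comfortably inside the asserted
tolerances (5% on emission means, 0.03 absolute on transition
probabilities, 25% on a planted covariate slope) while keeping the whole
battery at desk scale — a full survey-scale multistart campaign (hundreds
of restarts on half a million fixes) is a cluster job, not a test.

## Known limitations

* Step "normality" is resolved by truncation; fits to data generated
  under other positive families will show small systematic offsets in
  $\sigma$.
* $\Pi$ is a single shared simplex across segments; per-segment initial
  distributions are not fitted.
* No hidden semi-Markov dwell times, no random effects across herds, no
  Bayesian uncertainty on decoded states.
* The published field model ships with emissions and $\Pi$ only; its
  transition matrix was never published numerically, so
  `reference_model()` installs a clearly labelled synthetic stand-in
  (`synthetic_reference_gamma()`) reproducing the described qualitative
  structure — resting highly persistent, travelling exiting to foraging
  five times more often than to resting.
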