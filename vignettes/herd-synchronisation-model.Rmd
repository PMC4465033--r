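---
title: "The herd synchronisation model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The herd synchronisation model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dairysynch)
```

`dairysynch` predicts, herd by herd, how three routine hormonal
first-insemination programmes change the cost of production (£ per cow per
year) and the methane intensity of milk (g CH4 per litre) relative to
breeding from observed oestrus alone. This vignette documents the model,
its tunable parameters, the parts of the design that were genuinely open,
and what the simulation does and does not represent.

## Structure: three levels, four branches

The simulator has three levels. **Herds** are described by twelve inputs
drawn independently from uniform distributions (`sim_defaults()$herd_ranges`)
spanning the observed range of commercial dairy herds — reproductive
management (submission risk, pregnancy risk, voluntary waiting period, time
to first cycle, cycle length), production (305-day yield, heifer
proportion, forage metabolisable energy) and economics (milk margin, cull,
serve and calving-index costs). **Cows** (200 per herd by default) are drawn
conditionally on their herd: parity 1 with probability equal to the heifer
proportion, higher parities sharing the remainder (weights 0.30, 0.25,
0.20, 0.25 for parities 2–5+); post-partum anoestrus and oestrous cycle
length from mode-parameterised beta distributions on [10, 80] and [18, 27]
days with the herd means as modes; 305-d yield as the herd mean times a
parity factor (0.87 for heifers, 1.07 for parity 3+) times a lognormal
individual multiplier (CV 0.15). **Days**: each cow is followed for 730
days from a calving, with the first calving equally likely on any day of
the year.

Every herd is replayed under four branches — baseline, Ovsynch,
Ovsynch + progesterone, double prostaglandin — using the same cows and, as
far as the scenario leaves them unaltered, the same random draws.

## Conception

The probability that a service results in pregnancy follows a logistic
model with a cubic in days in milk (DIM), parity offsets, a penalty per
thousand kg of 305-d yield, a June–September season offset, and a
cow-level random intercept (variance 0.135 logit²) drawn once per cow and
reused at every service. The DIM cubic makes conception poorest immediately
post partum, best in mid-lactation and slightly declining later; season is
derived from the calving day of year plus DIM on a 365-day calendar
(1 June – 30 September inclusive).

Two readings of how the herd-level *pregnancy risk* input enters were
defensible, and both are implemented
(`sim_defaults()$conception$herd_effect`):

* `"risk_multiplier"` (default): the input scales the predicted probability
  of every service multiplicatively, exactly as the programme factors do.
* `"calibrated_offset"`: the herd receives a logit intercept chosen so the
  predicted probability at a reference service (DIM 120, herd yield, herd
  parity mix, season-averaged) equals the input.

The multiplier reading is the default because it reproduces the magnitude
of the packaged reference models — the intercept of the Ovsynch cost model
and the cull- and serve-cost sensitivities — whereas the calibrated offset
yields cost effects several-fold too small. The price is that under the
default the realised proportion of served cows conceiving is lower than the
nominal input (about 0.17 when the input is 0.375); the two definitions
cannot be satisfied simultaneously, and the package follows the one
consistent with the reference outputs. Under the default the herd-variance
component of the conception model is carried entirely by the sampled
pregnancy risk; `draw_random_intercepts()` exposes the herd- and cow-level
variances for standalone use.

Programme factors act on the probability scale with truncation at 1
(`multiplier_scale = "risk"`); an odds-scale option is provided because the
largest factor (1.7) could otherwise exceed 1 on fertile services.

## The reproductive state machine

Cows are in oestrus on day 1 of each ovarian cycle: first oestrus the day
after anoestrus ends, then every cycle length. At each oestrus at or after
the herd's voluntary waiting period, the cow is served with probability
equal to the submission risk; breeding stops at conception or 300 DIM.
Pregnant cows dry off 60 days before the 280-day-gestation calving and, if
the new calving falls inside the horizon, start a new lactation with parity
incremented, fresh anoestrus/cycle draws, and the same identity and random
intercept. Cows open at 300 DIM are culled exactly once and replaced by a
parity-1 heifer after a 60-day gap; the rule applies recursively to the
replacement. Oestrus times are kept on the continuous scale of the drawn
anoestrus/cycle lengths; conception days are rounded to whole days when
they anchor the calving/dry-off calendar.

The programmes overlay this machine:

* **Ovsynch** (and **+P4**): first AI on the herd's fortnightly treatment
  calendar — anchored, by choice, at herd day 0 — at the earliest batch day
  ≥ 50 DIM, hence between 50 and 63 DIM, regardless of the VWP, with
  submission 1. The ovarian cycle is reset on the treatment day, so repeat
  services after a failed programmed AI occur at the reset cycle's oestrus
  with baseline submission risk; the VWP is not re-applied to them (the
  herd has already overridden it). A cow still anoestrous past 64 DIM is
  served but cannot conceive to that service; with P4, 5% (an absolute
  probability, by choice) of such multiparous cows resume cyclicity and are
  fertile at the programmed AI. Anoestrous-infertile cows later resume at
  their natural anoestrus end, not the reset cycle — the natural resumption
  was judged the more physiological default for cows whose ovaries did not
  respond.
* **Double PG**: eligibility is frozen at the first batch day ≥ 50 DIM —
  cows already inseminated before it continue exactly as baseline
  (bit-identical, by the shared-draw contract). Eligible cows get an
  injection that induces oestrus with probability 0.8 *if* their cycles
  have resumed; induced oestrus is served with the herd submission risk; a
  second injection follows 14 days later if no insemination has occurred
  (maximum two). Natural oestrus during the 14-day regime window is not
  separately served — these are, by construction, cows the herd was failing
  to detect. Afterwards the cow reverts to baseline behaviour from the last
  induced oestrus (cycle reset) or her natural calendar. The £5 drug cost
  is charged once per treated cow regardless of injection count.

The programmes are applied to the first insemination of *every* lactation
inside the horizon, including replacements: they are herd policies run
continuously in fortnightly batches, not one-off treatments.

## Production, intake and methane

Milk follows a Wood curve *a·t^b·e^(−ct)* with parity-specific shape
(primiparous: b = 0.15, c = 0.0025; multiparous: b = 0.20, c = 0.0040 —
flatter and more persistent first lactations) and *a* solved so the 305-day
integral of a non-pregnant cow equals her 305-d yield exactly; a ±5%
sinusoidal seasonal multiplier peaks in spring (day 120); pregnancy
depresses yield by 0.4% per day beyond 150 days in calf (floor 0.6). Total
dry-matter intake is a documented stage-and-yield function: 10 kg DM + 0.2
kg per litre, ramping linearly from 70% at calving to 100% by DIM 70; dry
cows eat the base allowance. Concentrate is fed at 0.4 kg fresh (90% DM)
per litre above the 10 L supported by forage; forage intake is the
remainder (clipped at zero for extreme early-lactation yields). These
submodels stand in for production-modelling literature whose exact forms
are not reproduced here; they preserve the dependencies that matter
downstream — stage of lactation, season, pregnancy, and the
forage/concentrate partition — and all their parameters are configurable.

Methane is forage DMI times an emission rate decreasing linearly in forage
quality, r(ME) = 23.5 − 0.5·(ME − 9.5) g CH4 per kg DM, with concentrate
emitting 150× less per kg DM. Because the rate enters both arms of every
comparison, the intensity *difference* per litre is insensitive to its
absolute level. Herd totals are scaled by a replacement-rearing uplift
proportional to the realised replacement rate and anchored so that at a
commercial rate of 0.25/year heifers contribute 27% of herd methane; the
proportional (rather than fixed) form is deliberate, since replacement risk
is one of the mechanisms by which the programmes move methane.

## Outcomes and cost accounting

Per herd and branch the simulator totals milk sold, services, culls and
methane over the 730 days. The cost delta values the milk change at the
herd margin and the service change at the serve cost, each per cow-year,
while the change in the *proportion of cows culled* is charged once at the
cull (depreciation) cost. Charging the cull-risk change once rather than
per year is a deliberate accounting choice: it treats culling as a risk
difference over the episode, and it is the convention under which the
package's simulated sensitivities agree with its packaged reference models
(a fully annualised alternative is available via
`costs$annualize_culls`). Drug costs are kept out of the gross delta and
added separately (`d_cost_net`), since a farmer knows them exactly.
Negative deltas are savings. An optional calving-interval term (the
calving-index cost input) is off by default, matching the cost definition
above.

## Random numbers: the common-cow contract

Counterfactual comparison requires that branches differ only through
policy. Every cow identity is built from one integer seed, from which all
draws it could ever need are generated once in a fixed-layout block:
attributes, per-lactation redraws, submission uniforms indexed by
(lactation, oestrus event), conception uniforms indexed by (lactation,
service number), and reserved scenario slots (programme multipliers, the
P4 resumption draw, prostaglandin responses) that the baseline never
reads. Branches consume the same indexed draws wherever their event
sequences coincide, so a herd in which no cow is eligible for the double-PG
regime produces bit-identical output to baseline, and adding a scenario can
never perturb another. Replacement heifers derive from seeds stored in the
culled cow's block, so a cull occurring in one branch only still yields the
same replacement in any branch where it occurs.

## Summarisation

Herd deltas are summarised by linear models in covariates centred on the
theoretical means of the input distributions (so the rounded mean/upper
quartile 0.37/0.51 of the risk inputs are exactly 0.375/0.5125), with
squares and the investigated interactions formed *after* centring. With one
delta per herd a herd random intercept is not identifiable separately from
the residual, so the fit is ordinary least squares and the between-herd
variance is reported as the residual variance. Backward elimination removes
the least significant term with Wald p > 0.05 — the package's chosen
criterion, since an effect-size-versus-SE rule (|z| ≤ 1, available as
`criterion = "z1"`) would be incompatible with retained terms whose |z| far
exceeds 1 — always respecting marginality and never touching the
intercept. Prediction shifts evaluate a fitted or reference model at two
values of one covariate with the others at their means, where centring
makes all interactions vanish; prediction grids do the same over a lattice.

## Numerical choices and degenerate inputs

Mode-parameterised betas use the PERT convention (λ = 4; configurable),
the standard three-point parameterisation when only mode and support are
known; a degenerate support returns the common value. Seeds are 32-bit;
sub-seeds derive from a multiplicative-congruential mix so any master seed
below 2³¹ is safe. The calendar is 365 days (no leap years). A herd with
submission risk 0 never serves and culls every cow at 300 DIM; zero milk in
both arms of an intensity comparison is an error rather than a NaN.
Eligibility ties are fixed and documented: an oestrus exactly at the VWP is
eligible; a baseline service strictly before the first batch day makes a
cow ineligible for double PG; a programmed AI lands on the first batch day
at or after DIM 50.

## What the generator does and does not emulate

The input distributions are independent by construction, so the simulated
herd space deliberately includes combinations (very high yield with very
low submission risk, say) that are rare in practice; this is a feature for
mapping the decision surface, not a portrait of the national herd.
Disease, abortion, twinning, seasonal-calving policies, and culling for
any reason other than reproductive failure at 300 DIM are absent, so
absolute cull rates and methane intensities are higher than, and not
comparable to, field benchmarks — the object of inference is always the
*difference* between branches on identical cows. Milk, intake and methane
use the transparent default submodels above rather than the original
production-modelling formulations, so absolute levels (litres, kg DM, g
CH4) carry those defaults; passing tests demonstrate internal consistency
and faithful treatment contrasts, not calibration of absolute emissions to
field data.

## Problem sizes

The package's test suite exercises herds of 15–250 cows and populations up
to 10,000 synthetic herds for the regression machinery; the acceptance
script simulates 1000 replicate herds of 200 cows for the average-herd
saving (Monte-Carlo SE about £1.4 per cow) and evaluates the prediction
shifts exactly. The full experiment — 10,000 herds of 200 cows under all
four branches — runs in a few hours on one core via `simulate_herds()`.
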