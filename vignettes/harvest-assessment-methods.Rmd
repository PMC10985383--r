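---
title: "Methods: harvest sustainability assessment from minimal demography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: harvest sustainability assessment from minimal demography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(offtake)
```

## The problem and the model

The package asks a deliberately narrow question: given an observed level of
offtake and very limited demographic knowledge, is that offtake compatible
with a stated management objective? The population model behind every
computation is the scalar theta-logistic,

$$N_{t+1} = N_t + N_t r_{max}\left[1 - (N_t/K)^\theta\right] - h_t N_t,$$

whose assumptions the user must own: no age structure (no transient
dynamics or population momentum), temporally constant $r_{max}$ and $K$,
purely phenomenological compensation for harvest, and no depensation
(Allee) effects at low density. The harvestable surplus peaks at
$N_{MSY} = K(\theta+1)^{-1/\theta}$ with rate
$h_{MSY} = r_{max}\theta/(\theta+1)$. Equilibria above $N_{MSY}$ are
stable under quota harvest; those below are not, which is why a quota below
MSY can still extinguish a population that stochastic events have pushed
below the lower equilibrium — `project_population()` makes both behaviours
inspectable.

An assessment draws every uncertain input per Monte Carlo iteration,
computes the allowable take under the chosen rule (PTL, PEG or PBR), and
forms the sustainable harvest index $SHI = \text{harvest}/\text{allowable
take}$ *per draw* — the ratio of paired draws, not a ratio of summaries —
because the decision-relevant object is the distribution of SHI, its
median, SD and exceedance probability $P(SHI > 1)$. Medians are the
default summary because every distribution in sight is right-skewed.

## Growth rate from minimal life history

With adult survival $s$ and age at first breeding $\alpha$, the
demographic-invariant method solves

$$\lambda_{max} = \exp\left\{c \left[\alpha +
\frac{s}{\lambda_{max} - s}\right]^{-1}\right\}$$

for the unique root above $\max(1, s)$. The bracketed term is the
generation time $T$; the relation expresses the near-invariance of
$r_{max} T$ across bird life histories, with $c = 1$ for the long-lived
branch. Two consequences worth stating plainly, because they surprise
users: $\lambda_{max}$ *decreases* with adult survival at fixed $\alpha$
(higher survival means longer generations, hence slower maximum growth),
and it decreases with $\alpha$; sensitivity to survival is greatest for
early breeders. The root is found by `uniroot` on
$(\max(1,s) + 10^{-9},\, 5)$ at relative tolerance $10^{-10}$ — bird
growth rates plausibly stay below 5, and a bracket failure raises an error
rather than clamping. The short-lived branch uses a calibrated invariant
constant $c > 1$, so it always produces the higher growth rate; it is
intended only for birds breeding at age 1 (a later $\alpha$ warns but
runs, since the two branches differ by less than 0.1 at $\alpha = 2$ and
negligibly beyond — a bound the test suite checks).

Survival itself, when unknown, is predicted from body mass on the logit
scale, $\mathrm{logit}(s) = b_0 + b_1\log(\text{mass}) + b_2\alpha +
\epsilon_{taxon} + \epsilon_{resid}$, mimicking the structure of
captive-bird survival regressions: two Gaussian random-effect terms
(between-taxon and residual) that the user can sample per draw or hold at
zero via `random_effects = c(taxon =, residual =)`. Masses are in kg; a
two-sex mass is pooled as $\mu = (\mu_M + \mu_F)/2$ with variance equal to
the mean within-sex variance plus the between-sex mean spread, which never
understates the within-sex variance.

The density-dependence shape $\theta$ is the least estimable parameter in
the framework. Three modes: fixed; deterministic from the decreasing power
law $\log\theta = a + b\log r_{max}$; or with the relation's lognormal
residual added per draw. The residual is large, and turning it on inflates
the SHI spread considerably — that is a feature, not a bug: it represents
honest ignorance about compensation.

## The synthetic coefficient tables

The three relation tables shipped in `inst/extdata/` (survival model,
theta relation, growth invariants) are **synthetic calibrations**, and
their file names say so. The original fitted regressions are not published
as printable tables, so the constants here were fitted once, by
simulation, so that the full pipeline reproduces published median
estimates for three species spanning the life-history range — black
vulture ($r_{max}$ 0.12, $\theta$ 2.51), taiga bean goose (0.18, 2.20) and
rock ptarmigan (0.62, 0.99) — together with their reported SDs. The
calibration fixed the survival model's fixed effects exactly through the
three anchors, chose the total random-effect SD (0.40, split evenly
between the two terms) from a grid against the three reported $r_{max}$
SDs, fitted the theta power law by least squares through the three
anchors, and back-solved its residual SD (0.96) from the reported
$\theta$ SD/median pairs, which are mutually consistent with a lognormal
residual. The acceptance-style tests that route through these tables are
therefore checks that the calibration is stable, not independent
validations; tests of the framework's mathematics never touch the tables.
Users with access to the original fitted models should pass their own CSVs
(`survival_table =`, `theta_table =`, `invariants_table =`), and every
report bundle records which tables were used.

## Policy parameters

* `Fobj` (PTL): dimensionless objective factor in
  $(0, (\theta+1)/\theta)$; 1 targets MSY, the upper bound is the
  extinction boundary. A proportion-of-MSY objective `pobj` is inverted to
  `Fobj` on the sub-MSY branch $F_{obj} \le 1$ (bracketed root-finding,
  tolerance $10^{-10}$); that branch's equilibrium lies above $N_{MSY}$
  and is the stable, management-relevant one. The upper root is available
  behind `branch = "upper"` for exploration. When $\theta$ is stochastic
  and `pobj` is given, the factor is resolved *per draw* against that
  draw's $\theta$; published analyses have instead fixed `Fobj` from the
  posterior median $\theta$, which the interface equally supports by
  passing `Fobj` directly.
* `Fs` (PEG): safety factor in $(0, 0.5]$ — 0.5 is a strict maximum and
  violating it is an error, not a warning.
* `Fr` and `nmin_quantile` (PBR): recovery factor in $(0,1]$, and the
  quantile of the population-size draws used as the minimum population
  estimate, default 0.20. The quantile choice embeds risk attitude, which
  is why it is an explicit, echoed parameter rather than a constant.
* `survey_timing`: a post-breeding census includes young of the year, so
  the take rate is converted by $h \mapsto h/(1+h)$ before multiplying by
  the (post-breeding) population.
* `crippling_rate`: unretrieved kill added to every harvest draw as
  `harvest * (1 + rate)`; 0.20 is the North American duck convention,
  default 0 because crippling is rarely monitored.

## Monte Carlo design and numerical choices

Uncertain inputs are declarative `dist_spec` objects: fixed, lognormal by
natural-scale mean and SD (moment matching:
$\sigma^2_{\log} = \log(1 + SD^2/\text{mean}^2)$,
$\mu_{\log} = \log(\text{mean}) - \sigma^2_{\log}/2$), or uniform —
over integers for age at first breeding, a whole-year trait for which a
continuous uniform would be biologically meaningless.

Each species in a batch runs on its own sub-stream seeded as a fixed
affine function of the master seed, so adding or reordering species never
perturbs another species' draws. Harvest is sampled by inversion (uniforms
through the quantile function) so that candidate-ranking runs can reuse
the same uniforms — common random numbers — and candidate SHI
distributions differ only through the harvest spec itself. With a fixed
seed a run is bit-reproducible within this package; agreement with other
implementations of the same framework can only be distributional.

Degenerate situations are handled explicitly rather than silently:
survival draws from a direct distribution falling outside $(0,1)$ are
redrawn (at most 100 attempts, count reported) to preserve the
distribution's shape over hard clipping; the same policy applies to
non-positive $\theta$ draws, which with the packaged lognormal residual
cannot occur but can with user-supplied tables. Draws whose allowable take
is not positive (e.g. a non-positive growth draw from a user-supplied
spec) are flagged invalid, excluded from summaries, and counted in the
report; a run with over half its draws invalid stops with an error.
$P(SHI > 1)$ uses a strict inequality — for continuous draws the choice is
measure-zero, and the all-fixed corner case where every draw sits exactly
at 1 reports 0, consistent with "exceeds".

In the deterministic projector, quota harvest removes
$\min(H, N_t + \text{growth})$, keeping the population non-negative where
the raw difference equation could cross zero; extinction is a labelled
outcome, not an error. Optional environmental noise multiplies the growth
increment by a mean-one lognormal (`env_sd`, default 0 = off): the
reference behaviour is deterministic because the framework's published
uses do not parameterise environmental stochasticity.

## Stochastic dominance

Candidate harvest levels are compared on the smaller-is-better SHI scale.
First-order: $A$ dominates $B$ when $F_A \ge F_B$ everywhere on the merged
empirical support with strict inequality somewhere. Second-order
(risk-averse): the same test on the running trapezoidal integrals of the
CDFs over the merged support. Evaluating on the merged support is exact
for step functions and needs no discretisation tuning; the trapezoidal
accumulation makes the equal-centre/tighter-spread ordering come out the
intuitive way (e.g. draws {2,2} dominate {1,3} at second order). The
"better" direction is an explicit argument in every call because SHI is
smaller-is-better — the opposite of a yield framing — and a silent
direction error would invert conclusions. Dominance is tested on SHI, not
on projected population outcomes, because risk is defined here through the
SHI distribution; users wanting population-scale risk can project
candidate harvests explicitly. When a candidate with lower expected
harvest dominates the observed harvest, the report flags the observed
harvest as inconsistent with the management objective for a risk-averse
decision-maker.

## What the example scenarios do and do not emulate

The packaged scenarios (`example_config()`, `write_example_scenarios()`)
reproduce published assessment inputs for three real species — fixed or
lognormal population and harvest estimates, mass-based or externally
estimated growth, 20,000 draws. They emulate parameter uncertainty only.
They do not emulate: temporal dynamics in the inputs (each assessment is a
snapshot), estimation bias in population or harvest monitoring, spatial
population mixing, age structure, or environmental stochasticity. A
passing test suite therefore demonstrates that the machinery reproduces
the framework's published behaviour under its own assumptions — not that
those assumptions hold for any particular real population. The same
caveats apply to real use: field survival estimates bias $r_{max}$ high
(the relations want *intrinsic* survival under optimal conditions), and
allometric $r_{max}$ is an evolutionary maximum that contemporary
conditions may not permit.

## Problem sizes

The test suite runs the full worked examples at their published size of
20,000 draws (each takes well under a second); distributional unit checks
use 500–20,000 draws as precision requires, and grid/property checks use a
few hundred parameter combinations. The acceptance script runs one
20,000-draw assessment plus closed-form quantities.

## Known limitations

* The PEG/PBR implementations share the engine's draw structure; PBR's
  $N_{min}$ is a quantile of the *sampled* population distribution, so
  with a fixed population spec $N_{min} = N$ exactly.
* Juvenile survival is stored and echoed but does not enter the
  demographic-invariant relation, which is driven by adult survival and
  $\alpha$ alone; it exists so scenario files can carry the convention
  that sub-adult survival applies to ages $1..\alpha-1$.
* `lambda_max` is capped by the root bracket at 5; a species whose inputs
  imply faster growth errors out, which is almost certainly an input
  mistake for birds.
* The dominance verdicts are sample statements with no sampling-error
  assessment; at the default 20,000 draws, orderings between materially
  different candidates are stable, but near-ties should be treated as
  "none".
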