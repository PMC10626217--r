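---
title: "In silico in vivo association pattern analysis: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In silico in vivo association pattern analysis: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The structural model

`fluxpattern` studies when an observed association between a gut
species and a fecal metabolite can be read causally. Its generative
backbone is a linear structural equation system over four blocks of
variables per subject: latent host factors $h \in \mathbb{R}^K$,
relative species abundances $a \in [0,1]^L$ with $\sum_l a_l = 1$,
community net-secretion fluxes $f \in \mathbb{R}^J$, and metabolite
concentrations $c \in \mathbb{R}^J$:

$$a = s\,B_{ah} h + u, \qquad f = B_{fa}\, a, \qquad
  c = B_{cf} f + B_{ch} h + \varepsilon,$$

with $u \perp\!\!\!\perp h$, $\varepsilon \perp\!\!\!\perp (h, f)$, and
$B_{fa} B_{ah} = 0$. The flux equation has **no error term**: in the
analysis pipeline $f$ is computed deterministically from $a$ by
constraint-based community modeling, so all flux variation across
subjects is abundance-driven. The orthogonality condition encodes that
flux coefficients derive from genome content, not host physiology.

Two consequences carry the method. Compositionality forces every column
of $B_{ah}$ to sum to zero (a host factor can only redistribute relative
abundance), and together with orthogonality, the sample covariance
across species between any row of $B_{fa}$ and any column of $B_{ah}$
is exactly zero. From these, with abundances standardized to unit
variance, the covariance across species between the in vivo association
statistics $\hat b^{ca}_{j\cdot}$ and the in silico statistics
$\hat b^{fa}_{j\cdot}$ is nonzero **iff** the diagonal causal effect
$b^{cf}_{jj}$ is nonzero. Host confounding moves both statistic vectors,
but only in directions that are uncorrelated across species — which is
why the criterion survives unmeasured confounding.

Standardization is not cosmetic: without it both statistic vectors carry
the abundance variances and their covariance is biased.

# The simulator

`make_parameters()` draws $B_{ah}$ columns at random and projects them
onto the zero-sum subspace, then draws $B_{fa}$ rows and projects them
onto the orthogonal complement of the $B_{ah}$ column span, making both
identities exact at machine precision (`ortho_noise` re-perturbs them
for robustness experiments). Scenarios fix the sign structure of the
diagonal of $B_{cf}$: `null` (0), `secretion` (+), `consumption` (−),
`mixed` (random signs).

`simulate_cohort()` draws $u$ as a symmetric Dirichlet composition
(concentration `alpha_u`, default 1, giving the right-skewed,
many-rare-species look of real relative abundance data) and host
factors i.i.d. with mean zero and unit variance. Linearity and the
simplex cannot both hold exactly; the simulator keeps the linear
structure *approximately* by choosing the largest shrinkage $s \le 1$
such that fewer than 5% of abundance entries leave $[0,1]$, then
clipping and renormalizing each subject. The realized host-effect
matrix is re-estimated by per-species regression and stored
(`B_ah_realized`); `theoretical_association_moments()` uses it, so the
oracle moments refer to the effects actually present after repair. If
honoring the 5% budget would shrink host effects more than 1000-fold,
the simulation aborts — the requested effect scale is incompatible with
the simplex.

**Host factors and covariates.** One deliberate design choice: the
third host factor is balanced binary ($\pm 1$, unit variance) rather
than Gaussian, because the emulated study observes it as the binary sex
covariate. A Gaussian factor observed through a dichotomized covariate
leaves part of that factor in every species regression's residual as a
*common* (cross-species) component; such components inflate the in vivo
statistic vector in directions uncorrelated with the in silico
statistics and push the flux-shuffling permutation test toward
conservatism. With a genuinely binary factor measured exactly — which
is what sex is in a real cohort — the adjustment set can span it, and
the permutation test calibrates. `as_study_tables()` observes the first
two factors as age ($55 + 10 h_1$) and BMI ($24 + 3 h_2$) with
measurement noise `obs_noise` (default 0.3 factor SDs), sex exactly,
and adds an uninformative binary group covariate. Setting
`obs_noise = 0` yields the fully-adjusted regime; larger values leave
residual unmeasured confounding in play.

**Observed concentrations.** The linear $c$ is exported as
$\exp(c)$ with the lowest `detection_quantile` (default 10%) of each
metabolite censored to zero — reproducing the right-skewed,
zero-inflated marginals of fecal metabolomes and the "zeros are below
detection" convention the log-response screens rely on.

Noise scales: `sigma_eps` defaults to 0.5 and `conf_effect` (the SD of
host-to-concentration effects) to `host_effect` (default 1); with
$K = 3$ factors, host signal and noise are then of comparable order on
the log-concentration scale. The power-grid value used in the
acceptance suite is `effect_scale = 5`, i.e. the causal flux
contribution is strong enough for per-species coefficients to dominate
their estimation noise at $n = 2000$ — the "slope-detectable" regime
the power property is about.

# The community flux engine

`build_community_model()` mirrors the standard community-construction
recipe: each microbe's exchange reactions are rewired into IEX
transporters against a shared lumen compartment `[u]`; every lumen
metabolite gets a diet `[d]` and a fecal `[fe]` compartment with one
sink each; the community biomass reaction consumes each microbe's
biomass metabolite weighted by relative abundance (so at steady state
each microbe grows at its abundance share of the community rate) and is
bounded to $[0.4, 1]$ mmol/person/day; coupling rows
$|v_{IEX}| \le 400\, v_{bm}$ silence absent or non-growing microbes.
Zero-abundance microbes are excluded from the model entirely, not
carried at weight zero. Pan-models take the reaction union over strains
(widest bounds on shared ids; conflicting stoichiometry is an error)
and average the biomass stoichiometries.

Sign conventions: sinks remove mass from their compartment, so positive
sink flux is outflow and dietary uptake is a *negative* diet-sink flux
(`apply_diet()` sets the lower bound to −supply). Then
`maxProd = |maxFaecal + minDiet|` is production beyond dietary input
and `maxUpt = |minFaecal + maxDiet|` the uptake capacity.

FVA fixes the community biomass to its FBA optimum $w$ (both bounds;
an infeasible re-solve is retried once at $w(1-10^{-6})$) and optimizes
the four sink objectives independently. Absolute values below $10^{-8}$
are reported as zero so solver noise cannot flip signs in the capacity
arithmetic. The LP layer is a dense two-phase tableau simplex with
Bland's anti-cycling rule (pivot tolerance $10^{-9}$), written for this
package because no reliable LP interface is available among its
dependencies; at the tens-of-reactions scale of the bundled models it
is exact and fast, and the test suite checks it against exhaustive
vertex enumeration of the feasible polytope. It is not intended for
genome-scale models.

# Screens and pattern tests

Screens follow the standard filters — species present in at least
`ceiling(0.10 n)` samples, metabolites nonzero in at least half — and
fit one OLS per (species, metabolite) pair with intercept, the species
predictor (presence or unit-variance abundance), and the host
covariates. Concentration responses are natural-log transformed with
zeros treated as missing; flux responses are left untransformed (their
distributions are not consistently right-skewed). Inference uses
HC1 sandwich errors (HC3 selectable), and BH-FDR is computed over the
whole screen. Constant covariates are dropped (absorbed by the
intercept); a zero-variance predictor yields a flagged degenerate row
rather than an error, and screens never abort on individual fit
failures.

The pattern stage regresses, per metabolite, the in vivo coefficients
on the in silico coefficients across species. Because both vectors are
built from intercorrelated compositional data, their entries are
mutually dependent and the parametric $F_{1,n-2}$ reference for
$F = R^2/(1-R^2)(n-2)$ is too liberal; significance therefore comes
from shuffling the metabolite's flux vector across samples and
recomputing the *entire* per-metabolite in silico screen per
permutation. Implementation note: with the design matrices fixed, each
permuted coefficient vector is a single matrix product
$W y_{perm}$, where row $l$ of $W$ is the predictor row of species
$l$'s least-squares pseudoinverse — this is exactly the screen
recomputation, and the suite asserts the equality against the `lm`
route. P values use the add-one rule $(1 + \#\{F_{perm} \ge
F_{obs}\})/(B+1)$ with a $\ge$ count (ties conservative; observed and
permuted statistics are evaluated by the same code path so exact ties
count consistently), hence never zero; `B` defaults to 5000 with a
warning below 100; `exhaustive = TRUE` enumerates all $n!$ permutations
for micro-fixtures. Sign agreement tabulates the sign pairs (exact
zeros excluded) and both tails of the concordance count are evaluated
under the same permutation distribution, since discordance (net
consumption) is a finding, not a failure; the reported `perm_p_sign` is
the doubled smaller tail, capped at 1. Permutation p values are
additionally BH-adjusted across metabolites within each comparison set.

Classification: *concordant* requires significance (either permutation
p below `alpha`), positive slope, and at least as many sign agreements
as disagreements; *discordant* requires significance with negative
slope; anything else is *none*. A metabolite called concordant in one
comparison set and discordant in another is flagged inconsistent —
computed fluxes cannot indicate net secretion and net consumption at
once — and left to the analyst.

By default all species enter the pattern regression; the
`significant_only` option restricts the response to species with
FDR-significant in vivo associations, a stricter reading of the
three-step scheme.

# Calibration of the permutation test

Flux shuffling generates an exchangeable null: it answers "is the in
vivo pattern more aligned with the in silico pattern than with a random
coefficient vector of the same regression geometry?" The suite verifies
(200 null cohorts, $n = 2000$, $L = 40$, $B = 500$) that when the
adjustment covariates measure the host factors — the regime in which
the in vivo coefficient noise is itself exchangeable — the rejection
rate at $\alpha = 0.05$ lies within $[0.02, 0.10]$. When measurement
noise leaves part of a host factor unadjusted, the leftover common
residual component enlarges the in vivo vector in directions
uncorrelated with the in silico statistics, which can only *shrink* the
observed alignment relative to the permutation draw: residual
confounding moves the test toward conservatism, never toward
anti-conservatism. The power and sign-flip properties (secretion
detected concordant, consumption discordant in at least 90% of
replicates at `effect_scale = 5`) are asserted under the default,
noisily-measured covariates.

# Problem sizes and numerical choices

The validation suite standardizes on cohorts of $n = 2000$ with
$L = 40$ species, $K = 3$ host factors and $J = 5$ metabolites; power
and type-I properties use 50 and 200 replicates with $B = 200$ and
$B = 500$ permutations, and the null-covariance identity averages 500
cohorts. Larger-$n$ convergence checks (the oracle moments) run once at
$n = 10^5$. Community fixtures are kept at or below ~15 reactions so
vertex enumeration stays exhaustive. Degenerate inputs are handled
explicitly: constant fluxes and zero-variance in silico patterns are
refused with a degenerate-pattern error, perfect pattern fits cap the F
statistic and carry a `perfect_fit` flag, and per-sample community
failures drop the sample with a warning rather than aborting the
population run.

# What the simulator does and does not establish

Passing tests on simulated cohorts show that the three-step procedure
recovers the causal direction, holds its error rate, and honors the
analytic identities *within the linear structural model with
deterministic fluxes*. Real data differ in ways the generator does not
emulate: taxonomic profiling error in $a$, nonlinear or saturating
flux–abundance relations, host–microbiome feedback, non-diagonal
$B_{cf}$ (cross-metabolite effects), longitudinal dependence, and
reconstructions whose gene content misses transport or degradation
pathways (in which case the "secretion capacity" can behave as a
consumption metric — the discordant case). Species-level causal claims
remain out of reach: the criterion addresses whether community
secretion drives a concentration, not which species is responsible.
The flux engine is toy-scale by design; plugging in genome-scale
reconstruction collections requires an industrial LP solver behind the
same interfaces.
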