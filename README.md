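# fluxpattern

Causal inference on microbiome–metabolome relations from observational
cohort data, by **in silico in vivo association pattern analysis**.

## The problem

A fecal metabolite can correlate with a gut species for two very
different reasons: the species (community) actually secretes or consumes
the metabolite, or host factors (age, body composition, disease, …)
confound both the microbiome composition and the metabolome.
Association screens alone cannot tell these apart.

`fluxpattern` implements a three-step procedure that can:

1. **In vivo screen** — for each metabolite *j* and species *l*, the
   covariate-adjusted regression coefficient b̂ᶜᵃⱼₗ of the (log) fecal
   concentration cⱼ on the standardized abundance aₗ (or presence
   indicator), adjusting for age, BMI, sex and group, with
   heteroscedasticity-robust (HC1) standard errors.
2. **In silico screen** — the same regressions with the community **net
   secretion capacity** fⱼ as response, computed per sample by
   constraint-based community modeling: species reconstructions joined
   through a common lumen compartment with diet and fecal sinks, an
   abundance-weighted community biomass reaction constrained to
   [0.4, 1] mmol/person/day, coupling constraints |IEX| ≤ 400·bm, and
   flux variability analysis at the community biomass optimum, giving
   maxProd = |maxFaecal + minDiet| per metabolite.
3. **Pattern analysis** — per metabolite, regress the in vivo
   coefficient vector on the in silico one across species
   (b̂ᶜᵃⱼ. = β₀ + β₁ b̂ᶠᵃⱼ.), and test β₁ = 0 by shuffling the flux
   vector across samples and recomputing the whole in silico screen for
   each permutation (statistic F = R²/(1−R²)·(n−2); sign-agreement
   counts are tested from the same permutation distribution).

The justification is a linear structural equation model
a = B_ah h + u, f = B_fa a, c = B_cf f + B_ch h + ε with u ⫫ h, ε ⫫
(h, f) and B_fa B_ah = 0: because abundances are compositional, every
column of B_ah sums to zero, and the covariance across species between
in vivo and in silico association statistics (of standardized
abundances) is nonzero **iff** the diagonal causal effect b_cf_jj is
nonzero. A significantly positive pattern slope (*concordant*) indicates
microbial net secretion driving the host concentration; a significantly
negative one (*discordant*) indicates net consumption.

The package contains the complete machinery: a structural-equation
cohort simulator (the generative model above, with simplex repair,
right-skewed zero-inflated observed concentrations, and covariates that
are noisy measurements of the host factors), a toy-scale community
FBA/FVA engine with its own LP solver, the association screens, and the
permutation pattern tests — so the whole causal criterion is testable
end to end without external reconstructions or cohort data.

## Worked example

Simulate a cohort in which every metabolite is genuinely secreted by
the community (secretion scenario, strong effect), then run the full
three-step analysis:

```r
library(fluxpattern)

params <- make_parameters(L = 30, K = 3, J = 4, scenario = "secretion",
                          effect_scale = 5, seed = 42)
cohort <- simulate_cohort(params, n = 500, seed = 43)
tables <- as_study_tables(cohort, seed = 44)

cfg <- run_config(seed = 42, n_permutations = 500)
res <- run_pattern_analysis(tables, cfg)
res[res$predictor_kind == "abundance",
    c("metabolite", "slope", "perm_p", "perm_p_sign", "q_perm",
      "classification")]
#>  metabolite slope perm_p perm_p_sign q_perm classification
#>        met1  4.11  0.002     0.00399  0.002     concordant
#>        met2  4.31  0.002     0.00399  0.002     concordant
#>        met3  4.43  0.002     0.00399  0.002     concordant
#>        met4  4.92  0.002     0.00399  0.002     concordant
```

Every metabolite is correctly called concordant: the pattern slope
(≈ 4–5) recovers the planted flux→concentration effect (5), the
permutation p values sit at the resolution floor 1/(B+1), and the
BH-adjusted `q_perm` stays significant. Under `scenario = "consumption"`
the slopes flip sign and the calls become `discordant`; under
`scenario = "null"` (confounding only) the patterns are flagged `none`.

The community flux engine on the bundled toy reconstruction (one
glucose-feeding microbe that can side-produce butyrate, diet supplying
10 mmol glucose):

```r
m1 <- read_reconstruction(system.file("extdata", "m1_model.json",
                                      package = "fluxpattern"))
cm <- apply_diet(build_community_model(c(M1 = 1), list(M1 = m1)),
                 c(glc = 10))
w <- solve_community_fba(cm)$w       # 1: biomass cap binds
fv <- fva_exchange_bounds(cm, "but", w)
#>   minDiet   maxDiet minFaecal maxFaecal
#>         0         0         0         9
net_secretion_capacity(fv)
#> maxProd  maxUpt
#>       9       0
```

One glucose goes to biomass (w = 1), the remaining nine can be
fermented to butyrate: maxProd = |9 + 0| = 9.

A thin command-line wrapper is installed at `inst/cli/fluxpattern`
(subcommands `simulate`, `fluxes`, `associate`, `pattern`, `all`).

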