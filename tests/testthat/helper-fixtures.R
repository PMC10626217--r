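## Fixtures built in code: toy reconstructions and miniature study tables.

m1_reconstruction <- function() {
  read_reconstruction(system.file("extdata", "m1_model.json",
                                  package = "fluxpattern"))
}

## one-microbe, 7-reaction community: biomass feeds directly on lumen
## glucose; small enough for exhaustive vertex enumeration
micro_reconstruction <- function() {
  reconstruction(
    id = "MX",
    metabolites = data.frame(id = "glc", compartment = "e"),
    reactions = list(
      list(id = "bm", stoichiometry = c("glc[e]" = -1),
           lower = 0, upper = 1000),
      list(id = "EX_glc", stoichiometry = c("glc[e]" = -1),
           lower = -1000, upper = 1000)),
    biomass_reaction = "bm",
    exchange_reactions = "EX_glc")
}

## second toy microbe: converts glucose to acetate
m2_reconstruction <- function() {
  reconstruction(
    id = "M2",
    metabolites = data.frame(id = c("glc", "ac", "glc", "ac"),
                             compartment = c("c", "c", "e", "e")),
    reactions = list(
      list(id = "t_glc", stoichiometry = c("glc[e]" = -1, "glc[c]" = 1),
           lower = 0, upper = 1000),
      list(id = "r_ac", stoichiometry = c("glc[c]" = -1, "ac[c]" = 2),
           lower = 0, upper = 1000),
      list(id = "t_ac", stoichiometry = c("ac[c]" = -1, "ac[e]" = 1),
           lower = 0, upper = 1000),
      list(id = "bm", stoichiometry = c("glc[c]" = -1),
           lower = 0, upper = 1000),
      list(id = "EX_glc", stoichiometry = c("glc[e]" = -1),
           lower = -1000, upper = 1000),
      list(id = "EX_ac", stoichiometry = c("ac[e]" = -1),
           lower = -1000, upper = 1000)),
    biomass_reaction = "bm",
    exchange_reactions = c("EX_glc", "EX_ac"))
}

## tiny aligned study tables for permutation / screen micro-tests
tiny_tables <- function(n = 5L, L = 4L, seed = 42L) {
  set.seed(seed)
  A <- matrix(rgamma(n * L, 2), n, L)
  A <- A / rowSums(A)
  dimnames(A) <- list(paste0("S", 1:n), paste0("sp", 1:L))
  conc <- matrix(exp(rnorm(n)), n, 1, dimnames = list(rownames(A), "m1"))
  flux <- matrix(rnorm(n), n, 1, dimnames = list(rownames(A), "m1"))
  covs <- data.frame(age = rep(50, n), BMI = rep(24, n),
                     sex = rep(1L, n), group = rep(0L, n),
                     row.names = rownames(A))
  study_tables(A, conc, covs, flux)
}

## a simulated cohort as study tables in one call
sim_tables <- function(scenario, n = 600L, L = 25L, K = 3L, J = 3L,
                       effect_scale = 5, seed = 1L, ...) {
  p <- make_parameters(L = L, K = K, J = J, scenario = scenario,
                       effect_scale = effect_scale, seed = seed, ...)
  co <- simulate_cohort(p, n, seed = seed + 1L)
  list(params = p, cohort = co,
       tables = as_study_tables(co, seed = seed + 2L))
}
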