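test_that("pattern regression recovers exact linear relations and orthogonality", {
  set.seed(3)
  b_fa <- rnorm(20)
  ## exact proportionality: slope 2, perfect fit flagged
  r <- suppressWarnings(pattern_regression(2 * b_fa, b_fa))
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  expect_equal(r$flag, "perfect_fit")
  ## response orthogonalised against the predictor: slope 0
  y <- rnorm(20)
  y_perp <- residuals(lm(y ~ b_fa))
  r0 <- pattern_regression(y_perp, b_fa)
  expect_lt(abs(r0$slope), 1e-12)
  expect_error(pattern_regression(rnorm(3), rnorm(3)), "at least 4")
  expect_error(pattern_regression(rnorm(6), rep(1, 6)), "zero variance")
})

test_that("pattern regression matches the normal-equations oracle on a 6-point fixture", {
  b_fa <- c(-1.2, -0.4, 0.1, 0.5, 1.1, 1.9)
  b_ca <- c(-0.9, -0.6, 0.3, 0.2, 1.4, 1.6)
  r <- pattern_regression(b_ca, b_fa)
  o <- ols_hc1_oracle(b_ca, cbind(1, b_fa))
  expect_equal(r$slope, o$beta[2], tolerance = 1e-10)
  expect_equal(r$intercept, o$beta[1], tolerance = 1e-10)
  expect_equal(r$robust_se, o$se[2], tolerance = 1e-10)
  r2 <- cor(b_ca, b_fa)^2
  expect_equal(r$F_measure, r2 / (1 - r2) * 4, tolerance = 1e-10)
})

test_that("sign agreement tabulates sign pairs and drops exact zeros", {
  b <- c(1, -2, 3, -4, 5)
  expect_equal(sign_agreement(b, b)$concordant, 5L)
  expect_equal(sign_agreement(b, -b)$concordant, 0L)
  sa <- sign_agreement(c(1, 0, -1, 2), c(1, 1, 1, -2))
  expect_equal(sa$n_tabulated, 3L)
  expect_equal(sa$concordant, 1L)
  expect_equal(unname(sa$table["-1", "1"]), 1L)
})

test_that("pattern classification combines significance, slope sign and agreement", {
  mk <- function(slope, perm_p, conc, n) list(
    regression = list(slope = slope),
    signs = list(concordant = conc, n_tabulated = n),
    perm_p_value = perm_p, perm_p_sign = 1)
  expect_equal(classify_pattern(mk(2.0, 0.001, 18, 20)), "concordant")
  expect_equal(classify_pattern(mk(-1.5, 0.001, 2, 20)), "discordant")
  expect_equal(classify_pattern(mk(0.4, 0.40, 15, 20)), "none")
  expect_error(classify_pattern(list(regression = list(slope = 1))),
               "permutation")
})

test_that("sampled permutation p matches exhaustive enumeration at n = 5", {
  tt <- tiny_tables(n = 5, L = 4, seed = 42)
  cfg <- run_config(n_permutations = 2000)
  ex <- flux_permutation_test(tt, "m1", "abundance", seed = 1,
                              config = cfg, exhaustive = TRUE)
  expect_equal(ex$B, 120L)
  sam <- flux_permutation_test(tt, "m1", "abundance", B = 2000, seed = 1,
                               config = cfg)
  ## binomial sampling error around the exhaustive probability
  p_ex <- ex$perm_p_value
  tol <- 3 * sqrt(p_ex * (1 - p_ex) / 2000) + 2 / 2000
  expect_lt(abs(sam$perm_p_value - p_ex), tol)
  expect_lt(abs(sam$perm_p_sign_concordant - ex$perm_p_sign_concordant),
            3 * sqrt(0.25 / 2000) + 0.05)
  ## the exhaustive p agrees with an independent enumeration oracle
  species <- filter_species(tt$abundance, cfg$min_prevalence)
  enc <- encode_predictors(tt$abundance, species)
  P <- enc$abundance_std
  b_ca <- sapply(seq_len(ncol(P)), function(l)
    coef(lm(log(tt$metabolome[, 1]) ~ P[, l]))[2])
  f_of <- function(fx) {
    bf <- sapply(seq_len(ncol(P)), function(l)
      coef(lm(fx ~ P[, l]))[2])
    r2 <- cor(b_ca, bf)^2
    r2 / (1 - r2) * (length(b_ca) - 2)
  }
  F_obs <- f_of(tt$flux[, 1])
  pm <- perms_oracle(5L)
  F_all <- apply(pm, 1, function(ix) f_of(tt$flux[ix, 1]))
  p_oracle <- (1 + sum(F_all >= F_obs)) / (120 + 1)
  expect_equal(p_ex, p_oracle, tolerance = 1e-12)
})

test_that("permutation p obeys the add-one floor and detects self-association", {
  tt <- tiny_tables(n = 30, L = 5, seed = 5)
  ## plant the flux into the concentrations: maximal association
  tt$metabolome[, 1] <- exp(tt$flux[, 1])
  cfg <- run_config(n_permutations = 500)
  res <- suppressWarnings(
    flux_permutation_test(tt, "m1", "abundance", B = 499, seed = 2,
                          config = cfg))
  expect_gte(res$perm_p_value, 1 / 500)
  expect_lte(res$perm_p_value, 0.05)
  w <- capture_warnings(
    flux_permutation_test(tt, "m1", "abundance", B = 50, seed = 2,
                          config = cfg))
  expect_true(any(grepl("poor p-value resolution", w)))
})

test_that("permutation p is invariant to positive flux rescaling; the slope is not", {
  tt <- tiny_tables(n = 40, L = 5, seed = 8)
  cfg <- run_config(n_permutations = 300)
  r1 <- flux_permutation_test(tt, "m1", "abundance", B = 300, seed = 3,
                              config = cfg)
  tt2 <- tt
  tt2$flux[, 1] <- 50 * tt$flux[, 1]
  r2 <- flux_permutation_test(tt2, "m1", "abundance", B = 300, seed = 3,
                              config = cfg)
  expect_equal(r1$perm_p_value, r2$perm_p_value)
  expect_equal(r2$regression$slope, r1$regression$slope / 50,
               tolerance = 1e-10)
})

test_that("degenerate flux columns are refused", {
  tt <- tiny_tables(n = 20, L = 4, seed = 13)
  tt$flux[, 1] <- 1
  expect_error(flux_permutation_test(tt, "m1", "abundance", B = 200,
                                     seed = 1, config = run_config()),
               "constant")
})

test_that("full pattern analysis recovers the planted causal direction", {
  st <- sim_tables("secretion", n = 800, L = 25, J = 3, effect_scale = 5,
                   seed = 31)
  cfg <- run_config(seed = 31, n_permutations = 200)
  res <- run_pattern_analysis(st$tables, cfg)
  expect_equal(nrow(res), 3L * 2L)      # metabolites x predictor kinds
  ab <- res[res$predictor_kind == "abundance", ]
  expect_true(all(ab$classification == "concordant"))
  expect_true(all(ab$slope > 0))
  expect_true(all(res$q_perm[!is.na(res$q_perm)] >=
                    res$perm_p[!is.na(res$perm_p)] - 1e-12))
  st2 <- sim_tables("consumption", n = 800, L = 25, J = 3,
                    effect_scale = 5, seed = 33)
  res2 <- run_pattern_analysis(st2$tables, cfg)
  ab2 <- res2[res2$predictor_kind == "abundance", ]
  expect_true(all(ab2$classification == "discordant"))
  expect_true(all(ab2$slope < 0))
  ## screens attached for all four comparison sets
  expect_setequal(names(attr(res, "screens")),
                  c("presence_concentration", "presence_flux",
                    "abundance_concentration", "abundance_flux"))
})
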