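## Step 3 of the paradigm: per-metabolite regression of the in vivo
## association statistics on the in silico association statistics, with
## flux-shuffling permutation tests and sign-agreement tabulation.
## Because association statistics computed on intercorrelated,
## compositional data are mutually dependent, the parametric F test of
## the pattern slope is too liberal; the permutation test shuffles the
## metabolite's flux vector across samples, recomputes the entire in
## silico screen for that metabolite, and compares the observed pattern
## statistics to their permutation distribution.

#' Pattern regression of in vivo on in silico association statistics
#'
#' OLS of the per-species in vivo coefficients on the in silico
#' coefficients with intercept, heteroscedasticity-robust (HC1) slope SE,
#' and the F transform of the coefficient of determination,
#' \code{F = R^2 / (1 - R^2) * (n - 2)}, which is the permutation test
#' statistic.  A perfect fit caps F at \code{.Machine$double.xmax} and is
#' flagged.
#'
#' @param b_ca numeric vector of in vivo association statistics (one per
#'   species).
#' @param b_fa numeric vector of in silico association statistics.
#' @return list with \code{slope}, \code{intercept}, \code{robust_se},
#'   \code{parametric_p}, \code{F_measure}, \code{r_squared},
#'   \code{n_species}, \code{flag}.
#' @export
pattern_regression <- function(b_ca, b_fa) {
  ok <- is.finite(b_ca) & is.finite(b_fa)
  b_ca <- b_ca[ok]; b_fa <- b_fa[ok]
  n <- length(b_ca)
  if (n < 4L) stop("need at least 4 species with finite statistics")
  if (stats::var(b_fa) == 0)
    stop("degenerate pattern: in silico statistics have zero variance")

  fit <- stats::lm(b_ca ~ b_fa)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  vc <- sandwich::vcovHC(fit, type = "HC1")
  se <- sqrt(vc[2L, 2L])
  p <- 2 * stats::pt(-abs(slope / se), df = n - 2L)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((b_ca - mean(b_ca))^2)
  flag <- ""
  if (1 - r2 < 1e-12) {
    Fm <- .Machine$double.xmax
    flag <- "perfect_fit"
  } else Fm <- r2 / (1 - r2) * (n - 2L)
  list(slope = slope, intercept = intercept, robust_se = se,
       parametric_p = p, F_measure = Fm, r_squared = r2,
       n_species = n, flag = flag)
}

#' Sign agreement between in vivo and in silico statistics
#'
#' Tabulates the sign of each species' in vivo statistic against the sign
#' of its in silico statistic.  Coefficients that are exactly zero are
#' excluded.  The concordance statistic is the number of species on the
#' agreeing diagonal (both positive or both negative).
#'
#' @param b_ca,b_fa association statistic vectors.
#' @return list with the 2 x 2 \code{table} (rows: in vivo sign, columns:
#'   in silico sign), \code{concordant} count and \code{n_tabulated}.
#' @export
sign_agreement <- function(b_ca, b_fa) {
  ok <- is.finite(b_ca) & is.finite(b_fa) & b_ca != 0 & b_fa != 0
  sv <- sign(b_ca[ok]); sf <- sign(b_fa[ok])
  tab <- table(factor(sv, levels = c(-1, 1)),
               factor(sf, levels = c(-1, 1)),
               dnn = c("in_vivo", "in_silico"))
  list(table = tab,
       concordant = sum(sv == sf),
       n_tabulated = sum(ok))
}

#' Flux-shuffling permutation test of one metabolite's pattern
#'
#' Holds the in vivo association statistics fixed, shuffles the
#' metabolite's flux vector across samples \code{B} times, recomputes for
#' each permutation the entire in silico screen for the metabolite
#' (per-species covariate-adjusted regressions of the shuffled flux) and
#' from it the pattern F statistic and the sign-concordance statistic.
#' P values use the add-one rule \code{(1 + #extreme) / (B + 1)} with a
#' \code{>=} extremity count, so they are never zero.  The concordance
#' statistic is evaluated in both tails (concordant patterns indicate net
#' secretion, discordant ones net consumption).
#'
#' @param tables a \code{study_tables} object with a flux matrix.
#' @param metabolite metabolite id (column of both the metabolome and the
#'   flux matrix).
#' @param predictor_kind \code{"presence"} or \code{"abundance"}.
#' @param B number of permutations (default 5000; below 100 the
#'   resolution is poor and a warning is emitted).
#' @param seed integer seed; the permutation stream is deterministic
#'   given it.
#' @param config a \code{\link{run_config}}.
#' @param exhaustive enumerate all n! sample permutations instead of
#'   sampling (only sensible for very small n; overrides \code{B}).
#' @return list with the observed \code{regression} and \code{signs},
#'   \code{perm_p_value} (F statistic), \code{perm_p_sign} (two-sided),
#'   \code{perm_p_sign_concordant}, \code{perm_p_sign_discordant},
#'   \code{B}, and summary quantiles of the permuted F distribution.
#' @export
flux_permutation_test <- function(tables, metabolite,
                                  predictor_kind = c("presence", "abundance"),
                                  B = 5000L, seed = 1L,
                                  config = run_config(),
                                  exhaustive = FALSE) {
  predictor_kind <- match.arg(predictor_kind)
  stopifnot(inherits(tables, "study_tables"))
  if (is.null(tables$flux))
    stop("study tables carry no flux matrix")
  if (!exhaustive && B < 100L)
    warning("B < 100 permutations gives poor p-value resolution")

  species <- filter_species(tables$abundance, config$min_prevalence)
  enc <- encode_predictors(tables$abundance, species)
  P <- if (predictor_kind == "presence") enc$presence else enc$abundance_std

  conc <- tables$metabolome[, metabolite]
  flux <- tables$flux[, metabolite]
  if (max(flux) - min(flux) == 0)
    stop("degenerate pattern: flux of '", metabolite, "' is constant")

  ## fixed in vivo statistics (log concentration, zeros treated as missing)
  sc_vivo <- screen_coefficients(conc, P, tables$covariates,
                                 log_response = TRUE)
  b_ca <- sc_vivo$beta
  ## in silico screen: same machinery, flux response untransformed
  sc_sil <- screen_coefficients(flux, P, tables$covariates,
                                log_response = FALSE)
  b_fa <- sc_sil$beta

  obs_reg <- pattern_regression(b_ca, b_fa)
  obs_sign <- sign_agreement(b_ca, b_fa)

  n <- length(sc_sil$rows_used)
  W <- sc_sil$weights                    # L x n coefficient extractor
  y <- sc_sil$y
  Lsp <- nrow(W)

  ## F statistic of the pattern regression from a permuted coefficient set
  f_stat <- function(bf) {
    if (max(bf) - min(bf) == 0) return(0)
    r2 <- stats::cor(b_ca, bf)^2
    if (1 - r2 < 1e-12) return(.Machine$double.xmax)
    r2 / (1 - r2) * (Lsp - 2L)
  }
  s_stat <- function(bf) {
    nz <- b_ca != 0 & bf != 0
    sum(sign(b_ca[nz]) == sign(bf[nz]))
  }

  if (exhaustive) {
    perms <- permutations_of(n)
    B <- nrow(perms)
    idx <- function(b) perms[b, ]
  } else {
    set.seed(derive_seeds(seed, 1L))
    idx <- function(b) sample.int(n)
  }
  ## the observed statistic is evaluated through the same function as the
  ## permuted ones, so exact ties (e.g. the identity permutation in
  ## exhaustive mode) are counted consistently
  F_obs <- f_stat(b_fa)
  F_perm <- numeric(B); S_perm <- numeric(B)
  for (b in seq_len(B)) {
    bf <- as.numeric(W %*% y[idx(b)])
    F_perm[b] <- f_stat(bf)
    S_perm[b] <- s_stat(bf)
  }
  p_F <- (1 + sum(F_perm >= F_obs)) / (B + 1)
  p_conc <- (1 + sum(S_perm >= obs_sign$concordant)) / (B + 1)
  p_disc <- (1 + sum(S_perm <= obs_sign$concordant)) / (B + 1)
  list(metabolite = metabolite, predictor_kind = predictor_kind,
       regression = obs_reg, signs = obs_sign,
       perm_p_value = p_F,
       perm_p_sign = min(1, 2 * min(p_conc, p_disc)),
       perm_p_sign_concordant = p_conc,
       perm_p_sign_discordant = p_disc,
       B = B,
       F_perm_quantiles = stats::quantile(F_perm, c(.5, .9, .95, .99)))
}

## all permutations of 1..n (n small), one per row
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- nrow(sub)
    block <- cbind(rep(k, rows), matrix(setdiff(seq_len(n), k)[sub],
                                        rows, n - 1L))
    out[r + seq_len(rows), ] <- block
    r <- r + rows
  }
  out
}

#' Classify a metabolite's association pattern
#'
#' A pattern is \code{concordant} (microbial net secretion drives the
#' host concentration) when either permutation p value is below
#' \code{alpha}, the slope is positive and sign agreements are at least
#' as frequent as disagreements; \code{discordant} (the secretion
#' capacity acts as a net-consumption metric) when significant with a
#' negative slope; otherwise \code{none}.
#'
#' @param result output of \code{\link{flux_permutation_test}}.
#' @param alpha significance level (default 0.05).
#' @return one of \code{"concordant"}, \code{"discordant"}, \code{"none"}.
#' @export
classify_pattern <- function(result, alpha = 0.05) {
  if (is.null(result$perm_p_value))
    stop("permutation results missing; run flux_permutation_test() first")
  signif <- result$perm_p_value < alpha || result$perm_p_sign < alpha
  if (!signif) return("none")
  slope <- result$regression$slope
  conc <- result$signs$concordant
  disc <- result$signs$n_tabulated - conc
  if (slope > 0 && conc >= disc) "concordant"
  else if (slope < 0) "discordant"
  else "none"
}

#' Run the full in silico in vivo pattern analysis
#'
#' Executes the association screens (steps 1-2) and the per-metabolite
#' pattern tests (step 3) for both predictor encodings, classifies every
#' metabolite, BH-adjusts the permutation p values across metabolites
#' within each comparison set, and cross-checks that no metabolite is
#' called both concordant and discordant across its comparison sets
#' (computed fluxes cannot indicate net secretion and net consumption at
#' once); conflicts are flagged, never silently dropped.
#'
#' @param tables a \code{study_tables} object with a flux matrix.
#' @param config a \code{\link{run_config}}; \code{n_permutations},
#'   \code{alpha} and the filters are taken from it.
#' @return data.frame with one row per metabolite x predictor kind:
#'   slope, robust_se, parametric_p, F, perm_p, perm_p_sign, q_perm, sign
#'   table cells, classification, consistency flag.  The four association
#'   screens are attached as attribute \code{"screens"}.
#' @export
run_pattern_analysis <- function(tables, config = run_config()) {
  stopifnot(inherits(tables, "study_tables"))
  mets <- intersect(filter_metabolites(tables$metabolome, config$min_nonzero),
                    colnames(tables$flux))
  if (!length(mets))
    stop("no metabolite passes the detection filter and has fluxes")

  screens <- list()
  for (pk in c("presence", "abundance"))
    for (rk in c("concentration", "flux"))
      screens[[paste(pk, rk, sep = "_")]] <-
        association_screen(tables, pk, rk, config)

  rows <- list()
  for (pk in c("presence", "abundance")) {
    for (m in mets) {
      res <- tryCatch(
        flux_permutation_test(tables, m, pk, B = config$n_permutations,
                              seed = config$seed + match(m, mets),
                              config = config),
        error = function(e) e)
      if (inherits(res, "error")) {
        rows[[paste(pk, m)]] <- data.frame(
          metabolite = m, predictor_kind = pk, slope = NA_real_,
          robust_se = NA_real_, parametric_p = NA_real_, F = NA_real_,
          perm_p = NA_real_, perm_p_sign = NA_real_,
          n_species = NA_integer_, sign_pp = NA_integer_,
          sign_pn = NA_integer_, sign_np = NA_integer_,
          sign_nn = NA_integer_, classification = "none",
          flag = conditionMessage(res), stringsAsFactors = FALSE)
        next
      }
      tab <- res$signs$table
      rows[[paste(pk, m)]] <- data.frame(
        metabolite = m, predictor_kind = pk,
        slope = res$regression$slope,
        robust_se = res$regression$robust_se,
        parametric_p = res$regression$parametric_p,
        F = res$regression$F_measure,
        perm_p = res$perm_p_value,
        perm_p_sign = res$perm_p_sign,
        n_species = res$regression$n_species,
        sign_pp = tab["1", "1"], sign_pn = tab["1", "-1"],
        sign_np = tab["-1", "1"], sign_nn = tab["-1", "-1"],
        classification = classify_pattern(res, config$alpha),
        flag = res$regression$flag, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out$q_perm <- NA_real_
  for (pk in unique(out$predictor_kind)) {
    sel <- out$predictor_kind == pk
    out$q_perm[sel] <- fdr_adjust(out$perm_p[sel])
  }
  ## consistency: a metabolite must not be concordant in one comparison
  ## set and discordant in another
  for (m in unique(out$metabolite)) {
    cls <- out$classification[out$metabolite == m]
    if (all(c("concordant", "discordant") %in% cls)) {
      sel <- out$metabolite == m
      out$flag[sel] <- paste0(out$flag[sel],
                              ";inconsistent_classification")
    }
  }
  attr(out, "screens") <- screens
  out
}
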