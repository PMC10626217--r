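## Structural-equation simulator of metabolic host-microbiome systems.
##
## The generative model is the linear system
##   a = s * B_ah h + u        (abundances; compositional, repaired to simplex)
##   f = B_fa a                (community net-secretion fluxes, exact)
##   c = B_cf f + B_ch h + eps (host metabolite concentrations)
## with u independent of h, eps independent of (h, f), every column of B_ah
## summing to zero (a consequence of compositionality), and every row of
## B_fa orthogonal to every column of B_ah.

#' Construct parameters of the structural host-microbiome model
#'
#' Builds the coefficient matrices of the linear structural system relating
#' latent host factors, microbial relative abundances, community
#' net-secretion fluxes and host metabolite concentrations.  Columns of the
#' host-to-abundance matrix \code{B_ah} are projected onto the zero-sum
#' subspace (compositional closure forces host effects on abundances to
#' cancel across species), and rows of the abundance-to-flux matrix
#' \code{B_fa} are projected onto the orthogonal complement of the span of
#' the \code{B_ah} columns, so \code{B_fa \%*\% B_ah} is exactly zero.
#' Since the \code{B_ah} columns are mean-zero, exact orthogonality also
#' makes the sample covariance across species between any \code{B_fa} row
#' and any \code{B_ah} column vanish.
#'
#' @param L number of microbial species (must satisfy \code{L >= K + J + 1}
#'   so the orthogonal complement used for the flux rows is non-empty).
#' @param K number of latent host factors.
#' @param J number of metabolites.
#' @param scenario one of \code{"null"} (no flux-to-concentration effect),
#'   \code{"secretion"} (all diagonal effects positive), \code{"consumption"}
#'   (all negative) or \code{"mixed"} (random signs).
#' @param effect_scale magnitude of the diagonal flux-to-concentration
#'   effects \code{B_cf} (ignored under \code{"null"}); must be positive.
#' @param seed integer seed; construction is deterministic given it.
#' @param host_effect scale of host effects on abundances: each column of
#'   \code{B_ah} is rescaled to standard deviation \code{host_effect / L}
#'   across species, keeping host shifts commensurate with mean relative
#'   abundance 1/L.  Set to 0 for a host-free microbiome.
#' @param conf_effect standard deviation of the entries of the
#'   host-to-concentration confounding matrix \code{B_ch}.
#' @param alpha_u concentration of the symmetric Dirichlet distribution of
#'   the intrinsic (host-independent) microbiome component \code{u};
#'   larger values give less dispersed compositions.
#' @param sigma_eps standard deviation of the concentration noise.
#' @param ortho_noise optional perturbation added to \code{B_fa} after
#'   projection, breaking exact orthogonality; default 0 keeps the
#'   orthogonality assumption exact.
#'
#' @return an object of class \code{sem_parameters}: a list with the
#'   dimension constants and matrices \code{B_ah} (L x K), \code{B_fa}
#'   (J x L), \code{B_cf} (J x J diagonal), \code{B_ch} (J x K).
#' @export
#' @examples
#' p <- make_parameters(L = 20, K = 3, J = 4, scenario = "secretion", seed = 1)
#' max(abs(colSums(p$B_ah)))        # zero-sum columns
#' max(abs(p$B_fa %*% p$B_ah))      # exact orthogonality
make_parameters <- function(L, K, J,
                            scenario = c("null", "secretion",
                                         "consumption", "mixed"),
                            effect_scale = 1, seed = 1L,
                            host_effect = 1, conf_effect = host_effect,
                            alpha_u = 1, sigma_eps = 0.5,
                            ortho_noise = 0) {
  scenario <- match.arg(scenario)
  if (L < K + J + 1)
    stop("infeasible dimensions: need L >= K + J + 1 (got L = ", L,
         ", K = ", K, ", J = ", J, ")")
  if (effect_scale <= 0) stop("effect_scale must be > 0")
  if (sigma_eps < 0) stop("sigma_eps must be >= 0")

  rng <- derive_seeds(seed, 2L)
  set.seed(rng[1L])

  ## host -> abundance effects: random columns, centred (zero-sum), scaled
  B_ah <- matrix(stats::rnorm(L * K), L, K)
  B_ah <- sweep(B_ah, 2L, colMeans(B_ah))
  if (host_effect > 0) {
    sds <- apply(B_ah, 2L, stats::sd)
    B_ah <- sweep(B_ah, 2L, sds, "/") * (host_effect / L)
  } else {
    B_ah[] <- 0
  }

  ## abundance -> flux effects: random rows projected off span{B_ah columns}
  B_fa <- matrix(stats::rnorm(J * L), J, L)
  if (host_effect > 0) {
    Q <- qr.Q(qr(B_ah))                       # orthonormal basis, L x K
    B_fa <- B_fa - (B_fa %*% Q) %*% t(Q)
  }
  if (ortho_noise > 0)
    B_fa <- B_fa + matrix(stats::rnorm(J * L, sd = ortho_noise), J, L)

  diag_cf <- switch(scenario,
    null        = rep(0, J),
    secretion   = rep(effect_scale, J),
    consumption = rep(-effect_scale, J),
    mixed       = effect_scale * sample(c(-1, 1), J, replace = TRUE))
  B_cf <- diag(diag_cf, nrow = J)

  B_ch <- matrix(stats::rnorm(J * K, sd = conf_effect), J, K)

  structure(list(L = L, K = K, J = J,
                 B_ah = B_ah, B_fa = B_fa, B_cf = B_cf, B_ch = B_ch,
                 scenario = scenario, effect_scale = effect_scale,
                 host_effect = host_effect, conf_effect = conf_effect,
                 alpha_u = alpha_u, sigma_eps = sigma_eps,
                 ortho_noise = ortho_noise, seed = seed),
            class = "sem_parameters")
}

#' @export
print.sem_parameters <- function(x, ...) {
  cat("Structural host-microbiome model parameters\n")
  cat(sprintf("  species L = %d, host factors K = %d, metabolites J = %d\n",
              x$L, x$K, x$J))
  cat(sprintf("  scenario: %s (effect scale %.3g)\n", x$scenario,
              x$effect_scale))
  cat(sprintf("  max |colsum B_ah| = %.2e, max |B_fa B_ah| = %.2e\n",
              max(abs(colSums(x$B_ah))), max(abs(x$B_fa %*% x$B_ah))))
  invisible(x)
}

#' Simulate a cohort from the structural host-microbiome model
#'
#' Draws \code{n} i.i.d. metabolic host-microbiome systems.  Host factors
#' \code{H} are standard normal; the intrinsic microbiome component
#' \code{U} is symmetric Dirichlet (independent of \code{H}); raw
#' abundances \code{U + s * H B_ah'} are repaired to the simplex by
#' clipping to [0, 1] and renormalising each sample to sum one, with the
#' shrinkage factor \code{s <= 1} chosen so that fewer than 5\% of entries
#' need clipping.  Fluxes are exact linear images of the realised
#' abundances (\code{F = A B_fa'}, no error term); concentrations follow
#' the linear concentration equation with independent Gaussian noise.
#'
#' @param params a \code{sem_parameters} object.
#' @param n number of samples (>= 2).
#' @param seed integer seed for the cohort draw (independent of the
#'   parameter-construction stream).
#' @param binary_factors indices of host factors drawn as balanced
#'   binary (+1/-1, mean zero, unit variance) rather than Gaussian.  The
#'   default makes the third factor binary, matching its observation as
#'   the sex covariate in the emulated study design; independence and
#'   moment assumptions are unaffected.
#'
#' @return an object of class \code{sem_cohort}: list with matrices
#'   \code{H} (n x K), \code{U}, \code{A} (n x L, rows on the simplex),
#'   \code{F}, \code{C}, \code{E} (n x J), the realised abundance scale
#'   \code{s}, the per-sample clip fraction, the regression-re-estimated
#'   host-to-abundance matrix \code{B_ah_realized}, and \code{params}.
#' @export
simulate_cohort <- function(params, n, seed = 1L,
                            binary_factors = if (params$K >= 3) 3L else
                              integer(0)) {
  stopifnot(inherits(params, "sem_parameters"))
  if (n < 2) stop("need n >= 2 samples")
  L <- params$L; K <- params$K; J <- params$J
  set.seed(derive_seeds(seed, 1L))

  H <- matrix(stats::rnorm(n * K), n, K)
  for (k in binary_factors)
    H[, k] <- 2 * stats::rbinom(n, 1L, 0.5) - 1
  ## symmetric Dirichlet rows via normalised gammas
  G <- matrix(stats::rgamma(n * L, shape = params$alpha_u, rate = 1), n, L)
  U <- G / rowSums(G)

  Delta <- H %*% t(params$B_ah)             # n x L host shifts
  s <- 1
  if (params$host_effect > 0 && any(Delta != 0)) {
    ## pick the largest s <= 1 for which < 5% of entries leave [0, 1]
    neg <- Delta < 0
    thr <- U[neg] / (-Delta[neg])           # entry e violates iff s > thr
    budget <- 0.05 * length(U)
    if (sum(thr < 1) > budget) {
      s <- stats::quantile(thr, budget / length(thr), names = FALSE)
      s <- max(s, 0)
    }
    if (s < 1e-3)
      stop("simplex repair failed: keeping < 5% of abundance entries ",
           "outside [0, 1] requires shrinking host effects by more than ",
           "1000-fold; host_effect = ", params$host_effect,
           " is too large for the abundance simplex")
  }
  A_raw <- U + s * Delta
  clipped <- A_raw < 0 | A_raw > 1
  clip_frac_row <- rowMeans(clipped)
  A <- pmin(pmax(A_raw, 0), 1)
  A <- A / rowSums(A)

  Fm <- A %*% t(params$B_fa)
  E <- matrix(stats::rnorm(n * J, sd = params$sigma_eps), n, J)
  C <- Fm %*% t(params$B_cf) + H %*% t(params$B_ch) + E

  ## realised host effects after repair (per-species OLS of A on H)
  X <- cbind(1, H)
  B_real <- t(qr.coef(qr(X), A)[-1L, , drop = FALSE])   # L x K

  dimnames(A) <- list(paste0("S", seq_len(n)), paste0("sp", seq_len(L)))
  dimnames(Fm) <- list(rownames(A), paste0("met", seq_len(J)))
  dimnames(C) <- dimnames(Fm)

  structure(list(n = n, H = H, U = U, A = A, F = Fm, C = C, E = E,
                 s = s, clip_fraction = mean(clipped),
                 clip_fraction_row = clip_frac_row,
                 B_ah_realized = B_real, params = params, seed = seed),
            class = "sem_cohort")
}

#' @export
print.sem_cohort <- function(x, ...) {
  cat(sprintf("Simulated host-microbiome cohort: n = %d, L = %d, J = %d\n",
              x$n, x$params$L, x$params$J))
  cat(sprintf("  scenario %s; abundance scale s = %.3g; %.2f%% entries clipped\n",
              x$params$scenario, x$s, 100 * x$clip_fraction))
  invisible(x)
}

#' Theoretical association moments of a simulated cohort
#'
#' Evaluates, from the known generative matrices and the empirical
#' covariances of the latent components, the theoretical values of
#' \eqn{VAR(a_l)\,\hat b^{fa}_{jl}} and \eqn{VAR(a_l)\,\hat b^{ca}_{jl}}:
#' the in silico statistic reduces to the covariance between the flux
#' loading of the intrinsic microbiome and the species' intrinsic
#' component, \eqn{COV(\sum_i b^{fa}_{ji} u_i, u_l)}, while the in vivo
#' statistic adds the direct causal term \eqn{b^{cf}_{jj}} times the in
#' silico statistic plus the host-confounding term
#' \eqn{COV(\sum_k b^{ch}_{jk} h_k, \sum_t b^{ah}_{lt} h_t)}.  These are
#' the oracle values against which fitted per-species regression
#' coefficients converge.
#'
#' @param params a \code{sem_parameters} object.
#' @param cohort the cohort simulated from \code{params} (its empirical
#'   covariances of \code{U} and \code{H} are used).
#' @return list with J x L matrices \code{insilico_var_b} and
#'   \code{invivo_var_b} (the variance-scaled statistics), and
#'   \code{bhat_fa}, \code{bhat_ca} (divided by the empirical abundance
#'   variances).
#' @export
theoretical_association_moments <- function(params, cohort) {
  stopifnot(inherits(params, "sem_parameters"),
            inherits(cohort, "sem_cohort"))
  if (ncol(cohort$U) != params$L || ncol(cohort$H) != params$K)
    stop("cohort dimensions do not match the parameters")
  Sigma_u <- stats::cov(cohort$U)
  Sigma_h <- stats::cov(cohort$H)
  var_a <- apply(cohort$A, 2L, stats::var)

  m_fa <- params$B_fa %*% Sigma_u                      # J x L
  bhat_fa <- sweep(m_fa, 2L, var_a, "/")
  ## the host->abundance effects realised after the simplex repair (the
  ## re-estimated coefficients, exact for the in-sample H covariance)
  conf <- params$B_ch %*% Sigma_h %*% t(cohort$B_ah_realized)     # J x L
  m_ca <- diag(params$B_cf) * m_fa + conf   # b_cf_jj * COV(f_j, a_l) + conf
  bhat_ca <- sweep(m_ca, 2L, var_a, "/")

  list(insilico_var_b = m_fa, invivo_var_b = m_ca,
       bhat_fa = bhat_fa, bhat_ca = bhat_ca)
}

#' Plain (unadjusted) association statistics of a cohort
#'
#' Per-species simple-regression coefficients of each metabolite response
#' on the standardised species abundance: \code{COV(y, a_l) / VAR(a_l)}
#' after scaling each abundance column to unit variance.  These are the
#' population-level association statistics of the theory layer; the
#' covariate-adjusted screening layer generalises them.
#'
#' @param response n x J matrix (fluxes or concentrations).
#' @param abundance n x L abundance matrix.
#' @return J x L matrix of coefficients on the standardised scale.
#' @export
association_statistics <- function(response, abundance) {
  A_std <- scale(abundance)            # unit variance (n-1 denominator)
  crossprod(scale(response, scale = FALSE), A_std) / (nrow(abundance) - 1)
}

## split a master seed into independent 31-bit substreams
derive_seeds <- function(seed, k) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, k)
}
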