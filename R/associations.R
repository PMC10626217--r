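## Steps 1 and 2 of the pattern-analysis paradigm: covariate-adjusted
## per-(species, metabolite) regression screens, run once with measured
## concentrations as response (in vivo) and once with community
## net-secretion fluxes (in silico).

#' Prevalence filter for species
#'
#' Keeps species detected (nonzero abundance) in at least
#' \code{ceiling(min_prevalence * n)} samples.
#'
#' @param abundance samples x species matrix of relative abundances.
#' @param min_prevalence minimum detection fraction (default 0.10).
#' @return character vector of retained species names.
#' @export
filter_species <- function(abundance, min_prevalence = 0.10) {
  stopifnot(is.matrix(abundance) || is.data.frame(abundance))
  abundance <- as.matrix(abundance)
  if (any(abundance < 0)) stop("abundances must be nonnegative")
  n <- nrow(abundance)
  keep <- colSums(abundance > 0) >= ceiling(min_prevalence * n)
  out <- colnames(abundance)[keep]
  if (length(out) == 0L)
    stop("no species pass the ", min_prevalence, " prevalence filter")
  out
}

#' Detection filter for metabolites
#'
#' Keeps metabolites with values above the detection limit (nonzero) in at
#' least \code{min_nonzero} of the samples.
#'
#' @param metabolome samples x metabolites concentration matrix (zeros are
#'   below-detection values).
#' @param min_nonzero minimum nonzero fraction (default 0.50).
#' @return character vector of retained metabolite names.
#' @export
filter_metabolites <- function(metabolome, min_nonzero = 0.50) {
  metabolome <- as.matrix(metabolome)
  if (any(metabolome < 0)) stop("concentrations must be nonnegative")
  n <- nrow(metabolome)
  keep <- colSums(metabolome > 0) >= min_nonzero * n
  colnames(metabolome)[keep]
}

#' Encode species predictors: presence and unit-variance abundance
#'
#' Builds the binary presence matrix and the standardised abundance matrix
#' (each column mean-centred and scaled to sample variance one, n-1
#' denominator).  Standardisation is required by the causal criterion:
#' without it both in vivo and in silico association statistics carry the
#' abundance variances and their covariance across species is biased.
#' Species whose abundance is constant across samples cannot be
#' standardised and are dropped with a warning.
#'
#' @param abundance samples x species matrix.
#' @param species species to encode (defaults to all columns).
#' @return list with matrices \code{presence} and \code{abundance_std}.
#' @export
encode_predictors <- function(abundance, species = colnames(abundance)) {
  abundance <- as.matrix(abundance)[, species, drop = FALSE]
  presence <- (abundance > 0) + 0
  sds <- apply(abundance, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance species from standardised encoding: ",
            paste(species[sds == 0], collapse = ", "))
  }
  keep <- sds > 0
  abundance_std <- scale(abundance[, keep, drop = FALSE])
  list(presence = presence,
       abundance_std = abundance_std[, , drop = FALSE])
}

#' Fit one covariate-adjusted species-response association
#'
#' Ordinary least squares of the (optionally log-transformed) response on
#' one species predictor plus the host covariates, with intercept.
#' Inference on the predictor coefficient uses heteroscedasticity-robust
#' (sandwich) standard errors, HC1 by default.  For log responses, zero
#' values are below the detection limit and treated as missing.  Constant
#' covariate columns are dropped (they are absorbed by the intercept).
#'
#' @param response numeric response vector (concentration or flux).
#' @param predictor numeric predictor vector (presence indicator or
#'   standardised abundance).
#' @param covariates data.frame of adjustment covariates (may be NULL).
#' @param log_response log-transform the response (use for concentrations;
#'   fluxes are not consistently right-skewed and are left untransformed).
#' @param drop_zero_response drop samples with response <= 0 (default:
#'   equal to \code{log_response}).
#' @param se_type sandwich flavour, \code{"HC1"} or \code{"HC3"}.
#' @return list with \code{coefficient}, \code{robust_se}, \code{p},
#'   \code{n_used} and \code{flag} (NA-free string on success).
#' @export
fit_association <- function(response, predictor, covariates = NULL,
                            log_response = FALSE,
                            drop_zero_response = log_response,
                            se_type = c("HC1", "HC3")) {
  se_type <- match.arg(se_type)
  n0 <- length(response)
  stopifnot(length(predictor) == n0)
  keep <- is.finite(response) & is.finite(predictor)
  if (drop_zero_response) keep <- keep & response > 0

  X_cov <- NULL
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0) {
    X_cov <- stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1L,
                                                                  drop = FALSE]
    stopifnot(nrow(X_cov) == n0)
    keep <- keep & stats::complete.cases(X_cov)
    X_cov <- X_cov[keep, , drop = FALSE]
    const <- apply(X_cov, 2L, function(z) max(z) - min(z) == 0)
    X_cov <- X_cov[, !const, drop = FALSE]
    if (ncol(X_cov) == 0L) X_cov <- NULL
  }
  y <- response[keep]
  x <- predictor[keep]
  if (log_response) y <- log(y)
  n_used <- length(y)

  k_terms <- 2L + if (is.null(X_cov)) 0L else ncol(X_cov)
  if (n_used < k_terms + 2L)
    stop("too few usable samples (", n_used, ") for ", k_terms,
         " model terms")
  if (max(x) - min(x) == 0 || stats::var(y) == 0) {
    return(list(coefficient = 0, robust_se = NA_real_, p = NA_real_,
                n_used = n_used, flag = "degenerate"))
  }

  dat <- data.frame(.y = y, .x = x)
  if (!is.null(X_cov)) dat <- cbind(dat, as.data.frame(X_cov))
  X_full <- cbind(1, x, X_cov)
  if (qr(X_full)$rank < ncol(X_full))
    stop("predictor is collinear with the covariates")
  fit <- stats::lm(.y ~ ., data = dat)
  beta <- unname(stats::coef(fit)[".x"])
  vc <- sandwich::vcovHC(fit, type = se_type)
  se <- sqrt(vc[".x", ".x"])
  p <- 2 * stats::pt(-abs(beta / se), df = fit$df.residual)
  list(coefficient = beta, robust_se = se, p = p, n_used = n_used,
       flag = "")
}

#' Coefficient-only association screen for one response vector
#'
#' Returns, for every column of the predictor matrix, the OLS coefficient
#' of the predictor in the covariate-adjusted regression of the response.
#' Because the response enters the normal equations linearly, each
#' coefficient is a fixed linear functional \code{w_l' y} of the response;
#' the returned weight matrix lets permutation tests recompute an entire
#' per-metabolite screen as one matrix product.  Coefficients agree
#' exactly with \code{\link{fit_association}} on the same rows.
#'
#' @param response numeric response vector.
#' @param P samples x species predictor matrix (presence or standardised
#'   abundance).
#' @param covariates data.frame of adjustment covariates or NULL.
#' @param log_response,drop_zero_response as in
#'   \code{\link{fit_association}}.
#' @return list with \code{beta} (length ncol(P)), \code{weights}
#'   (ncol(P) x n_used matrix with rows w_l), \code{rows_used} (indices of
#'   retained samples) and \code{y} (the transformed response used).
#' @export
screen_coefficients <- function(response, P, covariates = NULL,
                                log_response = FALSE,
                                drop_zero_response = log_response) {
  keep <- is.finite(response)
  if (drop_zero_response) keep <- keep & response > 0
  y <- response[keep]
  if (log_response) y <- log(y)
  Pk <- P[keep, , drop = FALSE]
  X_cov <- NULL
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0) {
    X_cov <- stats::model.matrix(~ ., data = as.data.frame(covariates))[keep, -1L,
                                                                 drop = FALSE]
    const <- apply(X_cov, 2L, function(z) max(z) - min(z) == 0)
    X_cov <- X_cov[, !const, drop = FALSE]
    if (ncol(X_cov) == 0L) X_cov <- NULL
  }
  L <- ncol(Pk)
  W <- matrix(NA_real_, L, length(y),
              dimnames = list(colnames(Pk), NULL))
  for (l in seq_len(L)) {
    X <- cbind(1, Pk[, l], X_cov)
    ## row of the pseudoinverse belonging to the predictor term
    W[l, ] <- chol2inv(chol(crossprod(X)))[2L, ] %*% t(X)
  }
  list(beta = as.numeric(W %*% y), weights = W,
       rows_used = which(keep), y = y)
}

#' Run one full association screen
#'
#' Fits one covariate-adjusted regression per (species, metabolite) pair
#' for a given predictor encoding (presence or standardised abundance) and
#' response table (in vivo concentrations, log-transformed with zeros
#' treated as missing, or in silico fluxes, untransformed).
#' Benjamini-Hochberg FDR is computed over the whole screen.  Individual
#' fit failures are kept as flagged rows with NA statistics; the screen
#' never aborts.
#'
#' @param tables a \code{study_tables} object (see
#'   \code{\link{study_tables}}).
#' @param predictor_kind \code{"presence"} or \code{"abundance"}.
#' @param response_kind \code{"concentration"} or \code{"flux"}.
#' @param config a \code{\link{run_config}} (prevalence and detection
#'   thresholds, robust-SE flavour).
#' @return data.frame with one row per (metabolite, species) pair:
#'   metabolite, species, predictor_kind, response_kind, beta, robust_se,
#'   p, q, n_used, flag.
#' @export
association_screen <- function(tables,
                               predictor_kind = c("presence", "abundance"),
                               response_kind = c("concentration", "flux"),
                               config = run_config()) {
  predictor_kind <- match.arg(predictor_kind)
  response_kind <- match.arg(response_kind)
  stopifnot(inherits(tables, "study_tables"))

  species <- filter_species(tables$abundance, config$min_prevalence)
  mets <- filter_metabolites(tables$metabolome, config$min_nonzero)
  resp_tab <- if (response_kind == "concentration") tables$metabolome else {
    if (is.null(tables$flux))
      stop("study tables carry no flux matrix; run the community flux ",
           "stage first")
    tables$flux
  }
  mets <- intersect(mets, colnames(resp_tab))
  enc <- encode_predictors(tables$abundance, species)
  P <- if (predictor_kind == "presence") enc$presence else enc$abundance_std
  species <- colnames(P)

  log_resp <- response_kind == "concentration"
  rows <- vector("list", length(mets) * length(species))
  i <- 0L
  for (m in mets) {
    y <- resp_tab[, m]
    for (sp in species) {
      i <- i + 1L
      res <- tryCatch(
        fit_association(y, P[, sp], tables$covariates,
                        log_response = log_resp,
                        se_type = config$robust_se_flavor),
        error = function(e) list(coefficient = NA_real_,
                                 robust_se = NA_real_, p = NA_real_,
                                 n_used = NA_integer_,
                                 flag = conditionMessage(e)))
      rows[[i]] <- data.frame(metabolite = m, species = sp,
                              predictor_kind = predictor_kind,
                              response_kind = response_kind,
                              beta = res$coefficient,
                              robust_se = res$robust_se,
                              p = res$p, n_used = res$n_used,
                              flag = res$flag,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- fdr_adjust(out$p)
  out[, c("metabolite", "species", "predictor_kind", "response_kind",
          "beta", "robust_se", "p", "q", "n_used", "flag")]
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Wrapper around \code{stats::p.adjust(method = "BH")} that excludes
#' missing p values from the number of tests and returns them as NA.
#'
#' @param pvals numeric p values in [0, 1] (NA allowed).
#' @return adjusted q values, same length and order.
#' @export
fdr_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    stop("p values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvals))
  out[ok] <- stats::p.adjust(pvals[ok], method = "BH")
  out
}
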