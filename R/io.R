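## Table input/output, run configuration and the study-table container.

#' Run configuration
#'
#' Bundles the tunable parameters of the pipeline with validation.
#'
#' @param seed master seed; every random stage derives its own stream
#'   from it.
#' @param n_permutations permutations per pattern test (>= 100).
#' @param alpha significance level for classification.
#' @param min_prevalence species prevalence filter (fraction of samples).
#' @param min_nonzero metabolite detection filter (fraction of samples).
#' @param coupling_coefficient exchange-to-biomass coupling factor.
#' @param biomass_bounds community biomass flux bounds (mmol/person/day).
#' @param robust_se_flavor sandwich flavour for all robust SEs.
#' @param significant_only restrict pattern regressions to species with
#'   FDR-significant in vivo associations.
#' @return validated list of class \code{run_config}.
#' @export
run_config <- function(seed = 1L, n_permutations = 5000L, alpha = 0.05,
                       min_prevalence = 0.10, min_nonzero = 0.50,
                       coupling_coefficient = 400,
                       biomass_bounds = c(0.4, 1),
                       robust_se_flavor = c("HC1", "HC3"),
                       significant_only = FALSE) {
  robust_se_flavor <- match.arg(robust_se_flavor)
  stopifnot(n_permutations >= 100L,
            alpha > 0, alpha < 1,
            min_prevalence > 0, min_prevalence < 1,
            min_nonzero > 0, min_nonzero <= 1,
            length(biomass_bounds) == 2L,
            biomass_bounds[1L] <= biomass_bounds[2L],
            coupling_coefficient > 0)
  cfg <- list(seed = as.integer(seed),
              n_permutations = as.integer(n_permutations),
              alpha = alpha, min_prevalence = min_prevalence,
              min_nonzero = min_nonzero,
              coupling_coefficient = coupling_coefficient,
              biomass_bounds = biomass_bounds,
              robust_se_flavor = robust_se_flavor,
              significant_only = significant_only)
  cfg$hash <- config_hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

## FNV-1a hash of the serialised configuration, hex string
config_hash <- function(cfg) {
  cfg$hash <- NULL
  bytes <- as.integer(charToRaw(paste(names(cfg),
                                      vapply(cfg, function(x)
                                        paste(format(x), collapse = ","),
                                        ""),
                                      sep = "=", collapse = ";")))
  ## 32-bit FNV-1a in double arithmetic (bitwXor needs operands < 2^31,
  ## so xor only the low byte, which is exact)
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h <- (h * 16777619) %% 4294967296
  }
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}

#' Study tables: the aligned analysis container
#'
#' Holds the four sample-aligned matrices of a study: relative
#' abundances, metabolite concentrations (zeros = below detection),
#' community net-secretion fluxes (optional until the flux stage has
#' run), and host covariates.
#'
#' @param abundance samples x species matrix, rows summing to ~1.
#' @param metabolome samples x metabolites concentration matrix.
#' @param covariates data.frame of host covariates (e.g. age, BMI, sex,
#'   group), one row per sample.
#' @param flux samples x metabolites maxProd matrix, or NULL.
#' @return object of class \code{study_tables}.
#' @export
study_tables <- function(abundance, metabolome, covariates, flux = NULL) {
  abundance <- as.matrix(abundance)
  metabolome <- as.matrix(metabolome)
  n <- nrow(abundance)
  stopifnot(nrow(metabolome) == n, nrow(covariates) == n,
            is.null(flux) || nrow(flux) == n)
  ids <- rownames(abundance)
  if (!is.null(ids)) {
    stopifnot(identical(rownames(metabolome), ids),
              is.null(flux) || identical(rownames(flux), ids))
  }
  if (any(abundance < 0) || any(abundance > 1))
    stop("abundance entries must lie in [0, 1]")
  structure(list(abundance = abundance, metabolome = metabolome,
                 covariates = as.data.frame(covariates), flux = flux),
            class = "study_tables")
}

#' @export
print.study_tables <- function(x, ...) {
  cat(sprintf("Study tables: %d samples, %d species, %d metabolites, flux %s\n",
              nrow(x$abundance), ncol(x$abundance), ncol(x$metabolome),
              if (is.null(x$flux)) "absent" else "present"))
  invisible(x)
}

read_table_auto <- function(path) {
  l1 <- readLines(path, n = 5L)
  l1 <- l1[!startsWith(l1, "#")]
  sep <- if (grepl("\t", l1[1L])) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(df[[1L]]))
    stop("duplicate sample ids in ", path)
  rownames(df) <- df[[1L]]
  df[[1L]] <- NULL
  df
}

#' Read aligned study tables from CSV/TSV files
#'
#' Reads the abundance, metabolome, covariate and (optionally) flux
#' tables (first column sample id; comma- or tab-separated, sniffed),
#' aligns them on the intersection of sample ids, and renormalises
#' abundance rows that are within 1\% of summing to one.
#'
#' @param abundance_path,metabolome_path,covariates_path,flux_path file
#'   paths; \code{flux_path} may be NULL for a staged run.
#' @return a \code{\link{study_tables}} object.
#' @export
read_study_tables <- function(abundance_path, metabolome_path,
                              covariates_path, flux_path = NULL) {
  ab <- read_table_auto(abundance_path)
  mb <- read_table_auto(metabolome_path)
  cv <- read_table_auto(covariates_path)
  fx <- if (!is.null(flux_path)) read_table_auto(flux_path) else NULL

  ids <- Reduce(intersect, c(list(rownames(ab), rownames(mb), rownames(cv)),
                             if (!is.null(fx)) list(rownames(fx))))
  dropped <- length(unique(c(rownames(ab), rownames(mb), rownames(cv)))) -
    length(ids)
  if (dropped > 0)
    message(dropped, " sample id(s) not shared by all tables were dropped")
  if (!length(ids)) stop("no shared sample ids across the tables")

  ab <- as.matrix(ab[ids, , drop = FALSE])
  rs <- rowSums(ab)
  off <- abs(rs - 1) > 0.01
  if (any(off))
    stop("abundance rows do not sum to 1 within 1%: ",
         paste(ids[off], collapse = ", "))
  ab <- ab / rs

  mb <- as.matrix(mb[ids, , drop = FALSE])
  if (!all(vapply(cv, is.numeric, TRUE) |
             vapply(cv, is.logical, TRUE) |
             vapply(cv, is.character, TRUE)))
    stop("covariate columns must be numeric, logical or categorical")
  study_tables(ab, mb, cv[ids, , drop = FALSE],
               if (!is.null(fx)) as.matrix(fx[ids, , drop = FALSE]))
}

#' Convert a simulated cohort to study tables
#'
#' Emulates what a real cohort measures: the metabolome is the
#' exponentiated linear concentration (giving right-skewed marginals),
#' zero-inflated by censoring values below a per-metabolite detection
#' quantile; fluxes are the exact linear images of the abundances.  The
#' host covariates are noisy observations of the latent host factors --
#' age tracks the first factor, BMI the second, sex the third
#' (dichotomised), mirroring how a real study measures and adjusts for
#' its host characterisation; \code{obs_noise} controls how much of each
#' factor the measurement misses (residual, unmeasured confounding).
#' The group indicator is independent.
#'
#' @param cohort a \code{sem_cohort}.
#' @param detection_quantile fraction of each metabolite's values
#'   censored to zero (below-detection); default 0.1.
#' @param obs_noise standard deviation of the measurement error on the
#'   observed host factors, relative to the unit factor scale
#'   (default 0.3).
#' @param seed seed for the covariate draw.
#' @return a \code{\link{study_tables}} object.
#' @export
as_study_tables <- function(cohort, detection_quantile = 0.1,
                            obs_noise = 0.3, seed = 1L) {
  stopifnot(inherits(cohort, "sem_cohort"))
  n <- cohort$n
  K <- ncol(cohort$H)
  conc <- exp(cohort$C)
  if (detection_quantile > 0) {
    for (j in seq_len(ncol(conc))) {
      lod <- stats::quantile(conc[, j], detection_quantile, names = FALSE)
      conc[conc[, j] < lod, j] <- 0
    }
  }
  set.seed(derive_seeds(seed + 17L, 1L))
  obs <- function(k) if (k <= K)
    cohort$H[, k] + stats::rnorm(n, sd = obs_noise) else stats::rnorm(n)
  ## sex is recorded exactly (a binary factor is measured without error);
  ## age and BMI are noisy continuous observations of their factors
  sex <- if (K >= 3) as.integer(cohort$H[, 3L] > 0) else
    stats::rbinom(n, 1L, 0.5)
  covariates <- data.frame(
    age = round(55 + 10 * obs(1L)),
    BMI = round(24 + 3 * obs(2L), 1),
    sex = sex,
    group = stats::rbinom(n, 1L, 0.5),
    row.names = rownames(cohort$A))
  study_tables(cohort$A, conc, covariates, cohort$F)
}

#' Write a cohort as the four study CSV tables plus a truth sidecar
#'
#' Emits \code{abundance.csv}, \code{metabolome.csv}, \code{flux.csv} and
#' \code{covariates.csv} in the layout \code{\link{read_study_tables}}
#' consumes, plus \code{truth.json} holding the generative parameter
#' matrices for parameter-recovery tests.
#'
#' @param cohort a \code{sem_cohort}.
#' @param dir output directory (created if missing).
#' @param detection_quantile,seed passed to \code{\link{as_study_tables}}.
#' @param config optional \code{run_config}; its hash is stamped into a
#'   comment line of every table.
#' @return (invisibly) the paths written.
#' @export
write_cohort_tables <- function(cohort, dir, detection_quantile = 0.1,
                                seed = 1L, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- as_study_tables(cohort, detection_quantile, seed)
  paths <- file.path(dir, c("abundance.csv", "metabolome.csv", "flux.csv",
                            "covariates.csv", "truth.json"))
  write_one <- function(m, path) {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(config))
      writeLines(paste0("# config_hash: ", config$hash), con)
    df <- data.frame(sample_id = rownames(as.matrix(m)),
                     as.data.frame(as.matrix(m)), check.names = FALSE)
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  }
  write_one(tabs$abundance, paths[1L])
  write_one(tabs$metabolome, paths[2L])
  write_one(tabs$flux, paths[3L])
  write_one(tabs$covariates, paths[4L])
  p <- cohort$params
  jsonlite::write_json(list(L = p$L, K = p$K, J = p$J,
                            scenario = p$scenario,
                            B_ah = p$B_ah, B_fa = p$B_fa,
                            B_cf = diag(p$B_cf), B_ch = p$B_ch,
                            s = cohort$s,
                            B_ah_realized = cohort$B_ah_realized),
                       paths[5L], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}

#' Read a diet constraint table
#'
#' Two-column TSV/CSV: metabolite id, supply (mmol/person/day, >= 0).
#'
#' @param path file path.
#' @return named numeric supply vector.
#' @export
read_diet <- function(path) {
  df <- utils::read.table(path, header = TRUE, comment.char = "#",
                          sep = if (grepl("\t", readLines(path, n = 1L)))
                            "\t" else ",",
                          stringsAsFactors = FALSE)
  supply <- as.numeric(df[[2L]])
  if (any(is.na(supply)) || any(supply < 0))
    stop("diet supplies must be nonnegative numbers")
  stats::setNames(supply, df[[1L]])
}

#' Write an association screen or pattern table as TSV
#'
#' @param df result data.frame.
#' @param path output path.
#' @param config optional \code{run_config} whose hash is stamped as a
#'   comment line.
#' @export
write_result_table <- function(df, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config))
    writeLines(paste0("# config_hash: ", config$hash), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_config_hash <- function(path) {
  l1 <- readLines(path, n = 1L)
  if (startsWith(l1, "# config_hash: "))
    sub("^# config_hash: ", "", l1) else NA_character_
}
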