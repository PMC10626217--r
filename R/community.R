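## Community model construction and flux variability analysis.
##
## A personalised community model joins the (pan-)reconstructions of the
## microbes detected in one sample through a shared lumen compartment [u],
## itself connected to a diet [d] and a fecal [fe] compartment.  Each
## microbe exchange reaction becomes an IEX transporter between the
## microbe's extracellular space and the lumen; for every lumen metabolite
## a diet sink and a fecal sink are added (positive sink flux = flow out
## of the compartment, so dietary uptake is a negative diet-sink flux).
## The community biomass reaction consumes each microbe's biomass
## metabolite with its relative abundance as coefficient, which at steady
## state forces every microbe to grow at its abundance share of the
## community rate.  Coupling constraints |IEX| <= 400 * bm tie each
## microbe's exchange fluxes to its biomass flux so that absent or
## non-growing microbes carry no flux.

#' Build a personalised community model
#'
#' @param abundances named numeric vector of relative abundances
#'   (nonnegative, summing to 1 within 1e-6).  Microbes with zero
#'   abundance are excluded from the model entirely.
#' @param reconstructions named list of \code{\link{reconstruction}}
#'   objects covering every microbe with positive abundance.
#' @param coupling_coefficient the factor tying exchange fluxes to the
#'   microbe biomass flux (default 400).
#' @param biomass_bounds bounds of the community biomass flux in
#'   mmol/person/day; the default [0.4, 1] spans fecal excretion once
#'   every three days to daily.
#' @param sink_upper finite upper bound of the diet and fecal sink and
#'   transporter reactions (default 1000).
#' @return object of class \code{community_model}: stoichiometric matrix
#'   \code{S}, bound vectors \code{lower}/\code{upper}, coupling
#'   inequality matrix \code{coupling} (rows \code{A v <= 0}), reaction
#'   and metabolite ids, the community biomass reaction id \code{cm}, and
#'   per-lumen-metabolite \code{diet_sinks} and \code{fecal_sinks} maps.
#' @export
build_community_model <- function(abundances, reconstructions,
                                  coupling_coefficient = 400,
                                  biomass_bounds = c(0.4, 1),
                                  sink_upper = 1000) {
  if (any(abundances < 0)) stop("abundances must be nonnegative")
  abundances <- abundances[abundances > 0]
  if (abs(sum(abundances) - 1) > 1e-6)
    stop("abundances must sum to 1 (got ", format(sum(abundances)), ")")
  abundances <- abundances / sum(abundances)
  if (length(miss <- setdiff(names(abundances), names(reconstructions))))
    stop("no reconstruction available for microbe(s): ",
         paste(miss, collapse = ", "))

  rxn_id <- character(); rxn_lb <- numeric(); rxn_ub <- numeric()
  sto <- list()                     # per reaction: named coefficient vector
  coupling_pairs <- list()          # (iex id, biomass id)
  lumen <- character()
  bm_ids <- character(length(abundances))
  names(bm_ids) <- names(abundances)

  add_rxn <- function(id, stoich, lb, ub) {
    rxn_id[[length(rxn_id) + 1L]] <<- id
    sto[[id]] <<- stoich
    rxn_lb[[length(rxn_lb) + 1L]] <<- lb
    rxn_ub[[length(rxn_ub) + 1L]] <<- ub
  }

  for (mi in names(abundances)) {
    rec <- reconstructions[[mi]]
    stopifnot(inherits(rec, "reconstruction"))
    pfx <- function(keys) paste0(mi, "|", keys)
    bm_ids[mi] <- paste0(mi, "|", rec$biomass_reaction)
    for (r in rec$reactions) {
      if (r$id %in% rec$exchange_reactions) {
        ## rewire the standalone exchange into a lumen transporter (IEX)
        s <- r$stoichiometry
        if (length(s) != 1L)
          stop("exchange reaction '", r$id, "' of microbe '", mi,
               "' must involve exactly one metabolite")
        met <- names(s)
        base <- sub("\\[.*$", "", met)
        lumen <- union(lumen, base)
        iex <- paste0(mi, "|IEX_", base)
        ## positive IEX flux = secretion into the lumen
        coef <- stats::setNames(c(-abs(s), 1),
                                c(pfx(met), paste0(base, "[u]")))
        add_rxn(iex, coef, r$lower, r$upper)
        coupling_pairs[[length(coupling_pairs) + 1L]] <-
          c(iex = iex, bm = bm_ids[[mi]])
      } else {
        s <- stats::setNames(as.numeric(r$stoichiometry),
                             pfx(names(r$stoichiometry)))
        if (r$id == rec$biomass_reaction &&
            !any(r$stoichiometry > 0 &
                   startsWith(names(r$stoichiometry), "biomass"))) {
          ## biomass reaction additionally produces the microbe's biomass
          ## metabolite, consumed by the community biomass reaction
          s <- c(s, stats::setNames(1, paste0(mi, "|biomass[c]")))
        }
        add_rxn(paste0(mi, "|", r$id), s, r$lower, r$upper)
      }
    }
  }

  ## lumen / diet / fecal plumbing, one sink pair per lumen metabolite
  diet_sinks <- stats::setNames(paste0("sink_d_", lumen), lumen)
  fecal_sinks <- stats::setNames(paste0("sink_fe_", lumen), lumen)
  for (x in lumen) {
    add_rxn(paste0("DUt_", x),
            stats::setNames(c(-1, 1), paste0(x, c("[d]", "[u]"))),
            0, sink_upper)
    add_rxn(paste0("UFEt_", x),
            stats::setNames(c(-1, 1), paste0(x, c("[u]", "[fe]"))),
            0, sink_upper)
    add_rxn(diet_sinks[[x]], stats::setNames(-1, paste0(x, "[d]")),
            0, sink_upper)
    add_rxn(fecal_sinks[[x]], stats::setNames(-1, paste0(x, "[fe]")),
            0, sink_upper)
  }

  ## community biomass: cm = sum_i a_i * bm_i via the biomass metabolites
  cm_sto <- stats::setNames(-as.numeric(abundances),
                            paste0(names(abundances), "|biomass[c]"))
  add_rxn("communityBiomass", cm_sto, biomass_bounds[1L], biomass_bounds[2L])

  mets <- unique(unlist(lapply(sto, names)))
  S <- matrix(0, length(mets), length(rxn_id),
              dimnames = list(mets, rxn_id))
  for (j in seq_along(rxn_id)) {
    s <- sto[[rxn_id[j]]]
    S[names(s), j] <- S[names(s), j] + s
  }

  ## coupling rows: IEX - 400 bm <= 0 and -IEX - 400 bm <= 0
  Cp <- matrix(0, 2L * length(coupling_pairs), length(rxn_id),
               dimnames = list(NULL, rxn_id))
  for (i in seq_along(coupling_pairs)) {
    pr <- coupling_pairs[[i]]
    Cp[2L * i - 1L, pr[["iex"]]] <- 1
    Cp[2L * i - 1L, pr[["bm"]]] <- -coupling_coefficient
    Cp[2L * i, pr[["iex"]]] <- -1
    Cp[2L * i, pr[["bm"]]] <- -coupling_coefficient
  }

  structure(list(S = S, lower = rxn_lb, upper = rxn_ub,
                 reactions = rxn_id, metabolites = mets,
                 cm = "communityBiomass", coupling = Cp,
                 coupling_coefficient = coupling_coefficient,
                 abundances = abundances, lumen = lumen,
                 diet_sinks = diet_sinks, fecal_sinks = fecal_sinks,
                 biomass_reactions = bm_ids,
                 biomass_bounds = biomass_bounds),
            class = "community_model")
}

#' @export
print.community_model <- function(x, ...) {
  cat(sprintf("Community model: %d microbes, %d metabolites, %d reactions, %d coupling rows\n",
              length(x$abundances), length(x$metabolites),
              length(x$reactions), nrow(x$coupling)))
  cat("  lumen metabolites:", paste(x$lumen, collapse = ", "), "\n")
  invisible(x)
}

#' Apply diet constraints
#'
#' Sets the lower bound of each diet sink to minus the dietary supply
#' (uptake is a negative diet-sink flux); diet sinks of unsupplied
#' metabolites stay lower-bounded at zero.  Diet entries naming
#' metabolites absent from the lumen are skipped with a warning.
#'
#' @param model a \code{community_model}.
#' @param diet named numeric vector, metabolite id -> supply (>= 0),
#'   mmol/person/day.
#' @return the constrained model.
#' @export
apply_diet <- function(model, diet) {
  stopifnot(inherits(model, "community_model"))
  if (any(diet < 0)) stop("diet supplies must be nonnegative")
  idx <- match(model$diet_sinks, model$reactions)
  model$lower[idx] <- 0
  unknown <- setdiff(names(diet), model$lumen)
  if (length(unknown)) {
    warning("diet metabolites absent from the lumen, skipped: ",
            paste(unknown, collapse = ", "))
    diet <- diet[setdiff(names(diet), unknown)]
  }
  for (x in names(diet)) {
    j <- match(model$diet_sinks[[x]], model$reactions)
    model$lower[j] <- -diet[[x]]
  }
  model$diet <- diet
  model
}

#' Community flux balance analysis
#'
#' Maximises the community biomass flux subject to mass balance, flux
#' bounds and the coupling constraints.
#'
#' @param model a diet-constrained \code{community_model}.
#' @return the optimum \code{w} (invisibly also the full flux vector) as
#'   a list with \code{w} and \code{fluxes}.
#' @export
solve_community_fba <- function(model) {
  stopifnot(inherits(model, "community_model"))
  obj <- as.numeric(model$reactions == model$cm)
  res <- solve_lp(obj, A_eq = model$S, b_eq = rep(0, nrow(model$S)),
                  A_le = model$coupling,
                  b_le = rep(0, nrow(model$coupling)),
                  lower = model$lower, upper = model$upper)
  if (res$status == "infeasible") {
    j <- match(model$cm, model$reactions)
    stop("community FBA infeasible: community biomass must reach ",
         model$lower[j], " but the constraints cannot support it ",
         "(total diet supply ",
         if (is.null(model$diet)) "not applied" else sum(model$diet), ")")
  }
  if (res$status != "optimal")
    stop("community FBA failed: model appears unbounded; check bounds")
  list(w = res$objective,
       fluxes = stats::setNames(res$solution, model$reactions))
}

#' Flux variability of the diet and fecal sinks of one metabolite
#'
#' With the community biomass flux fixed to the FBA optimum \code{w}
#' (both bounds), minimises and maximises the diet-sink and fecal-sink
#' fluxes of the metabolite independently.  Values below 1e-8 in absolute
#' value are reported as zero to keep solver noise out of downstream sign
#' arithmetic.
#'
#' @param model a diet-constrained \code{community_model}.
#' @param metabolite lumen metabolite id.
#' @param w community biomass optimum from
#'   \code{\link{solve_community_fba}}.
#' @return named numeric vector \code{(minDiet, maxDiet, minFaecal,
#'   maxFaecal)}.
#' @export
fva_exchange_bounds <- function(model, metabolite, w) {
  stopifnot(inherits(model, "community_model"))
  if (!metabolite %in% model$lumen)
    stop("metabolite '", metabolite, "' is not present in the lumen")
  jcm <- match(model$cm, model$reactions)

  run4 <- function(w_fix) {
    lower <- model$lower; upper <- model$upper
    lower[jcm] <- w_fix; upper[jcm] <- w
    targets <- c(model$diet_sinks[[metabolite]],
                 model$fecal_sinks[[metabolite]])
    out <- numeric(4L); k <- 0L
    for (t in targets) {
      obj <- as.numeric(model$reactions == t)
      for (maxi in c(FALSE, TRUE)) {
        k <- k + 1L
        r <- solve_lp(obj, A_eq = model$S, b_eq = rep(0, nrow(model$S)),
                      A_le = model$coupling,
                      b_le = rep(0, nrow(model$coupling)),
                      lower = lower, upper = upper, maximize = maxi)
        if (r$status != "optimal") return(NULL)
        out[k] <- r$objective
      }
    }
    out
  }
  vals <- run4(w)
  if (is.null(vals)) vals <- run4(w * (1 - 1e-6))   # numerical relaxation
  if (is.null(vals))
    stop("FVA infeasible for metabolite '", metabolite,
         "' even after relaxing the biomass fixing")
  vals[abs(vals) < 1e-8] <- 0
  stats::setNames(vals, c("minDiet", "maxDiet", "minFaecal", "maxFaecal"))
}

#' Net production and uptake capacity of a metabolite
#'
#' \code{maxProd = |maxFaecal + minDiet|}: the maximal fecal secretion
#' beyond what dietary uptake supplies (diet uptake being a negative
#' diet-sink flux).  \code{maxUpt = |minFaecal + maxDiet|}.
#'
#' @param minDiet,maxDiet,minFaecal,maxFaecal sink flux ranges, either as
#'   four scalars or a single named vector in \code{minDiet}.
#' @return named vector \code{(maxProd, maxUpt)}.
#' @export
net_secretion_capacity <- function(minDiet, maxDiet = NULL,
                                   minFaecal = NULL, maxFaecal = NULL) {
  if (is.null(maxDiet)) {
    v <- minDiet
    minDiet <- v[["minDiet"]]; maxDiet <- v[["maxDiet"]]
    minFaecal <- v[["minFaecal"]]; maxFaecal <- v[["maxFaecal"]]
  }
  if (minDiet > maxDiet || minFaecal > maxFaecal)
    stop("flux ranges must satisfy min <= max")
  c(maxProd = abs(maxFaecal + minDiet),
    maxUpt = abs(minFaecal + maxDiet))
}

#' Per-sample community net-secretion flux profiles
#'
#' Builds one community model per sample from its relative abundances
#' (zero-abundance microbes excluded), applies the same diet to every
#' sample, solves community FBA and runs per-metabolite FVA of the diet
#' and fecal sinks, returning the matrix of maximal net production
#' capacities (maxProd) together with per-sample model statistics.
#' Samples whose model fails are dropped with a warning, never aborting
#' the population run.
#'
#' @param abundance_table samples x species matrix, rows summing to ~1.
#' @param reconstructions named list of \code{reconstruction}s.
#' @param diet named supply vector (see \code{\link{apply_diet}}).
#' @param metabolites lumen metabolites to profile (default: all present
#'   in each sample's lumen; the output is the union, absent ones 0).
#' @param config a \code{\link{run_config}} (coupling coefficient and
#'   biomass bounds are taken from it).
#' @return list with \code{flux} (samples x metabolites maxProd matrix)
#'   and \code{stats} (data.frame: sample, n_reactions, n_metabolites, w).
#' @export
population_flux_profiles <- function(abundance_table, reconstructions, diet,
                                     metabolites = NULL,
                                     config = run_config()) {
  abundance_table <- as.matrix(abundance_table)
  samples <- rownames(abundance_table)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(abundance_table)))
  flux_rows <- list(); stats_rows <- list()
  for (i in seq_len(nrow(abundance_table))) {
    sid <- samples[i]
    res <- tryCatch({
      ab <- stats::setNames(as.numeric(abundance_table[i, ]),
                            colnames(abundance_table))
      model <- build_community_model(
        ab, reconstructions,
        coupling_coefficient = config$coupling_coefficient,
        biomass_bounds = config$biomass_bounds)
      model <- suppressWarnings(apply_diet(model, diet))
      w <- solve_community_fba(model)$w
      mets <- if (is.null(metabolites)) model$lumen else
        intersect(metabolites, model$lumen)
      prod <- vapply(mets, function(x)
        net_secretion_capacity(fva_exchange_bounds(model, x, w))[["maxProd"]],
        numeric(1))
      list(prod = prod,
           stats = data.frame(sample = sid,
                              n_reactions = length(model$reactions),
                              n_metabolites = length(model$metabolites),
                              w = w, stringsAsFactors = FALSE))
    }, error = function(e) {
      warning("sample '", sid, "' dropped: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (!is.null(res)) {
      flux_rows[[sid]] <- res$prod
      stats_rows[[sid]] <- res$stats
    }
  }
  if (!length(flux_rows))
    stop("all samples failed community modeling")
  all_mets <- sort(unique(unlist(lapply(flux_rows, names))))
  flux <- t(vapply(flux_rows, function(v) {
    out <- stats::setNames(numeric(length(all_mets)), all_mets)
    out[names(v)] <- v
    out
  }, numeric(length(all_mets))))
  list(flux = flux, stats = do.call(rbind, c(stats_rows,
                                             make.row.names = FALSE)))
}
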