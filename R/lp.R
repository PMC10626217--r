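## Dense two-phase simplex solver for the toy-scale linear programs of
## community flux balance / variability analysis.  Written in-package
## because no robust LP interface is available among the declared
## dependencies; problems here have tens of variables, where a dense
## tableau with Bland's anti-cycling rule is entirely adequate and
## numerically transparent.

#' Solve a bounded linear program
#'
#' Optimises \eqn{c^T v} subject to \eqn{A_{eq} v = b_{eq}},
#' \eqn{A_{le} v \le b_{le}} and box bounds \eqn{vl \le v \le vu}.
#' Variables are shifted to the nonnegative orthant internally, so lower
#' bounds must be finite; infinite upper bounds are capped at \code{big}.
#' The two-phase tableau simplex uses Bland's rule, which cannot cycle,
#' with pivot tolerance \code{tol}.
#'
#' @param obj numeric objective coefficients, length n.
#' @param A_eq,b_eq equality constraints (matrix may be NULL).
#' @param A_le,b_le inequality constraints \code{A_le v <= b_le}.
#' @param lower,upper box bounds, length n, lower finite.
#' @param maximize logical; maximise (default) or minimise.
#' @param big cap applied to infinite upper bounds.
#' @param tol feasibility / pivot tolerance.
#' @return list with \code{status} ("optimal" or "infeasible"),
#'   \code{objective} and \code{solution} (the flux vector v).
#' @keywords internal
solve_lp <- function(obj, A_eq = NULL, b_eq = NULL, A_le = NULL, b_le = NULL,
                     lower, upper, maximize = TRUE, big = 1e6, tol = 1e-9) {
  n <- length(obj)
  stopifnot(length(lower) == n, length(upper) == n)
  if (any(!is.finite(lower)))
    stop("solve_lp() requires finite lower bounds")
  upper <- pmin(upper, big)
  if (any(upper < lower - tol))
    return(list(status = "infeasible", objective = NA_real_, solution = NULL))

  ## shift x = v - lower, x >= 0; upper bounds become <= rows
  width <- upper - lower
  A1 <- diag(n); b1 <- width
  if (!is.null(A_le) && NROW(A_le) > 0) {
    A1 <- rbind(A1, A_le)
    b1 <- c(b1, b_le - as.numeric(A_le %*% lower))
  }
  A3 <- NULL; b3 <- NULL
  if (!is.null(A_eq) && NROW(A_eq) > 0) {
    A3 <- unname(as.matrix(A_eq))
    b3 <- b_eq - as.numeric(A_eq %*% lower)
  }

  res <- simplex_two_phase(obj, A1, b1, A3, b3, maximize = maximize,
                           tol = tol)
  if (res$status != "optimal")
    return(list(status = res$status, objective = NA_real_, solution = NULL))
  v <- res$x + lower
  list(status = "optimal", objective = sum(obj * v), solution = v)
}

## maximise/minimise c'x, A1 x <= b1, A3 x = b3, x >= 0
simplex_two_phase <- function(cc, A1, b1, A3 = NULL, b3 = NULL,
                              maximize = TRUE, tol = 1e-9) {
  n <- length(cc)
  A1 <- unname(as.matrix(A1))
  ## normalise all rows to rhs >= 0
  neg <- b1 < 0
  sl_sign <- ifelse(neg, -1, 1)         # slack coefficient after flip
  A1[neg, ] <- -A1[neg, , drop = FALSE]
  b1[neg] <- -b1[neg]
  m1 <- length(b1)
  m3 <- 0L
  if (!is.null(A3)) {
    neg3 <- b3 < 0
    A3[neg3, ] <- -A3[neg3, , drop = FALSE]
    b3[neg3] <- -b3[neg3]
    m3 <- length(b3)
  }
  m <- m1 + m3

  ## columns: x (n) | slacks (m1) | artificials (m1 flipped rows + m3)
  need_art1 <- sl_sign < 0              # flipped <= rows need artificials
  n_art <- sum(need_art1) + m3
  Ncol <- n + m1 + n_art
  Tb <- matrix(0, m, Ncol)
  Tb[seq_len(m1), seq_len(n)] <- A1
  if (m3) Tb[m1 + seq_len(m3), seq_len(n)] <- A3
  for (i in seq_len(m1)) Tb[i, n + i] <- sl_sign[i]
  art_cols <- integer(0)
  basis <- integer(m)
  k <- 0L
  for (i in seq_len(m1)) {
    if (need_art1[i]) {
      k <- k + 1L
      Tb[i, n + m1 + k] <- 1
      basis[i] <- n + m1 + k
      art_cols <- c(art_cols, n + m1 + k)
    } else basis[i] <- n + i
  }
  for (i in seq_len(m3)) {
    k <- k + 1L
    Tb[m1 + i, n + m1 + k] <- 1
    basis[m1 + i] <- n + m1 + k
    art_cols <- c(art_cols, n + m1 + k)
  }
  rhs <- c(b1, b3)

  pivot <- function(Tb, rhs, basis, r, s) {
    piv <- Tb[r, s]
    Tb[r, ] <- Tb[r, ] / piv
    rhs[r] <- rhs[r] / piv
    for (i in seq_len(nrow(Tb))) {
      if (i != r && abs(Tb[i, s]) > 0) {
        f <- Tb[i, s]
        Tb[i, ] <- Tb[i, ] - f * Tb[r, ]
        rhs[i] <- rhs[i] - f * rhs[r]
      }
    }
    basis[r] <- s
    list(Tb = Tb, rhs = rhs, basis = basis)
  }

  run_phase <- function(Tb, rhs, basis, cost, allowed, tol) {
    repeat {
      ## reduced costs (minimisation): z_j - c_j with z from basis costs
      cb <- cost[basis]
      red <- as.numeric(cb %*% Tb) - cost
      red[basis] <- 0
      enter <- which(allowed & red > tol)
      if (!length(enter)) return(list(Tb = Tb, rhs = rhs, basis = basis,
                                      status = "optimal"))
      s <- enter[1L]                     # Bland: lowest index
      col <- Tb[, s]
      pos <- which(col > tol)
      if (!length(pos)) return(list(Tb = Tb, rhs = rhs, basis = basis,
                                    status = "unbounded"))
      ratio <- rhs[pos] / col[pos]
      r <- pos[ratio == min(ratio)]
      r <- r[which.min(basis[r])]        # Bland tie-break
      st <- pivot(Tb, rhs, basis, r, s)
      Tb <- st$Tb; rhs <- st$rhs; basis <- st$basis
    }
  }

  ## phase 1: minimise artificial sum
  if (n_art > 0) {
    cost1 <- numeric(Ncol); cost1[art_cols] <- 1
    allowed <- rep(TRUE, Ncol)
    st <- run_phase(Tb, rhs, basis, cost1, allowed, tol)
    Tb <- st$Tb; rhs <- st$rhs; basis <- st$basis
    obj1 <- sum(cost1[basis] * rhs)
    if (obj1 > 1e-7)
      return(list(status = "infeasible"))
    ## pivot remaining artificials (at zero) out of the basis if possible
    for (r in which(basis %in% art_cols)) {
      s <- which(abs(Tb[r, seq_len(n + m1)]) > tol)[1L]
      if (!is.na(s)) {
        st <- pivot(Tb, rhs, basis, r, s)
        Tb <- st$Tb; rhs <- st$rhs; basis <- st$basis
      }
    }
  }

  ## phase 2 on the original objective (as minimisation)
  cost2 <- numeric(Ncol)
  cost2[seq_len(n)] <- if (maximize) -cc else cc
  allowed <- rep(TRUE, Ncol); allowed[art_cols] <- FALSE
  st <- run_phase(Tb, rhs, basis, cost2, allowed, tol)
  if (st$status == "unbounded") return(list(status = "unbounded"))
  Tb <- st$Tb; rhs <- st$rhs; basis <- st$basis
  x <- numeric(n)
  in_x <- basis <= n
  x[basis[in_x]] <- rhs[in_x]
  list(status = "optimal", x = x)
}
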