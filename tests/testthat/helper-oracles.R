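## Independent oracles, implemented from first principles and kept free of
## the package code paths they check.

## OLS + HC1 sandwich from the normal equations
ols_hc1_oracle <- function(y, X) {
  n <- nrow(X); k <- ncol(X)
  XtXi <- solve(t(X) %*% X)
  beta <- XtXi %*% t(X) %*% y
  e <- as.numeric(y - X %*% beta)
  meat <- t(X) %*% diag(e^2) %*% X
  vc <- (n / (n - k)) * XtXi %*% meat %*% XtXi
  se <- unname(sqrt(diag(vc)))
  tval <- as.numeric(beta) / se
  list(beta = as.numeric(beta), se = se,
       p = unname(2 * pt(-abs(tval), df = n - k)))
}

## Benjamini-Hochberg step-up by its definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

## all permutations of 1..n, one per row (recursive, independent of the
## package's internal enumerator)
perms_oracle <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- perms_oracle(n - 1L)
    cbind(k, matrix(setdiff(seq_len(n), k)[rest], nrow(rest), n - 1L))
  }))
}

## exhaustive vertex enumeration of {v : S v = 0, A v <= b, lb <= v <= ub};
## optimum of c'v over vertices equals the LP optimum for bounded feasible
## problems
lp_vertex_oracle <- function(obj, S, A = NULL, b = NULL, lb, ub,
                             extra_eq = NULL, extra_rhs = NULL,
                             tol = 1e-7) {
  n <- length(obj)
  Eq <- S; rhs_eq <- rep(0, nrow(S))
  if (!is.null(extra_eq)) {
    Eq <- rbind(Eq, extra_eq)
    rhs_eq <- c(rhs_eq, extra_rhs)
  }
  ## inequality rows: A v <= b, v <= ub, -v <= -lb
  In <- rbind(if (!is.null(A)) A else NULL, diag(n), -diag(n))
  rhs_in <- c(if (!is.null(b)) b else NULL, ub, -lb)
  r_eq <- qr(Eq)$rank
  need <- n - r_eq
  if (need < 0) stop("over-determined equality system")
  vals <- c()
  for (comb in utils::combn(nrow(In), need, simplify = FALSE)) {
    M <- rbind(Eq, In[comb, , drop = FALSE])
    r <- c(rhs_eq, rhs_in[comb])
    qrM <- qr(M)
    if (qrM$rank < n) next
    v <- qr.coef(qrM, r)
    if (any(is.na(v))) next
    if (max(abs(Eq %*% v - rhs_eq)) > tol) next
    if (any(In %*% v - rhs_in > tol)) next
    vals <- c(vals, sum(obj * v))
  }
  if (!length(vals)) return(NULL)
  c(min = min(vals), max = max(vals))
}
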