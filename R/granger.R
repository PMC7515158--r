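# State-space multivariate Granger causality.
#
# A fitted VAR(p) is put in innovations state-space form
#   z_{t+1} = A z_t + K e_t,   y_t = C z_t + e_t,
# with z_t the stacked lags, A the companion matrix, C the coefficient block
# row and K = [I; 0]. Removing a source node i leaves a state-space model
# whose observations are the remaining nodes; its innovation covariance V_R
# follows from the discrete algebraic Riccati equation (DARE) of that
# sub-process, so no reduced VAR is ever refit. Conditional GC from i to j
# given the rest is then ln(V_R[j,j] / V[j,j]) in nats.

# Solve the filtering DARE
#   P = A P A' + Q - (A P C' + S) (C P C' + R)^{-1} (A P C' + S)'
# by fixed-point iteration from P = Q (converges for the stable A produced by
# stationary VAR fits).
solve_dare <- function(a, cc, q, r, s, tol = 1e-11, max_iter = 5000L) {
  p <- q
  at <- t(a)
  cct <- t(cc)
  for (it in seq_len(max_iter)) {
    apc <- a %*% p %*% cct + s
    gain <- apc %*% solve(cc %*% p %*% cct + r, t(apc))
    p_new <- a %*% p %*% at + q - gain
    p_new <- (p_new + t(p_new)) / 2
    if (max(abs(p_new - p)) < tol * max(1, max(abs(p_new)))) {
      return(p_new)
    }
    p <- p_new
  }
  NULL
}

#' Multivariate Granger causality matrix (state-space form)
#'
#' Conditional Granger causality from every node to every other node given
#' all remaining nodes, from a single full-model VAR fit. Reduced-model
#' innovation variances are obtained by solving the discrete algebraic
#' Riccati equation of the sub-process state-space model obtained by dropping
#' the source node's observations — no reduced VAR is refit. Values are in
#' nats (natural log of the innovation-variance ratio); negative numerical
#' estimates are clipped to zero.
#'
#' @param record One scan: a T x N series matrix or a one-row cohort tibble
#'   (standardized series).
#' @param order VAR lag order (see [select_var_order()]).
#' @return Directed `connectivity_matrix`; entry `[i, j]` is the causality
#'   from node i to node j.
#' @export
granger_matrix <- function(record, order) {
  y <- scan_series(record)
  fit <- fit_var(y, order)
  n <- ncol(y); p <- fit$order
  a <- companion_matrix(fit$coefficients)
  cc <- matrix(a[seq_len(n), ], n) # coefficient block row: y_t = C z_t + e_t
  k <- rbind(diag(n), matrix(0, n * (p - 1L), n))
  v <- fit$innovation_covariance
  q <- k %*% v %*% t(k)
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    keep <- setdiff(seq_len(n), i)
    cr <- cc[keep, , drop = FALSE]
    sol <- solve_dare(a, cr, q, v[keep, keep, drop = FALSE],
                      k %*% v[, keep, drop = FALSE])
    if (is.null(sol)) {
      abort(sprintf("Riccati iteration did not converge for the model excluding node %d", i))
    }
    vr <- diag(cr %*% sol %*% t(cr) + v[keep, keep, drop = FALSE])
    w[i, keep] <- log(vr / diag(v)[keep])
  }
  w[w < 0] <- 0
  diag(w) <- 0
  prov <- scan_provenance(record)
  connectivity_matrix(w, "gc", prov$subject_id, prov$scan_position)
}

#' Granger causality by explicit dual regression (reference route)
#'
#' Fits, for every excluded source, a reduced VAR on the remaining nodes and
#' compares innovation variances with the full fit. Kept as an independent
#' cross-check of [granger_matrix()]. The reduced sub-process is a VARMA, so
#' the reduced VAR is fit at a higher order (`reduced_order`, default
#' `max(4 * order, 30)`) to keep the truncation bias negligible.
#'
#' @inheritParams granger_matrix
#' @param reduced_order Lag order of the reduced fits.
#' @return Directed `connectivity_matrix` (method tag `"gc"`).
#' @export
granger_matrix_dual <- function(record, order, reduced_order = NULL) {
  y <- scan_series(record)
  n <- ncol(y)
  reduced_order <- reduced_order %||% max(4L * order, 30L)
  full <- fit_var(y, order)
  v <- diag(full$innovation_covariance)
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    keep <- setdiff(seq_len(n), i)
    red <- fit_var(y[, keep, drop = FALSE], reduced_order)
    w[i, keep] <- log(diag(red$innovation_covariance) / v[keep])
  }
  w[w < 0] <- 0
  diag(w) <- 0
  prov <- scan_provenance(record)
  connectivity_matrix(w, "gc", prov$subject_id, prov$scan_position)
}
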