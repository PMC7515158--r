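#' Construct a connectivity matrix
#'
#' Light S3 wrapper around an `N x N` nonnegative weight matrix with the
#' estimator tag and directedness recorded. The diagonal is always zero;
#' undirected estimators (`pearson`, `partial`) must be symmetric, directed
#' ones (`gc`, `te`) need not be.
#'
#' @param weights N x N numeric matrix, nonnegative, zero diagonal.
#' @param method One of `"pearson"`, `"partial"`, `"gc"`, `"te"`.
#' @param subject_id,scan_position Optional provenance.
#' @return A `connectivity_matrix` object.
#' @export
connectivity_matrix <- function(weights, method, subject_id = NA_character_,
                                scan_position = NA_integer_) {
  method <- match.arg(method, c("pearson", "partial", "gc", "te"))
  directed <- method %in% c("gc", "te")
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) abort("weights must be square")
  if (any(!is.finite(weights))) abort("weights contain non-finite values")
  if (any(weights < 0)) abort("weights must be nonnegative")
  if (any(diag(weights) != 0)) abort("diagonal must be zero")
  if (!directed && !isTRUE(all.equal(weights, t(weights), tolerance = 1e-12))) {
    abort(sprintf("%s matrices must be symmetric", method))
  }
  structure(weights,
    method = method, directed = directed,
    subject_id = subject_id, scan_position = as.integer(scan_position),
    class = c("connectivity_matrix", "matrix", "array")
  )
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf(
    "<connectivity_matrix> %s (%s), %d nodes\n",
    attr(x, "method"), if (attr(x, "directed")) "directed" else "undirected",
    nrow(x)
  ))
  print(unclass(x)[, ], ...)
  invisible(x)
}

#' Is a connectivity matrix directed?
#' @param x A `connectivity_matrix`.
#' @return Logical flag.
#' @export
is_directed <- function(x) isTRUE(attr(x, "directed"))

#' Estimator tag of a connectivity matrix
#' @param x A `connectivity_matrix`.
#' @return `"pearson"`, `"partial"`, `"gc"` or `"te"`.
#' @export
conn_method <- function(x) attr(x, "method")

# Extract and validate one scan's series matrix from scan-row arguments.
scan_series <- function(record) {
  if (is.matrix(record)) return(record)
  if (is.data.frame(record) && "series" %in% names(record)) {
    if (nrow(record) != 1) abort("expected a single scan row")
    return(record$series[[1]])
  }
  abort("record must be a T x N matrix or a one-row cohort tibble")
}

scan_provenance <- function(record) {
  if (is.data.frame(record)) {
    list(subject_id = record$subject_id[[1]],
         scan_position = record$scan_position[[1]])
  } else {
    list(subject_id = NA_character_, scan_position = NA_integer_)
  }
}

# ---- undirected estimators -----------------------------------------------

#' Pearson correlation adjacency matrix
#'
#' Pairwise Pearson correlation with negative correlations clipped to zero and
#' a zero diagonal.
#'
#' @param record One scan: a T x N series matrix or a one-row cohort tibble.
#' @return Undirected `connectivity_matrix` with entries in `[0, 1]`.
#' @export
pearson_matrix <- function(record) {
  y <- scan_series(record)
  if (nrow(y) <= ncol(y)) abort("need more time points than nodes")
  if (any(apply(y, 2, sd) == 0)) abort("zero-variance node series")
  w <- cor(y)
  w[w < 0] <- 0
  diag(w) <- 0
  prov <- scan_provenance(record)
  connectivity_matrix(w, "pearson", prov$subject_id, prov$scan_position)
}

#' Partial correlation adjacency matrix
#'
#' Partial correlation of each node pair conditioned on all remaining nodes,
#' computed from the inverse correlation matrix
#' (`-P[i,j] / sqrt(P[i,i] * P[j,j])`), negatives clipped to zero.
#'
#' @inheritParams pearson_matrix
#' @param ridge Optional nonnegative ridge added to the correlation matrix
#'   diagonal before inversion (0 = plain inverse).
#' @return Undirected `connectivity_matrix` with entries in `[0, 1]`.
#' @export
partial_matrix <- function(record, ridge = 0) {
  y <- scan_series(record)
  if (nrow(y) <= ncol(y)) abort("need more time points than nodes")
  if (any(apply(y, 2, sd) == 0)) abort("zero-variance node series")
  r <- cor(y) + diag(ridge, ncol(y))
  p <- tryCatch(solve(r), error = function(e) {
    abort("correlation matrix is singular; retry with ridge > 0")
  })
  d <- sqrt(diag(p))
  w <- -p / tcrossprod(d)
  w <- (w + t(w)) / 2 # enforce exact symmetry against rounding
  w[w < 0] <- 0
  diag(w) <- 0
  prov <- scan_provenance(record)
  connectivity_matrix(w, "partial", prov$subject_id, prov$scan_position)
}

# ---- VAR fitting & order selection ---------------------------------------

#' Fit a vector autoregression by ordinary least squares
#'
#' Equation-wise OLS with an intercept. The Schwarz (BIC) score is
#' `T_eff * log(det(Sigma_ML)) + n_params * log(T_eff)`.
#'
#' @param record One scan (matrix or one-row cohort tibble).
#' @param order Lag order `p >= 1`.
#' @return A `var_model`: `order`, `coefficients` (p x N x N array,
#'   `[k, i, j]` = effect of node j at lag k on node i), `intercept`,
#'   `innovation_covariance`, `schwarz_score`, `spectral_radius`, `residuals`.
#' @export
fit_var <- function(record, order) {
  y <- scan_series(record)
  n <- ncol(y); tt <- nrow(y); p <- as.integer(order)
  if (p < 1) abort("order must be >= 1")
  t_eff <- tt - p
  if (t_eff <= n * p + 1) abort("series too short for OLS at this order")
  x <- cbind(1, do.call(cbind, lapply(seq_len(p), function(k) {
    y[(p + 1L - k):(tt - k), , drop = FALSE]
  })))
  yt <- y[(p + 1L):tt, , drop = FALSE]
  qx <- qr(x)
  if (qx$rank < ncol(x)) abort("rank-deficient VAR regression")
  b <- qr.coef(qx, yt)             # (1 + N p) x N
  e <- qr.resid(qx, yt)
  sigma_ml <- crossprod(e) / t_eff
  sigma <- crossprod(e) / (t_eff - ncol(x))
  coefs <- array(0, c(p, n, n))
  for (k in seq_len(p)) {
    # rows of b: intercept, then lag-1 block, lag-2 block, ...
    coefs[k, , ] <- t(b[(1L + (k - 1L) * n + 1L):(1L + k * n), , drop = FALSE])
  }
  rho <- spectral_radius(coefs)
  if (rho >= 1) {
    warn(sprintf("fitted VAR is unstable (spectral radius %.3f)", rho))
  }
  structure(list(
    order = p,
    coefficients = coefs,
    intercept = b[1, ],
    innovation_covariance = sigma,
    schwarz_score = t_eff * determinant(sigma_ml)$modulus[1] +
      (n^2 * p + n) * log(t_eff),
    spectral_radius = rho,
    residuals = e,
    n_timepoints = tt
  ), class = "var_model")
}

#' @export
print.var_model <- function(x, ...) {
  cat(sprintf(
    "<var_model> order %d, %d nodes, spectral radius %.3f, BIC %.1f\n",
    x$order, dim(x$coefficients)[2], x$spectral_radius, x$schwarz_score
  ))
  invisible(x)
}

#' Select a VAR order by the median Schwarz criterion
#'
#' Fits every candidate order `1..max_order` to every scan on a common
#' estimation sample (the first `max_order` points are dropped for all
#' candidates so scores are comparable) and returns the order minimizing the
#' median Schwarz (BIC) score across scans.
#'
#' @param records Cohort tibble (one row per scan) or list of series matrices.
#' @param max_order Largest order to try.
#' @return Integer order.
#' @export
select_var_order <- function(records, max_order) {
  if (is.data.frame(records)) {
    series <- records$series
  } else if (is.list(records)) {
    series <- records
  } else {
    series <- list(scan_series(records))
  }
  if (!length(series)) abort("no scans supplied")
  max_order <- as.integer(max_order)
  if (max_order < 1) abort("max_order must be >= 1")
  scores <- vapply(series, function(y) {
    n <- ncol(y); tt <- nrow(y)
    # common sample: model rows max_order+1 .. T for every candidate order
    vapply(seq_len(max_order), function(p) {
      x <- cbind(1, do.call(cbind, lapply(seq_len(p), function(k) {
        y[(max_order + 1L - k):(tt - k), , drop = FALSE]
      })))
      yt <- y[(max_order + 1L):tt, , drop = FALSE]
      e <- qr.resid(qr(x), yt)
      t_eff <- nrow(yt)
      t_eff * determinant(crossprod(e) / t_eff)$modulus[1] +
        (n^2 * p + n) * log(t_eff)
    }, numeric(1))
  }, numeric(max_order))
  med <- apply(matrix(scores, nrow = max_order), 1, median)
  which.min(med)
}
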