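# Shared fixtures and independent oracles for the suite. Oracles are written
# in the most literal form available (naive loops, direct definitions) and
# never share code with the implementation they check.

# Frozen closed-form oracle, computed before the build from the true spectrum
# (Kolmogorov prediction-variance formula, 2^16-point quadrature; Monte-Carlo
# AR(50) Yule-Walker check agreed to 0.0011): conditional GC x -> y of the
# bivariate fixture below.
BIVAR_GC_XY <- 0.3259

# Bivariate VAR(1): x self-coupled 0.9; y self-coupled 0.5, driven by x with
# coefficient 0.4; unit innovations. Coefficients indexed [lag, target, source].
bivar_coefs <- function(coupling = 0.4) {
  a <- array(0, c(1, 2, 2))
  a[1, 1, 1] <- 0.9
  a[1, 2, 2] <- 0.5
  a[1, 2, 1] <- coupling
  a
}

# Stable 5-node VAR(2) with known edges (x1 -> x2 -> x3 chain and x5 -> x4),
# the fixture used for estimator-equivalence checks.
fivenode_coefs <- function() {
  a <- array(0, c(2, 5, 5))
  a[1, , ] <- diag(0.5, 5)
  a[1, 2, 1] <- 0.4
  a[1, 3, 2] <- 0.35
  a[2, , ] <- diag(0.15, 5)
  a[2, 4, 5] <- 0.3
  a
}

# Edges of fivenode_coefs() in connectivity orientation (source, target).
fivenode_edges <- function() {
  cbind(source = c(1, 2, 5), target = c(2, 3, 4))
}

# Stable random VAR(p) coefficients, rescaled to a target spectral radius.
random_stable_coefs <- function(n, p, density = 0.3, radius = 0.7) {
  mask <- matrix(runif(n^2) < density, n, n)
  diag(mask) <- FALSE
  a <- array(0, c(p, n, n))
  for (k in seq_len(p)) {
    m <- matrix(rnorm(n^2, 0, 0.3), n, n) * mask
    diag(m) <- rnorm(n, 0.4 / k, 0.05)
    a[k, , ] <- m
  }
  a * (radius / spectral_radius(a))
}

# Random nonnegative weight matrix with zero diagonal.
random_weights <- function(n, directed = TRUE, density = 0.6) {
  w <- matrix(runif(n^2) * (runif(n^2) < density), n, n)
  if (!directed) w <- (w + t(w)) / 2
  diag(w) <- 0
  w
}

# --- independent oracles ----------------------------------------------------

# Partial correlation by explicit residual regression: regress i and j on all
# other columns, correlate the residuals.
oracle_partial_correlation <- function(y) {
  n <- ncol(y)
  out <- diag(0, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      others <- cbind(1, y[, -c(i, j), drop = FALSE])
      ri <- qr.resid(qr(others), y[, i])
      rj <- qr.resid(qr(others), y[, j])
      out[i, j] <- out[j, i] <- cor(ri, rj)
    }
  }
  out
}

# Metadata-only cohort table (no series); enough for the quadruple machinery.
scan_table <- function(n_subjects) {
  tidyr::crossing(
    subject_id = sprintf("S%04d", seq_len(n_subjects)),
    scan_position = 1:4
  ) |>
    dplyr::mutate(
      session_index = ((scan_position - 1L) %/% 2L) + 1L,
      scan_in_session = ((scan_position - 1L) %% 2L) + 1L,
      tr_seconds = 0.72
    )
}

# Small preprocessed cohort reused across tests (cheap: 5 nodes, T = 300).
tiny_cohort <- function(n_subjects = 4, rng_seed = 42) {
  generate_cohort(cohort_spec(
    n_subjects, n_timepoints = 300, n_nodes = 5, rng_seed = rng_seed
  ))
}

# Synthetic long ND table with exchangeable nodes (null world for the
# Kruskal-Wallis calibration): every (metric, method, node) stream shares one
# distribution.
null_local_nd <- function(n_nodes = 15, n_pairs = 24, pair_kind = "intra") {
  streams <- tidyr::crossing(
    node = seq_len(n_nodes),
    method = c("pearson", "partial", "gc", "te"),
    metric = c("strength", "betweenness", "efficiency", "clustering")
  )
  dplyr::bind_cols(
    streams[rep(seq_len(nrow(streams)), each = n_pairs), ],
    tibble::tibble(
      pair_kind = pair_kind, level = "local_metric",
      value = runif(nrow(streams) * n_pairs, -1, 1)
    )
  )
}
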