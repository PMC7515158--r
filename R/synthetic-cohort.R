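#' Specify a synthetic scan-rescan cohort
#'
#' Describes a cohort that emulates the structure of a four-scan test-retest
#' resting-state design: `n_subjects` subjects, each scanned
#' `n_scans_per_subject` times (2 sessions x 2 scans), each scan a
#' `n_timepoints` x `n_nodes` node time-series matrix sampled every
#' `tr_seconds` seconds. Subjects share a sparse population coupling pattern;
#' each subject perturbs the nonzero coefficients (scale `subject_sd`), and
#' each scan adds a smaller perturbation (scale `scan_jitter_sd`), so that —
#' with the default `scan_jitter_sd = 0.25 * subject_sd` — scans of the same
#' subject are more alike than scans of different subjects.
#'
#' @param n_subjects Number of subjects.
#' @param n_scans_per_subject Scans per subject (>= 2; the variability
#'   machinery assumes 4: two sessions on different days, two scans each).
#' @param n_nodes Number of network nodes (time-series channels).
#' @param n_timepoints Time points per scan.
#' @param tr_seconds Sampling interval (repetition time) in seconds.
#' @param var_order Lag order of the generating vector autoregression.
#' @param population_coupling_density Fraction of off-diagonal directed
#'   couplings present in the population coefficient pattern.
#' @param subject_sd Standard deviation of the subject-level Gaussian
#'   perturbation added to nonzero population coefficients.
#' @param scan_jitter_sd Standard deviation of the scan-level perturbation
#'   added to the subject coefficients; 0 gives identical dynamics across a
#'   subject's scans (only innovations differ).
#' @param innovation_sd Standard deviation of the VAR innovations.
#' @param hrf_enabled If `TRUE`, each simulated node series is convolved with
#'   a canonical double-gamma haemodynamic response sampled at `tr_seconds`
#'   before standardization (exercises the deconvolution stage).
#' @param rng_seed Integer root seed; all randomness in [generate_cohort()]
#'   derives from it.
#'
#' @return A `cohort_spec` list.
#' @seealso [generate_cohort()]
#' @export
#' @examples
#' spec <- cohort_spec(n_subjects = 2, n_timepoints = 200, n_nodes = 5)
cohort_spec <- function(n_subjects,
                        n_scans_per_subject = 4L,
                        n_nodes = 15L,
                        n_timepoints = 1200L,
                        tr_seconds = 0.72,
                        var_order = 2L,
                        population_coupling_density = 0.2,
                        subject_sd = 0.1,
                        scan_jitter_sd = 0.025,
                        innovation_sd = 1,
                        hrf_enabled = FALSE,
                        rng_seed = 1L) {
  spec <- list(
    n_subjects = as.integer(n_subjects),
    n_scans_per_subject = as.integer(n_scans_per_subject),
    n_nodes = as.integer(n_nodes),
    n_timepoints = as.integer(n_timepoints),
    tr_seconds = tr_seconds,
    var_order = as.integer(var_order),
    population_coupling_density = population_coupling_density,
    subject_sd = subject_sd,
    scan_jitter_sd = scan_jitter_sd,
    innovation_sd = innovation_sd,
    hrf_enabled = isTRUE(hrf_enabled),
    rng_seed = as.integer(rng_seed)
  )
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  stopifnot(
    spec$n_subjects >= 1,
    spec$n_scans_per_subject >= 2,
    spec$n_nodes >= 2,
    spec$n_timepoints >= 50,
    spec$tr_seconds > 0,
    spec$var_order >= 1,
    spec$population_coupling_density >= 0,
    spec$population_coupling_density <= 1,
    spec$subject_sd >= 0,
    spec$scan_jitter_sd >= 0,
    spec$innovation_sd > 0
  )
  invisible(spec)
}

# ---- VAR machinery -------------------------------------------------------

#' Companion matrix of a VAR coefficient array
#' @param coefficients `p x N x N` array; `coefficients[k, i, j]` is the
#'   effect of node j at lag k on node i.
#' @return The `Np x Np` companion matrix.
#' @keywords internal
companion_matrix <- function(coefficients) {
  p <- dim(coefficients)[1]
  n <- dim(coefficients)[2]
  m <- matrix(0, n * p, n * p)
  for (k in seq_len(p)) {
    m[seq_len(n), ((k - 1L) * n + 1L):(k * n)] <- coefficients[k, , ]
  }
  if (p > 1) {
    m[(n + 1L):(n * p), seq_len(n * (p - 1L))] <- diag(n * (p - 1L))
  }
  m
}

#' Spectral radius of the companion matrix
#' @inheritParams companion_matrix
#' @return Largest eigenvalue modulus; `< 1` means the VAR is stable.
#' @export
spectral_radius <- function(coefficients) {
  max(Mod(eigen(companion_matrix(coefficients), only.values = TRUE)$values))
}

#' Simulate a stationary VAR process
#'
#' @param coefficients `p x N x N` coefficient array (must be stable).
#' @param n_timepoints Length of the emitted series.
#' @param innovation_sd Innovation standard deviation.
#' @param burn_in Leading samples discarded so the process forgets its zero
#'   initial state.
#' @return `n_timepoints x N` matrix (not standardized).
#' @keywords internal
simulate_var <- function(coefficients, n_timepoints, innovation_sd = 1,
                         burn_in = 200L) {
  if (spectral_radius(coefficients) >= 1) {
    abort("cannot simulate: VAR coefficients are non-stationary (spectral radius >= 1)")
  }
  p <- dim(coefficients)[1]
  n <- dim(coefficients)[2]
  total <- n_timepoints + burn_in + p
  y <- matrix(0, total, n)
  e <- matrix(rnorm(total * n, sd = innovation_sd), total, n)
  a <- lapply(seq_len(p), function(k) coefficients[k, , , drop = TRUE])
  if (n == 1) a <- lapply(a, function(x) matrix(x, 1, 1))
  for (t in (p + 1L):total) {
    v <- e[t, ]
    for (k in seq_len(p)) v <- v + a[[k]] %*% y[t - k, ]
    y[t, ] <- v
  }
  y[(burn_in + p + 1L):total, , drop = FALSE]
}

# Sparse population coefficient array: off-diagonal directed couplings present
# with the given density, self-coupling on every node, magnitudes rescaled so
# the companion spectral radius equals target_radius.
make_population_coefficients <- function(n_nodes, var_order, density,
                                         target_radius = 0.8) {
  mask <- matrix(runif(n_nodes^2) < density, n_nodes, n_nodes)
  diag(mask) <- FALSE
  coefs <- array(0, c(var_order, n_nodes, n_nodes))
  for (k in seq_len(var_order)) {
    m <- matrix(rnorm(n_nodes^2, 0, 0.3), n_nodes, n_nodes) * mask
    diag(m) <- rnorm(n_nodes, mean = 0.4 / k, sd = 0.05)
    coefs[k, , ] <- m * 0.6^(k - 1)
  }
  rho <- spectral_radius(coefs)
  coefs * (target_radius / rho)
}

# Additive Gaussian perturbation on nonzero coefficients with rejection
# resampling (<= max_attempts) to keep the companion spectral radius < bound.
perturb_coefficients <- function(coefficients, sd, bound = 0.97,
                                 max_attempts = 100L) {
  if (sd == 0) return(coefficients)
  nz <- coefficients != 0
  for (attempt in seq_len(max_attempts)) {
    out <- coefficients
    out[nz] <- coefficients[nz] + rnorm(sum(nz), 0, sd)
    if (spectral_radius(out) < bound) return(out)
  }
  abort(sprintf(
    "failed to draw stationary perturbed coefficients in %d attempts (sd = %g)",
    max_attempts, sd
  ))
}

# ---- cohort generation ---------------------------------------------------

#' Generate a synthetic scan-rescan cohort
#'
#' Simulates every scan of every subject from a subject-specific vector
#' autoregression: population coefficients are drawn once (sparse, rescaled to
#' spectral radius 0.8), each subject adds Gaussian noise of scale
#' `subject_sd` on the nonzero coefficients, and each scan adds further noise
#' of scale `scan_jitter_sd` plus fresh innovations. Non-stationary draws are
#' rejection-resampled (up to 100 attempts). Each scan discards a 200-sample
#' burn-in, is optionally convolved with a canonical haemodynamic response,
#' and is standardized per node (zero mean, unit variance).
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per scan — columns `subject_id`,
#'   `session_index`, `scan_in_session`, `scan_position` (1-4 global order),
#'   `tr_seconds`, and `series` (list of T x N matrices) — carrying the ground
#'   truth as attribute `"ground_truth"` (see [ground_truth()]): population
#'   and per-subject coefficient arrays and the true directed edge mask.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(2, n_timepoints = 200, n_nodes = 5))
#' ground_truth(cohort)$true_edge_mask
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  local_seed(spec$rng_seed)
  pop <- make_population_coefficients(
    spec$n_nodes, spec$var_order, spec$population_coupling_density
  )
  subject_ids <- sprintf("S%03d", seq_len(spec$n_subjects))
  subject_coefs <- lapply(seq_len(spec$n_subjects), function(s) {
    perturb_coefficients(pop, spec$subject_sd)
  })
  names(subject_coefs) <- subject_ids
  n_scans <- spec$n_scans_per_subject
  # per-scan seeds fanned out from the root seed (kept below 2^31)
  scan_seeds <- matrix(
    sample.int(.Machine$integer.max, spec$n_subjects * n_scans),
    spec$n_subjects, n_scans
  )
  hrf <- if (spec$hrf_enabled) canonical_hrf(spec$tr_seconds) else NULL

  rows <- vector("list", spec$n_subjects * n_scans)
  idx <- 0L
  for (s in seq_len(spec$n_subjects)) {
    for (sc in seq_len(n_scans)) {
      set.seed(scan_seeds[s, sc])
      coefs <- perturb_coefficients(subject_coefs[[s]], spec$scan_jitter_sd)
      y <- simulate_var(coefs, spec$n_timepoints, spec$innovation_sd)
      if (!is.null(hrf)) y <- apply(y, 2, convolve_hrf, hrf = hrf)
      y <- standardize_matrix(y)
      idx <- idx + 1L
      rows[[idx]] <- tibble::tibble(
        subject_id = subject_ids[s],
        session_index = ((sc - 1L) %/% 2L) + 1L,
        scan_in_session = ((sc - 1L) %% 2L) + 1L,
        scan_position = sc,
        tr_seconds = spec$tr_seconds,
        series = list(y)
      )
    }
  }
  cohort <- dplyr::bind_rows(rows)
  truth <- list(
    population_coefficients = pop,
    subject_coefficients = subject_coefs,
    # coefficients are [lag, target, source]; transpose so the mask follows
    # the connectivity convention: [i, j] TRUE when node i drives node j
    true_edge_mask = t(apply(pop != 0, c(2, 3), any)) & !diag(spec$n_nodes)
  )
  attr(cohort, "ground_truth") <- truth
  attr(cohort, "cohort_spec") <- spec
  cohort
}

#' Ground truth of a synthetic cohort
#'
#' @param cohort Tibble returned by [generate_cohort()].
#' @return List with `population_coefficients` (p x N x N array, indexed
#'   `[lag, target, source]`), `subject_coefficients` (list per subject), and
#'   `true_edge_mask` (N x N logical in connectivity orientation: `[i, j]` is
#'   `TRUE` when node i drives node j).
#' @export
ground_truth <- function(cohort) {
  gt <- attr(cohort, "ground_truth")
  if (is.null(gt)) abort("no ground truth attached; was this cohort generated by generate_cohort()?")
  gt
}

#' Simulate a single scan from explicit VAR coefficients
#'
#' Validation fixture: one multivariate series from exactly the coefficients
#' supplied (no perturbation), deterministic given the seed, standardized.
#'
#' @param coefficients `p x N x N` stable coefficient array.
#' @param n_timepoints Series length.
#' @param innovation_sd Innovation standard deviation.
#' @param rng_seed Integer seed.
#' @param tr_seconds Sampling interval recorded with the scan.
#' @return One-row tibble in the cohort format (see [generate_cohort()]).
#' @export
#' @examples
#' a <- array(0, c(1, 2, 2)); a[1, , ] <- diag(c(0.9, 0.5)); a[1, 2, 1] <- 0.4
#' scan <- generate_var_fixture(a, 300, rng_seed = 7)
generate_var_fixture <- function(coefficients, n_timepoints,
                                 innovation_sd = 1, rng_seed = 1L,
                                 tr_seconds = 0.72) {
  if (spectral_radius(coefficients) >= 1) {
    abort("coefficients are non-stationary (companion spectral radius >= 1)")
  }
  local_seed(rng_seed)
  y <- standardize_matrix(
    simulate_var(coefficients, n_timepoints, innovation_sd)
  )
  tibble::tibble(
    subject_id = "FIX",
    session_index = 1L,
    scan_in_session = 1L,
    scan_position = 1L,
    tr_seconds = tr_seconds,
    series = list(y)
  )
}

# ---- haemodynamic response ----------------------------------------------

#' Canonical double-gamma haemodynamic response
#'
#' Standard two-gamma shape (response peaking near 6 s, undershoot near 16 s,
#' undershoot ratio 1/6) sampled at the scan repetition time.
#'
#' @param tr_seconds Sampling interval.
#' @param duration_seconds Length of the sampled kernel.
#' @return Numeric vector, peak-normalized to 1.
#' @export
canonical_hrf <- function(tr_seconds, duration_seconds = 32) {
  t <- seq(0, duration_seconds, by = tr_seconds)
  h <- dgamma(t, shape = 6, rate = 1) - dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

#' Ranking quality of estimated directed weights against true edges
#'
#' Area under the ROC curve for separating true directed edges from absent
#' ones by the estimated weights (off-diagonal entries only); 0.5 is chance,
#' 1 is perfect ranking.
#'
#' @param weights N x N estimated weight matrix, `[i, j]` = i drives j.
#' @param true_mask N x N logical in the same orientation (see
#'   [ground_truth()]).
#' @return AUC in `[0, 1]`.
#' @export
edge_recovery_auc <- function(weights, true_mask) {
  off <- !diag(nrow(true_mask))
  pos <- weights[true_mask & off]
  neg <- weights[!true_mask & off]
  if (!length(pos) || !length(neg)) abort("need both true and absent edges")
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# Causal convolution with an HRF kernel, preserving series length.
convolve_hrf <- function(x, hrf) {
  n <- length(x)
  m <- nextn(n + length(hrf))
  out <- Re(fft(fft(c(x, rep(0, m - n))) *
                  fft(c(hrf, rep(0, m - length(hrf)))), inverse = TRUE)) / m
  out[seq_len(n)]
}
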