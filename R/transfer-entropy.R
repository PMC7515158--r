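# Multivariate transfer entropy with non-uniform embedding.
#
# For each target node, conditioning terms are selected greedily from the set
# of all nodes' past values at lags 1..max_lag: at each step the candidate
# giving the largest decrease of the conditional entropy of the target's
# present is added, and selection stops when the decrease is not significant
# under a shuffle test. Entropies use the linear-Gaussian estimator
# (conditional entropy = 0.5 * log residual variance of a linear predictor,
# up to constants), which makes transfer entropy equal to half the Granger
# causality on Gaussian data.

#' Multivariate transfer entropy matrix (non-uniform embedding)
#'
#' Greedy non-uniform embedding per target: the candidate set contains the
#' past of every node at lags `1..max_lag`; candidates are added one at a
#' time, always taking the largest conditional-entropy decrease, until that
#' decrease is non-significant under a shuffle test (`n_shuffles` random
#' permutations of the candidate, level `alpha`) or candidates are exhausted.
#' The transfer entropy from source i to target j is the conditional-entropy
#' difference `CE(j | selected terms without i's) - CE(j | all selected
#' terms)` in nats, with entropies from the linear-Gaussian estimator.
#' Negatives are clipped to zero; sources with no selected term contribute 0.
#'
#' @param record One scan: a T x N series matrix or one-row cohort tibble
#'   (standardized series).
#' @param max_lag Maximum lag of candidate past terms.
#' @param n_shuffles Shuffle-test permutations per step.
#' @param alpha Shuffle-test significance level for continuing the embedding.
#' @param max_terms Safety cap on selected terms per target.
#' @param rng_seed Optional seed for the shuffle test (restores the caller's
#'   RNG state on exit).
#' @return Directed `connectivity_matrix`; entry `[i, j]` is the transfer
#'   entropy from node i to node j.
#' @export
transfer_entropy_matrix <- function(record, max_lag = 5, n_shuffles = 100,
                                    alpha = 0.05, max_terms = 30,
                                    rng_seed = NULL) {
  local_seed(rng_seed)
  y <- scan_series(record)
  tt <- nrow(y); n <- ncol(y)
  max_lag <- as.integer(max_lag)
  t_eff <- tt - max_lag
  if (t_eff < 10 * max_lag) abort("series too short for the requested max_lag")
  # candidate design matrix: column (l - 1) * N + i holds node i at lag l
  cand <- do.call(cbind, lapply(seq_len(max_lag), function(l) {
    y[(max_lag + 1L - l):(tt - l), , drop = FALSE]
  }))
  cand <- sweep(cand, 2, colMeans(cand))
  cand_node <- rep(seq_len(n), max_lag)
  w <- matrix(0, n, n)
  selected <- vector("list", n)

  for (j in seq_len(n)) {
    target <- y[(max_lag + 1L):tt, j]
    target <- target - mean(target)
    resid <- target
    ortho <- cand            # candidates orthogonalized against selections
    basis <- matrix(0, t_eff, 0)
    sel <- integer(0)
    repeat {
      norms2 <- colSums(ortho^2)
      usable <- norms2 >= 1e-8 * t_eff
      usable[sel] <- FALSE
      if (!any(usable)) break
      score <- rep(-Inf, length(norms2))
      proj <- crossprod(ortho[, usable, drop = FALSE], resid)
      score[usable] <- proj^2 / norms2[usable]
      pick <- which.max(score)
      rss <- sum(resid^2)
      gain <- score[pick] / rss
      # shuffle test: permute the ORIGINAL candidate column, orthogonalize
      # against the current selection, measure the spurious gain
      orig <- cand[, pick]
      null_gain <- vapply(seq_len(n_shuffles), function(dummy) {
        s <- sample(orig)
        if (ncol(basis) > 0) s <- s - basis %*% crossprod(basis, s)
        sum(s * resid)^2 / (sum(s^2) * rss)
      }, numeric(1))
      if (gain <= quantile(null_gain, 1 - alpha) || length(sel) >= max_terms) break
      sel <- c(sel, pick)
      qvec <- ortho[, pick] / sqrt(norms2[pick])
      basis <- cbind(basis, qvec)
      resid <- resid - qvec * sum(qvec * resid)
      ortho <- ortho - qvec %*% crossprod(qvec, ortho)
    }
    selected[[j]] <- tibble::tibble(node = cand_node[sel],
                                    lag = ((sel - 1L) %/% n) + 1L)
    if (length(sel)) {
      rss_full <- sum(resid^2)
      for (i in setdiff(unique(cand_node[sel]), j)) {
        keep <- sel[cand_node[sel] != i]
        rss_red <- if (length(keep)) {
          sum(qr.resid(qr(cand[, keep, drop = FALSE]), target)^2)
        } else {
          sum(target^2)
        }
        w[i, j] <- 0.5 * log(rss_red / rss_full)
      }
    }
  }
  w[w < 0] <- 0
  diag(w) <- 0
  prov <- scan_provenance(record)
  out <- connectivity_matrix(w, "te", prov$subject_id, prov$scan_position)
  attr(out, "embedding") <- selected
  out
}

#' Selected embedding terms of a transfer-entropy matrix
#'
#' @param x Result of [transfer_entropy_matrix()].
#' @return List (one tibble per target node) of selected `(node, lag)` terms.
#' @export
te_embedding <- function(x) {
  emb <- attr(x, "embedding")
  if (is.null(emb)) abort("no embedding attached; not a transfer-entropy matrix?")
  emb
}

# ---- cohort-level driver ---------------------------------------------------

#' Estimate connectivity matrices for every scan of a cohort
#'
#' Runs the requested estimators on each scan and returns a long tibble of
#' `connectivity_matrix` objects. The VAR order for Granger causality is
#' either fixed or selected once across all scans by the median Schwarz
#' criterion (`order = "auto"`).
#'
#' @param cohort Cohort tibble of preprocessed (standardized) scans.
#' @param methods Subset of `c("pearson", "partial", "gc", "te")`.
#' @param order `"auto"` or a fixed integer VAR order for `gc`.
#' @param max_order Search bound when `order = "auto"`.
#' @param max_lag Maximum lag for `te`.
#' @param rng_seed Seed for the transfer-entropy shuffle tests (fanned out
#'   per scan).
#' @param ridge Ridge for [partial_matrix()].
#' @return Tibble with columns `subject_id`, `scan_position`, `method`,
#'   `conn` (list of `connectivity_matrix`), carrying the selected VAR order
#'   as attribute `"var_order"` when `gc` is requested.
#' @export
estimate_connectivity <- function(cohort,
                                  methods = c("pearson", "partial", "gc", "te"),
                                  order = "auto", max_order = 8L,
                                  max_lag = 5L, rng_seed = 1L, ridge = 0) {
  methods <- match.arg(methods, c("pearson", "partial", "gc", "te"),
                       several.ok = TRUE)
  var_order <- NULL
  if ("gc" %in% methods) {
    var_order <- if (identical(order, "auto")) {
      select_var_order(cohort, max_order)
    } else {
      as.integer(order)
    }
  }
  local_seed(rng_seed)
  te_seeds <- sample.int(.Machine$integer.max, nrow(cohort))
  rows <- purrr::map(seq_len(nrow(cohort)), function(r) {
    rec <- cohort[r, ]
    purrr::map(methods, function(m) {
      cm <- switch(m,
        pearson = pearson_matrix(rec),
        partial = partial_matrix(rec, ridge = ridge),
        gc = granger_matrix(rec, var_order),
        te = transfer_entropy_matrix(rec, max_lag = max_lag,
                                     rng_seed = te_seeds[r])
      )
      tibble::tibble(
        subject_id = rec$subject_id, scan_position = rec$scan_position,
        method = m, conn = list(cm)
      )
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  attr(out, "var_order") <- var_order
  out
}
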