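# The normalized difference (ND) statistic and the balanced intra/inter pair
# sampling scheme. ND is dimensionless and bounded, which lets variability be
# pooled and compared across estimators, metrics and nodes that live on
# entirely different native scales.

#' Normalized difference of two scalars
#'
#' `ND = (a - b) / (a + b)`: a bounded (within `[-1, 1]` for nonnegative
#' inputs), dimensionless asymmetry between two measurements. Both arguments
#' zero gives 0 (identical degenerate measurements register no difference).
#'
#' @param a,b Finite numeric vectors (recycled); sums must be nonnegative.
#' @return `(a - b) / (a + b)`, elementwise.
#' @export
#' @examples
#' nd_scalar(3, 1) # 0.5
nd_scalar <- function(a, b) {
  if (any(!is.finite(a)) || any(!is.finite(b))) abort("inputs must be finite")
  s <- a + b
  if (any(s < 0)) abort("a + b must be nonnegative (metrics in scope are nonnegative)")
  out <- (a - b) / s
  out[s == 0] <- 0
  out
}

#' Normalized difference of two matrices (Frobenius form)
#'
#' Matrix-level ND: the ratio of the squared Frobenius norms of the
#' difference and the sum,
#' `trace((a - b) (a - b)') / trace((a + b) (a + b)')`, which lies in
#' `[0, 1]` for nonnegative matrices. Setting `sqrt = TRUE` returns the ratio
#' of Frobenius distances instead (the square root); the two are monotonically
#' related, so rank-based comparisons are unchanged.
#'
#' @param a,b `connectivity_matrix` objects (same shape and method) or plain
#'   matrices of the same shape.
#' @param sqrt Return the square-rooted (distance-ratio) variant?
#' @return Scalar in `[0, 1]`; 0 when both matrices are zero.
#' @export
#' @examples
#' nd_matrix(matrix(c(0, 0, 2, 0), 2), matrix(c(0, 0, 1, 0), 2)) # 1/9
nd_matrix <- function(a, b, sqrt = FALSE) {
  if (inherits(a, "connectivity_matrix") && inherits(b, "connectivity_matrix")) {
    if (!identical(conn_method(a), conn_method(b))) {
      abort("method mismatch between matrices")
    }
  }
  a <- unclass(a)[, , drop = FALSE]
  b <- unclass(b)[, , drop = FALSE]
  if (!all(dim(a) == dim(b))) abort("shape mismatch between matrices")
  num <- sum((a - b)^2)
  den <- sum((a + b)^2)
  if (den == 0) return(0)
  out <- num / den
  if (sqrt) base::sqrt(out) else out
}

# ---- quadruple construction ------------------------------------------------

quadruple_tbl <- function(quadruple_id, kind, subject_id, scan_position) {
  tibble::tibble(
    quadruple_id = quadruple_id, kind = kind,
    subject_id = subject_id, scan_position = scan_position
  )
}

#' Enumerate intra-subject scan quadruples
#'
#' One quadruple per subject, containing that subject's four scans (scan
#' positions 1-4). Downstream, each quadruple contributes all
#' `choose(4, 2) = 6` scan pairs.
#'
#' @param cohort Cohort tibble (only `subject_id` and `scan_position` are
#'   used, so metadata-only tables work).
#' @return Long tibble (quadruple_id, kind = "intra", subject_id,
#'   scan_position), four rows per quadruple.
#' @export
enumerate_intra_quadruples <- function(cohort) {
  counts <- table(cohort$subject_id)
  bad <- names(counts)[counts != 4]
  if (length(bad)) {
    abort(sprintf(
      "every subject needs exactly 4 scans; offending subject(s): %s",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  subjects <- sort(unique(cohort$subject_id))
  dplyr::bind_rows(purrr::imap(subjects, function(s, i) {
    pos <- sort(cohort$scan_position[cohort$subject_id == s])
    if (!identical(as.integer(pos), 1:4)) {
      abort(sprintf("subject %s does not cover scan positions 1-4", s))
    }
    quadruple_tbl(sprintf("intra_%04d", i), "intra", s, as.integer(pos))
  }))
}

#' Sample balanced inter-subject scan quadruples
#'
#' Each repeat draws four scans from four distinct subjects, sampled without
#' replacement within the repeat, and balanced over scan order: every
#' quadruple contains exactly one first, one second, one third and one fourth
#' scan (controls for habituation effects). Subjects may recur across
#' repeats. Deterministic given the seed.
#'
#' @inheritParams enumerate_intra_quadruples
#' @param n_repeats Number of quadruples to draw.
#' @param rng_seed Integer seed.
#' @return Long tibble (quadruple_id, kind = "inter", subject_id,
#'   scan_position), four rows per quadruple.
#' @export
sample_inter_quadruples <- function(cohort, n_repeats, rng_seed = 1L) {
  subjects <- sort(unique(cohort$subject_id))
  if (length(subjects) < 4) abort("need at least 4 subjects for inter-subject sampling")
  if (n_repeats < 1) abort("n_repeats must be >= 1")
  local_seed(rng_seed)
  dplyr::bind_rows(purrr::map(seq_len(n_repeats), function(r) {
    ss <- sample(subjects, 4)
    quadruple_tbl(sprintf("inter_%04d", r), "inter", ss, sample(1:4))
  }))
}

# ---- ND distribution construction ------------------------------------------

# All 6 unordered pairs within each quadruple, oriented a = earlier scan
# position, b = later.
quadruples_to_pairs <- function(quadruples) {
  pairs_of <- function(q) {
    q <- q[order(q$scan_position), ]
    idx <- combn(4, 2)
    tibble::tibble(
      quadruple_id = q$quadruple_id[1],
      kind = q$kind[1],
      subject_a = q$subject_id[idx[1, ]],
      scan_a = q$scan_position[idx[1, ]],
      subject_b = q$subject_id[idx[2, ]],
      scan_b = q$scan_position[idx[2, ]]
    )
  }
  quadruples |>
    dplyr::group_by(.data$quadruple_id) |>
    dplyr::group_split() |>
    purrr::map(pairs_of) |>
    dplyr::bind_rows()
}

#' Build intra/inter ND distributions
#'
#' For every scan pair of every quadruple, computes one ND value per feature
#' stream: matrix-level ND (Frobenius form, one per estimator), global-metric
#' ND and/or local-metric ND (scalar form, one per estimator x metric
#' (x node)). Scalar pairs are oriented earlier-scan minus later-scan.
#'
#' @param quadruples Output of [enumerate_intra_quadruples()] and/or
#'   [sample_inter_quadruples()] (rows can be concatenated).
#' @param conn_tbl Output of [estimate_connectivity()]; required for
#'   `"matrix"` level.
#' @param metrics_tbl Output of [compute_metrics_cohort()]; required for the
#'   metric levels.
#' @param levels Subset of `c("matrix", "global_metric", "local_metric")`.
#' @return Long tibble of ND values: pair_kind, level, method, metric, node,
#'   value, subject_a, scan_a, subject_b, scan_b.
#' @export
build_nd_distributions <- function(quadruples, conn_tbl = NULL,
                                   metrics_tbl = NULL,
                                   levels = c("matrix", "global_metric",
                                              "local_metric")) {
  levels <- match.arg(levels, c("matrix", "global_metric", "local_metric"),
                      several.ok = TRUE)
  pairs <- quadruples_to_pairs(quadruples)
  out <- list()

  if ("matrix" %in% levels) {
    if (is.null(conn_tbl)) abort("conn_tbl is required for matrix-level ND")
    key <- paste(conn_tbl$subject_id, conn_tbl$scan_position, conn_tbl$method)
    lookup <- stats::setNames(conn_tbl$conn, key)
    methods <- unique(conn_tbl$method)
    out$mat <- dplyr::bind_rows(purrr::map(methods, function(m) {
      ka <- paste(pairs$subject_a, pairs$scan_a, m)
      kb <- paste(pairs$subject_b, pairs$scan_b, m)
      missing <- c(ka, kb)[!(c(ka, kb) %in% names(lookup))]
      if (length(missing)) {
        abort(sprintf("missing connectivity for scan(s): %s",
                      paste(head(unique(missing), 3), collapse = "; ")))
      }
      tibble::tibble(
        pair_kind = pairs$kind, level = "matrix", method = m,
        metric = NA_character_, node = NA_integer_,
        value = purrr::map2_dbl(lookup[ka], lookup[kb], nd_matrix),
        subject_a = pairs$subject_a, scan_a = pairs$scan_a,
        subject_b = pairs$subject_b, scan_b = pairs$scan_b
      )
    }))
  }

  metric_levels <- intersect(levels, c("global_metric", "local_metric"))
  if (length(metric_levels)) {
    if (is.null(metrics_tbl)) abort("metrics_tbl is required for metric-level ND")
    mt <- dplyr::filter(metrics_tbl, .data$level %in% metric_levels)
    mt$node[mt$level == "global_metric"] <- 0L # single join key for globals
    feat_key <- paste(mt$subject_id, mt$scan_position, mt$method,
                      mt$level, mt$metric, mt$node)
    feat <- stats::setNames(mt$value, feat_key)
    streams <- dplyr::distinct(mt, .data$method, .data$level, .data$metric,
                               .data$node)
    out$met <- dplyr::bind_rows(purrr::pmap(
      unname(as.list(streams)),
      function(s_method, s_level, s_metric, s_node) {
        ka <- paste(pairs$subject_a, pairs$scan_a, s_method, s_level, s_metric, s_node)
        kb <- paste(pairs$subject_b, pairs$scan_b, s_method, s_level, s_metric, s_node)
        va <- feat[ka]; vb <- feat[kb]
        if (anyNA(va) || anyNA(vb)) {
          abort(sprintf("missing %s/%s features for some scans referenced by the quadruples",
                        s_method, s_metric))
        }
        tibble::tibble(
          pair_kind = pairs$kind, level = s_level, method = s_method,
          metric = s_metric,
          node = if (s_level == "local_metric") s_node else NA_integer_,
          value = nd_scalar(unname(va), unname(vb)),
          subject_a = pairs$subject_a, scan_a = pairs$scan_a,
          subject_b = pairs$subject_b, scan_b = pairs$scan_b
        )
      }
    ))
  }
  dplyr::bind_rows(out)
}
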