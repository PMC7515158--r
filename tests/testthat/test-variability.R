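test_that("nd_scalar matches hand arithmetic and handles boundaries", {
  expect_equal(nd_scalar(5, 5), 0)
  expect_equal(nd_scalar(1, 0), 1)
  expect_equal(nd_scalar(3, 1), 0.5)
  expect_equal(nd_scalar(0, 0), 0)
  expect_error(nd_scalar(-3, 1), "nonnegative")
  expect_error(nd_scalar(Inf, 1), "finite")
})

test_that("nd_matrix matches hand arithmetic on 2x2 matrices", {
  a <- matrix(c(0, 0, 2, 0), 2)
  b <- matrix(c(0, 0, 1, 0), 2)
  expect_equal(nd_matrix(a, b), 1 / 9) # (2-1)^2 / (2+1)^2
  expect_equal(nd_matrix(a, a), 0)
  expect_equal(nd_matrix(a, matrix(0, 2, 2)), 1)
  expect_equal(nd_matrix(matrix(0, 2, 2), matrix(0, 2, 2)), 0)
  expect_equal(nd_matrix(a, b, sqrt = TRUE), 1 / 3)
  expect_error(nd_matrix(a, matrix(0, 3, 3)), "shape")
  cm_a <- connectivity_matrix(matrix(0, 2, 2), "gc")
  cm_b <- connectivity_matrix(matrix(0, 2, 2), "te")
  expect_error(nd_matrix(cm_a, cm_b), "method")
})

test_that("ND invariants hold over random inputs", {
  set.seed(71)
  n_cases <- 10000
  a <- runif(n_cases, 0, 10); b <- runif(n_cases, 0, 10)
  cc <- runif(n_cases, 0.1, 10)
  v <- nd_scalar(a, b)
  expect_identical(v, -nd_scalar(b, a))                        # antisymmetry
  expect_equal(nd_scalar(cc * a, cc * b), v, tolerance = 1e-12) # scale invariance
  expect_true(all(abs(v) <= 1))                                 # bounds

  mat_ok <- vapply(seq_len(500), function(i) {
    n <- sample(2:6, 1)
    a <- random_weights(n); b <- random_weights(n); cc <- runif(1, 0.1, 10)
    v <- nd_matrix(a, b)
    identical(v, nd_matrix(b, a)) &&
      abs(nd_matrix(cc * a, cc * b) - v) < 1e-12 &&
      v >= 0 && v <= 1
  }, logical(1))
  expect_true(all(mat_ok))
})

test_that("intra enumeration yields one quadruple per subject with positions 1-4", {
  tbl <- scan_table(10)
  q <- enumerate_intra_quadruples(tbl)
  expect_equal(dplyr::n_distinct(q$quadruple_id), 10)
  expect_equal(nrow(q), 40)
  per <- dplyr::count(q, quadruple_id)
  expect_true(all(per$n == 4))
  expect_error(enumerate_intra_quadruples(tbl[-1, ]), "exactly 4 scans")
})

test_that("inter sampling is balanced, subject-distinct, and deterministic", {
  tbl <- scan_table(20)
  q <- sample_inter_quadruples(tbl, n_repeats = 50, rng_seed = 99)
  expect_equal(dplyr::n_distinct(q$quadruple_id), 50)
  by_quad <- split(q, q$quadruple_id)
  for (g in by_quad) {
    expect_equal(sort(g$scan_position), 1:4)       # balanced over positions
    expect_equal(dplyr::n_distinct(g$subject_id), 4) # distinct subjects
  }
  q2 <- sample_inter_quadruples(tbl, n_repeats = 50, rng_seed = 99)
  expect_identical(q, q2)
  q3 <- sample_inter_quadruples(tbl, n_repeats = 50, rng_seed = 100)
  expect_false(identical(q, q3))
  expect_error(sample_inter_quadruples(scan_table(3), 5), "4 subjects")
})

test_that("ND counting identities hold for every level", {
  cohort <- tiny_cohort(4, rng_seed = 23)
  conn <- estimate_connectivity(cohort, methods = c("pearson", "partial"),
                                rng_seed = 2)
  metrics <- compute_metrics_cohort(conn)
  quads <- dplyr::bind_rows(
    enumerate_intra_quadruples(cohort),
    sample_inter_quadruples(cohort, 4, rng_seed = 31)
  )
  nd <- build_nd_distributions(quads, conn, metrics)
  counts <- dplyr::count(nd, pair_kind, level)
  n_quads <- 4
  # matrix: quadruples x 6 pairs x 2 methods
  expect_equal(counts$n[counts$level == "matrix"],
               rep(n_quads * 6 * 2, 2))
  # global metrics: x 4 metrics
  expect_equal(counts$n[counts$level == "global_metric"],
               rep(n_quads * 6 * 2 * 4, 2))
  # local metrics: x 4 metrics x 5 nodes
  expect_equal(counts$n[counts$level == "local_metric"],
               rep(n_quads * 6 * 2 * 4 * 5, 2))
  # bounds by level
  expect_true(all(nd$value[nd$level == "matrix"] >= 0 &
                    nd$value[nd$level == "matrix"] <= 1))
  expect_true(all(abs(nd$value) <= 1))
  # node ids present exactly for local metrics
  expect_true(all(is.na(nd$node[nd$level != "local_metric"])))
  expect_true(all(!is.na(nd$node[nd$level == "local_metric"])))
})

test_that("identical features across scans give all-zero ND values", {
  cohort <- tiny_cohort(4, rng_seed = 29)
  conn <- estimate_connectivity(cohort, methods = "pearson", rng_seed = 2)
  # overwrite all matrices with one shared matrix
  conn$conn <- rep(conn$conn[1], nrow(conn))
  conn$conn <- purrr::map2(conn$conn, seq_len(nrow(conn)), function(cm, i) {
    attr(cm, "subject_id") <- conn$subject_id[i]
    attr(cm, "scan_position") <- conn$scan_position[i]
    cm
  })
  metrics <- compute_metrics_cohort(conn)
  quads <- dplyr::bind_rows(
    enumerate_intra_quadruples(cohort),
    sample_inter_quadruples(cohort, 2, rng_seed = 3)
  )
  nd <- build_nd_distributions(quads, conn, metrics)
  expect_true(all(nd$value == 0))
})

test_that("missing features for a referenced scan raise an error", {
  cohort <- tiny_cohort(4, rng_seed = 37)
  conn <- estimate_connectivity(cohort, methods = "pearson", rng_seed = 2)
  quads <- enumerate_intra_quadruples(cohort)
  expect_error(
    build_nd_distributions(quads, conn[-1, ], levels = "matrix"),
    "missing connectivity"
  )
})
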