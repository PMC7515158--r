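test_that("unit-weight triangle and path graphs give textbook metrics", {
  tri <- connectivity_matrix(1 - diag(3), "pearson")
  m <- compute_metrics(tri)
  expect_equal(m$local$clustering, rep(1, 3))
  expect_equal(m$global$transitivity, 1)
  expect_equal(m$local$strength, rep(2, 3))

  path <- matrix(0, 3, 3)
  path[1, 2] <- path[2, 1] <- path[2, 3] <- path[3, 2] <- 1
  mp <- compute_metrics(connectivity_matrix(path, "pearson"))
  # ordered-pair accumulation: the middle vertex lies on (1,3) and (3,1)
  expect_equal(mp$local$betweenness, c(0, 2, 0))
  expect_equal(mp$local$clustering, c(0, 0, 0))
})

test_that("betweenness equals exhaustive path enumeration on random 5-node graphs", {
  set.seed(61)
  for (i in 1:20) {
    directed <- i %% 2 == 0
    w <- random_weights(5, directed = directed)
    got <- compute_metrics(connectivity_matrix(
      w, if (directed) "gc" else "pearson"
    ))$local$betweenness
    expect_equal(got, connrep:::brute_force_betweenness(w), tolerance = 1e-10)
  }
})

test_that("all metrics agree with the independent reference routes", {
  set.seed(62)
  w_und <- random_weights(15, directed = FALSE)
  chk_und <- metrics_reference_check(connectivity_matrix(w_und, "partial"))
  expect_true(attr(chk_und, "agrees"))
  expect_true(all(chk_und$max_abs_diff <= 1e-8))

  w_dir <- random_weights(15, directed = TRUE)
  chk_dir <- metrics_reference_check(connectivity_matrix(w_dir, "te"))
  expect_true(attr(chk_dir, "agrees"))
  expect_true(all(chk_dir$max_abs_diff <= 1e-8))
})

test_that("globals are node averages of the locals", {
  set.seed(63)
  m <- compute_metrics(connectivity_matrix(random_weights(8), "gc"))
  expect_equal(m$global$strength, mean(m$local$strength))
  expect_equal(m$global$efficiency, mean(m$local$efficiency))
  expect_equal(m$global$clustering, mean(m$local$clustering))
})

test_that("metrics are permutation-equivariant and scale as documented", {
  set.seed(64)
  w <- random_weights(7)
  cm <- connectivity_matrix(w, "gc")
  m <- compute_metrics(cm)
  perm <- sample(7)
  mp <- compute_metrics(connectivity_matrix(w[perm, perm], "gc"))
  for (col in c("strength", "betweenness", "efficiency", "clustering")) {
    expect_equal(mp$local[[col]], m$local[[col]][perm], tolerance = 1e-10)
  }
  expect_equal(mp$global, m$global, tolerance = 1e-10)

  # scaling: strength scales by c, betweenness ranking and normalized
  # clustering are unchanged
  ms <- compute_metrics(connectivity_matrix(3.7 * w, "gc"))
  expect_equal(ms$local$strength, 3.7 * m$local$strength)
  expect_equal(order(ms$local$betweenness), order(m$local$betweenness))
  expect_equal(ms$local$clustering, m$local$clustering, tolerance = 1e-10)
})

test_that("a symmetric matrix processed as directed doubles strength, keeps clustering", {
  set.seed(65)
  w <- random_weights(6, directed = FALSE)
  und <- compute_metrics(connectivity_matrix(w, "pearson"))
  dir <- compute_metrics(w, directed = TRUE)
  expect_equal(dir$local$strength, 2 * und$local$strength)
  expect_equal(dir$local$clustering, und$local$clustering, tolerance = 1e-10)
  expect_equal(dir$global$transitivity, und$global$transitivity,
               tolerance = 1e-10)
})

test_that("degenerate inputs: isolated nodes get zero local metrics", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 0.5
  m <- compute_metrics(connectivity_matrix(w, "pearson"))
  expect_equal(m$local$strength[3:4], c(0, 0))
  expect_equal(m$local$clustering[3:4], c(0, 0))
  expect_equal(m$local$efficiency[3:4], c(0, 0))
  expect_error(compute_metrics(connectivity_matrix(matrix(-1, 2, 2), "gc")))
})

test_that("tidy/glance reshape metric sets into long and one-row tables", {
  set.seed(66)
  cm <- connectivity_matrix(random_weights(5), "te", subject_id = "S1",
                            scan_position = 2L)
  m <- compute_metrics(cm)
  long <- tidy(m)
  expect_equal(nrow(long), 5 * 4 + 4) # locals + globals
  expect_setequal(unique(long$level), c("local_metric", "global_metric"))
  g <- glance(m)
  expect_equal(nrow(g), 1)
  expect_equal(g$method, "te")
})
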