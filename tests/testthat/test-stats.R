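nd_from_groups <- function(intra, inter) {
  tibble::tibble(
    pair_kind = rep(c("intra", "inter"), c(length(intra), length(inter))),
    level = "matrix", method = "pearson", metric = NA_character_,
    node = NA_integer_, value = c(intra, inter)
  )
}

test_that("effect size is the difference of medians and label swaps flip it", {
  res <- compare_intra_inter(nd_from_groups(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(res$effect_size, 1)
  expect_equal(res$n_intra, 3)
  expect_equal(res$n_inter, 3)

  same <- compare_intra_inter(nd_from_groups(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$effect_size, 0)
  expect_gte(same$p_value, 0.99)

  set.seed(81)
  a <- runif(40); b <- runif(40) + 0.3
  fwd <- compare_intra_inter(nd_from_groups(a, b))
  rev <- compare_intra_inter(nd_from_groups(b, a))
  expect_equal(fwd$effect_size, -rev$effect_size)
  expect_equal(fwd$p_value, rev$p_value)
})

test_that("MWU p-values are invariant under monotone transforms of both samples", {
  set.seed(82)
  a <- rnorm(30); b <- rnorm(30, 0.5)
  shift <- min(a, b) - 1
  p1 <- compare_intra_inter(nd_from_groups(a - shift, b - shift))$p_value
  p2 <- compare_intra_inter(nd_from_groups(exp(a), exp(b)))$p_value
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("MWU type-I error is calibrated under exchangeable groups", {
  set.seed(83)
  rejections <- vapply(seq_len(1000), function(i) {
    x <- rnorm(30); y <- rnorm(30)
    compare_intra_inter(nd_from_groups(x, y))$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.015)
})

test_that("node effect pooling uses 16 streams per node and calibrates under the null", {
  set.seed(84)
  nd <- null_local_nd(n_nodes = 6, n_pairs = 12)
  eff <- node_effect_test(nd, "intra")
  expect_true(all(eff$n_streams$n == 16))
  expect_equal(dplyr::n_distinct(eff$samples$node), 6)

  # p uniform under exchangeable nodes: 200 replicate null tables
  pvals <- vapply(seq_len(200), function(i) {
    node_effect_test(null_local_nd(n_nodes = 8, n_pairs = 6), "intra")$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("node effect test detects a genuinely different node", {
  # rank tests are powerless against pure symmetric scale changes, so the
  # power alternative is a location shift of one node's pooled ND values
  set.seed(85)
  hits <- vapply(seq_len(50), function(i) {
    nd <- null_local_nd(n_nodes = 8, n_pairs = 6)
    idx <- nd$node == 1
    nd$value[idx] <- nd$value[idx] + 0.4
    node_effect_test(nd, "intra")$p_value < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("incomplete stream pooling warns but proceeds", {
  set.seed(86)
  nd <- null_local_nd(n_nodes = 4, n_pairs = 10)
  nd <- dplyr::filter(nd, method != "te") # 12 streams per node
  expect_warning(eff <- node_effect_test(nd, "intra"), "incomplete stream")
  expect_true(all(eff$n_streams$n == 12))
})

test_that("post-hoc pairwise comparisons count pairs and localize the shifted node", {
  set.seed(87)
  samples <- tibble::tibble(
    node = rep(1:5, each = 40),
    value = rnorm(200) + rep(c(1.2, 0, 0, 0, 0), each = 40)
  )
  ph <- posthoc_pairwise(samples)
  expect_equal(nrow(ph), 10) # 5 * 4 / 2
  pm <- attr(ph, "p_matrix")
  expect_equal(pm, t(pm))
  worst <- ph[order(ph$p_value), ][1:4, ]
  expect_true(all(worst$node_a == 1 | worst$node_b == 1))

  # identical distributions: false-positive rate at most nominal
  fp <- vapply(seq_len(100), function(i) {
    s <- tibble::tibble(node = rep(1:2, each = 25), value = rnorm(50))
    posthoc_pairwise(s)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(!fp), 0.94)
  expect_error(posthoc_pairwise(tibble::tibble(node = 1, value = 1)), "2 nodes")
})

test_that("adjustment columns respond to the chosen correction", {
  set.seed(88)
  samples <- tibble::tibble(node = rep(1:4, each = 20), value = rnorm(80))
  raw <- posthoc_pairwise(samples, adjust = "none")
  bonf <- posthoc_pairwise(samples, adjust = "bonferroni")
  expect_equal(raw$p_adjusted, raw$p_value)
  expect_true(all(bonf$p_adjusted >= bonf$p_value))
})

test_that("node significance summary counts significant nodes by ES sign", {
  cmp <- tibble::tibble(
    method = rep("gc", 4), metric = rep("strength", 4), node = 1:4,
    p_value = c(0.01, 0.2, 0.03, 0.5), effect_size = c(0.4, 0.1, -0.2, 0)
  )
  s <- summarize_node_significance(cmp)
  expect_equal(s$n_significant, 2)
  expect_equal(s$n_positive_es, 1)
  expect_equal(s$n_negative_es, 1)
})
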