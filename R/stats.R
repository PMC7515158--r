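# Nonparametric comparison battery for ND distributions: Mann-Whitney U for
# intra vs inter contrasts (effect size = difference of medians), a
# Kruskal-Wallis test for node (anatomical localization) effects on pooled
# local-metric ND, and post-hoc pairwise node comparisons.

mwu_compare <- function(intra, inter) {
  if (!length(intra) || !length(inter)) abort("both groups must be non-empty")
  p <- suppressWarnings(
    wilcox.test(inter, intra, exact = FALSE, correct = TRUE)$p.value
  )
  if (is.nan(p)) p <- 1 # all values tied in both groups
  tibble::tibble(
    p_value = p,
    effect_size = median(inter) - median(intra),
    n_intra = length(intra),
    n_inter = length(inter)
  )
}

#' Compare intra- vs inter-subject ND distributions
#'
#' Two-sided Mann-Whitney U test (normal approximation with tie correction)
#' per contrast, with effect size `ES = median(inter) - median(intra)`.
#' Positive ES means scans of the same subject are more alike than scans of
#' different subjects.
#'
#' @param nd Long ND tibble from [build_nd_distributions()] (or any tibble
#'   with `pair_kind` and `value`).
#' @param by Grouping columns defining one contrast each.
#' @return Tibble with one row per contrast: grouping columns plus `p_value`,
#'   `effect_size`, `n_intra`, `n_inter`.
#' @export
#' @examples
#' nd <- tibble::tibble(
#'   pair_kind = rep(c("intra", "inter"), each = 20), level = "matrix",
#'   method = "pearson", metric = NA, node = NA,
#'   value = c(rnorm(20, 0.1, 0.02), rnorm(20, 0.2, 0.02))
#' )
#' compare_intra_inter(nd)
compare_intra_inter <- function(nd, by = c("level", "method", "metric", "node")) {
  by <- intersect(by, names(nd))
  nd |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_modify(function(g, key) {
      mwu_compare(g$value[g$pair_kind == "intra"],
                  g$value[g$pair_kind == "inter"])
    }) |>
    dplyr::ungroup()
}

#' Test for a node effect on pooled local-metric ND
#'
#' Pools local-metric ND values per node across every estimator x metric
#' stream (4 metrics x 4 estimators = 16 streams per node when all are
#' present; fewer streams trigger a warning, not an error) and runs a
#' Kruskal-Wallis test of the node factor, separately for the given pair
#' kind.
#'
#' @param nd Long ND tibble (must contain local-metric rows).
#' @param pair_kind `"intra"` or `"inter"`.
#' @return List with `statistic`, `df`, `p_value`, `n_streams` (streams per
#'   node), and `samples` (tibble node/value of the pooled samples).
#' @export
node_effect_test <- function(nd, pair_kind = c("intra", "inter")) {
  pair_kind <- match.arg(pair_kind)
  loc <- dplyr::filter(nd, .data$level == "local_metric",
                       .data$pair_kind == !!pair_kind)
  if (!nrow(loc)) abort("no local-metric ND values for this pair kind")
  if (dplyr::n_distinct(loc$node) < 2) abort("need local-metric values for >= 2 nodes")
  streams <- loc |>
    dplyr::distinct(.data$node, .data$method, .data$metric) |>
    dplyr::count(.data$node)
  n_streams <- unique(streams$n)
  if (length(n_streams) > 1 || any(streams$n < 16)) {
    warn(sprintf("incomplete stream pooling: %s streams per node (16 = 4 metrics x 4 estimators)",
                 paste(sort(unique(streams$n)), collapse = "/")))
  }
  kw <- kruskal.test(loc$value, factor(loc$node))
  list(
    statistic = unname(kw$statistic),
    df = unname(kw$parameter),
    p_value = kw$p.value,
    n_streams = streams,
    samples = dplyr::select(loc, "node", "value")
  )
}

#' Post-hoc pairwise node comparisons
#'
#' Two-sided Mann-Whitney tests between all node pairs of the pooled samples
#' (typically run only after a significant [node_effect_test()]).
#'
#' @param samples Tibble with `node` and `value` columns (the `samples`
#'   element of [node_effect_test()]).
#' @param adjust Multiple-testing adjustment for the `p_adjusted` column:
#'   `"none"` (default, mirroring an uncorrected decision rule), `"BH"` or
#'   `"bonferroni"`.
#' @return Tibble (node_a, node_b, p_value, p_adjusted) for all unordered
#'   pairs; the symmetric p-value matrix is attached as attribute
#'   `"p_matrix"`.
#' @export
posthoc_pairwise <- function(samples, adjust = c("none", "BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  nodes <- sort(unique(samples$node))
  if (length(nodes) < 2) abort("need >= 2 nodes for pairwise comparison")
  idx <- combn(length(nodes), 2)
  vals <- split(samples$value, factor(samples$node, levels = nodes))
  p <- vapply(seq_len(ncol(idx)), function(k) {
    suppressWarnings(wilcox.test(vals[[idx[1, k]]], vals[[idx[2, k]]],
                                 exact = FALSE)$p.value)
  }, numeric(1))
  p[is.nan(p)] <- 1
  out <- tibble::tibble(
    node_a = nodes[idx[1, ]], node_b = nodes[idx[2, ]],
    p_value = p, p_adjusted = p.adjust(p, method = adjust)
  )
  pm <- matrix(NA_real_, length(nodes), length(nodes),
               dimnames = list(nodes, nodes))
  pm[cbind(idx[1, ], idx[2, ])] <- p
  pm[cbind(idx[2, ], idx[1, ])] <- p
  diag(pm) <- 1
  attr(out, "p_matrix") <- pm
  out
}

#' Count significant nodes per estimator and metric
#'
#' Summary of local-metric contrasts in the shape of a per-method x per-metric
#' table: how many nodes show a significant intra vs inter difference, split
#' by the sign of the effect size.
#'
#' @param comparisons Output of [compare_intra_inter()] on local-metric ND
#'   (must contain `method`, `metric`, `node`, `p_value`, `effect_size`).
#' @param alpha Significance level.
#' @return Tibble (method, metric, n_nodes, n_significant, n_positive_es,
#'   n_negative_es).
#' @export
summarize_node_significance <- function(comparisons, alpha = 0.05) {
  comparisons |>
    dplyr::filter(!is.na(.data$node)) |>
    dplyr::group_by(.data$method, .data$metric) |>
    dplyr::summarise(
      n_nodes = dplyr::n(),
      n_significant = sum(.data$p_value < alpha),
      n_positive_es = sum(.data$p_value < alpha & .data$effect_size > 0),
      n_negative_es = sum(.data$p_value < alpha & .data$effect_size < 0),
      .groups = "drop"
    )
}
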