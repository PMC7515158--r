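# End-to-end orchestration: simulate or ingest -> preprocess -> connectivity
# -> graph metrics -> ND distributions -> statistics, with every stage output
# written under one directory and hashed into a manifest so identical
# config + seed give identical manifests.

#' Build a pipeline run configuration
#'
#' @param input Either a [cohort_spec()] (synthetic run) or a directory of
#'   scan files (see [read_scans()]).
#' @param methods Estimators to run.
#' @param deconvolve Apply blind haemodynamic deconvolution during
#'   preprocessing.
#' @param check_stationarity Record per-node ADF checks.
#' @param var_order `"auto"` (median-Schwarz selection) or a fixed integer.
#' @param max_order Order-search bound for `"auto"`.
#' @param te_max_lag Maximum lag for the transfer-entropy embedding.
#' @param n_inter_repeats Inter-subject quadruples to draw; default equals
#'   the number of subjects (giving equal intra/inter counts).
#' @param correction Post-hoc multiple-testing adjustment.
#' @param tr_seconds Sampling interval for directory input.
#' @param seed Root seed fanned out to all stochastic stages.
#' @param out_dir Output directory.
#' @return A validated `run_config` list.
#' @export
run_config <- function(input, methods = c("pearson", "partial", "gc", "te"),
                       deconvolve = FALSE, check_stationarity = FALSE,
                       var_order = "auto", max_order = 8L, te_max_lag = 5L,
                       n_inter_repeats = NULL,
                       correction = c("none", "BH", "bonferroni"),
                       tr_seconds = 0.72, seed = 1L, out_dir = tempfile("connrep_run_")) {
  config <- list(
    input = input, methods = methods, deconvolve = isTRUE(deconvolve),
    check_stationarity = isTRUE(check_stationarity), var_order = var_order,
    max_order = as.integer(max_order), te_max_lag = as.integer(te_max_lag),
    n_inter_repeats = n_inter_repeats, correction = match.arg(correction),
    tr_seconds = tr_seconds, seed = as.integer(seed), out_dir = out_dir
  )
  validate_run_config(config)
  structure(config, class = "run_config")
}

#' Validate a run configuration against the schema
#'
#' Checks field presence, types and value domains before any computation.
#'
#' @param config A `run_config` (or plain list with the same fields).
#' @return The config, invisibly; aborts with the offending field otherwise.
#' @export
validate_run_config <- function(config) {
  required <- c("input", "methods", "deconvolve", "var_order", "te_max_lag",
                "correction", "seed", "out_dir")
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    abort(sprintf("config is missing field(s): %s", paste(missing, collapse = ", ")))
  }
  known <- c("pearson", "partial", "gc", "te")
  bad <- setdiff(config$methods, known)
  if (length(bad)) {
    abort(sprintf("unknown method(s): %s (known: %s)",
                  paste(bad, collapse = ", "), paste(known, collapse = ", ")))
  }
  if (!(identical(config$var_order, "auto") ||
        (is.numeric(config$var_order) && config$var_order >= 1))) {
    abort("var_order must be \"auto\" or a positive integer")
  }
  if (!is.numeric(config$te_max_lag) || config$te_max_lag < 1) {
    abort("te_max_lag must be a positive integer")
  }
  if (!config$correction %in% c("none", "BH", "bonferroni")) {
    abort("correction must be one of none/BH/bonferroni")
  }
  if (!(inherits(config$input, "cohort_spec") ||
        (is.character(config$input) && length(config$input) == 1))) {
    abort("input must be a cohort_spec or a directory path")
  }
  invisible(config)
}

#' Read a run configuration from YAML
#'
#' A `cohort` block is interpreted as a [cohort_spec()]; alternatively an
#' `input_dir` entry names a directory of scan files.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  input <- if (!is.null(raw$cohort)) {
    do.call(cohort_spec, raw$cohort)
  } else if (!is.null(raw$input_dir)) {
    raw$input_dir
  } else {
    abort("config must contain a `cohort` block or an `input_dir` entry")
  }
  raw$cohort <- NULL
  raw$input_dir <- NULL
  args <- raw[intersect(names(raw), names(formals(run_config)))]
  do.call(run_config, c(list(input = input), args))
}

run_stage <- function(name, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full variability analysis end-to-end
#'
#' Executes simulate/ingest, preprocessing, connectivity estimation, graph
#' metrics, ND-distribution construction (intra enumeration plus balanced
#' inter sampling) and the statistical battery, writing every stage's output
#' under `config$out_dir` together with the serialized configuration and a
#' manifest of MD5 content hashes. Identical config and seed give an
#' identical manifest.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the stage outputs (`cohort`, `conn`,
#'   `metrics`, `nd`, `comparisons`, `node_effects`, `manifest`).
#' @export
run_all <- function(config) {
  validate_run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_ser <- config
  cfg_ser$out_dir <- NULL # location-independent provenance
  cfg_ser$input <- if (inherits(config$input, "cohort_spec")) {
    c(list(.kind = "cohort_spec"), unclass(config$input))
  } else {
    list(.kind = "directory", path = config$input)
  }
  yaml::write_yaml(cfg_ser, file.path(out_dir, "config.yaml"))
  local_seed(config$seed)
  stage_seeds <- sample.int(.Machine$integer.max, 3)

  cohort <- run_stage("ingest", out_dir, {
    if (inherits(config$input, "cohort_spec")) {
      spec <- config$input
      spec$rng_seed <- stage_seeds[1]
      generate_cohort(spec)
    } else {
      read_scans(config$input, tr_seconds = config$tr_seconds)
    }
  })
  run_stage("ingest", out_dir, write_scans(cohort, file.path(out_dir, "scans")))

  cohort <- run_stage("preprocess", out_dir, preprocess_cohort(
    cohort, deconvolve = config$deconvolve, check = config$check_stationarity
  ))

  conn <- run_stage("connectivity", out_dir, estimate_connectivity(
    cohort, methods = config$methods, order = config$var_order,
    max_order = config$max_order, max_lag = config$te_max_lag,
    rng_seed = stage_seeds[2]
  ))
  run_stage("connectivity", out_dir,
            write_connectivity(conn, file.path(out_dir, "connectivity")))

  metrics <- run_stage("metrics", out_dir, compute_metrics_cohort(conn))
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)

  nd <- run_stage("variability", out_dir, {
    intra <- enumerate_intra_quadruples(cohort)
    n_rep <- config$n_inter_repeats %||% dplyr::n_distinct(cohort$subject_id)
    inter <- sample_inter_quadruples(cohort, n_rep, rng_seed = stage_seeds[3])
    build_nd_distributions(dplyr::bind_rows(intra, inter),
                           conn_tbl = conn, metrics_tbl = metrics)
  })
  utils::write.csv(nd, file.path(out_dir, "nd.csv"), row.names = FALSE)

  report <- run_stage("stats", out_dir, {
    comparisons <- compare_intra_inter(nd)
    node_effects <- purrr::map(c(intra = "intra", inter = "inter"), function(k) {
      eff <- node_effect_test(nd, k)
      post <- if (eff$p_value < 0.05) {
        posthoc_pairwise(eff$samples, adjust = config$correction)
      }
      list(p_value = eff$p_value, statistic = eff$statistic, df = eff$df,
           posthoc = post)
    })
    list(comparisons = comparisons, node_effects = node_effects)
  })
  jsonlite::write_json(
    list(
      comparisons = report$comparisons,
      node_effects = purrr::map(report$node_effects, function(x) {
        x[c("p_value", "statistic", "df")]
      })
    ),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA
  )
  summary_tbl <- summarize_node_significance(report$comparisons)
  utils::write.csv(summary_tbl, file.path(out_dir, "node_significance.csv"),
                   row.names = FALSE)

  files <- sort(list.files(out_dir, recursive = TRUE, full.names = TRUE))
  files <- files[basename(files) != "manifest.json"]
  manifest <- tibble::tibble(
    file = sub(paste0("^", out_dir, "/?"), "", files),
    md5 = unname(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(
    cohort = cohort, conn = conn, metrics = metrics, nd = nd,
    comparisons = report$comparisons, node_effects = report$node_effects,
    summary = summary_tbl, manifest = manifest, out_dir = out_dir
  ))
}
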