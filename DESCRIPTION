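Package: connrep
Title: Scan-Rescan Variability of Directed and Undirected Functional Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies intra- versus inter-subject variability of functional
    connectivity estimates in scan-rescan resting-state fMRI designs. Provides
    four connectivity estimators for node time series (Pearson correlation,
    partial correlation, state-space multivariate Granger causality, and
    multivariate transfer entropy with non-uniform embedding), weighted
    graph-theoretical metrics for the resulting directed and undirected
    networks, a bounded normalized difference (ND) statistic at the matrix,
    global-metric and local-metric levels, balanced intra/inter pair sampling,
    and a nonparametric comparison battery (Mann-Whitney U, Kruskal-Wallis,
    post-hoc pairwise tests). Includes a synthetic scan-rescan cohort
    generator with known ground truth for validation, and an end-to-end
    reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
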