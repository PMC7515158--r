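# Weighted graph metrics, following the conventions of the Brain Connectivity
# Toolbox for weighted directed/undirected matrices: path lengths are
# reciprocal weights, clustering uses cube-rooted weights normalized by the
# matrix maximum (Onnela; Fagiolo generalization for directed graphs),
# betweenness uses Brandes accumulation over ordered node pairs, and the
# "global" metrics are node averages of the local ones (transitivity is a
# separate whole-graph ratio).

# Dijkstra shortest-path distances from one source on a length matrix
# (Inf = no edge). Returns list(dist, nsp) where nsp counts distinct shortest
# paths, and preds, the predecessor sets, for Brandes accumulation.
dijkstra_source <- function(len, src) {
  n <- nrow(len)
  dist <- rep(Inf, n)
  nsp <- numeric(n)
  preds <- vector("list", n)
  dist[src] <- 0
  nsp[src] <- 1
  done <- rep(FALSE, n)
  order_settled <- integer(0)
  repeat {
    u <- which.min(replace(dist, done, Inf))
    if (!length(u) || !is.finite(dist[u])) break
    done[u] <- TRUE
    order_settled <- c(order_settled, u)
    for (v in which(is.finite(len[u, ]) & !done)) {
      alt <- dist[u] + len[u, v]
      if (alt < dist[v] - 1e-12) {
        dist[v] <- alt
        nsp[v] <- nsp[u]
        preds[[v]] <- u
      } else if (abs(alt - dist[v]) <= 1e-12) {
        nsp[v] <- nsp[v] + nsp[u]
        preds[[v]] <- c(preds[[v]], u)
      }
    }
    if (all(done | !is.finite(dist))) break
  }
  list(dist = dist, nsp = nsp, preds = preds, settled = order_settled)
}

length_matrix <- function(w) {
  len <- 1 / w
  len[w == 0] <- Inf
  diag(len) <- Inf
  len
}

# Weighted betweenness centrality, Brandes accumulation over ordered pairs
# (matrices are always treated as digraphs; symmetric input therefore yields
# twice the classic undirected value, matching the toolbox convention).
betweenness_weighted <- function(w) {
  n <- nrow(w)
  len <- length_matrix(w)
  bc <- numeric(n)
  for (s in seq_len(n)) {
    sp <- dijkstra_source(len, s)
    delta <- numeric(n)
    for (v in rev(sp$settled)) {
      for (u in sp$preds[[v]]) {
        delta[u] <- delta[u] + sp$nsp[u] / sp$nsp[v] * (1 + delta[v])
      }
      if (v != s) bc[v] <- bc[v] + delta[v]
    }
  }
  bc
}

# All-pairs inverse shortest-path distances on a length matrix; disconnected
# pairs contribute 0, diagonal 0.
distance_inverse <- function(len) {
  n <- nrow(len)
  out <- matrix(0, n, n)
  for (s in seq_len(n)) {
    d <- dijkstra_source(len, s)$dist
    out[s, ] <- ifelse(is.finite(d) & d > 0, 1 / d, 0)
  }
  diag(out) <- 0
  out
}

# Onnela weighted clustering for undirected graphs; weights pre-normalized by
# the matrix maximum. Nodes of binary degree < 2 get 0.
clustering_onnela <- function(w) {
  wn <- if (max(w) > 0) w / max(w) else w
  cr <- wn^(1 / 3)
  cyc <- diag(cr %*% cr %*% cr)
  k <- rowSums(w > 0)
  denom <- k * (k - 1)
  ifelse(denom > 0, cyc / denom, 0)
}

# Fagiolo directed weighted clustering; counts all directed triangles through
# a node, excluding "false" triangles from bilateral edges.
clustering_fagiolo <- function(w) {
  wn <- if (max(w) > 0) w / max(w) else w
  a <- (w > 0) * 1
  s <- wn^(1 / 3) + t(wn)^(1 / 3)
  cyc <- diag(s %*% s %*% s) / 2
  k_tot <- rowSums(a) + colSums(a)
  k_bil <- diag(a %*% a)
  denom <- k_tot * (k_tot - 1) - 2 * k_bil
  ifelse(denom > 0, cyc / denom, 0)
}

transitivity_weighted <- function(w, directed) {
  wn <- if (max(w) > 0) w / max(w) else w
  a <- (w > 0) * 1
  if (directed) {
    s <- wn^(1 / 3) + t(wn)^(1 / 3)
    num <- sum(diag(s %*% s %*% s)) / 2
    k_tot <- rowSums(a) + colSums(a)
    k_bil <- diag(a %*% a)
    den <- sum(k_tot * (k_tot - 1) - 2 * k_bil)
  } else {
    cr <- wn^(1 / 3)
    num <- sum(diag(cr %*% cr %*% cr))
    k <- rowSums(a)
    den <- sum(k * (k - 1))
  }
  if (den > 0) num / den else 0
}

# Weighted local efficiency (BCT efficiency_wei, local variant): for each
# node, cube-rooted inverse shortest-path distances within its neighborhood,
# on cube-rooted lengths, against the degree-based pair count. Handles both
# directed and undirected input.
local_efficiency_weighted <- function(w) {
  n <- nrow(w)
  a <- (w > 0) * 1
  cr_w <- w^(1 / 3)
  len3 <- length_matrix(w)^(1 / 3) # cube root of reciprocal weights
  eff <- numeric(n)
  for (u in seq_len(n)) {
    nb <- which(w[u, ] > 0 | w[, u] > 0)
    if (length(nb) < 2) next
    sw <- cr_w[u, nb] + cr_w[nb, u]
    e <- distance_inverse(len3[nb, nb, drop = FALSE])
    se <- e + t(e)
    numer <- sum(tcrossprod(sw) * se) / 2
    if (numer > 0) {
      sa <- a[u, nb] + a[nb, u]
      denom <- sum(sa)^2 - sum(sa^2)
      eff[u] <- numer / denom
    }
  }
  eff
}

#' Weighted graph metrics of a connectivity matrix
#'
#' Local metrics per node — strength (undirected: sum of incident weights;
#' directed: in-strength + out-strength), weighted shortest-path betweenness
#' (lengths = 1/weight, all shortest paths counted with multiplicity),
#' weighted local efficiency, and the weighted clustering coefficient
#' (Onnela for undirected, Fagiolo for directed matrices, weights normalized
#' by the matrix maximum) — plus whole-network values: the global strength,
#' efficiency and clustering are the node averages of the local metrics, and
#' transitivity is the ratio of closed weighted triplets to all triplets.
#'
#' @param matrix A `connectivity_matrix` (or plain nonnegative matrix, in
#'   which case `directed` must be given).
#' @param directed Override for plain matrices.
#' @return A `graph_metrics` object: tibble `local` (node, strength,
#'   betweenness, efficiency, clustering), tibble `global` (strength,
#'   efficiency, clustering, transitivity) and provenance fields.
#' @export
#' @examples
#' tri <- connectivity_matrix(1 - diag(3), "pearson")
#' compute_metrics(tri)$global
compute_metrics <- function(matrix, directed = NULL) {
  w <- unclass(matrix)[, , drop = FALSE]
  if (any(!is.finite(w)) || any(w < 0)) {
    abort("weights must be finite and nonnegative")
  }
  if (is.null(directed)) {
    directed <- if (inherits(matrix, "connectivity_matrix")) {
      is_directed(matrix)
    } else {
      abort("supply directed = TRUE/FALSE for plain matrices")
    }
  }
  strength <- if (directed) rowSums(w) + colSums(w) else rowSums(w)
  local <- tibble::tibble(
    node = seq_len(nrow(w)),
    strength = strength,
    betweenness = betweenness_weighted(w),
    efficiency = local_efficiency_weighted(w),
    clustering = if (directed) clustering_fagiolo(w) else clustering_onnela(w)
  )
  global <- tibble::tibble(
    strength = mean(local$strength),
    efficiency = mean(local$efficiency),
    clustering = mean(local$clustering),
    transitivity = transitivity_weighted(w, directed)
  )
  structure(list(
    local = local, global = global, directed = directed,
    method = attr(matrix, "method") %||% NA_character_,
    subject_id = attr(matrix, "subject_id") %||% NA_character_,
    scan_position = attr(matrix, "scan_position") %||% NA_integer_
  ), class = "graph_metrics")
}

#' @export
print.graph_metrics <- function(x, ...) {
  cat(sprintf(
    "<graph_metrics> %s (%s), %d nodes\nglobal:\n",
    x$method, if (x$directed) "directed" else "undirected", nrow(x$local)
  ))
  print(x$global)
  invisible(x)
}

#' @rdname compute_metrics
#' @param x A `graph_metrics` object.
#' @param ... Unused.
#' @return `tidy()`: long tibble (level, metric, node, value) of all local
#'   and global metrics; `glance()`: one-row tibble of the global metrics.
#' @export
tidy.graph_metrics <- function(x, ...) {
  loc <- tidyr::pivot_longer(x$local, -"node",
    names_to = "metric", values_to = "value"
  )
  loc$level <- "local_metric"
  glob <- tidyr::pivot_longer(x$global, dplyr::everything(),
    names_to = "metric", values_to = "value"
  )
  glob$node <- NA_integer_
  glob$level <- "global_metric"
  out <- dplyr::bind_rows(loc, glob)
  out$method <- x$method
  out$subject_id <- x$subject_id
  out$scan_position <- x$scan_position
  dplyr::select(
    out, "subject_id", "scan_position", "method", "level",
    "metric", "node", "value"
  )
}

#' @rdname compute_metrics
#' @export
glance.graph_metrics <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      subject_id = x$subject_id, scan_position = x$scan_position,
      method = x$method, directed = x$directed
    ),
    x$global
  )
}

#' Graph metrics for every connectivity matrix of a cohort
#'
#' @param conn_tbl Output of [estimate_connectivity()].
#' @return Long tidy tibble (subject_id, scan_position, method, level,
#'   metric, node, value).
#' @export
compute_metrics_cohort <- function(conn_tbl) {
  dplyr::bind_rows(purrr::map(conn_tbl$conn, function(cm) {
    tidy(compute_metrics(cm))
  }))
}

#' Cross-check graph metrics against independent reference routes
#'
#' Recomputes every metric through an independent implementation — weighted
#' betweenness and shortest-path distances through the igraph library (if
#' installed), strength/clustering/transitivity/local efficiency through
#' naive summation loops written separately from the vectorized code — and
#' reports the elementwise agreement.
#'
#' @param matrix A `connectivity_matrix`.
#' @param tol Agreement tolerance.
#' @return Tibble (metric, max_abs_diff, agrees); attribute `"agrees"` is the
#'   overall flag.
#' @export
metrics_reference_check <- function(matrix, tol = 1e-8) {
  m <- compute_metrics(matrix)
  w <- unclass(matrix)[, , drop = FALSE]
  directed <- is_directed(matrix)
  ref <- list(
    strength = reference_strength(w, directed),
    betweenness = reference_betweenness(w),
    efficiency = reference_local_efficiency(w),
    clustering = reference_clustering(w, directed)
  )
  rows <- purrr::imap(ref, function(vals, name) {
    d <- max(abs(vals - m$local[[name]]))
    tibble::tibble(metric = name, max_abs_diff = d, agrees = d <= tol)
  })
  d_tr <- abs(reference_transitivity(w, directed) - m$global$transitivity)
  rows$transitivity <- tibble::tibble(
    metric = "transitivity", max_abs_diff = d_tr, agrees = d_tr <= tol
  )
  out <- dplyr::bind_rows(rows)
  attr(out, "agrees") <- all(out$agrees)
  out
}

# --- naive/independent reference routes (loops, no shared code paths) -------

reference_strength <- function(w, directed) {
  n <- nrow(w)
  vapply(seq_len(n), function(i) {
    if (directed) sum(w[i, ]) + sum(w[, i]) else sum(w[i, ])
  }, numeric(1))
}

reference_betweenness <- function(w) {
  if (requireNamespace("igraph", quietly = TRUE)) {
    g <- igraph::graph_from_adjacency_matrix(w, mode = "directed",
                                             weighted = TRUE, diag = FALSE)
    return(igraph::betweenness(g, directed = TRUE,
                               weights = 1 / igraph::E(g)$weight))
  }
  brute_force_betweenness(w)
}

# Exhaustive simple-path enumeration; only for small graphs.
brute_force_betweenness <- function(w) {
  n <- nrow(w)
  len <- length_matrix(w)
  paths_between <- function(s, t) {
    out <- list()
    grow <- function(path, total) {
      u <- path[length(path)]
      if (u == t) {
        out[[length(out) + 1L]] <<- list(path = path, len = total)
        return(invisible(NULL))
      }
      for (v in which(is.finite(len[u, ]))) {
        if (!(v %in% path)) grow(c(path, v), total + len[u, v])
      }
    }
    grow(s, 0)
    out
  }
  bc <- numeric(n)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s == t) next
      ap <- paths_between(s, t)
      if (!length(ap)) next
      lens <- vapply(ap, `[[`, numeric(1), "len")
      shortest <- ap[abs(lens - min(lens)) <= 1e-12]
      for (p in shortest) {
        inner <- setdiff(p$path, c(s, t))
        bc[inner] <- bc[inner] + 1 / length(shortest)
      }
    }
  }
  bc
}

reference_clustering <- function(w, directed) {
  n <- nrow(w)
  wn <- if (max(w) > 0) w / max(w) else w
  out <- numeric(n)
  for (i in seq_len(n)) {
    num <- 0
    if (directed) {
      for (j in seq_len(n)) {
        for (h in seq_len(n)) {
          if (j == i || h == i || j == h) next
          # all 8 directed triangle orientations through i, j, h
          num <- num + (wn[i, j]^(1 / 3) + wn[j, i]^(1 / 3)) *
            (wn[i, h]^(1 / 3) + wn[h, i]^(1 / 3)) *
            (wn[j, h]^(1 / 3) + wn[h, j]^(1 / 3))
        }
      }
      num <- num / 2
      k_tot <- sum(w[i, ] > 0) + sum(w[, i] > 0)
      k_bil <- sum(w[i, ] > 0 & w[, i] > 0)
      den <- k_tot * (k_tot - 1) - 2 * k_bil
    } else {
      for (j in seq_len(n)) {
        for (h in seq_len(n)) {
          if (j == i || h == i || j == h) next
          num <- num + (wn[i, j] * wn[i, h] * wn[j, h])^(1 / 3)
        }
      }
      k <- sum(w[i, ] > 0)
      den <- k * (k - 1)
    }
    out[i] <- if (den > 0) num / den else 0
  }
  out
}

reference_transitivity <- function(w, directed) {
  n <- nrow(w)
  wn <- if (max(w) > 0) w / max(w) else w
  num <- 0; den <- 0
  for (i in seq_len(n)) {
    if (directed) {
      for (j in seq_len(n)) {
        for (h in seq_len(n)) {
          if (j == i || h == i || j == h) next
          num <- num + (wn[i, j]^(1 / 3) + wn[j, i]^(1 / 3)) *
            (wn[i, h]^(1 / 3) + wn[h, i]^(1 / 3)) *
            (wn[j, h]^(1 / 3) + wn[h, j]^(1 / 3)) / 2
        }
      }
      k_tot <- sum(w[i, ] > 0) + sum(w[, i] > 0)
      k_bil <- sum(w[i, ] > 0 & w[, i] > 0)
      den <- den + k_tot * (k_tot - 1) - 2 * k_bil
    } else {
      for (j in seq_len(n)) {
        for (h in seq_len(n)) {
          if (j == i || h == i || j == h) next
          num <- num + (wn[i, j] * wn[i, h] * wn[j, h])^(1 / 3)
        }
      }
      k <- sum(w[i, ] > 0)
      den <- den + k * (k - 1)
    }
  }
  if (den > 0) num / den else 0
}

reference_local_efficiency <- function(w) {
  n <- nrow(w)
  out <- numeric(n)
  len3 <- length_matrix(w)^(1 / 3)
  dist3_inv <- function(sub) {
    # Floyd-Warshall on the sub-length-matrix (independent of Dijkstra route)
    k <- nrow(sub)
    d <- sub
    for (mid in seq_len(k)) {
      for (a in seq_len(k)) {
        for (b in seq_len(k)) {
          if (d[a, mid] + d[mid, b] < d[a, b]) d[a, b] <- d[a, mid] + d[mid, b]
        }
      }
    }
    inv <- ifelse(is.finite(d) & d > 0, 1 / d, 0)
    diag(inv) <- 0
    inv
  }
  for (u in seq_len(n)) {
    nb <- which(w[u, ] > 0 | w[, u] > 0)
    if (length(nb) < 2) next
    e <- dist3_inv(len3[nb, nb, drop = FALSE])
    num <- 0
    for (a in seq_along(nb)) {
      for (b in seq_along(nb)) {
        if (a == b) next
        num <- num + (w[u, nb[a]]^(1 / 3) + w[nb[a], u]^(1 / 3)) *
          (w[u, nb[b]]^(1 / 3) + w[nb[b], u]^(1 / 3)) *
          (e[a, b] + e[b, a]) / 2
      }
    }
    sa <- (w[u, nb] > 0) + (w[nb, u] > 0)
    den <- sum(sa)^2 - sum(sa^2)
    if (num > 0) out[u] <- num / den
  }
  out
}
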