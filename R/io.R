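# Plain-text interchange: scans as whitespace-delimited matrices (rows = time
# points, columns = nodes), one file per scan named <subject>_<scan>.txt;
# connectivity matrices as CSV with a JSON sidecar; ND tables and reports as
# CSV/JSON.

#' Write a cohort's scans to a directory
#'
#' @param cohort Cohort tibble.
#' @param dir Output directory (created if missing).
#' @param truth Write the ground truth (if attached) as a JSON sidecar?
#' @return Invisibly, the written file paths.
#' @export
write_scans <- function(cohort, dir, truth = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- purrr::pmap_chr(
    list(cohort$subject_id, cohort$scan_position, cohort$series),
    function(sid, pos, y) {
      path <- file.path(dir, sprintf("%s_%d.txt", sid, pos))
      write.table(format(y, digits = 10, scientific = TRUE, trim = TRUE),
                  path, row.names = FALSE, col.names = FALSE, quote = FALSE)
      path
    }
  )
  gt <- attr(cohort, "ground_truth")
  if (truth && !is.null(gt)) {
    jsonlite::write_json(
      list(
        population_coefficients = gt$population_coefficients,
        true_edge_mask = gt$true_edge_mask * 1L
      ),
      file.path(dir, "ground_truth.json"),
      digits = NA
    )
  }
  invisible(paths)
}

#' Read scans from a directory of whitespace-delimited text files
#'
#' Expects one file per scan named `<subject>_<scan>.txt` (rows = time
#' points, columns = nodes), the layout written by [write_scans()] and the
#' common dialect of node time-series releases.
#'
#' @param dir Directory of scan files.
#' @param tr_seconds Sampling interval to record with each scan.
#' @return Cohort tibble (see [generate_cohort()] for the columns).
#' @export
read_scans <- function(dir, tr_seconds = 0.72) {
  files <- sort(list.files(dir, pattern = "_[0-9]+\\.txt$", full.names = TRUE))
  if (!length(files)) abort(sprintf("no scan files (<subject>_<scan>.txt) found in %s", dir))
  rows <- purrr::map(files, function(f) {
    base <- sub("\\.txt$", "", basename(f))
    pos <- as.integer(sub(".*_", "", base))
    sid <- sub("_[0-9]+$", "", base)
    y <- as.matrix(read.table(f, header = FALSE))
    dimnames(y) <- NULL
    if (anyNA(y)) abort(sprintf("non-finite entries in %s", f))
    tibble::tibble(
      subject_id = sid,
      session_index = ((pos - 1L) %/% 2L) + 1L,
      scan_in_session = ((pos - 1L) %% 2L) + 1L,
      scan_position = pos,
      tr_seconds = tr_seconds,
      series = list(y)
    )
  })
  dplyr::bind_rows(rows)
}

#' Write connectivity matrices as CSV + JSON sidecars
#'
#' @param conn_tbl Output of [estimate_connectivity()].
#' @param dir Output directory.
#' @return Invisibly, the CSV paths.
#' @export
write_connectivity <- function(conn_tbl, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- purrr::pmap_chr(
    list(conn_tbl$subject_id, conn_tbl$scan_position, conn_tbl$method,
         conn_tbl$conn),
    function(sid, pos, m, cm) {
      stem <- file.path(dir, sprintf("%s_%d_%s", sid, pos, m))
      w <- unclass(cm)[, , drop = FALSE]
      colnames(w) <- sprintf("node%02d", seq_len(ncol(w)))
      utils::write.csv(w, paste0(stem, ".csv"), row.names = FALSE)
      jsonlite::write_json(
        list(method = m, directed = is_directed(cm), subject_id = sid,
             scan_position = pos),
        paste0(stem, ".json"), auto_unbox = TRUE
      )
      paste0(stem, ".csv")
    }
  )
  invisible(paths)
}
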