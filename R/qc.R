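#' Quality-control filtering of annotated cells
#'
#' Retains cells satisfying, with strict inequalities,
#' `n_features > min_features`, `n_features < max_features` and
#' `percent_mt < max_percent_mt`. The defaults are the standard single-cell
#' QC gate (`nFeature_RNA > 200 & nFeature_RNA < 4000 & percent.mt < 8`).
#' The operation is idempotent.
#'
#' @param cells Cell annotation tibble with `n_features` and `percent_mt`.
#' @param min_features,max_features,max_percent_mt QC thresholds.
#' @return The retained cells; the `"qc_report"` attribute (see
#'   [qc_report()]) counts the removals per criterion (a cell failing several
#'   criteria is counted under each).
#' @export
#' @examples
#' cells <- tibble::tibble(n_features = c(100, 200, 1500, 5000),
#'                         percent_mt = c(2, 2, 9, 2))
#' nrow(filter_cells(cells))
filter_cells <- function(cells, min_features = 200, max_features = 4000,
                         max_percent_mt = 8) {
  if (!all(c("n_features", "percent_mt") %in% names(cells))) {
    stop_data("filter_cells: cells must carry n_features and percent_mt")
  }
  if (any(is.na(cells$n_features)) || any(is.na(cells$percent_mt))) {
    stop_data("filter_cells: n_features / percent_mt contain missing values")
  }
  low  <- !(cells$n_features > min_features)
  high <- !(cells$n_features < max_features)
  mt   <- !(cells$percent_mt < max_percent_mt)
  keep <- !(low | high | mt)
  out <- cells[keep, , drop = FALSE]
  attr(out, "qc_report") <- list(
    n_input = nrow(cells),
    n_retained = sum(keep),
    removed_low_features = sum(low),
    removed_high_features = sum(high),
    removed_high_mt = sum(mt),
    thresholds = list(min_features = min_features, max_features = max_features,
                      max_percent_mt = max_percent_mt)
  )
  out
}

#' Retrieve the QC report attached by [filter_cells()]
#' @param cells Output of [filter_cells()].
#' @return A list of per-criterion removal counts and the thresholds used.
#' @export
qc_report <- function(cells) attr(cells, "qc_report")
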