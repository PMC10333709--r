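# Cell-level quality filter: UMI count and mitochondrial fraction.

#' Filter cells on UMI count and mitochondrial fraction
#'
#' Removes cells with fewer than `min_umi` or more than `max_umi` unique
#' molecular identifiers, or with a mitochondrial fraction above `max_mito`
#' (dead cells, residual doublets and cell clumps). All inequalities for
#' removal are strict, so cells exactly at 200, 4000 or 0.25 are retained
#' under the defaults.
#'
#' @param metrics Tibble with columns `cell_id`, `umi_count`,
#'   `mito_fraction`; `cell_id` must be unique.
#' @param min_umi,max_umi Retained UMI range (inclusive).
#' @param max_mito Maximum retained mitochondrial fraction (inclusive).
#'
#' @return The input with logical columns `retained`, `low_umi`, `high_umi`,
#'   `high_mito` and a character `reason` (comma-separated, `NA` when
#'   retained). A cell can count toward several removal reasons.
#' @seealso [qc_summary()] for per-reason removal counts,
#'   [retained_cells()] for the retained id vector.
#' @export
#' @examples
#' m <- tibble::tibble(
#'   cell_id = c("a", "b", "c"),
#'   umi_count = c(199L, 200L, 5000L),
#'   mito_fraction = c(0.1, 0.25, 0.3)
#' )
#' filter_cells(m)
filter_cells <- function(metrics, min_umi = 200, max_umi = 4000,
                         max_mito = 0.25) {
  check_columns(metrics, c("cell_id", "umi_count", "mito_fraction"), "metrics")
  if (anyDuplicated(metrics$cell_id)) abort("`cell_id` must be unique.")
  min_umi <- check_positive(min_umi, "min_umi")
  max_umi <- check_positive(max_umi, "max_umi")
  if (min_umi > max_umi) abort("`min_umi` must be <= `max_umi`.")
  max_mito <- check_fraction(max_mito, "max_mito")
  if (any(metrics$mito_fraction < 0 | metrics$mito_fraction > 1, na.rm = TRUE)) {
    abort("`mito_fraction` must lie in [0, 1].")
  }

  out <- metrics %>%
    dplyr::mutate(
      low_umi = .data$umi_count < min_umi,
      high_umi = .data$umi_count > max_umi,
      high_mito = .data$mito_fraction > max_mito,
      retained = !.data$low_umi & !.data$high_umi & !.data$high_mito,
      reason = purrr::pmap_chr(
        list(.data$low_umi, .data$high_umi, .data$high_mito),
        function(lo, hi, mt) {
          r <- c("low_umi", "high_umi", "high_mito")[c(lo, hi, mt)]
          if (length(r) == 0) NA_character_ else paste(r, collapse = ",")
        }
      )
    )
  as_tibble(out)
}

#' Summarize a QC filtering result
#'
#' @param qc Output of [filter_cells()].
#' @return One-row tibble: cells in/retained and per-reason removal counts
#'   (a cell failing several criteria counts toward each).
#' @export
qc_summary <- function(qc) {
  check_columns(qc, c("retained", "low_umi", "high_umi", "high_mito"), "qc")
  tibble(
    n_cells = nrow(qc),
    n_retained = sum(qc$retained),
    n_removed = sum(!qc$retained),
    n_low_umi = sum(qc$low_umi),
    n_high_umi = sum(qc$high_umi),
    n_high_mito = sum(qc$high_mito)
  )
}

#' Retained cell ids from a QC result
#'
#' @param qc Output of [filter_cells()].
#' @return Character vector of retained `cell_id`s.
#' @export
retained_cells <- function(qc) {
  check_columns(qc, c("cell_id", "retained"), "qc")
  qc$cell_id[qc$retained]
}
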