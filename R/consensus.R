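# Consensus of the two demultiplexing modalities: only cells assigned to the
# same donor by both the hashtag-based and the genotype-based method receive
# a final donor; every other combination is reported with an explicit status
# so the agreement cross-tabulation (diagonal = consensus, edges =
# single-modality cells, off-diagonal = conflicts) can be inspected.

#' Combine hashtag and genotype donor calls
#'
#' @param hashtag_calls Tibble with `cell_id`, `donor_call` (e.g. from
#'   [assign_by_hashtag()]); `NA` = not assigned by that modality.
#' @param genotype_calls Tibble with `cell_id`, `donor_call` (e.g. from
#'   [assign_by_genotype()]). Cells missing from either input are treated as
#'   unassigned by that modality.
#'
#' @return Tibble `cell_id`, `hashtag_donor`, `genotype_donor`,
#'   `final_donor`, `status`; `status` is one of `"consistent"`,
#'   `"conflict"`, `"hashtag_only"`, `"genotype_only"`, `"unassigned"`, and
#'   `final_donor` is non-`NA` exactly for `"consistent"` cells.
#' @seealso [consensus_crosstab()] for the donor x donor agreement table.
#' @export
consensus_assign <- function(hashtag_calls, genotype_calls) {
  check_columns(hashtag_calls, c("cell_id", "donor_call"), "hashtag_calls")
  check_columns(genotype_calls, c("cell_id", "donor_call"), "genotype_calls")
  if (anyDuplicated(hashtag_calls$cell_id)) {
    abort("Duplicate `cell_id` in `hashtag_calls`.")
  }
  if (anyDuplicated(genotype_calls$cell_id)) {
    abort("Duplicate `cell_id` in `genotype_calls`.")
  }
  dplyr::full_join(
    hashtag_calls %>% dplyr::select("cell_id", hashtag_donor = "donor_call"),
    genotype_calls %>% dplyr::select("cell_id", genotype_donor = "donor_call"),
    by = "cell_id"
  ) %>%
    dplyr::mutate(
      status = dplyr::case_when(
        !is.na(.data$hashtag_donor) & !is.na(.data$genotype_donor) &
          .data$hashtag_donor == .data$genotype_donor ~ "consistent",
        !is.na(.data$hashtag_donor) & !is.na(.data$genotype_donor) ~ "conflict",
        !is.na(.data$hashtag_donor) ~ "hashtag_only",
        !is.na(.data$genotype_donor) ~ "genotype_only",
        TRUE ~ "unassigned"
      ),
      final_donor = ifelse(.data$status == "consistent",
                           .data$hashtag_donor, NA_character_)
    ) %>%
    dplyr::arrange(.data$cell_id)
}

#' Cross-tabulate hashtag vs genotype donor calls
#'
#' Cell counts per (hashtag donor, genotype donor) combination; unassigned
#' cells appear under the `"(none)"` level on the corresponding axis. The
#' diagonal is the consensus set, the `"(none)"` row/column are the
#' single-modality edges, and the remaining off-diagonal entries are cells
#' identified differently by the two methods.
#'
#' @param assignments Tibble from [consensus_assign()].
#' @return Tibble `hashtag_donor`, `genotype_donor`, `n_cells`.
#' @export
consensus_crosstab <- function(assignments) {
  check_columns(assignments, c("hashtag_donor", "genotype_donor"),
                "assignments")
  assignments %>%
    dplyr::mutate(
      hashtag_donor = dplyr::coalesce(.data$hashtag_donor, "(none)"),
      genotype_donor = dplyr::coalesce(.data$genotype_donor, "(none)")
    ) %>%
    dplyr::count(.data$hashtag_donor, .data$genotype_donor, name = "n_cells")
}
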