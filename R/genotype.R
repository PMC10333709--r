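# Genotype-based donor deconvolution from per-cell SNP allele counts:
# select donor-discriminating SNPs from the pooled pileup, call per-sample
# genotypes from cumulated counts, validate sample-to-donor links by all-pairs
# genotype concordance, and assign each cell to its most likely donor
# genotype under a three-state binomial likelihood.

# Alt-allele probability per dosage g in {0,1,2}: epsilon, 0.5, 1 - epsilon.
dosage_prob <- function(error_rate) c(error_rate, 0.5, 1 - error_rate)

#' Pool per-cell allele counts into per-SNP totals
#'
#' @param allele_counts Tibble `cell_id`, `snp_id`, `ref_count`, `alt_count`.
#' @return Tibble `snp_id`, `ref_count`, `alt_count` summed over cells.
#' @export
pool_allele_counts <- function(allele_counts) {
  check_columns(allele_counts, c("snp_id", "ref_count", "alt_count"),
                "allele_counts")
  allele_counts %>%
    dplyr::group_by(.data$snp_id) %>%
    dplyr::summarise(
      ref_count = sum(.data$ref_count),
      alt_count = sum(.data$alt_count),
      .groups = "drop"
    )
}

#' Select donor-discriminating SNPs from pooled counts
#'
#' Positions likely to differ between the pooled donors are those that are
#' polymorphic in the pool: adequately covered and with a pooled
#' alternative-allele fraction away from 0 and 1.
#'
#' @param pooled Tibble `snp_id`, `ref_count`, `alt_count` (e.g. from
#'   [pool_allele_counts()]); optional locus columns (`chrom`, `pos`, `ref`,
#'   `alt`) are carried through.
#' @param min_depth Minimum pooled depth (inclusive).
#' @param af_low,af_high Retained pooled alt-fraction interval (inclusive).
#'
#' @return Tibble of retained SNPs with `pooled_depth` and
#'   `pooled_alt_fraction`; may be empty.
#' @export
select_informative_snps <- function(pooled, min_depth = 50, af_low = 0.05,
                                    af_high = 0.95) {
  check_columns(pooled, c("snp_id", "ref_count", "alt_count"), "pooled")
  min_depth <- check_positive(min_depth, "min_depth")
  af_low <- check_fraction(af_low, "af_low")
  af_high <- check_fraction(af_high, "af_high")
  pooled %>%
    dplyr::mutate(
      pooled_depth = .data$ref_count + .data$alt_count,
      pooled_alt_fraction = ifelse(
        .data$pooled_depth > 0, .data$alt_count / .data$pooled_depth, NA_real_
      )
    ) %>%
    dplyr::filter(
      .data$pooled_depth >= min_depth,
      !is.na(.data$pooled_alt_fraction),
      .data$pooled_alt_fraction >= af_low,
      .data$pooled_alt_fraction <= af_high
    )
}

#' Cumulate per-cell allele counts by sample
#'
#' Sums the per-SNP reference and alternative counts of all cells
#' provisionally assigned to the same sample (e.g. hashtag singlets of one
#' donor in one run). Cells without an assignment are ignored.
#'
#' @param allele_counts Tibble `cell_id`, `snp_id`, `ref_count`, `alt_count`.
#' @param assignment Tibble `cell_id`, `sample_id`.
#' @return Tibble `sample_id`, `snp_id`, `ref_count`, `alt_count`.
#' @export
aggregate_counts_by_sample <- function(allele_counts, assignment) {
  check_columns(allele_counts, c("cell_id", "snp_id", "ref_count", "alt_count"),
                "allele_counts")
  check_columns(assignment, c("cell_id", "sample_id"), "assignment")
  if (anyDuplicated(assignment$cell_id)) {
    abort("`assignment` must contain each cell at most once.")
  }
  allele_counts %>%
    dplyr::inner_join(assignment, by = "cell_id") %>%
    dplyr::group_by(.data$sample_id, .data$snp_id) %>%
    dplyr::summarise(
      ref_count = sum(.data$ref_count),
      alt_count = sum(.data$alt_count),
      .groups = "drop"
    )
}

#' Call genotypes from cumulated sample counts
#'
#' At each SNP with depth at least `min_call_depth`, the alternative-allele
#' dosage g in `{0, 1, 2}` maximizing `Binomial(alt; depth, q_g)` is called,
#' with `q = (error_rate, 0.5, 1 - error_rate)`. Likelihood ties are broken
#' toward the heterozygote (a residual 0-vs-2 tie toward 0); positions below
#' `min_call_depth` are missing.
#'
#' @param sample_counts Tibble `sample_id`, `snp_id`, `ref_count`,
#'   `alt_count` (e.g. from [aggregate_counts_by_sample()]).
#' @param error_rate Base-miscall fraction in `[0, 0.5)`.
#' @param min_call_depth Minimum depth for a call.
#' @return Tibble `sample_id`, `snp_id`, `depth`, `genotype` (integer dosage
#'   or `NA`).
#' @export
call_genotypes <- function(sample_counts, error_rate = 0.01,
                           min_call_depth = 5) {
  check_columns(sample_counts, c("sample_id", "snp_id", "ref_count",
                                 "alt_count"), "sample_counts")
  error_rate <- check_fraction(error_rate, "error_rate", 0, 0.5, open_hi = TRUE)
  min_call_depth <- check_positive(min_call_depth, "min_call_depth")
  q <- dosage_prob(error_rate)

  depth <- sample_counts$ref_count + sample_counts$alt_count
  alt <- sample_counts$alt_count
  ll <- vapply(q, function(p) dbinom(alt, depth, p, log = TRUE),
               numeric(length(alt)))
  ll <- matrix(ll, ncol = 3)
  best <- apply(ll, 1, function(l) {
    top <- which(l >= max(l) - 0, arr.ind = TRUE)
    if (2L %in% top) 1L else min(top) - 1L # prefer het among exact ties
  })
  tibble(
    sample_id = sample_counts$sample_id,
    snp_id = sample_counts$snp_id,
    depth = as.integer(depth),
    genotype = ifelse(depth >= min_call_depth, as.integer(best), NA_integer_)
  )
}

#' Spread long genotype calls to a samples x SNPs matrix
#'
#' @param calls Tibble from [call_genotypes()].
#' @param snp_ids Optional full SNP universe for the columns (uncovered SNPs
#'   become missing).
#' @return Integer matrix (samples x SNPs) with `NA` for missing calls.
#' @export
genotype_matrix <- function(calls, snp_ids = NULL) {
  check_columns(calls, c("sample_id", "snp_id", "genotype"), "calls")
  samples <- unique(calls$sample_id)
  if (is.null(snp_ids)) snp_ids <- sort(unique(calls$snp_id))
  g <- matrix(NA_integer_, length(samples), length(snp_ids),
              dimnames = list(samples, snp_ids))
  keep <- calls$snp_id %in% snp_ids
  g[cbind(match(calls$sample_id[keep], samples),
          match(calls$snp_id[keep], snp_ids))] <- calls$genotype[keep]
  g
}

#' Genotype concordance between two samples
#'
#' Fraction of co-called SNPs (both genotypes non-missing) at which the two
#' dosage vectors agree. Symmetric; undefined (`NA`, with `n_shared = 0`)
#' when no SNP is co-called.
#'
#' @param a,b Genotype vectors over the same SNP universe (`NA` = missing),
#'   e.g. rows of [genotype_matrix()].
#' @return List with `concordance` and `n_shared`.
#' @export
genotype_concordance <- function(a, b) {
  if (length(a) != length(b)) abort("Genotype vectors must share a SNP universe.")
  shared <- !is.na(a) & !is.na(b)
  n_shared <- sum(shared)
  list(
    concordance = if (n_shared == 0) NA_real_ else
      sum(a[shared] == b[shared]) / n_shared,
    n_shared = as.integer(n_shared)
  )
}

#' All-pairs genotype concordance
#'
#' @param genotypes Samples x SNPs matrix (from [genotype_matrix()]).
#' @param donor_of Optional named vector mapping sample id to donor id; adds
#'   a `same_donor_expected` flag per pair.
#' @return Tibble `sample_a`, `sample_b`, `concordance`, `n_shared`
#'   (and `same_donor_expected`) for all unordered pairs.
#' @export
pairwise_concordance <- function(genotypes, donor_of = NULL) {
  samples <- rownames(genotypes)
  if (is.null(samples) || nrow(genotypes) < 2) {
    abort("`genotypes` must have >= 2 named sample rows.")
  }
  pairs <- utils::combn(samples, 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    cc <- genotype_concordance(genotypes[a, ], genotypes[b, ])
    tibble(sample_a = a, sample_b = b,
           concordance = cc$concordance, n_shared = cc$n_shared)
  })
  if (!is.null(donor_of)) {
    out <- out %>%
      dplyr::mutate(same_donor_expected =
                      unname(donor_of[.data$sample_a] == donor_of[.data$sample_b]))
  }
  out
}

#' Pool per-run sample counts into per-donor genotypes
#'
#' Cumulates the positional counts of samples linked to the same donor across
#' runs and calls the donor genotypes from the pooled counts. When the
#' per-sample genotypes are available, each link is validated by concordance:
#' if any same-donor pair's concordance falls at or below the maximum
#' different-donor concordance, a linkage warning is raised (the pooled calls
#' are still returned).
#'
#' @param sample_counts Tibble `sample_id`, `snp_id`, `ref_count`,
#'   `alt_count` covering all runs.
#' @param links Tibble `sample_id`, `donor_id`.
#' @param error_rate,min_call_depth Passed to [call_genotypes()].
#' @param validate Check links by pairwise concordance (default `TRUE`; needs
#'   >= 2 samples).
#' @return Tibble `sample_id` (= donor id), `snp_id`, `depth`, `genotype`.
#' @export
pool_donor_genotypes <- function(sample_counts, links, error_rate = 0.01,
                                 min_call_depth = 5, validate = TRUE) {
  check_columns(links, c("sample_id", "donor_id"), "links")
  if (validate && nrow(links) >= 2 && dplyr::n_distinct(links$donor_id) >= 2) {
    sg <- call_genotypes(sample_counts, error_rate, min_call_depth)
    gm <- genotype_matrix(sg)
    donor_of <- setNames(links$donor_id, links$sample_id)
    pc <- pairwise_concordance(gm[links$sample_id, , drop = FALSE], donor_of)
    same <- pc$concordance[pc$same_donor_expected]
    diff <- pc$concordance[!pc$same_donor_expected]
    if (length(same) > 0 && length(diff) > 0 &&
        min(same, na.rm = TRUE) <= max(diff, na.rm = TRUE)) {
      warn(paste(
        "Linkage check failed: a same-donor pair's concordance does not",
        "exceed the maximum different-donor concordance."
      ))
    }
  }
  sample_counts %>%
    dplyr::inner_join(links, by = "sample_id") %>%
    dplyr::group_by(sample_id = .data$donor_id, .data$snp_id) %>%
    dplyr::summarise(
      ref_count = sum(.data$ref_count),
      alt_count = sum(.data$alt_count),
      .groups = "drop"
    ) %>%
    call_genotypes(error_rate, min_call_depth)
}

#' Assign cells to donors by genotype likelihood
#'
#' For each cell, the log-likelihood of every donor is the sum over covered
#' SNPs (cell depth > 0, donor genotype non-missing) of
#' `log Binomial(alt; depth, q_g)` with `q = (error_rate, 0.5,
#' 1 - error_rate)` indexed by the donor's dosage. The most likely donor is
#' called only when its lead over the runner-up is at least `min_margin`
#' natural-log units and at least `min_informative` SNPs informed the
#' comparison; otherwise the call is `NA`.
#'
#' @param allele_counts Tibble `cell_id`, `snp_id`, `ref_count`, `alt_count`.
#' @param donor_genotypes Donors x SNPs dosage matrix (`NA` = missing), e.g.
#'   [genotype_matrix()] of [pool_donor_genotypes()] output.
#' @param error_rate Base-miscall fraction in `[0, 0.5)`.
#' @param min_margin Minimum best-minus-second log-likelihood margin.
#' @param min_informative Minimum covered, co-called SNPs for the best donor.
#'
#' @return Tibble `cell_id`, `donor_call` (`NA` when below the margin or
#'   coverage thresholds), `best_donor`, `margin`, `n_informative`.
#' @export
assign_by_genotype <- function(allele_counts, donor_genotypes,
                               error_rate = 0.01, min_margin = 2.0,
                               min_informative = 3) {
  check_columns(allele_counts, c("cell_id", "snp_id", "ref_count", "alt_count"),
                "allele_counts")
  if (is.null(rownames(donor_genotypes)) || nrow(donor_genotypes) == 0) {
    abort("`donor_genotypes` must have at least one named donor row.")
  }
  error_rate <- check_fraction(error_rate, "error_rate", 0, 0.5, open_hi = TRUE)
  snps <- colnames(donor_genotypes)
  donors <- rownames(donor_genotypes)
  ac <- allele_counts %>% dplyr::filter(.data$snp_id %in% snps)
  cells <- unique(allele_counts$cell_id)
  ci <- match(ac$cell_id, cells)
  si <- match(ac$snp_id, snps)
  A <- Matrix::sparseMatrix(i = ci, j = si, x = as.numeric(ac$alt_count),
                            dims = c(length(cells), length(snps)))
  R <- Matrix::sparseMatrix(i = ci, j = si, x = as.numeric(ac$ref_count),
                            dims = c(length(cells), length(snps)))
  D <- Matrix::sparseMatrix(
    i = ci, j = si,
    x = as.numeric(ac$ref_count + ac$alt_count > 0),
    dims = c(length(cells), length(snps))
  )

  # q clamped away from {0, 1} so error_rate = 0 stays finite; a missing
  # donor genotype zeroes both log terms, i.e. excludes the SNP for that donor
  q <- pmin(pmax(dosage_prob(error_rate), 1e-12), 1 - 1e-12)
  G1 <- donor_genotypes + 1L
  LQ <- matrix(log(q)[G1], nrow(donor_genotypes), ncol(donor_genotypes))
  LR <- matrix(log(1 - q)[G1], nrow(donor_genotypes), ncol(donor_genotypes))
  called <- !is.na(donor_genotypes)
  LQ[!called] <- 0
  LR[!called] <- 0

  L <- as.matrix(A %*% t(LQ) + R %*% t(LR)) # cells x donors
  Ninf <- as.matrix(D %*% t(called * 1))    # informative SNPs per (cell, donor)

  best_j <- max.col(L, ties.method = "first")
  best_ll <- L[cbind(seq_along(cells), best_j)]
  second_ll <- if (length(donors) == 1) {
    rep(-Inf, length(cells))
  } else {
    L2 <- L
    L2[cbind(seq_along(cells), best_j)] <- -Inf
    apply(L2, 1, max)
  }
  margin <- best_ll - second_ll
  n_informative <- as.integer(Ninf[cbind(seq_along(cells), best_j)])
  ok <- margin >= min_margin & n_informative >= min_informative
  tibble(
    cell_id = cells,
    donor_call = ifelse(ok, donors[best_j], NA_character_),
    best_donor = donors[best_j],
    margin = margin,
    n_informative = n_informative
  )
}
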