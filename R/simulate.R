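# Synthetic multiplexed-run generator: hashtag counts, per-cell SNP allele
# counts, QC metrics and per-sample cluster-frequency tables, each emitted
# together with its ground truth so downstream assignments can be scored.

#' Simulation configuration for a multiplexed single-cell experiment
#'
#' Bundles the parameters of the synthetic-data generator. Defaults emulate
#' the study design the package targets: 15 hashtag-barcoded donors pooled
#' per 10x run, per-hashtag log10-counts that are bimodal with well-separated
#' peaks (a low ambient/noise component and a high signal component), a small
#' two-donor doublet fraction, and shallow per-SNP transcript coverage.
#'
#' @param n_runs Number of pooled runs to simulate.
#' @param donors_per_run Donors (hashtags) pooled in each run.
#' @param cells_per_donor Cells per donor per run.
#' @param doublet_rate Fraction of cells that are two-donor doublets.
#' @param mu_hi,sigma_hi Mean and sd of the signal component on the
#'   log10(count + 1) scale.
#' @param mu_lo,sigma_lo Mean and sd of the ambient/noise component on the
#'   same scale. `mu_hi` must exceed `mu_lo`.
#' @param n_snps Number of biallelic SNPs in the simulated panel.
#' @param maf_low,maf_high Bounds of the uniform distribution from which each
#'   SNP's minor-allele frequency is drawn.
#' @param depth_mean Mean per-SNP per-cell transcript depth (Poisson).
#' @param error_rate Base-miscall fraction \eqn{\epsilon \in [0, 0.5)}.
#' @param seed Master RNG seed; every generator draws from a substream
#'   derived from it, so identical configs reproduce outputs bit-exactly.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_runs = 1, cells_per_donor = 50, seed = 42)
sim_config <- function(n_runs = 2, donors_per_run = 15, cells_per_donor = 1000,
                       doublet_rate = 0.05,
                       mu_hi = 2.5, sigma_hi = 0.2,
                       mu_lo = 1.0, sigma_lo = 0.2,
                       n_snps = 200, maf_low = 0.1, maf_high = 0.5,
                       depth_mean = 20, error_rate = 0.01, seed = 1) {
  cfg <- list(
    n_runs = check_count(n_runs, "n_runs", min = 1L),
    donors_per_run = check_count(donors_per_run, "donors_per_run", min = 1L),
    cells_per_donor = check_count(cells_per_donor, "cells_per_donor", min = 0L),
    doublet_rate = check_fraction(doublet_rate, "doublet_rate"),
    mu_hi = as.numeric(mu_hi), sigma_hi = check_positive(sigma_hi, "sigma_hi"),
    mu_lo = as.numeric(mu_lo), sigma_lo = check_positive(sigma_lo, "sigma_lo"),
    n_snps = check_count(n_snps, "n_snps", min = 1L),
    maf_low = check_fraction(maf_low, "maf_low", 0, 0.5),
    maf_high = check_fraction(maf_high, "maf_high", 0, 0.5),
    depth_mean = check_fraction(depth_mean, "depth_mean", 0, Inf),
    error_rate = check_fraction(error_rate, "error_rate", 0, 0.5, open_hi = TRUE),
    seed = check_count(seed, "seed")
  )
  if (cfg$mu_hi <= cfg$mu_lo) abort("`mu_hi` must be greater than `mu_lo`.")
  if (cfg$maf_low > cfg$maf_high) abort("`maf_low` must be <= `maf_high`.")
  structure(cfg, class = "sim_config")
}

donor_ids <- function(n) sprintf("donor%02d", seq_len(n))

#' Simulate donor genotypes at biallelic SNPs
#'
#' For each SNP an allele frequency is drawn uniformly in
#' `[maf_low, maf_high]` and each donor's alternative-allele dosage is
#' Binomial(2, f), i.e. Hardy-Weinberg sampling of unrelated donors.
#'
#' @param n_donors Number of donors.
#' @param n_snps Number of SNPs.
#' @param maf_low,maf_high Allele-frequency bounds, each in `[0, 0.5]`.
#' @param seed RNG seed; the same seed reproduces the matrix bit-exactly.
#'
#' @return Integer matrix (donors x SNPs) of dosages in `{0, 1, 2}`, with
#'   donor/SNP ids as dimnames.
#' @export
#' @examples
#' simulate_genotypes(3, 5, 0.2, 0.5, seed = 1)
simulate_genotypes <- function(n_donors, n_snps, maf_low = 0.1, maf_high = 0.5,
                               seed = 1) {
  n_donors <- check_count(n_donors, "n_donors", min = 1L)
  n_snps <- check_count(n_snps, "n_snps", min = 1L)
  maf_low <- check_fraction(maf_low, "maf_low", 0, 0.5)
  maf_high <- check_fraction(maf_high, "maf_high", 0, 0.5)
  if (maf_low > maf_high) abort("`maf_low` must be <= `maf_high`.")
  withr::with_seed(derive_seed(seed, "genotypes"), {
    f <- runif(n_snps, maf_low, maf_high)
    g <- matrix(rbinom(n_donors * n_snps, 2L, rep(f, each = n_donors)),
      nrow = n_donors, ncol = n_snps,
      dimnames = list(donor_ids(n_donors), sprintf("snp%04d", seq_len(n_snps)))
    )
    storage.mode(g) <- "integer"
    g
  })
}

#' Simulate one pooled hashtag run
#'
#' Each cell carries one true donor (or, with probability `doublet_rate`, an
#' unordered pair of distinct donors). The count of a cell's own hashtag(s)
#' is drawn from the signal component -- `round(10^x - 1)` with
#' `x ~ Normal(mu_hi, sigma_hi)` -- and every other hashtag from the noise
#' component, reproducing the bimodal per-hashtag log-count shape that
#' hashtag demultiplexing exploits.
#'
#' @param config A [sim_config()].
#' @param run_id Label for the run; cell ids are prefixed with it and it
#'   seeds the run's RNG substream, so different runs of one config differ.
#'
#' @return A list with `counts` (integer matrix, cells x hashtags; hashtag
#'   columns are named by donor) and `truth` (tibble: `cell_id`, `donor`,
#'   `donor2` (`NA` for singlets), `is_doublet`).
#' @export
simulate_hashtag_run <- function(config, run_id = "run1") {
  stopifnot(inherits(config, "sim_config"))
  n_don <- config$donors_per_run
  n_cells <- n_don * config$cells_per_donor
  donors <- donor_ids(n_don)
  if (n_cells == 0) {
    return(list(
      counts = matrix(integer(0), nrow = 0, ncol = n_don,
                      dimnames = list(NULL, donors)),
      truth = tibble(cell_id = character(), donor = character(),
                     donor2 = character(), is_doublet = logical())
    ))
  }
  withr::with_seed(derive_seed(config$seed, paste0("hashtag:", run_id)), {
    cell_id <- sprintf("%s_cell%05d", run_id, seq_len(n_cells))
    donor <- rep(donors, each = config$cells_per_donor)
    is_doublet <- runif(n_cells) < config$doublet_rate & n_don > 1
    # second donor of a doublet: uniform over the other donors
    donor2 <- rep(NA_character_, n_cells)
    idx <- which(is_doublet)
    if (length(idx) > 0) {
      shift <- sample.int(n_don - 1L, length(idx), replace = TRUE)
      donor2[idx] <- donors[((match(donor[idx], donors) - 1L + shift) %% n_don) + 1L]
    }
    x <- matrix(rnorm(n_cells * n_don, config$mu_lo, config$sigma_lo),
                nrow = n_cells, ncol = n_don)
    own <- cbind(seq_len(n_cells), match(donor, donors))
    x[own] <- rnorm(n_cells, config$mu_hi, config$sigma_hi)
    if (length(idx) > 0) {
      own2 <- cbind(idx, match(donor2[idx], donors))
      x[own2] <- rnorm(length(idx), config$mu_hi, config$sigma_hi)
    }
    counts <- pmax(round(10^x - 1), 0)
    storage.mode(counts) <- "integer"
    dimnames(counts) <- list(cell_id, donors)
    list(
      counts = counts,
      truth = tibble(cell_id = cell_id, donor = donor, donor2 = donor2,
                     is_doublet = is_doublet)
    )
  })
}

#' Simulate per-cell SNP allele counts
#'
#' For every cell and SNP, sequenced depth is Poisson(`depth_mean`) and the
#' alternative-base count is Binomial(depth, q) with q = \eqn{\epsilon}, 0.5,
#' or \eqn{1 - \epsilon} for the cell's donor dosage 0, 1 or 2. Doublet cells
#' mix the two donors' q with equal weight. Pairs with zero depth are omitted
#' from the output; readers treat absence as depth 0.
#'
#' @param truth Truth tibble from [simulate_hashtag_run()] (`cell_id`,
#'   `donor`, `donor2`).
#' @param genotypes Dosage matrix from [simulate_genotypes()] covering every
#'   donor in `truth`.
#' @param depth_mean Mean per-SNP per-cell depth.
#' @param error_rate Base-miscall fraction in `[0, 0.5)`.
#' @param seed RNG seed.
#'
#' @return Tibble `cell_id`, `snp_id`, `ref_count`, `alt_count`.
#' @export
simulate_allele_counts <- function(truth, genotypes, depth_mean = 20,
                                   error_rate = 0.01, seed = 1) {
  check_columns(truth, c("cell_id", "donor"), "truth")
  error_rate <- check_fraction(error_rate, "error_rate", 0, 0.5, open_hi = TRUE)
  depth_mean <- check_fraction(depth_mean, "depth_mean", 0, Inf)
  missing_donors <- setdiff(
    stats::na.omit(c(truth$donor, truth$donor2)), rownames(genotypes)
  )
  if (length(missing_donors) > 0) {
    abort(sprintf("Donors absent from `genotypes`: %s.",
                  paste(missing_donors, collapse = ", ")))
  }
  n_cells <- nrow(truth)
  n_snps <- ncol(genotypes)
  q_of <- c(error_rate, 0.5, 1 - error_rate) # indexed by dosage + 1
  withr::with_seed(derive_seed(seed, "allele_counts"), {
    q1 <- matrix(q_of[genotypes[truth$donor, , drop = FALSE] + 1L],
                 nrow = n_cells, ncol = n_snps)
    q <- q1
    dbl <- !is.na(truth$donor2)
    if (any(dbl)) {
      q2 <- matrix(q_of[genotypes[truth$donor2[dbl], , drop = FALSE] + 1L],
                   nrow = sum(dbl), ncol = n_snps)
      q[dbl, ] <- (q1[dbl, , drop = FALSE] + q2) / 2
    }
    depth <- matrix(rpois(n_cells * n_snps, depth_mean),
                    nrow = n_cells, ncol = n_snps)
    alt <- matrix(rbinom(n_cells * n_snps, depth, q),
                  nrow = n_cells, ncol = n_snps)
    keep <- which(depth > 0, arr.ind = TRUE)
    tibble(
      cell_id = truth$cell_id[keep[, 1]],
      snp_id = colnames(genotypes)[keep[, 2]],
      ref_count = as.integer(depth[keep] - alt[keep]),
      alt_count = as.integer(alt[keep])
    ) %>% dplyr::arrange(.data$cell_id, .data$snp_id)
  })
}

#' Simulate per-cell QC metrics
#'
#' Emulates the two cell populations the UMI/mitochondrial filter separates:
#' healthy cells with lognormal UMI totals and low Beta-distributed
#' mitochondrial fractions, and a `low_quality_rate` fraction of damaged
#' cells with few UMIs and high mitochondrial content.
#'
#' @param cell_ids Character vector of cell ids.
#' @param low_quality_rate Fraction of damaged cells.
#' @param seed RNG seed.
#'
#' @return Tibble `cell_id`, `umi_count`, `mito_fraction`, `is_low_quality`
#'   (the generating label, for scoring).
#' @export
simulate_qc_metrics <- function(cell_ids, low_quality_rate = 0.05, seed = 1) {
  low_quality_rate <- check_fraction(low_quality_rate, "low_quality_rate")
  n <- length(cell_ids)
  withr::with_seed(derive_seed(seed, "qc_metrics"), {
    bad <- runif(n) < low_quality_rate
    umi <- ifelse(bad,
      round(rlnorm(n, log(120), 0.7)),
      round(rlnorm(n, log(1500), 0.6))
    )
    mito <- ifelse(bad, rbeta(n, 4, 8), rbeta(n, 2, 30))
    tibble(
      cell_id = cell_ids,
      umi_count = as.integer(pmax(umi, 0)),
      mito_fraction = mito,
      is_low_quality = bad
    )
  })
}

#' Simulate per-sample cluster-frequency tables
#'
#' Generates, for each sample (one donor at one timepoint) and cluster, a
#' binomial count out of the sample's total with success probability
#' `plogis(beta0 + beta1 * after + u_donor + e_sample)`, where `u` is a
#' donor-level and `e` a sample-level (observation-level) Gaussian random
#' effect on the logit scale -- the generative counterpart of the
#' overdispersed binomial mixed model fitted downstream.
#'
#' @param design Tibble with columns `donor_id`, `group`, `timepoint`
#'   (`"before"`/`"after"`); each donor appears once per timepoint.
#' @param params Tibble with columns `cluster_id`, `beta0`, `beta1`,
#'   `sigma_u`, `sigma_e`.
#' @param total_sampler Mean of the truncated-Poisson (>= 1) totals.
#' @param seed RNG seed.
#'
#' @return A list with `table` (tibble: `sample_id`, `donor_id`, `group`,
#'   `timepoint`, `cluster_id`, `count`, `total`, `denominator_kind`) and
#'   `truth` (the parameters plus the drawn `u` and `e`).
#' @export
simulate_cluster_counts <- function(design, params, total_sampler = 2000,
                                    seed = 1) {
  check_columns(design, c("donor_id", "group", "timepoint"), "design")
  check_columns(params, c("cluster_id", "beta0", "beta1", "sigma_u", "sigma_e"),
                "params")
  if (nrow(design) == 0) abort("`design` must contain at least one sample.")
  bad_tp <- setdiff(unique(design$timepoint), c("before", "after"))
  if (length(bad_tp) > 0) {
    abort(sprintf("`timepoint` must be 'before'/'after'; found: %s.",
                  paste(bad_tp, collapse = ", ")))
  }
  dup <- design %>%
    dplyr::count(.data$donor_id, .data$timepoint) %>%
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) abort("Each donor must appear at most once per timepoint.")
  total_sampler <- check_positive(total_sampler, "total_sampler")

  withr::with_seed(derive_seed(seed, "cluster_counts"), {
    design <- design %>%
      dplyr::mutate(sample_id = sprintf("%s_%s", .data$donor_id, .data$timepoint))
    donors <- unique(design$donor_id)
    # totals are per sample (one denominator per biopsy), shared by clusters
    totals <- tibble(
      sample_id = design$sample_id,
      total = pmax(1L, rpois(nrow(design), total_sampler))
    )
    out <- purrr::pmap(params, function(cluster_id, beta0, beta1, sigma_u,
                                        sigma_e, ...) {
      u <- setNames(rnorm(length(donors), 0, sigma_u), donors)
      e <- rnorm(nrow(design), 0, sigma_e)
      p <- plogis(beta0 + beta1 * (design$timepoint == "after") +
                    u[design$donor_id] + e)
      n_s <- totals$total[match(design$sample_id, totals$sample_id)]
      list(
        rows = design %>%
          dplyr::mutate(
            cluster_id = cluster_id,
            count = rbinom(dplyr::n(), n_s, p),
            total = n_s,
            denominator_kind = "CD45"
          ),
        u = tibble(cluster_id = cluster_id, donor_id = donors, u = unname(u)),
        e = tibble(cluster_id = cluster_id, sample_id = design$sample_id, e = e)
      )
    })
    list(
      table = purrr::map_dfr(out, "rows") %>%
        dplyr::select("sample_id", "donor_id", "group", "timepoint",
                      "cluster_id", "count", "total", "denominator_kind"),
      truth = list(
        params = as_tibble(params),
        donor_effects = purrr::map_dfr(out, "u"),
        sample_effects = purrr::map_dfr(out, "e")
      )
    )
  })
}

#' Simulate a complete multiplexed experiment
#'
#' Convenience wrapper generating, from one [sim_config()]: donor genotypes,
#' hashtag counts + truth for each run, per-cell allele counts, and QC
#' metrics, keyed so downstream stages can be run end to end.
#'
#' @param config A [sim_config()].
#' @return List with `genotypes`, `runs` (per run: `counts`, `truth`,
#'   `allele_counts`, `qc`), and the flattened `truth` tibble.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genotypes <- simulate_genotypes(
    config$donors_per_run, config$n_snps, config$maf_low, config$maf_high,
    seed = config$seed
  )
  run_names <- sprintf("run%d", seq_len(config$n_runs))
  runs <- purrr::map(run_names, function(rid) {
    hr <- simulate_hashtag_run(config, run_id = rid)
    ac <- simulate_allele_counts(
      hr$truth, genotypes, config$depth_mean, config$error_rate,
      seed = derive_seed(config$seed, paste0("ac:", rid))
    )
    qc <- simulate_qc_metrics(
      hr$truth$cell_id,
      seed = derive_seed(config$seed, paste0("qc:", rid))
    )
    list(counts = hr$counts, truth = hr$truth, allele_counts = ac, qc = qc)
  })
  names(runs) <- run_names
  truth <- purrr::map_dfr(runs, "truth", .id = "run_id")
  list(genotypes = genotypes, runs = runs, truth = truth)
}
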