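# End-to-end driver: (optional) simulation -> QC -> hashtag demultiplexing ->
# genotype demultiplexing -> consensus -> cluster-abundance testing, with TSV
# outputs, a machine-readable run report, and full determinism from the
# single configuration seed (each stage draws from its own named substream).

#' Pipeline configuration
#'
#' Collects the stage toggles and parameters of [run_pipeline()]. With
#' `simulate = TRUE` (the default) the inputs are generated by the
#' synthetic-data module from `sim`; otherwise paths to the hashtag matrix,
#' allele counts, QC metrics and cluster table must be supplied.
#'
#' @param simulate Generate synthetic inputs from `sim`.
#' @param sim Either a [sim_config()] or a list of its arguments.
#' @param stages Character vector of stages to run, a subset (in order) of
#'   `c("qc", "hashtag", "genotype", "consensus", "abundance")`. The
#'   consensus stage requires both demultiplexing stages.
#' @param hashtag_counts,allele_counts,cell_qc,cluster_table Input paths
#'   (ignored when `simulate = TRUE`). `hashtag_counts` entries may be wide
#'   TSV files or MTX directories, one per run.
#' @param min_umi,max_umi,max_mito QC thresholds (see [filter_cells()]).
#' @param ratio_threshold Hashtag positivity odds threshold.
#' @param error_rate,min_call_depth,min_margin,min_informative Genotype-stage
#'   parameters (see [call_genotypes()], [assign_by_genotype()]).
#' @param snp_min_depth,af_low,af_high SNP-panel selection parameters.
#' @param alpha BH significance level for the abundance stage.
#' @param cluster_params Abundance-simulation parameters (tibble or list of
#'   columns `cluster_id`, `beta0`, `beta1`, `sigma_u`, `sigma_e`); defaults
#'   to three clusters with challenge effects 0.8, 0 and -0.5.
#' @param seed Master seed; all stage randomness derives from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = TRUE, sim = list(),
                            stages = c("qc", "hashtag", "genotype",
                                       "consensus", "abundance"),
                            hashtag_counts = NULL, allele_counts = NULL,
                            cell_qc = NULL, cluster_table = NULL,
                            min_umi = 200, max_umi = 4000, max_mito = 0.25,
                            ratio_threshold = 3,
                            error_rate = 0.01, min_call_depth = 5,
                            min_margin = 2, min_informative = 3,
                            snp_min_depth = 50, af_low = 0.05, af_high = 0.95,
                            alpha = 0.1, cluster_params = NULL, seed = 1) {
  all_stages <- c("qc", "hashtag", "genotype", "consensus", "abundance")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  if ("consensus" %in% stages &&
      !all(c("hashtag", "genotype") %in% stages)) {
    abort("The consensus stage requires both the hashtag and genotype stages.")
  }
  if (!inherits(sim, "sim_config")) {
    sim$seed <- sim$seed %||% seed
    sim <- do.call(sim_config, sim)
  }
  if (is.null(cluster_params)) {
    cluster_params <- tibble(
      cluster_id = c("MPS1", "MPS2", "MPS3"),
      beta0 = c(-2, -3, -2.5), beta1 = c(0.8, 0, -0.5),
      sigma_u = 0.5, sigma_e = 0.3
    )
  } else {
    cluster_params <- as_tibble(cluster_params)
  }
  structure(
    list(
      simulate = isTRUE(simulate), sim = sim,
      stages = all_stages[all_stages %in% stages],
      hashtag_counts = hashtag_counts, allele_counts = allele_counts,
      cell_qc = cell_qc, cluster_table = cluster_table,
      min_umi = min_umi, max_umi = max_umi, max_mito = max_mito,
      ratio_threshold = ratio_threshold,
      error_rate = error_rate, min_call_depth = min_call_depth,
      min_margin = min_margin, min_informative = min_informative,
      snp_min_depth = snp_min_depth, af_low = af_low, af_high = af_high,
      alpha = alpha, cluster_params = cluster_params,
      seed = check_count(seed, "seed")
    ),
    class = "pipeline_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_run_counts <- function(path) {
  if (dir.exists(path)) read_hashtag_mtx(path) else read_hashtag_tsv(path)
}

#' Run the demultiplexing and abundance pipeline
#'
#' Executes the configured stages in order (simulate -> qc -> hashtag ->
#' genotype -> consensus -> abundance), writes each stage's outputs as TSV
#' under `out_dir`, and returns a run report (per-stage record counts,
#' parameters actually used, output paths, warnings). Identical config and
#' seed reproduce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return The run report, invisibly: a list with `counts`, `paths`,
#'   `parameters`, `warnings`. Also written as `report.yaml`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- unclass(config)[setdiff(names(config), "cluster_params")]
  params$sim <- unclass(params$sim)
  report <- list(
    parameters = params,
    counts = list(), paths = list(), warnings = character()
  )
  note <- function(stage, msg) {
    report$warnings <<- c(report$warnings, sprintf("[%s] %s", stage, msg))
  }
  out_path <- function(name) file.path(out_dir, name)

  # ---- inputs (simulated or read) -------------------------------------------
  if (config$simulate) {
    expt <- simulate_experiment(config$sim)
    runs <- purrr::map(expt$runs, "counts")
    allele_counts <- purrr::map_dfr(expt$runs, "allele_counts")
    qc_metrics <- purrr::map_dfr(expt$runs, "qc") %>%
      dplyr::select("cell_id", "umi_count", "mito_fraction")
    design <- tidyr::expand_grid(
      donor_id = rownames(expt$genotypes),
      timepoint = c("before", "after")
    ) %>%
      dplyr::mutate(group = ifelse(
        match(.data$donor_id, rownames(expt$genotypes)) %% 2 == 0,
        "allergic", "non-allergic"
      ))
    cl <- simulate_cluster_counts(design, config$cluster_params,
                                  seed = derive_seed(config$sim$seed, "pipeline"))
    cluster_table <- cl$table
    truth <- expt$truth
    readr::write_tsv(truth, out_path("simulation_truth.tsv"))
    report$paths$simulation_truth <- out_path("simulation_truth.tsv")
    report$counts$simulated_cells <- nrow(truth)
  } else {
    if ("hashtag" %in% config$stages) {
      if (is.null(config$hashtag_counts)) abort("`hashtag_counts` paths required.")
      runs <- purrr::map(config$hashtag_counts, read_run_counts)
      names(runs) <- names(config$hashtag_counts) %||%
        sprintf("run%d", seq_along(runs))
    }
    if ("genotype" %in% config$stages) {
      if (is.null(config$allele_counts)) abort("`allele_counts` path required.")
      allele_counts <- read_allele_counts(config$allele_counts)
    }
    if ("qc" %in% config$stages) {
      if (is.null(config$cell_qc)) abort("`cell_qc` path required.")
      qc_metrics <- read_cell_qc(config$cell_qc)
    }
    if ("abundance" %in% config$stages) {
      if (is.null(config$cluster_table)) abort("`cluster_table` path required.")
      cluster_table <- read_cluster_table(config$cluster_table)
    }
  }

  retained <- NULL

  # ---- qc -------------------------------------------------------------------
  if ("qc" %in% config$stages) {
    qc <- filter_cells(qc_metrics, config$min_umi, config$max_umi,
                       config$max_mito)
    retained <- retained_cells(qc)
    readr::write_tsv(qc %>% dplyr::select("cell_id", "retained", "reason"),
                     out_path("qc_calls.tsv"))
    report$paths$qc <- out_path("qc_calls.tsv")
    report$counts$qc_in <- nrow(qc)
    report$counts$qc_retained <- length(retained)
  }

  # ---- hashtag demultiplexing ----------------------------------------------
  hashtag_calls <- NULL
  if ("hashtag" %in% config$stages) {
    hashtag_calls <- purrr::imap_dfr(runs, function(counts, rid) {
      if (!is.null(retained)) {
        counts <- counts[rownames(counts) %in% retained, , drop = FALSE]
      }
      fits <- fit_hashtag_mixtures(counts)
      assign_by_hashtag(counts, fits, config$ratio_threshold) %>%
        dplyr::mutate(run_id = rid)
    })
    readr::write_tsv(hashtag_calls, out_path("hashtag_calls.tsv"))
    report$paths$hashtag <- out_path("hashtag_calls.tsv")
    report$counts$hashtag_cells <- nrow(hashtag_calls)
    report$counts$hashtag_singlets <- sum(hashtag_calls$status == "singlet")
  }

  # ---- genotype demultiplexing ---------------------------------------------
  genotype_calls <- NULL
  if ("genotype" %in% config$stages) {
    ac <- allele_counts
    if (!is.null(retained)) {
      ac <- ac %>% dplyr::filter(.data$cell_id %in% retained)
    }
    panel <- select_informative_snps(pool_allele_counts(ac),
                                     config$snp_min_depth,
                                     config$af_low, config$af_high)
    ac <- ac %>% dplyr::filter(.data$snp_id %in% panel$snp_id)
    if (is.null(hashtag_calls)) {
      abort(paste("The genotype stage needs a provisional per-sample",
                  "assignment; run the hashtag stage."))
    }
    provisional <- hashtag_calls %>%
      dplyr::filter(!is.na(.data$donor_call)) %>%
      dplyr::transmute(.data$cell_id,
                       sample_id = paste(.data$run_id, .data$donor_call,
                                         sep = ":"),
                       donor_id = .data$donor_call)
    sample_counts <- aggregate_counts_by_sample(ac, provisional)
    links <- provisional %>% dplyr::distinct(.data$sample_id, .data$donor_id)
    donor_geno <- withCallingHandlers(
      pool_donor_genotypes(sample_counts, links, config$error_rate,
                           config$min_call_depth),
      warning = function(w) {
        note("genotype", conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    gm <- genotype_matrix(donor_geno, snp_ids = panel$snp_id)
    genotype_calls <- assign_by_genotype(ac, gm, config$error_rate,
                                         config$min_margin,
                                         config$min_informative)
    readr::write_tsv(genotype_calls, out_path("genotype_calls.tsv"))
    readr::write_tsv(donor_geno, out_path("donor_genotypes.tsv"))
    report$paths$genotype <- out_path("genotype_calls.tsv")
    report$counts$snp_panel <- nrow(panel)
    report$counts$genotype_called <- sum(!is.na(genotype_calls$donor_call))
  }

  # ---- consensus ------------------------------------------------------------
  if ("consensus" %in% config$stages) {
    assignments <- consensus_assign(
      hashtag_calls %>% dplyr::select("cell_id", "donor_call"),
      genotype_calls %>% dplyr::select("cell_id", "donor_call")
    )
    crosstab <- consensus_crosstab(assignments)
    readr::write_tsv(assignments, out_path("consensus_assignments.tsv"))
    readr::write_tsv(crosstab, out_path("consensus_crosstab.tsv"))
    report$paths$consensus <- out_path("consensus_assignments.tsv")
    report$counts$consensus <- sum(assignments$status == "consistent")
  }

  # ---- abundance ------------------------------------------------------------
  if ("abundance" %in% config$stages) {
    results <- test_cluster_abundance(cluster_table, alpha = config$alpha)
    readr::write_tsv(results, out_path("abundance_results.tsv"))
    report$paths$abundance <- out_path("abundance_results.tsv")
    report$counts$clusters_tested <- nrow(results)
    report$counts$clusters_significant <- sum(results$significant)
  }

  yaml::write_yaml(report, out_path("report.yaml"))
  report$paths$report <- out_path("report.yaml")
  invisible(report)
}
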