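test_that("SNP selection keeps pool-polymorphic, covered positions", {
  pooled <- tibble::tibble(
    snp_id = c("s1", "s2", "s3", "s4"),
    ref_count = c(100L, 49L, 30L, 60L),
    alt_count = c(0L, 0L, 30L, 40L)
  )
  # s1 monomorphic, s2 below depth (49 < 50), s3 and s4 retained
  panel <- select_informative_snps(pooled, min_depth = 50)
  expect_identical(panel$snp_id, c("s3", "s4"))
  expect_equal(panel$pooled_alt_fraction, c(0.5, 0.4))

  boundary <- tibble::tibble(snp_id = "b", ref_count = 25L, alt_count = 25L)
  expect_identical(nrow(select_informative_snps(boundary, min_depth = 50)), 1L)
})

test_that("most truly polymorphic SNPs survive selection on synthetic pools", {
  cfg <- sim_config(n_runs = 1, donors_per_run = 15, cells_per_donor = 40,
                    n_snps = 200, maf_low = 0.1, maf_high = 0.5,
                    depth_mean = 20, seed = 23)
  e <- simulate_experiment(cfg)
  pooled <- pool_allele_counts(e$runs$run1$allele_counts)
  panel <- select_informative_snps(pooled)
  # truly polymorphic in the pool: donors are not all the same homozygote
  poly <- colnames(e$genotypes)[apply(e$genotypes, 2, function(g) {
    length(unique(g)) > 1 || g[1] == 1L
  })]
  expect_gte(mean(poly %in% panel$snp_id), 0.90)
})

test_that("per-sample aggregation is additive and order-invariant", {
  ac <- tibble::tibble(
    cell_id = c("c1", "c2", "c3"),
    snp_id = "s1",
    ref_count = c(3L, 2L, 7L),
    alt_count = c(1L, 2L, 5L)
  )
  map <- tibble::tibble(cell_id = c("c1", "c2"), sample_id = "A")
  agg <- aggregate_counts_by_sample(ac, map)
  expect_identical(agg$ref_count, 5L)
  expect_identical(agg$alt_count, 3L)

  # single mapped cell: identity; unmapped cells ignored
  one <- aggregate_counts_by_sample(ac, tibble::tibble(cell_id = "c3",
                                                       sample_id = "B"))
  expect_identical(one$ref_count, 7L)

  # permuting rows changes nothing
  agg2 <- aggregate_counts_by_sample(ac[c(3, 1, 2), ], map)
  expect_identical(agg, agg2)

  expect_error(
    aggregate_counts_by_sample(ac, tibble::tibble(cell_id = c("c1", "c1"),
                                                  sample_id = c("A", "B"))),
    "at most once"
  )
})

test_that("genotype calls match the brute-force binomial oracle", {
  counts <- tibble::tibble(
    sample_id = "s", snp_id = c("a", "b", "c"),
    ref_count = c(20L, 10L, 0L), alt_count = c(0L, 10L, 0L)
  )
  calls <- call_genotypes(counts, error_rate = 0.01, min_call_depth = 5)
  expect_identical(calls$genotype, c(0L, 1L, NA_integer_))

  # randomized agreement with the elementwise oracle
  set.seed(31)
  n <- 1000
  depth <- sample(0:30, n, replace = TRUE)
  alt <- rbinom(n, depth, runif(n))
  rc <- tibble::tibble(
    sample_id = "s", snp_id = sprintf("r%04d", seq_len(n)),
    ref_count = as.integer(depth - alt), alt_count = as.integer(alt)
  )
  got <- call_genotypes(rc, error_rate = 0.05, min_call_depth = 1)
  want <- mapply(oracle_genotype_call, rc$ref_count, rc$alt_count,
                 MoreArgs = list(error_rate = 0.05))
  covered <- depth >= 1
  expect_identical(got$genotype[covered], as.integer(want[covered]))
  expect_true(all(is.na(got$genotype[!covered])))
})

test_that("concordance is symmetric and handles missingness", {
  a <- c(0L, 1L, 2L, NA, 1L)
  b <- c(0L, 1L, 0L, 2L, NA)
  cc <- genotype_concordance(a, b)
  expect_equal(cc$concordance, 2 / 3)
  expect_identical(cc$n_shared, 3L)
  expect_identical(genotype_concordance(b, a), cc)

  ident <- genotype_concordance(a, a)
  expect_equal(ident$concordance, 1)

  none <- genotype_concordance(c(NA, 1L), c(2L, NA))
  expect_true(is.na(none$concordance))
  expect_identical(none$n_shared, 0L)
})

# Shared two-run synthetic experiment for the cross-run checks.
two_run_experiment <- function() {
  cfg <- sim_config(n_runs = 2, donors_per_run = 15, cells_per_donor = 40,
                    n_snps = 200, maf_low = 0.1, maf_high = 0.5,
                    depth_mean = 20, error_rate = 0.01, seed = 29)
  simulate_experiment(cfg)
}

sample_counts_from <- function(e) {
  # per-sample (run x true donor) cumulated counts, using singlet truth
  purrr::imap_dfr(e$runs, function(r, rid) {
    singlets <- r$truth[!r$truth$is_doublet, c("cell_id", "donor")]
    aggregate_counts_by_sample(
      r$allele_counts,
      tibble::tibble(cell_id = singlets$cell_id,
                     sample_id = paste(rid, singlets$donor, sep = ":"))
    )
  })
}

test_that("same-donor concordance separates completely from different-donor", {
  e <- two_run_experiment()
  sc <- sample_counts_from(e)
  calls <- call_genotypes(sc)
  gm <- genotype_matrix(calls)
  donor_of <- setNames(sub("^run\\d+:", "", rownames(gm)), rownames(gm))
  pairs <- pairwise_concordance(gm, donor_of)
  same <- pairs$concordance[pairs$same_donor_expected]
  diff <- pairs$concordance[!pairs$same_donor_expected]
  expect_identical(length(same), 15L)
  expect_gt(min(same), max(diff))
})

test_that("pooling across runs reduces missingness and is accurate", {
  e <- two_run_experiment()
  sc <- sample_counts_from(e)
  links <- tibble::tibble(sample_id = unique(sc$sample_id)) |>
    dplyr::mutate(donor_id = sub("^run\\d+:", "", sample_id))

  pooled <- pool_donor_genotypes(sc, links)
  per_sample <- call_genotypes(sc)

  # single run: pooling is the identity on that run's sample genotypes
  r1 <- sc[grepl("^run1:", sc$sample_id), ]
  l1 <- links[grepl("^run1:", links$sample_id), ]
  p1 <- pool_donor_genotypes(r1, l1, validate = FALSE)
  s1 <- call_genotypes(r1) |>
    dplyr::mutate(sample_id = sub("^run1:", "", sample_id)) |>
    dplyr::arrange(sample_id, snp_id)
  expect_identical(p1 |> dplyr::arrange(sample_id, snp_id), s1)

  # pooled missingness <= per-sample missingness (depth adds)
  miss_pooled <- mean(is.na(pooled$genotype))
  miss_sample <- mean(is.na(per_sample$genotype))
  expect_lte(miss_pooled, miss_sample)

  # pooled calls match simulation truth
  gm <- genotype_matrix(pooled, snp_ids = colnames(e$genotypes))
  truth_g <- e$genotypes[rownames(gm), ]
  called <- !is.na(gm)
  expect_gte(mean(gm[called] == truth_g[called]), 0.99)

  # corrupted links are flagged by the concordance check
  bad <- links
  bad$donor_id[bad$sample_id == "run2:donor01"] <- "donor02"
  bad$donor_id[bad$sample_id == "run2:donor02"] <- "donor01"
  expect_warning(pool_donor_genotypes(sc, bad), "Linkage")
})

test_that("cell assignment matches the brute-force likelihood oracle", {
  # alt-only reads at 5 SNPs where donor A is hom-alt and others hom-ref
  g <- rbind(
    dA = rep(2L, 5), dB = rep(0L, 5), dC = rep(0L, 5)
  )
  colnames(g) <- sprintf("s%d", 1:5)
  cell <- tibble::tibble(
    cell_id = "c1", snp_id = colnames(g),
    ref_count = 0L, alt_count = 2L
  )
  call <- assign_by_genotype(cell, g, error_rate = 0.01)
  expect_identical(call$donor_call, "dA")
  ll <- oracle_cell_donor_loglik(cell, g, 0.01)
  expect_equal(call$margin,
               unname(max(ll) - sort(ll, decreasing = TRUE)[2]))

  # zero covered SNPs: below min_informative, null call
  empty <- tibble::tibble(cell_id = "c0", snp_id = character(0),
                          ref_count = integer(0), alt_count = integer(0))
  both <- dplyr::bind_rows(cell, empty)
  expect_true(is.na(assign_by_genotype(
    tibble::tibble(cell_id = "c0", snp_id = "s1", ref_count = 0L,
                   alt_count = 0L), g
  )$donor_call))

  # randomized cells against the oracle
  set.seed(37)
  gm <- simulate_genotypes(6, 30, 0.2, 0.5, seed = 41)
  for (i in 1:25) {
    snps <- sample(colnames(gm), sample(3:10, 1))
    depth <- sample(0:30, length(snps), replace = TRUE)
    alt <- rbinom(length(snps), depth, runif(length(snps)))
    cc <- tibble::tibble(cell_id = "x", snp_id = snps,
                         ref_count = as.integer(depth - alt),
                         alt_count = as.integer(alt))
    got <- assign_by_genotype(cc, gm, error_rate = 0.02, min_margin = 0,
                              min_informative = 1)
    ll <- oracle_cell_donor_loglik(cc, gm, 0.02)
    if (sum(depth) > 0) {
      expect_identical(got$best_donor, names(which.max(ll)))
      expect_equal(got$margin,
                   unname(max(ll) - sort(ll, decreasing = TRUE)[2]),
                   tolerance = 1e-9)
    }
  }
})

test_that("assignment is invariant to SNP order and uninformative loci", {
  e <- two_run_experiment()
  r1 <- e$runs$run1
  sub <- r1$allele_counts[r1$allele_counts$cell_id %in%
                            r1$truth$cell_id[1:50], ]
  g <- e$genotypes

  a1 <- assign_by_genotype(sub, g)
  a2 <- assign_by_genotype(sub[sample(nrow(sub)), ], g[, sample(ncol(g))])
  a1s <- dplyr::arrange(a1, cell_id)
  a2s <- dplyr::arrange(a2, cell_id)
  expect_identical(a1s$donor_call, a2s$donor_call)
  expect_identical(a1s$n_informative, a2s$n_informative)
  # margins agree up to float summation order
  expect_equal(a1s$margin, a2s$margin, tolerance = 1e-12)

  # a locus where every donor shares one genotype changes no ranking
  g_ext <- cbind(g, shared = rep(1L, nrow(g)))
  extra <- dplyr::bind_rows(sub, tibble::tibble(
    cell_id = unique(sub$cell_id), snp_id = "shared",
    ref_count = 5L, alt_count = 5L
  ))
  a3 <- assign_by_genotype(extra, g_ext)
  expect_identical(
    dplyr::arrange(a1, cell_id)$donor_call,
    dplyr::arrange(a3, cell_id)$donor_call
  )
})

test_that("genotype assignment is accurate and improves with depth", {
  e <- two_run_experiment()
  r1 <- e$runs$run1
  gm <- e$genotypes
  calls <- assign_by_genotype(r1$allele_counts, gm)
  scored <- dplyr::inner_join(calls, r1$truth, by = "cell_id")
  singlets <- scored[!scored$is_doublet, ]
  called <- singlets[!is.na(singlets$donor_call), ]
  expect_gte(nrow(called) / nrow(singlets), 0.90) # call rate
  expect_gte(mean(called$donor_call == called$donor), 0.99)

  # accuracy nondecreasing in depth (2, 10, 50) among called singlets
  acc <- sapply(c(2, 10, 50), function(dm) {
    cfg <- sim_config(n_runs = 1, donors_per_run = 8, cells_per_donor = 40,
                      n_snps = 60, depth_mean = dm, doublet_rate = 0,
                      seed = 43)
    ee <- simulate_experiment(cfg)
    cl <- assign_by_genotype(ee$runs$run1$allele_counts, ee$genotypes,
                             min_margin = 0, min_informative = 1)
    sc <- dplyr::inner_join(cl, ee$runs$run1$truth, by = "cell_id")
    mean(sc$donor_call == sc$donor, na.rm = TRUE)
  })
  expect_true(all(diff(acc) >= 0))

  expect_error(assign_by_genotype(r1$allele_counts, gm[0, , drop = FALSE]),
               "donor row")
})
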