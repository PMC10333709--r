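test_that("frequency normalization divides counts by totals exactly", {
  tab <- tibble::tibble(
    sample_id = "s1", cluster_id = c("a", "b", "c"),
    count = c(20L, 30L, 50L), total = 100L
  )
  out <- normalize_frequencies(tab)
  expect_equal(out$proportion, c(0.2, 0.3, 0.5))
  expect_lt(abs(sum(out$proportion) - 1), 1e-9)
  expect_identical(out$proportion * out$total, as.numeric(out$count))

  zero <- normalize_frequencies(tibble::tibble(count = 0L, total = 10L))
  expect_identical(zero$proportion, 0)

  expect_error(normalize_frequencies(tibble::tibble(count = 5L, total = 4L)),
               "exceed")
  expect_error(normalize_frequencies(tibble::tibble(count = 0L, total = 0L)),
               "positive")
})

test_that("switching the denominator rescales proportions by the total ratio", {
  cd45 <- tibble::tibble(
    sample_id = c("s1", "s2"), cluster_id = "a",
    count = c(30L, 40L), total = c(300L, 500L)
  )
  # mononuclear denominator: granulocytes removed from the totals
  mono <- dplyr::mutate(cd45, total = c(200L, 250L))
  p_cd45 <- normalize_frequencies(cd45)$proportion
  p_mono <- normalize_frequencies(mono)$proportion
  expect_equal(p_mono, p_cd45 * cd45$total / mono$total)
})

test_that("the GLMM recovers generating parameters when variances vanish", {
  design <- make_design(12, group = rep("allergic", 12))
  params <- tibble::tibble(cluster_id = "k", beta0 = -2, beta1 = 0.8,
                           sigma_u = 0, sigma_e = 0)
  sim <- simulate_cluster_counts(design, params, total_sampler = 5000,
                                 seed = 61)
  fit <- fit_overdispersed_binomial_glmm(sim$table)
  expect_lt(abs(fit$beta1 - 0.8), 3 * fit$se_beta1)
  se0 <- sqrt(diag(as.matrix(stats::vcov(fit$fit))))[1]
  expect_lt(abs(fit$beta0 - (-2)), 3 * se0)
  expect_lt(fit$sigma_u, 0.1)
  expect_lt(fit$sigma_e, 0.1)
  expect_true(fit$boundary) # zero variances sit on the boundary

  td <- tidy(fit)
  expect_identical(td$term[2], "beta1")
  expect_equal(td$estimate[2], fit$beta1)
  expect_identical(glance(fit)$n_donors, 12L)
})

test_that("separation and thin designs are rejected", {
  design <- make_design(6)
  tab <- design |>
    dplyr::mutate(sample_id = paste(donor_id, timepoint), cluster_id = "k",
                  count = 0L, total = 100L)
  expect_error(fit_overdispersed_binomial_glmm(tab), "separation")
  expect_error(
    fit_overdispersed_binomial_glmm(dplyr::mutate(tab, count = total)),
    "separation"
  )
  expect_error(fit_overdispersed_binomial_glmm(tab[1:4, ]), "donors")
})

test_that("doubling all counts and totals preserves beta1 and shrinks its SE", {
  design <- make_design(10, group = rep("allergic", 10))
  # binomial-noise-dominated regime (modest totals, small sample effect),
  # where doubling the counts genuinely adds evidence about beta1
  params <- tibble::tibble(cluster_id = "k", beta0 = -2, beta1 = 0.5,
                           sigma_u = 0.3, sigma_e = 0.05)
  sim <- simulate_cluster_counts(design, params, total_sampler = 150,
                                 seed = 67)
  f1 <- fit_overdispersed_binomial_glmm(sim$table)
  f2 <- fit_overdispersed_binomial_glmm(
    dplyr::mutate(sim$table, count = 2L * count, total = 2L * total)
  )
  expect_lt(abs(f2$beta1 - f1$beta1), 0.05)
  expect_lt(f2$se_beta1, f1$se_beta1)
})

test_that("the challenge contrast equals beta1 and an EMM oracle", {
  design <- make_design(8, group = rep("allergic", 8))
  params <- tibble::tibble(cluster_id = "k", beta0 = -1.5, beta1 = 0.6,
                           sigma_u = 0.4, sigma_e = 0.2)
  sim <- simulate_cluster_counts(design, params, total_sampler = 2000,
                                 seed = 71)
  fit <- fit_overdispersed_binomial_glmm(sim$table)
  ct <- contrast_challenge(fit)
  # with one two-level factor the EMM contrast is the coefficient
  expect_equal(ct$estimate, fit$beta1, tolerance = 1e-8)
  expect_equal(ct$se, fit$se_beta1, tolerance = 1e-8)
  expect_equal(ct$p_raw, 2 * pnorm(-abs(fit$beta1 / fit$se_beta1)),
               tolerance = 1e-8)

  # independent EMM computation: difference of the two timepoint marginal
  # means of the linear predictor at zero random effects
  X <- unique(stats::model.matrix(~timepoint,
                                  data.frame(timepoint = factor(
                                    c("before", "after"),
                                    levels = c("before", "after")
                                  ))))
  emm_by_hand <- drop((X[2, ] - X[1, ]) %*% lme4::fixef(fit$fit))
  expect_equal(ct$estimate, emm_by_hand, tolerance = 1e-10)
})

test_that("Wald coverage and type-I error are calibrated on simulations", {
  # parameter recovery: 95% CI covers beta1 in >= 90% of replicates
  design <- make_design(30, group = rep("allergic", 30))
  hits <- 0L
  n_rep <- 30L
  for (i in seq_len(n_rep)) {
    sim <- simulate_cluster_counts(
      design,
      tibble::tibble(cluster_id = "k", beta0 = -2, beta1 = 0.8,
                     sigma_u = 0.5, sigma_e = 0.3),
      total_sampler = 2000, seed = 100 + i
    )
    f <- fit_overdispersed_binomial_glmm(sim$table)
    hits <- hits + (abs(f$beta1 - 0.8) <= 1.96 * f$se_beta1)
  }
  expect_gte(hits / n_rep, 0.9 - 1e-9)

  # null rejection rate near the nominal 5%
  rej <- 0L
  n_null <- 60L
  for (i in seq_len(n_null)) {
    sim <- simulate_cluster_counts(
      design,
      tibble::tibble(cluster_id = "k", beta0 = -2, beta1 = 0,
                     sigma_u = 0.5, sigma_e = 0.3),
      total_sampler = 2000, seed = 500 + i
    )
    f <- fit_overdispersed_binomial_glmm(sim$table)
    rej <- rej + (2 * pnorm(-abs(f$beta1 / f$se_beta1)) < 0.05)
  }
  # 3 SE binomial slack around 5% at 60 replicates
  expect_lt(abs(rej / n_null - 0.05), 3 * sqrt(0.05 * 0.95 / n_null))
})

test_that("BH adjustment matches the exhaustive step-up oracle", {
  expect_equal(adjust_bh(0.04)$p_adj, 0.04) # m = 1 identity

  four <- adjust_bh(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(four$p_adj, rep(0.04, 4))

  set.seed(73)
  for (i in 1:50) {
    p <- runif(sample(1:10, 1))
    out <- adjust_bh(p)
    expect_equal(out$p_adj, oracle_bh(p))
    expect_identical(out$significant, out$p_adj < 0.1)
    # adjusted >= raw, monotone in the raw ranking
    expect_true(all(out$p_adj >= out$p_raw))
    o <- order(out$p_raw)
    expect_true(all(diff(out$p_adj[o]) >= -1e-12))
  }

  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH is applied within each group family by the cluster driver", {
  design <- make_design(8)
  params <- tibble::tibble(
    cluster_id = c("k1", "k2"), beta0 = c(-2, -2.5), beta1 = c(1.2, 0),
    sigma_u = 0.3, sigma_e = 0.2
  )
  sim <- simulate_cluster_counts(design, params, total_sampler = 2000,
                                 seed = 79)
  res <- test_cluster_abundance(sim$table)
  expect_identical(nrow(res), 4L) # 2 groups x 2 clusters
  for (g in unique(res$group)) {
    sub <- res[res$group == g, ]
    expect_equal(sub$p_adj, oracle_bh(sub$p_raw))
  }
  expect_identical(res$significant, res$p_adj < 0.1)
})

test_that("signed-rank p values match full enumeration", {
  # constant shift, n = 6: the smallest achievable two-sided p is 2/2^6
  before <- c(1.0, 2.0, 3.0, 4.1, 5.3, 6.9)
  after <- before + 1
  out <- paired_rank_test(before, after)
  expect_identical(out$method, "exact")
  expect_equal(out$p_value, 2 / 2^6)
  expect_equal(out$p_value, oracle_signed_rank_p(before, after))

  set.seed(83)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    b <- rnorm(n)
    a <- rnorm(n)
    got <- paired_rank_test(b, a)
    expect_equal(got$p_value, oracle_signed_rank_p(b, a), tolerance = 1e-12)
  }

  expect_warning(res0 <- paired_rank_test(1:4, 1:4), "undefined")
  expect_true(is.na(res0$p_value))
  expect_error(paired_rank_test(1:3, 1:4), "equal length")
})

test_that("rank-sum p values match full enumeration and are symmetric", {
  set.seed(89)
  for (i in 1:20) {
    x <- rnorm(sample(3:8, 1))
    y <- rnorm(sample(3:8, 1))
    got <- unpaired_rank_test(x, y)
    expect_identical(got$method, "exact")
    expect_equal(got$p_value, oracle_rank_sum_p(x, y), tolerance = 1e-12)
    expect_equal(got$p_value, unpaired_rank_test(y, x)$p_value)
  }
})

test_that("identically distributed groups reject near the nominal rate", {
  set.seed(97)
  n_sim <- 400
  rej <- 0L
  for (i in seq_len(n_sim)) {
    x <- rnorm(12); y <- rnorm(12)
    rej <- rej + (unpaired_rank_test(x, y)$p_value < 0.05)
  }
  expect_lt(abs(rej / n_sim - 0.05), 0.02 + 3 * sqrt(0.05 * 0.95 / n_sim))
})
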