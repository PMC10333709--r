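# Differential cluster-abundance testing: per-sample cluster counts are
# modeled as overdispersed binomial proportions of each sample's total, with
# the allergen challenge (before/after) as fixed effect, the volunteer as a
# donor-level random effect, and a sample-level (observation-level) random
# effect absorbing extra-binomial variation. One model is fitted per cluster
# and group; p values are Benjamini-Hochberg corrected within each family.

#' Normalize cluster counts to per-sample proportions
#'
#' Divides each cluster count by its sample's total (CD45+ or mononuclear
#' denominator) to correct for varying biopsy yields.
#'
#' @param table Tibble with at least `count` and `total` columns (a cluster
#'   frequency table).
#' @return The input with a `proportion` column; `proportion * total`
#'   reproduces `count` exactly.
#' @export
normalize_frequencies <- function(table) {
  check_columns(table, c("count", "total"), "table")
  if (any(table$total <= 0)) abort("All `total` values must be positive.")
  if (any(table$count < 0)) abort("`count` must be non-negative.")
  if (any(table$count > table$total)) {
    abort("`count` must not exceed `total`.")
  }
  table %>% dplyr::mutate(proportion = .data$count / .data$total)
}

#' Fit the overdispersed binomial mixed model for one cluster
#'
#' Fits, by maximum (Laplace-approximated) marginal likelihood,
#' \deqn{count_s \sim Binomial(total_s, logit^{-1}(\beta_0 + \beta_1
#' [timepoint = after] + u_{donor(s)} + e_s)),} with
#' \eqn{u \sim N(0, \sigma_u^2)} (volunteer random effect) and
#' \eqn{e \sim N(0, \sigma_e^2)} a sample-specific (observation-level)
#' random effect that absorbs overdispersion. Intended for the rows of one
#' cluster within one group (models are fitted per cluster and group, not
#' with a group interaction).
#'
#' @param data Tibble with columns `donor_id`, `timepoint`
#'   (`"before"`/`"after"`), `count`, `total`, and optionally `sample_id`
#'   (defaults to one sample per row).
#' @param min_donors Minimum donors with both timepoints (default 4).
#'
#' @return Object of class `cluster_glmm`: the fixed effects `beta0`,
#'   `beta1` (challenge effect, log-odds), `se_beta1`, random-effect sds
#'   `sigma_u`, `sigma_e`, `loglik`, `converged`, `boundary` (a variance
#'   estimated at 0), `n_donors`, `n_samples`, and the underlying
#'   [lme4::glmer()] `fit`. Supports [tidy()] and [glance()].
#' @export
fit_overdispersed_binomial_glmm <- function(data, min_donors = 4) {
  check_columns(data, c("donor_id", "timepoint", "count", "total"), "data")
  bad_tp <- setdiff(unique(data$timepoint), c("before", "after"))
  if (length(bad_tp) > 0) {
    abort(sprintf("`timepoint` must be 'before'/'after'; found: %s.",
                  paste(bad_tp, collapse = ", ")))
  }
  if (any(data$count > data$total)) abort("`count` must not exceed `total`.")
  if (!"sample_id" %in% names(data)) {
    data <- data %>% dplyr::mutate(sample_id = sprintf("s%04d", dplyr::row_number()))
  }
  complete <- data %>%
    dplyr::distinct(.data$donor_id, .data$timepoint) %>%
    dplyr::count(.data$donor_id) %>%
    dplyr::filter(.data$n == 2)
  if (nrow(complete) < min_donors) {
    abort(sprintf("Need >= %d donors observed at both timepoints.", min_donors))
  }
  if (all(data$count == 0) || all(data$count == data$total)) {
    abort("Complete separation: all counts are 0 or all equal their totals.")
  }
  data <- data %>%
    dplyr::mutate(timepoint = factor(.data$timepoint, levels = c("before", "after")))

  fit <- suppressMessages(lme4::glmer(
    cbind(count, total - count) ~ timepoint + (1 | donor_id) + (1 | sample_id),
    data = data, family = stats::binomial()
  ))
  cf <- lme4::fixef(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_u <- vc$sdcor[vc$grp == "donor_id"]
  sigma_e <- vc$sdcor[vc$grp == "sample_id"]
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  msgs <- fit@optinfo$conv$lme4$messages
  converged <- is.null(msgs) ||
    !any(grepl("failed to converge", msgs, ignore.case = TRUE))
  structure(
    list(
      beta0 = unname(cf[1]), beta1 = unname(cf[2]),
      se_beta1 = unname(se[2]),
      sigma_u = sigma_u, sigma_e = sigma_e,
      loglik = as.numeric(stats::logLik(fit)),
      converged = converged,
      boundary = isTRUE(lme4::isSingular(fit)),
      n_donors = dplyr::n_distinct(data$donor_id),
      n_samples = nrow(data),
      fit = fit
    ),
    class = "cluster_glmm"
  )
}

#' @export
print.cluster_glmm <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Overdispersed binomial GLMM (%d donors, %d samples)\n",
      "  challenge effect beta1 = %.4f (SE %.4f), log-odds\n",
      "  intercept beta0 = %.4f; sigma_donor = %.4f; sigma_sample = %.4f\n",
      "  logLik = %.2f%s%s\n"
    ),
    x$n_donors, x$n_samples, x$beta1, x$se_beta1, x$beta0, x$sigma_u,
    x$sigma_e, x$loglik,
    if (x$converged) "" else "  [NOT converged]",
    if (x$boundary) "  [variance at boundary]" else ""
  ))
  invisible(x)
}

#' Challenge contrast from a fitted cluster model
#'
#' Estimated-marginal-means post-hoc contrast of the two timepoints
#' (after - before) on the log-odds scale. With the single two-level fixed
#' factor this equals the fitted challenge coefficient `beta1` with its Wald
#' standard error; the p value is two-sided normal. The EMM machinery is
#' delegated to \pkg{emmeans}.
#'
#' @param fit A `cluster_glmm` from [fit_overdispersed_binomial_glmm()].
#' @return One-row tibble: `estimate`, `se`, `z`, `p_raw`, `converged`. For
#'   a non-converged fit the p value is `NA`.
#' @export
contrast_challenge <- function(fit) {
  stopifnot(inherits(fit, "cluster_glmm"))
  emm <- emmeans::emmeans(fit$fit, ~timepoint)
  ct <- as.data.frame(emmeans::contrast(emm, method = "revpairwise"))
  est <- ct$estimate[1]
  se <- ct$SE[1]
  z <- est / se
  tibble(
    estimate = est, se = se, z = z,
    p_raw = if (fit$converged) 2 * pnorm(-abs(z)) else NA_real_,
    converged = fit$converged
  )
}

#' Benjamini-Hochberg adjustment with a significance flag
#'
#' Step-up false-discovery-rate adjustment (via [stats::p.adjust()]) with
#' significance declared at adjusted p below `alpha` (default 0.1).
#'
#' @param p_values Numeric vector of raw p values in `[0, 1]` (`NA` allowed).
#' @param alpha Significance level on the adjusted scale.
#' @return Tibble `p_raw`, `p_adj`, `significant`.
#' @export
adjust_bh <- function(p_values, alpha = 0.1) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p values must lie in [0, 1].")
  }
  p_adj <- p.adjust(p_values, method = "BH")
  tibble(p_raw = p_values, p_adj = p_adj, significant = !is.na(p_adj) & p_adj < alpha)
}

#' Test the challenge effect for every cluster
#'
#' Pipe-friendly driver: for each (group, cluster) family in a cluster
#' frequency table, fits the overdispersed binomial mixed model, extracts the
#' challenge contrast, and applies Benjamini-Hochberg correction across
#' clusters within each group.
#'
#' @param table Cluster frequency tibble (`sample_id`, `donor_id`, `group`,
#'   `timepoint`, `cluster_id`, `count`, `total`).
#' @param alpha Significance level on the BH-adjusted scale.
#' @param min_donors Passed to [fit_overdispersed_binomial_glmm()].
#' @return Tibble with one row per (group, cluster): model estimates,
#'   `p_raw`, `p_adj`, `significant`, `converged`, `boundary`.
#' @export
#' @examples
#' \donttest{
#' design <- tidyr::expand_grid(
#'   donor_id = sprintf("d%02d", 1:8), timepoint = c("before", "after")
#' ) |> dplyr::mutate(group = "allergic")
#' params <- tibble::tibble(
#'   cluster_id = c("MPS1", "MPS2"), beta0 = c(-2, -3),
#'   beta1 = c(0.8, 0), sigma_u = 0.5, sigma_e = 0.3
#' )
#' sim <- simulate_cluster_counts(design, params, total_sampler = 1500, seed = 9)
#' test_cluster_abundance(sim$table)
#' }
test_cluster_abundance <- function(table, alpha = 0.1, min_donors = 4) {
  check_columns(table, c("donor_id", "group", "timepoint", "cluster_id",
                         "count", "total"), "table")
  table %>%
    dplyr::group_by(.data$group) %>%
    dplyr::group_modify(function(gdat, gkey) {
      res <- gdat %>%
        dplyr::group_by(.data$cluster_id) %>%
        dplyr::group_modify(function(cdat, ckey) {
          fit <- fit_overdispersed_binomial_glmm(cdat, min_donors = min_donors)
          ct <- contrast_challenge(fit)
          tibble(
            beta0 = fit$beta0, beta1 = fit$beta1, se = ct$se, z = ct$z,
            sigma_u = fit$sigma_u, sigma_e = fit$sigma_e,
            p_raw = ct$p_raw, converged = fit$converged,
            boundary = fit$boundary
          )
        }) %>%
        dplyr::ungroup()
      adj <- adjust_bh(res$p_raw, alpha = alpha)
      res %>% dplyr::mutate(p_adj = adj$p_adj, significant = adj$significant)
    }) %>%
    dplyr::ungroup()
}

# Exact two-sided signed-rank p over the 2^n equiprobable sign patterns,
# handling tied absolute differences. Ranks are doubled so midranks become
# integers, and the null distribution of the doubled positive-rank sum is
# built by convolution -- equivalent to full enumeration without the 2^n
# cost. stats::psignrank covers only the tie-free case.
exact_signed_rank_p <- function(d) {
  r2 <- as.integer(round(2 * rank(abs(d))))
  tot <- sum(r2)
  f <- numeric(tot + 1)
  f[1] <- 1
  for (r in r2) {
    g <- f
    g[(r + 1):(tot + 1)] <- g[(r + 1):(tot + 1)] + f[seq_len(tot + 1 - r)]
    f <- g
  }
  f <- f / 2^length(d)
  w2 <- as.integer(round(sum(r2[d > 0])))
  p_le <- sum(f[seq_len(w2 + 1)])
  p_ge <- sum(f[(w2 + 1):(tot + 1)])
  min(1, 2 * min(p_le, p_ge))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided matched-pairs signed-rank test of `after` vs `before`. With at
#' most 25 effective (nonzero-difference) pairs the p value is exact -- the
#' full null distribution over all sign patterns, computed by convolution and
#' valid under tied absolute differences (midranks). Larger samples use the
#' tie-corrected normal approximation. All-zero differences yield `NA` with
#' a warning.
#'
#' @param before,after Paired numeric vectors of equal length.
#' @return One-row tibble: `statistic` (positive-rank sum), `p_value`,
#'   `n_effective`, `method` (`"exact"` or `"normal"`).
#' @export
paired_rank_test <- function(before, after) {
  if (length(before) != length(after)) {
    abort("`before` and `after` must have equal length.")
  }
  d <- after - before
  d <- d[!is.na(d)]
  n_eff <- sum(d != 0)
  if (n_eff == 0) {
    warn("All paired differences are zero; the signed-rank test is undefined.")
    return(tibble(statistic = NA_real_, p_value = NA_real_,
                  n_effective = 0L, method = NA_character_))
  }
  if (n_eff < 3) warn("Fewer than 3 effective pairs; the test has little power.")
  dd <- d[d != 0]
  if (n_eff <= 25) {
    w <- sum(rank(abs(dd))[dd > 0])
    p <- exact_signed_rank_p(dd)
    return(tibble(statistic = w, p_value = p,
                  n_effective = as.integer(n_eff), method = "exact"))
  }
  wt <- suppressWarnings(wilcox.test(after, before, paired = TRUE,
                                     exact = FALSE, correct = TRUE))
  tibble(
    statistic = unname(wt$statistic), p_value = wt$p.value,
    n_effective = as.integer(n_eff), method = "normal"
  )
}

#' Unpaired Mann-Whitney rank test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test. Exact enumeration is used
#' when both groups have at most 25 observations and there are no ties;
#' otherwise a tie-corrected normal approximation.
#'
#' @param x,y Numeric vectors.
#' @return One-row tibble: `statistic`, `p_value`, `method`.
#' @export
unpaired_rank_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) abort("Both groups must be non-empty.")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !ties && length(x) <= 25 && length(y) <= 25
  wt <- suppressWarnings(wilcox.test(x, y, exact = use_exact,
                                     correct = !use_exact))
  tibble(
    statistic = unname(wt$statistic), p_value = wt$p.value,
    method = if (use_exact) "exact" else "normal"
  )
}
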