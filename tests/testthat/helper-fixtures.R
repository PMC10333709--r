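# Shared fixture builders and independent oracles.

# Balanced before/after design for n donors, alternating groups.
make_design <- function(n_donors, group = NULL) {
  donors <- sprintf("d%02d", seq_len(n_donors))
  if (is.null(group)) {
    group <- ifelse(seq_len(n_donors) %% 2 == 0, "allergic", "non-allergic")
  }
  tidyr::expand_grid(donor_id = donors, timepoint = c("before", "after")) |>
    dplyr::left_join(tibble::tibble(donor_id = donors, group = group),
                     by = "donor_id")
}

# Brute-force three-state binomial genotype likelihoods (independent oracle).
oracle_genotype_call <- function(ref, alt, error_rate) {
  depth <- ref + alt
  q <- c(error_rate, 0.5, 1 - error_rate)
  ll <- sapply(q, function(p) dbinom(alt, depth, p, log = TRUE))
  top <- which(ll == max(ll))
  if (2L %in% top) 1L else min(top) - 1L
}

# Brute-force donor log-likelihood for one cell (independent oracle).
oracle_cell_donor_loglik <- function(cell_counts, genotypes, error_rate) {
  q <- c(error_rate, 0.5, 1 - error_rate)
  q <- pmin(pmax(q, 1e-12), 1 - 1e-12)
  sapply(rownames(genotypes), function(d) {
    ll <- 0
    for (k in seq_len(nrow(cell_counts))) {
      g <- genotypes[d, cell_counts$snp_id[k]]
      if (is.na(g)) next
      dep <- cell_counts$ref_count[k] + cell_counts$alt_count[k]
      if (dep == 0) next
      ll <- ll + dbinom(cell_counts$alt_count[k], dep, q[g + 1], log = TRUE)
    }
    ll
  })
}

# Exhaustive Benjamini-Hochberg step-up: adj_i = min over k with p(k) >= p(i)
# ranked >= rank(i) of m * p(k) / k, clipped at 1 (independent oracle).
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  padj <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(o == i)
    padj[i] <- min(1, min(m * p[o[rank_i:m]] / (rank_i:m)))
  }
  padj
}

# Exact two-sided signed-rank p by enumeration of all 2^n sign patterns.
oracle_signed_rank_p <- function(before, after) {
  d <- after - before
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p <- 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs))
  min(p, 1)
}

# Exact two-sided Mann-Whitney p by enumeration of all group assignments.
oracle_rank_sum_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  u_all <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(p, 1)
}
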