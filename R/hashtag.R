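# Hashtag (HTO) demultiplexing: per-hashtag two-component Gaussian mixture on
# log10(count + 1), then donor assignment by a likelihood-ratio rule -- a cell
# is positive for a hashtag when it is at least `ratio_threshold` times more
# likely under the hashtag's high-count (signal) component than under its
# low-count (noise) component, and is assigned to a donor only when exactly
# one hashtag is positive.

#' Fit a two-component Gaussian mixture to one hashtag's log-counts
#'
#' Expectation-maximization fit of a univariate two-component Gaussian
#' mixture, intended for per-hashtag log10(count + 1) distributions, which
#' are bimodal in hashed pools: an ambient noise peak from the cells of all
#' other donors and a signal peak from the hashtag's own donor. The
#' initialization is deterministic (noise mean at the 25th percentile,
#' signal mean at the 95th, both sds at half the pooled sd, signal weight
#' 0.1), chosen for minority-signal mixtures; no RNG is consumed.
#' Components are relabeled after fitting so `mu_hi >= mu_lo`.
#'
#' @param log_counts Numeric vector, typically `log10(count + 1)`; at least
#'   20 observations with nonzero variance.
#' @param tol Convergence tolerance on the change in log-likelihood.
#' @param max_iter Maximum EM iterations; the fit is returned with
#'   `converged = FALSE` if exceeded.
#'
#' @return Object of class `hashtag_gmm`: `mu_lo`, `sigma_lo`, `mu_hi`,
#'   `sigma_hi`, `pi_hi`, `converged`, `n_iter`, `log_likelihood`, `n`, and
#'   the data `x` (kept for plotting). Supports [tidy()], [glance()] and
#'   [ggplot2::autoplot()].
#' @export
#' @examples
#' x <- c(rnorm(900, 1, 0.2), rnorm(100, 2.5, 0.2))
#' fit <- fit_hashtag_gmm(x)
#' glance(fit)
fit_hashtag_gmm <- function(log_counts, tol = 1e-6, max_iter = 500) {
  x <- as.numeric(log_counts)
  if (anyNA(x)) abort("`log_counts` must not contain NA.")
  if (length(x) < 20) abort("Need at least 20 observations to fit the mixture.")
  if (sd(x) == 0) abort("Degenerate input: all log-counts are identical.")
  max_iter <- check_count(max_iter, "max_iter", min = 1L)

  mu <- c(quantile(x, 0.25, names = FALSE), quantile(x, 0.95, names = FALSE))
  if (mu[1] == mu[2]) mu <- range(x)
  s <- rep(max(sd(x) / 2, 1e-3), 2)
  pi_hi <- 0.1
  sigma_floor <- 1e-6

  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d_lo <- (1 - pi_hi) * dnorm(x, mu[1], s[1])
    d_hi <- pi_hi * dnorm(x, mu[2], s[2])
    tot <- d_lo + d_hi
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    r <- d_hi / tot # responsibility of the signal component
    n_hi <- sum(r)
    n_lo <- length(x) - n_hi
    if (n_hi < 1e-8 || n_lo < 1e-8) break # component vanished; keep last params
    mu[2] <- sum(r * x) / n_hi
    mu[1] <- sum((1 - r) * x) / n_lo
    s[2] <- max(sqrt(sum(r * (x - mu[2])^2) / n_hi), sigma_floor)
    s[1] <- max(sqrt(sum((1 - r) * (x - mu[1])^2) / n_lo), sigma_floor)
    pi_hi <- min(max(n_hi / length(x), 1e-8), 1 - 1e-8)
    if (iter >= max_iter) break
  }
  if (mu[2] < mu[1]) { # relabel so the signal component is the high mean
    mu <- rev(mu); s <- rev(s); pi_hi <- 1 - pi_hi
  }
  structure(
    list(
      mu_lo = mu[1], sigma_lo = s[1], mu_hi = mu[2], sigma_hi = s[2],
      pi_hi = pi_hi, converged = converged, n_iter = iter,
      log_likelihood = ll, n = length(x), x = x
    ),
    class = "hashtag_gmm"
  )
}

#' @export
print.hashtag_gmm <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Two-component Gaussian mixture (n = %d)\n",
      "  noise : mu = %.4f, sigma = %.4f  (weight %.3f)\n",
      "  signal: mu = %.4f, sigma = %.4f  (weight %.3f)\n",
      "  logLik = %.3f, %s in %d iterations\n"
    ),
    x$n, x$mu_lo, x$sigma_lo, 1 - x$pi_hi, x$mu_hi, x$sigma_hi, x$pi_hi,
    x$log_likelihood, if (x$converged) "converged" else "NOT converged",
    x$n_iter
  ))
  invisible(x)
}

#' Fit the hashtag mixture for every hashtag of a count matrix
#'
#' @param counts Cells x hashtags count matrix with column names.
#' @param ... Passed to [fit_hashtag_gmm()].
#' @return Named list of `hashtag_gmm` fits, one per hashtag column.
#' @export
fit_hashtag_mixtures <- function(counts, ...) {
  if (is.null(colnames(counts))) abort("`counts` must have hashtag column names.")
  fits <- purrr::map(
    seq_len(ncol(counts)),
    function(j) fit_hashtag_gmm(log10(counts[, j] + 1), ...)
  )
  setNames(fits, colnames(counts))
}

# Posterior odds of the signal vs noise component at log-count x. With
# weighted = TRUE the components are weighted by the fitted mixing
# proportions (the default: a donor's positives are a minority of the pooled
# cells); weighted = FALSE gives the plain density ratio.
hashtag_log_odds <- function(x, fit, weighted = TRUE) {
  lo <- dnorm(x, fit$mu_hi, fit$sigma_hi, log = TRUE) -
    dnorm(x, fit$mu_lo, fit$sigma_lo, log = TRUE)
  if (weighted) lo <- lo + log(fit$pi_hi) - log(1 - fit$pi_hi)
  lo
}

#' Assign cells to donors from hashtag counts
#'
#' A hashtag is called positive for a cell when the fitted signal component
#' explains the cell's log-count at least `ratio_threshold` times better than
#' the noise component (inclusive: odds exactly equal to the threshold are
#' positive; the comparison carries a 1e-9 tolerance on the log scale so the
#' boundary is robust to floating-point rounding). A cell is assigned to a
#' donor only when exactly one hashtag is positive; cells with zero positives
#' are `"negative"` and cells with two or more are `"multiplet"` -- both
#' carry `NA` donor calls and are excluded from downstream donor-level
#' analyses.
#'
#' @param counts Cells x hashtags matrix of non-negative counts with row
#'   (cell) and column (hashtag) names.
#' @param fits Named list of `hashtag_gmm` fits covering every column of
#'   `counts`, e.g. from [fit_hashtag_mixtures()].
#' @param ratio_threshold Minimum signal/noise odds for positivity.
#' @param weighted Weight the odds by the fitted mixing proportions
#'   (default); `FALSE` uses the unweighted density ratio.
#'
#' @return Tibble: `cell_id`, `donor_call` (`NA` unless exactly one
#'   positive), `n_positive`, `positive_hashtags` (comma-separated),
#'   `status` (`"singlet"`, `"negative"`, `"multiplet"`).
#' @export
assign_by_hashtag <- function(counts, fits, ratio_threshold = 3,
                              weighted = TRUE) {
  if (is.null(colnames(counts))) abort("`counts` must have hashtag column names.")
  missing_fit <- setdiff(colnames(counts), names(fits))
  if (length(missing_fit) > 0) {
    abort(sprintf("No mixture fit supplied for hashtag(s): %s.",
                  paste(missing_fit, collapse = ", ")))
  }
  if (any(counts < 0)) abort("`counts` must be non-negative.")
  ratio_threshold <- check_positive(ratio_threshold, "ratio_threshold")
  cell_id <- rownames(counts)
  if (is.null(cell_id)) cell_id <- sprintf("cell%05d", seq_len(nrow(counts)))

  x <- log10(counts + 1)
  log_thr <- log(ratio_threshold) - 1e-9 # inclusive boundary
  pos <- vapply(
    colnames(counts),
    function(h) hashtag_log_odds(x[, h], fits[[h]], weighted) >= log_thr,
    logical(nrow(counts))
  )
  pos <- matrix(pos, nrow = nrow(counts),
                dimnames = list(cell_id, colnames(counts)))
  n_positive <- as.integer(rowSums(pos))
  donor_call <- ifelse(
    n_positive == 1L,
    colnames(counts)[max.col(pos, ties.method = "first")],
    NA_character_
  )
  tibble(
    cell_id = cell_id,
    donor_call = donor_call,
    n_positive = n_positive,
    positive_hashtags = apply(pos, 1, function(p) {
      paste(colnames(counts)[p], collapse = ",")
    }),
    status = dplyr::case_when(
      n_positive == 0L ~ "negative",
      n_positive == 1L ~ "singlet",
      TRUE ~ "multiplet"
    )
  )
}

#' Histogram of the number of positive hashtags per cell
#'
#' @param calls Tibble from [assign_by_hashtag()].
#' @return Tibble `n_positive`, `n_cells`, `fraction`; bin counts sum to the
#'   number of cells.
#' @export
summarize_hashtag_positivity <- function(calls) {
  check_columns(calls, "n_positive", "calls")
  calls %>%
    dplyr::count(.data$n_positive, name = "n_cells") %>%
    dplyr::arrange(.data$n_positive) %>%
    dplyr::mutate(fraction = .data$n_cells / sum(.data$n_cells))
}
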