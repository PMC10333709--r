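# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a hashtag mixture fit
#'
#' @param x A `hashtag_gmm` from [fit_hashtag_gmm()].
#' @param ... Unused.
#' @return Tibble with one row per mixture component (`noise`, `signal`):
#'   `component`, `mean`, `sd`, `weight`.
#' @method tidy hashtag_gmm
#' @export
tidy.hashtag_gmm <- function(x, ...) {
  tibble(
    component = c("noise", "signal"),
    mean = c(x$mu_lo, x$mu_hi),
    sd = c(x$sigma_lo, x$sigma_hi),
    weight = c(1 - x$pi_hi, x$pi_hi)
  )
}

#' @rdname tidy.hashtag_gmm
#' @return `glance()`: one-row tibble `n`, `log_likelihood`, `n_iter`,
#'   `converged`.
#' @method glance hashtag_gmm
#' @export
glance.hashtag_gmm <- function(x, ...) {
  tibble(
    n = x$n, log_likelihood = x$log_likelihood,
    n_iter = x$n_iter, converged = x$converged
  )
}

#' Tidy a cluster abundance mixed-model fit
#'
#' @param x A `cluster_glmm` from [fit_overdispersed_binomial_glmm()].
#' @param ... Unused.
#' @return Tibble with one row per model term (`beta0`, `beta1`, and the two
#'   random-effect sds), with estimates and (for `beta1`) the Wald SE.
#' @method tidy cluster_glmm
#' @export
tidy.cluster_glmm <- function(x, ...) {
  tibble(
    term = c("beta0", "beta1", "sigma_donor", "sigma_sample"),
    estimate = c(x$beta0, x$beta1, x$sigma_u, x$sigma_e),
    std.error = c(NA_real_, x$se_beta1, NA_real_, NA_real_)
  )
}

#' @rdname tidy.cluster_glmm
#' @return `glance()`: one-row tibble `n_donors`, `n_samples`, `loglik`,
#'   `converged`, `boundary`.
#' @method glance cluster_glmm
#' @export
glance.cluster_glmm <- function(x, ...) {
  tibble(
    n_donors = x$n_donors, n_samples = x$n_samples, loglik = x$loglik,
    converged = x$converged, boundary = x$boundary
  )
}
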