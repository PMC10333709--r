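#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

# Argument checks ------------------------------------------------------------

check_count <- function(x, name, min = 0L) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x != as.integer(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1, open_hi = FALSE) {
  ok <- length(x) == 1 && is.numeric(x) && !is.na(x) && x >= lo &&
    (if (open_hi) x < hi else x <= hi)
  if (!ok) {
    abort(sprintf(
      "`%s` must be a single number in [%g, %g%s.", name, lo, hi,
      if (open_hi) ")" else "]"
    ))
  }
  as.numeric(x)
}

check_positive <- function(x, name) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", name))
  }
  as.numeric(x)
}

check_columns <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "`%s` is missing required column(s): %s.", name,
      paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# Seed substreams ------------------------------------------------------------

# Deterministic per-stage seed derived from the master seed and a stage label,
# so no stage consults (or perturbs) global RNG state. Kept below 2^31.
derive_seed <- function(seed, label) {
  stopifnot(length(seed) == 1, is.numeric(seed))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

logit <- stats::qlogis

#' @importFrom stats plogis dnorm dbinom rnorm rbinom rpois runif rbeta rlnorm
#'   quantile sd pnorm p.adjust wilcox.test setNames
NULL
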