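#' Tidy a fitted survival model
#'
#' One row per model parameter with posterior mean, sd, central credible
#' interval, split-Rhat and minimum per-chain effective sample size.
#'
#' @param x A `camcr_fit`.
#' @param conf_level Credible interval mass.
#' @param ... Unused.
#' @returns A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `rhat`, `ess_per_chain`.
#' @export
tidy.camcr_fit <- function(x, conf_level = 0.95, ...) {
  a <- (1 - conf_level) / 2
  qs <- apply(x$draws, 2, quantile, probs = c(a, 1 - a))
  tibble::tibble(
    term = colnames(x$draws),
    estimate = unname(colMeans(x$draws)),
    std.error = unname(apply(x$draws, 2, sd)),
    conf.low = unname(qs[1, ]),
    conf.high = unname(qs[2, ]),
    rhat = x$diagnostics$rhat,
    ess_per_chain = x$diagnostics$ess_per_chain
  )
}

#' @rdname tidy.camcr_fit
#' @returns `glance()` returns a one-row tibble with run sizes, `max_rhat`,
#'   `min_ess_per_chain`, `converged` and runtime.
#' @export
glance.camcr_fit <- function(x, ...) {
  tibble::tibble(
    n_site_years = nrow(x$site_years),
    n_nests = ncol(x$y),
    n_chains = x$mcmc$n_chains,
    n_draws = nrow(x$draws),
    max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
    min_ess_per_chain = min(x$diagnostics$ess_per_chain, na.rm = TRUE),
    converged = max(x$diagnostics$rhat, na.rm = TRUE) < x$mcmc$rhat_threshold,
    runtime_s = x$runtime
  )
}

#' Full posterior draws in long format
#'
#' @param x A `camcr_fit` or `camcr_reg`.
#' @returns Tibble with columns `draw` (within chain), `chain`,
#'   `parameter`, `value`.
#' @export
posterior_draws <- function(x) {
  stopifnot(inherits(x, c("camcr_fit", "camcr_reg")))
  n <- nrow(x$draws)
  per_chain <- n / length(unique(x$chain))
  tibble::tibble(
    draw = rep(rep(seq_len(per_chain), times = length(unique(x$chain))),
               times = ncol(x$draws)),
    chain = rep(x$chain, times = ncol(x$draws)),
    parameter = rep(colnames(x$draws), each = n),
    value = as.numeric(x$draws)
  )
}

#' Tidy a driver regression fit
#'
#' @param x A `camcr_reg`.
#' @param conf_level Credible interval mass.
#' @param ... Unused.
#' @returns One row per parameter (`alpha`, `beta`, `sigma`) with posterior
#'   median (`estimate`), mean, sd and central credible interval. The
#'   median is reported as the point estimate for comparability with
#'   slope summaries conventionally reported as "median \[95% CI\]".
#' @export
tidy.camcr_reg <- function(x, conf_level = 0.95, ...) {
  a <- (1 - conf_level) / 2
  pars <- x$draws[, c("alpha", "beta", "sigma"), drop = FALSE]
  qs <- apply(pars, 2, quantile, probs = c(a, 1 - a))
  tibble::tibble(
    term = colnames(pars),
    estimate = unname(apply(pars, 2, median)),
    mean = unname(colMeans(pars)),
    std.error = unname(apply(pars, 2, sd)),
    conf.low = unname(qs[1, ]),
    conf.high = unname(qs[2, ])
  )
}

#' @rdname tidy.camcr_reg
#' @export
glance.camcr_reg <- function(x, ...) {
  tibble::tibble(
    covariate = x$covariate,
    n = x$n,
    beta_median = median(x$draws[, "beta"]),
    beta_low = unname(quantile(x$draws[, "beta"], 0.025)),
    beta_high = unname(quantile(x$draws[, "beta"], 0.975)),
    max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
    min_ess_per_chain = min(x$diagnostics$ess_per_chain, na.rm = TRUE)
  )
}

#' Tidy a Friedman test result
#'
#' @param x A `camcr_friedman`.
#' @param ... Unused.
#' @returns One-row tibble with `statistic`, `df`, `p.value`, `n_blocks`,
#'   `k_treatments`, `ties_corrected`.
#' @export
tidy.camcr_friedman <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p_value,
                 n_blocks = x$n_blocks, k_treatments = x$k_treatments,
                 ties_corrected = x$ties_corrected)
}
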