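#' Exact marginal log-likelihood of one nest's observation series
#'
#' Marginalizes the latent chick count (0, 1 or 2) out of the state-space
#' model by a forward recursion over the three latent states: transitions
#' are `Binomial(z_t | z_{t-1}, phi)` from the fixed initial state
#' `z_1 = 2`, and each non-missing observation contributes
#' `Binomial(y_t | z_t, p_t)`. Missing days contribute no observation
#' factor. This is exact (equivalent to summing over all `3^T` latent
#' paths) and makes the discrete latent states unnecessary during
#' sampling.
#'
#' @param y Integer vector of daily counts (0, 1, 2 or `NA`).
#' @param phi Daily survival probability in `[0, 1]`.
#' @param p Detection probabilities, recycled to `length(y)`.
#' @returns Log marginal likelihood (scalar; `-Inf` for impossible data).
#' @examples
#' nest_marginal_loglik(c(NA, 2), phi = 0.9, p = 0.8)  # log(0.9^2 * 0.8^2)
#' @export
nest_marginal_loglik <- function(y, phi, p) {
  if (any(!is.na(y) & !(y %in% 0:2)))
    stop("observed counts must be 0, 1 or 2 (clutch cap)")
  if (!is.finite(phi) || phi < 0 || phi > 1)
    stop("phi must be a probability")
  p <- rep_len(p, length(y))
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p must be probabilities")
  nest_loglik_cpp(as.integer(y), phi, as.numeric(p))
}

#' Prior specification for the survival model
#'
#' Normal priors on the logit-scale location parameters and half-Normal
#' priors on the hierarchical standard deviations. Daily egg/chick survival
#' in long-lived seabirds sits far into the upper logit range (a daily
#' survival of 0.995 is logit 5.3), so the grand-mean survival prior is a
#' wide `N(0, 5^2)` that keeps that regime in its bulk; the detection-scale
#' location priors use sd 1.5, which covers detection probabilities from
#' about 0.05 to 0.95 at one sd.
#'
#' @param theta_phi_sd,mu_p_sd,mu_beta_p_sd Normal prior sds (mean 0).
#' @param sigma_mu_phi_scale,sigma_beta_p_scale,sigma_nu_p_scale
#'   Half-Normal scales.
#' @returns A `survival_priors` list.
#' @export
survival_priors <- function(theta_phi_sd = 5, mu_p_sd = 1.5,
                            mu_beta_p_sd = 1.5, sigma_mu_phi_scale = 1,
                            sigma_beta_p_scale = 1, sigma_nu_p_scale = 1) {
  structure(list(theta_phi_sd = theta_phi_sd, mu_p_sd = mu_p_sd,
                 mu_beta_p_sd = mu_beta_p_sd,
                 sigma_mu_phi_scale = sigma_mu_phi_scale,
                 sigma_beta_p_scale = sigma_beta_p_scale,
                 sigma_nu_p_scale = sigma_nu_p_scale),
            class = "survival_priors")
}

#' MCMC configuration
#'
#' Desk-scale defaults (4 chains of 1500 warmup plus 10 500 post-warmup
#' iterations thinned by 7) converge on synthetic datasets of a few
#' site/years in under a minute. `preset = "production"` mirrors the full-data settings used for
#' multi-season camera-network analyses (6 chains, 400 000 warmup, 400 000
#' draws thinned by 100) and is only sensible for long compute budgets.
#'
#' @param n_chains,n_warmup,n_samples,thin MCMC run lengths; `n_samples` is
#'   the number of post-warmup iterations per chain before thinning.
#' @param rng_seed Integer seed; chain c uses `rng_seed + c`.
#' @param rhat_threshold Split-Rhat warning threshold.
#' @param min_ess_per_chain ESS-per-chain warning threshold.
#' @param preset `"desk"` (default) or `"production"`.
#' @returns An `mcmc_config` list.
#' @export
mcmc_config <- function(n_chains = 4, n_warmup = 1500, n_samples = 10500,
                        thin = 7, rng_seed = 1L, rhat_threshold = 1.1,
                        min_ess_per_chain = 100, preset = c("desk", "production")) {
  preset <- match.arg(preset)
  if (preset == "production") {
    n_chains <- 6; n_warmup <- 400000; n_samples <- 400000; thin <- 100
  }
  stopifnot(n_chains >= 1, n_warmup >= 0, n_samples >= 1, thin >= 1,
            rhat_threshold > 1)
  structure(list(n_chains = as.integer(n_chains),
                 n_warmup = as.integer(n_warmup),
                 n_samples = as.integer(n_samples), thin = as.integer(thin),
                 rng_seed = as.integer(rng_seed),
                 rhat_threshold = rhat_threshold,
                 min_ess_per_chain = min_ess_per_chain, preset = preset),
            class = "mcmc_config")
}

# Assemble the y matrix stack and site/year index from heterogeneous input.
as_model_data <- function(data) {
  series <- NULL
  if (inherits(data, "sim_dataset")) {
    series <- lapply(data$sims, function(s)
      list(y = s$y, site_id = s$site_id, year_id = s$year_id,
           nest_ids = sprintf("nest%03d", seq_len(ncol(s$y)))))
  } else if (inherits(data, "obs_series")) {
    series <- list(list(y = data$y, site_id = data$site_id,
                        year_id = data$year_id, nest_ids = data$nest_ids))
  } else if (is.list(data) && all(vapply(data, inherits, TRUE, "obs_series"))) {
    series <- lapply(data, function(s)
      list(y = s$y, site_id = s$site_id, year_id = s$year_id,
           nest_ids = s$nest_ids))
  } else if (is.data.frame(data)) {
    need <- c("site_id", "year_id", "nest_id", "t", "count")
    if (!all(need %in% names(data)))
      stop("long-format data needs columns: ", paste(need, collapse = ", "))
    series <- data |>
      dplyr::group_by(.data$site_id, .data$year_id) |>
      dplyr::group_map(function(d, key) {
        nest_ids <- sort(unique(d$nest_id))
        Tt <- max(d$t)
        y <- matrix(NA_integer_, Tt, length(nest_ids))
        y[cbind(d$t, match(d$nest_id, nest_ids))] <- as.integer(d$count)
        list(y = y, site_id = key$site_id, year_id = key$year_id,
             nest_ids = nest_ids)
      })
  } else {
    stop("unsupported data type for fit_survival_model()")
  }
  Ts <- vapply(series, function(s) nrow(s$y), 1L)
  if (length(unique(Ts)) != 1)
    stop("all observation series must have the same length")
  for (s in series) {
    if (all(is.na(s$y)))
      stop("site/year ", s$site_id, "/", s$year_id,
           " has zero observed values; exclude it before fitting")
  }
  y <- do.call(cbind, lapply(series, `[[`, "y"))
  sy <- rep(seq_along(series) - 1L, vapply(series, function(s) ncol(s$y), 1L))
  site_years <- purrr::map_dfr(seq_along(series), function(j) {
    tibble::tibble(j = j, site_id = as.character(series[[j]]$site_id),
                   year_id = as.character(series[[j]]$year_id),
                   n_nests = ncol(series[[j]]$y))
  })
  nests <- purrr::map_dfr(seq_along(series), function(j) {
    tibble::tibble(j = j, nest_id = as.character(series[[j]]$nest_ids))
  })
  list(y = y, sy = sy, site_years = site_years, nests = nests,
       T_days = nrow(y))
}

#' Fit the hierarchical state-space survival model
#'
#' Fits the Bayesian capture-recapture model for nest-level chick counts:
#' daily binomial survival with one logit-scale rate per site/year drawn
#' from a common Normal, and binomial detection whose logit is a global
#' intercept plus a nest-level offset plus a site/year slope on the
#' rescaled day index. Discrete latent chick counts are marginalized by an
#' exact 3-state forward recursion; latent trajectories used for derived
#' quantities are recovered by backward sampling (FFBS) at every retained
#' draw. Sampling uses adaptive Metropolis-within-Gibbs with conjugate
#' Gibbs updates for the hierarchical means.
#'
#' @param data A `sim_dataset`, an `obs_series`, a list of `obs_series`, or
#'   a long tibble with columns `site_id`, `year_id`, `nest_id`, `t`,
#'   `count`.
#' @param priors A [survival_priors()].
#' @param mcmc An [mcmc_config()].
#' @param save_z Keep per-draw total-chick trajectories (needed for
#'   [total_chicks()] and [breeding_success()]).
#' @returns A `camcr_fit` object with elements `draws` (iterations x
#'   parameters matrix), `chain` (chain id per row), `Z` (draws x day x
#'   site/year array of total chicks), `site_years`, `diagnostics` (tibble
#'   with split-Rhat and ESS per parameter), `priors`, `mcmc`.
#' @seealso [tidy.camcr_fit()], [glance.camcr_fit()], [breeding_success()]
#' @export
fit_survival_model <- function(data, priors = survival_priors(),
                               mcmc = mcmc_config(), save_z = TRUE) {
  stopifnot(inherits(priors, "survival_priors"), inherits(mcmc, "mcmc_config"))
  md <- as_model_data(data)
  J <- nrow(md$site_years)
  N <- ncol(md$y)
  x <- detection_time_covariate(md$T_days)

  par_names <- c("theta_phi", "sigma_mu_phi", "mu_p", "mu_beta_p",
                 "sigma_beta_p", "sigma_nu_p",
                 sprintf("mu_phi[%d]", seq_len(J)),
                 sprintf("beta_p[%d]", seq_len(J)),
                 sprintf("nu_p[%d]", seq_len(N)))

  chains <- vector("list", mcmc$n_chains)
  Zs <- vector("list", mcmc$n_chains)
  t0 <- Sys.time()
  for (c in seq_len(mcmc$n_chains)) {
    set.seed(mcmc$rng_seed + c)
    init <- list(
      theta_phi = rnorm(1, 3.5, 0.5),
      sigma_mu_phi = runif(1, 0.3, 1),
      mu_p = rnorm(1, 0.5, 0.5),
      mu_beta_p = rnorm(1, 1, 0.5),
      sigma_beta_p = runif(1, 0.3, 1),
      sigma_nu_p = runif(1, 0.3, 1),
      mu_phi = rnorm(J, 3.5, 0.5),
      beta_p = rnorm(J, 1, 0.5),
      nu_p = rnorm(N, 0, 0.3)
    )
    res <- ssm_mcmc_chain(md$y, md$sy, x, unclass(priors), init,
                          mcmc$n_warmup, mcmc$n_samples, mcmc$thin, save_z)
    colnames(res$draws) <- par_names
    chains[[c]] <- res$draws
    if (save_z) Zs[[c]] <- res$Z
  }
  runtime <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  draws <- do.call(rbind, chains)
  chain_id <- rep(seq_len(mcmc$n_chains), each = nrow(chains[[1]]))
  Z <- NULL
  if (save_z) {
    Z <- array(NA_integer_, dim = c(nrow(draws), md$T_days, J))
    off <- 0
    for (c in seq_len(mcmc$n_chains)) {
      n_c <- dim(Zs[[c]])[1]
      Z[off + seq_len(n_c), , ] <- Zs[[c]]
      off <- off + n_c
    }
  }

  diagnostics <- mcmc_diagnostics(draws, chain_id)
  fit <- structure(
    list(draws = draws, chain = chain_id, Z = Z,
         site_years = md$site_years, nests = md$nests,
         T_days = md$T_days, x = x, y = md$y, sy = md$sy,
         diagnostics = diagnostics, priors = priors, mcmc = mcmc,
         runtime = runtime),
    class = "camcr_fit"
  )
  max_rhat <- max(diagnostics$rhat, na.rm = TRUE)
  min_ess <- min(diagnostics$ess_per_chain, na.rm = TRUE)
  if (is.finite(max_rhat) && max_rhat >= mcmc$rhat_threshold) {
    warning(sprintf(
      "convergence not reached: max split-Rhat = %.3f (threshold %.2f); %s",
      max_rhat, mcmc$rhat_threshold,
      paste(head(diagnostics$parameter[order(-diagnostics$rhat)], 3),
            collapse = ", ")), call. = FALSE)
  } else if (is.finite(min_ess) && min_ess < mcmc$min_ess_per_chain) {
    warning(sprintf("low effective sample size: min ESS/chain = %.0f", min_ess),
            call. = FALSE)
  }
  fit
}

#' @export
print.camcr_fit <- function(x, ...) {
  g <- glance(x)
  cat("<camcr_fit>", nrow(x$site_years), "site/years,",
      ncol(x$y), "nests,", x$T_days, "days\n")
  cat(sprintf("  %d chains x %d draws; max Rhat %.3f, min ESS/chain %.0f\n",
              g$n_chains, g$n_draws, g$max_rhat, g$min_ess_per_chain))
  invisible(x)
}

# ---- convergence diagnostics ----

# Split-Rhat: each chain halved, then the usual between/within variance
# ratio across the 2*n_chains half-chains.
split_rhat <- function(x, chain_id) {
  halves <- list()
  for (c in unique(chain_id)) {
    v <- x[chain_id == c]
    h <- length(v) %/% 2
    halves <- c(halves, list(v[seq_len(h)], v[h + seq_len(h)]))
  }
  m <- length(halves)
  n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(halves, mean, 1.0)
  vars <- vapply(halves, var, 1.0)
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(1.0)
  sqrt(((n - 1) / n * W + B / n) / W)
}

mcmc_diagnostics <- function(draws, chain_id) {
  ess_pc <- vapply(seq_len(ncol(draws)), function(k) {
    min(vapply(unique(chain_id), function(c) {
      v <- draws[chain_id == c, k]
      if (var(v) == 0) return(length(v))
      as.numeric(coda::effectiveSize(v))
    }, 1.0))
  }, 1.0)
  tibble::tibble(
    parameter = colnames(draws),
    mean = colMeans(draws),
    sd = apply(draws, 2, sd),
    rhat = apply(draws, 2, split_rhat, chain_id = chain_id),
    ess_per_chain = ess_pc
  )
}

# ---- derived quantities ----

sy_index <- function(fit, site_id, year_id = NULL) {
  sys <- fit$site_years
  hit <- if (is.null(year_id)) which(sys$site_id == site_id)
  else which(sys$site_id == site_id & sys$year_id == year_id)
  if (length(hit) != 1)
    stop("unknown or ambiguous site/year: ", site_id,
         if (!is.null(year_id)) paste0("/", year_id))
  hit
}

#' Total-chick trajectory draws for one site/year
#'
#' The total number of chicks alive on each day, summed over nests, per
#' posterior draw (latent states recovered by backward sampling). With
#' `summarise = TRUE` returns the posterior mean and sd per day — the
#' ribbon representation used for seasonal trajectory plots. On day 1 the
#' total is exactly twice the number of nests (two-egg clutches) with zero
#' variance.
#'
#' @param fit A [fit_survival_model()] result with `save_z = TRUE`.
#' @param site_id,year_id Site/year selector (year may be omitted when
#'   unambiguous).
#' @param summarise Return per-day summaries instead of draws.
#' @returns Tibble: either `t`, `Z_mean`, `Z_sd` or `draw`, `t`, `Z`.
#' @export
total_chicks <- function(fit, site_id, year_id = NULL, summarise = TRUE) {
  stopifnot(inherits(fit, "camcr_fit"))
  if (is.null(fit$Z)) stop("fit was run with save_z = FALSE")
  j <- sy_index(fit, site_id, year_id)
  Zj <- fit$Z[, , j, drop = TRUE]
  if (summarise) {
    tibble::tibble(t = seq_len(fit$T_days),
                   Z_mean = colMeans(Zj),
                   Z_sd = apply(Zj, 2, sd))
  } else {
    tibble::tibble(draw = rep(seq_len(nrow(Zj)), times = fit$T_days),
                   t = rep(seq_len(fit$T_days), each = nrow(Zj)),
                   Z = as.integer(Zj))
  }
}

#' Breeding success (chicks per pair) per site/year
#'
#' Derived per posterior draw as the total chicks alive on the final day
#' divided by the number of nests; bounded in `[0, 2]` for a two-egg
#' clutch.
#'
#' @param fit A [fit_survival_model()] result with `save_z = TRUE`.
#' @param summarise Return per-site/year posterior mean and sd (default)
#'   or all draws.
#' @returns Tibble with `site_id`, `year_id`, and either `bs_mean`,
#'   `bs_sd` or `draw`, `bs`.
#' @export
breeding_success <- function(fit, summarise = TRUE) {
  stopifnot(inherits(fit, "camcr_fit"))
  if (is.null(fit$Z)) stop("fit was run with save_z = FALSE")
  out <- purrr::map_dfr(seq_len(nrow(fit$site_years)), function(j) {
    bs <- fit$Z[, fit$T_days, j] / fit$site_years$n_nests[j]
    if (summarise) {
      tibble::tibble(site_id = fit$site_years$site_id[j],
                     year_id = fit$site_years$year_id[j],
                     n_nests = fit$site_years$n_nests[j],
                     bs_mean = mean(bs), bs_sd = sd(bs))
    } else {
      tibble::tibble(site_id = fit$site_years$site_id[j],
                     year_id = fit$site_years$year_id[j],
                     draw = seq_along(bs), bs = bs)
    }
  })
  out
}

#' Posterior predictive check
#'
#' Replicates datasets from posterior parameter draws (latent trajectories
#' re-simulated from the fitted survival rates, observations re-drawn with
#' the fitted detection curves, missingness pattern copied from the data)
#' and compares a discrepancy statistic between replicates and data.
#' The Bayesian p-value is the proportion of replicates whose statistic is
#' at least the observed one; values near 0 or 1 indicate misfit.
#'
#' @param fit A [fit_survival_model()] result.
#' @param statistic `"total_count"` (sum of all observed counts) or
#'   `"daily_total"` (per-day sums; returns one p-value per day plus the
#'   overall one) or `"n_detections"` (number of non-missing cells with a
#'   chick seen).
#' @param n_rep Number of replicate datasets (posterior draws are
#'   subsampled evenly).
#' @returns A `camcr_ppc` list with `p_value`, the observed statistic, the
#'   replicate statistics, and (for `"daily_total"`) a per-day tibble.
#' @export
posterior_predictive_check <- function(fit, statistic = c("total_count",
                                                          "daily_total",
                                                          "n_detections"),
                                       n_rep = 200) {
  stopifnot(inherits(fit, "camcr_fit"))
  statistic <- match.arg(statistic)
  y <- fit$y
  Tt <- fit$T_days
  N <- ncol(y)
  miss <- is.na(y)
  idx <- unique(round(seq(1, nrow(fit$draws), length.out = n_rep)))
  J <- nrow(fit$site_years)

  stat_total <- function(m) sum(m, na.rm = TRUE)
  stat_daily <- function(m) rowSums(m, na.rm = TRUE)
  stat_ndet <- function(m) sum(!is.na(m) & m > 0)

  obs_total <- stat_total(y)
  obs_daily <- stat_daily(y)
  obs_ndet <- stat_ndet(y)

  rep_total <- numeric(length(idx))
  rep_daily <- matrix(0, length(idx), Tt)
  rep_ndet <- numeric(length(idx))
  for (r in seq_along(idx)) {
    d <- idx[r]
    phi_j <- plogis(fit$draws[d, sprintf("mu_phi[%d]", seq_len(J))])
    mu_p <- fit$draws[d, "mu_p"]
    beta_j <- fit$draws[d, sprintf("beta_p[%d]", seq_len(J))]
    nu <- fit$draws[d, sprintf("nu_p[%d]", seq_len(N))]
    z <- matrix(2L, Tt, N)
    for (t in 2:Tt) z[t, ] <- rbinom(N, z[t - 1, ], phi_j[fit$sy + 1])
    p <- plogis(outer(fit$x, beta_j[fit$sy + 1]) +
                  matrix(mu_p + nu, Tt, N, byrow = TRUE))
    yrep <- matrix(rbinom(Tt * N, z, p), Tt, N)
    yrep[miss] <- NA_integer_
    rep_total[r] <- stat_total(yrep)
    rep_daily[r, ] <- stat_daily(yrep)
    rep_ndet[r] <- stat_ndet(yrep)
  }
  pval <- function(rep, obs) mean(rep >= obs)
  out <- list(statistic = statistic,
              p_value = switch(statistic,
                               total_count = pval(rep_total, obs_total),
                               daily_total = pval(rep_total, obs_total),
                               n_detections = pval(rep_ndet, obs_ndet)),
              observed = switch(statistic,
                                total_count = obs_total,
                                daily_total = obs_total,
                                n_detections = obs_ndet),
              replicates = switch(statistic,
                                  total_count = rep_total,
                                  daily_total = rep_total,
                                  n_detections = rep_ndet))
  if (statistic == "daily_total") {
    observed_days <- which(rowSums(!miss) > 0)
    out$per_day <- tibble::tibble(
      t = seq_len(Tt),
      observed = obs_daily,
      rep_mean = colMeans(rep_daily),
      p_value = vapply(seq_len(Tt), function(t)
        mean(rep_daily[, t] >= obs_daily[t]), 1.0)
    )[observed_days, ]
  }
  structure(out, class = "camcr_ppc")
}

#' @export
print.camcr_ppc <- function(x, ...) {
  cat("<camcr_ppc>", x$statistic, "- Bayesian p-value:",
      round(x$p_value, 3), "\n")
  invisible(x)
}
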