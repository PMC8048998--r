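#' Count precipitation events of magnitude 2 or greater
#'
#' Precipitation events are scored per causative event on a 1-3 magnitude
#' scale for rain (R1-R3) and snow (S1-S3). The seasonal covariate is the
#' number of events of magnitude >= 2, rain and snow pooled.
#'
#' @param scores Data frame with columns `magnitude` (1, 2 or 3) and
#'   optionally `kind` (`"rain"`/`"snow"`) and `date`; one row per event.
#' @returns Integer count.
#' @examples
#' count_precip_events(data.frame(kind = c("rain", "rain", "snow"),
#'                                magnitude = c(1, 2, 3)))  # 2
#' @export
count_precip_events <- function(scores) {
  scores <- tibble::as_tibble(scores)
  if (nrow(scores) == 0) return(0L)
  if (any(!scores$magnitude %in% 1:3))
    stop("precipitation magnitude must be 1, 2 or 3")
  sum(scores$magnitude >= 2)
}

#' Count tourist visits inside the breeding window
#'
#' Sums visitors on dates from the extrapolated lay date to the crèche
#' date, both endpoints inclusive.
#'
#' @param visits Data frame with columns `date` and `visitors`.
#' @param lay_date,creche_date Window endpoints (`Date`).
#' @returns Integer count of visitors.
#' @export
tourism_window_count <- function(visits, lay_date, creche_date) {
  lay_date <- as.Date(lay_date); creche_date <- as.Date(creche_date)
  stopifnot(lay_date <= creche_date)
  visits <- tibble::as_tibble(visits)
  if (nrow(visits) == 0) return(0L)
  d <- as.Date(visits$date)
  as.integer(sum(visits$visitors[d >= lay_date & d <= creche_date]))
}

#' Assemble a driver table
#'
#' Joins per-site/year breeding success estimates (posterior mean and sd)
#' with the three driver covariates. Rows are matched on `site_id` and
#' `year_id`.
#'
#' @param bs Tibble from [breeding_success()] (`site_id`, `year_id`,
#'   `bs_mean`, `bs_sd`).
#' @param precip_events,krill_catch,tourists Tibbles with `site_id`,
#'   `year_id` and the covariate column (`precip_events`, `krill_catch`,
#'   `tourists`); any may be `NULL`.
#' @returns A tibble (`driver table`) with columns `site_id`, `year_id`,
#'   `bs_obs`, `sigma_bs` and the supplied covariates.
#' @export
build_driver_table <- function(bs, precip_events = NULL, krill_catch = NULL,
                               tourists = NULL) {
  out <- bs |>
    dplyr::transmute(.data$site_id, .data$year_id,
                     bs_obs = .data$bs_mean, sigma_bs = .data$bs_sd)
  if (any(out$sigma_bs <= 0))
    stop("sigma_bs must be positive for every site/year")
  by <- c("site_id", "year_id")
  if (!is.null(precip_events)) out <- dplyr::left_join(out, precip_events, by = by)
  if (!is.null(krill_catch)) out <- dplyr::left_join(out, krill_catch, by = by)
  if (!is.null(tourists)) out <- dplyr::left_join(out, tourists, by = by)
  out
}

#' Bayesian errors-in-variables regression of breeding success on a driver
#'
#' Fits `bs_obs_i ~ N(bs_true_i, sigma_bs_i)`,
#' `bs_true_i ~ N(alpha + beta * x_i, sigma)` with the per-point
#' measurement sd `sigma_bs_i` given (not estimated), so uncertainty in
#' the breeding-success estimates propagates into the slope. Priors:
#' `alpha, beta ~ N(0, 10^2)` and half-Normal(1) on `sigma` (configurable).
#' Sampling is by Gibbs steps for `bs_true` and `(alpha, beta)` (both
#' conditionally Normal) and an adaptive random-walk Metropolis step on
#' `log(sigma)`; with `sigma_fixed` supplied, `sigma` is held constant and
#' the sampler is fully conjugate.
#'
#' The krill covariate is log-transformed. Zero catches have no logarithm:
#' an offset (default half the smallest positive catch) is added before
#' the log when zeros are present, and recorded in the result.
#'
#' @param table A driver table (see [build_driver_table()]), or any data
#'   frame with columns `bs_obs`, `sigma_bs` and the covariate.
#' @param covariate Column name of the driver, e.g. `"precip_events"`,
#'   `"krill_catch"` (log-transformed automatically), `"tourists"`.
#' @param log_covariate Force/disable the log transform (default: `TRUE`
#'   for covariates named like krill catch, else `FALSE`).
#' @param zero_offset Offset added before a log transform when zeros are
#'   present; default half the smallest positive value.
#' @param prior_sd Normal prior sd for `alpha` and `beta`.
#' @param prior_sigma_scale Half-Normal scale for `sigma`.
#' @param sigma_fixed Optional fixed residual sd (disables the `sigma`
#'   update; used e.g. for conjugate cross-checks).
#' @param n_chains,n_warmup,n_samples Run lengths.
#' @param rng_seed Integer seed.
#' @returns A `camcr_reg` object: `draws` (matrix with columns `alpha`,
#'   `beta`, `sigma`), `bs_true_mean`, `diagnostics`, `covariate`, `data`,
#'   and `log_offset` (NA unless a zero-offset log transform was applied).
#' @export
fit_driver_regression <- function(table, covariate,
                                  log_covariate = grepl("krill", covariate),
                                  zero_offset = NULL,
                                  prior_sd = 10, prior_sigma_scale = 1,
                                  sigma_fixed = NULL,
                                  n_chains = 4, n_warmup = 1000,
                                  n_samples = 2500, rng_seed = 1L) {
  table <- tibble::as_tibble(table)
  stopifnot(all(c("bs_obs", "sigma_bs") %in% names(table)),
            covariate %in% names(table))
  if (nrow(table) < 3) stop("need at least 3 site/years")
  x <- table[[covariate]]
  log_offset <- NA_real_
  if (log_covariate) {
    if (any(x < 0)) stop("negative covariate under log transform")
    if (any(x == 0)) {
      if (is.null(zero_offset)) {
        pos <- x[x > 0]
        if (length(pos) == 0) stop(
          "all-zero covariate cannot be log-transformed; supply zero_offset")
        zero_offset <- min(pos) / 2
      }
      log_offset <- zero_offset
      x <- x + zero_offset
    }
    x <- log(x)
  }
  yobs <- table$bs_obs
  sbs <- table$sigma_bs
  if (any(sbs < 0)) stop("sigma_bs must be >= 0")
  n <- length(yobs)
  X <- cbind(1, x)
  prior_prec <- diag(1 / prior_sd^2, 2)

  run_chain <- function(seed) {
    set.seed(seed)
    ab <- c(mean(yobs), 0) + rnorm(2, 0, 0.1)
    sig <- if (is.null(sigma_fixed)) exp(rnorm(1, log(0.3), 0.3)) else sigma_fixed
    lstep <- log(0.5)
    niter <- n_warmup + n_samples
    out <- matrix(NA_real_, n_samples, 3,
                  dimnames = list(NULL, c("alpha", "beta", "sigma")))
    bs_true_sum <- numeric(n)
    for (it in seq_len(niter)) {
      mu <- X %*% ab
      # bs_true | rest (exact when sigma_bs = 0)
      bst <- yobs
      free <- sbs > 0
      if (any(free)) {
        prec_obs <- 1 / sbs[free]^2
        v <- 1 / (prec_obs + 1 / sig^2)
        m <- v * (yobs[free] * prec_obs + mu[free] / sig^2)
        bst[free] <- rnorm(sum(free), m, sqrt(v))
      }
      # (alpha, beta) | rest: conjugate bivariate normal
      Vinv <- crossprod(X) / sig^2 + prior_prec
      V <- solve(Vinv)
      mab <- V %*% (crossprod(X, bst) / sig^2)
      L <- chol(V)
      ab <- as.numeric(mab + t(L) %*% rnorm(2))
      # sigma | rest: adaptive RW Metropolis on log(sigma)
      if (is.null(sigma_fixed)) {
        resid <- bst - X %*% ab
        ss <- sum(resid^2)
        ltarget <- function(ls) {
          s <- exp(ls)
          -n * ls - ss / (2 * s^2) - s^2 / (2 * prior_sigma_scale^2) + ls
        }
        prop <- log(sig) + exp(lstep) * rnorm(1)
        acc <- min(1, exp(ltarget(prop) - ltarget(log(sig))))
        if (runif(1) < acc) sig <- exp(prop)
        if (it <= n_warmup) lstep <- lstep + (acc - 0.44) / sqrt(it)
      }
      if (it > n_warmup) {
        out[it - n_warmup, ] <- c(ab, sig)
        bs_true_sum <- bs_true_sum + bst
      }
    }
    list(draws = out, bs_true_mean = bs_true_sum / n_samples)
  }

  res <- lapply(seq_len(n_chains), function(c) run_chain(rng_seed + c))
  draws <- do.call(rbind, lapply(res, `[[`, "draws"))
  chain_id <- rep(seq_len(n_chains), each = n_samples)
  keep <- if (is.null(sigma_fixed)) 1:3 else 1:2
  diagnostics <- mcmc_diagnostics(draws[, keep, drop = FALSE], chain_id)
  structure(
    list(draws = draws, chain = chain_id,
         bs_true_mean = rowMeans(do.call(cbind, lapply(res, `[[`, "bs_true_mean"))),
         diagnostics = diagnostics, covariate = covariate, n = n,
         data = tibble::tibble(x = x, bs_obs = yobs, sigma_bs = sbs),
         log_transformed = log_covariate, log_offset = log_offset,
         priors = list(prior_sd = prior_sd,
                       prior_sigma_scale = prior_sigma_scale,
                       sigma_fixed = sigma_fixed)),
    class = "camcr_reg"
  )
}

#' @export
print.camcr_reg <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<camcr_reg> bs ~ %s%s (n = %d)\n",
              if (x$log_transformed) "log " else "", x$covariate, x$n))
  cat(sprintf("  median beta = %.3f [95%% CI: %.3f, %.3f]\n",
              g$beta_median, g$beta_low, g$beta_high))
  invisible(x)
}

#' Long-format overlay of a seasonal trajectory and precipitation events
#'
#' One row per day with the posterior mean and sd of the total-chick
#' trajectory and the magnitude of any precipitation event that day,
#' ready for storm-overlay plots.
#'
#' @param z_summary Tibble with columns `t`, `Z_mean`, `Z_sd` (from
#'   [total_chicks()]).
#' @param precip Data frame of events with columns `day`, `kind`,
#'   `magnitude` (may be empty).
#' @returns Tibble with columns `t`, `Z_mean`, `Z_sd`, `event_kind`,
#'   `event_magnitude` (`NA` on days without an event).
#' @export
event_overlay_export <- function(z_summary, precip = NULL) {
  stopifnot(all(c("t", "Z_mean", "Z_sd") %in% names(z_summary)))
  out <- tibble::tibble(t = z_summary$t, Z_mean = z_summary$Z_mean,
                        Z_sd = z_summary$Z_sd,
                        event_kind = NA_character_,
                        event_magnitude = NA_integer_)
  if (!is.null(precip) && nrow(precip) > 0) {
    i <- match(precip$day, out$t)
    ok <- !is.na(i)
    out$event_kind[i[ok]] <- as.character(precip$kind[ok])
    out$event_magnitude[i[ok]] <- as.integer(precip$magnitude[ok])
  }
  out
}
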