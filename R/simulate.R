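#' Simulation configuration for synthetic site/year datasets
#'
#' Defines the generative conditions for synthetic camera datasets with the
#' exact statistical structure the survival model assumes: two-egg clutches,
#' daily binomial survival with a site/year-specific rate, and binomial
#' detection with a logistic-in-time detection curve plus nest-level
#' offsets. Defaults emulate a gentoo penguin colony season: the grand mean
#' daily survival `plogis(5.23)` (about 0.9947) yields roughly 1.46 chicks
#' per pair over 59 daily transitions, and `sigma_mu_phi = 0.8` on the logit
#' scale spreads site/year breeding success over roughly 0.6-1.9 chicks per
#' pair. Hatch defaults to day 31, the first day after the 30-day egg
#' period; detection of chicks once hatched is high because the daily count
#' is a maximum over many images.
#'
#' @param n_site_years Number of site/year datasets.
#' @param n_nests Nests per site/year.
#' @param T_days Season length in days (the model requires 60).
#' @param theta_phi Logit-scale grand mean daily survival.
#' @param sigma_mu_phi Logit-scale sd of site/year survival around
#'   `theta_phi`.
#' @param mu_p Logit-scale detection intercept.
#' @param mu_beta_p,sigma_beta_p Hyperparameters (mean, sd) of the
#'   site/year detection slope on the rescaled time covariate
#'   `x_t = (t - 1)/(T - 1)`.
#' @param sigma_nu_p Sd of logit-scale nest-level detection offsets.
#' @param hatch_day First day chicks are observable (observation window
#'   start); counts before it are missing.
#' @param p_outage Per-day probability an entire day's image set is missing
#'   (camera outage), applied after `hatch_day`.
#' @param rng_seed Integer seed; all simulation randomness derives from it.
#' @returns A `sim_config` list.
#' @export
sim_config <- function(n_site_years = 3, n_nests = 20, T_days = 60,
                       theta_phi = 5.23, sigma_mu_phi = 0.8,
                       mu_p = 0.5, mu_beta_p = 2.5, sigma_beta_p = 0.5,
                       sigma_nu_p = 0.5, hatch_day = 31, p_outage = 0,
                       rng_seed = 1L) {
  stopifnot(sigma_mu_phi >= 0, sigma_beta_p >= 0, sigma_nu_p >= 0,
            n_nests >= 1, hatch_day >= 1, hatch_day <= T_days,
            p_outage >= 0, p_outage <= 1)
  structure(
    list(n_site_years = as.integer(n_site_years),
         n_nests = as.integer(n_nests), T_days = as.integer(T_days),
         theta_phi = theta_phi, sigma_mu_phi = sigma_mu_phi,
         mu_p = mu_p, mu_beta_p = mu_beta_p, sigma_beta_p = sigma_beta_p,
         sigma_nu_p = sigma_nu_p, hatch_day = as.integer(hatch_day),
         p_outage = p_outage, rng_seed = as.integer(rng_seed)),
    class = "sim_config"
  )
}

#' Detection time covariate
#'
#' The day index rescaled linearly to `[0, 1]` over the season, so the
#' detection slope is comparable across site/years.
#' @param T_days Season length.
#' @returns Numeric vector of length `T_days`.
#' @export
detection_time_covariate <- function(T_days = 60) {
  (seq_len(T_days) - 1) / (T_days - 1)
}

# Core trajectory simulator with a per-day survival vector, so extreme-event
# injection can reuse it with one day's survival multiplied down.
simulate_zy <- function(n_nests, T_days, phi_t, p_mat, hatch_day, p_outage) {
  z <- matrix(0L, nrow = T_days, ncol = n_nests)
  z[1, ] <- 2L
  for (t in 2:T_days) {
    z[t, ] <- rbinom(n_nests, z[t - 1, ], phi_t[t])
  }
  y <- matrix(NA_integer_, nrow = T_days, ncol = n_nests)
  for (t in seq_len(T_days)) {
    if (t < hatch_day) next
    y[t, ] <- rbinom(n_nests, z[t, ], p_mat[t, ])
  }
  if (p_outage > 0) {
    out_days <- which(runif(T_days) < p_outage)
    out_days <- out_days[out_days >= hatch_day]
    if (length(out_days)) y[out_days, ] <- NA_integer_
  }
  list(z = z, y = y)
}

#' Simulate one site/year of nest observation data
#'
#' Generative mirror of the survival model: per-nest latent chick counts
#' start at 2, decline by daily binomial survival, and are observed through
#' binomial detection with a logistic-in-time detection curve and nest
#' offsets. Seasonal covariates (precipitation event scores, krill catch,
#' tourist visits) are also drawn so downstream driver analyses have inputs.
#'
#' @param config A [sim_config()].
#' @param site_year_index 1-based index; the simulation seed is
#'   `rng_seed + site_year_index` so site/years are independent and
#'   individually reproducible.
#' @returns A `sim_site_year` list: matrices `z` (true counts) and `y`
#'   (observed, `NA` before hatch), `params` (the realised parameter
#'   values), `covariates` (list with `precip`, `krill_catch`, `tourists`),
#'   `bs_true = sum(z[T, ]) / n_nests`, and ids.
#' @export
simulate_site_year <- function(config, site_year_index = 1L) {
  stopifnot(inherits(config, "sim_config"))
  seed <- config$rng_seed + as.integer(site_year_index)
  withr_seed(seed)
  Tt <- config$T_days
  n <- config$n_nests
  mu_phi <- rnorm(1, config$theta_phi, config$sigma_mu_phi)
  beta_p <- rnorm(1, config$mu_beta_p, config$sigma_beta_p)
  nu_p <- rnorm(n, 0, config$sigma_nu_p)
  x <- detection_time_covariate(Tt)
  phi <- plogis(mu_phi)
  p_mat <- plogis(matrix(config$mu_p, Tt, n) +
                    matrix(nu_p, Tt, n, byrow = TRUE) +
                    beta_p * matrix(x, Tt, n))
  zy <- simulate_zy(n, Tt, rep(phi, Tt), p_mat, config$hatch_day,
                    config$p_outage)
  n_events <- rpois(1, 3)
  precip <- tibble::tibble(
    day = sort(sample.int(Tt, n_events, replace = FALSE)),
    kind = sample(c("rain", "snow"), n_events, replace = TRUE),
    magnitude = sample(1:3, n_events, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  )
  covariates <- list(
    precip = precip,
    krill_catch = exp(rnorm(1, log(500), 1)),
    tourists = rpois(1, 500)
  )
  structure(
    list(site_id = sprintf("SIM%02d", site_year_index),
         year_id = "synthetic",
         z = zy$z, y = zy$y,
         params = list(mu_phi = mu_phi, phi = phi, beta_p = beta_p,
                       nu_p = nu_p, mu_p = config$mu_p,
                       theta_phi = config$theta_phi,
                       sigma_mu_phi = config$sigma_mu_phi,
                       hatch_day = config$hatch_day),
         covariates = covariates,
         bs_true = sum(zy$z[Tt, ]) / n,
         config = config, site_year_index = as.integer(site_year_index),
         seed = seed),
    class = "sim_site_year"
  )
}

#' @export
print.sim_site_year <- function(x, ...) {
  cat("<sim_site_year>", x$site_id, "-", ncol(x$z), "nests, phi =",
      signif(x$params$phi, 4), ", true BS =", round(x$bs_true, 3), "\n")
  invisible(x)
}

#' Simulate a multi-site/year dataset
#'
#' @param config A [sim_config()].
#' @returns A `sim_dataset`: list of [simulate_site_year()] results plus a
#'   `truth` tibble (one row per site/year with the realised parameters and
#'   true breeding success).
#' @export
simulate_dataset <- function(config) {
  sims <- lapply(seq_len(config$n_site_years),
                 function(j) simulate_site_year(config, j))
  truth <- purrr::map_dfr(sims, function(s) {
    tibble::tibble(site_id = s$site_id, year_id = s$year_id,
                   mu_phi = s$params$mu_phi, phi = s$params$phi,
                   beta_p = s$params$beta_p, bs_true = s$bs_true)
  })
  structure(list(sims = sims, truth = truth, config = config),
            class = "sim_dataset")
}

#' Inject an extreme weather event into a simulated site/year
#'
#' Re-simulates the latent trajectories with the survival probability on
#' `event_day` multiplied by `1 - survival_drop`, emulating a storm that
#' kills a fraction of eggs/chicks in one day. The event is recorded in the
#' covariate table as a magnitude-3 snow event. The same base seed is used,
#' so `survival_drop = 0` reproduces the input exactly.
#'
#' @param sim A [simulate_site_year()] result.
#' @param event_day Day of the event (2..T).
#' @param survival_drop Fraction of that day's survivors lost, in `[0, 1]`.
#' @returns A modified `sim_site_year`.
#' @export
inject_extreme_event <- function(sim, event_day, survival_drop) {
  stopifnot(inherits(sim, "sim_site_year"),
            event_day > 1, event_day <= nrow(sim$z),
            survival_drop >= 0, survival_drop <= 1)
  cfg <- sim$config
  withr_seed(sim$seed)
  Tt <- cfg$T_days
  n <- cfg$n_nests
  # replay the parameter draws so the trajectory replay aligns
  mu_phi <- rnorm(1, cfg$theta_phi, cfg$sigma_mu_phi)
  beta_p <- rnorm(1, cfg$mu_beta_p, cfg$sigma_beta_p)
  nu_p <- rnorm(n, 0, cfg$sigma_nu_p)
  x <- detection_time_covariate(Tt)
  phi_t <- rep(plogis(mu_phi), Tt)
  phi_t[event_day] <- phi_t[event_day] * (1 - survival_drop)
  p_mat <- plogis(matrix(cfg$mu_p, Tt, n) +
                    matrix(nu_p, Tt, n, byrow = TRUE) +
                    beta_p * matrix(x, Tt, n))
  zy <- simulate_zy(n, Tt, phi_t, p_mat, cfg$hatch_day, cfg$p_outage)
  out <- sim
  out$z <- zy$z
  out$y <- zy$y
  out$bs_true <- sum(zy$z[Tt, ]) / n
  out$covariates$precip <- dplyr::bind_rows(
    sim$covariates$precip,
    tibble::tibble(day = as.integer(event_day), kind = "snow", magnitude = 3L)
  ) |> dplyr::arrange(.data$day)
  out$event <- list(day = as.integer(event_day), survival_drop = survival_drop)
  out
}

#' Simulate a driver table with known regression effects
#'
#' Generative mirror of the errors-in-variables regression: true breeding
#' success is linear in a covariate with residual sd `sigma`, and the
#' observed value adds known per-point measurement noise `sigma_bs`. No
#' truncation to `[0, 2]` is applied, matching the regression model's
#' Normal assumption.
#'
#' @param n_site_years Number of rows.
#' @param alpha,beta,sigma Intercept, slope and residual sd of the true
#'   relationship.
#' @param sigma_bs_range Range from which per-point posterior sds are drawn
#'   uniformly.
#' @param covariate_generator Function of `n` returning covariate values.
#' @param rng_seed Integer seed.
#' @returns Tibble with columns `site_year`, `x`, `bs_true`, `bs_obs`,
#'   `sigma_bs`.
#' @export
simulate_drivers <- function(n_site_years = 28, alpha = 1.4, beta = -0.02,
                             sigma = 0.2, sigma_bs_range = c(0.02, 0.1),
                             covariate_generator = function(n) runif(n, 0, 20),
                             rng_seed = 1L) {
  stopifnot(sigma >= 0, all(sigma_bs_range >= 0))
  withr_seed(rng_seed)
  x <- covariate_generator(n_site_years)
  bs_true <- alpha + beta * x + rnorm(n_site_years, 0, sigma)
  sigma_bs <- runif(n_site_years, sigma_bs_range[1], sigma_bs_range[2])
  bs_obs <- bs_true + rnorm(n_site_years, 0, sigma_bs)
  tibble::tibble(site_year = sprintf("SY%02d", seq_len(n_site_years)),
                 x = x, bs_true = bs_true, bs_obs = bs_obs,
                 sigma_bs = sigma_bs)
}

#' Convert a simulated site/year to an observation series
#'
#' @param sim A `sim_site_year`.
#' @param creche_date Calendar date of crèche (defaults to an arbitrary
#'   fixed date; only alignment matters).
#' @returns An `obs_series`.
#' @export
as_obs_series <- function(sim, creche_date = as.Date("2015-02-01")) {
  stopifnot(inherits(sim, "sim_site_year"))
  lay <- creche_date - 60
  nest_ids <- sprintf("nest%03d", seq_len(ncol(sim$y)))
  obs <- which(!is.na(sim$y), arr.ind = TRUE)
  daily <- tibble::tibble(
    nest_id = nest_ids[obs[, 2]],
    date = lay + obs[, 1],
    count = sim$y[obs]
  )
  build_observation_series(daily, creche_date = creche_date,
                           first_chick_date = lay + sim$params$hatch_day,
                           site_id = sim$site_id, year_id = sim$year_id,
                           nest_ids = nest_ids)
}

# simulator functions are explicitly seeded; NULL keeps the current stream
withr_seed <- function(seed) {
  if (!is.null(seed)) set.seed(seed)
  invisible(seed)
}
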