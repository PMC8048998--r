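#' Phase-specific daily mortality from a total-chick trajectory
#'
#' Splits the 60-day modelled season into an egg period (days 1-30), a
#' young chick period (days 31-45) and an old chick period (days 46-60),
#' and computes the average daily loss of chicks in each: the difference
#' between the trajectory value at the phase start and end divided by the
#' phase length. Phase endpoints are shared (day 30 ends the egg period and
#' starts the young chick period), so the three rates telescope exactly to
#' `(Z_1 - Z_60)` when multiplied by the phase lengths.
#'
#' @param z Either a numeric vector of length 60 (posterior-mean total
#'   chicks per day) or a tibble from [total_chicks()] with columns `t` and
#'   `Z_mean`.
#' @param boundaries Integer vector of phase end days, default
#'   `c(30, 45, 60)`.
#' @param site_id,year_id Optional labels for the output row.
#' @returns One-row tibble with `egg_rate`, `young_rate`, `old_rate`
#'   (chicks lost per day).
#' @export
phase_mortality <- function(z, boundaries = c(30, 45, 60),
                            site_id = NA_character_, year_id = NA_character_) {
  if (is.data.frame(z)) {
    stopifnot(all(c("t", "Z_mean") %in% names(z)))
    z <- z$Z_mean[order(z$t)]
  }
  stopifnot(length(z) == max(boundaries), length(boundaries) == 3)
  if (anyNA(z)) stop("trajectory contains missing values")
  b <- c(1, boundaries)
  lengths <- c(boundaries[1], diff(boundaries))  # 30 / 15 / 15 days
  rates <- (z[b[-4]] - z[b[-1]]) / lengths
  tibble::tibble(site_id = site_id, year_id = year_id,
                 egg_rate = rates[1], young_rate = rates[2],
                 old_rate = rates[3])
}

#' Phase mortality for every site/year in a fit
#'
#' @param fit A [fit_survival_model()] result.
#' @param boundaries Phase end days.
#' @param posterior With `posterior = TRUE`, rates are computed per
#'   posterior draw instead of from the posterior-mean trajectory.
#' @returns Tibble with one row per site/year (or per site/year x draw).
#' @export
phase_mortality_fit <- function(fit, boundaries = c(30, 45, 60),
                                posterior = FALSE) {
  stopifnot(inherits(fit, "camcr_fit"))
  purrr::map_dfr(seq_len(nrow(fit$site_years)), function(j) {
    if (!posterior) {
      tr <- total_chicks(fit, fit$site_years$site_id[j],
                         fit$site_years$year_id[j])
      phase_mortality(tr$Z_mean, boundaries,
                      site_id = fit$site_years$site_id[j],
                      year_id = fit$site_years$year_id[j])
    } else {
      Zj <- fit$Z[, , j]
      b <- c(1, boundaries)
      purrr::map_dfr(seq_len(nrow(Zj)), function(d) {
        r <- phase_mortality(Zj[d, ], boundaries,
                             site_id = fit$site_years$site_id[j],
                             year_id = fit$site_years$year_id[j])
        r$draw <- d
        r
      })
    }
  })
}

#' Friedman rank test for matched blocks
#'
#' Nonparametric test for treatment differences across matched blocks
#' (here: mortality-rate phases measured on the same site/years), without
#' a normality assumption. Values are midranked within each block (ties
#' averaged); the statistic is
#' `Q = 12 / (n k (k + 1)) * sum(R_j^2) - 3 n (k + 1)` with rank sums
#' `R_j`, divided by the tie-correction factor
#' `1 - sum(t^3 - t) / (n k (k^2 - 1))` when ties are present. The p-value
#' is from the chi-square distribution with `k - 1` degrees of freedom.
#' When every block is completely tied the statistic is 0 and p = 1.
#'
#' @param data A numeric matrix (blocks x treatments) or a long data frame.
#' @param value,treatment,block For long data: column names (as strings).
#' @returns A `camcr_friedman` list with `statistic`, `df`, `p_value`,
#'   `n_blocks`, `k_treatments`, `ties_corrected`. See
#'   [tidy.camcr_friedman()].
#' @examples
#' m <- matrix(c(1, 2, 3, 1.5, 2.5, 3.5), nrow = 2, byrow = TRUE)
#' friedman_rank_test(m)
#' @export
friedman_rank_test <- function(data, value = "value", treatment = "treatment",
                               block = "block") {
  if (is.data.frame(data)) {
    wide <- tidyr::pivot_wider(
      data[, c(block, treatment, value)],
      names_from = dplyr::all_of(treatment),
      values_from = dplyr::all_of(value))
    m <- as.matrix(wide[, -1, drop = FALSE])
  } else {
    m <- as.matrix(data)
  }
  if (anyNA(m))
    stop("missing cells in the block design; remove incomplete blocks")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 blocks and 2 treatments")
  r <- t(apply(m, 1, rank))  # midranks within block
  Rj <- colSums(r)
  Q <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  # tie correction
  tie_sum <- sum(apply(m, 1, function(row) {
    tt <- table(row)
    sum(tt^3 - tt)
  }))
  ties <- tie_sum > 0
  if (ties) {
    C <- 1 - tie_sum / (n * k * (k^2 - 1))
    Q <- if (C > 0) Q / C else 0
  }
  if (!is.finite(Q) || Q < 0) Q <- 0
  p <- pchisq(Q, df = k - 1, lower.tail = FALSE)
  structure(list(statistic = Q, df = k - 1, p_value = p, n_blocks = n,
                 k_treatments = k, ties_corrected = ties),
            class = "camcr_friedman")
}

#' @export
print.camcr_friedman <- function(x, ...) {
  cat(sprintf("Friedman rank test: Q = %.4g, df = %d, p = %.4g (n = %d blocks%s)\n",
              x$statistic, x$df, x$p_value, x$n_blocks,
              if (x$ties_corrected) ", tie-corrected" else ""))
  invisible(x)
}
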