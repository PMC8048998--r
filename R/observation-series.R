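#' Build a 60-day observation series aligned to the extrapolated lay date
#'
#' The modelled season runs for exactly `T = 60` days ending at the crèche
#' date; the extrapolated lay date is `creche_date - 60` days, so day `t`
#' corresponds to calendar date `lay_date + t`. Daily counts before the
#' first-chick sighting are set to missing (egg contents are not scored),
#' and days inside the window with no usable images stay missing.
#'
#' @param daily_counts Data frame with columns `nest_id`, `date`
#'   (class `Date`) and `count` (0, 1, 2 or `NA`).
#' @param creche_date,first_chick_date `Date` scalars with
#'   `first_chick_date <= creche_date`. All dates in `daily_counts` must lie
#'   in `(creche_date - 60, creche_date]`.
#' @param site_id,year_id Labels stored on the series.
#' @param nest_ids Optional full nest roster; nests never detected still
#'   enter the series (all-missing-then-zero data inform survival downward).
#' @returns An `obs_series` object: a list with the 60 x N integer matrix
#'   `y` (rows t = 1..60, columns nests), `nest_ids`, `site_id`, `year_id`,
#'   `creche_date`, `lay_date`, `first_chick_date`.
#' @export
build_observation_series <- function(daily_counts, creche_date,
                                     first_chick_date,
                                     site_id = NA_character_,
                                     year_id = NA_character_,
                                     nest_ids = NULL) {
  creche_date <- as.Date(creche_date)
  first_chick_date <- as.Date(first_chick_date)
  if (first_chick_date > creche_date)
    stop("first_chick_date must not be after creche_date")
  lay_date <- creche_date - 60
  daily_counts <- tibble::as_tibble(daily_counts)
  stopifnot(all(c("nest_id", "date", "count") %in% names(daily_counts)))
  daily_counts$date <- as.Date(daily_counts$date)
  tt <- as.integer(daily_counts$date - lay_date)
  if (any(tt < 1 | tt > 60))
    stop("daily counts dated outside (lay_date, creche_date]")
  if (is.null(nest_ids)) nest_ids <- sort(unique(daily_counts$nest_id))
  n <- length(nest_ids)
  y <- matrix(NA_integer_, nrow = 60, ncol = n,
              dimnames = list(NULL, as.character(nest_ids)))
  ci <- match(daily_counts$nest_id, nest_ids)
  if (anyNA(ci)) stop("daily counts for nests absent from nest_ids")
  y[cbind(tt, ci)] <- as.integer(daily_counts$count)
  t_first <- as.integer(first_chick_date - lay_date)
  if (t_first > 1) y[seq_len(t_first - 1), ] <- NA_integer_
  bad <- !is.na(y) & !(y %in% 0:2)
  if (any(bad)) stop("counts must be 0, 1, 2 or missing")
  structure(
    list(y = y, nest_ids = nest_ids, site_id = site_id, year_id = year_id,
         creche_date = creche_date, lay_date = lay_date,
         first_chick_date = first_chick_date),
    class = "obs_series"
  )
}

#' @export
print.obs_series <- function(x, ...) {
  cat("<obs_series>", x$site_id, x$year_id, "-", ncol(x$y), "nests x 60 days;",
      sum(!is.na(x$y)), "observed cells\n")
  invisible(x)
}

#' Convert an observation series to a long tibble
#'
#' @param x An `obs_series`.
#' @param ... Unused.
#' @returns A tibble with columns `site_id`, `year_id`, `nest_id`, `t`,
#'   `date`, `count` (one row per nest-day, missing counts as `NA`).
#' @export
tidy.obs_series <- function(x, ...) {
  tibble::tibble(
    site_id = x$site_id,
    year_id = x$year_id,
    nest_id = rep(as.character(x$nest_ids), each = 60),
    t = rep(1:60, times = ncol(x$y)),
    date = x$lay_date + rep(1:60, times = ncol(x$y)),
    count = as.integer(x$y)
  )
}

#' Read and write observation series CSV (long format)
#'
#' The on-disk format is one row per nest-day with columns `site_id`,
#' `year_id`, `nest_id`, `t`, `date`, `count`; empty cells are missing.
#' Round-tripping a series through CSV is lossless.
#'
#' @param x An `obs_series`.
#' @param path File path.
#' @returns `write_observation_series()` returns `path` invisibly;
#'   `read_observation_series()` returns an `obs_series` (the file must
#'   contain exactly one site/year).
#' @export
write_observation_series <- function(x, path) {
  stopifnot(inherits(x, "obs_series"))
  long <- tidy(x)
  long$creche_date <- x$creche_date
  long$first_chick_date <- x$first_chick_date
  readr::write_csv(long, path, na = "")
  invisible(path)
}

#' @rdname write_observation_series
#' @export
read_observation_series <- function(path) {
  long <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(length(unique(paste(long$site_id, long$year_id))) == 1)
  nest_ids <- sort(unique(long$nest_id))
  creche <- as.Date(long$creche_date[1])
  # counts before the stored first-chick date were blanked on write, so the
  # matrix rebuild reproduces the original missing pattern
  obs <- long[!is.na(long$count), c("nest_id", "date", "count")]
  build_observation_series(obs, creche_date = creche,
                           first_chick_date = as.Date(long$first_chick_date[1]),
                           site_id = long$site_id[1],
                           year_id = long$year_id[1],
                           nest_ids = nest_ids)
}

#' Read nest annotation and detection tables
#'
#' Nest annotations: CSV with columns `site_id`, `year_id`, `nest_id`,
#' `x_px`, `y_px`, `frame_w`, `frame_h`. Detections: CSV with columns
#' `site_id`, `year_id`, `timestamp` (ISO-8601), `x_px`, `y_px`.
#'
#' @param path CSV file path.
#' @returns A tibble.
#' @export
read_nest_annotations <- function(path) {
  ann <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("site_id", "year_id", "nest_id", "x_px", "y_px", "frame_w", "frame_h")
  if (!all(need %in% names(ann)))
    stop("annotation file missing columns: ",
         paste(setdiff(need, names(ann)), collapse = ", "))
  ann
}

#' @rdname read_nest_annotations
#' @export
read_detections <- function(path) {
  det <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("site_id", "year_id", "timestamp", "x_px", "y_px")
  if (!all(need %in% names(det)))
    stop("detection file missing columns: ",
         paste(setdiff(need, names(det)), collapse = ", "))
  det
}

#' Build daily per-nest counts from raw detections
#'
#' Assigns every image's detections to nest zones and takes the daily
#' maximum per nest (see [assign_detections()] and [aggregate_daily()]).
#'
#' @param detections Tibble from [read_detections()] (one site/year).
#' @param map A [build_nest_zones()] result for the same site/year.
#' @returns Tibble with columns `nest_id`, `date`, `count`.
#' @export
daily_counts_from_detections <- function(detections, map) {
  detections <- tibble::as_tibble(detections)
  detections$date <- as.Date(substr(as.character(detections$timestamp), 1, 10))
  per_image <- detections |>
    dplyr::group_by(.data$date, .data$timestamp) |>
    dplyr::group_modify(function(d, key) {
      assign_detections(
        tibble::tibble(x = d$x_px, y = d$y_px, timestamp = key$timestamp),
        map
      )[, c("nest_id", "count")]
    }) |>
    dplyr::ungroup()
  per_image |>
    dplyr::group_by(.data$nest_id, .data$date) |>
    dplyr::summarise(count = aggregate_daily(.data$count), .groups = "drop") |>
    dplyr::arrange(.data$nest_id, .data$date)
}
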