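# Spatial support for the krill-catch covariate: a local Lambert azimuthal
# equal-area (LAEA) projection per site, a geodesic circular buffer, and
# area-weighted polygon overlay of management-unit polygons on the buffer.

EARTH_RADIUS_KM <- 6371.0088  # mean Earth radius

#' Project lon/lat to a local azimuthal equal-area plane
#'
#' Spherical Lambert azimuthal equal-area projection centred on
#' `(lon0, lat0)`; output coordinates in km. Equal-area by construction, so
#' polygon-overlay weights computed in the projected plane match the true
#' area proportions.
#'
#' @param lon,lat Coordinates in degrees (WGS84 treated as spherical).
#' @param lon0,lat0 Projection centre in degrees.
#' @returns A two-column matrix (x, y) in km.
#' @export
laea_project <- function(lon, lat, lon0, lat0) {
  d2r <- pi / 180
  lam <- lon * d2r; phi <- lat * d2r
  lam0 <- lon0 * d2r; phi0 <- lat0 * d2r
  denom <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  kk <- sqrt(2 / denom)
  x <- EARTH_RADIUS_KM * kk * cos(phi) * sin(lam - lam0)
  y <- EARTH_RADIUS_KM * kk * (cos(phi0) * sin(phi) -
                                 sin(phi0) * cos(phi) * cos(lam - lam0))
  cbind(x = x, y = y)
}

# A geodesic circle of great-circle radius r about the projection centre
# maps, under LAEA, to a plane circle of radius 2R sin(r / (2R)).
geodesic_buffer_ring <- function(radius_km, n_vertices = 256) {
  rho <- 2 * EARTH_RADIUS_KM * sin(radius_km / (2 * EARTH_RADIUS_KM))
  theta <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices
  cbind(x = rho * cos(theta), y = rho * sin(theta))
}

ring_area <- function(p) polygon_area(cbind(p$x, p$y))

# Intersection area of two polygons given as ring matrices, via polyclip.
intersection_area <- function(a, b) {
  A <- list(x = a[, 1], y = a[, 2])
  B <- list(x = b[, 1], y = b[, 2])
  pieces <- polyclip::polyclip(A, B, op = "intersection")
  if (length(pieces) == 0) return(0)
  sum(vapply(pieces, ring_area, 1.0))
}

#' Read SSMU polygons from GeoJSON
#'
#' Reads a GeoJSON FeatureCollection of small-scale management unit (SSMU)
#' polygons in WGS84. Each feature must carry an `ssmu_id` property and a
#' Polygon or MultiPolygon geometry (holes are not supported).
#'
#' @param path GeoJSON file path.
#' @returns Tibble with `ssmu_id` and a list-column `rings` of two-column
#'   lon/lat matrices.
#' @export
read_ssmu_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  stopifnot(identical(gj$type, "FeatureCollection"))
  purrr::map_dfr(gj$features, function(f) {
    id <- f$properties$ssmu_id
    geom <- f$geometry
    ring_of <- function(coords) {
      m <- do.call(rbind, lapply(coords, function(pt)
        c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))))
      m
    }
    rings <- switch(
      geom$type,
      Polygon = list(ring_of(geom$coordinates[[1]])),
      MultiPolygon = lapply(geom$coordinates, function(pp) ring_of(pp[[1]])),
      stop("unsupported geometry type: ", geom$type)
    )
    tibble::tibble(ssmu_id = as.character(id), rings = list(rings))
  })
}

#' Buffer-weighted SSMU overlay weights for one site
#'
#' Computes, for each SSMU polygon, the proportion of a geodesic buffer
#' around the site covered by that SSMU. Weights sum to 1 when the SSMUs
#' tile the buffer and to less than 1 when part of the buffer is
#' uncovered (uncovered area implicitly carries zero catch).
#'
#' @param site_lon,site_lat Site coordinates in degrees.
#' @param ssmu Tibble from [read_ssmu_geojson()].
#' @param radius_km Buffer radius (great-circle km).
#' @returns Tibble with `ssmu_id` and `weight`.
#' @export
ssmu_buffer_weights <- function(site_lon, site_lat, ssmu, radius_km = 150) {
  stopifnot(radius_km > 0)
  buf <- geodesic_buffer_ring(radius_km)
  buf_area <- polygon_area(buf)
  w <- vapply(seq_len(nrow(ssmu)), function(s) {
    rings <- ssmu$rings[[s]]
    a <- sum(vapply(rings, function(r) {
      proj <- laea_project(r[, 1], r[, 2], site_lon, site_lat)
      intersection_area(proj, buf)
    }, 1.0))
    a / buf_area
  }, 1.0)
  tibble::tibble(ssmu_id = ssmu$ssmu_id, weight = w)
}

#' Seasonal krill catch within a geodesic buffer of a site
#'
#' Area-weighted average of SSMU monthly catch over a buffer of
#' `radius_km` around the site, summed over the 11-month window from March
#' of the year before the season ends through January of the season-end
#' year. The window covers the pre-breeding overwinter period plus the
#' breeding season, capturing carry-over effects of fishing on adult
#' condition.
#'
#' @param site_lon,site_lat Site coordinates (degrees, WGS84).
#' @param ssmu Tibble from [read_ssmu_geojson()].
#' @param catch Tibble with columns `ssmu_id`, `year`, `month` (1-12),
#'   `tonnes`.
#' @param season_end_year Calendar year in which the breeding season ends
#'   (year "t"; the window runs March(t-1)..January(t)).
#' @param radius_km Buffer radius in km.
#' @param window_months Month labels included, as a tibble with columns
#'   `year_offset` (-1 or 0 relative to `season_end_year`) and `month`.
#'   Defaults to March(t-1)..January(t).
#' @returns Scalar tonnes; the per-SSMU weights are attached as attribute
#'   `"weights"`. Zero overlap between buffer and SSMUs returns 0 with a
#'   warning.
#' @export
krill_buffer_catch <- function(site_lon, site_lat, ssmu, catch,
                               season_end_year, radius_km = 150,
                               window_months = NULL) {
  stopifnot(all(c("ssmu_id", "year", "month", "tonnes") %in% names(catch)))
  if (any(catch$tonnes < 0)) stop("negative catch")
  if (is.null(window_months)) {
    window_months <- tibble::tibble(
      year_offset = c(rep(-1L, 10), 0L),
      month = c(3:12, 1L)
    )
  }
  wts <- ssmu_buffer_weights(site_lon, site_lat, ssmu, radius_km)
  if (sum(wts$weight) <= 0) {
    warning("buffer has zero overlap with SSMU polygons; returning 0 tonnes",
            call. = FALSE)
    return(structure(0, weights = wts))
  }
  window <- dplyr::mutate(window_months,
                          year = season_end_year + .data$year_offset)
  in_window <- dplyr::semi_join(catch, window, by = c("year", "month"))
  tot <- in_window |>
    dplyr::inner_join(wts, by = "ssmu_id") |>
    dplyr::summarise(t = sum(.data$tonnes * .data$weight)) |>
    dplyr::pull(t)
  if (length(tot) == 0) tot <- 0
  structure(tot, weights = wts)
}
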