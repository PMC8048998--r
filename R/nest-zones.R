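#' Build Voronoi nest zones from annotated nest seeds
#'
#' Partitions a camera frame into one convex "nest zone" per annotated nest
#' location using a Voronoi tessellation (via [deldir::deldir()]) clipped to
#' the frame rectangle. Every pixel in a zone is closer to that zone's nest
#' seed than to any other seed, so zones are the natural spatial unit for
#' attributing chick detections to nests. Camera positions are fixed within a
#' season, so zones are computed once per site/year and reused for all images.
#'
#' Image coordinates follow the usual raster convention: origin at the
#' top-left corner, x increasing rightward, y increasing downward, in pixels.
#'
#' @param seeds Data frame with columns `nest_id`, `x`, `y` (pixel
#'   coordinates of each nest), one row per nest. `nest_id` may be character
#'   or integer; ordering of `nest_id` values defines the tie-break order for
#'   boundary points (lower id wins).
#' @param frame_width,frame_height Frame dimensions in pixels.
#' @returns An object of class `nest_map`: a list with elements `site_id`,
#'   `year_id` (filled by the caller or `NA`), `frame_width`, `frame_height`,
#'   `seeds` (tibble), and `zones`, a tibble with columns `nest_id`, `area`
#'   and a list-column `polygon` of two-column matrices (closed rings in
#'   pixel coordinates).
#' @param site_id,year_id Optional labels stored on the map.
#' @examples
#' seeds <- data.frame(nest_id = c("n1", "n2"), x = c(10, 30), y = c(10, 10))
#' m <- build_nest_zones(seeds, frame_width = 40, frame_height = 20)
#' m$zones
#' @export
build_nest_zones <- function(seeds, frame_width, frame_height,
                             site_id = NA_character_, year_id = NA_character_) {
  seeds <- tibble::as_tibble(seeds)
  stopifnot(all(c("nest_id", "x", "y") %in% names(seeds)), nrow(seeds) >= 1)
  if (anyDuplicated(seeds[, c("x", "y")])) {
    d <- which(duplicated(seeds[, c("x", "y")]) |
                 duplicated(seeds[, c("x", "y")], fromLast = TRUE))
    stop("duplicate nest seeds: ",
         paste(seeds$nest_id[d], collapse = ", "))
  }
  if (anyDuplicated(seeds$nest_id)) stop("duplicate nest_id values")
  out_of_frame <- seeds$x < 0 | seeds$x > frame_width |
    seeds$y < 0 | seeds$y > frame_height
  if (any(out_of_frame)) {
    stop("nest seeds outside the frame: ",
         paste(seeds$nest_id[out_of_frame], collapse = ", "))
  }
  seeds <- dplyr::arrange(seeds, .data$nest_id)

  if (nrow(seeds) == 1) {
    ring <- rbind(c(0, 0), c(frame_width, 0),
                  c(frame_width, frame_height), c(0, frame_height), c(0, 0))
    zones <- tibble::tibble(nest_id = seeds$nest_id,
                            area = frame_width * frame_height,
                            polygon = list(ring))
  } else {
    dd <- deldir::deldir(seeds$x, seeds$y,
                         rw = c(0, frame_width, 0, frame_height),
                         suppressMsge = TRUE)
    tiles <- deldir::tile.list(dd)
    polys <- lapply(tiles, function(tl) {
      ring <- cbind(tl$x, tl$y)
      rbind(ring, ring[1, , drop = FALSE])
    })
    zones <- tibble::tibble(
      nest_id = seeds$nest_id[vapply(tiles, function(tl) tl$ptNum, 1L)],
      area = unname(vapply(polys, polygon_area, 1.0)),
      polygon = polys
    )
    zones <- zones[order(zones$nest_id), ]
  }
  structure(
    list(site_id = site_id, year_id = year_id,
         frame_width = frame_width, frame_height = frame_height,
         seeds = seeds, zones = zones),
    class = "nest_map"
  )
}

#' @export
print.nest_map <- function(x, ...) {
  cat("<nest_map>", x$site_id, x$year_id, "-", nrow(x$seeds), "nests,",
      paste0(x$frame_width, "x", x$frame_height), "px frame\n")
  invisible(x)
}

# Shoelace area of a (closed or open) ring.
polygon_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1 }
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Assign chick detections to nest zones
#'
#' Assigns each detected chick location to the nest whose seed is nearest
#' (Euclidean distance in pixels), which for points off zone boundaries is
#' identical to point-in-zone membership. Points equidistant from two or
#' more seeds go to the lowest `nest_id` (deterministic tie-break). Per-nest
#' counts are capped at 2 — the clutch size the survival model assumes — and
#' a warning identifies capped records (annotation noise or crowding from
#' neighbouring nests).
#'
#' @param detections Data frame with columns `x`, `y` and optionally
#'   `timestamp`; one row per detected chick in one image.
#' @param map A [build_nest_zones()] result.
#' @returns A tibble with one row per nest: `nest_id`, `count` (0, 1 or 2),
#'   `n_points` (uncapped), plus `timestamp` if supplied.
#' @export
assign_detections <- function(detections, map) {
  stopifnot(inherits(map, "nest_map"))
  detections <- tibble::as_tibble(detections)
  if (nrow(detections) > 0) {
    bad <- detections$x < 0 | detections$x > map$frame_width |
      detections$y < 0 | detections$y > map$frame_height
    if (any(bad)) stop(sum(bad), " detection point(s) outside the frame")
  }
  counts <- integer(nrow(map$seeds))
  if (nrow(detections) > 0) {
    # nearest seed; ties resolved to the first (lowest) nest_id because
    # seeds are sorted by nest_id and which.min takes the first minimum
    d2 <- outer(detections$x, map$seeds$x, "-")^2 +
      outer(detections$y, map$seeds$y, "-")^2
    idx <- apply(d2, 1, which.min)
    tab <- tabulate(idx, nbins = nrow(map$seeds))
    counts <- tab
  }
  capped <- pmin(counts, 2L)
  if (any(counts > 2L)) {
    over <- which(counts > 2L)
    ts <- if ("timestamp" %in% names(detections) && nrow(detections) > 0)
      as.character(detections$timestamp[1]) else "<no timestamp>"
    warning("count capped at 2 (clutch size) for nest(s) ",
            paste(map$seeds$nest_id[over], collapse = ", "),
            " at ", ts, call. = FALSE)
  }
  out <- tibble::tibble(nest_id = map$seeds$nest_id,
                        count = capped, n_points = counts)
  if ("timestamp" %in% names(detections) && nrow(detections) > 0) {
    out$timestamp <- detections$timestamp[1]
  }
  out
}

#' Aggregate hourly chick counts to a daily count
#'
#' Daily resolution uses the highest number of chicks seen in a nest over
#' the course of a day; a day with no usable images is missing.
#'
#' @param counts Integer vector of within-day counts (0, 1, 2 or `NA`).
#' @returns A single integer, or `NA` if all inputs are missing/empty.
#' @examples
#' aggregate_daily(c(1, 2, 0, NA, 1))  # 2
#' @export
aggregate_daily <- function(counts) {
  counts <- counts[!is.na(counts)]
  if (length(counts) == 0) return(NA_integer_)
  stopifnot(all(counts %in% 0:2))
  as.integer(max(counts))
}

#' Export nest zones as GeoJSON for visual QC
#'
#' Writes the zone polygons (pixel coordinates) as a GeoJSON
#' FeatureCollection so they can be overlaid on a camera frame in any
#' GIS-style viewer.
#'
#' @param map A [build_nest_zones()] result.
#' @param path Output file path.
#' @returns `path`, invisibly.
#' @export
zones_to_geojson <- function(map, path) {
  stopifnot(inherits(map, "nest_map"))
  features <- purrr::map2(map$zones$nest_id, map$zones$polygon, function(id, ring) {
    list(
      type = "Feature",
      properties = list(nest_id = id),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)),
                                  function(r) as.numeric(ring[r, ])))
      )
    )
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @describeIn build_nest_zones Plot the tessellation with nest seeds.
#' @param object A `nest_map`.
#' @param ... Unused.
#' @export
autoplot.nest_map <- function(object, ...) {
  polys <- purrr::map2_dfr(object$zones$nest_id, object$zones$polygon,
                           function(id, ring) {
                             tibble::tibble(nest_id = as.character(id),
                                            x = ring[, 1], y = ring[, 2])
                           })
  ggplot2::ggplot() +
    ggplot2::geom_polygon(data = polys,
                          ggplot2::aes(.data$x, .data$y, group = .data$nest_id),
                          fill = NA, colour = "darkgreen") +
    ggplot2::geom_point(data = object$seeds,
                        ggplot2::aes(.data$x, .data$y), colour = "red") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)",
                  title = paste("Nest zones:", object$site_id, object$year_id))
}
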