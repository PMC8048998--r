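test_that("a single seed owns the entire frame", {
  m <- build_nest_zones(data.frame(nest_id = "a", x = 10, y = 10), 40, 20)
  expect_equal(nrow(m$zones), 1)
  expect_equal(m$zones$area, 800)
})

test_that("two seeds split the frame along the perpendicular bisector", {
  seeds <- data.frame(nest_id = c("n1", "n2"), x = c(10, 30), y = c(10, 10))
  m <- build_nest_zones(seeds, 40, 20)
  expect_equal(sort(m$zones$area), c(400, 400))
  # all vertices of each zone on the correct side of x = 20
  z1 <- m$zones$polygon[[which(m$zones$nest_id == "n1")]]
  z2 <- m$zones$polygon[[which(m$zones$nest_id == "n2")]]
  expect_true(all(z1[, 1] <= 20 + 1e-9))
  expect_true(all(z2[, 1] >= 20 - 1e-9))
})

test_that("zones partition the frame and match brute-force nearest-seed", {
  skip_if_not_installed("sp")
  set.seed(42)
  n <- 25
  seeds <- data.frame(nest_id = sprintf("n%02d", 1:n),
                      x = runif(n, 0, 640), y = runif(n, 0, 480))
  m <- build_nest_zones(seeds, 640, 480)
  # partition: areas sum to the frame area
  expect_equal(sum(m$zones$area), 640 * 480, tolerance = 1e-6)
  # zone membership by point-in-polygon equals nearest seed by distance scan
  qx <- runif(10000, 0, 640); qy <- runif(10000, 0, 480)
  d2 <- outer(qx, m$seeds$x, "-")^2 + outer(qy, m$seeds$y, "-")^2
  nearest <- apply(d2, 1, which.min)
  # drop points suspiciously close to a bisector (ties are a separate rule)
  second <- apply(d2, 1, function(r) sort(r)[2])
  off_boundary <- sqrt(second) - sqrt(d2[cbind(seq_along(qx), nearest)]) > 1e-6
  in_zone <- rep(NA_integer_, length(qx))
  for (k in seq_len(nrow(m$zones))) {
    ring <- m$zones$polygon[[k]]
    hit <- sp::point.in.polygon(qx, qy, ring[, 1], ring[, 2]) > 0
    in_zone[hit & is.na(in_zone)] <- match(m$zones$nest_id[k], m$seeds$nest_id)
  }
  idx <- off_boundary & !is.na(in_zone)
  expect_gt(mean(idx), 0.99)
  expect_equal(in_zone[idx], nearest[idx])
})

test_that("invalid seed sets are rejected with informative errors", {
  expect_error(
    build_nest_zones(data.frame(nest_id = c("a", "b"), x = c(1, 1), y = c(2, 2)),
                     10, 10),
    "duplicate nest seeds: a, b")
  expect_error(
    build_nest_zones(data.frame(nest_id = "a", x = 11, y = 5), 10, 10),
    "outside the frame: a")
})

test_that("detections are assigned to the nearest nest with the clutch cap", {
  seeds <- data.frame(nest_id = c("n1", "n2"), x = c(10, 30), y = c(10, 10))
  m <- build_nest_zones(seeds, 40, 20)
  out <- assign_detections(data.frame(x = 15, y = 5), m)
  expect_equal(out$count, c(1L, 0L))
  # three points in one zone cap at two chicks with a warning
  pts <- data.frame(x = c(9, 10, 11), y = c(9, 10, 11),
                    timestamp = "2015-01-01T10:00:00")
  expect_warning(out <- assign_detections(pts, m), "capped at 2.*n1")
  expect_equal(out$count[out$nest_id == "n1"], 2L)
  expect_equal(out$n_points[out$nest_id == "n1"], 3L)
  expect_error(assign_detections(data.frame(x = 50, y = 5), m),
               "outside the frame")
})

test_that("boundary ties go to the lower nest_id, deterministically", {
  seeds <- data.frame(nest_id = c("n1", "n2"), x = c(10, 30), y = c(10, 10))
  m <- build_nest_zones(seeds, 40, 20)
  reps <- replicate(5, assign_detections(data.frame(x = 20, y = 10), m)$count[1])
  expect_true(all(reps == 1L))
})

test_that("daily aggregation takes the max over non-missing hourly counts", {
  expect_equal(aggregate_daily(c(1, 2, 0, NA, 1)), 2L)
  expect_true(is.na(aggregate_daily(rep(NA_integer_, 16))))
  expect_true(is.na(aggregate_daily(integer())))
  expect_equal(aggregate_daily(c(0, 0, 0)), 0L)
  # idempotent on singletons, invariant to permutation
  expect_equal(aggregate_daily(2L), 2L)
  set.seed(1)
  v <- sample(c(0:2, NA), 10, replace = TRUE)
  expect_equal(aggregate_daily(v), aggregate_daily(rev(v)))
})

test_that("zones export to GeoJSON and read back with the same geometry", {
  seeds <- data.frame(nest_id = c("n1", "n2"), x = c(10, 30), y = c(10, 10))
  m <- build_nest_zones(seeds, 40, 20)
  path <- withr::local_tempfile(fileext = ".geojson")
  zones_to_geojson(m, path)
  gj <- jsonlite::read_json(path)
  expect_equal(gj$type, "FeatureCollection")
  expect_equal(length(gj$features), 2)
  ids <- vapply(gj$features, function(f) f$properties$nest_id, "")
  expect_setequal(ids, c("n1", "n2"))
})
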