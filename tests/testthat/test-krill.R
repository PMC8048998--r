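# Synthetic SSMU fixtures are built around a site at (58 W, 62.5 S); the
# rectangles are huge relative to the 150 km buffer so only the dividing
# meridian matters for the half/half case.
site_lon <- -58
site_lat <- -62.5

rect_feature <- function(id, lon_min, lon_max, lat_min, lat_max) {
  list(type = "Feature",
       properties = list(ssmu_id = id),
       geometry = list(
         type = "Polygon",
         coordinates = list(list(
           list(lon_min, lat_min), list(lon_max, lat_min),
           list(lon_max, lat_max), list(lon_min, lat_max),
           list(lon_min, lat_min)))))
}

write_ssmu <- function(features) {
  path <- withr::local_tempfile(fileext = ".geojson",
                                .local_envir = parent.frame())
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  path
}

catch_flat <- function(ids, tonnes_per_month) {
  tidyr::expand_grid(ssmu_id = ids, year = 2014:2015, month = 1:12) |>
    dplyr::mutate(tonnes = tonnes_per_month)
}

test_that("a buffer wholly inside one SSMU inherits its full window catch", {
  path <- write_ssmu(list(rect_feature("A", -70, -46, -70, -55)))
  ssmu <- read_ssmu_geojson(path)
  catch <- catch_flat("A", 100)  # 11-month window -> 1100 t
  tot <- krill_buffer_catch(site_lon, site_lat, ssmu, catch,
                            season_end_year = 2015)
  expect_equal(as.numeric(tot), 1100, tolerance = 1e-6)
  w <- attr(tot, "weights")
  expect_equal(w$weight, 1, tolerance = 1e-6)
})

test_that("two SSMUs covering half the buffer each give the 50/50 average", {
  path <- write_ssmu(list(
    rect_feature("W", -80, site_lon, -70, -55),
    rect_feature("E", site_lon, -36, -70, -55)))
  ssmu <- read_ssmu_geojson(path)
  # window totals: W = 1000 t, E = 2000 t
  catch <- dplyr::bind_rows(
    catch_flat("W", 1000 / 11),
    catch_flat("E", 2000 / 11))
  tot <- krill_buffer_catch(site_lon, site_lat, ssmu, catch,
                            season_end_year = 2015)
  w <- attr(tot, "weights")
  expect_equal(sort(w$weight), c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(sum(w$weight), 1, tolerance = 1e-6)
  expect_equal(as.numeric(tot), 1500, tolerance = 1e-6)
})

test_that("weights never exceed one and partial coverage drops catch", {
  # single SSMU covering only the eastern half: weight 0.5, half the catch
  path <- write_ssmu(list(rect_feature("E", site_lon, -36, -70, -55)))
  ssmu <- read_ssmu_geojson(path)
  tot <- krill_buffer_catch(site_lon, site_lat, ssmu, catch_flat("E", 100),
                            season_end_year = 2015)
  w <- attr(tot, "weights")
  expect_equal(w$weight, 0.5, tolerance = 1e-6)
  expect_lte(sum(w$weight), 1)
  expect_equal(as.numeric(tot), 550, tolerance = 1e-6)
})

test_that("zero SSMU overlap returns zero tonnes with a warning", {
  path <- write_ssmu(list(rect_feature("FAR", 0, 10, 0, 10)))
  ssmu <- read_ssmu_geojson(path)
  expect_warning(
    tot <- krill_buffer_catch(site_lon, site_lat, ssmu,
                              catch_flat("FAR", 100), 2015),
    "zero overlap")
  expect_equal(as.numeric(tot), 0)
})

test_that("the catch window runs March of year t-1 through January of year t", {
  path <- write_ssmu(list(rect_feature("A", -70, -46, -70, -55)))
  ssmu <- read_ssmu_geojson(path)
  catch <- tibble::tibble(
    ssmu_id = "A",
    year = c(2014, 2014, 2015, 2015, 2014),
    month = c(2, 3, 1, 2, 12),
    tonnes = c(7, 100, 200, 11, 300))
  # Feb 2014 and Feb 2015 fall outside; Mar+Dec 2014 and Jan 2015 inside
  tot <- krill_buffer_catch(site_lon, site_lat, ssmu, catch, 2015)
  expect_equal(as.numeric(tot), 600, tolerance = 1e-6)
})

test_that("overlay weights agree with a Monte-Carlo area oracle", {
  skip_if_not_installed("sp")
  # three staggered rectangles partially covering the buffer
  path <- write_ssmu(list(
    rect_feature("A", -80, -58.5, -70, -55),
    rect_feature("B", -58.5, -57.2, -70, -62.4),
    rect_feature("C", -58.5, -57.2, -62.4, -55)))
  ssmu <- read_ssmu_geojson(path)
  w <- ssmu_buffer_weights(site_lon, site_lat, ssmu, radius_km = 150)
  rho <- 2 * 6371.0088 * sin(150 / (2 * 6371.0088))
  set.seed(20)
  for (s in seq_len(nrow(ssmu))) {
    proj <- camcr::laea_project(ssmu$rings[[s]][[1]][, 1],
                                ssmu$rings[[s]][[1]][, 2],
                                site_lon, site_lat)
    mc <- mc_disc_coverage(proj, rho, n = 2e5)
    expect_lt(abs(w$weight[s] - mc), 0.01)
  }
  expect_lte(sum(w$weight), 1 + 1e-9)
})

test_that("the equal-area projection preserves geodesic distances near centre", {
  # a point 150 km due north of the site projects ~150 km away
  skip_if_not_installed("geosphere")
  dest <- geosphere::destPoint(c(site_lon, site_lat), b = 0, d = 150000)
  xy <- laea_project(dest[1], dest[2], site_lon, site_lat)
  expect_equal(sqrt(sum(xy^2)), 150, tolerance = 0.01)
})
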