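test_that("field 1 sits on the disc, field 2 on the fovea, field 3 temporal", {
  lay <- build_field_layout(c(-15, 1.5), c(0, 0), "OD")
  f <- lay$fields
  expect_equal(c(f$center_lon[1], f$center_lat[1]), c(-15, 1.5))
  expect_equal(c(f$center_lon[2], f$center_lat[2]), c(0, 0))
  # F3's nasal edge touches the fovea: center 15 deg temporal along axis
  d3 <- sqrt(f$center_lon[3]^2 + f$center_lat[3]^2)
  expect_equal(d3, 15, tolerance = 1e-9)
  expect_gt(f$center_lon[3], 0)
  expect_equal(nrow(f), 7)
  expect_true(all(f$radius_deg == 15))
})

test_that("OS layouts are the longitude mirror image of OD layouts", {
  od <- build_field_layout(c(-15.5, 1.5), c(0, 0), "OD")
  os <- build_field_layout(c(15.5, 1.5), c(0, 0), "OS")
  expect_equal(os$fields$center_lon, -od$fields$center_lon, tolerance = 1e-9)
  expect_equal(os$fields$center_lat, od$fields$center_lat, tolerance = 1e-9)
})

test_that("degenerate or inconsistent landmarks are rejected", {
  expect_error(build_field_layout(c(0, 0), c(0, 0), "OD"), "coincide")
  expect_error(build_field_layout(c(15, 1.5), c(0, 0), "OD"), "landmark")
  expect_error(build_field_layout(c(-15, 1.5), c(0, 0), "OS"), "landmark")
})

test_that("union area agrees with a Monte-Carlo point-in-union estimate", {
  lay <- build_field_layout(c(-15.5, 1.5), c(0, 0), "OD")
  ua <- layout_union_area(lay)
  set.seed(31)
  n <- 1e6
  v <- matrix(rnorm(3 * n), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  v <- v[v[, 3] > 0, ] # fields live well inside the posterior hemisphere
  centers <- or_chart_to_xyz(cbind(lay$fields$center_lon,
                                   lay$fields$center_lat))
  ang <- acos(pmin(pmax(v %*% t(centers), -1), 1)) * 180 / pi
  inside <- apply(ang <= lay$field_radius_deg, 1, any)
  mc <- mean(inside) * 2 * pi * rq_eye_radius()^2
  expect_lt(abs(ua / mc - 1), 0.005)
})

test_that("layout GeoJSON export writes seven polygon features", {
  lay <- build_field_layout(c(-15.5, 1.5), c(0, 0), "OD")
  f <- tempfile(fileext = ".geojson")
  write_layout_geojson(lay, f)
  gj <- jsonlite::read_json(f)
  expect_equal(length(gj$features), 7)
  expect_equal(gj$crs_note, "retinal-degrees")
  unlink(f)
})
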