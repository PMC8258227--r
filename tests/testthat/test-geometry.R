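test_that("absolute-angle and azimuth conversions anchor to the compass convention", {
  expect_equal(absangle_to_azimuth(0), 90)
  expect_equal(absangle_to_azimuth(pi / 2), 0)
  expect_equal(absangle_to_azimuth(-pi / 2), 180)
  expect_equal(absangle_to_azimuth(pi), 270)
  expect_equal(absangle_to_azimuth(pi / 4), 45)
  expect_equal(azimuth_to_absangle(90), 0)
  expect_equal(azimuth_to_absangle(0), pi / 2)
  expect_equal(azimuth_to_absangle(270), pi)  # +pi, not -pi
  expect_error(absangle_to_azimuth(NaN))
  expect_error(azimuth_to_absangle(360))
  expect_error(azimuth_to_absangle(-1))
})

test_that("conversions are mutual inverses on a 0.1-degree grid", {
  az <- seq(0, 359.9, by = 0.1)
  expect_equal(absangle_to_azimuth(azimuth_to_absangle(az)), az,
               tolerance = 1e-9)
  theta <- wrap_pi(seq(-pi + 0.001, pi, length.out = 500))
  expect_equal(azimuth_to_absangle(absangle_to_azimuth(theta)), theta,
               tolerance = 1e-9)
})

test_that("declination is added east-positive and wraps", {
  expect_equal(apply_declination(30, 5.133), 35.133)
  expect_equal(apply_declination(123.4, 0), 123.4)
  expect_equal(apply_declination(358, 5.133), 3.133)
  expect_error(apply_declination(400, 0))
})

test_that("circular bearing error is symmetric, bounded and metric-like", {
  expect_equal(circular_error_deg(350, 10), 20)
  expect_equal(circular_error_deg(90, 90), 0)
  expect_equal(circular_error_deg(0, 180), 180)
  set.seed(1)
  a <- runif(200, 0, 360); b <- runif(200, 0, 360); c <- runif(200, 0, 360)
  expect_equal(circular_error_deg(a, b), circular_error_deg(b, a))
  expect_true(all(circular_error_deg(a, b) >= 0))
  expect_true(all(circular_error_deg(a, b) <= 180))
  expect_true(all(circular_error_deg(a, c) <=
                    circular_error_deg(a, b) + circular_error_deg(b, c) + 1e-9))
})

test_that("dead reckoning matches an independent geodesic oracle", {
  start <- c(19.0609, 47.4724)
  one <- db_to_coords(start, data.frame(distance_m = 10, azimuth_deg = 0))
  d_geo <- geosphere::distGeo(start, c(one$lon[2], one$lat[2]))
  expect_equal(d_geo, 10, tolerance = 0.01 / 10)
  expect_gt(one$lat[2], start[2])          # due north
  expect_equal(one$lon[2], start[1])
  p100 <- geosphere::destPoint(start, 0, 100)
  xy <- local_project(p100[1], p100[2], start)
  expect_equal(xy$x, 0, tolerance = 0.05)
  expect_equal(xy$y, 100, tolerance = 0.05)
})

test_that("empty, out-and-back and collinear paths behave", {
  start <- c(19.0609, 47.4724)
  expect_equal(nrow(db_to_coords(start, data.frame(distance_m = numeric(0),
                                                   azimuth_deg = numeric(0)))), 1)
  oab <- db_to_coords(start, data.frame(distance_m = c(15, 15),
                                        azimuth_deg = c(73, (73 + 180) %% 360)))
  back <- local_project(oab$lon[3], oab$lat[3], start)
  expect_lt(sqrt(back$x^2 + back$y^2), 1e-3)   # within 1 mm
  line <- db_to_coords(start, data.frame(distance_m = c(5, 7),
                                         azimuth_deg = c(40, 40)))
  s <- coords_to_steps(line$lon, line$lat)
  expect_equal(s$turning_angles, 0, tolerance = 1e-9)
  expect_equal(length(coords_to_steps(19.06, 47.47)$step_lengths), 0)
  expect_error(db_to_coords(start, data.frame(distance_m = -1, azimuth_deg = 0)),
               "order 1")
})

test_that("DB -> coordinates -> steps round trip recovers the design", {
  set.seed(7)
  start <- c(19.0609, 47.4724)
  for (i in 1:100) {
    n <- sample(2:50, 1)
    steps <- data.frame(distance_m = round(runif(n, 0.5, 20), 1),
                        azimuth_deg = runif(n, 0, 359.99))
    pts <- db_to_coords(start, steps)
    got <- coords_to_steps(pts$lon, pts$lat)
    expect_equal(got$step_lengths, steps$distance_m,
                 tolerance = 1e-3)                       # 0.1 %
    expect_true(all(circular_error_deg(got$abs_azimuths,
                                       steps$azimuth_deg) < 0.1))
    expect_equal(sum(got$step_lengths), sum(steps$distance_m),
                 tolerance = 1e-3)
  }
})

test_that("planar and spherical dead reckoning agree at fine scale", {
  start <- c(19.0609, 47.4724)
  set.seed(3)
  steps <- data.frame(distance_m = runif(40, 0.5, 20),
                      azimuth_deg = runif(40, 0, 360 - 1e-9))
  a <- db_to_coords(start, steps, mode = "planar")
  b <- db_to_coords(start, steps, mode = "sphere")
  xy_a <- local_project(a$lon, a$lat, start)
  xy_b <- local_project(b$lon, b$lat, start)
  gap <- sqrt((xy_a$x - xy_b$x)^2 + (xy_a$y - xy_b$y)^2)
  expect_lt(max(gap), 0.005)   # sub-5 mm over a few-hundred-meter track
})

test_that("local projection round-trips and flags excessive extent", {
  origin <- c(19.0609, 47.4724)
  expect_equal(unlist(local_project(origin[1], origin[2], origin)),
               c(x = 0, y = 0))
  set.seed(9)
  x <- runif(50, -1000, 1000); y <- runif(50, -1000, 1000)
  p <- local_unproject(x, y, origin)
  back <- local_project(p$lon, p$lat, origin)
  expect_equal(back$x, x, tolerance = 1e-6)
  expect_equal(back$y, y, tolerance = 1e-6)
  expect_warning(local_project(origin[1] + 1, origin[2], origin), "10 km")
})

test_that("zero-length steps yield missing azimuths, never a northward bearing", {
  tr <- track_from_xy(c(0, 0, 3, 3, 10), c(0, 0, 4, 4, 4))
  s <- coords_to_steps(tr$lon, tr$lat)
  expect_equal(s$step_lengths, c(0, 5, 0, 7), tolerance = 1e-6)
  expect_true(is.na(s$abs_azimuths[1]) && is.na(s$abs_azimuths[3]))
  expect_true(all(is.na(s$turning_angles)))  # every turn touches a zero step
  full <- coords_to_steps(tr$lon[c(1, 3, 5)], tr$lat[c(1, 3, 5)])
  expect_false(any(is.na(full$turning_angles)))
})
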