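test_that("landing g-force matches the unit-conversion oracle on a step profile", {
  # -600 -> 0 ft/min across one 0.1 s sample, derived by hand:
  # (600 ft/min * 0.3048 m/ft / 60 s) / 0.1 s / 9.8 m/s^2
  oracle <- (600 * 0.3048 / 60) / 0.1 / 9.8
  expect_equal(landing_gforce(step_trace()), oracle, tolerance = 1e-12)
  expect_equal(round(landing_gforce(step_trace()), 2), 3.11)
  # zero vertical speed near touchdown -> 0 g
  zero <- flat_trace(rep(0, 6), alt = c(5, 4, 3, 2, 1, 0))
  expect_equal(landing_gforce(zero), 0)
  # halving the step exactly halves the g
  half <- flat_trace(c(rep(-300, 5), 0), alt = c(5, 4, 3, 2, 1, 0))
  expect_equal(landing_gforce(half), oracle / 2, tolerance = 1e-12)
  # missed landings have no defined g-force
  m <- flight_trace(seq(0, 0.5, 0.1), rep(34, 6), rep(-118, 6),
                    alt = rep(50, 6), vspeed = rep(-100, 6), missed = TRUE)
  expect_true(is.na(landing_gforce(m)))
})

test_that("geodetic-to-Cartesian is a local ENU transform on a spherical Earth", {
  origin <- c(lat = 0, lon = 0)
  expect_equal(as.numeric(geodetic_to_cartesian(0, 0, 0, origin)),
               c(0, 0, 0))
  # 1 degree of latitude = great-circle arc R * pi / 180
  north <- geodetic_to_cartesian(1, 0, 0, origin)
  expect_equal(unname(north[1, "y"]), 6371000 * pi / 180, tolerance = 1e-9)
  expect_equal(unname(north[1, "y"]), 111194.9, tolerance = 1e-6)
  # independent oracle: spherical great-circle distance (geosphere)
  skip_if_not_installed("geosphere")
  d <- geosphere::distCosine(c(0, 0), c(0, 1), r = 6371000)
  expect_equal(unname(north[1, "y"]), d, tolerance = 1e-6)
  # altitude-only offset is a pure unit conversion
  up <- geodetic_to_cartesian(0, 0, 100, origin)
  expect_equal(as.numeric(up), c(0, 0, 100 * 0.3048))
  expect_error(geodetic_to_cartesian(95, 0, 0, origin), "latitude")
})

test_that("path deviation sums aligned Euclidean distances and matches brute force", {
  ap <- autopilot_trace()
  expect_equal(path_deviation(ap, ap), 0)
  # constant 10 m vertical offset over 100 aligned samples -> 1000 m
  n <- 100
  base <- flat_trace(rep(-300, n), alt = seq(99, 0))
  lifted <- flight_trace(base$t, base$lat, base$lon,
                         base$alt + 10 / 0.3048, base$vspeed)
  expect_equal(path_deviation(lifted, base, window = 1), 1000,
               tolerance = 1e-9)
  # window = 1 equals the naive pointwise oracle on equal-length traces
  set.seed(31)
  a <- generate_flight_trace(ap, skill = 2, seed = 32)
  ns <- min(length(a), length(ap))
  a_trim <- flight_trace(a$t[1:ns], a$lat[1:ns], a$lon[1:ns],
                         a$alt[1:ns], a$vspeed[1:ns])
  ap_trim <- flight_trace(ap$t[1:ns], ap$lat[1:ns], ap$lon[1:ns],
                          ap$alt[1:ns], ap$vspeed[1:ns])
  origin <- c(lat = ap$lat[ap$touchdown_index], lon = ap$lon[ap$touchdown_index])
  xs <- geodetic_to_cartesian(a_trim$lat, a_trim$lon, a_trim$alt, origin)
  xa <- geodetic_to_cartesian(ap_trim$lat, ap_trim$lon, ap_trim$alt, origin)
  brute <- sum(sqrt(rowSums((xs - xa)^2)))
  expect_equal(path_deviation(a_trim, ap_trim, window = 1, origin = origin),
               brute, tolerance = 1e-9)
  expect_gte(path_deviation(a, ap), 0)
  expect_error(path_deviation(flat_trace(rep(-1, 5)), ap, window = 10),
               "shorter than the alignment window")
})

test_that("vertical-speed deviation matches the pointwise oracle", {
  n <- 50
  a <- flat_trace(rep(-500, n))
  b <- flat_trace(rep(-600, n))
  expect_equal(vspeed_deviation(a, a), 0)
  expect_equal(vspeed_deviation(a, b, window = 1), 100 * n)
  set.seed(33)
  va <- rnorm(80, -500, 50); vb <- rnorm(80, -500, 50)
  expect_equal(vspeed_deviation(flat_trace(va), flat_trace(vb), window = 1),
               sum(abs(va - vb)), tolerance = 1e-9)
})

test_that("vertical-speed variance has the closed forms and scaling law", {
  expect_equal(vspeed_variance(flat_trace(rep(-600, 40))), 0)
  # +/- a around a constant mean: sample variance a^2 * n / (n - 1)
  n <- 400; a <- 35
  alternating <- flat_trace(-500 + a * rep(c(1, -1), n / 2))
  expect_equal(vspeed_variance(alternating), a^2 * n / (n - 1),
               tolerance = 1e-12)
  expect_equal(vspeed_variance(alternating), a^2, tolerance = 0.01)
  set.seed(34)
  v <- rnorm(60, -400, 80)
  expect_equal(vspeed_variance(flat_trace(3 * v)),
               9 * vspeed_variance(flat_trace(v)), tolerance = 1e-9)
})

test_that("control inputs count vertical-speed sign changes with zero hysteresis", {
  expect_equal(control_inputs(flat_trace(c(-1, -2, -3, -1))), 0)
  expect_equal(control_inputs(flat_trace(c(-1, -2, 1, -1))), 2)
  # zeros inherit the previous sign: a held 0 ft/min counts nothing
  expect_equal(control_inputs(flat_trace(c(-1, 0, 0, -2))), 0)
  expect_equal(control_inputs(flat_trace(c(-1, 0, 0, 2))), 1)
  # invariant to positive rescaling
  set.seed(35)
  v <- rnorm(50)
  expect_equal(control_inputs(flat_trace(v)),
               control_inputs(flat_trace(v * 17.3)))
  # the autopilot reference has exactly 1 major control input (the flare)
  expect_equal(control_inputs(autopilot_trace()), 1)
})

test_that("missed-landing classification is inclusive at the runway end", {
  origin <- c(lat = 34, lon = -118)
  mk <- function(dist_m) {
    lat_td <- 34 + dist_m / (6371000 * pi / 180)
    flight_trace(seq(0, 0.2, 0.1), c(34, 34, lat_td), rep(-118, 3),
                 alt = c(10, 5, 0), vspeed = rep(-300, 3))
  }
  expect_false(classify_missed(mk(500), origin, 1000))
  expect_false(classify_missed(mk(1000), origin, 1000))  # boundary inclusive
  expect_true(classify_missed(mk(1100), origin, 1000))
  no_td <- flight_trace(seq(0, 0.2, 0.1), rep(34, 3), rep(-118, 3),
                        alt = c(30, 30, 30), vspeed = rep(0, 3), missed = TRUE)
  expect_true(classify_missed(no_td, origin, 1000))
})

test_that("metrics are invariant to the time origin", {
  ap <- autopilot_trace()
  shifted <- flight_trace(ap$t + 100, ap$lat, ap$lon, ap$alt, ap$vspeed)
  expect_equal(landing_gforce(shifted), landing_gforce(ap))
  expect_equal(vspeed_variance(shifted), vspeed_variance(ap))
  expect_equal(control_inputs(shifted), control_inputs(ap))
})

test_that("the autopilot reference matches its stated profile", {
  ap <- autopilot_trace()
  pre_flare <- ap$vspeed[seq_len(ap$touchdown_index - 51)]
  expect_true(all(pre_flare == -600))  # constant until the final 5 s
  expect_false(is.na(ap$touchdown_index))
  expect_equal(ap$alt[ap$touchdown_index], 0)
  expect_true(all(diff(ap$alt[seq_len(ap$touchdown_index)]) <= 0))
})

test_that("subject traces converge to the reference as skill grows", {
  ap <- autopilot_trace()
  perfect <- generate_flight_trace(ap, skill = Inf)
  expect_identical(perfect, ap)
  expect_equal(path_deviation(perfect, ap), 0)
  expect_equal(vspeed_deviation(perfect, ap), 0)
  set.seed(36)
  rough <- mean(replicate(5, path_deviation(
    generate_flight_trace(ap, skill = 0.5), ap)))
  fine <- mean(replicate(5, path_deviation(
    generate_flight_trace(ap, skill = 5), ap)))
  expect_lt(fine, rough)
  expect_error(flight_trace(c(0, 0.2, 0.1), 1:3, 1:3, c(3, 2, 1), 1:3),
               "strictly increasing")
})
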