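test_that("polygon_area computes calibrated shoelace areas", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(polygon_area(sq, 1), 1)

  tri <- cbind(c(0, 4, 0), c(0, 0, 3))
  expect_equal(polygon_area(tri, 2.74), 6 * 2.74^2) # 45.0456

  # 256-gon approximation of a radius-100 circle within 0.1% of pi r^2
  circ <- circle_poly(0, 0, 100, 256)
  expect_lt(abs(polygon_area(circ, 1) - pi * 1e4) / (pi * 1e4), 0.001)
})

test_that("polygon_area is invariant under translation, rotation of vertex order, and reversal", {
  set.seed(42)
  for (i in 1:20) {
    v <- random_star_polygon(n = sample(5:20, 1))
    a <- polygon_area(v, 2.74)
    shift <- sweep(v, 2, stats::runif(2, -100, 100), "+")
    expect_equal(polygon_area(shift, 2.74), a, tolerance = 1e-10)
    k <- sample(nrow(v), 1)
    rotated <- v[c(k:nrow(v), seq_len(k - 1)), ]
    expect_equal(polygon_area(rotated, 2.74), a)
    expect_equal(polygon_area(v[nrow(v):1, ], 2.74), a)
  }
})

test_that("polygon_area rejects degenerate and self-intersecting contours", {
  expect_error(polygon_area(cbind(c(0, 1), c(0, 1))), "3 distinct vertices")
  bowtie <- cbind(c(0, 1, 1, 0), c(0, 1, 0, 1))
  expect_error(polygon_area(bowtie), "edge 1 crosses edge 3")
  collinear <- cbind(c(0, 1, 2), c(0, 0, 0))
  expect_error(polygon_area(collinear), "zero area")
  expect_error(polygon_area(cbind(c(0, 1, NA), c(0, 0, 1))), "missing")
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_error(polygon_area(sq, pixel_pitch = 0), "pixel_pitch")
})

test_that("measure_osteon pairs outline and canal with invariant checks", {
  outer <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  inner <- cbind(c(4, 6, 6, 4), c(4, 4, 6, 6))
  m <- measure_osteon(outer, inner, 1, "S1", "os1")
  expect_equal(m$onar_um2, 100)
  expect_equal(m$har_um2, 4)

  # synthetic annulus with known radii: within 1% of analytic areas
  m2 <- measure_osteon(circle_poly(50, 50, 40), circle_poly(50, 50, 6),
                       2.74, "S1", "os2")
  expect_lt(abs(m2$onar_um2 - pi * (40 * 2.74)^2) / (pi * (40 * 2.74)^2), 0.01)
  expect_lt(abs(m2$har_um2 - pi * (6 * 2.74)^2) / (pi * (6 * 2.74)^2), 0.01)

  # canal identical to outline -> mis-trace error
  expect_error(measure_osteon(outer, outer, 1), "mis-traced")
  # canal outside the outline -> containment error
  outside <- cbind(c(20, 22, 22, 20), c(20, 20, 22, 22))
  expect_error(measure_osteon(outer, outside, 1), "not inside")
})

test_that("summarize_specimen reduces measurements with sample SD and SE", {
  m <- data.frame(specimen_id = "S", osteon_id = 1:3,
                  onar_um2 = c(13000, 13500, 14731.7),
                  har_um2 = c(400, 450, 500))
  s <- summarize_specimen(m)
  expect_equal(s$mean_onar, 13743.9)
  expect_equal(s$sd_onar, stats::sd(c(13000, 13500, 14731.7)))
  expect_equal(s$se_onar, s$sd_onar / sqrt(3))
  expect_equal(s$n_on, 3L)

  one <- summarize_specimen(m[1, ])
  expect_equal(one$mean_onar, 13000)
  expect_true(is.na(one$sd_onar))

  expect_error(summarize_specimen(m[0, ]), "no measurements")
  m2 <- m; m2$specimen_id <- c("S", "S", "T")
  expect_error(summarize_specimen(m2), "multiple specimens")
})

test_that("summary statistics recover generator targets within sampling error", {
  cfg <- population_config("SIM", 500, 18174.1, 5226.5, 478.7, 186.2,
                           seed = 101)
  s <- summarize_specimen(generate_population(cfg))
  # mean within 2 standard errors of the target
  expect_lt(abs(s$mean_onar - 18174.1), 2 * 5226.5 / sqrt(500))
  expect_lt(abs(s$mean_har - 478.7), 2 * 186.2 / sqrt(500))
})

test_that("dispersion_to_sd converts SE via sqrt(n) and passes SD through", {
  expect_equal(dispersion_to_sd(224893.3, 27974.9, "SE", 18),
               27974.9 * sqrt(18))
  expect_equal(dispersion_to_sd(23984.0, 6324.2, "SD", 41), 6324.2)
  expect_error(dispersion_to_sd(1, 1, "SE", 1), "n must be")
  expect_error(dispersion_to_sd(1, 1, "CI", 10), "unknown dispersion kind")

  # round trip: SD back to SE returns the input to machine precision
  for (n in c(2, 18, 117)) {
    se <- 987.6
    expect_equal(dispersion_to_sd(5584.1, se, "SE", n) / sqrt(n), se)
  }
})

test_that("contour files round-trip through JSON and CSV", {
  contours <- structure(
    list(specimen_id = "S9", calibration_um_per_px = 2.74,
         osteons = list(
           list(id = "a", outline = circle_poly(40, 40, 20, 128),
                canal = circle_poly(40, 40, 3, 128)),
           list(id = "b", outline = cbind(c(100, 120, 120, 100),
                                          c(100, 100, 120, 120)),
                canal = cbind(c(108, 112, 112, 108), c(108, 108, 112, 112))))),
    class = "contour_set")

  jpath <- tempfile(fileext = ".json")
  write_contours_json(contours, jpath)
  back <- read_contours_json(jpath)
  expect_equal(back$specimen_id, "S9")
  expect_equal(back$calibration_um_per_px, 2.74)
  expect_equal(back$osteons[[1]]$outline, contours$osteons[[1]]$outline,
               ignore_attr = TRUE)

  meas <- measure_contours(back)
  expect_equal(nrow(meas), 2)
  expect_equal(meas$onar_um2[meas$osteon_id == "b"], 400 * 2.74^2)
  expect_true(all(meas$har_um2 < meas$onar_um2))

  # long CSV carrying the same information measures identically
  long <- do.call(rbind, lapply(contours$osteons, function(o) {
    rbind(
      data.frame(specimen_id = "S9", osteon_id = o$id, role = "outline",
                 vertex_index = seq_len(nrow(o$outline)),
                 x = o$outline[, 1], y = o$outline[, 2],
                 calibration_um_per_px = 2.74),
      data.frame(specimen_id = "S9", osteon_id = o$id, role = "canal",
                 vertex_index = seq_len(nrow(o$canal)),
                 x = o$canal[, 1], y = o$canal[, 2],
                 calibration_um_per_px = 2.74))
  }))
  cpath <- tempfile(fileext = ".csv")
  utils::write.csv(long, cpath, row.names = FALSE)
  meas2 <- measure_contours(read_contours_csv(cpath))
  expect_equal(meas2[order(meas2$osteon_id), c("onar_um2", "har_um2")],
               meas[order(meas$osteon_id), c("onar_um2", "har_um2")],
               ignore_attr = TRUE)
})

test_that("report rounding is half-away-from-zero at one decimal", {
  expect_equal(round_report(24232.133), 24232.1)
  expect_equal(round_report(0.05), 0.1)
  expect_equal(round_report(-0.05), -0.1)
  expect_equal(round_report(654.049999), 654.0)
})
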