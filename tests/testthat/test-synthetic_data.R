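test_that("population generator is deterministic and respects constraints", {
  cfg <- population_config("P", 200, 18174.1, 5226.5, 478.7, 186.2, seed = 11)
  a <- generate_population(cfg)
  b <- generate_population(cfg)
  expect_identical(a, b)
  expect_true(all(a$har_um2 < a$onar_um2))
  expect_true(all(a$onar_um2 > 0))
  expect_equal(attr(a, "seed"), 11L)

  one <- generate_population(population_config("P", 1, 100, 1, 10, 1, seed = 2))
  expect_equal(nrow(one), 1)
  expect_true(is.na(summarize_specimen(one)$sd_onar))

  expect_error(population_config("P", 10, 100, 10, 200, 10), "infeasible")
  expect_error(population_config("P", 10, 100, -1, 10, 1), "positive")
  expect_error(population_config("P", 10, 100, 10, 10, 1, correlation = 1),
               "correlation")
})

test_that("large populations recover the configured moments within 2%", {
  # FK-B-003-like targets, n inflated to 5000
  cfg <- population_config("BIG", 5000, 18174.1, 5226.5, 478.7, 186.2,
                           seed = 31)
  s <- summarize_specimen(generate_population(cfg))
  expect_lt(abs(s$mean_onar / 18174.1 - 1), 0.02)
  expect_lt(abs(s$sd_onar / 5226.5 - 1), 0.02)
  expect_lt(abs(s$mean_har / 478.7 - 1), 0.02)
  expect_lt(abs(s$sd_har / 186.2 - 1), 0.02)

  # heavy truncation case (SD ~ 0.74 x mean): moment matching still holds;
  # bound the mean by 3 standard errors (relative 2% is only ~1.9 SE here)
  cfg2 <- population_config("TRUNC", 5000, 15936.1, 3689.1, 500.5, 370.7,
                            seed = 32)
  s2 <- summarize_specimen(generate_population(cfg2))
  expect_lt(abs(s2$mean_har - 500.5), 3 * 370.7 / sqrt(5000))
  expect_lt(abs(s2$sd_har / 370.7 - 1), 0.05)

  # lognormal alternative matches its moments too
  cfg3 <- population_config("LN", 5000, 18174.1, 5226.5, 478.7, 186.2,
                            seed = 33, distribution = "lognormal")
  s3 <- summarize_specimen(generate_population(cfg3))
  expect_lt(abs(s3$mean_onar / 18174.1 - 1), 0.02)
  expect_lt(abs(s3$sd_onar / 5226.5 - 1), 0.05) # lognormal SD converges slower
})

test_that("synthetic slices carry analytic ground truth recoverable by measurement", {
  cfg <- slice_config(image_size = 640, pixel_pitch = 2.74, osteon_count = 6,
                      target_onar = pi * (70 * 2.74)^2, target_har = 500,
                      seed = 5)
  sl <- generate_slice(cfg)
  expect_equal(dim(sl$image), c(640, 640))
  expect_true(all(sl$image >= 0 & sl$image <= 1))
  expect_equal(nrow(sl$ground_truth), 6)

  # ground truth equals the analytic circle area by construction
  expect_equal(unique(sl$ground_truth$onar_um2), pi * (70 * 2.74)^2,
               tolerance = 1e-10)

  # measuring the ground-truth contours recovers analytic areas within 1%
  meas <- measure_contours(sl$contours)
  expect_equal(nrow(meas), 6)
  expect_true(all(abs(meas$onar_um2 / sl$ground_truth$onar_um2 - 1) < 0.01))
  expect_true(all(abs(meas$har_um2 / sl$ground_truth$har_um2 - 1) < 0.01))

  # independent pixel-counting oracle on a noise-free slice: the bright
  # annulus + dark lumen pixel count approximates the osteon disk area
  cfg0 <- slice_config(image_size = 640, pixel_pitch = 2.74, osteon_count = 6,
                       target_onar = pi * (70 * 2.74)^2, target_har = 500,
                       noise_sd = 0, seed = 5)
  sl0 <- generate_slice(cfg0)
  disk_px <- sum(sl0$image > 0.7) + sum(sl0$image < 0.3)
  disk_um2 <- disk_px * 2.74^2
  expect_lt(abs(disk_um2 / sum(sl0$ground_truth$onar_um2) - 1), 0.02)

  # osteons are disjoint and inside the frame
  ctr <- sl$ground_truth
  r_px <- sqrt(cfg$target_onar / pi) / cfg$pixel_pitch
  expect_true(all(ctr$center_x_px > r_px & ctr$center_x_px < 640 - r_px))
  if (nrow(ctr) > 1) {
    d <- as.matrix(stats::dist(ctr[, c("center_x_px", "center_y_px")]))
    expect_true(all(d[upper.tri(d)] > 2 * r_px))
  }
})

test_that("slice generation is deterministic and validates packing", {
  cfg <- slice_config(osteon_count = 4, seed = 9)
  s1 <- generate_slice(cfg)
  s2 <- generate_slice(cfg)
  expect_identical(s1$image, s2$image)

  # byte-identical contour JSON under a fixed seed
  p1 <- tempfile(fileext = ".json"); p2 <- tempfile(fileext = ".json")
  write_contours_json(s1$contours, p1)
  write_contours_json(s2$contours, p2)
  expect_identical(readLines(p1), readLines(p2))

  empty <- generate_slice(slice_config(osteon_count = 0, seed = 1))
  expect_equal(nrow(empty$ground_truth), 0)
  expect_length(empty$contours$osteons, 0)
  expect_true(all(abs(empty$image - 0.5) < 0.2)) # blank matrix + noise

  expect_error(slice_config(image_size = 100, osteon_count = 50,
                            target_onar = 18000),
               "packing")

  tf <- tempfile(fileext = ".tiff")
  write_slice_tiff(s1, tf)
  expect_true(file.exists(tf) && file.size(tf) > 0)
})

test_that("null-group generator supports type-I and power sanity checks", {
  expect_error(generate_null_groups(1, 0, 1, 10), "k must be")
  expect_error(generate_null_groups(2, 0, 1, 1), "n must be")

  g <- generate_null_groups(2, 50, 5, 30, seed = 77)
  expect_length(g, 2)
  expect_s3_class(g[[1]], "group_summary")

  # two groups 10 SD apart: essentially always rejected
  set.seed(99)
  rejections <- vapply(1:100, function(i) {
    gs <- generate_null_groups(2, 0, 1, 30)
    gs[[2]]$mean <- gs[[2]]$mean + 10
    games_howell_pair(gs[[1]], gs[[2]], k_groups = 2)$significant
  }, logical(1))
  expect_equal(mean(rejections), 1)
})

test_that("synthetic slice feeds the full pipeline end to end", {
  # slice with FK-B-003-like osteon scale -> measure -> summarize ->
  # shrinkage bounds -> classifier: medium artiodactyls must be a candidate
  cfg <- slice_config(image_size = 500, pixel_pitch = 2.74, osteon_count = 8,
                      target_onar = 18174.1, target_har = 478.7, seed = 21)
  sl <- generate_slice(cfg)
  meas <- measure_contours(sl$contours)
  summ <- summarize_specimen(meas)
  # circles all equal size: SD ~ 0, give it the empirical fragment SDs so
  # the statistical stage stays well-posed
  summ <- specimen_summary(summ$specimen_id, summ$n_on,
                           summ$mean_onar, 5226.5, summ$mean_har, 186.2)
  iv <- apply_shrinkage_bounds(summ)
  ref <- load_reference()
  rects <- build_group_rectangles(ref, "group")
  refs_stat <- filter_statistical_set(ref)
  tables <- list(
    no_shrinkage = build_comparison_table(list(iv), refs_stat, "no_shrinkage"),
    shrinkage_700 = build_comparison_table(list(iv), refs_stat, "shrinkage_700"))
  rep <- classify_fragment(fragment_rectangle(iv), rects, tables)
  expect_true("medium_artiodactyls" %in% rep$candidates)
  expect_true("proboscideans" %in% names(rep$excluded))
})
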