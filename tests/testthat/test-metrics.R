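# Measurement scheme: five-point placement, index extraction, section
# classification, exclusion rules.

test_that("five points sit at the defined positions", {
  prof <- synthetic_profile()
  # symmetric lesion: midpoints at quarter positions
  pts <- locate_five_points(prof, c(0.010, 0.020, 0.030))
  expect_equal(unclass(pts),
               c(origin = 0.010, m_up = 0.015, apex = 0.020,
                 m_down = 0.025, terminal = 0.030))
  # asymmetric: 6 mm upstream, 4 mm downstream
  pts2 <- locate_five_points(prof, c(0.010, 0.016, 0.020))
  expect_equal(pts2[["m_up"]], 0.013)
  expect_equal(pts2[["m_down"]], 0.018)
  # degenerate extents are refused
  expect_error(locate_five_points(prof, c(0.02, 0.02, 0.03)),
               class = "icasflow_invalid_lesion_error")
  expect_error(locate_five_points(prof, c(0.03, 0.02, 0.01)),
               class = "icasflow_invalid_lesion_error")
  expect_error(locate_five_points(prof, c(0.01, 0.02, 0.05)),
               class = "icasflow_input_error")
})

test_that("index extraction matches a brute-force scan of the profile", {
  prof <- synthetic_profile()
  pts <- locate_five_points(prof, c(0.010, 0.020, 0.030))
  ind <- extract_indices(prof, pts)

  # independent brute-force scan over the discretised window
  win <- prof$s >= 0.010 - 1e-9 & prof$s <= 0.030 + 1e-9
  expect_equal(ind$wss_max, max(prof$wss[win]))
  expect_equal(ind$wss_max_s, prof$s[win][which.max(prof$wss[win])])
  expect_equal(ind$wss_min, min(prof$wss[win]))
  expect_equal(ind$pressure_max, max(prof$pressure[win]))
  expect_equal(ind$pressure_min, min(prof$pressure[win]))

  # the synthetic construction puts WSS peak at 18 mm (upstream of apex)
  expect_equal(ind$wss_max_s, 0.018, tolerance = 1e-4)
  expect_identical(ind$wss_max_loc, "Mup-to-apex")

  # point values interpolate the profile
  expect_equal(ind$wss_at[["apex"]],
               approx(prof$s, prof$wss, 0.020)$y)
  # ratios and drops are consistent
  expect_equal(ind$pressure_ratio_terminal_over_origin,
               ind$pressure_at[["terminal"]] / ind$pressure_at[["origin"]])
  expect_equal(ind$pressure_drop_total,
               ind$pressure_at[["origin"]] - ind$pressure_at[["terminal"]])
})

test_that("segment drops sum to the total drop", {
  # property over randomised profiles
  set.seed(42)
  for (rep in 1:20) {
    s <- seq(0, 0.04, length.out = 301)
    prof <- structure(
      data.frame(s = s,
                 wss = 1 + abs(cumsum(rnorm(301, sd = 0.05))),
                 pressure = 12000 + cumsum(rnorm(301, mean = -3))),
      class = c("wall_profile", "data.frame"))
    o <- sort(runif(1, 0.002, 0.012))
    a <- runif(1, o + 0.004, 0.025)
    t <- runif(1, a + 0.004, 0.038)
    ind <- extract_indices(prof, locate_five_points(prof, c(o, a, t)))
    expect_equal(ind$pressure_drop_total, sum(ind$segment_drops),
                 tolerance = 1e-10)
    expect_gte(ind$wss_ratio_max_over_origin, 1)
  }
})

test_that("constant profiles give unit ratios and upstream-tied extrema", {
  s <- seq(0, 0.04, length.out = 201)
  prof <- structure(data.frame(s = s, wss = rep(2, 201),
                               pressure = rep(1e4, 201)),
                    class = c("wall_profile", "data.frame"))
  pts <- locate_five_points(prof, c(0.01, 0.02, 0.03))
  ind <- extract_indices(prof, pts)
  expect_equal(ind$wss_ratio_max_over_origin, 1)
  expect_equal(ind$wss_ratio_min_over_origin, 1)
  expect_equal(ind$pressure_ratio_terminal_over_origin, 1)
  expect_equal(ind$pressure_drop_total, 0)
  expect_true(all(ind$segment_drops == 0))
  # ties break to the most upstream sample, which is the origin point
  expect_equal(ind$wss_max_s, 0.01)
  expect_identical(ind$wss_max_loc, "Origin")
})

test_that("zero origin WSS flags the ratios as undefined", {
  s <- seq(0, 0.04, length.out = 201)
  wss <- pmax(0, sin(2 * pi * s / 0.04))  # zero at the window edges
  prof <- structure(data.frame(s = s, wss = wss, pressure = 1e4 - 1e4 * s),
                    class = c("wall_profile", "data.frame"))
  pts <- locate_five_points(prof, c(0.0, 0.02, 0.04))
  ind <- extract_indices(prof, pts)
  expect_false(ind$ratio_defined)
  expect_true(is.na(ind$wss_ratio_max_over_origin))
  expect_false(is.na(ind$wss_max))     # absolute indices still returned
  expect_false(is.na(ind$pressure_drop_total))
})

test_that("section classification is total and snaps to named points", {
  prof <- synthetic_profile()
  pts <- locate_five_points(prof, c(0.010, 0.020, 0.030))
  expect_identical(classify_extremum_location(0.020, pts), "Apex")
  expect_identical(classify_extremum_location(0.010, pts), "Origin")
  expect_identical(classify_extremum_location(0.030, pts), "Terminal")
  expect_identical(classify_extremum_location(0.0175, pts), "Mup-to-apex")
  expect_identical(classify_extremum_location(0.0125, pts), "Origin-to-Mup")
  expect_identical(classify_extremum_location(0.0225, pts), "Apex-to-Mdown")
  expect_identical(classify_extremum_location(0.0285, pts),
                   "Mdown-to-terminal")
  # snap tolerance: 2% of 20 mm lesion = 0.4 mm
  expect_identical(classify_extremum_location(0.0203, pts), "Apex")
  expect_identical(classify_extremum_location(0.0206, pts), "Apex-to-Mdown")
  expect_error(classify_extremum_location(0.05, pts),
               class = "icasflow_out_of_range_error")
  # every sampled point in the window gets a label
  ss <- seq(0.010, 0.030, length.out = 101)
  labs <- vapply(ss, classify_extremum_location, character(1), points = pts)
  expect_true(all(labs %in% c("Origin", "Origin-to-Mup", "Mup", "Mup-to-apex",
                              "Apex", "Apex-to-Mdown", "Mdown",
                              "Mdown-to-terminal", "Terminal")))
})

test_that("coarse aliases partition the fine labels", {
  expect_identical(coarse_location(c("Origin", "Mup-to-apex")),
                   c("Upstream", "Upstream"))
  expect_identical(coarse_location("Apex"), "Apex")
  expect_identical(coarse_location(c("Mdown", "Terminal")),
                   c("Downstream", "Downstream"))
})

test_that("exclusion rules follow the tandem and bifurcation criteria", {
  cases <- sample_cohort(6, seed = 11)
  cases$distance_to_nearest_lesion_m <- c(0.019, 0.025, NA, 0.05, 0.010, 0.02)
  cases$at_bifurcation <- c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE)
  res <- exclusion_filter(cases)
  expect_setequal(res$excluded$case_id,
                  cases$case_id[c(1, 3, 5)])
  expect_identical(
    res$excluded$exclusion_reason[match(cases$case_id[c(1, 3, 5)],
                                        res$excluded$case_id)],
    c("tandem", "bifurcation", "tandem+bifurcation"))
  # 2.0 cm is not "< 2 cm": retained
  expect_true(cases$case_id[6] %in% res$retained$case_id)
  # missing distance means no neighbour: retained
  expect_true(cases$case_id[4] %in% res$retained$case_id)
  expect_equal(nrow(res$retained) + nrow(res$excluded), 6)
})

test_that("solver output for a 50% lesion yields the expected index signs", {
  f <- fixture_field_50()
  ind <- measure_lesion(f)
  expect_lt(ind$pressure_ratio_terminal_over_origin, 1)
  expect_gt(ind$wss_ratio_max_over_origin, 1)
  # WSS peaks in the throat neighbourhood, pressure peaks upstream
  expect_true(ind$wss_max_loc %in% c("Mup", "Mup-to-apex", "Apex",
                                     "Apex-to-Mdown", "Mdown"))
  expect_true(ind$pressure_max_loc %in% c("Origin", "Origin-to-Mup", "Mup"))
  expect_true(coarse_location(ind$pressure_min_loc) %in%
                c("Apex", "Downstream"))
})
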