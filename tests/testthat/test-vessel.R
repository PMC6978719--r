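# Parametric vessel synthesis: WASID arithmetic, cosine lesion profiles,
# lesion-extent detection, cohort sampling.

test_that("WASID percent stenosis follows the diameter formula", {
  expect_equal(percent_stenosis_wasid(1.5e-3, 3.0e-3), 50)
  expect_equal(percent_stenosis_wasid(3.0e-3, 3.0e-3), 0)
  expect_equal(percent_stenosis_wasid(1.971e-3, 3.0e-3), 34.3)
  expect_equal(percent_stenosis_wasid(c(1, 2), c(4, 4)), c(75, 50))
})

test_that("WASID rejects invalid diameters", {
  expect_error(percent_stenosis_wasid(3.1e-3, 3.0e-3),
               class = "icasflow_geometry_error")
  expect_error(percent_stenosis_wasid(0, 3e-3),
               class = "icasflow_geometry_error")
  expect_error(percent_stenosis_wasid(-1e-3, 3e-3),
               class = "icasflow_geometry_error")
})

test_that("stenosis_spec validates its invariants", {
  expect_s3_class(stenosis_spec(1.5e-3, 43, 8e-3, 19e-3), "stenosis_spec")
  expect_error(stenosis_spec(1.5e-3, 100, 8e-3, 19e-3),
               class = "icasflow_geometry_error")
  expect_error(stenosis_spec(1.5e-3, -1, 8e-3, 19e-3),
               class = "icasflow_geometry_error")
  expect_error(stenosis_spec(-1, 50, 8e-3, 19e-3),
               class = "icasflow_geometry_error")
  expect_error(stenosis_spec(1.5e-3, 50, 8e-3, 19e-3, shape = "gauss"),
               class = "icasflow_geometry_error")
})

test_that("cosine profile hits the prescribed narrowing exactly", {
  # identity case: no lesion leaves the wall at the reference radius
  g0 <- make_stenosis_profile(stenosis_spec(1.5e-3, 0, 8e-3, 19e-3), 38e-3)
  expect_true(all(g0$wall == 1.5e-3))

  # minimum radius at the centre equals R0 * (1 - s), WASID round-trip
  for (s in c(10, 25, 43.2, 50, 72, 85)) {
    g <- make_stenosis_profile(stenosis_spec(1.5e-3, s, 8e-3, 19e-3), 38e-3,
                               axial_resolution = 512L)
    expect_equal(min(g$wall), 1.5e-3 * (1 - s / 100), tolerance = 1e-10)
    round_trip <- percent_stenosis_wasid(2 * min(g$wall),
                                         2 * g$reference_radius)
    expect_lt(abs(round_trip - s), 0.1)
  }
})

test_that("cosine lesion is symmetric about its centre", {
  spec <- stenosis_spec(1.5e-3, 50, 8e-3, 19e-3)
  g <- make_stenosis_profile(spec, 38e-3, axial_resolution = 380L)
  i0 <- which.min(abs(g$z - 19e-3))
  for (k in 1:30) {
    expect_equal(g$wall[i0 + k], g$wall[i0 - k], tolerance = 1e-12)
  }
  # and unstenosed outside the lesion
  outside <- abs(g$z - 19e-3) > 4e-3 + 1e-9
  expect_true(all(g$wall[outside] == 1.5e-3))
})

test_that("geometry validation refuses lesions that do not fit", {
  spec <- stenosis_spec(1.5e-3, 50, 8e-3, 5e-3)  # lesion too close to inlet
  expect_error(make_stenosis_profile(spec, 38e-3),
               class = "icasflow_geometry_error")
  expect_error(
    make_stenosis_profile(stenosis_spec(1.5e-3, 50, 8e-3, 10e-3), 20e-3),
    class = "icasflow_geometry_error")
})

test_that("planar eccentric mode carves the deficit from one wall", {
  spec <- stenosis_spec(1.5e-3, 40, 8e-3, 19e-3, side = "upper")
  g <- make_stenosis_profile(spec, 38e-3)
  expect_identical(g$mode, "planar")
  expect_true(all(g$wall_lower == 1.5e-3))
  # the total gap reproduces the WASID narrowing
  gap_min <- min(g$wall_upper + g$wall_lower)
  expect_equal(gap_min, 2 * 1.5e-3 * 0.6, tolerance = 1e-10)
  # single-sided plaques cannot cross the centreline
  expect_error(
    make_stenosis_profile(stenosis_spec(1.5e-3, 60, 8e-3, 19e-3,
                                        side = "lower"), 38e-3),
    class = "icasflow_geometry_error")
})

test_that("lesion extent detection recovers the cosine bump", {
  spec <- stenosis_spec(1.5e-3, 50, 8e-3, 19e-3)
  g <- make_stenosis_profile(spec, 38e-3, axial_resolution = 512L)
  dz <- g$z[2] - g$z[1]

  # near-zero threshold recovers the full analytic support
  ext0 <- detect_lesion_extent(g, deficit_threshold = 1e-6)
  expect_lt(abs(ext0[["z_origin"]] - 15e-3), 2 * dz)
  expect_lt(abs(ext0[["z_apex"]] - 19e-3), dz + 1e-12)
  expect_lt(abs(ext0[["z_terminal"]] - 23e-3), 2 * dz)

  # default threshold: apex equals the brute-force profile minimum
  ext <- detect_lesion_extent(g)
  expect_identical(ext[["z_apex"]], g$z[which.min(g$wall)])
  expect_true(ext[["z_origin"]] < ext[["z_apex"]])
  expect_true(ext[["z_apex"]] < ext[["z_terminal"]])

  # resolution refinement moves the bounds by at most one coarse cell
  g2 <- make_stenosis_profile(spec, 38e-3, axial_resolution = 1024L)
  ext2 <- detect_lesion_extent(g2)
  expect_lt(max(abs(ext2 - ext)), dz + 1e-12)
})

test_that("extent detection refuses degenerate inputs", {
  straight <- make_stenosis_profile(stenosis_spec(1.5e-3, 0, 8e-3, 19e-3),
                                    38e-3)
  expect_error(detect_lesion_extent(straight),
               class = "icasflow_nolesion_error")
  # two disjoint lesions: stitch two bumps into one wall manually
  g <- make_stenosis_profile(stenosis_spec(1.5e-3, 50, 6e-3, 20e-3), 60e-3)
  g2 <- make_stenosis_profile(stenosis_spec(1.5e-3, 50, 6e-3, 40e-3), 60e-3)
  g$wall <- pmin(g$wall, g2$wall)
  expect_error(detect_lesion_extent(g), class = "icasflow_ambiguity_error")
  expect_error(detect_lesion_extent(g, deficit_threshold = 0.7),
               class = "icasflow_input_error")
})

test_that("cohort sampling is reproducible and hits the population targets", {
  a <- sample_cohort(55, seed = 1)
  b <- sample_cohort(55, seed = 1)
  expect_identical(a, b)
  expect_equal(nrow(a), 55)
  expect_false(identical(a, sample_cohort(55, seed = 2)))

  # distributional target: mean stenosis within 3 SE of 43.2
  expect_lt(abs(mean(a$percent_stenosis) - 43.2), 3 * 17.3 / sqrt(55))
  expect_true(all(a$percent_stenosis >= 10 & a$percent_stenosis <= 85))
  expect_true(all(a$psv_m_s >= a$edv_m_s))
  expect_true(all(a$edv_m_s > 0))
  expect_true(all(a$systolic_bp_mmhg > a$diastolic_bp_mmhg))
  expect_true(all(a$sex %in% c("M", "F")))

  single <- sample_cohort(1, seed = 7)
  expect_equal(nrow(single), 1)
  expect_true(single$percent_stenosis >= 10 && single$percent_stenosis <= 85)
})

test_that("invalid population parameters are refused", {
  expect_error(cohort_population(stenosis_sd = -1),
               class = "icasflow_config_error")
  expect_error(cohort_population(stenosis_range = c(50, 10)),
               class = "icasflow_config_error")
  expect_error(cohort_population(nonsense = 1),
               class = "icasflow_config_error")
  expect_error(sample_cohort(0, seed = 1), class = "icasflow_config_error")
})

test_that("cohort CSV round-trips", {
  a <- sample_cohort(12, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(a, path)
  b <- read_cohort_csv(path)
  expect_equal(as.data.frame(b), as.data.frame(a), tolerance = 1e-12)
})

test_that("case_geometry honours the geometry mode", {
  case <- sample_cohort(5, seed = 3)[3, ]
  g_ax <- case_geometry(case, 128L, "axisymmetric")
  expect_identical(g_ax$mode, "axisymmetric")
  expect_equal(percent_stenosis_wasid(2 * min(g_ax$wall),
                                      2 * g_ax$reference_radius),
               case$percent_stenosis, tolerance = 1e-3)
})
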