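test_that("phantom organ volumes match their closed forms after rasterisation", {
  ph <- make_phantom()
  vb <- mask_volume(rasterize(ph$structures$structures$Bladder, ph$geometry))
  expect_lt(abs(vb - ph$analytic_volumes_cm3[["Bladder"]]) /
              ph$analytic_volumes_cm3[["Bladder"]], 0.01)
  vt <- mask_volume(rasterize(ph$structures$structures$Target, ph$geometry))
  expect_lt(abs(vt - ph$analytic_volumes_cm3[["Target"]]) /
              ph$analytic_volumes_cm3[["Target"]], 0.01)
  # narrow tube: lattice fluctuation dominates, but stays within a few percent
  vr <- mask_volume(rasterize(ph$structures$structures$Rectum, ph$geometry))
  expect_lt(abs(vr - ph$analytic_volumes_cm3[["Rectum"]]) /
              ph$analytic_volumes_cm3[["Rectum"]], 0.05)
})

test_that("generation is deterministic for identical specs", {
  p1 <- make_phantom()
  p2 <- make_phantom()
  v1 <- do.call(rbind, lapply(p1$structures$structures$Bladder$contours,
                              `[[`, "points"))
  v2 <- do.call(rbind, lapply(p2$structures$structures$Bladder$contours,
                              `[[`, "points"))
  expect_identical(v1, v2)
})

test_that("the analytic dose field has the stated shape", {
  spec <- dose_field_spec(prescription_gy = 40, plateau_radius_mm = 15,
                          falloff_width_mm = 3)
  # half-maximum exactly at the plateau edge, by construction
  expect_equal(dose_field_at(spec, matrix(c(15, 0, 0), ncol = 3)), 20)
  # centre dose equals the prescription to within the logistic tail
  expect_equal(dose_field_at(spec, matrix(0, 1, 3)), 40, tolerance = 1e-2)
  # monotone non-increasing with radius, tending to zero
  r <- seq(0, 120, by = 0.5)
  d <- dose_field_at(spec, cbind(r, 0, 0))
  expect_true(all(diff(d) <= 0))
  expect_lt(d[length(d)], 1e-10)
})

test_that("bladder volume scaling hits the requested ratio within 2%", {
  ph <- make_phantom()
  base <- mask_volume(rasterize(ph$structures$structures$Bladder, ph$geometry))
  for (s in c(0.5, 0.401, 1.857)) {
    d <- perturb_structures(ph$structures, perturbation_spec(bladder_scale = s))
    v <- mask_volume(rasterize(d$structures$Bladder, ph$geometry))
    expect_lt(abs(v / base - s) / s, 0.02)
  }
})

test_that("the identity perturbation leaves every vertex untouched", {
  ph <- make_phantom()
  d <- perturb_structures(ph$structures, perturbation_spec())
  for (nm in names(ph$structures$structures)) {
    v1 <- do.call(rbind, lapply(ph$structures$structures[[nm]]$contours,
                                `[[`, "points"))
    v2 <- do.call(rbind, lapply(d$structures[[nm]]$contours, `[[`, "points"))
    expect_lt(max(abs(v1 - v2)), 1e-9)
  }
})

test_that("a 6 mm bump over 5 slices distends exactly 5 slices past a 5 mm margin", {
  ph <- make_phantom()
  d <- perturb_structures(ph$structures, perturbation_spec(
    distension_amplitude_mm = 6, distension_slices = 5L))
  pct <- rasterize(ph$structures$structures$Rectum, ph$geometry)
  daily <- rasterize(d$structures$Rectum, ph$geometry)
  expect_equal(anterior_distension_slices(daily, expand_mask(pct, 5)), 5L)
  # the unperturbed rectum never distends past its own expansion
  expect_equal(anterior_distension_slices(pct, expand_mask(pct, 5)), 0L)
})

test_that("shift scenarios encode the couch-shift sign convention", {
  sc <- make_shift_scenarios()
  expect_equal(nrow(sc), 5L)
  expect_equal(shift_for_scenario("A")$translation, c(0, -4, 0))
  expect_equal(shift_for_scenario("P")$translation, c(0, 4, 0))
  for (case in c("RA", "RA-A", "RA-P"))
    expect_error(shift_for_scenario(case), "requires dose recalculation")
  expect_error(shift_for_scenario("Q"), "unknown")
})

test_that("shifted superimposition is exact on an analytic field (Case A)", {
  # reference: field recentred 4 mm anteriorly; evaluated: original field
  # sampled through the Case A shift — identical in the interior
  g <- grid_geometry(c(-30, -30, -30), c(2, 2, 2), c(31, 31, 31))
  spec0 <- dose_field_spec(plateau_radius_mm = 18, falloff_width_mm = 3)
  shift <- shift_for_scenario("A")
  t <- shift$translation
  recentred <- dose_field_spec(plateau_radius_mm = 18, falloff_width_mm = 3,
                               center = -t)
  ref <- make_dose(recentred, g)             # dose recomputed about -t
  planned <- make_dose(spec0, g)
  # "shift dose 4 mm anteriorly": grid holding the planned values, its
  # origin moved so that shifted(p) = planned(p + t)
  shifted <- dose_grid(planned$values,
                       grid_geometry(g$origin - t, g$spacing, g$dims))
  pts <- as.matrix(expand.grid(x = seq(-16, 16, 4), y = seq(-16, 16, 4),
                               z = seq(-16, 16, 4)))
  a <- sample_dose(planned, transform_points(pts, shift))$dose
  b <- sample_dose(ref, pts)$dose
  expect_equal(a, b, tolerance = 1e-9)

  # the superimposed (shifted) and recomputed distributions agree, so the
  # interior gamma passes everywhere
  r <- gamma_map(ref, shifted, gamma_params(low_dose_threshold_pct = 50,
                                            max_search_radius_mm = 6))
  expect_equal(r$passing_rate_pct, 100)
})

test_that("cohort sampling respects its ranges and reproduces under a seed", {
  m1 <- sample_cohort(seed = 7)
  m2 <- sample_cohort(seed = 7)
  expect_identical(m1, m2)
  expect_equal(nrow(m1), 200L)
  expect_true(all(m1$bladder_scale >= 0.401 & m1$bladder_scale <= 1.857))
  expect_true(all(m1$rectum_scale >= 0.570 & m1$rectum_scale <= 2.308))
  expect_true(all(abs(c(m1$tx, m1$ty, m1$tz)) <= 8))
  expect_true(all(m1$distension_slices[m1$distension_amplitude_mm > 0] >= 2))
  m3 <- sample_cohort(seed = 8)
  expect_false(identical(m1$bladder_scale, m3$bladder_scale))
})

test_that("fixtures round-trip through the DICOM writers", {
  ph <- make_phantom(phantom_spec(spacing_mm = 2.5))
  ds <- make_dose(dose_field_spec(), ph$geometry)
  out <- withr::local_tempdir()
  paths <- write_fixtures(ph, ds, out, shift = rigid_shift(c(0, -4, 0)))
  expect_true(all(file.exists(paths)))
  d2 <- read_rtdose(paths[["rtdose"]])
  expect_lte(max(abs(d2$values - ds$values)), 0.001 / 2 + 1e-12)
  s2 <- read_rtstruct(paths[["rtstruct"]])
  expect_setequal(names(s2$structures), names(ph$structures$structures))
  expect_equal(read_shift(paths[["reg"]])$translation, c(0, -4, 0))
})
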