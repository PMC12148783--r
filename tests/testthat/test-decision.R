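obs_with <- function(ratio_pct, bowel = FALSE, slices = NA_integer_) {
  setup_observation(
    bladder_comparison = compare_volumes(300, 300 * ratio_pct / 100),
    small_bowel_in_80pct_isodose_increased = bowel,
    distension_slices = slices)
}

test_that("bladder rule: 2/3 volume threshold and small-bowel branch", {
  expect_equal(bladder_rule(obs_with(80))$category, "B2")
  expect_equal(bladder_rule(obs_with(50, bowel = FALSE))$category, "B1N")
  expect_equal(bladder_rule(obs_with(66.0, bowel = TRUE))$category, "B1Y")
  expect_equal(bladder_rule(obs_with(66.0, bowel = FALSE))$category, "B1N")
  # boundary: exactly 2/3 (200 of 300 cm^3) proceeds as B2
  boundary <- setup_observation(bladder_comparison = compare_volumes(300, 200))
  expect_equal(bladder_rule(boundary)$category, "B2")
  # each observation lands in exactly one category
  set.seed(31)
  for (i in 1:30) {
    o <- obs_with(runif(1, 10, 200), bowel = runif(1) < 0.5)
    expect_length(bladder_rule(o)$category, 1L)
  }
})

test_that("rectum rule: at-least-three-slices trigger", {
  expect_false(rectum_rule(obs_with(100, slices = 0L))$flagged)
  expect_false(rectum_rule(obs_with(100, slices = 2L))$flagged)
  expect_true(rectum_rule(obs_with(100, slices = 3L))$flagged)
  expect_true(rectum_rule(obs_with(100, slices = 5L))$flagged)
})

test_that("decision outcomes carry a non-empty rule trace", {
  d <- evaluate_decision(obs_with(50, slices = 4L))
  expect_equal(d$bladder_category, "B1N")
  expect_true(d$rectum_flagged)
  expect_gte(length(d$trace), 2L)
})

test_that("the A/P shift cap is enforced on observations", {
  expect_error(setup_observation(applied_ap_shift_mm = 5,
                                 distension_slices = 0L), "cap")
  expect_silent(setup_observation(applied_ap_shift_mm = 4,
                                  distension_slices = 0L))
  r <- decision_rules(ap_shift_cap_mm = 6)
  expect_silent(setup_observation(applied_ap_shift_mm = 5,
                                  distension_slices = 0L, rules = r))
})

test_that("concordance audit on constructed cohorts", {
  mk_assessment <- function(bladder_v18_class) {
    structure(list(
      metrics = data.frame(structure = "Bladder", metric = "V18Gy",
                           value = 1, units = "pct", primary = 30,
                           secondary = 45, class = bladder_v18_class,
                           stringsAsFactors = FALSE),
      structure_worst = c(Bladder = bladder_v18_class),
      fraction_class = bladder_v18_class,
      volume_comparisons = list(), decision = NULL,
      out_of_grid = numeric(0), config_hash = "x"),
      class = "fraction_assessment")
  }
  mk_decision <- function(cat) {
    structure(list(bladder_category = cat, rectum_flagged = FALSE,
                   trace = "t"), class = "decision_outcome")
  }

  # all optimal, nothing flagged: full concordance, sensitivity undefined
  a <- replicate(5, mk_assessment("optimal"), simplify = FALSE)
  d <- replicate(5, mk_decision("B2"), simplify = FALSE)
  res <- audit_concordance(d, a)
  expect_equal(res$overall_concordance, 1)
  expect_true(is.nan(res$bladder$sensitivity_major))

  # every under-filled-bladder fraction has a V18 major: rule catches all
  a2 <- c(replicate(3, mk_assessment("major"), simplify = FALSE),
          replicate(4, mk_assessment("optimal"), simplify = FALSE))
  d2 <- c(replicate(3, mk_decision("B1N"), simplify = FALSE),
          replicate(4, mk_decision("B2"), simplify = FALSE))
  res2 <- audit_concordance(d2, a2)
  expect_equal(res2$bladder$sensitivity_major, 1)
  expect_equal(res2$bladder$n_major, 3L)

  # violations driven by the rectum only: bladder rules fire on none
  a3 <- replicate(3, mk_assessment("major"), simplify = FALSE)
  for (i in seq_along(a3)) a3[[i]]$metrics$structure <- "Rectum"
  d3 <- replicate(3, mk_decision("B2"), simplify = FALSE)
  res3 <- audit_concordance(d3, a3)
  expect_equal(res3$rectum$n_major_flagged, 0L)
  expect_error(audit_concordance(d3, a2), "aligned")
})

test_that("relative-metric majors only occur in under-filled bladders", {
  # bladder anchored at its target-side wall: the irradiated sub-volume is
  # held fixed while total volume changes, so percent metrics scale as the
  # inverse volume ratio and majors concentrate below the 2/3 threshold
  ph <- make_phantom(filling_study_spec(spacing_mm = 1.25, padding_mm = 8))
  ds <- make_dose(dose_field_spec(), resample_geometry(ph$geometry))
  scales <- c(0.42, 0.5, 0.6, 2 / 3, 0.75, 0.9, 1, 1.2, 1.5, 1.857)
  for (s in scales) {
    daily <- perturb_structures(ph$structures, perturbation_spec(
      bladder_scale = s, bladder_anchor = "target_side"))
    a <- suppressWarnings(assess_setup(ds, ph$structures, daily,
                                       mask_spacing_mm = 1.25))
    m <- a$metrics[a$metrics$structure == "Bladder" &
                     a$metrics$metric %in% c("V18Gy", "V33Gy", "V36Gy"), ]
    under <- a$volume_comparisons$Bladder$under_filled
    if (any(m$class == "major")) expect_true(under)
    if (!under) expect_true(all(m$class != "major"))
    # absolute V37 stays in its class as volume changes
    v37 <- a$metrics[a$metrics$metric == "V37Gy", ]
    expect_equal(v37$class, "optimal")
  }
})
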