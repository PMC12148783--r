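test_that("RTDOSE round trip preserves a uniform dose field", {
  d <- uniform_dose(40, dims = c(6, 5, 4))
  path <- withr::local_tempfile(fileext = ".dcm")
  write_rtdose(d, path)
  d2 <- read_rtdose(path)
  expect_equal(max(d2$values), 40, tolerance = 1e-9)
  expect_equal(min(d2$values), 40, tolerance = 1e-9)
  expect_equal(d2$geometry$origin, d$geometry$origin)
  expect_equal(d2$geometry$spacing, d$geometry$spacing)
  expect_equal(d2$geometry$dims, d$geometry$dims)
})

test_that("dose scaling arithmetic: stored integer x scaling = Gy", {
  d <- uniform_dose(40, dims = c(4, 4, 4))
  path <- withr::local_tempfile(fileext = ".dcm")
  write_rtdose(d, path, scaling = 0.01)
  d2 <- read_rtdose(path)
  # stored value must be 4000 exactly at this scaling
  expect_equal(d2$values[1, 1, 1], 4000 * 0.01)

  # independent cross-check: pydicom reads the same stored integers
  py <- Sys.which("python")
  expect_true(nzchar(py))
  out <- system2(py, c("-c", shQuote(paste0(
    "import pydicom; d = pydicom.dcmread('", path, "'); ",
    "print(int(d.pixel_array.flat[0]), float(d.DoseGridScaling))"))),
    stdout = TRUE)
  expect_equal(out, "4000 0.01")
})

test_that("round trip quantisation error is bounded by scaling/2", {
  g <- tiny_geometry(c(8, 8, 8))
  set.seed(5)
  d <- dose_grid(array(runif(512, 0, 42), dim = c(8, 8, 8)), g)
  path <- withr::local_tempfile(fileext = ".dcm")
  write_rtdose(d, path, scaling = 0.001)
  d2 <- read_rtdose(path)
  expect_lte(max(abs(d2$values - d$values)), 0.001 / 2 + 1e-12)
})

test_that("irregular frame offsets are rejected", {
  # hand-build an RTDOSE with offsets {0, 1, 2.5}
  el <- sabrcheck:::el
  pix <- writeBin(rep(100L, 2 * 2 * 3), raw(), size = 4L, endian = "little")
  elems <- list(
    el(0x0008, 0x0060, "CS", "RTDOSE"),
    el(0x0020, 0x0032, "DS", c(0, 0, 0)),
    el(0x0020, 0x0037, "DS", c(1, 0, 0, 0, 1, 0)),
    el(0x0028, 0x0008, "IS", 3L),
    el(0x0028, 0x0010, "US", 2L), el(0x0028, 0x0011, "US", 2L),
    el(0x0028, 0x0030, "DS", c(1, 1)),
    el(0x0028, 0x0100, "US", 32L),
    el(0x3004, 0x000C, "DS", c(0, 1, 2.5)),
    el(0x3004, 0x000E, "DS", 0.01),
    el(0x7FE0, 0x0010, "OW", pix))
  path <- withr::local_tempfile(fileext = ".dcm")
  sabrcheck:::.dcm_write_file(path, sabrcheck:::.SOP_RTDOSE, "2.25.1", elems)
  expect_error(read_rtdose(path), "non-uniform frame offsets")
})

test_that("missing dose scaling is a hard error", {
  el <- sabrcheck:::el
  pix <- writeBin(rep(1L, 8), raw(), size = 4L, endian = "little")
  elems <- list(
    el(0x0008, 0x0060, "CS", "RTDOSE"),
    el(0x0020, 0x0032, "DS", c(0, 0, 0)),
    el(0x0020, 0x0037, "DS", c(1, 0, 0, 0, 1, 0)),
    el(0x0028, 0x0008, "IS", 2L),
    el(0x0028, 0x0010, "US", 2L), el(0x0028, 0x0011, "US", 2L),
    el(0x0028, 0x0030, "DS", c(1, 1)),
    el(0x0028, 0x0100, "US", 32L),
    el(0x3004, 0x000C, "DS", c(0, 1)),
    el(0x7FE0, 0x0010, "OW", pix))
  path <- withr::local_tempfile(fileext = ".dcm")
  sabrcheck:::.dcm_write_file(path, sabrcheck:::.SOP_RTDOSE, "2.25.1", elems)
  expect_error(read_rtdose(path), "DoseGridScaling")
})

test_that("non-axial orientation is rejected rather than resampled", {
  el <- sabrcheck:::el
  pix <- writeBin(rep(1L, 8), raw(), size = 4L, endian = "little")
  elems <- list(
    el(0x0008, 0x0060, "CS", "RTDOSE"),
    el(0x0020, 0x0032, "DS", c(0, 0, 0)),
    el(0x0020, 0x0037, "DS", c(0, 1, 0, 1, 0, 0)),
    el(0x0028, 0x0008, "IS", 2L),
    el(0x0028, 0x0010, "US", 2L), el(0x0028, 0x0011, "US", 2L),
    el(0x0028, 0x0030, "DS", c(1, 1)),
    el(0x0028, 0x0100, "US", 32L),
    el(0x3004, 0x000C, "DS", c(0, 1)),
    el(0x3004, 0x000E, "DS", 0.01),
    el(0x7FE0, 0x0010, "OW", pix))
  path <- withr::local_tempfile(fileext = ".dcm")
  sabrcheck:::.dcm_write_file(path, sabrcheck:::.SOP_RTDOSE, "2.25.1", elems)
  expect_error(read_rtdose(path), "unsupported orientation")
})

test_that("descending frame offsets load with strictly increasing z", {
  el <- sabrcheck:::el
  vals <- 1:12  # distinguishable per-frame values
  pix <- writeBin(as.integer(vals), raw(), size = 4L, endian = "little")
  elems <- list(
    el(0x0008, 0x0060, "CS", "RTDOSE"),
    el(0x0020, 0x0032, "DS", c(0, 0, 10)),
    el(0x0020, 0x0037, "DS", c(1, 0, 0, 0, 1, 0)),
    el(0x0028, 0x0008, "IS", 3L),
    el(0x0028, 0x0010, "US", 2L), el(0x0028, 0x0011, "US", 2L),
    el(0x0028, 0x0030, "DS", c(1, 1)),
    el(0x0028, 0x0100, "US", 32L),
    el(0x3004, 0x000C, "DS", c(0, -2, -4)),
    el(0x3004, 0x000E, "DS", 1),
    el(0x7FE0, 0x0010, "OW", pix))
  path <- withr::local_tempfile(fileext = ".dcm")
  sabrcheck:::.dcm_write_file(path, sabrcheck:::.SOP_RTDOSE, "2.25.1", elems)
  d <- read_rtdose(path)
  expect_true(all(diff(grid_axis(d$geometry, 3)) > 0))
  expect_equal(d$geometry$origin[3], 6)      # lowest slice centre
  expect_equal(d$values[1, 1, ], c(9, 5, 1)) # frames reversed to ascending z
})

test_that("RTSTRUCT round trip preserves names and vertices", {
  ph <- make_phantom(phantom_spec(spacing_mm = 2))
  path <- withr::local_tempfile(fileext = ".dcm")
  write_rtstruct(ph$structures, path)
  s2 <- read_rtstruct(path)
  expect_setequal(names(s2$structures), c("Bladder", "Rectum", "Target"))
  expect_length(s2$structures$Bladder$contours,
                length(ph$structures$structures$Bladder$contours))
  v1 <- do.call(rbind, lapply(ph$structures$structures$Bladder$contours,
                              `[[`, "points"))
  v2 <- do.call(rbind, lapply(s2$structures$Bladder$contours, `[[`, "points"))
  expect_lt(max(abs(v1 - v2)), 1e-3)
})

test_that("degenerate and non-planar contours are skipped with a warning", {
  el <- sabrcheck:::el
  roi_items <- list(list(el(0x3006, 0x0022, "IS", 1L),
                         el(0x3006, 0x0026, "LO", "Rectum")))
  cseq <- list(
    list(el(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
         el(0x3006, 0x0046, "IS", 2L),
         el(0x3006, 0x0050, "DS", c(0, 0, 0, 1, 0, 0))),        # 2 points
    list(el(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
         el(0x3006, 0x0046, "IS", 3L),
         el(0x3006, 0x0050, "DS", c(0, 0, 0, 1, 0, 0, 0, 1, 5))), # non-planar
    list(el(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
         el(0x3006, 0x0046, "IS", 3L),
         el(0x3006, 0x0050, "DS", c(0, 0, 0, 10, 0, 0, 0, 10, 0))))
  contour_items <- list(list(el(0x3006, 0x0040, "SQ", cseq),
                             el(0x3006, 0x0084, "IS", 1L)))
  elems <- list(
    el(0x0008, 0x0060, "CS", "RTSTRUCT"),
    el(0x3006, 0x0020, "SQ", roi_items),
    el(0x3006, 0x0039, "SQ", contour_items))
  path <- withr::local_tempfile(fileext = ".dcm")
  sabrcheck:::.dcm_write_file(path, sabrcheck:::.SOP_RTSTRUCT, "2.25.2", elems)
  expect_warning(expect_warning(s <- read_rtstruct(path), "degenerate"),
                 "non-planar")
  expect_length(s$structures$Rectum$contours, 1L)
})

test_that("duplicate ROI names are rejected", {
  el <- sabrcheck:::el
  roi_items <- list(
    list(el(0x3006, 0x0022, "IS", 1L), el(0x3006, 0x0026, "LO", "Bladder")),
    list(el(0x3006, 0x0022, "IS", 2L), el(0x3006, 0x0026, "LO", "Bladder")))
  elems <- list(el(0x0008, 0x0060, "CS", "RTSTRUCT"),
                el(0x3006, 0x0020, "SQ", roi_items))
  path <- withr::local_tempfile(fileext = ".dcm")
  sabrcheck:::.dcm_write_file(path, sabrcheck:::.SOP_RTSTRUCT, "2.25.3", elems)
  expect_error(read_rtstruct(path), "duplicate structure name")
})

test_that("empty ROI loads as an empty structure, with a message", {
  el <- sabrcheck:::el
  roi_items <- list(list(el(0x3006, 0x0022, "IS", 1L),
                         el(0x3006, 0x0026, "LO", "Sigmoid")))
  elems <- list(el(0x0008, 0x0060, "CS", "RTSTRUCT"),
                el(0x3006, 0x0020, "SQ", roi_items))
  path <- withr::local_tempfile(fileext = ".dcm")
  sabrcheck:::.dcm_write_file(path, sabrcheck:::.SOP_RTSTRUCT, "2.25.4", elems)
  expect_message(s <- read_rtstruct(path), "no contours")
  expect_length(s$structures$Sigmoid$contours, 0L)
})

test_that("shift ingestion: numeric triplet, REG file, and 6-DOF rejection", {
  expect_equal(read_shift(c(0, 0, 0))$translation, c(0, 0, 0))
  # 4 mm anterior couch shift under the DICOM axis convention
  expect_equal(read_shift(c(0, -4, 0))$translation, c(0, -4, 0))

  path <- withr::local_tempfile(fileext = ".dcm")
  write_reg(rigid_shift(c(1.5, -4, 2)), path)
  expect_equal(read_shift(path)$translation, c(1.5, -4, 2))

  # REG with a 5-degree rotation about z
  el <- sabrcheck:::el
  th <- 5 * pi / 180
  m <- diag(4); m[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  matrix_item <- list(el(0x0070, 0x030C, "CS", "RIGID"),
                      el(0x3006, 0x00C6, "DS", as.vector(t(m))))
  reg_item <- list(el(0x0070, 0x0309, "SQ",
                      list(list(el(0x0070, 0x030A, "SQ", list(matrix_item))))))
  elems <- list(el(0x0008, 0x0060, "CS", "REG"),
                el(0x0070, 0x0308, "SQ", list(reg_item)))
  path2 <- withr::local_tempfile(fileext = ".dcm")
  sabrcheck:::.dcm_write_file(path2, sabrcheck:::.SOP_REG, "2.25.5", elems)
  expect_error(read_shift(path2), "6-DOF registration unsupported")
})

test_that("shift sign convention: anterior shift raises dose on a posterior gradient", {
  # dose increases toward posterior (+y); an anterior isocenter shift moves
  # the patient anterior relative to the dose cloud, i.e. daily points map
  # to p + (0,-4,0) in plan space and sample lower dose
  g <- tiny_geometry(c(5, 21, 5), origin = c(0, -10, 0))
  d <- affine_dose(10, c(0, 0.5, 0), g)
  p <- matrix(c(2, 0, 2), ncol = 3)
  d0 <- sample_dose(d, transform_points(p, rigid_shift(c(0, 0, 0))))$dose
  da <- sample_dose(d, transform_points(p, rigid_shift(c(0, -4, 0))))$dose
  expect_equal(d0 - da, 0.5 * 4)
})
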