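#' Read a DICOM RTDOSE file
#'
#' Reconstructs the dose grid in physical Gy (DoseGridScaling applied) with
#' its patient-coordinate geometry from ImagePositionPatient, PixelSpacing and
#' GridFrameOffsetVector. Only axial, identity-orientation grids with uniform
#' frame offsets are accepted; anything else is an error rather than a silent
#' resample. Descending frame offsets are flipped so that the loaded geometry
#' z is strictly increasing.
#'
#' @param path path to an RTDOSE file (Explicit VR Little Endian).
#' @return A \code{\link{dose_grid}}.
#' @export
read_rtdose <- function(path) {
  ds <- dcm_read_file(path)
  modality <- dcm_get(ds, "0008,0060")
  if (!is.null(modality) && !identical(modality, "RTDOSE"))
    stop("not an RTDOSE object (Modality = ", modality, ")")

  rows <- as.integer(dcm_get(ds, "0028,0010", TRUE, "Rows"))
  cols <- as.integer(dcm_get(ds, "0028,0011", TRUE, "Columns"))
  nframes <- as.integer(dcm_get(ds, "0028,0008", TRUE, "NumberOfFrames"))
  ipp <- dcm_get(ds, "0020,0032", TRUE, "ImagePositionPatient")
  iop <- dcm_get(ds, "0020,0037", TRUE, "ImageOrientationPatient")
  if (max(abs(iop - c(1, 0, 0, 0, 1, 0))) > 1e-6)
    stop("unsupported orientation: only axial identity-orientation dose grids are supported")
  psp <- dcm_get(ds, "0028,0030", TRUE, "PixelSpacing")  # (row = dy, col = dx)
  offsets <- dcm_get(ds, "3004,000C", TRUE, "GridFrameOffsetVector")
  scaling <- dcm_get(ds, "3004,000E", required = FALSE)
  if (is.null(scaling)) stop("missing DoseGridScaling: cannot convert stored values to Gy")

  if (length(offsets) != nframes)
    stop("GridFrameOffsetVector length does not match NumberOfFrames")
  if (nframes > 1L) {
    steps <- diff(offsets)
    if (max(abs(steps - steps[1])) > 1e-6)
      stop("non-uniform frame offsets: ", paste(offsets, collapse = ", "))
    if (abs(steps[1]) < 1e-9) stop("degenerate (zero) frame offset step")
    dz <- steps[1]
  } else {
    dz <- 1
  }

  bits <- as.integer(dcm_get(ds, "0028,0100", TRUE, "BitsAllocated"))
  pix <- dcm_get(ds, "7FE0,0010", TRUE, "PixelData")
  n <- rows * cols * nframes
  if (bits == 16L) {
    stored <- readBin(pix, "integer", n = n, size = 2L, signed = FALSE,
                      endian = "little")
  } else if (bits == 32L) {
    stored <- readBin(pix, "integer", n = n, size = 4L, endian = "little")
    stored <- as.numeric(stored)
    stored[stored < 0] <- stored[stored < 0] + 4294967296
  } else {
    stop("unsupported BitsAllocated: ", bits)
  }
  if (length(stored) < n) stop("PixelData shorter than Rows*Columns*Frames")

  # within a frame DICOM pixel order is row-major (y outer, x inner), frames
  # along z: exactly the (x, y, z) array layout with x fastest
  values <- array(as.numeric(stored[seq_len(n)]) * scaling, dim = c(cols, rows, nframes))

  origin_z <- ipp[3] + offsets[1]
  if (nframes > 1L && dz < 0) {
    values <- values[, , rev(seq_len(nframes)), drop = FALSE]
    origin_z <- ipp[3] + offsets[nframes]
    dz <- -dz
  }
  geom <- grid_geometry(origin = c(ipp[1], ipp[2], origin_z),
                        spacing = c(psp[2], psp[1], dz),
                        dims = c(cols, rows, nframes))
  uid <- dcm_get(ds, "0008,0018")
  dose_grid(values, geom, source_uid = if (is.null(uid)) "" else uid)
}

#' Read a DICOM RTSTRUCT file
#'
#' Parses every CLOSED_PLANAR contour of every ROI. Degenerate contours
#' (fewer than 3 points) and non-planar contours (z spread over 1e-3 mm) are
#' skipped with a warning. An ROI without contours is kept as an empty
#' structure. Duplicate ROI names are an error.
#'
#' @param path path to an RTSTRUCT file (Explicit VR Little Endian).
#' @return A \code{\link{structure_set}}.
#' @export
read_rtstruct <- function(path) {
  ds <- dcm_read_file(path)
  modality <- dcm_get(ds, "0008,0060")
  if (!is.null(modality) && !identical(modality, "RTSTRUCT"))
    stop("not an RTSTRUCT object (Modality = ", modality, ")")

  roi_seq <- dcm_get(ds, "3006,0020", TRUE, "StructureSetROISequence")
  roi_names <- character(0)
  roi_frames <- character(0)
  for (item in roi_seq) {
    num <- as.character(as.integer(item[["3006,0022"]]$value))
    nm <- item[["3006,0026"]]$value
    if (is.null(nm)) nm <- paste0("ROI_", num)
    if (nm %in% roi_names) stop("duplicate structure name: ", nm)
    roi_names[num] <- nm
    fr <- item[["3006,0024"]]$value
    roi_frames[num] <- if (is.null(fr)) "" else fr
  }

  contour_seq <- dcm_get(ds, "3006,0039", required = FALSE)
  contours_by_roi <- stats::setNames(vector("list", length(roi_names)),
                                     names(roi_names))
  if (!is.null(contour_seq)) {
    for (item in contour_seq) {
      num <- as.character(as.integer(item[["3006,0084"]]$value))
      cseq <- item[["3006,0040"]]$value
      if (is.null(cseq)) next
      for (cit in cseq) {
        gtype <- cit[["3006,0042"]]$value
        if (!is.null(gtype) && !identical(gtype, "CLOSED_PLANAR")) {
          warning("skipping non-CLOSED_PLANAR contour (", gtype, ") in ROI ",
                  roi_names[num])
          next
        }
        cdata <- cit[["3006,0050"]]$value
        if (is.null(cdata) || length(cdata) %% 3L != 0L) {
          warning("skipping malformed contour data in ROI ", roi_names[num])
          next
        }
        pts <- matrix(cdata, ncol = 3L, byrow = TRUE)
        if (nrow(pts) < 3L) {
          warning("skipping degenerate contour (<3 points) in ROI ",
                  roi_names[num])
          next
        }
        if (diff(range(pts[, 3])) > 1e-3) {
          warning("skipping non-planar contour (z spread > 1e-3 mm) in ROI ",
                  roi_names[num])
          next
        }
        contours_by_roi[[num]] <- c(contours_by_roi[[num]], list(rt_contour(pts)))
      }
    }
  }

  structs <- lapply(names(roi_names), function(num) {
    cl <- contours_by_roi[[num]]
    if (is.null(cl)) cl <- list()
    if (length(cl) == 0L)
      message("structure '", roi_names[num], "' has no contours")
    rt_structure(roi_names[num], cl)
  })
  frame <- unique(roi_frames[nzchar(roi_frames)])
  structure_set(structs,
                frame_of_reference = if (length(frame)) frame[1] else "")
}

#' Read the online rigid-registration couch shift
#'
#' Accepts either three numeric translation components (mm) or the path to a
#' DICOM Spatial Registration (REG) object whose transformation matrix is
#' translation-only. The returned shift maps daily-image coordinates into
#' planning coordinates (see \code{\link{rigid_shift}} for the sign
#' convention). A registration with a non-identity rotation part is rejected:
#' the clinic's treatment couches are 3-DOF (translation-only).
#'
#' @param source numeric length-3 (tx, ty, tz) mm, or path to a REG file.
#' @param rotation_tol tolerance for "identity" on the rotation block.
#' @return A \code{\link{rigid_shift}}.
#' @export
read_shift <- function(source, rotation_tol = 1e-4) {
  if (is.numeric(source)) {
    return(rigid_shift(source))
  }
  ds <- dcm_read_file(source)
  reg_seq <- dcm_get(ds, "0070,0308", TRUE, "RegistrationSequence")
  mats <- list()
  for (item in reg_seq) {
    mreg <- item[["0070,0309"]]$value
    if (is.null(mreg)) next
    for (mitem in mreg) {
      mseq <- mitem[["0070,030A"]]$value
      if (is.null(mseq)) next
      for (m in mseq) {
        v <- m[["3006,00C6"]]$value
        if (!is.null(v) && length(v) == 16L)
          mats[[length(mats) + 1L]] <- matrix(v, 4, 4, byrow = TRUE)
      }
    }
  }
  if (length(mats) == 0L) stop("no transformation matrix found in REG object")
  # ignore pure identity matrices (the fixed frame's own registration)
  nontrivial <- Filter(function(m) max(abs(m - diag(4))) > 1e-12, mats)
  if (length(nontrivial) == 0L) return(rigid_shift(c(0, 0, 0)))
  m <- nontrivial[[length(nontrivial)]]
  if (max(abs(m[1:3, 1:3] - diag(3))) > rotation_tol)
    stop("6-DOF registration unsupported: rotation part is not identity")
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-6)
    stop("malformed transformation matrix (last row not 0 0 0 1)")
  rigid_shift(m[1:3, 4])
}
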