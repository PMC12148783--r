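#' Write a dose grid as a DICOM RTDOSE file
#'
#' Dose is stored as 32-bit unsigned integers with the given DoseGridScaling;
#' the write/read round trip therefore quantises dose by at most
#' \code{scaling / 2}.
#'
#' @param dose a \code{\link{dose_grid}}.
#' @param path output file path.
#' @param scaling Gy per stored integer unit (default 0.001).
#' @param frame_of_reference FrameOfReferenceUID to embed.
#' @return \code{path}, invisibly.
#' @export
write_rtdose <- function(dose, path, scaling = 0.001,
                         frame_of_reference = dcm_new_uid()) {
  stopifnot(inherits(dose, "dose_grid"))
  if (scaling <= 0) stop("scaling must be positive")
  g <- dose$geometry
  stored <- round(dose$values / scaling)
  if (max(stored) > 4294967295) stop("dose too large for 32-bit storage at this scaling")
  # encode unsigned 32-bit via signed representation
  sv <- as.vector(stored)
  sv[sv > 2147483647] <- sv[sv > 2147483647] - 4294967296
  pix <- writeBin(as.integer(sv), raw(), size = 4L, endian = "little")

  uid <- dcm_new_uid()
  elems <- list(
    el(0x0008, 0x0016, "UI", .SOP_RTDOSE),
    el(0x0008, 0x0018, "UI", uid),
    el(0x0008, 0x0060, "CS", "RTDOSE"),
    el(0x0010, 0x0010, "PN", "PHANTOM^SYNTHETIC"),
    el(0x0010, 0x0020, "LO", "SYN001"),
    el(0x0020, 0x0032, "DS", g$origin),
    el(0x0020, 0x0037, "DS", c(1, 0, 0, 0, 1, 0)),
    el(0x0020, 0x0052, "UI", frame_of_reference),
    el(0x0028, 0x0002, "US", 1L),
    el(0x0028, 0x0004, "CS", "MONOCHROME2"),
    el(0x0028, 0x0008, "IS", g$dims[3]),
    el(0x0028, 0x0010, "US", g$dims[2]),          # Rows (y)
    el(0x0028, 0x0011, "US", g$dims[1]),          # Columns (x)
    el(0x0028, 0x0030, "DS", c(g$spacing[2], g$spacing[1])),  # row\col
    el(0x0028, 0x0100, "US", 32L),
    el(0x0028, 0x0101, "US", 32L),
    el(0x0028, 0x0102, "US", 31L),
    el(0x0028, 0x0103, "US", 0L),
    el(0x3004, 0x0002, "CS", "GY"),
    el(0x3004, 0x0004, "CS", "PHYSICAL"),
    el(0x3004, 0x000A, "CS", "PLAN"),
    el(0x3004, 0x000C, "DS", (seq_len(g$dims[3]) - 1) * g$spacing[3]),
    el(0x3004, 0x000E, "DS", scaling),
    el(0x7FE0, 0x0010, "OW", pix)
  )
  .dcm_write_file(path, .SOP_RTDOSE, uid, elems)
}

#' Write a structure set as a DICOM RTSTRUCT file
#'
#' @param sset a \code{\link{structure_set}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_rtstruct <- function(sset, path) {
  stopifnot(inherits(sset, "structure_set"))
  frame <- sset$frame_of_reference
  if (!nzchar(frame)) frame <- dcm_new_uid()
  uid <- dcm_new_uid()

  roi_items <- list()
  contour_items <- list()
  for (i in seq_along(sset$structures)) {
    s <- sset$structures[[i]]
    roi_items[[i]] <- list(
      el(0x3006, 0x0022, "IS", i),
      el(0x3006, 0x0024, "UI", frame),
      el(0x3006, 0x0026, "LO", s$name)
    )
    cseq <- lapply(s$contours, function(ct) {
      list(
        el(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
        el(0x3006, 0x0046, "IS", nrow(ct$points)),
        el(0x3006, 0x0050, "DS", as.vector(t(ct$points)))
      )
    })
    item <- list()
    if (length(cseq)) item <- list(el(0x3006, 0x0040, "SQ", cseq))
    item <- c(item, list(el(0x3006, 0x0084, "IS", i)))
    contour_items[[i]] <- item
  }

  elems <- list(
    el(0x0008, 0x0016, "UI", .SOP_RTSTRUCT),
    el(0x0008, 0x0018, "UI", uid),
    el(0x0008, 0x0060, "CS", "RTSTRUCT"),
    el(0x0010, 0x0010, "PN", "PHANTOM^SYNTHETIC"),
    el(0x0010, 0x0020, "LO", "SYN001"),
    el(0x3006, 0x0002, "SH", "SABRCHECK"),
    el(0x3006, 0x0020, "SQ", roi_items),
    el(0x3006, 0x0039, "SQ", contour_items)
  )
  .dcm_write_file(path, .SOP_RTSTRUCT, uid, elems)
}

#' Write a rigid shift as a DICOM Spatial Registration (REG) file
#'
#' The stored 4x4 matrix has an identity rotation block and the shift's
#' translation in the last column, i.e. it maps daily-image coordinates into
#' planning coordinates.
#'
#' @param shift a \code{\link{rigid_shift}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_reg <- function(shift, path) {
  stopifnot(inherits(shift, "rigid_shift"))
  m <- diag(4)
  m[1:3, 4] <- shift$translation
  uid <- dcm_new_uid()
  matrix_item <- list(
    el(0x0070, 0x030C, "CS", "RIGID"),
    el(0x3006, 0x00C6, "DS", as.vector(t(m)))
  )
  reg_item <- list(
    el(0x0020, 0x0052, "UI", dcm_new_uid()),
    el(0x0070, 0x0309, "SQ", list(list(
      el(0x0070, 0x030A, "SQ", list(matrix_item))
    )))
  )
  elems <- list(
    el(0x0008, 0x0016, "UI", .SOP_REG),
    el(0x0008, 0x0018, "UI", uid),
    el(0x0008, 0x0060, "CS", "REG"),
    el(0x0070, 0x0308, "SQ", list(reg_item))
  )
  .dcm_write_file(path, .SOP_REG, uid, elems)
}
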