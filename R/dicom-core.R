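# Minimal DICOM Part-10 codec: Explicit VR Little Endian only.
# Covers exactly the element set the RT workflow needs (RTDOSE, RTSTRUCT,
# translation-only Spatial Registration). Other transfer syntaxes error out;
# this is a documented limitation, not a fallback.

.TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.SOP_RTDOSE <- "1.2.840.10008.5.1.4.1.1.481.2"
.SOP_RTSTRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"
.SOP_REG <- "1.2.840.10008.5.1.4.1.1.66.1"
# UUID-derived UID prefix (ITU-T X.667 "2.25" arc)
.UID_PREFIX <- "2.25."

.LONG_VRS <- c("OB", "OW", "OF", "OD", "SQ", "UC", "UR", "UT", "UN")
.TEXT_VRS <- c("AE", "AS", "CS", "DA", "DS", "DT", "IS", "LO", "LT", "PN",
               "SH", "ST", "TM", "UI", "UC", "UR", "UT")

dcm_new_uid <- function() {
  # not cryptographic; uniqueness within a session is all that is needed
  paste0(.UID_PREFIX,
         paste0(sample(0:9, 32, replace = TRUE), collapse = ""))
}

# ---- byte helpers ----------------------------------------------------------

.u16_raw <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256))
}

.u32_raw <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

.rd_u16 <- function(buf, pos) {
  as.integer(buf[pos]) + 256L * as.integer(buf[pos + 1L])
}

.rd_u32 <- function(buf, pos) {
  # as double: lengths can exceed .Machine$integer.max (0xFFFFFFFF sentinel)
  as.numeric(buf[pos]) + 256 * as.numeric(buf[pos + 1L]) +
    65536 * as.numeric(buf[pos + 2L]) + 16777216 * as.numeric(buf[pos + 3L])
}

# ---- encoding --------------------------------------------------------------

.dcm_encode_value <- function(vr, value) {
  if (vr == "SQ") {
    items <- lapply(value, function(item_elems) {
      body <- .dcm_encode_dataset(item_elems)
      c(.u16_raw(0xFFFE), .u16_raw(0xE000), .u32_raw(length(body)), body)
    })
    return(do.call(c, c(list(raw(0)), items)))
  }
  if (vr %in% c("OB", "OW", "UN")) {
    stopifnot(is.raw(value))
    return(value)
  }
  if (vr == "US") {
    return(do.call(c, lapply(as.numeric(value), .u16_raw)))
  }
  if (vr == "UL") {
    return(do.call(c, lapply(as.numeric(value), .u32_raw)))
  }
  if (vr == "DS") {
    txt <- paste(vapply(as.numeric(value),
                        function(v) sprintf("%.10g", v), character(1)),
                 collapse = "\\")
    return(charToRaw(txt))
  }
  if (vr == "IS") {
    return(charToRaw(paste(format(as.integer(value), scientific = FALSE,
                                  trim = TRUE), collapse = "\\")))
  }
  if (vr %in% .TEXT_VRS) {
    return(charToRaw(paste(as.character(value), collapse = "\\")))
  }
  stop("unsupported VR for encoding: ", vr)
}

.dcm_encode_element <- function(group, element, vr, value) {
  body <- .dcm_encode_value(vr, value)
  if (length(body) %% 2L == 1L) {
    pad <- if (vr == "UI") as.raw(0L) else as.raw(32L)  # NUL for UIDs, space otherwise
    body <- c(body, pad)
  }
  hdr <- c(.u16_raw(group), .u16_raw(element), charToRaw(vr))
  if (vr %in% .LONG_VRS) {
    hdr <- c(hdr, as.raw(c(0L, 0L)), .u32_raw(length(body)))
  } else {
    if (length(body) > 65534) stop("value too long for short-VR element")
    hdr <- c(hdr, .u16_raw(length(body)))
  }
  c(hdr, body)
}

# elements: list of list(group, element, vr, value), already tag-sorted
.dcm_encode_dataset <- function(elements) {
  do.call(c, c(list(raw(0)),
               lapply(elements, function(e)
                 .dcm_encode_element(e$group, e$element, e$vr, e$value))))
}

el <- function(group, element, vr, value) {
  list(group = group, element = element, vr = vr, value = value)
}

# Write a complete Part-10 file: preamble + meta group + dataset
.dcm_write_file <- function(path, sop_class_uid, sop_instance_uid, elements) {
  meta_elems <- list(
    el(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    el(0x0002, 0x0002, "UI", sop_class_uid),
    el(0x0002, 0x0003, "UI", sop_instance_uid),
    el(0x0002, 0x0010, "UI", .TS_EXPLICIT_LE),
    el(0x0002, 0x0012, "UI", paste0(.UID_PREFIX, "8467200982271."))
  )
  meta_body <- .dcm_encode_dataset(meta_elems)
  meta <- c(.dcm_encode_element(0x0002, 0x0000, "UL", length(meta_body)),
            meta_body)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(meta, con)
  writeBin(.dcm_encode_dataset(elements), con)
  invisible(path)
}

# ---- decoding --------------------------------------------------------------

.dcm_decode_value <- function(vr, body) {
  if (vr %in% c("OB", "OW", "OF", "OD", "UN")) return(body)
  if (vr == "US") {
    n <- length(body) %/% 2L
    if (n == 0L) return(integer(0))
    return(vapply(seq_len(n), function(i) .rd_u16(body, 2L * i - 1L), integer(1)))
  }
  if (vr == "UL") {
    n <- length(body) %/% 4L
    if (n == 0L) return(numeric(0))
    return(vapply(seq_len(n), function(i) .rd_u32(body, 4L * i - 3L), numeric(1)))
  }
  txt <- rawToChar(body[body != as.raw(0L)])
  if (vr %in% c("DS", "IS")) {
    parts <- trimws(strsplit(txt, "\\", fixed = TRUE)[[1]])
    parts <- parts[nzchar(parts)]
    return(as.numeric(parts))
  }
  if (vr %in% .TEXT_VRS) {
    parts <- trimws(strsplit(txt, "\\", fixed = TRUE)[[1]])
    return(parts)
  }
  body
}

# Parse a dataset region [pos, end]; returns list(elements = named list, pos)
.dcm_parse_dataset <- function(buf, pos, end) {
  out <- list()
  while (pos + 7L <= end + 1L && pos <= end) {
    group <- .rd_u16(buf, pos)
    element <- .rd_u16(buf, pos + 2L)
    if (group == 0xFFFE && element %in% c(0xE00D, 0xE0DD)) {
      # item / sequence delimiter: caller handles; stop here
      break
    }
    vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("cannot parse element at byte ", pos,
           ": not Explicit VR Little Endian (unsupported transfer syntax)")
    if (vr %in% .LONG_VRS) {
      len <- .rd_u32(buf, pos + 8L)
      vpos <- pos + 12L
    } else {
      len <- .rd_u16(buf, pos + 6L)
      vpos <- pos + 8L
    }
    key <- sprintf("%04X,%04X", group, element)
    if (vr == "SQ") {
      if (len == 4294967295) {
        parsed <- .dcm_parse_sq_undef(buf, vpos, end)
      } else {
        parsed <- .dcm_parse_sq_defined(buf, vpos, vpos + len - 1L)
      }
      out[[key]] <- list(vr = vr, value = parsed$items)
      pos <- parsed$pos
    } else {
      if (len == 4294967295) stop("undefined length on non-SQ element ", key)
      body <- if (len > 0) buf[vpos:(vpos + len - 1L)] else raw(0)
      out[[key]] <- list(vr = vr, value = .dcm_decode_value(vr, body))
      pos <- vpos + len
    }
  }
  list(elements = out, pos = pos)
}

.dcm_parse_item <- function(buf, pos, end) {
  group <- .rd_u16(buf, pos); element <- .rd_u16(buf, pos + 2L)
  if (group != 0xFFFE || element != 0xE000)
    stop("malformed sequence: expected item tag at byte ", pos)
  len <- .rd_u32(buf, pos + 4L)
  vpos <- pos + 8L
  if (len == 4294967295) {
    parsed <- .dcm_parse_dataset(buf, vpos, end)
    pos <- parsed$pos
    # consume item delimiter
    if (.rd_u16(buf, pos) == 0xFFFE && .rd_u16(buf, pos + 2L) == 0xE00D)
      pos <- pos + 8L
    list(elements = parsed$elements, pos = pos)
  } else {
    parsed <- .dcm_parse_dataset(buf, vpos, vpos + len - 1L)
    list(elements = parsed$elements, pos = vpos + len)
  }
}

.dcm_parse_sq_defined <- function(buf, pos, end) {
  items <- list()
  while (pos <= end) {
    it <- .dcm_parse_item(buf, pos, end)
    items[[length(items) + 1L]] <- it$elements
    pos <- it$pos
  }
  list(items = items, pos = pos)
}

.dcm_parse_sq_undef <- function(buf, pos, end) {
  items <- list()
  repeat {
    if (.rd_u16(buf, pos) == 0xFFFE && .rd_u16(buf, pos + 2L) == 0xE0DD) {
      pos <- pos + 8L
      break
    }
    it <- .dcm_parse_item(buf, pos, end)
    items[[length(items) + 1L]] <- it$elements
    pos <- it$pos
    if (pos > end) break
  }
  list(items = items, pos = pos)
}

# Read and parse a Part-10 DICOM file into a flat keyed element list.
dcm_read_file <- function(path) {
  buf <- readBin(path, "raw", n = file.size(path))
  if (length(buf) < 200 || rawToChar(buf[129:132]) != "DICM")
    stop("not a DICOM Part-10 file: ", path)
  pos <- 133L
  # file meta group is always Explicit VR LE
  meta <- list()
  while (pos + 7L <= length(buf) && .rd_u16(buf, pos) == 0x0002) {
    parsed1 <- .dcm_parse_single(buf, pos)
    meta[[parsed1$key]] <- parsed1$elem
    pos <- parsed1$pos
  }
  ts <- meta[["0002,0010"]]$value
  if (!is.null(ts) && !identical(ts, .TS_EXPLICIT_LE))
    stop("unsupported transfer syntax: ", ts,
         " (only Explicit VR Little Endian is supported)")
  data <- .dcm_parse_dataset(buf, pos, length(buf))$elements
  list(meta = meta, data = data, path = path)
}

# parse exactly one (non-SQ or SQ) element; used for the meta group walk
.dcm_parse_single <- function(buf, pos) {
  group <- .rd_u16(buf, pos); element <- .rd_u16(buf, pos + 2L)
  vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
  if (vr %in% .LONG_VRS) {
    len <- .rd_u32(buf, pos + 8L); vpos <- pos + 12L
  } else {
    len <- .rd_u16(buf, pos + 6L); vpos <- pos + 8L
  }
  body <- if (len > 0) buf[vpos:(vpos + len - 1L)] else raw(0)
  list(key = sprintf("%04X,%04X", group, element),
       elem = list(vr = vr, value = .dcm_decode_value(vr, body)),
       pos = vpos + len)
}

dcm_get <- function(ds, key, required = FALSE, what = key) {
  e <- ds$data[[key]]
  if (is.null(e)) {
    if (required) stop("required DICOM element missing: ", what, " (", key, ")")
    return(NULL)
  }
  e$value
}
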