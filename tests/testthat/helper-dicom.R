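## Build a minimal single-slice DICOM file (explicit VR little endian) at
## test time, so the reader can be exercised without committing binary
## fixtures. Only the tags the reader consumes are written.

u16le <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
u32le <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

dicom_element <- function(group, elem, vr, value_raw) {
  len <- length(value_raw)
  if (len %% 2L == 1L) {  # DICOM values are even-length padded
    pad <- if (vr %in% c("UI")) as.raw(0) else charToRaw(" ")
    value_raw <- c(value_raw, pad)
    len <- len + 1L
  }
  head <- c(u16le(group), u16le(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN"))
    c(head, as.raw(c(0, 0)), u32le(len), value_raw)
  else
    c(head, u16le(len), value_raw)
}

## `pixels`: integer matrix of stored values (row-major display convention).
write_minimal_dicom <- function(path, pixels, spacing_mm = 0.98,
                                slope = 1, intercept = -1024,
                                signed = FALSE) {
  rows <- nrow(pixels); cols <- ncol(pixels)
  stored <- as.integer(t(pixels))   # row-major
  px_raw <- writeBin(stored, raw(), size = 2L, endian = "little")
  ds <- function(x) charToRaw(paste(format(x, trim = TRUE), collapse = "\\"))
  body <- c(
    dicom_element(0x0002, 0x0010, "UI", charToRaw("1.2.840.10008.1.2.1")),
    dicom_element(0x0028, 0x0010, "US", u16le(rows)),
    dicom_element(0x0028, 0x0011, "US", u16le(cols)),
    dicom_element(0x0028, 0x0030, "DS", ds(c(spacing_mm, spacing_mm))),
    dicom_element(0x0028, 0x0100, "US", u16le(16)),
    dicom_element(0x0028, 0x0103, "US", u16le(as.integer(signed))),
    dicom_element(0x0028, 0x1052, "DS", ds(intercept)),
    dicom_element(0x0028, 0x1053, "DS", ds(slope)),
    dicom_element(0x7FE0, 0x0010, "OW", px_raw))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), body), con)
  invisible(path)
}
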