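# Minimal explicit-VR little-endian DICOM slice writer used to build
# single-series fixtures on the fly (uncompressed uint16 pixels).

dcm_write_u16 <- function(con, x)
  writeBin(as.integer(x), con, size = 2, endian = "little")

dcm_element <- function(con, group, elem, vr, payload) {
  dcm_write_u16(con, c(group, elem))
  writeChar(vr, con, eos = NULL)
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    dcm_write_u16(con, 0L)  # reserved
    writeBin(as.integer(length(payload)), con, size = 4, endian = "little")
  } else {
    dcm_write_u16(con, length(payload))
  }
  writeBin(payload, con)
}

dcm_string_payload <- function(s) {
  if (nchar(s) %% 2 == 1) s <- paste0(s, " ")
  charToRaw(s)
}

write_dicom_slice <- function(path, pixels, position_z,
                              pixel_spacing = c(0.4, 0.4),
                              slice_thickness = 0.4) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeChar("DICM", con, eos = NULL)
  rows <- ncol(pixels)   # DICOM rows = y, columns = x
  cols <- nrow(pixels)
  dcm_element(con, 0x0018L, 0x0050L, "DS",
              dcm_string_payload(format(slice_thickness)))
  dcm_element(con, 0x0020L, 0x0032L, "DS",
              dcm_string_payload(sprintf("0\\0\\%g", position_z)))
  dcm_element(con, 0x0028L, 0x0010L, "US",
              writeBin(as.integer(rows), raw(), size = 2, endian = "little"))
  dcm_element(con, 0x0028L, 0x0011L, "US",
              writeBin(as.integer(cols), raw(), size = 2, endian = "little"))
  dcm_element(con, 0x0028L, 0x0030L, "DS",
              dcm_string_payload(sprintf("%g\\%g", pixel_spacing[1],
                                         pixel_spacing[2])))
  dcm_element(con, 0x0028L, 0x0100L, "US",
              writeBin(16L, raw(), size = 2, endian = "little"))
  dcm_element(con, 0x0028L, 0x0103L, "US",
              writeBin(0L, raw(), size = 2, endian = "little"))
  # pixel data row-major (all columns of row 1, then row 2, ...)
  px <- integer(rows * cols)
  for (r in 1:rows) px[(r - 1) * cols + 1:cols] <- as.integer(pixels[, r])
  dcm_element(con, 0x7FE0L, 0x0010L, "OW",
              writeBin(px, raw(), size = 2, endian = "little"))
  invisible(path)
}
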