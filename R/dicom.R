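# Minimal DICOM series reader: uncompressed, explicit-VR, little-endian
# slices only (the common export of CBCT consoles). Slices are sorted by
# ImagePositionPatient z ascending and stacked along the canonical z axis.

dcm_uint16 <- function(raw, off) {
  readBin(raw[(off + 1):(off + 2)], "integer", size = 2, signed = FALSE,
          endian = "little")
}
dcm_uint32 <- function(raw, off) {
  readBin(raw[(off + 1):(off + 4)], "integer", size = 4, endian = "little")
}

# Parse one DICOM file into the handful of attributes the reader needs.
read_dicom_slice <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  off <- 0L
  if (length(raw) > 132 && rawToChar(raw[129:132]) == "DICM") off <- 132L
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  out <- list(path = path)
  while (off + 8 <= length(raw)) {
    group <- dcm_uint16(raw, off)
    elem <- dcm_uint16(raw, off + 2)
    vr <- rawToChar(raw[(off + 5):(off + 6)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("DICOM parse error (implicit VR or corrupt file): ", path)
    if (vr %in% long_vrs) {
      len <- dcm_uint32(raw, off + 8)
      body <- off + 12L
    } else {
      len <- dcm_uint16(raw, off + 6)
      body <- off + 8L
    }
    tag <- sprintf("%04x%04x", group, elem)
    val_raw <- if (len > 0) raw[(body + 1):(body + len)] else raw(0)
    if (tag %in% c("00280010", "00280011", "00280100", "00280103")) {
      out[[tag]] <- dcm_uint16(val_raw, 0)
    } else if (tag %in% c("00200032", "00280030", "00180050", "00180088",
                          "00201041")) {
      out[[tag]] <- as.numeric(strsplit(trimws(rawToChar(val_raw)),
                                        "\\\\")[[1]])
    } else if (tag == "7fe00010") {
      bits <- out[["00280100"]]
      if (is.null(bits)) bits <- 16L
      signed <- isTRUE(out[["00280103"]] == 1L)
      out$pixels <- readBin(val_raw, "integer", n = len %/% (bits %/% 8),
                            size = bits %/% 8, signed = signed || bits > 8,
                            endian = "little")
      break
    }
    off <- body + len
  }
  if (is.null(out$pixels))
    stop("no PixelData element found in ", path)
  if (is.null(out[["00280010"]]) || is.null(out[["00280011"]]))
    stop("DICOM slice missing Rows/Columns: ", path)
  out
}

read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) stop("no DICOM files found in ", dir)
  slices <- lapply(files, read_dicom_slice)

  consistent <- function(tag, name) {
    vals <- lapply(slices, `[[`, tag)
    if (any(vapply(vals, is.null, logical(1))) ||
        !all(vapply(vals, identical, logical(1), vals[[1]])))
      stop("inconsistent DICOM series: attribute ", name,
           " differs across slices")
    vals[[1]]
  }
  rows <- consistent("00280010", "Rows")
  cols <- consistent("00280011", "Columns")
  pixsp <- consistent("00280030", "PixelSpacing")

  zpos <- vapply(slices, function(s) {
    if (!is.null(s[["00200032"]])) s[["00200032"]][3]
    else if (!is.null(s[["00201041"]])) s[["00201041"]][1]
    else NA_real_
  }, numeric(1))
  if (any(is.na(zpos)))
    stop("DICOM slices lack ImagePositionPatient/SliceLocation; ",
         "cannot order the series")
  ord <- order(zpos)
  slices <- slices[ord]
  zpos <- zpos[ord]

  nz <- length(slices)
  zsp <- if (nz > 1) stats::median(diff(zpos)) else {
    s1 <- slices[[1]]
    if (!is.null(s1[["00180088"]])) s1[["00180088"]][1]
    else if (!is.null(s1[["00180050"]])) s1[["00180050"]][1] else 1
  }
  if (!is.finite(zsp) || zsp <= 0)
    stop("inconsistent DICOM series: non-positive slice spacing ",
         "(ImagePositionPatient)")

  data <- array(0, dim = c(cols, rows, nz))
  for (k in seq_len(nz)) {
    px <- slices[[k]]$pixels
    if (length(px) != rows * cols)
      stop("PixelData length mismatch in ", slices[[k]]$path)
    # DICOM pixel order is row-major; canonical x = column, y = row
    data[, , k] <- matrix(px, nrow = cols, ncol = rows)
  }
  # PixelSpacing is (row spacing, column spacing) = (y, x)
  volume(data, c(pixsp[2], pixsp[1], zsp))
}
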