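#' @useDynLib canalseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Construct a CBCT volume
#'
#' A volume couples a 3D intensity array with its voxel spacing in mm. The
#' axis convention is fixed throughout the package: the first array index runs
#' left-right (x), the second anterior-posterior (y), the third
#' inferior-superior (z); an axial slice is `data[, , z]`. Intensities are
#' arbitrary CBCT units (cone-beam scanners are not Hounsfield-calibrated),
#' kept as floating point.
#'
#' @param data 3D numeric array of intensities (all finite).
#' @param spacing numeric length-3, voxel edge lengths in mm (all > 0).
#' @return An object of class `canal_volume` with fields `data` and `spacing`.
#' @export
volume <- function(data, spacing = c(1, 1, 1)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("volume data must have exactly 3 dimensions, got ",
         length(dim(data)))
  if (!all(is.finite(data))) stop("volume intensities must all be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values (mm)")
  structure(list(data = data, spacing = spacing), class = "canal_volume")
}

#' @export
print.canal_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("CBCT volume: %d x %d x %d voxels @ %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

is_volume <- function(x) inherits(x, "canal_volume")

#' Binary mask aligned to a volume
#'
#' @param data logical (or 0/1 numeric) array, 2D or 3D.
#' @param spacing voxel spacing in mm (3D masks).
#' @return Object of class `canal_mask` with logical `data`.
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1)) {
  data <- as.array(data)
  if (!is.logical(data)) {
    if (!all(data %in% c(0, 1)))
      stop("mask values must be in {0, 1}")
    storage.mode(data) <- "logical"
  }
  structure(list(data = data, spacing = as.numeric(spacing)),
            class = "canal_mask")
}

is_mask <- function(x) inherits(x, "canal_mask")

# Accept a canal_mask, logical array, or 0/1 array; return logical array.
mask_data <- function(m) {
  if (is_mask(m)) return(m$data)
  m <- as.array(m)
  if (!is.logical(m)) {
    stopifnot(all(m %in% c(0, 1)))
    storage.mode(m) <- "logical"
  }
  m
}

#' Half-open bounding box
#'
#' Boxes are 0-based and half-open: voxel indices `i` with
#' `lo[a] <= i[a] < hi[a]` on each axis `a`, so boxes compose without
#' off-by-one ambiguity.
#'
#' @param lo,hi integer length-3 vectors, `lo < hi` component-wise.
#' @return Object of class `canal_bbox`.
#' @export
bounding_box <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (length(lo) != 3L || length(hi) != 3L) stop("lo and hi must be length 3")
  if (any(lo < 0L)) stop("bounding box lo must be >= 0")
  if (any(lo >= hi)) stop("bounding box must satisfy lo < hi per axis")
  structure(list(lo = lo, hi = hi), class = "canal_bbox")
}

#' Bounding box of a mask
#'
#' @param mask logical array or `canal_mask` with at least one TRUE voxel.
#' @return `canal_bbox` (0-based, half-open) tightly enclosing the mask.
#' @export
mask_bounding_box <- function(mask) {
  m <- mask_data(mask)
  if (!any(m)) stop("cannot take the bounding box of an empty mask")
  w <- which(m, arr.ind = TRUE)
  bounding_box(apply(w, 2, min) - 1L, apply(w, 2, max))
}

#' Read a volume from NIfTI or a DICOM series directory
#'
#' NIfTI files (`.nii`, `.nii.gz`) are read with RNifti; spacing is taken from
#' `pixdim`. A directory is treated as one DICOM series: slices are sorted by
#' slice position ascending and stacked along z. The array storage order is
#' taken as the canonical (x, y, z) frame.
#'
#' @param path a NIfTI file or a directory containing DICOM slices.
#' @return A [volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path)
  if (dir.exists(path)) return(read_dicom_series(path))
  img <- RNifti::readNifti(path)
  data <- array(as.vector(img), dim(img))  # plain array, no image attributes
  if (length(dim(data)) == 4L && dim(data)[4] == 1L)
    data <- array(data, dim(data)[1:3])
  if (length(dim(data)) != 3L)
    stop("expected a 3D volume, file has ", length(dim(data)),
         " dimensions: ", path)
  volume(data, RNifti::pixdim(img)[1:3])
}

#' Read a binary mask from NIfTI
#'
#' @param path NIfTI file holding a uint8 0/1 mask.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  binary_mask(v$data != 0, v$spacing)
}

#' Write a volume or mask as NIfTI
#'
#' Masks (`canal_mask` or logical arrays) are written as uint8 with voxel
#' values exactly 0/1; intensity volumes are written as float32.
#'
#' @param vol a [volume()], [binary_mask()], or plain array.
#' @param path output path ending in `.nii` or `.nii.gz`; the parent
#'   directory must exist.
#' @param spacing spacing override for plain arrays.
#' @export
write_volume <- function(vol, path, spacing = NULL) {
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  if (is_mask(vol)) {
    data <- array(as.integer(vol$data), dim(vol$data))
    sp <- vol$spacing
    dt <- "uint8"
  } else if (is_volume(vol)) {
    data <- vol$data
    sp <- vol$spacing
    dt <- "float"
  } else {
    data <- as.array(vol)
    sp <- if (is.null(spacing)) c(1, 1, 1) else spacing
    dt <- "float"
  }
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' Downsample a volume by a factor of two per axis
#'
#' Output dimensions are `ceiling(n / 2)` (a trailing odd slice is never
#' discarded) and spacing doubles. Intensity volumes are linearly
#' interpolated at the center of each 2-voxel block; masks use
#' nearest-neighbor sampling so values stay in {0, 1}.
#'
#' @param vol a [volume()] or [binary_mask()] (3D).
#' @return Downsampled object of the same class.
#' @export
downsample_half <- function(vol) {
  msk <- is_mask(vol)
  data <- if (msk) vol$data else vol$data
  d <- dim(data)
  if (any(d < 2L)) stop("every dimension must be >= 2 to downsample")
  out <- data
  for (axis in 1:3) {
    n <- dim(out)[axis]
    m <- ceiling(n / 2)
    pos <- pmin((seq_len(m) - 1) * 2 + 1.5, n)  # center of each voxel pair
    if (msk) {
      idx <- pmin(floor(pos), n)  # first voxel of the pair
      out <- slab_index(out, axis, idx)
    } else {
      lo <- floor(pos); hi <- pmin(lo + 1, n); w <- pos - lo
      a <- slab_index(out, axis, lo)
      b <- slab_index(out, axis, hi)
      out <- a + sweep_axis(b - a, axis, w)
    }
  }
  if (msk) binary_mask(out, vol$spacing * 2) else volume(out, vol$spacing * 2)
}

# index an array along one axis
slab_index <- function(arr, axis, idx) {
  switch(axis,
         arr[idx, , , drop = FALSE],
         arr[, idx, , drop = FALSE],
         arr[, , idx, drop = FALSE])
}

# multiply arr by weights w along the given axis
sweep_axis <- function(arr, axis, w) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  a <- a * w  # recycles along first dim
  aperm(a, order(perm))
}

#' Crop a volume or mask to a bounding box
#'
#' @param vol a [volume()] or [binary_mask()].
#' @param box a [bounding_box()] (0-based, half-open) within bounds.
#' @return Cropped object with shape `hi - lo`; spacing unchanged.
#' @export
crop_volume <- function(vol, box) {
  d <- dim(vol$data)
  if (any(box$hi > d))
    stop("bounding box exceeds volume extent (",
         paste(d, collapse = "x"), ")")
  data <- vol$data[(box$lo[1] + 1):box$hi[1],
                   (box$lo[2] + 1):box$hi[2],
                   (box$lo[3] + 1):box$hi[3], drop = FALSE]
  if (is_mask(vol)) binary_mask(data, vol$spacing) else volume(data, vol$spacing)
}

#' Embed a cropped volume back at a box position
#'
#' Inverse of [crop_volume()] on the cropped region: values inside `box` are
#' replaced by `sub`, the rest of `target` is untouched.
#'
#' @param target full-size [volume()] or [binary_mask()].
#' @param sub cropped object whose shape equals the box extent.
#' @param box the [bounding_box()] `sub` was cropped with.
#' @return `target` with `sub` written into `box`.
#' @export
embed_volume <- function(target, sub, box) {
  if (!identical(dim(sub$data), as.integer(box$hi - box$lo)))
    stop("sub-volume shape does not match box extent")
  data <- target$data
  data[(box$lo[1] + 1):box$hi[1],
       (box$lo[2] + 1):box$hi[2],
       (box$lo[3] + 1):box$hi[3]] <- sub$data
  if (is_mask(target)) binary_mask(data, target$spacing)
  else volume(data, target$spacing)
}
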