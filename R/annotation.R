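#' Extract a canal mask from a color tracing image
#'
#' Clinician tracings are exported as grayscale slices with the canal drawn
#' in a flat color; the mask is recovered by color keying: a pixel belongs to
#' the mask iff every channel differs from the key color by at most the
#' tolerance.
#'
#' @param image `(H, W, 3)` numeric RGB array.
#' @param color RGB triple of the trace color.
#' @param tolerance per-channel maximum absolute difference (>= 0).
#' @return Logical `(H, W)` mask.
#' @export
extract_canal_mask_from_tracing <- function(image, color = c(1, 0, 0),
                                            tolerance = 0) {
  image <- as.array(image)
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("tracing image must have 3 channels (RGB); grayscale input ",
         "cannot be color-keyed")
  if (tolerance < 0) stop("tolerance must be >= 0")
  abs(image[, , 1] - color[1]) <= tolerance &
    abs(image[, , 2] - color[2]) <= tolerance &
    abs(image[, , 3] - color[3]) <= tolerance
}

#' Densify sparse slice annotations by cubic interpolation
#'
#' Restores a dense mask from annotations drawn every few slices, the way
#' clinical ground truth is produced (tracing at 1 mm intervals, restored to
#' the native 0.2 mm slice interval by cubic interpolation). The annotated
#' masks are taken as a {0,1}-valued field; each in-plane position is
#' interpolated along the slice axis with a natural cubic spline (which
#' passes through the annotated values exactly), values are clamped to
#' \code{[0, 1]} to suppress cubic overshoot, and the field is thresholded.
#' Because the spline is linear in the data, the whole operation is one
#' matrix product with a precomputed interpolation operator.
#'
#' @param sparse a `sparse_annotation` (see [sparse_annotation()]), or a list
#'   with `entries` (`list(slice_index, mask)`), and `shape`.
#' @param threshold mask threshold on the interpolated field.
#' @param linear fall back to linear interpolation when fewer than 4 slices
#'   are annotated (cubic needs 4 support points).
#' @return A [binary_mask()] covering the full `shape`: dense between the
#'   first and last annotated slice, empty elsewhere. Annotated slices are
#'   reproduced exactly.
#' @export
densify_annotation <- function(sparse, threshold = 0.5, linear = FALSE) {
  entries <- sparse$entries
  m <- length(entries)
  idx <- vapply(entries, `[[`, numeric(1), "slice_index")
  if (any(diff(idx) <= 0)) stop("annotated slice indices must be increasing")
  if (m < 4 && !linear)
    stop("cubic densification needs >= 4 annotated slices (got ", m,
         "); set linear = TRUE for linear interpolation")
  shape <- sparse$shape
  if (is.null(shape)) {
    d2 <- dim(entries[[1]]$mask)
    shape <- c(d2, max(idx))
  }
  u <- seq(min(idx), max(idx))
  # interpolation operator: W[j, k] = basis of knot k evaluated at slice u[j]
  W <- vapply(seq_len(m), function(k) {
    e <- numeric(m); e[k] <- 1
    if (m < 4) stats::approx(idx, e, xout = u)$y
    else stats::splinefun(idx, e, method = "natural")(u)
  }, numeric(length(u)))
  A <- vapply(entries, function(e) as.numeric(e$mask),
              numeric(prod(shape[1:2])))
  dense <- A %*% t(W)
  dense <- pmin(pmax(dense, 0), 1)
  out <- array(FALSE, shape)
  out[, , u] <- dense >= threshold
  sp <- if (!is.null(sparse$spacing)) sparse$spacing
  else if (!is.null(sparse$slice_spacing_mm))
    c(1, 1, sparse$slice_spacing_mm) else c(1, 1, 1)
  binary_mask(out, sp)
}

#' Dice similarity coefficient between two masks
#'
#' @param a,b logical arrays or [binary_mask()] objects of equal shape.
#' @return `2|A n B| / (|A| + |B|)`; `NA` if both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  a <- mask_data(a); b <- mask_data(b)
  stopifnot(identical(dim(a), dim(b)))
  s <- sum(a) + sum(b)
  if (s == 0) return(NA_real_)
  2 * sum(a & b) / s
}
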