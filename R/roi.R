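#' Multi-level Otsu thresholding
#'
#' Selects `n_levels` thresholds maximizing between-class intensity variance
#' over a 256-bin histogram of min-max-normalized intensities (CBCT units are
#' scanner-arbitrary, so the histogram is always built on the normalized
#' scale). The optimum is exact: every ordered threshold tuple is searched
#' exhaustively (supported for 1-3 levels).
#'
#' @param x a [volume()], matrix, or numeric array.
#' @param n_levels number of thresholds (1-3).
#' @param bins histogram resolution.
#' @return A `threshold_set`: `levels` (increasing, on the original intensity
#'   scale), with `bone` aliasing the first level and `teeth` the last.
#' @export
multi_otsu <- function(x, n_levels = 3L, bins = 256L) {
  v <- if (is_volume(x)) x$data else as.array(x)
  v <- as.numeric(v)
  rng <- range(v)
  if (rng[1] == rng[2])
    stop("degenerate input: constant intensity, cannot threshold")
  q <- pmin(floor((v - rng[1]) / (rng[2] - rng[1]) * bins), bins - 1L)
  if (length(unique(q)) < n_levels + 1L)
    stop("degenerate input: fewer than ", n_levels + 1L,
         " distinct quantized intensity values")
  h <- tabulate(q + 1L, nbins = bins)
  t_bins <- cpp_multiotsu(as.numeric(h), n_levels)
  # threshold = upper edge of the last bin of each class
  levels <- rng[1] + (t_bins + 1) / bins * (rng[2] - rng[1])
  structure(list(levels = levels, bone = levels[1],
                 teeth = levels[n_levels], bins = bins, range = rng),
            class = "threshold_set")
}

#' Reconstruct a 2D panoramic view of the dental arches
#'
#' The default projection is the per-column maximum intensity along the
#' anterior-posterior (y) axis, giving an image with rows = z
#' (inferior-superior) and columns = x (left-right). `columns` records which
#' volume x-columns each panorama column aggregates, so 2D regions found in
#' the panorama can be mapped back to 3D.
#'
#' @param vol a [volume()].
#' @return A `panoramic_view`: `image` (nz x nx matrix), `columns`
#'   (volume x index per panorama column), `spacing` (row, column spacing mm).
#' @export
reconstruct_panorama <- function(vol) {
  stopifnot(is_volume(vol))
  img <- t(apply(vol$data, c(1, 3), max))  # (nz, nx)
  structure(list(image = img, columns = seq_len(dim(vol$data)[1]),
                 spacing = c(vol$spacing[3], vol$spacing[1])),
            class = "panoramic_view")
}

#' Restrict a panoramic view to its center third
#'
#' Keeps columns `[floor(W/3), floor(2W/3))` (0-based, half-open) of a
#' width-`W` view, the region dominated by the anterior dental arch.
#'
#' @param view a `panoramic_view`.
#' @return The restricted `panoramic_view` (columns map preserved).
#' @export
center_third <- function(view) {
  W <- ncol(view$image)
  if (W < 3) stop("panorama width must be >= 3 columns")
  keep <- (floor(W / 3) + 1):floor(2 * W / 3)
  structure(list(image = view$image[, keep, drop = FALSE],
                 columns = view$columns[keep], spacing = view$spacing),
            class = "panoramic_view")
}

#' Keep the k largest connected components of a mask
#'
#' Components are ranked by voxel count; equal sizes are broken by the
#' smaller label index, labels being assigned in raster-scan order of each
#' component's first voxel, so the result is deterministic. Fewer than `k`
#' components means all are retained; an empty mask is returned as-is with a
#' warning.
#'
#' @param mask logical matrix/array or [binary_mask()].
#' @param k number of components to keep (>= 1).
#' @param connectivity `"face"` (4-/6-connectivity) or `"full"`
#'   (8-/26-connectivity).
#' @return Object of the same kind as `mask`.
#' @export
largest_components <- function(mask, k = 1L, connectivity = c("face", "full")) {
  connectivity <- match.arg(connectivity)
  if (k < 1) stop("k must be >= 1")
  m <- mask_data(mask)
  if (!any(m)) {
    warning("largest_components: empty mask")
    return(mask)
  }
  lab <- cpp_label(as.logical(m), dim(m),
                  if (connectivity == "face") 6L else 26L)
  sizes <- tabulate(lab)
  keep <- order(-sizes, seq_along(sizes))[seq_len(min(k, length(sizes)))]
  out <- array(lab %in% keep, dim(m))
  if (is_mask(mask)) binary_mask(out, mask$spacing) else out
}

# Core morphology on logical arrays. Ball/disk structuring element with
# per-axis voxel radius round(radius_mm / spacing); realized through the
# exact Euclidean distance transform (dilate = distance-to-foreground within
# the ellipsoid; erode by duality).
morph_mask <- function(m, op, radius_mm, spacing) {
  nd <- length(dim(m))
  if (op == "complement") return(!m)
  r <- round(radius_mm / spacing[seq_len(nd)])
  if (all(r < 1) || !any(m) || all(m)) {
    if (op %in% c("dilate", "erode", "close")) return(m)
  }
  w <- ifelse(r >= 1, 1 / r, 1e6)  # zero radius on an axis: no spread
  dil <- function(x) {
    d2 <- cpp_edt_sq(as.logical(x), dim(x), w)
    array(d2 <= 1 + 1e-9, dim(x))
  }
  switch(op,
         dilate = dil(m),
         erode = !dil(!m),
         close = {
           d <- dil(m)
           !dil(!d)
         },
         stop("unknown morphology op: ", op))
}

#' Morphological operations with a physical-size structuring element
#'
#' Applies a ball (3D) or disk (2D) structuring element of per-axis radius
#' `round(radius_mm / spacing)` voxels. `"complement"` flips every voxel and
#' ignores the radius.
#'
#' @param mask [binary_mask()] or logical array.
#' @param op one of `"dilate"`, `"erode"`, `"close"`, `"complement"`.
#' @param radius_mm element radius in mm (>= 0).
#' @param spacing_mm spacing for plain arrays (per retained axis).
#' @return Same kind of object as `mask`.
#' @export
morph <- function(mask, op = c("dilate", "erode", "close", "complement"),
                  radius_mm = 1, spacing_mm = NULL) {
  op <- match.arg(op)
  if (radius_mm < 0 && op != "complement") stop("radius_mm must be >= 0")
  m <- mask_data(mask)
  sp <- if (is_mask(mask)) mask$spacing
  else if (!is.null(spacing_mm)) spacing_mm
  else rep(1, length(dim(m)))
  out <- morph_mask(m, op, radius_mm, sp)
  if (is_mask(mask)) binary_mask(out, mask$spacing) else out
}

#' Extract the mandible region of interest from a head CBCT volume
#'
#' Automatic isolation of the 3D mandibular part, step by step: (A) the
#' center third of the reconstructed panoramic view; (B) binarization of (A)
#' at the teeth threshold; (C) dilation, keeping the largest object (the
#' tooth arc); (D) the full-width panorama confined to the tooth height
#' spanned by (C); (E) binarization of (D) at the bone threshold; (F) the two
#' largest components of the complement (the buccal corridors); (G) union of
#' the corridors and the tooth object; (H) upward extension of (G), per
#' panorama column, marking the maxillary region; (I) binarization of the 3D
#' volume at the bone threshold, removal of the per-column maxillary
#' z-ranges, 3D morphological closing and retention of the largest component
#' (the mandible mask); (J) cropping to the mask's bounding box with voxels
#' outside the mask set to the volume minimum.
#'
#' Thresholds are obtained by area-limited multi-level Otsu (the teeth
#' threshold from (A), the bone threshold from (D)); when a run produces an
#' inaccurate segmentation, both can be overridden manually.
#'
#' @param vol a [volume()] containing bone.
#' @param overrides optional `list(bone =, teeth =)` manual thresholds
#'   replacing the Otsu values entirely.
#' @param dilate_mm dilation radius for step (C), mm.
#' @param close_mm closing radius for step (I), mm.
#' @param connectivity 3D component connectivity, `"face"` or `"full"`.
#' @param keep_intermediates if TRUE, the per-step masks A-I are returned.
#' @return An `roi_result`: `mandible_mask` (full-size), `box`
#'   ([bounding_box()]), `cropped` (masked-and-cropped [volume()]),
#'   `thresholds`, and optionally `intermediates`.
#' @export
extract_mandible_roi <- function(vol, overrides = NULL, dilate_mm = 1.0,
                                 close_mm = 2.0,
                                 connectivity = c("face", "full"),
                                 keep_intermediates = FALSE) {
  connectivity <- match.arg(connectivity)
  stopifnot(is_volume(vol))
  pano <- reconstruct_panorama(vol)
  A <- center_third(pano)

  teeth_th <- if (!is.null(overrides)) overrides$teeth
  else multi_otsu(A$image, 3L)$teeth

  B <- A$image > teeth_th
  if (!any(B))
    stop("no teeth detected above the teeth threshold; ",
         "supply manual thresholds via overrides")
  Bd <- morph_mask(B, "dilate", dilate_mm, A$spacing)
  C <- largest_components(Bd, 1L, "face")

  tooth_rows <- which(apply(C, 1, any))
  pad <- round(dilate_mm / pano$spacing[1])
  rlo <- max(1L, min(tooth_rows) - pad)
  rhi <- min(nrow(pano$image), max(tooth_rows) + pad)
  D <- pano$image[rlo:rhi, , drop = FALSE]

  bone_th <- if (!is.null(overrides)) overrides$bone
  else multi_otsu(D, 3L)$bone
  if (!any(vol$data > bone_th))
    stop("no bone detected above the bone threshold")

  E <- D > bone_th
  F_ <- largest_components(!E, 2L, "face")

  G <- matrix(FALSE, nrow(pano$image), ncol(pano$image))
  G[rlo:rhi, ] <- G[rlo:rhi, ] | F_
  Gc <- G
  a_cols <- match(A$columns, pano$columns)
  Gc[, a_cols] <- Gc[, a_cols] | C
  G <- Gc

  # (H) per-column top of G; columns with no G pixel inherit the nearest
  # defined column's cut
  top <- apply(G, 2, function(col) if (any(col)) max(which(col)) else NA_integer_)
  if (all(is.na(top)))
    stop("no teeth detected; supply manual thresholds via overrides")
  defined <- which(!is.na(top))
  near <- ifelse(is.na(top),
                 top[vapply(seq_along(top), function(i)
                   defined[which.min(abs(defined - i))], integer(1))],
                 top)

  bone3 <- vol$data > bone_th
  nz <- dim(bone3)[3]
  for (xi in seq_along(near)) {
    cz <- near[xi]
    if (cz < nz) bone3[pano$columns[xi], , (cz + 1):nz] <- FALSE
  }

  closed <- morph_mask(bone3, "close", close_mm, vol$spacing)
  mand <- largest_components(closed, 1L, connectivity)

  box <- mask_bounding_box(mand)
  cropped <- crop_volume(vol, box)
  inmask <- crop_volume(binary_mask(mand, vol$spacing), box)
  fill <- min(vol$data)
  cd <- cropped$data
  cd[!inmask$data] <- fill
  cropped <- volume(cd, vol$spacing)

  res <- list(mandible_mask = binary_mask(mand, vol$spacing), box = box,
              cropped = cropped,
              thresholds = list(bone = bone_th, teeth = teeth_th))
  if (keep_intermediates)
    res$intermediates <- list(A = A, B = B, C = C, D = D, E = E, F = F_,
                              G = G, maxilla_cut = near)
  structure(res, class = "roi_result")
}
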