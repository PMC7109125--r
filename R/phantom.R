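#' Configuration for the synthetic CBCT phantom
#'
#' The phantom emulates the anatomy the segmentation pipeline operates on: a
#' U-shaped mandible (parabolic axial arch with two posterior rami) with a
#' cortical shell and trabecular interior, one low-intensity canal tube per
#' side wrapped in a thin high-intensity cortical rim, a row of high-intensity
#' teeth on the superior arch surface, a separate maxillary arch above an air
#' gap, and additive Gaussian noise. Geometry is parametric (fractions of the
#' physical volume extent) so every mask has an analytic ground truth at any
#' shape/spacing.
#'
#' Default intensities (arbitrary CBCT units) keep the ordering
#' tooth > cortical >= canal_rim > trabecular > canal_lumen >= soft_tissue >
#' air, and are spaced so that 3-level Otsu thresholding of the clean phantom
#' puts its first threshold between soft tissue and trabecular bone and its
#' third between cortical bone and teeth.
#'
#' @param shape integer length-3 voxel counts, each >= 48.
#' @param spacing_mm voxel spacing in mm (scalar or length 3).
#' @param seed integer RNG seed; identical seeds give identical phantoms.
#' @param intensities named list of tissue intensities.
#' @param canal_radius_mm radius of the canal lumen tube (mm).
#' @param rim_thickness_mm thickness of the cortical rim around the canal
#'   (mm); 0 reproduces the hard case of a canal with no visible rim.
#' @param noise_sigma standard deviation of additive Gaussian noise.
#' @param maxilla_gap_mm air gap between mandibular teeth and the maxilla.
#' @param canal_z_fracs length-4 fractions of the volume height giving the
#'   Bezier z control points of the canal path, from the
#'   mandibular-foramen analog to the mental-foramen analog. The default
#'   dips anteriorly and rises to the exit, as the nerve does; a monotone
#'   profile (e.g. `c(0.46, 0.37, 0.28, 0.19)`) gives an oblique canal that
#'   crosses every axial slice transversally, the regime in which
#'   slice-by-slice annotation emulates clinical cross-sectional tracing
#'   (clinical tracings are drawn on sections perpendicular to the canal).
#' @param canal_x_fracs length-4 fractions of the arch half-width giving the
#'   (mirrored) Bezier x control points of the canal path.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(shape = c(160, 160, 128),
                           spacing_mm = 0.4,
                           seed = 0L,
                           intensities = list(air = 0, soft_tissue = 4,
                                              canal_lumen = 87,
                                              trabecular = 90,
                                              canal_rim = 150, cortical = 160,
                                              dentin = 200, tooth = 255),
                           canal_radius_mm = 1.0,
                           rim_thickness_mm = 0.6,
                           noise_sigma = 4,
                           maxilla_gap_mm = 4,
                           canal_z_fracs = c(0.46, 0.20, 0.16, 0.22),
                           canal_x_fracs = c(0.87, 0.72, 0.52, 0.42)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 48L))
    stop("phantom shape must be 3 integers, each >= 48")
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3)
  need <- c("air", "soft_tissue", "canal_lumen", "trabecular", "canal_rim",
            "cortical", "tooth")
  if (!all(need %in% names(intensities)))
    stop("intensities must name: ", paste(need, collapse = ", "))
  ii <- intensities
  # teeth are two-part: enamel crowns at `tooth`, dentin roots in between
  if (is.null(ii$dentin)) ii$dentin <- (ii$cortical + ii$tooth) / 2
  ok <- ii$tooth > ii$cortical && ii$cortical >= ii$canal_rim &&
    ii$canal_rim > ii$trabecular && ii$trabecular > ii$canal_lumen &&
    ii$canal_lumen >= ii$soft_tissue && ii$soft_tissue > ii$air
  if (!ok)
    warning("intensity ordering differs from the default ",
            "tooth > cortical >= rim > trabecular > lumen >= soft > air")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (maxilla_gap_mm <= 0) stop("maxilla_gap_mm must be > 0")
  structure(list(shape = shape, spacing = as.numeric(spacing_mm),
                 seed = as.integer(seed), intensities = ii,
                 canal_radius_mm = canal_radius_mm,
                 rim_thickness_mm = rim_thickness_mm,
                 noise_sigma = noise_sigma,
                 maxilla_gap_mm = maxilla_gap_mm,
                 canal_z_fracs = as.numeric(canal_z_fracs),
                 canal_x_fracs = as.numeric(canal_x_fracs)),
            class = "phantom_config")
}

# Evaluate a cubic Bezier through 4 control points (rows of P) at parameters t.
bezier3 <- function(P, t) {
  b <- cbind((1 - t)^3, 3 * (1 - t)^2 * t, 3 * (1 - t) * t^2, t^3)
  b %*% P
}

# Distance-based tube rendering: squared mm distance of every voxel to the
# rasterized path, via the exact Euclidean distance transform.
tube_distance_sq <- function(path_mm, shape, spacing) {
  seedmask <- array(FALSE, shape)
  idx <- round(sweep(path_mm, 2, spacing, "/") + 0.5)
  idx <- pmin(pmax(idx, 1), matrix(shape, nrow(idx), 3, byrow = TRUE))
  seedmask[idx] <- TRUE
  array(cpp_edt_sq(as.logical(seedmask), dim(seedmask), spacing), shape)
}

#' Generate a synthetic CBCT phantom
#'
#' @param cfg a [phantom_config()].
#' @return A `phantom_sample`: `volume` plus `canal_mask`, `mandible_mask`,
#'   `teeth_mask` and `maxilla_mask` ([binary_mask()] objects), and the
#'   config. The canal mask is contained in the mandible mask; teeth and
#'   maxilla are disjoint from the canal.
#' @export
generate_phantom <- function(cfg = phantom_config()) {
  stopifnot(inherits(cfg, "phantom_config"))
  n <- cfg$shape; sp <- cfg$spacing
  L <- n * sp                      # physical extent, mm
  ii <- cfg$intensities

  # voxel-center physical coordinates
  xs <- (seq_len(n[1]) - 0.5) * sp[1]
  ys <- (seq_len(n[2]) - 0.5) * sp[2]
  zs <- (seq_len(n[3]) - 0.5) * sp[3]
  X <- array(rep(xs, times = n[2] * n[3]), n)
  Y <- array(rep(rep(ys, each = n[1]), times = n[3]), n)
  Z <- array(rep(zs, each = n[1] * n[2]), n)

  cx <- L[1] / 2
  wa <- 0.33 * L[1]                     # arch half-width
  y_front <- 0.18 * L[2]
  y_back <- 0.72 * L[2]
  karch <- (y_back - y_front) / wa^2
  y_c <- function(x) y_front + karch * (x - cx)^2
  half_th <- 0.055 * L[2]               # arch band half-thickness
  # slope-corrected band: constant thickness perpendicular to the arch curve
  band_th <- function(x) half_th * sqrt(1 + (2 * karch * (x - cx))^2)

  z_body0 <- 0.08 * L[3]
  z_body1 <- 0.42 * L[3]
  z_ramus <- 0.54 * L[3]
  y_ramus <- 0.42 * L[2]

  in_arch <- abs(X - cx) <= wa & abs(Y - y_c(X)) <= band_th(X)
  mandible <- in_arch & ((Z >= z_body0 & Z <= z_body1) |
                           (Z > z_body1 & Z <= z_ramus & Y >= y_ramus))

  # head soft-tissue ellipsoid
  head <- ((X - cx) / (0.47 * L[1]))^2 + ((Y - 0.5 * L[2]) / (0.45 * L[2]))^2 +
    ((Z - 0.5 * L[3]) / (0.55 * L[3]))^2 <= 1

  # teeth: ellipsoids half-embedded in the superior arch surface
  # (dentin roots below the crest, enamel crowns above)
  tooth_r <- 0.028 * L[1]
  tooth_hz <- 0.05 * L[3]
  tooth_x <- cx + seq(-0.72, 0.72, length.out = 11) * wa
  teeth <- array(FALSE, n)
  for (tx in tooth_x) {
    ty <- y_c(tx)
    teeth <- teeth | (((X - tx) / tooth_r)^2 + ((Y - ty) / tooth_r)^2 +
                        ((Z - z_body1) / tooth_hz)^2 <= 1)
  }
  teeth_top <- z_body1 + tooth_hz

  # maxillary arch above the air gap (no distinct tooth intensities)
  z_max0 <- teeth_top + cfg$maxilla_gap_mm
  z_max1 <- min(z_max0 + 0.18 * L[3], 0.97 * L[3])
  if (z_max1 <= z_max0) stop("maxilla_gap_mm too large for this volume")
  maxilla <- in_arch & Z >= z_max0 & Z <= z_max1

  # canal path per side: x and z follow a cubic Bezier (descending from the
  # mandibular-foramen analog, dipping, and rising to the mental-foramen
  # analog), y rides the arch centerline so the tube stays inside the band
  canal_d2 <- array(Inf, n)
  for (sgn in c(-1, 1)) {
    px <- cx + sgn * cfg$canal_x_fracs * wa
    P <- cbind(px, 0, cfg$canal_z_fracs * L[3])
    path <- bezier3(P, seq(0, 1, length.out = 200))
    path[, 2] <- y_c(path[, 1])
    canal_d2 <- pmin(canal_d2, tube_distance_sq(path, n, sp))
  }
  r <- cfg$canal_radius_mm
  lumen <- canal_d2 <= r^2
  rim <- canal_d2 <= (r + cfg$rim_thickness_mm)^2 & !lumen

  if (any((lumen | rim) & !mandible))
    stop("canal tube exits the mandible; adjust canal_radius_mm/",
         "rim_thickness_mm or the phantom shape")

  # compose intensities
  vol <- array(ii$air, n)
  vol[head] <- ii$soft_tissue
  shell_mm <- 0.8
  interior <- morph_mask(mandible, "erode", shell_mm, sp)
  vol[mandible] <- ii$cortical
  vol[interior] <- ii$trabecular
  max_int <- morph_mask(maxilla, "erode", shell_mm, sp)
  vol[maxilla] <- ii$cortical
  vol[max_int] <- ii$trabecular
  vol[teeth & Z <= z_body1] <- ii$dentin
  vol[teeth & Z > z_body1] <- ii$tooth
  vol[rim] <- ii$canal_rim
  vol[lumen] <- ii$canal_lumen

  if (cfg$noise_sigma > 0) {
    vol <- vol + with_phantom_seed(cfg$seed, {
      array(stats::rnorm(length(vol), 0, cfg$noise_sigma), n)
    })
  }

  structure(list(
    volume = volume(vol, sp),
    canal_mask = binary_mask(lumen, sp),
    mandible_mask = binary_mask(mandible, sp),
    teeth_mask = binary_mask(teeth, sp),
    maxilla_mask = binary_mask(maxilla, sp),
    config = cfg
  ), class = "phantom_sample")
}

# Run expr under a temporary RNG state derived from seed, restoring the
# caller's RNG afterwards.
with_phantom_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Render a clinician-style tracing overlay for one axial slice
#'
#' Produces the fixture consumed by [extract_canal_mask_from_tracing()]: the
#' grayscale cross-section with every canal pixel replaced by a flat trace
#' color, as clinical tracing exports store it.
#'
#' @param sample a `phantom_sample`.
#' @param slice_index 1-based axial (z) slice index.
#' @param trace_color RGB triple in \code{[0, 1]}; must not be pure gray.
#' @return `(nx, ny, 3)` numeric array in \code{[0, 1]}.
#' @export
render_tracing_overlay <- function(sample, slice_index,
                                   trace_color = c(1, 0, 0)) {
  nz <- dim(sample$volume$data)[3]
  if (slice_index < 1 || slice_index > nz)
    stop("slice_index out of range [1, ", nz, "]")
  if (length(unique(trace_color)) == 1L)
    stop("trace_color must not be a pure gray so it is separable from ",
         "the grayscale background")
  sl <- sample$volume$data[, , slice_index]
  rng <- range(sample$volume$data)
  g <- (sl - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
  img <- array(rep(g, 3), c(dim(sl), 3))
  cm <- sample$canal_mask$data[, , slice_index]
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[cm] <- trace_color[ch]
    img[, , ch] <- plane
  }
  img
}

#' Subsample the dense canal mask into sparse slice annotations
#'
#' Emulates clinician tracing at a fixed physical interval: axial slices
#' spaced `round(interval_mm / slice_spacing)` voxels apart are retained,
#' starting at the first canal-containing slice.
#'
#' @param sample a `phantom_sample`.
#' @param interval_mm annotation interval in mm (>= slice spacing).
#' @return A `sparse_annotation`: list with `entries` (each
#'   `list(slice_index, mask)`), `slice_spacing_mm`, `annotation_interval_mm`.
#' @export
sparse_annotation <- function(sample, interval_mm = 1.0) {
  sz <- sample$volume$spacing[3]
  if (interval_mm < sz)
    stop("annotation interval (", interval_mm,
         " mm) must be >= slice spacing (", sz, " mm)")
  step <- max(1L, as.integer(round(interval_mm / sz)))
  has <- which(apply(sample$canal_mask$data, 3, any))
  if (length(has) == 0) stop("phantom has no canal voxels to annotate")
  idx <- seq(min(has), max(has), by = step)
  # the last visible canal section is always traced
  if (idx[length(idx)] != max(has)) idx <- c(idx, max(has))
  entries <- lapply(idx, function(k)
    list(slice_index = k, mask = sample$canal_mask$data[, , k]))
  structure(list(entries = entries, slice_spacing_mm = sz,
                 annotation_interval_mm = interval_mm,
                 spacing = sample$volume$spacing,
                 shape = dim(sample$canal_mask$data)),
            class = "sparse_annotation")
}
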