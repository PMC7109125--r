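# Seeded evaluation helper shared across the package: run expr under a
# temporary RNG state, restoring the caller's afterwards.
with_seed <- function(seed, expr) with_phantom_seed(seed, expr)

#' Median-frequency class weights
#'
#' Class balancing for extremely rare foregrounds: the frequency of class c
#' is `pixel_counts[c] / (presence_counts[c] * image_pixel_count)` (pixels of
#' c over pixels of all images in which c appears), and its weight is
#' `median(freq) / freq[c]`, so rare classes are upweighted. For two classes
#' the median is the mean of the two frequencies.
#'
#' @param pixel_counts named vector of per-class pixel totals (> 0).
#' @param presence_counts named vector: number of images containing each
#'   class (> 0).
#' @param image_pixel_count pixels per image.
#' @return A `class_weights` object: positive `weights` (same names) and
#'   `method = "median_frequency"`.
#' @export
median_frequency_weights <- function(pixel_counts, presence_counts,
                                     image_pixel_count) {
  if (!identical(sort(names(pixel_counts)), sort(names(presence_counts))))
    stop("pixel_counts and presence_counts must name the same classes")
  presence_counts <- presence_counts[names(pixel_counts)]
  if (any(presence_counts <= 0))
    stop("zero presence count for class: ",
         paste(names(presence_counts)[presence_counts <= 0], collapse = ", "))
  if (any(pixel_counts <= 0) || image_pixel_count <= 0)
    stop("pixel counts and image_pixel_count must be positive")
  freq <- pixel_counts / (presence_counts * image_pixel_count)
  w <- stats::median(freq) / freq
  structure(list(weights = w, method = "median_frequency"),
            class = "class_weights")
}

#' Manually specified class weights
#'
#' @param weights named positive vector, e.g.
#'   `c(background = 5.3, canal = 1000)`, the operating point used by the
#'   benchmark study for all networks.
#' @return A `class_weights` object.
#' @export
manual_weights <- function(weights) {
  if (any(weights <= 0)) stop("class weights must be positive")
  structure(list(weights = weights, method = "manual"),
            class = "class_weights")
}

#' Weighted binary cross-entropy for canal segmentation
#'
#' Mean over voxels of `-(w_canal * t * log(p) + w_bg * (1 - t) *
#' log(1 - p))`, with probabilities clipped to `[eps, 1 - eps]`.
#'
#' @param pred_prob per-voxel predicted probability of the canal class.
#' @param target [binary_mask()] or logical array of the same shape.
#' @param weights a `class_weights` with entries `background` and `canal`
#'   (unit weights reduce to the ordinary binary cross-entropy).
#' @param eps clipping floor.
#' @return Scalar loss.
#' @export
weighted_bce <- function(pred_prob,
                         target,
                         weights = manual_weights(c(background = 1,
                                                    canal = 1)),
                         eps = 1e-7) {
  p <- as.array(pred_prob)
  t_ <- mask_data(target)
  if (!identical(dim(p), dim(t_)))
    stop("prediction and target shapes differ")
  p <- pmin(pmax(p, eps), 1 - eps)
  w <- weights$weights
  mean(-(w[["canal"]] * t_ * log(p) + w[["background"]] * (1 - t_) *
           log(1 - p)))
}
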