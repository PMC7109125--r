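#' Confusion counts for binary canal segmentation
#'
#' The canal is the positive class.
#'
#' @param pred,truth [binary_mask()] objects or logical arrays of identical
#'   shape.
#' @return A `confusion_counts` list with `TP`, `FP`, `FN`, `TN` summing to
#'   the number of voxels.
#' @export
confusion_counts <- function(pred, truth) {
  p <- mask_data(pred); t_ <- mask_data(truth)
  if (!identical(dim(p), dim(t_)))
    stop("prediction and truth shapes differ: ",
         paste(dim(p), collapse = "x"), " vs ", paste(dim(t_), collapse = "x"))
  structure(list(TP = sum(p & t_), FP = sum(p & !t_),
                 FN = sum(!p & t_), TN = sum(!p & !t_)),
            class = "confusion_counts")
}

#' Segmentation metrics in the printed and the standard formulation
#'
#' Computes canal/background pixel accuracy, global accuracy, class accuracy
#' (the mean of the two pixel accuracies) and IoU (with mean IoU the mean of
#' the two) from confusion counts. Two variants are first-class:
#'
#' * `"printed"` follows the benchmark publication's typeset formulas
#'   verbatim: pixel accuracy of the canal is `TP/(TP+FP)` (a precision
#'   form), of the background `TN/(TN+FN)`; IoU of the canal is
#'   `TP/(FN+TP+TN)` and of the background `TN/(FP+TN+TP)` (denominators
#'   that include the true negatives of the other class). These are needed
#'   to reproduce that paper's arithmetic exactly.
#' * `"standard"` uses the community definitions: pixel accuracy as recall
#'   (`TP/(TP+FN)`, `TN/(TN+FP)`) and IoU as `TP/(TP+FP+FN)`,
#'   `TN/(TN+FN+FP)`.
#'
#' Global and class accuracy are identical across variants. A metric whose
#' denominator is zero is reported as `NA`, never silently 0.
#'
#' @param c a `confusion_counts` object (or list with TP/FP/FN/TN).
#' @param variant `"printed"` (default) or `"standard"`.
#' @return A `metrics_report` list: `pixel_acc_canal`,
#'   `pixel_acc_background`, `global_acc`, `class_acc`, `iou_canal`,
#'   `iou_background`, `mean_iou`, `variant`, and the raw counts.
#' @export
compute_metrics <- function(c, variant = c("printed", "standard")) {
  variant <- match.arg(variant)
  TP <- c$TP; FP <- c$FP; FN <- c$FN; TN <- c$TN
  if (any(c(TP, FP, FN, TN) < 0)) stop("confusion counts must be >= 0")
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  if (variant == "printed") {
    pa_c <- frac(TP, TP + FP)
    pa_b <- frac(TN, TN + FN)
    iou_c <- frac(TP, FN + TP + TN)
    iou_b <- frac(TN, FP + TN + TP)
  } else {
    pa_c <- frac(TP, TP + FN)
    pa_b <- frac(TN, TN + FP)
    iou_c <- frac(TP, TP + FP + FN)
    iou_b <- frac(TN, TN + FN + FP)
  }
  structure(list(
    pixel_acc_canal = pa_c,
    pixel_acc_background = pa_b,
    global_acc = frac(TP + TN, TP + TN + FP + FN),
    class_acc = mean(c(pa_c, pa_b)),
    iou_canal = iou_c,
    iou_background = iou_b,
    mean_iou = mean(c(iou_c, iou_b)),
    variant = variant,
    counts = list(TP = TP, FP = FP, FN = FN, TN = TN)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("segmentation metrics (%s variant)\n", x$variant))
  for (f in c("pixel_acc_canal", "pixel_acc_background", "global_acc",
              "class_acc", "iou_canal", "iou_background", "mean_iou"))
    cat(sprintf("  %-21s %s\n", f,
                ifelse(is.na(x[[f]]), "undefined", sprintf("%.5f", x[[f]]))))
  invisible(x)
}

#' Evaluate a predicted segmentation against ground truth
#'
#' Composition of [confusion_counts()] and [compute_metrics()]; both metric
#' variants are reported side by side, plus a flat row suitable for CSV
#' output.
#'
#' @param pred,truth aligned [binary_mask()] objects or logical arrays.
#' @return List with `printed` and `standard` `metrics_report`s, the raw
#'   `counts`, and `row` (a one-row data.frame of every metric in both
#'   variants plus counts).
#' @export
evaluate_run <- function(pred, truth) {
  cc <- confusion_counts(pred, truth)
  pr <- compute_metrics(cc, "printed")
  st <- compute_metrics(cc, "standard")
  fields <- c("pixel_acc_canal", "pixel_acc_background", "global_acc",
              "class_acc", "iou_canal", "iou_background", "mean_iou")
  row <- data.frame(c(stats::setNames(lapply(fields, function(f) pr[[f]]),
                                      paste0(fields, "_printed")),
                      stats::setNames(lapply(fields, function(f) st[[f]]),
                                      paste0(fields, "_standard")),
                      cc[c("TP", "FP", "FN", "TN")]))
  list(printed = pr, standard = st, counts = cc, row = row)
}

#' Published CBCT canal-segmentation benchmark metrics
#'
#' Test-set metrics reported by the benchmark study of encoder-decoder
#' networks for mandibular canal segmentation on 102 clinical CBCT scans
#' (background/canal pixel accuracy, global accuracy, class accuracy and
#' mean IoU per network). Bundled so that internal arithmetic
#' (class accuracy as the mean of the per-class accuracies; the relative
#' mean-IoU gain of the 3D network) can be recomputed without the private
#' clinical data.
#'
#' @return data.frame with columns `network`, `pretrained`,
#'   `original_filters`, `acc_background`, `acc_canal`, `global_acc`,
#'   `class_acc`, `mean_iou`.
#' @export
benchmark_results <- function() {
  data.frame(
    network = c("segnet2d", "unet2d", "unet2d", "unet2d",
                "unet2d_adjacent", "unet3d"),
    pretrained = c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE),
    original_filters = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
    acc_background = c(0.96265, 0.76764, 0.91744, 0.83897, 0.82013, 0.99972),
    acc_canal = c(0.84278, 0.50470, 0.26388, 0.42008, 0.54608, 0.92738),
    global_acc = c(0.96254, 0.76741, 0.91686, 0.83859, 0.81988, 0.99922),
    class_acc = c(0.90271, 0.63617, 0.59066, 0.62953, 0.68310, 0.95915),
    mean_iou = c(0.49116, 0.38462, 0.45984, 0.42043, 0.41125, 0.57721),
    stringsAsFactors = FALSE
  )
}
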