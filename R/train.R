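#' Training configuration
#'
#' Optimization is Adam throughout. Two learning-rate decay semantics are
#' supported, matching the protocols used for the 2D and 3D networks: a
#' multiplicative per-epoch decay `lr / (1 + decay * epoch)` (the 2D
#' protocol: SegNet at lr 0.01 / decay 0.005, U-Net at lr 1e-4 / decay 5e-4,
#' beta1 0.9), and a step schedule dividing the rate by `factor` every
#' `period` epochs (the 3D protocol: lr 5e-4 divided by 5 after 5 epochs);
#' when a step schedule is supplied it takes precedence.
#'
#' @param learning_rate initial Adam learning rate (> 0).
#' @param decay multiplicative per-epoch decay coefficient.
#' @param momentum_beta1 Adam first-moment coefficient (the protocol's
#'   "momentum 0.9"; Adam has no classical momentum term).
#' @param epochs number of epochs (>= 0).
#' @param batch_size samples per optimization step.
#' @param seed RNG seed covering shuffling and dropout.
#' @param schedule optional `list(factor =, period =)` step decay.
#' @param class_weights a `class_weights` for the weighted binary
#'   cross-entropy loss.
#' @param max_steps optional cap on total optimization steps.
#' @return A `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, decay = 0,
                         momentum_beta1 = 0.9, epochs = 1L, batch_size = 8L,
                         seed = 0L, schedule = NULL,
                         class_weights = manual_weights(c(background = 1,
                                                          canal = 1)),
                         max_steps = NULL) {
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (epochs < 0) stop("epochs must be >= 0")
  structure(list(learning_rate = learning_rate, decay = decay,
                 momentum_beta1 = momentum_beta1, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 schedule = schedule, class_weights = class_weights,
                 max_steps = max_steps),
            class = "train_config")
}

# learning rate in force during a given 1-based epoch
epoch_lr <- function(cfg, epoch) {
  if (!is.null(cfg$schedule))
    cfg$learning_rate / cfg$schedule$factor^((epoch - 1) %/%
                                               cfg$schedule$period)
  else cfg$learning_rate / (1 + cfg$decay * (epoch - 1))
}

#' 3D patch sampling specification
#'
#' @param count number of patches (the volumetric protocol draws 64).
#' @param size cubic patch edge length in voxels (132 in that protocol).
#' @return A `patch_spec`.
#' @export
patch_spec <- function(count = 64L, size = 132L) {
  if (count < 1) stop("count must be >= 1")
  structure(list(count = as.integer(count), size = as.integer(size)),
            class = "patch_spec")
}

#' Randomly sample 3D patches from a volume
#'
#' Corner positions are uniform over the valid range (so a volume exactly
#' patch-sized yields the unique patch `count` times) and seed-reproducible.
#' When `valid_margin > 0` the mask patch is center-cropped by that many
#' voxels per side, matching the output region of a valid-padding network.
#'
#' @param vol a [volume()].
#' @param mask aligned [binary_mask()].
#' @param spec a [patch_spec()].
#' @param seed RNG seed.
#' @param valid_margin voxels to trim from each side of the mask patch.
#' @return List of `list(x, y, corner)`; `corner` is the 0-based corner.
#' @export
sample_patches <- function(vol, mask, spec, seed = 0L, valid_margin = 0L) {
  d <- dim(vol$data)
  p <- spec$size
  if (any(d < p))
    stop("volume (", paste(d, collapse = "x"),
         ") is smaller than the patch size ", p)
  corners <- with_seed(seed, {
    vapply(1:3, function(a) sample.int(d[a] - p + 1L, spec$count,
                                       replace = TRUE) - 1L,
           integer(spec$count))
  })
  corners <- matrix(corners, ncol = 3)
  lapply(seq_len(spec$count), function(i) {
    lo <- corners[i, ]
    x <- vol$data[lo[1] + 1:p, lo[2] + 1:p, lo[3] + 1:p, drop = FALSE]
    y <- mask_data(mask)[lo[1] + 1:p, lo[2] + 1:p, lo[3] + 1:p,
                         drop = FALSE]
    if (valid_margin > 0) {
      keep <- (valid_margin + 1):(p - valid_margin)
      y <- y[keep, keep, keep, drop = FALSE]
    }
    list(x = x, y = y, corner = lo)
  })
}

#' Train a segmentation model
#'
#' Runs weighted binary cross-entropy optimization with Adam over a list of
#' samples, recording the mean loss per epoch and honoring the configured
#' learning-rate schedule. With a validation set, the parameters achieving
#' the best validation loss are restored at the end (best-on-validation
#' checkpoint selection). Zero epochs leave the parameters untouched. A
#' non-finite loss aborts with a diagnostic.
#'
#' @param model a `canalseg_model` from [build_model()].
#' @param data list of samples `list(x = input array, y = target mask)`;
#'   inputs must carry a trailing channel dimension.
#' @param cfg a [train_config()].
#' @param valid optional validation samples in the same format.
#' @return List: `model` (trained), `history` (data.frame epoch /
#'   train_loss / valid_loss / lr), `steps`.
#' @export
train_model <- function(model, data, cfg, valid = NULL) {
  stopifnot(inherits(model, "canalseg_model"), inherits(cfg, "train_config"))
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        valid_loss = numeric(), lr = numeric())
  if (cfg$epochs == 0)
    return(list(model = model, history = history, steps = 0L))
  n <- length(data)
  steps <- 0L
  best_val <- Inf; best_snap <- NULL
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      lr <- epoch_lr(cfg, epoch)
      ord <- sample.int(n)
      losses <- c()
      for (b in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
        if (!is.null(cfg$max_steps) && steps >= cfg$max_steps) break
        xs <- lapply(data[b], `[[`, "x")
        ys <- lapply(data[b], function(s) crop_target(s$y, model))
        zero_grads(model)
        fw <- net_forward(model, xs, train = TRUE)
        lg <- batch_loss_grad(fw$vals[[model$out]], ys, cfg$class_weights)
        if (!is.finite(lg$loss))
          stop("non-finite training loss at step ", steps + 1,
               " (epoch ", epoch, "); lower the learning rate")
        net_backward(model, fw, lg$dscores)
        adam_step(model, lr, beta1 = cfg$momentum_beta1)
        losses <- c(losses, lg$loss)
        steps <- steps + 1L
      }
      vloss <- NA_real_
      if (!is.null(valid)) {
        vloss <- eval_loss(model, valid, cfg$class_weights)
        if (vloss < best_val) {
          best_val <- vloss
          best_snap <- param_snapshot(model)
        }
      }
      history <- rbind(history,
                       data.frame(epoch = epoch,
                                  train_loss = mean(losses),
                                  valid_loss = vloss, lr = lr))
      if (!is.null(cfg$max_steps) && steps >= cfg$max_steps) break
    }
  })
  if (!is.null(best_snap)) param_restore(model, best_snap)
  list(model = model, history = history, steps = steps)
}

# crop a target mask to the model's output region (valid-padding networks)
crop_target <- function(y, model) {
  y <- mask_data(y)
  nd <- model$nd
  insz <- dim(y)[seq_len(nd)]
  outsz <- model$output_size
  if (all(insz == outsz)) return(y)
  off <- (insz - outsz) %/% 2
  idx <- lapply(seq_len(nd), function(a) off[a] + seq_len(outsz[a]))
  if (nd == 2) y[idx[[1]], idx[[2]]] else y[idx[[1]], idx[[2]], idx[[3]]]
}

eval_loss <- function(model, samples, w) {
  tot <- 0
  for (s in samples) {
    fw <- net_forward(model, list(s$x), train = FALSE)
    p <- scores_to_prob(fw$vals[[model$out]][[1]])
    tot <- tot + weighted_bce(p, crop_target(s$y, model), w)
  }
  tot / length(samples)
}

#' Canal IoU of a model over a set of samples
#'
#' Convenience wrapper: predicts each sample, thresholds the canal
#' probability at 0.5, accumulates confusion counts and returns the
#' standard-variant canal IoU.
#'
#' @param model trained `canalseg_model`.
#' @param samples list of `list(x, y)` samples.
#' @return Scalar IoU (TP / (TP + FP + FN)).
#' @export
model_canal_iou <- function(model, samples) {
  TP <- FP <- FN <- 0
  for (s in samples) {
    p <- predict_canal_prob(model, s$x) >= 0.5
    t_ <- crop_target(s$y, model)
    TP <- TP + sum(p & t_); FP <- FP + sum(p & !t_); FN <- FN + sum(!p & t_)
  }
  if (TP + FP + FN == 0) return(NA_real_)
  TP / (TP + FP + FN)
}

#' Build a 2D training set from phantom slices
#'
#' Extracts the canal-containing axial slices of a phantom, crops a fixed
#' square window centered on the canal's centroid (clamped to the volume),
#' and min-max normalizes intensities, yielding samples ready for
#' [train_model()] with a 2D network.
#'
#' @param sample a `phantom_sample` from [generate_phantom()].
#' @param size window edge length in voxels (must suit the network's
#'   pooling depth).
#' @return List of `list(x = size x size x 1 array, y = logical mask)`.
#' @export
phantom_slice_dataset <- function(sample, size = 64L) {
  vol <- sample$volume$data
  msk <- sample$canal_mask$data
  d <- dim(vol)
  if (any(d[1:2] < size))
    stop("phantom axial extent smaller than the window size")
  ctr <- colMeans(which(msk, arr.ind = TRUE))[1:2]
  lo <- pmin(pmax(round(ctr - size / 2), 1), d[1:2] - size + 1L)
  ix <- lo[1]:(lo[1] + size - 1L); iy <- lo[2]:(lo[2] + size - 1L)
  # keep slices whose canal intersects the window, so every sample carries
  # foreground signal
  keep <- which(apply(msk[ix, iy, , drop = FALSE], 3, any))
  rng <- range(vol)
  norm <- (vol - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
  lapply(keep, function(z)
    list(x = array(norm[ix, iy, z], c(size, size, 1L)),
         y = msk[ix, iy, z], slice = z))
}
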