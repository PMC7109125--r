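#' Encoder channel plans for U-Net variants
#'
#' @param base filters at the first stage (64 for the original plan, 32 for
#'   the "fewer filters" variant, small values for desk-scale tests).
#' @param depth number of pooling stages.
#' @return Integer vector of length `depth + 1` (encoder stages + bottleneck).
#' @export
unet_filters <- function(base = 64, depth = 4) base * 2^(0:depth)

#' VGG-style channel plan for the SegNet encoder
#'
#' Thirteen convolution layers with pooling after layers 2, 4, 7, 10 and 13.
#'
#' @param base filters at the first stage (64 for the original plan).
#' @return Integer vector of length 13.
#' @export
segnet_filters <- function(base = 64)
  base * c(1, 1, 2, 2, 4, 4, 4, 8, 8, 8, 8, 8, 8)

#' Declarative description of a segmentation architecture
#'
#' Three families are supported. `segnet2d` is a VGG-style 13-layer encoder
#' with batch normalization and max pooling whose argmax indices drive a
#' mirrored, non-learned decoder upsampling. `unet2d` is the 4-down/4-up
#' encoder-decoder in its zero-padded form: 'same' padding in every
#' convolution and no cropping before skip concatenation, so the output
#' resolution equals the input (the variant suited to a tiny target partially
#' lying at the image edge). `unet3d` is the volumetric counterpart (3D
#' convolutions, 3D max pooling, 3D up-convolutions) with three pooling
#' stages, channel doubling before each pool, batch normalization, no
#' dropout, and valid padding as in its original formulation, which entails
#' center-cropping skip connections.
#'
#' @param family `"segnet2d"`, `"unet2d"` or `"unet3d"`.
#' @param filters channel plan: [unet_filters()] for U-Nets (for `unet3d`
#'   the entries are the first-conv widths per level), [segnet_filters()]
#'   for SegNet. `NULL` selects the family's original plan.
#' @param input_channels 1, or `2 * a + 1` for adjacent-slice input feeding
#'   `a` neighboring slices per side through the shared 2D network.
#' @param input_size spatial input edge length used for the layer-shape
#'   report (256 for 2D, 132 for 3D by default).
#' @param batch_norm add batch normalization after every convolution.
#'   Always on for `segnet2d` and `unet3d`; optional for `unet2d` (off in
#'   the reference 2D U-Net, but a stabilizer worth enabling for small-batch
#'   desk-scale training).
#' @param dropout add dropout (p = 0.5) at the bottleneck (`unet2d` only).
#' @param pretrained_encoder optional path to an RDS file of encoder weights
#'   for [load_encoder_weights()]; no download is ever performed.
#' @return A `model_spec` with all invariants resolved (`segnet2d` forces
#'   batch norm; `unet3d` forces valid padding, batch norm and no dropout;
#'   `unet2d` uses same padding).
#' @export
model_spec <- function(family = c("unet2d", "segnet2d", "unet3d"),
                       filters = NULL, input_channels = 1L,
                       input_size = NULL, batch_norm = NULL,
                       dropout = FALSE, pretrained_encoder = NULL) {
  family <- match.arg(family)
  if (is.null(filters))
    filters <- switch(family, unet2d = unet_filters(64),
                      segnet2d = segnet_filters(64),
                      unet3d = unet_filters(32, 3)[1:3])
  if (family == "segnet2d" && length(filters) != 13L)
    stop("segnet2d needs a 13-layer channel plan (see segnet_filters())")
  if (is.null(input_size))
    input_size <- if (family == "unet3d") 132L else 256L
  structure(list(
    family = family, filters = as.integer(filters),
    input_channels = as.integer(input_channels),
    input_size = as.integer(input_size),
    padding = if (family == "unet3d") "valid" else "same",
    batch_norm = if (family %in% c("segnet2d", "unet3d")) TRUE
    else isTRUE(batch_norm),
    dropout = if (family == "unet3d") FALSE else isTRUE(dropout),
    pretrained_encoder = pretrained_encoder
  ), class = "model_spec")
}

# --- tape builder shared machinery -----------------------------------------
new_tape <- function(nd, input_size, input_channels) {
  env <- new.env()
  env$ops <- list(); env$layers <- list()
  env$desc <- list()
  env$nd <- nd
  env$cur <- "input"; env$size <- rep(input_size, nd)
  env$ch <- input_channels
  env$sizes <- list(input = rep(input_size, nd))
  env
}

tp_add <- function(tp, op, out, size, ch, nparams = 0) {
  op$out <- out
  tp$ops[[length(tp$ops) + 1]] <- op
  if (!is.null(op$layer)) tp$layers[[op$name]] <- op$layer
  tp$desc[[length(tp$desc) + 1]] <-
    data.frame(name = if (is.null(op$name)) op$type else op$name,
               type = op$type,
               out_size = paste(size, collapse = "x"),
               channels = ch, params = nparams)
  tp$cur <- out; tp$size <- size; tp$ch <- ch
  tp$sizes[[out]] <- size
  length(tp$ops)
}

tp_conv <- function(tp, name, cout, k = 3, pad_mode = "same") {
  pad <- if (pad_mode == "same") (k - 1) %/% 2 else 0L
  newsize <- tp$size + 2 * pad - k + 1
  if (any(newsize < 1))
    stop("layer ", name, ": input size ", paste(tp$size, collapse = "x"),
         " incompatible with valid padding (kernel ", k, ")")
  lay <- new_conv(k, tp$ch, cout, pad, tp$nd)
  tp_add(tp, list(type = "conv", inp = tp$cur, layer = lay, name = name),
         name, newsize, cout, k^tp$nd * tp$ch * cout + cout)
}

tp_bn <- function(tp, name) {
  lay <- new_bn(tp$ch)
  tp_add(tp, list(type = "bn", inp = tp$cur, layer = lay, name = name),
         name, tp$size, tp$ch, 2 * tp$ch)
}

tp_relu <- function(tp, name) {
  tp_add(tp, list(type = "relu", inp = tp$cur), name, tp$size, tp$ch)
}

tp_pool <- function(tp, name) {
  if (any(tp$size %% 2 != 0))
    stop("layer ", name, ": cannot 2x-pool odd spatial size ",
         paste(tp$size, collapse = "x"))
  tp_add(tp, list(type = "pool", inp = tp$cur), name, tp$size %/% 2, tp$ch)
}

tp_unpool <- function(tp, name, pool_id) {
  pool_in <- tp$ops[[pool_id]]$inp
  tp_add(tp, list(type = "unpool", inp = tp$cur, pool_id = pool_id),
         name, tp$sizes[[pool_in]], tp$ch)
}

tp_upconv <- function(tp, name, cout) {
  lay <- new_upconv(tp$ch, cout, tp$nd)
  tp_add(tp, list(type = "upconv", inp = tp$cur, layer = lay, name = name),
         name, tp$size * 2, cout, 2^tp$nd * tp$ch * cout + cout)
}

tp_concat <- function(tp, name, skip, skip_ch) {
  tp_add(tp, list(type = "concat", inp = c(tp$cur, skip)),
         name, tp$size, tp$ch + skip_ch)
}

tp_dropout <- function(tp, name, p) {
  tp_add(tp, list(type = "dropout", inp = tp$cur, p = p), name, tp$size,
         tp$ch)
}

conv_block <- function(tp, name, cout, pad_mode, bn) {
  tp_conv(tp, name, cout, 3, pad_mode)
  if (bn) tp_bn(tp, paste0(name, "_bn"))
  tp_relu(tp, paste0(name, "_relu"))
}

# --- family builders --------------------------------------------------------
build_unet <- function(spec, nd) {
  f <- spec$filters
  # 2D plans list encoder stages plus the bottleneck; 3D plans list the
  # first-conv width of each level (the bottleneck doubles the last level)
  depth <- if (nd == 2) length(f) - 1 else length(f)
  tp <- new_tape(nd, spec$input_size, spec$input_channels)
  skips <- character(depth); skip_ch <- integer(depth)
  for (i in seq_len(depth)) {
    if (nd == 2) {
      conv_block(tp, sprintf("enc%d_conv1", i), f[i], spec$padding,
                 spec$batch_norm)
      conv_block(tp, sprintf("enc%d_conv2", i), f[i], spec$padding,
                 spec$batch_norm)
    } else {  # channel doubling before pooling
      conv_block(tp, sprintf("enc%d_conv1", i), f[i], spec$padding,
                 spec$batch_norm)
      conv_block(tp, sprintf("enc%d_conv2", i), 2 * f[i], spec$padding,
                 spec$batch_norm)
    }
    skips[i] <- tp$cur; skip_ch[i] <- tp$ch
    tp_pool(tp, sprintf("pool%d", i))
  }
  if (nd == 2) {
    conv_block(tp, "bottom_conv1", f[depth + 1], spec$padding,
               spec$batch_norm)
    conv_block(tp, "bottom_conv2", f[depth + 1], spec$padding,
               spec$batch_norm)
  } else {
    conv_block(tp, "bottom_conv1", tp$ch, spec$padding, spec$batch_norm)
    conv_block(tp, "bottom_conv2", 2 * tp$ch, spec$padding, spec$batch_norm)
  }
  if (spec$dropout) tp_dropout(tp, "bottom_dropout", 0.5)
  for (i in rev(seq_len(depth))) {
    tp_upconv(tp, sprintf("dec%d_up", i),
              if (nd == 2) skip_ch[i] else tp$ch)
    tp_concat(tp, sprintf("dec%d_concat", i), skips[i], skip_ch[i])
    conv_block(tp, sprintf("dec%d_conv1", i), skip_ch[i], spec$padding,
               spec$batch_norm)
    conv_block(tp, sprintf("dec%d_conv2", i), skip_ch[i], spec$padding,
               spec$batch_norm)
  }
  tp_conv(tp, "classifier", 2L, 1, "same")
  tp
}

build_segnet <- function(spec) {
  f <- spec$filters
  stages <- list(1:2, 3:4, 5:7, 8:10, 11:13)
  tp <- new_tape(2, spec$input_size, spec$input_channels)
  pool_ids <- integer(5)
  for (s in seq_along(stages)) {
    for (j in stages[[s]])
      conv_block(tp, sprintf("enc%d", j), f[j], "same", TRUE)
    pool_ids[s] <- tp_pool(tp, sprintf("pool%d", s))
  }
  for (s in rev(seq_along(stages))) {
    tp_unpool(tp, sprintf("unpool%d", s), pool_ids[s])
    idx <- rev(stages[[s]])
    prev_ch <- if (s == 1) f[1] else f[stages[[s - 1]][length(stages[[s - 1]])]]
    for (k in seq_along(idx)) {
      cout <- if (k == length(idx)) prev_ch else f[idx[k]]
      conv_block(tp, sprintf("dec%d", idx[k]), cout, "same", TRUE)
    }
  }
  tp_conv(tp, "classifier", 2L, 1, "same")
  tp
}

#' Build a segmentation network from a specification
#'
#' Instantiates the trainable model (weights He-initialized from `seed`) and
#' a per-layer description reporting every layer's output spatial size and
#' parameter count — for valid-padding networks this is the shape recurrence
#' that determines, e.g., the 44-cube output of a 132-cube 3D input. An
#' input size incompatible with the architecture (a valid-padding
#' convolution underflowing, or an odd size reaching a pooling stage) raises
#' an error naming the first failing layer.
#'
#' @param spec a [model_spec()].
#' @param seed RNG seed for weight initialization.
#' @return A `canalseg_model`: `spec`, `ops`, `layers`, `description`
#'   (data.frame), `output_size`, `n_params`. Feed it to [train_model()] and
#'   [predict_canal_prob()].
#' @export
build_model <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "model_spec"))
  tp <- with_seed(seed, {
    switch(spec$family,
           unet2d = build_unet(spec, 2),
           unet3d = build_unet(spec, 3),
           segnet2d = build_segnet(spec))
  })
  desc <- do.call(rbind, tp$desc)
  model <- structure(list(spec = spec, ops = tp$ops, layers = tp$layers,
                          out = tp$cur, nd = tp$nd, description = desc,
                          output_size = tp$size,
                          n_params = sum(desc$params)),
                     class = "canalseg_model")
  if (!is.null(spec$pretrained_encoder))
    model <- load_encoder_weights(model, spec$pretrained_encoder)
  model
}

#' @export
print.canalseg_model <- function(x, ...) {
  cat(sprintf("%s: %d layers, %s parameters, input %s^%d -> output %s\n",
              x$spec$family, nrow(x$description),
              format(x$n_params, big.mark = ","), x$spec$input_size, x$nd,
              paste(x$output_size, collapse = "x")))
  invisible(x)
}

#' Load external encoder weights into a model
#'
#' Hook for transfer learning from externally supplied weights: reads an RDS
#' file holding a named list of parameter arrays (`<layer>.W`, `<layer>.b`,
#' ...) and copies every entry whose name and dimensions match a model
#' layer. The package never downloads weights; all bundled tests run from
#' random initialization.
#'
#' @param model a `canalseg_model`.
#' @param path RDS file path.
#' @return The model, with matching weights replaced.
#' @export
load_encoder_weights <- function(model, path) {
  if (!file.exists(path)) stop("weight file not found: ", path)
  w <- readRDS(path)
  if (!is.list(w) || is.null(names(w)))
    stop("weight file must hold a named list of arrays")
  for (nm in names(w)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    lay <- model$layers[[parts[1]]]
    if (is.null(lay) || !(parts[2] %in% lay$param_names)) next
    cur <- lay[[parts[2]]]
    if (!identical(dim(as.array(cur)), dim(as.array(w[[nm]]))))
      stop("dimension mismatch for ", nm)
    lay[[parts[2]]] <- w[[nm]]
  }
  model
}
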