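# Shared phantom fixtures, generated once per test run.
.fixtures <- new.env()

default_phantom <- function() {
  if (is.null(.fixtures$default))
    .fixtures$default <- generate_phantom(phantom_config())
  .fixtures$default
}

clean_phantom <- function() {
  if (is.null(.fixtures$clean))
    .fixtures$clean <- generate_phantom(phantom_config(noise_sigma = 0))
  .fixtures$clean
}

# steep-canal 0.2 mm phantom for annotation-densification checks: the
# clinical tracing protocol annotates sections perpendicular to the canal,
# which on the canonical slice axis corresponds to a canal crossing axial
# slices transversally
densify_phantom_config <- function() {
  phantom_config(shape = c(160, 160, 480), spacing_mm = 0.2,
                 canal_radius_mm = 1.0, rim_thickness_mm = 0.3,
                 noise_sigma = 0,
                 canal_z_fracs = c(0.50, 0.39, 0.27, 0.16),
                 canal_x_fracs = c(0.84, 0.70, 0.56, 0.45))
}

densify_phantom <- function() {
  if (is.null(.fixtures$densify))
    .fixtures$densify <- generate_phantom(densify_phantom_config())
  .fixtures$densify
}

# desk-scale learning protocol shared by the smoke tests: train a tiny
# batch-normalized U-Net for 200 seeded steps on the canal-window slices of
# one phantom, evaluate canal IoU on a second phantom with an independent
# noise realization
smoke_model <- function(seed) {
  build_model(model_spec("unet2d", filters = unet_filters(8, 3),
                         input_size = 64, batch_norm = TRUE), seed = seed)
}

smoke_train_config <- function(seed, steps = 200) {
  train_config(learning_rate = 2e-3, epochs = 100,
               batch_size = 4, seed = seed,
               class_weights = manual_weights(c(background = 1, canal = 8)),
               max_steps = steps)
}

smoke_run <- function(seed, rim_mm) {
  tr <- generate_phantom(phantom_config(rim_thickness_mm = rim_mm,
                                        seed = seed))
  te <- generate_phantom(phantom_config(rim_thickness_mm = rim_mm,
                                        seed = seed + 500L))
  fit <- train_model(smoke_model(seed), phantom_slice_dataset(tr, 64),
                     smoke_train_config(seed))
  list(iou = model_canal_iou(fit$model, phantom_slice_dataset(te, 64)),
       history = fit$history$train_loss, steps = fit$steps)
}
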