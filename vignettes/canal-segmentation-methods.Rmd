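---
title: "Methods: automatic mandibular canal segmentation in CBCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automatic mandibular canal segmentation in CBCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The inferior alveolar nerve (IAN) runs through the mandibular canal, a
bony channel inside the lower jaw. Locating it precisely on cone-beam CT
(CBCT) is a prerequisite for implant planning, third-molar extraction and
orthognathic surgery, because nerve injury causes lasting numbness. CBCT,
unlike medical CT, is not Hounsfield-calibrated and is noisy; the canal
itself is a thin, low-intensity tube whose only reliable signature is the
thin cortical (high-intensity) rim that sheathes it. It occupies a minute
fraction of the volume, so any learning approach faces extreme class
imbalance.

`canalseg` implements the full workflow around this problem:

1. **volume I/O** — NIfTI and single-series DICOM input, half-resolution
   downsampling, cropping;
2. **automatic mandible ROI** — a panorama-based multi-level Otsu +
   morphology pipeline that strips the maxilla and confines training
   volumes to the mandible;
3. **ground-truth densification** — clinician tracings drawn every 1 mm
   are restored to the native slice interval by cubic interpolation;
4. **training core** — SegNet-style and U-Net-style 2D networks and a
   valid-padding 3D U-Net, with median-frequency class balancing and
   weighted binary cross-entropy, trainable at desk scale on the CPU;
5. **evaluation** — confusion-count metrics in two formulations (see
   below);
6. **phantom** — a seeded synthetic CBCT generator that provides analytic
   ground truth for all of the above, since clinical datasets of this kind
   are private.

## The synthetic phantom: what it emulates and what it does not

`phantom_config()` / `generate_phantom()` build a volume containing a
U-shaped mandible — a parabolic arch band (slope-corrected so its
perpendicular thickness is constant) extruded over a body height, with two
posterior rami — plus a cortical shell around a trabecular interior, a
canal per side (a tube around a cubic-Bézier path descending from the
mandibular-foramen analog, dipping, and rising toward the mental-foramen
analog), a row of teeth with dentin roots embedded in the crest and enamel
crowns above it, a separate maxillary arch across an air gap, and additive
Gaussian noise.

Default intensities (arbitrary units): air 0, soft tissue 4, canal lumen
87, trabecular 90, canal rim 150, cortical 160, dentin 200, enamel 255;
noise sigma 4; shape 160×160×128 at 0.4 mm. Two of these choices carry the
science:

* **The lumen sits close to trabecular bone (87 vs 90).** In CBCT the
  canal lumen is near medullary intensity; the cortical rim is the
  feature that makes the canal detectable. With this contrast structure,
  removing the rim (`rim_thickness_mm = 0`) reproduces the clinically
  hard case of an "unclear cortical layer", and a fixed training budget
  measurably degrades — the qualitative behavior reported for all
  networks on clinical data.
* **Teeth are two-part (dentin roots + enamel crowns).** This gives the
  area-limited panorama histograms four well-separated modes (dark,
  cortical bone, dentin, enamel), so all three thresholds of 3-level Otsu
  fall into real inter-tissue gaps: the first threshold separates soft
  tissue from bone and the third separates bone from teeth, which is what
  the ROI pipeline requires of its "bone" and "teeth" binarization
  coefficients. With a single tooth intensity the spare threshold tends to
  fall inside the dark mode and the bone threshold collapses toward air.

What the phantom does **not** emulate: beam hardening, scatter, metal
artifacts, patient anatomy variability, or soft-tissue texture. Passing
phantom tests therefore demonstrates the correctness of the pipeline's
logic and its behavior under the stated geometry and contrast assumptions
— not clinical-grade accuracy.

## Mandible ROI extraction

`extract_mandible_roi()` executes, in order: (A) center third of the
panoramic view — here a maximum-intensity projection along the
anterior-posterior axis, with a `columns` map that ties every panorama
column back to its 3D voxel columns; (B) teeth binarization of (A);
(C) 2D dilation (default 1 mm) and largest connected component — the tooth
arc; (D) the full-width panorama confined to the tooth height (padded by
the dilation radius); (E) bone binarization of (D); (F) the two largest
components of its complement — the buccal corridors; (G) union of
corridors and tooth object; (H) per-column upward extension of (G) — the
maxillary region; (I) 3D bone binarization, removal of each column's
maxillary z-range, 3D closing (default 2 mm) and retention of the largest
component; (J) bounding box, crop, and masking of non-mandible voxels with
the volume minimum (a neutral fill for downstream thresholding).

Design choices where the procedure was genuinely open:

* Thresholds are computed by **area-limited** multi-level Otsu: the teeth
  threshold on (A), the bone threshold on (D). Manual overrides replace
  both, for the inaccurate-segmentation fallback.
* The panorama is an axial-axis MIP rather than a curved dental-arch
  reformation; the `columns` abstraction would let a curved projection be
  swapped in without touching the rest of the pipeline.
* Step (D) uses the full-width panorama (not the center third), because
  the lateral corridors needed by (F) do not exist in the center third.
* The maxilla cut (H→I) is per panorama column (the weakest assumption
  consistent with a 2D-to-3D mapping); columns with no (G) content take
  the cut of the nearest defined column.
* After closing, only the largest 3D component is kept — the same
  largest-object logic steps (C) and (F) use — so threshold-noise specks
  cannot inflate the bounding box.
* Ties between equal-sized components are broken by raster order of each
  component's first voxel, making the whole pipeline deterministic.

Morphology uses ball/disk structuring elements of per-axis radius
`round(radius_mm / spacing)` voxels, realized through an exact Euclidean
distance transform (so anisotropic voxels are handled correctly); 3-level
Otsu is an exhaustive maximization of between-class variance over a
256-bin histogram of min-max-normalized intensities — exact, not a
heuristic, because CBCT units are scanner-arbitrary and the thresholds
drive everything downstream.

## Annotation densification

Clinical ground truth is traced on cross-sections at 1 mm intervals and
restored to the native 0.2 mm interval by cubic interpolation.
`densify_annotation()` treats the sparse masks as a {0,1}-valued field and
interpolates each in-plane position along the slice axis with a natural
cubic spline (linear in the data, so the whole volume is one matrix
product with a precomputed operator), clamps to [0, 1] to suppress cubic
overshoot, and thresholds at 0.5 (symmetric; configurable). Annotated
slices are reproduced exactly because the interpolant passes through its
knots; nothing can appear outside the union of annotated in-plane
footprints or outside the annotated slice range.

One geometric caveat governs the tests: clinical tracings are drawn on
sections roughly *perpendicular* to the canal, so consecutive annotated
sections see nearly congruent cross-sections. Mapped onto the canonical
axial slice axis, that regime corresponds to a canal crossing slices
transversally. The densification accuracy test therefore uses a phantom
configuration with a steep, z-monotone canal (`canal_z_fracs =
c(0.50, 0.39, 0.27, 0.16)`) in a tall 0.2 mm volume: 1 mm tracings
densify to Dice ≈ 0.96 against the analytic tube, degrading monotonically
as the interval grows to 2 and 3 mm. Near-horizontal canal segments (the
anatomical dip of the default profile) are intrinsically ill-posed for
slice-axis interpolation — axial slices are tangent to the tube there —
which is why the default profile is kept for everything except this test.

## Networks and training

`build_model()` instantiates three families from a declarative
`model_spec()`:

* **segnet2d** — 13 VGG-style encoder convolutions (plan
  64,64,128,128,256,256,256,512,512,512,512,512,512), batch norm
  everywhere, 2×2 max pooling with stored argmax indices, and a mirrored
  decoder that upsamples *by those indices* (no learned upsampling),
  ending in a 1×1 classifier.
* **unet2d** — the 4-down/4-up encoder-decoder in its zero-padded form:
  'same' padding and no cropping before skip concatenation, so 256×256
  input gives 256×256 output. Rationale: the canal is tiny and often lies
  near the image edge, where valid-padding erosion of the field of view
  costs exactly the voxels that matter. Channel plans: original
  (64…1024), "fewer filters" (32…512), or any `unet_filters(base,
  depth)`. Batch norm is off by default (as in the reference 2D U-Net)
  but available as a flag.
* **unet3d** — the volumetric counterpart with three pooling stages,
  channel doubling before each pool (32/64 → 64/128 → 128/256, bottleneck
  256/512), batch norm, no dropout, and valid padding as in its original
  formulation — hence center-cropped skips and the 132³ → 44³
  input-output relation the per-layer report reproduces. Training volumes
  are fed as randomly sampled 132³ patches (`sample_patches()`, 64 per
  volume), with mask patches optionally cropped to the valid output
  region.

Parameter counts of the default configurations (31.0M for unet2d, 29.5M
for segnet2d, 19.1M for unet3d) match the well-known totals of the
reference architectures, which serves as an independent check on the
builders.

The engine itself is a compact tape of forward/backward ops (im2col-based
convolutions through BLAS, hand-derived gradients, Adam); it is verified
against numerical differentiation in the test suite. "Momentum 0.9" in
the 2D protocol is interpreted as Adam's first-moment coefficient β₁ —
Adam has no classical momentum term. The learning-rate "decay" of the 2D
protocol is applied as `lr / (1 + decay · epoch)`; the 3D protocol's step
schedule divides the rate by `factor` every `period` epochs (5e-4 → 1e-4
after 5 epochs at factor 5, period 5). `train_model()` supports
best-on-validation checkpoint selection and aborts on non-finite loss.

**Class balancing.** `median_frequency_weights()` implements
median-frequency balancing: `freq(c) = pixels(c) / (images-containing(c) ·
pixels-per-image)`, `weight(c) = median(freq)/freq(c)` (for two classes
the median is their mean). A background:canal frequency ratio of 1000:5.3
yields weights in the ratio 5.3:1000 — the operating point used on the
clinical data, with the small number attached to the abundant background
class, since median-frequency balancing by construction upweights the
rare class.

**Desk-scale smoke configuration.** The learning check trains a tiny
unet2d (filters 8-16-32-64, batch norm on, input 64×64 crops centered on
the canal) for 200 Adam steps (lr 2e-3, batch 4) with class weights
background:canal = 1:8, on the canal-window slices of one phantom, and
scores standard canal IoU on a second phantom generated with an
independent noise seed. The deliberate choices: *batch norm*, because
without it a 200-step small-batch run collapses to all-background on
some seeds — incidentally reproducing the zero-convergence failure mode
reported for the plain 2D U-Net on clinical data; *crops*, because
centering 64×64 windows on the canal reduces the class imbalance from
~0.1% to ~3%; *the 1:8 weight*, because at this short budget the
unweighted loss still collapses while the full median-frequency weight
(~16) grossly over-segments at the 0.5 decision threshold; and
*phantom-level hold-out* rather than a within-phantom slice split,
because with only ~38 canal-bearing slices a random split can place all
of a morphologically unique canal region (the near-tangent dip, the
foramen entries) in the held-out set, turning the check into a lottery
over slice assignment — a second phantom keeps every morphology in
training while the evaluation data remain unseen. Its limitation is
stated openly: the held-out phantom differs only in its noise
realization, not in anatomy, so the check measures noise-robust
generalization of a learned geometry, not cross-patient generalization.
Under this protocol the clear-rim phantom reaches IoU far above 0.3
across seeds and the rim-free phantom scores consistently and
substantially lower — the direction, not the magnitude, being the claim.

## Evaluation metrics: printed vs standard

The benchmark publication typesets its metrics as

* pixel accuracy of canal = TP/(TP+FP) — a *precision* form;
* pixel accuracy of background = TN/(TN+FN);
* global accuracy = (TP+TN)/total;
* class accuracy = mean of the two pixel accuracies;
* IoU of canal = TP/(FN+TP+TN) — a denominator that *includes the true
  negatives* and excludes FP;
* mean IoU = mean of the two IoUs.

`compute_metrics()` implements these verbatim as the `"printed"` variant —
required to reproduce that paper's arithmetic (e.g. its class-accuracy
rows recompute exactly as the mean of the per-class accuracies, and the
relative mean-IoU gain of the 3D network over SegNet is 17.5%, printed as
"about 18%") — and the community-standard definitions (recall-form pixel
accuracies, IoU = TP/(TP+FP+FN)) as the `"standard"` variant for external
comparability. Every report is stamped with its variant; zero-denominator
metrics are reported as `NA`, never as silent zeros. One known
inconsistency is left as-is: the published 3D U-Net class-accuracy value
does not equal the mean of its per-class accuracies under either variant,
so consistency is asserted only for the 2D rows.

## Numerical and interface choices

* Bounding boxes are 0-based and half-open, so crops compose without
  off-by-one ambiguity; `downsample_half()` uses `ceiling(n/2)` so a
  trailing odd slice is never discarded (545×900×400 → 273×450×200), with
  linear interpolation for intensities and nearest-neighbor for masks.
* Intensities stay floating point end to end; only histograms quantize
  (256 bins on the min-max-normalized scale).
* DICOM support covers uncompressed explicit-VR little-endian series —
  the common CBCT console export — with slices sorted by
  ImagePositionPatient and consistency checks that name the offending
  attribute; NIfTI is the canonical on-disk form for everything else,
  masks as uint8.
* All randomness (phantom noise, splits, patch corners, weight
  initialization, shuffling, dropout) flows from explicit integer seeds,
  and the command-line runs record seed, configuration and input
  checksums in a manifest, making phantom and split outputs byte-identical
  across reruns.
* The transfer-learning hook (`load_encoder_weights()`) copies named,
  dimension-checked arrays from an RDS file; the package never downloads
  weights and all bundled tests run from random initialization.

## Problem sizes used in the bundled checks

The bundled tests and the acceptance script run entirely on synthetic
data at sizes chosen for a single CPU: the default 160×160×128 phantom for
the ROI pipeline, the tall 160×160×480 0.2 mm phantom for densification,
and 200-step trainings of the small U-Net for the learning checks. These
sizes are part of the package's stated desk-scale protocol; the network
builders themselves instantiate the full-scale architectures
(256×256 2D inputs, 132³ 3D patches) and report their exact layer shapes.

## Known limitations

* The phantom's geometry is parametric, not atlas-based; it validates
  logic, not clinical accuracy.
* Slice-axis densification cannot represent near-horizontal canal
  segments faithfully (see above); a cross-section-frame or
  centerline-based mode is out of scope.
* The ROI panorama is an MIP, not a curved-arch reformation.
* 2D training at full clinical scale (tens of thousands of slices, 600
  epochs) is far outside CPU budgets; the training core is exercised at
  desk scale and its components (shapes, gradients, schedules, balancing)
  are verified exactly.
* No surface-distance metrics (none are part of the benchmark's
  evaluation).
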