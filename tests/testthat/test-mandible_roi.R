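# independent brute-force maximizer of between-class variance over an
# explicit histogram, used as the oracle for multi_otsu
otsu_oracle <- function(h, k) {
  bins <- seq_along(h) - 1
  total_mean <- sum(h * bins) / sum(h)
  score <- function(cuts) {
    edges <- c(-1, cuts, length(h))
    s <- 0
    for (i in seq_len(length(edges) - 1)) {
      sel <- bins > edges[i] & bins <= edges[i + 1]
      w <- sum(h[sel])
      if (w > 0) s <- s + w * (sum(h[sel] * bins[sel]) / w - total_mean)^2
    }
    s
  }
  best <- NULL; best_s <- -Inf
  combs <- utils::combn(0:(length(h) - 2), k)
  for (j in seq_len(ncol(combs))) {
    s <- score(combs[, j])
    if (s > best_s) { best_s <- s; best <- combs[, j] }
  }
  best
}

test_that("multi_otsu matches exhaustive between-class-variance search", {
  # trimodal synthetic histogram, modes near 30/120/220
  set.seed(21)
  x <- c(rnorm(3000, 30, 6), rnorm(2000, 120, 8), rnorm(800, 220, 5))
  x <- pmin(pmax(x, 0), 255)
  th <- multi_otsu(matrix(x, ncol = 100), n_levels = 2, bins = 64)
  rng <- range(x)
  q <- pmin(floor((x - rng[1]) / (rng[2] - rng[1]) * 64), 63)
  h <- tabulate(q + 1, nbins = 64)
  oracle_bins <- otsu_oracle(h, 2)
  got_bins <- round((th$levels - rng[1]) / (rng[2] - rng[1]) * 64) - 1
  expect_equal(got_bins, oracle_bins)

  # random histograms, three levels
  for (i in 1:3) {
    set.seed(30 + i)
    h <- rpois(32, lambda = sample(5:50, 32, replace = TRUE))
    h[h == 0] <- 1
    got <- canalseg:::cpp_multiotsu(as.numeric(h), 3)
    expect_equal(as.integer(got), as.integer(otsu_oracle(h, 3)))
  }
})

test_that("multi_otsu separates a bimodal image with one threshold", {
  x <- c(rep(10, 60), rep(200, 40))
  th <- multi_otsu(matrix(x, 10, 10), n_levels = 1)
  expect_gt(th$levels[1], 10)
  expect_lt(th$levels[1], 200)
  expect_error(multi_otsu(matrix(5, 4, 4)), "degenerate")
})

test_that("panorama is the per-column maximum projection with z rows", {
  v <- volume(array(0, c(7, 6, 5)))
  p0 <- reconstruct_panorama(v)
  expect_true(all(p0$image == 0))
  expect_equal(nrow(p0$image), 5)   # rows = nz
  expect_equal(ncol(p0$image), 7)   # cols = nx

  v$data[3, 4, 2] <- 9
  p <- reconstruct_panorama(v)
  expect_equal(which(p$image == 9, arr.ind = TRUE)[1, ], c(row = 2, col = 3))
  expect_equal(sum(p$image > 0), 1)
})

test_that("center third keeps columns [floor(W/3), floor(2W/3))", {
  mk <- function(W) {
    v <- volume(array(seq_len(W * 2 * 3), c(W, 2, 3)))
    reconstruct_panorama(v)
  }
  expect_equal(center_third(mk(9))$columns, 4:6)    # 0-based 3..5
  expect_equal(center_third(mk(10))$columns, 4:6)   # floor convention
  v2 <- volume(array(1, c(2, 2, 2)))
  expect_error(center_third(reconstruct_panorama(v2)), ">= 3")
})

test_that("largest_components ranks by size with deterministic tie-breaks", {
  m <- array(FALSE, c(30, 30, 3))
  m[1:10, 1:10, 1] <- TRUE            # 100 voxels
  m[20:29, 1:5, 1:3] <- TRUE          # 150 voxels
  m[15, 20:29, 1] <- TRUE             # 10 voxels
  top2 <- largest_components(m, 2)
  expect_equal(sum(top2), 250)
  expect_true(all(top2[1:10, 1:10, 1]))
  expect_false(any(top2[15, 20:29, 1]))

  single <- largest_components(m[, , 1, drop = FALSE], 1)
  expect_equal(sum(single), 100)      # the slab is only 50 voxels per slice
  expect_equal(sum(largest_components(m, 5)), sum(m))  # k clamps

  # equal sizes: the component whose first voxel comes first in raster
  # order wins
  t2 <- matrix(FALSE, 10, 10)
  t2[2, 2] <- TRUE; t2[5, 5] <- TRUE
  keep <- largest_components(t2, 1)
  expect_true(keep[2, 2]); expect_false(keep[5, 5])

  expect_warning(largest_components(matrix(FALSE, 3, 3), 1), "empty")
})

test_that("morphology follows the ball structuring-element contract", {
  # brute-force dilation oracle on a small 2D mask
  dilate_oracle <- function(m, r) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    offs <- expand.grid(dx = -r:r, dy = -r:r)
    offs <- offs[offs$dx^2 + offs$dy^2 <= r^2, ]
    w <- which(m, arr.ind = TRUE)
    for (k in seq_len(nrow(offs))) {
      i <- w[, 1] + offs$dx[k]; j <- w[, 2] + offs$dy[k]
      ok <- i >= 1 & i <= nrow(m) & j >= 1 & j <= ncol(m)
      out[cbind(i[ok], j[ok])] <- TRUE
    }
    out
  }
  set.seed(9)
  m <- matrix(runif(21 * 17) > 0.9, 21, 17)
  expect_equal(morph(m, "dilate", 3, spacing_mm = c(1, 1)),
               dilate_oracle(m, 3))

  # closing a digital ball with a smaller ball is the identity
  d <- c(31, 31, 31)
  co <- as.matrix(expand.grid(1:31, 1:31, 1:31))
  ball <- array(colSums((t(co) - 16)^2) <= 36, d)
  expect_identical(morph(ball, "close", 2, spacing_mm = c(1, 1, 1)), ball)
  opened <- morph(morph(ball, "dilate", 2, spacing_mm = c(1, 1, 1)),
                  "erode", 2, spacing_mm = c(1, 1, 1))
  expect_true(all(ball <= opened))

  # closing fills a hole smaller than the element
  hole <- matrix(TRUE, 15, 15); hole[8, 8] <- FALSE
  expect_true(all(morph(hole, "close", 2, spacing_mm = c(1, 1))))

  expect_identical(morph(morph(ball, "complement"), "complement"), ball)
})

test_that("ROI extraction fails informatively on degenerate volumes", {
  air <- volume(array(rnorm(50^3, 0, 0.1), c(50, 50, 50)), c(1, 1, 1))
  expect_error(extract_mandible_roi(air, overrides = list(bone = 50,
                                                          teeth = 100)),
               "teeth|bone")
})

test_that("manual threshold overrides bypass Otsu and reproduce the run", {
  s <- default_phantom()
  auto <- extract_mandible_roi(s$volume)
  manual <- extract_mandible_roi(s$volume,
                                 overrides = list(bone = auto$thresholds$bone,
                                                  teeth = auto$thresholds$teeth))
  expect_equal(manual$box$lo, auto$box$lo)
  expect_equal(manual$box$hi, auto$box$hi)
  expect_identical(manual$mandible_mask$data, auto$mandible_mask$data)

  # deterministic: identical input, identical result
  again <- extract_mandible_roi(s$volume)
  expect_identical(again$mandible_mask$data, auto$mandible_mask$data)

  # a deliberately different threshold pair changes the segmentation
  shifted <- extract_mandible_roi(s$volume,
                                  overrides = list(bone = 120, teeth = 220))
  expect_false(identical(shifted$mandible_mask$data,
                         auto$mandible_mask$data))
})

test_that("the cropped ROI masks out non-mandible voxels with the volume minimum", {
  s <- default_phantom()
  roi <- extract_mandible_roi(s$volume)
  inmask <- crop_volume(binary_mask(roi$mandible_mask$data,
                                    s$volume$spacing), roi$box)
  expect_equal(dim(roi$cropped$data), as.integer(roi$box$hi - roi$box$lo))
  expect_true(all(roi$cropped$data[!inmask$data] == min(s$volume$data)))
})
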