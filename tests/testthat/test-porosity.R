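test_that("crop_valid honors the indexing contract and rejects bad ROIs", {
  sc <- cached_scene("intact")
  stk <- sc$stk
  d <- dim(stk$intensities)
  full <- roi(rows = c(1, d[1]), cols = c(1, d[2]),
              depths = range(slice_depths(stk)))
  expect_identical(crop_valid(stk, full)$intensities, stk$intensities)

  sub <- crop_valid(stk, roi(rows = c(51, 150), cols = c(51, 150),
                             depths = c(100, 110)))
  expect_equal(dim(sub$intensities)[1:2], c(100L, 100L))
  expect_equal(sub$intensities[1, 1, 1],
               stk$intensities[51, 51, which(slice_depths(stk) == 100)])
  expect_equal(sub$depth_origin, 100)

  expect_error(crop_valid(stk, roi(rows = c(1, 9999), cols = c(1, 10),
                                   depths = c(100, 110))),
               class = "tb_invalid_roi")
  expect_error(crop_valid(stk, roi(rows = c(1, 10), cols = c(1, 10),
                                   depths = c(5000, 6000))),
               class = "tb_invalid_roi")
})

test_that("enhance is a monotone stretch onto [0, 1] and rejects flat images", {
  set.seed(1)
  img <- matrix(runif(4000, 10, 500), 50, 80)
  out <- enhance(img)
  expect_true(all(out >= 0 & out <= 1))
  q <- quantile(img, c(0.01, 0.99))
  mid <- img > q[1] & img < q[2]
  expect_identical(order(img[mid]), order(out[mid]))
  expect_error(enhance(matrix(7, 5, 5)), class = "tb_degenerate_image")
})

test_that("histogram threshold maximizes between-class variance (brute-force oracle)", {
  set.seed(42)
  for (i in 1:5) {
    img <- matrix(c(rnorm(600, 0.25, 0.05), rnorm(400, 0.75, 0.08)), 40, 25)
    expect_equal(histogram_threshold(img), brute_force_otsu(img),
                 tolerance = 1e-12)
  }
  # two-delta histogram: threshold separates the classes
  img2 <- matrix(rep(c(0.2, 0.8), each = 50), 10, 10)
  thr <- histogram_threshold(img2)
  expect_gt(thr, 0.2); expect_lt(thr, 0.8)
  expect_error(histogram_threshold(matrix(1, 4, 4)),
               class = "tb_degenerate_image")
})

test_that("histogram threshold agrees with an independent Otsu implementation", {
  set.seed(7)
  img <- matrix(c(rbeta(1500, 2, 8), rbeta(1500, 8, 2)), 50, 60)
  ours <- histogram_threshold(img)
  # EBImage discretizes the same criterion; agree to within one bin width
  ref <- EBImage::otsu(img, range = range(img), levels = 256)
  expect_lt(abs(ours - ref), (max(img) - min(img)) / 256 + 1e-12)
})

test_that("segment_pores uses a strict below-threshold convention", {
  img <- matrix(seq(0, 1, length.out = 25), 5, 5)
  expect_true(all(segment_pores(img, 2)))
  expect_false(any(segment_pores(img, 0)))
  expect_equal(sum(segment_pores(img, 0.5)), sum(img < 0.5))
})

test_that("a binary checkerboard has porosity exactly one half", {
  cb <- outer(1:16, 1:16, function(i, j) (i + j) %% 2)
  stk <- image_stack(array(cb, c(16, 16, 1)), lateral_pitch = 2,
                     axial_step = 5, depth_origin = 0)
  pp <- porosity_profile(stk, roi(rows = c(1, 16), cols = c(1, 16),
                                  depths = c(0, 0)))
  expect_equal(pp$porosity, 0.5)
  expect_equal(pp$pore_pixels / pp$valid_pixels, pp$porosity)
})

test_that("porosity is invariant to monotone rescaling when classes are separated", {
  # nonlinear monotone maps move the Otsu cut within the histogram; the pore
  # count is unchanged (to re-quantization) as long as the inter-class valley
  # is empty, which a noise-free render guarantees
  cfg <- small_scene_config(seed = 21L, psf_sigma = c(0, 0))
  stk <- render_intensities(build_labels(cfg), cfg, noise = FALSE)
  r <- cfg$tm_roi
  p0 <- porosity_profile(stk, r)$porosity
  for (f in list(function(x) 3 * x + 100, function(x) sqrt(x + 1),
                 function(x) (x / 100)^1.5)) {
    stk2 <- stk
    stk2$intensities <- f(stk$intensities)
    expect_equal(porosity_profile(stk2, r)$porosity, p0, tolerance = 0.01)
  }
  # affine maps additionally leave the noisy estimate unchanged up to binning
  cfg2 <- small_scene_config(seed = 21L)
  stkn <- render_intensities(build_labels(cfg2), cfg2)
  pn <- porosity_profile(stkn, r)$porosity
  stkn2 <- stkn
  stkn2$intensities <- 3 * stkn$intensities + 100
  expect_equal(porosity_profile(stkn2, r)$porosity, pn, tolerance = 0.01)
})

test_that("inverting the image complements the pore fraction", {
  cfg <- small_scene_config(seed = 31L)
  stk <- render_intensities(build_labels(cfg), cfg)
  cropped <- crop_valid(stk, cfg$tm_roi)
  sl <- enhance(cropped$intensities[, , 3])
  thr <- histogram_threshold(sl)
  p <- mean(segment_pores(sl, thr))
  inv <- 1 - sl
  thr_inv <- histogram_threshold(inv)
  p_inv_tissue <- mean(inv > thr_inv)   # inverted pore convention
  expect_equal(p_inv_tissue, p, tolerance = 0.02)
})

test_that("estimated porosity matches ground truth within 0.01 on noise-free renders", {
  cfg <- small_scene_config(psf_sigma = c(0, 0))
  lab <- build_labels(cfg)
  stk <- render_intensities(lab, cfg, noise = FALSE)
  est <- porosity_profile(stk, cfg$tm_roi)
  gt <- label_pore_fraction(lab)
  expect_equal(est$depth_um, gt$depth_um)
  expect_lt(max(abs(est$porosity - gt$pore_fraction)), 0.01)
})

test_that("estimated porosity tracks the target within 0.03 on noisy default presets", {
  for (preset in c("intact", "broken")) {
    sc <- cached_scene(preset)
    est <- porosity_profile(sc$stk, default_tm_roi(sc$cfg))
    target <- stats::approx(sc$cfg$porosity_knots$depth_um,
                            sc$cfg$porosity_knots$porosity,
                            xout = est$depth_um, rule = 2)$y
    expect_lt(max(abs(est$porosity - target)), 0.03,
              label = sprintf("max |estimated - target| (%s)", preset))
  }
})

test_that("degenerate slices are reported as failed entries, not dropped silently", {
  x <- array(runif(16 * 16 * 3, 0.2, 0.9), c(16, 16, 3))
  x[, , 2] <- 0.5  # constant slice
  stk <- image_stack(x, 2, 5, 0)
  pp <- porosity_profile(stk, roi(rows = c(1, 16), cols = c(1, 16),
                                  depths = c(0, 10)))
  expect_equal(nrow(pp), 2)
  f <- attr(pp, "failed")
  expect_equal(f$depth_um, 5)
  expect_match(f$reason, "constant")
})
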