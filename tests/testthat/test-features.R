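test_that("ROI rectangles are filled from the original image", {
  ct <- ct_slice(matrix(seq_len(100), 10, 10))
  m <- matrix(FALSE, 10, 10)
  m[3:6, 4:8] <- TRUE
  roi <- roi_from_mask(m)
  patch <- fill_roi_rectangle(ct, roi)
  expect_equal(patch, ct$pixels[3:6, 4:8])          # mask equals its box
  expect_equal(dim(patch), c(roi$bbox[3] - roi$bbox[1],
                             roi$bbox[4] - roi$bbox[2]))

  # circular mask: box corners keep the original image values
  mc <- matrix(FALSE, 10, 10)
  for (r in 1:10) for (c in 1:10) mc[r, c] <- (r - 5)^2 + (c - 5)^2 <= 6
  roic <- roi_from_mask(mc)
  pc <- fill_roi_rectangle(ct, roic)
  expect_false(mc[roic$bbox[1], roic$bbox[2]])       # corner outside mask
  expect_equal(pc[1, 1], ct$pixels[roic$bbox[1], roic$bbox[2]])

  bad <- roi_from_mask(m); bad$bbox <- c(3, 4, 3, 8)
  expect_error(fill_roi_rectangle(ct, bad), "degenerate")
})

test_that("co-occurrence matrices enumerate intensity pairs", {
  g0 <- compute_glcm(matrix(5, 4, 4), levels = 8)
  expect_equal(g0$g[1, 1], 1)                        # constant: single cell
  expect_equal(sum(g0$g), 1)

  checker <- outer(1:4, 1:4, function(r, c) (r + c) %% 2)
  gc <- compute_glcm(checker, levels = 2, angles = 0)
  expect_equal(gc$g, matrix(c(0, 0.5, 0.5, 0), 2, 2))

  stripes <- matrix(rep(c(0, 1), each = 1, times = 8), 4, 4)  # rows alternate
  gs <- compute_glcm(stripes, levels = 2, angles = 0)          # horizontal
  expect_equal(sum(diag(gs$g)), 1)                   # all mass on diagonal
})

test_that("texture features match their closed forms on tiny matrices", {
  # point mass
  f0 <- texture_features(compute_glcm(matrix(5, 4, 4), levels = 8))
  expect_equal(f0$energy, 1)
  expect_equal(f0$contrast, 0)
  expect_equal(f0$entropy, 0)
  expect_equal(f0$homogeneity, 1)
  expect_false(f0$correlation_defined)
  expect_equal(f0$correlation, 0)

  # checkerboard: G = [[0, .5], [.5, 0]]
  checker <- outer(1:4, 1:4, function(r, c) (r + c) %% 2)
  fc <- texture_features(compute_glcm(checker, levels = 2, angles = 0))
  expect_equal(fc$contrast, 1)
  expect_equal(fc$energy, 0.5)
  expect_equal(fc$entropy, 1)
  expect_equal(fc$homogeneity, 0.5)
  expect_equal(fc$correlation, -1)                   # perfect anti-correlation

  # horizontal stripes: diagonal GLCM, perfect correlation, zero contrast
  stripes <- matrix(rep(c(0, 1), times = 8), 4, 4)
  fs <- texture_features(compute_glcm(stripes, levels = 2, angles = 0))
  expect_equal(fs$contrast, 0)
  expect_equal(fs$correlation, 1)
})

test_that("GLCM and features match the naive double-loop oracle", {
  set.seed(55)
  for (i in 1:10) {
    patch <- matrix(stats::runif(64, -200, 400), 8, 8)
    g <- compute_glcm(patch)
    expect_equal(g$g, glcm_oracle(patch), tolerance = 1e-12)
    f <- texture_features(g)
    fo <- texture_oracle(g$g)
    for (k in c("contrast", "correlation", "energy", "homogeneity",
                "entropy")) {
      expect_equal(f[[k]], fo[[k]], tolerance = 1e-10)
    }
    expect_equal(sum(g$g), 1, tolerance = 1e-12)
  }
})

test_that("SUV maps apply the dose-per-weight calibration linearly", {
  p <- pet_slice(matrix(0.0025, 3, 3), dose_mbq = 185, weight_g = 74000)
  expect_equal(suv_image(p)[1, 1], 1.0)

  p2 <- pet_slice(matrix(0.0132, 3, 3), dose_mbq = 370, weight_g = 70000)
  expect_equal(suv_image(p2)[1, 1], 0.0132 / (370 / 70000))
  expect_equal(suv_image(p2)[1, 1], 2.4973, tolerance = 1e-4)

  double <- pet_slice(2 * p$activity, 185, 74000)
  expect_equal(suv_image(double), 2 * suv_image(p))

  expect_error(pet_slice(matrix(1, 2, 2), dose_mbq = 0, weight_g = 100))
})

test_that("feature vectors are deterministic and respect their ranges", {
  p <- fast_params(seed = 7L, malignant_fraction = 1)
  s <- generate_slice(p)
  roi <- roi_from_mask(s$truth$nodule_masks[[1]])
  f1 <- extract_features(s$ct, s$pet, s$truth$misalignment, roi)
  f2 <- extract_features(s$ct, s$pet, s$truth$misalignment, roi)
  expect_identical(f1, f2)
  expect_gt(f1$energy, 0); expect_lte(f1$energy, 1)
  expect_gte(f1$entropy, 0)
  expect_gte(f1$contrast, 0)
  expect_gt(f1$homogeneity, 0); expect_lte(f1$homogeneity, 1)
  expect_gte(f1$correlation, -1); expect_lte(f1$correlation, 1)
  expect_gte(f1$suvmax, f1$suvmean)
})
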