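test_that("PET hot spots become lung-gated candidate markers", {
  p <- fast_params(seed = 5L, malignant_fraction = 1)
  s <- generate_slice(p)
  lung <- segment_lung(s$ct)
  det <- detect_pet_candidates(s$pet, lung, s$truth$misalignment)
  expect_equal(length(det$candidates), 1)
  d <- sqrt((det$markers$row[1] - s$truth$nodules$row)^2 +
              (det$markers$col[1] - s$truth$nodules$col)^2)
  expect_lte(d, 1.5)   # marker at the planted center up to grid rounding
  expect_true(lung$parenchyma[det$markers$row[1], det$markers$col[1]])

  # a cold PET map yields no candidates
  cold <- pet_slice(matrix(0.0025, 64, 64), 185, 74000)   # SUV 1.0 everywhere
  expect_length(detect_pet_candidates(cold, lung,
                                      rigid_transform())$candidates, 0)

  # a hot spot outside the lungs is excluded by the mask intersection
  act <- matrix(0.0025 * 0.4, 64, 64)
  act[32:34, 31:33] <- 0.0025 * 5       # center of the slice: mediastinum
  hot <- pet_slice(act, 185, 74000)
  det2 <- detect_pet_candidates(hot, lung, rigid_transform())
  expect_length(det2$candidates, 0)
})

test_that("the Sobel landscape matches a direct convolution", {
  expect_true(all(gradient_image(matrix(7, 5, 5))$gradient == 0))

  step <- matrix(rep(c(0, 0, 1, 1), each = 4), 4, 4, byrow = TRUE)
  g <- gradient_image(t(step))  # vertical edge between columns 2 and 3
  expect_true(all(g$gradient[, 2:3] > g$gradient[, c(1, 4)]))

  set.seed(23)
  patch <- matrix(stats::runif(25, -50, 400), 5, 5)
  g2 <- gradient_image(patch)$gradient
  pad <- patch[c(1, 1:5, 5), c(1, 1:5, 5)]   # replicate padding
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)   # col derivative
  ky <- t(kx)                                            # row derivative
  for (r in 1:5) for (c in 1:5) {
    win <- pad[r:(r + 2), c:(c + 2)]
    expect_equal(g2[r, c], sqrt(sum(win * ky)^2 + sum(win * kx)^2),
                 tolerance = 1e-10)
  }
})

test_that("flooding builds dams on gradient ridges and plateaus", {
  # ridge column: two basins split at the value-5 wall
  lv <- matrix(rep(c(0, 1, 5, 1, 0), each = 5), 5, 5, byrow = TRUE)
  fl <- flood_from_markers(landscape_from_levels(lv),
                           data.frame(row = c(3, 3), col = c(1, 5),
                                      marker_id = 1:2))
  expect_true(all(fl$labels[, 1:2] == 1))
  expect_true(all(fl$labels[, 4:5] == 2))
  expect_true(all(fl$dam[, 3]))

  # single marker: one basin, no dam
  fl1 <- flood_from_markers(landscape_from_levels(lv),
                            data.frame(row = 3, col = 3, marker_id = 1))
  expect_true(all(fl1$labels == 1))
  expect_false(any(fl1$dam))

  # flat landscape: FIFO growth splits at the equidistant line
  flat <- matrix(0L, 5, 7)
  fl2 <- flood_from_markers(landscape_from_levels(flat),
                            data.frame(row = c(3, 3), col = c(2, 6),
                                       marker_id = 1:2))
  expect_true(all(fl2$labels[, 1:3] == 1))
  expect_true(all(fl2$labels[, 5:7] == 2))
  expect_true(all(fl2$dam[, 4]))

  expect_error(flood_from_markers(landscape_from_levels(flat),
                                  data.frame(row = 99, col = 1,
                                             marker_id = 1)), "outside")
  expect_error(flood_from_markers(landscape_from_levels(flat),
                                  data.frame(row = c(1, 1), col = c(1, 1),
                                             marker_id = 1:2)), "distinct")
})

test_that("flooding matches the brute-force immersion oracle", {
  set.seed(77)
  for (i in 1:80) {
    nr <- sample(3:6, 1); nc <- sample(3:6, 1)
    lv <- matrix(sample(0:2, nr * nc, replace = TRUE), nr, nc)
    pix <- sample(nr * nc, 2)
    mk <- data.frame(row = (pix - 1) %% nr + 1, col = (pix - 1) %/% nr + 1,
                     marker_id = 1:2)
    ls <- landscape_from_levels(lv)
    got <- flood_from_markers(ls, mk)
    want <- flood_oracle(ls, mk)
    expect_identical(got$labels, want$labels)
    expect_identical(got$dam, want$dam)
    # partition: each marker in its own basin; labels and dams disjoint
    expect_equal(got$labels[cbind(mk$row, mk$col)], mk$marker_id)
    expect_false(any(got$dam & got$labels > 0))
  }
})

test_that("level snapshots nest as basin-and-sublevel intersections", {
  # radial cone landscapes: every sublevel set is connected to the marker,
  # so the basin at level n is the final basin within {f <= n}
  for (seed in 1:3) {
    set.seed(seed)
    nr <- 9
    cn <- sample(3:7, 2)
    lv <- outer(seq_len(nr), seq_len(nr), function(r, c)
      pmin(abs(r - cn[1]) + abs(c - cn[2]), 255))
    ls <- landscape_from_levels(lv)
    mk <- data.frame(row = cn[1], col = cn[2], marker_id = 1L)
    fl <- flood_from_markers(ls, mk, record_snapshots = TRUE)
    for (n in c(1, 3, 5, 7)) {
      snap <- fl$snapshots[[as.character(n)]] == 1L
      expect_identical(snap, fl$labels == 1L & ls$levels <= n)
    }
  }
})

test_that("internal dams dissolve, leaving a closed outer boundary", {
  # two interior basins inside a high-gradient rim, plus the background
  lv <- matrix(0L, 11, 11)
  lv[3, 3:9] <- lv[9, 3:9] <- lv[3:9, 3] <- lv[3:9, 9] <- 200L   # rim
  lv[4:8, 6] <- 100L                                             # inner wall
  mk <- data.frame(row = c(6, 6, 1), col = c(4, 8, 1), marker_id = 1:3)
  fl <- flood_from_markers(landscape_from_levels(lv), mk)
  ob <- outer_boundary(fl, interior_ids = c(1, 2))
  # merged region is 4-connected despite the dissolved wall
  lab <- spncad:::label_components(ob$region)
  expect_equal(max(lab), 1)
  # the inner wall's dam pixels are inside the region, not on its boundary
  inner_dam <- fl$dam & ob$region
  expect_true(any(inner_dam[4:8, 5:7]))
  expect_false(any(ob$boundary[5:7, 5:7]))
  # closed curve: every boundary pixel has >= 2 boundary neighbours
  bidx <- which(ob$boundary, arr.ind = TRUE)
  for (k in seq_len(nrow(bidx))) {
    r <- bidx[k, 1]; c <- bidx[k, 2]
    nb <- ob$boundary[max(r - 1, 1):min(r + 1, 11),
                      max(c - 1, 1):min(c + 1, 11)]
    expect_gte(sum(nb) - 1, 2)
  }

  # single basin: boundary is the basin's morphological perimeter
  flat <- flood_from_markers(landscape_from_levels(matrix(0L, 6, 6)),
                             data.frame(row = 3, col = 3, marker_id = 1))
  ob1 <- outer_boundary(flat)
  expect_true(all(ob1$region))
  expect_identical(ob1$boundary,
                   ob1$region & !spncad:::erode_mask(ob1$region))
})

test_that("watershed delineation recovers phantom nodules", {
  p <- fast_params(seed = 21L, malignant_fraction = 1, noise_sd_ct = 0,
                   noise_sd_pet = 0, nodule_radius_range = c(5, 7))
  s <- generate_slice(p)
  lung <- segment_lung(s$ct)
  det <- detect_pet_candidates(s$pet, lung, s$truth$misalignment)
  roi <- segment_nodule(s$ct, det$candidates[[1]], det$markers)
  expect_s3_class(roi, "candidate_roi")
  expect_gte(dice_coefficient(roi$mask, s$truth$nodule_masks[[1]]), 0.85)
  expect_false(roi$low_confidence)
  # tight bounding rectangle
  rows <- range(which(rowSums(roi$mask) > 0))
  cols <- range(which(colSums(roi$mask) > 0))
  expect_equal(roi$bbox, c(rows[1], cols[1], rows[2] + 1, cols[2] + 1))

  # a flat window floods into a single low-confidence basin
  flat_ct <- ct_slice(matrix(0, 64, 64), scan_id = "flat")
  cand <- list(candidate_id = 1L,
               mask = disc_mask <- {
                 m <- matrix(FALSE, 64, 64); m[30:34, 30:34] <- TRUE; m
               },
               bbox = c(30L, 30L, 35L, 35L), suvmax = 5, n_pet_pixels = 9)
  mk <- data.frame(row = 32L, col = 32L, source = "pet-hotspot",
                   marker_id = 1L, candidate_id = 1L)
  roi_flat <- segment_nodule(flat_ct, cand, mk)
  expect_true(roi_flat$low_confidence)
})
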