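#' Rectangle-fill a candidate ROI
#'
#' Returns the ROI's outer bounding rectangle cropped from the original CT
#' image. Pixels outside the (irregular) nodule mask keep their original
#' image values -- filling from the original image rather than with a mean
#' or median constant, which reduces the error introduced by segmentation
#' imperfections into the co-occurrence statistics.
#'
#' @param ct a [ct_slice()]
#' @param roi a `candidate_roi` from [segment_nodule()] (its `bbox` is
#'   half-open: `(row0, col0, row1, col1)`)
#' @return numeric matrix of dimension `(row1 - row0, col1 - col0)`
#' @export
fill_roi_rectangle <- function(ct, roi) {
  stopifnot(inherits(ct, "ct_slice"))
  bb <- roi$bbox
  if (bb[3] <= bb[1] || bb[4] <= bb[2]) stop("degenerate zero-area rectangle")
  stopifnot(bb[1] >= 1, bb[2] >= 1,
            bb[3] - 1 <= nrow(ct$pixels), bb[4] - 1 <= ncol(ct$pixels))
  ct$pixels[bb[1]:(bb[3] - 1L), bb[2]:(bb[4] - 1L), drop = FALSE]
}

# angle (degrees) -> (drow, dcol) co-occurrence offset at unit distance
glcm_offset <- function(angle, distance) {
  switch(as.character(angle),
         "0" = c(0L, distance),
         "45" = c(-distance, distance),
         "90" = c(-distance, 0L),
         "135" = c(-distance, -distance),
         stop("unsupported GLCM angle: ", angle))
}

#' Gray-level co-occurrence matrix of a patch
#'
#' The patch is quantized to `levels` equal-width bins over its min-max
#' range (a constant patch collapses to a single level, putting all mass
#' at cell (1,1)). Pair counts are accumulated for each requested angle at
#' the given pixel distance, added in both directions when `symmetric`,
#' summed over angles (equal-weight averaging) and normalized to sum 1.
#'
#' @param patch numeric matrix
#' @param levels number of gray levels (>= 2)
#' @param distance offset length in pixels
#' @param angles subset of `c(0, 45, 90, 135)` degrees
#' @param symmetric accumulate both pair directions (default TRUE)
#' @return an object of class `glcm`: `g` (normalized levels x levels
#'   matrix), `levels`, `distance`, `angles`, `symmetric`
#' @export
compute_glcm <- function(patch, levels = 16L, distance = 1L,
                         angles = c(0, 45, 90, 135), symmetric = TRUE) {
  stopifnot(is.matrix(patch), levels >= 2, distance >= 1,
            max(dim(patch)) > distance)
  lo <- min(patch); hi <- max(patch)
  q <- if (hi > lo) {
    matrix(pmin(floor((patch - lo) / (hi - lo) * levels), levels - 1L),
           nrow(patch), ncol(patch))
  } else matrix(0L, nrow(patch), ncol(patch))
  nr <- nrow(q); nc <- ncol(q)
  counts <- matrix(0, levels, levels)
  for (ang in angles) {
    off <- glcm_offset(ang, distance)
    r <- seq_len(nr); c <- seq_len(nc)
    rv <- r[r + off[1] >= 1 & r + off[1] <= nr]
    cv <- c[c + off[2] >= 1 & c + off[2] <= nc]
    if (length(rv) == 0 || length(cv) == 0) next
    a <- q[rv, cv, drop = FALSE]
    b <- q[rv + off[1], cv + off[2], drop = FALSE]
    tab <- matrix(tabulate(a * levels + b + 1L, nbins = levels * levels),
                  levels, levels, byrow = TRUE)
    counts <- counts + tab
    if (symmetric) counts <- counts + t(tab)
  }
  if (sum(counts) == 0) stop("no co-occurring pairs at the given offset")
  structure(list(g = counts / sum(counts), levels = levels,
                 distance = distance, angles = angles, symmetric = symmetric),
            class = "glcm")
}

#' Haralick-style texture features of a GLCM
#'
#' With `G(i, j)` the normalized co-occurrence matrix over gray levels
#' `0..k-1`:
#' contrast `CON = sum n^2 * sum_{|i-j|=n} G(i,j)`;
#' correlation `COR = (sum ij G(i,j) - u_i u_j) / (s_i s_j)` with marginal
#' means/sds `u_i, u_j, s_i, s_j`;
#' energy `ASM = sum G(i,j)^2`;
#' homogeneity `HOM = sum G(i,j) / (1 + |i - j|)`;
#' entropy `ENT = -sum G log2 G` (0 log 0 = 0, bits).
#' When a marginal is degenerate (constant gray level), correlation is
#' undefined and reported as 0 with `correlation_defined = FALSE`.
#'
#' @param g a `glcm` from [compute_glcm()]
#' @return named list: `contrast`, `correlation`, `energy`, `homogeneity`,
#'   `entropy`, `correlation_defined`
#' @export
texture_features <- function(g) {
  stopifnot(inherits(g, "glcm"))
  G <- g$g
  k <- g$levels
  I <- matrix(0:(k - 1), k, k)
  J <- matrix(0:(k - 1), k, k, byrow = TRUE)
  con <- sum((I - J)^2 * G)
  asm <- sum(G^2)
  hom <- sum(G / (1 + abs(I - J)))
  ent <- -sum(G[G > 0] * log2(G[G > 0]))
  p_i <- rowSums(G); p_j <- colSums(G)
  u_i <- sum((0:(k - 1)) * p_i); u_j <- sum((0:(k - 1)) * p_j)
  s_i <- sqrt(sum(((0:(k - 1)) - u_i)^2 * p_i))
  s_j <- sqrt(sum(((0:(k - 1)) - u_j)^2 * p_j))
  if (s_i < 1e-12 || s_j < 1e-12) {
    cor <- 0; defined <- FALSE
  } else {
    cor <- (sum(I * J * G) - u_i * u_j) / (s_i * s_j)
    defined <- TRUE
  }
  list(contrast = con, correlation = cor, energy = asm, homogeneity = hom,
       entropy = ent, correlation_defined = defined)
}

#' Per-pixel standardized uptake value map
#'
#' `SUV = tissue concentration (MBq/g) / (injected dose (MBq) / body
#' weight (g))`, applied pixel-wise to the activity map.
#'
#' @param pet a [pet_slice()]
#' @return numeric matrix of SUV values
#' @examples
#' p <- pet_slice(matrix(0.0025, 4, 4), dose_mbq = 185, weight_g = 74000)
#' suv_image(p)[1, 1] # 1.0
#' @export
suv_image <- function(pet) {
  stopifnot(inherits(pet, "pet_slice"))
  pet$activity / (pet$dose_mbq / pet$weight_g)
}

#' Extract the feature vector of one candidate ROI
#'
#' CT texture: the ROI rectangle is filled from the original image
#' ([fill_roi_rectangle()]), its GLCM computed and the five texture
#' features derived. PET metabolism: the ROI mask is mapped into native
#' PET coordinates through the registration transform (nearest-neighbour
#' sampling) and SUVmax is the maximum SUV over the mapped region
#' (SUVmean over the same region is included as an optional extra).
#'
#' @param ct a [ct_slice()]
#' @param pet a [pet_slice()]
#' @param transform the PET-to-CT aligning [rigid_transform()] (CT pixels)
#' @param roi a `candidate_roi`
#' @param config optional list: `levels` (16), `distance` (1), `angles`
#'   (0/45/90/135), `symmetric` (TRUE)
#' @return one-row data.frame: `scan_id`, `candidate_id`, `contrast`,
#'   `correlation`, `energy`, `homogeneity`, `entropy`, `suvmax`,
#'   `suvmean`, `label` (NA; filled by the evaluation harness)
#' @export
extract_features <- function(ct, pet, transform, roi, config = list()) {
  stopifnot(inherits(ct, "ct_slice"), inherits(pet, "pet_slice"),
            inherits(transform, "rigid_transform"))
  patch <- fill_roi_rectangle(ct, roi)
  g <- compute_glcm(patch,
                    levels = config$levels %||% 16L,
                    distance = config$distance %||% 1L,
                    angles = config$angles %||% c(0, 45, 90, 135),
                    symmetric = config$symmetric %||% TRUE)
  tx <- texture_features(g)
  suv <- suv_image(pet)
  n_ct <- nrow(ct$pixels); n_pet <- nrow(suv)
  qidx <- which(roi$mask, arr.ind = TRUE)
  src <- transform_points(transform, qidx, c((n_ct + 1) / 2, (n_ct + 1) / 2))
  pp <- round(ct_to_pet_points(src, n_ct, n_pet))
  ok <- pp[, 1] >= 1 & pp[, 1] <= n_pet & pp[, 2] >= 1 & pp[, 2] <= n_pet
  vals <- suv[pp[ok, , drop = FALSE]]
  if (length(vals) == 0) vals <- NA_real_
  data.frame(scan_id = roi$scan_id %||% ct$scan_id,
             candidate_id = roi$candidate_id %||% 1L,
             contrast = tx$contrast, correlation = tx$correlation,
             energy = tx$energy, homogeneity = tx$homogeneity,
             entropy = tx$entropy,
             suvmax = max(vals), suvmean = mean(vals),
             label = NA_character_)
}
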