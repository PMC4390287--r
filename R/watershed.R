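#' Detect PET hot-spot candidates and seed markers
#'
#' Converts the PET activity map to SUV, thresholds it at `suv_threshold`
#' (default 2.5, the malignancy criterion), labels the connected hot-spot
#' components (4-connectivity on the PET grid), maps each component into CT
#' coordinates through the registration transform, intersects it with the
#' lung mask, and emits one seed marker at each surviving component's
#' SUV-max pixel. Components whose mapped support does not intersect the
#' lung parenchyma are excluded. An empty result is allowed.
#'
#' @param pet a [pet_slice()]
#' @param lung_mask a `lung_mask` from [segment_lung()] (CT grid)
#' @param transform the PET-to-CT aligning [rigid_transform()] (CT pixels),
#'   as returned by [register_rigid()]
#' @param suv_threshold SUV cutoff for hot spots (> 0)
#' @return list with `markers` (data.frame: `row`, `col`, `source`,
#'   `marker_id`, `candidate_id`; CT coordinates) and `candidates` (list of
#'   per-hot-spot records: `candidate_id`, `mask` and `bbox` on the CT
#'   grid, `suvmax`, `n_pet_pixels`)
#' @export
detect_pet_candidates <- function(pet, lung_mask, transform,
                                  suv_threshold = 2.5) {
  stopifnot(inherits(pet, "pet_slice"), inherits(lung_mask, "lung_mask"),
            inherits(transform, "rigid_transform"), suv_threshold > 0)
  suv <- suv_image(pet)
  hot <- suv >= suv_threshold
  n_ct <- nrow(lung_mask$parenchyma)
  n_pet <- nrow(suv)
  comp <- label_components(hot)
  if (max(comp) == 0L)
    return(list(markers = empty_marker_set(), candidates = list()))

  # CT pixel q sees the aligned PET value at pet coordinate g(T(q))
  grid <- cbind(rep(seq_len(n_ct), times = n_ct),
                rep(seq_len(n_ct), each = n_ct))
  src_ct <- transform_points(transform, grid, c((n_ct + 1) / 2, (n_ct + 1) / 2))
  src_pet <- round(ct_to_pet_points(src_ct, n_ct, n_pet))
  ok <- src_pet[, 1] >= 1 & src_pet[, 1] <= n_pet &
    src_pet[, 2] >= 1 & src_pet[, 2] <= n_pet
  comp_ct <- matrix(0L, n_ct, n_ct)
  comp_ct[ok] <- comp[src_pet[ok, , drop = FALSE]]
  comp_ct[!lung_mask$parenchyma] <- 0L

  inv <- invert_transform(transform)
  center_ct <- c((n_ct + 1) / 2, (n_ct + 1) / 2)
  markers <- list()
  candidates <- list()
  cid <- 0L
  for (k in seq_len(max(comp))) {
    mask <- comp_ct == k
    if (!any(mask)) next
    cid <- cid + 1L
    comp_idx <- which(comp == k)
    peak_pet_idx <- comp_idx[which.max(suv[comp_idx])]
    peak_pet <- c((peak_pet_idx - 1L) %% n_pet + 1L,
                  (peak_pet_idx - 1L) %/% n_pet + 1L)
    peak_ct <- round(transform_points(
      inv, pet_to_ct_points(peak_pet, n_ct, n_pet), center_ct))
    if (peak_ct[1] < 1 || peak_ct[1] > n_ct || peak_ct[2] < 1 ||
        peak_ct[2] > n_ct || !mask[peak_ct[1], peak_ct[2]]) {
      # rounding can push the mapped peak just off the support; snap to the
      # nearest support pixel
      idx <- which(mask, arr.ind = TRUE)
      d2 <- (idx[, 1] - peak_ct[1])^2 + (idx[, 2] - peak_ct[2])^2
      peak_ct <- idx[which.min(d2), ]
    }
    rows <- range(which(rowSums(mask) > 0))
    cols <- range(which(colSums(mask) > 0))
    markers[[cid]] <- data.frame(row = peak_ct[1], col = peak_ct[2],
                                 source = "pet-hotspot", marker_id = cid,
                                 candidate_id = cid)
    candidates[[cid]] <- list(candidate_id = cid, mask = mask,
                              bbox = c(rows[1], cols[1], rows[2] + 1L,
                                       cols[2] + 1L),
                              suvmax = max(suv[comp_idx]),
                              n_pet_pixels = length(comp_idx))
  }
  list(markers = if (cid > 0) do.call(rbind, markers) else empty_marker_set(),
       candidates = candidates)
}

empty_marker_set <- function() {
  data.frame(row = integer(), col = integer(), source = character(),
             marker_id = integer(), candidate_id = integer())
}

#' Gradient landscape of a CT patch
#'
#' Sobel gradient magnitude with replicate edge padding, plus the integer
#' quantization (gray levels 0..255 over the min-max range) used as
#' flooding levels by [flood_from_markers()].
#'
#' @param ct_patch numeric matrix, at least 3 x 3
#' @return an object of class `gradient_landscape`: `gradient` (magnitude),
#'   `min`, `max`, `levels` (integer matrix in 0..255)
#' @export
gradient_image <- function(ct_patch) {
  stopifnot(is.matrix(ct_patch), nrow(ct_patch) >= 3, ncol(ct_patch) >= 3)
  nr <- nrow(ct_patch); nc <- ncol(ct_patch)
  sh <- function(dr, dc) {
    ri <- clamp(seq_len(nr) + dr, 1L, nr)
    ci <- clamp(seq_len(nc) + dc, 1L, nc)
    ct_patch[ri, ci, drop = FALSE]
  }
  # Sobel derivative along rows (gr) and columns (gc)
  gr <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
    (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  gc <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
    (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  g <- sqrt(gr^2 + gc^2)
  lo <- min(g); hi <- max(g)
  levels <- if (hi > lo) {
    matrix(as.integer(pmin(floor((g - lo) / (hi - lo) * 256), 255L)), nr, nc)
  } else matrix(0L, nr, nc)
  structure(list(gradient = g, min = lo, max = hi, levels = levels),
            class = "gradient_landscape")
}

#' Marker-controlled immersion flooding
#'
#' Token-based water-basin flooding of a gradient landscape from seed
#' markers: levels are raised from the minimum to the maximum quantized
#' gray level; at each level, pixels whose gradient lies below the water
#' level join the basin of an adjacent labeled region (8-connectivity,
#' FIFO order of discovery on plateaus, so the first-come basin wins).
#' A pixel adjacent to two or more distinct basins at its joining level
#' becomes a dam pixel: dams are built on the boundaries to prevent
#' leakage between basins. Pixels never reached stay unlabeled.
#'
#' @param landscape a `gradient_landscape` from [gradient_image()]
#' @param markers data.frame with `row`, `col`, `marker_id` (distinct
#'   pixels inside the landscape)
#' @param connectivity 4 or 8 (default 8)
#' @param record_snapshots if TRUE, store the label image after each
#'   flooding level (for auditing the level-nesting property)
#' @return an object of class `flood_result`: `labels` (integer matrix,
#'   0 = unlabeled, otherwise the marker id), `dam` (logical matrix),
#'   `join_level` (integer matrix, NA where unlabeled), `marker_ids`, and
#'   optionally `snapshots` (named list, level -> label matrix)
#' @export
flood_from_markers <- function(landscape, markers, connectivity = 8L,
                               record_snapshots = FALSE) {
  stopifnot(inherits(landscape, "gradient_landscape"),
            connectivity %in% c(4L, 8L), nrow(markers) >= 1)
  lv <- landscape$levels
  nr <- nrow(lv); nc <- ncol(lv)
  if (any(markers$row < 1 | markers$row > nr | markers$col < 1 |
            markers$col > nc))
    stop("marker outside the landscape")
  midx <- (markers$col - 1L) * nr + markers$row
  if (anyDuplicated(midx)) stop("markers must be distinct pixels")

  labels <- matrix(0L, nr, nc)
  dam <- matrix(FALSE, nr, nc)
  join_level <- matrix(NA_integer_, nr, nc)
  in_queue <- matrix(FALSE, nr, nc)
  labels[midx] <- as.integer(markers$marker_id)
  join_level[midx] <- lv[midx]

  offs <- if (connectivity == 8L) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  n_lvl <- 256L
  queues <- vector("list", n_lvl)   # FIFO bucket per level (1-based: level+1)
  heads <- rep(1L, n_lvl)
  push <- function(idx, level) {
    l <- level + 1L
    queues[[l]] <<- c(queues[[l]], idx)
    in_queue[idx] <<- TRUE
  }
  neighbours <- function(idx) {
    r <- (idx - 1L) %% nr + 1L
    c <- (idx - 1L) %/% nr + 1L
    rr <- r + offs[, 1]; cc <- c + offs[, 2]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    (cc[ok] - 1L) * nr + rr[ok]
  }
  for (i in seq_along(midx)) {
    for (nb in neighbours(midx[i])) {
      if (labels[nb] == 0L && !in_queue[nb]) push(nb, lv[nb])
    }
  }
  snapshots <- if (record_snapshots) list() else NULL
  for (level in 0:(n_lvl - 1L)) {
    repeat {
      l <- level + 1L
      if (heads[l] > length(queues[[l]])) break
      idx <- queues[[l]][heads[l]]
      heads[l] <- heads[l] + 1L
      if (labels[idx] != 0L || dam[idx]) next
      nbs <- neighbours(idx)
      nb_labels <- unique(labels[nbs])
      nb_labels <- nb_labels[nb_labels != 0L]
      if (length(nb_labels) == 0L) next        # orphaned entry; re-queued later
      if (length(nb_labels) >= 2L) {
        dam[idx] <- TRUE
      } else {
        labels[idx] <- nb_labels
        join_level[idx] <- level
        for (nb in nbs) {
          if (labels[nb] == 0L && !dam[nb] && !in_queue[nb])
            push(nb, max(lv[nb], level))     # pockets flood at the current level
        }
      }
    }
    if (record_snapshots) snapshots[[as.character(level)]] <- labels
  }
  structure(list(labels = labels, dam = dam, join_level = join_level,
                 marker_ids = as.integer(markers$marker_id),
                 snapshots = snapshots),
            class = "flood_result")
}

#' Dissolve internal dams and extract the outer boundary
#'
#' Basins belonging to one candidate (the `interior_ids`) are merged; dam
#' pixels completely surrounded by the merged candidate are internal dams
#' and are flooded into the region. Only the outermost dam remains as the
#' segmentation boundary: the dam pixels adjacent to the merged candidate
#' that separate it from the exterior (other basins or unlabeled pixels).
#' The ROI is the merged region together with its outermost dam. When the
#' flood produced no dams at all (a single basin), the boundary falls back
#' to the basin's morphological perimeter.
#'
#' @param flood a `flood_result`
#' @param interior_ids marker ids forming the candidate (default: all)
#' @return list with `region` (logical mask: merged basins, dissolved
#'   internal dams, and the outermost dam) and `boundary` (logical mask:
#'   the outer closed curve, a subset of `region`)
#' @export
outer_boundary <- function(flood, interior_ids = NULL) {
  stopifnot(inherits(flood, "flood_result"))
  interior_ids <- as.integer(interior_ids %||% flood$marker_ids)
  region <- matrix(flood$labels %in% interior_ids, nrow(flood$labels),
                   ncol(flood$labels))
  if (!any(region)) stop("degenerate flood: no interior region to bound")
  nr <- nrow(region); nc <- ncol(region)
  # dissolve dams whose labeled/unlabeled neighbourhood is entirely interior
  dam_idx <- which(flood$dam)
  if (length(dam_idx)) {
    repeat {
      grew <- FALSE
      for (idx in dam_idx) {
        if (region[idx]) next
        r <- (idx - 1L) %% nr + 1L; c <- (idx - 1L) %/% nr + 1L
        rr <- pmax(r - 1L, 1L):pmin(r + 1L, nr)
        cc <- pmax(c - 1L, 1L):pmin(c + 1L, nc)
        nbh <- flood$labels[rr, cc, drop = FALSE]
        nbd <- flood$dam[rr, cc, drop = FALSE]
        outside_vals <- nbh[!nbd]
        if (all(outside_vals %in% c(0L, interior_ids)) &&
            any(outside_vals %in% interior_ids) &&
            !any(outside_vals == 0L)) {
          region[idx] <- TRUE
          grew <- TRUE
        }
      }
      if (!grew) break
    }
  }
  outer_dam <- flood$dam & dilate_mask(region) & !region
  if (any(outer_dam)) {
    region <- region | outer_dam
    boundary <- outer_dam
  } else {
    boundary <- region & !erode_mask(region)
  }
  list(region = region, boundary = boundary)
}

# 8-connected dilation by one pixel.
dilate_mask <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    rd <- max(1, 1 - dr):min(nr, nr - dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    cd <- max(1, 1 - dc):min(nc, nc - dc)
    out[rd, cd] <- out[rd, cd] | mask[rs, cs]
  }
  out
}

# 8-connected erosion by one pixel; pixels on the image edge erode.
erode_mask <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  padded <- matrix(FALSE, nr + 2L, nc + 2L)
  padded[2:(nr + 1L), 2:(nc + 1L)] <- mask
  out <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    out <- out & padded[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  }
  out
}

#' Delineate one nodule candidate with the marker-controlled watershed
#'
#' Crops a working window around the candidate's hot-spot support (margin
#' 1.5x the support bounding box, at least 16 px), computes the Sobel
#' gradient landscape (after optional Gaussian pre-smoothing), seeds the
#' flood with the hot-spot marker plus the `k_seeds` lowest-gradient
#' pixels inside the support (a plurality of seed points in the target)
#' and with background markers at the lowest-gradient pixel of each window
#' edge, floods, dissolves internal dams and fills the outer boundary.
#'
#' @param ct a [ct_slice()]
#' @param candidate one element of `detect_pet_candidates()$candidates`
#' @param markers the marker data.frame from [detect_pet_candidates()]
#' @param config optional list: `margin_factor` (1.5), `min_window` (16),
#'   `k_seeds` (3), `connectivity` (8), `smooth_sigma` (1)
#' @return a `candidate_roi`: `scan_id`, `candidate_id`, `mask` (CT-grid
#'   logical), `bbox` (row0, col0, row1, col1; half-open), `seed_suvmax`,
#'   `provenance` (marker ids), `low_confidence` flag; or `NULL` when the
#'   delineated mask is empty (candidate dropped)
#' @export
segment_nodule <- function(ct, candidate, markers, config = list()) {
  stopifnot(inherits(ct, "ct_slice"))
  mk <- markers[markers$candidate_id == candidate$candidate_id, , drop = FALSE]
  stopifnot(nrow(mk) >= 1)
  img <- ct$pixels
  nr <- nrow(img); nc <- ncol(img)
  margin_factor <- config$margin_factor %||% 1.5
  min_window <- config$min_window %||% 16L
  k_seeds <- config$k_seeds %||% 3L
  bb <- candidate$bbox
  h <- bb[3] - bb[1]; w <- bb[4] - bb[2]
  half <- max(ceiling(margin_factor * max(h, w) / 2), ceiling(min_window / 2))
  cr <- floor((bb[1] + bb[3] - 1) / 2); cc <- floor((bb[2] + bb[4] - 1) / 2)
  r0 <- max(1L, cr - half); r1 <- min(nr, cr + half)
  c0 <- max(1L, cc - half); c1 <- min(nc, cc + half)
  patch <- img[r0:r1, c0:c1, drop = FALSE]
  smooth_sigma <- config$smooth_sigma %||% 1
  landscape <- gradient_image(gaussian_blur(patch, smooth_sigma))
  flat <- landscape$max - landscape$min < 1e-9

  support <- candidate$mask[r0:r1, c0:c1, drop = FALSE]
  # interior seeds: hot-spot peak + k lowest-gradient pixels in the support
  seeds <- data.frame(row = mk$row - r0 + 1L, col = mk$col - c0 + 1L,
                      source = mk$source, marker_id = seq_len(nrow(mk)))
  sup_idx <- which(support)
  sup_idx <- setdiff(sup_idx, (seeds$col - 1L) * nrow(patch) + seeds$row)
  if (length(sup_idx) > 0 && k_seeds > 0) {
    ord <- sup_idx[order(landscape$gradient[sup_idx])]
    extra <- utils::head(ord, k_seeds)
    seeds <- rbind(seeds, data.frame(
      row = (extra - 1L) %% nrow(patch) + 1L,
      col = (extra - 1L) %/% nrow(patch) + 1L,
      source = "gradient-minimum",
      marker_id = nrow(seeds) + seq_along(extra)))
  }
  n_interior <- nrow(seeds)
  # background seeds: lowest-gradient pixel on each window edge
  edges <- list(cbind(1L, seq_len(ncol(patch))),
                cbind(nrow(patch), seq_len(ncol(patch))),
                cbind(seq_len(nrow(patch)), 1L),
                cbind(seq_len(nrow(patch)), ncol(patch)))
  for (e in edges) {
    gvals <- landscape$gradient[e]
    best <- e[which.min(gvals), , drop = FALSE]
    cand_idx <- (best[2] - 1L) * nrow(patch) + best[1]
    if (!cand_idx %in% ((seeds$col - 1L) * nrow(patch) + seeds$row)) {
      seeds <- rbind(seeds, data.frame(row = best[1], col = best[2],
                                       source = "background",
                                       marker_id = nrow(seeds) + 1L))
    }
  }
  fl <- flood_from_markers(landscape, seeds,
                           connectivity = config$connectivity %||% 8L)
  ob <- outer_boundary(fl, interior_ids = seq_len(n_interior))
  if (!any(ob$region)) return(NULL)
  mask <- matrix(FALSE, nr, nc)
  mask[r0:r1, c0:c1] <- ob$region
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  structure(list(scan_id = ct$scan_id,
                 candidate_id = candidate$candidate_id,
                 mask = mask,
                 bbox = c(rows[1], cols[1], rows[2] + 1L, cols[2] + 1L),
                 seed_suvmax = candidate$suvmax,
                 provenance = seeds$marker_id[seq_len(n_interior)],
                 low_confidence = flat),
            class = "candidate_roi")
}
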