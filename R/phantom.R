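#' CT and PET slice containers
#'
#' Light S3 containers for a single axial slice. CT pixels live on an
#' abstract attenuation scale (air ~ -1000, lung parenchyma ~ -800, soft
#' tissue ~ 40). PET carries tracer activity (MBq/g) together with the
#' injected dose and body weight needed for standardized-uptake-value (SUV)
#' calibration: `SUV = activity / (dose_mbq / weight_g)`.
#'
#' @param pixels,activity numeric matrix
#' @param pixel_spacing optional pixel spacing in mm
#' @param dose_mbq injected dose in MBq (> 0)
#' @param weight_g body weight in g (> 0)
#' @param scan_id identifier string
#' @return an object of class `ct_slice` / `pet_slice`
#' @export
ct_slice <- function(pixels, pixel_spacing = NULL, scan_id = "scan") {
  stopifnot(is.matrix(pixels), all(is.finite(pixels)), length(pixels) > 0)
  structure(list(pixels = pixels, pixel_spacing = pixel_spacing,
                 scan_id = scan_id), class = "ct_slice")
}

#' @rdname ct_slice
#' @export
pet_slice <- function(activity, dose_mbq, weight_g, scan_id = "scan") {
  stopifnot(is.matrix(activity), all(is.finite(activity)),
            all(activity >= 0), dose_mbq > 0, weight_g > 0)
  structure(list(activity = activity, dose_mbq = dose_mbq,
                 weight_g = weight_g, scan_id = scan_id), class = "pet_slice")
}

#' Parameters of the paired CT/PET digital thorax phantom
#'
#' The phantom emulates a single axial thorax slice: a soft-tissue body
#' ellipse containing two low-attenuation lung fields, vessel-like linear
#' structures, and planted nodules of known position, size and contrast,
#' with a co-registered PET activity map whose hot spots have controllable
#' SUVmax and a known rigid misalignment applied to PET (CT is the
#' reference). Defaults follow the study conditions the package is
#' evaluated under: one solitary nodule per scan, malignant with
#' probability 120/219, malignant SUVmax in \[2.5, 8\] and benign
#' (inflammation) in \[0.5, 2.4\].
#'
#' @param image_size_ct CT grid size in pixels (square)
#' @param image_size_pet PET grid size in pixels (square)
#' @param n_nodules nodules planted per slice
#' @param nodule_radius_range nodule radius range in CT pixels
#' @param nodule_ct_contrast attenuation offset of a nodule above the lung
#'   background
#' @param malignant_suv_range,benign_suv_range SUVmax ranges per class
#' @param malignant_fraction probability that a nodule is malignant
#' @param vessel_count vessel segments drawn per lung
#' @param noise_sd_ct additive Gaussian noise sd on CT (attenuation units)
#' @param noise_sd_pet additive Gaussian noise sd on PET activity
#'   (MBq/g; the default corresponds to ~0.1 SUV at the default calibration)
#' @param misalignment [rigid_transform()] applied to PET, expressed in CT
#'   grid pixels (this is the transform registration should recover)
#' @param misalign_shift_max,misalign_angle_max bounds used when a cohort
#'   draws per-scan random misalignments (CT pixels / degrees)
#' @param dose_mbq,weight_g SUV calibration metadata
#' @param smooth_sigma_ct Gaussian blur sd applied to the noise-free CT, px
#' @param seed integer RNG seed; a fixed seed makes output byte-identical
#' @return an object of class `phantom_params`
#' @export
phantom_params <- function(image_size_ct = 256L,
                           image_size_pet = 128L,
                           n_nodules = 1L,
                           nodule_radius_range = c(4, 9),
                           nodule_ct_contrast = 600,
                           malignant_suv_range = c(2.5, 8),
                           benign_suv_range = c(0.5, 2.4),
                           malignant_fraction = 120 / 219,
                           vessel_count = 4L,
                           noise_sd_ct = 20,
                           noise_sd_pet = 2.5e-4,
                           misalignment = rigid_transform(6, -4, 3),
                           misalign_shift_max = 8,
                           misalign_angle_max = 5,
                           dose_mbq = 185,
                           weight_g = 74000,
                           smooth_sigma_ct = 1,
                           seed = 1L) {
  p <- list(image_size_ct = as.integer(image_size_ct),
            image_size_pet = as.integer(image_size_pet),
            n_nodules = as.integer(n_nodules),
            nodule_radius_range = as.numeric(nodule_radius_range),
            nodule_ct_contrast = nodule_ct_contrast,
            malignant_suv_range = as.numeric(malignant_suv_range),
            benign_suv_range = as.numeric(benign_suv_range),
            malignant_fraction = malignant_fraction,
            vessel_count = as.integer(vessel_count),
            noise_sd_ct = noise_sd_ct, noise_sd_pet = noise_sd_pet,
            misalignment = misalignment,
            misalign_shift_max = misalign_shift_max,
            misalign_angle_max = misalign_angle_max,
            dose_mbq = dose_mbq, weight_g = weight_g,
            smooth_sigma_ct = smooth_sigma_ct,
            seed = as.integer(seed))
  validate_phantom_params(p)
  structure(p, class = "phantom_params")
}

validate_phantom_params <- function(p) {
  stopifnot(p$image_size_ct > 0, p$image_size_pet > 0, p$n_nodules >= 0,
            length(p$nodule_radius_range) == 2,
            p$nodule_radius_range[1] <= p$nodule_radius_range[2],
            p$malignant_suv_range[1] <= p$malignant_suv_range[2],
            p$benign_suv_range[1] <= p$benign_suv_range[2],
            p$malignant_fraction >= 0, p$malignant_fraction <= 1,
            p$vessel_count >= 0, p$noise_sd_ct >= 0, p$noise_sd_pet >= 0,
            p$dose_mbq > 0, p$weight_g > 0,
            inherits(p$misalignment, "rigid_transform"))
  invisible(p)
}

# Tissue attenuation levels of the phantom (abstract scale).
PHANTOM_LEVELS <- list(air = -1000, lung = -800, soft = 40, vessel = 30)
# Background SUV levels of the PET phantom. The mediastinum (cardiac blood
# pool) is the usual bright reference structure on FDG PET.
PHANTOM_SUV <- list(outside = 0.02, soft = 0.8, lung = 0.3, mediastinum = 1.6)

ellipse_mask <- function(nr, nc, center, semi) {
  r <- matrix(seq_len(nr), nr, nc)
  c <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ((r - center[1]) / semi[1])^2 + ((c - center[2]) / semi[2])^2 <= 1
}

disc_mask <- function(nr, nc, center, radius) {
  r <- matrix(seq_len(nr), nr, nc)
  c <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (r - center[1])^2 + (c - center[2])^2 <= radius^2
}

# Stamp a thick line segment (disc-swept) into a logical mask.
segment_mask <- function(nr, nc, from, to, width) {
  n_steps <- max(2L, ceiling(2 * sqrt(sum((to - from)^2))))
  ts <- seq(0, 1, length.out = n_steps)
  m <- matrix(FALSE, nr, nc)
  for (t in ts) {
    p <- from + t * (to - from)
    m <- m | disc_mask(nr, nc, p, width)
  }
  m
}

# Normalised thorax geometry shared by the CT and PET renderers. A
# fractional field-of-view position f maps to pixel index f * n + 0.5
# (pixel centers at integers), so the same fractions land on corresponding
# physical positions on both grids.
phantom_geometry <- function(n, jitter = c(0, 0)) {
  list(
    body = list(center = c(0.52, 0.50) * n + 0.5, semi = c(0.38, 0.45) * n),
    lungs = list(
      list(center = (c(0.52, 0.30) + jitter) * n + 0.5, semi = c(0.27, 0.155) * n),
      list(center = (c(0.52, 0.70) - jitter) * n + 0.5, semi = c(0.27, 0.155) * n)
    ),
    mediastinum = list(center = c(0.40, 0.50) * n + 0.5, semi = c(0.10, 0.075) * n)
  )
}

#' Generate one paired CT/PET phantom slice with ground truth
#'
#' Rendering order on CT: body ellipse over air, lung ellipses, vessel
#' segments, nodule discs (lung level + contrast), Gaussian smoothing, then
#' additive noise last. The PET activity map is rendered natively on the PET
#' grid, misaligned by `params$misalignment` (rotation + translation,
#' CT-pixel units scaled to the PET grid), and each nodule's hot spot is
#' planted so that the SUV computed from the activity calibration equals
#' the planted SUVmax exactly at the hot-spot peak pixel in the absence of
#' noise.
#'
#' @param params a [phantom_params()] object
#' @return a list with elements `ct` ([ct_slice()]), `pet` ([pet_slice()])
#'   and `truth` (class `phantom_truth`: per-nodule records, the applied
#'   misalignment, the ground-truth lung mask and per-nodule masks)
#' @export
generate_slice <- function(params) {
  validate_phantom_params(params)
  with_seed(params$seed, generate_slice_impl(params))
}

generate_slice_impl <- function(params) {
  n <- params$image_size_ct
  m <- params$image_size_pet
  jit <- stats::runif(2, -0.008, 0.008)
  geo <- phantom_geometry(n, jit)

  ct <- matrix(PHANTOM_LEVELS$air, n, n)
  body <- ellipse_mask(n, n, geo$body$center, geo$body$semi)
  ct[body] <- PHANTOM_LEVELS$soft
  lung_mask <- matrix(FALSE, n, n)
  for (lg in geo$lungs) lung_mask <- lung_mask | ellipse_mask(n, n, lg$center, lg$semi)
  ct[lung_mask] <- PHANTOM_LEVELS$lung

  # vessel-like linear structures inside each lung (do not touch the pleura)
  for (lg in geo$lungs) {
    for (v in seq_len(params$vessel_count)) {
      from <- lg$center + stats::runif(2, -0.35, 0.35) * lg$semi
      ang <- stats::runif(1, 0, 2 * pi)
      len <- stats::runif(1, 0.08, 0.18) * n
      to <- from + len * c(cos(ang), sin(ang))
      # pull the endpoint back inside a shrunken lung ellipse
      shrink <- 0.8
      d <- ((to[1] - lg$center[1]) / (shrink * lg$semi[1]))^2 +
        ((to[2] - lg$center[2]) / (shrink * lg$semi[2]))^2
      if (d > 1) to <- lg$center + (to - lg$center) / sqrt(d)
      seg <- segment_mask(n, n, from, to, width = 1.3) & lung_mask
      ct[seg] <- PHANTOM_LEVELS$vessel
    }
  }

  # nodule placement with bounded retries
  nodules <- list()
  nodule_masks <- list()
  for (i in seq_len(params$n_nodules)) {
    radius <- stats::runif(1, params$nodule_radius_range[1],
                           params$nodule_radius_range[2])
    placed <- FALSE
    for (try in seq_len(200)) {
      lg <- geo$lungs[[sample.int(2, 1)]]
      margin <- (radius + 5)
      u <- stats::runif(2, -1, 1)
      if (sum(u^2) > 1) next
      center <- lg$center + u * pmax(lg$semi - margin, 0)
      inside <- ((center[1] - lg$center[1]) / (lg$semi[1] - margin))^2 +
        ((center[2] - lg$center[2]) / (lg$semi[2] - margin))^2
      if (!is.finite(inside) || inside > 1) next
      ok <- TRUE
      for (nd in nodules) {
        if (sqrt(sum((center - c(nd$row, nd$col))^2)) < radius + nd$radius + 6) ok <- FALSE
      }
      if (!ok) next
      placed <- TRUE
      break
    }
    if (!placed) stop("nodule placement failed: lungs too crowded for ",
                      params$n_nodules, " nodules")
    malignant <- stats::runif(1) < params$malignant_fraction
    rng <- if (malignant) params$malignant_suv_range else params$benign_suv_range
    suv <- stats::runif(1, rng[1], rng[2])
    dm <- disc_mask(n, n, center, radius)
    ct[dm] <- PHANTOM_LEVELS$lung + params$nodule_ct_contrast
    nodules[[i]] <- list(nodule_id = i, row = center[1], col = center[2],
                         radius = radius,
                         label = if (malignant) "malignant" else "benign",
                         planted_suvmax = suv)
    nodule_masks[[i]] <- dm
  }

  ct <- gaussian_blur(ct, params$smooth_sigma_ct)

  # PET: background rendered on the PET grid, misaligned, hot spots planted
  # at their misaligned positions with exact peak values.
  cal <- params$dose_mbq / params$weight_g        # SUV of 1.0 in activity units
  geo_p <- phantom_geometry(m, jit)
  suv_map <- matrix(PHANTOM_SUV$outside, m, m)
  suv_map[ellipse_mask(m, m, geo_p$body$center, geo_p$body$semi)] <- PHANTOM_SUV$soft
  for (lg in geo_p$lungs) {
    suv_map[ellipse_mask(m, m, lg$center, lg$semi)] <- PHANTOM_SUV$lung
  }
  suv_map[ellipse_mask(m, m, geo_p$mediastinum$center,
                       geo_p$mediastinum$semi)] <- PHANTOM_SUV$mediastinum
  suv_map <- gaussian_blur(suv_map, 1.2)
  t_pet <- scale_transform(params$misalignment, m / n)
  suv_map <- warp_image(suv_map, invert_transform(t_pet),
                        interp = "bilinear", fill = PHANTOM_SUV$outside)

  center_pet_grid <- c((m + 1) / 2, (m + 1) / 2)
  for (nd in nodules) {
    u_aligned <- ct_to_pet_points(c(nd$row, nd$col), n, m)
    u_obs <- transform_points(t_pet, u_aligned, center_pet_grid)
    peak <- clamp(round(u_obs), 1, m)
    sigma_pet <- max(0.8, nd$radius * m / n / 1.8)
    r <- matrix(seq_len(m), m, m)
    c2 <- matrix(seq_len(m), m, m, byrow = TRUE)
    d2 <- (r - peak[1])^2 + (c2 - peak[2])^2
    blob <- nd$planted_suvmax * exp(-d2 / (2 * sigma_pet^2))
    suv_map <- pmax(suv_map, blob)
  }
  activity <- suv_map * cal

  # noise added last
  if (params$noise_sd_ct > 0)
    ct <- ct + matrix(stats::rnorm(n * n, 0, params$noise_sd_ct), n, n)
  if (params$noise_sd_pet > 0)
    activity <- pmax(activity +
                       matrix(stats::rnorm(m * m, 0, params$noise_sd_pet), m, m), 0)

  truth <- structure(list(
    nodules = do.call(rbind, lapply(nodules, function(nd)
      data.frame(nodule_id = nd$nodule_id, row = nd$row, col = nd$col,
                 radius = nd$radius, label = nd$label,
                 planted_suvmax = nd$planted_suvmax))),
    misalignment = params$misalignment,
    lung_mask = lung_mask,
    nodule_masks = nodule_masks
  ), class = "phantom_truth")
  if (is.null(truth$nodules))
    truth$nodules <- data.frame(nodule_id = integer(), row = numeric(),
                                col = numeric(), radius = numeric(),
                                label = character(), planted_suvmax = numeric())

  list(ct = ct_slice(ct, scan_id = "phantom"),
       pet = pet_slice(activity, params$dose_mbq, params$weight_g,
                       scan_id = "phantom"),
       truth = truth)
}

#' Apply a rigid misalignment to a PET slice
#'
#' Moves the image content by `t` (expressed in PET-grid pixels): the
#' activity map is resampled so that a structure at `p` appears at `t(p)`.
#' Calibration metadata is unchanged. Nearest-neighbour interpolation (the
#' default) preserves activity values exactly.
#'
#' @param pet a [pet_slice()]
#' @param t a [rigid_transform()] in PET-grid pixels
#' @param interp `"nearest"` (default) or `"bilinear"`
#' @return a [pet_slice()]
#' @export
apply_misalignment <- function(pet, t, interp = c("nearest", "bilinear")) {
  interp <- match.arg(interp)
  stopifnot(inherits(pet, "pet_slice"), inherits(t, "rigid_transform"))
  act <- warp_image(pet$activity, invert_transform(t), interp = interp, fill = 0)
  act[is.na(act)] <- 0
  pet_slice(act, pet$dose_mbq, pet$weight_g, pet$scan_id)
}

#' Generate a phantom cohort on disk
#'
#' Writes per-scan CT, PET, ground-truth lung and nodule-label masks as
#' NIfTI (`.nii.gz`), a per-scan truth JSON, a cohort-level truth CSV and a
#' `manifest.json`. Per-scan seeds and per-scan random misalignments
#' (within `misalign_shift_max` / `misalign_angle_max`) are derived
#' reproducibly from the master seed.
#'
#' @param n_scans number of scans (>= 1)
#' @param params a [phantom_params()] template
#' @param seed master seed
#' @param out_dir output directory (created if needed)
#' @return the manifest, invisibly
#' @export
generate_cohort <- function(n_scans, params, seed, out_dir) {
  stopifnot(n_scans >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)

  entries <- vector("list", n_scans)
  truth_rows <- list()
  for (i in seq_len(n_scans)) {
    scan_id <- sprintf("scan_%03d", i)
    pi <- params
    pi$seed <- as.integer((seed * 131L + i * 7919L) %% 2147483647L)
    mis <- with_seed(pi$seed + 1L, rigid_transform(
      stats::runif(1, -params$misalign_shift_max, params$misalign_shift_max),
      stats::runif(1, -params$misalign_shift_max, params$misalign_shift_max),
      stats::runif(1, -params$misalign_angle_max, params$misalign_angle_max)))
    pi$misalignment <- mis
    sl <- generate_slice(pi)
    sl$ct$scan_id <- scan_id
    sl$pet$scan_id <- scan_id

    ct_path <- file.path(out_dir, paste0(scan_id, "_ct.nii.gz"))
    pet_path <- file.path(out_dir, paste0(scan_id, "_pet.nii.gz"))
    lung_path <- file.path(out_dir, paste0(scan_id, "_lungmask.nii.gz"))
    nod_path <- file.path(out_dir, paste0(scan_id, "_nodulemask.nii.gz"))
    truth_path <- file.path(out_dir, paste0(scan_id, "_truth.json"))
    RNifti::writeNifti(RNifti::asNifti(sl$ct$pixels), ct_path)
    RNifti::writeNifti(RNifti::asNifti(sl$pet$activity), pet_path)
    RNifti::writeNifti(RNifti::asNifti(sl$truth$lung_mask + 0), lung_path)
    nod_lab <- matrix(0L, nrow(sl$ct$pixels), ncol(sl$ct$pixels))
    for (k in seq_along(sl$truth$nodule_masks))
      nod_lab[sl$truth$nodule_masks[[k]]] <- k
    RNifti::writeNifti(RNifti::asNifti(nod_lab), nod_path)
    jsonlite::write_json(list(
      scan_id = scan_id,
      misalignment = list(tx = mis$tx, ty = mis$ty, theta = mis$theta),
      dose_mbq = params$dose_mbq, weight_g = params$weight_g,
      nodules = sl$truth$nodules
    ), truth_path, auto_unbox = TRUE, digits = NA)

    if (nrow(sl$truth$nodules) > 0) {
      tr <- sl$truth$nodules
      tr$scan_id <- scan_id
      truth_rows[[length(truth_rows) + 1L]] <- tr
    }
    entries[[i]] <- list(
      scan_id = scan_id, seed = pi$seed,
      ct = basename(ct_path), pet = basename(pet_path),
      lung_mask = basename(lung_path), nodule_mask = basename(nod_path),
      truth = basename(truth_path),
      n_nodules = nrow(sl$truth$nodules),
      checksum_ct = checksum_array(sl$ct$pixels),
      checksum_pet = checksum_array(sl$pet$activity))
  }
  truth_df <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(scan_id = character())
  utils::write.csv(truth_df, file.path(out_dir, "truth.csv"), row.names = FALSE)
  manifest <- list(n_scans = n_scans, master_seed = seed,
                   dose_mbq = params$dose_mbq, weight_g = params$weight_g,
                   image_size_ct = params$image_size_ct,
                   image_size_pet = params$image_size_pet,
                   scans = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# Deterministic fingerprint of a numeric array (md5 of its serialised,
# rounded values).
checksum_array <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(round(as.numeric(x), 9), NULL, version = 2), f)
  unname(tools::md5sum(f))
}

#' Read a cohort manifest and a single scan
#'
#' @param dir cohort directory written by [generate_cohort()]
#' @return `read_manifest()`: the parsed manifest list; `read_scan()`: a
#'   list with `ct`, `pet` and `truth` for one scan entry.
#' @export
read_manifest <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) stop("no scans found: missing ", path)
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

#' @rdname read_manifest
#' @param entry one element of `manifest$scans`
#' @export
read_scan <- function(dir, entry) {
  ctm <- as.matrix(RNifti::readNifti(file.path(dir, entry$ct)))
  petm <- as.matrix(RNifti::readNifti(file.path(dir, entry$pet)))
  truth <- jsonlite::read_json(file.path(dir, entry$truth),
                               simplifyVector = TRUE)
  lung <- as.matrix(RNifti::readNifti(file.path(dir, entry$lung_mask))) > 0.5
  nod <- as.matrix(RNifti::readNifti(file.path(dir, entry$nodule_mask)))
  list(ct = ct_slice(ctm, scan_id = entry$scan_id),
       pet = pet_slice(petm, truth$dose_mbq, truth$weight_g,
                       scan_id = entry$scan_id),
       truth = list(
         nodules = as.data.frame(truth$nodules),
         misalignment = rigid_transform(truth$misalignment$tx,
                                        truth$misalignment$ty,
                                        truth$misalignment$theta),
         lung_mask = lung,
         nodule_label_mask = round(nod)))
}
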