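# Reduced-size phantom parameters for fast module tests. The geometry is
# the same thorax template at half resolution.
fast_params <- function(...) {
  defaults <- list(image_size_ct = 128L, image_size_pet = 64L,
                   nodule_radius_range = c(4, 6),
                   misalignment = rigid_transform(4, -3, 2),
                   misalign_shift_max = 5, misalign_angle_max = 3,
                   seed = 1L)
  args <- utils::modifyList(defaults, list(...))
  do.call(phantom_params, args)
}

# Build a candidate_roi-shaped object from a plain logical mask.
roi_from_mask <- function(mask, scan_id = "test", candidate_id = 1L,
                          suvmax = NA_real_) {
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  structure(list(scan_id = scan_id, candidate_id = candidate_id,
                 mask = mask,
                 bbox = c(rows[1], cols[1], rows[2] + 1L, cols[2] + 1L),
                 seed_suvmax = suvmax, provenance = integer(),
                 low_confidence = FALSE),
            class = "candidate_roi")
}

# Wrap a plain matrix of quantized flooding levels as a gradient_landscape.
landscape_from_levels <- function(lv) {
  structure(list(gradient = lv, min = min(lv), max = max(lv),
                 levels = matrix(as.integer(lv), nrow(lv), ncol(lv))),
            class = "gradient_landscape")
}
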