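#' Iterative dynamic threshold for lung parenchyma
#'
#' Fixed-point threshold iteration: starting from `p0`, each update sets the
#' new threshold to the mean of the two class means,
#' `p <- (mean(pixels <= p) + mean(pixels > p)) / 2`, and stops when
#' successive thresholds differ by at most `sigma`. Pixels at or below the
#' threshold are the parenchyma class (ties go to parenchyma; only strictly
#' larger values are background).
#'
#' @param image numeric matrix or vector of intensities
#' @param p0 initial threshold; defaults to the image mean, which always
#'   splits a non-constant image into two non-empty classes
#' @param sigma convergence tolerance (> 0), intensity units
#' @param max_iter iteration guard
#' @return an object of class `threshold_state` with fields `p_i` (the
#'   converged threshold), `p_t` (mean of the non-parenchyma class at
#'   convergence), `iteration`, and `sigma`
#' @examples
#' img <- c(rep(0, 8), rep(200, 8))
#' iterate_threshold(img, p0 = 100)$p_i  # 100: the symmetric fixed point
#' @export
iterate_threshold <- function(image, p0 = NULL, sigma = 0.5, max_iter = 100L) {
  stopifnot(sigma > 0, max_iter >= 1)
  v <- as.numeric(image)
  stopifnot(all(is.finite(v)), length(v) > 0)
  p <- if (is.null(p0)) mean(v) else p0
  iter <- 0L
  repeat {
    lo <- v[v <= p]
    hi <- v[v > p]
    if (length(lo) == 0 || length(hi) == 0)
      stop("degenerate split: threshold ", format(p),
           " leaves an empty class (constant image?)")
    p_new <- (mean(lo) + mean(hi)) / 2
    iter <- iter + 1L
    delta <- abs(p_new - p)
    p <- p_new
    if (delta <= sigma) break
    if (iter >= max_iter)
      stop("dynamic threshold did not converge within ", max_iter,
           " iterations (last delta = ", format(delta), ")")
  }
  structure(list(p_i = p, p_t = mean(v[v > p]), iteration = iter,
                 sigma = sigma), class = "threshold_state")
}

#' Binarize a CT image into parenchyma and background
#'
#' Pixels strictly larger than the threshold become background (255);
#' pixels at or below it become parenchyma (0).
#'
#' @param image numeric matrix
#' @param threshold finite scalar
#' @return an object of class `lung_mask`: a list with `values` (a 0/255
#'   matrix, 255 = background) and `parenchyma` (logical, TRUE = parenchyma)
#' @export
binarize_parenchyma <- function(image, threshold) {
  stopifnot(is.finite(threshold), is.matrix(image))
  paren <- image <= threshold
  structure(list(values = matrix(ifelse(paren, 0, 255), nrow(image), ncol(image)),
                 parenchyma = paren), class = "lung_mask")
}

#' Refine a binary lung mask
#'
#' Removes parenchyma-labeled regions touching the image border (exterior
#' air), drops speckle components smaller than `min_area` as well as
#' sprawling non-compact ones (bounding-box fill fraction below
#' `min_solidity`; lung fields are compact blobs whereas thresholded noise
#' percolates into dendritic clusters), keeps the `keep` largest remaining
#' interior components (the two lungs), and fills interior holes up to
#' `hole_area_max` pixels (vessels and nodules binarize as background and
#' would otherwise punch holes in the lungs). Idempotent.
#'
#' @param mask a `lung_mask`
#' @param keep number of components to keep (default 2)
#' @param hole_area_max largest hole area (px) filled inside a component
#' @param min_area smallest component (px) accepted as a lung field
#' @param min_solidity minimum component area / bounding-box area
#' @return a refined `lung_mask`; if no interior component remains, an
#'   empty mask with a warning
#' @export
refine_lung_mask <- function(mask, keep = 2L, hole_area_max = 500,
                             min_area = 64L, min_solidity = 0.4) {
  stopifnot(inherits(mask, "lung_mask"))
  m <- mask$parenchyma
  lab <- label_components(m)
  if (max(lab) > 0) {
    border <- setdiff(unique(c(lab[1, ], lab[nrow(lab), ],
                               lab[, 1], lab[, ncol(lab)])), 0L)
    lab[lab %in% border] <- 0L
  }
  keep_mask <- matrix(FALSE, nrow(m), ncol(m))
  if (max(lab) > 0) {
    sizes <- tabulate(lab, nbins = max(lab))
    ids <- order(sizes, decreasing = TRUE)
    ids <- ids[sizes[ids] >= min_area]
    solid <- vapply(ids, function(i) {
      idx <- which(lab == i, arr.ind = TRUE)
      sizes[i] / (diff(range(idx[, 1])) + 1) / (diff(range(idx[, 2])) + 1)
    }, numeric(1))
    ids <- ids[solid >= min_solidity]
    ids <- utils::head(ids, keep)
    keep_mask <- lab %in% ids
    dim(keep_mask) <- dim(m)
  }
  if (!any(keep_mask)) {
    warning("no interior parenchyma component found; returning empty lung mask")
    return(binarize_from_logical(keep_mask))
  }
  keep_mask <- fill_small_holes(keep_mask, hole_area_max)
  binarize_from_logical(keep_mask)
}

binarize_from_logical <- function(paren) {
  structure(list(values = matrix(ifelse(paren, 0, 255), nrow(paren), ncol(paren)),
                 parenchyma = paren), class = "lung_mask")
}

#' Segment lung parenchyma on a CT slice
#'
#' Composition of [iterate_threshold()], [binarize_parenchyma()] and
#' [refine_lung_mask()].
#'
#' @param ct a [ct_slice()]
#' @param config optional list overriding `p0`, `sigma`, `max_iter`,
#'   `keep_components`, `hole_area_max`
#' @return a `lung_mask`
#' @export
segment_lung <- function(ct, config = list()) {
  stopifnot(inherits(ct, "ct_slice"))
  st <- iterate_threshold(ct$pixels,
                          p0 = config$p0,
                          sigma = config$sigma %||% 0.5,
                          max_iter = config$max_iter %||% 100L)
  m <- binarize_parenchyma(ct$pixels, st$p_i)
  refine_lung_mask(m,
                   keep = config$keep_components %||% 2L,
                   hole_area_max = config$hole_area_max %||% 500,
                   min_area = config$min_area %||% 64L,
                   min_solidity = config$min_solidity %||% 0.4)
}
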