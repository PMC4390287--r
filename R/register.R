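#' Joint intensity histogram of a reference and a warped floating image
#'
#' The floating image is resampled under `transform` (pull-back about the
#' image center); counts are accumulated only over the overlap region, i.e.
#' reference pixels whose mapped source location falls inside the floating
#' image. Equal-width bins span each image's intensity range over the
#' overlap.
#'
#' @param reference,floating numeric matrices of identical dimension
#' @param transform a [rigid_transform()] applied to the floating image
#' @param bins number of bins per image (>= 2)
#' @param interpolation `"bilinear"` or `"nearest"`
#' @return an object of class `joint_histogram`: `counts` (bins x bins),
#'   `p_ab` (normalized joint distribution), `p_a`, `p_b` (marginals),
#'   `edges_a`, `edges_b`, and `overlap_fraction`
#' @export
joint_histogram <- function(reference, floating, transform = rigid_transform(),
                            bins = 64L, interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stopifnot(bins >= 2, identical(dim(reference), dim(floating)))
  warped <- warp_image(floating, transform, interp = interpolation)
  ok <- !is.na(warped)
  overlap <- mean(ok)
  if (!any(ok)) stop("no overlap between images under the given transform")
  a <- reference[ok]
  b <- warped[ok]
  ia <- bin_index(a, bins)
  ib <- bin_index(b, bins)
  counts <- matrix(tabulate((ib$idx - 1L) * bins + ia$idx, nbins = bins * bins),
                   bins, bins)
  p_ab <- counts / sum(counts)
  structure(list(counts = counts, p_ab = p_ab,
                 p_a = rowSums(p_ab), p_b = colSums(p_ab),
                 edges_a = ia$edges, edges_b = ib$edges,
                 overlap_fraction = overlap),
            class = "joint_histogram")
}

# Equal-width binning over the value range; a constant vector maps to bin 1.
bin_index <- function(v, bins) {
  lo <- min(v); hi <- max(v)
  if (hi <= lo) {
    idx <- rep(1L, length(v))
  } else {
    idx <- pmin(floor((v - lo) / (hi - lo) * bins) + 1L, bins)
  }
  list(idx = as.integer(idx), edges = seq(lo, hi, length.out = bins + 1L))
}

#' Shannon entropy of a probability distribution
#'
#' `-sum(p * log2(p))` with the convention `0 * log 0 = 0`. Log base 2, so
#' entropies are in bits.
#'
#' @param distribution non-negative vector or matrix summing to 1 (within
#'   1e-9)
#' @return entropy in bits
#' @examples
#' shannon_entropy(rep(0.25, 4)) # 2 bits
#' @export
shannon_entropy <- function(distribution) {
  p <- as.numeric(distribution)
  if (any(p < 0)) stop("negative probabilities")
  if (abs(sum(p) - 1) > 1e-9) stop("distribution does not sum to 1")
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Mutual information between a reference and a warped floating image
#'
#' `MI = H(A) + H(B) - H(A, B)`, with all three entropies computed from the
#' same joint histogram (marginals are its row/column sums), so the
#' identity holds to machine precision.
#'
#' @inheritParams joint_histogram
#' @return an object of class `mi_result`: `mi`, `h_a`, `h_b`, `h_ab`,
#'   `overlap_fraction`
#' @export
mutual_information <- function(reference, floating,
                               transform = rigid_transform(), bins = 64L,
                               interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  jh <- joint_histogram(reference, floating, transform, bins, interpolation)
  h_a <- shannon_entropy(jh$p_a)
  h_b <- shannon_entropy(jh$p_b)
  h_ab <- shannon_entropy(jh$p_ab)
  structure(list(mi = h_a + h_b - h_ab, h_a = h_a, h_b = h_b, h_ab = h_ab,
                 overlap_fraction = jh$overlap_fraction),
            class = "mi_result")
}

#' Powell's direction-set minimisation
#'
#' Derivative-free minimisation by cycles of sequential 1-D line
#' minimisations along a set of search directions (initially the coordinate
#' axes). After each cycle the first direction is replaced by the cycle
#' displacement (end minus start of the cycle) and one extra line
#' minimisation is performed along it. Line minimisation brackets the
#' minimum with a coarse scan over `[-line_range, line_range]` and refines
#' it by golden-section/parabolic search ([stats::optimize()]). When a
#' cycle fails to improve the objective by `tol`, the direction set is
#' restarted from the initial axes once before stopping (the replacement
#' rule can make the set linearly dependent).
#'
#' @param objective function of a numeric vector returning a finite scalar
#' @param x0 starting point
#' @param directions matrix whose columns are initial search directions
#'   (default: coordinate axes)
#' @param tol stop when a full cycle improves the objective by less than
#'   this amount
#' @param max_cycles cycle guard
#' @param line_range half-width of the 1-D search bracket, in units of each
#'   direction vector
#' @param line_tol tolerance of the 1-D search
#' @return list with `x` (the minimiser), `value`, `cycles`, and `trace`
#'   (best objective value after each cycle, non-increasing)
#' @examples
#' powell_optimize(function(p) (p[1] - 3)^2 + (p[2] + 1)^2, c(0, 0))$x
#' @export
powell_optimize <- function(objective, x0, directions = NULL, tol = 1e-3,
                            max_cycles = 50L, line_range = 10,
                            line_tol = 1e-4) {
  stopifnot(tol > 0, max_cycles >= 1)
  x <- as.numeric(x0)
  k <- length(x)
  dirs0 <- directions %||% diag(k)
  dirs <- matrix(dirs0, nrow = k)
  f <- function(p) {
    v <- objective(p)
    if (!is.finite(v)) stop("non-finite objective value at ",
                            paste(format(p), collapse = ", "))
    v
  }
  # Bracket the 1-D minimum with a coarse scan (the section of the
  # objective along a direction need not be unimodal), then refine by
  # golden-section/parabolic search inside the bracketing sub-interval.
  line_min <- function(x, s) {
    ts <- seq(-line_range, line_range, length.out = 13L)
    fs <- vapply(ts, function(t) f(x + t * s), numeric(1))
    i <- which.min(fs)
    lo <- ts[max(i - 1L, 1L)]
    hi <- ts[min(i + 1L, length(ts))]
    opt <- stats::optimize(function(t) f(x + t * s), interval = c(lo, hi),
                           tol = line_tol)
    if (fs[i] < opt$objective) {
      list(x = x + ts[i] * s, value = fs[i])
    } else {
      list(x = x + opt$minimum * s, value = opt$objective)
    }
  }
  fx <- f(x)
  trace <- fx
  cycles <- 0L
  repeat {
    cycles <- cycles + 1L
    x_start <- x
    f_start <- fx
    for (j in seq_len(ncol(dirs))) {
      lm <- line_min(x, dirs[, j])
      if (lm$value < fx) { x <- lm$x; fx <- lm$value }
    }
    disp <- x - x_start
    if (sqrt(sum(disp^2)) > 0) {
      dirs[, 1] <- disp
      lm <- line_min(x, disp)
      if (lm$value < fx) { x <- lm$x; fx <- lm$value }
    }
    trace <- c(trace, fx)
    if (cycles >= max_cycles) break
    if (f_start - fx < tol) {
      # The replaced direction set can become (nearly) linearly dependent
      # and stall; restart once from the initial axes and only stop when a
      # fresh-axes cycle also fails to improve.
      if (identical(dirs, matrix(dirs0, nrow = k))) break
      dirs <- matrix(dirs0, nrow = k)
    }
  }
  list(x = x, value = fx, cycles = cycles, trace = trace)
}

#' Rigid PET-to-CT registration by mutual-information maximisation
#'
#' The PET activity map (floating image) is first upsampled to the CT grid
#' (bilinear, shared field of view), then the transform `(tx, ty, theta)`
#' maximising the mutual information between the CT slice and the warped
#' PET is found with [powell_optimize()] on the negated MI, starting from
#' the identity.
#'
#' @param ct a [ct_slice()] (reference)
#' @param pet a [pet_slice()] (floating)
#' @param config optional list overriding `bins` (64), `interpolation`
#'   (`"bilinear"`), `tol` (1e-3, MI units), `max_cycles` (50),
#'   `line_range` (15 px/deg), `line_tol` (0.05)
#' @return list with `transform` (the recovered [rigid_transform()] in CT
#'   pixels), `mi` (the `mi_result` at the optimum), and `trace`
#' @export
register_rigid <- function(ct, pet, config = list()) {
  stopifnot(inherits(ct, "ct_slice"), inherits(pet, "pet_slice"))
  bins <- config$bins %||% 64L
  interp <- config$interpolation %||% "bilinear"
  pet_up <- resample_image(pet$activity, dim(ct$pixels), interp = "bilinear")
  objective <- function(p) {
    -mutual_information(ct$pixels, pet_up,
                        rigid_transform(p[1], p[2], p[3]),
                        bins = bins, interpolation = interp)$mi
  }
  opt <- powell_optimize(objective, c(0, 0, 0),
                         tol = config$tol %||% 1e-3,
                         max_cycles = config$max_cycles %||% 50L,
                         line_range = config$line_range %||% 15,
                         line_tol = config$line_tol %||% 0.05)
  tr <- rigid_transform(opt$x[1], opt$x[2], opt$x[3])
  list(transform = tr,
       mi = mutual_information(ct$pixels, pet_up, tr, bins = bins,
                               interpolation = interp),
       trace = opt$trace)
}
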