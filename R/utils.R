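#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded helpers do not disturb
#' the caller's random stream.
#' @param seed integer seed
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Separable Gaussian blur with replicate edge padding
#'
#' @param img numeric matrix
#' @param sigma standard deviation in pixels; `sigma <= 0` returns `img`
#' @return blurred matrix of the same dimensions
#' @keywords internal
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  nr <- nrow(img); nc <- ncol(img)
  # blur along rows (vertical), then columns, shifting with replicate padding
  pass <- function(m, along_rows) {
    out <- matrix(0, nr, nc)
    for (s in (-r):r) {
      w <- k[s + r + 1L]
      if (along_rows) {
        idx <- clamp(seq_len(nr) + s, 1L, nr)
        out <- out + w * m[idx, , drop = FALSE]
      } else {
        idx <- clamp(seq_len(nc) + s, 1L, nc)
        out <- out + w * m[, idx, drop = FALSE]
      }
    }
    out
  }
  pass(pass(img, TRUE), FALSE)
}

#' Dice overlap coefficient between two binary masks
#'
#' @param a,b logical matrices of identical dimension
#' @return Dice coefficient in \[0, 1\]; 1 when both masks are empty
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  a <- as.logical(a); b <- as.logical(b)
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}

#' Label connected components of a binary mask
#'
#' Thin wrapper around [EBImage::bwlabel()] (4-connectivity).
#' @param mask logical or 0/1 matrix
#' @return integer matrix of component labels (0 = background)
#' @keywords internal
label_components <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  matrix(as.integer(EBImage::bwlabel(m)), nrow(mask), ncol(mask))
}

#' Fill interior holes of a binary mask up to a maximum area
#'
#' A hole is a background component that does not touch the image border.
#' @param mask logical matrix (TRUE = foreground)
#' @param max_area holes with at most this many pixels are filled; `Inf`
#'   fills all interior holes
#' @return logical matrix
#' @keywords internal
fill_small_holes <- function(mask, max_area = Inf) {
  lab <- label_components(!mask)
  if (max(lab) == 0L) return(mask)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  sizes <- tabulate(lab, nbins = max(lab))
  fill <- setdiff(which(sizes <= max_area), c(0L, border))
  mask[lab %in% fill] <- TRUE
  mask
}
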