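#' 2-D rigid transforms
#'
#' A rigid transform is a rotation about the image center followed by a
#' translation, acting on (row, col) pixel coordinates. Pixel centers sit at
#' integer indices (1-based); the rotation center of an `nr x nc` image is
#' `((nr + 1) / 2, (nc + 1) / 2)`. Angles are in degrees, positive in the
#' direction that rotates the +row axis towards the +col axis.
#'
#' As a point map, `T(p) = R(theta) (p - c) + c + (tx, ty)`.
#'
#' @param tx,ty translation along rows / columns, in pixels
#' @param theta rotation angle in degrees
#' @return an object of class `rigid_transform`
#' @examples
#' t <- rigid_transform(5, -3, 10)
#' compose_transforms(t, invert_transform(t)) # ~ identity
#' @export
rigid_transform <- function(tx = 0, ty = 0, theta = 0) {
  stopifnot(is.finite(tx), is.finite(ty), is.finite(theta))
  structure(list(tx = tx, ty = ty, theta = theta), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform: tx = %.4g px, ty = %.4g px, theta = %.4g deg\n",
              x$tx, x$ty, x$theta))
  invisible(x)
}

rotation_matrix <- function(theta_deg) {
  a <- theta_deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

#' Apply a rigid transform to (row, col) points
#'
#' @param t a [rigid_transform()]
#' @param pts n x 2 matrix of (row, col) coordinates
#' @param center length-2 rotation center (row, col)
#' @return n x 2 matrix of transformed coordinates
#' @export
transform_points <- function(t, pts, center) {
  pts <- matrix(pts, ncol = 2)
  R <- rotation_matrix(t$theta)
  sw <- sweep(pts, 2, center)
  out <- sw %*% t(R)
  sweep(out, 2, center + c(t$tx, t$ty), FUN = "+")
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` is the point map `p -> a(b(p))` (apply `b`
#' first). Both transforms must share a rotation center for the closed form
#' used here to hold; in this package all transforms on one grid do.
#' @param a,b [rigid_transform()] objects
#' @return a [rigid_transform()]
#' @export
compose_transforms <- function(a, b) {
  Ra <- rotation_matrix(a$theta)
  tr <- Ra %*% c(b$tx, b$ty) + c(a$tx, a$ty)
  rigid_transform(tr[1], tr[2], a$theta + b$theta)
}

#' Invert a rigid transform
#' @param t a [rigid_transform()]
#' @return the inverse [rigid_transform()]
#' @export
invert_transform <- function(t) {
  Ri <- rotation_matrix(-t$theta)
  tr <- -Ri %*% c(t$tx, t$ty)
  rigid_transform(tr[1], tr[2], -t$theta)
}

#' Rescale a rigid transform between pixel grids
#'
#' Translations scale with the grid spacing; the angle is unchanged. Valid
#' when the two grids share a field of view so that image centers coincide.
#' @param t a [rigid_transform()]
#' @param s grid scale factor (target pixels per source pixel)
#' @return a [rigid_transform()]
#' @export
scale_transform <- function(t, s) rigid_transform(t$tx * s, t$ty * s, t$theta)

#' Resample an image under a rigid transform
#'
#' Pull-back warping: `out[q] = img[T(q)]` with `T` acting about the image
#' center, so warping by `invert_transform(t)` moves image content by `+t`.
#' Output pixels whose source falls outside the image get `fill`.
#'
#' @param img numeric matrix
#' @param t a [rigid_transform()]
#' @param interp `"bilinear"` or `"nearest"`
#' @param fill value for unmapped pixels (default `NA`)
#' @return matrix of the same dimension as `img`
#' @export
warp_image <- function(img, t, interp = c("bilinear", "nearest"), fill = NA_real_) {
  interp <- match.arg(interp)
  nr <- nrow(img); nc <- ncol(img)
  center <- c((nr + 1) / 2, (nc + 1) / 2)
  grid <- cbind(rep(seq_len(nr), times = nc), rep(seq_len(nc), each = nr))
  src <- transform_points(t, grid, center)
  sample_bilinear_or_nn(img, src[, 1], src[, 2], interp, fill, nr, nc)
}

# Vectorised sampling shared by warp_image() and resample_image().
sample_bilinear_or_nn <- function(img, r, c, interp, fill, out_nr, out_nc) {
  nr <- nrow(img); nc <- ncol(img)
  out <- rep(fill, length(r))
  if (interp == "nearest") {
    ri <- round(r); ci <- round(c)
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    out[ok] <- img[cbind(ri[ok], ci[ok])]
  } else {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    r0 <- pmin(floor(r[ok]), nr - 1L); c0 <- pmin(floor(c[ok]), nc - 1L)
    fr <- r[ok] - r0; fc <- c[ok] - c0
    v <- (1 - fr) * (1 - fc) * img[cbind(r0, c0)] +
      fr * (1 - fc) * img[cbind(r0 + 1, c0)] +
      (1 - fr) * fc * img[cbind(r0, c0 + 1)] +
      fr * fc * img[cbind(r0 + 1, c0 + 1)]
    out[ok] <- v
  }
  matrix(out, out_nr, out_nc)
}

#' Resample an image to a new grid size over the same field of view
#'
#' Pixel-center mapping: source index `= (dst - 0.5) * n_src / n_dst + 0.5`,
#' so the image centers of the two grids coincide.
#' @param img numeric matrix
#' @param new_dim length-2 integer (rows, cols)
#' @param interp `"bilinear"` or `"nearest"`
#' @return matrix with dimensions `new_dim`
#' @export
resample_image <- function(img, new_dim, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  nr <- nrow(img); nc <- ncol(img)
  rr <- (seq_len(new_dim[1]) - 0.5) * nr / new_dim[1] + 0.5
  cc <- (seq_len(new_dim[2]) - 0.5) * nc / new_dim[2] + 0.5
  r <- rep(rr, times = new_dim[2])
  c <- rep(cc, each = new_dim[1])
  sample_bilinear_or_nn(img, r, c, interp, NA_real_, new_dim[1], new_dim[2])
}

# Grid maps between the CT grid (n_ct) and the PET grid (n_pet) sharing one
# field of view: ct = (pet - 0.5) * s + 0.5 with s = n_ct / n_pet.
ct_to_pet_points <- function(pts, n_ct, n_pet) {
  (matrix(pts, ncol = 2) - 0.5) * (n_pet / n_ct) + 0.5
}
pet_to_ct_points <- function(pts, n_ct, n_pet) {
  (matrix(pts, ncol = 2) - 0.5) * (n_ct / n_pet) + 0.5
}
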