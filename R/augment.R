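#' Data-augmentation parameters
#'
#' Six randomized transformations applied jointly to a training patch and
#' its label patch: shift, rotation, rescale, flip, blur, elastic
#' deformation. Geometric transforms use mirror fill, bilinear
#' interpolation for the image and nearest-neighbor for the label, so
#' classes always stay in \{0, 1, 2\}.
#'
#' @param shift_max Maximum shift as a fraction of the patch side
#'   (default 0.10); offsets are drawn uniformly in \[0, shift_max * side\]
#'   with random sign on each axis.
#' @param rotation_range Rotation magnitude range in degrees
#'   (default c(5, 89)); sign randomized.
#' @param rescale_range Rescale factor range (default c(1/1.2, 1.2)).
#' @param blur_range Gaussian blur SD range in pixels (default c(0, 4));
#'   the label is never blurred.
#' @param elastic_alpha_range Elastic deformation coefficient range
#'   (default c(1, 8)): per-pixel displacements are drawn uniformly in
#'   \[-1, 1\], Gaussian-smoothed, then scaled by alpha, so alpha bounds the
#'   maximum displacement in pixels.
#' @param elastic_sigma Fixed SD (pixels) of the Gaussian that smooths the
#'   elastic displacement fields (default 4).
#' @param p Per-transform application probability (default 0.5).
#' @return An `augmentation_spec` list.
#' @export
augmentation_spec <- function(shift_max = 0.10, rotation_range = c(5, 89),
                              rescale_range = c(1 / 1.2, 1.2),
                              blur_range = c(0, 4),
                              elastic_alpha_range = c(1, 8),
                              elastic_sigma = 4, p = 0.5) {
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  structure(list(shift_max = shift_max, rotation_range = rotation_range,
                 rescale_range = rescale_range, blur_range = blur_range,
                 elastic_alpha_range = elastic_alpha_range,
                 elastic_sigma = elastic_sigma, p = p),
            class = "augmentation_spec")
}

as_int_mask <- function(m) {
  storage.mode(m) <- "integer"
  m
}

#' Random joint shift of an image patch and its label patch
#'
#' Integer offsets are drawn uniformly in \[0, shift_max * side\] pixels on
#' each axis, with random sign; vacated borders are mirror-filled.
#'
#' @param img Numeric image matrix.
#' @param mask Integer class matrix of the same shape.
#' @param shift_max Maximum shift as a fraction of the patch side.
#' @return `list(image, mask)`.
#' @export
random_shift <- function(img, mask, shift_max = 0.10) {
  side <- nrow(img)
  dr <- sample(c(-1, 1), 1) * floor(runif(1, 0, shift_max * side))
  dc <- sample(c(-1, 1), 1) * floor(runif(1, 0, shift_max * ncol(img)))
  A <- c(1, 0, dr, 0, 1, dc)  # output (r,c) reads input (r+dr, c+dc)
  list(image = cpp_warp_affine(img, A, TRUE),
       mask = as_int_mask(cpp_warp_affine(mask + 0, A, FALSE)))
}

rotation_matrix <- function(theta_deg, h, w) {
  th <- theta_deg * pi / 180
  cy <- (h - 1) / 2
  cx <- (w - 1) / 2
  # output coords rotate by -theta about the patch center to find the source
  c(cos(th), -sin(th), cy - cos(th) * cy + sin(th) * cx,
    sin(th), cos(th), cx - sin(th) * cy - cos(th) * cx)
}

#' Random joint rotation
#'
#' The magnitude is uniform in `rotation_range` degrees with random sign;
#' rotation is about the patch center with mirror fill.
#'
#' @inheritParams random_shift
#' @param rotation_range Magnitude range in degrees.
#' @return `list(image, mask)`.
#' @export
random_rotation <- function(img, mask, rotation_range = c(5, 89)) {
  theta <- sample(c(-1, 1), 1) * runif(1, rotation_range[1], rotation_range[2])
  A <- rotation_matrix(theta, nrow(img), ncol(img))
  list(image = cpp_warp_affine(img, A, TRUE),
       mask = as_int_mask(cpp_warp_affine(mask + 0, A, FALSE)))
}

resize_mat <- function(x, h, w, nearest = FALSE) {
  EBImage::resize(x, w = h, h = w, filter = if (nearest) "none" else "bilinear")
}

rescale_one <- function(x, f, nearest = FALSE) {
  side_r <- nrow(x)
  side_c <- ncol(x)
  if (f == 1) return(x)
  if (f > 1) {           # crop the central floor(side/f) region, upscale back
    sr <- floor(side_r / f)
    sc <- floor(side_c / f)
    r0 <- floor((side_r - sr) / 2)
    c0 <- floor((side_c - sc) / 2)
    resize_mat(x[r0 + seq_len(sr), c0 + seq_len(sc), drop = FALSE],
               side_r, side_c, nearest)
  } else {               # downscale, mirror-pad back to size, centered
    sr <- max(1L, floor(side_r * f))
    sc <- max(1L, floor(side_c * f))
    small <- resize_mat(x, sr, sc, nearest)
    t0 <- floor((side_r - sr) / 2)
    l0 <- floor((side_c - sc) / 2)
    cpp_mirror_pad(small, t0, side_r - sr - t0, l0, side_c - sc - l0)
  }
}

#' Random joint rescale
#'
#' A factor is drawn uniformly in `rescale_range`. Factors above 1 crop the
#' central `floor(side / f)` square and upscale it back to the patch size;
#' factors below 1 downscale and mirror-pad back, centered.
#'
#' @inheritParams random_shift
#' @param rescale_range Scale factor range.
#' @return `list(image, mask)`.
#' @export
random_rescale <- function(img, mask, rescale_range = c(1 / 1.2, 1.2)) {
  f <- runif(1, rescale_range[1], rescale_range[2])
  list(image = rescale_one(img, f, nearest = FALSE),
       mask = as_int_mask(round(rescale_one(mask + 0, f, nearest = TRUE))))
}

#' Random joint flip
#'
#' Flips both patches about the horizontal or vertical axis, chosen
#' uniformly.
#'
#' @inheritParams random_shift
#' @return `list(image, mask)`.
#' @export
random_flip <- function(img, mask) {
  if (runif(1) < 0.5) {
    list(image = img[nrow(img):1, , drop = FALSE],
         mask = mask[nrow(mask):1, , drop = FALSE])
  } else {
    list(image = img[, ncol(img):1, drop = FALSE],
         mask = mask[, ncol(mask):1, drop = FALSE])
  }
}

#' Random Gaussian blur of the image patch only
#'
#' @param img Numeric image matrix.
#' @param blur_range SD range in pixels; the draw is uniform.
#' @return The blurred image matrix.
#' @export
random_blur <- function(img, blur_range = c(0, 4)) {
  s <- runif(1, blur_range[1], blur_range[2])
  cpp_gaussian_blur(img, s)
}

#' Random joint elastic deformation
#'
#' Per-pixel displacement fields are drawn uniformly in \[-1, 1\],
#' Gaussian-smoothed with SD `sigma`, and scaled by a coefficient `alpha`
#' drawn uniformly from `alpha_range`; smoothing averages values in
#' \[-1, 1\], so `alpha` bounds the maximum displacement in pixels. The
#' image is warped bilinearly, the label with nearest-neighbor.
#'
#' @inheritParams random_shift
#' @param alpha_range Deformation coefficient range (pixels).
#' @param sigma Smoothing SD (pixels).
#' @param alpha Optional forced coefficient (e.g. 0 for the identity).
#' @return `list(image, mask)`.
#' @export
elastic_deform <- function(img, mask, alpha_range = c(1, 8), sigma = 4,
                           alpha = NULL) {
  if (is.null(alpha)) alpha <- runif(1, alpha_range[1], alpha_range[2])
  h <- nrow(img)
  w <- ncol(img)
  dr <- matrix(runif(h * w, -1, 1), h, w)
  dc <- matrix(runif(h * w, -1, 1), h, w)
  dr <- alpha * cpp_gaussian_blur(dr, sigma)
  dc <- alpha * cpp_gaussian_blur(dc, sigma)
  list(image = cpp_warp_displacement(img, dr, dc, TRUE),
       mask = as_int_mask(cpp_warp_displacement(mask + 0, dr, dc, FALSE)))
}

#' Apply the full augmentation chain to a patch pair
#'
#' Applies shift, rotation, rescale, flip, blur and elastic deformation in
#' that order, each independently with probability `spec$p`, drawing from
#' R's global random number stream (seed with [set.seed()] for
#' reproducibility).
#'
#' @param img Numeric image matrix.
#' @param mask Integer class matrix of the same shape.
#' @param spec An [augmentation_spec()].
#' @return `list(image, mask, applied)` where `applied` is a named logical
#'   vector recording which transforms fired.
#' @export
augment <- function(img, mask, spec = augmentation_spec()) {
  stopifnot(inherits(spec, "augmentation_spec"))
  fire <- runif(6) < spec$p
  names(fire) <- c("shift", "rotation", "rescale", "flip", "blur", "elastic")
  out <- list(image = img, mask = mask)
  if (fire["shift"])
    out <- random_shift(out$image, out$mask, spec$shift_max)
  if (fire["rotation"])
    out <- random_rotation(out$image, out$mask, spec$rotation_range)
  if (fire["rescale"])
    out <- random_rescale(out$image, out$mask, spec$rescale_range)
  if (fire["flip"])
    out <- random_flip(out$image, out$mask)
  if (fire["blur"])
    out$image <- random_blur(out$image, spec$blur_range)
  if (fire["elastic"])
    out <- elastic_deform(out$image, out$mask, spec$elastic_alpha_range,
                          spec$elastic_sigma)
  out$applied <- fire
  out
}
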