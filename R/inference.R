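#' Overlap-tile parameters
#'
#' Inference windows of `window` pixels overlap by `overlap` pixels on each
#' side; only each window's central `window - 2*overlap` core is emitted,
#' suppressing border artifacts of the fully convolutional network.
#'
#' @param window Inference patch side (default 512).
#' @param overlap Overlap `d` in pixels (default 25; `0 <= d < window/2`).
#' @return A `tiling_spec` with the derived `core` size.
#' @export
tiling_spec <- function(window = 512L, overlap = 25L) {
  window <- as.integer(window)
  overlap <- as.integer(overlap)
  if (overlap < 0 || overlap >= window / 2)
    stop("overlap must satisfy 0 <= d < window/2")
  structure(list(window = window, overlap = overlap,
                 core = window - 2L * overlap),
            class = "tiling_spec")
}

#' Plan the overlap-tile windows for an image
#'
#' The image is conceptually mirror-padded by `overlap` on all sides plus a
#' remainder so that the interior is a multiple of the core size; windows
#' step by the core size and each emits only its central core. Emitted
#' regions (clipped to the image) cover every pixel exactly once.
#'
#' @param height,width Image size in pixels (at the model's pixel size).
#' @param spec A [tiling_spec()].
#' @return Data frame with one row per tile: `window_row`, `window_col`
#'   (0-based origins in the padded frame), `out_row`, `out_col` (0-based
#'   origins in the image frame) and `out_height`, `out_width` (clipped
#'   core extents).
#' @export
plan_tiles <- function(height, width, spec = tiling_spec()) {
  stopifnot(inherits(spec, "tiling_spec"))
  core <- spec$core
  nh <- ceiling(height / core)
  nw <- ceiling(width / core)
  grid <- expand.grid(i = seq_len(nh) - 1L, j = seq_len(nw) - 1L)
  data.frame(
    window_row = grid$i * core,
    window_col = grid$j * core,
    out_row = grid$i * core,
    out_col = grid$j * core,
    out_height = pmin(core, height - grid$i * core),
    out_width = pmin(core, width - grid$j * core))
}

#' Segment an arbitrarily sized image with a trained model
#'
#' The image is bilinearly resampled to the model's working pixel size,
#' mirror-padded, and segmented window by window (each window normalized
#' exactly as during training); the central core of each window's
#' probability map is kept and stitched. The three stitched probability
#' maps are bilinearly resampled back to the native resolution before the
#' per-pixel argmax (ties broken towards the lowest class index), so the
#' returned mask has the input's shape and pixel size.
#'
#' @param img A [scalar_image()] with a known pixel size.
#' @param model A trained `fiberseg_network`.
#' @param tiling A [tiling_spec()]; its window side must be divisible by
#'   `2^depth`.
#' @param return_probs Also return the stitched class-probability maps at
#'   the model's working resolution.
#' @return A [segmentation_mask()] of the input shape, or (with
#'   `return_probs`) `list(mask, probs)` where `probs` is `(H, W, 3)`.
#' @export
segment_image <- function(img, model, tiling = tiling_spec(),
                          return_probs = FALSE) {
  stopifnot(inherits(img, "scalar_image"),
            inherits(model, "fiberseg_network"))
  div <- 2^model$spec$depth
  if (tiling$window %% div != 0)
    stop("tiling window must be divisible by ", div)
  rimg <- resample_image(img, model$spec$pixel_size)
  h <- nrow(rimg$pixels)
  w <- ncol(rimg$pixels)
  core <- tiling$core
  d <- tiling$overlap
  nh <- ceiling(h / core)
  nw <- ceiling(w / core)
  padded <- mirror_pad(rimg$pixels, d, d + nh * core - h,
                       d, d + nw * core - w)
  tiles <- plan_tiles(h, w, tiling)
  probs <- array(0, dim = c(nh * core, nw * core, 3L))
  for (t in seq_len(nrow(tiles))) {
    wr <- tiles$window_row[t]
    wc <- tiles$window_col[t]
    win <- padded[wr + seq_len(tiling$window), wc + seq_len(tiling$window),
                  drop = FALSE]
    fw <- nn_forward(model, normalize_patch(win), training = FALSE)
    cr <- d + seq_len(core)
    probs[tiles$out_row[t] + seq_len(core),
          tiles$out_col[t] + seq_len(core), ] <- fw$probs[cr, cr, , 1]
  }
  probs <- probs[seq_len(h), seq_len(w), , drop = FALSE]
  native <- dim(img$pixels)
  if (!identical(c(h, w), native)) {
    out <- array(0, dim = c(native, 3L))
    for (c in 1:3)
      out[, , c] <- EBImage::resize(probs[, , c], w = native[1],
                                    h = native[2], filter = "bilinear")
  } else {
    out <- probs
  }
  cls <- channel_argmax(array(out, dim = c(dim(out), 1L)))[, , 1]
  mask <- segmentation_mask(cls, img$pixel_size)
  if (return_probs) list(mask = mask, probs = probs) else mask
}
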