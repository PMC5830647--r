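#' Grayscale microscopy image with physical pixel size
#'
#' A `scalar_image` couples a 2-d intensity grid (8-bit on disk, real-valued
#' in memory, nominal range 0-255) with its isotropic pixel size in
#' micrometers. Row-major, 0-based, origin at the top-left corner.
#'
#' @param pixels Numeric matrix of intensities (rows = image rows).
#' @param pixel_size Isotropic pixel size in micrometers (> 0).
#' @return An object of class `scalar_image` with elements `pixels` and
#'   `pixel_size`.
#' @export
scalar_image <- function(pixels, pixel_size) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("`pixels` must be a non-empty numeric matrix")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      is.na(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number (um per pixel)")
  structure(list(pixels = pixels, pixel_size = as.numeric(pixel_size)),
            class = "scalar_image")
}

#' @export
print.scalar_image <- function(x, ...) {
  cat(sprintf("<scalar_image> %d x %d pixels, %.4g um/pixel\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size))
  invisible(x)
}

#' Three-class segmentation mask (background / myelin / axon)
#'
#' Class indices are 0 = background, 1 = myelin, 2 = axon. On disk the mask
#' is an 8-bit PNG with the conventional encoding background = 0,
#' myelin = 127, axon = 255; [decode_mask()] and [encode_mask()] convert.
#'
#' @param classes Matrix with values in \{0, 1, 2\}.
#' @param pixel_size Isotropic pixel size in micrometers (> 0).
#' @return An object of class `segmentation_mask`.
#' @export
segmentation_mask <- function(classes, pixel_size) {
  classes <- as.matrix(classes)
  storage.mode(classes) <- "integer"
  bad <- setdiff(unique(as.vector(classes)), c(0L, 1L, 2L))
  if (length(bad))
    stop("mask classes must be in {0, 1, 2}; found: ",
         paste(bad, collapse = ", "))
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number (um per pixel)")
  structure(list(classes = classes, pixel_size = as.numeric(pixel_size)),
            class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  tab <- tabulate(as.vector(x$classes) + 1L, 3L)
  cat(sprintf(
    "<segmentation_mask> %d x %d pixels, %.4g um/pixel (bg %d, myelin %d, axon %d)\n",
    nrow(x$classes), ncol(x$classes), x$pixel_size, tab[1], tab[2], tab[3]))
  invisible(x)
}

read_pixels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (use PNG or TIFF)"))
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3]
    rgb <- arr[, , seq_len(min(nc, 3L)), drop = FALSE]
    rng <- apply(rgb, c(1, 2), function(v) max(v) - min(v))
    if (max(rng) > 0)
      stop("multi-channel image with differing channels; ",
           "convert to grayscale before reading")
    arr <- rgb[, , 1L]
  }
  round(arr * 255)
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

read_sidecar_pixel_size <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("no pixel size given and no sidecar found at ", sc)
  meta <- jsonlite::read_json(sc)
  ps <- meta$pixel_size_um
  if (is.null(ps)) stop("sidecar ", sc, " has no `pixel_size_um` field")
  as.numeric(ps)
}

#' Read a grayscale image from PNG or TIFF
#'
#' @param path Path to an 8-bit grayscale PNG or TIFF file.
#' @param pixel_size Pixel size in micrometers. If `NULL`, a JSON sidecar
#'   `<basename>.json` with a `pixel_size_um` field is read instead.
#' @return A [scalar_image()].
#' @export
read_image <- function(path, pixel_size = NULL) {
  if (is.null(pixel_size)) pixel_size <- read_sidecar_pixel_size(path)
  scalar_image(read_pixels(path), pixel_size)
}

#' Write a grayscale image as 8-bit PNG/TIFF plus a pixel-size sidecar
#'
#' Intensities are clamped to \[0, 255\] and quantized to 8 bits. A JSON
#' sidecar `{"pixel_size_um": x}` is written next to the image.
#'
#' @param img A [scalar_image()].
#' @param path Output path (.png, .tif or .tiff).
#' @param sidecar Write the JSON sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, sidecar = TRUE) {
  stopifnot(inherits(img, "scalar_image"))
  px <- pmin(pmax(round(img$pixels), 0), 255) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(px, path),
    tif = ,
    tiff = tiff::writeTIFF(px, path, bits.per.sample = 8L),
    stop("unsupported image format: .", ext))
  if (sidecar)
    jsonlite::write_json(list(pixel_size_um = img$pixel_size),
                         sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Decode a 0/127/255 label image into a 3-class mask
#'
#' @param label Matrix of 8-bit label values; only 0 (background),
#'   127 (myelin) and 255 (axon) are allowed.
#' @param pixel_size Pixel size in micrometers.
#' @return A [segmentation_mask()].
#' @export
decode_mask <- function(label, pixel_size) {
  label <- as.matrix(label)
  bad <- setdiff(unique(as.vector(label)), c(0, 127, 255))
  if (length(bad))
    stop("label image contains values outside {0, 127, 255}: ",
         paste(bad, collapse = ", "))
  cls <- matrix(0L, nrow(label), ncol(label))
  cls[label == 127] <- 1L
  cls[label == 255] <- 2L
  segmentation_mask(cls, pixel_size)
}

#' Encode a 3-class mask as a 0/127/255 label matrix
#'
#' @param mask A [segmentation_mask()].
#' @return Integer matrix with values in \{0, 127, 255\}.
#' @export
encode_mask <- function(mask) {
  stopifnot(inherits(mask, "segmentation_mask"))
  out <- matrix(c(0L, 127L, 255L)[mask$classes + 1L],
                nrow(mask$classes), ncol(mask$classes))
  out
}

#' Read / write segmentation masks in the 0/127/255 PNG encoding
#'
#' @param path PNG path.
#' @param pixel_size Pixel size in micrometers; if `NULL` the JSON sidecar
#'   is consulted.
#' @return `read_mask()` returns a [segmentation_mask()].
#' @export
read_mask <- function(path, pixel_size = NULL) {
  if (is.null(pixel_size)) pixel_size <- read_sidecar_pixel_size(path)
  decode_mask(read_pixels(path), pixel_size)
}

#' @rdname read_mask
#' @param mask A [segmentation_mask()].
#' @param sidecar Write the JSON pixel-size sidecar (default `TRUE`).
#' @export
write_mask <- function(mask, path, sidecar = TRUE) {
  png::writePNG(encode_mask(mask) / 255, path)
  if (sidecar)
    jsonlite::write_json(list(pixel_size_um = mask$pixel_size),
                         sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

resampled_shape <- function(shape, from, to) {
  out <- round(shape * from / to)
  if (any(out < 1))
    stop("resampling to ", to, " um/pixel yields a degenerate image")
  as.integer(out)
}

#' Resample an image to a target pixel size (bilinear)
#'
#' The output grid has `round(shape * pixel_size / target)` pixels per side;
#' intensities are bilinearly interpolated. Resampling to the current pixel
#' size returns the input unchanged.
#'
#' @param img A [scalar_image()].
#' @param target_pixel_size Target pixel size in micrometers (> 0).
#' @return A [scalar_image()] at the target pixel size.
#' @export
resample_image <- function(img, target_pixel_size) {
  stopifnot(inherits(img, "scalar_image"))
  if (target_pixel_size <= 0) stop("target pixel size must be positive")
  if (target_pixel_size == img$pixel_size) return(img)
  sh <- resampled_shape(dim(img$pixels), img$pixel_size, target_pixel_size)
  px <- EBImage::resize(img$pixels, w = sh[1], h = sh[2], filter = "bilinear")
  scalar_image(px, target_pixel_size)
}

#' Resample a mask to a target pixel size (nearest-neighbor)
#'
#' Labels are interpolated with nearest-neighbor so classes stay in
#' \{0, 1, 2\}.
#'
#' @param mask A [segmentation_mask()].
#' @param target_pixel_size Target pixel size in micrometers (> 0).
#' @return A [segmentation_mask()] at the target pixel size.
#' @export
resample_mask <- function(mask, target_pixel_size) {
  stopifnot(inherits(mask, "segmentation_mask"))
  if (target_pixel_size <= 0) stop("target pixel size must be positive")
  if (target_pixel_size == mask$pixel_size) return(mask)
  sh <- resampled_shape(dim(mask$classes), mask$pixel_size, target_pixel_size)
  cls <- EBImage::resize(mask$classes + 0, w = sh[1], h = sh[2],
                         filter = "none")
  segmentation_mask(cls, target_pixel_size)
}

#' Mirror-pad a matrix
#'
#' Reflection padding without edge repetition, used wherever patches or
#' tiles extend past the image border.
#'
#' @param x Numeric matrix.
#' @param top,bottom,left,right Number of rows/columns to add on each side.
#' @return The padded matrix.
#' @export
mirror_pad <- function(x, top = 0L, bottom = 0L, left = 0L, right = 0L) {
  cpp_mirror_pad(as.matrix(x) + 0, as.integer(top), as.integer(bottom),
                 as.integer(left), as.integer(right))
}

#' Cut an image (and its mask) into non-overlapping square patches
#'
#' The canvas is mirror-padded so each side becomes the next multiple of
#' `patch_size`, then tiled by a regular grid. Patch origins (top-left
#' corners, 0-based) are recorded in the padded frame.
#'
#' @param img A [scalar_image()].
#' @param mask Optional [segmentation_mask()] of identical shape and pixel
#'   size.
#' @param patch_size Patch side in pixels (default 512).
#' @return A `patch_set`: list with `images` (list of matrices), `masks`
#'   (list or `NULL`), `origins` (data frame `origin_row`, `origin_col`),
#'   `split` (per-patch `"train"`/`"val"`/`NA`), and geometry metadata.
#' @export
extract_patches <- function(img, mask = NULL, patch_size = 512L) {
  stopifnot(inherits(img, "scalar_image"))
  sh <- dim(img$pixels)
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "segmentation_mask"))
    if (!identical(dim(mask$classes), sh))
      stop("image and mask shapes differ")
    if (mask$pixel_size != img$pixel_size)
      stop("image and mask pixel sizes differ")
  }
  patch_size <- as.integer(patch_size)
  padded <- as.integer(ceiling(sh / patch_size) * patch_size)
  pimg <- mirror_pad(img$pixels, 0L, padded[1] - sh[1], 0L, padded[2] - sh[2])
  pmask <- if (!is.null(mask))
    mirror_pad(mask$classes, 0L, padded[1] - sh[1], 0L, padded[2] - sh[2])
  grid <- expand.grid(
    origin_row = seq(0L, padded[1] - patch_size, by = patch_size),
    origin_col = seq(0L, padded[2] - patch_size, by = patch_size))
  images <- vector("list", nrow(grid))
  masks <- if (!is.null(mask)) vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    r <- grid$origin_row[i] + seq_len(patch_size)
    co <- grid$origin_col[i] + seq_len(patch_size)
    images[[i]] <- pimg[r, co, drop = FALSE]
    if (!is.null(mask)) {
      m <- pmask[r, co, drop = FALSE]
      storage.mode(m) <- "integer"
      masks[[i]] <- m
    }
  }
  structure(list(images = images, masks = masks, origins = grid,
                 split = rep(NA_character_, nrow(grid)),
                 patch_size = patch_size, pixel_size = img$pixel_size,
                 padded_shape = padded, original_shape = as.integer(sh)),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches of %d x %d (%d train / %d val / %d unsplit)\n",
              length(x$images), x$patch_size, x$patch_size,
              sum(x$split == "train", na.rm = TRUE),
              sum(x$split == "val", na.rm = TRUE), sum(is.na(x$split))))
  invisible(x)
}

#' Restitch a patch set into the original image
#'
#' Places every patch back at its recorded origin and crops the mirror
#' padding; exactly inverts [extract_patches()].
#'
#' @param ps A `patch_set`.
#' @param what `"images"` or `"masks"`.
#' @return A matrix of the original image shape.
#' @export
restitch_patches <- function(ps, what = c("images", "masks")) {
  what <- match.arg(what)
  src <- ps[[what]]
  if (is.null(src)) stop("patch set has no ", what)
  canvas <- matrix(0, ps$padded_shape[1], ps$padded_shape[2])
  for (i in seq_along(src)) {
    r <- ps$origins$origin_row[i] + seq_len(ps$patch_size)
    co <- ps$origins$origin_col[i] + seq_len(ps$patch_size)
    canvas[r, co] <- src[[i]]
  }
  canvas[seq_len(ps$original_shape[1]), seq_len(ps$original_shape[2]),
         drop = FALSE]
}

#' Global 256-bin histogram equalization
#'
#' @param x Numeric matrix with intensities on the 0-255 scale.
#' @return Equalized matrix on the 0-255 scale.
#' @export
equalize_hist <- function(x) {
  b <- pmin(pmax(floor(x), 0), 255)
  counts <- tabulate(b + 1L, 256L)
  cdf <- cumsum(counts) / length(x)
  out <- 255 * cdf[b + 1L]
  matrix(out, nrow(x), ncol(x))
}

#' Normalize a patch: histogram equalization then standardization
#'
#' Applies global 256-bin histogram equalization first, then centers and
#' scales to zero mean and unit variance (variance floored at 1e-8, so a
#' constant patch maps to all zeros).
#'
#' @param patch Numeric matrix of intensities on the 0-255 scale.
#' @return Numeric matrix with mean 0 and (for non-constant input) SD 1.
#' @export
normalize_patch <- function(patch) {
  y <- equalize_hist(patch)
  m <- mean(y)
  v <- max(mean((y - m)^2), 1e-8)
  (y - m) / sqrt(v)
}

#' Randomly split a patch set into training and validation patches
#'
#' @param ps A `patch_set` with at least 2 patches.
#' @param fraction Training fraction; the train count is
#'   `round(fraction * n)` (default 0.7).
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @return The patch set with its `split` field assigned.
#' @export
split_train_val <- function(ps, fraction = 0.7, seed = NULL) {
  stopifnot(inherits(ps, "patch_set"))
  n <- length(ps$images)
  if (n < 2L) stop("need at least 2 patches to split")
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  idx <- with_seed(seed, sample.int(n))
  n_train <- round(fraction * n)
  split <- rep("val", n)
  split[idx[seq_len(n_train)]] <- "train"
  if (n_train == n)
    warning("training fraction leaves an empty validation set")
  ps$split <- split
  ps
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Persist / load a patch set as paired PNGs plus an index TSV
#'
#' Writes `patch_0001.png`, `mask_0001.png`, ... along with `index.tsv`
#' (`patch`, `origin_row`, `origin_col`, `split`) and `meta.json`.
#'
#' @param ps A `patch_set`.
#' @param dir Output directory (created if needed).
#' @return `save_patchset()` returns `dir`; `load_patchset()` the
#'   `patch_set`.
#' @export
save_patchset <- function(ps, dir) {
  stopifnot(inherits(ps, "patch_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(ps$images)) {
    png::writePNG(pmin(pmax(round(ps$images[[i]]), 0), 255) / 255,
                  file.path(dir, sprintf("patch_%04d.png", i)))
    if (!is.null(ps$masks)) {
      enc <- matrix(c(0, 127, 255)[ps$masks[[i]] + 1L],
                    nrow(ps$masks[[i]]), ncol(ps$masks[[i]]))
      png::writePNG(enc / 255, file.path(dir, sprintf("mask_%04d.png", i)))
    }
  }
  idx <- cbind(data.frame(patch = seq_along(ps$images)), ps$origins,
               data.frame(split = ps$split))
  write.table(idx, file.path(dir, "index.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(patch_size = ps$patch_size, pixel_size = ps$pixel_size,
         padded_shape = ps$padded_shape, original_shape = ps$original_shape,
         has_masks = !is.null(ps$masks)),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_patchset
#' @export
load_patchset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  idx <- read.delim(file.path(dir, "index.tsv"))
  images <- lapply(idx$patch, function(i)
    read_pixels(file.path(dir, sprintf("patch_%04d.png", i))))
  masks <- NULL
  if (isTRUE(meta$has_masks))
    masks <- lapply(idx$patch, function(i) {
      m <- read_pixels(file.path(dir, sprintf("mask_%04d.png", i)))
      cls <- matrix(0L, nrow(m), ncol(m))
      cls[m == 127] <- 1L
      cls[m == 255] <- 2L
      cls
    })
  structure(list(images = images, masks = masks,
                 origins = idx[, c("origin_row", "origin_col")],
                 split = as.character(idx$split),
                 patch_size = as.integer(meta$patch_size),
                 pixel_size = as.numeric(meta$pixel_size),
                 padded_shape = as.integer(unlist(meta$padded_shape)),
                 original_shape = as.integer(unlist(meta$original_shape))),
            class = "patch_set")
}
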