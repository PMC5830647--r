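#' Sample a non-overlapping population of myelinated fibers
#'
#' Fibers are modelled as annuli: an axon disk of diameter `d` wrapped by a
#' myelin sheath out to the fiber diameter `d / g`, where `g` is the fiber's
#' g-ratio. Centers are placed by dart throwing with rejection: a candidate
#' is kept only if it keeps every pairwise center distance at least the sum
#' of the two outer radii, and lies at least its own outer radius away from
#' the canvas border (so no fiber is clipped).
#'
#' Defaults emulate white-matter tissue at the working resolution of the
#' segmentation model: log-normal axon diameters (median 3 um, log-SD 0.3)
#' and truncated-normal g-ratios (mean 0.7, SD 0.05, bounds 0.4-0.95),
#' giving the 0.5-0.75 g-ratio range typical of healthy fibers.
#'
#' @param n_fibers Number of fibers to place (>= 1).
#' @param diameter_distribution List describing the axon-diameter law:
#'   `list(type = "lognormal", median, sdlog, min = NULL, max = NULL)`
#'   (diameters in micrometers; optional truncation by rejection).
#' @param g_ratio_distribution List `list(mean, sd, lower, upper)` for the
#'   truncated-normal g-ratio law.
#' @param canvas_size_um Canvas side in micrometers (default 102.4, i.e. a
#'   1024-pixel square at 0.1 um/pixel, so patching is exercised).
#' @param pixel_size Pixel size in micrometers (default 0.1).
#' @param min_gap_um Minimum clearance between fiber boundaries in
#'   micrometers (default 0.2, two pixels at the default resolution). A
#'   small extracellular gap keeps neighbouring sheaths from sharing
#'   rasterized pixels, so every fiber is one connected object.
#' @param seed Optional integer seed (caller's RNG preserved).
#' @param max_attempts Dart-throwing budget per fiber before giving up.
#' @return A `fiber_population`: data frame `fibers` with columns
#'   `center_row_um`, `center_col_um`, `axon_diameter_um`, `g_ratio`, plus
#'   `canvas_size_um` and `pixel_size`.
#' @export
sample_population <- function(n_fibers,
                              diameter_distribution = list(
                                type = "lognormal", median = 3, sdlog = 0.3,
                                min = NULL, max = NULL),
                              g_ratio_distribution = list(
                                mean = 0.7, sd = 0.05,
                                lower = 0.4, upper = 0.95),
                              canvas_size_um = 102.4,
                              pixel_size = 0.1,
                              min_gap_um = 0.2,
                              seed = NULL,
                              max_attempts = 10000L) {
  if (n_fibers < 1L) stop("n_fibers must be >= 1")
  dd <- modifyList(list(type = "lognormal", median = 3, sdlog = 0.3,
                        min = NULL, max = NULL), diameter_distribution)
  gd <- modifyList(list(mean = 0.7, sd = 0.05, lower = 0.4, upper = 0.95),
                   g_ratio_distribution)
  draw_d <- function() {
    for (i in 1:1000) {
      d <- rlnorm(1, meanlog = log(dd$median), sdlog = dd$sdlog)
      if ((is.null(dd$min) || d >= dd$min) && (is.null(dd$max) || d <= dd$max))
        return(d)
    }
    stop("diameter truncation bounds reject everything")
  }
  draw_g <- function() {
    for (i in 1:1000) {
      g <- rnorm(1, gd$mean, gd$sd)
      if (g > gd$lower && g < gd$upper) return(g)
    }
    stop("g-ratio truncation bounds reject everything")
  }
  fibers <- with_seed(seed, {
    cr <- cc <- d <- g <- r_out <- numeric(n_fibers)
    for (i in seq_len(n_fibers)) {
      placed <- FALSE
      for (a in seq_len(max_attempts)) {
        di <- draw_d()
        gi <- draw_g()
        ri <- di / (2 * gi)
        if (2 * ri >= canvas_size_um) next  # cannot fit; rejected attempt
        y <- runif(1, ri, canvas_size_um - ri)
        x <- runif(1, ri, canvas_size_um - ri)
        if (i == 1L ||
            all(sqrt((cr[seq_len(i - 1)] - y)^2 +
                     (cc[seq_len(i - 1)] - x)^2) >=
                r_out[seq_len(i - 1)] + ri + min_gap_um)) {
          cr[i] <- y; cc[i] <- x; d[i] <- di; g[i] <- gi; r_out[i] <- ri
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place fiber ", i, " after ", max_attempts,
             " attempts; canvas too crowded")
    }
    data.frame(center_row_um = cr, center_col_um = cc,
               axon_diameter_um = d, g_ratio = g)
  })
  structure(list(fibers = fibers, canvas_size_um = canvas_size_um,
                 pixel_size = pixel_size),
            class = "fiber_population")
}

#' @export
print.fiber_population <- function(x, ...) {
  cat(sprintf("<fiber_population> %d fibers on a %.4g um canvas (%.4g um/pixel)\n",
              nrow(x$fibers), x$canvas_size_um, x$pixel_size))
  invisible(x)
}

#' Rasterize a fiber population into a 3-class ground-truth mask
#'
#' A pixel belongs to a region iff its center lies inside it: within
#' `axon_diameter/2` of a fiber center it is axon (class 2), within the
#' outer radius `axon_diameter / (2 g)` it is myelin (class 1), otherwise
#' background. Pixel (i, j) has its center at ((i+0.5) ps, (j+0.5) ps) um.
#' Point sampling (no anti-aliasing) keeps the mask exactly 3-valued.
#'
#' @param pop A `fiber_population`.
#' @return A [segmentation_mask()] covering the canvas.
#' @export
rasterize <- function(pop) {
  stopifnot(inherits(pop, "fiber_population"))
  ps <- pop$pixel_size
  n <- as.integer(round(pop$canvas_size_um / ps))
  cls <- matrix(0L, n, n)
  f <- pop$fibers
  for (i in seq_len(nrow(f))) {
    r_ax <- f$axon_diameter_um[i] / 2
    r_out <- r_ax / f$g_ratio[i]
    rows <- max(1L, floor((f$center_row_um[i] - r_out) / ps)):
            min(n, ceiling((f$center_row_um[i] + r_out) / ps))
    cols <- max(1L, floor((f$center_col_um[i] - r_out) / ps)):
            min(n, ceiling((f$center_col_um[i] + r_out) / ps))
    cy <- (rows - 0.5) * ps - f$center_row_um[i]
    cx <- (cols - 0.5) * ps - f$center_col_um[i]
    d2 <- outer(cy^2, cx^2, `+`)
    sub <- cls[rows, cols, drop = FALSE]
    sub[d2 <= r_out^2] <- 1L
    sub[d2 <= r_ax^2] <- 2L
    cls[rows, cols] <- sub
  }
  segmentation_mask(cls, ps)
}

#' Rendering parameters for synthetic electron-microscopy appearance
#'
#' Class-wise mean intensities plus Gaussian blur and i.i.d. Gaussian noise
#' emulate osmium-stained EM contrast. The `"tem"` polarity renders myelin
#' dark (transmission EM-like), `"sem"` renders myelin bright (scanning
#' EM-like).
#'
#' @param polarity `"tem"` (myelin-dark) or `"sem"` (myelin-bright).
#' @param background,myelin,axon Mean 8-bit intensities per class; defaults
#'   depend on `polarity`.
#' @param noise_sd SD of the additive Gaussian noise (8-bit scale,
#'   default 10).
#' @param blur_sd SD of the Gaussian blur in pixels (default 1).
#' @return A `render_spec` list.
#' @export
render_spec <- function(polarity = c("tem", "sem"), background = NULL,
                        myelin = NULL, axon = NULL, noise_sd = 10,
                        blur_sd = 1) {
  polarity <- match.arg(polarity)
  def <- if (polarity == "tem") c(bg = 130, my = 50, ax = 200)
         else c(bg = 130, my = 210, ax = 70)
  spec <- list(polarity = polarity,
               background = if (is.null(background)) def[["bg"]] else background,
               myelin = if (is.null(myelin)) def[["my"]] else myelin,
               axon = if (is.null(axon)) def[["ax"]] else axon,
               noise_sd = noise_sd, blur_sd = blur_sd)
  with(spec, {
    if (any(c(background, myelin, axon) < 0 | c(background, myelin, axon) > 255))
      stop("class intensities must lie in [0, 255]")
    if (noise_sd < 0) stop("noise_sd must be >= 0")
  })
  structure(spec, class = "render_spec")
}

#' Render a mask into a synthetic EM intensity image
#'
#' Paints class-wise mean intensities, applies Gaussian blur, adds i.i.d.
#' Gaussian noise, and clips to \[0, 255\].
#'
#' @param mask A [segmentation_mask()].
#' @param spec A [render_spec()].
#' @param seed Optional integer seed for the noise (caller's RNG preserved).
#' @return A [scalar_image()] with the mask's pixel size.
#' @export
render <- function(mask, spec = render_spec(), seed = NULL) {
  stopifnot(inherits(mask, "segmentation_mask"), inherits(spec, "render_spec"))
  levels <- c(spec$background, spec$myelin, spec$axon)
  img <- matrix(levels[mask$classes + 1L], nrow(mask$classes),
                ncol(mask$classes))
  if (spec$blur_sd > 0) img <- cpp_gaussian_blur(img, spec$blur_sd)
  if (spec$noise_sd > 0)
    img <- img + with_seed(seed,
      matrix(rnorm(length(img), 0, spec$noise_sd), nrow(img), ncol(img)))
  scalar_image(pmin(pmax(img, 0), 255), mask$pixel_size)
}

#' Generate a synthetic dataset on disk with exact morphometric ground truth
#'
#' Writes `image_%03d.png` / `mask_%03d.png` pairs (with pixel-size
#' sidecars) and a per-fiber TSV `fibers.tsv` (image id, center, axon
#' diameter, g-ratio) usable as ground truth for morphometry validation.
#'
#' @param out_dir Output directory.
#' @param n_images Number of image/mask pairs.
#' @param n_fibers Fibers per image.
#' @param render_params A [render_spec()].
#' @param seed Integer seed; image `i` uses sub-seeds derived from it, so a
#'   rerun is byte-identical.
#' @param ... Passed on to [sample_population()].
#' @return Invisibly, the per-fiber ground-truth data frame.
#' @export
generate_dataset <- function(out_dir, n_images = 3L, n_fibers = 40L,
                             render_params = render_spec(), seed = 1L, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  tables <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    pop <- sample_population(n_fibers, seed = seed * 1000L + i, ...)
    mask <- rasterize(pop)
    img <- render(mask, render_params, seed = seed * 1000L + 500L + i)
    write_image(img, file.path(out_dir, sprintf("image_%03d.png", i)))
    write_mask(mask, file.path(out_dir, sprintf("mask_%03d.png", i)))
    tables[[i]] <- cbind(data.frame(image = i), pop$fibers)
  }
  truth <- do.call(rbind, tables)
  write.table(format(truth, digits = 10, trim = TRUE, scientific = FALSE),
              file.path(out_dir, "fibers.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(truth)
}
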