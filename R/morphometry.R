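#' Per-axon morphometric table
#'
#' 8-connected components of the axon class, with area in square
#' micrometers (pixel count x pixel_size^2), centroid in micrometers
#' (pixel centers, origin at the top-left image corner) and equivalent
#' diameter `sqrt(4 * Area / pi)`.
#'
#' @param mask A [segmentation_mask()] with a pixel size.
#' @return Data frame with columns `id`, `centroid_row_um`,
#'   `centroid_col_um`, `area_um2`, `diameter_um`.
#' @export
axon_table <- function(mask) {
  stopifnot(inherits(mask, "segmentation_mask"))
  ps <- mask$pixel_size
  lab <- cpp_label8(matrix(as.integer(mask$classes == 2L),
                           nrow(mask$classes), ncol(mask$classes)))
  cents <- component_centroids(lab)
  data.frame(id = cents$id,
             centroid_row_um = (cents$row - 0.5) * ps,
             centroid_col_um = (cents$col - 0.5) * ps,
             area_um2 = cents$area * ps^2,
             diameter_um = sqrt(4 * cents$area * ps^2 / pi))
}

#' Binned morphometric maps
#'
#' Tiles the mask into square bins of `bin_size_um` a side (default
#' 50 x 50 um^2) and computes per bin: axon volume fraction (AVF, axon
#' pixel fraction), myelin volume fraction (MVF), aggregate g-ratio
#' `sqrt(1 / (1 + MVF/AVF))`, axon density (axon centroids per mm^2), and
#' the mean and SD of the equivalent axon diameters of the axons whose
#' centroid falls in the bin (each axon counted in exactly one bin).
#' Partial edge bins, bins without axon pixels, and bins with less than
#' 50% region-mask coverage are flagged invalid.
#'
#' @param mask A [segmentation_mask()].
#' @param bin_size_um Bin side in micrometers (default 50; must span at
#'   least 2 pixels).
#' @param region_mask Optional logical/0-1 matrix of the mask's shape
#'   selecting the tissue region to keep (e.g. white matter).
#' @return Data frame with one row per bin: `bin_row`, `bin_col` (1-based),
#'   `row0_um`, `col0_um` (bin origin), `avf`, `mvf`, `g_ratio`,
#'   `density_per_mm2`, `diameter_mean_um`, `diameter_sd_um`, `n_axons`,
#'   `valid`.
#' @export
grid_metrics <- function(mask, bin_size_um = 50, region_mask = NULL) {
  stopifnot(inherits(mask, "segmentation_mask"))
  ps <- mask$pixel_size
  bin_px <- round(bin_size_um / ps)
  if (bin_px < 2) stop("bin size must span at least 2 pixels")
  cls <- mask$classes
  sh <- dim(cls)
  if (!is.null(region_mask) && !identical(dim(region_mask), sh))
    stop("region mask shape differs from the segmentation mask")
  nb <- ceiling(sh / bin_px)
  ax <- axon_table(mask)
  bin_um <- bin_px * ps
  ax$bin_row <- pmin(floor(ax$centroid_row_um / bin_um) + 1L, nb[1])
  ax$bin_col <- pmin(floor(ax$centroid_col_um / bin_um) + 1L, nb[2])
  out <- expand.grid(bin_row = seq_len(nb[1]), bin_col = seq_len(nb[2]))
  n <- nrow(out)
  out$row0_um <- (out$bin_row - 1L) * bin_um
  out$col0_um <- (out$bin_col - 1L) * bin_um
  out$avf <- out$mvf <- out$g_ratio <- out$density_per_mm2 <- NA_real_
  out$diameter_mean_um <- out$diameter_sd_um <- NA_real_
  out$n_axons <- 0L
  out$valid <- FALSE
  bin_area_mm2 <- (bin_um^2) / 1e6
  for (i in seq_len(n)) {
    r <- ((out$bin_row[i] - 1L) * bin_px + 1L):min(out$bin_row[i] * bin_px,
                                                   sh[1])
    co <- ((out$bin_col[i] - 1L) * bin_px + 1L):min(out$bin_col[i] * bin_px,
                                                    sh[2])
    full <- length(r) == bin_px && length(co) == bin_px
    sub <- cls[r, co, drop = FALSE]
    npx <- length(sub)
    out$avf[i] <- sum(sub == 2L) / npx
    out$mvf[i] <- sum(sub == 1L) / npx
    out$g_ratio[i] <- if (out$avf[i] > 0)
      sqrt(1 / (1 + out$mvf[i] / out$avf[i])) else NA_real_
    in_bin <- ax$bin_row == out$bin_row[i] & ax$bin_col == out$bin_col[i]
    out$n_axons[i] <- sum(in_bin)
    out$density_per_mm2[i] <- sum(in_bin) / bin_area_mm2
    if (any(in_bin)) {
      out$diameter_mean_um[i] <- mean(ax$diameter_um[in_bin])
      out$diameter_sd_um[i] <- sd(ax$diameter_um[in_bin])
    }
    coverage <- if (is.null(region_mask)) 1
                else mean(region_mask[r, co] != 0)
    out$valid[i] <- full && out$avf[i] > 0 && coverage >= 0.5
  }
  attr(out, "bin_size_um") <- bin_um
  attr(out, "bin_px") <- bin_px
  attr(out, "pixel_size") <- ps
  out
}

#' Compare measured morphometry against generator ground truth
#'
#' Labels whole fibers (axon + myelin components; fibers never touch by
#' construction), measures each fiber's equivalent axon diameter and
#' g-ratio `sqrt(axon area / fiber area)` from the mask, and matches
#' fibers to the generated truth table by nearest center. Summaries give
#' the bias and RMSE of both quantities plus the object-count check.
#'
#' @param mask A rasterized [segmentation_mask()] from [rasterize()] (or a
#'   prediction of it).
#' @param truth Data frame of generated fibers with columns
#'   `center_row_um`, `center_col_um`, `axon_diameter_um`, `g_ratio`
#'   (e.g. `pop$fibers` or rows of `fibers.tsv`).
#' @return List with `per_fiber` (matched table with measurement errors)
#'   and `summary` (`n_truth`, `n_measured`, `count_match`,
#'   `diameter_bias_um`, `diameter_rmse_um`, `g_bias`, `g_rmse`).
#' @export
recover_population <- function(mask, truth) {
  stopifnot(inherits(mask, "segmentation_mask"))
  ps <- mask$pixel_size
  cls <- mask$classes
  lab <- cpp_label8(matrix(as.integer(cls > 0L), nrow(cls), ncol(cls)))
  n <- max(lab)
  meas <- data.frame(id = seq_len(n), row_um = NA_real_, col_um = NA_real_,
                     diameter_um = NA_real_, g = NA_real_)
  for (i in seq_len(n)) {
    sel <- lab == i
    fib_px <- sum(sel)
    ax_px <- sum(sel & cls == 2L)
    idx <- which(sel, arr.ind = TRUE)
    meas$row_um[i] <- (mean(idx[, 1]) - 0.5) * ps
    meas$col_um[i] <- (mean(idx[, 2]) - 0.5) * ps
    meas$diameter_um[i] <- sqrt(4 * ax_px * ps^2 / pi)
    meas$g[i] <- sqrt(ax_px / fib_px)
  }
  per <- truth
  per$measured_diameter_um <- per$measured_g <- NA_real_
  for (j in seq_len(nrow(truth))) {
    if (!n) break
    d2 <- (meas$row_um - truth$center_row_um[j])^2 +
          (meas$col_um - truth$center_col_um[j])^2
    k <- which.min(d2)
    per$measured_diameter_um[j] <- meas$diameter_um[k]
    per$measured_g[j] <- meas$g[k]
  }
  dd <- per$measured_diameter_um - per$axon_diameter_um
  dg <- per$measured_g - per$g_ratio
  list(per_fiber = per,
       summary = list(
         n_truth = nrow(truth), n_measured = n,
         count_match = n == nrow(truth),
         diameter_bias_um = mean(dd, na.rm = TRUE),
         diameter_rmse_um = sqrt(mean(dd^2, na.rm = TRUE)),
         g_bias = mean(dg, na.rm = TRUE),
         g_rmse = sqrt(mean(dg^2, na.rm = TRUE))))
}
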