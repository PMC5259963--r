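#' Crop the valid region of a stack
#'
#' Extracts the sub-stack covered by the ROI box and depth window, preserving
#' pitch metadata and adjusting `depth_origin` to the first retained slice.
#'
#' @param stack an [image_stack()].
#' @param roi a [roi()].
#' @return The cropped `image_stack`.
#' @export
crop_valid <- function(stack, roi) {
  check_roi_bounds(stack, roi)
  ks <- slices_in_window(stack, roi$depths)
  sub <- stack$intensities[roi$rows[1]:roi$rows[2],
                           roi$cols[1]:roi$cols[2], ks, drop = FALSE]
  image_stack(sub, stack$lateral_pitch, stack$axial_step,
              depth_origin = slice_depths(stack)[ks[1]])
}

#' Contrast-enhance an optical section
#'
#' Linear contrast stretch of a single slice to its 1st-99th percentile
#' window, rescaled to `[0, 1]` with clipping. The mapping is monotone, so
#' pixel ordering (hence any rank-based threshold) is preserved on
#' non-clipped pixels.
#'
#' @param slice 2D numeric matrix.
#' @param probs lower/upper percentile of the stretch window.
#' @return Matrix of the same shape with values in `[0, 1]`.
#' @export
enhance <- function(slice, probs = c(0.01, 0.99)) {
  if (length(slice) == 0) tb_stop("tb_degenerate_image", "empty slice")
  rng <- range(slice)
  if (rng[1] == rng[2])
    tb_stop("tb_degenerate_image",
            "constant image: no threshold separates pores from tissue")
  q <- stats::quantile(slice, probs, names = FALSE)
  if (q[1] == q[2]) q <- rng  # heavily quantized image: fall back to full range
  out <- (slice - q[1]) / (q[2] - q[1])
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Gray-histogram segmentation threshold (Otsu)
#'
#' Returns the intensity threshold maximizing the between-class variance of
#' the gray histogram (Otsu's criterion) on a fixed-bin histogram over the
#' slice's intensity range; ties are broken toward the lower threshold. The
#' returned value lies strictly between the minimum and maximum intensity.
#'
#' @param slice 2D numeric matrix with at least two distinct values.
#' @param nbins number of histogram bins.
#' @return Scalar threshold on the intensity scale of `slice`.
#' @export
histogram_threshold <- function(slice, nbins = 256L) {
  rng <- range(slice)
  if (rng[1] == rng[2])
    tb_stop("tb_degenerate_image",
            "needs >= 2 distinct intensities to place a threshold")
  # bin i (1-based) covers [mn + (i-1)w, mn + iw); max value goes in last bin
  bin <- pmin(floor((slice - rng[1]) / (rng[2] - rng[1]) * nbins) + 1L, nbins)
  counts <- tabulate(bin, nbins)
  n <- length(slice)
  w0 <- cumsum(counts) / n
  mids <- rng[1] + (seq_len(nbins) - 0.5) * (rng[2] - rng[1]) / nbins
  mu0 <- cumsum(counts * mids) / n        # unnormalized class-0 mean * w0
  mu_t <- mu0[nbins]
  # between-class variance for a cut after bin t (classes: bins <= t vs > t)
  t_idx <- seq_len(nbins - 1L)
  w0t <- w0[t_idx]
  valid <- w0t > 0 & w0t < 1
  sigma_b <- rep(-Inf, nbins - 1L)
  sigma_b[valid] <- (mu_t * w0t[valid] - mu0[t_idx][valid])^2 /
    (w0t[valid] * (1 - w0t[valid]))
  t_best <- which.max(sigma_b)  # which.max takes the first (lowest) maximizer
  rng[1] + t_best * (rng[2] - rng[1]) / nbins
}

#' Segment pores in an optical section
#'
#' Pores are signal voids: the pore mask is the strictly-below-threshold
#' pixel set.
#'
#' @param slice 2D numeric matrix.
#' @param threshold scalar intensity threshold.
#' @return Logical matrix, `TRUE` at pore pixels.
#' @export
segment_pores <- function(slice, threshold) {
  slice < threshold
}

#' Depth-resolved TM porosity profile
#'
#' Runs the full porosity pipeline per optical section inside the ROI:
#' crop the valid region, contrast-enhance, derive a per-slice gray-histogram
#' threshold, segment pores, and report the pore-area ratio
#' `pore_pixels / valid_pixels`. Per-slice thresholds absorb the
#' depth-dependent attenuation of two-photon signal. Slices on which no
#' threshold can be placed are reported in the `failed` attribute with their
#' reason, never silently dropped.
#'
#' @param stack an [image_stack()].
#' @param roi a [roi()] delimiting the valid TM region and depth window.
#' @return A data.frame of class `porosity_profile` with columns `depth_um`,
#'   `porosity`, `threshold`, `pore_pixels`, `valid_pixels`, sorted by depth;
#'   attribute `failed` lists skipped depths and reasons.
#' @export
porosity_profile <- function(stack, roi) {
  cropped <- crop_valid(stack, roi)
  z <- slice_depths(cropped)
  rows <- list(); failed <- list()
  for (k in seq_along(z)) {
    sl <- cropped$intensities[, , k]
    res <- tryCatch({
      enh <- enhance(sl)
      thr <- histogram_threshold(enh)
      mask <- segment_pores(enh, thr)
      data.frame(depth_um = z[k], porosity = sum(mask) / length(mask),
                 threshold = thr, pore_pixels = sum(mask),
                 valid_pixels = length(mask))
    }, tb_degenerate_image = function(e) e)
    if (inherits(res, "condition")) {
      failed[[length(failed) + 1L]] <-
        data.frame(depth_um = z[k], reason = conditionMessage(res))
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(depth_um = numeric(), porosity = numeric(),
               threshold = numeric(), pore_pixels = integer(),
               valid_pixels = integer())
  out <- out[order(out$depth_um), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "failed") <- if (length(failed)) do.call(rbind, failed) else NULL
  class(out) <- c("porosity_profile", "data.frame")
  out
}

#' @export
print.porosity_profile <- function(x, ...) {
  cat(sprintf("porosity_profile: %d depths", nrow(x)))
  if (nrow(x))
    cat(sprintf(", porosity %0.3f..%0.3f over %g..%g um",
                min(x$porosity), max(x$porosity),
                min(x$depth_um), max(x$depth_um)))
  cat("\n")
  print.data.frame(x, ...)
  f <- attr(x, "failed")
  if (!is.null(f)) {
    cat("failed slices:\n")
    print.data.frame(f)
  }
  invisible(x)
}
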