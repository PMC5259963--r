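#' Render a label volume into a synthetic two-photon intensity stack
#'
#' Imaging model: collagen-bearing classes (cornea, sclera, TM beams) emit a
#' high mean signal and fluid-filled voids (TM pores, SC lumen, vein lumen)
#' near-zero signal; the mean is attenuated by `exp(-depth /
#' attenuation_length)` to emulate scattering losses with depth, blurred by an
#' anisotropic Gaussian PSF, and finally corrupted by Poisson shot noise plus
#' Gaussian read noise. Output counts are integers clamped to the 16-bit
#' range. Rendering is deterministic given `config$seed` and never modifies
#' the label volume.
#'
#' @param labels a [label_volume()], geometrically consistent with `config`.
#' @param config the `scene_config` that generated `labels`.
#' @param noise if `FALSE`, skip shot and read noise and return the rounded
#'   deterministic mean signal (the infinite-photon limit).
#' @return An [image_stack()].
#' @export
render_intensities <- function(labels, config, noise = TRUE) {
  if (!inherits(labels, "label_volume"))
    tb_stop("tb_invalid_input", "labels must be a label_volume")
  d <- dim(labels$labels)
  if (!all(d == config$stack_shape[c(2, 3, 1)]))
    tb_stop("tb_invalid_input", "labels and config have inconsistent shapes")

  lg <- labels$legend
  # Relative emission per class; all tissue well above half, all voids well
  # below, so a half-intensity threshold recovers the tissue mask in the
  # noise-free, unblurred limit.
  emission <- c(background = 0.01, cornea = 0.95, sclera = 1.0, tm_beam = 1.0,
                tm_pore = 0.02, sc_lumen = 0.02, vein_lumen = 0.02)
  lut <- numeric(max(lg) + 1L)
  lut[lg + 1L] <- emission[names(lg)]

  mean_counts <- array(lut[as.integer(labels$labels) + 1L], dim = d)
  z <- slice_depths(labels)
  att <- if (is.finite(config$attenuation_length))
    exp(-z / config$attenuation_length) else rep(1, length(z))
  scale <- config$noise$photon_scale
  for (k in seq_len(d[3]))
    mean_counts[, , k] <- mean_counts[, , k] * (scale * att[k])

  mean_counts <- blur_stack(mean_counts,
                            sigma_lat = config$psf_sigma[1] / config$lateral_pitch,
                            sigma_ax  = config$psf_sigma[2] / config$axial_step)

  if (noise) {
    counts <- with_seed(config$seed + 2L, {
      n <- stats::rpois(length(mean_counts), lambda = as.vector(mean_counts))
      if (config$noise$read_sigma > 0)
        n <- n + stats::rnorm(length(n), sd = config$noise$read_sigma)
      n
    })
  } else {
    counts <- as.vector(mean_counts)
  }
  counts <- round(pmin(pmax(counts, 0), 65535))
  image_stack(array(counts, dim = d), config$lateral_pitch,
              config$axial_step, config$depth_origin)
}

# Separable anisotropic Gaussian blur: lateral per-slice, then axial across
# slices with a discrete kernel (skipped when the sd is negligible).
blur_stack <- function(x, sigma_lat, sigma_ax) {
  d <- dim(x)
  if (sigma_lat > 0.05) {
    for (k in seq_len(d[3]))
      x[, , k] <- EBImage::gblur(x[, , k], sigma = sigma_lat)
  }
  if (sigma_ax > 0.05) {
    half <- max(1L, ceiling(3 * sigma_ax))
    w <- stats::dnorm(-half:half, sd = sigma_ax)
    w <- w / sum(w)
    out <- array(0, dim = d)
    for (k in seq_len(d[3])) {
      acc <- matrix(0, d[1], d[2])
      wsum <- 0
      for (j in -half:half) {
        kk <- k + j
        if (kk < 1 || kk > d[3]) next
        acc <- acc + w[j + half + 1L] * x[, , kk]
        wsum <- wsum + w[j + half + 1L]
      }
      out[, , k] <- acc / wsum
    }
    x <- out
  }
  x
}
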