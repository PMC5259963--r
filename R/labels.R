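#' Voxelize a synthetic limbus scene into ground-truth labels
#'
#' Realizes the scene geometry of a [scene_config()] as a semantic label
#' volume. In-plane, columns left of the TM box are cornea and columns right
#' of it are sclera. Within the TM box, at depths inside the TM window, a
#' beam/pore texture is generated by thresholding spatially correlated
#' Gaussian noise (correlation length set by `beam_thickness_mean`); the
#' per-slice threshold is the order statistic of the target pore fraction, so
#' the realized pore fraction matches the interpolated porosity profile to
#' within half a pixel in area. Schlemm's canal is carved as an elliptical
#' void inside the sclera and the aqueous vein (trunk plus branch) as
#' near-axial circular voids.
#'
#' Generation is deterministic given `config$seed`.
#'
#' @param config a `scene_config`.
#' @return A [label_volume()].
#' @export
build_labels <- function(config) {
  validate_scene_config(config)
  check_tm_feasible(config)
  s <- config$stack_shape
  ns <- s[1]; nr <- s[2]; nc <- s[3]
  lg <- scene_legend()
  pl <- config$lateral_pitch
  depths <- config$depth_origin + (seq_len(ns) - 1) * config$axial_step

  tm <- config$tm_roi
  base <- matrix(lg[["sclera"]], nr, nc)
  if (tm$cols[1] > 1) base[, seq_len(tm$cols[1] - 1)] <- lg[["cornea"]]

  labels <- array(0L, dim = c(nr, nc, ns))
  rows_g <- matrix(seq_len(nr), nr, nc)
  cols_g <- matrix(seq_len(nc), nr, nc, byrow = TRUE)

  tm_rows <- tm$rows[1]:tm$rows[2]
  tm_cols <- tm$cols[1]:tm$cols[2]
  sigma_px <- beam_sigma_px(config)

  with_seed(config$seed + 1L, {
    for (k in seq_len(ns)) {
      sl <- base
      d <- depths[k]

      if (d >= tm$depths[1] - 1e-9 && d <= tm$depths[2] + 1e-9) {
        p <- stats::approx(config$porosity_knots$depth_um,
                           config$porosity_knots$porosity,
                           xout = d, rule = 2)$y
        tex <- tm_texture(length(tm_rows), length(tm_cols), sigma_px, p)
        tm_block <- matrix(lg[["tm_beam"]], length(tm_rows), length(tm_cols))
        tm_block[tex] <- lg[["tm_pore"]]
        sl[tm_rows, tm_cols] <- tm_block
      }

      sc <- interp_path(config$sc_path, d,
                        c("row", "col", "major_um", "minor_um"))
      if (!is.null(sc)) {
        a <- sc$major_um / 2; b <- sc$minor_um / 2
        inside <- (((cols_g - sc$col) * pl) / a)^2 +
                  (((rows_g - sc$row) * pl) / b)^2 <= 1
        sl[inside] <- lg[["sc_lumen"]]
      }

      for (vp in list(config$vein_path, config$vein_branch)) {
        v <- interp_path(vp, d, c("row", "col", "diameter_um"))
        if (!is.null(v)) {
          r <- v$diameter_um / 2
          inside <- ((cols_g - v$col) * pl)^2 + ((rows_g - v$row) * pl)^2 <= r^2
          sl[inside] <- lg[["vein_lumen"]]
        }
      }
      labels[, , k] <- sl
    }
  })

  label_volume(labels, lg, config$lateral_pitch, config$axial_step,
               config$depth_origin)
}

beam_sigma_px <- function(config) {
  config$beam_thickness_mean / (2 * config$lateral_pitch)
}

# Reject TM boxes too small to carry the beam/pore texture: the pore-fraction
# order statistic needs enough pixels for sub-0.02 accuracy and the box must
# hold several beam correlation lengths.
check_tm_feasible <- function(config) {
  tm <- config$tm_roi
  nr <- tm$rows[2] - tm$rows[1] + 1L
  nc <- tm$cols[2] - tm$cols[1] + 1L
  sigma_px <- beam_sigma_px(config)
  if (nr * nc < 100 || min(nr, nc) < 4 * sigma_px)
    tb_stop("tb_infeasible_geometry", sprintf(
      paste0("TM box (%d x %d px) too small to realize the porosity target ",
             "with beam thickness %g um (needs >= 100 px and >= %g px across)"),
      nr, nc, config$beam_thickness_mean, ceiling(4 * sigma_px)))
  invisible(TRUE)
}

# Correlated-noise pore texture: smooth white noise at the beam correlation
# length, then mark as pore exactly the `round(p * n)` lowest values.
tm_texture <- function(nr, nc, sigma_px, p) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (sigma_px > 0) z <- EBImage::gblur(z, sigma = sigma_px)
  k <- round(p * length(z))
  pore <- matrix(FALSE, nr, nc)
  if (k > 0) pore[order(z)[seq_len(k)]] <- TRUE
  pore
}

#' Realized per-slice pore fraction of a label volume
#'
#' Ground-truth pore fraction `tm_pore / (tm_pore + tm_beam)` for every slice
#' that contains TM texture; the reference against which the porosity
#' estimation pipeline is validated.
#'
#' @param labels a `label_volume`.
#' @return data.frame with columns `depth_um` and `pore_fraction`.
#' @export
label_pore_fraction <- function(labels) {
  lg <- labels$legend
  z <- slice_depths(labels)
  out <- lapply(seq_along(z), function(k) {
    sl <- labels$labels[, , k]
    npore <- sum(sl == lg[["tm_pore"]])
    nbeam <- sum(sl == lg[["tm_beam"]])
    if (npore + nbeam == 0) return(NULL)
    data.frame(depth_um = z[k], pore_fraction = npore / (npore + nbeam))
  })
  do.call(rbind, out)
}
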