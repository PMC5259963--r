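#' Configure a synthetic limbus scene
#'
#' Describes the geometry and imaging model of a synthetic two-photon optical
#' section stack of the limbal drainage pathway: a porous trabecular meshwork
#' (TM) band between cornea (left) and sclera (right), an elliptical
#' signal-void Schlemm's canal (SC) inside the sclera with depth-varying
#' diameter, a branching signal-void aqueous vein near the surface,
#' depth-dependent signal attenuation and photon shot noise.
#'
#' Depths are measured from the eye surface (0 um); slice `k` of the stack
#' lies at `depth_origin + (k - 1) * axial_step` um. In-plane, everything left
#' of the TM box is cornea and everything right of it is sclera; the TM box
#' itself is filled with beam/pore texture at TM depths and with sclera
#' elsewhere.
#'
#' @param stack_shape integer vector `c(slices, rows, cols)`.
#' @param lateral_pitch in-plane pixel size, um/pixel.
#' @param axial_step slice spacing, um.
#' @param depth_origin depth of slice 1 below the surface, um.
#' @param tm_roi a [roi()] delimiting the TM band (in-plane box and depth
#'   window over which beam/pore texture is generated).
#' @param porosity_knots data.frame with columns `depth_um` (strictly
#'   increasing) and `porosity` (in `[0, 1]`); the per-slice target pore
#'   fraction is linearly interpolated between knots.
#' @param sc_path data.frame with columns `depth_um`, `row`, `col` (voxel
#'   coords of the SC centroid) and `major_um`, `minor_um` (ellipse diameters,
#'   um, > 0); interpolated per slice over its depth range.
#' @param vein_path data.frame with columns `depth_um`, `row`, `col`,
#'   `diameter_um` for the main aqueous vein trunk (a near-axial tube).
#' @param vein_branch like `vein_path`, for the side branch; may be `NULL`.
#' @param beam_thickness_mean characteristic TM beam thickness, um; sets the
#'   correlation length of the beam/pore texture.
#' @param noise list with `photon_scale` (mean counts from undimmed tissue)
#'   and `read_sigma` (Gaussian read noise sd, counts).
#' @param attenuation_length depth scale of exponential signal loss, um;
#'   `Inf` disables attenuation.
#' @param psf_sigma numeric `c(lateral, axial)` Gaussian PSF sd in um;
#'   zero disables blurring along that axis.
#' @param seed integer RNG seed making label generation and rendering
#'   deterministic.
#' @return An object of class `scene_config`.
#' @seealso [default_intact_config()], [default_broken_config()],
#'   [build_labels()], [render_intensities()]
#' @export
scene_config <- function(stack_shape, lateral_pitch, axial_step, depth_origin,
                         tm_roi, porosity_knots, sc_path = NULL,
                         vein_path = NULL, vein_branch = NULL,
                         beam_thickness_mean = 12,
                         noise = list(photon_scale = 2000, read_sigma = 5),
                         attenuation_length = 180,
                         psf_sigma = c(lateral = 2, axial = 1),
                         seed = 42L) {
  cfg <- structure(list(
    stack_shape = as.integer(stack_shape),
    lateral_pitch = as.numeric(lateral_pitch),
    axial_step = as.numeric(axial_step),
    depth_origin = as.numeric(depth_origin),
    tm_roi = tm_roi,
    porosity_knots = porosity_knots,
    sc_path = sc_path,
    vein_path = vein_path,
    vein_branch = vein_branch,
    beam_thickness_mean = as.numeric(beam_thickness_mean),
    noise = noise,
    attenuation_length = as.numeric(attenuation_length),
    psf_sigma = as.numeric(psf_sigma),
    seed = as.integer(seed)
  ), class = "scene_config")
  validate_scene_config(cfg)
  cfg
}

validate_scene_config <- function(cfg) {
  s <- cfg$stack_shape
  if (length(s) != 3 || any(s < 1))
    tb_stop("tb_invalid_input", "stack_shape must be (slices, rows, cols), all >= 1")
  if (cfg$lateral_pitch <= 0 || cfg$axial_step <= 0)
    tb_stop("tb_invalid_input", "lateral_pitch and axial_step must be > 0")
  pk <- cfg$porosity_knots
  if (!is.data.frame(pk) || !all(c("depth_um", "porosity") %in% names(pk)))
    tb_stop("tb_invalid_input", "porosity_knots needs columns depth_um, porosity")
  if (any(pk$porosity < 0 | pk$porosity > 1))
    tb_stop("tb_invalid_input", "porosity knot values must lie in [0, 1]")
  if (nrow(pk) > 1 && any(diff(pk$depth_um) <= 0))
    tb_stop("tb_invalid_input", "porosity knot depths must be strictly increasing")
  r <- cfg$tm_roi
  if (!inherits(r, "tb_roi")) tb_stop("tb_invalid_input", "tm_roi must be a roi()")
  if (r$rows[1] < 1 || r$rows[2] > s[2] || r$cols[1] < 1 || r$cols[2] > s[3])
    tb_stop("tb_invalid_input", "tm_roi does not fit inside stack_shape")
  for (nm in c("sc_path", "vein_path", "vein_branch")) {
    p <- cfg[[nm]]
    if (is.null(p)) next
    dcol <- intersect(c("major_um", "minor_um", "diameter_um"), names(p))
    if (any(unlist(p[dcol]) <= 0))
      tb_stop("tb_invalid_input", sprintf("%s diameters must be > 0", nm))
  }
  if (!is.finite(cfg$noise$photon_scale) || cfg$noise$photon_scale <= 0)
    tb_stop("tb_invalid_input", "noise$photon_scale must be positive and finite")
  if (cfg$noise$read_sigma < 0)
    tb_stop("tb_invalid_input", "noise$read_sigma must be >= 0")
  if (any(cfg$psf_sigma < 0) || length(cfg$psf_sigma) != 2)
    tb_stop("tb_invalid_input", "psf_sigma must be c(lateral, axial) >= 0")
  if (cfg$attenuation_length <= 0)
    tb_stop("tb_invalid_input", "attenuation_length must be > 0 (Inf allowed)")
  invisible(TRUE)
}

#' @export
print.scene_config <- function(x, ...) {
  s <- x$stack_shape
  cat(sprintf("scene_config: %d slices of %d x %d px (pitch %g um, step %g um)\n",
              s[1], s[2], s[3], x$lateral_pitch, x$axial_step))
  cat(sprintf("  depths %g..%g um; seed %d\n", x$depth_origin,
              x$depth_origin + (s[1] - 1) * x$axial_step, x$seed))
  cat(sprintf("  TM porosity %g -> %g over %g..%g um\n",
              x$porosity_knots$porosity[1],
              x$porosity_knots$porosity[nrow(x$porosity_knots)],
              x$porosity_knots$depth_um[1],
              x$porosity_knots$depth_um[nrow(x$porosity_knots)]))
  if (!is.null(x$sc_path))
    cat(sprintf("  SC diameter %g..%g um over %g..%g um depth\n",
                min(x$sc_path$major_um), max(x$sc_path$major_um),
                min(x$sc_path$depth_um), max(x$sc_path$depth_um)))
  if (!is.null(x$vein_path))
    cat(sprintf("  vein diameter %g..%g um over %g..%g um depth\n",
                min(x$vein_path$diameter_um), max(x$vein_path$diameter_um),
                min(x$vein_path$depth_um), max(x$vein_path$depth_um)))
  invisible(x)
}

#' Default synthetic scene: intact (normal IOP) eye
#'
#' The calibration of the default scene reproduces the measured ranges of the
#' rat limbal drainage pathway under normal intraocular pressure: TM porosity
#' rising linearly from 0.63 at 185 um depth to 0.74 at 215 um; SC diameter
#' rising from 48 um at 190 um depth to a 64.67 um peak at 207 um and falling
#' to 52 um at 215 um; aqueous vein diameters spanning 32-43 um over depths
#' 95-120 um, with a smaller side branch near the surface. Imaging geometry:
#' 512 x 512 px slices at 2 um lateral pitch, 5 um axial step, stack covering
#' depths 90-220 um so that the vein, TM and SC windows all exist in one
#' acquisition.
#'
#' @param seed integer RNG seed; the documented default is 42.
#' @return A `scene_config`.
#' @export
default_intact_config <- function(seed = 42L) {
  nslices <- 27L; nrows <- 512L; ncols <- 512L
  sc_path <- data.frame(
    depth_um = c(190, 207, 215),
    row      = c(256, 256, 256),
    col      = c(356, 360, 364),
    major_um = c(48, 64.67, 52),
    minor_um = c(48, 64.67, 52)
  )
  vein_path <- data.frame(
    depth_um    = c(95, 120),
    row         = c(132, 148),
    col         = c(336, 348),
    diameter_um = c(32, 43)
  )
  # Branch diverges laterally; junction with the trunk falls between sampled
  # slices so trunk and branch stay disjoint in every optical section.
  vein_branch <- data.frame(
    depth_um    = c(95, 105),
    row         = c(172, 186),
    col         = c(328, 318),
    diameter_um = c(18, 14)
  )
  scene_config(
    stack_shape = c(nslices, nrows, ncols),
    lateral_pitch = 2, axial_step = 5, depth_origin = 90,
    tm_roi = roi(rows = c(113, 400), cols = c(217, 296), depths = c(185, 215)),
    porosity_knots = data.frame(depth_um = c(185, 215), porosity = c(0.63, 0.74)),
    sc_path = sc_path, vein_path = vein_path, vein_branch = vein_branch,
    seed = seed
  )
}

#' Default synthetic scene: broken (high IOP / depressurized) eye
#'
#' Identical geometry to [default_intact_config()] except that the TM porosity
#' knots run 0.44 -> 0.59 over the same 185-215 um depth window, emulating TM
#' collapse when the pressure balance across the tissue is lost. The same
#' preset stands for both the "high IOP" and the "broken" (depressurized)
#' condition; both names denote the reduced-porosity state.
#'
#' @inheritParams default_intact_config
#' @return A `scene_config`.
#' @export
default_broken_config <- function(seed = 42L) {
  cfg <- default_intact_config(seed = seed)
  cfg$porosity_knots$porosity <- c(0.44, 0.59)
  cfg
}

#' @rdname default_broken_config
#' @export
default_high_iop_config <- default_broken_config

#' Default measurement ROIs for a synthetic scene
#'
#' Derive the region-of-interest boxes used by the measurement pipelines from
#' a scene configuration: the TM porosity ROI is the configured TM box; the
#' SC and vein ROIs are the bounding boxes of the respective centreline paths
#' dilated by the maximum lumen radius plus a margin.
#'
#' @param config a `scene_config`.
#' @param margin_px extra in-plane margin around luminal structures, pixels.
#' @return A [roi()].
#' @export
default_tm_roi <- function(config) config$tm_roi

#' @rdname default_tm_roi
#' @export
default_sc_roi <- function(config, margin_px = 14L) {
  path_roi(config, config$sc_path, max(config$sc_path$major_um), margin_px)
}

#' @rdname default_tm_roi
#' @export
default_vein_roi <- function(config, margin_px = 14L) {
  p <- rbind(
    config$vein_path[c("depth_um", "row", "col", "diameter_um")],
    if (!is.null(config$vein_branch))
      config$vein_branch[c("depth_um", "row", "col", "diameter_um")]
  )
  path_roi(config, p, max(p$diameter_um), margin_px,
           depths = range(config$vein_path$depth_um))
}

path_roi <- function(config, path, max_diam_um, margin_px, depths = NULL) {
  if (is.null(path)) tb_stop("tb_invalid_input", "scene has no such structure")
  rad_px <- ceiling(max_diam_um / 2 / config$lateral_pitch) + margin_px
  s <- config$stack_shape
  roi(
    rows = c(max(1L, floor(min(path$row)) - rad_px),
             min(s[2], ceiling(max(path$row)) + rad_px)),
    cols = c(max(1L, floor(min(path$col)) - rad_px),
             min(s[3], ceiling(max(path$col)) + rad_px)),
    depths = if (is.null(depths)) range(path$depth_um) else depths
  )
}

# Linear interpolation of a path data.frame at a given depth; NULL outside
# the path's depth range.
interp_path <- function(path, depth, cols) {
  if (is.null(path)) return(NULL)
  rng <- range(path$depth_um)
  if (depth < rng[1] - 1e-9 || depth > rng[2] + 1e-9) return(NULL)
  out <- lapply(cols, function(cn)
    stats::approx(path$depth_um, path[[cn]], xout = depth, rule = 2)$y)
  names(out) <- cols
  out
}
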