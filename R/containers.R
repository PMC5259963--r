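#' Construct a 3D intensity image stack
#'
#' An `image_stack` is a 3D non-negative intensity array (row, column, slice)
#' with physical voxel pitch and a depth origin. The depth convention follows
#' trans-scleral optical sectioning: the eye surface is depth 0 um and the
#' physical depth of slice `k` (1-based) is `depth_origin + (k - 1) * axial_step`.
#'
#' @param intensities 3D numeric array, dimensions (rows, cols, slices);
#'   all values finite and >= 0.
#' @param lateral_pitch in-plane pixel size, um/pixel (> 0).
#' @param axial_step distance between consecutive slices, um (> 0).
#' @param depth_origin depth of the first slice below the eye surface, um.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(intensities, lateral_pitch, axial_step, depth_origin = 0) {
  if (length(dim(intensities)) != 3L)
    tb_stop("tb_invalid_input", "intensities must be a 3D array (rows, cols, slices)")
  if (!all(is.finite(intensities)) || any(intensities < 0))
    tb_stop("tb_invalid_input", "intensities must be finite and non-negative")
  if (!is.numeric(lateral_pitch) || lateral_pitch <= 0 ||
      !is.numeric(axial_step) || axial_step <= 0)
    tb_stop("tb_invalid_input", "lateral_pitch and axial_step must be positive")
  structure(list(
    intensities = intensities,
    lateral_pitch = as.numeric(lateral_pitch),
    axial_step = as.numeric(axial_step),
    depth_origin = as.numeric(depth_origin)
  ), class = "image_stack")
}

#' Physical depths of the slices of a stack or label volume
#'
#' @param x an `image_stack` or `label_volume`.
#' @return Numeric vector of slice depths in um, one per slice.
#' @export
slice_depths <- function(x) {
  d <- dim(if (inherits(x, "label_volume")) x$labels else x$intensities)
  x$depth_origin + (seq_len(d[3]) - 1) * x$axial_step
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("image_stack: %d x %d px, %d slices\n", d[1], d[2], d[3]))
  cat(sprintf("  lateral pitch %g um, axial step %g um, depths %g..%g um\n",
              x$lateral_pitch, x$axial_step,
              x$depth_origin, x$depth_origin + (d[3] - 1) * x$axial_step))
  cat(sprintf("  intensity range [%g, %g]\n",
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' Semantic label legend of the synthetic limbus scene
#'
#' Integer codes of the voxel classes used by the generator: background,
#' cornea, sclera, trabecular meshwork beams and pores, Schlemm's canal
#' lumen, aqueous vein lumen.
#'
#' @return Named integer vector mapping class name to label id.
#' @export
scene_legend <- function() {
  c(background = 0L, cornea = 1L, sclera = 2L, tm_beam = 3L,
    tm_pore = 4L, sc_lumen = 5L, vein_lumen = 6L)
}

#' Construct a voxel label volume
#'
#' Ground-truth semantic labels aligned voxel-for-voxel with an intensity
#' stack; used to validate the measurement pipelines by parameter recovery.
#'
#' @param labels 3D integer array (rows, cols, slices).
#' @param legend named integer vector covering every id present in `labels`.
#' @inheritParams image_stack
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, legend = scene_legend(),
                         lateral_pitch, axial_step, depth_origin = 0) {
  if (length(dim(labels)) != 3L)
    tb_stop("tb_invalid_input", "labels must be a 3D array")
  present <- unique(as.integer(labels))
  if (!all(present %in% legend))
    tb_stop("tb_invalid_input", "legend does not cover every label id present")
  structure(list(
    labels = labels, legend = legend,
    lateral_pitch = as.numeric(lateral_pitch),
    axial_step = as.numeric(axial_step),
    depth_origin = as.numeric(depth_origin)
  ), class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("label_volume: %d x %d px, %d slices\n", d[1], d[2], d[3]))
  tab <- table(factor(as.integer(x$labels), levels = x$legend,
                      labels = names(x$legend)))
  cat("  voxel counts:\n")
  for (nm in names(tab)) if (tab[[nm]] > 0)
    cat(sprintf("    %-10s %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' Define a region of interest
#'
#' Axis-aligned in-plane box plus an inclusive depth window. Row/column
#' bounds are 1-based and inclusive, matching R array indexing.
#'
#' @param rows integer vector `c(first, last)` row bounds.
#' @param cols integer vector `c(first, last)` column bounds.
#' @param depths numeric vector `c(shallow, deep)` depth window in um.
#' @return An object of class `tb_roi`.
#' @export
roi <- function(rows, cols, depths) {
  if (length(rows) != 2 || length(cols) != 2 || length(depths) != 2 ||
      rows[1] > rows[2] || cols[1] > cols[2] || depths[1] > depths[2])
    tb_stop("tb_invalid_roi", "roi bounds must be ordered pairs")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 depths = as.numeric(depths)), class = "tb_roi")
}

#' @export
print.tb_roi <- function(x, ...) {
  cat(sprintf("roi: rows %d..%d, cols %d..%d, depths %g..%g um\n",
              x$rows[1], x$rows[2], x$cols[1], x$cols[2],
              x$depths[1], x$depths[2]))
  invisible(x)
}

# Indices of the slices of `stack` whose depth lies in the inclusive window.
slices_in_window <- function(stack, depths, tol = 1e-6) {
  z <- slice_depths(stack)
  which(z >= depths[1] - tol & z <= depths[2] + tol)
}

check_roi_bounds <- function(stack, r) {
  d <- dim(if (inherits(stack, "label_volume")) stack$labels else stack$intensities)
  if (r$rows[1] < 1 || r$rows[2] > d[1] || r$cols[1] < 1 || r$cols[2] > d[2])
    tb_stop("tb_invalid_roi", sprintf(
      "roi box (rows %d..%d, cols %d..%d) outside image bounds %d x %d",
      r$rows[1], r$rows[2], r$cols[1], r$cols[2], d[1], d[2]))
  z <- slice_depths(stack)
  if (r$depths[2] < min(z) - 1e-6 || r$depths[1] > max(z) + 1e-6)
    tb_stop("tb_invalid_roi", "roi depth window outside the stack's depth range")
  if (length(slices_in_window(stack, r$depths)) == 0)
    tb_stop("tb_invalid_roi", "roi depth window contains no slice")
  invisible(TRUE)
}
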