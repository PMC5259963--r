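#' Read and write image stacks as multi-page TIFF
#'
#' Intensity stacks are stored as 16-bit multi-page TIFF with a JSON sidecar
#' holding the physical pitch metadata; integer count stacks up to 65535
#' round-trip bit-exactly. Label volumes are stored as 8-bit multi-page TIFF
#' plus a JSON legend.
#'
#' @param stack an [image_stack()] with integer counts in `[0, 65535]`.
#' @param path TIFF file path.
#' @param meta_path sidecar JSON path; defaults to `<path>.json`.
#' @return `write_image_stack()` returns `path` invisibly;
#'   `read_image_stack()` returns an `image_stack`.
#' @export
write_image_stack <- function(stack, path, meta_path = paste0(path, ".json")) {
  x <- stack$intensities
  if (any(x != round(x)) || max(x) > 65535)
    tb_stop("tb_invalid_input", "stack must hold integer counts in [0, 65535]")
  pages <- lapply(seq_len(dim(x)[3]), function(k) x[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(list(
    lateral_pitch = stack$lateral_pitch, axial_step = stack$axial_step,
    depth_origin = stack$depth_origin, kind = "intensity"
  ), meta_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path, meta_path = paste0(path, ".json")) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  d <- c(dim(pages[[1]]), length(pages))
  x <- array(0, dim = d)
  for (k in seq_along(pages)) x[, , k] <- round(pages[[k]] * 65535)
  image_stack(x, meta$lateral_pitch, meta$axial_step, meta$depth_origin)
}

#' @rdname write_image_stack
#' @param labels a [label_volume()] with label ids in `[0, 255]`.
#' @export
write_label_volume <- function(labels, path, meta_path = paste0(path, ".json")) {
  x <- labels$labels
  if (max(x) > 255) tb_stop("tb_invalid_input", "label ids must fit 8 bits")
  pages <- lapply(seq_len(dim(x)[3]), function(k) x[, , k] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  jsonlite::write_json(list(
    lateral_pitch = labels$lateral_pitch, axial_step = labels$axial_step,
    depth_origin = labels$depth_origin, kind = "labels",
    legend = as.list(labels$legend)
  ), meta_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_label_volume <- function(path, meta_path = paste0(path, ".json")) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  d <- c(dim(pages[[1]]), length(pages))
  x <- array(0L, dim = d)
  for (k in seq_along(pages)) x[, , k] <- as.integer(round(pages[[k]] * 255))
  legend <- unlist(meta$legend)
  storage.mode(legend) <- "integer"
  label_volume(x, legend, meta$lateral_pitch, meta$axial_step, meta$depth_origin)
}

#' Read and write ROI and scene configuration as JSON
#'
#' @param x a [roi()] or `scene_config`.
#' @param path JSON file path.
#' @return Readers return the reconstructed object; writers return `path`
#'   invisibly.
#' @export
write_roi <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_roi
#' @export
read_roi <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  roi(rows = j$rows, cols = j$cols, depths = j$depths)
}

#' @rdname write_roi
#' @export
write_scene_config <- function(x, path) {
  y <- unclass(x)
  y$tm_roi <- unclass(y$tm_roi)
  jsonlite::write_json(y, path, auto_unbox = FALSE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_roi
#' @export
read_scene_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_path_df <- function(p) if (is.null(p) || length(p) == 0) NULL else
    as.data.frame(p)
  scene_config(
    stack_shape = j$stack_shape, lateral_pitch = j$lateral_pitch,
    axial_step = j$axial_step, depth_origin = j$depth_origin,
    tm_roi = roi(j$tm_roi$rows, j$tm_roi$cols, j$tm_roi$depths),
    porosity_knots = as.data.frame(j$porosity_knots),
    sc_path = as_path_df(j$sc_path),
    vein_path = as_path_df(j$vein_path),
    vein_branch = as_path_df(j$vein_branch),
    beam_thickness_mean = j$beam_thickness_mean,
    noise = list(photon_scale = j$noise$photon_scale,
                 read_sigma = j$noise$read_sigma),
    attenuation_length = if (is.null(j$attenuation_length)) Inf else
      j$attenuation_length,
    psf_sigma = j$psf_sigma, seed = j$seed
  )
}
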