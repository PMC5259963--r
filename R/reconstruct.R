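#' Threshold segmentation of a tissue volume
#'
#' Collagen-bearing tissue is bright under two-photon contrast, so the tissue
#' mask is the at-or-above-threshold voxel set. Every segmentation carries a
#' replayable provenance: the ordered list of steps that produced it.
#'
#' @param stack an [image_stack()].
#' @param threshold scalar intensity threshold.
#' @return A `segmented_volume`: list with `mask` (3D logical), `pitch`
#'   `c(lateral, axial)` um, and `provenance`.
#' @export
threshold_segment <- function(stack, threshold) {
  mask <- stack$intensities >= threshold
  if (!any(mask))
    tb_stop("tb_empty_segmentation",
            "threshold above every intensity: empty tissue mask")
  segmented_volume(mask, c(stack$lateral_pitch, stack$axial_step),
                   list(list(step = "threshold", threshold = threshold)))
}

segmented_volume <- function(mask, pitch, provenance) {
  structure(list(mask = mask, pitch = as.numeric(pitch),
                 provenance = provenance), class = "segmented_volume")
}

#' @export
print.segmented_volume <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("segmented_volume: %d x %d x %d voxels, %d tissue (%.1f%%)\n",
              d[1], d[2], d[3], sum(x$mask), 100 * mean(x$mask)))
  cat("  provenance:", paste(vapply(x$provenance, `[[`, "", "step"),
                             collapse = " -> "), "\n")
  invisible(x)
}

#' Region growing from a seed voxel
#'
#' Retains only the connected component of the seed, under 6- or
#' 26-connectivity.
#'
#' @param volume a `segmented_volume`.
#' @param seed integer `c(row, col, slice)` voxel inside the mask.
#' @param connectivity 6 (face) or 26 (face/edge/corner).
#' @return The grown `segmented_volume` with provenance appended.
#' @export
region_grow <- function(volume, seed, connectivity = 6) {
  d <- dim(volume$mask)
  seed <- as.integer(seed)
  if (length(seed) != 3 || any(seed < 1) || any(seed > d))
    tb_stop("tb_invalid_seed", "seed voxel outside the volume")
  if (!volume$mask[seed[1], seed[2], seed[3]])
    tb_stop("tb_invalid_seed", "seed voxel is not inside the tissue mask")
  comp <- flood_fill_3d(volume$mask, seed, connectivity)
  segmented_volume(comp, volume$pitch, c(volume$provenance, list(
    list(step = "region_grow", seed = seed, connectivity = connectivity))))
}

neighbor_offsets_3d <- function(connectivity) {
  offs <- as.matrix(expand.grid(dr = -1:1, dc = -1:1, ds = -1:1))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  if (connectivity == 6) {
    offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  } else if (connectivity != 26) {
    tb_stop("tb_invalid_input", "connectivity must be 6 or 26")
  }
  offs
}

# Vectorized frontier-expansion flood fill on a 3D logical array.
flood_fill_3d <- function(mask, seed, connectivity = 6) {
  d <- dim(mask)
  offs <- neighbor_offsets_3d(connectivity)
  visited <- array(FALSE, dim = d)
  visited[seed[1], seed[2], seed[3]] <- TRUE
  frontier <- matrix(seed, nrow = 1)
  while (nrow(frontier)) {
    nxt <- list()
    for (j in seq_len(nrow(offs))) {
      nb <- frontier + matrix(offs[j, ], nrow(frontier), 3, byrow = TRUE)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
            nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      if (!nrow(nb)) next
      lin <- nb[, 1] + d[1] * (nb[, 2] - 1L) + d[1] * d[2] * (nb[, 3] - 1L)
      keep <- mask[lin] & !visited[lin]
      if (any(keep)) {
        lin <- lin[keep]
        visited[lin] <- TRUE
        nxt[[length(nxt) + 1L]] <- nb[keep, , drop = FALSE]
      }
    }
    frontier <- if (length(nxt)) unique(do.call(rbind, nxt)) else
      matrix(0L, 0, 3)
  }
  visited
}

#' Morphological editing of a segmentation
#'
#' Applies binary morphology steps in order, with ball structuring elements
#' of a physical radius (converted to anisotropic voxel radii through the
#' lateral/axial pitch). Supported operations: `close` (dilate then erode),
#' `open` (erode then dilate), `fill_holes` (fill background cavities not
#' connected to the volume border, 6-connectivity).
#'
#' @param volume a `segmented_volume`.
#' @param ops list of `list(op = "close"|"open"|"fill_holes", radius_um = r)`;
#'   `radius_um` is ignored by `fill_holes`.
#' @return The edited `segmented_volume` with provenance appended.
#' @export
morphological_edit <- function(volume, ops) {
  mask <- volume$mask
  for (o in ops) {
    r <- if (is.null(o$radius_um)) 0 else o$radius_um
    if (r < 0) tb_stop("tb_invalid_input", "morphology radius must be >= 0")
    mask <- switch(o$op,
      close = erode_3d(dilate_3d(mask, r, volume$pitch), r, volume$pitch),
      open = dilate_3d(erode_3d(mask, r, volume$pitch), r, volume$pitch),
      fill_holes = fill_holes_3d(mask),
      tb_stop("tb_invalid_input", sprintf("unknown morphology op '%s'", o$op))
    )
  }
  segmented_volume(mask, volume$pitch,
                   c(volume$provenance, list(list(step = "edit", ops = ops))))
}

ball_offsets <- function(radius_um, pitch) {
  if (radius_um <= 0) return(matrix(0L, 1, 3))
  mr <- floor(radius_um / pitch[1]); ms <- floor(radius_um / pitch[2])
  g <- as.matrix(expand.grid(dr = -mr:mr, dc = -mr:mr, ds = -ms:ms))
  d2 <- (g[, 1] * pitch[1])^2 + (g[, 2] * pitch[1])^2 + (g[, 3] * pitch[2])^2
  g[d2 <= radius_um^2 + 1e-9, , drop = FALSE]
}

# Shift a 3D logical array by (dr, dc, ds), padding with `fill`.
shift_3d <- function(x, o, fill = FALSE) {
  d <- dim(x)
  out <- array(fill, dim = d)
  src_r <- max(1, 1 - o[1]):min(d[1], d[1] - o[1])
  src_c <- max(1, 1 - o[2]):min(d[2], d[2] - o[2])
  src_s <- max(1, 1 - o[3]):min(d[3], d[3] - o[3])
  if (!length(src_r) || !length(src_c) || !length(src_s)) return(out)
  out[src_r + o[1], src_c + o[2], src_s + o[3]] <-
    x[src_r, src_c, src_s, drop = FALSE]
  out
}

dilate_3d <- function(mask, radius_um, pitch) {
  offs <- ball_offsets(radius_um, pitch)
  out <- array(FALSE, dim = dim(mask))
  for (j in seq_len(nrow(offs))) out <- out | shift_3d(mask, offs[j, ])
  out
}

erode_3d <- function(mask, radius_um, pitch) {
  # erosion treats the outside of the volume as background
  !dilate_3d(!mask, radius_um, pitch)
}

fill_holes_3d <- function(mask) {
  d <- dim(mask)
  bg <- !mask
  # flood the background from every border voxel; unreached background = hole
  reached <- array(FALSE, dim = d)
  border <- array(FALSE, dim = d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  border[, , c(1, d[3])] <- TRUE
  seeds <- which(bg & border, arr.ind = TRUE)
  if (nrow(seeds)) {
    # grow all border seeds at once: iterate masked dilation of the reached set
    reached[seeds] <- TRUE
    offs <- neighbor_offsets_3d(6)
    repeat {
      grown <- reached
      for (j in seq_len(nrow(offs)))
        grown <- grown | shift_3d(reached, offs[j, ])
      grown <- grown & bg
      if (identical(grown, reached)) break
      reached <- grown
    }
  }
  mask | (bg & !reached)
}

#' Replay a segmentation provenance
#'
#' Re-applies the recorded steps of a `segmented_volume` to the source stack;
#' the result is bit-identical to the original segmentation.
#'
#' @param stack the source [image_stack()].
#' @param provenance the `provenance` field of a `segmented_volume`.
#' @return The reconstructed `segmented_volume`.
#' @export
replay_provenance <- function(stack, provenance) {
  if (length(provenance) == 0 || provenance[[1]]$step != "threshold")
    tb_stop("tb_invalid_input", "provenance must start with a threshold step")
  vol <- threshold_segment(stack, provenance[[1]]$threshold)
  for (p in provenance[-1]) {
    vol <- switch(p$step,
      region_grow = region_grow(vol, p$seed, p$connectivity),
      edit = morphological_edit(vol, p$ops),
      tb_stop("tb_invalid_input", sprintf("unknown provenance step '%s'", p$step))
    )
  }
  vol
}
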