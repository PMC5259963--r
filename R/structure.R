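#' Detect a signal-void luminal structure in an optical section
#'
#' Identifies Schlemm's canal or an aqueous vein cross-section as the largest
#' below-threshold 8-connected component lying fully inside the ROI box
#' (components clipped by the ROI border are discarded as truncated).
#' Components smaller than `min_area_um2` (default: the area of a 10 um
#' diameter circle, below any reported lumen) are rejected as noise specks.
#'
#' @param slice 2D numeric matrix (a full, uncropped optical section).
#' @param roi_box a [roi()]; only the in-plane box is used.
#' @param threshold intensity threshold separating void from tissue; if
#'   `NULL`, the slice window is contrast-enhanced and an Otsu threshold is
#'   derived from its gray histogram.
#' @param pitch lateral pixel size, um.
#' @param min_area_um2 minimum component area, um^2.
#' @return A `lumen_region`: list with `mask` (logical matrix over the ROI
#'   box), `box` (row/col offsets), `centroid` (row, col in full-slice
#'   coordinates), `area_px` and `area_um2`.
#' @export
detect_lumen <- function(slice, roi_box, threshold = NULL, pitch,
                         min_area_um2 = pi * 25) {
  if (roi_box$rows[1] < 1 || roi_box$rows[2] > nrow(slice) ||
      roi_box$cols[1] < 1 || roi_box$cols[2] > ncol(slice))
    tb_stop("tb_invalid_roi", "roi box outside slice bounds")
  win <- slice[roi_box$rows[1]:roi_box$rows[2],
               roi_box$cols[1]:roi_box$cols[2], drop = FALSE]
  if (is.null(threshold)) {
    enh <- enhance(win)
    threshold <- histogram_threshold(enh)
    win <- enh
  }
  mask <- win < threshold
  if (!any(mask))
    tb_stop("tb_no_lumen", "no below-threshold pixels inside the roi")
  lab <- label_components_2d(mask)
  ncomp <- max(lab)
  if (ncomp == 0) tb_stop("tb_no_lumen", "no component found")
  min_area_px <- min_area_um2 / pitch^2
  nr <- nrow(mask); nc <- ncol(mask)
  best <- 0L; best_area <- -1
  for (i in seq_len(ncomp)) {
    comp <- lab == i
    area <- sum(comp)
    if (area < min_area_px) next
    idx <- which(comp, arr.ind = TRUE)
    if (any(idx[, 1] == 1L | idx[, 1] == nr | idx[, 2] == 1L | idx[, 2] == nc))
      next  # clipped by the roi border
    if (area > best_area) { best <- i; best_area <- area }
  }
  if (best == 0L)
    tb_stop("tb_no_lumen", sprintf(
      "no interior below-threshold component of area >= %.0f px", min_area_px))
  comp <- lab == best
  idx <- which(comp, arr.ind = TRUE)
  centroid <- c(row = mean(idx[, 1]) + roi_box$rows[1] - 1,
                col = mean(idx[, 2]) + roi_box$cols[1] - 1)
  structure(list(
    mask = comp,
    box = c(row0 = roi_box$rows[1], col0 = roi_box$cols[1]),
    centroid = centroid, area_px = best_area,
    area_um2 = best_area * pitch^2
  ), class = "lumen_region")
}

# 8-connected component labeling of a logical matrix by frontier expansion.
label_components_2d <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  todo <- which(mask)
  current <- 0L
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  while (length(todo)) {
    seedidx <- todo[1]
    current <- current + 1L
    frontier <- seedidx
    lab[seedidx] <- current
    while (length(frontier)) {
      r <- (frontier - 1L) %% nr + 1L
      c <- (frontier - 1L) %/% nr + 1L
      nxt <- integer(0)
      for (j in seq_len(nrow(offs))) {
        rr <- r + offs$dr[j]; cc <- c + offs$dc[j]
        ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
        if (!any(ok)) next
        ii <- (cc[ok] - 1L) * nr + rr[ok]
        ii <- ii[mask[ii] & lab[ii] == 0L]
        if (length(ii)) {
          lab[ii] <- current
          nxt <- c(nxt, ii)
        }
      }
      frontier <- unique(nxt)
    }
    todo <- todo[lab[todo] == 0L]
  }
  lab
}

#' Measure a lumen diameter by repeated centroid chords
#'
#' Emulates repeated manual caliper measurements deterministically: the mask
#' extent is measured along `n_repeats` directions through the component
#' centroid at uniformly spaced orientations (0, pi/n, ...), each chord being
#' the span of mask pixels intersected by the line, in um; the mean diameter
#' is the arithmetic mean of the repeats.
#'
#' @param region a `lumen_region` from [detect_lumen()].
#' @param n_repeats number of chord orientations (default 5).
#' @param pitch lateral pixel size, um.
#' @return List with `repeats` (chord lengths, um) and `mean_um`.
#' @export
measure_diameter <- function(region, n_repeats = 5L, pitch) {
  if (n_repeats < 1) tb_stop("tb_invalid_input", "n_repeats must be >= 1")
  mask <- region$mask
  nr <- nrow(mask); nc <- ncol(mask)
  cr <- region$centroid["row"] - region$box["row0"] + 1
  cc <- region$centroid["col"] - region$box["col0"] + 1
  ci <- round(cr); cj <- round(cc)
  if (ci < 1 || ci > nr || cj < 1 || cj > nc || !mask[ci, cj])
    tb_warn("tb_nonconvex_lumen",
            "centroid falls outside the lumen mask; chords measured anyway")
  tmax <- sqrt(nr^2 + nc^2)
  step <- 0.2
  ts <- seq(-tmax, tmax, by = step)
  angles <- (seq_len(n_repeats) - 1) * pi / n_repeats
  repeats <- vapply(angles, function(a) {
    rr <- round(cr + ts * sin(a))
    cj2 <- round(cc + ts * cos(a))
    ok <- rr >= 1 & rr <= nr & cj2 >= 1 & cj2 <= nc
    hit <- ok
    hit[ok] <- mask[cbind(rr[ok], cj2[ok])]
    if (!any(hit)) return(0)
    # span of hit pixel centers projected on the ray, plus one pixel footprint
    p <- (rr[hit] - cr) * sin(a) + (cj2[hit] - cc) * cos(a)
    (max(p) - min(p) + 1) * pitch
  }, numeric(1))
  if (any(repeats <= 0))
    tb_warn("tb_nonconvex_lumen", "a chord missed the mask entirely")
  list(repeats = repeats, mean_um = mean(repeats))
}

#' Diameter-versus-depth profile of a luminal structure
#'
#' Detects the lumen and measures its mean chord diameter on every optical
#' section of the ROI depth window. Slices on which no lumen is found are
#' recorded in the `failed` attribute with the reason.
#'
#' @param stack an [image_stack()].
#' @param roi a [roi()]: in-plane search box plus depth window.
#' @param n_repeats chord orientations per slice (default 5).
#' @param threshold optional fixed intensity threshold; default derives an
#'   Otsu threshold per slice from the ROI window.
#' @return A data.frame of class `diameter_profile` with columns `depth_um`,
#'   `repeat_1..n` (chords, um), `mean_diameter_um`, `found`; sorted by depth.
#' @export
diameter_profile <- function(stack, roi, n_repeats = 5L, threshold = NULL) {
  check_roi_bounds(stack, roi)
  ks <- slices_in_window(stack, roi$depths)
  if (length(ks) == 0) tb_stop("tb_invalid_range", "empty depth range")
  z <- slice_depths(stack)
  rows <- list(); failed <- list()
  for (k in ks) {
    res <- tryCatch({
      reg <- detect_lumen(stack$intensities[, , k], roi, threshold = threshold,
                          pitch = stack$lateral_pitch)
      m <- measure_diameter(reg, n_repeats = n_repeats,
                            pitch = stack$lateral_pitch)
      row <- as.data.frame(as.list(stats::setNames(
        m$repeats, paste0("repeat_", seq_len(n_repeats)))))
      cbind(data.frame(depth_um = z[k]), row,
            data.frame(mean_diameter_um = m$mean_um, found = TRUE))
    }, tb_no_lumen = function(e) e)
    if (inherits(res, "condition")) {
      failed[[length(failed) + 1L]] <-
        data.frame(depth_um = z[k], reason = conditionMessage(res))
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(depth_um = numeric())
  if (nrow(out)) out <- out[order(out$depth_um), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "failed") <- if (length(failed)) do.call(rbind, failed) else NULL
  class(out) <- c("diameter_profile", "data.frame")
  out
}

#' @export
print.diameter_profile <- function(x, ...) {
  cat(sprintf("diameter_profile: %d depths", nrow(x)))
  if (nrow(x) && "mean_diameter_um" %in% names(x))
    cat(sprintf(", mean diameter %0.1f..%0.1f um",
                min(x$mean_diameter_um), max(x$mean_diameter_um)))
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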