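# Cell geometry: label masks -> ellipse-fitted ROIs with QC ------------------
#
# Segmentation masks (e.g. from Cellpose) are ingested as integer label
# images whose edges bisect the plasma-membrane ring. Each labelled region
# becomes a CellROI; a moment-based ellipse approximates the cell, and
# rule-based QC replaces the original manual ROI curation so the pipeline is
# deterministic.

#' Convert an integer label mask into cell ROIs
#'
#' @param mask integer matrix: 0 = background, each cell one unique positive
#'   label. Dimensions must match `field` when given.
#' @param field optional `mcc_field` the mask belongs to (shape check only).
#' @return list of `mcc_roi` objects (label, pixel indices, area,
#'   `touches_border` flag), ordered by label.
#' @export
load_label_mask <- function(mask, field = NULL) {
  check_that(is.matrix(mask) && is.numeric(mask), "mask must be a numeric matrix")
  check_that(all(mask >= 0) && all(mask == round(mask)),
             "mask must contain non-negative integers")
  if (!is.null(field)) {
    d <- dim(get_frame(field, 1L, 1L))
    check_that(all(dim(mask) == d),
               sprintf("mask shape %dx%d does not match field shape %dx%d",
                       nrow(mask), ncol(mask), d[1], d[2]))
  }
  labs <- sort(unique(mask[mask > 0]))
  nr <- nrow(mask); nc <- ncol(mask)
  lapply(labs, function(lb) {
    idx <- which(mask == lb)
    rows <- (idx - 1) %% nr
    cols <- (idx - 1) %/% nr
    structure(list(label = as.integer(lb), pixel_idx = idx,
                   rows = rows, cols = cols,
                   area_px = length(idx),
                   touches_border = any(rows == 0 | rows == nr - 1 |
                                          cols == 0 | cols == nc - 1),
                   dim = c(nr, nc), ellipse = NULL, qc = NULL),
              class = "mcc_roi")
  })
}

#' @export
print.mcc_roi <- function(x, ...) {
  cat(sprintf("<mcc_roi> label %d, %d px%s%s\n", x$label, x$area_px,
              if (isTRUE(x$touches_border)) ", touches border" else "",
              if (!is.null(x$ellipse))
                sprintf(", ellipse a=%.1f b=%.1f px", x$ellipse$semi_axes[1],
                        x$ellipse$semi_axes[2]) else ""))
  invisible(x)
}

#' Moment-based ellipse fit of a cell ROI
#'
#' Centre = pixel centroid; orientation and axis ratio from the second
#' central moments; both semi-axes rescaled so the ellipse area equals the
#' mask area. Coordinates are 0-based (row, col); the orientation is the
#' angle of the major axis from the +col axis, in `[0, pi)`.
#'
#' @param roi an `mcc_roi`.
#' @param min_area smallest mask area accepted for fitting (pixels).
#' @return the ROI with `$ellipse = list(center, semi_axes, orientation)`
#'   filled in, or with `$qc = "degenerate"` when the mask is too small or
#'   has a vanishing second moment (QC rejection, not an error).
#' @export
fit_ellipse <- function(roi, min_area = 50L) {
  check_that(inherits(roi, "mcc_roi"), "roi must be an mcc_roi")
  if (roi$area_px < min_area) {
    roi$qc <- "degenerate"
    return(roi)
  }
  # x along columns, y along rows, 0-based pixel centres
  x <- roi$cols; y <- roi$rows
  cx <- mean(x); cy <- mean(y)
  # + 1/12: second moment of the unit pixel itself, removes the bias of
  # point-sampling each pixel at its centre
  mxx <- mean((x - cx)^2) + 1 / 12
  myy <- mean((y - cy)^2) + 1 / 12
  mxy <- mean((x - cx) * (y - cy))
  det <- mxx * myy - mxy^2
  if (!is.finite(det) || det <= 1e-9) {
    roi$qc <- "degenerate"
    return(roi)
  }
  tr <- mxx + myy
  disc <- sqrt(max(0, (mxx - myy)^2 / 4 + mxy^2))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  if (l2 <= 0) {
    roi$qc <- "degenerate"
    return(roi)
  }
  # uniform ellipse: eigenvalues of the covariance are a^2/4, b^2/4
  a <- 2 * sqrt(l1); b <- 2 * sqrt(l2)
  scale <- sqrt(roi$area_px / (pi * a * b))
  a <- a * scale; b <- b * scale
  orient <- if (abs(mxy) < 1e-12 && mxx >= myy) 0
    else 0.5 * atan2(2 * mxy, mxx - myy)
  orient <- orient %% pi
  roi$ellipse <- list(center = c(cy, cx), semi_axes = c(a, b),
                      orientation = orient)
  roi
}

#' Rule-based cell QC
#'
#' Replaces the manual ROI curation of the original workflow with
#' deterministic rules: drop border-touching cells (incompletely imaged),
#' cells outside the area gates, and failed ellipse fits. ROIs without a fit
#' are fitted first.
#'
#' @param rois list of `mcc_roi`.
#' @param min_area,max_area area gates in pixels.
#' @param drop_border drop ROIs touching the image border.
#' @return list with `kept` (ROIs, input order preserved, ellipses fitted)
#'   and `rejected` (data frame: label, area_px, reason).
#' @export
filter_cells <- function(rois, min_area = 50L, max_area = 20000L,
                         drop_border = TRUE) {
  kept <- list()
  rej <- list()
  for (roi in rois) {
    if (is.null(roi$ellipse) && is.null(roi$qc))
      roi <- fit_ellipse(roi, min_area = min_area)
    reason <- NULL
    if (isTRUE(drop_border) && roi$touches_border) reason <- "touches_border"
    else if (roi$area_px < min_area) reason <- "below_min_area"
    else if (roi$area_px > max_area) reason <- "above_max_area"
    else if (!is.null(roi$qc)) reason <- roi$qc
    else if (is.null(roi$ellipse)) reason <- "fit_failed"
    if (is.null(reason)) kept[[length(kept) + 1L]] <- roi
    else rej[[length(rej) + 1L]] <- data.frame(label = roi$label,
                                               area_px = roi$area_px,
                                               reason = reason,
                                               stringsAsFactors = FALSE)
  }
  list(kept = kept,
       rejected = if (length(rej)) do.call(rbind, rej)
       else data.frame(label = integer(0), area_px = integer(0),
                       reason = character(0), stringsAsFactors = FALSE))
}

#' ROI list as a table
#' @param rois list of `mcc_roi` (fitted).
#' @return data frame: label, centre, semi-axes, orientation, area, border flag.
#' @export
roi_table <- function(rois) {
  do.call(rbind, lapply(rois, function(r) {
    e <- r$ellipse
    data.frame(label = r$label,
               center_row = if (is.null(e)) NA_real_ else e$center[1],
               center_col = if (is.null(e)) NA_real_ else e$center[2],
               a_px = if (is.null(e)) NA_real_ else e$semi_axes[1],
               b_px = if (is.null(e)) NA_real_ else e$semi_axes[2],
               orientation_rad = if (is.null(e)) NA_real_ else e$orientation,
               area_px = r$area_px,
               touches_border = r$touches_border,
               stringsAsFactors = FALSE)
  }))
}
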