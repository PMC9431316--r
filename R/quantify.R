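# Per-cell plasma-membrane quantification ------------------------------------
#
# Region partitioning around the fitted ellipse, mean/integrated region
# intensities, the PM/interior intensity ratio, circular membrane intensity
# profiles, patch (peak) detection with topographic prominence, patch density
# along the perimeter, and the dye-uptake ratio.

#' Partition a cell into membrane band, interior and whole-cell masks
#'
#' The PM band is an annulus of width `band_width_um` centred on the fitted
#' ellipse boundary (half inside, half outside). The interior is the ellipse
#' shrunk by half the band; the whole cell is the ellipse grown by half the
#' band. By construction band and interior partition the whole-cell mask.
#'
#' @param ellipse list with `center` (row, col; 0-based px), `semi_axes`
#'   (major, minor; px), `orientation` (radians).
#' @param dim image dimensions `c(rows, cols)`.
#' @param band_width_um band width in micrometres.
#' @param pixel_size_um pixel size in micrometres.
#' @return list of logical matrices `band`, `interior`, `whole`.
#' @export
partition_regions <- function(ellipse, dim, band_width_um = 0.4,
                              pixel_size_um = 0.1) {
  hw <- band_width_um / 2 / pixel_size_um
  b <- min(ellipse$semi_axes)
  check_that(band_width_um / pixel_size_um < b,
             sprintf("band width (%.1f px) must be thinner than the minor semi-axis (%.1f px)",
                     band_width_um / pixel_size_um, b))
  rad <- max(ellipse$semi_axes) + hw + 2
  rows <- max(0, floor(ellipse$center[1] - rad)):
    min(dim[1] - 1, ceiling(ellipse$center[1] + rad))
  cols <- max(0, floor(ellipse$center[2] - rad)):
    min(dim[2] - 1, ceiling(ellipse$center[2] + rad))
  fr <- cell_frame(rows, cols, ellipse$center, ellipse$semi_axes,
                   ellipse$orientation)
  band <- interior <- whole <- matrix(FALSE, dim[1], dim[2])
  whole[rows + 1, cols + 1] <- fr$d <= hw
  interior[rows + 1, cols + 1] <- fr$d < -hw
  band <- whole & !interior
  list(band = band, interior = interior, whole = whole)
}

#' Mean and integrated intensity per region
#'
#' @param img numeric matrix (one frame of one channel).
#' @param masks named list of logical matrices (e.g. from
#'   [partition_regions()]).
#' @param background constant background to subtract per pixel (default 0,
#'   i.e. none).
#' @return data frame: region, n_px, integrated, mean (NA with zero pixels).
#' @export
region_intensities <- function(img, masks, background = 0) {
  do.call(rbind, lapply(names(masks), function(nm) {
    n <- sum(masks[[nm]])
    tot <- if (n > 0) sum(img[masks[[nm]]]) - background * n else NA_real_
    data.frame(region = nm, n_px = n, integrated = tot,
               mean = if (n > 0) tot / n else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' PM/interior intensity ratio
#'
#' Mean plasma-membrane-band intensity divided by mean cell-interior
#' intensity, the per-cell redistribution readout.
#'
#' @param pm_mean,interior_mean region means.
#' @return the ratio, or `NA` (flagged by attribute `reason`) when the
#'   interior mean is not positive.
#' @export
pm_interior_ratio <- function(pm_mean, interior_mean) {
  if (!is.finite(interior_mean) || interior_mean <= 0)
    return(structure(NA_real_, reason = "non-positive interior mean"))
  pm_mean / interior_mean
}

#' Extract the circular membrane intensity profile of a cell
#'
#' At `n_samples` evenly spaced ellipse parametric angles, the intensity is
#' the mean of bilinear samples along a short radial segment spanning the
#' band. The perimeter comes from Ramanujan's ellipse-perimeter
#' approximation.
#'
#' @param img numeric matrix.
#' @param ellipse fitted ellipse (see [partition_regions()]).
#' @param pixel_size_um pixel size (micrometres).
#' @param band_width_um radial extent of the averaged segment.
#' @param n_samples angular samples (>= 64).
#' @param n_radial samples along each radial segment.
#' @return an `mcc_profile`: list(angles, intensities, perimeter_um,
#'   n_samples).
#' @export
extract_membrane_profile <- function(img, ellipse, pixel_size_um,
                                     band_width_um = 0.4, n_samples = 360L,
                                     n_radial = 9L) {
  check_that(is_count(n_samples) && n_samples >= 64, "n_samples must be >= 64")
  hw <- band_width_um / 2 / pixel_size_um
  a <- ellipse$semi_axes[1]; b <- ellipse$semi_axes[2]
  phi <- ellipse$orientation
  ext <- max(a, b) + hw + 1
  inside <- ellipse$center[1] - ext >= 0 && ellipse$center[2] - ext >= 0 &&
    ellipse$center[1] + ext <= nrow(img) - 1 &&
    ellipse$center[2] + ext <= ncol(img) - 1
  check_that(inside,
             "ellipse (grown by the band) extends outside the image; cell should have been QC-filtered")
  theta <- 2 * pi * (seq_len(n_samples) - 1) / n_samples
  # boundary points and outward normals in image coordinates
  bu <- a * cos(theta); bv <- b * sin(theta)
  bx <- bu * cos(phi) - bv * sin(phi)  # col offset
  by <- bu * sin(phi) + bv * cos(phi)  # row offset
  nu <- cos(theta) / a; nv <- sin(theta) / b
  nn <- sqrt(nu^2 + nv^2)
  nu <- nu / nn; nv <- nv / nn
  nx <- nu * cos(phi) - nv * sin(phi)
  ny <- nu * sin(phi) + nv * cos(phi)
  s <- seq(-hw, hw, length.out = n_radial)
  rows <- outer(ellipse$center[1] + by, rep(1, n_radial)) + outer(ny, s)
  cols <- outer(ellipse$center[2] + bx, rep(1, n_radial)) + outer(nx, s)
  vals <- matrix(bilinear(img, as.vector(rows), as.vector(cols)),
                 nrow = n_samples)
  structure(list(angles = theta, intensities = rowMeans(vals),
                 perimeter_um = ellipse_perimeter(a, b) * pixel_size_um,
                 n_samples = as.integer(n_samples)),
            class = "mcc_profile")
}

#' @export
print.mcc_profile <- function(x, ...) {
  cat(sprintf("<mcc_profile> %d samples, perimeter %.2f um, intensity [%.3g, %.3g]\n",
              x$n_samples, x$perimeter_um, min(x$intensities), max(x$intensities)))
  invisible(x)
}

# Topographic prominence of local maxima on a circular profile.
circular_prominence <- function(x, peaks) {
  n <- length(x)
  gmin <- min(x)
  vapply(peaks, function(p) {
    h <- x[p]
    if (h == max(x)) return(h - gmin)
    side_min <- function(step) {
      m <- h
      i <- p
      for (k in seq_len(n)) {
        i <- ((i - 1 + step) %% n) + 1
        if (x[i] > h) return(m)
        if (x[i] < m) m <- x[i]
      }
      m
    }
    h - max(side_min(1L), side_min(-1L))
  }, 0)
}

#' Detect membrane patches as peaks of the circular profile
#'
#' The profile is smoothed with a circular Gaussian; peaks are local maxima
#' whose topographic prominence is at least `min_prominence_frac` times the
#' profile median and whose circular separation is at least
#' `min_separation_rad` (the higher peak wins a conflict; exact height ties
#' go to the smaller angle). Valleys are the circular minima between
#' consecutive retained peaks.
#'
#' @param profile an `mcc_profile`.
#' @param smoothing_sigma Gaussian sigma in samples.
#' @param min_prominence_frac prominence threshold as a fraction of the
#'   smoothed-profile median (relative, so detection is invariant to uniform
#'   intensity rescaling).
#' @param min_separation_rad minimum angular distance between retained peaks.
#' @return list: `n` patches, `angles`, `peak_intensity`, `valley_intensity`
#'   (per retained arc), `smoothed` profile values, `indices`.
#' @export
detect_patches <- function(profile, smoothing_sigma = 2,
                           min_prominence_frac = 0.10,
                           min_separation_rad = 4 * pi / 180) {
  check_that(inherits(profile, "mcc_profile"), "profile must be an mcc_profile")
  x <- smooth_circular(profile$intensities, smoothing_sigma)
  n <- length(x)
  lag <- x[c(n, 1:(n - 1))]; lead <- x[c(2:n, 1)]
  cand <- which(x > lag & x >= lead)
  if (!length(cand))
    return(list(n = 0L, angles = numeric(0), peak_intensity = numeric(0),
                valley_intensity = numeric(0), smoothed = x,
                indices = integer(0)))
  prom <- circular_prominence(x, cand)
  thr <- min_prominence_frac * stats::median(x)
  keep <- prom >= thr & prom > 0
  cand <- cand[keep]
  if (!length(cand))
    return(list(n = 0L, angles = numeric(0), peak_intensity = numeric(0),
                valley_intensity = numeric(0), smoothed = x,
                indices = integer(0)))
  # greedy separation pruning: highest first, ties to the smaller angle
  ord <- order(-x[cand], cand)
  sel <- integer(0)
  for (i in cand[ord]) {
    if (!length(sel) ||
        min(circ_dist(profile$angles[i], profile$angles[sel])) >=
          min_separation_rad)
      sel <- c(sel, i)
  }
  sel <- sort(sel)
  valleys <- if (length(sel) == 1) min(x)
  else vapply(seq_along(sel), function(j) {
    from <- sel[j]
    to <- sel[if (j == length(sel)) 1 else j + 1]
    idx <- if (to > from) (from:to) else c(from:n, 1:to)
    min(x[idx])
  }, 0)
  list(n = length(sel), angles = profile$angles[sel],
       peak_intensity = x[sel], valley_intensity = valleys,
       smoothed = x, indices = sel)
}

#' Patch prominence of a cell
#'
#' Ratio of the mean detected-peak intensity to the mean valley intensity on
#' the smoothed membrane profile. Undefined (NA) with zero patches, or when
#' the mean valley intensity is not positive.
#'
#' @param patches result of [detect_patches()].
#' @return dimensionless ratio, or `NA_real_` with attribute `reason`.
#' @export
patch_prominence <- function(patches) {
  if (patches$n == 0)
    return(structure(NA_real_, reason = "no patches detected"))
  v <- mean(patches$valley_intensity)
  if (!is.finite(v) || v <= 0)
    return(structure(NA_real_, reason = "non-positive valley intensity"))
  mean(patches$peak_intensity) / v
}

#' Patch density along the membrane
#' @param patch_count detected patches in the cross-section.
#' @param perimeter_um fitted-ellipse perimeter in micrometres.
#' @return patches per micrometre.
#' @export
patch_density <- function(patch_count, perimeter_um) {
  check_that(is_number(perimeter_um) && perimeter_um > 0,
             "perimeter_um must be positive")
  patch_count / perimeter_um
}

#' Dye-uptake ratio
#'
#' Ratio of the integrated intensity in the cell interior to the integrated
#' intensity in the whole cell.
#'
#' @param img numeric matrix.
#' @param whole,interior logical masks (from [partition_regions()]).
#' @return fraction, or `NA_real_` (attribute `reason`) when the whole-cell
#'   integral is not positive.
#' @export
uptake_ratio <- function(img, whole, interior) {
  tot <- sum(img[whole])
  if (!is.finite(tot) || tot <= 0)
    return(structure(NA_real_, reason = "non-positive whole-cell integral"))
  sum(img[interior]) / tot
}

#' Quantify every cell of a field
#'
#' Runs the full per-cell pipeline: QC filtering, region partitioning,
#' region intensities, PM/interior ratio, membrane profile, patch detection,
#' prominence, density and uptake ratio.
#'
#' @param field an `mcc_field`.
#' @param mask integer label matrix (or a list of fitted `mcc_roi`).
#' @param channel,frame which image plane to quantify.
#' @param band_width_um PM band width.
#' @param n_samples profile samples per cell.
#' @param smoothing_sigma,min_prominence_frac,min_separation_rad detector
#'   settings, see [detect_patches()].
#' @param background constant background subtracted from region intensities.
#' @param min_area,max_area,drop_border QC gates, see [filter_cells()].
#' @return data frame of class `mcc_metrics`, one row per retained cell,
#'   with attribute `rejected` (the QC log).
#' @export
quantify_field <- function(field, mask, channel = 1L, frame = 1L,
                           band_width_um = 0.4, n_samples = 360L,
                           smoothing_sigma = 2, min_prominence_frac = 0.10,
                           min_separation_rad = 4 * pi / 180,
                           background = 0,
                           min_area = 50L, max_area = 20000L,
                           drop_border = TRUE) {
  img <- get_frame(field, channel, frame)
  if (is.list(mask) && !is.matrix(mask)) {
    rois <- mask
    flt <- list(kept = rois,
                rejected = data.frame(label = integer(0), area_px = integer(0),
                                      reason = character(0)))
  } else {
    rois <- load_label_mask(mask, field)
    flt <- filter_cells(rois, min_area = min_area, max_area = max_area,
                        drop_border = drop_border)
  }
  rows <- list()
  rej_extra <- list()
  for (roi in flt$kept) {
    e <- roi$ellipse
    res <- tryCatch({
      # bounding-box-cropped partition (same geometry as partition_regions)
      hw <- band_width_um / 2 / field$pixel_size_um
      check_that(band_width_um / field$pixel_size_um < min(e$semi_axes),
                 "band width must be thinner than the minor semi-axis")
      rad <- max(e$semi_axes) + hw + 2
      bb_r <- max(0, floor(e$center[1] - rad)):
        min(nrow(img) - 1, ceiling(e$center[1] + rad))
      bb_c <- max(0, floor(e$center[2] - rad)):
        min(ncol(img) - 1, ceiling(e$center[2] + rad))
      fr <- cell_frame(bb_r, bb_c, e$center, e$semi_axes, e$orientation)
      sub <- img[bb_r + 1, bb_c + 1]
      regions <- list(whole = fr$d <= hw, interior = fr$d < -hw)
      regions$band <- regions$whole & !regions$interior
      ri <- region_intensities(sub, regions, background = background)
      prof <- extract_membrane_profile(img, e, field$pixel_size_um,
                                       band_width_um, n_samples)
      det <- detect_patches(prof, smoothing_sigma, min_prominence_frac,
                            min_separation_rad)
      g <- function(region, what) ri[ri$region == region, what]
      data.frame(
        label = roi$label, area_px = roi$area_px,
        perimeter_um = prof$perimeter_um,
        whole_mean = g("whole", "mean"), whole_int = g("whole", "integrated"),
        pm_mean = g("band", "mean"), pm_int = g("band", "integrated"),
        interior_mean = g("interior", "mean"),
        interior_int = g("interior", "integrated"),
        pm_interior_ratio = as.numeric(pm_interior_ratio(g("band", "mean"),
                                                         g("interior", "mean"))),
        patch_count = det$n,
        patch_density_per_um = det$n / prof$perimeter_um,
        prominence = as.numeric(patch_prominence(det)),
        uptake_ratio = as.numeric(uptake_ratio(sub, regions$whole,
                                               regions$interior)),
        stringsAsFactors = FALSE)
    }, error = function(err) err)
    if (inherits(res, "error"))
      rej_extra[[length(rej_extra) + 1L]] <-
        data.frame(label = roi$label, area_px = roi$area_px,
                   reason = conditionMessage(res), stringsAsFactors = FALSE)
    else rows[[length(rows) + 1L]] <- res
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(label = integer(0))
  attr(out, "rejected") <- rbind(flt$rejected,
                                 if (length(rej_extra)) do.call(rbind, rej_extra))
  class(out) <- c("mcc_metrics", class(out))
  out
}
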