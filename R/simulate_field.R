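# Synthetic micrograph generator ----------------------------------------------
#
# Renders ground-truthed equatorial cross-sections of yeast cells: a bright
# elliptical plasma-membrane ring with a dimmer interior, carrying punctate
# membrane patches (MCC/eisosome-like) of controlled count and contrast.
# Every generated artefact carries its ground truth so that each downstream
# measurement can be validated against the value it was constructed from.

#' Parameters of a synthetic field
#'
#' Defaults emulate deconvolved high-NA confocal sections of exponentially
#' growing budding yeast at 0.1 um/px: cell semi-axes 1.6-2.6 um, a membrane
#' ring of 0.4 um, ~6 patches per equatorial cross-section with a peak/valley
#' contrast of 2, and a camera noise model of Poisson shot noise plus additive
#' Gaussian read noise. The residual blur (`psf_sigma_um`) is small because
#' the emulated inputs are deconvolved images.
#'
#' @param n_cells number of cells per field.
#' @param image_shape image size in pixels, `c(rows, cols)`.
#' @param pixel_size_um physical pixel size (micrometres per pixel).
#' @param semi_axis_range_um range (min, max) each ellipse semi-axis is drawn
#'   from, in micrometres.
#' @param pm_band_width_um true thickness of the rendered membrane ring.
#' @param pm_intensity ring baseline intensity (photons/pixel).
#' @param pm_interior_ratio true ratio of ring baseline to interior intensity.
#' @param patch_lambda expected patch count per cell (Poisson mean); ignored
#'   when `patch_count_fixed` is given.
#' @param patch_count_fixed optional fixed patch count per cell.
#' @param patch_contrast true noiseless peak/valley intensity ratio (>= 1).
#' @param patch_angular_sigma_rad angular width (Gaussian sigma) of a patch.
#' @param min_patch_separation_rad minimum angular gap between patch centres;
#'   must be >= 6 * `patch_angular_sigma_rad` so that the compactly supported
#'   patch bumps do not overlap and the rendered peak/valley ratio equals
#'   `patch_contrast` exactly.
#' @param background uniform background offset (photons/pixel).
#' @param psf_sigma_um Gaussian blur scale; 0 disables blurring.
#' @param read_noise_sd additive Gaussian read-noise SD; 0 disables it.
#' @param shot_noise logical; apply Poisson shot noise to the photon signal.
#' @param seed RNG seed used by the generators (NULL = use current RNG state).
#' @return a validated list of class `mcc_field_params`.
#' @export
field_params <- function(n_cells = 12L,
                         image_shape = c(512L, 512L),
                         pixel_size_um = 0.1,
                         semi_axis_range_um = c(1.6, 2.6),
                         pm_band_width_um = 0.4,
                         pm_intensity = 800,
                         pm_interior_ratio = 3,
                         patch_lambda = 6,
                         patch_count_fixed = NULL,
                         patch_contrast = 2,
                         patch_angular_sigma_rad = 0.09,
                         min_patch_separation_rad = 0.54,
                         background = 10,
                         psf_sigma_um = 0.015,
                         read_noise_sd = 5,
                         shot_noise = TRUE,
                         seed = NULL) {
  p <- list(n_cells = as.integer(n_cells), image_shape = as.integer(image_shape),
            pixel_size_um = pixel_size_um, semi_axis_range_um = semi_axis_range_um,
            pm_band_width_um = pm_band_width_um, pm_intensity = pm_intensity,
            pm_interior_ratio = pm_interior_ratio, patch_lambda = patch_lambda,
            patch_count_fixed = patch_count_fixed, patch_contrast = patch_contrast,
            patch_angular_sigma_rad = patch_angular_sigma_rad,
            min_patch_separation_rad = min_patch_separation_rad,
            background = background, psf_sigma_um = psf_sigma_um,
            read_noise_sd = read_noise_sd, shot_noise = isTRUE(shot_noise),
            seed = seed)
  check_that(is_count(p$n_cells), "n_cells must be a positive integer")
  check_that(length(p$image_shape) == 2 && all(p$image_shape >= 32),
             "image_shape must be (rows, cols), each >= 32")
  check_that(is_number(p$pixel_size_um) && p$pixel_size_um > 0,
             "pixel_size_um must be positive")
  check_that(length(p$semi_axis_range_um) == 2 &&
               all(p$semi_axis_range_um > 0) &&
               p$semi_axis_range_um[1] <= p$semi_axis_range_um[2],
             "semi_axis_range_um must be positive (min, max) with min <= max")
  check_that(is_number(p$pm_band_width_um) && p$pm_band_width_um > 0,
             "pm_band_width_um must be positive")
  check_that(is_number(p$pm_intensity) && p$pm_intensity >= 0 &&
               is_number(p$background) && p$background >= 0,
             "intensities must be non-negative")
  check_that(is_number(p$pm_interior_ratio) && p$pm_interior_ratio > 0,
             "pm_interior_ratio must be > 0")
  check_that(is_number(p$patch_contrast) && p$patch_contrast >= 1,
             "patch_contrast must be >= 1")
  check_that(is_number(p$patch_lambda) && p$patch_lambda >= 0,
             "patch_lambda must be >= 0")
  if (!is.null(p$patch_count_fixed))
    check_that(is_count(p$patch_count_fixed + 1), # allows 0
               "patch_count_fixed must be a non-negative integer")
  check_that(is_number(p$patch_angular_sigma_rad) && p$patch_angular_sigma_rad > 0,
             "patch_angular_sigma_rad must be positive")
  check_that(is_number(p$min_patch_separation_rad) &&
               p$min_patch_separation_rad >= 6 * p$patch_angular_sigma_rad - 1e-9,
             "min_patch_separation_rad must be >= 6 * patch_angular_sigma_rad")
  check_that(is_number(p$psf_sigma_um) && p$psf_sigma_um >= 0,
             "psf_sigma_um must be >= 0")
  check_that(is_number(p$read_noise_sd) && p$read_noise_sd >= 0,
             "read_noise_sd must be >= 0")
  class(p) <- "mcc_field_params"
  p
}

# Compactly supported angular patch bump: a Gaussian of scale `sigma`
# truncated at +/- 3 sigma and rescaled to be continuous, with peak exactly 1
# and exactly 0 outside the support. Non-overlapping bumps therefore yield a
# noiseless peak/valley ratio of exactly `patch_contrast`.
patch_bump <- function(delta, sigma) {
  floor_v <- exp(-4.5)
  v <- (exp(-0.5 * (delta / sigma)^2) - floor_v) / (1 - floor_v)
  v[abs(delta) > 3 * sigma] <- 0
  v
}

#' Noiseless, blur-free ring intensity profile
#'
#' The analytic intensity the generator places on the membrane ring as a
#' function of the ellipse parametric angle. Used by the renderer itself and
#' available to tests as the ground-truth profile.
#'
#' @param theta angles (radians) at which to evaluate.
#' @param patch_angles patch centre angles (radians).
#' @param contrast peak/valley intensity ratio (>= 1).
#' @param sigma angular patch width (radians).
#' @param pm_intensity ring baseline intensity.
#' @return numeric vector of ring intensities at `theta`.
#' @export
true_ring_profile <- function(theta, patch_angles, contrast, sigma,
                              pm_intensity = 1) {
  bump <- rep(0, length(theta))
  for (a in patch_angles) {
    d <- circ_dist(theta, a)
    bump <- bump + patch_bump(d, sigma)
  }
  pm_intensity * (1 + (contrast - 1) * bump)
}

# Draw k patch angles uniformly on the circle conditional on every circular
# gap being >= min_sep: each of the k gaps is min_sep plus a Dirichlet(1,..,1)
# share of the angular surplus, rotated by a uniform offset. Exact and
# rejection-free.
sample_patch_angles <- function(k, min_sep) {
  if (k == 0) return(numeric(0))
  if (k == 1) return(stats::runif(1, 0, 2 * pi))
  surplus <- 2 * pi - k * min_sep
  check_that(surplus > 0,
             sprintf("cannot place %d patches with min separation %.3g rad",
                     k, min_sep))
  w <- stats::rexp(k)
  gaps <- min_sep + surplus * w / sum(w)
  sort(wrap_angle(stats::runif(1, 0, 2 * pi) + cumsum(c(0, gaps[-k]))))
}

# Draw per-cell patch count. A Poisson draw that is geometrically infeasible
# for the separation constraint is redrawn (documented truncation; negligible
# mass at the default lambda).
draw_patch_count <- function(params) {
  if (!is.null(params$patch_count_fixed)) return(as.integer(params$patch_count_fixed))
  kmax <- floor(2 * pi / params$min_patch_separation_rad)
  for (i in 1:100) {
    k <- stats::rpois(1, params$patch_lambda)
    if (k <= kmax) return(k)
  }
  kmax
}

# Geometry of one cell in pixel units.
# d: approximate signed Euclidean distance to the ellipse boundary (negative
# inside), from the first-order expansion of rho = sqrt((u/a)^2 + (v/b)^2).
cell_frame <- function(rows, cols, center, axes, orient) {
  x <- matrix(rep(cols - center[2], each = length(rows)), nrow = length(rows))
  y <- matrix(rep(rows - center[1], times = length(cols)), nrow = length(rows))
  u <- x * cos(orient) + y * sin(orient)
  v <- -x * sin(orient) + y * cos(orient)
  a <- axes[1]; b <- axes[2]
  rho <- sqrt((u / a)^2 + (v / b)^2)
  g <- sqrt((u / a^2)^2 + (v / b^2)^2)
  d <- ifelse(rho > 1e-9, (rho - 1) * rho / g, -min(a, b))
  theta <- atan2(v / b, u / a)
  list(rho = rho, d = d, theta = theta)
}

# Render one cell's noiseless signal into `img` and its label into `labels`.
render_cell <- function(img, labels, cell, params, ring_profile = TRUE,
                        thin_ring_weight = NULL) {
  px <- params$pixel_size_um
  hw <- params$pm_band_width_um / 2 / px
  rad <- max(cell$axes) + hw + 4
  nr <- nrow(img); nc <- ncol(img)
  rows <- max(0, floor(cell$center[1] - rad)):min(nr - 1, ceiling(cell$center[1] + rad))
  cols <- max(0, floor(cell$center[2] - rad)):min(nc - 1, ceiling(cell$center[2] + rad))
  fr <- cell_frame(rows, cols, cell$center, cell$axes, cell$orient)
  sub <- img[rows + 1, cols + 1]
  if (is.null(thin_ring_weight)) {
    # antialiased region coverage: 1-px linear ramps at the ring boundaries,
    # so the band-mean profile is free of pixelation ripple
    aa <- 0.5  # antialiasing ramp width (px)
    cov_outer <- pmin(pmax((hw - fr$d) / aa + 0.5, 0), 1)
    cov_inner <- pmin(pmax((fr$d + hw) / aa + 0.5, 0), 1)
    w_ring <- cov_outer * cov_inner
    w_int <- cov_outer * (1 - cov_inner)
    sel <- w_ring > 0
    if (any(sel)) {
      val <- if (ring_profile)
        true_ring_profile(fr$theta[sel], cell$patch_angles, cell$contrast,
                          params$patch_angular_sigma_rad, params$pm_intensity)
      else params$pm_intensity
      sub[sel] <- sub[sel] + val * w_ring[sel]
    }
    sub <- sub + params$pm_intensity / cell$pm_interior_ratio * w_int
  } else {
    # uptake mode: thin antialiased membrane ring + interior pool, each
    # carrying a prescribed share of the cell's total integrated signal
    w_m <- exp(-0.5 * (fr$d / 0.6)^2)
    w_m[abs(fr$d) > 1.8] <- 0
    margin <- thin_ring_weight$interior_margin_px
    w_i <- as.numeric(fr$d < -(hw + margin))
    tot_m <- sum(w_m); tot_i <- sum(w_i)
    S <- thin_ring_weight$total_signal
    f <- thin_ring_weight$uptake_fraction
    if (tot_m > 0) sub <- sub + (1 - f) * S * w_m / tot_m
    if (f > 0 && tot_i > 0) sub <- sub + f * S * w_i / tot_i
  }
  img[rows + 1, cols + 1] <- sub
  lsub <- labels[rows + 1, cols + 1]
  lsub[fr$rho <= 1 & lsub == 0] <- cell$label
  labels[rows + 1, cols + 1] <- lsub
  list(img = img, labels = labels)
}

# Rejection-sample non-overlapping cell geometries; fail loudly on density.
place_cells <- function(params, max_attempts = 10000L) {
  px <- params$pixel_size_um
  ax_range <- params$semi_axis_range_um / px
  hw <- params$pm_band_width_um / 2 / px
  margin <- ax_range[2] + hw + 6
  nr <- params$image_shape[1]; nc <- params$image_shape[2]
  check_that(nr - 2 * margin > 1 && nc - 2 * margin > 1,
             "image too small for the requested cell size")
  cells <- list()
  attempts <- 0L
  while (length(cells) < params$n_cells) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop_bad(sprintf(
        "cell placement failed after %d attempts: %d cells of semi-axis up to %.1f px do not fit a %dx%d image",
        max_attempts, params$n_cells, ax_range[2], nr, nc))
    axes <- sort(stats::runif(2, ax_range[1], ax_range[2]), decreasing = TRUE)
    center <- c(stats::runif(1, margin, nr - 1 - margin),
                stats::runif(1, margin, nc - 1 - margin))
    rmax <- axes[1] + hw + 2
    clash <- FALSE
    for (cl in cells) {
      if (sqrt(sum((center - cl$center)^2)) < rmax + cl$axes[1] + hw + 2) {
        clash <- TRUE; break
      }
    }
    if (clash) next
    cells[[length(cells) + 1L]] <- list(label = length(cells) + 1L,
                                        center = center, axes = axes,
                                        orient = stats::runif(1, 0, pi))
  }
  cells
}

# Apply the camera model: Gaussian PSF, Poisson shot noise, Gaussian read noise.
camera <- function(signal, params) {
  img <- gaussian_blur(signal, params$psf_sigma_um / params$pixel_size_um) +
    params$background
  img[img < 0] <- 0
  if (params$shot_noise)
    img <- matrix(stats::rpois(length(img), img), nrow = nrow(img))
  if (params$read_noise_sd > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, params$read_noise_sd),
                        nrow = nrow(img))
  img
}

truth_row <- function(cell) {
  data.frame(label = cell$label,
             center_row = cell$center[1], center_col = cell$center[2],
             a_px = cell$axes[1], b_px = cell$axes[2],
             orientation_rad = cell$orient,
             true_patch_count = length(cell$patch_angles),
             true_patch_angles = paste(sprintf("%.6f", cell$patch_angles),
                                       collapse = ";"),
             true_contrast = cell$contrast,
             true_pm_interior_ratio = cell$pm_interior_ratio,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic single-time-point field
#'
#' Places non-overlapping elliptical cells, renders each as a membrane ring
#' (baseline `pm_intensity`, interior `pm_intensity / pm_interior_ratio`)
#' carrying angular patches whose noiseless peak/valley ratio equals
#' `patch_contrast` exactly, applies the camera model, and returns the image
#' together with the label mask and the per-cell ground truth. The label mask
#' traces each cell's ellipse, so its edge bisects the membrane ring.
#'
#' @param params a [field_params()] object.
#' @param render if `FALSE`, skip image/mask rendering and return the ground
#'   truth only (fast path for statistical tests on the truth itself).
#' @return a list of class `mcc_sim`: `field` (an `mcc_field`), `mask`
#'   (integer label matrix), `truth` (data frame, one row per cell, plus
#'   field-level entries as attributes), `params`.
#' @export
generate_field <- function(params = field_params(), render = TRUE) {
  check_that(inherits(params, "mcc_field_params"), "params must come from field_params()")
  if (!is.null(params$seed)) set.seed(params$seed)
  cells <- place_cells(params)
  for (i in seq_along(cells)) {
    k <- draw_patch_count(params)
    cells[[i]]$patch_angles <- sample_patch_angles(k, params$min_patch_separation_rad)
    cells[[i]]$contrast <- params$patch_contrast
    cells[[i]]$pm_interior_ratio <- params$pm_interior_ratio
  }
  truth <- do.call(rbind, lapply(cells, truth_row))
  if (!render)
    return(structure(list(field = NULL, mask = NULL, truth = truth,
                          params = params), class = "mcc_sim"))
  img <- matrix(0, params$image_shape[1], params$image_shape[2])
  labels <- matrix(0L, params$image_shape[1], params$image_shape[2])
  for (cell in cells) {
    out <- render_cell(img, labels, cell, params)
    img <- out$img; labels <- out$labels
  }
  field <- new_field(list(gfp = camera(img, params)), params$pixel_size_um,
                     meta = list(seed = params$seed))
  structure(list(field = field, mask = labels, truth = truth, params = params),
            class = "mcc_sim")
}

#' Generate a synthetic time lapse with exponentially decaying patch density
#'
#' Cells and masks are static across frames. Each patch present at frame 0 is
#' assigned an exponential death time with half-life `half_life_min`, so a
#' patch survives to time t with probability `2^(-t / half_life_min)` and a
#' lost patch stays lost (monotone thinning). `half_life_min = Inf` disables
#' decay.
#'
#' @param params a [field_params()] object.
#' @param n_frames number of frames (>= 2).
#' @param frame_interval_min minutes between frames.
#' @param half_life_min patch-survival half-life in minutes (> 0, may be Inf).
#' @param render if `FALSE`, skip rendering (truth and frame counts only).
#' @return an `mcc_sim` list; `field` has one channel with `n_frames` frames
#'   and `times_min` set; `truth` gains per-patch death times and the field
#'   attribute `true_half_life_min`; `frame_counts` is a cells x frames matrix
#'   of true surviving-patch counts.
#' @export
generate_timelapse <- function(params = field_params(), n_frames = 13L,
                               frame_interval_min = 10,
                               half_life_min = 80, render = TRUE) {
  check_that(is_count(n_frames) && n_frames >= 2, "n_frames must be >= 2")
  check_that(is.numeric(half_life_min) && length(half_life_min) == 1 &&
               half_life_min > 0, "half_life_min must be positive (may be Inf)")
  check_that(is_number(frame_interval_min) && frame_interval_min > 0,
             "frame_interval_min must be positive")
  if (!is.null(params$seed)) set.seed(params$seed)
  cells <- place_cells(params)
  for (i in seq_along(cells)) {
    k <- draw_patch_count(params)
    cells[[i]]$patch_angles <- sample_patch_angles(k, params$min_patch_separation_rad)
    cells[[i]]$contrast <- params$patch_contrast
    cells[[i]]$pm_interior_ratio <- params$pm_interior_ratio
    cells[[i]]$death_min <- if (is.finite(half_life_min))
      stats::rexp(k, rate = log(2) / half_life_min) else rep(Inf, k)
  }
  times <- (seq_len(n_frames) - 1) * frame_interval_min
  labels <- matrix(0L, params$image_shape[1], params$image_shape[2])
  frames <- vector("list", n_frames)
  frame_counts <- matrix(0L, length(cells), n_frames)
  for (i in seq_along(cells)) for (j in seq_len(n_frames))
    frame_counts[i, j] <- sum(cells[[i]]$death_min > times[j])
  if (!render) {
    truth <- do.call(rbind, lapply(cells, truth_row))
    truth$death_min <- vapply(cells, function(cl)
      paste(sprintf("%.4f", cl$death_min), collapse = ";"), "")
    attr(truth, "true_half_life_min") <- half_life_min
    return(structure(list(field = NULL, mask = NULL, truth = truth,
                          frame_counts = frame_counts, params = params,
                          times_min = times), class = "mcc_sim"))
  }
  for (j in seq_len(n_frames)) {
    img <- matrix(0, params$image_shape[1], params$image_shape[2])
    lab_j <- matrix(0L, params$image_shape[1], params$image_shape[2])
    for (i in seq_along(cells)) {
      cell <- cells[[i]]
      alive <- cell$death_min > times[j]
      frame_counts[i, j] <- sum(alive)
      cell$patch_angles <- cell$patch_angles[alive]
      out <- render_cell(img, lab_j, cell, params)
      img <- out$img; lab_j <- out$labels
    }
    if (j == 1) labels <- lab_j
    frames[[j]] <- camera(img, params)
  }
  truth <- do.call(rbind, lapply(cells, truth_row))
  truth$death_min <- vapply(cells, function(cl)
    paste(sprintf("%.4f", cl$death_min), collapse = ";"), "")
  attr(truth, "true_half_life_min") <- half_life_min
  field <- new_field(list(gfp = frames), params$pixel_size_um,
                     times_min = times, meta = list(seed = params$seed))
  structure(list(field = field, mask = labels, truth = truth,
                 frame_counts = frame_counts, params = params),
            class = "mcc_sim")
}

#' Generate a two-channel colocalization pair
#'
#' Channel 2 reuses a fraction `shared_fraction` of channel 1's patch angles
#' in every cell (the remainder is drawn independently under the same
#' separation constraint), is scaled by `channel2_gain`, and is rigidly
#' translated by `true_shift` pixels before the camera model is applied
#' independently per channel.
#'
#' @param params a [field_params()] object.
#' @param shared_fraction fraction of channel-1 patch angles reused in
#'   channel 2, in `[0, 1]`.
#' @param true_shift integer pixel translation `c(d_row, d_col)` applied to
#'   channel 2; `abs()` must be <= `max_shift`.
#' @param channel2_gain intensity scale of channel 2 relative to channel 1.
#' @param max_shift maximum permitted `|true_shift|` component.
#' @return an `mcc_sim` list with a two-channel `field` (`ch1`, `ch2`); the
#'   truth carries attributes `true_shared_fraction` and `true_shift`.
#' @export
generate_coloc_pair <- function(params = field_params(), shared_fraction = 0.5,
                                true_shift = c(0L, 0L), channel2_gain = 0.8,
                                max_shift = 10L) {
  check_that(is_number(shared_fraction) && shared_fraction >= 0 &&
               shared_fraction <= 1, "shared_fraction must be in [0, 1]")
  check_that(length(true_shift) == 2 && all(true_shift == round(true_shift)) &&
               all(abs(true_shift) <= max_shift),
             "true_shift must be integer pixels within +/- max_shift")
  true_shift <- as.integer(true_shift)
  if (!is.null(params$seed)) set.seed(params$seed)
  cells <- place_cells(params)
  for (i in seq_along(cells)) {
    k <- draw_patch_count(params)
    ang1 <- sample_patch_angles(k, params$min_patch_separation_rad)
    n_shared <- round(shared_fraction * k)
    shared <- if (n_shared > 0) sort(sample(ang1, n_shared)) else numeric(0)
    ang2 <- shared
    need <- k - n_shared
    if (need > 0) {
      for (t in 1:5000) {
        a <- stats::runif(1, 0, 2 * pi)
        if (!length(ang2) || min(circ_dist(a, ang2)) >=
            params$min_patch_separation_rad) {
          ang2 <- c(ang2, a)
          if (length(ang2) == k) break
        }
      }
    }
    cells[[i]]$patch_angles <- ang1
    cells[[i]]$patch_angles2 <- sort(ang2)
    cells[[i]]$contrast <- params$patch_contrast
    cells[[i]]$pm_interior_ratio <- params$pm_interior_ratio
  }
  shape <- params$image_shape
  img1 <- matrix(0, shape[1], shape[2])
  img2 <- matrix(0, shape[1], shape[2])
  labels <- matrix(0L, shape[1], shape[2])
  for (cell in cells) {
    out <- render_cell(img1, labels, cell, params)
    img1 <- out$img; labels <- out$labels
    cell1 <- cell; cell1$patch_angles <- cell$patch_angles2
    out2 <- render_cell(img2, matrix(0L, shape[1], shape[2]), cell1, params)
    img2 <- out2$img
  }
  img2 <- translate_image(img2 * channel2_gain, true_shift, fill = 0)
  field <- new_field(list(ch1 = camera(img1, params),
                          ch2 = camera(img2, params)),
                     params$pixel_size_um, meta = list(seed = params$seed))
  truth <- do.call(rbind, lapply(cells, truth_row))
  truth$true_patch_angles_ch2 <- vapply(cells, function(cl)
    paste(sprintf("%.6f", cl$patch_angles2), collapse = ";"), "")
  attr(truth, "true_shared_fraction") <- shared_fraction
  attr(truth, "true_shift") <- true_shift
  structure(list(field = field, mask = labels, truth = truth, params = params),
            class = "mcc_sim")
}

#' Generate a dye-uptake field with a controlled interior fraction
#'
#' Per cell, a fraction `uptake_fraction` of the cell's total noiseless
#' integrated signal is placed in an interior pool (kept a small margin away
#' from the membrane band so that blur leakage stays within the measurement
#' tolerance) and the remainder on a thin membrane ring at the cell boundary.
#'
#' @param params a [field_params()] object.
#' @param uptake_fraction fraction of total signal in the interior, `[0, 1]`.
#' @param interior_margin_um gap between the quantification band and the
#'   interior pool.
#' @return an `mcc_sim` list; truth carries attribute `true_uptake_fraction`.
#' @export
generate_uptake_field <- function(params = field_params(), uptake_fraction = 0.5,
                                  interior_margin_um = 0.3) {
  check_that(is_number(uptake_fraction) && uptake_fraction >= 0 &&
               uptake_fraction <= 1, "uptake_fraction must be in [0, 1]")
  if (!is.null(params$seed)) set.seed(params$seed)
  cells <- place_cells(params)
  img <- matrix(0, params$image_shape[1], params$image_shape[2])
  labels <- matrix(0L, params$image_shape[1], params$image_shape[2])
  for (i in seq_along(cells)) {
    cells[[i]]$patch_angles <- numeric(0)
    cells[[i]]$contrast <- 1
    cells[[i]]$pm_interior_ratio <- params$pm_interior_ratio
    ring_area <- pi * (prod(cells[[i]]$axes + 1) - prod(cells[[i]]$axes - 1))
    out <- render_cell(img, labels, cells[[i]], params,
                       thin_ring_weight = list(
                         uptake_fraction = uptake_fraction,
                         total_signal = params$pm_intensity * ring_area,
                         interior_margin_px = interior_margin_um / params$pixel_size_um))
    img <- out$img; labels <- out$labels
  }
  field <- new_field(list(dye = camera(img, params)), params$pixel_size_um,
                     meta = list(seed = params$seed))
  truth <- do.call(rbind, lapply(cells, truth_row))
  attr(truth, "true_uptake_fraction") <- uptake_fraction
  structure(list(field = field, mask = labels, truth = truth, params = params),
            class = "mcc_sim")
}

#' Rigid integer-pixel translation of an image
#' @param img numeric matrix.
#' @param shift integer `c(d_row, d_col)`; positive moves content down/right.
#' @param fill value for vacated pixels.
#' @return translated matrix of the same size.
#' @export
translate_image <- function(img, shift, fill = 0) {
  dr <- as.integer(shift[1]); dc <- as.integer(shift[2])
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - dr; src_c <- seq_len(nc) - dc
  ok_r <- src_r >= 1 & src_r <= nr; ok_c <- src_c >= 1 & src_c <= nc
  out[which(ok_r), which(ok_c)] <- img[src_r[ok_r], src_c[ok_c]]
  out
}

#' Write a simulation to disk
#'
#' Writes the image(s) as multi-page 16-bit TIFF, the label mask as 16-bit
#' TIFF, the per-cell ground truth as CSV, and the field-level truth (seed,
#' shared fraction, shift, half-life, uptake fraction, saturation) as JSON.
#'
#' @param sim an `mcc_sim` from one of the generators.
#' @param dir output directory (created if missing).
#' @param stem file-name stem.
#' @return invisibly, the named vector of written paths.
#' @export
write_simulation <- function(sim, dir, stem = "field") {
  check_that(inherits(sim, "mcc_sim"), "sim must be an mcc_sim")
  check_that(!is.null(sim$field), "sim was generated with render = FALSE")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pages <- unlist(sim$field$channels, recursive = FALSE)
  img_path <- file.path(dir, paste0(stem, ".tif"))
  sat <- suppressWarnings(write_tiff(pages, img_path, bits = 16L))
  mask_path <- file.path(dir, paste0(stem, "_mask.tif"))
  write_tiff(sim$mask, mask_path, bits = 16L)
  truth_path <- file.path(dir, paste0(stem, "_truth.csv"))
  utils::write.csv(sim$truth, truth_path, row.names = FALSE)
  meta <- list(seed = sim$params$seed,
               pixel_size_um = sim$field$pixel_size_um,
               channels = names(sim$field$channels),
               n_frames = n_frames(sim$field),
               times_min = sim$field$times_min,
               saturation_fraction = sat)
  for (a in c("true_shared_fraction", "true_shift", "true_half_life_min",
              "true_uptake_fraction"))
    if (!is.null(attr(sim$truth, a))) meta[[a]] <- attr(sim$truth, a)
  meta_path <- file.path(dir, paste0(stem, "_truth.json"))
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(image = img_path, mask = mask_path, truth = truth_path,
              meta = meta_path))
}
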