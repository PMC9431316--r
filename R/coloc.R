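# Two-channel registration and Pearson colocalization ------------------------

#' Register two channels by integer-pixel translation
#'
#' Exhaustive search over translations within `+/- max_shift_px`, maximizing
#' the Pearson correlation of the overlapping region. Ties are broken toward
#' the smaller `|d_row| + |d_col|`, then lexicographically by (d_row, d_col).
#'
#' @param ch1,ch2 numeric matrices of equal dimensions; the returned shift is
#'   the displacement of `ch2` relative to `ch1` (so `ch2` rolled by
#'   `(2, -1)` registers as `c(2, -1)`); apply the negated shift to `ch2` to
#'   align it onto `ch1`.
#' @param max_shift_px search window half-width (default 5).
#' @return integer `c(d_row, d_col)` with attribute `score` (the correlation
#'   at the optimum). If the optimum lies on the window boundary a warning
#'   notes that the true shift may be larger.
#' @export
register_channels <- function(ch1, ch2, max_shift_px = 5L) {
  check_that(all(dim(ch1) == dim(ch2)), "channels must share dimensions")
  check_that(stats::sd(ch1) > 0 && stats::sd(ch2) > 0,
             "cannot register a flat (zero-variance) channel")
  m <- as.integer(max_shift_px)
  nr <- nrow(ch1); nc <- ncol(ch1)
  best <- NULL
  for (dr in -m:m) {
    r1 <- (max(1, 1 - dr)):(min(nr, nr - dr))
    r2 <- r1 + dr
    for (dc in -m:m) {
      c1 <- (max(1, 1 - dc)):(min(nc, nc - dc))
      c2 <- c1 + dc
      a <- ch1[r1, c1]; b <- ch2[r2, c2]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) next
      r <- stats::cor(as.vector(a), as.vector(b))
      cand <- list(shift = c(dr, dc), score = r,
                   rank = c(-r, abs(dr) + abs(dc), dr, dc))
      if (is.null(best) || order_rank(cand$rank, best$rank)) best <- cand
    }
  }
  check_that(!is.null(best), "registration failed: no valid overlap")
  if (any(abs(best$shift) == m))
    warning("register_channels: optimum on the search-window boundary; ",
            "the true shift may exceed max_shift_px = ", m)
  structure(as.integer(best$shift), score = best$score)
}

# TRUE when rank vector a precedes b lexicographically (strictly better).
order_rank <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' Pearson colocalization coefficient over a cell mask
#'
#' Sample Pearson correlation of the two (already registered) channels over
#' the pixels of one cell.
#'
#' @param ch1,ch2 numeric matrices.
#' @param mask logical matrix selecting the cell's pixels (>= 10 px).
#' @return correlation in `[-1, 1]`, or `NA_real_` with attribute `reason`
#'   when a channel does not vary within the mask.
#' @export
pearson_coloc <- function(ch1, ch2, mask) {
  check_that(all(dim(ch1) == dim(ch2)) && all(dim(ch1) == dim(mask)),
             "channels and mask must share dimensions")
  n <- sum(mask)
  check_that(n >= 10, "mask must contain at least 10 pixels")
  a <- ch1[mask]; b <- ch2[mask]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(structure(NA_real_, reason = "zero variance within mask"))
  stats::cor(a, b)
}

#' Per-cell colocalization of a two-channel field
#'
#' Registers channel 2 onto channel 1 (unless a shift is supplied), then
#' computes the per-cell Pearson coefficient over each retained ROI.
#'
#' @param field two-channel `mcc_field`.
#' @param mask integer label matrix.
#' @param channels indices/names of the two channels (default first two).
#' @param max_shift_px registration window.
#' @param shift optional known integer shift to apply instead of registering.
#' @param ... QC arguments passed to [filter_cells()].
#' @return data frame (label, pearson_r, n_px) with attribute `shift`.
#' @export
coloc_field <- function(field, mask, channels = c(1L, 2L), max_shift_px = 5L,
                        shift = NULL, ...) {
  check_that(length(field$channels) >= 2, "field must have two channels")
  ch1 <- get_frame(field, channels[1])
  ch2 <- get_frame(field, channels[2])
  if (is.null(shift)) shift <- register_channels(ch1, ch2, max_shift_px)
  ch2r <- translate_image(ch2, -shift, fill = NA)
  # exclude vacated border pixels from every cell
  valid <- !is.na(ch2r)
  ch2r[!valid] <- 0
  flt <- filter_cells(load_label_mask(mask, field), ...)
  rows <- lapply(flt$kept, function(roi) {
    m <- matrix(FALSE, nrow(ch1), ncol(ch1))
    m[roi$pixel_idx] <- TRUE
    m <- m & valid
    r <- if (sum(m) >= 10) pearson_coloc(ch1, ch2r, m)
    else structure(NA_real_, reason = "too few pixels")
    data.frame(label = roi$label, pearson_r = as.numeric(r), n_px = sum(m),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "shift") <- as.integer(shift)
  out
}

#' Normalized dual-channel membrane line profiles
#'
#' Extracts both channels' membrane profiles along the same fitted ellipse
#' and min-max normalizes each independently to `[0, 1]` on a common angular
#' axis (the presentation used for dual-marker membrane line plots).
#'
#' @param field two-channel `mcc_field`.
#' @param ellipse fitted cell ellipse.
#' @param channels the two channels to plot.
#' @param band_width_um,n_samples profile settings, see
#'   [extract_membrane_profile()].
#' @return data frame: angle, plus one normalized column per channel. A
#'   constant profile normalizes to all zeros and is flagged in attribute
#'   `flat_channels`.
#' @export
normalized_line_profiles <- function(field, ellipse, channels = c(1L, 2L),
                                     band_width_um = 0.4, n_samples = 360L) {
  check_that(length(field$channels) >= 2, "field must have two channels")
  flat <- character(0)
  cols <- lapply(channels, function(ch) {
    prof <- extract_membrane_profile(get_frame(field, ch), ellipse,
                                     field$pixel_size_um, band_width_um,
                                     n_samples)
    rng <- range(prof$intensities)
    if (diff(rng) == 0) {
      flat <<- c(flat, as.character(ch))
      rep(0, n_samples)
    } else (prof$intensities - rng[1]) / diff(rng)
  })
  names(cols) <- paste0("ch", channels)
  out <- cbind(data.frame(angle = 2 * pi * (seq_len(n_samples) - 1) / n_samples),
               as.data.frame(cols))
  attr(out, "flat_channels") <- flat
  out
}
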