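# Field: the in-memory image container ---------------------------------------

#' Construct a Field
#'
#' A `Field` holds one imaged position: one or more channels, each a stack of
#' frames with identical dimensions, plus the pixel size. Single-time-point
#' fields have one frame per channel.
#'
#' @param channels named list; each element is a numeric matrix (one frame) or
#'   a list of numeric matrices (frames of a time lapse). All frames of all
#'   channels must share dimensions.
#' @param pixel_size_um physical pixel size in micrometres per pixel.
#' @param times_min optional numeric vector of frame acquisition times in
#'   minutes (length = number of frames).
#' @param meta optional list of free-form metadata (kept on round trips).
#' @return an object of class `mcc_field`.
#' @export
new_field <- function(channels, pixel_size_um, times_min = NULL, meta = list()) {
  check_that(is.list(channels) && length(channels) >= 1,
             "channels must be a non-empty list")
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    names(channels) <- paste0("ch", seq_along(channels))
  channels <- lapply(channels, function(ch) if (is.matrix(ch)) list(ch) else ch)
  dims <- unique(do.call(rbind, lapply(channels, function(ch)
    do.call(rbind, lapply(ch, dim)))))
  check_that(nrow(dims) == 1, "all channels/frames must share dimensions")
  nfr <- vapply(channels, length, 1L)
  check_that(length(unique(nfr)) == 1, "all channels must have equal frame counts")
  check_that(is_number(pixel_size_um) && pixel_size_um > 0,
             "pixel_size_um must be a positive number")
  if (!is.null(times_min))
    check_that(length(times_min) == nfr[1],
               "times_min length must equal the frame count")
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 times_min = times_min, meta = meta),
            class = "mcc_field")
}

#' @export
print.mcc_field <- function(x, ...) {
  d <- dim(x$channels[[1]][[1]])
  cat(sprintf("<mcc_field> %d x %d px, %d channel(s) [%s], %d frame(s), %.3g um/px\n",
              d[1], d[2], length(x$channels),
              paste(names(x$channels), collapse = ", "),
              n_frames(x), x$pixel_size_um))
  invisible(x)
}

#' Number of frames in a Field
#' @param field an `mcc_field`.
#' @return integer frame count.
#' @export
n_frames <- function(field) length(field$channels[[1]])

#' Extract one frame of one channel as a matrix
#' @param field an `mcc_field`.
#' @param channel channel name or index.
#' @param frame frame index (1-based).
#' @return numeric matrix.
#' @export
get_frame <- function(field, channel = 1L, frame = 1L) {
  ch <- field$channels[[channel]]
  check_that(frame >= 1 && frame <= length(ch), "frame out of range")
  ch[[frame]]
}

#' Maximum-intensity projection across frames
#'
#' Collapses the frame axis of every channel by the elementwise maximum, the
#' standard presentation for focal-plane stacks and short time windows.
#'
#' @param field an `mcc_field` with the planes stored as frames.
#' @return an `mcc_field` with a single frame per channel;
#'   `meta$projection = "max"` records the operation.
#' @export
max_project <- function(field) {
  nf <- n_frames(field)
  if (nf < 2) {
    warning("max_project: single plane, returning the field unchanged")
    return(field)
  }
  ch <- lapply(field$channels, function(frames) {
    acc <- frames[[1]]
    for (i in 2:nf) acc <- pmax(acc, frames[[i]])
    list(acc)
  })
  meta <- field$meta
  meta$projection <- "max"
  meta$projected_frames <- nf
  new_field(ch, field$pixel_size_um, times_min = NULL, meta = meta)
}
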