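# Minimal baseline TIFF I/O --------------------------------------------------
#
# Self-contained reader/writer for the subset of TIFF 6.0 that microscopy
# exports and segmenters actually emit for quantification: little-endian,
# uncompressed, single-sample (grayscale / integer label) images, 8-, 16- or
# 32-bit unsigned, one or more pages (channels or frames). No external image
# package is required.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, spp = 277L,
               rows_per_strip = 278L, strip_counts = 279L, sample_format = 339L)

#' Write matrices as a multi-page 16-bit TIFF
#'
#' Pages are written uncompressed, little-endian, one strip per page. Values
#' are rounded and clipped to the unsigned range of `bits`; the fraction of
#' clipped (saturated) pixels is returned invisibly and reported with a
#' warning when nonzero.
#'
#' @param pages a numeric matrix or list of numeric matrices (equal dims).
#' @param path output file path.
#' @param bits bits per sample: 8, 16 (default) or 32.
#' @return invisibly, the fraction of saturated pixels.
#' @export
write_tiff <- function(pages, path, bits = 16L) {
  if (is.matrix(pages)) pages <- list(pages)
  check_that(length(pages) >= 1 && all(vapply(pages, is.matrix, TRUE)),
             "pages must be a matrix or list of matrices")
  check_that(bits %in% c(8L, 16L, 32L), "bits must be 8, 16 or 32")
  dims <- unique(t(vapply(pages, dim, c(1L, 1L))))
  check_that(nrow(dims) == 1, "all pages must share dimensions")
  nr <- dims[1, 1]; nc <- dims[1, 2]
  vmax <- 2^bits - 1
  n_sat <- 0L; n_tot <- 0L
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  # header
  writeBin(charToRaw("II"), con); w2(42L)
  data_bytes <- nr * nc * (bits / 8)
  ifd0 <- 8 + length(pages) * data_bytes
  w4(ifd0)
  # pixel data, page after page (row-major)
  for (pg in pages) {
    v <- round(t(pg))
    n_tot <- n_tot + length(v)
    n_sat <- n_sat + sum(v < 0 | v > vmax)
    v <- pmin(pmax(v, 0), vmax)
    if (bits == 8L) {
      writeBin(as.raw(v), con)
    } else {
      # writeBin truncates to the low bytes, which is exactly the unsigned
      # little-endian encoding for values within range (32-bit values above
      # .Machine$integer.max are clipped there; labels/intensities never reach it)
      v <- pmin(v, .Machine$integer.max)
      writeBin(as.integer(v), con, size = bits / 8, endian = "little")
    }
  }
  # IFDs
  entry <- function(tag, type, count, value) {
    w2(tag); w2(type); w4(count)
    if (type == 3L) { w2(value); w2(0L) } else w4(value)
  }
  for (i in seq_along(pages)) {
    w2(10L)  # entry count
    entry(TIFF_TAGS[["width"]], 4L, 1L, nc)
    entry(TIFF_TAGS[["length"]], 4L, 1L, nr)
    entry(TIFF_TAGS[["bits"]], 3L, 1L, bits)
    entry(TIFF_TAGS[["compression"]], 3L, 1L, 1L)
    entry(TIFF_TAGS[["photometric"]], 3L, 1L, 1L)
    entry(TIFF_TAGS[["strip_offsets"]], 4L, 1L, 8 + (i - 1) * data_bytes)
    entry(TIFF_TAGS[["spp"]], 3L, 1L, 1L)
    entry(TIFF_TAGS[["rows_per_strip"]], 4L, 1L, nr)
    entry(TIFF_TAGS[["strip_counts"]], 4L, 1L, data_bytes)
    entry(TIFF_TAGS[["sample_format"]], 3L, 1L, 1L)
    # offset of next IFD (0 terminates); IFD size = 2 + 10*12 + 4 = 126
    w4(if (i < length(pages)) ifd0 + i * 126 else 0L)
  }
  sat <- n_sat / n_tot
  if (sat > 0)
    warning(sprintf("write_tiff: %.3g%% of pixels saturated at %d bits",
                    100 * sat, bits))
  invisible(sat)
}

#' Read a grayscale/label TIFF
#'
#' Reads little-endian, uncompressed, single-sample baseline TIFFs (the
#' format written by [write_tiff()] and by common segmentation tools when
#' exporting label masks).
#'
#' @param path file path.
#' @return a list of numeric matrices, one per page, with attribute `bits`.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  check_that(length(raw) > 8, "not a TIFF file: ", path)
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.numeric(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
  check_that(rawToChar(raw[1:2]) == "II" && u16(2) == 42L,
             "unsupported TIFF (need little-endian baseline): ", path)
  type_size <- c(1, 1, 2, 4, 8)
  read_values <- function(off, type, count) {
    sz <- type_size[type]
    src <- if (sz * count <= 4) off + 8 else u32(off + 8)
    vapply(seq_len(count) - 1, function(k) {
      if (sz == 1) as.numeric(raw[src + k + 1])
      else if (sz == 2) u16(src + 2 * k)
      else u32(src + 4 * k)
    }, 0)
  }
  pages <- list()
  ifd <- u32(4)
  while (ifd != 0) {
    n <- u16(ifd)
    tags <- list()
    for (j in seq_len(n)) {
      off <- ifd + 2 + (j - 1) * 12
      tag <- u16(off); type <- u16(off + 2); count <- u32(off + 4)
      if (tag %in% TIFF_TAGS && type %in% c(1L, 3L, 4L))
        tags[[as.character(tag)]] <- read_values(off, type, count)
    }
    g <- function(name, default = NULL) {
      v <- tags[[as.character(TIFF_TAGS[[name]])]]
      if (is.null(v)) default else v
    }
    nc <- g("width"); nr <- g("length")
    check_that(!is.null(nc) && !is.null(nr), "TIFF page missing dimensions")
    bits <- g("bits", 8)[1]
    check_that(g("compression", 1) == 1, "compressed TIFF not supported")
    check_that(g("spp", 1) == 1, "multi-sample TIFF not supported")
    check_that(g("sample_format", 1) == 1, "only unsigned integer TIFF supported")
    offs <- g("strip_offsets"); cnts <- g("strip_counts")
    check_that(!is.null(offs) && !is.null(cnts), "TIFF page missing strip layout")
    vals <- unlist(lapply(seq_along(offs), function(s) {
      b <- as.numeric(raw[offs[s] + seq_len(cnts[s])])
      if (bits == 8) return(b)
      m <- matrix(b, nrow = bits / 8)
      drop(2^(8 * (seq_len(bits / 8) - 1)) %*% m)
    }))
    check_that(length(vals) == nr * nc, "TIFF strip data does not match dimensions")
    pg <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
    pages[[length(pages) + 1L]] <- pg
    ifd <- u32(ifd + 2 + n * 12)
  }
  attr(pages, "bits") <- NULL
  pages
}
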