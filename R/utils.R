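#' @keywords internal
"_PACKAGE"

# Internal validation helpers -------------------------------------------------

stop_bad <- function(...) stop(..., call. = FALSE)

check_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop_bad(...)
  invisible(TRUE)
}

is_count <- function(x) length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)

is_number <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)

#' Wrap angles into [0, 2*pi)
#' @param theta numeric vector of angles (radians).
#' @return angles reduced modulo 2*pi into [0, 2*pi).
#' @keywords internal
wrap_angle <- function(theta) theta %% (2 * pi)

#' Smallest circular distance between angles
#' @param a,b angles in radians.
#' @return elementwise circular distance in [0, pi].
#' @keywords internal
circ_dist <- function(a, b) {
  d <- abs(wrap_angle(a) - wrap_angle(b))
  pmin(d, 2 * pi - d)
}

#' Ramanujan's approximation to the ellipse perimeter
#'
#' Second Ramanujan approximation, accurate to well below 0.01% for the
#' aspect ratios of yeast cell cross-sections. Exact for circles.
#'
#' @param a,b semi-axes (same unit; the result is in that unit).
#' @return approximate perimeter.
#' @export
#' @examples
#' ellipse_perimeter(10, 10)  # 2*pi*10
ellipse_perimeter <- function(a, b) {
  check_that(all(a > 0) && all(b > 0), "semi-axes must be positive")
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

# Bilinear interpolation of a matrix at fractional (row, col) positions.
# 0-based coordinates: (0, 0) is the centre of the top-left pixel.
# Points outside the image clamp to the border pixel.
bilinear <- function(img, row, col) {
  nr <- nrow(img); nc <- ncol(img)
  r <- pmin(pmax(row, 0), nr - 1)
  c <- pmin(pmax(col, 0), nc - 1)
  r0 <- pmin(floor(r), nr - 2); c0 <- pmin(floor(c), nc - 2)
  fr <- r - r0; fc <- c - c0
  i00 <- img[cbind(r0 + 1, c0 + 1)]
  i01 <- img[cbind(r0 + 1, c0 + 2)]
  i10 <- img[cbind(r0 + 2, c0 + 1)]
  i11 <- img[cbind(r0 + 2, c0 + 2)]
  (1 - fr) * ((1 - fc) * i00 + fc * i01) + fr * ((1 - fc) * i10 + fc * i11)
}

# FFT-based Gaussian blur with sigma in pixels; sigma = 0 is the identity.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  nr <- nrow(img); nc <- ncol(img)
  # frequency-domain Gaussian (circular convolution; fields keep a background
  # margin so wrap-around is negligible)
  fr <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1)) / nr
  fc <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1)) / nc
  gr <- exp(-2 * pi^2 * sigma^2 * fr^2)
  gc <- exp(-2 * pi^2 * sigma^2 * fc^2)
  ker <- outer(gr, gc)
  Re(stats::fft(stats::fft(img) * ker, inverse = TRUE)) / (nr * nc)
}

# Circular Gaussian smoothing of a 1-D profile (sigma in samples).
smooth_circular <- function(x, sigma) {
  if (sigma <= 0) return(x)
  n <- length(x)
  half <- min(max(1L, ceiling(4 * sigma)), floor((n - 1) / 2))
  k <- exp(-0.5 * ((-half):half)^2 / sigma^2)
  k <- k / sum(k)
  as.numeric(stats::filter(x, k, method = "convolution",
                           sides = 2, circular = TRUE))
}
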