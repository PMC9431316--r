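# Shared fixtures: everything is generated in code at test time.

# noise- and blur-free field parameters (geometry identical to the defaults)
noise_off_params <- function(...) {
  args <- list(...)
  defaults <- list(shot_noise = FALSE, read_noise_sd = 0, psf_sigma_um = 0,
                   background = 0)
  do.call(field_params, utils::modifyList(defaults, args))
}

# parameters emulating dual patch-resident markers (eisosome-protein pairs):
# no membrane/interior contrast, narrow bright patches, so the Pearson
# coefficient reflects patch overlap rather than shared cell geometry
coloc_params <- function(...) {
  args <- list(...)
  defaults <- list(pm_interior_ratio = 1, patch_contrast = 4,
                   patch_angular_sigma_rad = 0.05,
                   min_patch_separation_rad = 0.3)
  do.call(field_params, utils::modifyList(defaults, args))
}

# a filled disc mask of radius r centred in an n x n image
disc_mask <- function(n, r, center = c((n - 1) / 2, (n - 1) / 2), label = 1L) {
  rows <- matrix(rep(0:(n - 1), times = n), n)
  cols <- matrix(rep(0:(n - 1), each = n), n)
  m <- matrix(0L, n, n)
  m[(rows - center[1])^2 + (cols - center[2])^2 <= r^2] <- label
  m
}

# axis-aligned filled ellipse mask (semi-axes a along cols, b along rows)
ellipse_mask <- function(n, a, b, center = c((n - 1) / 2, (n - 1) / 2)) {
  rows <- matrix(rep(0:(n - 1), times = n), n)
  cols <- matrix(rep(0:(n - 1), each = n), n)
  m <- matrix(0L, n, n)
  m[((cols - center[2]) / a)^2 + ((rows - center[1]) / b)^2 <= 1] <- 1L
  m
}

# wrap a plain intensity vector as an mcc_profile on a unit circle
as_profile <- function(intensities, perimeter_um = 10) {
  n <- length(intensities)
  structure(list(angles = 2 * pi * (seq_len(n) - 1) / n,
                 intensities = intensities, perimeter_um = perimeter_um,
                 n_samples = as.integer(n)),
            class = "mcc_profile")
}

parse_angles <- function(s) {
  if (!nzchar(s)) return(numeric(0))
  as.numeric(strsplit(s, ";")[[1]])
}
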