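circle_ellipse <- function(r, center = c(31.5, 31.5))
  list(center = center, semi_axes = c(r, r), orientation = 0)

test_that("partition_regions tiles the cell and matches the annulus area", {
  e <- circle_ellipse(20)
  reg <- partition_regions(e, c(64, 64), band_width_um = 0.4,
                           pixel_size_um = 0.1)
  expect_equal(sum(reg$band) + sum(reg$interior), sum(reg$whole))
  expect_false(any(reg$band & reg$interior))
  # pixel-counting oracle: annulus 18..22 px has area pi*(22^2 - 18^2)
  expect_lt(abs(sum(reg$band) / (pi * (22^2 - 18^2)) - 1), 0.05)
  expect_error(partition_regions(circle_ellipse(4), c(64, 64), 0.4, 0.1),
               "thinner")
})

test_that("region intensities are sums/means with additivity", {
  img <- matrix(7, 20, 20)
  mask <- matrix(FALSE, 20, 20); mask[1:10, 1:10] <- TRUE
  ri <- region_intensities(img, list(m = mask))
  expect_equal(ri$integrated, 700)
  expect_equal(ri$mean, 7)
  m2 <- matrix(FALSE, 20, 20); m2[11:20, 11:20] <- TRUE
  set.seed(2); img2 <- matrix(stats::runif(400), 20, 20)
  ri2 <- region_intensities(img2, list(a = mask, b = m2, both = mask | m2))
  expect_equal(ri2$integrated[1] + ri2$integrated[2], ri2$integrated[3])
  expect_true(is.na(region_intensities(img, list(e = matrix(FALSE, 20, 20)))$mean))
})

test_that("pm_interior_ratio handles uniform and degenerate input", {
  expect_equal(pm_interior_ratio(5, 5), 1)
  flagged <- pm_interior_ratio(5, 0)
  expect_true(is.na(flagged))
  expect_match(attr(flagged, "reason"), "interior")
})

test_that("PM/interior ratio recovers generator truth without noise", {
  sim <- generate_field(noise_off_params(n_cells = 8, pm_interior_ratio = 3,
                                         patch_lambda = 0, seed = 41))
  m <- quantify_field(sim$field, sim$mask)
  expect_lt(abs(mean(m$pm_interior_ratio) / 3 - 1), 0.05)
})

test_that("membrane profile is flat on uniform input and perimeter is Ramanujan", {
  img <- matrix(5, 64, 64)
  prof <- extract_membrane_profile(img, circle_ellipse(20), 0.1)
  expect_lt(diff(range(prof$intensities)) / mean(prof$intensities), 0.01)
  # circle: exact closed form
  expect_equal(ellipse_perimeter(20, 20), 2 * pi * 20, tolerance = 1e-12)
  # high-resolution numeric arc-length oracle for a = 20, b = 10 px
  th <- seq(0, pi / 2, length.out = 200001)
  arc <- 4 * sum(sqrt((20 * sin(th))^2 + (10 * cos(th))^2)) * (th[2] - th[1])
  expect_equal(ellipse_perimeter(20, 10), arc, tolerance = 1e-5)
  expect_equal(prof$perimeter_um, 2 * pi * 20 * 0.1)
  expect_equal(ellipse_perimeter(20, 10) * 0.1, 9.688, tolerance = 1e-3)
  # out-of-bounds ellipse is an error, not silent garbage
  expect_error(extract_membrane_profile(img, circle_ellipse(33), 0.1),
               "outside")
})

test_that("detect_patches finds generator bumps and respects circular wrap", {
  expect_equal(detect_patches(as_profile(rep(3, 360)))$n, 0)
  expect_equal(detect_patches(as_profile(rep(0, 360)))$n, 0)
  # noiseless profile with 4 generator bumps: peaks within 2 samples of truth
  set.seed(42)
  th <- 2 * pi * (0:359) / 360
  for (rep in 1:5) {
    ang <- mccquant:::sample_patch_angles(4, 0.54)
    det <- detect_patches(as_profile(true_ring_profile(th, ang, 2, 0.09, 800)))
    expect_equal(det$n, 4)
    for (a in ang)
      expect_lt(min(circ_dist(det$angles, a)), 2 * (2 * pi / 360) + 1e-9)
  }
  # rendered noiseless field: counts exact, angles within 4 samples (the
  # fitted-ellipse parametric angle differs slightly from the true one)
  sim <- generate_field(noise_off_params(n_cells = 4, patch_count_fixed = 4,
                                         seed = 42))
  m <- quantify_field(sim$field, sim$mask)
  expect_true(all(m$patch_count == 4))
  rois <- filter_cells(load_label_mask(sim$mask))$kept
  img <- get_frame(sim$field)
  for (roi in rois) {
    det <- detect_patches(extract_membrane_profile(img, roi$ellipse, 0.1))
    tr <- parse_angles(sim$truth$true_patch_angles[
      sim$truth$label == roi$label])
    for (a in tr)
      expect_lt(min(circ_dist(det$angles, a)), 4 * (2 * pi / 360) + 1e-9)
  }
  # a single bump at the wrap point is one peak, not two
  th <- 2 * pi * (0:359) / 360
  prof <- as_profile(true_ring_profile(th, 0, contrast = 2, sigma = 0.09,
                                       pm_intensity = 100))
  det <- detect_patches(prof)
  expect_equal(det$n, 1)
  expect_lt(circ_dist(det$angles, 0), 2 * (2 * pi / 360) + 1e-9)
})

test_that("detection is invariant to uniform rescaling and monotone in threshold", {
  set.seed(43)
  th <- 2 * pi * (0:359) / 360
  x <- true_ring_profile(th, c(0.5, 2.5, 4.5), 2, 0.09, 200) + stats::rnorm(360, 0, 6)
  p1 <- detect_patches(as_profile(x))
  p2 <- detect_patches(as_profile(x * 7.3))
  expect_identical(p1$indices, p2$indices)
  counts <- vapply(c(0.02, 0.05, 0.1, 0.2, 0.4, 0.8),
                   function(f) detect_patches(as_profile(x),
                                              min_prominence_frac = f)$n, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("patch prominence matches constructed and generated contrast", {
  # square wave: plateaus at 200 and 100 -> prominence 2 after smoothing
  x <- rep(100, 360); x[60:120] <- 200; x[240:300] <- 200
  det <- detect_patches(as_profile(x))
  expect_equal(patch_prominence(det), 2, tolerance = 1e-6)
  # constant profile: undefined
  und <- patch_prominence(detect_patches(as_profile(rep(7, 360))))
  expect_true(is.na(und))
  # generator truth at default noise
  proms <- unlist(lapply(1:2, function(s) {
    sim <- generate_field(field_params(n_cells = 25, patch_contrast = 1.8,
                                       seed = 44 + s))
    quantify_field(sim$field, sim$mask)$prominence
  }))
  expect_lt(abs(mean(proms, na.rm = TRUE) - 1.8), 0.1)
  # prominence >= 1 whenever defined
  expect_true(all(proms >= 1, na.rm = TRUE))
})

test_that("patch density follows its definition and scaling law", {
  expect_equal(patch_density(8, 16), 0.5)
  expect_equal(patch_density(0, 10), 0)
  expect_equal(patch_density(5, ellipse_perimeter(40, 20) * 0.1),
               patch_density(5, ellipse_perimeter(20, 10) * 0.1) / 2)
})

test_that("uptake ratio covers extremes and recovers the generated fraction", {
  img <- matrix(0, 20, 20)
  whole <- matrix(FALSE, 20, 20); whole[5:15, 5:15] <- TRUE
  interior <- matrix(FALSE, 20, 20); interior[8:12, 8:12] <- TRUE
  img[interior] <- 3
  expect_equal(uptake_ratio(img, whole, interior), 1)
  img2 <- matrix(0, 20, 20); img2[whole & !interior] <- 2
  expect_equal(uptake_ratio(img2, whole, interior), 0)
  expect_true(is.na(uptake_ratio(matrix(0, 20, 20), whole, interior)))
  sim <- generate_uptake_field(field_params(n_cells = 10, seed = 46),
                               uptake_fraction = 0.6)
  m <- quantify_field(sim$field, sim$mask, background = 10)
  expect_lt(abs(mean(m$uptake_ratio) - 0.6), 0.03)
})

test_that("region integrals satisfy the partition property per cell", {
  sim <- generate_field(field_params(n_cells = 6, seed = 47))
  m <- quantify_field(sim$field, sim$mask)
  expect_equal(m$pm_int + m$interior_int, m$whole_int, tolerance = 1e-12)
})

test_that("parameter recovery at default SNR (patch-adjusted ratio truth)", {
  sims <- lapply(1:4, function(s)
    generate_field(field_params(n_cells = 25, seed = 50 + s)))
  ms <- lapply(sims, function(sim) quantify_field(sim$field, sim$mask))
  errs <- unlist(mapply(function(sim, m)
    m$patch_count - sim$truth$true_patch_count[match(m$label, sim$truth$label)],
    sims, ms, SIMPLIFY = FALSE))
  expect_lte(stats::median(abs(errs)), 1)
  proms <- unlist(lapply(ms, `[[`, "prominence"))
  expect_lt(abs(mean(proms, na.rm = TRUE) / 2 - 1), 0.10)
  # patches raise the band mean; analytic expectation of the measured ratio
  sigma <- sims[[1]]$params$patch_angular_sigma_rad
  bump_integral <- sigma * (sqrt(2 * pi) * (stats::pnorm(3) - stats::pnorm(-3)) -
                              6 * exp(-4.5)) / (1 - exp(-4.5))
  mean_k <- mean(unlist(lapply(sims, function(s) s$truth$true_patch_count)))
  expected <- 3 * (1 + (2 - 1) * mean_k * bump_integral / (2 * pi))
  ratios <- unlist(lapply(ms, `[[`, "pm_interior_ratio"))
  expect_lt(abs(mean(ratios) / expected - 1), 0.10)
})
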