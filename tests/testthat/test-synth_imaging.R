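test_that("generators are seed-deterministic", {
  p <- field_params(n_cells = 4, image_shape = c(256L, 256L), seed = 7)
  a <- generate_field(p); b <- generate_field(p)
  expect_identical(get_frame(a$field), get_frame(b$field))
  expect_identical(a$mask, b$mask)
  expect_identical(a$truth, b$truth)
  la <- generate_lipid_dataset(lipid_sim_params(seed = 7))
  lb <- generate_lipid_dataset(lipid_sim_params(seed = 7))
  expect_identical(la$table$amounts, lb$table$amounts)
  expect_identical(la$protein, lb$protein)
})

test_that("field carries n_cells consistent labels, truth and mask", {
  sim <- generate_field(field_params(n_cells = 12, seed = 3))
  expect_equal(nrow(sim$truth), 12)
  labs <- sort(unique(sim$mask[sim$mask > 0]))
  expect_equal(labs, 1:12)
  # mask centroids match the ground-truth centres within 1 px
  for (i in 1:12) {
    idx <- which(sim$mask == i)
    cen <- c(mean((idx - 1) %% nrow(sim$mask)),
             mean((idx - 1) %/% nrow(sim$mask)))
    expect_lt(max(abs(cen - c(sim$truth$center_row[i], sim$truth$center_col[i]))), 1)
  }
})

test_that("true patch counts follow the Poisson mean", {
  counts <- unlist(lapply(1:20, function(s)
    generate_field(field_params(n_cells = 25, seed = 1000 + s),
                   render = FALSE)$truth$true_patch_count))
  expect_length(counts, 500)
  se <- sqrt(6 / 500)
  expect_lt(abs(mean(counts) - 6), 3 * se)
})

test_that("noiseless blur-free ring profile peak/valley ratio equals the contrast", {
  sim <- generate_field(noise_off_params(n_cells = 3, seed = 5), render = FALSE)
  theta <- seq(0, 2 * pi, length.out = 20001)[-20001]
  for (i in 1:3) {
    ang <- parse_angles(sim$truth$true_patch_angles[i])
    prof <- true_ring_profile(c(theta, ang), ang, contrast = 2,
                              sigma = sim$params$patch_angular_sigma_rad,
                              pm_intensity = 800)
    expect_equal(max(prof) / min(prof), 2, tolerance = 1e-3)
  }
})

test_that("invalid generator parameters are rejected", {
  expect_error(field_params(n_cells = 0), "n_cells")
  expect_error(field_params(pm_interior_ratio = 0), "pm_interior_ratio")
  expect_error(field_params(patch_contrast = 0.5), "patch_contrast")
  expect_error(field_params(semi_axis_range_um = c(3, 1)), "semi_axis_range_um")
  expect_error(field_params(min_patch_separation_rad = 0.1,
                            patch_angular_sigma_rad = 0.09), "separation")
  expect_error(generate_timelapse(field_params(seed = 1), half_life_min = -1),
               "half_life")
  expect_error(generate_coloc_pair(field_params(seed = 1), shared_fraction = 1.2),
               "shared_fraction")
  expect_error(generate_uptake_field(field_params(seed = 1), uptake_fraction = -0.1),
               "uptake_fraction")
})

test_that("placement fails loudly at impossible density", {
  expect_error(generate_field(field_params(n_cells = 200,
                                           image_shape = c(256L, 256L),
                                           seed = 1)),
               "placement|too small")
})

test_that("time-lapse thinning is monotone and matches 2^(-t/T) in expectation", {
  # narrow patches so the geometric capacity (floor(2*pi/min_sep) = 20) leaves
  # the Poisson(8) counts effectively untruncated
  fc <- do.call(rbind, lapply(1:80, function(s)
    generate_timelapse(field_params(n_cells = 25, patch_lambda = 8,
                                    patch_angular_sigma_rad = 0.05,
                                    min_patch_separation_rad = 0.3,
                                    seed = 21 + s),
                       n_frames = 13, frame_interval_min = 10,
                       half_life_min = 80, render = FALSE)$frame_counts))
  # monotone per cell
  expect_true(all(apply(fc, 1, function(r) all(diff(r) <= 0))))
  # binomial-thinning expectation within 5% at every frame (n = 2000 cells,
  # relative Monte-Carlo SE ~1.5% at the sparsest frame)
  t <- (0:12) * 10
  expected <- 8 * 2^(-t / 80)
  expect_true(all(abs(colMeans(fc) / expected - 1) < 0.05))
})

test_that("half_life = Inf keeps every frame identical", {
  sim <- generate_timelapse(noise_off_params(n_cells = 4,
                                             image_shape = c(256L, 256L),
                                             seed = 9),
                            n_frames = 3, frame_interval_min = 30,
                            half_life_min = Inf)
  expect_identical(get_frame(sim$field, frame = 1), get_frame(sim$field, frame = 3))
  expect_true(all(sim$frame_counts == sim$frame_counts[, 1]))
})

test_that("coloc pair: full sharing without noise differs only by channel gain", {
  sim <- generate_coloc_pair(noise_off_params(n_cells = 4,
                                              image_shape = c(256L, 256L),
                                              seed = 11),
                             shared_fraction = 1, true_shift = c(0, 0),
                             channel2_gain = 0.8)
  ch1 <- get_frame(sim$field, "ch1") - sim$params$background
  ch2 <- get_frame(sim$field, "ch2") - sim$params$background
  expect_lt(max(abs(ch2 - 0.8 * ch1)), 1e-9)
})

test_that("coloc pair: zero sharing draws independent patch-angle sets", {
  sim <- generate_coloc_pair(field_params(n_cells = 6, seed = 12),
                             shared_fraction = 0)
  same <- vapply(seq_len(6), function(i) {
    a1 <- parse_angles(sim$truth$true_patch_angles[i])
    a2 <- parse_angles(sim$truth$true_patch_angles_ch2[i])
    length(a1) && length(a2) && any(outer(a1, a2, function(x, y)
      abs(x - y) < 1e-9))
  }, TRUE)
  expect_false(any(same))
})

test_that("uptake field: extreme fractions place signal in one compartment only", {
  p <- noise_off_params(n_cells = 3, image_shape = c(256L, 256L), seed = 13)
  for (f in c(0, 1)) {
    sim <- generate_uptake_field(p, uptake_fraction = f)
    img <- get_frame(sim$field)
    rois <- filter_cells(load_label_mask(sim$mask))$kept
    for (roi in rois) {
      reg <- partition_regions(roi$ellipse, dim(img), 0.4, 0.1)
      if (f == 0) expect_equal(sum(img[reg$interior]), 0)
      else expect_lt(sum(img[reg$band]) / sum(img[reg$whole]), 0.01)
    }
  }
})

test_that("lipid dataset: noiseless unit-Pi table recovers shifts exactly", {
  sim <- generate_lipid_dataset(lipid_sim_params(noise_cv = 0,
                                                 pi_scale_range = c(1, 1),
                                                 seed = 14))
  fc <- log2_fold_change(pi_normalize(sim$table))
  expect_equal(fc[, colnames(sim$truth$log2_fc)], sim$truth$log2_fc,
               tolerance = 1e-12)
})

test_that("protein amounts track the designated class at the target rho", {
  rs <- vapply(1:200, function(s) {
    sim <- generate_lipid_dataset(lipid_sim_params(seed = 2000 + s))
    norm <- pi_normalize(sim$table)
    pooled <- class_pool(norm)
    keep <- norm$samples$strain == "wt"
    cls <- pooled$amounts[keep, sim$truth$designated_class]
    cond_means <- tapply(cls, norm$samples$condition[keep], mean)
    stats::cor(sim$protein$amount[match(names(cond_means),
                                        sim$protein$condition)], cond_means)
  }, 0)
  expect_lt(abs(mean(rs) - 0.9), 0.15)
})

test_that("unknown class in shifts is rejected", {
  expect_error(lipid_sim_params(condition_class_shifts = list(
    control = c(), phs = c(Nonexistent = 2))), "unknown class")
})

test_that("write_simulation round-trips image, mask and truth", {
  dir <- withr::local_tempdir()
  sim <- generate_field(field_params(n_cells = 3, image_shape = c(256L, 256L),
                                     seed = 15))
  paths <- suppressWarnings(write_simulation(sim, dir, stem = "f"))
  expect_true(all(file.exists(paths)))
  mask_back <- read_tiff(paths[["mask"]])[[1]]
  expect_equal(mask_back, sim$mask + 0)
  img_back <- read_tiff(paths[["image"]])[[1]]
  expect_lt(max(abs(img_back - pmin(pmax(round(get_frame(sim$field)), 0), 65535))), 1e-9)
  truth_back <- utils::read.csv(paths[["truth"]])
  expect_equal(nrow(truth_back), 3)
})
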