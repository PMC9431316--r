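toy_table <- function(amounts, pi = rep(1, nrow(amounts)),
                      conditions = rep("control", nrow(amounts)),
                      strains = rep("wt", nrow(amounts)),
                      classes = NULL) {
  lipids <- colnames(amounts)
  if (is.null(classes)) classes <- stats::setNames(rep("IPC", length(lipids)),
                                                   lipids)
  lipid_table(amounts, data.frame(strain = strains, condition = conditions,
                                  replicate = seq_len(nrow(amounts))),
              pi, classes)
}

test_that("Pi normalization divides by Pi, is scale-invariant and idempotent", {
  tab <- toy_table(matrix(c(10, 20), 1, dimnames = list(NULL, c("a", "b"))),
                   pi = 2, classes = c(a = "IPC", b = "MIPC"))
  norm <- pi_normalize(tab)
  expect_equal(unname(norm$amounts[1, ]), c(5, 10))
  # multiplying a sample's amounts and Pi by 7 leaves the result unchanged
  tab7 <- toy_table(7 * matrix(c(10, 20), 1, dimnames = list(NULL, c("a", "b"))),
                    pi = 14, classes = c(a = "IPC", b = "MIPC"))
  expect_equal(pi_normalize(tab7)$amounts, norm$amounts)
  # second pass is the identity (Pi reset to 1)
  expect_equal(pi_normalize(norm)$amounts, norm$amounts)
})

test_that("log2 fold change matches hand values and generator shifts", {
  am <- matrix(c(2, 2, 8, 8), 4, 1, dimnames = list(NULL, "a"))
  tab <- toy_table(am, conditions = c("control", "control", "treat", "treat"),
                   classes = c(a = "IPC"))
  fc <- log2_fold_change(tab)
  expect_equal(unname(fc["a", "wt:treat"]), 2)
  # control against itself is zero: treated amounts equal to control
  am0 <- matrix(c(2, 2, 2, 2), 4, 1, dimnames = list(NULL, "a"))
  fc0 <- log2_fold_change(toy_table(am0,
                                    conditions = c("control", "control",
                                                   "treat", "treat"),
                                    classes = c(a = "IPC")))
  expect_equal(unname(fc0["a", "wt:treat"]), 0)
  # noiseless generator with a single 1.5x class shift
  p <- lipid_sim_params(strains = "wt",
                        conditions = c("control", "treat"),
                        condition_class_shifts = list(control = c(),
                                                      treat = c(IPC = 1.5)),
                        strain_class_shifts = list(),
                        noise_cv = 0, pi_scale_range = c(1, 1), seed = 71)
  sim <- generate_lipid_dataset(p)
  fc15 <- log2_fold_change(pi_normalize(sim$table))
  ipc <- names(sim$table$class_map)[sim$table$class_map == "IPC"]
  expect_equal(unname(fc15[ipc, "wt:treat"]), rep(log2(1.5), length(ipc)),
               tolerance = 1e-12)
  expect_equal(unname(fc15[setdiff(rownames(fc15), ipc), "wt:treat"]),
               rep(0, nrow(fc15) - length(ipc)), tolerance = 1e-12)
  expect_error(log2_fold_change(toy_table(am, conditions = rep("treat", 4),
                                          classes = c(a = "IPC"))),
               "control")
})

test_that("class pooling sums within classes and partitions the row total", {
  am <- matrix(c(3, 4, 5), 1, 3, dimnames = list(NULL, c("i1", "i2", "m1")))
  tab <- toy_table(am, classes = c(i1 = "IPC", i2 = "IPC", m1 = "MIPC"))
  pooled <- class_pool(tab)
  expect_equal(unname(pooled$amounts[1, "IPC"]), 7)
  expect_equal(unname(pooled$amounts[1, "MIPC"]), 5)   # single-lipid class
  expect_equal(sum(pooled$amounts[1, ]), sum(am))
})

test_that("pi_normalize and class_pool commute", {
  sim <- generate_lipid_dataset(lipid_sim_params(seed = 72))
  a <- class_pool(pi_normalize(sim$table))$amounts
  b <- pi_normalize(class_pool(sim$table))$amounts
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("PCA: collinear samples, variance conservation, eigen oracle", {
  t <- c(-2, -1, 0, 1, 2)
  x <- outer(t, c(1, 2, -1)) + matrix(rep(c(5, 1, 3), each = 5), 5)
  colnames(x) <- c("a", "b", "c")
  pc <- lipid_pca(x, scaling = "center")
  expect_equal(pc$explained_variance_fraction[1], 1, tolerance = 1e-12)
  set.seed(73)
  y <- matrix(sample(1:40, 12), 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  pc2 <- lipid_pca(y, scaling = "auto")
  expect_equal(sum(pc2$explained_variance_fraction), 1, tolerance = 1e-12)
  expect_equal(unname(colSums(pc2$contributions)),
               rep(100, ncol(pc2$contributions)), tolerance = 1e-9)
  # independent eigendecomposition oracle on the correlation matrix
  ys <- scale(y)
  ev <- eigen(stats::cov(ys))
  for (k in 1:2) {
    v <- ev$vectors[, k]
    if (v[which.max(abs(v))] < 0) v <- -v        # same sign convention
    expect_equal(unname(pc2$loadings[, k]), v, tolerance = 1e-8)
    expect_equal(unname(pc2$scores[, k]), unname(ys %*% v)[, 1],
                 tolerance = 1e-8)
    expect_equal(pc2$explained_variance_fraction[k],
                 ev$values[k] / sum(ev$values), tolerance = 1e-8)
  }
  y_const <- cbind(y, d = 1)
  expect_error(lipid_pca(y_const, scaling = "auto"), "d")
})

test_that("protein-lipid correlation: closed forms, gating and key mismatch", {
  am <- matrix(c(2, 4, 6, 8, 10, 12,
                 5, 5, 5, 5, 5, 5), 6, 2,
               dimnames = list(NULL, c("prop", "const")))
  tab <- toy_table(am, conditions = paste0("c", 1:6),
                   classes = c(prop = "IPC", const = "MIPC"))
  protein <- data.frame(condition = paste0("c", 1:6), amount = c(1:6))
  res <- protein_lipid_correlation(protein, tab)
  row <- res$per_lipid[res$per_lipid$lipid == "prop", ]
  expect_equal(row$r, 1)
  expect_lt(row$p, 1e-6)
  expect_true(row$significant)
  crow <- res$per_lipid[res$per_lipid$lipid == "const", ]
  expect_true(is.na(crow$r))
  expect_equal(crow$note, "constant")
  expect_equal(res$mu_r, 1)
  # hand-computable: protein (1,2,3,4), lipid (2,1,4,3) -> r = 0.6,
  # two-tailed p = 0.4 exactly for df = 2
  am2 <- matrix(c(2, 1, 4, 3), 4, 1, dimnames = list(NULL, "l"))
  tab2 <- toy_table(am2, conditions = paste0("c", 1:4), classes = c(l = "IPC"))
  res2 <- protein_lipid_correlation(data.frame(condition = paste0("c", 1:4),
                                               amount = 1:4), tab2)
  expect_equal(res2$per_lipid$r, 0.6, tolerance = 1e-12)
  expect_equal(res2$per_lipid$p, 0.4, tolerance = 1e-9)
  expect_false(res2$per_lipid$significant)
  expect_true(is.na(res2$mu_r))
  expect_error(protein_lipid_correlation(
    data.frame(condition = c("x", "y", "z"), amount = 1:3), tab),
    "unmatched")
})
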