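# Sphingolipidomics table post-processing ------------------------------------
#
# Operates on sample x lipid amount tables: inorganic-phosphate (Pi)
# normalization, class pooling, log2 fold changes against the matched
# control, PCA with per-lipid contributions, and protein-lipid Pearson
# correlation with the mu_r summary.

#' Construct a lipid amount table
#'
#' @param amounts numeric matrix or data frame, samples x lipids,
#'   non-negative.
#' @param samples data frame with columns `strain`, `condition`, `replicate`
#'   (one row per row of `amounts`).
#' @param pi positive numeric vector of per-sample inorganic-phosphate
#'   abundances.
#' @param class_map named character vector mapping every lipid to its class.
#' @return an object of class `lipid_table`.
#' @export
lipid_table <- function(amounts, samples, pi, class_map) {
  amounts <- as.matrix(amounts)
  check_that(is.numeric(amounts) && all(amounts >= 0),
             "amounts must be non-negative numeric")
  check_that(nrow(samples) == nrow(amounts),
             "samples must have one row per sample")
  check_that(all(c("strain", "condition", "replicate") %in% names(samples)),
             "samples needs strain, condition, replicate columns")
  check_that(length(pi) == nrow(amounts) && all(pi > 0),
             "pi must be positive, one value per sample")
  lipids <- colnames(amounts)
  check_that(!is.null(lipids) && all(lipids %in% names(class_map)),
             "every lipid column must appear in class_map")
  structure(list(amounts = amounts, samples = as.data.frame(samples),
                 pi = as.numeric(pi),
                 class_map = class_map[lipids],
                 pi_normalized = FALSE),
            class = "lipid_table")
}

#' @export
print.lipid_table <- function(x, ...) {
  cat(sprintf("<lipid_table> %d samples x %d lipids (%d classes)%s\n",
              nrow(x$amounts), ncol(x$amounts),
              length(unique(x$class_map)),
              if (x$pi_normalized) ", Pi-normalized" else ""))
  invisible(x)
}

#' Normalize lipid amounts by per-sample inorganic phosphate
#'
#' Divides every amount by its sample's Pi value and resets Pi to 1, so a
#' second pass is the identity.
#'
#' @param table a `lipid_table`.
#' @return the normalized `lipid_table`.
#' @export
pi_normalize <- function(table) {
  check_that(inherits(table, "lipid_table"), "table must be a lipid_table")
  bad <- which(!is.finite(table$pi) | table$pi <= 0)
  if (length(bad))
    stop_bad("missing/invalid Pi for sample(s): ",
             paste(bad, collapse = ", "))
  table$amounts <- table$amounts / table$pi
  table$pi <- rep(1, length(table$pi))
  table$pi_normalized <- TRUE
  table
}

#' Pool lipid amounts into classes
#' @param table a `lipid_table`.
#' @return a `lipid_table` whose columns are the per-sample class sums (the
#'   class map becomes the identity on class names).
#' @export
class_pool <- function(table) {
  check_that(inherits(table, "lipid_table"), "table must be a lipid_table")
  classes <- unique(table$class_map)
  pooled <- vapply(classes, function(cl)
    rowSums(table$amounts[, table$class_map == cl, drop = FALSE]),
    numeric(nrow(table$amounts)))
  if (is.null(dim(pooled)))
    pooled <- matrix(pooled, nrow = nrow(table$amounts))
  colnames(pooled) <- classes
  table$amounts <- pooled
  table$class_map <- stats::setNames(classes, classes)
  table
}

#' Log2 fold changes against matched controls
#'
#' For every strain, each non-control condition is compared with the same
#' strain's control (mean over replicates); additionally each non-reference
#' strain's control is compared with the reference strain's control. Zeros
#' are replaced by `pseudo_amount` before forming the ratio.
#'
#' @param table a `lipid_table` (normalize first if desired).
#' @param control_condition name of the control condition.
#' @param reference_strain strain whose control anchors the cross-strain
#'   contrast (default: first strain encountered).
#' @param pseudo_amount replacement for zero means; default half the
#'   smallest nonzero amount in the table.
#' @return lipids x contrasts matrix of log2 fold changes; contrast columns
#'   are named `strain:condition` (and `strain:control_vs_<ref>` for the
#'   cross-strain contrast).
#' @export
log2_fold_change <- function(table, control_condition = "control",
                             reference_strain = NULL, pseudo_amount = NULL) {
  check_that(inherits(table, "lipid_table"), "table must be a lipid_table")
  s <- table$samples
  strains <- unique(s$strain)
  if (is.null(reference_strain)) reference_strain <- strains[1]
  check_that(reference_strain %in% strains, "unknown reference strain")
  if (is.null(pseudo_amount)) {
    nz <- table$amounts[table$amounts > 0]
    check_that(length(nz) > 0, "table is all zeros")
    pseudo_amount <- min(nz) / 2
  }
  cond_mean <- function(strain, condition) {
    sel <- s$strain == strain & s$condition == condition
    check_that(any(sel), sprintf("no replicates for %s / %s", strain, condition))
    m <- colMeans(table$amounts[sel, , drop = FALSE])
    ifelse(m > 0, m, pseudo_amount)
  }
  cols <- list()
  for (st in strains) {
    ctrl <- cond_mean(st, control_condition)
    for (cond in setdiff(unique(s$condition[s$strain == st]),
                         control_condition))
      cols[[paste0(st, ":", cond)]] <- log2(cond_mean(st, cond) / ctrl)
    if (st != reference_strain)
      cols[[paste0(st, ":control_vs_", reference_strain)]] <-
        log2(ctrl / cond_mean(reference_strain, control_condition))
  }
  do.call(cbind, cols)
}

#' PCA of a lipid table with per-lipid contributions
#'
#' Column-centred (and unit-variance scaled under the default
#' `scaling = "auto"`) singular-value decomposition. Loadings are unit-norm;
#' the contribution of lipid l to component k is `100 * loading^2`. The sign
#' of each component is fixed so its largest-magnitude loading is positive.
#'
#' @param table a `lipid_table`, or a plain samples x variables matrix.
#' @param scaling `"auto"` (centre + unit variance) or `"center"`.
#' @param n_components number of components to keep (default all).
#' @return list of class `lipid_pca`: `scores`, `loadings`,
#'   `explained_variance_fraction`, `contributions` (percent, columns sum to
#'   100).
#' @export
lipid_pca <- function(table, scaling = c("auto", "center"),
                      n_components = NULL) {
  scaling <- match.arg(scaling)
  x <- if (inherits(table, "lipid_table")) table$amounts else as.matrix(table)
  check_that(nrow(x) >= 3, "need at least 3 samples")
  check_that(ncol(x) >= 2, "need at least 2 variables")
  check_that(!anyNA(x), "missing values are not supported")
  if (scaling == "auto") {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0))
      stop_bad("constant column(s) under auto scaling: ",
               paste(colnames(x)[sds == 0], collapse = ", "))
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = (scaling == "auto"))
  k <- if (is.null(n_components)) ncol(pc$rotation)
  else min(n_components, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  sco <- pc$x[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = sco, loadings = rot,
                 explained_variance_fraction = ev[seq_len(k)],
                 contributions = 100 * rot^2,
                 scaling = scaling),
            class = "lipid_pca")
}

#' @export
print.lipid_pca <- function(x, ...) {
  cat(sprintf("<lipid_pca> %d components (%s scaling); PC1 %.1f%%, PC2 %.1f%%\n",
              ncol(x$scores), x$scaling,
              100 * x$explained_variance_fraction[1],
              if (length(x$explained_variance_fraction) > 1)
                100 * x$explained_variance_fraction[2] else NA))
  invisible(x)
}

#' Protein-lipid Pearson correlation with the mu_r summary
#'
#' Per lipid, the Pearson correlation between a protein amount and the
#' condition-mean lipid amount over matched conditions, the two-tailed p
#' from `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` df, the
#' significance flag at `p <= alpha`, and `mu_r`, the mean r over the
#' significant lipids (no multiple-testing correction, matching the
#' per-lipid gate).
#'
#' @param protein data frame with columns `condition` and `amount`, one row
#'   per condition.
#' @param table a `lipid_table` (use the Pi-normalized table by default
#'   upstream); amounts are averaged over replicates per condition.
#' @param alpha significance level (default 0.05).
#' @param strain restrict the lipid table to one strain (default: all rows).
#' @return list of class `lipid_correlation`: `per_lipid` data frame (lipid,
#'   class, r, p, significant, n) and `mu_r` (`NA` if nothing is
#'   significant). Constant lipids are excluded with reason in the table.
#' @export
protein_lipid_correlation <- function(protein, table, alpha = 0.05,
                                      strain = NULL) {
  check_that(inherits(table, "lipid_table"), "table must be a lipid_table")
  check_that(all(c("condition", "amount") %in% names(protein)),
             "protein needs condition and amount columns")
  s <- table$samples
  amounts <- table$amounts
  if (!is.null(strain)) {
    keep <- s$strain == strain
    s <- s[keep, , drop = FALSE]
    amounts <- amounts[keep, , drop = FALSE]
  }
  conds <- intersect(protein$condition, unique(s$condition))
  miss <- union(setdiff(protein$condition, s$condition),
                setdiff(unique(s$condition), protein$condition))
  check_that(length(conds) >= 3,
             "need >= 3 matched conditions; unmatched: ",
             paste(miss, collapse = ", "))
  prot <- protein$amount[match(conds, protein$condition)]
  lipid_means <- vapply(conds, function(cc)
    colMeans(amounts[s$condition == cc, , drop = FALSE]),
    numeric(ncol(amounts)))
  if (ncol(amounts) == 1) lipid_means <- matrix(lipid_means, nrow = 1)
  n <- length(conds)
  per <- do.call(rbind, lapply(seq_len(ncol(amounts)), function(j) {
    y <- lipid_means[j, ]
    if (stats::sd(y) == 0 || stats::sd(prot) == 0)
      return(data.frame(lipid = colnames(amounts)[j],
                        class = unname(table$class_map[j]),
                        r = NA_real_, p = NA_real_, significant = FALSE,
                        n = n, note = "constant", stringsAsFactors = FALSE))
    r <- stats::cor(prot, y)
    p <- if (abs(r) >= 1) 0
    else 2 * stats::pt(-abs(r * sqrt((n - 2) / (1 - r^2))), df = n - 2)
    data.frame(lipid = colnames(amounts)[j], class = unname(table$class_map[j]),
               r = r, p = p, significant = p <= alpha, n = n, note = "",
               stringsAsFactors = FALSE)
  }))
  sig <- per$significant & !is.na(per$r)
  structure(list(per_lipid = per,
                 mu_r = if (any(sig)) mean(per$r[sig]) else NA_real_,
                 alpha = alpha),
            class = "lipid_correlation")
}

#' @export
print.lipid_correlation <- function(x, ...) {
  cat(sprintf("<lipid_correlation> %d lipids, %d significant at p <= %g; mu_r = %.3f\n",
              nrow(x$per_lipid), sum(x$per_lipid$significant), x$alpha, x$mu_r))
  invisible(x)
}
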