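# Hierarchical replicate aggregation and significance tests ------------------
#
# The statistical unit is the biological replicate, never the cell: per-cell
# metrics are first averaged within each replicate, and condition-level
# means, SDs and all tests operate on those replicate means.

#' Two-stage replicate aggregation of per-cell metrics
#'
#' Stage 1: mean of each metric over the cells of every (condition,
#' replicate), excluding undefined per-cell values (NA; exclusions are
#' counted). Stage 2: unweighted mean and sample SD over the replicate means
#' of each condition.
#'
#' @param metrics data frame of per-cell metrics with `condition` and
#'   `replicate` columns.
#' @param metric_cols character vector of metric columns to aggregate
#'   (default: all numeric columns except the keys and `label`).
#' @return list: `replicates` (condition, replicate, metric, mean, n_cells,
#'   n_excluded) and `conditions` (condition, metric, mean, sd,
#'   n_replicates; SD is NA-flagged for single-replicate conditions).
#' @export
replicate_aggregate <- function(metrics, metric_cols = NULL) {
  check_that(all(c("condition", "replicate") %in% names(metrics)),
             "metrics needs condition and replicate columns")
  if (is.null(metric_cols))
    metric_cols <- setdiff(names(metrics)[vapply(metrics, is.numeric, TRUE)],
                           c("label", "replicate"))
  check_that(length(metric_cols) >= 1, "no metric columns to aggregate")
  key <- interaction(metrics$condition, metrics$replicate, drop = TRUE)
  reps <- do.call(rbind, lapply(levels(key), function(k) {
    sub <- metrics[key == k, , drop = FALSE]
    do.call(rbind, lapply(metric_cols, function(mc) {
      v <- sub[[mc]]
      data.frame(condition = sub$condition[1], replicate = sub$replicate[1],
                 metric = mc, mean = mean(v, na.rm = TRUE),
                 n_cells = sum(!is.na(v)), n_excluded = sum(is.na(v)),
                 stringsAsFactors = FALSE)
    }))
  }))
  conds <- do.call(rbind, lapply(split(reps, reps[c("condition", "metric")],
                                       drop = TRUE), function(sub) {
    data.frame(condition = sub$condition[1], metric = sub$metric[1],
               mean = mean(sub$mean),
               sd = if (nrow(sub) >= 2) stats::sd(sub$mean) else NA_real_,
               n_replicates = nrow(sub), stringsAsFactors = FALSE)
  }))
  rownames(conds) <- NULL
  list(replicates = reps, conditions = conds)
}

#' Classical one-way fixed-effects ANOVA on replicate means
#'
#' @param groups list of numeric vectors (>= 2 groups, each >= 2 values);
#'   in this pipeline each value is one biological replicate's mean.
#' @return list: `F`, `p`, `df` (between, within). When all values are
#'   identical, `F = 0`, `p = 1` with attribute `flag = "all values
#'   identical"` by convention.
#' @export
one_way_anova <- function(groups) {
  check_that(is.list(groups) && length(groups) >= 2, "need >= 2 groups")
  check_that(all(vapply(groups, length, 1L) >= 2),
             "every group needs >= 2 values")
  k <- length(groups)
  n <- vapply(groups, length, 1L)
  N <- sum(n)
  gm <- mean(unlist(groups))
  mi <- vapply(groups, mean, 0)
  ssb <- sum(n * (mi - gm)^2)
  ssw <- sum(vapply(seq_len(k), function(i) sum((groups[[i]] - mi[i])^2), 0))
  dfb <- k - 1; dfw <- N - k
  if (ssw == 0 && ssb == 0)
    return(structure(list(F = 0, p = 1, df = c(dfb, dfw)),
                     flag = "all values identical"))
  Fv <- (ssb / dfb) / (ssw / dfw)
  list(F = Fv, p = stats::pf(Fv, dfb, dfw, lower.tail = FALSE),
       df = c(dfb, dfw))
}

#' Two-way fixed-effects ANOVA
#'
#' Standard fixed-effects two-way ANOVA with interaction for condition x
#' strain designs, on replicate means.
#'
#' @param values numeric vector.
#' @param factor_a,factor_b factors (coerced) of the same length.
#' @return data frame: term, df, F, p.
#' @export
two_way_anova <- function(values, factor_a, factor_b) {
  check_that(length(values) == length(factor_a) &&
               length(values) == length(factor_b), "lengths must match")
  dat <- data.frame(y = values, A = factor(factor_a), B = factor(factor_b))
  fit <- stats::aov(y ~ A * B, data = dat)
  sm <- summary(fit)[[1]]
  terms <- trimws(rownames(sm))
  data.frame(term = terms, df = sm$Df, F = sm$`F value`, p = sm$`Pr(>F)`,
             stringsAsFactors = FALSE)[terms != "Residuals", ]
}

#' Paired two-tailed t test
#'
#' @param a,b numeric vectors of equal length >= 2, paired by replicate.
#' @return list: `t`, `p`, `df`, `mean_difference`. Zero-variance
#'   differences: all-zero gives `t = 0`, `p = 1` with a flag; a nonzero
#'   constant difference is undefined (`NA` with a flag).
#' @export
paired_t_test <- function(a, b) {
  check_that(length(a) == length(b) && length(a) >= 2,
             "a and b must be paired with length >= 2")
  d <- a - b
  n <- length(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (mean(d) == 0)
      return(structure(list(t = 0, p = 1, df = n - 1, mean_difference = 0),
                       flag = "zero-variance differences"))
    return(structure(list(t = NA_real_, p = NA_real_, df = n - 1,
                          mean_difference = mean(d)),
                     flag = "constant nonzero differences: t undefined"))
  }
  t <- mean(d) / (sdd / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1), df = n - 1,
       mean_difference = mean(d))
}
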