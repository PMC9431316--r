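# Synthetic sphingolipidomics dataset ----------------------------------------
#
# Emulates the structure of an LC-MS sphingolipid amount table: samples keyed
# by (strain, condition, replicate), lipid species grouped into the yeast
# sphingolipid classes, multiplicative condition x class effects, log-normal
# measurement noise, a per-sample inorganic-phosphate factor that must be
# divided out (Pi normalization), and a protein-amount table constructed to
# correlate with a designated lipid class at a target Pearson rho.

default_lipid_classes <- function() {
  list(
    "LCB"          = c("DHS 18:0", "PHS 18:0;3", "PHS 20:0;3", "DHS 20:0"),
    "LCB-P"        = c("DHS-1-P 18:0", "PHS-1-P 18:0;3"),
    "Cer"          = c("Cer 18:0;2/26:0", "Cer 20:0;2/26:0", "Cer 18:0;2/24:0"),
    "PhytoCer"     = c("PhytoCer 18:0;3/26:0", "PhytoCer 20:0;3/26:0",
                       "PhytoCer 18:0;3/24:0"),
    "OH-PhytoCer"  = c("OH-PhytoCer 18:0;3/26:0;1", "OH-PhytoCer 20:0;3/26:0;1",
                       "OH-PhytoCer 18:0;3/24:0;1"),
    "IPC"          = c("IPC 18:0;3/26:0", "IPC 20:0;3/26:0", "IPC 18:0;3/24:0",
                       "IPC 18:0;2/26:0"),
    "OH-IPC"       = c("OH-IPC 18:0;3/26:0;1", "OH-IPC 20:0;3/26:0;1",
                       "OH-IPC 18:0;3/24:0;1"),
    "MIPC"         = c("MIPC 18:0;3/26:0", "MIPC 20:0;3/26:0",
                       "MIPC 18:0;3/24:0", "MIPC 18:0;2/26:0"),
    "OH-MIPC"      = c("OH-MIPC 18:0;3/26:0;1", "OH-MIPC 20:0;3/26:0;1",
                       "OH-MIPC 18:0;3/24:0;1"))
}

default_condition_shifts <- function() {
  list(
    control     = c(),
    fluconazole = c(IPC = 1.6, MIPC = 1.4),
    ethanol     = c(IPC = 0.7, LCB = 1.3),
    heat37      = c(IPC = 2.2, Cer = 1.5, PhytoCer = 1.4),
    phs         = c(IPC = 2.8, LCB = 2.5, PhytoCer = 1.8),
    dhs         = c(IPC = 1.9, LCB = 2.0, Cer = 1.3),
    hypoxia     = c(IPC = 0.5, MIPC = 0.7),
    osmotic     = c(IPC = 1.2, `OH-IPC` = 1.3))
}

#' Parameters of the synthetic lipidomics dataset
#'
#' Defaults emulate a chronic-stress survey of wild-type and deletion-mutant
#' cultures: 2 strains x 8 conditions x 4 replicates, 9 sphingolipid classes
#' (29 species), multiplicative condition effects concentrated on the
#' complex sphingolipids, 15% measurement CV, a 0.6-1.6x per-sample Pi
#' factor, and a protein amount correlated with the IPC class at rho = 0.9.
#'
#' @param strains character vector of strain names (first = reference).
#' @param conditions character vector of condition names; must include
#'   `"control"`.
#' @param n_replicates biological replicates per strain x condition.
#' @param lipid_classes named list: class -> character vector of species.
#' @param base_amount_log_mean,base_amount_log_sd log-normal parameters of
#'   per-species base amounts.
#' @param condition_class_shifts named list: condition -> named numeric of
#'   multiplicative class shifts (classes not named shift by 1).
#' @param strain_class_shifts named list: strain -> named numeric of class
#'   shifts (applied on top of condition shifts).
#' @param designated_class class whose condition profile the protein amount
#'   tracks.
#' @param protein_lipid_rho target Pearson correlation between protein
#'   amount and the designated class, in `[-1, 1]`.
#' @param pi_scale_range range of the per-sample multiplicative Pi factor.
#' @param noise_cv coefficient of variation of the log-normal measurement
#'   noise (>= 0).
#' @param seed RNG seed.
#' @return a validated list of class `mcc_lipid_params`.
#' @export
lipid_sim_params <- function(strains = c("wt", "nce102d"),
                             conditions = names(default_condition_shifts()),
                             n_replicates = 4L,
                             lipid_classes = default_lipid_classes(),
                             base_amount_log_mean = log(100),
                             base_amount_log_sd = 1,
                             condition_class_shifts = default_condition_shifts(),
                             strain_class_shifts = list(nce102d = c(IPC = 0.8)),
                             designated_class = "IPC",
                             protein_lipid_rho = 0.9,
                             pi_scale_range = c(0.6, 1.6),
                             noise_cv = 0.15,
                             seed = NULL) {
  p <- list(strains = strains, conditions = conditions,
            n_replicates = as.integer(n_replicates),
            lipid_classes = lipid_classes,
            base_amount_log_mean = base_amount_log_mean,
            base_amount_log_sd = base_amount_log_sd,
            condition_class_shifts = condition_class_shifts,
            strain_class_shifts = strain_class_shifts,
            designated_class = designated_class,
            protein_lipid_rho = protein_lipid_rho,
            pi_scale_range = pi_scale_range, noise_cv = noise_cv, seed = seed)
  check_that("control" %in% p$conditions, "conditions must include 'control'")
  check_that(is_count(p$n_replicates), "n_replicates must be >= 1")
  check_that(length(p$lipid_classes) >= 1 &&
               all(lengths(p$lipid_classes) >= 1),
             "lipid_classes must be a non-empty named list of species")
  classes <- names(p$lipid_classes)
  for (cond in names(p$condition_class_shifts)) {
    sh <- p$condition_class_shifts[[cond]]
    check_that(all(names(sh) %in% classes),
               "unknown class in shifts for condition ", cond, ": ",
               paste(setdiff(names(sh), classes), collapse = ", "))
    check_that(all(sh > 0), "shifts must be > 0 (condition ", cond, ")")
  }
  for (st in names(p$strain_class_shifts)) {
    sh <- p$strain_class_shifts[[st]]
    check_that(all(names(sh) %in% classes),
               "unknown class in shifts for strain ", st)
    check_that(all(sh > 0), "strain shifts must be > 0")
  }
  check_that(p$designated_class %in% classes, "unknown designated_class")
  check_that(is_number(p$protein_lipid_rho) && abs(p$protein_lipid_rho) <= 1,
             "protein_lipid_rho must be in [-1, 1]")
  check_that(length(p$pi_scale_range) == 2 && all(p$pi_scale_range > 0) &&
               p$pi_scale_range[1] <= p$pi_scale_range[2],
             "pi_scale_range must be positive (min, max)")
  check_that(is_number(p$noise_cv) && p$noise_cv >= 0, "noise_cv must be >= 0")
  class(p) <- "mcc_lipid_params"
  p
}

# Multiplicative shift of one class under one strain x condition.
lookup_shift <- function(params, strain, condition, class) {
  sh <- 1
  cs <- params$condition_class_shifts[[condition]]
  if (!is.null(cs) && class %in% names(cs)) sh <- sh * cs[[class]]
  ss <- params$strain_class_shifts[[strain]]
  if (!is.null(ss) && class %in% names(ss)) sh <- sh * ss[[class]]
  sh
}

#' Generate a synthetic lipidomics dataset
#'
#' Amounts are `base x condition-class shift x strain-class shift x
#' log-normal noise`, then multiplied by the per-sample Pi factor, so Pi
#' normalization is required to recover the shifts. The protein table tracks
#' the designated class's condition profile at the target rho (reference
#' strain only, one amount per condition, as densitometry data come).
#'
#' @param params a [lipid_sim_params()] object.
#' @return list of class `mcc_lipid_sim`: `table` (a raw, un-normalized
#'   `lipid_table`), `protein` (data frame condition/amount), `truth` (list:
#'   per-contrast true log2 fold changes, designated class, rho, Pi factors).
#' @export
generate_lipid_dataset <- function(params = lipid_sim_params()) {
  check_that(inherits(params, "mcc_lipid_params"),
             "params must come from lipid_sim_params()")
  if (!is.null(params$seed)) set.seed(params$seed)
  species <- unlist(params$lipid_classes, use.names = FALSE)
  class_map <- stats::setNames(
    rep(names(params$lipid_classes), lengths(params$lipid_classes)), species)
  base <- stats::setNames(
    stats::rlnorm(length(species), params$base_amount_log_mean,
                  params$base_amount_log_sd), species)
  samples <- expand.grid(replicate = seq_len(params$n_replicates),
                         condition = params$conditions,
                         strain = params$strains,
                         stringsAsFactors = FALSE)[, c("strain", "condition",
                                                       "replicate")]
  n_s <- nrow(samples)
  cv <- params$noise_cv
  sdlog <- sqrt(log(1 + cv^2))
  amounts <- matrix(0, n_s, length(species),
                    dimnames = list(NULL, species))
  for (i in seq_len(n_s)) {
    shifts <- vapply(class_map, function(cl)
      lookup_shift(params, samples$strain[i], samples$condition[i], cl), 0)
    noise <- if (cv > 0)
      stats::rlnorm(length(species), -sdlog^2 / 2, sdlog) else 1
    amounts[i, ] <- base * shifts * noise
  }
  pi_fac <- stats::runif(n_s, params$pi_scale_range[1], params$pi_scale_range[2])
  tbl <- lipid_table(amounts * pi_fac, samples, pi_fac, class_map)
  # protein amount: rho * standardized designated-class profile + noise
  ref <- params$strains[1]
  prof <- vapply(params$conditions, function(cond)
    sum(base[class_map == params$designated_class] *
          vapply(class_map[class_map == params$designated_class],
                 function(cl) lookup_shift(params, ref, cond, cl), 0)), 0)
  z <- if (stats::sd(prof) > 0) (prof - mean(prof)) / stats::sd(prof)
  else rep(0, length(prof))
  rho <- params$protein_lipid_rho
  w <- rho * z + sqrt(max(0, 1 - rho^2)) * stats::rnorm(length(z))
  protein <- data.frame(condition = params$conditions,
                        amount = 100 + 25 * w,
                        stringsAsFactors = FALSE)
  # true log2 fold changes per contrast, matching log2_fold_change() columns
  true_fc <- list()
  for (st in params$strains) {
    for (cond in setdiff(params$conditions, "control")) {
      fc <- vapply(class_map, function(cl)
        log2(lookup_shift(params, st, cond, cl) /
               lookup_shift(params, st, "control", cl)), 0)
      true_fc[[paste0(st, ":", cond)]] <- fc
    }
    if (st != params$strains[1])
      true_fc[[paste0(st, ":control_vs_", params$strains[1])]] <-
        vapply(class_map, function(cl)
          log2(lookup_shift(params, st, "control", cl) /
                 lookup_shift(params, params$strains[1], "control", cl)), 0)
  }
  structure(list(table = tbl, protein = protein,
                 truth = list(log2_fc = do.call(cbind, true_fc),
                              designated_class = params$designated_class,
                              rho = rho, pi_factors = pi_fac, base = base)),
            class = "mcc_lipid_sim")
}
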