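#' Simulation configuration for a synthetic rhizobox experiment
#'
#' Bundles every tunable of the synthetic experiment generator into a single
#' validated object. The defaults emulate a 20-day randomized complete block
#' rhizobox trial on juvenile spring wheat: 9 genotypes x 8 blocks (72 boxes),
#' non-destructive measurements on days 4, 7, 11, 14, 18 and 20 (leaves from
#' day 7 on), destructive harvests at days 1 and 20, and nutrient assays on two
#' pooled batches per genotype.
#'
#' @param n_genotypes Number of genotypes (>= 1).
#' @param n_blocks Number of replicate blocks; each genotype appears once per
#'   block.
#' @param measurement_days Strictly increasing days after sowing on which
#'   visible root traits are recorded.
#' @param leaf_days Days on which leaf length/width are recorded (leaves are
#'   too small for reliable measurement before day 7).
#' @param harvest_days Length-2 vector (initial, final) of destructive harvest
#'   days; the final day must not precede the last measurement day.
#' @param rgr_range Bounds (d^-1) for the genotype-true relative growth rates;
#'   true values are evenly spaced across this range.
#' @param lar_range Bounds (cm^2 mg^-1) for the genotype-true leaf area ratio.
#' @param root_leaf_slope_range Bounds for the genotype-true log-log slope of
#'   visible root length on leaf area.
#' @param pnc_range Bounds (mg N mg^-1) for the genotype-true whole-plant N
#'   concentration, held constant over time.
#' @param initial_biomass_mg Median whole-seedling dry mass at the initial
#'   harvest (mg).
#' @param element_ratio_profile Named vector of target element-to-N pool ratios
#'   (fractions of the N pool) around which genotype-true ratios are drawn.
#' @param ratio_genotype_cv Coefficient of variation of the lognormal
#'   genotype-level spread around `element_ratio_profile`.
#' @param ratio_noise_cv CV of the multiplicative lognormal noise on per-plant
#'   element concentrations.
#' @param measurement_noise_cv CV of the multiplicative lognormal measurement
#'   noise on biomass, areas and lengths.
#' @param longitudinal_autocorrelation AR(1) coefficient in [0, 1) of the
#'   within-plant longitudinal residual process.
#' @param block_effect_sd SD of the multiplicative block effect on the log
#'   scale.
#' @param lar_drift Linear drift of LAR in time (cm^2 mg^-1 d^-1); 0 keeps LAR
#'   constant so the light-based decomposition is exactly recoverable.
#' @param niche_exponent Optional planted scaling exponent: when set, the
#'   genotype-true concentrations of the "other" elements (K, Ca, S, Mg, Cu,
#'   Fe, Mn, Zn) are constructed so that the log niche volume of N and P
#'   regresses on the log volume of the other elements with exactly this RMA
#'   slope (used for recovery tests). `NULL` leaves element ratios independent.
#' @param genotype_ratio_multipliers Optional named list `element -> numeric
#'   vector of length n_genotypes` of multipliers on the genotype-true element
#'   ratios (e.g. to plant a weak-P genotype).
#' @param n_batches Number of pooled nutrient batches per genotype; must not
#'   exceed `n_blocks`.
#' @param seed Integer root seed; all random draws derive from it.
#'
#' @return An object of class `"simulation_config"` (a validated list).
#' @seealso [generate_experiment()], [read_config()], [write_config()]
#' @export
#' @examples
#' cfg <- simulation_config(seed = 42)
#' cfg$n_genotypes * cfg$n_blocks # 72 rhizoboxes
simulation_config <- function(n_genotypes = 9,
                              n_blocks = 8,
                              measurement_days = c(4, 7, 11, 14, 18, 20),
                              leaf_days = c(7, 11, 14, 18),
                              harvest_days = c(1, 20),
                              rgr_range = c(0.09, 0.11),
                              lar_range = c(0.17, 0.23),
                              root_leaf_slope_range = c(1.0, 1.4),
                              pnc_range = c(0.035, 0.045),
                              initial_biomass_mg = 45,
                              element_ratio_profile = c(
                                P = 0.143, K = 0.683, S = 0.080, Ca = 0.083,
                                Mg = 0.087, Fe = 0.008, Mn = 0.005,
                                Zn = 0.003, Cu = 0.0008
                              ),
                              ratio_genotype_cv = 0.10,
                              ratio_noise_cv = 0.08,
                              measurement_noise_cv = 0.08,
                              longitudinal_autocorrelation = 0.6,
                              block_effect_sd = 0.05,
                              lar_drift = 0,
                              niche_exponent = NULL,
                              genotype_ratio_multipliers = NULL,
                              n_batches = 2,
                              seed = 1L) {
  cfg <- list(
    n_genotypes = as.integer(n_genotypes),
    n_blocks = as.integer(n_blocks),
    measurement_days = as.numeric(measurement_days),
    leaf_days = as.numeric(leaf_days),
    harvest_days = as.numeric(harvest_days),
    rgr_range = as.numeric(rgr_range),
    lar_range = as.numeric(lar_range),
    root_leaf_slope_range = as.numeric(root_leaf_slope_range),
    pnc_range = as.numeric(pnc_range),
    initial_biomass_mg = as.numeric(initial_biomass_mg),
    element_ratio_profile = element_ratio_profile,
    ratio_genotype_cv = as.numeric(ratio_genotype_cv),
    ratio_noise_cv = as.numeric(ratio_noise_cv),
    measurement_noise_cv = as.numeric(measurement_noise_cv),
    longitudinal_autocorrelation = as.numeric(longitudinal_autocorrelation),
    block_effect_sd = as.numeric(block_effect_sd),
    lar_drift = as.numeric(lar_drift),
    niche_exponent = if (is.null(niche_exponent)) NULL else as.numeric(niche_exponent),
    genotype_ratio_multipliers = genotype_ratio_multipliers,
    n_batches = as.integer(n_batches),
    seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  validate_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks every invariant of [simulation_config()]; errors name the offending
#' field.
#'
#' @param cfg A `"simulation_config"` object or plain list with the same
#'   fields.
#' @return `cfg`, invisibly, if valid.
#' @export
validate_config <- function(cfg) {
  fail <- function(field, msg) {
    stop(sprintf("invalid simulation config: field '%s' %s", field, msg),
         call. = FALSE)
  }
  if (is.na(cfg$n_genotypes) || cfg$n_genotypes < 1L) {
    fail("n_genotypes", "must be a count >= 1")
  }
  if (is.na(cfg$n_blocks) || cfg$n_blocks < 1L) {
    fail("n_blocks", "must be a count >= 1")
  }
  if (is.na(cfg$n_batches) || cfg$n_batches < 1L) {
    fail("n_batches", "must be a count >= 1")
  }
  if (cfg$n_blocks < cfg$n_batches) {
    fail("n_batches", "cannot exceed n_blocks (cannot pool)")
  }
  if (length(cfg$measurement_days) < 1 ||
      any(diff(cfg$measurement_days) <= 0)) {
    fail("measurement_days", "must be strictly increasing")
  }
  if (length(cfg$harvest_days) != 2 ||
      cfg$harvest_days[2] <= cfg$harvest_days[1]) {
    fail("harvest_days", "must be an increasing (initial, final) pair")
  }
  if (cfg$harvest_days[2] < max(cfg$measurement_days)) {
    fail("harvest_days", "final harvest must not precede the last measurement day")
  }
  for (fld in c("rgr_range", "lar_range", "root_leaf_slope_range", "pnc_range")) {
    v <- cfg[[fld]]
    if (length(v) != 2 || any(!is.finite(v)) || v[1] > v[2]) {
      fail(fld, "must be a finite non-decreasing pair")
    }
  }
  if (any(cfg$rgr_range <= 0) || any(cfg$rgr_range >= 1)) {
    fail("rgr_range", "must lie within (0, 1) per day")
  }
  if (any(cfg$lar_range <= 0)) fail("lar_range", "must be positive")
  if (any(cfg$pnc_range <= 0)) fail("pnc_range", "must be positive")
  if (cfg$initial_biomass_mg <= 0) {
    fail("initial_biomass_mg", "must be positive")
  }
  if (length(cfg$element_ratio_profile) < 1 ||
      is.null(names(cfg$element_ratio_profile)) ||
      any(cfg$element_ratio_profile <= 0)) {
    fail("element_ratio_profile", "must be a named vector of positive ratios")
  }
  for (fld in c("ratio_genotype_cv", "ratio_noise_cv", "measurement_noise_cv",
                "block_effect_sd")) {
    if (!is.finite(cfg[[fld]]) || cfg[[fld]] < 0) {
      fail(fld, "must be a finite non-negative number")
    }
  }
  rho <- cfg$longitudinal_autocorrelation
  if (!is.finite(rho) || rho < 0 || rho >= 1) {
    fail("longitudinal_autocorrelation", "must lie in [0, 1)")
  }
  if (!is.null(cfg$niche_exponent) &&
      (!is.finite(cfg$niche_exponent) || cfg$niche_exponent == 0)) {
    fail("niche_exponent", "must be a nonzero finite number or NULL")
  }
  if (!is.null(cfg$genotype_ratio_multipliers)) {
    m <- cfg$genotype_ratio_multipliers
    if (!is.list(m) || is.null(names(m)) ||
        !all(names(m) %in% names(cfg$element_ratio_profile)) ||
        !all(vapply(m, length, 1L) == cfg$n_genotypes)) {
      fail("genotype_ratio_multipliers",
           "must be a named list (profile elements) of length-n_genotypes vectors")
    }
  }
  if (is.na(cfg$seed)) fail("seed", "must be an integer")
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Synthetic rhizobox experiment configuration\n")
  cat(sprintf("  design: %d genotypes x %d blocks (RCBD, %d rhizoboxes)\n",
              x$n_genotypes, x$n_blocks, x$n_genotypes * x$n_blocks))
  cat(sprintf("  measurement days: %s (leaves: %s)\n",
              paste(x$measurement_days, collapse = ", "),
              paste(x$leaf_days, collapse = ", ")))
  cat(sprintf("  harvests: day %g and day %g; %d pooled nutrient batches\n",
              x$harvest_days[1], x$harvest_days[2], x$n_batches))
  cat(sprintf("  true RGR in [%.3f, %.3f] d^-1; LAR in [%.2f, %.2f] cm^2 mg^-1\n",
              x$rgr_range[1], x$rgr_range[2], x$lar_range[1], x$lar_range[2]))
  cat(sprintf("  noise: measurement CV %.2f, ratio CV %.2f, block SD %.2f, AR(1) %.2f\n",
              x$measurement_noise_cv, x$ratio_noise_cv, x$block_effect_sd,
              x$longitudinal_autocorrelation))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Write / read a simulation configuration as structured text
#'
#' Configurations are serialized as YAML so that a simulation is fully
#' reproducible from its config file; [read_config()] re-validates on load.
#'
#' @param cfg A `"simulation_config"`.
#' @param path File path.
#' @return `write_config()` returns `path` invisibly; `read_config()` returns
#'   a validated `"simulation_config"`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "simulation_config"))
  x <- unclass(cfg)
  if (!is.null(x$element_ratio_profile)) {
    x$element_ratio_profile <- as.list(x$element_ratio_profile)
  }
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$element_ratio_profile <- unlist(x$element_ratio_profile)
  if (!is.null(x$genotype_ratio_multipliers)) {
    x$genotype_ratio_multipliers <- lapply(x$genotype_ratio_multipliers, unlist)
  }
  do.call(simulation_config, x)
}
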