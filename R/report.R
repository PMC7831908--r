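# End-to-end analysis of an experiment and report assembly.

#' Run the full early-vigor analysis pipeline
#'
#' Executes every stage on an experiment's tables: the genotype growth summary
#' and driver regressions, day-20 element pools with observed-vs-expected
#' evaluation, pairwise element scaling against N, the surrogate-productivity
#' biomass model, niche volumes and their scaling exponent, the trait
#' correlation matrix across genotype means, one-way ANOVAs for genotype
#' effects on per-plant harvest traits, and the root-on-leaf slope
#' heterogeneity analysis.
#'
#' @param experiment A `"rhizobox_experiment"` (synthetic or read from CSVs
#'   via [read_experiment()]).
#' @param main_interval,area_interval Growth-analysis intervals (days), see
#'   [growth_summary()].
#' @param ratios Optimum ratio table, see [optimum_ratios()].
#' @param other_elements Element set of the "other nutrients" niche volume.
#' @param shape_factor Leaf shape factor.
#' @param diameter_threshold_mm Main/lateral root diameter threshold.
#' @param tie Tie rule for a diameter class exactly at the threshold
#'   (see [partition_roots()]); the pipeline default assigns it to main roots.
#' @return A list of class `"earlyvigor_results"` with elements `growth`,
#'   `drivers`, `pools`, `ratio_eval`, `scaling`, `productivity_model`,
#'   `niche`, `correlations`, `anova`, `slopes`, and `meta`.
#' @export
analyze_experiment <- function(experiment,
                               main_interval = c(1, 20),
                               area_interval = c(7, 20),
                               ratios = optimum_ratios(),
                               other_elements = c("K", "Ca", "S", "Mg",
                                                  "Cu", "Fe", "Mn", "Zn"),
                               shape_factor = WHEAT_SHAPE_FACTOR,
                               diameter_threshold_mm = 0.2,
                               tie = "main") {
  stopifnot(inherits(experiment, "rhizobox_experiment"))
  growth <- growth_summary(experiment, main_interval, area_interval,
                           shape_factor)
  drivers <- driver_regressions(growth)

  final_day <- main_interval[2]
  pools <- element_pools(experiment, day = final_day)
  ratio_eval <- ratio_evaluation(pools, ratios)
  scaling <- dplyr::bind_rows(lapply(
    setdiff(intersect(names(ratios), unique(pools$element)), "N"),
    function(el) pairwise_scaling(pools, "N", el)
  ))
  prod_model <- biomass_productivity_model(pools)

  have_other <- intersect(other_elements, unique(pools$element))
  niche <- NULL
  if (length(have_other) >= 1 && all(c("N", "P") %in% pools$element)) {
    v_np <- niche_volume(pools, c("N", "P"))
    v_other <- niche_volume(pools, have_other)
    exponent <- niche_scaling_exponent(v_np, v_other)
    niche <- list(v_np = v_np, v_other = v_other, exponent = exponent,
                  other_elements = have_other)
  }

  # Per-plant day-20 traits for ANOVA and genotype means for correlations.
  hv <- experiment$harvest |>
    dplyr::filter(.data$day == final_day) |>
    dplyr::inner_join(experiment$plants[, c("plant_id", "genotype")],
                      by = "plant_id")
  part <- hv |>
    dplyr::group_by(.data$plant_id, .data$genotype) |>
    dplyr::summarise(
      shoot_biomass_mg = .data$shoot_biomass_mg[1],
      root_biomass_mg = .data$root_biomass_mg[1],
      whole_biomass_mg = .data$shoot_biomass_mg[1] + .data$root_biomass_mg[1],
      total_leaf_area_cm2 = .data$total_leaf_area_cm2[1],
      main_root_m = partition_roots(
        stats::setNames(.data$root_length_m, .data$diameter_class_mm),
        diameter_threshold_mm, tie = tie)$main_length,
      lateral_root_m = partition_roots(
        stats::setNames(.data$root_length_m, .data$diameter_class_mm),
        diameter_threshold_mm, tie = tie)$lateral_length,
      .groups = "drop"
    ) |>
    dplyr::mutate(total_root_m = .data$main_root_m + .data$lateral_root_m)

  anova_traits <- c("shoot_biomass_mg", "root_biomass_mg", "whole_biomass_mg",
                    "total_leaf_area_cm2", "main_root_m", "lateral_root_m",
                    "total_root_m")
  anova_tbl <- dplyr::bind_rows(lapply(anova_traits, function(tr) {
    one_way_anova(part[[tr]], part$genotype, trait = tr)
  }))

  gmeans <- part |>
    dplyr::group_by(.data$genotype) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(anova_traits), mean),
                     .groups = "drop")
  pool_wide <- tidyr::pivot_wider(pools[, c("genotype", "element", "pool_mg")],
                                  names_from = "element",
                                  values_from = "pool_mg")
  corr_tbl <- dplyr::inner_join(
    pool_wide[, c("genotype",
                  intersect(c("N", "P", "K", "S", "Ca", "Mg"),
                            names(pool_wide)))],
    gmeans[, c("genotype", "shoot_biomass_mg", "total_leaf_area_cm2",
               "total_root_m", "main_root_m", "lateral_root_m")],
    by = "genotype"
  )
  correlations <- pearson_matrix(corr_tbl)

  slope_days <- experiment$config$leaf_days %||% c(7, 11, 14, 18)
  slopes <- slope_heterogeneity(
    leaf_root_means(experiment, days = slope_days, shape_factor = shape_factor)
  )

  meta <- list(
    main_interval = main_interval,
    area_interval = area_interval,
    shape_factor = shape_factor,
    diameter_threshold_mm = diameter_threshold_mm,
    diameter_tie = tie,
    ratios = as.list(ratios),
    other_elements = have_other,
    lar_pnc_convention = paste(
      "LAP/PNP use the classical unit-rate interval formula;",
      "LAR = RGR/LAP and PNC = RGR/PNP so the decompositions are exact",
      "on their shared intervals"),
    biomass_convention = paste(
      "growth analysis uses exp(mean ln biomass); pools use the",
      "arithmetic genotype-mean biomass"),
    seed = experiment$config$seed %||% NA_integer_,
    package_version = as.character(utils::packageVersion("earlyvigor"))
  )

  structure(
    list(growth = growth, drivers = drivers, pools = pools,
         ratio_eval = ratio_eval, scaling = scaling,
         productivity_model = prod_model, niche = niche,
         correlations = correlations, anova = anova_tbl, slopes = slopes,
         per_plant = part, meta = meta),
    class = "earlyvigor_results"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.earlyvigor_results <- function(x, ...) {
  cat("Early-vigor analysis results\n")
  cat(sprintf("  %d genotypes; RGR %.4f-%.4f d^-1\n",
              nrow(x$growth), min(x$growth$RGR), max(x$growth$RGR)))
  if (!is.null(x$niche)) {
    cat(sprintf("  niche scaling exponent (N*P vs %s): %.3f (r = %.3f)\n",
                paste(x$niche$other_elements, collapse = ","),
                x$niche$exponent$exponent, x$niche$exponent$r))
  }
  cat(sprintf("  slope heterogeneity interaction p = %.3g\n",
              x$slopes$interaction_p))
  invisible(x)
}

#' Write an analysis report bundle to a directory
#'
#' Writes every stage output as a CSV table plus a `metadata.yaml` describing
#' the run (intervals, conventions, ratio table, seed, versions). Stages
#' missing from `results` are skipped, leaving an explicit gap note in the
#' metadata. Rerunning on the same experiment produces byte-identical files.
#'
#' @param results An `"earlyvigor_results"` list from [analyze_experiment()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
build_report <- function(results, dir) {
  stopifnot(inherits(results, "earlyvigor_results"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gaps <- character(0)
  wr <- function(x, name) {
    if (is.null(x)) {
      gaps <<- c(gaps, name)
      return(invisible(NULL))
    }
    utils::write.csv(as.data.frame(x), file.path(dir, name), row.names = FALSE)
  }
  wr(results$growth, "growth_summary.csv")
  wr(results$drivers, "driver_regressions.csv")
  wr(results$pools, "element_pools.csv")
  wr(results$ratio_eval, "ratio_evaluation.csv")
  wr(results$scaling, "pairwise_scaling.csv")
  wr(results$anova, "anova.csv")
  if (!is.null(results$correlations)) {
    utils::write.csv(results$correlations$r,
                     file.path(dir, "correlation_r.csv"))
    utils::write.csv(results$correlations$p,
                     file.path(dir, "correlation_p.csv"))
  } else {
    gaps <- c(gaps, "correlation_r.csv", "correlation_p.csv")
  }
  if (!is.null(results$niche)) {
    niche_tbl <- dplyr::inner_join(results$niche$v_np, results$niche$v_other,
                                   by = "genotype",
                                   suffix = c("_np", "_other"))
    wr(niche_tbl, "niche_volumes.csv")
    wr(tibble::tibble(
      exponent = results$niche$exponent$exponent,
      r = results$niche$exponent$r,
      n = results$niche$exponent$n
    ), "niche_exponent.csv")
  } else {
    gaps <- c(gaps, "niche_volumes.csv", "niche_exponent.csv")
  }
  if (!is.null(results$slopes)) {
    wr(results$slopes$slopes, "slopes.csv")
    wr(results$slopes$pairwise, "slope_pairwise.csv")
  } else {
    gaps <- c(gaps, "slopes.csv", "slope_pairwise.csv")
  }
  if (!is.null(results$productivity_model)) {
    wr(tibble::as_tibble(results$productivity_model),
       "productivity_model.csv")
  } else {
    gaps <- c(gaps, "productivity_model.csv")
  }
  meta <- results$meta
  meta$missing_outputs <- if (length(gaps) > 0) gaps else NULL
  yaml::write_yaml(meta, file.path(dir, "metadata.yaml"), precision = 15)
  invisible(dir)
}
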