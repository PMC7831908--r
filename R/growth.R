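# Functional growth analysis: relative growth rate and its light-based
# (RGR = LAR x LAP) and nitrogen-based (RGR = PNC x PNP) decompositions,
# the relative N accumulation rate, and the cross-genotype driver
# regressions of RGR on its components.
#
# Conventions: the analysis unit is the genotype. Whole-plant biomass enters
# as the genotype mean of per-plant natural-log biomass; W below denotes
# exp(mean ln W). LAP and PNP use the classical unit-leaf-rate interval
# formula; LAR and PNC are then defined as RGR / LAP and RGR / PNP so the
# decomposition identities hold exactly on the shared interval.

#' Interval summary of genotype means
#'
#' Packages the genotype-level quantities a growth interval needs: endpoint
#' days, mean log whole-plant biomass, mean total leaf area and mean
#' whole-plant N pool at both endpoints. Fields not needed by a given
#' estimator may be `NA`.
#'
#' @param t1,t2 Endpoint days (t2 > t1).
#' @param mean_lnW1,mean_lnW2 Genotype means of ln whole-plant biomass (ln mg).
#' @param mean_A1,mean_A2 Genotype mean total leaf area (cm^2).
#' @param mean_Np1,mean_Np2 Genotype mean whole-plant N pool (mg).
#' @return A list of class `"interval_summary"`.
#' @export
interval_summary <- function(t1, t2, mean_lnW1 = NA_real_, mean_lnW2 = NA_real_,
                             mean_A1 = NA_real_, mean_A2 = NA_real_,
                             mean_Np1 = NA_real_, mean_Np2 = NA_real_) {
  if (!is.finite(t1) || !is.finite(t2) || t2 <= t1) {
    stop("interval error: t2 must exceed t1", call. = FALSE)
  }
  structure(list(t1 = t1, t2 = t2, mean_lnW1 = mean_lnW1,
                 mean_lnW2 = mean_lnW2, mean_A1 = mean_A1, mean_A2 = mean_A2,
                 mean_Np1 = mean_Np1, mean_Np2 = mean_Np2),
            class = "interval_summary")
}

#' Relative growth rate over an interval
#'
#' RGR is the per-day increase of mean log whole-plant biomass:
#' `(mean_lnW2 - mean_lnW1) / (t2 - t1)`. Because it is a log difference it is
#' invariant to the biomass unit.
#'
#' @param interval An [interval_summary()].
#' @return Rate in d^-1.
#' @export
rgr <- function(interval) {
  with(interval, {
    if (!is.finite(mean_lnW1) || !is.finite(mean_lnW2)) {
      stop("rgr needs finite mean log biomass at both endpoints", call. = FALSE)
    }
    (mean_lnW2 - mean_lnW1) / (t2 - t1)
  })
}

#' Relative N accumulation rate
#'
#' The log-rate of increase of the whole-plant N pool, the N analogue of RGR:
#' `(ln Np2 - ln Np1) / (t2 - t1)`.
#'
#' @inheritParams rgr
#' @return Rate in d^-1.
#' @export
nar_n <- function(interval) {
  with(interval, {
    if (!is.finite(mean_Np1) || !is.finite(mean_Np2) ||
        mean_Np1 <= 0 || mean_Np2 <= 0) {
      stop("nar_n needs positive N pools at both endpoints", call. = FALSE)
    }
    (log(mean_Np2) - log(mean_Np1)) / (t2 - t1)
  })
}

#' Leaf area productivity (unit leaf rate / net assimilation rate)
#'
#' Classical interval formula for biomass production per unit leaf area and
#' time: `(W2 - W1) (ln A2 - ln A1) / ((A2 - A1) (t2 - t1))` with
#' `W = exp(mean ln W)`. When the leaf area does not change the formula is
#' degenerate; `allow_limit = TRUE` substitutes the constant-area limit
#' `(W2 - W1) / (A (t2 - t1))`.
#'
#' @inheritParams rgr
#' @param allow_limit Use the constant-area limit when `A2 == A1`.
#' @return Productivity in mg cm^-2 d^-1.
#' @export
lap <- function(interval, allow_limit = FALSE) {
  with(interval, {
    if (!is.finite(mean_A1) || !is.finite(mean_A2) ||
        mean_A1 <= 0 || mean_A2 <= 0) {
      stop("lap needs positive leaf areas at both endpoints", call. = FALSE)
    }
    w1 <- exp(mean_lnW1); w2 <- exp(mean_lnW2)
    if (mean_A2 == mean_A1) {
      if (!allow_limit) {
        stop(paste("degenerate interval: leaf area unchanged;",
                   "set allow_limit = TRUE for the constant-area form"),
             call. = FALSE)
      }
      return((w2 - w1) / (mean_A1 * (t2 - t1)))
    }
    (w2 - w1) * (log(mean_A2) - log(mean_A1)) /
      ((mean_A2 - mean_A1) * (t2 - t1))
  })
}

#' Leaf area ratio consistent with the decomposition identity
#'
#' Defined as `RGR / LAP` on the shared interval so that `RGR = LAR x LAP`
#' holds exactly. The instantaneous ratios A/W at both endpoints are returned
#' as diagnostics; when LAR varies smoothly over the interval the enforced
#' value lies between them.
#'
#' @inheritParams rgr
#' @param rgr_same_interval RGR computed on the same interval (d^-1).
#' @return A list with `lar` (cm^2 mg^-1), and diagnostics `ratio_t1`,
#'   `ratio_t2`.
#' @export
lar <- function(interval, rgr_same_interval) {
  lap_val <- lap(interval)
  if (lap_val == 0) stop("zero LAP: LAR undefined", call. = FALSE)
  list(
    lar = rgr_same_interval / lap_val,
    ratio_t1 = interval$mean_A1 / exp(interval$mean_lnW1),
    ratio_t2 = interval$mean_A2 / exp(interval$mean_lnW2)
  )
}

#' Plant N productivity and N concentration
#'
#' PNP uses the unit formula with the N pool in place of leaf area:
#' `(W2 - W1) (ln Np2 - ln Np1) / ((Np2 - Np1) (t2 - t1))`; PNC is then
#' `RGR / PNP` so that `RGR = PNC x PNP` holds exactly on the shared interval.
#'
#' @inheritParams lar
#' @param allow_limit Use the constant-pool limit when `Np2 == Np1`.
#' @return A list with `pnp` (mg mg(N)^-1 d^-1) and `pnc` (mg(N) mg^-1).
#' @export
pnp_pnc <- function(interval, rgr_same_interval, allow_limit = FALSE) {
  with(interval, {
    if (!is.finite(mean_Np1) || !is.finite(mean_Np2) ||
        mean_Np1 <= 0 || mean_Np2 <= 0) {
      stop("pnp_pnc needs positive N pools at both endpoints", call. = FALSE)
    }
    w1 <- exp(mean_lnW1); w2 <- exp(mean_lnW2)
    pnp <- if (mean_Np2 == mean_Np1) {
      if (!allow_limit) {
        stop(paste("degenerate interval: N pool unchanged;",
                   "set allow_limit = TRUE for the constant-pool form"),
             call. = FALSE)
      }
      (w2 - w1) / (mean_Np1 * (t2 - t1))
    } else {
      (w2 - w1) * (log(mean_Np2) - log(mean_Np1)) /
        ((mean_Np2 - mean_Np1) * (t2 - t1))
    }
    if (pnp == 0) stop("zero PNP: PNC undefined", call. = FALSE)
    list(pnp = pnp, pnc = rgr_same_interval / pnp)
  })
}

#' Genotype-level growth summary of an experiment
#'
#' Runs the full functional growth analysis on an experiment's tables and
#' returns one row per genotype with: the headline RGR over the main harvest
#' interval, the relative N accumulation rate, PNC and PNP (same interval),
#' and LAR and LAP over the leaf-area interval together with the
#' interval-matched RGR used in their decomposition.
#'
#' Whole-plant biomass at the start of the leaf-area interval is not harvested;
#' it is back-cast under the exponential model as
#' `ln W(t) = ln W(final) - RGR (final - t)`, which makes the interval-matched
#' RGR equal the headline RGR by construction. Leaf area at the early endpoint
#' comes from the non-destructive leaf dimensions ([plant_leaf_area()]); at
#' the final harvest it is the destructively measured area. N pools are the
#' batch-mean concentration times the genotype geometric-mean biomass.
#'
#' @param experiment A `"rhizobox_experiment"` (synthetic or read from CSVs).
#' @param main_interval Days (start, end) for RGR, NAR_N, PNC, PNP.
#' @param area_interval Days (start, end) for LAR and LAP.
#' @param shape_factor Leaf shape factor for the non-destructive areas.
#' @return A tibble with one row per genotype and columns `RGR`, `NAR_N`,
#'   `PNC`, `PNP`, `RGR_matched`, `LAR`, `LAP`, plus the interval endpoints
#'   and the endpoint A/W diagnostic ratios.
#' @export
growth_summary <- function(experiment,
                           main_interval = c(1, 20),
                           area_interval = c(7, 20),
                           shape_factor = WHEAT_SHAPE_FACTOR) {
  stopifnot(inherits(experiment, "rhizobox_experiment"))
  plants <- experiment$plants
  harvest <- experiment$harvest
  nutrients <- experiment$nutrient_batches

  # One row per plant per harvest day (the diameter classes repeat scalars).
  hv <- harvest |>
    dplyr::distinct(.data$plant_id, .data$day, .data$shoot_biomass_mg,
                    .data$root_biomass_mg, .data$total_leaf_area_cm2) |>
    dplyr::inner_join(plants[, c("plant_id", "genotype")], by = "plant_id") |>
    dplyr::mutate(whole_mg = .data$shoot_biomass_mg + .data$root_biomass_mg)

  mean_ln_w <- function(d) {
    x <- hv[hv$day == d, ]
    if (nrow(x) == 0L) stop(sprintf("no harvest at day %g", d), call. = FALSE)
    tapply(log(x$whole_mg), x$genotype, mean)
  }
  mean_area_harvest <- function(d) {
    x <- hv[hv$day == d, ]
    tapply(x$total_leaf_area_cm2, x$genotype, mean)
  }
  n_conc <- function(d) {
    x <- nutrients[nutrients$element == "N" & nutrients$day == d, ]
    if (nrow(x) == 0L) stop(sprintf("no N assay at day %g", d), call. = FALSE)
    tapply(x$concentration_mg_per_g, x$genotype, mean) # mean over batches
  }

  t1 <- main_interval[1]; t2 <- main_interval[2]
  a1 <- area_interval[1]; a2 <- area_interval[2]
  lnw1 <- mean_ln_w(t1)
  lnw2 <- mean_ln_w(t2)
  genotypes <- names(lnw1)

  # N pools: batch-mean concentration (mg g^-1) x geometric-mean biomass (mg).
  np1 <- n_conc(t1)[genotypes] * exp(lnw1) / 1000
  np2 <- n_conc(t2)[genotypes] * exp(lnw2) / 1000

  # Leaf area: non-destructive reconstruction at the early endpoint,
  # destructive area at the final harvest.
  pla <- plant_leaf_area(experiment$longitudinal, shape_factor) |>
    dplyr::inner_join(plants[, c("plant_id", "genotype")], by = "plant_id")
  area_early <- pla[pla$day == a1, ]
  if (nrow(area_early) == 0L) {
    stop(sprintf("no leaf dimension records at day %g", a1), call. = FALSE)
  }
  a_early <- tapply(area_early$total_leaf_area_cm2, area_early$genotype, mean)
  a_final <- mean_area_harvest(a2)

  out <- lapply(genotypes, function(g) {
    main_iv <- interval_summary(t1, t2,
                                mean_lnW1 = lnw1[[g]], mean_lnW2 = lnw2[[g]],
                                mean_Np1 = np1[[g]], mean_Np2 = np2[[g]])
    rgr_head <- rgr(main_iv)
    narn <- nar_n(main_iv)
    np <- pnp_pnc(main_iv, rgr_head)

    # Back-cast ln W to the start of the leaf-area interval.
    lnw_a1 <- lnw2[[g]] - rgr_head * (t2 - a1)
    area_iv <- interval_summary(a1, a2,
                                mean_lnW1 = lnw_a1, mean_lnW2 = lnw2[[g]],
                                mean_A1 = a_early[[g]], mean_A2 = a_final[[g]])
    rgr_matched <- rgr(area_iv)
    lap_val <- lap(area_iv)
    lar_val <- lar(area_iv, rgr_matched)

    tibble::tibble(
      genotype = g,
      RGR = rgr_head, NAR_N = narn, PNC = np$pnc, PNP = np$pnp,
      RGR_matched = rgr_matched, LAR = lar_val$lar, LAP = lap_val,
      area_ratio_t1 = lar_val$ratio_t1, area_ratio_t2 = lar_val$ratio_t2,
      main_t1 = t1, main_t2 = t2, area_t1 = a1, area_t2 = a2
    )
  })
  dplyr::bind_rows(out)
}

#' Cross-genotype regressions of RGR on its components
#'
#' Ordinary least-squares of RGR on each growth component (LAR, LAP, PNC,
#' PNP, NAR_N) across genotypes — the analysis behind asking which component
#' drives genotypic variation in growth. Both the plain and the adjusted R^2
#' are reported since published regressions do not always say which they
#' print (a negative printed value can only be adjusted).
#'
#' @param summaries Output of [growth_summary()].
#' @param components Character vector of component columns to regress on.
#' @return A tibble with `component`, `slope`, `r_squared`, `adj_r_squared`,
#'   `p_value`, `n`, and `degenerate` (TRUE when the component is constant and
#'   the regression undefined).
#' @export
driver_regressions <- function(summaries,
                               components = c("LAR", "LAP", "PNC", "PNP",
                                              "NAR_N")) {
  if (nrow(summaries) < 3) {
    stop("driver regressions need at least 3 genotypes", call. = FALSE)
  }
  rows <- lapply(components, function(comp) {
    x <- summaries[[comp]]
    y <- summaries$RGR
    if (is.null(x)) stop(sprintf("unknown component '%s'", comp), call. = FALSE)
    if (stats::sd(x) == 0) {
      return(tibble::tibble(component = comp, slope = NA_real_,
                            r_squared = NA_real_, adj_r_squared = NA_real_,
                            p_value = NA_real_, n = length(x),
                            degenerate = TRUE))
    }
    fit <- stats::lm(y ~ x)
    sm <- summary(fit)
    tibble::tibble(
      component = comp,
      slope = unname(stats::coef(fit)[2]),
      r_squared = sm$r.squared,
      adj_r_squared = sm$adj.r.squared,
      p_value = sm$coefficients[2, 4],
      n = length(x),
      degenerate = FALSE
    )
  })
  dplyr::bind_rows(rows)
}
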