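# Multi-element nutrient stoichiometry: whole-plant element pools from pooled
# assay batches, expected pools under optimum N-based element ratios, pairwise
# element scaling, surrogate productivities, the biomass-productivity model,
# and stoichiometric niche volumes with their RMA scaling exponents.

#' Optimum N-based element ratios
#'
#' The published optimum N:P:K:Ca:Mg proportions for non-co-limited growth,
#' expressed with N = 100: P 14.3, K 68.3, Ca 8.3, Mg 8.7. Override any
#' component to evaluate other ratio tables.
#'
#' @param P,K,Ca,Mg Ratio-to-N x 100 for each element.
#' @param ... Further named elements (ratio-to-N x 100).
#' @return Named numeric vector including `N = 100`.
#' @export
#' @examples
#' optimum_ratios() # N 100, P 14.3, K 68.3, Ca 8.3, Mg 8.7
optimum_ratios <- function(P = 14.3, K = 68.3, Ca = 8.3, Mg = 8.7, ...) {
  extra <- c(...)
  r <- c(N = 100, P = P, K = K, Ca = Ca, Mg = Mg, extra)
  if (any(r <= 0)) stop("optimum ratios must be positive", call. = FALSE)
  r
}

#' Expected element pool under optimum N-based ratios
#'
#' The pool of `element` a plant should hold, given its N pool, for its
#' element-to-N ratio to be at the published optimum:
#' `n_pool x ratio(element) / 100`.
#'
#' @param n_pool Whole-plant N pool (mg), >= 0.
#' @param element Element name present in `ratios`.
#' @param ratios Named ratio table, see [optimum_ratios()].
#' @return Expected pool in mg.
#' @export
#' @examples
#' expected_pool(100, "P") # 14.3 mg
expected_pool <- function(n_pool, element, ratios = optimum_ratios()) {
  if (any(n_pool < 0)) stop("n_pool must be non-negative", call. = FALSE)
  if (!element %in% names(ratios)) {
    stop(sprintf("unknown element '%s'; supported: %s", element,
                 paste(names(ratios), collapse = ", ")), call. = FALSE)
  }
  n_pool * ratios[[element]] / 100
}

#' Element pools from pooled assay batches
#'
#' `pool_from_batches()` turns the batch records of one genotype into
#' whole-plant element pools: the concentration is the arithmetic mean over
#' batches and the pool is that concentration times the genotype-mean
#' whole-plant biomass. `element_pools()` maps it over every genotype of an
#' experiment at a harvest day.
#'
#' @param batches Tibble of batch records with columns `element` and
#'   `concentration_mg_per_g` (one genotype, one day).
#' @param biomass_mg Genotype-mean whole-plant biomass (mg).
#' @return Tibble with `element`, `concentration_mg_per_g`, `biomass_mg` and
#'   `pool_mg` (`concentration x biomass / 1000`).
#' @export
#' @examples
#' b <- tibble::tibble(element = "N", concentration_mg_per_g = c(40, 44))
#' pool_from_batches(b, biomass_mg = 300)$pool_mg # 12.6 mg
pool_from_batches <- function(batches, biomass_mg) {
  if (nrow(batches) == 0L) {
    stop("missing data: no batch records supplied", call. = FALSE)
  }
  if (!is.finite(biomass_mg) || biomass_mg < 0) {
    stop("biomass_mg must be a non-negative number", call. = FALSE)
  }
  conc <- tapply(batches$concentration_mg_per_g, batches$element, mean)
  tibble::tibble(
    element = names(conc),
    concentration_mg_per_g = as.numeric(conc),
    biomass_mg = biomass_mg,
    pool_mg = as.numeric(conc) * biomass_mg / 1000
  )
}

#' @rdname pool_from_batches
#' @param experiment A `"rhizobox_experiment"`.
#' @param day Harvest day of the assays (default: the final harvest day in
#'   the nutrient table).
#' @export
element_pools <- function(experiment, day = NULL) {
  stopifnot(inherits(experiment, "rhizobox_experiment"))
  nt <- experiment$nutrient_batches
  if (is.null(day)) day <- max(nt$day)
  nt <- nt[nt$day == day, ]
  if (nrow(nt) == 0L) {
    stop(sprintf("missing data: no nutrient batches at day %g", day),
         call. = FALSE)
  }
  hv <- experiment$harvest |>
    dplyr::distinct(.data$plant_id, .data$day, .data$shoot_biomass_mg,
                    .data$root_biomass_mg) |>
    dplyr::inner_join(experiment$plants[, c("plant_id", "genotype")],
                      by = "plant_id")
  hv <- hv[hv$day == day, ]
  if (nrow(hv) == 0L) {
    stop(sprintf("missing data: no harvest at day %g", day), call. = FALSE)
  }
  wmean <- tapply(hv$shoot_biomass_mg + hv$root_biomass_mg, hv$genotype, mean)
  out <- lapply(names(wmean), function(g) {
    p <- pool_from_batches(nt[nt$genotype == g, ], wmean[[g]])
    p$genotype <- g
    p$day <- day
    p[, c("genotype", "day", "element", "concentration_mg_per_g",
          "biomass_mg", "pool_mg")]
  })
  dplyr::bind_rows(out)
}

#' Observed versus expected element pools
#'
#' Compares each genotype's observed element pools with the pools expected
#' under the optimum N-based ratios given its own N pool; an observed pool
#' below the expected one is flagged suboptimal.
#'
#' @param pools Long pool tibble from [element_pools()] (columns `genotype`,
#'   `element`, `pool_mg`).
#' @param ratios Ratio table, see [optimum_ratios()].
#' @return Tibble with `genotype`, `element`, `observed_mg`, `expected_mg`,
#'   `obs_over_exp` and `suboptimal`.
#' @export
ratio_evaluation <- function(pools, ratios = optimum_ratios()) {
  elements <- setdiff(intersect(names(ratios), unique(pools$element)), "N")
  out <- lapply(split(pools, pools$genotype), function(pg) {
    n_row <- pg[pg$element == "N", ]
    if (nrow(n_row) != 1L) {
      stop(sprintf("genotype %s is missing its N pool", pg$genotype[1]),
           call. = FALSE)
    }
    obs <- pg[pg$element %in% elements, ]
    exp_mg <- vapply(obs$element, function(el) {
      expected_pool(n_row$pool_mg, el, ratios)
    }, numeric(1))
    tibble::tibble(
      genotype = pg$genotype[1],
      element = obs$element,
      observed_mg = obs$pool_mg,
      expected_mg = unname(exp_mg),
      obs_over_exp = obs$pool_mg / unname(exp_mg),
      suboptimal = obs$pool_mg < unname(exp_mg)
    )
  })
  dplyr::bind_rows(out)
}

#' Pairwise element-pool scaling across genotypes
#'
#' OLS regression of one element's pool on another's across genotypes — the
#' analysis asking whether elements accumulate as linear functions of N.
#'
#' @param pools Long pool tibble ([element_pools()]).
#' @param x_element,y_element Element names.
#' @return One-row tibble with `slope`, `intercept`, `r_squared`,
#'   `adj_r_squared`, `p_value`, `n`, `degenerate`.
#' @export
pairwise_scaling <- function(pools, x_element, y_element) {
  wide <- tidyr::pivot_wider(pools[, c("genotype", "element", "pool_mg")],
                             names_from = "element", values_from = "pool_mg")
  for (el in c(x_element, y_element)) {
    if (!el %in% names(wide)) {
      stop(sprintf("element '%s' not present in pools", el), call. = FALSE)
    }
  }
  x <- wide[[x_element]]; y <- wide[[y_element]]
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need >= 3 genotypes with both elements", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(x_element = x_element, y_element = y_element,
                          slope = NA_real_, intercept = NA_real_,
                          r_squared = NA_real_, adj_r_squared = NA_real_,
                          p_value = NA_real_, n = length(x), degenerate = TRUE))
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  tibble::tibble(
    x_element = x_element, y_element = y_element,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
    p_value = sm$coefficients[2, 4], n = length(x), degenerate = FALSE
  )
}

#' Surrogate nutrient productivity
#'
#' When initial-harvest element contents are unavailable, the inverse of the
#' final mass-based concentration serves as a surrogate productivity (under
#' near-constant growth conditions, biomass per unit nutrient is proportional
#' to 1/concentration).
#'
#' @param concentration Final mass-based concentration (mg g^-1), > 0.
#' @return Surrogate productivity in g mg^-1. Vectorized.
#' @export
#' @examples
#' surrogate_productivity(40) # 0.025
surrogate_productivity <- function(concentration) {
  if (any(!is.finite(concentration)) || any(concentration <= 0)) {
    stop("concentration must be positive", call. = FALSE)
  }
  1 / concentration
}

#' Whole-plant biomass as a function of surrogate N and P productivities
#'
#' Fits `ln(biomass) ~ ln(P productivity) + ln(N productivity)` across
#' genotypes, with the productivities taken as the inverses of the final
#' mass-based concentrations.
#'
#' @param pools Long pool tibble ([element_pools()]) containing N and P rows
#'   with `concentration_mg_per_g` and `biomass_mg`.
#' @return A list with `coef_ln_p_prod`, `coef_ln_n_prod`, `intercept`,
#'   `r_squared`, `adj_r_squared`, `p_value` (overall F), `n`, and
#'   `rank_deficient` (TRUE when the regressors are collinear or constant, in
#'   which case coefficients that could not be estimated are `NA`).
#' @export
biomass_productivity_model <- function(pools) {
  wide <- tidyr::pivot_wider(
    pools[, c("genotype", "element", "concentration_mg_per_g")],
    names_from = "element", values_from = "concentration_mg_per_g"
  )
  bio <- pools |>
    dplyr::distinct(.data$genotype, .data$biomass_mg)
  d <- dplyr::inner_join(wide, bio, by = "genotype")
  if (nrow(d) < 4) stop("need >= 4 genotypes", call. = FALSE)
  if (any(!is.finite(d$N)) || any(!is.finite(d$P)) ||
      any(d$N <= 0) || any(d$P <= 0) || any(d$biomass_mg <= 0)) {
    stop("biomasses and N, P concentrations must be positive", call. = FALSE)
  }
  ln_p_prod <- log(surrogate_productivity(d$P))
  ln_n_prod <- log(surrogate_productivity(d$N))
  fit <- stats::lm(log(d$biomass_mg) ~ ln_p_prod + ln_n_prod)
  sm <- summary(fit)
  co <- stats::coef(fit)
  rank_def <- anyNA(co) || fit$rank < 3
  fstat <- sm$fstatistic
  p_overall <- if (is.null(fstat)) NA_real_ else {
    unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  }
  list(
    coef_ln_p_prod = unname(co["ln_p_prod"]),
    coef_ln_n_prod = unname(co["ln_n_prod"]),
    intercept = unname(co["(Intercept)"]),
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    p_value = p_overall,
    n = nrow(d),
    rank_deficient = rank_def
  )
}

#' Stoichiometric niche volume
#'
#' The product of a genotype's element concentrations over a chosen element
#' set (mg g^-1 each). `standardize = TRUE` first divides each element by its
#' geometric mean across genotypes, which changes the volume scale but not
#' log-scale slopes.
#'
#' @param pools Long pool tibble ([element_pools()]).
#' @param elements Element set of the volume.
#' @param standardize Divide concentrations by per-element geometric means.
#' @return Tibble with `genotype`, `volume` and `elements` (collapsed name).
#' @export
niche_volume <- function(pools, elements, standardize = FALSE) {
  sub <- pools[pools$element %in% elements,
               c("genotype", "element", "concentration_mg_per_g")]
  missing <- setdiff(elements, unique(sub$element))
  if (length(missing) > 0) {
    stop(sprintf("missing elements for niche volume: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (any(!is.finite(sub$concentration_mg_per_g)) ||
      any(sub$concentration_mg_per_g <= 0)) {
    stop("all member concentrations must be positive", call. = FALSE)
  }
  if (standardize) {
    gm <- tapply(log(sub$concentration_mg_per_g), sub$element, mean)
    sub$concentration_mg_per_g <-
      sub$concentration_mg_per_g / exp(gm[sub$element])
  }
  vol <- tapply(sub$concentration_mg_per_g, sub$genotype, prod)
  tibble::tibble(
    genotype = names(vol),
    volume = as.numeric(vol),
    elements = paste(sort(elements), collapse = "+")
  )
}

#' Reduced major axis (RMA) regression
#'
#' Symmetric line fit standard in allometry: slope = sign(r) sd(y)/sd(x), the
#' line passing through the means. The slope magnitude never falls below the
#' OLS slope's and the two agree exactly when |r| = 1.
#'
#' @param x,y Numeric vectors (paired).
#' @return A list with `slope`, `intercept`, `r` and `n`; `slope` is `NA`
#'   with `degenerate = TRUE` when either axis has zero variance.
#' @export
rma_regression <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("RMA needs at least 3 pairs", call. = FALSE)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) {
    return(list(slope = NA_real_, intercept = NA_real_, r = NA_real_,
                n = length(x), degenerate = TRUE))
  }
  r <- stats::cor(x, y)
  slope <- sign(r) * sy / sx
  list(slope = slope, intercept = mean(y) - slope * mean(x), r = r,
       n = length(x), degenerate = FALSE)
}

#' Niche-volume scaling exponent
#'
#' RMA slope of ln(volume of N and P) on ln(volume of the other elements)
#' across genotypes: a negative exponent means the other elements' combined
#' concentrations rise more slowly than those of N and P. `invert = TRUE`
#' swaps the axes (the symmetric convention of the method makes the inverted
#' slope the reciprocal).
#'
#' @param v_np Niche-volume tibble for N and P ([niche_volume()]).
#' @param v_other Niche-volume tibble for the other element set.
#' @param invert Regress ln(v_other) on ln(v_np) instead.
#' @return A list with `exponent`, `r`, `n`, `degenerate`.
#' @export
niche_scaling_exponent <- function(v_np, v_other, invert = FALSE) {
  d <- dplyr::inner_join(v_np[, c("genotype", "volume")],
                         v_other[, c("genotype", "volume")],
                         by = "genotype", suffix = c("_np", "_other"))
  if (any(d$volume_np <= 0) || any(d$volume_other <= 0)) {
    stop("volumes must be positive", call. = FALSE)
  }
  x <- log(d$volume_other); y <- log(d$volume_np)
  if (invert) { tmp <- x; x <- y; y <- tmp }
  fit <- rma_regression(x, y)
  list(exponent = fit$slope, r = fit$r, n = fit$n,
       degenerate = isTRUE(fit$degenerate))
}
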