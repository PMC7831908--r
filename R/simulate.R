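# Synthetic rhizobox experiment generator.
#
# The growth model is deliberately the minimal one that the downstream
# functional growth analysis presumes: per-genotype exponential whole-plant
# growth W(t) = W0 * exp(RGR * t), leaf area A(t) = LAR(t) * W(t), visible
# root length allometric in leaf area on the log-log scale, constant
# whole-plant N concentration, and element pools proportional to the N pool.
# Multiplicative lognormal block effects, AR(1) within-plant longitudinal
# residuals and lognormal measurement/assay noise sit on top. Every true
# parameter is retained so estimators can be checked by parameter recovery.

# Elements whose concentrations enter the "other nutrients" niche volume.
OTHER_ELEMENTS <- c("K", "Ca", "S", "Mg", "Cu", "Fe", "Mn", "Zn")

# Diameter-class layout used for destructive root length (class midpoints, mm,
# and the within-partition length shares). 0.2 mm separates lateral from main.
LATERAL_CLASSES <- c("0.05" = 0.4, "0.15" = 0.6)
MAIN_CLASSES <- c("0.3" = 0.8, "0.75" = 0.2)

# Substream seeds: stream k of root seed s is (s mod 65011) * 33013 + 7919 k + 1.
# Keeps every derived seed a positive 32-bit integer and distinct per stream.
substream_seed <- function(seed, k) {
  as.integer((abs(as.numeric(seed)) %% 65011) * 33013 + 7919 * k + 1)
}

lognormal_sigma <- function(cv) sqrt(log(1 + cv^2))

# Leaf count schedule: tillering wheat seedlings carry 2 leaves at day 7 and
# about one new leaf every 3-4 days thereafter, capped at 5 by day 20.
leaf_count <- function(day) pmin(2L + (day >= 10) + (day >= 13) + (day >= 17), 5L)

#' Generate a complete synthetic rhizobox experiment
#'
#' Simulates a randomized complete block trial with the data structure of a
#' non-destructive rhizobox phenotyping study: a plant registry, longitudinal
#' leaf and visible-root measurements, destructive harvests at two days, and
#' element concentrations reported for pooled batches. The embedded ground
#' truth ([truth_table()]) makes every downstream estimator testable by
#' parameter recovery. Identical configurations (including the seed) reproduce
#' identical output.
#'
#' Genotype-true parameters are evenly spaced across their configured ranges
#' (RGR in sowing order; LAR, root/leaf slope and plant N concentration in
#' independently permuted orders so traits are not artificially collinear).
#' Replicates of each genotype are assigned round-robin by block to the pooled
#' nutrient batches, whose reported concentration is the biomass-weighted mean
#' of their member plants.
#'
#' @param config A [simulation_config()].
#' @return An object of class `"rhizobox_experiment"`: a list with tibbles
#'   `plants`, `longitudinal`, `harvest`, `nutrient_batches`, the ground-truth
#'   tibble `truth`, and the `config`.
#' @export
#' @examples
#' exp <- generate_experiment(simulation_config(seed = 42))
#' nrow(exp$plants) # 72
generate_experiment <- function(config) {
  validate_config(config)
  cfg <- config
  ng <- cfg$n_genotypes
  nb <- cfg$n_blocks
  genotypes <- sprintf("G%02d", seq_len(ng))
  blocks <- sprintf("B%d", seq_len(nb))
  t0 <- cfg$harvest_days[1]
  t_final <- cfg$harvest_days[2]

  spread <- function(rng, n) {
    if (n == 1L) mean(rng) else seq(rng[1], rng[2], length.out = n)
  }

  ## --- stream 1: genotype-true parameters -------------------------------
  set.seed(substream_seed(cfg$seed, 1L))
  rgr_g <- spread(cfg$rgr_range, ng)
  lar_g <- spread(cfg$lar_range, ng)[sample.int(ng)]
  slope_g <- spread(cfg$root_leaf_slope_range, ng)[sample.int(ng)]
  pnc_g <- spread(cfg$pnc_range, ng)[sample.int(ng)]
  w0_g <- cfg$initial_biomass_mg * exp(stats::rnorm(ng, 0, 0.05))

  profile <- cfg$element_ratio_profile
  elements <- names(profile)
  sg <- lognormal_sigma(cfg$ratio_genotype_cv)
  ratio_g <- matrix(
    rep(profile, each = ng) *
      exp(stats::rnorm(ng * length(profile), 0, sg)),
    nrow = ng, dimnames = list(genotypes, elements)
  )
  if (!is.null(cfg$genotype_ratio_multipliers)) {
    for (el in names(cfg$genotype_ratio_multipliers)) {
      ratio_g[, el] <- ratio_g[, el] * cfg$genotype_ratio_multipliers[[el]]
    }
  }
  if (!is.null(cfg$niche_exponent) && "P" %in% elements) {
    # Plant an exact RMA scaling exponent b between the N*P concentration
    # volume and the product volume of the other elements: set the
    # genotype-varying part of each other-element log concentration to
    # (1/(n_other * b)) * centred ln(V_NP), so ln(V_NP) = b * ln(V_other) + c.
    b <- cfg$niche_exponent
    others <- intersect(OTHER_ELEMENTS, elements)
    conc_n <- 1000 * pnc_g                      # mg g^-1
    conc_p <- ratio_g[, "P"] * conc_n
    ln_vnp <- log(conc_n) + log(conc_p)
    dev <- (ln_vnp - mean(ln_vnp)) / (length(others) * b)
    for (el in others) {
      base <- profile[[el]] * 1000 * mean(pnc_g) # mg g^-1, genotype-invariant
      ratio_g[, el] <- exp(log(base) + dev) / conc_n
    }
  }

  truth <- tibble::tibble(
    genotype = genotypes,
    rgr = rgr_g,
    lar = lar_g,
    root_leaf_slope = slope_g,
    pnc = pnc_g,
    w0_mg = w0_g
  )
  for (el in elements) truth[[paste0("ratio_", el)]] <- ratio_g[, el]

  ## --- plant registry ----------------------------------------------------
  plants <- tibble::tibble(
    plant_id = sprintf("P%03d", seq_len(ng * nb)),
    genotype = rep(genotypes, times = nb),
    block = rep(blocks, each = ng),
    rhizobox_id = sprintf("RB%03d", seq_len(ng * nb))
  )
  np <- nrow(plants)
  gi <- match(plants$genotype, genotypes)
  bi <- match(plants$block, blocks)

  ## --- stream 2: block effects ------------------------------------------
  set.seed(substream_seed(cfg$seed, 2L))
  block_eff <- stats::rnorm(nb, 0, cfg$block_effect_sd)

  # Per-plant true log-biomass trajectory (block effect included).
  ln_w <- function(day) log(w0_g[gi]) + rgr_g[gi] * day + block_eff[bi]
  lar_at <- function(day) pmax(lar_g[gi] + cfg$lar_drift * (day - t_final), 1e-6)

  sm <- lognormal_sigma(cfg$measurement_noise_cv)
  rho <- cfg$longitudinal_autocorrelation

  ## --- stream 3: longitudinal measurements ------------------------------
  set.seed(substream_seed(cfg$seed, 3L))
  days <- cfg$measurement_days
  nd <- length(days)
  ar1 <- function() {
    e <- matrix(0, np, nd)
    e[, 1] <- stats::rnorm(np)
    if (nd > 1) {
      for (j in 2:nd) {
        e[, j] <- rho * e[, j - 1] + sqrt(1 - rho^2) * stats::rnorm(np)
      }
    }
    e
  }
  e_leaf <- ar1()
  e_root <- ar1()

  long_rows <- vector("list", nd)
  # Allometric anchor: a plant with 60 cm^2 of leaves shows ~400 cm of root.
  intercept_g <- log(400) - slope_g * log(60)
  for (j in seq_len(nd)) {
    d <- days[j]
    a_true <- lar_at(d) * exp(ln_w(d))
    l_tot <- exp(slope_g[gi] * log(a_true) + intercept_g[gi] +
                   sm * e_root[, j])
    l_main <- 0.45 * l_tot
    depth <- pmin(89, 15 * (l_tot / 100)^0.7)
    width <- pmin(68, 8 * (l_tot / 100)^0.6)
    root_tbl <- tibble::tibble(
      plant_id = rep(plants$plant_id, 5L),
      day = d,
      trait = rep(c("visible_total_root_len_cm", "visible_main_root_len_cm",
                    "visible_lateral_root_len_cm", "visible_root_depth_cm",
                    "visible_root_width_cm"), each = np),
      value = c(l_tot, l_main, l_tot - l_main, depth, width),
      unit = "cm"
    )
    if (d %in% cfg$leaf_days) {
      a_meas <- a_true * exp(sm * e_leaf[, j])
      nl <- leaf_count(d)
      share <- seq_len(nl) / sum(seq_len(nl))
      leaf_area_i <- as.vector(outer(a_meas, share))    # plant-major blocks
      aspect <- 0.08                                    # width/length of a wheat leaf
      len <- sqrt(leaf_area_i / (WHEAT_SHAPE_FACTOR * aspect))
      wid <- aspect * len
      leaf_tbl <- tibble::tibble(
        plant_id = rep(plants$plant_id, 2L * nl),
        day = d,
        trait = c(sprintf("leaf_length_cm_%02d", rep(seq_len(nl), each = np)),
                  sprintf("leaf_max_width_cm_%02d", rep(seq_len(nl), each = np))),
        value = c(len, wid),
        unit = "cm"
      )
      root_tbl <- dplyr::bind_rows(leaf_tbl, root_tbl)
    }
    long_rows[[j]] <- root_tbl
  }
  longitudinal <- dplyr::arrange(
    dplyr::bind_rows(long_rows),
    .data$day, .data$plant_id, .data$trait
  )

  ## --- stream 4: destructive harvests -----------------------------------
  set.seed(substream_seed(cfg$seed, 4L))
  harvest_rows <- vector("list", 2L)
  w_harv <- list()
  for (h in 1:2) {
    d <- cfg$harvest_days[h]
    w <- exp(ln_w(d) + sm * stats::rnorm(np))
    w_harv[[h]] <- w
    shoot_frac <- 0.8
    if (h == 1L) {
      harvest_rows[[h]] <- tibble::tibble(
        plant_id = plants$plant_id,
        day = d,
        shoot_biomass_mg = shoot_frac * w,
        root_biomass_mg = (1 - shoot_frac) * w,
        total_leaf_area_cm2 = NA_real_,
        diameter_class_mm = NA_real_,
        root_length_m = NA_real_,
        leaf_number = NA_integer_,
        seminal_root_number = NA_integer_,
        nodal_root_number = NA_integer_
      )
    } else {
      area <- lar_at(d) * w
      # Destructive root length anchored at the reported day-20 magnitudes
      # (lateral ~8 m, main ~4 m at 60 cm^2 of leaf area).
      lateral_m <- 8 * (area / 60)^1.1 * exp(sm * stats::rnorm(np))
      main_m <- 4 * (area / 60)^0.8 * exp(sm * stats::rnorm(np))
      leaf_no <- leaf_count(d) + stats::rpois(np, 0.5)
      seminal_no <- 4L + stats::rpois(np, 0.8)
      nodal_no <- 1L + stats::rpois(np, 2)
      class_mm <- as.numeric(c(names(LATERAL_CLASSES), names(MAIN_CLASSES)))
      class_len <- cbind(outer(lateral_m, unname(LATERAL_CLASSES)),
                         outer(main_m, unname(MAIN_CLASSES)))
      harvest_rows[[h]] <- tibble::tibble(
        plant_id = rep(plants$plant_id, length(class_mm)),
        day = d,
        shoot_biomass_mg = rep(shoot_frac * w, length(class_mm)),
        root_biomass_mg = rep((1 - shoot_frac) * w, length(class_mm)),
        total_leaf_area_cm2 = rep(area, length(class_mm)),
        diameter_class_mm = rep(class_mm, each = np),
        root_length_m = as.vector(class_len),
        leaf_number = rep(leaf_no, length(class_mm)),
        seminal_root_number = rep(seminal_no, length(class_mm)),
        nodal_root_number = rep(nodal_no, length(class_mm))
      )
    }
  }
  harvest <- dplyr::arrange(
    dplyr::bind_rows(harvest_rows),
    .data$day, .data$plant_id, .data$diameter_class_mm
  )

  ## --- stream 5: nutrient concentrations, pooled into batches -----------
  set.seed(substream_seed(cfg$seed, 5L))
  sr <- lognormal_sigma(cfg$ratio_noise_cv)
  batch_of <- ((bi - 1L) %% cfg$n_batches) + 1L
  pool_batches <- function(day_idx, element_set) {
    d <- cfg$harvest_days[day_idx]
    w <- w_harv[[day_idx]]
    out <- list()
    for (el in element_set) {
      conc_true <- if (el == "N") {
        1000 * pnc_g[gi]
      } else {
        1000 * ratio_g[cbind(gi, match(el, elements))] * pnc_g[gi]
      }
      conc_p <- conc_true * exp(sr * stats::rnorm(np))
      agg_num <- tapply(conc_p * w, list(plants$genotype, batch_of), sum)
      agg_den <- tapply(w, list(plants$genotype, batch_of), sum)
      conc_b <- agg_num / agg_den
      out[[el]] <- tibble::tibble(
        genotype = rep(rownames(conc_b), ncol(conc_b)),
        day = d,
        batch_id = rep(seq_len(ncol(conc_b)), each = nrow(conc_b)),
        element = el,
        concentration_mg_per_g = as.vector(conc_b)
      )
    }
    dplyr::bind_rows(out)
  }
  # N is assayed at both harvests; the other elements only at the final one.
  nutrient_batches <- dplyr::arrange(
    dplyr::bind_rows(pool_batches(1L, "N"),
                     pool_batches(2L, c("N", setdiff(elements, "N")))),
    .data$day, .data$genotype, .data$batch_id, .data$element
  )

  structure(
    list(plants = plants, longitudinal = longitudinal, harvest = harvest,
         nutrient_batches = nutrient_batches, truth = truth, config = cfg),
    class = "rhizobox_experiment"
  )
}

#' Ground truth of a synthetic experiment
#'
#' Returns the per-genotype true parameters embedded by
#' [generate_experiment()]: relative growth rate (`rgr`, d^-1), leaf area
#' ratio at final harvest (`lar`, cm^2 mg^-1), log-log visible root/leaf
#' slope, whole-plant N concentration (`pnc`, mg mg^-1), initial biomass
#' (`w0_mg`) and element-to-N pool ratios (`ratio_*`).
#'
#' @param experiment A `"rhizobox_experiment"`.
#' @return A tibble with one row per genotype.
#' @export
truth_table <- function(experiment) {
  stopifnot(inherits(experiment, "rhizobox_experiment"))
  experiment$truth
}

#' @export
print.rhizobox_experiment <- function(x, ...) {
  cat("Synthetic rhizobox experiment\n")
  cat(sprintf("  %d plants (%d genotypes x %d blocks), seed %d\n",
              nrow(x$plants), x$config$n_genotypes, x$config$n_blocks,
              x$config$seed))
  cat(sprintf("  %d longitudinal records over days %s\n",
              nrow(x$longitudinal),
              paste(x$config$measurement_days, collapse = ", ")))
  cat(sprintf("  harvests at days %g and %g; %d pooled nutrient records\n",
              x$config$harvest_days[1], x$config$harvest_days[2],
              nrow(x$nutrient_batches)))
  invisible(x)
}

#' Write / read an experiment as the four analysis CSV tables
#'
#' `write_experiment()` writes `plants.csv`, `longitudinal.csv`,
#' `harvest.csv`, `nutrients.csv`, the ground truth (`truth.csv`) and the
#' configuration (`config.yaml`) to a directory. `read_experiment()` loads
#' them back; truth and config are optional on disk (real data has neither).
#'
#' @param experiment A `"rhizobox_experiment"`.
#' @param dir Directory path (created if absent).
#' @return `write_experiment()` returns `dir` invisibly; `read_experiment()`
#'   returns a `"rhizobox_experiment"` (with `truth`/`config` `NULL` when not
#'   on disk).
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "rhizobox_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) {
    utils::write.csv(as.data.frame(x), file.path(dir, name), row.names = FALSE)
  }
  wr(experiment$plants, "plants.csv")
  wr(experiment$longitudinal, "longitudinal.csv")
  wr(experiment$harvest, "harvest.csv")
  wr(experiment$nutrient_batches, "nutrients.csv")
  if (!is.null(experiment$truth)) wr(experiment$truth, "truth.csv")
  if (!is.null(experiment$config)) {
    write_config(experiment$config, file.path(dir, "config.yaml"))
  }
  invisible(dir)
}

#' @rdname write_experiment
#' @export
read_experiment <- function(dir) {
  rd <- function(name) {
    tibble::as_tibble(utils::read.csv(file.path(dir, name),
                                      stringsAsFactors = FALSE))
  }
  truth_path <- file.path(dir, "truth.csv")
  cfg_path <- file.path(dir, "config.yaml")
  structure(
    list(
      plants = rd("plants.csv"),
      longitudinal = rd("longitudinal.csv"),
      harvest = rd("harvest.csv"),
      nutrient_batches = rd("nutrients.csv"),
      truth = if (file.exists(truth_path)) rd("truth.csv") else NULL,
      config = if (file.exists(cfg_path)) read_config(cfg_path) else NULL
    ),
    class = "rhizobox_experiment"
  )
}
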