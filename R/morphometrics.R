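# Shoot and root morphometrics: leaf-area estimation from manual length/width
# measurements, partition of scanned root length into main and lateral roots
# by a diameter threshold, and per-genotype trait trajectories.

#' Wheat leaf shape factor
#'
#' Dimensionless factor `k` relating a leaf's length x maximum width rectangle
#' to its true area (`area = length x max width x k`); 0.858 for wheat leaves.
#' @export
WHEAT_SHAPE_FACTOR <- 0.858

#' Estimate leaf area from length and maximum width
#'
#' `leaf_area()` applies the classical linear-dimension estimator
#' `area = length x max_width x shape_factor`; `total_leaf_area()` sums it
#' over all leaves of a plant (an empty plant has zero area). Both are
#' vectorized.
#'
#' @param length Leaf length (cm), non-negative.
#' @param max_width Maximum leaf width (cm), non-negative.
#' @param shape_factor Dimensionless shape factor; defaults to the wheat value
#'   [WHEAT_SHAPE_FACTOR].
#' @return Leaf area in cm^2.
#' @export
#' @examples
#' leaf_area(10, 1.2) # 10.296 cm^2
leaf_area <- function(length, max_width, shape_factor = WHEAT_SHAPE_FACTOR) {
  if (any(length < 0, na.rm = TRUE) || any(max_width < 0, na.rm = TRUE)) {
    stop("leaf dimensions must be non-negative", call. = FALSE)
  }
  if (any(shape_factor <= 0)) {
    stop("shape_factor must be positive", call. = FALSE)
  }
  length * max_width * shape_factor
}

#' @rdname leaf_area
#' @param lengths,max_widths Equal-length vectors of per-leaf dimensions (cm);
#'   may be empty.
#' @export
total_leaf_area <- function(lengths, max_widths,
                            shape_factor = WHEAT_SHAPE_FACTOR) {
  if (length(lengths) != length(max_widths)) {
    stop("lengths and max_widths must have equal length", call. = FALSE)
  }
  if (length(lengths) == 0L) return(0)
  sum(leaf_area(lengths, max_widths, shape_factor))
}

#' Partition diameter-classed root length into main and lateral roots
#'
#' Scanned root length arrives binned by diameter class; roots thicker than
#' the threshold (default 0.2 mm) count as main roots, thinner ones as lateral
#' roots. A class whose stated bound equals the threshold is ambiguous: with
#' nonzero length it is an error unless `tie` names the side it belongs to.
#'
#' @param class_lengths Named numeric vector: names are diameter-class bounds
#'   or midpoints (mm, strictly increasing), values are root lengths (m, >= 0).
#' @param threshold_mm Diameter threshold in mm.
#' @param tie How to assign a class exactly at the threshold: `"error"`
#'   (default), `"main"` or `"lateral"`.
#' @return A list with `main_length`, `lateral_length` and `total_length` (m);
#'   main + lateral equals total exactly.
#' @export
#' @examples
#' partition_roots(c("0.1" = 5, "0.3" = 3)) # main 3, lateral 5, total 8
partition_roots <- function(class_lengths, threshold_mm = 0.2,
                            tie = c("error", "main", "lateral")) {
  tie <- match.arg(tie)
  if (length(class_lengths) == 0L) {
    return(list(main_length = 0, lateral_length = 0, total_length = 0))
  }
  d <- as.numeric(names(class_lengths))
  if (anyNA(d)) {
    stop("class names must be numeric diameter bounds (mm)", call. = FALSE)
  }
  if (is.unsorted(d, strictly = TRUE)) {
    stop("diameter classes must be strictly increasing", call. = FALSE)
  }
  if (any(class_lengths < 0)) {
    stop("root lengths must be non-negative", call. = FALSE)
  }
  at <- d == threshold_mm
  if (any(at & class_lengths > 0) && tie == "error") {
    stop(sprintf(paste("diameter class at exactly %g mm carries length;",
                       "set tie = 'main' or 'lateral' to assign it"),
                 threshold_mm), call. = FALSE)
  }
  main <- d > threshold_mm | (at & tie == "main")
  lateral <- d < threshold_mm | (at & tie == "lateral")
  list(
    main_length = sum(class_lengths[main]),
    lateral_length = sum(class_lengths[lateral]),
    total_length = sum(class_lengths[main]) + sum(class_lengths[lateral])
  )
}

#' Per-genotype trait trajectory (mean and standard error by day)
#'
#' Summarises a longitudinal trait as genotype x day means with standard
#' errors (sample SD / sqrt(n), n - 1 denominator), optionally after a log or
#' square-root transform — the transforms under which root and leaf traits are
#' usually analysed. Missing genotype x day cells are simply absent from the
#' output, never imputed.
#'
#' @param longitudinal Tibble with columns `plant_id`, `day`, `trait`, `value`.
#' @param plants Plant registry tibble with `plant_id` and `genotype`.
#' @param trait Trait name to summarise (must occur in `longitudinal$trait`).
#' @param transform One of `"identity"`, `"log"`, `"sqrt"`.
#' @return Tibble with `genotype`, `day`, `n`, `mean`, `se` (of the
#'   transformed values).
#' @export
trait_trajectory <- function(longitudinal, plants, trait,
                             transform = c("identity", "log", "sqrt")) {
  transform <- match.arg(transform)
  rows <- longitudinal[longitudinal$trait == trait, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop(sprintf("unknown trait '%s': not present in the longitudinal table",
                 trait), call. = FALSE)
  }
  v <- rows$value
  if (transform == "log") {
    if (any(v <= 0)) stop("log transform requires strictly positive values",
                          call. = FALSE)
    v <- log(v)
  } else if (transform == "sqrt") {
    if (any(v < 0)) stop("sqrt transform requires non-negative values",
                         call. = FALSE)
    v <- sqrt(v)
  }
  rows$value <- v
  rows |>
    dplyr::inner_join(plants[, c("plant_id", "genotype")], by = "plant_id") |>
    dplyr::group_by(.data$genotype, .data$day) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      se = stats::sd(.data$value) / sqrt(dplyr::n()),
      .groups = "drop"
    )
}

#' Reconstruct per-plant total leaf area from longitudinal leaf dimensions
#'
#' Pairs the per-leaf `leaf_length_cm_*` and `leaf_max_width_cm_*` records of
#' each plant and day, applies [leaf_area()] to each leaf and sums.
#'
#' @param longitudinal Longitudinal tibble (see [trait_trajectory()]).
#' @param shape_factor Leaf shape factor.
#' @return Tibble with `plant_id`, `day`, `total_leaf_area_cm2`.
#' @export
plant_leaf_area <- function(longitudinal, shape_factor = WHEAT_SHAPE_FACTOR) {
  leaf <- longitudinal[grepl("^leaf_(length|max_width)_cm_", longitudinal$trait), ]
  if (nrow(leaf) == 0L) {
    stop("no leaf dimension records found", call. = FALSE)
  }
  leaf$leaf_index <- sub("^leaf_(length|max_width)_cm_", "", leaf$trait)
  leaf$dim <- ifelse(grepl("^leaf_length", leaf$trait), "length", "max_width")
  wide <- tidyr::pivot_wider(
    leaf[, c("plant_id", "day", "leaf_index", "dim", "value")],
    names_from = "dim", values_from = "value"
  )
  if (anyNA(wide$length) || anyNA(wide$max_width)) {
    stop("unpaired leaf length/width records", call. = FALSE)
  }
  wide$area <- leaf_area(wide$length, wide$max_width, shape_factor)
  wide |>
    dplyr::group_by(.data$plant_id, .data$day) |>
    dplyr::summarise(total_leaf_area_cm2 = sum(.data$area), .groups = "drop")
}
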