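# Statistical surfaces of the trial: Pearson correlation matrices across
# genotype means, one-way ANOVA for genotype effects on per-plant traits, and
# the genotype slope-heterogeneity analysis of root length on leaf area with
# Tukey-adjusted pairwise slope comparisons.

#' Pearson correlation matrix across genotype means
#'
#' Correlates every pair of trait columns, returning the coefficient matrix,
#' the matching two-sided p-values (t distribution on n - 2 degrees of
#' freedom) and the pairwise-complete n. Zero-variance traits yield `NA`
#' entries rather than errors.
#'
#' @param trait_table Data frame of one row per genotype; non-numeric columns
#'   (e.g. a genotype id) are ignored.
#' @return An object of class `"correlation_matrix"`: list with matrices `r`,
#'   `p`, `n` and the trait names.
#' @export
pearson_matrix <- function(trait_table) {
  num <- trait_table[vapply(trait_table, is.numeric, logical(1))]
  if (ncol(num) < 2) stop("need at least two numeric traits", call. = FALSE)
  if (nrow(num) < 3) stop("need at least 3 genotypes", call. = FALSE)
  traits <- names(num)
  k <- length(traits)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      xi <- num[[i]]; xj <- num[[j]]
      keep <- is.finite(xi) & is.finite(xj)
      m <- sum(keep)
      n[i, j] <- m
      if (i == j) {
        r[i, j] <- 1
        p[i, j] <- 1
        next
      }
      if (m < 3 || stats::sd(xi[keep]) == 0 || stats::sd(xj[keep]) == 0) next
      ct <- stats::cor.test(xi[keep], xj[keep], method = "pearson")
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  structure(list(r = r, p = p, n = n, traits = traits),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("Pearson correlation matrix (%d traits)\n", length(x$traits)))
  cat("r (lower triangle) / p (upper triangle):\n")
  m <- x$r
  m[upper.tri(m)] <- x$p[upper.tri(x$p)]
  print(round(m, digits))
  invisible(x)
}

#' One-way ANOVA for a genotype effect
#'
#' Standard between/within sums-of-squares decomposition with the F test. The
#' degenerate all-identical case is handled (F = 0, p = 1) rather than
#' erroring.
#'
#' @param values Per-plant trait values.
#' @param groups Group (genotype) labels, same length.
#' @param trait Optional trait name carried into the output.
#' @return One-row tibble with `trait`, `f_statistic`, `df_between`,
#'   `df_within`, `p_value`, `ss_between`, `ss_within`.
#' @export
one_way_anova <- function(values, groups, trait = NA_character_) {
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (length(values) <= nlevels(groups)) {
    stop("need replication within at least one group", call. = FALSE)
  }
  gm <- tapply(values, groups, mean)
  gn <- tapply(values, groups, length)
  ss_between <- sum(gn * (gm - mean(values))^2)
  ss_within <- sum((values - gm[groups])^2)
  df_b <- nlevels(groups) - 1L
  df_w <- length(values) - nlevels(groups)
  f <- if (ss_within == 0 && ss_between == 0) {
    0
  } else if (ss_within == 0) {
    Inf
  } else {
    (ss_between / df_b) / (ss_within / df_w)
  }
  p <- if (is.infinite(f)) 0 else if (f == 0 && ss_between == 0) 1 else {
    stats::pf(f, df_b, df_w, lower.tail = FALSE)
  }
  tibble::tibble(trait = trait, f_statistic = f, df_between = df_b,
                 df_within = df_w, p_value = p,
                 ss_between = ss_between, ss_within = ss_within)
}

#' Genotype heterogeneity in root-on-leaf allometric slopes
#'
#' Fits `ln(root length) ~ ln(leaf area) * genotype` on genotype x day means
#' of the non-destructive measurements and asks whether the genotypes share a
#' slope: it reports per-genotype slopes with standard errors, the interaction
#' F-test p-value, and Tukey-adjusted (alongside unadjusted) pairwise slope
#' differences via the studentized range on the model's residual degrees of
#' freedom.
#'
#' @param means Tibble of genotype x day means with columns `genotype`,
#'   `day`, `leaf_area` and `root_length` (both positive). Genotypes with
#'   fewer than 3 points are excluded with a warning.
#' @return A list of class `"slope_comparison"`: `slopes` (tibble of
#'   `genotype`, `slope`, `se`, `n_points`), `interaction_p`,
#'   `pairwise` (tibble of `contrast`, `estimate`, `se`, `p_tukey`,
#'   `p_unadjusted`), and the symmetric `p_matrix` of Tukey-adjusted p-values.
#' @export
slope_heterogeneity <- function(means) {
  need <- c("genotype", "day", "leaf_area", "root_length")
  if (!all(need %in% names(means))) {
    stop("means must have columns genotype, day, leaf_area, root_length",
         call. = FALSE)
  }
  if (any(means$leaf_area <= 0) || any(means$root_length <= 0)) {
    stop("leaf areas and root lengths must be positive for the log model",
         call. = FALSE)
  }
  counts <- table(means$genotype)
  drop <- names(counts)[counts < 3]
  if (length(drop) > 0) {
    warning(sprintf("excluding genotypes with < 3 points: %s",
                    paste(drop, collapse = ", ")))
    means <- means[!means$genotype %in% drop, ]
  }
  if (length(unique(means$genotype)) < 2) {
    stop("need at least 2 genotypes with >= 3 points", call. = FALSE)
  }
  d <- data.frame(
    ln_leaf = log(means$leaf_area),
    ln_root = log(means$root_length),
    genotype = factor(means$genotype)
  )
  fit <- stats::lm(ln_root ~ ln_leaf * genotype, data = d)
  an <- stats::anova(fit)
  interaction_p <- an["ln_leaf:genotype", "Pr(>F)"]

  tr <- emmeans::emtrends(fit, "genotype", var = "ln_leaf")
  tr_df <- as.data.frame(tr)
  slopes <- tibble::tibble(
    genotype = as.character(tr_df$genotype),
    slope = tr_df$ln_leaf.trend,
    se = tr_df$SE,
    n_points = as.integer(counts[as.character(tr_df$genotype)])
  )
  pw_tukey <- as.data.frame(emmeans::contrast(tr, method = "pairwise",
                                              adjust = "tukey"))
  pw_none <- as.data.frame(emmeans::contrast(tr, method = "pairwise",
                                             adjust = "none"))
  pairwise <- tibble::tibble(
    contrast = as.character(pw_tukey$contrast),
    estimate = pw_tukey$estimate,
    se = pw_tukey$SE,
    p_tukey = pw_tukey$p.value,
    p_unadjusted = pw_none$p.value[match(pw_tukey$contrast, pw_none$contrast)]
  )
  gn <- slopes$genotype
  p_matrix <- matrix(NA_real_, length(gn), length(gn),
                     dimnames = list(gn, gn))
  diag(p_matrix) <- 1
  for (k in seq_len(nrow(pairwise))) {
    pair <- strsplit(pairwise$contrast[k], " - ", fixed = TRUE)[[1]]
    # emmeans quotes levels containing special characters
    pair <- gsub("^\\(|\\)$", "", pair)
    p_matrix[pair[1], pair[2]] <- pairwise$p_tukey[k]
    p_matrix[pair[2], pair[1]] <- pairwise$p_tukey[k]
  }
  structure(list(slopes = slopes, interaction_p = interaction_p,
                 pairwise = pairwise, p_matrix = p_matrix,
                 residual_df = fit$df.residual),
            class = "slope_comparison")
}

#' @export
print.slope_comparison <- function(x, ...) {
  cat("Genotype slope heterogeneity: ln(root length) ~ ln(leaf area)\n")
  cat(sprintf("  interaction p = %.4g (residual df = %d)\n",
              x$interaction_p, x$residual_df))
  print(as.data.frame(x$slopes), row.names = FALSE)
  invisible(x)
}

#' Genotype x day means of leaf area and visible root length
#'
#' Convenience builder of the input [slope_heterogeneity()] expects: the
#' genotype x day means of non-destructively measured total leaf area (from
#' leaf dimensions) and visible total root length, restricted to the days on
#' which leaves were measured.
#'
#' @param experiment A `"rhizobox_experiment"`.
#' @param days Days to include (default: all days with leaf measurements).
#' @param shape_factor Leaf shape factor.
#' @return Tibble with `genotype`, `day`, `leaf_area`, `root_length`.
#' @export
leaf_root_means <- function(experiment, days = NULL,
                            shape_factor = WHEAT_SHAPE_FACTOR) {
  stopifnot(inherits(experiment, "rhizobox_experiment"))
  pla <- plant_leaf_area(experiment$longitudinal, shape_factor)
  if (is.null(days)) days <- sort(unique(pla$day))
  pla <- pla[pla$day %in% days, ]
  root <- experiment$longitudinal[
    experiment$longitudinal$trait == "visible_total_root_len_cm" &
      experiment$longitudinal$day %in% days,
    c("plant_id", "day", "value")
  ]
  names(root)[3] <- "root_length"
  d <- dplyr::inner_join(pla, root, by = c("plant_id", "day")) |>
    dplyr::inner_join(experiment$plants[, c("plant_id", "genotype")],
                      by = "plant_id")
  d |>
    dplyr::group_by(.data$genotype, .data$day) |>
    dplyr::summarise(leaf_area = mean(.data$total_leaf_area_cm2),
                     root_length = mean(.data$root_length),
                     .groups = "drop")
}
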