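test_that("the correlation matrix has unit diagonal, symmetry and bounded r", {
  set.seed(12)
  tbl <- tibble::tibble(genotype = sprintf("G%d", 1:9),
                        a = rnorm(9), b = rnorm(9), c = rnorm(9))
  tbl$d <- -tbl$a
  cm <- pearson_matrix(tbl)
  expect_equal(unname(diag(cm$r)), rep(1, 4))
  expect_identical(cm$r, t(cm$r))
  expect_identical(cm$p, t(cm$p))
  expect_true(all(cm$r >= -1 & cm$r <= 1))
  expect_true(all(cm$p > 0 & cm$p <= 1))
  expect_equal(cm$r["a", "d"], -1, tolerance = 1e-12)
  # positive semidefinite on complete data
  expect_true(all(eigen(cm$r, symmetric = TRUE)$values > -1e-10))
})

test_that("correlations and p-values match the direct-formula oracle", {
  set.seed(13)
  for (k in 1:20) {
    tbl <- as.data.frame(matrix(rnorm(9 * 5), 9, 5))
    cm <- pearson_matrix(tbl)
    for (i in 1:4) {
      for (j in (i + 1):5) {
        o <- oracle_pearson(tbl[[i]], tbl[[j]])
        expect_equal(cm$r[i, j], o$r, tolerance = 1e-8)
        expect_equal(cm$p[i, j], o$p, tolerance = 1e-8)
      }
    }
  }
})

test_that("a zero-variance trait yields NA correlations, not an error", {
  tbl <- tibble::tibble(a = rnorm(9), b = rep(2, 9))
  cm <- pearson_matrix(tbl)
  expect_true(is.na(cm$r["a", "b"]))
  expect_equal(cm$r["b", "b"], 1) # the diagonal is defined by convention
})

test_that("one-way ANOVA reduces to the squared pooled t for two groups", {
  set.seed(14)
  v <- rnorm(12)
  g <- rep(c("A", "B"), each = 6)
  an <- one_way_anova(v, g)
  tt <- stats::t.test(v ~ g, var.equal = TRUE)
  expect_equal(an$f_statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(an$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("ANOVA handles equal means, identical values and matches the SS oracle", {
  # equal group means, positive within-variance: F small, p large
  v <- c(1, 3, 1, 3, 1, 3)
  g <- rep(c("A", "B", "C"), each = 2)
  an <- one_way_anova(v, g)
  expect_equal(an$f_statistic, 0)
  expect_gte(an$p_value, 0.99)
  # all values identical
  an0 <- one_way_anova(rep(5, 10), rep(c("A", "B"), 5))
  expect_equal(an0$f_statistic, 0)
  expect_equal(an0$p_value, 1)
  # SS decomposition is exact and F/p match the oracle on random draws
  set.seed(15)
  for (k in 1:20) {
    v <- rnorm(72, mean = rep(rnorm(9), each = 8))
    g <- rep(sprintf("G%d", 1:9), each = 8)
    an <- one_way_anova(v, g)
    o <- oracle_anova(v, g)
    expect_equal(an$f_statistic, o$f, tolerance = 1e-8)
    expect_equal(an$p_value, o$p, tolerance = 1e-8)
    total_ss <- sum((v - mean(v))^2)
    expect_equal(an$ss_between + an$ss_within, total_ss, tolerance = 1e-10)
    # cross-check against the linear-model F test
    lm_f <- stats::anova(stats::lm(v ~ g))
    expect_equal(an$f_statistic, lm_f[1, "F value"], tolerance = 1e-8)
  }
})

test_that("slope heterogeneity recovers exact slope differences without noise", {
  days <- c(7, 11, 14, 18)
  leaf <- exp(seq(2, 4, length.out = 4))
  means <- tibble::tibble(
    genotype = rep(c("A", "B"), each = 4),
    day = rep(days, 2),
    leaf_area = rep(leaf, 2),
    root_length = c(exp(1 * log(leaf)), exp(2 * log(leaf) + 0.3))
  )
  sc <- slope_heterogeneity(means)
  expect_equal(sort(sc$slopes$slope), c(1, 2), tolerance = 1e-10)
  expect_equal(abs(sc$pairwise$estimate), 1, tolerance = 1e-10)
  # shared true slope: all pairwise differences are zero
  means2 <- means
  means2$root_length <- rep(exp(1.5 * log(leaf)), 2)
  sc2 <- slope_heterogeneity(means2)
  expect_equal(sc2$pairwise$estimate, 0, tolerance = 1e-10)
})

test_that("Tukey-adjusted slope p-values are never below the unadjusted ones", {
  set.seed(16)
  days <- c(7, 11, 14, 18)
  means <- tidyr::expand_grid(genotype = sprintf("G%d", 1:5), day = days)
  means$leaf_area <- exp(0.3 * means$day + rnorm(nrow(means), sd = 0.05))
  means$root_length <- exp(1.2 * log(means$leaf_area) +
                             rnorm(nrow(means), sd = 0.1))
  sc <- slope_heterogeneity(means)
  expect_true(all(sc$pairwise$p_tukey >= sc$pairwise$p_unadjusted - 1e-12))
  expect_identical(sc$p_matrix, t(sc$p_matrix))
  # a genotype with < 3 points is excluded with a warning
  means_cut <- means[!(means$genotype == "G1" & means$day > 7), ]
  expect_warning(sc_cut <- slope_heterogeneity(means_cut), "G1")
  expect_false("G1" %in% sc_cut$slopes$genotype)
})

test_that("genotype-specific allometric slopes are detected in low-noise simulations", {
  n_rep <- 200
  detected <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    exp <- generate_experiment(
      simulation_config(seed = 5000 + i, measurement_noise_cv = 0.04)
    )
    means <- leaf_root_means(exp)
    detected[i] <- slope_heterogeneity(means)$interaction_p < 0.001
  }
  expect_gte(mean(detected), 0.95)
})
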