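test_that("expected pools reproduce the optimum ratio components", {
  expect_equal(expected_pool(100, "P"), 14.3)
  expect_equal(expected_pool(100, "K"), 68.3)
  expect_equal(expected_pool(100, "Ca"), 8.3)
  expect_equal(expected_pool(100, "Mg"), 8.7)
  expect_equal(expected_pool(0, "P"), 0)
  expect_equal(expected_pool(12, "K"), 8.196, tolerance = 1e-12)
  expect_error(expected_pool(10, "Xx"), "supported")
  # linearity in the N pool
  set.seed(6)
  for (k in 1:20) {
    n <- runif(1, 0, 50); a <- runif(1, 0, 5)
    expect_equal(expected_pool(a * n, "Mg"), a * expected_pool(n, "Mg"),
                 tolerance = 1e-12)
  }
})

test_that("pools from batches use the batch-mean concentration", {
  b <- tibble::tibble(element = c("N", "N"),
                      concentration_mg_per_g = c(40, 44))
  expect_equal(pool_from_batches(b, 300)$pool_mg, 12.6)
  one <- tibble::tibble(element = "P", concentration_mg_per_g = 5)
  expect_equal(pool_from_batches(one, 200)$pool_mg, 1)
  zero <- tibble::tibble(element = "P", concentration_mg_per_g = 0)
  expect_equal(pool_from_batches(zero, 200)$pool_mg, 0)
  expect_error(pool_from_batches(b[0, ], 300), "missing")
})

test_that("ratio evaluation flags pools below their expectation", {
  pools <- tibble::tibble(
    genotype = "G1",
    element = c("N", "P", "K"),
    pool_mg = c(100, 14.3, 0.5 * 68.3)
  )
  ev <- ratio_evaluation(pools)
  expect_equal(ev$obs_over_exp[ev$element == "P"], 1)
  expect_false(ev$suboptimal[ev$element == "P"])
  expect_equal(ev$obs_over_exp[ev$element == "K"], 0.5)
  expect_true(ev$suboptimal[ev$element == "K"])
  # observed/expected is invariant to the biomass (hence pool) unit
  pools_g <- dplyr::mutate(pools, pool_mg = pool_mg / 1000)
  expect_equal(ratio_evaluation(pools_g)$obs_over_exp, ev$obs_over_exp)
  expect_error(ratio_evaluation(pools[pools$element != "N", ]), "N pool")
})

test_that("a planted weak-P genotype is flagged suboptimal and surrogate productivity tracks PNP", {
  n_rep <- 200
  flagged <- logical(n_rep)
  pos_cor <- logical(n_rep)
  mult <- list(P = c(0.7, rep(1, 8))) # genotype 1: true P ratio 0.7 x optimum
  for (i in seq_len(n_rep)) {
    exp <- generate_experiment(
      simulation_config(seed = 3000 + i, genotype_ratio_multipliers = mult)
    )
    pools <- element_pools(exp, day = 20)
    ev <- ratio_evaluation(pools)
    flagged[i] <- ev$suboptimal[ev$genotype == "G01" & ev$element == "P"]
    gs <- growth_summary(exp)
    conc_n <- pools$concentration_mg_per_g[pools$element == "N"]
    names(conc_n) <- pools$genotype[pools$element == "N"]
    pos_cor[i] <- stats::cor(surrogate_productivity(conc_n[gs$genotype]),
                             gs$PNP) > 0
  }
  expect_gte(mean(flagged), 0.95)
  expect_gte(mean(pos_cor), 0.95)
})

test_that("pairwise scaling matches the OLS oracle and handles degeneracy", {
  pools <- tibble::tibble(
    genotype = rep(sprintf("G%d", 1:9), 2),
    element = rep(c("N", "K"), each = 9),
    pool_mg = c(1:9, 2 * (1:9))
  )
  sc <- pairwise_scaling(pools, "N", "K")
  expect_equal(sc$slope, 2, tolerance = 1e-12)
  expect_equal(sc$r_squared, 1, tolerance = 1e-12)
  # constructed orthogonality -> slope 0
  x <- 1:9
  y <- (x - mean(x))^2
  y <- y - sum(y * (x - mean(x))) / sum((x - mean(x))^2) * (x - mean(x))
  pools2 <- tibble::tibble(genotype = rep(sprintf("G%d", 1:9), 2),
                           element = rep(c("N", "Mg"), each = 9),
                           pool_mg = c(x, y))
  expect_equal(pairwise_scaling(pools2, "N", "Mg")$slope, 0, tolerance = 1e-10)
  # random draws against the normal-equations oracle
  set.seed(7)
  for (k in 1:20) {
    xp <- runif(9, 8, 16); yp <- runif(9, 1, 3)
    p3 <- tibble::tibble(genotype = rep(sprintf("G%d", 1:9), 2),
                         element = rep(c("N", "P"), each = 9),
                         pool_mg = c(xp, yp))
    sc3 <- pairwise_scaling(p3, "N", "P")
    o <- oracle_ols(xp, yp)
    expect_equal(sc3$slope, o$slope, tolerance = 1e-8)
    expect_equal(sc3$r_squared, o$r_squared, tolerance = 1e-8)
    expect_equal(sc3$p_value, o$p, tolerance = 1e-8)
  }
  # degenerate variance -> flag, not error
  p4 <- tibble::tibble(genotype = rep(sprintf("G%d", 1:9), 2),
                       element = rep(c("N", "Ca"), each = 9),
                       pool_mg = c(rep(10, 9), runif(9)))
  expect_true(pairwise_scaling(p4, "N", "Ca")$degenerate)
})

test_that("surrogate productivity is the reciprocal concentration", {
  expect_equal(surrogate_productivity(40), 0.025)
  expect_error(surrogate_productivity(0), "positive")
  expect_error(surrogate_productivity(-3), "positive")
})

test_that("the biomass-productivity model recovers an exact log-linear construction", {
  set.seed(8)
  conc_n <- runif(9, 35, 45)
  conc_p <- runif(9, 4, 6)
  a <- 0.97; b <- -2.96; c0 <- -4.60
  biomass <- exp(a * log(1 / conc_p) + b * log(1 / conc_n) + c0)
  pools <- tibble::tibble(
    genotype = rep(sprintf("G%d", 1:9), 2),
    element = rep(c("N", "P"), each = 9),
    concentration_mg_per_g = c(conc_n, conc_p),
    biomass_mg = rep(biomass, 2),
    pool_mg = NA_real_
  )
  fit <- biomass_productivity_model(pools)
  expect_equal(fit$coef_ln_p_prod, a, tolerance = 1e-8)
  expect_equal(fit$coef_ln_n_prod, b, tolerance = 1e-8)
  expect_equal(fit$intercept, c0, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_false(fit$rank_deficient)
  # constant P productivity -> rank deficiency flagged
  pools$concentration_mg_per_g[pools$element == "P"] <- 5
  expect_true(biomass_productivity_model(pools)$rank_deficient)
})

test_that("the biomass-productivity model matches a two-regressor oracle", {
  # oracle: solve the 3x3 normal equations directly
  set.seed(9)
  for (k in 1:10) {
    conc_n <- runif(9, 35, 45); conc_p <- runif(9, 4, 6)
    biomass <- exp(rnorm(9, log(300), 0.2))
    pools <- tibble::tibble(
      genotype = rep(sprintf("G%d", 1:9), 2),
      element = rep(c("N", "P"), each = 9),
      concentration_mg_per_g = c(conc_n, conc_p),
      biomass_mg = rep(biomass, 2), pool_mg = NA_real_
    )
    fit <- biomass_productivity_model(pools)
    X <- cbind(1, log(1 / conc_p), log(1 / conc_n))
    beta <- solve(t(X) %*% X, t(X) %*% log(biomass))
    expect_equal(fit$intercept, beta[1], tolerance = 1e-8)
    expect_equal(fit$coef_ln_p_prod, beta[2], tolerance = 1e-8)
    expect_equal(fit$coef_ln_n_prod, beta[3], tolerance = 1e-8)
  }
})

test_that("niche volumes are products of member concentrations", {
  pools <- tibble::tibble(
    genotype = rep("G1", 3),
    element = c("N", "P", "K"),
    concentration_mg_per_g = c(1, 1, 1),
    pool_mg = NA_real_
  )
  expect_equal(niche_volume(pools, c("N", "P", "K"))$volume, 1)
  pools$concentration_mg_per_g <- c(2, 3, 10)
  expect_equal(niche_volume(pools, c("N", "P"))$volume, 6)
  expect_error(niche_volume(pools, c("N", "Zn")), "missing")
  pools$concentration_mg_per_g[1] <- 0
  expect_error(niche_volume(pools, c("N", "P")), "positive")
})

test_that("niche volume is multiplicative over disjoint element sets and matches a product oracle", {
  set.seed(10)
  els <- c("N", "P", "K", "Ca", "S", "Mg", "Fe", "Zn")
  for (k in 1:20) {
    conc <- runif(length(els), 0.01, 50)
    pools <- tibble::tibble(genotype = "G1", element = els,
                            concentration_mg_per_g = conc, pool_mg = NA_real_)
    expect_equal(niche_volume(pools, els)$volume, prod(conc),
                 tolerance = 1e-10)
    s1 <- els[1:3]; s2 <- els[4:8]
    expect_equal(niche_volume(pools, els)$volume,
                 niche_volume(pools, s1)$volume *
                   niche_volume(pools, s2)$volume,
                 tolerance = 1e-10)
  }
})

test_that("RMA regression has the sd-ratio slope and its symmetry properties", {
  g <- sprintf("G%d", 1:9)
  v_other <- tibble::tibble(genotype = g, volume = exp(seq(0.1, 2, length.out = 9)))
  v_np <- tibble::tibble(genotype = g, volume = v_other$volume^2)
  ex <- niche_scaling_exponent(v_np, v_other)
  expect_equal(ex$exponent, 2, tolerance = 1e-10)
  # axis swap inverts the exponent (same sign)
  ex_inv <- niche_scaling_exponent(v_np, v_other, invert = TRUE)
  expect_equal(ex_inv$exponent, 1 / ex$exponent, tolerance = 1e-10)
  set.seed(11)
  for (k in 1:30) {
    x <- rnorm(9); y <- 0.5 * x + rnorm(9, sd = 0.6)
    fit <- rma_regression(x, y)
    expect_equal(fit$slope, oracle_rma(x, y), tolerance = 1e-10)
    expect_equal(abs(fit$slope), stats::sd(y) / stats::sd(x),
                 tolerance = 1e-10)
    expect_equal(sign(fit$slope), sign(stats::cor(x, y)))
    # |RMA slope| >= |OLS slope|, equality iff |r| = 1
    expect_gte(abs(fit$slope), abs(oracle_ols(x, y)$slope) - 1e-12)
  }
  expect_true(rma_regression(rep(1, 5), rnorm(5))$degenerate)
})
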