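test_that("rgr is the per-day log-biomass difference", {
  iv <- interval_summary(0, 20, mean_lnW1 = 1, mean_lnW2 = 3)
  expect_equal(rgr(iv), 0.1)
  expect_equal(rgr(interval_summary(1, 5, mean_lnW1 = 2, mean_lnW2 = 2)), 0)
  expect_error(interval_summary(5, 5), "t2 must exceed t1")
  # unit invariance: mg -> g shifts both log means equally
  iv_g <- interval_summary(0, 20, mean_lnW1 = 1 - log(1000),
                           mean_lnW2 = 3 - log(1000))
  expect_equal(rgr(iv_g), rgr(iv))
})

test_that("relative N accumulation rate is the log-rate of the N pool", {
  iv <- interval_summary(0, log(2) / 0.1, mean_Np1 = 4, mean_Np2 = 8)
  expect_equal(nar_n(iv), 0.1, tolerance = 1e-12)
  expect_equal(nar_n(interval_summary(0, 5, mean_Np1 = 3, mean_Np2 = 3)), 0)
  expect_error(nar_n(interval_summary(0, 5, mean_Np1 = -1, mean_Np2 = 3)),
               "positive")
})

test_that("lap follows the classical unit-leaf-rate formula", {
  iv <- interval_summary(7, 20, mean_lnW1 = log(100), mean_lnW2 = log(300),
                         mean_A1 = 10, mean_A2 = 30)
  expect_equal(lap(iv), 200 * log(3) / (20 * 13), tolerance = 1e-12)
  # no biomass change -> zero productivity
  iv0 <- interval_summary(7, 20, mean_lnW1 = log(100), mean_lnW2 = log(100),
                          mean_A1 = 10, mean_A2 = 30)
  expect_equal(lap(iv0), 0)
  # constant area degenerates unless the limit form is requested
  ivc <- interval_summary(0, 10, mean_lnW1 = log(100), mean_lnW2 = log(200),
                          mean_A1 = 20, mean_A2 = 20)
  expect_error(lap(ivc), "degenerate")
  expect_equal(lap(ivc, allow_limit = TRUE), 100 / (20 * 10))
})

test_that("pnp follows the unit formula and pnc closes the identity", {
  iv <- interval_summary(1, 20, mean_lnW1 = log(100), mean_lnW2 = log(300),
                         mean_Np1 = 4, mean_Np2 = 12)
  r <- rgr(iv)
  out <- pnp_pnc(iv, r)
  expect_equal(out$pnp, 200 * log(3) / (8 * 19), tolerance = 1e-12)
  expect_equal(out$pnc * out$pnp, r, tolerance = 1e-12)
})

test_that("both decomposition identities hold on 1000 random intervals", {
  set.seed(4)
  for (k in 1:1000) {
    iv <- random_interval()
    r <- rgr(iv)
    lr <- lar(iv, r)
    expect_equal(lr$lar * lap(iv), r, tolerance = 1e-12)
    np <- pnp_pnc(iv, r)
    expect_equal(np$pnc * np$pnp, r, tolerance = 1e-12)
  }
})

test_that("noise-free constant-LAR constant-PNC simulation is recovered exactly", {
  exp <- generate_experiment(noise_free_config(seed = 21))
  truth <- truth_table(exp)
  gs <- growth_summary(exp)
  stopifnot(identical(gs$genotype, truth$genotype))
  rel <- function(est, tru) max(abs(est - tru) / abs(tru))
  expect_lt(rel(gs$RGR, truth$rgr), 1e-10)
  expect_lt(rel(gs$RGR_matched, truth$rgr), 1e-10)
  expect_lt(rel(gs$LAR, truth$lar), 1e-10)
  expect_lt(rel(gs$LAP, truth$rgr / truth$lar), 1e-10)
  expect_lt(rel(gs$PNC, truth$pnc), 1e-10)
  expect_lt(rel(gs$PNP, truth$rgr / truth$pnc), 1e-10)
  expect_lt(rel(gs$NAR_N, gs$RGR), 1e-10) # N tracks biomass exactly
})

test_that("with drifting LAR the enforced LAR lies between the endpoint ratios", {
  exp <- generate_experiment(noise_free_config(seed = 22, lar_drift = 0.003))
  gs <- growth_summary(exp)
  lo <- pmin(gs$area_ratio_t1, gs$area_ratio_t2)
  hi <- pmax(gs$area_ratio_t1, gs$area_ratio_t2)
  expect_true(all(gs$LAR >= lo - 1e-12 & gs$LAR <= hi + 1e-12))
})

test_that("driver regressions detect exact and absent linear structure", {
  gs <- tibble::tibble(
    genotype = sprintf("G%d", 1:9),
    RGR = seq(0.09, 0.11, length.out = 9)
  )
  gs$LAP <- 2 * gs$RGR + 0.01          # exactly linear
  gs$LAR <- rep(0.2, 9)                # constant -> undefined regression
  x <- seq(-4, 4, length.out = 9)
  gs$PNC <- (x - mean(x))^2 # even in x, hence orthogonal to the linear RGR
  gs$PNP <- rnorm(9)
  gs$NAR_N <- gs$RGR
  dr <- driver_regressions(gs)
  lap_row <- dr[dr$component == "LAP", ]
  expect_equal(lap_row$r_squared, 1, tolerance = 1e-9)
  expect_lt(lap_row$p_value, 1e-9)
  expect_true(dr$degenerate[dr$component == "LAR"])
  expect_equal(dr$slope[dr$component == "PNC"], 0, tolerance = 1e-9)
})

test_that("driver regressions match the normal-equations oracle on random draws", {
  set.seed(5)
  for (k in 1:20) {
    gs <- tibble::tibble(
      genotype = sprintf("G%d", 1:9),
      RGR = runif(9, 0.08, 0.12),
      LAP = runif(9, 0.3, 0.7), LAR = runif(9, 0.1, 0.3),
      PNC = runif(9, 0.03, 0.05), PNP = runif(9, 1, 3),
      NAR_N = runif(9, 0.08, 0.12)
    )
    dr <- driver_regressions(gs)
    for (comp in dr$component) {
      o <- oracle_ols(gs[[comp]], gs$RGR)
      row <- dr[dr$component == comp, ]
      expect_equal(row$slope, o$slope, tolerance = 1e-8)
      expect_equal(row$r_squared, o$r_squared, tolerance = 1e-8)
      expect_equal(row$adj_r_squared, o$adj_r_squared, tolerance = 1e-8)
      expect_equal(row$p_value, o$p, tolerance = 1e-8)
    }
  }
})
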