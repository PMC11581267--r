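test_that("constant covariates leave the malnourished share unchanged", {
  path <- constant_nutrition(horizon = 25, pmc0 = 20, popc = 5e6)
  res <- project_malnutrition(path)
  expect_true(all(res$pmc_by_year == 20))
  expect_true(all(res$mc_by_year == 1e6))
})

test_that("a one-step calorie rise moves the share by the elasticity", {
  # +1% kcal at year 2: dPMC = -25.24 * ln(1.01)
  path <- nutrition_path(c(2000, 2020), c(1.05, 1.05), c(35, 35),
                         c(0.6, 0.6), c(5e6, 5e6), pmc0 = 20)
  res <- project_malnutrition(path)
  expect_equal(res$pmc_by_year[1], 20)
  expect_equal(res$pmc_by_year[2], 20 - 25.24 * log(1.01),
               tolerance = 1e-12)
  expect_equal(20 - res$pmc_by_year[2], 0.2512, tolerance = 1e-3)
})

test_that("each covariate contributes its coefficient times its change", {
  coefs <- nutrition_coefficients(warn_water = FALSE)
  base <- list(kcal = c(2000, 2000), lf = c(1.05, 1.06), schl = c(35, 40),
               water = c(0.6, 0.6))
  path <- nutrition_path(base$kcal, base$lf, base$schl, base$water,
                         c(1e6, 1e6), pmc0 = 50)
  res <- project_malnutrition(path, coefs)
  expect_equal(res$pmc_by_year[2],
               50 + (-71.755094) * 0.01 + (-0.219831) * 5,
               tolerance = 1e-9)
  # water term defaults to zero coefficient
  path_w <- nutrition_path(c(2000, 2000), c(1.05, 1.05), c(35, 35),
                           c(0.6, 0.9), c(1e6, 1e6), pmc0 = 50)
  expect_equal(project_malnutrition(path_w, coefs)$pmc_by_year[2], 50)
  # a supplied water coefficient takes effect
  coefs_w <- nutrition_coefficients(water_coef = -10)
  expect_equal(project_malnutrition(path_w, coefs_w)$pmc_by_year[2],
               50 - 10 * 0.3)
})

test_that("share is clamped to [0, 100] under extreme covariate swings", {
  up <- nutrition_path(c(2000, 200), rep(1.05, 2), rep(35, 2),
                       rep(0.6, 2), rep(1e6, 2), pmc0 = 95)
  down <- nutrition_path(c(2000, 20000), rep(1.05, 2), rep(35, 2),
                         rep(0.6, 2), rep(1e6, 2), pmc0 = 5)
  expect_equal(project_malnutrition(up)$pmc_by_year[2], 100)
  expect_equal(project_malnutrition(down)$pmc_by_year[2], 0)
})

test_that("projection depends only on kcal ratios, not its scale", {
  set.seed(11)
  kcal <- 2000 * exp(cumsum(rnorm(10, 0, 0.02)))
  mk <- function(k) nutrition_path(k, rep(1.05, 10), rep(35, 10),
                                   rep(0.6, 10), rep(1e6, 10), pmc0 = 30)
  expect_equal(project_malnutrition(mk(kcal))$pmc_by_year,
               project_malnutrition(mk(3.7 * kcal))$pmc_by_year,
               tolerance = 1e-12)
})

test_that("pointwise-higher calories never raise the malnourished share", {
  # both paths measured against the same pre-path calorie reference
  set.seed(5)
  for (rep_i in 1:5) {
    base_kcal <- 2000 + cumsum(rnorm(15, 0, 30))
    base_kcal <- pmax(base_kcal, 500)
    lift <- runif(15, 0, 100)
    mk <- function(k) nutrition_path(k, rep(1.05, 15), rep(35, 15),
                                     rep(0.6, 15), rep(1e6, 15), pmc0 = 40,
                                     pckcal0 = 2000)
    pmc_base <- project_malnutrition(mk(base_kcal))$pmc_by_year
    pmc_hi <- project_malnutrition(mk(base_kcal + lift))$pmc_by_year
    expect_true(all(pmc_hi <= pmc_base + 1e-12))
  }
})

test_that("production-to-kcal linkage does plain unit arithmetic", {
  base <- rep(2300, 5)
  expect_equal(kcal_shift_from_production(0, 3.5e6, 1e6, base), base)
  # 365 million kcal over a million people is +1 kcal/cap/day
  expect_equal(kcal_shift_from_production(365, 1e6, 1e6, base), base + 1)
  one <- kcal_shift_from_production(100, 3.5e6, 1e6, base) - base
  two <- kcal_shift_from_production(200, 3.5e6, 1e6, base) - base
  expect_equal(two, 2 * one)
  expect_error(kcal_shift_from_production(100, 3.5e6, 0, base),
               "population")
})

test_that("scenario-minus-baseline difference behaves and checks horizons", {
  path <- constant_nutrition(10)
  res <- project_malnutrition(path)
  expect_equal(delta_malnourished(res, res, 10), 0)
  short <- project_malnutrition(constant_nutrition(5))
  expect_error(delta_malnourished(res, short, 5), "horizons differ")
  # two-year toy case evaluated by hand: kcal 2000 -> 2100 in the scenario
  base2 <- nutrition_path(c(2000, 2000), rep(1.05, 2), rep(35, 2),
                          rep(0.6, 2), rep(2e6, 2), pmc0 = 30)
  scen2 <- nutrition_path(c(2000, 2100), rep(1.05, 2), rep(35, 2),
                          rep(0.6, 2), rep(2e6, 2), pmc0 = 30)
  d <- delta_malnourished(project_malnutrition(base2),
                          project_malnutrition(scen2), 2)
  expect_equal(d, 2e6 * (-25.24 * log(2100 / 2000)) / 100,
               tolerance = 1e-9)
  expect_lt(d, 0)
})

test_that("technology nutrition outcome improves nutrition for a yield gain", {
  p <- cowpea_exemplar()
  macro <- toy_macro(toy_country())
  path <- build_adoption_path(p)
  out <- nutrition_outcome(p, macro, path, constant_nutrition(25), 3e7)
  expect_lt(out$delta_mc_at_T, 0)
  expect_equal(out$eval_year, 10)
})

test_that("invalid paths and coefficients are rejected", {
  expect_error(nutrition_path(c(2000, -5), rep(1, 2), rep(1, 2),
                              rep(1, 2), rep(1, 2), 20), "pckcal")
  expect_error(nutrition_path(rep(2000, 3), rep(1, 2), rep(1, 3),
                              rep(1, 3), rep(1, 3), 20), "equal length")
  expect_error(nutrition_coefficients(kcal_elasticity = 2,
                                      warn_water = FALSE), "negative")
  expect_warning(nutrition_coefficients(), "water_coef")
})
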