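test_that("a structurally null predictor's CI covers zero at the nominal rate", {
  # bone fully decoupled from muscle: the population coefficient of the
  # baseline muscle predictor on BMD change is exactly zero
  set.seed(80)
  cover <- replicate(120, {
    cfg <- quiet_config(1200, seed = sample.int(2^30, 1),
                        beta_MB = c(0, 0, 0), gamma_MB = c(0, 0),
                        gamma_BM = c(0, 0))
    ds <- build_analysis_dataset(simulate_cohort(cfg))
    cm <- change_model(ds, "V0_leg_LM", "leg_BMD", c("V3", "V5"),
                       covariates = c("age", "height", "grip"))
    cm$conf.low <= 0 && cm$conf.high >= 0
  })
  mc <- 3 * sqrt(0.05 * 0.95 / 120)
  expect_gt(mean(cover), 0.95 - mc)
  expect_lt(mean(cover), pmin(1, 0.95 + mc))
})

test_that("a constant outcome yields a zero coefficient", {
  set.seed(81)
  d <- tibble::tibble(
    id = paste0("p", 1:50),
    V0_leg_LM = rnorm(50, 10),
    V3_leg_BMD = rnorm(50, 1.4, 0.1)
  )
  d$V5_leg_BMD <- d$V3_leg_BMD # change identically zero
  cm <- change_model(d, "V0_leg_LM", "leg_BMD", c("V3", "V5"),
                     covariates = character())
  expect_equal(cm$estimate, 0, tolerance = 1e-12)
})

test_that("baseline-outcome adjustment attenuates the predictor coefficient", {
  # a setting whose baseline-muscle association with later BMD change flows
  # entirely through the window-start BMD (no late contemporaneous path),
  # so conditioning on that value ablates it -- the published pattern
  cfg <- quiet_config(6000, seed = 82,
                      beta_MB = c(0.0316, 0.01, 0), gamma_MB = c(0.0093, 0),
                      rho_bone = 0.9)
  ds <- build_analysis_dataset(simulate_cohort(cfg))
  covs <- c("age", "height", "grip")
  un <- change_model(ds, "V0_leg_LM", "leg_BMD", c("V3", "V5"),
                     covariates = covs)
  ad <- change_model(ds, "V0_leg_LM", "leg_BMD", c("V3", "V5"),
                     adjust_for_baseline_outcome = TRUE, covariates = covs)
  expect_lt(abs(ad$estimate), abs(un$estimate))
  # the analytic (population) slopes show the same ablation
  S <- implied_population_cov(cfg, "leg")$sigma
  dvec <- S["V5_leg_BMD", ] - S["V3_leg_BMD", ]
  un_pop <- dvec["V0_leg_LM"] / S["V0_leg_LM", "V0_leg_LM"]
  X <- c("V0_leg_LM", "V3_leg_BMD")
  ad_pop <- solve(S[X, X], dvec[X])[1]
  expect_lt(abs(ad_pop), abs(un_pop) / 10)
})

test_that("collinear designs raise an explicit error naming the column", {
  ds <- build_analysis_dataset(simulate_cohort(quiet_config(200, seed = 83)))
  ds$dup <- ds$age
  expect_error(
    change_model(ds, "V0_leg_LM", "leg_BMD", c("V3", "V5"),
                 covariates = c("age", "dup")),
    "Collinear"
  )
})

test_that("change on its own baseline recovers the autoregressive-minus-one slope", {
  cfg <- nocov_config(20000, seed = 84)
  ds <- build_analysis_dataset(simulate_cohort(cfg))
  cm <- change_model(ds, "V3_leg_BMD", "leg_BMD", c("V3", "V5"),
                     covariates = character())
  # analytic slope from the generative covariance:
  # cov(B5 - B3, B3) / var(B3) = r * sd5/sd3 - 1
  S <- implied_population_cov(cfg, "leg")$sigma
  slope <- S["V3_leg_BMD", "V5_leg_BMD"] / S["V3_leg_BMD", "V3_leg_BMD"] - 1
  r <- S["V3_leg_BMD", "V5_leg_BMD"] /
    sqrt(S["V3_leg_BMD", "V3_leg_BMD"] * S["V5_leg_BMD", "V5_leg_BMD"])
  sd_ratio <- sqrt(S["V5_leg_BMD", "V5_leg_BMD"] / S["V3_leg_BMD", "V3_leg_BMD"])
  expect_equal(slope, r * sd_ratio - 1, tolerance = 1e-12)
  halfwidth <- (cm$conf.high - cm$conf.low) / 2
  expect_lt(abs(cm$estimate - slope), 1.6 * halfwidth)
})

test_that("the timing artifact induces an association only for the window-start predictor", {
  cfg <- induced_association_config(n_participants = 20000, seed = 85)
  res <- induced_association_experiment(cfg)
  v0 <- res[res$predictor == "V0_leg_LM", ]
  v3 <- res[res$predictor == "V3_leg_LM", ]
  # analytic oracle from the generative covariance
  S <- implied_population_cov(cfg, "leg")$sigma
  slope_of <- function(pred) {
    (S["V5_leg_BMD", pred] - S["V3_leg_BMD", pred]) / S[pred, pred]
  }
  expect_equal(slope_of("V0_leg_LM"), 0, tolerance = 1e-12)
  expect_equal(slope_of("V3_leg_LM"),
               (cfg$rho_bone - 1) * cfg$beta_MB[2], tolerance = 1e-10)
  # fitted: baseline predictor null, window-start predictor significant
  expect_true(v0$conf.low <= 0 && v0$conf.high >= 0)
  expect_true(v3$conf.high < 0)
  expect_lt(v3$p.value, 1e-6)
  # fitted slopes sit on the analytic values
  expect_lt(abs(v3$estimate - slope_of("V3_leg_LM")),
            (v3$conf.high - v3$conf.low))
})

test_that("a fully null contemporaneous structure leaves both predictors null", {
  cfg <- induced_association_config(n_participants = 8000, seed = 90,
                                    beta_v3 = 0)
  res <- induced_association_experiment(cfg)
  expect_true(all(res$conf.low <= 0 & res$conf.high >= 0))
})

test_that("the induced association grows with the contemporaneous coefficient", {
  slopes <- vapply(c(0.01, 0.03, 0.05), function(b) {
    S <- implied_population_cov(induced_association_config(beta_v3 = b),
                                "leg")$sigma
    abs((S["V5_leg_BMD", "V3_leg_LM"] - S["V3_leg_BMD", "V3_leg_LM"]) /
          S["V3_leg_LM", "V3_leg_LM"])
  }, numeric(1))
  expect_true(all(diff(slopes) > 0))
  # one fitted point verifies the middle of the grid
  res <- induced_association_experiment(
    induced_association_config(n_participants = 10000, seed = 87,
                               beta_v3 = 0.03)
  )
  v3 <- res[res$predictor == "V3_leg_LM", ]
  expect_lt(abs(abs(v3$estimate) - slopes[2]), 3 * (v3$conf.high - v3$conf.low) / 3.92)
})

test_that("constraint-validity correlations meet their thresholds on calibrated data", {
  ds <- build_analysis_dataset(simulate_cohort(quiet_config(3000, seed = 88)))
  for (m in c("leg_LM", "leg_BMD", "arm_LM", "arm_BMD")) {
    v <- validate_constraints(ds, m)
    expect_equal(nrow(v), 2L)
    # at cohort calibration every lag clears the 0.80 fallback and at least
    # one clears 0.90 (the late bone window widens with its growing SD)
    expect_true(all(v$pass_fallback))
    expect_true(any(v$pass_threshold))
    expect_lt(max(v$p.value), 1e-10)
  }
})

test_that("a high-autoregression, low-noise process clears the 0.90 threshold", {
  # attenuation oracle: with pure AR dynamics, r(V0,V3) = rho * sd0 / sd3
  # with sd3^2 = rho^2 sd0^2 + psi^2
  cfg <- quiet_config(4000, seed = 89,
                      rho_muscle = 0.95, rho_bone = 0.95,
                      beta_MB = c(0, 0, 0), gamma_MB = c(0, 0),
                      gamma_BM = c(0, 0),
                      covariate_effects_muscle = c(age = 0),
                      covariate_effects_bone = c(age = 0),
                      disturbance_sd = c(
                        V0_leg_LM = 1.5, V0_leg_BMD = 0.14,
                        V0_arm_LM = 0.75, V0_arm_BMD = 0.08,
                        V3_leg_LM = 0.3, V3_leg_BMD = 0.02,
                        V3_arm_LM = 0.15, V3_arm_BMD = 0.012,
                        V5_leg_LM = 0.3, V5_leg_BMD = 0.02,
                        V5_arm_LM = 0.15, V5_arm_BMD = 0.012
                      ))
  ds <- build_analysis_dataset(simulate_cohort(cfg))
  r_oracle <- 0.95 * 1.5 / sqrt(0.95^2 * 1.5^2 + 0.3^2)
  v <- validate_constraints(ds, "leg_LM")
  expect_gt(r_oracle, 0.90)
  expect_lt(abs(v$r[1] - r_oracle), 4 / sqrt(nrow(ds)))
  expect_true(all(v$pass_threshold))
})

test_that("degenerate correlation inputs behave as specified", {
  d <- tibble::tibble(id = paste0("p", 1:30),
                      V0_x = rnorm(30), V3_x = NA_real_, V5_x = rnorm(30))
  d$V3_x <- d$V0_x # identical columns correlate at 1
  v <- validate_constraints(d, "x")
  expect_equal(v$r[1], 1)
  set.seed(89)
  d2 <- tibble::tibble(id = paste0("p", 1:2000), V0_x = rnorm(2000),
                       V3_x = rnorm(2000), V5_x = rnorm(2000))
  v2 <- validate_constraints(d2, "x")
  expect_lt(max(abs(v2$r)), 0.1)
  expect_false(any(v2$pass_threshold))
  d3 <- tibble::tibble(id = c("a", "b"), V0_x = c(1, 1), V3_x = c(1, 2),
                       V5_x = c(1, 3))
  expect_error(validate_constraints(d3, "x"), "zero variance")
})
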