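test_that("implied covariance matches closed forms on small graphs", {
  sp <- two_var_spec()
  sig <- implied_covariance(sp, c(a = 0.6, vx = 2, vy = 1.5))
  expect_equal(sig["x", "y"], 0.6 * 2)
  expect_equal(sig["y", "y"], 0.6^2 * 2 + 1.5)
  # chain x -> m -> y: cov(x, y) = a * b * var(x)
  chain <- path_spec(
    c("x", "m", "y"),
    data.frame(src = c("x", "m", "x", "m", "y"), dst = c("m", "y", "x", "m", "y"),
               type = c("directed", "directed", rep("bidirected", 3)),
               label = c("a", "b", "vx", "vm", "vy"), value = NA)
  )
  sig <- implied_covariance(chain, c(a = 0.5, b = -0.4, vx = 2, vm = 1, vy = 1))
  expect_equal(sig["x", "y"], 0.5 * -0.4 * 2)
})

test_that("implied covariance equals the Wright path-tracing oracle", {
  set.seed(20)
  worst <- 0
  for (i in 1:200) {
    p <- sample(3:8, 1)
    rs <- random_acyclic_spec(p, dens = 0.45, with_cov = i %% 3 == 0)
    sig <- implied_covariance(rs$spec, rs$params)
    sig_oracle <- wright_sigma(rs$spec, rs$params)
    worst <- max(worst, max(abs(sig - sig_oracle)))
  }
  expect_lt(worst, 1e-9)
})

test_that("ML discrepancy has its closed-form and invariance properties", {
  s <- matrix(c(2, 0.5, 0.5, 1), 2)
  expect_equal(ml_discrepancy(s, s), 0)
  # scalar case: F = log(sigma/s) + s/sigma - 1
  expect_equal(ml_discrepancy(matrix(1), matrix(2)), log(1 / 2) + 2 - 1)
  set.seed(21)
  for (i in 1:25) {
    a <- crossprod(matrix(rnorm(16), 4)) + diag(4)
    b <- crossprod(matrix(rnorm(16), 4)) + diag(4)
    f <- ml_discrepancy(a, b)
    expect_gte(f, 0)
    # congruence by a common diagonal rescaling leaves F unchanged
    d <- diag(runif(4, 0.2, 5))
    expect_equal(ml_discrepancy(d %*% a %*% d, d %*% b %*% d), f,
                 tolerance = 1e-10)
  }
  expect_error(ml_discrepancy(diag(2), matrix(c(1, 2, 2, 1), 2)), "positive definite")
})

test_that("a single-edge fit reproduces the least-squares slope and SE", {
  set.seed(22)
  d <- data.frame(x = rnorm(400))
  d$y <- 0.7 * d$x + rnorm(400, sd = 0.8)
  fit <- fit_clpm(two_var_spec(), d)
  ls <- lm(y ~ x, data = d)
  expect_equal(unname(fit$estimates["a"]), unname(coef(ls)["x"]),
               tolerance = 1e-8)
  # SEs agree up to the N vs N-1 residual-variance convention
  expect_equal(unname(fit$se["a"]),
               unname(summary(ls)$coefficients["x", "Std. Error"]),
               tolerance = 0.01)
})

test_that("saturated models fit exactly with zero df", {
  set.seed(23)
  d <- as.data.frame(matrix(rnorm(300), ncol = 3))
  names(d) <- c("a", "b", "c")
  fit <- fit_clpm(saturated_spec(c("a", "b", "c")), d)
  expect_equal(fit$discrepancy, 0, tolerance = 1e-10)
  expect_equal(fit$df, 0L)
  expect_equal(fit$implied_cov, unclass(fit$sample_cov), tolerance = 1e-7,
               ignore_attr = TRUE)
})

test_that("equality constraints never improve on the unconstrained fit", {
  ds <- build_analysis_dataset(simulate_cohort(quiet_config(600, seed = 24)))
  spec_c <- build_clpm_spec("leg_LM", "leg_BMD")
  spec_u <- spec_c
  # split the two shared autoregressive labels into free per-lag labels
  dir_m <- spec_u$edges$label == "ar_muscle"
  spec_u$edges$label[dir_m] <- paste0("ar_muscle_", seq_len(sum(dir_m)))
  dir_b <- spec_u$edges$label == "ar_bone"
  spec_u$edges$label[dir_b] <- paste0("ar_bone_", seq_len(sum(dir_b)))
  spec_u <- path_spec(spec_u$vars, spec_u$edges, start = c(
    ar_muscle_1 = 0.8, ar_muscle_2 = 0.8, ar_bone_1 = 0.8, ar_bone_2 = 0.8
  ))
  f_c <- fit_clpm(spec_c, ds)
  f_u <- fit_clpm(spec_u, ds)
  expect_gte(f_c$discrepancy, f_u$discrepancy - 1e-10)
  expect_equal(f_u$df, f_c$df - 2L)
})

test_that("the quasi-Newton fallback is triggered and recorded when the primary optimizer is starved", {
  set.seed(25)
  d <- data.frame(x = rnorm(200))
  d$y <- 0.4 * d$x + rnorm(200)
  fit <- fit_clpm(two_var_spec(), d, control = list(iter.max = 1, eval.max = 2))
  expect_true(fit$convergence$fallback_used)
  expect_equal(fit$convergence$optimizer, "nlminb+BFGS")
  expect_equal(unname(fit$estimates["a"]), unname(coef(lm(y ~ x, d))["x"]),
               tolerance = 1e-6)
})

test_that("standardized coefficients are scale invariant and reduce to raw on unit variance", {
  ds <- build_analysis_dataset(simulate_cohort(quiet_config(800, seed = 26)))
  vars <- canonical_vars("leg")
  spec <- build_clpm_spec("leg_LM", "leg_BMD")
  fit <- fit_clpm(spec, ds)
  std <- standardize(fit)
  # rescaling a source variable by 1000 leaves standardized estimates intact
  ds2 <- ds
  for (v in grep("leg_LM", vars, value = TRUE)) ds2[[v]] <- ds2[[v]] * 1000
  std2 <- standardize(fit_clpm(spec, ds2))
  expect_equal(std2$std_estimate, std$std_estimate, tolerance = 1e-5)
  # pre-scaled unit-variance data and an exactly fitting model:
  # standardized equals unstandardized (implied SDs are all 1)
  d2 <- data.frame(x = as.numeric(scale(ds$V0_leg_LM)),
                   y = as.numeric(scale(ds$V0_leg_BMD)))
  std_unit <- standardize(fit_clpm(two_var_spec(), d2))
  expect_equal(std_unit$std_estimate, std_unit$estimate, tolerance = 1e-6)
  # near-saturated canonical fit: the two agree to the size of the misfit
  std3 <- standardize(fit_clpm(spec, ds %>%
    dplyr::mutate(dplyr::across(dplyr::all_of(vars), ~ as.numeric(scale(.))))))
  expect_equal(std3$std_estimate, std3$estimate, tolerance = 0.05)
})

test_that("structural parameters are recovered from generated data", {
  cfg <- quiet_config(6000, seed = 27)
  ds <- build_analysis_dataset(simulate_cohort(cfg))
  spec <- build_clpm_spec("leg_LM", "leg_BMD",
                          covariates = c("age", "height", "grip"))
  fit <- fit_clpm(spec, ds)
  gp <- implied_population_cov(cfg, "leg")
  truth <- gp$params
  labels <- c("beta_V0", "beta_V3", "beta_V5", "gMB_V0V3", "gMB_V3V5",
              "gBM_V0V3", "gBM_V3V5", "ar_muscle", "ar_bone")
  z <- abs(fit$estimates[labels] - truth[labels]) / fit$se[labels]
  expect_lt(max(z), 4)
})

test_that("tidy and glance expose the fitted model in broom form", {
  ds <- build_analysis_dataset(simulate_cohort(quiet_config(500, seed = 28)))
  fit <- fit_clpm(build_clpm_spec("leg_LM", "leg_BMD"), ds)
  td <- tidy(fit)
  expect_equal(nrow(td), 11L) # one row per directed edge
  expect_true(all(c("predictor", "outcome", "estimate", "std.error",
                    "std_estimate") %in% names(td)))
  # the two edges of a shared label report one common estimate
  expect_length(unique(td$estimate[td$label == "ar_muscle"]), 1L)
  gl <- glance(fit)
  expect_equal(gl$df, 6L)
  expect_true(all(c("chi2", "srmr", "rmsea", "bb_nfi", "adequate") %in% names(gl)))
})

test_that("fit input validation names the offending argument", {
  spec <- two_var_spec()
  expect_error(fit_clpm(spec), "data")
  expect_error(fit_clpm(spec, sample_cov = diag(2)), "n")
  expect_error(fit_clpm(spec, data.frame(x = 1:3)), "missing columns")
  expect_error(fit_clpm(spec, sample_cov = diag(2), n = 2), "n")
})
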