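test_that("one-lag mediation routes include both quoted parallel paths", {
  spec <- build_clpm_spec("leg_LM", "leg_BMD")
  paths <- enumerate_mediation_paths(spec, "V0_leg_LM", "V3_leg_BMD")
  # the two dominant parallel routes: through lagged muscle and through
  # contemporaneous bone; plus the route chaining both cross-construct edges
  expect_length(paths, 3L)
  keys <- vapply(paths, paste, collapse = ">", FUN.VALUE = "")
  expect_true("V0_leg_LM>V3_leg_LM>V3_leg_BMD" %in% keys)
  expect_true("V0_leg_LM>V0_leg_BMD>V3_leg_BMD" %in% keys)
})

test_that("route enumeration matches an exhaustive igraph oracle", {
  spec <- build_clpm_spec("leg_LM", "leg_BMD", covariates = c("age", "grip"))
  dir <- spec$edges[spec$edges$type == "directed", c("src", "dst")]
  g <- igraph::graph_from_data_frame(dir, directed = TRUE)
  for (pair in list(c("V0_leg_LM", "V5_leg_BMD"),
                    c("V0_leg_BMD", "V5_leg_LM"),
                    c("age", "V5_leg_BMD"))) {
    mine <- enumerate_mediation_paths(spec, pair[1], pair[2])
    oracle <- igraph::all_simple_paths(g, pair[1], pair[2], mode = "out")
    oracle <- Filter(function(p) length(p) > 2, oracle)
    expect_length(mine, length(oracle))
    expect_setequal(
      vapply(mine, paste, collapse = ">", FUN.VALUE = ""),
      vapply(oracle, function(p) paste(names(p), collapse = ">"), "")
    )
  }
  expect_error(enumerate_mediation_paths(spec, "V0_leg_LM", "V0_leg_LM"),
               "outcome")
  expect_error(enumerate_mediation_paths(spec, "nope", "V0_leg_LM"),
               "predictor")
})

test_that("effect arithmetic reproduces the published decomposition rows", {
  # fully reported row: leg lean-mass index, first lag
  r <- effect_ratios(0.0642, 0.2214)
  expect_equal(r$total, 0.2856)
  expect_equal(round(r$pct_direct, 1), 22.5)
  expect_equal(round(r$pct_indirect, 1), 77.5)
  expect_equal(round(r$ratio, 1), 3.4)
  expect_false(r$flag_pct || r$flag_ratio)
  # near-zero total: percentages are flagged but the ratio survives
  r2 <- effect_ratios(0.0172, -0.0167)
  expect_true(r2$flag_pct)
  expect_false(r2$flag_ratio)
  expect_equal(round(r2$ratio, 1), 1.0)
  # near-zero direct: ratio flagged, percentages survive
  r3 <- effect_ratios(-0.0040, 0.3078)
  expect_true(r3$flag_ratio)
  expect_false(r3$flag_pct)
  expect_equal(round(r3$pct_direct, 1), -1.3)
  expect_equal(round(r3$pct_indirect, 1), 101.3)
  # negative direct with total above threshold: percentages beyond 100
  r4 <- effect_ratios(-0.0256, 0.0476)
  expect_equal(round(r4$pct_direct, 1), -116.4)
  expect_equal(round(r4$pct_indirect, 1), 216.4)
  expect_equal(round(r4$ratio, 1), 1.9)
})

test_that("additional published rows keep percentages summing to 100", {
  rows <- list(c(-0.0646, 0.3596), c(-0.0382, 0.1098), c(-0.0396, 0.3379),
               c(-0.0452, 0.3956), c(-0.0304, 0.0632))
  for (x in rows) {
    r <- effect_ratios(x[1], x[2])
    expect_equal(r$total, x[1] + x[2], tolerance = 1e-12)
    if (!r$flag_pct) expect_equal(r$pct_direct + r$pct_indirect, 100)
  }
})

test_that("decomposition is additive and matches the total-effect algebra", {
  ds <- build_analysis_dataset(simulate_cohort(quiet_config(1500, seed = 70)))
  fit <- fit_clpm(build_clpm_spec("leg_LM", "leg_BMD"), ds)
  for (pair in list(c("V0_leg_LM", "V3_leg_BMD"),
                    c("V3_leg_LM", "V5_leg_BMD"),
                    c("V0_leg_LM", "V5_leg_BMD"))) {
    d <- decompose(fit, pair[1], pair[2])
    expect_equal(d$total, d$direct + d$indirect, tolerance = 1e-12)
    # sum of path products (direct + all mediation routes) equals the
    # matrix-algebra total effect (I - A)^-1 on the unstandardized scale
    ms <- musclebone:::spec_matrices(fit$spec, fit$params)
    Tm <- solve(diag(length(fit$spec$vars)) - ms$A)
    dimnames(Tm) <- list(fit$spec$vars, fit$spec$vars)
    sds <- sqrt(diag(fit$implied_cov))
    total_unstd <- d$total * sds[pair[2]] / sds[pair[1]]
    expect_equal(unname(total_unstd), Tm[pair[2], pair[1]], tolerance = 1e-8)
  }
})

test_that("the decomposition of generative parameters matches the covariance oracle", {
  cfg <- nocov_config(400, seed = 71)
  gp <- implied_population_cov(cfg, "leg")
  # a fit whose estimates are exactly the generative parameters: fit to the
  # implied population covariance, where the optimum is the truth
  fit <- fit_clpm(gp$spec, sample_cov = gp$sigma, n = 100000)
  expect_lt(fit$discrepancy, 1e-10)
  d <- decompose(fit, "V0_leg_LM", "V3_leg_BMD")
  sds <- sqrt(diag(gp$sigma))
  scale <- sds["V0_leg_LM"] / sds["V3_leg_BMD"]
  direct_true <- cfg$gamma_MB[1] * scale
  paths_true <- (cfg$rho_muscle * cfg$beta_MB[2] +
                 cfg$beta_MB[1] * cfg$rho_bone +
                 cfg$beta_MB[1] * cfg$gamma_BM[1] * cfg$beta_MB[2]) * scale
  expect_equal(d$direct, unname(direct_true), tolerance = 1e-6)
  expect_equal(d$indirect, unname(paths_true), tolerance = 1e-6)
})

test_that("no-mediator graphs decompose to the direct effect alone", {
  set.seed(72)
  d <- data.frame(x = rnorm(300))
  d$y <- 0.5 * d$x + rnorm(300)
  d$z <- rnorm(300) # disconnected third variable
  sp <- path_spec(
    c("x", "y", "z"),
    data.frame(src = c("x", "x", "y", "z"), dst = c("y", "x", "y", "z"),
               type = c("directed", rep("bidirected", 3)),
               label = c("a", "vx", "vy", "vz"), value = NA)
  )
  fit <- fit_clpm(sp, d)
  dec <- decompose(fit, "x", "y")
  expect_equal(dec$indirect, 0)
  expect_equal(dec$total, dec$direct)
  expect_equal(dec$n_paths, 0L)
})

test_that("delta-method indirect SE agrees with a bootstrap oracle", {
  cfg <- nocov_config(2000, seed = 73)
  ds <- build_analysis_dataset(simulate_cohort(cfg))
  spec <- build_clpm_spec("leg_LM", "leg_BMD")
  fit <- fit_clpm(spec, ds)
  d0 <- decompose(fit, "V0_leg_LM", "V3_leg_BMD")
  set.seed(74)
  boot <- replicate(300, {
    idx <- sample.int(nrow(ds), replace = TRUE)
    f <- fit_clpm(spec, ds[idx, ])
    decompose(f, "V0_leg_LM", "V3_leg_BMD")$indirect
  })
  expect_lt(abs(sd(boot) - d0$indirect_se) / d0$indirect_se, 0.15)
})

test_that("the assembled comparison table renders flags as Div by 0", {
  ds <- build_analysis_dataset(simulate_cohort(quiet_config(800, seed = 75)))
  fit <- fit_clpm(build_clpm_spec("leg_LM", "leg_BMD"), ds)
  tab <- decomposition_table(list(leg_LM = fit))
  expect_equal(nrow(tab), 2L) # the two one-lag muscle-to-bone pairings
  expect_true(all(c("direct", "indirect", "total", "dir_pct_of_total",
                    "ind_dir_ratio") %in% names(tab)))
  expect_equal(tab$total, tab$direct + tab$indirect, tolerance = 1e-12)
  # empty pairing list gives an empty table
  empty <- decomposition_table(list(leg_LM = fit),
                               pairs = tibble::tibble(model = character(),
                                                      predictor = character(),
                                                      outcome = character()))
  expect_equal(nrow(empty), 0L)
  # a forced tiny total renders the percentage cells as flags
  tiny <- decomposition_table(
    list(leg_LM = fit),
    pairs = tibble::tibble(model = "leg_LM", predictor = "V3_leg_LM",
                           outcome = "V5_leg_BMD"),
    threshold = 10 # everything under this magnitude flags
  )
  expect_equal(tiny$dir_pct_of_total, "Div by 0")
  expect_equal(tiny$ind_dir_ratio, "Div by 0")
})
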