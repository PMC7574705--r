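# Three-wave synthetic cohort generator. The generative structure mirrors the
# cross-lagged panel model the package fits: per limb, muscle (lean mass, kg)
# and bone (areal BMD, g/cm^2) follow autoregressive dynamics with
# contemporaneous muscle->bone paths, cross-lags in both directions, and
# baseline covariate effects at every visit; left and right limbs are
# correlated replicates. Defaults are calibrated so baseline and follow-up
# marginal means/SDs match the configured cohort-scale targets.

default_metric_targets <- function() {
  tibble(
    metric = c("leg_LM", "leg_BMD", "arm_LM", "arm_BMD"),
    mean_V0 = c(10.58, 1.403, 4.38, 0.920),
    sd_V0 = c(1.54, 0.146, 0.77, 0.084),
    mean_V3 = c(10.42, 1.381, 4.33, 0.912),
    sd_V3 = c(1.55, 0.146, 0.80, 0.083),
    mean_V5 = c(9.77, 1.390, 4.05, 0.903),
    sd_V5 = c(1.51, 0.166, 0.78, 0.090)
  )
}

#' Configuration of the synthetic three-wave cohort
#'
#' Collects every generative parameter: cohort size and seed, visit schedule,
#' marginal mean/SD targets per metric and visit, structural coefficients
#' (autoregressive, contemporaneous, cross-lagged, covariate effects),
#' disturbance scales, limb correlation, and missingness probabilities.
#'
#' Disturbance SDs default to `NULL`, meaning they are solved analytically so
#' the implied marginal SDs reproduce the configured targets exactly given
#' the structural coefficients; supply a named vector
#' (`<visit>_<metric>`, e.g. `V3_leg_LM`) to override.
#'
#' The covariate distributions for walking amount and grip strength are
#' invented (no reference values are published for this cohort); their
#' defaults are chosen to be realistic for community-dwelling men over 40.
#'
#' @param n_participants Cohort size, `>= 1`.
#' @param seed Integer RNG seed.
#' @param visit_months Three strictly increasing visit times in months.
#' @param metric_targets Data frame like `default_metric_targets()`:
#'   per-metric mean/SD at each visit (metric units; kg for lean mass,
#'   g/cm^2 for BMD).
#' @param rho_muscle,rho_bone Unitless autoregressive coefficients, shared
#'   across the two lag periods (the equality the fitted model constrains).
#' @param beta_MB Length-3 contemporaneous muscle->bone coefficients
#'   (g/cm^2 per kg), one per visit.
#' @param gamma_MB,gamma_BM Length-2 cross-lag coefficients (muscle->bone in
#'   g/cm^2 per kg; bone->muscle in kg per g/cm^2), one per lag period.
#' @param covariate_effects_muscle,covariate_effects_bone Named vectors of
#'   per-visit covariate effects on each metric, expressed per covariate
#'   unit and per baseline SD of the metric (the raw effect applied to a
#'   limb is the value times that limb's baseline SD, so the same vector
#'   carries a comparable relative effect at the leg and the arm); names
#'   must be covariate columns.
#' @param disturbance_sd Optional named override of disturbance SDs.
#' @param disturbance_df Degrees of freedom for scaled-t disturbances;
#'   `Inf` (default) gives Gaussian disturbances.
#' @param limb_correlation Correlation of left/right disturbances.
#' @param dropout_prob Per-visit probability that a participant misses the
#'   visit entirely (missing completely at random); baseline is never missed.
#' @param side_flag_prob Probability that a side/limb carries a
#'   prosthesis/fracture exclusion flag (drawn once, persists across visits).
#' @param age_mean,age_sd,age_min Target mean/SD of the age distribution
#'   after truncation at `age_min` (the parent normal is solved so the
#'   truncated moments match).
#' @param height_mean,height_sd,bmi_mean,bmi_sd Anthropometric targets; body
#'   weight is generated as `BMI * (height/100)^2` so the BMI identity holds
#'   exactly.
#' @param prevalence Named list of binary covariate prevalences.
#' @param alcohol_shape,alcohol_scale Gamma parameters for units/week.
#' @param walking_shape,walking_scale Gamma parameters for minutes/week.
#' @param grip_mean,grip_sd Normal parameters for grip strength (kg).
#'
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_participants = 1286,
                         seed = 20201001L,
                         visit_months = c(0, 48, 120),
                         metric_targets = default_metric_targets(),
                         rho_muscle = 0.92,
                         rho_bone = 0.95,
                         beta_MB = c(0.0316, -0.0108, 0.0085),
                         gamma_MB = c(0.0093, 0.0003),
                         gamma_BM = c(0.0238, 0.0136),
                         covariate_effects_muscle = c(
                           age = -0.006, height = 0.010, grip = 0.006,
                           smoking = -0.06, diabetes = -0.03
                         ),
                         covariate_effects_bone = c(
                           age = -0.005, weight = 0.002,
                           smoking = -0.02, fracture40 = -0.05
                         ),
                         disturbance_sd = NULL,
                         disturbance_df = Inf,
                         limb_correlation = 0.95,
                         dropout_prob = c(V0 = 0, V3 = 0.02, V5 = 0.02),
                         side_flag_prob = 0.01,
                         age_mean = 53, age_sd = 9, age_min = 40,
                         height_mean = 175.4, height_sd = 6.8,
                         bmi_mean = 27.43, bmi_sd = 4.23,
                         prevalence = list(
                           ethnicity = 0.97, arthritis = 0.20,
                           fracture40 = 0.05, smoking = 0.12,
                           diabetes = 0.15, hospitalization = 0.05,
                           glucocorticoid = 1 / 1286
                         ),
                         alcohol_shape = 0.8, alcohol_scale = 6,
                         walking_shape = 1.5, walking_scale = 60,
                         grip_mean = 44, grip_sd = 8) {
  n_participants <- check_count(n_participants, "n_participants")
  seed <- check_count(seed, "seed", min = 0L)
  if (length(visit_months) != 3L || any(visit_months < 0) ||
      any(diff(visit_months) <= 0)) {
    stop_field("visit_months", "must be three nonnegative, strictly increasing months")
  }
  metric_targets <- as_tibble(metric_targets)
  sds <- unlist(metric_targets[, c("sd_V0", "sd_V3", "sd_V5")])
  if (any(sds <= 0)) stop_field("metric_targets", "all SDs must be > 0")
  for (nm in c("rho_muscle", "rho_bone")) check_scalar_number(get(nm), nm)
  if (length(beta_MB) != 3L || any(!is.finite(beta_MB))) {
    stop_field("beta_MB", "must be three finite coefficients (one per visit)")
  }
  for (nm in c("gamma_MB", "gamma_BM")) {
    g <- get(nm)
    if (length(g) != 2L || any(!is.finite(g))) {
      stop_field(nm, "must be two finite coefficients (one per lag)")
    }
  }
  if (any(!is.finite(covariate_effects_muscle)) ||
      any(!is.finite(covariate_effects_bone))) {
    stop_field("covariate_effects", "must be finite")
  }
  check_probability(limb_correlation, "limb_correlation")
  if (length(dropout_prob) != 3L) {
    stop_field("dropout_prob", "must give one probability per visit")
  }
  for (p in dropout_prob) check_probability(p, "dropout_prob")
  check_probability(side_flag_prob, "side_flag_prob")
  for (nm in names(prevalence)) check_probability(prevalence[[nm]], paste0("prevalence$", nm))
  for (nm in c("age_sd", "height_sd", "bmi_sd", "alcohol_shape", "alcohol_scale",
               "walking_shape", "walking_scale", "grip_sd")) {
    check_positive(get(nm), nm)
  }
  if (!is.infinite(disturbance_df) && disturbance_df <= 2) {
    stop_field("disturbance_df", "must be > 2 (finite variance) or Inf")
  }
  structure(list(
    n_participants = n_participants, seed = seed, visit_months = visit_months,
    metric_targets = metric_targets,
    rho_muscle = rho_muscle, rho_bone = rho_bone,
    beta_MB = unname(beta_MB), gamma_MB = unname(gamma_MB),
    gamma_BM = unname(gamma_BM),
    covariate_effects_muscle = covariate_effects_muscle,
    covariate_effects_bone = covariate_effects_bone,
    disturbance_sd = disturbance_sd, disturbance_df = disturbance_df,
    limb_correlation = limb_correlation,
    dropout_prob = setNames(as.numeric(dropout_prob), c("V0", "V3", "V5")),
    side_flag_prob = side_flag_prob,
    age_mean = age_mean, age_sd = age_sd, age_min = age_min,
    height_mean = height_mean, height_sd = height_sd,
    bmi_mean = bmi_mean, bmi_sd = bmi_sd,
    prevalence = prevalence,
    alcohol_shape = alcohol_shape, alcohol_scale = alcohol_scale,
    walking_shape = walking_shape, walking_scale = walking_scale,
    grip_mean = grip_mean, grip_sd = grip_sd
  ), class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf("<synth_config> n = %d, seed = %d, visits at %s months\n",
              x$n_participants, x$seed,
              paste(x$visit_months, collapse = "/")))
  invisible(x)
}

# Parent normal parameters such that truncation at `a` leaves the target
# mean/SD; closed-form truncated moments, solved by Nelder-Mead.
truncnorm_parent <- function(target_mean, target_sd, a) {
  moments <- function(mu, sigma) {
    alpha <- (a - mu) / sigma
    lambda <- exp(dnorm(alpha, log = TRUE) - pnorm(alpha, lower.tail = FALSE, log.p = TRUE))
    m <- mu + sigma * lambda
    v <- sigma^2 * (1 + alpha * lambda - lambda^2)
    c(m, sqrt(v))
  }
  obj <- function(par) {
    mm <- moments(par[1], exp(par[2]))
    (mm[1] - target_mean)^2 + (mm[2] - target_sd)^2
  }
  fit <- optim(c(target_mean, log(target_sd)), obj,
               control = list(reltol = 1e-14, maxit = 2000))
  list(mu = fit$par[1], sigma = exp(fit$par[2]),
       alpha = (a - fit$par[1]) / exp(fit$par[2]))
}

rtruncnorm_lower <- function(n, mu, sigma, a) {
  plo <- pnorm((a - mu) / sigma)
  mu + sigma * qnorm(plo + runif(n) * (1 - plo))
}

# Analytic means and covariance matrix of the baseline covariate block
# (model covariates; ethnicity as the ancestry indicator). Exact for all
# components except BMI, whose truncation at 15 kg/m^2 is ignored
# (probability ~2e-3). Used for centering and disturbance calibration.
covariate_moments <- function(config) {
  pv <- config$prevalence
  parent <- truncnorm_parent(config$age_mean, config$age_sd, config$age_min)
  h_mu <- config$height_mean; h_sd <- config$height_sd
  # m = (height/100)^2 and weight = BMI * m, BMI independent of height
  Eh2 <- h_mu^2 + h_sd^2
  Eh3 <- h_mu^3 + 3 * h_mu * h_sd^2
  Eh4 <- h_mu^4 + 6 * h_mu^2 * h_sd^2 + 3 * h_sd^4
  Em <- Eh2 / 1e4
  Em2 <- Eh4 / 1e8
  Eb <- config$bmi_mean; Vb <- config$bmi_sd^2
  Ew <- Eb * Em
  Vw <- (Vb + Eb^2) * Em2 - Eb^2 * Em^2
  cov_wh <- Eb * (Eh3 / 1e4 - Em * h_mu)
  means <- c(
    age = config$age_mean,
    ethnicity = pv$ethnicity,
    arthritis = pv$arthritis,
    fracture40 = pv$fracture40,
    alcohol = config$alcohol_shape * config$alcohol_scale,
    smoking = pv$smoking,
    diabetes = pv$diabetes,
    walking = config$walking_shape * config$walking_scale,
    grip = config$grip_mean,
    hospitalization = pv$hospitalization,
    height = h_mu,
    weight = Ew
  )
  vars <- c(
    age = config$age_sd^2,
    ethnicity = pv$ethnicity * (1 - pv$ethnicity),
    arthritis = pv$arthritis * (1 - pv$arthritis),
    fracture40 = pv$fracture40 * (1 - pv$fracture40),
    alcohol = config$alcohol_shape * config$alcohol_scale^2,
    smoking = pv$smoking * (1 - pv$smoking),
    diabetes = pv$diabetes * (1 - pv$diabetes),
    walking = config$walking_shape * config$walking_scale^2,
    grip = config$grip_sd^2,
    hospitalization = pv$hospitalization * (1 - pv$hospitalization),
    height = h_sd^2,
    weight = Vw
  )
  sigma <- diag(vars)
  dimnames(sigma) <- list(names(vars), names(vars))
  sigma["height", "weight"] <- sigma["weight", "height"] <- cov_wh
  list(means = means, sigma = sigma, age_parent = parent)
}

# Names of the model covariates the generator produces.
synth_covariate_names <- function() {
  c("age", "ethnicity", "arthritis", "fracture40", "alcohol", "smoking",
    "diabetes", "walking", "grip", "hospitalization", "height", "weight")
}

#' Generate the baseline covariate block
#'
#' Draws the baseline covariates of a synthetic cohort: age from a normal
#' distribution truncated at `age_min` whose truncated moments match the
#' configured mean/SD, height normal, BMI normal (truncated at 15 kg/m^2)
#' with weight derived as `BMI * (height/100)^2`, gamma-distributed alcohol
#' and walking amounts, normal grip strength, and Bernoulli indicators at the
#' configured prevalences. Reproducible given `config$seed`.
#'
#' @param config A [synth_config()].
#' @return Tibble with one row per participant: `id`, the covariates above,
#'   and the `glucocorticoid` indicator.
#' @export
generate_covariates <- function(config) {
  if (!inherits(config, "synth_config")) {
    stop_field("config", "must be a synth_config")
  }
  set.seed(config$seed)
  n <- config$n_participants
  pv <- config$prevalence
  parent <- truncnorm_parent(config$age_mean, config$age_sd, config$age_min)
  age <- rtruncnorm_lower(n, parent$mu, parent$sigma, config$age_min)
  height <- rnorm(n, config$height_mean, config$height_sd)
  bmi <- rtruncnorm_lower(n, config$bmi_mean, config$bmi_sd, 15)
  tibble(
    id = sprintf("P%05d", seq_len(n)),
    age = age,
    ethnicity = ifelse(rbinom(n, 1, pv$ethnicity) == 1, "African", "Other"),
    arthritis = rbinom(n, 1, pv$arthritis),
    fracture40 = rbinom(n, 1, pv$fracture40),
    alcohol = rgamma(n, shape = config$alcohol_shape, scale = config$alcohol_scale),
    smoking = rbinom(n, 1, pv$smoking),
    diabetes = rbinom(n, 1, pv$diabetes),
    walking = rgamma(n, shape = config$walking_shape, scale = config$walking_scale),
    grip = rnorm(n, config$grip_mean, config$grip_sd),
    hospitalization = rbinom(n, 1, pv$hospitalization),
    glucocorticoid = rbinom(n, 1, pv$glucocorticoid),
    height = height,
    bmi = bmi,
    weight = bmi * (height / 100)^2
  )
}

# Full generative parameter vector for one limb, in the label scheme of
# build_clpm_spec(): structural coefficients, covariate effects, analytic
# exogenous moments and (calibrated or supplied) disturbance variances.
generative_params <- function(config, limb, covariates = synth_covariate_names(),
                              moments = covariate_moments(config)) {
  muscle <- paste0(limb, "_LM"); bone <- paste0(limb, "_BMD")
  visits <- c("V0", "V3", "V5")
  spec <- build_clpm_spec(muscle, bone, covariates = covariates)
  m <- paste(visits, muscle, sep = "_"); b <- paste(visits, bone, sep = "_")
  endo <- spec$meta$endogenous
  par <- c(
    setNames(config$beta_MB, paste0("beta_", visits)),
    gMB_V0V3 = config$gamma_MB[1], gMB_V3V5 = config$gamma_MB[2],
    gBM_V0V3 = config$gamma_BM[1], gBM_V3V5 = config$gamma_BM[2],
    ar_muscle = config$rho_muscle, ar_bone = config$rho_bone
  )
  tg <- config$metric_targets
  sd_m0 <- tg$sd_V0[tg$metric == muscle]
  sd_b0 <- tg$sd_V0[tg$metric == bone]
  for (cv in covariates) {
    em <- config$covariate_effects_muscle[cv] %||% 0
    eb <- config$covariate_effects_bone[cv] %||% 0
    em <- ifelse(is.na(em), 0, em); eb <- ifelse(is.na(eb), 0, eb)
    par[paste0("b_", cv, "_", m)] <- em * sd_m0
    par[paste0("b_", cv, "_", b)] <- eb * sd_b0
  }
  for (i in seq_along(covariates)) {
    for (j in i:length(covariates)) {
      par[paste0("phi_", covariates[i], "_", covariates[j])] <-
        moments$sigma[covariates[i], covariates[j]]
    }
  }
  # target marginal variances per endogenous variable, causal order
  target_sd <- c(
    tg$sd_V0[tg$metric == muscle], tg$sd_V0[tg$metric == bone],
    tg$sd_V3[tg$metric == muscle], tg$sd_V3[tg$metric == bone],
    tg$sd_V5[tg$metric == muscle], tg$sd_V5[tg$metric == bone]
  )
  names(target_sd) <- endo
  psi <- setNames(numeric(6), paste0("v_", endo))
  if (!is.null(config$disturbance_sd)) {
    need <- endo
    got <- config$disturbance_sd[need]
    if (anyNA(got)) stop_field("disturbance_sd", "must name every <visit>_<metric>")
    psi[] <- got^2
  } else {
    # solve each disturbance variance in causal order so the implied
    # marginal SD matches its target exactly
    par[names(psi)] <- 0
    for (k in seq_along(endo)) {
      sig <- implied_covariance(spec, par)
      resid <- target_sd[endo[k]]^2 - sig[endo[k], endo[k]]
      if (resid <= 1e-10) {
        stop_field(
          "metric_targets",
          sprintf("target SD for %s is not attainable with the configured coefficients (needed disturbance variance %.3g)",
                  endo[k], resid)
        )
      }
      par[paste0("v_", endo[k])] <- resid
      psi[k] <- resid
    }
  }
  par[names(psi)] <- psi
  target_mean <- c(
    tg$mean_V0[tg$metric == muscle], tg$mean_V0[tg$metric == bone],
    tg$mean_V3[tg$metric == muscle], tg$mean_V3[tg$metric == bone],
    tg$mean_V5[tg$metric == muscle], tg$mean_V5[tg$metric == bone]
  )
  list(spec = spec, params = par, psi = psi,
       target_mean = setNames(target_mean, endo),
       endo = endo, muscle_vars = m, bone_vars = b)
}

#' Population covariance implied by a generator configuration
#'
#' The exact covariance matrix (endogenous measures of one limb's left side
#' plus covariates) implied by the configured structural coefficients,
#' computed through [implied_covariance()] on the same canonical
#' specification the fitting engine uses. Ties the generator to the engine:
#' the empirical covariance of a large generated sample converges to this
#' matrix.
#'
#' @param config A [synth_config()].
#' @param limb `"leg"` or `"arm"`.
#' @return List with the `spec` ([path_spec()]), the full generative
#'   parameter vector `params`, and the implied covariance `sigma`.
#' @export
implied_population_cov <- function(config, limb = c("leg", "arm")) {
  limb <- match.arg(limb)
  gp <- generative_params(config, limb)
  list(spec = gp$spec, params = gp$params,
       sigma = implied_covariance(gp$spec, gp$params))
}

# disturbances: n x 6 matrix, unit variance, Gaussian or scaled-t
rdisturb <- function(n, k, df) {
  if (is.infinite(df)) {
    matrix(rnorm(n * k), n, k)
  } else {
    matrix(stats::rt(n * k, df) * sqrt((df - 2) / df), n, k)
  }
}

#' Simulate the three-wave measurement panel
#'
#' Given a covariate block, simulates left/right arm and leg lean mass and
#' BMD at the three visits from the configured cross-lagged structure:
#' within each limb, baseline muscle is covariates plus disturbance, baseline
#' bone adds the contemporaneous muscle effect, and each later visit combines
#' the autoregressive carry-over, the incoming cross-lag, the contemporaneous
#' effect and covariate effects. Left and right sides share covariate
#' contributions and have disturbances correlated at
#' `config$limb_correlation`. Visit-level means are then shifted to the
#' configured targets. Dropout (whole visits missing completely at random)
#' and prosthesis/fracture side-exclusion flags are applied last.
#'
#' @param covariates Output of [generate_covariates()].
#' @param config The same [synth_config()].
#' @return A `cohort_table` tibble, wide across visits: per-visit
#'   height/weight/BMI, per-visit left/right limb measures
#'   (`<visit>_<side>_<limb>_<metric>`), per-visit side-exclusion flags
#'   (`<visit>_<side>_<limb>_excl`), and the baseline covariates.
#' @export
simulate_panel <- function(covariates, config) {
  if (!inherits(config, "synth_config")) stop_field("config", "must be a synth_config")
  n <- nrow(covariates)
  if (n < 1L) stop_field("covariates", "must have at least one row")
  moments <- covariate_moments(config)
  cn <- synth_covariate_names()
  X <- as.matrix(as.data.frame(covariates)[, setdiff(cn, "ethnicity")])
  X <- cbind(X, ethnicity = as.numeric(covariates$ethnicity == "African"))
  X <- X[, cn, drop = FALSE]
  Xc <- sweep(X, 2, moments$means[cn]) # centered at population means

  visits <- c("V0", "V3", "V5")
  out <- tibble(id = covariates$id)

  # anthropometrics per visit; BMI identity holds by construction
  h <- covariates$height; bmi <- covariates$bmi
  h_v <- list(V0 = h, V3 = h + rnorm(n, 0.1, 0.3), V5 = h + rnorm(n, 0.2, 0.3))
  bmi_v <- list(V0 = bmi, V3 = bmi + rnorm(n, 0.12, 0.6), V5 = bmi + rnorm(n, 0, 0.6))
  for (v in visits) {
    out[[paste0(v, "_height")]] <- h_v[[v]]
    out[[paste0(v, "_bmi")]] <- bmi_v[[v]]
    out[[paste0(v, "_weight")]] <- bmi_v[[v]] * (h_v[[v]] / 100)^2
  }

  r <- config$limb_correlation
  for (limb in c("leg", "arm")) {
    gp <- generative_params(config, limb, moments = moments)
    effm <- gp$params[paste0("b_", cn, "_", gp$muscle_vars[1])]
    effb <- gp$params[paste0("b_", cn, "_", gp$bone_vars[1])]
    cxm <- drop(Xc %*% effm)
    cxb <- drop(Xc %*% effb)
    psi_sd <- sqrt(gp$psi)
    eL <- rdisturb(n, 6, config$disturbance_df)
    eZ <- rdisturb(n, 6, config$disturbance_df)
    eR <- r * eL + sqrt(1 - r^2) * eZ
    for (side in c("L", "R")) {
      e <- sweep(if (side == "L") eL else eR, 2, psi_sd, `*`)
      M <- list(); B <- list()
      M[[1]] <- cxm + e[, 1]
      B[[1]] <- config$beta_MB[1] * M[[1]] + cxb + e[, 2]
      for (k in 2:3) {
        M[[k]] <- config$rho_muscle * M[[k - 1]] +
          config$gamma_BM[k - 1] * B[[k - 1]] + cxm + e[, 2 * k - 1]
        B[[k]] <- config$rho_bone * B[[k - 1]] +
          config$gamma_MB[k - 1] * M[[k - 1]] +
          config$beta_MB[k] * M[[k]] + cxb + e[, 2 * k]
      }
      for (k in 1:3) {
        out[[paste0(visits[k], "_", side, "_", limb, "_LM")]] <-
          gp$target_mean[gp$muscle_vars[k]] + M[[k]]
        out[[paste0(visits[k], "_", side, "_", limb, "_BMD")]] <-
          gp$target_mean[gp$bone_vars[k]] + B[[k]]
      }
    }
  }

  # prosthesis/fracture exclusion flags: drawn once per side/limb, persistent
  for (side in c("L", "R")) {
    for (limb in c("leg", "arm")) {
      flag <- rbinom(n, 1, config$side_flag_prob)
      for (v in visits) out[[paste0(v, "_", side, "_", limb, "_excl")]] <- flag
    }
  }

  # whole-visit dropout, missing completely at random
  for (v in visits) {
    pd <- config$dropout_prob[[v]]
    if (pd > 0) {
      gone <- runif(n) < pd
      cols <- grep(paste0("^", v, "_"), names(out), value = TRUE)
      cols <- setdiff(cols, grep("_excl$", cols, value = TRUE))
      for (cl in cols) out[[cl]][gone] <- NA_real_
    }
  }

  out <- bind_cols(out, covariates[, setdiff(names(covariates),
                                             c("id", "height", "weight", "bmi"))])
  class(out) <- c("cohort_table", class(out))
  attr(out, "config") <- config
  out
}

#' Generate a complete synthetic cohort
#'
#' Seeds the RNG from `config$seed`, generates covariates and the measurement
#' panel, and returns the wide cohort table. Two calls with the same config
#' produce identical tables.
#'
#' @param config A [synth_config()].
#' @return A `cohort_table` tibble; see [simulate_panel()].
#' @examples
#' cohort <- simulate_cohort(synth_config(n_participants = 50, seed = 1))
#' dim(cohort)
#' @export
simulate_cohort <- function(config = synth_config()) {
  covs <- generate_covariates(config) # seeds the RNG
  simulate_panel(covs, config)
}

#' Write / read a cohort table as CSV
#'
#' Plain one-row-per-participant CSV in the
#' `<visit>_<side>_<limb>_<metric>` column dialect; empty cells are the
#' missing-value sentinel. Values round-trip to within floating-point
#' printing precision.
#'
#' @param cohort A cohort table.
#' @param path File path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns a `cohort_table` tibble.
#' @export
write_cohort_csv <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop_field("path", "file does not exist")
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  class(out) <- c("cohort_table", class(out))
  out
}
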