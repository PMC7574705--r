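# Ingest rules for wide-format cohort tables: side selection (left unless
# flagged, then contralateral), derived composition indices, glucocorticoid
# exclusion, and complete-case filtering with a counts log.

#' Resolve the measurement side for one limb at one visit
#'
#' The left side is used unless its prosthesis/fracture exclusion flag is
#' set, in which case the contralateral (right) side is used; if both sides
#' are flagged or missing the record is marked incomplete (`NA`, to be
#' removed by the complete-case filter). The chosen side is recorded.
#'
#' @param cohort A cohort table (see [simulate_cohort()] /
#'   [read_cohort_csv()]).
#' @param limb `"leg"` or `"arm"`.
#' @param visit `"V0"`, `"V3"` or `"V5"`.
#' @return Tibble with `LM`, `BMD` (side-resolved values) and `side`
#'   (`"L"`, `"R"` or `NA`) for every row of `cohort`.
#' @export
select_side <- function(cohort, limb = c("leg", "arm"),
                        visit = c("V0", "V3", "V5")) {
  limb <- match.arg(limb); visit <- match.arg(visit)
  col <- function(side, metric) cohort[[paste(visit, side, limb, metric, sep = "_")]]
  lm_l <- col("L", "LM"); lm_r <- col("R", "LM")
  bmd_l <- col("L", "BMD"); bmd_r <- col("R", "BMD")
  fl_l <- col("L", "excl") %||% rep(0L, nrow(cohort))
  fl_r <- col("R", "excl") %||% rep(0L, nrow(cohort))
  if (is.null(lm_l) && is.null(lm_r)) {
    stop_field("cohort", sprintf("no %s %s columns for either side", visit, limb))
  }
  left_ok <- !is.na(lm_l) & !is.na(bmd_l) & (is.na(fl_l) | fl_l == 0)
  right_ok <- !is.na(lm_r) & !is.na(bmd_r) & (is.na(fl_r) | fl_r == 0)
  side <- ifelse(left_ok, "L", ifelse(right_ok, "R", NA_character_))
  tibble(
    LM = ifelse(left_ok, lm_l, ifelse(right_ok, lm_r, NA_real_)),
    BMD = ifelse(left_ok, bmd_l, ifelse(right_ok, bmd_r, NA_real_)),
    side = side
  )
}

#' Derive regional body-composition indices
#'
#' From single-side leg and arm lean mass (kg) and BMD (g/cm^2), height (cm)
#' and BMI (kg/m^2), derives for each region (leg, arm, appendicular):
#' lean mass LM, the height-squared index LMI = LM / (height in m)^2, the
#' BMI-adjusted LM/BMI, and BMD. Appendicular lean mass doubles the
#' single-side sum, `ALM = 2 * (leg LM + arm LM)`; appendicular BMD is the
#' simple average of the two regional BMDs (a convention: DXA area weights
#' are not carried in the table format).
#'
#' @param LM_leg,LM_arm,BMD_leg,BMD_arm Numeric vectors, metric units.
#' @param height Height in cm, `> 0`.
#' @param BMI Body-mass index in kg/m^2, `> 0`.
#' @return Tibble with columns `<region>_<metric>` for region in
#'   leg/arm/app and metric in LM/LMI/LM_BMI/BMD.
#' @examples
#' derive_indices(10.58, 4.38, 1.403, 0.920, height = 175.4, BMI = 27.43)
#' @export
derive_indices <- function(LM_leg, LM_arm, BMD_leg, BMD_arm, height, BMI) {
  if (any(height <= 0, na.rm = TRUE)) stop_field("height", "must be > 0")
  if (any(BMI <= 0, na.rm = TRUE)) stop_field("BMI", "must be > 0")
  h2 <- (height / 100)^2
  alm <- 2 * (LM_leg + LM_arm)
  tibble(
    leg_LM = LM_leg, leg_LMI = LM_leg / h2, leg_LM_BMI = LM_leg / BMI,
    leg_BMD = BMD_leg,
    arm_LM = LM_arm, arm_LMI = LM_arm / h2, arm_LM_BMI = LM_arm / BMI,
    arm_BMD = BMD_arm,
    app_LM = alm, app_LMI = alm / h2, app_LM_BMI = alm / BMI,
    app_BMD = (BMD_leg + BMD_arm) / 2
  )
}

#' Exclude glucocorticoid users
#'
#' Removes rows whose `glucocorticoid` flag is set and counts them.
#'
#' @param dataset Data frame with a `glucocorticoid` column.
#' @return The filtered tibble; the number removed is in
#'   `attr(, "n_excluded_glucocorticoid")`.
#' @export
exclude_glucocorticoid <- function(dataset) {
  if (!"glucocorticoid" %in% names(dataset)) {
    stop_field("dataset", "must contain a `glucocorticoid` column")
  }
  keep <- is.na(dataset$glucocorticoid) | dataset$glucocorticoid == 0
  out <- as_tibble(dataset[keep, , drop = FALSE])
  attr(out, "n_excluded_glucocorticoid") <- sum(!keep)
  out
}

#' Complete-case filter
#'
#' Retains only rows with every required variable present; no imputation is
#' performed anywhere in the package. Erroring on an empty result keeps a
#' misconfigured variable list from propagating silently.
#'
#' @param dataset Data frame.
#' @param required Character vector of required column names.
#' @return Filtered tibble with `attr(, "n_excluded_incomplete")` recording
#'   the number of rows dropped.
#' @export
complete_case_filter <- function(dataset, required) {
  miss <- setdiff(required, names(dataset))
  if (length(miss)) {
    stop_field("required", paste("columns absent from dataset:", paste(miss, collapse = ", ")))
  }
  ok <- complete.cases(as.data.frame(dataset)[, required, drop = FALSE])
  if (!any(ok)) {
    abort("Complete-case filter removed every row", class = "musclebone_error")
  }
  out <- as_tibble(dataset[ok, , drop = FALSE])
  attr(out, "n_excluded_incomplete") <- sum(!ok)
  out
}

#' Build the analysis dataset from a wide cohort table
#'
#' Applies, in order: the glucocorticoid exclusion, side selection for each
#' limb and visit (left unless flagged), index derivation
#' ([derive_indices()], using same-visit height and BMI), and the
#' complete-case filter over every derived measure at all three visits plus
#' the baseline covariates. Ethnicity is converted to a numeric
#' African-ancestry indicator.
#'
#' @param cohort A cohort table.
#' @param covariates Covariate columns to carry (and require complete);
#'   defaults to the model covariate set.
#' @return Tibble with columns `<visit>_<region>_<metric>`, the covariates,
#'   and a `counts` attribute logging records read and exclusions at each
#'   stage.
#' @examples
#' cohort <- simulate_cohort(synth_config(n_participants = 80, seed = 2))
#' ds <- build_analysis_dataset(cohort)
#' attr(ds, "counts")
#' @export
build_analysis_dataset <- function(cohort,
                                   covariates = c(
                                     "age", "ethnicity", "arthritis",
                                     "fracture40", "alcohol", "smoking",
                                     "diabetes", "walking", "grip",
                                     "hospitalization", "height", "weight"
                                   )) {
  n_read <- nrow(cohort)
  dat <- exclude_glucocorticoid(cohort)
  n_gluco <- attr(dat, "n_excluded_glucocorticoid")

  out <- tibble(id = dat$id)
  for (v in c("V0", "V3", "V5")) {
    leg <- select_side(dat, "leg", v)
    arm <- select_side(dat, "arm", v)
    idx <- derive_indices(leg$LM, arm$LM, leg$BMD, arm$BMD,
                          height = dat[[paste0(v, "_height")]],
                          BMI = dat[[paste0(v, "_bmi")]])
    names(idx) <- paste(v, names(idx), sep = "_")
    out <- bind_cols(out, idx)
    out[[paste0(v, "_leg_side")]] <- leg$side
    out[[paste0(v, "_arm_side")]] <- arm$side
  }
  # baseline covariates; ethnicity as ancestry indicator
  for (cv in covariates) {
    if (cv == "height") {
      out$height <- dat$V0_height
    } else if (cv == "weight") {
      out$weight <- dat$V0_weight
    } else if (cv == "ethnicity" && is.character(dat$ethnicity)) {
      out$ethnicity <- as.numeric(dat$ethnicity == "African")
    } else {
      if (!cv %in% names(dat)) stop_field("covariates", paste("unknown covariate:", cv))
      out[[cv]] <- dat[[cv]]
    }
  }
  metric_cols <- grep("^V[035]_(leg|arm|app)_(LM|LMI|LM_BMI|BMD)$",
                      names(out), value = TRUE)
  out <- complete_case_filter(out, c(metric_cols, covariates))
  n_cc <- attr(out, "n_excluded_incomplete")
  attr(out, "counts") <- c(
    read = n_read,
    excluded_glucocorticoid = n_gluco,
    excluded_incomplete = n_cc,
    retained = nrow(out)
  )
  attr(out, "covariates") <- covariates
  class(out) <- c("analysis_dataset", class(out))
  out
}
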