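#' Visit-level summary with repeated-measures contrasts
#'
#' Per-visit means, SDs and ns for one metric, plus contrasts of each
#' follow-up visit against baseline from a linear model with a
#' participant-level random intercept and visit as a categorical fixed
#' effect (the repeated-measurement adjustment), fitted with [nlme::lme()].
#'
#' @param dataset An analysis dataset (see [build_analysis_dataset()]) or
#'   any data frame with `id` and `<visit>_<metric>` columns.
#' @param metric Column stem, e.g. `"leg_LM"`.
#' @param visits Visit prefixes, baseline first.
#' @return Object of class `visit_summary`: a list with `summary` (tibble of
#'   visit, mean, sd, n), `contrasts` (tibble of contrast, estimate, se,
#'   p.value), and the metric name.
#' @examples
#' ds <- build_analysis_dataset(simulate_cohort(synth_config(200, seed = 3)))
#' visit_summary(ds, "leg_LM")
#' @export
visit_summary <- function(dataset, metric, visits = c("V0", "V3", "V5")) {
  cols <- paste(visits, metric, sep = "_")
  miss <- setdiff(cols, names(dataset))
  if (length(miss)) {
    stop_field("metric", paste("columns absent:", paste(miss, collapse = ", ")))
  }
  if (nrow(dataset) < 2L) stop_field("dataset", "need at least 2 participants")
  long <- tidyr::pivot_longer(
    dplyr::select(as_tibble(dataset), "id", all_of(cols)),
    cols = all_of(cols), names_to = "visit", values_to = "value"
  ) %>%
    mutate(visit = factor(sub(paste0("_", metric, "$"), "", .data$visit),
                          levels = visits)) %>%
    filter(!is.na(.data$value))
  smry <- long %>%
    group_by(.data$visit) %>%
    summarise(mean = mean(.data$value), sd = sd(.data$value), n = dplyr::n(),
              .groups = "drop")
  rows <- paste0("visit", visits[-1])
  fit <- tryCatch(
    nlme::lme(value ~ visit, random = ~ 1 | id, data = long),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    tt <- summary(fit)$tTable
    est <- tt[rows, "Value"]; se <- tt[rows, "Std.Error"]
    pv <- tt[rows, "p-value"]
    method <- "random intercept (lme)"
  } else {
    # degenerate variance components (e.g. an exact deterministic shift):
    # the within-participant fixed-effects fit gives the same contrasts
    fx <- lm(value ~ visit + id, data = long)
    cf <- suppressWarnings(coef(summary(fx))) # perfect fits warn here
    est <- cf[rows, "Estimate"]; se <- cf[rows, "Std. Error"]
    pv <- cf[rows, "Pr(>|t|)"]
    method <- "within-participant fixed effects (degenerate fallback)"
  }
  contrasts <- tibble(
    contrast = paste(visits[-1], "-", visits[1]),
    estimate = unname(est), se = unname(se), p.value = unname(pv)
  )
  structure(list(metric = metric, summary = smry, contrasts = contrasts,
                 method = method),
            class = "visit_summary")
}

#' @export
print.visit_summary <- function(x, ...) {
  cat(sprintf("<visit_summary> %s\n", x$metric))
  print(x$summary)
  print(x$contrasts)
  invisible(x)
}

#' @method tidy visit_summary
#' @export
tidy.visit_summary <- function(x, ...) {
  left_join(
    x$summary %>% mutate(visit = as.character(.data$visit)),
    x$contrasts %>%
      mutate(visit = sub(" - .*$", "", .data$contrast)) %>%
      select("visit", "estimate", "se", "p.value"),
    by = "visit"
  ) %>% mutate(metric = x$metric, .before = 1)
}

#' Mean per-participant percent change between two visits
#'
#' Computes `100 * (x_to - x_from) / x_from` for every participant and
#' averages across participants. This is the mean of per-participant ratios,
#' not the percent change of the group means; the two differ whenever change
#' correlates with the baseline value. Participants with a zero baseline are
#' excluded and counted.
#'
#' @param dataset Analysis dataset.
#' @param metric Column stem, e.g. `"leg_LM"`.
#' @param from,to Visit prefixes.
#' @return One-row tibble: `metric`, `from`, `to`, `mean_pct_change`, `n`,
#'   `n_excluded_zero`.
#' @export
percent_change <- function(dataset, metric, from = "V0", to = "V5") {
  cf <- paste(from, metric, sep = "_"); ct <- paste(to, metric, sep = "_")
  for (cl in c(cf, ct)) {
    if (!cl %in% names(dataset)) stop_field("metric", paste("column absent:", cl))
  }
  x0 <- dataset[[cf]]; xt <- dataset[[ct]]
  ok <- !is.na(x0) & !is.na(xt)
  zero <- ok & x0 == 0
  use <- ok & !zero
  tibble(
    metric = metric, from = from, to = to,
    mean_pct_change = mean(100 * (xt[use] - x0[use]) / x0[use]),
    n = sum(use), n_excluded_zero = sum(zero)
  )
}

#' Annualize a percent change
#'
#' Divides a percent change over a window by the window length in years
#' (`months / 12`).
#'
#' @param pct_change Percent change over the window.
#' @param months Window length in months, `> 0`.
#' @return Percent change per year.
#' @examples
#' annualize(-7.6, 120) # -0.76 percent per year
#' @export
annualize <- function(pct_change, months) {
  if (!is.numeric(pct_change)) stop_field("pct_change", "must be numeric")
  check_positive(months, "months")
  pct_change / (months / 12)
}
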