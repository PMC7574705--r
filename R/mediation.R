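#' Enumerate mediation routes between two variables
#'
#' All directed routes from `predictor` to `outcome` through the acyclic
#' graph, excluding the single direct edge. In the canonical cross-lagged
#' model the one-lag muscle-to-bone query returns the two parallel mediation
#' paths (through the lagged muscle measure and through the contemporaneous
#' bone measure) plus the route that chains both cross-construct edges.
#'
#' @param spec A [path_spec()].
#' @param predictor,outcome Distinct variable names in `spec$vars`.
#' @return List of character vectors, each a variable sequence from
#'   `predictor` to `outcome`; empty when no indirect route exists.
#' @export
enumerate_mediation_paths <- function(spec, predictor, outcome) {
  if (!predictor %in% spec$vars) stop_field("predictor", "not a model variable")
  if (!outcome %in% spec$vars) stop_field("outcome", "not a model variable")
  if (identical(predictor, outcome)) {
    stop_field("outcome", "must differ from `predictor`")
  }
  dir <- spec$edges[spec$edges$type == "directed", c("src", "dst")]
  adj <- split(dir$dst, factor(dir$src, levels = spec$vars))
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    for (w in adj[[v]]) {
      if (w %in% path) next
      new <- c(path, w)
      if (w == outcome) {
        if (length(new) > 2L) paths[[length(paths) + 1L]] <<- new
      } else {
        walk(new)
      }
    }
  }
  walk(predictor)
  paths
}

#' Arithmetic of a direct/indirect effect pair
#'
#' Given a direct and an indirect effect (standardized units), computes the
#' total effect, each component as a percent of the total, and the
#' indirect/direct ratio of absolute values. Ratios and percentages whose
#' denominator magnitude falls below `threshold` are flagged as
#' divide-by-zero rather than reported; the flag is a reporting convention,
#' not an exception.
#'
#' @param direct,indirect Effect estimates.
#' @param threshold Denominator magnitude below which a derived quantity is
#'   flagged (default 0.01 standardized units).
#' @return One-row tibble: `direct`, `indirect`, `total`, `pct_direct`,
#'   `pct_indirect`, `ratio`, `flag_pct`, `flag_ratio`.
#' @examples
#' effect_ratios(0.0642, 0.2214) # total 0.2856, 22.5% / 77.5%, ratio 3.4
#' @export
effect_ratios <- function(direct, indirect, threshold = 0.01) {
  check_scalar_number(direct, "direct")
  check_scalar_number(indirect, "indirect")
  check_positive(threshold, "threshold")
  total <- direct + indirect
  flag_pct <- abs(total) < threshold
  flag_ratio <- abs(direct) < threshold
  tibble(
    direct = direct, indirect = indirect, total = total,
    pct_direct = if (flag_pct) NA_real_ else 100 * direct / total,
    pct_indirect = if (flag_pct) NA_real_ else 100 * indirect / total,
    ratio = if (flag_ratio) NA_real_ else abs(indirect) / abs(direct),
    flag_pct = flag_pct, flag_ratio = flag_ratio
  )
}

# Standardized (direct, indirect) effects as a function of the optimized
# parameter vector; used for the point estimates and the delta method.
decomposition_fun <- function(fit, predictor, outcome, paths) {
  spec <- fit$spec
  fixed <- fit$exog_moments
  nm <- names(fit$estimates)
  function(theta) {
    params <- c(setNames(theta, nm), fixed)
    ms <- spec_matrices(spec, params)
    sds <- sqrt(diag(implied_covariance(spec, params)))
    scale <- sds[predictor] / sds[outcome]
    direct <- ms$A[outcome, predictor] * scale
    indirect <- 0
    for (pth in paths) {
      prod <- 1
      for (k in seq_len(length(pth) - 1L)) prod <- prod * ms$A[pth[k + 1L], pth[k]]
      indirect <- indirect + prod * scale
    }
    c(direct = unname(direct), indirect = unname(indirect))
  }
}

#' Decompose a cross-lagged effect into direct and indirect components
#'
#' The direct effect is the standardized coefficient of the direct edge (zero
#' if absent); the indirect effect is the sum, over every mediation route
#' enumerated by [enumerate_mediation_paths()], of the product of
#' standardized path coefficients along the route. Standard errors come from
#' the first-order delta method on the joint covariance of the fitted
#' parameters; the total is direct + indirect by construction. Percentages of
#' total and the absolute-value indirect/direct ratio follow
#' [effect_ratios()], with divide-by-zero flags below `threshold`.
#'
#' @param fit A converged [fit_clpm()].
#' @param predictor,outcome Model variable names.
#' @param threshold Flagging threshold for derived ratios.
#' @return Object of class `effect_decomposition`: a one-row tibble with the
#'   effects, delta-method SEs and normal-reference p-values, percentage and
#'   ratio columns, and flags; the enumerated paths are in attribute
#'   `"paths"`.
#' @export
decompose <- function(fit, predictor, outcome, threshold = 0.01) {
  if (!inherits(fit, "clpm_fit")) stop_field("fit", "must be a clpm_fit")
  paths <- enumerate_mediation_paths(fit$spec, predictor, outcome)
  f <- decomposition_fun(fit, predictor, outcome, paths)
  theta <- unname(fit$estimates)
  eff <- f(theta)
  ses <- c(direct = NA_real_, indirect = NA_real_, total = NA_real_)
  ps <- ses
  if (length(theta) && !anyNA(fit$vcov)) {
    J <- num_jacobian(f, theta)
    Jt <- rbind(J, colSums(J)) # total = direct + indirect
    V <- Jt %*% fit$vcov %*% t(Jt)
    ses <- sqrt(pmax(diag(V), 0))
    ps <- 2 * pnorm(-abs(c(eff, sum(eff)) / ses))
  }
  rat <- effect_ratios(unname(eff["direct"]), unname(eff["indirect"]), threshold)
  out <- tibble(
    predictor = predictor, outcome = outcome,
    direct = rat$direct, direct_se = ses[[1]], direct_p = ps[[1]],
    indirect = rat$indirect, indirect_se = ses[[2]], indirect_p = ps[[2]],
    total = rat$total, total_se = ses[[3]], total_p = ps[[3]],
    pct_direct = rat$pct_direct, pct_indirect = rat$pct_indirect,
    ratio = rat$ratio, flag_pct = rat$flag_pct, flag_ratio = rat$flag_ratio,
    n_paths = length(paths)
  )
  attr(out, "paths") <- paths
  class(out) <- c("effect_decomposition", class(out))
  out
}

#' Assemble a direct/indirect/total comparison table
#'
#' One row per (model, predictor, outcome) pairing, mirroring a published
#' decomposition layout: effect estimates with SEs and p-values, percent of
#' total, and the indirect/direct ratio, with flagged cells rendered as
#' `"Div by 0"`.
#'
#' @param fits Named list of [fit_clpm()] objects.
#' @param pairs Data frame with columns `model`, `predictor`, `outcome`
#'   naming the pairings; `NULL` uses, for every canonical CLPM fit, the two
#'   one-lag muscle-to-bone cross-lag pairings.
#' @param threshold Flagging threshold, see [decompose()].
#' @return Tibble with numeric effect columns and character `dir_pct_of_total`,
#'   `ind_pct_of_total`, `ind_dir_ratio` display columns.
#' @export
decomposition_table <- function(fits, pairs = NULL, threshold = 0.01) {
  if (inherits(fits, "clpm_fit")) fits <- list(model = fits)
  if (is.null(names(fits))) names(fits) <- paste0("model", seq_along(fits))
  if (is.null(pairs)) {
    pairs <- bind_rows(lapply(names(fits), function(nm) {
      meta <- fits[[nm]]$spec$meta
      if (is.null(meta)) return(NULL)
      m <- paste(meta$visits, meta$muscle, sep = "_")
      b <- paste(meta$visits, meta$bone, sep = "_")
      tibble(model = nm, predictor = m[1:2], outcome = b[2:3])
    }))
  }
  pairs <- as_tibble(pairs)
  if (nrow(pairs) == 0L) {
    return(tibble(
      model = character(), predictor = character(), outcome = character()
    ))
  }
  rows <- purrr::pmap(pairs, function(model, predictor, outcome) {
    d <- decompose(fits[[model]], predictor, outcome, threshold)
    d$model <- model
    d
  })
  out <- bind_rows(rows)
  fmt1 <- function(x, flag) ifelse(flag, "Div by 0", sprintf("%.1f", x))
  out %>%
    mutate(
      dir_pct_of_total = fmt1(.data$pct_direct, .data$flag_pct),
      ind_pct_of_total = fmt1(.data$pct_indirect, .data$flag_pct),
      ind_dir_ratio = fmt1(.data$ratio, .data$flag_ratio)
    ) %>%
    select("model", "predictor", "outcome",
           "direct", "direct_se", "direct_p",
           "indirect", "indirect_se", "indirect_p",
           "total", "total_se", "total_p",
           "dir_pct_of_total", "ind_pct_of_total", "ind_dir_ratio")
}
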