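# Reticular-action-model machinery: a path model with directed-coefficient
# matrix A (A[target, source]) and symmetric variance/covariance matrix S
# implies Sigma = (I - A)^-1 S (I - A)^-T over the observed variables.

# Resolve the full named parameter vector (labels -> values) into A and S.
spec_matrices <- function(spec, params) {
  p <- length(spec$vars)
  A <- matrix(0, p, p, dimnames = list(spec$vars, spec$vars))
  S <- matrix(0, p, p, dimnames = list(spec$vars, spec$vars))
  ed <- spec$edges
  val <- ifelse(is.na(ed$value), unname(params[ed$label]), ed$value)
  if (anyNA(val)) {
    missing <- unique(ed$label[is.na(val)])
    stop_field("params", paste("no value for label(s):", paste(missing, collapse = ", ")))
  }
  for (k in seq_len(nrow(ed))) {
    i <- ed$dst[k]; j <- ed$src[k]
    if (ed$type[k] == "directed") {
      A[i, j] <- val[k]
    } else {
      S[i, j] <- val[k]; S[j, i] <- val[k]
    }
  }
  list(A = A, S = S)
}

#' Model-implied covariance matrix
#'
#' Computes `Sigma = (I - A)^-1 S (I - A)^-T` for a path specification and a
#' full set of parameter values, where `A` holds the directed-edge
#' coefficients and `S` the variances/covariances. Symmetric by construction;
#' `I - A` is always invertible because the directed subgraph is acyclic.
#'
#' @param spec A [path_spec()].
#' @param params Named numeric vector giving a value for every free label in
#'   the spec (fixed edges take their fixed value).
#' @return Symmetric covariance matrix over `spec$vars`.
#' @examples
#' sp <- path_spec(
#'   c("x", "y"),
#'   data.frame(src = c("x", "x", "y"), dst = c("y", "x", "y"),
#'              type = c("directed", "bidirected", "bidirected"),
#'              label = c("a", "vx", "vy"))
#' )
#' implied_covariance(sp, c(a = 0.5, vx = 2, vy = 1))
#' @export
implied_covariance <- function(spec, params) {
  if (!is.numeric(params)) stop_field("params", "must be a named numeric vector")
  if (any(!is.finite(params))) stop_field("params", "must be finite")
  ms <- spec_matrices(spec, params)
  B <- solve(diag(length(spec$vars)) - ms$A)
  sig <- B %*% ms$S %*% t(B)
  dimnames(sig) <- list(spec$vars, spec$vars)
  symmetrize(sig)
}

#' Normal-theory maximum-likelihood discrepancy
#'
#' `F = log|Sigma| + tr(S Sigma^-1) - log|S| - p`, the fit function whose
#' minimum, times the chi-square multiplier, is the model chi-square.
#' Nonnegative, and zero exactly when `Sigma = S`.
#'
#' @param sigma Model-implied covariance matrix (positive definite).
#' @param s Sample covariance matrix (positive definite).
#' @return Nonnegative scalar.
#' @export
ml_discrepancy <- function(sigma, s) {
  p <- nrow(s)
  if (!isTRUE(all.equal(dim(sigma), dim(s)))) {
    stop_field("sigma", "must be conformable with `s`")
  }
  ch_s <- tryCatch(chol(s), error = function(e) NULL)
  if (is.null(ch_s)) stop_field("s", "sample covariance must be positive definite")
  ch_sig <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch_sig)) stop_field("sigma", "implied covariance must be positive definite")
  logdet_sig <- 2 * sum(log(diag(ch_sig)))
  logdet_s <- 2 * sum(log(diag(ch_s)))
  sig_inv <- chol2inv(ch_sig)
  max(logdet_sig + sum(sig_inv * s) - logdet_s - p, 0)
}

# Objective/gradient over the free (optimized) parameter vector.
# Returns list(fn, gr, info env) ; penalizes non-PD S (possible only when a
# free disturbance covariance is present).
make_objective <- function(spec, s_sample, theta_labels, fixed_params) {
  p <- length(spec$vars)
  ed <- spec$edges
  idx <- match(spec$vars, spec$vars) # identity, kept for clarity
  di <- match(ed$dst, spec$vars)
  si <- match(ed$src, spec$vars)
  is_dir <- ed$type == "directed"
  lab <- ed$label
  info <- new.env(parent = emptyenv())
  info$npd <- 0L

  build <- function(theta) {
    params <- c(theta, fixed_params)
    A <- matrix(0, p, p); S <- matrix(0, p, p)
    val <- ifelse(is.na(ed$value), unname(params[lab]), ed$value)
    for (k in seq_along(val)) {
      if (is_dir[k]) A[di[k], si[k]] <- val[k]
      else { S[di[k], si[k]] <- val[k]; S[si[k], di[k]] <- val[k] }
    }
    list(A = A, S = S)
  }

  fn <- function(theta) {
    ms <- build(theta)
    B <- solve(diag(p) - ms$A)
    sigma <- B %*% ms$S %*% t(B)
    ch <- tryCatch(chol(symmetrize(sigma)), error = function(e) NULL)
    if (is.null(ch)) {
      info$npd <- info$npd + 1L
      return(1e10 * (1 + sum(theta^2)))
    }
    logdet_sig <- 2 * sum(log(diag(ch)))
    sig_inv <- chol2inv(ch)
    logdet_sig + sum(sig_inv * s_sample) - attr(s_sample, "logdet") - p
  }

  gr <- function(theta) {
    ms <- build(theta)
    B <- solve(diag(p) - ms$A)
    sigma <- symmetrize(B %*% ms$S %*% t(B))
    ch <- tryCatch(chol(sigma), error = function(e) NULL)
    if (is.null(ch)) return(2e10 * theta)
    sig_inv <- chol2inv(ch)
    W <- sig_inv - sig_inv %*% s_sample %*% sig_inv
    GA <- 2 * t(B) %*% W %*% sigma    # dF/dA[i,j]
    GS <- t(B) %*% W %*% B            # dF/dS: diag -> GS_ii, offdiag -> 2*GS_ij
    g <- setNames(numeric(length(theta_labels)), theta_labels)
    for (k in seq_along(lab)) {
      l <- lab[k]
      if (!is.na(ed$value[k]) || !(l %in% theta_labels)) next
      g[l] <- g[l] + if (is_dir[k]) {
        GA[di[k], si[k]]
      } else if (di[k] == si[k]) {
        GS[di[k], si[k]]
      } else {
        2 * GS[di[k], si[k]]
      }
    }
    unname(g[theta_labels])
  }

  list(fn = fn, gr = gr, info = info)
}

#' Fit a path model by maximum likelihood
#'
#' Minimizes the normal-theory discrepancy [ml_discrepancy()] between the
#' sample covariance matrix and the model-implied covariance over all free
#' labelled parameters (shared labels impose equality constraints). Exogenous
#' block moments are profiled at their sample values, which is their ML
#' solution for this model class. Optimization starts from
#' identity-scaled values (autoregressive labels 0.8 where the spec declares
#' starts, other structural coefficients 0, variances at sample values) and
#' uses a bounded quasi-Newton method; if it fails to converge, a BFGS
#' restart with an enlarged evaluation budget is attempted and recorded.
#'
#' Standard errors come from the inverse observed information at the optimum,
#' scaled by `2/(N-1)` (or `2/N` when `chi2_multiplier = "N"`); p-values use
#' the normal reference distribution.
#'
#' @param spec A [path_spec()].
#' @param data Data frame containing `spec$vars` columns; rows with missing
#'   values in those columns are dropped (complete-case).
#' @param sample_cov,n Alternatively, a sample covariance matrix over
#'   `spec$vars` and the number of observations behind it.
#' @param chi2_multiplier `"N-1"` (Wishart convention, default) or `"N"`.
#' @param control List of optimizer controls: `iter.max`, `eval.max` for the
#'   primary optimizer, `maxit` for the fallback.
#'
#' @return An object of class `clpm_fit` with parameter estimates, standard
#'   errors, the implied covariance, the minimized discrepancy, sample size
#'   and a convergence record. An explicit non-convergence failure (after the
#'   fallback) is signalled as an error of class `musclebone_nonconvergence`.
#' @examples
#' set.seed(1)
#' d <- data.frame(x = rnorm(200))
#' d$y <- 0.5 * d$x + rnorm(200)
#' sp <- path_spec(
#'   c("x", "y"),
#'   data.frame(src = c("x", "x", "y"), dst = c("y", "x", "y"),
#'              type = c("directed", "bidirected", "bidirected"),
#'              label = c("a", "vx", "vy"))
#' )
#' fit <- fit_clpm(sp, d)
#' tidy(fit)
#' @export
fit_clpm <- function(spec, data = NULL, sample_cov = NULL, n = NULL,
                     chi2_multiplier = c("N-1", "N"), control = list()) {
  chi2_multiplier <- match.arg(chi2_multiplier)
  if (!inherits(spec, "path_spec")) stop_field("spec", "must be a path_spec")
  if (is.null(sample_cov)) {
    if (is.null(data)) stop_field("data", "supply `data` or `sample_cov` + `n`")
    miss <- setdiff(spec$vars, names(data))
    if (length(miss)) stop_field("data", paste("missing columns:", paste(miss, collapse = ", ")))
    d <- as.data.frame(data)[, spec$vars, drop = FALSE]
    d <- d[complete.cases(d), , drop = FALSE]
    n <- nrow(d)
    sample_cov <- cov(d)
  } else {
    if (is.null(n)) stop_field("n", "must accompany `sample_cov`")
    sample_cov <- as.matrix(sample_cov)
    if (is.null(dimnames(sample_cov)[[1]])) {
      dimnames(sample_cov) <- list(spec$vars, spec$vars)
    }
    sample_cov <- sample_cov[spec$vars, spec$vars, drop = FALSE]
  }
  p <- length(spec$vars)
  if (n <= p) stop_field("n", sprintf("need n > %d variables, got %d", p, n))
  ch <- tryCatch(chol(sample_cov), error = function(e) NULL)
  if (is.null(ch)) stop_field("sample_cov", "must be positive definite")
  attr(sample_cov, "logdet") <- 2 * sum(log(diag(ch)))

  ed <- spec$edges
  free <- free_labels(spec)
  # exogenous moments: fixed at sample values, not optimized
  exog_edge <- ed$type == "bidirected" & ed$src %in% spec$exog & ed$dst %in% spec$exog
  exog_labels <- unique(ed$label[exog_edge & is.na(ed$value)])
  theta_labels <- setdiff(free, exog_labels)
  fixed_params <- numeric(0)
  if (length(exog_labels)) {
    ee <- ed[exog_edge & is.na(ed$value), ]
    fixed_params <- setNames(
      sample_cov[cbind(ee$dst, ee$src)][match(exog_labels, ee$label)],
      exog_labels
    )
  }

  # starting values: declared starts, else 0 for paths; variances at sample
  # values of the variable they belong to
  varlab <- ed[ed$type == "bidirected" & ed$src == ed$dst & is.na(ed$value), ]
  start <- setNames(numeric(length(theta_labels)), theta_labels)
  lower <- setNames(rep(-Inf, length(theta_labels)), theta_labels)
  for (l in theta_labels) {
    if (l %in% varlab$label) {
      v <- varlab$src[varlab$label == l][1L]
      start[l] <- sample_cov[v, v]
      lower[l] <- 1e-10 * sample_cov[v, v]
    }
  }
  # free covariance (non-self bidirected) labels start at 0, unbounded
  if (!is.null(spec$start)) {
    keep <- intersect(names(spec$start), theta_labels)
    start[keep] <- spec$start[keep]
  }

  obj <- make_objective(spec, sample_cov, theta_labels, fixed_params)
  ctl <- modifyList(list(iter.max = 500L, eval.max = 1000L, maxit = 2000L), control)

  # per-parameter magnitudes so mixed measurement units (kg vs g/cm^2 vs
  # covariate units) do not ill-condition the search: directed labels scale
  # as SD(target)/SD(source), variance labels as the variable's variance
  sds <- sqrt(diag(sample_cov))
  pscale <- setNames(rep(1, length(theta_labels)), theta_labels)
  for (l in theta_labels) {
    rows <- which(ed$label == l & is.na(ed$value))
    k <- rows[1L]
    pscale[l] <- if (ed$type[k] == "directed") {
      max(sds[ed$dst[k]] / sds[ed$src[k]], 1e-12)
    } else {
      max(sds[ed$dst[k]] * sds[ed$src[k]], 1e-12)
    }
  }
  fn_s <- function(phi) obj$fn(phi * pscale)
  gr_s <- function(phi) obj$gr(phi * pscale) * pscale

  fallback_used <- FALSE
  res <- nlminb(start / pscale, fn_s, gradient = gr_s, lower = lower / pscale,
                control = list(iter.max = ctl$iter.max, eval.max = ctl$eval.max))
  theta <- res$par * pscale
  converged <- res$convergence == 0 && is.finite(res$objective) &&
    res$objective < 1e9
  iterations <- res$iterations
  optimizer <- "nlminb"
  if (!converged) {
    # quasi-Newton restart with enlarged evaluation budget
    fallback_used <- TRUE
    res2 <- optim(theta / pscale, fn_s, gr = gr_s, method = "BFGS",
                  control = list(maxit = ctl$maxit, reltol = 1e-14))
    if (res2$value <= obj$fn(theta) || !converged) {
      theta <- res2$par * pscale
      iterations <- iterations + res2$counts[["function"]]
      optimizer <- "nlminb+BFGS"
      converged <- res2$convergence == 0 && is.finite(res2$value) &&
        res2$value < 1e9 && max(abs(gr_s(res2$par))) < 1e-3
    }
  }
  if (!converged) {
    abort("Model did not converge after quasi-Newton fallback",
          class = c("musclebone_nonconvergence", "musclebone_error"))
  }
  fmin <- max(obj$fn(theta), 0)
  names(theta) <- theta_labels

  # observed information -> parameter covariance
  mult_n <- if (chi2_multiplier == "N-1") n - 1 else n
  # Hessian in the unit-scaled space (well conditioned), mapped back
  H <- tryCatch(optimHess(theta / pscale, fn_s, gr = gr_s),
                error = function(e) NULL)
  vcov_theta <- matrix(NA_real_, length(theta), length(theta),
                       dimnames = list(theta_labels, theta_labels))
  if (!is.null(H)) {
    Hi <- tryCatch(solve(symmetrize(H)), error = function(e) NULL)
    if (!is.null(Hi)) {
      vcov_theta <- (2 / mult_n) * symmetrize(Hi) * outer(pscale, pscale)
    }
  }
  se <- sqrt(pmax(diag(vcov_theta), 0))

  params <- c(theta, fixed_params)
  sigma <- implied_covariance(spec, params)

  fit <- structure(list(
    spec = spec,
    estimates = theta,
    se = setNames(se, theta_labels),
    p_values = setNames(2 * pnorm(-abs(theta / ifelse(se > 0, se, NA_real_))), theta_labels),
    exog_moments = fixed_params,
    params = params,
    vcov = vcov_theta,
    sample_cov = sample_cov,
    implied_cov = sigma,
    discrepancy = fmin,
    n = n,
    p = p,
    df = model_df(spec),
    chi2_multiplier = chi2_multiplier,
    convergence = list(converged = TRUE, optimizer = optimizer,
                       iterations = unname(iterations),
                       fallback_used = fallback_used,
                       npd_penalties = obj$info$npd)
  ), class = "clpm_fit")
  fit
}

#' @export
print.clpm_fit <- function(x, ...) {
  cat(sprintf(
    "<clpm_fit> %d variables, N = %d, df = %d, F = %.6g (%s%s)\n",
    x$p, x$n, x$df, x$discrepancy, x$convergence$optimizer,
    if (x$convergence$fallback_used) ", fallback" else ""
  ))
  invisible(x)
}

# Standardized coefficient vector for the directed free/fixed edges, as a
# function of the optimized parameter vector (used for the delta method).
std_coef_fun <- function(fit, edge_rows) {
  spec <- fit$spec
  fixed <- fit$exog_moments
  function(theta) {
    params <- c(setNames(theta, names(fit$estimates)), fixed)
    sig <- implied_covariance(spec, params)
    sds <- sqrt(diag(sig))
    ms <- spec_matrices(spec, params)
    vapply(edge_rows, function(k) {
      i <- spec$edges$dst[k]; j <- spec$edges$src[k]
      ms$A[i, j] * sds[j] / sds[i]
    }, numeric(1))
  }
}

# Central-difference Jacobian of f at x (small problems only).
num_jacobian <- function(f, x, eps = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (k in seq_along(x)) {
    h <- eps * max(1, abs(x[k]))
    xp <- x; xp[k] <- xp[k] + h
    xm <- x; xm[k] <- xm[k] - h
    J[, k] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

#' Standardized path coefficients
#'
#' Each directed coefficient is multiplied by the ratio of model-implied
#' standard deviations, `SD(source)/SD(target)`; standard errors are
#' transformed by the first-order delta method on the joint covariance of the
#' optimized parameters. Coefficients whose source or target has (numerically)
#' zero implied variance are flagged.
#'
#' @param fit A converged [fit_clpm()] object.
#' @return Tibble with one row per directed edge: `predictor`, `outcome`,
#'   `label`, unstandardized `estimate`, `std_estimate`, `std_se`, `std_p`,
#'   `flagged`.
#' @export
standardize <- function(fit) {
  if (!inherits(fit, "clpm_fit")) stop_field("fit", "must be a clpm_fit")
  ed <- fit$spec$edges
  rows <- which(ed$type == "directed")
  f <- std_coef_fun(fit, rows)
  theta <- fit$estimates
  std <- f(unname(theta))
  sds <- sqrt(diag(fit$implied_cov))
  flag <- vapply(rows, function(k) {
    sds[ed$src[k]] < 1e-12 || sds[ed$dst[k]] < 1e-12
  }, logical(1))
  std_se <- rep(NA_real_, length(rows))
  if (length(theta) && !anyNA(fit$vcov)) {
    J <- num_jacobian(f, unname(theta))
    std_se <- sqrt(pmax(rowSums((J %*% fit$vcov) * J), 0))
  }
  # unstandardized estimates per edge (fixed edges keep their fixed value)
  est <- ifelse(is.na(ed$value[rows]), unname(fit$params[ed$label[rows]]), ed$value[rows])
  tibble(
    predictor = ed$src[rows],
    outcome = ed$dst[rows],
    label = ed$label[rows],
    estimate = est,
    std_estimate = std,
    std_se = std_se,
    std_p = 2 * pnorm(-abs(std / std_se)),
    flagged = flag
  )
}

#' @rdname fit_clpm
#' @param x A `clpm_fit` object.
#' @param standardized Include standardized estimates (delta-method SEs).
#' @param ... Unused.
#' @method tidy clpm_fit
#' @export
tidy.clpm_fit <- function(x, standardized = TRUE, ...) {
  ed <- x$spec$edges
  rows <- ed$type == "directed"
  lab <- ed$label[rows]
  free <- is.na(ed$value[rows])
  out <- tibble(
    predictor = ed$src[rows],
    outcome = ed$dst[rows],
    label = lab,
    estimate = ifelse(free, unname(x$params[lab]), ed$value[rows]),
    std.error = ifelse(free, unname(x$se[lab]), NA_real_),
    p.value = ifelse(free, unname(x$p_values[lab]), NA_real_)
  )
  if (standardized) {
    out <- left_join(
      out,
      standardize(x) %>% select("predictor", "outcome", "label",
                                "std_estimate", "std_se", "std_p"),
      by = c("predictor", "outcome", "label")
    )
  }
  out
}

#' @rdname fit_clpm
#' @method glance clpm_fit
#' @export
glance.clpm_fit <- function(x, ...) {
  fi <- fit_indices(x)
  tibble(
    n = x$n, p = x$p, df = fi$df, discrepancy = x$discrepancy,
    chi2 = fi$chi2, p_chi2 = fi$p_chi2, srmr = fi$srmr,
    rmsea = fi$rmsea, rmsea_lower = fi$rmsea_lower, rmsea_upper = fi$rmsea_upper,
    bb_nfi = fi$bb_nfi, adequate = fi$adequate,
    optimizer = x$convergence$optimizer,
    fallback_used = x$convergence$fallback_used
  )
}
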