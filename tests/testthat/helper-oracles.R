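# Independent oracles and fixture builders used across the suite.

# Wright path-tracing oracle for the implied covariance: total effects are
# accumulated by exhaustive depth-first enumeration of directed paths (no
# matrix inversion), then combined with the bidirected block:
#   cov(i, j) = sum_{k,l} T[i,k] S[k,l] T[j,l],  T[i,k] = sum over directed
#   paths k -> i of the product of edge coefficients (T[i,i] = 1).
wright_sigma <- function(spec, params) {
  vars <- spec$vars
  p <- length(vars)
  ed <- spec$edges
  val <- ifelse(is.na(ed$value), unname(params[ed$label]), ed$value)
  dir <- ed$type == "directed"
  S <- matrix(0, p, p, dimnames = list(vars, vars))
  for (k in which(!dir)) {
    i <- ed$dst[k]; j <- ed$src[k]
    S[i, j] <- val[k]; S[j, i] <- val[k]
  }
  kids <- lapply(vars, function(v) which(dir & ed$src == v))
  names(kids) <- vars
  Tm <- diag(p); dimnames(Tm) <- list(vars, vars)
  total_into <- function(target, src) {
    # sum over all directed paths src -> target of coefficient products
    tot <- 0
    for (k in kids[[src]]) {
      nxt <- ed$dst[k]
      tot <- tot + val[k] * (if (nxt == target) 1 else total_into(target, nxt))
    }
    tot
  }
  for (i in vars) for (j in vars) if (i != j) Tm[i, j] <- total_into(i, j)
  Tm %*% S %*% t(Tm)
}

# Random acyclic spec over p variables with edge density `dens`; variances
# in [0.5, 2], coefficients in [-0.8, 0.8], occasionally a free covariance
# between the first two source variables.
random_acyclic_spec <- function(p, dens = 0.4, with_cov = FALSE) {
  vars <- paste0("v", seq_len(p))
  rows <- list()
  params <- c()
  for (i in seq_len(p)) {
    lb <- paste0("var_", i)
    rows[[length(rows) + 1L]] <- data.frame(
      src = vars[i], dst = vars[i], type = "bidirected", label = lb, value = NA
    )
    params[lb] <- runif(1, 0.5, 2)
  }
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      if (runif(1) < dens) {
        lb <- paste0("a_", i, "_", j)
        rows[[length(rows) + 1L]] <- data.frame(
          src = vars[i], dst = vars[j], type = "directed", label = lb, value = NA
        )
        params[lb] <- runif(1, -0.8, 0.8)
      }
    }
  }
  if (with_cov && p >= 2) {
    rows[[length(rows) + 1L]] <- data.frame(
      src = vars[1], dst = vars[2], type = "bidirected", label = "c_12", value = NA
    )
    params["c_12"] <- runif(1, -0.3, 0.3)
  }
  list(spec = path_spec(vars, do.call(rbind, rows)), params = params)
}

# Generator config with missingness switched off (complete panels), used
# wherever a test wants the raw structural process.
quiet_config <- function(n, seed, ...) {
  synth_config(n_participants = n, seed = seed,
               dropout_prob = c(0, 0, 0), side_flag_prob = 0, ...)
}

# Config whose generating process is exactly the no-covariate canonical CLPM
# (all covariate effects zero), i.e. the six-variable model is correctly
# specified for the generated data.
nocov_config <- function(n, seed, ...) {
  quiet_config(n, seed,
               covariate_effects_muscle = c(age = 0),
               covariate_effects_bone = c(age = 0), ...)
}

# Two-variable regression spec y ~ x used by estimator-correctness tests.
two_var_spec <- function() {
  path_spec(
    c("x", "y"),
    data.frame(src = c("x", "x", "y"), dst = c("y", "x", "y"),
               type = c("directed", "bidirected", "bidirected"),
               label = c("a", "vx", "vy"), value = NA)
  )
}

canonical_vars <- function(limb = "leg") {
  as.vector(t(outer(c("V0", "V3", "V5"),
                    paste0(limb, c("_LM", "_BMD")), paste, sep = "_")))
}
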