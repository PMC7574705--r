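#' Construct an observed-variable path model specification
#'
#' A path model is held as a variable list plus an edge table. Directed edges
#' carry regression coefficients; bidirected edges carry variances (self
#' edges) and covariances. Edges sharing a parameter `label` are constrained
#' equal; edges with a non-missing `value` are fixed constants. Variables in
#' `exog` form an exogenous block whose variances/covariances are profiled at
#' the sample moments when the model is fitted (their maximum-likelihood
#' solution when every exogenous variable predicts every endogenous one), but
#' they still count as free parameters of the model when degrees of freedom
#' are computed.
#'
#' @param vars Character vector of observed variable names (order is the
#'   order of rows/columns in all matrices).
#' @param edges Data frame with columns `src`, `dst`, `type`
#'   (`"directed"`/`"bidirected"`), `label` (character) and `value` (numeric,
#'   `NA` for free parameters).
#' @param exog Character vector naming the exogenous covariate block (subset
#'   of `vars`).
#' @param start Optional named numeric vector of starting values per label.
#'
#' @return An object of class `path_spec`.
#' @seealso [build_clpm_spec()], [implied_covariance()], [fit_clpm()]
#' @export
path_spec <- function(vars, edges, exog = character(), start = NULL) {
  if (!is.character(vars) || anyDuplicated(vars)) {
    stop_field("vars", "must be a character vector without duplicates")
  }
  edges <- as_tibble(edges)
  needed <- c("src", "dst", "type", "label")
  if (!all(needed %in% names(edges))) {
    stop_field("edges", paste("must contain columns", paste(needed, collapse = ", ")))
  }
  if (!"value" %in% names(edges)) edges$value <- NA_real_
  if (!all(edges$src %in% vars) || !all(edges$dst %in% vars)) {
    stop_field("edges", "src/dst must name declared variables")
  }
  if (!all(edges$type %in% c("directed", "bidirected"))) {
    stop_field("edges", "type must be 'directed' or 'bidirected'")
  }
  if (!all(exog %in% vars)) stop_field("exog", "must be a subset of vars")

  dir <- edges[edges$type == "directed", ]
  if (any(dir$src == dir$dst)) {
    stop_field("edges", "directed self-loops are not allowed")
  }
  # a label maps to one value: all fixed edges under a label agree, and a
  # label is not both fixed and free
  for (lb in unique(edges$label)) {
    v <- edges$value[edges$label == lb]
    if (length(unique(is.na(v))) > 1L || length(unique(v[!is.na(v)])) > 1L) {
      stop_field("edges", sprintf("label '%s' maps to more than one value", lb))
    }
  }
  # every variable has exactly one variance parameter
  self <- edges[edges$type == "bidirected" & edges$src == edges$dst, ]
  nvar <- table(factor(self$src, levels = vars))
  if (any(nvar != 1L)) {
    bad <- names(nvar)[nvar != 1L][1L]
    stop_field("edges", sprintf("variable '%s' must have exactly one variance parameter", bad))
  }
  spec <- structure(
    list(vars = vars, edges = edges, exog = exog, start = start),
    class = "path_spec"
  )
  if (is.null(topological_order(spec))) {
    stop_field("edges", "directed subgraph must be acyclic")
  }
  spec
}

# Kahn topological sort of the directed subgraph; NULL if cyclic.
topological_order <- function(spec) {
  vars <- spec$vars
  dir <- spec$edges[spec$edges$type == "directed", c("src", "dst")]
  indeg <- setNames(integer(length(vars)), vars)
  tab <- table(factor(dir$dst, levels = vars))
  indeg[names(tab)] <- as.integer(tab)
  out <- character(0)
  ready <- names(indeg)[indeg == 0L]
  while (length(ready)) {
    v <- ready[1L]; ready <- ready[-1L]
    out <- c(out, v)
    hit <- dir$dst[dir$src == v]
    for (w in unique(hit)) {
      indeg[w] <- indeg[w] - sum(hit == w)
      if (indeg[w] == 0L) ready <- c(ready, w)
    }
  }
  if (length(out) == length(vars)) out else NULL
}

#' @export
print.path_spec <- function(x, ...) {
  nfree <- length(free_labels(x))
  cat(sprintf(
    "<path_spec> %d variables, %d edges (%d free labels, %d exogenous)\n",
    length(x$vars), nrow(x$edges), nfree, length(x$exog)
  ))
  invisible(x)
}

#' Distinct free parameter labels of a specification
#'
#' @param spec A [path_spec()].
#' @return Character vector of labels with no fixed value.
#' @export
free_labels <- function(spec) {
  unique(spec$edges$label[is.na(spec$edges$value)])
}

#' Model degrees of freedom
#'
#' Degrees of freedom of the covariance structure: `p(p+1)/2` distinct sample
#' moments minus the number of distinct free parameter labels. Negative df
#' means the model is under-identified and is an error.
#'
#' @param spec A [path_spec()].
#' @return Integer degrees of freedom.
#' @export
model_df <- function(spec) {
  p <- length(spec$vars)
  df <- p * (p + 1) / 2 - length(free_labels(spec))
  if (df < 0) {
    abort(sprintf("Model is under-identified: df = %d < 0", df),
          class = "musclebone_error")
  }
  as.integer(df)
}

#' Canonical three-wave cross-lagged panel model specification
#'
#' Builds the CLPM used throughout the package for one muscle metric and one
#' bone metric measured at three visits: a contemporaneous muscle-to-bone path
#' within each visit (3 free parameters), muscle-to-bone and bone-to-muscle
#' cross-lags for each of the two lag periods (4 free), autoregressive paths
#' sharing one label per construct across the two lags (2 free; the equality
#' constraint that boosts degrees of freedom), one disturbance variance per
#' endogenous variable (6 free), and an exogenous covariate block that is
#' freely inter-covarying with a directed path from every covariate to every
#' endogenous variable.
#'
#' Without covariates the endogenous block alone has 21 sample moments and 15
#' free parameters, hence 6 degrees of freedom; adding covariates leaves the
#' df unchanged. `free_v3_disturbance_cov = TRUE` frees the disturbance
#' covariance between the two 48-month variables, giving df = 5.
#'
#' @param muscle,bone Column stems of the muscle and bone metric (e.g.
#'   `"leg_LM"`, `"leg_BMD"`); visit columns are `<visit>_<stem>`.
#' @param covariates Character vector of baseline covariate column names
#'   (possibly empty). Duplicates are rejected.
#' @param visits Three visit prefixes, baseline first.
#' @param free_v3_disturbance_cov Free the mid-visit muscle-bone disturbance
#'   covariance (reduces df by one).
#'
#' @return A [path_spec()].
#' @examples
#' spec <- build_clpm_spec("leg_LM", "leg_BMD", covariates = c("age", "height"))
#' model_df(spec)
#' @export
build_clpm_spec <- function(muscle, bone, covariates = character(),
                            visits = c("V0", "V3", "V5"),
                            free_v3_disturbance_cov = FALSE) {
  if (!is.character(muscle) || !is.character(bone) || muscle == bone) {
    stop_field("muscle/bone", "must be two distinct column stems")
  }
  if (length(visits) != 3L) stop_field("visits", "exactly three visits required")
  if (anyDuplicated(covariates)) {
    stop_field("covariates", "duplicate covariate names are not allowed")
  }
  m <- paste(visits, muscle, sep = "_")
  b <- paste(visits, bone, sep = "_")
  endo <- c(m[1], b[1], m[2], b[2], m[3], b[3])
  vars <- c(endo, covariates)

  e <- list()
  add <- function(src, dst, type, label, value = NA_real_) {
    tibble(src = src, dst = dst, type = type, label = label, value = value)
  }
  # contemporaneous muscle -> bone, one free coefficient per visit
  for (k in 1:3) e <- c(e, list(add(m[k], b[k], "directed", paste0("beta_", visits[k]))))
  # cross-lags per lag period
  for (k in 1:2) {
    lag <- paste0(visits[k], visits[k + 1])
    e <- c(e, list(
      add(m[k], b[k + 1], "directed", paste0("gMB_", lag)),
      add(b[k], m[k + 1], "directed", paste0("gBM_", lag))
    ))
  }
  # autoregressive paths, equality-constrained across the two lags
  for (k in 1:2) {
    e <- c(e, list(
      add(m[k], m[k + 1], "directed", "ar_muscle"),
      add(b[k], b[k + 1], "directed", "ar_bone")
    ))
  }
  # disturbance variances
  for (v in endo) e <- c(e, list(add(v, v, "bidirected", paste0("v_", v))))
  if (free_v3_disturbance_cov) {
    e <- c(e, list(add(m[2], b[2], "bidirected", "d_V3")))
  }
  # covariate block: path to every endogenous variable, free moments
  for (cv in covariates) {
    for (v in endo) e <- c(e, list(add(cv, v, "directed", paste0("b_", cv, "_", v))))
  }
  if (length(covariates)) {
    for (i in seq_along(covariates)) {
      for (j in i:length(covariates)) {
        e <- c(e, list(add(
          covariates[i], covariates[j], "bidirected",
          paste0("phi_", covariates[i], "_", covariates[j])
        )))
      }
    }
  }
  edges <- bind_rows(e)
  start <- c(ar_muscle = 0.8, ar_bone = 0.8)
  spec <- path_spec(vars, edges, exog = covariates, start = start)
  spec$meta <- list(muscle = muscle, bone = bone, visits = visits,
                    endogenous = endo)
  spec
}

#' Independence (null) model specification
#'
#' All covariances fixed at zero, every variance free: the baseline model of
#' the Bentler-Bonett normed fit index.
#'
#' @param vars Character vector of variable names.
#' @return A [path_spec()].
#' @export
independence_spec <- function(vars) {
  edges <- bind_rows(lapply(vars, function(v) {
    tibble(src = v, dst = v, type = "bidirected",
           label = paste0("v_", v), value = NA_real_)
  }))
  path_spec(vars, edges)
}

#' Saturated model specification
#'
#' Every variance and covariance free; fits any positive-definite sample
#' covariance exactly (df = 0).
#'
#' @param vars Character vector of variable names.
#' @return A [path_spec()].
#' @export
saturated_spec <- function(vars) {
  e <- list()
  for (i in seq_along(vars)) {
    for (j in i:length(vars)) {
      e <- c(e, list(tibble(
        src = vars[i], dst = vars[j], type = "bidirected",
        label = paste0("s_", vars[i], "_", vars[j]), value = NA_real_
      )))
    }
  }
  path_spec(vars, bind_rows(e))
}

#' Serialize a path specification to a plain-text edge list
#'
#' One line per edge: `src -> dst [label]` for directed edges,
#' `src <-> dst [label]` for bidirected; fixed edges append `= value`.
#'
#' @param spec A [path_spec()].
#' @param path Optional file path; when given the lines are written there.
#' @return The character vector of lines, invisibly when `path` is given.
#' @export
spec_to_edgelist <- function(spec, path = NULL) {
  op <- ifelse(spec$edges$type == "directed", "->", "<->")
  lines <- sprintf("%s %s %s [%s]", spec$edges$src, op, spec$edges$dst, spec$edges$label)
  fixed <- !is.na(spec$edges$value)
  lines[fixed] <- sprintf("%s = %g", lines[fixed], spec$edges$value[fixed])
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Read a path specification back from a plain-text edge list
#'
#' Inverse of [spec_to_edgelist()]. Variables are collected in order of first
#' appearance; the exogenous block is not recorded in the text format and may
#' be supplied via `exog`.
#'
#' @param lines Character vector of edge lines, or a file path of length one
#'   pointing at a file written by [spec_to_edgelist()].
#' @param exog Optional exogenous block.
#' @return A [path_spec()].
#' @export
spec_from_edgelist <- function(lines, exog = character()) {
  if (length(lines) == 1L && file.exists(lines)) lines <- readLines(lines)
  pat <- "^(\\S+)\\s+(<->|->)\\s+(\\S+)\\s+\\[([^]]+)\\](\\s*=\\s*(\\S+))?\\s*$"
  ok <- grepl(pat, lines)
  if (!all(ok)) stop_field("lines", sprintf("unparseable edge line: '%s'", lines[!ok][1L]))
  src <- sub(pat, "\\1", lines)
  op <- sub(pat, "\\2", lines)
  dst <- sub(pat, "\\3", lines)
  label <- sub(pat, "\\4", lines)
  val <- sub(pat, "\\6", lines)
  edges <- tibble(
    src = src, dst = dst,
    type = ifelse(op == "->", "directed", "bidirected"),
    label = label,
    value = suppressWarnings(as.numeric(ifelse(val == "", NA, val)))
  )
  vars <- unique(c(rbind(src, dst)))
  path_spec(vars, edges, exog = exog)
}
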