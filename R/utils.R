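# Internal validation helpers. All user-facing errors name the offending field.

stop_field <- function(field, msg) {
  abort(sprintf("Invalid `%s`: %s", field, msg), class = "musclebone_error")
}

check_scalar_number <- function(x, field, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_field(field, "must be a single non-missing number")
  }
  if (finite && !is.finite(x)) stop_field(field, "must be finite")
  invisible(x)
}

check_positive <- function(x, field) {
  check_scalar_number(x, field)
  if (x <= 0) stop_field(field, "must be > 0")
  invisible(x)
}

check_probability <- function(x, field) {
  check_scalar_number(x, field)
  if (x < 0 || x > 1) stop_field(field, "must lie in [0, 1]")
  invisible(x)
}

check_count <- function(x, field, min = 1L) {
  check_scalar_number(x, field)
  if (x < min || x != floor(x)) {
    stop_field(field, sprintf("must be an integer >= %d", min))
  }
  invisible(as.integer(x))
}

# Symmetrize a nearly-symmetric matrix (guards accumulated floating error).
symmetrize <- function(m) (m + t(m)) / 2

`%||%` <- function(x, y) if (is.null(x)) y else x
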