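#' @keywords internal
"_PACKAGE"

# Internal argument-checking helpers. All user-facing errors go through
# stop() with call. = FALSE so messages name the offending quantity, not
# the internal frame.

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE, strict_upper = FALSE) {
  assert_that(is.numeric(x) && length(x) == 1L && is.finite(x),
              sprintf("'%s' must be a single finite number", name))
  if (strict_lower) assert_that(x > lower, sprintf("'%s' must be > %g", name, lower))
  else assert_that(x >= lower, sprintf("'%s' must be >= %g", name, lower))
  if (strict_upper) assert_that(x < upper, sprintf("'%s' must be < %g", name, upper))
  else assert_that(x <= upper, sprintf("'%s' must be <= %g", name, upper))
  invisible(x)
}

assert_columns <- function(df, cols, name = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  assert_that(length(missing) == 0L,
              sprintf("%s is missing required column(s): %s",
                      name, paste(missing, collapse = ", ")))
  invisible(df)
}

# Population (n-denominator) variance and sd; the z-score convention used
# throughout feature standardization.
pop_var <- function(x) mean((x - mean(x))^2)
pop_sd <- function(x) sqrt(pop_var(x))

# Extract slice s of a (slices x rows x cols) array as a matrix, robust to
# singleton row/column dimensions (plain drop = TRUE would collapse them).
get_slice <- function(arr, s) {
  d <- dim(arr)
  matrix(arr[s, , ], d[2], d[3])
}

# Weighted mean / population variance used by balance metrics.
wmean <- function(x, w) sum(w * x) / sum(w)
wvar <- function(x, w) {
  m <- wmean(x, w)
  sum(w * (x - m)^2) / sum(w)
}
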