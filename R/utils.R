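# Internal helpers shared across modules.

# Derive a reproducible stage-specific sub-seed from a master seed.
# Offsets keep generator streams independent; result stays a 32-bit integer.
split_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483629L)
}

# Validate a numeric column of p-values lies in (0, 1]; errors name the
# offending row index so bad input tables are easy to fix.
check_p_column <- function(p, what = "p") {
  bad <- which(!is.finite(p) | p <= 0 | p > 1)
  if (length(bad) > 0) {
    abort(sprintf(
      "%s values must lie in (0, 1]; offending row(s): %s",
      what, paste(head(bad, 5), collapse = ", ")
    ))
  }
  invisible(TRUE)
}

check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(TRUE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
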