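## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_cfg <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

check_scalar_num <- function(x, field, lower = -Inf, upper = Inf,
                             allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_cfg(field, "must be a single finite number")
  if (x < lower || x > upper || (!allow_zero && x == 0))
    stop_cfg(field, sprintf("must be in [%g, %g]%s", lower, upper,
                            if (!allow_zero) " and nonzero" else ""))
  invisible(x)
}

## Logistic helpers used by the bile-acid simulator.
logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

## Row-normalize a non-negative matrix; all-zero rows are returned as zero
## rows and reported via the "empty" attribute.
row_normalize <- function(m) {
  rs <- rowSums(m)
  empty <- rs <= 0
  rs[empty] <- 1
  out <- m / rs
  attr(out, "empty") <- empty
  out
}

## Checksum used by the run manifest (tools::md5sum works on files only).
file_checksum <- function(path) unname(tools::md5sum(path))

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(df)
}
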