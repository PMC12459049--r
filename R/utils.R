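# Internal numerical helpers shared across modules.

# Prefix sums with a leading zero: psum(x)[j + 1] == sum(x[1:j]).
psum <- function(x) c(0, cumsum(x))

# Column-wise prefix sums for a bins x samples matrix; (n + 1) x S.
psum_mat <- function(m) rbind(0, apply(m, 2, cumsum))

# Row medians without a matrixStats dependency.
row_medians <- function(m) apply(m, 1, stats::median)

# Population variance (denominator n), the bin-weight convention.
pop_var <- function(x) {
  mean((x - mean(x))^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn_fmt <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
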