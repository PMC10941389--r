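# Internal helpers shared across modules.

# Shortest interval containing `prob` posterior mass of a sample.
hpd_interval <- function(x, prob = 0.95) {
  stopifnot(is.numeric(x), length(x) >= 2, prob > 0, prob < 1)
  xs <- sort(x)
  n <- length(xs)
  k <- ceiling(prob * n)
  if (k >= n) {
    return(c(lower = xs[1], upper = xs[n]))
  }
  starts <- seq_len(n - k)
  widths <- xs[starts + k] - xs[starts]
  i <- which.min(widths)
  c(lower = xs[i], upper = xs[i + k])
}

# Tukey fences on a single pass over the input distribution; "beyond" is
# strict, so values exactly at a fence are kept.
tukey_outliers <- function(x) {
  q <- quantile(x, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  iqr <- q[2] - q[1]
  !is.na(x) & (x < q[1] - 1.5 * iqr | x > q[2] + 1.5 * iqr)
}

# Deterministic per-stage seed derivation, kept below 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1013L * as.integer(offset)) %% 2147483647L
}

assert_cols <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing column(s): %s", what,
                  paste(missing, collapse = ", ")))
  }
  invisible(data)
}
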