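# rolling median over runs of exactly m consecutive values; returns one
# median per run start (length n - m + 1)
running_median <- function(x, m) {
  n <- length(x)
  if (m > n) stop("run length exceeds number of values")
  if (m == 1L) return(x)
  vapply(seq_len(n - m + 1L), function(i) {
    stats::median(x[i:(i + m - 1L)])
  }, numeric(1))
}

# linear interpolation of y (defined at xs, NAs allowed) onto xout,
# constant extrapolation at the ends
interp_na <- function(xs, y, xout) {
  ok <- !is.na(y)
  if (sum(ok) < 2L) return(rep(if (any(ok)) y[ok][1] else NA_real_,
                               length(xout)))
  stats::approx(xs[ok], y[ok], xout = xout, rule = 2)$y
}

`%||%` <- function(a, b) if (is.null(a)) b else a
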