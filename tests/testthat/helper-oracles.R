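# Independent oracles used across test files.

# Horner-scheme polynomial evaluation, coefficients in increasing degree.
horner <- function(coefs, x) {
  out <- rep(0, length(x))
  for (c_ in rev(coefs)) out <- out * x + c_
  out
}

# Construct n raw observations with exactly the given sample mean and
# sample SD (used to cross-check the summary-statistic likelihood against
# a raw Gaussian likelihood).
raw_obs <- function(mean, sd, n) {
  z <- seq_len(n) - (n + 1) / 2          # symmetric, nonconstant
  z <- z / stats::sd(z)                  # unit sample SD, zero mean
  mean + sd * z
}

ref_gompertz <- c(0.0018282, 1.1735, 0.077577)  # fetal total-mass curve
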