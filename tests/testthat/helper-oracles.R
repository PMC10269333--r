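## Shared oracle helpers for the test suite.

RT300 <- 0.0083145 * 300

## Kolmogorov-Smirnov distance between samples and the Boltzmann distribution
## of a 1D potential, with the reference CDF built by dense quadrature.
ks_against_potential <- function(samples, u_fn, x_lo, x_hi, RT, n = 20001) {
  xg <- seq(x_lo, x_hi, length.out = n)
  lw <- -u_fn(xg) / RT
  w <- exp(lw - max(lw))
  cdf <- cumsum(w)
  cdf <- cdf / cdf[length(cdf)]
  s <- sort(samples)
  F_ref <- stats::approx(xg, cdf, xout = s, rule = 2)$y
  i <- seq_along(s)
  max(abs(F_ref - i / length(s)), abs(F_ref - (i - 1) / length(s)))
}

## Analytic energies of the displaced harmonic pair fixture used in several
## tests (written out independently of the package internals).
pair_state_energies <- function(x, k, d, delta_e) {
  cbind(0.5 * k * x^2, 0.5 * k * (x - d)^2 + delta_e)
}
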