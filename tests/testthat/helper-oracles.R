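# Independent oracles used across the test files.

# Forward-simulate the single-turnover induction by numerically integrating
# dC/dt = sigma * i(t) * (1 - C) / (1 - p*C) with deSolve (lsoda), treating
# the flux as piecewise constant over the interval ending at each sample.
# Independent of the closed-form/implicit solution used by the package.
ode_st_oracle <- function(time_us, flux, F0, Fmax, sigma, p = 0) {
  rate_at <- stats::approxfun(c(0, time_us), c(flux[1], flux),
                              method = "constant", f = 1, rule = 2)
  deriv <- function(t, y, parms) {
    list(sigma * rate_at(t) * (1 - y[1]) / (1 - p * y[1]))
  }
  sol <- deSolve::lsoda(c(C = 0), times = c(0, time_us), func = deriv,
                        parms = NULL, rtol = 1e-10, atol = 1e-12)
  C <- sol[-1, "C"]
  F0 + (Fmax - F0) * C
}

# Random valid light-regulated yield triples (Fo' < F' <= Fm').
random_yields <- function(n) {
  Fm_prime <- stats::runif(n, 100, 1000)
  Fo_prime <- Fm_prime * stats::runif(n, 0.05, 0.9)
  F_prime <- Fo_prime + (Fm_prime - Fo_prime) * stats::runif(n)
  data.frame(Fo_prime = Fo_prime, F_prime = F_prime, Fm_prime = Fm_prime)
}
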