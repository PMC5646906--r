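## Shared fixtures for the test suite. All randomness uses fixed seeds
## chosen up front; sizes are desk scale (seconds to a few minutes).

## constant intensity c on [0, T] at step delta
const_grid <- function(c, T_, delta = 0.1) {
  intensity_grid(rep(c, as.integer(round(T_ / delta)) + 1L), delta)
}

## the oscillating reference intensity on [0, T]
xdet_grid <- function(T_ = 16 * pi, delta = 0.1) {
  reference_intensity("x_det", n = as.integer(round(T_ / delta)),
                      delta = delta)
}

## reduced hyperparameter grid that keeps single-cell fits around a second
small_config <- function(...) {
  fit_config(gamma_grid = c(2, 4, 6, 9, 14),
             kappa_grid = c(0.05, 0.2, 1),
             sigma_f_grid = c(0.5, 1.5), ...)
}

## independent left-rule quadrature oracle (straight loop, no package code)
oracle_left_integral <- function(values, delta, ia, ib) {
  s <- 0
  k <- ia
  while (k < ib) { s <- s + values[k + 1L]; k <- k + 1L }
  s * delta
}
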