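## Surrogate spike-sequence generation from an intensity function.
##
## All three algorithms draw in continuous time where applicable and then
## snap events to the simulation grid (at most one spike per frame), which
## keeps generated sequences consistent with the gridded likelihood in which
## spike times are integer multiples of delta.

## first t > lp*delta with cumulative left-rule integral from lp equal to v;
## NA if the target is not reached inside the window
.invert_cum <- function(chX, xvals, lp, v, delta, n) {
  if (v <= 0) return(lp * delta)
  base <- chX[lp + 1L]
  nodes <- (lp + 1L):(n + 1L)          # node indices k+1 for k = lp+1 .. n
  cum <- chX[nodes] - base
  hit <- which(cum >= v)[1L]
  if (is.na(hit)) return(NA_real_)
  kb <- lp + hit - 2L                  # event lies in bin [kb*delta, (kb+1)*delta)
  prev <- cum[hit - 1L]                # cumulative at the bin's left node
  kb * delta + (v - prev) / xvals[kb + 1L]
}

#' Simulate one spike sequence from an intensity function
#'
#' Generates a spike sequence on `[0, T]` (`T = n * delta` of the grid) under
#' the chosen ISI family, by one of three interchangeable algorithms:
#'
#' * `"inverse"` — each ISI is drawn by inverting the conditional CDF
#'   implied by [isi_density()] via bisection to `delta/10` resolution;
#' * `"bernoulli"` — a per-frame coin flip with success probability
#'   `min(q * delta, 1)` where `q` is the [conditional_intensity()]; a
#'   warning reports the maximum `q * delta` when it exceeds 0.1 (the
#'   discretisation is then coarse);
#' * `"rescaling"` — unit-scale renewal draws in rescaled time mapped back
#'   through the inverse of the cumulative intensity (time-rescaling).
#'
#' The first spike is drawn from the inhomogeneous Poisson first-passage form
#' for every family, matching the likelihood's boundary term; sequences are
#' right-censored at `T`.
#'
#' @param x an [intensity_grid()].
#' @param model an [isi_model()].
#' @param method `"inverse"`, `"bernoulli"` or `"rescaling"`.
#' @param seed mandatory integer seed.
#' @param cell_id label for the returned sequence.
#' @return A [spike_seq()] with times on the grid of `x`.
#' @examples
#' x <- intensity_grid(rep(2, 501), 0.1)
#' y <- simulate_sequence(x, isi_model("IP"), "rescaling", seed = 1)
#' @export
simulate_sequence <- function(x, model,
                              method = c("inverse", "bernoulli", "rescaling"),
                              seed, cell_id = "sim") {
  stopifnot(inherits(x, "intensity_grid"), inherits(model, "isi_model"))
  method <- match.arg(method)
  if (missing(seed)) stop("an explicit seed is required")
  set.seed(seed)
  n <- x$n; delta <- x$delta; T_ <- n * delta
  chX <- .cum_rescale(x)
  ip <- isi_model("IP")
  times <- integer(0)   # spike node indices
  l_last <- 0L
  first <- TRUE

  if (method == "bernoulli") {
    max_qd <- 0
    for (k in seq_len(n)) {
      mdl <- if (first) ip else model
      X <- chX[k + 1L] - chX[l_last + 1L]
      ls <- .renewal_logsurv(X, mdl)
      q <- if (ls < log(1e-300)) {
        x$values[k + 1L] * .renewal_hazard_limit(mdl)
      } else x$values[k + 1L] * exp(.renewal_logpdf(X, mdl) - ls)
      p <- min(q * delta, 1)
      max_qd <- max(max_qd, q * delta)
      if (stats::runif(1L) < p) {
        times <- c(times, k)
        l_last <- k
        first <- FALSE
      }
    }
    if (max_qd > 0.1)
      warning(sprintf("bernoulli discretisation is coarse: max q*delta = %.3g",
                      max_qd))
  } else {
    repeat {
      mdl <- if (first) ip else model
      if (method == "rescaling") {
        v <- .renewal_rand(1L, mdl)
        t_new <- .invert_cum(chX, x$values, l_last, v, delta, n)
      } else {  # inverse: bisection on the conditional CDF
        u <- stats::runif(1L)
        Xtot <- chX[n + 1L] - chX[l_last + 1L]
        if (u >= -expm1(.renewal_logsurv(Xtot, mdl))) {
          t_new <- NA_real_
        } else {
          lo <- l_last * delta; hi <- T_
          cdf <- function(t) {
            k <- floor(t / delta)
            Xc <- (chX[min(k, n) + 1L] - chX[l_last + 1L]) +
              if (k < n) (t - k * delta) * x$values[k + 1L] else 0
            -expm1(.renewal_logsurv(Xc, mdl))
          }
          while (hi - lo > delta / 10) {
            mid <- (lo + hi) / 2
            if (cdf(mid) < u) lo <- mid else hi <- mid
          }
          t_new <- (lo + hi) / 2
        }
      }
      if (is.na(t_new)) break
      l_new <- max(as.integer(round(t_new / delta)), l_last + 1L)
      if (l_new > n) break
      times <- c(times, l_new)
      l_last <- l_new
      first <- FALSE
    }
  }
  spike_seq(times * delta, t_end = T_, delta = delta, cell_id = cell_id)
}

#' Simulate an ensemble of spike sequences
#'
#' `m` independent sequences from a common intensity; per-sequence seeds are
#' derived from the base seed (and recorded in the `"seeds"` attribute) so
#' the ensemble is reproducible and its members independent.
#'
#' @inheritParams simulate_sequence
#' @param m number of sequences (>= 1).
#' @return A list of [spike_seq()] objects with cell ids `sim001`, ...
#' @export
simulate_ensemble <- function(x, model,
                              method = c("inverse", "bernoulli", "rescaling"),
                              m, seed) {
  method <- match.arg(method)
  stopifnot(m >= 1)
  seeds <- .derive_seeds(seed, m)
  out <- lapply(seq_len(m), function(i)
    simulate_sequence(x, model, method, seed = seeds[i],
                      cell_id = sprintf("sim%03d", i)))
  attr(out, "seeds") <- seeds
  out
}
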