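## Renewal ISI families in rescaled (dimensionless) time.
##
## Every family is specified through the density g(v) of a unit-scale renewal
## process on v > 0:
##   IP  -> Exp(1)
##   IG  -> Gamma(shape gamma, rate gamma)        (mean 1)
##   IIG -> inverse Gaussian(mean alpha, lambda = 1)
## The observed-time ISI density is p(y_i, y_{i-1} | x) = x(y_i) g(X) with
## X the rescaled duration between the two spikes, so every density, hazard
## and survival computation reduces to the unit-scale family plus X.

.renewal_logpdf <- function(v, model) {
  switch(model$family,
    IP  = -v,
    IG  = stats::dgamma(v, shape = model$shape, rate = model$shape, log = TRUE),
    IIG = {
      a <- model$shape
      -0.5 * log(2 * pi * v^3) - (v - a)^2 / (2 * a^2 * v)
    })
}

## log survival 1 - G(v); stable in the far tail
.renewal_logsurv <- function(v, model) {
  switch(model$family,
    IP  = -v,
    IG  = stats::pgamma(v, shape = model$shape, rate = model$shape,
                        lower.tail = FALSE, log.p = TRUE),
    IIG = {
      a <- model$shape
      out <- numeric(length(v))
      pos <- v > 0
      vv <- v[pos]
      la <- stats::pnorm(-(vv / a - 1) / sqrt(vv), log.p = TRUE)
      lb <- stats::pnorm(-(vv / a + 1) / sqrt(vv), log.p = TRUE)
      ## S = Phi(-a1) - e^{2/a} Phi(-b1); the second term is always smaller
      r <- exp(pmin(2 / a + lb - la, 0))
      out[pos] <- la + log1p(-r)
      out[!pos] <- 0
      out
    })
}

.renewal_cumhaz <- function(v, model) -.renewal_logsurv(v, model)

## first and second derivatives of log g(v) w.r.t. v (used by the Newton MAP)
.renewal_dlogpdf <- function(v, model) {
  switch(model$family,
    IP  = rep(-1, length(v)),
    IG  = (model$shape - 1) / v - model$shape,
    IIG = {
      a <- model$shape
      -1.5 / v - 1 / (2 * a^2) + 1 / (2 * v^2)
    })
}

.renewal_d2logpdf <- function(v, model) {
  switch(model$family,
    IP  = rep(0, length(v)),
    IG  = -(model$shape - 1) / v^2,
    IIG = 1.5 / v^2 - 1 / v^3)
}

## quantile of the unit-scale family
.renewal_quantile <- function(p, model) {
  switch(model$family,
    IP  = stats::qexp(p),
    IG  = stats::qgamma(p, shape = model$shape, rate = model$shape),
    IIG = vapply(p, function(pp) {
      if (pp <= 0) return(0)
      f <- function(v) .renewal_logsurv(v, model) - log1p(-pp)
      up <- 1
      while (f(up) > 0 && up < 1e6) up <- up * 2
      stats::uniroot(f, c(1e-12, up), tol = 1e-10)$root
    }, numeric(1L)))
}

## random unit-scale ISIs; inverse Gaussian via Michael-Schucany-Haas
.renewal_rand <- function(n, model) {
  switch(model$family,
    IP  = stats::rexp(n),
    IG  = stats::rgamma(n, shape = model$shape, rate = model$shape),
    IIG = {
      mu <- model$shape; lam <- 1
      y <- stats::rnorm(n)^2
      xx <- mu + mu^2 * y / (2 * lam) -
        mu / (2 * lam) * sqrt(4 * mu * lam * y + mu^2 * y^2)
      u <- stats::runif(n)
      ifelse(u <= mu / (mu + xx), xx, mu^2 / xx)
    })
}

## asymptotic hazard of the unit-scale family (tail fallback for q)
.renewal_hazard_limit <- function(model) {
  switch(model$family,
    IP  = 1,
    IG  = model$shape,
    IIG = 1 / (2 * model$shape^2))
}

#' Rescaled duration between two times
#'
#' Integrates the intensity over `[a, b)` with the left-rectangle rule on the
#' grid of `x`, giving the dimensionless rescaled duration
#' \eqn{\hat X(a,b) = \Delta \sum_{k=l_a}^{l_b-1} x_k}. The half-open
#' convention makes the quadrature exactly additive over adjacent intervals:
#' `rescale_integral(x, a, c) == rescale_integral(x, a, b) +
#' rescale_integral(x, b, c)`.
#'
#' @param x an [intensity_grid()].
#' @param a,b interval endpoints in seconds, `0 <= a <= b <= T`, on (or
#'   within `delta/2` of) the grid.
#' @return Non-negative rescaled duration.
#' @examples
#' x <- intensity_grid(rep(2, 101), 0.1)
#' rescale_integral(x, 1, 4)  # 6
#' @export
rescale_integral <- function(x, a, b) {
  stopifnot(inherits(x, "intensity_grid"))
  T_ <- x$n * x$delta
  if (a < -1e-9 || b > T_ + x$delta / 2 + 1e-9 || a > b + 1e-9)
    stop("interval endpoints must satisfy 0 <= a <= b <= T")
  ia <- .grid_index(a, x$delta, x$n, "interval endpoint")
  ib <- .grid_index(b, x$delta, x$n, "interval endpoint")
  if (ib <= ia) return(0)
  x$delta * sum(x$values[(ia + 1L):ib])
}

## cumulative left-rule integral on the grid: chX[k+1] = X(0, k*delta)
.cum_rescale <- function(x) c(0, cumsum(x$values[seq_len(x$n)]) * x$delta)

#' ISI probability density conditioned on an intensity
#'
#' Density of the next spike at `y_curr` given the previous spike at
#' `y_prev` under the chosen renewal family and intensity function:
#' \eqn{p(y_i, y_{i-1} | x) = x(y_i)\, g(\hat X(y_{i-1}, y_i))} where `g` is
#' the unit-scale family density. For the `IG` family this is the
#' inhomogeneous Gamma density
#' \eqn{\gamma x(y_i)/\Gamma(\gamma) [\gamma X]^{\gamma-1} e^{-\gamma X}};
#' shape 1 reduces it exactly to the inhomogeneous Poisson form
#' \eqn{x(y_i) e^{-X}}.
#'
#' @param model an [isi_model()].
#' @param x an [intensity_grid()].
#' @param y_prev,y_curr previous and current spike times, `y_prev < y_curr`.
#' @return Probability density per second (non-negative scalar).
#' @examples
#' x <- intensity_grid(rep(1, 101), 0.1)
#' isi_density(isi_model("IP"), x, 1, 2)  # exp(-1)
#' @export
isi_density <- function(model, x, y_prev, y_curr) {
  stopifnot(inherits(model, "isi_model"), inherits(x, "intensity_grid"))
  if (y_prev >= y_curr) stop("y_prev must precede y_curr")
  X <- rescale_integral(x, y_prev, y_curr)
  ic <- .grid_index(y_curr, x$delta, x$n, "spike time")
  x$values[ic + 1L] * exp(.renewal_logpdf(X, model))
}

#' Conditional intensity (hazard) of the next spike
#'
#' Hazard rate \eqn{q(t | y_k, x) = p(t, y_k|x) / (1 - \int_{y_k}^t p)} of a
#' spike at `t` given the last spike at `y_last`. Computed through the
#' unit-scale family hazard evaluated at the rescaled elapsed duration, so
#' that for the `IP` family `q(t | y_last, x) = x(t)` exactly. In the extreme
#' tail where the survival underflows, the hazard is replaced by its
#' asymptotic limit times `x(t)` with a warning.
#'
#' @inheritParams isi_density
#' @param t evaluation time, `t > y_last`.
#' @param y_last time of the most recent spike (0 allowed for the start of
#'   the window).
#' @return Hazard rate per second.
#' @export
conditional_intensity <- function(model, x, t, y_last) {
  stopifnot(inherits(model, "isi_model"), inherits(x, "intensity_grid"))
  if (t <= y_last) stop("t must exceed y_last")
  X <- rescale_integral(x, y_last, t)
  it <- .grid_index(t, x$delta, x$n, "time")
  xv <- x$values[it + 1L]
  ls <- .renewal_logsurv(X, model)
  if (ls < log(1e-300)) {
    warning("survival underflow in conditional intensity; using tail-limit hazard")
    return(xv * .renewal_hazard_limit(model))
  }
  xv * exp(.renewal_logpdf(X, model) - ls)
}

#' Log density of a full spike sequence
#'
#' Joint log probability density of a spike sequence given an intensity
#' function and ISI family. The density factorises into a first-spike term,
#' the interior ISI terms, and a censoring term for the spike-free tail of
#' the observation window; the first and last terms use the inhomogeneous
#' Poisson forms \eqn{p_1(y_1|x) = x(y_1) e^{-\hat X(0, y_1)}} and
#' \eqn{p_T(T, y_N|x) = e^{-\hat X(y_N, T)}} for every family. An empty
#' sequence contributes the pure survival term \eqn{-\hat X(0, T)}.
#'
#' Spike times are snapped to the grid of `x` (they must lie within
#' `delta/2` of a node); the observation window of `y` must match the grid
#' extent.
#'
#' @param y a [spike_seq()].
#' @param x an [intensity_grid()] whose extent `n * delta` equals `y$t_end`.
#' @param model an [isi_model()].
#' @return Finite log density (scalar), `-Inf` if a spike falls in a
#'   zero-intensity bin.
#' @examples
#' x <- intensity_grid(rep(1, 21), 0.1)
#' y <- spike_seq(1, t_end = 2, delta = 0.1)
#' sequence_log_density(y, x, isi_model("IP"))  # -2
#' @export
sequence_log_density <- function(y, x, model) {
  stopifnot(.is_spike_seq(y), inherits(x, "intensity_grid"),
            inherits(model, "isi_model"))
  T_ <- x$n * x$delta
  if (abs(T_ - y$t_end) > x$delta / 2 + 1e-9)
    stop("intensity grid extent does not match the observation window")
  chX <- .cum_rescale(x)
  N <- length(y$times)
  if (N == 0L) return(-chX[x$n + 1L])
  l <- .grid_index(y$times, x$delta, x$n, "spike time")
  if (any(l == 0L)) stop("spike at time 0 is outside the open window")
  xv <- x$values[l + 1L]
  ## first spike (IP form) and censored tail
  ll <- log(xv[1L]) - chX[l[1L] + 1L] - (chX[x$n + 1L] - chX[l[N] + 1L])
  if (N > 1L) {
    Xi <- chX[l[-1L] + 1L] - chX[l[-N] + 1L]
    ll <- ll + sum(log(xv[-1L]) + .renewal_logpdf(Xi, model))
  }
  ll
}
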