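#' Gaussian-process hyperparameters
#'
#' Bundles the squared-exponential kernel parameters with the ISI shape
#' parameter, since both are marginalised together during inference. Units:
#' `mu` and `sigma_f` in events/second, `kappa` in 1/second^2 (inverse
#' squared length scale), `sigma_v2` a dimensionless nugget variance fixed at
#' 1e-4 by default and excluded from hyperparameter optimisation.
#'
#' @param mu prior mean intensity level.
#' @param sigma_f signal standard deviation (> 0).
#' @param kappa smoothness parameter (> 0); larger values give rougher draws.
#' @param sigma_v2 nugget variance added on the diagonal.
#' @param shape optional ISI shape/location parameter carried alongside.
#' @return An object of class `"gp_hyperparams"`.
#' @export
gp_hyperparams <- function(mu, sigma_f, kappa, sigma_v2 = 1e-4, shape = NULL) {
  stopifnot(is.finite(mu), is.finite(sigma_f), is.finite(kappa),
            is.finite(sigma_v2))
  if (sigma_f <= 0) stop("sigma_f must be strictly positive")
  if (kappa <= 0) stop("kappa must be strictly positive")
  if (sigma_v2 < 0) stop("sigma_v2 must be non-negative")
  structure(list(mu = mu, sigma_f = sigma_f, kappa = kappa,
                 sigma_v2 = sigma_v2, shape = shape),
            class = "gp_hyperparams")
}

#' @export
print.gp_hyperparams <- function(x, ...) {
  cat(sprintf("GP hyperparameters: mu = %g, sigma_f = %g, kappa = %g, sigma_v2 = %g%s\n",
              x$mu, x$sigma_f, x$kappa, x$sigma_v2,
              if (!is.null(x$shape)) paste0(", shape = ", signif(x$shape, 4)) else ""))
  invisible(x)
}

#' Squared-exponential covariance
#'
#' \eqn{\Sigma(t_1, t_2) = \sigma_f^2 e^{-\kappa (t_1 - t_2)^2 / 2} +
#' \delta(t_1 - t_2)\, \sigma_v^2}. Vectorised over `t1`/`t2`.
#'
#' @param t1,t2 times in seconds.
#' @param h a [gp_hyperparams()] object.
#' @return Covariance value(s).
#' @examples
#' h <- gp_hyperparams(mu = 2.1, sigma_f = 1.5, kappa = 0.5)
#' se_covariance(0, 0, h)  # sigma_f^2 + sigma_v2
#' @export
se_covariance <- function(t1, t2, h) {
  stopifnot(inherits(h, "gp_hyperparams"))
  d <- t1 - t2
  h$sigma_f^2 * exp(-h$kappa * d^2 / 2) + (abs(d) < 1e-12) * h$sigma_v2
}

#' Gram matrix of the SE kernel on a time grid
#'
#' The nugget keeps the matrix positive definite; if the Cholesky
#' factorisation still fails (pathological grids), the jitter is escalated
#' once before erroring.
#'
#' @param times numeric vector of grid times.
#' @param h a [gp_hyperparams()] object.
#' @return Symmetric positive-definite matrix.
#' @export
gram_matrix <- function(times, h) {
  stopifnot(inherits(h, "gp_hyperparams"))
  d <- outer(times, times, "-")
  K <- h$sigma_f^2 * exp(-h$kappa * d^2 / 2)
  diag(K) <- diag(K) + h$sigma_v2
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) {
    diag(K) <- diag(K) + 1e-8 * h$sigma_f^2
    ch <- chol(K)  # errors if still not PD
  }
  attr(K, "chol") <- ch
  K
}

#' Sample intensity functions from the GP prior
#'
#' Draws realisations of the GP on the grid and rectifies them into valid
#' intensity functions by clipping negative excursions at zero. The fraction
#' of clipped grid points of each draw is recorded in the `"clip_frac"`
#' attribute so heavily clipped draws can be rejected by the caller.
#'
#' @param h a [gp_hyperparams()] object; `h$mu` is the constant prior mean.
#' @param n number of grid steps (grid has `n + 1` points, `T = n * delta`).
#' @param delta grid step in seconds.
#' @param n_samples number of independent draws.
#' @param seed integer seed (mandatory: all randomness is explicit).
#' @param rectify clip negative excursions at zero (default)? Set `FALSE` to
#'   obtain the raw Gaussian draws, whose pointwise moments are exactly
#'   (`mu`, `sigma_f^2 + sigma_v2`); raw draws are returned as plain numeric
#'   vectors since they need not be valid intensities.
#' @return A list of [intensity_grid()] objects, each with a `"clip_frac"`
#'   attribute (or of numeric vectors when `rectify = FALSE`).
#' @examples
#' h <- gp_hyperparams(2.1, 1.5, 0.5)
#' xs <- sample_intensity(h, n = 100, delta = 0.1, n_samples = 3, seed = 1)
#' @export
sample_intensity <- function(h, n, delta, n_samples = 1L, seed,
                             rectify = TRUE) {
  stopifnot(inherits(h, "gp_hyperparams"), n >= 0, delta > 0, n_samples >= 1)
  if (missing(seed)) stop("an explicit seed is required")
  set.seed(seed)
  times <- seq(0, by = delta, length.out = n + 1L)
  K <- gram_matrix(times, h)
  ch <- attr(K, "chol")
  z <- matrix(stats::rnorm((n + 1L) * n_samples), nrow = n + 1L)
  draws <- h$mu + crossprod(ch, z)
  if (!rectify)
    return(lapply(seq_len(n_samples), function(j) draws[, j]))
  lapply(seq_len(n_samples), function(j) {
    v <- draws[, j]
    clipped <- mean(v < 0)
    g <- intensity_grid(pmax(v, 0), delta)
    attr(g, "clip_frac") <- clipped
    g
  })
}

#' Reference intensity functions
#'
#' `"x_det"` is the regularly oscillating test intensity
#' \eqn{x_{det}(t) = 0.5\cos(t) + 0.5\cos(0.5 t) + 1} (non-negative on the
#' real line); `"x_GP"` is a draw from the GP prior through
#' [sample_intensity()].
#'
#' @param name `"x_det"` or `"x_GP"`.
#' @param n,delta grid size and step.
#' @param h hyperparameters, required for `"x_GP"`.
#' @param seed seed, required for `"x_GP"`.
#' @return An [intensity_grid()].
#' @examples
#' x <- reference_intensity("x_det", n = 126, delta = 0.1)
#' @export
reference_intensity <- function(name = c("x_det", "x_GP"), n, delta,
                                h = NULL, seed = NULL) {
  name <- match.arg(name)
  if (name == "x_det") {
    t <- seq(0, by = delta, length.out = n + 1L)
    intensity_grid(0.5 * cos(t) + 0.5 * cos(0.5 * t) + 1, delta)
  } else {
    if (is.null(h) || is.null(seed))
      stop("x_GP requires hyperparameters and a seed")
    sample_intensity(h, n, delta, 1L, seed)[[1L]]
  }
}
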