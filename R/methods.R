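## S3 methods for fitted spikegp_fit objects.

#' @export
print.spikegp_fit <- function(x, ...) {
  nsp <- vapply(x$data, function(s) length(s$times), integer(1L))
  cat("Calcium spike intensity fit (GP prior, Laplace-weighted grid)\n")
  print(x$model)
  cat(sprintf("Sequences: %d (%s spikes), window [0, %g] s, grid delta %g s\n",
              length(x$data), paste(nsp, collapse = "+"),
              x$data[[1L]]$t_end, x$delta))
  best <- which.max(x$weights$weight)
  cat(sprintf("Top hyperparameter weight %.3f at kappa = %.3g, sigma_f = %.3g%s\n",
              x$weights$weight[best], x$weights$kappa[best],
              x$weights$sigma_f[best],
              if (x$family != "IP")
                sprintf(", shape = %.3g", x$weights$shape[best]) else ""))
  cat(sprintf("Marginal MAP intensity in [%.3g, %.3g] events/s\n",
              min(x$x_star$values), max(x$x_star$values)))
  invisible(x)
}

#' @export
summary.spikegp_fit <- function(object, ...) {
  w <- object$weights
  agg <- w[order(-w$weight), , drop = FALSE]
  out <- list(fit = object, top = utils::head(agg, 5L),
              ess = 1 / sum(w$weight^2),
              band_mean_halfwidth = mean((object$ci_upper - object$ci_lower) / 2))
  class(out) <- "summary.spikegp_fit"
  out
}

#' @export
print.summary.spikegp_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("\nEffective number of contributing grid points: %.1f of %d\n",
              x$ess, nrow(x$fit$weights)))
  cat(sprintf("Mean 95%% band half-width: %.3g events/s\n",
              x$band_mean_halfwidth))
  cat("\nTop hyperparameter grid points:\n")
  print(format(x$top[, c("shape", "kappa", "sigma_f", "weight")],
               digits = 3), row.names = FALSE)
  invisible(x)
}

#' @export
coef.spikegp_fit <- function(object, ...) {
  w <- object$weights
  best <- which.max(w$weight)
  out <- c(shape = w$shape[best], kappa = w$kappa[best],
           sigma_f = w$sigma_f[best], mu = w$mu[best])
  if (object$family == "IP") out <- out[-1L]
  out
}

#' @export
fitted.spikegp_fit <- function(object, ...) object$x_star$values

#' Predict the fitted intensity at arbitrary times
#'
#' Linear interpolation of the marginal MAP intensity and its 95% credible
#' band.
#'
#' @param object a `spikegp_fit`.
#' @param times evaluation times (default: the fit grid).
#' @param ... unused.
#' @return Data frame with columns `time`, `estimate`, `lwr`, `upr`.
#' @export
predict.spikegp_fit <- function(object, times = NULL, ...) {
  tg <- object$x_star$times
  if (is.null(times)) times <- tg
  data.frame(
    time = times,
    estimate = stats::approx(tg, object$x_star$values, times, rule = 2)$y,
    lwr = stats::approx(tg, object$ci_lower, times, rule = 2)$y,
    upr = stats::approx(tg, object$ci_upper, times, rule = 2)$y)
}

#' @export
plot.spikegp_fit <- function(x, truth = NULL, ...) {
  tg <- x$x_star$times
  ylim <- range(0, x$ci_upper, if (!is.null(truth)) truth$values)
  plot(tg, x$x_star$values, type = "n", ylim = ylim,
       xlab = "time (s)", ylab = "intensity (events/s)", ...)
  graphics::polygon(c(tg, rev(tg)), c(x$ci_lower, rev(x$ci_upper)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(tg, x$x_star$values, lwd = 2)
  if (!is.null(truth))
    graphics::lines(truth$times, truth$values, col = "red", lty = 2)
  for (s in x$data) graphics::rug(s$times)
  invisible(x)
}

#' Simulate surrogate sequences from a fitted intensity
#'
#' @param object a `spikegp_fit`.
#' @param nsim number of sequences.
#' @param seed mandatory seed.
#' @param method surrogate algorithm, see [simulate_sequence()].
#' @param ... unused.
#' @return A list of [spike_seq()] objects.
#' @export
simulate.spikegp_fit <- function(object, nsim = 1L, seed = NULL,
                                 method = "rescaling", ...) {
  if (is.null(seed)) stop("an explicit seed is required")
  simulate_ensemble(object$x_star, object$model, method, m = nsim,
                    seed = seed)
}

#' Time-rescaling residuals of a fit
#'
#' Rescaled ISIs of the fitted cell(s) under the fitted intensity and ISI
#' model; `"rescaled"` residuals are unit-mean exponential and `"uniform"`
#' residuals are standard uniform when the model is correct, which makes
#' them the natural goodness-of-fit residuals of a point-process fit.
#'
#' @param object a `spikegp_fit`.
#' @param type `"rescaled"` (tau) or `"uniform"` (u).
#' @param ... unused.
#' @return Numeric vector pooled over the fitted sequences (sequences with
#'   fewer than 2 spikes contribute nothing).
#' @export
residuals.spikegp_fit <- function(object, type = c("rescaled", "uniform"),
                                  ...) {
  type <- match.arg(type)
  out <- numeric(0)
  for (s in object$data) {
    if (length(s$times) < 2L) next
    r <- rescale_isis(s, object$x_star, object$model)
    out <- c(out, if (type == "rescaled") r$tau else r$u)
  }
  out
}
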