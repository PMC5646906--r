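## MAP estimation of the intensity under the GP prior, Laplace-weighted
## hyperparameter marginalisation, and the user-facing fitting function.

#' Fitting configuration
#'
#' Collects the hyperparameter grids, optimiser tolerances and data filters
#' used by [fit_intensity()]. The hyperparameter prior is independent uniform
#' over log-spaced grids; `mu` defaults to the empirical rate `N/T` of the
#' data being fitted. The nugget `sigma_v2` is held fixed and excluded from
#' the grid.
#'
#' @param gamma_grid candidate ISI shape values (IG).
#' @param alpha_grid candidate ISI location values (IIG); `NULL` (default)
#'   falls back to `gamma_grid`. A separate grid matters when comparing
#'   families: a well-matched IIG location is typically well below 1 for
#'   regular spiking (the coefficient of variation of the IIG family is
#'   `sqrt(alpha)`), far from useful IG shapes.
#' @param kappa_grid candidate GP smoothness values (1/s^2).
#' @param sigma_f_grid candidate GP signal scales (events/s).
#' @param mu prior mean level; `NULL` (default) uses the empirical rate.
#' @param sigma_v2 fixed nugget variance.
#' @param delta inference grid step in seconds; `NULL` uses the frame
#'   interval of the data.
#' @param min_spikes sequences with no more than this many spikes trigger an
#'   inclusion warning (the population analyses only use cells that spiked
#'   more than 10 times).
#' @param max_iter,tol_grad,tol_obj projected-Newton controls: iteration cap,
#'   convergence thresholds on the projected-gradient infinity norm and on
#'   the relative objective change.
#' @return A list of class `"fit_config"`.
#' @export
fit_config <- function(gamma_grid = exp(seq(log(1), log(20), length.out = 12)),
                       kappa_grid = 10^seq(-3, 1, length.out = 10),
                       sigma_f_grid = exp(seq(log(0.1), log(5), length.out = 8)),
                       alpha_grid = NULL,
                       mu = NULL, sigma_v2 = 1e-4, delta = NULL,
                       min_spikes = 10L, max_iter = 200L,
                       tol_grad = 1e-6, tol_obj = 1e-8) {
  structure(list(gamma_grid = gamma_grid, alpha_grid = alpha_grid,
                 kappa_grid = kappa_grid,
                 sigma_f_grid = sigma_f_grid, mu = mu, sigma_v2 = sigma_v2,
                 delta = delta, min_spikes = min_spikes, max_iter = max_iter,
                 tol_grad = tol_grad, tol_obj = tol_obj),
            class = "fit_config")
}

#' Hyperparameter grid with a normalised uniform prior
#'
#' @param shape,kappa,sigma_f candidate values (Cartesian product is taken);
#'   pass `shape = NA` for the IP family.
#' @param mu prior mean attached to every grid point.
#' @param sigma_v2 fixed nugget variance.
#' @return A data frame of class `"hyper_grid"` with columns `shape`,
#'   `kappa`, `sigma_f`, `mu`, `sigma_v2`, `log_prior`; the log prior
#'   normalises to one over the grid.
#' @export
hyper_grid <- function(shape, kappa, sigma_f, mu, sigma_v2 = 1e-4) {
  g <- expand.grid(shape = shape, kappa = kappa, sigma_f = sigma_f,
                   KEEP.OUT.ATTRS = FALSE)
  g$mu <- mu
  g$sigma_v2 <- sigma_v2
  g$log_prior <- -log(nrow(g))
  class(g) <- c("hyper_grid", class(g))
  g
}

## ---------------------------------------------------------------------------
## Pooled log-likelihood machinery on the inference grid.
##
## For sequences sharing one intensity x on a grid of npts = n + 1 nodes the
## pooled log-likelihood is
##   ll(x) = sum_k c_k log x_k - Delta * b.x + sum_int phi(Delta * (A x)_i)
## with c the spike-bin counts, b the coverage counts of the boundary
## (first-spike and censoring) intervals, A the 0/1 interval-membership
## matrix of the interior ISIs and phi the unit-scale family log density.

.ll_precompute <- function(seqs, delta, n) {
  npts <- n + 1L
  cnt <- numeric(npts)
  bnd <- numeric(npts)
  rows <- list()
  for (s in seqs) {
    if (abs(s$t_end - n * delta) > delta / 2 + 1e-9)
      stop("all sequences must share the observation window of the grid")
    N <- length(s$times)
    if (N == 0L) { bnd[seq_len(n)] <- bnd[seq_len(n)] + 1; next }
    l <- .grid_index(s$times, delta, n, "spike time")
    if (any(l == 0L)) stop("spike at time 0 is outside the open window")
    cnt[l + 1L] <- cnt[l + 1L] + 1
    if (l[1L] >= 1L) bnd[1:l[1L]] <- bnd[1:l[1L]] + 1
    if (l[N] < n) bnd[(l[N] + 1L):n] <- bnd[(l[N] + 1L):n] + 1
    if (N > 1L)
      for (i in 2:N) rows[[length(rows) + 1L]] <- c(l[i - 1L] + 1L, l[i])
  }
  A <- NULL
  if (length(rows)) {
    A <- matrix(0, nrow = length(rows), ncol = npts)
    for (r in seq_along(rows)) A[r, rows[[r]][1L]:rows[[r]][2L]] <- 1
  }
  list(cnt = cnt, bnd = bnd, A = A, delta = delta, npts = npts,
       n_spikes = sum(cnt))
}

.ll_value <- function(xv, pre, model) {
  sp <- pre$cnt > 0
  if (any(xv[sp] <= 0)) return(-Inf)
  v <- sum(pre$cnt[sp] * log(xv[sp])) - pre$delta * sum(pre$bnd * xv)
  if (!is.null(pre$A)) {
    X <- pre$delta * drop(pre$A %*% xv)
    if (any(X <= 0)) return(-Inf)
    v <- v + sum(.renewal_logpdf(X, model))
  }
  v
}

.ll_grad <- function(xv, pre, model) {
  g <- -pre$delta * pre$bnd
  sp <- pre$cnt > 0
  g[sp] <- g[sp] + pre$cnt[sp] / xv[sp]
  if (!is.null(pre$A)) {
    X <- pre$delta * drop(pre$A %*% xv)
    g <- g + pre$delta * drop(crossprod(pre$A, .renewal_dlogpdf(X, model)))
  }
  g
}

.ll_hessian <- function(xv, pre, model) {
  H <- matrix(0, pre$npts, pre$npts)
  sp <- pre$cnt > 0
  dg <- numeric(pre$npts)
  dg[sp] <- -pre$cnt[sp] / xv[sp]^2
  diag(H) <- dg
  if (!is.null(pre$A)) {
    X <- pre$delta * drop(pre$A %*% xv)
    w <- .renewal_d2logpdf(X, model)
    H <- H + pre$delta^2 * crossprod(pre$A * w, pre$A)
  }
  H
}

## ---------------------------------------------------------------------------

#' MAP intensity for fixed hyperparameters
#'
#' Maximises the log posterior \eqn{\log p(y|x,\theta) + \log p(x|\theta)}
#' over the non-negative orthant by projected Newton iterations: negative
#' coordinates are truncated to zero each step, the Newton system is solved
#' on the free set, and a step-halving line search guarantees monotone
#' ascent. Keeping the estimate in the original (rate) parameterisation
#' preserves the exact Laplace algebra used by [laplace_log_weight()] in the
#' interior of the constraint set.
#'
#' @param y a [spike_seq()] or a list of them sharing one observation window
#'   (pooled fits sum the per-sequence log-likelihoods under a common
#'   intensity).
#' @param h a [gp_hyperparams()] object; `h$shape` supplies the ISI shape if
#'   `model` carries none.
#' @param model an [isi_model()].
#' @param delta inference grid step; defaults to the frame interval.
#' @param init optional initial intensity values.
#' @param max_iter,tol_grad,tol_obj optimiser controls, see [fit_config()].
#' @return An [intensity_grid()] with attributes `iterations`, `grad_norm`
#'   (projected-gradient infinity norm), `converged`, and `log_posterior`
#'   (up to the Gaussian normalising constant).
#' @export
map_intensity <- function(y, h, model, delta = NULL, init = NULL,
                          max_iter = 200L, tol_grad = 1e-6, tol_obj = 1e-8) {
  seqs <- .as_seq_list(y)
  stopifnot(inherits(h, "gp_hyperparams"), inherits(model, "isi_model"))
  if (model$family != "IP" && is.null(model$shape) && !is.null(h$shape))
    model <- isi_model(model$family, h$shape)
  if (is.null(delta)) delta <- seqs[[1L]]$delta
  T_ <- seqs[[1L]]$t_end
  n <- as.integer(round(T_ / delta))
  if (n == 0L) {  # zero-length window: prior-only posterior
    out <- intensity_grid(max(h$mu, 0), delta)
    attr(out, "iterations") <- 0L; attr(out, "grad_norm") <- 0
    attr(out, "converged") <- TRUE
    return(out)
  }
  pre <- .ll_precompute(seqs, delta, n)
  times <- seq(0, by = delta, length.out = n + 1L)
  K <- gram_matrix(times, h)
  Qinv <- chol2inv(attr(K, "chol"))
  mu <- rep(h$mu, n + 1L)

  obj <- function(xv) {  # negative log posterior (up to constants)
    ll <- .ll_value(xv, pre, model)
    if (!is.finite(ll)) return(Inf)
    d <- xv - mu
    -ll + 0.5 * sum(d * (Qinv %*% d))
  }
  gr <- function(xv) -.ll_grad(xv, pre, model) + drop(Qinv %*% (xv - mu))

  xv <- if (!is.null(init)) pmax(init, 1e-6) else
    rep(max(h$mu, pre$n_spikes / max(T_, delta), 0.1), n + 1L)
  sp <- pre$cnt > 0
  xv[sp] <- pmax(xv[sp], 1e-3)
  f <- obj(xv)
  converged <- FALSE
  it <- 0L
  gnorm <- Inf
  while (it < max_iter) {
    it <- it + 1L
    g <- gr(xv)
    active <- xv <= 0 & g > 0
    pg <- g; pg[active] <- 0
    gnorm <- max(abs(pg))
    if (gnorm < tol_grad) { converged <- TRUE; break }
    H <- -.ll_hessian(xv, pre, model) + Qinv
    free <- which(!active)
    d <- numeric(length(xv))
    ridge <- 0
    repeat {
      Hf <- H[free, free, drop = FALSE]
      if (ridge > 0) diag(Hf) <- diag(Hf) + ridge
      ch <- tryCatch(chol(Hf), error = function(e) NULL)
      if (!is.null(ch)) {
        d[free] <- -backsolve(ch, forwardsolve(t(ch), g[free]))
        break
      }
      ridge <- if (ridge == 0) 1e-6 * max(diag(H)) else ridge * 10
      if (ridge > 1e12) { d[free] <- -g[free]; break }
    }
    step <- 1
    improved <- FALSE
    for (ls in 1:40) {
      xn <- pmax(xv + step * d, 0)
      fn <- obj(xn)
      if (fn < f - 1e-14 * abs(f)) {
        improved <- TRUE
        rel <- (f - fn) / max(abs(f), 1)
        xv <- xn; f <- fn
        ## stall guard: negligible progress near a stationary point
        if (rel < tol_obj && max(abs(gr(xv))[!active]) < sqrt(tol_grad))
          converged <- TRUE
        break
      }
      step <- step / 2
    }
    if (!improved) converged <- TRUE  # no descent direction left
    if (converged) break
  }
  g <- gr(xv)
  pg <- g; pg[xv <= 0 & g > 0] <- 0
  gnorm <- max(abs(pg))
  if (!converged && it >= max_iter)
    stop(sprintf("MAP did not converge in %d iterations (grad norm %.3g)",
                 it, gnorm))
  out <- intensity_grid(pmax(xv, 0), delta)
  attr(out, "iterations") <- it
  attr(out, "grad_norm") <- gnorm
  attr(out, "converged") <- TRUE
  attr(out, "log_posterior") <- -f
  out
}

#' Laplace-approximated log evidence weight
#'
#' Computes \eqn{\log F(y, x^*_\theta, \theta)} where
#' \eqn{F = p(\theta) p(y|x^*,\theta) p(x^*|\theta) (2\pi)^{n/2}
#' |\Lambda^* + \Sigma^{-1}|^{-1/2}} and
#' \eqn{\Lambda^* = -\nabla_x^2 \log p(y|x^*,\theta)}; `exp(log F)`
#' approximates \eqn{p(\theta) p(y|\theta)} by Laplace's method around the
#' converged MAP point.
#'
#' @param y a [spike_seq()] or list of them.
#' @param x_theta_star converged MAP intensity from [map_intensity()].
#' @param h a [gp_hyperparams()] object.
#' @param model an [isi_model()].
#' @param log_prior log prior mass of this hyperparameter point.
#' @return Finite log weight (scalar).
#' @export
laplace_log_weight <- function(y, x_theta_star, h, model, log_prior = 0) {
  seqs <- .as_seq_list(y)
  stopifnot(inherits(x_theta_star, "intensity_grid"))
  if (model$family != "IP" && is.null(model$shape) && !is.null(h$shape))
    model <- isi_model(model$family, h$shape)
  n <- x_theta_star$n
  delta <- x_theta_star$delta
  pre <- .ll_precompute(seqs, delta, n)
  xv <- x_theta_star$values
  ll <- .ll_value(xv, pre, model)
  K <- gram_matrix(x_theta_star$times, h)
  chK <- attr(K, "chol")
  Qinv <- chol2inv(chK)
  d <- xv - h$mu
  lp_quad <- -0.5 * sum(d * (Qinv %*% d)) - sum(log(diag(chK)))
  Lam <- -.ll_hessian(xv, pre, model)
  M <- Lam + Qinv
  ## at a boundary MAP (coordinates clamped at zero by the non-negativity
  ## constraint) the Gaussian volume lives in the free subspace only; each
  ## clamped dimension contributes no (2 pi)^{1/2} factor
  free <- xv > 0
  chM <- tryCatch(chol(M[free, free, drop = FALSE]), error = function(e)
    stop("Hessian-plus-precision matrix is not positive definite on the ",
         "free set; x_theta_star is not a MAP point"))
  log_prior + ll + lp_quad - sum(log(diag(chM))) -
    0.5 * sum(!free) * log(2 * pi)
}

#' Marginalise the intensity over a hyperparameter grid
#'
#' For each grid point computes the MAP intensity and its Laplace evidence
#' weight, normalises the weights over the grid, and returns the
#' weight-averaged intensity \eqn{x^* \approx \int x^*_\theta p(\theta|y)
#' d\theta} together with a pointwise 95% credible band. The band mixes the
#' per-\eqn{\theta} Laplace variances \eqn{diag[(\Lambda^* +
#' \Sigma^{-1})^{-1}]} with the between-\eqn{\theta} spread of the MAP
#' curves, then clips at zero.
#'
#' @param y a [spike_seq()] or list of them sharing one window.
#' @param grid a [hyper_grid()] data frame.
#' @param model an [isi_model()]; its family is combined with each grid
#'   point's `shape`.
#' @param delta inference grid step; defaults to the data frame interval.
#' @param control optimiser settings from [fit_config()] (only the tolerance
#'   fields are used).
#' @return An object of class `"spikegp_fit"`; see [fit_intensity()].
#' @export
marginalize_hyperparameters <- function(y, grid, model, delta = NULL,
                                        control = fit_config()) {
  seqs <- .as_seq_list(y)
  stopifnot(nrow(grid) >= 1L)
  if (is.null(delta)) delta <- seqs[[1L]]$delta
  npts <- as.integer(round(seqs[[1L]]$t_end / delta)) + 1L
  nth <- nrow(grid)
  logF <- numeric(nth)
  Xmat <- matrix(NA_real_, npts, nth)
  Vmat <- matrix(NA_real_, npts, nth)
  init <- NULL
  for (j in seq_len(nth)) {
    h <- gp_hyperparams(grid$mu[j], grid$sigma_f[j], grid$kappa[j],
                        grid$sigma_v2[j],
                        shape = if (model$family == "IP") NULL else grid$shape[j])
    mj <- if (model$family == "IP") model else
      isi_model(model$family, grid$shape[j])
    xs <- map_intensity(seqs, h, mj, delta = delta, init = init,
                        max_iter = control$max_iter,
                        tol_grad = control$tol_grad,
                        tol_obj = control$tol_obj)
    init <- xs$values  # warm start the next grid point
    Xmat[, j] <- xs$values
    logF[j] <- laplace_log_weight(seqs, xs, h, mj, grid$log_prior[j])
    pre <- .ll_precompute(seqs, delta, xs$n)
    K <- gram_matrix(xs$times, h)
    M <- -.ll_hessian(xs$values, pre, mj) + chol2inv(attr(K, "chol"))
    free <- xs$values > 0
    vj <- numeric(npts)  # clamped coordinates carry no Laplace variance
    vj[free] <- diag(chol2inv(chol(M[free, free, drop = FALSE])))
    Vmat[, j] <- vj
  }
  logZ <- .logsumexp(logF)
  if (!is.finite(logZ))
    stop("all hyperparameter weights underflowed; re-centre the grid")
  w <- exp(logF - logZ)
  x_star <- drop(Xmat %*% w)
  Vmix <- drop((Vmat + Xmat^2) %*% w) - x_star^2
  Vmix <- pmax(Vmix, 0)
  half <- 1.96 * sqrt(Vmix)
  wt <- grid
  wt$logF <- logF
  wt$weight <- w
  best <- which.max(w)
  fitted_model <- if (model$family == "IP") model else
    isi_model(model$family, grid$shape[best])
  structure(list(
    x_star = intensity_grid(pmax(x_star, 0), delta),
    ci_lower = pmax(x_star - half, 0),
    ci_upper = x_star + half,
    weights = wt,
    per_theta = Xmat,
    log_Z = logZ,
    model = fitted_model,
    family = model$family,
    data = seqs,
    delta = delta), class = "spikegp_fit")
}

#' Fit the intensity function of calcium spike sequences
#'
#' The main entry point of the package: given one cell's spike sequence (or
#' several sequences recorded under a shared condition, which are pooled by
#' summing their log-likelihoods under a common intensity), estimates the
#' latent spike-rate/intensity function under an inhomogeneous renewal ISI
#' model with a squared-exponential GP prior. The fit is fully deterministic
#' given its configuration: the ISI shape and GP hyperparameters are
#' marginalised over a finite grid with Laplace-approximated weights rather
#' than sampled.
#'
#' @param y a [spike_seq()] or list of them sharing one observation window.
#' @param family ISI family, `"IG"` (default), `"IP"` or `"IIG"`.
#' @param config a [fit_config()] with grids and tolerances.
#' @return An object of class `"spikegp_fit"` with components `x_star` (the
#'   marginal MAP intensity as an [intensity_grid()]), `ci_lower`/`ci_upper`
#'   (pointwise 95% credible band), `weights` (per-grid-point log evidence
#'   and normalised weight), `per_theta`, `log_Z`, `model` (family with the
#'   highest-weight shape) and the data. Methods: [print.spikegp_fit()],
#'   `summary`, `coef`, `predict`, `fitted`, `plot`, `simulate`,
#'   `residuals`.
#' @examples
#' x <- reference_intensity("x_det", n = 63, delta = 0.2)
#' y <- simulate_sequence(x, isi_model("IG", 5.9), "rescaling", seed = 7)
#' cfg <- fit_config(gamma_grid = c(2, 6, 12), kappa_grid = c(0.1, 1),
#'                   sigma_f_grid = c(0.5, 1.5))
#' fit <- fit_intensity(y, family = "IG", config = cfg)
#' fit
#' @export
fit_intensity <- function(y, family = c("IG", "IP", "IIG"),
                          config = fit_config()) {
  family <- match.arg(family)
  seqs <- .as_seq_list(y)
  nsp <- vapply(seqs, function(s) length(s$times), integer(1L))
  if (any(nsp <= config$min_spikes))
    warning(sprintf("%d sequence(s) with <= %d spikes; population analyses only include cells that spiked more than %d times",
                    sum(nsp <= config$min_spikes), config$min_spikes,
                    config$min_spikes))
  delta <- if (is.null(config$delta)) seqs[[1L]]$delta else config$delta
  T_ <- seqs[[1L]]$t_end
  mu <- if (is.null(config$mu)) sum(nsp) / (length(seqs) * T_) else config$mu
  if (mu <= 0) mu <- 1 / T_  # empty data: one notional spike per window
  shapes <- switch(family,
                   IP = NA,
                   IG = config$gamma_grid,
                   IIG = if (is.null(config$alpha_grid)) config$gamma_grid
                         else config$alpha_grid)
  grid <- hyper_grid(shape = shapes,
                     kappa = config$kappa_grid,
                     sigma_f = config$sigma_f_grid,
                     mu = mu, sigma_v2 = config$sigma_v2)
  ## the IIG rescaled ISI has mean alpha (not 1), so the intensity consistent
  ## with N spikes in [0, T] integrates to alpha * N; anchor the prior mean
  ## accordingly per grid point
  if (family == "IIG") grid$mu <- mu * grid$shape
  stub <- structure(list(family = family, shape = NULL), class = "isi_model")
  fit <- marginalize_hyperparameters(seqs, grid, stub,
                                     delta = delta, control = config)
  fit$config <- config
  fit$call <- match.call()
  fit
}
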