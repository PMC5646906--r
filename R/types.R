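#' Spike sequence
#'
#' Container for one cell's calcium spike sequence: strictly increasing event
#' times inside an observation window `[0, t_end]` recorded at frame interval
#' `delta`. Empty sequences are allowed (the likelihood of observing no spike
#' is well defined).
#'
#' @param times numeric vector of spike times in seconds, strictly increasing,
#'   all in `(0, t_end]`. May be empty.
#' @param t_end observation-window end `T` in seconds (> 0).
#' @param delta frame interval in seconds (> 0); consecutive spikes closer
#'   than `delta` are rejected since events are resolved at the frame rate.
#' @param cell_id optional label carried through tables and reports.
#' @return An object of class `"spike_seq"`.
#' @examples
#' y <- spike_seq(c(1.2, 3.4, 7.8), t_end = 10, delta = 0.1)
#' y
#' @export
spike_seq <- function(times, t_end, delta, cell_id = "cell") {
  times <- as.numeric(times)
  stopifnot(is.numeric(t_end), length(t_end) == 1L, t_end >= 0,
            is.numeric(delta), length(delta) == 1L, delta > 0)
  if (length(times)) {
    if (anyNA(times) || any(!is.finite(times)))
      stop("spike times must be finite")
    if (any(times <= 0) || any(times > t_end + 1e-9))
      stop("spike times must lie in (0, t_end]")
    if (is.unsorted(times, strictly = TRUE))
      stop("spike times must be strictly increasing")
    if (length(times) > 1L && any(diff(times) < delta - 1e-9))
      stop("consecutive spikes closer than the frame interval delta")
  }
  structure(list(times = times, t_end = t_end, delta = delta,
                 cell_id = as.character(cell_id)),
            class = "spike_seq")
}

#' @export
print.spike_seq <- function(x, ...) {
  cat(sprintf("Spike sequence '%s': %d spikes on [0, %g] s (delta = %g s)\n",
              x$cell_id, length(x$times), x$t_end, x$delta))
  if (length(x$times))
    cat("  rate N/T =", signif(length(x$times) / x$t_end, 4), "spikes/s\n")
  invisible(x)
}

#' @export
length.spike_seq <- function(x) length(x$times)

#' Discretised intensity function
#'
#' A non-negative rate \eqn{x_i = x(i\Delta)} sampled on the uniform grid
#' \eqn{i = 0, \dots, n} with \eqn{T = n\Delta}. This is both the latent
#' object recovered by [fit_intensity()] and the input to the surrogate
#' generators.
#'
#' @param values non-negative finite rates (events/second), length `n + 1`.
#' @param delta grid step in seconds.
#' @return An object of class `"intensity_grid"` with fields `values`,
#'   `delta`, `n` and `times`.
#' @examples
#' x <- intensity_grid(rep(2, 101), delta = 0.1)  # constant 2 Hz on [0, 10]
#' @export
intensity_grid <- function(values, delta) {
  values <- as.numeric(values)
  stopifnot(length(values) >= 1L, delta > 0)
  if (anyNA(values) || any(!is.finite(values)))
    stop("intensity values must be finite")
  if (any(values < 0)) stop("intensity values must be non-negative")
  n <- length(values) - 1L
  structure(list(values = values, delta = delta, n = n,
                 times = seq(0, by = delta, length.out = n + 1L)),
            class = "intensity_grid")
}

#' @export
print.intensity_grid <- function(x, ...) {
  cat(sprintf("Intensity grid: %d points on [0, %g] s (delta = %g s), range [%g, %g]\n",
              x$n + 1L, x$n * x$delta, x$delta,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Renewal ISI family
#'
#' Tags one of the three inter-spike-interval families conditioned on an
#' intensity function: inhomogeneous Poisson (`"IP"`), inhomogeneous Gamma
#' (`"IG"`, shape \eqn{\gamma > 0}) or inhomogeneous inverse Gaussian
#' (`"IIG"`, location \eqn{\alpha > 0}). `IG` with shape 1 is identically the
#' `IP` family.
#'
#' @param family one of `"IP"`, `"IG"`, `"IIG"`.
#' @param shape positive shape (`IG`) or location (`IIG`) parameter; ignored
#'   for `IP`.
#' @return An object of class `"isi_model"`.
#' @examples
#' isi_model("IG", shape = 5.9)
#' @export
isi_model <- function(family = c("IP", "IG", "IIG"), shape = NULL) {
  family <- match.arg(family)
  if (family == "IP") {
    shape <- NULL
  } else {
    if (is.null(shape) || !is.numeric(shape) || length(shape) != 1L ||
        !is.finite(shape) || shape <= 0)
      stop(family, " family requires a strictly positive shape parameter")
  }
  structure(list(family = family, shape = shape), class = "isi_model")
}

#' @export
print.isi_model <- function(x, ...) {
  if (x$family == "IP") cat("ISI family: inhomogeneous Poisson\n")
  else cat(sprintf("ISI family: inhomogeneous %s (%s = %g)\n",
                   if (x$family == "IG") "Gamma" else "inverse Gaussian",
                   if (x$family == "IG") "gamma" else "alpha", x$shape))
  invisible(x)
}

## grid index of a time, insisting it sits within delta/2 of a node
.grid_index <- function(t, delta, n, what = "time") {
  i <- round(t / delta)
  off <- abs(t - i * delta)
  if (any(off > delta / 2 + 1e-9))
    stop(what, " not on the intensity grid (offset exceeds delta/2)")
  if (any(off > 1e-9 * pmax(1, abs(t))))
    warning(what, " snapped to the nearest grid node")
  i <- pmin(pmax(i, 0L), n)
  as.integer(i)
}

.is_spike_seq <- function(x) inherits(x, "spike_seq")
.as_seq_list <- function(y) {
  if (.is_spike_seq(y)) list(y)
  else if (is.list(y) && all(vapply(y, .is_spike_seq, logical(1L)))) y
  else stop("expected a spike_seq or a list of spike_seq objects")
}

.logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

## derive per-replicate seeds from a base seed (kept below 2^31)
.derive_seeds <- function(seed, m) {
  set.seed(seed)
  sample.int(.Machine$integer.max, m)
}
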