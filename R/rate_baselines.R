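## Classical spike-rate estimators used as baselines for the GP fit:
## Gaussian kernel smoothing and the peri-stimulus time histogram (PSTH),
## with data-driven bandwidth / bin-width selection, and the normalised L2
## error used to score every estimator against a known rate.

.pooled_times <- function(seqs) {
  seqs <- .as_seq_list(seqs)
  list(times = unlist(lapply(seqs, `[[`, "times")), m = length(seqs),
       t_end = seqs[[1L]]$t_end,
       delta = seqs[[1L]]$delta)
}

#' Kernel-smoothing rate estimate
#'
#' \eqn{r(t) = \frac{1}{m} \sum_j \sum_i f(t - y_{ij}, \sigma)} with a
#' Gaussian kernel \eqn{f}. Kernel tails are not truncated at the window
#' edges and no boundary correction is applied, so the estimate is biased
#' low within a bandwidth of 0 and `T`; its integral over the whole real
#' line equals (total spikes)/m.
#'
#' @param seqs a [spike_seq()] or list of them (same window).
#' @param sigma kernel bandwidth in seconds (> 0).
#' @param n,delta output grid; default to the data frame interval.
#' @return An [intensity_grid()].
#' @export
kernel_rate <- function(seqs, sigma, n = NULL, delta = NULL) {
  p <- .pooled_times(seqs)
  if (sigma <= 0) stop("bandwidth sigma must be strictly positive")
  if (is.null(delta)) delta <- p$delta
  if (is.null(n)) n <- as.integer(round(p$t_end / delta))
  tg <- seq(0, by = delta, length.out = n + 1L)
  vals <- numeric(n + 1L)
  for (y in p$times) vals <- vals + stats::dnorm(tg - y, sd = sigma)
  intensity_grid(vals / p$m, delta)
}

#' PSTH rate estimate
#'
#' Piecewise-constant rate from pooled counts: bins of width `bin_width`
#' anchored at `t = 0`, rate = count / (m * width); the final partial bin is
#' normalised by its true width so the estimate integrates to
#' (total spikes)/m over the window.
#'
#' @inheritParams kernel_rate
#' @param bin_width bin width in seconds (0 < bin_width <= T).
#' @return An [intensity_grid()] sampling the step function at the grid
#'   nodes.
#' @export
psth_rate <- function(seqs, bin_width, n = NULL, delta = NULL) {
  p <- .pooled_times(seqs)
  if (bin_width <= 0) stop("bin_width must be strictly positive")
  if (bin_width > p$t_end) stop("bin_width exceeds the observation window")
  if (is.null(delta)) delta <- p$delta
  if (is.null(n)) n <- as.integer(round(p$t_end / delta))
  edges <- seq(0, p$t_end, by = bin_width)
  if (edges[length(edges)] < p$t_end - 1e-9) edges <- c(edges, p$t_end)
  widths <- diff(edges)
  cnt <- if (length(p$times))
    tabulate(findInterval(pmin(p$times, p$t_end - 1e-12), edges,
                          rightmost.closed = TRUE),
             nbins = length(widths)) else numeric(length(widths))
  rate <- cnt / (p$m * widths)
  tg <- seq(0, by = delta, length.out = n + 1L)
  bin_of <- pmin(findInterval(pmin(tg, p$t_end - 1e-12), edges,
                              rightmost.closed = TRUE), length(widths))
  intensity_grid(rate[pmax(bin_of, 1L)], delta)
}

## leave-one-out L2 risk of the pooled Gaussian-kernel rate estimate
.ks_cost <- function(diffs, n_spk, m, sigma) {
  ## integral term: sum_{s,s'} k_{sigma*sqrt2}(d) includes the diagonal
  intg <- (2 * sum(stats::dnorm(diffs, sd = sigma * sqrt(2))) +
             n_spk * stats::dnorm(0, sd = sigma * sqrt(2))) / m^2
  ## (2/m^2) * sum_{s != s'} k_sigma: each unordered pair appears twice
  cross <- 4 * sum(stats::dnorm(diffs, sd = sigma)) / m^2
  intg - cross
}

#' Data-driven kernel bandwidth
#'
#' Selects the bandwidth minimising an unbiased estimate of the integrated
#' squared error of the pooled kernel rate estimate (leave-one-out
#' cross-validated risk) over a log-spaced candidate grid. The risk depends
#' on the number of pooled sequences, so the selected bandwidth shifts with
#' `m` even for identical pooled spike times.
#'
#' @param seqs a [spike_seq()] or list of them.
#' @param candidates optional bandwidth grid (seconds); defaults to 30
#'   log-spaced values spanning the window from fractions of the mean ISI to
#'   half the window.
#' @return The selected bandwidth, with the candidate grid and costs in
#'   attributes `candidates` and `cost`.
#' @export
optimal_bandwidth <- function(seqs, candidates = NULL) {
  p <- .pooled_times(seqs)
  if (length(p$times) < 2L)
    stop("at least 2 pooled spikes are required to select a bandwidth")
  if (is.null(candidates)) {
    lo <- max(p$t_end / (4 * length(p$times)), p$delta / 2)
    hi <- p$t_end / 2
    candidates <- exp(seq(log(lo), log(hi), length.out = 30L))
  }
  d <- as.vector(stats::dist(p$times))  # unordered pairwise differences
  cost <- vapply(candidates, function(s) .ks_cost(d, length(p$times), p$m, s),
                 numeric(1L))
  out <- candidates[which.min(cost)]
  attr(out, "candidates") <- candidates
  attr(out, "cost") <- cost
  out
}

#' Data-driven PSTH bin width
#'
#' Shimazaki-Shinomoto style bin-width selection: for each candidate width
#' the pooled counts' mean and (biased) variance across bins give the cost
#' \eqn{C(w) = (2\bar k - v) / (m w)^2}, minimised over the candidates.
#'
#' @inheritParams optimal_bandwidth
#' @param candidates optional widths; defaults to `T/2 ... T/50`.
#' @return Selected bin width with attributes `candidates` and `cost`.
#' @export
optimal_bin_width <- function(seqs, candidates = NULL) {
  p <- .pooled_times(seqs)
  if (length(p$times) < 2L)
    stop("at least 2 pooled spikes are required to select a bin width")
  if (is.null(candidates)) candidates <- p$t_end / seq(2L, 50L)
  cost <- vapply(candidates, function(w) {
    edges <- seq(0, p$t_end + w, by = w)
    k <- tabulate(findInterval(p$times, edges, rightmost.closed = TRUE),
                  nbins = length(edges) - 1L)
    kbar <- mean(k); v <- mean((k - kbar)^2)
    (2 * kbar - v) / (p$m * w)^2
  }, numeric(1L))
  out <- candidates[which.min(cost)]
  attr(out, "candidates") <- candidates
  attr(out, "cost") <- cost
  out
}

#' Normalised L2 error between two rates
#'
#' \eqn{L_2 = [\int_0^T (\hat r - \tilde r)^2 dt]^{1/2} / \int_0^T \tilde r\,
#' dt} with left-rule quadrature on the shared grid; dimensionless, zero iff
#' the two rates agree on the grid.
#'
#' @param estimate,truth [intensity_grid()] objects on the same grid; `truth`
#'   is the known reference rate.
#' @return Non-negative scalar.
#' @examples
#' a <- intensity_grid(rep(2, 41), 0.1); b <- intensity_grid(rep(1, 41), 0.1)
#' l2_error(a, b)  # 0.5
#' @export
l2_error <- function(estimate, truth) {
  stopifnot(inherits(estimate, "intensity_grid"), inherits(truth, "intensity_grid"))
  if (estimate$n != truth$n || abs(estimate$delta - truth$delta) > 1e-12)
    stop("estimate and truth must share one grid")
  idx <- seq_len(truth$n)
  den <- truth$delta * sum(truth$values[idx])
  if (den <= 0) stop("reference rate integrates to zero")
  num <- sqrt(truth$delta * sum((estimate$values[idx] - truth$values[idx])^2))
  num / den
}
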