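test_that("rescale_integral matches closed forms and the quadrature oracle", {
  x0 <- const_grid(0, 10)
  expect_identical(rescale_integral(x0, 0, 10), 0)

  x2 <- const_grid(2, 10)
  expect_equal(rescale_integral(x2, 1, 4), 6)

  ## x_det over one slow period: antiderivative 0.5 sin t + sin(t/2) + t
  delta <- 1e-3
  xd <- xdet_grid(2 * pi, delta)
  expect_equal(rescale_integral(xd, 0, 2 * pi), 2 * pi, tolerance = 1e-3)

  ## random grid against the independent loop oracle
  set.seed(42)
  v <- runif(51, 0, 3)
  xr <- intensity_grid(v, 0.2)
  expect_equal(rescale_integral(xr, 0.4, 7.2),
               oracle_left_integral(v, 0.2, 2L, 36L))
})

test_that("rescale_integral is additive and monotone in b", {
  set.seed(7)
  x <- intensity_grid(runif(101, 0, 2), 0.1)
  a <- 0.5; b <- 3.7; cc <- 8.2
  expect_equal(rescale_integral(x, a, cc),
               rescale_integral(x, a, b) + rescale_integral(x, b, cc))
  bs <- seq(1, 10, by = 0.5)
  ints <- vapply(bs, function(b) rescale_integral(x, 0.5, b), numeric(1))
  expect_true(all(diff(ints) >= 0))
})

test_that("rescale_integral rejects bad endpoints and snaps off-node times", {
  x <- const_grid(1, 10)
  expect_error(rescale_integral(x, 4, 2), "a <= b")
  expect_error(rescale_integral(x, -1, 2), "0 <= a")
  expect_error(rescale_integral(x, 0, 11), "b <= T")
  ## off-node times inside delta/2 are snapped with a warning
  expect_warning(rescale_integral(x, 0, 5.03), "snapped")
})

test_that("isi_density matches closed forms", {
  x1 <- const_grid(1, 10)
  expect_equal(isi_density(isi_model("IP"), x1, 1, 2), exp(-1))
  ## IG gamma=2 at X=1: gamma*x/Gamma(2) * (2X)^(2-1) * exp(-2X) = 4 e^-2
  expect_equal(isi_density(isi_model("IG", 2), x1, 0, 1), 4 * exp(-2))
})

test_that("IG with shape 1 is identically IP across density-level operations", {
  set.seed(11)
  x <- intensity_grid(runif(101, 0.2, 3), 0.1)
  ig1 <- isi_model("IG", 1)
  ip <- isi_model("IP")
  for (pair in list(c(0.5, 2.1), c(1.0, 1.4), c(3.3, 9.9))) {
    expect_equal(isi_density(ig1, x, pair[1], pair[2]),
                 isi_density(ip, x, pair[1], pair[2]))
    expect_equal(conditional_intensity(ig1, x, pair[2], pair[1]),
                 conditional_intensity(ip, x, pair[2], pair[1]))
  }
  y <- spike_seq(c(0.5, 2.1, 3.3, 7.7), 10, 0.1)
  expect_equal(sequence_log_density(y, x, ig1),
               sequence_log_density(y, x, ip))
})

test_that("conditional intensity matches hazards and limits", {
  set.seed(3)
  x <- intensity_grid(runif(101, 0.2, 3), 0.1)
  ## IP: hazard equals the intensity itself
  for (tt in c(0.7, 2.5, 6.2))
    expect_equal(conditional_intensity(isi_model("IP"), x, tt, 0.1),
                 x$values[round(tt / 0.1) + 1L])
  ## IG gamma=2, x == 1: Gamma(2, rate 2) hazard 4v/(1+2v) at v = 0.5 -> 1
  x1 <- const_grid(1, 10)
  expect_equal(conditional_intensity(isi_model("IG", 2), x1, 0.5, 0), 1.0)
  ## refractoriness: q -> 0 as t -> y_last+ for gamma > 1
  xf <- const_grid(1, 2, 0.01)
  expect_lt(conditional_intensity(isi_model("IG", 5), xf, 0.01, 0), 1e-3)
  expect_lt(conditional_intensity(isi_model("IIG", 0.5), xf, 0.01, 0), 1e-3)
})

test_that("sequence_log_density closed forms and brute-force oracle", {
  x1 <- const_grid(1, 2)
  y1 <- spike_seq(1, t_end = 2, delta = 0.1)
  expect_equal(sequence_log_density(y1, x1, isi_model("IP")), -2)

  ## empty sequence: pure survival -cT
  y0 <- spike_seq(numeric(0), t_end = 4, delta = 0.1)
  expect_equal(sequence_log_density(y0, const_grid(1.5, 4), isi_model("IP")),
               -6)

  ## IG gamma=6.2, 5 spikes, random intensity: term-by-term oracle
  set.seed(99)
  v <- runif(101, 0.3, 2.5)
  x <- intensity_grid(v, 0.1)
  tms <- c(1.3, 2.8, 4.1, 6.6, 8.0)
  y <- spike_seq(tms, 10, 0.1)
  l <- round(tms / 0.1)
  Xh <- function(ia, ib) oracle_left_integral(v, 0.1, ia, ib)
  ll_o <- log(v[l[1] + 1]) - Xh(0, l[1])            # first spike, IP form
  for (i in 2:5) {
    X <- Xh(l[i - 1], l[i])
    ll_o <- ll_o + log(v[l[i] + 1]) +
      dgamma(X, shape = 6.2, rate = 6.2, log = TRUE)
  }
  ll_o <- ll_o - Xh(l[5], 100)                      # censored tail, IP form
  expect_equal(sequence_log_density(y, x, isi_model("IG", 6.2)), ll_o,
               tolerance = 1e-10)
})

test_that("constant intensity makes isi_density depend only on the lag", {
  x <- const_grid(1.7, 20)
  for (mdl in list(isi_model("IP"), isi_model("IG", 3), isi_model("IIG", 0.5)))
    expect_equal(isi_density(mdl, x, 1, 3.5),
                 isi_density(mdl, x, 11, 13.5))
})

test_that("IIG density and survival match the inverse-Gaussian law", {
  a <- 0.4
  m <- isi_model("IIG", a)
  v <- c(0.1, 0.4, 1.3, 4)
  ## density of IG(mean a, lambda 1): sqrt(1/(2 pi v^3)) exp(-(v-a)^2/(2a^2 v))
  dens <- sqrt(1 / (2 * pi * v^3)) * exp(-(v - a)^2 / (2 * a^2 * v))
  expect_equal(exp(spikegp:::.renewal_logpdf(v, m)), dens, tolerance = 1e-12)
  ## survival oracle by numeric integration of the density
  for (vv in v) {
    S <- 1 - integrate(function(s)
      sqrt(1 / (2 * pi * s^3)) * exp(-(s - a)^2 / (2 * a^2 * s)),
      0, vv, rel.tol = 1e-10)$value
    expect_equal(exp(spikegp:::.renewal_logsurv(vv, m)), S, tolerance = 1e-7)
  }
  ## far tail stays finite (guarded)
  expect_true(is.finite(spikegp:::.renewal_logsurv(1e4, m)))
})

test_that("spike_seq validates its invariants", {
  expect_error(spike_seq(c(2, 1), 10, 0.1), "increasing")
  expect_error(spike_seq(c(1, 1.05), 10, 0.1), "closer than")
  expect_error(spike_seq(c(-1, 2), 10, 0.1), "lie in")
  expect_error(spike_seq(c(1, 11), 10, 0.1), "lie in")
  expect_silent(spike_seq(numeric(0), 10, 0.1))
  expect_error(intensity_grid(c(1, -0.1), 0.1), "non-negative")
  expect_error(isi_model("IG"), "shape")
  expect_error(isi_model("IIG", -2), "shape")
})
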