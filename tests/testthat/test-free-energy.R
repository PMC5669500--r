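test_that("WHAM recovers an analytic double-well to within 0.1 kT RMS", {
  Ffun <- function(x) 5 * (x^2 - 1)^2
  centers <- seq(-1.4, 1.4, by = 0.2)
  k <- 60
  wins <- lapply(seq_along(centers), function(i) {
    list(da0 = centers[i], k = k,
         series = sample_biased(Ffun, centers[i], k, 4000, seed = 100 + i))
  })
  pmf <- wham(wins, n_bins = 120, n_boot = 20, thin = FALSE)
  sup <- pmf$n > 200 & abs(pmf$da) < 1.45
  Fref <- Ffun(pmf$da[sup])
  Fref <- Fref - min(Fref)
  Fg <- pmf$F[sup] - min(pmf$F[sup])
  rms <- sqrt(mean((Fg - Fref)^2))
  expect_lt(rms, 0.1)
  # window overlaps are substantial for this spacing
  expect_true(all(attr(pmf, "overlaps") > 0.1))
})

test_that("degenerate WHAM: a single unbiased window is a log-histogram", {
  Ffun <- function(x) 2 * x^2
  w <- list(list(da0 = 0, k = 0,
                 series = sample_biased(Ffun, 0, 0, 20000, seed = 5)))
  pmf <- wham(w, n_bins = 40, n_boot = 0, thin = FALSE)
  sup <- pmf$n > 300
  h <- -log(pmf$n[sup] / sum(pmf$n))
  expect_equal(pmf$F[sup] - min(pmf$F[sup]), h - min(h), tolerance = 1e-8)
})

test_that("WHAM is stable under binning changes and window deletion", {
  Ffun <- function(x) 5 * (x^2 - 1)^2
  centers <- seq(-1.4, 1.4, by = 0.2)
  wins <- lapply(seq_along(centers), function(i) {
    list(da0 = centers[i], k = 60,
         series = sample_biased(Ffun, centers[i], 60, 4000, seed = 200 + i))
  })
  barrier <- function(pmf) {
    sup <- pmf$n > 100
    d <- pmf$da[sup]; Fv <- pmf$F[sup]
    max(Fv[abs(d) < 0.3]) - min(Fv[d > 0.6])
  }
  b1 <- barrier(wham(wins, n_bins = 100, n_boot = 0, thin = FALSE))
  b2 <- barrier(wham(wins, n_bins = 200, n_boot = 0, thin = FALSE))
  b3 <- barrier(wham(wins[-8], n_bins = 100, n_boot = 0, thin = FALSE))
  expect_equal(b1, b2, tolerance = 0.1)
  expect_equal(b1, b3, tolerance = 0.15)
  expect_equal(b1, 5, tolerance = 0.2)  # analytic barrier height
})

test_that("non-overlapping windows are reported as separate segments", {
  Ffun <- function(x) 2 * x^2
  w1 <- list(da0 = -1.5, k = 400, series = sample_biased(Ffun, -1.5, 400, 2000, seed = 7))
  w2 <- list(da0 = 1.5, k = 400, series = sample_biased(Ffun, 1.5, 400, 2000, seed = 8))
  pmf <- wham(list(w1, w2), n_bins = 80, n_boot = 0, thin = FALSE)
  expect_gt(max(pmf$segment, na.rm = TRUE), 1)
})

test_that("umbrella window machinery biases the area difference", {
  m <- build_icosphere(2)
  mod <- free_vesicle_model(m)
  w <- run_umbrella_window(m, da0 = 1.01, k = 2e5, model = mod,
                           n_sweeps = 600, n_burn = 400, seed = 12)
  expect_length(w$series, 600)
  # strongly biased: the sampled mean sits near the window center
  expect_equal(mean(w$series), 1.01, tolerance = 0.005)
  # a window centered far outside the reachable range is flagged as drifting
  far <- run_umbrella_window(m, da0 = 1.3, k = 2e5, model = mod,
                             n_sweeps = 120, n_burn = 40, seed = 13)
  expect_true(far$drift)
})

test_that("biexponential autocorrelation fit recovers known parameters", {
  # mixture of two AR(1) processes with known relaxation times
  set.seed(33)
  n <- 60000
  tau1 <- 3; tau2 <- 45; wgt <- 0.5
  a1 <- exp(-1 / tau1); a2 <- exp(-1 / tau2)
  x1 <- as.numeric(stats::filter(rnorm(n), a1, method = "recursive"))
  x2 <- as.numeric(stats::filter(rnorm(n), a2, method = "recursive"))
  x1 <- x1 / sd(x1); x2 <- x2 / sd(x2)
  series <- sqrt(wgt) * x1 + sqrt(1 - wgt) * x2
  fit <- autocorr_biexp_fit(series, lag_max = 200)
  expect_equal(fit$w, wgt, tolerance = 0.15)
  expect_equal(fit$t1, tau1, tolerance = 0.35)
  expect_equal(fit$t2, tau2, tolerance = 0.25)
  expect_false(fit$degenerate)
  expect_gte(fit$t2, fit$t1)
})

test_that("biexponential fit flags degenerate single-exponential inputs", {
  set.seed(44)
  n <- 40000
  x <- as.numeric(stats::filter(rnorm(n), exp(-1 / 20), method = "recursive"))
  fit1 <- autocorr_biexp_fit(x, lag_max = 150)
  # both time scales collapse onto ~20 or the weight saturates
  expect_true(fit1$degenerate || abs(fit1$t2 / fit1$t1 - 1) < 0.5)
  wn <- rnorm(20000)
  fit0 <- autocorr_biexp_fit(wn, lag_max = 40)
  expect_lt(fit0$t2, 2)  # white noise decorrelates within a lag or two
})

test_that("Kramers escape time: limits, paper magnitude, monotonicity", {
  expect_equal(kramers_escape_time(2, 0), 4 * pi, tolerance = 1e-12)
  # tau = 0.05 us and H = 21 kT: about 7 minutes
  t_esc <- kramers_escape_time(0.05e-6, 21)   # seconds
  expect_equal(t_esc / 60, 7, tolerance = 0.05)
  # H = 42 kT: far more than one day
  expect_gt(kramers_escape_time(0.05e-6, 42) / 86400, 1)
  H <- seq(0, 30, by = 5)
  expect_true(all(diff(kramers_escape_time(1, H)) > 0))
})
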