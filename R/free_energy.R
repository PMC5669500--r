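#' Run one umbrella-sampling window on the area difference
#'
#' Continues an annealed structure at ambient temperature (T = 1 k_B T)
#' with a harmonic bias `0.5 * k * (da - da0)^2` added to the free-vesicle
#' energy. The stiff area-difference constraint is off during umbrella
#' runs: the bias is the only restraint on the reaction coordinate, so the
#' reweighting is well defined. The per-sweep area-difference time series is
#' recorded and returned.
#'
#' @param mesh starting `trimesh` (typically an SA structure near `da0`).
#' @param da0 window center.
#' @param k bias stiffness in k_B T (default 2e5).
#' @param model `energy_model` (area/volume constraints active; `K_da`
#'   forced to 0 here).
#' @param n_sweeps sampled sweeps.
#' @param n_burn discarded warm-up sweeps.
#' @param widths frozen move widths.
#' @param seed RNG seed.
#' @return object of class `umbrella_window`: `da0`, `k`, `series` (da per
#'   sweep), `mesh` (final), `seed`, plus a `drift` flag when the sample
#'   mean is more than 3 standard deviations from `da0`.
#' @export
run_umbrella_window <- function(mesh, da0, k = 2e5, model = energy_model(),
                                n_sweeps = 2000L, n_burn = 200L,
                                widths = c(0.1, 0.15), seed = 1L) {
  model$K_da <- 0
  if (is.na(model$A_ref)) model$A_ref <- surface_area(mesh)
  if (is.na(model$V_ref)) model$V_ref <- signed_volume(mesh)
  sc <- mc_schedule(n_burn + n_sweeps, temperature = 1,
                    width_vertex = widths[1], width_bead = widths[2],
                    tune = FALSE, stride = 0L, seed = seed)
  r <- run_mc(mesh, model, sc, bias_k = k, bias_c = da0, record_da = TRUE)
  series <- r$da_series[(n_burn + 1):(n_burn + n_sweeps)]
  drift <- abs(mean(series) - da0) > 3 * sd(series)
  structure(list(da0 = da0, k = k, series = series, mesh = r$mesh,
                 seed = seed, drift = drift),
            class = "umbrella_window")
}

#' Weighted histogram analysis method (WHAM)
#'
#' Combines biased samples from harmonic umbrella windows into one
#' potential of mean force along the reaction coordinate, by iterating the
#' self-consistent WHAM equations for the unbiased density and the window
#' free-energy shifts until the shifts change by less than `tol`.
#' Samples are thinned by their integrated autocorrelation time
#' (statistical inefficiency) before histogramming, and bootstrap
#' resampling of whole windows gives error bars. Non-overlapping windows
#' are reported as disconnected segments rather than silently joined.
#'
#' @param windows list of `umbrella_window` objects (or lists with
#'   `da0`, `k`, `series`).
#' @param n_bins histogram bins across the sampled range (default 200).
#' @param tol convergence tolerance on the free-energy shifts (k_B T).
#' @param max_iter iteration cap.
#' @param n_boot bootstrap resamples for error bars (0 = none).
#' @param thin `TRUE` thins each series by its estimated autocorrelation
#'   time; or an integer stride.
#' @return data.frame (class `pmf`): bin center `da`, `F` (k_B T, minimum
#'   at 0), `err` (bootstrap SE, `NA` if `n_boot = 0`), `n` (samples in
#'   bin), `segment` (id of connected support segment). Attributes:
#'   `shifts`, `iterations`, `overlaps` (adjacent-window histogram
#'   overlaps).
#' @export
wham <- function(windows, n_bins = 200L, tol = 1e-8, max_iter = 100000L,
                 n_boot = 100L, thin = TRUE) {
  stopifnot(length(windows) >= 1)
  series <- lapply(windows, function(w) {
    s <- w$series
    if (isTRUE(thin)) {
      g <- statistical_inefficiency(s)
      s[seq(1, length(s), by = max(1L, as.integer(round(g))))]
    } else if (is.numeric(thin)) {
      s[seq(1, length(s), by = max(1L, as.integer(thin)))]
    } else s
  })
  centers <- vapply(windows, `[[`, numeric(1), "da0")
  ks <- vapply(windows, `[[`, numeric(1), "k")
  rng <- range(unlist(series))
  brk <- seq(rng[1] - 1e-12, rng[2] + 1e-12, length.out = n_bins + 1L)
  mid <- (brk[-1] + brk[-length(brk)]) / 2
  counts <- vapply(series, function(s)
    tabulate(findInterval(s, brk, all.inside = TRUE), nbins = n_bins),
    numeric(n_bins))
  core <- function(counts) {
    # log-space iteration: stiff biases make exp(-bias) and the window
    # shifts overflow in linear space
    N <- colSums(counts)
    Htot <- rowSums(counts)
    bias <- vapply(seq_along(centers), function(w)
      0.5 * ks[w] * (mid - centers[w])^2, numeric(n_bins))
    logN <- log(N)
    lHtot <- ifelse(Htot > 0, log(Htot), -Inf)
    f <- numeric(length(centers))
    it <- 0L
    lrho <- NULL
    repeat {
      it <- it + 1L
      M <- sweep(-bias, 2, f + logN, `+`)        # n_bins x W
      mmax <- apply(M, 1, max)
      ldenom <- mmax + log(rowSums(exp(M - mmax)))
      lrho <- lHtot - ldenom
      M2 <- sweep(-bias, 1, lrho, `+`)
      m2 <- apply(M2, 2, max)
      fnew <- -ifelse(is.finite(m2),
                      m2 + log(colSums(exp(sweep(M2, 2, m2)))), -Inf)
      fnew <- fnew - fnew[1]
      if (max(abs(fnew - f)) < tol || it >= max_iter) { f <- fnew; break }
      f <- fnew
    }
    M <- sweep(-bias, 2, f + logN, `+`)
    mmax <- apply(M, 1, max)
    lrho <- lHtot - (mmax + log(rowSums(exp(M - mmax))))
    F_ <- ifelse(is.finite(lrho), -lrho, NA)
    list(F = F_ - min(F_, na.rm = TRUE), f = f, iterations = it)
  }
  main <- core(counts)
  err <- rep(NA_real_, n_bins)
  if (n_boot > 0 && length(windows) > 1) {
    boots <- matrix(NA_real_, n_bins, n_boot)
    for (b in seq_len(n_boot)) {
      res <- vapply(series, function(s) {
        sb <- s[sample.int(length(s), replace = TRUE)]
        tabulate(findInterval(sb, brk, all.inside = TRUE), nbins = n_bins)
      }, numeric(n_bins))
      boots[, b] <- core(res)$F
    }
    err <- apply(boots, 1, sd, na.rm = TRUE)
  }
  # connected support segments
  occ <- rowSums(counts) > 0
  segid <- integer(n_bins); cur <- 0L
  for (i in seq_len(n_bins)) {
    if (occ[i]) {
      if (i == 1 || !occ[i - 1]) cur <- cur + 1L
      segid[i] <- cur
    } else segid[i] <- NA_integer_
  }
  # adjacent-window overlaps (fraction of shared histogram mass)
  ov <- if (length(windows) > 1) {
    ordw <- order(centers)
    vapply(seq_len(length(windows) - 1), function(q) {
      h1 <- counts[, ordw[q]] / sum(counts[, ordw[q]])
      h2 <- counts[, ordw[q + 1]] / sum(counts[, ordw[q + 1]])
      sum(pmin(h1, h2))
    }, numeric(1))
  } else numeric(0)
  out <- data.frame(da = mid, F = main$F, err = err, n = rowSums(counts),
                    segment = segid)
  attr(out, "shifts") <- main$f
  attr(out, "iterations") <- main$iterations
  attr(out, "overlaps") <- ov
  class(out) <- c("pmf", "data.frame")
  out
}

# integrated autocorrelation-based statistical inefficiency g = 1 + 2 tau
statistical_inefficiency <- function(x, c_stop = 0) {
  x <- x - mean(x)
  n <- length(x)
  v <- mean(x^2)
  if (v == 0 || n < 10) return(1)
  g <- 1
  for (t in seq_len(min(n - 1, 2000))) {
    ct <- mean(x[1:(n - t)] * x[(t + 1):n]) / v
    if (ct <= c_stop) break
    g <- g + 2 * ct * (1 - t / n)
  }
  max(1, g)
}

#' Biexponential fit of an autocorrelation function
#'
#' Fits the normalized autocorrelation of a stationary series to
#' `w * exp(-t/t1) + (1 - w) * exp(-t/t2)` with `t2 >= t1`, the form used
#' to separate a fast molecular relaxation from the slow shape-fluctuation
#' time that enters the Kramers escape-time estimate.
#'
#' @param series numeric time series, or a two-column matrix/data.frame of
#'   (lag, autocorrelation) values to fit directly.
#' @param lag_max maximum lag used (default: lag where the ACF first drops
#'   below 0.02, capped at `length/4`).
#' @param dt time per sample (units carried into t1, t2).
#' @return list `w`, `t1`, `t2` (t2 >= t1), `fitted` (data.frame lag, acf,
#'   fit) and `degenerate` (`TRUE` when a single exponential suffices,
#'   w ~ 0 or 1).
#' @export
autocorr_biexp_fit <- function(series, lag_max = NULL, dt = 1) {
  if (is.matrix(series) || is.data.frame(series)) {
    lag <- series[[1]]; ac <- series[[2]]
  } else {
    n <- length(series)
    if (is.null(lag_max)) {
      a0 <- acf(series, lag.max = n %/% 4, plot = FALSE)$acf[, 1, 1]
      below <- which(a0 < 0.02)
      lag_max <- if (length(below)) max(10L, below[1]) else n %/% 4
    }
    a0 <- acf(series, lag.max = lag_max, plot = FALSE)$acf[, 1, 1]
    lag <- (seq_along(a0) - 1) * dt
    ac <- a0
  }
  tau0 <- max(dt, sum(ac[ac > 0]) * dt)
  fit <- tryCatch(minpack.lm::nlsLM(
    ac ~ w * exp(-lag / t1) + (1 - w) * exp(-lag / t2),
    start = list(w = 0.5, t1 = tau0 / 5, t2 = tau0 * 2),
    lower = c(w = 0, t1 = dt / 100, t2 = dt / 100),
    upper = c(w = 1, t1 = Inf, t2 = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # degenerate input (e.g. white noise): report a single time scale
    p <- list(w = 1, t1 = tau0, t2 = tau0)
    return(list(w = 1, t1 = tau0, t2 = tau0,
                fitted = data.frame(lag = lag, acf = ac,
                                    fit = exp(-lag / tau0)),
                degenerate = TRUE))
  }
  p <- as.list(coef(fit))
  if (p$t1 > p$t2) {  # enforce t2 >= t1
    tmp <- p$t1; p$t1 <- p$t2; p$t2 <- tmp
    p$w <- 1 - p$w
  }
  list(w = p$w, t1 = p$t1, t2 = p$t2,
       fitted = data.frame(lag = lag, acf = ac,
                           fit = p$w * exp(-lag / p$t1) +
                                 (1 - p$w) * exp(-lag / p$t2)),
       degenerate = p$w < 0.05 || p$w > 0.95)
}

#' Kramers escape time from a metastable state
#'
#' `t_esc = 2 * pi * tau * exp(H / k_B T)` with `tau` the relaxation time
#' of the slow shape fluctuation and `H` the barrier height in k_B T. A
#' barrier of 21 k_B T with `tau = 0.05` microseconds gives about 7
#' minutes; 42 k_B T gives far more than a day.
#'
#' @param tau relaxation time (any time unit).
#' @param H barrier height in k_B T (>= 0).
#' @return escape time in the unit of `tau`.
#' @export
kramers_escape_time <- function(tau, H) {
  stopifnot(all(tau > 0), all(H >= 0))
  2 * pi * tau * exp(H)
}
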