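#' Plot a shape branch
#'
#' Rescaled bending energy versus area difference with located stationary
#' points marked. Requires ggplot2.
#'
#' @param branch output of `shape_branch_scan`.
#' @return a ggplot object.
#' @export
plot_branch <- function(branch) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  bar <- extract_barriers(branch)
  p <- ggplot2::ggplot(branch, ggplot2::aes(x = da, y = E_b_8pk)) +
    ggplot2::geom_line(color = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = expression(Delta * a),
                  y = expression(E[b] / (8 * pi * kappa)))
  if (nrow(bar$stationary))
    p <- p + ggplot2::geom_point(data = bar$stationary[!is.na(bar$stationary$role), ],
                                 ggplot2::aes(x = da, y = E),
                                 color = "red", size = 3, shape = 1)
  p
}

#' Plot a potential of mean force
#'
#' @param pmf output of `wham`.
#' @return a ggplot object.
#' @export
plot_pmf <- function(pmf) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  d <- pmf[is.finite(pmf$F), ]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = da, y = F)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(Delta * a), y = expression(F / k[B] * T))
  if (any(is.finite(d$err)))
    p <- p + ggplot2::geom_ribbon(ggplot2::aes(ymin = F - err,
                                               ymax = F + err),
                                  alpha = 0.25)
  p
}

#' Plot observable traces of an MC run
#'
#' @param run an `mc_run`.
#' @param vars observable columns to show.
#' @return a ggplot object.
#' @export
plot_observables <- function(run, vars = c("E_b", "A", "V", "da")) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  obs <- run$obs
  long <- do.call(rbind, lapply(vars, function(v)
    data.frame(step = obs$step, variable = v, value = obs[[v]])))
  ggplot2::ggplot(long, ggplot2::aes(x = step, y = value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "MC sweep", y = NULL)
}

utils::globalVariables(c("da", "E_b_8pk", "E", "F", "err", "step", "value"))
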