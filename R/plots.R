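#' Plot the erratic-state occupancy curve
#'
#' Proportion of examinees classified erratic at each item position, with a
#' Monte Carlo 95% band.
#'
#' @param posterior a `joint_posterior` (or the data.frame from
#'   [occupancy_curve()]).
#' @param ... passed to [graphics::plot()].
#' @export
plot_occupancy_curve <- function(posterior, ...) {
  oc <- if (inherits(posterior, "joint_posterior")) occupancy_curve(posterior) else posterior
  graphics::plot(oc$position, oc$prop_erratic, type = "b", pch = 16,
                 ylim = c(0, max(0.05, oc$q975)),
                 xlab = "Item position", ylab = "Proportion in erratic state", ...)
  graphics::lines(oc$position, oc$q025, lty = 3)
  graphics::lines(oc$position, oc$q975, lty = 3)
  invisible(oc)
}

#' Histogram of estimated change points
#'
#' @param posterior a `joint_posterior` fitted with a change-point structure.
#' @param ... passed to [graphics::hist()].
#' @export
plot_changepoints <- function(posterior, ...) {
  if (is.null(posterior$changepoints)) stop("posterior has no change points")
  graphics::hist(posterior$changepoints$k_mode,
                 breaks = seq(0.5, posterior$n_items + 0.5, 1),
                 xlab = "Change point k (posterior mode)", main = "", ...)
  invisible(posterior$changepoints)
}

#' Histogram of residuals after the change point
#'
#' Standardized RT residuals of the cells classified erratic: a negatively
#' skewed distribution with a substantial positive tail indicates that both
#' rapid and protracted unexpected response times occur after the shift.
#'
#' @param posterior a `joint_posterior`.
#' @param dataset the fitted [test_dataset()].
#' @param ... passed to [graphics::hist()].
#' @export
plot_postchange_residuals <- function(posterior, dataset, ...) {
  st <- modal_states(posterior)
  rtfit <- fit_lognormal_rt(log_transform(dataset$response_times))
  rtfit$state_variances <- unname(posterior$sigma2)
  res <- rt_residuals(log_transform(dataset$response_times), rtfit)
  z <- res$standardized[st == 2L]
  z <- z[!is.na(z)]
  if (!length(z)) stop("no erratic cells to plot")
  graphics::hist(z, breaks = 30, xlab = "Standardized residual (erratic cells)",
                 main = "", ...)
  invisible(z)
}

#' Corrected versus whole-test ability estimates
#'
#' Scatter with the identity diagonal: points above the diagonal are
#' examinees whose ability estimate rose once erratic responses were trimmed.
#'
#' @param corrected,original `ability_estimates` (or numeric vectors).
#' @param ... passed to [graphics::plot()].
#' @export
plot_corrected_vs_original <- function(corrected, original, ...) {
  x <- if (is.data.frame(original)) original$eap else original
  y <- if (is.data.frame(corrected)) corrected$eap else corrected
  graphics::plot(x, y, pch = 16, cex = 0.6,
                 xlab = "Whole-test ability (EAP)",
                 ylab = "Corrected ability (EAP, trimmed)", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(data.frame(original = x, corrected = y))
}
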