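#' @export
print.vc_fit <- function(x, ...) {
  cat("Sigmoidal vulnerability curve fit (n =", x$n_obs, ")\n")
  if (!isTRUE(x$converged)) {
    cat("  NOT CONVERGED:", x$message %||% "unknown reason", "\n")
    return(invisible(x))
  }
  cat(sprintf("  P50 (b): %.2f MPa  (SE %.3f, 95%% CI [%.2f, %.2f])\n",
              x$b_MPa, x$b_se, x$ci95_b[1], x$ci95_b[2]))
  cat(sprintf("  slope S: %.2f %%/MPa (SE %.3f, 95%% CI [%.2f, %.2f])\n",
              x$S, x$S_se, x$ci95_S[1], x$ci95_S[2]))
  cat(sprintf("  residual SD: %.2f %%\n", x$residual_sd))
  invisible(x)
}

#' Tidy a vulnerability-curve fit
#'
#' @param x A `vc_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`b`, `S`): `term`,
#'   `estimate`, `std.error`, `conf.low`, `conf.high`.
#' @method tidy vc_fit
#' @export
tidy.vc_fit <- function(x, ...) {
  tibble::tibble(
    term = c("b", "S"),
    estimate = c(x$b_MPa, x$S),
    std.error = c(x$b_se, x$S_se),
    conf.low = c(x$ci95_b[1], x$ci95_S[1]),
    conf.high = c(x$ci95_b[2], x$ci95_S[2])
  )
}

#' One-row summary of a vulnerability-curve fit
#'
#' @param x A `vc_fit`.
#' @param ... Unused.
#' @return A tibble: `p50_MPa`, `slope`, `residual_sd`, `n_obs`, `converged`,
#'   `source`, `label`.
#' @method glance vc_fit
#' @export
glance.vc_fit <- function(x, ...) {
  tibble::tibble(
    p50_MPa = x$b_MPa, slope = x$S, residual_sd = x$residual_sd,
    n_obs = x$n_obs, converged = x$converged,
    source = x$source, label = x$label
  )
}

#' Vulnerability-curve plot (PLC against water potential)
#'
#' Observations, the fitted sigmoid, and a pointwise Wald 95% confidence
#' band for the mean curve (delta method on (b, S)).
#'
#' @param object A converged `vc_fit`.
#' @param n_grid Number of curve evaluation points.
#' @param band Draw the confidence band?
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vc_fit
#' @export
autoplot.vc_fit <- function(object, n_grid = 200, band = TRUE, ...) {
  stopifnot(inherits(object, "vc_fit"))
  if (!isTRUE(object$converged)) abort("cannot plot a non-converged fit")
  rng <- range(object$data$psi_MPa)
  grid <- tibble::tibble(psi_MPa = seq(rng[1], rng[2], length.out = n_grid))
  grid$plc_percent <- predict_plc(object, grid$psi_MPa)
  if (band && !is.null(object$fit)) {
    vc <- tryCatch(stats::vcov(object$fit), error = function(e) NULL)
    if (!is.null(vc)) {
      b <- object$b_MPa; S <- object$S
      p <- grid$plc_percent / 100
      # d PLC/db = 100 p(1-p) S/25 ; d PLC/dS = -100 p(1-p) (psi-b)/25
      gb <- 100 * p * (1 - p) * S / 25
      gS <- -100 * p * (1 - p) * (grid$psi_MPa - b) / 25
      se <- sqrt(pmax(0, gb^2 * vc["b", "b"] + gS^2 * vc["S", "S"] +
                        2 * gb * gS * vc["b", "S"]))
      tcrit <- qt(0.975, object$n_obs - 2)
      grid$lo <- pmax(0, grid$plc_percent - tcrit * se)
      grid$hi <- pmin(100, grid$plc_percent + tcrit * se)
    } else band <- FALSE
  }
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$psi_MPa,
                                          y = .data$plc_percent))
  if (band && !is.null(grid$lo)) {
    p <- p + ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo,
                                               ymax = .data$hi),
                                  alpha = 0.2)
  }
  p +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = object$data) +
    ggplot2::geom_hline(yintercept = 50, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = object$b_MPa, linetype = "dotted") +
    ggplot2::labs(
      x = "Xylem water potential (MPa)",
      y = "Percent loss of conductance (%)",
      title = object$label %||% NULL,
      subtitle = sprintf("P50 = %.2f MPa, S = %.1f %%/MPa",
                         object$b_MPa, object$S)
    ) +
    ggplot2::theme_minimal()
}

#' @export
predict.vc_fit <- function(object, psi_MPa, ...) predict_plc(object, psi_MPa)
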