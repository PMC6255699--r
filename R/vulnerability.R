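#' Fit a sigmoidal vulnerability curve
#'
#' Fits `PLC = 100 / (1 + exp((S/25) * (psi - b)))` to (water potential, PLC)
#' observations by bounded Levenberg--Marquardt nonlinear least squares. `b`
#' is the P50 (the potential at which half the conductance is lost) and `S`
#' the slope of the curve at P50 in percent per MPa. Standard errors are
#' Wald-type, from the Jacobian at the optimum; 95% confidence intervals use
#' the t(n - 2) quantile.
#'
#' PLC scatter around a vulnerability curve is strongly heteroscedastic in
#' practice: points on the saturated tails (PLC near 0 or 100) vary far less
#' than points in the transition region, which carry most of the information
#' about `b`. The default `se = "sandwich"` therefore uses an HC3
#' heteroscedasticity-consistent covariance for the Wald intervals;
#' `se = "classical"` gives the textbook homoscedastic errors.
#'
#' @param data A data frame of observations.
#' @param psi,plc Column names (unquoted) holding the water potential (MPa,
#'   <= 0) and PLC (percent, 0--100). Defaults `psi_MPa`, `plc_percent`.
#' @param se `"sandwich"` (HC3 heteroscedasticity-robust, default) or
#'   `"classical"` (homoscedastic) standard errors.
#' @param source Data provenance label (e.g. `"microct_midrib"`,
#'   `"centrifuge_branch"`); stored on the fit.
#' @param label Free-text species/organ label.
#' @return An object of class `vc_fit`: a list with `b_MPa`, `b_se`, `S`,
#'   `S_se`, `ci95_b`, `ci95_S`, `residual_sd`, `n_obs`, `converged`,
#'   `message`, `data`, and the underlying `nls` object (`fit`). A fit whose
#'   slope collapses to the boundary (unidentifiable data, e.g. all PLC equal)
#'   is returned with `converged = FALSE`, never silently.
#' @examples
#' d <- tibble::tibble(psi_MPa = seq(-0.5, -4, length.out = 10))
#' d$plc_percent <- plc_sigmoid(d$psi_MPa, -2, 50)
#' fit <- fit_vulnerability_curve(d)
#' fit$b_MPa  # -2
#' @export
fit_vulnerability_curve <- function(data, psi = psi_MPa, plc = plc_percent,
                                    se = c("sandwich", "classical"),
                                    source = NA_character_,
                                    label = NA_character_) {
  se <- match.arg(se)
  stopifnot(is.data.frame(data))
  psi_v <- as.numeric(dplyr::pull(data, {{ psi }}))
  plc_v <- as.numeric(dplyr::pull(data, {{ plc }}))
  n <- length(psi_v)
  if (n < 4L) {
    abort("at least 4 observations are required to fit the two-parameter sigmoid with uncertainty")
  }
  if (diff(range(psi_v)) == 0) {
    abort("water potentials are all identical; the curve is unidentifiable")
  }
  if (any(plc_v < 0 | plc_v > 100)) abort("PLC observations must lie in [0, 100]")

  start <- vc_start_values(psi_v, plc_v)
  lower <- c(b = min(psi_v) - 5, S = 1e-6)
  upper <- c(b = 0, S = 500)
  df_fit <- data.frame(psi = psi_v, plc = plc_v)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      plc ~ 100 / (1 + exp((S / 25) * (psi - b))),
      data = df_fit, start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) e
  )

  out <- structure(list(
    b_MPa = NA_real_, b_se = NA_real_, S = NA_real_, S_se = NA_real_,
    ci95_b = c(NA_real_, NA_real_), ci95_S = c(NA_real_, NA_real_),
    residual_sd = NA_real_, n_obs = n, converged = FALSE, message = NULL,
    source = source, label = label,
    data = tibble::tibble(psi_MPa = psi_v, plc_percent = plc_v), fit = NULL
  ), class = "vc_fit")

  if (inherits(fit, "error")) {
    out$message <- paste("optimizer failed:", conditionMessage(fit))
    return(out)
  }

  est <- coef(fit)
  ses <- vc_wald_se(fit, method = se)
  tcrit <- qt(0.975, df = n - 2)
  out$fit <- fit
  out$se_method <- se
  out$b_MPa <- unname(est["b"]); out$b_se <- unname(ses["b"])
  out$S <- unname(est["S"]); out$S_se <- unname(ses["S"])
  out$ci95_b <- out$b_MPa + c(-1, 1) * tcrit * out$b_se
  out$ci95_S <- out$S + c(-1, 1) * tcrit * out$S_se
  out$residual_sd <- summary(fit)$sigma

  at_bound <- out$S <= 1e-4 || out$S >= upper["S"] - 1e-6 ||
    out$b_MPa <= lower["b"] + 1e-6 || out$b_MPa >= -1e-9
  if (at_bound) {
    out$converged <- FALSE
    out$message <- "parameter at bound: slope/P50 unidentifiable from these observations"
  } else if (!isTRUE(fit$convInfo$isConv)) {
    out$converged <- FALSE
    out$message <- fit$convInfo$stopMessage
  } else {
    out$converged <- TRUE
  }
  out
}

# Wald standard errors at the optimum. "classical" assumes homoscedastic
# residuals (sigma^2 (J'J)^-1); "sandwich" is the HC3 leverage-adjusted
# heteroscedasticity-consistent estimator on the nonlinear Jacobian.
vc_wald_se <- function(fit, method = c("sandwich", "classical")) {
  method <- match.arg(method)
  if (method == "classical") {
    sm <- summary(fit)$coefficients
    return(setNames(sm[, "Std. Error"], rownames(sm)))
  }
  J <- fit$m$gradient()
  colnames(J) <- names(coef(fit))
  e <- as.vector(fit$m$resid())
  XtXi <- solve(crossprod(J))
  h <- pmin(rowSums((J %*% XtXi) * J), 0.99)
  u <- J * (e / (1 - h))
  V <- XtXi %*% crossprod(u) %*% XtXi
  setNames(sqrt(diag(V)), colnames(J))
}

# Starting values: b0 where linearly interpolated PLC crosses 50 (fallback
# median psi); S0 from the logit-linearised slope (fallback 30).
vc_start_values <- function(psi, plc) {
  ord <- order(psi)
  ps <- psi[ord]; pl <- plc[ord]
  b0 <- tryCatch({
    cross <- which(diff(sign(pl - 50)) != 0)
    if (length(cross) > 0) {
      i <- cross[1]
      ps[i] + (50 - pl[i]) * (ps[i + 1] - ps[i]) / (pl[i + 1] - pl[i])
    } else median(psi)
  }, error = function(e) median(psi))
  if (!is.finite(b0) || b0 >= 0) b0 <- min(median(psi), -1e-3)

  ok <- plc > 1 & plc < 99
  S0 <- if (sum(ok) >= 3 && diff(range(psi[ok])) > 0) {
    lg <- log(plc[ok] / (100 - plc[ok]))
    sl <- tryCatch(unname(coef(lm(lg ~ psi[ok]))[2]), error = function(e) NA)
    if (is.finite(sl) && sl < 0) -25 * sl else 30
  } else 30
  c(b = b0, S = min(max(S0, 1), 400))
}

#' Predict PLC from a fitted vulnerability curve
#'
#' Evaluates the fitted sigmoid: `predict_plc(fit, fit$b_MPa)` is exactly 50,
#' and `predict_plc(fit, b - d) + predict_plc(fit, b + d) = 100` for any `d`
#' (logistic symmetry).
#'
#' @param fit A converged `vc_fit`.
#' @param psi_MPa Water potential(s) in MPa (vectorised).
#' @return PLC in percent.
#' @export
predict_plc <- function(fit, psi_MPa) {
  stopifnot(inherits(fit, "vc_fit"))
  if (!isTRUE(fit$converged)) abort("cannot predict from a non-converged fit")
  plc_sigmoid(psi_MPa, fit$b_MPa, fit$S)
}

#' P50 difference between two fitted curves
#'
#' Reports `b_a - b_b` rounded to two decimals (table precision). Inputs may
#' be `vc_fit` objects or bare P50 values in MPa.
#'
#' @param fit_a,fit_b `vc_fit` objects or numeric P50 estimates (MPa).
#' @param digits Decimal places for the reported difference.
#' @return The rounded P50 difference in MPa.
#' @export
p50_difference <- function(fit_a, fit_b, digits = 2) {
  round(p50_of(fit_a) - p50_of(fit_b), digits)
}

p50_of <- function(x) {
  if (inherits(x, "vc_fit")) {
    if (!isTRUE(x$converged)) abort("fit has not converged; no usable P50")
    x$b_MPa
  } else if (is.numeric(x) && length(x) == 1L) {
    x
  } else {
    abort("expected a `vc_fit` or a single numeric P50")
  }
}

#' Compare two fits by 95% confidence-interval overlap
#'
#' The difference in a parameter is declared significant iff the two 95%
#' confidence intervals are disjoint; touching or overlapping intervals are
#' not significant.
#'
#' @param fit_a,fit_b `vc_fit` objects, or numeric length-2 intervals.
#' @param parameter `"b"` (P50) or `"S"` (slope); ignored when raw intervals
#'   are supplied.
#' @return `"significant"` or `"not_significant"`.
#' @export
compare_by_ci_overlap <- function(fit_a, fit_b, parameter = c("b", "S")) {
  parameter <- match.arg(parameter)
  ia <- ci_of(fit_a, parameter)
  ib <- ci_of(fit_b, parameter)
  disjoint <- ia[2] < ib[1] || ib[2] < ia[1]
  if (disjoint) "significant" else "not_significant"
}

ci_of <- function(x, parameter) {
  if (inherits(x, "vc_fit")) {
    if (!isTRUE(x$converged)) abort("fit has not converged; no usable confidence interval")
    if (parameter == "b") x$ci95_b else x$ci95_S
  } else if (is.numeric(x) && length(x) == 2L) {
    sort(x)
  } else {
    abort("expected a `vc_fit` or a numeric length-2 interval")
  }
}

#' Case-resampling bootstrap confidence intervals for a vulnerability fit
#'
#' Refits the sigmoid to observation-level resamples and returns percentile
#' intervals -- an alternative to the Wald intervals when the residual
#' distribution is in doubt.
#'
#' @param fit A converged `vc_fit`.
#' @param reps Number of bootstrap resamples.
#' @param seed Optional integer seed.
#' @param level Confidence level.
#' @return A list with `ci_b`, `ci_S` (percentile intervals) and the number
#'   of resamples that produced a converged refit (`n_used`).
#' @export
vc_bootstrap_ci <- function(fit, reps = 1999, seed = NULL, level = 0.95) {
  stopifnot(inherits(fit, "vc_fit"))
  if (!isTRUE(fit$converged)) abort("cannot bootstrap a non-converged fit")
  d <- fit$data
  n <- nrow(d)
  with_seed(seed, {
    est <- vapply(seq_len(reps), function(r) {
      idx <- sample.int(n, n, replace = TRUE)
      f <- tryCatch(
        suppressWarnings(fit_vulnerability_curve(d[idx, , drop = FALSE])),
        error = function(e) NULL
      )
      if (!is.null(f) && isTRUE(f$converged)) c(f$b_MPa, f$S) else c(NA, NA)
    }, numeric(2))
    a <- (1 - level) / 2
    list(
      ci_b = unname(quantile(est[1, ], c(a, 1 - a), na.rm = TRUE)),
      ci_S = unname(quantile(est[2, ], c(a, 1 - a), na.rm = TRUE)),
      n_used = sum(!is.na(est[1, ]))
    )
  })
}

#' Mean per-branch P50 for centrifuge datasets
#'
#' Fits one vulnerability curve per branch and averages the P50s -- the
#' reporting convention for flow-centrifuge measurements, where each branch
#' segment yields its own curve. The returned interval is the t-based 95% CI
#' of the mean across branches.
#'
#' @param data Data frame with `psi_MPa`, `plc_percent` and a branch
#'   identifier column.
#' @param branch Unquoted name of the branch identifier column.
#' @return A tibble with `n_branches`, `b_MPa` (mean), `b_se`, `ci95_lo`,
#'   `ci95_hi`, and a list-column `fits` of the per-branch `vc_fit`s.
#' @export
p50_by_branch <- function(data, branch = branch) {
  stopifnot(is.data.frame(data))
  groups <- dplyr::group_split(dplyr::group_by(data, {{ branch }}))
  fits <- purrr::map(groups, fit_vulnerability_curve)
  ok <- purrr::map_lgl(fits, "converged")
  if (!all(ok)) {
    warn(paste(sum(!ok), "of", length(fits), "per-branch fits did not converge; excluded from the mean"))
  }
  b <- purrr::map_dbl(fits[ok], "b_MPa")
  k <- length(b)
  if (k == 0L) abort("no per-branch fit converged")
  se <- if (k > 1) sd(b) / sqrt(k) else NA_real_
  half <- if (k > 1) qt(0.975, k - 1) * se else NA_real_
  tibble::tibble(
    n_branches = k, b_MPa = mean(b), b_se = se,
    ci95_lo = mean(b) - half, ci95_hi = mean(b) + half,
    fits = list(fits)
  )
}
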