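# Locus-level sigmoid fitting and scaling.  Each background-normalized
# locus series is fitted with value(t) = B + A * t^n / (t^n + t0^n):
# B is the locus-specific differential background at t = 0, A the fitted
# asymptote above B, and t0 the response time (half-rise) that combines
# induction and turnover delay.  Subtracting B and multiplying by
# alpha = rho_inf / A (the relative antibody affinity) maps the series
# onto the in-vivo occupancy-ratio scale where the kinetic theory's
# boundary conditions hold: 0 at t = 0 and rho_inf at steady state.

#' Fit a Hill sigmoid with additive background to a locus series
#'
#' @param series A locus series: list/data frame with `times` (minutes,
#'   including 0) and `values` (background-normalized ratios); at least 5
#'   time points.
#' @param hill_n Fixed Hill exponent (default 4).
#' @param rho_inf Optional global saturation concentration ratio; when
#'   supplied the scale factor `alpha = rho_inf / amplitude` is filled in.
#' @param t0_bounds Allowed response-time range in minutes for the fit.
#' @return Object of class `locus_scaling_fit`: list with `B`, `amplitude`,
#'   `t0`, `t0_se`, `alpha`, `rss`, `n_points`, `converged` and `usable`
#'   (`FALSE` when the fit did not converge or the amplitude is not
#'   positive).  Non-convergence is flagged, never thrown.
#' @export
fit_locus_sigmoid <- function(series, hill_n = 4L, rho_inf = NULL,
                              t0_bounds = c(1, 500)) {
  t <- as.numeric(series$times)
  y <- as.numeric(series$values)
  stopifnot(length(t) == length(y))
  if (length(t) < 5L) stop("need at least 5 time points", call. = FALSE)
  if (!any(t == 0)) stop("series must include t = 0", call. = FALSE)
  n <- as.integer(hill_n)

  B0 <- mean(y[t == 0])
  A0 <- max(max(y) - B0, 1e-3)
  t00 <- min(max(half_rise_time(t, y, base = B0, top = max(y)),
                 t0_bounds[1]), t0_bounds[2])
  df <- data.frame(t = t, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ B + A * t^n / (t^n + t0^n),
      data = df,
      start = list(B = B0, A = A0, t0 = t00),
      lower = c(B = -Inf, A = 1e-8, t0 = t0_bounds[1]),
      upper = c(B = Inf, A = Inf, t0 = t0_bounds[2]),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)

  if (is.null(fit)) {
    out <- list(locus_id = series$locus_id %||% NA_character_,
                B = NA_real_, amplitude = NA_real_, t0 = NA_real_,
                t0_se = NA_real_, alpha = NA_real_, rss = NA_real_,
                n_points = length(t), converged = FALSE, usable = FALSE)
    class(out) <- "locus_scaling_fit"
    return(out)
  }
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))),
                 error = function(e) c(B = NA, A = NA, t0 = NA))
  amplitude <- unname(est[["A"]])
  out <- list(
    locus_id = series$locus_id %||% NA_character_,
    B = unname(est[["B"]]),
    amplitude = amplitude,
    t0 = unname(est[["t0"]]),
    t0_se = unname(se[["t0"]]),
    alpha = if (!is.null(rho_inf)) rho_inf / amplitude else NA_real_,
    rss = sum(resid(fit)^2),
    n_points = length(t),
    converged = isTRUE(fit$convInfo$isConv %||% TRUE),
    usable = amplitude > 0)
  out$usable <- out$usable && out$converged
  class(out) <- "locus_scaling_fit"
  out
}

#' @export
print.locus_scaling_fit <- function(x, ...) {
  cat(sprintf(
    "locus sigmoid fit: B = %.4g, amplitude = %.4g, t0 = %.4g min (se %.3g), rss = %.3g%s\n",
    x$B, x$amplitude, x$t0, x$t0_se, x$rss,
    if (x$usable) "" else "  [UNUSABLE]"))
  invisible(x)
}

#' Scale a locus series to the in-vivo occupancy-ratio boundary conditions
#'
#' Subtracts the locus-specific background `B` and multiplies by
#' `alpha = rho_inf / amplitude` so that the fitted value at `t = 0` is 0
#' and the fitted asymptote equals `rho_inf`, as the kinetic theory
#' requires.
#'
#' @param series The locus series that was fitted.
#' @param fit Its [fit_locus_sigmoid()] result (must be usable).
#' @param rho_inf Global saturation concentration ratio from the induction
#'   fit.
#' @param sd_check Flag loci whose scaled `t = 0` value deviates from 0 by
#'   more than this many fitted-noise SDs (default 3); stored in
#'   `boundary_ok`, never silently dropped.
#' @return Object of class `scaled_locus_series`: list with `locus_id`,
#'   `times`, `values`, `alpha`, `B` and `boundary_ok`.
#' @export
scale_series <- function(series, fit, rho_inf, sd_check = 3) {
  stopifnot(inherits(fit, "locus_scaling_fit"))
  check_positive(rho_inf)
  if (!isTRUE(fit$usable)) {
    stop(structure(
      class = c("unusable_locus_fit", "error", "condition"),
      list(message = "locus fit unconverged or amplitude <= 0; locus excluded",
           call = sys.call(-1))))
  }
  alpha <- rho_inf / fit$amplitude
  t <- as.numeric(series$times)
  v <- alpha * (as.numeric(series$values) - fit$B)
  noise_sd <- sqrt(fit$rss / max(fit$n_points - 3L, 1L)) * alpha
  boundary_ok <- all(abs(v[t == 0]) <= sd_check * max(noise_sd, 1e-12))
  structure(
    list(locus_id = series$locus_id %||% NA_character_,
         times = t, values = v, alpha = alpha, B = fit$B,
         boundary_ok = boundary_ok),
    class = "scaled_locus_series")
}

#' Percent error of the fitted response time
#'
#' `100 * t0_se / t0`, the fit-precision summary used to screen loci.
#'
#' @param fit A usable [fit_locus_sigmoid()] result.
#' @return Percent error (scalar).
#' @export
t0_percent_error <- function(fit) {
  stopifnot(inherits(fit, "locus_scaling_fit"))
  if (!is.finite(fit$t0) || fit$t0 <= 0) {
    stop("t0 must be positive and finite", call. = FALSE)
  }
  100 * fit$t0_se / fit$t0
}

#' Reliability screen for a fitted locus
#'
#' A locus enters kinetic fitting only if its sigmoid fit converged, its
#' response time exceeds the resolution threshold (below `t0_min` the
#' series is indistinguishable from the induction curve within noise), its
#' residuals are small relative to the squared dynamic range, and its
#' response time is precisely determined.
#'
#' @param fit A [fit_locus_sigmoid()] result.
#' @param t0_min Minimum resolvable response time, minutes (default 24.5).
#' @param max_relative_rss Maximum `rss / (n_points * rho_inf^2)`.  The
#'   default 0.001 sits a factor ~2.5 above the residual level expected
#'   from ~0.1-log2 replicate noise (the platform's typical scale), so
#'   routine data pass while series whose noise makes the response time
#'   unidentifiable are rejected.
#' @param max_pct_err Maximum percent error in `t0` (default 50).
#' @param rho_inf Saturation ratio used to normalise the residuals.
#' @return List with logical `pass` and character vector `reasons`
#'   (empty when passing).
#' @export
reliability_filter <- function(fit, t0_min = 24.5, max_relative_rss = 0.001,
                               max_pct_err = 50, rho_inf = 2.23) {
  stopifnot(inherits(fit, "locus_scaling_fit"))
  reasons <- character()
  if (!isTRUE(fit$converged)) reasons <- c(reasons, "fit did not converge")
  if (!isTRUE(fit$usable)) reasons <- c(reasons, "non-positive amplitude")
  if (isTRUE(fit$converged)) {
    if (is.finite(fit$t0) && fit$t0 < t0_min) {
      reasons <- c(reasons, "t0 below resolution threshold")
    }
    rel_rss <- fit$rss / (fit$n_points * rho_inf^2)
    if (!is.finite(rel_rss) || rel_rss > max_relative_rss) {
      reasons <- c(reasons, "residuals exceed noise criterion")
    }
    pct <- if (is.finite(fit$t0_se)) 100 * fit$t0_se / fit$t0 else Inf
    if (pct > max_pct_err) {
      reasons <- c(reasons, "t0 percent error too large")
    }
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}
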