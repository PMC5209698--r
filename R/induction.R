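# Induction-curve model: the ratio rho(t) of soluble competitor to
# endogenous TF concentration after induction, modelled as a Hill-like
# sigmoid that is zero at t = 0, rises with positive then negative
# curvature, and saturates at rho_inf.  t_ind is exactly the
# half-saturation time.

#' Construct a Hill-form induction curve
#'
#' Represents the ratio \eqn{\rho(t) = C_B(t)/C_A} of soluble competitor to
#' endogenous transcription-factor concentration as
#' \deqn{\rho(t) = \rho_\infty \frac{t^n}{t^n + t_{ind}^n}}
#' so that \eqn{\rho(0) = 0}, \eqn{\rho(t_{ind}) = \rho_\infty/2} and
#' \eqn{\rho \to \rho_\infty} monotonically.
#'
#' @param rho_inf Saturation concentration ratio (dimensionless, > 0).
#'   Default 2.23, the fitted value for the TBP competitor system.
#' @param t_ind Half-saturation (induction) time in minutes (> 0).
#'   Default 22 min.
#' @param hill_n Positive integer Hill exponent, held fixed (default 4).
#' @return An object of class `induction_curve`.
#' @examples
#' curve <- induction_curve()
#' eval_induction(curve, c(0, 22, 70))
#' @export
induction_curve <- function(rho_inf = 2.23, t_ind = 22, hill_n = 4L) {
  check_positive(rho_inf)
  check_positive(t_ind)
  if (!is.numeric(hill_n) || length(hill_n) != 1L || hill_n < 1 ||
      hill_n != round(hill_n)) {
    stop("`hill_n` must be a positive integer", call. = FALSE)
  }
  structure(
    list(rho_inf = as.numeric(rho_inf), t_ind = as.numeric(t_ind),
         hill_n = as.integer(hill_n),
         rho_inf_se = NA_real_, t_ind_se = NA_real_,
         rss = NA_real_, converged = TRUE),
    class = "induction_curve"
  )
}

#' @export
print.induction_curve <- function(x, ...) {
  cat(sprintf(
    "Hill induction curve: rho_inf = %.4g (se %.3g), t_ind = %.4g min (se %.3g), n = %d\n",
    x$rho_inf, x$rho_inf_se, x$t_ind, x$t_ind_se, x$hill_n))
  invisible(x)
}

#' Evaluate an induction curve
#'
#' @param curve An [induction_curve()].
#' @param t Times in minutes (>= 0); vectorised.
#' @return \eqn{\rho(t)}, dimensionless; 0 at `t = 0` and
#'   `rho_inf / 2` at `t = t_ind` exactly.
#' @export
eval_induction <- function(curve, t) {
  stopifnot(inherits(curve, "induction_curve"))
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("times must be finite and >= 0", call. = FALSE)
  }
  tn <- t^curve$hill_n
  curve$rho_inf * tn / (tn + curve$t_ind^curve$hill_n)
}

# Coerce an induction specification (curve object or plain function of t)
# into a rho(t) function.  Internal: lets the kinetics layer accept step
# inductions and other analytic profiles in oracle tests.
as_rho_function <- function(induction) {
  if (inherits(induction, "induction_curve")) {
    function(t) eval_induction(induction, t)
  } else if (is.function(induction)) {
    induction
  } else {
    stop("`induction` must be an induction_curve or a function of time",
         call. = FALSE)
  }
}

#' Fit the induction curve to concentration-ratio measurements
#'
#' Least-squares fit of the Hill-form induction curve to measured
#' competitor/endogenous concentration ratios (e.g. quantified Western
#' blots) with the Hill exponent held fixed.  Starting values are analytic:
#' `rho_inf` from the maximum observed ratio and `t_ind` from the first
#' half-maximum crossing by linear interpolation.
#'
#' @param data Data frame with columns `time_min` (>= 0) and `ratio`
#'   (>= 0); at least 4 distinct times are required.
#' @param hill_n Fixed Hill exponent (default 4).
#' @return An `induction_curve` whose `rho_inf_se`, `t_ind_se`, `rss` and
#'   `converged` fields are filled from the fit.
#' @export
fit_induction <- function(data, hill_n = 4L) {
  stopifnot(is.data.frame(data), all(c("time_min", "ratio") %in% names(data)))
  t <- as.numeric(data$time_min)
  y <- as.numeric(data$ratio)
  if (any(!is.finite(t)) || any(!is.finite(y))) {
    stop("times and ratios must be finite", call. = FALSE)
  }
  check_nonnegative(t, "time_min")
  check_nonnegative(y, "ratio")
  if (length(unique(t)) < 4L) {
    stop("at least 4 distinct time points are needed to fit (rho_inf, t_ind)",
         call. = FALSE)
  }
  n <- as.integer(hill_n)

  rho0 <- max(y)
  t0 <- half_rise_time(t, y, base = 0, top = rho0)
  starts <- list(
    c(rho_inf = rho0, t_ind = t0),
    c(rho_inf = rho0 * 1.2, t_ind = t0 * 0.5),
    c(rho_inf = rho0 * 1.2, t_ind = t0 * 2),
    c(rho_inf = rho0, t_ind = max(t) / 2)
  )
  df <- data.frame(t = t, y = y)
  fit <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ rho_inf * t^n / (t^n + t_ind^n),
        data = df,
        start = as.list(st),
        lower = c(rho_inf = 1e-8, t_ind = 1e-3),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    stop(structure(
      class = c("induction_fit_error", "error", "condition"),
      list(message = sprintf(
             "induction fit failed to converge after %d restarts (n = %d points)",
             length(starts), nrow(df)),
           call = sys.call(-1))))
  }
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) {
    c(rho_inf = NA_real_, t_ind = NA_real_)
  })
  out <- induction_curve(est[["rho_inf"]], est[["t_ind"]], n)
  out$rho_inf_se <- unname(se[["rho_inf"]])
  out$t_ind_se <- unname(se[["t_ind"]])
  out$rss <- sum(resid(fit)^2)
  out$converged <- fit$convInfo$isConv %||% TRUE
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# First time at which y crosses base + (top - base)/2, by linear
# interpolation on the sorted series; falls back to the median time.
half_rise_time <- function(t, y, base, top) {
  o <- order(t)
  t <- t[o]; y <- y[o]
  half <- base + (top - base) / 2
  idx <- which(y >= half)
  if (!length(idx) || idx[1] == 1L) return(max(median(t), 1e-3))
  i <- idx[1]
  t0 <- t[i - 1] + (half - y[i - 1]) / (y[i] - y[i - 1]) * (t[i] - t[i - 1])
  max(t0, 1e-3)
}

#' Read induction measurements from a tab-delimited file
#'
#' Expects a header `time_min<TAB>ratio`; lines starting with `#` are
#' ignored.
#'
#' @param path File path.
#' @return Data frame with columns `time_min` and `ratio`.
#' @export
read_induction_table <- function(path) {
  df <- read_tsv(path)
  if (!all(c("time_min", "ratio") %in% names(df))) {
    stop("induction table must have columns `time_min` and `ratio`",
         call. = FALSE)
  }
  df
}
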