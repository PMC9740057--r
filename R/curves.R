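#' Gamma-variate tissue concentration curve
#'
#' Model-free perfusion metrics in this package integrate the tissue
#' contrast-agent concentration curve C(t).  The phantom generates C(t) as a
#' gamma variate, `C(t) = A * t^shape * exp(-t / scale)`, the classical
#' smooth bolus-passage form whose exponential tail plays the role of the
#' washout.  Its running integral has the closed form
#' `A * scale^(shape+1) * Gamma(shape+1) * P(shape+1, t/scale)` (lower
#' regularized incomplete gamma `P`), which serves as the analytic oracle
#' for trapezoidal area-under-curve estimates.
#'
#' @param times_s Sample times in seconds since injection (non-negative).
#' @param amplitude Curve amplitude `A` (>= 0); 0 gives the flat zero curve.
#' @param shape Dimensionless uptake sharpness (> 0). Default 3.
#' @param scale_s Washout time constant (s, > 0).
#' @return Concentration in mmol/L at `times_s`; `C(0) = 0`, all values >= 0.
#' @examples
#' tt <- seq(0, 300, by = 3.6)
#' cc <- gamma_variate_conc(tt, amplitude = 2e-4, scale_s = 14)
#' @export
gamma_variate_conc <- function(times_s, amplitude, shape = 3, scale_s) {
  if (amplitude < 0) stop("amplitude must be non-negative")
  if (shape <= 0 || scale_s <= 0) stop("shape and scale_s must be positive")
  if (any(times_s < 0)) stop("times_s must be non-negative")
  if (amplitude == 0) return(numeric(length(times_s)) * 0 + 0)
  amplitude * times_s^shape * exp(-times_s / scale_s)
}

#' Closed-form area under a gamma-variate curve
#'
#' Analytic integral of [gamma_variate_conc()] over `(0, window_s]`,
#' reported in mmol/L * min (time converted from seconds to minutes), the
#' unit convention used for the AUC30/AUC300 perfusion surrogates.
#'
#' @inheritParams gamma_variate_conc
#' @param window_s Upper integration limit (s, > 0).
#' @return Area in mmol/L * min.
#' @export
gamma_variate_auc <- function(amplitude, shape = 3, scale_s, window_s) {
  if (amplitude < 0) stop("amplitude must be non-negative")
  if (shape <= 0 || scale_s <= 0) stop("shape and scale_s must be positive")
  if (window_s <= 0) stop("window_s must be positive")
  a <- shape + 1
  amplitude * gamma(a) * scale_s^a *
    stats::pgamma(window_s, shape = a, rate = 1 / scale_s) / 60
}

#' Solve gamma-variate parameters from target AUC30 and AUC300
#'
#' Given target areas over the first 30 s and 300 s after injection, find
#' the washout constant by 1-D root finding on the incomplete-gamma ratio
#' (which is monotone in the scale) and then the amplitude by linear
#' scaling.  This is how the phantom presets turn printed AUC pairs into an
#' analytically integrable ground-truth curve.
#'
#' @param auc30,auc300 Target areas (mmol/L * min), `auc300 >= auc30 >= 0`.
#' @param shape Fixed uptake sharpness; see [gamma_variate_conc()].
#' @return List with elements `amplitude`, `shape`, `scale_s`.
#' @examples
#' cp <- solve_curve_params(0.067, 0.193)
#' gamma_variate_auc(cp$amplitude, cp$shape, cp$scale_s, 30)   # 0.067
#' @export
solve_curve_params <- function(auc30, auc300, shape = 3) {
  if (auc30 < 0 || auc300 < auc30)
    stop("need auc300 >= auc30 >= 0")
  if (auc30 == 0) {
    if (auc300 > 0) stop("auc300 > 0 requires auc30 > 0 for this curve form")
    return(list(amplitude = 0, shape = shape, scale_s = 10))
  }
  a <- shape + 1
  ratio <- auc300 / auc30
  max_ratio <- 10^a  # scale -> Inf limit: (300/30)^(shape+1)
  if (ratio >= max_ratio * 0.999)
    stop("auc300/auc30 ratio too large for the gamma-variate form")
  f <- function(b) {
    stats::pgamma(300, a, rate = 1 / b) / stats::pgamma(30, a, rate = 1 / b) -
      ratio
  }
  scale_s <- if (ratio <= 1 + 1e-12) 0.5 else
    stats::uniroot(f, c(0.05, 5000), tol = 1e-12)$root
  amplitude <- auc30 / gamma_variate_auc(1, shape, scale_s, 30)
  list(amplitude = amplitude, shape = shape, scale_s = scale_s)
}

#' Evaluate a stored curve-parameter list
#'
#' @param curve_params List with `amplitude`, `shape`, `scale_s`, as produced
#'   by [solve_curve_params()].
#' @param times_s Sample times (s since injection).
#' @return Concentration in mmol/L.
#' @export
tissue_concentration_curve <- function(curve_params, times_s) {
  gamma_variate_conc(times_s, curve_params$amplitude, curve_params$shape,
                     curve_params$scale_s)
}
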