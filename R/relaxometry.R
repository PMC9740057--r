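#' Scalar parameter map
#'
#' A 3D scalar field (T1, T2, ADC, AUC30, ...) with units, a validity mask
#' marking voxels where estimation succeeded, and free-form provenance.
#'
#' @param values 3D numeric array.
#' @param units One of `"ms"`, `"mm2/s"`, `"unitless"`, `"mmol/L*min"`.
#' @param mask 3D logical array; defaults to all finite voxels.
#' @param provenance List of fit metadata.
#' @return A `parameter_map` object.
#' @export
parameter_map <- function(values, units = c("unitless", "ms", "mm2/s",
                                            "mmol/L*min"),
                          mask = NULL, provenance = list()) {
  units <- match.arg(units)
  stopifnot(length(dim(values)) == 3)
  if (is.null(mask)) mask <- is.finite(values)
  stopifnot(identical(dim(mask), dim(values)), is.logical(mask))
  if (any(mask & !is.finite(values)))
    stop("values must be finite wherever the validity mask is TRUE")
  structure(list(values = values, units = units, mask = mask,
                 provenance = provenance),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("Parameter map %s [%s]: %d valid voxels",
              paste(dim(x$values), collapse = " x "), x$units, length(v)))
  if (length(v))
    cat(sprintf(", mean %.4g (sd %.3g)", mean(v), stats::sd(v)))
  cat("\n")
  invisible(x)
}

#' Extract the value array from a map or plain array
#' @param x A [parameter_map()] or numeric array.
#' @return Numeric array.
#' @export
map_values <- function(x) {
  if (inherits(x, "parameter_map")) x$values else x
}

#' Signal stack
#'
#' A 4D stack of volumes acquired while one acquisition variable (flip
#' angle, echo time, or b-value) is swept.
#'
#' @param volumes 4D numeric array, acquisition index last.
#' @param axis_values Per-volume value of the swept variable, strictly
#'   increasing, same length as the 4th dimension.
#' @param axis Name of the swept variable.
#' @param protocol Optional [acq_protocol()] reference.
#' @return A `signal_stack` object.
#' @export
signal_stack <- function(volumes, axis_values,
                         axis = c("flip_angle_deg", "echo_time_ms",
                                  "b_value"),
                         protocol = NULL) {
  axis <- match.arg(axis)
  stopifnot(length(dim(volumes)) == 4)
  if (length(axis_values) != dim(volumes)[4])
    stop("axis_values length must match the number of volumes")
  if (any(diff(axis_values) <= 0))
    stop("axis_values must be strictly increasing")
  structure(list(volumes = volumes, axis_values = as.numeric(axis_values),
                 axis = axis, protocol = protocol),
            class = "signal_stack")
}

#' @export
print.signal_stack <- function(x, ...) {
  cat(sprintf("Signal stack %s: %d volumes of %s (%s = %s)\n",
              x$axis, dim(x$volumes)[4],
              paste(dim(x$volumes)[1:3], collapse = " x "),
              x$axis, paste(signif(x$axis_values, 4), collapse = ", ")))
  invisible(x)
}

# Per-voxel ordinary least squares of Y (nvox x k) on x (k), with NA cells
# excluded sample-wise.  Returns slope/intercept/n per voxel.
.rowwise_ols <- function(Y, x) {
  W <- is.finite(Y)
  Yw <- ifelse(W, Y, 0)
  X <- matrix(x, nrow(Y), length(x), byrow = TRUE)
  Xw <- ifelse(W, X, 0)
  n <- rowSums(W)
  sx <- rowSums(Xw); sy <- rowSums(Yw)
  sxx <- rowSums(Xw^2); sxy <- rowSums(Xw * Yw)
  denom <- sxx - sx^2 / n
  slope <- (sxy - sx * sy / n) / denom
  slope[denom <= 0 | n < 2] <- NA_real_
  intercept <- sy / n - slope * sx / n
  list(slope = slope, intercept = intercept, n = n)
}

.flatten_mask <- function(stack, mask) {
  dims <- dim(stack$volumes)[1:3]
  if (is.null(mask)) {
    mask <- apply(stack$volumes != 0, 1:3, any)
  } else {
    mask <- map_values(mask)
    if (is.numeric(mask)) mask <- mask > 0
    stopifnot(identical(dim(mask), dims))
  }
  mask
}

.empty_map <- function(dims) {
  list(values = array(NA_real_, dims), mask = array(FALSE, dims))
}

#' Fit T1 by the variable-flip-angle method
#'
#' Classical linearized VFA estimator: for each voxel, regress
#' `S/sin(a)` on `S/tan(a)`; the slope is `E1 = exp(-TR/T1)` and the
#' intercept `M0 (1 - E1)`.  Voxels with `E1` outside (0, 1) or T1 outside
#' the plausibility gate are flagged invalid.  With `refine = TRUE` each
#' voxel is polished by 1-D nonlinear least squares on T1 (M0 profiled out
#' in closed form), starting from the linear estimate; this removes the
#' noise bias of the linearized estimator and is recommended for noisy
#' data.
#'
#' @param stack A flip-angle [signal_stack()].
#' @param tr_ms Repetition time (ms); defaults to the stack's protocol.
#' @param mask Optional 3D logical (or numeric) fitting mask; default:
#'   voxels with any non-zero signal.
#' @param refine Run nonlinear refinement (default `FALSE`; the linear
#'   estimator is exact on noiseless data).
#' @param t1_gate Physical plausibility bounds in ms; fits outside are
#'   invalid.
#' @return List with `t1` and `m0` [parameter_map()]s sharing a validity
#'   mask.
#' @export
fit_t1_vfa <- function(stack, tr_ms = NULL, mask = NULL, refine = FALSE,
                       t1_gate = c(1, 10000)) {
  stopifnot(inherits(stack, "signal_stack"),
            stack$axis == "flip_angle_deg")
  if (is.null(tr_ms)) {
    if (is.null(stack$protocol)) stop("tr_ms missing and no protocol on stack")
    tr_ms <- stack$protocol$tr_ms
  }
  if (tr_ms <= 0) stop("tr_ms must be positive")
  angles <- stack$axis_values
  if (length(angles) < 2) stop("need at least 2 flip angles")
  if (any(angles <= 0 | angles >= 90))
    stop("flip angles must lie strictly inside (0, 90) degrees")
  dims <- dim(stack$volumes)[1:3]
  mask <- .flatten_mask(stack, mask)
  idx <- which(mask)
  t1v <- array(NA_real_, dims); m0v <- array(NA_real_, dims)
  valid <- array(FALSE, dims)
  if (length(idx)) {
    S <- matrix(stack$volumes, prod(dims), length(angles))[idx, , drop = FALSE]
    a <- angles * pi / 180
    Ysin <- sweep(S, 2, sin(a), `/`)
    Xtan <- sweep(S, 2, tan(a), `/`)
    # reuse the OLS core by treating Xtan as per-voxel regressor
    n <- ncol(S)
    sx <- rowSums(Xtan); sy <- rowSums(Ysin)
    sxx <- rowSums(Xtan^2); sxy <- rowSums(Xtan * Ysin)
    denom <- sxx - sx^2 / n
    e1 <- (sxy - sx * sy / n) / denom
    e1[denom <= 0] <- NA_real_
    icpt <- sy / n - e1 * sx / n
    ok <- is.finite(e1) & e1 > 0 & e1 < 1
    t1 <- ifelse(ok, -tr_ms / log(e1), NA_real_)
    m0 <- ifelse(ok, icpt / (1 - e1), NA_real_)
    ok <- ok & t1 > t1_gate[1] & t1 < t1_gate[2] & is.finite(m0)
    ok[is.na(ok)] <- FALSE
    if (refine) {
      f_design <- function(t1) .spgr_unit(t1, tr_ms, angles)
      for (j in which(ok)) {
        sj <- S[j, ]
        rss <- function(t1) {
          f <- f_design(t1)
          m <- sum(sj * f) / sum(f * f)
          sum((sj - m * f)^2)
        }
        lo <- max(t1_gate[1], t1[j] / 3)
        hi <- min(t1_gate[2], t1[j] * 3)
        opt <- stats::optimize(rss, c(lo, hi), tol = 1e-4)
        t1[j] <- opt$minimum
        f <- f_design(t1[j])
        m0[j] <- sum(sj * f) / sum(f * f)
      }
    }
    t1v[idx] <- t1; m0v[idx] <- m0
    valid[idx] <- ok
    t1v[!valid] <- NA_real_; m0v[!valid] <- NA_real_
  }
  prov <- list(model = "spgr_vfa", tr_ms = tr_ms, refined = refine)
  list(t1 = parameter_map(t1v, "ms", valid, prov),
       m0 = parameter_map(m0v, "unitless", valid, prov))
}

# Shared log-linear decay fitter: ln S = ln S0 + slope * x, non-positive
# samples excluded voxel-wise (>= 2 usable samples required).  Clamping
# negatives instead would bias the slope.
.fit_loglinear <- function(stack, mask, gate, slope_to_value, units, model) {
  dims <- dim(stack$volumes)[1:3]
  mask <- .flatten_mask(stack, mask)
  idx <- which(mask)
  vv <- array(NA_real_, dims); s0v <- array(NA_real_, dims)
  valid <- array(FALSE, dims)
  if (length(idx)) {
    S <- matrix(stack$volumes, prod(dims),
                length(stack$axis_values))[idx, , drop = FALSE]
    Y <- array(NA_real_, dim(S))
    pos <- S > 0
    Y[pos] <- log(S[pos])
    fit <- .rowwise_ols(Y, stack$axis_values)
    est <- slope_to_value(fit$slope)
    ok <- is.finite(est) & fit$n >= 2 & est >= gate[1] & est < gate[2]
    ok[is.na(ok)] <- FALSE
    vv[idx] <- ifelse(ok, est, NA_real_)
    s0v[idx] <- ifelse(ok, exp(fit$intercept), NA_real_)
    valid[idx] <- ok
  }
  prov <- list(model = model, axis = stack$axis)
  list(value = parameter_map(vv, units, valid, prov),
       s0 = parameter_map(s0v, "unitless", valid, prov))
}

#' Fit T2 from a multi-echo series
#'
#' Log-linear fit of `ln S` against echo time; the slope is `-1/T2`.
#' Voxels with fewer than two positive samples are invalid, as are fits
#' outside the plausibility gate.
#'
#' @param stack An echo-time [signal_stack()].
#' @param mask Optional fitting mask.
#' @param t2_gate Plausibility bounds (ms).
#' @return List with `t2` and `s0` [parameter_map()]s.
#' @export
fit_t2 <- function(stack, mask = NULL, t2_gate = c(1, 2000)) {
  stopifnot(inherits(stack, "signal_stack"), stack$axis == "echo_time_ms")
  if (length(stack$axis_values) < 2) stop("need at least 2 echo times")
  r <- .fit_loglinear(stack, mask, t2_gate,
                      function(sl) ifelse(sl < 0, -1 / sl, NA_real_),
                      "ms", "monoexp_t2")
  list(t2 = r$value, s0 = r$s0)
}

#' Fit the apparent diffusion coefficient
#'
#' Log-linear fit of `ln S` against b-value; the slope is `-ADC`.  A
#' constant signal across b-values legitimately yields ADC = 0.
#'
#' @param stack A b-value [signal_stack()].
#' @param mask Optional fitting mask.
#' @param adc_gate Plausibility bounds (mm^2/s); lower bound inclusive.
#' @return List with `adc` and `s0` [parameter_map()]s.
#' @export
fit_adc <- function(stack, mask = NULL, adc_gate = c(0, 1e-2)) {
  stopifnot(inherits(stack, "signal_stack"), stack$axis == "b_value")
  if (length(stack$axis_values) < 2) stop("need at least 2 b-values")
  r <- .fit_loglinear(stack, mask, adc_gate, function(sl) -sl,
                      "mm2/s", "monoexp_adc")
  list(adc = r$value, s0 = r$s0)
}
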